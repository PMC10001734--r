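panel6 <- tibble::tibble(
  expert = paste0("DM", 1:6),
  label = c(rep("very relevant", 5), "relevant")
)

test_that("expert weights reproduce the six-expert panel and a hand-computed pair", {
  w <- expert_weights(panel6)
  expect_equal(round(w$weight, 6), c(rep(0.171429, 5), 0.142857))
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)

  # hand evaluation: scores 0.9 + 0.05*0.9/0.95 and 0.5 + 0.1*0.5/0.9
  two <- tibble::tibble(expert = c("A", "B"), mu = c(0.9, 0.5),
                        nu = c(0.05, 0.4))
  w2 <- expert_weights(two)
  expect_equal(w2$score, c(0.947368421053, 0.555555555556), tolerance = 1e-9)
  expect_equal(w2$weight, c(0.630350194553, 0.369649805447), tolerance = 1e-9)

  # symmetry: identical experts share the weight equally
  same <- tibble::tibble(expert = letters[1:4], mu = 0.75, nu = 0.2)
  expect_equal(expert_weights(same)$weight, rep(0.25, 4))

  # ordering by score equals ordering by weight
  withr::local_seed(5)
  ifn <- random_ifns(8)
  pn <- tibble::tibble(expert = letters[1:8], mu = ifn$mu, nu = ifn$nu)
  pn <- pn[pn$mu + pn$nu > 0, ]
  ww <- expert_weights(pn)
  expect_equal(order(ww$score), order(ww$weight))

  expect_error(expert_weights(tibble::tibble(expert = "x", mu = 0, nu = 0)),
               class = "ifmcdm_validation_error")
  expect_error(
    expert_weights(tibble::tibble(expert = "x", label = "stupendous")),
    regexp = "stupendous", class = "ifmcdm_validation_error")
})

test_that("judgment aggregation is the per-cell IFWA", {
  elements <- c("A", "B", "C")
  # single expert with weight 1 returns the matrix unchanged
  withr::local_seed(21)
  j1 <- random_judgments(1, elements)
  agg1 <- aggregate_judgments(j1, c(E1 = 1))
  expect_equal(agg1$mu[match(paste(j1$row, j1$col),
                             paste(agg1$row, agg1$col))], j1$mu,
               tolerance = 1e-12)

  # identical experts leave the matrix unchanged (idempotence)
  j3 <- dplyr::bind_rows(
    j1, dplyr::mutate(j1, expert = "E2"), dplyr::mutate(j1, expert = "E3"))
  agg3 <- aggregate_judgments(j3, c(E1 = 0.5, E2 = 0.3, E3 = 0.2))
  expect_equal(agg3$mu, agg1$mu, tolerance = 1e-12)
  expect_equal(agg3$nu, agg1$nu, tolerance = 1e-12)

  # random 3-expert panel equals a per-cell ifwa loop
  jr <- random_judgments(3, elements)
  w <- c(E1 = 0.2, E2 = 0.5, E3 = 0.3)
  agg <- aggregate_judgments(jr, w)
  for (k in seq_len(nrow(agg))) {
    cell <- jr[jr$row == agg$row[k] & jr$col == agg$col[k], ]
    cell <- cell[order(match(cell$expert, names(w))), ]
    orc <- ifwa_log(cell$mu, cell$nu, unname(w))
    expect_equal(agg$mu[k], unname(orc["mu"]), tolerance = 1e-10)
    expect_equal(agg$nu[k], unname(orc["nu"]), tolerance = 1e-10)
  }

  # missing expert weight is an error
  expect_error(aggregate_judgments(jr, c(E1 = 0.5, E2 = 0.5)),
               regexp = "E3", class = "ifmcdm_validation_error")
  # mismatched element sets are an error
  broken <- jr
  broken$col[1] <- "Z"
  expect_error(aggregate_judgments(broken, w), class = "ifmcdm_validation_error")
})

test_that("consistency ratio is zero for ratio matrices and matches power iteration", {
  # matrices built from one weight vector are perfectly consistent
  for (n in 3:9) {
    v <- seq_len(n) + 0.5
    A <- outer(v, v, `/`)
    expect_equal(as.numeric(consistency_ratio(A)), 0, tolerance = 1e-9)
  }
  # CR = 0 for n <= 2 by definition
  expect_equal(as.numeric(consistency_ratio(matrix(c(1, 2, 0.5, 1), 2, 2))), 0)

  # random perturbed reciprocal matrix: eigenvalue matches power iteration
  withr::local_seed(33)
  for (rep in 1:5) {
    v <- stats::runif(4, 0.5, 2)
    A <- outer(v, v, `/`) * exp(stats::rnorm(16, 0, 0.2))
    A[lower.tri(A)] <- 1 / t(A)[lower.tri(A)]
    diag(A) <- 1
    cr <- consistency_ratio(A)
    lambda_oracle <- power_iteration_lambda(A)
    expect_equal(attr(cr, "lambda_max"), lambda_oracle, tolerance = 1e-8)
    expect_equal(as.numeric(cr), ((lambda_oracle - 4) / 3) / 0.90,
                 tolerance = 1e-8)
  }

  # the aggregated healthcare-equipment matrix is consistent (CR < 0.10)
  agg <- load_fixture("table2_h2_aggregated")
  expect_lt(as.numeric(consistency_ratio(agg)), 0.10)

  expect_error(consistency_ratio(outer(1:16, 1:16, `/`)),
               class = "ifmcdm_validation_error") # no RI for n = 16
})

test_that("row IFNs of the aggregated matrix match the printed weight table", {
  agg <- load_fixture("table2_h2_aggregated")
  rows <- row_ifn(agg)
  expect_equal(rows$element, c("SH6", "SH7", "SH8"))
  expect_equal(round(rows$mu, 3), c(0.083, 0.084, 0.103))
  expect_equal(round(rows$nu, 3), c(0.195, 0.186, 0.177))
  # a row of identical IFNs collapses to that IFN
  one <- tibble::tibble(row = rep("X", 2), col = c("X", "Y"),
                        mu = 0.3, nu = 0.55)
  got <- row_ifn(one)
  expect_equal(got$mu, 0.3)
  expect_equal(got$nu, 0.55)
})

test_that("entropy weights match direct formula evaluation and are permutation-invariant", {
  # identical IFNs give equal weights
  eq <- tibble::tibble(element = letters[1:4], mu = 0.3, nu = 0.5)
  expect_equal(entropy_weights(eq)$weight, rep(0.25, 4))

  # frozen two-element case evaluated with a scalar calculator:
  # (0.4, 0.4, 0.2) has entropy exactly 1, so all weight goes to the second
  two <- tibble::tibble(element = c("a", "b"), mu = c(0.4, 0.1),
                        nu = c(0.4, 0.8))
  got <- entropy_weights(two)
  expect_equal(got$entropy, c(1, 0.552932501298), tolerance = 1e-9)
  expect_equal(got$weight, c(0, 1), tolerance = 1e-9)

  # permutation invariance
  withr::local_seed(77)
  ifn <- random_ifns(6)
  df <- tibble::tibble(element = letters[1:6], mu = ifn$mu, nu = ifn$nu)
  w1 <- entropy_weights(df)
  p <- sample(6)
  w2 <- entropy_weights(df[p, ])
  expect_equal(w2$weight[match(w1$element, w2$element)], w1$weight,
               tolerance = 1e-12)
  expect_equal(sum(w1$weight), 1, tolerance = 1e-9)
})

test_that("global weights compose local and parent priorities", {
  t4 <- load_fixture("table4_weights")
  crit_rows <- t4[t4$level == "criterion", ]
  sub_rows <- t4[t4$level == "subcriterion", ]
  parent <- tibble::tibble(element = crit_rows$code, weight = crit_rows$overall)
  children <- tibble::tibble(parent = sub_rows$parent, element = sub_rows$code,
                             weight = sub_rows$local)
  gw <- global_weights(children, parent)
  expect_equal(sum(gw$global), 1, tolerance = 1e-6)
  # raw products reproduce the printed overall weights within the precision
  # two 3-d.p. roundings allow (one printed cell, SH18, rounds the other way)
  raw <- global_weights(children, parent, renormalize = FALSE)
  printed <- t4$overall[t4$level == "subcriterion"]
  expect_lt(max(abs(raw$global - printed)), 7.5e-4)
  expect_equal(round(raw$global[raw$element == "SH8"], 3), 0.043)
  expect_equal(round(raw$global[raw$element == "SH6"], 3), 0.038)

  # single criterion of weight 1 leaves the local weights unchanged
  solo <- global_weights(
    tibble::tibble(parent = "C", element = c("x", "y"), weight = c(0.4, 0.6)),
    tibble::tibble(element = "C", weight = 1))
  expect_equal(solo$global, c(0.4, 0.6))

  expect_error(
    global_weights(
      tibble::tibble(parent = "nope", element = "x", weight = 1), parent),
    regexp = "orphan", class = "ifmcdm_validation_error")
})

test_that("the if_ahp pipeline flags inconsistency and yields unit global weights", {
  withr::local_seed(9)
  crit <- generate_panel(4, c("H1", "H2"), type = "ahp", noise = 0.05)
  s1 <- generate_panel(4, c("S1", "S2", "S3"), type = "ahp", noise = 0.05)
  s2 <- generate_panel(4, c("S4", "S5"), type = "ahp", noise = 0.05)
  judg <- dplyr::bind_rows(
    dplyr::mutate(crit$judgments, cluster = "criteria"),
    dplyr::mutate(s1$judgments, cluster = "H1"),
    dplyr::mutate(s2$judgments, cluster = "H2"))
  fit <- if_ahp(judg, crit$panel)
  td <- tidy(fit)
  expect_equal(sum(td$global[td$cluster != "criteria"]), 1, tolerance = 1e-6)
  expect_true(all(td$local >= 0))
  expect_true(all(fit$clusters$cr < 0.1))
  expect_equal(glance(fit)$n_experts, 4L)

  # an inconsistent matrix warns but still reports
  bad <- tibble::tibble(
    expert = "E1",
    row = rep(c("A", "B", "C"), each = 3),
    col = rep(c("A", "B", "C"), 3),
    # memberships imply wildly intransitive ratios
    mu = c(0.4, 0.8, 0.0, 0.0, 0.4, 0.8, 0.8, 0.0, 0.4),
    nu = c(0.4, 0.1, 0.9, 0.9, 0.4, 0.1, 0.1, 0.9, 0.4))
  expect_warning(
    fit_bad <- if_ahp(bad, tibble::tibble(expert = "E1", mu = 0.9, nu = 0.05)),
    regexp = "inconsistent")
  expect_false(all(fit_bad$clusters$consistent))
})

test_that("zero-noise synthetic panels are perfectly consistent and recoverable", {
  gp <- generate_panel(5, c("A", "B", "C", "D"), type = "ahp",
                       noise = 0, seed = 123)
  agg <- aggregate_judgments(gp$judgments, expert_weights(gp$panel))
  expect_equal(as.numeric(consistency_ratio(agg)), 0, tolerance = 1e-9)
  rec <- eigen_weights(agg)
  expect_equal(rec$weight, gp$priorities / sum(gp$priorities),
               tolerance = 1e-6)
  # determinism: same seed, same panel
  gp2 <- generate_panel(5, c("A", "B", "C", "D"), type = "ahp",
                        noise = 0, seed = 123)
  expect_identical(gp, gp2)
  # low noise stays comfortably consistent
  gl <- generate_panel(6, c("A", "B", "C", "D", "E"), type = "ahp",
                       noise = 0.05, seed = 7)
  aggl <- aggregate_judgments(gl$judgments, expert_weights(gl$panel))
  expect_lt(as.numeric(consistency_ratio(aggl)), 0.1)
})
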