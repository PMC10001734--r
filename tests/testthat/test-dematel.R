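test_that("influence defuzzification chains the two operators and zeroes the diagonal", {
  j <- load_fixture("table5_expert1_influence")
  j$expert <- "E1"
  got <- defuzzify_influence(j)
  # scale pairs map to the printed crisp values
  expect_equal(got$crisp[got$row == "SH19" & got$col == "SH20"], 3.6)
  expect_equal(got$crisp[got$row == "SH19" & got$col == "SH21"], 3.1)
  expect_equal(got$crisp[got$row == "SH20" & got$col == "SH21"], 2.1)
  expect_equal(got$crisp[got$row == got$col], rep(0, 4))

  # an all-"no influence" grid crisps to 0.4 off-diagonal
  el <- c("a", "b", "c")
  grid <- expand.grid(row = el, col = el, stringsAsFactors = FALSE)
  uni <- tibble::tibble(expert = "E1", row = grid$row, col = grid$col,
                        label = "no influence")
  gu <- defuzzify_influence(uni)
  expect_equal(sort(unique(gu$crisp)), c(0, 0.4))

  # random grid equals the composition of the two core operators
  withr::local_seed(13)
  ifn <- random_ifns(9)
  rnd <- tibble::tibble(expert = "E1", row = grid$row, col = grid$col,
                        mu = ifn$mu, nu = ifn$nu)
  gr <- defuzzify_influence(rnd)
  off <- gr$row != gr$col
  expect_equal(gr$crisp[off],
               defuzzify_crisp(to_standard_fuzzy(gr$mu[off], gr$nu[off]),
                               c(0, 4)),
               tolerance = 1e-12)
})

test_that("direct-relation aggregation is the unweighted cell mean", {
  m1 <- matrix(c(0, 3.6, 3.1, 0), 2, 2, byrow = TRUE)
  m2 <- matrix(c(0, 3.1, 2.1, 0), 2, 2, byrow = TRUE)
  expect_equal(aggregate_direct_relation(list(m1)), m1)
  expect_equal(aggregate_direct_relation(list(m1, m2))[1, 2], 3.35)
  # six synthetic experts match an explicit accumulation loop
  withr::local_seed(14)
  grids <- lapply(1:6, function(i) matrix(stats::runif(16, 0, 4), 4, 4))
  got <- aggregate_direct_relation(grids)
  acc <- matrix(0, 4, 4)
  for (g in grids) acc <- acc + g / 6
  expect_equal(got, acc, tolerance = 1e-12)
  expect_error(aggregate_direct_relation(list(m1, matrix(0, 3, 3))),
               class = "ifmcdm_validation_error")
})

test_that("convergence index is the mean absolute relative change", {
  m <- matrix(2, 3, 3); diag(m) <- 0
  expect_equal(convergence_index(m, m), 0)
  m2 <- matrix(2.1, 3, 3); diag(m2) <- 0
  expect_equal(convergence_index(m, m2), 0.05) # |2 - 2.1| / 2
  # sequential aggregation over a random panel matches a double loop
  withr::local_seed(15)
  grids <- lapply(1:6, function(i) {
    g <- matrix(stats::runif(25, 0.5, 4), 5, 5); diag(g) <- 0; g
  })
  zp <- aggregate_direct_relation(grids)
  zp1 <- aggregate_direct_relation(grids[1:5])
  got <- convergence_index(zp, zp1)
  acc <- 0; cnt <- 0
  for (i in 1:5) for (j in 1:5) if (i != j) {
    acc <- acc + abs(zp[i, j] - zp1[i, j]) / zp[i, j]; cnt <- cnt + 1
  }
  expect_equal(got, acc / cnt, tolerance = 1e-12)
  # zero reference cells are skipped with a warning
  zz <- zp; zz[1, 2] <- 0
  expect_warning(convergence_index(zz, zp1), regexp = "skipped")
})

test_that("normalization divides by the max row/column sum", {
  Z <- load_fixture("table8_human_talent_Z")
  N <- normalize_direct_relation(Z)
  expect_equal(attr(N, "s"), 9.3)
  expect_equal(round(N["SH19", "SH20"], 3), 0.324)
  expect_true(all(rowSums(N) <= 1 + 1e-12) && all(colSums(N) <= 1 + 1e-12))
  # the printed total-influence body matches N from the exact-sixths
  # aggregate cell for cell (3 d.p.)
  body <- load_fixture("table10_total_influence_body")
  N6 <- normalize_direct_relation(human_talent_Z_exact())
  expect_equal(round(unclass(N6), 3), body, ignore_attr = TRUE)
  # single nonzero cell becomes 1; N * s recovers Z exactly
  one <- matrix(c(0, 2.5, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(normalize_direct_relation(one)[1, 2], 1)
  withr::local_seed(16)
  R <- matrix(stats::runif(16), 4, 4)
  NR <- normalize_direct_relation(R)
  expect_equal(unclass(NR) * attr(NR, "s"), R, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(normalize_direct_relation(matrix(0, 2, 2)),
               class = "ifmcdm_numeric_error")
})

test_that("total influence solves the Neumann series and conserves totals", {
  zero <- matrix(0, 3, 3)
  expect_equal(unclass(total_influence(zero)), zero, ignore_attr = TRUE)
  # random contractive matrices match the truncated series oracle
  withr::local_seed(17)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    N <- matrix(stats::runif(n * n), n, n)
    N <- N / max(c(rowSums(N), colSums(N))) * stats::runif(1, 0.3, 0.95)
    radius <- max(Mod(eigen(N, only.values = TRUE)$values))
    if (radius >= 0.95) next
    Tm <- total_influence(N)
    expect_equal(unclass(Tm), neumann_series(N, 2000), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # fixed point T = N + N T
    expect_equal(unclass(Tm), N + N %*% Tm, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(Tm >= N - 1e-12))
    # conservation: total dispatched equals total received
    pr <- prominence_relation(Tm)
    expect_equal(sum(pr$D), sum(pr$R), tolerance = 1e-6)
    expect_equal(sum(pr$D), sum(Tm), tolerance = 1e-6)
  }
  # divergent normalization errors with the radius reported
  hot <- matrix(1, 2, 2)
  expect_error(total_influence(hot), regexp = "spectral radius",
               class = "ifmcdm_numeric_error")
})

test_that("the human-talent chain reproduces the printed prominence table", {
  # the printed aggregate stores exact sixths at 3 d.p.; verify then use them
  Z6 <- human_talent_Z_exact()
  expect_equal(round(Z6, 3), load_fixture("table8_human_talent_Z"),
               ignore_attr = TRUE)
  Tm <- total_influence(normalize_direct_relation(Z6))
  pr <- prominence_relation(Tm)
  expect_equal(round(pr$D, 3), c(16.532, 17.222, 15.898, 16.256))
  expect_equal(round(pr$R, 3), c(16.394, 16.377, 16.973, 16.164))
  expect_equal(round(pr$prominence, 3), c(32.926, 33.599, 32.871, 32.420))
  expect_equal(round(pr$relation, 3), c(0.138, 0.844, -1.075, 0.093))
  expect_equal(pr$role, c("dispatcher", "dispatcher", "receiver", "dispatcher"))
  sig <- significant_links(Tm)
  expect_equal(round(sig$theta, 3), 4.119)
  # printed reference margins agree to the printed precision
  margins <- load_fixture("table10_margins")
  expect_equal(round(pr$D, 3), margins$D)
  expect_equal(round(pr$R, 3), margins$R)
})

test_that("prominence classification uses the strict dispatcher rule", {
  sym <- matrix(c(0.1, 0.3, 0.3, 0.1), 2, 2)
  pr <- prominence_relation(sym)
  expect_equal(pr$relation, c(0, 0))
  expect_equal(pr$role, c("receiver", "receiver")) # boundary goes to receiver
})

test_that("significant links use a strict threshold and are antitone in it", {
  uni <- matrix(0.7, 3, 3)
  sig <- significant_links(uni)
  expect_equal(sig$theta, 0.7)
  expect_equal(nrow(sig$links), 0L) # strict inequality: no edges
  # criteria-level arithmetic: sum 71.5578 over an 8 x 8 grid
  withr::local_seed(18)
  Tm <- matrix(stats::runif(64), 8, 8)
  Tm <- Tm / sum(Tm) * 71.5578
  expect_equal(round(significant_links(Tm)$theta, 3), 1.118)
  # raising the threshold never adds edges
  th <- significant_links(Tm)$theta
  for (bump in c(0, 0.1, 0.3, 0.8)) {
    e1 <- nrow(significant_links(Tm, theta = th + bump)$links)
    e2 <- nrow(significant_links(Tm, theta = th + bump + 0.1)$links)
    expect_gte(e1, e2)
  }
})

test_that("the if_dematel pipeline runs per cluster with convergence checking", {
  gp <- generate_panel(6, c("A", "B", "C", "D"), type = "dematel", seed = 19)
  # uniform random labels carry no shared signal, so the leave-one-out
  # convergence warning is expected noise here
  fit <- suppressWarnings(if_dematel(gp$judgments))
  gl <- glance(fit)
  expect_equal(gl$n, 4L)
  expect_equal(gl$n_experts, 6L)
  expect_lt(gl$spectral_radius, 1)
  td <- tidy(fit)
  expect_equal(sum(td$D), sum(td$R), tolerance = 1e-6)
  links <- influence_links(fit)
  if (nrow(links) > 0) expect_true(all(links$tij > gl$theta))
  # single expert: convergence check is skipped with a warning
  single <- gp$judgments[gp$judgments$expert == "E1", ]
  expect_warning(if_dematel(single), regexp = "skipped")
  # determinism of the generator
  gp2 <- generate_panel(6, c("A", "B", "C", "D"), type = "dematel", seed = 19)
  expect_identical(gp$judgments, gp2$judgments)
})
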