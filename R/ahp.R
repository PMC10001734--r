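# Intuitionistic fuzzy AHP: expert weighting, cell-wise IFWA aggregation of
# pairwise judgment matrices, Saaty consistency checking of the defuzzified
# comparison matrix, and fuzzy-entropy priority extraction.

# --- long-format judgment helpers -------------------------------------------

#' @keywords internal
#' @noRd
resolve_judgments <- function(judgments, scale = NULL) {
  df <- tibble::as_tibble(judgments)
  need <- c("expert", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("judgments are missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  if (!all(c("mu", "nu") %in% names(df))) {
    if (!"label" %in% names(df)) {
      rlang::abort("judgments need either `mu`/`nu` columns or a `label` column.",
                   class = "ifmcdm_validation_error")
    }
    if (is.null(scale)) {
      rlang::abort("labelled judgments need a `scale` to resolve against.",
                   class = "ifmcdm_validation_error")
    }
    ifn <- scale_ifns(scale, df$label)
    df$mu <- ifn$mu
    df$nu <- ifn$nu
  }
  make_ifn(df$mu, df$nu) # validate
  df
}

# element order = first appearance down the `row` column
#' @keywords internal
#' @noRd
judgment_elements <- function(judgments) {
  unique(as.character(judgments$row))
}

# check each expert supplies one complete n x n grid over the same elements
#' @keywords internal
#' @noRd
check_conformant <- function(judgments, min_n = 2L) {
  elems <- judgment_elements(judgments)
  n <- length(elems)
  if (n < min_n) {
    rlang::abort(sprintf("need at least %d decision elements, got %d.", min_n, n),
                 class = "ifmcdm_validation_error")
  }
  if (!all(judgments$col %in% elems)) {
    extra <- setdiff(unique(judgments$col), elems)
    rlang::abort(paste0("column element(s) absent from rows: ",
                        paste(extra, collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  counts <- dplyr::count(judgments, .data$expert)
  if (any(counts$n != n * n)) {
    bad <- counts$expert[counts$n != n * n]
    rlang::abort(paste0("incomplete judgment grid for expert(s): ",
                        paste(bad, collapse = ", "),
                        sprintf(" (expected %d cells).", n * n)),
                 class = "ifmcdm_validation_error")
  }
  elems
}

# --- expert weighting --------------------------------------------------------

#' Expert importance weights
#'
#' Converts per-expert importance IFNs into normalized panel weights using
#' the score `mu_k + pi_k * mu_k / (mu_k + nu_k)`: the hesitancy is credited
#' to the expert in proportion to the membership share of their rating.
#'
#' @param panel A data frame with one row per expert: an `expert` id column
#'   plus either `mu`/`nu` columns or a `label` column resolved against
#'   `scale`.
#' @param scale Scale used to resolve `label`s
#'   (default [expert_importance_scale()]).
#'
#' @return A tibble `expert`, `mu`, `nu`, `pi`, `score`, `weight`; the
#'   weights are non-negative and sum to 1.
#'
#' @examples
#' panel <- tibble::tibble(
#'   expert = paste0("DM", 1:6),
#'   label = c(rep("very relevant", 5), "relevant")
#' )
#' expert_weights(panel)
#' @export
expert_weights <- function(panel, scale = expert_importance_scale()) {
  df <- tibble::as_tibble(panel)
  if (!"expert" %in% names(df)) {
    rlang::abort("`panel` needs an `expert` column.",
                 class = "ifmcdm_validation_error")
  }
  if (nrow(df) == 0L) {
    rlang::abort("`panel` must contain at least one expert.",
                 class = "ifmcdm_validation_error")
  }
  if (anyDuplicated(df$expert)) {
    rlang::abort("duplicated expert ids in `panel`.",
                 class = "ifmcdm_validation_error")
  }
  if (!all(c("mu", "nu") %in% names(df))) {
    if (!"label" %in% names(df)) {
      rlang::abort("`panel` needs `mu`/`nu` columns or a `label` column.",
                   class = "ifmcdm_validation_error")
    }
    ifn <- scale_ifns(scale, df$label)
    df$mu <- ifn$mu
    df$nu <- ifn$nu
  }
  ifn <- make_ifn(df$mu, df$nu)
  if (any(ifn$mu + ifn$nu <= 0)) {
    rlang::abort("expert importance with mu = nu = 0 leaves the score undefined.",
                 class = "ifmcdm_validation_error")
  }
  score <- ifn$mu + ifn$pi * ifn$mu / (ifn$mu + ifn$nu)
  tibble::tibble(
    expert = df$expert,
    mu = ifn$mu, nu = ifn$nu, pi = ifn$pi,
    score = score,
    weight = score / sum(score)
  )
}

# --- aggregation -------------------------------------------------------------

#' Aggregate per-expert judgment matrices with IFWA
#'
#' Applies the intuitionistic fuzzy weighted average cell by cell across
#' experts, yielding a single aggregated IFN matrix in long form.
#'
#' @param judgments Long-format judgments: columns `expert`, `row`, `col`
#'   and `mu`/`nu` (or `label` + `scale`). Every expert must supply a
#'   complete square grid over the same elements.
#' @param weights Expert weights: either the tibble returned by
#'   [expert_weights()] (columns `expert`, `weight`) or a named numeric
#'   vector. Must cover every expert and sum to 1.
#' @param scale Optional scale used to resolve judgment `label`s.
#'
#' @return A tibble `row`, `col`, `mu`, `nu`, `pi` with one row per cell.
#' @export
aggregate_judgments <- function(judgments, weights, scale = NULL) {
  df <- resolve_judgments(judgments, scale)
  check_conformant(df)
  if (is.data.frame(weights)) {
    w <- stats::setNames(weights$weight, weights$expert)
  } else {
    w <- weights
  }
  experts <- unique(df$expert)
  if (!all(experts %in% names(w))) {
    rlang::abort(paste0("missing weight for expert(s): ",
                        paste(setdiff(experts, names(w)), collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  w <- w[as.character(experts)]
  if (abs(sum(w) - 1) > 1e-9) {
    rlang::abort(sprintf("expert weights must sum to 1 (got %.12f).", sum(w)),
                 class = "ifmcdm_validation_error")
  }
  df$expert <- factor(df$expert, levels = experts)
  out <- df |>
    dplyr::arrange(.data$expert) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::reframe(ifwa(dplyr::pick("mu", "nu"), w))
  elems <- judgment_elements(df)
  out |>
    dplyr::arrange(match(.data$row, elems), match(.data$col, elems))
}

# --- consistency -------------------------------------------------------------

#' Saaty random consistency indices
#'
#' Random index (RI) values for reciprocal matrices of order 1-15, used to
#' scale the consistency index into the consistency ratio.
#'
#' @return A named numeric vector indexed by matrix order.
#' @export
saaty_ri <- function() {
  c(`1` = 0, `2` = 0, `3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24,
    `7` = 1.32, `8` = 1.41, `9` = 1.45, `10` = 1.49, `11` = 1.51,
    `12` = 1.48, `13` = 1.56, `14` = 1.57, `15` = 1.59)
}

#' Crisp reciprocal comparison matrix from an aggregated IFN matrix
#'
#' Each aggregated cell is collapsed with [to_standard_fuzzy()], the
#' diagonal is forced to 1, and the lower triangle is replaced by the
#' reciprocal of the upper triangle, producing the positive reciprocal
#' matrix required by eigenvalue-based consistency analysis.
#'
#' @param aggregated Long-format aggregated matrix (`row`, `col`, `mu`,
#'   `nu`), e.g. from [aggregate_judgments()].
#'
#' @return A square numeric matrix with dimnames set to the element ids.
#' @export
crisp_reciprocal <- function(aggregated) {
  elems <- judgment_elements(aggregated)
  n <- length(elems)
  f <- matrix(NA_real_, n, n, dimnames = list(elems, elems))
  f[cbind(match(aggregated$row, elems), match(aggregated$col, elems))] <-
    to_standard_fuzzy(aggregated$mu, aggregated$nu)
  if (anyNA(f)) {
    rlang::abort("aggregated matrix has missing cells.",
                 class = "ifmcdm_validation_error")
  }
  A <- diag(n)
  dimnames(A) <- list(elems, elems)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        A[i, j] <- f[i, j]
        A[j, i] <- 1 / f[i, j]
      }
    }
  }
  A
}

#' Consistency ratio of a comparison matrix
#'
#' Computes Saaty's consistency ratio
#' `CR = ((lambda_max - n) / (n - 1)) / RI(n)` from the principal
#' eigenvalue of the crisp reciprocal matrix. Matrices of order 1 or 2 are
#' consistent by construction (`CR = 0`). A matrix is conventionally
#' acceptable when `CR < 0.10`.
#'
#' @param x Either a long-format aggregated IFN matrix (see
#'   [crisp_reciprocal()]) or a square positive reciprocal numeric matrix.
#' @param ri Named vector of random indices (default [saaty_ri()]); supply
#'   an extended table for orders above 15.
#'
#' @return The consistency ratio, with attributes `lambda_max` and `n`.
#' @export
consistency_ratio <- function(x, ri = saaty_ri()) {
  A <- if (is.matrix(x)) x else crisp_reciprocal(x)
  n <- nrow(A)
  if (n != ncol(A)) {
    rlang::abort("comparison matrix must be square.",
                 class = "ifmcdm_validation_error")
  }
  if (n <= 2L) {
    return(structure(0, lambda_max = as.numeric(n), n = n))
  }
  key <- as.character(n)
  if (!key %in% names(ri)) {
    rlang::abort(sprintf("no random index for order %d; supply an extended `ri`.", n),
                 class = "ifmcdm_validation_error")
  }
  lambda_max <- max(Re(eigen(A, only.values = TRUE)$values))
  cr <- ((lambda_max - n) / (n - 1)) / ri[[key]]
  structure(cr, lambda_max = lambda_max, n = n)
}

# --- priority extraction -----------------------------------------------------

#' Row-wise IFNs of an aggregated matrix
#'
#' Summarizes each row of an aggregated judgment matrix into a single IFN by
#' taking the arithmetic mean of the membership and of the non-membership
#' degrees across the row's cells (hesitancy recomputed as the residual).
#'
#' @param aggregated Long-format aggregated matrix (`row`, `col`, `mu`, `nu`).
#'
#' @return A tibble `element`, `mu`, `nu`, `pi`, in matrix row order.
#' @export
row_ifn <- function(aggregated) {
  elems <- judgment_elements(aggregated)
  aggregated |>
    dplyr::group_by(element = .data$row) |>
    dplyr::summarise(mu = mean(.data$mu), nu = mean(.data$nu)) |>
    dplyr::arrange(match(.data$element, elems)) |>
    dplyr::mutate(pi = pmin(pmax(1 - .data$mu - .data$nu, 0), 1))
}

# x * log(x), continuously extended with 0 at x = 0
#' @keywords internal
#' @noRd
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Fuzzy-entropy priority weights
#'
#' Derives local priorities from per-element IFNs via an intuitionistic
#' fuzzy entropy: each element's entropy is
#' `e_i = -(1/ln 2) * (mu ln mu + nu ln nu - (1 - pi) ln(1 - pi) - pi ln 2)`
#' (with `x ln x := 0` at `x = 0`), and the weight is the normalized
#' complement `w_i = (1 - e_i) / (n - sum(e))`. Elements whose judgments are
#' more decisive (lower entropy) receive larger weights; identical IFNs give
#' equal weights `1/n`.
#'
#' @param row_ifns A data frame with columns `element`, `mu`, `nu` (and
#'   optionally `pi`, recomputed if absent), e.g. from [row_ifn()].
#'
#' @return A tibble `element`, `entropy`, `weight`, weights summing to 1.
#' @export
entropy_weights <- function(row_ifns) {
  df <- tibble::as_tibble(row_ifns)
  ifn <- make_ifn(df$mu, df$nu)
  n <- nrow(df)
  if (n < 2L) {
    rlang::abort("entropy weighting needs at least two elements.",
                 class = "ifmcdm_validation_error")
  }
  e <- -(1 / log(2)) *
    (xlogx(ifn$mu) + xlogx(ifn$nu) - xlogx(1 - ifn$pi) - ifn$pi * log(2))
  denom <- n - sum(e)
  if (abs(denom) < 1e-12) {
    rlang::abort("degenerate entropies: n - sum(e) is zero.",
                 class = "ifmcdm_numeric_error")
  }
  w <- (1 - e) / denom
  tibble::tibble(element = df$element, entropy = e, weight = w / sum(w))
}

#' Eigenvector priority weights
#'
#' Classical AHP priority extraction: the principal right eigenvector of the
#' crisp reciprocal comparison matrix, normalized to sum to 1. For a
#' perfectly consistent matrix this recovers the generating priority vector
#' exactly; it is mainly used to cross-check synthetic panels.
#'
#' @inheritParams consistency_ratio
#' @return A tibble `element`, `weight`.
#' @export
eigen_weights <- function(x) {
  A <- if (is.matrix(x)) x else crisp_reciprocal(x)
  ev <- eigen(A)
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v <- abs(v)
  tibble::tibble(
    element = if (is.null(rownames(A))) as.character(seq_len(nrow(A))) else rownames(A),
    weight = v / sum(v)
  )
}

#' Compose local weights into global weights
#'
#' Multiplies each sub-criterion's local weight by the weight of its parent
#' criterion. With `renormalize = TRUE` (default) the parent vector and each
#' child vector are first rescaled to sum exactly to 1, so the resulting
#' global weights also sum to 1 even when the inputs carry printed-rounding
#' residue.
#'
#' @param children A data frame `parent`, `element`, `weight` of local
#'   sub-criterion weights grouped by parent criterion.
#' @param parent A data frame `element`, `weight` of criterion weights.
#' @param renormalize Rescale parent and per-parent child weights to sum to
#'   1 before composing.
#'
#' @return A tibble `parent`, `element`, `local`, `global`.
#' @export
global_weights <- function(children, parent, renormalize = TRUE) {
  ch <- tibble::as_tibble(children)
  pa <- tibble::as_tibble(parent)
  orphan <- setdiff(unique(ch$parent), pa$element)
  if (length(orphan)) {
    rlang::abort(paste0("orphan sub-criterion parent(s): ",
                        paste(orphan, collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  if (any(ch$weight < 0) || any(pa$weight < 0)) {
    rlang::abort("weights must be non-negative.",
                 class = "ifmcdm_validation_error")
  }
  if (renormalize) {
    pa$weight <- pa$weight / sum(pa$weight)
    ch <- ch |>
      dplyr::group_by(.data$parent) |>
      dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
      dplyr::ungroup()
  }
  ch |>
    dplyr::left_join(pa, by = c(parent = "element"), suffix = c("", ".parent")) |>
    dplyr::transmute(.data$parent, .data$element,
                     local = .data$weight,
                     global = .data$weight * .data$weight.parent)
}

# --- pipeline ----------------------------------------------------------------

#' Intuitionistic fuzzy AHP weighting pipeline
#'
#' Runs the full weighting stage: expert weights from their importance
#' ratings, cell-wise IFWA aggregation of each cluster's judgment matrices,
#' consistency checking of every aggregated matrix, fuzzy-entropy local
#' priorities, and (when a criteria-level cluster is present) global weights
#' for the sub-criteria.
#'
#' Judgments carry an optional `cluster` column: the cluster named in
#' `root_cluster` compares the criteria themselves, and every other cluster
#' id must match one criterion element, whose weight scales that cluster's
#' local priorities. Without a `cluster` column a single matrix is assumed
#' and local weights are returned as global.
#'
#' @param judgments Long-format judgments: `expert`, optional `cluster`,
#'   `row`, `col`, and `mu`/`nu` or `label`.
#' @param panel Expert panel (see [expert_weights()]).
#' @param scale Scale for judgment labels (default [ahp_relevance_scale()]).
#' @param importance_scale Scale for panel labels
#'   (default [expert_importance_scale()]).
#' @param root_cluster Name of the criteria-level cluster (default
#'   `"criteria"`).
#' @param cr_threshold Consistency threshold; matrices with `CR >=` this
#'   value raise a warning and are flagged (default 0.10).
#' @param ri Random-index table (default [saaty_ri()]).
#'
#' @return An object of class `if_ahp`: a list with `experts` (weighted
#'   panel), `clusters` (per-cluster tibble: `cluster`, `n`, `cr`,
#'   `lambda_max`, `consistent`), `weights` (tibble `cluster`, `element`,
#'   `local`, `global`) and `aggregated` (named list of aggregated
#'   matrices). Use [generics::tidy()] / [generics::glance()] or
#'   [ggplot2::autoplot()] on it.
#' @export
if_ahp <- function(judgments, panel, scale = ahp_relevance_scale(),
                   importance_scale = expert_importance_scale(),
                   root_cluster = "criteria", cr_threshold = 0.10,
                   ri = saaty_ri()) {
  ew <- expert_weights(panel, importance_scale)
  df <- resolve_judgments(judgments, scale)
  if (!"cluster" %in% names(df)) df$cluster <- root_cluster
  cluster_ids <- unique(df$cluster)

  per_cluster <- purrr::map(cluster_ids, function(cl) {
    sub <- df[df$cluster == cl, , drop = FALSE]
    agg <- aggregate_judgments(sub, ew)
    cr <- consistency_ratio(agg, ri = ri)
    if (cr >= cr_threshold) {
      rlang::warn(sprintf(
        "cluster '%s' is inconsistent (CR = %.3f >= %.2f); judgments should be revised.",
        cl, as.numeric(cr), cr_threshold))
    }
    lw <- entropy_weights(row_ifn(agg))
    list(aggregated = agg, cr = cr, local = lw)
  })
  names(per_cluster) <- cluster_ids

  clusters <- tibble::tibble(
    cluster = cluster_ids,
    n = unname(purrr::map_int(per_cluster, ~ attr(.x$cr, "n"))),
    lambda_max = unname(purrr::map_dbl(per_cluster,
                                       ~ attr(.x$cr, "lambda_max"))),
    cr = unname(purrr::map_dbl(per_cluster, ~ as.numeric(.x$cr))),
    consistent = .data$cr < cr_threshold
  )

  locals <- purrr::imap(per_cluster, function(x, cl) {
    dplyr::mutate(x$local[, c("element", "weight")], cluster = cl, .before = 1)
  }) |> purrr::list_rbind()

  if (root_cluster %in% cluster_ids && length(cluster_ids) > 1L) {
    parent <- per_cluster[[root_cluster]]$local[, c("element", "weight")]
    children <- locals |>
      dplyr::filter(.data$cluster != root_cluster) |>
      dplyr::rename(parent = "cluster")
    missing_parent <- setdiff(unique(children$parent), parent$element)
    if (length(missing_parent)) {
      rlang::abort(paste0("cluster id(s) without a matching criterion: ",
                          paste(missing_parent, collapse = ", ")),
                   class = "ifmcdm_validation_error")
    }
    gw <- global_weights(children, parent)
    weights <- dplyr::bind_rows(
      tibble::tibble(cluster = root_cluster, element = parent$element,
                     local = parent$weight, global = parent$weight),
      tibble::tibble(cluster = gw$parent, element = gw$element,
                     local = gw$local, global = gw$global)
    )
  } else {
    weights <- dplyr::transmute(locals, .data$cluster, .data$element,
                                local = .data$weight, global = .data$weight)
  }

  structure(
    list(experts = ew, clusters = clusters, weights = weights,
         aggregated = purrr::map(per_cluster, "aggregated"),
         root_cluster = root_cluster, cr_threshold = cr_threshold),
    class = "if_ahp"
  )
}

#' @export
print.if_ahp <- function(x, ...) {
  cat("Intuitionistic fuzzy AHP:", nrow(x$experts), "experts,",
      nrow(x$clusters), "cluster(s)\n")
  cat("Max CR:", sprintf("%.3f", max(x$clusters$cr)),
      if (all(x$clusters$consistent)) "(all consistent)" else "(INCONSISTENT matrices present)",
      "\n\n")
  print(x$weights, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname if_ahp
#' @param x An `if_ahp` object.
#' @param ... Unused.
#' @method tidy if_ahp
#' @export
tidy.if_ahp <- function(x, ...) {
  dplyr::left_join(x$weights,
                   x$clusters[, c("cluster", "cr", "consistent")],
                   by = "cluster")
}

#' @rdname if_ahp
#' @method glance if_ahp
#' @export
glance.if_ahp <- function(x, ...) {
  tibble::tibble(
    n_experts = nrow(x$experts),
    n_clusters = nrow(x$clusters),
    max_cr = max(x$clusters$cr),
    all_consistent = all(x$clusters$consistent)
  )
}
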