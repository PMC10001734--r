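# Intuitionistic fuzzy DEMATEL: defuzzified aggregation of influence
# judgments, total-relation matrix, prominence/relation scores and
# significant-link extraction.

#' Defuzzify an influence judgment grid
#'
#' Converts intuitionistic fuzzy influence judgments into crisp scores by
#' chaining [to_standard_fuzzy()] with [defuzzify_crisp()] on the scale's
#' triangular support. The diagonal (self-influence) is forced to 0.
#'
#' @param judgments Long-format judgments: `expert`, `row`, `col` plus
#'   `mu`/`nu` or `label`. Diagonal cells may carry any IFN (conventionally
#'   `[0, 0]`); they are zeroed after defuzzification.
#' @param scale The influence scale supplying labels and the crisp support
#'   (default [dematel_influence_scale()], support `(0, 4)`).
#'
#' @return The input tibble with a `crisp` column appended.
#' @export
defuzzify_influence <- function(judgments, scale = dematel_influence_scale()) {
  df <- tibble::as_tibble(judgments)
  if (!all(c("mu", "nu") %in% names(df)) && "label" %in% names(df)) {
    # resolve labels off-diagonal only; diagonal is conventional and zeroed
    diag_cell <- df$row == df$col
    ifn <- scale_ifns(scale, replace(df$label, diag_cell,
                                     scale$entries$label[1]))
    df$mu <- replace(ifn$mu, diag_cell, 0)
    df$nu <- replace(ifn$nu, diag_cell, 0)
  }
  df <- resolve_judgments(df, scale)
  f <- to_standard_fuzzy(df$mu, df$nu)
  df$crisp <- ifelse(df$row == df$col, 0,
                     defuzzify_crisp(f, scale$crisp_support))
  df
}

# long (expert, row, col, crisp) -> named list of matrices, one per expert
#' @keywords internal
#' @noRd
crisp_grids <- function(df) {
  elems <- judgment_elements(df)
  n <- length(elems)
  split(df, factor(df$expert, levels = unique(df$expert))) |>
    lapply(function(sub) {
      m <- matrix(NA_real_, n, n, dimnames = list(elems, elems))
      m[cbind(match(sub$row, elems), match(sub$col, elems))] <- sub$crisp
      if (anyNA(m)) {
        rlang::abort("incomplete influence grid.", class = "ifmcdm_validation_error")
      }
      m
    })
}

#' Aggregate direct-relation matrices across experts
#'
#' Unweighted cell-wise arithmetic mean of the experts' crisp direct-relation
#' grids. (Aggregation is deliberately unweighted even when the panel
#' carries importance weights from the weighting stage; the influence stage
#' treats every expert's view of the network symmetrically.)
#'
#' @param x Either a tibble from [defuzzify_influence()] (columns `expert`,
#'   `row`, `col`, `crisp`) or a list of conformant numeric matrices.
#'
#' @return A numeric matrix `Z` with element ids as dimnames.
#' @export
aggregate_direct_relation <- function(x) {
  grids <- if (is.data.frame(x)) crisp_grids(x) else x
  if (length(grids) < 1L) {
    rlang::abort("need at least one expert grid.",
                 class = "ifmcdm_validation_error")
  }
  dims <- unique(lapply(grids, dim))
  if (length(dims) != 1L || dims[[1]][1] != dims[[1]][2]) {
    rlang::abort("expert grids must be square and conformant.",
                 class = "ifmcdm_validation_error")
  }
  Reduce(`+`, grids) / length(grids)
}

#' Convergence index between two aggregated matrices
#'
#' Mean absolute relative change between the direct-relation aggregates of
#' `p` and `p - 1` experts, used as an internal-consistency check of the
#' panel: `mean(|Z_p - Z_(p-1)| / Z_p)` over off-diagonal cells. The panel
#' is conventionally judged consistent when the index is at most 0.05.
#' Off-diagonal cells where the reference `Z_p` entry is zero cannot be
#' scaled and are skipped with a warning.
#'
#' @param agg_p Aggregate over `p` experts (reference).
#' @param agg_pm1 Aggregate over `p - 1` experts.
#'
#' @return The convergence index (a non-negative scalar).
#' @export
convergence_index <- function(agg_p, agg_pm1) {
  if (!is.matrix(agg_p) || !all(dim(agg_p) == dim(agg_pm1))) {
    rlang::abort("matrices must be conformant.", class = "ifmcdm_validation_error")
  }
  off <- !diag(nrow(agg_p))
  ref <- agg_p[off]
  new <- agg_pm1[off]
  if (all(ref == 0)) {
    rlang::abort("reference matrix is all zero off-diagonal.",
                 class = "ifmcdm_numeric_error")
  }
  skip <- ref == 0
  if (any(skip)) {
    rlang::warn(sprintf(
      "convergence index: skipped %d off-diagonal cell(s) with zero reference value.",
      sum(skip)))
  }
  mean(abs(ref[!skip] - new[!skip]) / ref[!skip])
}

#' Normalize a direct-relation matrix
#'
#' Scales `Z` by `s`, the maximum over all row sums and column sums, so that
#' every row and column of `N = Z / s` sums to at most 1 and the Neumann
#' series of `N` converges.
#'
#' @param Z Non-negative direct-relation matrix.
#'
#' @return The normalized matrix `N`, with the norm stored in `attr(, "s")`.
#' @export
normalize_direct_relation <- function(Z) {
  if (any(Z < 0)) {
    rlang::abort("`Z` must be non-negative.", class = "ifmcdm_validation_error")
  }
  s <- max(c(rowSums(Z), colSums(Z)))
  if (s == 0) {
    rlang::abort("`Z` is all zeros; nothing to normalize.",
                 class = "ifmcdm_numeric_error")
  }
  structure(Z / s, s = s)
}

#' Total-influence matrix
#'
#' Accumulates direct and all indirect influence paths:
#' `T = N (I - N)^(-1) = N + N^2 + N^3 + ...`. Requires the spectral radius
#' of `N` to be strictly below 1; otherwise the series diverges and an error
#' reporting the radius is raised.
#'
#' @param N Normalized direct-relation matrix.
#'
#' @return The total-influence matrix `T` (element-wise `>= N`), with the
#'   spectral radius in `attr(, "spectral_radius")`.
#' @export
total_influence <- function(N) {
  N <- unclass(N)
  attr(N, "s") <- NULL
  radius <- max(Mod(eigen(N, only.values = TRUE)$values))
  if (radius >= 1) {
    rlang::abort(sprintf(
      "total influence diverges: spectral radius of N is %.6f (must be < 1).",
      radius), class = "ifmcdm_numeric_error")
  }
  Tm <- N %*% solve(diag(nrow(N)) - N)
  dimnames(Tm) <- dimnames(N)
  structure(Tm, spectral_radius = radius)
}

#' Prominence and relation scores
#'
#' From a total-influence matrix computes, per element, the dispatched
#' influence `D` (row sum), received influence `R` (column sum), prominence
#' `D + R` (centrality in the influence network) and relation `D - R` (net
#' influence). Elements with strictly positive relation are classified as
#' dispatchers (causes); all others, including exact zero, as receivers
#' (effects).
#'
#' @param T_mat Total-influence matrix from [total_influence()].
#'
#' @return A tibble `element`, `D`, `R`, `prominence`, `relation`, `role`.
#' @export
prominence_relation <- function(T_mat) {
  elems <- rownames(T_mat)
  if (is.null(elems)) elems <- as.character(seq_len(nrow(T_mat)))
  D <- rowSums(T_mat)
  R <- colSums(T_mat)
  tibble::tibble(
    element = elems,
    D = unname(D), R = unname(R),
    prominence = unname(D + R),
    relation = unname(D - R),
    role = ifelse(D - R > 0, "dispatcher", "receiver")
  )
}

#' Significant influence links
#'
#' Computes the significance threshold `theta` as the mean of all
#' total-influence entries (`sum(T) / n^2`) and returns the directed edges
#' whose influence strictly exceeds it; these are the links drawn in an
#' impact-digraph map.
#'
#' @param T_mat Total-influence matrix.
#' @param theta Optional threshold override; defaults to `mean(T)`.
#'
#' @return A list with `theta` and `links`, a tibble
#'   `source`, `target`, `tij` sorted by decreasing influence.
#' @export
significant_links <- function(T_mat, theta = NULL) {
  if (is.null(theta)) theta <- sum(T_mat) / length(T_mat)
  elems <- rownames(T_mat)
  if (is.null(elems)) elems <- as.character(seq_len(nrow(T_mat)))
  idx <- which(T_mat > theta, arr.ind = TRUE)
  links <- tibble::tibble(
    source = elems[idx[, 1]],
    target = elems[idx[, 2]],
    tij = T_mat[idx]
  ) |> dplyr::arrange(dplyr::desc(.data$tij))
  list(theta = theta, links = links)
}

# --- pipeline ----------------------------------------------------------------

#' Intuitionistic fuzzy DEMATEL pipeline
#'
#' Runs the full cause-effect analysis per cluster: per-expert
#' defuzzification, unweighted aggregation, convergence-index check (full
#' panel versus the panel without its last expert, in input order),
#' normalization, total-influence matrix, prominence/relation scores and
#' significant links.
#'
#' @param judgments Long-format influence judgments: `expert`, optional
#'   `cluster`, `row`, `col`, plus `label` or `mu`/`nu`.
#' @param scale Influence scale (default [dematel_influence_scale()]).
#' @param convergence_threshold Panel-consistency bound on the convergence
#'   index (default 0.05); exceeding it raises a warning. With a single
#'   expert the index is undefined and skipped with a warning.
#'
#' @return An object of class `if_dematel`: a list with `clusters`, a named
#'   list holding per cluster `Z`, `N`, `T`, `scores` (prominence tibble),
#'   `theta`, `links` and `convergence`, and `summary`, a per-cluster
#'   tibble. Use [generics::tidy()], [generics::glance()] or
#'   [ggplot2::autoplot()] on it.
#' @export
if_dematel <- function(judgments, scale = dematel_influence_scale(),
                       convergence_threshold = 0.05) {
  df <- defuzzify_influence(judgments, scale)
  if (!"cluster" %in% names(df)) df$cluster <- "network"
  cluster_ids <- unique(df$cluster)

  clusters <- purrr::map(cluster_ids, function(cl) {
    sub <- df[df$cluster == cl, , drop = FALSE]
    check_conformant(sub)
    grids <- crisp_grids(sub)
    Z <- aggregate_direct_relation(grids)
    conv <- NA_real_
    if (length(grids) >= 2L) {
      Zm1 <- aggregate_direct_relation(grids[-length(grids)])
      conv <- convergence_index(Z, Zm1)
      if (conv > convergence_threshold) {
        rlang::warn(sprintf(
          "cluster '%s': convergence index %.3f exceeds %.2f; judgments may be unreliable.",
          cl, conv, convergence_threshold))
      }
    } else {
      rlang::warn(sprintf(
        "cluster '%s': single expert, convergence check skipped.", cl))
    }
    N <- normalize_direct_relation(Z)
    Tm <- total_influence(N)
    sig <- significant_links(Tm)
    list(Z = Z, N = N, T = Tm, scores = prominence_relation(Tm),
         theta = sig$theta, links = sig$links, convergence = conv,
         n_experts = length(grids))
  })
  names(clusters) <- cluster_ids

  summary <- tibble::tibble(
    cluster = cluster_ids,
    n = unname(purrr::map_int(clusters, ~ nrow(.x$Z))),
    n_experts = unname(purrr::map_int(clusters, "n_experts")),
    s = unname(purrr::map_dbl(clusters, ~ attr(.x$N, "s"))),
    spectral_radius = unname(purrr::map_dbl(clusters,
                                            ~ attr(.x$T, "spectral_radius"))),
    convergence = unname(purrr::map_dbl(clusters, "convergence")),
    converged = .data$convergence <= convergence_threshold,
    theta = unname(purrr::map_dbl(clusters, "theta")),
    n_links = unname(purrr::map_int(clusters, ~ nrow(.x$links)))
  )

  structure(list(clusters = clusters, summary = summary,
                 convergence_threshold = convergence_threshold),
            class = "if_dematel")
}

#' @export
print.if_dematel <- function(x, ...) {
  cat("Intuitionistic fuzzy DEMATEL:", nrow(x$summary), "cluster(s)\n\n")
  print(x$summary, ...)
  invisible(x)
}

#' @rdname if_dematel
#' @param x An `if_dematel` object.
#' @param ... Unused.
#' @method tidy if_dematel
#' @export
tidy.if_dematel <- function(x, ...) {
  purrr::imap(x$clusters, function(cl, id) {
    dplyr::mutate(cl$scores, cluster = id, .before = 1)
  }) |> purrr::list_rbind()
}

#' @rdname if_dematel
#' @method glance if_dematel
#' @export
glance.if_dematel <- function(x, ...) x$summary

#' Edge list of significant influence links
#'
#' @param x An `if_dematel` object.
#' @return A tibble `cluster`, `source`, `target`, `tij`, `theta`.
#' @export
influence_links <- function(x) {
  stopifnot(inherits(x, "if_dematel"))
  purrr::imap(x$clusters, function(cl, id) {
    dplyr::mutate(cl$links, cluster = id, theta = cl$theta, .before = 1)
  }) |> purrr::list_rbind()
}
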