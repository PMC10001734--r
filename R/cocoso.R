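# Combined compromise solution (CoCoSo) ranking of alternatives from a
# weighted decision matrix with benefit/cost directions.

#' Min-max normalization of a decision matrix
#'
#' Benefit columns map as `(x - min) / (max - min)`, cost columns as
#' `(max - x) / (max - min)`. A constant column (max = min) carries no
#' discriminating information and is mapped to 1 for every alternative
#' ("all tied at best"), so fully tied indicators still contribute to the
#' power comparability.
#'
#' @param values Numeric matrix, sub-criteria in rows, alternatives in
#'   columns.
#' @param directions Character vector, one of `"benefit"`/`"cost"` per row.
#'
#' @return A matrix of normalized values in `[0, 1]`, same shape as
#'   `values`.
#' @export
normalize_matrix <- function(values, directions) {
  if (nrow(values) != length(directions)) {
    rlang::abort("one direction per sub-criterion row is required.",
                 class = "ifmcdm_validation_error")
  }
  if (!all(directions %in% c("benefit", "cost"))) {
    bad <- setdiff(unique(directions), c("benefit", "cost"))
    rlang::abort(paste0("directions must be 'benefit' or 'cost'; got: ",
                        paste(bad, collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  r <- values
  for (j in seq_len(nrow(values))) {
    x <- values[j, ]
    rng <- max(x) - min(x)
    if (rng == 0) {
      r[j, ] <- 1
    } else if (directions[j] == "benefit") {
      r[j, ] <- (x - min(x)) / rng
    } else {
      r[j, ] <- (max(x) - x) / rng
    }
  }
  r
}

#' Weighted and power-weighted comparability
#'
#' For each alternative computes the additive score `S_i = sum(w_j r_ij)`
#' (in `[0, 1]`) and the multiplicative-exponential score
#' `P_i = sum(r_ij ^ w_j)`, with the convention `0^w = 0` for `w > 0`.
#'
#' @param r Normalized matrix from [normalize_matrix()] (sub-criteria in
#'   rows, alternatives in columns).
#' @param weights Sub-criterion weights summing to 1.
#'
#' @return A tibble `alternative`, `S`, `P`.
#' @export
comparability <- function(r, weights) {
  if (length(weights) != nrow(r)) {
    rlang::abort("one weight per sub-criterion row is required.",
                 class = "ifmcdm_validation_error")
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    rlang::abort(sprintf("weights must sum to 1 (got %.6f).", sum(weights)),
                 class = "ifmcdm_validation_error")
  }
  alts <- colnames(r)
  if (is.null(alts)) alts <- as.character(seq_len(ncol(r)))
  tibble::tibble(
    alternative = alts,
    S = colSums(r * weights),
    P = colSums(r^weights)
  )
}

#' CoCoSo appraisal scores
#'
#' Blends the comparability scores three ways:
#' `Ma = (P + S) / sum(P + S)` (relative share),
#' `Mb = S / min(S) + P / min(P)` (distance from the worst),
#' `Mc = (lambda S + (1 - lambda) P) / (lambda max(S) + (1 - lambda) max(P))`
#' (compromise against the best, `lambda` balancing the additive and power
#' terms, default 0.5).
#'
#' @param S,P Numeric vectors of comparability scores (length = number of
#'   alternatives, at least 2).
#' @param lambda Balance parameter in `[0, 1]`.
#'
#' @return A tibble `Ma`, `Mb`, `Mc`.
#' @export
appraisal_scores <- function(S, P, lambda = 0.5) {
  if (length(S) < 2L || length(S) != length(P)) {
    rlang::abort("need S and P for at least two alternatives.",
                 class = "ifmcdm_validation_error")
  }
  if (lambda < 0 || lambda > 1) {
    rlang::abort("`lambda` must lie in [0, 1].",
                 class = "ifmcdm_validation_error")
  }
  if (min(S) <= 0 || min(P) <= 0) {
    rlang::abort(paste0(
      "Mb is undefined when min(S) or min(P) is 0. This happens when one ",
      "alternative is worst on every non-constant sub-criterion; drop it or ",
      "rescore before ranking."), class = "ifmcdm_numeric_error")
  }
  tibble::tibble(
    Ma = (P + S) / sum(P + S),
    Mb = S / min(S) + P / min(P),
    Mc = (lambda * S + (1 - lambda) * P) /
      (lambda * max(S) + (1 - lambda) * max(P))
  )
}

#' Final CoCoSo index and ranking
#'
#' Combines the three appraisal scores into the compromise index
#' `M = (Ma Mb Mc)^(1/3) + (Ma + Mb + Mc) / 3` and ranks alternatives by
#' decreasing `M`, breaking ties lexicographically by alternative id.
#'
#' @param Ma,Mb,Mc Positive appraisal-score vectors.
#' @param alternative Optional alternative ids (default positional).
#'
#' @return A tibble `alternative`, `M`, `rank`.
#' @export
final_index <- function(Ma, Mb, Mc, alternative = NULL) {
  if (any(Ma <= 0) || any(Mb <= 0) || any(Mc <= 0)) {
    rlang::abort("appraisal scores must be positive.",
                 class = "ifmcdm_numeric_error")
  }
  if (is.null(alternative)) alternative <- as.character(seq_along(Ma))
  M <- (Ma * Mb * Mc)^(1 / 3) + (Ma + Mb + Mc) / 3
  tibble::tibble(
    alternative = alternative,
    M = M,
    rank = order(order(-M, alternative))
  )
}

#' Weakness report
#'
#' Flags, per alternative, the sub-criteria on which it sits at (or near)
#' the bottom of the normalized scale: non-constant sub-criteria with
#' `r_ij <= cutoff`, sorted by sub-criterion weight so the heaviest
#' weaknesses come first. Constant sub-criteria are never flagged (they
#' cannot discriminate).
#'
#' @param r Normalized matrix (sub-criteria in rows, alternatives in
#'   columns).
#' @param weights Sub-criterion weights.
#' @param cutoff Weakness cutoff in `[0, 1)` (default 0.1); `cutoff = 0`
#'   flags only exact minima.
#'
#' @return A tibble `alternative`, `subcriterion`, `value`, `weight`.
#' @export
weakness_report <- function(r, weights, cutoff = 0.1) {
  if (cutoff < 0 || cutoff >= 1) {
    rlang::abort("`cutoff` must lie in [0, 1).",
                 class = "ifmcdm_validation_error")
  }
  subs <- rownames(r)
  if (is.null(subs)) subs <- as.character(seq_len(nrow(r)))
  alts <- colnames(r)
  if (is.null(alts)) alts <- as.character(seq_len(ncol(r)))
  non_constant <- apply(r, 1, function(x) max(x) > min(x))
  idx <- which(r <= cutoff & non_constant, arr.ind = TRUE)
  tibble::tibble(
    alternative = alts[idx[, 2]],
    subcriterion = subs[idx[, 1]],
    value = r[idx],
    weight = weights[idx[, 1]]
  ) |>
    dplyr::arrange(.data$alternative, dplyr::desc(.data$weight))
}

#' Combined compromise solution ranking
#'
#' Runs the full CoCoSo chain on a tidy decision matrix: min-max
#' normalization with benefit/cost directions, weighted (`S`) and
#' power-weighted (`P`) comparability, the three appraisal scores, the
#' final compromise index `M` with ranking, and a weakness report.
#'
#' @param data A data frame with a `subcriterion` id column, a `direction`
#'   column (`"benefit"`/`"cost"`), a `weight` column, and one numeric
#'   column per alternative. Weights off a unit sum by more than `1e-6`
#'   are renormalized with a message.
#' @param lambda Balance parameter for the compromise appraisal score
#'   (default 0.5).
#' @param cutoff Weakness cutoff for [weakness_report()] (default 0.1).
#'
#' @return An object of class `cocoso`: a list with `scores` (tibble
#'   `alternative`, `S`, `P`, `Ma`, `Mb`, `Mc`, `M`, `rank`), `normalized`
#'   (long tibble of `r_ij`), `weaknesses`, `lambda` and `cutoff`. Use
#'   [generics::tidy()], [generics::glance()] or [ggplot2::autoplot()].
#'
#' @examples
#' cocoso(load_fixture("table13_decision_matrix"))
#' @export
cocoso <- function(data, lambda = 0.5, cutoff = 0.1) {
  df <- tibble::as_tibble(data)
  need <- c("subcriterion", "direction", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("decision matrix is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  alt_cols <- setdiff(names(df), need)
  alt_cols <- alt_cols[vapply(df[alt_cols], is.numeric, logical(1))]
  if (length(alt_cols) < 2L) {
    rlang::abort("need at least two numeric alternative columns.",
                 class = "ifmcdm_validation_error")
  }
  if (anyDuplicated(df$subcriterion)) {
    rlang::abort("duplicated sub-criterion ids.",
                 class = "ifmcdm_validation_error")
  }
  if (anyNA(df$direction)) {
    rlang::abort("every sub-criterion needs a direction.",
                 class = "ifmcdm_validation_error")
  }
  w <- df$weight
  if (any(w < 0)) {
    rlang::abort("weights must be non-negative.",
                 class = "ifmcdm_validation_error")
  }
  if (abs(sum(w) - 1) > 1e-6) {
    rlang::inform(sprintf(
      "weights sum to %.6f; renormalizing to 1.", sum(w)))
  }
  w <- w / sum(w)

  values <- as.matrix(df[alt_cols])
  rownames(values) <- df$subcriterion
  r <- normalize_matrix(values, df$direction)
  comp <- comparability(r, w)
  app <- appraisal_scores(comp$S, comp$P, lambda)
  fin <- final_index(app$Ma, app$Mb, app$Mc, comp$alternative)
  scores <- dplyr::bind_cols(comp, app) |>
    dplyr::left_join(fin, by = "alternative") |>
    dplyr::arrange(.data$rank)

  normalized <- tibble::as_tibble(r, rownames = "subcriterion") |>
    tidyr::pivot_longer(-"subcriterion", names_to = "alternative",
                        values_to = "r")

  structure(
    list(scores = scores, normalized = normalized,
         weaknesses = weakness_report(r, w, cutoff),
         lambda = lambda, cutoff = cutoff),
    class = "cocoso"
  )
}

#' @export
print.cocoso <- function(x, ...) {
  cat("CoCoSo ranking (lambda =", x$lambda, ")\n\n")
  print(x$scores, ...)
  invisible(x)
}

#' @rdname cocoso
#' @param x A `cocoso` object.
#' @param ... Unused.
#' @method tidy cocoso
#' @export
tidy.cocoso <- function(x, ...) x$scores

#' @rdname cocoso
#' @method glance cocoso
#' @export
glance.cocoso <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$scores),
    n_subcriteria = dplyr::n_distinct(x$normalized$subcriterion),
    lambda = x$lambda,
    best = x$scores$alternative[x$scores$rank == 1],
    M_best = max(x$scores$M)
  )
}
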