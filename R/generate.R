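# Synthetic expert-panel generator: reproducible panels over the package's
# linguistic scales, used to exercise every pipeline stage without external
# data.

#' Generate a synthetic expert panel with judgment matrices
#'
#' Builds a reproducible panel of experts together with one complete
#' judgment grid per expert, in the long format consumed by [if_ahp()] and
#' [if_dematel()].
#'
#' For `type = "ahp"` the panel shares a latent priority vector: the
#' membership of each upper-triangle cell is the priority ratio
#' `u_i / u_j`, perturbed multiplicatively by log-normal noise of scale
#' `noise` and clamped to `[0.1, 0.9]`; the IFN is completed with a fixed
#' hesitancy of 0.2 (`mu = f - 0.1`, `nu = 0.9 - f`) and mirrored cells swap
#' membership and non-membership. At `noise = 0` the defuzzified reciprocal
#' comparison matrix is exactly consistent (CR = 0) and its principal
#' eigenvector recovers the latent priorities; at small noise CR stays well
#' below 0.1. Latent priorities must be increasing along `elements` with
#' pairwise ratios in `[1/9, 0.9]` so that every ratio is a valid
#' membership; the default draws admissible log-spaced priorities.
#'
#' For `type = "dematel"` each off-diagonal cell draws a label from the
#' influence scale with probabilities `label_probs` (default uniform), and
#' diagonal cells carry the conventional `[0, 0]` pair (zeroed on
#' defuzzification).
#'
#' @param n_experts Number of experts (>= 1).
#' @param elements Character vector of decision-element ids (>= 2).
#' @param type `"ahp"` or `"dematel"`.
#' @param noise Log-normal perturbation scale for AHP panels (default 0.1).
#' @param seed Optional integer seed; identical inputs and seed yield
#'   identical panels.
#' @param priorities Optional latent priority vector for AHP panels (see
#'   Details); drawn automatically when `NULL`.
#' @param label_probs Optional label sampling probabilities for DEMATEL
#'   panels, one per scale entry.
#' @param importance_labels Expert importance labels (default all
#'   `"very relevant"`).
#' @param scale Judgment scale for DEMATEL panels
#'   (default [dematel_influence_scale()]).
#'
#' @return A list with `panel` (tibble `expert`, `label`), `judgments`
#'   (long tibble `expert`, `row`, `col`, `mu`, `nu` and, for DEMATEL,
#'   `label`), `type` and, for AHP, the latent `priorities`.
#'
#' @examples
#' gp <- generate_panel(3, c("A", "B", "C"), type = "ahp", seed = 42)
#' consistency_ratio(aggregate_judgments(gp$judgments,
#'                                       expert_weights(gp$panel)))
#' @export
generate_panel <- function(n_experts, elements,
                           type = c("ahp", "dematel"),
                           noise = 0.1, seed = NULL,
                           priorities = NULL, label_probs = NULL,
                           importance_labels = NULL,
                           scale = dematel_influence_scale()) {
  type <- match.arg(type)
  n <- length(elements)
  if (n < 2L) {
    rlang::abort("need at least two elements.", class = "ifmcdm_validation_error")
  }
  if (n_experts < 1L) {
    rlang::abort("need at least one expert.", class = "ifmcdm_validation_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  if (is.null(importance_labels)) {
    importance_labels <- rep("very relevant", n_experts)
  }
  experts <- sprintf("E%d", seq_len(n_experts))
  panel <- tibble::tibble(expert = experts, label = importance_labels)

  if (type == "ahp") {
    if (is.null(priorities)) {
      # log-spaced increments keep all pairwise ratios within [1/9, 0.9]
      steps <- stats::runif(n - 1, 0.12, min(0.45, 2.19 / (n - 1)))
      priorities <- exp(c(0, cumsum(steps)))
    }
    if (length(priorities) != n || any(priorities <= 0)) {
      rlang::abort("`priorities` must be positive, one per element.",
                   class = "ifmcdm_validation_error")
    }
    ratio <- outer(priorities, priorities, `/`)
    if (any(ratio[upper.tri(ratio)] > 0.9 + 1e-12) ||
        any(ratio[upper.tri(ratio)] < 1 / 9 - 1e-12)) {
      rlang::abort(paste0(
        "`priorities` must be increasing along `elements` with pairwise ",
        "ratios in [1/9, 0.9] so each ratio is a valid membership."),
        class = "ifmcdm_validation_error")
    }
    judgments <- purrr::map(experts, function(ex) {
      f <- ratio
      if (noise > 0) {
        pert <- matrix(exp(stats::rnorm(n * n, 0, noise)), n, n)
        f <- f * pert
      }
      f <- pmin(pmax(f, 0.1), 0.9)
      cells <- expand.grid(i = seq_len(n), j = seq_len(n))
      mu <- nu <- numeric(nrow(cells))
      for (k in seq_len(nrow(cells))) {
        i <- cells$i[k]; j <- cells$j[k]
        if (i == j) {
          mu[k] <- 0.4; nu[k] <- 0.4      # self-comparison, membership 0.5
        } else if (i < j) {
          mu[k] <- f[i, j] - 0.1; nu[k] <- 0.9 - f[i, j]
        } else {
          mu[k] <- 0.9 - f[j, i]; nu[k] <- f[j, i] - 0.1  # mirrored judgment
        }
      }
      tibble::tibble(expert = ex, row = elements[cells$i],
                     col = elements[cells$j], mu = mu, nu = nu)
    }) |> purrr::list_rbind()
    return(list(panel = panel, judgments = judgments, type = type,
                priorities = priorities))
  }

  # dematel
  labels <- scale$entries$label
  if (length(labels) == 0L) {
    rlang::abort("`scale` has no entries.", class = "ifmcdm_validation_error")
  }
  if (is.null(label_probs)) label_probs <- rep(1 / length(labels), length(labels))
  judgments <- purrr::map(experts, function(ex) {
    cells <- expand.grid(i = seq_len(n), j = seq_len(n))
    lab <- sample(labels, nrow(cells), replace = TRUE, prob = label_probs)
    diag_cell <- cells$i == cells$j
    ifn <- scale_ifns(scale, lab)
    tibble::tibble(
      expert = ex,
      row = elements[cells$i], col = elements[cells$j],
      label = ifelse(diag_cell, NA_character_, lab),
      mu = ifelse(diag_cell, 0, ifn$mu),
      nu = ifelse(diag_cell, 0, ifn$nu)
    )
  }) |> purrr::list_rbind()
  list(panel = panel, judgments = judgments, type = type)
}
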