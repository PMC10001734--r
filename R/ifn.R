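# Intuitionistic fuzzy number (IFN) algebra shared by the AHP and DEMATEL
# stages. An IFN is a pair (mu, nu) of membership and non-membership degrees
# with mu + nu <= 1; the residual pi = 1 - mu - nu is the hesitancy degree
# and is always recomputed, never stored independently.

#' Construct intuitionistic fuzzy numbers
#'
#' An intuitionistic fuzzy number (IFN) extends an ordinary fuzzy membership
#' degree `mu` with an explicit non-membership degree `nu`. The two must
#' satisfy `0 <= mu + nu <= 1`; the residual `pi = 1 - mu - nu` is the
#' hesitancy degree, modelling the indeterminacy of an expert's judgment.
#'
#' @param mu Numeric vector of membership degrees in `[0, 1]`.
#' @param nu Numeric vector of non-membership degrees in `[0, 1]`. Recycled
#'   against `mu` if either has length 1.
#' @param tol Absolute numeric tolerance for the validity checks
#'   (default `1e-9`).
#'
#' @return A tibble with columns `mu`, `nu` and `pi`, one row per IFN.
#'   `pi` is clamped to `[0, 1]` to absorb floating-point residue.
#'
#' @examples
#' make_ifn(0.9, 0.05) # hesitancy 0.05
#' make_ifn(mu = c(0.5, 1), nu = c(0.45, 0))
#' @export
make_ifn <- function(mu, nu, tol = 1e-9) {
  if (!is.numeric(mu) || !is.numeric(nu)) {
    rlang::abort("`mu` and `nu` must be numeric.", class = "ifmcdm_validation_error")
  }
  n <- max(length(mu), length(nu))
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (length(nu) == 1L) nu <- rep(nu, n)
  if (length(mu) != length(nu)) {
    rlang::abort("`mu` and `nu` must have the same length.",
                 class = "ifmcdm_validation_error")
  }
  bad <- !is.finite(mu) | !is.finite(nu) |
    mu < -tol | mu > 1 + tol | nu < -tol | nu > 1 + tol
  if (any(bad)) {
    rlang::abort(
      paste0("membership and non-membership degrees must lie in [0, 1]; ",
             "offending position(s): ", paste(which(bad), collapse = ", ")),
      class = "ifmcdm_validation_error"
    )
  }
  over <- mu + nu > 1 + tol
  if (any(over)) {
    rlang::abort(
      paste0("invalid intuitionistic pair: mu + nu > 1 at position(s): ",
             paste(which(over), collapse = ", ")),
      class = "ifmcdm_validation_error"
    )
  }
  tibble::tibble(
    mu = pmin(pmax(mu, 0), 1),
    nu = pmin(pmax(nu, 0), 1),
    pi = pmin(pmax(1 - mu - nu, 0), 1)
  )
}

#' Collapse an IFN to a standard fuzzy membership value
#'
#' Converts an intuitionistic pair into a classical fuzzy membership degree
#' by splitting the hesitancy evenly between membership and non-membership
#' (the `C_phi` operator at `phi = 0.5`, the value minimising the Euclidean
#' distance between the collapsed set and the original IFN):
#' `f = (1 + mu - nu) / 2`.
#'
#' @param mu Numeric vector of membership degrees, or a data frame with
#'   columns `mu` and `nu` (in which case `nu` is ignored).
#' @param nu Numeric vector of non-membership degrees.
#'
#' @return A numeric vector of membership values, guaranteed in `[0, 1]`.
#'
#' @examples
#' to_standard_fuzzy(0.5, 0.45) # 0.525
#' to_standard_fuzzy(make_ifn(0.9, 0.1)) # 0.9
#' @export
to_standard_fuzzy <- function(mu, nu = NULL) {
  if (is.data.frame(mu)) {
    df <- mu
    if (!all(c("mu", "nu") %in% names(df))) {
      rlang::abort("data-frame input must have columns `mu` and `nu`.",
                   class = "ifmcdm_validation_error")
    }
    mu <- df$mu
    nu <- df$nu
  }
  if (is.null(nu)) {
    rlang::abort("`nu` is required when `mu` is not a data frame.",
                 class = "ifmcdm_validation_error")
  }
  make_ifn(mu, nu) # validation only
  pmin(pmax((1 + mu - nu) / 2, 0), 1)
}

#' Map a fuzzy membership value onto a crisp triangular support
#'
#' Places a membership value on the support of a triangular fuzzy number:
#' `x = l + f * (m - l)`. This is the second half of the defuzzification
#' chain used by the DEMATEL influence scale, whose support is `(0, 4)` so
#' that e.g. `f = 0.9` maps to the crisp influence score `3.6`.
#'
#' @param membership Numeric vector of membership values in `[0, 1]`.
#' @param support Either a numeric vector `c(l, m)` with `l < m`, or a
#'   [linguistic_scale()] whose `crisp_support` is used.
#'
#' @return Numeric vector of crisp values in `[l, m]`.
#'
#' @examples
#' defuzzify_crisp(0.525, c(0, 4)) # 2.1
#' defuzzify_crisp(0.9, dematel_influence_scale()) # 3.6
#' @export
defuzzify_crisp <- function(membership, support = c(0, 4)) {
  if (inherits(support, "linguistic_scale")) support <- support$crisp_support
  if (!is.numeric(support) || length(support) < 2L || support[1] >= support[2]) {
    rlang::abort("`support` must be numeric with l < m.",
                 class = "ifmcdm_validation_error")
  }
  if (any(!is.finite(membership)) || any(membership < 0 | membership > 1)) {
    rlang::abort("`membership` must lie in [0, 1].",
                 class = "ifmcdm_validation_error")
  }
  support[1] + membership * (support[2] - support[1])
}

#' Intuitionistic fuzzy weighted average (IFWA)
#'
#' Aggregates several IFNs into one with the weighted-average operator
#' `mu = 1 - prod((1 - mu_k)^w_k)`, `nu = prod(nu_k^w_k)`,
#' `pi = prod((1 - mu_k)^w_k) - prod(nu_k^w_k)`. This is the canonical
#' group-aggregation operator for expert judgments: idempotent on identical
#' inputs and invariant to joint permutation of value/weight pairs.
#'
#' A zero non-membership combines by the convention `0^w = 0` for `w > 0`
#' (and `0^0 = 1`, i.e. a zero-weight expert contributes nothing), so any
#' expert with `nu_k = 0` and positive weight forces `nu = 0` in the
#' aggregate.
#'
#' @param values A data frame of IFNs with columns `mu` and `nu`.
#' @param weights Numeric vector of non-negative weights, same length as
#'   `nrow(values)`, summing to 1 within `tol`.
#' @param tol Tolerance on the weight-sum check (default `1e-9`).
#'
#' @return A one-row tibble with columns `mu`, `nu`, `pi`.
#'
#' @examples
#' ifwa(make_ifn(c(0.5, 0.3), c(0.4, 0.6)), c(0.5, 0.5))
#' @export
ifwa <- function(values, weights, tol = 1e-9) {
  ifn <- make_ifn(values$mu, values$nu)
  if (!is.numeric(weights) || length(weights) != nrow(ifn)) {
    rlang::abort("`weights` must be numeric with one weight per IFN.",
                 class = "ifmcdm_validation_error")
  }
  if (any(weights < -tol)) {
    rlang::abort("`weights` must be non-negative.",
                 class = "ifmcdm_validation_error")
  }
  if (abs(sum(weights) - 1) > tol) {
    rlang::abort(sprintf("`weights` must sum to 1 (got %.12f).", sum(weights)),
                 class = "ifmcdm_validation_error")
  }
  comp_mu <- prod((1 - ifn$mu)^weights) # complement product
  nu_agg <- prod(ifn$nu^weights)
  make_ifn(1 - comp_mu, nu_agg)
}
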