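# Linguistic scales: ordered label -> IFN maps plus the triangular support
# used when judgments are defuzzified to crisp scores.

#' Construct a linguistic scale
#'
#' A linguistic scale maps ordered verbal labels (e.g. "no influence" ...
#' "very high influence") to intuitionistic fuzzy numbers, and carries the
#' support `(l, m)` of the triangular number used when memberships are
#' converted to crisp values with [defuzzify_crisp()].
#'
#' @param name Scale identifier.
#' @param labels Character vector of unique labels, in increasing order of
#'   intensity.
#' @param mu,nu Numeric vectors of membership / non-membership degrees, one
#'   per label; each pair must be a valid IFN.
#' @param crisp_support Numeric `c(l, m)` with `l < m`. A third triangular
#'   parameter `u` is accepted and stored but unused by the linear
#'   defuzzification map.
#'
#' @return An object of class `linguistic_scale`: a list with `name`,
#'   `entries` (tibble `label`, `mu`, `nu`, `pi`) and `crisp_support`.
#'
#' @examples
#' linguistic_scale("yesno", c("no", "yes"), mu = c(0.1, 0.9),
#'                  nu = c(0.9, 0.1), crisp_support = c(0, 1))
#' @export
linguistic_scale <- function(name, labels, mu, nu, crisp_support = c(0, 1)) {
  if (anyDuplicated(labels)) {
    rlang::abort("scale labels must be unique.", class = "ifmcdm_validation_error")
  }
  if (length(labels) != length(mu) || length(labels) != length(nu)) {
    rlang::abort("`labels`, `mu` and `nu` must have equal length.",
                 class = "ifmcdm_validation_error")
  }
  if (!is.numeric(crisp_support) || length(crisp_support) < 2L ||
      crisp_support[1] >= crisp_support[2]) {
    rlang::abort("`crisp_support` must satisfy l < m.",
                 class = "ifmcdm_validation_error")
  }
  entries <- dplyr::bind_cols(tibble::tibble(label = as.character(labels)),
                              make_ifn(mu, nu))
  structure(
    list(name = name, entries = entries,
         crisp_support = unname(crisp_support)),
    class = "linguistic_scale"
  )
}

#' @export
print.linguistic_scale <- function(x, ...) {
  cat("<linguistic_scale: ", x$name, ">  support (",
      paste(x$crisp_support, collapse = ", "), ")\n", sep = "")
  print(x$entries, ...)
  invisible(x)
}

#' Built-in linguistic scales
#'
#' Three scales are shipped with the package:
#' * `ahp_relevance_scale()` - the five relevance labels used in pairwise
#'   importance comparisons (much less relevant ... much more relevant).
#' * `dematel_influence_scale()` - the five influence labels used in
#'   pairwise influence comparisons, with triangular support `(0, 4)` so the
#'   defuzzification chain maps the labels to crisp scores
#'   0.4, 1.5, 2.1, 3.1 and 3.6.
#' * `expert_importance_scale()` - the five labels grading the experience of
#'   a panel member, used to derive expert weights.
#'
#' @return A [linguistic_scale()].
#' @name builtin_scales
#' @examples
#' dematel_influence_scale()
NULL

#' @rdname builtin_scales
#' @export
ahp_relevance_scale <- function() {
  linguistic_scale(
    name = "ahp_relevance",
    labels = c("much less relevant", "less relevant", "equally relevant",
               "more relevant", "much more relevant"),
    mu = c(0.27, 0.27, 0.02, 0.13, 0.33),
    nu = c(0.33, 0.13, 0.18, 0.27, 0.27),
    crisp_support = c(0, 1)
  )
}

#' @rdname builtin_scales
#' @export
dematel_influence_scale <- function() {
  linguistic_scale(
    name = "dematel_influence",
    labels = c("no influence", "low influence", "medium influence",
               "high influence", "very high influence"),
    mu = c(0.10, 0.35, 0.50, 0.75, 0.90),
    nu = c(0.90, 0.60, 0.45, 0.20, 0.10),
    crisp_support = c(0, 4)
  )
}

#' @rdname builtin_scales
#' @export
expert_importance_scale <- function() {
  linguistic_scale(
    name = "expert_importance",
    labels = c("very irrelevant", "irrelevant", "moderately relevant",
               "relevant", "very relevant"),
    mu = c(0.10, 0.25, 0.50, 0.75, 0.90),
    nu = c(0.80, 0.60, 0.40, 0.20, 0.05),
    crisp_support = c(0, 1)
  )
}

#' Look up scale labels
#'
#' Resolves a character vector of labels against a scale, returning the
#' corresponding IFNs. Unknown labels raise an error naming each offender.
#'
#' @param scale A [linguistic_scale()].
#' @param labels Character vector of labels to resolve.
#'
#' @return A tibble with columns `label`, `mu`, `nu`, `pi` (one row per
#'   requested label, in request order).
#' @export
scale_ifns <- function(scale, labels) {
  stopifnot(inherits(scale, "linguistic_scale"))
  idx <- match(labels, scale$entries$label)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    rlang::abort(
      paste0("unknown label(s) for scale '", scale$name, "': ",
             paste0('"', bad, '"', collapse = ", ")),
      class = "ifmcdm_validation_error"
    )
  }
  scale$entries[idx, , drop = FALSE]
}

#' Read a linguistic scale from a JSON file
#'
#' The expected layout is
#' `{"name": ..., "entries": [{"label": ..., "mu": ..., "nu": ...}, ...],
#'   "crisp_support": [l, m]}`.
#'
#' @param path Path to a JSON scale description.
#' @return A [linguistic_scale()].
#' @export
read_scale_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "entries", "crisp_support")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    rlang::abort(paste0("scale file is missing field(s): ",
                        paste(miss, collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  linguistic_scale(x$name, x$entries$label, x$entries$mu, x$entries$nu,
                   as.numeric(x$crisp_support))
}
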