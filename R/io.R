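# CSV/JSON front door: readers for the long judgment format, expert panels
# and decision matrices, plus one-call drivers that run a stage and write
# its report files with a reproducibility manifest.

#' Read long-format judgments from CSV
#'
#' Expected columns: `expert_id`, `cluster_id` (optional), `row_element`,
#' `col_element`, `label` (or `mu`/`nu`); the short names `expert`,
#' `cluster`, `row`, `col` are also accepted. When a `scale` is supplied,
#' labels are validated immediately and offending rows are reported by
#' number.
#'
#' @param path CSV file (UTF-8, comma-separated, header row, `.` decimal).
#' @param scale Optional [linguistic_scale()] used to validate labels.
#'
#' @return A tibble `expert`, (`cluster`,) `row`, `col`, (`label`,)
#'   (`mu`, `nu`).
#' @export
read_judgments <- function(path, scale = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ren <- c(expert = "expert_id", cluster = "cluster_id",
           row = "row_element", col = "col_element")
  for (new in names(ren)) {
    if (ren[[new]] %in% names(df)) names(df)[names(df) == ren[[new]]] <- new
  }
  need <- c("expert", "row", "col")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("judgment file is missing column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "ifmcdm_validation_error")
  }
  if (!is.null(scale) && "label" %in% names(df)) {
    known <- scale$entries$label
    off_diag <- df$row != df$col
    bad <- which(off_diag & !df$label %in% known)
    if (length(bad)) {
      rlang::abort(paste0(
        "unknown label(s) for scale '", scale$name, "' at data row(s) ",
        paste(utils::head(bad, 10), collapse = ", "),
        if (length(bad) > 10) " ..." else "", ": ",
        paste0('"', unique(df$label[bad]), '"', collapse = ", ")),
        class = "ifmcdm_validation_error")
    }
  }
  df
}

#' Read an expert panel from CSV
#'
#' Expected columns: `expert_id` (or `expert`) and `importance_label` (or
#' `label`), optionally `mu`/`nu` instead of a label.
#'
#' @inheritParams read_judgments
#' @return A tibble with `expert` and `label` (and/or `mu`, `nu`).
#' @export
read_panel <- function(path, scale = expert_importance_scale()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("expert_id" %in% names(df)) names(df)[names(df) == "expert_id"] <- "expert"
  if ("importance_label" %in% names(df)) {
    names(df)[names(df) == "importance_label"] <- "label"
  }
  if (!"expert" %in% names(df)) {
    rlang::abort("panel file needs an `expert_id` (or `expert`) column.",
                 class = "ifmcdm_validation_error")
  }
  if ("label" %in% names(df) && !is.null(scale)) {
    bad <- which(!df$label %in% scale$entries$label)
    if (length(bad)) {
      rlang::abort(paste0("invalid importance label(s) at data row(s) ",
                          paste(bad, collapse = ", "), ": ",
                          paste0('"', unique(df$label[bad]), '"', collapse = ", ")),
                   class = "ifmcdm_validation_error")
    }
  }
  df
}

#' Read a decision matrix from CSV
#'
#' Rows are sub-criteria; columns are a `subcriterion` id, one numeric
#' column per alternative, a `direction` column (`benefit`/`cost`) and a
#' `weight` column (weights may also be joined later from a weights file).
#'
#' @param path CSV file.
#' @return A tibble in the layout [cocoso()] expects.
#' @export
read_decision_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subcriterion" %in% names(df)) {
    rlang::abort("decision-matrix file needs a `subcriterion` column.",
                 class = "ifmcdm_validation_error")
  }
  if (!"direction" %in% names(df)) {
    rlang::abort("decision-matrix file needs a `direction` column.",
                 class = "ifmcdm_validation_error")
  }
  df
}

#' @keywords internal
#' @noRd
write_manifest <- function(out_dir, inputs, config) {
  paths <- inputs[vapply(inputs, function(p) is.character(p) && file.exists(p),
                         logical(1))]
  manifest <- list(
    package = "ifmcdm",
    version = as.character(utils::packageVersion("ifmcdm")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the weighting stage and write its report
#'
#' Reads (or accepts) a panel and a set of pairwise judgments, runs
#' [if_ahp()], and optionally writes `weights.csv` (element, cluster,
#' local/global weight, CR of the source matrix), `experts.csv` and a
#' `manifest.json` recording input hashes and configuration.
#'
#' @param judgments Path to a judgments CSV or a data frame.
#' @param panel Path to a panel CSV or a data frame.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @inheritParams if_ahp
#' @return The [if_ahp()] object, invisibly when writing.
#' @export
run_weights <- function(judgments, panel, out_dir = NULL,
                        scale = ahp_relevance_scale(),
                        importance_scale = expert_importance_scale(),
                        cr_threshold = 0.10) {
  j_path <- if (is.character(judgments)) judgments else NA_character_
  p_path <- if (is.character(panel)) panel else NA_character_
  if (is.character(judgments)) judgments <- read_judgments(judgments, scale)
  if (is.character(panel)) panel <- read_panel(panel, importance_scale)
  fit <- if_ahp(judgments, panel, scale = scale,
                importance_scale = importance_scale,
                cr_threshold = cr_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(fit), file.path(out_dir, "weights.csv"))
    readr::write_csv(fit$experts, file.path(out_dir, "experts.csv"))
    write_manifest(out_dir,
                   list(judgments = j_path, panel = p_path),
                   list(stage = "weights", cr_threshold = cr_threshold,
                        scale = scale$name))
    return(invisible(fit))
  }
  fit
}

#' Run the cause-effect stage and write its report
#'
#' Reads (or accepts) influence judgments, runs [if_dematel()], and
#' optionally writes `influence.csv` (per-element D, R, prominence,
#' relation, role), `edges.csv` (significant links with the threshold), a
#' `network.json` dump consumable by graph tooling, and `manifest.json`.
#'
#' @param judgments Path to a judgments CSV or a data frame.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @inheritParams if_dematel
#' @return The [if_dematel()] object, invisibly when writing.
#' @export
run_dematel <- function(judgments, out_dir = NULL,
                        scale = dematel_influence_scale(),
                        convergence_threshold = 0.05) {
  j_path <- if (is.character(judgments)) judgments else NA_character_
  if (is.character(judgments)) judgments <- read_judgments(judgments, scale)
  fit <- if_dematel(judgments, scale = scale,
                    convergence_threshold = convergence_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(fit), file.path(out_dir, "influence.csv"))
    readr::write_csv(influence_links(fit), file.path(out_dir, "edges.csv"))
    network <- purrr::imap(fit$clusters, function(cl, id) {
      list(cluster = id, theta = cl$theta,
           nodes = cl$scores, edges = cl$links)
    })
    jsonlite::write_json(unname(network), file.path(out_dir, "network.json"),
                         auto_unbox = TRUE, dataframe = "rows", digits = NA)
    write_manifest(out_dir, list(judgments = j_path),
                   list(stage = "dematel", scale = scale$name,
                        convergence_threshold = convergence_threshold))
    return(invisible(fit))
  }
  fit
}

#' Run the ranking stage and write its report
#'
#' Reads (or accepts) a decision matrix, optionally joining global weights
#' from a weights file (columns `element`/`subcriterion` and
#' `global`/`weight`), runs [cocoso()], and optionally writes
#' `ranking.csv`, `weaknesses.json` and `manifest.json`.
#'
#' @param decision Path to a decision-matrix CSV or a data frame.
#' @param weights Optional path to a weights CSV (e.g. written by
#'   [run_weights()]) or a data frame; overrides any `weight` column.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @inheritParams cocoso
#' @return The [cocoso()] object, invisibly when writing.
#' @export
run_cocoso <- function(decision, weights = NULL, out_dir = NULL,
                       lambda = 0.5, cutoff = 0.1) {
  d_path <- if (is.character(decision)) decision else NA_character_
  w_path <- if (is.character(weights)) weights else NA_character_
  if (is.character(decision)) decision <- read_decision_matrix(decision)
  if (!is.null(weights)) {
    if (is.character(weights)) {
      weights <- readr::read_csv(weights, show_col_types = FALSE,
                                 progress = FALSE)
    }
    key <- if ("element" %in% names(weights)) "element" else "subcriterion"
    wcol <- if ("global" %in% names(weights)) "global" else "weight"
    w <- weights[, c(key, wcol)]
    names(w) <- c("subcriterion", ".w")
    decision$weight <- NULL
    decision <- dplyr::inner_join(decision, w, by = "subcriterion") |>
      dplyr::rename(weight = ".w")
    unmatched <- setdiff(w$subcriterion, decision$subcriterion)
    if (nrow(decision) == 0L) {
      rlang::abort("no sub-criterion ids shared between matrix and weights.",
                   class = "ifmcdm_validation_error")
    }
    if (length(unmatched)) {
      rlang::warn(paste0("weights without a matrix row: ",
                         paste(unmatched, collapse = ", ")))
    }
  }
  fit <- cocoso(decision, lambda = lambda, cutoff = cutoff)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(fit$scores, file.path(out_dir, "ranking.csv"))
    weak <- split(fit$weaknesses[, c("subcriterion", "value", "weight")],
                  fit$weaknesses$alternative)
    jsonlite::write_json(weak, file.path(out_dir, "weaknesses.json"),
                         auto_unbox = TRUE, dataframe = "rows", digits = NA)
    write_manifest(out_dir, list(decision = d_path, weights = w_path),
                   list(stage = "cocoso", lambda = lambda, cutoff = cutoff))
    return(invisible(fit))
  }
  fit
}
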