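#' Pipeline configuration
#'
#' A plain serialisable record of the choices that determine a run: weight
#' handling, surgery side handling, regularisation grid, selection scope and
#' seeds. Round-trips unchanged through JSON.
#'
#' @param metric_weight_kind weights for the graph measures:
#'   "log10_transformed" (default) or "streamline_count".
#' @param selection_scope "per_fold" or "full_cohort".
#' @param grid list with `lambda` and `rho` ladders.
#' @param cost SVM regularisation constant.
#' @param seed integer seed recorded for provenance.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(metric_weight_kind = "log10_transformed",
                            selection_scope = "per_fold",
                            grid = default_regularisation_grid(),
                            cost = 1, seed = 1L) {
  structure(
    list(metric_weight_kind = metric_weight_kind,
         selection_scope = selection_scope,
         grid = lapply(grid, as.numeric),
         cost = cost, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write a pipeline configuration to JSON
#' @param config a [pipeline_config()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#' @param path JSON path written by [write_pipeline_config()].
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(x$metric_weight_kind, x$selection_scope,
                  x$grid, x$cost, x$seed)
}

#' Run the per-subject pipeline: build, resect, measure
#'
#' Builds the pre-operative endpoint connectome, removes every streamline
#' intersecting the resection mask, rebuilds the post-operative connectome,
#' applies the hemisphere flip for right-sided surgery (so the surgical side
#' is uniformly ipsilateral), and computes all change metrics. Deterministic:
#' identical inputs give identical outputs.
#'
#' @param streamlines a [streamline_set()].
#' @param parc a [parcellation()] (region table required for right-sided
#'   subjects).
#' @param mask a [resection_mask()].
#' @param surgery_side "left" or "right".
#' @param metric_weight_kind weights for the graph measures (see
#'   [change_metrics()]).
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>_changes.tsv` (tidy long format) and `<prefix>_provenance.json`.
#' @return an object of class `subject_result`: list with `pre`, `post`
#'   (count [connectivity_matrix()] objects, flipped as needed),
#'   `resection` (the `resection_result`), `change` ([change_metrics()])
#'   and `surgery_side`.
#' @export
run_subject <- function(streamlines, parc, mask,
                        surgery_side = c("left", "right"),
                        metric_weight_kind = "log10_transformed",
                        out_prefix = NULL) {
  surgery_side <- match.arg(surgery_side)
  pre <- build_connectome(streamlines, parc)
  res <- predict_postop_network(streamlines, parc, mask)
  post <- res$postop_connectome
  vol <- res$volume_remaining
  if (surgery_side == "right") {
    pre <- flip_hemispheres(pre, parc, "right")
    post <- flip_hemispheres(post, parc, "right")
    perm <- homologue_permutation(parc, pre$region_ids)
    vol <- stats::setNames(vol[perm], names(vol))
  }
  change <- change_metrics(pre, post, volume_remaining = vol,
                           metric_weight_kind = metric_weight_kind)
  out <- structure(
    list(pre = pre, post = post, resection = res, change = change,
         surgery_side = surgery_side),
    class = "subject_result"
  )
  if (!is.null(out_prefix)) {
    write.table(as.data.frame(change), paste0(out_prefix, "_changes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(package = "netresect",
           version = as.character(utils::packageVersion("netresect")),
           surgery_side = surgery_side,
           metric_weight_kind = metric_weight_kind,
           n_streamlines = length(streamlines),
           n_removed = length(res$removed)),
      paste0(out_prefix, "_provenance.json"), auto_unbox = TRUE
    )
  }
  out
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("Subject pipeline result (%s-sided surgery)\n", x$surgery_side))
  print(x$resection)
  print(x$change)
  invisible(x)
}

#' Run the cohort stage: feature assembly, grid search, LOOCV evaluation
#'
#' @param subjects list of `subject_result` objects from [run_subject()].
#' @param outcomes vector in \{+1 seizure-free, -1 not\}, one per subject;
#'   both classes must be present.
#' @param config a [pipeline_config()].
#' @return an object of class `cohort_result`: list with `features`
#'   ([cohort_features()]), `search` ([grid_search()] result) and `config`.
#' @export
run_cohort <- function(subjects, outcomes, config = pipeline_config()) {
  if (length(subjects) < 2L) stopf("a cohort needs at least 2 subjects")
  if (length(unique(sign(outcomes))) < 2L) {
    stopf("both outcome classes must be present")
  }
  changes <- lapply(subjects, function(s) {
    if (inherits(s, "subject_result")) s$change else s
  })
  features <- assemble_features(changes, outcomes)
  search <- grid_search(features, config$grid,
                        selection_scope = config$selection_scope,
                        cost = config$cost)
  structure(list(features = features, search = search, config = config),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  print(x$features)
  print(x$search)
  invisible(x)
}
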