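# End-to-end orchestration: simulate/load -> coelution grouping -> marker
# screening -> satellite deduplication -> annotation -> report bundle, with
# a run manifest for reproducibility.

#' Run the full marker-screening and annotation pipeline
#'
#' Executes, in order: coelution grouping, the screening cascade
#' (quality, element, ANOVA, VIP, top-N), adduct/ISF satellite detection
#' and collapse over the selected markers, and rule-based annotation
#' against the in-house database.  Writes \code{markers.csv},
#' \code{compounds.csv}, \code{annotations.csv}, \code{funnel.json} and
#' \code{manifest.json} to \code{out_dir} when given.  Inputs are never
#' mutated; a failing stage aborts with the stage named.
#'
#' @param ft A \code{\link{feature_table}}.
#' @param spectra Named list of \code{ms2_spectrum} objects.
#' @param db Optional in-house database data.frame.
#' @param cfg A \code{\link{cascade_config}}.
#' @param out_dir Optional output directory (created if needed).
#' @param seed Optional seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return List of class \code{"herbmarker_run"}: \code{screen} (a
#'   \code{marker_screen}), \code{edges}, \code{collapse},
#'   \code{annotations}, \code{funnel} (named vector incl. the compound
#'   count), \code{manifest}.
#' @export
run_pipeline <- function(ft, spectra = list(), db = NULL,
                         cfg = cascade_config(), out_dir = NULL, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  grouped <- stage("group", group_features(ft, cfg))
  scr <- stage("screen", screen_markers(grouped, cfg))
  marker_ft <- subset_features(scr$table,
                               match(scr$markers$id, scr$table$features$id))
  edges <- stage("dedup", rbind(
    detect_adduct_pairs(marker_ft, rt_tol = cfg$group_rt_min,
                        mz_tol = cfg$group_mz_ppm),
    detect_isf(marker_ft, spectra, rt_tol = cfg$group_rt_min)))
  col <- stage("collapse", collapse_features(marker_ft, edges))
  ann <- if (!is.null(db)) {
    stage("annotate", {
      recs <- db_precursor_search(marker_ft, db, spectra = spectra)
      apply_exclusion_rules(recs, cfg$allowed_elements)
    })
  } else NULL
  funnel <- c(scr$funnel, compounds = col$n_compounds)
  manifest <- list(config = unclass(cfg), seed = seed,
                   n_input_features = nrow(ft$features),
                   funnel = as.list(funnel),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   version = as.character(utils::packageVersion("herbmarker")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(scr$markers, file.path(out_dir, "markers.csv"))
    write_report(merge(col$members, col$compounds, by = "compound"),
                 file.path(out_dir, "compounds.csv"))
    if (!is.null(ann)) write_report(ann, file.path(out_dir, "annotations.csv"))
    jsonlite::write_json(as.list(funnel), file.path(out_dir, "funnel.json"),
                         auto_unbox = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  }
  structure(list(screen = scr, edges = edges, collapse = col,
                 annotations = ann, funnel = funnel, manifest = manifest),
            class = "herbmarker_run")
}

#' @export
print.herbmarker_run <- function(x, ...) {
  cat("herbmarker pipeline run\n")
  cat(sprintf("  funnel: %s\n",
              paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = " -> ")))
  cat(sprintf("  satellite edges: %d; compounds: %d\n",
              nrow(x$edges), x$collapse$n_compounds))
  invisible(x)
}
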