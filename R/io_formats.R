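# Readers and writers for the external artifacts: wide feature-table CSV,
# sample manifests, MGF tandem spectra, MSP spectral libraries, in-house
# compound database CSV, and result reports.
#
# Wide layout: one "area:SAMPLE" and one "rating:SAMPLE" column per sample,
# mirroring vendor exports.  RT is minutes everywhere internally; MGF
# RTINSECONDS is converted on read.

io_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "herbmarker_io_error", "error", "condition")))
}

#' Construct a feature table
#'
#' @param features data.frame with columns \code{id}, \code{mz}, \code{rt}
#'   and optionally \code{adduct}, \code{formula}, \code{spectrum_id}.
#' @param areas Numeric matrix (features x samples) of peak areas.
#' @param ratings Numeric matrix (features x samples) of 0-10 peak ratings,
#'   or \code{NULL} to default every rating to 10 (pass-through for tables
#'   without quality scores).
#' @param manifest data.frame mapping \code{sample} to \code{group}.
#' @return An object of class \code{"feature_table"}.
#' @export
feature_table <- function(features, areas, ratings = NULL, manifest) {
  stopifnot(is.data.frame(features), all(c("id", "mz", "rt") %in% names(features)))
  areas <- as.matrix(areas)
  if (is.null(ratings)) {
    warning("no peak ratings supplied; defaulting all ratings to 10")
    ratings <- matrix(10, nrow(areas), ncol(areas), dimnames = dimnames(areas))
  }
  ratings <- as.matrix(ratings)
  for (col in c("adduct", "formula", "spectrum_id")) {
    if (!col %in% names(features)) {
      features[[col]] <- rep(NA_character_, nrow(features))
    }
  }
  features$id <- as.character(features$id)
  validate_feature_table_parts(features, areas, ratings, manifest)
  rownames(areas) <- rownames(ratings) <- features$id
  structure(list(features = features, areas = areas, ratings = ratings,
                 manifest = manifest),
            class = "feature_table")
}

validate_feature_table_parts <- function(features, areas, ratings, manifest) {
  if (anyDuplicated(features$id)) io_error("duplicate feature ids", "herbmarker_validation_error")
  if (any(features$mz <= 0)) io_error("m/z must be positive", "herbmarker_validation_error")
  if (any(features$rt < 0)) io_error("RT must be non-negative", "herbmarker_validation_error")
  if (nrow(areas) != nrow(features) || nrow(ratings) != nrow(features))
    io_error("area/rating rows must match feature rows", "herbmarker_validation_error")
  if (!identical(colnames(areas), colnames(ratings)))
    io_error("area and rating sample sets differ", "herbmarker_validation_error")
  if (any(areas < 0, na.rm = TRUE)) io_error("areas must be non-negative", "herbmarker_validation_error")
  if (any(ratings < 0 | ratings > 10, na.rm = TRUE))
    io_error("ratings must lie in [0, 10]", "herbmarker_validation_error")
  stopifnot(is.data.frame(manifest), all(c("sample", "group") %in% names(manifest)))
  missing <- setdiff(colnames(areas), manifest$sample)
  if (length(missing))
    io_error(sprintf("sample(s) absent from manifest: %s", paste(missing, collapse = ", ")),
             "herbmarker_validation_error")
  invisible(TRUE)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features, %d samples, %d groups\n",
              nrow(x$features), ncol(x$areas),
              length(unique(x$manifest$group[match(colnames(x$areas), x$manifest$sample)]))))
  invisible(x)
}

#' Number of features in a feature table
#' @param x A \code{feature_table}.
#' @param ... Ignored.
#' @export
length.feature_table <- function(x) nrow(x$features)

#' Per-sample group labels of a feature table
#' @param ft A \code{feature_table}.
#' @return Factor of group labels aligned with the area matrix columns.
#' @export
sample_groups <- function(ft) {
  factor(ft$manifest$group[match(colnames(ft$areas), ft$manifest$sample)])
}

subset_features <- function(ft, keep) {
  structure(list(features = ft$features[keep, , drop = FALSE],
                 areas = ft$areas[keep, , drop = FALSE],
                 ratings = ft$ratings[keep, , drop = FALSE],
                 manifest = ft$manifest),
            class = "feature_table")
}

#' Read a wide feature-table CSV plus its sample manifest
#'
#' Expects columns \code{id}, \code{mz}, \code{rt}, optional \code{adduct},
#' \code{formula}, \code{spectrum_id}, and one \code{area:SAMPLE} column per
#' sample with matching \code{rating:SAMPLE} columns.  Missing rating
#' columns default to 10 with a warning.
#'
#' @param path Feature CSV path.
#' @param manifest_path CSV with columns \code{sample,group}.
#' @return A \code{\link{feature_table}}.
#' @export
read_feature_table <- function(path, manifest_path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  for (col in c("id", "mz", "rt")) {
    if (!col %in% names(df)) io_error(sprintf("missing column: %s", col),
                                      "herbmarker_missing_column")
  }
  area_cols <- grep("^area:", names(df), value = TRUE)
  if (!length(area_cols)) io_error("missing column: area:<sample>", "herbmarker_missing_column")
  samples <- sub("^area:", "", area_cols)
  rating_cols <- paste0("rating:", samples)
  areas <- as.matrix(df[, area_cols, drop = FALSE])
  colnames(areas) <- samples
  if (all(rating_cols %in% names(df))) {
    ratings <- as.matrix(df[, rating_cols, drop = FALSE])
    colnames(ratings) <- samples
  } else {
    ratings <- NULL
  }
  bad <- which(!is.finite(df$mz) | df$mz <= 0 | !is.finite(df$rt) | df$rt < 0)
  if (length(bad)) {
    io_error(sprintf("malformed feature row(s) at line(s): %s",
                     paste(bad + 1L, collapse = ", ")),
             "herbmarker_validation_error")
  }
  keep <- intersect(c("id", "mz", "rt", "adduct", "formula", "spectrum_id"), names(df))
  feature_table(df[, keep, drop = FALSE], areas, ratings, manifest)
}

#' Write a feature table (and optionally its manifest) as CSV
#'
#' @param ft A \code{\link{feature_table}}.
#' @param path Output CSV path.
#' @param manifest_path Optional manifest CSV output path.
#' @export
write_feature_table <- function(ft, path, manifest_path = NULL) {
  samples <- colnames(ft$areas)
  df <- ft$features[, c("id", "mz", "rt", "adduct", "formula", "spectrum_id")]
  area_df <- as.data.frame(ft$areas)
  names(area_df) <- paste0("area:", samples)
  rating_df <- as.data.frame(ft$ratings)
  names(rating_df) <- paste0("rating:", samples)
  out <- cbind(df, area_df, rating_df)
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  if (!is.null(manifest_path)) {
    utils::write.csv(ft$manifest, manifest_path, row.names = FALSE)
  }
  invisible(path)
}

new_spectrum <- function(spectrum_id, precursor_mz, rt, collision_energy, peaks) {
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  colnames(peaks) <- c("mz", "intensity")
  if (!nrow(peaks)) io_error("spectrum must contain at least one peak",
                             "herbmarker_validation_error")
  if (any(peaks[, "intensity"] < 0)) io_error("peak intensities must be non-negative",
                                              "herbmarker_validation_error")
  structure(list(spectrum_id = spectrum_id, precursor_mz = precursor_mz,
                 rt = rt, collision_energy = collision_energy, peaks = peaks),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 spectrum %s: precursor %.5f, RT %.3f min, %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$rt, nrow(x$peaks)))
  invisible(x)
}

#' Read tandem spectra from an MGF file
#'
#' Parses standard \code{BEGIN IONS}/\code{END IONS} blocks with
#' \code{PEPMASS}, \code{RTINSECONDS} (converted to minutes), and optional
#' \code{COLLISION_ENERGY} and \code{TITLE} headers.  Spectrum ids come from
#' \code{TITLE} when present, else the block sequence number.
#'
#' @param path MGF path.
#' @return Named list of \code{ms2_spectrum} objects (possibly empty).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) > length(ends)) {
    io_error(sprintf("unterminated MGF block starting at line %d",
                     starts[length(ends) + 1L]),
             "herbmarker_parse_error")
  }
  spectra <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grep("=", block, fixed = TRUE, value = TRUE)
    pk_lines <- block[!grepl("=", block, fixed = TRUE) & nzchar(trimws(block))]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    pepmass <- as.numeric(strsplit(trimws(get("PEPMASS")), "\\s+")[[1]][1])
    rt_sec <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    ce <- suppressWarnings(as.numeric(get("COLLISION_ENERGY")))
    title <- get("TITLE")
    id <- if (!is.na(title) && nzchar(title)) title else sprintf("spectrum_%d", k)
    pk <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "\\s+"),
                                function(p) as.numeric(p[1:2])))
    spectra[[k]] <- new_spectrum(id, pepmass,
                                 if (is.na(rt_sec)) NA_real_ else rt_sec / 60,
                                 ce, pk)
  }
  names(spectra) <- vapply(spectra, `[[`, "", "spectrum_id")
  spectra
}

#' Write tandem spectra to an MGF file
#'
#' @param spectra List of \code{ms2_spectrum} objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", sp$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.8f", sp$precursor_mz), con)
    if (!is.na(sp$rt)) writeLines(sprintf("RTINSECONDS=%.6f", sp$rt * 60), con)
    if (!is.null(sp$collision_energy) && !is.na(sp$collision_energy))
      writeLines(sprintf("COLLISION_ENERGY=%g", sp$collision_energy), con)
    writeLines(sprintf("%.8f %.6f", sp$peaks[, "mz"], sp$peaks[, "intensity"]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a spectral library in MSP format
#'
#' Records are validated against the adduct registry: an entry whose
#' \code{PrecursorMZ} deviates from the theoretical ion m/z of its formula
#' and adduct by more than \code{precursor_tol_ppm} is quarantined (returned
#' in the \code{"quarantined"} attribute with a warning), never silently
#' dropped.
#'
#' @param path MSP path.
#' @param precursor_tol_ppm Consistency tolerance (default 10 ppm).
#' @return List of library entries, each with \code{name}, \code{formula},
#'   \code{adduct}, \code{precursor_mz}, \code{collision_energy},
#'   \code{class_tag}, \code{source}, \code{peaks}.
#' @export
read_msp <- function(path, precursor_tol_ppm = 10) {
  lines <- readLines(path, warn = FALSE)
  name_idx <- grep("^Name:", lines)
  entries <- list(); quarantined <- list()
  bounds <- c(name_idx, length(lines) + 1L)
  for (k in seq_along(name_idx)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    get <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(hit)) trimws(sub(paste0("^", key, ":"), "", hit[1])) else NA_character_
    }
    npk <- suppressWarnings(as.integer(get("Num Peaks")))
    pk_start <- grep("^Num Peaks:", block)[1] + 1L
    pk_lines <- block[pk_start:length(block)]
    pk_lines <- pk_lines[nzchar(trimws(pk_lines))]
    pk <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "[\\s;]+", perl = TRUE),
                                function(p) as.numeric(p[1:2])))
    if (!is.na(npk) && nrow(pk) != npk) {
      io_error(sprintf("MSP entry '%s': Num Peaks=%d but %d peak lines",
                       get("Name"), npk, nrow(pk)), "herbmarker_parse_error")
    }
    entry <- list(name = get("Name"),
                  formula = get("Formula"),
                  adduct = get("Precursor_type"),
                  precursor_mz = suppressWarnings(as.numeric(get("PrecursorMZ"))),
                  collision_energy = suppressWarnings(as.numeric(get("Collision_energy"))),
                  class_tag = get("Comment"),
                  source = get("Source"),
                  peaks = pk[order(pk[, 1L]), , drop = FALSE])
    colnames(entry$peaks) <- c("mz", "intensity")
    ok <- TRUE
    if (!is.na(entry$formula) && !is.na(entry$adduct) && !is.na(entry$precursor_mz)) {
      theo <- tryCatch(ion_mz(entry$formula, entry$adduct), error = function(e) NA_real_)
      if (!is.na(theo) && abs(ppm_error(entry$precursor_mz, theo)) > precursor_tol_ppm) {
        ok <- FALSE
      }
    }
    if (ok) entries[[length(entries) + 1L]] <- entry
    else quarantined[[length(quarantined) + 1L]] <- entry
  }
  if (length(quarantined)) {
    warning(sprintf("%d MSP entr%s quarantined: PrecursorMZ inconsistent with formula/adduct",
                    length(quarantined), if (length(quarantined) == 1L) "y" else "ies"))
  }
  attr(entries, "quarantined") <- quarantined
  entries
}

#' Write a spectral library in MSP format
#'
#' @param entries List of library entries as returned by \code{\link{read_msp}}.
#' @param path Output path.
#' @export
write_msp <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in entries) {
    writeLines(sprintf("Name: %s", e$name), con)
    if (!is.na(e$formula)) writeLines(sprintf("Formula: %s", e$formula), con)
    if (!is.na(e$adduct)) writeLines(sprintf("Precursor_type: %s", e$adduct), con)
    if (!is.na(e$precursor_mz)) writeLines(sprintf("PrecursorMZ: %.8f", e$precursor_mz), con)
    if (!is.null(e$collision_energy) && !is.na(e$collision_energy))
      writeLines(sprintf("Collision_energy: %g", e$collision_energy), con)
    if (!is.na(e$class_tag)) writeLines(sprintf("Comment: %s", e$class_tag), con)
    if (!is.null(e$source) && !is.na(e$source)) writeLines(sprintf("Source: %s", e$source), con)
    writeLines(sprintf("Num Peaks: %d", nrow(e$peaks)), con)
    writeLines(sprintf("%.8f %.6f", e$peaks[, "mz"], e$peaks[, "intensity"]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read the in-house compound database
#'
#' CSV with columns \code{name,formula,class} and optional \code{clogp},
#' \code{cas}.  Formulas must parse; names must be unique.
#'
#' @param path CSV path.
#' @return data.frame with columns \code{name}, \code{formula},
#'   \code{class_tag}, \code{clogp}, \code{cas}.
#' @export
read_inhouse_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("name", "formula", "class")) {
    if (!col %in% names(df)) io_error(sprintf("missing column: %s", col),
                                      "herbmarker_missing_column")
  }
  if (anyDuplicated(df$name))
    io_error("in-house database names must be unique", "herbmarker_validation_error")
  for (f in df$formula) parse_formula(f)  # raises on malformed formulas
  data.frame(name = df$name, formula = df$formula, class_tag = df$class,
             clogp = if ("clogp" %in% names(df)) df$clogp else NA_real_,
             cas = if ("cas" %in% names(df)) df$cas else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write an analysis report as CSV
#'
#' @param records data.frame of per-feature or per-annotation records
#'   (cascade flags, scores, reasons).
#' @param path Output CSV path.
#' @export
write_report <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
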