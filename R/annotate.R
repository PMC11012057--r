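# Rule-based compound identification: Method A, targeted diagnostic-
# product-ion (DPI) class discovery; Method B, in-house database precursor
# search with a fragmentation-pattern check; Method C, spectral-library
# matching with score/confidence/matched-fragment acceptance rules; plus
# heteroatom and terpene-isomer exclusion and ClogP-based isomer retention
# ordering.

#' Shipped diagnostic-product-ion rules
#'
#' Class-characteristic fragment m/z values: the caffeoyl acylium ion
#' (163.03897, protonated C9H6O3) for caffeoylquinic acids, and the
#' protonated aglycone ions of luteolin (287.05501), apigenin (271.06009),
#' diosmetin (301.07037), and acacetin (285.07574) for the corresponding
#' flavonoid glycoside classes.  Ships as editable plain text
#' (\code{inst/extdata/dpi_rules.csv}); the \code{dpi_mz} field is a
#' space-separated list.
#'
#' @param path Optional alternative rules CSV.
#' @return data.frame with columns \code{class}, \code{dpi_mz} (list
#'   column of numeric vectors), \code{tolerance_ppm}.
#' @export
dpi_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dpi_rules.csv", package = "herbmarker")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$dpi_mz <- lapply(strsplit(as.character(df$dpi_mz), "\\s+"), as.numeric)
  df
}

#' Targeted DPI class search (Method A)
#'
#' A spectrum is a hit for a class iff at least one of the class's DPI m/z
#' values matches a fragment within the rule tolerance.  Hits carry the
#' matched fragment m/z and its ppm deviation; candidate molecular formulas
#' for the precursor can then be obtained with
#' \code{\link{enumerate_formulas}}.
#'
#' @param spectra List of \code{ms2_spectrum} objects.
#' @param rules DPI rule table from \code{\link{dpi_rules}}.
#' @return data.frame with columns \code{spectrum_id}, \code{class},
#'   \code{dpi_mz}, \code{matched_mz}, \code{error_ppm}; zero rows when
#'   nothing hits.
#' @export
dpi_search <- function(spectra, rules = dpi_rules()) {
  hits <- data.frame(spectrum_id = character(), class = character(),
                     dpi_mz = numeric(), matched_mz = numeric(),
                     error_ppm = numeric(), stringsAsFactors = FALSE)
  for (sp in spectra) {
    for (r in seq_len(nrow(rules))) {
      tol <- rules$tolerance_ppm[r]
      for (dpi in rules$dpi_mz[[r]]) {
        d <- abs(sp$peaks[, "mz"] - dpi)
        k <- which.min(d)
        if (length(k) && d[k] <= dpi * tol * 1e-6) {
          hits <- rbind(hits, data.frame(
            spectrum_id = sp$spectrum_id, class = rules$class[r],
            dpi_mz = dpi, matched_mz = sp$peaks[k, "mz"],
            error_ppm = 1e6 * (sp$peaks[k, "mz"] - dpi) / dpi,
            stringsAsFactors = FALSE))
          break  # one DPI match suffices for the class
        }
      }
    }
  }
  hits
}

#' In-house database precursor search (Method B)
#'
#' For each database entry and each adduct hypothesis, features whose m/z
#' lies within \code{tol} ppm of the theoretical ion m/z are candidates.
#' A candidate is promoted to \code{"identified"} when its linked spectrum
#' carries a DPI of the entry's compound class (the fragmentation-pattern
#' check); otherwise it stays \code{"tentative"}.
#'
#' @param ft A \code{\link{feature_table}}.
#' @param db In-house database data.frame (see
#'   \code{\link{read_inhouse_db}}).
#' @param adducts Adduct names to hypothesise (default [M+H]+ and [M+Na]+).
#' @param spectra Named list of \code{ms2_spectrum} objects.
#' @param rules DPI rule table.
#' @param tol Precursor tolerance in ppm (default 10).
#' @return data.frame of annotation records (feature, method = "B",
#'   candidate name, formula, adduct, theoretical and observed m/z, ppm
#'   error, status, evidence).
#' @export
db_precursor_search <- function(ft, db, adducts = c("[M+H]+", "[M+Na]+"),
                                spectra = list(), rules = dpi_rules(),
                                tol = 10) {
  stopifnot(all(c("name", "formula", "class_tag") %in% names(db)))
  hits <- if (length(spectra)) dpi_search(spectra, rules) else
    data.frame(spectrum_id = character(), class = character())
  recs <- NULL
  fx <- ft$features
  for (e in seq_len(nrow(db))) {
    for (add in adducts) {
      theo <- ion_mz(db$formula[e], add)
      err <- ppm_error(fx$mz, theo)
      for (i in which(abs(err) <= tol)) {
        sid <- fx$spectrum_id[i]
        pattern_ok <- !is.na(sid) &&
          any(hits$spectrum_id == sid & hits$class == db$class_tag[e])
        recs <- rbind(recs, data.frame(
          feature = fx$id[i], method = "B", name = db$name[e],
          formula = db$formula[e], class_tag = db$class_tag[e], adduct = add,
          theoretical_mz = theo, observed_mz = fx$mz[i], error_ppm = err[i],
          status = if (pattern_ok) "identified" else "tentative",
          evidence = if (pattern_ok) sprintf("precursor %.1f ppm + class DPI", err[i])
                     else sprintf("precursor %.1f ppm, no spectrum/DPI", err[i]),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(recs)) {
    recs <- data.frame(feature = character(), method = character(),
                       name = character(), formula = character(),
                       class_tag = character(), adduct = character(),
                       theoretical_mz = numeric(), observed_mz = numeric(),
                       error_ppm = numeric(), status = character(),
                       evidence = character(), stringsAsFactors = FALSE)
  }
  recs
}

#' Match a query spectrum against one library entry (Method C)
#'
#' Entries whose collision energy differs from the query's by more than
#' \code{ce_tol} (relative) are skipped (\code{NULL} return).  Fragments
#' are paired greedily within \code{frag_tol} ppm, highest intensity
#' product first, each peak used at most once.  The score is 100 times the
#' cosine similarity of square-root intensity vectors over the union peak
#' set; the confidence is 100 times the matched fraction of total library
#' intensity.
#'
#' @param spectrum Query \code{ms2_spectrum}.
#' @param entry Library entry (see \code{\link{read_msp}}).
#' @param frag_tol Fragment tolerance in ppm (default 10).
#' @param ce_tol Relative collision-energy tolerance (default 0.2).
#' @return A list of class \code{"match_result"} with \code{name},
#'   \code{score}, \code{confidence}, \code{n_matched}, \code{source}; or
#'   \code{NULL} when the entry is skipped on collision energy.
#' @export
library_match <- function(spectrum, entry, frag_tol = 10, ce_tol = 0.2) {
  q <- spectrum$peaks; l <- entry$peaks
  if (!nrow(q) || !nrow(l)) stop("both peak lists must be non-empty")
  if (sum(q[, "intensity"]) <= 0 || sum(l[, "intensity"]) <= 0) {
    stop("zero-intensity spectra cannot be matched")
  }
  ce_q <- spectrum$collision_energy; ce_l <- entry$collision_energy
  if (!is.null(ce_q) && !is.null(ce_l) && !is.na(ce_q) && !is.na(ce_l) &&
      ce_l > 0 && abs(ce_q - ce_l) / ce_l > ce_tol) {
    return(NULL)
  }
  # candidate pairs within tolerance, greedy by intensity product
  cand <- NULL
  for (i in seq_len(nrow(q))) {
    d <- abs(l[, "mz"] - q[i, "mz"])
    ok <- which(d <= pmax(q[i, "mz"], l[, "mz"]) * frag_tol * 1e-6)
    if (length(ok)) {
      cand <- rbind(cand, cbind(i = i, j = ok,
                                prod = q[i, "intensity"] * l[ok, "intensity"]))
    }
  }
  matched <- matrix(integer(), 0L, 2L)
  if (!is.null(cand)) {
    cand <- cand[order(-cand[, "prod"]), , drop = FALSE]
    used_q <- logical(nrow(q)); used_l <- logical(nrow(l))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (!used_q[i] && !used_l[j]) {
        matched <- rbind(matched, c(i, j))
        used_q[i] <- TRUE; used_l[j] <- TRUE
      }
    }
  }
  sq <- sqrt(q[, "intensity"]); sl <- sqrt(l[, "intensity"])
  dot <- if (nrow(matched)) sum(sq[matched[, 1L]] * sl[matched[, 2L]]) else 0
  score <- 100 * dot / (sqrt(sum(sq^2)) * sqrt(sum(sl^2)))
  conf <- 100 * (if (nrow(matched)) sum(l[matched[, 2L], "intensity"]) else 0) /
    sum(l[, "intensity"])
  structure(list(name = entry$name, formula = entry$formula,
                 class_tag = entry$class_tag,
                 score = score, confidence = conf, n_matched = nrow(matched),
                 source = if (is.null(entry$source) || is.na(entry$source))
                   "vault-like" else entry$source,
                 accepted = NA, reject_reason = NA_character_),
            class = "match_result")
}

#' Apply the library-match acceptance rules
#'
#' Keeps the top \code{max_results} results by score.  A result is
#' accepted iff (cloud-like source AND score >= 90 AND confidence >= 60)
#' OR (vault-like source AND score >= 90 AND at least 3 matched
#' fragments).  Every rejection carries a reason.  The rule is monotone:
#' raising any threshold never accepts a previously rejected result.
#'
#' @param results List of \code{match_result} objects.
#' @param max_results Maximum results kept per query (default 10).
#' @param score_min Minimum score (default 90).
#' @param confidence_min Minimum confidence for cloud-like sources
#'   (default 60).
#' @param min_matched Minimum matched fragments for vault-like sources
#'   (default 3).
#' @return The retained results with \code{accepted} and
#'   \code{reject_reason} filled in, ordered by descending score.
#' @export
accept_matches <- function(results, max_results = 10, score_min = 90,
                           confidence_min = 60, min_matched = 3) {
  results <- results[!vapply(results, is.null, logical(1L))]
  if (!length(results)) return(list())
  ord <- order(-vapply(results, `[[`, 0, "score"))
  results <- results[ord][seq_len(min(max_results, length(results)))]
  lapply(results, function(r) {
    if (r$score < score_min) {
      r$accepted <- FALSE
      r$reject_reason <- sprintf("score %.1f below %g", r$score, score_min)
    } else if (identical(r$source, "cloud-like")) {
      if (r$confidence >= confidence_min) {
        r$accepted <- TRUE
      } else {
        r$accepted <- FALSE
        r$reject_reason <- sprintf("confidence %.1f below %g", r$confidence,
                                   confidence_min)
      }
    } else {
      if (r$n_matched >= min_matched) {
        r$accepted <- TRUE
      } else {
        r$accepted <- FALSE
        r$reject_reason <- sprintf("fewer than %d matched fragments", min_matched)
      }
    }
    r
  })
}

#' Heteroatom and terpene-isomer exclusion rules
#'
#' Rejects candidates whose formula contains elements outside
#' \code{allowed_elements}; and, for terpene-class candidates, when more
#' than two accepted isomers share a molecular formula on one feature the
#' spectra cannot distinguish them, so all are rejected with reason
#' "terpene isomer ambiguity".
#'
#' @param records Annotation data.frame with columns \code{feature},
#'   \code{name}, \code{formula}, \code{class_tag}, \code{status}.
#' @param allowed_elements Permitted elements (default C, H, N, O).
#' @return The records with \code{status}/\code{reason} updated.
#' @export
apply_exclusion_rules <- function(records, allowed_elements = c("C", "H", "N", "O")) {
  if (!nrow(records)) return(records)
  if (!"reason" %in% names(records)) records$reason <- NA_character_
  for (i in seq_len(nrow(records))) {
    els <- tryCatch(formula_elements(records$formula[i]), error = function(e) NULL)
    if (is.null(els) || !all(els %in% allowed_elements)) {
      records$status[i] <- "rejected"
      records$reason[i] <- "formula contains disallowed elements"
    }
  }
  live <- records$status != "rejected" & records$class_tag == "terpene"
  if (any(live)) {
    key <- paste(records$feature, records$formula)
    for (k in unique(key[live])) {
      idx <- which(live & key == k)
      if (length(unique(records$name[idx])) > 2L) {
        records$status[idx] <- "rejected"
        records$reason[idx] <- "terpene isomer ambiguity"
      }
    }
  }
  records
}

#' Assign coeluting isomers to features by ClogP order
#'
#' Under reversed-phase chromatography a higher calculated logP implies a
#' longer retention time, so candidates sorted by ascending ClogP are
#' paired with features sorted by ascending RT.  Ties or missing ClogP
#' values yield no assignment (flagged \code{"unresolved"}).
#'
#' @param candidates data.frame with columns \code{name}, \code{clogp}.
#' @param features data.frame with columns \code{id}, \code{rt}.
#' @return data.frame with columns \code{name}, \code{clogp},
#'   \code{feature}, \code{rt}, \code{status}; the candidate and feature
#'   lists must have equal length.
#' @export
assign_isomers_by_clogp <- function(candidates, features) {
  if (nrow(candidates) != nrow(features)) {
    stop("candidate and feature lists must have equal length")
  }
  unresolved <- anyNA(candidates$clogp) ||
    anyDuplicated(candidates$clogp) > 0L
  if (unresolved) {
    return(data.frame(name = candidates$name, clogp = candidates$clogp,
                      feature = NA_character_, rt = NA_real_,
                      status = "unresolved", stringsAsFactors = FALSE))
  }
  co <- order(candidates$clogp)
  fo <- order(features$rt)
  data.frame(name = candidates$name[co], clogp = candidates$clogp[co],
             feature = features$id[fo], rt = features$rt[fo],
             status = "assigned", stringsAsFactors = FALSE)
}
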