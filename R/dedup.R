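# In-source-fragment and adduct deduplication: detect coeluting satellite
# features that are alternative adducts or ISF products of a parent, and
# collapse marker features to compounds.  Satellites are flagged, not
# deleted: a coeluting genuine compound could otherwise be lost silently.

#' Registered neutral losses
#'
#' Common losses for plant metabolites: water, CO, hexosyl, deoxyhexosyl
#' (rhamnosyl), caffeoyl, malonyl, and glucuronyl moieties.  Ships as a
#' plain-text table (\code{inst/extdata/neutral_losses.csv}).
#'
#' @param path Optional alternative registry CSV with columns
#'   \code{name,mass}.
#' @return data.frame with columns \code{name}, \code{mass} (Da).
#' @export
neutral_loss_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "neutral_losses.csv", package = "herbmarker")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

relation_edges <- function(parent = character(), child = character(),
                           kind = character(), evidence = character(),
                           delta_ppm = numeric(), delta_rt = numeric()) {
  data.frame(parent = parent, child = child, kind = kind,
             evidence = evidence, delta_ppm = delta_ppm, delta_rt = delta_rt,
             stringsAsFactors = FALSE)
}

#' Detect coeluting adduct pairs
#'
#' For every pair of features within \code{rt_tol} minutes, if their m/z
#' difference equals the difference between two registered adduct deltas
#' (e.g. [M+Na]+ minus [M+H]+ = 21.981944 Da) within \code{mz_tol} ppm of
#' the larger m/z, an adduct edge is emitted.  The parent is the [M+H]+
#' member when one side's declared adduct identifies it, otherwise the
#' larger-area member.
#'
#' @param ft A \code{\link{feature_table}}.
#' @param rt_tol Coelution tolerance in minutes (default 0.1).
#' @param mz_tol Mass tolerance in ppm (default 5).
#' @param registry Adduct registry (see \code{\link{adduct_registry}}).
#' @return data.frame of relation edges (parent, child, kind = "adduct",
#'   evidence, delta_ppm, delta_rt).
#' @export
detect_adduct_pairs <- function(ft, rt_tol = 0.1, mz_tol = 5,
                                registry = adduct_registry()) {
  fx <- ft$features
  n <- nrow(fx)
  edges <- relation_edges()
  if (n < 2L) return(edges)
  combos <- utils::combn(nrow(registry), 2L)
  pair_delta <- abs(registry$mass_delta[combos[1L, ]] - registry$mass_delta[combos[2L, ]])
  pair_name <- paste(registry$name[combos[1L, ]], "vs", registry$name[combos[2L, ]])
  max_area <- apply(ft$areas, 1L, max, na.rm = TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      drt <- abs(fx$rt[i] - fx$rt[j])
      if (drt > rt_tol) next
      dmz <- abs(fx$mz[i] - fx$mz[j])
      tol_da <- max(fx$mz[i], fx$mz[j]) * mz_tol * 1e-6
      hit <- which(abs(dmz - pair_delta) <= tol_da)
      if (!length(hit)) next
      k <- hit[which.min(abs(dmz - pair_delta[hit]))]
      # parent preference: declared [M+H]+ member, else larger area
      is_ph <- c(identical(fx$adduct[i], "[M+H]+"), identical(fx$adduct[j], "[M+H]+"))
      if (xor(is_ph[1], is_ph[2])) {
        pi_ <- if (is_ph[1]) i else j
      } else {
        pi_ <- if (max_area[i] >= max_area[j]) i else j
      }
      ci_ <- if (pi_ == i) j else i
      edges <- rbind(edges, relation_edges(
        parent = fx$id[pi_], child = fx$id[ci_], kind = "adduct",
        evidence = pair_name[k],
        delta_ppm = 1e6 * (dmz - pair_delta[k]) / max(fx$mz[i], fx$mz[j]),
        delta_rt = drt))
    }
  }
  edges
}

#' Detect in-source-fragmentation satellites
#'
#' For each coeluting ordered pair (parent = larger precursor m/z), an
#' \code{isf_fragment} edge is emitted when the child's precursor m/z
#' matches a fragment in the parent's MS/MS spectrum within \code{frag_tol}
#' ppm; otherwise an \code{isf_neutral_loss} edge is emitted when the
#' precursor difference matches a registered neutral loss within
#' \code{frag_tol} ppm of the parent precursor.  Parents without a linked
#' spectrum contribute through the precursor-difference rule only.
#'
#' @param ft A \code{\link{feature_table}}.
#' @param spectra Named list of \code{ms2_spectrum} objects; features link
#'   through their \code{spectrum_id} column.
#' @param rt_tol Coelution tolerance in minutes (default 0.1).
#' @param frag_tol Fragment/precursor mass tolerance in ppm (default 10).
#' @param losses Neutral-loss registry data.frame.
#' @return data.frame of relation edges.
#' @export
detect_isf <- function(ft, spectra = list(), rt_tol = 0.1, frag_tol = 10,
                       losses = neutral_loss_registry()) {
  fx <- ft$features
  n <- nrow(fx)
  edges <- relation_edges()
  if (n < 2L) return(edges)
  spec_of <- function(i) {
    sid <- fx$spectrum_id[i]
    if (!is.na(sid) && sid %in% names(spectra)) spectra[[sid]] else NULL
  }
  for (pi_ in seq_len(n)) {
    for (ci_ in seq_len(n)) {
      if (pi_ == ci_ || fx$mz[pi_] <= fx$mz[ci_]) next
      drt <- abs(fx$rt[pi_] - fx$rt[ci_])
      if (drt > rt_tol) next
      tol_da <- fx$mz[pi_] * frag_tol * 1e-6
      sp <- spec_of(pi_)
      found <- FALSE
      if (!is.null(sp)) {
        dmz <- abs(sp$peaks[, "mz"] - fx$mz[ci_])
        k <- which.min(dmz)
        if (dmz[k] <= fx$mz[ci_] * frag_tol * 1e-6) {
          edges <- rbind(edges, relation_edges(
            parent = fx$id[pi_], child = fx$id[ci_], kind = "isf_fragment",
            evidence = sprintf("fragment %.5f", sp$peaks[k, "mz"]),
            delta_ppm = 1e6 * (fx$mz[ci_] - sp$peaks[k, "mz"]) / sp$peaks[k, "mz"],
            delta_rt = drt))
          found <- TRUE
        }
      }
      if (!found) {
        dprec <- fx$mz[pi_] - fx$mz[ci_]
        dl <- abs(dprec - losses$mass)
        k <- which.min(dl)
        if (dl[k] <= tol_da) {
          edges <- rbind(edges, relation_edges(
            parent = fx$id[pi_], child = fx$id[ci_], kind = "isf_neutral_loss",
            evidence = sprintf("loss %s", losses$name[k]),
            delta_ppm = 1e6 * (dprec - losses$mass[k]) / fx$mz[pi_],
            delta_rt = drt))
          found <- TRUE
        }
      }
      if (!found && !is.null(sp)) {
        # child precursor plus a registered loss matching a parent fragment
        for (k in seq_len(nrow(losses))) {
          target <- fx$mz[ci_] - losses$mass[k]
          if (target <= 0) next
          dmz <- abs(sp$peaks[, "mz"] - target)
          m <- which.min(dmz)
          if (dmz[m] <= fx$mz[ci_] * frag_tol * 1e-6) {
            edges <- rbind(edges, relation_edges(
              parent = fx$id[pi_], child = fx$id[ci_], kind = "isf_neutral_loss",
              evidence = sprintf("fragment %.5f + loss %s", sp$peaks[m, "mz"], losses$name[k]),
              delta_ppm = 1e6 * (target - sp$peaks[m, "mz"]) / sp$peaks[m, "mz"],
              delta_rt = drt))
            break
          }
        }
      }
    }
  }
  edges
}

#' Collapse satellite features into compounds
#'
#' Connected components over the relation-edge graph become compounds; the
#' representative is the [M+H]+ parent when one is present in the
#' component, else the largest-area member.  Satellites are annotated
#' ("ISF product of X" / "adduct form of X"), not deleted, and the
#' member-to-compound audit table is returned.
#'
#' @param ft A \code{\link{feature_table}}.
#' @param edges Relation edges from \code{\link{detect_adduct_pairs}} and/or
#'   \code{\link{detect_isf}} (row-bound).
#' @return List with \code{compounds} (data.frame: compound id,
#'   representative feature, n_members), \code{members} (audit table with
#'   per-member role and annotation), and \code{n_compounds}.
#' @export
collapse_features <- function(ft, edges) {
  fx <- ft$features
  ids <- fx$id
  if (nrow(edges)) {
    bad <- setdiff(c(edges$parent, edges$child), ids)
    if (length(bad)) stop(sprintf("edge references unknown feature(s): %s",
                                  paste(bad, collapse = ", ")))
  }
  # union-find over feature ids
  comp <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(match(edges$parent[e], ids))
      b <- find(match(edges$child[e], ids))
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(ids), find, integer(1L))
  max_area <- apply(ft$areas, 1L, max, na.rm = TRUE)
  members <- NULL
  compounds <- NULL
  for (r in sort(unique(root))) {
    mem <- which(root == r)
    ph <- mem[!is.na(fx$adduct[mem]) & fx$adduct[mem] == "[M+H]+" &
                !(fx$id[mem] %in% edges$child)]
    rep_i <- if (length(ph) == 1L) ph
             else if (length(ph) > 1L) ph[which.max(max_area[ph])]
             else mem[which.max(max_area[mem])]
    cid <- fx$id[rep_i]
    role <- rep("representative", length(mem))
    note <- rep(NA_character_, length(mem))
    for (m in seq_along(mem)) {
      if (mem[m] == rep_i) next
      kinds <- edges$kind[edges$child == fx$id[mem[m]]]
      role[m] <- if (any(grepl("^isf", kinds))) "isf_satellite"
                 else if ("adduct" %in% kinds) "adduct_satellite"
                 else "member"
      note[m] <- switch(role[m],
                        isf_satellite = sprintf("ISF product of %s", cid),
                        adduct_satellite = sprintf("adduct form of %s", cid),
                        NA_character_)
    }
    members <- rbind(members, data.frame(
      feature = fx$id[mem], compound = cid, role = role, annotation = note,
      stringsAsFactors = FALSE))
    compounds <- rbind(compounds, data.frame(
      compound = cid, representative_mz = fx$mz[rep_i],
      representative_rt = fx$rt[rep_i], n_members = length(mem),
      stringsAsFactors = FALSE))
  }
  list(compounds = compounds, members = members, n_compounds = nrow(compounds))
}
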