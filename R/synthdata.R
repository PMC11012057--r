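# Synthetic-study generator: complete feature tables, tandem spectra,
# spectral libraries and an in-house database with full ground truth
# (planted group effects, adduct and ISF satellites, true identities), so
# every pipeline stage can be validated without external data.  Also the
# ready-made 25-feature worked-example fixture transcribed from published
# marker tables shipped with the package.

#' Simulation configuration
#'
#' Defaults emulate a seven-group herbal study (batch sizes 10, 9, 12, 13,
#' 12, 12, 12 across cultivars), log-normal peak areas (sigma 0.2 on the
#' log10 scale) with multiplicative group effects planted on marker
#' features, Gaussian mass errors of SD 1 ppm (sub-ppm instrument
#' accuracy), small RT jitter, coeluting adduct/ISF satellite features,
#' and a peak-rating mixture in which roughly a fifth of features fail the
#' rating-6 quality threshold.
#'
#' @param n_groups Number of sample groups (default 7).
#' @param samples_per_group Integer vector of per-group sample counts
#'   (recycled to \code{n_groups}; default \code{c(10,9,12,13,12,12,12)}).
#' @param n_null_features Features without group effects (default 500).
#' @param n_marker_features Features with planted group shifts (default 20).
#' @param effect_size_sd Planted shift in units of the within-group SD
#'   (default 4).
#' @param area_lognormal_sigma Within-group SD of log10 areas (default 0.2).
#' @param mass_error_sd_ppm Gaussian m/z error SD in ppm (default 1).
#' @param rt_jitter_sd_min RT jitter SD for satellites, minutes (default 0.01).
#' @param adduct_satellite_rate,isf_satellite_rate Per-parent probability
#'   of planting a coeluting [M+Na]+ or in-source-fragment satellite.
#' @param rating_low_rate Fraction of features whose ratings fall below the
#'   quality threshold (default 0.22).
#' @param seed Mandatory RNG seed.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_groups = 7,
                       samples_per_group = c(10, 9, 12, 13, 12, 12, 12),
                       n_null_features = 500,
                       n_marker_features = 20,
                       effect_size_sd = 4,
                       area_lognormal_sigma = 0.2,
                       mass_error_sd_ppm = 1,
                       rt_jitter_sd_min = 0.01,
                       adduct_satellite_rate = 0.15,
                       isf_satellite_rate = 0.15,
                       rating_low_rate = 0.22,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible studies")
  rates <- c(adduct_satellite_rate, isf_satellite_rate, rating_low_rate)
  stopifnot(all(rates >= 0 & rates <= 1), n_groups >= 2,
            n_null_features + n_marker_features >= 2)
  samples_per_group <- rep_len(samples_per_group, n_groups)
  structure(list(n_groups = n_groups, samples_per_group = samples_per_group,
                 n_null_features = n_null_features,
                 n_marker_features = n_marker_features,
                 effect_size_sd = effect_size_sd,
                 area_lognormal_sigma = area_lognormal_sigma,
                 mass_error_sd_ppm = mass_error_sd_ppm,
                 rt_jitter_sd_min = rt_jitter_sd_min,
                 adduct_satellite_rate = adduct_satellite_rate,
                 isf_satellite_rate = isf_satellite_rate,
                 rating_low_rate = rating_low_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Loss moiety formulas used when building ISF satellites (child formula =
# parent formula minus loss).
LOSS_FORMULA <- list(H2O = c(H = 2L, O = 1L),
                     CO = c(C = 1L, O = 1L),
                     hexose = c(C = 6L, H = 10L, O = 5L),
                     deoxyhexose = c(C = 6L, H = 10L, O = 4L),
                     caffeoyl = c(C = 9L, H = 6L, O = 3L),
                     malonyl = c(C = 3L, H = 2L, O = 3L),
                     glucuronyl = c(C = 6L, H = 8L, O = 6L))

# Random plausible CHNO formula: pick C, N, RDBE, O, derive H.
random_formula <- function() {
  repeat {
    nC <- sample(8:40, 1L)
    nN <- sample(0:2, 1L, prob = c(0.8, 0.15, 0.05))
    dbe <- sample(1:14, 1L)
    nH <- 2L * nC + 2L + nN - 2L * dbe
    nO <- sample(2:12, 1L)
    if (nH < 4L) next
    hc <- nH / nC
    if (hc < 0.5 || hc > 2.2) next
    return(c(C = nC, H = nH, N = nN, O = nO))
  }
}

class_dpi_mz <- function(cls) {
  rules <- dpi_rules()
  i <- match(cls, rules$class)
  if (is.na(i)) NULL else rules$dpi_mz[[i]]
}

#' Generate a complete synthetic study with ground truth
#'
#' Builds a feature table (parent compounds plus planted adduct and ISF
#' satellites), tandem spectra with class-characteristic diagnostic ions,
#' a spectral library (true spectra with mild intensity noise), an
#' in-house database, and the full ground truth needed to score every
#' pipeline stage.  Parent compounds elute on an evenly spread RT ladder
#' so distinct compounds are chromatographically resolved; satellites
#' coelute with their parents within the RT jitter.  Deterministic per
#' seed.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{features} (a \code{\link{feature_table}}),
#'   \code{spectra}, \code{library}, \code{db}, and \code{truth} (marker
#'   ids with affected groups, satellite edge table, per-feature class and
#'   formula, per-spectrum identity).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_parent <- cfg$n_null_features + cfg$n_marker_features
  if ((cfg$adduct_satellite_rate > 0 || cfg$isf_satellite_rate > 0) && n_parent == 0L) {
    stop("satellites requested but no parent features configured")
  }
  groups <- paste0("G", seq_len(cfg$n_groups))
  samples <- unlist(lapply(seq_len(cfg$n_groups), function(g) {
    paste0(groups[g], "_S", seq_len(cfg$samples_per_group[g]))
  }))
  manifest <- data.frame(sample = samples,
                         group = rep(groups, cfg$samples_per_group),
                         stringsAsFactors = FALSE)
  n_samp <- length(samples)
  classes <- c("caffeoylquinic", "apigenin", "luteolin", "diosmetin",
               "acacetin", "terpene", "other")

  formulas <- replicate(n_parent, random_formula(), simplify = FALSE)
  cls <- sample(classes, n_parent, replace = TRUE,
                prob = c(0.12, 0.08, 0.08, 0.05, 0.05, 0.2, 0.42))
  neutral <- vapply(formulas, monoisotopic_mass, numeric(1L))
  reg <- adduct_registry()
  proton <- reg$mass_delta[reg$name == "[M+H]+"]
  na_delta <- reg$mass_delta[reg$name == "[M+Na]+"]
  mz_err <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, cfg$mass_error_sd_ppm) * 1e-6)

  # evenly spread elution ladder: distinct compounds are resolved
  spacing <- (48 - 2) / n_parent
  rt_parent <- 2 + (sample(n_parent) - 1L + stats::runif(n_parent, -0.3, 0.3)) * spacing

  # markers: planted multiplicative group effects on log10 areas.  Effects
  # follow a small set of latent chemotype contrasts (a species axis, a
  # cultivar-cluster axis, a single-cultivar axis) rather than arbitrary
  # per-marker patterns: cultivar chemistry differentiates along a few
  # shared axes, and the screening model assumes low-dimensional class
  # structure.
  marker_idx <- if (cfg$n_marker_features > 0)
    sort(sample(n_parent, cfg$n_marker_features)) else integer()
  sigma <- cfg$area_lognormal_sigma
  axes <- rbind(as.numeric(seq_len(cfg$n_groups) == cfg$n_groups),
                as.numeric(seq_len(cfg$n_groups) <= ceiling(cfg$n_groups / 2) &
                             seq_len(cfg$n_groups) < cfg$n_groups),
                as.numeric(seq_len(cfg$n_groups) == 1L))
  effects <- matrix(0, n_parent, cfg$n_groups)
  marker_groups <- vector("list", length(marker_idx))
  for (k in seq_along(marker_idx)) {
    ax <- axes[sample(nrow(axes), 1L), ]
    effects[marker_idx[k], ] <- sample(c(-1, 1), 1L) *
      cfg$effect_size_sd * sigma * ax
    marker_groups[[k]] <- groups[ax != 0]
  }

  mu <- stats::runif(n_parent, 5.3, 7)
  grp_of_sample <- rep(seq_len(cfg$n_groups), cfg$samples_per_group)
  areas_parent <- matrix(0, n_parent, n_samp, dimnames = list(NULL, samples))
  for (i in seq_len(n_parent)) {
    lg <- mu[i] + effects[i, grp_of_sample] + stats::rnorm(n_samp, 0, sigma)
    areas_parent[i, ] <- 10^lg
  }

  # peak-rating mixture: low-rated features fail the quality filter
  low <- stats::runif(n_parent) < cfg$rating_low_rate
  low[marker_idx] <- FALSE
  max_rating <- ifelse(low, stats::runif(n_parent, 2, 5.9),
                       stats::runif(n_parent, 6.5, 10))
  make_ratings <- function(mx) pmax(0, pmin(10, mx - stats::runif(n_samp, 0, 1.5)))
  ratings_of <- function(mx) {
    r <- make_ratings(mx)
    r[which.max(r)] <- mx          # the best file carries the max rating
    r
  }

  ids <- character(); mzs <- numeric(); rts <- numeric(); adds <- character()
  fstr <- character(); sids <- character()
  areas <- NULL; ratings <- NULL
  spectra <- list()
  truth_edges <- NULL
  spec_identity <- NULL

  add_row <- function(id, mz, rt, adduct, formula, sid, ar, rat) {
    ids <<- c(ids, id); mzs <<- c(mzs, mz); rts <<- c(rts, rt)
    adds <<- c(adds, adduct); fstr <<- c(fstr, formula); sids <<- c(sids, sid)
    areas <<- rbind(areas, ar); ratings <<- rbind(ratings, rat)
  }

  for (i in seq_len(n_parent)) {
    id <- sprintf("F%04d", i)
    f_str <- format_formula(formulas[[i]])
    mz_i <- mz_err(neutral[i] + proton)
    rat_i <- ratings_of(max_rating[i])
    sid <- sprintf("S%04d", i)

    # class-aware fragment list: DPI(s) plus random minor fragments
    dpi <- class_dpi_mz(cls[i])
    frag <- c(if (!is.null(dpi)) mz_err(dpi),
              stats::runif(sample(3:6, 1L), 60, max(70, 0.85 * mz_i)))
    isf_loss <- NA_character_
    child <- NULL
    if (stats::runif(1) < cfg$isf_satellite_rate) {
      # in-source water loss is the [M-H2O+H]+ adduct form, which belongs
      # to the adduct channel; ISF satellites are planted for moiety losses
      isf_losses <- LOSS_FORMULA[setdiff(names(LOSS_FORMULA), "H2O")]
      feas <- vapply(isf_losses, function(lf) {
        d <- formulas[[i]]
        all(names(lf) %in% names(d)) && all(d[names(lf)] >= lf) &&
          (neutral[i] - monoisotopic_mass(lf)) > 120
      }, logical(1L))
      if (any(feas)) {
        isf_loss <- sample(names(isf_losses)[feas], 1L)
        lf <- isf_losses[[isf_loss]]
        child_counts <- formulas[[i]]
        child_counts[names(lf)] <- child_counts[names(lf)] - lf
        child_neutral <- neutral[i] - monoisotopic_mass(lf)
        child_mz <- mz_err(child_neutral + proton)
        frag <- c(frag, mz_err(child_neutral + proton))  # ISF ion is a CID fragment too
        child <- list(id = sprintf("F%04d_isf", i),
                      mz = child_mz,
                      rt = rt_parent[i] + stats::rnorm(1, 0, cfg$rt_jitter_sd_min),
                      formula = format_formula(child_counts[child_counts > 0L]))
      }
    }
    frag <- frag[frag < mz_i - 1]
    frag <- sort(unique(frag))
    ints <- 10^stats::runif(length(frag), 3, 6)
    spectra[[sid]] <- new_spectrum(sid, mz_i, rt_parent[i], 20,
                                   cbind(frag, ints))
    spec_identity <- rbind(spec_identity, data.frame(
      spectrum_id = sid, compound = sprintf("compound_%04d", i),
      stringsAsFactors = FALSE))
    add_row(id, mz_i, rt_parent[i], "[M+H]+", f_str, sid, areas_parent[i, ], rat_i)

    if (stats::runif(1) < cfg$adduct_satellite_rate) {
      aid <- sprintf("F%04d_na", i)
      add_row(aid, mz_err(neutral[i] + na_delta),
              rt_parent[i] + stats::rnorm(1, 0, cfg$rt_jitter_sd_min),
              "[M+Na]+", f_str, NA_character_,
              areas_parent[i, ] * stats::runif(1, 0.1, 0.4),
              ratings_of(stats::runif(1, 6.5, 10)))
      truth_edges <- rbind(truth_edges, data.frame(
        parent = id, child = aid, kind = "adduct", stringsAsFactors = FALSE))
    }
    if (!is.null(child)) {
      add_row(child$id, child$mz, child$rt, "[M+H]+", child$formula,
              NA_character_,
              areas_parent[i, ] * stats::runif(1, 0.1, 0.4),
              ratings_of(stats::runif(1, 6.5, 10)))
      truth_edges <- rbind(truth_edges, data.frame(
        parent = id, child = child$id, kind = "isf", stringsAsFactors = FALSE))
    }
  }

  colnames(areas) <- colnames(ratings) <- samples
  feats <- data.frame(id = ids, mz = mzs, rt = rts, adduct = adds,
                      formula = fstr, spectrum_id = sids,
                      stringsAsFactors = FALSE)
  ft <- feature_table(feats, areas, ratings, manifest)

  # spectral library: true spectra with mild intensity noise
  lib <- lapply(seq_len(n_parent), function(i) {
    sid <- sprintf("S%04d", i)
    sp <- spectra[[sid]]
    pk <- sp$peaks
    pk[, "intensity"] <- pk[, "intensity"] * exp(stats::rnorm(nrow(pk), 0, 0.1))
    list(name = sprintf("compound_%04d", i),
         formula = format_formula(formulas[[i]]),
         adduct = "[M+H]+",
         precursor_mz = neutral[i] + proton,
         collision_energy = 20,
         class_tag = cls[i],
         source = "vault-like",
         peaks = pk)
  })

  db <- data.frame(name = sprintf("compound_%04d", seq_len(n_parent)),
                   formula = vapply(formulas, format_formula, ""),
                   class_tag = cls,
                   clogp = round(stats::runif(n_parent, -2, 6), 2),
                   cas = NA_character_, stringsAsFactors = FALSE)

  if (is.null(truth_edges)) {
    truth_edges <- data.frame(parent = character(), child = character(),
                              kind = character(), stringsAsFactors = FALSE)
  }
  truth <- list(
    marker_ids = sprintf("F%04d", marker_idx),
    marker_groups = stats::setNames(marker_groups, sprintf("F%04d", marker_idx)),
    edges = truth_edges,
    feature_class = stats::setNames(cls, sprintf("F%04d", seq_len(n_parent))),
    feature_formula = stats::setNames(vapply(formulas, format_formula, ""),
                                      sprintf("F%04d", seq_len(n_parent))),
    low_rated = sprintf("F%04d", which(low)),
    spectrum_identity = spec_identity)

  list(features = ft, spectra = spectra, library = lib, db = db, truth = truth)
}

#' The 25-feature worked-example fixture
#'
#' Returns the package's bundled table of 25 ranked marker features from a
#' published chrysanthemum study (VIP, RT, formula, adduct, experimental
#' m/z, printed ppm error, and MS/MS fragment lists) as a ready-made
#' \code{\link{feature_table}} plus one spectrum per feature built from
#' the printed fragment list.  Only unit bookkeeping is added: a single
#' pooled QC sample with uniform areas and ratings, and arbitrary
#' descending fragment intensities (the source table prints fragment m/z
#' only).
#'
#' @return List with \code{features} (a \code{feature_table} of 25 rows),
#'   \code{spectra} (25 \code{ms2_spectrum} objects), and \code{table}
#'   (the raw transcription data.frame).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "top25_features.csv", package = "herbmarker")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  spectra <- list()
  for (i in seq_len(nrow(df))) {
    frag <- as.numeric(strsplit(df$fragments[i], "\\s+")[[1]])
    sid <- paste0("MS2_", df$feature[i])
    spectra[[sid]] <- new_spectrum(sid, df$mz[i], df$rt[i], NA_real_,
                                   cbind(frag, rev(seq_along(frag)) * 100))
  }
  feats <- data.frame(id = df$feature, mz = df$mz, rt = df$rt,
                      adduct = df$adduct, formula = df$formula,
                      spectrum_id = paste0("MS2_", df$feature),
                      stringsAsFactors = FALSE)
  areas <- matrix(1e6, nrow(df), 1L, dimnames = list(df$feature, "QC1"))
  ratings <- matrix(10, nrow(df), 1L, dimnames = list(df$feature, "QC1"))
  manifest <- data.frame(sample = "QC1", group = "QC", stringsAsFactors = FALSE)
  list(features = feature_table(feats, areas, ratings, manifest),
       spectra = spectra, table = df)
}
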