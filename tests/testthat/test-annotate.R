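# Compound identification: DPI class search, database precursor search,
# spectral-library matching, exclusion rules, ClogP isomer ordering.

test_that("DPI search flags class-characteristic fragments", {
  fx <- table2_fixture()
  hits <- dpi_search(fx$spectra)
  m15 <- hits[hits$spectrum_id == "MS2_M15", ]
  expect_true("caffeoylquinic" %in% m15$class)   # 163.03897 caffeoyl acylium
  expect_lt(abs(m15$error_ppm[m15$class == "caffeoylquinic"]), 10)
  sp <- spec_of("lut", 449.1078, 12.0, c(287.05501, 153.01864))
  h2 <- dpi_search(list(sp))
  expect_true("luteolin" %in% h2$class)
  expect_equal(nrow(dpi_search(list())), 0L)
})

test_that("database precursor search promotes DPI-consistent candidates", {
  db <- data.frame(name = "1,5-O-dicaffeoylquinic acid", formula = "C25H24O12",
                   class_tag = "caffeoylquinic", clogp = 1.0,
                   cas = NA_character_, stringsAsFactors = FALSE)
  fx <- table2_fixture()
  recs <- db_precursor_search(fx$features, db, spectra = fx$spectra)
  m15 <- recs[recs$feature == "M15", ]
  expect_equal(nrow(m15), 1L)
  expect_identical(m15$status, "identified")    # caffeoyl DPI in its spectrum
  expect_identical(m15$adduct, "[M+H]+")
  expect_lt(abs(m15$error_ppm), 10)

  # same entry, matching feature but no linked spectrum: tentative
  ft <- toy_table(1, mz = ion_mz("C25H24O12", "[M+H]+"), rt = 15.1,
                  formula = "C25H24O12")
  rec2 <- db_precursor_search(ft, db)
  expect_identical(rec2$status, "tentative")

  # nothing within 10 ppm: no record
  ft3 <- toy_table(1, mz = 800.5, rt = 15.1)
  expect_equal(nrow(db_precursor_search(ft3, db)), 0L)
})

test_that("library match scores follow the sqrt-intensity cosine", {
  mzs <- c(100.05, 150.07, 200.09, 250.11, 300.13)
  q <- spec_of("q", 400, 10, mzs, c(100, 400, 900, 400, 100))
  same <- entry_of("self", mzs, c(100, 400, 900, 400, 100))
  r <- library_match(q, same)
  expect_equal(r$score, 100, tolerance = 1e-9)
  expect_equal(r$confidence, 100, tolerance = 1e-9)
  expect_equal(r$n_matched, 5L)

  disj <- entry_of("other", mzs + 5, c(100, 400, 900, 400, 100))
  r0 <- library_match(q, disj)
  expect_equal(r0$score, 0)
  expect_equal(r0$n_matched, 0L)

  # shares 3 of 5 peaks at equal intensities: hand-computed cosine
  # all intensities equal -> sqrt vectors equal -> cos = 3/5
  qe <- spec_of("q", 400, 10, mzs, rep(100, 5))
  part <- entry_of("part", c(mzs[1:3], 500.1, 600.1), rep(100, 5))
  rp <- library_match(qe, part)
  expect_equal(rp$score, 100 * 3 / 5, tolerance = 1e-9)
  expect_equal(rp$n_matched, 3L)
  expect_equal(rp$confidence, 60, tolerance = 1e-9)
})

test_that("library match is symmetric and intensity-scale invariant", {
  set.seed(33)
  for (rep in 1:10) {
    m1 <- sort(runif(6, 100, 500)); m2 <- c(m1[1:3], sort(runif(3, 100, 500)))
    i1 <- 10^runif(6, 2, 5); i2 <- 10^runif(6, 2, 5)
    a <- spec_of("a", 600, 1, m1, i1)
    b <- entry_of("b", m2, i2)
    ab <- library_match(a, b)$score
    ba <- library_match(spec_of("b", 600, 1, m2, i2), entry_of("a", m1, i1))$score
    expect_equal(ab, ba, tolerance = 1e-9)
    scaled <- library_match(spec_of("a", 600, 1, m1, i1 * 1234), b)$score
    expect_equal(scaled, ab, tolerance = 1e-9)
  }
})

test_that("collision-energy gating skips entries outside 20 percent", {
  q <- spec_of("q", 400, 10, c(100.05, 200.09), ce = 20)
  near <- entry_of("near", c(100.05, 200.09), c(1, 1), ce = 23)
  far <- entry_of("far", c(100.05, 200.09), c(1, 1), ce = 30)
  expect_false(is.null(library_match(q, near)))   # 15% off: kept
  expect_null(library_match(q, far))              # 50% off: skipped
})

test_that("acceptance thresholds are inclusive, reasoned, and monotone", {
  mk <- function(score, conf, nm, source) {
    structure(list(name = "x", score = score, confidence = conf,
                   n_matched = nm, source = source, accepted = NA,
                   reject_reason = NA_character_), class = "match_result")
  }
  res <- accept_matches(list(
    mk(90, 60, 5, "cloud-like"),    # boundary accept
    mk(91, 59, 5, "cloud-like"),    # confidence fails
    mk(95, 0, 2, "vault-like"),     # too few matched fragments
    mk(95, 0, 3, "vault-like"),     # vault accept
    mk(89.9, 99, 9, "cloud-like"))) # score fails
  scores <- vapply(res, `[[`, 0, "score")
  expect_false(is.unsorted(rev(scores)))   # ordered by descending score
  expect_true(any(vapply(res, function(r) r$score == 90 && isTRUE(r$accepted), NA)))
  expect_true(any(vapply(res, function(r)
    isFALSE(r$accepted) && grepl("fewer than 3", r$reject_reason), NA)))
  expect_true(any(vapply(res, function(r)
    isFALSE(r$accepted) && grepl("confidence", r$reject_reason), NA)))
  expect_true(any(vapply(res, function(r) r$score == 95 && r$n_matched == 3 &&
                           isTRUE(r$accepted), NA)))

  # monotonicity: raising any threshold never accepts a previously rejected one
  base <- accept_matches(list(mk(92, 70, 4, "cloud-like"),
                              mk(92, 50, 4, "cloud-like"),
                              mk(92, 0, 2, "vault-like")))
  for (args in list(list(score_min = 95), list(confidence_min = 80),
                    list(min_matched = 5))) {
    stricter <- do.call(accept_matches,
                        c(list(list(mk(92, 70, 4, "cloud-like"),
                                    mk(92, 50, 4, "cloud-like"),
                                    mk(92, 0, 2, "vault-like"))), args))
    for (k in seq_along(base)) {
      if (!isTRUE(base[[k]]$accepted)) expect_false(isTRUE(stricter[[k]]$accepted))
    }
  }
  # top max_results by score are retained
  many <- lapply(seq(50, 99, by = 1), function(s) mk(s, 99, 5, "cloud-like"))
  kept <- accept_matches(many, max_results = 10)
  expect_length(kept, 10L)
  expect_equal(min(vapply(kept, `[[`, 0, "score")), 90)
})

test_that("exclusion rules drop heteroatoms and ambiguous terpene isomers", {
  recs <- data.frame(
    feature = c("F1", "F2", "F2", "F2", "F3", "F3"),
    name = c("chloro thing", paste0("terpene", 1:3), "terpA", "terpB"),
    formula = c("C10H11ClO2", rep("C15H24O3", 3), rep("C15H26O2", 2)),
    class_tag = c("other", rep("terpene", 3), rep("terpene", 2)),
    status = rep("identified", 6), stringsAsFactors = FALSE)
  out <- apply_exclusion_rules(recs)
  expect_identical(out$status[1], "rejected")
  expect_match(out$reason[1], "elements")
  expect_true(all(out$status[2:4] == "rejected"))       # 3 isomers: all out
  expect_true(all(out$reason[2:4] == "terpene isomer ambiguity"))
  expect_true(all(out$status[5:6] == "identified"))     # 2 isomers: retained
})

test_that("ClogP ordering assigns isomers to retention times monotonically", {
  cand <- data.frame(name = c("A", "B"), clogp = c(-1.9, -0.6),
                     stringsAsFactors = FALSE)
  feats <- data.frame(id = c("f2", "f1"), rt = c(13.2, 8.9),
                      stringsAsFactors = FALSE)
  asg <- assign_isomers_by_clogp(cand, feats)
  expect_identical(asg$feature[asg$name == "A"], "f1")  # lowest ClogP, earliest RT
  expect_identical(asg$feature[asg$name == "B"], "f2")
  one <- assign_isomers_by_clogp(data.frame(name = "A", clogp = 2),
                                 data.frame(id = "f", rt = 5))
  expect_identical(one$status, "assigned")
  tie <- assign_isomers_by_clogp(data.frame(name = c("A", "B"), clogp = c(1, 1)),
                                 feats)
  expect_true(all(tie$status == "unresolved"))
  expect_error(assign_isomers_by_clogp(cand, feats[1, ]), "equal length")
})

test_that("the true library entry ranks first under 10 percent intensity noise", {
  study <- generate_study(sim_config(seed = 17, n_null_features = 30,
                                     n_marker_features = 0,
                                     samples_per_group = 2,
                                     adduct_satellite_rate = 0,
                                     isf_satellite_rate = 0))
  lib <- study$library
  set.seed(17)
  wins <- 0L
  n_trials <- 200L
  for (trial in seq_len(n_trials)) {
    truth_i <- sample(length(lib), 1L)
    e <- lib[[truth_i]]
    pk <- e$peaks
    pk[, "intensity"] <- pk[, "intensity"] * exp(rnorm(nrow(pk), 0, 0.1))
    q <- herbmarker:::new_spectrum("q", e$precursor_mz, 10, e$collision_energy, pk)
    scores <- vapply(lib, function(l) library_match(q, l)$score, numeric(1L))
    if (which.max(scores) == truth_i) wins <- wins + 1L
  }
  expect_gte(wins / n_trials, 0.95)
})
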