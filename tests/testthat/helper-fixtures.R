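# Small in-code fixtures shared across test files.

# Minimal feature table: n features, 2 samples in 2 groups.
toy_table <- function(n = 3, mz = seq(200, by = 50, length.out = n),
                      rt = seq(5, by = 1, length.out = n),
                      formula = rep(NA_character_, n),
                      adduct = rep(NA_character_, n),
                      areas = matrix(1e6, n, 2, dimnames = list(NULL, c("A1", "B1"))),
                      ratings = matrix(8, n, 2, dimnames = list(NULL, c("A1", "B1")))) {
  feats <- data.frame(id = sprintf("F%d", seq_len(n)), mz = mz, rt = rt,
                      adduct = adduct, formula = formula,
                      stringsAsFactors = FALSE)
  manifest <- data.frame(sample = c("A1", "B1"), group = c("A", "B"),
                         stringsAsFactors = FALSE)
  feature_table(feats, areas, ratings, manifest)
}

# A spectrum literal.
spec_of <- function(id, prec, rt, peaks_mz, peaks_int = rep(100, length(peaks_mz)),
                    ce = NA_real_) {
  herbmarker:::new_spectrum(id, prec, rt, ce, cbind(peaks_mz, peaks_int))
}

# Library entry literal for matching tests.
entry_of <- function(name, peaks_mz, peaks_int, source = "vault-like", ce = NA_real_) {
  pk <- cbind(mz = peaks_mz, intensity = peaks_int)
  list(name = name, formula = NA_character_, adduct = NA_character_,
       precursor_mz = NA_real_, collision_energy = ce,
       class_tag = NA_character_, source = source,
       peaks = pk[order(pk[, 1L]), , drop = FALSE])
}
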