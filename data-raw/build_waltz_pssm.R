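# Builds inst/extdata/pssm_waltz_ph7_synthetic.tsv, the synthetic stand-in
# hexapeptide profile used by the PSSM predictor (the original pH-7 matrix is
# not redistributable here; see the vignette). Deterministic: a pseudocount-
# smoothed log-odds profile over experimentally established amyloid-forming
# hexapeptides, affine-scaled per position so the achievable window-score
# range is exactly [0, 100], making the 79.0 / 92.0 cut-offs meaningful.
#
# Run from the repository root: Rscript data-raw/build_waltz_pssm.R

aa <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")

# Amyloid-forming hexapeptides with fibril evidence in the literature
# (de novo STVIIE; Sup35 GNNQQNY-derived; Abeta KLVFFA/MVGGVV/GGVVIA/AIIGLM;
# tau VQIVYK; IAPP NFGAIL/FGAILS/SSTNVG; insulin VEALYL/LYQLEN; PrP SNQNNF).
train <- c("STVIIE", "NNQQNY", "GNNQQN", "KLVFFA", "VQIVYK",
           "NFGAIL", "FGAILS", "SSTNVG", "GGVVIA", "MVGGVV",
           "AIIGLM", "VEALYL", "LYQLEN", "SNQNNF")
stopifnot(all(nchar(train) == 6L))

pseudo <- 0.5
bg <- 1 / 20
counts <- matrix(0, nrow = 6, ncol = 20, dimnames = list(1:6, aa))
for (p in train) {
  ch <- strsplit(p, "")[[1]]
  for (i in 1:6) counts[i, ch[i]] <- counts[i, ch[i]] + 1
}
freq <- (counts + pseudo) / (length(train) + 20 * pseudo)
logodds <- log2(freq / bg)

# Affine rescale: subtract each position's minimum, scale the total so the
# best achievable window scores 100 and the worst 0.
shifted <- sweep(logodds, 1, apply(logodds, 1, min))
total <- sum(apply(shifted, 1, max))
scaled <- round(shifted * 100 / total, 3)

score <- function(p) {
  ch <- strsplit(p, "")[[1]]
  sum(scaled[cbind(1:6, match(ch, aa))])
}
cat("training-peptide scores:\n")
print(sort(vapply(train, score, numeric(1))))
cat("polar background examples:",
    score("DEKRST"), score("SSGNTE"), score("QNHDKE"), "\n")

out <- file.path("inst", "extdata", "pssm_waltz_ph7_synthetic.tsv")
con <- file(out, "w")
writeLines(c(
  "# SYNTHETIC STAND-IN hexapeptide PSSM (pH-7 style profile). Built by",
  "# data-raw/build_waltz_pssm.R as a pseudocount-smoothed log-odds profile",
  "# over 14 experimentally established amyloid-forming hexapeptides,",
  "# affine-scaled so the achievable window-score range is [0, 100].",
  "# It is NOT the matrix of Maurer-Stroh et al. (2010) Nat Methods 7:237,",
  "# which is not redistributable here; see the package vignette.",
  paste(c("position", aa), collapse = "\t")), con)
for (i in 1:6) {
  writeLines(paste(c(i, format(scaled[i, ], trim = TRUE)), collapse = "\t"), con)
}
close(con)
cat("wrote", out, "\n")
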