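test_that("hexapeptide pattern predictor matches its definition", {
  r <- run_amyloidogenic_pattern(protein_sequence("p", "STVIIE"))
  expect_true(all(r$hits))
  expect_identical(r$status, "ok")

  expect_false(any(run_amyloidogenic_pattern(protein_sequence("p", "PPPPPP"))$hits))

  # no full window: zero hits but still status ok on direct call
  short <- run_amyloidogenic_pattern(protein_sequence("p", "STVIE"))
  expect_identical(short$status, "ok")
  expect_false(any(short$hits))

  # overlapping matches union; pattern hits equal the regex oracle
  set.seed(101)
  for (i in 1:40) {
    s <- random_protein(sample(6:80, 1))
    expect_identical(run_amyloidogenic_pattern(s)$hits, oracle_pattern_hits(s))
  }
})

test_that("packing-density homopolymers behave per their scale value", {
  scale <- load_scale("packing_density_synthetic")
  lo <- names(scale)[scale <= 21.4][1]
  hi <- names(scale)[scale > 21.4][1]
  expect_false(any(run_average_packing_density(
    protein_sequence("p", strrep(lo, 12)))$hits))
  expect_true(all(run_average_packing_density(
    protein_sequence("p", strrep(hi, 12)))$hits))
  expect_identical(run_average_packing_density(
    protein_sequence("p", "ACDE"))$status, "skipped_too_short")
})

test_that("beta-strand contiguity accumulates qualifying window means", {
  # homopolymer below the propensity minimum: y identically zero
  r <- run_beta_contiguity(protein_sequence("p", strrep("E", 30)))
  expect_identical(unname(r$scores), rep(0, 30))
  expect_false(any(r$hits))

  # widening the window range can only add non-negative contributions
  cfg <- method_registry()$bsc
  cfg_narrow <- cfg
  cfg_narrow$params$window_max <- 8
  set.seed(102)
  s <- random_protein(60)
  expect_true(all(run_beta_contiguity(s, cfg)$scores >=
                  run_beta_contiguity(s, cfg_narrow)$scores))

  # y equals the brute-force enumeration over all placements and lengths
  expect_equal(unname(run_beta_contiguity(s)$scores), oracle_bsc_y(s))
})

test_that("aggrescan windows are local and length-dependent", {
  expect_false(any(run_aggrescan(protein_sequence("p", strrep("D", 20)))$hits))

  # appending far-away residues cannot change existing hits (locality)
  set.seed(103)
  s <- random_protein(50)
  ext <- protein_sequence(s$id, paste0(s$residues, strrep("D", 20)))
  expect_identical(run_aggrescan(s)$hits, run_aggrescan(ext)$hits[1:50])

  # window length switches with protein length per the packaged rule
  long <- random_protein(200)
  expect_identical(run_aggrescan(long)$hits, oracle_aggrescan(long))
})

test_that("PSSM window score is the sum of its matrix entries", {
  m <- load_pssm()
  r <- run_waltz_pssm(protein_sequence("p", "AAAAAA"))
  expect_equal(unique(r$scores), sum(m[, "A"]))

  # raising the cut-off to the strict setting only removes hits
  cfg <- method_registry()$waltz
  strict <- cfg
  strict$params$threshold <- cfg$params$threshold_strict
  set.seed(104)
  for (i in 1:20) {
    s <- random_protein(30)
    h79 <- run_waltz_pssm(s, cfg)$hits
    h92 <- run_waltz_pssm(s, strict)$hits
    expect_true(all(h79[h92]))
  }
  expect_identical(run_waltz_pssm(protein_sequence("p", "AAAAA"))$status,
                   "skipped_too_short")
})

test_that("every native predictor equals its brute-force oracle", {
  set.seed(105)
  for (i in 1:40) {
    s <- random_protein(sample(6:100, 1))
    expect_identical(run_average_packing_density(s)$hits, oracle_apd(s))
    expect_identical(run_aggrescan(s)$hits, oracle_aggrescan(s))
    expect_identical(run_waltz_pssm(s)$hits, oracle_waltz(s))
    expect_equal(unname(run_beta_contiguity(s)$scores), oracle_bsc_y(s))
    expect_identical(run_amyloidogenic_pattern(s)$hits, oracle_pattern_hits(s))
  }
})

test_that("non-standard residues can never be hits", {
  set.seed(106)
  for (i in 1:10) {
    s <- random_protein(40)
    chars <- strsplit(s$residues, "")[[1]]
    pos <- sample(40, 3)
    chars[pos] <- sample(c("X", "B", "Z", "U"), 3, replace = TRUE)
    sx <- protein_sequence(s$id, paste(chars, collapse = ""))
    for (r in run_all(sx)) expect_false(any(r$hits[pos]))
  }
})

test_that("adapter thresholding follows the published boundary wording", {
  seqs3 <- protein_sequence("t", "AAA")
  reg <- method_registry()

  tango <- apply_method_threshold(reg$tango,
                                  data.frame(beta_agg = c(0, 4.99, 5.01)), seqs3)
  expect_identical(tango$hits, c(FALSE, FALSE, TRUE))

  hce <- apply_method_threshold(reg$hce,
    data.frame(energy = c(-26.99, -27.00, -27.01, 0, 0, 0)),
    protein_sequence("t", "AAAAAA"))
  expect_identical(hce$hits, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))

  pafig <- apply_method_threshold(reg$pafig,
    data.frame(ri = c(6, 7, 8, NA, 9, 1)), protein_sequence("t", "AAAAAA"))
  expect_identical(pafig$hits, c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))

  net <- apply_method_threshold(reg$netcssp,
    data.frame(pbeta = c(7, 7, 6.0, 8, 1, 1, 1),
               phelix = c(7, 6.9, 0.5, 2, 1, 1, 1)),
    protein_sequence("t", "AAAAAAA"))
  # row 1: hbp exactly 1 -> no; row 2: hbp > 1 and pbeta > 6 -> yes;
  # row 3: pbeta not above 6 -> no; row 4: both strict -> yes
  expect_identical(net$hits[1:4], c(FALSE, TRUE, FALSE, TRUE))
})

test_that("adapters report missing externals and sentinel positions never hit", {
  reg <- method_registry()
  seq6 <- protein_sequence("t", "AAAAAA")
  expect_identical(apply_method_threshold(reg$tango, NULL, seq6)$status,
                   "external_missing")
  wrong <- apply_method_threshold(reg$tango, data.frame(other = rep(9, 6)), seq6)
  expect_identical(wrong$status, "external_missing")
  withNA <- apply_method_threshold(reg$tango,
    data.frame(beta_agg = c(99, NA, 99, NA, 99, NA)), seq6)
  expect_identical(withNA$hits, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("run_all respects minimum lengths and canonical order", {
  set.seed(107)
  s <- random_protein(50)
  res <- run_all(s)
  expect_length(res, 5)
  expect_true(all(vapply(res, function(r) r$status, character(1)) == "ok"))

  s5 <- protein_sequence("p", "ACDEG")
  res <- run_all(s5, method_order())
  status <- vapply(res, function(r) r$status, character(1))
  names(status) <- vapply(res, function(r) r$method, character(1))
  expect_identical(unname(status[c("pattern", "waltz", "pafig", "netcssp", "amylmut")]),
                   rep("skipped_too_short", 5))
  expect_identical(unname(status[c("apd", "aggrescan", "bsc")]), rep("ok", 3))
  # adapters long enough to run but with no score file are external_missing
  expect_identical(unname(status[c("tango", "hce", "secstr")]),
                   rep("external_missing", 3))

  # order of the result list is canonical, not selection order
  r1 <- run_all(s, c("waltz", "pattern", "apd"))
  r2 <- run_all(s, c("apd", "waltz", "pattern"))
  expect_identical(vapply(r1, function(r) r$method, character(1)),
                   vapply(r2, function(r) r$method, character(1)))
  expect_error(run_all(s, character()), "empty")
  expect_error(run_all(s, "nosuch"), "unknown")
})

test_that("identical input gives identical results and hits imply real scores", {
  set.seed(108)
  s <- random_protein(60)
  a <- run_all(s)
  b <- run_all(s)
  expect_identical(a, b)
  for (r in a) expect_false(any(r$hits & is.na(r$scores)))
})
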