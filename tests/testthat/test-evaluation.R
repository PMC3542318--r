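test_that("confusion counts match the per-residue definition", {
  truth <- region_annotation("p", 2, 4)
  cc <- confusion_counts(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE), truth)
  expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]),
                   c(tp = 3, tn = 3, fp = 0, fn = 0))
  cc <- confusion_counts(rep(FALSE, 6), truth)
  expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]),
                   c(tp = 0, tn = 3, fp = 0, fn = 3))
  expect_error(confusion_counts(rep(TRUE, 3), truth), "exceed")

  # random vectors against an explicit per-residue loop
  set.seed(301)
  for (i in 1:10) {
    pred <- runif(50) < 0.4
    st <- sort(sample(50, 2))
    truth <- region_annotation("p", st[1], st[2])
    pos <- seq(st[1], st[2])
    tp <- tn <- fp <- fn <- 0
    for (j in 1:50) {
      inside <- j %in% pos
      if (inside && pred[j]) tp <- tp + 1
      if (inside && !pred[j]) fn <- fn + 1
      if (!inside && pred[j]) fp <- fp + 1
      if (!inside && !pred[j]) tn <- tn + 1
    }
    cc <- confusion_counts(pred, truth)
    expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]),
                     c(tp = tp, tn = tn, fp = fp, fn = fn))
  }
})

test_that("metrics implement the published formulas and conventions", {
  m <- metrics(confusion_counts_record(25, 25, 25, 25))
  expect_equal(m$sensitivity, 50)
  expect_equal(m$specificity, 50)
  expect_equal(m$q, 50)
  expect_equal(m$mcc, 0)
  expect_false(m$degenerate)

  # Q is the mean of sensitivity and specificity by construction
  set.seed(302)
  for (i in 1:10) {
    cc <- confusion_counts_record(sample(0:99, 1) + 1, sample(0:99, 1) + 1,
                                  sample(0:99, 1), sample(0:99, 1))
    m <- metrics(cc)
    expect_equal(m$q, (m$sensitivity + m$specificity) / 2)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }

  # zero denominators report 0 with the degenerate flag
  m <- metrics(confusion_counts_record(0, 10, 0, 0))
  expect_true(m$degenerate)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$mcc, 0)
})

test_that("class swap negates MCC and exchanges sensitivity with specificity", {
  set.seed(303)
  for (i in 1:10) {
    pred <- runif(60) < 0.5
    st <- sort(sample(60, 2))
    truth <- region_annotation("p", st[1], st[2])
    m <- metrics(confusion_counts(pred, truth))
    # swap both predictions and truth: relabels the classes symmetrically
    flipped <- region_annotation("p", aprvote:::regions_from_hits(
      !aprvote:::hits_from_regions(truth$intervals, 60))$start,
      aprvote:::regions_from_hits(
        !aprvote:::hits_from_regions(truth$intervals, 60))$end)
    m2 <- metrics(confusion_counts(!pred, flipped))
    expect_equal(m2$sensitivity, m$specificity)
    expect_equal(m2$specificity, m$sensitivity)
    expect_equal(m2$mcc, m$mcc)
    # swapping predictions only negates MCC
    m3 <- metrics(confusion_counts(!pred, truth))
    expect_equal(m3$mcc, -m$mcc)
  }
})

test_that("aggregation pools counts element-wise and macro-MCC is the mean", {
  a <- confusion_counts_record(1, 2, 3, 4)
  b <- confusion_counts_record(10, 20, 30, 40)
  agg <- aggregate_counts(list(a, b))
  expect_identical(unlist(agg[c("tp", "tn", "fp", "fn")]),
                   c(tp = 11, tn = 22, fp = 33, fn = 44))
  expect_identical(aggregate_counts(list(a)), a)
  expect_identical(aggregate_counts(list(b, a)), agg)

  expect_equal(macro_mcc(c(0.5, 0.1)), 0.3)
  expect_equal(macro_mcc(rep(0.42, 7)), 0.42)
  set.seed(304)
  v <- runif(33, -1, 1)
  expect_equal(macro_mcc(v), sum(v) / 33)
})

test_that("exposure classes follow the accessibility cut-offs", {
  tr <- accessibility_track("p", c(30, 30, 30, 15, 15, 15, 5, 5, 5, 25, 8, 12))
  expect_identical(classify_exposure(c(1, 3), tr), "surface")
  expect_identical(classify_exposure(c(4, 6), tr), "semi-surface")
  expect_identical(classify_exposure(c(7, 9), tr), "buried")
  # boundaries: >= 20 surface, [10, 20) semi-surface
  expect_identical(classify_exposure(c(1, 1), accessibility_track("p", 20)), "surface")
  expect_identical(classify_exposure(c(1, 1), accessibility_track("p", 10)), "semi-surface")
  expect_identical(classify_exposure(c(1, 1), accessibility_track("p", 9.99)), "buried")
  # mean vs strict all-residue mode
  expect_identical(classify_exposure(c(10, 12), tr), "semi-surface") # mean 15
  expect_identical(classify_exposure(c(10, 12), tr, mode = "all"), "buried")
  expect_error(classify_exposure(c(10, 13), tr), "outside")
})

test_that("benchmark pools per-protein counts and is order-invariant", {
  fx <- generate_fixture(fixture_spec(seed = 11, n_sequences = 4, length = 90))
  results <- lapply(fx$sequences, run_all)
  names(results) <- vapply(fx$sequences, function(s) s$id, character(1))

  bench <- benchmark(fx$sequences, fx$annotations, results)
  expect_true(all(c(native_methods(), "consensus") %in% bench$pooled$method))
  expect_equal(bench$pooled$q,
               (bench$pooled$sensitivity + bench$pooled$specificity) / 2)
  # pooled counts equal the sum over proteins (conservation): recompute one
  # method's row with an independent end-to-end loop
  tp <- tn <- fp <- fn <- 0
  for (s in fx$sequences) {
    hits <- run_amyloidogenic_pattern(s)$hits
    pos <- aprvote:::hits_from_regions(fx$annotations[[s$id]]$intervals, s$length)
    tp <- tp + sum(hits & pos); tn <- tn + sum(!hits & !pos)
    fp <- fp + sum(hits & !pos); fn <- fn + sum(!hits & pos)
  }
  row <- bench$pooled[bench$pooled$method == "pattern", ]
  expect_identical(c(row$TP, row$TN, row$FP, row$FN), c(tp, tn, fp, fn))

  # shuffling protein order leaves the pooled table unchanged
  ord <- c(3, 1, 4, 2)
  bench2 <- benchmark(fx$sequences[ord], fx$annotations, results)
  expect_equal(bench2$pooled, bench$pooled)
  # macro-MCC is the equal-weight mean of the per-protein column
  expect_equal(unname(bench$macro_mcc["consensus"]),
               mean(bench$per_protein_mcc$consensus))

  expect_error(benchmark(fx$sequences, fx$annotations[-1], results),
               "missing annotation")
  expect_error(benchmark(fx$sequences, fx$annotations, results[-1]),
               "missing method outputs")
})

test_that("a perfect prediction set scores 100/100/100 and MCC 1", {
  fx <- generate_fixture(fixture_spec(seed = 12, n_sequences = 3, length = 80,
                                      motifs = "STVIIE"))
  results <- lapply(fx$sequences, run_all)
  names(results) <- vapply(fx$sequences, function(s) s$id, character(1))
  # truth taken as the consensus itself: every row of the consensus is exact
  truth <- lapply(fx$sequences, function(s) {
    cons <- vote(results[[s$id]])
    stopifnot(nrow(cons$regions) > 0)
    region_annotation(s$id, cons$regions$start, cons$regions$end)
  })
  names(truth) <- names(results)
  bench <- benchmark(fx$sequences, truth, results)
  row <- bench$pooled[bench$pooled$method == "consensus", ]
  expect_equal(row$sensitivity, 100)
  expect_equal(row$specificity, 100)
  expect_equal(row$q, 100)
  expect_equal(row$mcc, 1)
})
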