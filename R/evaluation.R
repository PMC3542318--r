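# Benchmark protocol: per-residue confusion counts against annotated regions,
# sensitivity/specificity/Q/MCC, pooled and per-protein aggregation with a
# macro-averaged MCC, and surface-exposure classification of predicted
# peptides.

#' Per-residue confusion counts
#'
#' Residues inside a truth interval are the positive class: predicted
#' positives there are TP, missed ones FN; outside, predicted positives are
#' FP and the rest TN.
#'
#' @param predicted Logical per-residue prediction vector.
#' @param truth A [region_annotation()] (intervals within range).
#' @return A [confusion_counts_record()].
#' @export
confusion_counts <- function(predicted, truth) {
  n <- length(predicted)
  if (nrow(truth$intervals) && max(truth$intervals$end) > n) {
    stop("truth intervals exceed prediction length ", n, call. = FALSE)
  }
  pos <- hits_from_regions(truth$intervals, n)
  predicted <- as.logical(predicted)
  confusion_counts_record(tp = sum(predicted & pos),
                          tn = sum(!predicted & !pos),
                          fp = sum(predicted & !pos),
                          fn = sum(!predicted & pos))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) (both percentages),
#' Q = (sensitivity + specificity)/2, and the Matthews correlation
#' coefficient (TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP)). Any
#' zero denominator yields 0 for that metric and sets the `degenerate` flag.
#' Values are kept at full precision; [format()] rounds to two decimals for
#' reports.
#'
#' @param counts A [confusion_counts_record()].
#' @return An object of class `metric_set` with fields `sensitivity`,
#'   `specificity`, `q`, `mcc`, `degenerate`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- 100 * ratio(tp, tp + fn)
  spec <- 100 * ratio(tn, tn + fp)
  q <- (sens + spec) / 2
  denom <- (tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
  mcc <- if (denom == 0) { degenerate <- TRUE; 0 } else {
    (tp * tn - fp * fn) / sqrt(denom)
  }
  structure(list(sensitivity = sens, specificity = spec, q = q, mcc = mcc,
                 degenerate = degenerate),
            class = "metric_set")
}

#' @export
format.metric_set <- function(x, ...) {
  sprintf("Sens %.2f%% Spec %.2f%% Q %.2f%% MCC %.2f%s",
          x$sensitivity, x$specificity, x$q, x$mcc,
          if (x$degenerate) " (degenerate)" else "")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>", format(x), "\n")
  invisible(x)
}

#' Pool confusion counts over proteins
#'
#' @param per_protein Non-empty list of [confusion_counts_record()]s.
#' @return A single [confusion_counts_record()] of element-wise sums.
#' @export
aggregate_counts <- function(per_protein) {
  if (!length(per_protein)) stop("empty count list", call. = FALSE)
  confusion_counts_record(
    tp = sum(vapply(per_protein, `[[`, numeric(1), "tp")),
    tn = sum(vapply(per_protein, `[[`, numeric(1), "tn")),
    fp = sum(vapply(per_protein, `[[`, numeric(1), "fp")),
    fn = sum(vapply(per_protein, `[[`, numeric(1), "fn")))
}

#' Macro-averaged MCC
#'
#' Arithmetic mean of per-protein MCC values, giving every protein the same
#' weight regardless of its length.
#'
#' @param per_protein_mcc Non-empty numeric vector.
#' @return The mean MCC.
#' @export
macro_mcc <- function(per_protein_mcc) {
  if (!length(per_protein_mcc)) stop("empty MCC list", call. = FALSE)
  mean(per_protein_mcc)
}

#' Surface-exposure class of a predicted peptide
#'
#' Aggregates per-residue solvent accessibility (DSSP ACC, square Angstroms)
#' over the peptide: mean >= 20 is `"surface"`, mean in [10, 20)
#' `"semi-surface"`, below 10 `"buried"`. The `"all"` mode instead requires
#' every residue of the peptide to clear the cut-off.
#'
#' @param interval Length-2 integer vector `(start, end)`, 1-based inclusive.
#' @param track An [accessibility_track()].
#' @param mode `"mean"` (default) or `"all"`.
#' @return One of `"surface"`, `"semi-surface"`, `"buried"`.
#' @export
classify_exposure <- function(interval, track, mode = c("mean", "all")) {
  mode <- match.arg(mode)
  start <- interval[[1]]; end <- interval[[2]]
  if (start < 1L || end > length(track$acc) || start > end) {
    stop("interval (", start, ", ", end, ") outside accessibility track",
         call. = FALSE)
  }
  v <- track$acc[start:end]
  stat <- if (mode == "mean") mean(v) else min(v)
  if (stat >= 20) "surface" else if (stat >= 10) "semi-surface" else "buried"
}

#' Benchmark a method set against annotated regions
#'
#' Reproduces the per-residue benchmark protocol: for every sequence,
#' confusion counts per method and for the consensus are accumulated; the
#' pooled table carries one row per method plus the consensus with
#' TP/TN/FP/FN and sensitivity/specificity/Q/MCC, and a per-protein MCC table
#' with its macro (equal-weight) average is returned alongside.
#'
#' @param sequences List of [protein_sequence()]s.
#' @param annotations Named list of [region_annotation()]s covering every
#'   sequence.
#' @param results_by_seq Named list (by sequence id) of lists of
#'   [method_result()]s, e.g. from [run_all()]; every selected method must
#'   have a result for every sequence.
#' @param threshold_override Optional consensus vote threshold.
#' @return A list with `pooled` (data frame), `per_protein_mcc` (data frame
#'   protein x method) and `macro_mcc` (named numeric).
#' @export
benchmark <- function(sequences, annotations, results_by_seq,
                      threshold_override = NULL) {
  ids <- vapply(sequences, function(s) s$id, character(1))
  missing_ann <- setdiff(ids, names(annotations))
  if (length(missing_ann)) {
    stop("missing annotation for sequence(s): ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  }
  missing_res <- setdiff(ids, names(results_by_seq))
  if (length(missing_res)) {
    stop("missing method outputs for sequence(s): ",
         paste(missing_res, collapse = ", "), call. = FALSE)
  }
  methods <- unique(unlist(lapply(results_by_seq[ids], function(rs) {
    vapply(rs, function(r) r$method, character(1))
  })))
  methods <- intersect(method_order(), methods)
  cols <- c(methods, "consensus")
  counts <- lapply(cols, function(m) list())
  names(counts) <- cols
  per_protein <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
                        dimnames = list(ids, cols))
  for (id in ids) {
    seq <- sequences[[match(id, ids)]]
    truth <- annotations[[id]]
    rs <- results_by_seq[[id]]
    tokens <- vapply(rs, function(r) r$method, character(1))
    for (m in methods) {
      r <- rs[[match(m, tokens)]]
      if (is.na(match(m, tokens))) {
        stop("no result for method '", m, "' on sequence '", id, "'",
             call. = FALSE)
      }
      cc <- confusion_counts(r$hits, truth)
      counts[[m]] <- c(counts[[m]], list(cc))
      per_protein[id, m] <- metrics(cc)$mcc
    }
    cons <- vote(rs, threshold_override)
    cc <- confusion_counts(cons$hits, truth)
    counts$consensus <- c(counts$consensus, list(cc))
    per_protein[id, "consensus"] <- metrics(cc)$mcc
  }
  pooled <- do.call(rbind, lapply(cols, function(m) {
    agg <- aggregate_counts(counts[[m]])
    ms <- metrics(agg)
    data.frame(method = m, TP = agg$tp, TN = agg$tn, FP = agg$fp, FN = agg$fn,
               sensitivity = ms$sensitivity, specificity = ms$specificity,
               q = ms$q, mcc = ms$mcc)
  }))
  list(pooled = pooled,
       per_protein_mcc = as.data.frame(per_protein),
       macro_mcc = colMeans(per_protein))
}

#' Write a benchmark report as TSV
#'
#' @param bench Result of [benchmark()].
#' @param pooled_path Path for the pooled one-row-per-method table.
#' @param per_protein_path Optional path for the per-protein MCC table (a
#'   final `macro` row carries the equal-weight averages).
#' @return `pooled_path`, invisibly.
#' @export
write_benchmark <- function(bench, pooled_path, per_protein_path = NULL) {
  pooled <- bench$pooled
  pooled$sensitivity <- round(pooled$sensitivity, 2)
  pooled$specificity <- round(pooled$specificity, 2)
  pooled$q <- round(pooled$q, 2)
  pooled$mcc <- round(pooled$mcc, 2)
  utils::write.table(pooled, pooled_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(per_protein_path)) {
    pp <- rbind(bench$per_protein_mcc,
                macro = as.list(bench$macro_mcc))
    pp <- round(pp, 4)
    pp <- cbind(protein = rownames(pp), pp)
    utils::write.table(pp, per_protein_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(pooled_path)
}
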