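# Consensus vote: per-residue hit counts over the participating methods, a
# floor(n/2) majority threshold, and merged consensus regions.

#' Consensus vote threshold
#'
#' The number of agreeing methods required for a consensus hit: at least
#' n/2 (rounded down) of the n participating methods, i.e. 5 of 11. For
#' n = 1 the floor would be 0 and every residue a hit, so the threshold is
#' clamped to 1.
#'
#' @param n Number of participating methods (>= 1).
#' @return Integer vote threshold.
#' @examples
#' consensus_threshold(11)  # 5
#' @export
consensus_threshold <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("method count must be >= 1", call. = FALSE)
  max(1L, n %/% 2L)
}

#' Combine per-method results into a consensus prediction
#'
#' Only methods with status `"ok"` participate; skipped and missing methods
#' are excluded from the method count n (a method that cannot run is not a
#' "no" vote). `votes[i]` is the number of participating methods flagging
#' residue i (the consensus histogram); residues with at least
#' [consensus_threshold()] votes — or `threshold_override` votes when given —
#' are consensus hits, and maximal runs of hits form the consensus regions.
#'
#' @param results List of [method_result()] objects for one sequence.
#' @param threshold_override Optional integer vote threshold replacing the
#'   floor(n/2) rule.
#' @return An object of class `consensus_result` with fields `sequence_id`,
#'   `n_methods`, `threshold`, `votes`, `hits`, `regions`, `methods`
#'   (participating tokens) and `excluded` (tokens with their non-ok status).
#' @export
vote <- function(results, threshold_override = NULL) {
  if (!length(results)) stop("no method results supplied", call. = FALSE)
  ids <- unique(vapply(results, function(r) r$sequence_id, character(1)))
  if (length(ids) != 1L) {
    stop("mixed sequence ids in vote(): ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  ok <- vapply(results, function(r) r$status == "ok", logical(1))
  if (!any(ok)) stop("zero participating methods (none returned status ok)",
                     call. = FALSE)
  part <- results[ok]
  n <- length(part)
  votes <- Reduce(`+`, lapply(part, function(r) as.integer(r$hits)))
  threshold <- if (is.null(threshold_override)) consensus_threshold(n)
               else as.integer(threshold_override)
  hits <- votes >= threshold
  excluded <- vapply(results[!ok], function(r) r$status, character(1))
  names(excluded) <- vapply(results[!ok], function(r) r$method, character(1))
  structure(list(sequence_id = ids,
                 n_methods = n,
                 threshold = threshold,
                 votes = votes,
                 hits = hits,
                 regions = regions_from_hits(hits),
                 methods = vapply(part, function(r) r$method, character(1)),
                 excluded = excluded),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", x$sequence_id, ": ", x$n_methods,
      " methods, threshold ", x$threshold, "\n", sep = "")
  if (nrow(x$regions)) {
    cat("  regions: ", paste0("[", x$regions$start, "-", x$regions$end, "]",
                              collapse = " "), "\n", sep = "")
  } else {
    cat("  no consensus regions\n")
  }
  invisible(x)
}

parse_mutations <- function(mutations) {
  if (is.list(mutations)) {
    return(lapply(mutations, function(m) {
      list(wt = NA_character_, pos = as.integer(m[[1]]),
           new = toupper(m[[2]]))
    }))
  }
  lapply(mutations, function(m) {
    mm <- regmatches(m, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", m))[[1]]
    if (length(mm) != 4L) {
      stop("malformed mutation '", m, "' (expected e.g. T28G)", call. = FALSE)
    }
    list(wt = toupper(mm[2]), pos = as.integer(mm[3]), new = toupper(mm[4]))
  })
}

apply_mutations <- function(seq, muts) {
  chars <- seq_chars(seq)
  for (m in muts) {
    if (m$pos < 1L || m$pos > seq$length) {
      stop("mutation position ", m$pos, " outside sequence '", seq$id,
           "' (length ", seq$length, ")", call. = FALSE)
    }
    if (!is.na(m$wt) && chars[m$pos] != m$wt) {
      stop("wild-type mismatch at position ", m$pos, ": sequence has '",
           chars[m$pos], "', mutation states '", m$wt, "'", call. = FALSE)
    }
    chars[m$pos] <- m$new
  }
  protein_sequence(seq$id, paste(chars, collapse = ""))
}

# Residue-level set difference a \ b of two region tables over n residues.
region_diff <- function(a, b, n) {
  regions_from_hits(hits_from_regions(a, n) & !hits_from_regions(b, n))
}

#' Substitution scan: consensus before and after point mutations
#'
#' Applies amino-acid substitutions (notation `<wt><pos><new>`, e.g. `"T28G"`;
#' the stated wild-type letter must match the sequence), reruns the selected
#' methods on the mutant, and reports both consensus results plus the region
#' delta. Adapter methods participate only if external scores are supplied for
#' both the original and the mutant sequence; otherwise they are dropped from
#' both runs symmetrically so the two consensus calls use the same method set.
#'
#' @param seq A [protein_sequence()].
#' @param mutations Character vector like `c("T28G", "I201E")`.
#' @param selection Method tokens (default: native methods).
#' @param external_scores Optional list with elements `before` and `after`,
#'   each shaped as in [run_all()].
#' @param threshold_override Optional vote threshold for both runs.
#' @return A list with `before` and `after` (`consensus_result`s),
#'   `regions_lost` (hit residues before but not after, merged) and
#'   `regions_gained` (the converse).
#' @export
substitution_scan <- function(seq, mutations, selection = native_methods(),
                              external_scores = NULL,
                              threshold_override = NULL) {
  muts <- parse_mutations(mutations)
  mutant <- apply_mutations(seq, muts)
  reg <- method_registry()
  keep <- vapply(selection, function(m) {
    if (reg[[m]]$kind == "native") return(TRUE)
    !is.null(external_scores$before[[m]][[seq$id]]) &&
      !is.null(external_scores$after[[m]][[seq$id]])
  }, logical(1))
  selection <- selection[keep]
  if (!length(selection)) stop("no runnable methods after dropping adapters",
                               call. = FALSE)
  before <- vote(run_all(seq, selection, external_scores$before),
                 threshold_override)
  after <- vote(run_all(mutant, selection, external_scores$after),
                threshold_override)
  list(before = before, after = after,
       regions_lost = region_diff(before$regions, after$regions, seq$length),
       regions_gained = region_diff(after$regions, before$regions, seq$length))
}

#' Per-residue consensus table
#'
#' @param seq A [protein_sequence()].
#' @param consensus A `consensus_result` for the same sequence.
#' @return Data frame with columns `residue`, `aa`, `votes`, `hit`.
#' @export
consensus_table <- function(seq, consensus) {
  stopifnot(identical(seq$id, consensus$sequence_id),
            seq$length == length(consensus$votes))
  data.frame(residue = seq_len(seq$length),
             aa = seq_chars(seq),
             votes = consensus$votes,
             hit = consensus$hits)
}
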