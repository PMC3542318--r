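# Domain containers shared across the package. All external coordinates are
# 1-based inclusive; internal vectors are indexed 1..length like any R vector,
# so no offset conversion is ever needed.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter codes. Non-standard codes ('X', 'B', 'Z', 'U',
#' 'O') are accepted on input but flagged: predictors treat them as positions
#' with no propensity value, which can never be hits.
#' @format Character vectors.
#' @name alphabet
#' @keywords internal
NULL

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NONSTANDARD_AA <- c("X", "B", "Z", "U", "O")

#' Construct a protein sequence record
#'
#' @param id Free-text record identifier.
#' @param residues One-letter amino-acid string. Lowercase letters are
#'   uppercased and whitespace is stripped. The 20 standard codes plus
#'   `X`, `B`, `Z`, `U`, `O` are accepted; anything else is an error naming
#'   the offending position.
#' @return An object of class `protein_sequence` with fields `id`, `residues`,
#'   `length`, and `nonstandard` (1-based positions of non-standard codes).
#' @examples
#' protein_sequence("p1", "stviie")
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  ok <- chars %in% c(STANDARD_AA, NONSTANDARD_AA)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("record '", id, "': illegal residue character '", chars[bad],
         "' at position ", bad, call. = FALSE)
  }
  structure(
    list(id = id,
         residues = residues,
         length = nchar(residues),
         nonstandard = which(chars %in% NONSTANDARD_AA)),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", x$length, " aa)\n", sep = "")
  shown <- if (x$length > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat("  ", shown, "\n", sep = "")
  if (length(x$nonstandard)) {
    cat("  non-standard positions:", paste(x$nonstandard, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.character.protein_sequence <- function(x, ...) x$residues

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1]]

#' Construct a region annotation
#'
#' Experimentally verified amyloidogenic intervals for one sequence, 1-based
#' inclusive in mature-protein numbering. Overlapping or adjacent intervals
#' are merged and the result sorted, so normalisation is idempotent.
#'
#' @param sequence_id Identifier of the annotated sequence.
#' @param starts,ends Integer vectors of equal length (may be empty).
#' @param seq_length Optional sequence length used to validate `ends`.
#' @return An object of class `region_annotation` with a data frame
#'   `intervals` (`start`, `end`).
#' @export
region_annotation <- function(sequence_id, starts = integer(), ends = integer(),
                              seq_length = NULL) {
  stopifnot(length(starts) == length(ends))
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (any(is.na(starts)) || any(is.na(ends))) {
    stop("annotation for '", sequence_id, "': non-integer coordinates", call. = FALSE)
  }
  if (any(starts < 1L)) {
    stop("annotation for '", sequence_id, "': start < 1", call. = FALSE)
  }
  if (any(starts > ends)) {
    i <- which(starts > ends)[1L]
    stop("annotation for '", sequence_id, "': inverted interval (",
         starts[i], ", ", ends[i], ")", call. = FALSE)
  }
  if (!is.null(seq_length) && any(ends > seq_length)) {
    stop("annotation for '", sequence_id, "': interval end exceeds sequence length ",
         seq_length, call. = FALSE)
  }
  if (length(starts)) {
    r <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
    intervals <- data.frame(start = IRanges::start(r), end = IRanges::end(r))
  } else {
    intervals <- data.frame(start = integer(), end = integer())
  }
  structure(list(sequence_id = sequence_id, intervals = intervals),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("<region_annotation> ", x$sequence_id, ": ",
      nrow(x$intervals), " interval(s)\n", sep = "")
  if (nrow(x$intervals)) {
    cat(" ", paste0("[", x$intervals$start, "-", x$intervals$end, "]",
                    collapse = " "), "\n")
  }
  invisible(x)
}

#' Construct a solvent-accessibility track
#'
#' @param sequence_id Identifier of the target sequence.
#' @param acc Numeric vector of per-residue solvent-accessible surface areas
#'   in square Angstroms, one per residue.
#' @return An object of class `accessibility_track`.
#' @export
accessibility_track <- function(sequence_id, acc) {
  acc <- as.numeric(acc)
  if (any(is.na(acc)) || any(acc < 0)) {
    stop("accessibility track for '", sequence_id,
         "': values must be non-negative numbers", call. = FALSE)
  }
  structure(list(sequence_id = sequence_id, acc = acc),
            class = "accessibility_track")
}

#' Construct a per-method prediction result
#'
#' @param method Method identifier (one of the registry tokens).
#' @param sequence_id Identifier of the scored sequence.
#' @param scores Per-residue raw score vector; `NA` is the "no score" sentinel.
#' @param hits Per-residue logical hit vector.
#' @param config The `method_config` used.
#' @param status One of `"ok"`, `"skipped_too_short"`, `"external_missing"`.
#' @return An object of class `method_result`.
#' @export
method_result <- function(method, sequence_id, scores, hits, config,
                          status = c("ok", "skipped_too_short", "external_missing")) {
  status <- match.arg(status)
  stopifnot(length(scores) == length(hits))
  hits <- as.logical(hits)
  stopifnot(!anyNA(hits))
  if (any(hits & is.na(scores))) {
    stop("method_result invariant violated: hit residue without a real score",
         call. = FALSE)
  }
  if (status != "ok" && any(hits)) {
    stop("method_result invariant violated: hits under non-ok status", call. = FALSE)
  }
  structure(list(method = method, sequence_id = sequence_id,
                 scores = as.numeric(scores), hits = hits,
                 config = config, status = status),
            class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat("<method_result> ", x$method, " on ", x$sequence_id,
      " [", x$status, "]: ", sum(x$hits), "/", length(x$hits),
      " residues hit\n", sep = "")
  invisible(x)
}

#' Construct a confusion-count record
#'
#' Per-residue true/false positive/negative counts.
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts_record <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || anyNA(v)) stop("confusion counts must be non-negative", call. = FALSE)
  structure(as.list(as.numeric(v)), names = names(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$tp, " TN=", x$tn,
      " FP=", x$fp, " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

# Maximal runs of TRUE as 1-based inclusive intervals.
regions_from_hits <- function(hits) {
  if (!length(hits) || !any(hits)) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(as.logical(hits))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Inverse of regions_from_hits for a sequence of known length.
hits_from_regions <- function(regions, n) {
  hits <- rep(FALSE, n)
  for (i in seq_len(nrow(regions))) {
    hits[regions$start[i]:regions$end[i]] <- TRUE
  }
  hits
}
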