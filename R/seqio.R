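# Readers and writers for every external format: FASTA, the bespoke region and
# score TSVs, DSSP accessibility, and GFF3 export. FASTA parsing is delegated
# to Biostrings; residue validation stays here so errors can name the record
# and position.

#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_sequence()] objects, in record order. A file
#'   with zero records yields an empty list.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!length(set)) return(list())
  ids <- sub("[[:space:]].*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header in record ", which(!nzchar(ids))[1L],
         " of '", path, "'", call. = FALSE)
  }
  lapply(seq_along(set), function(i) {
    protein_sequence(ids[i], as.character(set[[i]]))
  })
}

#' Write protein sequences to FASTA
#'
#' @param seqs List of [protein_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  chars <- vapply(seqs, function(s) s$residues, character(1))
  names(chars) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(chars), filepath = path)
  invisible(path)
}

#' Read region annotations from a TSV
#'
#' The bespoke region format is tab-separated with three columns:
#' `sequence_id`, `start`, `end` (1-based inclusive, mature-protein
#' numbering); lines starting with `#` are ignored. Intervals are grouped by
#' sequence, sorted, and overlapping or adjacent intervals merged.
#'
#' @param path Path to the TSV file.
#' @param sequences Optional list of [protein_sequence()] objects used to
#'   validate that coordinates do not exceed sequence lengths.
#' @return A named list of [region_annotation()] objects.
#' @export
read_regions <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(structure(list(), names = character()))
  tab <- utils::read.delim(text = lines, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) {
    stop("region file '", path, "' must have 3 columns: sequence_id, start, end",
         call. = FALSE)
  }
  names(tab)[1:3] <- c("sequence_id", "start", "end")
  lens <- NULL
  if (!is.null(sequences)) {
    lens <- stats::setNames(vapply(sequences, function(s) s$length, integer(1)),
                            vapply(sequences, function(s) s$id, character(1)))
  }
  out <- lapply(split(tab, tab$sequence_id), function(g) {
    id <- g$sequence_id[1L]
    if (!is.null(lens)) {
      if (!id %in% names(lens)) {
        stop("region file references unknown sequence '", id, "'", call. = FALSE)
      }
      region_annotation(id, g$start, g$end, seq_length = lens[[id]])
    } else {
      region_annotation(id, g$start, g$end)
    }
  })
  out[unique(tab$sequence_id)]
}

#' Write region annotations to the bespoke TSV
#'
#' @param annotations Named list of [region_annotation()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(annotations, path) {
  rows <- do.call(rbind, c(list(data.frame(sequence_id = character(),
                                           start = integer(), end = integer())),
    lapply(annotations, function(a) {
      if (!nrow(a$intervals)) return(NULL)
      data.frame(sequence_id = a$sequence_id,
                 start = a$intervals$start, end = a$intervals$end)
    })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an external per-residue score table
#'
#' Tab-separated with a header line: `sequence_id`, `index` (1-based residue
#' position), then one or more named score columns. Positions absent from the
#' table carry the "no score" sentinel `NA`, which no threshold rule can
#' turn into a hit.
#'
#' @param path Path to the TSV file.
#' @param sequences Optional list of [protein_sequence()] objects; when given,
#'   indices are validated against sequence lengths and the returned vectors
#'   are dense over `1..length`.
#' @return A named list (one element per `sequence_id`) of data frames with
#'   one row per residue and one column per score.
#' @export
read_score_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("score table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("sequence_id", "index")
  if (!all(need %in% names(tab))) {
    stop("score table '", path, "' must carry columns sequence_id and index",
         call. = FALSE)
  }
  score_cols <- setdiff(names(tab), need)
  if (!length(score_cols)) {
    stop("score table '", path, "' has no score columns", call. = FALSE)
  }
  key <- paste(tab$sequence_id, tab$index)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("score table '", path, "': duplicate row for (", d, ")", call. = FALSE)
  }
  lens <- NULL
  if (!is.null(sequences)) {
    lens <- stats::setNames(vapply(sequences, function(s) s$length, integer(1)),
                            vapply(sequences, function(s) s$id, character(1)))
  }
  out <- lapply(split(tab, tab$sequence_id), function(g) {
    id <- g$sequence_id[1L]
    n <- if (!is.null(lens)) {
      if (!id %in% names(lens)) {
        stop("score table references unknown sequence '", id, "'", call. = FALSE)
      }
      lens[[id]]
    } else {
      max(g$index)
    }
    if (any(g$index < 1L) || any(g$index > n)) {
      stop("score table '", path, "': index out of range for '", id, "'",
           call. = FALSE)
    }
    dense <- as.data.frame(
      stats::setNames(rep(list(rep(NA_real_, n)), length(score_cols)), score_cols))
    for (col in score_cols) dense[[col]][g$index] <- as.numeric(g[[col]])
    dense
  })
  out[unique(tab$sequence_id)]
}

#' Read a per-residue solvent-accessibility track
#'
#' Two dialects are supported: a two-column TSV (`index`, ACC in square
#' Angstroms) and the classic fixed-column DSSP output, from which the ACC
#' field (columns 35-38) is taken. Multi-chain DSSP files require an explicit
#' `chain`; insertion codes are rejected.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"dssp"`.
#' @param sequence The target [protein_sequence()]; the track must cover every
#'   residue exactly once.
#' @param chain Single chain identifier for multi-chain DSSP files.
#' @return An [accessibility_track()].
#' @export
read_accessibility <- function(path, dialect = c("tsv", "dssp"),
                               sequence, chain = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("accessibility file not found: ", path, call. = FALSE)
  acc <- if (dialect == "tsv") {
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    tab <- tab[order(tab[[1]]), , drop = FALSE]
    if (!identical(as.integer(tab[[1]]), seq_len(nrow(tab)))) {
      stop("accessibility TSV '", path, "' indices must cover 1..n exactly once",
           call. = FALSE)
    }
    as.numeric(tab[[2]])
  } else {
    read_dssp_acc(path, chain = chain)
  }
  if (length(acc) != sequence$length) {
    stop("accessibility track has ", length(acc), " residues but sequence '",
         sequence$id, "' has ", sequence$length, call. = FALSE)
  }
  accessibility_track(sequence$id, acc)
}

# Classic DSSP layout: data lines follow the '  #  RESIDUE AA' header;
# insertion code at column 11, chain at column 12, one-letter AA at 14,
# ACC right-justified in columns 35-38. Chain breaks ('!') are skipped.
read_dssp_acc <- function(path, chain = NULL) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP file (missing residue header): ", path,
                         call. = FALSE)
  body <- lines[seq.int(hdr[1L] + 1L, length(lines))]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  chains <- substr(body, 12, 12)
  if (is.null(chain)) {
    if (length(unique(chains)) > 1L) {
      stop("multi-chain DSSP file; supply chain = one of: ",
           paste(unique(chains), collapse = ", "), call. = FALSE)
    }
  } else {
    body <- body[chains == chain]
    if (!length(body)) stop("chain '", chain, "' not present in DSSP file",
                            call. = FALSE)
  }
  icode <- substr(body, 11, 11)
  if (any(icode != " ")) {
    stop("DSSP insertion codes are not supported", call. = FALSE)
  }
  acc <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  if (anyNA(acc)) stop("unparseable ACC field in DSSP file: ", path, call. = FALSE)
  acc
}

#' Export regions as GFF3
#'
#' Writes 1-based inclusive protein-coordinate features, one line per region.
#'
#' @param regions Data frame with columns `sequence_id`, `start`, `end` and
#'   optionally `score` and `type`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @param type Default feature type when `regions$type` is absent.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(regions, path, source = "aprvote",
                       type = "sequence_feature") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(regions))) {
    writeLines(paste(
      regions$sequence_id[i], source,
      if ("type" %in% names(regions)) regions$type[i] else type,
      regions$start[i], regions$end[i],
      if ("score" %in% names(regions)) format(regions$score[i]) else ".",
      ".", ".",
      paste0("ID=", regions$sequence_id[i], ":", regions$start[i], "-",
             regions$end[i]),
      sep = "\t"), con)
  }
  invisible(path)
}
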