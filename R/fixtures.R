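# Deterministic synthetic fixtures: polar-biased background sequences with
# planted aggregation-prone hexapeptide motifs and annotations that exactly
# cover the plantings. These provide controlled statistical structure for
# testing every pipeline stage; they do not simulate aggregation physics.

# Background alphabet biased toward polar/charged residues and excluding
# every residue that scores high on the packaged scales (F I L M V W Y C),
# so planted/background contrast is controllable.
default_background <- function() {
  c(D = 0.12, E = 0.12, K = 0.12, R = 0.10, S = 0.12, T = 0.10,
    G = 0.08, N = 0.06, Q = 0.06, H = 0.04, P = 0.04, A = 0.04)
}

#' Specify a synthetic fixture
#'
#' @param seed RNG seed (all randomness in [generate_fixture()] derives from
#'   it).
#' @param n_sequences Number of sequences.
#' @param length Residues per sequence.
#' @param motifs Hexapeptide motifs to plant, cycled across plantings.
#' @param density Motifs planted per sequence.
#' @param background Named probability weights over the background alphabet.
#' @param min_gap Minimum residues between plantings (>= 2 keeps annotation
#'   intervals from merging).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_sequences = 10L, length = 120L,
                         motifs = c("STVIIE", "GNNQQNY", "NNQQNY"),
                         density = 2L, background = default_background(),
                         min_gap = 3L) {
  stopifnot(n_sequences >= 1L, length >= 1L, density >= 0L, min_gap >= 2L)
  motifs <- toupper(motifs)
  structure(list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
                 length = as.integer(length), motifs = motifs,
                 density = as.integer(density), background = background,
                 min_gap = as.integer(min_gap)),
            class = "fixture_spec")
}

# Deterministic non-overlapping placement: sample starts left to right,
# drawing each gap uniformly from what still fits.
plant_positions <- function(len, widths, min_gap) {
  k <- length(widths)
  if (!k) return(integer())
  need <- sum(widths) + (k - 1L) * min_gap
  if (need > len) {
    stop("infeasible planting density: need ", need, " residues, have ", len,
         call. = FALSE)
  }
  slack <- len - need
  cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
  starts <- integer(k)
  at <- 1L
  for (i in seq_len(k)) {
    starts[i] <- at + cuts[i]
    at <- starts[i] + widths[i] + min_gap - cuts[i]
  }
  starts
}

#' Generate a synthetic fixture
#'
#' Reproducible for a fixed spec: background residues are drawn from the
#' polar-biased alphabet and motifs are planted at non-overlapping positions
#' (minimum gap `min_gap`), so the returned annotations exactly cover the
#' planted motifs and the manifest records every planting.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `sequences` (list of [protein_sequence()]),
#'   `annotations` (named list of [region_annotation()], one per sequence,
#'   possibly empty), `manifest` (data frame `sequence_id`, `motif`, `start`,
#'   `end`) and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  ab <- names(spec$background)
  pr <- spec$background / sum(spec$background)
  sequences <- vector("list", spec$n_sequences)
  annotations <- list()
  manifest <- data.frame(sequence_id = character(), motif = character(),
                         start = integer(), end = integer())
  for (s in seq_len(spec$n_sequences)) {
    id <- sprintf("syn%03d", s)
    chars <- sample(ab, spec$length, replace = TRUE, prob = pr)
    if (spec$density > 0L && length(spec$motifs)) {
      planted <- spec$motifs[((seq_len(spec$density) - 1L) %% length(spec$motifs)) + 1L]
      starts <- plant_positions(spec$length, nchar(planted), spec$min_gap)
      for (i in seq_along(planted)) {
        idx <- starts[i]:(starts[i] + nchar(planted[i]) - 1L)
        chars[idx] <- strsplit(planted[i], "", fixed = TRUE)[[1]]
        manifest <- rbind(manifest, data.frame(
          sequence_id = id, motif = planted[i],
          start = starts[i], end = starts[i] + nchar(planted[i]) - 1L))
      }
      annotations[[id]] <- region_annotation(
        id, manifest$start[manifest$sequence_id == id],
        manifest$end[manifest$sequence_id == id], seq_length = spec$length)
    } else {
      annotations[[id]] <- region_annotation(id)
    }
    sequences[[s]] <- protein_sequence(id, paste(chars, collapse = ""))
  }
  list(sequences = sequences, annotations = annotations,
       manifest = manifest, spec = spec)
}

#' Write a fixture to disk
#'
#' Emits `sequences.fasta`, `regions.tsv` (the bespoke region format) and
#' `manifest.json` (spec parameters plus every planting); the FASTA and
#' region files round-trip through [read_fasta()] / [read_regions()].
#'
#' @param fixture Result of [generate_fixture()].
#' @param dir Writable output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             regions = file.path(dir, "regions.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_fasta(fixture$sequences, paths[["fasta"]])
  write_regions(fixture$annotations, paths[["regions"]])
  spec <- fixture$spec
  jsonlite::write_json(
    list(spec = list(seed = spec$seed, n_sequences = spec$n_sequences,
                     length = spec$length, motifs = spec$motifs,
                     density = spec$density, min_gap = spec$min_gap,
                     background = as.list(spec$background)),
         plantings = fixture$manifest),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
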