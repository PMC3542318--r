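# Component predictors. Five methods run natively from packaged data; the
# other six consume external per-residue score tables through a generic
# threshold adapter. Window semantics are shared: only full-length windows are
# scored, and a residue is a hit when ANY qualifying window covers it (union).
# Non-standard residues carry no propensity value, poison every window that
# contains them, and can never be hits.

scale_for_chars <- function(scale, chars) {
  v <- unname(scale[chars])   # unknown residues -> NA
  as.numeric(v)
}

# Means of all full windows of width w; NA if the window touches an NA value.
sliding_means <- function(v, w) {
  n <- length(v)
  if (n < w) return(numeric(0))
  vapply(seq_len(n - w + 1L), function(i) {
    win <- v[i:(i + w - 1L)]
    if (anyNA(win)) NA_real_ else mean(win)
  }, numeric(1))
}

# Spread window statistics onto residues: per-residue max of the covering
# window values, and whether any covering window qualifies.
spread_windows <- function(win_values, win_hits, w, n) {
  scores <- rep(NA_real_, n)
  hits <- rep(FALSE, n)
  for (i in seq_along(win_values)) {
    idx <- i:(i + w - 1L)
    v <- win_values[i]
    if (!is.na(v)) {
      scores[idx] <- pmax(scores[idx], v, na.rm = TRUE)
      if (win_hits[i]) hits[idx] <- TRUE
    }
  }
  list(scores = scores, hits = hits)
}

skipped_result <- function(config, seq) {
  method_result(config$method, seq$id,
                scores = rep(NA_real_, seq$length),
                hits = rep(FALSE, seq$length),
                config = config, status = "skipped_too_short")
}

#' Amyloidogenic hexapeptide pattern predictor
#'
#' Slides a six-position pattern of allowed/forbidden residue sets (packaged,
#' transcribed from the saturation-mutagenesis pattern whose defining peptide
#' is STVIIE) along the sequence; every residue of every matching hexapeptide
#' window is a hit. Scores report how many matching windows cover each
#' residue. Sequences shorter than six residues yield zero hits with status
#' `"ok"` when called directly.
#'
#' @param seq A [protein_sequence()].
#' @param config Optional `method_config` override.
#' @return A [method_result()].
#' @export
run_amyloidogenic_pattern <- function(seq, config = method_registry()$pattern) {
  pat <- load_pattern()
  chars <- seq_chars(seq)
  n <- seq$length
  cover <- rep(0L, n)
  if (n >= 6L) {
    sets <- strsplit(pat$residues, "", fixed = TRUE)
    for (i in seq_len(n - 5L)) {
      ok <- TRUE
      for (p in 1:6) {
        ch <- chars[i + p - 1L]
        if (!ch %in% STANDARD_AA) { ok <- FALSE; break }
        inset <- ch %in% sets[[p]]
        if (pat$mode[p] == "allowed" && !inset) { ok <- FALSE; break }
        if (pat$mode[p] == "forbidden" && inset) { ok <- FALSE; break }
      }
      if (ok) cover[i:(i + 5L)] <- cover[i:(i + 5L)] + 1L
    }
  }
  method_result(config$method, seq$id, scores = as.numeric(cover),
                hits = cover > 0L, config = config, status = "ok")
}

#' Average packing density predictor
#'
#' Five-residue sliding-window mean of the packaged expected-packing-density
#' scale; residues covered by at least one window with mean strictly above the
#' 21.4 cut-off are hits. Scores report the maximum covering-window mean.
#'
#' @inheritParams run_amyloidogenic_pattern
#' @return A [method_result()]; status `"skipped_too_short"` below five
#'   residues.
#' @export
run_average_packing_density <- function(seq, config = method_registry()$apd) {
  w <- config$params$window
  if (seq$length < w) return(skipped_result(config, seq))
  scale <- load_scale("packing_density_synthetic")
  means <- sliding_means(scale_for_chars(scale, seq_chars(seq)), w)
  sp <- spread_windows(means, !is.na(means) & means > config$params$threshold,
                       w, seq$length)
  method_result(config$method, seq$id, sp$scores, sp$hits, config, "ok")
}

#' Beta-strand contiguity predictor (sliding-average procedure)
#'
#' For every window of length `window_min..window_max`, the mean beta-strand
#' propensity (packaged Chou-Fasman scale) is computed; windows with mean at
#' or above `mbp_min` (default 1.2) add their mean to the cumulative score
#' `y` of every residue they cover. Residues with `y` strictly above
#' `y_threshold` (default 20) are hits. Scores report `y`.
#'
#' @inheritParams run_amyloidogenic_pattern
#' @return A [method_result()]; status `"skipped_too_short"` below the
#'   minimum window length.
#' @export
run_beta_contiguity <- function(seq, config = method_registry()$bsc) {
  p <- config$params
  n <- seq$length
  if (n < p$window_min) return(skipped_result(config, seq))
  v <- scale_for_chars(load_scale("beta_propensity"), seq_chars(seq))
  y <- rep(0, n)
  for (w in p$window_min:min(p$window_max, n)) {
    means <- sliding_means(v, w)
    for (i in seq_along(means)) {
      if (!is.na(means[i]) && means[i] >= p$mbp_min) {
        idx <- i:(i + w - 1L)
        y[idx] <- y[idx] + means[i]
      }
    }
  }
  hits <- y > p$y_threshold
  # cumulative y is a real score for every standard residue (0 when no
  # window qualifies); non-standard residues keep the no-score sentinel
  scores <- y
  scores[seq$nonstandard] <- NA_real_
  method_result(config$method, seq$id, scores, hits & !is.na(scores),
                config, "ok")
}

aggrescan_window <- function(n, rule) {
  for (r in rule) if (n <= r[[1]]) return(as.integer(r[[2]]))
  as.integer(rule[[length(rule)]][[2]])
}

#' In-vivo aggregation-propensity predictor (sliding-average scale)
#'
#' Sliding-window mean of the packaged in-vivo aggregation-propensity scale
#' (a3v). Window length depends on sequence length (packaged rule: <=75
#' residues use 5, <=175 use 7, <=300 use 9, longer use 11); residues in
#' windows whose mean strictly exceeds the hot-spot threshold (-0.02) are
#' hits. Scores report the maximum covering-window mean.
#'
#' @inheritParams run_amyloidogenic_pattern
#' @return A [method_result()]; status `"skipped_too_short"` below five
#'   residues.
#' @export
run_aggrescan <- function(seq, config = method_registry()$aggrescan) {
  w <- aggrescan_window(seq$length, config$params$window_rule)
  if (seq$length < w) return(skipped_result(config, seq))
  scale <- load_scale("aggrescan_a3v")
  means <- sliding_means(scale_for_chars(scale, seq_chars(seq)), w)
  sp <- spread_windows(means, !is.na(means) & means > config$params$threshold,
                       w, seq$length)
  method_result(config$method, seq$id, sp$scores, sp$hits, config, "ok")
}

#' Hexapeptide PSSM predictor
#'
#' Scores every hexapeptide window as the sum of its six position-residue
#' entries in the packaged 0-100 scaled profile; windows scoring at or above
#' the high-sensitivity cut-off (79.0; a stricter 92.0 setting is also
#' packaged) mark their six residues as hits. Scores report the maximum
#' covering-window score.
#'
#' @inheritParams run_amyloidogenic_pattern
#' @return A [method_result()]; status `"skipped_too_short"` below six
#'   residues.
#' @export
run_waltz_pssm <- function(seq, config = method_registry()$waltz) {
  w <- config$params$window
  if (seq$length < w) return(skipped_result(config, seq))
  m <- load_pssm()
  chars <- seq_chars(seq)
  n <- seq$length
  win_scores <- vapply(seq_len(n - w + 1L), function(i) {
    ch <- chars[i:(i + w - 1L)]
    if (!all(ch %in% STANDARD_AA)) return(NA_real_)
    sum(m[cbind(1:6, match(ch, colnames(m)))])
  }, numeric(1))
  sp <- spread_windows(win_scores,
                       !is.na(win_scores) & win_scores >= config$params$threshold,
                       w, n)
  method_result(config$method, seq$id, sp$scores, sp$hits, config, "ok")
}

cmp_ops <- list(">"  = function(a, b) a > b,
                ">=" = function(a, b) a >= b,
                "<"  = function(a, b) a < b,
                "<=" = function(a, b) a <= b)

#' Threshold adapter for externally computed scores
#'
#' Applies a method's structured comparison rule to a per-residue score table
#' (as returned by [read_score_table()]). A residue is a hit iff every
#' comparison in the rule holds there; positions carrying the no-score
#' sentinel are never hits. Derived columns (e.g. the hidden beta-propensity
#' ratio `hbp = pbeta/phelix`) are computed from the raw columns first.
#'
#' @param config A `method_config` of kind `"adapter"`.
#' @param scores Data frame of per-residue score columns for one sequence, or
#'   `NULL` when the external run is unavailable.
#' @param seq The target [protein_sequence()].
#' @return A [method_result()]; status `"external_missing"` when `scores` is
#'   `NULL` or a required column is absent, `"skipped_too_short"` below the
#'   method's minimum length.
#' @export
apply_method_threshold <- function(config, scores, seq) {
  n <- seq$length
  if (n < config$min_length) return(skipped_result(config, seq))
  missing_result <- function() {
    method_result(config$method, seq$id, rep(NA_real_, n), rep(FALSE, n),
                  config, "external_missing")
  }
  if (is.null(scores)) return(missing_result())
  if (nrow(scores) != n) {
    stop("external scores for '", seq$id, "' cover ", nrow(scores),
         " residues, sequence has ", n, call. = FALSE)
  }
  for (d in names(config$params$derive)) {
    src <- unlist(config$params$derive[[d]])
    if (!all(src %in% names(scores))) return(missing_result())
    scores[[d]] <- scores[[src[1]]] / scores[[src[2]]]
  }
  rule <- config$params$rule
  cols <- vapply(rule, `[[`, character(1), "column")
  if (!all(cols %in% names(scores))) return(missing_result())
  hits <- rep(TRUE, n)
  for (r in rule) {
    v <- scores[[r$column]]
    ok <- cmp_ops[[r$op]](v, r$cutoff)
    hits <- hits & !is.na(ok) & ok
  }
  primary <- scores[[cols[1]]]
  hits <- hits & !is.na(primary)
  method_result(config$method, seq$id, primary, hits, config, "ok")
}

native_runners <- function() {
  list(pattern   = run_amyloidogenic_pattern,
       apd       = run_average_packing_density,
       bsc       = run_beta_contiguity,
       aggrescan = run_aggrescan,
       waltz     = run_waltz_pssm)
}

#' Run a selection of component methods on one sequence
#'
#' Dispatches every selected method in canonical registry order. Methods whose
#' minimum length exceeds the sequence length return `"skipped_too_short"`;
#' selected adapter methods with no external score table return
#' `"external_missing"`. Neither participates in the consensus vote.
#'
#' @param seq A [protein_sequence()].
#' @param selection Character vector of method tokens (default: the five
#'   native methods).
#' @param external_scores Named list, one element per adapter method, each a
#'   map from sequence id to a per-residue score data frame (the shape
#'   returned by [read_score_table()]).
#' @return A list of [method_result()] objects in canonical order.
#' @export
run_all <- function(seq, selection = native_methods(), external_scores = NULL) {
  if (!length(selection)) stop("empty method selection", call. = FALSE)
  reg <- method_registry()
  unknown <- setdiff(selection, names(reg))
  if (length(unknown)) {
    stop("unknown method(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  selection <- intersect(names(reg), selection)  # canonical order
  runners <- native_runners()
  lapply(selection, function(m) {
    cfg <- reg[[m]]
    if (seq$length < cfg$min_length) return(skipped_result(cfg, seq))
    if (cfg$kind == "native") {
      runners[[m]](seq, cfg)
    } else {
      apply_method_threshold(cfg, external_scores[[m]][[seq$id]], seq)
    }
  })
}
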