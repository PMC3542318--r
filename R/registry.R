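# Packaged method registry and numeric data files. Every threshold, window
# rule and minimum length lives in inst/extdata/method_registry.tsv; the
# propensity scales, the hexapeptide pattern and the PSSM are shipped as TSVs
# whose md5 checksums (inst/extdata/data_manifest.tsv) are verified at load.

the <- new.env(parent = emptyenv())

apr_data_file <- function(name) {
  p <- system.file("extdata", name, package = "aprvote")
  if (!nzchar(p)) stop("packaged data file missing: ", name, call. = FALSE)
  p
}

data_manifest <- function() {
  if (is.null(the$manifest)) {
    the$manifest <- utils::read.delim(apr_data_file("data_manifest.tsv"),
                                      stringsAsFactors = FALSE)
  }
  the$manifest
}

verify_checksum <- function(name) {
  man <- data_manifest()
  row <- man[man$file == name, , drop = FALSE]
  if (!nrow(row)) stop("no checksum recorded for data file ", name, call. = FALSE)
  got <- unname(tools::md5sum(apr_data_file(name)))
  if (!identical(got, row$md5[1L])) {
    stop("checksum mismatch for packaged data file ", name,
         " (expected ", row$md5[1L], ", got ", got, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a packaged propensity scale
#'
#' @param name Scale identifier: `"aggrescan_a3v"`, `"beta_propensity"` or
#'   `"packing_density_synthetic"`.
#' @return A named numeric vector over the 20 standard residues, with the
#'   source citation as attribute `"citation"`.
#' @export
load_scale <- function(name) {
  key <- paste0("scale_", name)
  if (!is.null(the[[key]])) return(the[[key]])
  file <- paste0("scale_", name, ".tsv")
  verify_checksum(file)
  tab <- utils::read.delim(apr_data_file(file), comment.char = "#",
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(as.numeric(tab$value), tab$residue)
  if (!setequal(names(vals), STANDARD_AA) || length(vals) != 20L) {
    stop("scale ", name, " must define exactly the 20 standard residues",
         call. = FALSE)
  }
  cite <- grep("^# ", readLines(apr_data_file(file), n = 5L), value = TRUE)
  attr(vals, "citation") <- paste(sub("^# ?", "", cite), collapse = " ")
  the[[key]] <- vals
  vals
}

#' Load the packaged amyloidogenic hexapeptide pattern
#'
#' Six positions, each either an allowed residue set (the window residue must
#' be in the set) or a forbidden set (must not be). Non-standard residues
#' never satisfy a position.
#'
#' @return A data frame with columns `position`, `mode`, `residues`.
#' @export
load_pattern <- function() {
  if (!is.null(the$pattern)) return(the$pattern)
  file <- "pattern_amyloidogenic_hexapeptide.tsv"
  verify_checksum(file)
  tab <- utils::read.delim(apr_data_file(file), comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(identical(tab$position, 1:6),
            all(tab$mode %in% c("allowed", "forbidden")))
  the$pattern <- tab
  tab
}

#' Load the packaged hexapeptide PSSM
#'
#' A 6-position x 20-residue scoring matrix (synthetic stand-in profile, see
#' the package vignette); a window score is the sum of its six
#' position-residue entries, scaled so the achievable range is 0-100.
#'
#' @return A 6 x 20 numeric matrix, rows = positions, columns = residues.
#' @export
load_pssm <- function() {
  if (!is.null(the$pssm)) return(the$pssm)
  file <- "pssm_waltz_ph7_synthetic.tsv"
  verify_checksum(file)
  tab <- utils::read.delim(apr_data_file(file), comment.char = "#",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, STANDARD_AA])
  rownames(m) <- tab$position
  stopifnot(nrow(m) == 6L, ncol(m) == 20L, !anyNA(m))
  the$pssm <- m
  m
}

#' The method registry
#'
#' One entry per component method, holding its kind (native or adapter),
#' minimum supported sequence length, packaged data file, and every threshold
#' and window parameter, read from `inst/extdata/method_registry.tsv`.
#'
#' @return A named list of `method_config` objects in canonical method order.
#' @export
method_registry <- function() {
  if (!is.null(the$registry)) return(the$registry)
  tab <- utils::read.delim(apr_data_file("method_registry.tsv"), quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  cfgs <- lapply(seq_len(nrow(tab)), function(i) {
    method_config(method = tab$method[i],
                  kind = tab$kind[i],
                  label = tab$label[i],
                  min_length = tab$min_length[i],
                  data_file = if (tab$data_file[i] == "-") NULL else tab$data_file[i],
                  params = jsonlite::fromJSON(tab$params[i],
                                              simplifyVector = FALSE))
  })
  names(cfgs) <- tab$method
  the$registry <- cfgs
  cfgs
}

#' Construct a method configuration
#'
#' @param method Method token (e.g. `"waltz"`).
#' @param kind `"native"` or `"adapter"`.
#' @param label Human-readable method name.
#' @param min_length Minimum sequence length the method supports.
#' @param data_file Packaged data file backing a native method, or `NULL`.
#' @param params List of method parameters (thresholds, windows, rules).
#' @return An object of class `method_config`.
#' @export
method_config <- function(method, kind = c("native", "adapter"), label = method,
                          min_length = 1L, data_file = NULL, params = list()) {
  kind <- match.arg(kind)
  structure(list(method = method, kind = kind, label = label,
                 min_length = as.integer(min_length),
                 data_file = data_file, params = params),
            class = "method_config")
}

#' @export
print.method_config <- function(x, ...) {
  cat("<method_config> ", x$method, " (", x$kind, ", min_length=",
      x$min_length, ")\n", sep = "")
  invisible(x)
}

#' Canonical method order
#'
#' @return Character vector of the 11 method tokens in registry order.
#' @export
method_order <- function() names(method_registry())

#' Native method tokens
#' @return Character vector of the five natively implemented methods.
#' @export
native_methods <- function() {
  reg <- method_registry()
  names(reg)[vapply(reg, function(c) c$kind == "native", logical(1))]
}
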