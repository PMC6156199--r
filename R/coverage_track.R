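#' Per-nucleotide strand-specific coverage track
#'
#' A coverage track holds one replicon's per-nucleotide read coverage for a
#' single strand, together with the library's total mapped reads. Values are
#' reads per nucleotide (raw) or reads per million mapped reads after
#' [normalize_by_library_size()].
#'
#' @param values Numeric vector of non-negative per-nucleotide coverage over
#'   `[0, replicon_length)`.
#' @param strand `"+"` or `"-"`.
#' @param replicon_id Replicon (chromosome/plasmid) name.
#' @param library_total Total mapped reads in the library; must be positive.
#' @param normalized Logical; `TRUE` once values are library-size normalized.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, strand, replicon_id = "chr",
                           library_total = sum(values), normalized = FALSE) {
  values <- as.numeric(values)
  if (any(is.na(values)) || any(values < 0)) {
    stopf("coverage values must be non-negative and non-missing")
  }
  strand <- match.arg(strand, c("+", "-"))
  library_total <- as.numeric(library_total)
  if (length(library_total) != 1L || is.na(library_total) || library_total <= 0) {
    stopf("library_total must be a single positive number")
  }
  structure(
    list(replicon_id = as.character(replicon_id), strand = strand,
         values = values, library_total = library_total,
         normalized = isTRUE(normalized)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s (%s) %d nt, library %.4g reads, %s\n",
    x$replicon_id, x$strand, length(x$values), x$library_total,
    if (x$normalized) "normalized (RPM)" else "raw (reads/nt)"))
  invisible(x)
}

#' @export
length.coverage_track <- function(x) length(x$values)

#' Normalize a coverage track by library size
#'
#' Multiplies every value by `1e6 / library_total` (reads-per-million).
#' The paper's maps were "normalized by the number of mapped reads in each
#' library"; any fixed constant cancels in downstream ratios, and RPM keeps
#' values readable. Double normalization is refused.
#'
#' @param track A [coverage_track()].
#' @return The normalized track, with `normalized = TRUE`.
#' @export
normalize_by_library_size <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalized) stopf("track is already library-size normalized")
  if (track$library_total <= 0) stopf("library_total must be positive")
  track$values <- track$values * (1e6 / track$library_total)
  track$normalized <- TRUE
  track
}

#' Extract coverage over a 0-based half-open interval
#'
#' @param track A [coverage_track()].
#' @param start,end 0-based half-open bounds within the replicon.
#' @return Numeric vector of length `end - start`.
#' @export
track_slice <- function(track, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  n <- length(track$values)
  if (start < 0 || end > n || end <= start) {
    stopf("interval [%d, %d) outside replicon of length %d", start, end, n)
  }
  track$values[(start + 1L):end]
}

#' Mean coverage over an interval
#' @inheritParams track_slice
#' @export
interval_mean <- function(track, start, end) mean(track_slice(track, start, end))
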