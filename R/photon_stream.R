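#' Time-stamped photon stream
#'
#' The raw substrate of all single-molecule FRET stages: one record per
#' detected photon, carrying its macrotime (laboratory-clock ticks), its
#' microtime (TCSPC bin, i.e. delay after the excitation pulse), and its
#' spectral detection channel. The PIE scheme maps microtimes to
#' excitation slots (Dex/Aex); photons outside both PIE windows are kept in
#' the container but excluded from every analysis.
#'
#' @param timestamps Numeric/integer macrotimes in clock ticks,
#'   non-decreasing.
#' @param nanotimes Integer TCSPC bins, in `[0, pie$n_bins)`.
#' @param detectors Integer channel per photon: 0 = donor (D), 1 = acceptor
#'   (A).
#' @param clock_rate_hz Macrotime clock rate (ticks per second).
#' @param pie A [pie_scheme()].
#' @param duration_s Acquisition duration in seconds (defaults to the last
#'   timestamp).
#' @param meta Optional named list of free-form acquisition metadata.
#'
#' @return An object of class `photon_stream`: a list with the validated
#'   fields above plus `slot`, the per-photon excitation-slot factor.
#'
#' @examples
#' ps <- photon_stream(timestamps = c(0, 10, 25), nanotimes = c(5L, 3000L, 7L),
#'                     detectors = c(0L, 1L, 1L), clock_rate_hz = 80e6,
#'                     pie = pie_scheme())
#' table(ps$slot)
#' @export
photon_stream <- function(timestamps, nanotimes, detectors,
                          clock_rate_hz, pie, duration_s = NULL,
                          meta = list()) {
  stopifnot(inherits(pie, "pie_scheme"), clock_rate_hz > 0)
  n <- length(timestamps)
  if (length(nanotimes) != n || length(detectors) != n)
    stop("timestamps, nanotimes and detectors must have equal length")
  if (n > 0) {
    d <- diff(timestamps)
    if (any(d < 0)) {
      i <- which(d < 0)[1] + 1L
      stop(sprintf("timestamps must be non-decreasing (first violation at photon %d)", i))
    }
    if (any(nanotimes < 0 | nanotimes >= pie$n_bins))
      stop("nanotimes out of TCSPC range")
    if (!all(detectors %in% c(0L, 1L)))
      stop("detectors must be 0 (donor) or 1 (acceptor)")
  }
  if (is.null(duration_s))
    duration_s <- if (n > 0) max(timestamps) / clock_rate_hz else 0
  structure(list(
    timestamps = as.double(timestamps),
    nanotimes = as.integer(nanotimes),
    detectors = as.integer(detectors),
    clock_rate_hz = clock_rate_hz,
    pie = pie,
    duration_s = duration_s,
    slot = excitation_slot(as.integer(nanotimes), pie),
    meta = meta),
    class = "photon_stream")
}

#' Number of photons in a stream
#' @param x A `photon_stream`.
#' @return Integer photon count.
#' @export
n_photons <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  length(x$timestamps)
}

#' Photon macrotimes in seconds
#' @param x A `photon_stream`.
#' @return Numeric vector of arrival times (s).
#' @export
photon_times_s <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  x$timestamps / x$clock_rate_hz
}

#' Photon microtimes in nanoseconds
#' @param x A `photon_stream`.
#' @return Numeric vector of TCSPC delays (ns), measured from the start of
#'   the photon's excitation window so that Dex and Aex photons are on the
#'   same per-pulse scale.
#' @export
photon_nanotimes_ns <- function(x) {
  stopifnot(inherits(x, "photon_stream"))
  off <- integer(length(x$nanotimes))
  off[!is.na(x$slot) & x$slot == "Aex"] <- x$pie$aex_window[1]
  (x$nanotimes - off) * x$pie$tcspc_unit_ns
}

# The three photon sub-streams the pipeline consumes. Returns a logical
# index vector into the stream for the requested (slot, channel) pair.
stream_mask <- function(x, which = c("DexD", "DexA", "AexA")) {
  which <- match.arg(which)
  s <- x$slot
  d <- x$detectors
  switch(which,
         DexD = !is.na(s) & s == "Dex" & d == 0L,
         DexA = !is.na(s) & s == "Dex" & d == 1L,
         AexA = !is.na(s) & s == "Aex" & d == 1L)
}

#' @export
print.photon_stream <- function(x, ...) {
  n <- n_photons(x)
  cat(sprintf("photon_stream: %d photons, %.4g s, clock %.4g Hz\n",
              n, x$duration_s, x$clock_rate_hz))
  if (n > 0) {
    cat(sprintf("  Dex/D %d  Dex/A %d  Aex/A %d  (outside windows: %d)\n",
                sum(stream_mask(x, "DexD")), sum(stream_mask(x, "DexA")),
                sum(stream_mask(x, "AexA")), sum(is.na(x$slot))))
  }
  invisible(x)
}
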