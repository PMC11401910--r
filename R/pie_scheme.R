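#' Pulsed-interleaved excitation (PIE) scheme
#'
#' Defines how TCSPC microtimes are partitioned into donor-excitation (Dex)
#' and acceptor-excitation (Aex) slots. In PIE (ns-ALEX) the donor and
#' acceptor lasers fire alternately within one TCSPC period, so a photon's
#' microtime identifies which laser excited the molecule.
#'
#' Windows are half-open intervals `[lo, hi)` in TCSPC bins, must be disjoint
#' and must lie within `[0, n_bins)`.
#'
#' @param period_ns Alternation period in ns (one full Dex+Aex cycle).
#' @param n_bins Number of TCSPC bins spanning the period.
#' @param dex_window Integer vector `c(lo, hi)`: Dex slot in TCSPC bins.
#' @param aex_window Integer vector `c(lo, hi)`: Aex slot in TCSPC bins.
#'
#' @return An object of class `pie_scheme`: a list with elements
#'   `period_ns`, `n_bins`, `tcspc_unit_ns` (= period_ns / n_bins),
#'   `dex_window`, `aex_window`.
#'
#' @details The default models a 20 MHz alternation (50 ns period) with a
#'   50:50 duty cycle and 4096 TCSPC bins; both are configurable because
#'   repetition rate and duty cycle are instrument choices.
#'
#' @examples
#' pie <- pie_scheme()
#' pie$tcspc_unit_ns
#' @export
pie_scheme <- function(period_ns = 50,
                       n_bins = 4096L,
                       dex_window = c(0L, n_bins %/% 2L),
                       aex_window = c(n_bins %/% 2L, n_bins)) {
  stopifnot(period_ns > 0, n_bins >= 2)
  dex_window <- as.integer(dex_window)
  aex_window <- as.integer(aex_window)
  if (length(dex_window) != 2L || length(aex_window) != 2L ||
      dex_window[1] >= dex_window[2] || aex_window[1] >= aex_window[2])
    stop("PIE windows must be non-empty half-open intervals c(lo, hi)")
  if (min(dex_window[1], aex_window[1]) < 0L ||
      max(dex_window[2], aex_window[2]) > n_bins)
    stop("PIE windows must lie within [0, n_bins)")
  # disjointness of half-open intervals
  if (max(dex_window[1], aex_window[1]) < min(dex_window[2], aex_window[2]))
    stop("dex_window and aex_window must be disjoint")
  structure(
    list(period_ns = period_ns,
         n_bins = as.integer(n_bins),
         tcspc_unit_ns = period_ns / n_bins,
         dex_window = dex_window,
         aex_window = aex_window),
    class = "pie_scheme")
}

#' Assign excitation slots from microtimes
#'
#' @param nanotimes Integer TCSPC bin numbers.
#' @param pie A [pie_scheme()].
#' @return Factor with levels `Dex`, `Aex`; `NA` for photons outside both
#'   windows (such photons are excluded from all analyses).
#' @export
excitation_slot <- function(nanotimes, pie) {
  stopifnot(inherits(pie, "pie_scheme"))
  slot <- rep(NA_character_, length(nanotimes))
  slot[nanotimes >= pie$dex_window[1] & nanotimes < pie$dex_window[2]] <- "Dex"
  slot[nanotimes >= pie$aex_window[1] & nanotimes < pie$aex_window[2]] <- "Aex"
  factor(slot, levels = c("Dex", "Aex"))
}

#' @export
print.pie_scheme <- function(x, ...) {
  cat(sprintf("PIE scheme: period %.3g ns, %d TCSPC bins (%.4g ps/bin)\n",
              x$period_ns, x$n_bins, 1000 * x$tcspc_unit_ns))
  cat(sprintf("  Dex window: [%d, %d)  Aex window: [%d, %d)\n",
              x$dex_window[1], x$dex_window[2],
              x$aex_window[1], x$aex_window[2]))
  invisible(x)
}
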