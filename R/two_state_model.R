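#' Ground-truth model for the photon-stream simulator
#'
#' Describes a freely diffusing, doubly labelled molecule interconverting
#' between two FRET states under PIE excitation, together with the
#' instrument: channel crosstalk, detection asymmetry, background and the
#' instrument response offset. `simulate_photon_stream()` samples photon
#' records from this model; the corrections in [corrected_es()] with the
#' same [correction_set()] recover the state efficiencies in expectation.
#'
#' Setting `k12 = k21 = 0` gives a static model (the molecule stays in
#' state 1). Transits are modelled as rectangular-rate emission periods of
#' exponentially distributed duration, the picture appropriate for the
#' low-picomolar regime where at most one molecule occupies the confocal
#' volume at a time; overlapping transits are dropped.
#'
#' @param E1,E2 True FRET efficiencies of states 1 and 2, in `[0, 1]`.
#' @param k12,k21 Exchange rates state 1 -> 2 and 2 -> 1 (per second);
#'   both zero means static.
#' @param S_true True stoichiometry in (0, 1); 0.5 for a doubly labelled
#'   molecule with balanced excitation.
#' @param tau_D0 Donor-only fluorescence lifetime (ns).
#' @param tau_A Acceptor fluorescence lifetime (ns); only shapes acceptor
#'   microtimes, which the lifetime analysis does not consume.
#' @param burst_rate Molecule-transit rate (per second).
#' @param transit_mean Mean transit duration (seconds).
#' @param peak_rate Detected donor-excitation fluorescence event rate during
#'   a transit (counts/s), i.e. the F_DD + F_DA photon budget before
#'   crosstalk.
#' @param bg_rates Named numeric vector of background rates (counts/s) for
#'   the three analysed streams: `DexD`, `DexA`, `AexA`.
#' @param corrections [correction_set()] applied in generation.
#' @param irf_mean Instrument-response mean delay (ns), a fixed offset added
#'   to every fluorescence microtime.
#' @param pie [pie_scheme()].
#' @param clock_rate_hz Macrotime clock rate.
#' @param seed Integer seed; identical seeds give bit-identical streams.
#'
#' @return An object of class `two_state_model`.
#' @examples
#' m <- two_state_model(E1 = 0.45, E2 = 0.45, seed = 7)
#' @export
two_state_model <- function(E1, E2 = E1, k12 = 0, k21 = 0,
                            S_true = 0.5,
                            tau_D0 = 4.0, tau_A = 1.7,
                            burst_rate = 5, transit_mean = 1e-3,
                            peak_rate = 1e5,
                            bg_rates = c(DexD = 1000, DexA = 600, AexA = 400),
                            corrections = neutral_corrections(),
                            irf_mean = 2.0,
                            pie = pie_scheme(),
                            clock_rate_hz = 80e6,
                            seed = 1L) {
  stopifnot(E1 >= 0, E1 <= 1, E2 >= 0, E2 <= 1,
            k12 >= 0, k21 >= 0,
            S_true > 0, S_true < 1,
            tau_D0 > 0, tau_A > 0,
            burst_rate >= 0, transit_mean > 0, peak_rate > 0,
            irf_mean >= 0,
            inherits(corrections, "correction_set"),
            inherits(pie, "pie_scheme"),
            clock_rate_hz > 0)
  if (!all(c("DexD", "DexA", "AexA") %in% names(bg_rates)))
    stop("bg_rates must be named with DexD, DexA, AexA")
  if (any(bg_rates < 0)) stop("background rates must be >= 0")
  structure(list(
    E1 = E1, E2 = E2, k12 = k12, k21 = k21,
    S_true = S_true, tau_D0 = tau_D0, tau_A = tau_A,
    burst_rate = burst_rate, transit_mean = transit_mean,
    peak_rate = peak_rate,
    bg_rates = bg_rates[c("DexD", "DexA", "AexA")],
    corrections = corrections,
    irf_mean = irf_mean, pie = pie,
    clock_rate_hz = clock_rate_hz,
    seed = as.integer(seed)),
    class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  kind <- if (x$k12 == 0 && x$k21 == 0) "static" else
    sprintf("dynamic (k12=%.3g/s, k21=%.3g/s)", x$k12, x$k21)
  cat(sprintf("two_state_model: E1=%.3g E2=%.3g, %s, S=%.2g, tau_D0=%.3g ns\n",
              x$E1, x$E2, kind, x$S_true, x$tau_D0))
  cat(sprintf("  bursts %.3g/s, transit %.3g ms, peak %.3g counts/s, seed %d\n",
              x$burst_rate, 1000 * x$transit_mean, x$peak_rate, x$seed))
  invisible(x)
}
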