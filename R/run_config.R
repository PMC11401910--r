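#' Correction factors for ALEX burst counts
#'
#' The four consensus correction factors used to convert raw burst counts to
#' absolute FRET efficiency and stoichiometry: donor spectral leakage into
#' the acceptor channel (`lk`), acceptor direct excitation by the donor
#' laser (`dir`), the detection-efficiency/quantum-yield factor `gamma`,
#' and the excitation-rate ratio `beta`.
#'
#' @param lk Donor leakage fraction (>= 0).
#' @param dir Direct-excitation fraction (>= 0).
#' @param gamma Gamma factor (> 0).
#' @param beta Beta factor (> 0).
#' @return An object of class `correction_set`.
#' @examples
#' correction_set()            # the study defaults
#' correction_set(0, 0, 1, 1)  # neutral corrections
#' @export
correction_set <- function(lk = 0.14, dir = 0.14, gamma = 1.0, beta = 1.4) {
  stopifnot(lk >= 0, dir >= 0, gamma > 0, beta > 0)
  structure(list(lk = lk, dir = dir, gamma = gamma, beta = beta),
            class = "correction_set")
}

#' Neutral corrections (identity)
#' @return A `correction_set` with lk = dir = 0, gamma = beta = 1.
#' @export
neutral_corrections <- function() correction_set(0, 0, 1, 1)

#' @export
print.correction_set <- function(x, ...) {
  cat(sprintf("corrections: lk=%.3g dir=%.3g gamma=%.3g beta=%.3g\n",
              x$lk, x$dir, x$gamma, x$beta))
  invisible(x)
}

#' Analysis run configuration
#'
#' Bundles every tunable of the burst pipeline with the study's published
#' values as defaults: background estimated per 60-s segment; dual-channel
#' burst search at 3x background with a minimum burst size of 50
#' donor-excitation photons; corrections lk = 0.14, dir = 0.14, gamma = 1.0,
#' beta = 1.4; stoichiometry filter S in [0.3, 0.7]; ALEX-2CDE cutoff 95;
#' BVA with 5-photon windows and 0.05-wide E_raw bins; donor-only selection
#' at S > 0.9.
#'
#' @param corrections A [correction_set()].
#' @param bg_segment_s Background segment length, seconds.
#' @param threshold_factor Burst-search rate threshold, multiples of the
#'   segment background rate.
#' @param min_size Minimum n_DD + n_DA per burst.
#' @param window_m Photons per sliding window in the burst search.
#' @param s_min,s_max Corrected-stoichiometry filter bounds (inclusive).
#' @param cde_max ALEX-2CDE cutoff (bursts with score <= cde_max kept).
#' @param cde_tau_us ALEX-2CDE exponential kernel width, microseconds.
#' @param bva_window BVA window size, photons.
#' @param bva_bin_width BVA E_raw bin width.
#' @param donor_only_s_min S threshold above which bursts count as donor-only.
#' @param lifetime_min_photons Minimum Dex/D photons for a burst lifetime.
#' @param filter_on_raw_s If TRUE, the S filter uses raw instead of
#'   corrected stoichiometry.
#' @param edge_trim Gap-based burst edge refinement, see [search_bursts()].
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(corrections = correction_set(),
                       bg_segment_s = 60,
                       threshold_factor = 3,
                       min_size = 50L,
                       window_m = 10L,
                       s_min = 0.3, s_max = 0.7,
                       cde_max = 95,
                       cde_tau_us = 100,
                       bva_window = 5L,
                       bva_bin_width = 0.05,
                       donor_only_s_min = 0.9,
                       lifetime_min_photons = 10L,
                       filter_on_raw_s = FALSE,
                       edge_trim = TRUE) {
  stopifnot(inherits(corrections, "correction_set"),
            bg_segment_s > 0, threshold_factor > 0,
            min_size >= 1, window_m >= 2, s_min < s_max,
            cde_tau_us > 0, bva_window >= 2, bva_bin_width > 0,
            lifetime_min_photons >= 1)
  if (min_size < window_m)
    stop("min_size must be >= window_m")
  structure(list(
    corrections = corrections,
    bg_segment_s = bg_segment_s,
    threshold_factor = threshold_factor,
    min_size = as.integer(min_size),
    window_m = as.integer(window_m),
    s_min = s_min, s_max = s_max,
    cde_max = cde_max,
    cde_tau_us = cde_tau_us,
    bva_window = as.integer(bva_window),
    bva_bin_width = bva_bin_width,
    donor_only_s_min = donor_only_s_min,
    lifetime_min_photons = as.integer(lifetime_min_photons),
    filter_on_raw_s = filter_on_raw_s,
    edge_trim = edge_trim),
    class = "run_config")
}

# Serialise a run_config (and nested corrections) to a single JSON string,
# used in output-file headers so any result is reproducible from the file.
config_json <- function(config) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$corrections <- unclass(x$corrections)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}
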