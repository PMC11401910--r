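# Burst-averaged donor lifetimes from TCSPC microtimes, and the static /
# two-state dynamic FRET lines in the E-vs-lifetime plane. A conformational
# exchange that is slow on the fluorescence timescale but fast on the burst
# timescale shifts bursts off the static line toward the dynamic line,
# because the burst-mean lifetime is an intensity-weighted mixture of the
# state lifetimes while E averages occupancy-weighted.

#' Donor lifetime of one burst
#'
#' The apparent donor lifetime in the presence of the acceptor, estimated
#' as the mean microtime of the burst's donor-excitation donor-channel
#' photons minus the mean microtime of the instrument response function.
#' Optionally, the expected background contribution (uniform microtimes at
#' the segment background rate) is removed first; the plain estimator
#' matches the published procedure, the background-corrected one removes
#' its small upward bias at non-negligible background.
#'
#' @param nanotimes_ns Microtimes (ns) of the burst's Dex/D photons.
#' @param irf_mean IRF mean delay (ns).
#' @param min_photons Minimum photon count; below it the burst is excluded
#'   (`NA`).
#' @param bg_photons Expected number of background photons among
#'   `nanotimes_ns` (rate x duration), for the optional correction.
#' @param bg_mean_ns Mean microtime of background photons (window
#'   midpoint), required with `bg_photons`.
#' @return `tau_DA` in ns (may be negative for pathological inputs; such
#'   estimates are reported, not clipped, so they can be flagged).
#' @examples
#' burst_lifetime(c(2, 4, 6), irf_mean = 1)  # 3 ns
#' @export
burst_lifetime <- function(nanotimes_ns, irf_mean, min_photons = 10L,
                           bg_photons = 0, bg_mean_ns = NULL) {
  n <- length(nanotimes_ns)
  if (n < min_photons) return(NA_real_)
  if (bg_photons > 0) {
    if (is.null(bg_mean_ns))
      stop("bg_mean_ns required when bg_photons > 0")
    if (n - bg_photons <= 0) return(NA_real_)
    m <- (sum(nanotimes_ns) - bg_photons * bg_mean_ns) / (n - bg_photons)
  } else {
    m <- mean(nanotimes_ns)
  }
  m - irf_mean
}

#' Donor lifetimes for every burst of a stream
#'
#' @param bursts A `burst_set`.
#' @param stream The parent [photon_stream()].
#' @param irf_mean IRF mean delay (ns).
#' @param min_photons Minimum Dex/D photons per burst.
#' @param bg Optional [estimate_background()]; when given, the expected
#'   background microtime mass is subtracted per burst.
#' @return Data frame per burst: `tau_DA` (ns), `n_photons`, `excluded`,
#'   `negative` (flag for negative estimates).
#' @export
burst_lifetimes <- function(bursts, stream, irf_mean, min_photons = 10L,
                            bg = NULL) {
  stopifnot(inherits(bursts, "burst_set"))
  nts <- photon_nanotimes_ns(stream)
  dd_mask <- stream_mask(stream, "DexD")
  bg_mid <- diff(stream$pie$dex_window) * stream$pie$tcspc_unit_ns / 2
  bg_rate <- if (is.null(bg)) rep(0, nrow(bursts))
             else bg_lookup(bg, bursts$segment, "DexD")
  tau <- numeric(nrow(bursts)); np <- integer(nrow(bursts))
  for (i in seq_len(nrow(bursts))) {
    idx <- bursts$i_first[i]:bursts$i_last[i]
    idx <- idx[dd_mask[idx]]
    np[i] <- length(idx)
    tau[i] <- burst_lifetime(nts[idx], irf_mean, min_photons,
                             bg_photons = bg_rate[i] * bursts$duration[i],
                             bg_mean_ns = bg_mid)
  }
  data.frame(tau_DA = tau, n_photons = np,
             excluded = is.na(tau),
             negative = !is.na(tau) & tau < 0)
}

#' Donor-only reference lifetime
#'
#' Pools the Dex/D microtimes of all bursts whose stoichiometry exceeds
#' `s_threshold` (donor-only molecules carry no acceptor, so their donor
#' decay is unquenched) and applies the mean-microtime estimator.
#'
#' @param bursts A `burst_set`.
#' @param stream The parent [photon_stream()].
#' @param S Corrected stoichiometry per burst (from [burst_metrics()]).
#' @param irf_mean IRF mean delay (ns).
#' @param s_threshold Bursts with `S > s_threshold` are used.
#' @param min_bursts Minimum number of qualifying bursts.
#' @return `tau_D0` in ns.
#' @export
donor_only_lifetime <- function(bursts, stream, S, irf_mean,
                                s_threshold = 0.9, min_bursts = 10L) {
  stopifnot(inherits(bursts, "burst_set"), length(S) == nrow(bursts))
  sel <- which(!is.na(S) & S > s_threshold)
  if (length(sel) < min_bursts)
    stop(sprintf("only %d burst(s) with S > %g (need >= %d)",
                 length(sel), s_threshold, min_bursts))
  nts <- photon_nanotimes_ns(stream)
  dd_mask <- stream_mask(stream, "DexD")
  pooled <- unlist(lapply(sel, function(i) {
    idx <- bursts$i_first[i]:bursts$i_last[i]
    nts[idx[dd_mask[idx]]]
  }))
  mean(pooled) - irf_mean
}

#' Static and two-state dynamic FRET lines
#'
#' The static line is `E(tau) = 1 - tau / tau_D0`: a conformationally
#' static species has a lifetime proportional to `1 - E`. For a molecule
#' exchanging between two states with donor lifetimes `tau1`, `tau2`
#' within a burst, the burst-averaged (intensity-weighted) lifetime and
#' occupancy-averaged E trace the dynamic line
#' `E(tau_bar) = 1 - tau1 * tau2 / (tau_D0 * (tau1 + tau2 - tau_bar))`,
#' which passes through both state points and lies above the static line
#' between them.
#'
#' @param tau_D0 Donor-only lifetime (ns, > 0).
#' @param states Lifetimes `c(tau1, tau2)` of the two states (ns, each in
#'   `(0, tau_D0)`), for the dynamic line; `NULL` for static only.
#' @param n_points Samples per line.
#' @return List with data frames `static` (`tau`, `E` over
#'   `[0, tau_D0]`) and, if `states` is given, `dynamic` (`tau`, `E` over
#'   `[min(states), max(states)]`). Degenerate `tau1 == tau2` collapses the
#'   dynamic line to its single state point (with a warning).
#' @examples
#' fl <- fret_lines(4, states = c(1, 3))
#' fl$dynamic[1, ]  # passes through the state point (1, 0.75)
#' @export
fret_lines <- function(tau_D0, states = NULL, n_points = 200L) {
  stopifnot(tau_D0 > 0)
  tau <- seq(0, tau_D0, length.out = n_points)
  out <- list(static = data.frame(tau = tau, E = 1 - tau / tau_D0))
  if (!is.null(states)) {
    stopifnot(length(states) == 2, all(states > 0), all(states < tau_D0))
    tau1 <- states[1]; tau2 <- states[2]
    if (tau1 == tau2) {
      warning("tau1 == tau2: dynamic line collapses to a point")
      out$dynamic <- data.frame(tau = tau1, E = 1 - tau1 / tau_D0)
    } else {
      tb <- seq(min(states), max(states), length.out = n_points)
      out$dynamic <- data.frame(
        tau = tb,
        E = 1 - (tau1 * tau2) / (tau_D0 * (tau1 + tau2 - tb)))
    }
  }
  out
}

#' Dynamic-line FRET efficiency at given mean lifetimes
#'
#' @param tau_bar Burst-mean donor lifetimes (ns).
#' @param tau_D0 Donor-only lifetime (ns).
#' @param tau1,tau2 State lifetimes (ns).
#' @return `E` on the two-state dynamic line.
#' @export
dynamic_line_E <- function(tau_bar, tau_D0, tau1, tau2) {
  1 - (tau1 * tau2) / (tau_D0 * (tau1 + tau2 - tau_bar))
}
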