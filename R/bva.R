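# Burst variance analysis (BVA): compares the spread of acceptor fractions
# across fixed-size photon windows within a burst to the binomial
# shot-noise expectation. Excess spread means the FRET efficiency changed
# during the burst, i.e. conformational dynamics on the ~ms transit
# timescale. Windows use raw donor-excitation photons of both channels
# (no background subtraction or corrections): the shot-noise null is
# binomial in raw counts.

#' Per-burst BVA standard deviation
#'
#' Segments a burst's donor-excitation photons, in time order, into
#' consecutive non-overlapping windows of `window_n` photons (trailing
#' remainder discarded), computes each window's acceptor fraction, and
#' returns the population standard deviation `s_i` over the windows.
#' Bursts with fewer than two complete windows are excluded (`NA`).
#'
#' @param acceptor Logical (or 0/1) vector: is each Dex photon of the burst
#'   an acceptor-channel photon, in time order.
#' @param window_n Photons per window.
#' @return `s_i`, or `NA_real_` when fewer than 2 windows fit.
#' @examples
#' bva_burst(rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 4))  # identical windows
#' @export
bva_burst <- function(acceptor, window_n = 5L) {
  window_n <- as.integer(window_n)
  stopifnot(window_n >= 2)
  n <- length(acceptor)
  k <- n %/% window_n
  if (k < 2L) return(NA_real_)
  a <- as.integer(acceptor[seq_len(k * window_n)])
  frac <- colMeans(matrix(a, nrow = window_n))
  sqrt(sum((frac - mean(frac))^2) / k)  # population SD
}

#' Expected static-population BVA standard deviation
#'
#' The binomial shot-noise expectation for a conformationally static burst:
#' windows of `window_n` photons drawn at fixed acceptor probability `E`
#' have acceptor-fraction standard deviation `sqrt(E * (1 - E) / window_n)`.
#' This is the solid static line of a BVA plot.
#'
#' @param E FRET efficiency (proximity ratio), in `[0, 1]`.
#' @param window_n Photons per window.
#' @return Expected standard deviation.
#' @examples
#' bva_static_expectation(0.5)  # sqrt(0.05) = 0.2236...
#' @export
bva_static_expectation <- function(E, window_n = 5L) {
  stopifnot(all(E >= 0 & E <= 1), window_n >= 1)
  sqrt(E * (1 - E) / window_n)
}

#' BVA for every burst of a stream
#'
#' @param bursts A `burst_set` from [search_bursts()].
#' @param stream The parent [photon_stream()].
#' @param bg The matching [estimate_background()] (for `E_raw`).
#' @param window_n Photons per BVA window.
#' @return Data frame, one row per burst: `E_raw`, `s_i`, `n_windows`,
#'   `excluded` (too few windows).
#' @export
bva_bursts <- function(bursts, stream, bg, window_n = 5L) {
  stopifnot(inherits(bursts, "burst_set"))
  raw <- raw_es(bursts, bg)
  si <- numeric(nrow(bursts)); nw <- integer(nrow(bursts))
  for (i in seq_len(nrow(bursts))) {
    idx <- burst_dex_indices(stream, bursts[i, ])
    acc <- stream$detectors[idx] == 1L
    si[i] <- bva_burst(acc, window_n)
    nw[i] <- length(acc) %/% window_n
  }
  data.frame(E_raw = raw$E_raw, s_i = si, n_windows = nw,
             excluded = is.na(si))
}

#' Bin per-burst BVA values along the E_raw axis
#'
#' Bins `[0, bin_width), [bin_width, 2*bin_width), ...` partition `[0, 1]`
#' (half-open; E_raw = 1 joins the last bin). Empty bins are emitted with
#' count 0. Alongside each bin's mean `s_i`, the binomial static
#' expectation at the bin centre and the standard error of the mean are
#' reported.
#'
#' @param bva_df A [bva_bursts()] table (excluded bursts are dropped).
#' @param bin_width E_raw bin width; widths that do not divide 1 evenly
#'   truncate the last bin with a warning.
#' @param window_n Window size used for the static expectation column.
#' @return Data frame per bin: `bin_lo`, `bin_centre`, `n_bursts`,
#'   `mean_si`, `se_si`, `static_sd`.
#' @export
bva_bin <- function(bva_df, bin_width = 0.05, window_n = 5L) {
  stopifnot(bin_width > 0, bin_width <= 1)
  n_bins <- ceiling(1 / bin_width - 1e-9)
  if (abs(n_bins * bin_width - 1) > 1e-9)
    warning("bin_width does not divide 1 evenly; last bin truncated")
  d <- bva_df[!bva_df$excluded & !is.na(bva_df$E_raw), , drop = FALSE]
  bin <- pmin(floor(d$E_raw / bin_width), n_bins - 1) + 1L
  lo <- (seq_len(n_bins) - 1) * bin_width
  centre <- pmin(lo + bin_width / 2, (lo + 1) / 2)
  out <- data.frame(bin_lo = lo, bin_centre = centre,
                    n_bursts = 0L, mean_si = NA_real_, se_si = NA_real_,
                    static_sd = bva_static_expectation(centre, window_n))
  if (nrow(d)) {
    cnt <- tabulate(bin, n_bins)
    out$n_bursts <- cnt
    sums <- vapply(seq_len(n_bins), function(b) sum(d$s_i[bin == b]),
                   numeric(1))
    out$mean_si <- ifelse(cnt > 0, sums / cnt, NA_real_)
    out$se_si <- vapply(seq_len(n_bins), function(b) {
      x <- d$s_i[bin == b]
      if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
    }, numeric(1))
  }
  out
}

#' Monte-Carlo null expectation of mean s_i for finite bursts
#'
#' The closed-form static line `sqrt(E(1-E)/n)` is the large-burst limit of
#' the expected `s_i`; for a finite number of windows `K` the population-SD
#' statistic sits slightly below it (the usual small-sample bias of a
#' standard deviation). This oracle computes `E[s_i]` under the binomial
#' null at given window counts by direct simulation, for calibrated
#' static-line comparisons.
#'
#' @param E Acceptor probability.
#' @param n_windows Integer vector of per-burst window counts.
#' @param window_n Photons per window.
#' @param n_rep Monte-Carlo replicates per burst.
#' @return Expected mean `s_i` across bursts with these window counts.
#' @export
bva_null_mean_si <- function(E, n_windows, window_n = 5L, n_rep = 2000L) {
  stopifnot(E >= 0, E <= 1, all(n_windows >= 2))
  per_k <- vapply(sort(unique(n_windows)), function(k) {
    fr <- matrix(stats::rbinom(n_rep * k, window_n, E) / window_n,
                 nrow = k)
    mean(apply(fr, 2, function(x) sqrt(sum((x - mean(x))^2) / k)))
  }, numeric(1))
  names(per_k) <- sort(unique(n_windows))
  mean(per_k[as.character(n_windows)])
}
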