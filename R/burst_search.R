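#' Dual-channel sliding-window burst search
#'
#' Locates single-molecule bursts as periods where the local photon rate
#' exceeds `threshold_factor` times the segment background rate in the
#' donor-excitation donor-channel stream AND in the donor-excitation
#' acceptor-channel stream (the construction that selects doubly labelled
#' molecules under ALEX). The local rate at a photon of a stream is
#' assessed over windows of `window_m` consecutive photons of that stream:
#' the photon is "in burst" if any such window containing it spans less
#' than `window_m / (threshold_factor * rate_bg)`. Maximal flagged runs per
#' stream become time intervals; bursts are the connected components of the
#' intersection of the two streams' interval unions. Candidates with fewer
#' than `min_size` donor-excitation photons are discarded.
#'
#' @param stream A [photon_stream()].
#' @param bg A [estimate_background()] result covering the stream.
#' @param threshold_factor Rate threshold in multiples of background (> 0).
#' @param min_size Minimum `n_DD + n_DA` per burst (raw counts).
#' @param window_m Photons per sliding window.
#' @param edge_trim Refine burst edges by dropping boundary
#'   donor-excitation photons whose gap to the next burst photon exceeds
#'   `1 / (threshold_factor * (rate_DexD + rate_DexA))`. Sliding windows
#'   that straddle a burst boundary recruit a few background photons whose
#'   inter-photon gaps are background-like; trimming them makes the burst
#'   span an unbiased basis for per-burst background expectations
#'   (lifetime correction, BVA nulls). Photons inside a genuine transit
#'   have gaps far below the threshold and are never trimmed.
#' @return Data frame of class `burst_set`, one row per accepted burst:
#'   `i_first`/`i_last` (photon indices into the full stream covering the
#'   burst's time span), `t_start`/`t_stop` (s), `n_DD`, `n_DA`, `n_AA`,
#'   `duration` (s), `segment`.
#' @examples
#' m <- two_state_model(E1 = 0.5, burst_rate = 20, seed = 2)
#' ps <- simulate_photon_stream(m, duration = 5)
#' bg <- estimate_background(ps, segment_s = 5)
#' b <- search_bursts(ps, bg)
#' nrow(b)
#' @export
search_bursts <- function(stream, bg, threshold_factor = 3,
                          min_size = 50L, window_m = 10L,
                          edge_trim = TRUE) {
  stopifnot(inherits(stream, "photon_stream"),
            inherits(bg, "background_estimate"))
  if (threshold_factor <= 0) stop("threshold_factor must be > 0")
  min_size <- as.integer(min_size); window_m <- as.integer(window_m)
  if (min_size < window_m) stop("min_size must be >= window_m")
  segment_s <- attr(bg, "segment_s")
  t <- photon_times_s(stream)

  iv <- lapply(c(DexD = "DexD", DexA = "DexA"), function(s) {
    flagged_intervals(t[stream_mask(stream, s)], bg, s, segment_s,
                      threshold_factor, window_m)
  })
  both <- intersect_intervals(iv$DexD, iv$DexA)
  empty <- data.frame(i_first = integer(0), i_last = integer(0),
                      t_start = numeric(0), t_stop = numeric(0),
                      n_DD = integer(0), n_DA = integer(0),
                      n_AA = integer(0), duration = numeric(0),
                      segment = integer(0))
  class(empty) <- c("burst_set", "data.frame")
  if (nrow(both) == 0) return(empty)

  dex <- which(!is.na(stream$slot) & stream$slot == "Dex")
  td <- t[dex]
  taa <- t[stream_mask(stream, "AexA")]
  # cumulative donor-channel count over the Dex photon sequence
  cs_d <- c(0L, cumsum(stream$detectors[dex] == 0L))

  a <- findInterval(both$lo, td, left.open = TRUE) + 1L  # first Dex >= lo
  b <- findInterval(both$hi, td)                          # last Dex <= hi
  if (edge_trim) {
    seg_of <- function(x) as.integer(floor(x / segment_s)) + 1L
    for (k in seq_along(a)) {
      if (a[k] > b[k]) next
      seg <- seg_of(td[a[k]])
      r_tot <- bg_lookup(bg, seg, "DexD") + bg_lookup(bg, seg, "DexA")
      if (r_tot <= 0) next
      gap_max <- 1 / (threshold_factor * r_tot)
      while (a[k] < b[k] && td[a[k] + 1L] - td[a[k]] > gap_max) a[k] <- a[k] + 1L
      while (b[k] > a[k] && td[b[k]] - td[b[k] - 1L] > gap_max) b[k] <- b[k] - 1L
    }
  }
  n_dex <- pmax(0L, b - a + 1L)
  keep <- n_dex >= min_size
  if (!any(keep)) return(empty)
  a <- a[keep]; b <- b[keep]
  t_start <- td[a]; t_stop <- td[b]
  n_dd <- cs_d[b + 1L] - cs_d[a]
  n_da <- (b - a + 1L) - n_dd
  n_aa <- findInterval(t_stop, taa) -
    findInterval(t_start, taa, left.open = TRUE)
  res <- data.frame(
    i_first = findInterval(t_start, t, left.open = TRUE) + 1L,
    i_last = findInterval(t_stop, t),
    t_start = t_start, t_stop = t_stop,
    n_DD = as.integer(n_dd), n_DA = as.integer(n_da),
    n_AA = as.integer(pmax(0L, n_aa)),
    duration = t_stop - t_start,
    segment = as.integer(floor(t_start / segment_s)) + 1L)
  class(res) <- c("burst_set", "data.frame")
  res
}

# Time intervals where a single photon stream is above threshold.
# Returns data.frame(lo, hi) of maximal flagged runs.
flagged_intervals <- function(ts, bg, stream_name, segment_s,
                              threshold_factor, m) {
  K <- length(ts)
  none <- data.frame(lo = numeric(0), hi = numeric(0))
  if (K < m) return(none)
  # per-photon background rate from its segment
  seg <- as.integer(floor(ts / segment_s)) + 1L
  rate <- bg_lookup(bg, seg, stream_name)
  # window i covers photons i..i+m-1; qualifying iff span < m/(F*rate),
  # with rate 0 meaning any window qualifies
  span <- ts[m:K] - ts[1:(K - m + 1L)]
  rate_w <- rate[1:(K - m + 1L)]  # window keyed by its first photon's segment
  lim <- ifelse(rate_w > 0, m / (threshold_factor * rate_w), Inf)
  ok <- span < lim
  if (!any(ok)) return(none)
  # photon j flagged if any qualifying window covers it
  wi <- which(ok)
  delta <- tabulate(wi, nbins = K + 1L) - tabulate(wi + m, nbins = K + 1L)
  flag <- cumsum(delta[1:K]) > 0L
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  data.frame(lo = ts[starts[runs]], hi = ts[ends[runs]])
}

# Connected components of the intersection of two interval unions.
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(lo = numeric(0), hi = numeric(0)))
  out_lo <- numeric(0); out_hi <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a$lo[i], b$lo[j])
    hi <- min(a$hi[i], b$hi[j])
    if (lo <= hi) { out_lo <- c(out_lo, lo); out_hi <- c(out_hi, hi) }
    if (a$hi[i] < b$hi[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(lo = out_lo, hi = out_hi)
}

# Photon indices (into the full stream) of a burst's Dex photons, in time
# order.
burst_dex_indices <- function(stream, burst_row) {
  idx <- burst_row$i_first:burst_row$i_last
  idx[!is.na(stream$slot[idx]) & stream$slot[idx] == "Dex"]
}
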