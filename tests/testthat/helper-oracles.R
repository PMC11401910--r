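# Independent brute-force reference implementations used as oracles.
# These are deliberately literal (nested loops, no vectorised tricks) so
# they share no code path with the package implementations they check.

# Local (slot, channel) mask; tests only see the exported surface.
stream_mask <- function(x, which) {
  s <- x$slot; d <- x$detectors
  switch(which,
         DexD = !is.na(s) & s == "Dex" & d == 0L,
         DexA = !is.na(s) & s == "Dex" & d == 1L,
         AexA = !is.na(s) & s == "Aex" & d == 1L)
}

# Burst search: same definition as search_bursts, written as plain loops.
brute_force_bursts <- function(stream, bg, threshold_factor = 3,
                               min_size = 50L, window_m = 10L,
                               edge_trim = TRUE) {
  segment_s <- attr(bg, "segment_s")
  t <- photon_times_s(stream)
  sub_times <- function(name) t[stream_mask(stream, name)]

  flag_runs <- function(ts, name) {
    K <- length(ts)
    m <- window_m
    if (K < m) return(list())
    flag <- rep(FALSE, K)
    for (i in seq_len(K - m + 1L)) {
      seg <- floor(ts[i] / segment_s) + 1
      r <- bg$rate[bg$stream == name & bg$segment == seg]
      if (length(r) == 0) r <- 0
      lim <- if (r > 0) m / (threshold_factor * r) else Inf
      if ((ts[i + m - 1L] - ts[i]) < lim)
        flag[i:(i + m - 1L)] <- TRUE
    }
    runs <- list()
    j <- 1L
    while (j <= K) {
      if (flag[j]) {
        k <- j
        while (k < K && flag[k + 1L]) k <- k + 1L
        runs[[length(runs) + 1L]] <- c(ts[j], ts[k])
        j <- k + 1L
      } else j <- j + 1L
    }
    runs
  }

  iv_d <- flag_runs(sub_times("DexD"), "DexD")
  iv_a <- flag_runs(sub_times("DexA"), "DexA")
  # intersection components
  comps <- list()
  for (d in iv_d) for (a in iv_a) {
    lo <- max(d[1], a[1]); hi <- min(d[2], a[2])
    if (lo <= hi) comps[[length(comps) + 1L]] <- c(lo, hi)
  }
  if (length(comps) == 0)
    return(data.frame(t_start = numeric(0), t_stop = numeric(0),
                      n_DD = integer(0), n_DA = integer(0)))
  # merge touching components (sorted; overlap only possible via shared ends)
  comps <- comps[order(vapply(comps, `[`, 1, 1))]
  merged <- list(comps[[1]])
  for (cc in comps[-1]) {
    last <- merged[[length(merged)]]
    if (cc[1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], cc[2]))
    else merged[[length(merged) + 1L]] <- cc
  }
  slot <- stream$slot; det <- stream$detectors
  rows <- list()
  for (cc in merged) {
    dex_t <- c(); dex_d <- c()
    for (i in seq_along(t)) {
      if (!is.na(slot[i]) && slot[i] == "Dex" && t[i] >= cc[1] && t[i] <= cc[2]) {
        dex_t <- c(dex_t, t[i]); dex_d <- c(dex_d, det[i])
      }
    }
    if (length(dex_t) == 0) next
    if (edge_trim) {
      seg <- floor(dex_t[1] / segment_s) + 1
      r_tot <- sum(bg$rate[bg$segment == seg & bg$stream %in% c("DexD", "DexA")])
      if (r_tot > 0) {
        gap_max <- 1 / (threshold_factor * r_tot)
        while (length(dex_t) > 1 && dex_t[2] - dex_t[1] > gap_max) {
          dex_t <- dex_t[-1]; dex_d <- dex_d[-1]
        }
        nn <- length(dex_t)
        while (nn > 1 && dex_t[nn] - dex_t[nn - 1] > gap_max) {
          dex_t <- dex_t[-nn]; dex_d <- dex_d[-nn]; nn <- nn - 1
        }
      }
    }
    n_dd <- sum(dex_d == 0L); n_da <- sum(dex_d == 1L)
    if (n_dd + n_da >= min_size)
      rows[[length(rows) + 1L]] <- data.frame(
        t_start = dex_t[1], t_stop = dex_t[length(dex_t)],
        n_DD = n_dd, n_DA = n_da)
  }
  if (length(rows) == 0)
    return(data.frame(t_start = numeric(0), t_stop = numeric(0),
                      n_DD = integer(0), n_DA = integer(0)))
  do.call(rbind, rows)
}

# ALEX-2CDE: literal double loop over photon pairs.
brute_force_alex2cde <- function(td, ta, tau) {
  nd <- length(td); na <- length(ta)
  if (nd == 0 || na == 0) return(100)
  kde_one <- function(t0, from) {
    s <- 0
    for (x in from) s <- s + exp(-abs(t0 - x) / tau)
    s
  }
  br_da <- 0
  for (t0 in ta) br_da <- br_da + kde_one(t0, td) / kde_one(t0, ta)
  br_ad <- 0
  for (t0 in td) br_ad <- br_ad + kde_one(t0, ta) / kde_one(t0, td)
  100 - 50 * (br_da / nd + br_ad / na)
}

# BVA: literal window scan.
brute_force_bva <- function(acceptor, window_n = 5L) {
  k <- length(acceptor) %/% window_n
  if (k < 2) return(NA_real_)
  fr <- numeric(k)
  for (w in seq_len(k)) {
    idx <- ((w - 1L) * window_n + 1L):(w * window_n)
    fr[w] <- sum(acceptor[idx]) / window_n
  }
  sqrt(mean((fr - mean(fr))^2))
}

# Contamination-aware BVA null: expected mean s_i for pipeline bursts that
# carry a few background photons at their edges. Each replicate draws, per
# burst, n_sig signal photons (acceptor prob E) flanked by b background
# photons (acceptor prob p_bg, split between the two ends), split into
# consecutive 5-photon windows. b uses the boundary-conditioned (Palm)
# expectation rate*duration + 2, since burst spans are delimited by photons.
bva_null_contaminated <- function(E, p_bg, n_dex, b, window_n = 5L,
                                  n_rep = 200L) {
  stopifnot(length(n_dex) == length(b))
  means <- vapply(seq_along(n_dex), function(i) {
    n <- n_dex[i]
    bl <- round(b[i] / 2); br <- round(b[i]) - bl
    ns <- max(0L, n - bl - br)
    si <- vapply(seq_len(n_rep), function(r) {
      x <- c(stats::rbinom(bl, 1, p_bg),
             stats::rbinom(ns, 1, E),
             stats::rbinom(br, 1, p_bg))
      k <- length(x) %/% window_n
      if (k < 2) return(NA_real_)
      fr <- colMeans(matrix(x[seq_len(k * window_n)], nrow = window_n))
      sqrt(sum((fr - mean(fr))^2) / k)
    }, numeric(1))
    mean(si, na.rm = TRUE)
  }, numeric(1))
  mean(means)
}

# A hand-built photon stream: explicit photon times (s) per substream.
make_stream <- function(dexd = numeric(0), dexa = numeric(0),
                        aexa = numeric(0), duration = NULL,
                        clock = 1e8, pie = pie_scheme()) {
  t <- c(dexd, dexa, aexa)
  det <- c(rep(0L, length(dexd)), rep(1L, length(dexa)),
           rep(1L, length(aexa)))
  # nanotimes: mid-Dex-window for Dex photons, mid-Aex for Aex photons
  dex_mid <- as.integer(mean(pie$dex_window))
  aex_mid <- as.integer(mean(pie$aex_window))
  nt <- c(rep(dex_mid, length(dexd) + length(dexa)),
          rep(aex_mid, length(aexa)))
  o <- order(t)
  photon_stream(timestamps = round(t[o] * clock), nanotimes = nt[o],
                detectors = det[o], clock_rate_hz = clock, pie = pie,
                duration_s = duration)
}

# Uniform background estimate for hand-built streams (single segment).
flat_background <- function(rates = c(DexD = 0, DexA = 0, AexA = 0),
                            duration = 1, segment_s = duration) {
  df <- data.frame(segment = 1L, t_start = 0, t_stop = duration,
                   stream = c("DexD", "DexA", "AexA"),
                   rate = unname(rates[c("DexD", "DexA", "AexA")]),
                   n_photons = NA_integer_, stringsAsFactors = FALSE)
  class(df) <- c("background_estimate", "data.frame")
  attr(df, "segment_s") <- segment_s
  df
}

# Minimal valid peak-table row(s).
make_peaks <- function(residue, intensity, noise_floor = 0.05,
                       wH = 0.8, wC = 12, domain = "core-N",
                       type = "Ile-d1", flags = "") {
  n <- length(residue)
  data.frame(residue = residue,
             residue_type = rep_len(type, n),
             wH_ppm = rep_len(wH, n), wC_ppm = rep_len(wC, n),
             intensity = intensity,
             noise_floor = rep_len(noise_floor, n),
             domain = rep_len(domain, n),
             flags = rep_len(flags, n), stringsAsFactors = FALSE)
}

# Random fuzzed stream for property tests: Poisson background plus a few
# rectangular bursts with random rates.
fuzz_stream <- function(seed, duration = 0.5) {
  set.seed(seed)
  pie <- pie_scheme()
  bg_d <- stats::runif(1, 200, 2000)
  bg_a <- stats::runif(1, 200, 2000)
  dexd <- sort(stats::runif(stats::rpois(1, bg_d * duration), 0, duration))
  dexa <- sort(stats::runif(stats::rpois(1, bg_a * duration), 0, duration))
  aexa <- sort(stats::runif(stats::rpois(1, 500 * duration), 0, duration))
  n_b <- sample(0:4, 1)
  for (b in seq_len(n_b)) {
    t0 <- stats::runif(1, 0, duration * 0.9)
    len <- stats::runif(1, 5e-4, 3e-3)
    rate <- stats::runif(1, 2e4, 1e5)
    e <- stats::runif(1, 0.2, 0.8)
    nb <- stats::rpois(1, rate * len)
    tb <- t0 + sort(stats::runif(nb, 0, len))
    is_a <- stats::runif(nb) < e
    dexd <- c(dexd, tb[!is_a]); dexa <- c(dexa, tb[is_a])
  }
  make_stream(sort(dexd), sort(dexa), aexa, duration = duration, pie = pie)
}
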