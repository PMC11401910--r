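# Photon-stream Monte Carlo under PIE excitation with two-state FRET
# interconversion. Crosstalk composition, in order: FRET branching, donor
# leakage as extra A-channel detections at probability lk per detected D
# photon, independent direct-excitation A photons during Dex, gamma as a
# detection-efficiency thinning of one channel, beta as the Dex/Aex
# excitation-rate ratio. With this composition the consensus correction
# formulas are exactly invertible in expectation.

#' Simulate a PIE photon stream
#'
#' Samples time-stamped photon records (macrotime, microtime, channel) from
#' a [two_state_model()]: bursty fluorescence from single-molecule transits
#' atop homogeneous Poisson background, with two-state FRET interconversion
#' sampled as a continuous-time Markov chain within each transit. Dex/D
#' microtimes are exponential with mean `tau_D0 * (1 - E_state)` plus the
#' IRF offset, so the mean-microtime lifetime estimator is consistent by
#' construction.
#'
#' @param model A [two_state_model()]; its `seed` keys the single RNG
#'   stream, so identical models and durations give bit-identical output.
#' @param duration Acquisition duration in seconds (> 0).
#' @return A [photon_stream()] sorted by macrotime. Attribute `"truth"`
#'   holds the ground-truth transit table (start, duration, donor-excitation
#'   photon count, time fraction spent in state 1) and the model.
#' @examples
#' m <- two_state_model(E1 = 0.5, burst_rate = 20, seed = 3)
#' ps <- simulate_photon_stream(m, duration = 2)
#' @export
simulate_photon_stream <- function(model, duration) {
  stopifnot(inherits(model, "two_state_model"))
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a positive number of seconds")
  pie <- model$pie
  dex_span_ns <- diff(pie$dex_window) * pie$tcspc_unit_ns
  aex_span_ns <- diff(pie$aex_window) * pie$tcspc_unit_ns
  if (model$irf_mean >= min(dex_span_ns, aex_span_ns))
    stop("irf_mean exceeds the PIE window span")
  set.seed(model$seed)

  co <- model$corrections
  # detection efficiencies realising gamma as a channel thinning
  c_D <- if (co$gamma >= 1) 1 / co$gamma else 1
  c_A <- if (co$gamma >= 1) 1 else co$gamma
  # Aex acceptor rate fixing S_true through beta
  lambda_AA <- co$beta * model$peak_rate * (1 - model$S_true) / model$S_true

  t_list <- list(); nt_list <- list(); det_list <- list()
  add <- function(times_s, nanobins, channel) {
    k <- length(times_s)
    if (k == 0) return(invisible())
    i <- length(t_list) + 1L
    t_list[[i]] <<- times_s
    nt_list[[i]] <<- nanobins
    det_list[[i]] <<- rep.int(channel, k)
    invisible()
  }

  # --- background: homogeneous Poisson per analysed stream
  bg <- model$bg_rates
  bg_window <- list(DexD = pie$dex_window, DexA = pie$dex_window,
                    AexA = pie$aex_window)
  bg_channel <- c(DexD = 0L, DexA = 1L, AexA = 1L)
  for (s in names(bg_channel)) {
    n <- stats::rpois(1, bg[[s]] * duration)
    if (n > 0) {
      w <- bg_window[[s]]
      add(stats::runif(n, 0, duration),
          as.integer(floor(stats::runif(n, w[1], w[2]))),
          bg_channel[[s]])
    }
  }

  # --- transits (one molecule at a time: overlapping transits dropped)
  n_tr <- stats::rpois(1, model$burst_rate * duration)
  truth <- NULL
  if (n_tr > 0) {
    starts <- sort(stats::runif(n_tr, 0, duration))
    durs <- stats::rexp(n_tr, 1 / model$transit_mean)
    keep <- logical(n_tr)
    t_end <- -Inf
    for (i in seq_len(n_tr)) {
      if (starts[i] >= t_end) {
        keep[i] <- TRUE
        t_end <- starts[i] + durs[i]
      }
    }
    starts <- starts[keep]
    durs <- pmin(durs[keep], duration - starts)
    ok <- durs > 0
    starts <- starts[ok]; durs <- durs[ok]
    truth <- data.frame(start = starts, duration = durs,
                        n_dex_events = 0L, occ1 = NA_real_)
    for (i in seq_along(starts)) {
      tr <- sim_transit(model, starts[i], durs[i], lambda_AA, c_D, c_A,
                        dex_span_ns, aex_span_ns)
      truth$n_dex_events[i] <- tr$n_dex_events
      truth$occ1[i] <- tr$occ1
      add(tr$t_D, tr$nt_D, 0L)
      add(tr$t_A, tr$nt_A, 1L)
    }
  }

  times <- unlist(t_list, use.names = FALSE)
  if (is.null(times)) times <- numeric(0)
  nts <- unlist(nt_list, use.names = FALSE)
  dets <- unlist(det_list, use.names = FALSE)
  o <- order(times)
  ps <- photon_stream(
    timestamps = round(times[o] * model$clock_rate_hz),
    nanotimes = if (length(o)) nts[o] else integer(0),
    detectors = if (length(o)) dets[o] else integer(0),
    clock_rate_hz = model$clock_rate_hz,
    pie = pie,
    duration_s = duration,
    meta = list(origin = "smfretr::simulate_photon_stream", seed = model$seed))
  attr(ps, "truth") <- list(model = model, transits = truth)
  ps
}

# One rectangular-rate transit: returns donor-channel and acceptor-channel
# photon times (s) and nanotime bins, plus ground truth.
sim_transit <- function(model, t0, dur, lambda_AA, c_D, c_A,
                        dex_span_ns, aex_span_ns) {
  pie <- model$pie
  co <- model$corrections
  unit <- pie$tcspc_unit_ns

  traj <- sim_state_trajectory(model, dur)

  state_at <- function(tt) {
    # tt relative to transit start
    if (length(traj$jumps) == 0) rep.int(traj$states[1], length(tt))
    else traj$states[findInterval(tt, c(0, traj$jumps)) ]
  }
  tau_state <- function(st)
    model$tau_D0 * (1 - ifelse(st == 1L, model$E1, model$E2))

  t_D <- numeric(0); nt_D <- integer(0)
  t_A <- numeric(0); nt_A <- integer(0)

  # donor-excitation fluorescence events
  n_dex <- stats::rpois(1, model$peak_rate * dur)
  if (n_dex > 0) {
    tt <- stats::runif(n_dex, 0, dur)
    st <- state_at(tt)
    E <- ifelse(st == 1L, model$E1, model$E2)
    is_fret <- stats::runif(n_dex) < E
    tau <- tau_state(st)

    # FRET photons -> A channel, thinned by c_A; microtime = donor dwell +
    # acceptor decay + IRF
    fr <- which(is_fret & stats::runif(n_dex) < c_A)
    if (length(fr)) {
      mt <- trunc_exp_sum(length(fr), tau[fr], model$tau_A, model$irf_mean,
                          dex_span_ns)
      t_A <- c(t_A, t0 + tt[fr])
      nt_A <- c(nt_A, as.integer(floor(mt / unit)))
    }

    # donor-emitted photons detected in D, thinned by c_D
    dn <- which(!is_fret & stats::runif(n_dex) < c_D)
    if (length(dn)) {
      mt <- trunc_exp_sum(length(dn), tau[dn], 0, model$irf_mean, dex_span_ns)
      t_D <- c(t_D, t0 + tt[dn])
      nt_D <- c(nt_D, as.integer(floor(mt / unit)))

      # leakage: each detected D photon spawns an extra A-channel photon
      # with probability lk (donor decay law, independent time in transit)
      nl <- stats::rbinom(1, length(dn), min(co$lk, 1))
      if (nl > 0) {
        tl <- stats::runif(nl, 0, dur)
        taul <- tau_state(state_at(tl))
        mt <- trunc_exp_sum(nl, taul, 0, model$irf_mean, dex_span_ns)
        t_A <- c(t_A, t0 + tl)
        nt_A <- c(nt_A, as.integer(floor(mt / unit)))
      }
    }
  }

  # direct excitation of the acceptor during Dex
  n_dir <- stats::rpois(1, co$dir * lambda_AA * dur)
  if (n_dir > 0) {
    mt <- trunc_exp_sum(n_dir, rep.int(model$tau_A, n_dir), 0,
                        model$irf_mean, dex_span_ns)
    t_A <- c(t_A, t0 + stats::runif(n_dir, 0, dur))
    nt_A <- c(nt_A, as.integer(floor(mt / unit)))
  }

  # Aex acceptor photons
  n_aa <- stats::rpois(1, lambda_AA * dur)
  if (n_aa > 0) {
    mt <- trunc_exp_sum(n_aa, rep.int(model$tau_A, n_aa), 0,
                        model$irf_mean, aex_span_ns)
    t_A <- c(t_A, t0 + stats::runif(n_aa, 0, dur))
    nt_A <- c(nt_A, pie$aex_window[1] + as.integer(floor(mt / unit)))
  }

  list(t_D = t_D, nt_D = nt_D, t_A = t_A, nt_A = nt_A,
       n_dex_events = n_dex, occ1 = traj$occ1)
}

# Continuous-time two-state Markov trajectory over [0, dur].
# Returns jump times, the state on each inter-jump interval, and the time
# fraction spent in state 1.
sim_state_trajectory <- function(model, dur) {
  k12 <- model$k12; k21 <- model$k21
  if (k12 == 0 && k21 == 0)
    return(list(jumps = numeric(0), states = 1L, occ1 = 1))
  p1 <- if (k12 + k21 > 0) k21 / (k12 + k21) else 1
  s0 <- if (stats::runif(1) < p1) 1L else 2L
  # absorbing edge cases
  if ((s0 == 1L && k12 == 0) || (s0 == 2L && k21 == 0))
    return(list(jumps = numeric(0), states = s0,
                occ1 = if (s0 == 1L) 1 else 0))
  jumps <- numeric(0)
  t <- 0; s <- s0
  repeat {
    # draw dwells in blocks for speed; states alternate from s
    n_blk <- max(16L, ceiling((dur - t) * (k12 + k21)))
    st_seq <- if (s == 1L) rep_len(c(1L, 2L), n_blk) else rep_len(c(2L, 1L), n_blk)
    dw <- stats::rexp(n_blk, ifelse(st_seq == 1L, k12, k21))
    ct <- t + cumsum(dw)
    over <- ct >= dur
    if (any(over)) {
      j <- which(over)[1]
      if (j > 1) jumps <- c(jumps, ct[seq_len(j - 1)])
      break
    }
    jumps <- c(jumps, ct)
    t <- ct[n_blk]
    s <- if (st_seq[n_blk] == 1L) 2L else 1L
  }
  # reconstruct full state sequence over intervals [0,j1),[j1,j2),...,[jk,dur)
  n_int <- length(jumps) + 1L
  states <- integer(n_int)
  states[1] <- s0
  if (n_int > 1)
    for (i in 2:n_int) states[i] <- if (states[i - 1] == 1L) 2L else 1L
  bounds <- c(0, jumps, dur)
  lens <- diff(bounds)
  occ1 <- sum(lens[states == 1L]) / dur
  list(jumps = jumps, states = states, occ1 = occ1)
}

# n microtimes (ns): irf offset + Exp(tau1_i) [+ Exp(tau2) if tau2 > 0],
# rejection-resampled to stay inside the window span.
trunc_exp_sum <- function(n, tau1, tau2, irf, span_ns) {
  if (n == 0) return(numeric(0))
  mt <- irf + stats::rexp(n, 1 / tau1) +
    (if (tau2 > 0) stats::rexp(n, 1 / tau2) else 0)
  bad <- which(mt >= span_ns)
  guard <- 0L
  while (length(bad) > 0 && guard < 1000L) {
    mt[bad] <- irf + stats::rexp(length(bad), 1 / tau1[bad]) +
      (if (tau2 > 0) stats::rexp(length(bad), 1 / tau2) else 0)
    bad <- bad[mt[bad] >= span_ns]
    guard <- guard + 1L
  }
  if (length(bad)) mt[bad] <- span_ns * (1 - 1e-9)  # pathological tau only
  mt
}
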