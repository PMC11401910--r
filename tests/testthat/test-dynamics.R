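# BVA shot-noise statistics and lifetime / FRET-line analysis.

test_that("bva_burst matches closed forms and the brute-force window scan", {
  # identical windows -> zero spread
  expect_equal(bva_burst(rep(c(TRUE, TRUE, FALSE, FALSE, FALSE), 4)), 0)
  # two windows with acceptor fractions 0.2 and 0.6 -> population SD 0.2
  acc <- c(c(1, 0, 0, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(bva_burst(acc), 0.2)
  # trailing remainder photons are discarded
  expect_equal(bva_burst(c(acc, 1, 1)), 0.2)
  # fewer than two windows -> excluded
  expect_true(is.na(bva_burst(rep(TRUE, 9))))
  # brute-force equivalence on random bursts
  set.seed(17)
  for (rep in 1:20) {
    a <- runif(sample(10:400, 1)) < runif(1)
    expect_equal(bva_burst(a), brute_force_bva(a), tolerance = 1e-14)
  }
})

test_that("the static expectation is the binomial closed form", {
  expect_equal(bva_static_expectation(0), 0)
  expect_equal(bva_static_expectation(0.5, 5), sqrt(0.05))
  expect_equal(bva_static_expectation(0.2, 5), sqrt(0.16 / 5))
  expect_equal(bva_static_expectation(0.5, 5), 0.22360679, tolerance = 1e-7)
})

test_that("bva_bin uses half-open bins and arithmetic bin means", {
  d <- data.frame(E_raw = c(0.12, 0.12, 0.12), s_i = c(0.1, 0.2, 0.3),
                  n_windows = 5L, excluded = FALSE)
  b <- bva_bin(d, bin_width = 0.05)
  expect_equal(nrow(b), 20)
  row <- b[b$bin_lo == 0.10, ]
  expect_equal(row$n_bursts, 3L)
  expect_equal(row$mean_si, 0.2)
  expect_equal(b$n_bursts[4], 0L)  # [0.15, 0.20) empty
  # E_raw = 1 joins the last bin rather than falling off the edge
  d2 <- data.frame(E_raw = 1, s_i = 0.1, n_windows = 5L, excluded = FALSE)
  expect_equal(bva_bin(d2)$n_bursts[20], 1L)
})

test_that("static bursts sit on the shot-noise line; ms two-state bursts exceed it", {
  # static control at E = 0.5
  m_st <- two_state_model(E1 = 0.5, corrections = neutral_corrections(),
                          burst_rate = 20, peak_rate = 2e5, seed = 23)
  ps <- simulate_photon_stream(m_st, 25)
  res <- burst_pipeline(ps, run_config(bg_segment_s = 25,
                                       corrections = neutral_corrections()))
  acc <- res$accepted; class(acc) <- c("burst_set", "data.frame")
  bv <- bva_bursts(acc, ps, res$background)
  bv_ok <- bv[!bv$excluded, ]
  expect_gt(nrow(bv_ok), 150)
  # compare to the finite-size binomial null for the same statistic
  null_mean <- bva_null_mean_si(0.5, bv_ok$n_windows)
  se <- sd(bv_ok$s_i) / sqrt(nrow(bv_ok))
  expect_lt(abs(mean(bv_ok$s_i) - null_mean), 3 * se)
  # and within 0.01 of the asymptotic closed-form line
  expect_lt(abs(mean(bv_ok$s_i) - bva_static_expectation(0.5)), 0.01)

  # two-state exchange with dwell ~ transit time: excess variance at
  # intermediate E_raw
  m_dyn <- two_state_model(E1 = 0.2, E2 = 0.8, k12 = 1000, k21 = 1000,
                           corrections = neutral_corrections(),
                           burst_rate = 20, peak_rate = 2e5, seed = 24)
  ps2 <- simulate_photon_stream(m_dyn, 25)
  res2 <- burst_pipeline(ps2, run_config(bg_segment_s = 25,
                                         corrections = neutral_corrections()))
  acc2 <- res2$accepted; class(acc2) <- c("burst_set", "data.frame")
  bv2 <- bva_bursts(acc2, ps2, res2$background)
  mid <- bv2[!bv2$excluded & bv2$E_raw >= 0.35 & bv2$E_raw <= 0.65, ]
  expect_gt(nrow(mid), 20)
  excess <- mean(mid$s_i) - bva_static_expectation(0.5)
  se2 <- sd(mid$s_i) / sqrt(nrow(mid))
  expect_gt(excess, 3 * se2)
})

test_that("burst lifetimes follow the mean-microtime rule", {
  expect_equal(burst_lifetime(c(2, 4, 6), irf_mean = 1, min_photons = 3), 3)
  expect_true(is.na(burst_lifetime(c(2, 4), irf_mean = 1, min_photons = 10)))
  # background correction removes the expected uniform-background mass
  nts <- c(rep(2, 90), rep(10, 10))  # 10 background photons at mean 10 ns
  plain <- burst_lifetime(nts, irf_mean = 0)
  corr <- burst_lifetime(nts, irf_mean = 0, bg_photons = 10, bg_mean_ns = 10)
  expect_gt(plain, 2)
  expect_equal(corr, 2)
})

test_that("simulated burst lifetimes recover tau_D0 * (1 - E)", {
  # bright-burst regime: the mean-microtime estimator assumes the in-burst
  # signal rate dominates the background (leakage gives E = 0 molecules
  # their Dex/A stream, as in the instrument)
  for (E in c(0, 0.75)) {
    m <- two_state_model(E1 = E, corrections = correction_set(),
                         tau_D0 = 4, irf_mean = 2, burst_rate = 20,
                         peak_rate = 5e5, seed = 300 + E * 4)
    ps <- simulate_photon_stream(m, 20)
    res <- burst_pipeline(ps, run_config(bg_segment_s = 20))
    acc <- res$accepted; class(acc) <- c("burst_set", "data.frame")
    lt <- burst_lifetimes(acc, ps, irf_mean = 2, min_photons = 50L,
                          bg = res$background)
    ok <- !lt$excluded
    expect_gt(sum(ok), 100)
    # photon-weighted mean: per-burst estimates from few photons are noisy
    # and skewed, but contribute in proportion to their evidence
    tau_bar <- weighted.mean(lt$tau_DA[ok], lt$n_photons[ok])
    expect_lt(abs(tau_bar - 4 * (1 - E)), 0.1)
  }
})

test_that("donor-only lifetime pools only high-S bursts", {
  m <- two_state_model(E1 = 0, S_true = 0.97, tau_D0 = 4, irf_mean = 2,
                       corrections = correction_set(), burst_rate = 20,
                       peak_rate = 5e5, seed = 31)
  ps <- simulate_photon_stream(m, 20)
  bg <- estimate_background(ps, segment_s = 20)
  bursts <- search_bursts(ps, bg)
  mets <- burst_metrics(bursts, ps, bg, run_config(bg_segment_s = 20))
  tau0 <- donor_only_lifetime(bursts, ps, mets$S, irf_mean = 2,
                              s_threshold = 0.9)
  expect_lt(abs(tau0 - 4), 0.15)
  expect_error(donor_only_lifetime(bursts, ps, mets$S, irf_mean = 2,
                                   s_threshold = 1.1), "S > 1.1")
})

test_that("FRET lines pass through their anchor points", {
  fl <- fret_lines(4, states = c(1, 3))
  # static line endpoints
  expect_equal(fl$static$E[fl$static$tau == 0], 1)
  expect_equal(fl$static$E[fl$static$tau == 4], 0)
  # dynamic line passes through both state points exactly
  expect_equal(dynamic_line_E(1, 4, 1, 3), 1 - 1 / 4, tolerance = 1e-12)
  expect_equal(dynamic_line_E(3, 4, 1, 3), 1 - 3 / 4, tolerance = 1e-12)
  # mid-curve value: tau_bar = 2 -> E = 1 - 3/8, above the static 0.5
  expect_equal(dynamic_line_E(2, 4, 1, 3), 0.625, tolerance = 1e-12)
  # degenerate states collapse with a warning
  expect_warning(fret_lines(4, states = c(2, 2)), "collapses")
})

test_that("two-state bursts shift toward the dynamic line", {
  tau_D0 <- 4; irf <- 2
  m <- two_state_model(E1 = 0.2, E2 = 0.8, k12 = 1000, k21 = 1000,
                       tau_D0 = tau_D0, irf_mean = irf,
                       corrections = neutral_corrections(),
                       burst_rate = 20, peak_rate = 2e5, seed = 41)
  ps <- simulate_photon_stream(m, 25)
  res <- burst_pipeline(ps, run_config(bg_segment_s = 25,
                                       corrections = neutral_corrections()))
  acc <- res$accepted; class(acc) <- c("burst_set", "data.frame")
  lt <- burst_lifetimes(acc, ps, irf_mean = irf, bg = res$background)
  ok <- !lt$excluded & !is.na(acc$E)
  # signed horizontal displacement from the static line, normalised
  d <- lt$tau_DA[ok] / tau_D0 - (1 - acc$E[ok])
  tt <- t.test(d, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_gt(mean(d), 0.02)
})
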