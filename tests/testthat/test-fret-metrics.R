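# Raw/corrected (E, S), ALEX-2CDE scoring and burst filtering.

# a burst_set row with given counts/duration, for arithmetic checks
fake_bursts <- function(n_DD, n_DA, n_AA, duration = 0.01, segment = 1L) {
  df <- data.frame(i_first = 1L, i_last = n_DD + n_DA + n_AA,
                   t_start = 0, t_stop = duration,
                   n_DD = n_DD, n_DA = n_DA, n_AA = n_AA,
                   duration = duration, segment = segment)
  class(df) <- c("burst_set", "data.frame")
  df
}

test_that("raw E and S reproduce the count arithmetic", {
  bg0 <- flat_background(duration = 1)
  r <- raw_es(fake_bursts(50, 0, 10), bg0)
  expect_equal(r$E_raw, 0)
  r <- raw_es(fake_bursts(25, 25, 50), bg0)
  expect_equal(r$E_raw, 0.5)
  expect_equal(r$S_raw, 0.5)
  # background-subtracted: F_DD = 60-10 = 50, F_DA = 40-10 = 30
  bg <- flat_background(c(DexD = 1000, DexA = 1000, AexA = 1000),
                        duration = 1)
  r <- raw_es(fake_bursts(60, 40, 20, duration = 0.01), bg)
  expect_equal(r$E_raw, 30 / 80)
  # zero Dex signal after subtraction is flagged, not crashed
  r <- raw_es(fake_bursts(5, 5, 20, duration = 0.01), bg)
  expect_true(r$undefined)
  expect_true(is.na(r$E_raw))
})

test_that("corrected E and S follow the consensus correction chain", {
  bg0 <- flat_background(duration = 1)
  b <- fake_bursts(100, 64, 100)
  ce <- corrected_es(b, bg0, correction_set(0.14, 0.14, 1.0, 1.4))
  fda_p <- 64 - 14 - 14
  expect_equal(ce$E, fda_p / (fda_p + 100))
  expect_equal(ce$S, (fda_p + 100) / (fda_p + 100 + 100 / 1.4))
  expect_equal(round(ce$E, 4), 0.2647)
  expect_equal(round(ce$S, 4), 0.6556)
  # neutral corrections reproduce raw values to machine precision
  r <- raw_es(b, bg0)
  ce0 <- corrected_es(b, bg0, neutral_corrections())
  expect_equal(ce0$E, r$E_raw, tolerance = 1e-15)
  expect_equal(ce0$S, r$S_raw, tolerance = 1e-15)
})

test_that("corrected E decreases monotonically in lk and dir", {
  bg0 <- flat_background(duration = 1)
  b <- fake_bursts(100, 64, 100)
  e_of <- function(lk, dir) corrected_es(b, bg0, correction_set(lk, dir, 1, 1.4))$E
  lks <- seq(0, 0.3, by = 0.05)
  expect_true(all(diff(vapply(lks, e_of, numeric(1), dir = 0.1)) < 0))
  expect_true(all(diff(vapply(lks, function(d) e_of(0.1, d), numeric(1))) < 0))
})

test_that("gamma-corrected E of a simulated population is unbiased for E_true", {
  m <- two_state_model(E1 = 0.45, corrections = correction_set(0.14, 0.14, 1.0, 1.4),
                       burst_rate = 20, seed = 77)
  ps <- simulate_photon_stream(m, duration = 30)
  res <- burst_pipeline(ps, run_config(bg_segment_s = 30))
  e <- res$accepted$E
  expect_gt(length(e), 200)
  se <- sd(e) / sqrt(length(e))
  # per-burst ratio estimators carry a small finite-size bias; 3 SE + 0.01
  expect_lt(abs(mean(e) - 0.45), 3 * se + 0.01)
})

test_that("ALEX-2CDE matches the brute-force kernel-density oracle", {
  set.seed(91)
  for (rep in 1:5) {
    td <- sort(runif(40, 0, 2e-3))
    ta <- sort(runif(30, 0, 2e-3))
    tau <- 100e-6
    got <- smfretr:::alex_2cde_one(td, ta, tau)
    ref <- brute_force_alex2cde(td, ta, tau)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("ALEX-2CDE separates well-mixed from segregated bursts", {
  # strictly alternating equal-rate Dex/Aex photons: well mixed, low score
  n <- 100
  td <- (1:n) * 2e-5
  ta <- (1:n) * 2e-5 + 1e-5
  tau <- 100e-6
  mixed <- smfretr:::alex_2cde_one(td, ta, tau)
  expect_lt(mixed, 50)
  # all Aex photons precede all Dex photons (acceptor-bleach surrogate)
  ta2 <- (1:n) * 2e-5
  td2 <- 0.01 + (1:n) * 2e-5
  segregated <- smfretr:::alex_2cde_one(td2, ta2, tau)
  expect_gt(segregated, 95)
  # invariance under global time translation
  shifted <- smfretr:::alex_2cde_one(td + 5, ta + 5, tau)
  expect_equal(mixed, shifted, tolerance = 1e-9)
  # zero Aex photons: maximal score
  expect_equal(smfretr:::alex_2cde_one(td, numeric(0), tau), 100)
})

test_that("burst filters apply inclusive bounds with reason codes", {
  mt <- data.frame(S_raw = c(0.5, 0.5, 0.5, 0.5), S = c(0.5, 0.71, 0.29, 0.5),
                   alex2cde = c(95, 10, 10, 96), undefined = FALSE)
  f <- filter_bursts(mt, s_min = 0.3, s_max = 0.7, cde_max = 95)
  expect_equal(f$passed, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$reason, c("", "S_range", "S_range", "alex2cde"))
  expect_error(filter_bursts(mt, s_min = 0.7, s_max = 0.3), "s_min")
  # filter composition is order-independent: joint filter equals
  # S-filter-then-CDE-filter
  f1 <- filter_bursts(mt, cde_max = 95)
  f2 <- filter_bursts(f1[f1$reason != "S_range", ], cde_max = 95)
  expect_equal(sum(f1$passed), sum(f2$passed))
})

test_that("a donor-only population is rejected by the S filter", {
  # donor-only: no acceptor -> E 0, S_true ~ 1 (tiny Aex signal)
  m <- two_state_model(E1 = 0, S_true = 0.97,
                       corrections = correction_set(),
                       burst_rate = 20, seed = 13)
  ps <- simulate_photon_stream(m, duration = 20)
  res <- burst_pipeline(ps, run_config(bg_segment_s = 20))
  expect_gt(nrow(res$metrics), 100)
  expect_gte(mean(!res$metrics$passed), 0.99)
  expect_gt(mean(res$metrics$S, na.rm = TRUE), 0.9)
})
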