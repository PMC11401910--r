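# Intensity ratios, CSPs, Z-scores, broadened-peak handling and the
# perturbation map.

test_that("intensity ratios and both error-propagation modes are exact", {
  r <- intensity_ratio(100, 100, 0, 0)
  expect_equal(r$R, 1); expect_equal(r$dR, 0)
  # as-printed form: dR = |R| sqrt(dX/X) + sqrt(dY/Y)
  r <- intensity_ratio(100, 50, 10, 5)
  expect_equal(r$R, 0.5, tolerance = 1e-12)
  expect_equal(r$dR, 0.5 * sqrt(0.1) + sqrt(0.1), tolerance = 1e-12)
  expect_equal(r$dR, 0.47434, tolerance = 1e-5)
  # standard quadrature form for cross-checking
  rq <- intensity_ratio(100, 50, 10, 5, mode = "quadrature")
  expect_equal(rq$dR, 0.5 * sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_equal(rq$dR, 0.07071, tolerance = 1e-5)
  expect_error(intensity_ratio(0, 1, 1, 1), "X must be > 0")
})

test_that("CSP combines 1H and 13C shifts with the 0.251 scaling", {
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.37, 0), 0.37)
  expect_equal(csp(-0.37, 0), 0.37)           # sign-flip invariance
  expect_equal(csp(0.02, 0.2), sqrt(0.02^2 + (0.251 * 0.2)^2),
               tolerance = 1e-12)
  expect_equal(csp(0.02, 0.2), 0.0540374, tolerance = 1e-6)
  expect_equal(csp(0.02, -0.2), csp(0.02, 0.2))
})

test_that("Z-scores are population-normalised", {
  z <- zscores(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z[3], 1.2247449, tolerance = 1e-6)
  expect_error(zscores(rep(5, 4)), "identical")
  expect_error(zscores(1), "at least 2")
  set.seed(5)
  for (rep in 1:5) {
    z <- zscores(rnorm(sample(5:50, 1)))
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-12)
  }
})

test_that("broadened peaks take the bound noise floor and keep their flag", {
  h <- handle_broadened(c(0.025, 0.2), c(0.05, 0.05))
  expect_equal(h$intensity, c(0.05, 0.2))
  expect_equal(h$broadened, c(TRUE, FALSE))
  # pre-flagged peaks substituted even if numerically above the floor
  h2 <- handle_broadened(0.2, 0.05, flagged = TRUE)
  expect_equal(h2$intensity, 0.05)
  # substitution never decreases the intensity-loss Z of the residue
  apo <- make_peaks(1:10, rep(1, 10))
  bound <- make_peaks(1:10, c(0.01, rep(0.9, 9)))
  pm_raw <- map_perturbations(apo, transform(bound, intensity = pmax(intensity, 0.05)))
  pm_sub <- map_perturbations(apo, bound)
  expect_gte(pm_sub$records$Z_intensity[1], pm_raw$records$Z_intensity[1])
  expect_equal(pm_sub$records$mark[1], "*")
})

test_that("identical tables give a null perturbation map", {
  apo <- make_peaks(1:12, runif(12, 0.8, 1.2))
  pm <- map_perturbations(apo, apo)
  expect_true(all(pm$records$R == 1))
  expect_true(all(pm$records$CSP == 0))
  expect_error(zscores(pm$records$CSP), "identical")  # degenerate by design
  expect_false(any(pm$records$R < 1 & pm$records$significant))
})

test_that("overlapped/excluded peaks are dropped with a ledger entry", {
  apo <- make_peaks(1:6, rep(1, 6))
  apo$flags[2] <- "overlapped"
  bound <- make_peaks(1:6, rep(0.8, 6))
  bound$flags[5] <- "excluded"
  bound$intensity[1] <- 0.4
  pm <- map_perturbations(apo, bound)
  expect_equal(nrow(pm$records), 4)
  expect_setequal(pm$dropped$residue, c(2, 5))
  expect_error(map_perturbations(apo, make_peaks(10:12, rep(1, 3))),
               "no common residues")
})

test_that("planted hotspots are recovered in the top-Z ranking", {
  hits <- vapply(1:25, function(seed) {
    spec <- nmr_synth_spec(n_residues = 40,
                           hotspot_residues = c(3L, 9L, 17L, 22L, 30L, 38L),
                           attenuation = 0.4, noise_floor = 0.05,
                           seed = seed)
    tabs <- simulate_nmr_pair(spec)
    pm <- map_perturbations(tabs$apo, tabs$bound)
    top6 <- pm$records$residue[order(-pm$records$Z_intensity)][1:6]
    sum(top6 %in% spec$hotspot_residues)
  }, numeric(1))
  expect_gte(mean(hits >= 5), 0.9)
})

test_that("per-domain summaries order core above P2 for core-directed loss", {
  # core residues strongly attenuated, P2 mildly (10-40%)
  apo <- rbind(make_peaks(1:10, rep(1, 10), domain = "core-N"),
               make_peaks(11:18, rep(1, 8), domain = "P2"))
  set.seed(8)
  bound <- apo
  bound$intensity[1:10] <- runif(10, 0.2, 0.5)
  bound$intensity[11:18] <- runif(8, 0.6, 0.9)
  pm <- map_perturbations(apo, bound)
  core <- pm$domains[pm$domains$domain == "core-N", ]
  p2 <- pm$domains[pm$domains$domain == "P2", ]
  expect_gt(core$mean_Z_intensity, p2$mean_Z_intensity)
  expect_equal(core$n, 10); expect_equal(p2$n, 8)
})

test_that("the bundled example tables map core/P1 hotspots and P2 sparing", {
  path <- function(f) {
    p <- system.file("extdata", f, package = "smfretr")
    if (p == "") file.path("../../inst/extdata", f) else p
  }
  pm <- map_perturbations(read_peak_table(path("synthetic_sura_apo_peaks.tsv")),
                          read_peak_table(path("synthetic_sura_bound_peaks.tsv")))
  doms <- pm$domains
  expect_gt(doms$mean_Z_intensity[doms$domain == "core-N"],
            doms$mean_Z_intensity[doms$domain == "P2"])
  expect_gt(doms$mean_Z_intensity[doms$domain == "P1"],
            doms$mean_Z_intensity[doms$domain == "P2"])
  expect_equal(sum(pm$records$broadened), 1)
})
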