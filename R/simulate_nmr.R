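#' Specification for a synthetic NMR apo/bound peak-table pair
#'
#' Describes a methyl-labelled protein whose spectrum responds to client
#' binding in two ways: binding-site residues lose peak intensity
#' (attenuation, possibly below the noise floor), and residues reporting a
#' conformational change acquire chemical-shift perturbations. This is the
#' ground truth against which the perturbation-mapping statistics are
#' validated.
#'
#' @param n_residues Number of assigned methyl probes.
#' @param hotspot_residues Integer ids of binding-site residues (subset of
#'   `1:n_residues`).
#' @param attenuation Intensity multiplier applied to hotspot residues in
#'   the bound spectrum, in (0, 1).
#' @param conf_residues Integer ids receiving planted shift changes.
#' @param dH,dC Planted proton/carbon shift changes (ppm) for
#'   `conf_residues`.
#' @param noise_floor Spectrum noise level, as a fraction of the mean apo
#'   peak intensity (the tables are generated on a unit intensity scale).
#' @param domains Character vector of domain labels recycled across
#'   residues in contiguous blocks.
#' @param seed Integer seed.
#' @return An object of class `nmr_synth_spec`.
#' @export
nmr_synth_spec <- function(n_residues = 40L,
                           hotspot_residues = integer(0),
                           attenuation = 0.4,
                           conf_residues = integer(0),
                           dH = 0.02, dC = 0.1,
                           noise_floor = 0.05,
                           domains = c("core-N", "P1", "P2", "core-C"),
                           seed = 1L) {
  n_residues <- as.integer(n_residues)
  hotspot_residues <- as.integer(hotspot_residues)
  conf_residues <- as.integer(conf_residues)
  stopifnot(n_residues >= 2, noise_floor > 0,
            attenuation > 0, attenuation < 1)
  if (length(hotspot_residues) &&
      !all(hotspot_residues %in% seq_len(n_residues)))
    stop("hotspot_residues must be a subset of 1:n_residues")
  if (length(conf_residues) &&
      !all(conf_residues %in% seq_len(n_residues)))
    stop("conf_residues must be a subset of 1:n_residues")
  structure(list(n_residues = n_residues,
                 hotspot_residues = hotspot_residues,
                 attenuation = attenuation,
                 conf_residues = conf_residues,
                 dH = dH, dC = dC,
                 noise_floor = noise_floor,
                 domains = domains,
                 seed = as.integer(seed)),
            class = "nmr_synth_spec")
}

#' Simulate an apo/bound NMR peak-table pair
#'
#' Generates two peak tables (columns `residue`, `residue_type`, `wH_ppm`,
#' `wC_ppm`, `intensity`, `noise_floor`, `domain`, `flags`) with known
#' perturbations: apo intensities are drawn around a unit scale, bound
#' intensities are `attenuation * apo` at hotspot residues and unchanged
#' elsewhere, conformational-change residues get the planted (`dH`, `dC`)
#' shift, and additive Gaussian noise at the noise-floor scale is applied to
#' both spectra's intensities. Bound intensities falling below the noise
#' floor are flagged `broadened_below_noise`. Ile-d1 and Met-e methyl
#' shift statistics are used for plausible peak positions.
#'
#' @param spec An [nmr_synth_spec()].
#' @return List with elements `apo` and `bound` (data frames as above) and
#'   `truth` (the spec).
#' @examples
#' tabs <- simulate_nmr_pair(nmr_synth_spec(hotspot_residues = c(3L, 17L)))
#' head(tabs$bound)
#' @export
simulate_nmr_pair <- function(spec) {
  stopifnot(inherits(spec, "nmr_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  res <- seq_len(n)
  type <- ifelse(stats::runif(n) < 2 / 3, "Ile-d1", "Met-e")
  wH <- ifelse(type == "Ile-d1", stats::rnorm(n, 0.7, 0.2),
               stats::rnorm(n, 1.9, 0.15))
  wC <- ifelse(type == "Ile-d1", stats::rnorm(n, 12.5, 1.5),
               stats::rnorm(n, 16.5, 0.8))
  blocks <- sort(rep_len(seq_along(spec$domains), n))
  domain <- spec$domains[blocks]

  apo_clean <- stats::runif(n, 0.7, 1.3)
  bound_clean <- apo_clean
  bound_clean[spec$hotspot_residues] <-
    apo_clean[spec$hotspot_residues] * spec$attenuation

  nf <- spec$noise_floor
  apo_int <- pmax(apo_clean + stats::rnorm(n, 0, nf), 0)
  bound_int <- pmax(bound_clean + stats::rnorm(n, 0, nf), 0)

  wH_b <- wH; wC_b <- wC
  wH_b[spec$conf_residues] <- wH[spec$conf_residues] + spec$dH
  wC_b[spec$conf_residues] <- wC[spec$conf_residues] + spec$dC

  flags_b <- ifelse(bound_int < nf, "broadened_below_noise", "")

  mk <- function(wh, wc, int, flags) {
    data.frame(residue = res, residue_type = type,
               wH_ppm = wh, wC_ppm = wc,
               intensity = int, noise_floor = nf,
               domain = domain, flags = flags,
               stringsAsFactors = FALSE)
  }
  list(apo = mk(wH, wC, apo_int, rep("", n)),
       bound = mk(wH_b, wC_b, bound_int, flags_b),
       truth = spec)
}

#' Simulate a Hill-shaped titration
#'
#' Evaluates the Hill isotherm
#' `S_obs = S_U + (S_B - S_U) / (1 + (Kd_app / L)^n)` at the given ligand
#' concentrations and applies multiplicative Gaussian noise with
#' coefficient of variation `noise_cv`.
#'
#' @param S_U,S_B Unbound/bound signal plateaus.
#' @param Kd_app Apparent dissociation constant (same units as
#'   `concentrations`, > 0).
#' @param n Hill coefficient (> 0).
#' @param concentrations Ligand concentrations (> 0, non-empty).
#' @param noise_cv Multiplicative noise CV (0 for noiseless).
#' @param seed Integer seed.
#' @return Data frame with columns `concentration_uM` and `signal`.
#' @examples
#' simulate_binding_curve(800, 900, Kd_app = 2, n = 1.5,
#'                        concentrations = c(0.5, 2, 8), noise_cv = 0)
#' @export
simulate_binding_curve <- function(S_U, S_B, Kd_app, n, concentrations,
                                   noise_cv = 0.01, seed = 1L) {
  if (length(concentrations) == 0) stop("concentrations must be non-empty")
  stopifnot(Kd_app > 0, n > 0, all(concentrations > 0), noise_cv >= 0)
  set.seed(as.integer(seed))
  s <- hill_model(concentrations, S_U = S_U, S_B = S_B,
                  Kd_app = Kd_app, n = n)
  if (noise_cv > 0)
    s <- s * (1 + stats::rnorm(length(s), 0, noise_cv))
  data.frame(concentration_uM = concentrations, signal = s)
}
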