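# Methyl-TROSY perturbation mapping: intensity ratios with propagated
# errors, chemical shift perturbations, Z-scores and per-domain hotspot
# summaries for apo vs client-bound peak-table pairs.

#' Peak intensity ratio with propagated error
#'
#' `R = Y / X` with `X` the apo and `Y` the bound peak intensity. Two error
#' propagation modes are provided. `"as_printed"` follows the published
#' form exactly as typeset, `dR = |R| * sqrt(dX/X) + sqrt(dY/Y)`; that
#' expression is dimensionally anomalous (it adds a scaled ratio to the
#' square root of a ratio) and is almost certainly a typesetting slip of
#' the standard rule, so `"quadrature"` offers
#' `dR = |R| * sqrt((dX/X)^2 + (dY/Y)^2)`. Neither is silently preferred:
#' the mode is recorded in every output.
#'
#' @param X,Y Apo and bound peak intensities (`X > 0`).
#' @param dX,dY Noise-floor values of the two spectra.
#' @param mode `"as_printed"` or `"quadrature"`.
#' @return List with `R` and `dR` (vectorised).
#' @examples
#' intensity_ratio(100, 50, 10, 5)                       # dR = 0.47434...
#' intensity_ratio(100, 50, 10, 5, mode = "quadrature")  # dR = 0.07071...
#' @export
intensity_ratio <- function(X, Y, dX, dY, mode = c("as_printed", "quadrature")) {
  mode <- match.arg(mode)
  if (any(X <= 0)) stop("apo intensity X must be > 0")
  R <- Y / X
  dR <- if (mode == "as_printed")
    abs(R) * sqrt(dX / X) + sqrt(dY / Y)
  else
    abs(R) * sqrt((dX / X)^2 + (dY / Y)^2)
  list(R = R, dR = dR)
}

#' Combined chemical shift perturbation
#'
#' `CSP = sqrt(dH^2 + (0.251 * dC)^2)`: the carbon axis is scaled by 0.251
#' to account for the relative gyromagnetic ratios of 13C and 1H, putting
#' both dimensions on a common ppm scale.
#'
#' @param dH,dC Proton and carbon shift changes (ppm).
#' @return Non-negative CSP (ppm), invariant under sign flips of either
#'   input.
#' @examples
#' csp(0.02, 0.2)  # 0.054036...
#' @export
csp <- function(dH, dC) {
  sqrt(dH^2 + (0.251 * dC)^2)
}

#' Z-scores over a peak set
#'
#' `Z_i = (x_i - mu) / sigma` with `mu` and `sigma` the mean and population
#' standard deviation over all included peaks, so any output table has mean
#' 0 and population SD 1.
#'
#' @param x Per-peak statistic (>= 2 values).
#' @return Z-score per peak.
#' @examples
#' zscores(c(1, 2, 3))  # -1.2247, 0, 1.2247
#' @export
zscores <- function(x) {
  if (length(x) < 2) stop("need at least 2 peaks")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("all values identical: Z-scores undefined")
  (x - mu) / sigma
}

#' Broadened-peak substitution
#'
#' Peaks broadened below the noise in the bound spectrum have no measurable
#' intensity; their bound intensity is replaced by the bound spectrum's
#' noise floor (an upper bound on the true intensity, hence a lower bound
#' on the attenuation), the record is flagged, and flagged peaks are marked
#' with an asterisk in outputs. The substitution never decreases a peak's
#' intensity-loss Z-score.
#'
#' @param intensity Bound peak intensity.
#' @param noise_floor Bound spectrum noise floor.
#' @param flagged TRUE where the input table already flags the peak as
#'   `broadened_below_noise`.
#' @return List with `intensity` (effective values) and `broadened`
#'   (logical).
#' @export
handle_broadened <- function(intensity, noise_floor, flagged = FALSE) {
  broadened <- flagged | intensity < noise_floor
  list(intensity = ifelse(broadened, noise_floor, intensity),
       broadened = broadened)
}

#' Map apo-to-bound perturbations and summarise per domain
#'
#' Joins apo and bound peak tables on residue id, drops peaks flagged
#' `overlapped` or `excluded` in either table, applies the broadened-peak
#' substitution, and computes per residue: the intensity ratio `R` with
#' propagated error, the CSP, and Z-scores of the intensity-loss statistic
#' `1 - R` (positive Z = stronger loss) and of the CSP. Residues with
#' intensity-loss Z above `z_threshold` are classified significant,
#' mirroring the red/white Z > 0 colouring rule. A per-domain summary
#' (probe counts, mean Z, significant counts) accompanies the table. No
#' multiple-testing correction is applied.
#'
#' @param apo,bound Peak tables ([read_peak_table()] layout).
#' @param mode Error-propagation mode, see [intensity_ratio()].
#' @param z_threshold Significance threshold on the intensity-loss Z.
#' @return List of class `perturbation_map` with elements `records` (per
#'   residue: `residue`, `domain`, `R`, `dR`, `CSP`, `Z_intensity`,
#'   `Z_CSP`, `broadened`, `mark` (asterisk for broadened), `significant`),
#'   `domains` (per domain: `n`, `n_significant`, `mean_Z_intensity`,
#'   `mean_Z_CSP`), `dropped` (residues excluded and why), and `mode`.
#' @export
map_perturbations <- function(apo, bound, mode = c("as_printed", "quadrature"),
                              z_threshold = 0) {
  mode <- match.arg(mode)
  apo <- validate_peak_table(apo, "apo")
  bound <- validate_peak_table(bound, "bound")
  common <- intersect(apo$residue, bound$residue)
  if (length(common) == 0) stop("no common residues between tables")
  a <- apo[match(common, apo$residue), ]
  b <- bound[match(common, bound$residue), ]

  drop_flags <- has_flag(a$flags, "overlapped") | has_flag(a$flags, "excluded") |
    has_flag(b$flags, "overlapped") | has_flag(b$flags, "excluded")
  dropped <- data.frame(residue = common[drop_flags],
                        reason = rep("overlapped/excluded flag",
                                     sum(drop_flags)),
                        stringsAsFactors = FALSE)
  a <- a[!drop_flags, ]; b <- b[!drop_flags, ]
  if (nrow(a) < 2) stop("fewer than 2 usable peaks after exclusions")

  hb <- handle_broadened(b$intensity, b$noise_floor,
                         has_flag(b$flags, "broadened_below_noise"))
  ir <- intensity_ratio(a$intensity, hb$intensity, a$noise_floor,
                        b$noise_floor, mode = mode)
  csp_v <- csp(b$wH_ppm - a$wH_ppm, b$wC_ppm - a$wC_ppm)
  # a constant statistic (e.g. identical tables) has no Z-scale; report NA
  # rather than aborting the whole map
  z_safe <- function(x) tryCatch(zscores(x),
                                 error = function(e) rep(NA_real_, length(x)))
  z_int <- z_safe(1 - ir$R)
  z_csp <- z_safe(csp_v)

  rec <- data.frame(
    residue = a$residue, residue_type = a$residue_type, domain = a$domain,
    R = ir$R, dR = ir$dR, CSP = csp_v,
    Z_intensity = z_int, Z_CSP = z_csp,
    broadened = hb$broadened,
    mark = ifelse(hb$broadened, "*", ""),
    significant = !is.na(z_int) & z_int > z_threshold,
    stringsAsFactors = FALSE)

  doms <- unique(rec$domain)
  domains <- do.call(rbind, lapply(doms, function(d) {
    r <- rec[rec$domain == d, ]
    data.frame(domain = d, n = nrow(r),
               n_significant = sum(r$significant),
               mean_Z_intensity = mean(r$Z_intensity),
               mean_Z_CSP = mean(r$Z_CSP),
               stringsAsFactors = FALSE)
  }))

  structure(list(records = rec, domains = domains, dropped = dropped,
                 mode = mode, z_threshold = z_threshold),
            class = "perturbation_map")
}

#' @export
print.perturbation_map <- function(x, ...) {
  cat(sprintf("perturbation_map: %d residues (%d dropped), mode=%s\n",
              nrow(x$records), nrow(x$dropped), x$mode))
  print.data.frame(x$domains, row.names = FALSE)
  invisible(x)
}
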