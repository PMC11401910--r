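#' Raw FRET efficiency and stoichiometry of bursts
#'
#' Background-subtracted counts `F_xy = n_xy - rate_xy * duration` (floored
#' at 0, which keeps the proximity ratio inside `[0, 1]`) give the raw
#' proximity ratio `E_raw = F_DA / (F_DD + F_DA)` and raw stoichiometry
#' `S_raw = (F_DD + F_DA) / (F_DD + F_DA + F_AA)`.
#'
#' @param bursts A `burst_set` from [search_bursts()].
#' @param bg The [estimate_background()] used for the search.
#' @return Data frame with one row per burst: `F_DD`, `F_DA`, `F_AA`,
#'   `E_raw`, `S_raw`, `undefined` (TRUE when the Dex signal vanishes after
#'   subtraction, leaving `E_raw` as `NA`).
#' @export
raw_es <- function(bursts, bg) {
  f <- bg_subtracted_counts(bursts, bg)
  tot <- f$F_DD + f$F_DA
  und <- tot <= 0
  e <- ifelse(und, NA_real_, f$F_DA / tot)
  s_den <- tot + f$F_AA
  s <- ifelse(s_den <= 0, NA_real_, tot / s_den)
  data.frame(F_DD = f$F_DD, F_DA = f$F_DA, F_AA = f$F_AA,
             E_raw = e, S_raw = s, undefined = und)
}

#' Corrected FRET efficiency and stoichiometry of bursts
#'
#' Applies the consensus ALEX correction chain to background-subtracted
#' counts: `F_DA' = F_DA - lk * F_DD - dir * F_AA`, then
#' `E = F_DA' / (F_DA' + gamma * F_DD)` and
#' `S = (F_DA' + gamma * F_DD) / (F_DA' + gamma * F_DD + F_AA / beta)`.
#' Corrected values are not clipped: shot noise legitimately places them
#' slightly outside `[0, 1]`.
#'
#' @param bursts A `burst_set` from [search_bursts()].
#' @param bg The matching [estimate_background()].
#' @param corrections A [correction_set()].
#' @return Data frame with one row per burst: `E`, `S`, `undefined`.
#' @examples
#' # the study's corrections on F_DD=100, F_DA=64, F_AA=100:
#' # F_DA' = 64 - 14 - 14 = 36; E = 36/136; S = 136/(136 + 100/1.4)
#' @export
corrected_es <- function(bursts, bg, corrections = correction_set()) {
  stopifnot(inherits(corrections, "correction_set"))
  f <- bg_subtracted_counts(bursts, bg)
  fda_p <- f$F_DA - corrections$lk * f$F_DD - corrections$dir * f$F_AA
  dex_sig <- fda_p + corrections$gamma * f$F_DD
  und <- (f$F_DD + f$F_DA) <= 0 | dex_sig == 0
  e <- ifelse(und, NA_real_, fda_p / dex_sig)
  s_den <- dex_sig + f$F_AA / corrections$beta
  s <- ifelse(und | s_den == 0, NA_real_, dex_sig / s_den)
  data.frame(E = e, S = s, undefined = und)
}

# Background-subtracted burst counts, floored at zero.
bg_subtracted_counts <- function(bursts, bg) {
  stopifnot(inherits(bursts, "burst_set"),
            inherits(bg, "background_estimate"))
  data.frame(
    F_DD = pmax(0, bursts$n_DD -
                  bg_lookup(bg, bursts$segment, "DexD") * bursts$duration),
    F_DA = pmax(0, bursts$n_DA -
                  bg_lookup(bg, bursts$segment, "DexA") * bursts$duration),
    F_AA = pmax(0, bursts$n_AA -
                  bg_lookup(bg, bursts$segment, "AexA") * bursts$duration))
}

#' Full burst metrics table
#'
#' Computes raw and corrected (E, S) plus the ALEX-2CDE score for every
#' burst, the inputs to [filter_bursts()].
#'
#' @param bursts A `burst_set`.
#' @param stream The [photon_stream()] the bursts came from.
#' @param bg The matching [estimate_background()].
#' @param config A [run_config()].
#' @return Data frame: burst columns plus `E_raw`, `S_raw`, `E`, `S`,
#'   `alex2cde`, `undefined`.
#' @export
burst_metrics <- function(bursts, stream, bg, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  raw <- raw_es(bursts, bg)
  corr <- corrected_es(bursts, bg, config$corrections)
  cde <- alex_2cde(bursts, stream, kde_tau_us = config$cde_tau_us)
  cbind(as.data.frame(bursts),
        E_raw = raw$E_raw, S_raw = raw$S_raw,
        E = corr$E, S = corr$S,
        alex2cde = cde,
        undefined = raw$undefined | corr$undefined)
}

#' Apply the stoichiometry and ALEX-2CDE burst filters
#'
#' Keeps bursts with `s_min <= S <= s_max` (corrected S by default; raw S
#' when the config says so) and ALEX-2CDE score `<= cde_max` (the cutoff is
#' inclusive). Every rejection carries a reason code; the two filters
#' commute.
#'
#' @param metrics A [burst_metrics()] table.
#' @param s_min,s_max Stoichiometry bounds.
#' @param cde_max ALEX-2CDE cutoff.
#' @param use_raw_s Filter on `S_raw` instead of corrected `S`.
#' @return `metrics` with added columns `passed` (logical) and `reason`
#'   (`""`, or semicolon-joined codes from `S_range`, `alex2cde`,
#'   `undefined`).
#' @export
filter_bursts <- function(metrics, s_min = 0.3, s_max = 0.7, cde_max = 95,
                          use_raw_s = FALSE) {
  if (s_min >= s_max) stop("s_min must be < s_max")
  s <- if (use_raw_s) metrics$S_raw else metrics$S
  reasons <- character(nrow(metrics))
  bad_und <- metrics$undefined | is.na(s)
  bad_s <- !bad_und & (s < s_min | s > s_max)
  bad_cde <- !is.na(metrics$alex2cde) & metrics$alex2cde > cde_max
  add <- function(r, which, code) ifelse(which, ifelse(r == "", code,
                                                       paste(r, code, sep = ";")), r)
  reasons <- add(reasons, bad_und, "undefined")
  reasons <- add(reasons, bad_s, "S_range")
  reasons <- add(reasons, bad_cde, "alex2cde")
  metrics$passed <- reasons == ""
  metrics$reason <- reasons
  metrics
}
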