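#' Run the full burst pipeline on a photon stream
#'
#' Convenience wrapper chaining the standard stages with one
#' [run_config()]: per-segment background estimation, dual-channel burst
#' search, raw/corrected (E, S) with ALEX-2CDE, and the stoichiometry +
#' ALEX-2CDE filters.
#'
#' @param stream A [photon_stream()].
#' @param config A [run_config()].
#' @return List with `background`, `bursts` (all candidates), `metrics`
#'   (with `passed`/`reason`), `accepted` (filtered metrics subset), and
#'   `config`.
#' @examples
#' m <- two_state_model(E1 = 0.45, corrections = correction_set(),
#'                      burst_rate = 20, seed = 11)
#' ps <- simulate_photon_stream(m, duration = 5)
#' out <- burst_pipeline(ps)
#' nrow(out$accepted)
#' @export
burst_pipeline <- function(stream, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  bg <- estimate_background(stream, segment_s = config$bg_segment_s)
  bursts <- search_bursts(stream, bg,
                          threshold_factor = config$threshold_factor,
                          min_size = config$min_size,
                          window_m = config$window_m,
                          edge_trim = config$edge_trim)
  if (nrow(bursts) == 0) {
    return(list(background = bg, bursts = bursts,
                metrics = NULL, accepted = NULL, config = config))
  }
  metrics <- burst_metrics(bursts, stream, bg, config)
  metrics <- filter_bursts(metrics, s_min = config$s_min,
                           s_max = config$s_max, cde_max = config$cde_max,
                           use_raw_s = config$filter_on_raw_s)
  list(background = bg, bursts = bursts, metrics = metrics,
       accepted = metrics[metrics$passed, , drop = FALSE],
       config = config)
}
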