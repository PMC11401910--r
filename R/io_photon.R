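# Photon-HDF5-style container I/O.
#
# Dialect (documented subset of the Photon-HDF5 field layout; unknown
# groups in a file are ignored with a warning):
#   /acquisition_duration                  scalar, seconds
#   /photon_data/timestamps                integer ticks, non-decreasing
#   /photon_data/timestamps_specs/timestamps_unit   seconds per tick
#   /photon_data/nanotimes                 integer TCSPC bins
#   /photon_data/nanotimes_specs/tcspc_unit         seconds per bin
#   /photon_data/nanotimes_specs/tcspc_num_bins     bins per period
#   /photon_data/detectors                 0 = donor, 1 = acceptor
#   /photon_data/measurement_specs/measurement_type "smFRET-nsALEX"
#   /photon_data/measurement_specs/alex_excitation_period1  Dex bins c(lo, hi)
#   /photon_data/measurement_specs/alex_excitation_period2  Aex bins c(lo, hi)

#' Write a photon stream to a Photon-HDF5-layout file
#'
#' @param stream A [photon_stream()].
#' @param path Output `.h5` path (overwritten if it exists).
#' @param truth Optional ground-truth list (e.g. the `"truth"` attribute of
#'   a simulated stream); written as JSON to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_photon_file <- function(stream, path, truth = NULL) {
  stopifnot(inherits(stream, "photon_stream"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  rhdf5::h5writeDataset(stream$duration_s, h5, "acquisition_duration")
  rhdf5::h5createGroup(h5, "photon_data")
  rhdf5::h5writeDataset(stream$timestamps, h5, "photon_data/timestamps")
  rhdf5::h5createGroup(h5, "photon_data/timestamps_specs")
  rhdf5::h5writeDataset(1 / stream$clock_rate_hz, h5,
                        "photon_data/timestamps_specs/timestamps_unit")
  rhdf5::h5writeDataset(stream$nanotimes, h5, "photon_data/nanotimes")
  rhdf5::h5createGroup(h5, "photon_data/nanotimes_specs")
  rhdf5::h5writeDataset(stream$pie$tcspc_unit_ns * 1e-9, h5,
                        "photon_data/nanotimes_specs/tcspc_unit")
  rhdf5::h5writeDataset(stream$pie$n_bins, h5,
                        "photon_data/nanotimes_specs/tcspc_num_bins")
  rhdf5::h5writeDataset(stream$detectors, h5, "photon_data/detectors")
  rhdf5::h5createGroup(h5, "photon_data/measurement_specs")
  rhdf5::h5writeDataset("smFRET-nsALEX", h5,
                        "photon_data/measurement_specs/measurement_type")
  rhdf5::h5writeDataset(stream$pie$dex_window, h5,
                        "photon_data/measurement_specs/alex_excitation_period1")
  rhdf5::h5writeDataset(stream$pie$aex_window, h5,
                        "photon_data/measurement_specs/alex_excitation_period2")
  if (!is.null(truth)) {
    truth_clean <- truth
    truth_clean$model <- lapply(unclass(truth_clean$model), function(v)
      if (inherits(v, c("correction_set", "pie_scheme"))) unclass(v) else v)
    jsonlite::write_json(truth_clean, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a photon stream from a Photon-HDF5-layout file
#'
#' Reads the documented field subset (see [write_photon_file()]), rebuilds
#' the PIE scheme from the alternation metadata, and validates the stream
#' invariants; excitation-slot labels are re-derived from the nanotimes.
#' Unknown top-level groups are ignored with a warning, since vendor
#' conversions add extra metadata.
#'
#' @param path Path to an `.h5` file.
#' @return A [photon_stream()].
#' @export
read_photon_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  idx <- rhdf5::h5ls(path)
  have <- file.path(idx$group, idx$name)
  need <- c("//photon_data", "/photon_data/timestamps",
            "/photon_data/detectors", "/photon_data/nanotimes")
  miss <- setdiff(need, c(have, sub("^//", "/", have)))
  if (length(miss))
    stop("missing mandatory groups/datasets: ", paste(miss, collapse = ", "))
  known_top <- c("acquisition_duration", "photon_data")
  extra <- setdiff(idx$name[idx$group == "/"], known_top)
  if (length(extra))
    warning("ignoring unknown top-level groups: ", paste(extra, collapse = ", "))

  rd <- function(name) rhdf5::h5read(path, name)
  ts <- as.double(rd("photon_data/timestamps"))
  nt <- as.integer(rd("photon_data/nanotimes"))
  det <- as.integer(rd("photon_data/detectors"))
  ts_unit <- as.double(rd("photon_data/timestamps_specs/timestamps_unit"))
  tcspc_unit <- as.double(rd("photon_data/nanotimes_specs/tcspc_unit"))
  n_bins <- as.integer(rd("photon_data/nanotimes_specs/tcspc_num_bins"))
  dex <- as.integer(rd("photon_data/measurement_specs/alex_excitation_period1"))
  aex <- as.integer(rd("photon_data/measurement_specs/alex_excitation_period2"))
  dur <- as.double(rd("acquisition_duration"))

  pie <- pie_scheme(period_ns = tcspc_unit * 1e9 * n_bins, n_bins = n_bins,
                    dex_window = dex, aex_window = aex)
  photon_stream(timestamps = ts, nanotimes = nt, detectors = det,
                clock_rate_hz = 1 / ts_unit, pie = pie, duration_s = dur,
                meta = list(source_file = path))
}
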