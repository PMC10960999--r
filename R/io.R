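# Reading and validating the tabular inputs: wide or long spectra files,
# hourly microclimate, and plot-level physiology tables. Delimited text
# only (comma default, tab accepted), UTF-8, one header row.

read_delim_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop_ricelwc(sprintf("file not found: %s", path),
                 class = "ricelwc_error_io")
  }
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read canopy reflectance spectra
#'
#' Reads a delimited text file of canopy spectra in either wide format
#' (one column per band, named `R350`..`R2500`) or long format (columns
#' `wavelength` and `reflectance` plus identifying metadata). The
#' wavelength grid must match `grid` exactly (default: the full 1-nm
#' 350-2500 nm device grid, 2151 bands); other grids are rejected rather
#' than resampled. Reflectance must be a fraction in \[0, 1\]; inputs in
#' percent (detected by a maximum above 1.5) are converted with a
#' warning. Replicate scans (a `scan` column) are kept as separate rows,
#' to be averaged with [average_replicate_scans()].
#'
#' @param path Path to a CSV/TSV file.
#' @param format `"auto"` (default), `"wide"` or `"long"`.
#' @param delim Field delimiter; `NULL` auto-detects comma vs tab.
#' @param grid Integer vector of expected wavelengths, default
#'   `350:2500`.
#' @return A wide tibble: metadata columns plus one `R<wavelength>`
#'   column per grid band.
#' @export
read_spectra <- function(path, format = c("auto", "wide", "long"),
                         delim = NULL, grid = 350:2500) {
  format <- match.arg(format)
  raw <- read_delim_auto(path, delim)
  if (format == "auto") {
    format <- if (all(c("wavelength", "reflectance") %in% names(raw)))
      "long" else "wide"
  }
  if (format == "long") {
    check_columns(raw, c("wavelength", "reflectance"), "long spectra file")
    raw <- tidyr::pivot_wider(
      raw,
      names_from = "wavelength", values_from = "reflectance",
      names_prefix = "R"
    )
  }
  validate_spectra(raw, grid = grid)
}

#' Validate a wide spectra table
#'
#' Checks the band set against the expected grid, converts percent
#' reflectance to fractions when detected, and enforces the \[0, 1\]
#' bound.
#'
#' @param data Wide tibble with `R<wavelength>` columns.
#' @inheritParams read_spectra
#' @return The validated tibble, bands in increasing wavelength order.
#' @export
validate_spectra <- function(data, grid = 350:2500) {
  have <- band_wavelengths(data)
  missing <- setdiff(grid, have)
  if (length(missing) > 0) {
    stop_ricelwc(
      sprintf("spectra file is missing wavelength column R%d (and %d more)",
              missing[1], length(missing) - 1L),
      class = "ricelwc_error_schema"
    )
  }
  extra <- setdiff(have, grid)
  if (length(extra) > 0) {
    stop_ricelwc(
      sprintf("spectra carry off-grid band(s) (first: R%d); expected the %d-band grid %d-%d nm",
              extra[1], length(grid), min(grid), max(grid)),
      class = "ricelwc_error_schema"
    )
  }
  cols <- paste0("R", sort(grid))
  meta <- setdiff(names(data), band_columns(data))
  data <- data[c(meta, cols)]
  R <- as.matrix(data[cols])
  if (any(!is.finite(R))) {
    stop_ricelwc("non-finite reflectance values present",
                 class = "ricelwc_error_validation")
  }
  # percent-scale detection is robust to isolated bad cells: only when
  # the bulk of the distribution exceeds the fraction range is the whole
  # table treated as percent
  if (quantile(R, 0.95, names = FALSE) > 1.5) {
    warn("reflectance values look like percent; dividing by 100")
    R <- R / 100
    data[cols] <- as.data.frame(R)
  }
  if (any(R < 0 | R > 1)) {
    bad <- which(R < 0 | R > 1, arr.ind = TRUE)[1, ]
    stop_ricelwc(
      sprintf("reflectance outside [0, 1]: row %d, band %s (value %.4g)",
              bad[1], cols[bad[2]], R[bad[1], bad[2]]),
      class = "ricelwc_error_validation"
    )
  }
  tibble::as_tibble(data)
}

#' Read hourly microclimate records
#'
#' @param path Path to a CSV/TSV file with columns `plot_id`, `Tc`, `Ta`,
#'   `RH` and `hour` or `timestamp`.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return Validated tibble.
#' @export
read_microclimate <- function(path, delim = NULL) {
  mc <- read_delim_auto(path, delim)
  check_columns(mc, c("plot_id", "Tc", "Ta", "RH"), "microclimate file")
  if (!any(c("hour", "timestamp") %in% names(mc))) {
    stop_ricelwc("microclimate file needs an `hour` or `timestamp` column",
                 class = "ricelwc_error_schema")
  }
  if (any(mc$RH < 0 | mc$RH > 100)) {
    stop_ricelwc("relative humidity outside [0, 100] percent",
                 class = "ricelwc_error_validation")
  }
  if (any(!is.finite(mc$Tc)) || any(!is.finite(mc$Ta))) {
    stop_ricelwc("non-finite canopy or air temperatures",
                 class = "ricelwc_error_validation")
  }
  mc
}

#' Read a plot-level physiology table
#'
#' @param path Path to a CSV/TSV file with at least `plot_id`, `stage`
#'   and the raw measurement columns (`FW`, `DW`, `Fo`, `Fm`, `Fs`,
#'   `Fm_prime`, `SPAD`, ...).
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return Tibble.
#' @export
read_physiology <- function(path, delim = NULL) {
  ph <- read_delim_auto(path, delim)
  check_columns(ph, c("plot_id", "stage"), "physiology file")
  ph
}

#' Average replicate spectral scans
#'
#' Element-wise arithmetic mean of the reflectance of replicate scans of
#' the same plot/stage (the field protocol records several scans per
#' sample). Rows are grouped by every metadata column except `scan`; the
#' result carries `n_scans`.
#'
#' @param scans Wide spectra tibble, one row per scan, optionally with a
#'   `scan` column.
#' @return Wide tibble with one row per group and an `n_scans` column.
#' @export
average_replicate_scans <- function(scans) {
  if (nrow(scans) == 0) {
    stop_ricelwc("no scans to average", class = "ricelwc_error_validation")
  }
  cols <- band_columns(scans)
  if (length(cols) == 0) {
    stop_ricelwc("no reflectance columns found",
                 class = "ricelwc_error_schema")
  }
  keys <- setdiff(names(scans), c(cols, "scan", "n_scans"))
  scans %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      n_scans = dplyr::n(),
      dplyr::across(dplyr::all_of(cols), mean),
      .groups = "drop"
    )
}

#' Merge physiology, CWSI and canopy tables into plot observations
#'
#' Inner join on the shared keys (`plot_id`, `stage`, plus `year` when
#' present in every source). Duplicate keys in any source are an error;
#' keys dropped by the join are reported via a message.
#'
#' @param physiology Plot-level physiology tibble.
#' @param cwsi Per-plot CWSI tibble (e.g. from [summarise_cwsi()]).
#' @param canopy Optional canopy-trait tibble (LAI, biomass, yield).
#' @return Merged tibble of plot observations.
#' @export
merge_observations <- function(physiology, cwsi, canopy = NULL) {
  sources <- list(physiology = physiology, cwsi = cwsi)
  if (!is.null(canopy)) sources$canopy <- canopy
  keys <- Reduce(intersect, lapply(sources, names))
  keys <- intersect(c("plot_id", "year", "stage"), keys)
  if (length(keys) == 0) {
    stop_ricelwc("sources share no join keys among plot_id, year, stage",
                 class = "ricelwc_error_schema")
  }
  for (nm in names(sources)) {
    dup <- sources[[nm]] %>%
      dplyr::count(dplyr::across(dplyr::all_of(keys))) %>%
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop_ricelwc(
        sprintf("duplicate keys in %s source: %s", nm,
                paste(utils::capture.output(print(dup[keys])), collapse = " ")),
        class = "ricelwc_error_keys"
      )
    }
  }
  merged <- Reduce(function(a, b) dplyr::inner_join(a, b, by = keys), sources)
  dropped <- vapply(sources, nrow, integer(1)) - nrow(merged)
  if (any(dropped > 0)) {
    inform(sprintf(
      "merge_observations: %s unmatched row(s) dropped (%s)",
      sum(dropped),
      paste(sprintf("%s: %d", names(dropped), dropped), collapse = ", ")))
  }
  merged
}
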