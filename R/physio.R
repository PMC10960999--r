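# Physiological derivations: fluorescence ratios, leaf water content,
# SPAD aggregation and leaf area index.

#' Maximum photochemical efficiency of PSII
#'
#' Computes Fv/Fm = (Fm - Fo)/Fm from dark-adapted minimum (`fo`) and
#' maximum (`fm`) fluorescence. Vectorised.
#'
#' @param fo Dark-adapted minimum fluorescence level (instrument units).
#' @param fm Dark-adapted maximum fluorescence level (instrument units).
#' @return Numeric vector of Fv/Fm values in \[0, 1\].
#' @examples
#' fv_fm(500, 2000) # 0.75
#' @export
fv_fm <- function(fo, fm) {
  if (any(fm == 0)) {
    stop_ricelwc("Fv/Fm undefined: Fm = 0", class = "ricelwc_error_ratio")
  }
  if (any(fo < 0 | fm < 0)) {
    stop_ricelwc("fluorescence levels must be non-negative",
                 class = "ricelwc_error_validation")
  }
  if (any(fo > fm)) {
    stop_ricelwc("invariant violated: Fo > Fm",
                 class = "ricelwc_error_validation")
  }
  (fm - fo) / fm
}

#' Actual photochemical efficiency of PSII under light
#'
#' Computes Y(II) = (Fm' - Fs)/Fm' from steady-state fluorescence (`fs`)
#' and light-adapted maximal fluorescence (`fm_prime`). Vectorised.
#'
#' @param fs Steady-state fluorescence (instrument units).
#' @param fm_prime Light-adapted maximal fluorescence (instrument units).
#' @return Numeric vector of Y(II) values in \[0, 1\].
#' @export
y_ii <- function(fs, fm_prime) {
  if (any(fm_prime == 0)) {
    stop_ricelwc("Y(II) undefined: Fm' = 0", class = "ricelwc_error_ratio")
  }
  if (any(fs < 0 | fm_prime < 0)) {
    stop_ricelwc("fluorescence levels must be non-negative",
                 class = "ricelwc_error_validation")
  }
  if (any(fs > fm_prime)) {
    stop_ricelwc("invariant violated: Fs > Fm'",
                 class = "ricelwc_error_validation")
  }
  (fm_prime - fs) / fm_prime
}

#' Gravimetric leaf water content
#'
#' LWC = (FW - DW)/FW, the mass fraction of water in fresh leaves.
#'
#' @param fw Fresh leaf mass, g.
#' @param dw Dry leaf mass, g.
#' @return Numeric vector of LWC fractions in \[0, 1\].
#' @examples
#' leaf_water_content(4, 1) # 0.75
#' @export
leaf_water_content <- function(fw, dw) {
  if (any(fw == 0)) {
    stop_ricelwc("LWC undefined: FW = 0", class = "ricelwc_error_ratio")
  }
  if (any(fw < 0 | dw < 0)) {
    stop_ricelwc("leaf masses must be non-negative",
                 class = "ricelwc_error_validation")
  }
  if (any(dw > fw)) {
    stop_ricelwc("invariant violated: DW > FW",
                 class = "ricelwc_error_validation")
  }
  (fw - dw) / fw
}

#' Leaf area index from per-hill leaf area and planting density
#'
#' LAI = D * rho / 10000, converting cm^2 of green leaf per hill times
#' hills per m^2 into m^2 leaf per m^2 ground.
#'
#' @param d Green leaf area per hill, cm^2.
#' @param rho Planting density, hills per m^2.
#' @return LAI in m^2 m^-2.
#' @export
leaf_area_index <- function(d, rho) {
  if (any(d < 0)) {
    stop_ricelwc("leaf area D must be non-negative",
                 class = "ricelwc_error_validation")
  }
  if (any(rho <= 0)) {
    stop_ricelwc("planting density rho must be positive",
                 class = "ricelwc_error_validation")
  }
  d * rho / 10000
}

#' Aggregate SPAD readings to a plant or plot value
#'
#' Arithmetic mean of chlorophyll-meter readings (conventionally the top
#' three fully expanded leaves, several plants per plot).
#'
#' @param readings Numeric vector of SPAD readings.
#' @return The mean reading.
#' @export
aggregate_spad <- function(readings) {
  if (length(readings) == 0 || all(is.na(readings))) {
    stop_ricelwc("no SPAD readings to aggregate",
                 class = "ricelwc_error_validation")
  }
  mean(readings, na.rm = TRUE)
}

#' Derive physiology columns for a raw plot table
#'
#' Takes a per-plot table of raw measurements (`FW`, `DW`, `Fo`, `Fm`,
#' `Fs`, `Fm_prime`, and optionally `D`, `rho`) and appends the derived
#' quantities `LWC`, `FvFm`, `YII` and (when canopy columns are present)
#' `LAI`.
#'
#' @param data Data frame with the raw measurement columns.
#' @return The input as a tibble with derived columns appended.
#' @export
derive_physiology <- function(data) {
  check_columns(data, c("FW", "DW", "Fo", "Fm", "Fs", "Fm_prime"),
                "physiology table")
  out <- tibble::as_tibble(data) %>%
    dplyr::mutate(
      LWC  = leaf_water_content(.data$FW, .data$DW),
      FvFm = fv_fm(.data$Fo, .data$Fm),
      YII  = y_ii(.data$Fs, .data$Fm_prime)
    )
  if (all(c("D", "rho") %in% names(out))) {
    out <- dplyr::mutate(out, LAI = leaf_area_index(.data$D, .data$rho))
  }
  out
}
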