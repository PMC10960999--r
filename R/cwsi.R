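# Crop water stress index (CWSI) chain: saturation vapor pressure, VPD,
# the non-water-stressed baseline Tc - Ta = A + B * VPD fitted from
# well-watered plots, VPG, and the normalized index itself.

#' Saturation vapor pressure of air
#'
#' Tetens-form closed expression `0.61 * exp(17.27 * Ta / (Ta + 237.3))`,
#' in kPa. Vectorised over `ta`.
#'
#' @param ta Air temperature, degrees C. Must exceed -237.3.
#' @return Saturation vapor pressure, kPa.
#' @examples
#' saturation_vapor_pressure(0)  # 0.61
#' @export
saturation_vapor_pressure <- function(ta) {
  if (any(ta <= -237.3)) {
    stop_ricelwc("air temperature out of range (Ta <= -237.3 C)",
                 class = "ricelwc_error_validation")
  }
  0.61 * exp(17.27 * ta / (ta + 237.3))
}

#' Vapor pressure deficit
#'
#' VPD = es(Ta) * (1 - RH/100), kPa: the gap between saturation and
#' actual vapor pressure at air temperature `ta` and relative humidity
#' `rh` (percent).
#'
#' @param ta Air temperature, degrees C.
#' @param rh Relative humidity, percent (0-100).
#' @return VPD in kPa.
#' @export
vpd <- function(ta, rh) {
  if (any(rh < 0 | rh > 100)) {
    stop_ricelwc("relative humidity must lie in [0, 100] percent",
                 class = "ricelwc_error_validation")
  }
  saturation_vapor_pressure(ta) * (1 - rh / 100)
}

#' Vapor pressure gradient for the CWSI upper limit
#'
#' Idso's construction for the maximally stressed (non-transpiring)
#' canopy: VPG = es(Ta) - es(Ta + A), where `A` is the baseline
#' intercept. With A > 0 this is negative, which together with a
#' negative baseline slope B yields Tmax > Tmin. The opposite sign
#' convention can be selected with `sign = -1`.
#'
#' @param ta Air temperature, degrees C.
#' @param a Baseline intercept A, degrees C.
#' @param sign Either `1` (default, es(Ta) - es(Ta + A)) or `-1` for the
#'   reversed convention.
#' @return VPG in kPa.
#' @export
vpg <- function(ta, a, sign = 1) {
  if (!sign %in% c(1, -1)) {
    stop_ricelwc("`sign` must be 1 or -1", class = "ricelwc_error_validation")
  }
  sign * (saturation_vapor_pressure(ta) - saturation_vapor_pressure(ta + a))
}

#' Fit the non-water-stressed CWSI baseline
#'
#' Ordinary least squares of the canopy-air temperature difference
#' (Tc - Ta) on VPD over well-watered records inside a daily hour
#' window, yielding the lower-limit line Tmin = A + B * VPD.
#'
#' @param microclimate Data frame of hourly records with columns `Tc`,
#'   `Ta`, `RH` and either an `hour` column or a POSIXct `timestamp`.
#'   If a `treatment` column is present only rows with
#'   `treatment == well_watered` are used.
#' @param window Two-element numeric vector of inclusive hours,
#'   default `c(10, 14)` to match the midday measurement window.
#' @param well_watered Treatment label identifying non-stressed plots
#'   (default `"CK"`).
#' @return An object of class `lwc_baseline`: a list with intercept `A`
#'   (degrees C), slope `B` (degrees C per kPa), `n_fit` and `r2_fit`.
#' @export
fit_cwsi_baseline <- function(microclimate, window = c(10, 14),
                              well_watered = "CK") {
  check_columns(microclimate, c("Tc", "Ta", "RH"), "microclimate")
  mc <- tibble::as_tibble(microclimate)
  if ("treatment" %in% names(mc)) {
    mc <- dplyr::filter(mc, .data$treatment == well_watered)
  }
  mc <- dplyr::filter(mc, record_hour(mc) >= window[1],
                      record_hour(mc) <= window[2])
  if (nrow(mc) < 2) {
    stop_ricelwc("need at least 2 well-watered records inside the hour window",
                 class = "ricelwc_error_validation")
  }
  x <- vpd(mc$Ta, mc$RH)
  y <- mc$Tc - mc$Ta
  if (sd(x) == 0) {
    stop_ricelwc("all VPD values identical: baseline regression is rank-deficient",
                 class = "ricelwc_error_rank")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      A = unname(coef(fit)[1]),
      B = unname(coef(fit)[2]),
      n_fit = length(y),
      r2_fit = if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    ),
    class = "lwc_baseline"
  )
}

record_hour <- function(mc) {
  if ("hour" %in% names(mc)) return(mc$hour)
  if ("timestamp" %in% names(mc)) return(as.POSIXlt(mc$timestamp)$hour)
  stop_ricelwc("microclimate needs an `hour` or `timestamp` column",
               class = "ricelwc_error_schema")
}

#' @export
print.lwc_baseline <- function(x, ...) {
  cat(sprintf(
    "CWSI non-water-stressed baseline: Tmin = %.3f + (%.3f) * VPD  [n = %d, R2 = %.3f]\n",
    x$A, x$B, x$n_fit, x$r2_fit))
  invisible(x)
}

#' Crop water stress index for hourly records
#'
#' CWSI = ((Tc - Ta) - Tmin) / (Tmax - Tmin) with Tmin = A + B * VPD and
#' Tmax = A + B * VPG. Values are not clamped to \[0, 1\]; records
#' outside the envelope are flagged instead, since clamping would hide
#' baseline misfit.
#'
#' @param tc Canopy temperature, degrees C.
#' @param ta Air temperature, degrees C.
#' @param rh Relative humidity, percent.
#' @param baseline An `lwc_baseline` object (or a list with `A` and `B`).
#' @param vpg_sign Sign convention passed to [vpg()].
#' @return A tibble with columns `VPD`, `VPG`, `tmin`, `tmax`, `CWSI`
#'   and logical `out_of_envelope`.
#' @export
cwsi <- function(tc, ta, rh, baseline, vpg_sign = 1) {
  v_d <- vpd(ta, rh)
  v_g <- vpg(ta, baseline$A, sign = vpg_sign)
  tmin <- baseline$A + baseline$B * v_d
  tmax <- baseline$A + baseline$B * v_g
  if (any(tmax - tmin <= 0)) {
    i <- which(tmax - tmin <= 0)[1]
    stop_ricelwc(
      sprintf(paste0("degenerate CWSI envelope (Tmax <= Tmin) at ",
                     "Ta = %.2f, RH = %.1f with A = %.3f, B = %.3f"),
              ta[i], rh[i], baseline$A, baseline$B),
      class = "ricelwc_error_envelope"
    )
  }
  val <- ((tc - ta) - tmin) / (tmax - tmin)
  tibble::tibble(
    VPD = v_d, VPG = v_g, tmin = tmin, tmax = tmax, CWSI = val,
    out_of_envelope = val < 0 | val > 1
  )
}

#' Per-plot, per-stage CWSI from hourly microclimate
#'
#' Computes hourly CWSI inside the daily window and averages it for each
#' plot (and stage, when a `stage` column is present).
#'
#' @inheritParams fit_cwsi_baseline
#' @param baseline An `lwc_baseline` object.
#' @param vpg_sign Sign convention passed to [vpg()].
#' @return Tibble keyed by `plot_id` (and `stage`, `year` if present)
#'   with columns `CWSI` (window mean) and `n_hours`.
#' @export
summarise_cwsi <- function(microclimate, baseline, window = c(10, 14),
                           vpg_sign = 1) {
  check_columns(microclimate, c("plot_id", "Tc", "Ta", "RH"), "microclimate")
  mc <- tibble::as_tibble(microclimate)
  mc <- dplyr::filter(mc, record_hour(mc) >= window[1],
                      record_hour(mc) <= window[2])
  if (nrow(mc) == 0) {
    stop_ricelwc("no microclimate records inside the hour window",
                 class = "ricelwc_error_validation")
  }
  mc$CWSI <- cwsi(mc$Tc, mc$Ta, mc$RH, baseline, vpg_sign = vpg_sign)$CWSI
  keys <- intersect(c("plot_id", "year", "stage"), names(mc))
  mc %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(n_hours = dplyr::n(), CWSI = mean(.data$CWSI),
                     .groups = "drop")
}

#' @export
tidy.lwc_baseline <- function(x, ...) {
  tibble::tibble(term = c("A (intercept)", "B (slope)"),
                 estimate = c(x$A, x$B))
}

#' @export
glance.lwc_baseline <- function(x, ...) {
  tibble::tibble(n_fit = x$n_fit, r2_fit = x$r2_fit)
}
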