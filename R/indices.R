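# Vegetation indices computed from averaged canopy spectra stored as wide
# tibbles with reflectance columns "R350".."R2500" (fractions, 1-nm grid).

band_columns <- function(data) {
  grep("^R\\d+$", names(data), value = TRUE)
}

band_wavelengths <- function(data) {
  as.integer(sub("^R", "", band_columns(data)))
}

spectral_matrix <- function(data) {
  cols <- band_columns(data)
  if (length(cols) == 0) {
    stop_ricelwc("no reflectance columns (expected names like 'R1287')",
                 class = "ricelwc_error_schema")
  }
  wl <- as.integer(sub("^R", "", cols))
  ord <- order(wl)
  list(R = as.matrix(data[cols[ord]]), wavelengths = wl[ord],
       meta = data[setdiff(names(data), cols)])
}

#' Reflectance at a wavelength
#'
#' Exact lookup on the 1-nm grid, no interpolation. Off-grid wavelengths
#' raise an error naming the nearest grid bands.
#'
#' @param spectra Wide spectra tibble with `R<wavelength>` columns.
#' @param wavelength Wavelength in nm; must be a grid column.
#' @return Numeric vector of reflectance (one value per row of `spectra`).
#' @export
reflectance_at <- function(spectra, wavelength) {
  col <- paste0("R", format(wavelength, scientific = FALSE, trim = TRUE))
  if (!col %in% names(spectra)) {
    wl <- band_wavelengths(spectra)
    near <- wl[order(abs(wl - wavelength))][seq_len(min(2, length(wl)))]
    stop_ricelwc(
      sprintf("wavelength %s nm is not on the grid; nearest grid bands: %s",
              format(wavelength), paste(near, collapse = ", ")),
      class = "ricelwc_error_offgrid"
    )
  }
  spectra[[col]]
}

#' Two-band normalized difference index
#'
#' ND(lambda1, lambda2) = (R_l1 - R_l2) / (R_l1 + R_l2), antisymmetric in
#' the band order and bounded in \[-1, 1\] for positive reflectance.
#'
#' @inheritParams reflectance_at
#' @param lambda1,lambda2 Band wavelengths in nm (grid columns).
#' @return Numeric vector of index values.
#' @examples
#' df <- tibble::tibble(R1287 = 0.45, R1673 = 0.30)
#' normalized_difference(df, 1287, 1673) # 0.2
#' @export
normalized_difference <- function(spectra, lambda1, lambda2) {
  r1 <- reflectance_at(spectra, lambda1)
  r2 <- reflectance_at(spectra, lambda2)
  s <- r1 + r2
  if (any(s == 0)) {
    stop_ricelwc(
      sprintf("ND(%d, %d) undefined: zero band sum", lambda1, lambda2),
      class = "ricelwc_error_ratio"
    )
  }
  (r1 - r2) / s
}

# Registry of the classical water-sensitive indices. Two-band
# normalized-difference entries are declared by their band pair; ratio
# indices carry their own function. Additional ND-type indices can be
# supplied at call time through `extra_nd`.
vi_registry <- function() {
  list(
    NDVI = list(type = "nd",    bands = c(895, 675)),
    NDII = list(type = "nd",    bands = c(819, 1600)),
    NDWI = list(type = "nd",    bands = c(860, 1240)),
    WI   = list(type = "ratio", bands = c(970, 900)),
    MSI  = list(type = "ratio", bands = c(1600, 820))
  )
}

ratio_index <- function(spectra, bands, name) {
  den <- reflectance_at(spectra, bands[2])
  if (any(den == 0)) {
    stop_ricelwc(sprintf("%s undefined: zero denominator band R%d",
                         name, bands[2]),
                 class = "ricelwc_error_ratio")
  }
  reflectance_at(spectra, bands[1]) / den
}

#' Classical and tunable vegetation indices
#'
#' Computes the optimised two-band normalized-difference index
#' `ND` at `nd_pair` plus the five classical indices NDVI
#' (895, 675), NDII (819, 1600), NDWI (860, 1240), WI (R970/R900) and
#' MSI (R1600/R820), all read directly off the 1-nm grid.
#'
#' @inheritParams reflectance_at
#' @param nd_pair Integer pair (lambda1, lambda2) for the optimised ND,
#'   default `c(1287, 1673)`.
#' @param extra_nd Optional named list of extra two-band ND definitions,
#'   e.g. `list(ND_custom = c(1200, 1700))`.
#' @return Tibble of the metadata columns of `spectra` plus one column
#'   per index.
#' @export
classic_indices <- function(spectra, nd_pair = c(1287, 1673),
                            extra_nd = NULL) {
  sm <- spectral_matrix(spectra)
  out <- tibble::as_tibble(sm$meta)
  out$ND <- normalized_difference(spectra, nd_pair[1], nd_pair[2])
  for (name in names(vi_registry())) {
    def <- vi_registry()[[name]]
    out[[name]] <- if (def$type == "nd") {
      normalized_difference(spectra, def$bands[1], def$bands[2])
    } else {
      ratio_index(spectra, def$bands, name)
    }
  }
  for (name in names(extra_nd)) {
    p <- extra_nd[[name]]
    out[[name]] <- normalized_difference(spectra, p[1], p[2])
  }
  out
}
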