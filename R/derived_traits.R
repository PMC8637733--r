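#' Stemwood volume from diameter and height
#'
#' Cylinder approximation `V = 0.785 * DBH^2 * H`; the coefficient is the
#' form factor pi/4, so any single consistent length unit for both arguments
#' gives a volume in that unit cubed.
#'
#' @param dbh diameter at breast height (length).
#' @param h tree height (same length unit as `dbh`).
#' @return stemwood volume, `0.785 * dbh^2 * h`.
#' @export
stemwood_volume <- function(dbh, h) {
  if (any(dbh < 0, na.rm = TRUE) || any(h < 0, na.rm = TRUE)) {
    stop("dbh and h must be non-negative")
  }
  0.785 * dbh^2 * h
}

#' Stemwood biomass from volume and wood density
#'
#' `SB = V * WD`; units must be consistent (e.g. volume in m^3 and density
#' in kg/m^3 gives biomass in kg).
#'
#' @param v stemwood volume (non-negative).
#' @param wd wood (basic) density (strictly positive).
#' @return stemwood biomass `v * wd`.
#' @export
stemwood_biomass <- function(v, wd) {
  if (any(v < 0, na.rm = TRUE)) stop("volume must be non-negative")
  if (any(wd <= 0, na.rm = TRUE)) stop("wood density must be positive")
  v * wd
}

#' Leaf length/width ratio
#'
#' @param ll leaf length.
#' @param lw leaf width (same unit, strictly positive).
#' @return unitless ratio `ll / lw`.
#' @export
length_width_ratio <- function(ll, lw) {
  if (any(lw <= 0, na.rm = TRUE)) stop("leaf width must be positive")
  ll / lw
}

#' Append derived traits to a phenotype table
#'
#' Adds whichever of the derived columns the measured traits allow:
#' `V` (stemwood volume, m^3) from `DBH` and `H`, `SB` (stemwood biomass,
#' kg) from `V` and `WD`, and `L_W` (leaf length/width ratio) from `LL` and
#' `LW`.  By convention `DBH` is stored in mm and `H` in m; `DBH` is
#' converted to m before the volume formula, and `WD` (g/cm^3) to kg/m^3
#' before the biomass product.  The unit convention is configurable and, by
#' affine invariance of the LR scan, has no effect on QTL calls.
#'
#' @param phen a [phenotype_table()].
#' @param dbh_unit unit the `DBH` column is stored in (`"mm"`, `"cm"` or
#'   `"m"`).
#' @return The `phenotype_table` with derived columns appended.
#' @export
derive_traits <- function(phen, dbh_unit = c("mm", "cm", "m")) {
  dbh_unit <- match.arg(dbh_unit)
  to_m <- c(mm = 1e-3, cm = 1e-2, m = 1)[[dbh_unit]]
  tr <- trait_names(phen)
  if (all(c("DBH", "H") %in% tr)) {
    phen$V <- stemwood_volume(phen$DBH * to_m, phen$H)
  }
  if (all(c("V", "WD") %in% names(phen))) {
    phen$SB <- stemwood_biomass(phen$V, phen$WD * 1000)
  }
  if (all(c("LL", "LW") %in% tr)) {
    phen$L_W <- length_width_ratio(phen$LL, phen$LW)
  }
  phenotype_table(phen)
}
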