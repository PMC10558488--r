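#' Molecular weights of B vitamins used for molar conversions
#'
#' Fixed lookup (g/mol): B1 265.355, B2 376.36, NIA 123.111, B6 169.18,
#' PA 219.23, Biotin 244.31, Folate 441.4, B12 1355.388. Derivative
#' heterogeneity is deliberately ignored; one representative mass per vitamin.
#'
#' @return Named numeric vector.
#' @export
vitamin_mw_table <- function() {
  c(B1 = 265.355, B2 = 376.36, NIA = 123.111, B6 = 169.18,
    PA = 219.23, Biotin = 244.31, Folate = 441.4, B12 = 1355.388)
}

#' Unit conversions onto the common millimolar scale
#'
#' All pipeline statistics run on molar concentrations (mM).
#'
#' * `tissue_to_molar()`: tissue amounts in micromoles per gram map one-to-one
#'   onto mM under a tissue specific gravity of exactly 1.0 g/cm^3.
#' * `proteome_share_to_molar()`: a proteome abundance share (fraction of
#'   total protein, or ppm) times an assumed total protein concentration of
#'   5 mM.
#' * `mass_to_molar()`: food-composition values in mg per 100 g, converted via
#'   the vitamin's molecular weight assuming 100 g of food occupies 100 mL:
#'   `mM = mg_per_100g / MW * 10`.
#'
#' @param value Non-negative numeric vector (micromoles per gram of tissue).
#' @return Numeric vector in mM.
#' @export
#' @examples
#' tissue_to_molar(1)                      # 1 mM
#' proteome_share_to_molar(200, unit = "ppm")  # 0.001 mM
#' mass_to_molar(123.111, "NIA")           # 10 mM
tissue_to_molar <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("tissue amounts must be non-negative")
  value * 1.0
}

#' @rdname tissue_to_molar
#' @param share Abundance share in `[0, 1]`, or ppm when `unit = "ppm"`.
#' @param unit `"share"` or `"ppm"`.
#' @param total_protein_mM Assumed total protein concentration (default 5 mM).
#' @export
proteome_share_to_molar <- function(share, unit = c("share", "ppm"),
                                    total_protein_mM = 5) {
  unit <- match.arg(unit)
  if (any(share < 0, na.rm = TRUE)) stop("abundance shares must be non-negative")
  if (unit == "share" && any(share > 1, na.rm = TRUE)) {
    stop("share > 1; pass unit = \"ppm\" for parts-per-million data")
  }
  frac <- if (unit == "ppm") share / 1e6 else share
  frac * total_protein_mM
}

#' @rdname tissue_to_molar
#' @param mg_per_100g Mass concentration from a food-composition table.
#' @param vitamin Vitamin tag present in [vitamin_mw_table()].
#' @export
mass_to_molar <- function(mg_per_100g, vitamin) {
  mw <- vitamin_mw_table()
  if (!vitamin %in% names(mw)) {
    stop("unknown vitamin tag '", vitamin, "'; known: ",
         paste(names(mw), collapse = ", "))
  }
  if (any(mg_per_100g < 0, na.rm = TRUE)) stop("mass values must be non-negative")
  # mg/100 g over g/mol gives mmol/100 mL at density 1; x10 to mmol/L
  mg_per_100g / mw[[vitamin]] * 10
}

#' Convert a whole concentration matrix to mM
#'
#' Applies the unit conversion matching the matrix's unit tag to every cell.
#' `intensity` matrices cannot be converted (no absolute scale) and raise an
#' error.
#'
#' @param m A [conc_matrix()].
#' @param total_protein_mM Total protein concentration used for share/ppm data.
#' @return A [conc_matrix()] with unit `"mM"`.
#' @export
convert_matrix_to_molar <- function(m, total_protein_mM = 5) {
  unit <- conc_unit(m)
  vals <- unclass(m)
  out <- switch(unit,
    mM = vals,
    umol_per_g = tissue_to_molar(vals),
    share = proteome_share_to_molar(vals, "share", total_protein_mM),
    ppm = proteome_share_to_molar(vals, "ppm", total_protein_mM),
    stop("cannot convert unit '", unit, "' to mM without a molecular-weight map")
  )
  conc_matrix(out, unit = "mM", entity_kind = entity_kind(m))
}
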