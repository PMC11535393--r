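#' Conversion constants for absolute intracellular quantification
#'
#' Omics measurements are normalised to dry cell weight (gDCW); converting
#' them to intracellular molar concentrations requires the cell count per
#' gDCW, the single-cell volume and (for proteins measured per µg of total
#' protein) the protein fraction of biomass. Defaults are literature values
#' for *S. cerevisiae* grown on ammonium medium: 6.59e10 cells/gDCW, 66 fL
#' per cell, 0.63 g protein/gDCW.
#'
#' @param cells_per_gdcw cells per gram dry cell weight.
#' @param cell_volume_fl single-cell volume in femtolitres (= µm^3).
#' @param protein_fraction grams of protein per gDCW.
#' @return object of class `conversion_constants`.
#' @export
conversion_constants <- function(cells_per_gdcw = 6.59e10,
                                 cell_volume_fl = 66,
                                 protein_fraction = 0.63) {
  .stopifnot_scalar(cells_per_gdcw, "cells_per_gdcw", positive = TRUE)
  .stopifnot_scalar(cell_volume_fl, "cell_volume_fl", positive = TRUE)
  .stopifnot_scalar(protein_fraction, "protein_fraction", positive = TRUE)
  structure(list(cells_per_gdcw = cells_per_gdcw,
                 cell_volume_fl = cell_volume_fl,
                 protein_fraction = protein_fraction),
            class = "conversion_constants")
}

#' @export
print.conversion_constants <- function(x, ...) {
  cat(sprintf(paste0("Conversion constants: %.3g cells/gDCW, %g fL/cell, ",
                     "%g g protein/gDCW\n  (cell volume per gDCW: %.4g L)\n"),
              x$cells_per_gdcw, x$cell_volume_fl, x$protein_fraction,
              .vol_l_per_gdcw(x)))
  invisible(x)
}

# litres of cell volume per gram dry cell weight
.vol_l_per_gdcw <- function(const) {
  const$cells_per_gdcw * const$cell_volume_fl * 1e-15
}

#' Convert a biomass-specific metabolite amount to intracellular concentration
#'
#' `q` µmol/gDCW of a metabolite, distributed over the aggregate cell volume
#' per gDCW, corresponds to `q / (cells_per_gdcw * cell_volume_fl * 1e-15)`
#' µM. With the default constants 1 µmol/gDCW is 229.9 µM.
#'
#' @param q metabolite amount(s), µmol/gDCW, >= 0.
#' @param const a [conversion_constants()].
#' @return intracellular concentration(s), µM. Linear in `q`.
#' @export
amount_to_concentration <- function(q, const = conversion_constants()) {
  stopifnot(inherits(const, "conversion_constants"))
  if (any(!is.finite(q)) || any(q < 0))
    .schema_error("metabolite amounts (umol/gDCW) must be finite and >= 0")
  q / .vol_l_per_gdcw(const)  # umol/L = uM
}

#' Inverse of [amount_to_concentration()]
#' @param conc concentration(s), µM, >= 0.
#' @inheritParams amount_to_concentration
#' @return amount(s), µmol/gDCW.
#' @export
concentration_to_amount <- function(conc, const = conversion_constants()) {
  stopifnot(inherits(const, "conversion_constants"))
  if (any(!is.finite(conc)) || any(conc < 0))
    .schema_error("concentrations must be finite and >= 0")
  conc * .vol_l_per_gdcw(const)
}

#' Convert a protein-specific enzyme amount to intracellular concentration
#'
#' Enzyme abundances from absolute quantitative proteomics come in fmol per µg
#' of total protein. fmol/µg is numerically nmol/g protein; multiplying by the
#' protein fraction (g protein/gDCW) gives nmol/gDCW, and dividing by the cell
#' volume per gDCW gives nM. With defaults 1 fmol/µg is 144.8 nM.
#'
#' @param x enzyme abundance(s), fmol/µg protein, >= 0.
#' @param const a [conversion_constants()].
#' @return intracellular enzyme concentration(s), nM. Linear in `x`.
#' @export
protein_to_concentration <- function(x, const = conversion_constants()) {
  stopifnot(inherits(const, "conversion_constants"))
  if (any(!is.finite(x)) || any(x < 0))
    .schema_error("protein abundances (fmol/ug) must be finite and >= 0")
  x * const$protein_fraction / .vol_l_per_gdcw(const)
}

#' Inverse of [protein_to_concentration()]
#' @param conc_nm enzyme concentration(s), nM, >= 0.
#' @inheritParams protein_to_concentration
#' @return abundance(s), fmol/µg protein.
#' @export
concentration_to_protein <- function(conc_nm, const = conversion_constants()) {
  stopifnot(inherits(const, "conversion_constants"))
  if (any(!is.finite(conc_nm)) || any(conc_nm < 0))
    .schema_error("concentrations must be finite and >= 0")
  conc_nm * .vol_l_per_gdcw(const) / const$protein_fraction
}

#' Production flux of an accumulating end-product from pool dilution
#'
#' At metabolic steady state during exponential growth, and assuming no
#' degradation or reutilisation, an end-product's synthesis flux is balanced
#' solely by growth dilution: flux = concentration × growth rate.
#'
#' @param conc product concentration(s), µM, >= 0.
#' @param mu specific growth rate, 1/h, > 0.
#' @return production flux(es), µM/h.
#' @export
dilution_flux <- function(conc, mu) {
  if (any(!is.finite(conc)) || any(conc < 0))
    .schema_error("concentrations must be finite and >= 0")
  if (any(!is.finite(mu)) || any(mu <= 0))
    .schema_error("growth rate mu must be > 0 (dilution flux is only defined for growing cells)")
  conc * mu
}

#' Turnover number from maximal rate and enzyme concentration
#'
#' `kcat = vmax / enzyme_conc`, converted from 1/h to 1/s.
#'
#' @param vmax maximal rate, µM/h.
#' @param enzyme_conc enzyme concentration, µM (42 nM = 0.042 µM).
#' @return turnover number, 1/s.
#' @examples
#' turnover_number(849, 0.042)  # ~5.6 /s
#' @export
turnover_number <- function(vmax, enzyme_conc) {
  if (any(!is.finite(enzyme_conc)) || any(enzyme_conc <= 0))
    .schema_error("enzyme concentration must be > 0")
  if (any(!is.finite(vmax)) || any(vmax < 0))
    .schema_error("vmax must be finite and >= 0")
  vmax / (enzyme_conc * 3600)
}

# --- strain-panel measurement records ---------------------------------------

.conc_units   <- c("uM", "umol_per_gDCW")
.enzyme_units <- c("nM", "fmol_per_ug")

.panel_required_cols <- c("strain_id", "replicate", "growth_rate_per_h",
                          "substrate", "substrate_unit",
                          "product", "product_unit")
.panel_optional_cols <- c("promoter", "crt_e_copies", "enzyme", "enzyme_unit",
                          "substrate_below_loq", "product_below_loq",
                          "enzyme_below_loq")

#' Read a strain-panel measurement table
#'
#' Delimited text (comma or tab, auto-detected), one row per strain ×
#' replicate, with header columns `strain_id, promoter, replicate,
#' growth_rate_per_h, substrate, substrate_unit, product, product_unit`
#' and optionally `crt_e_copies, enzyme, enzyme_unit, *_below_loq`.
#' Concentration units are from the closed set `uM` / `umol_per_gDCW`,
#' enzyme units `nM` / `fmol_per_ug`; replicate indices are 1-based.
#'
#' @param path file path.
#' @return validated data.frame of measurement records.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) .schema_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  rec <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  validate_records(rec)
}

#' Validate strain-panel measurement records
#'
#' Checks required columns, the closed unit sets, positive growth rates and
#' non-negative concentrations. Missing `*_below_loq` columns default to
#' `FALSE`.
#'
#' @param rec data.frame of measurement records (see [read_panel()]).
#' @return the validated (possibly completed) data.frame, invisibly classed.
#' @export
validate_records <- function(rec) {
  if (!is.data.frame(rec)) .schema_error("records must be a data.frame")
  missing_cols <- setdiff(.panel_required_cols, names(rec))
  if (length(missing_cols))
    .schema_error(paste("missing required columns:",
                        paste(missing_cols, collapse = ", ")))
  for (fl in c("substrate_below_loq", "product_below_loq", "enzyme_below_loq"))
    if (is.null(rec[[fl]])) rec[[fl]] <- FALSE else rec[[fl]] <- as.logical(rec[[fl]])
  bad <- which(!is.finite(rec$growth_rate_per_h) | rec$growth_rate_per_h <= 0)
  if (length(bad))
    .schema_error(paste("growth_rate_per_h must be > 0; offending rows:",
                        paste(bad, collapse = ", ")))
  for (qt in c("substrate", "product")) {
    bad <- which(!is.finite(rec[[qt]]) | rec[[qt]] < 0)
    if (length(bad))
      .schema_error(sprintf("%s must be finite and >= 0; offending rows: %s",
                            qt, paste(bad, collapse = ", ")))
    u <- unique(rec[[paste0(qt, "_unit")]])
    if (!all(u %in% .conc_units))
      .schema_error(sprintf("unknown %s_unit value(s): %s (allowed: %s)",
                            qt, paste(setdiff(u, .conc_units), collapse = ", "),
                            paste(.conc_units, collapse = ", ")))
    if (length(u) > 1L)
      .schema_error(sprintf(
        "mixed %s_unit values (%s); offending rows: %s", qt,
        paste(u, collapse = ", "),
        paste(which(rec[[paste0(qt, "_unit")]] != u[1L]), collapse = ", ")))
  }
  if (!is.null(rec$enzyme) && any(is.finite(rec$enzyme))) {
    u <- unique(rec$enzyme_unit[is.finite(rec$enzyme)])
    if (!all(u %in% .enzyme_units) || length(u) > 1L)
      .schema_error(paste("enzyme_unit must be one of",
                          paste(.enzyme_units, collapse = "/"),
                          "and consistent across rows"))
  }
  rec
}

#' Build a kinetic dataset from strain-panel measurements
#'
#' Converts substrate and product measurements to µM (via
#' [amount_to_concentration()] when recorded in µmol/gDCW) and enzyme
#' abundances to nM, computes the per-record reaction rate as the product
#' dilution flux `product_uM * growth_rate`, applies the below-LOQ policy, and
#' returns the (substrate, rate) pairs ready for [mm_fit()]. Replicates are
#' retained as independent points, never averaged.
#'
#' The flux calculation is valid only under the steady-state, no-degradation
#' assumption; this is recorded in the dataset metadata.
#'
#' @param records measurement records ([read_panel()] /
#'   [generate_strain_panel()] output).
#' @param const a [conversion_constants()].
#' @param loq_policy what to do with records flagged below the limit of
#'   quantification: `"drop"` (default; the record is excluded and logged) or
#'   `"substitute"` (the flagged value is replaced by LOQ/2; requires
#'   `loq_substrate` / `loq_product`).
#' @param loq_substrate,loq_product limits of quantification in µM, used only
#'   under the `"substitute"` policy.
#' @return object of class `kinetic_dataset`: a data.frame with columns
#'   `substrate` (µM), `rate` (µM/h), `strain_id`, `replicate`, plus
#'   attributes `constants`, `dropped` (excluded records), `loq_policy`,
#'   `enzyme_nm` (mean enzyme concentration in nM if measured) and
#'   `assumptions`.
#' @export
build_dataset <- function(records, const = conversion_constants(),
                          loq_policy = c("drop", "substitute"),
                          loq_substrate = NA_real_, loq_product = NA_real_) {
  loq_policy <- match.arg(loq_policy)
  rec <- validate_records(records)
  stopifnot(inherits(const, "conversion_constants"))

  to_um <- function(x, unit) {
    if (unit[1L] == "umol_per_gDCW") amount_to_concentration(x, const) else x
  }
  sub_um  <- to_um(rec$substrate, rec$substrate_unit)
  prod_um <- to_um(rec$product, rec$product_unit)

  enzyme_nm <- NA_real_
  if (!is.null(rec$enzyme) && any(is.finite(rec$enzyme))) {
    e <- rec$enzyme
    if (rec$enzyme_unit[which(is.finite(e))[1L]] == "fmol_per_ug")
      e <- protein_to_concentration(e, const)
    keep_e <- is.finite(e) & !rec$enzyme_below_loq
    if (any(keep_e)) enzyme_nm <- mean(e[keep_e])
  }

  flagged <- rec$substrate_below_loq | rec$product_below_loq
  if (loq_policy == "substitute") {
    if (any(rec$substrate_below_loq) && !is.finite(loq_substrate))
      .config_error("loq_policy 'substitute' needs a finite loq_substrate")
    if (any(rec$product_below_loq) && !is.finite(loq_product))
      .config_error("loq_policy 'substitute' needs a finite loq_product")
    sub_um[rec$substrate_below_loq] <- loq_substrate / 2
    prod_um[rec$product_below_loq] <- loq_product / 2
    keep <- rep(TRUE, nrow(rec))
  } else {
    keep <- !flagged
  }
  # zero substrate carries no kinetic information and breaks the MM fit domain
  keep <- keep & sub_um > 0

  out <- data.frame(substrate = sub_um[keep],
                    rate = dilution_flux(prod_um[keep],
                                         rec$growth_rate_per_h[keep]),
                    strain_id = rec$strain_id[keep],
                    replicate = rec$replicate[keep],
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("kinetic_dataset", "data.frame"),
            constants = const,
            dropped = rec[!keep, , drop = FALSE],
            loq_policy = loq_policy,
            enzyme_nm = enzyme_nm,
            assumptions = paste("rates are product dilution fluxes:",
                                "metabolic steady state, no product",
                                "degradation or reutilisation assumed"))
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("Kinetic dataset: %d (substrate, rate) pairs from %d strains\n",
              nrow(x), length(unique(x$strain_id))))
  if (nrow(x))
    cat(sprintf("  substrate span: %.4g - %.4g uM (fold range %.3g)\n",
                min(x$substrate), max(x$substrate), fold_range(x)))
  nd <- nrow(attr(x, "dropped"))
  if (!is.null(nd) && nd > 0)
    cat(sprintf("  %d record(s) excluded (below-LOQ policy '%s' or zero substrate)\n",
                nd, attr(x, "loq_policy")))
  e <- attr(x, "enzyme_nm")
  if (is.finite(e)) cat(sprintf("  enzyme concentration: %.3g nM\n", e))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Fold range of the substrate span
#'
#' @param dataset a `kinetic_dataset` (or data.frame with a `substrate`
#'   column).
#' @param by_strain if `TRUE` (default) the ratio of the largest to smallest
#'   strain-mean substrate concentration; if `FALSE`, over individual pairs.
#' @return max/min substrate ratio.
#' @export
fold_range <- function(dataset, by_strain = TRUE) {
  s <- dataset$substrate
  if (by_strain && !is.null(dataset$strain_id))
    s <- tapply(s, dataset$strain_id, mean)
  max(s) / min(s)
}

#' Write a kinetic dataset with its provenance
#'
#' Writes the converted (substrate, rate) table as CSV and, alongside it, a
#' JSON provenance block (`<path>.provenance.json`) recording the conversion
#' constants, LOQ policy and steady-state assumptions used.
#'
#' @param dataset a `kinetic_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  const <- attr(dataset, "constants")
  prov <- list(
    constants = const[],
    loq_policy = attr(dataset, "loq_policy"),
    n_pairs = nrow(dataset),
    n_dropped = nrow(attr(dataset, "dropped")),
    enzyme_nm = if (is.finite(attr(dataset, "enzyme_nm")))
      attr(dataset, "enzyme_nm") else NULL,
    assumptions = attr(dataset, "assumptions"))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
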