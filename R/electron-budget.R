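# Stoichiometric electron accounting: electron equivalents of organics via
# the 4x + y - 2z rule, COD <-> coulomb conversions (8 g COD per mol e-),
# coulombic efficiencies, per-reactor multi-donor budgets, and the
# classification that separates cathode-sufficient production from
# multi-donor (electro-)fermentation.

#' Parse a CxHyOz formula into element counts
#' @noRd
parse_cho_formula <- function(formula) {
  formula <- gsub("\\s", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(tokens) || paste(tokens, collapse = "") != formula)
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  el <- gsub("[0-9]", "", tokens)
  n <- as.numeric(ifelse(gsub("[^0-9]", "", tokens) == "", "1",
                         gsub("[^0-9]", "", tokens)))
  counts <- tapply(n, el, sum)
  extra <- setdiff(names(counts), c("C", "H", "O"))
  if (length(extra))
    stop(sprintf(
      "formula '%s' contains element(s) %s outside C/H/O; supply an explicit ne",
      formula, paste(extra, collapse = ", ")), call. = FALSE)
  out <- c(C = 0, H = 0, O = 0)
  out[names(counts)] <- counts
  out
}

#' Electron equivalents of a compound
#'
#' Moles of electrons released by fully oxidising one mole of the compound to
#' CO2 and H2O. For a CxHyOz species this is `4x + y - 2z`, the electron
#' count implied by balancing `CxHyOz + ne/4 O2 -> x CO2 + y/2 H2O`.
#' Inorganic species must be registered with an explicit half-reaction
#' electron count (H2 -> 2; thiosulfate -> sulfate -> 8; Fe(III) -> Fe(II)
#' -> 1); formulas containing elements outside C/H/O are rejected with a
#' request for an explicit ne.
#'
#' @param formula formula string over C, H, O, e.g. `"C2H4O2"`.
#' @return Integer moles of electrons per mole of compound.
#' @export
#' @examples
#' electron_equivalents("C2H4O2") # acetic acid: 8
#' electron_equivalents("C4H8O2") # butyric acid: 20
electron_equivalents <- function(formula) {
  x <- parse_cho_formula(formula)
  ne <- 4 * x[["C"]] + x[["H"]] - 2 * x[["O"]]
  if (ne <= 0)
    stop(sprintf("formula '%s' yields non-positive electron equivalents",
                 formula), call. = FALSE)
  ne
}

#' Registry of donor/product compounds
#'
#' Loads the editable compound table shipped with the package (or a
#' user-supplied one in the same format) and derives per-compound electron
#' equivalents `ne` (from the C/H/O formula or the explicit override) and COD
#' `cod_gO2_per_mol = 8 * ne` (32 g O2 accepts 4 mol e-, hence 8 g COD per
#' mol e-).
#'
#' @param path delimited table with columns `name`, `formula`,
#'   `half_reaction`, `ne_override`, `mass_g_per_mol`, `role`; defaults to
#'   the registry shipped in `extdata`.
#' @return Tibble with the input columns plus `ne` and `cod_gO2_per_mol`.
#' @export
compound_registry <- function(path = system.file("extdata", "compounds.tsv",
                                                 package = "biocathode")) {
  reg <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                         progress = FALSE)
  reg$ne <- ifelse(
    !is.na(reg$ne_override), reg$ne_override,
    vapply(reg$formula, function(f) {
      if (is.na(f)) NA_real_ else electron_equivalents(f)
    }, numeric(1)))
  if (any(is.na(reg$ne) & reg$role %in% c("donor", "product", "both")))
    stop("every donor/product compound needs a formula or an ne_override",
         call. = FALSE)
  reg$cod_gO2_per_mol <- 8 * reg$ne
  tibble::as_tibble(reg)
}

#' Look up the electron equivalents of a registered compound
#' @param name compound name as in the registry.
#' @param registry output of [compound_registry()].
#' @return ne in mol e-/mol.
#' @export
compound_ne <- function(name, registry = compound_registry()) {
  i <- match(name, registry$name)
  if (is.na(i))
    stop(sprintf("compound '%s' not in registry (%s)", name,
                 paste(registry$name, collapse = ", ")), call. = FALSE)
  registry$ne[i]
}

#' Molar concentration of a compound from a mass concentration
#'
#' Boundary helper for medium recipes stated in g/L (e.g. 1.36 g/L sodium
#' formate = 20 mM formate).
#'
#' @param g_per_L mass concentration in g/L.
#' @param name registered compound name.
#' @param registry output of [compound_registry()].
#' @return Concentration in mM.
#' @export
mass_to_mM <- function(g_per_L, name, registry = compound_registry()) {
  i <- match(name, registry$name)
  if (is.na(i) || is.na(registry$mass_g_per_mol[i]))
    stop(sprintf("no molar mass registered for '%s'", name), call. = FALSE)
  g_per_L / registry$mass_g_per_mol[i] * 1000
}

#' Coulombic efficiency of one product
#'
#' Percentage of the charge passed at the cathode recovered in a product:
#' `CE% = F * ne * d[P] * V / Q * 100`, with d\[P\] the concentration increase
#' between first and last timepoints. Per-product CEs are additive; the total
#' CE is their sum, and values above 100% indicate that donors other than
#' the cathode contributed electrons.
#'
#' @param delta_mM product concentration increase in mM (>= 0).
#' @param ne electron equivalents of the product (mol e-/mol).
#' @param volume_L catholyte volume in litres.
#' @param coulombs_C charge passed at the cathode in C.
#' @return CE in percent; `NA` when `coulombs_C` is 0 (undefined, reported
#'   missing).
#' @export
coulombic_efficiency <- function(delta_mM, ne, volume_L, coulombs_C) {
  if (any(delta_mM < 0))
    stop("delta_mM must be >= 0 (production); route consumption donor-side",
         call. = FALSE)
  if (coulombs_C < 0) stop("coulombs_C must be >= 0", call. = FALSE)
  if (coulombs_C == 0) return(NA_real_)
  FARADAY * ne * (delta_mM / 1000) * volume_L / coulombs_C * 100
}

#' Charge embodied in a set of product concentration increases
#' @param deltas_mM named numeric vector of positive concentration increases.
#' @param ne named numeric vector of matching electron equivalents.
#' @param volume_L catholyte volume in litres.
#' @return Coulombs in the products, total and per product.
#' @export
product_coulombs <- function(deltas_mM, ne, volume_L) {
  stopifnot(length(deltas_mM) == length(ne))
  q <- FARADAY * ne * (deltas_mM / 1000) * volume_L
  list(total_C = sum(q), per_product_C = q)
}

#' Convert a COD decrease into coulombs
#'
#' 1 mol of electrons reduces 8 g of O2-equivalents (O2 + 4 H+ + 4 e- ->
#' 2 H2O; 32 g / 4 e-), so a COD decrease of dCOD g O2/L over volume V litres
#' carries `dCOD * V / 8 * F` coulombs. Only decreases contribute: a COD
#' increase is attributed to electroautotrophic carbon fixation and flagged,
#' contributing 0 C donor-side.
#'
#' @param delta_cod_gO2_per_L COD decrease (initial - final) in g O2/L; may
#'   be negative (increase).
#' @param volume_L catholyte volume in litres.
#' @return List with `coulombs_C` (>= 0) and `carbon_fixation_flag`
#'   (`TRUE` when COD increased).
#' @export
cod_to_coulombs <- function(delta_cod_gO2_per_L, volume_L) {
  if (!is.finite(volume_L) || volume_L <= 0)
    stop("volume_L must be > 0", call. = FALSE)
  list(coulombs_C = max(0, delta_cod_gO2_per_L) * volume_L / 8 * FARADAY,
       carbon_fixation_flag = delta_cod_gO2_per_L < 0)
}

#' COD embodied in produced organic acids
#'
#' Total oxygen demand of the measured product increases,
#' `sum(d[P] * V * 8 * ne)` in g O2. This is subtracted from the final COD
#' measurement before attributing the remaining COD decrease to yeast-extract
#' consumption, so that secreted acids are not double-counted as residual
#' substrate.
#'
#' @param deltas_mM named positive concentration increases in mM.
#' @param ne matching electron equivalents.
#' @param volume_L catholyte volume in litres.
#' @return COD of the products in g O2 (total grams, not per litre).
#' @export
organic_acid_cod_correction <- function(deltas_mM, ne, volume_L) {
  stopifnot(length(deltas_mM) == length(ne))
  if (any(deltas_mM < 0)) stop("product deltas must be >= 0", call. = FALSE)
  sum((deltas_mM / 1000) * volume_L * 8 * ne)
}

#' Yeast-extract electron donation from COD bookkeeping
#'
#' Coulombs attributable to microbial consumption of the yeast extract:
#' the COD of produced organic acids is subtracted from the final COD
#' measurement, the corrected decrease `COD_initial - (COD_final -
#' COD_products)` is floored at 0 and converted at 8 g COD per mol e-.
#'
#' @param cod a [cod_measurement()].
#' @param product_cod_gO2 COD of produced acids in g O2 (total grams), from
#'   [organic_acid_cod_correction()].
#' @param volume_L catholyte volume in litres.
#' @return List with `coulombs_C` and `carbon_fixation_flag`.
#' @export
yeast_extract_coulombs <- function(cod, product_cod_gO2, volume_L) {
  stopifnot(inherits(cod, "cod_measurement"))
  corrected_final <- cod$cod_final_gO2_per_L - product_cod_gO2 / volume_L
  cod_to_coulombs(cod$cod_initial_gO2_per_L - corrected_final, volume_L)
}

#' Thiosulfate-as-donor test with stoichiometric sulfate check
#'
#' Thiosulfate oxidation (S2O3^2- + 5 H2O -> 2 SO4^2- + 10 H+ + 8 e-) is
#' accepted as an electron donation route only when thiosulfate was consumed,
#' sulfate was produced, and the sulfate yield is close to the stoichiometric
#' 2 mol per mol thiosulfate: `produced_sulfate / (2 * consumed_thio)` within
#' `[1 - tolerance, 1 + tolerance]`. Otherwise concentration changes are
#' attributed to acceptor use or membrane crossover and contribute 0 C.
#'
#' @param delta_thio_mM,delta_sulfate_mM final - initial concentration
#'   changes in mM (consumption is negative).
#' @param volume_L catholyte volume in litres.
#' @param tolerance relative tolerance on the 1:2 ratio (default 0.5).
#' @return List with `is_donor` and `q_thiosulfate_C` (8 e- per mol
#'   thiosulfate when accepted, else 0).
#' @export
thiosulfate_donor_check <- function(delta_thio_mM, delta_sulfate_mM,
                                    volume_L, tolerance = 0.5) {
  consumed <- -delta_thio_mM
  is_donor <- consumed > 0 && delta_sulfate_mM > 0 && {
    ratio <- delta_sulfate_mM / (2 * consumed)
    ratio >= 1 - tolerance && ratio <= 1 + tolerance
  }
  list(is_donor = is_donor,
       q_thiosulfate_C = if (is_donor)
         (consumed / 1000) * volume_L * 8 * FARADAY else 0)
}

#' Coulombs from formate consumption
#'
#' Formate oxidation (HCOO- -> CO2 + H+ + 2 e-) donates 2 electrons per mole.
#' Only net consumption counts donor-side; net production is routed to the
#' product side of the budget.
#'
#' @param delta_formate_mM final - initial formate change in mM (consumption
#'   negative).
#' @param volume_L catholyte volume in litres.
#' @return Coulombs donated (0 when formate was produced).
#' @export
formate_coulombs <- function(delta_formate_mM, volume_L) {
  consumed <- max(0, -delta_formate_mM)
  (consumed / 1000) * volume_L * 2 * FARADAY
}

#' Assemble the per-reactor multi-donor electron budget
#'
#' Compares the coulombs available from the four candidate electron donors
#' (cathode, formate, thiosulfate, yeast extract) against the coulombs
#' embodied in the produced organic acids, computes per-product and total
#' coulombic efficiencies relative to the cathode charge, and classifies the
#' reactor:
#' * `cathode_sufficient` - product coulombs are covered by the cathode
#'   alone (CE <= 100%); consistent with electrotrophy/electrosynthesis.
#' * `multi_donor_electrofermentation` - products exceed the cathode charge
#'   but are covered by the summed donors; the cathode at most supplemented a
#'   fermentative metabolism.
#' * `donor_deficit_flag` - products exceed every accounted donor; an
#'   unmeasured donor or a bookkeeping gap.
#'
#' The cathode term is the total integrated charge over the run (the CE
#' denominator is the full current integral); biocoulombs enter the activity
#' score, not the budget. Acceptor consumption (nitrate, sulfate as acceptor,
#' Fe(III)) is reported elsewhere and never enters the donor side.
#'
#' @param q_cathode_C total integrated cathode charge in C.
#' @param product_deltas_mM named positive concentration increases in mM.
#' @param product_ne matching electron equivalents.
#' @param volume_L catholyte volume in litres.
#' @param q_formate_C,q_thiosulfate_C,q_yeast_extract_C donor coulombs
#'   (default 0; pass `NA` to mark a donor unmeasured).
#' @param carbon_fixation_flag from the COD bookkeeping.
#' @return An `electron_budget` list: donor terms, per-product and total
#'   product coulombs, `ce_percent` per product, `ce_total_percent`,
#'   `ce_over_100`, `classification`, `carbon_fixation_flag`.
#' @export
build_donor_budget <- function(q_cathode_C,
                               product_deltas_mM,
                               product_ne,
                               volume_L,
                               q_formate_C = 0,
                               q_thiosulfate_C = 0,
                               q_yeast_extract_C = 0,
                               carbon_fixation_flag = FALSE) {
  qp <- product_coulombs(product_deltas_mM, product_ne, volume_L)
  ce <- vapply(seq_along(product_deltas_mM), function(i)
    coulombic_efficiency(product_deltas_mM[i], product_ne[i], volume_L,
                         q_cathode_C), numeric(1))
  names(ce) <- names(product_deltas_mM)
  ce_total <- if (q_cathode_C > 0) sum(ce) else NA_real_
  donors_known <- c(q_formate_C, q_thiosulfate_C, q_yeast_extract_C)
  q_donors_total <- q_cathode_C + sum(donors_known, na.rm = TRUE)
  classification <- if (qp$total_C <= q_cathode_C) {
    "cathode_sufficient"
  } else if (qp$total_C <= q_donors_total) {
    "multi_donor_electrofermentation"
  } else {
    "donor_deficit_flag"
  }
  structure(
    list(q_cathode_C = q_cathode_C,
         q_formate_C = q_formate_C,
         q_thiosulfate_C = q_thiosulfate_C,
         q_yeast_extract_C = q_yeast_extract_C,
         q_products_C = qp$total_C,
         q_per_product_C = qp$per_product_C,
         ce_percent = ce,
         ce_total_percent = ce_total,
         ce_over_100 = isTRUE(ce_total > 100),
         classification = classification,
         carbon_fixation_flag = isTRUE(carbon_fixation_flag)),
    class = "electron_budget")
}

#' @export
print.electron_budget <- function(x, ...) {
  cat(sprintf(
    "<electron_budget> cathode %.3g C | formate %.3g | thiosulfate %.3g | yeast extract %.3g\n",
    x$q_cathode_C, x$q_formate_C, x$q_thiosulfate_C, x$q_yeast_extract_C))
  cat(sprintf("  products %.3g C, total CE %.1f%%%s -> %s\n",
              x$q_products_C,
              if (is.na(x$ce_total_percent)) NA else x$ce_total_percent,
              if (x$ce_over_100) " (>100%, extra donor)" else "",
              x$classification))
  invisible(x)
}

#' Extent of iron(III) reduction and magnetite consistency
#'
#' Fraction of the total iron pool reduced to Fe(II). Complete reduction of
#' ferrihydrite to magnetite (Fe3O4 = one Fe(II) per three Fe) caps the
#' microbially producible fraction at 1/3; fractions at or below
#' `1/3 + tolerance` are consistent with the magnetite endpoint.
#'
#' @param fe2_mM measured Fe(II) in mM.
#' @param fe_total_mM total iron initially supplied in mM.
#' @param tolerance slack on the 1/3 cap (default 0.05).
#' @return List with `fe2_mM`, `fe_total_mM`, `fraction_reduced`,
#'   `magnetite_consistent`.
#' @export
iron_reduction_extent <- function(fe2_mM, fe_total_mM, tolerance = 0.05) {
  if (fe2_mM < 0 || fe_total_mM <= 0)
    stop("iron concentrations must be >= 0 with fe_total > 0", call. = FALSE)
  if (fe2_mM > fe_total_mM)
    stop("fe2_mM cannot exceed fe_total_mM", call. = FALSE)
  fraction <- fe2_mM / fe_total_mM
  list(fe2_mM = fe2_mM, fe_total_mM = fe_total_mM,
       fraction_reduced = fraction,
       magnetite_consistent = fraction <= 1 / 3 + tolerance)
}
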