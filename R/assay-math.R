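#' A serial-dilution step
#'
#' @param source_concentration Concentration of the solution being diluted
#'   (any unit: U/mL, ug/mL, mM, ...).
#' @param source_volume Volume of that solution added (uL), > 0.
#' @param diluent_volume Volume of diluent (or pre-mixed recipient) it is
#'   added to (uL), >= 0.
#' @return A one-row tibble describing the step.
#' @export
dilution_step <- function(source_concentration, source_volume, diluent_volume) {
  if (!all(is.finite(c(source_concentration, source_volume, diluent_volume))))
    stop("dilution step values must be finite", call. = FALSE)
  if (source_volume <= 0) stop("`source_volume` must be > 0", call. = FALSE)
  if (diluent_volume < 0) stop("`diluent_volume` must be >= 0", call. = FALSE)
  if (source_concentration < 0)
    stop("`source_concentration` must be >= 0", call. = FALSE)
  tibble::tibble(source_concentration = source_concentration,
                 source_volume = source_volume,
                 diluent_volume = diluent_volume)
}

#' Concentration after a chain of serial dilutions
#'
#' Applies \eqn{c_{k+1} = c_k \, v_{src} / (v_{src} + v_{dil})} sequentially.
#' Only the first step's `source_concentration` is used; later steps dilute
#' the running product. With `total = "diluent"` the stated diluent volume is
#' instead treated as the total mixture volume (\eqn{c_{k+1} = c_k \,
#' v_{src} / v_{dil}}), a convention some protocols use when quoting a
#' made-up-to volume; it is exposed because published final concentrations
#' are sometimes reproducible only under that reading.
#'
#' @param chain A tibble of [dilution_step()] rows (bind with
#'   `dplyr::bind_rows()`).
#' @param total Either `"sum"` (physically correct: total = source +
#'   diluent; default) or `"diluent"` (stated volume is the total).
#' @return Final concentration in the unit of the first step.
#' @examples
#' # thrombin stock 200 U/mL: 10 uL into 90 uL buffer -> 20 U/mL
#' dilute(dilution_step(200, 10, 90))
#' @export
dilute <- function(chain, total = c("sum", "diluent")) {
  total <- match.arg(total)
  stopifnot(is.data.frame(chain), nrow(chain) >= 1L)
  conc <- chain$source_concentration[1L]
  for (k in seq_len(nrow(chain))) {
    v_src <- chain$source_volume[k]
    v_tot <- if (total == "sum") v_src + chain$diluent_volume[k]
             else chain$diluent_volume[k]
    if (v_tot <= 0) stop("total volume must be > 0", call. = FALSE)
    conc <- conc * v_src / v_tot
  }
  conc
}

#' Well recipe: component volumes dispensed into one microplate well
#'
#' @param ... Named component volumes (uL), e.g. `plasma = 25, lysis = 75,
#'   activation = 50`.
#' @return A `well_recipe` list with `volumes` and `total_volume`.
#' @export
well_recipe <- function(...) {
  volumes <- c(...)
  if (is.null(names(volumes)) || any(names(volumes) == ""))
    stop("all components must be named", call. = FALSE)
  if (any(volumes <= 0)) stop("volumes must be > 0", call. = FALSE)
  structure(list(volumes = volumes, total_volume = sum(volumes)),
            class = "well_recipe")
}

#' Final in-well concentration of a component
#'
#' The concentration of the component's mixture (after its dilution chain)
#' times the fraction of the well volume that mixture occupies.
#'
#' @param chain Dilution chain of the mixture containing the component
#'   (see [dilute()]); pass `NULL` for an undiluted stock and supply
#'   `stock_concentration`.
#' @param recipe A [well_recipe()].
#' @param component Name of the component's mixture in the recipe.
#' @param stock_concentration Concentration when `chain` is `NULL`.
#' @param total Volume convention passed to [dilute()].
#' @return Final in-well concentration.
#' @export
final_well_concentration <- function(chain, recipe, component,
                                     stock_concentration = NULL,
                                     total = c("sum", "diluent")) {
  stopifnot(inherits(recipe, "well_recipe"))
  if (!component %in% names(recipe$volumes))
    stop("unknown component: ", component, call. = FALSE)
  conc <- if (is.null(chain)) stock_concentration else dilute(chain, total)
  conc * recipe$volumes[[component]] / recipe$total_volume
}

#' Default turbidity-assay reagent preparation
#'
#' The standard validated protocol this package analyses: thrombin stock
#' (200 U/mL) diluted 10 uL into 90 uL permeation buffer; an activation
#' mixture of 54 uL diluted thrombin + 270 uL 1 M CaCl2 + 11.7 mL buffer; a
#' lysis mixture of 40 uL tPA (100 ug/mL) into 760 uL buffer, then 500 uL of
#' that into 14.5 mL buffer. Per well: 25 uL citrated plasma + 75 uL lysis
#' mixture + 50 uL activation mixture (150 uL total).
#'
#' @return A list with dilution chains (`thrombin`, `cacl2`, `tpa`) under the
#'   physically correct sum-of-volumes convention, `stated_total` variants in
#'   which each quoted diluent volume is read as the mixture's total volume,
#'   the per-well `recipe`, and units.
#' @export
assay_recipe <- function() {
  list(
    thrombin = dplyr::bind_rows(
      dilution_step(200, 10, 90),        # U/mL stock -> 20 U/mL
      dilution_step(20, 54, 270 + 11700) # into the activation mixture
    ),
    cacl2 = dplyr::bind_rows(
      dilution_step(1000, 270, 54 + 11700) # 1 M = 1000 mM
    ),
    tpa = dplyr::bind_rows(
      dilution_step(100, 40, 760),  # ug/mL
      dilution_step(5, 500, 14500)
    ),
    stated_total = list(
      thrombin = dplyr::bind_rows(
        dilution_step(200, 10, 100),
        dilution_step(20, 54, 11700)  # "11.7 mL" read as the total volume
      ),
      cacl2 = dplyr::bind_rows(dilution_step(1000, 270, 11700)),
      tpa = dplyr::bind_rows(
        dilution_step(100, 40, 760),
        dilution_step(100 * 40 / 760, 500, 14500)
      )
    ),
    recipe = well_recipe(plasma = 25, lysis = 75, activation = 50),
    units = c(thrombin = "U/mL", cacl2 = "mM", tpa = "ug/mL")
  )
}

#' Final-concentration table for the turbidity assay
#'
#' Computes the in-well concentration of every assay component from the
#' dilution chains and well recipe, under both volume conventions of
#' [dilute()]. The plasma dilution factor is the well volume over the plasma
#' volume. Note the activation-mixture CaCl2 value matches its commonly
#' quoted 7.7 mM figure only under the `"diluent"` (made-up-to-volume)
#' convention, and the quoted 0.35 ug/mL tPA figure is not reproducible from
#' the stated volumes under either convention (arithmetic gives ~0.083
#' ug/mL); both are reported as computed, not corrected.
#'
#' @return A tibble with one row per component: concentration under each
#'   convention plus unit.
#' @examples
#' assay_concentration_table()
#' @export
assay_concentration_table <- function() {
  rec <- assay_recipe()
  comp <- tibble::tibble(
    component = c("thrombin", "cacl2", "tpa"),
    mixture = c("activation", "activation", "lysis")
  )
  rows <- purrr::pmap(comp, function(component, mixture) {
    tibble::tibble(
      component = component,
      final_conc_sum = final_well_concentration(
        rec[[component]], rec$recipe, mixture, total = "sum"),
      final_conc_stated_total = final_well_concentration(
        rec$stated_total[[component]], rec$recipe, mixture, total = "diluent"),
      unit = rec$units[[component]]
    )
  })
  plasma <- tibble::tibble(
    component = "plasma_dilution_factor",
    final_conc_sum = rec$recipe$total_volume / rec$recipe$volumes[["plasma"]],
    final_conc_stated_total = rec$recipe$total_volume / rec$recipe$volumes[["plasma"]],
    unit = "fold"
  )
  dplyr::bind_rows(rows, plasma)
}

#' Convert HbA1c from NGSP percent to IFCC mmol/mol
#'
#' IFCC master equation: \eqn{(\%HbA1c - 2.15) \times 10.929}, rounded to
#' the nearest integer for reporting. 6.0% corresponds to 42 mmol/mol, the
#' WHO normoglycemia cut-off.
#'
#' @param percent HbA1c in NGSP % units, >= 2.15.
#' @param round Round to the nearest integer (reporting convention)?
#' @return HbA1c in mmol/mol.
#' @export
hba1c_percent_to_mmol_per_mol <- function(percent, round = TRUE) {
  if (any(!is.finite(percent)) || any(percent < 2.15))
    stop("`percent` must be finite and >= 2.15", call. = FALSE)
  out <- (percent - 2.15) * 10.929
  if (round) round(out) else out
}

#' Convert HbA1c from IFCC mmol/mol to NGSP percent
#'
#' Inverse of [hba1c_percent_to_mmol_per_mol()].
#'
#' @param mmol_per_mol HbA1c in mmol/mol, >= 0.
#' @return HbA1c in NGSP %.
#' @export
hba1c_mmol_per_mol_to_percent <- function(mmol_per_mol) {
  if (any(!is.finite(mmol_per_mol)) || any(mmol_per_mol < 0))
    stop("`mmol_per_mol` must be finite and >= 0", call. = FALSE)
  mmol_per_mol / 10.929 + 2.15
}
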