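#' Convert OD600 to a relative cell concentration
#'
#' `cells/uL = od600 * cells_per_od`, with the standard conversion constant
#' 8e5 cells/uL per OD unit by default.
#'
#' @param od600 optical density reading(s) at 600 nm (non-negative).
#' @param cells_per_od conversion constant (cells/uL per OD unit).
#' @return cells per microlitre.
#' @export
od600_to_cells <- function(od600, cells_per_od = 8e5) {
  if (any(od600 < 0)) abort_ss("OD600 must be non-negative", "bad_od")
  od600 * cells_per_od
}

#' Colony-forming units per millilitre from dilution plating
#'
#' `CFU/mL = colony_count * dilution_factor / (plated_volume / 1000)`.
#'
#' @param colony_count colonies counted on the plate (non-negative).
#' @param dilution_factor total serial dilution (>= 1), e.g. 1e4 for 1:10,000.
#' @param plated_volume volume plated in microlitres (> 0).
#' @return CFU per millilitre.
#' @export
cfu_per_ml <- function(colony_count, dilution_factor, plated_volume) {
  stopifnot(all(colony_count >= 0), all(dilution_factor >= 1))
  if (any(plated_volume <= 0)) abort_ss("plated volume must be positive", "bad_volume")
  colony_count * dilution_factor / (plated_volume / 1000)
}

#' Summary statistics of an OD600 growth curve
#'
#' @param curve data frame with columns `time` (hours) and `od600` (>= 3
#'   time points).
#' @return list with `max_od`, `time_to_half_max` (linear-interpolated first
#'   crossing of `max_od / 2`; `NA` with a warning when the curve starts at
#'   or above half-max or never reaches it), and `auc` (trapezoidal,
#'   OD x hours).
#' @export
growth_curve_summary <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("time", "od600") %in% names(curve)),
            nrow(curve) >= 3L, all(curve$od600 >= 0),
            !is.unsorted(curve$time, strictly = TRUE))
  t <- curve$time; y <- curve$od600
  max_od <- max(y)
  auc <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (max_od == 0) {
    warning("all-zero growth curve: half-max time undefined")
    return(list(max_od = 0, time_to_half_max = NA_real_, auc = 0))
  }
  half <- max_od / 2
  t_half <- if (y[1] >= half) {
    # flat or already-grown curves cross at (or before) the first sample
    t[1]
  } else {
    i <- which(y >= half)[1]
    t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  list(max_od = max_od, time_to_half_max = t_half, auc = auc)
}

#' Assemble a strain-by-dose lifespan-extension matrix
#'
#' Collects per-condition extension cells and adds a column normalized to a
#' reference condition (e.g. the wild-type feeding strain at the screening
#' dose). When the reference extension is zero the normalized column is
#' withheld (`NA`) with a warning and the raw values are kept.
#'
#' @param cells data frame with columns `strain`, `dose`,
#'   `percent_extension`, `logrank_p`, `n`.
#' @param reference_strain,reference_dose the reference condition.
#' @return the input data frame plus a `normalized_extension` column,
#'   ordered by strain and dose.
#' @export
extension_matrix <- function(cells, reference_strain, reference_dose) {
  need <- c("strain", "dose", "percent_extension", "logrank_p", "n")
  stopifnot(is.data.frame(cells), all(need %in% names(cells)))
  ref <- cells$strain == reference_strain & cells$dose == reference_dose
  if (sum(ref) != 1L)
    abort_ss("reference condition absent (or duplicated) in the cells",
             "missing_reference")
  ref_ext <- cells$percent_extension[ref]
  if (ref_ext == 0) {
    warning("reference extension is zero: normalization withheld")
    cells$normalized_extension <- NA_real_
  } else {
    cells$normalized_extension <- cells$percent_extension / ref_ext
  }
  cells[order(cells$strain, cells$dose), , drop = FALSE]
}

#' Classify whether a bacterial gene is required for the drug's effect
#'
#' Compares the drug-induced lifespan extension on a mutant strain with the
#' wild-type strain. The call is `required` when the mutant abolishes the
#' effect (non-significant or non-positive extension), `not_required` when
#' the mutant retains a significant extension within the noise band of the
#' wild-type value, and `partially_required` in between. A rescue
#' (re-expression) condition supports the call when it restores a
#' significant extension of at least `partial_fraction` of wild type.
#'
#' @param wildtype,mutant,rescue lists (or one-row data frames) with
#'   `percent_extension` and `logrank_p`; `rescue` may be `NULL`
#'   (not tested). Classification is refused when the wild-type extension is
#'   itself non-significant.
#' @param alpha significance level.
#' @param partial_fraction fraction of the wild-type extension a rescue must
#'   restore.
#' @param noise_band fractional shortfall from the wild-type extension still
#'   treated as equivalent (mutant >= (1 - noise_band) x wild type).
#' @return an object of class `dependence_call` with `call` (factor) and
#'   `rescue_supported` (logical or `"not_tested"`).
#' @export
classify_dependence <- function(wildtype, mutant, rescue = NULL, alpha = 0.05,
                                partial_fraction = 0.5, noise_band = 0.1) {
  get1 <- function(x, f) as.numeric(x[[f]][1])
  wt_ext <- get1(wildtype, "percent_extension"); wt_p <- get1(wildtype, "logrank_p")
  mu_ext <- get1(mutant, "percent_extension"); mu_p <- get1(mutant, "logrank_p")
  if (!(wt_p < alpha))
    abort_ss("wild-type extension not significant: classification refused",
             "wildtype_not_significant")
  call <- if (mu_p >= alpha || mu_ext <= 0) {
    "required"
  } else if (mu_ext >= (1 - noise_band) * wt_ext) {
    "not_required"
  } else {
    "partially_required"
  }
  rescue_supported <- if (is.null(rescue)) {
    "not_tested"
  } else {
    re_ext <- get1(rescue, "percent_extension"); re_p <- get1(rescue, "logrank_p")
    re_p < alpha && re_ext >= partial_fraction * wt_ext
  }
  structure(list(
    call = factor(call, levels = c("required", "partially_required",
                                   "not_required")),
    rescue_supported = rescue_supported,
    wildtype_extension = wt_ext, mutant_extension = mu_ext,
    alpha = alpha, partial_fraction = partial_fraction,
    noise_band = noise_band
  ), class = "dependence_call")
}
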