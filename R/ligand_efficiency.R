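#' Thermodynamic configuration for the inhibition constant
#'
#' @param gas_constant gas constant in kcal/(mol K). Default 1.98720425e-3.
#' @param temperature absolute temperature in K. Default 298.15 (25 C).
#' @return object of class `thermo_config`.
#' @export
thermo_config <- function(gas_constant = 1.98720425e-3, temperature = 298.15) {
  if (!is.numeric(gas_constant) || gas_constant <= 0) {
    stop("gas_constant must be > 0", call. = FALSE)
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("temperature must be > 0", call. = FALSE)
  }
  structure(list(gas_constant = gas_constant, temperature = temperature),
            class = "thermo_config")
}

#' Inhibition constant from a docking binding energy
#'
#' Converts a binding free energy into a concentration-scale inhibition
#' constant, Ki = exp(BE / RT), in molar units. More negative binding
#' energies give smaller (more potent) Ki.
#'
#' @param binding_energy binding energy in kcal/mol (negative = favourable).
#' @param thermo a [thermo_config()].
#' @return Ki in molar units (multiply by 1e6 for uM), vectorised.
#' @examples
#' inhibition_constant(-8.92) * 1e6 # ~0.29 uM
#' @export
inhibition_constant <- function(binding_energy, thermo = thermo_config()) {
  stopifnot(inherits(thermo, "thermo_config"))
  if (any(!is.finite(binding_energy))) {
    stop("binding_energy must be finite", call. = FALSE)
  }
  exp(binding_energy / (thermo$gas_constant * thermo$temperature))
}

#' Ligand efficiency
#'
#' Size-normalised potency: LE = -BE / HA, in kcal/mol per heavy atom.
#'
#' @param binding_energy binding energy in kcal/mol.
#' @param heavy_atoms number of non-hydrogen atoms (>= 1).
#' @return LE, vectorised.
#' @export
ligand_efficiency <- function(binding_energy, heavy_atoms) {
  if (any(!is.finite(binding_energy))) stop("binding_energy must be finite", call. = FALSE)
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be >= 1", call. = FALSE)
  -binding_energy / heavy_atoms
}

#' Size-dependent ligand-efficiency scaling function
#'
#' The empirical maximal-LE curve LE_Scale = 0.873 * exp(-0.026 * HA) - 0.064,
#' strictly decreasing in the heavy-atom count.
#'
#' @param heavy_atoms number of non-hydrogen atoms (>= 1).
#' @return dimensionless scale value, vectorised.
#' @export
le_scale <- function(heavy_atoms) {
  if (any(heavy_atoms < 1)) stop("heavy_atoms must be >= 1", call. = FALSE)
  0.873 * exp(-0.026 * heavy_atoms) - 0.064
}

#' Lipophilic ligand efficiency
#'
#' LLE = -log10(Ki) - logP, with Ki in molar units: potency corrected for
#' lipophilicity.
#'
#' @param ki inhibition constant in molar units (> 0).
#' @param logp octanol/water partition coefficient (log10 scale).
#' @return LLE, vectorised.
#' @export
lipophilic_efficiency <- function(ki, logp) {
  if (any(ki <= 0)) stop("ki must be > 0", call. = FALSE)
  -log10(ki) - logp
}

#' Fit quality
#'
#' FQ = LE / LE_Scale: observed ligand efficiency relative to the empirical
#' size-dependent maximum.
#'
#' @param le ligand efficiency (kcal/mol per heavy atom).
#' @param le_scale_value value of [le_scale()] for the same size.
#' @return FQ, vectorised.
#' @export
fit_quality <- function(le, le_scale_value) {
  if (any(le_scale_value == 0)) stop("le_scale_value must be non-zero", call. = FALSE)
  le / le_scale_value
}

#' Lipophilic price of ligand efficiency
#'
#' LELP = logP / LE: how much lipophilicity is paid per unit of ligand
#' efficiency. Values inside \[-10, 10\] are conventionally acceptable.
#'
#' @param logp octanol/water partition coefficient.
#' @param le ligand efficiency (non-zero).
#' @return LELP, vectorised.
#' @export
lelp <- function(logp, le) {
  if (any(le == 0)) stop("le must be non-zero", call. = FALSE)
  logp / le
}

#' Threshold set for ligand-efficiency classification
#'
#' Defaults are the conventional hit-triage thresholds: LE >= 0.3 kcal/mol/HA,
#' LLE >= 3, FQ >= 0.8 and LELP within \[-10, 10\]. All comparisons are
#' inclusive.
#'
#' @param le_min minimum ligand efficiency.
#' @param lle_min minimum lipophilic ligand efficiency.
#' @param fq_min minimum fit quality.
#' @param lelp_range closed acceptance interval for LELP.
#' @param ki_max optional maximum Ki (molar); `NULL` disables the check.
#' @return object of class `metric_thresholds`.
#' @export
metric_thresholds <- function(le_min = 0.3, lle_min = 3, fq_min = 0.8,
                              lelp_range = c(-10, 10), ki_max = NULL) {
  stopifnot(le_min > 0, lle_min > 0, fq_min > 0,
            length(lelp_range) == 2, lelp_range[1] <= lelp_range[2])
  if (!is.null(ki_max)) stopifnot(ki_max > 0)
  structure(list(le_min = le_min, lle_min = lle_min, fq_min = fq_min,
                 lelp_range = lelp_range, ki_max = ki_max),
            class = "metric_thresholds")
}

#' Evaluate all ligand-efficiency metrics with threshold flags
#'
#' Computes Ki, LE, LLE, LE_Scale, FQ and LELP for each compound and flags
#' each against its threshold. Ki is derived from the binding energy via
#' [inhibition_constant()] unless a measured/printed value is supplied in a
#' `ki_override` column (molar units), in which case that value feeds LLE and
#' the provenance is recorded in `ki_source`. All internal arithmetic is kept
#' in full precision; rounding is left to the caller for display.
#'
#' @param inputs data frame with columns `compound_id`, `binding_energy`
#'   (kcal/mol), `heavy_atoms`, `logp`, and optionally `ki_override` (molar).
#' @param thermo a [thermo_config()].
#' @param thresholds a [metric_thresholds()].
#' @return tibble with the six metrics (`ki` in molar, `ki_uM` in micromolar),
#'   per-rule pass flags (`pass_le`, `pass_lle`, `pass_fq`, `pass_lelp`,
#'   and `pass_ki` when a Ki ceiling is set), and `pass_all`.
#' @examples
#' evaluate_metrics(data.frame(compound_id = "A1", binding_energy = -9.35,
#'                             heavy_atoms = 24, logp = 2.763))
#' @export
evaluate_metrics <- function(inputs, thermo = thermo_config(),
                             thresholds = metric_thresholds()) {
  needed <- c("compound_id", "binding_energy", "heavy_atoms", "logp")
  missing_cols <- setdiff(needed, names(inputs))
  if (length(missing_cols) > 0) {
    stop(sprintf("inputs missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  stopifnot(inherits(thresholds, "metric_thresholds"))
  ki_eq <- inhibition_constant(inputs$binding_energy, thermo)
  if ("ki_override" %in% names(inputs)) {
    override <- inputs$ki_override
    if (any(!is.na(override) & override <= 0)) {
      stop("ki_override must be > 0 when present", call. = FALSE)
    }
    use_override <- !is.na(override)
    ki <- ifelse(use_override, override, ki_eq)
  } else {
    use_override <- rep(FALSE, nrow(inputs))
    ki <- ki_eq
  }
  le <- ligand_efficiency(inputs$binding_energy, inputs$heavy_atoms)
  scale <- le_scale(inputs$heavy_atoms)
  out <- tibble::tibble(
    compound_id = inputs$compound_id,
    ki = ki,
    ki_uM = ki * 1e6,
    le = le,
    lle = lipophilic_efficiency(ki, inputs$logp),
    le_scale = scale,
    fq = fit_quality(le, scale),
    lelp = lelp(inputs$logp, le),
    ki_source = ifelse(use_override, "override", "binding_energy")
  )
  out$pass_le <- out$le >= thresholds$le_min
  out$pass_lle <- out$lle >= thresholds$lle_min
  out$pass_fq <- out$fq >= thresholds$fq_min
  out$pass_lelp <- out$lelp >= thresholds$lelp_range[1] &
    out$lelp <= thresholds$lelp_range[2]
  flags <- c("pass_le", "pass_lle", "pass_fq", "pass_lelp")
  if (!is.null(thresholds$ki_max)) {
    out$pass_ki <- out$ki <= thresholds$ki_max
    flags <- c(flags, "pass_ki")
  }
  out$pass_all <- Reduce(`&`, out[flags])
  out
}
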