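#' One protein x substrate plate measurement
#'
#' @param protein_id accession of the assayed protein.
#' @param substrate substrate label.
#' @param signals replicate signals (assay units).
#' @param controls no-substrate control signals; may be empty only when the
#'   signals are already control-subtracted.
#' @param soluble_calls logical, one per expression replicate: was the band
#'   present on the gel?
#' @return A `plate_measurement` list.
#' @export
plate_measurement <- function(protein_id, substrate, signals,
                              controls = numeric(0),
                              soluble_calls = logical(0)) {
  if (length(signals) < 1L) stop("need at least one replicate signal")
  structure(list(protein_id = protein_id, substrate = substrate,
                 signals = as.numeric(signals),
                 controls = as.numeric(controls),
                 soluble_calls = as.logical(soluble_calls)),
            class = "plate_measurement")
}

#' Subtract the mean no-substrate control from each signal
#'
#' Negative corrected values are retained, not clipped: they carry
#' information about measurement noise around zero.
#'
#' @param signals replicate signals.
#' @param controls no-substrate controls (non-empty).
#' @return Corrected signals.
#' @export
subtract_controls <- function(signals, controls) {
  if (length(controls) == 0L) stop("no control measurements to subtract")
  signals - mean(controls)
}

#' Limit of detection from blank replicates
#'
#' `LOD = mean(blanks) + k_sd * sd(blanks)` with the sample (n-1) standard
#' deviation. The default `k_sd = 4` is a conservative screening cutoff.
#'
#' @param blank_replicates at least two blank measurements.
#' @param k_sd number of standard deviations above the blank mean.
#' @return The LOD in assay units.
#' @examples
#' detection_limit(c(8, 10, 12))  # 18
#' @export
detection_limit <- function(blank_replicates, k_sd = 4) {
  if (length(blank_replicates) < 2L)
    stop("SD undefined: need at least 2 blank replicates")
  mean(blank_replicates) + k_sd * sd(blank_replicates)
}

#' Call a screening hit
#'
#' A protein is a hit when it is both soluble (at least `min_soluble` of
#' the expression replicates showed a band) and active (at least
#' `min_active` control-subtracted replicates strictly above the LOD).
#'
#' @param measurement a [plate_measurement()]; signals are
#'   control-subtracted first when controls are present.
#' @param lod limit of detection, from [detection_limit()].
#' @param min_active,min_soluble replicate thresholds (default 2 of 3).
#' @return A list with logicals `soluble`, `active`, `hit`.
#' @export
call_hit <- function(measurement, lod, min_active = 2L, min_soluble = 2L) {
  corrected <- if (length(measurement$controls))
    subtract_controls(measurement$signals, measurement$controls)
  else measurement$signals
  soluble <- sum(measurement$soluble_calls) >= min_soluble
  active <- sum(corrected > lod) >= min_active
  list(soluble = soluble, active = active, hit = soluble && active)
}

#' Convert an absorbance slope to a reaction rate
#'
#' Beer-Lambert conversion for a chromogenic acceptor such as DCPIP
#' (extinction coefficient 20.7 mM^-1 cm^-1 at 600 nm):
#' `v = slope / (epsilon * 1000 * path_cm)` in M/s, and the observed
#' turnover `k_cat_obs = v / enzyme_conc`.
#'
#' @param slope absorbance change in AU/s.
#' @param epsilon extinction coefficient in mM^-1 cm^-1.
#' @param path_cm optical path length in cm.
#' @param enzyme_conc enzyme concentration in M.
#' @return A list with `v` (M/s) and `k_cat_obs` (1/s).
#' @export
rate_from_absorbance <- function(slope, epsilon = 20.7, path_cm = 1,
                                 enzyme_conc) {
  if (epsilon <= 0 || path_cm <= 0 || enzyme_conc <= 0)
    stop("epsilon, path_cm and enzyme_conc must be positive")
  v <- slope / (epsilon * 1000 * path_cm)
  list(v = v, k_cat_obs = v / enzyme_conc)
}

#' Fit Michaelis-Menten kinetics
#'
#' Unweighted least-squares fit of `v = V_max * S / (K_M + S)` via
#' Levenberg-Marquardt ([minpack.lm::nlsLM]), initialised at
#' `V_max = max(v)` and `K_M` at the substrate concentration whose velocity
#' is closest to half that. Standard errors come from the Jacobian.
#' `k_cat = V_max / enzyme_conc` and the catalytic efficiency
#' `k_cat / K_M` are derived from the fit.
#'
#' @param substrate substrate concentrations in M (>= 4 distinct values).
#' @param velocity initial velocities in M/s.
#' @param enzyme_conc enzyme concentration in M.
#' @return A `kinetic_fit`: list with `K_M`, `V_max`, `k_cat`,
#'   `efficiency`, `enzyme_conc` and `stderr` (named, for `K_M` and
#'   `V_max`). Warns "poorly constrained" when the fitted `K_M` falls
#'   outside the informative range `(max(S)/1e4, 100 * max(S))`.
#' @export
fit_michaelis_menten <- function(substrate, velocity, enzyme_conc) {
  if (length(substrate) != length(velocity))
    stop("'substrate' and 'velocity' must have equal length")
  if (length(unique(substrate)) < 4L)
    stop("need at least 4 distinct substrate concentrations")
  if (enzyme_conc <= 0) stop("enzyme_conc must be positive")
  S <- as.numeric(substrate); v <- as.numeric(velocity)
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- median(S)
  dat <- data.frame(S = S, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-15, ptol = 1e-10, maxiter = 500)),
    error = function(e)
      stop("Michaelis-Menten fit did not converge (start V_max = ",
           signif(vmax0, 4), ", K_M = ", signif(km0, 4), "): ",
           conditionMessage(e)))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  km <- unname(est["Km"]); vmax <- unname(est["Vmax"])
  if (!(km > max(S) / 1e4 && km < 100 * max(S)))
    warning("poorly constrained: fitted K_M = ", signif(km, 4),
            " is outside the informative substrate range")
  kcat <- vmax / enzyme_conc
  structure(list(K_M = km, V_max = vmax, k_cat = kcat,
                 efficiency = if (km > 0) kcat / km else NA_real_,
                 enzyme_conc = enzyme_conc,
                 stderr = c(K_M = unname(se["Km"]),
                            V_max = unname(se["Vmax"]))),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(paste0("kinetic_fit: K_M = %.3g M, k_cat = %.3g 1/s, ",
                     "k_cat/K_M = %.3g 1/(M*s)\n"),
              x$K_M, x$k_cat, x$efficiency))
  invisible(x)
}

#' Catalytic efficiency
#'
#' @param k_cat turnover number in 1/s.
#' @param K_M Michaelis constant in M (positive).
#' @return `k_cat / K_M` in 1/(M*s).
#' @examples
#' catalytic_efficiency(0.242, 1.97e-3)  # ~1.23e2
#' @export
catalytic_efficiency <- function(k_cat, K_M) {
  if (K_M <= 0) stop("K_M must be positive")
  k_cat / K_M
}

#' Read a kinetics table
#'
#' @param path TSV with columns `substrate_M`, `velocity_M_per_s`.
#' @return A data frame with those columns.
#' @export
read_kinetics_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate_M", "velocity_M_per_s")
  if (!all(need %in% names(tab)))
    stop("kinetics table must have columns substrate_M, velocity_M_per_s")
  tab
}

#' Read a plate table into measurements
#'
#' @param path TSV with columns `protein_id`, `substrate`, `replicate`,
#'   `signal`, `is_control` (logical or 0/1).
#' @return A list of [plate_measurement()] objects, one per
#'   protein x substrate combination.
#' @export
read_plate_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "substrate", "replicate", "signal", "is_control")
  if (!all(need %in% names(tab)))
    stop("plate table must have columns ", paste(need, collapse = ", "))
  tab$is_control <- as.logical(tab$is_control)
  key <- interaction(tab$protein_id, tab$substrate, drop = TRUE)
  lapply(split(tab, key), function(g)
    plate_measurement(g$protein_id[1], g$substrate[1],
                      signals = g$signal[!g$is_control],
                      controls = g$signal[g$is_control]))
}

#' Write a kinetic fit as JSON
#'
#' @param fit a `kinetic_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
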