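# Differential scanning fluorimetry: Boltzmann sigmoid evaluation and
# fitting, melting-temperature extraction, thermal-shift computation and
# screen classification.

#' Four-parameter Boltzmann sigmoid
#'
#' The DSF unfolding model
#' \deqn{F(T) = F_{min} + \frac{F_{max} - F_{min}}{1 + e^{(T_m - T)/a}}}
#' where `Tm` is the melting temperature (sigmoid midpoint, the temperature
#' at which half the protein is unfolded) and `a` the slope parameter in
#' degrees C. For `a > 0` the curve rises monotonically from `F_min` to
#' `F_max` and `F(Tm)` is the baseline midpoint.
#'
#' @param T temperature(s), degrees C.
#' @param F_min,F_max lower/upper fluorescence baselines, arbitrary units.
#' @param Tm melting temperature, degrees C.
#' @param a slope parameter, degrees C; must be non-zero.
#' @return fluorescence value(s), AU.
#' @export
boltzmann <- function(T, F_min, F_max, Tm, a) {
  if (a == 0) stop("slope parameter a must be non-zero")
  F_min + (F_max - F_min) / (1 + exp((Tm - T) / a))
}

#' Construct a melt curve
#'
#' @param temperature strictly increasing temperatures, degrees C (>= 10
#'   points).
#' @param fluorescence fluorescence readings, AU, same length.
#' @param well_id,condition optional identifiers.
#' @return object of class `gtusc_melt_curve`.
#' @export
melt_curve <- function(temperature, fluorescence, well_id = NA_character_,
                       condition = NA_character_) {
  temperature <- as.numeric(temperature)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperature) != length(fluorescence))
    stop("temperature and fluorescence must have equal length")
  if (length(temperature) < 10L)
    stop("a melt curve needs at least 10 points")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  structure(list(well_id = well_id, condition = condition,
                 temperature = temperature, fluorescence = fluorescence),
            class = "gtusc_melt_curve")
}

failed_fit <- function(window, note) {
  structure(list(Tm = NA_real_, slope_a = NA_real_, F_min = NA_real_,
                 F_max = NA_real_, rss = NA_real_, converged = FALSE,
                 fit_window = window, note = note),
            class = "gtusc_boltzmann_fit")
}

#' Fit the Boltzmann sigmoid to a melt curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the four-parameter
#' model of [boltzmann()]. SYPRO-Orange curves decay after the unfolding
#' peak as the dye dissociates, so the fit window is truncated at the
#' temperature of maximum fluorescence (standard thermofluor practice; the
#' window used is recorded in the result). Initialisation is deterministic:
#' `Tm0` at the maximum first difference of the 5-point-smoothed signal,
#' baselines at the window extrema, `a0 = 2` degrees C. Convergence is
#' declared only when the optimiser converges and the parameters are
#' physically sensible (`F_min < F_max`, `a > 0`, `Tm` inside the window);
#' otherwise `converged = FALSE` with a diagnostic note — degenerate curves
#' are reported, never silently dropped.
#'
#' @param curve a [melt_curve()].
#' @return object of class `gtusc_boltzmann_fit` with `Tm`, `slope_a`,
#'   `F_min`, `F_max`, `rss`, `converged`, `fit_window` and `note`.
#' @export
fit_melt_curve <- function(curve) {
  stopifnot(inherits(curve, "gtusc_melt_curve"))
  Tv <- curve$temperature
  Fv <- curve$fluorescence
  if (diff(range(Fv)) == 0)
    return(failed_fit(range(Tv), "flat signal: no transition"))
  peak <- which.max(Fv)
  win <- seq_len(peak)
  window <- c(Tv[1L], Tv[peak])
  if (length(win) < 4L)
    stop("insufficient data: fewer points than parameters in the fit window")
  Tw <- Tv[win]; Fw <- Fv[win]
  if (diff(range(Fw)) == 0)
    return(failed_fit(window, "flat signal: no transition in window"))
  # deterministic start values
  k <- min(5L, length(Fw))
  sm <- stats::filter(Fw, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- Fw[is.na(sm)]
  dF <- diff(as.numeric(sm))
  Tm0 <- Tw[which.max(dF)]
  start <- list(F_min = min(Fw), F_max = max(Fw), Tm = Tm0, a = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Fw ~ F_min + (F_max - F_min) / (1 + exp((Tm - Tw) / a)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(failed_fit(window, "optimiser failed"))
  p <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  ok <- is.finite(p["Tm"]) && p["F_min"] < p["F_max"] && p["a"] > 0 &&
    p["Tm"] >= window[1L] && p["Tm"] <= window[2L]
  structure(list(Tm = unname(p["Tm"]), slope_a = unname(p["a"]),
                 F_min = unname(p["F_min"]), F_max = unname(p["F_max"]),
                 rss = rss, converged = ok, fit_window = window,
                 note = if (ok) "ok" else "degenerate parameter estimates"),
            class = "gtusc_boltzmann_fit")
}

#' @export
print.gtusc_boltzmann_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Boltzmann fit: Tm = %.2f C, a = %.2f C, F in [%.0f, %.0f], rss = %.3g\n",
                x$Tm, x$slope_a, x$F_min, x$F_max, x$rss))
  else cat("Boltzmann fit: NOT converged (", x$note, ")\n", sep = "")
  invisible(x)
}

#' Thermal shift between two fitted conditions
#'
#' `delta_tm = Tm(condition) - Tm(reference)`: positive for stabilisation,
#' negative for destabilisation.
#'
#' @param fit,reference_fit converged `gtusc_boltzmann_fit` objects.
#' @return shift in degrees C.
#' @export
delta_tm <- function(fit, reference_fit) {
  if (!isTRUE(fit$converged) || !isTRUE(reference_fit$converged))
    stop("fit_failed: delta_tm requires two converged fits")
  fit$Tm - reference_fit$Tm
}

#' Classify a thermal-shift screen
#'
#' A condition is a stabilizer when its shift is at least `+threshold`, a
#' destabilizer at or below `-threshold`, otherwise no-effect. The default
#' 2 degrees C marks "best hit" reporting; a 1 degree C tier is the common
#' any-effect cut.
#'
#' @param results data.frame with columns `condition` and `delta_Tm`
#'   (`NA` for failed fits).
#' @param effect_threshold_C positive effect threshold, degrees C
#'   (default 2).
#' @return the input with a `classification` factor column added
#'   (levels stabilizer / destabilizer / no_effect / fit_failed).
#' @export
classify_screen <- function(results, effect_threshold_C = 2.0) {
  stopifnot(effect_threshold_C > 0)
  d <- results$delta_Tm
  cls <- ifelse(is.na(d), "fit_failed",
                ifelse(d >= effect_threshold_C, "stabilizer",
                       ifelse(d <= -effect_threshold_C, "destabilizer",
                              "no_effect")))
  results$classification <- factor(cls, levels = c("stabilizer",
                                                   "destabilizer",
                                                   "no_effect",
                                                   "fit_failed"))
  results
}

#' Read a long-format DSF plate CSV
#'
#' Columns: `well`, `condition`, `temperature_C`, `fluorescence_AU`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "condition", "temperature_C", "fluorescence_AU")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plate CSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Fit and classify a whole DSF plate
#'
#' Each well is fitted independently with [fit_melt_curve()]; replicate
#' wells of a condition are then combined as mean Tm with its standard
#' error. Shifts are taken against the named reference condition and
#' classified with [classify_screen()]. Conditions whose wells all fail to
#' converge are reported as `fit_failed`.
#'
#' @param plate long-format data.frame as from [read_plate()].
#' @param reference name of the reference condition (e.g. the
#'   protein-protein complex alone).
#' @param effect_threshold_C classification threshold, degrees C (default 2).
#' @return data.frame, one row per condition: `condition`, `n_wells`,
#'   `n_converged`, `Tm`, `Tm_se`, `delta_Tm`, `classification`.
#' @export
fit_plate <- function(plate, reference, effect_threshold_C = 2.0) {
  if (!reference %in% plate$condition)
    stop("reference condition not present on plate: ", reference)
  wells <- split(plate, plate$well)
  fits <- lapply(wells, function(w) {
    w <- w[order(w$temperature_C), ]
    fit_melt_curve(melt_curve(w$temperature_C, w$fluorescence_AU,
                              well_id = w$well[1L],
                              condition = w$condition[1L]))
  })
  cond <- vapply(wells, function(w) w$condition[1L], character(1))
  per_cond <- lapply(split(fits, cond), function(fl) {
    tms <- vapply(fl, function(f) if (f$converged) f$Tm else NA_real_,
                  numeric(1))
    ok <- sum(!is.na(tms))
    data.frame(n_wells = length(fl), n_converged = ok,
               Tm = if (ok) mean(tms, na.rm = TRUE) else NA_real_,
               Tm_se = if (ok > 1L) stats::sd(tms, na.rm = TRUE) / sqrt(ok)
                       else NA_real_)
  })
  out <- do.call(rbind, per_cond)
  out <- cbind(data.frame(condition = names(per_cond),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  ref_tm <- out$Tm[out$condition == reference]
  if (is.na(ref_tm)) stop("fit_failed: reference condition did not converge")
  out$delta_Tm <- out$Tm - ref_tm
  classify_screen(out, effect_threshold_C)
}
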