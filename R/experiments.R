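# The five-condition mechanism comparison and the four parameter sweeps,
# with min-max normalization of the phosphorylation readouts.

#' Min-max normalization
#'
#' `(Y - Y_min)/(Y_max - Y_min)` elementwise; the minimum maps to 0 and the
#' maximum to 1. All-equal input is degenerate (division by zero) and raises
#' an error.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Vector in `[0, 1]`.
#' @export
normalize_minmax <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  rng <- range(values)
  if (rng[1] == rng[2])
    stop("degenerate normalization: all input values are equal",
         call. = FALSE)
  (values - rng[1]) / (rng[2] - rng[1])
}

# Seed-averaged summary scalars for one condition/protocol. Returns means of
# the final phosphorylated CaMKII, the peak, and the AMPAR conductance gain
# over baseline.
.mean_run <- function(params, protocol, condition, config, seeds) {
  runs <- vapply(seeds, function(s) {
    cfg <- sim_config(dt = config$dt, t_end = config$t_end, seed = s,
                      record_stride = config$record_stride)
    sim <- simulate_spine(params, protocol, condition, cfg)
    c(final = sim$summary$final_ph_camkii,
      peak = sim$summary$peak_ph_camkii,
      dg = sim$summary$final_g_ampa - params$ampar$g_AMPA0)
  }, c(final = 0, peak = 0, dg = 0))
  rowMeans(runs)
}

#' Five-condition mechanism comparison
#'
#' Runs the five reference conditions — normal (no opioid), opioid, and the
#' three single-mechanism knockouts CK = 0 (no opioid effect on NMDAR
#' conductance), CMg = 0 (no opioid effect on the Mg2+ block) and Icr = 0
#' (no VGCC current) — under the same stimulus, averages the phosphorylation
#' readouts over the seed list, and min-max normalizes each readout across
#' the five conditions. Phosphorylated AMPAR is quantified as the final AMPAR
#' conductance gain over baseline, the model's only AMPAR-phosphorylation
#' observable.
#'
#' @param params A [spine_params()] set.
#' @param protocol A [stimulus_protocol()].
#' @param config A [sim_config()]; its seed field is ignored in favour of
#'   `seeds`.
#' @param Op Opioid concentration of the non-normal conditions (uM).
#' @param seeds Integer vector of seeds averaged per condition.
#' @param form Opioid saturation form (see [opioid_saturation()]).
#' @return An object of class `spine_conditions`: data frame with one row per
#'   condition (`label`, raw and normalized phosphorylated CaMKII and AMPAR,
#'   LTP flag).
#' @export
run_five_conditions <- function(params = spine_params(),
                                protocol = stimulus_protocol(),
                                config = sim_config(),
                                Op = 1, seeds = 1:5,
                                form = c("saturating", "printed")) {
  form <- match.arg(form)
  conds <- list(
    normal  = opioid_condition(Op = 0, form = form),
    opioid  = opioid_condition(Op = Op, form = form),
    `CK=0`  = opioid_condition(Op = Op, conductance_effect = FALSE,
                               form = form),
    `CMg=0` = opioid_condition(Op = Op, mg_effect = FALSE, form = form),
    `Icr=0` = opioid_condition(Op = Op, vgcc = FALSE, form = form))
  res <- t(vapply(conds, function(cn)
    .mean_run(params, protocol, cn, config, seeds),
    c(final = 0, peak = 0, dg = 0)))
  out <- data.frame(
    label = names(conds),
    raw_phospho_camkii = res[, "final"],
    raw_phospho_ampar = res[, "dg"],
    peak_ph_camkii = res[, "peak"],
    normalized_camkii = normalize_minmax(res[, "final"]),
    normalized_ampar = normalize_minmax(res[, "dg"]),
    ltp = res[, "peak"] > params$ampar$P_half,
    row.names = NULL)
  structure(out, class = c("spine_conditions", "data.frame"),
            seeds = seeds, Op = Op)
}

#' @export
print.spine_conditions <- function(x, ...) {
  cat(sprintf("Five-condition comparison (Op = %g uM, %d seeds)\n",
              attr(x, "Op"), length(attr(x, "seeds"))))
  print.data.frame(cbind(x[, "label", drop = FALSE],
                         round(x[, 2:6], 4), ltp = x$ltp),
                   row.names = FALSE)
  invisible(x)
}

#' @export
plot.spine_conditions <- function(x, ...) {
  graphics::barplot(rbind(x$normalized_camkii, x$normalized_ampar),
                    beside = TRUE, names.arg = x$label,
                    legend.text = c("Ph.CaMKII", "Ph.AMPAR"),
                    ylab = "normalized value", ...)
  invisible(x)
}

# Shared sweep runner: `modify(value)` returns list(protocol=, condition=).
.run_sweep <- function(name, grid, modify, params, config, seeds,
                       threshold) {
  res <- t(vapply(grid, function(g) {
    inp <- modify(g)
    .mean_run(params, inp$protocol, inp$condition, config, seeds)
  }, c(final = 0, peak = 0, dg = 0)))
  out <- data.frame(value = grid,
                    raw_phospho_camkii = res[, "final"],
                    raw_phospho_ampar = res[, "dg"],
                    peak_ph_camkii = res[, "peak"],
                    ltp = res[, "peak"] > threshold)
  out$normalized_camkii <- tryCatch(
    normalize_minmax(out$raw_phospho_camkii), error = function(e) NA_real_)
  out$normalized_ampar <- tryCatch(
    normalize_minmax(out$raw_phospho_ampar), error = function(e) NA_real_)
  structure(out, class = c("spine_sweep", "data.frame"),
            parameter = name, seeds = seeds, threshold = threshold)
}

#' @export
print.spine_sweep <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d seeds per point)\n",
              attr(x, "parameter"), length(attr(x, "seeds"))))
  print.data.frame(round(as.data.frame(x), 4), row.names = FALSE)
  det <- detected_threshold(x)
  if (!is.na(det))
    cat(sprintf("  detected threshold: %s = %g\n", attr(x, "parameter"), det))
  invisible(x)
}

#' @export
plot.spine_sweep <- function(x, ...) {
  graphics::plot(x$value, x$normalized_camkii, type = "b", pch = 19,
                 xlab = attr(x, "parameter"),
                 ylab = "normalized value", ylim = c(0, 1), ...)
  graphics::lines(x$value, x$normalized_ampar, type = "b", pch = 1,
                  col = "red3")
  graphics::legend("topleft", c("Ph.CaMKII", "Ph.AMPAR"), pch = c(19, 1),
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Detected threshold of a sweep
#'
#' For increasing-effect sweeps (conductance and VGCC coefficients,
#' frequency) the smallest grid value whose seed-averaged peak
#' phosphorylated CaMKII exceeds the LTP threshold; for the amplitude sweep
#' the largest grid value at which LTP fails. Grid values are reported as-is
#' (no interpolation).
#'
#' @param x A `spine_sweep` object.
#' @return A grid value, or `NA` if no threshold is crossed.
#' @export
detected_threshold <- function(x) {
  stopifnot(inherits(x, "spine_sweep"))
  if (attr(x, "parameter") == "glutamate_amplitude") {
    failed <- x$value[!x$ltp]
    if (length(failed) == 0) NA_real_ else max(failed)
  } else {
    pos <- x$value[x$ltp]
    if (length(pos) == 0) NA_real_ else min(pos)
  }
}

#' Sweep the opioid NMDAR-conductance coefficient
#'
#' Runs the opioid condition with the multiplier on the opioid conductance
#' term varied over the grid (0.1 increments by default) and reports the
#' smallest LTP-positive grid value. Coefficient 0 is identical to the
#' CK = 0 knockout.
#'
#' @param grid Coefficient grid (strictly monotone).
#' @param params,protocol,config,seeds,Op As in [run_five_conditions()].
#' @return A `spine_sweep` data frame.
#' @export
sweep_nmdar_coefficient <- function(grid = seq(0.1, 1, by = 0.1),
                                    params = spine_params(),
                                    protocol = stimulus_protocol(),
                                    config = sim_config(),
                                    seeds = 1:5, Op = 1) {
  stopifnot(all(diff(grid) > 0) || all(diff(grid) < 0))
  .run_sweep("nmdar_coeff", grid, function(g)
    list(protocol = protocol,
         condition = opioid_condition(Op = Op, nmdar_coeff = g)),
    params, config, seeds, params$ampar$P_half)
}

#' Sweep the VGCC current coefficient
#'
#' Multiplies the VGCC current by each grid value under the opioid condition;
#' the normalized phosphorylation readouts are non-decreasing in the
#' coefficient up to Monte-Carlo noise. Coefficient 0 matches the Icr = 0
#' knockout.
#'
#' @inheritParams sweep_nmdar_coefficient
#' @return A `spine_sweep` data frame.
#' @export
sweep_vgcc_coefficient <- function(grid = seq(0, 1, by = 0.1),
                                   params = spine_params(),
                                   protocol = stimulus_protocol(),
                                   config = sim_config(),
                                   seeds = 1:5, Op = 1) {
  stopifnot(all(diff(grid) > 0) || all(diff(grid) < 0))
  .run_sweep("vgcc_coeff", grid, function(g)
    list(protocol = protocol,
         condition = opioid_condition(Op = Op, vgcc_coeff = g)),
    params, config, seeds, params$ampar$P_half)
}

#' Sweep the glutamate pulse amplitude
#'
#' Runs the opioid condition at each pulse amplitude (descending from 0.2 mM
#' in 0.01 mM steps by default) and reports the largest amplitude at which
#' LTP fails.
#'
#' @param amplitudes Amplitude grid (mM).
#' @inheritParams sweep_nmdar_coefficient
#' @return A `spine_sweep` data frame.
#' @export
sweep_glutamate_amplitude <- function(amplitudes = seq(0.2, 0.13, by = -0.01),
                                      params = spine_params(),
                                      protocol = stimulus_protocol(),
                                      config = sim_config(),
                                      seeds = 1:5, Op = 1) {
  stopifnot(all(diff(amplitudes) > 0) || all(diff(amplitudes) < 0))
  .run_sweep("glutamate_amplitude", amplitudes, function(g)
    list(protocol = stimulus_protocol(protocol$frequency,
                                      protocol$pulse_width, g,
                                      protocol$duration),
         condition = opioid_condition(Op = Op)),
    params, config, seeds, params$ampar$P_half)
}

#' Sweep the glutamate pulse-train frequency
#'
#' Runs the opioid condition at each stimulation frequency (5 Hz down to
#' 0.1 Hz by default); the phosphorylation readout declines gradually with
#' decreasing frequency rather than switching off in a single step.
#'
#' @param frequencies Frequency grid (Hz).
#' @inheritParams sweep_nmdar_coefficient
#' @return A `spine_sweep` data frame.
#' @export
sweep_glutamate_frequency <- function(frequencies = c(5, 4, 3, 2, 1.5, 1,
                                                      0.5, 0.1),
                                      params = spine_params(),
                                      protocol = stimulus_protocol(),
                                      config = sim_config(),
                                      seeds = 1:5, Op = 1) {
  stopifnot(all(diff(frequencies) > 0) || all(diff(frequencies) < 0))
  .run_sweep("glutamate_frequency", frequencies, function(g)
    list(protocol = stimulus_protocol(g, protocol$pulse_width,
                                      protocol$amplitude,
                                      protocol$duration),
         condition = opioid_condition(Op = Op)),
    params, config, seeds, params$ampar$P_half)
}
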