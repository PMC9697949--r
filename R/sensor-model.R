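#' Heater-voltage ramp
#'
#' Defines the linear heater-voltage grid along which a thermally modulated
#' sweep is sampled. The default 0--5 V ramp at 0.01 V resolution yields the
#' standard 501-point grid.
#'
#' @param v_start,v_end Ramp endpoints in volts; `v_start < v_end`.
#' @param step Grid step in volts; must divide the ramp span.
#' @return An object of class `heater_ramp` with fields `v_start`, `v_end`,
#'   `step` and the voltage `grid`.
#' @examples
#' length(heater_ramp()$grid)  # 501
#' @export
heater_ramp <- function(v_start = 0, v_end = 5, step = 0.01) {
  stopifnot(is.numeric(v_start), is.numeric(v_end), is.numeric(step),
            length(v_start) == 1, length(v_end) == 1, length(step) == 1)
  if (!(v_start < v_end)) stop("heater_ramp: v_start must be < v_end")
  if (!(step > 0)) stop("heater_ramp: step must be > 0")
  n <- round((v_end - v_start) / step) + 1L
  # seq by length keeps the last grid point exactly at v_end
  grid <- seq(v_start, v_end, length.out = n)
  structure(list(v_start = v_start, v_end = v_end, step = step, grid = grid),
            class = "heater_ramp")
}

#' Analyte mixture
#'
#' A two-component mixture of ethanol and acetone, as mass fractions in
#' percent of the liquid sample the sensor headspace equilibrates with.
#'
#' @param c_ethanol,c_acetone Mass fractions in percent; both must be >= 0.
#' @return An object of class `analyte_mix`.
#' @export
analyte_mix <- function(c_ethanol = 0, c_acetone = 0) {
  stopifnot(is.numeric(c_ethanol), is.numeric(c_acetone),
            length(c_ethanol) == 1, length(c_acetone) == 1)
  if (c_ethanol < 0 || c_acetone < 0)
    stop("analyte_mix: concentrations must be non-negative")
  structure(list(c_ethanol = c_ethanol, c_acetone = c_acetone),
            class = "analyte_mix")
}

#' Voltage-divider circuit parameters
#'
#' The sensor resistance is read out through a voltage divider: a supply
#' voltage `v_c` drives the series combination of the sensor and a load
#' resistor `r_load`, and the output voltage is measured across the load.
#'
#' @param v_c Supply voltage in volts (default 5).
#' @param r_load Load resistance; resistances are expressed in units of
#'   `r_load`, so the default is 1.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(v_c = 5, r_load = 1) {
  if (!(v_c > 0)) stop("circuit_params: v_c must be > 0")
  if (!(r_load > 0)) stop("circuit_params: r_load must be > 0")
  structure(list(v_c = v_c, r_load = r_load), class = "circuit_params")
}

#' Gas-response parameters of the sensing film
#'
#' Shape constants of the forward model. The air-baseline resistance falls
#' log-linearly from `r_air_high` (cold heater) to `r_air_low` (full heater
#' power) across the ramp, and each reducing gas divides it by a
#' logistic-gated power-law term: the gate opens around an onset voltage
#' `v_on` over a width `w`, and the term scales as `(c / c_ref)^beta` with
#' concentration. Ethanol's onset must precede acetone's: on this sensor the
#' ethanol response rises earlier in the ramp while acetone rises later but
#' more steeply.
#'
#' Amplitudes default to 1 and are normally fixed afterwards by
#' [calibrate_amplitudes()] so that the single-gas peak output voltages hit
#' their measured values.
#'
#' @param ethanol,acetone Named lists with fields `amplitude`, `v_on` (V),
#'   `w` (V) and `beta`.
#' @param c_ref Reference concentration in percent at which the gas term
#'   equals its amplitude (default 0.5).
#' @param r_air_high,r_air_low Air-baseline resistances (units of the load
#'   resistor) at ramp start and end.
#' @param v_range Voltage range over which the air baseline is interpolated.
#' @return An object of class `gas_response_params`.
#' @export
gas_response_params <- function(ethanol = list(amplitude = 1, v_on = 1.6, w = 0.5, beta = 0.6),
                                acetone = list(amplitude = 1, v_on = 2.4, w = 0.35, beta = 0.6),
                                c_ref = 0.5,
                                r_air_high = 50, r_air_low = 8,
                                v_range = c(0, 5)) {
  gases <- list(ethanol = ethanol, acetone = acetone)
  for (g in names(gases)) {
    p <- gases[[g]]
    stopifnot(all(c("amplitude", "v_on", "w", "beta") %in% names(p)))
    if (!(p$amplitude > 0)) stop("gas_response_params: amplitude must be > 0 (", g, ")")
    if (!(p$v_on > 0 && p$v_on < max(v_range)))
      stop("gas_response_params: v_on must lie inside the ramp (", g, ")")
    if (!(p$w > 0)) stop("gas_response_params: w must be > 0 (", g, ")")
    if (!(p$beta > 0 && p$beta <= 1)) stop("gas_response_params: beta must be in (0, 1] (", g, ")")
  }
  if (!(r_air_high >= r_air_low && r_air_low > 0))
    stop("gas_response_params: need r_air_high >= r_air_low > 0")
  if (!(ethanol$v_on < acetone$v_on))
    stop("gas_response_params: ethanol onset must precede acetone onset")
  structure(list(ethanol = ethanol, acetone = acetone, c_ref = c_ref,
                 r_air_high = r_air_high, r_air_low = r_air_low,
                 v_range = v_range),
            class = "gas_response_params")
}

#' Air-baseline resistance along the ramp
#'
#' Log-linear interpolation between the cold-heater and hot-heater air
#' resistances.
#'
#' @param v_h Heater voltage(s) in volts.
#' @param params A [gas_response_params()] object.
#' @return Resistance(s) in units of the load resistor.
#' @export
air_resistance <- function(v_h, params) {
  frac <- (v_h - params$v_range[1]) / diff(params$v_range)
  exp(log(params$r_air_high) + frac * (log(params$r_air_low) - log(params$r_air_high)))
}

#' Sensor resistance under a gas mixture
#'
#' Forward model of the chemiresistor: the air baseline is divided by one
#' plus the sum of the per-gas response terms,
#' `R_S(v) = R_air(v) / (1 + sum_g A_g * logistic((v - v_on_g)/w_g) * (c_g/c_ref)^beta_g)`.
#' The response is strictly positive and non-increasing in each analyte
#' concentration.
#'
#' @param v_h Heater voltage(s) in volts, inside the ramp domain.
#' @param mix An [analyte_mix()] (or a list with `c_ethanol`, `c_acetone`).
#' @param params A [gas_response_params()] object.
#' @return Resistance(s) in units of the load resistor.
#' @examples
#' p <- gas_response_params()
#' sensor_resistance(3, analyte_mix(0, 0), p) == air_resistance(3, p)
#' @export
sensor_resistance <- function(v_h, mix, params = gas_response_params()) {
  if (mix$c_ethanol < 0 || mix$c_acetone < 0)
    stop("sensor_resistance: concentrations must be non-negative")
  conc <- c(ethanol = mix$c_ethanol, acetone = mix$c_acetone)
  term <- 0
  for (g in c("ethanol", "acetone")) {
    if (conc[[g]] > 0) {
      p <- params[[g]]
      term <- term + p$amplitude * stats::plogis((v_h - p$v_on) / p$w) *
        (conc[[g]] / params$c_ref)^p$beta
    }
  }
  air_resistance(v_h, params) / (1 + term)
}

#' Output voltage of the divider readout
#'
#' `V_OUT = V_C * R_L / (R_S + R_L)`: a falling sensor resistance pulls the
#' output towards the supply voltage; the output always lies strictly
#' between 0 and `v_c`.
#'
#' @param r_s Sensor resistance(s); must be > 0.
#' @param circuit A [circuit_params()] object.
#' @return Output voltage(s) in volts.
#' @examples
#' divider_voltage(3, circuit_params(v_c = 5, r_load = 1))  # 1.25
#' @export
divider_voltage <- function(r_s, circuit = circuit_params()) {
  if (any(r_s <= 0)) stop("divider_voltage: r_s must be > 0")
  circuit$v_c * circuit$r_load / (r_s + circuit$r_load)
}

#' Calibrate response amplitudes to measured single-gas peaks
#'
#' Fixes each gas amplitude so that the noise-free single-gas sweep at the
#' reference concentration (0.5 %) attains exactly a target peak output
#' voltage. Because the air baseline falls and the gas gate opens
#' monotonically along the ramp, the sensor resistance is strictly
#' decreasing in heater voltage and the peak sits at the ramp end; inverting
#' the divider there gives the closed form
#' `R_peak = R_L (V_C - V_peak)/V_peak` and
#' `A = (R_air(v_end)/R_peak - 1) / logistic((v_end - v_on)/w)`.
#'
#' The defaults are the peak voltages measured on the TGS2610-C sensor for
#' 0.5 % single-analyte solutions: 4.65 V for acetone and 4.13 V for
#' ethanol.
#'
#' @param targets Named numeric vector of peak output voltages in volts;
#'   names among `"ethanol"`, `"acetone"`.
#' @param params A [gas_response_params()] object to update.
#' @param circuit A [circuit_params()] object.
#' @param ramp A [heater_ramp()] over which the peak is verified.
#' @return The updated `gas_response_params` with calibrated amplitudes.
#' @examples
#' p <- calibrate_amplitudes()
#' s <- simulate_sweep(analyte_mix(0, 0.5), params = p, noise_sd = 0)
#' max(s$out_v)  # 4.65
#' @export
calibrate_amplitudes <- function(targets = c(acetone = 4.65, ethanol = 4.13),
                                 params = gas_response_params(),
                                 circuit = circuit_params(),
                                 ramp = heater_ramp()) {
  stopifnot(!is.null(names(targets)), all(names(targets) %in% c("ethanol", "acetone")))
  v_end <- ramp$v_end
  r_air_end <- air_resistance(v_end, params)
  for (g in names(targets)) {
    v_peak <- targets[[g]]
    if (!(v_peak > 0 && v_peak < circuit$v_c))
      stop("calibrate_amplitudes: target peak must lie in (0, v_c)")
    r_peak <- circuit$r_load * (circuit$v_c - v_peak) / v_peak
    if (r_peak >= r_air_end)
      stop("calibrate_amplitudes: target peak ", v_peak,
           " V is below the air baseline at full heater power; unattainable")
    gate <- stats::plogis((v_end - params[[g]]$v_on) / params[[g]]$w)
    params[[g]]$amplitude <- (r_air_end / r_peak - 1) / gate
  }
  # re-check: the simulated noise-free single-gas peak must hit each target
  for (g in names(targets)) {
    mix <- if (g == "ethanol") analyte_mix(params$c_ref, 0) else analyte_mix(0, params$c_ref)
    got <- max(divider_voltage(sensor_resistance(ramp$grid, mix, params), circuit))
    if (abs(got - targets[[g]]) > 1e-9)
      stop("calibrate_amplitudes: internal check failed for ", g)
  }
  params
}

#' Simulate one thermally modulated sweep
#'
#' Evaluates the forward model along the heater ramp and adds i.i.d.
#' Gaussian measurement noise on the output voltage, clipped to the divider
#' range `[0, v_c]`. With `noise_sd = 0` the sweep is deterministic and the
#' RNG is untouched.
#'
#' @param mix An [analyte_mix()].
#' @param ramp A [heater_ramp()].
#' @param params A [gas_response_params()], normally calibrated.
#' @param circuit A [circuit_params()].
#' @param noise_sd Noise standard deviation in volts (default 0.02).
#' @param seed Integer seed for the noise draw, or `NULL` to use the current
#'   RNG state. Identical `(mix, seed, noise_sd)` give identical sweeps.
#' @param replicate Integer replicate id stored with the sweep.
#' @return An object of class `sensor_sweep`: lists `heater_v`, `out_v`
#'   (volts), the `mix`, `replicate`, `seed` and `noise_sd`.
#' @export
simulate_sweep <- function(mix, ramp = heater_ramp(),
                           params = gas_response_params(),
                           circuit = circuit_params(),
                           noise_sd = 0.02, seed = NULL, replicate = 1L) {
  if (noise_sd < 0) stop("simulate_sweep: noise_sd must be >= 0")
  v <- divider_voltage(sensor_resistance(ramp$grid, mix, params), circuit)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sd)
    v <- pmin(pmax(v, 0), circuit$v_c)
  }
  structure(list(heater_v = ramp$grid, out_v = v, mix = mix,
                 replicate = as.integer(replicate),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 noise_sd = noise_sd),
            class = "sensor_sweep")
}

#' @export
print.sensor_sweep <- function(x, ...) {
  cat(sprintf("sensor_sweep: %d points, ethanol %.6g%%, acetone %.6g%%, replicate %d\n",
              length(x$out_v), x$mix$c_ethanol, x$mix$c_acetone, x$replicate))
  cat(sprintf("  out_v range [%.3f, %.3f] V, noise_sd %.3g V\n",
              min(x$out_v), max(x$out_v), x$noise_sd))
  invisible(x)
}

#' Serial-dilution concentration ladder
#'
#' The 13 mass-fraction levels of the factorial design: a geometric series
#' with ratio sqrt(2) from 2^-7 % (78 ppm) to 2^-1 % (5000 ppm), as produced
#' by serial dilution.
#'
#' @return Numeric vector of 13 concentrations in percent, increasing.
#' @examples
#' round(concentration_levels()[1] * 1e4)  # 78 ppm
#' @export
concentration_levels <- function() {
  2^seq(-7, -1, by = 0.5)
}

# deterministic per-item seed fan-out from a master seed (kept < 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 1009 * as.numeric(index)) %% 2147483647) + 1L
}

#' Generate a factorial sweep dataset
#'
#' Simulates the full concentration grid: every combination of ethanol and
#' acetone levels, each repeated `replicates` times with independent noise.
#' Per-sweep seeds are derived deterministically from the master seed, so
#' the whole dataset is reproducible.
#'
#' @param levels_eth,levels_ace Concentration ladders in percent (default
#'   the 13-level serial dilution).
#' @param replicates Number of replicate sweeps per combination (>= 1).
#' @param ramp,params,circuit Forward-model components.
#' @param noise_sd Noise standard deviation in volts.
#' @param seed Master integer seed.
#' @return A list of `sensor_sweep` objects of length
#'   `length(levels_eth) * length(levels_ace) * replicates`, in row-major
#'   order (ethanol slow, acetone fast, replicate fastest).
#' @examples
#' length(generate_dataset(levels_eth = 0.5, levels_ace = 0.5, replicates = 1))
#' @export
generate_dataset <- function(levels_eth = concentration_levels(),
                             levels_ace = concentration_levels(),
                             replicates = 3L,
                             ramp = heater_ramp(),
                             params = calibrate_amplitudes(),
                             circuit = circuit_params(),
                             noise_sd = 0.02, seed = 1L) {
  if (length(levels_eth) == 0 || length(levels_ace) == 0)
    stop("generate_dataset: concentration level lists must be non-empty")
  if (replicates < 1) stop("generate_dataset: replicates must be >= 1")
  sweeps <- vector("list", length(levels_eth) * length(levels_ace) * replicates)
  k <- 0L
  for (ce in levels_eth) for (ca in levels_ace) for (r in seq_len(replicates)) {
    k <- k + 1L
    sweeps[[k]] <- simulate_sweep(analyte_mix(ce, ca), ramp, params, circuit,
                                  noise_sd = noise_sd,
                                  seed = if (noise_sd > 0) derive_seed(seed, k) else NULL,
                                  replicate = r)
  }
  sweeps
}

#' Manifest table for a sweep dataset
#'
#' @param sweeps A list of `sensor_sweep` objects.
#' @param files Optional character vector of per-sweep file names.
#' @return A data frame with columns `file`, `c_ethanol_pct`,
#'   `c_acetone_pct`, `replicate`, `seed`.
#' @export
sweep_manifest <- function(sweeps, files = sprintf("sweep_%04d.csv", seq_along(sweeps))) {
  data.frame(
    file = files,
    c_ethanol_pct = vapply(sweeps, function(s) s$mix$c_ethanol, numeric(1)),
    c_acetone_pct = vapply(sweeps, function(s) s$mix$c_acetone, numeric(1)),
    replicate = vapply(sweeps, function(s) s$replicate, integer(1)),
    seed = vapply(sweeps, function(s) s$seed, integer(1)),
    stringsAsFactors = FALSE
  )
}
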