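#' Thermal, basal-cooling and gas-coupling parameter sets
#'
#' Parameterize the dynamics the campaign generator emulates:
#' * `thermal_params()` — a two-phase composting temperature course: near
#'   ambient during an initial lag, a logistic-type rise to a thermophilic
#'   plateau, then exponential relaxation back toward ambient once cooling
#'   starts (maturation phase).
#' * `basal_params()` — cooling of the pile base by the forced-air channels,
#'   a `strength_C * exp(-z / depth_scale_m)` depression strongest at the
#'   ground and fading with height.
#' * `gas_coupling()` — microbial activity draws O2 down linearly with
#'   temperature excess over ambient; CO2 mirrors the O2 depletion (inverse
#'   coupling, `o2 + co2 / co2_per_o2_depleted = 20.9` identically); CO grows
#'   exponentially with temperature, anchored to 1800 ppm at 75 degrees C.
#'
#' @param lag_days Days of near-ambient lag before heating (0 = none).
#' @param rise_rate Logistic rise steepness, per day.
#' @param plateau_C Thermophilic plateau temperature.
#' @param cooling_start_day Day the maturation cooling starts.
#' @param cooling_rate Exponential cooling rate, per day.
#' @param ambient_C Outside air temperature.
#' @return A named list.
#' @export
thermal_params <- function(lag_days = 0, rise_rate = 0.35, plateau_C = 65,
                           cooling_start_day = 35, cooling_rate = 0.05,
                           ambient_C = 18) {
  stopifnot(plateau_C > ambient_C, rise_rate > 0, cooling_rate > 0)
  list(lag_days = lag_days, rise_rate = rise_rate, plateau_C = plateau_C,
       cooling_start_day = cooling_start_day, cooling_rate = cooling_rate,
       ambient_C = ambient_C)
}

#' @rdname thermal_params
#' @param depth_scale_m Height scale of the basal cooling, metres.
#' @param strength_C Cooling depression at ground level, degrees C.
#' @export
basal_params <- function(depth_scale_m = 0.5, strength_C = 10) {
  stopifnot(depth_scale_m > 0, strength_C >= 0)
  list(depth_scale_m = depth_scale_m, strength_C = strength_C)
}

#' @rdname thermal_params
#' @param o2_drawdown_per_C O2 drawdown per degree of temperature excess,
#'   vol %% per degree C.
#' @param co2_per_o2_depleted CO2 produced per unit O2 depleted (respiratory
#'   quotient-like factor).
#' @param co_ref_ppm,co_ref_C,co_rate CO model: `co = co_ref_ppm *
#'   exp(co_rate * (temp - co_ref_C))`, anchored so the default gives
#'   1800 ppm at 75 degrees C.
#' @export
gas_coupling <- function(o2_drawdown_per_C = 0.18, co2_per_o2_depleted = 0.8,
                         co_ref_ppm = 1800, co_ref_C = 75, co_rate = 0.1) {
  stopifnot(o2_drawdown_per_C >= 0, co2_per_o2_depleted > 0)
  list(o2_drawdown_per_C = o2_drawdown_per_C,
       co2_per_o2_depleted = co2_per_o2_depleted,
       co_ref_ppm = co_ref_ppm, co_ref_C = co_ref_C, co_rate = co_rate)
}

#' Baseline pile temperature at a day and height
#'
#' Exactly ambient through the lag phase; after the lag, a logistic-family
#' rise `ambient + (plateau - ambient) * tanh(rise_rate * (day - lag) / 2)`
#' (zero exactly at the lag boundary, saturating at the plateau); after
#' `cooling_start_day`, exponential relaxation of the excess toward ambient;
#' minus the basal cooling term `strength_C * exp(-z / depth_scale_m)`
#' representing the cold forced-air base near the aeration channels.
#'
#' @param day Day of process (vectorized, >= 1).
#' @param z_m Height above ground, metres (vectorized).
#' @param thermal A [thermal_params()].
#' @param basal A [basal_params()]; `NULL` disables basal cooling.
#' @return Temperature in degrees C.
#' @export
baseline_temperature <- function(day, z_m, thermal = thermal_params(),
                                 basal = basal_params()) {
  th <- thermal
  rise <- function(d) {
    s <- pmax(0, d - th$lag_days)
    th$ambient_C + (th$plateau_C - th$ambient_C) * tanh(th$rise_rate * s / 2)
  }
  temp <- rise(day)
  cooling <- day > th$cooling_start_day
  if (any(cooling)) {
    t0 <- rise(th$cooling_start_day)
    temp[cooling] <- th$ambient_C + (t0 - th$ambient_C) *
      exp(-th$cooling_rate * (day[cooling] - th$cooling_start_day))
  }
  if (!is.null(basal))
    temp <- temp - basal$strength_C * exp(-z_m / basal$depth_scale_m)
  temp
}

#' Gas concentrations coupled to temperature
#'
#' O2 is drawn down linearly with the temperature excess over ambient and
#' clamped to [0, 20.9]; CO2 mirrors the O2 depletion so that
#' `o2 + co2 / co2_per_o2_depleted = 20.9` holds identically; CO grows
#' exponentially with temperature (1800 ppm at 75 degrees C under defaults).
#'
#' @param temp_C Temperature (vectorized).
#' @param coupling A [gas_coupling()].
#' @param ambient_C Ambient temperature the drawdown is measured from.
#' @return A tibble `o2_pct`, `co2_pct`, `co_ppm`.
#' @export
gas_fields <- function(temp_C, coupling = gas_coupling(), ambient_C = 18) {
  cp <- coupling
  o2 <- pmin(pmax(20.9 - cp$o2_drawdown_per_C * pmax(0, temp_C - ambient_C),
                  0), 20.9)
  co2 <- cp$co2_per_o2_depleted * (20.9 - o2)
  co <- cp$co_ref_ppm * exp(cp$co_rate * (temp_C - cp$co_ref_C))
  tibble(o2_pct = o2, co2_pct = co2, co_ppm = co)
}

#' Define an injectable anomaly
#'
#' A localized hot or cold anomaly: within `day_range`, the deltas are added
#' to the baseline signal with a Gaussian spatial kernel
#' `exp(-dist^2 / (2 * radius_m^2))` around the centre (3-D distance), so a
#' probe at the centre receives the full delta.
#'
#' @param type `"hot"` or `"cold"`.
#' @param x_m,y_m,z_m Anomaly centre (pile coordinates).
#' @param radius_m Gaussian kernel radius, metres.
#' @param day_start,day_end Active day range (inclusive).
#' @param d_temp_C,d_o2_pct,d_co2_pct,d_co_ppm Deltas applied at the centre.
#' @return A one-row tibble.
#' @export
spot_injection <- function(type, x_m, y_m, z_m, radius_m,
                           day_start, day_end,
                           d_temp_C = 0, d_o2_pct = 0, d_co2_pct = 0,
                           d_co_ppm = 0) {
  stopifnot(type %in% c("hot", "cold"), radius_m > 0)
  tibble(type = type, x_m = x_m, y_m = y_m, z_m = z_m, radius_m = radius_m,
         day_start = day_start, day_end = day_end,
         d_temp_C = d_temp_C, d_o2_pct = d_o2_pct, d_co2_pct = d_co2_pct,
         d_co_ppm = d_co_ppm)
}

#' Full parameterization of a synthetic campaign
#'
#' Bundles a pile spec with the dynamics parameters, an anomaly list, the
#' per-variable noise model and a seed into a reproducible scenario. Noise is
#' independent Gaussian per variable per probe reading, truncated to physical
#' bounds; readings are then quantized to instrument resolution (temperature
#' and CO to 1 unit, O2 and CO2 to 0.1).
#'
#' @param pile A one-row `pile_spec`.
#' @param n_cycles Number of measurement cycles (default: the pile's).
#' @param cycle_interval_days Days between cycles (default 7; first cycle on
#'   day 1).
#' @param thermal,basal,coupling Parameter sets (see [thermal_params()]).
#' @param anomalies A tibble of [spot_injection()] rows, or `NULL`.
#' @param noise_sd Named numeric: standard deviations for `temp_C`,
#'   `o2_pct`, `co2_pct`, `co_ppm`.
#' @param seed Integer RNG seed for reproducibility.
#' @param exclude_cold_startup Exclude cold-type ground-truth records on days
#'   when the pile-median noise-free temperature is itself below the cold
#'   threshold (whole-pile-cold startup is not a localized anomaly). Default
#'   `TRUE`.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(pile, n_cycles = NULL, cycle_interval_days = 7,
                            thermal = thermal_params(),
                            basal = basal_params(),
                            coupling = gas_coupling(),
                            anomalies = NULL,
                            noise_sd = c(temp_C = 0, o2_pct = 0,
                                         co2_pct = 0, co_ppm = 0),
                            seed = 1L,
                            exclude_cold_startup = TRUE) {
  stopifnot(nrow(pile) == 1L)
  full_sd <- c(temp_C = 0, o2_pct = 0, co2_pct = 0, co_ppm = 0)
  full_sd[names(noise_sd)] <- noise_sd
  if (any(full_sd < 0)) abort("Noise standard deviations must be >= 0.")
  structure(list(pile = pile,
                 n_cycles = as.integer(n_cycles %||% pile$n_cycles),
                 cycle_interval_days = cycle_interval_days,
                 thermal = thermal, basal = basal, coupling = coupling,
                 anomalies = anomalies, noise_sd = full_sd,
                 seed = as.integer(seed),
                 exclude_cold_startup = isTRUE(exclude_cold_startup)),
            class = "scenario_config")
}

#' Preset scenarios
#'
#' Illustrative presets qualitatively matching the two campaign regimes:
#' * `"A"` — a small-mass, highly aerated membrane pile: two-week lag near
#'   ambient, then a rise to a 62 degree plateau, with strong basal cooling.
#' * `"B"` — a large-mass pile heating without lag to a 65 degree plateau.
#'
#' These are illustrative regimes, not fits to any measured pile.
#'
#' @param type `"A"` or `"B"`.
#' @param pile Pile spec to attach (default: A1 resp. B1 from the packaged
#'   config).
#' @param ... Passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
preset_scenario <- function(type = c("A", "B"), pile = NULL, ...) {
  type <- match.arg(type)
  piles <- default_pile_specs()
  if (type == "A") {
    pile <- pile %||% pick_pile(piles, "A1")
    scenario_config(
      pile,
      thermal = thermal_params(lag_days = 14, rise_rate = 0.35,
                               plateau_C = 62, cooling_start_day = 50,
                               cooling_rate = 0.06, ambient_C = 18),
      basal = basal_params(depth_scale_m = 0.5, strength_C = 15),
      ...
    )
  } else {
    pile <- pile %||% pick_pile(piles, "B1")
    scenario_config(
      pile,
      thermal = thermal_params(lag_days = 0, rise_rate = 0.5,
                               plateau_C = 65, cooling_start_day = 35,
                               cooling_rate = 0.05, ambient_C = 18),
      basal = basal_params(depth_scale_m = 0.5, strength_C = 8),
      ...
    )
  }
}

quantize_records <- function(recs) {
  recs$temp_C <- round(recs$temp_C)
  recs$o2_pct <- round(recs$o2_pct, 1)
  recs$co2_pct <- round(recs$co2_pct, 1)
  recs$co_ppm <- round(recs$co_ppm)
  recs
}

clamp_records <- function(recs) {
  recs$o2_pct <- pmin(pmax(recs$o2_pct, 0), 21)
  recs$co2_pct <- pmin(pmax(recs$co2_pct, 0), 100)
  recs$co_ppm <- pmax(recs$co_ppm, 0)
  recs$temp_C <- pmin(pmax(recs$temp_C, -30), 100)
  recs
}

apply_injections <- function(recs, anomalies) {
  if (is.null(anomalies) || nrow(anomalies) == 0L) return(recs)
  for (i in seq_len(nrow(anomalies))) {
    a <- anomalies[i, ]
    active <- recs$day >= a$day_start & recs$day <= a$day_end
    if (!any(active)) next
    d2 <- (recs$x_m[active] - a$x_m)^2 + (recs$y_m[active] - a$y_m)^2 +
      (recs$z_m[active] - a$z_m)^2
    k <- exp(-d2 / (2 * a$radius_m^2))
    recs$temp_C[active] <- recs$temp_C[active] + a$d_temp_C * k
    recs$o2_pct[active] <- recs$o2_pct[active] + a$d_o2_pct * k
    recs$co2_pct[active] <- recs$co2_pct[active] + a$d_co2_pct * k
    recs$co_ppm[active] <- recs$co_ppm[active] + a$d_co_ppm * k
  }
  recs
}

startup_cold_windows <- function(clean, pile_id, cold_temp_lt) {
  med <- clean |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(med = stats::median(.data$temp_C), .groups = "drop")
  cold_days <- med$day[med$med < cold_temp_lt]
  if (length(cold_days) == 0L)
    return(exclusion_window(character(), character(), integer(), integer()))
  exclusion_window(pile_id, "cold", min(cold_days), max(cold_days))
}

#' Simulate a measurement campaign with known ground truth
#'
#' Evaluates the scenario's baseline dynamics plus injected anomalies at
#' every probe location of every cycle day, quantizes to instrument
#' resolution, and emits (a) the noisy measurement records in the standard
#' measurement schema and (b) the ground-truth spot inventory implied by
#' applying the spot criteria to the noise-free quantized signal at probe
#' locations. Identical seeds give identical record sets.
#'
#' @param scenario A [scenario_config()].
#' @param criteria Criteria defining the ground truth
#'   (default [spot_criteria()]).
#' @return A list of class `campaign_sim`: `records` (noisy measurement
#'   tibble with probe coordinates), `clean` (noise-free records),
#'   `ground_truth` (spot inventory, provenance
#'   `"synthetic-ground-truth"`), `exclusions` (the startup cold windows
#'   applied, possibly empty), `scenario`.
#' @export
simulate_campaign <- function(scenario, criteria = spot_criteria()) {
  stopifnot(inherits(scenario, "scenario_config"))
  pile <- scenario$pile
  grid <- build_sampling_grid(pile)
  # validate injection centres inside the pile volume
  if (!is.null(scenario$anomalies) && nrow(scenario$anomalies) > 0L) {
    a <- scenario$anomalies
    outline <- cross_section_outline(pile)
    ok <- a$x_m >= 0 & a$x_m <= pile$length_m &
      points_in_outline(outline, a$y_m, a$z_m)
    if (!all(ok))
      abort("Injection centre(s) outside the pile volume.")
  }
  days <- 1L + (seq_len(scenario$n_cycles) - 1L) * scenario$cycle_interval_days
  recs <- tidyr::expand_grid(day = days, grid)
  recs$temp_C <- baseline_temperature(recs$day, recs$z_m, scenario$thermal,
                                      scenario$basal)
  g <- gas_fields(recs$temp_C, scenario$coupling, scenario$thermal$ambient_C)
  recs <- dplyr::bind_cols(recs, g)
  recs <- apply_injections(recs, scenario$anomalies)
  recs <- clamp_records(recs)
  clean <- quantize_records(recs)
  noisy <- recs
  withr::with_seed(scenario$seed, {
    n <- nrow(noisy)
    sd <- scenario$noise_sd
    if (sd[["temp_C"]] > 0)
      noisy$temp_C <- noisy$temp_C + stats::rnorm(n, 0, sd[["temp_C"]])
    if (sd[["o2_pct"]] > 0)
      noisy$o2_pct <- noisy$o2_pct + stats::rnorm(n, 0, sd[["o2_pct"]])
    if (sd[["co2_pct"]] > 0)
      noisy$co2_pct <- noisy$co2_pct + stats::rnorm(n, 0, sd[["co2_pct"]])
    if (sd[["co_ppm"]] > 0)
      noisy$co_ppm <- noisy$co_ppm + stats::rnorm(n, 0, sd[["co_ppm"]])
  })
  noisy <- quantize_records(clamp_records(noisy))
  truth <- detect_spots(clean, criteria, piles = pile,
                        provenance = "synthetic-ground-truth")
  windows <- if (scenario$exclude_cold_startup)
    startup_cold_windows(clean, pile$pile_id, criteria$cold_temp_lt)
  else exclusion_window(character(), character(), integer(), integer())
  truth <- apply_exclusions(truth, windows)
  structure(list(records = noisy, clean = clean, ground_truth = truth,
                 exclusions = windows, scenario = scenario),
            class = "campaign_sim")
}

#' @export
print.campaign_sim <- function(x, ...) {
  cat("Synthetic campaign: pile ", x$scenario$pile$pile_id, ", ",
      x$scenario$n_cycles, " cycles, ", nrow(x$records), " records, ",
      nrow(x$ground_truth), " ground-truth spot records\n", sep = "")
  invisible(x)
}

#' Spot-recovery experiment
#'
#' Runs the full detection pipeline (record rejection, classification,
#' per-distance aggregation, startup exclusions) on a simulated campaign and
#' scores it against the simulation's ground truth by exact match on
#' (pile, day, distance, type) keys.
#'
#' @param scenario A [scenario_config()].
#' @param criteria Detection criteria (may differ from the truth criteria to
#'   probe threshold sensitivity).
#' @param truth_criteria Criteria defining the ground truth (default: the
#'   standard criteria).
#' @return A one-row tibble of class `recovery_result`: `precision`,
#'   `recall`, `tp`, `fp`, `fn`, `n_truth`, `n_detected`, plus the
#'   simulation in attribute `"sim"`. Precision (recall) is defined as 1
#'   when nothing is detected (nothing is true).
#' @export
recovery_experiment <- function(scenario, criteria = spot_criteria(),
                                truth_criteria = spot_criteria()) {
  sim <- simulate_campaign(scenario, truth_criteria)
  det <- detect_spots(sim$records, criteria, piles = scenario$pile,
                      provenance = "measured")
  det <- apply_exclusions(det, sim$exclusions)
  key <- function(inv) paste(inv$pile_id, inv$day, inv$distance_m, inv$type)
  kt <- key(sim$ground_truth)
  kd <- key(det)
  tp <- sum(kd %in% kt)
  fp <- sum(!kd %in% kt)
  fn <- sum(!kt %in% kd)
  out <- tibble(
    precision = if (length(kd) == 0L) 1 else tp / (tp + fp),
    recall = if (length(kt) == 0L) 1 else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn,
    n_truth = length(kt), n_detected = length(kd)
  )
  attr(out, "sim") <- sim
  class(out) <- c("recovery_result", class(out))
  out
}

#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  as_tibble(x)[, c("precision", "recall", "n_truth", "n_detected")]
}

#' Place injections that clear the spot thresholds at chosen probes
#'
#' Convenience builder for validation scenarios: given probe-grid rows and
#' days, constructs hot (or cold) injections centred exactly on the probe
#' tips with deltas chosen so the injected signal clears each criterion
#' threshold by `margin` at the centre, given the scenario baseline.
#'
#' @param scenario A [scenario_config()] (its baseline determines the deltas).
#' @param at A tibble with `distance_m`, `side`, `level`, `day` rows.
#' @param type `"hot"` or `"cold"`.
#' @param radius_m Injection radius (default 0.5 m, local to a single probe:
#'   neighbouring probes receive only negligible partial deltas).
#' @param margin How far past each threshold to aim, in threshold units
#'   (default: 2 degrees C / 2 vol %).
#' @param criteria Criteria to clear.
#' @return The scenario with the anomalies attached.
#' @export
inject_at_probes <- function(scenario, at, type = "hot", radius_m = 0.5,
                             margin = 2, criteria = spot_criteria()) {
  grid <- build_sampling_grid(scenario$pile)
  at <- as_tibble(at)
  inj <- purrr::pmap(at, function(distance_m, side, level, day, ...) {
    p <- grid[grid$distance_m == distance_m & grid$side == side &
                grid$level == level, ]
    if (nrow(p) != 1L) abort("Injection probe not found in the grid.")
    base_t <- baseline_temperature(day, p$z_m, scenario$thermal,
                                   scenario$basal)
    base_g <- gas_fields(base_t, scenario$coupling,
                         scenario$thermal$ambient_C)
    if (type == "hot") {
      spot_injection("hot", p$x_m, p$y_m, p$z_m, radius_m, day, day,
                     d_temp_C = (criteria$hot_temp_gt + margin) - base_t,
                     d_o2_pct = (criteria$hot_o2_lt - margin) - base_g$o2_pct,
                     d_co2_pct = (criteria$hot_co2_gt + margin) - base_g$co2_pct)
    } else {
      spot_injection("cold", p$x_m, p$y_m, p$z_m, radius_m, day, day,
                     d_temp_C = (criteria$cold_temp_lt - margin) - base_t,
                     d_o2_pct = (criteria$cold_o2_gt + margin) - base_g$o2_pct,
                     d_co2_pct = pmax((criteria$cold_co2_lt - margin), 0.5) - base_g$co2_pct)
    }
  })
  scenario$anomalies <- dplyr::bind_rows(scenario$anomalies,
                                         dplyr::bind_rows(inj))
  scenario
}
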