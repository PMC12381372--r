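# Prey consumption accounting, biomass capture, and logarithmic
# feeding-rate vs prey-density saturation curves.

#' Prey consumption and normalized capture rates from tank densities
#'
#' Converts before/after nauplii densities into per-tank consumption,
#' biomass capture (mean nauplius mass, default 3.2 ug), and
#' surface-area/time normalized rates. Negative apparent consumption
#' (final density above initial, i.e. counting noise) is clamped to zero
#' and flagged via the `clamped` column with a warning.
#'
#' Density inputs may be tank means, or raw triplicate counts supplied as
#' `density_initial_rep1..repK` / `density_final_rep1..repK` columns,
#' which are averaged internally.
#'
#' @param events Data frame of feeding events with columns
#'   `density_initial`, `density_final` (nauplii per litre; or replicate
#'   columns as above), `volume_L`, `duration_h`,
#'   `coral_surface_area_cm2`, and any identifier columns (`tank_id`,
#'   `treatment`, `date_index`), which are carried through.
#' @param nauplius_mass_ug Mean mass of one nauplius in micrograms.
#' @return `events` with appended columns `nauplii_consumed`,
#'   `biomass_consumed_mg`, `rate_nauplii_cm2_h`,
#'   `biomass_per_area_mg_cm2`, `clamped`.
#' @examples
#' ev <- data.frame(density_initial = 1000, density_final = 600,
#'                  volume_L = 40, duration_h = 2,
#'                  coral_surface_area_cm2 = 200)
#' consumption_from_densities(ev) # 16000 nauplii, 51.2 mg, 40 cm^-2 h^-1
#' @export
consumption_from_densities <- function(events, nauplius_mass_ug = 3.2) {
  check_number(nauplius_mass_ug, "nauplius_mass_ug", positive = TRUE)
  events <- average_density_replicates(events)
  check_columns(events, c("density_initial", "density_final", "volume_L",
                          "duration_h", "coral_surface_area_cm2"),
                "`events`")
  for (col in c("volume_L", "duration_h", "coral_surface_area_cm2")) {
    v <- events[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      abort_validation("`%s` must be numeric and strictly positive", col)
    }
  }
  for (col in c("density_initial", "density_final")) {
    v <- events[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      abort_validation("`%s` must be numeric and non-negative", col)
    }
  }
  raw_diff <- events$density_initial - events$density_final
  clamped <- raw_diff < 0
  if (any(clamped)) {
    warn_mixo("%d event(s) had final density above initial; consumption clamped to 0",
              sum(clamped))
  }
  consumed <- pmax(0, raw_diff) * events$volume_L
  events$nauplii_consumed <- consumed
  events$biomass_consumed_mg <- consumed * nauplius_mass_ug / 1000
  events$rate_nauplii_cm2_h <-
    consumed / events$coral_surface_area_cm2 / events$duration_h
  events$biomass_per_area_mg_cm2 <-
    events$biomass_consumed_mg / events$coral_surface_area_cm2
  events$clamped <- clamped
  events
}

# Fold density_*_rep<k> triplicate columns into their means, if present.
average_density_replicates <- function(events) {
  for (base in c("density_initial", "density_final")) {
    reps <- grep(paste0("^", base, "_rep[0-9]+$"), names(events), value = TRUE)
    if (length(reps) && !base %in% names(events)) {
      events[[base]] <- rowMeans(events[, reps, drop = FALSE])
    }
  }
  events
}

#' Cumulative biomass capture per tank
#'
#' Sums per-event area-normalized biomass capture over the experiment, at
#' tank level (fragments are not individually resolved by tank feeding
#' counts).
#'
#' @param capture Data frame from [consumption_from_densities()], with at
#'   least `tank_id` and `biomass_per_area_mg_cm2` (a `treatment` column
#'   is carried through when present).
#' @return Data frame: `tank_id` (+ `treatment`), `n_events`,
#'   `cumulative_mg_cm2`.
#' @export
cumulative_capture <- function(capture) {
  check_columns(capture, c("tank_id", "biomass_per_area_mg_cm2"), "`capture`")
  if (nrow(capture) == 0L) {
    abort_validation("`capture` has no events to accumulate")
  }
  tanks <- unique(as.character(capture$tank_id))
  out <- data.frame(
    tank_id = tanks,
    n_events = as.integer(tapply(capture$biomass_per_area_mg_cm2,
                                 capture$tank_id, length)[tanks]),
    cumulative_mg_cm2 = as.numeric(tapply(capture$biomass_per_area_mg_cm2,
                                          capture$tank_id, sum)[tanks]),
    stringsAsFactors = FALSE
  )
  if ("treatment" %in% names(capture)) {
    out$treatment <- as.character(capture$treatment[
      match(out$tank_id, capture$tank_id)])
    out <- out[, c("tank_id", "treatment", "n_events", "cumulative_mg_cm2")]
  }
  out
}

#' Fit a logarithmic feeding-rate saturation curve
#'
#' Ordinary least squares of capture rate on the natural log of prey
#' density, `rate = a + b * ln(density)` -- the standard non-zero-intercept
#' logarithmic functional-response form for tank feeding assays. R-squared
#' is computed on the rate scale.
#'
#' @param densities Prey densities (nauplii per litre), all > 0.
#' @param rates Capture rates (nauplii cm^-2 h^-1), same length.
#' @return An object of class `"log_curve_fit"`: `a` (intercept), `b`
#'   (slope per ln(nauplii/L)), `r_squared`, `n_points`, `residual_se`.
#'   Supports `predict(fit, density)`.
#' @export
fit_log_curve <- function(densities, rates) {
  densities <- as.numeric(densities)
  rates <- as.numeric(rates)
  if (length(densities) != length(rates)) {
    abort_validation("`densities` and `rates` must have equal length")
  }
  if (length(densities) < 3L) {
    abort_validation("need at least 3 points to fit a log curve (got %d)",
                     length(densities))
  }
  if (anyNA(densities) || anyNA(rates)) {
    abort_validation("log-curve inputs must not contain missing values")
  }
  if (any(densities <= 0)) {
    abort_validation("all densities must be > 0 for a logarithmic fit")
  }
  fit <- lm(rates ~ log(densities))
  cf <- coef(fit)
  resid <- rates - (cf[[1L]] + cf[[2L]] * log(densities))
  ss_res <- sum(resid^2)
  ss_tot <- sum((rates - mean(rates))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 0
  structure(
    list(a = unname(cf[[1L]]), b = unname(cf[[2L]]), r_squared = r2,
         n_points = length(rates),
         residual_se = sqrt(ss_res / max(1L, length(rates) - 2L))),
    class = "log_curve_fit"
  )
}

#' Predict capture rate from a fitted logarithmic curve
#'
#' @param object A `"log_curve_fit"`.
#' @param density Prey densities (> 0) at which to predict.
#' @param ... Unused.
#' @return Predicted rates `a + b * ln(density)`.
#' @export
predict.log_curve_fit <- function(object, density, ...) {
  density <- as.numeric(density)
  if (any(density <= 0, na.rm = TRUE)) {
    abort_validation("prediction densities must be > 0")
  }
  object$a + object$b * log(density)
}

#' @export
print.log_curve_fit <- function(x, ...) {
  cat(sprintf("rate = %.2f + %.2f * ln(density)   [R^2 = %.3f, n = %d]\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit feeding curves per treatment (or per tank)
#'
#' Pools event-level points within each group and fits [fit_log_curve()].
#' The default grouping is treatment (tank-level observations pooled);
#' per-tank fits are available via `per = "tank_id"`.
#'
#' @param capture Data frame from [consumption_from_densities()] with
#'   `density_initial`, `rate_nauplii_cm2_h` and the grouping column.
#' @param per Grouping column name, `"treatment"` (default) or
#'   `"tank_id"`.
#' @return Data frame: grouping column, `a`, `b`, `r_squared`, `n`.
#' @export
fit_feeding_curves <- function(capture, per = "treatment") {
  check_columns(capture, c(per, "density_initial", "rate_nauplii_cm2_h"),
                "`capture`")
  groups <- unique(as.character(capture[[per]]))
  rows <- lapply(groups, function(gr) {
    sub <- capture[capture[[per]] == gr, , drop = FALSE]
    fit <- fit_log_curve(sub$density_initial, sub$rate_nauplii_cm2_h)
    data.frame(group = gr, a = fit$a, b = fit$b, r_squared = fit$r_squared,
               n = fit$n_points, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- per
  out
}
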