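# Synthetic feeding-gradient experiments with known ground truth.
#
# The generator emulates the structure the downstream analysis assumes:
# 12 parent colonies whose fragments are spread across 4 treatments x
# 3 replicate tanks x ~10 fragments, two nutritional source endmembers,
# element-, treatment- and tissue-fraction-specific incorporation of
# heterotrophic material, additive Gaussian colony and tank effects on
# the delta scale, and measurement noise. Bleached-and-fed fragments have
# no symbiont-fraction records.

#' Default per-treatment incorporation fractions
#'
#' Fractions of tissue nitrogen (`element = "N"`) or carbon (`"C"`)
#' replaced by heterotrophic material, per treatment and tissue fraction.
#' Defaults are the benchmark treatment-mean turnovers of the experiment
#' this package models (see [reported_turnover_fractions()]); controls
#' are 0 by definition.
#'
#' @param element `"N"` or `"C"`.
#' @return Data frame: `treatment`, `fraction`, `f`.
#' @export
default_incorporation <- function(element = c("N", "C")) {
  element <- match.arg(element)
  base <- reported_turnover_fractions()
  ctrl <- data.frame(treatment = "control",
                     fraction = c("host", "symbiont"),
                     f = 0, stringsAsFactors = FALSE)
  f <- if (element == "N") base$f_N else base$f_C
  rbind(ctrl, data.frame(treatment = base$treatment,
                         fraction = base$fraction,
                         f = f, stringsAsFactors = FALSE))
}

#' Benchmark treatment-mean turnover fractions
#'
#' The five treatment-by-fraction (nitrogen, carbon) turnover pairs that
#' anchor the preferential-incorporation analysis, as fractions in
#' `[0, 1]`: F_2x host (0.224, 0.095), F_6x host (0.381, 0.095), B_F_6x
#' host (0.336, 0.095), F_2x symbiont (0.19, 0.015), F_6x symbiont
#' (0.31, 0.054). These double as the generator's default incorporation
#' truth.
#'
#' @return Data frame: `treatment`, `fraction`, `f_N`, `f_C`.
#' @export
reported_turnover_fractions <- function() {
  data.frame(
    treatment = c("F_2x", "F_6x", "B_F_6x", "F_2x", "F_6x"),
    fraction = c("host", "host", "host", "symbiont", "symbiont"),
    f_N = c(0.224, 0.381, 0.336, 0.19, 0.31),
    f_C = c(0.095, 0.095, 0.095, 0.015, 0.054),
    stringsAsFactors = FALSE
  )
}

#' Default per-FA response-pattern assignment and effect sizes
#'
#' Each fatty acid carries a true response pattern and additive
#' treatment effects (percentage points of relative abundance, applied
#' before renormalization): FAs positively tracking heterotrophy gain
#' +0.75 / +1.5 at the low / high feeding level, negatively tracking
#' FAs lose half that (so injected effects sum to zero within every
#' treatment and renormalization cannot leak effects into null FAs);
#' bleaching-responsive FAs shift only in the bleached-fed treatment
#' (symbiont-derived PUFAs decline by 3, saturated FAs rise by 5); the
#' remaining 9 FAs are unaffected.
#'
#' @return Data frame: `fa`, `pattern`, `eff_F_2x`, `eff_F_6x`,
#'   `eff_B_F_6x`.
#' @export
default_fa_effects <- function() {
  pos <- c("18:2n6", "18:3n3", "20:5n3", "22:4n6")
  neg <- c("18:1n9", "18:3n6", "20:1n9", "20:3n6", "22:1n9", "23:0")
  bleach_down <- c("14:0", "16:1n7", "18:4n3", "20:4n3", "22:6n3")
  bleach_up <- c("18:0", "20:0", "22:0")
  fas <- default_fa_names()
  pattern <- rep("no_effect", length(fas))
  names(pattern) <- fas
  pattern[pos] <- "positive_with_heterotrophy"
  pattern[neg] <- "negative_with_heterotrophy"
  pattern[c(bleach_down, bleach_up)] <- "bleaching_effect"
  e2 <- e6 <- eb <- setNames(numeric(length(fas)), fas)
  e2[pos] <- 0.75
  e6[pos] <- 1.5
  e2[neg] <- -0.5
  e6[neg] <- -1.0
  eb[pos] <- 1.5 # bleached corals are still fed at the 6x level
  eb[neg] <- -1.0
  eb[bleach_down] <- eb[bleach_down] - 3.0
  eb[bleach_up] <- eb[bleach_up] + 5.0
  data.frame(fa = fas, pattern = unname(pattern),
             eff_F_2x = unname(e2), eff_F_6x = unname(e6),
             eff_B_F_6x = unname(eb), stringsAsFactors = FALSE)
}

#' Default logarithmic feeding-curve coefficients per fed treatment
#'
#' `(a, b)` of `rate = a + b * ln(density)` in nauplii cm^-2 h^-1.
#'
#' @return Data frame: `treatment`, `a`, `b`.
#' @export
default_feeding_curves <- function() {
  data.frame(
    treatment = c("F_2x", "F_6x", "B_F_6x"),
    a = c(-275.7, -209.1, -177.1),
    b = c(54.4, 41.0, 33.8),
    stringsAsFactors = FALSE
  )
}

#' Build and validate a simulation configuration
#'
#' All structural and stochastic knobs of the synthetic experiment.
#' Invalid values raise a configuration error naming the offending field.
#' Identical `seed` + configuration always yields bit-identical output
#' from [generate_experiment()].
#'
#' @param n_colonies Number of parent colonies (genotypes).
#' @param n_tanks_per_treatment Replicate tanks per treatment.
#' @param n_fragments_per_tank Fragments placed in each tank.
#' @param treatments Ordered treatment labels; must include `"control"`.
#' @param endmembers List with `heterotrophic` and `autotrophic`
#'   [source_endmember()]s.
#' @param incorporation_N,incorporation_C Data frames
#'   (`treatment`, `fraction`, `f`) of incorporation fractions in
#'   `[0, 1]`; control rows must be 0.
#' @param fa_effects Per-FA pattern/effect table, see
#'   [default_fa_effects()].
#' @param host_symbiont_d15N_offset Host-minus-symbiont baseline d15N
#'   offset, permil.
#' @param sd_colony,sd_tank Colony/tank random-intercept SDs on the delta
#'   scale, permil.
#' @param sd_measurement_d15N,sd_measurement_d13C Residual measurement
#'   SDs, permil.
#' @param sd_CN Residual SD of molar C:N.
#' @param sd_fa_measurement,sd_fa_colony,sd_fa_tank FA relative-abundance
#'   noise components, percentage points.
#' @param feeding_curve_params Data frame (`treatment`, `a`, `b`) of true
#'   feeding-curve coefficients for fed treatments.
#' @param n_feedings Named integer vector of feeding events per tank for
#'   fed treatments.
#' @param density_range Uniform range of initial prey densities,
#'   nauplii/L.
#' @param sd_feeding_rate SD of event-level rate noise, nauplii cm^-2
#'   h^-1.
#' @param volume_L,duration_h Tank volume and feeding duration.
#' @param fragment_area_range Uniform range of fragment surface areas,
#'   cm^2. The default keeps total tank surface area below ~150 cm^2 so
#'   that the configured feeding curves never demand more prey than the
#'   tank volume holds (see the methods vignette).
#' @param n_nauplii_batches Replicate prey-batch FA profiles to draw.
#' @param sd_source_replicate Batch-to-batch FA SD, percentage points.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(
    n_colonies = 12L,
    n_tanks_per_treatment = 3L,
    n_fragments_per_tank = 10L,
    treatments = c("control", "F_2x", "F_6x", "B_F_6x"),
    endmembers = list(heterotrophic = heterotrophic_endmember(),
                      autotrophic = autotrophic_endmember()),
    incorporation_N = default_incorporation("N"),
    incorporation_C = default_incorporation("C"),
    fa_effects = default_fa_effects(),
    host_symbiont_d15N_offset = 2.0,
    sd_colony = 0.3,
    sd_tank = 0.15,
    sd_measurement_d15N = 0.4,
    sd_measurement_d13C = 0.5,
    sd_CN = 0.15,
    sd_fa_measurement = 0.3,
    sd_fa_colony = 0.15,
    sd_fa_tank = 0.10,
    feeding_curve_params = default_feeding_curves(),
    n_feedings = c(F_2x = 6L, F_6x = 18L, B_F_6x = 18L),
    density_range = c(200, 1500),
    sd_feeding_rate = 20,
    volume_L = 40,
    duration_h = 2,
    fragment_area_range = c(8, 15),
    n_nauplii_batches = 4L,
    sd_source_replicate = 0.25,
    seed = 1L) {

  for (fld in c("n_colonies", "n_tanks_per_treatment",
                "n_fragments_per_tank", "n_nauplii_batches")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v)) {
      abort_config("config field `%s` must be a positive integer", fld)
    }
  }
  if (!"control" %in% treatments) {
    abort_config("config field `treatments` must include \"control\"")
  }
  if (!is.list(endmembers) ||
      !inherits(endmembers$heterotrophic, "source_endmember") ||
      !inherits(endmembers$autotrophic, "source_endmember")) {
    abort_config("config field `endmembers` must hold heterotrophic and autotrophic source_endmember objects")
  }
  if (!identical(sort(names(endmembers$heterotrophic$fa_profile)),
                 sort(names(endmembers$autotrophic$fa_profile)))) {
    abort_config("config field `endmembers` FA profiles must share one FA name set")
  }
  for (fld in c("incorporation_N", "incorporation_C")) {
    inc <- get(fld)
    if (!is.data.frame(inc) ||
        !all(c("treatment", "fraction", "f") %in% names(inc))) {
      abort_config("config field `%s` must be a data frame with treatment, fraction, f", fld)
    }
    if (any(inc$f < 0 | inc$f > 1 | is.na(inc$f))) {
      abort_config("config field `%s` fractions must lie in [0, 1]", fld)
    }
    if (any(inc$f[inc$treatment == "control"] != 0)) {
      abort_config("config field `%s` must have zero incorporation for the control", fld)
    }
  }
  if (!is.data.frame(fa_effects) ||
      !all(c("fa", "pattern", "eff_F_2x", "eff_F_6x", "eff_B_F_6x") %in%
           names(fa_effects))) {
    abort_config("config field `fa_effects` must have fa, pattern and eff_* columns")
  }
  for (fld in c("host_symbiont_d15N_offset", "sd_colony", "sd_tank",
                "sd_measurement_d15N", "sd_measurement_d13C", "sd_CN",
                "sd_fa_measurement", "sd_fa_colony", "sd_fa_tank",
                "sd_feeding_rate", "sd_source_replicate")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        (grepl("^sd_", fld) && v < 0)) {
      abort_config("config field `%s` must be a single %snumber", fld,
                   if (grepl("^sd_", fld)) "non-negative " else "")
    }
  }
  check_number(volume_L, "volume_L", positive = TRUE)
  check_number(duration_h, "duration_h", positive = TRUE)
  for (fld in c("density_range", "fragment_area_range")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0) || v[1L] > v[2L]) {
      abort_config("config field `%s` must be an increasing positive range", fld)
    }
  }
  if (!is.data.frame(feeding_curve_params) ||
      !all(c("treatment", "a", "b") %in% names(feeding_curve_params))) {
    abort_config("config field `feeding_curve_params` must have treatment, a, b")
  }
  fed <- names(n_feedings)
  if (is.null(fed) || !all(fed %in% treatments) || "control" %in% fed) {
    abort_config("config field `n_feedings` must be named after fed (non-control) treatments")
  }
  if (!all(fed %in% feeding_curve_params$treatment)) {
    abort_config("config field `feeding_curve_params` must cover every fed treatment")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_config("config field `seed` must be a single integer")
  }

  structure(
    list(n_colonies = as.integer(n_colonies),
         n_tanks_per_treatment = as.integer(n_tanks_per_treatment),
         n_fragments_per_tank = as.integer(n_fragments_per_tank),
         treatments = treatments, endmembers = endmembers,
         incorporation_N = incorporation_N,
         incorporation_C = incorporation_C, fa_effects = fa_effects,
         host_symbiont_d15N_offset = host_symbiont_d15N_offset,
         sd_colony = sd_colony, sd_tank = sd_tank,
         sd_measurement_d15N = sd_measurement_d15N,
         sd_measurement_d13C = sd_measurement_d13C, sd_CN = sd_CN,
         sd_fa_measurement = sd_fa_measurement,
         sd_fa_colony = sd_fa_colony, sd_fa_tank = sd_fa_tank,
         feeding_curve_params = feeding_curve_params,
         n_feedings = n_feedings, density_range = density_range,
         sd_feeding_rate = sd_feeding_rate, volume_L = volume_L,
         duration_h = duration_h,
         fragment_area_range = fragment_area_range,
         n_nauplii_batches = as.integer(n_nauplii_batches),
         sd_source_replicate = sd_source_replicate,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Incorporation fraction lookup; absent (treatment, fraction) rows mean 0.
incorporation_lookup <- function(inc, treatment, fraction) {
  i <- which(inc$treatment == treatment & inc$fraction == fraction)
  if (length(i)) inc$f[i[1L]] else 0
}

#' Generate one synthetic feeding-gradient experiment
#'
#' Draws a full experiment under `config`: fragment-level tissue
#' measurements (d15N, d13C, molar C:N, and FA relative-abundance
#' profiles for host and symbiont fractions), tank-level feeding events
#' for the fed treatments, replicate prey-batch FA profiles, and the
#' ground truth behind all of it. Tissue deltas follow
#' `delta = base + f * (delta_het - base) + colony + tank + noise`, where
#' `base` is the autotrophic endmember (plus the host d15N offset for the
#' host fraction) and `f` the element/treatment/fraction incorporation
#' fraction; at `f = 1` the tissue sits exactly on the heterotrophic
#' source. Bleached-fed fragments get no symbiont-fraction rows.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"coral_experiment"`: `fragments` (one row
#'   per fragment x fraction, with `fa_*` abundance columns),
#'   `feeding_events`, `nauplii_batches` (matrix), `truth` (list:
#'   `incorporation`, `fragment_truth`, `fa_patterns`, `feeding_curves`,
#'   `seed`), and `config`.
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be built by simulation_config()")
  }
  with_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(config) {
  het <- config$endmembers$heterotrophic
  auto <- config$endmembers$autotrophic
  fas <- names(auto$fa_profile)
  nfa <- length(fas)
  trts <- config$treatments
  n_tanks <- config$n_tanks_per_treatment
  n_frag <- config$n_fragments_per_tank

  # layout ----------------------------------------------------------------
  tank_id <- unlist(lapply(trts, function(tr)
    rep(paste0(tr, "_T", seq_len(n_tanks)), each = n_frag)))
  treatment <- rep(trts, each = n_tanks * n_frag)
  n_total <- length(tank_id)
  fragment_id <- sprintf("frag_%03d", seq_len(n_total))
  colonies <- paste0("C", seq_len(config$n_colonies))
  colony <- sample(rep_len(colonies, n_total))
  area <- runif(n_total, config$fragment_area_range[1L],
                config$fragment_area_range[2L])

  # random effects ----------------------------------------------------------
  tanks <- unique(tank_id)
  col_eff <- matrix(rnorm(config$n_colonies * 2L, sd = config$sd_colony),
                    ncol = 2L, dimnames = list(colonies, c("N", "C")))
  tank_eff <- matrix(rnorm(length(tanks) * 2L, sd = config$sd_tank),
                     ncol = 2L, dimnames = list(tanks, c("N", "C")))
  col_fa <- matrix(rnorm(config$n_colonies * nfa, sd = config$sd_fa_colony),
                   nrow = config$n_colonies, dimnames = list(colonies, fas))
  tank_fa <- matrix(rnorm(length(tanks) * nfa, sd = config$sd_fa_tank),
                    nrow = length(tanks), dimnames = list(tanks, fas))

  # fatty-acid treatment effects, zero for treatments without a column
  fa_eff <- matrix(0, nrow = length(trts), ncol = nfa,
                   dimnames = list(trts, fas))
  fe <- config$fa_effects
  for (tr in intersect(trts, c("F_2x", "F_6x", "B_F_6x"))) {
    cn <- paste0("eff_", tr)
    if (cn %in% names(fe)) {
      fa_eff[tr, fe$fa] <- fe[[cn]]
    }
  }

  # fragment x fraction tissue rows ----------------------------------------
  make_fraction <- function(fraction) {
    keep <- if (fraction == "symbiont") treatment != "B_F_6x" else
      rep(TRUE, n_total)
    idx <- which(keep)
    n <- length(idx)
    base_N <- auto$d15N +
      if (fraction == "host") config$host_symbiont_d15N_offset else 0
    base_C <- auto$d13C
    fN <- vapply(treatment[idx], incorporation_lookup,
                 numeric(1L), inc = config$incorporation_N,
                 fraction = fraction)
    fC <- vapply(treatment[idx], incorporation_lookup,
                 numeric(1L), inc = config$incorporation_C,
                 fraction = fraction)
    d15N <- base_N + fN * (het$d15N - base_N) +
      col_eff[colony[idx], "N"] + tank_eff[tank_id[idx], "N"] +
      rnorm(n, sd = config$sd_measurement_d15N)
    d13C <- base_C + fC * (het$d13C - base_C) +
      col_eff[colony[idx], "C"] + tank_eff[tank_id[idx], "C"] +
      rnorm(n, sd = config$sd_measurement_d13C)
    CN <- auto$CN_molar + fC * (het$CN_molar - auto$CN_molar) +
      rnorm(n, sd = config$sd_CN)

    base_fa <- if (fraction == "host") auto$fa_profile else auto$fa_profile
    famat <- matrix(rep(base_fa, each = n), nrow = n,
                    dimnames = list(NULL, fas))
    if (fraction == "host") {
      famat <- famat + fa_eff[treatment[idx], , drop = FALSE]
    }
    famat <- famat + col_fa[colony[idx], , drop = FALSE] +
      tank_fa[tank_id[idx], , drop = FALSE] +
      matrix(rnorm(n * nfa, sd = config$sd_fa_measurement), nrow = n)
    famat[famat < 0] <- 0
    famat <- sweep(famat, 1L, rowSums(famat), function(x, s) x * (100 / s))
    colnames(famat) <- paste0("fa_", fas)

    df <- data.frame(
      fragment_id = fragment_id[idx], colony = colony[idx],
      tank = tank_id[idx], treatment = treatment[idx],
      fraction = fraction, surface_area_cm2 = area[idx],
      d15N_permil = d15N, d13C_permil = d13C, CN_molar = CN,
      f_N_true = fN, f_C_true = fC,
      stringsAsFactors = FALSE, check.names = FALSE
    )
    cbind(df, as.data.frame(famat, check.names = FALSE))
  }

  host_rows <- make_fraction("host")
  sym_rows <- make_fraction("symbiont")
  fragments <- rbind(host_rows, sym_rows)
  rownames(fragments) <- NULL

  # feeding events ----------------------------------------------------------
  ev <- list()
  for (tr in names(config$n_feedings)) {
    if (!tr %in% trts) next
    cp <- config$feeding_curve_params
    a <- cp$a[cp$treatment == tr][1L]
    b <- cp$b[cp$treatment == tr][1L]
    n_ev <- config$n_feedings[[tr]]
    for (tk in unique(tank_id[treatment == tr])) {
      sa <- sum(area[tank_id == tk])
      d0 <- runif(n_ev, config$density_range[1L], config$density_range[2L])
      mu <- pmax(0, a + b * log(d0))
      rate <- pmax(0, mu + rnorm(n_ev, sd = config$sd_feeding_rate))
      consumed <- rate * sa * config$duration_h
      d1 <- pmax(0, d0 - consumed / config$volume_L)
      ev[[length(ev) + 1L]] <- data.frame(
        tank_id = tk, treatment = tr, date_index = seq_len(n_ev),
        density_initial = d0, density_final = d1,
        volume_L = config$volume_L, duration_h = config$duration_h,
        coral_surface_area_cm2 = sa, stringsAsFactors = FALSE
      )
    }
  }
  feeding_events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(tank_id = character(), treatment = character(),
               date_index = integer(), density_initial = numeric(),
               density_final = numeric(), volume_L = numeric(),
               duration_h = numeric(), coral_surface_area_cm2 = numeric())
  rownames(feeding_events) <- NULL

  nauplii_batches <- generate_source_replicates(
    het, config$n_nauplii_batches, sd = config$sd_source_replicate)

  truth <- list(
    incorporation = merge(
      setNames(config$incorporation_N, c("treatment", "fraction", "f_N")),
      setNames(config$incorporation_C, c("treatment", "fraction", "f_C")),
      by = c("treatment", "fraction"), all = TRUE),
    fragment_truth = fragments[, c("fragment_id", "fraction", "treatment",
                                   "f_N_true", "f_C_true")],
    fa_patterns = config$fa_effects[, c("fa", "pattern")],
    feeding_curves = config$feeding_curve_params,
    seed = config$seed
  )

  structure(
    list(fragments = fragments, feeding_events = feeding_events,
         nauplii_batches = nauplii_batches, truth = truth, config = config),
    class = "coral_experiment"
  )
}

#' @export
print.coral_experiment <- function(x, ...) {
  cat(sprintf("<coral_experiment> %d fragment x fraction rows, %d feeding events, seed %d\n",
              nrow(x$fragments), nrow(x$feeding_events), x$truth$seed))
  invisible(x)
}

#' Write an experiment to CSV files
#'
#' Writes `fragments.csv`, `feeding_events.csv`, `truth.csv`
#' (fragment-level true incorporation fractions), `fa_patterns.csv`,
#' `sources.csv` (endmember means plus FA profiles), the replicate
#' `nauplii_batches.csv`, and a `metadata.json` recording the seed and
#' package version.
#'
#' @param experiment A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_experiment_csvs <- function(experiment, dir) {
  if (!inherits(experiment, "coral_experiment")) {
    abort_validation("`experiment` must be a coral_experiment")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frag <- experiment$fragments
  frag$f_N_true <- NULL
  frag$f_C_true <- NULL
  paths <- c(
    fragments = file.path(dir, "fragments.csv"),
    feeding_events = file.path(dir, "feeding_events.csv"),
    truth = file.path(dir, "truth.csv"),
    fa_patterns = file.path(dir, "fa_patterns.csv"),
    sources = file.path(dir, "sources.csv"),
    nauplii_batches = file.path(dir, "nauplii_batches.csv"),
    metadata = file.path(dir, "metadata.json")
  )
  write.csv(frag, paths[["fragments"]], row.names = FALSE)
  write.csv(experiment$feeding_events, paths[["feeding_events"]],
            row.names = FALSE)
  write.csv(experiment$truth$fragment_truth, paths[["truth"]],
            row.names = FALSE)
  write.csv(experiment$truth$fa_patterns, paths[["fa_patterns"]],
            row.names = FALSE)
  write.csv(endmembers_as_table(experiment$config$endmembers),
            paths[["sources"]], row.names = FALSE)
  write.csv(as.data.frame(experiment$nauplii_batches, check.names = FALSE),
            paths[["nauplii_batches"]], row.names = FALSE)
  jsonlite::write_json(
    list(seed = experiment$truth$seed,
         package = "mixotracer",
         version = as.character(packageVersion("mixotracer"))),
    paths[["metadata"]], auto_unbox = TRUE)
  invisible(paths)
}

endmembers_as_table <- function(endmembers) {
  rows <- lapply(endmembers[c("heterotrophic", "autotrophic")], function(e) {
    prof <- as.list(e$fa_profile)
    names(prof) <- paste0("fa_", names(prof))
    as.data.frame(c(list(name = e$name, d13C_permil = e$d13C,
                         d15N_permil = e$d15N, CN_molar = e$CN_molar),
                    prof), check.names = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read endmembers back from a `sources.csv` table
#'
#' @param sources Data frame as written by [write_experiment_csvs()] (or
#'   a path to the CSV).
#' @return List with `heterotrophic` and `autotrophic`
#'   [source_endmember()]s.
#' @export
read_endmembers <- function(sources) {
  if (is.character(sources)) {
    if (!file.exists(sources)) abort_io("sources file not found: %s", sources)
    sources <- read.csv(sources, check.names = FALSE)
  }
  check_columns(sources, c("name", "d13C_permil", "d15N_permil", "CN_molar"),
                "`sources`")
  fa_cols <- grep("^fa_", names(sources), value = TRUE)
  out <- lapply(seq_len(nrow(sources)), function(i) {
    prof <- as.numeric(sources[i, fa_cols])
    names(prof) <- sub("^fa_", "", fa_cols)
    source_endmember(sources$name[i], sources$d13C_permil[i],
                     sources$d15N_permil[i], sources$CN_molar[i], prof)
  })
  names(out) <- sources$name
  out
}
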