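# Pipeline orchestration: schema validation, stage execution, report
# tables and the run manifest.

.schemas <- list(
  fragments = list(
    required = c("fragment_id", "colony", "tank", "treatment", "fraction",
                 "d15N_permil", "d13C_permil", "CN_molar"),
    numeric = c("d15N_permil", "d13C_permil", "CN_molar"),
    vocab = list(fraction = c("host", "symbiont"))
  ),
  feeding_events = list(
    required = c("tank_id", "treatment", "date_index", "density_initial",
                 "density_final", "volume_L", "duration_h",
                 "coral_surface_area_cm2"),
    numeric = c("density_initial", "density_final", "volume_L",
                "duration_h", "coral_surface_area_cm2"),
    nonneg = c("density_initial", "density_final"),
    positive = c("volume_L", "duration_h", "coral_surface_area_cm2")
  ),
  sources = list(
    required = c("name", "d13C_permil", "d15N_permil", "CN_molar"),
    numeric = c("d13C_permil", "d15N_permil", "CN_molar"),
    vocab = list(name = c("heterotrophic", "autotrophic"))
  )
)

#' Validate a pipeline input CSV against its documented schema
#'
#' Checks required columns, numeric parseability (naming offending rows),
#' controlled vocabularies, and sign constraints. Percent-style FA
#' columns (`fa_*`) are checked to be numeric and non-negative wherever
#' present.
#'
#' @param path Path to a CSV file.
#' @param schema_name One of `"fragments"`, `"feeding_events"`,
#'   `"sources"`.
#' @return A list of class `"schema_report"`: `ok` (logical), `file`,
#'   `schema`, and `problems` (data frame `column`, `row`, `problem`).
#' @export
validate_schema <- function(path, schema_name) {
  schema_name <- match.arg(schema_name, names(.schemas))
  if (!file.exists(path)) abort_io("file not found: %s", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) abort_io("cannot read %s: %s", path,
                                              conditionMessage(e)))
  sch <- .schemas[[schema_name]]
  probs <- list()
  note <- function(column, row, problem) {
    probs[[length(probs) + 1L]] <<- data.frame(
      column = column, row = row, problem = problem,
      stringsAsFactors = FALSE)
  }
  for (col in setdiff(sch$required, names(df))) {
    note(col, NA_integer_, "missing required column")
  }
  for (col in intersect(sch$numeric, names(df))) {
    v <- suppressWarnings(as.numeric(as.character(df[[col]])))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    for (r in bad) note(col, r, "not numeric")
  }
  for (col in intersect(names(sch$vocab), names(df))) {
    bad <- which(!df[[col]] %in% sch$vocab[[col]])
    for (r in bad) {
      note(col, r, sprintf("value not in {%s}",
                           paste(sch$vocab[[col]], collapse = ", ")))
    }
  }
  for (col in intersect(sch$nonneg, names(df))) {
    if (is.numeric(df[[col]])) {
      for (r in which(df[[col]] < 0)) note(col, r, "negative value")
    }
  }
  for (col in intersect(sch$positive, names(df))) {
    if (is.numeric(df[[col]])) {
      for (r in which(df[[col]] <= 0)) note(col, r, "must be > 0")
    }
  }
  for (col in grep("^fa_", names(df), value = TRUE)) {
    v <- suppressWarnings(as.numeric(as.character(df[[col]])))
    for (r in which(is.na(v) & !is.na(df[[col]]))) note(col, r, "not numeric")
    for (r in which(!is.na(v) & v < 0)) note(col, r, "negative abundance")
  }
  problems <- if (length(probs)) do.call(rbind, probs) else
    data.frame(column = character(), row = integer(),
               problem = character(), stringsAsFactors = FALSE)
  structure(list(ok = nrow(problems) == 0L, file = path,
                 schema = schema_name, problems = problems),
            class = "schema_report")
}

#' @export
print.schema_report <- function(x, ...) {
  cat(sprintf("<schema_report> %s against '%s': %s\n", x$file, x$schema,
              if (x$ok) "PASS" else sprintf("FAIL (%d problem(s))",
                                            nrow(x$problems))))
  if (!x$ok) print(utils::head(x$problems, 20L))
  invisible(x)
}

#' Assemble a pipeline configuration
#'
#' Paths to the input CSVs plus every analysis threshold, validated up
#' front so a bad configuration fails before any stage runs.
#'
#' @param fragments,feeding_events,sources Paths to the input CSVs.
#' @param nauplii_batches Optional path to replicate prey-batch FA
#'   profiles (enables source-biomarker classification).
#' @param out Output directory for result tables.
#' @param alpha Significance level used throughout.
#' @param delta13C_capture_threshold Strict Delta13C cutoff (permil).
#' @param nauplius_mass_ug Mean prey mass for biomass conversion.
#' @param epsilon_separation Minimum endmember separation (permil).
#' @param n_perm Monte Carlo permutations for treatment contrasts.
#' @param seed Integer seed for the permutation draws.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fragments, feeding_events, sources,
                            nauplii_batches = NULL, out = ".",
                            alpha = 0.05,
                            delta13C_capture_threshold = -2.0,
                            nauplius_mass_ug = 3.2,
                            epsilon_separation = 0.5,
                            n_perm = 1999L, seed = 1L) {
  check_number(alpha, "alpha", positive = TRUE)
  check_number(delta13C_capture_threshold, "delta13C_capture_threshold")
  check_number(nauplius_mass_ug, "nauplius_mass_ug", positive = TRUE)
  check_number(epsilon_separation, "epsilon_separation")
  check_number(n_perm, "n_perm", positive = TRUE)
  check_number(seed, "seed")
  for (p in c(fragments, feeding_events, sources, nauplii_batches)) {
    if (!file.exists(p)) abort_io("input file not found: %s", p)
  }
  structure(
    list(fragments = fragments, feeding_events = feeding_events,
         sources = sources, nauplii_batches = nauplii_batches, out = out,
         alpha = alpha,
         delta13C_capture_threshold = delta13C_capture_threshold,
         nauplius_mass_ug = nauplius_mass_ug,
         epsilon_separation = epsilon_separation,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Validates input schemas, then executes the feeding, fatty-acid and
#' isotope stages, writing every result table plus `report_summary.csv`
#' and a `manifest.json` (configuration, thresholds, seed, package
#' version, timestamp -- the timestamp is confined to the manifest so
#' result tables are byte-reproducible under a fixed seed).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_validation("`config` must be built by pipeline_config()")
  }
  for (nm in c("fragments", "feeding_events", "sources")) {
    rep <- validate_schema(config[[nm]], nm)
    if (!rep$ok) {
      first <- rep$problems[1L, ]
      abort_validation(
        "schema check failed for %s (%s): column `%s`%s: %s (%d problem(s) total)",
        config[[nm]], nm, first$column,
        if (is.na(first$row)) "" else sprintf(", row %d", first$row),
        first$problem, nrow(rep$problems))
    }
  }
  fragments <- read.csv(config$fragments, check.names = FALSE)
  events <- read.csv(config$feeding_events, check.names = FALSE)
  endmembers <- read_endmembers(config$sources)
  het <- endmembers$heterotrophic
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    write.csv(df, file.path(config$out, name), row.names = FALSE)
    df
  }
  n_warn <- 0L
  count_warnings <- function(expr) {
    withCallingHandlers(expr, mixo_warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  }

  # stage: feeding ----------------------------------------------------------
  capture <- count_warnings(
    consumption_from_densities(events,
                               nauplius_mass_ug = config$nauplius_mass_ug))
  emit(capture, "capture_per_event.csv")
  cumulative <- emit(cumulative_capture(capture), "cumulative_per_tank.csv")
  curves <- emit(fit_feeding_curves(capture), "feeding_curves.csv")

  # stage: fatty acids ------------------------------------------------------
  host <- fragments[fragments$fraction == "host", , drop = FALSE]
  labels <- NULL
  if (!is.null(config$nauplii_batches)) {
    batches <- as.matrix(read.csv(config$nauplii_batches,
                                  check.names = FALSE))
    ctrl_sym <- fragments[fragments$fraction == "symbiont" &
                            fragments$treatment == "control", , drop = FALSE]
    labels <- emit(
      classify_source_biomarkers(batches, fa_matrix(ctrl_sym),
                                 alpha = config$alpha),
      "biomarker_labels.csv")
  }
  patterns <- emit(
    classify_response_patterns(fa_matrix(host), host,
                               alpha = config$alpha,
                               n_perm = config$n_perm, seed = config$seed),
    "pattern_calls.csv")

  # stage: isotopes ---------------------------------------------------------
  offsets <- delta_offsets(fragments)
  offsets$captured_heterotrophy <-
    flag_heterotrophy_capture(offsets$D13C,
                              config$delta13C_capture_threshold)
  emit(offsets, "delta_offsets.csv")
  turnover <- count_warnings(
    turnover_table(fragments, het, epsilon = config$epsilon_separation))
  emit(turnover, "turnover.csv")
  prefs <- emit(preference_table(turnover, het$CN_molar),
                "preference_factors.csv")

  # report ------------------------------------------------------------------
  report <- emit(build_report_summary(turnover, prefs, offsets, labels,
                                      patterns, cumulative),
                 "report_summary.csv")
  manifest <- list(
    package = "mixotracer",
    version = as.character(packageVersion("mixotracer")),
    seed = config$seed,
    alpha = config$alpha,
    delta13C_capture_threshold = config$delta13C_capture_threshold,
    nauplius_mass_ug = config$nauplius_mass_ug,
    epsilon_separation = config$epsilon_separation,
    n_perm = config$n_perm,
    inputs = list(fragments = config$fragments,
                  feeding_events = config$feeding_events,
                  sources = config$sources,
                  nauplii_batches = config$nauplii_batches),
    n_warnings = n_warn,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(capture = capture, cumulative = cumulative,
                 curves = curves, biomarker_labels = labels,
                 pattern_calls = patterns, delta_offsets = offsets,
                 turnover = turnover, preference_factors = prefs,
                 report_summary = report, manifest = manifest))
}

#' Treatment-level preference factors from a turnover table
#'
#' Averages per-fragment percent turnover within treatment x fraction,
#' converts to fractions, and computes the preferential
#' nitrogen-incorporation factor against the heterotrophic source C:N.
#' Groups lacking either element, and the unfed control, are skipped.
#'
#' @param turnover Output of [turnover_table()].
#' @param CN_source Molar C:N of the heterotrophic source.
#' @return Data frame: `treatment`, `fraction`, `f_N`, `f_C`, `factor`,
#'   `factor_rounded`.
#' @export
preference_table <- function(turnover, CN_source) {
  check_columns(turnover, c("treatment", "fraction", "element",
                            "percent_turnover"), "`turnover`")
  grp <- unique(turnover[turnover$treatment != "control",
                         c("treatment", "fraction")])
  rows <- list()
  for (i in seq_len(nrow(grp))) {
    sel <- turnover$treatment == grp$treatment[i] &
      turnover$fraction == grp$fraction[i]
    fN <- mean(turnover$percent_turnover[sel & turnover$element == "N"],
               na.rm = TRUE) / 100
    fC <- mean(turnover$percent_turnover[sel & turnover$element == "C"],
               na.rm = TRUE) / 100
    if (!is.finite(fN) || !is.finite(fC)) next
    fac <- if (fC > 0 && fN >= 0) preference_factor(fN, fC, CN_source)
           else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = grp$treatment[i], fraction = grp$fraction[i],
      f_N = fN, f_C = fC, factor = fac,
      factor_rounded = round(fac), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

build_report_summary <- function(turnover, prefs, offsets, labels,
                                 patterns, cumulative) {
  rows <- list()
  add <- function(section, group, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, group = group, metric = metric, value = value,
      stringsAsFactors = FALSE)
  }
  grp <- unique(turnover[, c("treatment", "fraction", "element")])
  for (i in seq_len(nrow(grp))) {
    sel <- turnover$treatment == grp$treatment[i] &
      turnover$fraction == grp$fraction[i] &
      turnover$element == grp$element[i]
    g <- sprintf("%s/%s/%s", grp$treatment[i], grp$fraction[i],
                 grp$element[i])
    add("turnover", g, "mean_percent",
        mean(turnover$percent_turnover[sel], na.rm = TRUE))
    add("turnover", g, "sd_percent",
        sd(turnover$percent_turnover[sel], na.rm = TRUE))
  }
  for (i in seq_len(nrow(prefs))) {
    add("preference", sprintf("%s/%s", prefs$treatment[i],
                              prefs$fraction[i]),
        "factor", prefs$factor[i])
  }
  flagged <- offsets$captured_heterotrophy
  add("delta13C_capture", "all", "percent_fragments_flagged",
      100 * mean(flagged, na.rm = TRUE))
  if (!is.null(labels)) {
    for (lb in c("heterotrophic", "autotrophic", "non_distinguishing")) {
      add("biomarkers", lb, "n_fas", sum(labels$label == lb))
    }
  }
  for (pt in c("positive_with_heterotrophy", "negative_with_heterotrophy",
               "bleaching_effect", "no_effect")) {
    add("patterns", pt, "n_fas", sum(patterns$pattern == pt))
  }
  for (i in seq_len(nrow(cumulative))) {
    add("cumulative_capture", cumulative$tank_id[i], "mg_cm2",
        cumulative$cumulative_mg_cm2[i])
  }
  do.call(rbind, rows)
}

#' Read a flat `key: value` configuration file
#'
#' Minimal YAML-subset parser: one `key: value` pair per line, `#`
#' comments and blank lines ignored, comma-separated values become
#' vectors, numerics auto-coerced.
#'
#' @param path Path to the file.
#' @return Named list.
#' @export
read_kv_config <- function(path) {
  if (!file.exists(path)) abort_io("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1L]]
    if (length(m) != 3L) abort_io("cannot parse config line: %s", ln)
    key <- trimws(m[2L])
    val <- trimws(strsplit(m[3L], ",")[[1L]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
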