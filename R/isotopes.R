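# Two-endmember stable-isotope mixing: Delta offsets, percent elemental
# turnover, the Delta13C heterotrophy-capture rule, and the preferential
# nitrogen-incorporation factor.

#' Host-minus-symbiont isotope offset
#'
#' The classic heterotrophy proxy Delta = delta_host - delta_symbiont,
#' applicable to both carbon (Delta13C) and nitrogen (Delta15N). Missing
#' values (e.g. bleached fragments with no symbiont fraction) propagate to
#' `NA` rather than erroring.
#'
#' @param host_delta,symbiont_delta Numeric delta values in permil.
#' @return `host_delta - symbiont_delta` (permil), vectorised.
#' @export
delta_offset <- function(host_delta, symbiont_delta) {
  as.numeric(host_delta) - as.numeric(symbiont_delta)
}

#' Flag fragments whose Delta13C indicates captured heterotrophy
#'
#' A fragment "captures heterotrophy" when its host-minus-symbiont carbon
#' isotope offset falls strictly below the threshold (default -2 permil).
#' The boundary value itself is *not* flagged.
#'
#' @param delta13C_offset Delta13C values (permil).
#' @param threshold Strict cutoff in permil (default `-2`).
#' @return Logical vector (`NA` where the offset is missing).
#' @export
flag_heterotrophy_capture <- function(delta13C_offset, threshold = -2.0) {
  check_number(threshold, "threshold")
  as.numeric(delta13C_offset) < threshold
}

#' Percent elemental turnover from a two-endmember mixing model
#'
#' Linear mixing between the control tissue mean (0% heterotrophic
#' turnover) and the heterotrophic source mean (100%):
#' `100 * (delta_fed - control_mean) / (source_mean - control_mean)`.
#' Values can fall outside \[0, 100\] under measurement noise; they are
#' returned untruncated so treatment means stay unbiased.
#'
#' @param delta_fed Tissue delta value(s) of the fragment(s), permil.
#' @param control_mean Mean delta of the control fragments (the 0% point).
#' @param source_mean Mean delta of the heterotrophic source (100% point).
#' @param epsilon Minimum endmember separation (permil); smaller
#'   separations raise an undefined-mixing error instead of dividing by a
#'   noise-scale denominator.
#' @return Percent turnover, vectorised over `delta_fed`.
#' @export
percent_turnover <- function(delta_fed, control_mean, source_mean,
                             epsilon = 0.5) {
  check_number(epsilon, "epsilon")
  sep <- source_mean - control_mean
  if (any(abs(sep) <= epsilon)) {
    abort_mixing(
      "endmember separation |source - control| = %.3g permil is below epsilon = %g; mixing model undefined",
      min(abs(sep)), epsilon)
  }
  100 * (as.numeric(delta_fed) - control_mean) / sep
}

#' Per-fragment turnover estimates for a whole experiment
#'
#' Applies [percent_turnover()] to every fragment and element, using as
#' the 0% point the mean tissue delta of *control* fragments within the
#' same colony (genotype) and tissue fraction, and as the 100% point the
#' heterotrophic source mean. Colonies with no control fragment for a
#' fraction fall back to the global control mean for that fraction
#' (`fallback_used = TRUE`). Zero trophic discrimination is assumed: no
#' enrichment offset is added to either endmember.
#'
#' @param records Data frame with one row per fragment x fraction and
#'   columns `fragment_id`, `colony`, `treatment`, `fraction`,
#'   `d15N_permil`, `d13C_permil`.
#' @param source A heterotrophic [source_endmember()] (fields `d15N`,
#'   `d13C`).
#' @param elements Elements to estimate, subset of `c("N", "C")`.
#' @param control_treatment Label identifying unfed control fragments.
#' @param epsilon Passed to [percent_turnover()].
#' @return Data frame with columns `fragment_id`, `colony`, `treatment`,
#'   `fraction`, `element`, `delta_fed`, `control_mean_used`,
#'   `source_mean_used`, `percent_turnover`, `fallback_used`,
#'   `out_of_range`.
#' @export
turnover_table <- function(records, source, elements = c("N", "C"),
                           control_treatment = "control", epsilon = 0.5) {
  check_columns(records, c("fragment_id", "colony", "treatment", "fraction",
                           "d15N_permil", "d13C_permil"), "`records`")
  elements <- match.arg(elements, several.ok = TRUE)
  ctrl <- records[records$treatment == control_treatment, , drop = FALSE]
  if (nrow(ctrl) == 0L) {
    abort_validation("no control fragments (treatment == \"%s\") found",
                     control_treatment)
  }
  delta_col <- c(N = "d15N_permil", C = "d13C_permil")
  source_mean <- c(N = source$d15N, C = source$d13C)

  out <- list()
  for (el in elements) {
    col <- delta_col[[el]]
    glob <- tapply(ctrl[[col]], ctrl$fraction, mean, na.rm = TRUE)
    by_colony <- tapply(ctrl[[col]],
                        list(ctrl$colony, ctrl$fraction),
                        mean, na.rm = TRUE)
    key_colony <- as.character(records$colony)
    key_frac <- as.character(records$fraction)
    cm <- rep(NA_real_, nrow(records))
    fb <- rep(FALSE, nrow(records))
    for (i in seq_len(nrow(records))) {
      v <- if (key_colony[i] %in% rownames(by_colony) &&
               key_frac[i] %in% colnames(by_colony)) {
        by_colony[key_colony[i], key_frac[i]]
      } else NA_real_
      if (is.na(v)) {
        v <- glob[[key_frac[i]]] %||% NA_real_
        fb[i] <- TRUE
      }
      cm[i] <- v
    }
    if (anyNA(cm)) {
      abort_validation("no control fragments available for fraction(s): %s",
                       paste(unique(key_frac[is.na(cm)]), collapse = ", "))
    }
    pt <- rep(NA_real_, nrow(records))
    ok <- !is.na(records[[col]])
    pt[ok] <- percent_turnover(records[[col]][ok], cm[ok], source_mean[[el]],
                               epsilon = epsilon)
    out[[el]] <- data.frame(
      fragment_id = records$fragment_id,
      colony = records$colony,
      treatment = records$treatment,
      fraction = records$fraction,
      element = el,
      delta_fed = records[[col]],
      control_mean_used = cm,
      source_mean_used = source_mean[[el]],
      percent_turnover = pt,
      fallback_used = fb,
      out_of_range = !is.na(pt) & (pt < 0 | pt > 100),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Preferential nitrogen-incorporation factor
#'
#' Excess of heterotrophic nitrogen over heterotrophic carbon retained in
#' tissue, relative to the stoichiometry delivered by the prey:
#' `(f_N / f_C) * CN_source`, where `f_N` and `f_C` are the fractions of
#' tissue nitrogen and carbon replaced by heterotrophic material and
#' `CN_source` is the molar C:N of the heterotrophic source. When
#' `f_N = f_C` the factor equals the source C:N itself. A zero `f_C`
#' yields `Inf` with a warning (infinite preference), not an error.
#'
#' @param f_N,f_C Turnover fractions in `[0, 1]` (vectorised).
#' @param CN_source Molar C:N ratio of the heterotrophic source (> 0).
#' @return Unrounded factor(s); round to the nearest integer for the
#'   conventional "~16x" style of reporting.
#' @export
preference_factor <- function(f_N, f_C, CN_source) {
  check_number(CN_source, "CN_source", positive = TRUE)
  f_N <- as.numeric(f_N)
  f_C <- as.numeric(f_C)
  if (any(f_N < 0, na.rm = TRUE) || any(f_C < 0, na.rm = TRUE)) {
    abort_validation("turnover fractions must be non-negative")
  }
  if (any(f_C == 0, na.rm = TRUE)) {
    warn_mixo("f_C = 0: preference factor is infinite for %d value(s)",
              sum(f_C == 0, na.rm = TRUE))
  }
  (f_N / f_C) * CN_source
}

#' Per-fragment host-minus-symbiont offsets for an experiment table
#'
#' Pivots a long fragment x fraction record table into one row per
#' fragment with `D13C` and `D15N` offsets; fragments lacking a symbiont
#' record (e.g. bleached) get `NA` offsets.
#'
#' @param records As in [turnover_table()].
#' @return Data frame: `fragment_id`, `colony`, `treatment`, `D13C`,
#'   `D15N`.
#' @export
delta_offsets <- function(records) {
  check_columns(records, c("fragment_id", "colony", "treatment", "fraction",
                           "d15N_permil", "d13C_permil"), "`records`")
  host <- records[records$fraction == "host", , drop = FALSE]
  sym <- records[records$fraction == "symbiont", , drop = FALSE]
  m <- match(host$fragment_id, sym$fragment_id)
  data.frame(
    fragment_id = host$fragment_id,
    colony = host$colony,
    treatment = host$treatment,
    D13C = delta_offset(host$d13C_permil, sym$d13C_permil[m]),
    D15N = delta_offset(host$d15N_permil, sym$d15N_permil[m]),
    stringsAsFactors = FALSE
  )
}
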