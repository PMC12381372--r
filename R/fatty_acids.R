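# Fatty-acid transformations, source-biomarker classification, and
# response-pattern typing across the feeding gradient.

#' Convert fatty-acid masses to relative abundance
#'
#' `100 * mass / total` per sample, so each profile sums to 100% of total
#' FAs. Relative abundances are scale-invariant: multiplying all masses by
#' a constant leaves them unchanged.
#'
#' @param masses Named numeric vector of per-FA masses (e.g. ug per g dry
#'   tissue), or a matrix/data frame with samples in rows.
#' @return Same shape as the input, values in % of total summing to 100
#'   per sample.
#' @export
relative_abundance <- function(masses) {
  if (is.data.frame(masses)) masses <- as.matrix(masses)
  if (is.matrix(masses)) {
    if (any(masses < 0, na.rm = TRUE)) {
      abort_validation("FA masses must be non-negative")
    }
    tot <- rowSums(masses)
    if (any(!is.finite(tot)) || any(tot <= 0)) {
      abort_validation("every sample must have a positive total FA mass")
    }
    return(sweep(masses, 1L, tot, function(x, s) 100 * x / s))
  }
  nm <- names(masses)
  masses <- as.numeric(masses)
  names(masses) <- nm
  if (anyNA(masses) || any(masses < 0)) {
    abort_validation("FA masses must be non-negative and non-missing")
  }
  tot <- sum(masses)
  if (tot <= 0) abort_validation("total FA mass must be > 0")
  100 * masses / tot
}

#' Min-max normalize a fragments-by-FA matrix
#'
#' Per-column mapping `(x - min) / (max - min)` onto `[0, 1]`, the scaling
#' used for biomarker heatmaps. Constant columns have no dynamic range and
#' map to 0 with a warning.
#'
#' @param mat Numeric matrix or data frame with at least 2 rows.
#' @return Numeric matrix of the same dimensions, each non-constant
#'   column spanning exactly `[0, 1]`.
#' @export
min_max_normalize <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat) || length(mat) == 0L) {
    abort_validation("`mat` must be a non-empty numeric matrix")
  }
  if (nrow(mat) < 2L) {
    abort_validation("min-max normalization needs at least 2 rows")
  }
  mins <- apply(mat, 2L, min)
  maxs <- apply(mat, 2L, max)
  rng <- maxs - mins
  const <- rng == 0
  if (any(const)) {
    warn_mixo("%d constant column(s) mapped to 0: %s", sum(const),
              paste(colnames(mat)[const] %||% which(const), collapse = ", "))
    rng[const] <- 1 # numerator is 0 for these columns anyway
  }
  sweep(sweep(mat, 2L, mins, "-"), 2L, rng, "/")
}

#' Classify fatty acids as heterotrophic or autotrophic biomarkers
#'
#' Compares each FA's relative abundance between replicate profiles of
#' the heterotrophic source (prey) and the autotrophic source (control
#' coral symbionts) with a two-sided Wilcoxon rank-sum test
#' ([rank_sum_test()]). FAs with `p < alpha` are labelled by the sign of
#' the median difference: higher in prey = `"heterotrophic"`, higher in
#' symbionts = `"autotrophic"`; otherwise `"non_distinguishing"`. Raw
#' p-values drive the labels; Benjamini-Hochberg adjusted p-values are
#' reported alongside for transparency.
#'
#' @param hetero_reps,auto_reps Matrices/data frames of replicate FA
#'   profiles (replicates in rows, FAs in columns, shared column names),
#'   at least 3 replicates each.
#' @param alpha Significance level for labelling (default 0.05).
#' @return Data frame: `fa`, `label`, `p_value`, `p_adj_bh`, `direction`
#'   (sign of prey-minus-symbiont median difference), `median_hetero`,
#'   `median_auto`.
#' @export
classify_source_biomarkers <- function(hetero_reps, auto_reps, alpha = 0.05) {
  hetero_reps <- as.matrix(hetero_reps)
  auto_reps <- as.matrix(auto_reps)
  if (nrow(hetero_reps) < 3L || nrow(auto_reps) < 3L) {
    abort_validation("need at least 3 replicates per source (got %d and %d)",
                     nrow(hetero_reps), nrow(auto_reps))
  }
  fas <- colnames(hetero_reps)
  if (is.null(fas) || !identical(sort(fas), sort(colnames(auto_reps)))) {
    abort_validation("hetero and auto replicates must share FA column names")
  }
  auto_reps <- auto_reps[, fas, drop = FALSE]
  p <- numeric(length(fas))
  dir <- numeric(length(fas))
  med_h <- numeric(length(fas))
  med_a <- numeric(length(fas))
  for (j in seq_along(fas)) {
    ts <- rank_sum_test(hetero_reps[, j], auto_reps[, j])
    p[j] <- ts$p_value
    med_h[j] <- median(hetero_reps[, j])
    med_a[j] <- median(auto_reps[, j])
    dir[j] <- sign(med_h[j] - med_a[j])
  }
  label <- ifelse(p >= alpha | dir == 0, "non_distinguishing",
                  ifelse(dir > 0, "heterotrophic", "autotrophic"))
  data.frame(fa = fas, label = label, p_value = p,
             p_adj_bh = adjust_p(p, "BH"), direction = dir,
             median_hetero = med_h, median_auto = med_a,
             stringsAsFactors = FALSE)
}

# The three treatment contrasts behind response-pattern typing, each as
# c(reference, treatment).
.pattern_contrasts <- list(
  F_2x_vs_control = c("control", "F_2x"),
  F_6x_vs_control = c("control", "F_6x"),
  B_F_6x_vs_F_6x = c("F_6x", "B_F_6x")
)

#' Type each fatty acid's response across the feeding gradient
#'
#' Computes three treatment contrasts per FA -- each feeding level vs the
#' unfed control, and bleached-fed vs fed at the same level -- via
#' colony-blocked permutation tests ([blocked_permutation_matrix()]; the
#' blocking respects the parent-genotype structure, and tank cannot be
#' used as a block here because tanks are nested within treatments). The
#' decision rule is:
#'
#' 1. if either feeding contrast (F_2x or F_6x vs control) is significant,
#'    the pattern is `positive_with_heterotrophy` or
#'    `negative_with_heterotrophy` by the shared sign of the significant
#'    effects; conflicting signs are resolved by the larger absolute
#'    effect and flagged `ambiguous = TRUE`;
#' 2. otherwise, if the bleached-vs-fed contrast is significant, the
#'    pattern is `bleaching_effect`;
#' 3. otherwise `no_effect`.
#'
#' @param values Numeric matrix of host FA relative abundances, fragments
#'   in rows, FAs in columns (a single FA may be passed as a vector via
#'   [classify_response_pattern()]).
#' @param design Data frame with one row per fragment: `treatment` (all
#'   four of control, F_2x, F_6x, B_F_6x present, >= 5 fragments each)
#'   and `colony`.
#' @param alpha Significance level (default 0.05, strict `p < alpha`).
#' @param n_perm Monte Carlo permutations per contrast.
#' @param seed Optional seed; contrasts use derived sub-seeds.
#' @return Data frame with one row per FA: `fa`, `pattern`, `ambiguous`,
#'   and per-contrast `effect_*` / `p_*` columns.
#' @export
classify_response_patterns <- function(values, design, alpha = 0.05,
                                       n_perm = 1999L, seed = NULL) {
  values <- as.matrix(values)
  check_columns(design, c("treatment", "colony"), "`design`")
  if (nrow(design) != nrow(values)) {
    abort_validation("`design` must have one row per fragment row of `values`")
  }
  trt <- as.character(design$treatment)
  needed <- unique(unlist(.pattern_contrasts))
  missing <- setdiff(needed, trt)
  if (length(missing)) {
    abort_validation("missing treatment(s): %s", paste(missing, collapse = ", "))
  }
  few <- names(which(table(trt)[needed] < 5L))
  if (length(few)) {
    abort_validation("need >= 5 fragments per treatment; too few in: %s",
                     paste(few, collapse = ", "))
  }
  fas <- colnames(values) %||% paste0("fa", seq_len(ncol(values)))

  stats <- list()
  for (ci in seq_along(.pattern_contrasts)) {
    cn <- names(.pattern_contrasts)[ci]
    pair <- .pattern_contrasts[[ci]]
    sel <- trt %in% pair
    res <- blocked_permutation_matrix(
      t(values[sel, , drop = FALSE]),
      groups = factor(trt[sel], levels = pair),
      blocks = design$colony[sel],
      n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + ci
    )
    stats[[cn]] <- res
  }

  eff <- vapply(stats, `[[`, numeric(length(fas)), "effects")
  pv <- vapply(stats, `[[`, numeric(length(fas)), "p_values")
  if (length(fas) == 1L) {
    eff <- matrix(eff, nrow = 1L, dimnames = list(NULL, names(stats)))
    pv <- matrix(pv, nrow = 1L, dimnames = list(NULL, names(stats)))
  }

  pattern <- character(length(fas))
  ambiguous <- logical(length(fas))
  for (j in seq_along(fas)) {
    sig_feed <- pv[j, 1:2] < alpha
    if (any(sig_feed)) {
      e <- eff[j, 1:2][sig_feed]
      signs <- unique(sign(e))
      if (length(signs) > 1L) {
        ambiguous[j] <- TRUE
        s <- sign(e[which.max(abs(e))])
      } else {
        s <- signs
      }
      pattern[j] <- if (s > 0) "positive_with_heterotrophy"
                    else "negative_with_heterotrophy"
    } else if (pv[j, 3L] < alpha) {
      pattern[j] <- "bleaching_effect"
    } else {
      pattern[j] <- "no_effect"
    }
  }
  data.frame(
    fa = fas, pattern = pattern, ambiguous = ambiguous,
    effect_F2x_vs_control = eff[, 1L], p_F2x_vs_control = pv[, 1L],
    effect_F6x_vs_control = eff[, 2L], p_F6x_vs_control = pv[, 2L],
    effect_BF6x_vs_F6x = eff[, 3L], p_BF6x_vs_F6x = pv[, 3L],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname classify_response_patterns
#' @param host_values Numeric vector of one FA's values (one per
#'   fragment).
#' @export
classify_response_pattern <- function(host_values, design, alpha = 0.05,
                                      n_perm = 1999L, seed = NULL) {
  classify_response_patterns(matrix(as.numeric(host_values), ncol = 1L),
                             design, alpha = alpha, n_perm = n_perm,
                             seed = seed)
}

#' Extract the FA abundance matrix from a fragments table
#'
#' Fragment tables written by the generator carry FA relative abundances
#' in columns prefixed `fa_`; this pulls them out as a plain numeric
#' matrix with the prefix stripped.
#'
#' @param fragments Fragment records data frame.
#' @return Numeric matrix, fragments in rows, FAs in columns.
#' @export
fa_matrix <- function(fragments) {
  cols <- grep("^fa_", names(fragments), value = TRUE)
  if (!length(cols)) abort_validation("no `fa_` columns found in `fragments`")
  m <- as.matrix(fragments[, cols, drop = FALSE])
  colnames(m) <- sub("^fa_", "", cols)
  m
}
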