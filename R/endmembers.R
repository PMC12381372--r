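# Nutritional source endmembers: the heterotrophic prey source (Artemia
# nauplii) and the autotrophic source (symbionts of unfed control corals),
# each described by a fatty-acid profile, bulk d13C / d15N, and molar C:N.

#' Construct a nutritional source endmember
#'
#' @param name `"heterotrophic"` or `"autotrophic"`.
#' @param d13C,d15N Bulk isotope values, permil (vs PDB / vs air).
#' @param CN_molar Molar C:N ratio (> 0).
#' @param fa_profile Named numeric vector of relative fatty-acid
#'   abundances (% of total); must be non-negative and sum to 100 within
#'   1e-6.
#' @return A list of class `"source_endmember"`.
#' @export
source_endmember <- function(name, d13C, d15N, CN_molar, fa_profile) {
  name <- match.arg(name, c("heterotrophic", "autotrophic"))
  check_number(d13C, "d13C")
  check_number(d15N, "d15N")
  check_number(CN_molar, "CN_molar", positive = TRUE)
  if (is.null(names(fa_profile)) || any(!nzchar(names(fa_profile)))) {
    abort_config("`fa_profile` must be a named vector of FA abundances")
  }
  if (any(fa_profile < 0)) {
    abort_config("`fa_profile` abundances must be non-negative")
  }
  if (abs(sum(fa_profile) - 100) > 1e-6) {
    abort_config("`fa_profile` must sum to 100 within 1e-6 (sum = %.8f)",
                 sum(fa_profile))
  }
  structure(
    list(name = name, d13C = d13C, d15N = d15N, CN_molar = CN_molar,
         fa_profile = fa_profile),
    class = "source_endmember"
  )
}

#' @export
print.source_endmember <- function(x, ...) {
  cat(sprintf("<source_endmember> %s: d13C = %.1f, d15N = %.1f, C:N = %.2f, %d FAs\n",
              x$name, x$d13C, x$d15N, x$CN_molar, length(x$fa_profile)))
  invisible(x)
}

#' The 27 fatty acids tracked by default
#'
#' @return Character vector of FA shorthand names (chain:double bonds,
#'   omega family).
#' @export
default_fa_names <- function() {
  names(.fa_profile_auto)
}

# Baked-in base profiles (% of total FAs). The autotrophic profile is
# Symbiodiniaceae-like (dominant 16:0, 22:6n3, 18:4n3, galactolipid-range
# C18 PUFAs); the heterotrophic profile is Artemia-nauplii-like (dominant
# 18:3n3, 18:1n9, 16:0, 20:5n3). 15:0, 17:0 and 16:2n4 are deliberately
# identical across sources (non-distinguishing). Both sum to 100 exactly.
.fa_profile_auto <- c(
  "14:0" = 4.0, "14:1" = 1.5, "15:0" = 0.6, "16:0" = 24.0, "16:1n7" = 5.0,
  "16:2n4" = 0.8, "17:0" = 0.6, "18:0" = 5.0, "18:1n9" = 4.0,
  "18:1n7" = 1.0, "18:2n6" = 1.0, "18:3n6" = 2.5, "18:3n3" = 0.4,
  "18:4n3" = 7.0, "20:0" = 1.0, "20:1n9" = 2.5, "20:3n6" = 2.0,
  "20:4n6" = 2.0, "20:4n3" = 4.0, "20:5n3" = 2.0, "22:0" = 1.2,
  "22:1n9" = 2.0, "22:4n6" = 1.6, "22:5n3" = 4.0, "22:6n3" = 16.0,
  "23:0" = 2.3, "24:0" = 2.0
)

.fa_profile_hetero <- c(
  "14:0" = 1.5, "14:1" = 0.3, "15:0" = 0.6, "16:0" = 12.0, "16:1n7" = 2.0,
  "16:2n4" = 0.8, "17:0" = 0.6, "18:0" = 9.0, "18:1n9" = 17.0,
  "18:1n7" = 6.0, "18:2n6" = 7.5, "18:3n6" = 0.8, "18:3n3" = 23.0,
  "18:4n3" = 2.5, "20:0" = 0.4, "20:1n9" = 0.6, "20:3n6" = 0.4,
  "20:4n6" = 3.5, "20:4n3" = 0.8, "20:5n3" = 8.0, "22:0" = 1.9,
  "22:1n9" = 0.3, "22:4n6" = 0.3, "22:5n3" = 0.1, "22:6n3" = 0.05,
  "23:0" = 0.05, "24:0" = 0.0
)

#' Default heterotrophic endmember (Artemia nauplii)
#'
#' Bulk values follow the experimental system this package models:
#' d13C = -20.5 permil, d15N = 9.8 permil, molar C:N = 4.48.
#'
#' @return A [source_endmember()].
#' @export
heterotrophic_endmember <- function() {
  source_endmember("heterotrophic", d13C = -20.5, d15N = 9.8,
                   CN_molar = 4.48, fa_profile = .fa_profile_hetero)
}

#' Default autotrophic endmember (control-coral symbionts)
#'
#' d15N = -1.5 permil and molar C:N = 5.79 as measured on control coral
#' symbionts; d13C = -16.1 permil, placed ~4.4 permil above the nauplii
#' source.
#'
#' @return A [source_endmember()].
#' @export
autotrophic_endmember <- function() {
  source_endmember("autotrophic", d13C = -16.1, d15N = -1.5,
                   CN_molar = 5.79, fa_profile = .fa_profile_auto)
}

#' Generate a pair of source fatty-acid profiles
#'
#' With default arguments, returns the built-in endmember pair with their
#' FA profiles pulled apart by `separation` around the common mean
#' profile: `separation = 1` reproduces the built-in profiles exactly and
#' `separation = 0` makes the two profiles identical. With custom
#' `fa_names`, profiles are built from a uniform base with the requested
#' subsets boosted in their respective source. Profiles are clamped at
#' zero and renormalized to sum to 100.
#'
#' @param separation Non-negative scale on the source contrast.
#' @param fa_names Optional custom FA name set.
#' @param hetero_elevated,auto_elevated FA subsets elevated in each source
#'   (only used with custom `fa_names`); overlapping subsets are a
#'   configuration error.
#' @param boost Abundance boost (percentage points, before renormalizing)
#'   applied to each elevated FA at `separation = 1`.
#' @return List with `heterotrophic` and `autotrophic`
#'   [source_endmember()]s.
#' @export
generate_source_profiles <- function(separation = 1, fa_names = NULL,
                                     hetero_elevated = NULL,
                                     auto_elevated = NULL, boost = 4) {
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0) {
    abort_config("`separation` must be a single non-negative number")
  }
  if (length(intersect(hetero_elevated, auto_elevated))) {
    abort_config("elevated FA subsets overlap: %s",
                 paste(intersect(hetero_elevated, auto_elevated),
                       collapse = ", "))
  }
  if (is.null(fa_names)) {
    h0 <- .fa_profile_hetero
    a0 <- .fa_profile_auto
    m <- (h0 + a0) / 2
    h <- renormalize_profile(pmax(m + separation * (h0 - m), 0))
    a <- renormalize_profile(pmax(m + separation * (a0 - m), 0))
  } else {
    if (!length(fa_names)) abort_config("`fa_names` must be non-empty")
    bad <- setdiff(c(hetero_elevated, auto_elevated), fa_names)
    if (length(bad)) {
      abort_config("elevated FAs not in `fa_names`: %s",
                   paste(bad, collapse = ", "))
    }
    base <- setNames(rep(100 / length(fa_names), length(fa_names)), fa_names)
    h <- base
    a <- base
    h[hetero_elevated] <- h[hetero_elevated] + separation * boost
    a[auto_elevated] <- a[auto_elevated] + separation * boost
    h <- renormalize_profile(h)
    a <- renormalize_profile(a)
  }
  list(
    heterotrophic = source_endmember("heterotrophic", -20.5, 9.8, 4.48, h),
    autotrophic = source_endmember("autotrophic", -16.1, -1.5, 5.79, a)
  )
}

renormalize_profile <- function(p) {
  s <- sum(p)
  if (s <= 0) abort_config("profile sums to zero after perturbation")
  p * (100 / s)
}

#' Draw replicate fatty-acid profiles around an endmember
#'
#' Emulates batch-to-batch (or fragment-to-fragment) variation: Gaussian
#' perturbation of each FA abundance, clamped at zero, renormalized to
#' 100%.
#'
#' @param endmember A [source_endmember()].
#' @param n Number of replicate profiles.
#' @param sd Perturbation SD in percentage points.
#' @param seed Optional seed (caller's RNG state is restored).
#' @return Matrix `n x n_fa`, rows summing to 100.
#' @export
generate_source_replicates <- function(endmember, n, sd = 0.25, seed = NULL) {
  if (!inherits(endmember, "source_endmember")) {
    abort_validation("`endmember` must be a source_endmember")
  }
  check_number(n, "n", positive = TRUE)
  check_number(sd, "sd")
  prof <- endmember$fa_profile
  with_seed(seed, {
    raw <- matrix(rep(prof, each = n) + rnorm(n * length(prof), sd = sd),
                  nrow = n, dimnames = list(NULL, names(prof)))
    raw[raw < 0] <- 0
    sweep(raw, 1L, rowSums(raw), function(x, s) x * (100 / s))
  })
}
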