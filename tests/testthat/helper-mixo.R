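# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (brute-force enumeration) and never call the code
# paths they check.

# A configuration with every stochastic component switched off: tissue
# values then sit exactly on the mixing line.
zero_noise_config <- function(...) {
  simulation_config(
    sd_colony = 0, sd_tank = 0, sd_measurement_d15N = 0,
    sd_measurement_d13C = 0, sd_CN = 0, sd_fa_measurement = 0,
    sd_fa_colony = 0, sd_fa_tank = 0, sd_feeding_rate = 0,
    sd_source_replicate = 0, ...)
}

# Incorporation table with a single constant fraction for every fed
# treatment/fraction (controls stay 0).
flat_incorporation <- function(f) {
  inc <- mixotracer::default_incorporation("N")
  inc$f[inc$treatment != "control"] <- f
  inc
}

# Brute-force two-sided rank-sum p-value by enumerating every subset of
# ranks the x-group could occupy (small N only).
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  N <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  sums <- combn(N, nx, sum)
  mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
}

# Brute-force blocked permutation p-value: enumerate every within-block
# assignment of the group-2 labels and compare |mean diff| tails.
oracle_blocked_perm_p <- function(values, groups, blocks) {
  groups <- factor(groups)
  lv <- levels(groups)
  idx_by_block <- split(seq_along(values), blocks)
  per_block <- lapply(idx_by_block, function(ix) {
    k2 <- sum(groups[ix] == lv[2L])
    combn(ix, k2, simplify = FALSE)
  })
  grid <- expand.grid(lapply(per_block, seq_along))
  n2 <- sum(groups == lv[2L])
  n1 <- sum(groups == lv[1L])
  eff <- function(sel) {
    mean(values[sel]) - mean(values[-sel])
  }
  obs <- eff(which(groups == lv[2L]))
  effs <- apply(grid, 1L, function(row) {
    sel <- unlist(mapply(function(ch, j) ch[[j]], per_block, row,
                         SIMPLIFY = FALSE))
    eff(sel)
  })
  mean(abs(effs) >= abs(obs) - 1e-12)
}
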