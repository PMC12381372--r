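# fatty_acids: transforms, biomarker labels, response patterns.

test_that("relative abundance normalizes masses to percent of total", {
  expect_equal(relative_abundance(c(A = 2, B = 3, C = 5)),
               c(A = 20, B = 30, C = 50))
  expect_equal(unname(relative_abundance(c(only = 7))), 100)
  expect_error(relative_abundance(c(A = 0, B = 0)),
               class = "mixo_validation_error")
  expect_error(relative_abundance(c(A = -1, B = 2)),
               class = "mixo_validation_error")
  # scale invariance
  m <- c(a = 0.3, b = 1.9, c = 7.7, d = 0.05)
  expect_equal(relative_abundance(m), relative_abundance(m * 1e6))
  # matrix form: every row sums to 100
  set.seed(5)
  M <- matrix(runif(40, 0.1, 5), 8, 5)
  expect_equal(rowSums(relative_abundance(M)), rep(100, 8))
})

test_that("min-max normalization maps each column onto [0, 1]", {
  expect_equal(min_max_normalize(cbind(x = c(1, 3, 5)))[, "x"],
               c(0, 0.5, 1))
  expect_warning(z <- min_max_normalize(cbind(c(2, 2, 2))),
                 class = "mixo_warning")
  expect_equal(as.vector(z), c(0, 0, 0))
  set.seed(6)
  M <- matrix(rnorm(60), 12, 5)
  Z <- min_max_normalize(M)
  expect_equal(unname(apply(Z, 2, min)), rep(0, 5))
  expect_equal(unname(apply(Z, 2, max)), rep(1, 5))
  expect_error(min_max_normalize(matrix(1, 1, 3)),
               class = "mixo_validation_error")
  expect_error(min_max_normalize(matrix(numeric(0), 0, 0)),
               class = "mixo_validation_error")
})

test_that("source biomarker labels follow exact rank-sum p and direction", {
  # 4 vs 4 complete separation: p = 2/70, labelled by direction
  h <- matrix(c(5, 6, 7, 8), 4, 2,
              dimnames = list(NULL, c("faA", "faB")))
  a <- matrix(c(1, 2, 3, 4), 4, 2,
              dimnames = list(NULL, c("faA", "faB")))
  a[, "faB"] <- c(9, 10, 11, 12) # higher in the autotrophic source
  lab <- classify_source_biomarkers(h, a)
  expect_equal(lab$p_value, rep(2 / 70, 2))
  expect_equal(lab$label, c("heterotrophic", "autotrophic"))

  # 3 vs 3 complete separation cannot reach p < 0.05 (p = 0.10)
  h3 <- matrix(c(4, 5, 6), 3, 1, dimnames = list(NULL, "fa"))
  a3 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "fa"))
  lab3 <- classify_source_biomarkers(h3, a3)
  expect_equal(lab3$p_value, 0.10)
  expect_equal(lab3$label, "non_distinguishing")

  # identical distributions are never distinguishing
  same <- matrix(rep(c(1, 2, 3, 4), 2), 4, 2,
                 dimnames = list(NULL, c("x", "y")))
  expect_true(all(classify_source_biomarkers(same, same)$label ==
                    "non_distinguishing"))

  expect_error(classify_source_biomarkers(h3[1:2, , drop = FALSE], a3),
               class = "mixo_validation_error")
})

test_that("swapping the source groups swaps labels and keeps p-values", {
  set.seed(31)
  pair <- generate_source_profiles()
  h <- generate_source_replicates(pair$heterotrophic, 5, seed = 1)
  a <- generate_source_replicates(pair$autotrophic, 5, seed = 2)
  fwd <- classify_source_biomarkers(h, a)
  rev <- classify_source_biomarkers(a, h)
  expect_equal(fwd$p_value, rev$p_value)
  swap <- c(heterotrophic = "autotrophic", autotrophic = "heterotrophic",
            non_distinguishing = "non_distinguishing")
  expect_equal(unname(swap[fwd$label]), rev$label)
})

test_that("constructed response patterns are classified by the decision rule", {
  # deterministic-by-construction calls on near-noiseless generated data
  cfg <- simulation_config(sd_fa_measurement = 0.05, sd_fa_colony = 0,
                           sd_fa_tank = 0, seed = 17)
  ex <- generate_experiment(cfg)
  host <- ex$fragments[ex$fragments$fraction == "host", ]
  calls <- suppressWarnings( # block-drop notices are by design here
    classify_response_patterns(fa_matrix(host), host,
                               n_perm = 999, seed = 18))
  truth <- ex$truth$fa_patterns
  called <- calls$pattern[match(truth$fa, calls$fa)]
  # FAs with injected effects are always recovered at these noise levels
  has_effect <- truth$pattern != "no_effect"
  expect_true(all(called[has_effect] == truth$pattern[has_effect]))
  # among them: a positive, a negative and a bleaching representative
  expect_equal(calls$pattern[calls$fa == "18:2n6"],
               "positive_with_heterotrophy")
  expect_equal(calls$pattern[calls$fa == "20:3n6"],
               "negative_with_heterotrophy")
  expect_equal(calls$pattern[calls$fa == "16:1n7"], "bleaching_effect")
})

test_that("conflicting significant feeding contrasts are flagged ambiguous", {
  ex <- generate_experiment(simulation_config(seed = 23))
  host <- ex$fragments[ex$fragments$fraction == "host", ]
  v <- rnorm(nrow(host), sd = 0.05) +
    ifelse(host$treatment == "F_2x", 3, 0) +
    ifelse(host$treatment %in% c("F_6x", "B_F_6x"), -3, 0)
  call <- suppressWarnings(
    classify_response_pattern(v, host, n_perm = 999, seed = 24))
  expect_true(call$ambiguous)
  expect_true(call$pattern %in% c("positive_with_heterotrophy",
                                  "negative_with_heterotrophy"))
})

test_that("pure-noise FAs are called no_effect at the structural bound", {
  # under the three-contrast rule at alpha = 0.05 the attainable no_effect
  # rate for a null FA is bounded below by 1 - 3 * alpha = 0.85
  rates <- c()
  for (s in 1:2) {
    ex <- generate_experiment(simulation_config(seed = s))
    host <- ex$fragments[ex$fragments$fraction == "host", ]
    set.seed(1000 + s)
    V <- matrix(rnorm(nrow(host) * 500, sd = 0.3), nrow(host), 500) +
      rnorm(12, sd = 0.15)[as.integer(factor(host$colony))]
    pc <- suppressWarnings(
      classify_response_patterns(V, host, n_perm = 999, seed = 2000 + s))
    rates <- c(rates, mean(pc$pattern == "no_effect"))
  }
  expect_gte(mean(rates), 0.85)
})

test_that("pattern classification validates its design", {
  ex <- generate_experiment(simulation_config(seed = 29))
  host <- ex$fragments[ex$fragments$fraction == "host", ]
  no_ctrl <- host[host$treatment != "control", ]
  expect_error(
    classify_response_patterns(fa_matrix(no_ctrl), no_ctrl, seed = 1),
    "control", class = "mixo_validation_error")
  keep3 <- which(host$treatment == "F_2x")[1:3]
  few <- host[host$treatment != "F_2x" | seq_len(nrow(host)) %in% keep3, ]
  expect_error(
    classify_response_patterns(fa_matrix(few), few, seed = 1),
    class = "mixo_validation_error")
})
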