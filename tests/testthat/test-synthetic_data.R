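# synthetic_data: generator structure, mixing identities, determinism,
# configuration validation, source profiles.

test_that("zero incorporation + zero noise sits exactly on the autotrophic base", {
  cfg <- zero_noise_config(incorporation_N = flat_incorporation(0),
                           incorporation_C = flat_incorporation(0),
                           seed = 1)
  ex <- generate_experiment(cfg)
  host <- ex$fragments[ex$fragments$fraction == "host", ]
  sym <- ex$fragments[ex$fragments$fraction == "symbiont", ]
  auto <- autotrophic_endmember()
  # host d15N carries the configured host-symbiont offset; all else is
  # the autotrophic endmember exactly
  expect_equal(unique(host$d15N_permil), auto$d15N + 2.0)
  expect_equal(unique(sym$d15N_permil), auto$d15N)
  expect_equal(unique(ex$fragments$d13C_permil), auto$d13C)
  expect_equal(unique(round(ex$fragments$CN_molar, 12)), auto$CN_molar)
})

test_that("full incorporation pins fed tissue to the heterotrophic source", {
  cfg <- zero_noise_config(incorporation_N = flat_incorporation(1), seed = 2)
  ex <- generate_experiment(cfg)
  fed_host <- ex$fragments[ex$fragments$fraction == "host" &
                             ex$fragments$treatment != "control", ]
  expect_equal(unique(fed_host$d15N_permil), 9.8)
})

test_that("identical seed and config give bit-identical output", {
  a <- generate_experiment(simulation_config(seed = 42))
  b <- generate_experiment(simulation_config(seed = 42))
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$feeding_events, b$feeding_events)
  expect_identical(a$nauplii_batches, b$nauplii_batches)
  c <- generate_experiment(simulation_config(seed = 43))
  expect_false(identical(a$fragments$d15N_permil, c$fragments$d15N_permil))
})

test_that("experiment layout matches the design", {
  ex <- generate_experiment(simulation_config(seed = 3))
  frag <- ex$fragments
  # 4 treatments x 3 tanks x 10 fragments of host rows; no symbiont rows
  # for bleached-fed fragments
  expect_equal(sum(frag$fraction == "host"), 120L)
  expect_equal(sum(frag$fraction == "symbiont"), 90L)
  expect_equal(nrow(frag[frag$treatment == "B_F_6x" &
                           frag$fraction == "symbiont", ]), 0L)
  expect_setequal(unique(frag$treatment),
                  c("control", "F_2x", "F_6x", "B_F_6x"))
  expect_equal(length(unique(frag$colony)), 12L)
  # FA profiles are relative abundances summing to 100
  expect_equal(rowSums(fa_matrix(frag)), rep(100, nrow(frag)),
               tolerance = 1e-9)
  # feeding events only for fed treatments, with the configured counts
  ev <- ex$feeding_events
  expect_false("control" %in% ev$treatment)
  expect_equal(sum(ev$treatment == "F_2x"), 3L * 6L)
  expect_equal(sum(ev$treatment == "F_6x"), 3L * 18L)
  # one truth record per fragment x fraction, per FA, per fed treatment
  expect_equal(nrow(ex$truth$fragment_truth), nrow(frag))
  expect_equal(nrow(ex$truth$fa_patterns), 27L)
  expect_setequal(ex$truth$feeding_curves$treatment,
                  c("F_2x", "F_6x", "B_F_6x"))
})

test_that("invalid configurations fail naming the field", {
  expect_error(simulation_config(n_colonies = 0),
               "n_colonies", class = "mixo_config_error")
  expect_error(simulation_config(treatments = c("F_2x", "F_6x")),
               "treatments", class = "mixo_config_error")
  bad <- flat_incorporation(0.5)
  bad$f[1] <- 1.7
  expect_error(simulation_config(incorporation_N = bad),
               "incorporation_N", class = "mixo_config_error")
  ctrl_fed <- flat_incorporation(0.3)
  ctrl_fed$f[ctrl_fed$treatment == "control"] <- 0.1
  expect_error(simulation_config(incorporation_C = ctrl_fed),
               "incorporation_C", class = "mixo_config_error")
  expect_error(simulation_config(density_range = c(1500, 200)),
               "density_range", class = "mixo_config_error")
  expect_error(simulation_config(n_feedings = c(control = 2L)),
               "n_feedings", class = "mixo_config_error")
})

test_that("source profile generation respects separation and normalization", {
  same <- generate_source_profiles(separation = 0)
  expect_equal(same$heterotrophic$fa_profile, same$autotrophic$fa_profile)
  pair <- generate_source_profiles()
  expect_equal(sum(pair$heterotrophic$fa_profile), 100, tolerance = 1e-6)
  expect_equal(sum(pair$autotrophic$fa_profile), 100, tolerance = 1e-6)
  # custom FA sets: overlapping elevated subsets are a config error
  expect_error(
    generate_source_profiles(fa_names = c("a", "b", "c"),
                             hetero_elevated = "a", auto_elevated = "a"),
    class = "mixo_config_error")
  cus <- generate_source_profiles(fa_names = c("a", "b", "c", "d"),
                                  hetero_elevated = "a",
                                  auto_elevated = "b")
  expect_gt(cus$heterotrophic$fa_profile[["a"]],
            cus$autotrophic$fa_profile[["a"]])
  expect_gt(cus$autotrophic$fa_profile[["b"]],
            cus$heterotrophic$fa_profile[["b"]])
})

test_that("replicate profiles renormalize to 100 after perturbation", {
  reps <- generate_source_replicates(heterotrophic_endmember(), 8,
                                     sd = 0.4, seed = 10)
  expect_equal(dim(reps), c(8L, 27L))
  expect_equal(rowSums(reps), rep(100, 8), tolerance = 1e-6)
  expect_true(all(reps >= 0))
})

test_that("generated source replicates separate for the downstream classifier", {
  pair <- generate_source_profiles()
  h <- generate_source_replicates(pair$heterotrophic, 4, seed = 21)
  a <- generate_source_replicates(pair$autotrophic, 4, seed = 22)
  labels <- classify_source_biomarkers(h, a)
  expect_gte(sum(labels$label != "non_distinguishing"), 20L)
})

test_that("experiment CSV round-trip preserves the tables", {
  td <- tempfile("mixo")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  ex <- generate_experiment(simulation_config(seed = 6))
  paths <- write_experiment_csvs(ex, td)
  expect_true(all(file.exists(paths)))
  frag <- read.csv(paths[["fragments"]], check.names = FALSE)
  expect_equal(nrow(frag), nrow(ex$fragments))
  expect_equal(fa_matrix(frag), fa_matrix(ex$fragments), tolerance = 1e-9)
  em <- read_endmembers(paths[["sources"]])
  expect_equal(em$heterotrophic$CN_molar, 4.48)
  expect_equal(em$heterotrophic$fa_profile,
               heterotrophic_endmember()$fa_profile, tolerance = 1e-9)
})
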