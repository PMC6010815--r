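test_that("generators are byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 42)
  expect_identical(simulate_phenology(cfg), simulate_phenology(cfg))
  expect_identical(simulate_foraging(cfg), simulate_foraging(cfg))
  expect_identical(simulate_crossings(cfg), simulate_crossings(cfg))
  expect_identical(simulate_spectra(cfg), simulate_spectra(cfg))
  cfg2 <- simulation_config(seed = 43)
  expect_false(identical(simulate_foraging(cfg), simulate_foraging(cfg2)))
})

test_that("phenology: point windows give zero variance, disjoint windows no overlap", {
  pt <- simulation_config(seed = 1, phenology = list(
    window = list(white = c("2016-08-01", "2016-08-01"),
                  pink = c("2016-08-01", "2016-08-01")),
    flower_lifespan_sd = 0))
  ph <- simulate_phenology(pt)
  expect_equal(length(unique(ph$plants$first_day)), 1L)

  dj <- simulation_config(seed = 1, phenology = list(
    window = list(white = c("2016-07-01", "2016-07-05"),
                  pink = c("2016-09-01", "2016-09-05"))))
  ph2 <- simulate_phenology(dj)
  ov <- overlap_days(ph2$intervals$white, ph2$intervals$pink)
  expect_equal(ov$shared, 0L)

  bad <- simulation_config(seed = 1)
  bad$phenology$window$white <- c("2016-09-01", "2016-08-01")
  expect_error(simulate_phenology(bad), class = "isobarrier_invalid_input")
})

test_that("form-level overlap tracks the configured windows", {
  cfg <- simulation_config(seed = 10)
  props <- vapply(1:50, function(i) {
    cfg$seed <- 10L + i
    ph <- simulate_phenology(cfg)
    ov <- overlap_days(ph$intervals$white, ph$intervals$pink)
    ov$shared / (ov$shared + ov$unshared)
  }, numeric(1))
  # configured windows overlap broadly; realised S/(S+U) should too
  expect_gt(mean(props), 0.7)
  expect_lt(stats::sd(props) / sqrt(length(props)), 0.02)
})

test_that("foraging: kappa = 1 means complete constancy, invalid kappa errors", {
  cfg <- simulation_config(seed = 5, foraging = list(species = list(
    list(species = "sim", kappa = 1, n_foragers = 20, bout_mean = 8))))
  log <- simulate_foraging(cfg)
  per_forager_forms <- tapply(log$form, log$forager_id,
                              function(f) length(unique(f)))
  expect_true(all(per_forager_forms == 1L))
  expect_error(simulation_config(foraging = list(species = list(
    list(species = "bad", kappa = 1.2, n_foragers = 5, bout_mean = 5)))),
    class = "isobarrier_invalid_input")
})

test_that("crossings respect cell probabilities and the Poisson limit", {
  cfg <- simulation_config(seed = 8)
  cr <- simulate_crossings(cfg)
  ctrl <- cr[cr$treatment == "control", ]
  expect_true(all(ctrl$fruit == 0))  # autogamy never sets fruit
  expect_true(all(is.na(cr$seeds_large[cr$fruit == 0])))
  fruited <- cr[cr$fruit == 1 & !is.na(cr$seeds_large), ]
  expect_true(all(fruited$seeds_large + fruited$seeds_small +
                    fruited$seeds_aborted + fruited$seeds_empty == 300))

  # dispersion -> infinity approaches Poisson (variance ~ mean)
  big <- simulation_config(seed = 9, crossing = list(
    n_per_cell = 2000, tube_dispersion = 1e9))
  tubes <- simulate_crossings(big)
  x <- tubes$pollen_tubes[tubes$maternal_form == "white" &
                            tubes$treatment == "intraform"]
  expect_equal(stats::var(x) / mean(x), 1, tolerance = 0.15)

  expect_error(
    simulation_config(seed = 1, crossing = list(embryo_p = list(
      white = list(self = c(large = 0.5, small = 0.5, aborted = 0.2,
                            empty = 0.1))))),
    class = "isobarrier_invalid_input")
})

test_that("generating fruit RI is recovered within the bootstrap interval", {
  cfg0 <- simulation_config(seed = 1)
  true_ri <- pairwise_ri(cfg0$crossing$fruit_p$white[["intraform"]],
                         cfg0$crossing$fruit_p$white[["interform"]])
  hits <- vapply(1:100, function(i) {
    cfg <- simulation_config(seed = 2000 + i,
                             crossing = list(n_per_cell = 60))
    cr <- simulate_crossings(cfg)
    con <- cr$fruit[cr$maternal_form == "white" &
                      cr$treatment == "intraform"]
    het <- cr$fruit[cr$maternal_form == "white" &
                      cr$treatment == "interform"]
    ci <- ri_bootstrap_ci(con, het, B = 500, seed = i)
    ci$low <= true_ri && true_ri <= ci$high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("spectra: no noise means zero distance; noise keeps it small", {
  cfg <- simulation_config(seed = 2, spectra = list(
    n = c(white = 2, pink = 1, intermediate = 1), noise_sd = 0))
  sp <- simulate_spectra(cfg)
  vm <- vision_model("honeybee")
  loci <- hexagon_loci(sp, vm)
  same <- chromatic_distance(loci[loci$spectrum == "white_1", ],
                             loci[loci$spectrum == "white_2", ])
  expect_equal(same, 0)

  dists <- vapply(1:50, function(i) {
    cfg <- simulation_config(seed = 3000 + i, spectra = list(
      n = c(white = 1, pink = 1, intermediate = 1), noise_sd = 0.005))
    loci <- hexagon_loci(simulate_spectra(cfg), vm)
    chromatic_distance(loci[loci$spectrum == "white_1", ],
                       loci[loci$spectrum == "pink_1", ])
  }, numeric(1))
  expect_gt(stats::sd(dists), 0)
  expect_lt(stats::sd(dists), 0.02)
})

test_that("simulate_study writes a readable bundle with provenance", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 4, spectra = list(
    n = c(white = 2, pink = 2, intermediate = 1)))
  paths <- simulate_study(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  expect_length(read_flowering(paths$flowering), 2)
  expect_gt(nrow(read_foraging_log(paths$foraging)), 0)
  expect_gt(nrow(read_crossing_trials(paths$crossings)), 0)
  expect_length(read_spectra(paths$spectra), 5)
  prov <- jsonlite::read_json(paths$provenance)
  expect_equal(prov$seed, 4L)
  expect_match(prov$config_hash, "^[0-9a-f]{8}$")
})

test_that("the shipped paper-like YAML reproduces the default config", {
  path <- system.file("extdata", "config", "paper_like.yaml",
                      package = "isobarrier")
  cfg <- read_simulation_config(path)
  def <- simulation_config(seed = 1)
  expect_equal(cfg$crossing$tube_mean, def$crossing$tube_mean)
  expect_equal(cfg$foraging$availability, def$foraging$availability)
  expect_equal(length(cfg$foraging$species), 2L)
  expect_identical(simulate_crossings(cfg), simulate_crossings(def))
})
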