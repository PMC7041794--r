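wt <- get_variant("WT")

test_that("configuration count arithmetic matches the published design", {
  paper <- sampler_params("paper-counts")
  expect_identical(configurations_per_run(paper), 1500L)
  expect_identical(configurations_per_run(paper) * paper$n_runs, 30000L)
  desk <- sampler_params("desk")
  expect_identical(configurations_per_run(desk), 1500L)
  expect_identical(desk$production_steps, 3e5)
  expect_identical(desk$equilibration_steps, 2e4)
  expect_error(sampler_params(production_steps = 1000, sampling_interval = 300),
               "divide")
})

test_that("ensembles have the configured size and provenance", {
  p <- tiny_params()
  ens <- sample_ensemble(wt, p)
  expect_equal(n_conformations(ens), configurations_per_run(p) * p$n_runs)
  expect_equal(dim(ens$coords), c(4L * 22L + 2L, 3L, n_conformations(ens)))
  expect_equal(ens$run, rep(1:2, each = configurations_per_run(p)))
  expect_length(ens$seeds, 2L)
})

test_that("identical seeds reproduce ensembles bit-for-bit; runs differ", {
  p <- tiny_params(base_seed = 77L)
  a <- sample_ensemble(wt, p)
  b <- sample_ensemble(wt, p)
  expect_identical(a$phi, b$phi)
  expect_identical(a$coords, b$coords)
  per <- configurations_per_run(p)
  expect_false(identical(a$phi[1:per, ], a$phi[(per + 1):(2 * per), ]))
  c <- sample_ensemble(wt, tiny_params(base_seed = 78L))
  expect_false(identical(a$phi, c$phi))
})

test_that("every sampled conformation satisfies the droplet constraint", {
  p <- tiny_params(droplet_radius = 25)
  ens <- sample_ensemble(wt, p)
  for (k in seq(1, n_conformations(ens), by = 7)) {
    x <- ens$coords[2:(4 * 22 + 1), , k]
    ctr <- colMeans(x)
    expect_lte(max(sqrt(rowSums(sweep(x, 2, ctr)^2))), 25 + 1e-9)
  }
})

test_that("an impossible droplet fails loudly", {
  expect_error(sample_ensemble(wt, tiny_params(droplet_radius = 4)),
               "droplet|acceptance")
})

test_that("with all interactions off the chain reproduces independent basin sampling", {
  # Markov-chain sampler vs a no-chain oracle drawing every residue
  # independently from the same basin mixture; <Ree^2> must agree within
  # 3 combined standard errors
  p <- sampler_params(n_runs = 6L, production_steps = 10000,
                      equilibration_steps = 1000, sampling_interval = 50,
                      interactions = c(sterics = FALSE, electrostatics = FALSE,
                                       helix_bias = FALSE),
                      base_seed = 5L)
  ens <- sample_ensemble(wt, p)
  dt <- descriptor_table(ens)
  ree2 <- dt$per_conformation$ree^2
  run_means <- tapply(ree2, ens$run, mean)
  se_mc <- sd(run_means) / sqrt(length(run_means))

  ann <- residue_annotations(wt)
  draw_residue <- function(w) {
    tot <- w + 2
    u <- runif(1) * tot
    if (u < w) {
      c(runif(1, -100, -30), runif(1, -67, -7))
    } else if (u < w + 1) {
      c(runif(1, -180, -50), runif(1, 90, 180))
    } else {
      repeat {
        x <- runif(2, -180, 180)
        if (!in_helical_basin(x[1], x[2]) &&
            !(x[1] >= -180 && x[1] <= -50 && x[2] >= 90 && x[2] <= 180)) return(x)
      }
    }
  }
  set.seed(99)
  n_draws <- 1200
  oracle <- replicate(n_draws, {
    pp <- t(vapply(ann$helix_propensity, draw_residue, numeric(2)))
    end_to_end(build_conformation(pp, wt))^2
  })
  se_or <- sd(oracle) / sqrt(n_draws)
  se <- sqrt(se_mc^2 + se_or^2)
  expect_lt(abs(mean(ree2) - mean(oracle)), 3 * se)
})

test_that("helicity responds monotonically to propensity overrides", {
  region <- 50:59
  levels <- c(0.6, 1.6, 4.0)
  f <- vapply(levels, function(w) {
    ov <- stats::setNames(rep(w, length(region)), region)
    p <- sampler_params(n_runs = 4L, production_steps = 30000,
                        equilibration_steps = 2000, sampling_interval = 100,
                        helix_propensity_overrides = ov, base_seed = 31L)
    region_helicity(sample_ensemble(wt, p), region = region)
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("excluded-volume reference records sterics-only provenance and is expanded", {
  p <- tiny_params(base_seed = 42L)
  ev <- excluded_volume_reference(wt, p)
  expect_identical(unname(ev$params$interactions[c("sterics", "electrostatics", "helix_bias")]),
                   c(TRUE, FALSE, FALSE))
  p_att <- tiny_params(base_seed = 42L,
                       interactions = c(sterics = TRUE, electrostatics = FALSE,
                                        helix_bias = FALSE, attraction = TRUE),
                       attraction_strength = 1.0)
  att <- sample_ensemble(wt, p_att)
  rg_ev <- mean(descriptor_table(ev)$per_conformation$rg)
  rg_att <- mean(descriptor_table(att)$per_conformation$rg)
  expect_gt(rg_ev, rg_att)
})

test_that("sampler parameter validation catches bad inputs", {
  expect_error(sampler_params(ionic_strength = 0), "ionic_strength")
  expect_error(sampler_params(droplet_radius = -1), "droplet_radius")
  expect_error(sample_ensemble(wt, tiny_params(
    helix_propensity_overrides = c("99" = 2))), "outside the sequence")
})
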