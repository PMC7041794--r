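wt <- get_variant("WT")

test_that("radius of gyration matches closed forms and the pairwise oracle", {
  expect_equal(radius_of_gyration(matrix(1, 4, 3)), 0)
  d <- 6.4
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(d, 0, 0))), d / 2)
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(15, sd = 4), 5, 3)
    expect_equal(radius_of_gyration(x), oracle_rg(x), tolerance = 1e-10)
  }
})

test_that("asphericity hits its closed-form limits and the moment oracle", {
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(asphericity(tetra), 0, tolerance = 1e-12)
  line <- cbind(c(-2, -1, 0, 1, 5), 0, 0)
  expect_equal(asphericity(line), 1, tolerance = 1e-12)
  expect_equal(asphericity(matrix(2, 5, 3)), 0)
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(18, sd = 3), 6, 3)
    expect_equal(asphericity(x), oracle_asphericity(x), tolerance = 1e-10)
  }
})

test_that("eigen and moment routes agree on sampled conformations", {
  ens <- sample_ensemble(wt, tiny_params(base_seed = 9L))
  dt <- descriptor_table(ens)
  for (k in seq(1, n_conformations(ens), by = 5)) {
    conf <- get_conformation(ens, k)
    expect_equal(dt$per_conformation$rg[k], radius_of_gyration(conf),
                 tolerance = 1e-8)
    expect_equal(dt$per_conformation$asphericity[k], asphericity(conf),
                 tolerance = 1e-8)
  }
  expect_true(all(dt$per_conformation$asphericity >= 0 &
                    dt$per_conformation$asphericity <= 1))
})

test_that("helicity applies the four-residue run rule", {
  n <- length(wt)
  helix_all <- build_conformation(cbind(rep(-57, n), rep(-47, n)), wt)
  ens1 <- as_test_ensemble(list(helix_all, helix_all))
  expect_equal(unname(per_residue_helicity(ens1)), rep(1, n))

  # exactly 3 consecutive helical residues -> no residue counts
  pp <- cbind(rep(180, n), rep(180, n))
  pp[8:10, ] <- matrix(rep(c(-57, -47), each = 3), 3)
  ens2 <- as_test_ensemble(list(build_conformation(pp, wt)))
  expect_equal(unname(per_residue_helicity(ens2)), rep(0, n))

  # mixed hand-built ensemble vs the window-enumeration oracle
  set.seed(4)
  confs <- lapply(1:10, function(i) {
    m <- cbind(runif(n, -180, 180), runif(n, -180, 180))
    helical <- runif(n) < 0.5
    m[helical, 1] <- runif(sum(helical), -100, -30)
    m[helical, 2] <- runif(sum(helical), -67, -7)
    build_conformation(m, wt)
  })
  ens3 <- as_test_ensemble(confs)
  expected <- rowMeans(vapply(confs, function(cf)
    oracle_mark_runs(in_helical_basin(cf$phi, cf$psi)), logical(n)))
  expect_equal(unname(per_residue_helicity(ens3)), expected)
})

test_that("mean distance map averages CA distances element-wise", {
  c1 <- random_conformation(wt, 21)
  c2 <- random_conformation(wt, 22)
  single <- mean_distance_map(as_test_ensemble(list(c1)))
  expect_equal(unname(single), unname(as.matrix(dist(ca_coords(c1)))),
               tolerance = 1e-10)
  both <- mean_distance_map(as_test_ensemble(list(c1, c2)))
  expected <- (as.matrix(dist(ca_coords(c1))) + as.matrix(dist(ca_coords(c2)))) / 2
  expect_equal(unname(both), unname(expected), tolerance = 1e-10)
  expect_equal(both, t(both))
  expect_true(all(diag(both) == 0))
  # adjacent residues sit at the fixed trans virtual bond ~3.8 A
  adj <- both[cbind(1:21, 2:22)]
  expect_true(all(abs(adj - 3.8) < 0.1))
})

test_that("scaling maps are ratios against the excluded-volume reference", {
  ens <- sample_ensemble(wt, tiny_params(base_seed = 3L))
  self <- scaling_map(mean_distance_map(ens), mean_distance_map(ens))
  off <- self[row(self) != col(self)]
  expect_true(all(off == 1))
  expect_true(all(is.na(diag(self))))
  expect_error(scaling_map(matrix(1, 3, 3), matrix(1, 4, 4)), "mismatch")

  # compaction under a strong attractive term: mean off-diagonal ratio < 1
  ev <- excluded_volume_reference(wt, tiny_params(base_seed = 12L))
  att <- sample_ensemble(wt, tiny_params(
    base_seed = 12L,
    interactions = c(sterics = TRUE, electrostatics = FALSE,
                     helix_bias = FALSE, attraction = TRUE),
    attraction_strength = 1.0))
  sm <- scaling_map(att, ev)
  sep <- abs(row(sm) - col(sm))
  expect_lt(mean(sm[sep >= 2]), 1)
  # bonded geometry identical: |i-j| = 1 ratios ~ 1
  expect_true(all(abs(sm[sep == 1] - 1) < 0.01))
})

test_that("region helicity validates its region", {
  ens <- as_test_ensemble(list(random_conformation(wt, 1)))
  expect_error(region_helicity(ens, region = 60:70), "outside")
})
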