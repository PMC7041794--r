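wt <- get_variant("WT")

test_that("local difference obeys the metric axioms and the hand check", {
  m1 <- matrix(c(0, 3.8, 7, 3.8, 0, 3.8, 7, 3.8, 0), 3)
  m2 <- matrix(c(0, 3.8, 9, 3.8, 0, 3.8, 9, 3.8, 0), 3)
  same <- local_difference(m1, m1)
  expect_equal(same$delta_local, 0)
  expect_true(all(same$map == 0))
  ab <- local_difference(m1, m2)
  ba <- local_difference(m2, m1)
  expect_equal(ab$map, ba$map)
  expect_equal(ab$delta_local, ba$delta_local)
  # only the |i-j| >= 2 pairs (1,3) and (3,1) enter the scalar
  expect_equal(ab$delta_local, 2)
  expect_error(local_difference(m1, matrix(0, 4, 4)), "mismatch")
})

test_that("Hellinger distance matches the closed-form sum and its bounds", {
  p <- c(0.2, 0.3, 0.5)
  q <- c(0.5, 0.25, 0.25)
  expected <- sqrt(1 - sum(sqrt(p * q)))
  expect_equal(hellinger(p, q), expected, tolerance = 1e-12)
  expect_equal(hellinger(p, p), 0)
  expect_equal(hellinger(c(1, 0), c(0, 1)), 1)
})

test_that("global difference is zero on self, one on disjoint supports, symmetric", {
  ens <- sample_ensemble(wt, tiny_params(base_seed = 8L))
  dt <- descriptor_table(ens)
  expect_equal(global_difference(dt, dt), 0)
  # shift the second table's Rg support far away
  dt2 <- dt
  dt2$per_conformation$rg <- dt$per_conformation$rg + 1000
  expect_equal(global_difference(dt, dt2), 1)
  ens2 <- sample_ensemble(wt, tiny_params(base_seed = 81L))
  dt3 <- descriptor_table(ens2)
  expect_equal(global_difference(dt, dt3), global_difference(dt3, dt))
  expect_gte(global_difference(dt, dt3), 0)
  expect_lte(global_difference(dt, dt3), 1)
})

test_that("heterogeneity is zero for a repeated conformation and matches brute force", {
  conf <- random_conformation(wt, 31)
  reps <- as_test_ensemble(list(conf, conf, conf))
  expect_equal(heterogeneity(reps, n_pairs = 10), 0)

  confs <- lapply(41:43, function(s) random_conformation(wt, s))
  ens <- as_test_ensemble(confs)
  D <- heterogeneity(ens, n_pairs = 100) # all 3 pairs enumerated
  n <- length(wt)
  sep <- abs(row(diag(n)) - col(diag(n)))
  idx <- which(upper.tri(diag(n)) & sep >= 2)
  maps <- lapply(confs, function(cf) as.matrix(dist(ca_coords(cf)))[idx])
  s <- c(cor(maps[[1]], maps[[2]]), cor(maps[[1]], maps[[3]]),
         cor(maps[[2]], maps[[3]]))
  expect_equal(D, mean(1 - (s + 1) / 2), tolerance = 1e-12)
})

test_that("heterogeneity is invariant under rigid motion and seed-stable", {
  ens <- sample_ensemble(wt, tiny_params(base_seed = 2L))
  D1 <- heterogeneity(ens, n_pairs = 200, seed = 7)
  expect_identical(D1, heterogeneity(ens, n_pairs = 200, seed = 7))
  R <- random_rotation(5)
  rot <- ens
  for (k in seq_len(n_conformations(ens))) rot$coords[, , k] <- ens$coords[, , k] %*% R
  expect_equal(heterogeneity(rot, n_pairs = 200, seed = 7), D1, tolerance = 1e-9)
  expect_gte(D1, 0); expect_lte(D1, 1)
  expect_error(heterogeneity(as_test_ensemble(list(random_conformation(wt, 1)))),
               "at least 2")
})

test_that("a disordered ensemble is more heterogeneous than a helix-locked one", {
  ev <- excluded_volume_reference(wt, tiny_params(base_seed = 6L))
  ov <- stats::setNames(rep(60, 22), 38:59)
  helixy <- sample_ensemble(wt, tiny_params(base_seed = 6L,
                                            helix_propensity_overrides = ov))
  expect_gt(heterogeneity(ev, n_pairs = 300, seed = 1),
            heterogeneity(helixy, n_pairs = 300, seed = 1))
})

test_that("rank_variants sorts, associates and flags degeneracy", {
  mk <- function(v, dl, dg, h) structure(
    list(variant = v, delta_local = dl, delta_global = dg,
         heterogeneity_mut = h, heterogeneity_wt = 0.3,
         local_deviation_map = matrix(0, 2, 2)),
    class = "mms6_comparison")
  res <- list(mk("A1", 0.4, 0.10, 0.30), mk("A2", 0.1, 0.30, 0.35),
              mk("A3", 0.3, 0.20, 0.32), mk("A4", 0.2, 0.05, 0.31))
  labels <- c(A1 = TRUE, A2 = FALSE, A3 = TRUE, A4 = FALSE)
  rep <- rank_variants(res, labels)
  expect_equal(rep$table$variant, c("A1", "A3", "A4", "A2")) # by delta_local desc
  expect_equal(sort(rep$table$rank_delta_local), 1:4)
  expect_false(any(rep$association$degenerate))
  # permuted labels recompute consistently
  rep2 <- rank_variants(res, c(A1 = FALSE, A2 = TRUE, A3 = FALSE, A4 = TRUE))
  expect_equal(rep2$association$rho, -rep$association$rho, tolerance = 1e-12)
  # identical metrics -> degenerate flag
  res_flat <- list(mk("B1", 1, 1, 1), mk("B2", 1, 1, 1))
  rep3 <- rank_variants(res_flat, c(B1 = TRUE, B2 = FALSE))
  expect_true(all(rep3$association$degenerate))
  expect_true(all(is.na(rep3$association$rho)))
  expect_error(rank_variants(res, labels[1:2]), "missing binding labels")
})

test_that("compare_variant bundles the metrics with the noise-floor logic", {
  a <- sample_ensemble(wt, tiny_params(base_seed = 101L))
  b <- sample_ensemble(wt, tiny_params(base_seed = 102L))
  cmp <- compare_variant(a, b, n_pairs = 100)
  expect_s3_class(cmp, "mms6_comparison")
  expect_gte(cmp$delta_local, 0)
  expect_gte(cmp$delta_global, 0); expect_lte(cmp$delta_global, 1)
  # same ensemble against itself: exact zeros (identity of indiscernibles)
  self <- compare_variant(a, a, n_pairs = 100)
  expect_equal(self$delta_local, 0)
  expect_equal(self$delta_global, 0)
  expect_equal(self$heterogeneity_mut, self$heterogeneity_wt)
})
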