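test_that("mixing arithmetic reproduces the published concentrations", {
  expect_equal(round(molar_concentration(1, 21.5, 63, 7)), 42)
  expect_equal(molar_concentration(1, 21.5, 10, 0), 1 / 21.5 * 1000)
  expect_equal(molar_concentration(2, 20, 50, 50), 50)
  expect_error(molar_concentration(0, 21.5, 63, 7), "positive")
  expect_error(molar_concentration(1, -1, 63, 7), "positive")
})

test_that("aliquot amounts convert volumes and concentrations to nmol", {
  expect_equal(round(aliquot_amount(8, 42), 2), 0.34)
  expect_equal(aliquot_amount(0, 123), 0)
  expect_equal(aliquot_amount(10, 100), 1.00)
  expect_error(aliquot_amount(-1, 5), ">= 0")
})

test_that("plate summaries compute mean and SEM by hand rules", {
  plate <- luminescence_plate(data.frame(
    sample = rep(c("a", "b"), each = 3), replicate = rep(1:3, 2),
    intensity = c(1, 2, 3, 5, 5, 5)))
  s <- summarize_plate(plate)
  expect_equal(s$mean[s$sample == "a"], 2)
  expect_equal(s$sem[s$sample == "a"], 1 / sqrt(3))
  expect_equal(s$sem[s$sample == "b"], 0)
  # permuting replicates changes nothing
  plate2 <- luminescence_plate(data.frame(
    sample = rep(c("a", "b"), each = 3), replicate = rep(1:3, 2),
    intensity = c(3, 1, 2, 5, 5, 5)))
  expect_equal(summarize_plate(plate2)$mean, s$mean)
  expect_equal(summarize_plate(plate2)$sem, s$sem)
  # single replicate: SEM undefined, flagged
  unbal <- suppressWarnings(luminescence_plate(data.frame(
    sample = c("a", "a", "b"), replicate = c(1, 2, 1),
    intensity = c(1, 2, 3))))
  expect_warning(s1 <- summarize_plate(unbal), "SEM undefined")
  expect_true(is.na(s1$sem[s1$sample == "b"]))
})

test_that("plate constructor validates and flags imbalance", {
  expect_error(luminescence_plate(data.frame(sample = "a", replicate = 1,
                                             intensity = -2)), ">= 0")
  expect_warning(luminescence_plate(data.frame(
    sample = c("a", "a", "b"), replicate = c(1, 2, 1),
    intensity = c(1, 2, 3))), "unbalanced")
})

test_that("pairwise ANOVA against the control matches brute-force sums of squares", {
  plate <- luminescence_plate(data.frame(
    sample = rep(c("WT", "mut"), each = 3), replicate = rep(1:3, 2),
    intensity = c(10, 12, 14, 3, 4, 5)))
  res <- anova_vs_control(plate, "WT")
  expect_equal(res$F[res$sample == "mut"],
               oracle_anova_f(list(c(10, 12, 14), c(3, 4, 5))),
               tolerance = 1e-12)
  # two-group ANOVA is t-test squared
  tt <- t.test(c(10, 12, 14), c(3, 4, 5), var.equal = TRUE)
  expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("ANOVA degenerate conventions hold", {
  same <- luminescence_plate(data.frame(
    sample = rep(c("WT", "m"), each = 3), replicate = rep(1:3, 2),
    intensity = rep(7, 6)))
  res <- anova_vs_control(same, "WT")
  expect_false(res$significant)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  sep <- luminescence_plate(data.frame(
    sample = rep(c("WT", "m"), each = 3), replicate = rep(1:3, 2),
    intensity = c(0, 0, 0, 10, 10, 10)))
  res2 <- anova_vs_control(sep, "WT")
  expect_true(res2$significant)
  expect_equal(res2$p, 0)
  expect_equal(res2$F, Inf)
  expect_error(anova_vs_control(same, "GFP"), "not on plate")
})

test_that("the default synthetic plate reproduces the impaired-variant partition", {
  plate <- simulate_plate()
  expect_identical(simulate_plate()$data, plate$data) # seed determinism
  res <- anova_vs_control(plate, "WT")
  flagged <- sort(res$sample[res$significant])
  expect_identical(flagged, sort(c("GFP", "E44A", "E50A", "EE50AA", "R55A")))
  # noiseless plate equals the profile means exactly
  quiet <- simulate_plate(noise_sd = 0, seed = 1)
  expect_equal(quiet$data$intensity,
               rep(unname(default_effect_profile()), each = 3))
})

test_that("transition windows hold 400 baselined samples", {
  tr <- nps_trace(0:999, rep(550, 1000), c(iron = 500), "flat")
  w <- transition_window(tr, 500)
  expect_length(w$dlambda, 400L)
  expect_equal(w$time_rel, seq(-100, 299))
  expect_true(all(w$dlambda == 0))
  expect_equal(mean(w$dlambda[w$time_rel < 0]), 0)
  # clean step of height h -> post-switch plateau = h
  h <- 2.5
  step <- nps_trace(0:999, c(rep(550, 500), rep(550 + h, 500)), c(iron = 500), "step")
  ws <- transition_window(step, "iron")
  expect_equal(mean(ws$dlambda[ws$time_rel >= 0]), h)
  expect_equal(window_plateau(ws), h)
  expect_error(transition_window(tr, 50), "exceeds trace bounds")
  expect_error(transition_window(tr, "water"), "no transition labelled")
})

test_that("re-baselining an already baselined window changes nothing", {
  tr <- simulate_nps_trace("Mms6", seed = 3)
  w <- transition_window(tr, "iron")
  again <- nps_trace(0:399, w$dlambda, c(iron = 100), "rebase")
  w2 <- transition_window(again, 100)
  expect_equal(w2$dlambda, w$dlambda, tolerance = 1e-12)
  expect_equal(w2$baseline, 0, tolerance = 1e-12)
})

test_that("post-switch drift recovers constructed slopes", {
  flat <- nps_trace(0:999, rep(551.2, 1000), c(iron = 500), "flat")
  expect_equal(post_switch_drift(transition_window(flat, 500))$slope, 0)
  ramp_y <- c(rep(550, 600), 550 - 0.01 * seq_len(400))
  ramp <- nps_trace(0:999, ramp_y, c(iron = 600), "ramp")
  dr <- post_switch_drift(transition_window(ramp, 600))
  expect_equal(dr$slope, -0.01, tolerance = 1e-6)
  expect_true(dr$decaying)
  # pure zero-mean noise stays under the drift threshold
  set.seed(12)
  noisy <- nps_trace(0:999, 550 + rnorm(1000, 0, 0.02), c(iron = 500), "noise")
  expect_false(post_switch_drift(transition_window(noisy, 500))$decaying)
})

test_that("NPS trace validation enforces the 1 Hz contract", {
  expect_error(nps_trace(c(0, 1, 3), rep(1, 3), c(iron = 1)), "1 s spacing")
  expect_error(nps_trace(0:10, rep(1, 11), c(iron = 99)), "inside the trace")
  expect_error(simulate_nps_trace("bogus"), "arg")
})

test_that("the synthetic NPS generator encodes the scenario contrasts", {
  expect_identical(simulate_nps_trace("Mms6", seed = 5)$wavelength,
                   simulate_nps_trace("Mms6", seed = 5)$wavelength)
  m6 <- simulate_nps_trace("Mms6", noise_sd = 0)
  mm <- simulate_nps_trace("Mms6MM", noise_sd = 0)
  free <- simulate_nps_trace("protein_free", noise_sd = 0)
  # protein-free sensor shows no adsorption shift
  wf <- transition_window(free, "protein")
  expect_equal(max(abs(wf$dlambda)), 0)
  # both proteins adsorb comparably
  pa <- window_plateau(transition_window(m6, "protein"))
  pb <- window_plateau(transition_window(mm, "protein"))
  expect_gt(pa, 1); expect_gt(pb, 1)
  expect_lt(abs(pa - pb) / pa, 0.2)
  # iron transition: the triple mutant decays, wild type holds
  expect_true(post_switch_drift(transition_window(mm, "iron"))$decaying)
  expect_false(post_switch_drift(transition_window(m6, "iron"))$decaying)
  # water-after-iron: large shift for Mms6 and protein-free, suppressed for MM
  w_m6 <- window_plateau(transition_window(m6, "water"))
  w_mm <- window_plateau(transition_window(mm, "water"))
  w_free <- window_plateau(transition_window(free, "water"))
  expect_gt(w_m6, 5 * window_plateau(transition_window(m6, "iron")))
  expect_gt(w_m6, 5 * w_mm)
  expect_gt(w_free, 5 * w_mm)
})
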