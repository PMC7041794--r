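# Quantification stages for the two wet-lab experiments: luminol-based
# ferric-binding plate assay (mixing arithmetic, replicate statistics,
# one-way ANOVA against a control) and nanoplasmonic sensing traces
# (400 s transition windows with 100 s pre-switch baseline subtraction).
# Both come with synthetic generators that emulate the qualitative
# structure of the published figures; no real instrument data ship with
# the package.

#' Molar concentration after mixing with a reagent
#'
#' `(mass_conc / MW) * v_sample / (v_sample + v_reagent)` expressed in uM.
#'
#' @param mass_conc protein mass concentration in mg/ml.
#' @param molecular_weight kDa.
#' @param v_sample,v_reagent volumes in ul; `v_reagent = 0` gives the
#'   undiluted concentration.
#' @return Concentration in uM (unrounded).
#' @examples
#' molar_concentration(1, 21.5, 63, 7)  # ~42 uM
#' @export
molar_concentration <- function(mass_conc, molecular_weight, v_sample, v_reagent) {
  if (mass_conc <= 0 || molecular_weight <= 0 || v_sample <= 0 || v_reagent < 0)
    stop("inputs must be positive (v_reagent may be zero)")
  mass_conc / molecular_weight * 1000 * v_sample / (v_sample + v_reagent)
}

#' Amount of protein in an aliquot
#'
#' @param volume ul.
#' @param conc uM.
#' @return nmol, unrounded; round to 2 decimals for display.
#' @examples
#' round(aliquot_amount(8, 42), 2)  # 0.34 nmol
#' @export
aliquot_amount <- function(volume, conc) {
  if (volume < 0 || conc < 0) stop("inputs must be >= 0")
  volume * conc / 1000
}

#' Luminescence plate table
#'
#' @param data data frame with columns `sample`, `replicate`, `intensity`
#'   (arbitrary luminescence units, >= 0).
#' @return An object of class `luminescence_plate`.  Unbalanced replicate
#'   counts are allowed but flagged with a warning.
#' @export
luminescence_plate <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("sample", "replicate", "intensity") %in% names(data)))
  if (any(data$intensity < 0)) stop("intensities must be >= 0")
  counts <- table(data$sample)
  if (length(unique(counts)) > 1L)
    warning("unbalanced replicate counts across samples")
  structure(list(data = data, samples = unique(data$sample)),
            class = "luminescence_plate")
}

#' @export
print.luminescence_plate <- function(x, ...) {
  cat(sprintf("<luminescence_plate> %d samples, %d wells\n",
              length(x$samples), nrow(x$data)))
  invisible(x)
}

#' Per-sample mean and standard error of a plate
#'
#' @param plate a [luminescence_plate()].
#' @return Data frame with `sample`, `n`, `mean`, `sem` (sd/sqrt(n); `NA`
#'   and flagged with a warning for single-replicate samples).
#' @export
summarize_plate <- function(plate) {
  stopifnot(inherits(plate, "luminescence_plate"))
  d <- plate$data
  out <- do.call(rbind, lapply(unique(d$sample), function(s) {
    x <- d$intensity[d$sample == s]
    data.frame(sample = s, n = length(x), mean = mean(x),
               sem = if (length(x) >= 2L) sd(x) / sqrt(length(x)) else NA_real_)
  }))
  if (anyNA(out$sem)) warning("SEM undefined for single-replicate sample(s)")
  rownames(out) <- NULL
  out
}

# one-way ANOVA F and p for a two-group (or k-group) comparison computed
# from sums of squares; conventions: F = Inf, p = 0 when within-group
# variance is zero but means differ; p = 1 (flagged) when both are zero
.anova_f <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  gm <- mean(unlist(groups))
  ssb <- sum(n * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  df1 <- k - 1L; df2 <- sum(n) - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = NaN, p = 1, degenerate = TRUE))
    return(list(F = Inf, p = 0, degenerate = FALSE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), degenerate = FALSE)
}

#' Pairwise one-way ANOVA of every sample against a control
#'
#' Each non-control sample is compared to the control with a two-group
#' one-way ANOVA F-test (equivalent to a t-test, F = t^2); a sample is
#' flagged significant when `p < alpha`.  A global k-group ANOVA across
#' all samples is attached as the `"global"` attribute.  No multiple
#' testing correction is applied unless `bonferroni = TRUE`.
#'
#' @param plate a [luminescence_plate()].
#' @param control_label sample name used as reference (required; the
#'   source experiment does not state whether GFP or wild type anchored
#'   the test).
#' @param alpha significance level (default 0.05).
#' @param bonferroni divide `alpha` by the number of comparisons.
#' @return Data frame with `sample`, `F`, `p`, `significant`, `degenerate`.
#' @export
anova_vs_control <- function(plate, control_label, alpha = 0.05,
                             bonferroni = FALSE) {
  stopifnot(inherits(plate, "luminescence_plate"))
  d <- plate$data
  if (!control_label %in% d$sample) stop("control '", control_label, "' not on plate")
  others <- setdiff(unique(d$sample), control_label)
  if (length(others) < 1L) stop("need at least 2 groups")
  thr <- if (bonferroni) alpha / length(others) else alpha
  ctrl <- d$intensity[d$sample == control_label]
  out <- do.call(rbind, lapply(others, function(s) {
    a <- .anova_f(list(ctrl, d$intensity[d$sample == s]))
    data.frame(sample = s, F = a$F, p = a$p,
               significant = is.finite(a$p) && a$p < thr,
               degenerate = a$degenerate)
  }))
  rownames(out) <- NULL
  g <- .anova_f(split(d$intensity, d$sample))
  attr(out, "global") <- data.frame(F = g$F, p = g$p)
  attr(out, "control") <- control_label
  attr(out, "alpha") <- thr
  out
}

#' Default synthetic plate effect profile
#'
#' Mean luminescence per sample (arbitrary units) encoding the published
#' qualitative ordering: the GFP negative control lowest; the
#' binding-impaired variants E44A, E50A, EE50AA, R55A intermediate; wild
#' type and the unimpaired variants highest.  The numbers themselves are
#' free synthetic parameters.
#'
#' @return Named numeric vector of per-sample means.
#' @export
default_effect_profile <- function() {
  c(GFP = 5,
    WT = 100, D42A = 100, D49A = 98, E51A = 102, E53A = 99, D56A = 101,
    E44A = 45, E50A = 42, EE50AA = 40, R55A = 48)
}

#' Simulate a synthetic luminescence plate
#'
#' Gaussian replicates around the per-sample effect profile, truncated at
#' zero, fully determined by `seed`.
#'
#' @param effect_profile named numeric vector of per-sample means.
#' @param noise_sd replicate standard deviation (default 8).
#' @param n_rep replicates per sample (default 3).
#' @param seed integer seed.
#' @return A [luminescence_plate()].
#' @export
simulate_plate <- function(effect_profile = default_effect_profile(),
                           noise_sd = 8, n_rep = 3L, seed = 42L) {
  stopifnot(!is.null(names(effect_profile)))
  vals <- withr_seed(seed, {
    stats::rnorm(length(effect_profile) * n_rep,
                 mean = rep(effect_profile, each = n_rep), sd = noise_sd)
  })
  vals <- pmax(vals, 0)
  luminescence_plate(data.frame(
    sample = rep(names(effect_profile), each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(effect_profile)),
    intensity = vals, stringsAsFactors = FALSE))
}

# run code under a local RNG seed without disturbing the caller's state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# ------------------------------------------------------------- NPS -------

#' Nanoplasmonic sensing trace
#'
#' @param time seconds, strictly increasing at uniform 1 s spacing.
#' @param wavelength plasmon-peak wavelength in nm.
#' @param transitions named numeric vector of labelled switch times
#'   (`protein` = buffer to protein, `iron` = water to iron solution,
#'   `water` = iron solution back to water); each must lie inside the
#'   trace's time range.
#' @param scenario label (`"Mms6"`, `"Mms6MM"`, `"protein_free"`, ...).
#' @return An object of class `nps_trace`.
#' @export
nps_trace <- function(time, wavelength, transitions, scenario = "unknown") {
  stopifnot(length(time) == length(wavelength))
  dt <- diff(time)
  if (any(dt <= 0) || any(abs(dt - 1) > 1e-9))
    stop("time must be strictly increasing at uniform 1 s spacing")
  if (any(transitions < min(time) | transitions > max(time)))
    stop("every transition time must lie inside the trace's time range")
  structure(list(time = time, wavelength = wavelength,
                 transitions = transitions, scenario = scenario),
            class = "nps_trace")
}

#' @export
print.nps_trace <- function(x, ...) {
  cat(sprintf("<nps_trace> %s: %d s, transitions at %s\n", x$scenario,
              length(x$time),
              paste(names(x$transitions), x$transitions, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Extract a baseline-subtracted transition window
#'
#' A 400 s window spanning 100 s before to 300 s after the switch point.
#' The mean wavelength over the 100 pre-switch samples is the baseline,
#' subtracted from the whole window to give the wavelength change
#' (delta-lambda).  Windows from different scenarios can be overlaid at
#' `t = 0` (the switch point).
#'
#' @param trace an [nps_trace()].
#' @param t_switch numeric switch time, or the name of a labelled
#'   transition in the trace.
#' @return An object of class `nps_window` with `time_rel` (-100..299 s),
#'   `dlambda` (nm), `baseline` (nm), `t_switch`, `scenario`.
#' @export
transition_window <- function(trace, t_switch) {
  stopifnot(inherits(trace, "nps_trace"))
  if (is.character(t_switch)) {
    if (!t_switch %in% names(trace$transitions))
      stop("no transition labelled '", t_switch, "'")
    t_switch <- trace$transitions[[t_switch]]
  }
  lo <- t_switch - 100; hi <- t_switch + 299
  if (lo < min(trace$time) || hi > max(trace$time))
    stop("window [", lo, ", ", hi, "] exceeds trace bounds")
  sel <- trace$time >= lo & trace$time <= hi
  w <- trace$wavelength[sel]
  if (length(w) != 400L) stop("window does not hold 400 samples")
  baseline <- mean(w[1:100])
  structure(list(time_rel = seq(-100, 299), dlambda = w - baseline,
                 baseline = baseline, t_switch = t_switch,
                 scenario = trace$scenario),
            class = "nps_window")
}

#' Post-switch drift of a transition window
#'
#' Least-squares slope of delta-lambda over the final 200 s of the window;
#' a slope more negative than `threshold` labels the window "decaying"
#' (the signature of weak, reversible iron binding).
#'
#' @param win an `nps_window`.
#' @param threshold nm/s; default -5e-4.
#' @return Named list with `slope` (nm/s) and `decaying` (logical).
#' @export
post_switch_drift <- function(win, threshold = -5e-4) {
  stopifnot(inherits(win, "nps_window"))
  sel <- win$time_rel >= 100
  fit <- lsfit(win$time_rel[sel], win$dlambda[sel])
  slope <- unname(coef(fit)[2])
  list(slope = slope, decaying = slope < threshold)
}

#' Mean plateau of a transition window
#'
#' @param win an `nps_window`.
#' @param last seconds at the end of the window to average (default 100).
#' @return Mean delta-lambda (nm) over the final `last` seconds.
#' @export
window_plateau <- function(win, last = 100) {
  mean(win$dlambda[win$time_rel > max(win$time_rel) - last])
}

#' Simulate a synthetic nanoplasmonic sensing trace
#'
#' Piecewise 1 Hz trace with three labelled transitions, emulating the
#' published qualitative contrasts: a protein-adsorption shift (absent in
#' the protein-free scenario), a small iron-binding shift for both
#' proteins (with exponential decay for the triple mutant, near-zero for
#' protein-free), and a large post-iron water shift for wild-type Mms6 and
#' the protein-free sensor that is suppressed for the triple mutant
#' (interpreted as blocked ferric-oxide precipitation).  Gaussian read
#' noise; fully determined by `seed`.
#'
#' @param scenario one of `"Mms6"`, `"Mms6MM"`, `"protein_free"`.
#' @param seed integer seed.
#' @param noise_sd read noise in nm (default 0.02; 0 disables noise).
#' @param base_wavelength resting plasmon-peak position in nm.
#' @return An [nps_trace()].
#' @export
simulate_nps_trace <- function(scenario = c("Mms6", "Mms6MM", "protein_free"),
                               seed = 42L, noise_sd = 0.02,
                               base_wavelength = 550) {
  scenario <- match.arg(scenario)
  t <- 0:1799
  tr <- c(protein = 300, iron = 900, water = 1300)
  rise <- function(t0, amp, tau) ifelse(t < t0, 0, amp * (1 - exp(-(t - t0) / tau)))
  lam <- rep(base_wavelength, length(t))
  ads <- switch(scenario, Mms6 = 2.0, Mms6MM = 1.9, protein_free = 0)
  lam <- lam + rise(tr[["protein"]], ads, 70)
  if (scenario == "Mms6") {
    lam <- lam + rise(tr[["iron"]], 0.5, 40)
  } else if (scenario == "Mms6MM") {
    # binding followed by loss: the signal decays over time
    d <- t - tr[["iron"]]
    lam <- lam + ifelse(d < 0, 0, 0.55 * (1 - exp(-d / 30)) * exp(-d / 180))
  } else {
    lam <- lam + rise(tr[["iron"]], 0.05, 40)
  }
  wat <- switch(scenario, Mms6 = 5.0, Mms6MM = 0.3, protein_free = 4.5)
  lam <- lam + rise(tr[["water"]], wat, 60)
  if (noise_sd > 0)
    lam <- lam + withr_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  nps_trace(t, lam, tr, scenario)
}

#' Qualitative feature report for the three NPS scenarios
#'
#' Runs [transition_window()] and [post_switch_drift()] on all three
#' labelled transitions of a trace.
#'
#' @param trace an [nps_trace()].
#' @return Data frame with one row per transition: `transition`,
#'   `baseline`, `plateau`, `slope`, `decaying`.
#' @export
nps_features <- function(trace) {
  do.call(rbind, lapply(names(trace$transitions), function(nm) {
    w <- transition_window(trace, nm)
    dr <- post_switch_drift(w)
    data.frame(scenario = trace$scenario, transition = nm,
               baseline = w$baseline, plateau = window_plateau(w),
               slope = dr$slope, decaying = dr$decaying,
               stringsAsFactors = FALSE)
  }))
}
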