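# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (double loops, closed forms) so they check the
# package implementations through a different route.

# Rg via the pairwise-distance identity: Rg^2 = sum_ij d_ij^2 / (2 N^2)
oracle_rg <- function(x) {
  n <- nrow(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + sum((x[i, ] - x[j, ])^2)
  sqrt(s / (2 * n^2))
}

# asphericity from explicit second moments, no eigen decomposition:
# delta = 1 - 3 * (tr^2 - tr(S^2)) / (2 tr^2)
oracle_asphericity <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  S <- matrix(0, 3, 3)
  for (k in seq_len(nrow(xc))) S <- S + tcrossprod(xc[k, ])
  S <- S / nrow(xc)
  tr <- sum(diag(S))
  if (tr == 0) return(0)
  trS2 <- sum(S * S)
  1 - 3 * (tr^2 - trS2) / (2 * tr^2)
}

# one-way ANOVA F statistic from explicit sums of squares
oracle_anova_f <- function(groups) {
  k <- length(groups)
  nn <- sapply(groups, length)
  gm <- mean(unlist(groups))
  ssb <- sum(nn * (sapply(groups, mean) - gm)^2)
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  (ssb / (k - 1)) / (ssw / (sum(nn) - k))
}

# helicity with the run rule by explicit window enumeration: residue i is
# helical iff some window of 4 consecutive helical-basin residues covers it
oracle_mark_runs <- function(h, min_run = 4L) {
  n <- length(h)
  out <- logical(n)
  for (j in seq_len(n - min_run + 1L)) {
    if (all(h[j:(j + min_run - 1L)])) out[j:(j + min_run - 1L)] <- TRUE
  }
  out
}

# assemble an mms6_ensemble from a list of mms6_conformation objects
as_test_ensemble <- function(confs, seq = confs[[1]]$sequence,
                             params = sampler_params()) {
  m <- length(confs)
  coords <- array(0, dim = c(nrow(confs[[1]]$coords), 3L, m))
  for (k in seq_len(m)) coords[, , k] <- confs[[k]]$coords
  structure(list(sequence = seq,
                 phi = do.call(rbind, lapply(confs, `[[`, "phi")),
                 psi = do.call(rbind, lapply(confs, `[[`, "psi")),
                 coords = coords,
                 energy = rep(NA_real_, m),
                 run = rep(1L, m), seeds = "test",
                 acceptance_rates = NA_real_, params = params),
            class = "mms6_ensemble")
}

# random conformation for a given sequence
random_conformation <- function(seq, seed = 1L) {
  set.seed(seed)
  n <- length(seq)
  build_conformation(cbind(runif(n, -180, 180), runif(n, -180, 180)), seq)
}

# small fast sampler settings for unit tests
tiny_params <- function(...) {
  sampler_params(n_runs = 2L, production_steps = 2000, equilibration_steps = 1000,
                 sampling_interval = 100, ...)
}

# random 3D rotation matrix
random_rotation <- function(seed = 1L) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}
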