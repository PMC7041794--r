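# Per-conformation and per-ensemble structural descriptors.

#' Radius of gyration
#'
#' Mass-uniform root-mean-square distance of all real beads (backbone +
#' side-chain beads, cap atoms excluded) from their centroid.
#'
#' @param conf an `mms6_conformation`, or a bare m x 3 bead coordinate
#'   matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  x <- if (inherits(conf, "mms6_conformation")) .real_beads(conf) else as.matrix(conf)
  if (nrow(x) < 1L) stop("need at least one bead")
  ctr <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2L, ctr)^2)))
}

#' Asphericity of the gyration tensor
#'
#' `delta = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2` with `l_k`
#' the gyration-tensor eigenvalues: 0 for spherically symmetric bead
#' clouds, 1 for collinear ones.  An all-coincident bead cloud is defined
#' to have asphericity 0.
#'
#' @param conf an `mms6_conformation` or bare m x 3 coordinate matrix.
#' @return Dimensionless value in \[0, 1\].
#' @export
asphericity <- function(conf) {
  x <- if (inherits(conf, "mms6_conformation")) .real_beads(conf) else as.matrix(conf)
  xc <- sweep(x, 2L, colMeans(x))
  S <- crossprod(xc) / nrow(xc)
  tr <- sum(diag(S))
  if (tr < .Machine$double.eps) return(0)
  l <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  1 - 3 * (l[1] * l[2] + l[2] * l[3] + l[3] * l[1]) / tr^2
}

#' End-to-end CA distance
#' @param conf an `mms6_conformation`.
#' @return Distance between the first and last CA in Angstrom.
#' @export
end_to_end <- function(conf) {
  ca <- ca_coords(conf)
  sqrt(sum((ca[nrow(ca), ] - ca[1, ])^2))
}

# residues marked helical: in the helical basin AND in a run of >= min_run
# consecutive basin residues
.mark_helical_runs <- function(h, min_run = 4L) {
  r <- rle(h)
  keep <- r$values & r$lengths >= min_run
  rep(keep, r$lengths)
}

#' Per-residue transient helicity
#'
#' A residue counts as helical in a conformation iff its (phi, psi) lies in
#' the helical basin and it belongs to a run of at least `min_run`
#' consecutive such residues (default 4, one helical turn).  `f_i` is the
#' fraction of conformations in which residue i is helical.
#'
#' @param ens an `mms6_ensemble` (or any object with `phi`/`psi` matrices).
#' @param min_run minimum helical run length.
#' @return Numeric vector of fractions in \[0, 1\], named by absolute
#'   residue position.
#' @export
per_residue_helicity <- function(ens, min_run = 4L) {
  H <- in_helical_basin(ens$phi, ens$psi)
  marked <- t(apply(H, 1L, .mark_helical_runs, min_run = min_run))
  f <- colMeans(marked)
  if (!is.null(ens$sequence))
    names(f) <- ens$sequence$start_number + seq_along(f) - 1L
  f
}

#' Mean helicity over a residue region
#'
#' Averages [per_residue_helicity()] over the given absolute positions;
#' default is the C-terminal region, residues 50-59.
#'
#' @param ens an `mms6_ensemble`.
#' @param region absolute residue positions.
#' @param min_run minimum helical run length.
#' @return Mean fractional helicity.
#' @export
region_helicity <- function(ens, region = 50:59, min_run = 4L) {
  f <- per_residue_helicity(ens, min_run = min_run)
  idx <- as.character(region)
  if (!all(idx %in% names(f))) stop("region outside the peptide")
  mean(f[idx])
}

#' Mean CA-CA distance map of an ensemble
#'
#' @param ens an `mms6_ensemble`.
#' @return Symmetric n x n matrix of mean pairwise CA distances in
#'   Angstrom, dimnames = absolute residue positions.
#' @export
mean_distance_map <- function(ens) {
  n <- length(ens$sequence)
  ca <- ens$coords[.rows_atom(n, "CA"), , , drop = FALSE]
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    xi <- matrix(ca[i, , ], 3L)
    for (j in (i + 1L):n) {
      d <- sqrt(colSums((xi - matrix(ca[j, , ], 3L))^2))
      m[i, j] <- m[j, i] <- mean(d)
    }
  }
  pos <- ens$sequence$start_number + seq_len(n) - 1L
  dimnames(m) <- list(pos, pos)
  m
}

#' Scaling map against an excluded-volume reference
#'
#' Element-wise ratio `R_ij = <d_ij>_ens / <d_ij>_EV`; ratios below 1
#' indicate compaction relative to the excluded-volume chain.  The
#' diagonal is undefined and set to `NA`.
#'
#' @param ens an `mms6_ensemble` or a precomputed mean distance map.
#' @param ev_ens the excluded-volume reference (`mms6_ensemble` or map);
#'   if an ensemble, a warning is issued unless its provenance flags read
#'   sterics-only.
#' @return Matrix of class `mms6_scaling_map`.
#' @export
scaling_map <- function(ens, ev_ens) {
  m1 <- if (inherits(ens, "mms6_ensemble")) mean_distance_map(ens) else as.matrix(ens)
  if (inherits(ev_ens, "mms6_ensemble")) {
    fl <- ev_ens$params$interactions
    if (fl[["electrostatics"]] || fl[["helix_bias"]])
      warning("reference ensemble was not generated with sterics-only interactions")
    m2 <- mean_distance_map(ev_ens)
  } else m2 <- as.matrix(ev_ens)
  if (!all(dim(m1) == dim(m2))) stop("ensemble/reference length mismatch")
  r <- m1 / m2
  diag(r) <- NA_real_
  class(r) <- c("mms6_scaling_map", class(r))
  r
}

#' Ensemble descriptor table
#'
#' Bundles the per-conformation descriptors (Rg, asphericity, end-to-end
#' distance), per-residue helicity, and the mean CA distance map for one
#' ensemble.
#'
#' @param ens an `mms6_ensemble`.
#' @param min_run minimum helical run length for the helicity rule.
#' @return An object of class `mms6_descriptors` with elements
#'   `per_conformation` (data frame), `helicity`, `mean_distance_map`,
#'   `variant`, `n_conformations`.
#' @export
descriptor_table <- function(ens, min_run = 4L) {
  stopifnot(inherits(ens, "mms6_ensemble"))
  n <- length(ens$sequence)
  m <- n_conformations(ens)
  real <- ens$coords[.rows_real(n), , , drop = FALSE]
  nb <- dim(real)[1]
  # vectorised Rg and gyration-tensor moments across conformations
  ctr <- apply(real, c(2L, 3L), mean)
  rg2 <- numeric(m); tr2 <- numeric(m)
  sxx <- matrix(0, 3L, m)
  cross <- matrix(0, 3L, m) # xy, xz, yz second moments
  for (k in 1:3) {
    xc <- real[, k, ] - matrix(ctr[k, ], nb, m, byrow = TRUE)
    sxx[k, ] <- colMeans(xc * xc)
  }
  xc1 <- real[, 1, ] - matrix(ctr[1, ], nb, m, byrow = TRUE)
  xc2 <- real[, 2, ] - matrix(ctr[2, ], nb, m, byrow = TRUE)
  xc3 <- real[, 3, ] - matrix(ctr[3, ], nb, m, byrow = TRUE)
  cross[1, ] <- colMeans(xc1 * xc2)
  cross[2, ] <- colMeans(xc1 * xc3)
  cross[3, ] <- colMeans(xc2 * xc3)
  tr <- colSums(sxx)
  rg <- sqrt(tr)
  # sum of pairwise eigenvalue products = (tr^2 - tr(S^2)) / 2
  trS2 <- colSums(sxx^2) + 2 * colSums(cross^2)
  m2 <- (tr^2 - trS2) / 2
  asph <- ifelse(tr < .Machine$double.eps, 0, 1 - 3 * m2 / tr^2)
  ca_first <- ens$coords[.rows_atom(n, "CA")[1L], , ]
  ca_last <- ens$coords[.rows_atom(n, "CA")[n], , ]
  ree <- sqrt(colSums((ca_first - ca_last)^2))
  structure(list(per_conformation = data.frame(conformation = seq_len(m),
                                               run = ens$run,
                                               rg = rg, asphericity = asph,
                                               ree = ree),
                 helicity = per_residue_helicity(ens, min_run = min_run),
                 mean_distance_map = mean_distance_map(ens),
                 variant = ens$sequence$name,
                 n_conformations = m),
            class = "mms6_descriptors")
}

#' @export
print.mms6_descriptors <- function(x, ...) {
  cat(sprintf("<mms6_descriptors> %s: %d conformations; mean Rg %.2f A, mean asphericity %.3f\n",
              x$variant, x$n_conformations,
              mean(x$per_conformation$rg), mean(x$per_conformation$asphericity)))
  invisible(x)
}
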