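# Mutant-versus-wild-type ensemble comparison metrics: local pairwise
# distance deviation, global (Rg, asphericity) distribution distance,
# conformational heterogeneity, and the cross-variant ranking report.

#' Local pairwise-distance deviation between two ensembles
#'
#' `map_ij = |<d_ij>_mut - <d_ij>_wt|`; the scalar summary is the
#' unweighted mean over residue pairs with `|i - j| >= 2` (bonded-geometry
#' pairs are constants and would dilute the signal).
#'
#' @param mut,wt `mms6_descriptors` objects (or bare mean distance maps)
#'   for peptides of equal length.
#' @param min_sep minimum sequence separation entering the scalar.
#' @return List with `map` (Angstrom matrix) and `delta_local` (Angstrom).
#' @export
local_difference <- function(mut, wt, min_sep = 2L) {
  m1 <- if (inherits(mut, "mms6_descriptors")) mut$mean_distance_map else as.matrix(mut)
  m2 <- if (inherits(wt, "mms6_descriptors")) wt$mean_distance_map else as.matrix(wt)
  if (!all(dim(m1) == dim(m2))) stop("sequence length mismatch")
  map <- abs(m1 - m2)
  n <- nrow(map)
  sep <- abs(row(map) - col(map))
  list(map = map, delta_local = mean(map[sep >= min_sep]))
}

# normalised 2D histogram on a fixed grid
.hist2d <- function(x, y, xbreaks, ybreaks) {
  ix <- findInterval(x, xbreaks, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ybreaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- matrix(0, length(xbreaks) - 1L, length(ybreaks) - 1L)
  t <- table(factor(ix, levels = seq_len(nrow(h))), factor(iy, levels = seq_len(ncol(h))))
  h[] <- as.numeric(t)
  h / sum(h)
}

#' Hellinger distance between two discrete distributions
#'
#' `H = sqrt(1 - sum(sqrt(p q)))`, bounded in \[0, 1\], 0 iff identical,
#' 1 for disjoint supports.
#'
#' @param p,q non-negative arrays of equal shape; normalised internally.
#' @return Hellinger distance.
#' @export
hellinger <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  bc <- sum(sqrt(p * q))
  sqrt(max(0, 1 - bc))
}

#' Global (Rg, asphericity) distribution distance
#'
#' Hellinger distance between the two normalised 2D histograms of
#' (radius of gyration, asphericity) on a shared bin grid spanning the
#' pooled range of both ensembles.
#'
#' @param mut,wt `mms6_descriptors` objects.
#' @param bins number of bins per axis (default 30).
#' @return `delta_global` in \[0, 1\]; symmetric in its arguments.
#' @export
global_difference <- function(mut, wt, bins = 30L) {
  a <- mut$per_conformation; b <- wt$per_conformation
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty descriptor table")
  xr <- range(c(a$rg, b$rg)); yr <- range(c(a$asphericity, b$asphericity))
  # widen degenerate ranges so single-valued distributions still bin
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.005, 0.005)
  xb <- seq(xr[1], xr[2], length.out = bins + 1L)
  yb <- seq(yr[1], yr[2], length.out = bins + 1L)
  hellinger(.hist2d(a$rg, a$asphericity, xb, yb),
            .hist2d(b$rg, b$asphericity, xb, yb))
}

# instantaneous CA distance-map upper triangle (|i-j| >= min_sep) of one
# conformation, as a flat vector
.inst_map_vec <- function(ca, idx) {
  d <- as.matrix(stats::dist(ca))
  d[idx]
}

#' Conformational heterogeneity of an ensemble
#'
#' Over `n_pairs` uniformly sampled conformation pairs (m, n), structural
#' similarity is the Pearson correlation of the upper-triangle
#' (`|i - j| >= 2`) entries of their instantaneous CA distance maps,
#' mapped to \[0, 1\] via `(s + 1) / 2`; `D` is the mean of one minus the
#' mapped similarity.  Larger values indicate a more heterogeneous
#' (more disordered) ensemble.
#'
#' @param ens an `mms6_ensemble` with at least 2 conformations.
#' @param n_pairs number of sampled pairs (default 1000); capped at the
#'   number of distinct pairs, in which case all pairs are enumerated.
#' @param seed integer seed controlling pair sampling.
#' @param min_sep minimum sequence separation of map entries.
#' @return Heterogeneity `D` in \[0, 1\].
#' @export
heterogeneity <- function(ens, n_pairs = 1000L, seed = 1L, min_sep = 2L) {
  m <- n_conformations(ens)
  if (m < 2L) stop("heterogeneity needs at least 2 conformations")
  n <- length(ens$sequence)
  ca_rows <- .rows_atom(n, "CA")
  sep <- abs(row(diag(n)) - col(diag(n)))
  idx <- which(upper.tri(diag(n)) & sep >= min_sep)
  total_pairs <- m * (m - 1) / 2
  if (n_pairs >= total_pairs) {
    pairs <- t(utils::combn(m, 2L))
  } else {
    rng <- .counter_rng(seed)
    pairs <- matrix(0L, n_pairs, 2L)
    for (k in seq_len(n_pairs)) {
      a <- 1L + as.integer(rng() * m)
      b <- 1L + as.integer(rng() * (m - 1L))
      if (b >= a) b <- b + 1L
      pairs[k, ] <- c(a, b)
    }
  }
  # precompute maps lazily for the conformations actually used
  used <- sort(unique(as.vector(pairs)))
  maps <- matrix(0, length(idx), length(used))
  colnames(maps) <- used
  for (u in seq_along(used)) {
    ca <- ens$coords[ca_rows, , used[u]]
    maps[, u] <- .inst_map_vec(ca, idx)
  }
  pos <- match(pairs, used)
  dim(pos) <- dim(pairs)
  s <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- maps[, pos[k, 1]]; b <- maps[, pos[k, 2]]
    if (sd(a) == 0 || sd(b) == 0) return(1) # identical rigid maps
    cor(a, b)
  }, numeric(1))
  mean(1 - (s + 1) / 2)
}

# small deterministic uniform generator (splitmix-style) so heterogeneity
# pair sampling does not touch R's global RNG state
.counter_rng <- function(seed) {
  state <- as.numeric(seed)
  function() {
    state <<- (state * 69069 + 1) %% 2^32
    state / 2^32
  }
}

#' Compare a mutant ensemble against wild type
#'
#' @param mut_ens,wt_ens `mms6_ensemble` objects of equal sequence length.
#' @param mut_desc,wt_desc optional precomputed [descriptor_table()]s.
#' @param bins histogram bins per axis for the global metric.
#' @param n_pairs,het_seed heterogeneity pair-sampling controls.
#' @return An object of class `mms6_comparison` with the local deviation
#'   map and scalar, the global distribution distance, and the
#'   heterogeneity of both ensembles.
#' @export
compare_variant <- function(mut_ens, wt_ens, mut_desc = NULL, wt_desc = NULL,
                            bins = 30L, n_pairs = 1000L, het_seed = 1L) {
  if (is.null(mut_desc)) mut_desc <- descriptor_table(mut_ens)
  if (is.null(wt_desc)) wt_desc <- descriptor_table(wt_ens)
  loc <- local_difference(mut_desc, wt_desc)
  structure(list(variant = mut_desc$variant,
                 local_deviation_map = loc$map,
                 delta_local = loc$delta_local,
                 delta_global = global_difference(mut_desc, wt_desc, bins = bins),
                 heterogeneity_mut = heterogeneity(mut_ens, n_pairs = n_pairs, seed = het_seed),
                 heterogeneity_wt = heterogeneity(wt_ens, n_pairs = n_pairs, seed = het_seed)),
            class = "mms6_comparison")
}

#' @export
print.mms6_comparison <- function(x, ...) {
  cat(sprintf("<mms6_comparison> %s vs WT: delta_local %.3f A, delta_global %.3f, D(mut) %.3f, D(WT) %.3f\n",
              x$variant, x$delta_local, x$delta_global,
              x$heterogeneity_mut, x$heterogeneity_wt))
  invisible(x)
}

#' Rank variants by comparison metrics and test association with binding
#'
#' Sorts variants by each comparison metric and reports a rank-association
#' statistic (Spearman correlation against the binary binding label) per
#' metric.  The report states association; it does not by itself test any
#' mechanistic conclusion.
#'
#' @param results list of `mms6_comparison` objects.
#' @param binding_labels named logical vector (`TRUE` = binding impaired)
#'   covering every variant in `results`.
#' @return An object of class `mms6_rank_report`: a list with `table`
#'   (variants with metrics, per-metric ranks and labels) and
#'   `association` (per-metric Spearman rho and p, with a `degenerate`
#'   flag when a metric is constant across variants).
#' @export
rank_variants <- function(results, binding_labels) {
  if (length(results) < 2L) stop("need at least 2 variants")
  vars <- vapply(results, `[[`, character(1), "variant")
  if (!all(vars %in% names(binding_labels)))
    stop("missing binding labels for: ",
         paste(setdiff(vars, names(binding_labels)), collapse = ", "))
  tab <- data.frame(variant = vars,
                    delta_local = vapply(results, `[[`, numeric(1), "delta_local"),
                    delta_global = vapply(results, `[[`, numeric(1), "delta_global"),
                    heterogeneity = vapply(results, `[[`, numeric(1), "heterogeneity_mut"),
                    impaired = unname(binding_labels[vars]),
                    stringsAsFactors = FALSE)
  metrics <- c("delta_local", "delta_global", "heterogeneity")
  for (m in metrics) tab[[paste0("rank_", m)]] <- rank(tab[[m]])
  assoc <- do.call(rbind, lapply(metrics, function(m) {
    x <- tab[[m]]; y <- as.numeric(tab$impaired)
    degenerate <- sd(x) == 0 || sd(y) == 0
    if (degenerate) {
      data.frame(metric = m, rho = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
      data.frame(metric = m, rho = unname(ct$estimate), p = ct$p.value,
                 degenerate = FALSE)
    }
  }))
  structure(list(table = tab[order(tab$delta_local, decreasing = TRUE), ],
                 association = assoc),
            class = "mms6_rank_report")
}

#' @export
print.mms6_rank_report <- function(x, ...) {
  cat("<mms6_rank_report>\n")
  print(x$table, row.names = FALSE)
  cat("metric / binding-label association (Spearman):\n")
  print(x$association, row.names = FALSE)
  invisible(x)
}
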