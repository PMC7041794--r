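# End-to-end pipeline configuration and orchestration.  Every stage works
# through files under the run directory so that the CLI subcommands and
# run_pipeline() compose to identical outputs; all randomness flows from
# the config's base_seed.

.CONFIG_KEYS <- c("variants", "sampler", "descriptors", "compare", "assay",
                  "nps", "base_seed")

# deterministic per-stage seed offsets derived from base_seed
.seed_variant <- function(base, i) base + 101L * i
.seed_wt_replicate <- function(base) base + 7919L
.seed_ev <- function(base) base + 15013L

#' Pipeline configuration
#'
#' @param variants construct labels to simulate (must include `"WT"`).
#' @param sampler named list of [sampler_params()] arguments (without
#'   `base_seed`, which is derived from the pipeline seed).
#' @param descriptors list with `min_run` (helical run threshold) and
#'   `region` (absolute positions of the C-terminal summary region).
#' @param compare list with `bins`, `n_pairs`, `impaired` (variant labels
#'   considered binding-impaired for the rank report).
#' @param assay list with `noise_sd`, `n_rep`, `alpha`, `control`.
#' @param nps list with `noise_sd`.
#' @param base_seed master integer seed for every stage.
#' @return An object of class `pipeline_config`.  Unknown keys anywhere in
#'   the structure are rejected.
#' @export
pipeline_config <- function(variants = mms6_variant_names(),
                            sampler = list(preset = "desk"),
                            descriptors = list(min_run = 4L, region = 50:59),
                            compare = list(bins = 30L, n_pairs = 1000L,
                                           impaired = c("E44A", "E50A", "EE50AA", "R55A", "MM")),
                            assay = list(noise_sd = 8, n_rep = 3L, alpha = 0.05,
                                         control = "WT"),
                            nps = list(noise_sd = 0.02),
                            base_seed = 1203L) {
  .check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0L)
      stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "))
  }
  if (!"WT" %in% variants) stop("variants must include 'WT'")
  bad <- setdiff(variants, mms6_variant_names())
  if (length(bad) > 0L) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  .check_keys(sampler, setdiff(names(formals(sampler_params)), "base_seed"), "sampler")
  .check_keys(descriptors, c("min_run", "region"), "descriptors")
  .check_keys(compare, c("bins", "n_pairs", "impaired"), "compare")
  .check_keys(assay, c("noise_sd", "n_rep", "alpha", "control", "effect_profile"), "assay")
  .check_keys(nps, c("noise_sd"), "nps")
  defaults <- list(descriptors = list(min_run = 4L, region = 50:59),
                   compare = list(bins = 30L, n_pairs = 1000L,
                                  impaired = c("E44A", "E50A", "EE50AA", "R55A", "MM")),
                   assay = list(noise_sd = 8, n_rep = 3L, alpha = 0.05, control = "WT"),
                   nps = list(noise_sd = 0.02))
  structure(list(variants = variants, sampler = sampler,
                 descriptors = modifyList(defaults$descriptors, descriptors),
                 compare = modifyList(defaults$compare, compare),
                 assay = modifyList(defaults$assay, assay),
                 nps = modifyList(defaults$nps, nps),
                 base_seed = as.integer(base_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file whose top-level keys match the arguments of
#'   [pipeline_config()]; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(extra) > 0L)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to JSON
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.config_sampler_params <- function(config, seed) {
  do.call(sampler_params, c(config$sampler, list(base_seed = seed)))
}

.ensure_dir <- function(...) {
  d <- file.path(...)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Simulation stage: sample and write all ensembles
#'
#' Writes, under `outdir/trajectories/`, a multi-model PDB and an XYZ
#' trajectory per requested variant, plus a wild-type replicate (`WTrep`,
#' independent seed; the Monte Carlo noise floor for the comparison
#' metrics) and the excluded-volume reference (`EV`).
#'
#' @param config a `pipeline_config`.
#' @param outdir run directory.
#' @return Character vector of written files, invisibly.
#' @export
stage_simulate <- function(config, outdir) {
  tdir <- .ensure_dir(outdir, "trajectories")
  files <- character(0)
  log <- list()
  jobs <- c(stats::setNames(as.list(seq_along(config$variants)), config$variants),
            list(WTrep = NA, EV = NA))
  for (nm in names(jobs)) {
    if (nm == "WTrep") {
      p <- .config_sampler_params(config, .seed_wt_replicate(config$base_seed))
      ens <- sample_ensemble(get_variant("WT"), p)
    } else if (nm == "EV") {
      p <- .config_sampler_params(config, .seed_ev(config$base_seed))
      ens <- excluded_volume_reference(get_variant("WT"), p)
    } else {
      p <- .config_sampler_params(config, .seed_variant(config$base_seed, jobs[[nm]]))
      ens <- sample_ensemble(get_variant(nm), p)
    }
    ens$sequence$name <- nm
    pdb <- file.path(tdir, paste0(nm, ".pdb"))
    xyz <- file.path(tdir, paste0(nm, ".xyz"))
    write_trajectory(ens, pdb)
    write_trajectory(ens, xyz)
    files <- c(files, pdb, xyz)
    log[[nm]] <- list(seed = p$base_seed,
                      acceptance_rate = mean(ens$acceptance_rates),
                      conformations = n_conformations(ens))
  }
  jsonlite::write_json(log, file.path(tdir, "sampler_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, file.path(tdir, "sampler_log.json")))
}

#' Descriptor stage: per-variant descriptor tables and scaling maps
#'
#' Reads the trajectories written by [stage_simulate()] and writes, per
#' variant, the per-conformation descriptor CSV, the helicity CSV, the
#' mean CA distance map CSV, and (for the peptide variants) the scaling
#' map against the excluded-volume reference.
#'
#' @inheritParams stage_simulate
#' @return Character vector of written files, invisibly.
#' @export
stage_descriptors <- function(config, outdir) {
  ddir <- .ensure_dir(outdir, "descriptors")
  tdir <- file.path(outdir, "trajectories")
  ev_map <- NULL
  files <- character(0)
  for (nm in c(config$variants, "WTrep", "EV")) {
    ens <- read_trajectory(file.path(tdir, paste0(nm, ".pdb")))
    dt <- descriptor_table(ens, min_run = config$descriptors$min_run)
    f1 <- file.path(ddir, paste0(nm, "_conformers.csv"))
    write.csv(dt$per_conformation, f1, row.names = FALSE)
    f2 <- file.path(ddir, paste0(nm, "_helicity.csv"))
    write.csv(data.frame(position = as.integer(names(dt$helicity)),
                         helicity = unname(dt$helicity)), f2, row.names = FALSE)
    f3 <- file.path(ddir, paste0(nm, "_distance_map.csv"))
    write.csv(dt$mean_distance_map, f3)
    files <- c(files, f1, f2, f3)
    if (nm == "EV") ev_map <- dt$mean_distance_map
  }
  for (nm in config$variants) {
    map <- as.matrix(read.csv(file.path(ddir, paste0(nm, "_distance_map.csv")),
                              row.names = 1, check.names = FALSE))
    sm <- scaling_map(map, ev_map)
    f <- file.path(ddir, paste0(nm, "_scaling_map.csv"))
    write.csv(unclass(sm), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Comparison stage: mutant-vs-wild-type metrics and rank report
#'
#' Computes, per non-wild-type variant, the local deviation map and
#' scalar, the global (Rg, asphericity) distribution distance, and
#' heterogeneity; the Monte Carlo noise floor from the independent
#' wild-type replicate; and the cross-variant rank report with binding
#' labels from the config.
#'
#' @inheritParams stage_simulate
#' @return Character vector of written files, invisibly.
#' @export
stage_compare <- function(config, outdir) {
  cdir <- .ensure_dir(outdir, "compare")
  tdir <- file.path(outdir, "trajectories")
  wt_ens <- read_trajectory(file.path(tdir, "WT.pdb"))
  wt_desc <- descriptor_table(wt_ens, min_run = config$descriptors$min_run)
  results <- list()
  files <- character(0)
  for (nm in c(setdiff(config$variants, "WT"), "WTrep")) {
    ens <- read_trajectory(file.path(tdir, paste0(nm, ".pdb")))
    cmp <- compare_variant(ens, wt_ens, wt_desc = wt_desc,
                           bins = config$compare$bins,
                           n_pairs = config$compare$n_pairs,
                           het_seed = config$base_seed)
    f1 <- file.path(cdir, paste0(nm, "_vs_WT.json"))
    jsonlite::write_json(list(variant = cmp$variant,
                              delta_local = cmp$delta_local,
                              delta_global = cmp$delta_global,
                              heterogeneity_mut = cmp$heterogeneity_mut,
                              heterogeneity_wt = cmp$heterogeneity_wt),
                         f1, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    f2 <- file.path(cdir, paste0(nm, "_deviation_map.csv"))
    write.csv(cmp$local_deviation_map, f2)
    files <- c(files, f1, f2)
    if (nm != "WTrep") results[[nm]] <- cmp
  }
  rows <- data.frame(variant = vapply(results, `[[`, character(1), "variant"),
                     delta_local = vapply(results, `[[`, numeric(1), "delta_local"),
                     delta_global = vapply(results, `[[`, numeric(1), "delta_global"),
                     heterogeneity = vapply(results, `[[`, numeric(1), "heterogeneity_mut"))
  f <- file.path(cdir, "comparisons.csv")
  write.csv(rows, f, row.names = FALSE)
  files <- c(files, f)
  if (length(results) >= 2L) {
    labels <- stats::setNames(names(results) %in% config$compare$impaired,
                              names(results))
    rep <- rank_variants(results, labels)
    f3 <- file.path(cdir, "rank_report.csv")
    write.csv(rep$table, f3, row.names = FALSE)
    f4 <- file.path(cdir, "rank_association.csv")
    write.csv(rep$association, f4, row.names = FALSE)
    files <- c(files, f3, f4)
  }
  invisible(files)
}

#' Assay stage: synthetic luminescence plate and statistics
#'
#' @inheritParams stage_simulate
#' @return Character vector of written files, invisibly.
#' @export
stage_assay <- function(config, outdir) {
  adir <- .ensure_dir(outdir, "assay")
  a <- config$assay
  profile <- if (is.null(a$effect_profile)) default_effect_profile() else unlist(a$effect_profile)
  plate <- simulate_plate(profile, noise_sd = a$noise_sd, n_rep = a$n_rep,
                          seed = config$base_seed)
  f1 <- file.path(adir, "plate.csv")
  write.csv(plate$data, f1, row.names = FALSE)
  f2 <- file.path(adir, "plate_summary.csv")
  write.csv(summarize_plate(plate), f2, row.names = FALSE)
  res <- anova_vs_control(plate, a$control, alpha = a$alpha)
  f3 <- file.path(adir, "anova.csv")
  write.csv(res, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}

#' NPS stage: synthetic sensing traces and window features
#'
#' @inheritParams stage_simulate
#' @return Character vector of written files, invisibly.
#' @export
stage_nps <- function(config, outdir) {
  ndir <- .ensure_dir(outdir, "nps")
  files <- character(0)
  feats <- list()
  for (sc in c("Mms6", "Mms6MM", "protein_free")) {
    tr <- simulate_nps_trace(sc, seed = config$base_seed,
                             noise_sd = config$nps$noise_sd)
    f1 <- file.path(ndir, paste0(sc, "_trace.csv"))
    write.csv(data.frame(time_s = tr$time, wavelength_nm = tr$wavelength),
              f1, row.names = FALSE)
    f2 <- file.path(ndir, paste0(sc, "_transitions.csv"))
    write.csv(data.frame(transition = names(tr$transitions),
                         time_s = unname(tr$transitions)), f2, row.names = FALSE)
    feats[[sc]] <- nps_features(tr)
    files <- c(files, f1, f2)
  }
  f3 <- file.path(ndir, "features.csv")
  write.csv(do.call(rbind, feats), f3, row.names = FALSE)
  invisible(c(files, f3))
}

#' Run the full analysis pipeline
#'
#' Executes the simulation, descriptor, comparison, assay and NPS stages
#' in order, then writes a manifest with the config (and its MD5 hash),
#' stage timings and the complete output file list.  A stage failure
#' aborts with the failed stage named; outputs of completed stages are
#' retained.  Re-running with the same config and seed reproduces all
#' CSV outputs byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  .ensure_dir(outdir)
  cfg_path <- file.path(outdir, "config.json")
  write_pipeline_config(config, cfg_path)
  stages <- list(simulate = stage_simulate, descriptors = stage_descriptors,
                 compare = stage_compare, assay = stage_assay, nps = stage_nps)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   base_seed = config$base_seed,
                   package_version = as.character(utils::packageVersion("mms6ens")),
                   stages = list())
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(stages[[nm]](config, outdir),
                      error = function(e) stop("pipeline stage '", nm, "' failed: ",
                                               conditionMessage(e), call. = FALSE))
    manifest$stages[[nm]] <- list(files = as.character(files),
                                  seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
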