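# Multi-model PDB and XYZ trajectory readers/writers.  The PDB writer
# emits chain A with the peptide's absolute residue numbering (38-59 for
# the study constructs); the two virtual cap atoms are written as ACE/NME
# residues immediately before and after the peptide so that backbone
# dihedrals survive a round trip.  Coordinates survive at PDB format
# precision (1e-3 Angstrom); XYZ keeps full precision.

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")
.AA3_TO_1 <- stats::setNames(names(.AA3), unname(.AA3))

.traj_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("pdb", "xyz")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("pdb", "xyz")) stop("cannot infer trajectory format from '", path, "'")
  ext
}

#' Write an ensemble trajectory
#'
#' @param ens an `mms6_ensemble`.
#' @param path output path; format inferred from the `.pdb`/`.xyz`
#'   extension unless `format` is given.
#' @param format `"pdb"` (multi-model, MODEL/ENDMDL) or `"xyz"`
#'   (concatenated frames).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(ens, path, format = NULL) {
  stopifnot(inherits(ens, "mms6_ensemble"))
  format <- .traj_format(path, format)
  n <- length(ens$sequence)
  m <- n_conformations(ens)
  aa <- strsplit(ens$sequence$residues, "")[[1]]
  start <- ens$sequence$start_number
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    resn <- c("ACE", rep(.AA3[aa], each = 4L), "NME")
    resi <- c(start - 1L, rep(start + seq_len(n) - 1L, each = 4L), start + n)
    anam <- c("C", rep(c("N", "CA", "C", "CB"), n), "N")
    for (k in seq_len(m)) {
      x <- ens$coords[, , k]
      lines <- sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(nrow(x)), sprintf(" %-3s", anam), resn, resi,
                       x[, 1], x[, 2], x[, 3])
      writeLines(c(sprintf("MODEL %8d", k), lines, "ENDMDL"), con)
    }
    writeLines("END", con)
  } else {
    lab <- c("C0", rep(c("N", "CA", "C", "SB"), n), "NX")
    for (k in seq_len(m)) {
      x <- ens$coords[, , k]
      writeLines(c(sprintf("%d", nrow(x)),
                   sprintf("variant=%s start=%d seq=%s model=%d",
                           ens$sequence$name, start, ens$sequence$residues, k),
                   sprintf("%-3s %15.8f %15.8f %15.8f", lab, x[, 1], x[, 2], x[, 3])),
                 con)
    }
  }
  invisible(path)
}

.read_pdb_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trajectory file: ", path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) stop("no MODEL records in ", path)
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  frames <- vector("list", length(model_starts))
  resn <- NULL; resi <- NULL
  for (k in seq_along(model_starts)) {
    rows <- which(is_atom & seq_along(lines) > model_starts[k] &
                    seq_along(lines) < model_ends[k])
    at <- lines[rows]
    xyz <- matrix(NA_real_, length(at), 3L)
    for (i in seq_along(at)) {
      x <- suppressWarnings(as.numeric(c(substr(at[i], 31, 38),
                                         substr(at[i], 39, 46),
                                         substr(at[i], 47, 54))))
      if (anyNA(x)) stop("malformed ATOM record at line ", rows[i], " of ", path)
      xyz[i, ] <- x
    }
    if (k == 1L) {
      resn <- trimws(substr(at, 18, 20))
      resi <- as.integer(substr(at, 23, 26))
    } else if (length(at) != nrow(frames[[1]])) {
      stop("inconsistent atom count in model ", k, " of ", path)
    }
    frames[[k]] <- xyz
  }
  nr <- nrow(frames[[1]])
  if ((nr - 2L) %% 4L != 0L) stop("unexpected atom count (", nr, ") in ", path)
  n <- (nr - 2L) %/% 4L
  ca_rows <- .rows_atom(n, "CA")
  aa <- .AA3_TO_1[resn[ca_rows]]
  if (anyNA(aa)) stop("unknown residue name(s) in ", path)
  seq <- peptide_sequence(paste(aa, collapse = ""), resi[ca_rows[1]],
                          sub("\\.(pdb|xyz)$", "", basename(path)))
  list(frames = frames, sequence = seq)
}

.read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trajectory file: ", path)
  frames <- list(); i <- 1L; hdr <- NULL
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(lines[i]))
    if (is.na(nat)) stop("malformed XYZ atom count at line ", i, " of ", path)
    if (i + 1L + nat > length(lines)) stop("truncated XYZ frame at line ", i, " of ", path)
    if (is.null(hdr)) hdr <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v)) stop("malformed XYZ coordinate line in ", path)
      v
    }, numeric(3)))
    if (length(frames) > 0L && nrow(xyz) != nrow(frames[[1]]))
      stop("inconsistent atom count across XYZ frames in ", path)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  kv <- strsplit(strsplit(hdr, "\\s+")[[1]], "=")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  seq <- peptide_sequence(vals[keys == "seq"], as.integer(vals[keys == "start"]),
                          vals[keys == "variant"])
  list(frames = frames, sequence = seq)
}

#' Read an ensemble trajectory
#'
#' Accepts multi-model PDB or XYZ files written by [write_trajectory()].
#' Backbone dihedrals are re-derived from the coordinates (the cap atoms
#' stored with each model make phi of the first and psi of the last
#' residue recoverable).
#'
#' @param path trajectory file.
#' @param format `"pdb"` or `"xyz"`; inferred from the extension if `NULL`.
#' @return An `mms6_ensemble` (provenance fields `params`, `seeds` are
#'   `NULL` for ensembles read from disk).
#' @export
read_trajectory <- function(path, format = NULL) {
  format <- .traj_format(path, format)
  parsed <- if (format == "pdb") .read_pdb_trajectory(path) else .read_xyz_trajectory(path)
  m <- length(parsed$frames)
  nr <- nrow(parsed$frames[[1]])
  coords <- array(0, dim = c(nr, 3L, m))
  for (k in seq_len(m)) coords[, , k] <- parsed$frames[[k]]
  n <- (nr - 2L) %/% 4L
  phi <- matrix(0, m, n); psi <- matrix(0, m, n)
  for (k in seq_len(m)) {
    dh <- cpp_dihedrals(coords[, , k])
    phi[k, ] <- dh[, 1]; psi[k, ] <- dh[, 2]
  }
  structure(list(sequence = parsed$sequence, phi = phi, psi = psi,
                 coords = coords, energy = rep(NA_real_, m),
                 run = rep(NA_integer_, m), seeds = NULL,
                 acceptance_rates = NULL,
                 params = NULL, source = path),
            class = "mms6_ensemble")
}
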