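# Coarse-grained conformation plumbing: each residue carries backbone
# N/CA/C atoms plus one side-chain bead (SB) at fixed geometry off CA; two
# virtual cap atoms make phi of the first and psi of the last residue
# well-defined.  All coordinates in Angstrom, dihedrals in degrees.

# row indices (1-based) into the (4n+2) x 3 coordinate matrix
.row_cap_c <- function(n) 1L
.row_cap_n <- function(n) 4L * n + 2L
.rows_real <- function(n) 2L:(4L * n + 1L)
.rows_atom <- function(n, atom) {
  off <- match(atom, c("N", "CA", "C", "SB"))
  if (is.na(off)) stop("unknown atom type '", atom, "'")
  1L + off + 4L * (0:(n - 1L))
}

# fixed ideal bond lengths (Angstrom), mirrored from the compiled core
.BOND_N_CA <- 1.458
.BOND_CA_C <- 1.525
.BOND_C_N  <- 1.329

# Ramachandran basin bounds (degrees); recorded constants of the model
.HELIX_BASIN    <- c(phi_lo = -100, phi_hi = -30, psi_lo = -67, psi_hi = -7)
.EXTENDED_BASIN <- c(phi_lo = -180, phi_hi = -50, psi_lo = 90, psi_hi = 180)

#' Helical-basin membership
#'
#' A residue is in the helical basin when phi is in \[-100, -30\] and psi in
#' \[-67, -7\] degrees.
#'
#' @param phi,psi dihedrals in degrees (vectors or matrices of equal shape).
#' @return Logical of the same shape.
#' @export
in_helical_basin <- function(phi, psi) {
  phi >= .HELIX_BASIN["phi_lo"] & phi <= .HELIX_BASIN["phi_hi"] &
    psi >= .HELIX_BASIN["psi_lo"] & psi <= .HELIX_BASIN["psi_hi"]
}

#' Build a conformation from backbone dihedrals
#'
#' Places the backbone with fixed ideal bond lengths and angles and trans
#' peptide bonds (omega = 180 degrees), plus one side-chain bead per
#' residue at fixed geometry off CA.  Re-extracting dihedrals with
#' [conformation_dihedrals()] recovers the inputs to better than 1e-4
#' degrees.
#'
#' @param phi_psi numeric matrix with one (phi, psi) row per residue, in
#'   degrees.
#' @param seq a [peptide_sequence()] of matching length.
#' @return An object of class `mms6_conformation` with elements `coords`
#'   ((4n+2) x 3 matrix including the two cap atoms), `phi`, `psi`,
#'   `sequence`.
#' @examples
#' wt <- get_variant("WT")
#' helix <- build_conformation(cbind(rep(-57, length(wt)), rep(-47, length(wt))), wt)
#' @export
build_conformation <- function(phi_psi, seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  phi_psi <- as.matrix(phi_psi)
  n <- length(seq)
  if (nrow(phi_psi) != n || ncol(phi_psi) != 2L)
    stop("phi_psi must be an n x 2 matrix matching the sequence length (",
         n, " residues)")
  coords <- cpp_build_chain(phi_psi[, 1], phi_psi[, 2])
  structure(list(coords = coords, phi = phi_psi[, 1], psi = phi_psi[, 2],
                 sequence = seq),
            class = "mms6_conformation")
}

#' Extract backbone dihedrals from a conformation
#'
#' @param conf an `mms6_conformation`, or a bare (4n+2) x 3 coordinate
#'   matrix in the package's chain layout.
#' @return n x 2 matrix of (phi, psi) in degrees.
#' @export
conformation_dihedrals <- function(conf) {
  coords <- if (inherits(conf, "mms6_conformation")) conf$coords else as.matrix(conf)
  out <- cpp_dihedrals(coords)
  colnames(out) <- c("phi", "psi")
  out
}

#' CA coordinates of a conformation
#'
#' @param conf an `mms6_conformation` or raw coordinate matrix.
#' @return n x 3 matrix of CA positions.
#' @export
ca_coords <- function(conf) {
  coords <- if (inherits(conf, "mms6_conformation")) conf$coords else as.matrix(conf)
  n <- (nrow(coords) - 2L) %/% 4L
  coords[.rows_atom(n, "CA"), , drop = FALSE]
}

# all real beads (backbone + side beads, caps excluded)
.real_beads <- function(conf) {
  coords <- if (inherits(conf, "mms6_conformation")) conf$coords else as.matrix(conf)
  n <- (nrow(coords) - 2L) %/% 4L
  coords[.rows_real(n), , drop = FALSE]
}

#' @export
print.mms6_conformation <- function(x, ...) {
  cat(sprintf("<mms6_conformation> %s, %d residues, %d beads (+2 caps)\n",
              x$sequence$name, length(x$sequence), 4L * length(x$sequence)))
  invisible(x)
}
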