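# Registry of the Mms6 C-terminal ferric-binding region (residues 38-59)
# and its alanine substitution variants, with residue-level annotations.

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.WT_RESIDUES <- "MKSRDIESAQSDEEVELRDALA"
.WT_START <- 38L

# side-chain formal charge at pH 7.4; termini capped/neutral, His neutral
.CHARGE <- c(D = -1, E = -1, K = 1, R = 1)

# relative helix propensity weights by residue type (dimensionless, >= 0);
# loosely ordered like experimental helix propensity scales (Ala most
# helical, Gly/Pro helix breakers).  Multiplied by .HELIX_SCALE, these are
# the shipped default basin weights of the sampler, calibrated once so the
# wild-type C-terminal region shows 10-15% transient helicity (see the
# methods vignette).
.HELIX_PROP <- c(A = 1.25, C = 0.90, D = 0.85, E = 1.05, F = 1.00, G = 0.55,
                 H = 0.95, I = 1.00, K = 1.05, L = 1.15, M = 1.10, N = 0.85,
                 P = 0.20, Q = 1.05, R = 1.10, S = 0.90, T = 0.85, V = 0.90,
                 W = 1.00, Y = 0.95)
.HELIX_SCALE <- 1.55

# side-chain bead steric radius (Angstrom), coarse volume ordering
.SB_RADIUS <- c(A = 1.5, C = 1.8, D = 1.9, E = 2.1, F = 2.4, G = 1.2,
                H = 2.3, I = 2.2, K = 2.3, L = 2.2, M = 2.3, N = 2.0,
                P = 1.9, Q = 2.2, R = 2.4, S = 1.7, T = 1.9, V = 2.0,
                W = 2.6, Y = 2.5)
.CA_RADIUS <- 1.9

# variant name -> alanine substitution positions (absolute numbering)
.VARIANT_SUBS <- list(
  WT     = integer(0),
  D42A   = 42L,
  E44A   = 44L,
  D49A   = 49L,
  E50A   = 50L,
  E51A   = 51L,
  EE50AA = c(50L, 51L), # the two adjacent glutamic acids E50 + E51
  E53A   = 53L,
  R55A   = 55L,
  D56A   = 56L,
  MM     = c(44L, 50L, 55L) # triple mutant EER44,50,55AAA
)

#' Peptide sequence with absolute residue numbering
#'
#' @param residues one-letter amino-acid string (canonical 20 codes only).
#' @param start_number absolute position of the first residue (38 for the
#'   Mms6 C-terminal study peptide).
#' @param name construct label.
#' @return An object of class `peptide_sequence`.
#' @examples
#' peptide_sequence("MKSRDIESAQSDEEVELRDALA", 38, "WT")
#' @export
peptide_sequence <- function(residues, start_number = 38L, name = "peptide") {
  stopifnot(is.character(residues), length(residues) == 1L)
  aa <- strsplit(residues, "")[[1]]
  if (length(aa) < 2L) stop("sequence must have at least 2 residues")
  bad <- setdiff(aa, .AA1)
  if (length(bad) > 0)
    stop("non-canonical residue code(s): ", paste(unique(bad), collapse = ", "))
  structure(list(residues = residues,
                 start_number = as.integer(start_number),
                 name = as.character(name)),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<peptide_sequence> %s: %s (residues %d-%d)\n",
              x$name, x$residues, x$start_number, x$start_number + n - 1L))
  invisible(x)
}

#' @export
length.peptide_sequence <- function(x) nchar(x$residues)

#' @export
as.character.peptide_sequence <- function(x, ...) x$residues

#' Names of the registered Mms6 variants
#' @return Character vector of construct labels.
#' @export
mms6_variant_names <- function() names(.VARIANT_SUBS)

#' Substitution specification for a registered variant
#'
#' @param name construct label (see [mms6_variant_names()]).
#' @return Data frame with columns `position` (absolute), `from`, `to`;
#'   zero rows for `"WT"`.
#' @export
variant_spec <- function(name) {
  if (!name %in% names(.VARIANT_SUBS))
    stop("unknown variant '", name, "'; valid names: ",
         paste(names(.VARIANT_SUBS), collapse = ", "))
  pos <- .VARIANT_SUBS[[name]]
  wt <- strsplit(.WT_RESIDUES, "")[[1]]
  data.frame(position = pos,
             from = if (length(pos)) wt[pos - .WT_START + 1L] else character(0),
             to = rep("A", length(pos)),
             stringsAsFactors = FALSE)
}

#' Retrieve a registered Mms6 C-terminal variant
#'
#' Applies the variant's alanine substitutions to the wild-type 22-residue
#' peptide MKSRDIESAQSDEEVELRDALA (residues 38-59).
#'
#' @param name construct label; one of [mms6_variant_names()].
#' @return A [peptide_sequence()].
#' @examples
#' get_variant("MM")
#' @export
get_variant <- function(name) {
  spec <- variant_spec(name)
  aa <- strsplit(.WT_RESIDUES, "")[[1]]
  if (nrow(spec)) {
    idx <- spec$position - .WT_START + 1L
    if (any(idx < 1L | idx > length(aa)))
      stop("substitution position outside the peptide")
    if (!all(aa[idx] == spec$from))
      stop("substitution does not match the wild-type residue")
    aa[idx] <- spec$to
  }
  peptide_sequence(paste(aa, collapse = ""), .WT_START, name)
}

#' Net side-chain formal charge at pH 7.4
#'
#' Sums per-residue side-chain formal charges (D, E = -1; K, R = +1; all
#' others, including His, 0).  The fragment termini are treated as capped
#' and contribute no charge.
#'
#' @param seq a [peptide_sequence()].
#' @return Integer net charge.
#' @examples
#' net_charge(get_variant("WT"))  # -4
#' @export
net_charge <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  aa <- strsplit(seq$residues, "")[[1]]
  ch <- .CHARGE[aa]
  ch[is.na(ch)] <- 0
  as.integer(sum(ch))
}

#' Per-residue annotations for a peptide
#'
#' @param seq a [peptide_sequence()].
#' @return Data frame with absolute `position`, `residue`, side-chain
#'   `charge` at pH 7.4, default `helix_propensity` weight, and side-chain
#'   bead `steric_radius` in Angstrom.
#' @export
residue_annotations <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  aa <- strsplit(seq$residues, "")[[1]]
  ch <- .CHARGE[aa]; ch[is.na(ch)] <- 0
  data.frame(position = seq$start_number + seq_along(aa) - 1L,
             residue = aa,
             charge = as.integer(ch),
             helix_propensity = unname(.HELIX_PROP[aa] * .HELIX_SCALE),
             steric_radius = unname(.SB_RADIUS[aa]),
             stringsAsFactors = FALSE)
}

#' Write registered variants to a FASTA file
#'
#' One record per construct; record ID is the variant name.
#'
#' @param path output file path.
#' @param names variant labels to write (default: all registered).
#' @return `path`, invisibly.
#' @export
write_variants_fasta <- function(path, names = mms6_variant_names()) {
  seqs <- vapply(names, function(nm) get_variant(nm)$residues, character(1))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read peptide variants from a FASTA file
#'
#' @param path FASTA file as written by [write_variants_fasta()].
#' @param start_number absolute numbering offset applied to every record.
#' @return Named list of [peptide_sequence()] objects.
#' @export
read_variants_fasta <- function(path, start_number = 38L) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    peptide_sequence(as.character(set[[i]]), start_number, names(set)[i]))
  names(out) <- names(set)
  out
}
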