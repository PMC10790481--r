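# Biomass precursor coefficients from genome composition.
#
# Monomer fractions are estimated from the annotated genome: amino acids
# from translated coding sequences, dNTPs from the double-stranded genome
# (sequence plus reverse complement, forcing f(A)=f(T) and f(C)=f(G)), NTPs
# from the coding-strand nucleotide frequencies of the annotated genes (a
# transcription proxy; transcript-abundance weighting is out of scope).
# Each macromolecule's monomer coefficient in the biomass equation is
#   coef_i = mass_fraction * f_i / sum_j f_j * MW_j(residue) * 1000
# in mmol monomer per gDCW, with polymerised residue masses (monomer minus
# water) so that the coefficients of a macromolecule multiply back to its
# mass fraction.

# average residue masses, g/mol (monomer minus one water)
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

DNA_RESIDUE_MASS <- c(dA = 313.21, dC = 289.18, dG = 329.21, dT = 304.20)
RNA_RESIDUE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)

.monomer_coefficients <- function(fractions, residue_mass, mass_fraction) {
  f <- fractions[names(residue_mass)]
  f[is.na(f)] <- 0
  names(f) <- names(residue_mass)
  if (abs(sum(f) - 1) > 1e-9) {
    warning("normalization warning: fractions sum to ", sum(f),
            "; renormalizing")
    f <- f / sum(f)
  }
  mass_fraction * f / sum(f * residue_mass) * 1000
}

.letter_freq <- function(seqs, alphabet) {
  tab <- colSums(Biostrings::letterFrequency(seqs, letters = alphabet))
  bad_total <- sum(Biostrings::width(seqs)) - sum(tab)
  if (bad_total > 0)
    stop("parse error: ", bad_total, " characters outside alphabet {",
         paste(alphabet, collapse = ""), "}")
  tab / sum(tab)
}

#' Monomer composition and biomass coefficients from genome sequence
#'
#' @param cds_path FASTA of coding sequences (DNA, coding strand), or a
#'   \code{Biostrings::DNAStringSet}.
#' @param genome_path FASTA of the genome sequence (one or more replicons),
#'   or a \code{DNAStringSet}.
#' @param mass_fractions named numeric: grams per gDCW for \code{protein},
#'   \code{dna}, \code{rna} (their sum must be <= 1; other macromolecules
#'   are outside this calculation).
#' @return list with fraction vectors \code{amino_acids} (20), \code{dntp}
#'   (4), \code{ntp} (4), and \code{coefficients}: named vector of biomass
#'   precursor coefficients in mmol/gDCW (negative = consumed), names
#'   prefixed \code{aa_}, \code{dntp_}, \code{ntp_}.
#' @export
biomass_from_genome <- function(cds_path, genome_path, mass_fractions) {
  req <- c("protein", "dna", "rna")
  if (!all(req %in% names(mass_fractions)))
    stop("validation error: mass_fractions needs protein, dna, rna")
  if (sum(mass_fractions[req]) > 1 + 1e-9)
    stop("validation error: mass fractions sum above 1")
  cds <- if (inherits(cds_path, "DNAStringSet")) cds_path
         else Biostrings::readDNAStringSet(cds_path)
  genome <- if (inherits(genome_path, "DNAStringSet")) genome_path
            else Biostrings::readDNAStringSet(genome_path)

  prot <- Biostrings::translate(cds, if.fuzzy.codon = "error")
  aa_counts <- colSums(Biostrings::letterFrequency(
    prot, letters = names(AA_RESIDUE_MASS)))
  stops <- sum(Biostrings::letterFrequency(prot, letters = "*"))
  covered <- sum(aa_counts) + stops
  if (covered < sum(Biostrings::width(prot)))
    stop("parse error: non-standard amino acids in translated CDS")
  aa_frac <- aa_counts / sum(aa_counts)

  ds <- c(genome, Biostrings::reverseComplement(genome))
  dntp_frac <- .letter_freq(ds, c("A", "C", "G", "T"))
  names(dntp_frac) <- c("dA", "dC", "dG", "dT")

  ntp_frac <- .letter_freq(cds, c("A", "C", "G", "T"))
  names(ntp_frac) <- c("A", "C", "G", "U")   # coding strand, T read as U

  coef <- c(
    stats::setNames(
      -.monomer_coefficients(aa_frac, AA_RESIDUE_MASS,
                             mass_fractions[["protein"]]),
      paste0("aa_", names(AA_RESIDUE_MASS))),
    stats::setNames(
      -.monomer_coefficients(dntp_frac, DNA_RESIDUE_MASS,
                             mass_fractions[["dna"]]),
      paste0("dntp_", names(DNA_RESIDUE_MASS))),
    stats::setNames(
      -.monomer_coefficients(ntp_frac, RNA_RESIDUE_MASS,
                             mass_fractions[["rna"]]),
      paste0("ntp_", names(RNA_RESIDUE_MASS))))
  list(amino_acids = aa_frac, dntp = dntp_frac, ntp = ntp_frac,
       coefficients = coef)
}
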