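# Protein molecular weight from amino-acid sequence.
#
# Average (not monoisotopic) residue masses in daltons for the 20 standard
# amino acids, i.e. the free amino-acid mass minus one water. The chain mass
# is the residue sum plus one water for the terminal H/OH.
AVERAGE_RESIDUE_MASS_DA <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

WATER_MASS_DA <- 18.0153

#' Molecular weight of a protein from its amino-acid sequence
#'
#' Computes the average molecular mass of a polypeptide as the sum of average
#' residue masses over the 20 standard amino acids plus one water, reported in
#' kilodaltons. Used to support the small-protein (<= 25 kDa) triage criterion
#' when annotation tables carry sequences rather than masses.
#'
#' @param sequence Character vector of amino-acid sequences (one-letter code,
#'   upper or lower case). Only the 20 standard residues are accepted;
#'   ambiguity codes such as `X`, and gap characters, raise an error.
#'
#' @return Numeric vector of masses in kilodaltons. The empty sequence returns
#'   the mass of water alone.
#'
#' @examples
#' mw_from_sequence("G")
#' mw_from_sequence(c("GG", "ACDEFGHIKLMNPQRSTVWY"))
#' @export
mw_from_sequence <- function(sequence) {
  if (!is.character(sequence)) abort("`sequence` must be a character vector.")
  vapply(sequence, mw_one, numeric(1), USE.NAMES = FALSE)
}

mw_one <- function(seq) {
  if (is.na(seq)) return(NA_real_)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0) return(WATER_MASS_DA / 1000)
  idx <- match(chars, names(AVERAGE_RESIDUE_MASS_DA))
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    abort(sprintf(
      "Non-standard residue '%s' at position %d; only the 20 standard amino acids are accepted.",
      chars[pos], pos
    ))
  }
  (sum(AVERAGE_RESIDUE_MASS_DA[idx]) + WATER_MASS_DA) / 1000
}
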