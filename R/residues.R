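# Residue alphabet, side-chain classes and masses shared by all modules.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical order; this ordering is used for all matrix columns.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Subsite labels of the P5-P4' frame
#'
#' The nine-subsite coordinate system around the scissile bond
#' (Schechter-Berger nomenclature). Cleavage occurs between `P1` and `P1p`
#' (P1'), i.e. after the frame position with index [p1_index()].
#'
#' @return Character vector of the nine subsite labels, N- to C-terminal.
#' @export
#' @examples
#' subsite_labels()
subsite_labels <- function() {
  c("P5", "P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p")
}

#' @rdname subsite_labels
#' @return For `p1_index()`, the 1-based index of P1 within the frame (5).
#' @export
p1_index <- function() 5L

#' Side-chain class scheme for consensus alignment
#'
#' Partition of the 20 standard residues into six side-chain property
#' classes: aromatic (F, Y, W); negatively charged (D, E); positively
#' charged (K, R); small aliphatic (G, A); larger aliphatic (V, L, I, P);
#' hydrophilic (S, T, H, N, Q, C, M). Every residue belongs to exactly one
#' class.
#'
#' @return Named character vector mapping residue -> class name.
#' @export
#' @examples
#' residue_classes()[["V"]]
residue_classes <- function() {
  c(
    F = "aromatic", Y = "aromatic", W = "aromatic",
    D = "negative", E = "negative",
    K = "positive", R = "positive",
    G = "small_aliphatic", A = "small_aliphatic",
    V = "larger_aliphatic", L = "larger_aliphatic",
    I = "larger_aliphatic", P = "larger_aliphatic",
    S = "hydrophilic", T = "hydrophilic", H = "hydrophilic",
    N = "hydrophilic", Q = "hydrophilic", C = "hydrophilic",
    M = "hydrophilic"
  )[aa_alphabet()]
}

#' @rdname residue_classes
#' @return For `class_names()`, the six class names in a fixed order.
#' @export
class_names <- function() {
  c("aromatic", "negative", "positive",
    "small_aliphatic", "larger_aliphatic", "hydrophilic")
}

#' Classify a residue by side-chain property
#'
#' @param aa One-letter residue code(s); must be standard residues.
#' @param scheme Named vector mapping residues to classes, as returned by
#'   [residue_classes()].
#' @return Character vector of class names, same length as `aa`.
#' @export
#' @examples
#' classify_residue(c("F", "P", "M"))
classify_residue <- function(aa, scheme = residue_classes()) {
  aa <- as.character(aa)
  bad <- !(aa %in% names(scheme))
  if (any(bad)) {
    abort(sprintf(
      "Non-standard residue(s): %s. Only the 20 standard one-letter codes are accepted.",
      paste(unique(aa[bad]), collapse = ", ")
    ), class = "phagespec_alphabet_error")
  }
  unname(scheme[aa])
}

# Average (isotope-averaged) residue masses in Da, i.e. the amino-acid mass
# minus one water; a free chain adds 18.0153 Da.
residue_masses <- function() {
  c(
    A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
    G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
    M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
    S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
  )
}

WATER_DA <- 18.0153

#' Average molecular mass of a peptide chain
#'
#' Sum of average residue masses plus one water per chain.
#'
#' @param sequence Peptide sequence(s) as character strings (standard
#'   residues only).
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' peptide_mass("GG")  # 132.12 Da
peptide_mass <- function(sequence) {
  masses <- residue_masses()
  vapply(sequence, function(s) {
    aa <- split_residues(s)
    bad <- !(aa %in% names(masses))
    if (any(bad)) {
      abort(sprintf("Non-standard residue(s) in sequence: %s",
                    paste(unique(aa[bad]), collapse = ", ")),
            class = "phagespec_alphabet_error")
    }
    sum(masses[aa]) + WATER_DA
  }, numeric(1), USE.NAMES = FALSE)
}

# -- internal helpers ---------------------------------------------------------

split_residues <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

is_standard_seq <- function(s) {
  all(split_residues(s) %in% aa_alphabet())
}

assert_standard_seq <- function(s, what = "sequence") {
  if (!is_standard_seq(s)) {
    abort(sprintf("%s contains non-standard residues: %s", what, s),
          class = "phagespec_alphabet_error")
  }
  invisible(s)
}

# Encode sequences of equal length as an integer matrix (rows = sequences,
# columns = positions, values = index into aa_alphabet(); NA for
# non-standard letters).
encode_residues <- function(sequences, width) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  lens <- lengths(chars)
  if (any(lens != width)) {
    abort(sprintf("All sequences must have length %d.", width))
  }
  matrix(match(unlist(chars), aa_alphabet()),
         nrow = length(sequences), ncol = width, byrow = TRUE)
}
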