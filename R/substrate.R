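# Tandem-thioredoxin reporter substrates: construct assembly, fragment
# masses, and cleavage-site prediction including the SalI-site Val
# fallback.

# E. coli thioredoxin 1 (TrxA), mature chain, 108 residues.
TRXA_SEQ <- paste0(
  "SDKIIHLTDDSFDTDVLKADGAILVDFWAEWCGPCKMIAPILDEIADEYQGKLTVAKLNIDQNPGTAP",
  "KYGIRGIPTLLLFKNGEVAATKVGALSKGQLKEFLDANLA"
)

#' Assemble a tandem-thioredoxin reporter construct
#'
#' The reporter is `Met + Trx + GS + insert + VD + Trx + His6`: two
#' thioredoxin domains joined by a linker whose cleavable core is ligated
#' between a BamHI site (encoding Gly-Ser) and a SalI site (encoding
#' Val-Asp), with a C-terminal His6 purification tag. Exact
#' vector-derived residues beyond GS/VD/His6 are not modeled; absolute
#' masses therefore carry a ~1 kDa model tolerance.
#'
#' @param insert Cleavable core sequence, 6-9 standard residues.
#' @return Object of class `trx_construct` with the full sequence and
#'   0-free (1-based) coordinates of the linker, insert and SalI Val.
#' @export
#' @examples
#' cons <- build_construct("VLLVSEVL")
#' substr(cons$sequence, cons$linker_start, cons$linker_end)
build_construct <- function(insert) {
  if (!is.character(insert) || length(insert) != 1 || nchar(insert) < 6 ||
      nchar(insert) > 9) {
    abort("`insert` must be a single sequence of 6-9 residues.")
  }
  assert_standard_seq(insert, "insert")
  len_i <- nchar(insert)
  sequence <- paste0("M", TRXA_SEQ, "GS", insert, "VD", TRXA_SEQ, "HHHHHH")
  trx_len <- nchar(TRXA_SEQ)
  linker_start <- 1 + trx_len + 1                 # the G of GS
  insert_start <- linker_start + 2
  insert_end <- insert_start + len_i - 1
  sal_val_pos <- insert_end + 1
  linker_end <- sal_val_pos + 1                   # the D of VD
  x <- structure(
    list(sequence = sequence, insert = insert,
         linker_start = linker_start, linker_end = linker_end,
         insert_start = insert_start, insert_end = insert_end,
         sal_val_pos = sal_val_pos, length = nchar(sequence)),
    class = "trx_construct"
  )
  stopifnot(substr(sequence, sal_val_pos, sal_val_pos) == "V")
  x
}

#' @export
print.trx_construct <- function(x, ...) {
  cat("<trx_construct>", x$length, "aa,", sprintf("%.2f kDa", construct_mass(x)), "\n")
  cat("  linker: GS +", x$insert, "+ VD (SalI Val at", x$sal_val_pos, ")\n")
  invisible(x)
}

#' Construct and fragment masses
#'
#' Average-isotopic masses (gel scale). Cleavage after position `p1`
#' yields fragments `[1..p1]` and `[p1+1..end]`; hydrolysis adds one
#' water, so the fragment masses sum to the construct mass + 0.018 kDa.
#'
#' @param construct A [build_construct()] object.
#' @param p1 1-based P1 position (cleavage after this residue).
#' @return `construct_mass()`: mass in kDa. `fragment_masses()`: named
#'   numeric `c(n = , c = )` in kDa.
#' @export
construct_mass <- function(construct) {
  stopifnot(inherits(construct, "trx_construct"))
  peptide_mass(construct$sequence) / 1000
}

#' @rdname construct_mass
#' @export
fragment_masses <- function(construct, p1) {
  stopifnot(inherits(construct, "trx_construct"))
  if (p1 < 1 || p1 >= construct$length) {
    abort("`p1` must satisfy 1 <= p1 < construct length.")
  }
  n_frag <- substr(construct$sequence, 1, p1)
  c_frag <- substr(construct$sequence, p1 + 1, construct$length)
  c(n = peptide_mass(n_frag) / 1000, c = peptide_mass(c_frag) / 1000)
}

#' Predict cleavage sites in a reporter construct
#'
#' Scores every nine-residue window whose P1 lies in the linker
#' (GS + insert) at an anchor-compatible residue. Sites at or above
#' `threshold` are reported as kind `"insert"`, ranked by score. If no
#' insert site passes, the window centered on the SalI-encoded Val is
#' evaluated and reported as `"sal_fallback"` when it passes — the
#' secondary cleavage observed when the inserted test sequence itself is
#' refractory. Positions inside the folded thioredoxin domains are
#' excluded by an accessibility mask under native conditions; SDS mode
#' (`sds_mode = TRUE`) lifts the mask, emulating the detergent-opened
#' state in which cleavage within the Trx domains also occurs.
#'
#' Weak-tier P1 anchors are penalized by `weak_penalty_bits` (default 1
#' bit, a two-fold odds reduction).
#'
#' @param construct A [build_construct()] object.
#' @param m A [position_matrix].
#' @param anchors A [primary_specificity].
#' @param threshold Minimum (penalized) score in bits.
#' @param weak_penalty_bits Penalty for weak-tier P1 residues.
#' @param sds_mode Lift the folded-domain accessibility mask.
#' @param mask_sal If `TRUE`, the SalI Val is masked and no fallback is
#'   evaluated.
#' @return Tibble of class `cleavage_prediction`: `p1_pos`, `residue`,
#'   `kind`, `score`, `frag_n_kda`, `frag_c_kda`, sorted by descending
#'   score; zero rows when nothing passes.
#' @export
predict_cleavage <- function(construct, m,
                             anchors = primary_specificity("hNE"),
                             threshold = 0, weak_penalty_bits = 1,
                             sds_mode = FALSE, mask_sal = FALSE) {
  stopifnot(inherits(construct, "trx_construct"),
            inherits(m, "position_matrix"),
            inherits(anchors, "primary_specificity"))
  seq <- construct$sequence
  residues <- split_residues(seq)

  score_site <- function(pos) {
    window <- substr(seq, pos - 4, pos + 4)
    s <- score_window(m, window)
    if (residues[pos] %in% anchors$weak) s <- s - weak_penalty_bits
    s
  }

  insert_positions <- if (sds_mode) {
    setdiff(5:(construct$length - 4), construct$sal_val_pos)
  } else {
    construct$linker_start:(construct$sal_val_pos - 1)
  }
  insert_positions <- insert_positions[
    residues[insert_positions] %in% anchors$anchor_set]

  build_rows <- function(positions, kind) {
    if (length(positions) == 0) return(empty_prediction())
    scores <- vapply(positions, score_site, numeric(1))
    keep <- scores >= threshold
    positions <- positions[keep]; scores <- scores[keep]
    if (length(positions) == 0) return(empty_prediction())
    frags <- vapply(positions, function(p) fragment_masses(construct, p),
                    numeric(2))
    tibble(p1_pos = positions, residue = residues[positions], kind = kind,
           score = scores, frag_n_kda = frags["n", ],
           frag_c_kda = frags["c", ])
  }

  hits <- build_rows(insert_positions, "insert")
  if (nrow(hits) == 0 && !mask_sal &&
      "V" %in% anchors$anchor_set) {
    hits <- build_rows(construct$sal_val_pos, "sal_fallback")
  }
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$p1_pos)
  structure(hits, class = c("cleavage_prediction", class(hits)),
            construct = construct)
}

empty_prediction <- function() {
  tibble(p1_pos = integer(), residue = character(), kind = character(),
         score = numeric(), frag_n_kda = numeric(), frag_c_kda = numeric())
}

#' The recombinant substrate panel
#'
#' The panel of linker inserts used with the tandem-thioredoxin
#' reporters, with the enzyme tested and the gel-observed site kind
#' (`insert`: cleaved within the inserted core; `sal_fallback`: cleaved
#' at the SalI-encoded Val; `none`). Rows with `inferred = TRUE`
#' reconstruct the flanking scaffold (GRGG...GRG) from the stated design
#' because the full insert sequence was not printed; they are synthetic
#' reconstructions, not verbatim published sequences.
#'
#' @return Tibble with columns `name`, `insert`, `enzyme`,
#'   `observed_site`, `inferred`.
#' @export
substrate_panel <- function() {
  path <- system.file("extdata", "substrate_panel.tsv", package = "phagespec")
  readr::read_tsv(path, show_col_types = FALSE, comment = "#") |>
    dplyr::mutate(inferred = as.logical(.data$inferred))
}
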