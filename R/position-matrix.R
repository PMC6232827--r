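# Position frequency / log-odds matrices over the P5-P4' subsite frame.

#' Construct a position matrix
#'
#' A `position_matrix` holds per-subsite residue frequencies for the nine
#' subsites P5..P4' together with the pseudocount and background
#' composition used to build it, and the derived log-odds matrix
#' `log2(freq / background)` in bits.
#'
#' @param freq Numeric 9 x 20 matrix; rows are subsites (P5..P4'), columns
#'   the 20 standard residues in [aa_alphabet()] order. Each row must sum
#'   to 1.
#' @param alpha Pseudocount used when the matrix was built (metadata).
#' @param background Length-20 background residue composition (sums to 1).
#'   Default uniform (1/20).
#' @param n_obs Optional per-subsite observation counts (metadata).
#' @return An object of class `position_matrix`.
#' @export
position_matrix <- function(freq, alpha = 0,
                            background = uniform_background(),
                            n_obs = NULL) {
  freq <- as.matrix(freq)
  if (!all(dim(freq) == c(9L, 20L))) {
    abort("`freq` must be a 9 x 20 matrix (subsites x residues).")
  }
  dimnames(freq) <- list(subsite_labels(), aa_alphabet())
  background <- validate_background(background)
  if (alpha < 0) abort("`alpha` must be >= 0.")
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9)) {
    abort("Each subsite row of `freq` must sum to 1 (tolerance 1e-9).")
  }
  if (any(freq < 0)) abort("Frequencies must be non-negative.")
  logodds <- log2(sweep(freq, 2, background, "/"))
  structure(
    list(freq = freq, alpha = alpha, background = background,
         logodds = logodds, n_obs = n_obs),
    class = "position_matrix"
  )
}

#' @rdname position_matrix
#' @return For `uniform_background()`, a named length-20 vector of 1/20.
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), aa_alphabet())
}

validate_background <- function(background) {
  if (length(background) != 20) abort("`background` must have length 20.")
  if (is.null(names(background))) {
    names(background) <- aa_alphabet()
  } else {
    if (!setequal(names(background), aa_alphabet())) {
      abort("`background` names must be the 20 standard residues.")
    }
    background <- background[aa_alphabet()]
  }
  if (any(background <= 0)) abort("`background` must be strictly positive.")
  if (abs(sum(background) - 1) > 1e-9) abort("`background` must sum to 1.")
  background
}

#' @export
print.position_matrix <- function(x, ...) {
  cat("<position_matrix> 9 subsites x 20 residues\n")
  cat("  pseudocount alpha:", x$alpha, "\n")
  ic <- information_content(x)
  cat("  information content (bits):",
      paste(sprintf("%s=%.2f", names(ic), ic), collapse = " "), "\n")
  cat("  consensus:", paste(consensus_residues(x), collapse = ""), "\n")
  invisible(x)
}

consensus_residues <- function(m) {
  aa_alphabet()[apply(m$freq, 1, which.max)]
}

#' Build a position frequency matrix from an aligned peptide block
#'
#' Counts residues in each subsite of the P5-P4' frame, weighting each
#' peptide by its copy count, and smooths with a pseudocount:
#' `freq[j, a] = (count_j(a) + alpha * background[a]) / (N_j + alpha)`.
#'
#' Frame cells that fall outside a peptide's nonamer are taken from the
#' capsid context (`PGG` prefix / `HHHHHH` suffix) when
#' `context = "fill"`, or excluded from the counts when
#' `context = "mask"` (the default, so that constant vector residues do
#' not contaminate the inferred specificity).
#'
#' @param block An [aligned_block] (or any data frame with columns
#'   `peptide`, `count`, `anchor`; `anchor` is the 1-based position of the
#'   P1 residue within the nonamer).
#' @param alpha Pseudocount (default 1).
#' @param background Background residue composition; default uniform.
#' @param context `"mask"` or `"fill"` (see Details).
#' @return A [position_matrix].
#' @export
build_pfm <- function(block, alpha = 1, background = uniform_background(),
                      context = c("mask", "fill")) {
  context <- match.arg(context)
  block <- as_block_df(block)
  if (nrow(block) == 0) abort("Cannot build a matrix from an empty block.")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  background <- validate_background(background)

  counts <- matrix(0, nrow = 9, ncol = 20,
                   dimnames = list(subsite_labels(), aa_alphabet()))
  for (i in seq_len(nrow(block))) {
    cells <- frame_cells(block$peptide[i], block$anchor[i],
                         context = context == "fill")
    for (j in seq_len(9)) {
      if (!is.na(cells[j])) {
        counts[j, cells[j]] <- counts[j, cells[j]] + block$count[i]
      }
    }
  }
  n_obs <- rowSums(counts)
  if (alpha == 0 && any(n_obs == 0)) {
    abort("A subsite has no observations and alpha = 0; cannot normalize.")
  }
  freq <- sweep(counts, 2, background * alpha, "+") / (n_obs + alpha)
  position_matrix(freq, alpha = alpha, background = background, n_obs = n_obs)
}

# Residues of the P5..P4' frame for one peptide. `anchor` is the 1-based
# index of the P1 residue within the nonamer. Returns a length-9 character
# vector with NA where the frame leaves the available sequence.
frame_cells <- function(peptide, anchor, context = FALSE,
                        prefix = "PGG", suffix = "HHHHHH") {
  aa <- split_residues(peptide)
  if (length(aa) != 9) abort("Peptides must be nonamers (9 residues).")
  if (anchor < 1 || anchor > 9) abort("`anchor` must be in 1..9.")
  idx <- anchor + (seq_len(9) - p1_index())   # nonamer index per subsite
  if (context) {
    ext <- c(split_residues(prefix), aa, split_residues(suffix))
    ext_idx <- idx + nchar(prefix)
    out <- ifelse(ext_idx >= 1 & ext_idx <= length(ext), ext[pmax(ext_idx, 1)], NA)
  } else {
    out <- ifelse(idx >= 1 & idx <= 9, aa[pmax(idx, 1)], NA)
  }
  out
}

as_block_df <- function(block) {
  df <- as_tibble(block)
  need <- c("peptide", "count", "anchor")
  if (!all(need %in% names(df))) {
    abort("Block must have columns `peptide`, `count` and `anchor`.")
  }
  if (nrow(df) > 0 && any(df$count < 1)) abort("Copy counts must be >= 1.")
  df
}

#' Per-subsite information content
#'
#' `IC_j = log2(20) + sum_a freq[j, a] * log2(freq[j, a])` in bits, with
#' `0 * log2(0)` taken as 0. Bounded by `[0, log2(20)]`.
#'
#' @param m A [position_matrix].
#' @return Named numeric vector of nine IC values (bits).
#' @export
information_content <- function(m) {
  stopifnot(inherits(m, "position_matrix"))
  f <- m$freq
  plogp <- ifelse(f > 0, f * log2(f), 0)
  setNames(log2(20) + rowSums(plogp), subsite_labels())
}

#' Collapse residue frequencies into side-chain class frequencies
#'
#' @param m A [position_matrix].
#' @param scheme Residue class scheme, as [residue_classes()].
#' @return 9 x 6 matrix of class frequencies; each row sums to 1.
#' @export
class_collapse <- function(m, scheme = residue_classes()) {
  stopifnot(inherits(m, "position_matrix"))
  cls <- class_names()
  out <- sapply(cls, function(cl) {
    members <- names(scheme)[scheme == cl]
    rowSums(m$freq[, members, drop = FALSE])
  })
  rownames(out) <- subsite_labels()
  out
}

#' Score a nine-residue window against a position matrix
#'
#' Additive log-odds score in bits: `sum_j logodds[j, window_j]`.
#'
#' @param m A [position_matrix].
#' @param window A 9-residue string (or character vector of such strings).
#' @return Numeric score(s) in bits.
#' @export
#' @examples
#' # a background-equal matrix scores every window 0
#' m <- position_matrix(matrix(1 / 20, 9, 20))
#' score_window(m, "AAAAAAAAA")
score_window <- function(m, window) {
  stopifnot(inherits(m, "position_matrix"))
  enc <- encode_residues(window, 9L)
  if (anyNA(enc)) {
    abort("Window contains non-standard residues.",
          class = "phagespec_alphabet_error")
  }
  score_encoded(m, enc)
}

# enc: integer matrix (n x 9) of alphabet indices; returns n scores.
score_encoded <- function(m, enc) {
  s <- numeric(nrow(enc))
  for (j in seq_len(9)) {
    s <- s + m$logodds[j, ][enc[, j]]
  }
  unname(s)
}

# -- tidiers and plotting -----------------------------------------------------

#' Tidy a position matrix into a long tibble
#'
#' @param x A [position_matrix].
#' @param ... Unused.
#' @return Tibble with columns `subsite`, `residue`, `class`, `freq`,
#'   `logodds`.
#' @exportS3Method generics::tidy
tidy.position_matrix <- function(x, ...) {
  scheme <- residue_classes()
  tidyr::expand_grid(subsite = factor(subsite_labels(), subsite_labels()),
                     residue = aa_alphabet()) |>
    dplyr::mutate(
      class = unname(scheme[.data$residue]),
      freq = as.vector(t(x$freq)),
      logodds = as.vector(t(x$logodds))
    )
}

#' One-row summary of a position matrix
#'
#' @param x A [position_matrix].
#' @param ... Unused.
#' @return Tibble with pseudocount, total/maximal information content and
#'   the per-subsite argmax consensus.
#' @exportS3Method generics::glance
glance.position_matrix <- function(x, ...) {
  ic <- information_content(x)
  tibble(
    alpha = x$alpha,
    total_ic_bits = sum(ic),
    max_ic_bits = max(ic),
    max_ic_subsite = names(ic)[which.max(ic)],
    consensus = paste(consensus_residues(x), collapse = "")
  )
}

#' Sequence-logo style plot of a position matrix
#'
#' Stacked per-subsite bars; bar heights are `freq * IC` in bits (the
#' classical logo letter heights), colored by side-chain class.
#'
#' @param object A [position_matrix].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.position_matrix <- function(object, ...) {
  dat <- export_logo_data(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$subsite, y = .data$height_bits,
                                    fill = .data$class)) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = "subsite", y = "information (bits)",
                  fill = "side-chain class") +
    ggplot2::theme_minimal()
}

#' Export logo letter heights
#'
#' Heights are `freq * IC_j` per subsite, so the per-subsite heights sum
#' to the subsite information content. Suitable input for any logo
#' renderer.
#'
#' @param m A [position_matrix].
#' @return Tibble with `subsite`, `residue`, `class`, `freq`,
#'   `height_bits`.
#' @export
export_logo_data <- function(m) {
  stopifnot(inherits(m, "position_matrix"))
  ic <- information_content(m)
  tidy(m) |>
    dplyr::mutate(height_bits = .data$freq * ic[as.character(.data$subsite)]) |>
    dplyr::select("subsite", "residue", "class", "freq", "height_bits")
}

# -- serialization ------------------------------------------------------------

#' Read and write position matrices
#'
#' `write_pfm_tsv()` writes the frequency matrix as TSV (rows = subsites,
#' columns = residues, 6-decimal frequencies); `read_pfm_tsv()` reads it
#' back (re-normalizing rounding error). `write_pfm_json()` /
#' `read_pfm_json()` round-trip the full object including pseudocount,
#' background and provenance metadata.
#'
#' @param m A [position_matrix].
#' @param path File path.
#' @param meta Optional named list of provenance metadata (JSON only).
#' @return The input (writers, invisibly) or a [position_matrix] (readers).
#' @name pfm_io
NULL

#' @rdname pfm_io
#' @export
write_pfm_tsv <- function(m, path) {
  stopifnot(inherits(m, "position_matrix"))
  df <- as.data.frame(round(m$freq, 6))
  df <- cbind(subsite = rownames(m$freq), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(m)
}

#' @rdname pfm_io
#' @export
read_pfm_tsv <- function(path, alpha = 0, background = uniform_background()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  freq <- as.matrix(df[, aa_alphabet()])
  rownames(freq) <- df$subsite
  freq <- freq / rowSums(freq)  # undo 6-decimal rounding
  position_matrix(freq, alpha = alpha, background = background)
}

#' @rdname pfm_io
#' @export
write_pfm_json <- function(m, path, meta = list()) {
  stopifnot(inherits(m, "position_matrix"))
  obj <- list(
    subsites = subsite_labels(),
    residues = aa_alphabet(),
    freq = unname(apply(m$freq, 1, as.numeric, simplify = FALSE)),
    alpha = m$alpha,
    background = as.list(m$background),
    meta = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(m)
}

#' @rdname pfm_io
#' @export
read_pfm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  freq <- if (is.matrix(obj$freq)) obj$freq else
    matrix(unlist(obj$freq), nrow = 9, byrow = TRUE)
  background <- unlist(obj$background)[aa_alphabet()]
  position_matrix(freq, alpha = obj$alpha, background = background)
}
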