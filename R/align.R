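# Anchored ungapped alignment of selected nonamers into the P5-P4' frame.
#
# Reconstructs algorithmically what was originally done by hand: choose,
# for every selected peptide, which anchor residue (a P1-compatible
# residue) sits at P1 so that the peptides agree as much as possible in
# side-chain class across the frame. Peptides with a single possible
# anchor are fixed first; ambiguous peptides are then placed to fit the
# emerging pattern, and the placement is polished by coordinate ascent.

#' Alignment parameters
#'
#' @param anchors A [primary_specificity] (strong/weak P1 tiers) or a
#'   character vector of anchor residues (all treated as strong).
#' @param weights Positive per-subsite weight vector (length 9). The
#'   default up-weights the four P1-proximal columns (P2, P1, P1', P2')
#'   two-fold.
#' @param weak_penalty Additive penalty per peptide copy anchored at a
#'   weak-tier residue (default 0.5, i.e. half a same-class pair).
#' @param max_iters Maximum coordinate-ascent passes.
#' @return Object of class `align_params`.
#' @export
align_params <- function(anchors = primary_specificity("hNE"),
                         weights = default_subsite_weights(),
                         weak_penalty = 0.5, max_iters = 20) {
  if (is.character(anchors)) {
    anchors <- primary_specificity("custom", strong = anchors)
  }
  stopifnot(inherits(anchors, "primary_specificity"))
  if (length(weights) != 9 || any(weights <= 0)) {
    abort("`weights` must be 9 positive values.")
  }
  if (weak_penalty < 0) abort("`weak_penalty` must be >= 0.")
  structure(list(anchors = anchors,
                 weights = setNames(as.numeric(weights), subsite_labels()),
                 weak_penalty = weak_penalty,
                 max_iters = as.integer(max_iters)),
            class = "align_params")
}

#' @rdname align_params
#' @export
default_subsite_weights <- function() {
  setNames(c(1, 1, 1, 2, 2, 2, 2, 1, 1), subsite_labels())
}

#' Candidate P1 anchor positions within a nonamer
#'
#' @param nonamer A 9-residue string.
#' @param anchor_set Residues allowed at P1.
#' @return Integer vector of 1-based positions (possibly empty).
#' @export
#' @examples
#' candidate_anchors("VLLVSEVLA", c("V", "A", "I"))  # 1 4 7 9
candidate_anchors <- function(nonamer, anchor_set) {
  aa <- split_residues(nonamer)
  if (length(aa) != 9) abort("`nonamer` must have 9 residues.")
  which(aa %in% anchor_set)
}

#' Construct an aligned peptide block
#'
#' @param peptide Character vector of nonamers.
#' @param count Positive integer copy counts.
#' @param anchor 1-based P1 positions within each nonamer.
#' @param discarded Optional tibble of unplaceable peptides.
#' @return Tibble of class `aligned_block` with columns `peptide`,
#'   `count`, `anchor`, `offset` (= anchor - 5, the shift of the peptide
#'   against the frame).
#' @export
aligned_block <- function(peptide, count = 1L, anchor,
                          discarded = NULL) {
  count <- rep_len(as.integer(count), length(peptide))
  if (any(count < 1)) abort("Copy counts must be >= 1.")
  if (any(anchor < 1 | anchor > 9)) abort("Anchors must be in 1..9.")
  for (p in peptide) assert_standard_seq(p, "peptide")
  df <- tibble(peptide = peptide, count = count,
               anchor = as.integer(anchor),
               offset = as.integer(anchor) - p1_index())
  structure(df,
            discarded = discarded %||% tibble(peptide = character(),
                                              count = integer(),
                                              reason = character()),
            context_prefix = "PGG", context_suffix = "HHHHHH",
            class = c("aligned_block", class(df)))
}

#' Class-coherence objective of an aligned block
#'
#' Weighted count of same-class peptide pairs per frame column:
#' `sum_j w_j * sum_c choose(n_jc, 2)`, where `n_jc` counts peptide
#' copies whose residue in column j belongs to class c. Only nonamer
#' residues contribute (capsid context is constant across clones and is
#' never allowed to drive the alignment).
#'
#' @param block An [aligned_block] (or data frame with `peptide`,
#'   `count`, `anchor`).
#' @param scheme Residue class scheme.
#' @param weights Per-subsite weights (length 9).
#' @return The objective value (non-negative number).
#' @export
alignment_objective <- function(block, scheme = residue_classes(),
                                weights = default_subsite_weights()) {
  block <- as_block_df(block)
  counts <- class_count_matrix(block, scheme)
  sum(weights * rowSums(counts * (counts - 1) / 2))
}

# 9 x 6 matrix of per-column class copy-counts (nonamer cells only).
class_count_matrix <- function(block, scheme = residue_classes()) {
  counts <- matrix(0, 9, length(class_names()),
                   dimnames = list(subsite_labels(), class_names()))
  for (i in seq_len(nrow(block))) {
    cells <- frame_cells(block$peptide[i], block$anchor[i], context = FALSE)
    for (j in which(!is.na(cells))) {
      cl <- scheme[[cells[j]]]
      counts[j, cl] <- counts[j, cl] + block$count[i]
    }
  }
  counts
}

#' Align nonamers into the P5-P4' frame by anchor choice
#'
#' Every peptide is placed so that one of its anchor residues sits at P1.
#' Peptides are seeded in order of increasing anchor ambiguity (forced
#' single-anchor peptides first), each subsequent peptide is placed
#' greedily at the anchor that maximizes the class-coherence objective
#' against the partial block, and placements are then polished by
#' coordinate ascent (single-peptide re-placement; additionally pairwise
#' re-placement for blocks of up to `pair_move_max` peptides) until no
#' move improves the objective. Weak-tier anchors are admissible but
#' penalized. Ties prefer the anchor closest to the nonamer center, then
#' the leftmost. The result is deterministic given input order.
#'
#' Peptides with no anchor residue, or containing non-standard residues,
#' are reported in the `discarded` attribute, never silently dropped.
#'
#' When the space of anchor assignments is small (at most `exact_limit`
#' combinations) the optimum is found by exhaustive enumeration instead,
#' which guarantees the attained objective is the global one and is
#' independent of input order; typical sequenced samples (~100 peptides)
#' use the greedy/ascent path.
#'
#' @param peptides Character vector of nonamers, or a data frame with
#'   columns `peptide` and (optionally) `count`.
#' @param params An [align_params].
#' @param scheme Residue class scheme.
#' @param pair_move_max Maximum block size for the pairwise-move polish.
#' @param exact_limit Maximum number of anchor combinations solved by
#'   exhaustive enumeration.
#' @return An [aligned_block]; attributes `objective` (penalized
#'   objective attained), `pair_objective` (unpenalized), `discarded`.
#' @export
align_nonamers <- function(peptides, params = align_params(),
                           scheme = residue_classes(),
                           pair_move_max = 12L, exact_limit = 20000L) {
  stopifnot(inherits(params, "align_params"))
  df <- if (is.data.frame(peptides)) as_tibble(peptides) else
    tibble(peptide = as.character(peptides))
  if (!"count" %in% names(df)) df$count <- 1L
  if (nrow(df) == 0) abort("No peptides supplied.")
  df$count <- as.integer(df$count)
  if (any(df$count < 1)) abort("Copy counts must be >= 1.")

  anchors <- params$anchors
  weak <- anchors$weak
  discard <- tibble(peptide = character(), count = integer(),
                    reason = character())
  cand <- vector("list", nrow(df))
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    p <- df$peptide[i]
    if (nchar(p) != 9) {
      discard <- dplyr::add_row(discard, peptide = p, count = df$count[i],
                                reason = "not_a_nonamer")
    } else if (!is_standard_seq(p)) {
      discard <- dplyr::add_row(discard, peptide = p, count = df$count[i],
                                reason = "non_standard_residue")
    } else {
      ci <- candidate_anchors(p, anchors$anchor_set)
      if (length(ci) == 0) {
        discard <- dplyr::add_row(discard, peptide = p, count = df$count[i],
                                  reason = "no_anchor")
      } else {
        cand[[i]] <- ci
        ok[i] <- TRUE
      }
    }
  }
  if (!any(ok)) abort("No peptide has a candidate anchor; nothing to align.")

  kept <- df[ok, ]
  cand <- cand[ok]
  n <- nrow(kept)
  w <- params$weights
  lambda <- params$weak_penalty

  # Precompute, per peptide and candidate anchor, the contributing cells
  # (subsite index, class index) and the weak-anchor penalty.
  cls_idx <- matrix(match(scheme[split_residues(paste(kept$peptide, collapse = ""))],
                          class_names()),
                    nrow = n, ncol = 9, byrow = TRUE)
  cell_info <- function(i, a) {
    idx <- a + (seq_len(9) - p1_index())
    jj <- which(idx >= 1 & idx <= 9)
    list(j = jj, c = cls_idx[i, idx[jj]],
        penalty = lambda * kept$count[i] *
          (split_residues(kept$peptide[i])[a] %in% weak))
  }
  info <- lapply(seq_len(n), function(i)
    setNames(lapply(cand[[i]], function(a) cell_info(i, a)),
             as.character(cand[[i]])))

  M <- matrix(0, 9, length(class_names()))
  placement <- integer(n)

  assignment_objective <- function(anchors_vec) {
    Mx <- matrix(0, 9, length(class_names()))
    pen <- 0
    for (i in seq_len(n)) {
      ci <- info[[i]][[as.character(anchors_vec[i])]]
      Mx[cbind(ci$j, ci$c)] <- Mx[cbind(ci$j, ci$c)] + kept$count[i]
      pen <- pen + ci$penalty
    }
    sum(w * rowSums(Mx * (Mx - 1) / 2)) - pen
  }

  # exact enumeration when the assignment space is small: guarantees the
  # global optimum and order-invariance of the attained objective
  n_comb <- prod(lengths(cand))
  if (n_comb <= exact_limit) {
    # candidates pre-sorted by the tie-break preference so the first
    # optimum encountered respects it
    cand_sorted <- lapply(cand, function(a) a[order(abs(a - p1_index()), a)])
    grid <- as.matrix(expand.grid(cand_sorted, KEEP.OUT.ATTRS = FALSE))
    best_val <- -Inf
    best_row <- NULL
    for (r in seq_len(nrow(grid))) {
      val <- assignment_objective(grid[r, ])
      if (val > best_val + 1e-9) {
        best_val <- val
        best_row <- grid[r, ]
      }
    }
    out <- aligned_block(kept$peptide, kept$count, as.integer(best_row),
                         discarded = discard)
    attr(out, "objective") <- best_val
    attr(out, "pair_objective") <- alignment_objective(out, scheme, w)
    attr(out, "params") <- params
    return(out)
  }

  add_delta <- function(i, a) {
    ci <- info[[i]][[as.character(a)]]
    m <- kept$count[i]
    sum(w[ci$j] * (M[cbind(ci$j, ci$c)] * m + m * (m - 1) / 2)) - ci$penalty
  }
  apply_place <- function(i, a, sign = 1) {
    ci <- info[[i]][[as.character(a)]]
    M[cbind(ci$j, ci$c)] <<- M[cbind(ci$j, ci$c)] + sign * kept$count[i]
  }
  pick_best <- function(i) {
    as_ <- cand[[i]]
    deltas <- vapply(as_, function(a) add_delta(i, a), numeric(1))
    best <- max(deltas)
    tied <- as_[deltas >= best - 1e-9]
    tied[order(abs(tied - p1_index()), tied)][1]
  }

  # greedy seeding, least-ambiguous first
  ord <- order(lengths(cand), seq_len(n))
  for (i in ord) {
    a <- pick_best(i)
    placement[i] <- a
    apply_place(i, a)
  }

  objective <- function() {
    pen <- sum(vapply(seq_len(n), function(i)
      info[[i]][[as.character(placement[i])]]$penalty, numeric(1)))
    sum(w * rowSums(M * (M - 1) / 2)) - pen
  }

  # coordinate ascent: single-peptide re-placement
  single_pass <- function() {
    changed <- FALSE
    for (i in ord) {
      if (length(cand[[i]]) == 1) next
      cur <- placement[i]
      apply_place(i, cur, sign = -1)
      a <- pick_best(i)
      if (a != cur && add_delta(i, a) > add_delta(i, cur) + 1e-9) {
        placement[i] <<- a
        changed <- TRUE
        apply_place(i, a)
      } else {
        apply_place(i, cur)
      }
    }
    changed
  }
  pair_pass <- function() {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (k in (i + 1):n) {
        if (length(cand[[i]]) == 1 && length(cand[[k]]) == 1) next
        cur_i <- placement[i]; cur_k <- placement[k]
        apply_place(i, cur_i, -1); apply_place(k, cur_k, -1)
        best <- c(cur_i, cur_k)
        apply_place(i, cur_i); apply_place(k, cur_k)
        base <- objective()
        best_val <- base
        for (ai in cand[[i]]) {
          for (ak in cand[[k]]) {
            if (ai == cur_i && ak == cur_k) next
            apply_place(i, cur_i, -1); apply_place(k, cur_k, -1)
            placement[i] <<- ai; placement[k] <<- ak
            apply_place(i, ai); apply_place(k, ak)
            val <- objective()
            if (val > best_val + 1e-9) {
              best_val <- val
              best <- c(ai, ak)
            }
            apply_place(i, ai, -1); apply_place(k, ak, -1)
            placement[i] <<- cur_i; placement[k] <<- cur_k
            apply_place(i, cur_i); apply_place(k, cur_k)
          }
        }
        if (best_val > base + 1e-9) {
          apply_place(i, cur_i, -1); apply_place(k, cur_k, -1)
          placement[i] <<- best[1]; placement[k] <<- best[2]
          apply_place(i, best[1]); apply_place(k, best[2])
          improved <- TRUE
        }
      }
    }
    improved
  }

  last_obj <- objective()
  for (iter in seq_len(params$max_iters)) {
    changed <- single_pass()
    if (!changed && n <= pair_move_max) changed <- pair_pass()
    obj <- objective()
    stopifnot(obj >= last_obj - 1e-9)  # ascent must be monotone
    if (!changed) break
    last_obj <- obj
  }

  out <- aligned_block(kept$peptide, kept$count, placement,
                       discarded = discard)
  attr(out, "objective") <- objective()
  attr(out, "pair_objective") <- alignment_objective(out, scheme, w)
  attr(out, "params") <- params
  out
}

#' @export
print.aligned_block <- function(x, ...) {
  cat(sprintf("<aligned_block> %d peptide(s), %d cop(ies); objective %.2f; %d discarded\n",
              nrow(x), sum(x$count), attr(x, "objective") %||% NA_real_,
              nrow(attr(x, "discarded"))))
  NextMethod()
}

#' Consensus report for an aligned block
#'
#' Lists each unique peptide with its copy count and frame cells, and
#' summarizes each column by its majority side-chain class and majority
#' residue. Exact ties are reported as ties (all tied values joined with
#' `"/"`, `tie = TRUE`), never broken arbitrarily.
#'
#' @param block An [aligned_block].
#' @param scheme Residue class scheme.
#' @param context Fill frame cells outside the nonamer from the capsid
#'   context (`PGG`/`HHHHHH`)?
#' @return List of class `consensus_report` with `peptides` (one row per
#'   peptide: peptide, count, offset, P5..P4p cells) and `consensus`
#'   (subsite, majority_class, class_share, class_tie, majority_residue,
#'   residue_share, residue_tie).
#' @export
consensus_report <- function(block, scheme = residue_classes(),
                             context = FALSE) {
  block <- as_block_df(block)
  if (nrow(block) == 0) abort("Empty block.")
  cells <- t(vapply(seq_len(nrow(block)), function(i)
    frame_cells(block$peptide[i], block$anchor[i], context = context),
    character(9)))
  colnames(cells) <- subsite_labels()
  peptides <- dplyr::bind_cols(
    tibble(peptide = block$peptide, count = block$count,
           offset = block$anchor - p1_index()),
    as_tibble(as.data.frame(cells, stringsAsFactors = FALSE))
  ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$peptide)

  summarize_col <- function(j, values) {
    present <- !is.na(cells[, j])
    counts <- block$count[present]
    vals <- values[present]
    if (length(vals) == 0) {
      return(list(value = NA_character_, share = NA_real_, tie = FALSE))
    }
    tab <- tapply(counts, vals, sum)
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])
    list(value = paste(winners, collapse = "/"),
         share = top / sum(tab), tie = length(winners) > 1)
  }
  cons <- purrr::map_dfr(seq_len(9), function(j) {
    cl <- summarize_col(j, unname(scheme[cells[, j]]))
    res <- summarize_col(j, cells[, j])
    tibble(subsite = subsite_labels()[j],
           majority_class = cl$value, class_share = cl$share,
           class_tie = cl$tie,
           majority_residue = res$value, residue_share = res$share,
           residue_tie = res$tie)
  })
  structure(list(peptides = peptides, consensus = cons),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report>\n")
  print(x$consensus)
  cat(sprintf("%d unique peptide(s)\n", nrow(x$peptides)))
  invisible(x)
}

#' Write an aligned block (and its discards) as TSV
#'
#' @param block An [aligned_block].
#' @param path Output path for the block table.
#' @param discard_path Optional path for the discard report.
#' @return The block, invisibly.
#' @export
write_block_tsv <- function(block, path, discard_path = NULL) {
  rep <- consensus_report(block)
  readr::write_tsv(rep$peptides, path)
  if (!is.null(discard_path)) {
    readr::write_tsv(attr(block, "discarded"), discard_path)
  }
  invisible(block)
}

#' Read peptides for alignment from FASTA or TSV
#'
#' FASTA headers may carry duplicate counts as `|n=<k>`; TSV files need
#' columns `peptide` (or `sequence`/`nonamer`) and optionally `count`.
#'
#' @param path Input file.
#' @return Tibble with `peptide` and `count`.
#' @export
read_peptides <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    set <- Biostrings::readAAStringSet(path)
    ids <- names(set)
    count <- suppressWarnings(
      as.integer(stringr::str_match(ids, "\\|n=(\\d+)")[, 2]))
    tibble(peptide = as.character(set),
           count = dplyr::coalesce(count, 1L))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    seq_col <- intersect(c("peptide", "sequence", "nonamer"), names(df))[1]
    if (is.na(seq_col)) abort("TSV must have a peptide/sequence/nonamer column.")
    tibble(peptide = df[[seq_col]],
           count = if ("count" %in% names(df)) as.integer(df$count) else 1L)
  }
}
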