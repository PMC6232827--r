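# Sliding-window scan of protein sequences for candidate cleavage sites.

#' Score-threshold calibration for a position matrix
#'
#' Scores a large deterministic sample of windows drawn from the
#' background composition and returns an upper quantile. Used as the
#' default hit threshold in scanning: with the default 99.9th
#' percentile, about one background window in a thousand passes.
#'
#' @param m A [position_matrix].
#' @param quantile Upper quantile (default 0.999).
#' @param n Number of background windows sampled.
#' @param background Residue composition to sample from; defaults to the
#'   matrix's own background.
#' @param seed Internal seed (fixed by default so the threshold is a
#'   deterministic property of the matrix).
#' @return Threshold score in bits.
#' @export
score_threshold <- function(m, quantile = 0.999, n = 1e5,
                            background = NULL, seed = 104729L) {
  stopifnot(inherits(m, "position_matrix"))
  background <- validate_background(background %||% m$background)
  withr::with_seed(seed, {
    enc <- matrix(sample.int(20L, n * 9, replace = TRUE, prob = background),
                  nrow = n, ncol = 9)
    unname(stats::quantile(score_encoded(m, enc), quantile))
  })
}

#' Scan a protein sequence for candidate cleavage sites
#'
#' Scores every nine-residue window (P5..P4') of the protein against the
#' matrix. Hits at or above the threshold are returned sorted by
#' descending score, then ascending position, and ranked. P1 positions
#' are 1-based; cleavage occurs after the P1 residue. Windows containing
#' non-standard residues are skipped and counted (attribute
#' `windows_skipped`), not errors. Sequences shorter than nine residues
#' yield zero hits with a warning. Scores are sequence-only: no
#' structural-accessibility correction is applied.
#'
#' @param protein A single protein sequence string.
#' @param m A [position_matrix].
#' @param threshold Minimum score in bits; `NULL` for the calibrated
#'   default [score_threshold()].
#' @param id Protein identifier carried into the result.
#' @return Tibble with `protein_id`, `p1_pos`, `window`, `score`,
#'   `rank`; attributes `windows_scored` and `windows_skipped`.
#' @export
scan_sequence <- function(protein, m, threshold = NULL, id = "protein") {
  stopifnot(inherits(m, "position_matrix"))
  threshold <- threshold %||% score_threshold(m)
  len <- nchar(protein)
  empty <- tibble(protein_id = character(), p1_pos = integer(),
                  window = character(), score = numeric(), rank = integer())
  if (len < 9) {
    if (len > 0) warn(sprintf("Sequence '%s' is shorter than 9 residues; no windows scored.", id))
    return(structure(empty, windows_scored = 0L, windows_skipped = 0L))
  }
  starts <- seq_len(len - 8L)
  windows <- substring(protein, starts, starts + 8L)
  enc <- encode_residues(windows, 9L)
  valid <- !apply(is.na(enc), 1, any)
  skipped <- sum(!valid)
  scores <- rep(NA_real_, length(windows))
  if (any(valid)) {
    scores[valid] <- score_encoded(m, enc[valid, , drop = FALSE])
  }
  p1 <- starts + 4L  # P1 is the 5th residue of each window
  keep <- valid & scores >= threshold
  hits <- tibble(protein_id = id, p1_pos = p1[keep],
                 window = windows[keep], score = scores[keep]) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$p1_pos) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(hits, windows_scored = sum(valid), windows_skipped = skipped)
}

#' Scan a multi-record FASTA file
#'
#' Applies [scan_sequence()] to every record. Duplicate record
#' identifiers are rejected. Hits are re-ranked across all records.
#'
#' @param path FASTA file path.
#' @param m A [position_matrix].
#' @param threshold Minimum score; `NULL` for the calibrated default.
#' @return List of class `scan_result`: `hits` (tibble as in
#'   [scan_sequence()], ranked globally) and `summary` (tibble with
#'   records processed, windows scored and skipped).
#' @export
scan_fasta <- function(path, m, threshold = NULL) {
  stopifnot(inherits(m, "position_matrix"))
  threshold <- threshold %||% score_threshold(m)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    abort(sprintf("Malformed FASTA '%s': %s", path,
                                  conditionMessage(e)))
                  })
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate FASTA record id(s): %s",
                  paste(dup, collapse = ", ")))
  }
  scored <- 0L
  skipped <- 0L
  if (length(set) == 0) {
    return(structure(
      list(hits = tibble(protein_id = character(), p1_pos = integer(),
                         window = character(), score = numeric(),
                         rank = integer()),
           summary = tibble(records = 0L, windows_scored = 0L,
                            windows_skipped = 0L, threshold = threshold)),
      class = "scan_result"
    ))
  }
  hits <- purrr::map(seq_along(set), function(i) {
    h <- scan_sequence(as.character(set[[i]]), m, threshold = threshold,
                       id = ids[i])
    scored <<- scored + attr(h, "windows_scored")
    skipped <<- skipped + attr(h, "windows_skipped")
    h
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$score), .data$protein_id, .data$p1_pos) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(
    list(hits = hits,
         summary = tibble(records = length(set), windows_scored = scored,
                          windows_skipped = skipped,
                          threshold = threshold)),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d record(s), %d window(s) scored, %d skipped, %d hit(s)\n",
              x$summary$records, x$summary$windows_scored,
              x$summary$windows_skipped, nrow(x$hits)))
  print(head(x$hits, 10))
  invisible(x)
}

#' Write scan hits as TSV with a JSON summary
#'
#' @param result A `scan_result`.
#' @param path Output TSV path.
#' @param summary_path Optional JSON summary path.
#' @return The result, invisibly.
#' @export
write_scan_tsv <- function(result, path, summary_path = NULL) {
  stopifnot(inherits(result, "scan_result"))
  readr::write_tsv(result$hits, path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(as.list(result$summary), summary_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
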