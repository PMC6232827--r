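# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (plain loops, exhaustive enumeration)
# and share no code path with the package implementation.

# Side-chain class of one residue, written out independently.
oracle_class <- function(aa) {
  if (aa %in% c("F", "Y", "W")) return("aromatic")
  if (aa %in% c("D", "E")) return("negative")
  if (aa %in% c("K", "R")) return("positive")
  if (aa %in% c("G", "A")) return("small_aliphatic")
  if (aa %in% c("V", "L", "I", "P")) return("larger_aliphatic")
  "hydrophilic"
}

# Penalized class-coherence objective of a full anchor assignment,
# computed by direct pair enumeration per column.
oracle_objective <- function(peptides, counts, anchors_vec, weights,
                             weak = character(), lambda = 0) {
  weights <- unname(weights)
  total <- 0
  for (j in 1:9) {
    labels <- character(0)
    for (i in seq_along(peptides)) {
      pos <- anchors_vec[i] + (j - 5)
      if (pos >= 1 && pos <= 9) {
        cl <- oracle_class(substr(peptides[i], pos, pos))
        labels <- c(labels, rep(cl, counts[i]))
      }
    }
    if (length(labels) > 0) {
      tab <- table(labels)
      total <- total + weights[j] * sum(choose(tab, 2))
    }
  }
  penalty <- 0
  for (i in seq_along(peptides)) {
    a <- anchors_vec[i]
    if (substr(peptides[i], a, a) %in% weak) {
      penalty <- penalty + lambda * counts[i]
    }
  }
  total - penalty
}

# Exhaustive-enumeration optimum over all candidate-anchor combinations.
oracle_best_objective <- function(peptides, counts, anchor_set, weights,
                                  weak = character(), lambda = 0) {
  cand <- lapply(peptides, function(p) {
    which(strsplit(p, "")[[1]] %in% anchor_set)
  })
  stopifnot(all(lengths(cand) > 0))
  grid <- expand.grid(cand)
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    val <- oracle_objective(peptides, counts, as.integer(grid[r, ]),
                            weights, weak, lambda)
    if (val > best) best <- val
  }
  best
}

# Random nonamer guaranteed to contain at least one anchor residue.
random_anchored_nonamer <- function(anchor_set = c("V", "A", "I")) {
  repeat {
    p <- paste(sample(aa_alphabet(), 9, replace = TRUE), collapse = "")
    if (any(strsplit(p, "")[[1]] %in% anchor_set)) return(p)
  }
}

# A sharp toy matrix concentrated on a single window, handy for planting.
toy_consensus_matrix <- function(window = "LLLLVSLLL", focus = 0.6) {
  stopifnot(nchar(window) == 9)
  aa <- aa_alphabet()
  freq <- matrix((1 - focus) / 19, nrow = 9, ncol = 20,
                 dimnames = list(subsite_labels(), aa))
  for (j in 1:9) {
    freq[j, ] <- (1 - focus) / 19
    freq[j, substr(window, j, j)] <- focus
  }
  position_matrix(freq)
}

# helper: splice a planted clone into a pool tibble
new_pool_with_plant <- function(pool, nonamer, n) {
  df <- dplyr::bind_rows(tibble::as_tibble(pool),
                         tibble::tibble(nonamer = nonamer, abundance = n))
  df <- dplyr::summarise(dplyr::group_by(df, nonamer),
                         abundance = sum(abundance), .groups = "drop")
  structure(df, round = 0L, total = sum(df$abundance),
            class = c("phage_pool", class(df)))
}
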