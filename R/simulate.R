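# Stochastic simulator of substrate phage-display biopanning.
#
# A naive library of random nonamers displayed as PGG(X)9HHHHHH is bound
# to a Ni-NTA matrix via the C-terminal His6 tag; protease treatment
# releases clones whose displayed peptide is cleavable; released phages
# are amplified and re-panned. A PBS control arm measures background
# release. After the last round individual clones are picked and
# sequenced.

#' Biopanning run parameters
#'
#' Defaults are desk-scale versions of the published protocol: a library
#' of 5e7 unique nonamer clones panned over five rounds with ~1e8-1e9 pfu
#' bound per round and ten high-salt washes, 120 clones picked and 96
#' sequenced after the final round. The scaled defaults
#' (`n0 = bound = 1e5`) preserve the selection dynamics at tractable
#' size; protocol-scale values can be requested explicitly.
#'
#' @param n0 Library complexity (unique-clone draws at round 0).
#' @param bound Phages bound to the matrix per round.
#' @param rounds Number of biopanning rounds.
#' @param washes Wash count (not modeled explicitly; absorbed into the
#'   background release probability, kept as metadata).
#' @param clones_picked Plaques picked after the last round.
#' @param clones_sequenced Clones successfully sequenced
#'   (<= `clones_picked`).
#' @return Object of class `panning_params`.
#' @export
panning_params <- function(n0 = 1e5, bound = 1e5, rounds = 5, washes = 10,
                           clones_picked = 120, clones_sequenced = 96) {
  vals <- c(n0 = n0, bound = bound, rounds = rounds, washes = washes,
            clones_picked = clones_picked, clones_sequenced = clones_sequenced)
  if (any(vals <= 0)) abort("All panning parameters must be positive.")
  if (clones_sequenced > clones_picked) {
    abort("`clones_sequenced` must be <= `clones_picked`.",
          class = "phagespec_validation_error")
  }
  structure(as.list(vals), class = "panning_params")
}

#' Generate a naive phage library
#'
#' Draws `n0` i.i.d. nonamers from `residue_probs` (default uniform over
#' the 20 standard residues) and merges duplicates.
#'
#' @param n0 Number of clone draws.
#' @param residue_probs Length-20 residue distribution (must sum to 1).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A phage pool: tibble with columns `nonamer`, `abundance`, and
#'   attributes `round = 0` and `total`.
#' @export
generate_library <- function(n0, residue_probs = uniform_background(),
                             seed = NULL) {
  if (n0 < 1) abort("`n0` must be >= 1.")
  residue_probs <- validate_background(residue_probs)
  if (!is.null(seed)) withr::local_seed(seed)
  pool <- tibble(nonamer = random_nonamers(as.integer(n0), residue_probs)) |>
    dplyr::count(.data$nonamer, name = "abundance") |>
    dplyr::arrange(.data$nonamer)
  new_phage_pool(pool, round = 0L)
}

new_phage_pool <- function(df, round) {
  structure(as_tibble(df), round = as.integer(round),
            total = sum(df$abundance),
            class = c("phage_pool", class(as_tibble(df))))
}

#' @export
print.phage_pool <- function(x, ...) {
  cat(sprintf("<phage_pool> round %d: %d clones, %s phages\n",
              attr(x, "round"), nrow(x),
              format(attr(x, "total"), big.mark = ",")))
  NextMethod()
}

#' Per-clone release probability
#'
#' `p = p_bg + (1 - p_bg) * logistic(beta * dose * (s_max - s0))` with
#' `s_max` from [max_window_score()]. At `beta = 0` selection is flat:
#' every clone has `p = p_bg + (1 - p_bg) / 2`.
#'
#' @param nonamers Character vector of nonamers (or a phage pool, whose
#'   `nonamer` column is used).
#' @param truth A [ground_truth] model.
#' @return Numeric vector of probabilities in `[p_bg, 1]`.
#' @export
release_probability <- function(nonamers, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.data.frame(nonamers)) nonamers <- nonamers$nonamer
  s <- max_window_score(nonamers, truth$pwm)
  truth$p_bg + (1 - truth$p_bg) *
    stats::plogis(truth$beta * truth$dose * (s - truth$s0))
}

#' Simulate one biopanning round
#'
#' Binds `min(bound, total)` phages by sampling without replacement from
#' the pool (multivariate hypergeometric; every phage binds when the pool
#' fits on the matrix), releases each bound phage independently with its
#' release probability (`p = p_bg` in the control arm), and amplifies the
#' released clones back to `bound` phages by multinomial resampling.
#' Within a round, `released_i <= bound_i <= abundance_i` for every
#' clone.
#'
#' @param pool A phage pool tibble (`nonamer`, `abundance`).
#' @param truth A [ground_truth].
#' @param params A [panning_params].
#' @param control If `TRUE`, release is background-only (`p = p_bg`).
#' @return List with `released` (pool of released clones),
#'   `released_count`, `bound_count`, `amplified` (next-round pool), and
#'   `status` (`"ok"` or `"extinct"` when nothing was released).
#' @export
simulate_round <- function(pool, truth, params, control = FALSE) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "panning_params"))
  if (nrow(pool) == 0 || sum(pool$abundance) == 0) {
    abort("Cannot pan an empty pool.")
  }
  total <- sum(pool$abundance)
  n_bind <- min(params$bound, total)
  bound <- if (n_bind >= total) pool$abundance else
    rmvhyper(n_bind, pool$abundance)
  p <- if (control) rep(truth$p_bg, nrow(pool)) else
    release_probability(pool$nonamer, truth)
  released <- rbinom(nrow(pool), bound, p)
  released_count <- sum(released)
  round_next <- attr(pool, "round") %||% 0L
  if (released_count == 0) {
    empty <- new_phage_pool(tibble(nonamer = character(),
                                   abundance = integer()),
                            round = round_next + 1L)
    return(list(released = empty, released_count = 0L,
                bound_count = n_bind, amplified = empty,
                status = "extinct"))
  }
  keep <- released > 0
  released_pool <- new_phage_pool(
    tibble(nonamer = pool$nonamer[keep], abundance = released[keep]),
    round = round_next + 1L
  )
  amp <- as.vector(rmultinom(1, params$bound, prob = released[keep]))
  keep_amp <- amp > 0
  amplified <- new_phage_pool(
    tibble(nonamer = pool$nonamer[keep][keep_amp], abundance = amp[keep_amp]),
    round = round_next + 1L
  )
  list(released = released_pool, released_count = released_count,
       bound_count = n_bind, amplified = amplified, status = "ok")
}

# k draws without replacement from categories with counts n
# (multivariate hypergeometric, sequential conditional sampling).
rmvhyper <- function(k, n) {
  out <- integer(length(n))
  rem <- sum(n)
  for (i in seq_along(n)) {
    if (k == 0) break
    x <- stats::rhyper(1, n[i], rem - n[i], k)
    out[i] <- x
    k <- k - x
    rem <- rem - n[i]
  }
  out
}

#' Run a full multi-round biopanning selection
#'
#' Simulates a protease arm and a control arm from the same naive
#' library, records per-round released counts and enrichment factors
#' (protease released / control released), and samples sequenced clones
#' from the final released pool.
#'
#' The control arm models the PBS mock selection: release is
#' background-only (`control = "background"`). `control = "shared"`
#' instead runs the control arm under the same release model as the
#' protease arm; the enrichment ratio then has expectation ~1 regardless
#' of the model, which is the configuration used to calibrate the
#' enrichment estimator (e.g. under a `beta = 0` null).
#'
#' @param params A [panning_params].
#' @param truth A [ground_truth].
#' @param seed Optional integer seed.
#' @param control `"background"` (PBS mock) or `"shared"` (same release
#'   model in both arms).
#' @param keep_pools Keep all per-round amplified pools (memory-heavy for
#'   large runs).
#' @return Object of class `biopanning`: list with `rounds` (tibble:
#'   round, bound, released_protease, released_control, enrichment),
#'   `final_pool` (released pool of the last round), `sequenced` (tibble
#'   nonamer/count summing to `clones_sequenced`), `pools` (optional),
#'   `params`, `truth`, `seed`, `status`. A control arm releasing zero
#'   phages yields an `Inf` enrichment sentinel with a warning.
#' @export
run_biopanning <- function(params, truth, seed = NULL,
                           control = c("background", "shared"),
                           keep_pools = FALSE) {
  control <- match.arg(control)
  stopifnot(inherits(params, "panning_params"), inherits(truth, "ground_truth"))
  if (!is.null(seed)) withr::local_seed(seed)

  naive <- generate_library(params$n0)
  pool_p <- naive
  pool_c <- naive
  rounds <- vector("list", params$rounds)
  pools <- if (keep_pools) vector("list", params$rounds) else NULL
  final_released <- NULL
  status <- "ok"

  for (r in seq_len(params$rounds)) {
    res_p <- simulate_round(pool_p, truth, params, control = FALSE)
    res_c <- simulate_round(pool_c, truth, params,
                            control = (control == "background"))
    if (res_c$released_count == 0) {
      warn(sprintf("Control arm released zero phages in round %d; enrichment reported as Inf.", r))
    }
    enrich <- if (res_c$released_count == 0) Inf else
      res_p$released_count / res_c$released_count
    rounds[[r]] <- tibble(
      round = r, bound = res_p$bound_count,
      released_protease = res_p$released_count,
      released_control = res_c$released_count,
      enrichment = enrich
    )
    if (res_p$status == "extinct") {
      status <- sprintf("extinct_round_%d", r)
      warn(sprintf("Protease arm released zero phages in round %d; selection halted.", r))
      rounds <- rounds[seq_len(r)]
      break
    }
    final_released <- res_p$released
    pool_p <- res_p$amplified
    pool_c <- if (res_c$status == "extinct") pool_c else res_c$amplified
    if (keep_pools) pools[[r]] <- pool_p
  }

  sequenced <- NULL
  if (!is.null(final_released) && nrow(final_released) > 0) {
    picked <- sample(final_released$nonamer, size = params$clones_picked,
                     replace = TRUE, prob = final_released$abundance)
    seqd <- picked[seq_len(params$clones_sequenced)]
    sequenced <- tibble(nonamer = seqd) |>
      dplyr::count(.data$nonamer, name = "count") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$nonamer)
  }

  structure(
    list(rounds = dplyr::bind_rows(rounds), final_pool = final_released,
         sequenced = sequenced, pools = pools, params = params,
         truth = truth, seed = seed, control = control, status = status),
    class = "biopanning"
  )
}

#' @export
print.biopanning <- function(x, ...) {
  cat(sprintf("<biopanning> %d round(s), status: %s\n",
              nrow(x$rounds), x$status))
  print(x$rounds)
  if (!is.null(x$sequenced)) {
    cat(sprintf("sequenced: %d clones (%d unique)\n",
                sum(x$sequenced$count), nrow(x$sequenced)))
  }
  invisible(x)
}

#' Tidy per-round biopanning results
#'
#' @param x A `biopanning` object.
#' @param ... Unused.
#' @return The per-round tibble (round, bound, released counts,
#'   enrichment).
#' @exportS3Method generics::tidy
tidy.biopanning <- function(x, ...) x$rounds

#' One-row biopanning summary
#'
#' @param x A `biopanning` object.
#' @param ... Unused.
#' @return Tibble with rounds run, final enrichment, sequenced clone
#'   counts and run status.
#' @exportS3Method generics::glance
glance.biopanning <- function(x, ...) {
  tibble(
    rounds = nrow(x$rounds),
    final_enrichment = x$rounds$enrichment[nrow(x$rounds)],
    sequenced_clones = if (is.null(x$sequenced)) 0L else sum(x$sequenced$count),
    unique_sequenced = if (is.null(x$sequenced)) 0L else nrow(x$sequenced),
    status = x$status
  )
}

#' Enrichment trajectory plot
#'
#' @param object A `biopanning` object.
#' @param ... Unused.
#' @return A ggplot of enrichment factor by round (log scale).
#' @exportS3Method ggplot2::autoplot
autoplot.biopanning <- function(object, ...) {
  ggplot2::ggplot(object$rounds,
                  ggplot2::aes(x = .data$round, y = .data$enrichment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "biopanning round",
                  y = "enrichment (protease / control released)") +
    ggplot2::theme_minimal()
}

#' Write biopanning outputs to disk
#'
#' `write_pool_tsv()` writes a clone table (sequence, abundance, round);
#' `write_sequenced_fasta()` writes the sequenced sample as FASTA with
#' duplicate counts in headers (`>clone_001|n=3`); `write_run_json()`
#' writes run metadata (seed, parameters, per-round counts).
#'
#' @param pool,run,sequenced Objects from the simulator.
#' @param path Output file path.
#' @return The input, invisibly.
#' @name biopanning_io
NULL

#' @rdname biopanning_io
#' @export
write_pool_tsv <- function(pool, path) {
  df <- as_tibble(pool)
  df$round <- attr(pool, "round") %||% NA_integer_
  readr::write_tsv(df, path)
  invisible(pool)
}

#' @rdname biopanning_io
#' @export
write_sequenced_fasta <- function(sequenced, path) {
  ids <- sprintf("clone_%03d|n=%d", seq_len(nrow(sequenced)), sequenced$count)
  set <- Biostrings::AAStringSet(setNames(sequenced$nonamer, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(sequenced)
}

#' @rdname biopanning_io
#' @export
write_run_json <- function(run, path) {
  stopifnot(inherits(run, "biopanning"))
  obj <- list(
    seed = run$seed, control = run$control, status = run$status,
    params = unclass(run$params),
    truth = list(p_bg = run$truth$p_bg, beta = run$truth$beta,
                 s0 = run$truth$s0, dose = run$truth$dose),
    rounds = run$rounds
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(run)
}
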