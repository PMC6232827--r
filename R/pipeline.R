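# End-to-end pipeline: simulate -> align -> build matrix -> design / scan,
# with provenance-stamped artifacts.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML/JSON file path) with
#' fields:
#' * `seed` (integer, required) — used for every stochastic stage and
#'   recorded in all outputs.
#' * `enzyme` — `"hNE"`, `"hPR3"` or `"xPR3"` (preset resolving to a
#'   [primary_specificity] and a ground-truth matrix), default `"hNE"`.
#' * `scale` — `"scaled"` (default; library and bound size 1e5) or
#'   `"protocol"` (5e7 / 1e9, the full wet-lab scale; memory- and
#'   time-hungry).
#' * `panning` — optional overrides for [panning_params()].
#' * `pfm` — optional list: `alpha` (default 1), `context`
#'   (`"mask"`/`"fill"`).
#' * `design` — optional list with `inserts` (character vector) to run
#'   cleavage prediction on.
#' * `scan` — optional list with `fasta` (path) and `threshold`.
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return Validated config list of class `run_config` (with defaults
#'   filled in). Invalid configurations abort with a
#'   `phagespec_validation_error` before any computation.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a file path.")
  if (is.null(config$seed)) {
    abort("`seed` is required in the configuration.",
          class = "phagespec_validation_error")
  }
  config$seed <- as.integer(config$seed)
  config$enzyme <- config$enzyme %||% "hNE"
  if (!config$enzyme %in% c("hNE", "hPR3", "xPR3")) {
    abort(sprintf("Unknown enzyme preset '%s'.", config$enzyme),
          class = "phagespec_validation_error")
  }
  config$scale <- config$scale %||% "scaled"
  base <- if (identical(config$scale, "protocol")) {
    list(n0 = 5e7, bound = 1e9)
  } else {
    list(n0 = 1e5, bound = 1e5)
  }
  pan <- utils::modifyList(
    c(base, list(rounds = 5, washes = 10, clones_picked = 120,
                 clones_sequenced = 96)),
    config$panning %||% list()
  )
  # validation (incl. clones_sequenced <= clones_picked) happens here,
  # before any simulation work
  config$panning <- tryCatch(do.call(panning_params, pan),
                             error = function(e) {
                               abort(conditionMessage(e),
                                     class = "phagespec_validation_error")
                             })
  config$pfm <- utils::modifyList(list(alpha = 1, context = "mask"),
                                  config$pfm %||% list())
  config$schema_version <- "1"
  structure(config, class = "run_config")
}

#' Run the full specificity-profiling pipeline
#'
#' Executes simulate -> align -> build-matrix, plus substrate design
#' and/or FASTA scanning when configured, writing all artifacts to
#' `out_dir`. Every output carries provenance (config hash, seed,
#' package version); the run is deterministic given the configuration,
#' so repeated runs produce byte-identical tables. Stage failures abort
#' with the stage name; artifacts already written are left in place.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("# phagespec %s | seed=%d | config=%s",
                  as.character(utils::packageVersion("phagespec")),
                  config$seed, rlang::hash(unclass(config)))
  artifacts <- list()
  out <- function(name) file.path(out_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  anchors <- primary_specificity(config$enzyme)
  truth <- ground_truth(elastase_truth_matrix(config$enzyme))

  run <- stage("simulate", {
    r <- run_biopanning(config$panning, truth, seed = config$seed)
    inform(sprintf("simulate: %d round(s), %d sequenced clone(s), final enrichment %.1f",
                   nrow(r$rounds),
                   if (is.null(r$sequenced)) 0L else sum(r$sequenced$count),
                   r$rounds$enrichment[nrow(r$rounds)]))
    write_tsv_prov(r$rounds, out("rounds.tsv"), prov)
    artifacts$rounds <- out("rounds.tsv")
    if (!is.null(r$sequenced)) {
      write_sequenced_fasta(r$sequenced, out("sequenced.fasta"))
      artifacts$sequenced <- out("sequenced.fasta")
    }
    r
  })

  block <- stage("align", {
    if (is.null(run$sequenced)) abort("no sequenced clones to align")
    b <- align_nonamers(
      dplyr::rename(run$sequenced, peptide = "nonamer"),
      params = align_params(anchors = anchors)
    )
    inform(sprintf("align: %d peptide(s) placed, %d discarded, objective %.1f",
                   nrow(b), nrow(attr(b, "discarded")),
                   attr(b, "objective")))
    rep <- consensus_report(b)
    write_tsv_prov(rep$peptides, out("aligned_block.tsv"), prov)
    write_tsv_prov(attr(b, "discarded"), out("discards.tsv"), prov)
    write_tsv_prov(rep$consensus, out("consensus.tsv"), prov)
    artifacts$aligned_block <- out("aligned_block.tsv")
    artifacts$discards <- out("discards.tsv")
    artifacts$consensus <- out("consensus.tsv")
    b
  })

  pfm <- stage("build-pssm", {
    m <- build_pfm(block, alpha = config$pfm$alpha,
                   context = config$pfm$context)
    inform(sprintf("build-pssm: total IC %.2f bits",
                   sum(information_content(m))))
    writeLines(prov, out("pfm.tsv"))
    df <- as.data.frame(round(m$freq, 6))
    df <- cbind(subsite = rownames(m$freq), df)
    readr::write_tsv(as_tibble(df), out("pfm.tsv"), append = TRUE,
                     col_names = TRUE)
    write_pfm_json(m, out("pfm.json"),
                   meta = list(provenance = prov, seed = config$seed,
                               enzyme = config$enzyme))
    write_tsv_prov(export_logo_data(m), out("logo_data.tsv"), prov)
    artifacts$pfm_tsv <- out("pfm.tsv")
    artifacts$pfm_json <- out("pfm.json")
    artifacts$logo_data <- out("logo_data.tsv")
    m
  })

  if (!is.null(config$design$inserts)) {
    stage("design-substrate", {
      preds <- purrr::map(config$design$inserts, function(ins) {
        cons <- build_construct(ins)
        p <- predict_cleavage(cons, pfm, anchors = anchors)
        dplyr::mutate(as_tibble(p), insert = ins,
                      construct_kda = construct_mass(cons),
                      .before = 1)
      }) |> dplyr::bind_rows()
      inform(sprintf("design-substrate: %d insert(s), %d predicted site(s)",
                     length(config$design$inserts), nrow(preds)))
      write_tsv_prov(preds, out("predictions.tsv"), prov)
      artifacts$predictions <- out("predictions.tsv")
    })
  }

  if (!is.null(config$scan$fasta)) {
    stage("scan", {
      res <- scan_fasta(config$scan$fasta, pfm,
                        threshold = config$scan$threshold)
      inform(sprintf("scan: %d record(s), %d hit(s)",
                     res$summary$records, nrow(res$hits)))
      write_tsv_prov(res$hits, out("scan_hits.tsv"), prov)
      jsonlite::write_json(c(as.list(res$summary), list(provenance = prov)),
                           out("scan_summary.json"), auto_unbox = TRUE,
                           digits = NA)
      artifacts$scan_hits <- out("scan_hits.tsv")
      artifacts$scan_summary <- out("scan_summary.json")
    })
  }

  meta <- list(
    tool = "phagespec",
    version = as.character(utils::packageVersion("phagespec")),
    schema_version = config$schema_version,
    seed = config$seed,
    enzyme = config$enzyme,
    config_hash = rlang::hash(unclass(config)),
    panning = unclass(config$panning),
    rounds = run$rounds,
    status = run$status
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  artifacts$run_meta <- file.path(out_dir, "run_meta.json")
  invisible(artifacts)
}

write_tsv_prov <- function(df, path, prov) {
  writeLines(prov, path)
  readr::write_tsv(as_tibble(df), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
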