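test_that("library generation is reproducible and respects edge cases", {
  one <- generate_library(1, seed = 4)
  expect_equal(nrow(one), 1)
  expect_equal(one$abundance, 1L)
  expect_equal(nchar(one$nonamer), 9)

  a <- generate_library(5000, seed = 99)
  b <- generate_library(5000, seed = 99)
  expect_identical(a, b)

  bad <- setNames(rep(0.1, 20), aa_alphabet())
  expect_error(generate_library(10, residue_probs = bad))
})

test_that("naive library residue frequencies match the sampling law", {
  pool <- generate_library(1e4, seed = 21)
  n <- sum(pool$abundance)
  chars <- strsplit(pool$nonamer, "")
  counts <- table(factor(unlist(chars), levels = aa_alphabet()))
  freq <- as.numeric(counts) / (9 * n)
  se <- sqrt(0.05 * 0.95 / (9 * n))
  # Bonferroni-style bound across the 20 residues
  expect_true(all(abs(freq - 0.05) < 4 * se))
})

test_that("release probability matches its closed forms", {
  pwm <- position_matrix(matrix(1 / 20, 9, 20))  # all windows score 0

  flat <- ground_truth(pwm, p_bg = 0.01, beta = 0, s0 = 3)
  p <- release_probability("ACDEFGHIK", flat)
  expect_equal(p, 0.01 + 0.99 * 0.5, tolerance = 1e-12)

  gt <- ground_truth(pwm, p_bg = 0.02, beta = 1, s0 = 2)
  # s_max = 0 for every clone; hand-evaluated logistic
  expect_equal(release_probability("ACDEFGHIK", gt),
               0.02 + 0.98 / (1 + exp(2)), tolerance = 1e-12)

  # far-below-threshold scores approach the background asymptote
  deep <- ground_truth(pwm, p_bg = 1e-3, beta = 2, s0 = 50)
  expect_equal(release_probability("ACDEFGHIK", deep), 1e-3,
               tolerance = 1e-9)
})

test_that("release probabilities stay within [p_bg, 1]", {
  gt <- ground_truth(elastase_truth_matrix("hNE"))
  withr::local_seed(8)
  pool <- generate_library(2000)
  p <- release_probability(pool, gt)
  expect_true(all(p >= gt$p_bg & p <= 1))
})

test_that("a control round with zero background releases nothing", {
  gt <- ground_truth(elastase_truth_matrix("hNE"), p_bg = 0)
  pool <- generate_library(500, seed = 2)
  withr::local_seed(5)
  res <- simulate_round(pool, gt, panning_params(n0 = 500, bound = 500),
                        control = TRUE)
  expect_equal(res$released_count, 0L)
  expect_equal(res$status, "extinct")
})

test_that("a certain-release clone is released in full", {
  pwm <- position_matrix(matrix(1 / 20, 9, 20))
  gt <- ground_truth(pwm, p_bg = 0, beta = 1, s0 = -60)  # p ~ 1
  pool <- generate_library(100, seed = 3)
  withr::local_seed(6)
  res <- simulate_round(pool, gt, panning_params(n0 = 100, bound = 100))
  expect_equal(res$released_count, sum(res$released$abundance))
  expect_equal(res$released_count, res$bound_count)
})

test_that("per-clone counts conserve abundance within a round", {
  gt <- ground_truth(elastase_truth_matrix("hNE"), beta = 1, s0 = 2)
  pool <- generate_library(3000, seed = 13)
  params <- panning_params(n0 = 3000, bound = 1000)  # forces subsampling
  withr::local_seed(14)
  res <- simulate_round(pool, gt, params)
  expect_lte(res$bound_count, sum(pool$abundance))
  joined <- dplyr::left_join(as.data.frame(res$released),
                             as.data.frame(pool),
                             by = "nonamer", suffix = c("_rel", "_pool"))
  expect_true(all(joined$abundance_rel <= joined$abundance_pool))
})

test_that("biopanning runs are deterministic under a fixed seed", {
  gt <- ground_truth(elastase_truth_matrix("hNE"))
  params <- panning_params(n0 = 5000, bound = 5000, rounds = 3,
                           clones_picked = 30, clones_sequenced = 24)
  r1 <- run_biopanning(params, gt, seed = 7)
  r2 <- run_biopanning(params, gt, seed = 7)
  expect_identical(r1$rounds, r2$rounds)
  expect_identical(r1$sequenced, r2$sequenced)
  expect_identical(as.data.frame(r1$final_pool), as.data.frame(r2$final_pool))
})

test_that("enrichment is the released-count ratio and Inf when control dies", {
  gt <- ground_truth(elastase_truth_matrix("hNE"))
  params <- panning_params(n0 = 5000, bound = 5000, rounds = 2,
                           clones_picked = 10, clones_sequenced = 10)
  run <- run_biopanning(params, gt, seed = 31)
  expect_equal(run$rounds$enrichment,
               run$rounds$released_protease / run$rounds$released_control)

  gt0 <- ground_truth(elastase_truth_matrix("hNE"), p_bg = 0)
  expect_warning(
    run0 <- run_biopanning(panning_params(n0 = 2000, bound = 2000, rounds = 1,
                                          clones_picked = 5,
                                          clones_sequenced = 5),
                           gt0, seed = 8),
    "Inf"
  )
  expect_true(is.infinite(run0$rounds$enrichment[1]))
})

test_that("a planted strong-motif clone gains pool share round over round", {
  pwm <- elastase_truth_matrix("hNE")
  cons <- paste(aa_alphabet()[apply(pwm$freq, 1, which.max)], collapse = "")
  # strong effect size, with the half-max score well inside the library's
  # range so the planted consensus clone releases near-certainly
  gt <- ground_truth(pwm, beta = 1, s0 = 5)
  params <- panning_params(n0 = 2000, bound = 2000, rounds = 3,
                           clones_picked = 10, clones_sequenced = 10)
  shares <- matrix(NA_real_, nrow = 20, ncol = 4)
  for (rep in 1:20) {
    withr::local_seed(1000 + rep)
    pool <- generate_library(1980)
    pool <- new_pool_with_plant(pool, cons, 20L)  # ~1% planted
    shares[rep, 1] <- 20 / sum(pool$abundance)
    for (r in 1:3) {
      res <- simulate_round(pool, gt, params)
      pool <- res$amplified
      sh <- pool$abundance[pool$nonamer == cons]
      shares[rep, r + 1] <- ifelse(length(sh) == 0, 0,
                                   sh / sum(pool$abundance))
    }
  }
  mean_shares <- colMeans(shares)
  expect_true(all(diff(mean_shares) > 0))
})

test_that("sequenced samples respect the picked/sequenced contract", {
  gt <- ground_truth(elastase_truth_matrix("hNE"))
  params <- panning_params(n0 = 5000, bound = 5000, rounds = 3,
                           clones_picked = 40, clones_sequenced = 32)
  run <- run_biopanning(params, gt, seed = 77)
  expect_equal(sum(run$sequenced$count), 32)
  expect_error(panning_params(clones_picked = 10, clones_sequenced = 20),
               class = "phagespec_validation_error")
})

test_that("biopanning tidiers summarize the run", {
  gt <- ground_truth(elastase_truth_matrix("hNE"))
  params <- panning_params(n0 = 3000, bound = 3000, rounds = 2,
                           clones_picked = 10, clones_sequenced = 10)
  run <- run_biopanning(params, gt, seed = 5)
  expect_identical(tidy(run), run$rounds)
  gl <- glance(run)
  expect_equal(gl$rounds, 2L)
  expect_equal(gl$sequenced_clones, 10L)
  expect_s3_class(autoplot(run), "ggplot")
})

test_that("biopanning artifacts round-trip to disk", {
  gt <- ground_truth(elastase_truth_matrix("hNE"))
  params <- panning_params(n0 = 3000, bound = 3000, rounds = 2,
                           clones_picked = 12, clones_sequenced = 12)
  run <- run_biopanning(params, gt, seed = 15)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_sequenced_fasta(run$sequenced, fa)
  back <- read_peptides(fa)
  expect_equal(sum(back$count), 12)
  expect_setequal(back$peptide, run$sequenced$nonamer)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pool_tsv(run$final_pool, tsv)
  df <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(sum(df$abundance), sum(run$final_pool$abundance))

  js <- withr::local_tempfile(fileext = ".json")
  write_run_json(run, js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$seed, 15)
  expect_equal(nrow(meta$rounds), 2)
})
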