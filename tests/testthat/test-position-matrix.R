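block_df <- function(peptides, counts = 1L, anchors) {
  tibble::tibble(peptide = peptides,
                 count = rep_len(counts, length(peptides)),
                 anchor = anchors)
}

test_that("unanimous and single-peptide blocks give unit columns at alpha 0", {
  blk <- block_df(c("GGGGVGGGG", "AAAAVAAAA"), anchors = c(5L, 5L))
  m <- build_pfm(blk, alpha = 0)
  expect_equal(unname(m$freq["P1", "V"]), 1)

  m1 <- build_pfm(block_df("CWHNQYKDE", anchors = 5L), alpha = 0)
  expect_true(all(apply(m1$freq, 1, max) == 1))  # every column a unit vector
})

test_that("pseudocount arithmetic matches the hand-computed table", {
  peps <- c("GGGGVSGGG", "AAAAVSAAA", "LLLLISLLL", "KKKKVTKKK")
  blk <- block_df(peps, anchors = rep(5L, 4))
  m <- build_pfm(blk, alpha = 1, background = uniform_background())
  # independent hand count: freq = (count + 1 * 1/20) / (4 + 1)
  for (j in 1:9) {
    for (a in aa_alphabet()) {
      cnt <- sum(vapply(peps, function(p) substr(p, j, j) == a, logical(1)))
      expect_equal(unname(m$freq[j, a]), (cnt + 0.05) / 5, tolerance = 1e-12)
    }
  }
})

test_that("rows normalize to 1 after construction and after collapse", {
  blk <- block_df(c("VLLVSEVLA", "GRGGVGGRG"), anchors = c(4L, 5L))
  for (alpha in c(0, 1, 5)) {
    m <- build_pfm(blk, alpha = alpha)
    expect_true(all(abs(rowSums(m$freq) - 1) < 1e-9))
    cc <- class_collapse(m)
    expect_true(all(abs(rowSums(cc) - 1) < 1e-9))
  }
})

test_that("empty blocks and negative pseudocounts are rejected", {
  expect_error(build_pfm(block_df(character(), anchors = integer())))
  expect_error(build_pfm(block_df("GGGGVGGGG", anchors = 5L), alpha = -1))
})

test_that("information content hits its closed-form values and bounds", {
  unit <- matrix(0, 9, 20); unit[, 1] <- 1
  expect_equal(unname(information_content(position_matrix(unit))),
               rep(log2(20), 9), tolerance = 1e-12)

  unif <- matrix(1 / 20, 9, 20)
  expect_equal(unname(information_content(position_matrix(unif))),
               rep(0, 9), tolerance = 1e-12)

  half <- matrix(0, 9, 20); half[, 1] <- 0.5; half[, 2] <- 0.5
  expect_equal(unname(information_content(position_matrix(half))),
               rep(log2(20) - 1, 9), tolerance = 1e-12)
})

test_that("increasing the pseudocount smooths the profile monotonically", {
  withr::local_seed(11)
  for (rep in 1:5) {
    peps <- replicate(6, paste(sample(aa_alphabet(), 9, TRUE), collapse = ""))
    blk <- block_df(peps, anchors = sample(3:7, 6, TRUE))
    ics <- vapply(c(0.5, 1, 2, 8),
                  function(a) sum(information_content(build_pfm(blk, alpha = a))),
                  numeric(1))
    expect_true(all(diff(ics) < 0))
    expect_true(all(ics >= 0 & ics <= 9 * log2(20)))
  }
})

test_that("class_collapse pools same-class residues and counts classes", {
  f <- matrix(1 / 20, 9, 20, dimnames = list(subsite_labels(), aa_alphabet()))
  f[1, ] <- 0; f[1, "V"] <- 0.6; f[1, "L"] <- 0.4
  m <- position_matrix(f)
  cc <- class_collapse(m)
  expect_equal(unname(cc["P5", "larger_aliphatic"]), 1)
  # uniform rows: class mass = class size / 20
  expect_equal(unname(cc["P1", ]),
               c(3, 2, 2, 2, 4, 7) / 20, tolerance = 1e-12)
})

test_that("window scores are additive log-odds with background giving zero", {
  bgm <- position_matrix(matrix(1 / 20, 9, 20))
  expect_equal(score_window(bgm, "ACDEFGHIK"), 0, tolerance = 1e-12)

  m <- elastase_truth_matrix("hNE")
  w <- "RLIAVSGEK"
  manual <- sum(vapply(1:9, function(j) m$logodds[j, substr(w, j, j)],
                       numeric(1)))
  expect_equal(score_window(m, w), manual, tolerance = 1e-12)

  # the per-column argmax consensus attains the maximal achievable score
  cons <- paste(aa_alphabet()[apply(m$freq, 1, which.max)], collapse = "")
  smax <- sum(apply(m$logodds, 1, max))
  expect_equal(score_window(m, cons), smax, tolerance = 1e-12)
  withr::local_seed(3)
  rand <- replicate(20, paste(sample(aa_alphabet(), 9, TRUE), collapse = ""))
  expect_true(all(score_window(m, rand) <= smax))
})

test_that("scores are invariant to common rescaling of copy counts", {
  blk <- block_df(c("VLLVSEVLA", "GRGGVGGRG", "LLIAVSGEK"),
                  counts = c(2L, 1L, 3L), anchors = c(4L, 5L, 5L))
  blk3 <- dplyr::mutate(blk, count = count * 5L)
  m1 <- build_pfm(blk, alpha = 0)
  m2 <- build_pfm(blk3, alpha = 0)
  expect_equal(m1$freq, m2$freq, tolerance = 1e-12)
  expect_equal(score_window(m1, "GRGGVGGRG"), score_window(m2, "GRGGVGGRG"))
})

test_that("score_window rejects wrong lengths and bad residues", {
  m <- elastase_truth_matrix("hNE")
  expect_error(score_window(m, "VLV"))
  expect_error(score_window(m, "VLLVSEVLX"),
               class = "phagespec_alphabet_error")
})

test_that("context fill uses capsid residues, mask drops them", {
  # anchor at position 2: P5..P3 reach into the PGG prefix
  blk <- block_df("VLLVSEVLA", anchors = 2L)
  filled <- build_pfm(blk, alpha = 0, context = "fill")
  # P4 and P3 come from the GG of the PGG prefix
  expect_equal(unname(filled$freq["P4", "G"]), 1)
  expect_equal(unname(filled$freq["P3", "G"]), 1)
  masked <- build_pfm(blk, alpha = 1, context = "mask")
  # masked cells contribute nothing: P4 is pure pseudocount (uniform)
  expect_equal(unname(masked$freq["P4", ]), rep(1 / 20, 20),
               tolerance = 1e-12)
})

test_that("position matrices round-trip through TSV and JSON", {
  m <- build_pfm(block_df(c("VLLVSEVLA", "GRGGVGGRG"), anchors = c(4L, 5L)),
                 alpha = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pfm_tsv(m, tsv)
  m2 <- read_pfm_tsv(tsv, alpha = 1)
  expect_equal(m2$freq, m$freq, tolerance = 1e-5)

  js <- withr::local_tempfile(fileext = ".json")
  write_pfm_json(m, js, meta = list(note = "round-trip"))
  m3 <- read_pfm_json(js)
  expect_equal(m3$freq, m$freq, tolerance = 1e-12)
  expect_equal(m3$alpha, m$alpha)
})

test_that("logo heights are freq x IC and sum to the column IC", {
  unit <- matrix(0, 9, 20); unit[, 5] <- 1
  lg <- export_logo_data(position_matrix(unit))
  expect_equal(max(lg$height_bits), log2(20), tolerance = 1e-12)

  unif <- export_logo_data(position_matrix(matrix(1 / 20, 9, 20)))
  expect_true(all(abs(unif$height_bits) < 1e-12))

  m <- elastase_truth_matrix("hNE")
  lg2 <- export_logo_data(m)
  sums <- tapply(lg2$height_bits, lg2$subsite, sum)
  expect_equal(as.numeric(sums[subsite_labels()]),
               unname(information_content(m)), tolerance = 1e-9)
})

test_that("tidy and glance expose the matrix as tibbles", {
  m <- elastase_truth_matrix("hNE")
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 180)
  expect_equal(td$freq[td$subsite == "P1" & td$residue == "V"], 0.55)
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(substr(gl$consensus, 5, 6), "VS")  # P1 Val, P1' Ser
  expect_s3_class(autoplot(m), "ggplot")
})
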