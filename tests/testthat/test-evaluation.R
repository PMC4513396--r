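test_that("overlap is exact interval intersection", {
  a <- regions("s", 0, 10)
  b <- regions("s", 5, 20)
  expect_equal(overlap_bp(a, b), 5)
  expect_equal(overlap_bp(a, a), 10)
  expect_equal(overlap_bp(a, regions("s", 50, 60)), 0)
  expect_equal(overlap_bp(a, regions("q", 0, 10)), 0)  # different sequence
  expect_equal(overlap_bp(regions(), a), 0)
  # self-overlapping inputs are merged first
  expect_equal(overlap_bp(regions(c("s", "s"), c(0, 5), c(10, 15)), b), 10)
})

test_that("sweep overlap agrees with the per-base bitmap oracle", {
  set.seed(19)
  for (rep in 1:5) {
    mk <- function() {
      s <- sort(sample(0:990, 30))
      regions(sample(c("a", "b"), 30, replace = TRUE), s,
              s + sample(1:60, 30, replace = TRUE))
    }
    a <- mk(); b <- mk()
    lens <- c(a = 1100L, b = 1100L)
    expect_equal(overlap_bp(a, b),
                 oracle_overlap_bp(a, b, c("a", "b"), lens))
    # SN/SP built from the same primitive agree with the bitmap route
    expect_equal(sensitivity(a, b),
                 100 * oracle_overlap_bp(a, b, c("a", "b"), lens) /
                   sum(vapply(oracle_bitmap(b, c("a", "b"), lens), sum, 0)))
  }
})

test_that("sensitivity is 100*O/R with class filtering and NA when undefined", {
  truth <- regions(c("s", "s", "s"), c(0, 100, 200), c(50, 150, 260),
                   class = c("te", "tr", "te"))
  expect_equal(sensitivity(truth, truth), 100)
  expect_equal(sensitivity(regions("s", 0, 25), truth, "te"),
               100 * 25 / 110)
  expect_equal(sensitivity(regions("s", 300, 400), truth), 0)
  expect_true(is.na(sensitivity(regions("s", 0, 50), truth, "low")))
  # half-covering predictions
  pred <- regions(c("s", "s", "s"), c(0, 100, 200), c(25, 125, 230))
  expect_equal(sensitivity(pred, truth), 50)
})

test_that("exon specificity and percentage predicted follow definitions", {
  exons <- regions("s", c(0, 100), c(40, 140))
  expect_equal(specificity_exon(regions("s", 500, 600), exons), 100)
  expect_equal(specificity_exon(regions("s", 0, 200), exons), 0)
  expect_equal(specificity_exon(regions("s", 0, 20), exons), 75)  # O = E/4
  expect_true(is.na(specificity_exon(regions("s", 0, 10), regions())))
  g <- c(s = strrep("ACGT", 250))
  expect_equal(percentage_predicted(regions("s", 0, 1000), g), 100)
  expect_equal(percentage_predicted(regions(), g), 0)
  expect_equal(percentage_predicted(regions("s", 0, 250), g), 25)
  # only valid bases count in the denominator
  gn <- c(s = paste0(strrep("ACGT", 100), strrep("N", 600)))
  expect_equal(percentage_predicted(regions("s", 0, 100), gn), 25)
})

test_that("random genomes preserve length, composition and determinism", {
  gA <- c(s = strrep("A", 300))
  expect_identical(random_genome(gA, 3, seed = 5), gA)
  set.seed(23)
  g <- c(s = random_text(200000))
  r1 <- random_genome(g, 6, seed = 9)
  r2 <- random_genome(g, 6, seed = 9)
  expect_identical(r1, r2)  # byte-reproducible
  expect_false(identical(r1, random_genome(g, 6, seed = 10)))
  expect_equal(nchar(r1[[1]]), nchar(g[[1]]))
  # mono- and di-nucleotide composition within 3 sigma of multinomial
  n <- nchar(g[[1]])
  p1 <- base_freqs(g[[1]])
  z1 <- (base_freqs(r1[[1]]) - p1) / sqrt(p1 * (1 - p1) / n)
  expect_true(all(abs(z1) < 3))
  p2 <- dinuc_freqs(g[[1]])
  z2 <- (dinuc_freqs(r1[[1]]) - p2) / sqrt(p2 * (1 - p2) / (n - 1))
  expect_true(all(abs(z2) < 3))
})

test_that("FPL and PR follow their subtraction definitions", {
  pred <- regions("s", c(0, 100), c(50, 160))
  expect_equal(false_positive_length(regions()), 0)
  expect_equal(false_positive_length(pred), 110)
  expect_equal(false_positive_length(pred, truth_filter = pred), 0)
  expect_equal(false_positive_length(pred, regions("s", 0, 25)), 85)
  truth <- regions("s", 50, 100)
  expect_equal(potential_repeats(regions("s", 60, 90), truth), 0)
  expect_equal(potential_repeats(pred, regions()), 110)
  expect_equal(potential_repeats(regions("s", 0, 100), truth), 50)
  # identity: PR = predicted - O, O <= min(predicted, R)
  set.seed(29)
  for (rep in 1:5) {
    s <- sort(sample(0:900, 20)); a <- regions("x", s, s + 30)
    s2 <- sort(sample(0:900, 20)); b <- regions("x", s2, s2 + 30)
    O <- overlap_bp(a, b)
    expect_equal(potential_repeats(a, b),
                 sum(repdetect:::merge_regions(a)$end -
                       repdetect:::merge_regions(a)$start) - O)
    expect_lte(O, min(sum(repdetect:::merge_regions(a)$end -
                            repdetect:::merge_regions(a)$start),
                      sum(repdetect:::merge_regions(b)$end -
                            repdetect:::merge_regions(b)$start)))
  }
})

test_that("the report row carries all nine benchmark columns", {
  truth <- regions(c("s", "s"), c(0, 200), c(100, 260),
                   class = c("te", "tr"))
  exons <- regions("s", 400, 500)
  g <- c(s = strrep("ACGT", 250))
  pred <- regions("s", c(0, 200), c(100, 230))
  rep_tab <- evaluation_report(pred, truth, exons, g, fpl = 12)
  expect_identical(names(rep_tab),
                   c("SN_te", "SN_tr", "SN_low", "SN_other", "SN_all",
                     "SP_exon", "PP", "FPL", "PR"))
  expect_equal(rep_tab$SN_te, 100)
  expect_equal(rep_tab$SN_tr, 50)
  expect_true(is.na(rep_tab$SN_low))
  expect_equal(rep_tab$SN_all, 100 * 130 / 160)
  expect_equal(rep_tab$SP_exon, 100)
  expect_equal(rep_tab$PP, 13)
  expect_equal(rep_tab$FPL, 12)
  expect_equal(rep_tab$PR, 0)
})
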