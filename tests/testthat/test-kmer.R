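test_that("quaternary encoding matches the positional formula", {
  expect_identical(encode_kmer("AAA"), 0)
  expect_identical(encode_kmer("TTT"), 63)
  expect_identical(encode_kmer("CGT"), 27)  # 1*16 + 2*4 + 3
  expect_identical(encode_kmer("acgt"), encode_kmer("ACGT"))
  expect_true(is.na(encode_kmer("ANT")))
})

test_that("rolling Horner indices agree with direct encoding and skip Ns", {
  expect_equal(rolling_indices("ACGT", 2), c(1, 6, 11))
  expect_equal(rolling_indices("ACNGT", 2), c(1, NA, NA, 11))
  expect_length(rolling_indices("AC", 5), 0)
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(2:12, 1)
    txt <- random_text(1000)
    expect_equal(rolling_indices(txt, k), oracle_window_indices(txt, k))
  }
  # with invalid bases interspersed
  txt <- paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                      prob = c(rep(0.24, 4), 0.04)), collapse = "")
  expect_equal(rolling_indices(txt, 6), oracle_window_indices(txt, 6))
})

test_that("k-mer counting conserves the number of valid windows", {
  tab <- count_kmers(c(s = "AAAA"), 2)
  expect_equal(tab$counts[encode_kmer("AA") + 1], 3)
  expect_equal(sum(tab$counts), 3)
  tab <- count_kmers(c(s = "ACGT"), 4)
  expect_equal(sum(tab$counts > 0), 1)
  expect_equal(max(tab$counts), 1)
  set.seed(7)
  txt <- paste(sample(c("A", "C", "G", "T", "N"), 10000, replace = TRUE,
                      prob = c(rep(0.245, 4), 0.02)), collapse = "")
  tab <- count_kmers(c(s = txt), 5)
  expect_equal(sum(tab$counts),
               sum(!is.na(oracle_window_indices(txt, 5))))
  # multi-record counting pools records
  two <- count_kmers(c(a = "AAAA", b = "AAA"), 2)
  expect_equal(two$counts[1], 5)
  expect_error(count_kmers(c(s = "ACGT"), 14), "capacity")
})

test_that("background chain is the ML conditional frequency estimate", {
  bg <- train_background(c(s = strrep("A", 50)), 2)
  expect_equal(bg$cond[encode_kmer("AAA") + 1], 1)
  bg0 <- train_background(c(s = "ACGTACGT"), 0)
  expect_equal(bg0$cond, rep(0.25, 4))
  bg1 <- train_background(c(s = "AAAC"), 1)
  expect_equal(bg1$cond[encode_kmer("AA") + 1], 2 / 3)
  expect_equal(bg1$cond[encode_kmer("AC") + 1], 1 / 3)
  # unseen contexts fall back to uniform; every context row sums to 1
  rows <- matrix(bg1$cond, nrow = 4)
  expect_equal(colSums(rows), rep(1, 4), tolerance = 1e-9)
  expect_error(train_background(c(s = "ACGT"), -1), "order")
})

test_that("expected counts equal the brute-force chain expectation", {
  # uniform order-0 composition: every 2-mer expects N/16
  g <- c(s = strrep("ACGT", 10))
  bg <- train_background(g, 0)
  n_win <- count_kmers(g, 2)$n_windows
  expect_equal(expected_count("AA", bg, n_windows = n_win), n_win / 16)
  expect_equal(expected_count("GT", bg, n_windows = n_win), n_win / 16)
  # degenerate chain: all-A word expects ~ every window; C/G/T words ~ 0
  gA <- c(s = strrep("A", 100))
  bgA <- train_background(gA, 1)
  expect_equal(expected_count("AAAA", bgA), bgA$total_positions)
  expect_equal(expected_count("ACAA", bgA), 0)
  # 200-bp fixture vs independent enumeration of the chain product
  set.seed(11)
  txt <- random_text(200)
  o <- 2L; k <- 5L
  bg2 <- train_background(c(s = txt), o)
  words <- substring(txt, 1:(200 - k + 1), k:200)
  words3 <- substring(txt, 1:(200 - o), (o + 1):200)  # (o+1)-windows
  ctx_occ <- substr(words3, 1, o)  # context occurrences, as trained
  ctx_freq <- function(cx) sum(ctx_occ == cx) / length(ctx_occ)
  cond_or <- function(cx, b) {
    num <- sum(words3 == paste0(cx, b))
    den <- sum(ctx_occ == cx)
    if (den == 0) 0.25 else num / den
  }
  for (w in sample(unique(words), 5)) {
    p <- ctx_freq(substr(w, 1, o))
    for (j in (o + 1):k) p <- p * cond_or(substr(w, j - o, j - 1), substr(w, j, j))
    expect_equal(expected_count(w, bg2, n_windows = 100), 100 * p,
                 tolerance = 1e-12)
  }
})

test_that("the adjustment rule is the three-clause definition", {
  # rare words are zeroed regardless of expectation
  expect_equal(adjusted_count(0, 0.1), 0)
  expect_equal(adjusted_count(1, 0.1), 0)
  expect_equal(adjusted_count(2, 0.1), 0)
  # at or below expectation -> 0; above -> observed - expected
  expect_equal(adjusted_count(3, 3.5), 0)
  expect_equal(adjusted_count(3, 3.0), 0)
  expect_equal(adjusted_count(5, 2.0), 3.0)
  # monotone in observed, bounded by observed, never negative
  obs <- 0:50
  for (e in c(0, 0.5, 3, 10)) {
    adj <- adjusted_count(obs, e)
    expect_true(all(diff(adj) >= 0))
    expect_true(all(adj >= 0 & adj <= obs))
  }
})

test_that("exact duplication is suppressed to an all-zero table", {
  set.seed(5)
  repeat {  # a text whose 8-mers are all distinct
    txt <- random_text(400)
    if (!anyDuplicated(oracle_window_indices(txt, 8))) break
  }
  g <- c(s = strrep(txt, 2))
  tab <- adjust_counts(count_kmers(g, 8), train_background(g, 2))
  expect_true(all(tab$values == 0))
})

test_that("an order-6 chain absorbs polyploid gene copies", {
  # short enough that 6-mer contexts are mostly unique within the gene
  set.seed(9)
  txt <- random_text(300)
  g <- c(s = strrep(txt, 4))  # tetraploid-like: every gene word 4 copies
  tab <- adjust_counts(count_kmers(g, 8), train_background(g, 6))
  hot <- tab$counts >= 3
  expect_lt(mean(tab$values[hot]), 0.2)
  # without background adjustment the same words would all score >= 1
  expect_gte(min(tab$counts[hot] - 2), 1)
})

test_that("scoring maps window adjusted counts onto positions", {
  tab <- count_kmers(c(s = "AAAAAA"), 3)
  tab$values <- numeric(64)
  tab$values[encode_kmer("AAA") + 1] <- 5  # fixed adjusted table
  expect_equal(score_sequence("AAAAAA", tab), c(5, 5, 5, 5, 0, 0))
  expect_equal(score_sequence("AC", tab), c(0, 0))
  expect_equal(score_sequence("AANAAA", tab), c(0, 0, 0, 5, 0, 0))
  expect_error(score_sequence("AAA", count_kmers(c(s = "AAAA"), 3)),
               "adjusted")
})

test_that("a planted repeated word scores near copies-minus-expected", {
  set.seed(13)
  word <- random_text(20)
  bgtxt <- random_text(5000)
  pieces <- c(vapply(0:9, function(i) {
    paste0(substr(bgtxt, i * 500 + 1, (i + 1) * 500), word)
  }, ""))
  g <- c(s = paste(pieces, collapse = ""))
  tab <- adjust_counts(count_kmers(g, 8), train_background(g, 2))
  sc <- score_sequence(g[[1]], tab)
  inside <- 501:(500 + 13)  # windows fully inside the first copy
  expect_true(all(sc[inside] > 7))
})

test_that("default k follows the log4 rule with clamping", {
  expect_equal(default_k(c(s = random_text(1000))), 8)     # clamp up
  expect_equal(default_k(c(s = strrep("ACGT", 250000))), 9)
  expect_equal(default_k(c(s = random_text(100)), max_table = 4^10), 8)
})
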