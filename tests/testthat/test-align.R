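test_that("a perfect full-length match is the single MUM", {
  m <- find_mums(genome("r", "GATTACAT"), genome("q", "GATTACAT"), 8)
  expect_equal(m[m$strand == "+", c("ref_start", "qry_start", "length")],
               data.frame(ref_start = 0L, qry_start = 0L, length = 8L))
})

test_that("repeated content yields no short unique matches", {
  # every candidate substring of the shorter homopolymer occurs multiple
  # times in the longer one, so nothing is unique
  m <- find_mums(genome("r", strrep("A", 10)), genome("q", strrep("A", 14)),
                 8)
  expect_equal(nrow(m), 0L)
  # a tandem repeat suppresses anchors inside the repeated unit
  unit <- "ACGTTGCAGT"
  m2 <- find_mums(genome("r", strrep(unit, 4)), genome("q", strrep(unit, 4)),
                  8)
  expect_true(all(m2$length >= 8L))
})

test_that("find_mums equals the brute-force oracle on random pairs", {
  withr::local_seed(202)
  for (case in 1:150) {
    n <- sample(20:250, 1); m <- sample(20:250, 1)
    ml <- sample(8:12, 1)
    alpha <- switch(1 + case %% 3, c("A", "C", "G", "T"), c("A", "C"),
                    c("A", "C", "G", "T", "N"))
    r <- random_seq(n, alpha)
    q <- if (case %% 4 == 0) paste0(substr(r, 1, n %/% 2), random_seq(m))
         else random_seq(m, alpha)
    got <- find_mums(genome("r", r), genome("q", q), ml)
    exp <- mum_bruteforce(r, q, ml)
    expect_setequal(anchor_key(got), anchor_key(exp))
  }
})

test_that("anchors are symmetric under exchanging reference and query", {
  withr::local_seed(7)
  for (case in 1:20) {
    r <- random_seq(150); q <- substitute_base(r, sample(20:120, 1))
    a <- find_mums(genome("r", r), genome("q", q), 10, strands = "+")
    b <- find_mums(genome("q", q), genome("r", r), 10, strands = "+")
    expect_setequal(sprintf("%d:%d:%d", a$ref_start, a$qry_start, a$length),
                    sprintf("%d:%d:%d", b$qry_start, b$ref_start, b$length))
  }
})

test_that("anchors containing N are split at the ambiguous position", {
  r <- paste0(strrep("ACGTTGCA", 3), "N", strrep("TTGACCGA", 3))
  q <- r
  m <- find_mums(genome("r", r), genome("q", q), 8, strands = "+")
  expect_true(all(m$length <= 24L))
  expect_true(nrow(m) >= 2L)  # one anchor per side of the N
})

test_that("chaining respects gaps, monotonicity and the cluster minimum", {
  two <- data.frame(ref_start = c(0L, 130L), qry_start = c(0L, 130L),
                    length = c(30L, 40L), strand = "+")
  # anchors 100 bp apart chain together under a 200 bp gap allowance
  cl <- chain_anchors(two, max_gap = 200L, min_cluster = 65L)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 2L)
  # but not under a 50 bp allowance; each alone is below min_cluster
  cl2 <- chain_anchors(two, max_gap = 50L, min_cluster = 65L)
  expect_length(cl2, 0L)
  # crossing order (ref ascending, qry descending) is never co-chained
  crossing <- data.frame(ref_start = c(0L, 50L), qry_start = c(50L, 0L),
                         length = c(40L, 40L), strand = "+")
  cl3 <- chain_anchors(crossing, max_gap = 200L, min_cluster = 30L)
  for (c3 in cl3) expect_equal(nrow(c3), 1L)
})

test_that("gap closure produces the expected edit transcripts", {
  withr::local_seed(31)
  left <- random_seq(20); right <- random_seq(20)
  # single substitution between two 20 bp anchors
  mid_r <- "A"; mid_q <- "C"
  ref <- genome("r", paste0(left, mid_r, right))
  qry <- genome("q", paste0(left, mid_q, right))
  cl <- data.frame(ref_start = c(0L, 21L), qry_start = c(0L, 21L),
                   length = c(20L, 20L), strand = "+")
  attr(cl, "strand") <- "+"
  blocks <- close_gaps(ref, qry, cl)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$transcript,
               paste0(strrep("M", 20), "X", strrep("M", 20)))
  # 2 bp query insertion
  qry2 <- genome("q", paste0(left, "GG", right))
  cl2 <- data.frame(ref_start = c(0L, 20L), qry_start = c(0L, 22L),
                    length = c(20L, 20L), strand = "+")
  attr(cl2, "strand") <- "+"
  b2 <- close_gaps(genome("r", paste0(left, right)), qry2, cl2)
  expect_length(b2, 1L)
  expect_equal(gsub("[^I]", "", b2[[1]]$transcript), "II")
  expect_equal(b2[[1]]$qry_end - b2[[1]]$qry_start,
               b2[[1]]$ref_end - b2[[1]]$ref_start + 2L)
  # single-anchor cluster is an identity block
  cl3 <- data.frame(ref_start = 0L, qry_start = 0L, length = 20L,
                    strand = "+")
  attr(cl3, "strand") <- "+"
  b3 <- close_gaps(genome("r", left), genome("q", left), cl3)
  expect_equal(b3[[1]]$identity, 1.0)
  expect_equal(b3[[1]]$transcript, strrep("M", 20))
})

test_that("transcripts conserve reference and query spans", {
  withr::local_seed(17)
  r <- random_seq(3000)
  chars <- strsplit(r, "", fixed = TRUE)[[1]]
  chars <- append(chars[-(1001:1003)], strsplit(random_seq(5), "")[[1]],
                  after = 2000)
  chars[500] <- setdiff(c("A", "C", "G", "T"), chars[500])[1]
  q <- paste(chars, collapse = "")
  blocks <- align_pair(genome("r", r), genome("q", q),
                       align_params(min_len = 12L))
  expect_gt(length(blocks), 0L)
  for (b in blocks) {
    ops <- strsplit(b$transcript, "", fixed = TRUE)[[1]]
    expect_equal(sum(ops %in% c("M", "X", "D")), b$ref_end - b$ref_start)
    expect_equal(sum(ops %in% c("M", "X", "I")), b$qry_end - b$qry_start)
    expect_equal(b$identity, sum(ops == "M") / length(ops))
  }
})

test_that("one-to-one filtering keeps the best block per region", {
  mk <- function(rs, re, qs, qe, idy) {
    n <- re - rs
    nx <- round(n * (1 - idy))
    tr <- paste0(strrep("X", nx), strrep("M", n - nx))
    b <- structure(list(ref_start = rs, ref_end = re, qry_start = qs,
                        qry_end = qe, strand = "+", transcript = tr,
                        identity = 1 - nx / n), class = "alignment_block")
    b
  }
  hi <- mk(0L, 100L, 0L, 100L, 0.99)
  lo <- mk(0L, 100L, 200L, 300L, 0.90)
  kept <- filter_one_to_one(list(lo, hi))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$identity, hi$identity)
  # disjoint blocks are all retained
  far <- mk(500L, 600L, 500L, 600L, 1.0)
  expect_length(filter_one_to_one(list(hi, far)), 2L)
  # a query segment aligning twice to one reference locus keeps one copy
  dup <- mk(0L, 100L, 400L, 500L, 0.99)
  kept2 <- filter_one_to_one(list(hi, dup))
  expect_length(kept2, 1L)
  # retained intervals are pairwise disjoint on both axes
  kept3 <- filter_one_to_one(list(hi, lo, far, dup))
  for (i in seq_along(kept3)) for (j in seq_along(kept3)) {
    if (i >= j) next
    a <- kept3[[i]]; b <- kept3[[j]]
    expect_false(a$ref_start < b$ref_end && b$ref_start < a$ref_end)
    expect_false(a$qry_start < b$qry_end && b$qry_start < a$qry_end)
  }
})

test_that("align_pair handles identity, reverse complement and planted SNPs", {
  g <- simulate_genome(10000, 0.6, seed = 3, id = "ref")
  b <- align_pair(g, g)
  expect_length(b, 1L)
  expect_equal(b[[1]]$identity, 1.0)
  expect_equal(c(b[[1]]$ref_start, b[[1]]$ref_end), c(0L, 10000L))
  expect_false(grepl("X", b[[1]]$transcript, fixed = TRUE))

  rc <- genome("rc", revcomp(g$seq))
  brc <- align_pair(g, rc)
  expect_length(brc, 1L)
  expect_equal(brc[[1]]$strand, "-")
  expect_equal(brc[[1]]$identity, 1.0)

  withr::local_seed(5)
  pos <- sort(sample(seq(300, 9700, by = 450), 10))
  q <- g$seq
  for (p in pos) q <- substitute_base(q, p)
  bp <- align_pair(g, genome("mut", q))
  x_cols <- unlist(lapply(bp, function(b) {
    ops <- strsplit(b$transcript, "", fixed = TRUE)[[1]]
    rp <- b$ref_start + cumsum(ops %in% c("M", "X", "D")) - 1L
    rp[ops == "X"]
  }))
  expect_equal(sort(x_cols), pos)
})

test_that("block tables export cleanly", {
  g <- simulate_genome(2000, 0.5, seed = 9, id = "g")
  blocks <- align_pair(g, g)
  df <- blocks_as_table(blocks)
  expect_equal(nrow(df), 1L)
  expect_equal(df$identity, 1.0)
  f <- withr::local_tempfile(fileext = ".tsv")
  blocks_as_table(blocks, f)
  expect_equal(nrow(utils::read.delim(f)), 1L)
})
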