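# Frozen cross-check values from an independent nearest-neighbor
# implementation (Biopython MeltingTemp, SantaLucia unified parameters,
# 250 nM total strand concentration, 50 mM Na+, entropic salt correction).
BIOPYTHON_TM <- c(
  TGATATGGCGAATGCTTGCA = 54.7385,   # strain-assay forward primer
  CGGCTTGTGTGTCGTCATG  = 56.1934,   # strain-assay reverse primer
  ACCCTTTTCATTTCCCTGC  = 52.1699,   # strain-assay probe (unmodified)
  ATGCATGCATGCATGCATGC = 57.6834,
  GGGCCCGGGCCCGGGCCCAA = 73.0403,
  AAATTTAAATTTAAATTTAA = 34.4206,
  ACGTACGTACGTAC       = 42.1026)

test_that("melting temperatures match an independent implementation", {
  for (s in names(BIOPYTHON_TM))
    expect_equal(melting_temp(s), BIOPYTHON_TM[[s]], tolerance = 0.005)
})

test_that("Tm respects duplex symmetry and increases with GC content", {
  withr::local_seed(81)
  for (i in 1:25) {
    s <- random_seq(sample(10:30, 1))
    expect_equal(melting_temp(s), melting_temp(revcomp(s)), tolerance = 1e-9)
  }
  # replacing A/T by G/C at random positions raises Tm step by step
  for (trial in 1:10) {
    s <- random_seq(20, c("A", "T"))
    tms <- melting_temp(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in sample(20)) {
      chars[p] <- sample(c("G", "C"), 1)
      tms <- c(tms, melting_temp(paste(chars, collapse = "")))
    }
    expect_true(all(diff(tms) > 0))
  }
})

test_that("Tm rejects invalid inputs", {
  expect_error(melting_temp("ACGTNACGTA"), "A/C/G/T")
  expect_error(melting_temp("ACGT"), "length")
  expect_error(melting_temp(strrep("ACGT", 11)), "length")
})

test_that("enumerated designs satisfy every constraint and cover the SNP", {
  g <- simulate_genome(2000, 0.45, seed = 91, id = "t")
  snp <- 1000L
  designs <- enumerate_assays(g, snp)
  expect_gt(nrow(designs), 0L)
  cons <- assay_constraints()
  for (i in seq_len(min(nrow(designs), 50L))) {
    d <- designs[i, ]
    # primers are genomic substrings at their stated loci
    expect_equal(substr(g$seq, d$amplicon_start + 1L,
                        d$amplicon_start + nchar(d$fwd)), d$fwd)
    expect_equal(revcomp(substr(g$seq, d$amplicon_end - nchar(d$rev) + 1L,
                                d$amplicon_end)), d$rev)
    expect_equal(d$amplicon_length, d$amplicon_end - d$amplicon_start)
    expect_true(d$amplicon_start <= snp && snp < d$amplicon_end)
    # probe covers the SNP at the declared offset
    probe_start <- snp - d$snp_offset_in_probe
    expect_equal(substr(g$seq, probe_start + 1L,
                        probe_start + nchar(d$probe)), d$probe)
    expect_false(startsWith(d$probe, "G"))
    expect_true(d$probe_tm >= cons$probe_tm[1] &&
                d$probe_tm <= cons$probe_tm[2])
    expect_true(d$fwd_tm >= cons$primer_tm[1] &&
                d$fwd_tm <= cons$primer_tm[2])
    expect_true(d$amplicon_length >= cons$amplicon_len[1] &&
                d$amplicon_length <= cons$amplicon_len[2])
  }
  # a narrowed amplicon window is honoured
  narrow <- enumerate_assays(g, snp,
                             assay_constraints(amplicon_len = c(50L, 61L)))
  expect_true(all(narrow$amplicon_length >= 50L &
                  narrow$amplicon_length <= 61L))
  # insufficient flank is an error
  expect_error(enumerate_assays(g, 5L), "flank")
})

test_that("in-silico PCR rediscovers a constructed 61 bp product", {
  fwd <- "TGATATGGCGAATGCTTGCA"
  rev <- "CGGCTTGTGTGTCGTCATG"
  probe <- "ACCCTTTTCATTTCCCTGC"
  withr::local_seed(101)
  insert <- random_seq(61L - nchar(fwd) - nchar(rev))
  template <- paste0(random_seq(150), fwd, insert, revcomp(rev),
                     random_seq(150))
  g <- genome("template", template)
  amps <- insilico_pcr(g, fwd, rev)
  expect_equal(nrow(amps), 1L)
  expect_equal(amps$length, 61L)
  expect_equal(amps$fwd_mismatches + amps$rev_mismatches, 0L)
  # no product without a reverse site
  g2 <- genome("norev", paste0(random_seq(150), fwd, random_seq(150)))
  expect_equal(nrow(insilico_pcr(g2, fwd, rev)), 0L)
  # two tandem template copies give two products
  g3 <- genome("two", paste0(template, template))
  amps3 <- insilico_pcr(g3, fwd, rev, max_product = 200L)
  expect_equal(nrow(amps3), 2L)
  expect_equal(amps3$length, c(61L, 61L))
  # probe status is evaluated within the product
  amps4 <- insilico_pcr(g, fwd, rev, probe = probe, snp_offset_in_probe = 9L)
  expect_false(isTRUE(amps4$probe_bound[1]))  # probe absent from template
})

test_that("mismatch tolerance demands an exact 3' seed", {
  fwd <- "TGATATGGCGAATGCTTGCA"
  rev <- "CGGCTTGTGTGTCGTCATG"
  withr::local_seed(111)
  mk <- function(f) genome("g", paste0(random_seq(100), f, random_seq(30),
                                       revcomp(rev), random_seq(100)))
  # one internal mismatch in the forward primer is tolerated
  fwd_mid <- paste0(substr(fwd, 1, 9), "A", substr(fwd, 11, 20))
  stopifnot(fwd_mid != fwd)
  expect_equal(nrow(insilico_pcr(mk(fwd_mid), fwd, rev, max_mismatch = 1L)),
               1L)
  # the same mismatch inside the 3' seed kills the site
  fwd_3p <- paste0(substr(fwd, 1, 18), "AA")
  g3 <- mk(fwd_3p)
  expect_equal(nrow(insilico_pcr(g3, fwd, rev, max_mismatch = 2L,
                                 three_prime_exact = 3L)), 0L)
})

test_that("specificity screening separates target from near neighbours", {
  g <- simulate_genome(3000, 0.45, seed = 121, id = "target")
  snp <- 1500L
  designs <- enumerate_assays(g, snp)
  expect_gt(nrow(designs), 0L)
  d <- as.list(designs[1, ])
  # non-target: same locus but the other allele under the probe
  other <- genome("other", substitute_base(g$seq, snp))
  scr <- specificity_screen(d, list(g, other), "target")
  expect_true(scr$pass)
  amps_other <- scr$per_genome[scr$per_genome$genome_id == "other", ]
  expect_true(all(vapply(amps_other$probe_mismatch_at_snp, isTRUE,
                         logical(1))))
  # a non-target carrying the identical locus (SNP allele included) fails
  clone <- genome("clone", g$seq)
  scr2 <- specificity_screen(d, list(g, clone), "target")
  expect_false(scr2$pass)
  expect_true(any(grepl("clone", scr2$rationale)))
  # target-only panels pass with a warning
  expect_warning(scr3 <- specificity_screen(d, list(g), "target"),
                 "target only")
  expect_true(scr3$pass)
})
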