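# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol*K); propagated to all 16 dinucleotides
# via reverse-complement equivalence.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal base pair
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
GAS_CONSTANT <- 1.98722               # cal/(mol*K)

#' Nearest-neighbor duplex melting temperature
#'
#' SantaLucia (1998) unified nearest-neighbor model with initiation terms,
#' the 0.368 x (N-1) x ln\[Na+\] entropic salt correction, and
#' Tm = dH / (dS + R ln(C/4)) - 273.15 for non-self-complementary oligos
#' (C/1 with a symmetry entropy correction for self-complementary ones).
#'
#' @param seq Oligonucleotide sequence (8-40 nt, no N).
#' @param primer_conc Total strand concentration in mol/L (default 250 nM).
#' @param monovalent_salt Monovalent cation concentration in mol/L
#'   (default 50 mM).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(seq, primer_conc = 250e-9, monovalent_salt = 0.05) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 8L || n > 40L) stop("sequence length must be in [8, 40]")
  if (grepl("[^ACGT]", s)) stop("sequence must contain only A/C/G/T")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  dinucs <- paste0(chars[-n], chars[-1])
  dH <- sum(NN_DH[dinucs])
  dS <- sum(NN_DS[dinucs])
  term <- function(b) if (b %in% c("G", "C")) "GC" else "AT"
  dH <- dH + NN_INIT_DH[term(chars[1])] + NN_INIT_DH[term(chars[n])]
  dS <- dS + NN_INIT_DS[term(chars[1])] + NN_INIT_DS[term(chars[n])]
  selfcomp <- identical(s, revcomp(s))
  x <- 4
  if (selfcomp) { dS <- dS - 1.4; x <- 1 }
  dS_salt <- 0.368 * (n - 1) * log(monovalent_salt)
  tm <- 1000 * dH / (dS + dS_salt + GAS_CONSTANT * log(primer_conc / x)) -
    273.15
  unname(tm)
}

gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

max_gc_run <- function(seq) {
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1]] %in% c("G", "C"))
  m <- r$lengths[r$values]
  if (length(m) == 0L) 0L else max(m)
}

#' Default TaqMan design constraints
#'
#' Primer and probe length windows, amplicon length window, melting
#' temperature windows and a maximum G/C run. The probe window is a proxy
#' for an MGB-stabilized probe (the stabilization itself is not modeled).
#'
#' @param primer_len,probe_len,amplicon_len Integer ranges `c(min, max)`.
#' @param primer_tm,probe_tm Celsius windows `c(min, max)`.
#' @param gc Allowed GC fraction range for primers and probe.
#' @param max_gc_run Longest allowed consecutive G/C run.
#' @param primer_conc,monovalent_salt Thermodynamic settings for
#'   [melting_temp()].
#' @return Named list of constraints.
#' @export
assay_constraints <- function(primer_len = c(18L, 25L),
                              probe_len = c(13L, 25L),
                              amplicon_len = c(50L, 150L),
                              primer_tm = c(54, 62),
                              probe_tm = c(58, 63),
                              gc = c(0.30, 0.80),
                              max_gc_run = 4L,
                              primer_conc = 250e-9,
                              monovalent_salt = 0.05) {
  list(primer_len = as.integer(primer_len), probe_len = as.integer(probe_len),
       amplicon_len = as.integer(amplicon_len), primer_tm = primer_tm,
       probe_tm = probe_tm, gc = gc, max_gc_run = as.integer(max_gc_run),
       primer_conc = primer_conc, monovalent_salt = monovalent_salt)
}

oligo_ok <- function(seq, len_range, tm_range, cons, is_probe = FALSE) {
  if (grepl("N", seq, fixed = TRUE)) return(NULL)
  if (is_probe && startsWith(seq, "G")) return(NULL)  # 5' G quenches the dye
  g <- gc_fraction(seq)
  if (g < cons$gc[1] || g > cons$gc[2]) return(NULL)
  if (max_gc_run(seq) > cons$max_gc_run) return(NULL)
  tm <- melting_temp(seq, cons$primer_conc, cons$monovalent_salt)
  if (tm < tm_range[1] || tm > tm_range[2]) return(NULL)
  list(seq = seq, tm = tm, gc = g)
}

#' Enumerate TaqMan assay designs over a marker SNP
#'
#' Exhaustive enumeration of forward primer / probe / reverse primer
#' triples within the constraint windows. The probe must cover the SNP
#' and lie strictly between the primers; probes starting with G are
#' rejected (reporter quenching). Results are ranked by distance of the
#' probe Tm from the centre of its window, then by amplicon length, then
#' by amplicon start, deterministically.
#'
#' @param genome Target [genome].
#' @param snp_pos 0-based SNP position.
#' @param constraints [assay_constraints()].
#' @return A data.frame of designs: `fwd`, `rev`, `probe`, their Tm and GC
#'   columns, `amplicon_start`, `amplicon_end` (0-based half-open),
#'   `amplicon_length`, `snp_offset_in_probe`.
#' @export
enumerate_assays <- function(genome, snp_pos, constraints = assay_constraints()) {
  cons <- constraints
  amp_max <- cons$amplicon_len[2]
  if (snp_pos < amp_max || snp_pos + amp_max > genome$length)
    stop("snp_pos must be flanked by at least the maximum amplicon length")
  win_s <- snp_pos - amp_max  # 0-based window start, enough for any design
  win_e <- snp_pos + amp_max
  seqwin <- substr(genome$seq, win_s + 1L, win_e)
  snp_w <- snp_pos - win_s    # SNP position within window

  probes <- list()
  for (pl in cons$probe_len[1]:cons$probe_len[2]) {
    for (ps in (snp_w - pl + 1L):snp_w) {
      if (ps < 0L || ps + pl > nchar(seqwin)) next
      o <- oligo_ok(substr(seqwin, ps + 1L, ps + pl), cons$probe_len,
                    cons$probe_tm, cons, is_probe = TRUE)
      if (!is.null(o)) probes[[length(probes) + 1L]] <-
          c(o, list(start = ps, len = pl))
    }
  }
  fwds <- list()
  rvs <- list()
  for (fl in cons$primer_len[1]:cons$primer_len[2]) {
    for (fs in 0:(nchar(seqwin) - fl)) {
      sub <- substr(seqwin, fs + 1L, fs + fl)
      if (fs + fl <= snp_w) {          # candidate forward: upstream of SNP
        o <- oligo_ok(sub, cons$primer_len, cons$primer_tm, cons)
        if (!is.null(o)) fwds[[length(fwds) + 1L]] <-
            c(o, list(start = fs, len = fl))
      }
      if (fs > snp_w) {                # candidate reverse: downstream of SNP
        o <- oligo_ok(revcomp(sub), cons$primer_len, cons$primer_tm, cons)
        if (!is.null(o)) rvs[[length(rvs) + 1L]] <-
            c(o, list(start = fs, len = fl))
      }
    }
  }
  designs <- list()
  for (p in probes) {
    for (f in fwds) {
      if (f$start + f$len > p$start) next
      for (r in rvs) {
        if (r$start < p$start + p$len) next
        alen <- r$start + r$len - f$start
        if (alen < cons$amplicon_len[1] || alen > cons$amplicon_len[2]) next
        designs[[length(designs) + 1L]] <- data.frame(
          fwd = f$seq, rev = r$seq, probe = p$seq,
          fwd_tm = f$tm, rev_tm = r$tm, probe_tm = p$tm,
          fwd_gc = f$gc, rev_gc = r$gc, probe_gc = p$gc,
          amplicon_start = win_s + f$start,
          amplicon_end = win_s + r$start + r$len,
          amplicon_length = alen,
          snp_offset_in_probe = snp_w - p$start,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(designs) == 0L) {
    message(sprintf(paste0(
      "enumerate_assays: no feasible design (probe candidates: %d, ",
      "fwd candidates: %d, rev candidates: %d)"),
      length(probes), length(fwds), length(rvs)))
    return(empty_designs())
  }
  out <- do.call(rbind, designs)
  target_tm <- mean(cons$probe_tm)
  out <- out[order(abs(out$probe_tm - target_tm), out$amplicon_length,
                   out$amplicon_start, out$fwd, out$rev), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_designs <- function() {
  data.frame(fwd = character(), rev = character(), probe = character(),
             fwd_tm = numeric(), rev_tm = numeric(), probe_tm = numeric(),
             fwd_gc = numeric(), rev_gc = numeric(), probe_gc = numeric(),
             amplicon_start = integer(), amplicon_end = integer(),
             amplicon_length = integer(), snp_offset_in_probe = integer(),
             stringsAsFactors = FALSE)
}

# Mismatch count of `oligo` against `subject` at 0-based offset.
mismatches_at <- function(oligo, subject, offset) {
  a <- strsplit(oligo, "", fixed = TRUE)[[1]]
  b <- strsplit(substr(subject, offset + 1L, offset + nchar(oligo)), "",
                fixed = TRUE)[[1]]
  sum(a != b | a == "N" | b == "N")
}

find_primer_sites <- function(primer, subject_seq, max_mismatch,
                              three_prime_exact, three_prime_at_end) {
  subject <- Biostrings::DNAString(subject_seq)
  pat <- Biostrings::DNAString(primer)
  hits <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch,
                                   fixed = TRUE)
  if (length(hits) == 0L)
    return(data.frame(start = integer(), mismatches = integer()))
  st <- Biostrings::start(hits) - 1L   # 0-based
  mm <- vapply(st, function(s) mismatches_at(primer, subject_seq, s),
               integer(1))
  n <- nchar(primer)
  seed_ok <- vapply(st, function(s) {
    if (three_prime_at_end) {
      mismatches_at(substr(primer, n - three_prime_exact + 1L, n),
                    subject_seq, s + n - three_prime_exact) == 0L
    } else {
      mismatches_at(substr(primer, 1L, three_prime_exact), subject_seq, s) == 0L
    }
  }, logical(1))
  keep <- mm <= max_mismatch & seed_ok
  data.frame(start = st[keep], mismatches = mm[keep])
}

#' In-silico PCR: predict amplicons for a primer pair
#'
#' Finds all template sites where the forward primer matches the plus
#' strand and the reverse primer matches the minus strand, each within
#' `max_mismatch` mismatches and with an exact 3' seed of
#' `three_prime_exact` bases, oriented toward each other, with product
#' length at most `max_product`. When a probe is supplied, the best probe
#' hybridization site inside each product is located (either strand) and
#' the base under `snp_offset_in_probe` is checked.
#'
#' @param genome Template [genome].
#' @param fwd,rev Primer sequences (5'->3').
#' @param probe Optional probe sequence.
#' @param snp_offset_in_probe 0-based offset of the discriminating SNP in
#'   the probe (required to report `probe_mismatch_at_snp`).
#' @param max_mismatch Per-primer mismatch allowance.
#' @param three_prime_exact Length of the exact 3' seed.
#' @param max_product Maximum product length (bp).
#' @return A data.frame of amplicons: `genome_id`, `start`, `end`
#'   (0-based half-open), `length`, `fwd_mismatches`, `rev_mismatches`,
#'   `probe_bound`, `probe_mismatches`, `probe_mismatch_at_snp`.
#' @export
insilico_pcr <- function(genome, fwd, rev, probe = NULL,
                         snp_offset_in_probe = NA_integer_,
                         max_mismatch = 2L, three_prime_exact = 3L,
                         max_product = 2000L) {
  f_sites <- find_primer_sites(fwd, genome$seq, max_mismatch,
                               three_prime_exact, three_prime_at_end = TRUE)
  # reverse primer binds the minus strand: its plus-strand site is
  # revcomp(rev), whose 3' seed maps to the START of that site
  r_sites <- find_primer_sites(revcomp(rev), genome$seq, max_mismatch,
                               three_prime_exact, three_prime_at_end = FALSE)
  out <- list()
  for (i in seq_len(nrow(f_sites))) {
    fs <- f_sites$start[i]
    for (j in seq_len(nrow(r_sites))) {
      re <- r_sites$start[j] + nchar(rev)      # product end (exclusive)
      len <- re - fs
      if (len < nchar(fwd) + nchar(rev) || len > max_product) next
      amp <- list(genome_id = genome$id, start = fs, end = re, length = len,
                  fwd_mismatches = f_sites$mismatches[i],
                  rev_mismatches = r_sites$mismatches[j],
                  probe_bound = NA, probe_mismatches = NA_integer_,
                  probe_mismatch_at_snp = NA)
      if (!is.null(probe)) {
        amp_seq <- substr(genome$seq, fs + 1L, re)
        pb <- probe_best_site(probe, amp_seq, snp_offset_in_probe)
        amp$probe_bound <- pb$mismatches == 0L
        amp$probe_mismatches <- pb$mismatches
        amp$probe_mismatch_at_snp <- pb$mismatch_at_snp
      }
      out[[length(out) + 1L]] <- as.data.frame(amp, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      probe_bound = logical(), probe_mismatches = integer(),
                      probe_mismatch_at_snp = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# Best (fewest-mismatch) probe hybridization site within an amplicon,
# searching both strands; ties resolve to the leftmost plus-strand site.
probe_best_site <- function(probe, amp_seq, snp_offset) {
  n <- nchar(probe); m <- nchar(amp_seq)
  best <- list(mismatches = n, mismatch_at_snp = NA)
  if (m < n) return(best)
  for (strand in c("+", "-")) {
    p <- if (strand == "+") probe else revcomp(probe)
    off_snp <- if (strand == "+") snp_offset else n - 1L - snp_offset
    for (s in 0:(m - n)) {
      mm <- mismatches_at(p, amp_seq, s)
      if (mm < best$mismatches) {
        at_snp <- if (is.na(off_snp)) NA else
          mismatches_at(substr(p, off_snp + 1L, off_snp + 1L), amp_seq,
                        s + off_snp) > 0L
        best <- list(mismatches = mm, mismatch_at_snp = at_snp)
      }
    }
  }
  best
}

#' Screen an assay design against a genome panel
#'
#' The assay passes iff the target genome yields exactly one predicted
#' amplicon with a perfect probe match, and every non-target genome
#' yields either no amplicon or only amplicons whose probe site
#' mismatches at the SNP offset. Allele discrimination by a single probe
#' mismatch is a deliberate simplification of qPCR chemistry and is
#' recorded in the rationale.
#'
#' @param assay One row of [enumerate_assays()] (or a list with `fwd`,
#'   `rev`, `probe`, `snp_offset_in_probe`).
#' @param panel List of [genome] objects (target included).
#' @param target_id Id of the target genome.
#' @param ... Passed to [insilico_pcr()].
#' @return A list with `pass` (logical), `rationale` (character),
#'   `per_genome` (data.frame of predicted amplicons and probe status).
#' @export
specificity_screen <- function(assay, panel, target_id, ...) {
  if (is.data.frame(assay)) assay <- as.list(assay[1, ])
  per <- list()
  for (g in panel) {
    amps <- insilico_pcr(g, assay$fwd, assay$rev, probe = assay$probe,
                         snp_offset_in_probe = assay$snp_offset_in_probe, ...)
    if (nrow(amps) == 0L)
      amps <- data.frame(genome_id = g$id, start = NA_integer_,
                         end = NA_integer_, length = NA_integer_,
                         fwd_mismatches = NA_integer_,
                         rev_mismatches = NA_integer_, probe_bound = FALSE,
                         probe_mismatches = NA_integer_,
                         probe_mismatch_at_snp = NA,
                         stringsAsFactors = FALSE)
    per[[g$id]] <- amps
  }
  per_genome <- do.call(rbind, per)
  rownames(per_genome) <- NULL
  ids <- vapply(panel, `[[`, character(1), "id")
  if (!target_id %in% ids)
    stop("target '", target_id, "' not in panel")
  tgt <- per_genome[per_genome$genome_id == target_id &
                      !is.na(per_genome$start), , drop = FALSE]
  target_ok <- nrow(tgt) == 1L && isTRUE(tgt$probe_bound[1])
  offenders <- character()
  for (id in setdiff(ids, target_id)) {
    amps <- per_genome[per_genome$genome_id == id & !is.na(per_genome$start),
                       , drop = FALSE]
    bad <- nrow(amps) > 0L && any(!vapply(amps$probe_mismatch_at_snp,
                                          isTRUE, logical(1)))
    if (bad) offenders <- c(offenders, id)
  }
  pass <- target_ok && length(offenders) == 0L
  rationale <- c(
    if (target_ok) "target yields exactly one amplicon with perfect probe match"
    else "target does not yield exactly one perfectly probed amplicon",
    if (length(offenders) > 0L)
      paste("non-target amplification without SNP-site probe mismatch:",
            paste(offenders, collapse = ", "))
    else "all non-targets fail to amplify or mismatch the probe at the SNP",
    "criterion: single probe mismatch at the SNP offset (simplified model)")
  if (length(ids) == 1L)
    warning("specificity screen ran with the target only; no non-targets tested")
  list(pass = pass, rationale = rationale, per_genome = per_genome)
}
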