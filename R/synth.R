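# Run code under a local RNG state so generators are pure functions of
# their seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a random genome sequence
#'
#' I.i.d. bases at the requested GC content; reproducible for a fixed
#' seed and independent of the caller's RNG state.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param id Genome id.
#' @return A [genome] object.
#' @export
simulate_genome <- function(length, gc = 0.6, seed = 1L, id = "ancestor") {
  stopifnot(length >= 1000L, gc > 0, gc < 1)
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), size = length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    genome(id, paste(bases, collapse = ""))
  })
}

#' Describe the mutations planted in a synthetic panel
#'
#' Positions are 0-based on the target genome (after the optional
#' duplication is applied to the ancestor). `private_snps` are applied to
#' every comparator so the target allele is private; `shared_snps` only
#' to the named subset of comparators, so they are not private;
#' `indels` and the deletion-style confounders are applied per comparator.
#'
#' @param private_snps Data.frame with columns `pos`, `alt`.
#' @param shared_snps Data.frame with columns `pos`, `alt`, `strains`
#'   (comma-joined comparator ids).
#' @param indels Data.frame with columns `pos`, `len`, `type` (`ins` or
#'   `del`), `strain` (comparator id).
#' @param duplication `NULL` or list `(start, end, insert_pos)`: the
#'   target segment `[start, end)` is copied into every genome at
#'   `insert_pos` (multi-copy confounder).
#' @param background_snp_rate Per-bp rate of random comparator-specific
#'   substitutions emulating ~99.9% panel ANI.
#' @param seed Integer seed for the background mutations.
#' @return A list of class `mutation_spec`.
#' @export
mutation_spec <- function(private_snps = NULL, shared_snps = NULL,
                          indels = NULL, duplication = NULL,
                          background_snp_rate = 1e-3, seed = 1L) {
  spec <- list(private_snps = private_snps, shared_snps = shared_snps,
               indels = indels, duplication = duplication,
               background_snp_rate = background_snp_rate,
               seed = as.integer(seed))
  class(spec) <- "mutation_spec"
  spec
}

other_base <- function(base, rng_draw) {
  choices <- setdiff(c("A", "C", "G", "T"), base)
  choices[rng_draw]
}

apply_substitution <- function(chars, pos, alt) {
  stopifnot(pos >= 0L, pos < length(chars))
  chars[pos + 1L] <- alt
  chars
}

#' Build a synthetic strain panel with planted truth
#'
#' The target genome is the ancestor (plus the optional duplicated
#' segment). Comparators derive from the same base genome by planted
#' private SNPs (applied to all comparators), shared SNPs (a subset),
#' per-comparator indels/deletions, and random background substitutions.
#' The returned truth lists exactly the target-private positions expected
#' to survive marker selection and the planted confounders with their
#' exclusion reasons (`shared`, `uncovered`, `multi-copy`).
#'
#' @param ancestor A [genome] (the target before edits).
#' @param n_strains Number of comparator strains (>= 1).
#' @param spec A [mutation_spec()].
#' @return A list: `target` ([genome]), `comparators` (list of genomes),
#'   `truth` (list `expected_private` (0-based positions),
#'   `expected_excluded` (named character: position -> reason)).
#' @export
build_panel <- function(ancestor, n_strains, spec = mutation_spec()) {
  stopifnot(inherits(ancestor, "genome"), n_strains >= 1L)
  dup <- spec$duplication
  base_chars <- strsplit(ancestor$seq, "", fixed = TRUE)[[1]]
  if (!is.null(dup)) {
    stopifnot(dup$start >= 0L, dup$end > dup$start,
              dup$end <= length(base_chars))
    seg <- base_chars[(dup$start + 1L):dup$end]
    ip <- dup$insert_pos
    base_chars <- append(base_chars, seg, after = ip)
  }
  target <- genome(ancestor$id, paste(base_chars, collapse = ""),
                   accession = ancestor$accession)
  glen <- target$length

  edits <- list()  # per comparator: list of data.frames pos/alt, indel table
  comp_ids <- sprintf("comparator_%02d", seq_len(n_strains))
  all_planted <- integer()
  collect_pos <- function(df) if (!is.null(df) && nrow(df) > 0L) df$pos else integer()
  all_planted <- c(collect_pos(spec$private_snps),
                   collect_pos(spec$shared_snps),
                   collect_pos(spec$indels))
  if (anyDuplicated(all_planted))
    stop("planted edit positions must be distinct")
  if (length(all_planted) > 0L && (min(all_planted) < 0L ||
                                   max(all_planted) >= glen))
    stop("planted edit positions must lie within the genome")

  excluded <- character()
  dup_hits <- function(pos) {
    if (is.null(dup)) return(FALSE)
    in_seg <- pos >= dup$start && pos < dup$end
    in_copy <- pos >= dup$insert_pos && pos < dup$insert_pos + (dup$end - dup$start)
    in_seg || in_copy
  }

  expected_private <- integer()
  if (!is.null(spec$private_snps) && nrow(spec$private_snps) > 0L) {
    for (i in seq_len(nrow(spec$private_snps))) {
      p <- spec$private_snps$pos[i]
      if (spec$private_snps$alt[i] == base_chars[p + 1L])
        stop("private SNP alt equals the target allele at pos ", p)
      if (dup_hits(p)) excluded[as.character(p)] <- "multi-copy"
      else expected_private <- c(expected_private, p)
    }
  }
  if (!is.null(spec$shared_snps) && nrow(spec$shared_snps) > 0L) {
    for (i in seq_len(nrow(spec$shared_snps))) {
      strains <- strsplit(spec$shared_snps$strains[i], ",", fixed = TRUE)[[1]]
      if (length(setdiff(comp_ids, strains)) == 0L)
        stop("a shared SNP applied to every comparator would be private; ",
             "use private_snps")
      excluded[as.character(spec$shared_snps$pos[i])] <- "shared"
    }
  }
  # deletions in one comparator covering a private SNP leave it uncovered
  if (!is.null(spec$indels) && nrow(spec$indels) > 0L) {
    unknown <- setdiff(spec$indels$strain, comp_ids)
    if (length(unknown) > 0L)
      stop("indel targets unknown comparator(s): ",
           paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(spec$indels))) {
      ind <- spec$indels[i, ]
      if (ind$type == "del") {
        covered <- expected_private[expected_private >= ind$pos &
                                    expected_private < ind$pos + ind$len]
        for (p in covered) {
          expected_private <- setdiff(expected_private, p)
          excluded[as.character(p)] <- "uncovered"
        }
      }
    }
  }

  comparators <- with_seed(spec$seed, {
    lapply(seq_len(n_strains), function(k) {
      chars <- base_chars
      cid <- comp_ids[k]
      # background substitutions unique to this comparator; kept >= 100 bp
      # from planted sites so planted markers keep their isolation (the
      # panel emulates markers inside conserved single-copy loci)
      n_bg <- stats::rpois(1, spec$background_snp_rate * glen)
      if (n_bg > 0L) {
        cand <- sample.int(glen, n_bg) - 1L
        if (length(all_planted) > 0L)
          cand <- cand[vapply(cand, function(p)
            min(abs(p - all_planted)) >= 100L, logical(1))]
        for (p in cand)
          chars[p + 1L] <- other_base(chars[p + 1L], sample.int(3L, 1L))
      }
      if (!is.null(spec$private_snps) && nrow(spec$private_snps) > 0L)
        for (i in seq_len(nrow(spec$private_snps)))
          chars <- apply_substitution(chars, spec$private_snps$pos[i],
                                      spec$private_snps$alt[i])
      if (!is.null(spec$shared_snps) && nrow(spec$shared_snps) > 0L)
        for (i in seq_len(nrow(spec$shared_snps))) {
          strains <- strsplit(spec$shared_snps$strains[i], ",",
                              fixed = TRUE)[[1]]
          if (cid %in% strains)
            chars <- apply_substitution(chars, spec$shared_snps$pos[i],
                                        spec$shared_snps$alt[i])
        }
      # indels applied right-to-left so earlier positions stay valid
      ind <- spec$indels
      if (!is.null(ind) && nrow(ind) > 0L) {
        ind <- ind[ind$strain == cid, , drop = FALSE]
        if (nrow(ind) > 0L) {
          ind <- ind[order(-ind$pos), , drop = FALSE]
          for (i in seq_len(nrow(ind))) {
            p <- ind$pos[i]; l <- ind$len[i]
            if (ind$type[i] == "del") {
              chars <- chars[-((p + 1L):(p + l))]
            } else {
              insert <- sample(c("A", "C", "G", "T"), l, replace = TRUE)
              chars <- append(chars, insert, after = p)
            }
          }
        }
      }
      genome(cid, paste(chars, collapse = ""))
    })
  })
  names(comparators) <- comp_ids
  list(target = target, comparators = comparators,
       truth = list(expected_private = as.integer(sort(expected_private)),
                    expected_excluded = excluded))
}

#' Simulate a Cq dilution-ladder table from a known standard curve
#'
#' cq = intercept + slope * x + N(0, noise_sd), reproducible per seed.
#'
#' @param curve A `standard_curve` (or list with `slope`, `intercept`).
#' @param levels log10 quantities of the ladder.
#' @param reps Replicates per level (>= 1).
#' @param noise_sd Gaussian Cq noise in cycles (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `x`, `cq`, `replicate`.
#' @export
simulate_cq <- function(curve, levels, reps = 3L, noise_sd = 0.15,
                        seed = 1L) {
  stopifnot(reps >= 1L, noise_sd >= 0)
  with_seed(seed, {
    x <- rep(levels, each = reps)
    cq <- curve$intercept + curve$slope * x +
      stats::rnorm(length(x), mean = 0, sd = noise_sd)
    data.frame(x = x, cq = cq, replicate = rep(seq_len(reps),
                                               times = length(levels)))
  })
}

#' Default synthetic study panel
#'
#' Convenience wrapper producing the package's reference desk-scale
#' conditions: a 100 kb ancestor, five comparator strains at ~99.9%
#' identity (1 background substitution per kb), five planted private
#' SNPs, and the three confounders (a SNP shared by a comparator subset,
#' a private SNP inside a duplicated segment, and a private SNP deleted
#' in one comparator).
#'
#' @param seed Integer seed.
#' @param genome_length Ancestor length in bp.
#' @param n_strains Number of comparators.
#' @return As [build_panel()], plus the `spec` used.
#' @export
default_panel <- function(seed = 1L, genome_length = 100000L,
                          n_strains = 5L) {
  ancestor <- simulate_genome(genome_length, gc = 0.60, seed = seed,
                              id = "target")
  L <- genome_length
  pos <- as.integer(round(seq(0.15, 0.75, length.out = 5) * L))
  seg_len <- as.integer(max(400L, min(2000L, round(0.02 * L))))
  dup_start <- as.integer(round(0.84 * L)); dup_end <- dup_start + seg_len
  dup_insert <- as.integer(round(0.95 * L))
  dup_snp <- dup_start + seg_len %/% 2L
  del_pos <- as.integer(round(0.05 * L))
  base <- simulate_genome(L, gc = 0.60, seed = seed)  # for allele lookup
  alt_at <- function(p) {
    ref <- substr(base$seq, p + 1L, p + 1L)
    setdiff(c("A", "C", "G", "T"), ref)[1]
  }
  spec <- mutation_spec(
    private_snps = data.frame(
      pos = c(pos, dup_snp, del_pos),
      alt = vapply(c(pos, dup_snp, del_pos), alt_at, character(1)),
      stringsAsFactors = FALSE),
    shared_snps = if (n_strains >= 2L) data.frame(
      pos = as.integer(round(0.5 * L)) + 137L,
      alt = alt_at(as.integer(round(0.5 * L)) + 137L),
      strains = paste(sprintf("comparator_%02d",
                              seq_len(max(1L, n_strains %/% 2L))),
                      collapse = ","),
      stringsAsFactors = FALSE) else NULL,
    indels = data.frame(
      pos = del_pos - 40L, len = 120L, type = "del",
      strain = sprintf("comparator_%02d", min(3L, n_strains)),
      stringsAsFactors = FALSE),
    duplication = list(start = dup_start, end = dup_end,
                       insert_pos = dup_insert),
    background_snp_rate = 1e-3, seed = seed + 1L)
  res <- build_panel(ancestor, n_strains, spec)
  res$spec <- spec
  res
}

#' Write a synthetic panel to disk
#'
#' FASTA per genome, a panel config, the truth as JSON.
#'
#' @param panel Result of [build_panel()] / [default_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- c(list(panel$target), unname(panel$comparators))
  paths <- list()
  for (g in genomes) {
    p <- file.path(dir, paste0(g$id, ".fasta"))
    write_fasta(g, p)
    paths[[g$id]] <- basename(p)
  }
  cfg <- list(target = panel$target$id,
              comparators = names(panel$comparators),
              paths = paths)
  yaml::write_yaml(cfg, file.path(dir, "panel.yaml"))
  jsonlite::write_json(
    list(expected_private = panel$truth$expected_private,
         expected_excluded = as.list(panel$truth$expected_excluded)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
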