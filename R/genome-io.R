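#' @useDynLib strainmarker, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Construct a genome object
#'
#' A genome is a named nucleotide sequence with optional assembly accession.
#' Sequences are stored uppercase over the alphabet \{A, C, G, T, N\}; all
#' internal coordinates in the package are 0-based half-open.
#'
#' @param id Record identifier (non-empty string).
#' @param seq Nucleotide sequence string.
#' @param accession Optional assembly accession, e.g. `"GCA_003606305.1"`.
#' @return An object of class `genome` with fields `id`, `accession`,
#'   `seq` and `length`.
#' @export
genome <- function(id, seq, accession = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  norm <- normalize_seq(seq)
  structure(
    list(id = id, accession = accession, seq = norm$seq,
         length = nchar(norm$seq), n_ambiguous = norm$n_ambiguous),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s%s: %d bp\n", x$id,
              if (!is.null(x$accession)) paste0(" (", x$accession, ")") else "",
              x$length))
  invisible(x)
}

# Uppercase, U->T, IUPAC ambiguity codes other than N -> N (count kept).
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  s <- gsub("U", "T", s, fixed = TRUE)
  s <- gsub("[^ACGTN]", "\01", s)  # placeholder so replacements are countable
  n_amb <- sum(charToRaw(s) == as.raw(1L))
  s <- gsub("\01", "N", s, fixed = TRUE)
  list(seq = s, n_ambiguous = n_amb)
}

#' Read a FASTA file into genome objects
#'
#' Records are normalized on input: lowercase mapped to uppercase, U to T,
#' and IUPAC ambiguity codes other than N to N (the replacement count is
#' reported with a message and stored in each genome's `n_ambiguous`).
#'
#' @param path Path to a FASTA file.
#' @return A named list of [genome] objects, one per record.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", "))
  genomes <- lapply(seq_along(set), function(i) {
    genome(id = ids[i], seq = as.character(set[[i]]))
  })
  names(genomes) <- ids
  n_amb <- sum(vapply(genomes, `[[`, integer(1), "n_ambiguous"))
  if (n_amb > 0L)
    message(sprintf("read_fasta: replaced %d ambiguity code(s) with N", n_amb))
  genomes
}

#' Write genomes to a FASTA file
#'
#' @param genomes A [genome] or list of genomes.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "seq"))
  names(set) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene/CDS intervals from a GFF3 file
#'
#' Coordinates are converted from the GFF 1-based inclusive convention to
#' the package's 0-based half-open convention; intervals are returned
#' sorted by start.
#'
#' @param path Path to a GFF3 file.
#' @param seq_id Sequence id to restrict to (optional).
#' @param types Feature types to keep.
#' @return A data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `name` (0-based half-open coordinates).
#' @export
read_gff_genes <- function(path, seq_id = NULL, types = c("gene", "CDS")) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns, found %d",
                   i, nf))
  }
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- as.data.frame(rtracklayer::readGFF(path))
    nm <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
    if ("Name" %in% names(g)) nm <- ifelse(is.na(nm), as.character(g$Name), nm)
    df <- data.frame(seq_id = as.character(g$seqid),
                     start = as.integer(g$start) - 1L,
                     end = as.integer(g$end),
                     strand = as.character(g$strand),
                     name = nm,
                     type = as.character(g$type),
                     stringsAsFactors = FALSE)
  } else {
    f <- do.call(rbind, strsplit(lines[body], "\t", fixed = TRUE))
    nm <- sub("^.*ID=([^;]+).*$", "\\1", f[, 9])
    nm[!grepl("ID=", f[, 9])] <- NA_character_
    df <- data.frame(seq_id = f[, 1], start = as.integer(f[, 4]) - 1L,
                     end = as.integer(f[, 5]), strand = f[, 7], name = nm,
                     type = f[, 3], stringsAsFactors = FALSE)
  }
  df <- df[df$type %in% types, , drop = FALSE]
  if (!is.null(seq_id)) df <- df[df$seq_id == seq_id, , drop = FALSE]
  df$type <- NULL
  if (nrow(df) == 0L) return(empty)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a panel configuration file
#'
#' The panel config (YAML or JSON) names the target genome, the comparator
#' genomes and optional parameter overrides:
#' ```yaml
#' target: HN019
#' comparators: [BB12, Bi07]
#' paths:
#'   HN019: genomes/hn019.fasta
#'   BB12: genomes/bb12.fasta
#'   Bi07: genomes/bi07.fasta
#' params:
#'   min_len: 20
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A list with elements `target`, `comparators`, `paths`, `params`.
#' @export
read_panel_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$target) || !nzchar(cfg$target))
    stop("panel config must name a 'target'")
  comparators <- unlist(cfg$comparators)
  if (length(comparators) < 1L)
    stop("panel config must list at least one comparator")
  if (cfg$target %in% comparators)
    stop("target '", cfg$target, "' must not appear among the comparators")
  paths <- cfg$paths
  if (!is.null(paths)) {
    paths <- unlist(paths)
    base <- dirname(path)
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
    names(abs) <- names(paths)
    missing <- names(abs)[!file.exists(abs)]
    if (length(missing) > 0L)
      stop("panel config references missing file(s) for: ",
           paste(missing, collapse = ", "))
    need <- setdiff(c(cfg$target, comparators), names(abs))
    if (length(need) > 0L)
      stop("panel config lacks a path for: ", paste(need, collapse = ", "))
    paths <- as.list(abs)
  }
  list(target = cfg$target, comparators = as.character(comparators),
       paths = paths, params = if (is.null(cfg$params)) list() else cfg$params)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string over \{A, C, G, T, N\}.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Integer coding for the aligner: A,C,G,T -> 1..4; N and anything else gets
# a unique code >= offset so it never matches (not even another N).
encode_seq <- function(seq, offset = 5L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- match(v, c("A", "C", "G", "T"))
  na <- which(is.na(codes))
  if (length(na) > 0L) codes[na] <- offset + seq_along(na) - 1L
  list(codes = as.integer(codes), next_free = offset + length(na))
}
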