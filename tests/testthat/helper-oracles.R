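# Independent oracles used across the test files.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Matrix of maximal common-extension lengths: L[i, j] = length of the
# longest common prefix of a[i..] and b[j..]; N matches nothing.
match_length_matrix <- function(a, b) {
  n <- length(a); m <- length(b)
  eq <- outer(a, b, "==")
  eq[a == "N", ] <- FALSE
  eq[, b == "N"] <- FALSE
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in n:1)
    L[i, 1:m] <- ifelse(eq[i, ], L[i + 1L, 2:(m + 1L)] + 1L, 0L)
  L[1:n, 1:m, drop = FALSE]
}

# Brute-force maximal-unique-match enumeration over all substring pairs:
# a match qualifies iff it is maximal in both directions and its substring
# occurs exactly once in the reference and once in the (oriented) query.
# Completely independent of the suffix-array implementation.
mum_bruteforce <- function(ref_seq, qry_seq, min_len,
                           strands = c("+", "-")) {
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  a <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  Lrr <- match_length_matrix(a, a)
  for (st in strands) {
    qs <- if (st == "+") qry_seq else rc(qry_seq)
    b <- strsplit(qs, "", fixed = TRUE)[[1]]
    L <- match_length_matrix(a, b)
    n <- length(a); m <- length(b)
    leftmax <- matrix(TRUE, n, m)
    if (n > 1L && m > 1L)
      leftmax[2:n, 2:m] <- outer(a[-n], b[-m], "!=") |
        outer(a[-n] == "N", b[-m] == "N", "|")
    cand <- which(L >= min_len & leftmax, arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      len <- L[i, j]
      if (sum(Lrr[, i] >= len) != 1L) next  # not unique in reference
      if (sum(L[i, ] >= len) != 1L) next    # not unique in query
      out[[length(out) + 1L]] <- data.frame(
        ref_start = i - 1L, qry_start = j - 1L, length = len, strand = st,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(ref_start = integer(), qry_start = integer(),
               length = integer(), strand = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$strand, res$ref_start, res$qry_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Canonical form for anchor-set comparison.
anchor_key <- function(df) {
  sprintf("%s:%d:%d:%d", df$strand, df$ref_start, df$qry_start, df$length)
}

# Mutate one position of a sequence to a different base.
substitute_base <- function(seq, pos0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos0 + 1L] <- setdiff(c("A", "C", "G", "T"), chars[pos0 + 1L])[1]
  paste(chars, collapse = "")
}
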