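# Independent oracles used across the suite.  These deliberately use
# different algorithms (full-matrix DP, exhaustive enumeration) from the
# implementation paths they check.

# Full-matrix global alignment score (Needleman-Wunsch, linear gaps).
nw_full_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  S <- matrix(-Inf, m + 1, n + 1)
  S[1, ] <- gap * (0:n)
  S[, 1] <- gap * (0:m)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + if (A[i] == B[j]) match else mismatch,
        S[i, j + 1] + gap,
        S[i + 1, j] + gap)
    }
  }
  S[m + 1, n + 1]
}

# Exhaustive digest oracle: scan every substring and keep those bounded by
# cleavage boundaries with at most max_missed internal sites and a length
# in range.  O(L^2), independent of the boundary-pair construction.
digest_oracle <- function(protein, max_missed = 3, min_len = 6,
                          max_len = 45) {
  aa <- strsplit(protein, "")[[1]]
  L <- length(aa)
  is_site <- function(p) p >= 1 && p < L && aa[p] %in% c("K", "R") &&
    aa[p + 1] != "P"
  boundary <- vapply(0:L, function(p) p == 0 || p == L || is_site(p),
                     logical(1))
  out <- character(0)
  for (i in 0:(L - 1)) {
    if (!boundary[i + 1]) next
    for (j in (i + 1):L) {
      if (!boundary[j + 1]) next
      len <- j - i
      if (len < min_len || len > max_len) next
      internal <- if (j - i >= 2)
        sum(vapply((i + 1):(j - 1), is_site, logical(1))) else 0L
      if (internal <= max_missed) out <- c(out, paste(aa[(i + 1):j],
                                                      collapse = ""))
    }
  }
  sort(unique(out))
}

# Overlap-safe N-glycosylation sequon enumerator (N-X-[S/T], X != P).
sequon_oracle <- function(x) {
  m <- gregexpr("N(?=[^P][ST])", x, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Deterministic random protein / DNA strings for fixtures.
random_protein <- function(n, seed) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build a QualityScaledDNAStringSet from sequences and constant or listed
# per-base qualities.
make_reads <- function(seqs, quals) {
  if (is.numeric(quals)) quals <- lapply(nchar(seqs), function(n)
    rep(quals[1], n))
  qs <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), character(1))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, paste0("r", seq_along(seqs)))),
    Biostrings::PhredQuality(qs))
}

# Substitute k bases/residues of a sequence at distinct seeded positions.
plant_substitutions <- function(x, k, seed, alphabet) {
  set.seed(seed)
  ch <- strsplit(x, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  list(seq = paste(ch, collapse = ""), positions = sort(pos))
}
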