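# Read QC, template selection and pileup-majority consensus polishing.

#' Read filter configuration
#'
#' The filtering rule applied to raw long reads before consensus
#' generation: mean read quality strictly above `min_mean_q` and length
#' between `min_len` and `max_len`, both bounds inclusive.  Defaults match
#' the selection used for the MUC16 amplicon (mean quality above Q20,
#' length 10-10.5 kb).
#'
#' @param min_mean_q Phred units (default 20; strict `>`).
#' @param min_len,max_len read length bounds in nt, inclusive
#'   (defaults 10000 and 10500).
#' @return a classed list (`ReadFilterConfig`).
#' @export
readFilterConfig <- function(min_mean_q = 20, min_len = 10000L,
                             max_len = 10500L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (min_mean_q < 0) stop("min_mean_q must be >= 0")
  structure(list(min_mean_q = min_mean_q, min_len = as.integer(min_len),
                 max_len = as.integer(max_len)),
            class = c("ReadFilterConfig", "list"))
}

# Phred mean: average the per-base error probabilities, then convert back.
phred_mean <- function(q) {
  if (!length(q)) stop("cannot compute mean quality of an empty read")
  -10 * log10(mean(10^(-q / 10)))
}

#' Mean read quality (ONT convention)
#'
#' The mean quality of a read is defined on error probabilities, not raw
#' Phred scores: per-base qualities are converted to error probabilities,
#' averaged, and converted back, `-10 log10(mean(10^(-q/10)))`.
#'
#' @param x a numeric vector of per-base Phred scores, or a
#'   [Biostrings::QualityScaledDNAStringSet] (one value per read).
#' @return numeric vector of mean qualities in Phred units.
#' @examples
#' meanReadQuality(c(10, 30))  # ~12.97, not 20
#' @export
setGeneric("meanReadQuality", function(x) standardGeneric("meanReadQuality"))

#' @rdname meanReadQuality
#' @export
setMethod("meanReadQuality", "numeric", function(x) phred_mean(x))

#' @rdname meanReadQuality
#' @export
setMethod("meanReadQuality", "QualityScaledDNAStringSet", function(x) {
  quals <- methods::as(Biostrings::quality(x), "IntegerList")
  vapply(quals, phred_mean, numeric(1))
})

#' Filter reads on mean quality and length
#'
#' Keeps reads whose mean quality is strictly greater than
#' `cfg$min_mean_q` and whose length lies in `[cfg$min_len, cfg$max_len]`;
#' input order is preserved.  Idempotent.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param cfg a [readFilterConfig()].
#' @return the kept subset of `reads` (possibly empty).
#' @export
filterReads <- function(reads, cfg = readFilterConfig()) {
  stopifnot(inherits(cfg, "ReadFilterConfig"))
  if (!length(reads)) return(reads)
  len <- Biostrings::width(reads)
  q <- meanReadQuality(reads)
  reads[q > cfg$min_mean_q & len >= cfg$min_len & len <= cfg$max_len]
}

#' Per-read QC statistics
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return a data frame with columns `id`, `length`, `mean_quality`
#'   (one row per read).
#' @export
qcStats <- function(reads) {
  if (!length(reads))
    return(data.frame(id = character(0), length = integer(0),
                      mean_quality = numeric(0)))
  data.frame(id = names(reads), length = Biostrings::width(reads),
             mean_quality = meanReadQuality(reads), row.names = NULL)
}

#' Select the polishing template
#'
#' Returns the read with the highest mean quality; ties are broken by the
#' lexicographically smallest read id, so selection is deterministic.
#'
#' @param reads a non-empty [Biostrings::QualityScaledDNAStringSet].
#' @return a length-1 `QualityScaledDNAStringSet`.
#' @export
selectTemplate <- function(reads) {
  if (!length(reads)) stop("cannot select a template from zero reads")
  q <- meanReadQuality(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  best <- which(q == max(q))
  reads[best[order(ids[best])][1]]
}

#' Banded global alignment with deterministic tie-breaking
#'
#' Optimal global alignment under linear gap penalty, restricted to a
#' diagonal band: position offsets `j - i` outside `[-band, band]` are
#' excluded, so the band must be at least the length difference of the two
#' sequences.  Ties are resolved deterministically (diagonal, then gap in
#' `b`, then gap in `a`), so identical inputs always give identical
#' alignments.
#'
#' @param a,b sequences (character strings; any alphabet).
#' @param band band half-width; must be `>= abs(nchar(a) - nchar(b))`.
#' @param match,mismatch,gap scores (defaults +1/-1/-2).
#' @return a list with `aligned_a`, `aligned_b` (gap symbol `-`) and
#'   `score`.
#' @examples
#' bandedAlign("ACGT", "AGT", band = 2)
#' @export
bandedAlign <- function(a, b, band, match = 1, mismatch = -1, gap = -2) {
  a <- as_seq_character(a); b <- as_seq_character(b)
  .banded_align_cpp(a, b, as.integer(band), match, mismatch, gap)
}

# Build pileup counts for one round: align each read to the working
# sequence and return the new majority sequence plus per-column support.
polish_round <- function(w, read_seqs, band_extra, match, mismatch, gap) {
  L <- nchar(w)
  wchars <- s2c(w)
  n_reads <- length(read_seqs)
  symbols <- sort(unique(c(wchars, "-", unlist(strsplit(read_seqs, "")))))
  S <- length(symbols)
  counts <- matrix(0L, nrow = S, ncol = L, dimnames = list(symbols, NULL))
  ins_key <- character(0); ins_sym <- character(0)
  for (r in read_seqs) {
    band <- abs(nchar(r) - L) + band_extra
    al <- .banded_align_cpp(w, r, band, match, mismatch, gap)
    ca <- s2c(al$aligned_a); cb <- s2c(al$aligned_b)
    is_ref <- ca != "-"
    refpos <- cumsum(is_ref)
    i0 <- which(is_ref)
    counts[cbind(match(cb[i0], symbols), refpos[i0])] <-
      counts[cbind(match(cb[i0], symbols), refpos[i0])] + 1L
    gi <- which(!is_ref)
    if (length(gi)) {
      pos <- seq_along(ca)
      last_ref <- cummax(ifelse(is_ref, pos, 0L))
      rank <- gi - last_ref[gi]
      ins_key <- c(ins_key, paste(refpos[gi], rank, sep = ":"))
      ins_sym <- c(ins_sym, cb[gi])
    }
  }
  # majority per reference column; ties favor the working sequence symbol,
  # then the alphabetically smallest symbol (gap sorts first)
  maxv <- do.call(pmax, lapply(seq_len(S), function(i) counts[i, ]))
  wcode <- match(wchars, symbols)
  w_is_max <- counts[cbind(wcode, seq_len(L))] == maxv
  first_max <- max.col(t(counts), ties.method = "first")
  pick <- ifelse(w_is_max, wcode, first_max)
  chosen <- symbols[pick]
  support0 <- counts[cbind(pick, seq_len(L))]

  cols <- data.frame(refpos = seq_len(L), rank = 0L, symbol = chosen,
                     support = support0)
  if (length(ins_key)) {
    tab <- table(ins_key, ins_sym)
    keys <- rownames(tab)
    ins_counts <- matrix(as.integer(tab), nrow = nrow(tab),
                         dimnames = dimnames(tab))
    best_idx <- max.col(ins_counts, ties.method = "first")
    best_cnt <- ins_counts[cbind(seq_len(nrow(ins_counts)), best_idx)]
    best_sym <- colnames(ins_counts)[best_idx]
    # reads not inserting at this slot implicitly vote for no column;
    # a tie keeps the working sequence (no insertion)
    gap_votes <- n_reads - rowSums(ins_counts)
    keep <- best_cnt > gap_votes
    if (any(keep)) {
      kk <- strsplit(keys[keep], ":", fixed = TRUE)
      cols <- rbind(cols, data.frame(
        refpos = as.integer(vapply(kk, `[`, character(1), 1L)),
        rank = as.integer(vapply(kk, `[`, character(1), 2L)),
        symbol = best_sym[keep], support = best_cnt[keep]))
    }
  }
  cols <- cols[order(cols$refpos, cols$rank), , drop = FALSE]
  keep <- cols$symbol != "-"
  list(seq = paste(cols$symbol[keep], collapse = ""),
       support = as.integer(cols$support[keep]))
}

#' Polish a template into a consensus by iterative pileup majority
#'
#' Re-implements neural-network consensus polishing as a transparent
#' pileup-majority procedure: each round, every read is globally aligned
#' to the current working sequence with the banded aligner, a column
#' pileup (including insertion columns) is tabulated, and each column's
#' majority symbol is emitted (a gap majority deletes the column;
#' insertion columns are added only when more reads insert a base than
#' not).  Ties are broken in favor of the current working sequence.
#' Polishing stops early when a round changes nothing, which also makes
#' the procedure idempotent at a fixed point.
#'
#' @param template a length-1 [Biostrings::QualityScaledDNAStringSet],
#'   `DNAString` or character string.
#' @param reads a [Biostrings::QualityScaledDNAStringSet] or character
#'   vector of read sequences (should already be filtered).
#' @param max_rounds maximum polishing rounds (default 3).
#' @param max_reads use at most this many reads, highest mean quality
#'   first when qualities are available (default 1000).
#' @param band_extra band half-width added beyond the length difference
#'   when aligning each read (default 200 nt, adequate for a few percent
#'   total error at 10 kb).
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2).
#' @return a [ConsensusSequence-class].
#' @examples
#' reads <- Biostrings::DNAStringSet(c("ACGTACGT", "ACGTACGT", "ACCTACGT"))
#' polishConsensus("ACCTACGT", as.character(reads))
#' @export
polishConsensus <- function(template, reads, max_rounds = 3L,
                            max_reads = 1000L, band_extra = 200L,
                            match = 1, mismatch = -1, gap = -2) {
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  if (is(reads, "QualityScaledDNAStringSet") && length(reads) > max_reads) {
    q <- meanReadQuality(reads)
    reads <- reads[order(-q, names(reads))[seq_len(max_reads)]]
  }
  read_seqs <- as_seq_character(reads)
  if (length(read_seqs) > max_reads)
    read_seqs <- read_seqs[seq_len(max_reads)]
  if (!length(read_seqs)) stop("cannot polish with zero reads")
  w <- if (is(template, "QualityScaledDNAStringSet") ||
           is(template, "XStringSet")) as.character(template[[1]])
       else as_seq_character(template)
  support <- rep(NA_integer_, nchar(w))
  rounds <- 0L
  for (round in seq_len(max_rounds)) {
    res <- polish_round(w, read_seqs, band_extra, match, mismatch, gap)
    rounds <- round
    support <- res$support
    if (identical(res$seq, w)) break
    w <- res$seq
  }
  new("ConsensusSequence", sequence = Biostrings::DNAString(w),
      support = support, roundsRun = rounds,
      nReadsUsed = length(read_seqs))
}
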