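# Translation, amplicon extraction, periodicity estimation and anchor-based
# tandem-repeat segmentation.

#' Translate a nucleotide sequence
#'
#' `mode = "fixed"` translates from a fixed frame offset, trimming any
#' trailing partial codon, and fails loudly on an internal stop codon
#' (naming its codon position).  `mode = "longest-orf"` returns the longest
#' stop-free translation across the three forward frames.  Standard genetic
#' code.
#'
#' @param nt nucleotide string (or `DNAString`).
#' @param mode `"fixed"` or `"longest-orf"`.
#' @param frame frame offset 1-3 for fixed mode (default 1).
#' @return a protein string (possibly empty for inputs shorter than one
#'   codon).
#' @examples
#' translateFrame("ATGGCC")  # "MA"
#' @export
translateFrame <- function(nt, mode = c("fixed", "longest-orf"), frame = 1L) {
  mode <- match.arg(mode)
  nt <- toupper(as_seq_character(nt))
  if (!nzchar(nt)) stop("input sequence must be non-empty")
  one_frame <- function(off) {
    n <- nchar(nt) - off + 1L
    n <- n - n %% 3L
    if (n < 3L) return("")
    x <- Biostrings::DNAString(substr(nt, off, off + n - 1L))
    as.character(Biostrings::translate(x, no.init.codon = TRUE))
  }
  if (mode == "fixed") {
    stopifnot(frame %in% 1:3)
    aa <- one_frame(as.integer(frame))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at > 0 && stop_at < nchar(aa))
      stop("internal stop codon at codon position ", stop_at,
           " in frame ", frame)
    sub("\\*$", "", aa)
  } else {
    best <- ""
    for (off in 1:3) {
      pieces <- strsplit(one_frame(off), "*", fixed = TRUE)[[1]]
      for (p in pieces) if (nchar(p) > nchar(best)) best <- p
    }
    best
  }
}

#' Extract the amplicon span between two primer sites
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the transcript (allowing up to `max_mismatch` mismatches) and
#' returns the inclusive span from the start of the forward site to the end
#' of the reverse site, mirroring an RT-PCR amplicon.
#'
#' @param transcript nucleotide string (or `DNAString`).
#' @param fwd_primer,rev_primer primer sequences, each >= 15 nt; the
#'   reverse primer is given in its own 5'->3' orientation.
#' @param max_mismatch mismatches tolerated per site (default 1).
#' @return the amplicon substring of `transcript`.
#' @export
extractAmplicon <- function(transcript, fwd_primer, rev_primer,
                            max_mismatch = 1L) {
  transcript <- toupper(as_seq_character(transcript))
  fwd_primer <- toupper(as_seq_character(fwd_primer))
  rev_primer <- toupper(as_seq_character(rev_primer))
  if (nchar(fwd_primer) < 15 || nchar(rev_primer) < 15)
    stop("primers must be at least 15 nt")
  subject <- Biostrings::DNAString(transcript)
  rev_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev_primer)))
  find_site <- function(pat, label) {
    m <- Biostrings::matchPattern(pat, subject,
                                  max.mismatch = as.integer(max_mismatch))
    if (length(m) != 1)
      stop(length(m), " candidate site(s) for the ", label, " primer",
           if (length(m)) paste0(" (at ",
                                 paste(IRanges::start(m), collapse = ", "),
                                 ")") else "",
           "; expected exactly one")
    m
  }
  f <- find_site(fwd_primer, "forward")
  r <- find_site(rev_site, "reverse")
  if (IRanges::start(f) >= IRanges::start(r))
    stop("forward primer site does not precede the reverse primer site")
  substr(transcript, IRanges::start(f), IRanges::end(r))
}

#' Estimate the repeat period from k-word positional offsets
#'
#' Builds the histogram of positional offsets between occurrences of
#' identical k-words and returns the modal nonzero offset — for a tandem
#' repeat domain, the repeat period.
#'
#' @param protein protein string (or `AAString`).
#' @param k word size (default 10).
#' @return integer period estimate in residues.
#' @examples
#' estimatePeriod(strrep("AB", 50), k = 2)  # 2
#' @export
estimatePeriod <- function(protein, k = 10L) {
  protein <- as_seq_character(protein)
  L <- nchar(protein)
  if (L < 2 * k) stop("sequence too short for word size k = ", k)
  starts <- seq_len(L - k + 1L)
  words <- substring(protein, starts, starts + k - 1L)
  pos_by_word <- split(starts, words)
  pos_by_word <- pos_by_word[lengths(pos_by_word) > 1L]
  if (!length(pos_by_word))
    stop("no periodicity detected: no repeated ", k, "-words")
  offs <- unlist(lapply(pos_by_word, function(p) diff(sort(p))),
                 use.names = FALSE)
  tab <- table(offs)
  as.integer(names(tab)[which.max(tab)])
}

# All overlapping match positions of a regex anchor.
anchor_matches <- function(protein, anchor) {
  m <- gregexpr(paste0("(?=", anchor, ")"), protein, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Segment a protein into numbered tandem repeat units
#'
#' Locates anchor-motif matches (default: the C-loop motif `C-x(19)-C`
#' conserved in every MUC16 repeat unit), chains them into one anchor per
#' unit, and places unit boundaries at a fixed offset upstream of each
#' anchor's first cysteine (default 58 residues, so canonical units carry
#' the cysteines at positions 59 and 79).  Each unit ends where the next
#' begins; the last unit ends one period after its start (or at the end of
#' the sequence, whichever comes first), and anchors further than
#' 1.5 periods past the previous one are treated as beyond the repeat
#' domain.  Units are numbered R1..Rn in sequence order.
#'
#' Anchor chaining is two-pass: a greedy pass (successive anchors at least
#' `min_spacing` residues apart) estimates the period as the median
#' inter-anchor gap unless `period_hint` is given; a refinement pass then
#' picks, within `[previous + min_spacing, previous + 1.5 * period]`, the
#' match closest to one period after the previous anchor, which keeps the
#' chain on the true anchors when sequence divergence creates incidental
#' cysteine pairs.
#'
#' @param protein protein string (or `AAString`).
#' @param anchor regular expression for the anchor motif
#'   (default `"C.{19}C"`).
#' @param period_hint optional known period in residues; required when the
#'   anchor occurs fewer than two times.
#' @param anchor_offset unit start offset upstream of the anchor
#'   (default 58).
#' @param min_spacing minimum spacing between successive anchors
#'   (default 40 residues).
#' @return a [RepeatAnnotation-class].
#' @examples
#' units <- as.character(muc16RepeatUnits())
#' ann <- segmentRepeats(paste(units, collapse = ""))
#' length(ann)  # 19
#' @export
segmentRepeats <- function(protein, anchor = "C.{19}C", period_hint = NULL,
                           anchor_offset = 58L, min_spacing = 40L) {
  protein <- as_seq_character(protein)
  L <- nchar(protein)
  matches <- anchor_matches(protein, anchor)
  if (length(matches) < 2 && is.null(period_hint))
    stop("fewer than two anchor matches and no period_hint; ",
         "cannot segment")
  if (!length(matches))
    stop("anchor motif '", anchor, "' not found")

  greedy_chain <- function(cands) {
    chain <- cands[1]
    for (p in cands[-1])
      if (p - chain[length(chain)] >= min_spacing) chain <- c(chain, p)
    chain
  }
  g <- greedy_chain(matches)
  period <- if (!is.null(period_hint)) as.numeric(period_hint)
            else median(diff(g))

  # refinement: anchor nearest previous + period, within 1.5 periods
  chain <- matches[1]
  repeat {
    prev <- chain[length(chain)]
    cand <- matches[matches - prev >= min_spacing &
                    matches - prev <= 1.5 * period]
    if (!length(cand)) break
    chain <- c(chain, cand[which.min(abs(cand - (prev + period)))])
  }

  starts <- pmax(1L, as.integer(chain) - as.integer(anchor_offset))
  ends <- c(starts[-1] - 1L,
            min(L, starts[length(starts)] + as.integer(round(period)) - 1L))
  seqs <- substring(protein, starts, ends)
  repeatAnnotation(starts, ends, seqs, period = period, anchor = anchor)
}

#' Align repeat units to the first unit and profile the columns
#'
#' Star alignment: every unit is globally aligned to the first (reference)
#' unit with protein scores +1/-1/-2 (match/mismatch/gap), units are
#' projected into reference-plus-insertion columns, per-column residue
#' counts are tabulated and the majority-residue consensus is emitted
#' (ties resolved to the reference unit's residue).  A deterministic,
#' dependency-free stand-in for a progressive multiple alignment, adequate
#' for the >80%-identical mucin repeat units.
#'
#' @param units character vector or `AAStringSet` of unit sequences, or a
#'   [RepeatAnnotation-class].
#' @param band_extra band half-width margin for the pairwise aligner
#'   (default 30 residues).
#' @return a list of class `RepeatProfile` with elements `columns`
#'   (residue-count matrix, symbols x columns, gap row `-`), `consensus`
#'   (protein string over reference columns), `conserved_positions`
#'   (columns where all units agree) and `alignment` (character matrix of
#'   projected units).
#' @export
profileRepeatUnits <- function(units, band_extra = 30L) {
  if (is(units, "RepeatAnnotation")) units <- units@sequences
  units <- as_seq_character(units)
  if (!length(units)) stop("need at least one unit")
  n <- length(units)
  ref <- units[1]
  Lr <- nchar(ref)
  # project each unit into reference coordinates; record insertions
  proj <- matrix("-", nrow = n, ncol = Lr)
  ins_key <- character(0); ins_unit <- integer(0); ins_sym <- character(0)
  for (i in seq_len(n)) {
    if (i == 1) { proj[1, ] <- s2c(ref); next }
    band <- abs(nchar(units[i]) - Lr) + band_extra
    al <- .banded_align_cpp(ref, units[i], band, 1, -1, -2)
    ca <- s2c(al$aligned_a); cb <- s2c(al$aligned_b)
    is_ref <- ca != "-"
    refpos <- cumsum(is_ref)
    proj[i, refpos[is_ref]] <- cb[is_ref]
    gi <- which(!is_ref)
    if (length(gi)) {
      pos <- seq_along(ca)
      last_ref <- cummax(ifelse(is_ref, pos, 0L))
      ins_key <- c(ins_key, paste(refpos[gi], gi - last_ref[gi], sep = ":"))
      ins_unit <- c(ins_unit, rep(i, length(gi)))
      ins_sym <- c(ins_sym, cb[gi])
    }
  }
  symbols <- sort(unique(c(as.vector(proj), "-")))
  counts <- vapply(seq_len(Lr),
                   function(j) tabulate(match(proj[, j], symbols),
                                        nbins = length(symbols)),
                   integer(length(symbols)))
  rownames(counts) <- symbols
  maxv <- do.call(pmax, lapply(seq_along(symbols), function(i) counts[i, ]))
  refcode <- match(s2c(ref), symbols)
  ref_is_max <- counts[cbind(refcode, seq_len(Lr))] == maxv
  pick <- ifelse(ref_is_max, refcode,
                 max.col(t(counts), ties.method = "first"))
  consensus <- c2s(symbols[pick])
  conserved <- which(apply(counts, 2, function(v) any(v == n)))
  # append insertion columns to the count matrix (labelled by slot)
  if (length(ins_key)) {
    for (k in unique(ins_key)) {
      sel <- ins_key == k
      v <- tabulate(match(ins_sym[sel], symbols), nbins = length(symbols))
      v[symbols == "-"] <- n - sum(sel)
      counts <- cbind(counts, matrix(v, ncol = 1,
                                     dimnames = list(NULL, paste0("ins", k))))
    }
  }
  structure(list(columns = counts, consensus = consensus,
                 conserved_positions = conserved, alignment = proj,
                 n_units = n),
            class = c("RepeatProfile", "list"))
}

#' Locate the C-loop cysteine pair of a repeat unit
#'
#' Scans for cysteine pairs with exactly `intervening` residues between
#' them (19 for the MUC16 C-loop).  Returns the unique such pair; when
#' several qualify, the most C-terminal pair is returned and flagged.
#'
#' @param unit protein string (or `AAString`) of one repeat unit.
#' @param intervening required number of residues strictly between the
#'   cysteines (default 19).
#' @return a list of class `CLoop`: `cys1`, `cys2` (1-based positions),
#'   `intervening`, and `multiple` (logical flag).
#' @examples
#' findCLoop(as.character(muc16RepeatUnits()[["R1"]]))  # 59, 79
#' @export
findCLoop <- function(unit, intervening = 19L) {
  unit <- as_seq_character(unit)
  if (!nzchar(unit)) stop("unit must be non-empty")
  cys <- as.integer(gregexpr("C", unit, fixed = TRUE)[[1]])
  if (cys[1] == -1) cys <- integer(0)
  gap <- as.integer(intervening) + 1L
  firsts <- cys[(cys + gap) %in% cys]
  if (!length(firsts))
    stop("no C-loop motif: no cysteine pair with ", intervening,
         " intervening residues")
  c1 <- firsts[length(firsts)]
  structure(list(cys1 = c1, cys2 = c1 + gap,
                 intervening = as.integer(intervening),
                 multiple = length(firsts) > 1L),
            class = c("CLoop", "list"))
}
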