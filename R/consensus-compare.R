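# Multi-source consensus building, difference counting, variant naming and
# glycosylation-sequon change assessment.

# Coerce a set of equal-length sequences to a character matrix (rows =
# entries). Unequal lengths are an error: the sources being combined have
# the same structure with no insertions or deletions, so alignment-free
# column-wise comparison is valid.
entry_matrix <- function(entries) {
  entries <- as_seq_character(entries)
  if (is.null(names(entries)) || anyDuplicated(names(entries)))
    stop("entries must have unique names")
  lens <- nchar(entries)
  if (length(unique(lens)) != 1)
    stop("entries must all have equal length (got ",
         paste(unique(lens), collapse = ", "),
         "); indel-containing sets are not supported")
  do.call(rbind, strsplit(toupper(entries), ""))
}

#' Column-majority consensus of equal-length sequences
#'
#' Emits the most frequent symbol per column.  Ties are broken first in
#' favor of the designated reference entry's symbol, then alphabetically;
#' tied columns are reported.
#'
#' @param entries named character vector (or `XStringSet`) of equal-length
#'   sequences; at least two.
#' @param reference name of the reference entry used for tie-breaking
#'   (default: the first entry).
#' @return a list with `consensus` (character string) and `ties` (data
#'   frame `position`, `symbols`, `resolved`).
#' @examples
#' majorityConsensus(c(a = "ACGT", b = "ACGA", c = "ACGT"))
#' @export
majorityConsensus <- function(entries, reference = NULL) {
  m <- entry_matrix(entries)
  if (nrow(m) < 2) stop("need at least two entries")
  if (is.null(reference)) reference <- rownames(m)[1]
  if (!reference %in% rownames(m))
    stop("reference entry '", reference, "' not found")
  L <- ncol(m)
  symbols <- sort(unique(as.vector(m)))
  counts <- vapply(seq_len(L),
                   function(j) tabulate(match(m[, j], symbols),
                                        nbins = length(symbols)),
                   integer(length(symbols)))
  maxv <- do.call(pmax, lapply(seq_along(symbols),
                               function(i) counts[i, , drop = TRUE]))
  refcode <- match(m[reference, ], symbols)
  ref_is_max <- counts[cbind(refcode, seq_len(L))] == maxv
  first_max <- max.col(t(counts), ties.method = "first")
  pick <- ifelse(ref_is_max, refcode, first_max)
  n_at_max <- vapply(seq_len(L), function(j) sum(counts[, j] == maxv[j]),
                     integer(1))
  tie_cols <- which(n_at_max > 1L)
  ties <- data.frame(
    position = tie_cols,
    symbols = vapply(tie_cols, function(j)
      paste(symbols[counts[, j] == maxv[j]], collapse = "/"), character(1)),
    resolved = symbols[pick[tie_cols]]
  )
  list(consensus = c2s(symbols[pick]), ties = ties)
}

#' Count positional differences between two equal-length sequences
#'
#' @param entry,consensus equal-length sequences (character or `XString`).
#' @return a list with `n` (Hamming distance) and `positions` (sorted
#'   1-based differing positions).
#' @examples
#' diffCount("ACGT", "ACCT")
#' @export
diffCount <- function(entry, consensus) {
  a <- toupper(as_seq_character(entry))
  b <- toupper(as_seq_character(consensus))
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length (", nchar(a), " vs ",
         nchar(b), ")")
  pos <- which(s2c(a) != s2c(b))
  list(n = length(pos), positions = pos)
}

#' Name amino acid variants in full-length coordinates
#'
#' Compares each entry's translation with the consensus translation and
#' names each difference `<ref><position + offset><alt>` (e.g. `S12536T`),
#' where `offset` maps amplicon protein coordinates to full-length isoform
#' numbering.  Synonymous nucleotide differences produce no record because
#' the comparison is at the amino acid level.  No default offset is
#' guessed: it depends on the N-terminal extent of the full-length
#' reference and must be supplied.
#'
#' @param translations named character vector (or `AAStringSet`) of entry
#'   translations, all of equal length.
#' @param consensus_translation the consensus translation (same length).
#' @param offset integer added to amplicon protein positions to obtain
#'   full-length positions.
#' @return a data frame with columns `source`, `position` (amplicon
#'   protein coordinates), `ref`, `alt`, `name`.
#' @export
variantNames <- function(translations, consensus_translation, offset) {
  if (missing(offset) || length(offset) != 1 || is.na(offset))
    stop("a full-length numbering offset must be supplied")
  offset <- as.integer(offset)
  translations <- as_seq_character(translations)
  cons <- toupper(as_seq_character(consensus_translation))
  if (is.null(names(translations)))
    names(translations) <- paste0("entry_", seq_along(translations))
  rows <- lapply(names(translations), function(nm) {
    d <- diffCount(translations[[nm]], cons)
    if (!d$n) return(NULL)
    refc <- s2c(cons)[d$positions]
    altc <- s2c(toupper(translations[[nm]]))[d$positions]
    data.frame(source = nm, position = d$positions, ref = refc, alt = altc,
               name = paste0(refc, d$positions + offset, altc))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      name = character(0))
  rownames(out) <- NULL
  out
}

# All N-glycosylation sequon start positions (N-X-[S/T], X != P) in a
# protein string.
sequon_starts <- function(protein) {
  aa <- s2c(protein)
  L <- length(aa)
  if (L < 3) return(integer(0))
  i <- seq_len(L - 2L)
  i[aa[i] == "N" & aa[i + 1L] != "P" & aa[i + 2L] %in% c("S", "T")]
}

#' Assess glycosylation-site change at a single-residue substitution
#'
#' For two protein sequences differing at exactly one position, scans the
#' window of sequon starts that the substitution can affect
#' (`[position - 2, position]`) for the N-linked glycosylation motif
#' N-X-[S/T] (X not proline) and reports sequons present only in the
#' reference (removed) or only in the alternate (added).  Separately
#' reports whether a serine/threonine residue — a possible O-linked
#' glycosylation site — was gained or lost at the substituted position.
#'
#' @param ref_protein,alt_protein equal-length protein strings differing
#'   at exactly one position.
#' @return a list of class `GlycoDelta`: `position`, `ref`, `alt`,
#'   `sequons_removed`, `sequons_added` (sequon start positions),
#'   `o_site` (`"gained"`, `"lost"` or `"none"`).
#' @examples
#' glycoSiteDelta("NAS", "NAA")  # sequon removed
#' @export
glycoSiteDelta <- function(ref_protein, alt_protein) {
  a <- toupper(as_seq_character(ref_protein))
  b <- toupper(as_seq_character(alt_protein))
  d <- diffCount(a, b)
  if (d$n != 1)
    stop("sequences must differ at exactly one position (found ", d$n, ")")
  pos <- d$positions
  win <- seq(max(1L, pos - 2L), pos)
  sa <- intersect(sequon_starts(a), win)
  sb <- intersect(sequon_starts(b), win)
  ra <- s2c(a)[pos]; rb <- s2c(b)[pos]
  o_site <- if (!(ra %in% c("S", "T")) && rb %in% c("S", "T")) "gained"
            else if (ra %in% c("S", "T") && !(rb %in% c("S", "T"))) "lost"
            else "none"
  structure(list(position = pos, ref = ra, alt = rb,
                 sequons_removed = setdiff(sa, sb),
                 sequons_added = setdiff(sb, sa),
                 o_site = o_site),
            class = c("GlycoDelta", "list"))
}
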