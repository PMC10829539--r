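#' Ordered tandem-repeat annotation of a protein
#'
#' Records the ordered, contiguous repeat-unit intervals (1-based, inclusive,
#' protein coordinates) recovered from a mucin-type tandem repeat domain,
#' together with the per-unit sequences, the period estimate and the anchor
#' motif used for segmentation.  Units are numbered R1..Rn in sequence order.
#'
#' @slot ranges an [IRanges::IRanges] of unit intervals, named R1..Rn.
#' @slot sequences an [Biostrings::AAStringSet] of unit sequences, parallel
#'   to `ranges`.
#' @slot period numeric(1), the repeat period estimate in residues.
#' @slot anchor character(1), the anchor motif pattern (regular expression).
#'
#' @seealso [segmentRepeats()], [repeatAnnotation()]
#' @exportClass RepeatAnnotation
setClass("RepeatAnnotation",
  representation(
    ranges = "IRanges",
    sequences = "AAStringSet",
    period = "numeric",
    anchor = "character"
  )
)

setValidity("RepeatAnnotation", function(object) {
  rng <- object@ranges
  n <- length(rng)
  msg <- character()
  if (length(object@sequences) != n)
    msg <- c(msg, "length(sequences) must equal length(ranges)")
  if (n > 0) {
    if (!identical(names(rng), paste0("R", seq_len(n))))
      msg <- c(msg, "units must be named R1..Rn in order")
    if (is.unsorted(IRanges::start(rng), strictly = TRUE))
      msg <- c(msg, "unit starts must be strictly increasing")
    if (n > 1 &&
        !all(IRanges::start(rng)[-1] == IRanges::end(rng)[-n] + 1L))
      msg <- c(msg, "units must tile the repeat domain contiguously")
    if (!all(IRanges::width(rng) ==
             Biostrings::width(object@sequences)))
      msg <- c(msg, "unit widths must match sequence lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RepeatAnnotation
#'
#' @param starts,ends integer vectors of 1-based inclusive unit intervals.
#' @param sequences character vector or `AAStringSet` of unit sequences.
#' @param period numeric(1) period estimate (residues).
#' @param anchor character(1) anchor motif pattern.
#' @return a [RepeatAnnotation-class] object.
#' @examples
#' repeatAnnotation(1, 10, paste(rep("A", 10), collapse = ""), period = 10)
#' @export
repeatAnnotation <- function(starts, ends, sequences,
                             period = NA_real_, anchor = NA_character_) {
  if (is.character(sequences)) sequences <- Biostrings::AAStringSet(sequences)
  rng <- IRanges::IRanges(start = as.integer(starts), end = as.integer(ends),
                          names = paste0("R", seq_along(starts)))
  names(sequences) <- names(rng)
  new("RepeatAnnotation", ranges = rng, sequences = sequences,
      period = as.numeric(period), anchor = as.character(anchor))
}

#' Polished consensus sequence with per-column support
#'
#' The product of pileup-majority polishing: the consensus nucleotide
#' sequence, the number of reads agreeing with each retained column, the
#' number of polishing rounds actually run and the number of reads used.
#'
#' @slot sequence a [Biostrings::DNAString].
#' @slot support integer vector, per-column count of agreeing reads.
#' @slot roundsRun integer(1).
#' @slot nReadsUsed integer(1).
#'
#' @seealso [polishConsensus()]
#' @exportClass ConsensusSequence
setClass("ConsensusSequence",
  representation(
    sequence = "DNAString",
    support = "integer",
    roundsRun = "integer",
    nReadsUsed = "integer"
  )
)

setValidity("ConsensusSequence", function(object) {
  msg <- character()
  if (length(object@support) != length(object@sequence))
    msg <- c(msg, "length(support) must equal sequence length")
  if (any(object@support > object@nReadsUsed))
    msg <- c(msg, "support cannot exceed the number of reads used")
  if (any(object@support < 0L))
    msg <- c(msg, "support must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A named protein model with repeat annotation
#'
#' Bundles a protein sequence with its tandem-repeat annotation and a region
#' of interest given as repeat numbers (by default repeats 8-12, the five
#' repeats present in MUC16 isoform 3 but absent from isoform 4).  This is
#' the object that gets digested, mapped against, and compared.
#'
#' @slot name character(1).
#' @slot sequence an [Biostrings::AAString].
#' @slot repeats a [RepeatAnnotation-class].
#' @slot regionOfInterest integer vector of repeat numbers.
#'
#' @seealso [proteinModel()], [digestProtein()], [mapPeptides()]
#' @exportClass ProteinModel
setClass("ProteinModel",
  representation(
    name = "character",
    sequence = "AAString",
    repeats = "RepeatAnnotation",
    regionOfInterest = "integer"
  )
)

setValidity("ProteinModel", function(object) {
  msg <- character()
  rng <- object@repeats@ranges
  if (length(rng) &&
      max(IRanges::end(rng)) > length(object@sequence))
    msg <- c(msg, "repeat intervals must lie within the protein sequence")
  if (length(rng) && min(IRanges::start(rng)) < 1L)
    msg <- c(msg, "repeat intervals must start at >= 1")
  bad <- setdiff(object@regionOfInterest, seq_along(rng))
  if (length(rng) && length(bad))
    msg <- c(msg, paste0("regionOfInterest names unknown repeats: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinModel
#'
#' @param name character(1) model name.
#' @param sequence protein sequence (character or `AAString`).
#' @param repeats a [RepeatAnnotation-class]; if missing, computed with
#'   [segmentRepeats()] default settings.
#' @param regionOfInterest integer vector of repeat numbers
#'   (default `8:12`).
#' @return a [ProteinModel-class] object.
#' @export
proteinModel <- function(name, sequence, repeats = NULL,
                         regionOfInterest = 8:12) {
  sequence <- Biostrings::AAString(as_seq_character(sequence))
  if (is.null(repeats))
    repeats <- segmentRepeats(as.character(sequence))
  regionOfInterest <- intersect(as.integer(regionOfInterest),
                                seq_along(repeats@ranges))
  new("ProteinModel", name = as.character(name), sequence = sequence,
      repeats = repeats, regionOfInterest = regionOfInterest)
}

#' Three-way digest comparison between two protein models
#'
#' Partition of the union of two in silico digest peptide sets into peptides
#' common to both models and peptides unique to either, with percentages of
#' the union (rounded to one decimal).
#'
#' @slot nameA,nameB character(1) model names.
#' @slot common,onlyA,onlyB character vectors of distinct peptide sequences.
#' @slot pctCommon,pctOnlyA,pctOnlyB numeric(1) percentages of the union.
#'
#' @seealso [compareModels()]
#' @exportClass VennReport
setClass("VennReport",
  representation(
    nameA = "character", nameB = "character",
    common = "character", onlyA = "character", onlyB = "character",
    pctCommon = "numeric", pctOnlyA = "numeric", pctOnlyB = "numeric"
  )
)

setValidity("VennReport", function(object) {
  msg <- character()
  if (length(intersect(object@common, object@onlyA)) ||
      length(intersect(object@common, object@onlyB)) ||
      length(intersect(object@onlyA, object@onlyB)))
    msg <- c(msg, "common/onlyA/onlyB must be disjoint")
  tot <- object@pctCommon + object@pctOnlyA + object@pctOnlyB
  if (length(object@common) + length(object@onlyA) + length(object@onlyB) > 0 &&
      abs(tot - 100) > 0.1)
    msg <- c(msg, "percentages must sum to 100 within rounding")
  if (length(msg)) msg else TRUE
})
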