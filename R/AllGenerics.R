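# Generics and simple methods (accessors, show) for the package classes.

#' @describeIn RepeatAnnotation-class number of repeat units
#' @param x a `RepeatAnnotation`
#' @export
setMethod("length", "RepeatAnnotation", function(x) length(x@ranges))

#' Repeat-unit intervals
#'
#' @param x a [RepeatAnnotation-class] or [ProteinModel-class].
#' @return an `IRanges` of 1-based inclusive unit intervals named R1..Rn.
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))

#' @rdname repeatRanges
#' @export
setMethod("repeatRanges", "RepeatAnnotation", function(x) x@ranges)

#' @rdname repeatRanges
#' @export
setMethod("repeatRanges", "ProteinModel", function(x) x@repeats@ranges)

#' Repeat-unit sequences
#'
#' @param x a [RepeatAnnotation-class] or [ProteinModel-class].
#' @return an `AAStringSet` of unit sequences named R1..Rn.
#' @export
setGeneric("repeatSequences", function(x) standardGeneric("repeatSequences"))

#' @rdname repeatSequences
#' @export
setMethod("repeatSequences", "RepeatAnnotation", function(x) x@sequences)

#' @rdname repeatSequences
#' @export
setMethod("repeatSequences", "ProteinModel", function(x) x@repeats@sequences)

#' Estimated repeat period in residues
#'
#' @param x a [RepeatAnnotation-class].
#' @return numeric(1).
#' @export
setGeneric("periodEstimate", function(x) standardGeneric("periodEstimate"))

#' @rdname periodEstimate
#' @export
setMethod("periodEstimate", "RepeatAnnotation", function(x) x@period)

setMethod("show", "RepeatAnnotation", function(object) {
  n <- length(object)
  cat("RepeatAnnotation with", n, "unit(s)\n")
  if (n) {
    w <- IRanges::width(object@ranges)
    cat("  span: ", min(IRanges::start(object@ranges)), "-",
        max(IRanges::end(object@ranges)),
        "  unit lengths: ", paste(range(w), collapse = "-"),
        "  period estimate: ", object@period, "\n", sep = "")
  }
})

#' Consensus sequence accessors
#'
#' @param x a [ConsensusSequence-class].
#' @return `consensusSequence`: a `DNAString`; `columnSupport`: integer
#'   per-column agreeing-read counts; `roundsRun` / `nReadsUsed`:
#'   integer(1).
#' @name ConsensusSequence-accessors
NULL

#' @rdname ConsensusSequence-accessors
#' @export
setGeneric("consensusSequence",
           function(x) standardGeneric("consensusSequence"))

#' @rdname ConsensusSequence-accessors
#' @export
setMethod("consensusSequence", "ConsensusSequence", function(x) x@sequence)

#' @rdname ConsensusSequence-accessors
#' @export
setGeneric("columnSupport", function(x) standardGeneric("columnSupport"))

#' @rdname ConsensusSequence-accessors
#' @export
setMethod("columnSupport", "ConsensusSequence", function(x) x@support)

#' @rdname ConsensusSequence-accessors
#' @export
setGeneric("roundsRun", function(x) standardGeneric("roundsRun"))

#' @rdname ConsensusSequence-accessors
#' @export
setMethod("roundsRun", "ConsensusSequence", function(x) x@roundsRun)

#' @rdname ConsensusSequence-accessors
#' @export
setGeneric("nReadsUsed", function(x) standardGeneric("nReadsUsed"))

#' @rdname ConsensusSequence-accessors
#' @export
setMethod("nReadsUsed", "ConsensusSequence", function(x) x@nReadsUsed)

setMethod("show", "ConsensusSequence", function(object) {
  cat("ConsensusSequence of length", length(object@sequence),
      "nt (", object@roundsRun, "round(s),", object@nReadsUsed, "reads)\n")
  if (length(object@support))
    cat("  median column support:", median(object@support), "\n")
})

setMethod("as.character", "ConsensusSequence",
          function(x) as.character(x@sequence))

#' ProteinModel accessors
#'
#' @param x a [ProteinModel-class].
#' @name ProteinModel-accessors
NULL

#' @rdname ProteinModel-accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname ProteinModel-accessors
#' @export
setMethod("modelName", "ProteinModel", function(x) x@name)

#' @rdname ProteinModel-accessors
#' @export
setGeneric("modelSequence", function(x) standardGeneric("modelSequence"))

#' @rdname ProteinModel-accessors
#' @export
setMethod("modelSequence", "ProteinModel", function(x) x@sequence)

#' @rdname ProteinModel-accessors
#' @export
setGeneric("modelRepeats", function(x) standardGeneric("modelRepeats"))

#' @rdname ProteinModel-accessors
#' @export
setMethod("modelRepeats", "ProteinModel", function(x) x@repeats)

#' @rdname ProteinModel-accessors
#' @export
setGeneric("regionOfInterest", function(x) standardGeneric("regionOfInterest"))

#' @rdname ProteinModel-accessors
#' @export
setMethod("regionOfInterest", "ProteinModel", function(x) x@regionOfInterest)

setMethod("show", "ProteinModel", function(object) {
  cat("ProteinModel '", object@name, "': ", length(object@sequence),
      " aa, ", length(object@repeats), " repeat unit(s), region of interest {",
      paste(object@regionOfInterest, collapse = ","), "}\n", sep = "")
})

#' VennReport accessors
#'
#' @param x a [VennReport-class].
#' @return `vennCounts`: named integer vector (common, only_a, only_b);
#'   `vennPercentages`: named numeric vector summing to 100 within
#'   rounding; `vennPeptides`: named list of the three peptide sets.
#' @name VennReport-accessors
NULL

#' @rdname VennReport-accessors
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' @rdname VennReport-accessors
#' @export
setMethod("vennCounts", "VennReport", function(x)
  c(common = length(x@common), only_a = length(x@onlyA),
    only_b = length(x@onlyB)))

#' @rdname VennReport-accessors
#' @export
setGeneric("vennPercentages", function(x) standardGeneric("vennPercentages"))

#' @rdname VennReport-accessors
#' @export
setMethod("vennPercentages", "VennReport", function(x)
  c(common = x@pctCommon, only_a = x@pctOnlyA, only_b = x@pctOnlyB))

#' @rdname VennReport-accessors
#' @export
setGeneric("vennPeptides", function(x) standardGeneric("vennPeptides"))

#' @rdname VennReport-accessors
#' @export
setMethod("vennPeptides", "VennReport", function(x)
  list(common = x@common, only_a = x@onlyA, only_b = x@onlyB))

setMethod("show", "VennReport", function(object) {
  cnt <- vennCounts(object)
  cat("VennReport: ", object@nameA, " vs ", object@nameB, "\n",
      "  common: ", cnt[["common"]], " (", object@pctCommon, "%)\n",
      "  only ", object@nameA, ": ", cnt[["only_a"]],
      " (", object@pctOnlyA, "%)\n",
      "  only ", object@nameB, ": ", cnt[["only_b"]],
      " (", object@pctOnlyB, "%)\n", sep = "")
})
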