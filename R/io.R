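# File I/O helpers and packaged reference data.

#' The 19 consensus tandem repeat units of the revised MUC16 model
#'
#' Amino acid sequences of repeat units R1-R19 of the 19-repeat MUC16
#' (CA125) consensus model derived from long-read cDNA sequencing of six
#' sources.  Units R1-R16 are 155-158 residues with the conserved C-loop
#' cysteines at positions 59 and 79; the terminal units R17-R19 are shorter
#' and shift the C-loop by a few residues (58/78 in R17 and R19, 52/72 in
#' R18).
#'
#' @return an [Biostrings::AAStringSet] named `R1`..`R19`.
#' @examples
#' units <- muc16RepeatUnits()
#' Biostrings::width(units)
#' @export
muc16RepeatUnits <- function() {
  path <- system.file("extdata", "muc16_repeat_units.fasta",
                      package = "muc16tr", mustWork = TRUE)
  Biostrings::readAAStringSet(path)
}

#' Read long reads from a FASTQ file
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastqReads <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}

#' Write long reads to a FASTQ file
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output FASTQ file (Phred+33 qualities).
#' @return `path`, invisibly.
#' @export
writeFastqReads <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Read a peptide list from a plain list or CSV/TSV export
#'
#' Accepts either a plain one-peptide-per-line text file or a delimited
#' table with a named peptide column (as exported by proteomics search
#' engines).  Modification annotations in parentheses or brackets, e.g.
#' `N(+.98)`, and flanking-residue notation `K.PEPTIDER.A` are stripped.
#'
#' @param path input file.
#' @param column name of the peptide column for tabular input (default
#'   `"Peptide"`, matched case-insensitively).
#' @return character vector of plain peptide sequences.
#' @export
readPeptideList <- function(path, column = "Peptide") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(character(0))
  delim <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1]))
    "," else NULL
  if (!is.null(delim)) {
    tab <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                    check.names = FALSE)
    hit <- which(tolower(names(tab)) == tolower(column))
    if (length(hit) != 1)
      stop("no unique '", column, "' column in ", path)
    peps <- as.character(tab[[hit]])
  } else {
    peps <- lines
  }
  cleanPeptideStrings(peps)
}

# Strip search-engine decorations from peptide strings.
cleanPeptideStrings <- function(peps) {
  peps <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", peps)
  flanked <- grepl("^[A-Z-]\\..+\\.[A-Z-]$", peps)
  peps[flanked] <- sub("^[A-Z-]\\.", "", sub("\\.[A-Z-]$", "", peps[flanked]))
  toupper(gsub("[^A-Za-z]", "", peps))
}

#' Write named sequences to FASTA
#'
#' @param x named character vector, `XStringSet`, or single sequence.
#' @param path output file.
#' @param type `"DNA"` or `"AA"` for character input.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, type = c("DNA", "AA")) {
  if (!is(x, "XStringSet")) {
    type <- match.arg(type)
    x <- as_seq_character(x)
    if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
    x <- if (type == "DNA") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
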