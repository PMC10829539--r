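# Synthetic MUC16-like gene models, noisy long reads and sampled peptide
# observations.  Everything is a pure function of (spec, seed).

#' Specification of a synthetic MUC16-like gene model
#'
#' Defaults reproduce the geometry of the revised MUC16 amplicon: a
#' 200-residue N-terminal fragment, 19 tandem repeats of 156 residues and a
#' 276-residue C-terminal domain, i.e. a 3,440-aa protein encoded by a
#' 10,322-nt amplicon (the coding sequence plus the first two bases of the
#' stop codon).  Repeat units diverge from a common ancestor by independent
#' per-site substitution, except at protected positions (the C-loop
#' cysteines 59 and 79, invariant in all real units).
#'
#' @param n_repeats integer, number of repeat units (default 19).
#' @param repeat_len integer, residues per unit (default 156).
#' @param n_flank_len integer, N-terminal fragment length (default 200).
#' @param c_term_len integer, C-terminal domain length (default 276).
#' @param ancestral_repeat `"auto"` or a protein string of length
#'   `repeat_len` with cysteine at the protected positions.  `"auto"` uses
#'   the first MUC16 consensus repeat unit when `repeat_len` is 156, and a
#'   seeded cysteine-free random sequence with planted cysteines otherwise.
#' @param divergence per-site substitution probability between units
#'   (default 0.05).
#' @param protected_positions 1-based unit positions never mutated
#'   (default `c(59, 79)`).
#' @param seed integer RNG seed.
#' @return a classed list (`GeneModelSpec`).
#' @examples
#' spec <- geneModelSpec(seed = 1)
#' @export
geneModelSpec <- function(n_repeats = 19L, repeat_len = 156L,
                          n_flank_len = 200L, c_term_len = 276L,
                          ancestral_repeat = "auto", divergence = 0.05,
                          protected_positions = c(59L, 79L), seed = 1L) {
  stopifnot(n_repeats >= 1, repeat_len >= 1,
            n_flank_len >= 0, c_term_len >= 0,
            divergence >= 0, divergence < 1)
  spec <- structure(list(
    n_repeats = as.integer(n_repeats),
    repeat_len = as.integer(repeat_len),
    n_flank_len = as.integer(n_flank_len),
    c_term_len = as.integer(c_term_len),
    ancestral_repeat = ancestral_repeat,
    divergence = divergence,
    protected_positions = as.integer(protected_positions),
    seed = as.integer(seed)
  ), class = c("GeneModelSpec", "list"))
  pp <- spec$protected_positions
  if (any(pp < 1L | pp > spec$repeat_len))
    stop("protected positions must lie within the repeat unit")
  anc <- resolve_ancestor(spec)
  if (nchar(anc) != spec$repeat_len)
    stop("ancestral repeat length (", nchar(anc),
         ") must equal repeat_len (", spec$repeat_len, ")")
  if (!all(s2c(anc)[pp] == "C"))
    stop("ancestral repeat must carry cysteine at the protected positions (",
         paste(pp, collapse = ", "),
         "): the C-loop cysteines are invariant in MUC16 repeats")
  spec
}

# Materialize the ancestral repeat unit for a spec.
resolve_ancestor <- function(spec) {
  if (!identical(spec$ancestral_repeat, "auto"))
    return(toupper(spec$ancestral_repeat))
  if (spec$repeat_len == 156L)
    return(as.character(muc16RepeatUnits()[["R1"]]))
  # seeded cysteine-free draw with cysteines planted at protected positions
  with_seed(spec$seed + 104729L, {
    x <- sample(setdiff(AA20, "C"), spec$repeat_len, replace = TRUE)
    x[spec$protected_positions] <- "C"
    c2s(x)
  })
}

#' Generate a family of diverged repeat units
#'
#' Derives `n_repeats` units from the ancestral repeat by independent
#' per-site substitution with probability `divergence`, replacing each
#' mutated residue uniformly by one of the 19 other residues.  Protected
#' positions (the C-loop cysteines) are never touched.
#'
#' @param spec a [geneModelSpec()].
#' @return character vector of `n_repeats` protein strings.
#' @examples
#' fam <- makeRepeatFamily(geneModelSpec(n_repeats = 3, seed = 1))
#' @export
makeRepeatFamily <- function(spec) {
  stopifnot(inherits(spec, "GeneModelSpec"))
  anc <- s2c(resolve_ancestor(spec))
  pp <- spec$protected_positions
  mutable <- setdiff(seq_along(anc), pp)
  with_seed(spec$seed, {
    vapply(seq_len(spec$n_repeats), function(i) {
      unit <- anc
      hit <- mutable[runif(length(mutable)) < spec$divergence]
      if (length(hit)) {
        repl <- vapply(anc[hit], function(a)
          sample(setdiff(AA20, a), 1L), character(1))
        unit[hit] <- repl
      }
      c2s(unit)
    }, character(1))
  })
}

#' Assemble the full synthetic gene model
#'
#' Builds the ground-truth bundle: protein (N-terminal fragment + diverged
#' repeat units + C-terminal domain), coding sequence (deterministic
#' back-translation using the most frequent human codon per residue),
#' amplicon (CDS plus the first two bases of the stop codon, matching the
#' published amplicon phase) and the exact repeat-interval truth table.
#' The flanking domains are generated cysteine-free so that the C-x(19)-C
#' anchor motif occurs only inside the repeat domain.
#'
#' @param spec a [geneModelSpec()].
#' @return a list with elements `protein`, `cds`, `amplicon` (character)
#'   and `annotation` (a [RepeatAnnotation-class] giving the true unit
#'   intervals).
#' @examples
#' truth <- assembleGeneModel(geneModelSpec(seed = 1))
#' nchar(truth$protein)   # 3440
#' nchar(truth$amplicon)  # 10322
#' @export
assembleGeneModel <- function(spec) {
  stopifnot(inherits(spec, "GeneModelSpec"))
  units <- makeRepeatFamily(spec)
  flanks <- with_seed(spec$seed + 7919L, {
    pool <- setdiff(AA20, "C")
    list(
      n = c2s(sample(pool, spec$n_flank_len, replace = TRUE)),
      c = c2s(sample(pool, spec$c_term_len, replace = TRUE))
    )
  })
  protein <- paste0(flanks$n, paste(units, collapse = ""), flanks$c)
  cds <- backTranslate(protein)
  amplicon <- paste0(cds, substr(HUMAN_CODON[["*"]], 1, 2))
  starts <- spec$n_flank_len + (seq_len(spec$n_repeats) - 1L) *
    spec$repeat_len + 1L
  ends <- starts + spec$repeat_len - 1L
  ann <- repeatAnnotation(starts, ends, units, period = spec$repeat_len,
                          anchor = "C.{19}C")
  list(protein = protein, cds = cds, amplicon = amplicon, annotation = ann)
}

#' Deterministic back-translation
#'
#' Maps each residue to the most frequent human codon; reproducible
#' nucleotide-level truth without modeling codon bias.
#'
#' @param protein protein string.
#' @return nucleotide string of length `3 * nchar(protein)`.
#' @export
backTranslate <- function(protein) {
  aa <- s2c(toupper(as_seq_character(protein)))
  bad <- setdiff(unique(aa), names(HUMAN_CODON))
  if (length(bad))
    stop("cannot back-translate residue(s): ", paste(bad, collapse = ", "))
  paste(HUMAN_CODON[aa], collapse = "")
}

#' Error profile for simulated long reads
#'
#' Emulates filtered nanopore-style reads: independent per-base
#' substitution, insertion and deletion, with Phred qualities drawn around
#' `quality_mean` (a per-read offset plus per-base jitter; the qualities
#' are assigned, not calibrated to the simulated error process).
#'
#' @param sub_rate,ins_rate,del_rate per-base error probabilities in
#'   `[0, 1)` (defaults 0.01 each).
#' @param quality_mean mean assigned Phred quality (default 24).
#' @param truncation_prob probability a read is truncated (default 0);
#'   truncated reads keep the 3' end with probability 0.5.
#' @param seed integer RNG seed.
#' @return a classed list (`ReadErrorProfile`).
#' @export
readErrorProfile <- function(sub_rate = 0.01, ins_rate = 0.01,
                             del_rate = 0.01, quality_mean = 24,
                             truncation_prob = 0, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates >= 1))
    stop("error rates must lie in [0, 1)")
  if (truncation_prob < 0 || truncation_prob > 1)
    stop("truncation_prob must lie in [0, 1]")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, quality_mean = quality_mean,
                 truncation_prob = truncation_prob, seed = as.integer(seed)),
            class = c("ReadErrorProfile", "list"))
}

#' Simulate noisy long reads from an amplicon
#'
#' Corrupts the amplicon base by base (deletion, then substitution, then
#' insertion after the base, each at the profile's rate), optionally
#' truncates, and assigns per-base Phred qualities.  Deterministic under
#' the profile seed.
#'
#' @param amplicon nucleotide string (or `DNAString`).
#' @param n_reads number of reads (>= 1).
#' @param profile a [readErrorProfile()].
#' @return a [Biostrings::QualityScaledDNAStringSet] named `read_1..n`.
#' @examples
#' reads <- simulateReads("ACGTACGTACGT", 3, readErrorProfile(seed = 1))
#' @export
simulateReads <- function(amplicon, n_reads, profile = readErrorProfile()) {
  amplicon <- toupper(as_seq_character(amplicon))
  if (nchar(amplicon) == 0) stop("amplicon must be non-empty")
  if (n_reads < 1) stop("n_reads must be >= 1")
  stopifnot(inherits(profile, "ReadErrorProfile"))
  tmpl <- s2c(amplicon)
  L <- length(tmpl)
  out <- with_seed(profile$seed, {
    lapply(seq_len(n_reads), function(i) {
      keep <- runif(L) >= profile$del_rate
      base <- tmpl
      sub <- runif(L) < profile$sub_rate
      if (any(sub))
        base[sub] <- vapply(base[sub], function(b)
          sample(setdiff(DNA4, b), 1L), character(1))
      ins <- runif(L) < profile$ins_rate
      pieces <- base
      pieces[!keep] <- ""
      if (any(ins))
        pieces[ins] <- paste0(pieces[ins], sample(DNA4, sum(ins),
                                                  replace = TRUE))
      seq <- paste(pieces, collapse = "")
      if (runif(1) < profile$truncation_prob && nchar(seq) > 1) {
        n <- nchar(seq)
        keep_n <- sample(seq(max(1L, floor(n / 2)), n - 1L), 1L)
        seq <- if (runif(1) < 0.5) substr(seq, n - keep_n + 1L, n)
               else substr(seq, 1L, keep_n)
      }
      read_off <- rnorm(1, 0, 1.5)
      q <- round(rnorm(nchar(seq), profile$quality_mean + read_off, 3))
      q <- pmin(pmax(q, 2L), 60L)
      list(seq = seq, qual = as.integer(q))
    })
  })
  seqs <- Biostrings::DNAStringSet(vapply(out, `[[`, character(1), "seq"))
  names(seqs) <- paste0("read_", seq_len(n_reads))
  quals <- Biostrings::PhredQuality(vapply(out, function(r)
    rawToChar(as.raw(r$qual + 33L)), character(1)))
  Biostrings::QualityScaledDNAStringSet(seqs, quals)
}

#' Specification for sampled peptide observations
#'
#' @param detection_prob probability each distinct digest peptide is
#'   observed, in `[0, 1]` (default 0.5).
#' @param digest_config a [digestConfig()].
#' @param seed integer RNG seed.
#' @return a classed list (`PeptideObservationSpec`).
#' @export
peptideObservationSpec <- function(detection_prob = 0.5,
                                   digest_config = digestConfig(),
                                   seed = 1L) {
  if (detection_prob < 0 || detection_prob > 1)
    stop("detection_prob must lie in [0, 1]")
  structure(list(detection_prob = detection_prob,
                 digest_config = digest_config, seed = as.integer(seed)),
            class = c("PeptideObservationSpec", "list"))
}

#' Simulate observed peptides from a tryptic digest
#'
#' Digests the protein in silico and retains each distinct peptide
#' independently with the detection probability; a stand-in for a search
#' engine's peptide export.  Observed peptides are always a subset of the
#' truth digest.
#'
#' @param protein protein string.
#' @param spec a [peptideObservationSpec()].
#' @return character vector of observed peptide sequences (sorted).
#' @export
simulatePeptideObservations <- function(protein,
                                        spec = peptideObservationSpec()) {
  stopifnot(inherits(spec, "PeptideObservationSpec"))
  dig <- digestProtein(protein, spec$digest_config)
  peps <- sort(unique(dig$peptide))
  keep <- with_seed(spec$seed, runif(length(peps)) < spec$detection_prob)
  peps[keep]
}
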