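# In silico tryptic digestion, peptide mapping, uniqueness classification,
# coverage and two-model digest comparison.

#' Digest configuration
#'
#' Defaults mirror common database-search settings for mucin proteomics:
#' trypsin (cleave C-terminal to K or R, but not when the next residue is
#' proline), up to 3 missed cleavages, peptides of 6-45 residues.
#'
#' @param enzyme currently only `"trypsin"`.
#' @param max_missed maximum internal missed cleavage sites (default 3).
#' @param min_len,max_len peptide length bounds in residues, inclusive
#'   (defaults 6 and 45).
#' @return a classed list (`DigestConfig`).
#' @export
digestConfig <- function(enzyme = "trypsin", max_missed = 3L,
                         min_len = 6L, max_len = 45L) {
  enzyme <- match.arg(enzyme)
  if (max_missed < 0) stop("max_missed must be >= 0")
  if (min_len > max_len) stop("min_len must be <= max_len")
  structure(list(enzyme = enzyme, max_missed = as.integer(max_missed),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = c("DigestConfig", "list"))
}

# 0-based cleavage boundaries of a protein under the trypsin rule
# (after K/R, not before P), including 0 and nchar.
tryptic_boundaries <- function(protein) {
  aa <- s2c(protein)
  L <- length(aa)
  site <- aa %in% c("K", "R") & c(aa[-1] != "P", FALSE)
  c(0L, which(site), L)
}

#' In silico tryptic digest
#'
#' Enumerates fully tryptic peptides with up to `max_missed` internal
#' cleavage sites, filtered to the configured length range.  Peptides are
#' reported with distinct-sequence semantics: a sequence occurring at
#' several loci appears once (mass spectrometry cannot distinguish
#' copies).  Isoleucine and leucine are treated as distinct characters.
#'
#' @param protein protein string (or `AAString` / [ProteinModel-class]).
#' @param cfg a [digestConfig()].
#' @return a data frame with columns `peptide` and `n_missed` (internal
#'   missed cleavage count), one row per distinct peptide sequence,
#'   sorted by peptide.
#' @examples
#' digestProtein("AKPAAA", digestConfig(max_missed = 0))  # KP blocks cleavage
#' @export
digestProtein <- function(protein, cfg = digestConfig()) {
  if (is(protein, "ProteinModel")) protein <- modelSequence(protein)
  protein <- toupper(as_seq_character(protein))
  if (!nzchar(protein)) stop("protein must be non-empty")
  stopifnot(inherits(cfg, "DigestConfig"))
  b <- tryptic_boundaries(protein)
  nb <- length(b)
  pep <- character(0); missed <- integer(0)
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + cfg$max_missed)
    for (j in (i + 1L):jmax) {
      len <- b[j] - b[i]
      if (len < cfg$min_len) next
      if (len > cfg$max_len) break
      pep <- c(pep, substr(protein, b[i] + 1L, b[j]))
      missed <- c(missed, j - i - 1L)
    }
  }
  if (!length(pep))
    return(data.frame(peptide = character(0), n_missed = integer(0)))
  keep <- !duplicated(pep)
  out <- data.frame(peptide = pep[keep], n_missed = missed[keep])
  out[order(out$peptide), , drop = FALSE]
}

#' Map peptides onto a protein model
#'
#' Finds every exact (possibly overlapping) occurrence of each peptide in
#' the model sequence; an occurrence "hits" every repeat whose interval it
#' overlaps by at least one residue, so junction-spanning peptides hit both
#' neighbours.  Peptides with no occurrence are reported unmapped (one row
#' with `NA` coordinates).
#'
#' @param peptides character vector of peptide sequences.
#' @param model a [ProteinModel-class].
#' @return a data frame with one row per occurrence (plus one `NA` row per
#'   unmapped peptide): columns `peptide`, `start`, `end`, `repeats_hit`
#'   (comma-separated repeat numbers, `""` outside the repeat domain) and
#'   `in_region` (occurrence hits only repeats in the model's region of
#'   interest).
#' @export
mapPeptides <- function(peptides, model) {
  stopifnot(is(model, "ProteinModel"))
  peptides <- unique(toupper(as_seq_character(peptides)))
  subject <- model@sequence
  rng <- repeatRanges(model)
  roi <- regionOfInterest(model)
  rows <- lapply(peptides, function(p) {
    if (!nzchar(p)) return(NULL)
    m <- Biostrings::matchPattern(p, subject)
    if (!length(m))
      return(data.frame(peptide = p, start = NA_integer_, end = NA_integer_,
                        repeats_hit = NA_character_, in_region = NA))
    st <- IRanges::start(m); en <- IRanges::end(m)
    hits <- lapply(seq_along(st), function(k) {
      ov <- which(IRanges::start(rng) <= en[k] & IRanges::end(rng) >= st[k])
      ov
    })
    data.frame(
      peptide = p, start = st, end = en,
      repeats_hit = vapply(hits, paste, character(1), collapse = ","),
      in_region = vapply(hits, function(h)
        length(h) > 0 && all(h %in% roi), logical(1))
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), repeats_hit = character(0),
                      in_region = logical(0))
  rownames(out) <- NULL
  out
}

#' Classify peptide uniqueness against region and background proteome
#'
#' Summarizes a mapping table per peptide: `unique_to_region` is `TRUE`
#' when the peptide occurs in the model and every occurrence hits only
#' repeats in the region of interest; `unique_to_model` is `TRUE` when the
#' peptide occurs nowhere in the background proteome.  Together these
#' implement the proteotypic filter used to attribute peptides to the five
#' repeats absent from the short MUC16 isoform.
#'
#' @param mappings output of [mapPeptides()].
#' @param model the [ProteinModel-class] used for mapping.
#' @param background background proteome: an `AAStringSet` or a FASTA
#'   path.  The model's own entry should not be included.
#' @return a data frame with one row per peptide: `peptide`, `n_occ`,
#'   `unique_to_region`, `unique_to_model`.
#' @export
classifyUniqueness <- function(mappings, model, background) {
  stopifnot(is(model, "ProteinModel"))
  if (is.character(background) && length(background) == 1 &&
      file.exists(background))
    background <- Biostrings::readAAStringSet(background)
  if (is.character(background))
    background <- Biostrings::AAStringSet(background)
  if (!is(background, "AAStringSet"))
    stop("background proteome must be an AAStringSet or a readable FASTA")
  peps <- unique(mappings$peptide)
  per <- lapply(peps, function(p) {
    rows <- mappings[mappings$peptide == p, , drop = FALSE]
    mapped <- !all(is.na(rows$start))
    in_bg <- any(Biostrings::vcountPattern(p, background) > 0)
    data.frame(
      peptide = p,
      n_occ = if (mapped) nrow(rows) else 0L,
      unique_to_region = if (mapped) all(rows$in_region) else FALSE,
      unique_to_model = !in_bg
    )
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Residue coverage of a repeat region
#'
#' Coverage is the fraction of region residues covered by at least one
#' peptide occurrence, reported per repeat and aggregated over the region.
#'
#' @param mappings output of [mapPeptides()].
#' @param model the [ProteinModel-class].
#' @param region repeat numbers (default the model's region of interest).
#' @param uniqueness optional output of [classifyUniqueness()], used to
#'   count region-unique peptides.
#' @return a list of class `CoverageReport`: `per_repeat` (data frame
#'   `repeat_number`, `covered`, `width`, `fraction`), `region_fraction`,
#'   `n_peptides_region` (distinct peptides with an occurrence overlapping
#'   the region) and `n_unique_region` (`NA` when `uniqueness` absent).
#' @export
regionCoverage <- function(mappings, model, region = regionOfInterest(model),
                           uniqueness = NULL) {
  stopifnot(is(model, "ProteinModel"))
  region <- as.integer(region)
  rng <- repeatRanges(model)
  if (!length(region) || !all(region %in% seq_along(rng)))
    stop("region must name existing repeats")
  occ <- mappings[!is.na(mappings$start), , drop = FALSE]
  cov_ir <- if (nrow(occ))
    IRanges::reduce(IRanges::IRanges(occ$start, occ$end))
  else IRanges::IRanges()
  per <- lapply(region, function(rn) {
    r <- rng[rn]
    ov <- IRanges::intersect(cov_ir, IRanges::IRanges(IRanges::start(r),
                                                      IRanges::end(r)))
    covered <- sum(IRanges::width(ov))
    data.frame(repeat_number = rn, covered = covered,
               width = IRanges::width(r),
               fraction = covered / IRanges::width(r))
  })
  per <- do.call(rbind, per)
  region_fraction <- sum(per$covered) / sum(per$width)
  reg_lo <- min(IRanges::start(rng[region]))
  reg_hi <- max(IRanges::end(rng[region]))
  in_reg <- occ[vapply(seq_len(nrow(occ)), function(k) {
    hits <- occ$repeats_hit[k]
    any(as.integer(strsplit(hits, ",")[[1]]) %in% region)
  }, logical(1)), , drop = FALSE]
  n_unique <- NA_integer_
  if (!is.null(uniqueness))
    n_unique <- sum(uniqueness$unique_to_region &
                    uniqueness$peptide %in% in_reg$peptide)
  structure(list(per_repeat = per, region_fraction = region_fraction,
                 n_peptides_region = length(unique(in_reg$peptide)),
                 n_unique_region = n_unique,
                 region = region, span = c(reg_lo, reg_hi)),
            class = c("CoverageReport", "list"))
}

#' Compare the digests of two protein models
#'
#' Digests both models with the same configuration and partitions the
#' union of distinct peptide sequences into common / only-A / only-B, with
#' percentages of the union rounded to one decimal.  This is the in silico
#' digest comparison used to contrast the 63-repeat and 19-repeat MUC16
#' models.
#'
#' @param model_a,model_b [ProteinModel-class] objects (or protein
#'   strings).
#' @param cfg a [digestConfig()] applied to both.
#' @return a [VennReport-class].
#' @export
compareModels <- function(model_a, model_b, cfg = digestConfig()) {
  name_of <- function(m, d) if (is(m, "ProteinModel")) modelName(m) else d
  set_of <- function(m) unique(digestProtein(m, cfg)$peptide)
  a <- set_of(model_a); b <- set_of(model_b)
  common <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  u <- length(common) + length(only_a) + length(only_b)
  pct <- function(x) if (u) round(100 * length(x) / u, 1) else 0
  new("VennReport",
      nameA = name_of(model_a, "model_a"), nameB = name_of(model_b, "model_b"),
      common = sort(common), onlyA = sort(only_a), onlyB = sort(only_b),
      pctCommon = pct(common), pctOnlyA = pct(only_a), pctOnlyB = pct(only_b))
}

#' Export peptide occurrences with repeat-local coordinates
#'
#' One row per (peptide, occurrence), positioned relative to the repeat
#' unit containing the occurrence start — the layout used for repeat-wise
#' peptide coverage maps.  Occurrences outside the repeat domain are
#' reported with `NA` repeat number.
#'
#' @param mappings output of [mapPeptides()].
#' @param model the [ProteinModel-class].
#' @param uniqueness optional output of [classifyUniqueness()]; adds the
#'   per-peptide `unique_to_region` flag.
#' @return a data frame with columns `peptide`, `repeat_number`,
#'   `start_in_repeat`, `end_in_repeat` (may extend past the repeat for
#'   junction-spanning peptides) and `unique_to_region`.
#' @export
exportCoverageTable <- function(mappings, model, uniqueness = NULL) {
  stopifnot(is(model, "ProteinModel"))
  occ <- mappings[!is.na(mappings$start), , drop = FALSE]
  rng <- repeatRanges(model)
  if (!nrow(occ))
    return(data.frame(peptide = character(0), repeat_number = integer(0),
                      start_in_repeat = integer(0),
                      end_in_repeat = integer(0),
                      unique_to_region = logical(0)))
  rn <- vapply(occ$start, function(s) {
    hit <- which(IRanges::start(rng) <= s & IRanges::end(rng) >= s)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  base <- ifelse(is.na(rn), NA_integer_, IRanges::start(rng)[rn] - 1L)
  flag <- rep(NA, nrow(occ))
  if (!is.null(uniqueness))
    flag <- uniqueness$unique_to_region[match(occ$peptide,
                                              uniqueness$peptide)]
  data.frame(peptide = occ$peptide, repeat_number = rn,
             start_in_repeat = occ$start - base,
             end_in_repeat = occ$end - base,
             unique_to_region = flag, row.names = NULL)
}
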