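# Translation, amplicon extraction, periodicity and repeat segmentation.

FWD_PRIMER <- "TTGGTTTACTAGAGACTACAGGCTTAC"
REV_PRIMER <- "TTGCAGATCCTCCAGGTCTAGG"

test_that("fixed-frame translation trims and rejects internal stops", {
  expect_identical(translateFrame("ATGGCC"), "MA")
  expect_identical(translateFrame("AT"), "")
  expect_identical(translateFrame("ATGGCCA"), "MA")  # partial codon trimmed
  expect_error(translateFrame("ATGTGAGCC"), "stop codon at codon position 2")
  # trailing stop is trimmed, not an error
  expect_identical(translateFrame("ATGGCCTGA"), "MA")
})

test_that("longest-orf mode returns the longest stop-free stretch", {
  longest_oracle <- function(nt) {
    best <- ""
    for (off in 1:3) {
      n <- nchar(nt) - off + 1; n <- n - n %% 3
      if (n < 3) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(nt, off, off + n - 1))))
      for (p in strsplit(aa, "*", fixed = TRUE)[[1]])
        if (nchar(p) > nchar(best)) best <- p
    }
    best
  }
  for (s in 81:85) {
    nt <- random_dna(299, s)
    got <- translateFrame(nt, mode = "longest-orf")
    expect_identical(got, longest_oracle(nt))
    expect_false(grepl("*", got, fixed = TRUE))
  }
})

test_that("amplicon extraction recovers the constructed primer span", {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  insert <- random_dna(500, 51)
  span <- paste0(FWD_PRIMER, insert, rc(REV_PRIMER))
  transcript <- paste0(random_dna(120, 52), span, random_dna(80, 53))
  expect_identical(extractAmplicon(transcript, FWD_PRIMER, REV_PRIMER), span)
  # no match
  expect_error(extractAmplicon(random_dna(300, 54), FWD_PRIMER, REV_PRIMER),
               "0 candidate")
  # multiple forward sites
  dbl <- paste0(FWD_PRIMER, insert, FWD_PRIMER, insert, rc(REV_PRIMER))
  expect_error(extractAmplicon(dbl, FWD_PRIMER, REV_PRIMER), "2 candidate")
  expect_error(extractAmplicon(span, "ACGTACGT", REV_PRIMER), "15 nt")
})

test_that("period estimation finds the modal k-word offset", {
  expect_identical(estimatePeriod(strrep("AB", 50), k = 2), 2L)
  truth <- assembleGeneModel(geneModelSpec(seed = 1))
  expect_identical(estimatePeriod(truth$protein, k = 10), 156L)
  expect_error(estimatePeriod(random_protein(200, 61), k = 10),
               "no periodicity")
})

test_that("segmentation recovers the 19 published repeat units", {
  units <- as.character(muc16RepeatUnits())
  ann <- segmentRepeats(paste(units, collapse = ""))
  expect_identical(length(ann), 19L)
  w <- IRanges::width(repeatRanges(ann))
  expect_identical(unname(w[1]), 156L)
  # canonical rows are recovered verbatim (boundary convention shifts the
  # three non-canonical terminal rows by at most a few residues)
  expect_identical(as.character(repeatSequences(ann)[["R1"]]), units[["R1"]])
  expect_identical(as.character(repeatSequences(ann)[["R10"]]),
                   units[["R10"]])
  # tiling: no gaps or overlaps
  rng <- repeatRanges(ann)
  expect_identical(unname(IRanges::start(rng)[-1]),
                   unname(IRanges::end(rng)[-19] + 1L))
})

test_that("a single unit segments with a period hint", {
  one <- as.character(muc16RepeatUnits()[["R5"]])
  ann <- segmentRepeats(one, period_hint = 156)
  expect_identical(length(ann), 1L)
  expect_identical(as.character(repeatSequences(ann)[[1]]), one)
  expect_error(segmentRepeats(random_protein(300, 71)), "period_hint")
})

test_that("segmentation of n-copy concatenations returns n units", {
  unit <- as.character(muc16RepeatUnits()[["R1"]])
  for (n in 1:30) {
    ann <- segmentRepeats(strrep(unit, n), period_hint = 156)
    expect_identical(length(ann), as.integer(n))
    rng <- repeatRanges(ann)
    expect_identical(unname(IRanges::start(rng)),
                     as.integer(156 * (seq_len(n) - 1) + 1))
  }
})

test_that("segmentation of the synthetic protein matches generator truth", {
  truth <- assembleGeneModel(geneModelSpec(seed = 1))
  ann <- segmentRepeats(truth$protein)
  expect_identical(as.character(repeatRanges(ann)),
                   as.character(repeatRanges(truth$annotation)))
  expect_identical(as.character(repeatSequences(ann)),
                   as.character(repeatSequences(truth$annotation)))
  expect_equal(periodEstimate(ann), 156)
})

test_that("unit profiling tabulates columns and conserves the C-loop", {
  ident <- profileRepeatUnits(rep("ACDEF", 4))
  expect_true(all(apply(ident$columns[, 1:5], 2, function(v) sum(v > 0)) == 1))
  expect_identical(ident$consensus, "ACDEF")
  expect_identical(ident$conserved_positions, 1:5)

  prof <- profileRepeatUnits(muc16RepeatUnits())
  expect_identical(unname(prof$columns["C", 59]), 19L)
  expect_identical(unname(prof$columns["C", 79]), 19L)
  ch <- strsplit(prof$consensus, "")[[1]]
  expect_identical(ch[c(59, 79)], c("C", "C"))

  # diverged family: consensus recovers the ancestor at most positions
  spec <- geneModelSpec(seed = 4)
  fam <- makeRepeatFamily(spec)
  anc <- strsplit(as.character(muc16RepeatUnits()[["R1"]]), "")[[1]]
  cons <- strsplit(profileRepeatUnits(fam)$consensus, "")[[1]]
  unprot <- setdiff(seq_along(anc), c(59, 79))
  expect_gte(mean(cons[unprot] == anc[unprot]), 0.95)
})

test_that("the C-loop scanner returns the cysteine pair and flags", {
  cl <- findCLoop(as.character(muc16RepeatUnits()[["R1"]]))
  expect_identical(cl$cys1, 59L)
  expect_identical(cl$cys2, 79L)
  expect_false(cl$multiple)

  toy <- paste0("C", strrep("A", 19), "C")
  expect_identical(findCLoop(toy)$cys1, 1L)
  expect_identical(findCLoop(toy)$cys2, 21L)

  iv <- vapply(as.character(muc16RepeatUnits()),
               function(u) findCLoop(u)$intervening, integer(1))
  expect_true(all(iv == 19L))

  # several qualifying pairs: last one wins and is flagged
  multi <- paste0("C", strrep("A", 19), "C", strrep("G", 19), "C")
  cm <- findCLoop(multi)
  expect_identical(cm$cys1, 21L)
  expect_true(cm$multiple)

  expect_error(findCLoop("AAAA"), "no C-loop")
})

test_that("repeat annotation enforces contiguity and naming", {
  expect_error(repeatAnnotation(c(1, 10), c(8, 20),
                                c(strrep("A", 8), strrep("B", 11))),
               "contiguous")
  ann <- repeatAnnotation(c(1, 9), c(8, 20),
                          c(strrep("A", 8), strrep("B", 12)))
  expect_identical(names(repeatRanges(ann)), c("R1", "R2"))
  expect_identical(length(ann), 2L)
})
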