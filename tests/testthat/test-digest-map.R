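# Tryptic digestion, peptide mapping, uniqueness, coverage and the
# two-model digest comparison.

test_that("digestion honours the trypsin rule and KP exception", {
  expect_identical(digestProtein("AAAAAA")$peptide, "AAAAAA")
  expect_identical(digestProtein("AKPAAA", digestConfig(max_missed = 0))$peptide,
                   "AKPAAA")
  d <- digestProtein("AAAKGGGRCCCCC", digestConfig(max_missed = 1,
                                                   min_len = 1, max_len = 45))
  expect_setequal(d$peptide,
                  c("AAAK", "GGGR", "CCCCC", "AAAKGGGR", "GGGRCCCCC"))
  expect_identical(d$n_missed[match("AAAKGGGR", d$peptide)], 1L)
})

test_that("digestion equals the exhaustive cleavage-subset oracle", {
  r1 <- as.character(muc16RepeatUnits()[["R1"]])
  expect_identical(digestProtein(r1)$peptide, digest_oracle(r1))
  # property: random proteins up to 200 residues, several configurations
  for (s in 1:12) {
    prot <- random_protein(sample(c(30, 80, 150, 200), 1), s)
    mm <- sample(0:3, 1); lo <- sample(1:6, 1); hi <- sample(20:60, 1)
    got <- digestProtein(prot, digestConfig(max_missed = mm, min_len = lo,
                                            max_len = hi))$peptide
    expect_identical(got, digest_oracle(prot, mm, lo, hi))
  }
})

test_that("missed-cleavage counts are consistent with peptide content", {
  d <- digestProtein(random_protein(150, 99))
  internal_sites <- vapply(d$peptide, function(p) {
    aa <- strsplit(p, "")[[1]]
    L <- length(aa)
    if (L < 2) return(0L)
    sum(aa[-L] %in% c("K", "R") & aa[-1] != "P")
  }, integer(1))
  expect_identical(unname(internal_sites), d$n_missed)
})

test_that("peptide mapping reports occurrences, hits and unmapped input", {
  units <- as.character(muc16RepeatUnits())
  concat <- paste(units, collapse = "")
  mod <- proteinModel("m19", concat)
  rng <- repeatRanges(mod)

  pep <- substr(units[["R9"]], 1, 10)
  junction <- substr(concat, IRanges::end(rng)[7] - 4L,
                     IRanges::end(rng)[7] + 5L)
  mp <- mapPeptides(c(pep, junction, "WWWWWW"), mod)

  row9 <- mp[mp$peptide == pep, ]
  expect_identical(nrow(row9), 1L)
  expect_identical(row9$repeats_hit, "9")
  expect_identical(unname(row9$start),
                   unname(IRanges::start(rng)[9]))

  rowj <- mp[mp$peptide == junction, ]
  expect_identical(rowj$repeats_hit, "7,8")

  expect_true(is.na(mp$start[mp$peptide == "WWWWWW"]))
})

test_that("uniqueness flags follow region and background occurrence", {
  units <- as.character(muc16RepeatUnits())
  mod <- proteinModel("m19", paste(units, collapse = ""))
  in_r10 <- substr(units[["R10"]], 100, 115)
  in_r1 <- substr(units[["R1"]], 1, 12)
  shared <- "FTLNFTITNL"  # occurs in many repeats, inside and outside 8-12
  mp <- mapPeptides(c(in_r10, in_r1, shared), mod)
  bg <- Biostrings::AAStringSet(c(other = paste0("MMM", in_r1, "KKK")))
  cu <- classifyUniqueness(mp, mod, bg)

  g <- function(p, col) cu[cu$peptide == p, col]
  expect_true(g(in_r10, "unique_to_region"))
  expect_true(g(in_r10, "unique_to_model"))
  expect_false(g(shared, "unique_to_region"))
  expect_false(g(in_r1, "unique_to_model"))
  expect_false(g(in_r1, "unique_to_region"))
})

test_that("region coverage equals the interval-union oracle", {
  truth <- assembleGeneModel(geneModelSpec(seed = 2))
  mod <- proteinModel("syn", truth$protein, repeats = truth$annotation)
  obs <- simulatePeptideObservations(truth$protein, peptideObservationSpec(
    detection_prob = 1, seed = 1))
  mp <- mapPeptides(obs, mod)
  cov <- regionCoverage(mp, mod)

  # brute-force union of occurrence spans over the region residues
  rng <- repeatRanges(mod)
  region_res <- unlist(lapply(8:12, function(i)
    seq(IRanges::start(rng)[i], IRanges::end(rng)[i])))
  occ <- mp[!is.na(mp$start), ]
  covered <- unique(unlist(mapply(seq, occ$start, occ$end,
                                  SIMPLIFY = FALSE)))
  expect_equal(cov$region_fraction,
               length(intersect(region_res, covered)) / length(region_res))

  expect_equal(regionCoverage(mapPeptides(character(0), mod),
                              mod)$region_fraction, 0)
  # full tiling of one repeat gives coverage 1 there
  tile <- as.character(repeatSequences(mod)[["R8"]])
  mp8 <- mapPeptides(tile, mod)
  cov8 <- regionCoverage(mp8, mod, region = 8)
  expect_equal(cov8$per_repeat$fraction, 1)
  expect_error(regionCoverage(mp8, mod, region = integer(0)), "region")
})

test_that("coverage is monotone in the observed peptide set", {
  truth <- assembleGeneModel(geneModelSpec(seed = 3))
  mod <- proteinModel("syn", truth$protein, repeats = truth$annotation)
  all_obs <- simulatePeptideObservations(truth$protein,
    peptideObservationSpec(detection_prob = 1, seed = 1))
  half <- all_obs[seq(1, length(all_obs), by = 2)]
  cov_half <- regionCoverage(mapPeptides(half, mod), mod)$region_fraction
  cov_full <- regionCoverage(mapPeptides(all_obs, mod), mod)$region_fraction
  expect_lte(cov_half, cov_full)
})

test_that("two-model digest comparison partitions the peptide union", {
  units <- as.character(muc16RepeatUnits())
  mod <- proteinModel("m19", paste(units, collapse = ""))
  self <- compareModels(mod, mod)
  expect_equal(unname(vennPercentages(self)),
               c(100, 0, 0))

  # toy models sharing one repeat of three: exhaustive enumeration
  a <- paste(units[c("R1", "R2", "R3")], collapse = "")
  b <- paste(units[c("R3", "R15", "R16")], collapse = "")
  vr <- compareModels(proteinModel("a", a, repeats = segmentRepeats(a)),
                      proteinModel("b", b, repeats = segmentRepeats(b)))
  da <- digest_oracle(a); db <- digest_oracle(b)
  expect_setequal(vennPeptides(vr)$common, intersect(da, db))
  expect_setequal(vennPeptides(vr)$only_a, setdiff(da, db))
  expect_setequal(vennPeptides(vr)$only_b, setdiff(db, da))
  u <- length(union(da, db))
  expect_equal(unname(vennPercentages(vr))[1],
               round(100 * length(intersect(da, db)) / u, 1))

  # symmetry under swap; percentages always sum to 100 within rounding
  sw <- compareModels(proteinModel("b", b), proteinModel("a", a))
  expect_setequal(vennPeptides(sw)$only_a, vennPeptides(vr)$only_b)
  for (s in 1:5) {
    pa <- random_protein(120, s); pb <- random_protein(120, s + 50)
    v <- compareModels(proteinModel("x", pa, repeatAnnotation(1, 120, pa)),
                       proteinModel("y", pb, repeatAnnotation(1, 120, pb)))
    expect_lte(abs(sum(vennPercentages(v)) - 100), 0.1)
  }
})

test_that("peptides unique to the full model localize to the deleted repeats", {
  # isoform-3-like truth vs a copy with repeats 8-12 excised
  truth <- assembleGeneModel(geneModelSpec(seed = 5))
  mod_full <- proteinModel("full", truth$protein,
                           repeats = truth$annotation)
  rng <- repeatRanges(mod_full)
  del_lo <- IRanges::start(rng)[8]; del_hi <- IRanges::end(rng)[12]
  short_seq <- paste0(substr(truth$protein, 1, del_lo - 1),
                      substr(truth$protein, del_hi + 1,
                             nchar(truth$protein)))
  expect_identical(nchar(truth$protein) - nchar(short_seq), 5L * 156L)

  cfg <- digestConfig()
  only_full <- setdiff(unique(digestProtein(mod_full, cfg)$peptide),
                       unique(digestProtein(short_seq, cfg)$peptide))
  expect_gt(length(only_full), 0)
  mp <- mapPeptides(only_full, mod_full)
  occ <- mp[!is.na(mp$start), ]
  # every full-model-unique peptide has a locus inside repeats 8-12 or
  # abutting the excision junction (where the cleavage context changes)
  touches <- occ$start <= del_hi + 1L & occ$end >= del_lo - 1L
  per_pep <- tapply(touches, occ$peptide, any)
  expect_true(all(per_pep))
})

test_that("the coverage export has one row per occurrence", {
  units <- as.character(muc16RepeatUnits())
  mod <- proteinModel("m19", paste(units, collapse = ""))
  expect_identical(nrow(exportCoverageTable(
    mapPeptides(character(0), mod), mod)), 0L)

  inside_r8 <- substr(units[["R8"]], 125, 140)
  mp <- mapPeptides(inside_r8, mod)
  tab <- exportCoverageTable(mp, mod)
  expect_identical(nrow(tab), sum(!is.na(mp$start)))
  expect_identical(tab$repeat_number[1], 8L)
  expect_identical(tab$start_in_repeat[1], 125L)
  expect_identical(tab$end_in_repeat[1], 140L)
})

test_that("peptide list parsing strips search-engine decorations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Scan,Peptide,Score",
               "1,K.LYSGCR.L,55",
               "2,N(+.98)ATER,44",
               "3,FTLNFTITNL,33"), path)
  expect_identical(readPeptideList(path),
                   c("LYSGCR", "NATER", "FTLNFTITNL"))
  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("lysgcr", "FTLNFTITNL"), plain)
  expect_identical(readPeptideList(plain), c("LYSGCR", "FTLNFTITNL"))
})
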