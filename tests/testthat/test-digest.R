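test_that("adapter detection is exact substring containment", {
  ad <- "CTGTCTCTTATACACATCT"
  r <- paste0(random_seq(20), ad, random_seq(10))
  expect_true(contains_adapter(r, adapter_fwd = ad))
  expect_false(contains_adapter(random_seq(50)))  # none configured
  ## partial terminal overlap (5 of 19 bases) is not a detection
  r2 <- paste0(strrep("G", 40), substring(ad, 1, 5))
  expect_false(grepl(ad, r2, fixed = TRUE))
  expect_false(contains_adapter(r2, adapter_fwd = ad))
  ## reverse mate can carry the hit
  expect_true(contains_adapter(strrep("A", 30), paste0("T", ad),
                               adapter_fwd = ad, adapter_rev = ad))
})

test_that("pair merging picks the longest admissible overlap", {
  ## brute-force check: overlap 5 ("TACGT") is the longest valid one
  m <- merge_pair("ACGTACGT", qual_string(30, 8),
                  "TACGTTTT", qual_string(30, 8),
                  min_overlap = 4, max_overlap = 5)
  expect_equal(m$seq, "ACGTACGTTTT")
  ## identical 8-mers at full overlap collapse to the 8-mer
  s <- random_seq(8)
  m2 <- merge_pair(s, qual_string(20, 8), s, qual_string(35, 8),
                   min_overlap = 8, max_overlap = 8)
  expect_equal(m2$seq, s)
  expect_equal(m2$qual, qual_string(35, 8))  # max quality kept
  ## disjoint sequences cannot merge without mismatch tolerance
  expect_equal(as.character(
    merge_pair("AAAAAAAA", qual_string(30, 8),
               "GGGGGGGG", qual_string(30, 8))), "fMergeFailed")
  ## discordant overlap base resolved towards the higher quality
  m3 <- merge_pair("AAAT", "III#", "CGGG", "IIII",
                   min_overlap = 1, max_overlap = 1,
                   max_mismatch_fraction = 1)
  expect_equal(substring(m3$seq, 4, 4), "C")  # rev qual 40 beats fwd 2
})

test_that("wild-type matching reproduces the naive exhaustive scan", {
  set.seed(21)
  for (i in 1:150) {
    L <- sample(c(9, 12, 18), 1)
    k <- sample(2:4, 1)
    wt <- stats::setNames(replicate(k, random_seq(L)), paste0("G", 1:k))
    base <- wt[[sample(k, 1)]]
    nmut <- sample(0:3, 1)
    seq <- base
    if (nmut > 0) {
      pos <- sample(L, nmut)
      for (p in pos) {
        substring(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substring(base, p, p)), 1)
      }
    }
    unit <- sample(c("base", "codon"), 1)
    mm <- sample(0:2, 1)
    pars <- digest_params(wildtype = wt, unit = unit, max_mutations = mm)
    got <- match_to_wildtype(seq, qual_string(30, L), wt, pars)
    want <- oracle_match(seq, wt, unit = unit, max_mutations = mm)
    if (is.na(want$reason)) {
      expect_s3_class(got, "MatchResult")
      expect_equal(got$wt_name, want$wt)
      expect_equal(got$n_mut_bases, want$n_mut_bases)
      expect_equal(got$n_mut_codons, want$n_mut_codons)
    } else {
      expect_equal(as.character(got), want$reason)
    }
  }
})

test_that("matching handles identity, tie and threshold cases", {
  wt <- c(GENEX = strrep("ACGTT", 4))
  pars <- digest_params(wildtype = wt, unit = "base", max_mutations = 3)
  hit <- match_to_wildtype(wt[[1]], qual_string(30, 20), wt, pars)
  expect_equal(hit$wt_name, "GENEX")
  expect_equal(nrow(hit$mutations), 0L)

  var <- wt[[1]]
  substring(var, 10, 10) <- "A"
  hit2 <- match_to_wildtype(var, qual_string(30, 20), wt, pars)
  expect_equal(hit2$mutations$position, 10L)
  expect_equal(hit2$mutations$alt, "A")
  expect_equal(name_variant(hit2, "base"), "GENEX.10.A")

  ## two wild-types each at distance 1 -> ambiguous, filtered
  wt2 <- c(A = "AAAA", B = "AATT")
  pars2 <- digest_params(wildtype = wt2, unit = "base", max_mutations = 2)
  expect_equal(as.character(
    match_to_wildtype("AAAT", qual_string(30, 4), wt2, pars2)),
    "fNoValidWildtype")

  ## low quality at the mutated base
  pars3 <- digest_params(wildtype = wt, unit = "base", max_mutations = 3,
                         min_mutation_quality = 25)
  q <- qual_string(30, 20)
  substring(q, 10, 10) <- intToUtf8(20 + 33)
  expect_equal(as.character(match_to_wildtype(var, q, wt, pars3)),
               "fMutQualTooLow")

  ## forbidden codon: NNW rejects observed codons ending in A or T
  wtc <- c(GENEY = "GCTGCTGCT")
  parsf <- digest_params(wildtype = wtc, unit = "codon", max_mutations = 1,
                         forbidden_codons = "NNW")
  varA <- "GCAGCTGCT"  # codon 1 -> GCA, ends in A
  expect_equal(as.character(
    match_to_wildtype(varA, qual_string(30, 9), wtc, parsf)),
    "fForbiddenCodon")
  varG <- "GCGGCTGCT"  # codon 1 -> GCG, ends in G: allowed
  expect_s3_class(match_to_wildtype(varG, qual_string(30, 9), wtc, parsf),
                  "MatchResult")
})

test_that("variant names follow the WT.position.alternative convention", {
  wt <- c(GENEX = paste(rep("GCT", 8), collapse = ""))
  pars <- digest_params(wildtype = wt, unit = "codon", max_mutations = 3)
  var <- wt[[1]]
  substring(var, 10, 12) <- "TTG"  # codon 4
  substring(var, 19, 21) <- "AAC"  # codon 7
  hit <- match_to_wildtype(var, qual_string(30, 24), wt, pars)
  expect_equal(name_variant(hit, "codon"), "GENEX.4.TTG_GENEX.7.AAC")
  wt_hit <- match_to_wildtype(wt[[1]], qual_string(30, 24), wt, pars)
  expect_equal(name_variant(wt_hit, "codon"), "GENEX")
})

test_that("constant-region check tallies mismatches by quality", {
  cc <- check_constant("ACGT", qual_string(30, 4), "ACGT", 0)
  expect_true(cc$pass)
  expect_equal(cc$tally["30", "nMatch"], 4L)
  expect_equal(sum(cc$tally[, "nMismatch"]), 0L)

  cc2 <- check_constant("ACAA", qual_string(30, 4), "ACGT", 1)
  expect_false(cc2$pass)  # 2 mismatches > 1

  q <- paste0(qual_string(30, 3), intToUtf8(20 + 33))
  cc3 <- check_constant("ACGA", q, "ACGT", 2)
  expect_true(cc3$pass)
  expect_equal(cc3$tally["20", "nMismatch"], 1L)
  expect_equal(cc3$tally["30", "nMatch"], 3L)

  ## tie between two references fails the read
  cc4 <- check_constant("AAAT", qual_string(30, 4), c("AAAA", "AATT"), 3)
  expect_false(cc4$pass)
})

test_that("quality and N filters apply in order with arithmetic-mean quality", {
  sp <- parse_element_spec("UV", c(6, 4))
  mk <- function(seq, qual) segment_read(seq, qual, sp)
  pars <- digest_params(avg_qual_min = 21, max_n_umi = 1)
  ## variable qualities 10,10,10,50: mean 20 < 21
  q <- paste0(qual_string(30, 6), intToUtf8(c(10, 10, 10, 50) + 33))
  cs <- mk(paste0("ACGAAT", "ACGT"), q)
  expect_equal(as.character(quality_filters(cs, pars)), "fAvgQualTooLow")
  ## mean 30 passes
  cs2 <- mk(paste0("ACGAAT", "ACGT"), qual_string(30, 10))
  expect_equal(quality_filters(cs2, pars), "pass")
  ## two N in the UMI with a budget of one
  cs3 <- mk(paste0("ACGNNT", "ACGT"), qual_string(30, 10))
  expect_equal(as.character(quality_filters(cs3, pars)), "fTooManyNinUmi")
})

test_that("digestion handles empty input and the read cap", {
  tmp <- withr::local_tempdir()
  empty <- file.path(tmp, "empty.fastq")
  writeLines(character(0), empty)
  ly <- parse_element_spec("V", -1)
  res <- digest_sample(empty, layout_fwd = ly)
  expect_equal(unname(res$filterTally[["nTotal"]]), 0L)
  expect_equal(nrow(res$countTable), 0L)

  fq <- file.path(tmp, "reads.fastq")
  set.seed(3)
  seqs <- replicate(50, random_seq(12))
  writeLines(paste0("@r", 1:50, "\n", seqs, "\n+\n", qual_string(30, 12)),
             fq)
  res2 <- digest_sample(fq, layout_fwd = ly,
                        params = digest_params(max_reads = 10))
  expect_equal(unname(res2$filterTally[["nTotal"]]), 10L)
  expect_equal(sum(res2$countTable$readCount), 10L)
})

test_that("digestion is order-independent and additive over files", {
  tmp <- withr::local_tempdir()
  setup <- std_sim_setup(seed = 31, n_per_wt = 10)
  cfg <- sim_config(setup$wildtypes, setup$variants, setup$layout_fwd,
                    setup$layout_rev, n_reads = 400,
                    constant_fwd = setup$constant, quality = 30,
                    error_rate = 0.003, seed = 17)
  sim <- simulate_library(cfg, file.path(tmp, "sim"))

  res_ab <- digest_sample(sim$fastq_fwd, sim$fastq_rev,
                          setup$layout_fwd, setup$layout_rev, setup$params)

  ## permuted read order
  perm_file <- function(path, ord, out) {
    l <- readLines(path)
    rec <- matrix(l, nrow = 4)
    writeLines(as.vector(rec[, ord]), out)
    out
  }
  set.seed(8)
  ord <- sample(400)
  pf <- perm_file(sim$fastq_fwd, ord, file.path(tmp, "p1.fastq"))
  pr <- perm_file(sim$fastq_rev, ord, file.path(tmp, "p2.fastq"))
  res_perm <- digest_sample(pf, pr, setup$layout_fwd, setup$layout_rev,
                            setup$params)
  expect_equal(res_perm$countTable, res_ab$countTable)
  expect_equal(res_perm$filterTally, res_ab$filterTally)
  expect_equal(res_perm$errorTally, res_ab$errorTally)

  ## split into two files: tallies and counts add
  split_file <- function(path, idx, out) {
    l <- readLines(path)
    rec <- matrix(l, nrow = 4)
    writeLines(as.vector(rec[, idx]), out)
    out
  }
  a1 <- split_file(sim$fastq_fwd, 1:150, file.path(tmp, "a1.fastq"))
  a2 <- split_file(sim$fastq_rev, 1:150, file.path(tmp, "a2.fastq"))
  b1 <- split_file(sim$fastq_fwd, 151:400, file.path(tmp, "b1.fastq"))
  b2 <- split_file(sim$fastq_rev, 151:400, file.path(tmp, "b2.fastq"))
  res_a <- digest_sample(a1, a2, setup$layout_fwd, setup$layout_rev,
                         setup$params)
  res_b <- digest_sample(b1, b2, setup$layout_fwd, setup$layout_rev,
                         setup$params)
  res_cat <- digest_sample(c(a1, b1), c(a2, b2),
                           setup$layout_fwd, setup$layout_rev, setup$params)
  expect_equal(res_cat$filterTally,
               res_a$filterTally + res_b$filterTally)
  joint <- merge(res_a$countTable[, c("variant", "readCount")],
                 res_b$countTable[, c("variant", "readCount")],
                 by = "variant", all = TRUE)
  joint[is.na(joint)] <- 0
  joint$total <- joint$readCount.x + joint$readCount.y
  joint <- joint[order(joint$variant), ]
  expect_equal(res_cat$countTable$readCount,
               joint$total[match(res_cat$countTable$variant, joint$variant)])
})

test_that("paired files with unequal read counts are a hard error", {
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "f1.fastq"); f2 <- file.path(tmp, "f2.fastq")
  writeLines(c("@a", "ACGT", "+", "IIII", "@b", "ACGT", "+", "IIII"), f1)
  writeLines(c("@a", "ACGT", "+", "IIII"), f2)
  ly <- parse_element_spec("V", 4)
  expect_error(digest_sample(f1, f2, ly, ly), "different read counts")
})

test_that("error-rate estimation is the per-quality mismatch fraction", {
  tally <- matrix(0L, 94, 2, dimnames = list(quality = 0:93,
                                             c("nMatch", "nMismatch")))
  tally["30", ] <- c(100L, 0L)
  tally["20", ] <- c(90L, 10L)
  er <- estimate_error_rates(tally)
  expect_equal(er$rate[er$quality == 30], 0)
  expect_equal(er$rate[er$quality == 20], 0.10)
  expect_equal(nrow(er), 2L)  # untouched qualities omitted
})

test_that("umi counts never exceed read counts and honour collapsing", {
  tmp <- withr::local_tempdir()
  setup <- std_sim_setup(seed = 41, n_per_wt = 8)
  cfg <- sim_config(setup$wildtypes, setup$variants, setup$layout_fwd,
                    setup$layout_rev, n_reads = 800,
                    constant_fwd = setup$constant, quality = 30,
                    umis_per_variant = 6, seed = 19)
  sim <- simulate_library(cfg, file.path(tmp, "sim"))
  res <- digest_sample(sim$fastq_fwd, sim$fastq_rev,
                       setup$layout_fwd, setup$layout_rev, setup$params)
  expect_true(all(res$countTable$umiCount <= res$countTable$readCount))
  expect_true(all(res$countTable$umiCount >= 1))
  expect_true(all(res$countTable$umiCount <= 6))
})
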