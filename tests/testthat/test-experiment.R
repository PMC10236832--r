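suppressMessages({
  library(SummarizedExperiment)
})

test_that("merging takes the union of variants with zero fill", {
  r1 <- fake_digest_result(c(A = 3))
  r2 <- fake_digest_result(c(B = 7))
  se <- merge_samples(list(s1 = r1, s2 = r2))
  m <- assay(se, "counts")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["A", ], c(s1 = 3L, s2 = 0L))
  expect_equal(m["B", ], c(s1 = 0L, s2 = 7L))

  ## single sample: matrix identical to its count table
  se1 <- merge_samples(list(only = fake_digest_result(c(X = 4, Y = 9))))
  expect_equal(unname(assay(se1)[, 1]), c(4L, 9L))
})

test_that("multi-sample merge equals a dictionary join", {
  set.seed(19)
  pool <- replicate(30, random_seq(10))
  samples <- lapply(1:3, function(i) {
    vars <- sample(pool, sample(10:25, 1))
    fake_digest_result(stats::setNames(sample(1:100, length(vars)), vars))
  })
  names(samples) <- paste0("s", 1:3)
  se <- merge_samples(samples)
  m <- assay(se, "counts")
  ## naive dictionary oracle
  dict <- list()
  for (s in names(samples)) {
    ct <- samples[[s]]$countTable
    for (k in seq_len(nrow(ct))) {
      v <- ct$variant[k]
      if (is.null(dict[[v]])) dict[[v]] <- stats::setNames(
        integer(3), names(samples))
      dict[[v]][s] <- ct$readCount[k]
    }
  }
  for (v in names(dict)) {
    expect_equal(m[v, ], dict[[v]])
  }
  expect_equal(nrow(m), length(dict))
  ## column sums equal per-sample retained totals
  for (s in names(samples)) {
    expect_equal(sum(m[, s]), sum(samples[[s]]$countTable$readCount))
  }
})

test_that("duplicate sample names and colData mismatches are errors", {
  r <- fake_digest_result(c(A = 1))
  expect_error(merge_samples(stats::setNames(list(r, r), c("s", "s"))),
               "duplicate")
  expect_error(merge_samples(list(s1 = r),
                             data.frame(name = "other",
                                        row.names = "other")),
               "absent")
})

test_that("mutation classification follows the standard genetic code", {
  x <- classify_mutations("GCTGCT", "GCTGCT")
  expect_equal(x$n_mut_bases, 0L)
  expect_equal(x$mutation_types, character(0))

  sil <- classify_mutations("GCC", "GCT")  # Ala -> Ala
  expect_equal(sil$mutation_types, "silent")
  expect_equal(sil$n_mut_aas, 0L)

  stp <- classify_mutations("TGA", "TGG")  # Trp -> ter
  expect_equal(stp$mutation_types, "stop")
  expect_equal(stp$n_mut_aas, 1L)

  ns <- classify_mutations("GATAAA", "GCTAAA")  # Ala -> Asp
  expect_equal(ns$mutation_types, "nonsynonymous")

  expect_error(classify_mutations("ACG", "ACGT"), "equal length")
})

test_that("classification agrees with an independent translation oracle", {
  skip_if_not_installed("seqinr")
  codons <- all_codons()
  for (ref in codons[seq(1, 64, by = 7)]) {  # spot sample; full grid in acceptance
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substring(ref, p, p))) {
        alt <- ref
        substring(alt, p, p) <- b
        got <- classify_mutations(alt, ref)
        aa_ref <- seqinr::translate(strsplit(ref, "")[[1]])
        aa_alt <- seqinr::translate(strsplit(alt, "")[[1]])
        want <- if (aa_alt == aa_ref) "silent"
                else if (aa_alt == "*") "stop" else "nonsynonymous"
        expect_equal(got$mutation_types, want)
      }
    }
  }
})

test_that("amino-acid collapsing sums synonymous rows and conserves columns", {
  r1 <- fake_digest_result(c(v1 = 4, v2 = 6, v3 = 5),
                           wildtype = c("G", "G", "G"),
                           sequences = c("GCT", "GCC", "TTA"))
  r2 <- fake_digest_result(c(v1 = 2, v3 = 8),
                           wildtype = c("G", "G"),
                           sequences = c("GCT", "TTA"))
  se <- merge_samples(list(a = r1, b = r2))
  aa <- collapse_to_aa(se)
  m <- assay(aa, "counts")
  expect_equal(nrow(m), 2L)  # Ala family + Leu
  expect_equal(colSums(m), colSums(assay(se, "counts")))
  ala <- which(rowData(aa)$protein == "A")
  expect_equal(unname(m[ala, ]), c(10L, 2L))
})

test_that("aa collapsing matches a group-by-translation oracle on random input", {
  skip_if_not_installed("seqinr")
  set.seed(23)
  for (i in 1:5) {
    n <- sample(10:30, 1)
    seqs <- replicate(n, random_seq(9))
    counts1 <- sample(1:50, n, replace = TRUE)
    counts2 <- sample(1:50, n, replace = TRUE)
    vars <- paste0("v", seq_len(n))
    r1 <- fake_digest_result(stats::setNames(counts1, vars),
                             wildtype = rep("W", n), sequences = seqs)
    r2 <- fake_digest_result(stats::setNames(counts2, vars),
                             wildtype = rep("W", n), sequences = seqs)
    se <- merge_samples(list(a = r1, b = r2))
    aa <- collapse_to_aa(se)
    prot <- vapply(seqs, function(s)
      paste(seqinr::translate(strsplit(s, "")[[1]]), collapse = ""),
      character(1))
    want <- rowsum(cbind(counts1, counts2), group = prot)
    m <- assay(aa, "counts")
    key <- rowData(aa)$protein
    expect_equal(unname(m[match(rownames(want), key), , drop = FALSE]),
                 unname(want))
  }
})

test_that("sample correlations use log10(count+1) Pearson", {
  m <- matrix(c(1, 10, 100, 1000,
                1, 10, 100, 1000,
                4, 2, 9, 7), ncol = 3,
              dimnames = list(paste0("v", 1:4), c("a", "b", "c")))
  se <- SummarizedExperiment(assays = list(counts = m))
  cc <- sample_correlations(se)
  expect_equal(cc["a", "b"], 1)
  ## closed-form Pearson on the transformed values
  x <- log10(m[, "a"] + 1); y <- log10(m[, "c"] + 1)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc["a", "c"], want)
  ## zero-variance column yields NA
  m2 <- cbind(m, d = rep(5, 4))
  se2 <- SummarizedExperiment(assays = list(counts = m2))
  cc2 <- sample_correlations(se2)
  expect_true(is.na(cc2["a", "d"]))
})

test_that("independent columns decorrelate at large n", {
  set.seed(77)
  m <- cbind(a = rpois(10000, 50), b = rpois(10000, 50))
  se <- SummarizedExperiment(assays = list(counts = m))
  expect_lt(abs(sample_correlations(se)["a", "b"]), 0.05)
})

test_that("filter summaries are complete and round-trip through TSV", {
  tmp <- withr::local_tempdir()
  setup <- std_sim_setup(seed = 53, n_per_wt = 6)
  cfg <- sim_config(setup$wildtypes, setup$variants, setup$layout_fwd,
                    setup$layout_rev, n_reads = 300,
                    constant_fwd = setup$constant, quality = 30,
                    error_rate = 0.01, seed = 5)
  sims <- lapply(1:2, function(i) {
    simulate_library(
      sim_config(setup$wildtypes, setup$variants, setup$layout_fwd,
                 setup$layout_rev, n_reads = 300,
                 constant_fwd = setup$constant, quality = 30,
                 error_rate = 0.01, seed = 5 + i),
      file.path(tmp, paste0("s", i)))
  })
  res <- lapply(sims, function(s)
    digest_sample(s$fastq_fwd, s$fastq_rev, setup$layout_fwd,
                  setup$layout_rev, setup$params))
  names(res) <- c("rep1", "rep2")
  se <- merge_samples(res, data.frame(name = c("rep1", "rep2"),
                                      condition = c("input", "output"),
                                      row.names = c("rep1", "rep2")))
  fs <- filtering_summary(se)
  for (s in c("rep1", "rep2")) {
    expect_equal(sum(fs$fraction[fs$sample == s]), 1)
    expect_equal(sum(fs$count[fs$sample == s]),
                 unname(res[[s]]$filterTally[["nTotal"]]))
  }
  ## serialization round trip restores counts, annotations and summaries
  d <- file.path(tmp, "exp")
  write_experiment(se, d)
  se2 <- read_experiment(d)
  expect_equal(assay(se2, "counts"), assay(se, "counts"))
  expect_equal(assay(se2, "umi_counts"), assay(se, "umi_counts"))
  expect_equal(as.data.frame(colData(se2))[, "condition"],
               as.data.frame(colData(se))[, "condition"])
  expect_equal(S4Vectors::metadata(se2)$filterSummaries$rep1,
               S4Vectors::metadata(se)$filterSummaries$rep1)
  expect_equal(filtering_summary(se2), fs)
})
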