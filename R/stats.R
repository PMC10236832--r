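## Normalization, per-variant count-model inference and enrichment-score
## computation. Model fitting is delegated to the established digital
## gene-expression frameworks: negative-binomial quasi-likelihood models
## (edgeR) and precision-weighted linear models (limma-voom). The
## package's own layer defines the normalization modes ("absolute" =
## TMM-normalized log-fold changes; "relative" = wild-type-offset
## log-fold changes), the input-count filter, and the PPI score.

as_count_matrix <- function(exp, assay = "counts") {
  if (methods::is(exp, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(exp, assay)
  } else {
    m <- as.matrix(exp)
  }
  if (any(m < 0)) stop("counts must be nonnegative")
  m
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Between-sample normalization factors computed by the TMM method
#' (log-ratio trim 0.30, abundance trim 0.05, precision weighting), with
#' the factors normalized to geometric mean 1. Zero-count features are
#' excluded pairwise.
#'
#' @param counts Count matrix (variants x samples) or
#'   `SummarizedExperiment`.
#' @param ref_sample Optional reference column (index or name); by default
#'   the column whose upper quartile is closest to the mean upper quartile.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2L) stop("at least two samples required")
  if (any(colSums(m) == 0)) stop("all-zero sample column(s): ",
                                 paste(colnames(m)[colSums(m) == 0],
                                       collapse = ", "))
  if (is.character(ref_sample)) ref_sample <- match(ref_sample, colnames(m))
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref_sample)
  stats::setNames(as.numeric(f), colnames(m))
}

#' Wild-type log offsets
#'
#' Per-sample offsets on the natural-log scale, computed as the log of the
#' sum (or geometric mean) of the counts of the designated wild-type rows.
#' Substituting these offsets for the log library sizes in the count model
#' makes the estimated log-fold changes wild-type-relative.
#'
#' @param counts Count matrix or `SummarizedExperiment`.
#' @param wt_rows Row names or indices of the wild-type variants.
#' @param method `"sum"` or `"geomean"` aggregation across wild-type rows.
#' @return Numeric vector of per-sample offsets (log scale).
#' @export
wt_offsets <- function(counts, wt_rows, method = c("sum", "geomean")) {
  method <- match.arg(method)
  m <- as_count_matrix(counts)
  if (length(wt_rows) == 0) stop("'wt_rows' must be nonempty")
  if (is.character(wt_rows)) {
    missing <- setdiff(wt_rows, rownames(m))
    if (length(missing) > 0)
      stop("wild-type row(s) not found: ", paste(missing, collapse = ", "))
  }
  w <- m[wt_rows, , drop = FALSE]
  agg <- if (method == "sum") colSums(w) else exp(colMeans(log(w)))
  if (any(!is.finite(agg)) || any(agg <= 0))
    stop("wild-type aggregate is zero (or undefined) in at least one sample")
  stats::setNames(log(agg), colnames(m))
}

resolve_offsets <- function(m, normalization, wt_rows) {
  switch(normalization,
    tmm = {
      nf <- tmm_factors(m)
      log(colSums(m) * nf)
    },
    wtsum = wt_offsets(m, wt_rows, "sum"),
    wtgeomean = wt_offsets(m, wt_rows, "geomean")
  )
}

check_design <- function(design, n_samples) {
  design <- as.matrix(design)
  if (nrow(design) != n_samples)
    stop("design has ", nrow(design), " rows but there are ",
         n_samples, " samples")
  if (qr(design)$rank < ncol(design)) stop("design matrix is not of full column rank")
  design
}

resolve_contrast <- function(contrast, design) {
  if (is.character(contrast)) {
    if (!contrast %in% colnames(design))
      stop("contrast '", contrast, "' is not a design coefficient")
    return(list(coef = contrast, contrast = NULL))
  }
  contrast <- as.numeric(contrast)
  if (length(contrast) != ncol(design))
    stop("numeric contrast must have one entry per design coefficient")
  list(coef = NULL, contrast = contrast)
}

#' Test variants with a negative-binomial quasi-likelihood model
#'
#' Fits, per variant, a negative-binomial generalized linear model with
#' log link and per-sample offsets (log effective library sizes under TMM
#' normalization, or wild-type offsets), with trended dispersion
#' estimation and empirical-Bayes shrinkage of the variant-wise
#' quasi-dispersions, and tests the requested contrast with a
#' quasi-likelihood F-test (the edgeR-QLF framework).
#'
#' @param exp Count matrix or `SummarizedExperiment`.
#' @param design Design matrix (samples x coefficients, full column rank).
#' @param contrast Coefficient name or numeric contrast vector.
#' @param normalization `"tmm"`, `"wtsum"` or `"wtgeomean"`.
#' @param wt_rows Wild-type row ids (required for the `wt*` modes).
#' @param assay Assay to test when `exp` is a `SummarizedExperiment`.
#' @return A data.frame of class `TestResult`: `variant`, `logFC` (log2),
#'   `aveAbundance` (average log2 CPM), `stat` (F), `pvalue`, `fdr`
#'   (Benjamini-Hochberg).
#' @export
fit_nb_ql <- function(exp, design, contrast,
                      normalization = c("tmm", "wtsum", "wtgeomean"),
                      wt_rows = NULL, assay = "counts") {
  normalization <- match.arg(normalization)
  m <- as_count_matrix(exp, assay)
  design <- check_design(design, ncol(m))
  if (nrow(m) - 0 < 1) stop("no variants to test")
  if (ncol(m) - ncol(design) < 1)
    stop("no residual degrees of freedom (", ncol(m), " samples, ",
         ncol(design), " coefficients)")
  y <- edgeR::DGEList(counts = m)
  if (normalization == "tmm") {
    y$samples$norm.factors <- unname(tmm_factors(m))
  } else {
    off <- resolve_offsets(m, normalization, wt_rows)
    y <- edgeR::scaleOffset(y, off)
  }
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  ct <- resolve_contrast(contrast, design)
  res <- if (is.null(ct$contrast)) {
    edgeR::glmQLFTest(fit, coef = ct$coef)
  } else {
    edgeR::glmQLFTest(fit, contrast = ct$contrast)
  }
  tab <- res$table
  out <- data.frame(
    variant = rownames(m),
    logFC = tab$logFC,
    aveAbundance = tab$logCPM,
    stat = tab$F,
    pvalue = tab$PValue,
    fdr = adjust_fdr(tab$PValue),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("TestResult", class(out))
  out
}

#' Test variants with precision-weighted linear models
#'
#' Log2-CPM transform with a 0.5 pseudocount, a mean-variance trend fitted
#' by local regression and inverted into observation weights, weighted
#' least squares per variant, and empirical-Bayes moderated t-statistics
#' (the limma-voom framework). Effective library sizes implement the
#' normalization: TMM-scaled column totals, or exponentiated wild-type
#' offsets rescaled to the depth of the data.
#'
#' @inheritParams fit_nb_ql
#' @return A data.frame of class `TestResult` (columns as in
#'   [fit_nb_ql()]; `stat` is the moderated t).
#' @export
fit_voom <- function(exp, design, contrast,
                     normalization = c("tmm", "wtsum", "wtgeomean"),
                     wt_rows = NULL, assay = "counts") {
  normalization <- match.arg(normalization)
  m <- as_count_matrix(exp, assay)
  design <- check_design(design, ncol(m))
  if (ncol(m) - ncol(design) < 1)
    stop("no residual degrees of freedom")
  if (normalization == "tmm") {
    ls <- colSums(m) * unname(tmm_factors(m))
  } else {
    off <- resolve_offsets(m, normalization, wt_rows)
    ls <- exp(off)
    ls <- ls * exp(mean(log(colSums(m))) - mean(log(ls)))
  }
  if (any(ls <= 0)) stop("nonpositive effective library size")
  v <- limma::voom(m, design, lib.size = ls)
  fit <- limma::lmFit(v, design)
  ct <- resolve_contrast(contrast, design)
  if (is.null(ct$contrast)) {
    eb <- limma::eBayes(fit)
    tab <- limma::topTable(eb, coef = ct$coef, number = Inf,
                           sort.by = "none")
  } else {
    cfit <- limma::contrasts.fit(fit, contrasts = ct$contrast)
    eb <- limma::eBayes(cfit)
    tab <- limma::topTable(eb, coef = 1L, number = Inf, sort.by = "none")
  }
  out <- data.frame(
    variant = rownames(m),
    logFC = tab$logFC,
    aveAbundance = tab$AveExpr,
    stat = tab$t,
    pvalue = tab$P.Value,
    fdr = adjust_fdr(tab$P.Value),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("TestResult", class(out))
  out
}

#' Filter variants by minimal input-sample count
#'
#' Retains variants whose count exceeds `min_count` in every designated
#' input sample — the standard pre-test filter for input/output selection
#' designs.
#'
#' @param exp Count matrix or `SummarizedExperiment`.
#' @param input_samples Column names or indices of the input samples.
#' @param min_count Threshold (default 50); a variant is kept when its
#'   count is greater than `min_count` in all input samples.
#' @return Logical vector over rows.
#' @export
filter_by_input_count <- function(exp, input_samples, min_count = 50) {
  m <- as_count_matrix(exp)
  rowSums(m[, input_samples, drop = FALSE] > min_count) ==
    length(input_samples)
}

#' Per-replicate wild-type-normalized enrichment (PPI) scores
#'
#' For growth-rate selection assays:
#' `score(v, r) = log2((out_v + p) / (in_v + p)) -
#'  log2((out_wt + p) / (in_wt + p))`,
#' so the wild-type scores are identically 0. Input and output samples are
#' paired by position; an optional multiplicative constant rescales the
#' scores (e.g. to generations of growth).
#'
#' @param exp Count matrix or `SummarizedExperiment`.
#' @param input_samples,output_samples Equal-length vectors of sample ids,
#'   paired by replicate.
#' @param wt_row Row id of the wild-type variant.
#' @param pseudocount Added to every count before forming ratios.
#' @param scale Multiplicative constant applied to the scores.
#' @return Matrix variants x replicates of scores.
#' @export
ppi_scores <- function(exp, input_samples, output_samples, wt_row,
                       pseudocount = 0, scale = 1) {
  m <- as_count_matrix(exp)
  if (length(input_samples) != length(output_samples))
    stop("input and output samples must pair up replicate by replicate")
  if (length(input_samples) == 0) stop("no replicates given")
  inm <- m[, input_samples, drop = FALSE] + pseudocount
  outm <- m[, output_samples, drop = FALSE] + pseudocount
  sc <- log2(outm / inm)
  wt <- sc[wt_row, , drop = TRUE]
  out <- sweep(sc, 2L, wt, "-") * scale
  colnames(out) <- paste0("rep", seq_along(input_samples))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Step-up adjusted values, monotone in the p-value ranking.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
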