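## Merging per-sample digestion results into a joint
## SummarizedExperiment, mutation classification under the standard
## genetic code, amino-acid-level collapsing and diagnostics.

GENETIC_CODE_TABLE <- NULL  # filled at load time from Biostrings

.onLoad <- function(libname, pkgname) {
  GENETIC_CODE_TABLE <<- Biostrings::GENETIC_CODE
}

translate_nt <- function(seq) {
  stopifnot(nchar(seq) %% 3L == 0L)
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) return(NA_character_)
  paste(aa, collapse = "")
}

#' Classify mutations between a variant and its wild-type sequence
#'
#' Compares two equal-length nucleotide sequences base by base and codon by
#' codon (reading frame starting at position 1, standard genetic code). A
#' mutated codon translating to the same residue contributes `"silent"`, to
#' a different residue `"nonsynonymous"`, and to a termination signal
#' `"stop"`. Codon- and amino-acid-level fields require the length to be a
#' multiple of 3; otherwise they are `NA`.
#'
#' @param var_seq,wt_seq Equal-length nucleotide sequences.
#' @return A list with `n_mut_bases`, `n_mut_codons`, `n_mut_aas` and
#'   `mutation_types` (character vector, subset of `silent`,
#'   `nonsynonymous`, `stop`).
#' @examples
#' classify_mutations("GCC", "GCT")  # silent (both Ala)
#' classify_mutations("TGA", "TGG")  # stop (Trp -> ter)
#' @export
classify_mutations <- function(var_seq, wt_seq) {
  if (nchar(var_seq) != nchar(wt_seq))
    stop("variant and wild-type sequences must have equal length")
  p <- cpp_diff_positions(var_seq, wt_seq)
  if (nchar(var_seq) %% 3L != 0L) {
    return(list(n_mut_bases = length(p), n_mut_codons = NA_integer_,
                n_mut_aas = NA_integer_, mutation_types = character(0)))
  }
  ci <- sort(unique((p - 1L) %/% 3L + 1L))
  types <- character(0)
  n_aas <- 0L
  ambiguous <- FALSE
  for (cc in ci) {
    ref_c <- substring(wt_seq, 3L * cc - 2L, 3L * cc)
    alt_c <- substring(var_seq, 3L * cc - 2L, 3L * cc)
    ref_aa <- unname(GENETIC_CODE_TABLE[ref_c])
    alt_aa <- unname(GENETIC_CODE_TABLE[alt_c])
    if (is.na(ref_aa) || is.na(alt_aa)) {
      ## ambiguous bases (e.g. N) have no translation; the codon counts as
      ## mutated but contributes no type and no amino-acid call
      ambiguous <- TRUE
    } else if (alt_aa == ref_aa) {
      types <- c(types, "silent")
    } else if (alt_aa == "*") {
      types <- c(types, "stop")
      n_aas <- n_aas + 1L
    } else {
      types <- c(types, "nonsynonymous")
      n_aas <- n_aas + 1L
    }
  }
  list(n_mut_bases = length(p), n_mut_codons = length(ci),
       n_mut_aas = if (ambiguous) NA_integer_ else n_aas,
       mutation_types = sort(unique(types)))
}

#' Merge per-sample digestion results into a joint experiment
#'
#' Builds a variants x samples [SummarizedExperiment::SummarizedExperiment]
#' whose variant universe is the union across samples; variants not
#' detected in a sample get a count of 0. Read counts (assay `"counts"`)
#' and, when every sample carries UMIs, UMI counts (assay `"umi_counts"`)
#' are stored as separate matrices. Row annotations (closest wild-type,
#' mutation counts and types, representative sequence), per-sample filter
#' tallies and parameter records are propagated. Rows are keyed by
#' (wild-type, variant name) so that equally named variants matched to
#' different wild-types never collide.
#'
#' @param results Named list of `DigestResult` objects (names are sample
#'   names).
#' @param col_data Data.frame of per-sample metadata; rows are matched to
#'   `names(results)` via its row names (or a `name` column).
#' @return A `SummarizedExperiment`.
#' @export
merge_samples <- function(results, col_data = NULL) {
  stopifnot(is.list(results), length(results) >= 1L)
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("'results' must be a named list of DigestResult objects")
  if (anyDuplicated(names(results)))
    stop("duplicate sample names: ",
         paste(unique(names(results)[duplicated(names(results))]),
               collapse = ", "))
  if (!all(vapply(results, inherits, logical(1), "DigestResult")))
    stop("all elements of 'results' must be DigestResult objects")
  sample_names <- names(results)
  if (is.null(col_data)) {
    col_data <- data.frame(name = sample_names, row.names = sample_names)
  } else {
    if (is.null(rownames(col_data)) ||
        all(rownames(col_data) == as.character(seq_len(nrow(col_data))))) {
      if (!"name" %in% colnames(col_data))
        stop("'col_data' needs row names or a 'name' column")
      rownames(col_data) <- col_data$name
    }
    missing <- setdiff(sample_names, rownames(col_data))
    if (length(missing) > 0)
      stop("samples absent from 'col_data': ",
           paste(missing, collapse = ", "))
    col_data <- col_data[sample_names, , drop = FALSE]
  }

  keyed <- lapply(results, function(r) {
    ct <- r$countTable
    wt <- ct$wildtype
    wt[is.na(wt)] <- ""
    key <- paste(wt, ct$variant, sep = "\r")
    cbind(key = key, ct, stringsAsFactors = FALSE)
  })
  all_keys <- sort(unique(unlist(lapply(keyed, `[[`, "key"))))
  nv <- length(all_keys)
  counts <- matrix(0L, nrow = nv, ncol = length(sample_names),
                   dimnames = list(NULL, sample_names))
  have_umi <- vapply(results, function(r) {
    nrow(r$countTable) == 0L || !anyNA(r$countTable$umiCount)
  }, logical(1))
  umi_counts <- if (all(have_umi)) counts else NULL
  for (s in seq_along(sample_names)) {
    k <- keyed[[s]]
    idx <- match(k$key, all_keys)
    counts[idx, s] <- k$readCount
    if (!is.null(umi_counts)) umi_counts[idx, s] <- k$umiCount
  }
  ann_pool <- do.call(rbind, keyed)
  first <- ann_pool[match(all_keys, ann_pool$key), , drop = FALSE]
  row_data <- S4Vectors::DataFrame(
    variant = first$variant,
    wildtype = first$wildtype,
    nMutBases = first$nMutBases,
    nMutCodons = first$nMutCodons,
    nMutAAs = first$nMutAAs,
    mutationTypes = first$mutationTypes,
    sequence = first$sequence
  )
  rn <- make.unique(first$variant)
  rownames(counts) <- rn
  if (!is.null(umi_counts)) rownames(umi_counts) <- rn
  assays <- list(counts = counts)
  if (!is.null(umi_counts)) assays$umi_counts <- umi_counts
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = row_data,
    colData = S4Vectors::DataFrame(col_data)
  )
  S4Vectors::metadata(se)$filterSummaries <-
    lapply(results, `[[`, "filterTally")
  S4Vectors::metadata(se)$paramRecords <-
    lapply(results, `[[`, "params")
  se
}

#' Collapse an experiment to the amino-acid level
#'
#' Variants whose variable sequences translate to the same protein (under
#' the same closest wild-type) are summed per sample; every column sum is
#' conserved. Row annotations are recomputed at the amino-acid level: when
#' the wild-type sequence is available from the propagated parameter
#' records, collapsed rows are named `"WT.pos.AA"` per substituted residue
#' (`*` for a termination); otherwise the protein sequence itself keys the
#' row.
#'
#' @param exp A `SummarizedExperiment` from [merge_samples()].
#' @return A `SummarizedExperiment` with one row per (wild-type, protein).
#' @export
collapse_to_aa <- function(exp) {
  rd <- SummarizedExperiment::rowData(exp)
  seqs <- rd$sequence
  bad <- which(is.na(seqs) | nchar(seqs) %% 3L != 0L)
  if (length(bad) > 0)
    stop("untranslatable variant rows: ",
         paste(utils::head(rownames(exp)[bad], 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  prot <- vapply(seqs, translate_nt, character(1), USE.NAMES = FALSE)
  if (anyNA(prot)) stop("untranslatable variant rows (ambiguous bases): ",
                        paste(utils::head(rownames(exp)[is.na(prot)], 10),
                              collapse = ", "))
  wt <- rd$wildtype
  wt[is.na(wt)] <- ""
  key <- paste(wt, prot, sep = "\r")
  grp <- factor(key, levels = unique(key))

  wt_map <- experiment_wildtype_map(exp)
  aa_name <- character(nlevels(grp))
  aa_nmut <- rep(NA_integer_, nlevels(grp))
  aa_types <- rep(NA_character_, nlevels(grp))
  first <- match(levels(grp), key)
  for (g in seq_len(nlevels(grp))) {
    i <- first[g]
    w <- wt_map[wt[i]]
    if (!is.na(w) && nchar(w) == nchar(seqs[i])) {
      wp <- translate_nt(w)
      dp <- cpp_diff_positions(prot[i], wp)
      if (length(dp) == 0L) {
        aa_name[g] <- wt[i]
      } else {
        alt <- substring(prot[i], dp, dp)
        aa_name[g] <- paste(paste(wt[i], dp, alt, sep = "."), collapse = "_")
      }
      aa_nmut[g] <- length(dp)
      alt <- substring(prot[i], dp, dp)
      tp <- character(0)
      if (any(alt == "*")) tp <- c(tp, "stop")
      if (any(alt != "*")) tp <- c(tp, "nonsynonymous")
      aa_types[g] <- paste(sort(tp), collapse = ",")
    } else {
      aa_name[g] <- paste0(wt[i], if (nzchar(wt[i])) ":" else "", prot[i])
    }
  }

  collapse_assay <- function(m) {
    out <- rowsum(m, group = grp, reorder = FALSE)
    storage.mode(out) <- storage.mode(m)
    out
  }
  assays <- lapply(SummarizedExperiment::assays(exp), collapse_assay)
  rn <- make.unique(aa_name)
  for (a in seq_along(assays)) rownames(assays[[a]]) <- rn
  row_data <- S4Vectors::DataFrame(
    variant = aa_name,
    wildtype = wt[first],
    protein = prot[first],
    nMutAAs = aa_nmut,
    mutationTypes = aa_types
  )
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = row_data,
    colData = SummarizedExperiment::colData(exp)
  )
  S4Vectors::metadata(out) <- S4Vectors::metadata(exp)
  out
}

## wild-type name -> sequence, from the propagated parameter records.
experiment_wildtype_map <- function(exp) {
  recs <- S4Vectors::metadata(exp)$paramRecords
  m <- character(0)
  for (r in recs) {
    wm <- tryCatch(wildtype_sequence_map(r), error = function(e) NULL)
    if (!is.null(wm)) m <- c(m, wm[setdiff(names(wm), names(m))])
  }
  m
}

#' Pairwise sample correlations of log-transformed counts
#'
#' Pearson correlation of `log10(count + 1)` across variants, for all
#' sample pairs. Samples with zero variance yield `NA` entries.
#'
#' @param exp A `SummarizedExperiment` (>= 2 samples).
#' @param assay Assay name (default `"counts"`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlations <- function(exp, assay = "counts") {
  m <- SummarizedExperiment::assay(exp, assay)
  if (ncol(m) < 2L) stop("at least two samples required")
  suppressWarnings(stats::cor(log10(m + 1), method = "pearson"))
}

#' Long-format summary of the read-filtering cascade
#'
#' @param exp A `SummarizedExperiment` carrying per-sample filter tallies
#'   (from [merge_samples()]).
#' @return A data.frame with columns `sample`, `reason` (the ordered filter
#'   reasons plus `"retained"`), `count` and `fraction` (of `nTotal`;
#'   fractions per sample sum to 1).
#' @export
filtering_summary <- function(exp) {
  fs <- S4Vectors::metadata(exp)$filterSummaries
  if (is.null(fs)) stop("no filter summaries stored in this experiment")
  out <- do.call(rbind, lapply(names(fs), function(s) {
    t <- fs[[s]]
    reasons <- c(FILTER_KEYS, "nRetained")
    data.frame(
      sample = s,
      reason = c(FILTER_KEYS, "retained"),
      count = unname(t[reasons]),
      fraction = unname(t[reasons]) / t[["nTotal"]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
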