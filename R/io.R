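## Plain-text serialization of digestion results and joint experiments.
## Every container is written as a directory of TSV files plus a JSON
## parameter record, and the loaders restore the tabular content exactly.

write_tsv <- function(df, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                rownames_col),
                as.data.frame(df, stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, na.strings = "NA")
}

params_to_json <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE,
                       pretty = TRUE)
}

#' Write a digestion result to a directory
#'
#' Writes `counts.tsv` (the variant count table), `filter.tsv` (the
#' ordered filter tally), `error_tally.tsv` (per-quality match/mismatch
#' counts), `error_rates.tsv` (the derived rate estimates) and
#' `params.json`.
#'
#' @param res A `DigestResult`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_digest_result <- function(res, dir) {
  stopifnot(inherits(res, "DigestResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$countTable, file.path(dir, "counts.tsv"))
  write_tsv(data.frame(step = names(res$filterTally),
                       count = unname(res$filterTally)),
            file.path(dir, "filter.tsv"))
  write_tsv(data.frame(quality = 0:93,
                       nMatch = res$errorTally[, 1L],
                       nMismatch = res$errorTally[, 2L]),
            file.path(dir, "error_tally.tsv"))
  write_tsv(estimate_error_rates(res$errorTally),
            file.path(dir, "error_rates.tsv"))
  params_to_json(res$params, file.path(dir, "params.json"))
  invisible(dir)
}

#' Read a digestion result written by [write_digest_result()]
#'
#' @param dir Directory path.
#' @return A `DigestResult`.
#' @export
read_digest_result <- function(dir) {
  ct <- read_tsv(file.path(dir, "counts.tsv"))
  for (col in c("variant", "mutationTypes", "sequences", "wildtype",
                "sequence")) {
    if (col %in% colnames(ct)) ct[[col]] <- as.character(ct[[col]])
  }
  ft <- read_tsv(file.path(dir, "filter.tsv"))
  et <- read_tsv(file.path(dir, "error_tally.tsv"))
  tally <- matrix(c(et$nMatch, et$nMismatch), ncol = 2,
                  dimnames = list(quality = 0:93, c("nMatch", "nMismatch")))
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  structure(list(
    countTable = ct,
    filterTally = stats::setNames(as.integer(ft$count), ft$step),
    errorTally = tally,
    params = params
  ), class = "DigestResult")
}

#' Write a joint experiment to a directory
#'
#' Writes `counts.tsv` (and `umi_counts.tsv` when present),
#' `row_data.tsv`, `col_data.tsv`, `filter.tsv` (the long-format
#' filtering summary) and `params.json` (the per-sample parameter
#' records). [read_experiment()] restores the tabular content exactly.
#'
#' @param exp A `SummarizedExperiment` from [merge_samples()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in SummarizedExperiment::assayNames(exp)) {
    write_tsv(as.data.frame(SummarizedExperiment::assay(exp, a)),
              file.path(dir, paste0(a, ".tsv")), rownames_col = "variant")
  }
  rd <- as.data.frame(SummarizedExperiment::rowData(exp))
  write_tsv(rd, file.path(dir, "row_data.tsv"), rownames_col = "row")
  cd <- as.data.frame(SummarizedExperiment::colData(exp))
  write_tsv(cd, file.path(dir, "col_data.tsv"), rownames_col = "sample")
  fs <- S4Vectors::metadata(exp)$filterSummaries
  if (!is.null(fs)) {
    write_tsv(filtering_summary(exp), file.path(dir, "filter.tsv"))
  }
  params_to_json(S4Vectors::metadata(exp)$paramRecords,
                 file.path(dir, "params.json"))
  invisible(dir)
}

#' Read a joint experiment written by [write_experiment()]
#'
#' @param dir Directory path.
#' @return A `SummarizedExperiment`.
#' @export
read_experiment <- function(dir) {
  read_assay <- function(path) {
    df <- read_tsv(path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "integer"
    m
  }
  assays <- list(counts = read_assay(file.path(dir, "counts.tsv")))
  up <- file.path(dir, "umi_counts.tsv")
  if (file.exists(up)) assays$umi_counts <- read_assay(up)
  rd <- read_tsv(file.path(dir, "row_data.tsv"))
  rownames(rd) <- as.character(rd$row)
  rd$row <- NULL
  cd <- read_tsv(file.path(dir, "col_data.tsv"))
  rownames(cd) <- as.character(cd$sample)
  cd$sample <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(rd),
    colData = S4Vectors::DataFrame(cd)
  )
  fp <- file.path(dir, "filter.tsv")
  if (file.exists(fp)) {
    long <- read_tsv(fp)
    fs <- lapply(split(long, long$sample), function(d) {
      keys <- ifelse(d$reason == "retained", "nRetained", d$reason)
      tly <- stats::setNames(as.integer(d$count), keys)
      c(nTotal = sum(tly), tly[c(FILTER_KEYS, "nRetained")])
    })
    S4Vectors::metadata(se)$filterSummaries <-
      fs[colnames(se)]
  }
  pj <- file.path(dir, "params.json")
  if (file.exists(pj)) {
    S4Vectors::metadata(se)$paramRecords <-
      jsonlite::read_json(pj, simplifyVector = TRUE)
  }
  se
}
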