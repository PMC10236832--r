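## Greedy collapsing of similar sequences (reference-free variants) and
## UMI deduplication. Both sweep sequences in decreasing count order
## (ties broken lexicographically): each unabsorbed sequence seeds a
## cluster, and every later sequence is absorbed into the earliest seed
## within the Hamming radius whose (original) count satisfies the
## abundance and ratio thresholds. Absorption is single-pass and
## non-transitive: an absorbed sequence never absorbs others.

greedy_order <- function(counts) {
  order(-counts, names(counts), method = "radix")
}

#' Collapse low-frequency sequences into similar abundant ones
#'
#' Intended for reference-free digestion, where distinct variable
#' sequences that differ by sequencing or PCR errors should be merged. A
#' sequence is absorbed into the first (most abundant) cluster seed with
#' Hamming distance at most `max_distance`, seed count at least
#' `min_abundance`, and seed-to-own count ratio at least `min_ratio`
#' (thresholds are tested against the original, pre-collapse counts).
#' Sequences of unequal length are never merged. Total read counts are
#' conserved.
#'
#' @param counts Named numeric vector: sequence -> read count.
#' @param max_distance Hamming radius for absorption (0 = identity
#'   transform).
#' @param min_abundance Minimal count of the absorbing seed.
#' @param min_ratio Minimal ratio seed count / absorbed count.
#' @return A data.frame with columns `sequence`, `count` and a list column
#'   `constituents` (the absorbed sequences, seed included), ordered by
#'   decreasing collapsed count.
#' @examples
#' collapse_sequences(c(AAAA = 100, AAAT = 5), max_distance = 1,
#'                    min_ratio = 5)
#' @export
collapse_sequences <- function(counts, max_distance = 0L,
                               min_abundance = 0, min_ratio = 0) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0), max_distance >= 0,
            min_abundance >= 0, min_ratio >= 0)
  if (length(counts) == 0) {
    return(data.frame(sequence = character(0), count = numeric(0),
                      constituents = I(list())))
  }
  o <- greedy_order(counts)
  seqs <- names(counts)[o]
  cnt <- unname(counts[o])
  assign <- cpp_greedy_collapse(seqs, cnt, as.integer(max_distance),
                                min_abundance, min_ratio)
  seed_idx <- sort(unique(assign))
  out <- data.frame(
    sequence = seqs[seed_idx],
    count = vapply(seed_idx, function(s) sum(cnt[assign == s]), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$constituents <- I(lapply(seed_idx, function(s) seqs[assign == s]))
  out[order(-out$count, out$sequence, method = "radix"), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Deduplicate UMIs within one variant
#'
#' Greedy absorption identical to [collapse_sequences()] but without
#' abundance or ratio thresholds: UMIs within `max_distance` of a more
#' abundant UMI are treated as sequencing-error copies of it.
#'
#' @param umis Named numeric vector: UMI -> read count.
#' @param max_distance Hamming radius (0 = count distinct UMIs).
#' @return Integer: the number of surviving (deduplicated) UMIs.
#' @examples
#' collapse_umis(c(ACGT = 10, ACGA = 1), max_distance = 1)  # 1
#' @export
collapse_umis <- function(umis, max_distance = 0L) {
  stopifnot(is.numeric(umis), !is.null(names(umis)), max_distance >= 0)
  if (length(umis) == 0) return(0L)
  if (max_distance == 0) return(length(umis))
  o <- greedy_order(umis)
  assign <- cpp_greedy_collapse(names(umis)[o], unname(umis[o]),
                                as.integer(max_distance), 0, 0)
  length(unique(assign))
}
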