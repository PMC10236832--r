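## Independent oracles and fixture builders. Each oracle recomputes the
## quantity it checks by the most naive route available, with no shared
## code with the implementation path.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

qual_string <- function(phred, len) {
  strrep(intToUtf8(phred + 33L), len)
}

## Exhaustive nearest-wild-type scan: recomputes all Hamming distances with
## a character-by-character loop and applies the budget/tie rules directly.
oracle_match <- function(seq, wt_set, unit = "base", max_mutations = Inf) {
  ham <- function(a, b) {
    if (nchar(a) != nchar(b)) return(NA_integer_)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  d <- vapply(wt_set, ham, integer(1), a = seq)
  if (all(is.na(d))) return(list(reason = "fNoValidWildtype"))
  dmin <- min(d, na.rm = TRUE)
  hits <- names(d)[!is.na(d) & d == dmin]
  if (length(hits) > 1) return(list(reason = "fNoValidWildtype"))
  if (unit == "base" && dmin > max_mutations)
    return(list(reason = "fNoValidWildtype"))
  w <- wt_set[[hits]]
  pos <- which(strsplit(seq, "")[[1]] != strsplit(w, "")[[1]])
  cidx <- sort(unique((pos - 1) %/% 3 + 1))
  if (unit == "codon" && length(cidx) > max_mutations)
    return(list(reason = "fTooManyMutations"))
  list(reason = NA_character_, wt = hits, n_mut_bases = length(pos),
       n_mut_codons = length(cidx), pos = pos)
}

## Naive greedy collapse: visits sequences in decreasing count order (ties
## lexicographic) and absorbs each one into the earliest qualifying seed.
oracle_collapse <- function(counts, max_distance, min_abundance = 0,
                            min_ratio = 0) {
  ham <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  o <- order(-counts, names(counts), method = "radix")
  seqs <- names(counts)[o]
  cnt <- unname(counts[o])
  seed_of <- integer(length(seqs))
  seeds <- integer(0)
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (s in seeds) {
      if (cnt[s] >= min_abundance &&
          (cnt[i] == 0 || cnt[s] / cnt[i] >= min_ratio) &&
          ham(seqs[i], seqs[s]) <= max_distance) {
        seed_of[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, i)
      seed_of[i] <- i
    }
  }
  out <- lapply(unique(seed_of), function(s) {
    list(sequence = seqs[s], count = sum(cnt[seed_of == s]),
         constituents = sort(seqs[seed_of == s]))
  })
  out[order(-vapply(out, `[[`, numeric(1), "count"),
            vapply(out, `[[`, character(1), "sequence"),
            method = "radix")]
}

## Independent trimmed-mean-of-M-values implementation (doubly trimmed,
## precision-weighted), coded directly from the published algorithm.
oracle_tmm <- function(counts, ref = 1) {
  lib <- colSums(counts)
  one <- function(obs, nO, refc, nR) {
    M <- log2((obs / nO) / (refc / nR))
    A <- (log2(obs / nO) + log2(refc / nR)) / 2
    keep <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[keep]; A <- A[keep]; obs <- obs[keep]; refc <- refc[keep]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    kp <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    2^(sum(M[kp] / v[kp], na.rm = TRUE) / sum(1 / v[kp], na.rm = TRUE))
  }
  f <- vapply(seq_len(ncol(counts)), function(s)
    one(counts[, s], lib[s], counts[, ref], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

all_codons <- function() {
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T"))[, 3:1], 1L,
        paste0, collapse = "")
}

## Build a small DigestResult by hand (for merge tests without FASTQ I/O).
fake_digest_result <- function(counts, wildtype = NULL, sequences = NULL,
                               umi = NULL) {
  n <- length(counts)
  ft <- stats::setNames(integer(length(mavekit:::FILTER_KEYS)),
                        mavekit:::FILTER_KEYS)
  structure(list(
    countTable = data.frame(
      variant = names(counts),
      readCount = as.integer(counts),
      umiCount = if (is.null(umi)) rep(NA_integer_, n) else as.integer(umi),
      nMutBases = rep(NA_integer_, n),
      nMutCodons = rep(NA_integer_, n),
      nMutAAs = rep(NA_integer_, n),
      mutationTypes = rep(NA_character_, n),
      sequences = if (is.null(sequences)) names(counts) else sequences,
      wildtype = if (is.null(wildtype)) rep(NA_character_, n) else wildtype,
      sequence = if (is.null(sequences)) names(counts) else sequences,
      stringsAsFactors = FALSE),
    filterTally = c(nTotal = sum(counts), ft, nRetained = sum(counts)),
    errorTally = matrix(0L, 94, 2,
                        dimnames = list(quality = 0:93,
                                        c("nMatch", "nMismatch"))),
    params = list()
  ), class = "DigestResult")
}

## Standard paired-end simulation setup used across tests: two wild-types,
## forward read SUCV (1 skip, 10 nt UMI, 18 nt constant, 66 nt variable),
## reverse read V (66 nt), 36 nt overlap covering a 96 nt variable region.
std_sim_setup <- function(seed = 1L, n_per_wt = 20L) {
  set.seed(seed)
  wt <- c(GENEA = random_seq(96), GENEB = random_seq(96))
  const <- random_seq(18)
  list(
    wildtypes = wt,
    constant = const,
    layout_fwd = parse_element_spec("SUCV", c(1, 10, 18, 66)),
    layout_rev = parse_element_spec("V", 66),
    variants = sim_variants(wt, n_per_wt = n_per_wt, wt_freq = 0.2,
                            seed = seed + 1L),
    params = digest_params(
      wildtype = wt, unit = "codon", max_mutations = 1,
      merge = TRUE, rev_complement_rev = TRUE,
      min_overlap = 20, min_merged_length = 96, max_merged_length = 96,
      constant = const)
  )
}
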