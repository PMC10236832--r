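## Per-sample digestion: FASTQ -> variant count table under an ordered
## filter cascade. The cascade order is fixed: adapter -> segmentation
## (primer, read length) -> reverse-complement -> pair merging -> average
## quality -> N content (variable, UMI) -> wild-type matching (distance
## budget, mutation quality, forbidden codons) -> constant-region check.
## The first failing step claims the read in the filter tally.

FILTER_KEYS <- c(
  "fAdapter", "fNoPrimer", "fReadLengthMismatch", "fMergeFailed",
  "fAvgQualTooLow", "fTooManyNinVar", "fTooManyNinUmi",
  "fNoValidWildtype", "fTooManyMutations", "fMutQualTooLow",
  "fForbiddenCodon", "fConstantMismatch"
)

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Parameters for per-sample digestion
#'
#' Collects all per-read thresholds and options of the digestion cascade.
#' Defaults are permissive: no adapters, no merging, no wild-type sets, no
#' quality or N filters, and no read cap.
#'
#' @param adapter_fwd,adapter_rev Adapter sequences; a read (pair) is
#'   dropped when the forward adapter occurs as an exact substring of the
#'   forward read or the reverse adapter occurs in the reverse read.
#' @param rev_complement_fwd,rev_complement_rev Reverse-complement the
#'   extracted variable and constant sequences of the forward / reverse
#'   mate (qualities are reversed alongside). Typically
#'   `rev_complement_rev = TRUE` when merging overlapping mates.
#' @param merge Merge the forward and reverse variable regions by overlap
#'   (paired-end only).
#' @param min_overlap,max_overlap Allowed overlap widths for merging.
#' @param min_merged_length,max_merged_length Allowed merged lengths.
#' @param max_mismatch_fraction Maximal fraction of mismatching bases in
#'   the accepted overlap.
#' @param wildtype Named character vector of wild-type sequences for the
#'   (merged or forward) variable region; `NULL` for reference-free mode.
#' @param wildtype_rev Optional separate wild-type set for the reverse
#'   variable region (paired, unmerged designs with two variable regions).
#' @param unit Mutation unit, `"base"` or `"codon"`; controls both the
#'   mutation budget and variant naming.
#' @param max_mutations Maximal number of mutated bases (`unit = "base"`)
#'   or mutated codons (`unit = "codon"`).
#' @param min_mutation_quality Minimal base quality required at every
#'   mutated position.
#' @param forbidden_codons Character vector of IUPAC codon patterns (e.g.
#'   `"NNW"`); a read is dropped when any observed mutated codon matches.
#' @param avg_qual_min Minimal arithmetic mean Phred score of the variable
#'   region.
#' @param max_n_variable,max_n_umi Maximal number of `N` bases tolerated in
#'   the variable region / the UMI.
#' @param constant,constant_rev Reference sequence(s) for the forward /
#'   reverse constant region; used for the error tally and the
#'   constant-mismatch filter.
#' @param max_constant_mismatch Maximal Hamming distance to the nearest
#'   constant reference.
#' @param max_reads Process only the first `max_reads` reads.
#' @param excluded_path Base path for FASTQ export of excluded reads (the
#'   filter reason is appended to the read identifier after a space).
#' @param umi_collapse_max_dist Hamming radius for greedy UMI collapsing
#'   within each variant (0 = exact deduplication).
#' @param collapse_max_dist,collapse_min_count,collapse_min_ratio
#'   Reference-free collapsing of similar variable sequences (only applied
#'   when no wild-type set is given); see [collapse_sequences()].
#' @return A list of class `DigestParams`.
#' @export
digest_params <- function(adapter_fwd = NULL, adapter_rev = NULL,
                          rev_complement_fwd = FALSE,
                          rev_complement_rev = FALSE,
                          merge = FALSE,
                          min_overlap = 1L, max_overlap = Inf,
                          min_merged_length = 0L, max_merged_length = Inf,
                          max_mismatch_fraction = 0,
                          wildtype = NULL, wildtype_rev = NULL,
                          unit = c("base", "codon"),
                          max_mutations = Inf,
                          min_mutation_quality = 0L,
                          forbidden_codons = NULL,
                          avg_qual_min = 0,
                          max_n_variable = Inf, max_n_umi = Inf,
                          constant = NULL, constant_rev = NULL,
                          max_constant_mismatch = Inf,
                          max_reads = NULL, excluded_path = NULL,
                          umi_collapse_max_dist = 0L,
                          collapse_max_dist = 0L,
                          collapse_min_count = 0L,
                          collapse_min_ratio = 0) {
  unit <- match.arg(unit)
  chk_nonneg <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0)
      stop("'", nm, "' must be a single nonnegative number")
  }
  for (nm in c("min_overlap", "min_merged_length", "max_mismatch_fraction",
               "max_mutations", "min_mutation_quality", "avg_qual_min",
               "max_n_variable", "max_n_umi", "max_constant_mismatch",
               "umi_collapse_max_dist", "collapse_max_dist",
               "collapse_min_count", "collapse_min_ratio")) {
    chk_nonneg(get(nm), nm)
  }
  if (!is.null(forbidden_codons)) {
    if (any(nchar(forbidden_codons) != 3L))
      stop("forbidden codon patterns must have length 3")
    bad <- setdiff(unique(strsplit(paste(forbidden_codons, collapse = ""),
                                   "")[[1]]), names(IUPAC_SETS))
    if (length(bad) > 0)
      stop("invalid IUPAC letter(s) in forbidden codons: ",
           paste(bad, collapse = ", "))
  }
  for (ws in list(wildtype, wildtype_rev)) {
    if (!is.null(ws)) {
      if (is.null(names(ws)) || any(!nzchar(names(ws))))
        stop("wild-type sequences must be named")
      if (anyDuplicated(names(ws)))
        stop("wild-type names must be unique")
    }
  }
  structure(as.list(environment())[c(
    "adapter_fwd", "adapter_rev", "rev_complement_fwd",
    "rev_complement_rev", "merge", "min_overlap", "max_overlap",
    "min_merged_length", "max_merged_length", "max_mismatch_fraction",
    "wildtype", "wildtype_rev", "unit", "max_mutations",
    "min_mutation_quality", "forbidden_codons", "avg_qual_min",
    "max_n_variable", "max_n_umi", "constant", "constant_rev",
    "max_constant_mismatch", "max_reads", "excluded_path",
    "umi_collapse_max_dist", "collapse_max_dist", "collapse_min_count",
    "collapse_min_ratio")], class = "DigestParams")
}

#' Adapter detection by exact substring containment
#'
#' @param fwd_seq,rev_seq Read sequences (vectors; `rev_seq` optional).
#' @param adapter_fwd,adapter_rev Adapter sequences; `NULL` or empty
#'   adapters never match.
#' @return Logical vector: `TRUE` where the read (pair) contains an
#'   adapter.
#' @export
contains_adapter <- function(fwd_seq, rev_seq = NULL,
                             adapter_fwd = NULL, adapter_rev = NULL) {
  hit <- rep(FALSE, length(fwd_seq))
  if (!is.null(adapter_fwd) && nzchar(adapter_fwd))
    hit <- hit | grepl(adapter_fwd, fwd_seq, fixed = TRUE)
  if (!is.null(rev_seq) && !is.null(adapter_rev) && nzchar(adapter_rev))
    hit <- hit | grepl(adapter_rev, rev_seq, fixed = TRUE)
  hit
}

#' Merge a read pair by overlap
#'
#' The reverse sequence must already be reverse-complemented (and its
#' qualities reversed) so that both mates are in forward orientation.
#' Overlap widths are scanned from the longest allowed down to the
#' shortest; the first width whose mismatch fraction and merged length are
#' admissible is accepted. At discordant overlap positions the base with
#' the higher quality wins (tie: forward base); the retained quality is the
#' maximum of the two.
#'
#' @param fwd_seq,fwd_qual Forward variable sequence and qualities.
#' @param rev_seq,rev_qual Reverse variable sequence (already
#'   reverse-complemented) and qualities (already reversed).
#' @param min_overlap,max_overlap,min_merged_length,max_merged_length,max_mismatch_fraction
#'   Merge options; see [digest_params()].
#' @return A list with `seq` and `qual`, or a `filter_reason`
#'   (`"fMergeFailed"`) when no admissible overlap exists.
#' @export
merge_pair <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                       min_overlap = 1L, max_overlap = Inf,
                       min_merged_length = 0L, max_merged_length = Inf,
                       max_mismatch_fraction = 0) {
  res <- cpp_merge_pairs(
    fwd_seq, fwd_qual, rev_seq, rev_qual,
    as.integer(min_overlap), as.integer(min(max_overlap, .Machine$integer.max)),
    as.integer(min_merged_length),
    as.integer(min(max_merged_length, .Machine$integer.max)),
    max_mismatch_fraction)
  if (length(fwd_seq) == 1L) {
    if (!res$ok[1L]) return(filter_reason("fMergeFailed"))
    return(list(seq = res$seq[1L], qual = res$qual[1L]))
  }
  res
}

## IUPAC codon pattern match: TRUE where codon (3 nt) matches any pattern.
iupac_codon_match <- function(codons, patterns) {
  hit <- rep(FALSE, length(codons))
  for (pat in patterns) {
    sets <- IUPAC_SETS[strsplit(pat, "")[[1]]]
    ok <- nchar(codons) == 3L
    for (k in 1:3) {
      ok <- ok & substring(codons, k, k) %in% sets[[k]]
    }
    hit <- hit | ok
  }
  hit
}

## Phred values (0-based) of single characters, vectorised via one
## utf8ToInt call on the pasted string.
phred_of_chars <- function(chars) {
  out <- rep(NA_integer_, length(chars))
  nz <- nzchar(chars) & !is.na(chars)
  if (any(nz)) out[nz] <- utf8ToInt(paste(chars[nz], collapse = "")) - 33L
  out
}

## Core wild-type matcher operating on unique sequences. Returns a list of
## per-unique-entry vectors/lists:
##   reason  - NA, "fNoValidWildtype" or "fTooManyMutations"
##   wt      - name of assigned wild-type (NA where filtered)
##   pos     - list of 1-based mutated base positions
##   cidx    - list of 1-based mutated codon indices
##   name    - variant name under the requested unit
##   n_mut_bases, n_mut_codons
##   forbidden - logical, any observed mutated codon matches a pattern
match_engine <- function(uniq, wt_set, params) {
  n <- length(uniq)
  D <- cpp_hamming_matrix(uniq, as.character(wt_set))
  wt_names <- names(wt_set)
  reason <- rep(NA_character_, n)
  wt <- rep(NA_character_, n)
  name <- rep(NA_character_, n)
  nb <- rep(NA_integer_, n)
  nc <- rep(NA_integer_, n)
  pos <- vector("list", n)
  cidx <- vector("list", n)
  forbidden <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    if (all(is.na(d))) { reason[i] <- "fNoValidWildtype"; next }
    dmin <- min(d, na.rm = TRUE)
    hits <- which(!is.na(d) & d == dmin)
    if (length(hits) > 1L) { reason[i] <- "fNoValidWildtype"; next }
    if (params$unit == "base" && dmin > params$max_mutations) {
      reason[i] <- "fNoValidWildtype"; next
    }
    j <- hits[1L]
    w <- as.character(wt_set[j])
    p <- cpp_diff_positions(uniq[i], w)
    ci <- sort(unique((p - 1L) %/% 3L + 1L))
    if (params$unit == "codon" && length(ci) > params$max_mutations) {
      wt[i] <- wt_names[j]
      reason[i] <- "fTooManyMutations"; next
    }
    wt[i] <- wt_names[j]
    pos[[i]] <- p
    cidx[[i]] <- ci
    nb[i] <- length(p)
    nc[i] <- length(ci)
    if (length(p) == 0L) {
      name[i] <- wt_names[j]
    } else if (params$unit == "base") {
      alt <- substring(uniq[i], p, p)
      name[i] <- paste(paste(wt_names[j], p, alt, sep = "."),
                       collapse = "_")
    } else {
      alt <- substring(uniq[i], (ci - 1L) * 3L + 1L, ci * 3L)
      name[i] <- paste(paste(wt_names[j], ci, alt, sep = "."),
                       collapse = "_")
    }
    if (!is.null(params$forbidden_codons) && length(ci) > 0L) {
      obs <- substring(uniq[i], (ci - 1L) * 3L + 1L, ci * 3L)
      forbidden[i] <- any(iupac_codon_match(obs, params$forbidden_codons))
    }
  }
  list(reason = reason, wt = wt, pos = pos, cidx = cidx, name = name,
       n_mut_bases = nb, n_mut_codons = nc, forbidden = forbidden)
}

#' Match a variable region to the nearest wild-type sequence
#'
#' Computes the Hamming distance from `var_seq` to every wild-type sequence
#' of compatible length and assigns the unique nearest one. The read is
#' filtered out (`"fNoValidWildtype"`) when no wild-type is within the
#' mutation budget or when two or more wild-types tie at the minimal
#' distance; with `unit = "codon"`, exceeding the mutated-codon budget
#' yields `"fTooManyMutations"`; a mutated base with quality below
#' `min_mutation_quality` yields `"fMutQualTooLow"`; an observed mutated
#' codon matching a forbidden IUPAC pattern yields `"fForbiddenCodon"`.
#'
#' @param var_seq Variable-region sequence (character scalar).
#' @param var_qual Phred+33 quality string (same length); may be `NULL` if
#'   `min_mutation_quality` is 0.
#' @param wt_set Named character vector of wild-type sequences.
#' @param params A [digest_params()] object.
#' @return A list of class `MatchResult` with `wt_name`, `mutations` (a
#'   data.frame with columns `position`, `ref`, `alt`; positions are
#'   1-based in base or codon units depending on `params$unit`),
#'   `n_mut_bases` and `n_mut_codons`; or a `filter_reason`.
#' @export
match_to_wildtype <- function(var_seq, var_qual = NULL, wt_set,
                              params = digest_params()) {
  stopifnot(length(var_seq) == 1L, length(wt_set) >= 1L)
  eng <- match_engine(var_seq, wt_set, params)
  if (!is.na(eng$reason[1L])) return(filter_reason(eng$reason[1L]))
  p <- eng$pos[[1L]]
  if (length(p) > 0L && params$min_mutation_quality > 0) {
    if (is.null(var_qual)) stop("'var_qual' needed for the mutation-quality filter")
    q <- phred_of_chars(substring(var_qual, p, p))
    if (any(q < params$min_mutation_quality))
      return(filter_reason("fMutQualTooLow"))
  }
  if (eng$forbidden[1L]) return(filter_reason("fForbiddenCodon"))
  w <- as.character(wt_set[eng$wt[1L]])
  if (length(p) == 0L) {
    mut <- data.frame(position = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  } else if (params$unit == "base") {
    mut <- data.frame(position = p,
                      ref = substring(w, p, p),
                      alt = substring(var_seq, p, p),
                      stringsAsFactors = FALSE)
  } else {
    ci <- eng$cidx[[1L]]
    mut <- data.frame(position = ci,
                      ref = substring(w, (ci - 1L) * 3L + 1L, ci * 3L),
                      alt = substring(var_seq, (ci - 1L) * 3L + 1L, ci * 3L),
                      stringsAsFactors = FALSE)
  }
  structure(list(wt_name = eng$wt[1L], mutations = mut,
                 n_mut_bases = eng$n_mut_bases[1L],
                 n_mut_codons = eng$n_mut_codons[1L]),
            class = "MatchResult")
}

#' Build a variant name from a match
#'
#' Variant identifiers consist of the name of the closest wild-type
#' sequence augmented with the observed deviations: `"WT.pos.ALT"` per
#' mutated base (or `"WT.codonIndex.ALTCODON"` per mutated codon), joined
#' in position order with `"_"`. A match with no mutations yields the bare
#' wild-type name.
#'
#' @param match A `MatchResult` (see [match_to_wildtype()]).
#' @param unit `"base"` or `"codon"`; must agree with the unit the match
#'   was computed under.
#' @return Character scalar.
#' @export
name_variant <- function(match, unit = c("base", "codon")) {
  unit <- match.arg(unit)
  stopifnot(inherits(match, "MatchResult"))
  if (nrow(match$mutations) == 0L) return(match$wt_name)
  paste(paste(match$wt_name, match$mutations$position,
              match$mutations$alt, sep = "."), collapse = "_")
}

#' Check a constant region against reference(s) and tally errors
#'
#' The nearest reference by Hamming distance (among references of matching
#' length) is used; the read fails when the distance exceeds
#' `max_mismatch` or when two or more references tie. Match/mismatch
#' counts per base quality are accumulated regardless of the pass/fail
#' outcome and feed the sequencing-error-rate estimate.
#'
#' @param const_seq,const_qual Constant-region sequences and qualities
#'   (vectors).
#' @param const_refs Character vector of reference sequences.
#' @param max_mismatch Maximal tolerated Hamming distance.
#' @return A list with `pass` (logical vector) and `tally` (94 x 2 integer
#'   matrix of `nMatch`, `nMismatch` by quality 0..93).
#' @export
check_constant <- function(const_seq, const_qual, const_refs,
                           max_mismatch = Inf) {
  res <- cpp_constant_check(const_seq, const_qual,
                            as.character(const_refs), max_mismatch)
  dimnames(res$tally) <- list(quality = 0:93, c("nMatch", "nMismatch"))
  res
}

#' Quality and N-content filters on extracted components
#'
#' Reasons are evaluated in order: average variable-region quality
#' (`"fAvgQualTooLow"`), N count in the variable region
#' (`"fTooManyNinVar"`), N count in the UMI (`"fTooManyNinUmi"`).
#'
#' @param components A `ComponentSet` (see [segment_read()]).
#' @param params A [digest_params()] object.
#' @return `"pass"` or a `filter_reason`.
#' @export
quality_filters <- function(components, params = digest_params()) {
  avg <- cpp_phred_means(components$variable_qual)
  if (!is.nan(avg) && avg < params$avg_qual_min)
    return(filter_reason("fAvgQualTooLow"))
  if (cpp_count_char(components$variable, "N") > params$max_n_variable)
    return(filter_reason("fTooManyNinVar"))
  if (cpp_count_char(components$umi, "N") > params$max_n_umi)
    return(filter_reason("fTooManyNinUmi"))
  "pass"
}

## Read one or more FASTQ files (plain or gzipped) into character vectors.
read_fastq_files <- function(paths) {
  ids <- seqs <- quals <- character(0)
  for (p in paths) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
    x <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p)),
      error = function(e) stop("failed to read FASTQ file '", p, "' near record ",
                               "boundary: ", conditionMessage(e), call. = FALSE))
    ids <- c(ids, names(x))
    seqs <- c(seqs, as.character(x))
    quals <- c(quals, as.character(Biostrings::quality(x)))
  }
  list(id = ids, seq = unname(seqs), qual = unname(quals))
}

write_fastq_records <- function(path, ids, seqs, quals, gzip = FALSE) {
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids) > 0) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  }
  invisible(path)
}

#' Digest FASTQ files into a variant count table
#'
#' Runs the full per-sample cascade: adapter detection, layout
#' segmentation, optional reverse-complementing and pair merging, quality
#' and N filters, nearest-wild-type matching with mutation-budget,
#' mutation-quality and forbidden-codon checks, and the constant-region
#' check with per-quality error tallies. Retained reads are tabulated by
#' variant name (and distinct UMIs when the layout contains a `U`
#' element). In reference-free mode (no wild-type set), variants are keyed
#' by their variable sequence and can be greedily collapsed.
#'
#' The result is deterministic and independent of the order of the input
#' reads.
#'
#' @param fastq_fwd Character vector of forward FASTQ paths (internally
#'   concatenated).
#' @param fastq_rev Optional reverse FASTQ paths (same length as
#'   `fastq_fwd`; record order must be synchronized).
#' @param layout_fwd,layout_rev `ElementSpec` layouts (see
#'   [parse_element_spec()]); `layout_rev` required for paired input.
#' @param params A [digest_params()] object.
#' @return A list of class `DigestResult` with components `countTable`
#'   (data.frame: variant, readCount, umiCount, nMutBases, nMutCodons,
#'   nMutAAs, mutationTypes, sequences, wildtype, sequence),
#'   `filterTally` (named integer vector: nTotal, the ordered filter
#'   counters, nRetained), `errorTally` (94 x 2 matrix) and `params` (the
#'   parameter record plus timestamp and package version).
#' @export
digest_sample <- function(fastq_fwd, fastq_rev = NULL,
                          layout_fwd, layout_rev = NULL,
                          params = digest_params()) {
  stopifnot(inherits(layout_fwd, "ElementSpec"), inherits(params, "DigestParams"))
  paired <- !is.null(fastq_rev)
  if (paired) {
    if (is.null(layout_rev)) stop("'layout_rev' required for paired input")
    if (length(fastq_rev) != length(fastq_fwd))
      stop("'fastq_fwd' and 'fastq_rev' must pair up file by file")
  }
  fwd <- read_fastq_files(fastq_fwd)
  if (paired) {
    rev <- read_fastq_files(fastq_rev)
    if (length(rev$seq) != length(fwd$seq))
      stop("paired FASTQ files contain different read counts (",
           length(fwd$seq), " vs ", length(rev$seq), ")")
  }
  n_all <- length(fwd$seq)
  if (!is.null(params$max_reads) && n_all > params$max_reads) {
    keep <- seq_len(params$max_reads)
    fwd <- lapply(fwd, `[`, keep)
    if (paired) rev <- lapply(rev, `[`, keep)
    n_all <- params$max_reads
  }
  n <- n_all
  reason <- rep(NA_character_, n)
  claim <- function(cond, key) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- key
  }

  ## 1. adapters
  claim(contains_adapter(fwd$seq, if (paired) rev$seq else NULL,
                         params$adapter_fwd, params$adapter_rev), "fAdapter")

  ## 2. segmentation
  segF <- segment_reads(fwd$seq, fwd$qual, layout_fwd)
  claim(segF$reason == "fNoPrimer", "fNoPrimer")
  claim(segF$reason == "fReadLengthMismatch", "fReadLengthMismatch")
  if (paired) {
    segR <- segment_reads(rev$seq, rev$qual, layout_rev)
    claim(segR$reason == "fNoPrimer", "fNoPrimer")
    claim(segR$reason == "fReadLengthMismatch", "fReadLengthMismatch")
  }

  ## 3. reverse-complement on request
  if (params$rev_complement_fwd) {
    segF$variable <- cpp_revcomp(segF$variable)
    segF$variable_qual <- cpp_reverse_strings(segF$variable_qual)
    segF$constant <- cpp_revcomp(segF$constant)
    segF$constant_qual <- cpp_reverse_strings(segF$constant_qual)
  }
  if (paired && params$rev_complement_rev) {
    segR$variable <- cpp_revcomp(segR$variable)
    segR$variable_qual <- cpp_reverse_strings(segR$variable_qual)
    segR$constant <- cpp_revcomp(segR$constant)
    segR$constant_qual <- cpp_reverse_strings(segR$constant_qual)
  }

  ## 4. merging
  merged <- FALSE
  if (paired && params$merge) {
    merged <- TRUE
    act <- which(is.na(reason))
    var <- var_qual <- rep(NA_character_, n)
    if (length(act) > 0) {
      mg <- cpp_merge_pairs(
        segF$variable[act], segF$variable_qual[act],
        segR$variable[act], segR$variable_qual[act],
        as.integer(params$min_overlap),
        as.integer(min(params$max_overlap, .Machine$integer.max)),
        as.integer(params$min_merged_length),
        as.integer(min(params$max_merged_length, .Machine$integer.max)),
        params$max_mismatch_fraction)
      fail <- act[!mg$ok]
      reason[fail] <- "fMergeFailed"
      var[act] <- mg$seq
      var_qual[act] <- mg$qual
    }
  } else if (paired) {
    if (is.null(params$wildtype_rev)) {
      var <- paste0(segF$variable, segR$variable)
      var_qual <- paste0(segF$variable_qual, segR$variable_qual)
    } else {
      var <- segF$variable        # matched per mate below
      var_qual <- segF$variable_qual
    }
  } else {
    var <- segF$variable
    var_qual <- segF$variable_qual
  }

  ## 5. quality / N filters (on the merged or combined variable region)
  two_sided <- paired && !merged && !is.null(params$wildtype_rev)
  qvar <- if (two_sided) paste0(var_qual, segR$variable_qual) else var_qual
  svar <- if (two_sided) paste0(var, segR$variable) else var
  avg <- cpp_phred_means(qvar)
  claim(!is.nan(avg) & avg < params$avg_qual_min, "fAvgQualTooLow")
  claim(cpp_count_char(svar, "N") > params$max_n_variable, "fTooManyNinVar")
  umi <- paste0(segF$umi, if (paired) segR$umi else "")
  has_umi <- any(layout_fwd$codes == "U") ||
    (paired && any(layout_rev$codes == "U"))
  if (has_umi) {
    claim(cpp_count_char(umi, "N") > params$max_n_umi, "fTooManyNinUmi")
  }

  ## 6. wild-type matching
  vname <- rep(NA_character_, n)
  vwt <- rep(NA_character_, n)
  vnb <- rep(NA_integer_, n)
  vnc <- rep(NA_integer_, n)
  vseq <- rep(NA_character_, n)
  ref_free <- is.null(params$wildtype)
  apply_match <- function(seqv, qualv, wt_set) {
    ## returns per-read list for the currently active reads; claims reasons
    act <- which(is.na(reason))
    out <- list(name = rep(NA_character_, n), wt = rep(NA_character_, n),
                nb = rep(NA_integer_, n), nc = rep(NA_integer_, n))
    if (length(act) == 0) return(out)
    uq <- sort(unique(seqv[act]))
    ui <- match(seqv[act], uq)
    eng <- match_engine(uq, wt_set, params)
    r <- eng$reason[ui]
    ## mutation-quality check (per read, positions from the unique entry)
    mutqual_fail <- rep(FALSE, length(act))
    if (params$min_mutation_quality > 0) {
      nmut <- lengths(eng$pos)
      for (u in which(is.na(eng$reason) & nmut > 0L)) {
        rows <- which(ui == u)
        minq <- rep(Inf, length(rows))
        for (p in eng$pos[[u]]) {
          minq <- pmin(minq, phred_of_chars(substring(qualv[act[rows]], p, p)))
        }
        mutqual_fail[rows] <- minq < params$min_mutation_quality
      }
    }
    forb <- eng$forbidden[ui]
    reason[act[is.na(reason[act]) & !is.na(r)]] <<- r[!is.na(r)]
    sel <- is.na(r) & mutqual_fail
    reason[act[sel]] <<- "fMutQualTooLow"
    sel2 <- is.na(r) & !mutqual_fail & forb
    reason[act[sel2]] <<- "fForbiddenCodon"
    keep <- is.na(r) & !mutqual_fail & !forb
    out$name[act[keep]] <- eng$name[ui[keep]]
    out$wt[act[keep]] <- eng$wt[ui[keep]]
    out$nb[act[keep]] <- eng$n_mut_bases[ui[keep]]
    out$nc[act[keep]] <- eng$n_mut_codons[ui[keep]]
    out
  }
  if (!ref_free) {
    if (two_sided) {
      mF <- apply_match(var, var_qual, params$wildtype)
      mR <- apply_match(segR$variable, segR$variable_qual, params$wildtype_rev)
      ok <- is.na(reason)
      vname[ok] <- paste(mF$name[ok], mR$name[ok], sep = "_")
      vwt[ok] <- paste(mF$wt[ok], mR$wt[ok], sep = "_")
      vnb[ok] <- mF$nb[ok] + mR$nb[ok]
      vnc[ok] <- mF$nc[ok] + mR$nc[ok]
      vseq[ok] <- paste0(var[ok], segR$variable[ok])
    } else {
      m <- apply_match(var, var_qual, params$wildtype)
      ok <- is.na(reason)
      vname[ok] <- m$name[ok]
      vwt[ok] <- m$wt[ok]
      vnb[ok] <- m$nb[ok]
      vnc[ok] <- m$nc[ok]
      vseq[ok] <- var[ok]
    }
  } else {
    ok <- is.na(reason)
    vseq[ok] <- svar[ok]
    vname[ok] <- svar[ok]
  }

  ## 7. constant-region check (tallies accumulate for all reads that reach
  ## this step, pass or fail)
  error_tally <- matrix(0L, nrow = 94, ncol = 2,
                        dimnames = list(quality = 0:93,
                                        c("nMatch", "nMismatch")))
  act <- which(is.na(reason))
  const_fail <- rep(FALSE, n)
  if (!is.null(params$constant) && length(act) > 0) {
    cc <- check_constant(segF$constant[act], segF$constant_qual[act],
                         params$constant, params$max_constant_mismatch)
    error_tally <- error_tally + cc$tally
    const_fail[act] <- const_fail[act] | !cc$pass
  }
  if (paired && !is.null(params$constant_rev) && length(act) > 0) {
    cc <- check_constant(segR$constant[act], segR$constant_qual[act],
                         params$constant_rev, params$max_constant_mismatch)
    error_tally <- error_tally + cc$tally
    const_fail[act] <- const_fail[act] | !cc$pass
  }
  claim(const_fail, "fConstantMismatch")

  ## excluded-read export
  if (!is.null(params$excluded_path)) {
    drop <- which(!is.na(reason))
    ids <- paste(fwd$id[drop], reason[drop])
    write_fastq_records(paste0(params$excluded_path, "_R1.fastq"),
                        ids, fwd$seq[drop], fwd$qual[drop])
    if (paired) {
      write_fastq_records(paste0(params$excluded_path, "_R2.fastq"),
                          paste(rev$id[drop], reason[drop]),
                          rev$seq[drop], rev$qual[drop])
    }
  }

  ## tabulation
  keep <- which(is.na(reason))
  kname <- vname[keep]
  kseq <- vseq[keep]
  kumi <- umi[keep]

  constituents <- NULL
  if (ref_free && params$collapse_max_dist > 0 && length(kname) > 0) {
    tab <- table(kname)
    cl <- collapse_sequences(stats::setNames(as.numeric(tab), names(tab)),
                             max_distance = params$collapse_max_dist,
                             min_abundance = params$collapse_min_count,
                             min_ratio = params$collapse_min_ratio)
    map <- stats::setNames(rep(cl$sequence, lengths(cl$constituents)),
                           unlist(cl$constituents))
    kname <- unname(map[kname])
    constituents <- cl
  }

  if (length(kname) == 0) {
    variants <- character(0)
    read_count <- integer(0)
  } else {
    tab <- table(kname)
    variants <- sort(names(tab))
    read_count <- as.integer(tab[variants])
  }
  umi_count <- rep(NA_integer_, length(variants))
  if (has_umi && length(variants) > 0) {
    by_var <- split(kumi, factor(kname, levels = variants))
    umi_count <- vapply(by_var, function(u) {
      ut <- table(u)
      collapse_umis(stats::setNames(as.numeric(ut), names(ut)),
                    max_distance = params$umi_collapse_max_dist)
    }, integer(1))
  }

  ## per-variant annotation
  first_idx <- match(variants, kname)
  rep_seq <- if (ref_free) variants else kseq[first_idx]
  wt_of <- vwt[keep][first_idx]
  nb_of <- vnb[keep][first_idx]
  nc_of <- vnc[keep][first_idx]
  n_aas <- rep(NA_integer_, length(variants))
  mut_types <- rep(NA_character_, length(variants))
  if (!ref_free && length(variants) > 0) {
    wt_seq_of <- wildtype_sequence_map(params)[wt_of]
    for (i in seq_along(variants)) {
      w <- wt_seq_of[i]
      if (is.na(w) || nchar(w) != nchar(rep_seq[i])) next
      if (nchar(w) %% 3L != 0L) next
      cls <- classify_mutations(rep_seq[i], w)
      n_aas[i] <- cls$n_mut_aas
      mut_types[i] <- paste(cls$mutation_types, collapse = ",")
    }
  }
  obs_seq <- if (!is.null(constituents)) {
    vapply(constituents$constituents[match(variants, constituents$sequence)],
           function(x) paste(sort(x), collapse = ","), character(1))
  } else if (length(variants) > 0) {
    vapply(split(kseq, factor(kname, levels = variants)),
           function(x) paste(sort(unique(x)), collapse = ","), character(1))
  } else character(0)

  count_table <- data.frame(
    variant = variants,
    readCount = read_count,
    umiCount = umi_count,
    nMutBases = nb_of,
    nMutCodons = nc_of,
    nMutAAs = n_aas,
    mutationTypes = mut_types,
    sequences = unname(obs_seq),
    wildtype = wt_of,
    sequence = rep_seq,
    stringsAsFactors = FALSE, row.names = NULL
  )

  tally <- stats::setNames(integer(length(FILTER_KEYS)), FILTER_KEYS)
  tt <- table(reason[!is.na(reason)])
  tally[names(tt)] <- as.integer(tt)
  filter_tally <- c(nTotal = n, tally, nRetained = length(keep))

  structure(list(
    countTable = count_table,
    filterTally = filter_tally,
    errorTally = error_tally,
    params = c(unclass(params),
               list(timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
                    package_version = as.character(utils::packageVersion("mavekit"))))
  ), class = "DigestResult")
}

## Map wild-type name -> sequence, including the concatenated names of
## two-sided (paired, unmerged) designs.
wildtype_sequence_map <- function(params) {
  m <- params$wildtype
  if (!is.null(params$wildtype_rev)) {
    comb <- outer(names(params$wildtype), names(params$wildtype_rev),
                  paste, sep = "_")
    seqs <- outer(as.character(params$wildtype),
                  as.character(params$wildtype_rev), paste0)
    m <- c(m, stats::setNames(as.vector(seqs), as.vector(comb)))
  }
  m
}

#' @export
print.DigestResult <- function(x, ...) {
  ft <- x$filterTally
  cat("DigestResult:", ft[["nTotal"]], "reads,", ft[["nRetained"]],
      "retained,", nrow(x$countTable), "variants\n")
  invisible(x)
}

#' Estimate sequencing error rates stratified by base quality
#'
#' Converts the per-quality match/mismatch tally over constant-region bases
#' into error-rate estimates: `rate(q) = nMismatch(q) / (nMatch(q) +
#' nMismatch(q))`. Qualities never observed are omitted.
#'
#' @param tally A 94 x 2 tally matrix (`errorTally` of a `DigestResult`, or
#'   the `tally` of [check_constant()]).
#' @return A data.frame with columns `quality`, `nTotal`, `nMismatch`,
#'   `rate`.
#' @export
estimate_error_rates <- function(tally) {
  stopifnot(is.matrix(tally), ncol(tally) == 2L)
  total <- rowSums(tally)
  keep <- total > 0
  data.frame(
    quality = (0:93)[keep],
    nTotal = unname(total[keep]),
    nMismatch = unname(tally[keep, 2L]),
    rate = unname(tally[keep, 2L] / total[keep]),
    row.names = NULL
  )
}
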