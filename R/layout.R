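#' Parse a read-layout element specification
#'
#' A read layout describes the composition of a sequencing read in terms of
#' five element types: variable regions (`V`, the sequence of interest),
#' constant regions (`C`, fixed sequence used for error-rate estimation and
#' filtering), skipped regions (`S`, ignored), a primer (`P`, an anchor
#' located by exact search rather than fixed position) and UMIs (`U`, random
#' molecular tags). For example, a read consisting of 1 skipped nt, a 10 nt
#' UMI, an 18 nt constant region and a 96 nt variable region is described by
#' the element string `"SUCV"` with lengths `c(1, 10, 18, 96)`.
#'
#' A length of `-1` marks the element that takes up the remainder of the
#' read not accounted for by the fixed-length elements. Without a primer at
#' most one such sentinel is allowed; with a primer, at most one before and
#' one after the primer (the primer splits the read into two independently
#' resolved parts).
#'
#' @param codes Single string over the alphabet `V`, `C`, `S`, `P`, `U`,
#'   giving the element order along the read.
#' @param lengths Integer vector, one entry per element; `-1` denotes the
#'   remainder sentinel. For a `P` element the length must equal
#'   `nchar(primer)` (it is filled in automatically when `NA`).
#' @param primer Primer sequence; required if (and only if) `codes`
#'   contains `P`.
#'
#' @return An object of class `ElementSpec`: a list with fields `codes`
#'   (character vector of single letters), `lengths`, `primer`, and
#'   `p_index` (position of the primer element, or `NA`).
#'
#' @examples
#' parse_element_spec("SUCV", c(1, 10, 18, 96))
#' parse_element_spec("SPV", c(-1, 10, -1), primer = "ACGTACGTAC")
#' @export
parse_element_spec <- function(codes, lengths, primer = NULL) {
  stopifnot(is.character(codes), length(codes) == 1L, nzchar(codes))
  cd <- strsplit(codes, "")[[1]]
  bad <- setdiff(cd, c("V", "C", "S", "P", "U"))
  if (length(bad) > 0) {
    stop("unknown element code(s): ", paste(unique(bad), collapse = ", "))
  }
  lengths <- as.integer(lengths)
  if (length(lengths) != length(cd)) {
    stop("'lengths' must have one entry per element code (",
         length(cd), " needed, ", length(lengths), " given)")
  }
  p_index <- which(cd == "P")
  if (length(p_index) > 1L) stop("at most one primer (P) element is allowed")
  if (length(p_index) == 1L) {
    if (is.null(primer) || !nzchar(primer)) {
      stop("a P element requires a non-empty 'primer' sequence")
    }
    if (is.na(lengths[p_index])) lengths[p_index] <- nchar(primer)
    if (lengths[p_index] != nchar(primer)) {
      stop("primer element length (", lengths[p_index],
           ") must equal nchar(primer) (", nchar(primer), ")")
    }
  } else {
    p_index <- NA_integer_
    if (!is.null(primer)) {
      stop("'primer' supplied but no P element in codes")
    }
  }
  if (anyNA(lengths)) stop("element lengths must not be NA")
  if (any(lengths < 1L & lengths != -1L)) {
    stop("element lengths must be >= 1, or -1 for the remainder sentinel")
  }
  sent <- which(lengths == -1L)
  if (is.na(p_index)) {
    if (length(sent) > 1L) {
      stop("at most one remainder sentinel (-1) is allowed without a primer")
    }
  } else {
    if (sum(sent < p_index) > 1L || sum(sent > p_index) > 1L) {
      stop("at most one remainder sentinel (-1) allowed on each side of the primer")
    }
    if (lengths[p_index] == -1L) stop("the primer element cannot be a sentinel")
  }
  structure(
    list(codes = cd, lengths = lengths,
         primer = if (is.na(p_index)) NULL else primer,
         p_index = p_index),
    class = "ElementSpec"
  )
}

#' @export
print.ElementSpec <- function(x, ...) {
  cat("ElementSpec:", paste0(x$codes, collapse = ""), "| lengths:",
      paste(x$lengths, collapse = ","),
      if (!is.na(x$p_index)) paste0("| primer: ", x$primer) else "", "\n")
  invisible(x)
}

#' Locate a primer in a read by exact search
#'
#' Returns the 0-based start of the first (leftmost) exact occurrence of
#' `primer` in `read`, or `NA` if the primer does not occur. Absence is a
#' value, not an error; the digestion cascade converts it into the
#' `fNoPrimer` filter reason.
#'
#' @param read Read sequence (character scalar or vector).
#' @param primer Primer sequence (non-empty).
#' @return Integer vector of 0-based start positions (`NA` where absent).
#' @examples
#' locate_primer("TTTACGTAA", "ACGT")  # 3
#' @export
locate_primer <- function(read, primer) {
  stopifnot(is.character(primer), length(primer) == 1L, nzchar(primer))
  pos <- regexpr(primer, read, fixed = TRUE)
  out <- as.integer(pos) - 1L
  out[out < 0L] <- NA_integer_
  out
}

#' @keywords internal
is_filter_reason <- function(x) inherits(x, "filter_reason")

filter_reason <- function(reason) structure(reason, class = "filter_reason")

## Resolve element lengths for one primer-free stretch of codes against an
## available span. Returns an n_elements x n_reads integer matrix of lengths,
## with NA columns where the span is incompatible (negative residual, or
## non-zero residual without a sentinel).
resolve_lengths <- function(lengths, avail) {
  sent <- which(lengths == -1L)
  fixed <- sum(lengths[lengths >= 0L])
  resid <- avail - fixed
  ok <- if (length(sent) == 0L) resid == 0L else resid >= 0L
  ok[is.na(ok)] <- FALSE
  m <- matrix(rep(lengths, length(avail)), nrow = length(lengths))
  if (length(sent) == 1L) m[sent, ] <- as.integer(resid)
  m[, !ok] <- NA_integer_
  m
}

## Vectorised segmentation of many reads under one ElementSpec.
## Returns a list of per-read component vectors plus a reason vector
## (NA = accepted, "fNoPrimer", "fReadLengthMismatch").
segment_reads <- function(seqs, quals, spec) {
  n <- length(seqs)
  len <- nchar(seqs)
  reason <- rep(NA_character_, n)
  ncode <- length(spec$codes)
  lenmat <- matrix(NA_integer_, nrow = ncode, ncol = n)
  startmat <- matrix(NA_integer_, nrow = ncode, ncol = n)

  if (is.na(spec$p_index)) {
    lenmat <- resolve_lengths(spec$lengths, len)
    bad <- is.na(lenmat[1L, ]) & is.na(reason)
    reason[bad] <- "fReadLengthMismatch"
    startmat <- apply_starts(lenmat, 0L)
  } else {
    p <- spec$p_index
    pos0 <- locate_primer(seqs, spec$primer)
    reason[is.na(pos0)] <- "fNoPrimer"
    plen <- spec$lengths[p]
    before <- seq_len(p - 1L)
    after <- if (p < ncode) seq(p + 1L, ncode) else integer(0)
    if (length(before) > 0) {
      lb <- resolve_lengths(spec$lengths[before], pos0)
      lenmat[before, ] <- lb
      startmat[before, ] <- apply_starts(lb, 0L)
    } else if (any(!is.na(pos0) & pos0 > 0L)) {
      # sequence before the anchor but no elements to hold it
      reason[is.na(reason) & pos0 > 0L] <- "fReadLengthMismatch"
    }
    lenmat[p, ] <- plen
    startmat[p, ] <- as.integer(pos0)
    if (length(after) > 0) {
      la <- resolve_lengths(spec$lengths[after], len - pos0 - plen)
      lenmat[after, ] <- la
      startmat[after, ] <- apply_starts(la, pos0 + plen)
    } else {
      mism <- !is.na(pos0) & (len - pos0 - plen) != 0L
      reason[is.na(reason) & mism] <- "fReadLengthMismatch"
    }
    bad <- apply(is.na(lenmat), 2L, any) & is.na(reason)
    reason[bad] <- "fReadLengthMismatch"
  }

  extract <- function(code, strings) {
    idx <- which(spec$codes == code)
    if (length(idx) == 0L) return(rep("", n))
    out <- rep("", n)
    for (i in idx) {
      s <- startmat[i, ] + 1L
      e <- startmat[i, ] + lenmat[i, ]
      piece <- substring(strings, s, e)
      piece[is.na(s) | is.na(e)] <- ""
      out <- paste0(out, piece)
    }
    out[!is.na(reason)] <- ""
    out
  }

  skipped_len <- if (any(spec$codes == "S")) {
    colSums(lenmat[spec$codes == "S", , drop = FALSE])
  } else rep(0L, n)
  list(
    variable = extract("V", seqs), variable_qual = extract("V", quals),
    constant = extract("C", seqs), constant_qual = extract("C", quals),
    umi = extract("U", seqs), umi_qual = extract("U", quals),
    skipped_len = as.integer(skipped_len),
    primer_len = if (is.na(spec$p_index)) rep(0L, n) else
      ifelse(is.na(reason), spec$lengths[spec$p_index], NA_integer_),
    reason = reason
  )
}

## Cumulative 0-based starts given a length matrix and a scalar-or-vector
## offset for the first element.
apply_starts <- function(lenmat, offset) {
  if (nrow(lenmat) == 0L) return(lenmat)
  s <- matrix(NA_integer_, nrow = nrow(lenmat), ncol = ncol(lenmat))
  run <- rep(as.integer(offset), length.out = ncol(lenmat))
  for (i in seq_len(nrow(lenmat))) {
    s[i, ] <- run
    run <- run + lenmat[i, ]
  }
  s
}

#' Split one read into its layout components
#'
#' Applies an [parse_element_spec()] layout to a single read, returning the
#' extracted components or a filter reason. Multiple regions of the same
#' element type are concatenated in read order into one logical component.
#' Reads whose length is incompatible with the fixed element lengths yield
#' the reason `"fReadLengthMismatch"`; a missing primer yields
#' `"fNoPrimer"`.
#'
#' @param seq Read sequence (character scalar).
#' @param qual Phred+33-encoded quality string of the same length.
#' @param spec An `ElementSpec`.
#' @return A list of class `ComponentSet` with fields `variable`,
#'   `variable_qual`, `constant`, `constant_qual`, `umi`, `umi_qual`,
#'   `skipped_len` and `primer_len`; or a `filter_reason` character scalar.
#' @examples
#' sp <- parse_element_spec("SUCV", c(1, 10, 18, 96))
#' r <- paste(rep("A", 125), collapse = "")
#' q <- paste(rep("I", 125), collapse = "")
#' segment_read(r, q, sp)$umi
#' @export
segment_read <- function(seq, qual, spec) {
  stopifnot(inherits(spec, "ElementSpec"), length(seq) == 1L)
  if (nchar(seq) != nchar(qual)) stop("sequence and quality lengths differ")
  res <- segment_reads(seq, qual, spec)
  if (!is.na(res$reason[1L])) return(filter_reason(res$reason[1L]))
  structure(
    lapply(res[setdiff(names(res), "reason")], `[`, 1L),
    class = "ComponentSet"
  )
}
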