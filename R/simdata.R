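## Deterministic synthetic-data engine: FASTQ libraries with known variant
## composition, UMIs, adapter contamination and per-quality sequencing
## errors, plus count matrices with controlled group effects. These are
## the ground-truth oracles for the end-to-end and statistical tests.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_bases <- function(n_strings, len) {
  if (len == 0L) return(rep("", n_strings))
  m <- matrix(sample(c("A", "C", "G", "T"), n_strings * len, replace = TRUE),
              nrow = n_strings)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Build a mutated-codon variant table for simulation
#'
#' Convenience constructor: for each wild-type, the wild-type variant
#' itself plus `n_per_wt` single-codon variants at random codon positions
#' with random replacement codons. Frequencies are uniform over the
#' mutants with a designated share for the wild-types.
#'
#' @param wildtypes Named character vector of wild-type variable-region
#'   sequences (lengths divisible by 3).
#' @param n_per_wt Number of single-codon variants per wild-type.
#' @param wt_freq Total frequency mass assigned to the wild-type variants.
#' @param seed RNG seed.
#' @return Data.frame with columns `wildtype`, `mutations` (empty string,
#'   or `"codonIndex:ALTCODON"`), `freq`.
#' @export
sim_variants <- function(wildtypes, n_per_wt = 50L, wt_freq = 0.2,
                         seed = 1L) {
  stopifnot(!is.null(names(wildtypes)), all(nchar(wildtypes) %% 3 == 0))
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste0,
                  collapse = "")
  with_seed(seed, {
    rows <- list()
    for (w in names(wildtypes)) {
      L3 <- nchar(wildtypes[[w]]) %/% 3L
      seen <- character(0)
      while (length(seen) < n_per_wt) {
        ci <- sample.int(L3, 1L)
        ref <- substring(wildtypes[[w]], 3L * ci - 2L, 3L * ci)
        alt <- sample(setdiff(codons, ref), 1L)
        key <- paste0(ci, ":", alt)
        if (!key %in% seen) seen <- c(seen, key)
      }
      rows[[w]] <- data.frame(wildtype = w,
                              mutations = c("", seen),
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    n_wt <- sum(tab$mutations == "")
    n_mut <- sum(tab$mutations != "")
    tab$freq <- ifelse(tab$mutations == "", wt_freq / n_wt,
                       (1 - wt_freq) / n_mut)
    rownames(tab) <- NULL
    tab
  })
}

apply_codon_mutations <- function(wt_seq, mutations) {
  if (!nzchar(mutations)) return(wt_seq)
  for (tok in strsplit(mutations, ";")[[1]]) {
    parts <- strsplit(tok, ":")[[1]]
    ci <- as.integer(parts[1L])
    substring(wt_seq, 3L * ci - 2L, 3L * ci) <- parts[2L]
  }
  wt_seq
}

## Variant name as the digestion cascade would assign it, derived from the
## construction arithmetic (not from the Hamming matcher).
truth_variant_name <- function(wt_name, wt_seq, var_seq, unit) {
  d <- which(strsplit(var_seq, "")[[1]] != strsplit(wt_seq, "")[[1]])
  if (length(d) == 0L) return(wt_name)
  if (unit == "base") {
    alt <- substring(var_seq, d, d)
    paste(paste(wt_name, d, alt, sep = "."), collapse = "_")
  } else {
    ci <- sort(unique((d - 1L) %/% 3L + 1L))
    alt <- substring(var_seq, 3L * ci - 2L, 3L * ci)
    paste(paste(wt_name, ci, alt, sep = "."), collapse = "_")
  }
}

#' Configuration for FASTQ library simulation
#'
#' Describes a synthetic amplicon library: the wild-type variable
#' sequences, the variant composition, the read layouts (fixed-length
#' elements only), constant-region content, quality tiers and error /
#' contamination rates. All randomness is fixed by `seed`.
#'
#' @param wildtypes Named character vector of wild-type variable regions.
#' @param variants Data.frame with columns `wildtype`, `mutations`
#'   (`""`, or `;`-separated `"codonIndex:ALTCODON"` tokens) and `freq`
#'   (summing to 1); see [sim_variants()].
#' @param layout_fwd,layout_rev `ElementSpec` layouts with fixed lengths
#'   (no `-1` sentinels). For paired designs the forward read carries the
#'   first `vF` bases of the variable region and the reverse read the last
#'   `vR` bases (reverse-complemented), with `vF + vR >= L`.
#' @param n_reads Number of reads (pairs) to draw.
#' @param constant_fwd,constant_rev Constant-region content (forward
#'   orientation; the reverse read stores its reverse complement).
#' @param quality Integer Phred tier emitted for every base.
#' @param error_rate Per-base substitution probability.
#' @param n_rate Per-base probability of replacement by `N`.
#' @param adapter,adapter_rate Adapter sequence and per-read contamination
#'   probability (the adapter overwrites the interior of the forward
#'   read).
#' @param umis_per_variant Size of the distinct-UMI pool per variant
#'   (UMI length is taken from the layout's `U` elements).
#' @param unit Naming unit for the ground truth, `"codon"` or `"base"`.
#' @param seed RNG seed; fixes the library bit-for-bit.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(wildtypes, variants, layout_fwd, layout_rev = NULL,
                       n_reads = 10000L, constant_fwd = NULL,
                       constant_rev = NULL, quality = 30L,
                       error_rate = 0, n_rate = 0,
                       adapter = NULL, adapter_rate = 0,
                       umis_per_variant = 20L,
                       unit = c("codon", "base"), seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(inherits(layout_fwd, "ElementSpec"),
            is.null(layout_rev) || inherits(layout_rev, "ElementSpec"),
            is.data.frame(variants),
            all(c("wildtype", "mutations", "freq") %in% colnames(variants)),
            !is.null(names(wildtypes)))
  if (abs(sum(variants$freq) - 1) > 1e-8)
    stop("variant frequencies must sum to 1")
  if (error_rate < 0 || error_rate > 1 || n_rate < 0 || n_rate > 1 ||
      adapter_rate < 0 || adapter_rate > 1)
    stop("rates must lie in [0, 1]")
  if (adapter_rate > 0 && is.null(adapter))
    stop("'adapter' required when adapter_rate > 0")
  for (ly in list(layout_fwd, layout_rev)) {
    if (!is.null(ly) && any(ly$lengths < 0))
      stop("simulation layouts must have fixed element lengths")
  }
  lens <- function(ly, code) if (is.null(ly)) 0L else
    sum(ly$lengths[ly$codes == code])
  vF <- lens(layout_fwd, "V"); vR <- lens(layout_rev, "V")
  L <- unique(nchar(wildtypes))
  if (length(L) != 1L) stop("all wild-types must have equal length")
  if (is.null(layout_rev)) {
    if (vF != L) stop("forward V length (", vF, ") must equal the ",
                      "wild-type length (", L, ") for single-end designs")
  } else {
    if (vF + vR < L) stop("V lengths (", vF, "+", vR,
                          ") must cover the wild-type length (", L, ")")
  }
  if (lens(layout_fwd, "C") > 0 && is.null(constant_fwd))
    stop("'constant_fwd' required by the forward layout")
  if (!is.null(constant_fwd) &&
      nchar(constant_fwd) != lens(layout_fwd, "C"))
    stop("'constant_fwd' length must match the layout's C length")
  if (lens(layout_rev, "C") > 0 && is.null(constant_rev))
    stop("'constant_rev' required by the reverse layout")
  if (!is.null(constant_rev) &&
      nchar(constant_rev) != lens(layout_rev, "C"))
    stop("'constant_rev' length must match the layout's C length")
  structure(list(
    wildtypes = wildtypes, variants = variants,
    layout_fwd = layout_fwd, layout_rev = layout_rev,
    n_reads = as.integer(n_reads),
    constant_fwd = constant_fwd, constant_rev = constant_rev,
    quality = as.integer(quality), error_rate = error_rate,
    n_rate = n_rate, adapter = adapter, adapter_rate = adapter_rate,
    umis_per_variant = as.integer(umis_per_variant), unit = unit,
    seed = as.integer(seed)
  ), class = "SimConfig")
}

assemble_reads <- function(layout, n, variable_piece, umi, constant,
                           primer) {
  parts <- vector("list", length(layout$codes))
  v_used <- 0L; u_used <- 0L; c_used <- 0L
  for (i in seq_along(layout$codes)) {
    code <- layout$codes[i]
    len <- layout$lengths[i]
    parts[[i]] <- switch(code,
      S = random_bases(n, len),
      U = {
        p <- substring(umi, u_used + 1L, u_used + len)
        u_used <- u_used + len; p
      },
      C = {
        p <- substring(constant, c_used + 1L, c_used + len)
        c_used <- c_used + len
        rep(p, length.out = n)
      },
      P = rep(primer, n),
      V = {
        p <- substring(variable_piece, v_used + 1L, v_used + len)
        v_used <- v_used + len; p
      })
  }
  do.call(paste0, parts)
}

#' Simulate a FASTQ library with known ground truth
#'
#' Draws variants by frequency, assembles reads according to the layouts
#' (skipped, UMI, constant, primer, variable elements), injects
#' substitution errors, `N` bases and adapter contamination at the
#' configured rates, and writes FASTQ file(s). The ground-truth table
#' records the exact variant counts and distinct-UMI counts expected from
#' a noise-free digestion (adapter-contaminated reads excluded).
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param gzip Write gzip-compressed FASTQ.
#' @return A list with `fastq_fwd`, `fastq_rev` (or `NULL`), `truth` (a
#'   data.frame: variant, wildtype, sequence, readCount, umiCount,
#'   nMutBases, nMutCodons), `n_adapter` (number of contaminated reads)
#'   and `config`.
#' @export
simulate_library <- function(config, out_dir, gzip = FALSE) {
  stopifnot(inherits(config, "SimConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paired <- !is.null(config$layout_rev)
  vt <- config$variants
  wt_seq <- config$wildtypes[vt$wildtype]
  var_seq <- mapply(apply_codon_mutations, wt_seq, vt$mutations,
                    USE.NAMES = FALSE)
  var_name <- mapply(truth_variant_name, vt$wildtype, wt_seq, var_seq,
                     MoreArgs = list(unit = config$unit),
                     USE.NAMES = FALSE)
  L <- nchar(var_seq[1L])
  lenv <- function(ly) if (is.null(ly)) 0L else
    sum(ly$lengths[ly$codes == "V"])
  vF <- lenv(config$layout_fwd); vR <- lenv(config$layout_rev)
  ulenF <- if (any(config$layout_fwd$codes == "U"))
    sum(config$layout_fwd$lengths[config$layout_fwd$codes == "U"]) else 0L
  ulenR <- if (paired && any(config$layout_rev$codes == "U"))
    sum(config$layout_rev$lengths[config$layout_rev$codes == "U"]) else 0L
  ulen <- ulenF + ulenR

  res <- with_seed(config$seed, {
    n <- config$n_reads
    vidx <- sample.int(nrow(vt), n, replace = TRUE, prob = vt$freq)
    umi_pool <- if (ulen > 0)
      replicate(nrow(vt), random_bases(config$umis_per_variant, ulen),
                simplify = FALSE) else NULL
    umi <- if (ulen > 0) {
      pick <- sample.int(config$umis_per_variant, n, replace = TRUE)
      vapply(seq_len(n), function(i) umi_pool[[vidx[i]]][pick[i]],
             character(1))
    } else rep("", n)
    vs <- var_seq[vidx]
    fwd_piece <- substring(vs, 1L, vF)
    rev_piece <- if (paired) cpp_revcomp(substring(vs, L - vR + 1L, L))
                 else NULL
    fwd <- assemble_reads(config$layout_fwd, n, fwd_piece,
                          substring(umi, 1L, ulenF),
                          config$constant_fwd, config$layout_fwd$primer)
    rev <- if (paired)
      assemble_reads(config$layout_rev, n, rev_piece,
                     substring(umi, ulenF + 1L, ulen),
                     if (is.null(config$constant_rev)) NULL else
                       cpp_revcomp(config$constant_rev),
                     config$layout_rev$primer) else NULL

    inject <- function(reads, rate_sub, rate_n) {
      if (rate_sub > 0) {
        tot <- sum(nchar(reads))
        reads <- cpp_inject_errors(reads, rep(rate_sub, length(reads)),
                                   stats::runif(tot), stats::runif(tot))
      }
      if (rate_n > 0) {
        ch <- strsplit(reads, "")
        reads <- vapply(ch, function(x) {
          hit <- stats::runif(length(x)) < rate_n
          x[hit] <- "N"
          paste(x, collapse = "")
        }, character(1))
      }
      reads
    }
    fwd <- inject(fwd, config$error_rate, config$n_rate)
    if (paired) rev <- inject(rev, config$error_rate, config$n_rate)

    adapter_hit <- rep(FALSE, n)
    if (config$adapter_rate > 0) {
      adapter_hit <- stats::runif(n) < config$adapter_rate
      if (any(adapter_hit)) {
        at <- 2L  # fixed interior offset keeps read lengths intact
        ad <- config$adapter
        idx <- which(adapter_hit)
        pre <- substring(fwd[idx], 1L, at)
        post <- substring(fwd[idx], at + nchar(ad) + 1L)
        fwd[idx] <- paste0(pre, ad, post)
        short <- nchar(fwd[idx]) < nchar(fwd[which(!adapter_hit)[1L]])
        if (any(is.na(short)) || any(short))
          stop("adapter too long for the configured read length")
      }
    }
    list(vidx = vidx, umi = umi, fwd = fwd, rev = rev,
         adapter_hit = adapter_hit)
  })

  n <- config$n_reads
  qF <- strrep(intToUtf8(config$quality + 33L), nchar(res$fwd))
  ids <- sprintf("sim%06d", seq_len(n))
  fq_fwd <- file.path(out_dir, paste0("sim_R1.fastq", if (gzip) ".gz"))
  write_fastq_records(fq_fwd, ids, res$fwd, qF, gzip = gzip)
  fq_rev <- NULL
  if (paired) {
    qR <- strrep(intToUtf8(config$quality + 33L), nchar(res$rev))
    fq_rev <- file.path(out_dir, paste0("sim_R2.fastq", if (gzip) ".gz"))
    write_fastq_records(fq_rev, ids, res$rev, qR, gzip = gzip)
  }

  ok <- !res$adapter_hit
  tab <- table(factor(res$vidx[ok], levels = seq_len(nrow(vt))))
  umi_n <- if (ulen > 0) {
    vapply(seq_len(nrow(vt)), function(v) {
      length(unique(res$umi[ok & res$vidx == v]))
    }, integer(1))
  } else rep(NA_integer_, nrow(vt))
  nmb <- mapply(function(v, w) length(cpp_diff_positions(v, w)),
                var_seq, wt_seq, USE.NAMES = FALSE)
  nmc <- mapply(function(v, w) {
    p <- cpp_diff_positions(v, w)
    length(unique((p - 1L) %/% 3L + 1L))
  }, var_seq, wt_seq, USE.NAMES = FALSE)
  truth <- data.frame(
    variant = var_name, wildtype = vt$wildtype, sequence = var_seq,
    readCount = as.integer(tab), umiCount = umi_n,
    nMutBases = as.integer(nmb), nMutCodons = as.integer(nmc),
    stringsAsFactors = FALSE
  )
  truth <- truth[truth$readCount > 0, , drop = FALSE]
  truth <- truth[order(truth$variant), , drop = FALSE]
  rownames(truth) <- NULL
  list(fastq_fwd = fq_fwd, fastq_rev = fq_rev, truth = truth,
       n_adapter = sum(res$adapter_hit), config = config)
}

#' Simulate a count matrix with controlled group effects
#'
#' Negative-binomial draws with per-variant baseline means around `depth`
#' and a log2 fold change applied to the samples of the second condition
#' level. `dispersion = 0` yields Poisson draws. With `logfc = 0`
#' everywhere this is the null design used for type-I-error evaluation.
#'
#' @param n_variants Number of variants (rows).
#' @param condition Factor (or coercible) over samples; the fold change
#'   applies to its second level. Use a constant factor for a pure null.
#' @param depth Expected baseline count per variant.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param logfc Per-variant true log2 fold change (recycled).
#' @param baseline_sd Standard deviation (log scale) of the per-variant
#'   relative abundances; 0 makes every baseline mean equal `depth`.
#' @param seed RNG seed.
#' @return A list with `counts` (matrix with sample columns), `truth`
#'   (data.frame: variant, baseline mean, logfc) and `condition`.
#' @export
simulate_counts <- function(n_variants, condition, depth = 1000,
                            dispersion = 0.1, logfc = 0,
                            baseline_sd = 1, seed = 1L) {
  stopifnot(n_variants >= 1, depth > 0, dispersion >= 0, baseline_sd >= 0)
  condition <- as.factor(condition)
  n_samples <- length(condition)
  logfc <- rep_len(logfc, n_variants)
  with_seed(seed, {
    rel <- if (baseline_sd > 0) {
      exp(stats::rnorm(n_variants, -baseline_sd^2 / 2, baseline_sd))
    } else rep(1, n_variants)
    mu_base <- depth * rel
    is2 <- as.integer(condition) == 2L
    mu <- outer(mu_base, rep(1, n_samples))
    mu[, is2] <- mu[, is2] * 2^logfc
    counts <- matrix(0L, n_variants, n_samples)
    for (s in seq_len(n_samples)) {
      counts[, s] <- if (dispersion == 0) {
        stats::rpois(n_variants, mu[, s])
      } else {
        stats::rnbinom(n_variants, mu = mu[, s], size = 1 / dispersion)
      }
    }
    rownames(counts) <- sprintf("V%05d", seq_len(n_variants))
    colnames(counts) <- sprintf("S%02d", seq_len(n_samples))
    list(counts = counts,
         truth = data.frame(variant = rownames(counts), mu = mu_base,
                            logfc = logfc, stringsAsFactors = FALSE),
         condition = condition)
  })
}
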