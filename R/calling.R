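# Quality-aware pileup and minor-variant calling with a Fisher's exact
# test error model.

#' Calling configuration
#'
#' @param min_baseq minimum Phred base quality for a base to support a
#'   substitution call (default 20; deletions carry no base quality and are
#'   exempt, recording the mean quality of the flanking read bases instead).
#' @param min_freq minimum alt frequency for a row to be emitted
#'   (default 0.01).
#' @param alpha p-value threshold for a call to pass (default 0.05,
#'   inclusive).
#' @export
call_config <- function(min_baseq = 20L, min_freq = 0.01, alpha = 0.05) {
  stopifnot(min_freq > 0, min_freq < 1)
  structure(list(min_baseq = as.integer(min_baseq), min_freq = min_freq,
                 alpha = alpha), class = "amp_call_config")
}

#' Build a pileup over a reference window
#'
#' One column per covered reference position. A read contributes its base
#' and quality at M positions; at a deletion it increments the spanning
#' depth of every deleted position and registers the `-SEQ` allele once at
#' the anchor (the aligned base 5' of the gap); an insertion registers
#' `+SEQ` at the base it follows. Soft-clipped bases contribute nothing.
#' Spanning depth has no quality gate; substitution support is gated at
#' `min_baseq`.
#'
#' @param alns filtered, clipped alignment data.frame.
#' @param g an `amp_genome`.
#' @param window optional `c(start, end)`; defaults to the aligned span.
#' @param cfg an `amp_call_config` (for the base-quality gate).
#' @return object of class `amp_pileup`.
#' @export
build_pileup <- function(alns, g, window = NULL, cfg = call_config()) {
  use <- alns$cigar != "*" & bitwAnd(alns$flag, 4L) == 0L
  alns <- alns[use, , drop = FALSE]
  if (!nrow(alns)) stop("no usable alignments for pileup")
  if (is.null(window)) {
    spans <- cigar_stats_cpp(alns$cigar)[, "ref_span"]
    window <- c(min(alns$pos), max(alns$pos + spans - 1L))
  }
  wstart <- max(1L, window[1]); wend <- min(g$length, window[2])
  res <- pileup_cpp(wstart, genome_sub(g, wstart, wend),
                    alns$pos, alns$cigar, alns$seq, alns$qual,
                    bitwAnd(alns$flag, 16L) != 0L, cfg$min_baseq)
  res$wstart <- wstart
  res$wend <- wend
  res$ref <- genome_sub(g, wstart, wend)
  res$region <- g$id
  class(res) <- "amp_pileup"
  res
}

#' @export
print.amp_pileup <- function(x, ...) {
  cat(sprintf("<amp_pileup> %s:%d-%d, max depth %d, %d indel allele(s)\n",
              x$region, x$wstart, x$wend, max(x$cov), nrow(x$indel)))
  invisible(x)
}

#' Fisher's exact test against the quality-implied error rate
#'
#' One-sided (greater) Fisher's exact test of the observed alt count
#' against the error count expected from the mean supporting quality:
#' `E = round(total_dp * 10^(-alt_qual/10))` (round half up, floored at
#' zero), on the 2x2 table `[[alt_dp, total_dp - alt_dp], [E, total_dp -
#' E]]`.
#'
#' @param alt_dp alt-supporting read count.
#' @param total_dp total spanning depth (> 0).
#' @param alt_qual mean Phred quality of the supporting observations.
#' @return p-value in `[0, 1]`.
#' @export
fisher_error_test <- function(alt_dp, total_dp, alt_qual) {
  if (total_dp <= 0L) stop("total_dp must be positive")
  if (alt_dp < 0L || alt_dp > total_dp) stop("alt_dp out of range")
  if (alt_dp == 0L) return(1.0)
  e <- max(0L, as.integer(floor(total_dp * 10^(-alt_qual / 10) + 0.5)))
  m <- matrix(c(alt_dp, total_dp - alt_dp, e, total_dp - e),
              nrow = 2L, byrow = TRUE)
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Call variants from a pileup
#'
#' Emits one row per (position, non-reference allele) whose alt frequency
#' reaches `min_freq`. Substitution support counts only bases with Phred
#' `>= min_baseq`; deletions are exempt (no base exists at the event) and
#' use the flanking-base quality recorded in the pileup. Each row carries
#' the Fisher's-exact-test p-value and `PASS = (PVAL <= alpha)`. Rows are
#' sorted by position then allele.
#'
#' @param pu an `amp_pileup`.
#' @param cfg an `amp_call_config`.
#' @param sample,fraction labels stored as attributes on the table.
#' @return data.frame of class `amp_variant_table` with iVar-style columns
#'   REGION, POS, REF, ALT, REF_DP, REF_QUAL, REF_RV, ALT_DP, ALT_QUAL,
#'   ALT_RV, ALT_FREQ, TOTAL_DP, PVAL, PASS, GFF_FEATURE.
#' @export
call_variants <- function(pu, cfg = call_config(), sample = "sample",
                          fraction = NA_character_) {
  bases <- c("A", "C", "G", "T")
  refch <- strsplit(pu$ref, "")[[1]]
  L <- length(refch)
  ref_i <- match(refch, bases)
  rows <- list()

  # substitutions
  cnt <- pu$base_count
  for (b in 1:4) {
    idx <- which(cnt[b, ] > 0L & ref_i != b)
    for (w in idx) {
      dp <- pu$cov[w]
      if (dp <= 0L) next
      altdp <- cnt[b, w]
      freq <- altdp / dp
      if (freq < cfg$min_freq) next
      altq <- pu$base_qualsum[b, w] / altdp
      refdp <- if (!is.na(ref_i[w])) cnt[ref_i[w], w] else 0L
      refq <- if (refdp > 0L) pu$base_qualsum[ref_i[w], w] / refdp else 0
      refrv <- if (!is.na(ref_i[w])) pu$base_rev[ref_i[w], w] else 0L
      p <- fisher_error_test(altdp, dp, altq)
      rows[[length(rows) + 1L]] <- data.frame(
        REGION = pu$region, POS = pu$wstart + w - 1L, REF = refch[w],
        ALT = bases[b], REF_DP = refdp, REF_QUAL = round(refq, 2),
        REF_RV = refrv, ALT_DP = altdp, ALT_QUAL = round(altq, 2),
        ALT_RV = pu$base_rev[b, w], ALT_FREQ = freq, TOTAL_DP = dp,
        PVAL = p, PASS = p <= cfg$alpha, GFF_FEATURE = NA_character_,
        stringsAsFactors = FALSE)
    }
  }

  # indels (registered at their anchor position)
  ind <- pu$indel
  for (k in seq_len(nrow(ind))) {
    w <- ind$pos[k] - pu$wstart + 1L
    if (w < 1L || w > L) next
    dp <- pu$cov[w]
    if (dp <= 0L) next
    altdp <- ind$count[k]
    freq <- altdp / dp
    if (freq < cfg$min_freq) next
    altq <- ind$mean_qual[k]
    refdp <- if (!is.na(ref_i[w])) cnt[ref_i[w], w] else 0L
    refq <- if (refdp > 0L) pu$base_qualsum[ref_i[w], w] / refdp else 0
    p <- fisher_error_test(altdp, dp, altq)
    rows[[length(rows) + 1L]] <- data.frame(
      REGION = pu$region, POS = ind$pos[k], REF = refch[w],
      ALT = ind$allele[k], REF_DP = refdp, REF_QUAL = round(refq, 2),
      REF_RV = if (!is.na(ref_i[w])) pu$base_rev[ref_i[w], w] else 0L,
      ALT_DP = altdp, ALT_QUAL = round(altq, 2), ALT_RV = ind$rev[k],
      ALT_FREQ = freq, TOTAL_DP = dp, PVAL = p, PASS = p <= cfg$alpha,
      GFF_FEATURE = NA_character_, stringsAsFactors = FALSE)
  }

  tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
    REGION = character(), POS = integer(), REF = character(),
    ALT = character(), REF_DP = integer(), REF_QUAL = numeric(),
    REF_RV = integer(), ALT_DP = integer(), ALT_QUAL = numeric(),
    ALT_RV = integer(), ALT_FREQ = numeric(), TOTAL_DP = integer(),
    PVAL = numeric(), PASS = logical(), GFF_FEATURE = character(),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$POS, tab$ALT), ]
  rownames(tab) <- NULL
  attr(tab, "sample") <- sample
  attr(tab, "fraction") <- fraction
  class(tab) <- c("amp_variant_table", "data.frame")
  tab
}

#' Variant-table TSV IO (iVar-compatible dialect)
#'
#' @param tab an `amp_variant_table`.
#' @param path file path.
#' @export
write_variant_tsv <- function(tab, path) {
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_variant_tsv
#' @param sample,fraction labels restored as attributes.
#' @export
read_variant_tsv <- function(path, sample = NULL, fraction = NA_character_) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(ALT = "character", REF = "character"))
  tab$PASS <- as.logical(tab$PASS)
  attr(tab, "sample") <- sample %||% sub("\\.tsv$", "", basename(path))
  attr(tab, "fraction") <- fraction
  class(tab) <- c("amp_variant_table", "data.frame")
  tab
}

#' Variant identity key
#'
#' The `(region, pos, ref, alt)` key used for replicate intersection and
#' cross-passage matching; exact equality after left-normalization, with
#' no positional tolerance.
#' @param tab an `amp_variant_table`.
#' @return character vector of keys.
#' @export
variant_key <- function(tab) {
  paste(tab$REGION, tab$POS, tab$REF, tab$ALT, sep = ":")
}
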