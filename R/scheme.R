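#' Design a two-pool tiled amplicon scheme
#'
#' Arithmetic tiling of the genome into overlapping amplicons: amplicons of
#' fixed length step along the genome by `amplicon_len - overlap`; the last
#' amplicon is clamped so its end coincides with the genome end. Odd-numbered
#' amplicons go to primer pool 1 and even-numbered ones to pool 2, so
#' neighbouring amplicons amplify in separate multiplex PCRs. Primers are the
#' terminal `primer_len` bases of each amplicon; the insert is everything
#' between them.
#'
#' @param g an `amp_genome`.
#' @param amplicon_len amplicon length in bp (default 1000).
#' @param overlap minimum overlap between consecutive amplicons (default 100).
#' @param primer_len primer length in bp (default 22).
#' @return a data.frame of class `amp_scheme` with one row per amplicon:
#'   `amplicon`, `name`, `start`, `end`, `pool`, `left_start`, `left_end`,
#'   `right_start`, `right_end`, `insert_start`, `insert_end`; the genome id
#'   is kept in attribute `ref_id`.
#' @export
design_tiling <- function(g, amplicon_len = 1000L, overlap = 100L,
                          primer_len = 22L) {
  L <- g$length
  if (amplicon_len > L) amplicon_len <- L
  if (amplicon_len <= 2L * primer_len + overlap && amplicon_len < L)
    stop("amplicon_len must exceed 2*primer_len + overlap")
  if (L <= 2L * primer_len)
    stop("genome shorter than one amplicon's primers")
  step <- amplicon_len - overlap
  starts <- seq(1L, max(1L, L - amplicon_len + 1L), by = max(step, 1L))
  if (starts[length(starts)] + amplicon_len - 1L < L)
    starts <- c(starts, L - amplicon_len + 1L)
  starts <- unique(starts)
  n <- length(starts)
  ends <- starts + amplicon_len - 1L
  sch <- data.frame(
    amplicon = seq_len(n),
    name = sprintf("amp_%03d", seq_len(n)),
    start = starts, end = ends,
    pool = ifelse(seq_len(n) %% 2L == 1L, 1L, 2L),
    left_start = starts, left_end = starts + primer_len - 1L,
    right_start = ends - primer_len + 1L, right_end = ends,
    insert_start = starts + primer_len,
    insert_end = ends - primer_len,
    stringsAsFactors = FALSE)
  attr(sch, "ref_id") <- g$id
  attr(sch, "primer_len") <- primer_len
  class(sch) <- c("amp_scheme", "data.frame")
  sch
}

scheme_primer_seqs <- function(sch, g) {
  left <- substring(g$sequence, sch$left_start, sch$left_end)
  right_plus <- substring(g$sequence, sch$right_start, sch$right_end)
  right <- vapply(right_plus, revcomp, "", USE.NAMES = FALSE)
  list(left = left, right = right)
}

# amplicons whose insert overlaps [start, end]
amplicons_overlapping <- function(sch, start, end) {
  which(sch$insert_start <= end & sch$insert_end >= start)
}

#' Primer-scheme BED IO (ARTIC-style dialect)
#'
#' Six columns: chrom, 0-based start, end, name with `_LEFT`/`_RIGHT`
#' suffix, pool, strand (+ for left, - for right primers).
#'
#' @param sch an `amp_scheme`.
#' @param path file path.
#' @export
write_scheme_bed <- function(sch, path) {
  ref <- attr(sch, "ref_id")
  lines <- c(
    sprintf("%s\t%d\t%d\t%s_LEFT\t%d\t+", ref, sch$left_start - 1L,
            sch$left_end, sch$name, sch$pool),
    sprintf("%s\t%d\t%d\t%s_RIGHT\t%d\t-", ref, sch$right_start - 1L,
            sch$right_end, sch$name, sch$pool))
  writeLines(lines[order(rep(sch$start, 2L))], path)
  invisible(path)
}

#' @rdname write_scheme_bed
#' @param primer_len primer length used to reconstruct amplicon bounds.
#' @export
read_scheme_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  amp <- sub("_(LEFT|RIGHT)$", "", x$V4)
  side <- sub("^.*_(LEFT|RIGHT)$", "\\1", x$V4)
  left <- x[side == "LEFT", ]
  right <- x[side == "RIGHT", ]
  lamp <- sub("_(LEFT|RIGHT)$", "", left$V4)
  ramp <- sub("_(LEFT|RIGHT)$", "", right$V4)
  right <- right[match(lamp, ramp), ]
  primer_len <- left$V3[1] - left$V2[1]
  sch <- data.frame(
    amplicon = seq_len(nrow(left)),
    name = lamp,
    start = left$V2 + 1L, end = right$V3,
    pool = left$V5,
    left_start = left$V2 + 1L, left_end = left$V3,
    right_start = right$V2 + 1L, right_end = right$V3,
    insert_start = left$V3 + 1L, insert_end = right$V2,
    stringsAsFactors = FALSE)
  sch <- sch[order(sch$start), ]
  sch$amplicon <- seq_len(nrow(sch))
  rownames(sch) <- NULL
  attr(sch, "ref_id") <- x$V1[1]
  attr(sch, "primer_len") <- primer_len
  class(sch) <- c("amp_scheme", "data.frame")
  sch
}

# all primer intervals as a data.frame (for clipping unassigned reads)
primer_intervals <- function(sch) {
  data.frame(
    amplicon = rep(sch$amplicon, 2L),
    start = c(sch$left_start, sch$right_start),
    end = c(sch$left_end, sch$right_end),
    side = rep(c("left", "right"), each = nrow(sch)),
    stringsAsFactors = FALSE)
}
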