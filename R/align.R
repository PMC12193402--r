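# Read placement: amplicon assignment by primer-prefix matching, banded
# affine-gap alignment within the assigned amplicon window, and indel
# left-normalization (the realignment analog for mapping errors around
# indels).

parse_cigar <- function(cig) {
  lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  ops <- regmatches(cig, gregexpr("[MIDSHNP=X]", cig))[[1]]
  list(lens = lens, ops = ops)
}

build_cigar <- function(lens, ops) {
  keep <- lens > 0L
  lens <- lens[keep]; ops <- ops[keep]
  if (!length(lens)) return("*")
  # merge adjacent identical ops
  i <- 1L
  while (i < length(lens)) {
    if (ops[i] == ops[i + 1L]) {
      lens[i] <- lens[i] + lens[i + 1L]
      lens <- lens[-(i + 1L)]; ops <- ops[-(i + 1L)]
    } else i <- i + 1L
  }
  paste0(lens, ops, collapse = "")
}

cigar_query_len <- function(cig) {
  if (cig == "*") return(0L)
  p <- parse_cigar(cig)
  sum(p$lens[p$ops %in% c("M", "I", "S", "=", "X")])
}

cigar_aligned_query_len <- function(cig) {
  if (cig == "*") return(0L)
  p <- parse_cigar(cig)
  sum(p$lens[p$ops %in% c("M", "I", "=", "X")])
}

cigar_ref_span <- function(cig) {
  if (cig == "*") return(0L)
  p <- parse_cigar(cig)
  sum(p$lens[p$ops %in% c("M", "D", "N", "=", "X")])
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), qual = character(), amplicon = integer(),
             stringsAsFactors = FALSE)
}

#' Assign read pairs to amplicons by their primer prefixes
#'
#' Matches each mate's 5' k-mer (k = primer length) against the scheme's
#' left and right primer sequences within an edit-distance tolerance, in
#' both pair orientations. A pair is assigned when exactly one amplicon
#' matches; zero matches or a tie leave it unassigned (ties are flagged
#' ambiguous).
#'
#' @param pairs data.frame with `seq1`, `seq2` (and optionally `name`).
#' @param sch an `amp_scheme`.
#' @param g the `amp_genome` the scheme was designed on.
#' @param tol maximum edit distance per primer (default 2).
#' @return data.frame `amplicon` (NA if unassigned), `orientation`
#'   (`"fwd"` = mate 1 carries the left primer), `ambiguous`.
#' @export
assign_amplicon <- function(pairs, sch, g, tol = 2L) {
  pl <- attr(sch, "primer_len")
  pr <- scheme_primer_seqs(sch, g)
  p1 <- substr(pairs$seq1, 1L, pl)
  p2 <- substr(pairs$seq2, 1L, pl)
  n <- nrow(pairs)
  amp <- rep(NA_integer_, n)
  orient <- rep(NA_character_, n)
  ambig <- rep(FALSE, n)
  dup_primer <- anyDuplicated(pr$left) || anyDuplicated(pr$right) ||
    length(intersect(pr$left, pr$right)) > 0
  # fast path: both prefixes match a primer pair exactly (and primers are
  # unique in the scheme)
  e1L <- match(p1, pr$left); e2R <- match(p2, pr$right)
  e1R <- match(p1, pr$right); e2L <- match(p2, pr$left)
  fwd_ok <- !is.na(e1L) & !is.na(e2R) & e1L == e2R & is.na(e1R) & is.na(e2L)
  rev_ok <- !is.na(e1R) & !is.na(e2L) & e1R == e2L & is.na(e1L) & is.na(e2R)
  if (!dup_primer) {
    amp[fwd_ok] <- e1L[fwd_ok]; orient[fwd_ok] <- "fwd"
    amp[rev_ok] <- e1R[rev_ok]; orient[rev_ok] <- "rev"
  }
  todo <- which(is.na(amp))
  if (length(todo)) {
    d1L <- adist(p1[todo], pr$left);  d2R <- adist(p2[todo], pr$right)
    d1R <- adist(p1[todo], pr$right); d2L <- adist(p2[todo], pr$left)
    okA <- d1L <= tol & d2R <= tol   # mate1 = left primer end
    okB <- d1R <= tol & d2L <= tol   # mate1 = right primer end
    for (k in seq_along(todo)) {
      i <- todo[k]
      ca <- which(okA[k, ]); cb <- which(okB[k, ])
      hits <- unique(c(ca, cb))
      if (length(hits) == 1L && length(ca) + length(cb) == 1L) {
        amp[i] <- hits
        orient[i] <- if (length(ca)) "fwd" else "rev"
      } else if (length(hits) >= 1L) {
        ambig[i] <- TRUE
      }
    }
  }
  data.frame(amplicon = amp, orientation = orient, ambiguous = ambig,
             stringsAsFactors = FALSE)
}

#' Align one read within a reference window
#'
#' Global-in-read, local-in-window banded affine-gap alignment. The band is
#' centred on the diagonal given by `expected_start` (amplicon reads start
#' at primer starts, so the start is known up to the indel length).
#'
#' @param seq read sequence (already on the plus strand).
#' @param g an `amp_genome`.
#' @param window `c(start, end)` reference interval to align into.
#' @param expected_start expected 1-based genome start of the read.
#' @param band half band width (default 64; covers indels shorter than the
#'   band).
#' @param match,mismatch,gap_open,gap_ext scoring (defaults +2/-4/-6/-1; a
#'   gap of length L costs `gap_open + L*gap_ext`).
#' @return list `pos` (genome), `cigar`, `score`.
#' @export
align_read <- function(seq, g, window, expected_start, band = 64L,
                       match = 2, mismatch = -4, gap_open = -6,
                       gap_ext = -1) {
  if (!nzchar(seq)) stop("empty read")
  wstart <- max(1L, window[1]); wend <- min(g$length, window[2])
  wseq <- genome_sub(g, wstart, wend)
  if (nchar(wseq) < nchar(seq) - band)
    stop("window shorter than read after banding")
  r <- align_banded_cpp(seq, wseq, expected_start - wstart + 1L,
                        as.integer(band), match, mismatch, gap_open,
                        gap_ext)
  list(pos = wstart + r$pos - 1L, cigar = r$cigar, score = r$score)
}

#' Align simulated or parsed read pairs against the reference
#'
#' Drives [assign_amplicon()] and [align_read()] over a table of read
#' pairs and returns SAM-style alignment records. Unassigned pairs are
#' reported as unmapped records. MAPQ is 60 for uniquely assigned pairs;
#' assignment ties are unassigned by construction.
#'
#' @param pairs data.frame with `name`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param g an `amp_genome`.
#' @param sch an `amp_scheme`.
#' @param pad window padding around the amplicon (default 50).
#' @param band,tol see [align_read()] / [assign_amplicon()].
#' @return alignment data.frame (SAM columns plus `amplicon`).
#' @export
align_pairs <- function(pairs, g, sch, pad = 50L, band = 64L, tol = 2L) {
  asg <- assign_amplicon(pairs, sch, g, tol = tol)
  n <- nrow(pairs)
  m <- 2L * n
  qname <- rep(pairs$name, each = 2L)
  flag <- integer(m); pos <- integer(m); mapq <- integer(m)
  cig <- character(m); seqv <- character(m); qualv <- character(m)
  rname <- rep("*", m); rnextv <- rep("*", m)
  pnextv <- integer(m)
  ampv <- rep(NA_integer_, m)

  fwd <- !is.na(asg$amplicon) & asg$orientation == "fwd"
  rev_ <- !is.na(asg$amplicon) & asg$orientation == "rev"
  # plus-strand query/qual per mate slot
  fseq <- ifelse(fwd, pairs$seq1, pairs$seq2)
  fqual <- ifelse(fwd, pairs$qual1, pairs$qual2)
  rseq0 <- ifelse(fwd, pairs$seq2, pairs$seq1)
  rqual0 <- ifelse(fwd, pairs$qual2, pairs$qual1)
  mapped <- fwd | rev_
  rseq <- rseq0
  rqual <- rqual0
  rseq[mapped] <- revcomp_vec(rseq0[mapped])
  rqual[mapped] <- rev_str_vec(rqual0[mapped])

  for (i in seq_len(n)) {
    jf <- 2L * i - 1L; jr <- 2L * i
    a <- asg$amplicon[i]
    if (is.na(a)) {
      flag[jf] <- 77L; flag[jr] <- 141L
      cig[jf] <- cig[jr] <- "*"
      seqv[jf] <- pairs$seq1[i]; qualv[jf] <- pairs$qual1[i]
      seqv[jr] <- pairs$seq2[i]; qualv[jr] <- pairs$qual2[i]
      next
    }
    astart <- sch$start[a]; aend <- sch$end[a]
    window <- c(astart - pad, aend + pad)
    af <- align_read(fseq[i], g, window, astart, band = band)
    ar <- align_read(rseq[i], g, window,
                     aend - nchar(rseq[i]) + 1L, band = band)
    if (fwd[i]) { flag[jf] <- 99L; flag[jr] <- 147L }
    else { flag[jf] <- 163L; flag[jr] <- 83L }
    rname[jf] <- rname[jr] <- g$id
    rnextv[jf] <- rnextv[jr] <- "="
    mapq[jf] <- mapq[jr] <- 60L
    ampv[jf] <- ampv[jr] <- a
    pos[jf] <- af$pos; cig[jf] <- af$cigar
    pos[jr] <- ar$pos; cig[jr] <- ar$cigar
    pnextv[jf] <- ar$pos; pnextv[jr] <- af$pos
    seqv[jf] <- fseq[i]; qualv[jf] <- fqual[i]
    seqv[jr] <- rseq[i]; qualv[jr] <- rqual[i]
  }
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cig, rnext = rnextv, pnext = pnextv,
             tlen = 0L, seq = seqv, qual = qualv, amplicon = ampv,
             stringsAsFactors = FALSE)
}

# shift one record's indels maximally 5'-ward; read reconstruction invariant
normalize_one <- function(pos, cig, seq, g) {
  p <- parse_cigar(cig)
  lens <- p$lens; ops <- p$ops
  refpos <- pos; qpos <- 1L
  i <- 1L
  while (i <= length(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      refpos <- refpos + len; qpos <- qpos + len
      i <- i + 1L
    } else if (op == "S") {
      qpos <- qpos + len
      i <- i + 1L
    } else if (op == "D") {
      prev_can <- if (i > 1L && ops[i - 1L] %in% c("M", "=", "X"))
        lens[i - 1L] else 0L
      s <- 0L
      while (s < prev_can && refpos - s - 1L >= 1L &&
             genome_sub(g, refpos - s - 1L, refpos - s - 1L) ==
             genome_sub(g, refpos + len - s - 1L, refpos + len - s - 1L))
        s <- s + 1L
      if (s > 0L) {
        lens[i - 1L] <- lens[i - 1L] - s
        if (i < length(ops) && ops[i + 1L] %in% c("M", "=", "X")) {
          lens[i + 1L] <- lens[i + 1L] + s
        } else {
          ops <- append(ops, "M", after = i)
          lens <- append(lens, s, after = i)
        }
        refpos <- refpos - s
      }
      refpos <- refpos + len
      i <- i + 1L
    } else if (op == "I") {
      prev_can <- if (i > 1L && ops[i - 1L] %in% c("M", "=", "X"))
        lens[i - 1L] else 0L
      s <- 0L
      while (s < prev_can && qpos - s - 1L >= 1L &&
             substr(seq, qpos + len - s - 1L, qpos + len - s - 1L) ==
             genome_sub(g, refpos - s - 1L, refpos - s - 1L))
        s <- s + 1L
      if (s > 0L) {
        lens[i - 1L] <- lens[i - 1L] - s
        if (i < length(ops) && ops[i + 1L] %in% c("M", "=", "X")) {
          lens[i + 1L] <- lens[i + 1L] + s
        } else {
          ops <- append(ops, "M", after = i)
          lens <- append(lens, s, after = i)
        }
        refpos <- refpos - s
        qpos <- qpos - s
      }
      qpos <- qpos + len
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  # cleanup: drop zero-length ops, merge, handle leading/trailing gaps
  keep <- lens > 0L
  lens <- lens[keep]; ops <- ops[keep]
  # leading deletion: skip it by advancing pos
  while (length(ops) && ops[1] == "D") {
    pos <- pos_after_leading_del(pos, cig, lens[1])
    lens <- lens[-1L]; ops <- ops[-1L]
  }
  # leading insertion becomes a soft clip
  j <- 1L
  while (j <= length(ops) && ops[j] == "S") j <- j + 1L
  if (j <= length(ops) && ops[j] == "I") ops[j] <- "S"
  # trailing deletion: drop
  while (length(ops) && ops[length(ops)] == "D") {
    lens <- lens[-length(lens)]; ops <- ops[-length(ops)]
  }
  list(pos = pos, cigar = build_cigar(lens, ops))
}

pos_after_leading_del <- function(pos, orig_cigar, dlen) pos + dlen

#' Left-normalize indels in alignment records
#'
#' Shifts every insertion/deletion maximally 5'-ward on the reference while
#' the deleted/inserted sequence is invariant under the shift (standard
#' left alignment in homopolymer and repeat context), so equivalent indel
#' representations become canonical before pileup and replicate
#' intersection. The implied read sequence is unchanged; the operation is
#' idempotent.
#'
#' @param alns alignment data.frame.
#' @param g an `amp_genome`.
#' @return the alignment data.frame with updated `pos`/`cigar`.
#' @export
left_normalize_indels <- function(alns, g) {
  idx <- which(grepl("[ID]", alns$cigar) & alns$cigar != "*")
  for (i in idx) {
    r <- normalize_one(alns$pos[i], alns$cigar[i], alns$seq[i], g)
    alns$pos[i] <- r$pos
    alns$cigar[i] <- r$cigar
  }
  alns
}
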