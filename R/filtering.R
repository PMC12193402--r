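# Alignment-level filters: SAM flag mask, mapping quality, primer
# soft-clipping, and post-clip length. Flag mask 2308 = 4 (unmapped) +
# 256 (secondary) + 2048 (supplementary).

#' Filter configuration
#'
#' @param mapq_min minimum mapping quality to keep (default 10, keep-if >=).
#' @param flag_mask SAM bits that exclude a record (default 2308:
#'   unmapped, secondary, supplementary).
#' @param min_post_clip_len minimum aligned (non-clipped) query length
#'   after primer clipping (default 200, keep-if >=).
#' @return list of class `amp_filter_config`.
#' @export
filter_config <- function(mapq_min = 10L, flag_mask = 2308L,
                          min_post_clip_len = 200L) {
  stopifnot(mapq_min >= 0L, flag_mask >= 0L)
  structure(list(mapq_min = as.integer(mapq_min),
                 flag_mask = as.integer(flag_mask),
                 min_post_clip_len = as.integer(min_post_clip_len)),
            class = "amp_filter_config")
}

#' Flag-mask and mapping-quality filter
#'
#' Keeps records with `(flag AND flag_mask) == 0` and `mapq >= mapq_min`;
#' record order is preserved.
#'
#' @param alns alignment data.frame.
#' @param cfg an `amp_filter_config`.
#' @export
filter_flags_mapq <- function(alns, cfg = filter_config()) {
  keep <- bitwAnd(alns$flag, cfg$flag_mask) == 0L & alns$mapq >= cfg$mapq_min
  out <- alns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# soft-clip aligned columns with refpos <= cut_left or >= cut_right
clip_cigar <- function(pos, cig, cut_left = 0L, cut_right = .Machine$integer.max) {
  p <- parse_cigar(cig)
  lens <- p$lens; ops <- p$ops
  n <- length(ops)
  out_lens <- integer(0); out_ops <- character(0)
  left_clip <- 0L; right_clip <- 0L
  refpos <- pos
  new_pos <- NA_integer_
  for (k in seq_len(n)) {
    op <- ops[k]; len <- lens[k]
    if (op == "S") {
      if (length(out_ops) == 0L) left_clip <- left_clip + len
      else right_clip <- right_clip + len
      next
    }
    if (op == "I") {
      # insertion is attached to the preceding reference position
      if (refpos - 1L <= cut_left) left_clip <- left_clip + len
      else if (refpos >= cut_right) right_clip <- right_clip + len
      else { out_lens <- c(out_lens, len); out_ops <- c(out_ops, op) }
      next
    }
    # M or D: reference-consuming span [refpos, refpos+len-1]
    lo <- refpos; hi <- refpos + len - 1L
    in_left <- max(0L, min(hi, cut_left) - lo + 1L)
    in_right <- max(0L, hi - max(lo, cut_right) + 1L)
    in_left <- min(in_left, len); in_right <- min(in_right, len - in_left)
    mid <- len - in_left - in_right
    if (op == "M") {
      left_clip <- left_clip + in_left
      right_clip <- right_clip + in_right
      if (mid > 0L) {
        if (is.na(new_pos)) new_pos <- lo + in_left
        out_lens <- c(out_lens, mid); out_ops <- c(out_ops, "M")
      }
    } else { # D: clipped deleted bases just vanish
      if (mid > 0L) {
        out_lens <- c(out_lens, mid); out_ops <- c(out_ops, "D")
      }
    }
    refpos <- refpos + len
  }
  # drop leading/trailing D in the kept part
  # new_pos already points at the first kept M, so dropping flanking D ops
  # does not move it
  while (length(out_ops) && out_ops[1] == "D") {
    out_lens <- out_lens[-1]; out_ops <- out_ops[-1]
  }
  while (length(out_ops) && out_ops[length(out_ops)] == "D") {
    out_lens <- out_lens[-length(out_lens)]
    out_ops <- out_ops[-length(out_ops)]
  }
  if (!length(out_ops)) {
    return(list(pos = 0L, cigar = "*", fully_clipped = TRUE))
  }
  if (is.na(new_pos)) new_pos <- pos
  lens2 <- c(if (left_clip) left_clip, out_lens, if (right_clip) right_clip)
  ops2 <- c(if (left_clip) "S", out_ops, if (right_clip) "S")
  list(pos = new_pos, cigar = build_cigar(lens2, ops2),
       fully_clipped = FALSE)
}

#' Soft-clip primer-derived bases from alignments
#'
#' Converts aligned bases that overlap primer intervals at either read end
#' into soft clips, advancing the record position accordingly, so
#' primer-encoded sequence cannot masquerade as reference support in the
#' pileup. Records with a known amplicon are clipped against that
#' amplicon's own primer pair (a deep read spanning a neighbouring
#' amplicon's primer site retains those genuine template bases); records
#' without an assignment are clipped against any primer interval
#' overlapping their leftmost/rightmost aligned positions. Clipping is
#' idempotent; a record left with no aligned bases is marked fully clipped
#' (`cigar == "*"`, flag bit 4 set) for removal by [filter_length()].
#'
#' @param alns alignment data.frame.
#' @param sch an `amp_scheme`.
#' @return the clipped alignment data.frame.
#' @export
clip_primers <- function(alns, sch) {
  piv <- primer_intervals(sch)
  spans <- cigar_stats_cpp(alns$cigar)[, "ref_span"]
  # fast path: all-M records of a known amplicon reduce to coordinate
  # arithmetic
  plain <- grepl("^[0-9]+M$", alns$cigar) & !is.na(alns$amplicon) &
    bitwAnd(alns$flag, 4L) == 0L
  if (any(plain)) {
    i <- which(plain)
    pos <- alns$pos[i]
    mlen <- spans[i]
    endp <- pos + mlen - 1L
    a <- alns$amplicon[i]
    cutL <- ifelse(pos <= sch$left_end[a], sch$left_end[a], 0L)
    cutR <- ifelse(endp >= sch$right_start[a], sch$right_start[a],
                   .Machine$integer.max)
    lclip <- pmax(0L, pmin(cutL - pos + 1L, mlen))
    rclip <- pmax(0L, pmin(endp - cutR + 1L, mlen - lclip))
    mid <- mlen - lclip - rclip
    full <- mid <= 0L
    newcig <- paste0(ifelse(lclip > 0L, paste0(lclip, "S"), ""),
                     ifelse(mid > 0L, paste0(mid, "M"), ""),
                     ifelse(rclip > 0L, paste0(rclip, "S"), ""))
    alns$cigar[i] <- ifelse(full, "*", newcig)
    alns$pos[i] <- ifelse(full, 0L, pos + lclip)
    alns$flag[i] <- ifelse(full, bitwOr(alns$flag[i], 4L), alns$flag[i])
  }
  for (i in which(!plain)) {
    if (alns$cigar[i] == "*" || bitwAnd(alns$flag[i], 4L) != 0L) next
    pos <- alns$pos[i]
    span_end <- pos + spans[i] - 1L
    a <- alns$amplicon[i]
    if (!is.na(a)) {
      cutL <- if (pos <= sch$left_end[a]) sch$left_end[a] else 0L
      cutR <- if (span_end >= sch$right_start[a]) sch$right_start[a]
      else .Machine$integer.max
    } else {
      hitL <- piv[piv$start <= pos & piv$end >= pos, ]
      hitR <- piv[piv$start <= span_end & piv$end >= span_end, ]
      cutL <- if (nrow(hitL)) max(hitL$end) else 0L
      cutR <- if (nrow(hitR)) min(hitR$start) else .Machine$integer.max
    }
    if (cutL == 0L && cutR == .Machine$integer.max) next
    r <- clip_cigar(pos, alns$cigar[i], cutL, cutR)
    if (r$fully_clipped) {
      alns$flag[i] <- bitwOr(alns$flag[i], 4L)
      alns$cigar[i] <- "*"
      alns$pos[i] <- 0L
    } else {
      alns$pos[i] <- r$pos
      alns$cigar[i] <- r$cigar
    }
  }
  alns
}

#' Post-clip length filter
#'
#' Keeps records whose aligned (non-clipped) query length is at least
#' `min_post_clip_len`; fully clipped or unmapped records are removed.
#'
#' @param alns alignment data.frame.
#' @param cfg an `amp_filter_config`.
#' @export
filter_length <- function(alns, cfg = filter_config()) {
  alen <- cigar_stats_cpp(alns$cigar)[, "aligned_qlen"]
  out <- alns[alen >= cfg$min_post_clip_len & alns$cigar != "*", ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}
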