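# Guide placement, estimated-indel-window prediction, on-target labeling
# and mismatch/PAM off-target scanning.

#' Locate a protospacer on the genome
#'
#' Exact-match search for the 20-mer spacer on the plus strand and for its
#' reverse complement on the minus strand, requiring an adjacent NGG-type
#' PAM 3' of the protospacer on the matching strand. The Cas9 blunt cut
#' falls between protospacer positions 17 and 18 (3 bp 5' of the PAM).
#'
#' @param g an `amp_genome`.
#' @param target one row of a targets table (or a list with `spacer`,
#'   `pam`).
#' @return list of class `amp_protospacer_site`: `strand` (genome strand
#'   carrying the protospacer), `proto_start`, `proto_end`, `pam_start`,
#'   `pam_end` (plus-strand coordinates), `cut_after` (plus-strand position
#'   after which the blunt cut falls).
#' @export
locate_protospacer <- function(g, target) {
  spacer <- target$spacer
  pam <- target$pam %||% "NGG"
  if (is.na(pam)) pam <- "NGG"
  pam <- sub("^[ACGT]", "N", pam)  # match any PAM of the same class
  dna <- Biostrings::DNAString(g$sequence)
  hits <- list()
  plus <- Biostrings::matchPattern(spacer, dna)
  for (i in seq_along(plus)) {
    s <- Biostrings::start(plus)[i]
    pe <- s + 19L + 3L
    if (pe > g$length) next
    if (pam_matches(genome_sub(g, s + 20L, pe), pam))
      hits[[length(hits) + 1L]] <- list(
        strand = "+", proto_start = s, proto_end = s + 19L,
        pam_start = s + 20L, pam_end = pe,
        cut_after = s + 16L)  # between protospacer positions 17 and 18
  }
  minus <- Biostrings::matchPattern(revcomp(spacer), dna)
  pam_rc <- revcomp(gsub("N", "A", pam))
  pam_rc <- paste0(substr(pam_rc, 1L, 2L), "N")  # CCN for NGG
  for (i in seq_along(minus)) {
    s <- Biostrings::start(minus)[i]
    if (s - 3L < 1L) next
    if (pam_matches(genome_sub(g, s - 3L, s - 1L), pam_rc))
      hits[[length(hits) + 1L]] <- list(
        strand = "-", proto_start = s, proto_end = s + 19L,
        pam_start = s - 3L, pam_end = s - 1L,
        cut_after = s + 2L)   # between protospacer positions 18 and 17
  }
  if (!length(hits))
    stop("protospacer not found with adjacent PAM: ", target$name %||% spacer)
  if (length(hits) > 1L)
    stop("ambiguous protospacer (", length(hits), " sites): ",
         target$name %||% spacer)
  site <- hits[[1]]
  site$name <- target$name %||% NA_character_
  class(site) <- "amp_protospacer_site"
  site
}

#' Predict the estimated indel window of a located protospacer
#'
#' The six reference positions at which 1-5 bp repair indels anchored 3-4
#' bp upstream of the PAM can be reported: protospacer positions 13-18,
#' mapped to plus-strand genome coordinates (`[start+12, start+17]` for a
#' plus-strand protospacer, `[start+2, start+7]` for a minus-strand one).
#' The window contains the two bases flanking the cut site.
#'
#' @param site an `amp_protospacer_site`.
#' @param g optional `amp_genome` for a bounds check.
#' @return list `start`, `end` (1-based inclusive; width 6), `name`.
#' @export
predict_edit_window <- function(site, g = NULL) {
  w <- if (site$strand == "+")
    c(site$proto_start + 12L, site$proto_start + 17L)
  else
    c(site$proto_start + 2L, site$proto_start + 7L)
  if (!is.null(g) && (w[1] < 1L || w[2] > g$length))
    stop("edit window extends past the genome end")
  list(start = w[1], end = w[2], name = site$name)
}

#' Edit windows for a targets table
#'
#' Locates each target's protospacer and predicts its window; a target row
#' carrying a declared `window_start`/`window_end` (the sense-strand
#' gp64-160 target, whose declared window is anchored rather than
#' derived) uses the declared coordinates.
#'
#' @param g an `amp_genome`.
#' @param targets targets table (see [default_targets()]).
#' @return data.frame `name`, `start`, `end`, `declared`.
#' @export
edit_windows <- function(g, targets) {
  tg <- targets[targets$role == "target", , drop = FALSE]
  out <- lapply(seq_len(nrow(tg)), function(i) {
    t <- as.list(tg[i, ])
    if (!is.na(t$window_start)) {
      data.frame(name = t$name, start = t$window_start,
                 end = t$window_end, declared = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      w <- predict_edit_window(locate_protospacer(g, t), g)
      data.frame(name = t$name, start = w$start, end = w$end,
                 declared = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Label variants as on-target or off-window
#'
#' A variant is on-target when its affected reference interval intersects
#' an estimated indel window. For deletions the interval runs from the
#' anchor through the last deleted base; insertions straddle the anchor
#' junction; SNVs are a point.
#'
#' @param tab an `amp_variant_table`.
#' @param windows data.frame from [edit_windows()].
#' @return the table with columns `TARGET_LABEL` (`on_target` /
#'   `off_window`) and `TARGET` (window name or NA); a per-window hit count
#'   is attached as attribute `window_hits`.
#' @export
match_on_target <- function(tab, windows) {
  n <- nrow(tab)
  lab <- rep("off_window", n)
  tgt <- rep(NA_character_, n)
  if (n) {
    iv <- t(vapply(seq_len(n), function(i)
      variant_interval(tab$POS[i], tab$ALT[i]), integer(2)))
    for (i in seq_len(n)) {
      hit <- which(windows$start <= iv[i, 2] & windows$end >= iv[i, 1])
      if (length(hit)) {
        lab[i] <- "on_target"
        tgt[i] <- windows$name[hit[1]]
      }
    }
  }
  tab$TARGET_LABEL <- lab
  tab$TARGET <- tgt
  hits <- table(factor(tgt[lab == "on_target"], levels = windows$name))
  attr(tab, "window_hits") <- as.data.frame(hits, stringsAsFactors = FALSE,
                                            responseName = "hits")
  tab
}

#' Scan the genome for off-target sites of a spacer
#'
#' Slides a 20 bp frame over both strands (the on-target site excluded),
#' counting Hamming mismatches against the spacer. With `pam_required`,
#' only frames with an NGG-type PAM immediately 3' (on the frame's strand)
#' are retained. Also reports the genome-wide minimum mismatch count
#' ignoring PAM presence.
#'
#' @param g an `amp_genome`.
#' @param target targets-table row (or list with `spacer`).
#' @param max_mm report hits with at most this many mismatches (default 6).
#' @param pam_required require the PAM (default TRUE).
#' @param exclude_on_target drop the perfect on-target frame (default TRUE).
#' @return list `hits` (data.frame pos/strand/mismatches/pam_present) and
#'   `min_mismatch` (ignoring PAM, on-target excluded).
#' @export
scan_off_targets <- function(g, target, max_mm = 6L, pam_required = TRUE,
                             exclude_on_target = TRUE) {
  if (g$length < 23L) stop("genome shorter than spacer + PAM")
  ch <- strsplit(g$sequence, "")[[1]]
  L <- g$length
  scan_strand <- function(pattern, strand) {
    pc <- strsplit(pattern, "")[[1]]
    nf <- L - 19L
    mm <- integer(nf)
    for (k in 1:20)
      mm <- mm + (ch[k:(L - 20L + k)] != pc[k])
    # PAM: plus frames need NGG at [p+20, p+22]; minus frames (pattern is
    # the spacer's reverse complement) need CCN at [p-3, p-1]
    pam <- rep(FALSE, nf)
    if (strand == "+") {
      # NGG: positions p+21, p+22 are G,G (p+20 is the N)
      idx <- seq_len(max(nf - 3L, 0L))
      pam[idx] <- ch[idx + 21L] == "G" & ch[idx + 22L] == "G"
    } else {
      idx <- which(seq_len(nf) >= 4L)
      pam[idx] <- ch[idx - 3L] == "C" & ch[idx - 2L] == "C"
    }
    data.frame(pos = seq_len(nf), strand = strand, mismatches = mm,
               pam_present = pam, stringsAsFactors = FALSE)
  }
  res <- rbind(scan_strand(target$spacer, "+"),
               scan_strand(revcomp(target$spacer), "-"))
  if (exclude_on_target) {
    on0 <- res$mismatches == 0L & res$pam_present
    res <- res[!on0, , drop = FALSE]
  }
  min_mm <- min(res$mismatches)
  hits <- res[res$mismatches <= max_mm &
                (!pam_required | res$pam_present), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, min_mismatch = min_mm)
}
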