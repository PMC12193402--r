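#' Emit alignment records as SAM text
#'
#' Writes a SAM v1 header (`@HD`, `@SQ` from the genome, `@PG`) and one
#' record per alignment row. Records round-trip through [parse_sam()].
#'
#' @param alns alignment data.frame (see [align_pairs()]).
#' @param g an `amp_genome`.
#' @param path optional output path; if `NULL` the lines are returned.
#' @return character vector of SAM lines, invisibly when `path` is given.
#' @export
emit_sam <- function(alns, g, path = NULL) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", g$id, g$length),
              "@PG\tID:ampedit\tPN:ampedit")
  amp_tag <- ifelse(is.na(alns$amplicon), "",
                    sprintf("\tXA:i:%d", alns$amplicon))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
                 alns$qname, alns$flag, alns$rname, alns$pos, alns$mapq,
                 alns$cigar, alns$rnext, alns$pnext, alns$tlen, alns$seq,
                 alns$qual, amp_tag)
  lines <- c(header, rec)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname emit_sam
#' @param x character vector of SAM lines, or a path to a SAM file.
#' @export
parse_sam <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  rec <- x[!startsWith(x, "@")]
  if (!length(rec)) return(empty_alignments())
  f <- strsplit(rec, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[`, "", i)
  amp <- vapply(f, function(z) {
    t <- grep("^XA:i:", z[-(1:11)], value = TRUE)
    if (length(t)) as.integer(sub("^XA:i:", "", t[1])) else NA_integer_
  }, 1L)
  data.frame(qname = get(1L), flag = as.integer(get(2L)), rname = get(3L),
             pos = as.integer(get(4L)), mapq = as.integer(get(5L)),
             cigar = get(6L), rnext = get(7L), pnext = as.integer(get(8L)),
             tlen = as.integer(get(9L)), seq = get(10L), qual = get(11L),
             amplicon = amp, stringsAsFactors = FALSE)
}
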