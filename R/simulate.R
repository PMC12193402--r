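#' Scenario specification
#'
#' A scenario describes one sample x fraction cell of the assay design: the
#' minor-variant haplotypes to spike (position, iVar-style allele notation,
#' true haplotype frequency), optional background variants (conserved / hr
#' variants spiked the same way), target depth, read geometry and one RNG
#' seed per technical replicate.
#'
#' Allele notation: a SNV is a single base; an insertion is `+SEQ` inserted
#' after `pos`; a deletion is `-SEQ` where `SEQ` is the `len` reference
#' bases immediately AFTER `pos` (the anchor base convention of
#' mpileup-style callers: the reported position is the last aligned base
#' before the gap).
#'
#' @param sample_name sample label (e.g. `"gp64+378"`).
#' @param fraction one of `cell_pellet`, `supernatant`, `stock`.
#' @param variants data.frame with columns `pos`, `alt`, `freq`.
#' @param background_variants optional data.frame, same shape.
#' @param depth target mean insert coverage (default 400).
#' @param read_length paired-read length (default 300, MiSeq v3 geometry).
#' @param replicates number of technical replicates (default 2).
#' @param seeds integer seed per replicate.
#' @return object of class `amp_scenario`.
#' @export
scenario <- function(sample_name, fraction = c("cell_pellet", "supernatant",
                                               "stock"),
                     variants, background_variants = NULL, depth = 400L,
                     read_length = 300L, replicates = 2L, seeds = NULL) {
  fraction <- match.arg(fraction)
  if (is.null(variants))
    variants <- data.frame(pos = integer(), alt = character(),
                           freq = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("pos", "alt", "freq") %in% names(variants)))
  if (nrow(variants) && (any(variants$freq <= 0) || any(variants$freq >= 1)))
    stop("variant frequencies must lie in (0, 1)")
  if (is.null(seeds)) seeds <- seq_len(replicates)
  if (length(seeds) != replicates)
    stop("need one seed per replicate")
  structure(list(sample_name = sample_name, fraction = fraction,
                 variants = variants,
                 background_variants = background_variants,
                 depth = depth, read_length = read_length,
                 replicates = replicates, seeds = as.integer(seeds)),
            class = "amp_scenario")
}

#' @export
print.amp_scenario <- function(x, ...) {
  cat(sprintf("<amp_scenario> %s / %s: %d variant(s), depth %dx, 2x%d bp, %d replicate(s)\n",
              x$sample_name, x$fraction, nrow(all_scenario_variants(x)),
              x$depth, x$read_length, x$replicates))
  invisible(x)
}

all_scenario_variants <- function(sc) {
  v <- sc$variants
  if (!is.null(sc$background_variants) && nrow(sc$background_variants))
    v <- rbind(v[, c("pos", "alt", "freq")],
               sc$background_variants[, c("pos", "alt", "freq")])
  v
}

# reference interval affected by a variant (anchor convention)
variant_interval <- function(pos, alt) {
  len <- nchar(alt)
  type <- substr(alt, 1L, 1L)
  if (type == "-") c(pos, pos + len - 1L)        # anchor..last deleted base
  else if (type == "+") c(pos, pos + 1L)         # straddles the junction
  else c(pos, pos)
}

validate_scenario_variants <- function(v, g) {
  if (!nrow(v)) return(invisible(TRUE))
  for (i in seq_len(nrow(v))) {
    alt <- v$alt[i]
    pos <- v$pos[i]
    if (pos < 1L || pos > g$length) stop("variant position outside genome")
    if (substr(alt, 1L, 1L) == "-") {
      del <- substr(alt, 2L, nchar(alt))
      ref <- genome_sub(g, pos + 1L, pos + nchar(del))
      if (ref != del)
        stop(sprintf("deletion allele %s at %d does not match reference (%s)",
                     alt, pos, ref))
    } else if (substr(alt, 1L, 1L) != "+") {
      if (nchar(alt) != 1L || !alt %in% c("A", "C", "G", "T"))
        stop("SNV allele must be a single base: ", alt)
      if (genome_sub(g, pos, pos) == alt)
        stop("SNV allele equals the reference at ", pos)
    }
  }
  # per-position (and overlapping-interval) frequency sums must stay < 1
  iv <- t(vapply(seq_len(nrow(v)),
                 function(i) variant_interval(v$pos[i], v$alt[i]),
                 integer(2)))
  cl <- overlap_clusters(iv)
  sums <- tapply(v$freq, cl, sum)
  if (any(sums >= 1))
    stop("summed frequencies of overlapping variants reach 1")
  invisible(TRUE)
}

# transitive clustering of intervals by overlap
overlap_clusters <- function(iv) {
  n <- nrow(iv)
  if (n == 0L) return(integer())
  o <- order(iv[, 1])
  cl <- integer(n)
  cur <- 0L
  hi <- -Inf
  for (k in o) {
    if (iv[k, 1] > hi) cur <- cur + 1L
    cl[k] <- cur
    hi <- max(hi, iv[k, 2])
  }
  cl
}

# apply a set of variants to the reference substring [astart, aend]
apply_variants_to_window <- function(g, astart, aend, v) {
  s <- genome_sub(g, astart, aend)
  if (!nrow(v)) return(s)
  v <- v[order(v$pos, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    pos <- v$pos[i]
    alt <- v$alt[i]
    type <- substr(alt, 1L, 1L)
    la <- pos - astart + 1L
    if (type == "-") {
      dlen <- nchar(alt) - 1L
      from <- max(la + 1L, 1L)
      to <- min(la + dlen, nchar(s))
      if (from > nchar(s) || to < 1L || from > to) next
      s <- paste0(substr(s, 1L, from - 1L),
                  substr(s, to + 1L, nchar(s)))
    } else if (type == "+") {
      if (la < 0L || la > nchar(s)) next
      ins <- substr(alt, 2L, nchar(alt))
      s <- paste0(substr(s, 1L, la), ins, substr(s, la + 1L, nchar(s)))
    } else {
      if (la < 1L || la > nchar(s)) next
      substr(s, la, la) <- alt
    }
  }
  s
}

# truncated-normal Phred qualities (mean/sd, bounds lo..hi) by rejection
sample_phred <- function(n, mean = 32, sd = 3, lo = 2L, hi = 41L) {
  q <- round(rnorm(n, mean, sd))
  bad <- which(q < lo | q > hi)
  while (length(bad)) {
    q[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[q[bad] < lo | q[bad] > hi]
  }
  as.integer(q)
}

#' Simulate paired-end tiled-amplicon reads
#'
#' Fragments are full amplicons (primer to primer); the read pair is the
#' first and last `read_length` bases of the fragment, so reads start at
#' primer starts as in amplicon sequencing. Per amplicon, fragments are
#' drawn until the mean insert coverage reaches the scenario depth. Each
#' fragment's haplotype is drawn independently; variants whose affected
#' reference intervals overlap are treated as mutually exclusive repair
#' outcomes (one multinomial draw per overlap cluster). Per-base Phred
#' qualities are drawn from a truncated normal (mean 32, sd 3, bounds
#' 2-41) and substitution errors are realized at rate `10^(-Q/10)`;
#' 1 bp indel sequencing errors occur at `indel_error_rate` (default 1e-5).
#' Two technical replicates differ only by their seeds.
#'
#' @param g an `amp_genome`.
#' @param sch an `amp_scheme` from [design_tiling()].
#' @param sc an `amp_scenario`.
#' @param out_dir directory for FASTQ output (created if needed).
#' @param region optional `c(start, end)`: only amplicons whose insert
#'   overlaps this interval are simulated (scales desk runs; geometry per
#'   amplicon is unchanged).
#' @param indel_error_rate per-base 1 bp indel sequencing error rate.
#' @param gzip write gzipped FASTQ.
#' @return list with `fastq` (per replicate: list(r1, r2) paths), `n_pairs`,
#'   `amplicons` (indices simulated), `scenario`.
#' @export
simulate_reads <- function(g, sch, sc, out_dir = tempfile("sim"),
                           region = NULL, indel_error_rate = 1e-5,
                           gzip = FALSE) {
  v <- all_scenario_variants(sc)
  validate_scenario_variants(v, g)
  idx <- seq_len(nrow(sch))
  if (!is.null(region))
    idx <- amplicons_overlapping(sch, region[1], region[2])
  if (!length(idx)) stop("no amplicon insert overlaps the requested region")
  if (nrow(v)) {
    cov_ok <- vapply(seq_len(nrow(v)), function(i) {
      iv <- variant_interval(v$pos[i], v$alt[i])
      any(sch$insert_start[idx] <= iv[1] & sch$insert_end[idx] >= iv[2])
    }, logical(1))
    if (!all(cov_ok))
      warning("variant(s) at ",
              paste(v$pos[!cov_ok], collapse = ", "),
              " fall outside every simulated amplicon insert; undetectable")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rl <- sc$read_length
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  out <- vector("list", sc$replicates)
  n_pairs_total <- 0L
  for (rep_i in seq_len(sc$replicates)) {
    res <- with_seed(sc$seeds[rep_i], {
      simulate_replicate(g, sch, sc, v, idx, rep_i, indel_error_rate)
    })
    tag <- gsub("[^A-Za-z0-9_.+-]", "_", sc$sample_name)
    r1 <- file.path(out_dir, sprintf("%s_%s_rep%d_R1%s", tag, sc$fraction,
                                     rep_i, ext))
    r2 <- file.path(out_dir, sprintf("%s_%s_rep%d_R2%s", tag, sc$fraction,
                                     rep_i, ext))
    write_fastq(res$names, res$seq1, res$qual1, r1)
    write_fastq(res$names, res$seq2, res$qual2, r2)
    out[[rep_i]] <- list(r1 = r1, r2 = r2)
    n_pairs_total <- n_pairs_total + length(res$names)
  }
  list(fastq = out, n_pairs = n_pairs_total, amplicons = idx, scenario = sc)
}

simulate_replicate <- function(g, sch, sc, v, idx, rep_i, indel_error_rate) {
  rl <- sc$read_length
  names_all <- seq1 <- qual1 <- seq2 <- qual2 <- list()
  iv <- if (nrow(v))
    t(vapply(seq_len(nrow(v)),
             function(i) variant_interval(v$pos[i], v$alt[i]), integer(2)))
  else matrix(integer(0), ncol = 2)
  for (a in idx) {
    astart <- sch$start[a]; aend <- sch$end[a]
    ist <- sch$insert_start[a]; ien <- sch$insert_end[a]
    # read bases falling inside the insert, per fragment
    w1 <- max(0L, min(astart + rl - 1L, ien) - max(astart, ist) + 1L)
    w2 <- max(0L, min(aend, ien) - max(aend - rl + 1L, ist) + 1L)
    per_frag <- w1 + w2
    if (per_frag <= 0L) next
    n_frag <- ceiling(sc$depth * (ien - ist + 1L) / per_frag)
    # variants touching this amplicon
    touch <- which(iv[, 1] <= aend & iv[, 2] >= astart)
    assign_mat <- matrix(FALSE, nrow = n_frag, ncol = nrow(v))
    if (length(touch)) {
      cl <- overlap_clusters(iv[touch, , drop = FALSE])
      for (cid in unique(cl)) {
        mem <- touch[cl == cid]
        p <- c(1 - sum(v$freq[mem]), v$freq[mem])
        draw <- sample.int(length(mem) + 1L, n_frag, replace = TRUE,
                           prob = p) - 1L
        for (j in seq_along(mem))
          assign_mat[draw == j, mem[j]] <- TRUE
      }
    }
    key <- if (ncol(assign_mat))
      apply(assign_mat, 1L, function(z) paste(which(z), collapse = ","))
    else rep("", n_frag)
    frag_seq <- character(n_frag)
    for (k in unique(key)) {
      sel <- if (nzchar(k)) as.integer(strsplit(k, ",")[[1]]) else integer()
      h <- apply_variants_to_window(g, astart, aend,
                                    v[sel, , drop = FALSE])
      frag_seq[key == k] <- h
    }
    flen <- nchar(frag_seq)
    s1 <- substr(frag_seq, 1L, pmin(rl, flen))
    s2 <- revcomp_vec(substr(frag_seq, pmax(1L, flen - rl + 1L), flen))
    nm <- sprintf("%s_rep%d_%s_%06d", gsub("[^A-Za-z0-9+._-]", "_",
                                           sc$sample_name),
                  rep_i, sch$name[a], seq_len(n_frag))
    names_all[[length(names_all) + 1L]] <- nm
    seq1[[length(seq1) + 1L]] <- s1
    seq2[[length(seq2) + 1L]] <- s2
  }
  names_all <- unlist(names_all) %||% character()
  seq1 <- unlist(seq1) %||% character()
  seq2 <- unlist(seq2) %||% character()
  # qualities + substitution errors, vectorised over all bases
  noisy <- function(seqs) {
    lens <- nchar(seqs)
    total <- sum(lens)
    q <- sample_phred(total)
    err <- runif(total) < 10^(-q / 10)
    chars <- strsplit(paste0(seqs, collapse = ""), "")[[1]]
    if (any(err)) {
      alt <- c("A", "C", "G", "T")
      repl <- sample(alt, sum(err), replace = TRUE)
      same <- repl == chars[err]
      while (any(same)) {
        repl[same] <- sample(alt, sum(same), replace = TRUE)
        same <- repl == chars[err]
      }
      chars[err] <- repl
    }
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs_out <- substring(paste0(chars, collapse = ""), starts, ends)
    qstr <- vapply(seq_along(lens), function(i)
      phred_to_char(q[starts[i]:ends[i]]), "")
    list(seq = seqs_out, qual = qstr)
  }
  n1 <- noisy(seq1); n2 <- noisy(seq2)
  out <- list(names = names_all, seq1 = n1$seq, qual1 = n1$qual,
              seq2 = n2$seq, qual2 = n2$qual)
  # sparse 1 bp indel sequencing errors
  if (indel_error_rate > 0 && length(names_all)) {
    for (mate in 1:2) {
      sq <- out[[if (mate == 1) "seq1" else "seq2"]]
      ql <- out[[if (mate == 1) "qual1" else "qual2"]]
      total <- sum(nchar(sq))
      n_ev <- rbinom(1L, total, indel_error_rate)
      if (n_ev > 0) {
        for (e in seq_len(n_ev)) {
          i <- sample.int(length(sq), 1L)
          p <- sample.int(max(nchar(sq[i]) - 1L, 1L), 1L)
          if (runif(1) < 0.5) { # deletion of one base
            sq[i] <- paste0(substr(sq[i], 1L, p - 1L),
                            substr(sq[i], p + 1L, nchar(sq[i])))
            ql[i] <- paste0(substr(ql[i], 1L, p - 1L),
                            substr(ql[i], p + 1L, nchar(ql[i])))
          } else {            # insertion of one random base
            b <- sample(c("A", "C", "G", "T"), 1L)
            sq[i] <- paste0(substr(sq[i], 1L, p), b,
                            substr(sq[i], p + 1L, nchar(sq[i])))
            ql[i] <- paste0(substr(ql[i], 1L, p),
                            phred_to_char(sample_phred(1L)),
                            substr(ql[i], p + 1L, nchar(ql[i])))
          }
        }
        out[[if (mate == 1) "seq1" else "seq2"]] <- sq
        out[[if (mate == 1) "qual1" else "qual2"]] <- ql
      }
    }
  }
  out
}

write_fastq <- function(names, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(name = sub("\\s.*$", "", names(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}
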