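# Banded alignment, amplicon assignment, indel left-normalization, SAM IO.

test_that("a read equal to a reference substring aligns all-M at its origin", {
  g <- random_genome(2000L, 3L)
  rd <- substr(g$sequence, 501, 700)
  a <- align_read(rd, g, c(401, 900), 501L)
  expect_equal(a$pos, 501L)
  expect_equal(a$cigar, "200M")
  expect_equal(a$score, 2 * 200)
})

test_that("a read carrying the 2 bp gp64 deletion yields a 2D CIGAR there", {
  ref <- fixture_ref()
  g <- ref$genome
  # haplotype read spanning 106935 [-CA]: delete 106936-106937
  left <- substr(g$sequence, 106850, 106935)
  right <- substr(g$sequence, 106938, 107023)
  rd <- paste0(left, right)
  a <- align_read(rd, g, c(106800, 107100), 106850L)
  a <- list(pos = a$pos, cigar = a$cigar)
  expect_equal(a$pos, 106850L)
  expect_equal(a$cigar, "86M2D86M")
})

test_that("banded scores equal an independent affine aligner on random instances", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(42)
  n_cases <- 120L
  for (i in seq_len(n_cases)) {
    win <- paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    st <- sample(1:150, 1)
    rd <- substr(win, st, min(st + 39, 200))
    # random small edit: deletion, insertion or substitutions
    kind <- sample(3, 1)
    if (kind == 1 && nchar(rd) > 20) {
      p <- sample(5:(nchar(rd) - 10), 1)
      l <- sample(1:5, 1)
      rd <- paste0(substr(rd, 1, p), substr(rd, p + l + 1, nchar(rd)))
    } else if (kind == 2) {
      p <- sample(5:(nchar(rd) - 5), 1)
      ins <- paste0(sample(c("A", "C", "G", "T"), sample(1:4, 1), TRUE),
                    collapse = "")
      rd <- paste0(substr(rd, 1, p), ins, substr(rd, p + 1, nchar(rd)))
    } else {
      for (k in sample(nchar(rd), 2))
        substr(rd, k, k) <- sample(c("A", "C", "G", "T"), 1)
    }
    g <- genome("w", win)
    a <- align_read(rd, g, c(1, 200), st, band = 16L)
    pa <- Biostrings::pairwiseAlignment(
      rd, win, type = "global-local", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1)
    expect_equal(a$score, Biostrings::score(pa))
  }
})

test_that("left-normalization shifts homopolymer deletions maximally 5'-ward", {
  # reference with an A4 homopolymer; a 1 bp deletion placed at the 3' A
  # must move to the 5'-most placement
  g <- genome("h", "CCGTTAAAAGCTTGGCCATG")
  alns <- data.frame(qname = "r", flag = 0L, rname = "h", pos = 3L,
                     mapq = 60L, cigar = "6M1D10M", rnext = "*",
                     pnext = 0L, tlen = 0L,
                     seq = "GTTAAAGCTTGGCCAT", qual = strrep("I", 16),
                     amplicon = NA_integer_, stringsAsFactors = FALSE)
  # 6M consumes ref 3-8 (GTTAAA), D deletes ref 9 (the last A)
  out <- left_normalize_indels(alns, g)
  expect_equal(out$pos, 3L)
  expect_equal(out$cigar, "3M1D13M")  # deletion now at the 5'-most A (ref 6)
  # equivalence oracle: every placement of the deletion reconstructs the
  # same read; the normalizer must pick the leftmost
  for (shift in 0:3) {
    alt <- alns
    alt$cigar <- sprintf("%dM1D%dM", 3L + shift, 13L - shift)
    expect_equal(left_normalize_indels(alt, g)$cigar, "3M1D13M")
  }
  # idempotence
  expect_equal(left_normalize_indels(out, g)$cigar, out$cigar)
  # no-indel records are untouched
  plain <- alns; plain$cigar <- "16M"
  expect_identical(left_normalize_indels(plain, g), plain)
})

test_that("insertion left-normalization preserves the read and is idempotent", {
  g <- genome("h", "CCGTTAAAAGCTTGG")
  # read with an extra A inserted in the A-run, reported at the 3' end
  alns <- data.frame(qname = "r", flag = 0L, rname = "h", pos = 3L,
                     mapq = 60L, cigar = "7M1I6M", rnext = "*", pnext = 0L,
                     tlen = 0L, seq = "GTTAAAAAGCTTGG",
                     qual = strrep("I", 14), amplicon = NA_integer_,
                     stringsAsFactors = FALSE)
  out <- left_normalize_indels(alns, g)
  p <- ampedit:::parse_cigar(out$cigar)
  # insertion sits immediately after the last M before the A-run
  expect_equal(p$ops, c("M", "I", "M"))
  expect_equal(p$lens[1], 3L)
  expect_equal(left_normalize_indels(out, g)$cigar, out$cigar)
})

test_that("the nested deletion series left-normalizes onto distinct anchors", {
  ref <- fixture_ref()
  g <- ref$genome
  # all five alleles end at reference position 107204 (anchor + len)
  for (v in list(c(107199L, 5L), c(107200L, 4L), c(107201L, 3L),
                 c(107202L, 2L), c(107204L, 1L))) {
    anchor <- v[1]; dlen <- v[2]
    expect_equal(anchor + dlen,
                 if (anchor == 107204L) 107205L else 107204L)
    rd <- paste0(substr(g$sequence, anchor - 60L, anchor),
                 substr(g$sequence, anchor + dlen + 1L, anchor + dlen + 60L))
    a <- align_read(rd, g, c(anchor - 120L, anchor + 120L), anchor - 60L,
                    band = 16L)
    alns <- data.frame(qname = "r", flag = 0L, rname = g$id, pos = a$pos,
                       mapq = 60L, cigar = a$cigar, rnext = "*",
                       pnext = 0L, tlen = 0L, seq = rd,
                       qual = strrep("I", nchar(rd)),
                       amplicon = NA_integer_, stringsAsFactors = FALSE)
    out <- left_normalize_indels(alns, g)
    p <- ampedit:::parse_cigar(out$cigar)
    di <- which(p$ops == "D")
    expect_length(di, 1L)
    expect_equal(p$lens[di], dlen)
    # reported anchor = pos + preceding M - 1
    expect_equal(out$pos + p$lens[1] - 1L, anchor)
  }
})

test_that("simulated pairs assign and align back to their amplicon of origin", {
  ref <- fixture_ref()
  sch <- fixture_scheme()
  sc <- scenario("rt", "cell_pellet", NULL, depth = 40L, seeds = c(3L, 4L))
  sim <- simulate_reads(ref$genome, sch, sc, tempfile(),
                        region = c(106300, 107400), indel_error_rate = 0)
  f1 <- read_fastq(sim$fastq[[1]]$r1)
  f2 <- read_fastq(sim$fastq[[1]]$r2)
  pairs <- data.frame(name = f1$name, seq1 = f1$seq, qual1 = f1$qual,
                      seq2 = f2$seq, qual2 = f2$qual,
                      stringsAsFactors = FALSE)
  asg <- assign_amplicon(pairs, sch, ref$genome)
  truth <- as.integer(sub("^rt_rep1_amp_(\\d+)_.*$", "\\1", pairs$name))
  ok <- !is.na(asg$amplicon) & asg$amplicon == truth
  expect_gt(mean(ok), 0.99)
  alns <- align_pairs(pairs, ref$genome, sch, band = 16L)
  mapped <- alns[bitwAnd(alns$flag, 4L) == 0L, ]
  starts_ok <- mapped$pos %in% c(sch$start, sch$end - 300L + 1L)
  expect_gt(mean(starts_ok), 0.99)
})

test_that("pairs matching no primer or duplicated primers are unassigned", {
  ref <- fixture_ref()
  sch <- fixture_scheme()
  g <- ref$genome
  junk <- strrep("ACGT", 75)
  pairs <- data.frame(name = "x", seq1 = junk, qual1 = strrep("I", 300),
                      seq2 = junk, qual2 = strrep("I", 300),
                      stringsAsFactors = FALSE)
  asg <- assign_amplicon(pairs, sch, g)
  expect_true(is.na(asg$amplicon))
  expect_false(asg$ambiguous)
  # engineered duplicate-primer scheme forces ambiguity
  sch2 <- sch[1:2, ]
  attr(sch2, "ref_id") <- attr(sch, "ref_id")
  attr(sch2, "primer_len") <- attr(sch, "primer_len")
  class(sch2) <- class(sch)
  sch2$left_start[2] <- sch2$left_start[1]
  sch2$left_end[2] <- sch2$left_end[1]
  sch2$right_start[2] <- sch2$right_start[1]
  sch2$right_end[2] <- sch2$right_end[1]
  r1 <- substr(g$sequence, sch$left_start[1], sch$left_start[1] + 299L)
  r2 <- revcomp(substr(g$sequence, sch$right_end[1] - 299L,
                       sch$right_end[1]))
  dup_pairs <- data.frame(name = "d", seq1 = r1, qual1 = strrep("I", 300),
                          seq2 = r2, qual2 = strrep("I", 300),
                          stringsAsFactors = FALSE)
  asg2 <- assign_amplicon(dup_pairs, sch2, g)
  expect_true(is.na(asg2$amplicon))
  expect_true(asg2$ambiguous)
})

test_that("SAM emit/parse round-trips byte-stably and flags encode state", {
  ref <- fixture_ref()
  sch <- fixture_scheme()
  g <- ref$genome
  r1 <- substr(g$sequence, sch$left_start[5], sch$left_start[5] + 299L)
  r2 <- revcomp(substr(g$sequence, sch$right_end[5] - 299L,
                       sch$right_end[5]))
  pairs <- data.frame(
    name = c("m", "u"), seq1 = c(r1, strrep("ACGT", 75)),
    qual1 = strrep("I", 300), seq2 = c(r2, strrep("TGCA", 75)),
    qual2 = strrep("I", 300), stringsAsFactors = FALSE)
  alns <- align_pairs(pairs, g, sch, band = 16L)
  mapped <- alns[alns$qname == "m", ]
  expect_true(all(bitwAnd(mapped$flag, 4L + 256L + 2048L) == 0L))
  unmapped <- alns[alns$qname == "u", ]
  expect_true(all(bitwAnd(unmapped$flag, 4L) != 0L))
  lines1 <- emit_sam(alns, g)
  back <- parse_sam(lines1)
  lines2 <- emit_sam(back, g)
  expect_identical(lines1, lines2)
  expect_equal(back$pos, alns$pos)
  expect_equal(back$cigar, alns$cigar)
})
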