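# Pileup construction, the Fisher error model and variant calling.

mk_reads <- function(g, pos, n, len = 250L, mutate = NULL, amplicon = NA_integer_) {
  seqs <- rep(substr(g$sequence, pos, pos + len - 1L), n)
  if (!is.null(mutate)) for (m in mutate) seqs[m$i] <- m$seq
  data.frame(qname = sprintf("r%03d", seq_len(n)), flag = 0L, rname = g$id,
             pos = pos, mapq = 60L,
             cigar = ifelse(nchar(seqs) == len, paste0(len, "M"),
                            vapply(seqs, function(s)
                              paste0(nchar(s), "M"), "")),
             rnext = "*", pnext = 0L, tlen = 0L, seq = seqs,
             qual = vapply(seqs, function(s) strrep("I", nchar(s)), ""),
             amplicon = amplicon, stringsAsFactors = FALSE)
}

test_that("identical error-free reads give a pure reference pileup", {
  g <- random_genome(1000L, 51L)
  alns <- mk_reads(g, 101L, 10L)
  pu <- build_pileup(alns, g)
  expect_true(all(pu$cov == 10L))
  tab <- call_variants(pu)
  expect_equal(nrow(tab), 0L)
})

test_that("a deletion registers its allele at the anchor with spanning depth", {
  g <- random_genome(1000L, 52L)
  # 1 of 20 reads carries a 2 bp deletion after position 300
  del_read <- paste0(substr(g$sequence, 101L, 300L),
                     substr(g$sequence, 303L, 352L))
  alns <- mk_reads(g, 101L, 20L)
  alns$seq[1] <- del_read
  alns$cigar[1] <- "200M2D50M"
  pu <- build_pileup(alns, g)
  k <- which(pu$indel$pos == 300L)
  expect_equal(pu$indel$allele[k],
               paste0("-", substr(g$sequence, 301L, 302L)))
  expect_equal(pu$indel$count[k], 1L)
  # deletion-spanning reads keep the physical depth at deleted positions
  expect_equal(pu$cov[301L - pu$wstart + 1L], 20L)
  tab <- call_variants(pu)
  row <- tab[tab$POS == 300L, ]
  expect_equal(row$ALT_DP, 1L)
  expect_equal(row$TOTAL_DP, 20L)
  expect_equal(row$ALT_FREQ, 0.05)
})

test_that("an insertion registers +SEQ at the preceding aligned base", {
  g <- random_genome(600L, 53L)
  ins_read <- paste0(substr(g$sequence, 101L, 250L), "GATC",
                     substr(g$sequence, 251L, 346L))
  alns <- mk_reads(g, 101L, 10L)
  alns$seq[1] <- ins_read
  alns$cigar[1] <- "150M4I96M"
  pu <- build_pileup(alns, g)
  k <- which(pu$indel$allele == "+GATC")
  expect_equal(pu$indel$pos[k], 250L)
})

test_that("error-model p-values match the hypergeometric tail oracle", {
  # exhaustive sweep over totals and alt counts at a fixed mean quality
  for (total in c(1:40, seq(45, 200, by = 5))) {
    for (alt in 0:total) {
      q <- 20
      e <- max(0L, as.integer(floor(total * 10^(-q / 10) + 0.5)))
      expect_equal(fisher_error_test(alt, total, q),
                   fisher_tail_oracle(alt, total, e), tolerance = 1e-9)
    }
  }
  # and at other qualities for a coarser grid
  for (q in c(13, 30, 41)) {
    for (total in c(10L, 88L, 200L)) {
      for (alt in unique(c(0L, 1L, 5L, total %/% 3L, total))) {
        e <- max(0L, as.integer(floor(total * 10^(-q / 10) + 0.5)))
        expect_equal(fisher_error_test(alt, total, q),
                     fisher_tail_oracle(alt, total, e), tolerance = 1e-9)
      }
    }
  }
})

test_that("the error model behaves: monotone in support, sensitive to quality", {
  expect_equal(fisher_error_test(0L, 400L, 30), 1.0)
  p5 <- fisher_error_test(5L, 400L, 30)
  p10 <- fisher_error_test(10L, 400L, 30)
  expect_gte(p5, p10)
  # high-quality low-frequency variants pass; Q~13 noise at 1-2% fails
  expect_lte(fisher_error_test(18L, 400L, 30), 0.05)
  expect_gt(fisher_error_test(6L, 400L, 13), 0.05)
  expect_error(fisher_error_test(1L, 0L, 30), "positive")
})

test_that("expected error count uses round-half-up with a floor at zero", {
  # total 400, q 30 -> E = round(0.4) = 0; q ~26.99 -> E = round(0.8) = 1
  # the boundary x.5 rounds up: total 500, q 30 -> E = round(0.5) = 1
  ft <- function(alt, total, q) fisher_error_test(alt, total, q)
  expect_equal(ft(5L, 400L, 30), fisher_tail_oracle(5L, 400L, 0L))
  expect_equal(ft(5L, 500L, 30), fisher_tail_oracle(5L, 500L, 1L))
  expect_false(isTRUE(all.equal(fisher_tail_oracle(5L, 500L, 0L),
                                fisher_tail_oracle(5L, 500L, 1L))))
})

test_that("alleles below 1% or under the base-quality gate are not called", {
  g <- random_genome(800L, 54L)
  alns <- mk_reads(g, 101L, 250L)
  # 2 of 250 reads (0.8%) carry a high-quality SNV at offset 50
  for (i in 1:2) {
    s <- alns$seq[i]
    b <- substr(s, 51L, 51L)
    nb <- setdiff(c("A", "C", "G", "T"), b)[1]
    substr(s, 51L, 51L) <- nb
    alns$seq[i] <- s
  }
  pu <- build_pileup(alns, g)
  tab <- call_variants(pu)
  expect_false(any(tab$POS == 151L))
  # same SNV in 5 reads (2%) but at Phred 15: excluded from support
  alns2 <- mk_reads(g, 101L, 250L)
  for (i in 1:5) {
    s <- alns2$seq[i]
    substr(s, 51L, 51L) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, 51L, 51L))[1]
    alns2$seq[i] <- s
    q <- alns2$qual[i]
    substr(q, 51L, 51L) <- "0"  # Phred 15
    alns2$qual[i] <- q
  }
  pu2 <- build_pileup(alns2, g)
  tab2 <- call_variants(pu2)
  expect_false(any(tab2$POS == 151L))
})

test_that("variant tables round-trip through the TSV dialect", {
  ref <- fixture_ref()
  tab <- scenario_variant_table(
    ref$genome, data.frame(pos = c(107222L, 3960L),
                           alt = c("-C", "T"), freq = c(0.0662, 0.05)),
    sample = "s1", fraction = "cell_pellet")
  p <- tempfile(fileext = ".tsv")
  write_variant_tsv(tab, p)
  back <- read_variant_tsv(p, sample = "s1", fraction = "cell_pellet")
  expect_equal(back$POS, tab$POS)
  expect_equal(back$ALT, tab$ALT)
  expect_equal(back$ALT_FREQ, tab$ALT_FREQ, tolerance = 1e-12)
  expect_equal(back$PASS, tab$PASS)
  expect_true(all(c("REGION", "POS", "REF", "ALT", "REF_DP", "REF_QUAL",
                    "ALT_DP", "ALT_QUAL", "ALT_FREQ", "TOTAL_DP", "PVAL",
                    "PASS") %in% names(back)))
})
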