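# Fixture genome, tiling scheme and read simulator.

test_that("fixture genome anchors the declared edit-window coordinates", {
  ref <- fixture_ref()
  w <- fixture_windows()
  expect_equal(w$start[w$name == "gp64+131"], 107222L)
  expect_equal(w$end[w$name == "gp64+131"], 107227L)
  # offset arithmetic between window starts follows the naming offsets
  s131 <- w$start[w$name == "gp64+131"]
  for (lab in c(278L, 378L, 384L, 418L)) {
    sX <- w$start[w$name == sprintf("gp64+%d", lab)]
    expect_equal(s131 - sX, lab - 131L)
  }
  # the two dual-target protospacers sit 287 bp apart (418 - 131)
  g <- ref$genome
  s1 <- locate_protospacer(g, as.list(ref$targets[ref$targets$name ==
                                                    "gp64+131", ]))
  s2 <- locate_protospacer(g, as.list(ref$targets[ref$targets$name ==
                                                    "gp64+418", ]))
  expect_equal(s1$proto_start - s2$proto_start, 287L)
})

test_that("every planted protospacer occurs exactly once with its PAM", {
  ref <- fixture_ref()
  tg <- ref$targets[ref$targets$role == "target", ]
  for (i in seq_len(nrow(tg))) {
    site <- locate_protospacer(ref$genome, as.list(tg[i, ]))
    expect_equal(site$proto_end - site$proto_start + 1L, 20L)
  }
  # the scrambled control spacer is absent
  expect_error(
    locate_protospacer(ref$genome,
                       list(name = "scrambled",
                            spacer = ref$targets$spacer[1], pam = "NGG")),
    "not found")
})

test_that("hr arrays are AT-rich tandem repeats and can be disabled", {
  ref <- fixture_ref()
  hr <- ref$annotation[ref$annotation$class == "hr", ]
  expect_equal(nrow(hr), 9L)
  for (i in seq_len(nrow(hr))) {
    s <- substr(ref$genome$sequence, hr$start[i], hr$end[i])
    at <- mean(strsplit(s, "")[[1]] %in% c("A", "T"))
    expect_gte(at, 0.6)
  }
  # long arrays are >= 150 bp, short ones 18-30 bp
  len <- hr$end - hr$start + 1L
  expect_true(all(len >= 150 | (len >= 18 & len <= 30)))
  ref0 <- build_reference(list(hr = data.frame(
    name = character(), start = integer(), unit_len = integer(),
    copies = integer(), stringsAsFactors = FALSE)))
  expect_false(any(ref0$annotation$class == "hr"))
})

test_that("annotated features are fully covered by amplicon inserts", {
  ref <- fixture_ref()
  sch <- fixture_scheme()
  covered <- rep(FALSE, ref$genome$length)
  for (i in seq_len(nrow(sch)))
    covered[sch$insert_start[i]:sch$insert_end[i]] <- TRUE
  ann <- ref$annotation
  for (i in seq_len(nrow(ann)))
    expect_true(all(covered[ann$start[i]:ann$end[i]]),
                info = ann$label[i])
})

test_that("tiling arithmetic: counts, pools, overlap, degenerate cases", {
  g <- random_genome(5000L, 7L)
  sch <- design_tiling(g, 1000L, 100L, 22L)
  expect_equal(nrow(sch), 6L)
  expect_equal(sch$pool, c(1L, 2L, 1L, 2L, 1L, 2L))
  expect_true(all(sch$start[-1] - sch$start[-nrow(sch)] <= 900L))
  # every position covered outside the terminal primers
  covered <- rep(FALSE, 5000L)
  for (i in seq_len(nrow(sch)))
    covered[sch$insert_start[i]:sch$insert_end[i]] <- TRUE
  expect_true(all(covered[23:(5000 - 22)]))
  # single amplicon when the genome is shorter than one amplicon
  g2 <- random_genome(700L, 8L)
  sch2 <- design_tiling(g2, 1000L, 100L, 22L)
  expect_equal(nrow(sch2), 1L)
  expect_equal(c(sch2$start, sch2$end), c(1L, 700L))
  # zero overlap: consecutive amplicons abut with no shared positions
  sch3 <- design_tiling(g, 1000L, 0L, 22L)
  expect_equal(nrow(sch3), 5L)
  expect_true(all(sch3$start[-1] == sch3$end[-nrow(sch3)] + 1L))
})

test_that("simulation is deterministic and byte-identical given seeds", {
  ref <- fixture_ref()
  sch <- fixture_scheme()
  sc <- deletion_scenario(106975L, "-T", 0.05, depth = 60L)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_reads(ref$genome, sch, sc, d1, region = c(106975, 106976))
  s2 <- simulate_reads(ref$genome, sch, sc, d2, region = c(106975, 106976))
  for (r in 1:2) {
    expect_identical(readLines(s1$fastq[[r]]$r1),
                     readLines(s2$fastq[[r]]$r1))
    expect_identical(readLines(s1$fastq[[r]]$r2),
                     readLines(s2$fastq[[r]]$r2))
  }
  # the two replicates themselves differ (different seeds)
  expect_false(identical(readLines(s1$fastq[[1]]$r1),
                         readLines(s1$fastq[[2]]$r1)))
})

test_that("spiked haplotype fraction matches the scenario frequency", {
  ref <- fixture_ref()
  sch <- fixture_scheme()
  f <- 0.0451
  sc <- deletion_scenario(106975L, "-T", f, depth = 400L)
  sim <- simulate_reads(ref$genome, sch, sc, tempfile(),
                        region = c(106975, 106976), indel_error_rate = 0)
  fq <- read_fastq(sim$fastq[[1]]$r2)
  # R2 reads span the deletion; a deletion read is 1 bp short of the
  # amplicon tail and lacks the deleted base in context
  n <- length(fq$seq)
  ref_ctx <- substr(ref$genome$sequence, 106970, 106981)
  ref_ctx_del <- paste0(substr(ref_ctx, 1, 6), substr(ref_ctx, 8, 12))
  carries <- grepl(revcomp(ref_ctx_del), fq$seq, fixed = TRUE)
  phat <- mean(carries)
  se <- sqrt(f * (1 - f) / n)
  expect_lt(abs(phat - f), 4 * se + 1e-3)
})

test_that("error-free, variant-free reads are reference substrings", {
  g <- random_genome(3000L, 21L)
  sch <- design_tiling(g)
  sc <- scenario("clean", "cell_pellet", NULL, depth = 20L,
                 read_length = 300L, seeds = c(5L, 6L))
  sim <- simulate_reads(g, sch, sc, tempfile(), indel_error_rate = 0)
  # reads start at primer starts; at the simulator's quality model the
  # per-base substitution rate is ~6e-4, so most reads are exact
  # reference substrings
  fq <- read_fastq(sim$fastq[[1]]$r1)
  starts <- substr(fq$seq, 1, 8)
  lefts <- substring(g$sequence, sch$left_start, sch$left_start + 7L)
  expect_gt(mean(starts %in% lefts), 0.97)
  exact <- vapply(fq$seq, function(s)
    grepl(s, g$sequence, fixed = TRUE), TRUE, USE.NAMES = FALSE)
  expect_gt(mean(exact), 0.75)
})

test_that("mean insert coverage reaches the scenario depth", {
  g <- random_genome(2000L, 31L)
  sch <- design_tiling(g)  # two amplicons
  sc <- scenario("cov", "cell_pellet", NULL, depth = 50L,
                 read_length = 300L, seeds = c(1L, 2L), replicates = 2L)
  sim <- simulate_reads(g, sch, sc, tempfile(), indel_error_rate = 0)
  fq1 <- read_fastq(sim$fastq[[1]]$r1)
  fq2 <- read_fastq(sim$fastq[[1]]$r2)
  # accounting oracle: fragments per amplicon x read bases inside insert
  # divided by insert length must be >= depth (and close to it)
  for (a in seq_len(nrow(sch))) {
    nfrag <- sum(startsWith(fq1$name, paste0("cov_rep1_", sch$name[a])))
    ins <- sch$insert_end[a] - sch$insert_start[a] + 1L
    rl <- 300L; pl <- 22L
    per_frag <- min(rl - pl, ins) + min(rl - pl, ins)
    mean_cov <- nfrag * per_frag / ins
    expect_gte(mean_cov, 50)
    expect_lt(mean_cov, 50 * 1.1 + 1)
  }
})

test_that("scenario fixtures encode the bundled deletion tables", {
  scs <- deletion_scenarios()
  sup160 <- scs[["gp64-160.supernatant"]]
  expect_equal(nrow(sup160$variants), 5L)
  expect_true(all(startsWith(sup160$variants$alt, "-")))
  cp418 <- scs[["gp64+418.cell_pellet"]]
  expect_equal(cp418$variants$pos, 106935L)
  expect_equal(cp418$variants$alt, "-CA")
  expect_equal(cp418$variants$freq, 0.0424)
  # stock: 141 variants, 97 flagged as carried over
  st <- stock_scenario(fixture_ref())
  expect_equal(nrow(st$variants), 141L)
  expect_equal(sum(st$conserved), 97L)
})

test_that("scenario YAML round-trips and invalid scenarios are rejected", {
  sc <- deletion_scenario(106975L, "-T", 0.0451)
  p <- tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, p)
  sc2 <- read_scenario_yaml(p)
  expect_equal(sc2$variants, sc$variants)
  expect_equal(sc2$seeds, sc$seeds)
  expect_error(scenario("x", "cell_pellet",
                        data.frame(pos = 1L, alt = "A", freq = 1.2)),
               "frequencies")
  ref <- fixture_ref()
  sch <- fixture_scheme()
  bad <- scenario("x", "cell_pellet",
                  data.frame(pos = c(107202L, 107203L),
                             alt = c("-CA", "-AT"), freq = c(0.6, 0.5)))
  expect_error(
    simulate_reads(ref$genome, sch, bad, tempfile(),
                   region = c(107200, 107206)),
    "frequencies|reference")
})

test_that("bundled scenario writer emits every cell plus controls/stock", {
  d <- tempfile()
  paths <- write_bundled_scenarios(d, fixture_ref())
  expect_length(paths, 10L)  # 7 deletion cells + 2 controls + stock
  expect_true(all(file.exists(paths)))
  back <- read_scenario_yaml(paths[["gp64-160.supernatant"]])
  expect_equal(nrow(back$variants), 5L)
})
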