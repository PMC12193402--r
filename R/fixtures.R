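# Scenario fixtures: the bundled sample x fraction deletion-recovery cells with
# their observed deletion alleles and frequencies, plus the virus-stock
# variant set used by the passage-conservation analyses.

deletion_cell_defs <- function() {
  list(
    list(sample = "gp64+131", fraction = "cell_pellet",
         variants = data.frame(pos = 107222L, alt = "-C", freq = 0.0662)),
    list(sample = "gp64-160", fraction = "cell_pellet",
         variants = data.frame(pos = c(107201L, 107202L),
                               alt = c("-CCA", "-CA"),
                               freq = c(0.0630, 0.0847))),
    list(sample = "gp64-160", fraction = "supernatant",
         variants = data.frame(pos = c(107199L, 107200L, 107201L, 107202L,
                                       107204L),
                               alt = c("-CTCCA", "-TCCA", "-CCA", "-CA",
                                       "-C"),
                               freq = c(0.0305, 0.0348, 0.0544, 0.0634,
                                        0.0143))),
    list(sample = "gp64+378", fraction = "cell_pellet",
         variants = data.frame(pos = 106975L, alt = "-T", freq = 0.0451)),
    list(sample = "gp64+378", fraction = "supernatant",
         variants = data.frame(pos = 106975L, alt = "-T", freq = 0.0404)),
    list(sample = "gp64+418", fraction = "cell_pellet",
         variants = data.frame(pos = 106935L, alt = "-CA", freq = 0.0424)),
    list(sample = "gp64+418", fraction = "supernatant",
         variants = data.frame(pos = 106935L, alt = "-CA", freq = 0.0217))
  )
}

#' Deletion-recovery scenarios
#'
#' One scenario per sample x fraction cell in which an on-target deletion
#' was observed: the spiked positions, anchor-convention deletion alleles
#' and true haplotype frequencies, at 400x in technical duplicate. Replicate
#' seeds are `seed_base + 2*(cell - 1) + 0:1`.
#'
#' @param seed_base integer; offsets the per-replicate seeds.
#' @return named list of `amp_scenario` objects.
#' @export
deletion_scenarios <- function(seed_base = 1000L) {
  defs <- deletion_cell_defs()
  out <- lapply(seq_along(defs), function(i) {
    d <- defs[[i]]
    scenario(d$sample, d$fraction, d$variants,
             seeds = seed_base + 2L * (i - 1L) + 0:1)
  })
  names(out) <- vapply(defs, function(d)
    paste(d$sample, d$fraction, sep = "."), "")
  out
}

#' Null (control) scenarios
#'
#' Scrambled and infected-only controls: no spiked gp64 variants.
#' @param seed_base integer seed offset.
#' @export
control_scenarios <- function(seed_base = 5000L) {
  list(
    scrambled = scenario("scrambled", "cell_pellet", NULL,
                         seeds = seed_base + 0:1),
    infected_only = scenario("infected_only", "cell_pellet", NULL,
                             seeds = seed_base + 10:11)
  )
}

# The conserved variants observed outside the hrs: region, type, reference
# and variant alleles, and position (anchor convention for indels).
conserved_offhr_variants <- function() {
  data.frame(
    pos = c(71443L, 27502L, 27505L, 27506L, 27509L, 3960L, 6375L, 45761L,
            78627L, 78666L, 7304L, 44073L, 12427L, 78926L),
    alt = c("T", "G", "A", "A", "A", "T", "A", "A", "A", "T",
            "+GATC", "+A", "-CTAGAGATCTCTAGAGATCT", "-TAT"),
    stringsAsFactors = FALSE)
}

#' Virus-stock variant fixture
#'
#' A deterministic stock variant set: 141 variants, of which 97 are flagged
#' as carried over into the transfection-infection (T-I) passage. The
#' carried-over set comprises 83 variants inside the three long hr arrays
#' (hr1-hr3, including one 19 bp deletion in hr2) and the 14 conserved
#' variants outside the hrs; the 44 stock-unique variants sit mostly in the
#' same hrs with a minority elsewhere in the genome.
#'
#' @param ref a fixture from [build_reference()].
#' @param seed RNG seed.
#' @return data.frame `pos`, `alt`, `freq`, `conserved`.
#' @export
build_stock_fixture <- function(ref, seed = 777L) {
  g <- ref$genome
  ann <- ref$annotation
  hr <- ann[ann$class == "hr" & ann$label %in% c("hr1", "hr2", "hr3"), ]
  with_seed(seed, {
    snv_at <- function(pos) {
      refb <- substring(g$sequence, pos, pos)
      vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "",
        USE.NAMES = FALSE)
    }
    used <- integer()
    pick <- function(label, n, pad = 0L) {
      h <- hr[hr$label == label, ]
      avail <- setdiff(seq(h$start + pad, h$end - pad), used)
      sample(avail, n)
    }
    take <- function(pos) { used <<- c(used, pos); pos }

    # conserved hr variants: 36 + 27 + 20 = 83, one hr2 slot being a
    # 19 bp deletion
    p1 <- take(pick("hr1", 36L))
    p2 <- take(pick("hr2", 27L, pad = 25L))
    p3 <- take(pick("hr3", 20L))
    del_anchor <- p2[1]
    del_seq <- substring(g$sequence, del_anchor + 1L, del_anchor + 19L)
    cons_hr <- data.frame(
      pos = c(p1, p2[-1], p3, del_anchor),
      alt = c(snv_at(p1), snv_at(p2[-1]), snv_at(p3),
              paste0("-", del_seq)),
      stringsAsFactors = FALSE)
    t2 <- conserved_offhr_variants()
    conserved <- rbind(cons_hr, t2)

    # stock-unique: 32 hr SNVs + 12 elsewhere
    u1 <- take(pick("hr1", 12L)); u2 <- take(pick("hr2", 10L))
    u3 <- take(pick("hr3", 10L))
    safe <- setdiff(c(14000:19000, 95000:104000), used)
    u4 <- sample(safe, 12L)
    uniq <- data.frame(pos = c(u1, u2, u3, u4),
                       alt = snv_at(c(u1, u2, u3, u4)),
                       stringsAsFactors = FALSE)
    if (anyDuplicated(c(conserved$pos, uniq$pos)))
      stop("fixture position collision; change seed")

    out <- rbind(
      data.frame(conserved, conserved = TRUE, stringsAsFactors = FALSE),
      data.frame(uniq, conserved = FALSE, stringsAsFactors = FALSE))
    out$freq <- round(runif(nrow(out), 0.011, 0.12), 4)
    out[order(out$pos), c("pos", "alt", "freq", "conserved")]
  })
}

#' Stock scenario (for the conservation analyses)
#'
#' Wraps [build_stock_fixture()] as an `amp_scenario` whose variants carry
#' the carry-over flag in the `conserved` column.
#' @inheritParams build_stock_fixture
#' @export
stock_scenario <- function(ref, seed = 777L) {
  v <- build_stock_fixture(ref, seed)
  sc <- scenario("virus_stock", "stock",
                 v[, c("pos", "alt", "freq")], seeds = c(9001L, 9002L))
  sc$conserved <- v$conserved
  sc
}

#' Construct a variant table directly from a variant specification
#'
#' Builds an iVar-style variant table from a (pos, alt, freq) specification
#' without simulating reads: supporting depths are the expected counts at
#' the given depth, qualities sit at the simulator's mean, and the
#' Fisher's-exact-test p-value is computed from those counts. Used for the
#' worked-example conservation and region-annotation fixtures, where the
#' variant sets (not the read-level noise) are the object under study.
#'
#' @param g an `amp_genome`.
#' @param variants data.frame `pos`, `alt`, `freq`.
#' @param sample,fraction labels stored as attributes.
#' @param depth assumed total depth per position.
#' @return a variant table (see [call_variants()] for columns).
#' @export
scenario_variant_table <- function(g, variants, sample = "sample",
                                   fraction = "cell_pellet", depth = 400L) {
  v <- variants
  n <- nrow(v)
  alt_dp <- pmax(1L, round(v$freq * depth))
  pval <- vapply(alt_dp, function(a) fisher_error_test(a, depth, 32), 0.0)
  tab <- data.frame(
    REGION = g$id, POS = v$pos,
    REF = substring(g$sequence, v$pos, v$pos),
    ALT = v$alt,
    REF_DP = depth - alt_dp, REF_QUAL = 32, REF_RV = 0L,
    ALT_DP = alt_dp, ALT_QUAL = 32, ALT_RV = 0L,
    ALT_FREQ = alt_dp / depth, TOTAL_DP = depth,
    PVAL = pval, PASS = pval <= 0.05,
    GFF_FEATURE = NA_character_,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$POS, tab$ALT), ]
  rownames(tab) <- NULL
  attr(tab, "sample") <- sample
  attr(tab, "fraction") <- fraction
  class(tab) <- c("amp_variant_table", "data.frame")
  tab
}

#' Conservation worked-example tables
#'
#' Deterministic stock, T-I and control variant tables reproducing the
#' passage-conservation bookkeeping: every carried-over stock variant
#' appears in at least one T-I table (97 of 141), no stock-unique variant
#' does, controls share a further set of hr variants with the T-I samples,
#' and each targeted T-I sample additionally carries its on-target gp64
#' deletions and a few sample-unique hr variants.
#'
#' @param ref fixture from [build_reference()].
#' @param seed RNG seed.
#' @return list with `stock` (variant table), `ti` (named list of variant
#'   tables), `controls` (named list), `stock_spec` (the underlying
#'   stock data.frame).
#' @export
fixture_conservation_tables <- function(ref, seed = 778L) {
  g <- ref$genome
  stock_spec <- build_stock_fixture(ref, seed = seed)
  hr <- ref$annotation[ref$annotation$class == "hr" &
                         ref$annotation$label %in% c("hr1", "hr2", "hr3"), ]
  cells <- deletion_cell_defs()
  samples <- unique(vapply(cells, function(d) d$sample, ""))
  samples <- c(samples, "gp64+278", "gp64+131/384")
  combos <- expand.grid(sample = samples,
                        fraction = c("cell_pellet", "supernatant"),
                        stringsAsFactors = FALSE)
  with_seed(seed + 1L, {
    n_tab <- nrow(combos)
    cons <- stock_spec[stock_spec$conserved, ]
    # membership of each conserved variant in the T-I tables (>= 1 each)
    member <- matrix(runif(nrow(cons) * n_tab) < 0.5, nrow = nrow(cons))
    none <- which(rowSums(member) == 0L)
    for (i in none) member[i, sample.int(n_tab, 1L)] <- TRUE

    # control-shared hr variants (absent from stock)
    snv_at <- function(pos) {
      refb <- substring(g$sequence, pos, pos)
      vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "",
        USE.NAMES = FALSE)
    }
    avail <- setdiff(unlist(mapply(seq, hr$start, hr$end,
                                   SIMPLIFY = FALSE)), stock_spec$pos)
    cs_pos <- sample(avail, 20L)
    ctrl_shared <- data.frame(pos = cs_pos, alt = snv_at(cs_pos),
                              freq = round(runif(20L, 0.011, 0.08), 4),
                              stringsAsFactors = FALSE)
    cs_member <- matrix(runif(20L * n_tab) < 0.4, nrow = 20L)

    # sample-unique hr variants
    avail2 <- setdiff(avail, cs_pos)
    uniq_pos <- sample(avail2, 3L * n_tab)

    ti <- vector("list", n_tab)
    for (k in seq_len(n_tab)) {
      v <- rbind(
        cons[member[, k], c("pos", "alt", "freq")],
        ctrl_shared[cs_member[, k], c("pos", "alt", "freq")],
        data.frame(pos = uniq_pos[(3L * (k - 1L) + 1L):(3L * k)],
                   alt = snv_at(uniq_pos[(3L * (k - 1L) + 1L):(3L * k)]),
                   freq = round(runif(3L, 0.011, 0.05), 4)))
      # on-target gp64 deletions for the matching cell
      for (d in cells) {
        if (d$sample == combos$sample[k] &&
            d$fraction == combos$fraction[k]) {
          dv <- d$variants
          v <- rbind(v, data.frame(pos = dv$pos, alt = dv$alt,
                                   freq = dv$freq))
        }
      }
      ti[[k]] <- scenario_variant_table(g, v, combos$sample[k],
                                        combos$fraction[k])
    }
    names(ti) <- paste(combos$sample, combos$fraction, sep = ".")

    controls <- sapply(c("scrambled", "infected_only"), function(nm) {
      keep <- runif(20L) < 0.9
      v <- ctrl_shared[keep, c("pos", "alt", "freq")]
      scenario_variant_table(g, v, nm, "cell_pellet")
    }, simplify = FALSE)

    list(stock = scenario_variant_table(
           g, stock_spec[, c("pos", "alt", "freq")], "virus_stock",
           "stock"),
         ti = ti, controls = controls, stock_spec = stock_spec)
  })
}

# Scenario text-file IO --------------------------------------------------

#' Write / read scenario files
#'
#' Scenarios are stored as YAML with keys `sample_name`, `fraction`,
#' `depth`, `read_length`, `replicates`, `seeds` and a `variants` list of
#' `{pos, alt, freq}` maps.
#' @param sc an `amp_scenario`.
#' @param path file path.
#' @export
write_scenario_yaml <- function(sc, path) {
  v <- all_scenario_variants(sc)
  obj <- list(sample_name = sc$sample_name, fraction = sc$fraction,
              depth = sc$depth, read_length = sc$read_length,
              replicates = sc$replicates, seeds = sc$seeds,
              variants = lapply(seq_len(nrow(v)), function(i)
                list(pos = v$pos[i], alt = v$alt[i], freq = v$freq[i])))
  if (!is.null(sc$conserved)) obj$conserved <- sc$conserved
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  v <- if (length(o$variants))
    do.call(rbind, lapply(o$variants, function(x)
      data.frame(pos = as.integer(x$pos), alt = x$alt, freq = x$freq,
                 stringsAsFactors = FALSE)))
  else NULL
  sc <- scenario(o$sample_name, o$fraction, v, depth = o$depth,
                 read_length = o$read_length, replicates = o$replicates,
                 seeds = o$seeds)
  if (!is.null(o$conserved)) sc$conserved <- o$conserved
  sc
}

#' Emit every bundled scenario as a YAML file
#'
#' Writes one file per deletion-recovery cell, the two control scenarios
#' and the stock scenario.
#' @param out_dir output directory.
#' @param ref fixture from [build_reference()] (for the stock scenario).
#' @param seed_base seed offset passed to the scenario builders.
#' @return invisibly, the written paths.
#' @export
write_bundled_scenarios <- function(out_dir, ref = build_reference(),
                                   seed_base = 1000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scs <- c(deletion_scenarios(seed_base), control_scenarios(seed_base + 4000L),
           list(virus_stock.stock = stock_scenario(ref)))
  paths <- vapply(names(scs), function(nm) {
    p <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.+-]", "_", nm),
                                   ".yaml"))
    write_scenario_yaml(scs[[nm]], p)
    p
  }, "")
  invisible(paths)
}
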