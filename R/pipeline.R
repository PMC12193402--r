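# End-to-end orchestration: simulate -> align -> clip/filter -> call ->
# replicate-intersect -> CRISPR / conservation reporting.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: mapping-quality
#' and flag-mask read filters (10 / 2308), primer clipping with a 200 bp
#' post-clip length floor, base quality >= 20 for substitution support,
#' a 1% calling floor and a 0.05 error-model alpha.
#'
#' @param scenarios list of `amp_scenario` objects (or a directory of
#'   scenario YAML files).
#' @param out_dir run directory for TSVs, reports and the log.
#' @param reference optional list from [build_reference()]; built with
#'   defaults when NULL.
#' @param region `"auto"` restricts each scenario's simulation to the
#'   amplicons overlapping its variants (padded by one amplicon);
#'   `NULL` simulates the whole scheme; or an explicit `c(start, end)`.
#' @param filter an `amp_filter_config`.
#' @param call an `amp_call_config`.
#' @param amplicon_len,overlap,primer_len tiling parameters.
#' @export
pipeline_config <- function(scenarios, out_dir = tempfile("ampedit_run"),
                            reference = NULL, region = "auto",
                            filter = filter_config(), call = call_config(),
                            amplicon_len = 1000L, overlap = 100L,
                            primer_len = 22L) {
  structure(list(scenarios = scenarios, out_dir = out_dir,
                 reference = reference, region = region, filter = filter,
                 call = call, amplicon_len = amplicon_len,
                 overlap = overlap, primer_len = primer_len),
            class = "amp_pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' Keys: `scenario_dir`, `out_dir`, `region` (`auto` or `[start, end]`),
#' and optional threshold overrides `mapq_min`, `flag_mask`, `min_len`,
#' `min_baseq`, `min_freq`, `alpha`, `amplicon_len`, `overlap`,
#' `primer_len`.
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  o <- yaml::read_yaml(path)
  scs <- lapply(list.files(o$scenario_dir, pattern = "\\.ya?ml$",
                           full.names = TRUE), read_scenario_yaml)
  names(scs) <- vapply(scs, function(s)
    paste(s$sample_name, s$fraction, sep = "."), "")
  pipeline_config(
    scenarios = scs,
    out_dir = o$out_dir %||% tempfile("ampedit_run"),
    region = if (identical(o$region, "auto")) "auto" else
      if (is.null(o$region)) NULL else as.integer(o$region),
    filter = filter_config(o$mapq_min %||% 10L, o$flag_mask %||% 2308L,
                           o$min_len %||% 200L),
    call = call_config(o$min_baseq %||% 20L, o$min_freq %||% 0.01,
                       o$alpha %||% 0.05),
    amplicon_len = o$amplicon_len %||% 1000L,
    overlap = o$overlap %||% 100L,
    primer_len = o$primer_len %||% 22L)
}

scenario_region <- function(sc, sch) {
  v <- all_scenario_variants(sc)
  if (!nrow(v)) return(NULL)
  iv <- range(unlist(lapply(seq_len(nrow(v)), function(i)
    variant_interval(v$pos[i], v$alt[i]))))
  c(iv[1], iv[2])
}

#' Run one scenario through the full pipeline
#'
#' Simulates each technical replicate, aligns, left-normalizes,
#' flag/MAPQ-filters, primer-clips, length-filters, builds the pileup and
#' calls variants; then intersects the replicate tables and applies the
#' error-model threshold.
#'
#' @param g an `amp_genome`.
#' @param sch an `amp_scheme`.
#' @param sc an `amp_scenario`.
#' @param fcfg,ccfg filter and call configurations.
#' @param region optional `c(start, end)` restriction for simulation.
#' @param out_dir directory for FASTQ/TSV output (temporary by default).
#' @param band aligner half band width (default 64; the working rule is
#'   twice the longest indel expected in the data).
#' @return list `replicates` (per-replicate variant tables), `merged`,
#'   `true` (merged table restricted to PVAL <= alpha), `n_pairs`.
#' @export
run_scenario <- function(g, sch, sc, fcfg = filter_config(),
                         ccfg = call_config(), region = NULL,
                         out_dir = tempfile("run"), band = 64L) {
  sim <- simulate_reads(g, sch, sc, out_dir = out_dir, region = region)
  amps <- sim$amplicons
  window <- c(min(sch$start[amps]), max(sch$end[amps]))
  reps <- vector("list", sc$replicates)
  for (r in seq_len(sc$replicates)) {
    f1 <- read_fastq(sim$fastq[[r]]$r1)
    f2 <- read_fastq(sim$fastq[[r]]$r2)
    pairs <- data.frame(name = f1$name, seq1 = f1$seq, qual1 = f1$qual,
                        seq2 = f2$seq, qual2 = f2$qual,
                        stringsAsFactors = FALSE)
    alns <- align_pairs(pairs, g, sch, band = band)
    alns <- left_normalize_indels(alns, g)
    alns <- filter_flags_mapq(alns, fcfg)
    alns <- clip_primers(alns, sch)
    alns <- filter_length(alns, fcfg)
    pu <- build_pileup(alns, g, window = window, cfg = ccfg)
    reps[[r]] <- call_variants(pu, ccfg, sample = sc$sample_name,
                               fraction = sc$fraction)
  }
  merged <- intersect_replicates(reps)
  list(replicates = reps, merged = merged,
       true = true_mutations(merged, ccfg$alpha), n_pairs = sim$n_pairs)
}

#' Run the full pipeline over a set of scenarios
#'
#' Executes every stage per sample x fraction x replicate, writes
#' per-replicate, merged and true-mutation TSVs plus an on-target match
#' report into the run directory, and logs every threshold and seed.
#'
#' @param config an `amp_pipeline_config`.
#' @return list with `reference`, `scheme`, `windows`, per-scenario
#'   `results`, and `on_target` (true on-target calls across scenarios).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  ref <- cfg$reference %||% build_reference()
  g <- ref$genome
  sch <- design_tiling(g, cfg$amplicon_len, cfg$overlap, cfg$primer_len)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat("", file = logf)
  logline("ampedit run: %d scenario(s)", length(cfg$scenarios))
  logline("filters: mapq_min=%d flag_mask=%d min_post_clip_len=%d",
          cfg$filter$mapq_min, cfg$filter$flag_mask,
          cfg$filter$min_post_clip_len)
  logline("calling: min_baseq=%d min_freq=%g alpha=%g",
          cfg$call$min_baseq, cfg$call$min_freq, cfg$call$alpha)

  windows <- edit_windows(g, ref$targets)
  results <- list()
  on_target <- list()
  for (nm in names(cfg$scenarios)) {
    sc <- cfg$scenarios[[nm]]
    region <- if (identical(cfg$region, "auto")) scenario_region(sc, sch)
    else cfg$region
    logline("scenario %s: seeds=%s region=%s", nm,
            paste(sc$seeds, collapse = ","),
            if (is.null(region)) "full" else paste(region, collapse = "-"))
    res <- tryCatch(
      run_scenario(g, sch, sc, cfg$filter, cfg$call, region = region,
                   out_dir = file.path(cfg$out_dir, "fastq", nm)),
      error = function(e) stop("stage failure in scenario '", nm, "': ",
                               conditionMessage(e), call. = FALSE))
    tag <- gsub("[^A-Za-z0-9_.+-]", "_", nm)
    for (r in seq_along(res$replicates))
      write_variant_tsv(res$replicates[[r]],
                        file.path(cfg$out_dir,
                                  sprintf("%s_rep%d.tsv", tag, r)))
    write_variant_tsv(res$merged,
                      file.path(cfg$out_dir, paste0(tag, ".merged.tsv")))
    labeled <- match_on_target(res$true, windows)
    write_variant_tsv(labeled,
                      file.path(cfg$out_dir, paste0(tag, ".true.tsv")))
    results[[nm]] <- c(res, list(labeled = labeled))
    ot <- labeled[labeled$TARGET_LABEL == "on_target", , drop = FALSE]
    if (nrow(ot)) {
      ot$scenario <- nm
      on_target[[nm]] <- ot
    }
    logline("scenario %s: %d true mutation(s), %d on-target", nm,
            nrow(res$true), nrow(ot))
  }
  ot_all <- if (length(on_target)) do.call(rbind, on_target) else NULL
  if (!is.null(ot_all)) {
    rownames(ot_all) <- NULL
    utils::write.table(ot_all, file.path(cfg$out_dir, "on_target.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reference = ref, scheme = sch, windows = windows,
       results = results, on_target = ot_all)
}
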