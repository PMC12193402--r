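#' Genome container
#'
#' A minimal reference-genome object: an identifier plus an uppercase DNA
#' sequence. All coordinates in the package are 1-based inclusive; only BED
#' emission converts to 0-based half-open.
#'
#' @param id sequence identifier.
#' @param sequence character scalar over A/C/G/T.
#' @return an object of class `amp_genome` with fields `id`, `sequence`,
#'   `length`.
#' @export
genome <- function(id, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("genome alphabet must be A/C/G/T")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "amp_genome")
}

#' @export
print.amp_genome <- function(x, ...) {
  cat(sprintf("<amp_genome> %s, %d bp\n", x$id, x$length))
  invisible(x)
}

genome_sub <- function(g, start, end) substr(g$sequence, start, end)

#' Guide-RNA targets fixture
#'
#' The spacer/PAM set used throughout the package: one scrambled
#' (non-genomic) control and six gp64 spacers, each a 20-mer with an NGG
#' PAM. `window_start`/`window_end` carry a declared estimated-indel window
#' only for the sense-strand gp64-160 target, whose declared window is
#' anchored directly rather than derived from the cut-site rule (it sits
#' 1 bp off the rule followed by every antisense target).
#'
#' @return data.frame with columns `name`, `spacer`, `pam`, `strand`
#'   (`sense`/`antisense`), `role` (`target`/`control`), `offset_label`,
#'   `window_start`, `window_end`.
#' @export
default_targets <- function() {
  data.frame(
    name = c("scrambled", "gp64+131", "gp64-160", "gp64+278", "gp64+378",
             "gp64+418", "gp64+384"),
    spacer = c("CACCTTGAAGCGCATGAACT",
               "GGAAACGCTGCAAAAGGACG",
               "GTTGTAGTCCGTCTCCACGA",
               "AACGCTGAATGTGGGCAAAG",
               "GACTGTTTTCGCGACAACGA",
               "AAGGCAAAGAGTTGGTGAAG",
               "TTTCGCGACAACGAGGGCCG"),
    pam = c(NA, "TGG", "TGG", "AGG", "GGG", "CGG", "CGG"),
    strand = c(NA, "antisense", "sense", "antisense", "antisense",
               "antisense", "antisense"),
    role = c("control", rep("target", 6L)),
    offset_label = c(NA, 131L, -160L, 278L, 378L, 418L, 384L),
    window_start = c(NA, NA, 107199L, NA, NA, NA, NA),
    window_end = c(NA, NA, 107204L, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# Fixed fixture layout ---------------------------------------------------

# Conserved-variant context outside the hrs: region label, class, interval,
# and the reference bases the fixture plants so each variant record is
# internally consistent (SNP reference alleles, insertion anchors that stay
# left-canonical, full deletion context sequences).
offhr_context <- function() {
  list(
    features = data.frame(
      label = c("AcOrf-603", "AcOrf-1629", "egt", "fgf-3pUTR", "AcOrf-51",
                "lef10", "AcOrf-84-prom", "AcOrf-91"),
      class = c("orf", "orf", "orf", "utr", "orf", "orf", "promoter", "orf"),
      start = c(3500L, 6000L, 11500L, 27400L, 43800L, 45500L, 71300L, 78500L),
      end = c(4200L, 7500L, 13000L, 27600L, 44300L, 46000L, 71500L, 79100L),
      strand = c("+", "+", "+", "+", "+", "+", "+", "+"),
      stringsAsFactors = FALSE),
    # position -> reference base to plant (SNP refs + shift guards)
    ref_bases = c(
      "3960" = "C", "6375" = "G", "27502" = "A", "27505" = "G",
      "27506" = "G", "27509" = "G", "45761" = "G", "71443" = "G",
      "78627" = "T", "78666" = "A",
      # insertion anchors: keep +GATC@7304 and +A@44073 left-canonical
      "7304" = "T", "44073" = "G",
      # deletion shift guards (base before anchor must differ from run end)
      "12427" = "A", "78926" = "G"),
    # longer planted context sequences (start -> sequence)
    ref_seqs = c(
      # 20 bp deleted in egt: bases 12428..12447
      "12428" = "CTAGAGATCTCTAGAGATCT",
      # 3 bp deleted in AcOrf-91: bases 78927..78929
      "78927" = "TAT")
  )
}

default_hr_spec <- function() {
  data.frame(
    name = c("hr1", "hr1a", "hr2", "hr2a", "hr3", "hr4a", "hr4b", "hr4c",
             "hr5"),
    start = c(20000L, 23000L, 30000L, 33000L, 52000L, 62000L, 69000L,
              75000L, 90000L),
    unit_len = c(30L, 24L, 30L, 24L, 30L, 30L, 30L, 24L, 30L),
    copies = c(6L, 1L, 6L, 1L, 6L, 6L, 6L, 1L, 6L),
    stringsAsFactors = FALSE)
}

default_reference_config <- function() {
  list(genome_id = "rBEV_syn", length = 120000L, anchor = 107222L,
       seed = 4242L, hr = default_hr_spec(), at_fraction = 0.7,
       gp64_start = 105842L, gp64_end = 107353L)
}

# protospacer genome placements implied by the anchor coordinate:
# antisense site at plus-strand start `anchor - 2 - (label - 131)`
# (estimated window = [start+2, start+7]); the sense gp64-160 site is
# anchored from its declared alleles at `anchor - 34`.
target_placements <- function(targets, anchor) {
  tg <- targets[targets$role == "target", , drop = FALSE]
  out <- lapply(seq_len(nrow(tg)), function(i) {
    t <- tg[i, ]
    if (t$strand == "antisense") {
      s <- anchor - 2L - (t$offset_label - 131L)
      list(name = t$name, strand = "-", proto_start = s, proto_end = s + 19L,
           pam_start = s - 3L, pam_end = s - 1L,
           proto_plus = revcomp(t$spacer),
           pam_plus = revcomp(t$pam))
    } else {
      s <- anchor - 34L
      list(name = t$name, strand = "+", proto_start = s, proto_end = s + 19L,
           pam_start = s + 20L, pam_end = s + 22L,
           proto_plus = t$spacer, pam_plus = t$pam)
    }
  })
  names(out) <- tg$name
  out
}

#' Build the synthetic reference fixture
#'
#' Constructs a deterministic synthetic baculovirus-like genome in which
#' every guide-RNA protospacer+PAM is planted exactly once at coordinates
#' anchored to the gp64+131 estimated-indel window, AT-rich tandem-repeat
#' homologous-repeat (hr) arrays are laid down, and the reference context
#' for the conserved-variant fixture (SNP reference alleles, insertion
#' anchors, deletion sequences) is planted. The target gene (gp64) is
#' annotated on the reverse strand.
#'
#' @param config optional list overriding any of `genome_id`, `length`,
#'   `anchor`, `seed`, `hr` (data.frame name/start/unit_len/copies; use a
#'   0-row data.frame for no hr arrays), `at_fraction`, `gp64_start`,
#'   `gp64_end`.
#' @return list with elements `genome` (class `amp_genome`), `annotation`
#'   (data.frame label/class/start/end/strand) and `targets`
#'   (see [default_targets()]).
#' @export
build_reference <- function(config = list()) {
  cfg <- default_reference_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  targets <- default_targets()
  L <- cfg$length
  if (cfg$anchor < 500L || cfg$anchor > L - 500L)
    stop("anchor coordinate too close to a genome edge")

  plac <- target_placements(targets, cfg$anchor)
  ctx <- offhr_context()

  seq <- with_seed(cfg$seed, {
    base <- paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
    # hr tandem arrays (AT-rich)
    hr <- cfg$hr
    if (nrow(hr) > 0) {
      at <- cfg$at_fraction
      p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
      for (i in seq_len(nrow(hr))) {
        repeat {
          unit <- paste0(sample(names(p), hr$unit_len[i], replace = TRUE,
                                prob = p), collapse = "")
          if (mean(strsplit(unit, "")[[1]] %in% c("A", "T")) >= 0.6) break
        }
        arr <- strrep(unit, hr$copies[i])
        if (hr$start[i] + nchar(arr) - 1L > L)
          stop("hr array '", hr$name[i], "' extends past genome end")
        base <- str_assign(base, hr$start[i], arr)
      }
    }
    base
  })

  # plant protospacers + PAMs; detect collisions with hr arrays / each other
  hr_iv <- if (nrow(cfg$hr) > 0)
    cbind(cfg$hr$start, cfg$hr$start + cfg$hr$unit_len * cfg$hr$copies - 1L)
  else matrix(numeric(0), ncol = 2)
  planted <- list()
  for (pl in plac) {
    iv <- c(min(pl$pam_start, pl$proto_start), max(pl$pam_end, pl$proto_end))
    if (iv[1] < 1L || iv[2] > L)
      stop("protospacer site for ", pl$name, " outside the genome")
    if (nrow(hr_iv) > 0 && any(iv[1] <= hr_iv[, 2] & iv[2] >= hr_iv[, 1]))
      stop("protospacer site for ", pl$name, " collides with an hr array")
    pamseq <- pl$pam_plus
    # N in the plus-strand PAM pattern: fix to A deterministically
    pamseq <- gsub("N", "A", pamseq)
    seq <- str_assign(seq, pl$proto_start, pl$proto_plus)
    seq <- str_assign(seq, pl$pam_start, pamseq)
    planted[[pl$name]] <- iv
  }
  # planted placements overlapping each other must agree on sequence; they do
  # by construction (gp64+378 / gp64+384 share a consistent 14 bp overlap),
  # verified below by exact-match uniqueness.

  # conserved-variant context
  for (p in names(ctx$ref_bases))
    seq <- str_assign(seq, as.integer(p), ctx$ref_bases[[p]])
  for (p in names(ctx$ref_seqs))
    seq <- str_assign(seq, as.integer(p), ctx$ref_seqs[[p]])
  # guard: deletion runs must not left-shift (base before anchor != run end)
  # handled via ref_bases above; also keep the 20-mer from duplicating the
  # spacers (disjoint coordinates by layout).

  g <- genome(cfg$genome_id, seq)

  # verify each spacer occurs exactly once genome-wide (either strand) and
  # the scrambled control not at all
  dna <- Biostrings::DNAString(seq)
  for (i in seq_len(nrow(targets))) {
    sp <- targets$spacer[i]
    n <- length(Biostrings::matchPattern(sp, dna)) +
      length(Biostrings::matchPattern(revcomp(sp), dna))
    if (targets$role[i] == "control") {
      if (n != 0) stop("scrambled control spacer present in fixture genome")
    } else if (n != 1) {
      stop("spacer ", targets$name[i], " occurs ", n, " times (expected 1)")
    }
  }

  ann <- rbind(
    if (nrow(cfg$hr) > 0)
      data.frame(label = cfg$hr$name, class = "hr", start = cfg$hr$start,
                 end = cfg$hr$start + cfg$hr$unit_len * cfg$hr$copies - 1L,
                 strand = ".", stringsAsFactors = FALSE),
    ctx$features,
    data.frame(label = "gp64", class = "orf", start = cfg$gp64_start,
               end = cfg$gp64_end, strand = "-", stringsAsFactors = FALSE)
  )
  ann <- ann[order(ann$start), ]
  rownames(ann) <- NULL
  stopifnot(!anyDuplicated(ann$label), all(ann$start <= ann$end))

  list(genome = g, annotation = ann, targets = targets)
}

# FASTA / BED IO ---------------------------------------------------------

#' Write / read a genome as FASTA
#' @param g an `amp_genome`.
#' @param path file path.
#' @export
write_genome_fasta <- function(g, path) {
  x <- Biostrings::DNAStringSet(g$sequence)
  names(x) <- g$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  genome(names(x)[1], as.character(x[[1]]))
}

#' Annotation BED IO
#'
#' Features are emitted as 6-column BED (0-based half-open) with the feature
#' class appended to the name as `label|class`.
#'
#' @param ann annotation data.frame (label/class/start/end/strand).
#' @param g an `amp_genome` (for the chrom column).
#' @param path file path.
#' @export
write_annotation_bed <- function(ann, g, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   g$id, ann$start - 1L, ann$end, ann$label, ann$class,
                   ifelse(ann$strand == ".", ".", ann$strand))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  parts <- strsplit(x$V4, "|", fixed = TRUE)
  data.frame(label = vapply(parts, `[`, "", 1L),
             class = vapply(parts, `[`, "", 2L),
             start = x$V2 + 1L, end = x$V3, strand = x$V6,
             stringsAsFactors = FALSE)
}
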