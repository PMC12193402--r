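# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fixture_ref <- function() {
  if (is.null(.fx$ref)) .fx$ref <- build_reference()
  .fx$ref
}

fixture_scheme <- function() {
  if (is.null(.fx$sch)) .fx$sch <- design_tiling(fixture_ref()$genome)
  .fx$sch
}

fixture_windows <- function() {
  if (is.null(.fx$win))
    .fx$win <- edit_windows(fixture_ref()$genome, fixture_ref()$targets)
  .fx$win
}

random_genome <- function(len, seed, id = "toy") {
  set.seed(seed)
  genome(id, paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = ""))
}

# independent hypergeometric tail-sum oracle for the error-model test:
# P(X >= alt) when drawing (alt+e) "successes" distributed over two columns
# of a 2x2 table with fixed margins
fisher_tail_oracle <- function(alt, total, e) {
  if (alt == 0) return(1.0)
  # margins: row sums (total, total); column sums (alt+e, 2*total-alt-e)
  m <- alt + e
  k <- total
  hi <- min(m, total)
  sum(stats::dhyper(alt:hi, m, 2 * total - m, k))
}

# simple scenario around a single spiked deletion for pipeline tests
deletion_scenario <- function(pos, alt, freq, seeds = c(1L, 2L),
                              depth = 400L, sample = "toy") {
  scenario(sample, "cell_pellet",
           data.frame(pos = pos, alt = alt, freq = freq),
           depth = depth, seeds = seeds)
}
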