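#' @useDynLib ampedit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fisher.test rnorm runif rbinom setNames
#' @importFrom utils adist read.delim write.table
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorised variants for bulk read handling
revcomp_vec <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rev_str_vec <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

# substring replacement keeping total length bookkeeping explicit
str_assign <- function(s, at, value) {
  substr(s, at, at + nchar(value) - 1L) <- value
  s
}

phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(q, 0L), 60L) + 33L, multiple = FALSE)
}

char_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

# IUPAC-aware single-pattern match (only N wildcards needed here)
pam_matches <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  all(pc == "N" | sc == pc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
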