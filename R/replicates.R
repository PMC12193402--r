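# Technical-replicate concordance filtering: a variant is kept only when
# its (region, pos, ref, alt) key is called in every replicate.

#' Intersect variant tables across technical replicates
#'
#' Output keys are exactly those present in all inputs. Merged statistics
#' are deliberately conservative: `ALT_FREQ` (and the depth columns) are
#' averaged across replicates, `PVAL` is the maximum, and `PASS` requires
#' every replicate to pass.
#'
#' @param tables list of two or more `amp_variant_table`s from the same
#'   sample.
#' @return merged `amp_variant_table` (extra column `N_REPS`).
#' @export
intersect_replicates <- function(tables) {
  if (length(tables) < 2L) stop("need at least two replicate tables")
  keys <- lapply(tables, variant_key)
  common <- Reduce(intersect, keys)
  base <- tables[[1]][match(common, keys[[1]]), , drop = FALSE]
  if (length(common)) {
    pick <- function(col) vapply(seq_along(common), function(i) {
      mean(vapply(seq_along(tables), function(t)
        tables[[t]][[col]][match(common[i], keys[[t]])], 0.0))
    }, 0.0)
    base$ALT_FREQ <- pick("ALT_FREQ")
    base$ALT_DP <- pick("ALT_DP")
    base$REF_DP <- pick("REF_DP")
    base$TOTAL_DP <- pick("TOTAL_DP")
    base$ALT_QUAL <- round(pick("ALT_QUAL"), 2)
    base$PVAL <- vapply(seq_along(common), function(i) {
      max(vapply(seq_along(tables), function(t)
        tables[[t]]$PVAL[match(common[i], keys[[t]])], 0.0))
    }, 0.0)
    base$PASS <- vapply(seq_along(common), function(i) {
      all(vapply(seq_along(tables), function(t)
        tables[[t]]$PASS[match(common[i], keys[[t]])], TRUE))
    }, TRUE)
  }
  base$N_REPS <- if (nrow(base)) length(tables) else integer(0)
  base <- base[order(base$POS, base$ALT), , drop = FALSE]
  rownames(base) <- NULL
  attr(base, "sample") <- attr(tables[[1]], "sample")
  attr(base, "fraction") <- attr(tables[[1]], "fraction")
  class(base) <- c("amp_variant_table", "data.frame")
  base
}

#' True mutations under the error model
#'
#' Subsets a merged table to rows with Fisher's exact test p-value at or
#' below `alpha` (boundary inclusive).
#'
#' @param tab an `amp_variant_table`.
#' @param alpha threshold (default 0.05).
#' @export
true_mutations <- function(tab, alpha = 0.05) {
  out <- tab[tab$PVAL <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample") <- attr(tab, "sample")
  attr(out, "fraction") <- attr(tab, "fraction")
  class(out) <- c("amp_variant_table", "data.frame")
  out
}
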