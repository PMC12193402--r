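# Cross-sample and cross-passage variant bookkeeping: conservation from
# the virus stock, control sharing, and hr / non-hr region annotation.

#' Classify T-I variants against the virus stock and controls
#'
#' Each variant key observed across the transfection-infection (T-I)
#' tables is labeled `conserved_from_stock` if present in the stock table,
#' else `control_shared` if present in any control table, else `unique`.
#' `percent_conserved` is the share of stock keys re-observed in the union
#' of the T-I tables.
#'
#' @param ti_tables list of `amp_variant_table`s from the T-I passage.
#' @param stock the virus-stock `amp_variant_table` (non-empty).
#' @param controls optional list of control tables.
#' @return list of class `amp_conservation_report`: `variants` (key,
#'   label), `counts`, `percent_conserved`, `n_stock`, `n_carried`.
#' @export
compare_to_stock <- function(ti_tables, stock, controls = list()) {
  if (!nrow(stock)) stop("stock table is empty; percent conserved undefined")
  stock_keys <- variant_key(stock)
  ti_keys <- unique(unlist(lapply(ti_tables, variant_key)))
  ctrl_keys <- unique(unlist(lapply(controls, variant_key)))
  lab <- ifelse(ti_keys %in% stock_keys, "conserved_from_stock",
                ifelse(ti_keys %in% ctrl_keys, "control_shared", "unique"))
  carried <- intersect(stock_keys, ti_keys)
  counts <- table(factor(lab, levels = c("conserved_from_stock",
                                         "control_shared", "unique")))
  structure(list(
    variants = data.frame(key = ti_keys, label = lab,
                          stringsAsFactors = FALSE),
    counts = counts,
    percent_conserved = 100 * length(carried) / length(stock_keys),
    n_stock = length(stock_keys),
    n_carried = length(carried)),
    class = "amp_conservation_report")
}

#' @export
print.amp_conservation_report <- function(x, ...) {
  cat(sprintf("<conservation> %d/%d stock variants carried over (%.1f%%)\n",
              x$n_carried, x$n_stock, x$percent_conserved))
  print(x$counts)
  invisible(x)
}

#' Annotate variants with genomic region labels
#'
#' Labels each variant by the feature its affected interval falls in
#' (`hr:<name>`, `orf:<name>`, `promoter:<name>`, `utr:<name>`, or
#' `intergenic`); variants whose interval intersects an estimated indel
#' window are labeled `on_target` instead. Deletions are assigned by
#' majority overlap of their full interval, ties resolved to the leftmost
#' feature.
#'
#' @param tab an `amp_variant_table`.
#' @param ann annotation data.frame (label/class/start/end/strand).
#' @param target_windows optional data.frame from [edit_windows()].
#' @return the table with a `REGION_LABEL` column.
#' @export
annotate_regions <- function(tab, ann, target_windows = NULL) {
  n <- nrow(tab)
  lab <- character(n)
  for (i in seq_len(n)) {
    iv <- variant_interval(tab$POS[i], tab$ALT[i])
    if (!is.null(target_windows) &&
        any(target_windows$start <= iv[2] & target_windows$end >= iv[1])) {
      lab[i] <- "on_target"
      next
    }
    ov <- pmin(ann$end, iv[2]) - pmax(ann$start, iv[1]) + 1L
    ov[ov < 0L] <- 0L
    if (!any(ov > 0L)) {
      lab[i] <- "intergenic"
    } else {
      best <- which(ov == max(ov))
      best <- best[which.min(ann$start[best])]
      lab[i] <- paste0(ann$class[best], ":", ann$label[best])
    }
  }
  tab$REGION_LABEL <- lab
  tab
}

#' Per-hr mutation counts, total and filtered
#'
#' Counts true hr mutations per sample and fraction twice: `total` counts
#' every true mutation inside an hr interval; `filtered` removes keys
#' present in any control table or in the virus stock (the
#' sample-unique view). Also returns the non-hr, non-target variant map.
#'
#' @param tables named list of `amp_variant_table`s (attributes `sample`
#'   and `fraction` are used for grouping).
#' @param ann annotation data.frame.
#' @param stock stock `amp_variant_table` (or NULL).
#' @param controls list of control tables.
#' @param target_windows optional data.frame from [edit_windows()].
#' @return list `total` and `filtered` (data.frames hr x sample x fraction
#'   counts) and `outside` (non-hr, non-target labeled variants).
#' @export
summarize_hr_counts <- function(tables, ann, stock = NULL,
                                controls = list(), target_windows = NULL) {
  drop_keys <- unique(c(
    if (!is.null(stock)) variant_key(stock),
    unlist(lapply(controls, variant_key))))
  rows_t <- list(); rows_f <- list(); outside <- list()
  for (nm in names(tables)) {
    tab <- true_mutations(tables[[nm]])
    tab <- annotate_regions(tab, ann, target_windows)
    is_hr <- startsWith(tab$REGION_LABEL, "hr:")
    smp <- attr(tables[[nm]], "sample") %||% nm
    frc <- attr(tables[[nm]], "fraction") %||% NA_character_
    if (any(is_hr)) {
      hr_name <- sub("^hr:", "", tab$REGION_LABEL[is_hr])
      keys <- variant_key(tab[is_hr, , drop = FALSE])
      keep_f <- !(keys %in% drop_keys)
      tt <- as.data.frame(table(hr = hr_name), stringsAsFactors = FALSE)
      tt$sample <- smp; tt$fraction <- frc
      rows_t[[length(rows_t) + 1L]] <- tt
      if (any(keep_f)) {
        ff <- as.data.frame(table(hr = hr_name[keep_f]),
                            stringsAsFactors = FALSE)
        ff$sample <- smp; ff$fraction <- frc
        rows_f[[length(rows_f) + 1L]] <- ff
      }
    }
    out_i <- !is_hr & tab$REGION_LABEL != "on_target" &
      !(variant_key(tab) %in% drop_keys)
    if (any(out_i)) {
      o <- tab[out_i, c("POS", "REF", "ALT", "ALT_FREQ", "REGION_LABEL")]
      o$sample <- smp; o$fraction <- frc
      outside[[length(outside) + 1L]] <- o
    }
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  empty_cnt <- data.frame(hr = character(), Freq = integer(),
                          sample = character(), fraction = character(),
                          stringsAsFactors = FALSE)
  list(total = bind(rows_t, empty_cnt),
       filtered = bind(rows_f, empty_cnt),
       outside = bind(outside, data.frame()))
}
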