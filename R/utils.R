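## Internal helpers shared across modules.

# Abort unless `cond` is a single TRUE.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# A peak table must carry these columns in this coordinate convention:
# 0-based half-open [start, end), summit an absolute base position.
peak_columns <- c("chrom", "start", "end", "name", "fold_enrichment", "summit")

check_peaks <- function(peaks, arg = "peaks") {
  check_that(is.data.frame(peaks), paste0("`", arg, "` must be a data frame"))
  missing_cols <- setdiff(peak_columns, names(peaks))
  check_that(
    length(missing_cols) == 0,
    paste0("`", arg, "` is missing peak column(s): ",
           paste(missing_cols, collapse = ", "))
  )
  if (nrow(peaks) > 0) {
    check_that(all(peaks$start < peaks$end),
               paste0("`", arg, "`: every peak needs start < end"))
    check_that(all(peaks$summit >= peaks$start & peaks$summit < peaks$end),
               paste0("`", arg, "`: every summit must lie in [start, end)"))
    fe <- peaks$fold_enrichment
    check_that(all(is.na(fe) | fe >= 0),
               paste0("`", arg, "`: fold_enrichment must be >= 0 or NA"))
  }
  invisible(peaks)
}

# Build a GRanges from a chrom/start/end table (0-based half-open in,
# 1-based closed inside GRanges).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

new_cistrome <- function(peaks, factor_label = NA_character_,
                         source_label = NA_character_) {
  out <- as_tibble(peaks)
  attr(out, "factor_label") <- factor_label
  attr(out, "source_label") <- source_label
  class(out) <- c("cistrome", class(tibble()))
  out
}

# Carry cistrome labels through an operation that returns a plain tibble.
relabel_cistrome <- function(out, template, factor_label = NULL,
                             source_label = NULL) {
  new_cistrome(
    out,
    factor_label = factor_label %||% attr(template, "factor_label") %||% NA_character_,
    source_label = source_label %||% attr(template, "source_label") %||% NA_character_
  )
}

#' @export
print.cistrome <- function(x, ...) {
  lbl <- attr(x, "factor_label")
  if (!is.null(lbl) && !is.na(lbl)) {
    cat("# Cistrome:", lbl, "\n")
  }
  NextMethod()
}
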