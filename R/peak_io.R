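## Peak/interval file I/O and blacklist filtering.
##
## Coordinates are 0-based half-open ([start, end)) everywhere, the BED
## convention. Summits are absolute base positions. Chromosome names are
## matched by exact string equality; no "chr" prefix harmonization.

#' Describe a genome as an ordered set of chromosome lengths
#'
#' A genome layout is the coordinate universe peaks and coverage live in:
#' chromosome names (unique) and lengths in base pairs (strictly positive).
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Integer vector of chromosome lengths in bp, one per
#'   name.
#' @return A tibble with columns `chrom` and `length`, classed
#'   `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  check_that(length(chrom_names) == length(chrom_lengths),
             "`chrom_names` and `chrom_lengths` must have equal length")
  check_that(!anyDuplicated(chrom_names), "chromosome names must be unique")
  check_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  out <- tibble(chrom = as.character(chrom_names),
                length = as.numeric(chrom_lengths))
  class(out) <- c("genome_layout", class(out))
  out
}

#' Read ChIP-seq peaks from a BED or narrowPeak file
#'
#' Reads a tab-separated peak file into a cistrome tibble. ENCODE
#' narrowPeak (10 columns) carries the summit as an offset in column 10
#' (`-1` meaning unknown) and fold enrichment in column 7 (signalValue;
#' `.` or a negative value meaning missing). For plain BED (3-6 columns)
#' the summit falls back to the interval midpoint, `floor((start + end)/2)`,
#' and fold enrichment is missing.
#'
#' @param path Path to a BED3/BED6 or narrowPeak file.
#' @param format One of `"auto"` (default; decided by column count),
#'   `"bed"`, or `"narrowPeak"`.
#' @param factor_label,source_label Optional provenance labels attached to
#'   the result.
#' @return A cistrome: a tibble with columns `chrom`, `start`, `end`,
#'   `name`, `fold_enrichment`, `summit` (plus `strand` when present).
#' @seealso [write_peaks()] for the exact-round-trip writer.
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak"),
                       factor_label = NA_character_,
                       source_label = NA_character_) {
  format <- match.arg(format)
  check_that(file.exists(path), paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(new_cistrome(
      tibble(chrom = character(), start = numeric(), end = numeric(),
             name = character(), fold_enrichment = numeric(),
             summit = numeric()),
      factor_label, source_label
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[1])[1]
    abort(paste0("malformed line ", bad, " in ", path,
                 ": expected ", ncols[1], " fields, found ", ncols[bad]))
  }
  nc <- ncols[1]
  if (format == "auto") {
    format <- if (nc == 10) "narrowPeak" else "bed"
  }
  if (format == "narrowPeak" && nc != 10) {
    abort(paste0("narrowPeak requires 10 columns, found ", nc, " in ", path))
  }
  if (format == "bed" && (nc < 3 || nc > 7)) {
    abort(paste0("unrecognized peak format (", nc, " columns) in ", path))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x)) {
      abort(paste0("malformed line ", which(is.na(x))[1], " in ", path,
                   ": non-numeric ", what))
    }
    x
  }
  start <- num(2, "start")
  end <- num(3, "end")
  check_that(all(start >= 0), "coordinates must be non-negative")
  bad <- which(end <= start)
  if (length(bad) > 0) {
    abort(paste0("malformed line ", bad[1], " in ", path, ": end <= start"))
  }
  name <- if (nc >= 4) col(4) else paste0("peak_", seq_along(lines))
  fe <- rep(NA_real_, length(lines))
  if (format == "narrowPeak") {
    sv <- col(7)
    keep <- sv != "." & sv != ""
    fe[keep] <- suppressWarnings(as.numeric(sv[keep]))
    fe[!is.na(fe) & fe < 0] <- NA_real_
    offset <- num(10, "summit offset")
    summit <- ifelse(offset >= 0, start + offset, floor((start + end) / 2))
  } else {
    summit <- floor((start + end) / 2)
  }
  out <- tibble(chrom = col(1), start = start, end = end, name = name,
                fold_enrichment = fe, summit = summit)
  if (nc >= 6) out$strand <- col(6)
  check_peaks(out, "peaks read from file")
  new_cistrome(out, factor_label, source_label)
}

#' Write a cistrome to a narrowPeak file
#'
#' Writes 10-column ENCODE narrowPeak. Fold enrichment goes in the
#' signalValue column (`.` when missing) and the summit as the column-10
#' offset, so `read_peaks(write_peaks(x))` reproduces coordinates, summits
#' and fold enrichment exactly.
#'
#' @param peaks A cistrome tibble (see [read_peaks()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  check_peaks(peaks)
  fe <- ifelse(is.na(peaks$fold_enrichment), ".",
               format(peaks$fold_enrichment, trim = TRUE, scientific = FALSE))
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
    peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
    peaks$name, fe, as.integer(peaks$summit - peaks$start)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read blacklist regions from a BED file
#'
#' @param path Path to a BED3+ file of artifact-prone regions to exclude.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_blacklist <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  check_that(all(lengths(fields) >= 3), "blacklist BED needs >= 3 columns")
  out <- tibble(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.numeric(vapply(fields, `[[`, character(1), 2)),
    end = as.numeric(vapply(fields, `[[`, character(1), 3))
  )
  check_that(all(out$start < out$end), "blacklist intervals need start < end")
  out
}

#' Remove intervals overlapping a blacklist
#'
#' Drops every row of `x` that shares at least one base with any blacklist
#' interval (any-overlap rule, not fractional). Both inputs must use
#' 0-based half-open coordinates; an interval ending exactly where a
#' blacklist region starts is kept. Row order of survivors is preserved,
#' and an empty blacklist returns `x` unchanged.
#'
#' @param x A tibble of intervals with columns `chrom`, `start`, `end`
#'   (peaks, windows, or any interval table).
#' @param blacklist A tibble with columns `chrom`, `start`, `end`, e.g.
#'   from [read_blacklist()].
#' @return `x` without the overlapping rows.
#' @export
filter_blacklist <- function(x, blacklist) {
  check_that(all(c("chrom", "start", "end") %in% names(x)),
             "`x` needs chrom/start/end columns")
  if (is.null(blacklist) || nrow(blacklist) == 0 || nrow(x) == 0) {
    return(x)
  }
  if (length(intersect(unique(x$chrom), unique(blacklist$chrom))) == 0) {
    warn("`x` and `blacklist` share no chromosome names; nothing filtered")
    return(x)
  }
  hits <- GenomicRanges::countOverlaps(as_granges0(x), as_granges0(blacklist))
  x[hits == 0, , drop = FALSE]
}
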