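## TSS-anchored metagene profiling of binned coverage.
##
## Coverage is held in fixed-width bins (100 bp by default). Windows are
## snapped to the bin grid at the bin containing the TSS, so a window of
## +/- 2 kb spans exactly 40 bins and its 1-kb baseline exactly 10.

#' Bin read start positions into fixed-width windows
#'
#' Counts 5' read start positions per half-open bin
#' `[k*w, (k+1)*w)` along each chromosome. Total counts are conserved:
#' the bins sum to the number of reads.
#'
#' @param reads A tibble with columns `chrom` and `pos` (0-based read
#'   start positions), or a pre-binned coverage track (returned
#'   unchanged).
#' @param layout A [genome_layout()].
#' @param bin_width Bin width in bp (default 100).
#' @return A coverage track: tibble of class `coverage_track` with
#'   columns `chrom`, `start`, `count` and attribute `bin_width`. All
#'   bins of every chromosome are present, including zero-count bins.
#' @export
bin_coverage <- function(reads, layout, bin_width = 100) {
  if (inherits(reads, "coverage_track")) return(reads)
  check_that(all(c("chrom", "pos") %in% names(reads)),
             "`reads` needs chrom and pos columns")
  check_that(bin_width > 0, "`bin_width` must be positive")
  len <- setNames(layout$length, layout$chrom)
  bad_chrom <- setdiff(unique(reads$chrom), layout$chrom)
  check_that(length(bad_chrom) == 0,
             paste0("reads on chromosome(s) absent from layout: ",
                    paste(bad_chrom, collapse = ", ")))
  out_of_bounds <- reads$pos < 0 | reads$pos >= len[reads$chrom]
  if (any(out_of_bounds)) {
    abort(paste0(sum(out_of_bounds),
                 " read position(s) beyond chromosome bounds"))
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(layout)), function(i) {
    chrom <- layout$chrom[i]
    nbins <- ceiling(layout$length[i] / bin_width)
    pos <- reads$pos[reads$chrom == chrom]
    counts <- tabulate(floor(pos / bin_width) + 1L, nbins = nbins)
    tibble(chrom = chrom,
           start = (seq_len(nbins) - 1) * bin_width,
           count = counts)
  }))
  new_coverage_track(out, bin_width)
}

new_coverage_track <- function(df, bin_width) {
  attr(df, "bin_width") <- bin_width
  class(df) <- c("coverage_track", class(tibble()))
  df
}

#' Read a bedGraph of pre-binned counts as a coverage track
#'
#' Expects fixed-width, non-overlapping intervals on the `bin_width`
#' grid; missing bins are filled with zero counts.
#'
#' @param path Path to a 4-column bedGraph.
#' @inheritParams bin_coverage
#' @return A `coverage_track` tibble.
#' @export
read_coverage_bedgraph <- function(path, layout, bin_width = 100) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "count"),
                        col_types = "ciid", progress = FALSE)
  check_that(all(df$end - df$start == bin_width) &&
               all(df$start %% bin_width == 0),
             paste0("bedGraph intervals must sit on the ", bin_width,
                    "-bp grid"))
  full <- dplyr::bind_rows(lapply(seq_len(nrow(layout)), function(i) {
    nbins <- ceiling(layout$length[i] / bin_width)
    tibble(chrom = layout$chrom[i],
           start = (seq_len(nbins) - 1) * bin_width)
  }))
  out <- dplyr::left_join(full, df[, c("chrom", "start", "count")],
                          by = c("chrom", "start"))
  out$count[is.na(out$count)] <- 0
  new_coverage_track(out, bin_width)
}

#' Build symmetric TSS windows with an upstream baseline
#'
#' One window per requested gene: `[tss - flank, tss + flank)` snapped to
#' the coverage bin grid, plus a `baseline_bp` stretch immediately
#' preceding the window. With `oriented = TRUE` (default) "preceding" is
#' read along the direction of transcription, so for `-` strand genes the
#' baseline lies at higher genomic coordinates; with `oriented = FALSE`
#' the baseline is always genomically upstream (lower coordinates).
#' Windows whose geometry does not fit inside the chromosome are dropped,
#' as are windows or baselines overlapping the blacklist; genes with no
#' TSS record are skipped with a warning. Drops are tallied in the
#' `n_dropped` attribute.
#'
#' @param gene_ids Character vector of gene ids to profile.
#' @param tss A TSS tibble (see [read_tss()]).
#' @param layout A [genome_layout()].
#' @param blacklist Optional blacklist tibble (`chrom`, `start`, `end`).
#' @param flank Half-width of the window in bp (default 2000).
#' @param baseline_bp Length of the baseline stretch in bp (default
#'   1000).
#' @param bin_width Coverage bin width the windows must align to.
#' @param oriented Flip baseline (and profile axis) for `-` strand genes.
#' @return A tibble of class `metagene_windows`: `gene_id`, `chrom`,
#'   `strand`, `tss_bin` (genomic bin index of the TSS), `win_start`,
#'   `win_end`, `base_start`, `base_end` (bp, half-open).
#' @export
build_tss_windows <- function(gene_ids, tss, layout, blacklist = NULL,
                              flank = 2000, baseline_bp = 1000,
                              bin_width = 100, oriented = TRUE) {
  check_tss(tss)
  check_that(flank > 0 && flank %% bin_width == 0,
             "`flank` must be a positive multiple of `bin_width`")
  check_that(baseline_bp > 0 && baseline_bp %% bin_width == 0,
             "`baseline_bp` must be a positive multiple of `bin_width`")
  gene_ids <- unique(gene_ids)
  found <- gene_ids %in% tss$gene_id
  if (any(!found)) {
    warn(paste0(sum(!found), " gene(s) have no TSS record and were skipped"))
  }
  t <- tss[match(gene_ids[found], tss$gene_id), ]
  len <- setNames(layout$length, layout$chrom)
  tss_bin <- floor(t$tss / bin_width)
  win_start <- (tss_bin * bin_width) - flank
  win_end <- (tss_bin * bin_width) + flank
  upstream <- if (oriented) t$strand == "+" else rep(TRUE, nrow(t))
  base_start <- ifelse(upstream, win_start - baseline_bp, win_end)
  base_end <- ifelse(upstream, win_start, win_end + baseline_bp)
  out <- tibble(gene_id = t$gene_id, chrom = t$chrom, strand = t$strand,
                tss_bin = tss_bin, win_start = win_start, win_end = win_end,
                base_start = base_start, base_end = base_end)
  fits <- pmin(out$win_start, out$base_start) >= 0 &
    pmax(out$win_end, out$base_end) <= len[out$chrom]
  out <- out[fits, , drop = FALSE]
  n_before <- nrow(out)
  if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(out) > 0) {
    span <- tibble(chrom = out$chrom,
                   start = pmin(out$win_start, out$base_start),
                   end = pmax(out$win_end, out$base_end))
    hits <- GenomicRanges::countOverlaps(as_granges0(span),
                                         as_granges0(blacklist))
    out <- out[hits == 0, , drop = FALSE]
  }
  attr(out, "n_dropped") <- length(gene_ids) - nrow(out)
  attr(out, "flank") <- flank
  attr(out, "baseline_bp") <- baseline_bp
  attr(out, "bin_width") <- bin_width
  attr(out, "oriented") <- oriented
  class(out) <- c("metagene_windows", class(tibble()))
  out
}

#' Average fold-change profile over TSS windows
#'
#' For each window, the baseline is the mean count of its baseline bins;
#' each window bin's fold change is `count / baseline`. Windows with a
#' zero baseline are excluded (their number is reported in the
#' `n_zero_baseline` attribute). The profile is the unweighted mean of
#' per-window fold changes across surviving windows; for `-` strand genes
#' in oriented mode the bin order is mirrored so the position axis always
#' runs in the direction of transcription.
#'
#' @param windows A `metagene_windows` tibble from [build_tss_windows()].
#' @param track A `coverage_track` from [bin_coverage()].
#' @return A tibble of class `metagene_profile` with columns `position`
#'   (bin centers relative to the TSS bin start, from `-flank + w/2` to
#'   `flank - w/2`) and `fold_change`; attributes `n_sites` and
#'   `n_zero_baseline`.
#' @export
fold_change_profile <- function(windows, track) {
  check_that(inherits(track, "coverage_track"),
             "`track` must come from bin_coverage()")
  w <- attr(track, "bin_width")
  check_that(identical(w, attr(windows, "bin_width")),
             "window and track bin widths differ")
  check_that(nrow(windows) > 0, "no windows to profile")
  flank <- attr(windows, "flank")
  base_bins <- attr(windows, "baseline_bp") / w
  half <- flank / w
  oriented <- isTRUE(attr(windows, "oriented"))

  counts <- split(track$count, track$chrom)
  per_site <- lapply(seq_len(nrow(windows)), function(i) {
    v <- counts[[windows$chrom[i]]]
    bt <- windows$tss_bin[i]
    win <- v[(bt - half + 1):(bt + half)]  # 1-based: bins bt-half .. bt+half-1
    bidx <- (windows$base_start[i] / w + 1):(windows$base_end[i] / w)
    baseline <- mean(v[bidx])
    if (baseline == 0) return(NULL)
    fc <- win / baseline
    if (oriented && windows$strand[i] == "-") fc <- rev(fc)
    fc
  })
  keep <- !vapply(per_site, is.null, logical(1))
  if (!any(keep)) abort("all windows have zero baseline coverage")
  mat <- do.call(rbind, per_site[keep])
  out <- tibble(
    position = seq(-flank + w / 2, flank - w / 2, by = w),
    fold_change = colMeans(mat)
  )
  attr(out, "n_sites") <- sum(keep)
  attr(out, "n_zero_baseline") <- sum(!keep)
  class(out) <- c("metagene_profile", class(tibble()))
  out
}
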