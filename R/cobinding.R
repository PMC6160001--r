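## Co-binding proximity statistics between two cistromes.
##
## The core quantity is the summit-to-summit distance from each query peak
## to its nearest reference peak on the same chromosome. Co-binding is a
## distance strictly below a threshold (120 bp by default); the co-binding
## ratio compares proximal to non-proximal events and is therefore
## insensitive to the total peak count of either cistrome.

#' Configuration for co-binding analysis
#'
#' @param proximal_threshold Distance (bp) below which a query summit is
#'   called co-bound with its nearest reference summit. Default 120 bp.
#'   A distance exactly at the threshold is non-proximal (strict `<` is
#'   proximal).
#' @param fe_stringencies Ascending fold-enrichment cutoffs defining
#'   stringency tiers; the highest (default 30) is the high-stringency
#'   tier.
#' @param histogram_bin Bin width (bp) for distance histograms.
#' @param histogram_max Right edge (bp) of the histogram; distances at or
#'   beyond it are counted as overflow. Must be a multiple of
#'   `histogram_bin`.
#' @return A list of class `cobind_config`.
#' @export
cobind_config <- function(proximal_threshold = 120,
                          fe_stringencies = c(10, 20, 30),
                          histogram_bin = 20,
                          histogram_max = 3000) {
  check_that(proximal_threshold > 0, "`proximal_threshold` must be positive")
  check_that(all(fe_stringencies >= 0) && !is.unsorted(fe_stringencies),
             "`fe_stringencies` must be non-negative and ascending")
  check_that(histogram_bin > 0, "`histogram_bin` must be positive")
  check_that(histogram_max %% histogram_bin == 0,
             "`histogram_bin` must divide `histogram_max`")
  structure(
    list(proximal_threshold = proximal_threshold,
         fe_stringencies = fe_stringencies,
         histogram_bin = histogram_bin,
         histogram_max = histogram_max),
    class = "cobind_config"
  )
}

#' Filter a cistrome by fold-enrichment stringency
#'
#' Keeps peaks with `fold_enrichment >= fe_cutoff` (inclusive: the "FE30"
#' tier keeps fold enrichment 30 and above). Peak order is preserved.
#' Peaks with missing fold enrichment are an error, since a stringency
#' filter cannot place them.
#'
#' @param peaks A cistrome tibble.
#' @param fe_cutoff Non-negative fold-enrichment cutoff.
#' @return The filtered cistrome.
#' @export
filter_by_fe <- function(peaks, fe_cutoff) {
  check_peaks(peaks)
  missing_fe <- is.na(peaks$fold_enrichment)
  if (any(missing_fe)) {
    abort(paste0(
      "cannot apply a fold-enrichment cutoff: peak(s) missing FE: ",
      paste(utils::head(peaks$name[missing_fe], 5), collapse = ", "),
      if (sum(missing_fe) > 5) ", ..." else ""
    ))
  }
  relabel_cistrome(peaks[peaks$fold_enrichment >= fe_cutoff, , drop = FALSE],
                   peaks)
}

#' Pool several cistromes into one
#'
#' Concatenates the peaks of all inputs, retaining duplicates (a multiset
#' union), e.g. to pool one factor's binding across circadian timepoints
#' so that phase differences between timepoints do not bias proximity
#' statistics.
#'
#' @param cistromes A list of cistrome tibbles (at least one).
#' @param label Factor label for the pooled cistrome.
#' @return A cistrome with `sum(sapply(cistromes, nrow))` peaks.
#' @export
pool_cistromes <- function(cistromes, label = "pooled") {
  check_that(is.list(cistromes) && length(cistromes) >= 1,
             "`cistromes` must be a non-empty list of peak tables")
  purrr::walk(cistromes, check_peaks)
  pooled <- dplyr::bind_rows(lapply(cistromes, function(x) {
    as_tibble(x)[, intersect(names(x), c(peak_columns, "strand"))]
  }))
  new_cistrome(pooled, factor_label = label)
}

# Nearest reference summit for query summits on one chromosome.
# `ref` must be sorted ascending. Returns index into `ref` (the summit
# vector), excluding, per query, at most one reference entry by name.
nearest_index_sorted <- function(q_summit, ref_summit, q_name = NULL,
                                 ref_name = NULL) {
  n <- length(ref_summit)
  pos <- findInterval(q_summit, ref_summit)
  pick <- function(cands, qs, excl) {
    cands <- cands[cands >= 1 & cands <= n]
    if (!is.null(excl)) cands <- cands[ref_name[cands] != excl]
    if (length(cands) == 0) return(NA_integer_)
    cands[which.min(abs(ref_summit[cands] - qs))]
  }
  vapply(seq_along(q_summit), function(i) {
    excl <- if (!is.null(q_name) && !is.null(ref_name)) q_name[i] else NULL
    # left/right neighbours, widened by one on each side so that excluding
    # a same-name reference peak still finds the true nearest remaining one
    pick(c(pos[i] - 1L, pos[i], pos[i] + 1L, pos[i] + 2L), q_summit[i], excl)
  }, integer(1))
}

#' Summit-to-summit distances from each query peak to its nearest
#' reference peak
#'
#' For every query peak, the unsigned distance to the nearest reference
#' summit on the same chromosome. Query peaks on chromosomes absent from
#' the reference are "orphans": they appear in the output with `NA`
#' distance and are excluded from downstream counts. When query and
#' reference are the same cistrome, a reference peak with the same name as
#' the query peak is excluded, so a self-comparison does not return
#' all-zero distances.
#'
#' @param query,ref Cistrome tibbles; `ref` must be non-empty.
#' @return A tibble of class `summit_distances` with one row per query
#'   peak: `name`, `chrom`, `summit`, `ref_name`, `distance` (`NA` for
#'   orphans). Attributes `query_label` and `ref_label` carry provenance.
#' @export
nearest_summit_distances <- function(query, ref) {
  check_peaks(query, "query")
  check_peaks(ref, "ref")
  check_that(nrow(query) > 0, "`query` cistrome is empty")
  check_that(nrow(ref) > 0, "`ref` cistrome is empty")

  has_names <- !anyDuplicated(ref$name) && !anyDuplicated(query$name)
  ref_by_chrom <- split(ref[, c("summit", "name")], ref$chrom)
  ref_by_chrom <- lapply(ref_by_chrom, function(r) r[order(r$summit), ])

  res <- lapply(split(seq_len(nrow(query)), query$chrom), function(idx) {
    chrom <- query$chrom[idx[1]]
    r <- ref_by_chrom[[chrom]]
    if (is.null(r)) {
      return(tibble(row = idx, ref_name = NA_character_,
                    distance = NA_real_))
    }
    j <- nearest_index_sorted(
      query$summit[idx], r$summit,
      q_name = if (has_names) query$name[idx] else NULL,
      ref_name = if (has_names) r$name else NULL
    )
    tibble(
      row = idx,
      ref_name = ifelse(is.na(j), NA_character_, r$name[j]),
      distance = ifelse(is.na(j), NA_real_,
                        abs(query$summit[idx] - r$summit[j]))
    )
  })
  res <- dplyr::bind_rows(res)
  res <- res[order(res$row), ]
  out <- tibble(
    name = query$name, chrom = query$chrom, summit = query$summit,
    ref_name = res$ref_name, distance = res$distance
  )
  attr(out, "query_label") <- attr(query, "factor_label") %||% NA_character_
  attr(out, "ref_label") <- attr(ref, "factor_label") %||% NA_character_
  class(out) <- c("summit_distances", class(tibble()))
  out
}

#' Summarize co-binding from a distance set
#'
#' Counts proximal (distance strictly below the threshold) and
#' non-proximal query peaks, their ratio, and the median interpeak
#' distance over proximal pairs and over all pairs. Orphan query peaks
#' (`NA` distance) are excluded from all counts. When every peak is
#' proximal the ratio is `Inf` (reported, not an error). Medians use the
#' usual midpoint of the two central order statistics for even counts.
#'
#' @param dset A `summit_distances` tibble from
#'   [nearest_summit_distances()].
#' @param config A [cobind_config()].
#' @return A one-row tibble: `query_label`, `ref_label`, `n_proximal`,
#'   `n_nonproximal`, `n_orphans`, `ratio`, `median_proximal_bp`,
#'   `median_all_bp`.
#' @export
cobinding_ratio <- function(dset, config = cobind_config()) {
  check_that(nrow(dset) > 0, "`dset` is empty")
  d <- dset$distance[!is.na(dset$distance)]
  thr <- config$proximal_threshold
  n_prox <- sum(d < thr)
  n_non <- sum(d >= thr)
  tibble(
    query_label = attr(dset, "query_label") %||% NA_character_,
    ref_label = attr(dset, "ref_label") %||% NA_character_,
    n_proximal = n_prox,
    n_nonproximal = n_non,
    n_orphans = sum(is.na(dset$distance)),
    ratio = if (n_non == 0) Inf else n_prox / n_non,
    median_proximal_bp = if (n_prox > 0) median(d[d < thr]) else NA_real_,
    median_all_bp = if (length(d) > 0) median(d) else NA_real_
  )
}

#' Histogram of nearest-summit distances
#'
#' Half-open bins `[k*w, (k+1)*w)` up to `histogram_max`; distances at or
#' beyond the right edge are counted in the `overflow` attribute, so bin
#' counts plus overflow equal the number of non-orphan query peaks.
#'
#' @inheritParams cobinding_ratio
#' @return A tibble of class `cobind_histogram` with columns `bin_left`,
#'   `bin_right`, `count`; attributes `overflow`, `n_orphans`,
#'   `proximal_threshold`, and the provenance labels.
#' @export
distance_histogram <- function(dset, config = cobind_config()) {
  d <- dset$distance[!is.na(dset$distance)]
  w <- config$histogram_bin
  edges <- seq(0, config$histogram_max, by = w)
  k <- length(edges) - 1
  idx <- floor(d / w) + 1
  counts <- tabulate(idx[idx <= k], nbins = k)
  out <- tibble(bin_left = edges[-length(edges)], bin_right = edges[-1],
                count = counts)
  attr(out, "overflow") <- sum(d >= config$histogram_max)
  attr(out, "n_orphans") <- sum(is.na(dset$distance))
  attr(out, "proximal_threshold") <- config$proximal_threshold
  attr(out, "query_label") <- attr(dset, "query_label") %||% NA_character_
  attr(out, "ref_label") <- attr(dset, "ref_label") %||% NA_character_
  class(out) <- c("cobind_histogram", class(tibble()))
  out
}

#' Extract co-bound peak pairs
#'
#' One pair per query peak whose nearest reference summit lies strictly
#' within the proximal threshold; each pair records both peaks and the
#' summit separation. Output is sorted by chromosome, then query start.
#'
#' @inheritParams nearest_summit_distances
#' @param config A [cobind_config()].
#' @return A tibble with the query peak columns, `ref_`-prefixed
#'   reference peak columns, and `distance_bp`.
#' @export
extract_cobound_pairs <- function(query, ref, config = cobind_config()) {
  dset <- nearest_summit_distances(query, ref)
  prox <- !is.na(dset$distance) & dset$distance < config$proximal_threshold
  q <- as_tibble(query)[prox, peak_columns]
  d <- dset[prox, ]
  r <- as_tibble(ref)[match(d$ref_name, ref$name), peak_columns]
  names(r) <- paste0("ref_", names(r))
  out <- dplyr::bind_cols(q, r["ref_name"], r["ref_summit"],
                          r["ref_start"], r["ref_end"])
  out$distance_bp <- d$distance
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Interval overlap between two cistromes
#'
#' A peak of one cistrome is "shared" if it intersects at least one base
#' of any peak of the other. Counts are computed in both directions, so
#' `shared_a` and `shared_b` can differ (one broad peak can cover several
#' narrow ones).
#'
#' @param a,b Cistrome tibbles.
#' @return A one-row tibble: `a_only`, `b_only`, `shared_a`, `shared_b`.
#' @export
cistrome_overlap <- function(a, b) {
  check_peaks(a, "a")
  check_peaks(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_only = nrow(a), b_only = nrow(b),
                  shared_a = 0L, shared_b = 0L))
  }
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  # fully disjoint chromosome sets are a legitimate zero-overlap answer
  shared_a <- sum(suppressWarnings(GenomicRanges::countOverlaps(ga, gb)) > 0)
  shared_b <- sum(suppressWarnings(GenomicRanges::countOverlaps(gb, ga)) > 0)
  tibble(a_only = nrow(a) - shared_a, b_only = nrow(b) - shared_b,
         shared_a = shared_a, shared_b = shared_b)
}

#' Expected proximal fraction for an unstructured reference cistrome
#'
#' Under uniform random placement of reference summits at density `rho`
#' per bp, the chance that an unrelated query summit falls within
#' `threshold` bp of one is `1 - exp(-2 * threshold * rho)` (no reference
#' summit in a window of length `2 * threshold`). Subtracting this
#' background rate from an observed proximal fraction estimates the truly
#' co-bound fraction.
#'
#' @param threshold Proximity threshold in bp.
#' @param ref_density Reference summits per bp (count / genome length).
#' @return The expected background proximal fraction, in `[0, 1]`.
#' @export
background_proximal_rate <- function(threshold, ref_density) {
  1 - exp(-2 * threshold * ref_density)
}

#' Run a full co-binding analysis between two cistromes
#'
#' Convenience wrapper: computes nearest-summit distances, the co-binding
#' summary, the distance histogram and the co-bound pairs in one call,
#' optionally after fold-enrichment filtering of the query cistrome.
#'
#' @inheritParams nearest_summit_distances
#' @param config A [cobind_config()].
#' @param fe_cutoff Optional fold-enrichment cutoff applied to `query`
#'   before analysis (e.g. 30 for the high-stringency tier).
#' @return An object of class `cobind` with elements `distances`,
#'   `summary`, `histogram`, `pairs`, `config`. Use [tidy()] for the
#'   per-peak distances, [glance()] for the one-row summary, and
#'   [autoplot()] for the histogram.
#' @examples
#' cfg <- sim_config(seed = 1, n_query_peaks = 400, n_ref_peaks = 300)
#' sim <- simulate_cistromes(cfg)
#' fit <- cobind_analysis(sim$query, sim$ref)
#' glance(fit)
#' @export
cobind_analysis <- function(query, ref, config = cobind_config(),
                            fe_cutoff = NULL) {
  if (!is.null(fe_cutoff)) query <- filter_by_fe(query, fe_cutoff)
  dset <- nearest_summit_distances(query, ref)
  structure(
    list(
      distances = dset,
      summary = cobinding_ratio(dset, config),
      histogram = distance_histogram(dset, config),
      pairs = extract_cobound_pairs(query, ref, config),
      config = config
    ),
    class = "cobind"
  )
}

#' @export
print.cobind <- function(x, ...) {
  s <- x$summary
  cat("Co-binding analysis:",
      s$query_label %||% "query", "vs", s$ref_label %||% "reference", "\n")
  cat(sprintf(
    "  proximal (< %d bp): %d   non-proximal: %d   orphans: %d\n",
    as.integer(x$config$proximal_threshold),
    s$n_proximal, s$n_nonproximal, s$n_orphans
  ))
  cat(sprintf("  co-binding ratio: %.3f\n", s$ratio))
  cat(sprintf("  median interpeak distance: %.0f bp (proximal), %.0f bp (all)\n",
              s$median_proximal_bp, s$median_all_bp))
  invisible(x)
}

#' @rdname cobind_analysis
#' @param x A `cobind` object.
#' @param ... Unused.
#' @method tidy cobind
#' @export
tidy.cobind <- function(x, ...) as_tibble(x$distances)

#' @rdname cobind_analysis
#' @method glance cobind
#' @export
glance.cobind <- function(x, ...) x$summary
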