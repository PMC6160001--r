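## Peak-to-gene assignment and stratification of condition-labelled
## differential-expression gene sets by proximity to co-bound sites.

#' Read a TSS table from a BED6 file
#'
#' The name column holds the gene id; the TSS is the `start` coordinate
#' for `+` strand genes and `end - 1` for `-` strand genes. A one-bp BED
#' (`end = start + 1`) therefore encodes the TSS directly on either
#' strand.
#'
#' @param path Path to a BED6 file.
#' @return A TSS tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  check_that(all(lengths(fields) >= 6), "TSS BED needs 6 columns")
  strand <- vapply(fields, `[[`, character(1), 6)
  start <- as.numeric(vapply(fields, `[[`, character(1), 2))
  end <- as.numeric(vapply(fields, `[[`, character(1), 3))
  out <- tibble(
    gene_id = vapply(fields, `[[`, character(1), 4),
    chrom = vapply(fields, `[[`, character(1), 1),
    tss = ifelse(strand == "-", end - 1, start),
    strand = strand
  )
  check_tss(out)
  out
}

check_tss <- function(tss) {
  check_that(all(c("gene_id", "chrom", "tss", "strand") %in% names(tss)),
             "TSS table needs gene_id/chrom/tss/strand columns")
  check_that(!anyDuplicated(tss$gene_id), "gene ids must be unique")
  check_that(all(tss$strand %in% c("+", "-")), "strand must be + or -")
  invisible(tss)
}

#' Assign each peak to its nearest transcription start site
#'
#' For each peak, the gene whose TSS minimizes `|summit - tss|` on the
#' peak's chromosome. The signed distance is `summit - tss`, with the sign
#' flipped for `-` strand genes so that positive always means downstream
#' of the TSS in the direction of transcription. Equidistant TSSs are
#' broken deterministically toward the lexicographically smaller
#' `gene_id`. Peaks with no same-chromosome TSS get `NA` assignments.
#'
#' @param peaks A cistrome tibble.
#' @param tss A TSS tibble (see [read_tss()]).
#' @return A tibble with one row per peak: the peak's `name`, `chrom`,
#'   `summit`, plus `gene_id` and `distance_to_tss`.
#' @export
nearest_tss <- function(peaks, tss) {
  check_peaks(peaks)
  check_tss(tss)
  check_that(nrow(tss) > 0, "TSS table is empty")
  # sort by (tss, gene_id) so the left candidate of a tie is the
  # lexicographically smaller gene
  tss_by_chrom <- split(tss, tss$chrom)
  tss_by_chrom <- lapply(tss_by_chrom, function(t) {
    t[order(t$tss, t$gene_id), ]
  })
  res <- lapply(split(seq_len(nrow(peaks)), peaks$chrom), function(idx) {
    t <- tss_by_chrom[[peaks$chrom[idx[1]]]]
    if (is.null(t)) {
      return(tibble(row = idx, gene_id = NA_character_,
                    distance_to_tss = NA_real_))
    }
    pos <- findInterval(peaks$summit[idx], t$tss)
    n <- nrow(t)
    j <- vapply(seq_along(idx), function(i) {
      cands <- unique(pmin(pmax(c(pos[i], pos[i] + 1L), 1L), n))
      dd <- abs(peaks$summit[idx[i]] - t$tss[cands])
      # ties: order() is stable, candidates are sorted by (tss, gene_id),
      # and the smaller-gene_id tie sits first among equal distances only
      # if we re-rank by (distance, gene_id)
      cands[order(dd, t$gene_id[cands])[1]]
    }, integer(1))
    signed <- peaks$summit[idx] - t$tss[j]
    signed <- ifelse(t$strand[j] == "-", -signed, signed)
    tibble(row = idx, gene_id = t$gene_id[j], distance_to_tss = signed)
  })
  res <- dplyr::bind_rows(res)
  res <- res[order(res$row), ]
  tibble(name = peaks$name, chrom = peaks$chrom, summit = peaks$summit,
         gene_id = res$gene_id, distance_to_tss = res$distance_to_tss)
}

#' Genes near co-bound peaks
#'
#' The deduplicated set of nearest-TSS genes of the query peaks of
#' co-bound pairs (see [extract_cobound_pairs()]). This is the "close to a
#' co-bound site" gene set used to enrich condition-specific target lists.
#'
#' @param pairs Co-bound pairs from [extract_cobound_pairs()].
#' @param tss A TSS tibble.
#' @return A character vector of unique gene ids (empty for zero pairs).
#' @export
genes_near_cobound <- function(pairs, tss) {
  if (nrow(pairs) == 0) return(character())
  assigned <- nearest_tss(pairs[, peak_columns], tss)
  sort(unique(assigned$gene_id[!is.na(assigned$gene_id)]))
}

#' Read a condition-labelled differential-expression gene list
#'
#' Two-column TSV (`gene_id`, optional `direction` in `{up, down}`), one
#' file per condition.
#'
#' @param path Path to the TSV.
#' @param label Condition tag, e.g. `"wt_day"`.
#' @return A tibble with columns `label`, `gene_id`, `direction`.
#' @export
read_de_set <- function(path, label) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        col_names = FALSE, progress = FALSE)
  out <- tibble(label = label, gene_id = df[[1]],
                direction = if (ncol(df) >= 2) df[[2]] else NA_character_)
  check_that(!anyDuplicated(out$gene_id),
             paste0("duplicate gene ids in ", path))
  out
}

de_condition_labels <- c("wt_day", "wt_night", "ko_day", "ko_night")

#' Stratify time-of-day specific glucocorticoid targets by co-binding
#'
#' Reproduces the gene-set algebra used to isolate genotype- and
#' time-specific glucocorticoid targets near co-bound sites. For each
#' genotype, the day-exclusive co-bound set is
#' `(day genes \ night genes) intersect cobound_genes` (night-exclusive is
#' the mirror image). The "lost plus gained" union for a time of day
#' collects genes whose exclusive response is present in only one
#' genotype: `(WT exclusive \ KO full set) union (KO exclusive \ WT full
#' set)` — the input the original analysis fed to gene-ontology tools.
#'
#' @param de_sets A tibble with columns `label` and `gene_id` where
#'   `label` covers all four of `wt_day`, `wt_night`, `ko_day`,
#'   `ko_night` (e.g. `dplyr::bind_rows()` of four [read_de_set()]
#'   calls).
#' @param cobound_genes Character vector of co-bound-proximal gene ids,
#'   from [genes_near_cobound()].
#' @return An object of class `gc_strata`: a list with the four exclusive
#'   co-bound sets, `lost_plus_gained_day`, `lost_plus_gained_night`, and
#'   a `counts` one-row tibble ([glance()] returns it).
#' @export
stratify_gc_targets <- function(de_sets, cobound_genes) {
  check_that(all(c("label", "gene_id") %in% names(de_sets)),
             "`de_sets` needs label and gene_id columns")
  missing <- setdiff(de_condition_labels, unique(de_sets$label))
  if (length(missing) > 0) {
    abort(paste0("missing DE condition(s): ", paste(missing, collapse = ", ")))
  }
  sets <- lapply(setNames(de_condition_labels, de_condition_labels),
                 function(l) unique(de_sets$gene_id[de_sets$label == l]))
  exclusive <- function(day, night) {
    sort(intersect(setdiff(day, night), cobound_genes))
  }
  wt_day_ex <- exclusive(sets$wt_day, sets$wt_night)
  ko_day_ex <- exclusive(sets$ko_day, sets$ko_night)
  wt_night_ex <- exclusive(sets$wt_night, sets$wt_day)
  ko_night_ex <- exclusive(sets$ko_night, sets$ko_day)
  res <- list(
    wt_day_exclusive_cobound = wt_day_ex,
    ko_day_exclusive_cobound = ko_day_ex,
    wt_night_exclusive_cobound = wt_night_ex,
    ko_night_exclusive_cobound = ko_night_ex,
    lost_plus_gained_day = sort(union(setdiff(wt_day_ex, sets$ko_day),
                                      setdiff(ko_day_ex, sets$wt_day))),
    lost_plus_gained_night = sort(union(setdiff(wt_night_ex, sets$ko_night),
                                        setdiff(ko_night_ex, sets$wt_night)))
  )
  res$counts <- tibble(
    wt_day_exclusive_cobound = length(wt_day_ex),
    ko_day_exclusive_cobound = length(ko_day_ex),
    wt_night_exclusive_cobound = length(wt_night_ex),
    ko_night_exclusive_cobound = length(ko_night_ex),
    lost_plus_gained_day = length(res$lost_plus_gained_day),
    lost_plus_gained_night = length(res$lost_plus_gained_night)
  )
  structure(res, class = "gc_strata")
}

#' @export
print.gc_strata <- function(x, ...) {
  cat("Stratified glucocorticoid target sets (co-bound, time-exclusive):\n")
  print(x$counts)
  invisible(x)
}

#' @rdname stratify_gc_targets
#' @param x A `gc_strata` object.
#' @param ... Unused.
#' @method glance gc_strata
#' @export
glance.gc_strata <- function(x, ...) x$counts

#' @rdname stratify_gc_targets
#' @method tidy gc_strata
#' @export
tidy.gc_strata <- function(x, ...) {
  nm <- setdiff(names(x), "counts")
  dplyr::bind_rows(lapply(setNames(nm, nm), function(n) {
    tibble(set = n, gene_id = x[[n]])
  }))
}
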