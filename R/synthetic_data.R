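## Seeded synthetic-data generators with recorded ground truth.
##
## Every generator is a pure function of its configuration: the same
## `seed` gives byte-identical output. Stages draw from independent
## streams derived from the one seed (cistromes: seed, DE sets: seed + 1,
## coverage: seed + 2, TSS table: seed + 3, motif regions: seed + 4), so
## regenerating one stage never perturbs another.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a toy genome of two 5-Mb chromosomes carrying a
#' reference cistrome of 1000 peaks and a query cistrome of 2000 peaks of
#' which 30% are planted co-bound: their summits sit at a reference
#' summit plus a discretized Laplace offset of scale 40 bp, a heavy-tailed
#' model of summit scatter between co-bound factors. Fold enrichment is
#' lognormal with a higher location for planted co-bound peaks
#' (`meanlog = log 40`) than background (`log 15`), so high-stringency
#' filtering enriches for true co-binding. Coverage rates (5 background /
#' 15 at enriched TSSs per 100-bp bin) give a threefold planted
#' acetylation signal.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param genome A [genome_layout()].
#' @param n_ref_peaks,n_query_peaks Peak counts for the two cistromes.
#' @param cobound_fraction Fraction of query peaks planted next to a
#'   reference summit, in `[0, 1]`.
#' @param offset_scale Laplace scale (bp) of planted summit offsets.
#' @param fe_meanlog_cobound,fe_meanlog_background,fe_sdlog Lognormal
#'   fold-enrichment parameters for planted and background query peaks
#'   (reference peaks draw from the background law).
#' @param peak_halfwidth Half-width (bp) of peak intervals around each
#'   summit; irrelevant to summit statistics.
#' @param n_genes Number of TSS records on the toy genome.
#' @param n_de Genes per differential-expression condition set.
#' @param de_overlap Fraction of co-bound-proximal genes seeded into each
#'   genotype's day set.
#' @param night_share Fraction of a genotype's seeded co-bound day genes
#'   also placed in its night set (making them non-exclusive).
#' @param coverage_lambda_bg,coverage_lambda_tss Poisson rates per
#'   100-bp bin for background coverage and for bins within 500 bp of an
#'   enriched TSS.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome = genome_layout(c("chr1", "chr2"),
                                              c(5e6, 5e6)),
                       n_ref_peaks = 1000,
                       n_query_peaks = 2000,
                       cobound_fraction = 0.3,
                       offset_scale = 40,
                       fe_meanlog_cobound = log(40),
                       fe_meanlog_background = log(15),
                       fe_sdlog = 0.6,
                       peak_halfwidth = 150,
                       n_genes = 1000,
                       n_de = 300,
                       de_overlap = 0.6,
                       night_share = 0.2,
                       coverage_lambda_bg = 5,
                       coverage_lambda_tss = 15) {
  check_that(seed == round(seed), "`seed` must be an integer")
  check_that(n_ref_peaks > 0 && n_query_peaks > 0 && n_genes > 0 &&
               n_de > 0, "counts must be positive")
  check_that(cobound_fraction >= 0 && cobound_fraction <= 1,
             "`cobound_fraction` must be in [0, 1]")
  check_that(de_overlap >= 0 && de_overlap <= 1,
             "`de_overlap` must be in [0, 1]")
  check_that(offset_scale > 0 && coverage_lambda_bg > 0 &&
               coverage_lambda_tss > 0, "scales and rates must be positive")
  structure(
    list(seed = as.integer(seed), genome = genome,
         n_ref_peaks = n_ref_peaks, n_query_peaks = n_query_peaks,
         cobound_fraction = cobound_fraction, offset_scale = offset_scale,
         fe_meanlog_cobound = fe_meanlog_cobound,
         fe_meanlog_background = fe_meanlog_background,
         fe_sdlog = fe_sdlog, peak_halfwidth = peak_halfwidth,
         n_genes = n_genes, n_de = n_de, de_overlap = de_overlap,
         night_share = night_share,
         coverage_lambda_bg = coverage_lambda_bg,
         coverage_lambda_tss = coverage_lambda_tss),
    class = "sim_config"
  )
}

# sample chromosomes proportional to length, positions uniform within
# [halfwidth, length - halfwidth)
sample_positions <- function(n, genome, halfwidth) {
  chrom <- sample(genome$chrom, n, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  len <- setNames(genome$length, genome$chrom)
  pos <- floor(runif(n, halfwidth, len[chrom] - halfwidth))
  tibble(chrom = chrom, summit = pos)
}

rlaplace_discrete <- function(n, scale) {
  round(sample(c(-1, 1), n, replace = TRUE) * rexp(n, rate = 1 / scale))
}

peaks_from_summits <- function(df, name_prefix, fe, halfwidth) {
  tibble(
    chrom = df$chrom,
    start = df$summit - halfwidth,
    end = df$summit + halfwidth,
    name = sprintf("%s%05d", name_prefix, seq_len(nrow(df))),
    fold_enrichment = fe,
    summit = df$summit
  )
}

#' Simulate a reference and a query cistrome with planted co-binding
#'
#' Reference summits are uniform over the genome. A planted fraction of
#' query summits sits at a uniformly chosen reference summit plus a
#' signed discretized-Laplace offset (clipped to chromosome bounds); the
#' remaining query summits are uniform. Ground truth records, per query
#' peak, whether it was planted, its offset and its partner reference
#' peak.
#'
#' @param config A [sim_config()].
#' @return A list with elements `ref` and `query` (cistrome tibbles) and
#'   `truth` (list; `truth$query` has columns `name`, `chrom`, `summit`,
#'   `is_cobound`, `offset`, `ref_name`).
#' @export
simulate_cistromes <- function(config) {
  g <- config$genome
  hw <- config$peak_halfwidth
  total <- sum(g$length)
  if ((config$n_ref_peaks + config$n_query_peaks) * 300 > total) {
    abort("genome too small for the requested peak count at 300 bp spacing")
  }
  withr::with_seed(config$seed, {
    ref_pos <- sample_positions(config$n_ref_peaks, g, hw)
    ref_pos <- ref_pos[order(ref_pos$chrom, ref_pos$summit), ]
    ref <- peaks_from_summits(
      ref_pos, "ref_",
      rlnorm(config$n_ref_peaks, config$fe_meanlog_background,
             config$fe_sdlog),
      hw
    )

    n_q <- config$n_query_peaks
    n_planted <- round(config$cobound_fraction * n_q)
    len <- setNames(g$length, g$chrom)
    planted_ref <- if (n_planted > 0) {
      sample.int(nrow(ref), n_planted, replace = TRUE)
    } else integer(0)
    offsets <- rlaplace_discrete(n_planted, config$offset_scale)
    planted_summit <- pmin(pmax(ref$summit[planted_ref] + offsets, hw),
                           len[ref$chrom[planted_ref]] - hw)
    bg <- sample_positions(n_q - n_planted, g, hw)
    q_pos <- tibble(
      chrom = c(ref$chrom[planted_ref], bg$chrom),
      summit = c(planted_summit, bg$summit)
    )
    fe <- c(
      rlnorm(n_planted, config$fe_meanlog_cobound, config$fe_sdlog),
      rlnorm(n_q - n_planted, config$fe_meanlog_background, config$fe_sdlog)
    )
    query <- peaks_from_summits(q_pos, "query_", fe, hw)
    truth_query <- tibble(
      name = query$name, chrom = query$chrom, summit = query$summit,
      is_cobound = c(rep(TRUE, n_planted), rep(FALSE, n_q - n_planted)),
      offset = c(offsets, rep(NA_real_, n_q - n_planted)),
      ref_name = c(ref$name[planted_ref],
                   rep(NA_character_, n_q - n_planted))
    )
    list(
      ref = new_cistrome(ref, factor_label = "reference",
                         source_label = "simulated"),
      query = new_cistrome(query, factor_label = "query",
                           source_label = "simulated"),
      truth = list(query = truth_query, config = config)
    )
  })
}

#' Simulate a TSS table on the toy genome
#'
#' Uniform TSS positions with random strands and unique gene ids.
#'
#' @param config A [sim_config()].
#' @return A TSS tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_tss <- function(config) {
  g <- config$genome
  withr::with_seed(config$seed + 3L, {
    pos <- sample_positions(config$n_genes, g, 0)
    tibble(
      gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
      chrom = pos$chrom,
      tss = pos$summit,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
    )
  })
}

#' Simulate four condition-labelled differential-expression gene sets
#'
#' Seeds each genotype's day set with a `de_overlap` fraction of the
#' genes nearest to planted co-bound query peaks, filled to `n_de` genes
#' with random non-co-bound genes; a `night_share` fraction of the seeded
#' co-bound genes is also placed in the night set so that exclusive sets
#' are nontrivial. The generator records its own set algebra (co-bound
#' gene list and all exclusive/lost-plus-gained counts) in the returned
#' truth for cross-checking against [stratify_gc_targets()].
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_cistromes()].
#' @param tss TSS tibble from [simulate_tss()].
#' @return A list: `de_sets` (tibble with `label`, `gene_id`,
#'   `direction`) and updated `truth` gaining `cobound_genes`,
#'   `strata_counts`, and `enriched_genes` (the WT day set, used by
#'   [simulate_coverage()]).
#' @export
simulate_de_sets <- function(config, truth, tss) {
  planted <- truth$query[truth$query$is_cobound, ]
  cobound_genes <- if (nrow(planted) > 0) {
    peaks <- tibble(chrom = planted$chrom, start = planted$summit,
                    end = planted$summit + 1, name = planted$name,
                    fold_enrichment = NA_real_, summit = planted$summit)
    sort(unique(nearest_tss(peaks, tss)$gene_id))
  } else character()
  all_genes <- tss$gene_id
  pool <- setdiff(all_genes, cobound_genes)
  n_seed <- round(config$de_overlap * length(cobound_genes))
  n_fill <- config$n_de - min(n_seed, config$n_de)
  if (n_fill > length(pool)) {
    abort("`de_overlap`/`n_de` demand more genes than the TSS table holds")
  }
  withr::with_seed(config$seed + 1L, {
    one_genotype <- function() {
      seeded <- if (n_seed > 0) {
        sample(cobound_genes, min(n_seed, length(cobound_genes)))
      } else character()
      day <- c(seeded, sample(pool, n_fill))
      shared <- if (length(seeded) > 0) {
        sample(seeded, round(config$night_share * length(seeded)))
      } else character()
      night <- c(shared, sample(setdiff(pool, day),
                                config$n_de - length(shared)))
      list(day = day, night = night)
    }
    wt <- one_genotype()
    ko <- one_genotype()
    sets <- list(wt_day = wt$day, wt_night = wt$night,
                 ko_day = ko$day, ko_night = ko$night)
    de_sets <- dplyr::bind_rows(lapply(names(sets), function(l) {
      tibble(label = l, gene_id = sets[[l]],
             direction = sample(c("up", "down"), length(sets[[l]]),
                                replace = TRUE))
    }))
  })
  # generator-side bookkeeping of the expected stratification
  ex <- function(day, night) {
    sort(intersect(setdiff(day, night), cobound_genes))
  }
  wt_day_ex <- ex(sets$wt_day, sets$wt_night)
  ko_day_ex <- ex(sets$ko_day, sets$ko_night)
  wt_night_ex <- ex(sets$wt_night, sets$wt_day)
  ko_night_ex <- ex(sets$ko_night, sets$ko_day)
  truth$cobound_genes <- cobound_genes
  truth$strata_counts <- tibble(
    wt_day_exclusive_cobound = length(wt_day_ex),
    ko_day_exclusive_cobound = length(ko_day_ex),
    wt_night_exclusive_cobound = length(wt_night_ex),
    ko_night_exclusive_cobound = length(ko_night_ex),
    lost_plus_gained_day = length(union(setdiff(wt_day_ex, sets$ko_day),
                                        setdiff(ko_day_ex, sets$wt_day))),
    lost_plus_gained_night = length(union(
      setdiff(wt_night_ex, sets$ko_night),
      setdiff(ko_night_ex, sets$wt_night)
    ))
  )
  truth$enriched_genes <- sets$wt_day
  list(de_sets = de_sets, truth = truth)
}

#' Simulate binned coverage with planted TSS enrichment
#'
#' Per-bin counts are Poisson with the background rate, except bins whose
#' start lies within 500 bp of an enriched gene's TSS, which draw from
#' the enriched rate.
#'
#' @param config A [sim_config()].
#' @param truth Truth list carrying `enriched_genes` (from
#'   [simulate_de_sets()]), or `NULL` with `enriched_genes` given
#'   directly.
#' @param tss TSS tibble.
#' @param enriched_genes Optional explicit gene list overriding the
#'   truth's.
#' @param bin_width Bin width in bp (default 100).
#' @return A `coverage_track` tibble.
#' @export
simulate_coverage <- function(config, truth, tss, enriched_genes = NULL,
                              bin_width = 100) {
  genes <- enriched_genes %||% truth$enriched_genes %||% character()
  g <- config$genome
  enr <- tss[tss$gene_id %in% genes, ]
  withr::with_seed(config$seed + 2L, {
    out <- dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
      nbins <- ceiling(g$length[i] / bin_width)
      counts <- rpois(nbins, config$coverage_lambda_bg)
      t <- enr[enr$chrom == g$chrom[i], ]
      if (nrow(t) > 0) {
        bt <- floor(t$tss / bin_width)
        hot <- unique(unlist(lapply(bt, function(b) (b - 5):(b + 4))))
        hot <- hot[hot >= 0 & hot < nbins]
        counts[hot + 1] <- rpois(length(hot), config$coverage_lambda_tss)
      }
      tibble(chrom = g$chrom[i],
             start = (seq_len(nbins) - 1) * bin_width,
             count = counts)
    }))
    new_coverage_track(out, bin_width)
  })
}

#' Simulate target and background regions with a planted motif
#'
#' Random uniform-composition sequences; a planted fraction of each set
#' receives one embedded draw from the motif at a random offset.
#'
#' @param motif A [pwm()] to plant.
#' @param n_targets,n_background Region counts.
#' @param region_length Sequence length in bp.
#' @param plant_frac_target,plant_frac_background Planted fractions.
#' @param seed Integer seed.
#' @return A list: `targets`, `background` (named character vectors) and
#'   `truth` (planting flags per region).
#' @export
simulate_motif_sequences <- function(motif, n_targets = 100,
                                     n_background = 100,
                                     region_length = 200,
                                     plant_frac_target = 0.4,
                                     plant_frac_background = 0.05,
                                     seed = 1) {
  L <- ncol(motif$matrix)
  check_that(region_length >= L, "regions shorter than the motif")
  withr::with_seed(as.integer(seed) + 4L, {
    make_set <- function(n, frac, prefix) {
      seqs <- vapply(seq_len(n), function(i) {
        paste(sample(DNA_BASES, region_length, replace = TRUE),
              collapse = "")
      }, character(1))
      planted <- seq_len(n) <= round(frac * n)
      for (i in which(planted)) {
        ins <- paste(apply(motif$matrix, 2, function(p) {
          sample(DNA_BASES, 1, prob = p)
        }), collapse = "")
        at <- sample.int(region_length - L + 1, 1)
        substr(seqs[i], at, at + L - 1) <- ins
      }
      list(seqs = setNames(seqs, sprintf("%s%04d", prefix, seq_len(n))),
           planted = planted)
    }
    tg <- make_set(n_targets, plant_frac_target, "target_")
    bg <- make_set(n_background, plant_frac_background, "bg_")
    list(targets = tg$seqs, background = bg$seqs,
         truth = list(target_planted = tg$planted,
                      background_planted = bg$planted))
  })
}
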