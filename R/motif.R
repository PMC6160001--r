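## Known-motif scanning and observed/expected enrichment ranking.
##
## A position weight matrix is stored as a 4 x L probability matrix
## (rows A, C, G, T). Scanning scores log2-odds against a background
## base composition at every offset on both strands; a hit is a score at
## or above the motif's threshold (by default 80% of the maximal
## attainable score).

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param motif_id Identifier for the motif.
#' @param matrix A 4 x L numeric matrix of per-position base
#'   probabilities, rows in order A, C, G, T; each column must sum to 1
#'   (within 1e-6). Columns are renormalized exactly.
#' @param background Background base frequencies (length 4, order
#'   A, C, G, T); default uniform.
#' @param score_threshold Log2-odds hit threshold; default `NULL` means
#'   80% of the maximal attainable score, computed at scan time.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4),
                score_threshold = NULL) {
  check_that(is.matrix(matrix) && nrow(matrix) == 4,
             "`matrix` must be a 4-row matrix (A, C, G, T)")
  check_that(ncol(matrix) >= 4, "motif length must be >= 4")
  sums <- colSums(matrix)
  check_that(all(abs(sums - 1) < 1e-6),
             "each PWM column must sum to 1 (within 1e-6)")
  matrix <- sweep(matrix, 2, sums, "/")
  rownames(matrix) <- DNA_BASES
  check_that(length(background) == 4 && all(background > 0),
             "`background` must be 4 positive frequencies")
  structure(
    list(motif_id = motif_id, matrix = matrix,
         background = background / sum(background),
         score_threshold = score_threshold),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "(", ncol(x$matrix), "bp ) consensus:",
      pwm_consensus(x), "\n")
  invisible(x)
}

# log2-odds score matrix; zero probabilities score -Inf (a mismatch to a
# hard consensus position can never reach threshold)
pwm_score_matrix <- function(x) {
  log2(x$matrix / x$background)
}

pwm_max_score <- function(x) {
  sum(apply(pwm_score_matrix(x), 2, max))
}

pwm_threshold <- function(x) {
  x$score_threshold %||% (0.8 * pwm_max_score(x))
}

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' IUPAC consensus string of a PWM
#'
#' A position with one base at probability `>= single_cutoff` (default
#' 0.6) collapses to that base; otherwise all bases at probability
#' `>= degenerate_cutoff` (default 0.25) collapse to their IUPAC
#' degenerate code (`N` if none qualifies). Used to detect duplicate
#' motifs deterministically.
#'
#' @param x A [pwm()].
#' @param single_cutoff,degenerate_cutoff Probability cutoffs.
#' @return A character consensus string.
#' @export
pwm_consensus <- function(x, single_cutoff = 0.6, degenerate_cutoff = 0.25) {
  paste(apply(x$matrix, 2, function(p) {
    if (max(p) >= single_cutoff) return(DNA_BASES[which.max(p)])
    key <- paste(DNA_BASES[p >= degenerate_cutoff], collapse = "")
    if (key == "") "N" else IUPAC_CODES[[key]]
  }), collapse = "")
}

revcomp <- function(seqs) {
  chartr("ACGTN", "TGCAN", vapply(seqs, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# score one strand of one sequence at every offset; NA where an N falls
# under the motif
scan_one_strand <- function(seq_chars, sm) {
  L <- ncol(sm)
  n <- length(seq_chars)
  if (n < L) return(numeric(0))
  idx <- match(seq_chars, DNA_BASES)  # N -> NA
  vapply(seq_len(n - L + 1), function(o) {
    cols <- idx[o:(o + L - 1)]
    if (anyNA(cols)) return(NA_real_)
    sum(sm[cbind(cols, seq_len(L))])
  }, numeric(1))
}

#' Scan sequences for PWM hits on both strands
#'
#' Scores every offset of every sequence and of its reverse complement
#' with the motif's log2-odds matrix; a hit is a score `>=` the motif
#' threshold. A genomic window counts once even if both strands score
#' above threshold (as a palindromic motif does), so `n_hits` is the
#' number of distinct windows with a hit on either strand. Offsets
#' containing `N` are skipped. Sequences shorter than the motif yield
#' zero hits.
#'
#' @param sequences Named character vector of DNA sequences over
#'   `A, C, G, T, N`.
#' @param motif A [pwm()].
#' @return A tibble with columns `seq_name` and `n_hits` (both strands
#'   combined), one row per input sequence.
#' @export
scan_pwm <- function(sequences, motif) {
  check_that(inherits(motif, "pwm"), "`motif` must be a pwm object")
  nm <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  check_that(!any(bad), "sequences must be over A, C, G, T, N")
  sm <- pwm_score_matrix(motif)
  thr <- pwm_threshold(motif)
  L <- ncol(sm)
  hits <- vapply(seq_along(sequences), function(i) {
    fwd <- strsplit(sequences[[i]], "")[[1]]
    rev <- strsplit(revcomp(sequences[[i]]), "")[[1]]
    sf <- scan_one_strand(fwd, sm)
    sr <- scan_one_strand(rev, sm)
    # reverse-strand offset o maps to forward window n - L - o + 2
    sr_mapped <- if (length(sr) > 0) base::rev(sr) else sr
    sum((!is.na(sf) & sf >= thr) | (!is.na(sr_mapped) & sr_mapped >= thr))
  }, integer(1))
  tibble(seq_name = nm, n_hits = hits)
}

#' Observed/expected enrichment of one motif
#'
#' Observed fraction = fraction of target regions with at least one hit;
#' expected fraction = the same over background regions. The %Ratio is
#' observed/expected (`Inf` when the expected fraction is zero but the
#' observed is not) and coverage is the observed fraction as a
#' percentage.
#'
#' @param target_hits,background_hits Per-region hit counts from
#'   [scan_pwm()] (tibbles with `n_hits`), or bare integer vectors.
#' @param motif_id Identifier for the output row.
#' @param consensus Optional consensus string (used for duplicate
#'   removal by [filter_and_rank_motifs()]).
#' @return A one-row tibble: `motif_id`, `consensus`,
#'   `observed_fraction`, `expected_fraction`, `percent_ratio`,
#'   `coverage`.
#' @export
motif_coverage_and_ratio <- function(target_hits, background_hits,
                                     motif_id = NA_character_,
                                     consensus = NA_character_) {
  th <- if (is.data.frame(target_hits)) target_hits$n_hits else target_hits
  bh <- if (is.data.frame(background_hits)) background_hits$n_hits else background_hits
  check_that(length(th) > 0 && length(bh) > 0,
             "need at least one target and one background region")
  obs <- mean(th >= 1)
  exp <- mean(bh >= 1)
  tibble(
    motif_id = motif_id, consensus = consensus,
    observed_fraction = obs, expected_fraction = exp,
    percent_ratio = if (exp == 0) {
      if (obs == 0) NA_real_ else Inf
    } else obs / exp,
    coverage = 100 * obs
  )
}

#' Scan a motif library against target and background regions
#'
#' Runs [scan_pwm()] for every motif over both region sets and stacks
#' the [motif_coverage_and_ratio()] rows into a rank table.
#'
#' @param targets,background Named character vectors of region
#'   sequences.
#' @param motifs A list of [pwm()] objects.
#' @return A motif rank table (tibble), unsorted and unfiltered; feed to
#'   [filter_and_rank_motifs()].
#' @export
motif_enrichment <- function(targets, background, motifs) {
  check_that(length(motifs) > 0, "`motifs` must be non-empty")
  dplyr::bind_rows(lapply(motifs, function(m) {
    motif_coverage_and_ratio(
      scan_pwm(targets, m), scan_pwm(background, m),
      motif_id = m$motif_id, consensus = pwm_consensus(m)
    )
  }))
}

#' Filter and rank a motif enrichment table
#'
#' Applies the reporting rule used for known-motif output: rows with
#' `percent_ratio < min_ratio` (default 1.5) or `coverage < min_coverage`
#' (default 5, in percent) are removed; among duplicate motifs (identical
#' IUPAC consensus) only the highest-%Ratio row is kept; the survivors
#' are sorted by descending %Ratio. Idempotent.
#'
#' @param table A motif rank table from [motif_enrichment()] or with the
#'   same columns.
#' @param min_ratio Minimum %Ratio to keep (default 1.5).
#' @param min_coverage Minimum coverage in percent (default 5).
#' @param dedup Remove duplicate-consensus motifs (default TRUE; rows
#'   with `NA` consensus are never treated as duplicates).
#' @return The filtered, ranked tibble (possibly empty).
#' @export
filter_and_rank_motifs <- function(table, min_ratio = 1.5, min_coverage = 5,
                                   dedup = TRUE) {
  check_that(all(c("percent_ratio", "coverage") %in% names(table)),
             "`table` needs percent_ratio and coverage columns")
  out <- table[!is.na(table$percent_ratio) &
                 table$percent_ratio >= min_ratio &
                 table$coverage >= min_coverage, , drop = FALSE]
  out <- out[order(-out$percent_ratio), , drop = FALSE]
  if (dedup && "consensus" %in% names(out) && nrow(out) > 0) {
    dup <- duplicated(out$consensus) & !is.na(out$consensus)
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Read motifs from JASPAR- or HOMER-style text
#'
#' Two layouts are recognized per record. JASPAR: a `>id name` header
#' followed by four rows `A [ 1 2 ... ]` (counts or frequencies, rows in
#' any A/C/G/T order). HOMER: a `>consensus id log-odds-threshold` header
#' followed by one row of four tab-separated probabilities per motif
#' position. Count matrices are converted to column-normalized
#' probabilities.
#'
#' @param path Path to the motif text file.
#' @return A named list of [pwm()] objects.
#' @export
read_motifs <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  check_that(length(starts) > 0, "no motif records (no '>' headers) found")
  ends <- c(starts[-1] - 1, length(lines))
  motifs <- lapply(seq_along(starts), function(i) {
    header <- strsplit(sub("^>", "", lines[starts[i]]), "[ \t]+")[[1]]
    body <- lines[(starts[i] + 1):ends[i]]
    if (all(grepl("^[ACGT]", body)) && length(body) == 4) {
      # JASPAR-style: lettered rows with bracketed numbers
      rows <- lapply(body, function(b) {
        nums <- regmatches(b, gregexpr("[0-9.eE+-]+", b))[[1]]
        as.numeric(nums)
      })
      bases <- substr(body, 1, 1)
      mat <- do.call(rbind, rows)[match(DNA_BASES, bases), , drop = FALSE]
      mat <- sweep(mat, 2, colSums(mat), "/")
      id <- if (length(header) >= 2) header[2] else header[1]
      pwm(id, mat)
    } else {
      # HOMER-style: one probability row per position
      mat <- t(do.call(rbind, lapply(strsplit(body, "[ \t]+"), as.numeric)))
      check_that(nrow(mat) == 4, paste0("bad motif body under ",
                                        lines[starts[i]]))
      id <- if (length(header) >= 2) header[2] else header[1]
      thr <- if (length(header) >= 3) {
        suppressWarnings(as.numeric(header[3]))
      } else NULL
      if (!is.null(thr) && is.na(thr)) thr <- NULL
      pwm(id, mat, score_threshold = thr)
    }
  })
  setNames(motifs, vapply(motifs, `[[`, character(1), "motif_id"))
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  check_that(file.exists(path), paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  check_that(length(starts) > 0, "no FASTA records found")
  ends <- c(starts[-1] - 1, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    paste(lines[(starts[i] + 1):ends[i]], collapse = "")
  }, character(1))
  setNames(toupper(seqs), sub("^>\\s*", "", sub("\\s.*$", "", lines[starts])))
}
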