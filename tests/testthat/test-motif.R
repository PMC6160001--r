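consensus_pwm <- function(consensus, id = "cons") {
  bases <- c("A", "C", "G", "T")
  cols <- vapply(strsplit(consensus, "")[[1]], function(b) {
    v <- rep(0, 4); v[match(b, bases)] <- 1; v
  }, numeric(4))
  pwm(id, cols)
}

test_that("a hard consensus motif hits exactly where it occurs", {
  m <- consensus_pwm("ACGT")
  expect_equal(scan_pwm(c(s = "TTACGTTT"), m)$n_hits, 1)
  expect_equal(scan_pwm(c(s = "AAAAAAAA"), m)$n_hits, 0)
  expect_equal(scan_pwm(c(s = "ACG"), m)$n_hits, 0)  # shorter than motif
  # non-palindromic motif is found via its reverse complement
  m2 <- consensus_pwm("AAACGTCA")
  expect_equal(scan_pwm(c(s = "TTTGACGTTTCCC"), m2)$n_hits, 1)
  # N-containing windows are skipped
  expect_equal(scan_pwm(c(s = "TTACNTTT"), m)$n_hits, 0)
})

test_that("scanning matches a naive per-offset rescoring oracle on random
           sequences", {
  withr::local_seed(41)
  m <- sharp_pwm()
  thr <- 0.8 * sum(apply(log2(m$matrix / m$background), 2, max))
  seqs <- random_dna(60, 200)
  # plant an exact consensus in a third of them
  for (i in 1:20) substr(seqs[i], 50, 59) <- "ACGTTGCACT"
  got <- scan_pwm(setNames(seqs, paste0("s", 1:60)), m)$n_hits
  want <- vapply(seqs, brute_force_pwm_hits, numeric(1), m = m,
                 threshold = thr)
  expect_equal(got, unname(as.integer(want)))
})

test_that("scanning is strand-symmetric", {
  withr::local_seed(43)
  m <- sharp_pwm()
  seqs <- random_dna(30, 150)
  rc <- chartr("ACGT", "TGCA", vapply(seqs, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1)))
  expect_equal(scan_pwm(seqs, m)$n_hits, scan_pwm(rc, m)$n_hits)
})

test_that("observed/expected rows compute %Ratio and coverage", {
  row <- motif_coverage_and_ratio(c(rep(1, 10), rep(0, 90)),
                                  c(rep(1, 2), rep(0, 98)), "m1")
  expect_equal(row$percent_ratio, 5)
  expect_equal(row$coverage, 10)

  expect_equal(motif_coverage_and_ratio(c(1, 0), c(1, 0))$percent_ratio, 1)
  expect_equal(motif_coverage_and_ratio(c(1, 1), c(0, 0))$percent_ratio, Inf)
  expect_error(motif_coverage_and_ratio(integer(), c(1)), "at least one")
})

test_that("a motif scanned against itself as background has %Ratio 1", {
  withr::local_seed(47)
  m <- sharp_pwm()
  seqs <- random_dna(40, 120)
  for (i in 1:10) substr(seqs[i], 20, 29) <- "ACGTTGCACT"
  hits <- scan_pwm(seqs, m)
  expect_equal(motif_coverage_and_ratio(hits, hits)$percent_ratio, 1)
})

test_that("motif table filtering applies the ratio and coverage cutoffs", {
  tab <- tibble::tibble(
    motif_id = c("m1", "m2", "m3"),
    consensus = c("AAAA", "CCCC", "GGGG"),
    observed_fraction = c(0.10, 0.20, 0.04),
    expected_fraction = c(0.02, 0.142857, 0.02),
    percent_ratio = c(5.0, 1.4, 2.0),
    coverage = c(10, 20, 4)
  )
  out <- filter_and_rank_motifs(tab)
  expect_equal(out$motif_id, "m1")  # 1.4 fails ratio, 4% fails coverage

  expect_equal(nrow(filter_and_rank_motifs(tab[0, ])), 0)
  # idempotence
  expect_identical(filter_and_rank_motifs(out), out)
})

test_that("duplicate-consensus motifs keep only the higher %Ratio row and
           output is ranked", {
  tab <- tibble::tibble(
    motif_id = c("a", "b", "c"),
    consensus = c("ACGT", "ACGT", "TTTT"),
    observed_fraction = 0.5, expected_fraction = 0.1,
    percent_ratio = c(2.0, 3.0, 2.5),
    coverage = 50
  )
  out <- filter_and_rank_motifs(tab)
  expect_equal(out$motif_id, c("b", "c"))
  expect_equal(out$percent_ratio, c(3.0, 2.5))
})

test_that("planted-motif enrichment recovers the planted %Ratio", {
  m <- sharp_pwm()
  sq <- simulate_motif_sequences(m, n_targets = 200, n_background = 200,
                                 plant_frac_target = 0.4,
                                 plant_frac_background = 0.05, seed = 7)
  tab <- motif_enrichment(sq$targets, sq$background, list(m))
  # planted in 40% of targets vs 5% of background: ratio near 8
  expect_gt(tab$percent_ratio, 5)
  expect_lt(tab$percent_ratio, 12)
  expect_true(all(scan_pwm(sq$targets[sq$truth$target_planted],
                           m)$n_hits >= 0))
})

test_that("IUPAC consensus collapses probabilities deterministically", {
  mat <- cbind(c(0.7, 0.1, 0.1, 0.1),    # A
               c(0.4, 0.4, 0.1, 0.1),    # A or C -> M
               c(0.25, 0.25, 0.25, 0.25), # N
               c(0.1, 0.1, 0.1, 0.7))    # T
  expect_equal(pwm_consensus(pwm("x", mat)), "AMNT")
})

test_that("JASPAR- and HOMER-style motif text parse to equivalent PWMs", {
  f <- withr::local_tempfile()
  writeLines(c(
    ">MA0001 motifA",
    "A [ 8 0 0 2 ]",
    "C [ 0 8 0 2 ]",
    "G [ 0 0 8 2 ]",
    "T [ 0 0 0 2 ]",
    ">ACGT motifB 6.0",
    "1.0\t0.0\t0.0\t0.0",
    "0.0\t1.0\t0.0\t0.0",
    "0.0\t0.0\t1.0\t0.0",
    "0.0\t0.0\t0.0\t1.0"
  ), f)
  ms <- read_motifs(f)
  expect_named(ms, c("motifA", "motifB"))
  expect_equal(ms$motifA$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(ms$motifA$matrix[, 4], c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25))
  expect_equal(ms$motifB$score_threshold, 6)
  expect_equal(pwm_consensus(ms$motifB), "ACGT")
})

test_that("FASTA sequences load with their names", {
  f <- withr::local_tempfile()
  writeLines(c(">r1 some description", "ACGT", "ACGT", ">r2", "ttnn"), f)
  seqs <- read_fasta(f)
  expect_equal(seqs, c(r1 = "ACGTACGT", r2 = "TTNN"))
})
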