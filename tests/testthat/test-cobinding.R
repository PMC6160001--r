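test_that("fold-enrichment stringency filtering is inclusive at the cutoff", {
  cis <- make_cistrome("chr1", c(100, 500, 900), fe = c(5, 30, 31))
  expect_equal(filter_by_fe(cis, 30)$name, c("pk0002", "pk0003"))
  expect_equal(nrow(filter_by_fe(cis, 0)), 3)       # identity at zero
  expect_equal(nrow(filter_by_fe(cis, 100)), 0)     # empty is fine
  cis$fold_enrichment[2] <- NA
  expect_error(filter_by_fe(cis, 30), "pk0002")
})

test_that("pooling concatenates peaks as a multiset", {
  a <- make_cistrome("chr1", c(100, 200, 300))
  b <- make_cistrome("chr1", c(300, 400, 500, 600))
  pooled <- pool_cistromes(list(a, b), label = "both")
  expect_equal(nrow(pooled), 7)  # the duplicate coordinate is retained
  expect_equal(attr(pooled, "factor_label"), "both")
  expect_equal(nrow(pool_cistromes(list(a))), nrow(a))
  expect_error(pool_cistromes(list()), "non-empty")
})

test_that("nearest distances to a pooled reference equal the elementwise
           minimum over component references", {
  withr::local_seed(11)
  for (rep in 1:5) {
    q <- random_cistrome(50, prefix = "q")
    r1 <- random_cistrome(50, prefix = "r")
    r2 <- random_cistrome(50, prefix = "s")
    d_pooled <- nearest_summit_distances(q, pool_cistromes(list(r1, r2)))
    d1 <- nearest_summit_distances(q, r1)$distance
    d2 <- nearest_summit_distances(q, r2)$distance
    expect_equal(d_pooled$distance, pmin(d1, d2, na.rm = TRUE))
  }
})

test_that("nearest-summit distances follow the definition on small cases", {
  q <- make_cistrome("chr1", c(100, 500), name = c("q1", "q2"))
  r <- make_cistrome("chr1", c(120, 1000), name = c("r1", "r2"))
  d <- nearest_summit_distances(q, r)
  expect_equal(d$distance, c(20, 380))  # |500 - 120|, r1 is nearer than r2
  expect_equal(d$ref_name, c("r1", "r1"))

  # query on a chromosome with no reference peak becomes an orphan
  q2 <- make_cistrome(c("chr1", "chr2"), c(100, 100), name = c("q1", "q2"))
  d2 <- nearest_summit_distances(q2, r)
  expect_equal(d2$distance, c(20, NA))
  expect_error(nearest_summit_distances(q, r[0, ]), "empty")
})

test_that("indexed nearest-summit distances match the all-pairs brute
           force on random instances", {
  withr::local_seed(42)
  for (rep in 1:10) {
    q <- random_cistrome(sample(50:300, 1), prefix = "q",
                         max_pos = sample(c(1e4, 1e6), 1))
    r <- random_cistrome(sample(50:300, 1), prefix = "r",
                         max_pos = 1e6)
    d <- nearest_summit_distances(q, r)
    expect_equal(d$distance, brute_force_nearest(q, r))
  }
})

test_that("nearest-summit distances agree with GenomicRanges
           distanceToNearest", {
  withr::local_seed(45)
  q <- random_cistrome(200, prefix = "q", max_pos = 1e5)
  r <- random_cistrome(150, prefix = "r", max_pos = 1e5)
  d <- nearest_summit_distances(q, r)$distance
  gq <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$summit, width = 1))
  gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$summit, width = 1))
  dtn <- GenomicRanges::distanceToNearest(gq, gr)
  # GRanges distance is the gap: |a - b| - 1 for separated width-1 ranges
  expect_equal(pmax(d[S4Vectors::queryHits(dtn)] - 1, 0),
               as.numeric(S4Vectors::mcols(dtn)$distance))
})

test_that("self-comparison excludes only the same-name reference peak", {
  cis <- make_cistrome("chr1", c(100, 150, 400), name = c("a", "b", "c"))
  d <- nearest_summit_distances(cis, cis)
  expect_equal(d$distance, c(50, 50, 250))  # never the zero self-match
  # a same-position peak under a different name is a genuine zero
  other <- make_cistrome("chr1", c(100, 900), name = c("x", "y"))
  expect_equal(nearest_summit_distances(cis, other)$distance[1], 0)
})

test_that("co-binding counts split strictly at the threshold", {
  d <- structure(
    tibble::tibble(name = paste0("q", 1:5), chrom = "chr1", summit = 1:5,
                   ref_name = "r", distance = c(20, 50, 119, 121, 400)),
    class = c("summit_distances", class(tibble::tibble()))
  )
  s <- cobinding_ratio(d, cobind_config())
  expect_equal(s$n_proximal, 3)
  expect_equal(s$n_nonproximal, 2)
  expect_equal(s$ratio, 1.5)
  expect_equal(s$median_proximal_bp, 50)
  expect_equal(s$median_all_bp, 119)

  # a tie at exactly 120 bp is non-proximal
  d$distance <- c(119, 120, 120, 121, 400)
  s2 <- cobinding_ratio(d, cobind_config())
  expect_equal(s2$n_proximal, 1)
  expect_equal(s2$n_nonproximal, 4)

  # all proximal -> infinite sentinel, not an error
  d$distance <- rep(10, 5)
  expect_equal(cobinding_ratio(d, cobind_config())$ratio, Inf)

  # orphans are excluded from both counts
  d$distance <- c(20, 500, NA, NA, NA)
  s3 <- cobinding_ratio(d, cobind_config())
  expect_equal(s3$n_proximal + s3$n_nonproximal, 2)
  expect_equal(s3$n_orphans, 3)
})

test_that("distance histograms conserve counts into bins plus overflow", {
  d <- structure(
    tibble::tibble(name = paste0("q", 1:3), chrom = "chr1", summit = 1:3,
                   ref_name = "r", distance = c(10, 25, 250)),
    class = c("summit_distances", class(tibble::tibble()))
  )
  h <- distance_histogram(d, cobind_config(histogram_bin = 20,
                                           histogram_max = 40))
  expect_equal(h$count, c(1, 1))
  expect_equal(attr(h, "overflow"), 1)

  withr::local_seed(3)
  for (rep in 1:20) {
    n <- sample(1:1000, 1)
    d2 <- d[rep(1, n), ]
    d2$distance <- runif(n, 0, 5000)
    h2 <- distance_histogram(d2, cobind_config())
    expect_equal(sum(h2$count) + attr(h2, "overflow"), n)
  }
})

test_that("co-bound pair extraction is consistent with the proximal count", {
  q <- make_cistrome("chr1", c(100, 500), name = c("q1", "q2"))
  r <- make_cistrome("chr1", c(120, 1000), name = c("r1", "r2"))
  pairs <- extract_cobound_pairs(q, r)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$distance_bp, 20)
  expect_equal(pairs$ref_name, "r1")

  expect_equal(
    nrow(extract_cobound_pairs(q, r, cobind_config(proximal_threshold = 1))),
    0
  )

  withr::local_seed(5)
  for (rep in 1:5) {
    qq <- random_cistrome(200, prefix = "q")
    rr <- random_cistrome(100, prefix = "r")
    s <- cobinding_ratio(nearest_summit_distances(qq, rr))
    expect_equal(nrow(extract_cobound_pairs(qq, rr)), s$n_proximal)
  }
})

test_that("pair output is sorted by chromosome then start", {
  withr::local_seed(6)
  qq <- random_cistrome(300, prefix = "q", max_pos = 1e5)
  rr <- random_cistrome(200, prefix = "r", max_pos = 1e5)
  pairs <- extract_cobound_pairs(qq, rr)
  expect_false(is.unsorted(order(pairs$chrom, pairs$start)))
  expect_identical(pairs, pairs[order(pairs$chrom, pairs$start), ])
})

test_that("cistrome overlap counts shared peaks symmetrically but not
           identically", {
  a <- make_cistrome("chr1", 150)          # [100, 200)
  a$start <- 100; a$end <- 200
  b <- make_cistrome("chr1", 200)
  b$start <- 150; b$end <- 250
  ov <- cistrome_overlap(a, b)
  expect_equal(ov$shared_a, 1)
  expect_equal(ov$shared_b, 1)

  b2 <- make_cistrome("chr2", c(100, 200))
  ov2 <- cistrome_overlap(a, b2)
  expect_equal(c(ov2$a_only, ov2$b_only), c(1, 2))
  expect_equal(c(ov2$shared_a, ov2$shared_b), c(0, 0))

  # one broad peak spanning two narrow ones
  wide <- make_cistrome("chr1", 500); wide$start <- 0; wide$end <- 1000
  two <- make_cistrome("chr1", c(100, 800), name = c("n1", "n2"))
  ov3 <- cistrome_overlap(wide, two)
  expect_equal(ov3$shared_a, 1)
  expect_equal(ov3$shared_b, 2)
})

test_that("the proximal/non-proximal split is equivariant under integer
           coordinate scaling", {
  withr::local_seed(13)
  q <- random_cistrome(200, prefix = "q", max_pos = 1e4)
  r <- random_cistrome(100, prefix = "r", max_pos = 1e4)
  s1 <- cobinding_ratio(nearest_summit_distances(q, r),
                        cobind_config(proximal_threshold = 120))
  for (c_scale in c(3, 10)) {
    qs <- q; rs <- r
    for (col in c("start", "end", "summit")) {
      qs[[col]] <- qs[[col]] * c_scale
      rs[[col]] <- rs[[col]] * c_scale
    }
    s2 <- cobinding_ratio(
      nearest_summit_distances(qs, rs),
      cobind_config(proximal_threshold = 120 * c_scale)
    )
    expect_equal(s2$n_proximal, s1$n_proximal)
    expect_equal(s2$n_nonproximal, s1$n_nonproximal)
  }
})

test_that("cobind_analysis bundles distances, summary, histogram and pairs
           coherently", {
  withr::local_seed(21)
  sim <- simulate_cistromes(sim_config(seed = 21, n_query_peaks = 400,
                                       n_ref_peaks = 300))
  fit <- cobind_analysis(sim$query, sim$ref)
  g <- glance(fit)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 400)
  expect_equal(nrow(fit$pairs), g$n_proximal)
  expect_equal(sum(fit$histogram$count) + attr(fit$histogram, "overflow"),
               g$n_proximal + g$n_nonproximal)
  expect_s3_class(autoplot(fit), "ggplot")
  # FE filtering inside the wrapper matches filtering outside
  fit30 <- cobind_analysis(sim$query, sim$ref, fe_cutoff = 30)
  expect_equal(nrow(tidy(fit30)), nrow(filter_by_fe(sim$query, 30)))
})
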