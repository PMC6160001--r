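# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (all-pairs scans, per-offset rescoring)
# and share no code with the package implementations they check.

# Build a peak table directly from summits; intervals are summit +/- 50.
make_cistrome <- function(chrom, summit, fe = NA_real_, name = NULL,
                          label = NA_character_) {
  n <- length(summit)
  tibble::tibble(
    chrom = chrom,
    start = summit - 50,
    end = summit + 50,
    name = name %||% sprintf("pk%04d", seq_len(n)),
    fold_enrichment = rep_len(fe, n),
    summit = summit
  ) -> out
  attr(out, "factor_label") <- label
  class(out) <- c("cistrome", class(out))
  out
}

random_cistrome <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e6,
                            fe = NA_real_, prefix = "pk") {
  make_cistrome(
    chrom = sample(chroms, n, replace = TRUE),
    summit = sample.int(max_pos, n, replace = TRUE) + 50,
    fe = fe,
    name = sprintf("%s%05d", prefix, seq_len(n))
  )
}

# All-pairs nearest-summit oracle (O(n*m)); same orphan and same-name
# exclusion semantics as the contract, derived independently.
brute_force_nearest <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- ref$chrom == query$chrom[i] & ref$name != query$name[i]
    if (!any(same)) return(NA_real_)
    min(abs(ref$summit[same] - query$summit[i]))
  }, numeric(1))
}

# All-TSS nearest-gene oracle with the lexicographic tie rule.
brute_force_nearest_tss <- function(peaks, tss) {
  vapply(seq_len(nrow(peaks)), function(i) {
    t <- tss[tss$chrom == peaks$chrom[i], ]
    if (nrow(t) == 0) return(NA_character_)
    d <- abs(peaks$summit[i] - t$tss)
    cand <- t$gene_id[d == min(d)]
    sort(cand)[1]
  }, character(1))
}

# Naive per-offset PWM rescoring oracle: explicit double loop over
# offsets and strands, counting distinct windows.
brute_force_pwm_hits <- function(seq, m, threshold) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  sm <- log2(m$matrix / m$background)
  L <- ncol(m$matrix)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < L) return(0L)
  score_at <- function(win) {
    if (any(!win %in% bases)) return(NA_real_)
    s <- 0
    for (k in seq_len(L)) s <- s + sm[match(win[k], bases), k]
    s
  }
  hit <- logical(n - L + 1)
  for (o in seq_len(n - L + 1)) {
    win <- chars[o:(o + L - 1)]
    rc <- rev(unname(comp[win]))
    sf <- score_at(win)
    sr <- score_at(rc)
    hit[o] <- (!is.na(sf) && sf >= threshold) ||
      (!is.na(sr) && sr >= threshold)
  }
  sum(hit)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# A sharp 10-bp motif for enrichment tests: consensus probability p at
# every position, the rest split evenly.
sharp_pwm <- function(id = "sharp", consensus = "ACGTTGCACT", p = 0.97) {
  bases <- c("A", "C", "G", "T")
  cols <- vapply(strsplit(consensus, "")[[1]], function(b) {
    v <- rep((1 - p) / 3, 4)
    v[match(b, bases)] <- p
    v
  }, numeric(4))
  clockbind::pwm(id, cols)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
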