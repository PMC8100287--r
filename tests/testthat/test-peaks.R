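# independent mini-caller: direct per-bin counting, Poisson tail, explicit
# merge scan — the oracle the vectorized caller must match
peak_oracle <- function(mids, rs, re, G, N, extend = 25L, bin = 10L,
                        local_windows = c(500L, 1000L), p_thresh = 1e-3,
                        merge_gap = 30L) {
  span <- bin + 2L * extend
  starts <- seq(rs, re - 1L, by = bin)
  k <- sapply(starts, function(x) sum(mids >= x - extend & mids < x + bin + extend))
  lam <- rep(N * span / G, length(starts))
  for (i in seq_along(starts)) {
    ctr <- starts[i] + bin %/% 2L
    for (w in local_windows) {
      wl <- max(rs, ctr - w %/% 2L); wh <- min(re, ctr + w %/% 2L)
      cw <- sum(mids >= wl & mids < wh)
      lam[i] <- max(lam[i], cw * span / max(wh - wl, 1L))
    }
  }
  p <- ppois(k - 1L, lam, lower.tail = FALSE)
  sig <- which(p < p_thresh)
  peaks <- list()
  while (length(sig)) {
    grp <- sig[1]; sig <- sig[-1]
    while (length(sig) && starts[sig[1]] - (starts[tail(grp, 1)] + bin) <= merge_gap) {
      grp <- c(grp, sig[1]); sig <- sig[-1]
    }
    peaks[[length(peaks) + 1L]] <- c(min(starts[grp]), max(starts[grp]) + bin)
  }
  list(k = as.integer(k), p = p, starts = starts, peaks = peaks)
}

test_that("the caller matches the brute-force Poisson oracle on small instances", {
  set.seed(41)
  ps <- promoter_set(c("gA", "gB"), "chr1", c(2000L, 6000L), c("+", "-"))
  mids <- c(sample(1000:3000, 150, replace = TRUE),
            sample(5000:7000, 80, replace = TRUE),
            sample(2400:2460, 60, replace = TRUE))      # planted cluster
  sf <- frags_from_midpoints(mids, size = 60L)
  pk <- call_sf_peaks(sf, ps, keep_bins = TRUE)
  bins <- attr(pk, "bins")
  orA <- peak_oracle(sort(mids), 1000L, 3000L, captured_bases(ps), length(mids))
  binsA <- bins[bstart >= 1000 & bstart < 3000]
  expect_equal(binsA$count, orA$k)
  expect_equal(binsA$p, orA$p, tolerance = 1e-12)
  # merged peak intervals agree with the oracle's scan
  pkA <- pk[pk$start < 3000, ]
  expect_equal(nrow(pkA), length(orA$peaks))
  for (i in seq_along(orA$peaks)) {
    expect_equal(pkA$start[i], orA$peaks[[i]][1])
    expect_equal(pkA$end[i], orA$peaks[[i]][2])
  }
})

test_that("a planted SF site yields one peak with an accurate summit", {
  set.seed(7)
  ps <- promoter_set("g1", "chr1", 5000L, "+")
  mids <- c(sample(4000:5999, 100, replace = TRUE),          # 0.05 / bp
            pmin(5999L, pmax(4000L, round(rnorm(500, 4500, 10)))))
  pk <- filter_peaks(call_sf_peaks(frags_from_midpoints(mids, size = 60L), ps))
  expect_equal(nrow(pk), 1L)
  expect_lte(abs(pk$summit - 4500), 10)
  expect_gt(pk$fold_enrichment, 4)
  expect_error(call_sf_peaks(fragment_set(NULL), ps), "no fragments")
})

test_that("pure-Poisson coverage is calibrated: significant-bin fraction <= alpha", {
  set.seed(8)
  n_prom <- 50L
  ps <- promoter_set(sprintf("n%02d", 1:n_prom), sprintf("n%02d", 1:n_prom),
                     rep(1000L, n_prom), rep("+", n_prom))
  fr <- data.table::data.table(chrom = sample(ps$chrom, 10000, replace = TRUE),
                               start = sample(0:1939, 10000, replace = TRUE))
  fr[, end := start + 60L]
  pk <- call_sf_peaks(fragment_set(fr), ps, keep_bins = TRUE)
  bins <- attr(pk, "bins")
  expect_gt(nrow(bins), 5000)
  expect_lte(mean(bins$p < 0.01), 0.01)
  expect_lte(mean(bins$p < 0.05), 0.05)
  expect_equal(nrow(filter_peaks(pk)), 0L)
})

test_that("q/fold filtering uses strict inequalities as printed", {
  pk <- data.table::data.table(
    chrom = "chr1", start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
    summit = c(50L, 250L, 450L), p_value = 1e-5,
    q_value = c(0.1, 0.05, 0.05), fold_enrichment = c(10, 4, 4.1))
  data.table::setattr(pk, "class", c("PeakSet", class(pk)))
  out <- filter_peaks(pk)
  expect_equal(out$start, 400L)   # q = 0.1 exactly and fold = 4 exactly rejected
  expect_equal(nrow(filter_peaks(pk[0, ])), 0L)
})

test_that("reciprocal-overlap reproducibility filtering is exact", {
  mk <- function(s, e) {
    d <- data.table::data.table(chrom = "chr1", start = s, end = e,
                                summit = (s + e) %/% 2L, p_value = 1e-6,
                                q_value = 1e-3, fold_enrichment = 10)
    data.table::setattr(d, "class", c("PeakSet", class(d)))
    d
  }
  a <- mk(c(0L, 1000L), c(100L, 1100L))
  expect_equal(nrow(reproducible_peaks(a, a)), 2L)
  expect_equal(nrow(reproducible_peaks(a, mk(5000L, 5100L))), 0L)
  # A=[0,100), B=[50,150): reciprocal overlap exactly 0.5
  b <- mk(50L, 150L)
  expect_equal(nrow(reproducible_peaks(mk(0L, 100L), b, min_frac = 0.5)), 1L)
  expect_equal(nrow(reproducible_peaks(mk(0L, 100L), b, min_frac = 0.51)), 0L)
})

test_that("peak overlap matches the O(n*m) enumeration oracle", {
  mk <- function(s, e) {
    d <- data.table::data.table(chrom = "chr1", start = s, end = e,
                                summit = (s + e) %/% 2L, p_value = 1e-6,
                                q_value = 1e-3, fold_enrichment = 10)
    data.table::setattr(d, "class", c("PeakSet", class(d)))
    d
  }
  a <- mk(c(0L, 200L), c(100L, 300L))
  b <- mk(90L, 110L)
  ov <- peak_overlap(a, b)
  expect_equal(ov$n_a_overlapping, 1L)
  expect_equal(ov$fraction_of_a, 0.5)
  expect_equal(ov$fraction_of_b, 1.0)
  # random instance vs enumeration
  set.seed(5)
  s1 <- sort(sample(0:5000, 40)); a2 <- mk(s1, s1 + sample(20:120, 40, TRUE))
  s2 <- sort(sample(0:5000, 30)); b2 <- mk(s2, s2 + sample(20:120, 30, TRUE))
  ov2 <- peak_overlap(a2, b2)
  brute_a <- sum(vapply(seq_len(nrow(a2)), function(i)
    any(a2$start[i] < b2$end & b2$start < a2$end[i]), logical(1)))
  brute_b <- sum(vapply(seq_len(nrow(b2)), function(j)
    any(b2$start[j] < a2$end & a2$start < b2$end[j]), logical(1)))
  expect_equal(ov2$n_a_overlapping, brute_a)
  expect_equal(ov2$n_b_overlapping, brute_b)
  # disjoint sets
  expect_equal(peak_overlap(a, mk(4000L, 4100L))$fraction_of_a, 0)
})

test_that("narrowPeak round trip preserves coordinates, summit and fold", {
  set.seed(6)
  pk <- data.table::data.table(
    chrom = "chr1", start = c(10L, 500L), end = c(200L, 700L),
    summit = c(90L, 600L), p_value = c(1e-8, 1e-4),
    q_value = c(1e-6, 1e-2), fold_enrichment = c(12.5, 5.25))
  data.table::setattr(pk, "class", c("PeakSet", class(pk)))
  f <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f)
  pk2 <- read_narrowpeak(f)
  expect_equal(pk2$start, pk$start)
  expect_equal(pk2$summit, pk$summit)
  expect_equal(pk2$fold_enrichment, pk$fold_enrichment)
  expect_equal(pk2$q_value, pk$q_value, tolerance = 1e-6)
})
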