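# a small generator configuration used across these tests
small_cfg <- function(seed = 11L, n = 120L, depth = 60000, ...) {
  generator_config(n_promoters = n, depth = depth, seed = seed, ...)
}

test_that("generation is deterministic for a fixed master seed", {
  a <- generate_dataset(small_cfg(n = 40L, depth = 8000))
  b <- generate_dataset(small_cfg(n = 40L, depth = 8000))
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$fragments$control$total$light$fragments,
                   b$fragments$control$total$light$fragments)
  expect_identical(a$expression, b$expression)
  c_ <- generate_dataset(small_cfg(seed = 12L, n = 40L, depth = 8000))
  expect_false(identical(a$sequences, c_$sequences))
})

test_that("a degenerate mixture labels every promoter with that class", {
  cls <- default_architecture_classes()
  cfg <- generator_config(n_promoters = 30L, depth = 5000, seed = 2L,
                          weights = c(1, rep(0, length(cls) - 1)))
  ds <- generate_dataset(cfg)
  expect_true(all(ds$truth$class == names(cls)[1]))
})

test_that("class counts follow the multinomial at default weights", {
  ds <- generate_dataset(small_cfg(n = 2000L, depth = 2000))
  counts <- table(factor(ds$truth$class,
                         levels = names(default_architecture_classes())))
  # multinomial 99% bounds for p = 1/7, n = 2000
  p <- 1 / 7
  bound <- 2.58 * sqrt(2000 * p * (1 - p))
  expect_true(all(abs(counts - 2000 * p) < bound + 1))
})

test_that("digestion weights produce the designed MSN/MRN log ratios", {
  # weight model: light = o(0.6 + 0.4(1 - s)), heavy = o(0.2 + 0.8 s)
  w <- function(o, s) c(light = o * (0.6 + 0.4 * (1 - s)),
                        heavy = o * (0.2 + 0.8 * s))
  expect_equal(unname(log2(w(1, 1)["light"] / w(1, 1)["heavy"])),
               log2(0.6 / 1.0), tolerance = 1e-12)          # MRN: -0.737
  expect_equal(unname(log2(w(1, 0)["light"] / w(1, 0)["heavy"])),
               log2(1.0 / 0.2), tolerance = 1e-12)          # MSN: +2.32
  # occupancy 0 emits nothing: weight is zero under both digests
  expect_equal(unname(w(0, 0.5)), c(0, 0))
})

test_that("ChIP retention follows the efficiency and background rates", {
  set.seed(3)
  cfg <- small_cfg()
  tot <- data.table::data.table(chrom = "x", start = 0L, end = 150L,
                                h2az = rep(c(TRUE, FALSE), c(20000, 20000)))
  kept <- simulate_chip(tot, cfg)
  rate_h <- mean(kept$h2az); n_h <- sum(kept$h2az); n_o <- sum(!kept$h2az)
  expect_lt(abs(n_h / 20000 - 0.8), 0.02)     # binomial expectation 0.8
  expect_lt(abs(n_o / 20000 - 0.02), 0.005)   # background 0.02
})

test_that("sequences carry the planted WW base rate and periodicity", {
  ds <- generate_dataset(small_cfg(n = 60L, depth = 30000))
  # outside footprints the genome-wide WW-start frequency is ~ ww_base
  flank <- substr(ds$sequences, 1, 150)       # upstream of any nucleosome
  ww_freq <- function(s) {
    b <- strsplit(s, "")[[1]]; w <- b %in% c("A", "T")
    mean(w[-length(w)] & w[-1])
  }
  freqs <- vapply(flank, ww_freq, numeric(1))
  expect_lt(abs(mean(freqs) - 0.25), 0.02)
  # pooled 147-150 bp fragments recover the planted 10 bp period
  comb <- pool_digests(ds$fragments$control$total$light,
                       ds$fragments$control$total$heavy)
  pr <- estimate_period(ww_profile(comb, ds$sequences))
  expect_equal(pr$period, 10L)
  # amplitude 0 plants no periodicity
  ds0 <- generate_dataset(generator_config(n_promoters = 60L, depth = 30000,
                                           seed = 4L, ww_amplitude = 0))
  comb0 <- pool_digests(ds0$fragments$control$total$light,
                        ds0$fragments$control$total$heavy)
  pr0 <- estimate_period(ww_profile(comb0, ds0$sequences))
  expect_true(is.na(pr0$period))
  expect_error(generator_config(n_promoters = 10, depth = 100, seed = 1,
                                ww_amplitude = 0.3, ww_base = 0.25),
               "amplitude")
})

test_that("knockdown multiplies the TSS SF rate by the burst factor", {
  cfg <- small_cfg(n = 80L)
  ds <- generate_dataset(cfg)
  ps <- ds$promoters
  tss_sf <- function(cond) {
    fs <- ds$fragments[[cond]]$total$light$fragments
    sum(fs$origin == "tss_burst")
  }
  ratio <- tss_sf("knockdown") / tss_sf("control")
  # burst factor 8 against the TF-footprint competition: the knockdown
  # library re-allocates its fixed SF budget toward TSS bursts
  expect_gt(ratio, 2)
  # burst factor 1 equalizes the rates (same SF budget, same sources)
  cfg1 <- small_cfg(n = 80L, tss_burst_factor = 1)
  ds1 <- generate_dataset(cfg1)
  f1 <- ds1$fragments
  r1 <- sum(f1$knockdown$total$light$fragments$origin == "tss_burst") /
    sum(f1$control$total$light$fragments$origin == "tss_burst")
  expect_lt(abs(r1 - 1), 0.35)
})

test_that("the full pipeline recovers planted architecture from a default-style dataset", {
  cfg <- generator_config(n_promoters = 400L, depth = 4e5, seed = 11L)
  ds <- generate_dataset(cfg)
  ps <- ds$promoters
  lt <- ds$fragments$control$total$light
  hv <- ds$fragments$control$total$heavy
  comb <- pool_digests(lt, hv)
  # (a) k-means at k = number of planted classes on occupancy
  occ <- normalize_rpm(dyad_occupancy_matrix(comb, ps), comb$count)
  ca <- kmeans_promoters(occ, k = length(cfg$classes), seed = 1L)
  expect_gte(ari(ds$truth$class, ca$labels[ps$gene_id]), 0.8)
  # (b) sensitivity sign recovery for planted MSN/MRN nucleosomes
  s <- sensitivity_matrix(
    normalize_rpm(dyad_occupancy_matrix(lt, ps), lt$count),
    normalize_rpm(dyad_occupancy_matrix(hv, ps), hv$count))
  cent <- as.numeric(colnames(s))
  ok <- 0L; tot <- 0L
  for (i in seq_len(nrow(ps))) {
    nucs <- cfg$classes[[ds$truth$class[i]]]$nucs
    nucs <- nucs[nucs$stab <= 0.3 | nucs$stab >= 0.8, ]
    for (j in seq_len(nrow(nucs))) {
      cols <- which(abs(cent - nucs$centre[j]) <= 30)
      ms <- mean(unclass(s)[i, cols])
      tot <- tot + 1L
      ok <- ok + (if (nucs$stab[j] <= 0.3) ms > 0 else ms < 0)
    }
  }
  expect_gte(ok / tot, 0.95)
  # (c) planted bound TF footprints recovered as filtered SF peaks
  sfc <- size_partition(comb)$sf
  pk <- filter_peaks(call_sf_peaks(sfc, ps))
  sites <- data.table::rbindlist(lapply(seq_len(nrow(ps)), function(i) {
    tfs <- cfg$classes[[ds$truth$class[i]]]$tfs
    tfs <- tfs[tfs$bound_control == TRUE, ]
    if (!nrow(tfs)) return(NULL)
    data.table::data.table(
      chrom = ps$chrom[i],
      site = ifelse(ps$strand[i] == "+", ps$tss[i] + tfs$offset,
                    ps$tss[i] - tfs$offset))
  }))
  hit <- vapply(seq_len(nrow(sites)), function(j)
    any(pk$chrom == sites$chrom[j] & abs(pk$summit - sites$site[j]) <= 20),
    logical(1))
  expect_gte(mean(hit), 0.9)
})
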