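## Subnucleosomal-fragment (SF) peak calling within captured promoter
## regions, reproducibility and effect-size filtering, and peak-set
## overlap statistics.
##
## The caller is a local-lambda Poisson model run without a control
## library: SF midpoints are extended +/- `extend` bp, counted in `bin` bp
## bins tiling the merged capture intervals, and each bin count is tested
## against the most conservative of a global expectation (over the merged
## captured bases, the effective genome) and local expectations estimated
## from surrounding windows of the treatment library itself.

#' Call subnucleosomal-fragment peaks
#'
#' @param sf `FragmentSet` of subnucleosomal fragments (< 125 bp).
#' @param ps `PromoterSet`; calling is restricted to the merged capture
#'   windows and the effective background size is [captured_bases()].
#' @param extend midpoints are extended ±`extend` bp (default 25).
#' @param bin bin width in bp (default 10).
#' @param local_windows local-lambda window sizes in bp, ascending
#'   (default 500 and 1000), clipped to the capture interval.
#' @param p_thresh per-bin Poisson p-value required to seed a peak
#'   (default 1e-3).
#' @param merge_gap significant bins closer than this are merged into one
#'   peak (default 30 bp).
#' @param q_keep permissive q-value retention threshold applied to merged
#'   peaks before any reproducibility filtering (default 0.9).
#' @param keep_bins if `TRUE`, attach the per-bin test table (counts,
#'   lambda, p, q) as attribute `bins` — used for null-calibration checks.
#' @return A `PeakSet`: `data.table` with `chrom`, `start`, `end`,
#'   `summit`, `p_value`, `q_value`, `fold_enrichment`, `summit_count`,
#'   sorted by coordinate, with the calling parameters in attribute
#'   `params`.
#' @export
call_sf_peaks <- function(sf, ps, extend = 25L, bin = 10L,
                          local_windows = c(500L, 1000L),
                          p_thresh = 1e-3, merge_gap = 30L, q_keep = 0.9,
                          keep_bins = FALSE) {
  stopifnot(inherits(sf, "FragmentSet"))
  if (sf$count == 0) stop("no fragments to call peaks from")
  if (extend <= 0) stop("extend must be positive")
  if (is.unsorted(local_windows)) stop("local_windows must be ascending")
  fr <- sf$fragments
  mid <- fragment_midpoint(fr$start, fr$end)
  G <- captured_bases(ps)
  N <- length(mid)
  span <- as.integer(bin + 2L * extend)     # bases a bin's count integrates
  lambda_global <- N * span / G

  # merged capture intervals
  regions <- reduce(GRanges(ps$chrom, IRanges(ps$start + 1L, ps$end)))
  reg_chr <- as.character(seqnames(regions))
  mids_by_chr <- split(mid, fr$chrom)

  rows <- vector("list", length(regions)); nr <- 0L
  for (i in seq_along(regions)) {
    chr <- reg_chr[i]
    mids <- sort(mids_by_chr[[chr]])
    if (is.null(mids)) next
    {
      rs <- start(regions)[i] - 1L; re <- end(regions)[i]  # 0-based half-open
      starts <- seq(rs, re - 1L, by = bin)
      k <- midpoint_window_counts(mids, starts - extend, starts + bin + extend)
      lam <- rep(lambda_global, length(starts))
      ctr <- starts + bin %/% 2L
      for (w in local_windows) {
        half <- w %/% 2L
        wl <- pmax(rs, ctr - half); wh <- pmin(re, ctr + half)
        cw <- midpoint_window_counts(mids, wl, wh)
        lam <- pmax(lam, cw * span / pmax(wh - wl, 1L))
      }
      p <- ppois(k - 1L, lam, lower.tail = FALSE)
      nr <- nr + 1L
      rows[[nr]] <- data.table(chrom = chr, bstart = starts,
                               bend = starts + bin, count = k,
                               lambda = lam, p = p,
                               rs = rs, re = re)
    }
  }
  bins <- rbindlist(rows[seq_len(nr)])
  bins[, q := p.adjust(p, method = "BH")]

  sig <- bins[p < p_thresh]
  peaks <- data.table(chrom = character(), start = integer(),
                      end = integer(), summit = integer(),
                      p_value = numeric(), q_value = numeric(),
                      fold_enrichment = numeric(), summit_count = integer())
  if (nrow(sig)) {
    setorder(sig, chrom, bstart)
    sig[, grp := cumsum(c(1L, (chrom[-1] != chrom[-.N]) |
                            (bstart[-1] - bend[-.N] > merge_gap)))]
    peaks <- sig[, {
      mids_c <- sort(mids_by_chr[[chrom[1]]])
      pos <- seq(min(bstart), max(bend) - 1L)
      cov <- midpoint_window_counts(mids_c, pos - extend, pos + 1L + extend)
      smt <- pos[which.max(cov)]
      lam_bp <- max(lambda_global,
                    max(lambda) ) / span * (2L * extend + 1L)
      .(start = min(bstart), end = max(bend), summit = smt,
        p_value = min(p), q_value = min(q),
        fold_enrichment = max(cov) / lam_bp,
        summit_count = max(cov))
    }, by = .(chrom, grp)][, grp := NULL][]
  }
  peaks <- peaks[q_value < q_keep]
  setorder(peaks, chrom, start)
  setattr(peaks, "params",
          list(extend = extend, bin = bin, local_windows = local_windows,
               p_thresh = p_thresh, merge_gap = merge_gap, q_keep = q_keep,
               genome_size = G, n_fragments = N,
               lambda_global = lambda_global,
               n_bins_tested = nrow(bins)))
  if (keep_bins)
    setattr(peaks, "bins",
            bins[, .(chrom, bstart, bend, count, lambda, p, q)])
  setattr(peaks, "class", c("PeakSet", class(peaks)))
  peaks[]
}

# number of sorted midpoints m with lo <= m < hi, vectorized over windows
midpoint_window_counts <- function(mids_sorted, lo, hi) {
  findInterval(hi - 1L, mids_sorted, left.open = FALSE) -
    findInterval(lo - 1L, mids_sorted, left.open = FALSE)
}

#' Filter peaks on q-value and fold enrichment
#'
#' Retains peaks with `q < q_max` and `fold > fold_min` — both strict
#' inequalities, so a peak at exactly the threshold is rejected.
#'
#' @param pk a `PeakSet`.
#' @param q_max q-value cutoff (default 0.1).
#' @param fold_min fold-enrichment cutoff (default 4).
#' @return The filtered `PeakSet` (parameters preserved).
#' @export
filter_peaks <- function(pk, q_max = 0.1, fold_min = 4) {
  out <- pk[pk$q_value < q_max & pk$fold_enrichment > fold_min, ]
  setattr(out, "params", c(attr(pk, "params"),
                           list(q_max = q_max, fold_min = fold_min)))
  setattr(out, "class", unique(c("PeakSet", class(out))))
  out[]
}

#' Reproducibility filter by reciprocal overlap
#'
#' A simplified replicate-consistency surrogate: keeps peaks of replicate A
#' that are overlapped by some replicate-B peak with reciprocal overlap
#' fraction >= `min_frac` (the shared span must cover that fraction of
#' both peaks).
#'
#' @param rep_a,rep_b `PeakSet`s from two replicates.
#' @param min_frac minimum reciprocal overlap fraction (default 0.5).
#' @return The retained subset of `rep_a`.
#' @export
reproducible_peaks <- function(rep_a, rep_b, min_frac = 0.5) {
  if (!nrow(rep_a) || !nrow(rep_b)) return(rep_a[0, ])
  ga <- GRanges(rep_a$chrom, IRanges(rep_a$start + 1L, rep_a$end))
  gb <- GRanges(rep_b$chrom, IRanges(rep_b$start + 1L, rep_b$end))
  hits <- findOverlaps(ga, gb)
  if (!length(hits)) return(rep_a[0, ])
  ai <- queryHits(hits); bi <- subjectHits(hits)
  shared <- pmin(rep_a$end[ai], rep_b$end[bi]) -
    pmax(rep_a$start[ai], rep_b$start[bi])
  ok <- shared / (rep_a$end[ai] - rep_a$start[ai]) >= min_frac &
    shared / (rep_b$end[bi] - rep_b$start[bi]) >= min_frac
  keep <- sort(unique(ai[ok]))
  out <- rep_a[keep, ]
  setattr(out, "class", unique(c("PeakSet", class(out))))
  out[]
}

#' Overlap statistics between two peak sets
#'
#' Two peaks overlap when they share >= 1 bp (`mode = "any"`), or when the
#' summit of an `a` peak falls inside a `b` peak (`mode = "summit"`). Both
#' directional fractions are reported.
#'
#' @param a,b `PeakSet`s.
#' @param mode `"any"` (default) or `"summit"`.
#' @return List with `n_a_overlapping`, `n_b_overlapping`,
#'   `fraction_of_a`, `fraction_of_b`.
#' @export
peak_overlap <- function(a, b, mode = c("any", "summit")) {
  mode <- match.arg(mode)
  if (!nrow(a) || !nrow(b))
    return(list(n_a_overlapping = 0L, n_b_overlapping = 0L,
                fraction_of_a = 0, fraction_of_b = 0))
  ga <- if (mode == "summit")
    GRanges(a$chrom, IRanges(a$summit + 1L, width = 1L))
  else GRanges(a$chrom, IRanges(a$start + 1L, a$end))
  gb <- GRanges(b$chrom, IRanges(b$start + 1L, b$end))
  hits <- findOverlaps(ga, gb)
  n_a <- length(unique(queryHits(hits)))
  n_b <- length(unique(subjectHits(hits)))
  list(n_a_overlapping = n_a, n_b_overlapping = n_b,
       fraction_of_a = n_a / nrow(a), fraction_of_b = n_b / nrow(b))
}

#' Write a peak set as narrowPeak (BED6+4)
#'
#' Columns: chrom, start, end, name, score (int 10*fold, capped 1000),
#' strand ".", signalValue (fold), pValue and qValue as -log10, and the
#' summit offset from `start`.
#'
#' @param pk a `PeakSet`.
#' @param path output path.
#' @param name_prefix prefix for peak names.
#' @export
write_narrowpeak <- function(pk, path, name_prefix = "sf_peak") {
  dt <- data.table(chrom = pk$chrom, start = pk$start, end = pk$end,
                   name = sprintf("%s_%d", name_prefix, seq_len(nrow(pk))),
                   score = pmin(1000L, as.integer(round(10 * pk$fold_enrichment))),
                   strand = ".",
                   signalValue = pk$fold_enrichment,
                   pValue = -log10(pmax(pk$p_value, 1e-300)),
                   qValue = -log10(pmax(pk$q_value, 1e-300)),
                   peak = pk$summit - pk$start)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file into a `PeakSet`
#' @param path narrowPeak path.
#' @return A `PeakSet`.
#' @export
read_narrowpeak <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  pk <- data.table(chrom = as.character(dt[[1]]),
                   start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
                   summit = as.integer(dt[[2]]) + as.integer(dt[[10]]),
                   p_value = 10^(-dt[[8]]), q_value = 10^(-dt[[9]]),
                   fold_enrichment = dt[[7]])
  setorder(pk, chrom, start)
  setattr(pk, "class", c("PeakSet", class(pk)))
  pk[]
}
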