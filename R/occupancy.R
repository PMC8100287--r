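## TSS-anchored occupancy/coverage matrices, fragment size partitions and
## size-position histograms.

#' The dyad-window bin scheme
#'
#' 60 bp windows advanced at a 10 bp step across the 2 kb surrounding each
#' TSS: bins `[x, x + 60)` for `x in {-1000, -990, ..., +940}` (195 bins),
#' bin centre `x + 30`. A fragment midpoint m contributes to every bin with
#' `x <= m < x + 60`.
#'
#' @param window_width window width in bp.
#' @param step stride in bp.
#' @return List with `starts`, `centers`, `width`, `step`, `n`.
#' @export
bin_scheme <- function(window_width = 60L, step = 10L) {
  starts <- seq(-1000L, 1000L - window_width, by = step)
  list(starts = starts, centers = starts + window_width %/% 2L,
       width = as.integer(window_width), step = as.integer(step),
       n = length(starts))
}

# map fragment midpoints into promoter windows; returns data.table with
# promoter row index and strand-oriented offset, one row per (fragment,
# promoter) hit (overlapping promoter windows each receive the fragment)
midpoint_offsets <- function(fr, ps) {
  if (!nrow(fr))
    return(data.table(row = integer(), frag = integer(), off = integer()))
  mid <- fragment_midpoint(fr$start, fr$end)
  q <- GRanges(fr$chrom, IRanges(mid + 1L, width = 1L))
  # pad one base each side so the minus-strand edge (genomic position `end`,
  # offset -1000) is not lost; the offset filter below discards anything
  # outside [-1000, 1000)
  s <- GRanges(ps$chrom, IRanges(ps$start, ps$end + 1L))
  hits <- findOverlaps(q, s)
  row <- subjectHits(hits)
  frag <- queryHits(hits)
  off <- to_relative(mid[frag], ps$tss[row], ps$strand[row])
  keep <- !is.na(off)
  data.table(row = row[keep], frag = frag[keep], off = off[keep])
}

new_signal_matrix <- function(m, ps, kind, units, meta = list()) {
  rownames(m) <- ps$gene_id
  structure(m, kind = kind, units = units, meta = meta,
            class = c("SignalMatrix", class(m)))
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf("SignalMatrix [%s, %s]: %d promoters x %d bins\n",
              attr(x, "kind"), attr(x, "units"), nrow(x), ncol(x)))
  invisible(x)
}

#' Dyad-window occupancy matrix
#'
#' Counts, per promoter and 60 bp/10 bp-step bin, the fragment midpoints
#' (dyad proxies) falling in the bin: midpoint m increments every bin with
#' `x <= m < x + 60`, on the strand-oriented TSS axis. This is the raw
#' (count) matrix; normalize with [normalize_rpm()].
#'
#' @param fs a `FragmentSet`.
#' @param ps a `PromoterSet`.
#' @param scheme a [bin_scheme()].
#' @param size_range keep fragments with `size_range[1] <= size <=
#'   size_range[2]`; must lie within 20–500 bp.
#' @return A raw-count `SignalMatrix` (kind `"dyad"`), columns named by bin
#'   centre.
#' @export
dyad_occupancy_matrix <- function(fs, ps, scheme = bin_scheme(),
                                  size_range = c(20L, 500L)) {
  stopifnot(inherits(fs, "FragmentSet"))
  if (!nrow(ps)) stop("empty PromoterSet")
  if (size_range[1] < 20 || size_range[2] > 500)
    stop("size_range must lie within [20, 500]")
  fr <- fs$fragments[size >= size_range[1] & size <= size_range[2]]
  m <- matrix(0, nrow(ps), scheme$n,
              dimnames = list(NULL, scheme$centers))
  hits <- midpoint_offsets(fr, ps)
  if (nrow(hits)) {
    w <- scheme$width; st <- scheme$step
    x0 <- scheme$starts[1]; xN <- scheme$starts[scheme$n]
    # bins with x <= off < x + w, clipped to the grid
    lo <- pmax(x0, st * ceiling((hits$off - w + 1L) / st))
    hi <- pmin(xN, st * floor(hits$off / st))
    nb <- pmax(0L, (hi - lo) %/% st + 1L)
    rows <- rep(hits$row, nb)
    bins <- (sequence(nb) - 1L) + rep((lo - x0) %/% st + 1L, nb)
    tab <- tabulate((bins - 1L) * nrow(ps) + rows, nbins = nrow(ps) * scheme$n)
    m <- matrix(as.numeric(tab), nrow(ps), scheme$n,
                dimnames = list(NULL, scheme$centers))
  }
  new_signal_matrix(m, ps, kind = "dyad", units = "count",
                    meta = list(condition = fs$condition, assay = fs$assay,
                                digest = fs$digest, size_range = size_range))
}

#' Per-base-pair coverage matrix
#'
#' Counts, per promoter and TSS-relative base pair in `[-1000, 1000)`, the
#' fragments whose span covers that base, then normalizes to fragments per
#' million mapped in the library (rpm).
#'
#' @inheritParams dyad_occupancy_matrix
#' @return An rpm `SignalMatrix` (kind `"coverage"`) with 2000 per-bp
#'   columns named by offset.
#' @export
coverage_matrix <- function(fs, ps) {
  stopifnot(inherits(fs, "FragmentSet"))
  if (!nrow(ps)) stop("empty PromoterSet")
  if (fs$count == 0) stop("zero-depth normalization: empty fragment library")
  fr <- fs$fragments
  offs <- -1000:999
  m <- matrix(0, nrow(ps), 2000L, dimnames = list(NULL, offs))
  q <- GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))
  s <- GRanges(ps$chrom, IRanges(ps$start + 1L, ps$end))
  hits <- findOverlaps(q, s)
  if (length(hits)) {
    fi <- queryHits(hits); pi <- subjectHits(hits)
    # clip the fragment to the window, in genomic coordinates
    gs <- pmax(fr$start[fi], ps$start[pi])
    ge <- pmin(fr$end[fi], ps$end[pi])
    plus <- ps$strand[pi] == "+"
    # covered offsets: [gs - tss, ge - tss) on +, [tss - ge + 1, tss - gs + 1) on -
    lo <- ifelse(plus, gs - ps$tss[pi], ps$tss[pi] - ge + 1L)
    hi <- ifelse(plus, ge - ps$tss[pi] - 1L, ps$tss[pi] - gs)  # inclusive
    lo <- pmax(lo, -1000L); hi <- pmin(hi, 999L)               # clip to axis
    ok <- hi >= lo
    pi <- pi[ok]; lo <- lo[ok]; hi <- hi[ok]
    # difference-accumulator per row, then cumulative sum along the axis
    np <- nrow(ps)
    j1 <- lo + 1001L; j2 <- hi + 2L + 1000L
    inc <- tabulate((j1 - 1L) * np + pi, nbins = np * 2001L)
    dec <- tabulate((j2 - 1L) * np + pi, nbins = np * 2001L)
    add <- matrix(inc - dec, np, 2001L)
    m <- t(apply(add, 1L, cumsum))[, 1:2000, drop = FALSE]
    dimnames(m) <- list(NULL, offs)
  }
  m <- m * 1e6 / fs$count
  new_signal_matrix(m, ps, kind = "coverage", units = "rpm",
                    meta = list(condition = fs$condition, assay = fs$assay,
                                digest = fs$digest, library_count = fs$count))
}

#' Fragments-per-million normalization
#'
#' @param m a raw-count `SignalMatrix`.
#' @param library_count total mapped fragments in the library (> 0).
#' @return The matrix scaled by `1e6 / library_count`, units `"rpm"`.
#' @export
normalize_rpm <- function(m, library_count) {
  if (library_count <= 0) stop("library_count must be positive")
  out <- m * 1e6 / library_count
  attr(out, "units") <- "rpm"
  meta <- attr(out, "meta"); meta$library_count <- library_count
  attr(out, "meta") <- meta
  out
}

#' Partition fragments at the subnucleosomal size threshold
#'
#' Subnucleosomal fragments (SFs) are `size < 125` bp; nucleosomal
#' fragments are `size >= 125` bp, so the partition is total and disjoint.
#'
#' @param fs a `FragmentSet`.
#' @param threshold size threshold in bp.
#' @return List with elements `sf` and `nuc`, both `FragmentSet`s.
#' @export
size_partition <- function(fs, threshold = 125L) {
  stopifnot(inherits(fs, "FragmentSet"))
  list(sf = fragment_set(fs$fragments[size < threshold],
                         fs$condition, fs$assay, fs$digest),
       nuc = fragment_set(fs$fragments[size >= threshold],
                          fs$condition, fs$assay, fs$digest))
}

#' Fragment size-position histogram around the TSS
#'
#' 2D counts of fragment midpoints by (size bin, TSS-relative position
#' bin); the classic V-plot summary per promoter class.
#'
#' @param fs a `FragmentSet`.
#' @param ps a `PromoterSet`.
#' @param size_breaks size bin breaks (left-closed, right-open).
#' @param pos_breaks position bin breaks on the TSS axis (left-closed).
#' @return Matrix of counts, rows = size bins, cols = position bins, with
#'   attribute `n_in_range` = total counted fragments.
#' @export
size_position_histogram <- function(fs, ps,
                                    size_breaks = seq(20, 250, by = 5),
                                    pos_breaks = seq(-500, 500, by = 10)) {
  stopifnot(!is.unsorted(size_breaks), !is.unsorted(pos_breaks))
  hits <- midpoint_offsets(fs$fragments, ps)
  off <- hits$off
  sz <- fs$fragments$size[hits$frag]
  si <- findInterval(sz, size_breaks, rightmost.closed = FALSE)
  pi <- findInterval(off, pos_breaks, rightmost.closed = FALSE)
  ok <- si >= 1 & si < length(size_breaks) & pi >= 1 & pi < length(pos_breaks)
  h <- matrix(0L, length(size_breaks) - 1L, length(pos_breaks) - 1L,
              dimnames = list(head(size_breaks, -1L), head(pos_breaks, -1L)))
  if (any(ok)) {
    tab <- tabulate((pi[ok] - 1L) * nrow(h) + si[ok], nbins = length(h))
    h[] <- tab
  }
  attr(h, "n_in_range") <- sum(ok)
  h
}

#' Capture enrichment fold
#'
#' Ratio of mean coverage inside the captured TSS windows to mean
#' genome-wide coverage; quantifies targeted-capture performance.
#'
#' @param mean_capture_cov mean coverage over captured promoter windows.
#' @param mean_gw_cov mean genome-wide coverage (> 0).
#' @return Fold enrichment (numeric scalar).
#' @export
capture_enrichment <- function(mean_capture_cov, mean_gw_cov) {
  if (mean_gw_cov <= 0) stop("genome-wide mean coverage must be positive")
  mean_capture_cov / mean_gw_cov
}
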