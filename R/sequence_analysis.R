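## Sequence analysis of subnucleosomal peak DNA: Markov background
## estimation, log-odds PWM scanning of summit windows, expressed-TF
## matching, and WW-dinucleotide rotational-phasing periodicity.

#' Extract sequences around peak summits
#'
#' One window of `2 * half_width` bp centred on each peak summit; windows
#' running off a contig end are clipped and flagged.
#'
#' @param pk a `PeakSet`.
#' @param seqs named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param half_width half window size in bp (default 250, i.e. 500 bp of
#'   DNA surrounding the summit).
#' @return `data.table` with `peak` (index), `chrom`, `start`, `end`,
#'   `clipped`, `seq`.
#' @export
summit_windows <- function(pk, seqs, half_width = 250L) {
  missing_chr <- setdiff(unique(pk$chrom), names(seqs))
  if (length(missing_chr))
    stop("missing chromosome sequence(s): ",
         paste(head(missing_chr, 5), collapse = ", "))
  len <- nchar(seqs)[pk$chrom]
  s <- pmax(0L, pk$summit - half_width)
  e <- pmin(len, pk$summit + half_width)
  clipped <- (s != pk$summit - half_width) | (e != pk$summit + half_width)
  if (any(clipped))
    warning(sum(clipped), " summit window(s) clipped at contig bounds")
  data.table(peak = seq_len(nrow(pk)), chrom = pk$chrom,
             start = as.integer(s), end = as.integer(e),
             clipped = unname(clipped),
             seq = unname(substr(seqs[pk$chrom], s + 1L, e)))
}

#' Estimate a Markov background model from sequences
#'
#' Order-0 (base frequencies) or order-1 (conditional dinucleotide
#' frequencies) maximum-likelihood model with pseudocount 1 per state;
#' `N` bases are skipped.
#'
#' @param sequences character vector of DNA sequences (total length >=
#'   1000 bases).
#' @param order 0 or 1.
#' @return A `MarkovBackground`: list with `order`, `p0` (named base
#'   probabilities) and, for order 1, `p1` (4x4 row-stochastic matrix of
#'   `P(next | current)`).
#' @export
markov_background <- function(sequences, order = 0L) {
  stopifnot(order %in% c(0L, 1L))
  if (sum(nchar(sequences)) < 1000)
    stop("need at least 1000 bases to estimate a background model")
  bases <- c("A", "C", "G", "T")
  x <- unlist(strsplit(toupper(paste(sequences, collapse = "")), ""))
  idx <- match(x, bases)                       # NA for N and separators
  counts <- tabulate(idx, nbins = 4L) + 1      # pseudocount 1 per state
  p0 <- setNames(counts / sum(counts), bases)
  out <- list(order = order, p0 = p0)
  if (order == 1L) {
    a <- idx[-length(idx)]; b <- idx[-1]
    ok <- !is.na(a) & !is.na(b)
    tab <- matrix(tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L),
                  4L, 4L, byrow = TRUE, dimnames = list(bases, bases)) + 1
    out$p1 <- tab / rowSums(tab)
  }
  structure(out, class = "MarkovBackground")
}

#' Read a motif library in minimal PWM text format
#'
#' Plain-text blocks: a line `MOTIF <name>` followed by one row per motif
#' position with 4 whitespace-separated probabilities (A C G T order).
#' Columns are renormalized after adding `pseudocount`.
#'
#' @param path motif library path.
#' @param pseudocount probability mass added per cell (default 1e-3).
#' @return Named list of `PWM`s: each a 4 x width probability matrix with
#'   rownames A,C,G,T.
#' @export
read_motifs <- function(path, pseudocount = 1e-3) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    name <- sub("^MOTIF\\s+", "", lines[starts[i]])
    block <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(strsplit(block, "\\s+"), as.numeric)
    m <- t(do.call(rbind, rows))
    if (nrow(m) != 4) stop("motif ", name, ": expected 4 probabilities per row")
    m <- m + pseudocount
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "T")
    out[[name]] <- m
  }
  out
}

#' Scan a sequence with a PWM
#'
#' Log-odds scoring in bits against an order-0 background:
#' `score = sum log2(p_motif(base, j) / p_bg(base))` over the motif
#' window. `N` positions contribute 0 bits; sequences with more than 10%
#' `N` are flagged in the result. Scanning the minus strand scores the
#' reverse complement of the window.
#'
#' @param seq a single DNA sequence (character scalar).
#' @param pwm 4 x w probability matrix (rownames A,C,G,T).
#' @param bg a `MarkovBackground` (its order-0 probabilities are used).
#' @param threshold minimum score in bits to report (default 6).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @param motif_name name recorded in the hits.
#' @return `data.table` with `motif`, `offset` (0-based, on the given
#'   sequence), `strand`, `score`; attribute `flagged_n` marks
#'   N-rich input.
#' @export
pwm_scan <- function(seq, pwm, bg, threshold = 6, both_strands = TRUE,
                     motif_name = "motif") {
  w <- ncol(pwm)
  n <- nchar(seq)
  if (w > n) stop("PWM wider than sequence")
  bases <- c("A", "C", "G", "T")
  x <- match(strsplit(toupper(seq), "")[[1]], bases)
  flagged <- mean(is.na(x)) > 0.1
  lod <- log2(pwm / bg$p0)                      # 4 x w, recycles bg by row
  score_strand <- function(codes, mat) {
    ns <- length(codes) - w + 1L
    sc <- numeric(ns)
    for (j in seq_len(w)) {
      v <- mat[, j][codes[j:(j + ns - 1L)]]
      v[is.na(v)] <- 0                          # N contributes 0 bits
      sc <- sc + v
    }
    sc
  }
  sc_plus <- score_strand(x, lod)
  hp <- which(sc_plus >= threshold)
  res <- list(data.table(motif = motif_name, offset = hp - 1L,
                         strand = "+", score = sc_plus[hp]))
  if (both_strands) {
    rc <- rev(5L - x)                           # A<->T, C<->G on reversed seq
    sc_rc <- score_strand(rc, lod)
    hm <- which(sc_rc >= threshold)
    # rc-scan position j matches the original window at 0-based n - w + 1 - j
    res[[2]] <- data.table(motif = motif_name, offset = n - w + 1L - hm,
                           strand = "-", score = sc_rc[hm])
  }
  hits <- rbindlist(res)
  setorder(hits, offset, strand)
  setattr(hits, "flagged_n", flagged)
  hits[]
}

#' Scan many peak-summit sequences with a motif library
#'
#' @param windows output of [summit_windows()].
#' @param motifs named list of PWMs ([read_motifs()]).
#' @param bg a `MarkovBackground`.
#' @param threshold minimum score in bits.
#' @param both_strands scan both strands.
#' @return `data.table` with `peak`, `motif`, `offset`, `strand`, `score`.
#' @export
scan_summits <- function(windows, motifs, bg, threshold = 6,
                         both_strands = TRUE) {
  out <- list()
  for (i in seq_len(nrow(windows))) {
    for (mn in names(motifs)) {
      if (ncol(motifs[[mn]]) > nchar(windows$seq[i])) next
      h <- pwm_scan(windows$seq[i], motifs[[mn]], bg, threshold,
                    both_strands, motif_name = mn)
      if (nrow(h)) out[[length(out) + 1L]] <- cbind(peak = windows$peak[i], h)
    }
  }
  if (!length(out))
    return(data.table(peak = integer(), motif = character(),
                      offset = integer(), strand = character(),
                      score = numeric()))
  rbindlist(out)[]
}

#' Retain motif hits whose transcription factor is expressed
#'
#' Maps motif names to TFs and keeps hits whose TF abundance in the given
#' condition is at least `min_abundance`; hits with unmapped motifs are
#' dropped with a warning.
#'
#' @param hits `data.table` of motif hits (needs a `motif` column).
#' @param motif_tf named character vector: motif name -> TF gene id.
#' @param expr expression table.
#' @param condition expression column.
#' @param min_abundance minimum abundance to call a TF expressed
#'   (default > 0, i.e. 1e-9).
#' @return The retained hits with a `tf` column added.
#' @export
match_expressed_tfs <- function(hits, motif_tf, expr, condition,
                                min_abundance = 1e-9) {
  unmapped <- setdiff(unique(hits$motif), names(motif_tf))
  if (length(unmapped))
    warning("unmapped motif(s) dropped: ", paste(unmapped, collapse = ", "))
  h <- hits[motif %in% names(motif_tf)]
  h[, tf := motif_tf[motif]]
  ab <- setNames(expr[[condition]], expr$gene_id)
  h[, abundance := ab[tf]]
  out <- h[!is.na(abundance) & abundance >= min_abundance]
  out[, abundance := NULL]
  out[]
}

#' Positional WW-dinucleotide frequency profile of nucleosome cores
#'
#' Restricts to 147-150 bp fragments, trims each to the 147 bp core
#' (symmetrically; the extra base is removed from the 3' end when the
#' excess is odd) so the fragment centre approximates the dyad, and
#' computes, for each of the 146 dinucleotide start positions across the
#' core, the frequency of WW (W = A or T) starts across fragments.
#' Dinucleotides containing `N` are excluded from both numerator and
#' denominator.
#'
#' @param fs `FragmentSet`; only fragments with sizes in `size_range`
#'   are used (>= `min_fragments` required).
#' @param seqs named character vector of contig sequences.
#' @param size_range inclusive fragment-size range (default 147-150).
#' @param min_fragments minimum number of qualifying fragments.
#' @return Numeric vector of length 146, names = positions relative to the
#'   dyad (-73..72); attribute `n_fragments` records the count.
#' @export
ww_profile <- function(fs, seqs, size_range = c(147L, 150L),
                       min_fragments = 100L) {
  fr <- fs$fragments[size >= size_range[1] & size <= size_range[2]]
  fr <- fr[chrom %in% names(seqs)]
  if (nrow(fr) < min_fragments)
    stop("need at least ", min_fragments, " fragments of ",
         size_range[1], "-", size_range[2], " bp; have ", nrow(fr))
  core <- 147L
  excess <- fr$size - core
  trim5 <- excess %/% 2L                 # odd excess: extra base off the 3' end
  s <- fr$start + trim5
  # guard against fragments running off the contig
  len <- nchar(seqs)[fr$chrom]
  ok <- s >= 0L & (s + core) <= len
  fr <- fr[ok]; s <- s[ok]
  seqmat <- substr(rep(seqs[fr$chrom], 1L), s + 1L, s + core)
  codes <- matrix(match(unlist(strsplit(toupper(seqmat), ""), use.names = FALSE),
                        c("A", "C", "G", "T")),
                  nrow = nrow(fr), ncol = core, byrow = TRUE)
  isW <- codes == 1L | codes == 4L       # NA propagates for N
  ww <- isW[, 1:(core - 1L), drop = FALSE] & isW[, 2:core, drop = FALSE]
  num <- colSums(ww, na.rm = TRUE)
  den <- colSums(!is.na(ww))
  prof <- ifelse(den > 0, num / den, NA_real_)
  names(prof) <- seq(-(core %/% 2L), core %/% 2L - 1L)
  attr(prof, "n_fragments") <- nrow(fr)
  prof
}

#' Estimate the dominant period of a positional frequency profile
#'
#' Linearly detrends the profile and finds the lag with the highest
#' autocorrelation within `lag_range`. A period is only reported when the
#' peak autocorrelation reaches `min_acf` (default 0.1) and clears the
#' white-noise significance bound (normal approximation, Bonferroni over
#' the tested lags at level 0.01) — autocorrelation is scale-free, so a
#' flat profile with any amount of noise would otherwise produce spurious
#' peaks. Ties go to the smaller lag.
#'
#' @param profile numeric vector (e.g. from [ww_profile()]); must be at
#'   least twice the maximum lag long.
#' @param lag_range inclusive lag range in bp (default 5-25).
#' @param min_acf minimum peak autocorrelation.
#' @return A `PeriodicityResult`: list with `period` (bp, or `NA` when no
#'   credible periodicity), `acf_peak`, `acf` (named vector over the lag
#'   range), `profile`.
#' @export
estimate_period <- function(profile, lag_range = c(5L, 25L), min_acf = 0.1) {
  prof <- as.numeric(profile)
  prof[is.na(prof)] <- mean(prof, na.rm = TRUE)
  if (length(prof) < 2 * lag_range[2])
    stop("profile must be at least twice the maximum lag long")
  detr <- residuals(lm(prof ~ seq_along(prof)))
  if (sd(detr) == 0) {
    return(structure(list(period = NA_integer_, acf_peak = 0,
                          acf = setNames(rep(0, diff(lag_range) + 1L),
                                         seq(lag_range[1], lag_range[2])),
                          profile = profile),
                     class = "PeriodicityResult"))
  }
  ac <- acf(detr, lag.max = lag_range[2], plot = FALSE)$acf[-1]
  lags <- seq_len(lag_range[2])
  sel <- lags >= lag_range[1]
  acv <- setNames(ac[sel], lags[sel])
  best <- which.max(acv)                    # ties -> smaller lag
  period <- as.integer(names(acv)[best])
  # harmonic correction: a period-p signal also peaks at 2p, 3p; prefer the
  # fundamental when its autocorrelation is comparable
  for (k in 3:2) {
    if (period %% k == 0) {
      d <- as.character(period %/% k)
      if (d %in% names(acv) && acv[d] >= 0.8 * acv[best]) {
        period <- as.integer(d); best <- which(names(acv) == d)
      }
    }
  }
  peak <- unname(acv[best])
  noise_bound <- qnorm(1 - 0.01 / (2 * length(acv))) / sqrt(length(prof))
  if (peak < max(min_acf, noise_bound)) period <- NA_integer_
  structure(list(period = period, acf_peak = peak, acf = acv,
                 profile = profile),
            class = "PeriodicityResult")
}

#' @export
print.PeriodicityResult <- function(x, ...) {
  if (is.na(x$period))
    cat("PeriodicityResult: no credible periodicity (peak acf ",
        format(x$acf_peak, digits = 3), ")\n", sep = "")
  else
    cat(sprintf("PeriodicityResult: period %d bp (peak acf %.3f)\n",
                x$period, x$acf_peak))
  invisible(x)
}
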