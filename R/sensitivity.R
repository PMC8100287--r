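## Differential MNase sensitivity: log2(light/heavy) matrices and
## cross-condition Welch comparisons. Positive values mark MNase-sensitive
## nucleosomes (MSNs), negative values MNase-resistant ones (MRNs).

#' MNase sensitivity matrix
#'
#' Elementwise `log2((L + eps) / (H + eps))` of matched light- and
#' heavy-digest signal matrices (both rpm-normalized so library depth
#' cancels). The pseudocount keeps the ratio finite and maps bins with
#' `L = H` (including 0/0) exactly to 0, so the matrix stays complete for
#' clustering.
#'
#' @param light,heavy rpm `SignalMatrix` objects of identical shape and
#'   promoter order.
#' @param eps pseudocount in rpm units (> 0); default 0.1.
#' @return A `SensitivityMatrix` (also a `SignalMatrix`, kind
#'   `"sensitivity"`, units `"log2_ratio"`); `eps` recorded in metadata.
#' @export
sensitivity_matrix <- function(light, heavy, eps = 0.1) {
  if (!all(dim(light) == dim(heavy)))
    stop("light and heavy matrices must have identical shape")
  if (!identical(rownames(light), rownames(heavy)))
    stop("light and heavy matrices must have identical promoter order")
  if (eps <= 0) stop("eps must be > 0")
  # log difference rather than log of the ratio: algebraically identical,
  # and makes the antisymmetry s(L,H) = -s(H,L) exact in floating point
  s <- log2(unclass(light) + eps) - log2(unclass(heavy) + eps)
  structure(s, kind = "sensitivity", units = "log2_ratio",
            meta = list(eps = eps,
                        condition = attr(light, "meta")$condition),
            class = c("SensitivityMatrix", "SignalMatrix", class(s)))
}

#' Welch's two-sample t-test (unequal variances)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`
#' returning the Welch statistic, Satterthwaite degrees of freedom and the
#' two-sided p-value.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t requires at least 2 observations per sample")
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate: t.test errors on two constant samples; identical constants
    # carry no evidence of a difference
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both samples constant with different means: variance is zero")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Compare a promoter cluster's MNase sensitivity between conditions
#'
#' For the promoters of one cluster, computes the per-promoter mean
#' sensitivity over a TSS-relative window in each condition's matrix and
#' compares the two samples with a two-sided Welch t-test.
#'
#' @param sens_a,sens_b `SensitivityMatrix` objects (conditions A and B).
#' @param cluster character vector of gene ids defining the cluster.
#' @param window length-2 offset range (bp, inclusive) selecting columns by
#'   bin centre; default ±500 bp.
#' @return List with `n_a`, `n_b`, `t`, `df`, `p`, and the per-promoter
#'   mean vectors `mean_a`, `mean_b`.
#' @export
cluster_sensitivity_compare <- function(sens_a, sens_b, cluster,
                                        window = c(-500, 500)) {
  sel_a <- intersect(cluster, rownames(sens_a))
  sel_b <- intersect(cluster, rownames(sens_b))
  if (!length(sel_a) || !length(sel_b))
    stop("cluster has no promoters in common with the matrix rows")
  cols_a <- window_columns(sens_a, window)
  cols_b <- window_columns(sens_b, window)
  ma <- rowMeans(unclass(sens_a)[sel_a, cols_a, drop = FALSE])
  mb <- rowMeans(unclass(sens_b)[sel_b, cols_b, drop = FALSE])
  if (identical(ma, mb)) {
    res <- list(t = 0, df = 2 * length(ma) - 2, p = 1)
  } else {
    res <- welch_t(ma, mb)
  }
  c(list(n_a = length(ma), n_b = length(mb)), res,
    list(mean_a = ma, mean_b = mb))
}

# columns whose (numeric) names fall inside the inclusive offset window
window_columns <- function(m, window) {
  centers <- as.numeric(colnames(m))
  sel <- which(centers >= window[1] & centers <= window[2])
  if (!length(sel)) stop("window [", window[1], ", ", window[2],
                         "] selects no columns of the matrix axis")
  sel
}
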