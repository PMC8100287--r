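## Promoter classification: k-means clustering on TSS-anchored matrices,
## dependent sorting, quantile partitions, expression linkage, transition
## (alluvial) tables, DE-fraction enrichment and gene-set intersections.

#' K-means promoter classification
#'
#' Clusters promoter rows of a signal or sensitivity matrix over a
#' TSS-relative feature window with Hartigan-Wong k-means (the best of
#' `restarts` initializations). Clusters are relabelled 1..k by descending
#' size (ties broken by the leftmost centroid peak) so labels are
#' reproducible; the display order sorts promoters by cluster, then by
#' descending mean signal over the window within each cluster.
#'
#' @param m `SignalMatrix`/`SensitivityMatrix` with gene-id rownames and
#'   bin-centre colnames.
#' @param k number of clusters (1 <= k <= number of promoters).
#' @param window length-2 inclusive offset range selecting the feature
#'   columns; default the ±500 bp clustering window.
#' @param seed integer seed (mandatory); clustering is deterministic for a
#'   fixed seed.
#' @param restarts number of random initializations; default 25.
#' @param standardize_rows if `TRUE`, z-score each row over the feature
#'   window before clustering (default `FALSE`: cluster the normalized
#'   values directly).
#' @return A `ClusterAssignment`: list with `k`, `labels` (named integer
#'   vector), `display_order` (gene ids), `seed`, `window`, `centers`,
#'   `tot_withinss`.
#' @export
kmeans_promoters <- function(m, k, window = c(-500, 500), seed,
                             restarts = 25L, standardize_rows = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(m)) stop("k exceeds the number of promoters")
  cols <- window_columns(m, window)
  feat <- unclass(m)[, cols, drop = FALSE]
  if (standardize_rows) {
    mu <- rowMeans(feat); s <- apply(feat, 1, sd); s[s == 0] <- 1
    feat <- (feat - mu) / s
  }
  if (k == 1L) {
    km <- list(cluster = rep(1L, nrow(feat)),
               centers = matrix(colMeans(feat), 1L),
               tot.withinss = sum(sweep(feat, 2, colMeans(feat))^2))
  } else if (k == nrow(feat)) {
    # every promoter its own cluster: the exact optimum
    km <- list(cluster = seq_len(k), centers = feat, tot.withinss = 0)
  } else {
    km <- with_seed(seed,
      kmeans(feat, centers = k, nstart = restarts, iter.max = 100L,
             algorithm = "Hartigan-Wong"))
  }
  sizes <- tabulate(km$cluster, nbins = k)
  peak <- apply(km$centers, 1L, which.max)       # leftmost max column
  relabel <- order(-sizes, peak)                 # old label -> rank
  new_of_old <- integer(k); new_of_old[relabel] <- seq_len(k)
  labels <- new_of_old[km$cluster]
  names(labels) <- rownames(m)
  key <- rowMeans(feat)
  ord <- order(labels, -key)
  structure(list(k = as.integer(k), labels = labels,
                 display_order = rownames(m)[ord], seed = seed,
                 window = window,
                 centers = km$centers[relabel, , drop = FALSE],
                 tot_withinss = km$tot.withinss),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: k = %d over %d promoters (window %d..%d)\n",
              x$k, length(x$labels), x$window[1], x$window[2]))
  print(table(cluster = x$labels))
  invisible(x)
}

#' TSS microcluster assignment (k = 3, ±50 bp)
#'
#' Resolves the sensitivity signal directly over the TSS into three
#' configurations — an MSN on the TSS, an MRN on the TSS, or no signal —
#' by k-means with a narrow ±50 bp clustering window.
#'
#' @param sens a `SensitivityMatrix`.
#' @param seed integer seed.
#' @param k,window fixed at 3 and ±50 bp by default.
#' @param restarts passed to [kmeans_promoters()].
#' @return A `ClusterAssignment`.
#' @export
tss_microcluster <- function(sens, seed, k = 3L, window = c(-50, 50),
                             restarts = 25L) {
  kmeans_promoters(sens, k = k, window = window, seed = seed,
                   restarts = restarts)
}

#' Apply a cluster assignment's display order to another matrix
#'
#' Dependent sort: the leftmost (primary) heatmap dictates the row order of
#' all other heatmaps in a panel. Values are never altered, only permuted;
#' per-cluster average profiles are computed alongside.
#'
#' @param target a matrix whose rows include all promoters of `ca`.
#' @param ca a `ClusterAssignment`.
#' @return List with `matrix` (rows permuted to `ca$display_order`) and
#'   `cluster_means` (k x ncol matrix of per-cluster column means).
#' @export
apply_sort <- function(target, ca) {
  missing_rows <- setdiff(ca$display_order, rownames(target))
  if (length(missing_rows))
    stop("target matrix lacks promoters: ",
         paste(head(missing_rows, 5), collapse = ", "),
         if (length(missing_rows) > 5) ", ..." else "")
  mt <- unclass(target)[ca$display_order, , drop = FALSE]
  cl <- ca$labels[ca$display_order]
  cm <- do.call(rbind, lapply(seq_len(ca$k), function(i)
    colMeans(mt[cl == i, , drop = FALSE])))
  rownames(cm) <- seq_len(ca$k)
  list(matrix = mt, cluster_means = cm)
}

#' Quantile partition by maximum signal near the TSS
#'
#' Sorts promoters by their maximum signal within a window (default the
#' 100 bp surrounding the TSS) in descending order and divides them into
#' `q` quantile groups of near-equal size (high to low). Ties keep stable
#' input order.
#'
#' @param m `SignalMatrix` (e.g. of subnucleosomal fragments).
#' @param window inclusive offset range for the maximum; default ±50 bp.
#' @param q number of groups (4 = quartiles, 6 = sextiles).
#' @return A `QuantilePartition`: list with `key` (named), `order` (gene
#'   ids, descending key), `group` (named integer, 1 = highest), `q`.
#' @export
sort_by_max_sf <- function(m, window = c(-50, 50), q = 4L) {
  cols <- window_columns(m, window)
  key <- apply(unclass(m)[, cols, drop = FALSE], 1L, max)
  ord <- order(-key, seq_along(key)) # ties keep stable input order
  n <- length(key)
  base <- n %/% q; extra <- n %% q
  sizes <- rep(base, q) + c(rep(1L, extra), rep(0L, q - extra))
  group_sorted <- rep(seq_len(q), times = sizes)
  group <- integer(n); group[ord] <- group_sorted
  names(group) <- names(key)
  structure(list(key = key, order = names(key)[ord], group = group,
                 q = as.integer(q)),
            class = "QuantilePartition")
}

#' Difference matrix between two conditions
#'
#' Elementwise `a - b` of two identically shaped rpm matrices; positive
#' values mean the signal is more abundant in `a`.
#'
#' @param a,b matrices of identical shape and row order.
#' @return The difference matrix (kind `"difference"`).
#' @export
differential_matrix <- function(a, b) {
  if (!all(dim(a) == dim(b)) || !identical(rownames(a), rownames(b)))
    stop("matrices must have identical shape and promoter order")
  d <- unclass(a) - unclass(b)
  structure(d, kind = "difference", units = attr(a, "units"),
            class = c("SignalMatrix", class(d)))
}

#' Restrict a matrix to the top expression quartile, sorted by expression
#'
#' @param m matrix with gene-id rownames.
#' @param expr expression table ([read_expression()] layout).
#' @param condition expression column to use.
#' @return The rows of `m` for the top 25% of expressing genes (among genes
#'   present in both), ordered by descending abundance; the key is attached
#'   as attribute `abundance`.
#' @export
sort_by_expression <- function(m, expr, condition) {
  genes <- intersect(rownames(m), expr$gene_id)
  if (!length(genes)) stop("no genes shared between matrix and expression table")
  ab <- setNames(expr[[condition]], expr$gene_id)[genes]
  ab <- ab[!is.na(ab)]
  n_keep <- max(1L, floor(length(ab) * 0.25))
  top <- names(sort(ab, decreasing = TRUE))[seq_len(n_keep)]
  out <- unclass(m)[top, , drop = FALSE]
  attr(out, "abundance") <- ab[top]
  out
}

#' Per-cluster expression summaries
#'
#' Median and quartiles of `log2(abundance + 1)` per promoter cluster —
#' the boxplot statistics linking architecture classes to expression.
#'
#' @param ca a `ClusterAssignment`.
#' @param expr expression table.
#' @param condition expression column.
#' @return `data.table` with `cluster`, `n`, `q1`, `median`, `q3`;
#'   clusters with no expressed genes have `n = 0` and `NA` summaries.
#' @export
cluster_expression_summary <- function(ca, expr, condition) {
  ab <- setNames(expr[[condition]], expr$gene_id)
  out <- rbindlist(lapply(seq_len(ca$k), function(i) {
    g <- names(ca$labels)[ca$labels == i]
    v <- ab[intersect(g, names(ab))]
    v <- log2(v[!is.na(v)] + 1)
    if (!length(v))
      data.table(cluster = i, n = 0L, q1 = NA_real_, median = NA_real_,
                 q3 = NA_real_)
    else
      data.table(cluster = i, n = length(v),
                 q1 = unname(quantile(v, 0.25)), median = median(v),
                 q3 = unname(quantile(v, 0.75)))
  }))
  out[]
}

#' Cross-condition cluster transition table
#'
#' Counts promoters moving from each source cluster to each target cluster
#' (the numbers behind an alluvial diagram), optionally restricted to a
#' gene filter set (e.g. significantly activated genes).
#'
#' @param src,dst `ClusterAssignment`s over the same promoters.
#' @param filter gene ids to count; default all genes common to both.
#' @return Integer matrix `src$k x dst$k`; `counts[i, j]` = promoters with
#'   source label i and target label j.
#' @export
transition_table <- function(src, dst, filter = NULL) {
  common <- intersect(names(src$labels), names(dst$labels))
  if (!is.null(filter)) common <- intersect(common, filter)
  tab <- table(factor(src$labels[common], levels = seq_len(src$k)),
               factor(dst$labels[common], levels = seq_len(dst$k)))
  m <- matrix(as.integer(tab), src$k, dst$k,
              dimnames = list(src = seq_len(src$k), dst = seq_len(dst$k)))
  m
}

#' Transition table as a long-format edge list
#' @param tt matrix from [transition_table()].
#' @return `data.table` with `src`, `dst`, `n` (zero edges dropped).
#' @export
transition_edges <- function(tt) {
  dt <- as.data.table(as.table(tt))
  setnames(dt, c("src", "dst", "n"))
  dt[n > 0][order(src, dst)][]
}

#' Differential-expression fraction enrichment
#'
#' Fraction of a target promoter set that belongs to a DE gene set,
#' compared to size-matched random draws from a background gene universe;
#' the empirical p-value is `(1 + #{null >= observed}) / (n_rand + 1)`.
#'
#' @param target_set gene ids of interest (subset of `background`).
#' @param de_set differentially expressed gene ids.
#' @param background gene universe to draw the null from.
#' The target fraction is discrete, so ties between the observed and null
#' fractions are common and `p` is conservative (sub-uniform under the
#' null). `p_randomized` breaks ties uniformly at random — it is exactly
#' uniform under the null and is the quantity to use for calibration
#' diagnostics; `p` is the quantity to report.
#'
#' @param n_rand number of random draws (>= 100).
#' @param seed integer seed.
#' @return List with `observed`, `null_mean`, `p`, `p_randomized`,
#'   `n_rand`.
#' @export
de_fraction_enrichment <- function(target_set, de_set, background,
                                   n_rand = 1000L, seed) {
  if (!length(target_set)) stop("empty target set")
  if (n_rand < 100) stop("n_rand must be >= 100")
  target_set <- unique(target_set); de_set <- unique(de_set)
  background <- unique(background)
  observed <- length(intersect(target_set, de_set)) / length(target_set)
  is_de <- background %in% de_set
  nt <- length(target_set)
  res <- with_seed(seed, {
    null <- vapply(seq_len(n_rand), function(i)
      sum(is_de[sample.int(length(background), nt)]) / nt, numeric(1))
    u <- runif(1)
    list(null = null, u = u)
  })
  null <- res$null
  n_gt <- sum(null > observed)
  n_eq <- sum(null == observed)
  list(observed = observed, null_mean = mean(null),
       p = (1 + n_gt + n_eq) / (n_rand + 1),
       p_randomized = (n_gt + res$u * (1 + n_eq)) / (n_rand + 1),
       n_rand = n_rand)
}

#' Intersection of gene sets
#' @param sets list of >= 2 character vectors of gene ids.
#' @return Sorted character vector of genes common to all sets.
#' @export
gene_set_intersection <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  sort(Reduce(intersect, sets))
}
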