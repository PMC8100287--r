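test_that("k-means recovers well-separated planted profile groups", {
  set.seed(2)
  sch <- bin_scheme()
  n <- 200
  truth <- rep(1:2, each = n / 2)
  mu <- rbind(ifelse(abs(sch$centers - 150) <= 60, 2, 0),
              ifelse(abs(sch$centers + 150) <= 60, 2, 0))
  m <- mu[truth, ] + matrix(rnorm(n * sch$n, 0, 0.2), n, sch$n) # 10x sep
  dimnames(m) <- list(sprintf("p%03d", 1:n), sch$centers)
  ca <- kmeans_promoters(m, k = 2, seed = 5)
  expect_equal(ari(truth, ca$labels), 1)
  # determinism for a fixed seed
  ca2 <- kmeans_promoters(m, k = 2, seed = 5)
  expect_identical(ca$labels, ca2$labels)
  # k = 1 trivially assigns one cluster
  expect_true(all(kmeans_promoters(m, k = 1, seed = 1)$labels == 1L))
  expect_error(kmeans_promoters(m, k = n + 1, seed = 1), "exceeds")
})

test_that("the k = 7, ±500 bp configuration clusters on the expected features", {
  sch <- bin_scheme()
  m <- matrix(rnorm(20 * sch$n), 20, sch$n,
              dimnames = list(sprintf("p%d", 1:20), sch$centers))
  expect_equal(sum(abs(sch$centers) <= 500), 101)  # feature bins in window
  ca <- kmeans_promoters(m, k = 7, window = c(-500, 500), seed = 1)
  expect_equal(ca$k, 7L)
  expect_equal(sort(unique(unname(ca$labels))), 1:7)
  expect_setequal(ca$display_order, rownames(m))
})

test_that("TSS microclusters recover planted MSN/MRN/no-signal groups", {
  set.seed(31)
  sch <- bin_scheme()
  n <- 300
  truth <- rep(1:3, each = 100)
  mu <- rbind(ifelse(abs(sch$centers) <= 50, 1.5, 0),
              ifelse(abs(sch$centers) <= 50, -1, 0),
              0)
  m <- mu[truth, ] + matrix(rnorm(n * sch$n, 0, 0.2), n, sch$n)
  dimnames(m) <- list(sprintf("p%03d", 1:n), sch$centers)
  ca <- tss_microcluster(m, seed = 3)
  expect_gte(ari(truth, ca$labels), 0.9)
  # k = 3 with 3 promoters gives singletons
  ca3 <- tss_microcluster(m[1:3, ], seed = 1)
  expect_equal(sort(unname(ca3$labels)), 1:3)
  expect_error(tss_microcluster(m, seed = 1, window = c(2000, 3000)),
               "window")
})

test_that("dependent sort permutes rows without altering values", {
  m <- matrix(1:12, 3, 4, dimnames = list(c("g1", "g2", "g3"), c(0, 10, 20, 30)))
  ca <- structure(list(k = 2L, labels = c(g1 = 1L, g2 = 2L, g3 = 1L),
                       display_order = c("g3", "g1", "g2"),
                       seed = 1L, window = c(-500, 500)),
                  class = "ClusterAssignment")
  out <- apply_sort(m, ca)
  expect_equal(rownames(out$matrix), c("g3", "g1", "g2"))
  expect_equal(sort(as.vector(out$matrix)), sort(as.vector(m)))
  expect_equal(out$cluster_means[1, ], colMeans(m[c("g1", "g3"), ]))
  expect_error(apply_sort(m[1:2, ], ca), "lacks")
})

test_that("max-signal quantile partitions are balanced, ordered and tie-stable", {
  m <- matrix(0, 8, 11, dimnames = list(sprintf("g%d", 1:8), seq(-50, 50, 10)))
  m[, 6] <- c(9, 7, 5, 3, 8, 6, 4, 2)
  qp <- sort_by_max_sf(m, q = 4)
  expect_equal(as.integer(table(qp$group)), rep(2L, 4))
  expect_equal(qp$order[1:2], c("g1", "g5"))          # highest keys first
  expect_equal(unname(qp$group[c("g1", "g8")]), c(1L, 4L))
  # distinct keys {9,7,5,3} with q = 4: one promoter per group
  qp2 <- sort_by_max_sf(m[1:4, ], q = 4)
  expect_equal(unname(qp2$group), 1:4)
  # all-equal keys: stable original order
  qp3 <- sort_by_max_sf(m * 0, q = 4)
  expect_equal(qp3$order, rownames(m))
})

test_that("difference matrices are antisymmetric and elementwise", {
  a <- matrix(c(5, 1), 1, 2, dimnames = list("g1", c(0, 10)))
  b <- matrix(c(2, 4), 1, 2, dimnames = list("g1", c(0, 10)))
  d <- differential_matrix(a, b)
  expect_equal(unclass(d)[1, ], c("0" = 3, "10" = -3))
  expect_equal(unclass(differential_matrix(b, a)), -unclass(d),
               ignore_attr = TRUE)
  expect_true(all(differential_matrix(a, a) == 0))
  expect_error(differential_matrix(a, b[, 1, drop = FALSE]), "shape")
})

test_that("expression sorting keeps the top quartile in descending order", {
  m <- matrix(0, 8, 2, dimnames = list(sprintf("g%d", 1:8), c(0, 10)))
  expr <- data.table::data.table(gene_id = sprintf("g%d", 1:8),
                                 tpm = c(10, 8, 6, 4, 2, 1, 0.5, 0.1))
  out <- sort_by_expression(m, expr, "tpm")
  expect_equal(rownames(out), c("g1", "g2"))
  expect_true(all(diff(attr(out, "abundance")) <= 0))
  expect_error(sort_by_expression(m, expr[0, ], "tpm"), "shared")
})

test_that("cluster expression summaries are log2(x+1) quartiles", {
  ca <- structure(list(k = 2L, labels = c(g1 = 1L, g2 = 2L, g3 = 2L)),
                  class = "ClusterAssignment")
  expr <- data.table::data.table(gene_id = c("g1", "g2", "g3"),
                                 tpm = c(3, 0, 0))
  s <- cluster_expression_summary(ca, expr, "tpm")
  expect_equal(s[cluster == 1]$median, 2)      # log2(3 + 1)
  expect_equal(s[cluster == 2]$median, 0)
  expect_equal(s$n, c(1L, 2L))
})

test_that("transition tables count fates with conserved row sums", {
  src <- structure(list(k = 2L, labels = c(g1 = 1L, g2 = 1L, g3 = 2L)),
                  class = "ClusterAssignment")
  dst <- structure(list(k = 2L, labels = c(g1 = 1L, g2 = 2L, g3 = 2L)),
                  class = "ClusterAssignment")
  tt <- transition_table(src, dst)
  expect_equal(unname(tt), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  expect_equal(unname(rowSums(tt)), c(2L, 1L))  # source cluster sizes
  # identical assignments give a diagonal table
  expect_true(all(transition_table(src, src)[row(tt) != col(tt)] == 0))
  # filter restricts the census
  tt2 <- transition_table(src, dst, filter = c("g1", "g3"))
  expect_equal(sum(tt2), 2L)
  e <- transition_edges(tt)
  expect_equal(sum(e$n), sum(tt))
})

test_that("DE-fraction enrichment computes observed fractions and a valid p", {
  bg <- sprintf("g%03d", 1:200)
  de <- bg[1:40]
  target <- c(bg[1:3], bg[100:106])            # 3 of 10 in the DE set
  r <- de_fraction_enrichment(target, de, bg, n_rand = 200, seed = 1)
  expect_equal(r$observed, 0.30)
  expect_equal(de_fraction_enrichment(de, de, bg, n_rand = 100, seed = 1)$observed, 1)
  expect_equal(de_fraction_enrichment(target, character(0), bg,
                                      n_rand = 100, seed = 1)$observed, 0)
  expect_true(r$p > 0 && r$p <= 1)
  expect_error(de_fraction_enrichment(character(0), de, bg, 100, 1), "empty")
})

test_that("gene-set intersection is exact and sorted", {
  expect_equal(gene_set_intersection(list(c("a", "b", "c"),
                                          c("b", "c", "d"),
                                          c("c", "e"))), "c")
  expect_equal(gene_set_intersection(list(c("x", "a"), c("a", "x"))),
               c("a", "x"))
  expect_equal(length(gene_set_intersection(list("a", "b"))), 0L)
  expect_error(gene_set_intersection(list("a")), "at least 2")
})
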