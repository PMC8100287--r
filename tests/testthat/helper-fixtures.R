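# shared fixture builders; everything is generated in code at test time

# small promoter set on one chromosome, alternating strands
tiny_promoters <- function(n = 4L, spacing = 3000L) {
  promoter_set(gene_id = sprintf("g%02d", seq_len(n)),
               chrom = "chr1",
               tss = 2000L + spacing * (seq_len(n) - 1L),
               strand = rep(c("+", "-"), length.out = n))
}

# fragment set from explicit midpoints and a common size
frags_from_midpoints <- function(mids, size = 150L, chrom = "chr1", ...) {
  fragment_set(data.table::data.table(chrom = chrom,
                                      start = as.integer(mids - size %/% 2L),
                                      end = as.integer(mids - size %/% 2L + size)),
               ...)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force dyad-bin oracle: for every (promoter, bin, fragment) triple,
# test x <= m < x + w directly
dyad_oracle <- function(fs, ps, scheme = bin_scheme()) {
  m <- matrix(0, nrow(ps), scheme$n, dimnames = list(ps$gene_id, scheme$centers))
  fr <- fs$fragments
  for (i in seq_len(nrow(ps))) {
    for (k in seq_len(nrow(fr))) {
      if (fr$chrom[k] != ps$chrom[i]) next
      mid <- (fr$start[k] + fr$end[k]) %/% 2L
      off <- if (ps$strand[i] == "+") mid - ps$tss[i] else ps$tss[i] - mid
      if (off < -1000 || off >= 1000) next
      for (j in seq_len(scheme$n)) {
        x <- scheme$starts[j]
        if (x <= off && off < x + scheme$width) m[i, j] <- m[i, j] + 1
      }
    }
  }
  m
}
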