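## Domain containers and readers/writers for the standard formats the
## pipeline touches. Coordinates are 0-based half-open throughout.

#' Construct a promoter set
#'
#' A `PromoterSet` is a `data.table` with one row per promoter and columns
#' `gene_id`, `chrom`, `tss`, `strand`, `start`, `end`, where
#' `[start, end) = [tss - 1000, tss + 1000)` is the 2 kb captured window
#' around the TSS. Iteration (row) order is stable. The attribute
#' `total_captured_bases` holds the number of genomic bases covered after
#' merging overlapping windows — the effective background size used by the
#' peak caller.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome (contig) name per promoter.
#' @param tss 0-based TSS coordinate (first transcribed base); must be
#'   >= 1000 so the upstream kilobase exists.
#' @param strand `"+"` or `"-"` per promoter.
#' @return A `PromoterSet`.
#' @export
promoter_set <- function(gene_id, chrom, tss, strand) {
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in PromoterSet")
  if (any(tss < 1000)) stop("tss must be >= 1000 (window extends 1 kb upstream)")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ps <- data.table(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   tss = as.integer(tss),
                   strand = as.character(strand))
  ps[, start := tss - 1000L]
  ps[, end := tss + 1000L]
  merged <- reduce(GRanges(ps$chrom, IRanges(ps$start + 1L, ps$end)))
  setattr(ps, "total_captured_bases", sum(width(merged)))
  setattr(ps, "class", c("PromoterSet", class(ps)))
  ps[]
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat(sprintf("PromoterSet: %d promoters, %d captured bases\n",
              nrow(x), attr(x, "total_captured_bases")))
  NextMethod()
}

#' Total merged captured bases of a promoter set
#' @param ps a `PromoterSet`.
#' @return Integer count of genomic bases under the capture windows.
#' @export
captured_bases <- function(ps) attr(ps, "total_captured_bases")

#' Construct a fragment set
#'
#' A `FragmentSet` bundles genomic fragments (0-based half-open intervals)
#' with the library metadata the pipeline keys on: condition, assay
#' (`total` MNase or H2A.Z `chip`) and digestion level (`light`, `heavy`,
#' or `combined`).
#'
#' @param fragments `data.table`/`data.frame` with columns `chrom`, `start`,
#'   `end` (extra columns are preserved).
#' @param condition free-text condition label (e.g. `"control"`).
#' @param assay `"total"` or `"chip"`.
#' @param digest `"light"`, `"heavy"` or `"combined"`.
#' @return A `FragmentSet`; `$fragments` carries a `size = end - start`
#'   column, `$count` the number of fragments.
#' @export
fragment_set <- function(fragments, condition = "control",
                         assay = c("total", "chip"),
                         digest = c("light", "heavy", "combined")) {
  assay <- match.arg(assay)
  digest <- match.arg(digest)
  fr <- as.data.table(fragments)
  if (nrow(fr)) {
    if (any(fr$start >= fr$end)) stop("fragment start >= end")
    if (any(fr$start < 0)) stop("negative fragment coordinate")
    fr[, size := as.integer(end - start)]
  } else {
    fr <- data.table(chrom = character(), start = integer(),
                     end = integer(), size = integer())
  }
  structure(list(fragments = fr, condition = condition, assay = assay,
                 digest = digest, count = nrow(fr)),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet: %d fragments [%s / %s / %s]\n",
              x$count, x$condition, x$assay, x$digest))
  invisible(x)
}

#' Pool two fragment sets into a combined digest
#'
#' Used to merge light and heavy digestion libraries into the `combined`
#' nucleosome map with equal weight (each fragment counted once).
#'
#' @param a,b `FragmentSet`s with identical condition and assay.
#' @return A `FragmentSet` with `digest = "combined"`.
#' @export
pool_digests <- function(a, b) {
  stopifnot(inherits(a, "FragmentSet"), inherits(b, "FragmentSet"))
  if (a$condition != b$condition || a$assay != b$assay)
    stop("can only pool libraries from the same condition and assay")
  fragment_set(rbind(a$fragments, b$fragments, fill = TRUE),
               condition = a$condition, assay = a$assay, digest = "combined")
}

#' Read fragments from BED3 or BEDPE
#'
#' BEDPE mate pairs are collapsed to the outer span of the pair (a proper
#' paired-end fragment). Malformed records — unparseable coordinates,
#' negative coordinates, `start >= end`, inter-chromosomal pairs, or sizes
#' outside the 20–500 bp fragment bounds — are dropped; their count is
#' attached as attribute `n_rejected` and reported via a warning with line
#' numbers.
#'
#' @param path file path (plain text; `#` comment lines are skipped).
#' @param format `"BED3"` or `"BEDPE"`.
#' @inheritParams fragment_set
#' @return A `FragmentSet`.
#' @export
read_fragments <- function(path, format = c("BED3", "BEDPE"),
                           condition = "control", assay = "total",
                           digest = "combined") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  top <- readLines(path, n = 100L)
  nskip <- sum(cumprod(startsWith(top, "#")))
  if (length(top) <= nskip)
    return(fragment_set(NULL, condition, assay, digest))
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              skip = nskip, blank.lines.skip = TRUE)
  if (nrow(dt) && is.character(dt[[1]]))
    dt <- dt[!startsWith(dt[[1]], "#")]
  if (!nrow(dt))
    return(fragment_set(NULL, condition, assay, digest))
  if (format == "BED3") {
    fr <- data.table(chrom = as.character(dt[[1]]),
                     start = suppressWarnings(as.integer(dt[[2]])),
                     end = suppressWarnings(as.integer(dt[[3]])))
  } else {
    if (ncol(dt) < 6) stop("BEDPE requires at least 6 columns")
    s1 <- suppressWarnings(as.integer(dt[[2]])); e1 <- suppressWarnings(as.integer(dt[[3]]))
    s2 <- suppressWarnings(as.integer(dt[[5]])); e2 <- suppressWarnings(as.integer(dt[[6]]))
    fr <- data.table(chrom = as.character(dt[[1]]),
                     start = pmin(s1, s2), end = pmax(e1, e2))
    same <- as.character(dt[[1]]) == as.character(dt[[4]])
    fr[!same | is.na(same), start := NA_integer_]
  }
  size <- fr$end - fr$start
  bad <- is.na(fr$start) | is.na(fr$end) | fr$start < 0 | fr$start >= fr$end |
    size < 20L | size > 500L
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    lines <- which(bad)
    warning(sprintf("%d malformed/out-of-range record(s) rejected (lines %s%s)",
                    sum(bad), paste(head(lines, 5), collapse = ","),
                    if (sum(bad) > 5) ",..." else ""))
  }
  fs <- fragment_set(fr[!bad], condition, assay, digest)
  attr(fs, "n_rejected") <- sum(bad)
  fs
}

#' Fragment midpoint
#'
#' Midpoint of a 0-based half-open interval, `floor((start + end) / 2)`,
#' used as the nucleosome dyad proxy.
#'
#' @param start,end integer vectors of interval bounds.
#' @return Integer midpoints.
#' @export
fragment_midpoint <- function(start, end) as.integer((start + end) %/% 2)

#' Genomic coordinate to strand-oriented TSS offset
#'
#' Converts a genomic position to an offset from the promoter TSS, oriented
#' so that positive offsets are downstream of transcription: `pos - tss` on
#' the `+` strand and `tss - pos` on the `-` strand. Positions mapping
#' outside `[-1000, 1000)` return `NA`.
#'
#' @param pos genomic coordinate(s), 0-based.
#' @param tss TSS coordinate (recycled).
#' @param strand `"+"` or `"-"` (recycled).
#' @return Integer offsets with `NA` outside the window.
#' @export
to_relative <- function(pos, tss, strand) {
  sgn <- ifelse(strand == "+", 1L, -1L)
  off <- as.integer(sgn * (pos - tss))
  off[off < -1000L | off >= 1000L] <- NA_integer_
  off
}

#' Subsample a fragment library without replacement
#'
#' @param fs a `FragmentSet`.
#' @param n number of fragments to keep; must not exceed `fs$count`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A `FragmentSet` with `n` fragments (input order preserved).
#' @export
subsample_fragments <- function(fs, n, seed) {
  stopifnot(inherits(fs, "FragmentSet"))
  if (n > fs$count) stop("cannot subsample ", n, " from ", fs$count, " fragments")
  keep <- with_seed(seed, sort(sample.int(fs$count, n)))
  fragment_set(fs$fragments[keep], fs$condition, fs$assay, fs$digest)
}

#' Read a promoter annotation from BED6
#'
#' The BED interval is the 2 kb capture window `[tss - 1000, tss + 1000)`;
#' the TSS is recovered as `start + 1000` unless an optional 7th numeric
#' column declares it explicitly. The name column carries the gene id.
#'
#' @param path BED6(+1) file; `#` lines skipped.
#' @return A `PromoterSet`.
#' @export
read_promoters <- function(path) {
  top <- readLines(path, n = 100L)
  nskip <- sum(cumprod(startsWith(top, "#")))
  dt <- fread(path, header = FALSE, sep = "\t", skip = nskip,
              blank.lines.skip = TRUE)
  if (is.character(dt[[1]])) dt <- dt[!startsWith(dt[[1]], "#")]
  if (ncol(dt) < 6) stop("promoter BED must have 6 columns (name = gene id, strand required)")
  strand <- as.character(dt[[6]])
  if (any(!strand %in% c("+", "-"))) stop("missing or invalid strand in promoter BED")
  tss <- if (ncol(dt) >= 7 && is.numeric(dt[[7]])) as.integer(dt[[7]])
         else as.integer(dt[[2]]) + 1000L
  promoter_set(gene_id = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
               tss = tss, strand = strand)
}

#' Write a promoter set as BED6
#' @param ps a `PromoterSet`.
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @export
write_promoters <- function(ps, path, seed = NA) {
  writeLines(provenance_line("write_promoters", seed), path)
  fwrite(ps[, .(chrom, start, end, gene_id, score = 0L, strand)],
         path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write fragments as BED3
#' @param fs a `FragmentSet`.
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @export
write_fragments <- function(fs, path, seed = NA) {
  writeLines(provenance_line("write_fragments", seed), path)
  fwrite(fs$fragments[, .(chrom, start, end)], path, sep = "\t",
         col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated with a header row; first column `gene_id`, remaining
#' columns one abundance (TPM-like, non-negative) per condition. `"."`
#' denotes missing and becomes `NA`.
#'
#' @param path TSV path.
#' @return A `data.table` keyed by `gene_id`.
#' @export
read_expression <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", na.strings = ".")
  setnames(dt, 1, "gene_id")
  if (anyDuplicated(dt$gene_id)) stop("duplicate gene_id in expression table")
  num <- names(dt)[-1]
  for (cn in num) set(dt, j = cn, value = as.numeric(dt[[cn]]))
  if (any(unlist(dt[, ..num]) < 0, na.rm = TRUE))
    stop("negative abundance in expression table")
  setkey(dt, gene_id)
  dt[]
}

#' Read promoter sequences from FASTA
#'
#' Sequences are uppercased; `N` bases are legal and are excluded from
#' dinucleotide counting downstream.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (names = contig ids).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a signal/sensitivity matrix as TSV
#'
#' Rows are gene ids, columns the bin centres (or per-bp offsets) of the
#' TSS-relative axis; a `#promarch` provenance line precedes the header.
#'
#' @param m matrix with rownames (gene ids) and numeric-parseable colnames.
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @export
write_matrix <- function(m, path, seed = NA) {
  dt <- data.table(gene_id = rownames(m))
  dt <- cbind(dt, as.data.table(unclass(m)))
  writeLines(provenance_line("write_matrix", seed), path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#' @param path TSV path.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_matrix <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", skip = 1)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
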