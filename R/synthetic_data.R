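## Ground-truth synthetic data: promoter architectures, differential MNase
## digestion, H2A.Z ChIP subsetting, subnucleosomal fragments at TF
## footprints and TSS bursts, and promoter sequences with planted WW
## rotational phasing. Emits exactly the containers/formats the rest of
## the pipeline consumes, so every stage is testable without sequencing
## data.

#' Default promoter architecture classes
#'
#' Seven classes spanning the architecture vocabulary of promoter
#' chromatin: a single dominant positioned nucleosome at the -2, -1, +1 or
#' +2 position (MNase-resistant, H2A.Z), an MNase-sensitive nucleosome
#' sitting on the TSS, a fuzzy/poorly-positioned sensitive repressed
#' configuration, and an H2A.Z-free promoter. Each class carries its
#' nucleosome specs (centre offset from the TSS, positional fuzziness sd,
#' occupancy, stability where 1 = MNase-resistant, H2A.Z flag), TF
#' footprints with the conditions in which they are bound, and a lognormal
#' expression model per condition.
#'
#' @return Named list of class descriptions.
#' @export
default_architecture_classes <- function() {
  nuc <- function(centre, fuzz, occ, stab, h2az)
    data.table(centre = centre, fuzz = fuzz, occ = occ, stab = stab,
               h2az = h2az)
  tf <- function(offset, width, control, knockdown)
    data.table(offset = offset, width = width,
               bound_control = control, bound_knockdown = knockdown)
  no_tf <- tf(integer(), integer(), logical(), logical())
  # statistically positioned array filling the window; stability 0.65 is the
  # neutral point where light and heavy digestion weights coincide
  array_nucs <- function(skip = integer()) {
    pos <- setdiff(c(-880L, -700L, -520L, 520L, 700L, 880L), skip)
    nuc(pos, 50, 0.35, 0.65, FALSE)
  }
  with_array <- function(core, skip = integer()) rbind(core, array_nucs(skip))
  list(
    "plus1_MRN" = list(
      nucs = with_array(rbind(nuc(125L, 20, 0.90, 0.90, TRUE),
                              nuc(320L, 35, 0.45, 0.65, FALSE),
                              nuc(-180L, 40, 0.35, 0.65, FALSE),
                              nuc(-380L, 50, 0.35, 0.65, FALSE))),
      tfs = tf(-300L, 20L, TRUE, TRUE),
      expr = c(control = 6, knockdown = 6)),
    "minus1_MRN" = list(
      nucs = with_array(rbind(nuc(-125L, 20, 0.90, 0.90, TRUE),
                              nuc(-320L, 35, 0.45, 0.65, FALSE),
                              nuc(180L, 40, 0.35, 0.65, FALSE),
                              nuc(380L, 50, 0.35, 0.65, FALSE))),
      tfs = no_tf,
      expr = c(control = 5.5, knockdown = 5.5)),
    "MSN_TSS" = list(
      nucs = with_array(rbind(nuc(0L, 15, 0.85, 0.05, TRUE),
                              nuc(180L, 30, 0.50, 0.65, FALSE),
                              nuc(-200L, 40, 0.40, 0.65, FALSE),
                              nuc(360L, 50, 0.35, 0.65, FALSE))),
      tfs = tf(-350L, 20L, TRUE, TRUE),
      expr = c(control = 8, knockdown = 5)),
    "plus2_MRN" = list(
      nucs = with_array(rbind(nuc(320L, 25, 0.85, 0.85, TRUE),
                              nuc(120L, 45, 0.30, 0.65, FALSE),
                              nuc(-150L, 45, 0.30, 0.65, FALSE),
                              nuc(-360L, 50, 0.35, 0.65, FALSE))),
      tfs = no_tf,
      expr = c(control = 4, knockdown = 4)),
    "minus2_MRN" = list(
      nucs = with_array(rbind(nuc(-320L, 25, 0.85, 0.85, TRUE),
                              nuc(-120L, 45, 0.30, 0.65, FALSE),
                              nuc(150L, 45, 0.30, 0.65, FALSE),
                              nuc(360L, 50, 0.35, 0.65, FALSE))),
      tfs = no_tf,
      expr = c(control = 3.5, knockdown = 3.5)),
    "fuzzy_repressed" = list(
      nucs = with_array(rbind(nuc(-100L, 70, 0.50, 0.15, TRUE),
                              nuc(100L, 70, 0.50, 0.15, TRUE),
                              nuc(-330L, 70, 0.35, 0.40, FALSE),
                              nuc(330L, 70, 0.35, 0.40, FALSE))),
      tfs = no_tf,
      expr = c(control = 1, knockdown = 4)),
    "no_h2az" = list(
      nucs = with_array(rbind(nuc(150L, 25, 0.60, 0.50, FALSE),
                              nuc(-80L, 45, 0.35, 0.65, FALSE),
                              nuc(-300L, 50, 0.35, 0.65, FALSE),
                              nuc(350L, 50, 0.35, 0.65, FALSE))),
      tfs = tf(-150L, 20L, FALSE, TRUE),
      expr = c(control = 3, knockdown = 3))
  )
}

#' Planted sensitivity-profile matrix
#'
#' Matrix-level planted model for clustering calibration: k classes with
#' distinct MSN/MRN-style mean profiles (a positive or negative block at a
#' class-specific position on the TSS axis) of amplitude
#' `separation * noise_sd`, plus i.i.d. Gaussian noise of sd `noise_sd`.
#' This isolates the separation-to-noise ratio, which fragment-level
#' simulation cannot control directly.
#'
#' @param n_promoters rows.
#' @param k classes.
#' @param separation class amplitude in units of `noise_sd` (default 5).
#' @param noise_sd per-bin noise sd (default 0.2).
#' @param seed integer seed.
#' @return List with `matrix` (rows `P00001`... and dyad-bin colnames) and
#'   `truth` (integer class labels).
#' @export
planted_sensitivity_matrix <- function(n_promoters = 2000L, k = 7L,
                                       separation = 5, noise_sd = 0.2,
                                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  sch <- bin_scheme()
  centres <- seq(-420, 420, length.out = k)     # block sites inside the
                                                # default +/-500 bp window
  signs <- rep_len(c(1, -1), k)                 # alternate MSN / MRN blocks
  with_seed(seed, {
    truth <- sort(rep_len(seq_len(k), n_promoters))
    mu <- matrix(0, k, sch$n)
    for (j in seq_len(k))
      mu[j, abs(sch$centers - centres[j]) <= 60] <-
        signs[j] * separation * noise_sd
    m <- mu[truth, ] + matrix(rnorm(n_promoters * sch$n, 0, noise_sd),
                              n_promoters, sch$n)
    dimnames(m) <- list(sprintf("P%05d", seq_len(n_promoters)), sch$centers)
    list(matrix = structure(m, kind = "sensitivity", units = "log2_ratio",
                            class = c("SensitivityMatrix", "SignalMatrix",
                                      class(m))),
         truth = truth)
  })
}

#' Generator configuration
#'
#' @param n_promoters number of promoters (default 2000).
#' @param classes architecture classes
#'   ([default_architecture_classes()]).
#' @param weights class mixture weights (must sum to 1; default uniform).
#' @param depth fragments per condition x digest library (default 2e6).
#' @param seed master seed (mandatory).
#' @param ww_period,ww_amplitude,ww_base planted rotational phasing: WW
#'   (A/T) dinucleotide start probability inside nucleosome footprints is
#'   `ww_base + ww_amplitude * cos(2 pi d / ww_period)` at offset d from
#'   the dyad (defaults 10 bp, 0.1, 0.25).
#' @param sf_len_mean,sf_len_sd subnucleosomal fragment length model,
#'   truncated to 20-124 bp (defaults 60, 10).
#' @param nuc_len_mean,nuc_len_sd nucleosomal fragment length model,
#'   truncated to 126-200 bp (defaults 150, 4; the mode keeps a 147-150
#'   bp core population).
#' @param background_frac fraction of each library that is uniform
#'   background over the windows (default 0.05).
#' @param sf_frac fraction of each total library emitted by TF footprints
#'   and TSS bursts (default 0.05).
#' @param tss_burst_factor multiplier on the TSS SF rate under H2A.Z
#'   knockdown for classes with a TSS nucleosome (default 8).
#' @param kd_stability_factor multiplier applied to the stability of
#'   H2A.Z nucleosomes under knockdown (default 0.25: loss of MNase
#'   resistance).
#' @param chip_efficiency,chip_background retention probabilities of the
#'   H2A.Z ChIP for fragments from H2A.Z-flagged vs other nucleosomes
#'   (defaults 0.8, 0.02).
#' @return A `GeneratorConfig` list.
#' @export
generator_config <- function(n_promoters = 2000L,
                             classes = default_architecture_classes(),
                             weights = NULL, depth = 2e6, seed,
                             ww_period = 10L, ww_amplitude = 0.1,
                             ww_base = 0.25,
                             sf_len_mean = 60, sf_len_sd = 10,
                             nuc_len_mean = 150, nuc_len_sd = 4,
                             background_frac = 0.05, sf_frac = 0.05,
                             tss_burst_factor = 8,
                             kd_stability_factor = 0.25,
                             chip_efficiency = 0.8,
                             chip_background = 0.02) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(weights)) weights <- rep(1 / length(classes), length(classes))
  if (abs(sum(weights) - 1) > 1e-8) stop("class weights must sum to 1")
  if (length(weights) != length(classes))
    stop("one weight per class required")
  if (depth <= 0) stop("depth must be positive")
  if (ww_amplitude > ww_base) stop("ww_amplitude must not exceed ww_base")
  cfg <- as.list(environment())
  structure(cfg, class = "GeneratorConfig")
}

# condition-adjusted nucleosome truth table: one row per (promoter,
# nucleosome) with genomic dyad centre
nucleosome_truth <- function(truth, ps, cfg, condition) {
  cls <- cfg$classes
  nt <- rbindlist(lapply(seq_len(nrow(ps)), function(i) {
    cn <- truth$class[i]
    n <- copy(cls[[cn]]$nucs)
    n[, gene_id := ps$gene_id[i]]
    n[, row := i]
    n
  }))
  nt[, dyad := ifelse(ps$strand[row] == "+", ps$tss[row] + centre,
                      ps$tss[row] - centre)]
  nt[, chrom := ps$chrom[row]]
  if (condition == "knockdown")
    nt[h2az == TRUE, stab := stab * cfg$kd_stability_factor]
  nt[]
}

rtrunc_lengths <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, as.integer(round(rnorm(n, mean, sd)))))
}

#' Simulate a differential MNase digestion library
#'
#' Each nucleosome emits fragments with sampling weight
#' `occ * (0.6 + 0.4 * (1 - stab))` under light digestion and
#' `occ * (0.2 + 0.8 * stab)` under heavy digestion, so resistant
#' nucleosomes (stab = 1) have log2(light/heavy) = log2(0.6) ~ -0.74 and
#' sensitive ones (stab = 0) log2(1/0.2) ~ +2.32. Fragment dyads are
#' drawn at the nucleosome centre plus a translational displacement
#' quantized to the helical repeat (`ww_period`), preserving the planted
#' rotational frame; lengths follow the nucleosomal model. Under heavy
#' digestion, sensitive nucleosomes (stab < 0.3) emit subnucleosomal
#' lengths with probability 0.3 (over-digestion of unstable particles).
#'
#' @param truth truth table from [generate_dataset()] (`$classes`).
#' @param ps the `PromoterSet`.
#' @param cfg a `GeneratorConfig`.
#' @param condition `"control"` or `"knockdown"`.
#' @param digest `"light"` or `"heavy"`.
#' @param n number of fragments to draw.
#' @return `data.table` of fragments with provenance columns `gene_id`,
#'   `h2az`, `origin = "nuc"`.
#' @export
simulate_digest <- function(truth, ps, cfg, condition, digest, n) {
  nt <- nucleosome_truth(truth, ps, cfg, condition)
  w <- if (digest == "light") nt$occ * (0.6 + 0.4 * (1 - nt$stab))
       else nt$occ * (0.2 + 0.8 * nt$stab)
  if (all(w == 0) || n == 0)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      h2az = logical(), origin = character()))
  idx <- sample.int(nrow(nt), n, replace = TRUE, prob = w)
  # translational displacement on the helical-repeat grid keeps the
  # rotational frame of the planted sequence periodicity; with no planted
  # rotational signal there is no frame to preserve and displacement is
  # continuous
  disp <- rnorm(n, 0, nt$fuzz[idx])
  if (cfg$ww_amplitude > 0)
    disp <- cfg$ww_period * round(disp / cfg$ww_period)
  dyad <- nt$dyad[idx] + as.integer(round(disp))
  len <- rtrunc_lengths(n, cfg$nuc_len_mean, cfg$nuc_len_sd, 126L, 200L)
  if (digest == "heavy") {
    sens <- nt$stab[idx] < 0.3
    sf <- sens & runif(n) < 0.3
    if (any(sf))
      len[sf] <- rtrunc_lengths(sum(sf), cfg$sf_len_mean, cfg$sf_len_sd,
                                20L, 124L)
  }
  start <- dyad - len %/% 2L
  end <- start + len
  out <- data.table(chrom = nt$chrom[idx], start = start, end = end,
                    gene_id = nt$gene_id[idx], h2az = nt$h2az[idx],
                    origin = "nuc")
  # drop the rare fragment running outside its 2 kb contig/window
  lim <- setNames(ps$end, ps$chrom)[out$chrom]
  out[start >= 0L & end <= lim]
}

#' Simulate subnucleosomal fragments at TF footprints and the TSS
#'
#' Bound TF footprints emit SF-length fragments centred on the site;
#' promoters whose class has a nucleosome on the TSS additionally emit
#' TSS-centred SFs whose rate is multiplied by `tss_burst_factor` under
#' H2A.Z knockdown.
#'
#' @inheritParams simulate_digest
#' @param n number of SF fragments to draw.
#' @return `data.table` of fragments with `origin` `"tf"` or `"tss_burst"`.
#' @export
simulate_sf <- function(truth, ps, cfg, condition, n) {
  bound_col <- paste0("bound_", condition)
  src <- rbindlist(lapply(seq_len(nrow(ps)), function(i) {
    cl <- cfg$classes[[truth$class[i]]]
    out <- list()
    tfs <- cl$tfs[cl$tfs[[bound_col]] == TRUE]
    if (nrow(tfs))
      out$tf <- data.table(offset = tfs$offset, width = tfs$width,
                           weight = 1, origin = "tf", row = i)
    has_tss_nuc <- any(abs(cl$nucs$centre) <= 30 & cl$nucs$h2az)
    if (has_tss_nuc) {
      burst <- if (condition == "knockdown") cfg$tss_burst_factor else 1
      out$tss <- data.table(offset = 0L, width = 30L, weight = 0.25 * burst,
                            origin = "tss_burst", row = i)
    }
    rbindlist(out)
  }))
  if (!nrow(src) || n == 0)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      h2az = logical(), origin = character()))
  idx <- sample.int(nrow(src), n, replace = TRUE, prob = src$weight)
  centre_rel <- src$offset[idx] +
    as.integer(round(rnorm(n, 0, src$width[idx] / 4)))
  row <- src$row[idx]
  centre <- ifelse(ps$strand[row] == "+", ps$tss[row] + centre_rel,
                   ps$tss[row] - centre_rel)
  len <- rtrunc_lengths(n, cfg$sf_len_mean, cfg$sf_len_sd, 20L, 124L)
  start <- as.integer(centre) - len %/% 2L
  out <- data.table(chrom = ps$chrom[row], start = start,
                    end = start + len, gene_id = ps$gene_id[row],
                    h2az = FALSE, origin = src$origin[idx])
  lim <- setNames(ps$end, ps$chrom)[out$chrom]
  out[start >= 0L & end <= lim]
}

#' Simulate an H2A.Z ChIP from a total MNase library
#'
#' Retains fragments originating from H2A.Z-flagged nucleosomes with
#' probability `chip_efficiency` and all other fragments with the
#' background rate `chip_background`.
#'
#' @param total fragment `data.table` with an `h2az` column.
#' @param cfg a `GeneratorConfig`.
#' @return The retained subset.
#' @export
simulate_chip <- function(total, cfg) {
  p <- ifelse(total$h2az, cfg$chip_efficiency, cfg$chip_background)
  total[runif(nrow(total)) < p]
}

#' Generate promoter sequences with planted rotational phasing
#'
#' Background positions are i.i.d. with per-base W (A/T) probability
#' `sqrt(ww_base)`, giving a genome-wide WW-start frequency of `ww_base`.
#' Inside each nucleosome footprint (dyad ±73 bp) the W marginal is
#' modulated as `sqrt(ww_base) + ww_amplitude / (2 sqrt(ww_base)) *
#' cos(2 pi d / ww_period)` at offset d from the dyad, which plants a
#' WW-start probability of `ww_base + ww_amplitude * cos(...)` up to a
#' second-order term. W resolves to A or T (and S to C or G) with equal
#' probability.
#'
#' @inheritParams simulate_digest
#' @return Named character vector, one 2 kb sequence per promoter contig.
#' @export
generate_sequences <- function(truth, ps, cfg) {
  if (cfg$ww_amplitude > cfg$ww_base)
    stop("ww_amplitude must not exceed ww_base")
  base_w <- sqrt(cfg$ww_base)
  amp_w <- cfg$ww_amplitude / (2 * base_w)
  nt <- nucleosome_truth(truth, ps, cfg, "control")
  seqs <- character(nrow(ps))
  for (i in seq_len(nrow(ps))) {
    wlen <- ps$end[i] - ps$start[i]
    pw <- rep(base_w, wlen)
    ni <- nt[row == i]
    for (j in seq_len(nrow(ni))) {
      d0 <- ni$dyad[j] - ps$start[i]           # dyad, window-local
      pos <- (d0 - 73L):(d0 + 73L)
      keep <- pos >= 0L & pos < wlen
      d <- (pos - d0)[keep]
      pw[pos[keep] + 1L] <- base_w + amp_w * cos(2 * pi * d / cfg$ww_period)
    }
    isW <- runif(wlen) < pw
    half <- runif(wlen) < 0.5
    b <- ifelse(isW, ifelse(half, "A", "T"), ifelse(half, "C", "G"))
    seqs[i] <- paste(b, collapse = "")
  }
  names(seqs) <- ps$chrom
  seqs
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Builds a promoter set (one 2 kb contig per promoter, TSS at 1000,
#' alternating strands), assigns architecture classes by the mixture
#' weights, plants rotationally phased sequences, simulates light/heavy
#' total MNase and H2A.Z ChIP libraries for a `control` and an H2A.Z
#' `knockdown` condition (each library: nucleosomal fragments + TF/TSS
#' subnucleosomal fragments + uniform background), and draws a lognormal
#' expression table with planted differential expression between the
#' conditions. Deterministic for a fixed master seed.
#'
#' @param cfg a [generator_config()].
#' @return List with `promoters`, `sequences`, `fragments` (nested
#'   `[[condition]][[assay]][[digest]]` of `FragmentSet`s; `assay` is
#'   `total` or `chip`), `expression` (`gene_id`, `control`,
#'   `knockdown`), `de_sets` (`top_DE_up`, `top_DE_down`), `truth`
#'   (class labels and nucleosome/footprint tables), `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  with_seed(cfg$seed, {
    n <- cfg$n_promoters
    gene_id <- sprintf("G%05d", seq_len(n))
    ps <- promoter_set(gene_id = gene_id, chrom = gene_id,
                       tss = rep(1000L, n),
                       strand = rep(c("+", "-"), length.out = n))
    class_names <- names(cfg$classes)
    cls <- class_names[sample.int(length(class_names), n, replace = TRUE,
                                  prob = cfg$weights)]
    truth <- list(class = cls,
                  classes = data.table(gene_id = gene_id, class = cls))
    seqs <- generate_sequences(truth, ps, cfg)

    conditions <- c("control", "knockdown")
    n_bg <- round(cfg$depth * cfg$background_frac)
    n_sf <- round(cfg$depth * cfg$sf_frac)
    n_nuc <- cfg$depth - n_bg - n_sf
    frags <- list()
    for (cond in conditions) {
      frags[[cond]] <- list(total = list(), chip = list())
      for (dg in c("light", "heavy")) {
        nucfr <- simulate_digest(truth, ps, cfg, cond, dg, n_nuc)
        sffr <- simulate_sf(truth, ps, cfg, cond, n_sf)
        bg_row <- sample.int(n, n_bg, replace = TRUE)
        bg_len <- rtrunc_lengths(n_bg, cfg$nuc_len_mean, cfg$nuc_len_sd,
                                 126L, 200L)
        bg_start <- ps$start[bg_row] +
          as.integer(floor(runif(n_bg) * (2000L - bg_len)))
        bgfr <- data.table(chrom = ps$chrom[bg_row], start = bg_start,
                           end = bg_start + bg_len,
                           gene_id = ps$gene_id[bg_row], h2az = FALSE,
                           origin = "background")
        tot <- rbind(nucfr, sffr, bgfr)
        frags[[cond]]$total[[dg]] <-
          fragment_set(tot, condition = cond, assay = "total", digest = dg)
        frags[[cond]]$chip[[dg]] <-
          fragment_set(simulate_chip(tot, cfg), condition = cond,
                       assay = "chip", digest = dg)
      }
      for (as_ in c("total", "chip"))
        frags[[cond]][[as_]]$combined <-
          pool_digests(frags[[cond]][[as_]]$light, frags[[cond]][[as_]]$heavy)
    }

    mu <- vapply(cfg$classes, function(cl) cl$expr, numeric(2L))
    expr <- data.table(
      gene_id = gene_id,
      control = 2^rnorm(n, mu["control", cls], 1),
      knockdown = 2^rnorm(n, mu["knockdown", cls], 1))
    lfc_planted <- mu["knockdown", cls] - mu["control", cls]
    de_sets <- list(top_DE_up = gene_id[lfc_planted >= 1],
                    top_DE_down = gene_id[lfc_planted <= -1])

    list(promoters = ps, sequences = seqs, fragments = frags,
         expression = expr, de_sets = de_sets, truth = truth,
         config = cfg)
  })
}
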