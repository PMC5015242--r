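#' Default expressed-transcriptome census
#'
#' Gene counts per taxonomy leaf emulating the biotype composition of an
#' expressed (mean CPM > 1) bulk neuronal transcriptome of 16,014 genes:
#' 84.5 % protein-coding, 10.7 % ncRNA (with ~45/49/5 % lincRNA/antisense/
#' sense-intronic among lncRNAs) and 4.8 % pseudogenes.
#'
#' @param scale Multiplier on all leaf counts (default 1); counts are
#'   rounded and kept >= 1 for scaled-down desk configurations.
#' @return Named integer vector of gene counts per leaf.
#' @export
default_census <- function(scale = 1) {
  full <- c(protein_coding = 13539L,
            lincRNA = 509L, antisense = 551L, sense_intronic = 59L,
            sense_overlapping = 4L, three_prime_overlapping = 1L,
            miRNA = 116L, snoRNA = 81L, snRNA = 20L, rRNA = 10L,
            miscRNA = 38L, processed_transcript = 319L,
            pseudogene = 767L)
  if (scale == 1) return(full)
  pmax(1L, as.integer(round_half_away(full * scale)))
}

#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions every synthetic bundle emulates: a 6-vs-5
#' two-group count matrix over the default census, negative-binomial noise
#' with one global dispersion, planted co-expressed lncRNA/coding pairs,
#' and one planted strongly upregulated lncRNA.
#'
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   config.
#' @param n_exposed,n_control Group sizes (default 6 and 5; samples are
#'   labelled N1..N6 and C1..C5).
#' @param census Named leaf counts (default \code{\link{default_census}()}).
#' @param depth Library size per sample in read-pairs (default 1e6, desk
#'   scale).
#' @param baseline_log2_mean,baseline_log2_sd Parameters of the log-normal
#'   baseline expression (log2 CPM), defaults 3 and 2.
#' @param baseline_log2_min Lower truncation of the baseline (log2 CPM,
#'   default 1, i.e. CPM >= 2) so that the generated matrix emulates the
#'   expressed transcriptome.
#' @param dispersion Global NB dispersion phi (default 0.1); 0 gives
#'   Poisson counts.
#' @param planted_pairs data.frame with columns \code{subclass}
#'   (\code{antisense}/\code{lincRNA}/\code{sense_intronic}),
#'   \code{geometry} (\code{antisense-overlap},
#'   \code{adjacent-with-promoter-overlap}, \code{adjacent-no-promoter}),
#'   \code{target_r} (|r| < 1) and \code{count}. Default: 8 antisense /
#'   6 lincRNA / 2 sense-intronic pairs at target r 0.9 (the 41:34:7
#'   detected-pair mix, scaled).
#' @param pair_baseline_cpm Baseline CPM of both genes of a planted pair
#'   (default 50).
#' @param pair_log_sd Natural-log SD of the shared lognormal factor driving
#'   planted-pair co-expression (default 1.5).
#' @param planted_de data.frame with columns \code{fold}, \code{biotype},
#'   \code{mean_cpm} (all-sample mean CPM of the planted gene). Default one
#'   80-fold upregulated antisense lncRNA at mean 4.5 CPM.
#' @param n_enhancers Number of enhancer intervals in the BED output
#'   (default 3); the first covers the TSS of the first planted antisense
#'   lncRNA, the rest are decoys in gene-free space.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             n_exposed = 6L, n_control = 5L,
                             census = default_census(),
                             depth = 1e6,
                             baseline_log2_mean = 3,
                             baseline_log2_sd = 2,
                             baseline_log2_min = 1,
                             dispersion = 0.1,
                             planted_pairs = data.frame(
                               subclass = c("antisense", "lincRNA",
                                            "sense_intronic"),
                               geometry = c("antisense-overlap",
                                            "adjacent-with-promoter-overlap",
                                            "adjacent-no-promoter"),
                               target_r = 0.9,
                               count = c(8L, 6L, 2L),
                               stringsAsFactors = FALSE),
                             pair_baseline_cpm = 50,
                             pair_log_sd = 1.5,
                             planted_de = data.frame(
                               fold = 80, biotype = "antisense",
                               mean_cpm = 4.5,
                               stringsAsFactors = FALSE),
                             n_enhancers = 3L) {
  stopifnot(depth > 0, n_exposed >= 1, n_control >= 1,
            dispersion >= 0, pair_baseline_cpm > 0, pair_log_sd > 0)
  if (any(abs(planted_pairs$target_r) >= 1))
    stop("|target r| must be < 1")
  if (nrow(planted_de) > 0 && any(planted_de$fold <= 0))
    stop("planted fold must be > 0")
  ok_geo <- c("antisense-overlap", "adjacent-with-promoter-overlap",
              "adjacent-no-promoter")
  if (!all(planted_pairs$geometry %in% ok_geo))
    stop("unknown planted-pair geometry")
  if (!all(planted_pairs$subclass %in% screened_subclasses()))
    stop("planted-pair subclass must be one of the screened classes")
  # planted genes are drawn from the census
  need_lnc <- tapply(planted_pairs$count, planted_pairs$subclass, sum)
  for (s in names(need_lnc)) {
    if (is.na(census[s]) || census[s] < need_lnc[[s]])
      stop("census leaf '", s, "' too small for the planted pairs")
  }
  need_cod <- sum(planted_pairs$count) + 2 * nrow(planted_de)
  if (census["protein_coding"] < need_cod)
    stop("census protein_coding too small for the planted structure")
  if (nrow(planted_de) > 0) {
    for (bt in planted_de$biotype)
      if (is.na(census[bt]) || census[bt] < sum(planted_de$biotype == bt))
        stop("census leaf '", bt, "' too small for the planted DE genes")
  }
  structure(list(seed = as.integer(seed),
                 n_exposed = as.integer(n_exposed),
                 n_control = as.integer(n_control),
                 census = census, depth = depth,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 baseline_log2_min = baseline_log2_min,
                 dispersion = dispersion,
                 planted_pairs = planted_pairs,
                 pair_baseline_cpm = pair_baseline_cpm,
                 pair_log_sd = pair_log_sd,
                 planted_de = planted_de,
                 n_enhancers = as.integer(n_enhancers)),
            class = "synthetic_config")
}

#' Latent-factor loading for a target CPM-scale correlation
#'
#' Closed-form calibration of the shared lognormal factor: with both genes
#' at baseline count mean \code{m}, lognormal multiplier of natural-log SD
#' \code{sigma} and NB dispersion \code{phi}, the realized covariance of
#' counts is \code{m^2 (exp(sigma^2 a1 a2) - 1)} against a per-gene count
#' variance \code{m + phi m^2 e^{sigma^2} + m^2 (e^{sigma^2} - 1)}. The
#' product of loadings solving for the target correlation is clipped to
#' [-1, 1]; NB sampling noise therefore caps the attainable |r| (at
#' phi = 0.1 near 0.91), and the cap is reported as \code{expected_r}.
#'
#' @param target_r Target Pearson correlation of expression (|r| < 1).
#' @param baseline_cpm Baseline CPM of both genes.
#' @param depth Library size.
#' @param phi NB dispersion.
#' @param sigma Natural-log SD of the lognormal factor.
#' @return List with \code{loading} (per-gene loading a, the second gene
#'   takes \code{sign(target_r) * a}) and \code{expected_r} (the analytic
#'   realized correlation after clipping).
#' @export
pair_loading <- function(target_r, baseline_cpm, depth, phi, sigma) {
  m <- baseline_cpm * depth / 1e6
  s2 <- sigma^2
  varx <- m + phi * m^2 * exp(s2) + m^2 * (exp(s2) - 1)
  S <- varx / m^2
  arg <- 1 + target_r * S
  lo <- exp(-s2)           # most negative attainable covariance factor
  c12 <- log(pmin(pmax(arg, lo), exp(s2))) / s2
  c12 <- pmin(pmax(c12, -1), 1)
  expected_r <- (exp(s2 * c12) - 1) * m^2 / varx
  list(loading = sqrt(abs(c12)) * c(1, sign(c12)),
       expected_r = expected_r)
}

# internal: deterministic planted-pair block geometry, one 200-kb block
# per pair on chr1. Returns genes/exons rows for the pair.
.pair_block <- function(k, geometry, subclass, lnc_id, cod_id) {
  o <- (k - 1L) * 200000L + 50000L
  gene <- function(id, bt, s, e, strand) {
    data.frame(gene_id = id, gene_name = id, biotype = bt, chrom = "chr1",
               start = s, end = e, strand = strand,
               stringsAsFactors = FALSE)
  }
  ex <- function(id, s, e) data.frame(gene_id = id, start = s, end = e,
                                      stringsAsFactors = FALSE)
  if (geometry == "antisense-overlap") {
    genes <- rbind(gene(cod_id, "protein_coding", o, o + 20000L, "+"),
                   gene(lnc_id, subclass, o + 4000L, o + 7000L, "-"))
    exons <- rbind(ex(cod_id, o, o + 1000L),
                   ex(cod_id, o + 15000L, o + 20000L),
                   ex(lnc_id, o + 4000L, o + 7000L))
  } else if (geometry == "adjacent-with-promoter-overlap") {
    genes <- rbind(gene(cod_id, "protein_coding", o + 12000L, o + 32000L,
                        "+"),
                   gene(lnc_id, subclass, o + 6000L, o + 9000L, "+"))
    exons <- rbind(ex(cod_id, o + 12000L, o + 13000L),
                   ex(cod_id, o + 28000L, o + 32000L),
                   ex(lnc_id, o + 6000L, o + 9000L))
  } else { # adjacent-no-promoter: lncRNA downstream of a + strand gene
    genes <- rbind(gene(cod_id, "protein_coding", o, o + 20000L, "+"),
                   gene(lnc_id, subclass, o + 30000L, o + 33000L, "+"))
    exons <- rbind(ex(cod_id, o, o + 20000L),
                   ex(lnc_id, o + 30000L, o + 33000L))
  }
  list(genes = genes, exons = exons)
}

# internal: planted DE block - a 3-exon lncRNA (mature length 662) on the
# plus strand, antisense to two minus-strand coding genes
.de_block <- function(k, n_pair_blocks, biotype, lnc_id, cod_ids) {
  o <- (n_pair_blocks + k - 1L) * 200000L + 50000L
  genes <- data.frame(
    gene_id = c(cod_ids, lnc_id),
    gene_name = c(cod_ids, lnc_id),
    biotype = c("protein_coding", "protein_coding", biotype),
    chrom = "chr1",
    start = c(o, o + 14000L, o + 8000L),
    end = c(o + 12000L, o + 26000L, o + 16000L),
    strand = c("-", "-", "+"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c(cod_ids[1], cod_ids[1], cod_ids[2], cod_ids[2],
                lnc_id, lnc_id, lnc_id),
    start = c(o, o + 10000L, o + 14000L, o + 24000L,
              o + 8000L, o + 11000L, o + 15800L),
    end = c(o + 2000L, o + 12000L, o + 16000L, o + 26000L,
            o + 8200L, o + 11262L, o + 16000L),
    stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

#' Generate a synthetic annotation with planted geometries
#'
#' Lays out genes on synthetic chromosomes without unintended overlaps.
#' Each planted pair occupies an isolated block on chr1 realizing its
#' requested geometry exactly (antisense pairs share coordinates on
#' opposite strands; promoter-overlap pairs place the lncRNA inside the
#' coding gene's 10-kb upstream window); each planted DE lncRNA is a
#' 3-exon antisense gene (mature length 662 nt) overlapping two coding
#' genes. Background genes fill chromosomes chr2 onwards in a seeded
#' shuffled order, so the census of the generated annotation matches the
#' configured leaf counts exactly. Enhancer intervals cover the designated
#' lncRNA TSS(s) plus decoy positions in gene-free space.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with \code{annot} (an \code{\link{annotation_set}}),
#'   \code{truth} (planted-structure tables: \code{pairs}, \code{de},
#'   \code{enhancer_lnc_ids}) and \code{enhancers} (BED-style data.frame).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  pp <- config$planted_pairs
  pair_rows <- pp[rep(seq_len(nrow(pp)), pp$count), , drop = FALSE]
  n_pairs <- nrow(pair_rows)
  n_de <- nrow(config$planted_de)

  genes <- list(); exons <- list()
  truth_pairs <- NULL
  if (n_pairs > 0) {
    lnc_ids <- sprintf("LNCP%03d", seq_len(n_pairs))
    cod_ids <- sprintf("CODP%03d", seq_len(n_pairs))
    for (k in seq_len(n_pairs)) {
      blk <- .pair_block(k, pair_rows$geometry[k], pair_rows$subclass[k],
                         lnc_ids[k], cod_ids[k])
      genes[[length(genes) + 1]] <- blk$genes
      exons[[length(exons) + 1]] <- blk$exons
    }
    cal <- lapply(pair_rows$target_r, pair_loading,
                  baseline_cpm = config$pair_baseline_cpm,
                  depth = config$depth, phi = config$dispersion,
                  sigma = config$pair_log_sd)
    truth_pairs <- data.frame(
      lnc_id = lnc_ids, coding_id = cod_ids,
      subclass = pair_rows$subclass, geometry = pair_rows$geometry,
      target_r = pair_rows$target_r,
      loading_lnc = vapply(cal, function(x) x$loading[1], 1),
      loading_coding = vapply(cal, function(x) x$loading[2], 1),
      expected_r = vapply(cal, function(x) x$expected_r, 1),
      stringsAsFactors = FALSE)
  } else {
    truth_pairs <- data.frame(lnc_id = character(), coding_id = character(),
                              subclass = character(), geometry = character(),
                              target_r = numeric(), loading_lnc = numeric(),
                              loading_coding = numeric(),
                              expected_r = numeric(),
                              stringsAsFactors = FALSE)
  }

  truth_de <- NULL
  if (n_de > 0) {
    de_ids <- sprintf("LNCDE%02d", seq_len(n_de))
    for (k in seq_len(n_de)) {
      cods <- sprintf("CODDE%02d%s", k, c("a", "b"))
      blk <- .de_block(k, n_pairs, config$planted_de$biotype[k],
                       de_ids[k], cods)
      genes[[length(genes) + 1]] <- blk$genes
      exons[[length(exons) + 1]] <- blk$exons
    }
    nE <- config$n_exposed; nC <- config$n_control
    fold <- config$planted_de$fold
    baseline_cpm <- config$planted_de$mean_cpm * (nE + nC) /
      (nC + nE * fold)
    truth_de <- data.frame(gene_id = de_ids,
                           biotype = config$planted_de$biotype,
                           fold = fold,
                           mean_cpm = config$planted_de$mean_cpm,
                           baseline_cpm = baseline_cpm,
                           stringsAsFactors = FALSE)
  } else {
    truth_de <- data.frame(gene_id = character(), biotype = character(),
                           fold = numeric(), mean_cpm = numeric(),
                           baseline_cpm = numeric(), stringsAsFactors = FALSE)
  }

  # background genes: census minus the planted consumption
  census <- config$census
  consumed <- table(c(pair_rows$subclass,
                      rep("protein_coding", n_pairs + 2L * n_de),
                      if (n_de > 0) config$planted_de$biotype))
  for (leaf in names(consumed)) census[leaf] <- census[leaf] - consumed[[leaf]]
  bg_leaves <- rep(names(census), as.integer(census))
  if (length(bg_leaves) > 0) {
    bg_leaves <- sample(bg_leaves)   # mix biotypes along chromosomes
    n_bg <- length(bg_leaves)
    n_chrom <- max(1L, min(18L, ceiling(n_bg / 900)))
    chrom <- sprintf("chr%d", 2L + (seq_len(n_bg) - 1L) %% n_chrom)
    per_chrom_pos <- stats::ave(seq_len(n_bg), chrom, FUN = seq_along)
    len <- ifelse(bg_leaves == "protein_coding", 20000L, 2000L)
    start <- (per_chrom_pos - 1L) * 40000L + 10000L
    strand <- ifelse(seq_len(n_bg) %% 2L == 0L, "+", "-")
    ids <- sprintf("BG%05d", seq_len(n_bg))
    bg_genes <- data.frame(gene_id = ids, gene_name = ids,
                           biotype = bg_leaves, chrom = chrom,
                           start = start, end = start + len,
                           strand = strand, stringsAsFactors = FALSE)
    genes[[length(genes) + 1]] <- bg_genes
    exons[[length(exons) + 1]] <- data.frame(gene_id = ids, start = start,
                                             end = start + len,
                                             stringsAsFactors = FALSE)
  }

  annot <- annotation_set(do.call(rbind, genes), do.call(rbind, exons))

  # enhancers: first covers the TSS of the first planted antisense lncRNA
  # (or the planted DE lncRNA when no pair exists); decoys go to empty space
  enh <- NULL
  covered <- character()
  if (config$n_enhancers > 0) {
    anchor <- NULL
    as_pairs <- truth_pairs$lnc_id[truth_pairs$subclass == "antisense"]
    if (length(as_pairs) > 0) anchor <- as_pairs[1]
    else if (nrow(truth_de) > 0) anchor <- truth_de$gene_id[1]
    rows <- list()
    k0 <- 1L
    if (!is.null(anchor)) {
      tss <- annot$genes$tss[match(anchor, annot$genes$gene_id)]
      rows[[1]] <- data.frame(chrom = "chr1", start = tss - 700L,
                              end = tss + 702L, stringsAsFactors = FALSE)
      covered <- anchor
      k0 <- 2L
    }
    if (config$n_enhancers >= k0) {
      far <- 50000000L + (seq_len(config$n_enhancers - k0 + 1L)) * 10000L
      rows[[length(rows) + 1]] <- data.frame(chrom = "chr1", start = far,
                                             end = far + 1400L,
                                             stringsAsFactors = FALSE)
    }
    enh <- do.call(rbind, rows)
  } else {
    enh <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }

  list(annot = annot,
       truth = list(pairs = truth_pairs, de = truth_de,
                    enhancer_lnc_ids = covered),
       enhancers = enh)
}

# internal: truncated-normal baseline draw (log2 CPM scale)
.rtrunc_log2 <- function(n, mean, sd, lo) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic count matrix with planted structure
#'
#' Per gene g and sample s, counts are negative binomial with mean
#' \code{q_gs * depth / 1e6} and global dispersion phi. Background
#' baselines q_g are log-normal (log2-CPM normal, truncated below so the
#' matrix emulates the expressed transcriptome). Each planted pair shares a
#' per-sample standard-normal latent factor whose loading is calibrated by
#' \code{\link{pair_loading}} so the expected CPM-scale Pearson correlation
#' approximates the target; planted DE genes have their exposed-group mean
#' multiplied by the fold. Library sizes equal the configured depth.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param annot The annotation from \code{\link{generate_annotation}}.
#' @param truth The truth tables from \code{\link{generate_annotation}}.
#' @return A \code{\link{count_matrix}} with samples N1..N\{nE\} (group
#'   \code{exposed}) and C1..C\{nC\} (group \code{control}).
#' @export
generate_counts <- function(config, annot, truth) {
  set.seed(config$seed + 1L)
  nE <- config$n_exposed; nC <- config$n_control
  n <- nE + nC
  samples <- c(sprintf("N%d", seq_len(nE)), sprintf("C%d", seq_len(nC)))
  groups <- stats::setNames(rep(c("exposed", "control"), c(nE, nC)),
                            samples)
  ids <- annot$genes$gene_id
  ng <- length(ids)

  base_cpm <- 2^.rtrunc_log2(ng, config$baseline_log2_mean,
                             config$baseline_log2_sd,
                             config$baseline_log2_min)
  names(base_cpm) <- ids
  pair_ids <- c(truth$pairs$lnc_id, truth$pairs$coding_id)
  base_cpm[pair_ids] <- config$pair_baseline_cpm
  if (nrow(truth$de) > 0)
    base_cpm[truth$de$gene_id] <- truth$de$baseline_cpm

  # cap expected CPM total so column sums stay below the library size
  tot <- sum(base_cpm)
  if (tot > 8e5) base_cpm <- base_cpm * (8e5 / tot)

  mu <- matrix(base_cpm * config$depth / 1e6, nrow = ng, ncol = n,
               dimnames = list(ids, samples))

  s2 <- config$pair_log_sd^2
  for (k in seq_len(nrow(truth$pairs))) {
    z <- stats::rnorm(n)
    for (side in c("lnc", "coding")) {
      gid <- truth$pairs[[paste0(side, "_id")]][k]
      a <- truth$pairs[[paste0("loading_", side)]][k]
      u <- a * z + sqrt(max(0, 1 - a^2)) * stats::rnorm(n)
      mu[gid, ] <- mu[gid, ] * exp(config$pair_log_sd * u - s2 / 2)
    }
  }
  if (nrow(truth$de) > 0) {
    for (k in seq_len(nrow(truth$de))) {
      mu[truth$de$gene_id[k], seq_len(nE)] <-
        mu[truth$de$gene_id[k], seq_len(nE)] * truth$de$fold[k]
    }
  }

  counts <- if (config$dispersion > 0) {
    matrix(stats::rnbinom(ng * n, mu = mu, size = 1 / config$dispersion),
           nrow = ng, dimnames = dimnames(mu))
  } else {
    matrix(stats::rpois(ng * n, lambda = mu), nrow = ng,
           dimnames = dimnames(mu))
  }
  count_matrix(counts, groups,
               stats::setNames(rep(config$depth, n), samples))
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits the exact dialects the pipeline readers consume: GENCODE-style GTF,
#' counts TSV, sample-metadata TSV, BED3 enhancers, truth TSVs and the
#' config as JSON. Byte-reproducible given the seed.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the generated objects (\code{annot},
#'   \code{counts}, \code{truth}, \code{enhancers}) and the file
#'   \code{paths}.
#' @export
write_fixture_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_annotation(config)
  cm <- generate_counts(config, gen$annot, gen$truth)

  paths <- list(
    gtf = file.path(dir, "annotation.gtf"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    bed = file.path(dir, "enhancers.bed"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_de = file.path(dir, "truth_de.tsv"),
    truth_enhancers = file.path(dir, "truth_enhancers.tsv"),
    config = file.path(dir, "config.json"))

  write_gtf(gen$annot, paths$gtf)
  ctab <- data.frame(gene_id = rownames(cm$counts),
                     cm$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
  .write_tsv(ctab, paths$counts)
  .write_tsv(data.frame(sample_id = names(cm$groups),
                        group = unname(cm$groups),
                        library_size = unname(cm$lib_sizes),
                        stringsAsFactors = FALSE), paths$samples)
  writeLines(sprintf("%s\t%d\t%d", gen$enhancers$chrom,
                     gen$enhancers$start, gen$enhancers$end), paths$bed)
  .write_tsv(gen$truth$pairs, paths$truth_pairs)
  .write_tsv(gen$truth$de, paths$truth_de)
  .write_tsv(data.frame(lnc_id = gen$truth$enhancer_lnc_ids,
                        stringsAsFactors = FALSE), paths$truth_enhancers)
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(annot = gen$annot, counts = cm, truth = gen$truth,
                 enhancers = gen$enhancers, paths = paths))
}
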