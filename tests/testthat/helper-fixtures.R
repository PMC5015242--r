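# fixtures and independent brute-force oracles shared across test files

# a GTF with two genes / three exons, hand-convertible: coordinates below
# are 1-based inclusive as in the file format
write_two_gene_gtf <- function(path) {
  writeLines(c(
    "##two-gene fixture",
    paste0("chr1\ttest\tgene\t101\t300\t.\t+\t.\t",
           'gene_id "gA"; gene_name "alpha"; gene_type "protein_coding";'),
    paste0("chr1\ttest\texon\t101\t150\t.\t+\t.\t",
           'gene_id "gA"; gene_name "alpha"; gene_type "protein_coding";'),
    paste0("chr1\ttest\texon\t201\t300\t.\t+\t.\t",
           'gene_id "gA"; gene_name "alpha"; gene_type "protein_coding";'),
    paste0("chr1\ttest\tgene\t501\t700\t.\t-\t.\t",
           'gene_id "gB"; gene_name "beta"; gene_type "lincRNA";'),
    paste0("chr1\ttest\texon\t501\t700\t.\t-\t.\t",
           'gene_id "gB"; gene_name "beta"; gene_type "lincRNA";')
  ), path)
  path
}

# an antisense 3-exon lncRNA (mature length 662) overlapping two coding
# genes on the opposite strand
antisense_662_annotation <- function() {
  genes <- data.frame(
    gene_id = c("codA", "codB", "lncX"),
    gene_name = c("codA", "codB", "lncX"),
    biotype = c("protein_coding", "protein_coding", "antisense"),
    chrom = "chr1",
    start = c(0L, 14000L, 8000L),
    end = c(12000L, 26000L, 16000L),
    strand = c("-", "-", "+"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("codA", "codA", "codB", "codB", "lncX", "lncX", "lncX"),
    start = c(0L, 10000L, 14000L, 24000L, 8000L, 11000L, 15800L),
    end = c(2000L, 12000L, 16000L, 26000L, 8200L, 11262L, 16000L),
    stringsAsFactors = FALSE)
  annotation_set(genes, exons)
}

# simple gene-table constructor for geometry tests (single-exon genes)
make_annot <- function(...) {
  rows <- list(...)
  genes <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r$id, gene_name = r$id, biotype = r$bt,
               chrom = r$chrom %||% "chr1", start = r$s, end = r$e,
               strand = r$strand, stringsAsFactors = FALSE)
  }))
  exons <- if (length(rows) > 0)
    data.frame(gene_id = genes$gene_id, start = genes$start,
               end = genes$end, stringsAsFactors = FALSE)
  else data.frame(gene_id = character(), start = integer(),
                  end = integer())
  annotation_set(genes, exons)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force linear-scan oracles for the interval index
scan_overlaps <- function(genes, chrom, start, end) {
  hit <- genes$chrom == chrom & genes$start < end & start < genes$end
  genes$gene_id[hit]
}
scan_nearest_coding <- function(genes, lnc_id) {
  i <- which(genes$gene_id == lnc_id)
  cand <- which(genes$biotype == "protein_coding" &
                  genes$chrom == genes$chrom[i] &
                  genes$gene_id != lnc_id)
  if (length(cand) == 0) return(character())
  ov <- cand[genes$start[cand] < genes$end[i] &
               genes$start[i] < genes$end[cand]]
  if (length(ov) > 0) return(sort(genes$gene_id[ov]))
  gap <- pmax(0, pmax(genes$start[i], genes$start[cand]) -
                pmin(genes$end[i], genes$end[cand]))
  sort(genes$gene_id[cand[gap == min(gap)]])
}

# random non-degenerate annotation for the index-equivalence property
random_annotation <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
  start <- sample.int(1e6, n)
  len <- sample.int(5e4, n)
  data.frame(gene_id = sprintf("r%04d", seq_len(n)),
             gene_name = sprintf("r%04d", seq_len(n)),
             biotype = sample(c("protein_coding", "lincRNA",
                                "pseudogene"), n, replace = TRUE),
             chrom = chrom, start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# hand-made count matrix: genes x samples with library sizes
toy_count_matrix <- function(counts, groups = NULL, lib = 1e6) {
  samples <- colnames(counts)
  if (is.null(groups))
    groups <- stats::setNames(rep("g", length(samples)), samples)
  count_matrix(counts, groups,
               stats::setNames(rep(lib, length(samples)), samples))
}

# exact-test enumeration oracle, written from the definition with raw
# log-binomial arithmetic (independent of dbinom-based vector comparison
# in the implementation's hot path)
oracle_exact_p <- function(ka, kb, la, lb) {
  k <- ka + kb
  if (k == 0) return(1)
  p0 <- sum(la) / (sum(la) + sum(lb))
  logpr <- vapply(0:k, function(i)
    lchoose(k, i) + i * log(p0) + (k - i) * log(1 - p0), numeric(1))
  obs <- logpr[ka + 1]
  min(1, sum(exp(logpr[logpr <= obs + 1e-9])))
}

# desk-scale synthetic configuration used by several test files
small_census <- function() {
  c(protein_coding = 60L, lincRNA = 25L, antisense = 20L,
    sense_intronic = 6L, sense_overlapping = 1L,
    three_prime_overlapping = 1L, miRNA = 5L, snoRNA = 3L, snRNA = 2L,
    rRNA = 1L, miscRNA = 2L, processed_transcript = 4L,
    pseudogene = 6L)
}
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, census = small_census(), ...)
}
no_planting <- function() {
  list(planted_pairs = data.frame(subclass = character(),
                                  geometry = character(),
                                  target_r = numeric(),
                                  count = integer(),
                                  stringsAsFactors = FALSE),
       planted_de = data.frame(fold = numeric(), biotype = character(),
                               mean_cpm = numeric(),
                               stringsAsFactors = FALSE))
}
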