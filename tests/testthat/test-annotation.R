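test_that("GTF parsing converts 1-based inclusive coordinates to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  write_two_gene_gtf(path)
  annot <- read_gtf(path)

  expect_s3_class(annot, "annotation_set")
  expect_equal(sort(annot$genes$gene_id), c("gA", "gB"))

  gA <- gene_model(annot, "gA")
  expect_equal(gA$chrom, "chr1")
  expect_equal(gA$start, 100L)          # GTF 101 -> internal 100
  expect_equal(gA$end, 300L)            # GTF 300 inclusive -> internal 300
  expect_equal(gA$strand, "+")
  expect_equal(gA$tss, 100L)
  expect_equal(gA$biotype, "protein_coding")
  expect_equal(gA$gene_name, "alpha")
  expect_equal(gA$exons$start, c(100L, 200L))
  expect_equal(gA$exons$end, c(150L, 300L))
  expect_equal(mature_length(gA), 150L)  # 50 + 100 nt

  gB <- gene_model(annot, "gB")
  expect_equal(gB$strand, "-")
  expect_equal(gB$start, 500L)
  expect_equal(gB$end, 700L)
  expect_equal(gB$tss, 699L)            # last base of the span on minus
  expect_equal(gB$biotype, "lincRNA")
})

test_that("malformed GTF lines are rejected with the offending line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "#comment",
    paste0("chr1\tx\tgene\t1\t10\t.\t+\t.\t", 'gene_id "g"; gene_type "lincRNA";'),
    "chr1\tonly\tthree"), path)
  expect_error(read_gtf(path), "line 3.*9 tab-separated fields")

  # unknown biotype without a fallback is an error; with one it maps
  path2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tx\tgene\t1\t10\t.\t+\t.\t",
                    'gene_id "g"; gene_type "TEC";'), path2)
  expect_error(read_gtf(path2), "unknown biotype")
  annot <- read_gtf(path2, biotype_taxonomy(fallback = "miscRNA"))
  expect_equal(annot$genes$biotype, "miscRNA")
})

test_that("a 662-nt three-exon antisense lncRNA is modelled and classified correctly", {
  annot <- antisense_662_annotation()
  lnc <- gene_model(annot, "lncX")
  expect_equal(nrow(lnc$exons), 3L)
  expect_equal(mature_length(lnc), 662L)  # 200 + 262 + 200 nt
  expect_equal(classify_lnc_position(annot, "lncX", use_tag = FALSE),
               "antisense")
  # overlaps both minus-strand coding genes -> both are partners
  expect_setequal(nearest_coding_partners(annot, "lncX"),
                  c("codA", "codB"))
})

test_that("promoter windows are strand-aware, half-open and clipped at zero", {
  annot <- make_annot(
    list(id = "p", bt = "protein_coding", s = 20000L, e = 40000L,
         strand = "+"),
    list(id = "m", bt = "protein_coding", s = 500L, e = 700L,
         strand = "-"),
    list(id = "near0", bt = "protein_coding", s = 3000L, e = 9000L,
         strand = "+", chrom = "chr2"))

  pw <- promoter_window(gene_model(annot, "p"))
  expect_equal(c(pw$start, pw$end), c(10000, 20000))  # [tss-1e4, tss)

  pw <- promoter_window(gene_model(annot, "m"))
  expect_equal(c(pw$start, pw$end), c(700, 10700))    # [tss+1, tss+1+1e4)

  pw <- promoter_window(gene_model(annot, "near0"))
  expect_equal(c(pw$start, pw$end), c(0, 3000))       # clipped at 0

  pw <- promoter_window(gene_model(annot, "p"), width = 500)
  expect_equal(c(pw$start, pw$end), c(19500, 20000))
  expect_error(promoter_window(gene_model(annot, "p"), width = 0))
})

test_that("positional classification covers all five leaves with the documented precedence", {
  annot <- make_annot(
    list(id = "cod1", bt = "protein_coding", s = 0L, e = 20000L,
         strand = "+"),
    # opposite strand overlap -> antisense
    list(id = "anti", bt = "lincRNA", s = 5000L, e = 8000L, strand = "-"),
    # same strand, inside cod2's intron -> sense_intronic
    list(id = "cod2", bt = "protein_coding", s = 100000L, e = 140000L,
         strand = "+"),
    list(id = "si", bt = "lincRNA", s = 110000L, e = 115000L,
         strand = "+"),
    # coding gene inside the lncRNA's intron -> sense_overlapping
    list(id = "so", bt = "lincRNA", s = 200000L, e = 260000L,
         strand = "+"),
    list(id = "cod3", bt = "protein_coding", s = 220000L, e = 240000L,
         strand = "+"),
    # no coding overlap on either strand -> lincRNA
    list(id = "linc", bt = "antisense", s = 400000L, e = 405000L,
         strand = "+"),
    # overlap restricted to cod4's last exon -> three_prime_overlapping
    list(id = "cod4", bt = "protein_coding", s = 500000L, e = 540000L,
         strand = "+"),
    list(id = "tpo", bt = "lincRNA", s = 535000L, e = 545000L,
         strand = "+"))
  # replace the single full-span exons where intron structure matters
  g <- annot$genes[, setdiff(names(annot$genes), "tss")]
  ex <- data.frame(
    gene_id = c("cod1", "anti", "cod2", "cod2", "si",
                "so", "so", "cod3", "linc",
                "cod4", "cod4", "tpo"),
    start = c(0L, 5000L, 100000L, 130000L, 110000L,
              200000L, 250000L, 220000L, 400000L,
              500000L, 530000L, 535000L),
    end = c(20000L, 8000L, 105000L, 140000L, 115000L,
            210000L, 260000L, 240000L, 405000L,
            505000L, 540000L, 545000L),
    stringsAsFactors = FALSE)
  annot <- annotation_set(g, ex)

  cls <- function(id) classify_lnc_position(annot, id, use_tag = FALSE)
  expect_equal(cls("anti"), "antisense")
  expect_equal(cls("si"), "sense_intronic")
  expect_equal(cls("so"), "sense_overlapping")
  expect_equal(cls("linc"), "lincRNA")
  expect_equal(cls("tpo"), "three_prime_overlapping")

  # a trusted tag short-circuits geometry; use_tag = FALSE re-derives it
  expect_equal(classify_lnc_position(annot, "linc"), "antisense")
  expect_equal(classify_lnc_position(annot, "linc", use_tag = FALSE),
               "lincRNA")
})

test_that("nearest coding partners: overlap beats distance and exact ties return all", {
  annot <- make_annot(
    list(id = "far", bt = "protein_coding", s = 100000L, e = 101000L,
         strand = "+"),
    list(id = "left", bt = "protein_coding", s = 0L, e = 500L,
         strand = "+"),
    list(id = "right", bt = "protein_coding", s = 2500L, e = 3000L,
         strand = "-"),
    list(id = "lnc", bt = "lincRNA", s = 1000L, e = 2000L, strand = "+"),
    list(id = "lonely", bt = "lincRNA", s = 0L, e = 100L, strand = "+",
         chrom = "chrX"))
  # gaps: left = 1000 - 500 = 500, right = 2500 - 2000 = 500 -> tie
  expect_setequal(nearest_coding_partners(annot, "lnc"),
                  c("left", "right"))
  # a chromosome without coding genes yields no partner
  expect_equal(nearest_coding_partners(annot, "lonely"), character())
  expect_error(nearest_coding_partners(annot, "nope"), "unknown gene_id")
})

test_that("the interval index agrees with a linear scan on randomized annotations", {
  for (seed in c(101L, 202L)) {
    tab <- random_annotation(300, seed)
    annot <- annotation_set(tab,
                            data.frame(gene_id = tab$gene_id,
                                       start = tab$start, end = tab$end,
                                       stringsAsFactors = FALSE))
    set.seed(seed + 1)
    for (q in seq_len(100)) {
      chrom <- sample(c("chr1", "chr2", "chr3"), 1)
      s <- sample.int(1.05e6, 1)
      e <- s + sample.int(8e4, 1)
      expect_setequal(overlapping_genes(annot, chrom, s, e),
                      scan_overlaps(tab, chrom, s, e))
    }
    non_coding <- tab$gene_id[tab$biotype != "protein_coding"]
    for (id in utils::head(non_coding, 50)) {
      expect_equal(sort(nearest_coding_partners(annot, id)),
                   scan_nearest_coding(tab, id))
    }
  }
})

test_that("write_gtf / read_gtf round-trips an annotation set", {
  tab <- random_annotation(80, 7)
  annot <- annotation_set(tab,
                          data.frame(gene_id = tab$gene_id,
                                     start = tab$start, end = tab$end,
                                     stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(annot, path)
  back <- read_gtf(path)

  ord <- function(df) df[order(df$gene_id), ]
  expect_equal(ord(back$genes), ord(annot$genes),
               ignore_attr = "row.names")
  o1 <- back$exons[order(back$exons$gene_id, back$exons$start), ]
  o2 <- annot$exons[order(annot$exons$gene_id, annot$exons$start), ]
  expect_equal(o1, o2, ignore_attr = "row.names")
})

test_that("annotation_set rejects inconsistent gene models", {
  g <- function(...) {
    d <- data.frame(gene_id = "g1", gene_name = "g1", biotype = "lincRNA",
                    chrom = "chr1", start = 0L, end = 100L, strand = "+",
                    stringsAsFactors = FALSE)
    mod <- list(...)
    for (nm in names(mod)) d[[nm]] <- mod[[nm]]
    d
  }
  ex0 <- data.frame(gene_id = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE)
  expect_error(annotation_set(g(strand = "*"), ex0), "strand")
  expect_error(annotation_set(g(start = 100L, end = 100L), ex0),
               "start < end")
  expect_error(annotation_set(rbind(g(), g()), ex0), "duplicate")
  expect_error(
    annotation_set(g(), data.frame(gene_id = "g1", start = 50L,
                                   end = 150L)),
    "exon outside")
  expect_error(
    annotation_set(g(), data.frame(gene_id = "g1", start = c(0L, 40L),
                                   end = c(50L, 90L))),
    "overlapping exons")
  expect_error(
    annotation_set(g(), data.frame(gene_id = "huh", start = 0L,
                                   end = 10L)),
    "unknown gene_id")
})
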