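test_that("critical_r matches the t-distribution derivation", {
  expect_equal(round_half_away(critical_r(11), 3), 0.602)
  expect_equal(round_half_away(critical_r(12), 3), 0.576)

  # identity check against the defining formula
  t <- qt(1 - 0.05 / 2, df = 9)
  expect_equal(critical_r(11), t / sqrt(t^2 + 9))

  # inverse identity: a sample correlation exactly at the critical value
  # has a two-sided t-test p-value exactly alpha
  rc <- critical_r(11, 0.05)
  tstat <- rc * sqrt(9 / (1 - rc^2))
  expect_equal(2 * pt(tstat, df = 9, lower.tail = FALSE), 0.05)

  # monotone: more samples -> smaller threshold; stricter alpha -> larger
  ns <- 3:50
  expect_true(all(diff(vapply(ns, critical_r, 1)) < 0))
  expect_gt(critical_r(11, 0.01), critical_r(11, 0.05))

  expect_error(critical_r(2), "n >= 3")
  expect_error(critical_r(11, 0), "alpha")
  expect_error(critical_r(11, 1), "alpha")
})

test_that("pearson_r matches a hand-computed case and its invariances", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  # centered cross-product 3, each sum of squares 5 -> r = 3/5
  expect_equal(pearson_r(x, y), 0.6)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)

  # invariant under per-gene positive affine transforms, sign-flipped by
  # negative scaling
  expect_equal(pearson_r(3 * x + 7, 0.5 * y - 2), 0.6)
  expect_equal(pearson_r(-2 * x + 1, y), -0.6)

  # zero variance is the undefined-correlation signal
  expect_true(is.na(pearson_r(rep(5, 4), y)))
  expect_error(pearson_r(x, y[1:3]), "unequal")
  expect_error(pearson_r(x[1:2], y[1:2]), ">= 3")
})

test_that("build_pairs enumerates expressed lncRNA / nearest-coding pairs", {
  annot <- make_annot(
    list(id = "as1", bt = "antisense", s = 1000L, e = 3000L,
         strand = "-"),
    list(id = "codA", bt = "protein_coding", s = 0L, e = 2000L,
         strand = "+"),
    # lincRNA equidistant from two coding genes -> two adjacent pairs
    list(id = "li1", bt = "lincRNA", s = 10000L, e = 11000L,
         strand = "+", chrom = "chr2"),
    list(id = "codL", bt = "protein_coding", s = 8000L, e = 9500L,
         strand = "+", chrom = "chr2"),
    list(id = "codR", bt = "protein_coding", s = 11500L, e = 13000L,
         strand = "-", chrom = "chr2"),
    # partner unexpressed -> no pair; subclass outside the screen -> none
    list(id = "li2", bt = "lincRNA", s = 50000L, e = 51000L,
         strand = "+", chrom = "chr3"),
    list(id = "codX", bt = "protein_coding", s = 53000L, e = 54000L,
         strand = "+", chrom = "chr3"),
    list(id = "sov", bt = "sense_overlapping", s = 100L, e = 1900L,
         strand = "+", chrom = "chr4"),
    list(id = "codS", bt = "protein_coding", s = 0L, e = 2000L,
         strand = "+", chrom = "chr4"))
  expressed <- setdiff(annot$genes$gene_id, "codX")

  pairs <- build_pairs(annot, expressed)
  key <- paste(pairs$lnc_id, pairs$coding_id)
  expect_setequal(key, c("as1 codA", "li1 codL", "li1 codR"))
  expect_equal(pairs$relation[pairs$lnc_id == "as1"], "overlapping")
  expect_setequal(pairs$relation[pairs$lnc_id == "li1"],
                  c("adjacent", "adjacent"))
  expect_equal(pairs$lnc_subclass[pairs$lnc_id == "as1"], "antisense")
  expect_error(build_pairs(annot, c(expressed, "ghost")), "absent")
})

test_that("the screen decision is |r| strictly above the analytic threshold", {
  set.seed(42)
  n <- 11
  m <- rbind(l1 = seq_len(n), c1 = seq_len(n) + rnorm(n, sd = 0.01),
             l2 = rnorm(n), c2 = rnorm(n),
             l3 = rev(seq_len(n)), c3 = seq_len(n),
             l4 = rep(3, n), c4 = rnorm(n)) * 10 + 100
  colnames(m) <- sprintf("s%d", seq_len(n))
  cm <- toy_count_matrix(round(m))
  expr <- cpm_normalize(cm)
  pairs <- data.frame(lnc_id = c("l1", "l2", "l3", "l4"),
                      coding_id = c("c1", "c2", "c3", "c4"),
                      relation = "adjacent", lnc_subclass = "lincRNA",
                      stringsAsFactors = FALSE)
  res <- screen_pairs(expr, pairs)

  rc <- critical_r(n)
  expect_equal(res$significant, !is.na(res$r) & abs(res$r) > rc)
  expect_true(res$significant[1]); expect_equal(res$sign[1], "positive")
  expect_true(res$significant[3]); expect_equal(res$sign[3], "negative")
  expect_false(res$significant[2])
  expect_true(res$skipped[4])      # constant profile -> NA r, skipped
  expect_false(res$significant[4])
  expect_equal(res$n, rep(n, 4))

  # log2 scale changes r but not the pathological cases
  res2 <- screen_pairs(expr, pairs, scale = "log2")
  expect_true(res2$significant[1])
  expect_true(res2$skipped[4])

  expect_error(screen_pairs(expr, transform(pairs, lnc_id = "nope")),
               "absent from expression matrix")
})

test_that("geometry annotation flags span overlap, promoter overlap and low ratio", {
  annot <- make_annot(
    list(id = "cod", bt = "protein_coding", s = 20000L, e = 40000L,
         strand = "+"),
    list(id = "lnc_prom", bt = "lincRNA", s = 12000L, e = 15000L,
         strand = "+"),       # inside [10000, 20000) promoter window
    list(id = "lnc_body", bt = "antisense", s = 25000L, e = 30000L,
         strand = "-"),       # overlaps the gene span itself
    list(id = "lnc_far", bt = "lincRNA", s = 90000L, e = 91000L,
         strand = "+"))
  counts <- matrix(rep(c(6, 30, 15, 2), 3), ncol = 3,
                   dimnames = list(c("lnc_prom", "cod", "lnc_body",
                                     "lnc_far"),
                                   c("s1", "s2", "s3")))
  expr <- cpm_normalize(toy_count_matrix(counts))

  res <- data.frame(lnc_id = c("lnc_prom", "lnc_body", "lnc_far"),
                    coding_id = "cod", lnc_subclass = "lincRNA",
                    significant = TRUE, skipped = FALSE,
                    sign = "positive", stringsAsFactors = FALSE)
  ann <- annotate_geometry(res, annot, expr)

  expect_equal(ann$gene_overlap, c(FALSE, TRUE, FALSE))
  expect_equal(ann$promoter_overlap, c(TRUE, FALSE, FALSE))
  # CPM means: 6/30 = 0.2 (below 30 %), 15/30 = 0.5, 2/30 ~ 0.067
  expect_equal(ann$expression_ratio, c(0.2, 0.5, 2 / 30))
  expect_equal(ann$ratio_below_30pct, c(TRUE, FALSE, TRUE))
  expect_false("enhancer_transcribed" %in% names(ann))

  enh <- data.frame(chrom = "chr1", start = 11000L, end = 13000L,
                    stringsAsFactors = FALSE)
  ann2 <- annotate_geometry(res, annot, expr, enhancers = enh)
  expect_equal(ann2$enhancer_transcribed, c(TRUE, FALSE, FALSE))
})

test_that("enhancer TSS containment respects half-open boundaries", {
  annot <- make_annot(
    list(id = "tss_last", bt = "lincRNA", s = 1999L, e = 2100L,
         strand = "+"),   # tss 1999: last position inside [1000, 2000)
    list(id = "tss_at_end", bt = "lincRNA", s = 2000L, e = 2100L,
         strand = "+"),   # tss 2000: just outside
    list(id = "tss_at_start", bt = "lincRNA", s = 1000L, e = 3000L,
         strand = "+"),   # tss 1000: first position inside
    list(id = "minus_in", bt = "lincRNA", s = 100L, e = 2000L,
         strand = "-"))   # minus-strand tss = 1999: inside
  enh <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                    stringsAsFactors = FALSE)
  ids <- annot$genes$gene_id
  expect_equal(enhancer_transcribed(annot, ids, enh),
               c(TRUE, FALSE, TRUE, TRUE))
  # any-overlap mode picks up body overlap even when the TSS is outside
  expect_equal(enhancer_transcribed(annot, "tss_at_end", enh,
                                    mode = "any"), FALSE)
  expect_equal(enhancer_transcribed(annot, "tss_at_start", enh,
                                    mode = "any"), TRUE)
  expect_equal(enhancer_transcribed(annot, ids, enh[0, ]),
               rep(FALSE, 4))
})

test_that("screen summary reproduces the reporting percentages", {
  subclass <- rep(c("antisense", "lincRNA", "sense_intronic"),
                  c(41, 34, 7))
  sign <- rep(c("positive", "negative"), c(59, 23))
  res <- data.frame(
    lnc_id = sprintf("L%02d", 1:82), coding_id = sprintf("C%02d", 1:82),
    lnc_subclass = subclass, r = ifelse(sign == "positive", 0.8, -0.8),
    n = 11, skipped = FALSE, significant = TRUE, sign = sign,
    gene_overlap = rep(c(TRUE, FALSE), c(65, 17)),
    promoter_overlap = rep(c(TRUE, FALSE), c(29, 53)),
    ratio_below_30pct = rep(c(TRUE, FALSE), c(40, 42)),
    stringsAsFactors = FALSE)
  summ <- summarize_screen(res)

  expect_equal(summ$pairs_examined, 82)
  expect_equal(summ$significant_total, 82)
  expect_equal(unname(summ$significant_by_subclass),
               c(41, 34, 7))
  expect_equal(summ$n_positive, 59)
  expect_equal(summ$n_negative, 23)
  expect_equal(summ$pct_positive$pct, 72)     # 59/82 = 71.95 -> 72
  expect_equal(summ$pct_negative$pct, 28)     # 23/82 = 28.05 -> 28
  expect_equal(summ$pct_promoter_overlap$pct, 35)  # 29/82 -> 35
  expect_equal(summ$pct_gene_overlap$pct, 79)      # 65/82 -> 79
  expect_equal(summ$pct_positive$pct1, 72.0)
  expect_equal(summ$n_positive + summ$n_negative, summ$significant_total)

  # no significant pairs -> zero percentages, no division by zero
  res0 <- res; res0$significant <- FALSE; res0$sign <- NA_character_
  summ0 <- summarize_screen(res0)
  expect_equal(summ0$significant_total, 0)
  expect_equal(summ0$pct_positive$pct, 0)
})
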