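#' Construct a validated gene-by-sample count matrix
#'
#' The statistical substrate of the pipeline: integer counts with per-sample
#' group labels and library sizes. The library size is the number of
#' read-pairs mapped to the reference genome and must be at least the
#' sample's exonic column sum.
#'
#' @param counts Integer matrix (genes x samples) with dimnames.
#' @param groups Named character vector, sample -> group label.
#' @param lib_sizes Named numeric vector, sample -> library size (positive).
#' @return An object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, groups, lib_sizes) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts needs sample column names")
  samples <- colnames(counts)
  if (!all(samples %in% names(groups)))
    stop("unknown sample(s) in counts: ",
         paste(setdiff(samples, names(groups)), collapse = ", "))
  if (!all(samples %in% names(lib_sizes)))
    stop("missing library size for sample(s): ",
         paste(setdiff(samples, names(lib_sizes)), collapse = ", "))
  groups <- groups[samples]
  lib_sizes <- lib_sizes[samples]
  if (length(counts) > 0) {
    if (any(counts < 0)) stop("negative count")
    if (any(counts != round(counts))) stop("non-integer count")
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  cs <- colSums(counts)
  if (nrow(counts) > 0 && any(cs > lib_sizes)) {
    bad <- samples[cs > lib_sizes]
    stop("column sum exceeds declared library size for sample(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(counts = counts, groups = groups, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  invisible(x)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' @param counts_path TSV with a gene-id first column and one column per
#'   sample.
#' @param samples_path TSV with columns \code{sample_id}, \code{group},
#'   \code{library_size}.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- .read_tsv(counts_path)
  meta <- .read_tsv(samples_path)
  need <- c("sample_id", "group", "library_size")
  if (!all(need %in% names(meta)))
    stop("sample metadata needs columns: ", paste(need, collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  count_matrix(m,
               groups = stats::setNames(meta$group, meta$sample_id),
               lib_sizes = stats::setNames(meta$library_size,
                                           meta$sample_id))
}

#' Counts-per-million normalization
#'
#' Each cell becomes \code{count / library_size * 1e6}. By default the
#' denominator is the externally supplied library size (read-pairs mapped to
#' the genome); \code{denominator = "column_sum"} switches to the exonic
#' column total for generic reuse.
#'
#' @param m A \code{\link{count_matrix}}.
#' @param denominator \code{"library"} (default) or \code{"column_sum"}.
#' @return An object of class \code{expression_matrix}: list with the CPM
#'   matrix (\code{cpm}), \code{groups} and \code{lib_sizes}.
#' @export
cpm_normalize <- function(m, denominator = c("library", "column_sum")) {
  denominator <- match.arg(denominator)
  denom <- switch(denominator,
                  library = m$lib_sizes,
                  column_sum = colSums(m$counts))
  if (any(denom == 0)) stop("zero library size")
  cpm <- sweep(m$counts, 2, denom, "/") * 1e6
  structure(list(cpm = cpm, groups = m$groups, lib_sizes = m$lib_sizes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (CPM)\n",
              nrow(x$cpm), ncol(x$cpm)))
  invisible(x)
}

#' Mean-expression filter
#'
#' Keeps genes whose unweighted mean CPM across all samples is strictly
#' greater than the threshold (a gene at exactly the threshold is excluded).
#'
#' @param e An \code{expression_matrix}.
#' @param threshold Mean-CPM cutoff (default 1).
#' @return Character vector of retained gene_ids.
#' @export
filter_expressed <- function(e, threshold = 1.0) {
  if (nrow(e$cpm) == 0) stop("empty expression matrix")
  rownames(e$cpm)[rowMeans(e$cpm) > threshold]
}

#' Composition report from a leaf census
#'
#' Computes nested counts and percentages (one decimal, half away from zero)
#' of the transcriptome composition: top classes out of the grand total,
#' ncRNA subclasses out of the ncRNA total, lncRNA and short-ncRNA leaves
#' out of their subclass totals, and (optionally) the breakdown of genes
#' overlapped by antisense lncRNAs out of the total overlapped genes.
#'
#' @param leaf_counts Named integer vector of gene counts per taxonomy leaf.
#' @param antisense_targets Optional named integer vector with elements
#'   \code{protein_coding}, \code{ncRNA}, \code{pseudogene}: counts of
#'   distinct genes overlapped by antisense lncRNAs.
#' @return A list of class \code{composition_report} of data.frames
#'   (\code{classes}, \code{ncRNA}, \code{lncRNA}, \code{short_ncRNA},
#'   \code{antisense_targets}), each with \code{count} and \code{pct}.
#' @export
composition_from_census <- function(leaf_counts, antisense_targets = NULL) {
  get <- function(leaf) {
    v <- leaf_counts[leaf]
    v[is.na(v)] <- 0
    unname(v)
  }
  lnc_leaves <- lncrna_leaves()
  short_leaves <- c("miRNA", "snoRNA", "snRNA", "rRNA", "miscRNA")
  lnc_total <- sum(get(lnc_leaves))
  short_total <- sum(get(short_leaves))
  pt <- get("processed_transcript")
  nc_total <- lnc_total + short_total + pt
  pc <- get("protein_coding")
  pg <- get("pseudogene")
  total <- pc + nc_total + pg

  tab <- function(labels, counts, denom) {
    data.frame(label = labels, count = counts,
               pct = if (denom > 0) pct_of(counts, denom) else rep(0, length(counts)),
               stringsAsFactors = FALSE)
  }
  out <- list(
    total = total,
    classes = tab(c("protein_coding", "ncRNA", "pseudogene"),
                  c(pc, nc_total, pg), total),
    ncRNA = tab(c("lncRNA", "short_ncRNA", "processed_transcript"),
                c(lnc_total, short_total, pt), nc_total),
    lncRNA = tab(lnc_leaves, get(lnc_leaves), lnc_total),
    short_ncRNA = tab(short_leaves, get(short_leaves), short_total)
  )
  if (!is.null(antisense_targets)) {
    at <- antisense_targets[c("protein_coding", "ncRNA", "pseudogene")]
    at[is.na(at)] <- 0
    out$antisense_targets <- tab(names(at), unname(at), sum(at))
  }
  structure(out, class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("composition_report: %d genes\n", x$total))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Transcriptome composition of an expressed gene set
#'
#' Tallies the expressed genes per taxonomy leaf and, for expressed antisense
#' lncRNAs, counts the distinct expressed genes their spans overlap on the
#' opposite strand, broken down by top class.
#'
#' @param annot An \code{\link{annotation_set}} covering all expressed genes.
#' @param expressed Character vector of expressed gene_ids.
#' @return A \code{composition_report} (see
#'   \code{\link{composition_from_census}}).
#' @export
composition_report <- function(annot, expressed) {
  g <- annot$genes
  i <- match(expressed, g$gene_id)
  if (anyNA(i))
    stop("expressed gene(s) absent from annotation: ",
         paste(expressed[is.na(i)][1], "..."))
  leaf_counts <- table(g$biotype[i])
  leaf_counts <- stats::setNames(as.integer(leaf_counts), names(leaf_counts))

  as_idx <- i[g$biotype[i] == "antisense"]
  targets <- character()
  if (length(as_idx) > 0) {
    expr_idx <- i
    for (a in as_idx) {
      cand <- expr_idx[g$chrom[expr_idx] == g$chrom[a] &
                         g$strand[expr_idx] != g$strand[a] &
                         g$gene_id[expr_idx] != g$gene_id[a]]
      hit <- cand[.iv_overlap(g$start[a], g$end[a], g$start[cand],
                              g$end[cand])]
      targets <- c(targets, g$gene_id[hit])
    }
    targets <- unique(targets)
  }
  tcls <- .leaf_class(g$biotype[match(targets, g$gene_id)])
  at <- c(protein_coding = sum(tcls == "protein_coding"),
          ncRNA = sum(tcls == "ncRNA"),
          pseudogene = sum(tcls == "pseudogene"))
  composition_from_census(leaf_counts, at)
}

#' Read a per-sample alignment-statistics table
#'
#' @param path TSV with columns \code{sample_id}, \code{input_read_pairs},
#'   \code{uniquely_mapped} (and optionally \code{group}).
#' @return data.frame with an added \code{percent_mapped} column.
#' @export
read_alignment_stats <- function(path) {
  tab <- .read_tsv(path)
  need <- c("sample_id", "input_read_pairs", "uniquely_mapped")
  if (!all(need %in% names(tab)))
    stop("alignment stats need columns: ", paste(need, collapse = ", "))
  if (any(tab$uniquely_mapped > tab$input_read_pairs) ||
      any(tab$uniquely_mapped < 0))
    stop("uniquely_mapped must lie in [0, input_read_pairs]")
  tab$percent_mapped <- tab$uniquely_mapped / tab$input_read_pairs * 100
  tab
}

#' Per-group and overall alignment summary
#'
#' Arithmetic means of input read-pairs and uniquely mapped read-pairs
#' (rounded to the nearest integer, half away from zero) and of the
#' per-sample mapped percentages (one decimal). The percentage column is the
#' mean of per-sample percentages, not the ratio of summed counts.
#'
#' @param stats data.frame as returned by \code{\link{read_alignment_stats}}.
#' @param groups Named character vector, sample -> group.
#' @return data.frame with one row per group plus an \code{overall} row:
#'   columns \code{group}, \code{n}, \code{mean_input_read_pairs},
#'   \code{mean_uniquely_mapped}, \code{mean_percent_mapped}.
#' @export
alignment_summary <- function(stats, groups) {
  if (nrow(stats) < 1) stop("need at least one sample")
  if (!all(stats$sample_id %in% names(groups)))
    stop("missing group label for sample(s): ",
         paste(setdiff(stats$sample_id, names(groups)), collapse = ", "))
  if (!"percent_mapped" %in% names(stats))
    stats$percent_mapped <- stats$uniquely_mapped / stats$input_read_pairs * 100
  grp <- groups[stats$sample_id]
  one <- function(label, idx) {
    data.frame(
      group = label, n = length(idx),
      mean_input_read_pairs =
        round_half_away(mean(stats$input_read_pairs[idx])),
      mean_uniquely_mapped =
        round_half_away(mean(stats$uniquely_mapped[idx])),
      mean_percent_mapped =
        round_half_away(mean(stats$percent_mapped[idx]), 1),
      stringsAsFactors = FALSE)
  }
  rows <- lapply(unique(grp), function(gl) one(gl, which(grp == gl)))
  out <- do.call(rbind, c(rows, list(one("overall", seq_len(nrow(stats))))))
  rownames(out) <- NULL
  out
}
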