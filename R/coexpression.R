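#' Analytic critical value of the Pearson correlation
#'
#' The minimal |r| significant at a two-tailed level \code{alpha} for
#' \code{n} paired observations, derived from the t distribution with
#' \code{n - 2} degrees of freedom:
#' \deqn{r_{crit} = t / \sqrt{t^2 + (n - 2)}}
#' where \eqn{t} is the upper \eqn{\alpha/2} quantile. For the 11-sample
#' two-group design this gives 0.602 at \code{alpha = 0.05}.
#'
#' @param n Sample count (>= 3).
#' @param alpha Two-tailed significance level in (0, 1), default 0.05.
#' @return The critical Pearson value in (0, 1).
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) stop("need n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  t <- stats::qt(1 - alpha / 2, df = n - 2)
  t / sqrt(t^2 + (n - 2))
}

#' Pearson product-moment correlation of two expression profiles
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The coefficient, or \code{NA} when either profile has zero
#'   variance (the undefined-correlation signal; such pairs are skipped and
#'   tallied separately by the screen).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths")
  if (length(x) < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Build lncRNA / nearest-coding-gene pair candidates
#'
#' For every expressed lncRNA of the three screened positional classes
#' (antisense, lincRNA, sense-intronic), pairs it with each of its expressed
#' nearest or overlapping protein-coding genes
#' (\code{\link{nearest_coding_partners}}). A lncRNA whose partners are all
#' unexpressed yields no pair; one lncRNA may yield several pairs.
#'
#' @param annot An \code{\link{annotation_set}}.
#' @param expressed Character vector of expressed gene_ids (from
#'   \code{\link{filter_expressed}}).
#' @return data.frame with columns \code{lnc_id}, \code{coding_id},
#'   \code{relation} (\code{overlapping}/\code{adjacent}),
#'   \code{lnc_subclass}.
#' @export
build_pairs <- function(annot, expressed) {
  g <- annot$genes
  idx <- match(expressed, g$gene_id)
  if (anyNA(idx)) stop("expressed gene(s) absent from annotation")
  lnc <- expressed[g$biotype[idx] %in% screened_subclasses()]
  expr_set <- expressed
  rows <- vector("list", length(lnc))
  for (k in seq_along(lnc)) {
    lid <- lnc[k]
    partners <- nearest_coding_partners(annot, lid)
    partners <- partners[partners %in% expr_set]
    if (length(partners) == 0) next
    li <- match(lid, g$gene_id)
    pi <- match(partners, g$gene_id)
    rel <- ifelse(.iv_overlap(g$start[li], g$end[li], g$start[pi],
                              g$end[pi]),
                  "overlapping", "adjacent")
    rows[[k]] <- data.frame(lnc_id = lid, coding_id = partners,
                            relation = rel,
                            lnc_subclass = g$biotype[li],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lnc_id = character(), coding_id = character(),
                      relation = character(), lnc_subclass = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Screen candidate pairs for significant co-expression
#'
#' Computes the Pearson correlation of each pair's per-sample expression
#' values and flags pairs with \code{|r|} strictly greater than the analytic
#' critical value \code{\link{critical_r}(n, alpha)}. No multiple-testing
#' correction is applied across pairs: a fixed per-test critical value is
#' the screen's decision rule. By default the correlation is taken on raw
#' CPM values; \code{scale = "log2"} uses \code{log2(CPM + 1)}.
#'
#' @param expr An \code{expression_matrix}.
#' @param pairs data.frame from \code{\link{build_pairs}}.
#' @param alpha Two-tailed level (default 0.05).
#' @param scale \code{"cpm"} (default) or \code{"log2"}.
#' @return \code{pairs} with added columns \code{r}, \code{n},
#'   \code{significant}, \code{sign} (\code{positive}/\code{negative}, only
#'   for significant pairs), \code{skipped} (zero-variance pairs).
#' @export
screen_pairs <- function(expr, pairs, alpha = 0.05,
                         scale = c("cpm", "log2")) {
  scale <- match.arg(scale)
  m <- expr$cpm
  if (scale == "log2") m <- log2(m + 1)
  miss <- setdiff(unique(c(pairs$lnc_id, pairs$coding_id)), rownames(m))
  if (length(miss) > 0)
    stop("pair member(s) absent from expression matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  n <- ncol(m)
  rc <- critical_r(n, alpha)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    pearson_r(m[pairs$lnc_id[i], ], m[pairs$coding_id[i], ])
  }, numeric(1))
  pairs$r <- r
  pairs$n <- n
  pairs$skipped <- is.na(r)
  pairs$significant <- !is.na(r) & abs(r) > rc
  pairs$sign <- ifelse(pairs$significant,
                       ifelse(r > 0, "positive", "negative"),
                       NA_character_)
  pairs
}

#' Annotate pair geometry, expression ratio and enhancer status
#'
#' Adds to each screened pair: whether the gene spans intersect
#' (\code{gene_overlap}); whether the lncRNA span intersects the coding
#' gene's upstream promoter window (\code{promoter_overlap}, >= 1 bp of the
#' gene span, 10 kb by default); the ratio of mean lncRNA CPM to mean coding
#' CPM (\code{expression_ratio}) and its below-30-percent flag; and, when
#' enhancer intervals are supplied, whether the lncRNA is transcribed from
#' an enhancer (\code{enhancer_transcribed}).
#'
#' @param results data.frame from \code{\link{screen_pairs}}.
#' @param annot An \code{\link{annotation_set}}.
#' @param expr An \code{expression_matrix}.
#' @param promoter_width Upstream window width in bp (default 10000).
#' @param ratio_cutoff Expression-ratio cutoff (default 0.30).
#' @param enhancers Optional data.frame from \code{\link{read_bed}}.
#' @param enhancer_mode \code{"tss"} (default: TSS containment) or
#'   \code{"any"} (any span overlap).
#' @return \code{results} with the added annotation columns.
#' @export
annotate_geometry <- function(results, annot, expr, promoter_width = 10000,
                              ratio_cutoff = 0.30, enhancers = NULL,
                              enhancer_mode = c("tss", "any")) {
  enhancer_mode <- match.arg(enhancer_mode)
  g <- annot$genes
  li <- match(results$lnc_id, g$gene_id)
  ci <- match(results$coding_id, g$gene_id)
  if (anyNA(li) || anyNA(ci)) stop("pair member absent from annotation")

  results$gene_overlap <- .iv_overlap(g$start[li], g$end[li],
                                      g$start[ci], g$end[ci]) &
    g$chrom[li] == g$chrom[ci]

  promoter_overlap <- logical(nrow(results))
  for (k in seq_len(nrow(results))) {
    pw <- promoter_window(gene_model(annot, results$coding_id[k]),
                          width = promoter_width)
    promoter_overlap[k] <- g$chrom[li[k]] == pw$chrom &&
      .iv_overlap(g$start[li[k]], g$end[li[k]], pw$start, pw$end)
  }
  results$promoter_overlap <- promoter_overlap

  mu <- rowMeans(expr$cpm)
  results$expression_ratio <- unname(mu[results$lnc_id] /
                                       mu[results$coding_id])
  results$ratio_below_30pct <- results$expression_ratio < ratio_cutoff

  if (!is.null(enhancers)) {
    results$enhancer_transcribed <-
      enhancer_transcribed(annot, results$lnc_id, enhancers,
                           mode = enhancer_mode)
  }
  results
}

#' Is a lncRNA transcribed from an enhancer interval?
#'
#' Default mode flags a lncRNA whose transcription start site lies within an
#' enhancer interval (half-open containment: \code{start <= tss < end});
#' \code{mode = "any"} flags any overlap between the lncRNA span and an
#' enhancer.
#'
#' @param annot An \code{\link{annotation_set}}.
#' @param lnc_ids Character vector of lncRNA gene_ids.
#' @param enhancers data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open).
#' @param mode \code{"tss"} (default) or \code{"any"}.
#' @return Logical vector along \code{lnc_ids}.
#' @export
enhancer_transcribed <- function(annot, lnc_ids, enhancers,
                                 mode = c("tss", "any")) {
  mode <- match.arg(mode)
  g <- annot$genes
  i <- match(lnc_ids, g$gene_id)
  if (anyNA(i)) stop("unknown gene_id in lnc_ids")
  if (is.null(enhancers) || nrow(enhancers) == 0)
    return(rep(FALSE, length(lnc_ids)))
  vapply(i, function(j) {
    same <- enhancers$chrom == g$chrom[j]
    if (!any(same)) return(FALSE)
    e <- enhancers[same, , drop = FALSE]
    if (mode == "tss") {
      any(e$start <= g$tss[j] & g$tss[j] < e$end)
    } else {
      any(.iv_overlap(g$start[j], g$end[j], e$start, e$end))
    }
  }, logical(1))
}

#' Summarize a co-expression screen
#'
#' Counts and percentages in the reporting style of the screen: integer
#' percentages for prose fields (\code{pct}), one-decimal values retained in
#' \code{pct1}. Sign and geometry percentages are taken out of the
#' significant-pair total.
#'
#' @param results data.frame from \code{\link{screen_pairs}}, optionally
#'   after \code{\link{annotate_geometry}}.
#' @return A list of class \code{screen_summary}.
#' @export
summarize_screen <- function(results) {
  sub_tab <- function(df) {
    sapply(screened_subclasses(),
           function(s) sum(df$lnc_subclass == s))
  }
  sig <- results[which(results$significant), , drop = FALSE]
  n_sig <- nrow(sig)
  pc <- function(k) {
    if (n_sig == 0) return(list(pct = 0, pct1 = 0))
    list(pct = unname(pct_of(k, n_sig, 0)), pct1 = unname(pct_of(k, n_sig, 1)))
  }
  out <- list(
    pairs_examined = nrow(results),
    pairs_skipped = sum(results$skipped %||% FALSE),
    lnc_examined = length(unique(results$lnc_id)),
    lnc_examined_by_subclass =
      sapply(screened_subclasses(),
             function(s) length(unique(results$lnc_id[
               results$lnc_subclass == s]))),
    significant_total = n_sig,
    significant_by_subclass = sub_tab(sig),
    n_positive = sum(sig$sign == "positive"),
    n_negative = sum(sig$sign == "negative")
  )
  out$pct_positive <- pc(out$n_positive)
  out$pct_negative <- pc(out$n_negative)
  if ("gene_overlap" %in% names(sig)) {
    out$n_gene_overlap <- sum(sig$gene_overlap)
    out$pct_gene_overlap <- pc(out$n_gene_overlap)
    out$n_promoter_overlap <- sum(sig$promoter_overlap)
    out$pct_promoter_overlap <- pc(out$n_promoter_overlap)
    out$n_ratio_below_30pct <- sum(sig$ratio_below_30pct)
    out$pct_ratio_below_30pct <- pc(out$n_ratio_below_30pct)
  }
  if ("enhancer_transcribed" %in% names(sig)) {
    out$n_enhancer_transcribed <- sum(sig$enhancer_transcribed)
  }
  structure(out, class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("screen_summary: %d pairs examined, %d significant (%d positive / %d negative)\n",
              x$pairs_examined, x$significant_total, x$n_positive,
              x$n_negative))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
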