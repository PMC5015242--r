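#' Exact conditional-binomial test for a two-library rate difference
#'
#' Aggregates counts within each group (\code{k_A}, \code{k_B}) and library
#' sizes (\code{L_A}, \code{L_B}); conditional on the total
#' \code{k = k_A + k_B}, \code{k_A} is Binomial(k, L_A / (L_A + L_B)) under
#' the null of a common rate. The two-sided p-value is the
#' minimum-likelihood sum: probabilities of all outcomes whose null
#' probability is at most that of the observed outcome (ties included),
#' capped at 1. Aggregation across replicates is deliberate: the test
#' addresses the rate difference and ignores biological replicate-to-
#' replicate variability, so its type-I error is inflated under
#' overdispersed counts (reported, not hidden, by the package's simulations).
#'
#' @param counts_a,counts_b Per-sample counts of one gene in each group.
#' @param lib_a,lib_b Per-sample library sizes (positive).
#' @return Two-sided p-value in (0, 1]; \code{k = 0} returns 1 by
#'   convention.
#' @export
exact_count_test <- function(counts_a, counts_b, lib_a, lib_b) {
  if (length(counts_a) < 1 || length(counts_b) < 1)
    stop("need >= 1 sample per group")
  if (any(c(lib_a, lib_b) <= 0)) stop("library sizes must be positive")
  k_a <- sum(counts_a)
  k <- k_a + sum(counts_b)
  if (k == 0) return(1)
  p0 <- sum(lib_a) / (sum(lib_a) + sum(lib_b))
  pr <- stats::dbinom(0:k, k, p0)
  p_obs <- pr[k_a + 1]
  # relative tolerance guards against ties lost to floating error
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (capped at 1, monotone in p-rank); the adjusted
#' value is conventionally called q.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' CPM fold change between two groups
#'
#' Ratio of group mean CPM (group A over group B) with a small pseudocount
#' added to both means to keep near-absent genes finite:
#' \code{(mean_A + c) / (mean_B + c)}.
#'
#' @param expr An \code{expression_matrix}.
#' @param gene_id Gene identifier (may be a vector).
#' @param group_a,group_b Group labels defining numerator and denominator.
#' @param pseudocount Pseudocount c in CPM units (default 0.01).
#' @return data.frame with columns \code{gene_id}, \code{ratio},
#'   \code{log2fc}.
#' @export
fold_change <- function(expr, gene_id, group_a, group_b,
                        pseudocount = 0.01) {
  a <- expr$groups == group_a
  b <- expr$groups == group_b
  if (!any(a) || !any(b)) stop("both groups must be non-empty")
  m <- expr$cpm[gene_id, , drop = FALSE]
  ma <- rowMeans(m[, a, drop = FALSE])
  mb <- rowMeans(m[, b, drop = FALSE])
  ratio <- (ma + pseudocount) / (mb + pseudocount)
  data.frame(gene_id = gene_id, ratio = unname(ratio),
             log2fc = unname(log2(ratio)), stringsAsFactors = FALSE)
}

# internal: shared scaffolding for the per-gene callers
.de_frame <- function(caller_id, cm, group_a, group_b, p, pseudocount) {
  expr <- cpm_normalize(cm)
  fc <- fold_change(expr, rownames(cm$counts), group_a, group_b,
                    pseudocount = pseudocount)
  data.frame(caller_id = caller_id, gene_id = fc$gene_id,
             log2fc = fc$log2fc, p = p, q = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Differential expression by the exact conditional-binomial caller
#'
#' Applies \code{\link{exact_count_test}} to every gene and BH-adjusts the
#' p-values.
#'
#' @param cm A \code{\link{count_matrix}}.
#' @param group_a,group_b Group labels (A over B for the fold change).
#' @param pseudocount CPM pseudocount for the fold change (default 0.01).
#' @return data.frame of per-gene calls: \code{caller_id}, \code{gene_id},
#'   \code{log2fc}, \code{p}, \code{q}.
#' @export
de_exact <- function(cm, group_a, group_b, pseudocount = 0.01) {
  a <- cm$groups == group_a
  b <- cm$groups == group_b
  if (!any(a) || !any(b)) stop("both groups must be non-empty")
  la <- cm$lib_sizes[a]; lb <- cm$lib_sizes[b]
  p <- vapply(seq_len(nrow(cm$counts)), function(i) {
    exact_count_test(cm$counts[i, a], cm$counts[i, b], la, lb)
  }, numeric(1))
  .de_frame("exact_binomial", cm, group_a, group_b, p, pseudocount)
}

#' Differential expression by a Poisson deviance caller
#'
#' Likelihood-ratio test of a common Poisson rate against group-specific
#' rates, on group-aggregated counts with library-size offsets: the deviance
#' \code{2 * [k_A log(k_A / e_A) + k_B log(k_B / e_B)]} (with
#' \code{e_g = k * L_g / L}) is referred to a chi-squared distribution with
#' one degree of freedom. The asymptotic unconditional counterpart of
#' \code{\link{de_exact}}'s exact conditional test; it shares that caller's
#' aggregation philosophy and its overdispersion blindness.
#'
#' @inheritParams de_exact
#' @return data.frame of per-gene calls (as \code{\link{de_exact}}).
#' @export
de_poisson <- function(cm, group_a, group_b, pseudocount = 0.01) {
  a <- cm$groups == group_a
  b <- cm$groups == group_b
  if (!any(a) || !any(b)) stop("both groups must be non-empty")
  ka <- rowSums(cm$counts[, a, drop = FALSE])
  kb <- rowSums(cm$counts[, b, drop = FALSE])
  la <- sum(cm$lib_sizes[a]); lb <- sum(cm$lib_sizes[b])
  k <- ka + kb
  ea <- k * la / (la + lb)
  eb <- k * lb / (la + lb)
  term <- function(obs, exp) ifelse(obs == 0, 0, obs * log(obs / exp))
  dev <- 2 * (term(ka, ea) + term(kb, eb))
  p <- ifelse(k == 0, 1, stats::pchisq(dev, df = 1, lower.tail = FALSE))
  .de_frame("poisson_deviance", cm, group_a, group_b, p, pseudocount)
}

#' Differential expression by exhaustive label permutation
#'
#' Statistic: absolute difference of group mean CPM. The null distribution
#' is built from every relabeling of the samples into groups of the
#' original sizes (462 relabelings for a 6-vs-5 design), evaluated for all
#' genes at once; the per-gene p-value is the fraction of relabelings
#' (including the observed one) whose statistic is at least the observed
#' statistic. This caller is honest about biological variability but has a
#' hard resolution floor of 1 / (number of relabelings): with 6-vs-5
#' groups no p can fall below 1/462, so after BH adjustment across a
#' transcriptome-scale gene set its q-values cannot reach conventional FDR
#' cutoffs. It is provided as a calibration diagnostic; transcriptome-scale
#' intersections should pair \code{\link{de_exact}} with
#' \code{\link{de_poisson}}.
#'
#' @inheritParams de_exact
#' @param max_permutations Cap on relabelings; exhaustive enumeration is
#'   used when the total count is within the cap (default 10000), otherwise
#'   an error asks for an explicit cap raise.
#' @return data.frame of per-gene calls (as \code{\link{de_exact}}).
#' @export
de_permutation <- function(cm, group_a, group_b, pseudocount = 0.01,
                           max_permutations = 10000) {
  a <- which(cm$groups == group_a)
  b <- which(cm$groups == group_b)
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty")
  n <- length(a) + length(b)
  idx <- c(a, b)
  n_a <- length(a)
  total <- choose(n, n_a)
  if (total > max_permutations)
    stop("exhaustive enumeration would need ", total,
         " relabelings; raise max_permutations to proceed")
  cpm <- cpm_normalize(cm)$cpm[, idx, drop = FALSE]
  combos <- utils::combn(n, n_a)
  # contrast matrix: +1/n_a for group-A members, -1/n_b for the rest
  contr <- matrix(-1 / (n - n_a), nrow = n, ncol = ncol(combos))
  for (j in seq_len(ncol(combos))) contr[combos[, j], j] <- 1 / n_a
  stat <- abs(cpm %*% contr)                  # genes x relabelings
  obs_col <- which(vapply(seq_len(ncol(combos)), function(j)
    identical(sort(combos[, j]), seq_len(n_a)), logical(1)))
  obs <- stat[, obs_col]
  p <- rowSums(stat >= obs - 1e-12) / ncol(combos)
  .de_frame("label_permutation", cm, group_a, group_b, p, pseudocount)
}

#' Intersection of differential-expression call sets
#'
#' The final DE list is the set of genes significant (\code{q <= threshold})
#' in every supplied caller's result. Intersection cardinality is monotone
#' non-increasing in the number of call sets.
#'
#' @param call_sets Non-empty list of call data.frames (from the
#'   \code{de_*} callers or any table with \code{caller_id},
#'   \code{gene_id}, \code{q}).
#' @param q_threshold Adjusted-p cutoff (default 0.05, compared with
#'   \code{<=}).
#' @return A list of class \code{de_intersection}: \code{gene_ids} (the
#'   intersection) and \code{q_table} (per-gene per-caller q values of the
#'   intersected genes).
#' @export
intersect_calls <- function(call_sets, q_threshold = 0.05) {
  if (length(call_sets) < 1) stop("need at least one call set")
  sig <- lapply(call_sets, function(cs) cs$gene_id[cs$q <= q_threshold])
  ids <- Reduce(intersect, sig)
  qt <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (cs in call_sets) {
    cname <- paste0("q_", cs$caller_id[1] %||% "caller")
    qt[[cname]] <- cs$q[match(ids, cs$gene_id)]
  }
  structure(list(gene_ids = ids, q_table = qt,
                 q_threshold = q_threshold),
            class = "de_intersection")
}

#' @export
print.de_intersection <- function(x, ...) {
  cat(sprintf("de_intersection: %d gene(s) at q <= %g\n",
              length(x$gene_ids), x$q_threshold))
  invisible(x)
}
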