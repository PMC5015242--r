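#' Run the full cis co-expression screen end-to-end
#'
#' Orchestrates read -> CPM -> mean-expression filter -> composition ->
#' pair building -> Pearson screen -> geometry/enhancer annotation ->
#' summary -> (optional) differential expression with the caller
#' intersection, and writes all machine reports plus a run log. Any stage
#' error aborts with a stage-named message and removes partial outputs.
#' Outputs are a pure function of (inputs, parameters).
#'
#' @param gtf,counts,samples Input paths (GTF, counts TSV, sample-metadata
#'   TSV).
#' @param out_dir Output directory (created if absent).
#' @param bed Optional enhancer BED path.
#' @param cpm_threshold Mean-CPM expression filter (default 1).
#' @param alpha Two-tailed level of the correlation screen (default 0.05).
#' @param q_threshold Adjusted-p cutoff of the DE intersection (default
#'   0.05).
#' @param promoter_width Promoter window width in bp (default 10000).
#' @param ratio_cutoff Expression-ratio cutoff (default 0.30).
#' @param correlation_scale \code{"cpm"} (default) or \code{"log2"}.
#' @param enhancer_mode \code{"tss"} (default) or \code{"any"}.
#' @param cpm_denominator \code{"library"} (default) or \code{"column_sum"}.
#' @param run_de Also run the two count-based DE callers and their
#'   intersection (default TRUE; needs exactly two groups).
#' @param group_a,group_b DE group labels; default: the two groups in the
#'   metadata, in order of first appearance (A over B).
#' @param taxonomy Biotype taxonomy for the GTF reader.
#' @return Invisibly, a list with the in-memory results (\code{expressed},
#'   \code{composition}, \code{pairs}, \code{screen}, \code{summary},
#'   \code{de}, \code{intersection}) and output \code{paths}.
#' @export
run_screen <- function(gtf, counts, samples, out_dir, bed = NULL,
                       cpm_threshold = 1.0, alpha = 0.05,
                       q_threshold = 0.05, promoter_width = 10000,
                       ratio_cutoff = 0.30,
                       correlation_scale = c("cpm", "log2"),
                       enhancer_mode = c("tss", "any"),
                       cpm_denominator = c("library", "column_sum"),
                       run_de = TRUE, group_a = NULL, group_b = NULL,
                       taxonomy = biotype_taxonomy()) {
  correlation_scale <- match.arg(correlation_scale)
  enhancer_mode <- match.arg(enhancer_mode)
  cpm_denominator <- match.arg(cpm_denominator)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      .stage_stop(name, conditionMessage(e))
    })
  }

  annot <- stage("read_gtf", read_gtf(gtf, taxonomy))
  cm <- stage("read_counts", {
    x <- read_counts(counts, samples)
    if (nrow(x$counts) == 0) stop("counts file contains no genes")
    x
  })
  enh <- if (!is.null(bed)) stage("read_bed", read_bed(bed)) else NULL

  expr <- stage("cpm_normalize", cpm_normalize(cm, cpm_denominator))
  expressed <- stage("filter_expressed",
                     filter_expressed(expr, cpm_threshold))
  comp <- stage("composition", composition_report(annot, expressed))
  pairs <- stage("build_pairs", build_pairs(annot, expressed))
  screen <- stage("screen_pairs",
                  screen_pairs(expr, pairs, alpha, correlation_scale))
  screen <- stage("annotate_geometry",
                  annotate_geometry(screen, annot, expr, promoter_width,
                                    ratio_cutoff, enhancers = enh,
                                    enhancer_mode = enhancer_mode))
  summ <- stage("summarize", summarize_screen(screen))

  de <- NULL; inter <- NULL
  if (run_de) {
    de <- stage("differential", {
      gl <- unique(unname(cm$groups))
      if (is.null(group_a)) group_a <- gl[1]
      if (is.null(group_b)) group_b <- gl[2]
      if (length(gl) != 2 && (is.null(group_a) || is.null(group_b)))
        stop("differential expression needs exactly two groups")
      list(exact = de_exact(cm, group_a, group_b),
           poisson = de_poisson(cm, group_a, group_b))
    })
    inter <- stage("intersection", intersect_calls(de, q_threshold))
  }

  paths <- stage("write_reports", {
    p <- list(
      composition = emit(file.path(out_dir, "composition.json")),
      pairs = emit(file.path(out_dir, "screen_pairs.tsv")),
      summary = emit(file.path(out_dir, "screen_summary.json")),
      log = emit(file.path(out_dir, "run_log.txt")))
    jsonlite::write_json(unclass(comp), p$composition, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "columns")
    .write_tsv(screen, p$pairs)
    jsonlite::write_json(unclass(summ), p$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    if (!is.null(de)) {
      for (nm in names(de)) {
        p[[paste0("de_", nm)]] <-
          emit(file.path(out_dir, sprintf("de_%s.tsv", nm)))
        .write_tsv(de[[nm]], p[[paste0("de_", nm)]])
      }
      p$intersection <- emit(file.path(out_dir, "de_intersection.tsv"))
      .write_tsv(inter$q_table, p$intersection)
    }
    inputs <- c(gtf = gtf, counts = counts, samples = samples,
                bed = if (!is.null(bed)) bed)
    log_lines <- c(
      sprintf("lncscreen %s",
              as.character(utils::packageVersion("lncscreen"))),
      sprintf("input %s = %s (md5 %s)", names(inputs), inputs,
              tools::md5sum(inputs)),
      sprintf("param cpm_threshold = %g", cpm_threshold),
      sprintf("param alpha = %g", alpha),
      sprintf("param q_threshold = %g", q_threshold),
      sprintf("param promoter_width = %g", promoter_width),
      sprintf("param ratio_cutoff = %g", ratio_cutoff),
      sprintf("param correlation_scale = %s", correlation_scale),
      sprintf("param enhancer_mode = %s", enhancer_mode),
      sprintf("param cpm_denominator = %s", cpm_denominator))
    writeLines(log_lines, p$log)
    p
  })

  invisible(list(annot = annot, expressed = expressed, composition = comp,
                 pairs = pairs, screen = screen, summary = summ, de = de,
                 intersection = inter, paths = paths))
}

#' Generate and write a synthetic fixture bundle
#'
#' Thin driver over \code{\link{write_fixture_bundle}}: validates the
#' configuration and writes the bundle a \code{\link{run_screen}} call can
#' consume.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param dir Output directory.
#' @return Invisibly, the \code{\link{write_fixture_bundle}} result.
#' @export
run_simulate <- function(config, dir) {
  if (!inherits(config, "synthetic_config"))
    .stage_stop("config", "not a synthetic_config")
  write_fixture_bundle(config, dir)
}
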