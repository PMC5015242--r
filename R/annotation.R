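#' Build an annotation set of stranded gene models
#'
#' The annotation set is the unit all interval logic operates on: one row per
#' gene (span, strand, biotype leaf, transcription start site) plus the exon
#' table. Coordinates are stored 0-based half-open; conversion to and from
#' the 1-based inclusive GTF convention happens only in \code{\link{read_gtf}}
#' and \code{\link{write_gtf}}.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{gene_name},
#'   \code{biotype} (a taxonomy leaf), \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (\code{+} or \code{-} only).
#' @param exons data.frame with columns \code{gene_id}, \code{start},
#'   \code{end}; each exon must lie within its gene's span, and exons of one
#'   gene must be non-overlapping.
#' @return An object of class \code{annotation_set} with elements
#'   \code{genes} (with an added \code{tss} column: \code{start} on the plus
#'   strand, \code{end - 1} on the minus strand), \code{exons} (sorted by
#'   gene and start), and a cached \code{GRanges} span index.
#' @export
annotation_set <- function(genes, exons) {
  need <- c("gene_id", "gene_name", "biotype", "chrom", "start", "end",
            "strand")
  if (!all(need %in% names(genes)))
    stop("genes is missing column(s): ",
         paste(setdiff(need, names(genes)), collapse = ", "))
  genes <- genes[, need]
  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_id in annotation")
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (any(genes$start < 0) || any(genes$start >= genes$end))
      stop("gene spans must satisfy 0 <= start < end")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)

  if (nrow(exons) > 0) {
    i <- match(exons$gene_id, genes$gene_id)
    if (anyNA(i))
      stop("exon references unknown gene_id: ",
           paste(unique(exons$gene_id[is.na(i)]), collapse = ", "))
    if (any(exons$start < 0) || any(exons$start >= exons$end))
      stop("exons must satisfy 0 <= start < end")
    bad <- exons$start < genes$start[i] | exons$end > genes$end[i]
    if (any(bad))
      stop("exon outside its gene span for gene(s): ",
           paste(unique(exons$gene_id[bad]), collapse = ", "))
    exons <- exons[order(i, exons$start), c("gene_id", "start", "end")]
    # non-overlap within each gene
    same <- exons$gene_id[-1] == exons$gene_id[-nrow(exons)]
    if (any(same & exons$start[-1] < exons$end[-nrow(exons)]))
      stop("overlapping exons within a gene")
  } else {
    exons <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  gr <- .spans_to_granges(genes)
  structure(list(genes = genes, exons = exons, gr = gr),
            class = "annotation_set")
}

# internal: 0-based half-open span table -> GRanges (1-based closed)
.spans_to_granges <- function(genes) {
  if (nrow(genes) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Number of genes in an annotation set
#' @param annot An \code{annotation_set}.
#' @return Integer gene count.
#' @export
n_genes <- function(annot) nrow(annot$genes)

#' Extract one gene model
#'
#' @param annot An \code{annotation_set}.
#' @param gene_id Gene identifier.
#' @return A list of class \code{gene_model} with the gene's fields and its
#'   exon table.
#' @export
gene_model <- function(annot, gene_id) {
  i <- match(gene_id, annot$genes$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  g <- as.list(annot$genes[i, ])
  g$exons <- annot$exons[annot$exons$gene_id == gene_id,
                         c("start", "end"), drop = FALSE]
  rownames(g$exons) <- NULL
  structure(g, class = "gene_model")
}

#' Mature transcript length of a gene model
#'
#' Sum of exon lengths, i.e. the length of the spliced transcript in
#' nucleotides.
#'
#' @param gene A \code{gene_model} (from \code{\link{gene_model}}).
#' @return Integer length in nucleotides.
#' @export
mature_length <- function(gene) {
  if (nrow(gene$exons) < 1) stop("gene has no exons")
  sum(gene$exons$end - gene$exons$start)
}

#' Strand-aware promoter window upstream of the TSS
#'
#' Returns the half-open interval of length at most \code{width} immediately
#' upstream of the gene's transcription start site, clipped at chromosome
#' position 0. On the plus strand this is \code{[tss - width, tss)}; on the
#' minus strand \code{[tss + 1, tss + 1 + width)}.
#'
#' @param gene A \code{gene_model}.
#' @param width Window width in bp (default 10000, the 10-kb convention).
#' @return A list with \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
promoter_window <- function(gene, width = 10000) {
  stopifnot(width > 0)
  if (gene$strand == "+") {
    s <- max(0, gene$tss - width)
    e <- gene$tss
  } else {
    s <- gene$tss + 1
    e <- s + width
  }
  list(chrom = gene$chrom, start = s, end = e, strand = gene$strand)
}

# internal: do two half-open intervals on the same chrom overlap by >= 1 bp?
.iv_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# internal: gap between two half-open spans (0 if overlapping or adjacent)
.iv_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s1, s2) - pmin(e1, e2))

#' Nearest (adjacent or overlapping) protein-coding partners of a lncRNA
#'
#' If the lncRNA span overlaps one or more protein-coding genes (either
#' strand), all overlapped coding genes are returned. Otherwise the coding
#' gene(s) on the same chromosome with the minimal span-to-span gap are
#' returned; exact ties return all tied genes. A chromosome without coding
#' genes yields an empty vector. Overlap takes precedence over any gap, and
#' one lncRNA may therefore pair with several coding genes.
#'
#' @param annot An \code{annotation_set}.
#' @param lnc_id Gene identifier of the lncRNA.
#' @return Character vector of coding gene_ids (position order).
#' @export
nearest_coding_partners <- function(annot, lnc_id) {
  g <- annot$genes
  i <- match(lnc_id, g$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", lnc_id)
  coding <- which(g$biotype == "protein_coding" & g$chrom == g$chrom[i] &
                    g$gene_id != lnc_id)
  if (length(coding) == 0) return(character())
  ov <- coding[.iv_overlap(g$start[i], g$end[i], g$start[coding],
                           g$end[coding])]
  if (length(ov) > 0) {
    return(g$gene_id[ov[order(g$start[ov])]])
  }
  gaps <- .iv_gap(g$start[i], g$end[i], g$start[coding], g$end[coding])
  hit <- coding[gaps == min(gaps)]
  g$gene_id[hit[order(g$start[hit])]]
}

#' Positional class of a lncRNA relative to protein-coding genes
#'
#' Classifies a lncRNA into one of the five positional leaves:
#' \itemize{
#'   \item \code{antisense}: span overlaps a protein-coding gene on the
#'     opposite strand;
#'   \item \code{sense_intronic}: same strand, span inside a coding gene
#'     without touching any of its exons;
#'   \item \code{sense_overlapping}: same strand, a coding gene lies entirely
#'     within one of the lncRNA's introns;
#'   \item \code{three_prime_overlapping}: same strand, overlap restricted to
#'     the 3'-most exon region of a coding gene (a gene-level approximation
#'     of transcription from the 3' UTR);
#'   \item \code{lincRNA}: no coding-gene overlap on either strand.
#' }
#' Ambiguous geometry is resolved by the precedence
#' antisense > sense_intronic > sense_overlapping > three_prime_overlapping >
#' lincRNA. When the annotation already carries a lncRNA subclass tag for the
#' gene and \code{use_tag} is \code{TRUE}, the tag is returned unchanged and
#' geometry is only consulted for untagged genes.
#'
#' @param annot An \code{annotation_set} containing the protein-coding genes.
#' @param lnc_id Gene identifier of the lncRNA.
#' @param use_tag Trust an existing subclass biotype tag (default TRUE).
#' @return One of the five positional leaf names.
#' @export
classify_lnc_position <- function(annot, lnc_id, use_tag = TRUE) {
  g <- annot$genes
  i <- match(lnc_id, g$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", lnc_id)
  if (use_tag && g$biotype[i] %in% lncrna_leaves())
    return(g$biotype[i])

  coding <- which(g$biotype == "protein_coding" & g$chrom == g$chrom[i])
  if (length(coding) == 0) return("lincRNA")
  ovl <- .iv_overlap(g$start[i], g$end[i], g$start[coding], g$end[coding])
  ov <- coding[ovl]
  if (length(ov) == 0) return("lincRNA")

  opp <- ov[g$strand[ov] != g$strand[i]]
  if (length(opp) > 0) return("antisense")

  same <- ov[g$strand[ov] == g$strand[i]]
  lnc_ex <- annot$exons[annot$exons$gene_id == lnc_id, , drop = FALSE]
  for (j in same) {
    cid <- g$gene_id[j]
    cex <- annot$exons[annot$exons$gene_id == cid, , drop = FALSE]
    inside <- g$start[i] >= g$start[j] && g$end[i] <= g$end[j]
    hits_exon <- any(.iv_overlap(g$start[i], g$end[i], cex$start, cex$end))
    if (inside && !hits_exon) return("sense_intronic")
  }
  for (j in same) {
    contained <- g$start[j] >= g$start[i] && g$end[j] <= g$end[i]
    in_intron <- contained &&
      !any(.iv_overlap(g$start[j], g$end[j], lnc_ex$start, lnc_ex$end))
    if (in_intron) return("sense_overlapping")
  }
  for (j in same) {
    cid <- g$gene_id[j]
    cex <- annot$exons[annot$exons$gene_id == cid, , drop = FALSE]
    if (nrow(cex) == 0) next
    last <- if (g$strand[j] == "+") which.max(cex$end) else which.min(cex$start)
    ov_ex <- .iv_overlap(g$start[i], g$end[i], cex$start, cex$end)
    if (ov_ex[last] && sum(ov_ex) == 1) return("three_prime_overlapping")
  }
  # same-strand overlap matching none of the specific geometries: closest
  # remaining leaf is sense_overlapping territory; fall back to lincRNA only
  # when nothing overlaps, so report three_prime_overlapping-adjacent cases
  # conservatively as sense_overlapping
  "sense_overlapping"
}

#' Genes whose spans overlap a query interval
#'
#' Thin wrapper over the \code{GenomicRanges} span index; results equal a
#' linear scan over the gene table.
#'
#' @param annot An \code{annotation_set}.
#' @param chrom Chromosome name.
#' @param start,end Half-open 0-based query coordinates.
#' @param strand Optional strand filter (\code{"+"} or \code{"-"}).
#' @return Character vector of gene_ids overlapping the query by >= 1 bp.
#' @export
overlapping_genes <- function(annot, chrom, start, end, strand = NULL) {
  if (n_genes(annot) == 0) return(character())
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, annot$gr, ignore.strand = TRUE)
  ids <- annot$gr$gene_id[S4Vectors::subjectHits(hits)]
  if (!is.null(strand)) {
    keep <- annot$genes$strand[match(ids, annot$genes$gene_id)] == strand
    ids <- ids[keep]
  }
  ids
}

#' Read gene models from a GENCODE-style GTF file
#'
#' Parses \code{gene} and \code{exon} features, groups exons under their
#' gene, maps raw \code{gene_type} (or \code{gene_biotype}) tags through the
#' taxonomy, and converts 1-based inclusive GTF coordinates to the internal
#' 0-based half-open convention. A header-only file yields an empty set.
#'
#' @param path GTF file path.
#' @param taxonomy A \code{\link{biotype_taxonomy}}; unknown tags are an
#'   error unless the taxonomy declares a fallback leaf.
#' @return An \code{\link{annotation_set}}.
#' @export
read_gtf <- function(path, taxonomy = biotype_taxonomy()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  if (any(nfield != 9)) {
    lineno <- which(body)[which(nfield != 9)[1]]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                 lineno, nfield[which(nfield != 9)[1]]))
  }
  empty <- annotation_set(
    data.frame(gene_id = character(), gene_name = character(),
               biotype = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE),
    data.frame(gene_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE))
  if (!any(body)) return(empty)

  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0) return(empty)
  mc <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(mc)) stop("GTF lacks gene_id attributes")
  raw_bt <- if ("gene_type" %in% names(mc)) mc$gene_type
            else if ("gene_biotype" %in% names(mc)) mc$gene_biotype
            else stop("GTF lacks gene_type/gene_biotype attributes")

  strands <- as.character(GenomicRanges::strand(gr))
  if (any(!strands %in% c("+", "-")))
    stop("strand symbols other than '+'/'-' are rejected")

  is_gene <- mc$type == "gene"
  is_exon <- mc$type == "exon"
  genes <- data.frame(
    gene_id = mc$gene_id[is_gene],
    gene_name = if ("gene_name" %in% names(mc))
        ifelse(is.na(mc$gene_name[is_gene]), mc$gene_id[is_gene],
               mc$gene_name[is_gene])
      else mc$gene_id[is_gene],
    biotype = .tax_leaf(raw_bt[is_gene], taxonomy),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = strands[is_gene],
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene_id = mc$gene_id[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE
  )
  annotation_set(genes, exons)
}

#' Write an annotation set as a GENCODE-style GTF file
#'
#' Emits one \code{gene} feature per gene followed by its \code{exon}
#' features, with \code{gene_id}, \code{gene_name} and \code{gene_type}
#' attributes. Internal 0-based half-open coordinates are converted back to
#' the 1-based inclusive GTF convention, so \code{read_gtf(write_gtf(x))}
#' round-trips.
#'
#' @param annot An \code{annotation_set}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(annot, path) {
  g <- annot$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  if (nrow(g) == 0) return(invisible(path))
  ord <- order(g$chrom, g$start)
  for (i in ord) {
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                     g$gene_id[i], g$gene_name[i], g$biotype[i])
    writeLines(sprintf("%s\tlncscreen\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i],
                       attrs), con)
    ex <- annot$exons[annot$exons$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ex) > 0) {
      writeLines(sprintf("%s\tlncscreen\texon\t%d\t%d\t.\t%s\t.\t%s",
                         g$chrom[i], ex$start + 1L, ex$end, g$strand[i],
                         attrs), con)
    }
  }
  invisible(path)
}

#' Read enhancer intervals from a BED file
#'
#' BED3+ with 0-based half-open coordinates; columns beyond the third are
#' ignored.
#'
#' @param path BED file path.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
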