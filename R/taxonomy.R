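#' Biotype taxonomy for count-based transcriptome composition
#'
#' Maps raw annotation biotype tags (GENCODE \code{gene_type} /
#' \code{gene_biotype} values) onto a three-level taxonomy:
#' top classes \code{protein_coding}, \code{ncRNA}, \code{pseudogene};
#' ncRNA subclasses \code{lncRNA}, \code{short_ncRNA},
#' \code{processed_transcript}; lncRNA leaves \code{lincRNA},
#' \code{antisense}, \code{sense_intronic}, \code{sense_overlapping},
#' \code{three_prime_overlapping}; short-ncRNA leaves \code{miRNA},
#' \code{snoRNA}, \code{snRNA}, \code{rRNA}, \code{miscRNA}.
#' Every raw tag maps to exactly one leaf.
#'
#' @param fallback Optional leaf name assigned to unknown raw tags. When
#'   \code{NULL} (default), an unknown tag in a GTF is an error.
#' @return An object of class \code{biotype_taxonomy}: a data.frame with
#'   columns \code{tag}, \code{leaf}, \code{subclass} (\code{NA} outside the
#'   ncRNA class), \code{class}, plus the \code{fallback} attribute.
#' @export
biotype_taxonomy <- function(fallback = NULL) {
  row <- function(tag, leaf, subclass, class) {
    data.frame(tag = tag, leaf = leaf, subclass = subclass, class = class,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("protein_coding", "protein_coding", NA, "protein_coding"),
    # lncRNA leaves (GENCODE mouse vM-era tags and modern synonyms)
    row("lincRNA", "lincRNA", "lncRNA", "ncRNA"),
    row("antisense", "antisense", "lncRNA", "ncRNA"),
    row("antisense_RNA", "antisense", "lncRNA", "ncRNA"),
    row("sense_intronic", "sense_intronic", "lncRNA", "ncRNA"),
    row("sense_overlapping", "sense_overlapping", "lncRNA", "ncRNA"),
    row("3prime_overlapping_ncrna", "three_prime_overlapping", "lncRNA", "ncRNA"),
    row("3prime_overlapping_ncRNA", "three_prime_overlapping", "lncRNA", "ncRNA"),
    row("three_prime_overlapping", "three_prime_overlapping", "lncRNA", "ncRNA"),
    # short ncRNA leaves
    row("miRNA", "miRNA", "short_ncRNA", "ncRNA"),
    row("snoRNA", "snoRNA", "short_ncRNA", "ncRNA"),
    row("snRNA", "snRNA", "short_ncRNA", "ncRNA"),
    row("rRNA", "rRNA", "short_ncRNA", "ncRNA"),
    row("misc_RNA", "miscRNA", "short_ncRNA", "ncRNA"),
    row("miscRNA", "miscRNA", "short_ncRNA", "ncRNA"),
    # processed transcripts: ncRNAs that fit neither the long nor short bin
    row("processed_transcript", "processed_transcript",
        "processed_transcript", "ncRNA"),
    # pseudogene tags collapse onto one leaf
    row("pseudogene", "pseudogene", NA, "pseudogene"),
    row("processed_pseudogene", "pseudogene", NA, "pseudogene"),
    row("unprocessed_pseudogene", "pseudogene", NA, "pseudogene"),
    row("transcribed_processed_pseudogene", "pseudogene", NA, "pseudogene"),
    row("transcribed_unprocessed_pseudogene", "pseudogene", NA, "pseudogene"),
    row("unitary_pseudogene", "pseudogene", NA, "pseudogene"),
    row("polymorphic_pseudogene", "pseudogene", NA, "pseudogene"),
    row("IG_pseudogene", "pseudogene", NA, "pseudogene"),
    row("TR_pseudogene", "pseudogene", NA, "pseudogene")
  )
  stopifnot(!anyDuplicated(tab$tag))
  if (!is.null(fallback) && !fallback %in% tab$leaf)
    stop("fallback must be one of the taxonomy leaves")
  structure(tab, fallback = fallback, class = c("biotype_taxonomy",
                                                "data.frame"))
}

#' Leaves of the lncRNA class
#' @return Character vector of the five lncRNA positional leaves.
#' @export
lncrna_leaves <- function() {
  c("lincRNA", "antisense", "sense_intronic", "sense_overlapping",
    "three_prime_overlapping")
}

#' Leaves screened for cis co-expression
#'
#' Only three of the five lncRNA positional classes enter the
#' nearest-coding-gene co-expression screen.
#' @return Character vector \code{c("antisense", "lincRNA", "sense_intronic")}.
#' @export
screened_subclasses <- function() {
  c("antisense", "lincRNA", "sense_intronic")
}

# internal: map raw tags to leaves, honouring the fallback
.tax_leaf <- function(tags, taxonomy) {
  i <- match(tags, taxonomy$tag)
  leaf <- taxonomy$leaf[i]
  if (anyNA(leaf)) {
    fb <- attr(taxonomy, "fallback")
    if (is.null(fb)) {
      bad <- unique(tags[is.na(leaf)])
      stop("unknown biotype tag(s) with no fallback declared: ",
           paste(bad, collapse = ", "))
    }
    leaf[is.na(leaf)] <- fb
  }
  leaf
}

# internal: leaf -> top class
.leaf_class <- function(leaf) {
  ifelse(leaf == "protein_coding", "protein_coding",
         ifelse(leaf == "pseudogene", "pseudogene", "ncRNA"))
}

# internal: leaf -> ncRNA subclass (NA outside ncRNA)
.leaf_subclass <- function(leaf) {
  out <- rep(NA_character_, length(leaf))
  out[leaf %in% lncrna_leaves()] <- "lncRNA"
  out[leaf %in% c("miRNA", "snoRNA", "snRNA", "rRNA", "miscRNA")] <-
    "short_ncRNA"
  out[leaf == "processed_transcript"] <- "processed_transcript"
  out
}
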