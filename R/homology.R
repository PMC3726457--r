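#' Classify homology-search results per query
#'
#' Triage of tabular alignment hits into three mutually exclusive categories:
#' \describe{
#'   \item{`annotated_gene`}{at least one hit satisfies *all three* conditions:
#'     e-value at or below `evalue_max`, bit score at or above `bitscore_min`,
#'     and the subject is annotated as a transcribed gene;}
#'   \item{`no_alignment`}{the query produced no hits at all;}
#'   \item{`unannotated_or_below_threshold`}{everything else — hits exist but
#'     none passes all three conditions.}
#' }
#'
#' @param hits Data frame of hits (see [read_homology_hits()]): columns
#'   `query_id`, `evalue`, `bitscore`, `subject_is_annotated_gene`.
#' @param queries Character vector of all query ids (the universe). Queries
#'   absent from `hits` are `no_alignment`. Defaults to the ids present in
#'   `hits` (in which case no query can be `no_alignment`).
#' @param evalue_max Maximum significant e-value (inclusive).
#' @param bitscore_min Minimum significant bit score (inclusive).
#' @return Named factor (one level per category) over `queries`.
#' @export
classify_homology <- function(hits, queries = NULL,
                              evalue_max = 1e-5, bitscore_min = 100) {
  stopifnot(evalue_max > 0, bitscore_min > 0)
  levels <- c("annotated_gene", "unannotated_or_below_threshold", "no_alignment")
  hits <- .normalize_hits(hits)
  if (is.null(queries)) queries <- unique(hits$query_id)
  queries <- as.character(queries)
  out <- stats::setNames(rep("no_alignment", length(queries)), queries)
  if (nrow(hits)) {
    pass <- hits$evalue <= evalue_max & hits$bitscore >= bitscore_min &
      hits$subject_is_annotated_gene
    good <- unique(hits$query_id[pass])
    seen <- unique(hits$query_id)
    out[names(out) %in% seen] <- "unannotated_or_below_threshold"
    out[names(out) %in% good] <- "annotated_gene"
  }
  factor(out, levels = levels)
}

#' Summarize homology categories
#'
#' Counts and integer percentages per category; counts always conserve the
#' total and percentages are rounded to the nearest integer (so they can sum
#' to slightly more or less than 100).
#'
#' @param categories Factor from [classify_homology()] (or character vector).
#' @return Data frame with `category`, `count`, `percent`.
#' @examples
#' cats <- rep(c("annotated_gene", "unannotated_or_below_threshold",
#'               "no_alignment"), c(197, 55, 176))
#' summarize_homology(cats)  # 46% / 13% / 41%
#' @export
summarize_homology <- function(categories) {
  levels <- c("annotated_gene", "unannotated_or_below_threshold", "no_alignment")
  if (!is.factor(categories)) categories <- factor(categories, levels = levels)
  if (!length(categories)) stop("no queries to summarize")
  counts <- as.integer(table(categories)[levels])
  total <- sum(counts)
  data.frame(category = levels, count = counts,
             percent = as.integer(round(100 * counts / total)))
}

# accept both the in-memory column names and the on-disk tabular layout
.normalize_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (!"query_id" %in% names(hits) && "qseqid" %in% names(hits)) {
    hits$query_id <- as.character(hits$qseqid)
    hits$subject_id <- as.character(hits$sseqid)
    hits$subject_is_annotated_gene <- hits$is_annotated == 1
  }
  need <- c("query_id", "evalue", "bitscore", "subject_is_annotated_gene")
  missing <- setdiff(need, names(hits))
  if (length(missing))
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  hits
}

#' Heuristic: does a subject description look like an annotated gene?
#'
#' A regex-based helper for hit tables that lack the `is_annotated` column.
#' It is *not* authoritative — the annotation flag should come from the
#' homology-search pipeline itself whenever available — and merely screens
#' descriptions for gene-like wording while rejecting clone/contig/genomic
#' survey entries.
#'
#' @param stitle Character vector of subject descriptions.
#' @return Logical vector.
#' @export
subject_looks_annotated <- function(stitle) {
  pos <- grepl("mRNA|gene|transcript|cDNA|CDS", stitle, ignore.case = TRUE)
  neg <- grepl("clone|contig|scaffold|chromosome .* genomic|survey sequence|BAC|WGS",
               stitle, ignore.case = TRUE)
  pos & !neg
}
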