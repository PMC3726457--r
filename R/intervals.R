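#' Genomic interval
#'
#' A minimal 1-based, fully closed genomic interval. This convention matches
#' GTF and the locus notation used throughout the package (`chr: start-end`);
#' any half-open representation used internally by Bioconductor machinery is
#' converted at the interface and never leaks out.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates; `end >= start >= 1`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("ECA29", 21894122, 21902694)
#' interval_length(gi)  # 8573
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("genomic_interval() builds a single interval")
  if (is.na(start) || is.na(end) || start < 1)
    stop("interval start must be >= 1")
  if (end < start)
    stop(sprintf("interval end (%s) < start (%s)", format(end), format(start)))
  strand <- match.arg(strand, c("+", "-", "*"))
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s: %s-%s (%s), %s bp>\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              x$strand,
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Length of a genomic interval in bases
#'
#' @param x A [genomic_interval()].
#' @return `end - start + 1`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start + 1
}

#' Distance between two genomic intervals
#'
#' Counts the bases strictly between two intervals on the same chromosome.
#' Overlapping or directly abutting intervals have distance 0; intervals on
#' different chromosomes are infinitely far apart (`Inf` sentinel). Strand is
#' ignored. Symmetric in its arguments.
#'
#' @param a,b [genomic_interval()] objects.
#' @return Number of intervening bases, 0, or `Inf`.
#' @examples
#' a <- genomic_interval("chr1", 1, 10)
#' interval_distance(a, genomic_interval("chr1", 21, 30))  # bases 11..20 -> 10
#' interval_distance(a, genomic_interval("chr1", 11, 30))  # abutting -> 0
#' @export
interval_distance <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  if (a$chrom != b$chrom) return(Inf)
  gap <- max(a$start, b$start) - min(a$end, b$end) - 1
  max(0, gap)
}

#' Do two genomic intervals overlap?
#'
#' Shares at least one base; strand-insensitive.
#' @param a,b [genomic_interval()] objects.
#' @return Logical.
#' @export
interval_overlaps <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}

#' Annotation set
#'
#' A queryable collection of annotated features (genes and pseudogenes) used as
#' the reference against which transcript novelty and feature distances are
#' judged. Backed by a `GRanges` index for overlap and nearest-feature queries.
#'
#' @param features A data frame with columns `id`, `chrom`, `start`, `end` and
#'   optionally `strand` and `biotype`. Coordinates are 1-based inclusive.
#'   Feature ids must be unique.
#' @return An object of class `annotation_set`.
#' @seealso [read_annotation()], [overlaps_annotation()],
#'   [nearest_feature_distance()]
#' @export
annotation_set <- function(features) {
  stopifnot(is.data.frame(features))
  need <- c("id", "chrom", "start", "end")
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop("annotation features lack column(s): ", paste(missing, collapse = ", "))
  if (!"strand" %in% names(features))
    features$strand <- rep("*", nrow(features))
  if (!"biotype" %in% names(features))
    features$biotype <- rep("protein_coding", nrow(features))
  if (anyDuplicated(features$id))
    stop("annotation feature ids must be unique")
  if (nrow(features) && any(features$end < features$start))
    stop("annotation features with end < start")
  features <- features[, c("id", "chrom", "start", "end", "strand", "biotype")]
  features$id <- as.character(features$id)
  features$chrom <- as.character(features$chrom)
  idx <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"),
    id = features$id, biotype = features$biotype)
  structure(list(features = features, index = idx), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d features on %d chromosome(s)>\n",
              nrow(x$features), length(unique(x$features$chrom))))
  invisible(x)
}

#' Number of features in an annotation set
#' @param x An [annotation_set()].
#' @export
n_features <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  nrow(x$features)
}

# GRanges view of a single genomic_interval (internal; 1-based closed on both
# sides, which is also the IRanges convention, so no shifting is required).
.as_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}
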