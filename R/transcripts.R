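#' Transcript model
#'
#' One putative transcript assembled from RNA-seq evidence: an ordered set of
#' exons on a single chromosome and strand, a per-model read-coverage depth,
#' and optional splice-junction support. Depth is a single scalar per model
#' (the minimum across exons, as supplied in the evidence sidecar); see the
#' methods vignette for why minimum rather than mean was adopted.
#'
#' @param id Transcript identifier.
#' @param chrom Chromosome name.
#' @param exons Data frame with columns `start`, `end` (1-based inclusive).
#'   Exons must not overlap; they are sorted by start.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param depth Mean/minimum read coverage for the model (reads, >= 0).
#' @param junctions Optional data frame of intron intervals with support:
#'   columns `start`, `end`, `reads`.
#' @return An object of class `transcript_model`.
#' @examples
#' m <- transcript_model("UU1", "chr1", data.frame(start = c(100, 300),
#'                                                 end = c(150, 350)), depth = 40)
#' n_exons(m)
#' spliced_length(m)  # 51 + 51
#' @export
transcript_model <- function(id, chrom, exons, strand = "*", depth = 0,
                             junctions = NULL) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) < 1L) stop("a transcript model needs at least one exon")
  exons <- data.frame(start = as.numeric(exons$start),
                      end = as.numeric(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start < 1) || any(exons$end < exons$start))
    stop(sprintf("transcript %s: invalid exon coordinates", id))
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop(sprintf("transcript %s: overlapping exons", id))
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) || depth < 0)
    stop(sprintf("transcript %s: depth must be a single non-negative number", id))
  if (!is.null(junctions)) {
    stopifnot(is.data.frame(junctions),
              all(c("start", "end", "reads") %in% names(junctions)))
  }
  structure(list(id = as.character(id), chrom = as.character(chrom),
                 strand = match.arg(strand, c("+", "-", "*")),
                 exons = exons, depth = depth, junctions = junctions),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  sp <- genomic_span(x)
  cat(sprintf("<transcript_model %s: %s:%s-%s (%s), %d exon(s), depth %s>\n",
              x$id, x$chrom, format(sp$start, scientific = FALSE),
              format(sp$end, scientific = FALSE), x$strand,
              n_exons(x), format(x$depth)))
  invisible(x)
}

#' Number of exons of a transcript model
#' @param model A [transcript_model()].
#' @export
n_exons <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  nrow(model$exons)
}

#' Spliced (mature transcript) length
#'
#' Sum of exon lengths; always less than or equal to the genomic span length,
#' with equality exactly for single-exon models.
#' @param model A [transcript_model()].
#' @export
spliced_length <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  sum(model$exons$end - model$exons$start + 1)
}

#' Genomic span of a transcript model
#'
#' The locus occupied by the model: from the first exon start to the last exon
#' end, introns included. This is the "Locus" convention used in reports.
#'
#' @param model A [transcript_model()].
#' @return A [genomic_interval()].
#' @export
genomic_span <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  genomic_interval(model$chrom, model$exons$start[1L],
                   model$exons$end[nrow(model$exons)], model$strand)
}

#' Does a transcript model overlap the annotation?
#'
#' A model is *unannotated* (novel) when no exon shares a single base with any
#' annotated gene or pseudogene. The check is strand-insensitive.
#'
#' @param model A [transcript_model()].
#' @param ann An [annotation_set()].
#' @return Logical: `TRUE` if any exon overlaps any feature.
#' @export
overlaps_annotation <- function(model, ann) {
  stopifnot(inherits(model, "transcript_model"), inherits(ann, "annotation_set"))
  if (!nrow(ann$features)) return(FALSE)
  ex <- GenomicRanges::GRanges(model$chrom,
                               IRanges::IRanges(model$exons$start,
                                                model$exons$end))
  any(suppressWarnings(
    GenomicRanges::countOverlaps(ex, ann$index, ignore.strand = TRUE)) > 0L)
}

# vectorized overlaps_annotation over a list of models (one overlap query)
.models_overlap_annotation <- function(models, ann) {
  if (!length(models)) return(logical(0))
  nex <- vapply(models, n_exons, integer(1))
  if (!nrow(ann$features)) return(rep(FALSE, length(models)))
  ex <- GenomicRanges::GRanges(
    rep(vapply(models, `[[`, character(1), "chrom"), nex),
    IRanges::IRanges(unlist(lapply(models, function(m) m$exons$start)),
                     unlist(lapply(models, function(m) m$exons$end))))
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(ex, ann$index, ignore.strand = TRUE)) > 0L
  as.logical(tapply(hit, rep(seq_along(models), nex), any))
}

#' Distance from a transcript model to the nearest annotated feature
#'
#' Minimum [interval_distance()] between the model's genomic span and any
#' feature of the annotation on the same chromosome. Models inside or abutting
#' a feature have distance 0; models on a chromosome with no features get the
#' infinite-distance sentinel `Inf`.
#'
#' @param model A [transcript_model()] (or a list of them, in which case a
#'   numeric vector is returned).
#' @param ann An [annotation_set()].
#' @return Distance in bases (`Inf` sentinel when no feature is comparable).
#' @export
nearest_feature_distance <- function(model, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  models <- if (inherits(model, "transcript_model")) list(model) else model
  stopifnot(all(vapply(models, inherits, logical(1), "transcript_model")))
  if (!length(models)) return(numeric(0))
  spans <- vapply(models, function(m) {
    c(m$exons$start[1L], m$exons$end[nrow(m$exons)])
  }, numeric(2))
  gr <- GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "chrom"),
    IRanges::IRanges(spans[1L, ], spans[2L, ]))
  out <- rep(Inf, length(models))
  if (nrow(ann$features)) {
    hits <- suppressWarnings(
      GenomicRanges::distanceToNearest(gr, ann$index, ignore.strand = TRUE))
    out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  names(out) <- vapply(models, `[[`, character(1), "id")
  if (inherits(model, "transcript_model")) unname(out[1L]) else out
}
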