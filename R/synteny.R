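#' Build an anchored synteny context around a focus locus
#'
#' Grows an interval symmetrically from the focus (the unannotated transcript's
#' genomic span) until it reaches `target_span` bases, then extends each end
#' outward so that both ends are anchored by a whole annotated gene: the
#' interval start moves to the start of the rightmost gene starting at or
#' before it, the end to the end of the leftmost gene ending at or after it.
#' If a flank has no such gene (the chromosome end is reached first), the
#' context is flagged partial and truncated at the outermost gene available.
#'
#' @param focus A [genomic_interval()] — the unannotated transcript locus.
#' @param ann An [annotation_set()] providing the surrounding gene models.
#' @param orthologs Optional ortholog table (see [read_ortholog_table()]).
#' @param blocks Optional alignment-block table (see
#'   [read_alignment_blocks()]).
#' @param target_span Target interval size in bases (default 1 Mb).
#' @return An object of class `synteny_context`: `focus`, `interval`, `genes`
#'   (data frame of wholly contained genes, sorted by start), `orthologs`,
#'   `blocks`, `partial` (logical).
#' @export
build_context <- function(focus, ann, orthologs = NULL, blocks = NULL,
                          target_span = 1e6) {
  stopifnot(inherits(focus, "genomic_interval"), inherits(ann, "annotation_set"),
            target_span > 0)
  genes <- ann$features[ann$features$chrom == focus$chrom, , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  pad <- max(0, ceiling((target_span - interval_length(focus)) / 2))
  sym_start <- focus$start - pad
  sym_end <- focus$end + pad
  partial <- FALSE

  left <- genes[genes$start <= sym_start, , drop = FALSE]
  if (nrow(left)) {
    start <- max(left$start)
  } else {
    partial <- TRUE
    start <- if (nrow(genes)) min(genes$start) else focus$start
  }
  right <- genes[genes$end >= sym_end, , drop = FALSE]
  if (nrow(right)) {
    end <- min(right$end)
  } else {
    partial <- TRUE
    end <- if (nrow(genes)) max(genes$end) else focus$end
  }
  start <- max(1, min(start, focus$start))
  end <- max(end, focus$end)
  contained <- genes[genes$start >= start & genes$end <= end, , drop = FALSE]
  rownames(contained) <- NULL
  structure(list(focus = focus,
                 interval = genomic_interval(focus$chrom, start, end),
                 genes = contained,
                 orthologs = orthologs,
                 blocks = blocks,
                 partial = partial),
            class = "synteny_context")
}

#' @export
print.synteny_context <- function(x, ...) {
  cat(sprintf("<synteny_context: %s:%s-%s (%s bp), %d genes%s>\n",
              x$interval$chrom,
              format(x$interval$start, big.mark = ",", scientific = FALSE),
              format(x$interval$end, big.mark = ",", scientific = FALSE),
              format(interval_length(x$interval), big.mark = ","),
              nrow(x$genes),
              if (x$partial) ", PARTIAL" else ""))
  invisible(x)
}

# ortholog rows of the context's genes for one species
.ctx_orthologs <- function(ctx, species) {
  if (is.null(ctx$orthologs)) stop("context has no ortholog table")
  o <- ctx$orthologs
  o <- o[o$species == species & o$source_gene %in% ctx$genes$id &
           !is.na(o$target_gene), , drop = FALSE]
  # order by source gene position in the context
  o[order(match(o$source_gene, ctx$genes$id)), , drop = FALSE]
}

#' Modal target chromosome of a species' orthologs in a context
#'
#' The chromosome carrying the largest number of ortholog placements; the
#' reference chromosome against which conserved synteny is scored. Ties break
#' to the lexicographically first name.
#'
#' @param ctx A [build_context()] result with an ortholog table.
#' @param species Species name as used in the ortholog table.
#' @return Chromosome name, or `NA` if the species has no orthologs here.
#' @export
modal_target_chromosome <- function(ctx, species) {
  o <- .ctx_orthologs(ctx, species)
  if (!nrow(o)) return(NA_character_)
  tab <- sort(table(o$target_chrom), decreasing = TRUE)
  names(tab)[1L]
}

#' Conserved-synteny fraction of a context
#'
#' Percentage of the context's genes that have an ortholog in the given
#' species on the modal target chromosome, over *all* genes in the context
#' (denominator includes genes with no ortholog), rounded to the nearest
#' integer. 0 when the species has no orthologs at all.
#'
#' @param ctx A [build_context()] result with an ortholog table.
#' @param species Species name.
#' @return Integer percent in `[0, 100]`.
#' @export
conserved_synteny_fraction <- function(ctx, species) {
  stopifnot(inherits(ctx, "synteny_context"))
  n <- nrow(ctx$genes)
  if (!n) return(0L)
  o <- .ctx_orthologs(ctx, species)
  if (!nrow(o)) return(0L)
  modal <- modal_target_chromosome(ctx, species)
  k <- length(unique(o$source_gene[o$target_chrom == modal]))
  as.integer(round(100 * k / n))
}

#' Detect a gene-order inversion relative to a target species
#'
#' Compares the order of the context's genes with the order of their ortholog
#' placements on the modal target chromosome. A negative Kendall rank
#' correlation between the two orders calls a whole-interval inversion; the
#' tau value itself is attached (attribute `tau`) so that partial/segmental
#' rearrangements can be inspected without being called. Fewer than 3 usable
#' ortholog pairs is an indeterminate signal (`NA`).
#'
#' @param ctx A [build_context()] result with an ortholog table.
#' @param species Species name.
#' @return Logical (`TRUE` = inverted), or `NA` when indeterminate; attribute
#'   `tau` carries the rank correlation.
#' @export
detect_inversion <- function(ctx, species) {
  stopifnot(inherits(ctx, "synteny_context"))
  o <- .ctx_orthologs(ctx, species)
  modal <- modal_target_chromosome(ctx, species)
  o <- o[o$target_chrom %in% modal, , drop = FALSE]
  o <- o[!duplicated(o$source_gene), , drop = FALSE]
  if (nrow(o) < 3L) return(structure(NA, tau = NA_real_))
  src_order <- match(o$source_gene, ctx$genes$id)
  tau <- suppressWarnings(
    stats::cor(src_order, o$target_start, method = "kendall"))
  if (is.na(tau)) return(structure(NA, tau = NA_real_))
  structure(unname(tau < 0), tau = unname(tau))
}

#' Alignment coverage of a context interval
#'
#' Percentage of the context interval covered by the species' alignment
#' blocks. Blocks are clipped to the interval and unioned first, so
#' overlapping or duplicated blocks are never double-counted.
#'
#' @param ctx A [build_context()] result with an alignment-block table.
#' @param species Species name.
#' @return Percent in `[0, 100]` (not rounded).
#' @export
alignment_coverage_percent <- function(ctx, species) {
  stopifnot(inherits(ctx, "synteny_context"))
  if (is.null(ctx$blocks)) stop("context has no alignment blocks")
  b <- ctx$blocks
  b <- b[b$species == species & b$chrom == ctx$interval$chrom, , drop = FALSE]
  if (!nrow(b)) return(0)
  starts <- pmax(b$start, ctx$interval$start)
  ends <- pmin(b$end, ctx$interval$end)
  keep <- ends >= starts
  if (!any(keep)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(starts[keep], ends[keep]))
  100 * sum(BiocGenerics::width(ir)) / interval_length(ctx$interval)
}

#' Ortholog conservation profile of the genes flanking the focus
#'
#' For the `k` annotated genes immediately upstream and downstream of the
#' focus, reports whether an ortholog exists in the species and whether it
#' maps to the modal (conserved-synteny) chromosome. A candidate sitting in a
#' "novel island" shows flanking genes with no ortholog, or with orthologs
#' displaced outside the conserved region.
#'
#' @param ctx A [build_context()] result with an ortholog table.
#' @param species Species name.
#' @param k Number of flanking genes per side (fewer are reported if the
#'   context runs out).
#' @return Data frame: `gene`, `side` (`upstream`/`downstream`), `offset`
#'   (1 = nearest), `has_ortholog`, `on_modal_chrom`.
#' @export
flank_conservation_profile <- function(ctx, species, k = 2) {
  stopifnot(inherits(ctx, "synteny_context"), k >= 1)
  g <- ctx$genes
  up <- g[g$end < ctx$focus$start, , drop = FALSE]
  down <- g[g$start > ctx$focus$end, , drop = FALSE]
  up <- utils::tail(up[order(up$end), , drop = FALSE], k)       # nearest last
  down <- utils::head(down[order(down$start), , drop = FALSE], k)
  o <- .ctx_orthologs(ctx, species)
  modal <- modal_target_chromosome(ctx, species)
  describe <- function(genes, side, offsets) {
    if (!nrow(genes)) {
      return(data.frame(gene = character(0), side = character(0),
                        offset = integer(0), has_ortholog = logical(0),
                        on_modal_chrom = logical(0)))
    }
    has <- genes$id %in% o$source_gene
    on_modal <- vapply(genes$id, function(id) {
      rows <- o[o$source_gene == id, , drop = FALSE]
      nrow(rows) > 0 && any(rows$target_chrom %in% modal)
    }, logical(1))
    data.frame(gene = genes$id, side = side, offset = offsets,
               has_ortholog = has, on_modal_chrom = unname(on_modal))
  }
  rbind(describe(up, "upstream", rev(seq_len(nrow(up)))),
        describe(down, "downstream", seq_len(nrow(down))))
}

#' Dot-plot point set for a context/species comparison
#'
#' Flattens the species' alignment blocks into source/target midpoint pairs
#' for external dot-plot rendering; blocks without target coordinates are
#' dropped.
#'
#' @param ctx A [build_context()] result with an alignment-block table.
#' @param species Species name.
#' @return Data frame with `source_start`, `source_end`, `target_start`,
#'   `target_end`.
#' @export
dotplot_points <- function(ctx, species) {
  stopifnot(inherits(ctx, "synteny_context"))
  if (is.null(ctx$blocks)) stop("context has no alignment blocks")
  b <- ctx$blocks
  b <- b[b$species == species & b$chrom == ctx$interval$chrom, , drop = FALSE]
  if (!all(c("target_start", "target_end") %in% names(b)))
    return(data.frame(source_start = numeric(0), source_end = numeric(0),
                      target_start = numeric(0), target_end = numeric(0)))
  b <- b[!is.na(b$target_start), , drop = FALSE]
  data.frame(source_start = b$start, source_end = b$end,
             target_start = b$target_start, target_end = b$target_end)
}
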