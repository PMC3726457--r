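#' Read transcript models from GTF or BED12 plus an evidence sidecar
#'
#' Exon records are grouped by transcript id into [transcript_model()] objects.
#' The evidence sidecar is a tab-separated table with a header and columns
#' `transcript_id`, `depth` and optionally `junctions` (a `;`-separated list of
#' `start-end:reads` intron records). Models with no evidence row get depth 0.
#'
#' @param model_file Path to a GTF (exon features carrying a `transcript_id`
#'   attribute) or BED12 file.
#' @param evidence_file Optional path to the depth/junction sidecar TSV.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return Named list of [transcript_model()] objects, ordered by id.
#' @export
read_transcript_models <- function(model_file, evidence_file = NULL,
                                   format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed($|\\.)", model_file, ignore.case = TRUE))
      "bed" else "gtf"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(model_file, format = "gtf")
    gr <- gr[is.na(gr$type) | tolower(as.character(gr$type)) == "exon"]
    ids <- as.character(gr$transcript_id)
    if (anyNA(ids)) stop("GTF exon records without transcript_id attribute")
    exon_list <- split(gr, ids)
  } else {
    gr <- rtracklayer::import(model_file, format = "bed")
    ids <- as.character(gr$name)
    exon_gr <- rtracklayer::blocks(gr)
    names(exon_gr) <- ids
    exon_list <- exon_gr
  }
  evidence <- NULL
  if (!is.null(evidence_file)) evidence <- read_evidence_table(evidence_file)
  models <- lapply(names(exon_list), function(id) {
    ex <- exon_list[[id]]
    chroms <- unique(as.character(GenomeInfoDb::seqnames(ex)))
    if (length(chroms) != 1L)
      stop(sprintf("transcript %s: exon records span multiple chromosomes (%s)",
                   id, paste(chroms, collapse = ", ")))
    strands <- unique(as.character(BiocGenerics::strand(ex)))
    exdf <- data.frame(start = BiocGenerics::start(ex),
                       end = BiocGenerics::end(ex))
    exdf <- unique(exdf[order(exdf$start), , drop = FALSE])
    depth <- 0
    junctions <- NULL
    if (!is.null(evidence) && id %in% evidence$transcript_id) {
      row <- evidence[match(id, evidence$transcript_id), ]
      depth <- row$depth
      junctions <- .parse_junctions(row$junctions)
    }
    transcript_model(id, chroms,
                     exdf,
                     strand = if (length(strands) == 1L &&
                                  strands %in% c("+", "-")) strands else "*",
                     depth = depth, junctions = junctions)
  })
  names(models) <- names(exon_list)
  models[order(names(models))]
}

#' Write transcript models to GTF plus an evidence sidecar
#'
#' Inverse of [read_transcript_models()]; round-trips field-for-field.
#'
#' @param models List of [transcript_model()] objects.
#' @param model_file Output GTF path.
#' @param evidence_file Optional output TSV path for depth/junctions.
#' @return Invisibly, `model_file`.
#' @export
write_transcript_models <- function(models, model_file, evidence_file = NULL) {
  stopifnot(all(vapply(models, inherits, logical(1), "transcript_model")))
  grs <- lapply(models, function(m) {
    GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(m$exons$start, m$exons$end),
      strand = m$strand, type = "exon",
      gene_id = m$id, transcript_id = m$id)
  })
  gr <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export(gr, model_file, format = "gtf")
  if (!is.null(evidence_file)) {
    ev <- data.frame(
      transcript_id = vapply(models, `[[`, character(1), "id"),
      depth = vapply(models, `[[`, numeric(1), "depth"),
      junctions = vapply(models, function(m) .format_junctions(m$junctions),
                         character(1)))
    utils::write.table(ev, evidence_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(model_file)
}

#' Read a depth/junction evidence sidecar table
#' @param file Path to a TSV with header `transcript_id`, `depth`,
#'   optionally `junctions`.
#' @return Data frame.
#' @export
read_evidence_table <- function(file) {
  ev <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "depth") %in% names(ev)))
    stop("evidence table needs columns transcript_id, depth")
  if (!"junctions" %in% names(ev)) ev$junctions <- ""
  ev$junctions[is.na(ev$junctions)] <- ""
  ev
}

.parse_junctions <- function(txt) {
  if (is.null(txt) || is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+):([0-9]+)$", parts))
  if (any(lengths(m) != 4L)) stop("malformed junction record: ", txt)
  data.frame(start = as.numeric(vapply(m, `[`, character(1), 2L)),
             end = as.numeric(vapply(m, `[`, character(1), 3L)),
             reads = as.numeric(vapply(m, `[`, character(1), 4L)))
}

.format_junctions <- function(j) {
  if (is.null(j) || !nrow(j)) return("")
  paste(sprintf("%d-%d:%d", as.integer(j$start), as.integer(j$end),
                as.integer(j$reads)), collapse = ";")
}

#' Read a reference annotation from GTF/GFF
#'
#' Keeps `gene` and `pseudogene` feature records (or, for annotation files that
#' carry only transcript/exon structure, falls back to one span per `gene_id`).
#'
#' @param file Path to GTF or GFF3.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(file) {
  fmt <- if (grepl("\\.gff3?($|\\.)", file, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- rtracklayer::import(file, format = fmt)
  type <- tolower(as.character(gr$type))
  keep <- gr[type %in% c("gene", "pseudogene")]
  if (!length(keep)) {  # per-gene spans as fallback
    ids <- as.character(gr$gene_id)
    spl <- split(gr, ids)
    keep <- unlist(range(spl, ignore.strand = TRUE))
    keep$gene_id <- names(spl)
    keep$gene_biotype <- NA_character_
  }
  ids <- as.character(keep$gene_id)
  if (anyNA(ids)) ids <- paste0("feature_", seq_along(keep))
  biotype <- if (!is.null(keep$gene_biotype)) as.character(keep$gene_biotype)
             else tolower(as.character(keep$type))
  biotype[is.na(biotype)] <- "protein_coding"
  annotation_set(data.frame(
    id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(keep)),
    start = BiocGenerics::start(keep), end = BiocGenerics::end(keep),
    strand = as.character(BiocGenerics::strand(keep)),
    biotype = biotype))
}

#' Write an annotation set to GTF
#' @param ann An [annotation_set()].
#' @param file Output GTF path.
#' @export
write_annotation <- function(ann, file) {
  stopifnot(inherits(ann, "annotation_set"))
  f <- ann$features
  gr <- GenomicRanges::GRanges(
    f$chrom, IRanges::IRanges(f$start, f$end),
    strand = ifelse(f$strand %in% c("+", "-"), f$strand, "*"),
    type = ifelse(f$biotype == "pseudogene", "pseudogene", "gene"),
    gene_id = f$id, gene_biotype = f$biotype)
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Read a genome from FASTA
#' @param file FASTA path.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(file) {
  g <- Biostrings::readDNAStringSet(file)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @param file Output path.
#' @export
write_genome <- function(genome, file) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, file)
  invisible(file)
}

#' Read a normalized expression matrix
#'
#' @param file TSV with header: `transcript_id` then one column per tissue.
#' @return Numeric matrix, transcripts in rows (rownames = ids), tissues in
#'   columns.
#' @export
read_expression <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "transcript_id")
    stop("expression table must start with a transcript_id column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- df$transcript_id
  m
}

#' Write a normalized expression matrix
#' @param expr Numeric matrix with transcript rownames and tissue colnames.
#' @param file Output TSV path.
#' @export
write_expression <- function(expr, file) {
  df <- data.frame(transcript_id = rownames(expr), expr,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read homology hits in extended 12-column tabular alignment format
#'
#' The standard tabular alignment columns (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject start/end, e-value,
#' bit score) plus two extension columns: `stitle` (subject description) and
#' `is_annotated` (0/1; whether the subject is annotated as a transcribed
#' gene). A header row is expected.
#'
#' @param file Path to the hit table TSV.
#' @return Data frame with at least `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `subject_is_annotated_gene`.
#' @export
read_homology_hits <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("qseqid", "sseqid", "evalue", "bitscore", "is_annotated")
  if (!all(need %in% names(df)))
    stop("homology table needs columns: ", paste(need, collapse = ", "))
  out <- data.frame(query_id = as.character(df$qseqid),
                    subject_id = as.character(df$sseqid),
                    evalue = as.numeric(df$evalue),
                    bitscore = as.numeric(df$bitscore),
                    subject_is_annotated_gene = df$is_annotated == 1,
                    stringsAsFactors = FALSE)
  if ("stitle" %in% names(df)) out$stitle <- as.character(df$stitle)
  if (any(!is.finite(out$evalue)) || any(!is.finite(out$bitscore)))
    stop("non-finite e-value or bit score in homology table")
  out
}

#' Read an ortholog table
#'
#' @param file TSV with header `source_gene`, `species`, `target_gene`,
#'   `target_chrom`, `target_start`, `target_end`, `target_strand`. Absent
#'   orthologs are rows with empty/NA target fields.
#' @return Data frame.
#' @export
read_ortholog_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("source_gene", "species", "target_gene", "target_chrom",
            "target_start", "target_end")
  if (!all(need %in% names(df)))
    stop("ortholog table needs columns: ", paste(need, collapse = ", "))
  present <- !is.na(df$target_gene)
  if (any(present & (is.na(df$target_chrom) | is.na(df$target_start))))
    stop("ortholog target fields must be jointly present or jointly absent")
  df
}

#' Read alignment blocks
#'
#' Source-interval alignment blocks per species (a MAF-subset flattened to
#' intervals), used for alignment-coverage summaries and dot-plot export.
#'
#' @param file TSV with header `species`, `chrom`, `start`, `end` and optional
#'   `target_start`, `target_end`.
#' @return Data frame.
#' @export
read_alignment_blocks <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("species", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("alignment block table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a primer table
#'
#' Mirrors the layout of published validation-primer tables: one row per
#' oligo with columns `transcript`, `primer` (role, e.g. F/R/F1/R2),
#' `sequence` and optionally `length` and `tm`.
#'
#' @param file TSV path.
#' @return Data frame.
#' @export
read_primer_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("transcript", "primer", "sequence")
  if (!all(need %in% names(df)))
    stop("primer table needs columns: ", paste(need, collapse = ", "))
  df$sequence <- toupper(df$sequence)
  df
}

#' Bundled validation primer set
#'
#' The 15 RT-PCR validation oligos shipped with the package as a worked
#' fixture (four unannotated transcript assays plus the RPLP0 control).
#' Note: the two UU18303 oligos are recorded with identical sequences in the
#' source table — an apparent typographical duplication that is preserved
#' verbatim here and exercised by the test suite.
#'
#' @return Data frame with columns `transcript`, `primer`, `sequence`,
#'   `length`, `tm`.
#' @export
validation_primers <- function() {
  read_primer_table(system.file("extdata", "validation_primers.tsv",
                                package = "novtx", mustWork = TRUE))
}

#' Bundled prioritized-transcript locus table
#'
#' The 36 prioritized unannotated transcript loci shipped as a reference
#' fixture: id, chromosome, genomic span, exon count, spliced length and the
#' closest cross-species homolog (where one was found).
#'
#' @return Data frame with columns `transcript`, `chrom`, `start`, `end`,
#'   `n_exons`, `length_bp`, `homolog`.
#' @export
prioritized_transcript_loci <- function() {
  utils::read.delim(system.file("extdata", "selected_transcripts.tsv",
                                package = "novtx", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
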