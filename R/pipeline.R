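#' Pipeline run configuration
#'
#' Bundles every input and threshold of an end-to-end run. Each data input may
#' be given either as a path to a standard-format file (GTF/FASTA/TSV, read
#' lazily at run time) or as the corresponding in-memory object; a
#' [simulate_cohort()] result can be passed wholesale via `cohort`. Optional
#' stages (primer validation, synteny) activate when their inputs are present.
#'
#' @param models Transcript models: path (GTF/BED12) or named list of
#'   [transcript_model()].
#' @param annotation Reference annotation: path or [annotation_set()].
#' @param genome Genome: path or [Biostrings::DNAStringSet]. Needed for the
#'   ORF stage; when absent that stage is skipped.
#' @param expression Expression matrix: path or matrix.
#' @param evidence Optional evidence sidecar path (when `models` is a path).
#' @param hits Optional homology hit table: path or data frame.
#' @param primers Optional primer table: path or data frame (see
#'   [read_primer_table()]).
#' @param orthologs,blocks Optional synteny inputs: paths or data frames.
#' @param cohort Optional [simulate_cohort()] result supplying
#'   models/annotation/genome/expression/hits at once.
#' @param filter A [filter_config()].
#' @param min_orf_aa Minimum ORF length in residues.
#' @param require_atg ATG-anchored ORF mode.
#' @param evalue_max,bitscore_min Homology significance thresholds.
#' @param thermo A [thermo_params()].
#' @param synteny_span Context size for the synteny stage (bp).
#' @param out_dir Optional directory for intermediate TSVs; `NULL` keeps the
#'   run in memory.
#' @param seed Optional seed (the pipeline itself is deterministic; the seed
#'   is recorded in the provenance block).
#' @return An object of class `run_config`.
#' @export
run_config <- function(models = NULL, annotation = NULL, genome = NULL,
                       expression = NULL, evidence = NULL, hits = NULL,
                       primers = NULL, orthologs = NULL, blocks = NULL,
                       cohort = NULL,
                       filter = filter_config(), min_orf_aa = 50,
                       require_atg = FALSE,
                       evalue_max = 1e-5, bitscore_min = 100,
                       thermo = thermo_params(), synteny_span = 1e6,
                       out_dir = NULL, seed = NULL) {
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "novtx_cohort"))
    if (is.null(models)) models <- cohort$models
    if (is.null(annotation)) annotation <- cohort$annotation
    if (is.null(genome)) genome <- cohort$genome
    if (is.null(expression)) expression <- cohort$expression
    if (is.null(hits)) hits <- cohort$hits
  }
  stopifnot(inherits(filter, "filter_config"), inherits(thermo, "thermo_params"),
            min_orf_aa >= 1, evalue_max > 0, bitscore_min > 0, synteny_span > 0)
  for (x in list(models, annotation, genome, expression, evidence, hits,
                 primers, orthologs, blocks)) {
    if (is.character(x) && !file.exists(x))
      stop("input path does not exist: ", x)
  }
  structure(list(models = models, annotation = annotation, genome = genome,
                 expression = expression, evidence = evidence, hits = hits,
                 primers = primers, orthologs = orthologs, blocks = blocks,
                 filter = filter, min_orf_aa = min_orf_aa,
                 require_atg = require_atg, evalue_max = evalue_max,
                 bitscore_min = bitscore_min, thermo = thermo,
                 synteny_span = synteny_span, out_dir = out_dir, seed = seed),
            class = "run_config")
}

# resolve a config slot: read from disk when it is a path
.load_input <- function(x, reader, ...) {
  if (is.null(x) || !is.character(x)) return(x)
  reader(x, ...)
}

.resolve_inputs <- function(config) {
  list(
    models = .load_input(config$models, read_transcript_models,
                         evidence_file = config$evidence),
    annotation = .load_input(config$annotation, read_annotation),
    genome = .load_input(config$genome, read_genome),
    expression = .load_input(config$expression, read_expression),
    hits = .load_input(config$hits, read_homology_hits),
    primers = .load_input(config$primers, read_primer_table),
    orthologs = .load_input(config$orthologs, read_ortholog_table),
    blocks = .load_input(config$blocks, read_alignment_blocks))
}

#' Validate pipeline inputs
#'
#' Screens the resolved inputs for coordinate violations, id mismatches and
#' malformed values, returning machine-readable findings rather than throwing.
#' `level` is `"error"` (the run cannot proceed meaningfully) or `"warning"`.
#'
#' @param config A [run_config()].
#' @return Data frame with columns `level`, `stage`, `message`; zero rows when
#'   the inputs are clean.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- list()
  add <- function(level, stage, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, stage = stage, message = message, stringsAsFactors = FALSE)
  }
  inp <- tryCatch(.resolve_inputs(config), error = function(e) e)
  if (inherits(inp, "error")) {
    add("error", "load", conditionMessage(inp))
    return(do.call(rbind, findings))
  }
  models <- inp$models
  if (!is.null(models)) {
    ids <- vapply(models, `[[`, character(1), "id")
    if (anyDuplicated(ids)) add("error", "models", "duplicated transcript ids")
    for (m in models) {
      if (any(m$exons$end < m$exons$start))
        add("error", "models", sprintf("%s: exon end < start", m$id))
      if (any(m$exons$start < 1))
        add("error", "models", sprintf("%s: exon start < 1", m$id))
    }
    if (!is.null(inp$genome)) {
      widths <- stats::setNames(Biostrings::width(inp$genome),
                                names(inp$genome))
      for (m in models) {
        if (!m$chrom %in% names(widths)) {
          add("error", "genome",
              sprintf("%s: chromosome %s absent from genome", m$id, m$chrom))
        } else if (max(m$exons$end) > widths[[m$chrom]]) {
          add("error", "genome",
              sprintf("%s: exon beyond end of %s", m$id, m$chrom))
        }
      }
    }
    if (!is.null(inp$expression)) {
      missing <- setdiff(ids, rownames(inp$expression))
      for (id in missing)
        add("warning", "expression",
            sprintf("%s: no expression row (excluded at the tissue stage)", id))
      if (any(inp$expression < 0, na.rm = TRUE))
        add("error", "expression", "negative expression values")
    }
    if (!is.null(inp$hits)) {
      orphan <- setdiff(unique(inp$hits$query_id), ids)
      if (length(orphan))
        add("warning", "homology",
            sprintf("%d hit quer%s without a transcript model",
                    length(orphan), if (length(orphan) == 1) "y" else "ies"))
    }
  }
  ann <- inp$annotation
  if (!is.null(ann) && nrow(ann$features) &&
      any(ann$features$end < ann$features$start))
    add("error", "annotation", "feature end < start")
  if (!length(findings)) {
    return(data.frame(level = character(0), stage = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Run the full triage pipeline
#'
#' Executes the end-to-end workflow: novelty screen (drop models overlapping
#' the annotation), the four-filter prioritization cascade, the ORF filter on
#' the prioritized set, homology triage of the whole unannotated set, and —
#' when their inputs are supplied — per-candidate primer/in-silico-PCR
#' validation and synteny-context scoring. Validation findings of level
#' `"error"` abort the run (condition class `novtx_validation_error`); stage
#' failures are re-signalled with the stage name (class `novtx_stage_error`).
#' With `out_dir` set, every stage writes its intermediate table so each
#' reported number can be recounted from disk.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: `cascade` (a `cascade_report`),
#'   `novel_ids`, `n_input`, `n_novel`, `orf_ids`, `n_orf`,
#'   `homology_summary`, `homology_categories`, `candidate_ids`,
#'   `primer_results`, `synteny_results`, `findings`, `provenance`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  findings <- validate_inputs(config)
  if (any(findings$level == "error")) {
    stop(structure(class = c("novtx_validation_error", "error", "condition"),
                   list(message = paste0("validation failed:\n",
                                         paste(findings$message, collapse = "\n")),
                        call = NULL, findings = findings)))
  }
  inp <- .resolve_inputs(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("novtx_stage_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", name,
                                            conditionMessage(e)),
                          call = NULL, stage = name)))
    })
  }
  models <- inp$models
  if (is.null(models)) models <- list()
  if (is.null(inp$annotation)) {
    inp$annotation <- annotation_set(data.frame(
      id = character(0), chrom = character(0),
      start = numeric(0), end = numeric(0)))
  }

  novel <- stage("novelty_screen", {
    if (length(models)) {
      models[!.models_overlap_annotation(models, inp$annotation)]
    } else models
  })
  novel_ids <- vapply(novel, `[[`, character(1), "id")

  cascade <- stage("cascade", {
    run_cascade(novel, inp$annotation, inp$expression, config$filter)
  })
  prioritized <- cascade$surviving_models

  orf_ids <- character(0)
  orf_survivors <- prioritized
  if (!is.null(inp$genome)) {
    orf_survivors <- stage("orf_filter", {
      orf_filter(prioritized, inp$genome, config$min_orf_aa,
                 config$require_atg)
    })
    orf_ids <- vapply(orf_survivors, `[[`, character(1), "id")
  } else {
    orf_ids <- vapply(prioritized, `[[`, character(1), "id")
  }

  homology_summary <- NULL
  categories <- NULL
  candidate_ids <- orf_ids
  if (!is.null(inp$hits) && length(novel_ids)) {
    categories <- stage("homology", {
      classify_homology(inp$hits, queries = novel_ids,
                        evalue_max = config$evalue_max,
                        bitscore_min = config$bitscore_min)
    })
    homology_summary <- summarize_homology(categories)
    candidate_ids <- orf_ids[orf_ids %in%
                               names(categories)[categories == "no_alignment"]]
  }

  primer_results <- NULL
  if (!is.null(inp$primers) && !is.null(inp$genome)) {
    primer_results <- stage("primer_validation", {
      .validate_primers(inp$primers, inp$genome, models, config$thermo)
    })
  }

  synteny_results <- NULL
  if (!is.null(inp$orthologs) && !is.null(inp$annotation) &&
      length(candidate_ids)) {
    synteny_results <- stage("synteny", {
      .score_candidate_contexts(models[candidate_ids], inp$annotation,
                                inp$orthologs, inp$blocks,
                                config$synteny_span)
    })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("novtx")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = .config_hash(config),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"))

  report <- structure(list(
    n_input = length(models),
    novel_ids = novel_ids,
    n_novel = length(novel_ids),
    cascade = cascade,
    orf_ids = orf_ids,
    n_orf = length(orf_ids),
    homology_summary = homology_summary,
    homology_categories = categories,
    candidate_ids = candidate_ids,
    primer_results = primer_results,
    synteny_results = synteny_results,
    findings = findings,
    config = config,
    provenance = provenance), class = "run_report")
  if (!is.null(config$out_dir)) .write_report_files(report, config$out_dir)
  report
}

# deterministic hash of the thresholds and input identities of a run
.config_hash <- function(config) {
  core <- config[c("filter", "min_orf_aa", "require_atg", "evalue_max",
                   "bitscore_min", "synteny_span", "seed")]
  core$inputs <- vapply(
    config[c("models", "annotation", "genome", "expression", "hits",
             "primers", "orthologs", "blocks")],
    function(x) if (is.character(x)) x else class(x)[1L], character(1))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, force = TRUE), f)
  unname(tools::md5sum(f))
}

.validate_primers <- function(primer_df, genome, models, thermo) {
  out <- list()
  for (tx in unique(primer_df$transcript)) {
    sub <- primer_df[primer_df$transcript == tx, , drop = FALSE]
    f <- sub$sequence[grepl("^F", toupper(sub$primer))][1L]
    r <- sub$sequence[grepl("^R", toupper(sub$primer))][1L]
    if (is.na(f) || is.na(r)) next
    model <- models[[tx]]
    target <- if (!is.null(model)) genomic_span(model) else NULL
    pair <- primer_pair(tx, f, r, target)
    qc <- check_primer_constraints(pair, params = thermo)
    max_prod <- if (!is.null(target)) interval_length(target) else 1e4
    amps <- insilico_pcr(genome, pair, max_product = max_prod)
    spec <- if (!is.null(target)) assess_specificity(amps, target) else NA
    spans <- if (!is.null(model))
      isTRUE(amplicon_spans_all_exons(model, pair, genome)) else NA
    out[[tx]] <- data.frame(
      transcript = tx, forward = f, reverse = r,
      tm_forward = round(primer_tm(f, thermo), 2),
      tm_reverse = round(primer_tm(r, thermo), 2),
      constraints_pass = qc$pass,
      constraint_notes = paste(qc$reasons, collapse = "; "),
      n_amplicons = nrow(amps),
      max_product = max_prod,
      specific = spec,
      spans_all_exons = spans,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.score_candidate_contexts <- function(models, ann, orthologs, blocks, span) {
  species <- unique(orthologs$species)
  out <- list()
  for (m in models) {
    ctx <- build_context(genomic_span(m), ann, orthologs, blocks,
                         target_span = span)
    for (sp in species) {
      inv <- detect_inversion(ctx, sp)
      cov <- if (!is.null(blocks)) alignment_coverage_percent(ctx, sp) else NA
      out[[paste(m$id, sp)]] <- data.frame(
        transcript = m$id, species = sp,
        n_genes = nrow(ctx$genes),
        partial = ctx$partial,
        synteny_percent = conserved_synteny_fraction(ctx, sp),
        inversion = as.logical(inv),
        tau = attr(inv, "tau"),
        coverage_percent = if (is.na(cov)) NA else round(cov, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.write_report_files <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  w <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  w(as.data.frame(report$cascade), "cascade_counts.tsv")
  surv <- report$cascade$surviving_ids
  w(data.frame(stage = rep(names(surv), lengths(surv)),
               transcript_id = unlist(surv, use.names = FALSE)),
    "cascade_survivors.tsv")
  w(data.frame(transcript_id = report$novel_ids), "novel_ids.tsv")
  w(data.frame(transcript_id = report$orf_ids), "orf_survivors.tsv")
  if (!is.null(report$homology_summary)) {
    w(report$homology_summary, "homology_summary.tsv")
    w(data.frame(transcript_id = names(report$homology_categories),
                 category = as.character(report$homology_categories)),
      "homology_categories.tsv")
  }
  w(data.frame(transcript_id = report$candidate_ids), "candidates.tsv")
  if (!is.null(report$primer_results)) w(report$primer_results, "pcr.tsv")
  if (!is.null(report$synteny_results)) w(report$synteny_results, "synteny.tsv")
  if (nrow(report$findings)) w(report$findings, "findings.tsv")
  cfg <- report$provenance[c("package_version", "config_hash", "seed")]
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"),
             p("provenance.json"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Unannotated-transcript triage run\n")
  cat(sprintf("  input models            %6d\n", x$n_input))
  cat(sprintf("  novel (no overlap)      %6d\n", x$n_novel))
  df <- as.data.frame(x$cascade)
  for (i in seq_len(nrow(df))[-1L])
    cat(sprintf("  cascade: %-14s %6d\n", df$stage[i], df$count[i]))
  cat(sprintf("  ORF >= %-3d aa           %6d\n",
              x$config$min_orf_aa, x$n_orf))
  if (!is.null(x$homology_summary)) {
    h <- x$homology_summary
    cat(sprintf("  homology: %s\n",
                paste(sprintf("%s %d (%d%%)", h$category, h$count, h$percent),
                      collapse = ", ")))
  }
  cat(sprintf("  candidates              %6d\n", length(x$candidate_ids)))
  if (!is.null(x$primer_results))
    cat(sprintf("  primer assays validated %6d\n", nrow(x$primer_results)))
  if (!is.null(x$synteny_results))
    cat(sprintf("  synteny contexts scored %6d\n",
                nrow(x$synteny_results)))
  invisible(x)
}
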