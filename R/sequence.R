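#' Reverse complement of a DNA string
#' @param dna Character DNA sequence over `A C G T N` (case-insensitive).
#' @return Character reverse complement (upper case).
#' @export
reverse_complement <- function(dna) {
  if (!nchar(dna)) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Extract the spliced sequence of a transcript model
#'
#' Concatenates the exon sequences in transcription order from the reference
#' genome using each exon's start/end coordinates. For minus-strand models the
#' concatenated plus-strand sequence is reverse-complemented as a whole. The
#' result length always equals [spliced_length()].
#'
#' @param genome Named [Biostrings::DNAStringSet] (see [read_genome()]), or a
#'   named character vector of chromosome sequences.
#' @param model A [transcript_model()].
#' @return Character DNA string.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ATGCCCTAG"))
#' m <- transcript_model("t", "chr1",
#'                       data.frame(start = c(1, 7), end = c(3, 9)))
#' extract_spliced_sequence(g, m)  # "ATGTAG"
#' @export
extract_spliced_sequence <- function(genome, model) {
  stopifnot(inherits(model, "transcript_model"))
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!model$chrom %in% names(genome))
    stop(sprintf("transcript %s: chromosome %s not in genome",
                 model$id, model$chrom))
  chr <- genome[[model$chrom]]
  L <- length(chr)
  bad <- which(model$exons$end > L | model$exons$start < 1)
  if (length(bad))
    stop(sprintf("transcript %s: exon %d (%s:%s-%s) outside chromosome bounds (length %s)",
                 model$id, bad[1L], model$chrom,
                 format(model$exons$start[bad[1L]], scientific = FALSE),
                 format(model$exons$end[bad[1L]], scientific = FALSE),
                 format(L, scientific = FALSE)))
  pieces <- Biostrings::extractAt(
    chr, IRanges::IRanges(model$exons$start, model$exons$end))
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Six-frame translation
#'
#' Translates a DNA sequence in all six reading frames under the standard
#' genetic code: frames `+1..+3` from the sequence itself and `-1..-3` from
#' its reverse complement. Stop codons are rendered `*`; any codon containing
#' `N` is rendered `X`; a trailing partial codon is dropped.
#'
#' @param dna Character DNA string over `A C G T N`.
#' @return Named character vector of the six peptides
#'   (`+1`, `+2`, `+3`, `-1`, `-2`, `-3`). An empty input yields six empty
#'   strings.
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(dna)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- stats::setNames(character(6), frames)
  if (!nchar(dna)) return(out)
  if (grepl("[^ACGTN]", dna)) stop("sequence contains non-ACGTN characters")
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  has_n <- grepl("N", dna, fixed = TRUE)
  for (k in 0:2) {
    for (tpl in list(c(paste0("+", k + 1), "f"), c(paste0("-", k + 1), "r"))) {
      src <- if (tpl[2L] == "f") fwd else rev
      n <- length(src) - k
      n <- n - n %% 3L
      out[tpl[1L]] <- if (n >= 3L) {
        sub <- Biostrings::subseq(src, start = k + 1L, width = n)
        # the fuzzy-codon path is markedly slower; only take it when needed
        if (has_n) {
          as.character(Biostrings::translate(sub, no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
        } else {
          as.character(Biostrings::translate(sub, no.init.codon = TRUE))
        }
      } else ""
    }
  }
  out
}

#' Length of the longest open reading frame, in residues
#'
#' Over all six frames, the longest stop-free peptide run: peptides are split
#' at stop symbols (`*`), with the frame ends also acting as boundaries. `X`
#' residues (unknown codons) do not break a run — unknown is not a stop. By
#' default no initiator methionine is required; `require_atg = TRUE` switches
#' to ATG-anchored mode, where a run is counted from its first `M` onward.
#'
#' @param dna Character DNA string.
#' @param require_atg Logical; require the run to start at a methionine.
#' @return Integer number of residues (0 if no open frame).
#' @export
longest_orf_length <- function(dna, require_atg = FALSE) {
  peps <- six_frame_translate(dna)
  best <- 0L
  for (p in peps) {
    if (!nchar(p)) next
    segs <- strsplit(p, "*", fixed = TRUE)[[1L]]
    if (!length(segs)) next
    if (require_atg) {
      m <- regexpr("M", segs, fixed = TRUE)
      lens <- ifelse(m > 0, nchar(segs) - m + 1L, 0L)
    } else {
      lens <- nchar(segs)
    }
    best <- max(best, lens)
  }
  as.integer(best)
}

#' Open-reading-frame filter
#'
#' Keeps transcript models whose spliced sequence supports a peptide of at
#' least `min_aa` residues in some reading frame (default 50).
#'
#' @param models List of [transcript_model()] objects.
#' @param genome Genome as for [extract_spliced_sequence()].
#' @param min_aa Minimum peptide length in residues (inclusive).
#' @param require_atg Passed to [longest_orf_length()].
#' @return The surviving subset of `models`.
#' @export
orf_filter <- function(models, genome, min_aa = 50, require_atg = FALSE) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!length(models)) return(models)
  spliced <- vapply(models, function(m) extract_spliced_sequence(genome, m),
                    character(1))
  lens <- integer(length(spliced))
  plain <- !grepl("N", spliced, fixed = TRUE) & !require_atg
  if (any(plain)) lens[plain] <- .longest_orf_batch(spliced[plain])
  if (any(!plain)) {
    lens[!plain] <- vapply(spliced[!plain], longest_orf_length, integer(1),
                           require_atg = require_atg)
  }
  models[lens >= min_aa]
}

#' Predicted peptides of a transcript model
#'
#' Convenience wrapper: spliced sequence extraction followed by six-frame
#' translation, e.g. for export of the combined peptide FASTA used by
#' downstream domain searches.
#'
#' @param genome Genome as for [extract_spliced_sequence()].
#' @param model A [transcript_model()].
#' @return Named character vector of six peptides.
#' @export
predicted_peptides <- function(genome, model) {
  six_frame_translate(extract_spliced_sequence(genome, model))
}
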