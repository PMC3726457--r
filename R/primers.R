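# Nearest-neighbor duplex parameter sets. Values are dimensioned the way the
# legacy design tools tabulate them: dH in kcal/mol, dS in cal/(mol K), both
# as positive magnitudes of the (negative) stacking terms.
.nn_tables <- list(
  breslauer1986 = list(
    dh = c(AA = 9.1, AC = 6.5, AG = 7.8, AT = 8.6,
           CA = 5.8, CC = 11.0, CG = 11.9, CT = 7.8,
           GA = 5.6, GC = 11.1, GG = 11.0, GT = 6.5,
           TA = 6.0, TC = 5.6, TG = 5.8, TT = 9.1),
    ds = c(AA = 24.0, AC = 17.3, AG = 20.8, AT = 23.9,
           CA = 12.9, CC = 26.6, CG = 27.8, CT = 20.8,
           GA = 13.5, GC = 26.7, GG = 26.6, GT = 17.3,
           TA = 16.9, TC = 13.5, TG = 12.9, TT = 24.0),
    init_dh = 0, init_ds = 10.8),  # helix-initiation entropy penalty
  santalucia1998 = list(
    dh = c(AA = 7.9, AC = 8.4, AG = 7.8, AT = 7.2,
           CA = 8.5, CC = 8.0, CG = 10.6, CT = 7.8,
           GA = 8.2, GC = 9.8, GG = 8.0, GT = 8.4,
           TA = 7.2, TC = 8.2, TG = 8.5, TT = 7.9),
    ds = c(AA = 22.2, AC = 22.4, AG = 21.0, AT = 20.4,
           CA = 22.7, CC = 19.9, CG = 27.2, CT = 21.0,
           GA = 22.2, GC = 24.4, GG = 19.9, GT = 22.4,
           TA = 21.3, TC = 22.2, TG = 22.7, TT = 22.2),
    init_dh = 0, init_ds = 0))

#' Thermodynamic parameters for oligo melting temperature
#'
#' Defaults pin the legacy primer-design configuration: Breslauer (1986)
#' nearest-neighbor dH/dS values with the Schildkraut–Lifson salt correction
#' (`16.6 log10[Na+]`) at 50 mM monovalent cation and 50 nM annealing oligo.
#' The SantaLucia (1998) unified table with its entropy salt correction
#' (`dS + 0.368 (n-1) ln[Na+]`) is available for modern practice.
#'
#' @param nn_table `"breslauer1986"` (default) or `"santalucia1998"`.
#' @param salt_correction `"schildkraut"` (default) or `"santalucia"`.
#' @param monovalent_mM Monovalent cation concentration, mM (> 0).
#' @param oligo_nM Annealing oligo concentration, nM (> 0).
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(nn_table = c("breslauer1986", "santalucia1998"),
                          salt_correction = c("schildkraut", "santalucia"),
                          monovalent_mM = 50, oligo_nM = 50) {
  nn_table <- match.arg(nn_table)
  salt_correction <- match.arg(salt_correction)
  stopifnot(monovalent_mM > 0, oligo_nM > 0)
  structure(list(nn_table = nn_table, salt_correction = salt_correction,
                 monovalent_mM = monovalent_mM, oligo_nM = oligo_nM),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params: %s + %s salt, %g mM monovalent, %g nM oligo>\n",
              x$nn_table, x$salt_correction, x$monovalent_mM, x$oligo_nM))
  invisible(x)
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature
#' \deqn{T_m = \frac{\Delta H}{\Delta S + R \ln(C/4)} - 273.15 + \mathrm{salt}}
#' with R = 1.987 cal/(mol K) and C the annealing oligo concentration; under
#' the default [thermo_params()] this reproduces the legacy design-tool values
#' to two decimals.
#'
#' @param seq Primer sequence, 5'-3', unambiguous `A C G T`, length >= 10.
#' @param params A [thermo_params()].
#' @return Melting temperature in degrees Celsius.
#' @examples
#' primer_tm("TGAGAAGGAAGCCAAGGAAA")  # 59.93
#' @export
primer_tm <- function(seq, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  seq <- toupper(seq)
  if (nchar(seq) < 10) stop("primer_tm needs sequences of length >= 10")
  if (grepl("[^ACGT]", seq)) stop("ambiguous base in primer sequence: ", seq)
  tab <- .nn_tables[[params$nn_table]]
  n <- nchar(seq)
  di <- substring(seq, 1:(n - 1), 2:n)
  dh <- -(tab$init_dh + sum(tab$dh[di])) * 1000  # cal/mol
  ds <- -(tab$init_ds + sum(tab$ds[di]))         # cal/(mol K)
  na_M <- params$monovalent_mM / 1000
  if (params$salt_correction == "santalucia")
    ds <- ds + 0.368 * (n - 1) * log(na_M)
  ct <- params$oligo_nM * 1e-9
  tm <- dh / (ds + 1.987 * log(ct / 4)) - 273.15
  if (params$salt_correction == "schildkraut")
    tm <- tm + 16.6 * log10(na_M)
  tm
}

#' Primer pair
#'
#' A named forward/reverse oligo pair with an optional genomic target interval
#' (the locus whose amplification the pair is meant to validate).
#'
#' @param name Assay name.
#' @param forward,reverse Primer sequences, 5'-3', over `A C G T`, length >= 10.
#' @param target Optional [genomic_interval()].
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, target = NULL) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (s in c(forward, reverse)) {
    if (nchar(s) < 10) stop("primer sequences must be >= 10 bases")
    if (grepl("[^ACGT]", s)) stop("primer sequences must be unambiguous ACGT")
  }
  if (!is.null(target)) stopifnot(inherits(target, "genomic_interval"))
  structure(list(name = as.character(name), forward = forward,
                 reverse = reverse, target = target), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair %s: F %s / R %s>\n", x$name, x$forward, x$reverse))
  invisible(x)
}

#' Check primer design constraints
#'
#' Both oligos of a pair must fall inside the length window (default 20 +/- 2
#' bases) and the melting-temperature window (default 60 +/- 3 degrees C,
#' boundaries inclusive, i.e. 57.0 passes and 56.9 fails).
#'
#' @param pair A [primer_pair()].
#' @param len_opt,len_tol Length window: `len_opt +/- len_tol` bases.
#' @param tm_opt,tm_tol Tm window: `tm_opt +/- tm_tol` degrees C.
#' @param params [thermo_params()] used for the Tm.
#' @return List with `pass` (logical) and `reasons` (character vector, empty
#'   when the pair passes; one entry per violated window).
#' @export
check_primer_constraints <- function(pair, len_opt = 20, len_tol = 2,
                                     tm_opt = 60, tm_tol = 3,
                                     params = thermo_params()) {
  stopifnot(inherits(pair, "primer_pair"))
  reasons <- character(0)
  for (role in c("forward", "reverse")) {
    s <- pair[[role]]
    n <- nchar(s)
    if (n < len_opt - len_tol || n > len_opt + len_tol)
      reasons <- c(reasons, sprintf("%s length %d outside %d +/- %d",
                                    role, n, len_opt, len_tol))
    tm <- primer_tm(s, params)
    if (tm < tm_opt - tm_tol || tm > tm_opt + tm_tol)
      reasons <- c(reasons, sprintf("%s Tm %.2f outside %g +/- %g",
                                    role, tm, tm_opt, tm_tol))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' In-silico PCR
#'
#' Enumerates every genomic site where the pair would amplify a product of at
#' most `max_product` bases: one primer matching the plus strand and the other
#' matching the minus strand downstream of it, in either role orientation (so
#' the output is invariant under swapping forward/reverse with their reverse
#' complements). Matching is exact over the full primer length by default;
#' `max_mismatches` relaxes it.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param pair A [primer_pair()].
#' @param max_product Maximum product size in bases (> 0); conventionally the
#'   genomic interval length of the targeted transcript.
#' @param max_mismatches Mismatches tolerated per primer site (default 0).
#' @return Data frame of amplicons: `chrom`, `start`, `end`, `product_size`,
#'   `strand` (+ when the forward primer is the plus-strand primer),
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (the two primer sites in
#'   plus-strand coordinates). Zero rows when nothing amplifies.
#' @export
insilico_pcr <- function(genome, pair, max_product, max_mismatches = 0) {
  stopifnot(inherits(pair, "primer_pair"), max_product > 0, max_mismatches >= 0)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  res <- list()
  for (chrom in names(genome)) {
    chr <- genome[[chrom]]
    site <- function(p) {  # plus-strand match positions of pattern p
      m <- Biostrings::matchPattern(p, chr, max.mismatch = max_mismatches)
      data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
    }
    f_plus <- site(pair$forward)
    r_minus <- site(reverse_complement(pair$reverse))
    r_plus <- site(pair$reverse)
    f_minus <- site(reverse_complement(pair$forward))
    both <- rbind(
      .pair_sites(f_plus, r_minus, "+"),
      .pair_sites(r_plus, f_minus, "-"))
    if (nrow(both)) {
      both <- both[both$end - both$start + 1 <= max_product, , drop = FALSE]
      if (nrow(both)) {
        both$chrom <- chrom
        res[[chrom]] <- both
      }
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), product_size = numeric(0),
                      strand = character(0), fwd_start = numeric(0),
                      fwd_end = numeric(0), rev_start = numeric(0),
                      rev_end = numeric(0)))
  }
  out <- do.call(rbind, res)
  out$product_size <- out$end - out$start + 1
  out <- out[, c("chrom", "start", "end", "product_size", "strand",
                 "fwd_start", "fwd_end", "rev_start", "rev_end")]
  # self-complementary / identical-primer pairs find each site pair twice,
  # once per orientation; keep one amplicon per genomic placement
  key <- paste(out$chrom, out$start, out$end)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# all upstream-site x downstream-site combinations where the downstream site
# starts at/after the upstream site's start and ends at/after its end
.pair_sites <- function(up, down, strand) {
  if (!nrow(up) || !nrow(down)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      strand = character(0), fwd_start = numeric(0),
                      fwd_end = numeric(0), rev_start = numeric(0),
                      rev_end = numeric(0)))
  }
  g <- expand.grid(i = seq_len(nrow(up)), j = seq_len(nrow(down)))
  ok <- down$start[g$j] >= up$start[g$i] & down$end[g$j] >= up$end[g$i]
  g <- g[ok, , drop = FALSE]
  data.frame(start = up$start[g$i], end = down$end[g$j],
             strand = rep(strand, nrow(g)),
             fwd_start = up$start[g$i], fwd_end = up$end[g$i],
             rev_start = down$start[g$j], rev_end = down$end[g$j])
}

#' Assess primer specificity from in-silico PCR amplicons
#'
#' A pair is specific for its target when it amplifies at all and *every*
#' predicted amplicon overlaps the target interval: any off-target product
#' fails the assay, and so does a pair that produces no product.
#'
#' @param amplicons Data frame from [insilico_pcr()].
#' @param target A [genomic_interval()].
#' @return Logical.
#' @export
assess_specificity <- function(amplicons, target) {
  stopifnot(inherits(target, "genomic_interval"))
  if (!nrow(amplicons)) return(FALSE)
  on_target <- amplicons$chrom == target$chrom &
    amplicons$start <= target$end & amplicons$end >= target$start
  all(on_target)
}

#' Does the pair's amplicon span all exons of a transcript?
#'
#' Locates the forward primer and the reverse complement of the reverse primer
#' on the *spliced* sequence of the model and checks that the resulting
#' spliced amplicon contains at least one base of every exon (the
#' exon-spanning requirement of an expression-validation assay). Both role
#' orientations are tried. When a primer cannot be located, the result is
#' `FALSE` with the reason attached as attribute `reason`.
#'
#' @param model A [transcript_model()].
#' @param pair A [primer_pair()].
#' @param genome Genome for [extract_spliced_sequence()] (ignored when
#'   `spliced` is given).
#' @param spliced Optional pre-extracted spliced sequence.
#' @return Logical (with attribute `reason` when `FALSE` for a structural
#'   reason).
#' @export
amplicon_spans_all_exons <- function(model, pair, genome = NULL,
                                     spliced = NULL) {
  stopifnot(inherits(model, "transcript_model"), inherits(pair, "primer_pair"))
  if (is.null(spliced)) {
    if (is.null(genome)) stop("need either genome or spliced sequence")
    spliced <- extract_spliced_sequence(genome, model)
  }
  locate <- function(fwd, rev) {
    a <- regexpr(fwd, spliced, fixed = TRUE)
    b <- regexpr(reverse_complement(rev), spliced, fixed = TRUE)
    if (a < 0 || b < 0) return(NULL)
    c(start = as.integer(a), end = as.integer(b) + nchar(rev) - 1L)
  }
  hit <- locate(pair$forward, pair$reverse)
  if (is.null(hit)) hit <- locate(pair$reverse, pair$forward)
  if (is.null(hit)) {
    return(structure(FALSE, reason = "primer not found on spliced sequence"))
  }
  if (hit["end"] < hit["start"]) {
    return(structure(FALSE, reason = "primer sites in non-amplifying order"))
  }
  # exon j occupies spliced coordinates [cum_(j-1)+1, cum_j] in transcription
  # order (genomic order reversed on the minus strand); an amplicon intersects
  # every exon iff it reaches into the first and the last one
  widths <- model$exons$end - model$exons$start + 1
  if (model$strand == "-") widths <- rev(widths)
  cum <- cumsum(widths)
  first_end <- cum[1L]
  last_start <- cum[length(cum)] - widths[length(widths)] + 1
  unname(hit["start"] <= first_end && hit["end"] >= last_start)
}
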