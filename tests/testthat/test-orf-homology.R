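test_that("spliced sequence extraction respects exon order and strand", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ATGCCCTAG"))
  m <- transcript_model("t", "chr1", data.frame(start = c(1, 7), end = c(3, 9)))
  expect_equal(extract_spliced_sequence(g, m), "ATGTAG")
  m2 <- transcript_model("t", "chr1", data.frame(start = c(1, 7), end = c(3, 9)),
                         strand = "-")
  expect_equal(extract_spliced_sequence(g, m2), oracle_revcomp("ATGTAG"))
  expect_equal(extract_spliced_sequence(g, m2), "CTACAT")

  bad <- transcript_model("t", "chr1", data.frame(start = 5, end = 20))
  expect_error(extract_spliced_sequence(g, bad), "outside chromosome bounds")
  expect_error(
    extract_spliced_sequence(g, transcript_model("t", "nope",
                                                 data.frame(start = 1, end = 3))),
    "not in genome")
})

test_that("extraction length equals the spliced length on random models", {
  set.seed(48)
  g <- Biostrings::DNAStringSet(c(c1 = rand_dna_ref(20000)))
  for (i in 1:200) {
    k <- sample(1:4, 1)
    starts <- sort(sample(19000, k))
    starts <- starts + cumsum(c(0, rep(250, k - 1)))
    ends <- starts + sample(5:200, k, replace = TRUE)
    m <- transcript_model("r", "c1", data.frame(start = starts, end = ends),
                          strand = sample(c("+", "-"), 1))
    expect_equal(nchar(extract_spliced_sequence(g, m)), spliced_length(m))
  }
})

test_that("six-frame translation uses the standard code with X for N codons", {
  expect_equal(six_frame_translate("ATGGCCTAA")[["+1"]], "MA*")
  expect_equal(six_frame_translate("TTACAT")[["-1"]], "M*")
  expect_equal(unname(six_frame_translate("")), rep("", 6))
  expect_equal(six_frame_translate("ATGNCCGGG")[["+1"]], "MXG")
  expect_error(six_frame_translate("ATGQ"), "non-ACGTN")
})

test_that("six-frame translation agrees with a codon-table oracle", {
  set.seed(49)
  for (i in 1:40) {
    n <- sample(60:300, 1)
    dna <- rand_dna_ref(n)
    if (i %% 4 == 0) {  # sprinkle ambiguity
      pos <- sample(n, 3)
      for (p in pos) substr(dna, p, p) <- "N"
    }
    got <- six_frame_translate(dna)
    rc <- oracle_revcomp(dna)
    expect_equal(unname(got), c(
      oracle_translate_frame(dna, 0), oracle_translate_frame(dna, 1),
      oracle_translate_frame(dna, 2), oracle_translate_frame(rc, 0),
      oracle_translate_frame(rc, 1), oracle_translate_frame(rc, 2)))
  }
})

test_that("frame -k equals frame +k of the reverse complement", {
  set.seed(50)
  for (i in 1:20) {
    dna <- rand_dna_ref(sample(30:200, 1))
    f <- six_frame_translate(dna)
    r <- six_frame_translate(oracle_revcomp(dna))
    for (k in 1:3) {
      expect_equal(f[[paste0("-", k)]], r[[paste0("+", k)]])
    }
  }
})

test_that("longest ORF scan matches brute-force segmentation", {
  expect_equal(longest_orf_length("TAATAATAA"), oracle_longest_orf("TAATAATAA"))
  expect_equal(longest_orf_length(strrep("A", 300)), 100L)  # poly-K, no stops
  set.seed(51)
  for (i in 1:60) {
    dna <- rand_dna_ref(400)
    expect_equal(longest_orf_length(dna), oracle_longest_orf(dna))
  }
})

test_that("longest ORF is reverse-complement invariant and X-tolerant", {
  set.seed(52)
  for (i in 1:25) {
    dna <- rand_dna_ref(sample(100:400, 1))
    expect_equal(longest_orf_length(dna),
                 longest_orf_length(oracle_revcomp(dna)))
  }
  # an unknown codon does not terminate a run (unknown is not a stop)
  with_n <- "ATGAAANNNAAATAA"
  expect_gte(longest_orf_length(with_n), 4L)
})

test_that("ATG-anchored mode counts runs from the first methionine", {
  # frame +1 reads P M A A A * (anchored run 4) but frame -3 of the reverse
  # complement reads M L L P W (anchored run 5), so the max is 5
  dna <- paste0("CCC", "ATG", "GCAGCAGCA", "TAA")
  expect_equal(longest_orf_length(dna, require_atg = TRUE), 5L)
  set.seed(53)
  for (i in 1:20) {
    dna <- rand_dna_ref(300)
    expect_lte(longest_orf_length(dna, require_atg = TRUE),
               longest_orf_length(dna))
  }
})

test_that("orf_filter applies an inclusive residue threshold", {
  set.seed(54)
  g <- Biostrings::DNAStringSet(c(c1 = rand_dna_ref(5000)))
  m <- transcript_model("t", "c1", data.frame(start = 101, end = 1300))
  L <- longest_orf_length(extract_spliced_sequence(g, m))
  expect_length(orf_filter(list(t = m), g, min_aa = L), 1L)
  expect_length(orf_filter(list(t = m), g, min_aa = L + 1), 0L)
})

test_that("planted cohort models all clear the 50-residue ORF rule", {
  co <- simulate_cohort(small_config(seed = 31), compute_orf = FALSE)
  planted <- co$models[co$planted_ids]
  expect_length(orf_filter(planted, co$genome, 50), length(planted))
  for (id in co$planted_ids[1:3]) {
    expect_gte(longest_orf_length(extract_spliced_sequence(co$genome,
                                                           co$models[[id]])),
               50L)
  }
})

test_that("homology triage applies the three joint significance conditions", {
  hits <- data.frame(
    query_id = c("a", "b", "c2"),
    subject_id = "s", evalue = c(1e-6, 1e-4, 1e-6),
    bitscore = c(150, 150, 150),
    subject_is_annotated_gene = c(TRUE, TRUE, FALSE))
  cats <- classify_homology(hits, queries = c("a", "b", "c2", "d"))
  expect_equal(as.character(cats[["a"]]), "annotated_gene")
  expect_equal(as.character(cats[["b"]]), "unannotated_or_below_threshold")
  expect_equal(as.character(cats[["c2"]]), "unannotated_or_below_threshold")
  expect_equal(as.character(cats[["d"]]), "no_alignment")
  # boundary values pass (e-value <= max, bit score >= min)
  edge <- data.frame(query_id = "e", subject_id = "s", evalue = 1e-5,
                     bitscore = 100, subject_is_annotated_gene = TRUE)
  expect_equal(as.character(classify_homology(edge)[["e"]]), "annotated_gene")
})

test_that("categories partition queries and respect threshold monotonicity", {
  set.seed(55)
  ids <- sprintf("q%03d", 1:80)
  hz <- generate_homology_table(small_config(seed = 6), ids,
                                mode = "multinomial")
  cats <- classify_homology(hz$hits, queries = ids)
  expect_equal(length(cats), 80L)
  expect_false(anyNA(cats))
  expect_equal(sum(summarize_homology(cats)$count), 80L)

  loose_e <- classify_homology(hz$hits, queries = ids, evalue_max = 1e-3)
  loose_b <- classify_homology(hz$hits, queries = ids, bitscore_min = 50)
  was_ann <- names(cats)[cats == "annotated_gene"]
  expect_true(all(loose_e[was_ann] == "annotated_gene"))
  expect_true(all(loose_b[was_ann] == "annotated_gene"))
})

test_that("homology summary reproduces the published category split", {
  cats <- rep(c("annotated_gene", "unannotated_or_below_threshold",
                "no_alignment"), c(197, 55, 176))
  s <- summarize_homology(cats)
  expect_equal(s$count, c(197L, 55L, 176L))
  expect_equal(s$percent, c(46L, 13L, 41L))
  expect_equal(sum(s$count), 428L)

  one <- summarize_homology(factor("no_alignment",
                                   levels = levels(classify_homology(
                                     data.frame(query_id = character(0),
                                                evalue = numeric(0),
                                                bitscore = numeric(0),
                                                subject_is_annotated_gene = logical(0)),
                                     queries = "x"))))
  expect_equal(one$percent[one$category == "no_alignment"], 100L)
})

test_that("the subject-description heuristic screens gene-like wording", {
  expect_true(subject_looks_annotated("Equus caballus FXYD4 mRNA, complete cds"))
  expect_false(subject_looks_annotated("BAC clone CH241-123 genomic survey sequence"))
})
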