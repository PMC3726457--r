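# evenly spaced genes every 50 kb (2 kb long) with an intergenic focus;
# expected context arithmetic, derived by hand for this layout:
#   symmetric 1 Mb window [526001, 1526000]; the left anchor is the gene
#   starting at 500001 (greatest start <= 526001), the right anchor the gene
#   ending at 1552000 (least end >= 1526000); wholly contained genes are
#   those starting 500001..1550001, i.e. grid indices 10..31 -> 22 genes
grid_annotation <- function() {
  starts <- 1 + (0:40) * 50000
  annotation_set(data.frame(id = sprintf("G%02d", 0:40), chrom = "c",
                            start = starts, end = starts + 1999))
}

test_that("build_context grows to the span and anchors on whole genes", {
  ann <- grid_annotation()
  focus <- genomic_interval("c", 1025001, 1027000)
  ctx <- build_context(focus, ann, target_span = 1e6)
  expect_false(ctx$partial)
  expect_equal(ctx$interval$start, 500001)
  expect_equal(ctx$interval$end, 1552000)
  expect_equal(nrow(ctx$genes), 22L)
  expect_gte(interval_length(ctx$interval), 1e6)
  # anchors are the first and last listed genes
  expect_equal(ctx$genes$start[1], ctx$interval$start)
  expect_equal(ctx$genes$end[nrow(ctx$genes)], ctx$interval$end)
  # independent re-derivation of the contained set
  g <- ann$features
  sym <- c(focus$start - (1e6 - 2000) / 2, focus$end + (1e6 - 2000) / 2)
  lo <- max(g$start[g$start <= sym[1]])
  hi <- min(g$end[g$end >= sym[2]])
  expect_equal(nrow(ctx$genes), sum(g$start >= lo & g$end <= hi))
})

test_that("a focus near the chromosome start yields a partial context", {
  ann <- grid_annotation()
  ctx <- build_context(genomic_interval("c", 60000, 62000), ann)
  expect_true(ctx$partial)
  expect_output(print(ctx), "PARTIAL")
})

test_that("generator contexts hold 19-25 genes at the observed density", {
  for (s in 1:5) {
    ctx <- generate_synteny_context(generator_config(seed = s))
    expect_gte(nrow(ctx$genes), 19L)
    expect_lte(nrow(ctx$genes), 25L)
    expect_true(all(attr(ctx, "truth")$human$n_genes == nrow(ctx$genes)))
  }
})

test_that("conserved synteny counts modal-chromosome orthologs over all genes", {
  mk_ctx <- function(n, orth) {
    starts <- 1 + (seq_len(n) - 1) * 50000
    genes <- data.frame(id = sprintf("g%02d", seq_len(n)), chrom = "c",
                        start = starts, end = starts + 1999,
                        strand = "+", biotype = "protein_coding")
    structure(list(focus = genomic_interval("c", 90000, 92000),
                   interval = genomic_interval("c", 1, max(genes$end)),
                   genes = genes, orthologs = orth, blocks = NULL,
                   partial = FALSE), class = "synteny_context")
  }
  orth_all <- data.frame(source_gene = sprintf("g%02d", 1:20),
                         species = "human", target_gene = letters[1:20],
                         target_chrom = "h5",
                         target_start = 1:20 * 1e5,
                         target_end = 1:20 * 1e5 + 1000,
                         target_strand = "+")
  expect_equal(conserved_synteny_fraction(mk_ctx(20, orth_all), "human"), 100L)
  orth3 <- orth_all[1:3, ]
  expect_equal(conserved_synteny_fraction(mk_ctx(4, orth3), "human"), 75L)
  expect_equal(conserved_synteny_fraction(mk_ctx(4, orth3[0, ]), "human"), 0L)

  # removing an ortholog never increases the fraction
  for (drop in 1:20) {
    expect_lte(conserved_synteny_fraction(mk_ctx(20, orth_all[-drop, ]),
                                          "human"), 100L)
    expect_lte(conserved_synteny_fraction(mk_ctx(20, orth_all[-drop, ]), "human"),
               conserved_synteny_fraction(mk_ctx(20, orth_all), "human"))
  }
})

test_that("inversion detection follows the sign of Kendall tau", {
  base <- generate_synteny_context(generator_config(seed = 2),
                                   n_genes = 20, synteny_count = 15)
  expect_false(detect_inversion(base, "human"))
  expect_equal(attr(detect_inversion(base, "human"), "tau"), 1)

  inv <- generate_synteny_context(generator_config(seed = 2),
                                  n_genes = 20, synteny_count = 15,
                                  inversion = TRUE)
  expect_true(detect_inversion(inv, "human"))
  expect_equal(attr(detect_inversion(inv, "human"), "tau"), -1)

  # flipping the target coordinate axis flips the call
  flipped <- base
  flipped$orthologs$target_start <- -flipped$orthologs$target_start
  flipped$orthologs$target_end <- -flipped$orthologs$target_end + 1e9
  expect_true(detect_inversion(flipped, "human"))

  two <- base
  two$orthologs <- two$orthologs[1:2, ]
  expect_true(is.na(detect_inversion(two, "human")))
})

test_that("inversion sign matches exhaustive pair counting on permutations", {
  ctx <- generate_synteny_context(generator_config(seed = 3),
                                  n_genes = 10, synteny_count = 5)
  o <- ctx$orthologs[ctx$orthologs$species == "human", ]
  set.seed(62)
  for (n in 3:5) {
    perms <- combinat_perms(n)
    for (p in perms) {
      oo <- o[1:n, ]
      oo$target_start <- p * 1e5
      oo$target_end <- oo$target_start + 10
      ctx$orthologs <- oo
      got <- detect_inversion(ctx, "human")
      s <- oracle_kendall_sign(seq_len(n), p)
      if (s == 0) {
        # a zero tau is not an inversion call
        expect_false(isTRUE(got))
      } else {
        expect_equal(unname(as.logical(got)), s < 0)
      }
    }
  }
})

test_that("alignment coverage unions blocks and matches the bitmap oracle", {
  ctx <- generate_synteny_context(generator_config(seed = 4), n_genes = 20,
                                  coverage_percent = 50)
  int <- ctx$interval
  half <- data.frame(species = "human", chrom = int$chrom, start = int$start,
                     end = int$start + interval_length(int) / 2 - 1)
  ctx$blocks <- half
  expect_equal(alignment_coverage_percent(ctx, "human"), 50, tolerance = 1e-6)
  ctx$blocks <- rbind(half, half)  # duplicate blocks never double-count
  expect_equal(alignment_coverage_percent(ctx, "human"), 50, tolerance = 1e-6)

  set.seed(63)
  for (i in 1:30) {
    nb <- sample(1:8, 1)
    s <- sample(seq(int$start, int$end - 2000), nb)
    b <- data.frame(species = "human", chrom = int$chrom, start = s,
                    end = s + sample(500:50000, nb, replace = TRUE))
    b$end <- pmin(b$end, int$end)
    ctx$blocks <- b
    expect_equal(alignment_coverage_percent(ctx, "human"),
                 oracle_coverage_percent(b, int$start, int$end),
                 tolerance = 1e-9)
    # splitting a block at an arbitrary point changes nothing
    cut <- floor((b$start[1] + b$end[1]) / 2)
    split_b <- rbind(b[-1, ],
                     data.frame(species = "human", chrom = int$chrom,
                                start = c(b$start[1], cut + 1),
                                end = c(cut, b$end[1])))
    ctx$blocks <- split_b
    expect_equal(alignment_coverage_percent(ctx, "human"),
                 oracle_coverage_percent(b, int$start, int$end),
                 tolerance = 1e-9)
  }
})

test_that("flank profiles expose missing and displaced orthologs", {
  cons <- generate_synteny_context(generator_config(seed = 5), n_genes = 20,
                                   synteny_count = 15, flank_mode = "conserved")
  fp <- flank_conservation_profile(cons, "human", k = 2)
  near <- fp[fp$offset == 1, ]
  expect_true(all(near$has_ortholog))
  expect_true(all(near$on_modal_chrom))

  miss <- generate_synteny_context(generator_config(seed = 5), n_genes = 20,
                                   synteny_count = 15, flank_mode = "missing")
  fpm <- flank_conservation_profile(miss, "human", k = 2)
  expect_true(all(!fpm$has_ortholog[fpm$offset == 1]))

  disp <- generate_synteny_context(generator_config(seed = 5), n_genes = 20,
                                   synteny_count = 15, flank_mode = "displaced")
  fpd <- flank_conservation_profile(disp, "human", k = 2)
  nd <- fpd[fpd$offset == 1, ]
  expect_true(all(nd$has_ortholog))
  expect_true(all(!nd$on_modal_chrom))
})

test_that("dot-plot export flattens blocks with target coordinates", {
  ctx <- generate_synteny_context(generator_config(seed = 6), n_genes = 20)
  pts <- dotplot_points(ctx, "dog")
  expect_true(nrow(pts) >= 1)
  expect_named(pts, c("source_start", "source_end",
                      "target_start", "target_end"))
})
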