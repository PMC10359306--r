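fixture_call <- function(start, end, strand = "+", seq_id = "chr",
                         k = 9L, tsd = "TGCGCACCA", name = "IS10tst") {
  data.frame(element_name = name, seq_id = seq_id, start = start, end = end,
             strand = strand, k = k, tsd_sequence = tsd,
             stringsAsFactors = FALSE)
}

test_that("disrupted gene, relative position and orientation are computed", {
  genes <- gene_models("chr", start = 100, end = 1600, strand = "+",
                       gene_name = "casC", system_label = "CRISPR-Cas")
  ann <- annotate_insertion(fixture_call(500, 700), genes)
  expect_equal(ann$disrupted_gene, "casC")
  expect_equal(ann$system_label, "CRISPR-Cas")
  expect_equal(ann$relative_position, (500 - 100) / 1500, tolerance = 1e-12)
  expect_equal(round(ann$relative_position, 2), 0.27)
  expect_equal(ann$orientation, "same")

  # position is measured on the gene's strand
  genes_m <- gene_models("chr", 100, 1600, "-", "casC")
  ann_m <- annotate_insertion(fixture_call(500, 700), genes_m)
  expect_equal(ann_m$relative_position, (1600 - 500) / 1500,
               tolerance = 1e-12)
  expect_equal(ann_m$orientation, "opposite")

  # intergenic insertion: no gene
  ann_ig <- annotate_insertion(fixture_call(2000, 2200), genes)
  expect_true(is.na(ann_ig$disrupted_gene))
  expect_true(is.na(ann_ig$relative_position))
})

test_that("maximal-overlap rule with leftmost tie-break picks the gene", {
  genes <- gene_models("chr", start = c(100, 1550), end = c(1600, 3000),
                       strand = c("+", "+"), gene_name = c("gA", "gB"))
  # element [1500, 1700): 100 bp in gA, 150 bp in gB -> gB
  expect_equal(annotate_insertion(fixture_call(1500, 1700),
                                  genes)$disrupted_gene, "gB")
  # element [1525, 1625): 75 bp in each -> leftmost start wins
  expect_equal(annotate_insertion(fixture_call(1525, 1625),
                                  genes)$disrupted_gene, "gA")
  # annotations on another sequence are an error
  expect_error(annotate_insertion(fixture_call(10, 20, seq_id = "other"),
                                  genes), "seq_id")
})

test_that("context scan applies the +/- 10 kb window with clipping", {
  genes <- gene_models("chr",
                       start = c(3000, 24000, 26000, 14200, 15400),
                       end = c(4400, 25000, 27000, 14800, 16800),
                       strand = "+",
                       gene_name = c("far_up", "near_down", "far_down",
                                     "rm1", "rm2"),
                       system_label = c(NA, NA, NA, "RM", "RM"))
  call <- fixture_call(14500, 15500)
  ctx <- scan_context(call, genes, window = 10000)
  # 9.5 kb downstream gene in; 10.5 kb out; 10.5 kb upstream out
  expect_setequal(ctx$gene_name, c("near_down", "rm1", "rm2"))
  expect_equal(ctx$system_label[ctx$gene_name %in% c("rm1", "rm2")],
               c("RM", "RM"))
  # window = 0 returns exactly the element-overlapping genes
  ctx0 <- scan_context(call, genes, window = 0)
  expect_setequal(ctx0$gene_name, c("rm1", "rm2"))
})

test_that("spectrum collapses shared sites and flags multi-mapping TSDs", {
  genes <- gene_models("chr", c(0, 5000), c(3000, 8000), c("+", "+"),
                       c("gA", "gB"))
  empty <- build_spectrum(annotate_insertions(fixture_call(100, 200)[0, ],
                                              genes))
  expect_equal(nrow(empty$sites), 0L)
  expect_length(empty$genes, 0L)

  calls <- rbind(fixture_call(500, 1268, k = 9, tsd = "TGCGCACCA",
                              name = "IS10tst"),
                 fixture_call(500, 1268, k = 9, tsd = "TGCGCACCA",
                              name = "IS1tst"),
                 fixture_call(6000, 6768, k = 8, tsd = "AATTAATT",
                              name = "IS1tst"))
  ann <- annotate_insertions(calls, genes)
  spec <- build_spectrum(ann, make_test_catalog())
  expect_equal(nrow(spec$sites), 2L)   # two unique sites from three events
  shared <- spec$sites[spec$sites$gene == "gA", ]
  expect_equal(shared$n_events, 2L)
  expect_equal(shared$families, "IS1,IS10")
  expect_equal(shared$gc, 6 / 9, tolerance = 1e-12)
  expect_equal(spec$per_gene_site_counts[["gA"]], 1L)
  expect_false(any(spec$sites$multi_mapping))

  # the same TSD at two distinct sites is flagged as potentially off-target
  calls2 <- rbind(calls[1, ], fixture_call(6000, 6768, k = 9,
                                           tsd = "TGCGCACCA"))
  spec2 <- build_spectrum(annotate_insertions(calls2, genes))
  expect_true(all(spec2$sites$multi_mapping))

  # column count never exceeds annotation count
  expect_lte(nrow(spec$sites), nrow(ann))
})

test_that("amplicon sizes follow base + element length + k", {
  set.seed(77)
  tpl <- random_dna(6000)
  fwd <- substr(tpl, 501, 520)
  rev <- revcomp(substr(tpl, 4924, 4943))   # 5' ends 500 and 4942 -> 4443 bp
  expect_equal(predict_amplicons(tpl, fwd, rev), 4443L)
  sizes <- predict_amplicons(tpl, fwd, rev,
                             data.frame(element_length = c(768, 1329),
                                        k = c(9, 9)))
  expect_equal(sizes, c(4443L, 5220L, 5781L))

  expect_error(predict_amplicons(tpl, "ACGTACGTACGTACGTACGA", rev),
               "not found.*fwd")
  tpl2 <- paste0(tpl, substr(tpl, 401, 700))  # duplicate the fwd site
  expect_error(predict_amplicons(tpl2, fwd, rev), "multi-maps.*fwd")
})

test_that("an implant grows any enclosing span by element length + k", {
  cat1 <- make_test_catalog()
  loc <- generate_locus(3, seed = 23)
  sp <- implant_spec("IS10tst", 1, c("9" = 1), seed = 23)
  imp <- implant_elements(loc$sequence, loc$genes, cat1, sp)
  expect_equal(nchar(imp$sequence),
               nchar(loc$sequence) + cat1[["IS10tst"]]$length + 9L)
})
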