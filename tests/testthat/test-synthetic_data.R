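test_that("generated loci have non-overlapping genes and stated GC", {
  loc <- generate_locus(8, gene_length_range = c(300, 3000), seed = 1)
  g <- loc$genes
  expect_equal(nrow(g), 8L)
  expect_true(all(g$end[-8] <= g$start[-1]))   # sorted, non-overlapping
  expect_true(all(g$end <= nchar(loc$sequence)))

  # byte-identical regeneration under the same seed
  loc2 <- generate_locus(8, gene_length_range = c(300, 3000), seed = 1)
  expect_identical(loc2$sequence, loc$sequence)
  expect_identical(loc2$genes, loc$genes)
  expect_false(identical(generate_locus(8, seed = 2)$sequence,
                         loc$sequence))

  # realized GC within the binomial bound at 100 kb
  big <- generate_locus(10, gene_length_range = c(8000, 11000),
                        intergenic_range = c(100, 200), gc = 0.5, seed = 4)
  expect_gt(nchar(big$sequence), 80000)
  expect_lt(abs(gc_fraction(big$sequence) - 0.5), 0.01)

  expect_error(generate_locus(0), "n_genes")
})

test_that("implants duplicate the target k-mer and keep the books", {
  cat1 <- make_test_catalog()
  loc <- generate_locus(6, seed = 31)
  sp <- implant_spec("IS1tst", 10, c("9" = 0.5, "8" = 0.5), seed = 31)
  imp <- implant_elements(loc$sequence, loc$genes, cat1, sp)
  elt <- cat1[["IS1tst"]]

  # conservation: total growth is sum of element length + k
  expect_equal(nchar(imp$sequence),
               nchar(loc$sequence) + sum(elt$length + imp$truth$k))

  for (i in seq_len(nrow(imp$truth))) {
    tr <- imp$truth[i, ]
    # element interval holds the element, oriented by strand
    obs <- substr(imp$sequence, tr$start + 1, tr$end)
    expect_identical(obs, if (tr$strand == "+") elt$sequence
                          else revcomp(elt$sequence))
    # the TSD flanks both sides
    expect_identical(substr(imp$sequence, tr$start - tr$k + 1, tr$start),
                     tr$tsd_sequence)
    expect_identical(substr(imp$sequence, tr$end + 1, tr$end + tr$k),
                     tr$tsd_sequence)
    # insertion point is the first base of the upstream copy
    expect_equal(tr$insertion_point, tr$start - tr$k)
  }

  # determinism
  imp2 <- implant_elements(loc$sequence, loc$genes, cat1, sp)
  expect_identical(imp2$sequence, imp$sequence)
  expect_identical(imp2$truth, imp$truth)
})

test_that("gene coordinates are shifted through implants", {
  cat1 <- make_test_catalog()
  loc <- generate_locus(6, seed = 32)
  sp <- implant_spec("IS10tst", 5, c("9" = 1), seed = 32)
  imp <- implant_elements(loc$sequence, loc$genes, cat1, sp)
  # every gene's sequence content is preserved up to the inserted blocks:
  # gene intervals must still be valid and ordered
  g <- imp$genes
  expect_true(all(g$start < g$end))
  expect_true(all(g$end <= nchar(imp$sequence)))
  # truth disrupted_gene agrees with the annotator on the mutated locus
  hits <- find_exact_copies(cat1, stats::setNames(imp$sequence, loc$seq_id))
  calls <- call_tsds(stats::setNames(imp$sequence, loc$seq_id), hits, cat1)
  ann <- annotate_insertions(calls, g)
  key <- function(df) paste(df$start, df$end)
  m <- match(key(imp$truth), key(ann))
  expect_false(anyNA(m))
  expect_equal(ann$disrupted_gene[m], imp$truth$disrupted_gene)
})

test_that("motif-biased sites all match the stated motif", {
  cat1 <- make_test_catalog()
  loc <- generate_locus(4, seed = 33)
  sp <- implant_spec("IS1tst", 15, c("4" = 1), site_motif = "YTAR",
                     seed = 33)
  imp <- implant_elements(loc$sequence, loc$genes, cat1, sp)
  for (tsd in imp$truth$tsd_sequence)
    expect_match(tsd, "^[CT]TA[AG]$")

  # an unsatisfiable motif fails with advice, not a hang
  sp_bad <- implant_spec("IS1tst", 1, c("8" = 1),
                         site_motif = "AAAAAAAA", seed = 33)
  tiny <- strrep("GC", 200)
  expect_error(implant_elements(tiny, loc$genes[0, ], cat1, sp_bad,
                                max_tries = 200), "looser")
})

test_that("k mixture draws follow the stated distribution", {
  cat1 <- make_test_catalog()
  set.seed(35)
  bg <- random_dna(120000)
  sp <- implant_spec("IS1tst", 200, c("9" = 0.78, "8" = 0.22), seed = 35)
  imp <- implant_elements(bg, gene_models(character(0), integer(0),
                                          integer(0), character(0),
                                          character(0)), cat1, sp)
  p9 <- mean(imp$truth$k == 9)
  # 95% binomial interval around 0.78 at n = 200
  half <- 1.96 * sqrt(0.78 * 0.22 / 200)
  expect_gt(p9, 0.78 - half)
  expect_lt(p9, 0.78 + half)
})

test_that("detection metrics score interval-and-k agreement", {
  truth <- data.frame(element_name = "e", seq_id = "s",
                      start = c(100, 900), end = c(400, 1200),
                      insertion_point = c(91, 891), k = c(9, 9),
                      tsd_sequence = "x", strand = "+",
                      disrupted_gene = NA, stringsAsFactors = FALSE)
  calls_exact <- data.frame(seq_id = "s", start = c(100, 900),
                            end = c(400, 1200), k = c(9, 9))
  m <- evaluate_detection(truth, calls_exact)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$exact_k_rate, 1)

  # one spurious call: precision n/(n+1)
  calls_extra <- rbind(calls_exact,
                       data.frame(seq_id = "s", start = 5000, end = 5300,
                                  k = 9))
  m2 <- evaluate_detection(truth, calls_extra)
  expect_equal(m2$recall, 1)
  expect_equal(m2$precision, 2 / 3)

  # right interval, wrong k: counted in position matches, not TPs
  calls_wrongk <- calls_exact; calls_wrongk$k[2] <- 10
  m3 <- evaluate_detection(truth, calls_wrongk)
  expect_equal(m3$recall, 0.5)
  expect_equal(m3$exact_k_rate, 0.5)
})

test_that("implant spec validation", {
  expect_error(implant_spec("e", 5, c("9" = 0.5, "8" = 0.4)), "sum to 1")
  expect_error(implant_spec("e", 5, c(0.5, 0.5)), "named")
  expect_error(implant_spec("e", 5, c("9" = 1), site_motif = "QQ"),
               "invalid IUPAC")
})
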