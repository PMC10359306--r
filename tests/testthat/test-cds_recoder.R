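test_that("IUPAC site finding matches the positionwise oracle", {
  # worked example: GGCTAGGG vs YTAR -> one site at [2, 6)
  s <- find_motif_sites("GGCTAGGG", "YTAR")
  expect_equal(s$start, 2L)
  expect_equal(s$end, 6L)

  # NNNN matches every window
  expect_equal(nrow(find_motif_sites(strrep("A", 10), "NNNN")), 7L)

  # YTAR is its own reverse complement: both_strands adds nothing
  set.seed(8)
  x <- random_dna(500)
  expect_equal(find_motif_sites(x, "YTAR"),
               find_motif_sites(x, "YTAR", both_strands = TRUE))

  expect_error(find_motif_sites(x, "YTXR"), "invalid IUPAC")

  # oracle equivalence over random sequences and motifs
  for (pat in c("NRAWWWWN", "YTAR", "NRCWNWRYN", "RYSWKM")) {
    for (rep in 1:10) {
      y <- random_dna(300)
      expect_equal(find_motif_sites(y, pat)$start,
                   oracle_iupac_sites(y, pat), ignore_attr = TRUE)
    }
  }

  # an N in the subject never matches, even against pattern N
  expect_equal(nrow(find_motif_sites("ACGNACG", "NNN")), 2L)  # ACG, ACG only
})

test_that("both-strands motif scan reports reverse-complement sites", {
  # NRAWWWWN is not strand-symmetric; plant a reverse-complement match
  pat <- "NRAWWWWN"
  set.seed(9)
  core <- sample_from_iupac(pat, 1)
  x <- paste0(strrep("C", 40), revcomp(core), strrep("C", 40))
  expect_equal(nrow(find_motif_sites(x, pat)), 0L)
  both <- find_motif_sites(x, pat, both_strands = TRUE)
  # the planted window is reported on -; W-runs allow a shifted match or
  # two, but all hits here are reverse-strand
  expect_true(any(both$start == 40L & both$strand == "-"))
  expect_true(all(both$strand == "-"))
})

test_that("repeat windows flag duplicated k-mers, optionally revcomp", {
  set.seed(10)
  u <- random_dna(12)
  x <- paste0(random_dna(40), u, random_dna(40), u, random_dna(40))
  w <- find_repeat_windows(x, 10)
  expect_gte(nrow(w), 6L)  # 3 windows per 12 bp copy, 2 copies
  expect_true(all(vapply(seq_len(nrow(w)), function(i)
    substr(x, w$start[i] + 1, w$end[i]) == w$kmer[i], logical(1))))

  y <- paste0(random_dna(40), u, random_dna(40), revcomp(u), random_dna(40))
  expect_equal(nrow(find_repeat_windows(y, 10)), 0L)
  expect_gte(nrow(find_repeat_windows(y, 10, include_revcomp = TRUE)), 6L)

  expect_equal(nrow(find_repeat_windows(random_dna(8), 10)), 0L)
})

test_that("a clean CDS is returned unchanged (idempotence)", {
  cds <- gc_only_cds(60, seed = 14)
  r <- recode_cds(cds, c("NRAWWWWN", "YTAR", "NRCWNWRYN"), min_repeat = 10)
  expect_identical(r$sequence, cds)
  expect_length(r$changed_codons, 0L)
  expect_equal(nrow(r$residual_motif_sites), 0L)
  expect_equal(nrow(r$residual_repeats), 0L)
})

test_that("a single planted motif is removed with one codon change", {
  # GC-only toy: the planted Leu codon CTA followed by G is the only YTAR
  # match and the only offense
  base <- gc_only_cds(60, seed = 15)
  codons <- substring(base, 3 * (1:60) - 2, 3 * (1:60))
  codons[30] <- "CTA"                      # CTA + G... -> CTAG, matches YTAR
  cds <- paste(codons, collapse = "")
  stopifnot(substr(cds, 90, 91) == "AG")   # next codon starts with G or C
  motifs <- c("NRAWWWWN", "YTAR", "NRCWNWRYN")
  sites <- find_motif_sites(cds, "YTAR")
  expect_equal(nrow(sites), 1L)

  r <- recode_cds(cds, motifs, min_repeat = 10, seed = 3)
  expect_equal(nrow(r$residual_motif_sites), 0L)
  expect_equal(nrow(r$residual_repeats), 0L)
  expect_equal(translate_oracle(r$sequence), translate_oracle(cds))

  # brute-force oracle: enumerate all synonymous variants of the codons
  # overlapping the site and confirm 1 change suffices - and that the
  # recoder used the minimum
  cix <- unique((sites$start[1]:(sites$end[1] - 1)) %/% 3 + 1)
  code <- Biostrings::GENETIC_CODE
  syn <- split(names(code), code)
  one_change_works <- FALSE
  for (i in cix) {
    for (alt in setdiff(syn[[unname(code[codons[i]])]], codons[i])) {
      cand <- codons; cand[i] <- alt
      cand_seq <- paste(cand, collapse = "")
      tot <- nrow(find_motif_sites(cand_seq, "YTAR")) +
        nrow(find_motif_sites(cand_seq, "NRAWWWWN")) +
        nrow(find_motif_sites(cand_seq, "NRCWNWRYN")) +
        nrow(find_repeat_windows(cand_seq, 10))
      if (tot == 0) one_change_works <- TRUE
    }
  }
  expect_true(one_change_works)
  expect_equal(length(r$changed_codons), 1L)
})

test_that("tandem duplications >= min_repeat are eliminated", {
  set.seed(16)
  u <- random_dna(12)
  # embed an exact 12 bp tandem duplication inside a random CDS
  cds <- random_cds(80, seed = 16)
  mid <- paste0(u, u)
  cds2 <- paste0(substr(cds, 1, 120), mid, substr(cds, 145, nchar(cds)))
  # fixture checked: length 240 (multiple of 3), no internal stop under seed 16
  expect_equal(nchar(cds2) %% 3, 0L)
  r <- recode_cds(cds2, "YTAR", min_repeat = 10, seed = 1)
  expect_equal(nrow(find_repeat_windows(r$sequence, 10)), 0L)
  expect_equal(translate_oracle(r$sequence), translate_oracle(cds2))
})

test_that("recode validates its input contract", {
  expect_error(recode_cds("ATGAA", "YTAR"), "multiple of 3")
  expect_error(recode_cds("ATGTAAAAATTT", "YTAR"), "internal stop")
  expect_error(recode_cds("ATGNNNAAATAA", "YTAR"), "non-ACGT")
  expect_error(recode_cds(random_cds(20, 1), character(0)), "nonempty")
})

test_that("recoding preserves the protein on random CDSs", {
  motifs <- c("NRAWWWWN", "YTAR", "NRCWNWRYN")
  for (seed in 1:5) {
    cds <- random_cds(100, seed = seed)
    r <- recode_cds(cds, motifs, min_repeat = 10, seed = seed)
    expect_equal(nchar(r$sequence), nchar(cds))
    expect_equal(translate_oracle(r$sequence), translate_oracle(cds))
    # start and stop codons are untouched
    expect_equal(substr(r$sequence, 1, 3), substr(cds, 1, 3))
    expect_equal(substr(r$sequence, nchar(cds) - 2, nchar(cds)),
                 substr(cds, nchar(cds) - 2, nchar(cds)))
    # recoding the output again changes nothing (fixpoint)
    r2 <- recode_cds(r$sequence, motifs, min_repeat = 10, seed = seed)
    if (nrow(r$residual_motif_sites) == 0 && nrow(r$residual_repeats) == 0)
      expect_identical(r2$sequence, r$sequence)
  }
})
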