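# Independent brute-force oracles and fixture builders. The oracles share no
# code with the implementation paths they check: matching is done by direct
# substring comparison and positionwise lookup tables defined here.

rc_oracle <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K")
  paste(rev(map[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# all exact full-length occurrences of each catalog element, by comparing
# the element to every offset of every target on both strands
oracle_find_copies <- function(catalog, targets) {
  rows <- list()
  for (sid in names(targets)) {
    tseq <- toupper(targets[[sid]])
    tlen <- nchar(tseq)
    for (e in catalog) {
      L <- e$length
      if (L > tlen) next
      for (off in 0:(tlen - L)) {
        win <- substr(tseq, off + 1, off + L)
        if (win == e$sequence)
          rows[[length(rows) + 1]] <- data.frame(
            element_name = e$name, seq_id = sid, start = off, end = off + L,
            strand = "+", stringsAsFactors = FALSE)
        if (win == rc_oracle(e$sequence))
          rows[[length(rows) + 1]] <- data.frame(
            element_name = e$name, seq_id = sid, start = off, end = off + L,
            strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_name = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  out[order(out$seq_id, out$start, out$element_name, out$strand), ,
      drop = FALSE]
}

# longest k in [k_min, k_max] with identical flanking k-mers, by direct
# substring comparison over every k
oracle_call_tsd <- function(tseq, s, e, k_min = 4, k_max = 25) {
  best <- 0L
  for (k in k_min:k_max) {
    if (s - k < 0 || e + k > nchar(tseq)) next
    up <- substr(tseq, s - k + 1, s)
    down <- substr(tseq, e + 1, e + k)
    if (up == down && !grepl("[^ACGT]", up)) best <- k
  }
  best
}

# positionwise IUPAC matcher with its own lookup table
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_sites <- function(seq, pattern) {
  seq <- toupper(seq); pattern <- toupper(pattern)
  w <- nchar(pattern)
  pb <- strsplit(pattern, "")[[1]]
  sb <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  if (nchar(seq) >= w) for (off in 0:(nchar(seq) - w)) {
    ok <- TRUE
    for (j in seq_len(w))
      if (!sb[off + j] %in% ORACLE_IUPAC[[pb[j]]]) { ok <- FALSE; break }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# draw a random sequence matching an IUPAC pattern (uniform over each
# position's allowed set)
sample_from_iupac <- function(pattern, n = 1) {
  pb <- strsplit(toupper(pattern), "")[[1]]
  vapply(seq_len(n), function(i)
    paste(vapply(pb, function(ch) sample(ORACLE_IUPAC[[ch]], 1),
                 character(1)), collapse = ""), character(1))
}

# --- fixtures --------------------------------------------------------------

# a two-element catalog shaped like IS1 (768 bp, canonical 8/9) and IS10
# (1329 bp, canonical 9); sequences are random but fixed by seed
make_test_catalog <- function(seed = 99) {
  set.seed(seed)
  is_catalog(list(
    is_element("IS1tst", "IS1", random_dna(768), c(8, 9), "NRAWWWWN"),
    is_element("IS10tst", "IS10", random_dna(1329), 9, "NRCWNWRYN")))
}

# GC-only 200ish-codon CDS (Gly/Ala/Arg/Pro codons over G/C letters) with no
# duplicated >= min_repeat window, so planted motifs are the only offenses
gc_only_cds <- function(n_codons, seed, min_repeat = 10) {
  gc_codons <- c("GGG", "GGC", "GCG", "GCC", "CGG", "CGC", "CCG", "CCC")
  set.seed(seed)
  repeat {
    cds <- paste(c("ATG", sample(gc_codons, n_codons - 1, replace = TRUE)),
                 collapse = "")
    if (nrow(isbreach::find_repeat_windows(cds, min_repeat)) == 0) return(cds)
  }
}

# random CDS of sense codons: ATG + random sense + TAA
random_cds <- function(n_codons, seed) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  set.seed(seed)
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

translate_oracle <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "error"))
}
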