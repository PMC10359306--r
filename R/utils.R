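# Low-level sequence helpers shared by every stage. All sequences are plain
# uppercase character scalars over ACGT (plus N in targets); all internal
# coordinates are 0-based half-open, converted to 1-based inclusive only at
# file boundaries.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy sets; N deliberately maps to ACGT only, so an N in a
# subject sequence never satisfies any pattern position (assembly gaps must
# not create motif or repeat matches).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Complements IUPAC degeneracy codes as well as ACGT, so it can be applied
#' to motifs ("YTAR" is its own reverse complement) and to targets with Ns.
#'
#' @param x Character scalar (or vector) of DNA.
#' @return Character of the same length, reverse-complemented.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Fraction of G or C bases
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  vapply(toupper(x), function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(b) == 0L) return(NA_real_)
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Random DNA string at a stated GC content
#'
#' Draws bases i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#' Uses the current RNG state; seed outside.
#'
#' @param n Length in bp.
#' @param gc Target GC fraction (default 0.5).
#' @return Character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# substring with 0-based half-open coordinates
subseq0 <- function(x, start, end) substr(x, start + 1L, end)

seq_len0 <- function(x) nchar(x)

# validate a DNA alphabet; returns index of first offending char or 0L
first_non_acgt <- function(x, allow = DNA_BASES) {
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!b %in% allow)
  if (length(bad)) bad[1] else 0L
}

is_iupac <- function(pattern) {
  b <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  length(b) > 0L && all(b %in% names(IUPAC_SETS))
}

# translate an IUPAC pattern to a regex of character classes; subject N never
# matches because no class contains N
iupac_regex <- function(pattern) {
  b <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (!all(b %in% names(IUPAC_SETS)))
    stop("invalid IUPAC letter(s) in pattern: ",
         paste(unique(b[!b %in% names(IUPAC_SETS)]), collapse = ", "))
  paste(vapply(b, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# does `x` (ACGTN string, length == nchar(pattern)) satisfy the IUPAC pattern
# positionwise? Ns in x never match.
iupac_match <- function(x, pattern) {
  x <- toupper(x)
  if (nchar(x) != nchar(pattern)) return(FALSE)
  grepl(paste0("^", iupac_regex(pattern), "$"), x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
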