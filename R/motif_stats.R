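# TSD motif statistics: position frequency matrices over equal-length TSD
# sets, IUPAC consensus reduction, Pearson comparison of motifs, and
# GC-content / length-mixture summaries. PFMs carry plain frequencies with
# no pseudocounts; correlations are computed on the flattened 4k frequency
# vectors.

#' Build a position frequency matrix from equal-length TSDs
#'
#' `freq[b, i]` is the fraction of sequences with base b at position i; no
#' pseudocounts. Mixed lengths are an error: TSD sets must be pre-clustered
#' by element type and duplication length before motif building.
#'
#' @param tsds Character vector of equal-length DNA strings over ACGT.
#' @return A `pfm` object: 4 x k numeric matrix (rows A, C, G, T) with
#'   attributes `k` and `n`.
#' @export
build_pfm <- function(tsds) {
  if (length(tsds) == 0L) stop("no sequences")
  tsds <- toupper(tsds)
  lens <- nchar(tsds)
  if (length(unique(lens)) != 1L)
    stop("mixed TSD lengths (", paste(sort(unique(lens)), collapse = ", "),
         "); pre-cluster by IS type and TSD length before building a PFM")
  k <- lens[1]
  bad <- vapply(tsds, first_non_acgt, integer(1), USE.NAMES = FALSE)
  if (any(bad > 0L))
    stop("non-ACGT character in TSD ", which(bad > 0L)[1])
  m <- do.call(rbind, strsplit(tsds, "", fixed = TRUE))
  freq <- vapply(seq_len(k), function(i) {
    tab <- table(factor(m[, i], levels = DNA_BASES))
    as.numeric(tab) / length(tsds)
  }, numeric(4))
  freq <- matrix(freq, nrow = 4, dimnames = list(DNA_BASES, NULL))
  structure(freq, k = as.integer(k), n = length(tsds), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm: k = %d, n = %d>\n", attr(x, "k"), attr(x, "n")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Pearson correlation between two PFMs
#'
#' The two matrices are flattened to 4k-vectors of frequencies and compared
#' with Pearson's r. Motifs are comparable only within a length class;
#' differing k is an error, as is a zero-variance (uniform) matrix for
#' which the correlation is undefined.
#'
#' @param a,b `pfm` objects with equal `k`.
#' @return Correlation in \[-1, 1\].
#' @export
pfm_pearson <- function(a, b) {
  if (attr(a, "k") != attr(b, "k"))
    stop("PFMs have different lengths (k = ", attr(a, "k"), " vs ",
         attr(b, "k"), "); motifs are comparable only within a length class")
  va <- as.numeric(a); vb <- as.numeric(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance: correlation undefined for a uniform PFM")
  if (identical(va, vb)) return(1)  # self-correlation is exactly 1
  stats::cor(va, vb)
}

# two-base IUPAC codes for consensus reduction
PAIR_CODES <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")

#' Reduce a PFM to an IUPAC consensus string
#'
#' Per column: the single base if its frequency is at least `major`; the
#' two-base code (R/Y/S/W/K/M) if the top two bases jointly reach `pair`;
#' otherwise N.
#'
#' @param pfm A `pfm` object.
#' @param major Single-base threshold (default 0.75).
#' @param pair Two-base joint threshold (default 0.9).
#' @return IUPAC string of length k.
#' @export
consensus_iupac <- function(pfm, major = 0.75, pair = 0.9) {
  stopifnot(major > 0.5, major <= 1, pair > 0.5, pair <= 1)
  k <- attr(pfm, "k")
  out <- character(k)
  for (i in seq_len(k)) {
    col <- pfm[, i]
    ord <- order(col, decreasing = TRUE)
    if (col[ord[1]] >= major) {
      out[i] <- DNA_BASES[ord[1]]
    } else if (col[ord[1]] + col[ord[2]] >= pair) {
      pr <- paste(sort(DNA_BASES[ord[1:2]]), collapse = "")
      out[i] <- PAIR_CODES[[pr]]
    } else out[i] <- "N"
  }
  paste(out, collapse = "")
}

#' Length-mixture and GC summary of a TSD collection
#'
#' Reports the proportion of each duplication length, the per-TSD GC
#' fractions, and (when a two-level `groups` factor is given) a two-sided
#' two-sample t comparison of GC between groups — Welch by default, pooled
#' variance with `var_equal = TRUE`.
#'
#' @param tsds Character vector of TSD sequences.
#' @param groups Optional factor/character of length `length(tsds)` with
#'   exactly two levels.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return List of class `tsd_summary`: `length_proportions` (named,
#'   sums to 1), `gc_values`, and optionally `group_comparison` with
#'   `t`, `p_value`, `group_means`.
#' @export
tsd_summary <- function(tsds, groups = NULL, var_equal = FALSE) {
  if (length(tsds) == 0L) stop("no sequences")
  lens <- nchar(tsds)
  prop <- table(lens) / length(lens)
  gc <- gc_fraction(tsds)
  out <- list(length_proportions = stats::setNames(as.numeric(prop),
                                                   names(prop)),
              gc_values = gc, group_comparison = NULL)
  if (!is.null(groups)) {
    g <- factor(groups)
    if (nlevels(g) != 2L)
      stop("groups must have exactly two levels")
    if (min(table(g)) < 2L) {
      warning("a group has fewer than 2 members; comparison omitted")
    } else {
      tt <- stats::t.test(gc ~ g, var.equal = var_equal,
                          alternative = "two.sided")
      out$group_comparison <- list(t = unname(tt$statistic),
                                   p_value = tt$p.value,
                                   group_means = tapply(gc, g, mean))
    }
  }
  class(out) <- "tsd_summary"
  out
}

#' @export
print.tsd_summary <- function(x, ...) {
  cat("<tsd_summary>\n length proportions:\n")
  print(x$length_proportions)
  cat(sprintf(" GC: mean %.3f over %d TSDs\n",
              mean(x$gc_values), length(x$gc_values)))
  if (!is.null(x$group_comparison))
    cat(sprintf(" group t = %.3f, p = %.3g\n",
                x$group_comparison$t, x$group_comparison$p_value))
  invisible(x)
}

#' Export a PFM as JASPAR-like text or JSON
#'
#' The text layout is one row per base, `A  [ n1 n2 ... ]`, with
#' frequencies rather than counts.
#'
#' @param pfm A `pfm` object.
#' @param path Output path.
#' @param name Motif name written in the header line.
#' @param format "jaspar" or "json".
#' @return Invisibly, the path.
#' @export
write_pfm <- function(pfm, path, name = "motif", format = c("jaspar", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(name = name, k = attr(pfm, "k"),
                              n = attr(pfm, "n"),
                              freq = apply(unclass(pfm), 1, identity,
                                           simplify = FALSE)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- c(paste0(">", name),
               vapply(DNA_BASES, function(b)
                 sprintf("%s  [ %s ]", b,
                         paste(format(pfm[b, ], digits = 6),
                               collapse = " ")), character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
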