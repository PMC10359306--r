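# Exact full-length IS detection: the 100% identity / 100% coverage
# retention rule. Matching is literal string matching on both strands via
# Biostrings::matchPattern(fixed = TRUE), so an N in a target can never be
# part of a hit.

#' Find every exact full-length occurrence of catalog elements
#'
#' Scans both strands of each target for literal, full-length copies of each
#' element (100% identity, 100% coverage). Overlapping hits are all
#' reported; order is deterministic by (seq_id, start, element_name, strand).
#'
#' @param catalog An [is_catalog()].
#' @param targets Named character vector of target sequences (see
#'   [load_targets()]).
#' @param circular If TRUE, each target is virtually extended by its first
#'   `L - 1` bases (L = longest element) so hits spanning the origin of a
#'   circular replicon are found; their start coordinates stay in
#'   `[0, target_length)`.
#' @return A `data.frame` of hits: `element_name`, `seq_id`, `start`, `end`
#'   (0-based half-open on the + strand), `strand`, `target_length`. An
#'   empty result is valid.
#' @export
find_exact_copies <- function(catalog, targets, circular = FALSE) {
  stopifnot(inherits(catalog, "ISCatalog"))
  if (length(targets) == 0L) stop("targets must be nonempty")
  if (is.null(names(targets)))
    names(targets) <- paste0("seq", seq_along(targets))
  targets <- chartr("U", "T", toupper(targets))
  rows <- list()
  for (sid in names(targets)) {
    tseq <- targets[[sid]]
    tlen <- nchar(tseq)
    scan_seq <- tseq
    if (circular) {
      ext <- max(vapply(catalog, function(e) e$length, integer(1))) - 1L
      scan_seq <- paste0(tseq, substr(tseq, 1L, min(ext, tlen)))
    }
    subject <- Biostrings::DNAString(scan_seq)
    for (e in catalog) {
      for (std in c("+", "-")) {
        pat <- if (std == "+") e$sequence else revcomp(e$sequence)
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                      fixed = TRUE)
        if (length(m) == 0L) next
        s0 <- Biostrings::start(m) - 1L
        keep <- s0 < tlen            # de-duplicate circular wrap copies
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          element_name = e$name, seq_id = sid,
          start = s0[keep], end = s0[keep] + e$length,
          strand = std, target_length = tlen, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_name = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               target_length = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$element_name, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the upstream and downstream flanks of an interval
#'
#' Returns the `up` bases immediately 5' of `start` and the `down` bases
#' immediately 3' of `end`, always on the + strand (TSDs are duplications of
#' target DNA, defined in the target's frame). Set `orient_by_strand = TRUE`
#' to reorient both flanks by the hit strand instead.
#'
#' @param target_sequence Target DNA string.
#' @param start,end 0-based half-open interval of the element.
#' @param up,down Flank lengths in bp (>= 0).
#' @param strand Hit strand, used only when `orient_by_strand` is TRUE.
#' @param orient_by_strand Reverse-complement and swap the flanks for "-"
#'   strand hits.
#' @return List with `upstream`, `downstream`, and logical `truncated`
#'   (TRUE when either window ran past a sequence boundary and was clipped).
#' @export
extract_flanks <- function(target_sequence, start, end, up, down,
                           strand = "+", orient_by_strand = FALSE) {
  tlen <- nchar(target_sequence)
  stopifnot(up >= 0, down >= 0)
  if (start < 0L || end > tlen || start >= end)
    stop("interval [", start, ", ", end, ") outside sequence of length ", tlen)
  u0 <- max(0L, start - as.integer(up))
  d1 <- min(tlen, end + as.integer(down))
  res <- list(upstream = subseq0(target_sequence, u0, start),
              downstream = subseq0(target_sequence, end, d1),
              truncated = (start - up < 0L) || (end + down > tlen))
  if (orient_by_strand && strand == "-") {
    res <- list(upstream = revcomp(res$downstream),
                downstream = revcomp(res$upstream),
                truncated = res$truncated)
  }
  res
}

#' Write IS hits as TSV (1-based inclusive coordinates)
#'
#' @param hits Result of [find_exact_copies()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(element = hits$element_name, seq_id = hits$seq_id,
                    start_1based = hits$start + 1L, end_1based = hits$end,
                    strand = hits$strand, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write IS hits as BED6
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param hits Result of [find_exact_copies()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hits_bed <- function(hits, path) {
  lines <- if (nrow(hits)) paste(hits$seq_id, hits$start, hits$end,
                                 hits$element_name, 0L, hits$strand,
                                 sep = "\t") else character(0)
  writeLines(lines, path)
  invisible(path)
}
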