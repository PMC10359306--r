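# CRISPR spacer -> protospacer matching at 100% identity / 100% coverage,
# with optional PAM checking. The PAM rule is expressed in protospacer-local
# orientation (IUPAC string + side), so a type I-E 5' AAG and a Cas9-style
# 3' NGG are both representable.

#' Match spacers against candidate target sequences
#'
#' Reports every exact, full-length occurrence of each spacer on both
#' strands of each target. When a PAM rule is supplied, the adjacent window
#' on the stated side (in protospacer orientation) is extracted and tested
#' against the IUPAC pattern; matches whose PAM window is truncated by a
#' sequence end get `pam_ok = FALSE` with note "truncated". PAM checking
#' never filters matches — it is reported alongside them.
#'
#' @param spacers Named character vector of spacer sequences (>= 20 nt,
#'   ACGT only).
#' @param targets Named character vector of target replicons.
#' @param pam Optional list `list(motif = "AAG", side = "5prime")` with
#'   `side` one of "5prime"/"3prime".
#' @return `data.frame`: `spacer_id`, `target_seq_id`, `start`, `end`
#'   (0-based half-open, + strand), `strand`, and (with a PAM rule)
#'   `pam_observed`, `pam_ok`, `pam_note`.
#' @export
match_spacers <- function(spacers, targets, pam = NULL) {
  if (length(spacers) == 0L) stop("no spacers")
  if (is.null(names(spacers)))
    names(spacers) <- paste0("spacer", seq_along(spacers))
  spacers <- toupper(spacers)
  for (id in names(spacers)) {
    bad <- first_non_acgt(spacers[[id]])
    if (bad > 0L)
      stop(sprintf("spacer '%s': non-ACGT character at position %d", id, bad))
    if (nchar(spacers[[id]]) < 20L)
      stop(sprintf("spacer '%s': length %d < 20 nt", id,
                   nchar(spacers[[id]])))
  }
  if (!is.null(pam)) {
    stopifnot(is.list(pam), pam$side %in% c("5prime", "3prime"))
    if (!is_iupac(pam$motif)) stop("invalid PAM motif: ", pam$motif)
  }
  if (is.null(names(targets)))
    names(targets) <- paste0("seq", seq_along(targets))
  targets <- chartr("U", "T", toupper(targets))
  rows <- list()
  for (sid in names(targets)) {
    tseq <- targets[[sid]]
    subject <- Biostrings::DNAString(tseq)
    tlen <- nchar(tseq)
    for (id in names(spacers)) {
      sp <- spacers[[id]]
      L <- nchar(sp)
      for (std in c("+", "-")) {
        pat <- if (std == "+") sp else revcomp(sp)
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                      fixed = TRUE)
        if (length(m) == 0L) next
        s0 <- Biostrings::start(m) - 1L
        df <- data.frame(spacer_id = id, target_seq_id = sid,
                         start = s0, end = s0 + L, strand = std,
                         stringsAsFactors = FALSE)
        if (!is.null(pam)) {
          pw <- t(vapply(s0, function(s) pam_window(tseq, s, s + L, std, pam),
                         character(3)))
          df$pam_observed <- pw[, 1]
          df$pam_ok <- pw[, 2] == "TRUE"
          df$pam_note <- pw[, 3]
        }
        rows[[length(rows) + 1L]] <- df
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    base <- data.frame(spacer_id = character(0), target_seq_id = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), stringsAsFactors = FALSE)
    if (!is.null(pam)) {
      base$pam_observed <- character(0); base$pam_ok <- logical(0)
      base$pam_note <- character(0)
    }
    base
  }
  out <- out[order(out$target_seq_id, out$start, out$spacer_id, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# the PAM window adjacent to a protospacer, in protospacer orientation
pam_window <- function(tseq, s, e, strand, pam) {
  w <- nchar(pam$motif)
  tlen <- nchar(tseq)
  # protospacer 5' side is upstream on + strand matches, downstream on -
  upstream_side <- (pam$side == "5prime") == (strand == "+")
  if (upstream_side) {
    lo <- s - w; hi <- s
  } else {
    lo <- e; hi <- e + w
  }
  truncated <- lo < 0L || hi > tlen
  obs <- subseq0(tseq, max(0L, lo), min(tlen, hi))
  if (strand == "-") obs <- revcomp(obs)
  ok <- !truncated && iupac_match(obs, pam$motif)
  c(obs, as.character(ok), if (truncated) "truncated" else "")
}

#' Write protospacer matches as TSV (1-based inclusive coordinates)
#'
#' @param matches Result of [match_spacers()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_matches_tsv <- function(matches, path) {
  out <- data.frame(spacer_id = matches$spacer_id,
                    target = matches$target_seq_id,
                    start_1based = matches$start + 1L,
                    end_1based = matches$end, strand = matches$strand,
                    stringsAsFactors = FALSE)
  if ("pam_ok" %in% names(matches)) {
    out$pam_observed <- matches$pam_observed
    out$pam_ok <- matches$pam_ok
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
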