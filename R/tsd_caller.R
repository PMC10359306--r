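# Direct-repeat (target-site duplication) calling at IS boundaries. The
# fixed-length repeat patterns used for natural-genome scans (8/9 bp around
# a 768 bp element, 9 bp around a 1329 bp element) generalise here to a
# longest-k search over a length range, which also surfaces aberrant
# duplication lengths (7, 11, even 23 bp have been observed).

#' Call the target-site duplication flanking an IS hit
#'
#' Finds the largest k in `[k_min, k_max]` for which the k bases immediately
#' 5' of the element equal the k bases immediately 3' of it, compared
#' exactly on the + strand regardless of hit strand. Ns never match, so no
#' TSD is called across assembly gaps. k values whose window would run past
#' a sequence end are skipped (not errors).
#'
#' @param target_sequence Target DNA string.
#' @param hit One row of [find_exact_copies()] output (or any list with
#'   `start`, `end`, `strand`, `element_name`, `seq_id`).
#' @param k_min,k_max Repeat-length search range (defaults 4 and 25, which
#'   covers reported aberrant lengths of 7-23 bp).
#' @param canonical_set Integer vector of the element family's canonical TSD
#'   lengths, used for status classification.
#' @param canonical_only If TRUE, restrict the search to `canonical_set`
#'   (still longest-first), reproducing a fixed-length pattern scan exactly.
#' @return A one-row `data.frame`: element/hit identity columns, `k` (0 when
#'   no repeat), `tsd_sequence`, `up_start`, `up_end`, `down_start`,
#'   `down_end` (0-based half-open repeat copies), `status` (canonical /
#'   aberrant / none), and `p_random` = 4^-k, the chance of a random exact
#'   k-mer duplication at one boundary.
#' @export
call_tsd <- function(target_sequence, hit, k_min = 4L, k_max = 25L,
                     canonical_set = integer(0), canonical_only = FALSE) {
  stopifnot(k_min >= 1L, k_min <= k_max, k_max <= 30L)
  tlen <- nchar(target_sequence)
  s <- as.integer(hit$start); e <- as.integer(hit$end)
  if (s < 0L || e > tlen || s >= e)
    stop("hit interval [", s, ", ", e, ") invalid for target of length ", tlen)
  ks <- if (canonical_only) {
    sort(canonical_set[canonical_set >= k_min & canonical_set <= k_max],
         decreasing = TRUE)
  } else seq(k_max, k_min)
  k_found <- 0L; tsd <- ""
  for (k in ks) {
    if (s - k < 0L || e + k > tlen) next
    up <- subseq0(target_sequence, s - k, s)
    down <- subseq0(target_sequence, e, e + k)
    if (up == down && first_non_acgt(up) == 0L) {
      k_found <- as.integer(k); tsd <- up
      break
    }
  }
  status <- classify_tsd(k_found, canonical_set)
  data.frame(element_name = hit$element_name %||% NA_character_,
             seq_id = hit$seq_id %||% NA_character_,
             start = s, end = e, strand = hit$strand %||% "+",
             k = k_found, tsd_sequence = tsd,
             up_start = if (k_found) s - k_found else NA_integer_,
             up_end = if (k_found) s else NA_integer_,
             down_start = if (k_found) e else NA_integer_,
             down_end = if (k_found) e + k_found else NA_integer_,
             status = status, p_random = 4^(-k_found),
             stringsAsFactors = FALSE)
}

#' Classify a TSD length as canonical, aberrant or none
#'
#' @param k Called duplication length (0 = no repeat).
#' @param canonical_set The element family's characteristic lengths
#'   (e.g. 8 and 9 bp for IS1, 9 bp for IS10).
#' @return "canonical", "aberrant", or "none".
#' @export
classify_tsd <- function(k, canonical_set) {
  if (k == 0L) "none"
  else if (k %in% canonical_set) "canonical"
  else "aberrant"
}

#' Call TSDs for a whole hit table
#'
#' Applies [call_tsd()] to every row of a hit table, pulling each element's
#' canonical length set from the catalog.
#'
#' @param targets Named character vector of target sequences.
#' @param hits [find_exact_copies()] output.
#' @param catalog The [is_catalog()] the hits came from.
#' @inheritParams call_tsd
#' @return A `data.frame` with one [call_tsd()] row per hit.
#' @export
call_tsds <- function(targets, hits, catalog, k_min = 4L, k_max = 25L,
                      canonical_only = FALSE) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    call_tsd(targets[[h$seq_id]], h, k_min = k_min, k_max = k_max,
             canonical_set = catalog[[h$element_name]]$canonical_tsd_lengths,
             canonical_only = canonical_only)
  })
  if (length(rows)) do.call(rbind, rows) else
    call_tsd("ACGT", list(start = 0, end = 4, strand = "+"),
             k_min = 1, k_max = 1)[0, ]
}

#' Write TSD calls as TSV (1-based inclusive element coordinates)
#'
#' @param calls Result of [call_tsds()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tsd_tsv <- function(calls, path) {
  out <- data.frame(element = calls$element_name, seq_id = calls$seq_id,
                    element_start_1based = calls$start + 1L,
                    element_end_1based = calls$end,
                    strand = calls$strand, k = calls$k,
                    tsd_sequence = calls$tsd_sequence, status = calls$status,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
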