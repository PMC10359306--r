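# Synonymous recoding of coding sequences to remove IS target-site motifs
# (e.g. NRAWWWWN for IS1's 8 bp sites, YTAR for IS5, NRCWNWRYN for IS10)
# and all exact internal repeats >= a length threshold, under codon
# degeneracy. The protein is invariant; elimination is greedy,
# deterministic given the seed, and reports residuals honestly when no
# synonymous escape exists.

#' Find all matches of an IUPAC pattern in a sequence
#'
#' Positionwise degenerate matching: a subject base satisfies a pattern
#' letter iff it is in that letter's IUPAC set. Overlapping matches are all
#' reported. An N in the subject never matches (no pattern letter's set
#' contains N), so assembly gaps cannot create sites. With `both_strands`,
#' windows whose reverse complement satisfies the pattern are also reported
#' (as + strand intervals).
#'
#' @param sequence Subject DNA string.
#' @param iupac_pattern Pattern over the IUPAC alphabet.
#' @param both_strands Also match the reverse complement of the pattern.
#' @return `data.frame` with `start`, `end` (0-based half-open) and
#'   `strand`, sorted and unique by interval.
#' @export
find_motif_sites <- function(sequence, iupac_pattern, both_strands = FALSE) {
  sequence <- toupper(sequence)
  scan1 <- function(pat, std) {
    m <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), sequence,
                  perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + nchar(pat),
               strand = std, stringsAsFactors = FALSE)
  }
  out <- scan1(iupac_pattern, "+")
  if (both_strands) {
    rcpat <- revcomp(iupac_pattern)
    if (rcpat != toupper(iupac_pattern))   # palindromic patterns add nothing
      out <- rbind(out, scan1(rcpat, "-"))
  }
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- unique(out[order(out$start, out$end, out$strand), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Find windows of exact internal repeats
#'
#' Reports every `min_repeat`-length window whose sequence occurs at least
#' twice in the input (optionally counting reverse-complement copies). Any
#' exact repeat of length >= `min_repeat` necessarily contains such
#' windows, so a sequence with no flagged window has no repeat >= the
#' threshold.
#'
#' @param sequence DNA string.
#' @param min_repeat Threshold length in bp (>= 4).
#' @param include_revcomp Count a window and its reverse complement as
#'   copies of each other.
#' @return `data.frame` with `start`, `end`, `kmer` for each offending
#'   window.
#' @export
find_repeat_windows <- function(sequence, min_repeat = 10L,
                                include_revcomp = FALSE) {
  stopifnot(min_repeat >= 4L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  k <- as.integer(min_repeat)
  empty <- data.frame(start = integer(0), end = integer(0),
                      kmer = character(0), stringsAsFactors = FALSE)
  if (L < 2L * k) {
    if (L < k + 1L) return(empty)  # cannot hold two distinct copies? still check overlaps below
  }
  n <- L - k + 1L
  if (n < 2L) return(empty)
  kmers <- substring(sequence, 1:n, k:L)
  valid <- !grepl("[^ACGT]", kmers)
  counts <- table(kmers[valid])
  dup <- names(counts)[counts >= 2L]
  flag <- valid & kmers %in% dup
  if (include_revcomp) {
    rc <- revcomp(kmers[valid])
    flag[valid] <- flag[valid] | rc %in% names(counts)
  }
  if (!any(flag)) return(empty)
  idx <- which(flag)
  data.frame(start = idx - 1L, end = idx - 1L + k, kmer = kmers[idx],
             stringsAsFactors = FALSE)
}

# synonymous codon sets under a genetic code (Biostrings names the standard
# one GENETIC_CODE; others by id through getGeneticCode)
get_code <- function(codon_table = "Standard") {
  if (identical(codon_table, "Standard") || identical(codon_table, "1"))
    Biostrings::GENETIC_CODE
  else Biostrings::getGeneticCode(codon_table)
}

syn_sets <- function(code) split(names(code), code)

translate_cds <- function(codons, code) paste(code[codons], collapse = "")

# all offending intervals of a CDS under a recode spec
offense_table <- function(seq, motifs, min_repeat, both_strands,
                          repeat_revcomp) {
  mo <- do.call(rbind, lapply(motifs, function(p) {
    s <- find_motif_sites(seq, p, both_strands = both_strands)
    if (nrow(s)) cbind(s, type = "motif", what = p) else NULL
  }))
  rp <- find_repeat_windows(seq, min_repeat, include_revcomp = repeat_revcomp)
  if (nrow(rp))
    rp <- data.frame(start = rp$start, end = rp$end, strand = "+",
                     type = "repeat", what = rp$kmer,
                     stringsAsFactors = FALSE)
  else rp <- NULL
  out <- rbind(mo, rp)
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), type = character(0),
                      what = character(0), stringsAsFactors = FALSE))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recode a CDS to remove target-site motifs and internal repeats
#'
#' Greedy, seeded, passes-until-fixpoint elimination: each pass locates
#' every motif site and every duplicated window >= `min_repeat`, then walks
#' them left to right trying synonymous codon substitutions (single codons
#' first, preferring the fewest base changes; bounded multi-codon
#' combinations as a fallback) that strictly reduce the global offense
#' count. The start and stop codons are never altered. If a site survives
#' all options it is reported as a residual rather than silently kept.
#'
#' @param cds DNA string; length divisible by 3, no internal stop codons.
#' @param motifs Character vector of IUPAC motifs to eliminate.
#' @param min_repeat Repeat threshold in bp (default 10; >= 4).
#' @param codon_table Genetic code: "Standard" or a
#'   [Biostrings::getGeneticCode()] id.
#' @param max_passes Maximum elimination passes (default 10).
#' @param seed Integer seed controlling tie-breaks among equally good
#'   substitutions.
#' @param both_strands Also eliminate motif matches on the reverse
#'   complement.
#' @param repeat_revcomp Count reverse-complement copies as repeats.
#' @param max_combos Cap on multi-codon combinations tried per stubborn
#'   site.
#' @return List of class `recode_result`: `sequence`, `changed_codons`
#'   (1-based codon indices), `residual_motif_sites`, `residual_repeats`,
#'   `passes`. Translation and length are preserved by construction.
#' @export
recode_cds <- function(cds, motifs, min_repeat = 10L,
                       codon_table = "Standard", max_passes = 10L,
                       seed = 1L, both_strands = FALSE,
                       repeat_revcomp = FALSE, max_combos = 4096L) {
  cds <- chartr("U", "T", toupper(cds))
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  bad <- first_non_acgt(cds)
  if (bad > 0L) stop("non-ACGT character at position ", bad)
  if (length(motifs) == 0L) stop("motifs must be nonempty")
  stopifnot(min_repeat >= 4L)
  code <- get_code(codon_table)
  nc <- nchar(cds) / 3L
  codons <- substring(cds, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  aas <- code[codons]
  if (any(aas[-nc] == "*"))
    stop("internal stop codon at codon ", which(aas[-nc] == "*")[1])
  syn <- syn_sets(code)
  protein <- unname(aas)
  # codons eligible for change: everything but the start codon and the
  # terminal codon (stop or last sense codon)
  mutable <- function(ix) ix[ix > 1L & ix < nc]

  set.seed(as.integer(seed))
  changed <- integer(0)
  offenses_of <- function(s) offense_table(s, motifs, min_repeat,
                                           both_strands, repeat_revcomp)
  cur <- paste(codons, collapse = "")

  codon_alternatives <- function(i) {
    alts <- setdiff(syn[[protein[i]]], codons[i])
    if (length(alts) == 0L) return(character(0))
    # fewest base changes first; seeded shuffle breaks ties reproducibly
    nd <- vapply(alts, function(a)
      sum(strsplit(a, "")[[1]] != strsplit(codons[i], "")[[1]]), integer(1))
    alts[order(nd, sample.int(length(alts)))]
  }

  apply_change <- function(i, alt) {
    codons[i] <<- alt
    cur <<- paste(codons, collapse = "")
    changed <<- union(changed, i)
  }

  n_off <- function(s) nrow(offenses_of(s))

  passes <- 0L
  repeat {
    passes <- passes + 1L
    off <- offenses_of(cur)
    if (nrow(off) == 0L || passes > max_passes) break
    progressed <- FALSE
    for (r in seq_len(nrow(off))) {
      site <- off[r, ]
      # the site may already be gone after earlier fixes this pass
      still <- offenses_of(cur)
      if (!any(still$start == site$start & still$end == site$end &
               still$type == site$type)) next
      base_count <- nrow(still)
      cix <- mutable(unique((site$start:(site$end - 1L)) %/% 3L + 1L))
      if (length(cix) == 0L) next
      fixed <- FALSE
      # single-codon substitutions
      for (i in cix) {
        for (alt in codon_alternatives(i)) {
          old <- codons[i]
          codons[i] <- alt
          cand <- paste(codons, collapse = "")
          if (n_off(cand) < base_count) {
            codons[i] <- old
            apply_change(i, alt)
            fixed <- TRUE; progressed <- TRUE
            break
          }
          codons[i] <- old
        }
        if (fixed) break
      }
      if (fixed) next
      # bounded multi-codon fallback over the site's codons
      alt_lists <- lapply(cix, function(i) c(codons[i], syn[[protein[i]]]))
      alt_lists <- lapply(alt_lists, unique)
      n_combo <- prod(lengths(alt_lists))
      if (n_combo > 1 && n_combo <= max_combos) {
        grid <- expand.grid(alt_lists, stringsAsFactors = FALSE)
        for (gi in seq_len(nrow(grid))) {
          cand_codons <- codons
          cand_codons[cix] <- unlist(grid[gi, ], use.names = FALSE)
          if (identical(cand_codons, codons)) next
          cand <- paste(cand_codons, collapse = "")
          if (n_off(cand) < base_count) {
            for (j in seq_along(cix))
              if (cand_codons[cix[j]] != codons[cix[j]])
                changed <- union(changed, cix[j])
            codons <- cand_codons
            cur <- cand
            fixed <- TRUE; progressed <- TRUE
            break
          }
        }
      }
    }
    if (!progressed) break
  }

  final_off <- offenses_of(cur)
  res <- structure(list(
    sequence = cur,
    changed_codons = sort(changed),
    residual_motif_sites = final_off[final_off$type == "motif", ,
                                     drop = FALSE],
    residual_repeats = final_off[final_off$type == "repeat", , drop = FALSE],
    passes = passes), class = "recode_result")
  stopifnot(nchar(res$sequence) == nchar(cds),
            translate_cds(substring(res$sequence,
                                    3L * seq_len(nc) - 2L,
                                    3L * seq_len(nc)), code) ==
              paste(protein, collapse = ""))
  res
}

#' @export
print.recode_result <- function(x, ...) {
  cat(sprintf(
    "<recode_result: %d codon(s) changed, %d residual motif site(s), %d residual repeat window(s), %d pass(es)>\n",
    length(x$changed_codons), nrow(x$residual_motif_sites),
    nrow(x$residual_repeats), x$passes))
  invisible(x)
}

#' Write a recode report as JSON
#'
#' @param result A [recode_cds()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_recode_json <- function(result, path) {
  jsonlite::write_json(list(changed_codons = result$changed_codons,
                            residual_motif_sites = result$residual_motif_sites,
                            residual_repeats = result$residual_repeats,
                            passes = result$passes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
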