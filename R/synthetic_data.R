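# Ground-truthed synthetic data: cas-like annotated loci, IS implants with
# controlled TSD length mixtures and motif-biased insertion sites, and
# detection metrics against the emitted truth table. Every random choice
# flows from the stated seed; identical seeds give byte-identical outputs.

#' Generate a random annotated locus
#'
#' A random sequence at the stated GC content carrying `n_genes`
#' non-overlapping CDS-like features with random strands, separated by
#' intergenic gaps. Valid ORF frames are not enforced (downstream stages
#' operate on intervals, not translation); features never overlap.
#'
#' @param n_genes Number of features.
#' @param gene_length_range Length range in bp, e.g. `c(300, 3000)`.
#' @param intergenic_range Gap range in bp between features (and at both
#'   ends).
#' @param gc Target GC fraction (default 0.5).
#' @param seed Integer seed.
#' @param seq_id Sequence identifier.
#' @param system_labels Optional character vector recycled over genes
#'   (e.g. "CRISPR-Cas"); NA entries leave the label unset.
#' @return List: `sequence` (string) and `genes` (a [gene_models()] table).
#' @export
generate_locus <- function(n_genes, gene_length_range = c(300L, 3000L),
                           intergenic_range = c(50L, 500L), gc = 0.5,
                           seed = 1L, seq_id = "locus1",
                           system_labels = NA_character_) {
  stopifnot(n_genes >= 1L, all(gene_length_range > 0L),
            all(intergenic_range >= 0L))
  set.seed(as.integer(seed))
  glens <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                  replace = TRUE)
  gaps <- sample(intergenic_range[1]:intergenic_range[2], n_genes + 1L,
                 replace = TRUE)
  total <- sum(glens) + sum(gaps)
  sequence <- random_dna(total, gc = gc)
  starts <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + glens[i]
  }
  labels <- rep_len(system_labels, n_genes)
  genes <- gene_models(seq_id = seq_id, start = starts, end = starts + glens,
                       strand = sample(c("+", "-"), n_genes, replace = TRUE),
                       gene_name = sprintf("gene%02d", seq_len(n_genes)),
                       system_label = labels)
  list(sequence = sequence, genes = genes, seq_id = seq_id)
}

#' Specification for a batch of IS implants
#'
#' @param element_name Catalog element to implant.
#' @param n_implants Number of implants.
#' @param k_distribution Named numeric: P(duplication length), summing
#'   to 1 — e.g. `c("9" = 0.78, "8" = 0.22)` for an IS1-like element.
#' @param site_motif Optional IUPAC string; insertion points are rejection-
#'   sampled until the k-mer at the point matches it.
#' @param strand_probability P(+ strand orientation) for the element.
#' @param seed Integer seed.
#' @return List of class `implant_spec`.
#' @export
implant_spec <- function(element_name, n_implants, k_distribution,
                         site_motif = NULL, strand_probability = 0.5,
                         seed = 1L) {
  p <- as.numeric(k_distribution)
  if (abs(sum(p) - 1) > 1e-9) stop("k_distribution must sum to 1")
  if (any(p < 0 | p > 1)) stop("k_distribution probabilities must be in [0,1]")
  if (is.null(names(k_distribution)))
    stop("k_distribution must be named by duplication length")
  if (!is.null(site_motif) && !is_iupac(site_motif))
    stop("invalid IUPAC site motif: ", site_motif)
  stopifnot(strand_probability >= 0, strand_probability <= 1, n_implants >= 1)
  structure(list(element_name = element_name,
                 n_implants = as.integer(n_implants),
                 k_distribution = stats::setNames(p, names(k_distribution)),
                 site_motif = site_motif,
                 strand_probability = strand_probability,
                 seed = as.integer(seed)),
            class = "implant_spec")
}

#' Implant IS copies into a sequence, with truth records
#'
#' For each implant a duplication length k is drawn from the spec's length
#' mixture, an insertion point is chosen uniformly (or by rejection
#' sampling against `site_motif` so the k-mer starting at the point matches
#' it), and the element — oriented by a strand draw — is inserted
#' immediately after that k-mer with a second copy of the k-mer appended,
#' so the k-mer flanks the element on both sides. The sequence grows by
#' exactly `element_length + k` per implant. Implants never land inside a
#' previously implanted element (or its TSD copies) unless `allow_nested`.
#' Gene coordinates are shifted/stretched through each insertion, and truth
#' records are emitted in final coordinate space.
#'
#' @param sequence Starting DNA string.
#' @param genes A [gene_models()] table for the sequence (may be empty).
#' @param catalog An [is_catalog()] containing `spec$element_name`.
#' @param spec An [implant_spec()].
#' @param allow_nested Permit insertion inside earlier implants.
#' @param max_tries Rejection-sampling budget per implant for motif-biased
#'   placement.
#' @return List: `sequence` (mutated), `genes` (coordinates updated),
#'   `truth` — `data.frame` with `element_name`, `seq_id`, `start`, `end`
#'   (element interval, final 0-based half-open coords), `insertion_point`
#'   (final coords, first base of the upstream TSD copy), `k`,
#'   `tsd_sequence`, `strand`, `disrupted_gene`.
#' @export
implant_elements <- function(sequence, genes, catalog, spec,
                             allow_nested = FALSE, max_tries = 10000L) {
  stopifnot(inherits(spec, "implant_spec"), inherits(catalog, "ISCatalog"))
  elt <- catalog[[spec$element_name]]
  if (is.null(elt)) stop("element not in catalog: ", spec$element_name)
  seq_id <- if (nrow(genes)) genes$seq_id[1] else "seq1"
  set.seed(spec$seed)
  ks <- as.integer(names(spec$k_distribution))
  occupied <- NULL  # intervals of implanted element+TSDs, current coords
  truth <- list()
  for (n in seq_len(spec$n_implants)) {
    L <- nchar(sequence)
    k <- ks[sample.int(length(ks), 1L, prob = spec$k_distribution)]
    strand <- if (stats::runif(1) <= spec$strand_probability) "+" else "-"
    p <- NA_integer_
    for (try in seq_len(max_tries)) {
      cand <- sample.int(L - k - 1L, 1L)  # 1..L-k-1, keeps nonempty flanks
      kmer <- subseq0(sequence, cand, cand + k)
      if (grepl("[^ACGT]", kmer)) next
      if (!allow_nested && !is.null(occupied) &&
          any(cand < occupied$end & cand + k > occupied$start)) next
      if (!is.null(spec$site_motif) &&
          !iupac_match(kmer, rep_motif(spec$site_motif, k))) next
      p <- cand
      break
    }
    if (is.na(p))
      stop("no insertion site found after ", max_tries,
           " draws; a looser site motif may be needed (implant ", n, ")")
    kmer <- subseq0(sequence, p, p + k)
    ins <- if (strand == "+") elt$sequence else revcomp(elt$sequence)
    sequence <- paste0(subseq0(sequence, 0L, p + k), ins, kmer,
                       subseq0(sequence, p + k, nchar(sequence)))
    delta <- elt$length + k
    # shift downstream coordinates (genes, occupied intervals, prior truth)
    shift_at <- p + k  # first inserted base
    if (nrow(genes)) {
      # genes spanning the insertion stretch; downstream genes shift
      genes$end <- ifelse(genes$end > shift_at, genes$end + delta, genes$end)
      genes$start <- ifelse(genes$start >= shift_at, genes$start + delta,
                            genes$start)
    }
    if (!is.null(occupied)) {
      occupied$start <- ifelse(occupied$start >= shift_at,
                               occupied$start + delta, occupied$start)
      occupied$end <- ifelse(occupied$end > shift_at,
                             occupied$end + delta, occupied$end)
    }
    if (length(truth)) for (i in seq_along(truth)) {
      if (truth[[i]]$insertion_point >= shift_at) {
        truth[[i]]$insertion_point <- truth[[i]]$insertion_point + delta
        truth[[i]]$start <- truth[[i]]$start + delta
        truth[[i]]$end <- truth[[i]]$end + delta
      }
    }
    disrupted <- NA_character_
    if (nrow(genes)) {
      # after stretching, the disrupted gene spans the inserted block
      hit <- which(genes$start < shift_at & genes$end >= shift_at + delta)
      if (length(hit)) disrupted <- genes$gene_name[hit[1]]
    }
    occupied <- rbind(occupied,
                      data.frame(start = p, end = p + k + delta,
                                 stringsAsFactors = FALSE))
    truth[[length(truth) + 1L]] <-
      list(element_name = elt$name, seq_id = seq_id,
           start = p + k, end = p + k + elt$length,
           insertion_point = p, k = k, tsd_sequence = kmer,
           strand = strand, disrupted_gene = disrupted)
  }
  truth_df <- do.call(rbind, lapply(truth, function(t)
    data.frame(t, stringsAsFactors = FALSE)))
  truth_df <- truth_df[order(truth_df$start), , drop = FALSE]
  rownames(truth_df) <- NULL
  list(sequence = sequence, genes = genes, truth = truth_df)
}

# a site motif shorter than k is anchored at the k-mer start and padded
# with N; longer than k is an error
rep_motif <- function(motif, k) {
  w <- nchar(motif)
  if (w > k) stop("site motif (", w, " bp) longer than duplication length ",
                  k)
  paste0(motif, strrep("N", k - w))
}

#' Score TSD calls against a synthetic truth table
#'
#' A call is a true positive iff its element interval AND duplication
#' length k match a truth record exactly. `exact_k_rate` is computed over
#' calls whose interval matches truth (how often the caller reported the
#' implanted k rather than a chance extension).
#'
#' @param truth Truth table from [implant_elements()].
#' @param calls [call_tsds()] output in the same (final) coordinate space.
#' @return List: `recall`, `precision`, `exact_k_rate`, `n_truth`,
#'   `n_calls`.
#' @export
evaluate_detection <- function(truth, calls) {
  key <- function(df) paste(df$seq_id, df$start, df$end, sep = "|")
  tkey <- key(truth); ckey <- key(calls)
  pos_match <- ckey %in% tkey
  tp <- if (nrow(calls)) vapply(seq_len(nrow(calls)), function(j) {
    i <- match(ckey[j], tkey)
    !is.na(i) && truth$k[i] == calls$k[j]
  }, logical(1)) else logical(0)
  n_tp <- sum(tp)
  list(recall = if (nrow(truth)) n_tp / nrow(truth) else NA_real_,
       precision = if (nrow(calls)) n_tp / nrow(calls) else NA_real_,
       exact_k_rate = if (any(pos_match)) sum(tp) / sum(pos_match)
                      else NA_real_,
       n_truth = nrow(truth), n_calls = nrow(calls))
}

#' Write a truth table as TSV (1-based inclusive coordinates)
#'
#' @param truth Truth table from [implant_elements()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_tsv <- function(truth, path) {
  out <- truth
  out$start_1based <- out$start + 1L
  out$end_1based <- out$end
  out$insertion_point_1based <- out$insertion_point + 1L
  out <- out[, c("element_name", "seq_id", "start_1based", "end_1based",
                 "insertion_point_1based", "k", "tsd_sequence", "strand",
                 "disrupted_gene")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
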