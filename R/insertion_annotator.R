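# Mapping TSD-verified insertions onto gene annotations: disrupted gene,
# defense-system context window, insertion-spectrum matrix, and diagnostic
# amplicon-size prediction. The "insertion point" is the + strand boundary
# between the upstream TSD copy and the element (hit start), the single
# unambiguous anchor used for spectrum collapsing.

#' Annotate one insertion against a gene table
#'
#' The disrupted gene is the feature with maximal overlap with the element
#' interval (ties broken by leftmost start); intergenic insertions return no
#' gene. `relative_position` is the insertion point's fractional position
#' along the gene, measured on the gene's strand; `orientation` compares the
#' element strand with the gene strand.
#'
#' @param call One row of [call_tsds()] output (or a hit row).
#' @param genes A [gene_models()] table on the same seq_id.
#' @return One-row `data.frame`: identity columns plus `disrupted_gene`,
#'   `system_label`, `relative_position`, `orientation`.
#' @export
annotate_insertion <- function(call, genes) {
  g <- genes[genes$seq_id == call$seq_id, , drop = FALSE]
  if (nrow(genes) > 0L && nrow(g) == 0L)
    stop("annotations are on different seq_id(s) than call (", call$seq_id, ")")
  s <- call$start; e <- call$end
  base <- data.frame(element_name = call$element_name, seq_id = call$seq_id,
                     start = s, end = e, strand = call$strand,
                     k = call$k %||% NA_integer_,
                     tsd_sequence = call$tsd_sequence %||% NA_character_,
                     disrupted_gene = NA_character_,
                     system_label = NA_character_,
                     relative_position = NA_real_,
                     orientation = NA_character_, stringsAsFactors = FALSE)
  if (nrow(g) == 0L) return(base)
  ov <- pmin(g$end, e) - pmax(g$start, s)
  hit_idx <- which(ov > 0L)
  if (length(hit_idx) == 0L) return(base)
  best <- hit_idx[order(-ov[hit_idx], g$start[hit_idx])][1]
  gs <- g$start[best]; ge <- g$end[best]; glen <- ge - gs
  ip <- s  # insertion point: upstream-TSD/element boundary, + strand coords
  rel <- if (g$strand[best] == "+") (ip - gs) / glen else (ge - ip) / glen
  base$disrupted_gene <- g$gene_name[best]
  base$system_label <- g$system_label[best]
  base$relative_position <- min(max(rel, 0), 1)
  base$orientation <- if (call$strand == g$strand[best]) "same" else "opposite"
  base
}

#' Annotate a whole call table
#'
#' @param calls [call_tsds()] output.
#' @param genes A [gene_models()] table.
#' @return `data.frame` with one [annotate_insertion()] row per call.
#' @export
annotate_insertions <- function(calls, genes) {
  rows <- lapply(seq_len(nrow(calls)), function(i)
    annotate_insertion(calls[i, ], genes))
  if (length(rows)) do.call(rbind, rows) else
    annotate_insertion(
      data.frame(element_name = "x", seq_id = "s", start = 0L, end = 1L,
                 strand = "+", k = 0L, tsd_sequence = "",
                 stringsAsFactors = FALSE),
      gene_models(character(0), integer(0), integer(0), character(0),
                  character(0)))[0, ]
}

#' Genes in the genomic context window around an insertion
#'
#' Returns all features overlapping `[element_start - window,
#' element_end + window)`, clipped at the sequence ends — the neighborhood
#' used to ask which defense systems an insertion sits in or near. With
#' `window = 0` this is exactly the genes overlapping the element itself.
#'
#' @param call One call/hit row.
#' @param genes A [gene_models()] table.
#' @param window Context half-width in bp (default 10000).
#' @return The overlapping subset of `genes`.
#' @export
scan_context <- function(call, genes, window = 10000L) {
  stopifnot(window >= 0)
  g <- genes[genes$seq_id == call$seq_id, , drop = FALSE]
  lo <- max(0L, call$start - as.integer(window))
  hi <- call$end + as.integer(window)
  out <- g[g$end > lo & g$start < hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the insertion-spectrum matrix
#'
#' Collapses annotated insertions into unique TSD sites keyed by
#' (gene, position-on-gene, k): rows are genes, columns are sites, entries
#' are the sets of inserting element families. Identical sites hit in
#' independent events share one column. TSD sequences that occur at more
#' than one distinct gene position are flagged (`multi_mapping`) as
#' potential false-positive loci rather than silently dropped.
#'
#' @param annotations [annotate_insertions()] output (rows without a
#'   disrupted gene are ignored).
#' @param catalog Optional [is_catalog()] used to translate element names to
#'   families; without it, element names are used as families.
#' @return List of class `spectrum_matrix`: `genes`, `sites` (`data.frame`
#'   with gene, position, k, tsd_sequence, gc, n_events, families,
#'   multi_mapping), `cells` (named list site_key -> character vector of
#'   families), and `per_gene_site_counts`.
#' @export
build_spectrum <- function(annotations, catalog = NULL) {
  ann <- annotations[!is.na(annotations$disrupted_gene), , drop = FALSE]
  fam <- function(el) {
    if (!is.null(catalog) && el %in% names(catalog)) catalog[[el]]$family
    else el
  }
  if (nrow(ann) == 0L) {
    return(structure(list(genes = character(0),
                          sites = data.frame(gene = character(0),
                                             position = integer(0),
                                             k = integer(0),
                                             tsd_sequence = character(0),
                                             gc = numeric(0),
                                             n_events = integer(0),
                                             families = character(0),
                                             multi_mapping = logical(0),
                                             stringsAsFactors = FALSE),
                          cells = list(),
                          per_gene_site_counts = integer(0)),
                     class = "spectrum_matrix"))
  }
  # site key: gene + fractional position on gene + duplication length
  key <- paste(ann$disrupted_gene,
               format(ann$relative_position, digits = 12), ann$k, sep = "|")
  split_idx <- split(seq_len(nrow(ann)), key)
  sites <- do.call(rbind, lapply(split_idx, function(ix) {
    a1 <- ann[ix[1], ]
    data.frame(gene = a1$disrupted_gene,
               position = a1$relative_position,
               k = a1$k, tsd_sequence = a1$tsd_sequence,
               gc = gc_fraction(a1$tsd_sequence),
               n_events = length(ix),
               families = paste(sort(unique(vapply(ann$element_name[ix], fam,
                                                   character(1)))),
                                collapse = ","),
               multi_mapping = FALSE, stringsAsFactors = FALSE)
  }))
  sites <- sites[order(sites$gene, sites$position, sites$k), , drop = FALSE]
  rownames(sites) <- NULL
  # a TSD sequence seen at >1 distinct site may be an off-target mapping
  if (nrow(sites)) {
    tab <- table(sites$tsd_sequence[nzchar(sites$tsd_sequence)])
    sites$multi_mapping <- sites$tsd_sequence %in% names(tab)[tab > 1]
  }
  cells <- stats::setNames(strsplit(sites$families, ",", fixed = TRUE),
                           paste(sites$gene, sites$position, sites$k,
                                 sep = "|"))
  counts <- table(sites$gene)
  structure(list(genes = sort(unique(ann$disrupted_gene)),
                 sites = sites, cells = cells,
                 per_gene_site_counts =
                   stats::setNames(as.integer(counts), names(counts))),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix: %d gene(s), %d unique site(s)>\n",
              length(x$genes), nrow(x$sites)))
  invisible(x)
}

#' Write a spectrum matrix as JSON
#'
#' @param spectrum A [build_spectrum()] result.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_spectrum_json <- function(spectrum, path) {
  jsonlite::write_json(list(genes = spectrum$genes, sites = spectrum$sites,
                            per_gene_site_counts =
                              as.list(spectrum$per_gene_site_counts)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Predict diagnostic PCR amplicon sizes across insertions
#'
#' The base amplicon is the span between the two primer 5' ends, inclusive;
#' every insertion inside the span enlarges it by `element_length + k` (the
#' element plus the one extra repeat copy transposition creates). Colony-PCR
#' logic: products larger than the base size indicate an IS insertion.
#'
#' @param template_sequence Template DNA string.
#' @param fwd,rev Primer sequences; `fwd` must occur exactly once on the +
#'   strand, `rev` exactly once as a reverse complement downstream of it.
#' @param insertions `data.frame` with columns `element_length` and `k`, one
#'   row per insertion assumed to fall inside the amplified span; or NULL.
#' @return Integer vector: the base size followed by the size with each
#'   insertion applied.
#' @export
predict_amplicons <- function(template_sequence, fwd, rev, insertions = NULL) {
  find_once <- function(primer, label) {
    m <- gregexpr(primer, template_sequence, fixed = TRUE)[[1]]
    if (m[1] == -1L) stop("primer not found on template: ", label)
    if (length(m) > 1L) stop("primer multi-maps on template: ", label)
    as.integer(m[1]) - 1L
  }
  f0 <- find_once(toupper(fwd), "fwd")
  rc <- revcomp(toupper(rev))
  r0 <- find_once(rc, "rev")
  r_end <- r0 + nchar(rc)           # rev primer 5' end is at r_end - 1 (+)
  if (r_end <= f0) stop("primers not in amplifying orientation (rev upstream of fwd)")
  base <- r_end - f0
  if (is.null(insertions) || nrow(insertions) == 0L) return(base)
  c(base, base + as.integer(insertions$element_length + insertions$k))
}
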