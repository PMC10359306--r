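# Catalog, target and annotation I/O. The catalog couples a FASTA of IS
# element sequences with a TSV metadata table (name, family,
# canonical_tsd_lengths as comma-separated bp, optional tsd_motif). Gene
# annotations travel as GFF3 with an optional `system=` attribute carrying a
# defense-system label.

#' Construct an IS element
#'
#' @param name Element identifier (unique within a catalog).
#' @param family IS family label, e.g. "IS1", "IS10".
#' @param sequence DNA string over ACGT, length >= 100.
#' @param canonical_tsd_lengths Integer vector of the family's characteristic
#'   target-site-duplication lengths, each in 2..30.
#' @param tsd_motif Optional IUPAC string describing the element's preferred
#'   target sites (e.g. "NRCWNWRYN" for IS10).
#' @return An object of class `ISElement`.
#' @export
is_element <- function(name, family, sequence,
                       canonical_tsd_lengths, tsd_motif = NULL) {
  sequence <- chartr("U", "T", toupper(sequence))
  bad <- first_non_acgt(sequence)
  if (bad > 0L)
    stop(sprintf("element '%s': non-ACGT character '%s' at position %d",
                 name, substr(sequence, bad, bad), bad))
  if (nchar(sequence) < 100L)
    stop(sprintf("element '%s': length %d < 100 bp", name, nchar(sequence)))
  k <- as.integer(canonical_tsd_lengths)
  if (length(k) == 0L || any(is.na(k)) || any(k < 2L | k > 30L))
    stop(sprintf("element '%s': canonical TSD lengths must be in [2, 30]", name))
  if (!is.null(tsd_motif)) {
    tsd_motif <- toupper(tsd_motif)
    if (!is_iupac(tsd_motif))
      stop(sprintf("element '%s': invalid IUPAC motif '%s'", name, tsd_motif))
  }
  structure(list(name = as.character(name), family = as.character(family),
                 sequence = sequence, length = nchar(sequence),
                 canonical_tsd_lengths = sort(unique(k)),
                 tsd_motif = tsd_motif),
            class = "ISElement")
}

#' @export
print.ISElement <- function(x, ...) {
  cat(sprintf("<ISElement %s (%s), %d bp, canonical TSD %s%s>\n",
              x$name, x$family, x$length,
              paste(x$canonical_tsd_lengths, collapse = "/"),
              if (is.null(x$tsd_motif)) "" else paste0(", motif ", x$tsd_motif)))
  invisible(x)
}

#' Construct an IS catalog from elements
#'
#' @param elements List of [is_element()] objects, unique by name.
#' @return An `ISCatalog` (named list of elements).
#' @export
is_catalog <- function(elements) {
  if (length(elements) == 0L) stop("empty catalog")
  nm <- vapply(elements, function(e) e$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate element name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(elements) <- nm
  # nested/truncated copies in reference catalogs are real; warn, don't fail
  seqs <- vapply(elements, function(e) e$sequence, character(1))
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    if (i != j && grepl(seqs[i], seqs[j], fixed = TRUE))
      warning(sprintf("element '%s' is an exact substring of '%s'",
                      nm[i], nm[j]), call. = FALSE)
  }
  structure(elements, class = "ISCatalog")
}

#' @export
print.ISCatalog <- function(x, ...) {
  cat(sprintf("<ISCatalog of %d element(s)>\n", length(x)))
  for (e in x) print(e)
  invisible(x)
}

#' Load an IS catalog from FASTA plus a metadata table
#'
#' Every FASTA record must have a metadata row (TSV columns `name`, `family`,
#' `canonical_tsd_lengths` comma-separated, optional `tsd_motif`). Lowercase
#' and U are normalised; any other non-ACGT character is rejected with the
#' record and position named.
#'
#' @param fasta_path Path to the element FASTA.
#' @param metadata_path Path to the metadata TSV.
#' @return An [is_catalog()].
#' @export
load_is_catalog <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty catalog: no FASTA records in ", fasta_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("name", "family", "canonical_tsd_lengths")
  if (!all(need %in% names(meta)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  nm <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(nm, meta$name)
  if (length(missing))
    stop("missing metadata row(s) for: ", paste(missing, collapse = ", "))
  elements <- lapply(seq_along(seqs), function(i) {
    row <- meta[match(nm[i], meta$name), ]
    motif <- row$tsd_motif
    if (is.null(motif) || is.na(motif) || !nzchar(motif)) motif <- NULL
    is_element(nm[i], row$family, as.character(seqs[[i]]),
               as.integer(strsplit(as.character(row$canonical_tsd_lengths),
                                   ",")[[1]]),
               motif)
  })
  is_catalog(elements)
}

#' Write an IS catalog back to FASTA + metadata TSV
#'
#' Inverse of [load_is_catalog()]; `load(write(catalog))` is the identity.
#'
#' @param catalog An `ISCatalog`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_is_catalog <- function(catalog, fasta_path, metadata_path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(catalog, function(e) e$sequence, character(1)))
  names(seqs) <- vapply(catalog, function(e) e$name, character(1))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  meta <- data.frame(
    name = names(seqs),
    family = vapply(catalog, function(e) e$family, character(1)),
    canonical_tsd_lengths = vapply(catalog, function(e)
      paste(e$canonical_tsd_lengths, collapse = ","), character(1)),
    tsd_motif = vapply(catalog, function(e) e$tsd_motif %||% "", character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Load target sequences from FASTA
#'
#' Targets are normalised to uppercase with U mapped to T; non-ACGT
#' characters (e.g. assembly Ns) are tolerated and simply never match
#' downstream.
#'
#' @param fasta_path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
load_targets <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- chartr("U", "T", toupper(as.character(seqs)))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write named sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param fasta_path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(sequences, fasta_path) {
  seqs <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  invisible(fasta_path)
}

#' Build a gene-model table
#'
#' Internal representation of gene annotations: one row per feature with
#' 0-based half-open `start`/`end`, strand, name and optional defense-system
#' label. File I/O ([load_annotations()], [write_annotations()]) converts
#' to/from 1-based inclusive GFF3 coordinates.
#'
#' @param seq_id,start,end,strand,gene_name,system_label Parallel vectors;
#'   `start`/`end` 0-based half-open; `strand` "+" or "-".
#' @return A `data.frame` of class `gene_models`, sorted by (seq_id, start).
#' @export
gene_models <- function(seq_id, start, end, strand, gene_name,
                        system_label = NA_character_) {
  system_label <- rep_len(as.character(system_label), length(start))
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   gene_name = as.character(gene_name),
                   system_label = as.character(system_label),
                   stringsAsFactors = FALSE)
  bad <- which(df$start < 0L | df$start >= df$end)
  if (length(bad))
    stop("invalid coordinates (start >= end or negative) for feature(s): ",
         paste(df$gene_name[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  df <- df[order(df$seq_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Load gene annotations from GFF3
#'
#' Reads gene/CDS features; the attribute `system=` (if present) populates
#' `system_label`. Coordinates are converted from GFF3 1-based inclusive to
#' the package's 0-based half-open convention. Features with start > end or
#' an unknown strand symbol are rejected.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param feature_types Feature types to keep (default gene and CDS).
#' @return A [gene_models()] table sorted by (seq_id, start).
#' @export
load_annotations <- function(gff3_path, feature_types = c("gene", "CDS")) {
  lines <- readLines(gff3_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(gene_models(character(0), integer(0), integer(0),
                       character(0), character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 9L))
    stop("malformed GFF3: expected 9 tab-separated columns at line(s) ",
         paste(which(nf != 9L), collapse = ", "))
  m <- do.call(rbind, f)
  keep <- m[, 3] %in% feature_types
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    return(gene_models(character(0), integer(0), integer(0),
                       character(0), character(0)))
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  if (any(is.na(start1)) || any(is.na(end1)) || any(start1 > end1))
    stop("GFF3 feature(s) with start > end or non-numeric coordinates")
  attr_field <- m[, 9]
  get_attr <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    found <- lengths(regmatches(attrs,
      gregexpr(paste0("(^|;)\\s*", key, "="), attrs))) > 0
    out[found] <- sub(paste0("^.*", key, "="), "", hit)
    out
  }
  gname <- get_attr(attr_field, "Name")
  gid <- get_attr(attr_field, "ID")
  gname[is.na(gname)] <- gid[is.na(gname)]
  gname[is.na(gname)] <- paste0("feature", which(is.na(gname)))
  gene_models(seq_id = m[, 1], start = start1 - 1L, end = end1,
              strand = m[, 7], gene_name = gname,
              system_label = get_attr(attr_field, "system"))
}

#' Write gene annotations to GFF3
#'
#' Inverse of [load_annotations()]: 0-based half-open internal coordinates
#' become 1-based inclusive, and `system_label` is emitted as a `system=`
#' attribute.
#'
#' @param genes A [gene_models()] table.
#' @param gff3_path Output path.
#' @param feature_type GFF3 column-3 value (default "CDS").
#' @param source GFF3 column-2 value.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(genes, gff3_path, feature_type = "CDS",
                              source = "isbreach") {
  attrs <- paste0("ID=", genes$gene_name, ";Name=", genes$gene_name,
                  ifelse(is.na(genes$system_label), "",
                         paste0(";system=", genes$system_label)))
  lines <- c("##gff-version 3",
             if (nrow(genes)) paste(genes$seq_id, source, feature_type,
                                    genes$start + 1L, genes$end, ".",
                                    genes$strand, "0", attrs, sep = "\t"))
  writeLines(lines, gff3_path)
  invisible(gff3_path)
}
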