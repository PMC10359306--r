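# Pipeline orchestration: scan -> TSD call -> annotate -> motif/summary ->
# optional spacer match, with machine-readable reports and a provenance
# manifest. Config is JSON; command-line flags override config values.

#' Assemble a run configuration
#'
#' @param catalog_fasta,catalog_meta IS catalog paths (FASTA + metadata
#'   TSV).
#' @param targets Target FASTA path.
#' @param gff Optional GFF3 annotation path.
#' @param spacers Optional spacer FASTA path.
#' @param k_min,k_max TSD search range.
#' @param canonical_only Restrict TSD lengths to each element's canonical
#'   set.
#' @param window Context window in bp.
#' @param pam_motif,pam_side Optional PAM rule for spacer matching.
#' @param seed Integer seed (recorded in the manifest; the scan itself is
#'   deterministic).
#' @param outdir Output directory (created if absent).
#' @return List of class `run_config`, validated.
#' @export
run_config <- function(catalog_fasta, catalog_meta, targets, gff = NULL,
                       spacers = NULL, k_min = 4L, k_max = 25L,
                       canonical_only = FALSE, window = 10000L,
                       pam_motif = NULL, pam_side = "5prime", seed = 1L,
                       outdir = "isbreach_out") {
  for (p in c(catalog_fasta, catalog_meta, targets, gff, spacers))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(k_min >= 1L, k_min <= k_max, k_max <= 30L, window >= 0L)
  structure(list(catalog_fasta = catalog_fasta, catalog_meta = catalog_meta,
                 targets = targets, gff = gff, spacers = spacers,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 canonical_only = isTRUE(canonical_only),
                 window = as.integer(window), pam_motif = pam_motif,
                 pam_side = pam_side, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Run the full scan pipeline
#'
#' Executes scan, TSD calling, (optional) annotation, motif statistics and
#' (optional) spacer matching, writing `hits.tsv`, `hits.bed`,
#' `tsd_calls.tsv`, `annotations.tsv`, `spectrum.json`, `pfm/*.txt`,
#' `summary.json` and a provenance `manifest.json` (package version, seed,
#' input MD5 digests) under `config$outdir`. Empty targets yield empty but
#' schema-valid outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`hits`, `calls`,
#'   `annotations`, `spectrum`, `pfms`, `matches`, `summary`).
#' @export
run_scan_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$outdir, "pfm"), showWarnings = FALSE)
  catalog <- load_is_catalog(config$catalog_fasta, config$catalog_meta)
  targets <- load_targets(config$targets)
  genes <- if (!is.null(config$gff)) load_annotations(config$gff) else NULL

  hits <- if (length(targets)) find_exact_copies(catalog, targets) else
    data.frame(element_name = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               target_length = integer(0), stringsAsFactors = FALSE)
  calls <- call_tsds(targets, hits, catalog, k_min = config$k_min,
                     k_max = config$k_max,
                     canonical_only = config$canonical_only)
  write_hits_tsv(hits, file.path(config$outdir, "hits.tsv"))
  write_hits_bed(hits, file.path(config$outdir, "hits.bed"))
  write_tsd_tsv(calls, file.path(config$outdir, "tsd_calls.tsv"))

  ann <- NULL; spectrum <- NULL
  if (!is.null(genes)) {
    ann <- annotate_insertions(calls, genes)
    utils::write.table(ann, file.path(config$outdir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    spectrum <- build_spectrum(ann, catalog)
    write_spectrum_json(spectrum, file.path(config$outdir, "spectrum.json"))
    ctx <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
      g <- scan_context(calls[i, ], genes, window = config$window)
      if (nrow(g)) cbind(g, context_of = calls$element_name[i]) else NULL
    }))
    if (!is.null(ctx))
      utils::write.table(ctx, file.path(config$outdir, "context.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  pfms <- list()
  with_tsd <- calls[calls$k > 0, , drop = FALSE]
  if (nrow(with_tsd)) {
    grp <- split(with_tsd$tsd_sequence,
                 paste(with_tsd$element_name, with_tsd$k, sep = "_"))
    pfms <- lapply(grp, build_pfm)
    for (nm in names(pfms))
      write_pfm(pfms[[nm]], file.path(config$outdir, "pfm",
                                      paste0(nm, ".txt")), name = nm)
  }

  matches <- NULL
  if (!is.null(config$spacers)) {
    spacers <- load_targets(config$spacers)
    pam <- if (!is.null(config$pam_motif))
      list(motif = config$pam_motif, side = config$pam_side) else NULL
    matches <- match_spacers(spacers, targets, pam = pam)
    write_matches_tsv(matches, file.path(config$outdir, "spacer_matches.tsv"))
  }

  summary <- list(
    n_targets = length(targets), n_elements = length(catalog),
    n_hits = nrow(hits), n_tsd_calls = sum(calls$k > 0),
    n_canonical = sum(calls$status == "canonical"),
    n_aberrant = sum(calls$status == "aberrant"),
    n_annotated = if (is.null(ann)) NA else sum(!is.na(ann$disrupted_gene)),
    n_spacer_matches = if (is.null(matches)) NA else nrow(matches))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  inputs <- c(config$catalog_fasta, config$catalog_meta, config$targets,
              config$gff, config$spacers)
  manifest <- list(
    tool = "isbreach",
    version = as.character(utils::packageVersion("isbreach")),
    seed = config$seed,
    coordinate_convention = "output tables 1-based inclusive",
    inputs = lapply(stats::setNames(inputs, basename(inputs)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(hits = hits, calls = calls, annotations = ann,
                 spectrum = spectrum, pfms = pfms, matches = matches,
                 summary = summary))
}

# --- command-line entry point ----------------------------------------------

parse_flags <- function(args) {
  out <- list(); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

as_num <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line interface
#'
#' Subcommands: `scan`, `tsd`, `annotate`, `match-spacers`, `recode`,
#' `simulate`, `evaluate` and the composite `run`. Config via
#' `--config file.json` plus flag overrides (flags win). Designed to be
#' invoked from the installed script as
#' `Rscript -e 'isbreach::isbreach_main()' -- run --config cfg.json`.
#'
#' @param argv Character vector of arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
isbreach_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  argv <- argv[argv != "--"]
  if (length(argv) == 0L) {
    message("usage: isbreach <run|scan|recode|simulate|match-spacers> [--flags]")
    return(invisible(1L))
  }
  cmd <- argv[1]
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error")) { message(conditionMessage(flags)); return(invisible(1L)) }
  cfg <- list()
  if (!is.null(flags$config)) {
    cfg <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    flags$config <- NULL
  }
  cfg[names(flags)] <- flags  # flags win
  status <- tryCatch({
    switch(cmd,
      run = , scan = {
        if (identical(cmd, "annotate") && is.null(cfg$gff))
          stop("--gff is required for annotate")
        rc <- run_config(
          catalog_fasta = cfg$catalog_fasta, catalog_meta = cfg$catalog_meta,
          targets = cfg$targets, gff = cfg$gff, spacers = cfg$spacers,
          k_min = as_num(cfg$k_min, 4), k_max = as_num(cfg$k_max, 25),
          canonical_only = isTRUE(cfg$canonical_only) ||
            identical(cfg$canonical_only, "TRUE"),
          window = as_num(cfg$window, 10000),
          pam_motif = cfg$pam_motif, pam_side = cfg$pam_side %||% "5prime",
          seed = as_num(cfg$seed, 1), outdir = cfg$outdir %||% "isbreach_out")
        run_scan_pipeline(rc)
        0L
      },
      annotate = {
        if (is.null(cfg$gff)) stop("missing required flag: --gff")
        rc <- run_config(
          catalog_fasta = cfg$catalog_fasta, catalog_meta = cfg$catalog_meta,
          targets = cfg$targets, gff = cfg$gff,
          k_min = as_num(cfg$k_min, 4), k_max = as_num(cfg$k_max, 25),
          window = as_num(cfg$window, 10000),
          seed = as_num(cfg$seed, 1), outdir = cfg$outdir %||% "isbreach_out")
        run_scan_pipeline(rc)
        0L
      },
      `match-spacers` = {
        spacers <- load_targets(cfg$spacers)
        targets <- load_targets(cfg$targets)
        pam <- if (!is.null(cfg$pam))
          list(motif = cfg$pam, side = cfg$pam_side %||% "5prime") else NULL
        m <- match_spacers(spacers, targets, pam = pam)
        write_matches_tsv(m, cfg$out %||% "spacer_matches.tsv")
        0L
      },
      recode = {
        cds <- load_targets(cfg$cds)
        motifs <- strsplit(cfg$motif, ",", fixed = TRUE)[[1]]
        outdir <- cfg$outdir %||% "."
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        recoded <- lapply(cds, recode_cds, motifs = motifs,
                          min_repeat = as_num(cfg$min_repeat, 10),
                          seed = as_num(cfg$seed, 1))
        write_fasta(vapply(recoded, `[[`, character(1), "sequence"),
                    file.path(outdir, "recoded.fasta"))
        for (nm in names(recoded))
          write_recode_json(recoded[[nm]],
                            file.path(outdir, paste0(nm, "_recode.json")))
        0L
      },
      simulate = {
        outdir <- cfg$outdir %||% "."
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        catalog <- load_is_catalog(cfg$catalog_fasta, cfg$catalog_meta)
        loc <- generate_locus(n_genes = as_num(cfg$n_genes, 8),
                              seed = as_num(cfg$seed, 1))
        kdist <- jsonlite::fromJSON(cfg$k_distribution %||% '{"9":1}')
        sp <- implant_spec(cfg$element %||% names(catalog)[1],
                           as_num(cfg$n_implants, 10), unlist(kdist),
                           site_motif = cfg$site_motif,
                           seed = as_num(cfg$seed, 1))
        imp <- implant_elements(loc$sequence, loc$genes, catalog, sp)
        write_fasta(stats::setNames(imp$sequence, loc$seq_id),
                    file.path(outdir, "simulated.fasta"))
        write_annotations(imp$genes, file.path(outdir, "simulated.gff3"))
        write_truth_tsv(imp$truth, file.path(outdir, "truth.tsv"))
        jsonlite::write_json(unclass(sp), file.path(outdir, "spec.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        0L
      },
      evaluate = {
        truth <- utils::read.delim(cfg$truth, comment.char = "#")
        calls <- utils::read.delim(cfg$calls, comment.char = "#")
        truth$start <- truth$start_1based - 1L; truth$end <- truth$end_1based
        calls$seq_id <- calls$seq_id
        calls$start <- calls$element_start_1based - 1L
        calls$end <- calls$element_end_1based
        m <- evaluate_detection(truth, calls)
        jsonlite::write_json(m, cfg$out %||% "metrics.json",
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        0L
      },
      { message("unknown subcommand: ", cmd); 1L })
  }, error = function(e) {
    message("[", cmd, "] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
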