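#' Run the full methylation-signature pipeline from a config
#'
#' Executes the stages applicable to the provided inputs, in order:
#' QC -> annotation -> signature calling (organ-specific; pluripotency
#' barcode and triplet memory when hiPSC clones are present) -> DMR
#' calling -> DEG integration (when a DEG table is given) -> enrichment.
#' Every inter-stage contract is a written file, so partial re-runs can
#' start from any stage's outputs; re-running with identical inputs and
#' config is byte-identical (the run manifest records input checksums and
#' a config hash, no timestamps).
#'
#' @param config Named list, or path to a YAML file, with elements:
#'   `inputs` (paths: `beta`, `sample_sheet`, `manifest`, `genes`;
#'   optional `cgis`, `bead_counts`, `detection_p`, `snp_probes`,
#'   `segmentation`, `degs`, `deltas`), and optional parameter blocks
#'   `qc`, `signature`, `dmr`, `deg_filter`, `annotation`
#'   (`shore_width`/`shelf_width`).
#' @param out_dir Output directory.
#' @return Invisibly, the run manifest (also written as
#'   `run_manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  inp <- config$inputs
  req <- c("beta", "sample_sheet", "manifest", "genes")
  miss <- setdiff(req, names(inp))
  if (length(miss)) stop_("config$inputs lacks: %s", collapse_ids(miss))
  paths <- unlist(inp)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop_("input file(s) not found: %s", collapse_ids(absent))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  counts <- list()

  beta <- read_beta_matrix(inp$beta)
  sheet <- read_sample_sheet(inp$sample_sheet, beta)
  manifest <- read_probe_manifest(inp$manifest)
  genes <- read_gene_models(inp$genes)
  cgis <- if (!is.null(inp$cgis)) read_intervals(inp$cgis) else NULL

  # --- qc ---------------------------------------------------------------
  thr <- do.call(qc_thresholds, config$qc %||% list())
  beads <- if (!is.null(inp$bead_counts))
    as.matrix(utils::read.delim(inp$bead_counts, row.names = 1L,
                                check.names = FALSE)) else NULL
  detp <- if (!is.null(inp$detection_p))
    as.matrix(utils::read.delim(inp$detection_p, row.names = 1L,
                                check.names = FALSE)) else NULL
  qc <- apply_probe_filters(beta, beads, detp, thr)
  snp <- if (!is.null(inp$snp_probes))
    readLines(inp$snp_probes) else character()
  sex <- drop_snp_and_sex_probes(qc$beta, manifest, snp, thr)
  beta <- sex$beta
  qc_report <- rbind(qc$dropped[c("probe_id", "reason")], sex$dropped)
  write_tsv(qc_report, fp("qc_report.tsv"))
  write_beta_matrix(beta, fp("beta_qc.tsv"))
  counts$qc <- list(probes_in = nrow(manifest), probes_out = nrow(beta),
                    cells_masked = qc$n_cells_masked)

  # --- annotation -------------------------------------------------------
  ann_par <- config$annotation %||% list()
  manifest <- annotate_manifest(manifest, genes, cgis,
                                ann_par$shore_width %||% 2000L,
                                ann_par$shelf_width %||% 2000L)
  write_tsv(manifest, fp("manifest_annotated.tsv"))

  # --- signatures -------------------------------------------------------
  sig_par <- config$signature %||% list()
  cfg_sig <- signature_config(sig_par$cutoff %||% 0.2, sig_par$pool)
  n_organs <- length(unique(sheet$organ[sheet$class == "fetal_organ"]))
  calls <- NULL
  if (n_organs >= 3L) {
    calls <- call_organ_specific_cpgs(beta, sheet, cfg_sig)
    write_signature_calls(calls, manifest, fp("organ_calls.tsv"),
                          fp("organ_calls.bed"))
    counts$signatures <- signature_counts(calls)
  }
  barcode <- memory <- NULL
  if (any(sheet$class == "hipsc_clone")) {
    barcode <- call_pluripotency_barcode(beta, sheet, cfg_sig)
    writeLines(barcode$hyper, fp("barcode_hyper.txt"))
    writeLines(barcode$hypo, fp("barcode_hypo.txt"))
    memory <- call_triplet_memory(beta, sheet, cfg_sig, manifest)
    write_tsv(as.data.frame(memory), fp("triplet_memory.tsv"))
    counts$barcode <- list(hyper = length(barcode$hyper),
                           hypo = length(barcode$hypo))
    counts$memory <- signature_counts(memory)
  }

  # --- dmr --------------------------------------------------------------
  if (!is.null(calls)) {
    dmr_par <- do.call(dmr_params, config$dmr %||% list())
    universe_man <- manifest[manifest$probe_id %in% rownames(beta), ]
    dmrs <- call_dmrs(calls, universe_man, dmr_par)
    dmrs <- map_dmr_to_gene(dmrs, manifest)
    write_dmrs(dmrs, fp("dmrs.tsv"), fp("dmrs.bed"))
    counts$dmrs <- nrow(dmrs)
  }

  # --- integration ------------------------------------------------------
  if (!is.null(inp$degs) && !is.null(inp$deltas)) {
    degs <- utils::read.delim(inp$degs, stringsAsFactors = FALSE)
    deltas <- utils::read.delim(inp$deltas, stringsAsFactors = FALSE)
    filt <- do.call(deg_filter, config$deg_filter %||% list())
    gene_chrom <- stats::setNames(genes$chrom, genes$gene_id)
    uniq <- select_organ_unique_degs(degs, filt, gene_chrom)
    summ <- deg_delta_beta(uniq, manifest, deltas)
    write_tsv(uniq, fp("organ_unique_degs.tsv"))
    write_tsv(summ$deltas, fp("deg_deltas_long.tsv"))
    write_tsv(summ$summary, fp("deg_delta_summary.tsv"))
    counts$integration <- list(n_unique_degs = nrow(uniq),
                               n_cells = nrow(summ$summary))
  }

  # --- enrichment -------------------------------------------------------
  if (!is.null(calls) && nrow(calls)) {
    universe <- rownames(beta)
    cat_gen <- stats::setNames(manifest$genic[match(universe, manifest$probe_id)],
                               universe)
    cat_cgi <- stats::setNames(manifest$cgi[match(universe, manifest$probe_id)],
                               universe)
    enr <- list()
    for (dir in c("hyper", "hypo")) {
      set <- unique(calls$probe_id[calls$direction == dir])
      if (!length(set)) next
      g <- category_enrichment(set, universe, cat_gen)
      g$annotation <- "genic"; g$direction <- dir
      c2 <- category_enrichment(set, universe, cat_cgi)
      c2$annotation <- "cgi"; c2$direction <- dir
      enr[[length(enr) + 1L]] <- rbind(g, c2)
      if (!is.null(inp$segmentation)) {
        seg <- read_intervals(inp$segmentation)
        s <- chromatin_state_enrichment(set, universe, seg, manifest)
        s$annotation <- "chromatin_state"; s$direction <- dir
        enr[[length(enr) + 1L]] <- s
      }
    }
    if (length(enr)) write_tsv(do.call(rbind, enr), fp("enrichment.tsv"))
  }

  # --- run manifest -----------------------------------------------------
  cfg_file <- tempfile()
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  run <- list(package = "methtrail",
              version = as.character(utils::packageVersion("methtrail")),
              config = config,
              config_md5 = unname(tools::md5sum(cfg_file)),
              input_md5 = as.list(tools::md5sum(paths)),
              counts = counts)
  unlink(cfg_file)
  jsonlite::write_json(run, fp("run_manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(run)
}

#' Summarise per-stage counts of a pipeline run
#'
#' Reads the stage outputs of a [run_pipeline()] output directory and
#' returns per-organ hyper/hypo CpG counts, DMR counts and
#' barcode/memory counts; stages whose outputs are absent are reported
#' as NULL.
#'
#' @param out_dir A pipeline output directory.
#' @param json_path Optional path to also write the summary as JSON.
#' @return Named list of counts.
#' @export
summarize_counts <- function(out_dir, json_path = NULL) {
  fp <- function(f) file.path(out_dir, f)
  rd <- function(f) if (file.exists(fp(f)))
    utils::read.delim(fp(f), stringsAsFactors = FALSE) else NULL
  out <- list(organ_cpgs = NULL, dmrs = NULL, barcode = NULL, memory = NULL)
  calls <- rd("organ_calls.tsv")
  if (!is.null(calls))
    out$organ_cpgs <- signature_counts(calls)
  dmrs <- rd("dmrs.tsv")
  if (!is.null(dmrs))
    out$dmrs <- if (nrow(dmrs)) signature_counts(dmrs) else
      data.frame(group = character(), direction = character(), n = integer())
  if (file.exists(fp("barcode_hyper.txt")))
    out$barcode <- list(hyper = length(readLines(fp("barcode_hyper.txt"))),
                        hypo = length(readLines(fp("barcode_hypo.txt"))))
  mem <- rd("triplet_memory.tsv")
  if (!is.null(mem))
    out$memory <- signature_counts(mem)
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  out
}
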