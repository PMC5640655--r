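#' DEG filtering thresholds
#'
#' Defaults follow the study design: differentially expressed genes at
#' FDR < 0.01 with |log2 fold change| > 1, X-linked genes excluded to
#' avoid sex bias, and only genes passing the thresholds in exactly one
#' organ retained ("organ-unique").
#'
#' @param max_fdr FDR cutoff (default 0.01, strict `<`).
#' @param min_abs_logfc |logFC| cutoff (default 1, strict `>`).
#' @param exclude_x_linked Drop chrX genes (default TRUE).
#' @return List of class `deg_filter`.
#' @export
deg_filter <- function(max_fdr = 0.01, min_abs_logfc = 1,
                       exclude_x_linked = TRUE) {
  assert_scalar_number(max_fdr, "max_fdr", 0, 1)
  assert_scalar_number(min_abs_logfc, "min_abs_logfc", lower = 0)
  structure(list(max_fdr = max_fdr, min_abs_logfc = min_abs_logfc,
                 exclude_x_linked = isTRUE(exclude_x_linked)),
            class = "deg_filter")
}

#' Select organ-unique differentially expressed genes
#'
#' Keeps DEG records with FDR below the cutoff and |logFC| above the
#' cutoff, optionally drops X-linked genes, then retains only genes that
#' pass the thresholds in exactly one organ. Uniqueness is evaluated
#' *after* thresholding: a gene weakly differential elsewhere does not
#' disqualify. Direction (up/down) follows the sign of logFC.
#'
#' @param records data.frame with `gene_id`, `organ`, `logFC`, `FDR`
#'   (one row per gene x organ).
#' @param filter A [deg_filter()] object.
#' @param gene_chrom Optional named vector gene_id -> chromosome, needed
#'   when `exclude_x_linked` is set.
#' @return data.frame of retained records with a `direction` column; the
#'   per-organ gene sets are pairwise disjoint.
#' @export
select_organ_unique_degs <- function(records, filter = deg_filter(),
                                     gene_chrom = NULL) {
  need <- c("gene_id", "organ", "logFC", "FDR")
  miss <- setdiff(need, colnames(records))
  if (length(miss)) stop_("DEG table lacks column(s): %s", collapse_ids(miss))
  key <- paste(records$gene_id, records$organ)
  if (anyDuplicated(key))
    stop_("duplicate gene x organ row(s): %s",
          collapse_ids(utils::head(unique(key[duplicated(key)]), 5L)))
  keep <- records$FDR < filter$max_fdr &
    abs(records$logFC) > filter$min_abs_logfc
  out <- records[keep, , drop = FALSE]
  if (filter$exclude_x_linked) {
    if (is.null(gene_chrom))
      stop_("exclude_x_linked is set but gene_chrom map is missing")
    chr <- gene_chrom[out$gene_id]
    out <- out[!(chr %in% c("chrX", "X")), , drop = FALSE]
  }
  n_org <- table(out$gene_id)
  out <- out[n_org[out$gene_id] == 1L, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Promoter / gene-body delta-beta summaries for organ-unique DEGs
#'
#' For every organ x DEG-direction x region (PP proximal promoter, GB
#' gene body), collects the per-CpG stage-to-stage delta betas of all
#' annotated probes of the selected genes, and summarises them (median,
#' quartiles). Genes without annotated probes contribute nothing and are
#' reported. The expected biological sign structure is promoter
#' methylation gain with downregulation and promoter loss with
#' upregulation (gene body opposite).
#'
#' @param degs Output of [select_organ_unique_degs()].
#' @param manifest Annotated manifest.
#' @param deltas Either a single [stage_delta_beta()] table (applied to
#'   every organ present in `degs`) or a long data.frame with columns
#'   `probe_id`, `organ`, `delta`.
#' @return List of class `region_delta_summary` with `deltas` (long
#'   per-CpG table), `summary` (organ x direction x region stats) and
#'   `genes_without_probes`.
#' @export
deg_delta_beta <- function(degs, manifest, deltas) {
  if (is.null(manifest$genic) || is.null(manifest$nearest_gene))
    stop_("manifest is not annotated; run annotate_manifest() first")
  single <- is.null(deltas$organ)
  long <- list(); no_probe <- character()
  for (i in seq_len(nrow(degs))) {
    gene <- degs$gene_id[i]; organ <- degs$organ[i]
    dir <- degs$direction[i]
    sel <- !is.na(manifest$nearest_gene) & manifest$nearest_gene == gene &
      manifest$genic %in% c("PP", "GB")
    if (!any(sel)) { no_probe <- c(no_probe, gene); next }
    dt <- if (single) deltas else deltas[deltas$organ == organ, , drop = FALSE]
    j <- match(manifest$probe_id[sel], dt$probe_id)
    long[[length(long) + 1L]] <-
      data.frame(organ = organ, direction = dir,
                 region = manifest$genic[sel],
                 gene_id = gene,
                 probe_id = manifest$probe_id[sel],
                 delta = dt$delta[j],
                 stringsAsFactors = FALSE)
  }
  long <- if (length(long)) do.call(rbind, long) else
    data.frame(organ = character(), direction = character(),
               region = character(), gene_id = character(),
               probe_id = character(), delta = numeric(),
               stringsAsFactors = FALSE)
  long <- long[!is.na(long$delta), , drop = FALSE]
  if (nrow(long)) {
    summ <- do.call(rbind, lapply(
      split(long, paste(long$organ, long$direction, long$region)),
      function(d) data.frame(organ = d$organ[1L], direction = d$direction[1L],
                             region = d$region[1L], n_probes = nrow(d),
                             median = stats::median(d$delta),
                             q1 = unname(stats::quantile(d$delta, 0.25)),
                             q3 = unname(stats::quantile(d$delta, 0.75)),
                             stringsAsFactors = FALSE)))
    summ <- summ[order(summ$organ, summ$direction, summ$region), ]
    rownames(summ) <- NULL
  } else {
    summ <- data.frame(organ = character(), direction = character(),
                       region = character(), n_probes = integer(),
                       median = numeric(), q1 = numeric(), q3 = numeric(),
                       stringsAsFactors = FALSE)
  }
  structure(list(deltas = long, summary = summ,
                 genes_without_probes = unique(no_probe)),
            class = "region_delta_summary")
}

#' @export
print.region_delta_summary <- function(x, ...) {
  cat(sprintf("delta-beta summary: %d CpG deltas, %d organ x direction x region cells\n",
              nrow(x$deltas), nrow(x$summary)))
  if (nrow(x$summary)) print.data.frame(x$summary)
  invisible(x)
}
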