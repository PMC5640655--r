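#' Read a beta-value matrix from TSV
#'
#' Reads a probes-by-samples table of methylation beta values. The first
#' column must hold probe identifiers and the header row the sample
#' identifiers. Empty cells (or the literal "NA") become missing values;
#' every non-missing value must lie in \[0, 1\].
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with probe ids as rownames and sample ids as
#'   colnames; missing cells are `NA`. Row and column order follow the file.
#' @export
read_beta_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop_("beta matrix '%s' needs a probe-id column plus >=1 sample column", path)
  probe_ids <- raw[[1L]]
  if (anyDuplicated(probe_ids))
    stop_("duplicate probe id(s) in '%s': %s", path,
          collapse_ids(unique(probe_ids[duplicated(probe_ids)])))
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop_("duplicate sample id(s) in '%s'", path)
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- raw[[j + 1L]]
    empty <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop_("non-numeric value '%s' at probe '%s', sample '%s'",
            cell[bad[1L]], probe_ids[bad[1L]], sample_ids[j])
    vals[, j] <- num
  }
  validate_beta_matrix(vals, context = path)
  vals
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()]: full `%.17g`-style precision so a
#' write/read round trip reproduces values and the missing mask exactly.
#'
#' @param m Beta matrix (probes x samples).
#' @param path Output path.
#' @export
write_beta_matrix <- function(m, path) {
  validate_beta_matrix(m)
  df <- data.frame(probe_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1L][is.na(m)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a beta matrix
#'
#' Checks the container invariants: numeric matrix, unique probe and sample
#' ids, all non-missing values in \[0, 1\].
#'
#' @param m Candidate matrix.
#' @param context Label used in error messages.
#' @return The matrix, invisibly.
#' @export
validate_beta_matrix <- function(m, context = "beta matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_("%s: expected a numeric matrix", context)
  if (nrow(m) > 0L && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    stop_("%s: probe ids must be present and unique", context)
  if (ncol(m) > 0L && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
    stop_("%s: sample ids must be present and unique", context)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop_("%s: beta value %.4g outside [0, 1] at probe '%s', sample '%s'",
          context, m[bad[1L, 1L], bad[1L, 2L]],
          rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]])
  invisible(m)
}

#' Read a sample sheet
#'
#' Expected columns: `sample_id`, `organ`, `stage` (one of W8-12 / W16-18 /
#' W20-22 / PSC), `fetus_id`, `class` (fetal_organ / hipsc_clone /
#' external_psc), optional `sex` and, for hiPSC clones, `origin_organ`.
#'
#' @param path TSV path.
#' @param beta Optional beta matrix to cross-check sample ids against.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path, beta = NULL) {
  sheet <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, beta)
}

#' Validate a sample sheet
#'
#' @param sheet data.frame to check.
#' @param beta Optional beta matrix whose columns must match `sample_id`.
#' @return The sheet (with `origin_organ`/`sex` columns guaranteed present).
#' @export
validate_sample_sheet <- function(sheet, beta = NULL) {
  need <- c("sample_id", "organ", "stage", "fetus_id", "class")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss)) stop_("sample sheet lacks column(s): %s", collapse_ids(miss))
  if (anyDuplicated(sheet$sample_id)) stop_("duplicate sample ids in sheet")
  okc <- c("fetal_organ", "hipsc_clone", "external_psc")
  if (!all(sheet$class %in% okc))
    stop_("sample class must be one of %s", collapse_ids(okc))
  if (is.null(sheet$origin_organ)) sheet$origin_organ <- NA_character_
  if (is.null(sheet$sex)) sheet$sex <- NA_character_
  cl <- sheet[sheet$class == "hipsc_clone", ]
  for (i in seq_len(nrow(cl))) {
    org <- sheet[sheet$class == "fetal_organ" & sheet$fetus_id == cl$fetus_id[i], "organ"]
    if (is.na(cl$origin_organ[i]) || !cl$origin_organ[i] %in% org)
      stop_("clone '%s': origin organ '%s' absent among fetal organs of fetus '%s'",
            cl$sample_id[i], cl$origin_organ[i], cl$fetus_id[i])
  }
  if (!is.null(beta)) {
    if (!setequal(colnames(beta), sheet$sample_id))
      stop_("sample sheet ids do not match beta matrix columns")
  }
  sheet
}

#' Read a CpG probe manifest
#'
#' Minimal input manifest: `probe_id`, `chrom`, `pos` (1-based position,
#' array convention). Annotation columns, when present, are kept.
#'
#' @param path TSV path.
#' @return data.frame sorted as in the file.
#' @export
read_probe_manifest <- function(path) {
  man <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  miss <- setdiff(need, colnames(man))
  if (length(miss)) stop_("probe manifest lacks column(s): %s", collapse_ids(miss))
  if (anyDuplicated(man$probe_id)) stop_("duplicate probe ids in manifest")
  man$pos <- as.integer(man$pos)
  man
}

#' Read gene models
#'
#' Columns: `gene_id`, `chrom`, `strand` (+/-), `tss`, `end3` (both 1-based).
#' For + strand genes `tss <= end3`; for - strand `tss >= end3`.
#'
#' @param path TSV path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  g <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "end3")
  miss <- setdiff(need, colnames(g))
  if (length(miss)) stop_("gene model table lacks column(s): %s", collapse_ids(miss))
  validate_gene_models(g)
}

#' @noRd
validate_gene_models <- function(g) {
  if (anyDuplicated(g$gene_id)) stop_("duplicate gene ids in gene models")
  if (!all(g$strand %in% c("+", "-"))) stop_("gene strand must be '+' or '-'")
  g$tss <- as.integer(g$tss); g$end3 <- as.integer(g$end3)
  bad <- (g$strand == "+" & g$tss > g$end3) | (g$strand == "-" & g$tss < g$end3)
  if (any(bad))
    stop_("gene(s) with tss/end3 inconsistent with strand: %s",
          collapse_ids(g$gene_id[bad]))
  g
}

#' Read genomic intervals from BED
#'
#' 3+ column BED, 0-based half-open. A 4th column, when present, is kept as
#' the interval label (e.g. a chromatin-state mnemonic). Intervals are
#' returned sorted within each chromosome; unsorted input is sorted with a
#' message. Overlapping intervals are retained — merging is left to callers.
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, sorted by (chrom, start, end).
#' @export
read_intervals <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) stop_("BED file '%s' needs >= 3 columns", path)
  out <- data.frame(chrom = as.character(bed[[1L]]),
                    start = as.integer(bed[[2L]]),
                    end   = as.integer(bed[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(bed) >= 4L) out$name <- as.character(bed[[4L]])
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop_("BED '%s': start >= end at line %d (%s:%d-%d)", path, bad[1L],
          out$chrom[bad[1L]], out$start[bad[1L]], out$end[bad[1L]])
  ord <- order(out$chrom, out$start, out$end)
  if (!identical(ord, seq_len(nrow(out)))) {
    message("read_intervals: input not sorted; sorting by (chrom, start)")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write intervals as BED
#'
#' @param x data.frame with `chrom`, `start`, `end` and optional further
#'   columns (written in order, BED-style, no header).
#' @param path Output path.
#' @export
write_intervals <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
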