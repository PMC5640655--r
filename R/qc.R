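#' Probe-level QC thresholds
#'
#' Defaults follow the 450K processing convention adopted here: probes with
#' a bead count below 3 or a detection p-value above 0.01 are unreliable in
#' that sample; a probe measured successfully in less than 95% of samples
#' is dropped altogether; probes overlapping common SNPs (minor allele
#' frequency > 5%) and probes on the sex chromosomes are excluded except
#' in isogenic-set analyses, where sex is constant by design.
#'
#' @param min_bead_count Minimum bead count per cell (default 3).
#' @param max_detection_p Maximum detection p-value per cell (default 0.01).
#' @param min_success_rate Minimum fraction of non-missing cells per probe
#'   (default 0.95), evaluated across all samples in the matrix.
#' @param exclude_snp_maf Allele-frequency cutoff documented for the SNP
#'   exclusion list (default 0.05); the list itself is supplied by the user.
#' @param exclude_sex_chromosomes Drop chrX/chrY probes (default TRUE; set
#'   FALSE for isogenic-set analyses).
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_bead_count = 3L,
                          max_detection_p = 0.01,
                          min_success_rate = 0.95,
                          exclude_snp_maf = 0.05,
                          exclude_sex_chromosomes = TRUE) {
  assert_scalar_number(min_bead_count, "min_bead_count", lower = 0)
  assert_scalar_number(max_detection_p, "max_detection_p", 0, 1)
  assert_scalar_number(min_success_rate, "min_success_rate", 0, 1)
  assert_scalar_number(exclude_snp_maf, "exclude_snp_maf", 0, 1)
  structure(list(min_bead_count = min_bead_count,
                 max_detection_p = max_detection_p,
                 min_success_rate = min_success_rate,
                 exclude_snp_maf = exclude_snp_maf,
                 exclude_sex_chromosomes = isTRUE(exclude_sex_chromosomes)),
            class = "qc_thresholds")
}

#' Apply bead-count / detection-p / success-rate probe filters
#'
#' Two-stage rule: cells failing the bead-count or detection-p threshold
#' are masked to missing; a probe whose fraction of non-missing cells then
#' falls below `min_success_rate` is dropped entirely. The operation is
#' idempotent and monotone in the thresholds.
#'
#' @param m Beta matrix (probes x samples).
#' @param bead_counts Integer matrix aligned to `m`, or NULL to skip.
#' @param detection_p Numeric matrix aligned to `m`, or NULL to skip.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `beta` (filtered matrix), `dropped` (data.frame:
#'   probe_id, reason, success_rate) and `n_cells_masked`.
#' @export
apply_probe_filters <- function(m, bead_counts = NULL, detection_p = NULL,
                                thresholds = qc_thresholds()) {
  validate_beta_matrix(m)
  check_aligned <- function(q, what) {
    if (!identical(dim(q), dim(m)) ||
        !identical(rownames(q), rownames(m)) ||
        !identical(colnames(q), colnames(m)))
      stop_("%s matrix is not aligned to the beta matrix", what)
  }
  mask <- matrix(FALSE, nrow(m), ncol(m))
  if (!is.null(bead_counts)) {
    check_aligned(bead_counts, "bead-count")
    mask <- mask | (!is.na(bead_counts) & bead_counts < thresholds$min_bead_count)
  }
  if (!is.null(detection_p)) {
    check_aligned(detection_p, "detection p-value")
    mask <- mask | (!is.na(detection_p) & detection_p > thresholds$max_detection_p)
  }
  n_masked <- sum(mask & !is.na(m))
  m[mask] <- NA_real_
  success <- rowMeans(!is.na(m))
  drop <- success < thresholds$min_success_rate
  dropped <- data.frame(probe_id = rownames(m)[drop],
                        reason = rep("low_success_rate", sum(drop)),
                        success_rate = unname(success[drop]),
                        stringsAsFactors = FALSE)
  list(beta = m[!drop, , drop = FALSE],
       dropped = dropped,
       n_cells_masked = n_masked)
}

#' Drop SNP-overlapping and sex-chromosome probes
#'
#' Probes named in `snp_probes` are always removed; probes mapping to
#' chrX/chrY are removed only when `exclude_sex_chromosomes` is set in the
#' thresholds (it is unset for isogenic-set analyses, where all samples
#' share one genome).
#'
#' @param m Beta matrix.
#' @param manifest Probe manifest covering all probes of `m`.
#' @param snp_probes Character vector of probe ids to exclude (e.g. probes
#'   over SNPs with allele frequency > 5%).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `beta` and `dropped` (probe_id, reason).
#' @export
drop_snp_and_sex_probes <- function(m, manifest, snp_probes = character(),
                                    thresholds = qc_thresholds()) {
  validate_beta_matrix(m)
  missing_probes <- setdiff(rownames(m), manifest$probe_id)
  if (length(missing_probes))
    stop_("probe(s) absent from manifest: %s",
          collapse_ids(utils::head(missing_probes, 10L)))
  chrom <- manifest$chrom[match(rownames(m), manifest$probe_id)]
  is_sex <- chrom %in% c("chrX", "chrY", "X", "Y")
  drop_snp <- rownames(m) %in% snp_probes
  drop_sex <- thresholds$exclude_sex_chromosomes & is_sex
  reason <- ifelse(drop_snp, "snp_probe",
                   ifelse(drop_sex, "sex_chromosome", NA_character_))
  drop <- !is.na(reason)
  list(beta = m[!drop, , drop = FALSE],
       dropped = data.frame(probe_id = rownames(m)[drop],
                            reason = reason[drop],
                            stringsAsFactors = FALSE))
}
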