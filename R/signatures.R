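#' Signature-calling configuration
#'
#' The single tunable is the pairwise delta-beta cutoff: a CpG is called
#' relatively hypermethylated in a group when its beta exceeds that of
#' every comparison sample by more than `cutoff` (hypomethylated when it
#' falls below every comparison sample by more than `cutoff`). Ties at
#' exactly the cutoff are not calls. `pool` optionally merges organ labels
#' into one group before comparison (e.g. tongue + skeletal muscle, two
#' muscular organs with near-identical methylation).
#'
#' @param cutoff Delta-beta cutoff in beta units (default 0.2).
#' @param pool Named list mapping a pooled label to the organ labels it
#'   absorbs, e.g. `list(muscle_tongue = c("muscle", "tongue"))`, or NULL.
#' @return List of class `signature_config`.
#' @export
signature_config <- function(cutoff = 0.2, pool = NULL) {
  assert_scalar_number(cutoff, "cutoff", lower = 0, upper = 1)
  if (cutoff <= 0 || cutoff >= 1) stop_("cutoff must satisfy 0 < cutoff < 1")
  structure(list(cutoff = cutoff, pool = pool), class = "signature_config")
}

#' @noRd
apply_pool <- function(organ, pool) {
  if (is.null(pool)) return(organ)
  for (lab in names(pool)) organ[organ %in% pool[[lab]]] <- lab
  organ
}

#' @noRd
row_max <- function(m) do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
#' @noRd
row_min <- function(m) do.call(pmin, c(as.data.frame(m), na.rm = FALSE))

# group-vs-rest caller shared by the organ-specific, barcode and triplet
# scopes: group_cols / other_cols index sample columns of the beta matrix.
# A probe is hyper iff min(group) - max(other) > cutoff, hypo iff
# max(group) - min(other) < -cutoff; min_pairwise_delta is the pairwise
# difference of smallest magnitude. Probes with any NA across the used
# columns are not evaluable and yield no call.
#' @noRd
call_group_vs_rest <- function(m, group_cols, other_cols, cutoff, label) {
  grp <- m[, group_cols, drop = FALSE]
  oth <- m[, other_cols, drop = FALSE]
  gmin <- row_min(grp); gmax <- row_max(grp)
  omin <- row_min(oth); omax <- row_max(oth)
  evaluable <- !(is.na(gmin) | is.na(gmax) | is.na(omin) | is.na(omax))
  d_hyper <- gmin - omax
  d_hypo <- gmax - omin
  hyper <- evaluable & d_hyper > cutoff
  hypo <- evaluable & d_hypo < -cutoff
  out <- rbind(
    data.frame(probe_id = rownames(m)[hyper],
               group = rep(label, sum(hyper)),
               direction = rep("hyper", sum(hyper)),
               min_pairwise_delta = unname(d_hyper[hyper]),
               stringsAsFactors = FALSE),
    data.frame(probe_id = rownames(m)[hypo],
               group = rep(label, sum(hypo)),
               direction = rep("hypo", sum(hypo)),
               min_pairwise_delta = unname(d_hypo[hypo]),
               stringsAsFactors = FALSE))
  attr(out, "n_not_evaluable") <- sum(!evaluable)
  out
}

#' Stage-to-stage delta beta per probe
#'
#' Per-probe difference of group means: mean beta over the late-stage
#' samples of an organ minus mean beta over its early-stage samples.
#' Missing values propagate (a probe with a missing value in either group
#' gets `NA`).
#'
#' @param m Beta matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @param organ Organ label.
#' @param early,late Stage labels (defaults "W8-12" and "W20-22").
#' @return data.frame `probe_id`, `delta`, with attributes `organ`,
#'   `early`, `late`.
#' @export
stage_delta_beta <- function(m, sheet, organ,
                             early = "W8-12", late = "W20-22") {
  sheet <- validate_sample_sheet(sheet)
  pick <- function(stage) {
    ids <- sheet$sample_id[sheet$organ == organ & sheet$stage == stage]
    ids <- intersect(colnames(m), ids)
    if (!length(ids))
      stop_("no sample of organ '%s' at stage '%s'", organ, stage)
    ids
  }
  e <- m[, pick(early), drop = FALSE]
  l <- m[, pick(late), drop = FALSE]
  delta <- rowMeans(l) - rowMeans(e)   # na.rm = FALSE: missing propagates
  out <- data.frame(probe_id = rownames(m), delta = unname(delta),
                    stringsAsFactors = FALSE)
  attr(out, "organ") <- organ
  attr(out, "early") <- early
  attr(out, "late") <- late
  out
}

#' Call organ-specific hyper/hypomethylated CpGs within an isogenic set
#'
#' For every organ of one isogenic set, a CpG is called hypermethylated
#' when the organ's beta exceeds the beta of every other organ by more
#' than the cutoff, and hypomethylated when it falls below every other
#' organ by more than the cutoff. When an organ has replicate samples the
#' replicate mean is compared. Organs may be pooled via the config.
#'
#' @param m Beta matrix restricted to one isogenic set (or use `fetus` to
#'   subset).
#' @param sheet Sample sheet.
#' @param config A [signature_config()].
#' @param fetus Optional fetus id; restricts to `fetal_organ` samples of
#'   that fetus.
#' @return data.frame of calls (`probe_id`, `group`, `direction`,
#'   `min_pairwise_delta`) with attribute `n_not_evaluable`.
#' @export
call_organ_specific_cpgs <- function(m, sheet, config = signature_config(),
                                     fetus = NULL) {
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[sheet$class == "fetal_organ" & sheet$sample_id %in% colnames(m), ]
  if (!is.null(fetus)) sheet <- sheet[sheet$fetus_id %in% fetus, ]
  if (!nrow(sheet)) stop_("no fetal_organ samples selected")
  organ <- apply_pool(sheet$organ, config$pool)
  organs <- sort(unique(organ))
  if (length(organs) < 3L)
    stop_("isogenic set has %d organ group(s); need >= 3 for a meaningful comparison",
          length(organs))
  # replicate mean per organ; NA propagates so a missing replicate makes
  # the organ mean (and hence the probe) not evaluable
  G <- matrix(vapply(organs, function(o)
    rowMeans(m[, sheet$sample_id[organ == o], drop = FALSE]),
    numeric(nrow(m))), nrow = nrow(m),
    dimnames = list(rownames(m), organs))
  res <- lapply(seq_along(organs), function(k)
    call_group_vs_rest(G, k, setdiff(seq_along(organs), k),
                       config$cutoff, organs[k]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_not_evaluable") <- sum(rowSums(is.na(G)) > 0L)
  attr(out, "organs") <- organs
  class(out) <- c("signature_calls", class(out))
  out
}

#' Call the hiPSC pluripotency barcode
#'
#' CpGs consistently hyper- or hypomethylated in every hiPSC clone
#' relative to the fetal organs of origin. Under the default `all_pairs`
#' scope a CpG is in the hypermethylated barcode iff every clone exceeds
#' every organ sample by more than the cutoff; under `own_organ` each
#' clone is compared only to its organ of origin.
#'
#' @param m Beta matrix.
#' @param sheet Sample sheet with `hipsc_clone` and `fetal_organ` rows.
#' @param config A [signature_config()].
#' @param scope "all_pairs" (default) or "own_organ".
#' @return List with character vectors `hyper` and `hypo` and the count
#'   `n_not_evaluable`.
#' @export
call_pluripotency_barcode <- function(m, sheet, config = signature_config(),
                                      scope = c("all_pairs", "own_organ")) {
  scope <- match.arg(scope)
  sheet <- validate_sample_sheet(sheet)
  clones <- sheet$sample_id[sheet$class == "hipsc_clone"]
  organs <- sheet$sample_id[sheet$class == "fetal_organ"]
  if (!length(clones) || !length(organs))
    stop_("need at least one hipsc_clone and one fetal_organ sample")
  if (scope == "all_pairs") {
    calls <- call_group_vs_rest(m, match(clones, colnames(m)),
                                match(organs, colnames(m)),
                                config$cutoff, "hiPSC")
  } else {
    # per-clone comparison against its own organ of origin only
    org_of <- function(cl) {
      row <- sheet[sheet$sample_id == cl, ]
      sheet$sample_id[sheet$class == "fetal_organ" &
                      sheet$organ == row$origin_organ &
                      sheet$fetus_id == row$fetus_id]
    }
    diffs <- vapply(clones, function(cl) {
      og <- org_of(cl)
      m[, cl] - rowMeans(m[, og, drop = FALSE])
    }, numeric(nrow(m)))
    dmin <- row_min(diffs); dmax <- row_max(diffs)
    evaluable <- !(is.na(dmin) | is.na(dmax))
    hyper <- evaluable & dmin > config$cutoff
    hypo <- evaluable & dmax < -config$cutoff
    calls <- rbind(
      data.frame(probe_id = rownames(m)[hyper], group = "hiPSC",
                 direction = "hyper", min_pairwise_delta = unname(dmin[hyper]),
                 stringsAsFactors = FALSE),
      data.frame(probe_id = rownames(m)[hypo], group = "hiPSC",
                 direction = "hypo", min_pairwise_delta = unname(dmax[hypo]),
                 stringsAsFactors = FALSE))
    attr(calls, "n_not_evaluable") <- sum(!evaluable)
  }
  list(hyper = calls$probe_id[calls$direction == "hyper"],
       hypo = calls$probe_id[calls$direction == "hypo"],
       n_not_evaluable = attr(calls, "n_not_evaluable"))
}

#' Call triplet epigenetic-memory CpGs
#'
#' A triplet is one fetal organ sample plus the two hiPSC clones derived
#' from it. A CpG carries hypermethylated memory for a triplet when every
#' triplet member exceeds every member of every other triplet by more than
#' the cutoff (hypomethylated symmetric). Such marks are residual
#' tissue-of-origin methylation surviving reprogramming.
#'
#' @param m Beta matrix.
#' @param sheet Sample sheet; each triplet is keyed by the clones'
#'   `origin_organ`.
#' @param config A [signature_config()].
#' @param manifest Optional annotated manifest; adds genic category and
#'   nearest gene to the calls.
#' @return data.frame of calls per triplet with attribute
#'   `n_not_evaluable`.
#' @export
call_triplet_memory <- function(m, sheet, config = signature_config(),
                                manifest = NULL) {
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(m), ]
  orgs <- sort(unique(sheet$origin_organ[sheet$class == "hipsc_clone"]))
  members <- lapply(orgs, function(o) {
    c(sheet$sample_id[sheet$class == "fetal_organ" & sheet$organ == o],
      sheet$sample_id[sheet$class == "hipsc_clone" & sheet$origin_organ == o])
  })
  names(members) <- orgs
  bad <- vapply(members, length, 1L) != 3L
  if (any(bad))
    stop_("triplet(s) without exactly 1 organ + 2 clones: %s",
          collapse_ids(orgs[bad]))
  all_cols <- match(unlist(members), colnames(m))
  res <- lapply(orgs, function(o) {
    gc <- match(members[[o]], colnames(m))
    call_group_vs_rest(m, gc, setdiff(all_cols, gc), config$cutoff, o)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(manifest)) {
    i <- match(out$probe_id, manifest$probe_id)
    out$genic <- manifest$genic[i]
    out$nearest_gene <- manifest$nearest_gene[i]
  }
  attr(out, "n_not_evaluable") <-
    if (length(res)) attr(res[[1L]], "n_not_evaluable") else 0L
  class(out) <- c("signature_calls", class(out))
  out
}

#' @export
print.signature_calls <- function(x, ...) {
  cat(sprintf("signature calls: %d (%d hyper, %d hypo) across %d group(s)\n",
              nrow(x), sum(x$direction == "hyper"), sum(x$direction == "hypo"),
              length(unique(x$group))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Per-group call counts
#'
#' @param calls A `signature_calls` data.frame.
#' @return data.frame `group`, `direction`, `n`.
#' @export
signature_counts <- function(calls) {
  if (!nrow(calls))
    return(data.frame(group = character(), direction = character(),
                      n = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n = seq_len(nrow(calls))),
                          by = list(group = calls$group,
                                    direction = calls$direction),
                          FUN = length)
  agg[order(agg$group, agg$direction), , drop = FALSE]
}

#' Write signature calls as TSV (and optionally BED5)
#'
#' @param calls `signature_calls` data.frame.
#' @param manifest Annotated manifest for coordinates/annotation columns.
#' @param path TSV output path.
#' @param bed_path Optional BED5 output path (0-based half-open).
#' @export
write_signature_calls <- function(calls, manifest, path, bed_path = NULL) {
  i <- match(calls$probe_id, manifest$probe_id)
  out <- data.frame(probe_id = calls$probe_id,
                    chrom = manifest$chrom[i],
                    pos = manifest$pos[i],
                    group = calls$group,
                    direction = calls$direction,
                    min_pairwise_delta = calls$min_pairwise_delta,
                    genic = manifest$genic[i] %||% NA,
                    cgi = manifest$cgi[i] %||% NA,
                    nearest_gene = manifest$nearest_gene[i] %||% NA,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = out$chrom, start = out$pos - 1L, end = out$pos,
                      name = paste0(out$group, ":", out$direction),
                      score = round(1000 * abs(out$min_pairwise_delta)))
    write_intervals(bed[order(bed$chrom, bed$start), ], bed_path)
  }
  invisible(path)
}
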