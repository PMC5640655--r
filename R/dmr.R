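#' DMR-calling parameters
#'
#' A differentially methylated region is a run of at least `min_core`
#' consecutive CpGs sharing a feature (hyper- or hypomethylation for one
#' group), with at most `max_gap_bp` between every pair of adjacent probes
#' in the region and at most `max_interrupt` probes inside it that lack
#' the feature. "Consecutive" is read on the ladder of all measured
#' probes, so interrupting probes are real array probes lying between
#' feature probes.
#'
#' @param min_core Minimum feature probes (default 3).
#' @param max_gap_bp Maximum adjacent-probe gap in bp (default 1000).
#' @param max_interrupt Maximum non-feature probes per region (default 3).
#' @return List of class `dmr_params`.
#' @export
dmr_params <- function(min_core = 3L, max_gap_bp = 1000L, max_interrupt = 3L) {
  if (min_core < 2L) stop_("min_core must be >= 2")
  if (max_gap_bp <= 0) stop_("max_gap_bp must be > 0")
  if (max_interrupt < 0L) stop_("max_interrupt must be >= 0")
  structure(list(min_core = as.integer(min_core),
                 max_gap_bp = as.integer(max_gap_bp),
                 max_interrupt = as.integer(max_interrupt)),
            class = "dmr_params")
}

#' @noRd
dmr_row <- function(chrom, pos, ids, feat, s, e, group, direction, opp) {
  core <- which(feat[s:e]) + s - 1L
  intr <- which(!feat[s:e]) + s - 1L
  list(chrom = chrom,
       start = pos[s], end = pos[e],
       group = group, direction = direction,
       n_core = length(core), n_interrupting = length(intr),
       core_probes = collapse_ids(ids[core]),
       interrupting_probes = collapse_ids(ids[intr]),
       opposite_interrupt = any(opp[intr]))
}

#' @noRd
dmr_rows_to_df <- function(rows) {
  grab <- function(f, what) vapply(rows, `[[`, f, what)
  data.frame(chrom = grab("", "chrom"),
             start = grab(1L, "start"), end = grab(1L, "end"),
             group = grab("", "group"), direction = grab("", "direction"),
             n_core = grab(1L, "n_core"),
             n_interrupting = grab(1L, "n_interrupting"),
             core_probes = grab("", "core_probes"),
             interrupting_probes = grab("", "interrupting_probes"),
             opposite_interrupt = grab(TRUE, "opposite_interrupt"),
             stringsAsFactors = FALSE)
}

# scan one chromosome ladder for one group x direction.
# pos sorted ascending; feat logical per ladder probe; opp marks ladder
# probes carrying the opposite-direction call for the same group.
#' @noRd
scan_ladder <- function(chrom, pos, ids, feat, opp, params) {
  n <- length(pos)
  if (!any(feat)) return(NULL)
  gaps <- diff(pos)
  block <- cumsum(c(0L, gaps > params$max_gap_bp))   # gap rule partitions
  nonfeat_cum <- cumsum(!feat)
  count_interrupt <- function(s, e)
    nonfeat_cum[e] - nonfeat_cum[s] + as.integer(!feat[s])
  rows <- list()
  cores <- which(feat)
  ci <- 1L
  while (ci <= length(cores)) {
    s <- cores[ci]
    # furthest ladder index reachable from s within block + interrupt budget
    # (the interruption count is monotone in the endpoint)
    lim <- max(which(block == block[s]))
    idx <- s:lim
    ok <- (nonfeat_cum[idx] - nonfeat_cum[s] + as.integer(!feat[s])) <=
      params$max_interrupt
    e_max <- idx[max(which(ok))]
    e_core <- max(cores[cores <= e_max])   # region must end on a core probe
    n_core <- sum(feat[s:e_core])
    if (n_core >= params$min_core) {
      rows[[length(rows) + 1L]] <-
        dmr_row(chrom, pos, ids, feat, s, e_core, NA_character_,
                NA_character_, opp)
      ci <- which(cores > e_core)[1L]
      if (is.na(ci)) break
    } else {
      ci <- ci + 1L
    }
  }
  rows
}

#' @noRd
split_calls <- function(calls) {
  if (!nrow(calls)) return(list())
  key <- paste(calls$group, calls$direction, sep = "\r")
  split(calls, key)
}

#' Call DMRs from per-probe signature calls
#'
#' Greedy left-to-right maximal-region scan per group and direction over
#' the full measured probe ladder of the manifest. A region is emitted iff
#' it contains at least `min_core` feature probes, every adjacent probe
#' pair inside it (feature or not) is at most `max_gap_bp` apart, and it
#' spans at most `max_interrupt` non-feature probes. Region boundaries are
#' the positions of the first and last core probe. Regions never overlap
#' within one group x direction; output is sorted by (chrom, start).
#'
#' @param calls `signature_calls` data.frame (probe_id, group, direction).
#' @param manifest Probe manifest with positions for *all* measured probes
#'   (interruptions are defined against the full ladder).
#' @param params A [dmr_params()] object.
#' @return data.frame of DMRs with core/interrupting probe bookkeeping and
#'   a flag marking interrupting probes that carry the opposite feature.
#' @export
call_dmrs <- function(calls, manifest, params = dmr_params()) {
  missing_probes <- setdiff(calls$probe_id, manifest$probe_id)
  if (length(missing_probes))
    stop_("call probe(s) missing from manifest: %s",
          collapse_ids(utils::head(missing_probes, 10L)))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      group = character(), direction = character(),
                      n_core = integer(), n_interrupting = integer(),
                      core_probes = character(), interrupting_probes = character(),
                      opposite_interrupt = logical(), stringsAsFactors = FALSE)
  groups <- split_calls(calls)
  if (!length(groups)) return(empty)
  res <- list()
  for (g in groups) {
    group <- g$group[1L]; direction <- g$direction[1L]
    opposite <- calls$probe_id[calls$group == group &
                               calls$direction != direction]
    for (ch in unique(manifest$chrom)) {
      lad <- manifest[manifest$chrom == ch, , drop = FALSE]
      lad <- lad[order(lad$pos, lad$probe_id), , drop = FALSE]
      feat <- lad$probe_id %in% g$probe_id
      opp <- lad$probe_id %in% opposite
      for (r in scan_ladder(ch, lad$pos, lad$probe_id, feat, opp, params)) {
        r$group <- group
        r$direction <- direction
        res[[length(res) + 1L]] <- r
      }
    }
  }
  if (!length(res)) return(empty)
  out <- dmr_rows_to_df(res)
  out <- out[order(out$group, out$direction, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Brute-force DMR reference (testing oracle)
#'
#' Enumerates every candidate window with core-probe endpoints, filters by
#' the three rules (core count, adjacent gap, interruption budget), keeps
#' maximal non-nested survivors and resolves overlaps by earliest start.
#' Intended for tests; refuses manifests above 10,000 probes.
#'
#' @inheritParams call_dmrs
#' @return data.frame in the same shape as [call_dmrs()].
#' @export
dmr_oracle <- function(calls, manifest, params = dmr_params()) {
  if (nrow(manifest) > 10000L)
    stop_("dmr_oracle is a testing reference; manifest exceeds 10,000 probes")
  missing_probes <- setdiff(calls$probe_id, manifest$probe_id)
  if (length(missing_probes))
    stop_("call probe(s) missing from manifest: %s",
          collapse_ids(utils::head(missing_probes, 10L)))
  res <- list()
  for (g in split_calls(calls)) {
    group <- g$group[1L]; direction <- g$direction[1L]
    opposite <- calls$probe_id[calls$group == group &
                               calls$direction != direction]
    for (ch in unique(manifest$chrom)) {
      lad <- manifest[manifest$chrom == ch, , drop = FALSE]
      lad <- lad[order(lad$pos, lad$probe_id), , drop = FALSE]
      pos <- lad$pos; ids <- lad$probe_id
      feat <- ids %in% g$probe_id
      opp <- ids %in% opposite
      cores <- which(feat)
      # enumerate, for every core start, all core ends satisfying the gap
      # partition, interruption budget and core count, via prefix sums
      blk <- cumsum(c(0L, diff(pos) > params$max_gap_bp))
      nf <- cumsum(!feat)
      cc <- cumsum(feat)
      valid <- list()
      for (s in cores) {
        e_ok <- cores[cores >= s & blk[cores] == blk[s] &
                      (nf[cores] - nf[s]) <= params$max_interrupt &
                      (cc[cores] - cc[s] + 1L) >= params$min_core]
        if (length(e_ok))
          valid[[length(valid) + 1L]] <- cbind(s, e_ok)
      }
      if (!length(valid)) next
      vm <- do.call(rbind, valid)
      # earliest-starting window wins (ties: the longest, i.e. the maximal
      # extension from that start); windows overlapping an emitted region
      # are discarded and the remainder reconsidered
      vm <- vm[order(vm[, 1L], -vm[, 2L]), , drop = FALSE]
      while (nrow(vm)) {
        s <- vm[1L, 1L]; e <- vm[1L, 2L]
        res[[length(res) + 1L]] <-
          dmr_row(ch, pos, ids, feat, s, e, group, direction, opp)
        vm <- vm[vm[, 1L] > e, , drop = FALSE]
      }
    }
  }
  if (!length(res))
    return(call_dmrs(calls[0, , drop = FALSE], manifest, params))
  out <- dmr_rows_to_df(res)
  out <- out[order(out$group, out$direction, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Map DMRs to their nearest locus
#'
#' The nearest gene of a DMR is the annotated nearest gene of the core
#' probe with the smallest absolute TSS distance; ties across distinct
#' genes are broken by the lexicographically smallest gene id and flagged.
#' The genic category is the majority category of the core probes (ties
#' resolved in IG < DP < PP < GB < DS order).
#'
#' @param dmrs Output of [call_dmrs()].
#' @param manifest Annotated manifest.
#' @return `dmrs` with `nearest_gene`, `genic`, `tss_distance` and
#'   `tie_flag` columns appended.
#' @export
map_dmr_to_gene <- function(dmrs, manifest) {
  if (is.null(manifest$nearest_gene))
    stop_("manifest is not annotated; run annotate_manifest() first")
  n <- nrow(dmrs)
  dmrs$nearest_gene <- NA_character_
  dmrs$genic <- NA_character_
  dmrs$tss_distance <- NA_integer_
  dmrs$tie_flag <- FALSE
  for (i in seq_len(n)) {
    core <- strsplit(dmrs$core_probes[i], ";", fixed = TRUE)[[1L]]
    j <- match(core, manifest$probe_id)
    d <- abs(manifest$tss_distance[j])
    if (all(is.na(d))) next
    dmin <- min(d, na.rm = TRUE)
    cand_genes <- sort(unique(manifest$nearest_gene[j][!is.na(d) & d == dmin]))
    dmrs$nearest_gene[i] <- cand_genes[1L]
    dmrs$tss_distance[i] <- dmin
    dmrs$tie_flag[i] <- length(cand_genes) > 1L
    tab <- table(factor(manifest$genic[j], levels = GENIC_LEVELS))
    dmrs$genic[i] <- names(tab)[which.max(tab)]
  }
  dmrs
}

#' Write DMRs as BED6 and TSV
#'
#' BED uses 0-based half-open coordinates: start = first core position - 1,
#' end = last core position (i.e. last core base included).
#'
#' @param dmrs DMR data.frame.
#' @param path TSV path.
#' @param bed_path Optional BED6 path.
#' @export
write_dmrs <- function(dmrs, path, bed_path = NULL) {
  write_tsv(dmrs, path)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                      end = dmrs$end,
                      name = paste0(dmrs$group, ":", dmrs$direction),
                      score = dmrs$n_core, strand = ".",
                      stringsAsFactors = FALSE)
    write_intervals(bed[order(bed$chrom, bed$start), ], bed_path)
  }
  invisible(path)
}
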