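#' Odds-ratio enrichment of a call set across categories
#'
#' For each category, builds the 2x2 table (a = calls in category, b =
#' calls outside, c = non-call universe probes in category, d = non-call
#' probes outside) and reports the odds ratio OR = (a/b)/(c/d) with a
#' chi-squared test (no continuity correction by default). When a zero
#' cell occurs, the Haldane-Anscombe 0.5 correction is applied to the OR
#' only and flagged; the test is still computed on the raw table. The
#' universe should be the QC-surviving probe set of the analysis that
#' produced the calls, since calls are only possible among evaluable
#' probes.
#'
#' @param calls Character vector of called probe ids (subset of universe).
#' @param universe Character vector of all evaluable probe ids.
#' @param categories Named character vector: category per universe probe
#'   (names = probe ids), or a data.frame with `probe_id` and `category`.
#' @param method "chisq" (default, no Yates), "yates", or "fisher".
#' @return data.frame per category: counts, `odds_ratio`, `p`,
#'   `p_bonferroni`, `zero_cell`.
#' @export
category_enrichment <- function(calls, universe, categories,
                                method = c("chisq", "yates", "fisher")) {
  method <- match.arg(method)
  if (is.data.frame(categories)) {
    categories <- stats::setNames(as.character(categories$category),
                                  categories$probe_id)
  }
  bad <- setdiff(calls, universe)
  if (length(bad))
    stop_("call set is not a subset of the universe (%d offender(s), e.g. %s)",
          length(bad), collapse_ids(utils::head(bad, 5L)))
  cat_u <- categories[universe]
  if (anyNA(cat_u)) stop_("category map does not cover the universe")
  in_set <- universe %in% calls
  res <- lapply(sort(unique(cat_u)), function(cc) {
    in_cat <- cat_u == cc
    a <- sum(in_set & in_cat); b <- sum(in_set & !in_cat)
    c_ <- sum(!in_set & in_cat); d <- sum(!in_set & !in_cat)
    zero <- any(c(a, b, c_, d) == 0L)
    or <- if (zero) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
          else (a * d) / (b * c_)
    tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE)
    p <- if (method == "fisher") stats::fisher.test(tab)$p.value
      else if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) NA_real_
      else suppressWarnings(
        stats::chisq.test(tab, correct = method == "yates")$p.value)
    data.frame(category = cc, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p = p, zero_cell = zero,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  rownames(out) <- NULL
  out
}

#' Chromatin-state enrichment of a call set
#'
#' Maps every universe probe to the chromatin-state segment containing
#' its single-base position (probes outside any segment get the state
#' "unsegmented") and computes per-state odds ratios as in
#' [category_enrichment()].
#'
#' @param calls,universe Probe id vectors (`calls` a subset of `universe`).
#' @param segmentation Labeled intervals (data.frame `chrom`, `start`,
#'   `end`, `name`; 0-based half-open, e.g. a Roadmap ChromHMM BED4).
#' @param manifest Probe manifest with positions.
#' @inheritParams category_enrichment
#' @return data.frame per state, as [category_enrichment()].
#' @export
chromatin_state_enrichment <- function(calls, universe, segmentation,
                                       manifest,
                                       method = c("chisq", "yates", "fisher")) {
  if (is.null(segmentation) || !nrow(segmentation))
    stop_("segmentation is empty")
  if (is.null(segmentation$name))
    stop_("segmentation must carry state labels (4th BED column)")
  i <- match(universe, manifest$probe_id)
  if (anyNA(i)) stop_("universe probe(s) missing from manifest")
  state <- rep("unsegmented", length(universe))
  for (ch in unique(manifest$chrom[i])) {
    sel <- which(manifest$chrom[i] == ch)
    seg <- segmentation[segmentation$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    ir <- IRanges::IRanges(seg$start + 1L, seg$end)   # 1-based closed
    pr <- IRanges::IRanges(manifest$pos[i][sel], manifest$pos[i][sel])
    ov <- IRanges::findOverlaps(pr, ir, select = "first")
    hit <- !is.na(ov)
    state[sel[hit]] <- seg$name[ov[hit]]
  }
  category_enrichment(calls, universe,
                      stats::setNames(state, universe), method = method)
}
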