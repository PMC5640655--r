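# Independent reference implementations used to cross-check the package's
# vectorized/greedy code paths. Deliberately written as plain enumerations.

# naive per-(probe, group, other-group) signature caller on a matrix of
# per-group columns built from a sample sheet
naive_signature_oracle <- function(m, group_of, cutoff) {
  groups <- sort(unique(group_of))
  gm <- sapply(groups, function(g)
    apply(m[, group_of == g, drop = FALSE], 1L, mean))
  rownames(gm) <- rownames(m)
  rows <- list()
  for (p in rownames(m)) {
    if (anyNA(gm[p, ])) next
    for (g in groups) {
      hyper_ok <- TRUE; hypo_ok <- TRUE
      worst_hyper <- Inf; worst_hypo <- -Inf
      for (o in setdiff(groups, g)) {
        d <- gm[p, g] - gm[p, o]
        if (d <= cutoff) hyper_ok <- FALSE
        if (d >= -cutoff) hypo_ok <- FALSE
        worst_hyper <- min(worst_hyper, d)
        worst_hypo <- max(worst_hypo, d)
      }
      if (hyper_ok)
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = p, group = g, direction = "hyper",
          min_pairwise_delta = worst_hyper, stringsAsFactors = FALSE)
      if (hypo_ok)
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = p, group = g, direction = "hypo",
          min_pairwise_delta = worst_hypo, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(probe_id = character(), group = character(),
                      direction = character(), min_pairwise_delta = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

sort_calls <- function(x) {
  x <- as.data.frame(x)[c("probe_id", "group", "direction",
                          "min_pairwise_delta")]
  x <- x[order(x$probe_id, x$group, x$direction), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# brute-force genic assignment: scan every gene, pick the nearest TSS
# (ties: smallest gene id), then look the signed distance up in an
# explicit window table for that gene
genic_oracle_one <- function(p, ch, genes) {
  g <- genes[genes$chrom == ch, , drop = FALSE]
  if (!nrow(g)) return(list(category = "IG", gene_id = NA, distance = NA))
  best <- NULL
  for (i in seq_len(nrow(g))) {
    ad <- abs(g$tss[i] - p)
    if (is.null(best) || ad < best$ad ||
        (ad == best$ad && g$gene_id[i] < best$gene))
      best <- list(ad = ad, gene = g$gene_id[i], i = i)
  }
  gi <- g[best$i, ]
  d <- if (gi$strand == "+") p - gi$tss else gi$tss - p
  len <- abs(gi$end3 - gi$tss)
  windows <- list(DP = c(-10000, -1501), PP = c(-1500, 500),
                  GB = c(501, len), DS = c(len + 1, len + 5000))
  cat <- "IG"
  for (w in names(windows))
    if (d >= windows[[w]][1L] && d <= windows[[w]][2L]) { cat <- w; break }
  list(category = cat, gene_id = gi$gene_id, distance = d)
}

# exhaustive DMR window enumeration with maximality + earliest-start
# selection; cumulative sums only, no streaming scan
dmr_window_oracle <- function(calls, manifest, params) {
  res <- list()
  key <- paste(calls$group, calls$direction, sep = "\r")
  for (kk in unique(key)) {
    g <- calls[key == kk, , drop = FALSE]
    for (ch in unique(manifest$chrom)) {
      lad <- manifest[manifest$chrom == ch, , drop = FALSE]
      lad <- lad[order(lad$pos, lad$probe_id), , drop = FALSE]
      feat <- lad$probe_id %in% g$probe_id
      cores <- which(feat)
      if (length(cores) < params$min_core) next
      blk <- cumsum(c(0L, diff(lad$pos) > params$max_gap_bp))
      nf <- cumsum(!feat)
      cand <- list()
      for (s in cores) {
        e_ok <- cores[cores >= s & blk[cores] == blk[s] &
                      (nf[cores] - nf[s] + !feat[s]) <= params$max_interrupt]
        ncore <- vapply(e_ok, function(e) sum(feat[s:e]), 1L)
        e_ok <- e_ok[ncore >= params$min_core]
        if (length(e_ok)) cand[[length(cand) + 1L]] <- c(s, max(e_ok))
      }
      if (!length(cand)) next
      # one candidate per start (its maximal extension); earliest start
      # wins, overlapping candidates drop out, remainder reconsidered
      vm <- unique(do.call(rbind, cand))
      vm <- vm[order(vm[, 1L]), , drop = FALSE]
      while (nrow(vm)) {
        s <- vm[1L, 1L]; e <- vm[1L, 2L]
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = lad$pos[s], end = lad$pos[e],
          group = g$group[1L], direction = g$direction[1L],
          n_core = sum(feat[s:e]), n_interrupting = sum(!feat[s:e]),
          stringsAsFactors = FALSE)
        vm <- vm[vm[, 1L] > e, , drop = FALSE]
      }
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), group = character(),
                      direction = character(), n_core = integer(),
                      n_interrupting = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$group, out$direction, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

dmr_core_cols <- function(d)
  d[c("chrom", "start", "end", "group", "direction", "n_core",
      "n_interrupting")]

# a synthetic enrichment universe realising the 2x2 table (a, b, c, d)
build_universe <- function(a, b, c_, d, cat = "X", other = "Y") {
  n <- a + b + c_ + d
  ids <- sprintf("cg%05d", seq_len(n))
  categories <- stats::setNames(
    c(rep(cat, a), rep(other, b), rep(cat, c_), rep(other, d)), ids)
  list(calls = ids[seq_len(a + b)], universe = ids, categories = categories)
}

# exact 2x2 chi-squared statistic and p from first principles
chi2_oracle <- function(a, b, c_, d) {
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
  n <- sum(tab)
  exp_ <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - exp_)^2 / exp_)
  list(stat = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

# random DMR test instance: probe ladder with mixed gaps and random
# feature labels, sometimes several groups/directions
random_dmr_instance <- function(n_probes, n_groups = 1L) {
  gaps <- sample(c(40L, 150L, 400L, 900L, 1001L, 2500L), n_probes,
                 replace = TRUE, prob = c(.25, .25, .2, .1, .1, .1))
  man <- data.frame(probe_id = sprintf("p%04d", seq_len(n_probes)),
                    chrom = "chr1", pos = 1000L + cumsum(gaps),
                    stringsAsFactors = FALSE)
  rows <- list()
  for (g in seq_len(n_groups)) for (dir in c("hyper", "hypo")) {
    sel <- stats::runif(n_probes) < stats::runif(1, 0.2, 0.6)
    if (dir == "hypo" && n_groups == 1L && stats::runif(1) < 0.5) next
    if (any(sel))
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = man$probe_id[sel], group = paste0("org", g),
        direction = dir, stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), group = character(),
               direction = character(), stringsAsFactors = FALSE)
  list(manifest = man, calls = calls)
}
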