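DEFAULT_ORGANS <- c("adrenal", "brain", "eye", "heart_atrium",
                    "heart_ventricle", "intestine", "kidney", "liver",
                    "lung", "muscle", "pancreas", "skin", "stomach",
                    "tongue")
TRIPLET_ORGANS <- c("brain", "kidney", "lung", "muscle", "pancreas", "skin")

#' Synthetic-study configuration
#'
#' Defines the structure of the simulated methylation study: a probe
#' ladder mixing CGI-dense clusters (tight spacing, so planted DMR runs
#' satisfy the 1 kb gap rule by construction) with sparse background; an
#' isogenic set of 14 organs with planted organ-specific CpGs and DMR
#' runs at +/-0.4 beta effect; a 6-triplet iPSC study (one organ + two
#' clones each) with a global pluripotency barcode and organ-specific
#' memory CpGs in one designated triplet (18 hyper + 6 hypo by default);
#' and organ-unique DEG tables whose genes carry coupled promoter /
#' gene-body delta-beta shifts of magnitude 0.3. Noise is logit-normal
#' (additive Gaussian on the logit of beta, sd `sigma`), which respects
#' the \[0, 1\] support; baseline betas come from a bimodal mixture with
#' modes near 0.1 and 0.9, mimicking the typical 450K beta distribution.
#'
#' @param n_probes Total probes (default 2000).
#' @param n_chromosomes Chromosomes (default 2).
#' @param organs Organ labels of the isogenic set (default 14 organs).
#' @param n_planted_per_organ Planted single organ-specific CpGs per organ
#'   per direction (default 4).
#' @param effect Planted beta shift (default 0.4).
#' @param n_planted_dmrs Planted DMR runs per organ per direction
#'   (default 1).
#' @param dmr_run_range Run length range of planted DMRs (default 3..8).
#' @param triplet_organs Six organs of origin for the iPSC study.
#' @param n_barcode_hyper,n_barcode_hypo Pluripotency-barcode CpGs
#'   (defaults 30 / 10).
#' @param memory_triplet Organ of the memory-bearing triplet ("brain").
#' @param n_memory_hyper,n_memory_hypo Memory CpGs in that triplet
#'   (defaults 18 / 6).
#' @param sigma Logit-scale noise sd (default 0.05; 0 = noiseless).
#' @param baseline_modes,baseline_weights,baseline_logit_sd Bimodal
#'   baseline mixture parameters.
#' @param n_genes Total gene models (default 120).
#' @param n_deg_per_organ Organ-unique DEGs per organ per direction
#'   (default 3).
#' @param deg_coupling Fraction of organ-unique DEGs given methylation
#'   coupling (default 1).
#' @param deg_pp_delta,deg_gb_delta Coupled delta-beta magnitudes
#'   (default 0.3 each): up-DEGs get PP -delta / GB +delta, down-DEGs the
#'   opposite.
#' @param cluster_prob Fraction of probes laid down in dense clusters
#'   (default 0.4).
#' @param cgi_fraction Fraction of clusters covered by a CpG island
#'   (default 0.5).
#' @param seed Base seed; every generator derives its stream from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000L, n_chromosomes = 2L,
                       organs = DEFAULT_ORGANS,
                       n_planted_per_organ = 4L, effect = 0.4,
                       n_planted_dmrs = 1L, dmr_run_range = c(3L, 8L),
                       triplet_organs = TRIPLET_ORGANS,
                       n_barcode_hyper = 30L, n_barcode_hypo = 10L,
                       memory_triplet = "brain",
                       n_memory_hyper = 18L, n_memory_hypo = 6L,
                       sigma = 0.05,
                       baseline_modes = c(0.1, 0.9),
                       baseline_weights = c(0.5, 0.5),
                       baseline_logit_sd = 0.5,
                       n_genes = 120L, n_deg_per_organ = 3L,
                       deg_coupling = 1, deg_pp_delta = 0.3,
                       deg_gb_delta = 0.3,
                       cluster_prob = 0.4, cgi_fraction = 0.5,
                       seed = 1L) {
  assert_scalar_number(effect, "effect", 0, 1)
  assert_scalar_number(sigma, "sigma", lower = 0)
  assert_scalar_number(deg_coupling, "deg_coupling", 0, 1)
  if (!memory_triplet %in% triplet_organs)
    stop_("memory_triplet must be one of the triplet organs")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic probe manifest, gene models and CGI track
#'
#' Lays down a sorted probe ladder per chromosome as a mixture of dense
#' clusters (adjacent spacing 50-300 bp) and sparse background probes
#' (1.2-8 kb spacing, so background gaps break the DMR gap rule), places
#' stranded gene models along the chromosomes, and covers a fraction of
#' the clusters with CpG islands. Fully deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_manifest`: `manifest` (probe_id, chrom,
#'   pos), `genes`, `cgis` (0-based half-open), `clusters` (list of probe
#'   id vectors).
#' @export
generate_manifest <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  per_chrom <- ceiling(cfg$n_probes / cfg$n_chromosomes)
  rows <- list(); cgis <- list(); clusters <- list()
  pid <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    ch <- paste0("chr", ci)
    pos <- integer(0); p <- 10000L
    clu_members <- list()
    # cluster_prob is the target *probe* fraction in clusters; convert to
    # the per-unit draw probability given the mean cluster size of 7.5
    q_unit <- cfg$cluster_prob / (7.5 * (1 - cfg$cluster_prob) + cfg$cluster_prob)
    while (length(pos) < per_chrom) {
      if (stats::runif(1) < q_unit) {
        k <- sample(5:10, 1L)
        k <- min(k, per_chrom - length(pos))
        # clusters are isolated by a > 1 kb gap on both sides so planted
        # runs never abut planted singles on the probe ladder
        base <- p + as.integer(stats::runif(1, 1200, 8000))
        steps <- as.integer(stats::runif(max(k - 1L, 0L), 50, 300))
        newp <- base + c(0L, cumsum(steps))
        if (k >= 2L) clu_members[[length(clu_members) + 1L]] <-
          length(pos) + seq_len(k)
        pos <- c(pos, newp)
        p <- newp[length(newp)]
      } else {
        p <- p + as.integer(stats::runif(1, 1200, 8000))
        pos <- c(pos, p)
      }
    }
    pos <- pos[seq_len(per_chrom)]
    ids <- sprintf("cg%08d", pid + seq_along(pos))
    pid <- pid + length(pos)
    rows[[ci]] <- data.frame(probe_id = ids, chrom = ch, pos = pos,
                             stringsAsFactors = FALSE)
    for (cm in clu_members) {
      cm <- cm[cm <= length(pos)]
      if (length(cm) < 2L) next
      clusters[[length(clusters) + 1L]] <- ids[cm]
      if (stats::runif(1) < cfg$cgi_fraction)
        cgis[[length(cgis) + 1L]] <-
          data.frame(chrom = ch, start = max(0L, min(pos[cm]) - 101L),
                     end = max(pos[cm]) + 100L, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  span <- stats::aggregate(pos ~ chrom, manifest, max)
  genes <- list()
  per_chrom_genes <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  gid <- 0L
  for (ci in seq_len(cfg$n_chromosomes)) {
    ch <- paste0("chr", ci)
    hi <- span$pos[span$chrom == ch]
    tss <- sort(sample(seq(15000L, max(hi, 30000L), by = 997L),
                       per_chrom_genes))
    strand <- sample(c("+", "-"), per_chrom_genes, replace = TRUE)
    len <- as.integer(stats::runif(per_chrom_genes, 3000, 20000))
    end3 <- ifelse(strand == "+", tss + len, pmax(1L, tss - len))
    genes[[ci]] <- data.frame(
      gene_id = sprintf("GENE%04d", gid + seq_len(per_chrom_genes)),
      chrom = ch, strand = strand, tss = as.integer(tss),
      end3 = as.integer(end3), stringsAsFactors = FALSE)
    gid <- gid + per_chrom_genes
  }
  genes <- do.call(rbind, genes)
  cgis <- if (length(cgis)) do.call(rbind, cgis) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  structure(list(manifest = manifest, genes = validate_gene_models(genes),
                 cgis = cgis, clusters = clusters),
            class = "sim_manifest")
}

#' @noRd
add_logit_noise <- function(mu, sigma) {
  if (sigma == 0) return(mu)
  stats::plogis(stats::qlogis(squeeze01(mu)) +
                stats::rnorm(length(mu), 0, sigma))
}

#' @noRd
baseline_mu <- function(n, cfg) {
  comp <- sample(seq_along(cfg$baseline_modes), n, replace = TRUE,
                 prob = cfg$baseline_weights)
  stats::plogis(stats::qlogis(cfg$baseline_modes[comp]) +
                stats::rnorm(n, 0, cfg$baseline_logit_sd))
}

#' Generate an isogenic multi-organ beta matrix with planted truth
#'
#' One sample per organ, a shared bimodal baseline, and planted
#' organ-specific CpGs: singles scattered over the ladder and DMR runs of
#' consecutive cluster probes. A hypermethylated plant raises the target
#' organ by `effect` above the (shared) baseline of the other organs;
#' hypomethylated plants are symmetric. Baselines at planted probes are
#' drawn so that the shifted value stays inside \[0, 1\] without clipping.
#' Per-sample logit-normal noise is added on top.
#'
#' @param cfg A [sim_config()].
#' @param sim A [generate_manifest()] result.
#' @return List of class `sim_study`: `beta`, `sheet`, `truth` (planted
#'   CpGs with organ/direction/source and planted DMR intervals).
#' @export
generate_isogenic_betas <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  man <- sim$manifest
  organs <- cfg$organs
  if (length(organs) < 3L) stop_("need >= 3 organs")
  n <- nrow(man)
  mu <- matrix(rep(baseline_mu(n, cfg), length(organs)), ncol = length(organs),
               dimnames = list(man$probe_id, organs))
  used <- character(0)
  truth_cpgs <- list(); truth_dmrs <- list()
  # planted DMR runs: consecutive probes of unused clusters
  avail_clusters <- sim$clusters[sample(length(sim$clusters))]
  take_cluster <- function() {
    for (k in seq_along(avail_clusters)) {
      if (is.null(avail_clusters[[k]])) next
      cl <- avail_clusters[[k]]
      # a planted run must be at least the minimum run length (clusters
      # at the chromosome end can be truncated shorter)
      if (length(cl) < cfg$dmr_run_range[1L]) next
      if (!any(cl %in% used)) { avail_clusters[[k]] <<- NULL; return(cl) }
    }
    stop_("not enough probe clusters for the requested planted DMRs")
  }
  plant <- function(ids, organ, direction) {
    b <- if (direction == "hyper") stats::runif(length(ids), 0.05, 0.55)
         else stats::runif(length(ids), 0.45, 0.95)
    mu[ids, ] <<- b
    shift <- if (direction == "hyper") cfg$effect else -cfg$effect
    mu[ids, organ] <<- b + shift
    used <<- c(used, ids)
  }
  for (o in organs) for (dir in c("hyper", "hypo")) {
    for (r in seq_len(cfg$n_planted_dmrs)) {
      cl <- take_cluster()
      run_len <- sample(seq(cfg$dmr_run_range[1L], cfg$dmr_run_range[2L]), 1L)
      run_len <- min(run_len, length(cl))
      start_at <- sample(seq_len(length(cl) - run_len + 1L), 1L)
      ids <- cl[start_at:(start_at + run_len - 1L)]
      plant(ids, o, dir)
      j <- match(ids, man$probe_id)
      truth_dmrs[[length(truth_dmrs) + 1L]] <-
        data.frame(chrom = man$chrom[j[1L]], start = min(man$pos[j]),
                   end = max(man$pos[j]), group = o, direction = dir,
                   n_core = run_len, probes = collapse_ids(ids),
                   stringsAsFactors = FALSE)
      truth_cpgs[[length(truth_cpgs) + 1L]] <-
        data.frame(probe_id = ids, group = o, direction = dir,
                   source = "dmr", stringsAsFactors = FALSE)
    }
    free <- setdiff(man$probe_id, c(used, unlist(sim$clusters)))
    ids <- sample(free, cfg$n_planted_per_organ)
    plant(ids, o, dir)
    truth_cpgs[[length(truth_cpgs) + 1L]] <-
      data.frame(probe_id = ids, group = o, direction = dir,
                 source = "single", stringsAsFactors = FALSE)
  }
  beta <- matrix(add_logit_noise(mu, cfg$sigma), nrow = n,
                 dimnames = dimnames(mu))
  sheet <- data.frame(sample_id = organs, organ = organs, stage = "W20-22",
                      fetus_id = "F1", class = "fetal_organ", sex = "M",
                      origin_organ = NA_character_, stringsAsFactors = FALSE)
  structure(list(beta = beta, sheet = sheet,
                 truth = list(organ_cpgs = do.call(rbind, truth_cpgs),
                              dmrs = do.call(rbind, truth_dmrs))),
            class = "sim_study")
}

#' Generate a triplet iPSC study with barcode and memory plants
#'
#' Eighteen samples: six fetal organs and two hiPSC clones per organ.
#' Barcode CpGs are shifted in all twelve clones relative to all organs;
#' memory CpGs are shifted only in the designated triplet (its organ and
#' its two clones) relative to the fifteen other samples.
#'
#' @inheritParams generate_isogenic_betas
#' @return List of class `sim_study`: `beta`, `sheet`, `truth` (barcode
#'   hyper/hypo ids, memory calls per triplet).
#' @export
generate_triplet_study <- function(cfg, sim) {
  set.seed(cfg$seed + 2L)
  man <- sim$manifest
  orgs <- cfg$triplet_organs
  clones <- as.vector(t(outer(orgs, c("_iPSC1", "_iPSC2"), paste0)))
  samples <- c(orgs, clones)
  n <- nrow(man)
  mu <- matrix(rep(baseline_mu(n, cfg), length(samples)),
               ncol = length(samples),
               dimnames = list(man$probe_id, samples))
  pool <- sample(man$probe_id)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  plant_shift <- function(ids, cols, direction) {
    b <- if (direction == "hyper") stats::runif(length(ids), 0.05, 0.55)
         else stats::runif(length(ids), 0.45, 0.95)
    mu[ids, ] <<- b
    shift <- if (direction == "hyper") cfg$effect else -cfg$effect
    mu[ids, cols] <<- b + shift
  }
  bc_hyper <- take(cfg$n_barcode_hyper)
  bc_hypo <- take(cfg$n_barcode_hypo)
  plant_shift(bc_hyper, clones, "hyper")
  plant_shift(bc_hypo, clones, "hypo")
  mem_cols <- c(cfg$memory_triplet,
                paste0(cfg$memory_triplet, c("_iPSC1", "_iPSC2")))
  mem_hyper <- take(cfg$n_memory_hyper)
  mem_hypo <- take(cfg$n_memory_hypo)
  plant_shift(mem_hyper, mem_cols, "hyper")
  plant_shift(mem_hypo, mem_cols, "hypo")
  beta <- matrix(add_logit_noise(mu, cfg$sigma), nrow = n,
                 dimnames = dimnames(mu))
  sheet <- rbind(
    data.frame(sample_id = orgs, organ = orgs, stage = "W20-22",
               fetus_id = "F1", class = "fetal_organ", sex = "M",
               origin_organ = NA_character_, stringsAsFactors = FALSE),
    data.frame(sample_id = clones,
               organ = rep(orgs, each = 2L), stage = "PSC",
               fetus_id = "F1", class = "hipsc_clone", sex = "M",
               origin_organ = rep(orgs, each = 2L),
               stringsAsFactors = FALSE))
  memory <- rbind(
    if (length(mem_hyper)) data.frame(probe_id = mem_hyper,
      group = cfg$memory_triplet, direction = "hyper",
      stringsAsFactors = FALSE),
    if (length(mem_hypo)) data.frame(probe_id = mem_hypo,
      group = cfg$memory_triplet, direction = "hypo",
      stringsAsFactors = FALSE))
  structure(list(beta = beta, sheet = sheet,
                 truth = list(barcode = list(hyper = bc_hyper,
                                             hypo = bc_hypo),
                              memory = memory)),
            class = "sim_study")
}

#' Generate an organ-unique DEG table with coupled delta betas
#'
#' Draws disjoint organ-unique DEG sets per organ (FDR < 0.01,
#' |logFC| > 1), plus sub-threshold decoy records and one gene
#' differential in two organs (to exercise the uniqueness filter). A
#' fraction `deg_coupling` of the organ-unique DEGs receives coupled
#' promoter / gene-body delta-beta shifts: up-DEGs lose promoter
#' methylation (PP delta -`deg_pp_delta`) and gain gene-body methylation;
#' down-DEGs the opposite. All other probe deltas are noise around zero
#' (sd `sigma`).
#'
#' @inheritParams generate_isogenic_betas
#' @return List of class `sim_deg`: `degs` (gene_id, organ, logFC, FDR),
#'   `deltas` (probe_id, organ, delta), `gene_chrom`, `manifest`
#'   (annotated), `truth` (coupled gene records).
#' @export
generate_deg_table <- function(cfg, sim) {
  set.seed(cfg$seed + 3L)
  ann <- annotate_manifest(sim$manifest, sim$genes, sim$cgis)
  organs <- cfg$organs
  need <- length(organs) * 2L * cfg$n_deg_per_organ + 3L
  if (need > nrow(sim$genes))
    stop_("more DEGs requested (%d) than genes available (%d)",
          need, nrow(sim$genes))
  pool <- sample(sim$genes$gene_id)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  degs <- list(); truth <- list()
  deltas <- do.call(rbind, lapply(organs, function(o)
    data.frame(probe_id = ann$probe_id, organ = o,
               delta = if (cfg$sigma > 0)
                 pmin(pmax(stats::rnorm(nrow(ann), 0, cfg$sigma), -1), 1)
               else 0,
               stringsAsFactors = FALSE)))
  set_delta <- function(organ, probes, value) {
    sel <- deltas$organ == organ & deltas$probe_id %in% probes
    val <- value + (if (cfg$sigma > 0) stats::rnorm(sum(sel), 0, cfg$sigma) else 0)
    deltas$delta[sel] <<- pmin(pmax(val, -1), 1)
  }
  for (o in organs) for (dir in c("up", "down")) {
    gs <- take(cfg$n_deg_per_organ)
    lfc <- stats::runif(length(gs), 1.5, 4) * if (dir == "up") 1 else -1
    degs[[length(degs) + 1L]] <-
      data.frame(gene_id = gs, organ = o, logFC = lfc,
                 FDR = 10^stats::runif(length(gs), -8, -3),
                 stringsAsFactors = FALSE)
    coupled <- stats::runif(length(gs)) < cfg$deg_coupling
    for (g in gs[coupled]) {
      pr <- gene_region_probes(g, ann, sim$genes)
      pp_shift <- if (dir == "up") -cfg$deg_pp_delta else cfg$deg_pp_delta
      gb_shift <- if (dir == "up") cfg$deg_gb_delta else -cfg$deg_gb_delta
      if (length(pr$pp)) set_delta(o, pr$pp, pp_shift)
      if (length(pr$gb)) set_delta(o, pr$gb, gb_shift)
    }
    truth[[length(truth) + 1L]] <-
      data.frame(gene_id = gs, organ = o, direction = dir,
                 coupled = coupled, stringsAsFactors = FALSE)
  }
  # decoys: sub-threshold records and a gene shared by two organs
  decoy <- take(3L)
  degs[[length(degs) + 1L]] <- data.frame(
    gene_id = c(decoy[1L], decoy[2L], decoy[3L], decoy[3L]),
    organ = c(organs[1L], organs[2L], organs[1L], organs[2L]),
    logFC = c(0.5, 2.5, 2.0, 2.2),
    FDR = c(0.001, 0.5, 0.001, 0.001),
    stringsAsFactors = FALSE)
  structure(list(degs = do.call(rbind, degs),
                 deltas = deltas,
                 gene_chrom = stats::setNames(sim$genes$chrom,
                                              sim$genes$gene_id),
                 manifest = ann,
                 truth = do.call(rbind, truth)),
            class = "sim_deg")
}

#' Write a simulated study to disk
#'
#' Emits the same TSV/BED dialects the package readers consume, plus a
#' `truth.json` with the planted ground truth, so a full pipeline run can
#' start from files alone.
#'
#' @param dir Output directory (created if needed).
#' @param sim A [generate_manifest()] result.
#' @param iso Optional [generate_isogenic_betas()] result.
#' @param triplet Optional [generate_triplet_study()] result.
#' @param deg Optional [generate_deg_table()] result.
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(dir, sim, iso = NULL, triplet = NULL,
                                  deg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_tsv(sim$manifest, fp("manifest.tsv"))
  write_tsv(sim$genes, fp("genes.tsv"))
  if (nrow(sim$cgis)) write_intervals(sim$cgis, fp("cgis.bed"))
  truth <- list()
  if (!is.null(iso)) {
    write_beta_matrix(iso$beta, fp("beta_isogenic.tsv"))
    write_tsv(iso$sheet, fp("samples_isogenic.tsv"))
    truth$isogenic <- iso$truth
  }
  if (!is.null(triplet)) {
    write_beta_matrix(triplet$beta, fp("beta_triplet.tsv"))
    write_tsv(triplet$sheet, fp("samples_triplet.tsv"))
    truth$triplet <- triplet$truth
  }
  if (!is.null(deg)) {
    write_tsv(deg$degs, fp("degs.tsv"))
    write_tsv(deg$deltas, fp("deltas.tsv"))
    truth$deg <- deg$truth
  }
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
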