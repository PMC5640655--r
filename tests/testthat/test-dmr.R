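ladder <- function(pos, chrom = "chr1")
  data.frame(probe_id = sprintf("p%03d", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos), stringsAsFactors = FALSE)

hyper_calls <- function(man, idx, group = "brain")
  data.frame(probe_id = man$probe_id[idx],
             group = rep(group, length(idx)),
             direction = rep("hyper", length(idx)),
             stringsAsFactors = FALSE)

test_that("three consecutive feature CpGs within 1 kb form a DMR", {
  man <- ladder(c(100, 500, 900))
  d <- call_dmrs(hyper_calls(man, 1:3), man)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 100L)
  expect_equal(d$end, 900L)
  expect_equal(d$n_core, 3L)
  expect_equal(d$n_interrupting, 0L)
  expect_identical(d$core_probes, "p001;p002;p003")
})

test_that("a gap above 1 kb splits the candidate run", {
  man <- ladder(c(100, 500, 1700))
  d <- call_dmrs(hyper_calls(man, 1:3), man)
  expect_equal(nrow(d), 0L)
})

test_that("more than three interrupting probes break a region", {
  man <- ladder(c(100, 300, 400, 500, 600, 700, 800, 900, 1000))
  calls <- hyper_calls(man, c(1, 2, 7, 8, 9))
  d <- call_dmrs(calls, man)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 800L)
  expect_equal(d$end, 1000L)
  expect_equal(d$n_core, 3L)
  expect_equal(d$n_interrupting, 0L)
})

test_that("interrupting probes are bookkept and opposite features flagged", {
  man <- ladder(c(100, 300, 500, 700, 900))
  calls <- rbind(hyper_calls(man, c(1, 2, 4, 5)),
                 data.frame(probe_id = "p003", group = "brain",
                            direction = "hypo", stringsAsFactors = FALSE))
  d <- call_dmrs(calls, man)
  hy <- d[d$direction == "hyper", ]
  expect_equal(hy$n_core, 4L)
  expect_equal(hy$n_interrupting, 1L)
  expect_identical(hy$interrupting_probes, "p003")
  expect_true(hy$opposite_interrupt)
})

test_that("degenerate inputs yield no DMRs and bad probes error", {
  man <- ladder(c(100, 500, 900))
  empty <- hyper_calls(man, integer(0))
  expect_equal(nrow(call_dmrs(empty, man)), 0L)
  expect_equal(nrow(dmr_oracle(empty, man)), 0L)
  one <- hyper_calls(man, 1L)
  expect_equal(nrow(call_dmrs(one, man)), 0L)
  expect_equal(nrow(dmr_oracle(one, man)), 0L)
  alien <- data.frame(probe_id = "zz", group = "g", direction = "hyper")
  expect_error(call_dmrs(alien, man), "missing from manifest")
  big <- ladder(seq(1, 20001, by = 2))
  expect_error(dmr_oracle(hyper_calls(big, 1:3), big), "10,000")
})

test_that("greedy caller, package oracle and window oracle agree on random instances", {
  set.seed(11)
  for (rep in 1:60) {
    inst <- random_dmr_instance(sample(30:120, 1L),
                                n_groups = sample(1:2, 1L))
    for (params in list(dmr_params(), dmr_params(3, 500, 1),
                        dmr_params(4, 1000, 0))) {
      got <- call_dmrs(inst$calls, inst$manifest, params)
      orc <- dmr_oracle(inst$calls, inst$manifest, params)
      expect_identical(got, orc)
      win <- dmr_window_oracle(inst$calls, inst$manifest, params)
      expect_identical(dmr_core_cols(got), dmr_core_cols(win))
    }
  }
})

test_that("every emitted DMR satisfies the three rules when re-checked", {
  set.seed(12)
  for (rep in 1:20) {
    inst <- random_dmr_instance(sample(50:200, 1L))
    params <- dmr_params()
    d <- call_dmrs(inst$calls, inst$manifest, params)
    man <- inst$manifest[order(inst$manifest$pos), ]
    for (i in seq_len(nrow(d))) {
      inside <- man[man$pos >= d$start[i] & man$pos <= d$end[i], ]
      feat <- inside$probe_id %in% inst$calls$probe_id[
        inst$calls$group == d$group[i] &
        inst$calls$direction == d$direction[i]]
      expect_gte(sum(feat), params$min_core)
      expect_lte(sum(!feat), params$max_interrupt)
      if (nrow(inside) > 1L)
        expect_lte(max(diff(inside$pos)), params$max_gap_bp)
      expect_true(feat[1L] && feat[length(feat)])
    }
  }
})

test_that("parameter tightening behaves as the rule implies", {
  # raising min_core can only suppress regions; tightening max_gap_bp or
  # max_interrupt can *split* one region into several, so for those the
  # guaranteed property is that stricter-regime DMRs remain valid windows
  # under the laxer constraints
  set.seed(13)
  check_valid <- function(d, inst, params) {
    man <- inst$manifest[order(inst$manifest$pos), ]
    for (i in seq_len(nrow(d))) {
      inside <- man[man$pos >= d$start[i] & man$pos <= d$end[i], ]
      feat <- inside$probe_id %in% inst$calls$probe_id[
        inst$calls$group == d$group[i] &
        inst$calls$direction == d$direction[i]]
      expect_gte(sum(feat), params$min_core)
      expect_lte(sum(!feat), params$max_interrupt)
      if (nrow(inside) > 1L)
        expect_lte(max(diff(inside$pos)), params$max_gap_bp)
    }
  }
  for (rep in 1:15) {
    inst <- random_dmr_instance(sample(50:150, 1L))
    lax <- dmr_params()
    base <- nrow(call_dmrs(inst$calls, inst$manifest, lax))
    expect_lte(nrow(call_dmrs(inst$calls, inst$manifest,
                              dmr_params(min_core = 4))), base)
    check_valid(call_dmrs(inst$calls, inst$manifest,
                          dmr_params(max_gap_bp = 400)), inst, lax)
    check_valid(call_dmrs(inst$calls, inst$manifest,
                          dmr_params(max_interrupt = 1)), inst, lax)
  }
})

test_that("planted DMR runs are recovered with exact boundaries (noiseless)", {
  cfg <- sim_config(seed = 21L, sigma = 0)
  sim <- generate_manifest(cfg)
  iso <- generate_isogenic_betas(cfg, sim)
  calls <- call_organ_specific_cpgs(iso$beta, iso$sheet)
  d <- call_dmrs(calls, sim$manifest)
  k <- function(x) paste(x$chrom, x$start, x$end, x$group, x$direction)
  expect_setequal(k(d), k(iso$truth$dmrs))
})

test_that("DMRs map to the gene nearest a core probe's TSS", {
  genes <- data.frame(gene_id = c("NEAR", "FARAWAY"), chrom = "chr1",
                      strand = "+", tss = c(10000L, 40000L),
                      end3 = c(30000L, 60000L), stringsAsFactors = FALSE)
  man <- ladder(c(12000, 12300, 12600))       # inside NEAR's body
  ann <- annotate_manifest(man, genes, NULL)
  d <- map_dmr_to_gene(call_dmrs(hyper_calls(man, 1:3), ann), ann)
  expect_identical(d$nearest_gene, "NEAR")
  expect_identical(d$genic, "GB")
  expect_false(d$tie_flag)
  # equidistant from two TSSs: lexicographic winner, flagged
  genes2 <- data.frame(gene_id = c("BBB", "AAA"), chrom = "chr1",
                       strand = "+", tss = c(10000L, 30000L),
                       end3 = c(12000L, 32000L), stringsAsFactors = FALSE)
  man2 <- ladder(c(19800, 20000, 20200))
  ann2 <- annotate_manifest(man2, genes2, NULL)
  d2 <- map_dmr_to_gene(call_dmrs(hyper_calls(man2, 1:3), ann2), ann2)
  expect_identical(d2$nearest_gene, "AAA")
  expect_true(d2$tie_flag)
})
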