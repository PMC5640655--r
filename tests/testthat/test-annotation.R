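one_gene <- function(strand = "+", tss = 100000L, end3 = 120000L,
                     id = "G1", chrom = "chr1") {
  data.frame(gene_id = id, chrom = chrom, strand = strand,
             tss = tss, end3 = end3, stringsAsFactors = FALSE)
}

test_that("genic windows follow the five-region definition around the TSS", {
  g <- one_gene()                                   # + strand, 20 kb body
  a <- assign_genic_region(c(99000L, 88000L, 99900L, 100400L, 101000L,
                             118000L, 123000L, 126000L),
                           rep("chr1", 8L), g)
  expect_identical(a$category,
                   c("PP",   # -1000, proximal promoter
                     "IG",   # -12000, beyond the 10 kb window
                     "PP",   # -100
                     "PP",   # +400 (PP reaches +500)
                     "GB",   # +1000, inside the body
                     "GB",   # +18000, still inside the 20 kb body
                     "DS",   # 3 kb past the 3' end
                     "IG"))  # past the downstream window
  expect_equal(a$distance[1:2], c(-1000L, -12000L))

  # minus-strand gene: body runs from tss downward
  gm <- one_gene(strand = "-", tss = 50000L, end3 = 40000L)
  b <- assign_genic_region(c(49000L, 51000L, 50200L), rep("chr1", 3L), gm)
  expect_identical(b$category, c("GB", "PP", "PP"))
  expect_equal(b$distance, c(1000L, -1000L, -200L))
})

test_that("CGI, shore, shelf assignment measures distance to island edges", {
  cgis <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  cats <- assign_cgi_region(c(10500L, 11500L, 14500L, 16000L, 9000L, 5000L),
                            rep("chr1", 6L), cgis)
  expect_identical(cats, c("CGI",  # inside
                           "SHO",  # 500 bp from right edge
                           "SHE",  # 3.5 kb
                           "NC",   # 5 kb
                           "SHO",  # ~1 kb from left edge
                           "NC"))  # ~5 kb from left edge
})

test_that("shore boundary cases and island merging behave", {
  cgis <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  # exactly at shore_width and shelf limits
  expect_identical(assign_cgi_region(c(13000L, 13001L, 15000L, 15001L),
                                     rep("chr1", 4L), cgis),
                   c("SHO", "SHE", "SHE", "NC"))
  # overlapping islands merge before edge distances are computed
  two <- data.frame(chrom = "chr1", start = c(10000L, 10800L),
                    end = c(11000L, 12000L))
  expect_identical(assign_cgi_region(11500L, "chr1", two), "CGI")
  # empty island set: everything NC
  expect_identical(assign_cgi_region(123L, "chr1", NULL), "NC")
})

test_that("every probe gets exactly one genic and one CGI category", {
  cfg <- sim_config(n_probes = 600L, seed = 31L)
  sim <- generate_manifest(cfg)
  ann <- annotate_manifest(sim$manifest, sim$genes, sim$cgis)
  expect_false(anyNA(ann$genic))
  expect_false(anyNA(ann$cgi))
  expect_true(all(ann$genic %in% c("IG", "DP", "PP", "GB", "DS")))
  expect_true(all(ann$cgi %in% c("CGI", "SHO", "SHE", "NC")))
  expect_equal(sum(table(ann$genic)), nrow(ann))
  expect_equal(sum(table(ann$cgi)), nrow(ann))
  # probes near a TSS are never intergenic
  near <- !is.na(ann$tss_distance) & abs(ann$tss_distance) <= 1500
  expect_true(all(ann$genic[near] %in% c("PP", "GB")))
})

test_that("vectorized genic assignment matches the brute-force oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n_genes <- sample(3:20, 1L)
    genes <- data.frame(
      gene_id = sprintf("G%02d", sample(n_genes)),
      chrom = "chr1",
      strand = sample(c("+", "-"), n_genes, TRUE),
      tss = sample(seq(20000L, 500000L, by = 13L), n_genes))
    len <- sample(2000:30000, n_genes)
    genes$end3 <- ifelse(genes$strand == "+", genes$tss + len,
                         genes$tss - len)
    pos <- sample(seq(1L, 550000L), 120L)
    got <- assign_genic_region(pos, rep("chr1", 120L), genes)
    for (i in seq_along(pos)) {
      want <- genic_oracle_one(pos[i], "chr1", genes)
      expect_identical(got$category[i], want$category)
      expect_identical(got$gene_id[i], want$gene_id)
      expect_equal(got$distance[i], want$distance)
    }
  }
})

test_that("a probe equidistant from two TSSs lands in exactly one gene's set", {
  genes <- rbind(one_gene(id = "GB_gene", tss = 100000L, end3 = 120000L),
                 one_gene(id = "GA_gene", tss = 102000L, end3 = 122000L))
  # probe at 101000 is 1000 from both: lexicographic tie-break -> GA_gene
  a <- assign_genic_region(101000L, "chr1", genes)
  expect_identical(a$gene_id, "GA_gene")
  man <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 101000L)
  ann <- annotate_manifest(man, genes, NULL)
  sets <- lapply(c("GA_gene", "GB_gene"), gene_region_probes,
                 manifest = ann, genes = genes)
  hits <- vapply(sets, function(s) length(s$pp) + length(s$gb), 1L)
  expect_equal(sum(hits), 1L)
})

test_that("gene PP/GB probe sets match a hand partition of a tiled gene", {
  genes <- one_gene(tss = 10000L, end3 = 20000L)
  man <- data.frame(probe_id = paste0("cg", 1:5), chrom = "chr1",
                    pos = c(8200L, 9900L, 10400L, 15000L, 21000L))
  ann <- annotate_manifest(man, genes, NULL)
  s <- gene_region_probes("G1", ann, genes)
  expect_setequal(s$pp, c("cg2", "cg3"))   # -100 and +400
  expect_setequal(s$gb, "cg4")             # +5000 inside body
  # cg1 is DP (-1800), cg5 is DS; neither is in PP/GB
  expect_error(gene_region_probes("NOPE", ann, genes), "unknown gene")
  far <- one_gene(id = "G2", tss = 900000L, end3 = 920000L)
  ann2 <- annotate_manifest(man, rbind(genes, far), NULL)
  s2 <- gene_region_probes("G2", ann2, rbind(genes, far))
  expect_length(s2$pp, 0L)
  expect_length(s2$gb, 0L)
})
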