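organ_fixture <- function(betas, organs = NULL) {
  # one probe per row of `betas`, one sample per organ
  if (is.null(organs)) organs <- paste0("org", seq_len(ncol(betas)))
  colnames(betas) <- organs
  rownames(betas) <- sprintf("cg%03d", seq_len(nrow(betas)))
  sheet <- data.frame(sample_id = organs, organ = organs, stage = "W20-22",
                      fetus_id = "F1", class = "fetal_organ",
                      stringsAsFactors = FALSE)
  list(beta = betas, sheet = sheet)
}

test_that("stage delta beta is the late-minus-early group-mean difference", {
  m <- matrix(c(0.80, 0.30,
                0.50, 0.50,
                NA,   0.40), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("cg", 1:3), c("e1", "l1")))
  sheet <- data.frame(sample_id = c("e1", "l1"), organ = "brain",
                      stage = c("W8-12", "W20-22"), fetus_id = c("F1", "F2"),
                      class = "fetal_organ", stringsAsFactors = FALSE)
  d <- stage_delta_beta(m, sheet, "brain")
  expect_equal(d$delta, c(-0.5, 0, NA))
  # replicate means: late (0.2, 0.4) vs early 0.1 -> +0.2
  m2 <- matrix(c(0.1, 0.2, 0.4), 1,
               dimnames = list("cg1", c("e1", "l1", "l2")))
  sheet2 <- data.frame(sample_id = c("e1", "l1", "l2"), organ = "lung",
                       stage = c("W8-12", "W20-22", "W20-22"),
                       fetus_id = "F1", class = "fetal_organ",
                       stringsAsFactors = FALSE)
  expect_equal(stage_delta_beta(m2, sheet2, "lung")$delta, 0.2)
  expect_error(stage_delta_beta(m2, sheet2, "lung", late = "W16-18"),
               "no sample of organ 'lung' at stage 'W16-18'")
})

test_that("organ-specific calls require the cutoff against every other organ", {
  # 14 organs; probe 1: organ 1 at 0.90, all others at/below 0.65
  b <- rbind(c(0.90, 0.65, rep(0.60, 12)),
             c(0.55, 0.40, rep(0.40, 12)),    # diff 0.15: no call
             rep(0.50, 14))                   # all equal: no call
  fx <- organ_fixture(b)
  calls <- call_organ_specific_cpgs(fx$beta, fx$sheet)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$probe_id, "cg001")
  expect_identical(calls$direction, "hyper")
  expect_equal(calls$min_pairwise_delta, 0.25)
  # a difference of exactly the cutoff is not a call
  b2 <- rbind(c(0.70, 0.50, 0.50))
  fx2 <- organ_fixture(b2)
  expect_equal(nrow(call_organ_specific_cpgs(fx2$beta, fx2$sheet)), 0L)
  expect_error(call_organ_specific_cpgs(fx2$beta, fx2$sheet[1:2, ]),
               ">= 3")
})

test_that("pooled organs are compared as one group", {
  b <- rbind(c(0.90, 0.88, rep(0.60, 12)))
  fx <- organ_fixture(b, c("muscle", "tongue", paste0("org", 1:12)))
  plain <- call_organ_specific_cpgs(fx$beta, fx$sheet)
  expect_equal(nrow(plain), 0L)   # muscle vs tongue differ by only 0.02
  pooled <- call_organ_specific_cpgs(
    fx$beta, fx$sheet,
    signature_config(pool = list(muscle_tongue = c("muscle", "tongue"))))
  expect_identical(pooled$group, "muscle_tongue")
  expect_equal(pooled$min_pairwise_delta, 0.29)
})

test_that("missing values make a probe not evaluable rather than miscalled", {
  b <- rbind(c(0.95, NA, 0.10, 0.10),
             c(0.95, 0.10, 0.10, 0.10))
  fx <- organ_fixture(b)
  calls <- call_organ_specific_cpgs(fx$beta, fx$sheet)
  expect_identical(unique(calls$probe_id), "cg002")
  expect_equal(attr(calls, "n_not_evaluable"), 1L)
})

test_that("barcode calls need every clone above (below) every organ", {
  clones <- sprintf("c%02d", 1:12)
  organs <- sprintf("o%d", 1:6)
  b <- rbind(c(rep(0.9, 12), rep(0.1, 6)),
             c(rep(0.9, 11), 0.25, rep(0.1, 6)),   # one clone too close
             rep(0.5, 18))
  colnames(b) <- c(clones, organs)
  rownames(b) <- paste0("cg", 1:3)
  sheet <- data.frame(
    sample_id = c(clones, organs),
    organ = c(rep(organs, 2), organs),
    stage = c(rep("PSC", 12), rep("W20-22", 6)),
    fetus_id = "F1",
    class = c(rep("hipsc_clone", 12), rep("fetal_organ", 6)),
    origin_organ = c(rep(organs, 2), rep(NA, 6)),
    stringsAsFactors = FALSE)
  bc <- call_pluripotency_barcode(b, sheet)
  expect_identical(bc$hyper, "cg1")
  expect_length(bc$hypo, 0L)
  expect_error(call_pluripotency_barcode(b, sheet[sheet$class != "hipsc_clone", ]),
               "at least one")
})

test_that("triplet memory calls compare all members against all other triplets", {
  orgs <- c("brain", "kidney", "lung", "muscle", "pancreas", "skin")
  clones <- as.vector(t(outer(orgs, c("_c1", "_c2"), paste0)))
  samples <- c(orgs, clones)
  mk <- function(brain_vals, other = 0.5) {
    v <- rep(other, 18); names(v) <- samples
    v[c("brain", "brain_c1", "brain_c2")] <- brain_vals
    v
  }
  b <- rbind(mk(c(0.85, 0.88, 0.90), 0.60),   # planted brain memory
             mk(c(0.85, 0.88, 0.65), 0.60),   # one clone too close (0.05)
             rep(0.5, 18))
  colnames(b) <- samples; rownames(b) <- paste0("cg", 1:3)
  sheet <- rbind(
    data.frame(sample_id = orgs, organ = orgs, stage = "W20-22",
               fetus_id = "F1", class = "fetal_organ",
               origin_organ = NA_character_, stringsAsFactors = FALSE),
    data.frame(sample_id = clones, organ = rep(orgs, each = 2),
               stage = "PSC", fetus_id = "F1", class = "hipsc_clone",
               origin_organ = rep(orgs, each = 2), stringsAsFactors = FALSE))
  mem <- call_triplet_memory(b, sheet)
  expect_equal(nrow(mem), 1L)
  expect_identical(mem$group, "brain")
  expect_identical(mem$probe_id, "cg1")
  expect_equal(mem$min_pairwise_delta, 0.25)
  # beta matrix missing the brain organ sample: incomplete triplet
  expect_error(call_triplet_memory(b[, -1], sheet), "triplet")
})

test_that("flipping the methylation scale flips hyper and hypo exactly", {
  set.seed(5)
  b <- matrix(runif(50 * 6), 50, 6,
              dimnames = list(sprintf("cg%02d", 1:50), paste0("s", 1:6)))
  fx <- organ_fixture(b)
  a <- call_organ_specific_cpgs(fx$beta, fx$sheet)
  flipped <- call_organ_specific_cpgs(1 - fx$beta, fx$sheet)
  a$direction <- ifelse(a$direction == "hyper", "hypo", "hyper")
  a$min_pairwise_delta <- -a$min_pairwise_delta
  expect_equal(sort_calls(a), sort_calls(flipped))
})

test_that("raising the cutoff never adds calls; hyper and hypo stay disjoint", {
  set.seed(6)
  for (rep in 1:10) {
    b <- matrix(runif(40 * 8), 40, 8,
                dimnames = list(sprintf("cg%02d", 1:40), paste0("s", 1:8)))
    fx <- organ_fixture(b)
    lo <- call_organ_specific_cpgs(fx$beta, fx$sheet, signature_config(0.1))
    hi <- call_organ_specific_cpgs(fx$beta, fx$sheet, signature_config(0.3))
    k <- function(d) paste(d$probe_id, d$group, d$direction)
    expect_true(all(k(hi) %in% k(lo)))
    kk <- paste(lo$probe_id, lo$group)
    expect_equal(anyDuplicated(kk), 0L)
  }
})

test_that("vectorized organ caller matches the naive pairwise oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(20:80, 1L)
    k <- sample(c(6L, 10L, 14L), 1L)
    b <- matrix(runif(n * k)^2, n, k,
                dimnames = list(sprintf("cg%03d", 1:n), paste0("s", 1:k)))
    b[sample(length(b), n %/% 10)] <- NA
    fx <- organ_fixture(b)
    got <- call_organ_specific_cpgs(fx$beta, fx$sheet)
    want <- naive_signature_oracle(fx$beta, colnames(fx$beta), 0.2)
    expect_equal(sort_calls(got), sort_calls(want))
  }
})
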