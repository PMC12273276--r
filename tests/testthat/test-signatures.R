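test_that("z-normalization centers and scales every gene", {
  expect_equal(unname(zscore_normalize(matrix(c(1, 2, 3), 1, 3,
    dimnames = list("g", paste0("S", 1:3))))[1, ]), c(-1, 0, 1))
  set.seed(20)
  expr <- matrix(rnorm(200, 5, 3), 20, 10,
                 dimnames = list(paste0("g", 1:20), paste0("S", 1:10)))
  z <- zscore_normalize(expr)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-10))
  ## idempotent on the z scale
  expect_equal(zscore_normalize(z), z, tolerance = 1e-12)
  expr[3, ] <- 7
  expect_warning(z2 <- zscore_normalize(expr), "constant")
  expect_true(all(is.na(z2[3, ])))
})

test_that("signature scores are per-sample medians over present genes", {
  z <- matrix(c(0.1, 0.5, 0.9, -1, 0, 1), 3, 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  sc <- signature_score(z, c("A", "B", "C"), signature = "sig")
  expect_equal(sc$score, c(0.5, 0))
  ## single-gene set with min_genes 1
  sc1 <- signature_score(z, "B", min_genes = 1)
  expect_equal(sc1$score, unname(z["B", ]))
  ## absent genes are reported; too few genes skips the signature
  sc2 <- signature_score(z, c("A", "B", "C", "Zz"), min_genes = 3)
  expect_identical(attr(sc2, "missing_genes"), "Zz")
  expect_equal(sc2$score, sc$score)
  expect_warning(sc3 <- signature_score(z, c("A", "Zz"), min_genes = 3),
                 "skipped")
  expect_identical(attr(sc3, "status"), "skipped")
})

test_that("dichotomization splits at the cohort median with ties to LO", {
  sc <- data.frame(sample_id = paste0("S", 1:6),
                   score = c(3, 1, 2, 2, 5, 4))
  d <- dichotomize(sc)
  expect_identical(as.character(d$group),
                   c("HI", "LO", "LO", "LO", "HI", "HI"))
  ## |HI| - |LO| is 0 or the number of ties at the median
  expect_lte(abs(sum(d$group == "HI") - sum(d$group == "LO")),
             sum(sc$score == median(sc$score)))
})

test_that("class association reproduces the hand chi-square", {
  labels <- setNames(rep(c("LOW", "CIMP"), each = 40), paste0("S", 1:80))
  grp <- rep(rep(c("HI", "LO"), times = c(30, 10)), 2)
  grp[41:80] <- rep(c("HI", "LO"), times = c(10, 30))
  d <- data.frame(sample_id = names(labels), score = 0,
                  group = factor(grp, levels = c("HI", "LO")))
  res <- class_association(d, labels)
  o <- oracle_chisq(matrix(c(30, 10, 10, 30), 2))
  expect_equal(res$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(res$p.value, o$p.value, tolerance = 1e-12)
  expect_equal(res$df, 1)
  ## perfectly balanced table: statistic 0, p 1
  bal <- d; bal$group <- factor(rep(c("HI", "LO"), 40), levels = c("HI", "LO"))
  res2 <- class_association(bal, labels)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p.value, 1)
})

test_that("enrichment score equals the brute-force running sum", {
  ## hand case: top-2 of 10 genes, weight 0
  ranked <- setNames(seq(10, 1), paste0("g", 1:10))
  top2 <- c("g1", "g2")
  r <- preranked_gsea(ranked, top2, weight = 0, n_perm = 45)
  expect_equal(r$es, 1)  # both hits first: running sum peaks at 2/2
  expect_equal(r$es, oracle_gsea_es(ranked, top2, 0), tolerance = 1e-12)
  ## the full universe as a set is all hits
  rall <- preranked_gsea(ranked, names(ranked), weight = 1, n_perm = 10)
  expect_gte(rall$es, 0)
  expect_equal(rall$es, oracle_gsea_es(ranked, names(ranked), 1),
               tolerance = 1e-12)
  ## randomized instances, both weights
  set.seed(21)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    stats <- setNames(rnorm(n), paste0("g", seq_len(n)))
    set <- sample(names(stats), sample(2:min(8, n - 1), 1))
    for (w in c(0, 1)) {
      got <- preranked_gsea(stats, set, weight = w, n_perm = 20)
      expect_equal(got$es, oracle_gsea_es(stats, set, w), tolerance = 1e-10)
      expect_lte(abs(got$es), 1)
    }
  }
})

test_that("enrichment score agrees with an independent implementation", {
  set.seed(22)
  stats <- setNames(sort(rnorm(40), decreasing = TRUE), paste0("g", 1:40))
  set <- sample(names(stats), 6)
  ours <- preranked_gsea(stats, set, weight = 1, n_perm = 50)$es
  ref <- fgsea::calcGseaStat(stats, selectedStats = which(names(stats) %in% set),
                             gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("small-universe permutation p is exact by enumeration", {
  ranked <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  set <- c("g1", "g2")
  r <- preranked_gsea(ranked, set, weight = 1, n_perm = 15)
  expect_true(r$exhaustive)
  expect_equal(r$n_perm, 15)
  null_es <- apply(combn(6, 2), 2, function(ii)
    oracle_gsea_es(ranked, names(ranked)[ii], 1))
  expect_equal(r$p.value, mean(abs(null_es) >= abs(r$es) - 1e-12),
               tolerance = 1e-12)
  expect_identical(sign(r$nes), sign(r$es))
})

test_that("activation z follows the signed-consistency closed form", {
  reg <- data.frame(target = paste0("t", 1:4), expected_sign = c(1, 1, -1, -1))
  de <- setNames(c(1, 1, -1, -1), reg$target)        # all consistent
  expect_equal(ur_activation_z(de, reg)$z, 2)         # 4 / sqrt(4)
  de2 <- setNames(c(1, -1, 1, -1), reg$target)        # half consistent
  expect_equal(ur_activation_z(de2, reg)$z, 0)
  reg10 <- data.frame(target = paste0("t", 1:10), expected_sign = 1)
  de3 <- setNames(c(rep(1, 9), -1), reg10$target)
  expect_equal(ur_activation_z(de3, reg10)$z, 8 / sqrt(10))
  ## |z| = sqrt(n) when all agree; too few usable targets -> not scored
  expect_equal(abs(ur_activation_z(setNames(rep(1, 10), reg10$target),
                                   reg10)$z), sqrt(10))
  de4 <- setNames(c(1, 1, 1, 0), reg$target)          # only 3 significant
  expect_identical(ur_activation_z(de4, reg)$status, "not_scored")
})

test_that("regulon tables round-trip and validate", {
  f <- withr::local_tempfile(lines = c(
    "regulator\ttarget\texpected_sign",
    "IFNG\tSTAT1\t1", "IFNG\tB2M\t1", "TREX1\tISG15\t-1"))
  regs <- read_regulon(f)
  expect_identical(names(regs), c("IFNG", "TREX1"))
  expect_equal(nrow(regs$IFNG), 2L)
  f2 <- withr::local_tempfile(lines = c("regulator\ttarget\texpected_sign",
                                        "X\tY\t2"))
  expect_error(read_regulon(f2), "expected_sign")
})

test_that("correlation filtering retains coherent genes in both cohorts", {
  set.seed(23)
  n <- 60
  shared <- rnorm(n)
  mk_cohort <- function(anti = FALSE) {
    m <- t(vapply(1:9, function(i) shared + rnorm(n, 0, 0.6),
                  numeric(n)))
    if (anti) m <- rbind(m, -shared + rnorm(n, 0, 0.6))
    else m <- rbind(m, shared + rnorm(n, 0, 0.6))
    rownames(m) <- paste0("g", 1:10)
    colnames(m) <- paste0("S", seq_len(n))
    m
  }
  ## all coherent: everything retained
  res <- derive_correlated_signature(mk_cohort(), mk_cohort(), paste0("g", 1:10))
  expect_identical(res$retained, paste0("g", 1:10))
  ## one planted anticorrelated gene is dropped
  set.seed(24)
  res2 <- derive_correlated_signature(mk_cohort(anti = TRUE),
                                      mk_cohort(anti = TRUE), paste0("g", 1:10))
  expect_identical(setdiff(paste0("g", 1:10), res2$retained), "g10")
  ## destroying cohort-b structure removes everything
  set.seed(25)
  b <- mk_cohort()
  b[] <- b[sample(length(b))]
  res3 <- derive_correlated_signature(mk_cohort(), b, paste0("g", 1:10))
  expect_length(res3$retained, 0L)
  expect_error(derive_correlated_signature(mk_cohort(), b, c("g1", "g2")),
               "at least 3")
})
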