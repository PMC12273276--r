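test_that("region aggregation matches the weighted-mean oracle", {
  beta <- matrix(c(.2, .4, .6), 3, 1,
                 dimnames = list(c("chr1:5", "chr1:15", "chr2:5"), "S1"))
  cov <- matrix(c(10L, 30L, 5L), 3, 1, dimnames = dimnames(beta))
  attr(beta, "coverage") <- cov
  regions <- data.frame(region_id = c("r1", "r2"), chrom = c("chr1", "chr2"),
                        start = c(0, 0), end = c(20, 10))
  uni <- aggregate_to_regions(beta, regions, weighting = "uniform")
  expect_equal(uni["r1", "S1"], 0.3)                    # (.2 + .4) / 2
  expect_equal(uni["r2", "S1"], 0.6)                    # single site
  wt <- aggregate_to_regions(beta, regions, weighting = "coverage")
  expect_equal(wt["r1", "S1"], (.2 * 10 + .4 * 30) / 40)
  ## region with no mapped site is missing with a warning
  regions2 <- rbind(regions, data.frame(region_id = "r3", chrom = "chr9",
                                        start = 0, end = 10))
  expect_warning(agg <- aggregate_to_regions(beta, regions2), "no mapped")
  expect_true(is.na(agg["r3", "S1"]))
  ## min_sites filter
  strict <- aggregate_to_regions(beta, regions, min_sites = 2)
  expect_true(is.na(strict["r2", "S1"]))
})

test_that("differential methylation p equals the exact rank-sum enumeration", {
  set.seed(10)
  labels <- setNames(rep(c("CIMP", "LOW"), each = 4), paste0("S", 1:8))
  beta <- matrix(runif(3 * 8), 3, 8,
                 dimnames = list(paste0("r", 1:3), names(labels)))
  dm <- differential_methylation(beta, labels, "CIMP")
  for (i in 1:3) {
    p_oracle <- oracle_ranksum(beta[i, 1:4], beta[i, 5:8])
    expect_equal(dm$p[dm$feature == paste0("r", i)], p_oracle,
                 tolerance = 1e-10)
    expect_equal(dm$effect[i], mean(beta[i, 1:4]) - mean(beta[i, 5:8]))
  }
  ## identical groups: zero effect, nothing flagged
  beta2 <- cbind(beta[, 1:4], beta[, 1:4])
  colnames(beta2) <- names(labels)
  dm2 <- differential_methylation(beta2, labels, "CIMP")
  expect_true(all(dm2$effect == 0))
  expect_true(all(dm2$flag == "none"))
  ## fully tied feature is degenerate with p = 1
  beta3 <- beta; beta3[1, ] <- 0.5
  dm3 <- differential_methylation(beta3, labels, "CIMP")
  expect_identical(dm3$status[1], "degenerate")
  expect_identical(dm3$p[1], 1)
})

test_that("differential expression: symmetry, exact permutation, BH bounds", {
  set.seed(11)
  labels <- setNames(rep(c("A", "B"), each = 6), paste0("S", 1:12))
  expr <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(paste0("g", 1:5), names(labels)))
  de_a <- differential_expression(expr, labels, "A", n_perm = 0)
  de_b <- differential_expression(expr, labels, "B", n_perm = 0)
  expect_equal(de_a$t, -de_b$t)
  expect_equal(de_a$p, de_b$p)
  ## n_perm >= all C(12,6) = 924 splits triggers exact enumeration
  de_x <- differential_expression(expr, labels, "A", n_perm = 924)
  for (i in 1:5)
    expect_equal(de_x$p_perm[i], oracle_perm_t(expr[i, 1:6], expr[i, 7:12]),
                 tolerance = 1e-10)
  ## BH q dominates p and is monotone in p-rank
  expect_true(all(de_a$q >= de_a$p - 1e-12))
  ord <- order(de_a$p)
  expect_true(all(diff(de_a$q[ord]) >= -1e-12))
  ## zero-variance gene gets p = 1
  expr[2, ] <- 3
  de_z <- differential_expression(expr, labels, "A", n_perm = 0)
  expect_identical(de_z$p[2], 1)
})

test_that("null expression data keeps the asymptotic type-I rate near alpha", {
  set.seed(12)
  n_genes <- 5000
  labels <- setNames(rep(c("A", "B"), each = 20), paste0("S", 1:40))
  expr <- matrix(rnorm(n_genes * 40), n_genes, 40,
                 dimnames = list(paste0("g", seq_len(n_genes)), names(labels)))
  de <- differential_expression(expr, labels, "A", n_perm = 0)
  hits <- sum(de$p <= 0.001)
  bounds <- qbinom(c(0.0005, 0.9995), n_genes, 0.001)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("quadrant assignment crosses calls and resolves multi-promoter genes", {
  dm <- data.frame(feature = c("p1", "p2", "p3", "p4"),
                   effect = c(-.3, .3, .1, -.2),
                   p = c(.001, .001, .5, .04), q = c(.004, .004, .6, .05),
                   flag = c("hypo", "hyper", "none", "hypo"),
                   status = "ok")
  de <- data.frame(feature = c("g1", "g2", "g3"),
                   effect = c(1, -1, 2), t = c(5, -5, 6),
                   p = c(1e-5, 1e-5, 1e-6), p_perm = NA, q = c(1e-4, 1e-4, 1e-5),
                   significant = c(TRUE, TRUE, FALSE),
                   direction = c("up", "down", "up"))
  map <- data.frame(region_id = c("p1", "p2", "p3", "p4"),
                    gene_id = c("g1", "g2", "g3", "g1"))
  expect_message(quad <- quadrant_assignment(dm, de, map), "multiple promoters")
  expect_identical(quad$category[quad$gene_id == "g1"], "up_hypo")
  expect_identical(quad$category[quad$gene_id == "g2"], "down_hyper")
  expect_identical(quad$category[quad$gene_id == "g3"], "none")
})

test_that("hypergeometric over-representation equals exhaustive enumeration", {
  background <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), cold = paste0("g", 16:18))
  category <- paste0("g", c(1:4, 10, 11))
  res <- overrepresentation_test(category, sets, background)
  expect_equal(res$p[res$set == "hit"], oracle_hyper(4, 5, 20, 6),
               tolerance = 1e-12)
  expect_equal(res$p[res$set == "cold"], oracle_hyper(0, 3, 20, 6),
               tolerance = 1e-12)
  ## category = background makes every set's tail probability 1
  res2 <- overrepresentation_test(background, sets, background)
  expect_true(all(res2$p == 1))
  expect_error(overrepresentation_test(c("zz"), sets, background), "subset")
  ## randomized instances against the oracle
  set.seed(13)
  for (i in 1:20) {
    bg <- paste0("g", seq_len(sample(10:25, 1)))
    st <- list(s = sample(bg, sample(2:6, 1)))
    cat_g <- sample(bg, sample(3:8, 1))
    r <- overrepresentation_test(cat_g, st, bg)
    expect_equal(r$p, oracle_hyper(r$overlap, r$set_size,
                                   r$background_size, r$category_size),
                 tolerance = 1e-12)
  }
})

test_that("planted promoter-suppressed genes land in down_hyper", {
  co <- simulate_cohort(tiny_config(), seed = 14)
  labels <- co$truth$class
  rb <- aggregate_to_regions(co$beta, co$regions)
  dm <- differential_methylation(rb, labels, "CIMP")
  de <- differential_expression(co$expression, labels, "CIMP", n_perm = 0,
                                p_threshold = 0.01, q_threshold = 0.05)
  quad <- quadrant_assignment(dm, de, co$regions[, c("region_id", "gene_id")])
  coup <- co$truth$coupled_genes
  sens <- mean(quad$category[quad$gene_id %in% coup] == "down_hyper")
  expect_gte(sens, 0.7)  # small cohort; the acceptance suite tests >= 0.8 at scale
  ora <- overrepresentation_test(quad$gene_id[quad$category == "down_hyper"],
                                 truth_gene_sets(co), quad$gene_id)
  expect_lte(ora$p[ora$set == "promoter_coupled"], 0.01)
})

test_that("promoter windows are strand-aware and half-open", {
  tss <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    tss = c(5000, 5000), strand = c("+", "-"))
  w <- build_promoter_windows(tss, upstream = 1500, downstream = 500)
  expect_equal(w$start[1], 3500); expect_equal(w$end[1], 5500)
  expect_equal(w$start[2], 4501); expect_equal(w$end[2], 6501)
})
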