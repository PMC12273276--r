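test_that("variable-site selection matches a brute-force variance ranking", {
  set.seed(42)
  beta <- matrix(runif(60), 10, 6,
                 dimnames = list(sprintf("chr1:%d", 1:10 * 10), paste0("S", 1:6)))
  v <- apply(beta, 1, var)                       # independent recomputation
  panel <- select_variable_cpgs(beta, fraction = 0.3)
  expect_equal(length(panel$site_ids), 3L)       # round(0.3 * 10)
  expect_identical(panel$site_ids, names(sort(v, decreasing = TRUE))[1:3])
  expect_equal(panel$statistic, unname(sort(v, decreasing = TRUE))[1:3])
})

test_that("panel selection is deterministic under ties and respects missingness", {
  beta <- matrix(0.5, 10, 4,
                 dimnames = list(sprintf("chr1:%d", 1:10), paste0("S", 1:4)))
  panel <- select_variable_cpgs(beta, fraction = 0.5)
  ## all variances zero: tie-break by site id, ascending
  expect_identical(panel$site_ids, sort(rownames(beta))[1:5])
  beta[1, 1:3] <- NA  # 75% missing -> excluded from the evaluable set
  panel2 <- select_variable_cpgs(beta, fraction = 0.5, max_missing_frac = 0.2)
  expect_equal(panel2$n_evaluable, 9L)
  expect_false("chr1:1" %in% panel2$site_ids)
})

test_that("perfectly separated blocks give a 0/1 consensus matrix and k = 2", {
  set.seed(1)
  block <- function(center) matrix(rnorm(50 * 10, rep(center, 10), 0.01), 50, 10)
  pattern <- rbinom(50, 1, .5)
  x <- cbind(block(pattern), block(1 - pattern))
  dimnames(x) <- list(sprintf("chr1:%d", 1:50), sprintf("S%02d", 1:20))
  cc <- consensus_cluster(x, k_range = 2:4, n_resamples = 50, seed = 1)
  cm <- cc$consensus[["2"]]
  truth <- rep(1:2, each = 10)
  same <- outer(truth, truth, `==`)
  expect_true(all(cm[same] == 1))
  expect_true(all(cm[!same] == 0))
  expect_identical(cc$chosen_k, 2L)
  expect_false(cc$weak_structure)
  ## consensus matrices are symmetric with unit diagonal, values in [0,1]
  for (cm in cc$consensus) {
    expect_identical(cm, t(cm))
    expect_true(all(diag(cm) == 1))
    expect_true(all(cm >= 0 & cm <= 1))
  }
})

test_that("consensus matrix equals recomputation from the stored resamples", {
  set.seed(2)
  x <- matrix(runif(30 * 12), 30, 12,
              dimnames = list(sprintf("chr1:%d", 1:30), sprintf("S%02d", 1:12)))
  cc <- suppressWarnings(  # random data: weak-structure warning expected
    consensus_cluster(x, k_range = 2:3, n_resamples = 50, seed = 3,
                      store_resamples = TRUE))
  for (k in c("2", "3")) {
    hits <- matrix(0, 12, 12); tries <- matrix(0, 12, 12)
    for (rec in cc$resamples[[k]]) {
      co <- outer(rec$labels, rec$labels, `==`) * 1
      hits[rec$idx, rec$idx] <- hits[rec$idx, rec$idx] + co
      tries[rec$idx, rec$idx] <- tries[rec$idx, rec$idx] + 1
    }
    expected <- hits / tries; diag(expected) <- 1
    expect_equal(unname(cc$consensus[[k]]), expected, tolerance = 1e-12)
  }
})

test_that("featureless noise yields k_min with a weak-structure warning", {
  set.seed(4)
  x <- matrix(runif(40 * 24), 40, 24,
              dimnames = list(sprintf("chr1:%d", 1:40), sprintf("S%02d", 1:24)))
  expect_warning(cc <- consensus_cluster(x, k_range = 2:5, n_resamples = 60,
                                         seed = 5),
                 "weak")
  expect_identical(cc$chosen_k, 2L)
  expect_true(cc$weak_structure)
})

test_that("cluster labels are ordered by mean beta and invariant to index permutation", {
  means <- c(.2, .4, .6, .8)
  beta <- do.call(cbind, lapply(means, function(m)
    matrix(m, 20, 5) + rnorm(100, 0, .01)))
  dimnames(beta) <- list(sprintf("chr1:%d", 1:20), sprintf("S%02d", 1:20))
  raw <- setNames(rep(c(3L, 1L, 4L, 2L), each = 5), colnames(beta))
  lab <- assign_class_labels(raw, beta)
  expect_identical(as.character(lab[1:5]), rep("DEM", 5))
  expect_identical(as.character(lab[16:20]), rep("CIMP", 5))
  expect_true(all(diff(attr(lab, "class_means")) > 0))
  ## permuting cluster indices leaves the class labels unchanged
  perm <- setNames(c(2L, 4L, 1L, 3L)[raw], names(raw))
  expect_identical(assign_class_labels(perm, beta), lab, ignore_attr = TRUE)
  ## non-4 k falls back to generic ordered labels
  raw3 <- setNames(rep(1:2, each = 10), colnames(beta))
  lab3 <- assign_class_labels(raw3, beta)
  expect_identical(levels(lab3), c("C1", "C2"))
})

test_that("centroid classifier is self-consistent and serializes losslessly", {
  co <- simulate_cohort(tiny_config(), seed = 9)
  panel <- select_variable_cpgs(co$beta, fraction = 0.05)
  bp <- co$beta[panel$site_ids, ]
  model <- train_centroid_classifier(bp, co$truth$class)
  expect_identical(model$classes, c("DEM", "LOW", "INT", "CIMP"))
  pred <- classify_samples(model, co$beta, min_shared_sites = 10)
  expect_equal(mean(as.character(pred$class) ==
                      as.character(co$truth$class[pred$sample_id])), 1)
  ## a sample equal to a centroid is that class at distance 0
  fake <- matrix(model$centroids[, "INT"], ncol = 1,
                 dimnames = list(rownames(model$centroids), "copy"))
  p1 <- classify_samples(model, fake, min_shared_sites = 10)
  expect_identical(as.character(p1$class), "INT")
  ## serialization round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".json")
  write_centroid_model(model, f)
  model2 <- read_centroid_model(f)
  pred2 <- classify_samples(model2, co$beta, min_shared_sites = 10)
  expect_identical(pred$class, pred2$class)
  expect_equal(pred$margin, pred2$margin)
})

test_that("classification reports unclassifiable and tied samples", {
  centroids <- cbind(a = c(.1, .9, .1, .9), b = c(.9, .1, .9, .1))
  rownames(centroids) <- sprintf("chr1:%d", 1:4 * 10)
  model <- structure(list(classes = c("a", "b"), centroids = centroids,
                          metric = "1 - Pearson correlation",
                          cohort_tag = "toy", schema_version = 1L),
                     class = "centroid_model")
  ## all-missing sample is unclassifiable, not an error
  new <- matrix(NA_real_, 4, 1, dimnames = list(rownames(centroids), "m"))
  out <- classify_samples(model, new, min_shared_sites = 2)
  expect_identical(out$status, "unclassifiable")
  expect_true(is.na(out$class))
  ## an exactly equidistant sample (zero correlation to both centroids)
  ## resolves to the lower-beta class with a flag
  tie <- matrix(c(.9, .9, .1, .1), 4, 1,
                dimnames = list(rownames(centroids), "t"))
  out2 <- classify_samples(model, tie, min_shared_sites = 2)
  expect_identical(out2$status, "tie")
  expect_identical(as.character(out2$class), "a")
})

test_that("training requires at least two samples per class", {
  beta <- matrix(runif(40), 10, 4,
                 dimnames = list(sprintf("chr1:%d", 1:10), paste0("S", 1:4)))
  labels <- setNames(c("A", "A", "B", "C"), colnames(beta))
  expect_error(train_centroid_classifier(beta, labels), "fewer than 2")
})
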