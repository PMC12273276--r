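## methylation_classes: discovery of the four ordered methylation
## classes and their transfer to new cohorts.

#' Select the most variable CpG sites
#'
#' Ranks evaluable sites (missing fraction at most `max_missing_frac`)
#' by the sample variance of beta across samples (missing ignored) and
#' keeps the top `fraction`.  Ties are broken by site id so the panel is
#' deterministic.
#'
#' @param beta sites x samples beta matrix.
#' @param fraction fraction of evaluable sites to keep (default 0.01,
#'   the "top 1 percent" convention).
#' @param max_missing_frac maximum tolerated per-site missingness.
#' @return a `cpg_panel`: list with `site_ids` (ordered by decreasing
#'   variance), `statistic`, `fraction`, `n_evaluable`.
#' @export
select_variable_cpgs <- function(beta, fraction = 0.01, max_missing_frac = 0.2) {
  stopifnot_matrix(beta, "beta")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  miss <- rowMeans(is.na(beta))
  evaluable <- miss <= max_missing_frac & apply(beta, 1L, function(x) sum(!is.na(x)) >= 2L)
  if (!any(evaluable)) stop("no evaluable CpG site after missingness filter")
  v <- apply(beta[evaluable, , drop = FALSE], 1L, var, na.rm = TRUE)
  ord <- order(-v, names(v))
  n_panel <- max(1L, round(fraction * sum(evaluable)))
  keep <- ord[seq_len(min(n_panel, length(ord)))]
  structure(list(site_ids = names(v)[keep],
                 statistic = unname(v[keep]),
                 fraction = fraction,
                 n_evaluable = sum(evaluable)),
            class = "cpg_panel")
}

#' @export
print.cpg_panel <- function(x, ...) {
  cat("CpG panel:", length(x$site_ids), "sites (top",
      sprintf("%.2f%%", 100 * x$fraction), "of", x$n_evaluable,
      "evaluable sites by variance)\n")
  invisible(x)
}

## Sample-by-sample 1 - Pearson distance over panel sites, pairwise
## complete.  cor() handles missing via 'pairwise.complete.obs'.
.cor_dist <- function(mat) {
  use <- if (anyNA(mat)) "pairwise.complete.obs" else "everything"
  as.dist(1 - cor(mat, use = use))
}

#' Consensus clustering of samples over a CpG panel
#'
#' Repeatedly subsamples the cohort, clusters each subsample by average
#' linkage on 1 - Pearson correlation distance, and records how often
#' every sample pair lands in the same cluster.  The consensus index of
#' a pair is its co-clustering count divided by its co-sampling count.
#' Final labels come from hierarchical clustering of 1 - consensus at
#' the chosen k (see [choose_k()]).
#'
#' @param beta_panel panel-sites x samples beta matrix (typically
#'   `beta[panel$site_ids, ]`).
#' @param k_range candidate cluster numbers, a subset of 2..10.
#' @param n_resamples subsampling iterations per k (at least 20;
#'   default 1000).
#' @param subsample_frac fraction of samples drawn (without
#'   replacement) per iteration.
#' @param seed master seed; each k uses a derived substream.
#' @param store_resamples keep the per-iteration sample indices and
#'   labels (for auditing; memory-heavy for large runs).
#' @return a `consensus_result` with per-k consensus matrices, CDF
#'   areas, delta-areas, `chosen_k`, final `labels`, and a
#'   `weak_structure` flag.
#' @export
consensus_cluster <- function(beta_panel, k_range = 2:6, n_resamples = 1000,
                              subsample_frac = 0.8, seed = 1,
                              store_resamples = FALSE) {
  stopifnot_matrix(beta_panel, "beta_panel")
  if (any(k_range < 2L | k_range > 10L)) stop("k_range must lie in 2..10")
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 2L) stop("need at least 2 candidate k")
  if (n_resamples < 20L) stop("n_resamples must be at least 20")
  n <- ncol(beta_panel)
  m <- ceiling(subsample_frac * n)
  samples <- colnames(beta_panel)
  consensus <- list()
  resamples <- list()
  for (k in k_range) {
    hits <- matrix(0, n, n)
    tries <- matrix(0, n, n)
    rec <- if (store_resamples) vector("list", n_resamples)
    with_seed(derive_seed(seed, paste0("consensus_k", k)), {
      for (r in seq_len(n_resamples)) {
        idx <- sort(sample.int(n, m))
        lab <- cutree(hclust(.cor_dist(beta_panel[, idx, drop = FALSE]),
                             method = "average"), k = k)
        co <- outer(lab, lab, `==`)
        hits[idx, idx] <- hits[idx, idx] + co
        tries[idx, idx] <- tries[idx, idx] + 1
        if (store_resamples) rec[[r]] <- list(idx = idx, labels = lab)
      }
    })
    off <- tries[upper.tri(tries)]
    if (any(off == 0))
      stop("some sample pairs were never co-sampled; ",
           "increase n_resamples or subsample_frac")
    cm <- hits / tries
    diag(cm) <- 1
    dimnames(cm) <- list(samples, samples)
    consensus[[as.character(k)]] <- cm
    if (store_resamples) resamples[[as.character(k)]] <- rec
  }
  res <- structure(list(k_range = k_range, consensus = consensus,
                        n_resamples = n_resamples,
                        subsample_frac = subsample_frac, seed = seed,
                        resamples = if (store_resamples) resamples),
                   class = "consensus_result")
  res <- c(res, .consensus_cdf_areas(res))
  class(res) <- "consensus_result"
  sel <- choose_k(res)
  res$chosen_k <- sel$k
  res$weak_structure <- sel$weak_structure
  cm <- consensus[[as.character(sel$k)]]
  lab <- cutree(hclust(as.dist(1 - cm), method = "average"), k = sel$k)
  res$labels <- setNames(lab, samples)
  res
}

## Area under the empirical CDF of off-diagonal consensus values, per k,
## and the relative delta-area series used for model selection.
.consensus_cdf_areas <- function(res) {
  grid <- seq(0, 1, by = 0.01)
  areas <- vapply(res$consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    sum(ecdf(v)(grid[-1L]) * diff(grid))
  }, 0)
  delta <- c(areas[1L], diff(areas) / areas[-length(areas)])
  names(delta) <- names(areas)
  ## proportion of ambiguous consensus entries, per k
  pac <- vapply(res$consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    mean(v > 0.1 & v < 0.9)
  }, 0)
  list(cdf_area = areas, delta_area = delta, pac = pac)
}

#' Choose the number of classes from a consensus result
#'
#' Two complementary consensus-CDF statistics drive the choice.  A k is
#' a *stable* candidate when its proportion of ambiguous consensus
#' entries (PAC: values in (0.1, 0.9)) is at most `pac_threshold`:
#' genuinely clustered data produce near-binary consensus matrices,
#' while forced splits of a coherent cluster inflate PAC.  Among the
#' stable candidates, the chosen k is the smallest one after which
#' every further stable candidate adds a relative delta-area gain below
#' `threshold`.  When no candidate is stable the data carry no
#' reproducible cluster structure: the smallest k is returned with a
#' "weak structure" flag and a warning.  All delta-areas and PAC values
#' are reported alongside.
#'
#' @param res a `consensus_result`.
#' @param threshold relative delta-area gain below which extra clusters
#'   are considered noise (default 0.025).
#' @param pac_threshold maximum proportion of ambiguous consensus
#'   entries for a candidate k (default 0.05).
#' @return list with `k`, `weak_structure`, `delta_area`, `pac`.
#' @export
choose_k <- function(res, threshold = 0.025, pac_threshold = 0.05) {
  stopifnot(inherits(res, "consensus_result"))
  ks <- res$k_range
  delta <- res$delta_area
  stable <- which(res$pac <= pac_threshold)
  if (!length(stable)) {
    warning("weak cluster structure: consensus values are mostly ambiguous ",
            "at every candidate k")
    return(list(k = ks[1L], weak_structure = TRUE,
                delta_area = delta, pac = res$pac))
  }
  k <- ks[stable[length(stable)]]
  for (pos in seq_along(stable)) {
    later <- stable[-seq_len(pos)]
    if (!length(later) || all(delta[later] < threshold)) {
      k <- ks[stable[pos]]
      break
    }
  }
  list(k = k, weak_structure = FALSE, delta_area = delta, pac = res$pac)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over k =",
      paste(x$k_range, collapse = ", "), "\n")
  cat("  chosen k:", x$chosen_k,
      if (isTRUE(x$weak_structure)) "(weak structure)" else "", "\n")
  cat("  delta-areas:",
      paste(sprintf("%s=%.3f", names(x$delta_area), x$delta_area),
            collapse = " "), "\n")
  invisible(x)
}

#' Assign ordered methylation class labels to clusters
#'
#' Clusters are ranked by their mean beta over the panel; with four
#' clusters the ascending ranks become DEM, LOW, INT, CIMP.  Any other
#' k yields generic ordered labels C1 < ... < Ck.  Exact ties in
#' cluster means (within 1e-9) are broken deterministically by the
#' smallest member sample id, with a message.
#'
#' @param labels integer cluster labels named by sample (e.g.
#'   `consensus_result$labels`).
#' @param beta_panel the panel matrix the clustering was computed on.
#' @return ordered factor of class labels named by sample, with the
#'   per-class mean panel beta in attribute `"class_means"`.
#' @export
assign_class_labels <- function(labels, beta_panel) {
  stopifnot_matrix(beta_panel, "beta_panel")
  if (is.null(names(labels))) stop("labels must be named by sample")
  labels <- labels[colnames(beta_panel)]
  k <- length(unique(labels))
  cl_means <- vapply(split(colnames(beta_panel), labels), function(s)
    mean(beta_panel[, s, drop = FALSE], na.rm = TRUE), 0)
  first_sample <- vapply(split(colnames(beta_panel), labels), min, "")
  if (any(diff(sort(cl_means)) < 1e-9)) {
    message("tied cluster means; breaking ties by smallest sample id")
    ord <- order(cl_means, first_sample)
  } else ord <- order(cl_means)
  level_names <- if (k == 4L) .CLASSES else paste0("C", seq_len(k))
  map <- setNames(level_names, names(cl_means)[ord])
  out <- factor(map[as.character(labels)], levels = level_names, ordered = TRUE)
  names(out) <- names(labels)
  attr(out, "class_means") <- setNames(sort(cl_means), level_names)[level_names]
  out
}

#' Train a nearest-centroid methylation-class model
#'
#' Centroids are per-site mean beta over the training samples of each
#' class (missing ignored); classification uses 1 - Pearson correlation
#' to each centroid over shared non-missing sites.
#'
#' @param beta_panel panel-sites x samples training matrix.
#' @param labels class labels named by sample (factor or character).
#' @param cohort_tag free-text training-cohort tag stored in the model.
#' @return a `centroid_model`.
#' @export
train_centroid_classifier <- function(beta_panel, labels,
                                      cohort_tag = "training") {
  stopifnot_matrix(beta_panel, "beta_panel")
  labels <- labels[colnames(beta_panel)]
  if (anyNA(labels)) stop("every training sample needs a label")
  counts <- table(as.character(labels))
  if (any(counts < 2L))
    stop("class with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  lv <- lv[lv %in% names(counts)]
  centroids <- vapply(lv, function(cl)
    rowMeans(beta_panel[, as.character(labels) == cl, drop = FALSE], na.rm = TRUE),
    numeric(nrow(beta_panel)))
  means <- colMeans(centroids, na.rm = TRUE)
  ord <- order(means)
  centroids <- centroids[, ord, drop = FALSE]
  if (any(diff(colMeans(centroids, na.rm = TRUE)) <= 0))
    stop("centroid global means are not strictly increasing; ",
         "labels do not define an ordered methylation gradient")
  structure(list(classes = colnames(centroids),
                 centroids = centroids,
                 metric = "1 - Pearson correlation",
                 cohort_tag = cohort_tag,
                 schema_version = 1L),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Nearest-centroid methylation classifier (", x$metric, ")\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = " < "),
      " panel:", nrow(x$centroids), "sites\n")
  invisible(x)
}

#' Classify new samples with a centroid model
#'
#' Each sample is assigned to the nearest centroid by correlation
#' distance over the panel sites present and non-missing in both.  The
#' margin (second-best minus best distance) quantifies confidence.
#' Samples sharing fewer than `min_shared_sites` sites with the model
#' are reported as unclassifiable rather than failing the run; exact
#' ties go to the lower-beta class and are flagged.
#'
#' @param model a `centroid_model`.
#' @param beta_new sites x samples matrix for the new cohort.
#' @param min_shared_sites minimum usable panel sites per sample
#'   (default 500).
#' @return data.frame with `sample_id`, `class`, `merged`, `margin`,
#'   `n_shared`, `status` (`"ok"`, `"tie"` or `"unclassifiable"`).
#' @export
classify_samples <- function(model, beta_new, min_shared_sites = 500) {
  stopifnot(inherits(model, "centroid_model"))
  stopifnot_matrix(beta_new, "beta_new")
  panel <- rownames(model$centroids)
  shared <- intersect(panel, rownames(beta_new))
  cent <- model$centroids[shared, , drop = FALSE]
  out <- lapply(colnames(beta_new), function(s) {
    x <- beta_new[shared, s]
    use <- !is.na(x) & rowSums(is.na(cent)) == 0L
    if (sum(use) < min_shared_sites)
      return(data.frame(sample_id = s, class = NA_character_,
                        margin = NA_real_, n_shared = sum(use),
                        status = "unclassifiable"))
    d <- 1 - as.vector(cor(x[use], cent[use, , drop = FALSE]))
    best <- which(d <= min(d) + 1e-12)
    status <- if (length(best) > 1L) "tie" else "ok"
    cls <- model$classes[best[1L]]  # classes are stored in ascending beta order
    margin <- if (length(d) > 1L) sort(d)[2L] - min(d) else NA_real_
    data.frame(sample_id = s, class = cls, margin = margin,
               n_shared = sum(use), status = status)
  })
  out <- do.call(rbind, out)
  out$class <- factor(out$class, levels = model$classes, ordered = TRUE)
  out$merged <- merge_classes(out$class)
  out[, c("sample_id", "class", "merged", "margin", "n_shared", "status")]
}

#' Serialize / load a centroid model as JSON
#'
#' @param model a `centroid_model`.
#' @param path JSON path.
#' @return `read_centroid_model` returns the model; predictions round
#'   trip identically.
#' @export
write_centroid_model <- function(model, path) {
  stopifnot(inherits(model, "centroid_model"))
  obj <- list(schema_version = model$schema_version,
              classes = model$classes,
              metric = model$metric,
              cohort_tag = model$cohort_tag,
              panel_sites = rownames(model$centroids),
              centroids = as.data.frame(model$centroids))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_centroid_model
#' @export
read_centroid_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- as.matrix(obj$centroids)
  rownames(centroids) <- obj$panel_sites
  structure(list(classes = obj$classes, centroids = centroids,
                 metric = obj$metric, cohort_tag = obj$cohort_tag,
                 schema_version = obj$schema_version),
            class = "centroid_model")
}
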