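## signature_analytics: per-sample signature scoring, dichotomization,
## class association, preranked enrichment, upstream-regulator
## activation and correlation-filtered signature derivation.

#' Z-score normalize an expression matrix per gene
#'
#' Each gene is centered and scaled across the samples of the scoring
#' cohort (missing ignored).  Genes with zero variance get missing z
#' with a warning; z-scores are always computed within one cohort.
#'
#' @param expr genes x samples matrix.
#' @return z matrix of the same shape.
#' @export
zscore_normalize <- function(expr) {
  stopifnot_matrix(expr, "expr")
  if (ncol(expr) < 2L) stop("need at least 2 samples to z-score")
  mu <- rowMeans(expr, na.rm = TRUE)
  sdv <- apply(expr, 1L, sd, na.rm = TRUE)
  constant <- is.na(sdv) | sdv == 0
  if (any(constant)) {
    warning(sum(constant), " constant gene(s): z set to missing")
    sdv[constant] <- NA_real_
  }
  (expr - mu) / sdv
}

#' Median-z signature score per sample
#'
#' The score of a sample is the median of the z-scores of the signature
#' genes present in the matrix.  Signatures with fewer than `min_genes`
#' present genes are not scored; missing genes are reported.
#'
#' @param z_matrix genes x samples z matrix (see [zscore_normalize()]).
#' @param gene_set character vector of gene ids.
#' @param min_genes minimum present genes (default 3).
#' @param signature name recorded in the output.
#' @return data.frame `sample_id`, `signature`, `score` with attributes
#'   `"missing_genes"` and `"status"` (`"ok"` or `"skipped"`).
#' @export
signature_score <- function(z_matrix, gene_set, min_genes = 3,
                            signature = "signature") {
  stopifnot_matrix(z_matrix, "z_matrix")
  present <- intersect(gene_set, rownames(z_matrix))
  missing <- setdiff(gene_set, present)
  if (length(present) < min_genes) {
    warning("signature '", signature, "' skipped: only ",
            length(present), " of ", length(gene_set), " genes present")
    out <- data.frame(sample_id = character(), signature = character(),
                      score = numeric())
    attr(out, "status") <- "skipped"
    attr(out, "missing_genes") <- missing
    return(out)
  }
  score <- apply(z_matrix[present, , drop = FALSE], 2L, median, na.rm = TRUE)
  out <- data.frame(sample_id = colnames(z_matrix), signature = signature,
                    score = unname(score), row.names = NULL)
  attr(out, "status") <- "ok"
  attr(out, "missing_genes") <- missing
  out
}

#' Dichotomize signature scores at the cohort median
#'
#' Samples strictly above the cohort median are `HI`; ties at the
#' median (and everything below) are `LO`.
#'
#' @param scores data.frame from [signature_score()] (or any frame with
#'   `sample_id` and `score`).
#' @return the input with an added `group` factor (`HI`/`LO`).
#' @export
dichotomize <- function(scores) {
  stopifnot(all(c("sample_id", "score") %in% names(scores)))
  med <- median(scores$score, na.rm = TRUE)
  scores$group <- factor(ifelse(scores$score > med, "HI", "LO"),
                         levels = c("HI", "LO"))
  scores
}

#' Chi-square association between a dichotomy and class labels
#'
#' Pearson chi-square without continuity correction on the
#' group x class contingency table; classes without samples are dropped
#' with a warning, and a warning is raised when any expected count
#' falls below 5.
#'
#' @param dichotomy data.frame from [dichotomize()].
#' @param labels class labels named by sample.
#' @return list `statistic`, `df`, `p.value`, `table`, `expected`.
#' @export
class_association <- function(dichotomy, labels) {
  lab <- labels[dichotomy$sample_id]
  keep <- !is.na(lab) & !is.na(dichotomy$group)
  lab <- droplevels(factor(lab[keep]))
  if (nlevels(lab) < length(unique(labels[!is.na(labels)])))
    warning("class(es) without scored samples dropped")
  if (nlevels(lab) < 2L) stop("need at least 2 classes present")
  tab <- table(group = dichotomy$group[keep], class = lab)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count below 5; chi-square approximation is weak")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab, expected = ct$expected)
}

## Core weighted Kolmogorov-Smirnov running-sum enrichment score.
## stats must be sorted in decreasing order; returns the signed maximal
## deviation of the running sum.
.gsea_es <- function(stats_sorted, in_set, weight) {
  hit_w <- abs(stats_sorted)^weight * in_set
  denom_hit <- sum(hit_w)
  if (denom_hit == 0) hit_w <- in_set / sum(in_set)  # all-zero stats fallback
  else hit_w <- hit_w / denom_hit
  miss_w <- if (all(in_set)) rep(0, length(in_set))
            else (!in_set) / sum(!in_set)
  running <- cumsum(hit_w - miss_w)
  running[which.max(abs(running))]
}

#' Preranked gene-set enrichment (weighted running-sum statistic)
#'
#' Genes are ranked by a signed statistic (ties broken deterministically
#' by gene id); hits advance the running sum by their |statistic|^weight
#' (normalized over the set), misses retreat it by 1/(N - set size).
#' ES is the signed maximal deviation.  The null is built by drawing
#' random gene sets of the same size (enumerated exhaustively when
#' feasible within `n_perm`); NES divides ES by the mean |null ES| of
#' the same sign, and the two-sided p compares |ES| against the full
#' null.
#'
#' @param ranked named numeric vector, gene -> statistic.
#' @param gene_set character vector (must be a subset of the universe).
#' @param weight exponent on |statistic| for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov form).
#' @param n_perm null size (default 1000).
#' @param seed RNG seed.
#' @return list `es`, `nes`, `p.value`, `n_perm`, `seed`, `exhaustive`.
#' @export
preranked_gsea <- function(ranked, gene_set, weight = 1, n_perm = 1000,
                           seed = 1) {
  if (is.null(names(ranked))) stop("ranked must be named by gene")
  if (!all(gene_set %in% names(ranked)))
    stop("gene set contains genes absent from the ranked universe")
  ord <- order(-ranked, names(ranked))
  stats_sorted <- ranked[ord]
  genes <- names(stats_sorted)
  N <- length(genes); m <- length(unique(gene_set))
  if (m < 1L || m > N) stop("gene set size must be in [1, N]")
  in_set <- genes %in% gene_set
  es <- .gsea_es(stats_sorted, in_set, weight)
  n_splits <- suppressWarnings(choose(N, m))
  exhaustive <- is.finite(n_splits) && n_splits <= n_perm
  null_es <- if (exhaustive) {
    apply(combn(N, m), 2L, function(ii) {
      sel <- rep(FALSE, N); sel[ii] <- TRUE
      .gsea_es(stats_sorted, sel, weight)
    })
  } else {
    with_seed(derive_seed(seed, "gsea_null"), {
      vapply(seq_len(n_perm), function(i) {
        sel <- rep(FALSE, N); sel[sample.int(N, m)] <- TRUE
        .gsea_es(stats_sorted, sel, weight)
      }, 0)
    })
  }
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- if (exhaustive) mean(abs(null_es) >= abs(es) - 1e-12)
       else (sum(abs(null_es) >= abs(es) - 1e-12) + 1) / (length(null_es) + 1)
  list(es = unname(es), nes = unname(nes), p.value = p,
       n_perm = length(null_es), seed = seed, exhaustive = exhaustive)
}

#' Read a regulon table (regulator, target, expected_sign)
#'
#' @param path TSV with columns `regulator`, `target`, `expected_sign`
#'   (+1 for activation, -1 for repression).
#' @return named list of data.frames (`target`, `expected_sign`).
#' @export
read_regulon <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "expected_sign")
  if (!all(need %in% names(df)))
    stop("regulon table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$expected_sign %in% c(-1L, 1L)))
    stop("expected_sign must be +1 or -1")
  split(df[, c("target", "expected_sign")], df$regulator)
}

#' Signed-consistency activation z for an upstream regulator
#'
#' Approximate activation score ("activation-z (approx.)"): over the
#' regulator's targets with a significant observed direction, a target
#' is consistent when observed direction times expected direction is
#' +1; z = (n_consistent - n_inconsistent) / sqrt(n_used).  Regulators
#' with fewer than 4 usable targets are not scored.
#'
#' @param de_signed named numeric vector gene -> signed significance
#'   (positive = significantly up, negative = significantly down, 0 or
#'   absent = not significant).  For [differential_expression()] output
#'   use `with(de, setNames(ifelse(significant, sign(t), 0), feature))`.
#' @param regulon data.frame with `target` and `expected_sign`.
#' @param min_targets minimum usable targets (default 4).
#' @return data.frame `n_consistent`, `n_inconsistent`, `z`, `status`.
#' @export
ur_activation_z <- function(de_signed, regulon, min_targets = 4) {
  stopifnot(all(c("target", "expected_sign") %in% names(regulon)))
  obs <- de_signed[regulon$target]
  usable <- !is.na(obs) & obs != 0
  n_cons <- sum(sign(obs[usable]) * regulon$expected_sign[usable] == 1)
  n_incons <- sum(usable) - n_cons
  if (sum(usable) < min_targets)
    return(data.frame(n_consistent = n_cons, n_inconsistent = n_incons,
                      z = NA_real_, status = "not_scored"))
  data.frame(n_consistent = n_cons, n_inconsistent = n_incons,
             z = (n_cons - n_incons) / sqrt(n_cons + n_incons),
             status = "ok")
}

#' Derive a correlation-filtered gene signature across two cohorts
#'
#' For each candidate gene and cohort, computes its Spearman
#' correlations (and test p-values) with every other candidate; the
#' gene-level summary is the mean pairwise rho and the median pairwise
#' p, BH-adjusted across genes within the cohort.  A gene is retained
#' when its mean rho is positive and its adjusted median p is at most
#' `alpha` in BOTH cohorts.
#'
#' @param expr_a,expr_b genes x samples expression matrices of the two
#'   cohorts.
#' @param candidate_genes candidate signature genes (at least 3,
#'   measured in both cohorts).
#' @param alpha BH threshold (default 0.05).
#' @return list `retained` (character), `summary` (per gene and
#'   cohort), `cor_matrices` (per cohort, for audit).
#' @export
derive_correlated_signature <- function(expr_a, expr_b, candidate_genes,
                                        alpha = 0.05) {
  if (length(candidate_genes) < 3L) stop("need at least 3 candidate genes")
  cohorts <- list(a = expr_a, b = expr_b)
  per_cohort <- lapply(names(cohorts), function(tag) {
    expr <- cohorts[[tag]]
    missing <- setdiff(candidate_genes, rownames(expr))
    if (length(missing))
      stop("candidate gene(s) not measured in cohort ", tag, ": ",
           paste(head(missing, 3L), collapse = ", "))
    x <- t(expr[candidate_genes, , drop = FALSE])
    g <- length(candidate_genes)
    rho <- matrix(NA_real_, g, g, dimnames = list(candidate_genes, candidate_genes))
    pmat <- rho
    for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
      ct <- suppressWarnings(cor.test(x[, i], x[, j], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
    mean_rho <- rowMeans(rho, na.rm = TRUE)
    med_p <- apply(pmat, 1L, median, na.rm = TRUE)
    data.frame(gene = candidate_genes, cohort = tag,
               mean_rho = unname(mean_rho),
               median_p = unname(med_p),
               q = p.adjust(med_p, method = "BH"),
               row.names = NULL,
               stringsAsFactors = FALSE) -> summary_df
    list(summary = summary_df, rho = rho, p = pmat)
  })
  names(per_cohort) <- names(cohorts)
  keep_in <- function(s) s$summary$mean_rho > 0 & s$summary$q <= alpha
  retained <- candidate_genes[keep_in(per_cohort$a) & keep_in(per_cohort$b)]
  list(retained = retained,
       summary = rbind(per_cohort$a$summary, per_cohort$b$summary),
       cor_matrices = list(a = per_cohort$a$rho, b = per_cohort$b$rho))
}
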