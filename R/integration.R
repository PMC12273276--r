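## meth_expr_integration: promoter/gene-level methylation vs expression.

#' Aggregate site-level beta to regions (promoters/genes)
#'
#' Region beta per sample is the (optionally coverage-weighted) mean of
#' the member sites' beta, ignoring missing values.  Regions with fewer
#' than `min_sites` informative members in a sample are missing for
#' that sample; regions with no mapped site at all are missing
#' everywhere, with a warning.  Membership uses 0-based half-open
#' region coordinates against the `chrom:pos` site ids.
#'
#' @param beta sites x samples matrix with `chrom:pos` rownames; a
#'   `"coverage"` attribute enables coverage weighting.
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`.
#' @param min_sites minimum informative member sites (default 1).
#' @param weighting `"uniform"` or `"coverage"`.
#' @return regions x samples beta matrix.
#' @export
aggregate_to_regions <- function(beta, regions, min_sites = 1,
                                 weighting = c("uniform", "coverage")) {
  stopifnot_matrix(beta, "beta")
  weighting <- match.arg(weighting)
  if (min_sites < 1L) stop("min_sites must be >= 1")
  cov <- attr(beta, "coverage")
  if (weighting == "coverage" && is.null(cov))
    stop("coverage weighting requested but beta has no coverage attribute")
  sites <- parse_site_ids(rownames(beta))
  ## 0-based half-open -> 1-based GRanges
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L, width = 1L))
  region_gr <- GenomicRanges::GRanges(regions$chrom,
                                      IRanges::IRanges(regions$start + 1L,
                                                       regions$end))
  ov <- GenomicRanges::findOverlaps(region_gr, site_gr)
  members <- split(S4Vectors::subjectHits(ov),
                   regions$region_id[S4Vectors::queryHits(ov)])
  out <- matrix(NA_real_, nrow(regions), ncol(beta),
                dimnames = list(regions$region_id, colnames(beta)))
  empty <- setdiff(regions$region_id, names(members))
  if (length(empty))
    warning(length(empty), " region(s) with no mapped CpG site")
  for (rid in names(members)) {
    rows <- members[[rid]]
    sub <- beta[rows, , drop = FALSE]
    w <- if (weighting == "coverage") cov[rows, , drop = FALSE]
         else matrix(1, length(rows), ncol(beta))
    w[is.na(sub)] <- 0
    sub[is.na(sub)] <- 0
    n_inf <- colSums(w > 0)
    val <- colSums(sub * w) / colSums(w)
    val[n_inf < min_sites] <- NA_real_
    out[rid, ] <- val
  }
  out
}

## BH-adjusted one-vs-rest split of a label vector.
.split_groups <- function(labels, group) {
  lab <- as.character(labels)
  merged <- as.character(merge_classes(lab))
  merged[is.na(merged)] <- ""
  in_group <- lab == group | merged == group
  if (!any(in_group, na.rm = TRUE)) stop("no sample in group '", group, "'")
  if (all(in_group, na.rm = TRUE)) stop("group '", group, "' covers all samples")
  in_group
}

#' Differential methylation of regions between a class and the rest
#'
#' Wilcoxon rank-sum test per region (group vs rest), effect = mean
#' beta difference (group minus rest), BH-adjusted q.  Regions are
#' flagged `hyper` when the effect is at least `delta` and `hypo` when
#' at most `-delta`, with q at most `alpha`.  Features with fewer than
#' 3 non-missing values on either side are skipped (`status`); fully
#' tied features get p = 1 and a `degenerate` status.
#'
#' @param region_beta regions x samples beta matrix.
#' @param labels class labels named by sample.
#' @param group class (`"CIMP"`) or merged group (`"INT+CIMP"`) to
#'   contrast against the remaining samples.
#' @param delta minimum absolute beta difference (default 0.1).
#' @param alpha BH q-value threshold (default 0.05).
#' @return data.frame `feature`, `effect`, `p`, `q`, `flag`, `status`.
#' @export
differential_methylation <- function(region_beta, labels, group,
                                     delta = 0.1, alpha = 0.05) {
  stopifnot_matrix(region_beta, "region_beta")
  labels <- labels[colnames(region_beta)]
  in_group <- .split_groups(labels, group)
  res <- lapply(rownames(region_beta), function(f) {
    x <- region_beta[f, in_group]
    y <- region_beta[f, !in_group]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L)
      return(data.frame(feature = f, effect = NA_real_, p = NA_real_,
                        status = "insufficient"))
    if (length(unique(c(x, y))) == 1L)
      return(data.frame(feature = f, effect = 0, p = 1, status = "degenerate"))
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    data.frame(feature = f, effect = mean(x) - mean(y), p = p, status = "ok")
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- p.adjust(res$p[ok], method = "BH")
  res$flag <- "none"
  res$flag[ok & res$effect >= delta & res$q <= alpha] <- "hyper"
  res$flag[ok & res$effect <= -delta & res$q <= alpha] <- "hypo"
  res[, c("feature", "effect", "p", "q", "flag", "status")]
}

## Vectorized Welch t over the rows of a matrix.
.welch_rows <- function(mat, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  m1 <- rowMeans(mat[, in_group, drop = FALSE])
  m2 <- rowMeans(mat[, !in_group, drop = FALSE])
  v1 <- apply(mat[, in_group, drop = FALSE], 1L, var)
  v2 <- apply(mat[, !in_group, drop = FALSE], 1L, var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, effect = m1 - m2,
       p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Differential expression between a class and the rest
#'
#' Welch t-test per gene on normalized (log-scale or z) expression,
#' with an optional label-permutation p-value and BH-adjusted q.  A
#' gene is called significant when the asymptotic p, the BH q and (if
#' computed) the permutation p all pass their thresholds.  When the
#' number of distinct label splits is at most `n_perm` the permutation
#' null is enumerated exactly; `n_perm = 0` skips the permutation test.
#'
#' @param expr genes x samples matrix of normalized expression.
#' @param labels class labels named by sample.
#' @param group class or merged group contrasted against the rest.
#' @param n_perm permutation count (default 10000).
#' @param seed RNG seed for the sampled permutations.
#' @param p_threshold,q_threshold,perm_threshold significance thresholds
#'   (defaults 0.001, 0.01, 0.01).
#' @return data.frame `feature`, `effect`, `t`, `p`, `p_perm`, `q`,
#'   `significant`, `direction`.
#' @export
differential_expression <- function(expr, labels, group, n_perm = 10000,
                                    seed = 1, p_threshold = 0.001,
                                    q_threshold = 0.01,
                                    perm_threshold = 0.01) {
  stopifnot_matrix(expr, "expr")
  labels <- labels[colnames(expr)]
  in_group <- .split_groups(labels, group)
  n <- length(in_group); n1 <- sum(in_group)
  if (n1 < 3L || n - n1 < 3L) stop("both groups need at least 3 samples")
  obs <- .welch_rows(expr, in_group)
  zero_var <- is.na(obs$t)
  obs$t[zero_var] <- 0; obs$p[zero_var] <- 1
  p_perm <- rep(NA_real_, nrow(expr))
  if (n_perm > 0L) {
    n_splits <- choose(n, n1)
    exceed <- numeric(nrow(expr))
    if (n_splits <= n_perm) {
      splits <- combn(n, n1)
      for (j in seq_len(ncol(splits))) {
        g <- rep(FALSE, n); g[splits[, j]] <- TRUE
        tp <- .welch_rows(expr, g)$t
        tp[is.na(tp)] <- 0
        exceed <- exceed + (abs(tp) >= abs(obs$t) - 1e-12)
      }
      p_perm <- exceed / ncol(splits)
    } else {
      with_seed(derive_seed(seed, "perm_de"), {
        for (j in seq_len(n_perm)) {
          g <- rep(FALSE, n); g[sample.int(n, n1)] <- TRUE
          tp <- .welch_rows(expr, g)$t
          tp[is.na(tp)] <- 0
          exceed <- exceed + (abs(tp) >= abs(obs$t) - 1e-12)
        }
      })
      p_perm <- (exceed + 1) / (n_perm + 1)
    }
  }
  q <- p.adjust(obs$p, method = "BH")
  significant <- obs$p <= p_threshold & q <= q_threshold &
    (if (n_perm > 0L) p_perm <= perm_threshold else TRUE)
  data.frame(feature = rownames(expr), effect = obs$effect, t = obs$t,
             p = obs$p, p_perm = p_perm, q = q,
             significant = significant,
             direction = ifelse(obs$t > 0, "up", ifelse(obs$t < 0, "down", "none")),
             row.names = NULL)
}

#' Cross methylation and expression calls into quadrants
#'
#' Genes are categorized by the cross of their expression call
#' (up/down, significant) and their promoter methylation call
#' (hypo/hyper flag): `up_hypo`, `down_hyper`, `up_hyper`, `down_hypo`,
#' or `none`.  Genes with several promoters use the most significant
#' (smallest p) promoter, with a message.
#'
#' @param dm output of [differential_methylation()] on promoter regions.
#' @param de output of [differential_expression()].
#' @param promoter_to_gene data.frame mapping `region_id` to `gene_id`.
#' @return data.frame `gene_id`, `category`, `meth_flag`, `expr_call`.
#' @export
quadrant_assignment <- function(dm, de, promoter_to_gene) {
  stopifnot(all(c("region_id", "gene_id") %in% names(promoter_to_gene)))
  dm2 <- merge(dm, promoter_to_gene, by.x = "feature", by.y = "region_id")
  if (anyDuplicated(dm2$gene_id)) {
    message("genes with multiple promoters: keeping most significant promoter")
    dm2 <- dm2[order(dm2$gene_id, dm2$p), ]
    dm2 <- dm2[!duplicated(dm2$gene_id), ]
  }
  genes <- intersect(de$feature, dm2$gene_id)
  de2 <- de[match(genes, de$feature), ]
  dm2 <- dm2[match(genes, dm2$gene_id), ]
  expr_call <- ifelse(!de2$significant, "none",
                      ifelse(de2$t > 0, "up", "down"))
  category <- rep("none", length(genes))
  category[expr_call == "up" & dm2$flag == "hypo"] <- "up_hypo"
  category[expr_call == "down" & dm2$flag == "hyper"] <- "down_hyper"
  category[expr_call == "up" & dm2$flag == "hyper"] <- "up_hyper"
  category[expr_call == "down" & dm2$flag == "hypo"] <- "down_hypo"
  data.frame(gene_id = genes, category = category,
             meth_flag = dm2$flag, expr_call = expr_call,
             row.names = NULL)
}

#' Hypergeometric over-representation of a gene category in gene sets
#'
#' One-sided hypergeometric tail probability P(X >= overlap) for each
#' gene set restricted to the background, BH-adjusted across sets.
#' Sets with no member in the background are skipped with a warning.
#'
#' @param category_genes genes of interest (must be a subset of
#'   `background`).
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param background the gene universe.
#' @return data.frame `set`, `overlap`, `set_size`, `category_size`,
#'   `background_size`, `p`, `q`.
#' @export
overrepresentation_test <- function(category_genes, gene_sets, background) {
  background <- unique(background)
  if (!all(category_genes %in% background))
    stop("category genes must be a subset of the background")
  category_genes <- unique(category_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set_bg <- intersect(gene_sets[[nm]], background)
    if (!length(set_bg)) {
      warning("gene set '", nm, "' has no member in the background; skipped")
      return(NULL)
    }
    k <- length(intersect(set_bg, category_genes))
    p <- phyper(k - 1L, length(set_bg),
                length(background) - length(set_bg),
                length(category_genes), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set_bg),
               category_size = length(category_genes),
               background_size = length(background), p = p)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable gene set")
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Build promoter windows around transcription start sites
#'
#' Convention: 1,500 bp upstream to 500 bp downstream of the TSS,
#' strand-aware, 0-based half-open.  Used when no curated promoter
#' region map is supplied.
#'
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (0-based
#'   position), `strand` (`"+"`/`"-"`).
#' @param upstream,downstream window extent in bp.
#' @return regions data.frame compatible with [aggregate_to_regions()].
#' @export
build_promoter_windows <- function(tss, upstream = 1500, downstream = 500) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(tss)))
  plus <- tss$strand != "-"
  start <- ifelse(plus, tss$tss - upstream, tss$tss - downstream + 1L)
  end <- ifelse(plus, tss$tss + downstream, tss$tss + upstream + 1L)
  data.frame(region_id = paste0("prom_", tss$gene_id),
             chrom = tss$chrom,
             start = pmax(0L, as.integer(start)),
             end = as.integer(end),
             gene_id = tss$gene_id,
             stringsAsFactors = FALSE)
}
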