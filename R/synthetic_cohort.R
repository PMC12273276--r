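## synthetic_cohort: ground-truth cohorts with the statistical structure
## the analysis assumes.
##
## Methylation model per CpG site: a tumor beta drawn from a Beta
## distribution with concentration kappa around a class- and
## site-specific mean, then linearly mixed with a fixed normal-tissue
## profile according to tumor purity (observed = purity * tumor +
## (1 - purity) * normal).  The class/site mean structure has three
## layers, all on CpG-island "informative" sites:
##   * per-class private marker CpGs: bimodal sites near-fully methylated
##     in the owning class and unmethylated elsewhere (the analogue of
##     subtype-defining CpGs);
##   * a nested hypermethylation gradient LOW < INT < CIMP over shared
##     island sites, with DEM globally demethylated at those sites;
##   * DEM additionally loses methylation at a fraction of open-sea
##     sites (global demethylation).
## Gradient fractions are calibrated so the mean beta over informative
## sites per class equals the configured targets exactly (up to site
## discretization).  The site/gene architecture is drawn from
## `architecture_seed` so cohorts simulated from the same configuration
## share their biology and differ only in samples.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: four
#' latent classes of 40 samples each, 20,000 CpG sites (30% island),
#' 2,000 informative island sites with class mean beta 0.05 (DEM), 0.15
#' (LOW), 0.35 (INT) and 0.60 (CIMP), Beta-distributed noise with
#' concentration 20, tumor purity uniform on 0.6-1 mixed against a
#' normal profile (island 0.1, open sea 0.8), 5,000 genes of which 500
#' are promoter-coupled (expression anticorrelated with promoter beta)
#' and 50 immune genes shifted +1 z in LOW, exponential survival with a
#' 60-month baseline median for LOW and hazard ratios 1.8/2.0/2.8 for
#' DEM/INT/CIMP, uniform administrative censoring on 1.9-194.3 months,
#' and per-class progression probabilities 0.80/0.62/0.75/0.83.
#'
#' @param n_samples total samples (split evenly over the four classes).
#' @param n_sites number of CpG sites.
#' @param island_fraction fraction of sites in CpG islands.
#' @param n_informative informative island sites (class-dependent mean).
#' @param class_beta_means named class means of beta over informative
#'   sites; must be strictly increasing DEM < LOW < INT < CIMP.
#' @param kappa Beta-distribution concentration (larger = less noise).
#' @param purity_range uniform range of tumor purity.
#' @param normal_island_beta,normal_opensea_beta fixed normal profile.
#' @param n_marker private bimodal marker CpGs per class.
#' @param dem_opensea_frac fraction of open-sea sites demethylated in DEM.
#' @param n_genes,n_coupled genes total / promoter-coupled genes.
#' @param coupling_noise_sd sd of the expression noise added on top of
#'   the standardized (negated) promoter beta for coupled genes.
#' @param n_immune,immune_effect immune gene count and their mean z shift
#'   in LOW samples.
#' @param baseline_median_months median survival of the LOW class.
#' @param hazard_ratios per-class hazard ratios relative to LOW.
#' @param progression_prob per-class probability of AJCC stage progression.
#' @param cns_prob per-class probability that a progression reaches CNS
#'   disease (final stage IVM1D).
#' @param censor_range administrative censoring window (months).
#' @param architecture_seed seed for the site/gene architecture; shared
#'   architecture (same config) makes cohorts transferable.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 160,
                          n_sites = 20000,
                          island_fraction = 0.3,
                          n_informative = 2000,
                          class_beta_means = c(DEM = 0.05, LOW = 0.15,
                                               INT = 0.35, CIMP = 0.60),
                          kappa = 20,
                          purity_range = c(0.6, 1),
                          normal_island_beta = 0.1,
                          normal_opensea_beta = 0.8,
                          n_marker = 40,
                          dem_opensea_frac = 0.15,
                          n_genes = 5000,
                          n_coupled = 500,
                          coupling_noise_sd = 1,
                          n_immune = 50,
                          immune_effect = 1,
                          baseline_median_months = 60,
                          hazard_ratios = c(DEM = 1.8, LOW = 1,
                                            INT = 2.0, CIMP = 2.8),
                          progression_prob = c(DEM = 0.80, LOW = 0.62,
                                               INT = 0.75, CIMP = 0.83),
                          cns_prob = c(DEM = 0.25, LOW = 0.093,
                                       INT = 0.173, CIMP = 0.265),
                          censor_range = c(1.9, 194.3),
                          architecture_seed = 20250718) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config a `cohort_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(is.list(config))
  m <- config$class_beta_means
  if (!identical(names(m), .CLASSES) || any(diff(m) <= 0))
    stop("class_beta_means must be strictly increasing over ",
         paste(.CLASSES, collapse = " < "))
  n_island <- round(config$island_fraction * config$n_sites)
  if (config$n_informative > n_island)
    stop("n_informative (", config$n_informative,
         ") exceeds island sites (", n_island, ")")
  if (4L * config$n_marker >= config$n_informative)
    stop("4 * n_marker must be below n_informative")
  if (3L * config$n_coupled > config$n_informative)
    stop("need 3 informative sites per coupled gene")
  if (2L * (config$n_genes - config$n_coupled) > config$n_sites - config$n_informative)
    stop("not enough non-informative sites for non-coupled promoters")
  probs <- c(config$progression_prob, config$cns_prob, config$purity_range)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (config$n_immune > config$n_genes - config$n_coupled)
    stop("n_immune exceeds non-coupled genes")
  config
}

## Architecture: everything about sites/genes that must be shared across
## cohorts from the same config.  Deterministic given the config.
.cohort_architecture <- function(config) {
  with_seed(config$architecture_seed, {
    K <- config$n_informative
    n_sites <- config$n_sites
    n_island <- round(config$island_fraction * n_sites)
    classes <- .CLASSES
    means <- config$class_beta_means
    pos <- (seq_len(n_sites) - 1L) * 100L
    site_ids <- make_site_ids("chr1", pos)

    low_state <- runif(K, 0.03, 0.15)       # unmethylated island level
    marker_high <- runif(K, 0.92, 0.98)
    idx <- sample(K)
    ## per-class marker counts grow with the class's methylator strength,
    ## so the marker compartment itself encodes the DEM < ... < CIMP
    ## ordering (hypermethylator classes own more marker islands)
    m_per <- round(config$n_marker * c(DEM = 0.6, LOW = 0.85,
                                       INT = 1.15, CIMP = 1.4))
    bounds <- cumsum(c(0L, m_per))
    marker <- lapply(seq_along(classes), function(i)
      idx[(bounds[i] + 1L):bounds[i + 1L]])
    names(marker) <- classes
    n_marker_total <- bounds[length(bounds)]
    grad <- idx[(n_marker_total + 1L):K]
    G <- length(grad)
    lbar <- mean(low_state[grad])
    ## gradient target mean per class, after the exact marker contribution
    mk_sum <- vapply(classes, function(cl)
      sum(marker_high[marker[[cl]]]) + 0.01 * (n_marker_total - m_per[[cl]]),
      0)
    gm <- (K * means - mk_sum) / G
    fr <- pmax(0, (gm - lbar) / (0.77 - lbar))
    names(fr) <- classes
    napprox <- setNames(pmin(G, round(fr * G)), .CLASSES)
    ## stratum-specific amplitudes keep the marker compartment on top of
    ## the variance ranking while every gradient boundary stays represented
    h <- numeric(G)
    s1 <- seq_len(max(napprox[["LOW"]], 1L))
    s2 <- seq(napprox[["LOW"]] + 1L, max(napprox[["INT"]], napprox[["LOW"]] + 1L))
    s3 <- seq(max(napprox[["INT"]] + 1L, max(s2) + 1L), G)
    h[s1] <- runif(length(s1), 0.65, 0.82)
    h[s2] <- runif(length(s2), 0.55, 0.78)
    h[s3] <- runif(length(s3), 0.65, 0.82)

    M <- matrix(rep(low_state, 4L), K, 4L, dimnames = list(NULL, classes))
    for (cl in classes) {
      M[unlist(marker), cl] <- 0.01
      M[marker[[cl]], cl] <- marker_high[marker[[cl]]]
    }
    cs <- cumsum(h - low_state[grad])
    for (cl in classes) {
      target <- G * (gm[[cl]] - lbar)
      if (target <= 0) {
        M[grad, cl] <- max(0.015, gm[[cl]])
      } else {
        nc <- which.min(abs(cs - target))
        M[grad[seq_len(nc)], cl] <- h[seq_len(nc)]
      }
    }

    n_osea <- n_sites - n_island
    osea_dem <- n_island + seq_len(round(config$dem_opensea_frac * n_osea))
    normal <- c(rep(config$normal_island_beta, n_island),
                rep(config$normal_opensea_beta, n_osea))

    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    coupled <- gene_ids[seq_len(config$n_coupled)]
    immune <- sort(sample(setdiff(gene_ids, coupled), config$n_immune))
    ## promoters: coupled genes own consecutive informative triples,
    ## non-coupled genes consecutive non-informative pairs
    prom_sites <- c(lapply(seq_len(config$n_coupled), function(j)
                      (3L * j - 2L):(3L * j)),
                    lapply(seq_len(config$n_genes - config$n_coupled), function(j)
                      K + (2L * j - 1L):(2L * j)))
    regions <- data.frame(
      region_id = paste0("prom_", gene_ids),
      chrom = "chr1",
      start = vapply(prom_sites, function(s) pos[s[1L]], 0L),
      end = vapply(prom_sites, function(s) pos[s[length(s)]] + 2L, 0L),
      gene_id = gene_ids,
      stringsAsFactors = FALSE)

    list(site_ids = site_ids, n_island = n_island, M = M,
         normal = normal, osea_dem = osea_dem,
         informative_sites = site_ids[seq_len(K)],
         marker_sites = lapply(marker, function(i) site_ids[sort(i)]),
         gene_ids = gene_ids, coupled_genes = coupled,
         immune_genes = immune, regions = regions,
         prom_sites = prom_sites)
  })
}

#' Simulate survival times for a vector of class labels
#'
#' Exponential event times with class-specific hazards (baseline median
#' for LOW, configured hazard ratios for the rest) under uniform
#' administrative censoring.
#'
#' @param classes character/factor vector of class labels.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame `time` (months), `event` (1 = death observed).
#' @export
simulate_survival <- function(classes, config = cohort_config(), seed = 1) {
  with_seed(derive_seed(seed, "survival"), {
    lambda0 <- log(2) / config$baseline_median_months
    lam <- lambda0 * config$hazard_ratios[as.character(classes)]
    t_event <- rexp(length(lam), rate = lam)
    t_cens <- runif(length(lam), config$censor_range[1L], config$censor_range[2L])
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}

#' Simulate a full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for the sample-level draws (noise, purity,
#'   outcomes).  The site/gene architecture comes from
#'   `config$architecture_seed`.
#' @param cohort_tag label stored in the sample sheet.
#' @return a `meth_cohort` list: `beta` (sites x samples), `expression`
#'   (genes x samples, normalized scale), `sheet` (clinical sample
#'   sheet), `regions` (promoter BED-like table with `gene_id`), and
#'   `truth` (latent class per sample, informative/marker site ids,
#'   coupled and immune gene ids).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1,
                            cohort_tag = "synthetic") {
  validate_cohort_config(config)
  arch <- .cohort_architecture(config)
  n <- config$n_samples
  base <- n %/% 4L
  counts <- base + (seq_len(4L) <= n %% 4L)
  cls <- factor(rep(.CLASSES, times = counts), levels = .CLASSES, ordered = TRUE)
  sample_ids <- sprintf("%s_S%03d", cohort_tag, seq_len(n))
  K <- config$n_informative
  n_sites <- config$n_sites

  beta <- with_seed(derive_seed(seed, "beta"), {
    purity <- runif(n, config$purity_range[1L], config$purity_range[2L])
    out <- matrix(NA_real_, n_sites, n, dimnames = list(arch$site_ids, sample_ids))
    for (s in seq_len(n)) {
      mu <- arch$normal
      mu[seq_len(K)] <- arch$M[, as.character(cls[s])]
      if (cls[s] == "DEM") mu[arch$osea_dem] <- 0.05
      mu <- pmin(0.985, pmax(0.015, mu))
      tumor <- rbeta(n_sites, mu * config$kappa, (1 - mu) * config$kappa)
      out[, s] <- purity[s] * tumor + (1 - purity[s]) * arch$normal
    }
    attr(out, "purity") <- setNames(purity, sample_ids)
    out
  })
  purity <- attr(beta, "purity")
  attr(beta, "purity") <- NULL

  expr <- with_seed(derive_seed(seed, "expression"), {
    z <- matrix(rnorm(config$n_genes * n), config$n_genes, n,
                dimnames = list(arch$gene_ids, sample_ids))
    for (j in seq_len(config$n_coupled)) {
      pb <- colMeans(beta[arch$prom_sites[[j]], , drop = FALSE])
      z[j, ] <- -(pb - mean(pb)) / sd(pb) +
        rnorm(n, sd = config$coupling_noise_sd)
    }
    z[arch$immune_genes, cls == "LOW"] <-
      z[arch$immune_genes, cls == "LOW"] + config$immune_effect
    z
  })
  attr(expr, "values_type") <- "normalized"

  surv <- simulate_survival(cls, config, seed)
  clinical <- with_seed(derive_seed(seed, "progression"), {
    progressed <- rbinom(n, 1L, config$progression_prob[as.character(cls)]) == 1L
    cns <- rbinom(n, 1L, config$cns_prob[as.character(cls)]) == 1L
    final <- ifelse(progressed, ifelse(cns, "IVM1D", "IV"), "III")
    data.frame(progressed = progressed, stage_final = final)
  })
  sheet <- data.frame(
    sample_id = sample_ids,
    patient_id = sub("_S", "_P", sample_ids),
    cohort = cohort_tag,
    stage_initial = "III",
    stage_final = clinical$stage_final,
    progressed = clinical$progressed,
    os_months = surv$time,
    os_event = surv$event,
    purity = purity,
    stringsAsFactors = FALSE)
  structure(list(beta = beta, expression = expr,
                 sheet = validate_sample_sheet(sheet),
                 regions = arch$regions,
                 truth = list(class = setNames(cls, sample_ids),
                              informative_sites = arch$informative_sites,
                              marker_sites = arch$marker_sites,
                              coupled_genes = arch$coupled_genes,
                              immune_genes = arch$immune_genes),
                 config = config, seed = seed),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort:",
      ncol(x$beta), "samples,", nrow(x$beta), "CpG sites,",
      nrow(x$expression), "genes\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Ground-truth gene sets of a simulated cohort
#'
#' @param cohort a `meth_cohort`.
#' @return named list with the planted `immune_response` and
#'   `promoter_coupled` gene sets (GMT-compatible).
#' @export
truth_gene_sets <- function(cohort) {
  sets <- list(immune_response = cohort$truth$immune_genes,
               promoter_coupled = cohort$truth$coupled_genes)
  attr(sets, "descriptions") <- c(
    immune_response = "planted immune genes upregulated in LOW",
    promoter_coupled = "planted promoter-methylation-coupled genes")
  sets
}

#' Write a simulated cohort as a file bundle in the supported formats
#'
#' Writes `beta.tsv`, `expression.tsv`, `sample_sheet.csv` and
#' `promoters.bed`; regenerating with the same config and seed is
#' byte-identical.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param include_gmt also write the planted gene sets as
#'   `signatures.gmt`.
#' @return named character vector of file paths, invisibly.
#' @export
make_fixture_bundle <- function(config = cohort_config(), seed = 1,
                                out_dir, include_gmt = FALSE) {
  cohort <- simulate_cohort(config, seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    beta = file.path(out_dir, "beta.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    sheet = file.path(out_dir, "sample_sheet.csv"),
    regions = file.path(out_dir, "promoters.bed"))
  write_beta_matrix(cohort$beta, paths[["beta"]])
  write_beta_matrix(cohort$expression, paths[["expression"]], id_col = "gene_id")
  utils::write.csv(cohort$sheet, paths[["sheet"]], row.names = FALSE, quote = FALSE)
  write_region_bed(cohort$regions, paths[["regions"]])
  if (include_gmt) {
    paths <- c(paths, gmt = file.path(out_dir, "signatures.gmt"))
    write_gmt(truth_gene_sets(cohort), paths[["gmt"]])
  }
  invisible(paths)
}
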