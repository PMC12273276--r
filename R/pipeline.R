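## pipeline_cli: end-to-end orchestration from one configuration, with
## a run manifest (checksums, timings, warnings) and stage caching.

.default_run_config <- function() {
  list(
    data = list(source = "simulate", simulate = list(), files = list()),
    discover = list(fraction = 0.01, max_missing_frac = 0.2,
                    k_range = c(2, 6), n_resamples = 100,
                    subsample_frac = 0.8),
    classify = list(min_shared_sites = 100),
    integrate = list(group = "CIMP", delta = 0.1, alpha = 0.05,
                     n_perm = 0, min_sites = 1),
    score = list(min_genes = 3),
    survive = list(),
    stages = c("discover", "classify", "integrate", "score", "survive"))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      .merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Load and normalize a pipeline run configuration
#'
#' @param config a YAML file path or a nested list; missing entries are
#'   filled with defaults (see the methods vignette).
#' @return complete configuration list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_run_config(), config)
  if (cfg$data$source == "files") {
    for (f in unlist(cfg$data$files))
      if (!file.exists(f)) stop("configured input file does not exist: ", f)
  }
  cfg
}

.config_hash <- function(cfg, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(cfg = cfg, seed = seed),
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  setNames(unname(tools::md5sum(paths)), basename(paths))
}

#' Run the full methylation-class pipeline
#'
#' Executes, in dependency order: data loading (or simulation), class
#' discovery (panel selection + consensus clustering), centroid model
#' training, methylation-expression integration, signature scoring and
#' survival/progression analysis.  Every stage writes headered TSV
#' outputs to `out_dir`; a JSON manifest records the configuration
#' hash, per-stage output checksums, wall-clock times and warnings,
#' and a JSON summary collects the headline numbers.  Re-running with
#' an identical configuration and seed reuses cached stage outputs
#' (verified by checksum); a changed input file under an unchanged
#' configuration is reported as a checksum mismatch.
#'
#' @param config YAML path or list (see [load_run_config()]).
#' @param out_dir output directory.
#' @param seed master seed for all stochastic stages.
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  cfg <- load_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- .config_hash(cfg, seed)
  prev_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(prev_path))
    tryCatch(jsonlite::read_json(prev_path, simplifyVector = TRUE),
             error = function(e) NULL)
  manifest <- list(package_version = as.character(utils::packageVersion("methclass")),
                   config_hash = hash, seed = seed, stages = list())
  summary <- list(seed = seed)
  warnings_seen <- character()

  cacheable <- !is.null(prev) && identical(prev$config_hash, hash)
  ## guard against silently reusing a cache built from altered inputs
  if (cacheable && cfg$data$source == "files") {
    cur <- .checksums(unlist(cfg$data$files))
    rec <- unlist(prev$input_checksums)
    changed <- names(cur)[!is.na(rec[names(cur)]) & rec[names(cur)] != cur]
    if (length(changed))
      stop("checksum mismatch for input file '", changed[1L],
           "': content changed since the cached run")
  }

  run_stage <- function(name, outputs, fun) {
    t0 <- proc.time()[[3L]]
    paths <- file.path(out_dir, outputs)
    rec <- prev$stages[[name]]
    if (cacheable && !is.null(rec) &&
        length(rec$checksums) && all(file.exists(paths)) &&
        identical(unlist(rec$checksums), .checksums(paths))) {
      manifest$stages[[name]] <<- list(status = "cached",
                                       checksums = as.list(rec$checksums),
                                       seconds = 0)
      return(invisible(NULL))
    }
    result <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (inherits(result, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(result),
                                       seconds = proc.time()[[3L]] - t0)
      manifest$warnings <<- warnings_seen
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(result),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok",
                                     checksums = as.list(.checksums(paths)),
                                     seconds = round(proc.time()[[3L]] - t0, 3))
    invisible(result)
  }

  ## ---- data -------------------------------------------------------
  if (cfg$data$source == "simulate") {
    sim_cfg <- do.call(cohort_config, cfg$data$simulate)
    cohort <- simulate_cohort(sim_cfg, seed = seed)
    beta <- cohort$beta; expr <- cohort$expression
    sheet <- cohort$sheet; regions <- cohort$regions
    gene_sets <- truth_gene_sets(cohort)
    manifest$stages$data <- list(status = "ok", simulated = TRUE)
  } else {
    f <- cfg$data$files
    beta <- read_beta_matrix(f$beta)
    expr <- if (!is.null(f$expression))
      read_beta_matrix(f$expression, expect_beta = FALSE)
    sheet <- read_sample_sheet(f$sheet)
    regions <- if (!is.null(f$regions)) {
      r <- read_region_bed(f$regions)
      r$gene_id <- sub("^prom_", "", r$region_id)
      r
    }
    gene_sets <- if (!is.null(f$gmt)) read_gmt(f$gmt)
    manifest$input_checksums <- as.list(.checksums(unlist(f)))
    manifest$stages$data <- list(status = "ok", simulated = FALSE)
  }

  labels <- NULL
  ## ---- discover ---------------------------------------------------
  if ("discover" %in% cfg$stages) {
    run_stage("discover", c("panel.tsv", "labels.tsv"), function() {
      d <- cfg$discover
      panel <- select_variable_cpgs(beta, d$fraction, d$max_missing_frac)
      cc <- consensus_cluster(beta[panel$site_ids, , drop = FALSE],
                              k_range = seq(d$k_range[1], d$k_range[2]),
                              n_resamples = d$n_resamples,
                              subsample_frac = d$subsample_frac,
                              seed = seed)
      lab <- assign_class_labels(cc$labels, beta[panel$site_ids, , drop = FALSE])
      write.table(data.frame(site_id = panel$site_ids,
                             variance = panel$statistic),
                  file.path(out_dir, "panel.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(sample_id = names(lab),
                             class = as.character(lab),
                             merged = as.character(merge_classes(lab))),
                  file.path(out_dir, "labels.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$discover <<- list(
        chosen_k = cc$chosen_k,
        weak_structure = cc$weak_structure,
        delta_area = as.list(round(cc$delta_area, 4)),
        class_sizes = as.list(table(lab)),
        class_mean_beta = as.list(round(attr(lab, "class_means"), 4)))
      lab
    })
    lab_df <- read.delim(file.path(out_dir, "labels.tsv"))
    lv <- if (all(lab_df$class %in% .CLASSES))
      intersect(.CLASSES, unique(lab_df$class)) else sort(unique(lab_df$class))
    labels <- setNames(factor(lab_df$class, levels = lv, ordered = TRUE),
                       lab_df$sample_id)
  }

  panel_sites <- if (file.exists(file.path(out_dir, "panel.tsv")))
    read.delim(file.path(out_dir, "panel.tsv"))$site_id

  ## ---- classify (train + self-classification) ---------------------
  if ("classify" %in% cfg$stages && !is.null(labels)) {
    run_stage("classify", c("model.json", "classes.tsv"), function() {
      bp <- beta[panel_sites, , drop = FALSE]
      model <- train_centroid_classifier(bp, labels)
      write_centroid_model(model, file.path(out_dir, "model.json"))
      pred <- classify_samples(model, beta,
                               min_shared_sites = cfg$classify$min_shared_sites)
      write.table(pred, file.path(out_dir, "classes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$classify <<- list(
        self_consistency = mean(as.character(pred$class) ==
                                  as.character(labels[pred$sample_id]),
                                na.rm = TRUE))
      NULL
    })
  }

  ## ---- integrate --------------------------------------------------
  if ("integrate" %in% cfg$stages && !is.null(expr) && !is.null(regions) &&
      !is.null(labels)) {
    run_stage("integrate",
              c("dm.tsv", "de.tsv", "quadrants.tsv", "ora.tsv"), function() {
      it <- cfg$integrate
      region_beta <- aggregate_to_regions(beta, regions,
                                          min_sites = it$min_sites)
      dm <- differential_methylation(region_beta, labels, it$group,
                                     delta = it$delta, alpha = it$alpha)
      de <- differential_expression(expr, labels, it$group,
                                    n_perm = it$n_perm, seed = seed)
      quad <- quadrant_assignment(dm, de,
                                  regions[, c("region_id", "gene_id")])
      write.table(dm, file.path(out_dir, "dm.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(de, file.path(out_dir, "de.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(quad, file.path(out_dir, "quadrants.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (!is.null(gene_sets)) {
        dh <- quad$gene_id[quad$category == "down_hyper"]
        ora <- overrepresentation_test(dh, gene_sets, quad$gene_id)
        write.table(ora, file.path(out_dir, "ora.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        summary$integrate <<- list(
          group = it$group,
          quadrant_counts = as.list(table(quad$category)),
          down_hyper_top_set = ora$set[which.min(ora$p)],
          down_hyper_top_p = min(ora$p))
      } else {
        summary$integrate <<- list(group = it$group,
                                   quadrant_counts = as.list(table(quad$category)))
      }
      NULL
    })
  }

  ## ---- score ------------------------------------------------------
  if ("score" %in% cfg$stages && !is.null(expr) && !is.null(gene_sets) &&
      !is.null(labels)) {
    run_stage("score", c("scores.tsv", "associations.tsv"), function() {
      z <- zscore_normalize(expr)
      all_scores <- list(); assoc <- list()
      for (nm in names(gene_sets)) {
        sc <- signature_score(z, gene_sets[[nm]],
                              min_genes = cfg$score$min_genes, signature = nm)
        if (attr(sc, "status") != "ok") next
        sc <- dichotomize(sc)
        ca <- class_association(sc, labels)
        all_scores[[nm]] <- sc
        assoc[[nm]] <- data.frame(signature = nm,
                                  statistic = ca$statistic, df = ca$df,
                                  p = ca$p.value)
      }
      write.table(do.call(rbind, all_scores), file.path(out_dir, "scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(do.call(rbind, assoc), file.path(out_dir, "associations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$score <<- lapply(assoc, function(a)
        list(chisq = a$statistic, df = a$df, p = a$p))
      NULL
    })
  }

  ## ---- survive ----------------------------------------------------
  if ("survive" %in% cfg$stages && !is.null(labels)) {
    run_stage("survive", c("km.tsv", "progression.tsv"), function() {
      sh <- sheet[sheet$sample_id %in% names(labels), ]
      lab <- labels[sh$sample_id]
      km <- km_estimate(sh$os_months, sh$os_event, lab)
      lr <- logrank_test(sh$os_months, sh$os_event, lab)
      fu <- median_followup(sh$os_months, sh$os_event)
      prog <- progression_analysis(sh, labels)
      write.table(km, file.path(out_dir, "km.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      prog_df <- data.frame(class = rownames(prog$table),
                            not_progressed = prog$table[, "FALSE"],
                            progressed = prog$table[, "TRUE"],
                            pct_progressed = round(prog$pct_progressed, 2),
                            nonprogressor_share = round(prog$nonprogressor_share, 2))
      write.table(prog_df, file.path(out_dir, "progression.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summary$survive <<- list(
        km_median_months = as.list(attr(km, "medians")),
        logrank_chisq = lr$statistic, logrank_df = lr$df,
        logrank_p = lr$p.value,
        median_followup_months = fu$median,
        followup_range = c(fu$min, fu$max),
        progression_chisq = prog$statistic, progression_p = prog$p.value,
        nonprogressor_share = as.list(round(prog$nonprogressor_share, 2)))
      NULL
    })
  }

  manifest$warnings <- warnings_seen
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Render a human-readable report for a completed run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list with `markdown` (also written to `report.md`) and the
#'   parsed `summary`; sections for stages that did not run are marked
#'   absent.
#' @export
pipeline_report <- function(run_dir) {
  sp <- file.path(run_dir, "summary.json")
  if (!file.exists(sp)) stop("no summary.json in ", run_dir, "; incomplete run?")
  s <- jsonlite::read_json(sp, simplifyVector = TRUE)
  md <- c("# Methylation-class pipeline report", "")
  if (!is.null(s$discover)) {
    md <- c(md, "## Class discovery",
            paste0("- chosen number of classes: ", s$discover$chosen_k,
                   if (isTRUE(s$discover$weak_structure)) " (weak structure)" else ""),
            paste0("- class sizes: ",
                   paste(sprintf("%s=%s", names(s$discover$class_sizes),
                                 unlist(s$discover$class_sizes)), collapse = ", ")),
            paste0("- mean panel beta by class: ",
                   paste(sprintf("%s=%.3f", names(s$discover$class_mean_beta),
                                 unlist(s$discover$class_mean_beta)), collapse = ", ")),
            "")
  } else md <- c(md, "## Class discovery", "- absent", "")
  if (!is.null(s$integrate)) {
    md <- c(md, "## Methylation-expression integration",
            paste0("- contrast: ", s$integrate$group, " vs rest"),
            paste0("- quadrant counts: ",
                   paste(sprintf("%s=%s", names(s$integrate$quadrant_counts),
                                 unlist(s$integrate$quadrant_counts)), collapse = ", ")),
            if (!is.null(s$integrate$down_hyper_top_set))
              paste0("- top down_hyper enrichment: ", s$integrate$down_hyper_top_set,
                     " (p = ", signif(s$integrate$down_hyper_top_p, 3), ")"),
            "")
  } else md <- c(md, "## Methylation-expression integration", "- absent", "")
  if (!is.null(s$score) && length(s$score)) {
    md <- c(md, "## Signature associations",
            vapply(names(s$score), function(nm)
              paste0("- ", nm, ": chi-square = ",
                     signif(s$score[[nm]]$chisq, 4), ", p = ",
                     signif(s$score[[nm]]$p, 3)), ""),
            "")
  } else md <- c(md, "## Signature associations", "- absent", "")
  if (!is.null(s$survive)) {
    med <- unlist(s$survive$km_median_months)
    md <- c(md, "## Survival and progression",
            paste0("- KM median survival (months): ",
                   paste(sprintf("%s=%s", names(med), signif(med, 4)), collapse = ", ")),
            paste0("- log-rank: chi-square = ", signif(s$survive$logrank_chisq, 4),
                   " (df ", s$survive$logrank_df, "), p = ",
                   signif(s$survive$logrank_p, 3)),
            paste0("- median follow-up: ", signif(s$survive$median_followup_months, 4),
                   " months (range ", signif(s$survive$followup_range[1], 4), "-",
                   signif(s$survive$followup_range[2], 4), ")"),
            paste0("- non-progressor share by class (%): ",
                   paste(sprintf("%s=%s", names(s$survive$nonprogressor_share),
                                 unlist(s$survive$nonprogressor_share)), collapse = ", ")),
            "")
  } else md <- c(md, "## Survival and progression", "- absent", "")
  writeLines(md, file.path(run_dir, "report.md"))
  invisible(list(markdown = md, summary = s))
}
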