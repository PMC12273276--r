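## survival_outcomes: Kaplan-Meier, log-rank, follow-up, and stage
## progression by methylation class.  Estimation is delegated to the
## survival package (product-limit estimator, observed-minus-expected
## log-rank); this module packages the results in tabular form and adds
## the class-specific progression analysis.

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator with events processed before censorings at
#' tied times.
#'
#' @param times follow-up times (months, non-negative).
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups optional group labels (one curve per group).
#' @return data.frame `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` with per-group median survival in attribute
#'   `"medians"`.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  fit <- survival::survfit(survival::Surv(times, events) ~ grp,
                           data = data.frame(grp = as.character(groups)))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(as.character(groups)), length(sm$time))
         else sub("^grp=", "", as.character(sm$strata))
  out <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, n_censor = sm$n.censor,
                    surv = sm$surv, row.names = NULL)
  med <- summary(fit)$table
  medians <- if (is.null(dim(med))) setNames(med[["median"]], unique(grp))
             else setNames(med[, "median"], sub("^grp=", "", rownames(med)))
  attr(out, "medians") <- medians
  out
}

#' Log-rank test between survival curves
#'
#' @inheritParams km_estimate
#' @param groups group labels (at least 2 non-empty groups).
#' @return list `statistic` (chi-square), `df` (groups - 1), `p.value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (any(times < 0)) stop("negative survival time")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp,
                           data = data.frame(grp = groups))
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p.value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median follow-up time
#'
#' Plain median of the follow-up times of all subjects (the
#' "median (range)" convention), with the reverse Kaplan-Meier
#' estimate (censoring-event-reversed) available as an option.
#'
#' @param times follow-up times.
#' @param events event indicators (needed for `method = "reverse_km"`).
#' @param method `"plain"` or `"reverse_km"`.
#' @return list `median`, `min`, `max`, `method`.
#' @export
median_followup <- function(times, events = NULL,
                            method = c("plain", "reverse_km")) {
  method <- match.arg(method)
  if (!length(times)) stop("need at least one subject")
  med <- if (method == "plain") median(times) else {
    if (is.null(events)) stop("reverse_km needs event indicators")
    fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
    unname(summary(fit)$table[["median"]])
  }
  list(median = med, min = min(times), max = max(times), method = method)
}

#' Stage-progression analysis by methylation class
#'
#' Builds the patient-level class x progression contingency table and
#' its Pearson chi-square (no continuity correction).  Patients with
#' several lesions in different classes are counted once under their
#' worst (highest-beta) class, with a message.  Reports per-class
#' progression percentages, the distribution of classes among
#' non-progressors (summing to 100%), and a CNS-progression breakdown
#' when the final stage encodes CNS disease (IVM1D).
#'
#' @param sheet sample sheet (see [read_sample_sheet()]); needs a
#'   `progressed` flag or derivable `stage_initial`/`stage_final`.
#' @param labels class labels named by sample id.
#' @return list `table`, `statistic`, `df`, `p.value`,
#'   `pct_progressed` (per class), `nonprogressor_share` (per class, %
#'   of all non-progressors), `cns` (optional), `degenerate` flag.
#' @export
progression_analysis <- function(sheet, labels) {
  stopifnot(is.data.frame(sheet), "sample_id" %in% names(sheet))
  if (!"progressed" %in% names(sheet)) {
    if (!all(c("stage_initial", "stage_final") %in% names(sheet)))
      stop("need a progressed flag or stage_initial/stage_final")
    sheet$progressed <- .stage_rank(sheet$stage_final) >
      .stage_rank(sheet$stage_initial)
  }
  lab <- labels[sheet$sample_id]
  keep <- !is.na(lab) & !is.na(sheet$progressed)
  sheet <- sheet[keep, ]
  lab <- factor(as.character(lab[keep]),
                levels = intersect(.CLASSES, unique(as.character(lab[keep]))))
  ## patient-level: worst (highest-beta) class across a patient's lesions
  pid <- if ("patient_id" %in% names(sheet)) sheet$patient_id else sheet$sample_id
  if (anyDuplicated(pid)) {
    message("multi-lesion patient(s) resolved to their worst class")
    ord <- order(pid, -as.integer(lab))
    first <- !duplicated(pid[ord])
    sheet <- sheet[ord, ][first, ]
    lab <- lab[ord][first]
  }
  tab <- table(class = lab, progressed = factor(sheet$progressed,
                                                levels = c(FALSE, TRUE)))
  degenerate <- any(colSums(tab) == 0) || any(rowSums(tab) == 0)
  if (degenerate) {
    warning("degenerate progression table (empty margin); ",
            "chi-square not computed")
    stat <- NA_real_; df <- NA_integer_; p <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
  }
  pct_progressed <- 100 * tab[, "TRUE"] / rowSums(tab)
  nonprog <- tab[, "FALSE"]
  nonprog_share <- if (sum(nonprog) > 0) 100 * nonprog / sum(nonprog)
                   else nonprog * NA_real_
  res <- list(table = tab, statistic = stat, df = df, p.value = p,
              pct_progressed = pct_progressed,
              nonprogressor_share = nonprog_share,
              degenerate = degenerate)
  if ("stage_final" %in% names(sheet) &&
      any(grepl("IVM1D", toupper(sheet$stage_final)))) {
    cns <- grepl("IVM1D", toupper(sheet$stage_final))
    res$cns <- list(table = table(class = lab, cns = cns),
                    pct_cns = 100 * tapply(cns, lab, mean))
  }
  res
}
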