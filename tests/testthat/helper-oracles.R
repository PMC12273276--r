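## Independent brute-force / hand oracles.  These deliberately share no
## code with the package implementation.

## Product-limit estimator by direct looping over event times.
oracle_km <- function(times, events) {
  ord <- order(times, -events)  # events before censorings at ties
  times <- times[ord]; events <- events[ord]
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

## Two-group log-rank chi-square via the observed-minus-expected sum and
## hypergeometric variance at each distinct event time.
oracle_logrank2 <- function(times, events, groups) {
  g <- unique(groups)
  stopifnot(length(g) == 2L)
  ev_times <- sort(unique(times[events == 1]))
  OmE <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g[1L])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g[1L])
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- OmE^2 / V
  list(statistic = chisq, p.value = pchisq(chisq, 1, lower.tail = FALSE))
}

## Pearson chi-square by the textbook formula.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

## Hypergeometric upper tail P(X >= k) by explicit enumeration.
oracle_hyper <- function(k, set_size, background, category) {
  jmax <- min(set_size, category)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j)
    choose(set_size, j) * choose(background - set_size, category - j),
    0)) / choose(background, category)
}

## Exact two-sided rank-sum p by enumerating every assignment of the
## pooled observations to the two groups.
oracle_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(n, n1)
  w_all <- apply(splits, 2L, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

## Exact permutation p for the Welch t of one gene by enumerating all
## group assignments.
oracle_perm_t <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  t_of <- function(ii) {
    a <- pooled[ii]; b <- pooled[-ii]
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  t_obs <- t_of(seq_len(n1))
  splits <- combn(n, n1)
  t_all <- apply(splits, 2L, t_of)
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

## Enrichment score by a literal step-by-step running sum.
oracle_gsea_es <- function(ranked, gene_set, weight) {
  ord <- order(-ranked, names(ranked))
  stats <- ranked[ord]
  genes <- names(stats)
  nh <- sum(genes %in% gene_set)
  denom <- sum(abs(stats[genes %in% gene_set])^weight)
  running <- 0; best <- 0
  for (i in seq_along(genes)) {
    if (genes[i] %in% gene_set) {
      running <- running + if (denom > 0) abs(stats[i])^weight / denom else 1 / nh
    } else {
      running <- running - 1 / (length(genes) - nh)
    }
    if (abs(running) > abs(best)) best <- running
  }
  unname(best)
}
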