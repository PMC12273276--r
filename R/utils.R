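## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible sub-seed for a named stochastic stream so that
## independent routines never share an RNG stream.  Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## "chrom:pos" site ids (0-based positions).
make_site_ids <- function(chrom, pos) paste0(chrom, ":", pos)

parse_site_ids <- function(ids) {
  parts <- regmatches(ids, regexpr(":[0-9]+$", ids))
  pos <- as.integer(sub(":", "", parts))
  chrom <- sub(":[0-9]+$", "", ids)
  if (anyNA(pos)) stop("malformed site ids (expected 'chrom:pos'): ",
                       paste(head(ids[is.na(pos)], 3L), collapse = ", "))
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

## Ranking used wherever sites are ordered genomically.
order_sites <- function(ids) {
  p <- parse_site_ids(ids)
  order(p$chrom, p$pos)
}

stopifnot_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names")
  invisible(x)
}
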