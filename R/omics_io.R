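## omics_io: readers/writers for the standard formats the pipeline touches,
## plus beta-matrix assembly and hygiene.  Coordinates are 0-based
## half-open internally; Bismark coverage files (1-based inclusive) are
## converted on read.  Missing beta is always NA, never 0.

#' Read a Bismark-style coverage file
#'
#' Parses the six-column coverage format (chromosome, start, end,
#' methylation percentage, methylated count, unmethylated count).  The
#' percentage column is ignored: beta is recomputed from the counts,
#' which are exact.  Sites whose total coverage falls below
#' `min_coverage` are retained with a missing beta so that downstream
#' completeness filters stay explicit.
#'
#' @param path path to a tab- or space-separated coverage file.
#' @param min_coverage minimum methylated + unmethylated read count for a
#'   beta value to be considered informative (default 5).  Sites below
#'   the threshold get `beta = NA`.
#' @return data.frame with columns `site_id`, `chrom`, `pos` (0-based),
#'   `strand`, `n_meth`, `n_unmeth`, `beta`.
#' @export
read_bismark_coverage <- function(path, min_coverage = 5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty coverage file: ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 6L)
  if (length(bad))
    stop("malformed coverage line ", bad[1L], " in ", path,
         " (expected >= 6 fields, got ", n_fields[bad[1L]], ")")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  n_meth <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  n_unmeth <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  bad <- which(is.na(start) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad))
    stop("malformed coverage line ", bad[1L], " in ", path,
         " (non-numeric coordinate or count)")
  if (any(n_meth < 0 | n_unmeth < 0))
    stop("negative read count at coverage line ",
         which(n_meth < 0 | n_unmeth < 0)[1L], " in ", path)
  total <- n_meth + n_unmeth
  beta <- ifelse(total > 0, n_meth / total, NA_real_)
  beta[total < max(1L, min_coverage)] <- NA_real_
  pos <- start - 1L  # 1-based inclusive -> 0-based
  data.frame(site_id = make_site_ids(chrom, pos),
             chrom = chrom, pos = pos, strand = ".",
             n_meth = n_meth, n_unmeth = n_unmeth, beta = beta,
             stringsAsFactors = FALSE)
}

#' Assemble a beta matrix from per-sample site tables
#'
#' Takes the union of site ids across samples; site/sample pairs absent
#' from a sample's table are missing.  Rows are ordered genomically
#' (chromosome, then position), so the result is independent of the
#' input sample order.
#'
#' @param per_sample_sites named list of data.frames as returned by
#'   [read_bismark_coverage()]; names are sample ids.
#' @return numeric matrix (sites x samples) of beta values with a
#'   parallel integer `"coverage"` attribute.
#' @export
assemble_beta_matrix <- function(per_sample_sites) {
  if (!length(per_sample_sites)) stop("need at least one sample")
  ids <- names(per_sample_sites)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("per_sample_sites must be a named list (sample ids)")
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1L])
  all_sites <- unique(unlist(lapply(per_sample_sites, `[[`, "site_id")))
  all_sites <- all_sites[order_sites(all_sites)]
  beta <- matrix(NA_real_, length(all_sites), length(ids),
                 dimnames = list(all_sites, ids))
  cov <- matrix(0L, length(all_sites), length(ids),
                dimnames = list(all_sites, ids))
  for (s in ids) {
    tab <- per_sample_sites[[s]]
    i <- match(tab$site_id, all_sites)
    beta[i, s] <- tab$beta
    cov[i, s] <- as.integer(tab$n_meth + tab$n_unmeth)
  }
  attr(beta, "coverage") <- cov
  beta
}

#' Write / read a beta (or any feature-by-sample) matrix as TSV
#'
#' Sites as rows, first column `site_id`, remaining columns one per
#' sample.  The round trip is value-identical.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output/input path.
#' @param id_col name of the feature-id column (default `"site_id"`).
#' @return `write_beta_matrix`: the path, invisibly.
#'   `read_beta_matrix`: the matrix.
#' @export
write_beta_matrix <- function(mat, path, id_col = "site_id") {
  stopifnot_matrix(mat, "beta matrix")
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @param expect_beta warn when values fall outside \[0, 1\] (disable
#'   when reading expression matrices).
#' @export
read_beta_matrix <- function(path, expect_beta = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate feature ids in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  bad <- mat[!is.na(mat)]
  if (expect_beta && length(bad) && (min(bad) < 0 || max(bad) > 1))
    warning("values outside [0, 1] in ", path,
            "; not a beta matrix?")
  mat
}

#' Read a GMT gene-set collection
#'
#' Standard dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`.  Duplicate members within a set
#' are dropped with a warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors; set descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields ",
         "(empty member list?) in ", path)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name '", nm[duplicated(nm)][1L], "' in ", path)
  sets <- lapply(seq_along(fields), function(i) {
    members <- fields[[i]][-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members deduplicated in set '", nm[i], "'")
      members <- unique(members)
    }
    if (!length(members)) stop("empty member list in set '", nm[i], "'")
    members
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED4 region file (0-based, half-open)
#'
#' @param path BED file with columns chrom, start, end, name.
#' @return data.frame `region_id`, `chrom`, `start`, `end`.
#' @export
read_region_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED4 needs 4 columns in ", path)
  names(df)[1:4] <- c("chrom", "start", "end", "region_id")
  if (any(df$start >= df$end))
    stop("BED region with start >= end at line ",
         which(df$start >= df$end)[1L], " in ", path)
  if (anyDuplicated(df$region_id))
    stop("duplicate region id in ", path)
  df[, c("region_id", "chrom", "start", "end")]
}

#' Write regions to BED4
#' @param regions data.frame as from [read_region_bed()].
#' @param path output path.
#' @export
write_region_bed <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end", "region_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Columns every sample sheet must carry.
.SHEET_MANDATORY <- c("sample_id", "patient_id", "os_months", "os_event")

## AJCC stage ordering used for progression consistency checks.  Stages
## we cannot rank are skipped by the check.
.stage_rank <- function(stage) {
  stage <- toupper(trimws(as.character(stage)))
  rank <- rep(NA_real_, length(stage))
  rank[grepl("^III", stage)] <- 3
  rank[grepl("^IV", stage)] <- 4
  rank[grepl("^IVM1D$", stage)] <- 4.5
  rank
}

#' Read and validate a clinical sample sheet
#'
#' Headered CSV, one row per sample.  Mandatory columns: `sample_id`,
#' `patient_id`, `os_months`, `os_event`.  Recognized optional columns:
#' `cohort`, `stage_initial`, `stage_final`, `progressed`, `rfs_months`,
#' `rfs_event`, `purity`.  Unknown columns are preserved.  Validation:
#' non-negative times, purity in \[0, 1\], and consistency of the
#' progression flag with the initial/final AJCC stages when all are
#' present.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet data.frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  missing_cols <- setdiff(.SHEET_MANDATORY, names(sheet))
  if (length(missing_cols))
    stop("sample sheet is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  for (col in intersect(c("os_months", "rfs_months"), names(sheet))) {
    if (any(sheet[[col]] < 0, na.rm = TRUE))
      stop("negative times in column ", col)
  }
  for (col in intersect(c("os_event", "rfs_event", "progressed"), names(sheet))) {
    v <- sheet[[col]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
    sheet[[col]] <- as.logical(as.integer(as.logical(v)))
    if (anyNA(sheet[[col]]) && !anyNA(v))
      stop("column ", col, " is not interpretable as 0/1 flags")
  }
  if ("purity" %in% names(sheet) &&
      any(sheet$purity < 0 | sheet$purity > 1, na.rm = TRUE))
    stop("purity outside [0, 1]")
  if (all(c("stage_initial", "stage_final", "progressed") %in% names(sheet))) {
    ri <- .stage_rank(sheet$stage_initial)
    rf <- .stage_rank(sheet$stage_final)
    ok <- is.na(ri) | is.na(rf) | is.na(sheet$progressed)
    inconsistent <- !ok & ((rf > ri) != sheet$progressed)
    if (any(inconsistent))
      stop("progression flag inconsistent with stages for sample(s): ",
           paste(head(sheet$sample_id[inconsistent], 3L), collapse = ", "))
  }
  sheet
}

#' Write result tables as headered TSV files
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @return character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}
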