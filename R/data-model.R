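#' Assemble and validate a samples-by-metabolites abundance table
#'
#' A `sample_table` couples a strictly positive AUC (mass-spectrometry peak
#' area) matrix with per-sample metadata. Abundances must be complete and
#' positive because every downstream statistic works on log2-transformed
#' values; cohorts with missing cells are rejected rather than imputed.
#'
#' @param auc Numeric matrix, samples in rows, metabolites in columns, with
#'   unique row and column names. All values must be finite and `> 0`.
#' @param metadata Data frame with columns `sample_id`, `group` (values
#'   `"case"` or `"control"`), `sex` (`"M"`/`"F"`), and `cohort`. Must cover
#'   every sample in `auc`.
#' @return An object of class `sample_table`: a list with elements `auc`
#'   (matrix) and `meta` (data frame aligned to the rows of `auc`).
#' @seealso [read_sample_table()], [zscore_transform()]
#' @examples
#' auc <- matrix(2^rnorm(6, 20), 3, 2,
#'               dimnames = list(paste0("s", 1:3), c("ATP", "GMP")))
#' meta <- data.frame(sample_id = paste0("s", 1:3),
#'                    group = c("case", "control", "control"),
#'                    sex = "M", cohort = "demo")
#' sample_table(auc, meta)
#' @export
sample_table <- function(auc, metadata) {
  if (!is.matrix(auc) || !is.numeric(auc)) stop("`auc` must be a numeric matrix")
  if (is.null(rownames(auc)) || is.null(colnames(auc)))
    stop("`auc` needs sample row names and metabolite column names")
  if (anyDuplicated(rownames(auc))) stop("duplicated sample ids in `auc`")
  if (anyDuplicated(colnames(auc))) {
    stop("duplicated metabolite ids: ",
         paste(unique(colnames(auc)[duplicated(colnames(auc))]), collapse = ", "))
  }
  bad <- which(!is.finite(auc) | auc <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("missing or non-positive AUC at sample '", rownames(auc)[bad[1, 1]],
         "', metabolite '", colnames(auc)[bad[1, 2]],
         "' (", nrow(bad), " offending cell(s)); log2 requires complete positive data")
  }
  need <- c("sample_id", "group", "sex", "cohort")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  metadata <- as.data.frame(metadata)[, need]
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample ids in metadata")
  absent <- setdiff(rownames(auc), metadata$sample_id)
  if (length(absent)) {
    stop("sample(s) in the AUC table absent from metadata: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  metadata <- metadata[match(rownames(auc), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$group %in% c("case", "control")))
    stop("metadata `group` must be 'case' or 'control'")
  if (sum(metadata$group == "control") < 2)
    stop("at least 2 control samples are required to compute control SDs")
  structure(list(auc = auc, meta = metadata), class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("<sample_table> ", nrow(x$auc), " samples x ", ncol(x$auc), " metabolites\n", sep = "")
  cat("  groups: ", paste(sprintf("%s=%d", names(table(x$meta$group)),
                                  table(x$meta$group)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an abundance matrix and sample metadata from delimited text
#'
#' Reads a CSV/TSV abundance table (delimiter sniffed from the extension,
#' falling back to content) together with a metadata table, auto-detects the
#' orientation of the abundance matrix, and returns a validated
#' [sample_table()]. Rows are taken to be samples when the first column
#' matches the metadata sample ids; when the header matches them instead,
#' the matrix is transposed.
#'
#' @param path Path to the abundance table. First column holds row ids.
#' @param metadata_path Path to the metadata table with columns `sample_id`,
#'   `group`, `sex`, `cohort`.
#' @return A validated [sample_table()].
#' @export
read_sample_table <- function(path, metadata_path) {
  meta <- .read_delim(metadata_path)
  tab <- .read_delim(path)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  row_hits <- mean(ids %in% meta$sample_id)
  col_hits <- mean(colnames(mat) %in% meta$sample_id)
  if (col_hits > 0.5 && col_hits > row_hits) mat <- t(mat)
  sample_table(mat, meta)
}

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  if (sep == "," && !grepl(",", first, fixed = TRUE) && grepl("\t", first, fixed = TRUE)) sep <- "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "",
                    fileEncoding = "UTF-8")
}

#' Read a metabolite-to-pathway annotation map
#'
#' Expects a two-column table (`metabolite_id`, `pathway`). Each metabolite
#' must map to exactly one pathway; exact duplicate rows are tolerated and
#' deduplicated, conflicting assignments are an error.
#'
#' @param path Path to a CSV/TSV file.
#' @return A named character vector of class `pathway_map` (names are
#'   metabolite ids, values pathway names).
#' @export
read_pathway_map <- function(path) {
  tab <- .read_delim(path)
  if (ncol(tab) < 2) stop("pathway map needs two columns (metabolite_id, pathway)")
  pathway_map(as.character(tab[[1]]), as.character(tab[[2]]))
}

#' Construct a pathway map from parallel vectors
#'
#' @param metabolite_id Character vector of metabolite ids.
#' @param pathway Character vector of pathway names, one per metabolite.
#' @return Named character vector of class `pathway_map`.
#' @export
pathway_map <- function(metabolite_id, pathway) {
  stopifnot(length(metabolite_id) == length(pathway))
  keep <- !duplicated(paste(metabolite_id, pathway, sep = "\r"))
  metabolite_id <- metabolite_id[keep]; pathway <- pathway[keep]
  dup <- metabolite_id[duplicated(metabolite_id)]
  if (length(dup)) {
    stop("metabolite(s) assigned to more than one pathway: ",
         paste(unique(dup), collapse = ", "))
  }
  pm <- structure(pathway, names = metabolite_id, class = "pathway_map")
  sizes <- table(pathway)
  message(length(sizes), " pathways over ", length(pm), " metabolites (sizes ",
          min(sizes), "-", max(sizes), ", median ", stats::median(sizes), ")")
  pm
}

#' @export
print.pathway_map <- function(x, ...) {
  cat("<pathway_map> ", length(x), " metabolites in ",
      length(unique(unclass(x))), " pathways\n", sep = "")
  invisible(x)
}

#' Control-referenced z-scores of log2 abundances
#'
#' Transforms each AUC to `(log2(auc) - control_mean) / control_sd`, where
#' the per-metabolite reference mean and SD (sample SD, `n - 1` denominator)
#' are computed on the control group only. Case samples are thereby expressed
#' in control-SD units. With `by_sex = TRUE` the reference statistics are
#' computed within each sex and applied to samples of the same sex, matching
#' sex-stratified network analyses.
#'
#' Pearson correlations downstream are invariant to this affine per-column
#' transformation; the scaling matters for effect-size reporting, not for
#' network topology.
#'
#' @param table A [sample_table()].
#' @param by_sex Use sex-matched control references (default `FALSE`).
#' @return An object of class `zmatrix`: list with `z` (samples x
#'   metabolites), `meta`, `control_mean`, `control_sd` (per metabolite; one
#'   row per sex when `by_sex`).
#' @export
zscore_transform <- function(table, by_sex = FALSE) {
  stopifnot(inherits(table, "sample_table"))
  lg <- log2(table$auc)
  strata <- if (by_sex) split(seq_len(nrow(lg)), table$meta$sex)
            else list(all = seq_len(nrow(lg)))
  z <- lg
  cm_out <- csd_out <- NULL
  for (snm in names(strata)) {
    rows <- strata[[snm]]
    ctrl <- rows[table$meta$group[rows] == "control"]
    if (length(ctrl) < 2)
      stop("stratum '", snm, "' has fewer than 2 control samples")
    cm <- colMeans(lg[ctrl, , drop = FALSE])
    csd <- apply(lg[ctrl, , drop = FALSE], 2, stats::sd)
    flat <- csd <= 0 | !is.finite(csd)
    if (any(flat)) {
      stop("metabolite(s) constant across controls (SD = 0): ",
           paste(colnames(lg)[flat], collapse = ", "))
    }
    z[rows, ] <- sweep(sweep(lg[rows, , drop = FALSE], 2, cm), 2, csd, "/")
    cm_out <- rbind(cm_out, cm); csd_out <- rbind(csd_out, csd)
  }
  rownames(cm_out) <- rownames(csd_out) <- names(strata)
  structure(list(z = z, meta = table$meta,
                 control_mean = cm_out, control_sd = csd_out,
                 by_sex = by_sex),
            class = "zmatrix")
}

#' @export
print.zmatrix <- function(x, ...) {
  cat("<zmatrix> ", nrow(x$z), " samples x ", ncol(x$z), " metabolites",
      if (x$by_sex) " (sex-stratified reference)", "\n", sep = "")
  invisible(x)
}

#' Subset a z-score matrix by group, sex, or explicit sample ids
#'
#' @param z A `zmatrix`.
#' @param group,sex Optional metadata filters.
#' @param sample_ids Optional explicit id selection (applied last).
#' @return A `zmatrix` restricted to the selected samples.
#' @export
subset_samples <- function(z, group = NULL, sex = NULL, sample_ids = NULL) {
  stopifnot(inherits(z, "zmatrix"))
  keep <- rep(TRUE, nrow(z$z))
  if (!is.null(group)) keep <- keep & z$meta$group %in% group
  if (!is.null(sex)) keep <- keep & z$meta$sex %in% sex
  if (!is.null(sample_ids)) {
    missing_ids <- setdiff(sample_ids, rownames(z$z))
    if (length(missing_ids)) stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
    keep <- keep & rownames(z$z) %in% sample_ids
  }
  z$z <- z$z[keep, , drop = FALSE]
  z$meta <- z$meta[keep, , drop = FALSE]
  z
}
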