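#' Construct an expression matrix container
#'
#' Bundles a log2-scale expression matrix (genes/probes in rows, samples in
#' columns) with an optional matrix of detection p-values of identical shape.
#' All downstream functions in the package operate on this container. Values
#' are log2-scale by contract; no automatic log detection is attempted.
#'
#' Row names may repeat at probe level (several probes per gene) until
#' [collapse_probes()] is applied; column (sample) names must be unique.
#'
#' @param values Numeric matrix with row names (gene/probe ids) and unique
#'   column names (sample ids). No missing values allowed.
#' @param detection_p Optional numeric matrix of the same dimensions with
#'   per-cell detection p-values in \[0, 1\].
#' @param platform Free-text platform tag carried along for provenance.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `detection_p` and `platform`.
#' @seealso [read_expression_tsv()], [quantile_normalize()], [filter_probes()]
#' @export
ExpressionMatrix <- function(values, detection_p = NULL, platform = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (genes) and column names (samples)")
  if (anyNA(values))
    stop("`values` must not contain missing values")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !all(dim(detection_p) == dim(values)))
      stop("`detection_p` must be a matrix with the same dimensions as `values`")
    if (anyNA(detection_p) || any(detection_p < 0) || any(detection_p > 1))
      stop("`detection_p` values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(list(values = values, detection_p = detection_p,
                 platform = platform),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$detection_p)) " (with detection p-values)" else "",
              if (nzchar(x$platform)) paste0(" [", x$platform, "]") else ""))
  invisible(x)
}

# Strict TSV table parse shared by the readers: enforces rectangular layout
# and numeric cells, reporting the 1-based file line of the first offence.
parse_numeric_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("file ", path, " must contain a header line and at least one row")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L)
    stop("header of ", path, " names no sample columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop("line ", bad[1L] + 1L, " of ", path, " has ", nfield[bad[1L]],
         " fields, expected ", length(header))
  ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(sample_ids))))
  vals <- matrix(vals, nrow = length(sample_ids))
  if (anyNA(vals)) {
    bad_row <- which(apply(vals, 2L, anyNA))[1L]
    stop("non-numeric value on line ", bad_row + 1L, " of ", path)
  }
  m <- t(vals)
  dimnames(m) <- list(ids, sample_ids)
  m
}

#' Read a tab-delimited expression matrix
#'
#' First column holds gene/probe ids, the header row the sample ids. An
#' optional companion file of identical layout supplies detection p-values.
#' Duplicate row ids are permitted (probe-level data) and are resolved later
#' by [collapse_probes()].
#'
#' @param path Path to the expression TSV.
#' @param detection_path Optional path to a detection p-value TSV with the
#'   same row/column layout.
#' @param platform Platform tag stored in the result.
#' @return An [ExpressionMatrix()].
#' @export
read_expression_tsv <- function(path, detection_path = NULL, platform = "") {
  vals <- parse_numeric_tsv(path)
  dp <- NULL
  if (!is.null(detection_path)) {
    dp <- parse_numeric_tsv(detection_path)
    if (!identical(dim(dp), dim(vals)) ||
        !identical(rownames(dp), rownames(vals)) ||
        !identical(colnames(dp), colnames(vals)))
      stop("detection p-value file layout does not match the expression file")
  }
  ExpressionMatrix(vals, detection_p = dp, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; round-trips exactly on text produced
#' by this writer (values are written with full precision).
#'
#' @param em An [ExpressionMatrix()].
#' @param path Output path for the expression values.
#' @param detection_path Optional output path for the detection p-values.
#' @export
write_expression_tsv <- function(em, path, detection_path = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  write_matrix <- function(m, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
    body <- apply(m, 1L, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  }
  write_matrix(em$values, path)
  if (!is.null(detection_path)) {
    if (is.null(em$detection_p))
      stop("no detection p-values to write")
    write_matrix(em$detection_p, detection_path)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT format: one gene set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' discarded.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene ids, with attribute
#'   `source` recording the file of origin. An empty file yields an empty
#'   collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list()
    attr(out, "source") <- path
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("line ", short[1L], " of ", path,
         " has fewer than 3 fields (name, description, >=1 gene)")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  out <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(out) <- nm
  attr(out, "source") <- path
  out
}

#' Write a gene-set collection as GMT
#'
#' @param collection Named list of character vectors of gene ids.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  writeLines(vapply(names(collection), function(nm)
    paste(c(nm, "na", collection[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Tab-delimited with required columns `sample_id`, `time_months`, `event`
#' and optional `age_years`, `size_cm`, `ggi`, `treatment`, `subtype`.
#'
#' @param path Path to the TSV.
#' @return A data.frame with one row per patient.
#' @export
read_clinical_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "time_months", "event")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("clinical table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(ann$time_months <= 0)) stop("all `time_months` must be > 0")
  if (!all(ann$event %in% c(0, 1))) stop("`event` must be 0/1")
  ann
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same value distribution by
#' replacing each value with the mean of the values at its rank across
#' samples. Deterministic and rank-preserving within each sample; used as the
#' normalization step of the cell-line preprocessing.
#'
#' @param em An [ExpressionMatrix()] with at least 2 samples.
#' @return A quantile-normalized [ExpressionMatrix()] (detection p-values and
#'   platform tag are carried through unchanged).
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  x <- em$values
  if (ncol(x) < 2L)
    stop("quantile normalization requires at least 2 samples")
  means <- rowMeans(apply(x, 2L, sort, method = "radix"))
  out <- apply(x, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (means[lo] + means[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  ExpressionMatrix(out, detection_p = em$detection_p, platform = em$platform)
}

#' Filter probes by detection p-value
#'
#' Retains exactly the rows whose minimum detection p-value over samples is
#' strictly below `p_cut`, i.e. probes detected (p < cut) in at least one
#' sample. Intended for bead-array style cell-line data; cohort matrices
#' without detection p-values bypass this step.
#'
#' @param em An [ExpressionMatrix()] carrying detection p-values.
#' @param p_cut Detection p-value cutoff (default 0.01, strict `<`).
#' @return The filtered [ExpressionMatrix()].
#' @export
filter_probes <- function(em, p_cut = 0.01) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(em$detection_p))
    stop("no detection p-values present; skip detection filtering for this matrix")
  keep <- apply(em$detection_p, 1L, min) < p_cut
  ExpressionMatrix(em$values[keep, , drop = FALSE],
                   detection_p = em$detection_p[keep, , drop = FALSE],
                   platform = em$platform)
}

#' Collapse probes to one row per gene
#'
#' For each gene the probe with the highest detection rate is chosen; with
#' equal detection rates, the probe with the highest interquartile range;
#' residual ties are broken by lexicographic probe id so the choice is
#' reproducible.
#'
#' @param em An [ExpressionMatrix()] whose rows are probes.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`,
#'   `detection_rate` (in \[0, 1\]) and `iqr` (>= 0); every matrix row id
#'   must be present.
#' @return An [ExpressionMatrix()] with one row per gene, rows renamed to
#'   gene ids.
#' @export
collapse_probes <- function(em, probe_map) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  req <- c("probe_id", "gene_id", "detection_rate", "iqr")
  if (!all(req %in% names(probe_map)))
    stop("`probe_map` must have columns ", paste(req, collapse = ", "))
  if (any(probe_map$detection_rate < 0 | probe_map$detection_rate > 1))
    stop("`detection_rate` must lie in [0, 1]")
  if (any(probe_map$iqr < 0)) stop("`iqr` must be >= 0")
  probes <- rownames(em$values)
  unmapped <- setdiff(probes, probe_map$probe_id)
  if (length(unmapped))
    stop("probe id(s) missing from `probe_map`: ",
         paste(unmapped, collapse = ", "))
  pm <- probe_map[match(probes, probe_map$probe_id), ]
  ord <- order(pm$gene_id, -pm$detection_rate, -pm$iqr, pm$probe_id,
               method = "radix")
  pm_sorted <- pm[ord, ]
  keep_idx <- sort(ord[!duplicated(pm_sorted$gene_id)])  # keep input row order
  vals <- em$values[keep_idx, , drop = FALSE]
  rownames(vals) <- pm$gene_id[keep_idx]
  dp <- em$detection_p
  if (!is.null(dp)) {
    dp <- dp[keep_idx, , drop = FALSE]
    rownames(dp) <- pm$gene_id[keep_idx]
  }
  ExpressionMatrix(vals, detection_p = dp, platform = em$platform)
}
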