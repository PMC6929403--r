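#' Expression matrix with tumor/normal pairing metadata
#'
#' Container for a non-negative RNA-by-sample expression matrix annotated with
#' an RNA type per row (`lncRNA`, `miRNA` or `mRNA`) and, per column, a
#' condition (`tumor` or `normal`) and a patient pair identifier. When both
#' conditions are present the design must be fully paired: every pair
#' identifier occurs exactly once as tumor and once as normal.
#'
#' @param values numeric matrix, rows = RNAs (unique rownames), columns =
#'   samples (unique colnames); all entries finite and >= 0.
#' @param rna_types character vector of length `nrow(values)` with values in
#'   `lncRNA`, `miRNA`, `mRNA`.
#' @param conditions character vector of length `ncol(values)` with values in
#'   `tumor`, `normal`.
#' @param pair_ids character vector of length `ncol(values)`; patient
#'   identifier shared by a tumor/normal sample pair.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, rna_types, conditions, pair_ids) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("`values` must have RNA rownames and sample colnames", call. = FALSE)
  }
  x <- structure(
    list(
      values = values,
      rna_types = as.character(rna_types),
      conditions = as.character(conditions),
      pair_ids = as.character(pair_ids)
    ),
    class = "expression_matrix"
  )
  validate_expression_matrix(x)
}

RNA_TYPES <- c("lncRNA", "miRNA", "mRNA")
CONDITIONS <- c("tumor", "normal")

#' Validate an expression matrix
#'
#' Checks dimensions, finiteness, non-negativity, identifier uniqueness and
#' the paired design (see [expression_matrix()]). Called by the constructor;
#' exposed so that externally assembled objects can be re-checked.
#'
#' @param x an `expression_matrix`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_expression_matrix <- function(x) {
  v <- x$values
  if (anyDuplicated(rownames(v))) {
    dup <- rownames(v)[duplicated(rownames(v))][1L]
    stop("duplicate RNA id: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(v))) {
    dup <- colnames(v)[duplicated(colnames(v))][1L]
    stop("duplicate sample id: ", dup, call. = FALSE)
  }
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at RNA '", rownames(v)[bad[1L]],
         "', sample '", colnames(v)[bad[2L]], "'", call. = FALSE)
  }
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop("negative expression value at RNA '", rownames(v)[bad[1L]],
         "', sample '", colnames(v)[bad[2L]], "'", call. = FALSE)
  }
  if (length(x$rna_types) != nrow(v)) {
    stop("rna_types length (", length(x$rna_types), ") != number of RNAs (",
         nrow(v), ")", call. = FALSE)
  }
  if (!all(x$rna_types %in% RNA_TYPES)) {
    bad <- setdiff(unique(x$rna_types), RNA_TYPES)[1L]
    stop("unknown RNA type '", bad, "' (expected lncRNA/miRNA/mRNA)",
         call. = FALSE)
  }
  if (length(x$conditions) != ncol(v) || length(x$pair_ids) != ncol(v)) {
    stop("conditions/pair_ids must have one entry per sample", call. = FALSE)
  }
  if (!all(x$conditions %in% CONDITIONS)) {
    bad <- setdiff(unique(x$conditions), CONDITIONS)[1L]
    stop("unknown condition '", bad, "' (expected tumor/normal)", call. = FALSE)
  }
  for (cond in intersect(CONDITIONS, x$conditions)) {
    p <- x$pair_ids[x$conditions == cond]
    if (anyDuplicated(p)) {
      stop("pair_id '", p[duplicated(p)][1L], "' occurs more than once with ",
           "condition=", cond, call. = FALSE)
    }
  }
  if (all(CONDITIONS %in% x$conditions)) {
    pt <- x$pair_ids[x$conditions == "tumor"]
    pn <- x$pair_ids[x$conditions == "normal"]
    miss <- c(setdiff(pt, pn), setdiff(pn, pt))
    if (length(miss)) {
      stop("unpaired sample: pair_id '", miss[1L],
           "' lacks its tumor or normal mate", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "RNAs x", ncol(x$values),
      "samples\n")
  cat("  RNA types:   ",
      paste(sprintf("%s=%d", names(table(x$rna_types)), table(x$rna_types)),
            collapse = ", "), "\n")
  cat("  conditions:  ",
      paste(sprintf("%s=%d", names(table(x$conditions)), table(x$conditions)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Accessors for expression-matrix metadata
#'
#' @param x an `expression_matrix`.
#' @return character vectors of identifiers or labels, or the numeric value
#'   matrix for `expr_values()`.
#' @name expression-accessors
NULL

#' @rdname expression-accessors
#' @export
rna_ids <- function(x) rownames(x$values)

#' @rdname expression-accessors
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expression-accessors
#' @export
rna_types <- function(x) stats::setNames(x$rna_types, rownames(x$values))

#' @rdname expression-accessors
#' @export
conditions <- function(x) stats::setNames(x$conditions, colnames(x$values))

#' @rdname expression-accessors
#' @export
pair_ids <- function(x) stats::setNames(x$pair_ids, colnames(x$values))

#' @rdname expression-accessors
#' @export
expr_values <- function(x) x$values

#' Read expression and sample-metadata tables
#'
#' The expression file is a TSV whose header row names the samples; the first
#' column holds the RNA identifier and the second its type. The metadata file
#' is a TSV with columns `sample_id`, `condition`, `pair_id`. Every sample in
#' the expression header must be described in the metadata.
#'
#' @param expression_path path to the expression TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @return a validated [expression_matrix()].
#' @export
read_expression_table <- function(expression_path, metadata_path) {
  expr <- utils::read.delim(expression_path, header = TRUE, sep = "\t",
                            quote = "", check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 3L) {
    stop("expression table needs rna_id, rna_type and >= 1 sample column",
         call. = FALSE)
  }
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            quote = "", check.names = FALSE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "pair_id")
  if (!all(need %in% colnames(meta))) {
    stop("metadata table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rna_id <- as.character(expr[[1L]])
  rna_type <- as.character(expr[[2L]])
  sample_cols <- colnames(expr)[-(1:2)]
  vals <- as.matrix(expr[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- sample_cols[!vapply(expr[-(1:2)], is.numeric, logical(1))][1L]
    stop("non-numeric expression values in sample column '", bad, "'",
         call. = FALSE)
  }
  rownames(vals) <- rna_id
  missing_meta <- setdiff(sample_cols, meta$sample_id)
  if (length(missing_meta)) {
    stop("sample '", missing_meta[1L], "' in expression header is absent ",
         "from the metadata table", call. = FALSE)
  }
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  expression_matrix(vals, rna_type, meta$condition, meta$pair_id)
}

#' Write expression and sample-metadata tables
#'
#' Inverse of [read_expression_table()]; numbers are written at full
#' precision so a write/read round trip reproduces the matrix exactly.
#'
#' @param x an `expression_matrix`.
#' @param expression_path,metadata_path output TSV paths.
#' @return `x`, invisibly.
#' @export
write_expression_table <- function(x, expression_path, metadata_path) {
  df <- data.frame(rna_id = rna_ids(x), rna_type = x$rna_types,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = sample_ids(x), condition = x$conditions,
                     pair_id = x$pair_ids, stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Remove low-frequency RNAs
#'
#' Drops RNAs that are expressed (value strictly greater than zero) in fewer
#' than `ceiling(min_fraction * n_samples)` samples. Such sparsely expressed
#' RNAs carry little information for the downstream binarization and mostly
#' contribute noise.
#'
#' @param x an `expression_matrix`.
#' @param min_fraction minimum fraction of samples with nonzero expression,
#'   in (0, 1]; default 0.5 (expressed in at least half the samples).
#' @return the filtered `expression_matrix`; retained rows are unchanged.
#' @export
filter_low_expression <- function(x, min_fraction = 0.5) {
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1L)
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must be in (0, 1]", call. = FALSE)
  }
  need <- ceiling(min_fraction * ncol(x$values))
  keep <- rowSums(x$values > 0) >= need
  if (!any(keep)) {
    warning("all RNAs removed by the low-expression filter", call. = FALSE)
  }
  expression_matrix(x$values[keep, , drop = FALSE], x$rna_types[keep],
                    x$conditions, x$pair_ids)
}

#' Binary (high/low) expression matrix
#'
#' 0/1 matrix with the same row/column identifiers as the expression matrix
#' it was derived from; 1 marks samples where the RNA is relatively highly
#' expressed.
#'
#' @param values integer or numeric matrix containing only 0 and 1, with
#'   unique rownames and colnames.
#' @return an object of class `binary_expression_matrix` (an integer matrix).
#' @export
binary_expression_matrix <- function(values) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values))) {
    stop("`values` must be a matrix with RNA rownames and sample colnames",
         call. = FALSE)
  }
  if (!all(values %in% c(0, 1))) {
    stop("binary expression entries must be 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate RNA or sample id in binary matrix", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("binary_expression_matrix", "matrix", "array"))
}

#' Equal-frequency binarization of expression
#'
#' Discretizes each RNA row at its median over the samples of `x`: values
#' strictly greater than the row median become 1 (relatively high), values
#' less than or equal to the median become 0 (relatively low). For rows with
#' all-distinct values and an even sample count this yields exactly half 1s
#' and half 0s. Constant rows binarize to all 0: a flat RNA can never form a
#' competition sample, so this is the conservative choice. The result depends
#' only on within-row rank order.
#'
#' @param x an `expression_matrix` with at least 2 samples.
#' @return a [binary_expression_matrix()].
#' @export
binarize_equal_frequency <- function(x) {
  v <- x$values
  if (ncol(v) < 2L) stop("binarization needs >= 2 samples", call. = FALSE)
  med <- apply(v, 1L, stats::median)
  b <- (v > med) * 1L
  dimnames(b) <- dimnames(v)
  binary_expression_matrix(b)
}

#' Restrict an expression matrix to one condition
#'
#' @param x an `expression_matrix`.
#' @param condition `"tumor"` or `"normal"`.
#' @return the sub-matrix over samples with that condition, order preserved.
#' @export
subset_samples <- function(x, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  keep <- x$conditions == condition
  if (!any(keep)) {
    stop("no samples with condition=", condition, call. = FALSE)
  }
  expression_matrix(x$values[, keep, drop = FALSE], x$rna_types,
                    x$conditions[keep], x$pair_ids[keep])
}
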