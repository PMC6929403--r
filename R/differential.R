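#' Type-specific differential-expression thresholds
#'
#' Ratio-scale fold-change cutoffs per RNA type plus a p-value gate. An RNA
#' is differential when `|log2FC| >= log2(fc_ratio[type])` and
#' `p <= p_max` (both comparisons inclusive). Defaults: lncRNA fold ratio 3,
#' miRNA and mRNA fold ratio 2, p_max 0.05.
#'
#' @param fc_ratio named positive numeric vector with entries `lncRNA`,
#'   `miRNA`, `mRNA`; all >= 1.
#' @param p_max p-value cutoff in (0, 1).
#' @return an object of class `de_thresholds`.
#' @export
de_thresholds <- function(fc_ratio = c(lncRNA = 3, miRNA = 2, mRNA = 2),
                          p_max = 0.05) {
  if (!all(RNA_TYPES %in% names(fc_ratio))) {
    stop("`fc_ratio` needs entries for lncRNA, miRNA and mRNA", call. = FALSE)
  }
  if (any(fc_ratio < 1)) stop("fold-ratio thresholds must be >= 1", call. = FALSE)
  if (p_max <= 0 || p_max >= 1) stop("`p_max` must be in (0, 1)", call. = FALSE)
  structure(list(fc_ratio = fc_ratio[RNA_TYPES], p_max = p_max),
            class = "de_thresholds")
}

.split_conditions <- function(x) {
  if (!all(CONDITIONS %in% x$conditions)) {
    missing <- setdiff(CONDITIONS, unique(x$conditions))
    stop("expression matrix lacks ", missing[1L], " samples", call. = FALSE)
  }
  t_idx <- which(x$conditions == "tumor")
  n_idx <- which(x$conditions == "normal")
  # align normal columns to tumor columns by patient pair
  n_idx <- n_idx[match(x$pair_ids[t_idx], x$pair_ids[n_idx])]
  list(tumor = t_idx, normal = n_idx)
}

#' Log2 fold change between tumor and normal means
#'
#' `log2((mean_tumor + pseudocount) / (mean_normal + pseudocount))`; a
#' positive value means up-regulated in tumor. The pseudocount stabilizes
#' ratios for lowly expressed RNAs.
#'
#' @param x an `expression_matrix` containing both conditions.
#' @param rna RNA identifier(s); default all RNAs.
#' @param pseudocount positive value added to both means; default 1.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(x, rna = rna_ids(x), pseudocount = 1) {
  stopifnot(pseudocount > 0)
  idx <- .split_conditions(x)
  miss <- setdiff(rna, rna_ids(x))
  if (length(miss)) stop("unknown RNA id: ", miss[1L], call. = FALSE)
  v <- x$values[rna, , drop = FALSE]
  mt <- rowMeans(v[, idx$tumor, drop = FALSE])
  mn <- rowMeans(v[, idx$normal, drop = FALSE])
  log2((mt + pseudocount) / (mn + pseudocount))
}

#' Paired t-test p-values per RNA
#'
#' Two-sided paired t-test on per-patient differences of `log2(value + 1)`
#' between tumor and normal. Degenerate cases: all differences zero gives
#' p = 1 (no evidence of change); a constant nonzero difference has zero
#' variance and is treated as the p -> 0 limit, returned as 0.
#'
#' @param x an `expression_matrix` with >= 2 complete tumor/normal pairs.
#' @param rna RNA identifier(s); default all RNAs.
#' @return named numeric vector of p-values in `[0, 1]`.
#' @export
paired_t_test <- function(x, rna = rna_ids(x)) {
  idx <- .split_conditions(x)
  if (length(idx$tumor) < 2L) {
    stop("paired t-test needs >= 2 tumor/normal pairs", call. = FALSE)
  }
  miss <- setdiff(rna, rna_ids(x))
  if (length(miss)) stop("unknown RNA id: ", miss[1L], call. = FALSE)
  v <- x$values[rna, , drop = FALSE]
  d <- log2(v[, idx$tumor, drop = FALSE] + 1) -
       log2(v[, idx$normal, drop = FALSE] + 1)
  apply(d, 1L, function(di) {
    if (all(di == 0)) return(1)
    m <- mean(di)
    # essentially-constant differences: the t statistic diverges
    if (stats::sd(di) <= 1e-10 * max(abs(di))) {
      return(if (abs(m) > 1e-10 * max(abs(di))) 0 else 1)
    }
    stats::t.test(di)$p.value
  })
}

#' Classify RNAs as up, down or unchanged
#'
#' Applies the type-specific thresholds to precomputed fold changes and
#' p-values: `up` when `log2_fc >= log2(ratio)` and `p <= p_max`, `down`
#' when `log2_fc <= -log2(ratio)` and `p <= p_max`, otherwise `unchanged`.
#'
#' @param log2_fc,p_value,rna_type equal-length vectors (named by RNA id for
#'   `log2_fc`, or supply `rna_id`).
#' @param thresholds a [de_thresholds()] object.
#' @param rna_id optional RNA identifiers; defaults to `names(log2_fc)`.
#' @return a `data.frame` with columns `rna_id`, `rna_type`, `log2_fc`,
#'   `p_value`, `status`.
#' @export
classify_differential <- function(log2_fc, p_value, rna_type,
                                  thresholds = de_thresholds(),
                                  rna_id = names(log2_fc)) {
  stopifnot(length(log2_fc) == length(p_value),
            length(log2_fc) == length(rna_type))
  bad <- setdiff(unique(rna_type), RNA_TYPES)
  if (length(bad)) stop("unknown RNA type '", bad[1L], "'", call. = FALSE)
  cut <- log2(thresholds$fc_ratio[rna_type])
  sig <- p_value <= thresholds$p_max
  status <- ifelse(sig & log2_fc >= cut, "up",
                   ifelse(sig & log2_fc <= -cut, "down", "unchanged"))
  data.frame(rna_id = rna_id, rna_type = rna_type,
             log2_fc = unname(log2_fc), p_value = unname(p_value),
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression over a paired tumor/normal matrix
#'
#' Convenience wrapper: computes [log2_fold_change()] and [paired_t_test()]
#' for every RNA and classifies with [classify_differential()].
#'
#' @inheritParams log2_fold_change
#' @param thresholds a [de_thresholds()] object.
#' @return a `data.frame` of per-RNA results (see [classify_differential()]).
#' @export
differential_expression <- function(x, thresholds = de_thresholds(),
                                    pseudocount = 1) {
  fc <- log2_fold_change(x, pseudocount = pseudocount)
  p <- paired_t_test(x)
  classify_differential(fc, p, x$rna_types, thresholds, rna_id = rna_ids(x))
}

#' Write a differential-expression results table
#'
#' @param de data.frame from [differential_expression()].
#' @param path output TSV path.
#' @return `de`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}
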