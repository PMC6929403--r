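#' End-to-end ceRNA network inference
#'
#' Runs the full pipeline: low-expression filter, differential expression,
#' candidate-network construction under the competition-regulation rule,
#' equal-frequency binarization, PMI competition scoring over the tumor
#' samples, erfc significance, selection and per-miRNA network assembly.
#'
#' @param x an [expression_matrix()], or the path to an expression TSV (then
#'   `metadata` must be the metadata TSV path).
#' @param targets a [target_map()] or the path to a target-map TSV.
#' @param metadata metadata TSV path when `x` is a path.
#' @param thresholds a [de_thresholds()] object.
#' @param pseudocount fold-change pseudocount.
#' @param min_fraction low-expression filter threshold.
#' @param binarize_scope `"tumor"` (default: the binarization median is
#'   taken over tumor samples only, the samples competition is assessed on)
#'   or `"all"` (median over the full cohort, tumor columns used for
#'   scoring).
#' @param log_base PMI log base, `"e"` or `"2"`.
#' @param grouping significance grouping, `"per_mirna"` or `"global"`.
#' @param alpha selection cutoff (strict `p < alpha`).
#' @param out_dir optional directory; when given, every intermediate table
#'   and the final networks (edge TSV, GraphML, JSON) are written there.
#' @return list of class `cerna_pipeline` with elements `de`, `networks`
#'   (candidate networks), `scored`, `tested`, `selected`, `assembled`
#'   (list of `cerna_network`) and `report` (named stage counts).
#' @export
run_pipeline <- function(x, targets, metadata = NULL,
                         thresholds = de_thresholds(), pseudocount = 1,
                         min_fraction = 0.5,
                         binarize_scope = c("tumor", "all"),
                         log_base = "e",
                         grouping = c("per_mirna", "global"),
                         alpha = 0.05, out_dir = NULL) {
  binarize_scope <- match.arg(binarize_scope)
  grouping <- match.arg(grouping)
  stopifnot(alpha >= 0, alpha <= 1)
  if (is.character(x)) {
    if (is.null(metadata)) {
      stop("`metadata` path is required when `x` is a file path",
           call. = FALSE)
    }
    x <- read_expression_table(x, metadata)
  }
  if (is.character(targets)) targets <- read_target_map(targets)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  n_input <- nrow(x$values)
  xf <- filter_low_expression(x, min_fraction)

  de <- differential_expression(xf, thresholds, pseudocount)
  nets <- candidate_networks(targets, de)

  tumor <- subset_samples(xf, "tumor")
  I <- if (binarize_scope == "tumor") {
    binarize_equal_frequency(tumor)
  } else {
    binarize_equal_frequency(xf)
  }
  tumor_samples <- sample_ids(tumor)

  scored <- lapply(names(nets), function(m) {
    tryCatch(score_network(nets[[m]], I, tumor_samples, log_base),
             error = function(e) {
               warning("network ", m, " dropped: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  })
  scored <- scored[!vapply(scored, is.null, logical(1))]
  scored <- if (length(scored)) {
    do.call(rbind, c(scored, list(make.row.names = FALSE)))
  } else {
    data.frame(lnc = character(), mirna = character(), mr = character(),
               supp = integer(), p_joint = numeric(), p_lnc = numeric(),
               p_mr = numeric(), pmi = numeric())
  }
  tested <- if (nrow(scored)) {
    significance(scored, grouping)
  } else {
    cbind(scored, theta = numeric(0), p_value = numeric(0))
  }
  selected <- select_significant(tested, alpha)
  assembled <- assemble_networks(selected)

  de_tab <- table(factor(de$rna_type, RNA_TYPES),
                  factor(de$status, c("up", "down", "unchanged")))
  report <- list(
    rnas_input = n_input,
    rnas_retained = nrow(xf$values),
    tumor_samples = length(tumor_samples),
    de_lncRNA = sum(de_tab["lncRNA", c("up", "down")]),
    de_miRNA = sum(de_tab["miRNA", c("up", "down")]),
    de_mRNA = sum(de_tab["mRNA", c("up", "down")]),
    candidate_networks = length(nets),
    candidate_crosstalks = sum(vapply(nets, function(n) {
      length(n$lncR) * length(n$mR)
    }, numeric(1))),
    positive_scores = nrow(tested),
    selected_crosstalks = nrow(selected),
    cerna_networks = length(assembled)
  )

  if (!is.null(out_dir)) {
    write_de_table(de, file.path(out_dir, "differential_expression.tsv"))
    write_candidate_table(nets, file.path(out_dir, "candidate_crosstalks.tsv"))
    write_scored_table(scored, file.path(out_dir, "scored_crosstalks.tsv"))
    write_scored_table(selected, file.path(out_dir, "selected_crosstalks.tsv"))
    for (fmt in c("edge-tsv", "graphml", "json")) {
      export_networks(assembled, file.path(out_dir, "networks"), fmt)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(de = de, networks = nets, scored = scored, tested = tested,
                 selected = selected, assembled = assembled, report = report),
            class = "cerna_pipeline")
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("cerna_pipeline run\n")
  for (k in names(x$report)) {
    cat(sprintf("  %-22s %s\n", k, x$report[[k]]))
  }
  invisible(x)
}

#' Compare selected crosstalks against planted ground truth
#'
#' Recall is the fraction of planted triples among the selected crosstalks;
#' precision the fraction of selected crosstalks that are planted.
#'
#' @param selected data.frame from [select_significant()].
#' @param truth_triples data.frame with columns `lnc`, `mirna`, `mr`.
#' @return list with `recall`, `precision`, `n_true_selected`,
#'   `n_selected`, `n_planted`.
#' @export
recovery_stats <- function(selected, truth_triples) {
  key <- function(d) paste(d$lnc, d$mirna, d$mr, sep = "\r")
  sel <- key(selected)
  tru <- key(truth_triples)
  tp <- sum(sel %in% tru)
  list(recall = tp / length(tru),
       precision = if (length(sel)) tp / length(sel) else NA_real_,
       n_true_selected = tp, n_selected = length(sel),
       n_planted = length(tru))
}
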