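#' miRNA target map
#'
#' A de-duplicated table of predicted miRNA targets, in the style of a
#' miRWalk export: one row per (miRNA, target) pair with the target's RNA
#' type (`lncRNA` or `mRNA`). An identifier must have a single consistent
#' type wherever it appears, and target identifiers may not collide with
#' miRNA identifiers.
#'
#' @param edges data.frame with columns `mirna_id`, `target_id`,
#'   `target_type`.
#' @return an object of class `target_map` (a normalized data.frame).
#' @export
target_map <- function(edges) {
  need <- c("mirna_id", "target_id", "target_type")
  if (!all(need %in% colnames(edges))) {
    stop("target map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  edges <- edges[, need]
  edges[] <- lapply(edges, as.character)
  bad <- setdiff(unique(edges$target_type), c("lncRNA", "mRNA"))
  if (length(bad)) {
    stop("unknown target_type '", bad[1L], "' (expected lncRNA or mRNA)",
         call. = FALSE)
  }
  edges <- unique(edges)
  tt <- unique(edges[, c("target_id", "target_type")])
  if (anyDuplicated(tt$target_id)) {
    dup <- tt$target_id[duplicated(tt$target_id)][1L]
    stop("target '", dup, "' appears with conflicting types", call. = FALSE)
  }
  clash <- intersect(edges$mirna_id, edges$target_id)
  if (length(clash)) {
    stop("id '", clash[1L], "' is used both as miRNA and as target",
         call. = FALSE)
  }
  edges <- edges[order(edges$mirna_id, edges$target_type, edges$target_id), ]
  rownames(edges) <- NULL
  structure(edges, class = c("target_map", "data.frame"))
}

#' @export
print.target_map <- function(x, ...) {
  cat("target_map:", nrow(x), "edges,", length(unique(x$mirna_id)),
      "miRNAs\n")
  invisible(x)
}

#' Targets of one miRNA
#'
#' @param map a [target_map()].
#' @param mirna miRNA identifier.
#' @return list with character vectors `lncRNA` and `mRNA` (sorted); both
#'   empty when the miRNA has no predicted targets.
#' @export
targets_of <- function(map, mirna) {
  sub <- map[map$mirna_id == mirna, , drop = FALSE]
  list(lncRNA = sort(sub$target_id[sub$target_type == "lncRNA"]),
       mRNA = sort(sub$target_id[sub$target_type == "mRNA"]))
}

#' Read a miRNA target map
#'
#' @param path TSV with header columns `mirna_id`, `target_id`,
#'   `target_type`.
#' @return a [target_map()].
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  target_map(df)
}

#' Write a miRNA target map
#'
#' @param map a [target_map()].
#' @param path output TSV path.
#' @return `map`, invisibly.
#' @export
write_target_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map)
}
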