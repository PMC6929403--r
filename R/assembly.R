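#' Group selected crosstalks into per-miRNA ceRNA networks
#'
#' All selected crosstalks mediated by the same miRNA form one ceRNA
#' network: a tripartite star with the miRNA as hub, its lncRNAs on one side
#' and its mRNAs on the other.
#'
#' @param selected data.frame from [select_significant()] (columns `lnc`,
#'   `mirna`, `mr`, `pmi`, `p_value`, ...).
#' @return list of `cerna_network` objects, one per miRNA with at least one
#'   selected crosstalk, named and ordered by miRNA id; empty input yields
#'   an empty list.
#' @export
assemble_networks <- function(selected) {
  if (nrow(selected) == 0L) return(list())
  nets <- lapply(sort(unique(selected$mirna)), function(m) {
    edges <- selected[selected$mirna == m, , drop = FALSE]
    edges <- edges[order(edges$lnc, edges$mr), , drop = FALSE]
    rownames(edges) <- NULL
    structure(list(mirna = m, edges = edges,
                   lncR = sort(unique(edges$lnc)),
                   mR = sort(unique(edges$mr))),
              class = "cerna_network")
  })
  names(nets) <- vapply(nets, `[[`, character(1), "mirna")
  nets
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("cerna_network:", x$mirna, "-", nrow(x$edges), "crosstalks,",
      length(x$lncR), "lncRNAs,", length(x$mR), "mRNAs\n")
  invisible(x)
}

#' Export a ceRNA network
#'
#' `edge-tsv` writes one row per crosstalk (`lnc_id`, `mirna_id`, `mr_id`,
#' `pmi`, `p_value`). `graphml` writes the tripartite graph with a
#' `rna_type` node attribute; each crosstalk contributes two graph edges,
#' lncRNA--miRNA and miRNA--mRNA, so no lnc--lnc, mr--mr or lnc--mr edge
#' ever occurs. `json` mirrors the data model (miRNA, node sets, edge
#' records).
#'
#' @param net a `cerna_network`.
#' @param path output file path.
#' @param format one of `"edge-tsv"`, `"graphml"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge-tsv", "graphml",
                                                 "json")) {
  format <- match.arg(format)
  edges <- net$edges
  if (format == "edge-tsv") {
    df <- data.frame(lnc_id = edges$lnc, mirna_id = edges$mirna,
                     mr_id = edges$mr, pmi = edges$pmi,
                     p_value = edges$p_value, stringsAsFactors = FALSE)
    utils::write.table(format(df, digits = 17, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "graphml") {
    g <- .as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    doc <- list(mirna = net$mirna, lncR = as.list(net$lncR),
                mR = as.list(net$mR),
                edges = lapply(seq_len(nrow(edges)), function(i) {
                  list(lnc = edges$lnc[i], mirna = edges$mirna[i],
                       mr = edges$mr[i], pmi = edges$pmi[i],
                       p_value = edges$p_value[i])
                }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.as_igraph <- function(net) {
  nodes <- data.frame(
    name = c(net$lncR, net$mirna, net$mR),
    rna_type = c(rep("lncRNA", length(net$lncR)), "miRNA",
                 rep("mRNA", length(net$mR))),
    stringsAsFactors = FALSE
  )
  e <- net$edges
  edge_df <- rbind(
    data.frame(from = e$lnc, to = e$mirna, pmi = e$pmi,
               p_value = e$p_value, stringsAsFactors = FALSE),
    data.frame(from = e$mirna, to = e$mr, pmi = e$pmi,
               p_value = e$p_value, stringsAsFactors = FALSE)
  )
  igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = nodes)
}

#' Import a ceRNA network written by [export_network()]
#'
#' @param path file path.
#' @param format one of `"edge-tsv"`, `"json"`.
#' @return a `cerna_network`.
#' @export
import_network <- function(path, format = c("edge-tsv", "json")) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    df <- utils::read.delim(path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    edges <- data.frame(lnc = as.character(df$lnc_id),
                        mirna = as.character(df$mirna_id),
                        mr = as.character(df$mr_id),
                        pmi = df$pmi, p_value = df$p_value,
                        stringsAsFactors = FALSE)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- as.data.frame(doc$edges, stringsAsFactors = FALSE)
  }
  if (nrow(edges) == 0L) stop("network file has no edges", call. = FALSE)
  nets <- assemble_networks(cbind(edges, selected = TRUE))
  if (length(nets) != 1L) {
    stop("file contains crosstalks of more than one miRNA", call. = FALSE)
  }
  nets[[1L]]
}

#' Export every network of a list
#'
#' Writes one file per network into a directory, named `<mirna_id>.<ext>`.
#'
#' @param nets list of `cerna_network` objects.
#' @param dir output directory (created if absent).
#' @param format passed to [export_network()].
#' @return character vector of written paths, invisibly.
#' @export
export_networks <- function(nets, dir, format = "edge-tsv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- c(`edge-tsv` = "tsv", graphml = "graphml", json = "json")[[format]]
  paths <- vapply(nets, function(n) {
    p <- file.path(dir, paste0(n$mirna, ".", ext))
    export_network(n, p, format)
    p
  }, character(1))
  invisible(paths)
}
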