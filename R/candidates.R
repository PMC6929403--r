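#' Initial ceRNA network of one differential miRNA
#'
#' Intersects the miRNA's predicted targets with the differentially
#' expressed RNAs: the initial network holds every mapped target lncRNA and
#' mRNA whose status is not `unchanged`. A miRNA absent from the target map
#' yields an empty network flagged `no_targets` rather than an error, since
#' real target databases do not cover every differential miRNA.
#'
#' @param mirna miRNA identifier with status `up` or `down`.
#' @param targets a [target_map()].
#' @param de classified differential results (see
#'   [differential_expression()]).
#' @return an object of class `initial_network`: list with `mirna`,
#'   `mirna_status`, `lncR`, `mR`, `no_targets`.
#' @export
build_initial_network <- function(mirna, targets, de) {
  row <- de[de$rna_id == mirna, , drop = FALSE]
  if (nrow(row) != 1L || row$rna_type != "miRNA") {
    stop("'", mirna, "' is not a miRNA in the differential results",
         call. = FALSE)
  }
  if (row$status == "unchanged") {
    stop("miRNA '", mirna, "' is not differentially expressed", call. = FALSE)
  }
  tg <- targets_of(targets, mirna)
  no_targets <- length(tg$lncRNA) + length(tg$mRNA) == 0L
  de_ids <- de$rna_id[de$status != "unchanged"]
  structure(
    list(mirna = mirna, mirna_status = row$status,
         lncR = intersect(tg$lncRNA, de_ids),
         mR = intersect(tg$mRNA, de_ids),
         no_targets = no_targets),
    class = "initial_network"
  )
}

#' Competition-regulation filter
#'
#' The competition rule fixes the fold-change sign pattern of a true ceRNA
#' triple: the miRNA's direction must be opposite to both the lncRNA's and
#' the mRNA's. An up-regulated miRNA keeps only down-regulated targets
#' (positive regulation mechanism); a down-regulated miRNA keeps only
#' up-regulated targets (negative mechanism). A candidate network needs at
#' least one lncRNA and one mRNA; otherwise `NULL` is returned.
#'
#' @param initial an [build_initial_network()] result.
#' @param de classified differential results.
#' @return an object of class `candidate_network` (list with `mirna`,
#'   `lncR`, `mR`, `mode`) or `NULL`.
#' @export
apply_competition_regulation <- function(initial, de) {
  mode <- if (initial$mirna_status == "up") "positive" else "negative"
  want <- if (mode == "positive") "down" else "up"
  status <- stats::setNames(de$status, de$rna_id)
  lncR <- initial$lncR[status[initial$lncR] == want]
  mR <- initial$mR[status[initial$mR] == want]
  if (length(lncR) == 0L || length(mR) == 0L) return(NULL)
  structure(list(mirna = initial$mirna, lncR = sort(lncR), mR = sort(mR),
                 mode = mode),
            class = "candidate_network")
}

#' @export
print.candidate_network <- function(x, ...) {
  cat("candidate_network:", x$mirna, sprintf("(%s mechanism)", x$mode), "-",
      length(x$lncR), "lncRNAs x", length(x$mR), "mRNAs\n")
  invisible(x)
}

#' Enumerate the candidate crosstalks of a network
#'
#' Every (lncRNA, mRNA) pair of the candidate network forms a crosstalk with
#' its miRNA; the full Cartesian product is returned in lexicographic
#' (lnc, mr) order for reproducibility.
#'
#' @param net a `candidate_network`.
#' @return data.frame with columns `lnc`, `mirna`, `mr`;
#'   `length(lncR) * length(mR)` rows.
#' @export
enumerate_crosstalks <- function(net) {
  lnc <- sort(net$lncR)
  mr <- sort(net$mR)
  data.frame(lnc = rep(lnc, each = length(mr)),
             mirna = net$mirna,
             mr = rep(mr, times = length(lnc)),
             stringsAsFactors = FALSE)
}

#' Build all candidate ceRNA networks
#'
#' Applies [build_initial_network()] and [apply_competition_regulation()] to
#' every differentially expressed miRNA in the target map order.
#'
#' @param targets a [target_map()].
#' @param de classified differential results.
#' @return named list of `candidate_network` objects (miRNAs yielding no
#'   candidates are dropped), ordered by miRNA id.
#' @export
candidate_networks <- function(targets, de) {
  mirnas <- sort(de$rna_id[de$rna_type == "miRNA" & de$status != "unchanged"])
  nets <- list()
  for (m in mirnas) {
    ini <- build_initial_network(m, targets, de)
    cand <- apply_competition_regulation(ini, de)
    if (!is.null(cand)) nets[[m]] <- cand
  }
  nets
}

#' Write candidate crosstalks of several networks
#'
#' @param nets list of `candidate_network` objects.
#' @param path output TSV path (columns `lnc_id`, `mirna_id`, `mr_id`,
#'   `mode`).
#' @return the combined data.frame, invisibly.
#' @export
write_candidate_table <- function(nets, path) {
  rows <- lapply(nets, function(n) {
    ct <- enumerate_crosstalks(n)
    data.frame(lnc_id = ct$lnc, mirna_id = ct$mirna, mr_id = ct$mr,
               mode = n$mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(lnc_id = character(), mirna_id = character(),
                      mr_id = character(), mode = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
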