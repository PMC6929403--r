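#' Competition-sample test
#'
#' A sample supports the competition between a lncRNA and an mRNA through a
#' miRNA when its binary expression pattern is one of the two competition
#' states: sponge low / miRNA high / mRNA low (`0,1,0` — the free miRNA
#' represses the mRNA) or sponge high / miRNA low / mRNA high (`1,0,1` — the
#' sponge sequesters the miRNA, de-repressing the mRNA). The two conditions
#' are mutually exclusive at any sample.
#'
#' @param I a [binary_expression_matrix()].
#' @param lnc,mirna,mr RNA identifiers (rows of `I`).
#' @param sample sample identifier(s) (columns of `I`).
#' @return logical vector, one entry per sample.
#' @export
is_competition_sample <- function(I, lnc, mirna, mr, sample) {
  ids <- c(lnc, mirna, mr)
  miss <- setdiff(ids, rownames(I))
  if (length(miss)) stop("unknown RNA id: ", miss[1L], call. = FALSE)
  miss <- setdiff(sample, colnames(I))
  if (length(miss)) stop("unknown sample id: ", miss[1L], call. = FALSE)
  l <- I[lnc, sample]
  m <- I[mirna, sample]
  r <- I[mr, sample]
  (l == 0 & m == 1 & r == 0) | (l == 1 & m == 0 & r == 1)
}

#' Support of a crosstalk over a sample set
#'
#' Number of competition samples (see [is_competition_sample()]) of the
#' triple over the given samples.
#'
#' @inheritParams is_competition_sample
#' @param samples non-empty subset of the columns of `I`.
#' @return integer count in `[0, length(samples)]`.
#' @export
support_count <- function(I, lnc, mirna, mr, samples) {
  if (length(samples) == 0L) stop("empty sample set", call. = FALSE)
  sum(is_competition_sample(I, lnc, mirna, mr, samples))
}

#' Support table of a candidate network
#'
#' Competition-sample counts for every (lncRNA, mRNA) pair of the network,
#' computed jointly: for samples where the miRNA is high, a pair competes
#' when both members are low; where the miRNA is low, when both are high.
#'
#' @param net a `candidate_network`.
#' @param I a [binary_expression_matrix()] containing all network members.
#' @param samples sample identifiers over which support is counted
#'   (typically the tumor samples); default all columns of `I`.
#' @return integer matrix, rows = lncRNAs, columns = mRNAs.
#' @export
support_table <- function(net, I, samples = colnames(I)) {
  if (length(samples) == 0L) stop("empty sample set", call. = FALSE)
  ids <- c(net$lncR, net$mirna, net$mR)
  miss <- setdiff(ids, rownames(I))
  if (length(miss)) stop("unknown RNA id: ", miss[1L], call. = FALSE)
  miss <- setdiff(samples, colnames(I))
  if (length(miss)) stop("unknown sample id: ", miss[1L], call. = FALSE)
  L <- I[net$lncR, samples, drop = FALSE]
  m <- I[net$mirna, samples]
  R <- I[net$mR, samples, drop = FALSE]
  hi <- m == 1
  supp <- (1L - L[, hi, drop = FALSE]) %*% t(1L - R[, hi, drop = FALSE]) +
    L[, !hi, drop = FALSE] %*% t(R[, !hi, drop = FALSE])
  storage.mode(supp) <- "integer"
  dimnames(supp) <- list(net$lncR, net$mR)
  supp
}

#' Competition-sample probabilities of a network
#'
#' Normalizes the support table into a joint distribution over (lncRNA,
#' mRNA) pairs; the marginals are its row and column sums. All three share
#' the network-wide total support as denominator.
#'
#' @param supports integer matrix from [support_table()] with a positive
#'   total.
#' @return list with `p_joint` (matrix), `p_lnc` (row marginals) and `p_mr`
#'   (column marginals).
#' @export
network_probabilities <- function(supports) {
  tot <- sum(supports)
  if (tot == 0) stop("network has no competition samples", call. = FALSE)
  p_joint <- supports / tot
  list(p_joint = p_joint,
       p_lnc = rowSums(p_joint),
       p_mr = colSums(p_joint))
}

#' Pointwise mutual information
#'
#' `log(p_joint / (p_lnc * p_mr))`. Positive values mean the pair occurs in
#' competition samples more often than expected under independence; negative
#' values, less often. A zero joint probability leaves the score undefined
#' (`NA`); such crosstalks are discarded before significance testing.
#'
#' @param p_joint,p_lnc,p_mr probabilities (vectorized); `p_lnc` and `p_mr`
#'   must be positive.
#' @param log_base `"e"` (natural log, default) or `"2"`.
#' @return numeric vector of scores, `NA` where `p_joint == 0`.
#' @export
pmi <- function(p_joint, p_lnc, p_mr, log_base = c("e", "2")) {
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  if (any(p_lnc <= 0) || any(p_mr <= 0)) {
    stop("marginal probabilities must be positive", call. = FALSE)
  }
  out <- ifelse(p_joint == 0, NA_real_, log(p_joint / (p_lnc * p_mr)))
  if (log_base == "2") out <- out / log(2)
  out
}

#' Score every crosstalk of a candidate network
#'
#' Computes supports, network probabilities and the PMI competition score
#' for the full (lncRNA, mRNA) grid of the network over the given samples.
#'
#' @inheritParams support_table
#' @param log_base passed to [pmi()].
#' @return data.frame with one row per crosstalk (lexicographic (lnc, mr)
#'   order): `lnc`, `mirna`, `mr`, `supp`, `p_joint`, `p_lnc`, `p_mr`,
#'   `pmi` (`NA` when the crosstalk has no competition samples).
#' @export
score_network <- function(net, I, samples = colnames(I), log_base = "e") {
  supp <- support_table(net, I, samples)
  pr <- network_probabilities(supp)
  ct <- enumerate_crosstalks(net)
  i <- match(ct$lnc, rownames(supp))
  j <- match(ct$mr, colnames(supp))
  k <- cbind(i, j)
  ct$supp <- supp[k]
  ct$p_joint <- pr$p_joint[k]
  ct$p_lnc <- pr$p_lnc[i]
  ct$p_mr <- pr$p_mr[j]
  # a zero joint leaves the score undefined; its marginals may themselves be
  # zero (an RNA with no competition sample at all), so pmi() is only
  # evaluated on the defined entries
  ct$pmi <- NA_real_
  ok <- ct$p_joint > 0
  ct$pmi[ok] <- pmi(ct$p_joint[ok], ct$p_lnc[ok], ct$p_mr[ok], log_base)
  ct
}

#' Complementary error function
#'
#' `erfc(x) = 2 * pnorm(-x * sqrt(2))`; used to convert a competition-score
#' z-score into a significance level.
#'
#' @param x numeric vector.
#' @return `erfc(x)`.
#' @export
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Significance of competition scores
#'
#' Crosstalks with undefined, zero or negative scores are discarded: they
#' carry no evidence of competition. For each retained crosstalk the score
#' is standardized against the mean and standard deviation of the positive
#' scores in its group — by default the scores of the same miRNA's network —
#' and converted to a significance level `p = erfc(theta / sqrt(2))`,
#' clamped to `[0, 1]` (the formula exceeds 1 for below-mean scores, whose
#' exact value is irrelevant to selection). Degenerate groups: a single
#' positive score or identical scores have zero spread, every p is set to 1
#' and a warning is emitted; a group with no positive scores is dropped with
#' a warning.
#'
#' @param scored data.frame from [score_network()] (possibly several
#'   networks row-bound together).
#' @param grouping `"per_mirna"` (default: standardize within each miRNA's
#'   network) or `"global"` (over all scores jointly).
#' @return the retained rows with added columns `theta` and `p_value`.
#' @export
significance <- function(scored, grouping = c("per_mirna", "global")) {
  grouping <- match.arg(grouping)
  keep <- !is.na(scored$pmi) & scored$pmi > 0
  out <- scored[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no positive competition scores; nothing to test", call. = FALSE)
    out$theta <- numeric(0)
    out$p_value <- numeric(0)
    return(out)
  }
  grp <- if (grouping == "per_mirna") out$mirna else rep("all", nrow(out))
  out$theta <- NA_real_
  out$p_value <- NA_real_
  for (g in unique(grp)) {
    sel <- grp == g
    s <- out$pmi[sel]
    sg <- if (length(s) > 1L) stats::sd(s) else 0
    if (sg == 0) {
      warning("group '", g, "': zero spread among positive scores; ",
              "all p-values set to 1", call. = FALSE)
      out$theta[sel] <- 0
      out$p_value[sel] <- 1
    } else {
      th <- (s - mean(s)) / sg
      out$theta[sel] <- th
      out$p_value[sel] <- pmin(pmax(erfc(th / sqrt(2)), 0), 1)
    }
  }
  rownames(out) <- NULL
  out
}

#' Select significantly competing crosstalks
#'
#' Keeps crosstalks with `p_value` strictly below `alpha`, sorted by
#' descending score.
#'
#' @param scored data.frame from [significance()].
#' @param alpha significance cutoff in `[0, 1]`; default 0.05.
#' @return the selected rows, sorted by decreasing `pmi`, with a `selected`
#'   flag column set to `TRUE`.
#' @export
select_significant <- function(scored, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  out <- scored[!is.na(scored$p_value) & scored$p_value < alpha, ,
                drop = FALSE]
  out <- out[order(-out$pmi, out$mirna, out$lnc, out$mr), , drop = FALSE]
  out$selected <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a scored-crosstalk table
#'
#' @param scored data.frame with crosstalk scores (any stage).
#' @param path output TSV path.
#' @return `scored`, invisibly.
#' @export
write_scored_table <- function(scored, path) {
  df <- scored
  names(df)[names(df) == "lnc"] <- "lnc_id"
  names(df)[names(df) == "mirna"] <- "mirna_id"
  names(df)[names(df) == "mr"] <- "mr_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(scored)
}
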