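# Shared fixture builders and independent brute-force oracles.

# Small paired expression matrix; values filled column-major unless given.
make_expr <- function(n_rna = 3, n_pairs = 2,
                      rna_type = rep_len(c("lncRNA", "miRNA", "mRNA"), n_rna),
                      values = NULL) {
  rna <- sprintf("rna%02d", seq_len(n_rna))
  patient <- sprintf("pt%02d", seq_len(n_pairs))
  samples <- c(paste0(patient, "_T"), paste0(patient, "_N"))
  if (is.null(values)) {
    values <- matrix(seq_len(n_rna * 2 * n_pairs), nrow = n_rna)
  }
  dimnames(values) <- list(rna, samples)
  expression_matrix(values, rna_type,
                    rep(c("tumor", "normal"), each = n_pairs),
                    c(patient, patient))
}

random_expr <- function(n_rna = 10, n_pairs = 4, zero_prob = 0.2) {
  v <- matrix(round(runif(n_rna * 2 * n_pairs, 0, 1000), 3),
              nrow = n_rna)
  v[runif(length(v)) < zero_prob] <- 0
  make_expr(n_rna, n_pairs, values = v)
}

# Random binary matrix holding a 1-miRNA network with n_l lncRNAs, n_m mRNAs.
random_binary_instance <- function(n_l, n_m, n_s, p = 0.5) {
  ids <- c(sprintf("l%d", seq_len(n_l)), "mir", sprintf("m%d", seq_len(n_m)))
  samples <- sprintf("s%d", seq_len(n_s))
  b <- matrix(rbinom((n_l + n_m + 1) * n_s, 1, p), ncol = n_s,
              dimnames = list(ids, samples))
  I <- binary_expression_matrix(b)
  net <- structure(list(mirna = "mir", lncR = sprintf("l%d", seq_len(n_l)),
                        mR = sprintf("m%d", seq_len(n_m)), mode = "negative"),
                   class = "candidate_network")
  list(I = I, net = net)
}

# Brute-force support: explicit per-sample loop over the two conditions.
brute_support <- function(I, lnc, mirna, mr, samples) {
  n <- 0L
  for (s in samples) {
    l <- I[lnc, s]; m <- I[mirna, s]; r <- I[mr, s]
    if ((l == 0 && m == 1 && r == 0) || (l == 1 && m == 0 && r == 1)) {
      n <- n + 1L
    }
  }
  n
}

# Brute-force scoring of a network: per-pair double loop over the equations.
brute_score <- function(net, I, samples) {
  n <- length(net$lncR); m <- length(net$mR)
  supp <- matrix(0L, n, m, dimnames = list(net$lncR, net$mR))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    supp[i, j] <- brute_support(I, net$lncR[i], net$mirna, net$mR[j], samples)
  }
  tot <- sum(supp)
  if (tot == 0) return(NULL)
  res <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pj <- supp[i, j] / tot
    pl <- sum(supp[i, ]) / tot
    pr <- sum(supp[, j]) / tot
    res <- rbind(res, data.frame(
      lnc = net$lncR[i], mr = net$mR[j], supp = supp[i, j],
      p_joint = pj, p_lnc = pl, p_mr = pr,
      pmi = if (pj == 0) NA_real_ else log(pj / (pl * pr)),
      stringsAsFactors = FALSE))
  }
  res[order(res$lnc, res$mr), ]
}

# DE table constructed directly (for network-construction tests).
make_de <- function(ids, types, statuses) {
  data.frame(rna_id = ids, rna_type = types,
             log2_fc = ifelse(statuses == "up", 2,
                              ifelse(statuses == "down", -2, 0)),
             p_value = ifelse(statuses == "unchanged", 0.5, 0.001),
             status = statuses, stringsAsFactors = FALSE)
}
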