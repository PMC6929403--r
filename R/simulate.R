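#' Configuration of the synthetic paired tumor/normal generator
#'
#' Describes a cohort of `n_pairs` patients with one tumor and one normal
#' sample each, `n_planted` true ceRNA triples and independent decoy RNAs.
#' Planted lncRNAs and mRNAs are up-regulated in tumor (mean ratios
#' `fold_lnc`, `fold_mr`) and their miRNAs down-regulated (`fold_mirna`),
#' the negative competition-regulation pattern. Several planted pairs share
#' each miRNA (`pairs_per_mirna`); within the tumor samples each pair is
#' competition-engaged in its own block of samples (see
#' [simulate_dataset()]). `flip_prob` independently flips each RNA's latent
#' high/low state per sample before counts are drawn; `dispersion` is the
#' negative-binomial overdispersion (variance `mu + dispersion * mu^2`).
#'
#' @param n_pairs number of patients (tumor/normal sample pairs).
#' @param n_planted number of true ceRNA triples.
#' @param n_decoy_lnc,n_decoy_mr,n_decoy_mirna decoy RNA counts.
#' @param fold_lnc,fold_mr,fold_mirna tumor/normal mean ratios of planted
#'   RNAs; defaults 4, 3 and 1/3 clear the differential-expression gates
#'   (lncRNA ratio 3, mRNA 2, miRNA 1/2) in expectation.
#' @param flip_prob per-RNA per-sample state-flip probability in `[0, 0.5)`.
#' @param dispersion negative-binomial overdispersion (> 0).
#' @param baseline_mean mean expression of a normal sample (> 0).
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the seed.
#' @param pairs_per_mirna planted ceRNA pairs sharing one miRNA (>= 1).
#' @param decoy_de_fraction fraction of decoy lncRNAs/mRNAs that are
#'   differentially expressed (tumor-up at the planted folds) yet
#'   uncorrelated with any competition state.
#' @param decoy_target_rate probability that a given miRNA targets a given
#'   decoy RNA.
#' @param regime_separation in `(0.5, 1)`: the high and low expression
#'   regimes of a state-carrying RNA have means `2 * s * mu` and
#'   `2 * (1 - s) * mu`, so their average stays `mu`.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 50, n_planted = 20,
                             n_decoy_lnc = 100, n_decoy_mr = 100,
                             n_decoy_mirna = 10,
                             fold_lnc = 4, fold_mr = 3, fold_mirna = 1 / 3,
                             flip_prob = 0.1, dispersion = 0.02,
                             baseline_mean = 500, seed = 1,
                             pairs_per_mirna = 4, decoy_de_fraction = 0.5,
                             decoy_target_rate = 0.2,
                             regime_separation = 0.8) {
  cfg <- list(n_pairs = n_pairs, n_planted = n_planted,
              n_decoy_lnc = n_decoy_lnc, n_decoy_mr = n_decoy_mr,
              n_decoy_mirna = n_decoy_mirna, fold_lnc = fold_lnc,
              fold_mr = fold_mr, fold_mirna = fold_mirna,
              flip_prob = flip_prob, dispersion = dispersion,
              baseline_mean = baseline_mean, seed = seed,
              pairs_per_mirna = pairs_per_mirna,
              decoy_de_fraction = decoy_de_fraction,
              decoy_target_rate = decoy_target_rate,
              regime_separation = regime_separation)
  with(cfg, {
    stopifnot(n_pairs >= 2, n_planted >= 1, n_decoy_lnc >= 0,
              n_decoy_mr >= 0, n_decoy_mirna >= 0,
              fold_lnc > 0, fold_mr > 0, fold_mirna > 0,
              flip_prob >= 0, flip_prob < 0.5, dispersion > 0,
              baseline_mean > 0, pairs_per_mirna >= 1,
              decoy_de_fraction >= 0, decoy_de_fraction <= 1,
              decoy_target_rate >= 0, decoy_target_rate <= 1,
              regime_separation > 0.5, regime_separation < 1)
  })
  structure(cfg, class = "synthetic_config")
}

.rnb <- function(n, mu, dispersion) {
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

.regime_draw <- function(state, mu, cfg) {
  # state 1 -> high regime, 0 -> low regime; regimes average back to mu
  s <- cfg$regime_separation
  .rnb(length(state), ifelse(state == 1, 2 * s * mu, 2 * (1 - s) * mu),
       cfg$dispersion)
}

#' Simulate a paired tumor/normal expression data set with planted ceRNA
#' triples
#'
#' Planted triples obey the negative competition-regulation pattern between
#' conditions (lncRNA and mRNA up in tumor, miRNA down). Within the tumor
#' samples, each planted miRNA is shared by `pairs_per_mirna` (lncRNA, mRNA)
#' pairs and the tumor samples are partitioned round-robin into one
#' engagement block per pair. At a sample of block `k`, a latent sponge
#' state `c ~ Bernoulli(0.5)` is drawn: the miRNA's latent state is `1 - c`,
#' the engaged pair's lncRNA and mRNA take state `c` (so the triple is in a
#' competition state: either the sponge is high and the miRNA sequestered,
#' or the sponge low and the miRNA free), and the other pairs of the group
#' track the miRNA's state (disengaged: their sponge program is inactive
#' there, so they are deliberately not in a competition state). This
#' sample-specific engagement is what makes true pairs distinguishable by
#' pointwise mutual information: a pair engaged everywhere would make the
#' network's support table factorize and all scores vanish. Each RNA's
#' state is then flipped independently with `flip_prob` and counts drawn
#' from the negative-binomial regime mean. Decoy RNAs are independent of
#' every latent state; a `decoy_de_fraction` of decoy lncRNAs/mRNAs is
#' tumor-up at the planted folds (differential but non-competing), the rest
#' (and all decoy miRNAs) are flat. The target map links each planted miRNA
#' to its group's lncRNAs and mRNAs plus random decoy targets.
#'
#' @param config a [synthetic_config()].
#' @return list with `expression` (an [expression_matrix()]), `targets`
#'   (a [target_map()]) and `truth` (list with `triples` — data.frame
#'   `lnc`, `mirna`, `mr` — and `directions` — data.frame `rna_id`,
#'   `rna_type`, `direction`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_mirna <- ceiling(cfg$n_planted / cfg$pairs_per_mirna)
  group_of_pair <- rep(seq_len(n_mirna),
                       each = cfg$pairs_per_mirna)[seq_len(cfg$n_planted)]

  patient <- sprintf("patient%03d", seq_len(cfg$n_pairs))
  tumor_ids <- paste0(patient, "_T")
  normal_ids <- paste0(patient, "_N")
  sample_id <- c(tumor_ids, normal_ids)
  condition <- rep(c("tumor", "normal"), each = cfg$n_pairs)
  pair_id <- c(patient, patient)

  lnc_p <- sprintf("lnc_p%03d", seq_len(cfg$n_planted))
  mr_p <- sprintf("mr_p%03d", seq_len(cfg$n_planted))
  mir_p <- sprintf("mir_p%02d", seq_len(n_mirna))
  lnc_d <- if (cfg$n_decoy_lnc) sprintf("lnc_d%03d", seq_len(cfg$n_decoy_lnc)) else character()
  mr_d <- if (cfg$n_decoy_mr) sprintf("mr_d%03d", seq_len(cfg$n_decoy_mr)) else character()
  mir_d <- if (cfg$n_decoy_mirna) sprintf("mir_d%03d", seq_len(cfg$n_decoy_mirna)) else character()

  all_ids <- c(lnc_p, mir_p, mr_p, lnc_d, mr_d, mir_d)
  all_types <- c(rep("lncRNA", length(lnc_p)), rep("miRNA", length(mir_p)),
                 rep("mRNA", length(mr_p)), rep("lncRNA", length(lnc_d)),
                 rep("mRNA", length(mr_d)), rep("miRNA", length(mir_d)))
  vals <- matrix(0, nrow = length(all_ids), ncol = length(sample_id),
                 dimnames = list(all_ids, sample_id))

  n_de_dlnc <- round(cfg$decoy_de_fraction * cfg$n_decoy_lnc)
  n_de_dmr <- round(cfg$decoy_de_fraction * cfg$n_decoy_mr)
  direction <- stats::setNames(rep("flat", length(all_ids)), all_ids)
  direction[c(lnc_p, mr_p)] <- "up"
  direction[mir_p] <- "down"
  if (n_de_dlnc) direction[lnc_d[seq_len(n_de_dlnc)]] <- "up"
  if (n_de_dmr) direction[mr_d[seq_len(n_de_dmr)]] <- "up"

  tumor_mu <- stats::setNames(rep(cfg$baseline_mean, length(all_ids)), all_ids)
  tumor_mu[lnc_p] <- cfg$baseline_mean * cfg$fold_lnc
  tumor_mu[mr_p] <- cfg$baseline_mean * cfg$fold_mr
  tumor_mu[mir_p] <- cfg$baseline_mean * cfg$fold_mirna
  tumor_mu[names(direction)[direction == "up" & names(direction) %in% lnc_d]] <-
    cfg$baseline_mean * cfg$fold_lnc
  tumor_mu[names(direction)[direction == "up" & names(direction) %in% mr_d]] <-
    cfg$baseline_mean * cfg$fold_mr

  # normal samples: everything at baseline, no latent structure
  vals[, normal_ids] <- .rnb(length(all_ids) * cfg$n_pairs,
                             cfg$baseline_mean, cfg$dispersion)

  # tumor samples: planted groups carry block-structured latent states
  flip <- function(state) {
    f <- stats::rbinom(length(state), 1L, cfg$flip_prob)
    ifelse(f == 1L, 1L - state, state)
  }
  block_of <- matrix(NA_integer_, nrow = cfg$n_planted, ncol = cfg$n_pairs,
                     dimnames = list(NULL, tumor_ids))
  for (g in seq_len(n_mirna)) {
    pairs_g <- which(group_of_pair == g)
    blocks <- rep(seq_along(pairs_g), length.out = cfg$n_pairs)
    # balanced sponge states within every engagement block: the median
    # binarization assigns exactly half the samples to each side, so any
    # latent imbalance (overall or per block, since each pair's state is a
    # block-wise mixture of c and 1-c) would turn into misclassification
    c_state <- integer(cfg$n_pairs)
    for (k in seq_along(pairs_g)) {
      idx <- which(blocks == k)
      c_state[idx] <- sample(rep_len(c(0L, 1L), length(idx)))
    }
    mir_latent <- 1L - c_state
    vals[mir_p[g], tumor_ids] <-
      .regime_draw(flip(mir_latent), tumor_mu[mir_p[g]], cfg)
    for (k in seq_along(pairs_g)) {
      p <- pairs_g[k]
      latent <- ifelse(blocks == k, c_state, mir_latent)
      block_of[p, ] <- as.integer(blocks == k)
      vals[lnc_p[p], tumor_ids] <-
        .regime_draw(flip(latent), tumor_mu[lnc_p[p]], cfg)
      vals[mr_p[p], tumor_ids] <-
        .regime_draw(flip(latent), tumor_mu[mr_p[p]], cfg)
    }
  }

  # decoys (and DE decoys): no latent state, just their tumor mean
  others <- c(lnc_d, mr_d, mir_d)
  if (length(others)) {
    vals[others, tumor_ids] <- .rnb(length(others) * cfg$n_pairs,
                                    rep(tumor_mu[others], cfg$n_pairs),
                                    cfg$dispersion)
  }

  x <- expression_matrix(vals, all_types, condition, pair_id)

  # target map: planted group members + random decoy targets
  edges <- list()
  for (g in seq_len(n_mirna)) {
    pairs_g <- which(group_of_pair == g)
    edges[[length(edges) + 1L]] <- data.frame(
      mirna_id = mir_p[g],
      target_id = c(lnc_p[pairs_g], mr_p[pairs_g]),
      target_type = rep(c("lncRNA", "mRNA"), each = length(pairs_g)),
      stringsAsFactors = FALSE)
  }
  decoy_targets <- function(mirna) {
    hit_l <- lnc_d[stats::runif(length(lnc_d)) < cfg$decoy_target_rate]
    hit_m <- mr_d[stats::runif(length(mr_d)) < cfg$decoy_target_rate]
    if (length(hit_l) + length(hit_m) == 0L) return(NULL)
    data.frame(mirna_id = mirna, target_id = c(hit_l, hit_m),
               target_type = c(rep("lncRNA", length(hit_l)),
                               rep("mRNA", length(hit_m))),
               stringsAsFactors = FALSE)
  }
  for (m in c(mir_p, mir_d)) {
    e <- decoy_targets(m)
    if (!is.null(e)) edges[[length(edges) + 1L]] <- e
  }
  targets <- target_map(do.call(rbind, edges))

  truth <- list(
    triples = data.frame(lnc = lnc_p, mirna = mir_p[group_of_pair],
                         mr = mr_p, stringsAsFactors = FALSE),
    directions = data.frame(rna_id = all_ids, rna_type = all_types,
                            direction = unname(direction[all_ids]),
                            stringsAsFactors = FALSE),
    engagement_blocks = block_of
  )
  list(expression = x, targets = targets, truth = truth)
}

#' Write a simulated data set to TSV files
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if absent); files
#'   `expression.tsv`, `metadata.tsv`, `targets.tsv`, `truth.tsv`.
#' @return the directory, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_table(sim$expression, file.path(dir, "expression.tsv"),
                         file.path(dir, "metadata.tsv"))
  write_target_map(sim$targets, file.path(dir, "targets.tsv"))
  utils::write.table(sim$truth$triples, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
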