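test_that("competition samples are exactly the two opposite patterns", {
  b <- matrix(c(0, 1, 1, 0,    # lnc
                1, 0, 1, 0,    # mir
                0, 1, 1, 0),   # mr
              nrow = 3, byrow = TRUE,
              dimnames = list(c("lnc", "mir", "mr"), paste0("s", 1:4)))
  I <- binary_expression_matrix(b)
  got <- is_competition_sample(I, "lnc", "mir", "mr", paste0("s", 1:4))
  # s1 = (0,1,0) true; s2 = (1,0,1) true; s3 = (1,1,1) false; s4 = (0,0,0) false
  expect_equal(unname(got), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(is_competition_sample(I, "nope", "mir", "mr", "s1"),
               "unknown RNA")
  expect_error(is_competition_sample(I, "lnc", "mir", "mr", "s9"),
               "unknown sample")
})

test_that("support counting agrees with the brute-force loop", {
  expect_error(
    support_count(binary_expression_matrix(
      matrix(0L, 1, 2, dimnames = list("a", c("s1", "s2")))),
      "a", "a", "a", character(0)),
    "empty sample set")

  set.seed(17)
  for (rep in 1:25) {
    inst <- random_binary_instance(n_l = sample(1:3, 1), n_m = sample(1:3, 1),
                                   n_s = 8, p = runif(1, 0.2, 0.8))
    I <- inst$I; net <- inst$net
    samples <- colnames(I)
    st <- support_table(net, I, samples)
    for (l in net$lncR) for (m in net$mR) {
      expect_identical(st[l, m], brute_support(I, l, "mir", m, samples))
      expect_identical(support_count(I, l, "mir", m, samples), st[l, m])
    }
    # the two conditions are mutually exclusive: supp = cond1 + cond2 counts
    for (l in net$lncR) for (m in net$mR) {
      c1 <- sum(I[l, ] == 0 & I["mir", ] == 1 & I[m, ] == 0)
      c2 <- sum(I[l, ] == 1 & I["mir", ] == 0 & I[m, ] == 1)
      expect_identical(st[l, m], as.integer(c1 + c2))
    }
  }
})

test_that("network probabilities normalize and marginalize correctly", {
  # hand-evaluated 2x2 diagonal support
  supp <- matrix(c(4L, 0L, 0L, 4L), 2, 2,
                 dimnames = list(c("l1", "l2"), c("m1", "m2")))
  pr <- network_probabilities(supp)
  expect_equal(pr$p_joint[1, 1], 0.5)
  expect_equal(unname(pr$p_lnc), c(0.5, 0.5))
  expect_equal(unname(pr$p_mr), c(0.5, 0.5))

  # single pair: everything normalizes to 1
  pr1 <- network_probabilities(matrix(4L, 1, 1, dimnames = list("l", "m")))
  expect_equal(pr1$p_joint[1, 1], 1)

  expect_error(network_probabilities(matrix(0L, 2, 2)),
               "no competition samples")

  # random supports: marginal-consistency sums hold
  set.seed(23)
  for (rep in 1:20) {
    supp <- matrix(rpois(12, 3), 3, 4)
    if (sum(supp) == 0) supp[1, 1] <- 1L
    pr <- network_probabilities(supp)
    expect_equal(sum(pr$p_joint), 1, tolerance = 1e-12)
    expect_equal(pr$p_lnc, rowSums(pr$p_joint), tolerance = 1e-12)
    expect_equal(pr$p_mr, colSums(pr$p_joint), tolerance = 1e-12)
  }
})

test_that("pmi matches closed forms, flags undefined, supports base 2", {
  expect_equal(pmi(0.25, 0.5, 0.5), 0)          # independence
  expect_equal(pmi(0.5, 0.5, 0.5), log(2))      # 2x2 diagonal case
  expect_equal(pmi(1, 1, 1), 0)                 # single-pair network
  expect_true(is.na(pmi(0, 0.5, 0.5)))          # undefined
  expect_equal(pmi(0.5, 0.5, 0.5, log_base = "2"), 1)
  expect_true(pmi(0.1, 0.5, 0.5) < 0)           # under-representation
  expect_error(pmi(0.5, 0, 0.5), "positive")
})

test_that("score_network reproduces the 2x2 diagonal fixture end to end", {
  # mir high in s1-s4, low in s5-s8; pair 1 competes only under Condition 1,
  # pair 2 only under Condition 2, never crossing
  b <- rbind(
    l1 = c(0, 0, 0, 0, 0, 0, 0, 0),
    l2 = c(1, 1, 1, 1, 1, 1, 1, 1),
    mir = c(1, 1, 1, 1, 0, 0, 0, 0),
    m1 = c(0, 0, 0, 0, 0, 0, 0, 0),
    m2 = c(1, 1, 1, 1, 1, 1, 1, 1))
  colnames(b) <- paste0("s", 1:8)
  I <- binary_expression_matrix(b)
  net <- structure(list(mirna = "mir", lncR = c("l1", "l2"),
                        mR = c("m1", "m2"), mode = "negative"),
                   class = "candidate_network")
  sc <- score_network(net, I)
  expect_equal(sc$supp, c(4L, 0L, 0L, 4L))
  expect_equal(sc$pmi, c(log(2), NA, NA, log(2)))

  # single-pair network scores exactly zero
  net1 <- structure(list(mirna = "mir", lncR = "l1", mR = "m1",
                         mode = "negative"), class = "candidate_network")
  expect_equal(score_network(net1, I)$pmi, 0)
})

test_that("significance standardizes positive scores within groups", {
  scored <- data.frame(
    lnc = paste0("l", 1:6), mirna = "mir1", mr = paste0("m", 1:6),
    supp = 5L, p_joint = 0.1, p_lnc = 0.3, p_mr = 0.3,
    pmi = c(0.9, 0.5, 0.3, 0.1, -0.2, NA))
  out <- significance(scored)
  expect_equal(nrow(out), 4L)  # negative and undefined discarded
  s <- c(0.9, 0.5, 0.3, 0.1)
  expect_equal(out$theta, (s - mean(s)) / sd(s))
  expect_equal(out$p_value, pmin(erfc(out$theta / sqrt(2)), 1))
  # p ordering is the exact reverse of pmi ordering
  expect_equal(order(out$p_value), order(-out$pmi))

  # per-miRNA vs global grouping
  scored2 <- scored
  scored2$mirna <- c("a", "a", "b", "b", "b", "b")
  out2 <- significance(scored2, grouping = "per_mirna")
  # group "a" holds scores 0.9 and 0.5: standardized to +/- sqrt(2)/2
  expect_equal(out2$theta[out2$mirna == "a"], c(1, -1) * sqrt(2) / 2)

  # zero spread -> all p = 1 with a warning
  same <- scored[1:3, ]
  same$pmi <- 0.4
  expect_warning(out3 <- significance(same), "zero spread")
  expect_true(all(out3$p_value == 1))

  # no positive scores -> empty result with warning
  neg <- scored[5, ]
  expect_warning(out4 <- significance(neg), "no positive")
  expect_equal(nrow(out4), 0L)
})

test_that("erfc agrees with an independent implementation", {
  x <- seq(-3, 3, by = 0.25)
  expect_equal(erfc(x), pracma::erfc(x), tolerance = 1e-12)
})

test_that("selection is strict at alpha and monotone", {
  scored <- data.frame(
    lnc = paste0("l", 1:3), mirna = "mir1", mr = paste0("m", 1:3),
    pmi = c(0.9, 0.5, 0.3), p_value = c(0.049, 0.05, 0.2))
  sel <- select_significant(scored, 0.05)
  expect_equal(sel$lnc, "l1")   # p = 0.05 excluded (strict)
  expect_true(all(sel$selected))
  expect_equal(nrow(select_significant(scored, 0)), 0L)

  # lowering alpha never enlarges the selection
  set.seed(29)
  for (rep in 1:10) {
    rs <- data.frame(lnc = paste0("l", 1:20), mirna = "m", mr = "x",
                     pmi = runif(20), p_value = runif(20))
    alphas <- sort(runif(5))
    sizes <- vapply(alphas,
                    function(a) nrow(select_significant(rs, a)), numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }

  # sorted by descending pmi
  many <- data.frame(lnc = paste0("l", 1:4), mirna = "m", mr = "x",
                     pmi = c(0.2, 0.8, 0.5, 0.9), p_value = 0.01)
  expect_equal(select_significant(many)$pmi, c(0.9, 0.8, 0.5, 0.2))
})
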