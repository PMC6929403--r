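test_that("target map de-duplicates and validates types", {
  df <- data.frame(
    mirna_id = c("mir1", "mir1", "mir1"),
    target_id = c("lncA", "lncA", "geneB"),
    target_type = c("lncRNA", "lncRNA", "mRNA"))
  tm <- target_map(df)
  expect_equal(nrow(tm), 2L)

  df$target_type[3] <- "gene"
  expect_error(target_map(df), "unknown target_type 'gene'")

  # conflicting type for one id
  expect_error(target_map(data.frame(
    mirna_id = c("mir1", "mir2"), target_id = c("A", "A"),
    target_type = c("lncRNA", "mRNA"))), "conflicting types")

  # round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_target_map(tm, path)
  expect_identical(as.data.frame(read_target_map(path)), as.data.frame(tm))
})

test_that("initial network intersects mapped targets with DE RNAs", {
  tm <- target_map(data.frame(
    mirna_id = "mir1",
    target_id = c("lncA", "lncB", "mrA", "mrB", "mrC"),
    target_type = c("lncRNA", "lncRNA", rep("mRNA", 3))))
  de <- make_de(c("mir1", "lncA", "lncB", "mrA", "mrB", "mrC"),
                c("miRNA", "lncRNA", "lncRNA", "mRNA", "mRNA", "mRNA"),
                c("up", "down", "down", "down", "down", "down"))
  ini <- build_initial_network("mir1", tm, de)
  expect_equal(length(ini$lncR), 2L)
  expect_equal(length(ini$mR), 3L)
  expect_false(ini$no_targets)

  # all targets unchanged -> empty network
  de2 <- make_de(c("mir1", "lncA", "lncB", "mrA", "mrB", "mrC"),
                 c("miRNA", "lncRNA", "lncRNA", "mRNA", "mRNA", "mRNA"),
                 c("up", rep("unchanged", 5)))
  ini2 <- build_initial_network("mir1", tm, de2)
  expect_equal(length(ini2$lncR) + length(ini2$mR), 0L)

  # miRNA absent from the map -> flagged, not an error
  de3 <- make_de(c("mirX"), "miRNA", "up")
  ini3 <- build_initial_network("mirX", tm, de3)
  expect_true(ini3$no_targets)
  expect_equal(length(ini3$lncR) + length(ini3$mR), 0L)

  expect_error(build_initial_network("lncA", tm, de), "not a miRNA")
})

test_that("competition regulation keeps the two opposite-sign patterns only", {
  tm <- target_map(data.frame(mirna_id = "mir1",
                              target_id = c("lncA", "mrA"),
                              target_type = c("lncRNA", "mRNA")))
  # exhaustive truth table over status sign combinations
  for (mir_s in c("up", "down")) {
    for (lnc_s in c("up", "down")) {
      for (mr_s in c("up", "down")) {
        de <- make_de(c("mir1", "lncA", "mrA"),
                      c("miRNA", "lncRNA", "mRNA"),
                      c(mir_s, lnc_s, mr_s))
        cand <- apply_competition_regulation(
          build_initial_network("mir1", tm, de), de)
        legal <- (mir_s == "up" && lnc_s == "down" && mr_s == "down") ||
          (mir_s == "down" && lnc_s == "up" && mr_s == "up")
        if (legal) {
          expect_equal(cand$mode,
                       if (mir_s == "up") "positive" else "negative")
          expect_equal(cand$lncR, "lncA")
          expect_equal(cand$mR, "mrA")
        } else {
          expect_null(cand)
        }
      }
    }
  }
})

test_that("partial retention keeps only correctly-signed members", {
  tm <- target_map(data.frame(
    mirna_id = "mir1", target_id = c("lncA", "lncB", "mrA"),
    target_type = c("lncRNA", "lncRNA", "mRNA")))
  de <- make_de(c("mir1", "lncA", "lncB", "mrA"),
                c("miRNA", "lncRNA", "lncRNA", "mRNA"),
                c("up", "down", "up", "down"))
  cand <- apply_competition_regulation(
    build_initial_network("mir1", tm, de), de)
  expect_equal(cand$lncR, "lncA")  # up-regulated lncB excluded
  expect_equal(cand$mode, "positive")
})

test_that("crosstalk enumeration is the lexicographic Cartesian product", {
  net <- structure(list(mirna = "mir1", lncR = c("l2", "l1"),
                        mR = c("m3", "m1", "m2"), mode = "negative"),
                   class = "candidate_network")
  ct <- enumerate_crosstalks(net)
  expect_equal(nrow(ct), 6L)
  # brute-force double loop in sorted order
  ref <- NULL
  for (l in sort(net$lncR)) for (m in sort(net$mR)) {
    ref <- rbind(ref, data.frame(lnc = l, mirna = "mir1", mr = m,
                                 stringsAsFactors = FALSE))
  }
  expect_equal(ct, ref)

  net1 <- structure(list(mirna = "mir1", lncR = "l1", mR = "m1",
                         mode = "positive"), class = "candidate_network")
  expect_equal(enumerate_crosstalks(net1),
               data.frame(lnc = "l1", mirna = "mir1", mr = "m1",
                          stringsAsFactors = FALSE))
})

test_that("candidate crosstalk totals add up across networks", {
  set.seed(13)
  sim <- simulate_dataset(synthetic_config(n_pairs = 10, n_planted = 4,
                                           n_decoy_lnc = 10, n_decoy_mr = 10,
                                           n_decoy_mirna = 2, seed = 13))
  de <- differential_expression(filter_low_expression(sim$expression))
  nets <- candidate_networks(sim$targets, de)
  total <- sum(vapply(nets, function(n) length(n$lncR) * length(n$mR),
                      numeric(1)))
  enum <- sum(vapply(nets, function(n) nrow(enumerate_crosstalks(n)),
                     numeric(1)))
  expect_equal(enum, total)
})
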