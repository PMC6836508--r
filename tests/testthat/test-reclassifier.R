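cfg <- classification_config()

test_that("clustering links breakpoints within the window, not beyond", {
  close_pair <- rbind(
    adjacencies("chr1", 100, "R", "chr1", 5000, "L", tool = "SIM", id = "a"),
    adjacencies("chr1", 4998, "L", "chr1", 9000, "R", tool = "SIM",
                id = "b"))
  cl <- cluster_adjacencies(close_pair, cfg)
  expect_equal(length(unique(cl$cluster)), 1L)

  far_pair <- rbind(
    adjacencies("chr1", 100, "R", "chr1", 5000, "L", tool = "SIM", id = "a"),
    adjacencies("chr1", 5011, "L", "chr1", 9000, "R", tool = "SIM",
                id = "b"))
  cl <- cluster_adjacencies(far_pair, cfg)
  expect_equal(length(unique(cl$cluster)), 2L)

  ## different tools never co-cluster
  cross <- close_pair
  cross$tool <- c("DELLY", "MANTA")
  expect_equal(length(unique(cluster_adjacencies(cross, cfg)$cluster)), 2L)
})

test_that("clustering matches the brute-force union-find oracle", {
  withr::with_seed(99, {
    for (rep in 1:30) {
      adjs <- random_adjacencies(sample(2:50, 1), n_chrom = 2,
                                 span = 3000,
                                 tools = c("DELLY", "MANTA"))
      got <- cluster_adjacencies(adjs, cfg)
      want <- oracle_cluster(adjs, cfg$cluster_window)
      expect_equal(partition_of(got$id, got$cluster),
                   partition_of(adjs$id, want))
    }
  })
})

test_that("singleton signatures: DEL, TDUP, INS, exclusions", {
  del <- adjacencies("chr1", 100, "R", "chr1", 5000, "L", tool = "SIM")
  res <- classify_singleton(del, cfg)
  expect_equal(res$calls$type, "DEL")
  expect_equal(res$calls$start, 100)
  expect_equal(res$calls$end, 5000)
  expect_equal(cnv_size(res$calls), 4900)

  tdup <- adjacencies("chr1", 100, "L", "chr1", 5000, "R", tool = "SIM")
  expect_equal(classify_singleton(tdup, cfg)$calls$type, "TDUP")

  ins <- adjacencies("chr1", 700, "R", "chr1", 700, "L",
                     inserted_seq = unknown_seq(), tool = "SIM")
  res <- classify_singleton(ins, cfg)
  expect_equal(res$calls$type, "INS")
  expect_equal(res$calls$ins_pos, 700)
  expect_true(is.na(cnv_size(res$calls)))

  small <- adjacencies("chr1", 100, "R", "chr1", 130, "L", tool = "SIM")
  expect_equal(classify_singleton(small, cfg)$excluded$reason,
               "below_min_size")

  inv <- adjacencies("chr1", 100, "R", "chr1", 5000, "R", tool = "SIM")
  expect_equal(classify_singleton(inv, cfg)$excluded$reason,
               "inversion_like")

  tra <- adjacencies("chr1", 100, "R", "chr2", 5000, "L", tool = "SIM")
  expect_equal(classify_singleton(tra, cfg)$excluded$reason,
               "interchromosomal_singleton")
})

test_that("a co-clustered TDUP-like + DEL-like pair becomes one DDUP", {
  pair <- rbind(
    adjacencies("chr1", 10000, "L", "chr1", 50000, "R", tool = "SIM",
                id = "t"),
    adjacencies("chr1", 12000, "R", "chr1", 50001, "L", tool = "SIM",
                id = "d"))
  res <- classify_cluster(pair, cfg)
  expect_equal(res$calls$type, "DDUP")
  expect_equal(res$calls$start, 10000)
  expect_equal(res$calls$end, 12000)
  expect_equal(res$calls$ins_pos, 50000)
  expect_equal(nrow(res$excluded), 0L)

  ## shared breakpoints 40 bp apart: no DDUP, falls back to DEL + TDUP
  apart <- pair
  apart$pos2[2] <- 50041
  res <- classify_cluster(apart, cfg)
  expect_setequal(res$calls$type, c("DEL", "TDUP"))
})

test_that("DDUP support counts are the per-signal minimum of the members", {
  pair <- rbind(
    adjacencies("chr1", 10000, "L", "chr1", 50000, "R", pe = 7, sr = 2,
                tool = "SIM", id = "t"),
    adjacencies("chr1", 12000, "R", "chr1", 50001, "L", pe = 3, sr = 9,
                tool = "SIM", id = "d"))
  res <- classify_cluster(pair, cfg)
  expect_equal(res$calls$pe_support, 3)
  expect_equal(res$calls$sr_support, 2)
})

test_that("interchromosomal pairs with co-located acceptor breakends become a DDUP", {
  pair <- rbind(
    adjacencies("chr2", 7000, "R", "chr5", 3000, "L", tool = "SIM",
                id = "x"),
    adjacencies("chr2", 9000, "L", "chr5", 3001, "R", tool = "SIM",
                id = "y"))
  res <- classify_cluster(pair, cfg)
  expect_equal(res$calls$type, "DDUP")
  expect_equal(res$calls$chrom, "chr2")
  expect_equal(res$calls$start, 7000)
  expect_equal(res$calls$end, 9000)
  expect_equal(res$calls$ins_chrom, "chr5")
})

test_that("upstream-copy dispersed duplications close the loop with the simulator", {
  ## landing site upstream of the template: DEL-like (p R, s L) +
  ## TDUP-like (p L, e R)
  truth <- cnv_calls("DDUP", "chr1", 60000, 64000, ins_chrom = "chr1",
                     ins_pos = 2000, id = "t1")
  truth$inter <- FALSE
  truth$dosage <- 2
  adjs <- truth_adjacencies(truth)[, names(cnvpost:::ADJ_COLS)]
  res <- reclassify(adjs, cfg)
  expect_equal(res$calls$type, "DDUP")
  expect_equal(res$calls$start, 60000)
  expect_equal(res$calls$end, 64000)
  expect_equal(res$calls$ins_pos, 2000)
})

test_that("inverted-copy signatures are excluded unless flag-gated on", {
  pair <- rbind(
    adjacencies("chr1", 12000, "R", "chr1", 50000, "R", tool = "SIM",
                id = "rr"),
    adjacencies("chr1", 10000, "L", "chr1", 50001, "L", tool = "SIM",
                id = "ll"))
  res <- classify_cluster(pair, cfg)
  expect_equal(nrow(res$calls), 0L)
  expect_setequal(res$excluded$reason, "inversion_like")

  res <- classify_cluster(pair, classification_config(
    allow_inverted_ddup = TRUE))
  expect_equal(res$calls$type, "DDUP")
  expect_equal(res$calls$start, 10000)
  expect_equal(res$calls$end, 12000)
})

test_that("reclassify corrects the mis-called DEL+TDUP pair; a lone adjacency stays a DEL or TDUP", {
  both <- rbind(
    adjacencies("chr1", 10000, "L", "chr1", 50000, "R", tool = "DELLY",
                id = "t"),
    adjacencies("chr1", 12000, "R", "chr1", 50001, "L", tool = "DELLY",
                id = "d"))
  res <- reclassify(both, cfg)
  expect_equal(table(res$calls$type)[["DDUP"]], 1L)
  expect_false(any(res$calls$type %in% c("DEL", "TDUP")))

  lone <- both[2, ]
  res <- reclassify(lone, cfg)
  expect_equal(res$calls$type, "DEL")

  empty <- reclassify(empty_adjacencies(), cfg)
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(nrow(empty$excluded), 0L)
})

test_that("every adjacency lands in exactly one call or exclusion record", {
  withr::with_seed(21, {
    truth <- simulate_truth(c(chr1 = 5e6), c(DEL = 10, INS = 5, TDUP = 5,
                                             DDUP = 10))
    em <- emulate_caller(truth_adjacencies(truth),
                         caller_profile("delly", jitter_sd = 1,
                                        fp_per_mb = c(DEL = 2, TDUP = 2,
                                                      INS = 1, DDUP = 0)),
                         c(chr1 = 5e6))
  })
  res <- reclassify(em, cfg)
  backing <- sum(ifelse(res$calls$type == "DDUP", 2L, 1L))
  expect_equal(backing + nrow(res$excluded), nrow(em))
  expect_true(all(cnv_size(res$calls) >= cfg$min_size |
                    is.na(cnv_size(res$calls))))
})

test_that("simulated DDUPs are recovered; withholding one adjacency gives the matching DEL or TDUP", {
  withr::with_seed(31, {
    truth <- simulate_truth(c(chr1 = 1e7), c(DDUP = 30),
                            ddup_inter_fraction = 0)
    adjs <- truth_adjacencies(truth)
    em <- emulate_caller(adjs, caller_profile(
      "delly", detection = c(DDUP = 1), jitter_sd = 2,
      fp_per_mb = c(DEL = 0, INS = 0, TDUP = 0, DDUP = 0)),
      c(chr1 = 1e7))
  })
  res <- reclassify(em, cfg)
  expect_equal(sum(res$calls$type == "DDUP"), 30L)
  ev <- evaluate_calls(res$calls, truth)
  expect_gte(ev$recall[ev$type == "DDUP"], 0.95)

  ## one adjacency withheld per event -> zero DDUPs, one DEL or TDUP each
  half <- adjs[!duplicated(adjs$variant_id), names(cnvpost:::ADJ_COLS)]
  res1 <- reclassify(half, cfg)
  expect_equal(sum(res1$calls$type == "DDUP"), 0L)
  expect_equal(sum(res1$calls$type %in% c("DEL", "TDUP")), 30L)
})
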