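acfg <- aux_filter_config(enabled = TRUE)

make_track <- function(chr1) depth_track(list(chr1 = chr1))

test_that("normalized median depth is region median over chromosome median", {
  track <- make_track(c(rep(20, 500), rep(10, 100), rep(20, 400)))
  del <- cnv_calls("DEL", "chr1", 500, 600)
  expect_equal(normalized_median_depth(del, track), 0.5)

  flat <- make_track(rep(13, 1000))
  expect_equal(normalized_median_depth(del, flat), 1)

  ## median is robust to a single pile-up base
  spiky <- make_track(c(rep(2, 997), 1, 2, 100))
  odd <- cnv_calls("DEL", "chr1", 997, 1000)
  expect_equal(normalized_median_depth(odd, spiky), 1)

  expect_error(normalized_median_depth(
    cnv_calls("DEL", "chr1", 900, 1100), track), "outside")
  expect_error(normalized_median_depth(
    cnv_calls("DEL", "chr9", 0, 10), track), "absent")
})

test_that("depth filter keeps depleted deletions and enriched duplications", {
  base <- rep(20, 2000)
  base[101:200] <- 8     # true deletion: ratio 0.4
  base[301:400] <- 30    # true duplication: ratio 1.5
  base[501:600] <- 15    # boundary deletion: ratio 0.75 survives (strict >)
  base[701:800] <- 1500  # excessive pile-up
  track <- make_track(base)
  calls <- rbind(
    cnv_calls("DEL", "chr1", 100, 200, id = "del_ok"),
    cnv_calls("TDUP", "chr1", 300, 400, id = "dup_ok"),
    cnv_calls("DEL", "chr1", 500, 600, id = "del_boundary"),
    cnv_calls("DEL", "chr1", 700, 800, id = "del_excessive"),
    cnv_calls("TDUP", "chr1", 1000, 1100, id = "dup_flat"),
    cnv_calls("INS", "chr1", 1200, 1200, ins_chrom = "chr1",
              ins_pos = 1200, id = "ins_any"))
  kept <- depth_filter(calls, track, acfg)
  expect_setequal(kept$id, c("del_ok", "dup_ok", "del_boundary", "ins_any"))
  removed <- attr(kept, "removed")
  expect_equal(removed$reason[removed$id == "del_excessive"],
               "excessive_depth")
  expect_equal(removed$reason[removed$id == "dup_flat"],
               "depth_not_duplicated")
  ## idempotent subset operator
  again <- depth_filter(kept, track, acfg)
  attr(kept, "removed") <- NULL
  attr(again, "removed") <- NULL
  expect_equal(again, kept)
})

test_that("depth filter separates simulated true and false deletions", {
  withr::with_seed(55, {
    n <- 60
    len <- 200
    depth <- rep(20, 200000)
    starts <- seq(100, by = 1500, length.out = 2 * n)
    ratio <- c(pmax(0.05, rnorm(n, 0.5, 0.1)), pmax(0.05, rnorm(n, 1, 0.1)))
    for (i in seq_along(starts))
      depth[(starts[i] + 1):(starts[i] + len)] <- 20 * ratio[i]
    track <- make_track(depth)
    calls <- cnv_calls("DEL", "chr1", starts, starts + len,
                       id = sprintf("d%d", seq_along(starts)))
    truth_true <- calls$id[seq_len(n)]
    kept <- depth_filter(calls, track, acfg)
    expect_gte(mean(truth_true %in% kept$id), 0.9)            # true kept
    expect_lte(mean(setdiff(calls$id, truth_true) %in% kept$id), 0.1)
  })
})

test_that("flank gap fraction counts Ns in clipped 400 bp flanks", {
  n400 <- strrep("N", 400)
  a400 <- strrep("A", 400)
  genome <- c(chr1 = paste0(n400, a400, n400, a400))
  call <- cnv_calls("DEL", "chr1", 400, 800)   # N-flank both sides
  expect_equal(flank_gap_fraction(call, genome, acfg), 1)
  clean <- cnv_calls("DEL", "chr1", 800, 1200) # A-flank both sides
  expect_equal(flank_gap_fraction(clean, genome, acfg), 0)
  half <- cnv_calls("DEL", "chr1", 400, 800)   # one N flank, one A flank
  genome_half <- c(chr1 = paste0(n400, a400, a400))
  expect_equal(flank_gap_fraction(half, genome_half, acfg), 0.5)
  nofl <- c(chr1 = paste0(a400, a400))
  expect_equal(flank_gap_fraction(cnv_calls("DEL", "chr1", 100, 700), nofl,
                                  acfg), 0)
  ## call at position 0: only the available flank bases count
  edge <- cnv_calls("DEL", "chr1", 0, 400)
  expect_equal(flank_gap_fraction(edge, genome, acfg), 0)
  expect_error(flank_gap_fraction(cnv_calls("DEL", "chrX", 0, 10), genome,
                                  acfg), "absent")
})

test_that("gap filter removes above the threshold, strictly", {
  genome <- c(chr1 = paste0(strrep("N", 300), strrep("A", 100),
                            strrep("A", 200),
                            strrep("N", 200), strrep("A", 200),
                            strrep("A", 5000)))
  over <- cnv_calls("DEL", "chr1", 400, 600, id = "over")    # 300+200 N/800
  genome2 <- c(chr1 = paste0(strrep("N", 200), strrep("A", 200),
                             strrep("C", 200),
                             strrep("N", 200), strrep("A", 5000)))
  exact <- cnv_calls("DEL", "chr1", 400, 600, id = "exact")  # 400 N / 800
  calls <- rbind(over, exact)
  kept1 <- gap_filter(calls, genome, acfg)
  expect_false("over" %in% kept1$id)
  kept2 <- gap_filter(calls, genome2, acfg)
  expect_true("exact" %in% kept2$id)   # fraction exactly 0.5 survives
  ## idempotence
  again <- gap_filter(kept2, genome2, acfg)
  attr(kept2, "removed") <- NULL
  attr(again, "removed") <- NULL
  expect_equal(again, kept2)
})
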