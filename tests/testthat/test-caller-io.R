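write_toy_vcf <- function(lines, extra_header = character(0)) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"pe\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"sr\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##contig=<ID=chr1,length=10000000>",
    "##contig=<ID=chr5,length=10000000>",
    extra_header,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}

delly <- default_dialects()$delly

test_that("symbolic DEL record becomes one right/left adjacency", {
  path <- write_toy_vcf(
    "chr1\t100\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5000;PE=5;SR=3\tGT\t0/1")
  adjs <- read_caller_vcf(path, delly)
  expect_equal(nrow(adjs), 1L)
  expect_equal(adjs$pos1, 100)
  expect_equal(adjs$ori1, "R")
  expect_equal(adjs$pos2, 5000)
  expect_equal(adjs$ori2, "L")
  expect_equal(adjs$pe, 5)
  expect_equal(adjs$sr, 3)
  expect_equal(adjs$tool, "DELLY")
})

test_that("BND mate records collapse to a single adjacency", {
  path <- write_toy_vcf(c(
    "chr1\t200\tb1\tN\tN[chr5:7001[\t.\tPASS\tSVTYPE=BND;MATEID=b2;PE=2;SR=1\tGT\t0/1",
    "chr5\t7001\tb2\tN\t]chr1:200]N\t.\tPASS\tSVTYPE=BND;MATEID=b1;PE=2;SR=1\tGT\t0/1"))
  adjs <- read_caller_vcf(path, delly)
  expect_equal(nrow(adjs), 1L)
  expect_equal(adjs$chrom1, "chr1")
  expect_equal(adjs$pos1, 200)
  expect_equal(adjs$ori1, "R")
  expect_equal(adjs$chrom2, "chr5")
  expect_equal(adjs$pos2, 7000)
  expect_equal(adjs$ori2, "L")
})

test_that("unmatched BND mates are skipped with a warning and counted", {
  path <- write_toy_vcf(
    "chr1\t200\tb1\tN\tN[chr5:7001[\t.\tPASS\tSVTYPE=BND;MATEID=zz;PE=2;SR=1\tGT\t0/1")
  expect_warning(adjs <- read_caller_vcf(path, delly), "unmatched")
  expect_equal(nrow(adjs), 0L)
  expect_equal(attr(adjs, "skipped"), 1L)
})

test_that("missing support fields default to zero with a warning", {
  path <- write_toy_vcf(
    "chr1\t100\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=5000\tGT\t0/1")
  odd <- caller_dialect("DELLY", "mixed",
                        pe_field = list(key = "NOPE", where = "info"),
                        sr_field = list(key = "NOSR", where = "info"))
  warns <- capture_warnings(adjs <- read_caller_vcf(path, odd))
  expect_length(warns, 2L)
  expect_match(warns, "missing support", all = TRUE)
  expect_equal(adjs$pe, 0)
  expect_equal(adjs$sr, 0)
})

test_that("header-only VCF yields an empty adjacency table", {
  path <- write_toy_vcf(character(0))
  adjs <- read_caller_vcf(path, delly)
  expect_s3_class(adjs, "data.frame")
  expect_equal(nrow(adjs), 0L)
})

test_that("n symbolic records give n adjacencies; breakend dialects 2 records each", {
  withr::with_seed(11, {
    truth <- simulate_truth(c(chr1 = 2e6, chr2 = 2e6),
                            c(DEL = 6, INS = 4, TDUP = 5, DDUP = 5))
    adjs <- truth_adjacencies(truth)[, names(cnvpost:::ADJ_COLS)]
  })
  d <- default_dialects()
  f_sym <- tempfile(fileext = ".vcf")
  write_caller_vcf(adjs, f_sym, d$delly, c(chr1 = 2e6, chr2 = 2e6))
  sym_lines <- sum(!startsWith(readLines(f_sym), "#"))
  back <- read_caller_vcf(f_sym, d$delly)
  expect_equal(nrow(back), nrow(adjs))
  f_bnd <- tempfile(fileext = ".vcf")
  write_caller_vcf(adjs, f_bnd, d$gridss, c(chr1 = 2e6, chr2 = 2e6))
  bnd_lines <- sum(!startsWith(readLines(f_bnd), "#"))
  expect_equal(bnd_lines, 2L * nrow(adjs))
  expect_equal(nrow(read_caller_vcf(f_bnd, d$gridss)), nrow(adjs))
})

test_that("vcf -> internal -> vcf preserves coordinates for every dialect", {
  withr::with_seed(5, {
    truth <- simulate_truth(c(chr1 = 3e6, chr2 = 2e6),
                            c(DEL = 5, INS = 3, TDUP = 4, DDUP = 6))
    adjs <- truth_adjacencies(truth)[, names(cnvpost:::ADJ_COLS)]
    adjs$pe <- sample.int(20, nrow(adjs), replace = TRUE)
    adjs$sr <- sample.int(20, nrow(adjs), replace = TRUE)
  })
  norm <- function(x) {
    x <- x[order(x$chrom1, x$pos1, x$pos2),
           c("chrom1", "pos1", "ori1", "chrom2", "pos2", "ori2",
             "inserted_seq", "pe", "sr")]
    rownames(x) <- NULL
    x
  }
  for (nm in c("delly", "gridss", "lumpy", "manta")) {
    dialect <- default_dialects()[[nm]]
    path <- tempfile(fileext = ".vcf")
    adjs$tool <- dialect$tool
    write_caller_vcf(adjs, path, dialect, c(chr1 = 3e6, chr2 = 2e6))
    back <- read_caller_vcf(path, dialect)
    expect_equal(norm(back), norm(adjs), info = nm)
  }
})

test_that("BEDPE encodes breakend intervals, strands and insertion points", {
  del <- cnv_calls("DEL", "chr1", 100, 5000, id = "d1")
  ddup <- cnv_calls("DDUP", "chr1", 10000, 12000, ins_chrom = "chr1",
                    ins_pos = 50000, id = "dd1")
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(rbind(del, ddup), path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "#chrom1"))
  f <- strsplit(lines[2], "\t")[[1]]
  expect_equal(f[2:3], c("99", "100"))       # right-anchored junction 100
  expect_equal(f[5:6], c("5000", "5001"))    # left-anchored junction 5000
  expect_equal(f[9:10], c("+", "-"))
  g <- strsplit(lines[3], "\t")[[1]]
  expect_equal(g[11], "DDUP")
  expect_equal(g[18], "50000")
})

test_that("BEDPE read/write round-trips a mixed four-type call set", {
  calls <- rbind(
    cnv_calls("DEL", "chr1", 100, 5000, pe_support = 3.5, sr_support = 2,
              source_tools = "DELLY,MANTA", n_donors = 2, id = "a"),
    cnv_calls("TDUP", "chr2", 900, 2000, score = 0.75, id = "b"),
    cnv_calls("INS", "chr1", 700, 700, ins_chrom = "chr1", ins_pos = 700,
              inserted_seq = unknown_seq(), id = "c"),
    cnv_calls("INS", "chr1", 800, 800, ins_chrom = "chr1", ins_pos = 800,
              inserted_seq = "ACGTACGT", id = "c2"),
    cnv_calls("DDUP", "chr2", 5000, 9000, ins_chrom = "chr5",
              ins_pos = 100000, id = "d"))
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(calls, path)
  back <- read_bedpe(path)
  expect_equal(back, calls)
  ## a DDUP line reconstructs both backing adjacencies
  two <- call_adjacencies(back[back$type == "DDUP", ])
  expect_equal(nrow(two), 2L)
  expect_equal(sort(two$ori2), c("L", "R"))
})

test_that("empty call set writes a header-only BEDPE that reads back empty", {
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(empty_calls(), path)
  expect_equal(nrow(read_bedpe(path)), 0L)
})

test_that("truncated BEDPE lines raise an error naming the line", {
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(cnv_calls("DEL", "chr1", 100, 5000), path)
  lines <- readLines(path)
  writeLines(c(lines, "chr1\t1\t2\tchr1"), path)
  expect_error(read_bedpe(path), "line 3")
})
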