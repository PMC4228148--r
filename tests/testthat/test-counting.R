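empty_catalog <- function(len = 1000L, chrom = "chrA") {
  genes <- GenomicRanges::GRanges(id = character(), role = character())
  partition_genome(genes, stats::setNames(len, chrom))
}

test_that("strandedness dialects set the fragment strand from read orientation", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chrI\t100\t200\tr1\t255\t+", bed)
  expect_equal(as.character(BiocGenerics::strand(
    read_alignments(bed, dialect = "forward"))), "+")
  expect_equal(as.character(BiocGenerics::strand(
    read_alignments(bed, dialect = "reverse"))), "-")
  expect_equal(as.character(BiocGenerics::strand(
    read_alignments(bed, dialect = "unstranded"))), "*")
  bed2 <- tempfile(fileext = ".bed")
  writeLines("chrI\t100\t200\tr1\t255\t-", bed2)
  expect_equal(as.character(BiocGenerics::strand(
    read_alignments(bed2, dialect = "forward"))), "-")
})

test_that("uniqueness filtering follows the configured policy and logs drops", {
  fr <- c(frag("chrA", 1, 100, "+", nhits = 1L),
          frag("chrA", 1, 100, "+", nhits = 3L),
          frag("chrA", 1, 100, "+", nhits = NA_integer_, mapq = 5L),
          frag("chrA", 1, 100, "+", nhits = NA_integer_, mapq = 50L))
  kept <- filter_unique(fr, policy = "auto")
  expect_equal(length(kept), 2L)        # NH==1 plus the high-mapq fallback
  log <- attr(kept, "drop_log")
  expect_equal(log$n[log$reason == "multi_mapped"], 1L)
  expect_equal(log$n[log$reason == "low_mapq"], 1L)
  expect_equal(length(filter_unique(fr, policy = "nhits")), 1L)
  # the mapq policy ignores hit counts entirely
  expect_equal(length(filter_unique(fr, policy = "mapq", mapq_min = 10L)), 3L)
  # larger enumeration: 4 multi-mapped of 10 dropped
  fr10 <- do.call(c, lapply(1:10, function(i)
    frag("chrA", i, i + 50, "+", nhits = if (i <= 4) 2L else 1L)))
  expect_equal(length(filter_unique(fr10, policy = "nhits")), 6L)
})

test_that("fragments are counted by their 5'-most base into same-strand regions", {
  cat <- empty_catalog(1000L)
  # fully inside the first plus window
  expect_equal(unname(count_reads(frag("chrA", 121, 220, "+"), cat)
                      [c("chrA:p:b0001:w01", "chrA:p:b0001:w02")]), c(1L, 0L))
  # spanning the window boundary with 5' base 481: first window only
  expect_equal(unname(count_reads(frag("chrA", 481, 580, "+"), cat)
                      [c("chrA:p:b0001:w01", "chrA:p:b0001:w02")]), c(1L, 0L))
  # minus-strand fragment anchors at its rightmost base
  expect_equal(unname(count_reads(frag("chrA", 481, 580, "-"), cat)
                      [c("chrA:m:b0001:w01", "chrA:m:b0001:w02")]), c(0L, 1L))
  # zero fragments: all-zero column
  expect_true(all(count_reads(frag("chrA", 1, 10, "+")[0], cat) == 0L))
})

test_that("counting conserves every fragment exactly once and respects strand", {
  set.seed(401)
  genes <- random_genes(8, 20000L)
  genes <- genes[!duplicated(paste(BiocGenerics::start(genes),
                                   BiocGenerics::strand(genes)))]
  cat <- suppressWarnings(partition_genome(genes, c(chrZ = 20000L)))
  n <- 5000
  starts <- sample.int(19899L, n, replace = TRUE)
  fr <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(starts, starts + 99L),
                               strand = sample(c("+", "-"), n, TRUE),
                               nhits = 1L, mapq = 255L,
                               read_role = "unpaired")
  counts <- count_reads(fr, cat)
  expect_equal(sum(counts), n)
  plus_regions <- cat$regions$id[as.logical(
    BiocGenerics::strand(cat$regions) == "+")]
  expect_equal(sum(counts[plus_regions]),
               sum(BiocGenerics::strand(fr) == "+"))
})

test_that("antisense fraction counts only ORF-opposite anchors", {
  genes <- make_genes(data.frame(chrom = "chrA",
                                 start = c(1001, 3001), end = c(2000, 3400),
                                 strand = c("+", "+"),
                                 id = c("ORF1", "NC1"),
                                 role = c("coding_gene", "noncoding_gene")),
                      c(chrA = 5000L))
  cat <- partition_genome(genes, c(chrA = 5000L))
  sense <- do.call(c, lapply(1:8, function(i)
    frag("chrA", 1001 + i * 10, 1100 + i * 10, "+")))
  anti <- c(frag("chrA", 1101, 1200, "-"), frag("chrA", 1301, 1400, "-"))
  expect_equal(antisense_fraction(c(sense, anti), cat), 0.2)
  expect_equal(antisense_fraction(sense, cat), 0)
  # antisense to a non-coding gene only: excluded from the numerator
  nc_anti <- frag("chrA", 3101, 3200, "-")
  expect_equal(antisense_fraction(c(sense, sense, nc_anti), cat), 0)
  expect_warning(res <- antisense_fraction(sense[0], cat), "no fragments")
  expect_true(is.na(res))
})

test_that("replicate correlation is Pearson on log2(count+1)", {
  ss <- sheet_2v2()
  m <- matrix(rpois(400, 50), ncol = 4,
              dimnames = list(NULL, ss$sample))
  m[, "wildtype_2"] <- m[, "wildtype_1"]
  r <- suppressWarnings(replicate_correlation(m, ss))
  expect_equal(unname(r["wildtype"]), 1)
  # textbook formula, written independently
  x <- log2(m[, "mutant_1"] + 1); y <- log2(m[, "mutant_2"] + 1)
  n <- length(x)
  rr <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(unname(r["mutant"]), rr, tolerance = 1e-12)
  m[, "mutant_1"] <- 7L
  expect_warning(r2 <- replicate_correlation(m, ss), "constant")
  expect_true(is.na(r2["mutant"]))
})

test_that("pearson agreement with the independent formula holds at scale", {
  set.seed(402)
  x <- log2(rnbinom(10000, mu = 40, size = 5) + 1)
  y <- x + rnorm(10000, sd = 0.3)
  n <- 10000
  rr <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(stats::cor(x, y), rr, tolerance = 1e-12)
})

test_that("bedGraph runs are maximal constant-coverage intervals", {
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(frag("chrA", 101, 200, "+"), path, strand = "+")
  got <- read_bedgraph(path)
  expect_equal(got, data.frame(chrom = "chrA", start = 100L, end = 200L,
                               value = 1L))
  # two overlapping fragments: coverage walk 1,2,1
  write_bedgraph(c(frag("chrA", 101, 200, "+"), frag("chrA", 151, 250, "+")),
                 path, strand = "+")
  got <- read_bedgraph(path)
  expect_equal(got$value, c(1L, 2L, 1L))
  expect_equal(got$start, c(100L, 150L, 200L))
  expect_equal(got$end, c(150L, 200L, 250L))
  # no fragments on the requested strand: header only
  write_bedgraph(frag("chrA", 101, 200, "+"), path, strand = "-")
  expect_equal(length(readLines(path)), 1L)
  # negation for display
  write_bedgraph(frag("chrA", 101, 200, "-"), path, strand = "-",
                 negate = TRUE)
  expect_equal(read_bedgraph(path)$value, -1L)
})

test_that("bedGraph mass equals total aligned bases", {
  set.seed(403)
  starts <- sample.int(5000L, 300, replace = TRUE)
  widths <- sample(50:150, 300, replace = TRUE)
  fr <- GenomicRanges::GRanges("chrA",
                               IRanges::IRanges(starts, width = widths),
                               strand = "+")
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(fr, path, strand = "+")
  got <- read_bedgraph(path)
  expect_equal(sum(got$value * (got$end - got$start)),
               sum(BiocGenerics::width(fr)))
})

test_that("SAM input honors flags, merges mates, and reads NH tags", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chrI\tLN:5000",
    # proper pair: mates at 101 and 201, fragment spans their union
    paste("p1", 99, "chrI", 101, 60, "100M", "=", 201, 200,
          strrep("A", 100), "*", "NH:i:1", sep = "\t"),
    paste("p1", 147, "chrI", 201, 60, "100M", "=", 101, -200,
          strrep("A", 100), "*", "NH:i:1", sep = "\t"),
    # unpaired unique plus-strand read
    paste("u1", 0, "chrI", 401, 60, "100M", "*", 0, 0,
          strrep("A", 100), "*", "NH:i:1", sep = "\t"),
    # multi-mapped read
    paste("m1", 0, "chrI", 501, 3, "100M", "*", 0, 0,
          strrep("A", 100), "*", "NH:i:3", sep = "\t"),
    # secondary alignment: dropped on input
    paste("s1", 256, "chrI", 601, 0, "100M", "*", 0, 0,
          "*", "*", "NH:i:2", sep = "\t"),
    # unpaired minus-strand read
    paste("u2", 16, "chrI", 701, 60, "100M", "*", 0, 0,
          strrep("A", 100), "*", "NH:i:1", sep = "\t")), sam)
  fr <- read_alignments(sam, dialect = "reverse")
  expect_equal(length(fr), 4L)          # pair merged; secondary gone
  pair <- fr[fr$read_role == "pair"]
  expect_equal(BiocGenerics::start(pair), 101L)
  expect_equal(BiocGenerics::end(pair), 300L)
  # read1 aligned plus; reverse dialect flips the fragment to minus
  expect_equal(as.character(BiocGenerics::strand(pair)), "-")
  u2 <- fr[BiocGenerics::start(fr) == 701L]
  expect_equal(as.character(BiocGenerics::strand(u2)), "+")
  kept <- filter_unique(fr, policy = "nhits")
  expect_equal(length(kept), 3L)
  # forward dialect keeps read-1 orientation
  fwd <- read_alignments(sam, dialect = "forward")
  expect_equal(as.character(BiocGenerics::strand(
    fwd[fwd$read_role == "pair"])), "+")
})

test_that("a count matrix assembles from a sample sheet of alignment BEDs", {
  cat <- empty_catalog(1000L)
  dir <- tempfile("beds"); dir.create(dir)
  ss <- sheet_2v2()
  ss$path <- file.path(dir, paste0(ss$sample, ".bed"))
  for (i in 1:4)
    writeLines(sprintf("chrA\t%d\t%d\tr%d\t255\t+", 100 + i, 200 + i, i),
               ss$path[i])
  m <- build_count_matrix(ss, cat, dialect = "forward")
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(unname(colSums(m)), rep(1L, 4))
  ss$path[2] <- file.path(dir, "missing.bed")
  expect_error(build_count_matrix(ss, cat, dialect = "forward"), "missing")
})
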