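# Internal coordinates are 1-based closed (GRanges); the half-open
# conventions of GFF3/BED apply only at the file boundaries.

test_that("annotation loading maps feature types to roles and sites", {
  f <- tiny_annotation_files()
  ann <- load_annotation(f$gff, f$sizes, f$bed)
  expect_setequal(ann$genes$id, c("GENE1", "GENE2", "tT1", "NC1"))
  expect_equal(ann$genes$role[ann$genes$id == "GENE1"], "coding_gene")
  expect_equal(ann$genes$role[ann$genes$id == "tT1"], "noncoding_gene")
  expect_equal(ann$genes$role[ann$genes$id == "NC1"], "noncoding_gene")
  # tRNA gene doubles as a tDNA site; BED entry becomes an ETC site
  expect_equal(ann$sites$site_class[ann$sites$id == "tT1"], "tDNA")
  etc <- ann$sites[ann$sites$id == "ETC9"]
  expect_equal(etc$site_class, "ETC")
  expect_equal(BiocGenerics::start(etc), 1001L)
  expect_equal(BiocGenerics::end(etc), 1100L)
})

test_that("absent or empty site BED yields zero extra sites without error", {
  f <- tiny_annotation_files()
  ann <- load_annotation(f$gff, f$sizes, etc_bed_source = NULL)
  expect_true(all(ann$sites$site_class == "tDNA"))
  empty_bed <- file.path(f$dir, "empty.bed")
  file.create(empty_bed)
  ann2 <- load_annotation(f$gff, f$sizes, empty_bed)
  expect_equal(sum(ann2$sites$site_class == "ETC"), 0L)
})

test_that("unknown chromosomes are a hard error naming the offender", {
  f <- tiny_annotation_files()
  bad <- file.path(f$dir, "bad.gff3")
  writeLines(c("##gff-version 3",
               "chrXIV\ttest\tgene\t100\t200\t.\t+\t.\tID=G9"), bad)
  expect_error(load_annotation(bad, f$sizes), "chrXIV")
})

test_that("partition of an empty chromosome tiles both strands exactly", {
  genes <- GenomicRanges::GRanges(id = character(), role = character())
  cat <- partition_genome(genes, c(chrA = 1000L))
  for (s in c("+", "-")) {
    w <- cat$regions[BiocGenerics::strand(cat$regions) == s]
    expect_equal(BiocGenerics::start(w), c(1L, 501L))
    expect_equal(BiocGenerics::end(w), c(500L, 1000L))
    expect_true(all(w$role == "intergenic_window"))
  }
})

test_that("windows follow the left-anchored remainder rule around a gene", {
  # one plus-strand gene occupying bases 1001..1600 of a 2300-base chromosome
  genes <- make_genes(data.frame(chrom = "chrA", start = 1001, end = 1600,
                                 strand = "+", id = "G1",
                                 role = "coding_gene"), c(chrA = 2300L))
  cat <- partition_genome(genes, c(chrA = 2300L))
  plus <- cat$regions[BiocGenerics::strand(cat$regions) == "+"]
  win <- plus[plus$role == "intergenic_window"]
  expect_equal(BiocGenerics::start(win), c(1L, 501L, 1601L, 2101L))
  expect_equal(BiocGenerics::end(win), c(500L, 1000L, 2100L, 2300L))
  # flanks of the second block
  b2 <- win[BiocGenerics::start(win) == 1601L]
  expect_equal(b2$flank_left_gene, "G1")
  expect_equal(b2$flank_right_gene, "")
  # the untouched minus strand tiles the whole chromosome: 4 x 500 + 300
  minus <- cat$regions[BiocGenerics::strand(cat$regions) == "-"]
  expect_equal(BiocGenerics::width(minus), c(500L, 500L, 500L, 500L, 300L))
})

test_that("blocks at or below the window size stay unsplit; short remainders merge", {
  mk <- function(len) {
    genes <- make_genes(data.frame(chrom = "chrA", start = len + 1,
                                   end = len + 300, strand = "+", id = "G1",
                                   role = "coding_gene"),
                        stats::setNames(len + 300L, "chrA"))
    cat <- partition_genome(genes, stats::setNames(len + 300L, "chrA"))
    w <- cat$regions[BiocGenerics::strand(cat$regions) == "+" &
                       cat$regions$role == "intergenic_window"]
    BiocGenerics::width(w)
  }
  expect_equal(mk(500L), 500L)          # exactly one window, unsplit
  expect_equal(mk(550L), 550L)          # remainder 50 < min_window: merged
  expect_equal(mk(620L), c(500L, 120L)) # remainder >= min_window: own window
  expect_equal(mk(80L), 80L)            # short single-window block kept whole
})

test_that("overlapping same-strand genes merge into one footprint with a warning", {
  genes <- make_genes(data.frame(chrom = "chrA",
                                 start = c(1001, 1501), end = c(2000, 2500),
                                 strand = "+", id = c("G1", "G2"),
                                 role = "coding_gene"), c(chrA = 5000L))
  expect_warning(cat <- partition_genome(genes, c(chrA = 5000L)), "merged")
  foot <- cat$regions[cat$regions$role == "coding_gene"]
  expect_equal(length(foot), 1L)
  expect_equal(foot$id, "G1+G2")
  expect_equal(BiocGenerics::start(foot), 1001L)
  expect_equal(BiocGenerics::end(foot), 2500L)
})

test_that("partition is complete, disjoint and idempotent on random genomes", {
  set.seed(301)
  for (rep in 1:20) {
    len <- sample(3000:20000, 1)
    genes <- random_genes(sample(3:15, 1), len)
    genes <- genes[!duplicated(paste(BiocGenerics::start(genes),
                                     BiocGenerics::strand(genes)))]
    cat <- suppressWarnings(partition_genome(genes, c(chrZ = len)))
    for (s in c("+", "-")) {
      rs <- cat$regions[BiocGenerics::strand(cat$regions) == s]
      expect_true(GenomicRanges::isDisjoint(rs))
      expect_equal(sum(BiocGenerics::width(rs)), len)
    }
    w <- cat$regions[cat$regions$role == "intergenic_window"]
    blocks <- split(BiocGenerics::width(w), w$block_id)
    single <- vapply(blocks, length, 1L) == 1L
    expect_true(all(unlist(blocks[!single]) >= 100))
    expect_true(all(BiocGenerics::width(w) <= 500 + 100 - 1))
    # re-partitioning the catalog's own gene footprint reproduces it
    foot <- cat$regions[cat$regions$role != "intergenic_window"]
    cat2 <- partition_genome(foot, c(chrZ = len))
    expect_identical(as.data.frame(cat$regions), as.data.frame(cat2$regions))
  }
})

test_that("nearest site distance follows the edge-gap convention", {
  sites <- GenomicRanges::GRanges("chrA",
    IRanges::IRanges(c(1501, 1701), c(1580, 1780)),
    id = c("sAdj", "sFar"), site_class = "tDNA")
  reg <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1001, 1500),
                                id = "r1")
  near <- nearest_polIII_site(reg, sites)
  expect_equal(near$site_id, "sAdj")    # book-ended: adjacency is distance 0
  expect_equal(near$distance, 0)
  near2 <- nearest_polIII_site(reg, sites[2])
  expect_equal(near2$distance, 200)     # pure gap arithmetic
  ovl <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1550, 1900),
                                id = "r2")
  expect_equal(nearest_polIII_site(ovl, sites)$distance, 0)  # overlap
  # empty registry: sentinel with infinite distance
  none <- nearest_polIII_site(reg, sites[0])
  expect_true(is.na(none$site_id))
  expect_equal(none$distance, Inf)
})

test_that("nearest site matches a brute-force scan on random regions", {
  set.seed(302)
  sites <- GenomicRanges::GRanges("chrA",
    IRanges::IRanges(sort(sample.int(99000, 40)), width = 80),
    id = sprintf("s%02d", 1:40), site_class = "tDNA")
  starts <- sample.int(99000, 1000)
  regs <- GenomicRanges::GRanges("chrA",
    IRanges::IRanges(starts, width = sample(50:500, 1000, replace = TRUE)),
    id = sprintf("r%04d", 1:1000))
  got <- nearest_polIII_site(regs, sites)
  gap <- function(s1, e1, s2, e2) {
    if (e1 < s2) s2 - e1 - 1L else if (e2 < s1) s1 - e2 - 1L else 0L
  }
  for (i in sample(1000, 200)) {
    d <- vapply(seq_along(sites), function(j)
      gap(BiocGenerics::start(regs)[i], BiocGenerics::end(regs)[i],
          BiocGenerics::start(sites)[j], BiocGenerics::end(sites)[j]), 0L)
    best <- min(d)
    pick <- which(d == best)
    pick <- pick[which.min(BiocGenerics::start(sites)[pick])]  # tie rule
    expect_equal(got$distance[i], best)
    expect_equal(got$site_id[i], sites$id[pick])
  }
})

test_that("catalog export writes BED6 plus a role sidecar", {
  f <- tiny_annotation_files()
  ann <- load_annotation(f$gff, f$sizes, f$bed)
  cat <- partition_genome(ann$genes, ann$chrom_sizes)
  bed <- tempfile(fileext = ".bed"); tsv <- tempfile(fileext = ".tsv")
  write_catalog(cat, bed, tsv)
  reread <- rtracklayer::import.bed(bed)
  expect_equal(length(reread), length(cat$regions))
  expect_equal(reread$name, cat$regions$id)
  side <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(side$role, cat$regions$role)
  expect_equal(side$start, BiocGenerics::start(cat$regions) - 1L)
})
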