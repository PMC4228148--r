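# Shared fixtures, all built in code at test time.

# A tiny two-chromosome annotation with one coding gene per strand, a tRNA
# gene and an ETC site, written as GFF3/BED/TSV files in a temp dir.
tiny_annotation_files <- function(dir = tempfile("ann")) {
  dir.create(dir)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\ttest\tgene\t1001\t2000\t.\t+\t.\tID=GENE1",
    "chrI\ttest\tgene\t3001\t3600\t.\t-\t.\tID=GENE2",
    "chrI\ttest\ttRNA_gene\t2501\t2580\t.\t+\t.\tID=tT1",
    "chrII\ttest\tncRNA_gene\t501\t700\t.\t+\t.\tID=NC1"), gff)
  bed <- file.path(dir, "etc.bed")
  writeLines("chrII\t1000\t1100\tETC9", bed)
  sizes <- file.path(dir, "sizes.tsv")
  writeLines(c("chrI\t5000", "chrII\t3000"), sizes)
  list(gff = gff, bed = bed, sizes = sizes, dir = dir)
}

# GRanges of genes from scratch (no files)
make_genes <- function(df, chrom_sizes) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$end),
                         strand = df$strand, id = df$id,
                         role = df$role)
}

# Random gene set on one chromosome for property tests
random_genes <- function(n, chrom_len, chrom = "chrZ") {
  starts <- sort(sample.int(chrom_len - 200L, n))
  width <- sample(50:400, n, replace = TRUE)
  ends <- pmin(starts + width, chrom_len)
  make_genes(data.frame(chrom = chrom, start = starts, end = ends,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        id = sprintf("g%03d", seq_len(n)),
                        role = "coding_gene"),
             stats::setNames(chrom_len, chrom))
}

# Fragment GRanges shortcut
frag <- function(chrom, start, end, strand, nhits = 1L, mapq = 255L) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, nhits = nhits, mapq = mapq,
                         read_role = "unpaired")
}

# 2v2 sample sheet
sheet_2v2 <- function() {
  data.frame(sample = c("wildtype_1", "wildtype_2", "mutant_1", "mutant_2"),
             condition = rep(c("wildtype", "mutant"), each = 2),
             replicate = c(1L, 2L, 1L, 2L))
}

# Independent log-space enumeration of the conditional NB exact test; kept
# deliberately separate from the implementation (gamma-function pmf,
# log-sum-exp normalization).
nb_exact_oracle <- function(kA, kB, sfa, sfb, alpha) {
  K <- kA + kB
  if (K == 0) return(1)
  sA <- sum(sfa); sB <- sum(sfb); q <- K / (sA + sB)
  lpmf <- function(x, mu, var) {
    if (var > mu) {
      r <- mu^2 / (var - mu); p <- r / (r + mu)
      lgamma(x + r) - lgamma(r) - lfactorial(x) + r * log(p) +
        x * log1p(-p)
    } else {
      x * log(mu) - mu - lfactorial(x)
    }
  }
  muA <- sA * q; muB <- sB * q
  vA <- muA + alpha * q^2 * sum(sfa^2)
  vB <- muB + alpha * q^2 * sum(sfb^2)
  a <- 0:K
  lp <- vapply(a, function(ai) lpmf(ai, muA, vA) + lpmf(K - ai, muB, vB), 0)
  lobs <- lpmf(kA, muA, vA) + lpmf(kB, muB, vB)
  M <- max(lp)
  min(1, sum(exp(lp[lp <= lobs + 1e-7] - M)) / sum(exp(lp - M)))
}

# A hand-built catalog + DE table for classifier scenarios.
# Layout (chrI, 10 kb, all relevant features on "+" unless noted):
#   GENEA + [1001,2000]; tDNA tX + or - as configured; GENEB + [4001,5500]
scenario_catalog <- function(genes_df, chrom_len = 10000L) {
  genes <- make_genes(genes_df, c(chrI = chrom_len))
  partition_genome(genes, c(chrI = chrom_len))
}

# Fake DE table marking the given window ids significant-up with meanB
fake_de <- function(catalog, up_ids, meanB = 50) {
  r <- catalog$regions
  data.frame(id = r$id, role = r$role, scope = ifelse(
    r$role == "intergenic_window", "intergenic", "genes"),
    baseMean = 1, meanA = 1,
    meanB = ifelse(r$id %in% up_ids, meanB, 1),
    foldChange = 1, log2FC = 0,
    pval = ifelse(r$id %in% up_ids, 1e-6, 0.9),
    padj = ifelse(r$id %in% up_ids, 1e-4, 1),
    significant = r$id %in% up_ids,
    direction = ifelse(r$id %in% up_ids, "up", "down"),
    dispersion = 0.1, stringsAsFactors = FALSE)
}
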