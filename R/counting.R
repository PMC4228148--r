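#' Read a sample sheet
#'
#' A TSV with columns `sample`, `condition`, `replicate` and optionally
#' `path` (alignment source per sample). Exactly two conditions are required
#' for the differential-expression stage.
#'
#' @param path Path to the TSV.
#' @return data.frame with the columns above.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_sample_sheet(ss)
}

#' @rdname read_sample_sheet
#' @param sample_sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(sample_sheet) {
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(sample_sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sample_sheet$sample))
    stop("duplicated sample ids in sample sheet")
  if (any(table(sample_sheet$condition) < 1L))
    stop("every condition needs at least one sample")
  sample_sheet
}

#' Read alignments as stranded fragment records
#'
#' Consumes SAM/BAM (standard flags honored: unmapped, secondary and
#' supplementary records are dropped; mate pairs are merged into one fragment
#' spanning the mate union) or a simplified 6-column alignment BED in which
#' each row is one fragment (score column read as mapping quality).
#'
#' The fragment strand is derived from the orientation of the first-in-pair
#' (or unpaired) read under the library dialect: `"forward"` keeps the read
#' strand, `"reverse"` (the default elsewhere in the package, matching
#' dUTP-type stranded kits) flips it, `"unstranded"` yields `*`.
#'
#' @param source Path to a `.sam`, `.bam` or `.bed` file.
#' @param dialect Strandedness dialect, one of `"reverse"`, `"forward"`,
#'   `"unstranded"`.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"bed"`.
#' @return GRanges of fragments with mcols `nhits` (reported hit count, `NA`
#'   when the aligner did not record it), `mapq`, and `read_role`.
#' @export
read_alignments <- function(source,
                            dialect = c("reverse", "forward", "unstranded"),
                            format = c("auto", "sam", "bam", "bed")) {
  dialect <- match.arg(dialect)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(source)),
                     sam = "sam", bam = "bam", bed = "bed",
                     stop("cannot infer alignment format from '", source,
                          "'; pass format="))
  }
  if (format == "bed") {
    bed <- rtracklayer::import.bed(source)
    frags <- GenomicRanges::granges(bed)
    S4Vectors::mcols(frags) <- S4Vectors::DataFrame(
      nhits = NA_integer_,
      mapq = if (is.null(bed$score)) NA_integer_ else as.integer(bed$score),
      read_role = "unpaired")
    return(.apply_dialect(frags, dialect))
  }
  bam_path <- source
  if (format == "sam")
    bam_path <- Rsamtools::asBam(source,
                                 destination = tempfile(fileext = ""),
                                 overwrite = TRUE, indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, tag = "NH",
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand"))
  ga <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(ga$pos)
  if (n == 0L)
    return(.apply_dialect(GenomicRanges::GRanges(
      nhits = integer(), mapq = integer(), read_role = character()), dialect))
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(ga$cigar)
  nh <- ga$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  reads <- data.frame(qname = ga$qname, flag = ga$flag,
                      chrom = as.character(ga$rname), start = ga$pos,
                      end = ga$pos + width - 1L,
                      strand = as.character(ga$strand),
                      mapq = as.integer(ga$mapq), nhits = as.integer(nh),
                      stringsAsFactors = FALSE)
  paired <- bitwAnd(reads$flag, 1L) > 0L
  first <- bitwAnd(reads$flag, 64L) > 0L

  frag_list <- list()
  un <- reads[!paired, , drop = FALSE]
  if (nrow(un))
    frag_list$unpaired <- data.frame(
      chrom = un$chrom, start = un$start, end = un$end, strand = un$strand,
      nhits = un$nhits, mapq = un$mapq, read_role = "unpaired")
  pr <- reads[paired, , drop = FALSE]
  if (nrow(pr)) {
    pr$first <- first[paired]
    sp <- split(pr, pr$qname)
    rows <- lapply(sp, function(m) {
      if (nrow(m) == 2L && length(unique(m$chrom)) == 1L) {
        r1 <- m[m$first, , drop = FALSE]
        if (nrow(r1) != 1L) r1 <- m[1L, , drop = FALSE]
        data.frame(chrom = m$chrom[1], start = min(m$start),
                   end = max(m$end), strand = r1$strand[1],
                   nhits = max(m$nhits), mapq = min(m$mapq),
                   read_role = "pair")
      } else {
        # orphan mates (or mates on different chromosomes) count singly
        data.frame(chrom = m$chrom, start = m$start, end = m$end,
                   strand = m$strand, nhits = m$nhits, mapq = m$mapq,
                   read_role = ifelse(m$first, "first", "second"))
      }
    })
    frag_list$paired <- do.call(rbind, rows)
  }
  fr <- do.call(rbind, frag_list)
  frags <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(fr$start, fr$end),
                                  strand = fr$strand, nhits = fr$nhits,
                                  mapq = fr$mapq, read_role = fr$read_role)
  .apply_dialect(frags, dialect)
}

.apply_dialect <- function(frags, dialect) {
  if (dialect == "reverse") {
    frags <- BiocGenerics::invertStrand(frags)
  } else if (dialect == "unstranded") {
    BiocGenerics::strand(frags) <- "*"
  }
  frags
}

#' Keep only uniquely mapped fragments
#'
#' Policy `"nhits"` keeps fragments whose reported hit count is 1; `"mapq"`
#' keeps fragments with mapping quality at or above `mapq_min`. The default
#' `"auto"` uses the hit count where that evidence exists and falls back to
#' the mapping-quality threshold where it does not.
#'
#' @param frags GRanges from [read_alignments()].
#' @param policy `"auto"`, `"nhits"` or `"mapq"`.
#' @param mapq_min Minimum mapping quality for the mapq policy (default 10).
#' @return Filtered GRanges; attribute `"drop_log"` is a data.frame of drop
#'   counts by reason.
#' @export
filter_unique <- function(frags, policy = c("auto", "nhits", "mapq"),
                          mapq_min = 10L) {
  policy <- match.arg(policy)
  nh <- frags$nhits; mq <- frags$mapq
  keep <- switch(policy,
    nhits = !is.na(nh) & nh == 1L,
    mapq = !is.na(mq) & mq >= mapq_min,
    auto = ifelse(!is.na(nh), nh == 1L, !is.na(mq) & mq >= mapq_min))
  keep[is.na(keep)] <- FALSE
  dropped <- frags[!keep]
  log <- data.frame(
    reason = c("multi_mapped", "low_mapq", "no_uniqueness_evidence"),
    n = c(sum(!is.na(dropped$nhits) & dropped$nhits > 1L),
          sum(is.na(dropped$nhits) & !is.na(dropped$mapq)),
          sum(is.na(dropped$nhits) & is.na(dropped$mapq))))
  out <- frags[keep]
  attr(out, "drop_log") <- log
  out
}

# 5'-most reference base of each fragment: leftmost base on +, rightmost on -.
# Unstranded fragments anchor at their leftmost base.
.five_prime_anchor <- function(frags) {
  minus <- as.logical(BiocGenerics::strand(frags) == "-")
  pos <- ifelse(minus, BiocGenerics::end(frags), BiocGenerics::start(frags))
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(frags),
                         IRanges::IRanges(pos, width = 1L),
                         strand = BiocGenerics::strand(frags))
}

#' Count fragments into catalog regions (one sample)
#'
#' Each uniquely mapped fragment increments exactly one region: the
#' same-strand region containing the fragment's 5'-most reference base. This
#' point rule guarantees that counts are conserved over the disjoint
#' partition (every fragment is assigned exactly once).
#'
#' @param frags Uniqueness-filtered GRanges of fragments.
#' @param catalog A `RegionCatalog`.
#' @return Named integer vector of counts, in catalog region order.
#' @export
count_reads <- function(frags, catalog) {
  regions <- catalog$regions
  chroms <- unique(as.character(GenomeInfoDb::seqnames(frags)))
  bad <- setdiff(chroms, names(catalog$chrom_sizes))
  if (length(bad))
    stop("alignment chromosome '", bad[1], "' absent from catalog")
  anchors <- .five_prime_anchor(frags)
  GenomeInfoDb::seqlevels(anchors) <- GenomeInfoDb::seqlevels(regions)
  hits <- GenomicRanges::findOverlaps(anchors, regions)
  if (length(hits) != length(anchors) ||
      anyDuplicated(S4Vectors::queryHits(hits)))
    stop("internal error: fragment 5' anchor not assigned to exactly one ",
         "same-strand region (incomplete partition?)")
  counts <- tabulate(S4Vectors::subjectHits(hits), nbins = length(regions))
  stats::setNames(as.integer(counts), regions$id)
}

#' Assemble a region-by-sample count matrix from a sample sheet
#'
#' @param sample_sheet data.frame with `sample`, `condition`, `replicate`,
#'   `path` columns; each path is read with [read_alignments()], filtered
#'   with [filter_unique()], and counted with [count_reads()].
#' @param catalog A `RegionCatalog`.
#' @param dialect,policy,mapq_min Passed to the per-sample steps.
#' @return Integer matrix, rows = catalog regions, columns = samples.
#' @export
build_count_matrix <- function(sample_sheet, catalog, dialect = "reverse",
                               policy = "auto", mapq_min = 10L) {
  validate_sample_sheet(sample_sheet)
  if (is.null(sample_sheet$path))
    stop("sample sheet needs a 'path' column to count from alignments")
  cols <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    p <- sample_sheet$path[i]
    if (!file.exists(p)) stop("alignment file missing for sample '",
                              sample_sheet$sample[i], "': ", p)
    fr <- filter_unique(read_alignments(p, dialect = dialect),
                        policy = policy, mapq_min = mapq_min)
    count_reads(fr, catalog)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- sample_sheet$sample
  m
}

#' Fraction of unique fragments antisense to ORFs
#'
#' The numerator counts fragments whose 5' base lies within a protein-coding
#' gene footprint on the opposite strand; non-coding genes are excluded from
#' the numerator by definition.
#'
#' @param frags Uniqueness-filtered fragments (GRanges).
#' @param catalog A `RegionCatalog`.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) when there are no
#'   fragments.
#' @export
antisense_fraction <- function(frags, catalog) {
  if (length(frags) == 0L) {
    warning("no fragments: antisense fraction undefined")
    return(NA_real_)
  }
  coding <- catalog$regions[catalog$regions$role == "coding_gene"]
  anchors <- BiocGenerics::invertStrand(.five_prime_anchor(frags))
  n_anti <- sum(IRanges::overlapsAny(anchors, coding))
  n_anti / length(frags)
}

#' Replicate correlation per condition
#'
#' Pearson correlation of `log2(count + 1)` between the two replicates of
#' each condition, across all regions.
#'
#' @param counts Count matrix (regions x samples).
#' @param sample_sheet Sample sheet data.frame.
#' @return Named numeric vector, one `r` per condition with exactly two
#'   replicates; conditions with fewer than two replicates are skipped with a
#'   warning, degenerate (zero-variance) columns give `NA`.
#' @export
replicate_correlation <- function(counts, sample_sheet) {
  conds <- unique(sample_sheet$condition)
  out <- numeric(0)
  for (cond in conds) {
    ids <- sample_sheet$sample[sample_sheet$condition == cond]
    if (length(ids) < 2L) {
      warning("condition '", cond, "' has <2 replicates; skipped")
      next
    }
    x <- log2(counts[, ids[1]] + 1)
    y <- log2(counts[, ids[2]] + 1)
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
         else stats::cor(x, y)
    if (is.na(r)) warning("constant column in condition '", cond,
                          "': correlation undefined")
    out[cond] <- r
  }
  out
}

#' Write a strand-specific bedGraph coverage track
#'
#' Coverage is the number of unique fragments overlapping each base;
#' intervals are maximal runs of constant non-zero coverage. Minus-strand
#' values may be negated for browser display.
#'
#' @param frags GRanges of fragments (both strands allowed; `strand` picks).
#' @param path Output file.
#' @param strand `"+"` or `"-"`.
#' @param negate Negate values (conventional for minus-strand display).
#' @param name Track name for the header line.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(frags, path, strand = "+", negate = FALSE,
                           name = paste0("coverage_", strand)) {
  fr <- frags[BiocGenerics::strand(frags) == strand]
  fr <- BiocGenerics::sort(fr, ignore.strand = TRUE)
  cov <- GenomicRanges::coverage(fr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  for (chrom in names(cov)) {
    rle <- cov[[chrom]]
    v <- S4Vectors::runValue(rle)
    len <- S4Vectors::runLength(rle)
    ends <- cumsum(len)
    starts <- ends - len  # 0-based starts
    keep <- v > 0
    if (!any(keep)) next
    val <- if (negate) -v[keep] else v[keep]
    writeLines(paste(chrom, starts[keep], ends[keep], val, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()]
#'
#' @param path bedGraph file.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  if (sum(!grepl("^track", lines)) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             value = gr$score)
}
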