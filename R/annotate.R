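#' Partition configuration
#'
#' Parameters controlling how intergenic space is cut into windows.
#'
#' @param window_size Window size in bases. Intergenic blocks longer than this
#'   are demarcated into windows of this size starting at the block's left
#'   edge. Default 500.
#' @param min_window Minimum window length in bases. A trailing remainder
#'   shorter than this is merged into the preceding window rather than kept as
#'   its own (undersized) window. Blocks shorter than `min_window` that form a
#'   single window are kept whole. Default 100.
#' @param include_noncoding_in_genespace If `TRUE` (default) non-coding genes
#'   (tRNA genes, ncRNA genes) are part of the annotated gene space subtracted
#'   from the chromosome before windowing; if `FALSE` only protein-coding
#'   genes are subtracted.
#' @return A list of class `PartitionConfig`.
#' @export
partition_config <- function(window_size = 500L, min_window = 100L,
                             include_noncoding_in_genespace = TRUE) {
  window_size <- as.integer(window_size)
  min_window <- as.integer(min_window)
  stopifnot(min_window > 0L, min_window <= window_size)
  structure(list(window_size = window_size, min_window = min_window,
                 include_noncoding_in_genespace =
                   isTRUE(include_noncoding_in_genespace)),
            class = "PartitionConfig")
}

GENE_ROLES <- c("coding_gene", "noncoding_gene")

#' Read a two-column chromosome-size table
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  if (anyDuplicated(tab$chrom))
    stop("duplicated chromosome in size table: ",
         tab$chrom[duplicated(tab$chrom)][1])
  stats::setNames(tab$length, tab$chrom)
}

# Feature types mapped to catalog roles. tRNA genes are both noncoding genes
# (they occupy gene space) and Pol III sites (tDNA class).
.coding_types <- c("gene", "protein_coding_gene")
.trna_types <- c("tRNA_gene", "tRNA")
.noncoding_types <- c("ncRNA_gene", "noncoding_gene", "snoRNA_gene",
                      "snRNA_gene", "rRNA_gene", "ncRNA")

#' Load genome annotation and the Pol III site registry
#'
#' Parses a GFF3 annotation into stranded gene regions and collects Pol III
#' complex binding sites: tRNA-gene features become sites of class `tDNA`
#' (while also counting as non-coding genes), and entries of an optional BED4
#' file of extra TFIIIC-bound loci become sites whose class is taken from the
#' BED name column (names starting with "ETC" give class `ETC`, otherwise
#' `other_polIII`).
#'
#' Coordinates are converted to the internal 0-based half-open convention at
#' this boundary (GFF3 is 1-based inclusive; BED is consumed natively).
#'
#' @param gff_source Path to a GFF3 file.
#' @param chrom_sizes Named integer vector (see [read_chrom_sizes()]) or path
#'   to a two-column TSV.
#' @param etc_bed_source Optional path to a BED4 file of extra Pol III sites.
#' @return A list with elements `genes` (GRanges with mcols `id`, `role`),
#'   `sites` (GRanges with mcols `id`, `site_class`, `name`) and
#'   `chrom_sizes`.
#' @export
load_annotation <- function(gff_source, chrom_sizes, etc_bed_source = NULL) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  gff <- tryCatch(
    rtracklayer::import.gff3(gff_source),
    error = function(e) stop("malformed GFF3 '", gff_source, "': ",
                             conditionMessage(e), call. = FALSE))
  .check_chroms(as.character(GenomeInfoDb::seqnames(gff)), chrom_sizes,
                gff_source)

  type <- as.character(gff$type)
  keep <- type %in% c(.coding_types, .trna_types, .noncoding_types)
  feats <- gff[keep]
  type <- type[keep]
  ids <- feats$ID
  if (is.null(ids)) ids <- feats$Name
  if (is.null(ids) || anyNA(ids))
    stop("GFF3 gene features must carry an ID attribute")
  role <- ifelse(type %in% .coding_types, "coding_gene", "noncoding_gene")

  genes <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(feats), IRanges::ranges(feats),
    strand = BiocGenerics::strand(feats),
    id = as.character(ids), role = role,
    seqinfo = .seqinfo(chrom_sizes))
  # hold genes 0-based half-open internally via IRanges start-1? IRanges are
  # 1-based closed; we standardise by storing the GFF coordinates as-is in the
  # GRanges (1-based) and exposing 0-based half-open only at text boundaries.
  if (any(BiocGenerics::end(genes) >
          chrom_sizes[as.character(GenomeInfoDb::seqnames(genes))]))
    stop("gene extends past chromosome end: ",
         genes$id[which(BiocGenerics::end(genes) >
           chrom_sizes[as.character(GenomeInfoDb::seqnames(genes))])][1])

  trna <- genes[type %in% .trna_types]
  sites <- GenomicRanges::GRanges(seqinfo = .seqinfo(chrom_sizes))
  if (length(trna)) {
    sites <- GenomicRanges::granges(trna)
    S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
      id = trna$id, site_class = "tDNA", name = trna$id)
  }
  if (!is.null(etc_bed_source)) {
    bed <- rtracklayer::import.bed(etc_bed_source)
    if (length(bed)) {
      .check_chroms(as.character(GenomeInfoDb::seqnames(bed)), chrom_sizes,
                    etc_bed_source)
      nm <- if (is.null(bed$name)) sprintf("site%04d", seq_along(bed))
            else as.character(bed$name)
      cls <- ifelse(grepl("^ETC", nm, ignore.case = TRUE), "ETC",
                    "other_polIII")
      extra <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(bed), IRanges::ranges(bed), strand = "*",
        id = nm, site_class = cls, name = nm,
        seqinfo = .seqinfo(chrom_sizes))
      sites <- c(sites, extra)
    }
  }
  list(genes = genes, sites = sites, chrom_sizes = chrom_sizes)
}

.seqinfo <- function(chrom_sizes) {
  GenomeInfoDb::Seqinfo(names(chrom_sizes),
                        seqlengths = unname(chrom_sizes))
}

.check_chroms <- function(chroms, chrom_sizes, what) {
  bad <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(bad))
    stop("unknown chromosome '", bad[1], "' in ", what,
         " (not in chromosome-size table)", call. = FALSE)
}

#' Partition a genome into gene space and stranded intergenic windows
#'
#' For each chromosome and strand, annotated gene footprints are subtracted
#' from the chromosome and every remaining maximal gap becomes an intergenic
#' block. Blocks longer than `window_size` are demarcated into windows of
#' `window_size` bases anchored at the block's left edge; a trailing remainder
#' of at least `min_window` bases becomes its own window, a shorter remainder
#' is merged into the preceding window. Both strands receive windows over
#' every block because libraries are strand-specific.
#'
#' Overlapping same-strand genes are merged into one composite footprint
#' region (ids joined with `+`) with a warning, so that the resulting catalog
#' is an exact disjoint partition of every chromosome on each strand.
#'
#' @param genes GRanges of genes with mcols `id` and `role` (as produced by
#'   [load_annotation()]).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param config A [partition_config()].
#' @return A `RegionCatalog`: list with `regions` (GRanges with mcols `id`,
#'   `role`, `block_id`, `flank_left_gene`, `flank_right_gene`),
#'   `chrom_sizes`, and `config`.
#' @export
partition_genome <- function(genes, chrom_sizes, config = partition_config()) {
  si <- .seqinfo(chrom_sizes)
  if (!config$include_noncoding_in_genespace)
    genes <- genes[genes$role == "coding_gene"]
  GenomeInfoDb::seqlevels(genes) <- names(chrom_sizes)
  GenomeInfoDb::seqinfo(genes) <- si

  gene_parts <- list(); win_parts <- list()
  for (s in c("+", "-")) {
    g <- genes[BiocGenerics::strand(genes) == s]
    g <- BiocGenerics::sort(g, ignore.strand = TRUE)
    # merge overlapping/adjacent-overlapping same-strand genes into one
    # footprint region so the partition stays disjoint
    red <- GenomicRanges::reduce(g, with.revmap = TRUE, min.gapwidth = 0L)
    rv <- red$revmap
    n_merged <- sum(lengths(rv) > 1L)
    if (n_merged > 0L)
      warning(n_merged, " overlapping same-strand gene cluster(s) on strand ",
              s, " merged into composite footprints", call. = FALSE)
    ids <- vapply(rv, function(i) paste(g$id[i], collapse = "+"), "")
    role <- vapply(rv, function(i)
      if (any(g$role[i] == "coding_gene")) "coding_gene" else "noncoding_gene",
      "")
    foot <- GenomicRanges::granges(red)
    blank <- rep("", length(ids))
    S4Vectors::mcols(foot) <- S4Vectors::DataFrame(
      id = ids, role = role, block_id = blank, flank_left_gene = blank,
      flank_right_gene = blank)
    gene_parts[[s]] <- foot

    # maximal gaps between footprints on this strand
    gaps <- GenomicRanges::gaps(foot)
    gaps <- gaps[BiocGenerics::strand(gaps) == s]
    if (length(gaps) == 0L && length(foot) == 0L) {
      gaps <- GenomicRanges::GRanges(names(chrom_sizes),
        IRanges::IRanges(1L, unname(chrom_sizes)), strand = s, seqinfo = si)
    }
    gaps <- BiocGenerics::sort(gaps, ignore.strand = TRUE)
    if (length(gaps)) {
      # flanking genes: footprint ending at the gap start / starting at its end
      if (length(foot)) {
        fchr <- as.character(GenomeInfoDb::seqnames(foot))
        ends_map <- stats::setNames(foot$id,
          paste0(fchr, ":", BiocGenerics::end(foot)))
        starts_map <- stats::setNames(foot$id,
          paste0(fchr, ":", BiocGenerics::start(foot)))
      } else {
        ends_map <- starts_map <- character(0)
      }
      gchr <- as.character(GenomeInfoDb::seqnames(gaps))
      key_l <- paste0(gchr, ":", BiocGenerics::start(gaps) - 1L)
      key_r <- paste0(gchr, ":", BiocGenerics::end(gaps) + 1L)
      fl <- unname(ends_map[key_l]); fl[is.na(fl)] <- ""
      fr <- unname(starts_map[key_r]); fr[is.na(fr)] <- ""
      sc <- if (s == "+") "p" else "m"
      block_id <- sprintf("%s:%s:b%04d", GenomeInfoDb::seqnames(gaps), sc,
                          seq_along(gaps))
      win_parts[[s]] <- .tile_blocks(gaps, block_id, fl, fr, config, si)
    }
  }
  regions <- c(do.call(c, unname(gene_parts)), do.call(c, unname(win_parts)))
  regions <- BiocGenerics::sort(regions, ignore.strand = TRUE)
  if (anyDuplicated(regions$id))
    stop("duplicated region ids in catalog: ",
         regions$id[duplicated(regions$id)][1])
  structure(list(regions = regions, chrom_sizes = chrom_sizes,
                 config = config),
            class = "RegionCatalog")
}

# Cut gap blocks into windows per the remainder rule.
.tile_blocks <- function(gaps, block_id, fl, fr, config, si) {
  w <- config$window_size; mw <- config$min_window
  out <- vector("list", length(gaps))
  for (i in seq_along(gaps)) {
    L <- BiocGenerics::width(gaps)[i]
    b0 <- BiocGenerics::start(gaps)[i]
    if (L <= w) {
      starts <- b0; ends <- b0 + L - 1L
    } else {
      nw <- L %/% w; r <- L %% w
      starts <- b0 + (seq_len(nw) - 1L) * w
      ends <- starts + w - 1L
      if (r >= mw) {
        starts <- c(starts, b0 + nw * w); ends <- c(ends, b0 + L - 1L)
      } else if (r > 0L) {
        ends[nw] <- ends[nw] + r
      }
    }
    gr <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(gaps)[i], IRanges::IRanges(starts, ends),
      strand = BiocGenerics::strand(gaps)[i], seqinfo = si)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      id = sprintf("%s:w%02d", block_id[i], seq_along(gr)),
      role = "intergenic_window", block_id = block_id[i],
      flank_left_gene = fl[i], flank_right_gene = fr[i])
    out[[i]] <- gr
  }
  do.call(c, out)
}

#' @export
print.RegionCatalog <- function(x, ...) {
  r <- x$regions
  cat("RegionCatalog:", length(r), "regions over",
      length(x$chrom_sizes), "chromosome(s)\n")
  print(table(r$role))
  invisible(x)
}

#' Nearest Pol III site for each region
#'
#' Distance is strand-blind and measured as the gap in bases between closest
#' edges; overlapping or book-ended (adjacent) intervals are at distance 0.
#' Ties are broken by the smaller site start coordinate.
#'
#' @param regions GRanges of query regions (or a `RegionCatalog`).
#' @param sites GRanges of Pol III sites (mcols `id`, `site_class`).
#' @return data.frame with one row per region: `region_id`, `site_id`,
#'   `site_class`, `distance`. With an empty registry `site_id` is `NA` and
#'   `distance` is `Inf`.
#' @export
nearest_polIII_site <- function(regions, sites) {
  if (inherits(regions, "RegionCatalog")) regions <- regions$regions
  rid <- if (!is.null(regions$id)) regions$id else as.character(seq_along(regions))
  if (length(sites) == 0L)
    return(data.frame(region_id = rid, site_id = NA_character_,
                      site_class = NA_character_, distance = Inf,
                      stringsAsFactors = FALSE))
  hits <- GenomicRanges::distanceToNearest(regions, sites, select = "all",
                                           ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  # ties: smaller site start wins
  ord <- order(qh, d, BiocGenerics::start(sites)[sh])
  first <- !duplicated(qh[ord])
  pick <- ord[first]
  res <- data.frame(region_id = rid, site_id = NA_character_,
                    site_class = NA_character_, distance = Inf,
                    stringsAsFactors = FALSE)
  res$site_id[qh[pick]] <- sites$id[sh[pick]]
  res$site_class[qh[pick]] <- sites$site_class[sh[pick]]
  res$distance[qh[pick]] <- d[pick]
  res
}

#' Write a region catalog as BED6 plus a TSV sidecar
#'
#' The BED name column carries the region id (score 0); the sidecar TSV adds
#' role, block and flanking-gene columns.
#'
#' @param catalog A `RegionCatalog`.
#' @param bed_path,tsv_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_catalog <- function(catalog, bed_path, tsv_path) {
  r <- catalog$regions
  out <- GenomicRanges::granges(r)
  out$name <- r$id
  out$score <- 0L
  rtracklayer::export.bed(out, bed_path)
  df <- data.frame(id = r$id,
                   chrom = as.character(GenomeInfoDb::seqnames(r)),
                   start = BiocGenerics::start(r) - 1L,
                   end = BiocGenerics::end(r),
                   strand = as.character(BiocGenerics::strand(r)),
                   role = r$role, block_id = r$block_id,
                   flank_left_gene = r$flank_left_gene,
                   flank_right_gene = r$flank_right_gene)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed_path, tsv_path))
}
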