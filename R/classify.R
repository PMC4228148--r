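#' Classification configuration
#'
#' @param proximity_threshold Maximum strand-blind edge distance (bases) for
#'   a region to count as "proximal" to a Pol III site. Default 500.
#' @param contiguity_gap Maximum gap (bases) tolerated between chained DE
#'   windows, or between a chain and a gene end, for them to count as
#'   contiguous. Default 0 (strict adjacency).
#' @param expression_continuity_ratio Minimum mutant-condition normalized
#'   mean of a chained window relative to the chain maximum; windows below
#'   this break the chain. Default 0.1.
#' @return List of class `ClassifyConfig`.
#' @export
classify_config <- function(proximity_threshold = 500L, contiguity_gap = 0L,
                            expression_continuity_ratio = 0.1) {
  stopifnot(proximity_threshold >= 0, contiguity_gap >= 0,
            expression_continuity_ratio >= 0)
  structure(list(proximity_threshold = as.integer(proximity_threshold),
                 contiguity_gap = as.integer(contiguity_gap),
                 expression_continuity_ratio = expression_continuity_ratio),
            class = "ClassifyConfig")
}

CATEGORY_LEVELS <- c("readthrough", "five_prime_extension",
                     "three_prime_extension", "derepressed_intergenic")

#' Chain significant up-regulated DE intergenic windows
#'
#' Significant up-regulated intergenic windows on the same strand within the
#' same intergenic block, separated by at most `contiguity_gap` bases and
#' passing the expression-continuity ratio (every chained window's
#' mutant-condition normalized mean at least `expression_continuity_ratio`
#' times the chain maximum), are merged into one chain.
#'
#' @param de DE table from [run_de()] (intergenic rows are used).
#' @param catalog A `RegionCatalog`.
#' @param config A [classify_config()].
#' @return data.frame of chains: `chain_id`, `chrom`, `start`, `end` (1-based
#'   closed, as in the catalog GRanges), `strand`, `block_id`, `window_ids`
#'   (comma-separated), `n_windows`, `max_meanB`.
#' @export
chain_de_windows <- function(de, catalog, config = classify_config()) {
  regions <- catalog$regions
  win <- de[de$role == "intergenic_window" & de$significant &
              !is.na(de$direction) & de$direction == "up", , drop = FALSE]
  empty <- data.frame(chain_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), block_id = character(),
                      window_ids = character(), n_windows = integer(),
                      max_meanB = numeric(), stringsAsFactors = FALSE)
  if (nrow(win) == 0L) return(empty)
  idx <- match(win$id, regions$id)
  win$chrom <- as.character(GenomeInfoDb::seqnames(regions))[idx]
  win$start <- BiocGenerics::start(regions)[idx]
  win$end <- BiocGenerics::end(regions)[idx]
  win$strand <- as.character(BiocGenerics::strand(regions))[idx]
  win$block_id <- regions$block_id[idx]
  win <- win[order(win$chrom, win$strand, win$start), , drop = FALSE]

  chains <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chain_id = NA_character_, chrom = cur$chrom[1],
               start = min(cur$start), end = max(cur$end),
               strand = cur$strand[1], block_id = cur$block_id[1],
               window_ids = paste(cur$id, collapse = ","),
               n_windows = nrow(cur), max_meanB = max(cur$meanB),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(win))) {
    w <- win[i, , drop = FALSE]
    if (is.null(cur)) { cur <- w; next }
    same <- w$block_id == cur$block_id[nrow(cur)] &&
      w$strand == cur$strand[1] && w$chrom == cur$chrom[1]
    gap <- w$start - cur$end[nrow(cur)] - 1L
    newmax <- max(c(cur$meanB, w$meanB))
    continuous <- all(c(cur$meanB, w$meanB) >=
                        config$expression_continuity_ratio * newmax)
    if (same && gap <= config$contiguity_gap && continuous) {
      cur <- rbind(cur, w)
    } else {
      chains[[length(chains) + 1L]] <- flush(cur)
      cur <- w
    }
  }
  chains[[length(chains) + 1L]] <- flush(cur)
  out <- do.call(rbind, chains)
  out$chain_id <- sprintf("chain%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, names(empty)]
}

# Block bounds and flank info for one block id.
.block_info <- function(catalog, block_id) {
  w <- catalog$regions[catalog$regions$role == "intergenic_window" &
                         catalog$regions$block_id == block_id]
  list(start = min(BiocGenerics::start(w)), end = max(BiocGenerics::end(w)),
       flank_left = w$flank_left_gene[1], flank_right = w$flank_right_gene[1])
}

#' Classify one DE intergenic chain
#'
#' Encodes the mis-expression geometry as explicit rules with fixed
#' precedence (first match wins):
#' 1. **readthrough** - the chain is contiguous with the 3' end of a
#'    same-strand upstream transcript, its span overlaps a tDNA, and
#'    same-strand expression continues past the tDNA's far edge;
#' 2. **five_prime_extension** - contiguous with the 5' start of a
#'    same-strand downstream gene;
#' 3. **three_prime_extension** - contiguous with the 3' end of a
#'    same-strand upstream gene;
#' 4. **derepressed_intergenic** - everything else.
#'
#' The precedence is needed because a readthrough chain also touches a gene
#' 3' end. A proximity flag and the nearest Pol III site are recorded for
#' every chain.
#'
#' @param chain One row of the [chain_de_windows()] output.
#' @param catalog A `RegionCatalog`.
#' @param sites Pol III site GRanges.
#' @param config A [classify_config()].
#' @return One-row data.frame: chain coordinates, `category`,
#'   `associated_gene`, `nearest_site`, `site_distance`, `proximal`,
#'   `overlapping_tdna`, `ambiguous`.
#' @export
classify_chain <- function(chain, catalog, sites,
                           config = classify_config()) {
  bi <- .block_info(catalog, chain$block_id)
  plus <- chain$strand == "+"
  gapv <- config$contiguity_gap
  touches_left <- (chain$start - bi$start) <= gapv && nzchar(bi$flank_left)
  touches_right <- (bi$end - chain$end) <= gapv && nzchar(bi$flank_right)
  # on + the upstream gene is the left flank (its 3' end at the block start);
  # on - the upstream gene is the right flank
  three_contig <- if (plus) touches_left else touches_right
  five_contig <- if (plus) touches_right else touches_left
  upstream_gene <- if (plus) bi$flank_left else bi$flank_right
  downstream_gene <- if (plus) bi$flank_right else bi$flank_left

  span <- GenomicRanges::GRanges(chain$chrom,
                                 IRanges::IRanges(chain$start, chain$end))
  tdna <- sites[sites$site_class == "tDNA"]
  ov <- IRanges::overlapsAny(tdna, span, ignore.strand = TRUE) &
    as.character(GenomeInfoDb::seqnames(tdna)) == chain$chrom
  overlapping <- tdna[ov]
  past_tdna <- FALSE
  if (length(overlapping)) {
    far <- if (plus) max(BiocGenerics::end(overlapping))
           else min(BiocGenerics::start(overlapping))
    past_tdna <- if (plus) chain$end > far else chain$start < far
  }

  category <- if (three_contig && length(overlapping) && past_tdna) {
    "readthrough"
  } else if (five_contig) {
    "five_prime_extension"
  } else if (three_contig) {
    "three_prime_extension"
  } else {
    "derepressed_intergenic"
  }
  associated <- switch(category,
    readthrough = upstream_gene,
    five_prime_extension = downstream_gene,
    three_prime_extension = upstream_gene,
    derepressed_intergenic = "")

  near <- nearest_polIII_site(span, sites)
  data.frame(chain_id = chain$chain_id, chrom = chain$chrom,
             start = chain$start, end = chain$end, strand = chain$strand,
             block_id = chain$block_id, window_ids = chain$window_ids,
             n_windows = chain$n_windows, category = category,
             associated_gene = associated,
             nearest_site = near$site_id, site_distance = near$distance,
             proximal = is.finite(near$distance) &
               near$distance <= config$proximity_threshold,
             overlapping_tdna = if (length(overlapping))
               paste(overlapping$id, collapse = ",") else "",
             ambiguous = three_contig && five_contig,
             stringsAsFactors = FALSE)
}

#' Chain and classify all up-regulated DE intergenic regions
#'
#' @param de DE table from [run_de()].
#' @param catalog A `RegionCatalog`.
#' @param sites Pol III site GRanges.
#' @param config A [classify_config()].
#' @return data.frame with one classified row per chain (see
#'   [classify_chain()]).
#' @export
classify_regions <- function(de, catalog, sites,
                             config = classify_config()) {
  chains <- chain_de_windows(de, catalog, config)
  if (nrow(chains) == 0L)
    return(data.frame(chain_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), block_id = character(),
                      window_ids = character(), n_windows = integer(),
                      category = character(), associated_gene = character(),
                      nearest_site = character(), site_distance = numeric(),
                      proximal = logical(), overlapping_tdna = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(chains)), function(i)
    classify_chain(chains[i, , drop = FALSE], catalog, sites, config)))
  rownames(out) <- NULL
  out
}

#' Summarize classification and DE-gene site proximity
#'
#' @param classified Output of [classify_regions()].
#' @param de DE table (for gene counts and down-regulated windows).
#' @param catalog A `RegionCatalog`.
#' @param sites Pol III site GRanges.
#' @param config A [classify_config()].
#' @return List of class `CategorySummary`: `category_counts`,
#'   `proximal_counts` (both named by category), `n_de_genes`,
#'   `n_de_genes_site_nearby` (significant genes whose flanking intergenic
#'   block contains a site), `n_de_intergenic_windows`,
#'   `n_up_intergenic_windows`, `n_down_intergenic_windows`.
#' @export
summarize_classification <- function(classified, de, catalog, sites,
                                     config = classify_config()) {
  cat_counts <- table(factor(classified$category, levels = CATEGORY_LEVELS))
  prox <- tapply(classified$proximal,
                 factor(classified$category, levels = CATEGORY_LEVELS), sum)
  prox[is.na(prox)] <- 0L
  genes <- de[de$role %in% GENE_ROLES & de$significant, , drop = FALSE]
  n_nearby <- 0L
  if (nrow(genes)) {
    regions <- catalog$regions
    win <- regions[regions$role == "intergenic_window"]
    for (gid in genes$id) {
      blocks <- unique(win$block_id[win$flank_left_gene == gid |
                                      win$flank_right_gene == gid])
      if (!length(blocks)) next
      bw <- win[win$block_id %in% blocks]
      if (any(IRanges::overlapsAny(sites, bw, ignore.strand = TRUE)))
        n_nearby <- n_nearby + 1L
    }
  }
  ig <- de[de$role == "intergenic_window" & de$significant, , drop = FALSE]
  structure(list(
    category_counts = c(cat_counts),
    proximal_counts = c(prox),
    n_de_genes = nrow(genes),
    n_de_genes_site_nearby = n_nearby,
    n_de_intergenic_windows = nrow(ig),
    n_up_intergenic_windows = sum(ig$direction == "up", na.rm = TRUE),
    n_down_intergenic_windows = sum(ig$direction == "down", na.rm = TRUE)),
    class = "CategorySummary")
}

#' @export
print.CategorySummary <- function(x, ...) {
  cat("DE genes:", x$n_de_genes,
      sprintf("(%d with a Pol III site in a flanking block)\n",
              x$n_de_genes_site_nearby))
  cat("DE intergenic windows:", x$n_de_intergenic_windows,
      sprintf("(%d up, %d down)\n", x$n_up_intergenic_windows,
              x$n_down_intergenic_windows))
  df <- data.frame(category = names(x$category_counts),
                   chains = as.integer(x$category_counts),
                   proximal = as.integer(x$proximal_counts))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write classification and summary tables
#' @param classified Output of [classify_regions()].
#' @param summary A `CategorySummary`.
#' @param class_path,summary_path Output TSV paths.
#' @return Invisibly, the paths.
#' @export
write_classification <- function(classified, summary, class_path,
                                 summary_path) {
  utils::write.table(classified, class_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sm <- data.frame(category = names(summary$category_counts),
                   chains = as.integer(summary$category_counts),
                   proximal = as.integer(summary$proximal_counts))
  extra <- data.frame(
    category = c("de_genes", "de_genes_site_nearby", "de_intergenic_windows",
                 "up_intergenic_windows", "down_intergenic_windows"),
    chains = c(summary$n_de_genes, summary$n_de_genes_site_nearby,
               summary$n_de_intergenic_windows,
               summary$n_up_intergenic_windows,
               summary$n_down_intergenic_windows),
    proximal = NA_integer_)
  utils::write.table(rbind(sm, extra), summary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(class_path, summary_path))
}
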