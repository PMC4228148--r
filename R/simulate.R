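#' Simulation configuration
#'
#' Defines the synthetic study: a compact genome of gene "cassettes" with
#' planted mis-expression events whose geometry mirrors the loci the analysis
#' is built to detect (a tDNA just upstream of a gene for 5'-UTR extensions, a
#' convergent tDNA downstream of a gene for 3'-UTR extensions, a tDNA inside
#' an expressed downstream gap for readthrough, an isolated near-silent
#' window near a tDNA for de-repression, and trans-acting up-regulated genes
#' with no nearby site). Two biological replicates per condition and
#' negative-binomial counts with library-size variation reproduce the
#' statistical structure the analysis assumes.
#'
#' @param seed Integer seed; fixes genome layout, counts and reads.
#' @param n_plain_genes Background genes with no planted effect. Default 150.
#' @param n_events_per_class Planted events per intergenic class
#'   (five_prime_extension, three_prime_extension, readthrough,
#'   derepressed_intergenic). Default 10.
#' @param n_trans_genes Trans-acting up-regulated genes (Gcn4-like effect,
#'   unrelated to Pol III sites). Default 10.
#' @param n_extra_tdnas Standalone tDNAs beyond those used by events.
#' @param n_etc ETC (extra-TFIIIC) sites. Default 10.
#' @param n_chromosomes Number of chromosomes. Default 8.
#' @param replicates Biological replicates per condition. Default 2.
#' @param lib_factors True library-size factors, recycled over the
#'   `2 * replicates` samples. Default `c(0.9, 1.1, 0.85, 1.15)`.
#' @param gene_mu_meanlog,gene_mu_sdlog Log-normal parameters of baseline
#'   gene NB means. Defaults `log(100)` and 1.
#' @param intergenic_mu Baseline NB mean of intergenic windows (near-silent
#'   relative to genes: about 10 reads per 500-bp window at a 40M-read
#'   library depth, two orders of magnitude below typical genes). Default 10.
#' @param tdna_mu Baseline NB mean of tRNA-gene regions. Default 30.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#'   Default 0.1.
#' @param fold Planted fold change for intergenic events. Default 16.
#' @param trans_fold Fold change of trans-acting genes. Default 16.
#' @param read_length Read length for the read-level simulator. Default 100.
#' @return List of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, n_plain_genes = 150L,
                              n_events_per_class = 10L, n_trans_genes = 10L,
                              n_extra_tdnas = 0L, n_etc = 10L,
                              n_chromosomes = 8L, replicates = 2L,
                              lib_factors = c(0.9, 1.1, 0.85, 1.15),
                              gene_mu_meanlog = log(100), gene_mu_sdlog = 1,
                              intergenic_mu = 10, tdna_mu = 30,
                              dispersion = 0.1, fold = 16, trans_fold = 16,
                              read_length = 100L) {
  stopifnot(seed == as.integer(seed), replicates >= 1L, dispersion >= 0,
            fold > 0, intergenic_mu > 0, n_chromosomes >= 1L)
  structure(as.list(environment()), class = "SimulationConfig")
}

# --- cassette builders ------------------------------------------------------
# Coordinates are 0-based half-open, relative to the cassette, in plus
# orientation; .flip_cassette mirrors them for minus-strand placement.
# Element tables: genes(start,end,role), sites(start,end,class),
# truth(start,end,class,gene_slot) where gene_slot indexes the cassette gene
# the event is tied to (NA for none).

.pad <- function() sample(300:900, 1L)

.cassette_plain <- function(cfg, trans = FALSE) {
  p1 <- .pad(); p2 <- .pad()
  glen <- round(min(max(stats::rlnorm(1, log(1500), 0.3), 400), 5000))
  genes <- data.frame(start = p1, end = p1 + glen, role = "coding_gene")
  truth <- if (trans)
    data.frame(start = p1, end = p1 + glen, class = "trans_gene_up",
               gene_slot = 1L)
  else
    data.frame(start = integer(), end = integer(), class = character(),
               gene_slot = integer())
  list(len = p1 + glen + p2, genes = genes,
       sites = data.frame(start = integer(), end = integer(),
                          class = character()),
       truth = truth)
}

.cassette_fpe <- function(cfg) {
  p1 <- 600L; tlen <- 80L; gap <- 700L; glen <- 1500L; p2 <- 600L
  td_end <- p1 + tlen
  gstart <- td_end + gap
  list(len = gstart + glen + p2,
       genes = data.frame(start = gstart, end = gstart + glen,
                          role = "coding_gene"),
       sites = data.frame(start = p1, end = td_end, class = "tDNA"),
       truth = data.frame(start = td_end, end = gstart,
                          class = "five_prime_extension", gene_slot = 1L))
}

.cassette_tpe <- function(cfg) {
  p1 <- 600L; glen <- 1500L; gap <- 550L; tlen <- 80L; p2 <- 700L
  gend <- p1 + glen
  list(len = gend + gap + tlen + p2,
       genes = data.frame(start = p1, end = gend, role = "coding_gene"),
       # convergent tDNA: opposite strand, downstream of the gene 3' end
       sites = data.frame(start = gend + gap, end = gend + gap + tlen,
                          class = "tDNA_opp"),
       truth = data.frame(start = gend, end = gend + 500L,
                          class = "three_prime_extension", gene_slot = 1L))
}

.cassette_rt <- function(cfg) {
  # tDNA just past the upstream gene's terminator; mutant transcription
  # reads through it and continues well beyond its far edge
  p1 <- 600L; glen <- 1500L; reserve <- 1500L; p2 <- 700L
  gend <- p1 + glen
  list(len = gend + reserve + p2,
       genes = data.frame(start = p1, end = gend, role = "coding_gene"),
       sites = data.frame(start = gend + 150L, end = gend + 230L,
                          class = "tDNA_opp"),
       truth = data.frame(start = gend, end = gend + 1000L,
                          class = "readthrough", gene_slot = 1L))
}

.cassette_der <- function(cfg) {
  p1 <- 600L; glen <- 1500L; p2 <- 700L
  gend <- p1 + glen
  list(len = gend + 1500L + p2,
       genes = data.frame(start = p1, end = gend, role = "coding_gene"),
       sites = data.frame(start = gend + 200L, end = gend + 280L,
                          class = "tDNA_opp"),
       # isolated window, one window away from the upstream gene
       truth = data.frame(start = gend + 500L, end = gend + 1000L,
                          class = "derepressed_intergenic", gene_slot = NA))
}

.cassette_tdna <- function(cfg) {
  p1 <- .pad(); p2 <- .pad()
  list(len = p1 + 80L + p2,
       genes = data.frame(start = integer(), end = integer(),
                          role = character()),
       sites = data.frame(start = p1, end = p1 + 80L, class = "tDNA"),
       truth = data.frame(start = integer(), end = integer(),
                          class = character(), gene_slot = integer()))
}

.cassette_etc <- function(cfg) {
  p1 <- .pad(); p2 <- .pad()
  list(len = p1 + 100L + p2,
       genes = data.frame(start = integer(), end = integer(),
                          role = character()),
       sites = data.frame(start = p1, end = p1 + 100L, class = "ETC"),
       truth = data.frame(start = integer(), end = integer(),
                          class = character(), gene_slot = integer()))
}

.flip_cassette <- function(cs) {
  fl <- function(df) {
    if (!nrow(df)) return(df)
    s <- cs$len - df$end; e <- cs$len - df$start
    df$start <- s; df$end <- e
    df[order(df$start), , drop = FALSE]
  }
  cs$genes <- fl(cs$genes); cs$sites <- fl(cs$sites); cs$truth <- fl(cs$truth)
  cs
}

#' Simulate a genome with planted mis-expression geometry
#'
#' @param config A [simulation_config()].
#' @return List of class `SimulatedGenome`: `genes` (GRanges with `id`,
#'   `role`), `sites` (GRanges with `id`, `site_class`, `name`),
#'   `chrom_sizes`, `truth` (data.frame: `event_id`, `class`, `chrom`,
#'   `start`, `end` (1-based closed), `strand`, `gene_id`, `fold`), and
#'   `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  set.seed(config$seed)
  specs <- c(rep("fpe", config$n_events_per_class),
             rep("tpe", config$n_events_per_class),
             rep("rt", config$n_events_per_class),
             rep("der", config$n_events_per_class),
             rep("trans", config$n_trans_genes),
             rep("plain", config$n_plain_genes),
             rep("tdna", config$n_extra_tdnas),
             rep("etc", config$n_etc))
  specs <- sample(specs)
  strands <- sample(c("+", "-"), length(specs), replace = TRUE)
  chrom_of <- rep(seq_len(config$n_chromosomes), length.out = length(specs))

  genes <- list(); sites <- list(); truth <- list()
  offsets <- stats::setNames(rep(0L, config$n_chromosomes),
                             sprintf("chr%02d", seq_len(config$n_chromosomes)))
  gi <- 0L; ti <- 0L; ei <- 0L; evi <- 0L
  for (k in seq_along(specs)) {
    cs <- switch(specs[k],
                 plain = .cassette_plain(config),
                 trans = .cassette_plain(config, trans = TRUE),
                 fpe = .cassette_fpe(config),
                 tpe = .cassette_tpe(config),
                 rt = .cassette_rt(config),
                 der = .cassette_der(config),
                 tdna = .cassette_tdna(config),
                 etc = .cassette_etc(config))
    s <- strands[k]
    if (s == "-") cs <- .flip_cassette(cs)
    chrom <- names(offsets)[chrom_of[k]]
    off <- offsets[[chrom]]

    gene_ids <- character(nrow(cs$genes))
    if (nrow(cs$genes)) {
      for (j in seq_len(nrow(cs$genes))) {
        gi <- gi + 1L
        gene_ids[j] <- sprintf("g%04d", gi)
      }
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = chrom, start = off + cs$genes$start, end = off + cs$genes$end,
        strand = s, id = gene_ids, role = cs$genes$role)
    }
    if (nrow(cs$sites)) {
      for (j in seq_len(nrow(cs$sites))) {
        cls <- cs$sites$class[j]
        site_strand <- if (cls == "tDNA_opp") {
          if (s == "+") "-" else "+"
        } else s
        cls <- sub("_opp$", "", cls)
        id <- if (cls == "tDNA") { ti <- ti + 1L; sprintf("t%04d", ti) }
              else { ei <- ei + 1L; sprintf("ETC%d", ei) }
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = chrom, start = off + cs$sites$start[j],
          end = off + cs$sites$end[j],
          strand = if (cls == "ETC") "*" else site_strand,
          id = id, site_class = cls)
      }
    }
    if (nrow(cs$truth)) {
      for (j in seq_len(nrow(cs$truth))) {
        evi <- evi + 1L
        truth[[length(truth) + 1L]] <- data.frame(
          event_id = sprintf("ev%03d", evi), class = cs$truth$class[j],
          chrom = chrom, start = off + cs$truth$start[j] + 1L,
          end = off + cs$truth$end[j], strand = s,
          gene_id = if (is.na(cs$truth$gene_slot[j])) ""
                    else gene_ids[cs$truth$gene_slot[j]],
          fold = if (cs$truth$class[j] == "trans_gene_up") config$trans_fold
                 else config$fold)
      }
    }
    offsets[[chrom]] <- off + cs$len
  }
  chrom_sizes <- vapply(offsets, function(o) as.integer(o + 500L), 1L)
  si <- .seqinfo(chrom_sizes)

  gdf <- do.call(rbind, genes)
  # tDNAs are genes too (non-coding): they occupy gene space
  sdf <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), id = character(),
               site_class = character())
  tdf <- sdf[sdf$site_class == "tDNA", , drop = FALSE]
  all_genes <- data.frame(chrom = gdf$chrom, start = gdf$start,
                          end = gdf$end, strand = gdf$strand, id = gdf$id,
                          role = gdf$role)
  if (nrow(tdf))
    all_genes <- rbind(all_genes,
      data.frame(chrom = tdf$chrom, start = tdf$start, end = tdf$end,
                 strand = tdf$strand, id = tdf$id, role = "noncoding_gene"))
  genes_gr <- GenomicRanges::GRanges(
    all_genes$chrom, IRanges::IRanges(all_genes$start + 1L, all_genes$end),
    strand = all_genes$strand, id = all_genes$id, role = all_genes$role,
    seqinfo = si)
  genes_gr <- BiocGenerics::sort(genes_gr, ignore.strand = TRUE)
  sites_gr <- GenomicRanges::GRanges(
    sdf$chrom, IRanges::IRanges(sdf$start + 1L, sdf$end),
    strand = sdf$strand, id = sdf$id, site_class = sdf$site_class,
    name = sdf$id, seqinfo = si)
  sites_gr <- BiocGenerics::sort(sites_gr, ignore.strand = TRUE)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(event_id = character(), class = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), gene_id = character(), fold = numeric())
  rownames(truth_df) <- NULL
  structure(list(genes = genes_gr, sites = sites_gr,
                 chrom_sizes = chrom_sizes, truth = truth_df,
                 config = config),
            class = "SimulatedGenome")
}

#' Write a simulated genome as standard files
#'
#' Writes `annotation.gff3` (gene and tRNA_gene features), `etc_sites.bed`
#' (BED4 of ETC sites), `chrom_sizes.tsv` and `truth.tsv` into `dir`; the
#' first three are directly consumable by [load_annotation()].
#'
#' @param sim A `SimulatedGenome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, named character vector of paths.
#' @export
write_simulated_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "annotation.gff3")
  g <- sim$genes
  df <- data.frame(
    seqid = as.character(GenomeInfoDb::seqnames(g)),
    source = "polIIItx_sim",
    type = ifelse(g$id %in% sim$sites$id[sim$sites$site_class == "tDNA"],
                  "tRNA_gene",
                  ifelse(g$role == "coding_gene", "gene", "ncRNA_gene")),
    start = BiocGenerics::start(g), end = BiocGenerics::end(g),
    score = ".", strand = as.character(BiocGenerics::strand(g)),
    phase = ".", attributes = paste0("ID=", g$id))
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = FALSE)
  close(con)
  bed <- file.path(dir, "etc_sites.bed")
  etc <- sim$sites[sim$sites$site_class != "tDNA"]
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(etc)),
               start = BiocGenerics::start(etc) - 1L,
               end = BiocGenerics::end(etc), name = etc$id),
    bed, sep = "\t", quote = FALSE, col.names = FALSE, row.names = FALSE)
  sizes <- file.path(dir, "chrom_sizes.tsv")
  utils::write.table(
    data.frame(chrom = names(sim$chrom_sizes),
               length = unname(sim$chrom_sizes)),
    sizes, sep = "\t", quote = FALSE, col.names = FALSE, row.names = FALSE)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gff = gff, etc_bed = bed, chrom_sizes = sizes, truth = truth))
}

#' Read a truth table written by [write_simulated_genome()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character"))
}

# Per-region baseline NB means and the mutant fold multiplier implied by the
# truth table.
#
# Window selection per event class: 5'-extensions and de-repressions raise
# the windows whose midpoint lies in the truth span (those spans are bounded
# by same-strand features, so they are window-aligned); 3'-extensions and
# readthrough raise the window chain walking distally from the associated
# gene's 3' end (one window for an extension; for readthrough, windows until
# the chain has passed the tDNA well beyond its far edge), because the
# window grid is anchored at the block's left edge and need not align with a
# gene's 3' boundary on the minus strand.
.region_model <- function(sim, catalog) {
  cfg <- sim$config
  regions <- catalog$regions
  q <- numeric(length(regions))
  coding <- regions$role == "coding_gene"
  q[coding] <- stats::rlnorm(sum(coding), cfg$gene_mu_meanlog,
                             cfg$gene_mu_sdlog)
  q[regions$role == "noncoding_gene"] <- cfg$tdna_mu
  q[regions$role == "intergenic_window"] <- cfg$intergenic_mu
  fold <- rep(1, length(regions))
  tr <- sim$truth
  if (nrow(tr)) {
    starts <- BiocGenerics::start(regions)
    ends <- BiocGenerics::end(regions)
    mid <- (starts + ends) / 2
    chrom <- as.character(GenomeInfoDb::seqnames(regions))
    str <- as.character(BiocGenerics::strand(regions))
    is_win <- regions$role == "intergenic_window"
    gid_of <- strsplit(regions$id, "+", fixed = TRUE)
    for (i in seq_len(nrow(tr))) {
      cls <- tr$class[i]
      if (cls == "trans_gene_up") {
        hit <- vapply(gid_of, function(p) tr$gene_id[i] %in% p, TRUE)
      } else if (cls %in% c("three_prime_extension", "readthrough")) {
        hit <- .windows_from_gene_end(regions, starts, ends, chrom, str,
                                      is_win, sim, tr[i, ],
                                      max_extent = if (cls == "readthrough")
                                        730L else 0L)
      } else {
        hit <- is_win & chrom == tr$chrom[i] & str == tr$strand[i] &
          mid >= tr$start[i] & mid <= tr$end[i]
      }
      fold[hit] <- fold[hit] * tr$fold[i]
    }
  }
  list(q = q, fold = fold)
}

# Logical index of the window chain starting at a gene's 3' end and walking
# distally until the chain extent exceeds max_extent (0 = just the adjacent
# window).
.windows_from_gene_end <- function(regions, starts, ends, chrom, str, is_win,
                                   sim, tr, max_extent = 0L) {
  g <- sim$genes[sim$genes$id == tr$gene_id]
  plus <- tr$strand == "+"
  anchor <- if (plus) BiocGenerics::end(g) else BiocGenerics::start(g)
  hit <- rep(FALSE, length(starts))
  cand <- which(is_win & chrom == tr$chrom & str == tr$strand)
  extent <- 0L
  repeat {
    nxt <- if (plus) cand[starts[cand] == anchor + 1L]
           else cand[ends[cand] == anchor - 1L]
    if (length(nxt) != 1L) break
    hit[nxt] <- TRUE
    extent <- extent + (ends[nxt] - starts[nxt] + 1L)
    anchor <- if (plus) ends[nxt] else starts[nxt]
    if (extent > max_extent) break
  }
  hit
}

#' Simulate a count matrix with planted events
#'
#' Inverts the analysis model: counts are drawn
#' `NB(mean = s_j * q_i * fold_i(condition), variance = mu + alpha mu^2)`,
#' with baseline means `q_i` by region role, true library-size factors
#' `s_j`, and the planted fold applied in the mutant condition only.
#'
#' @param sim A `SimulatedGenome`.
#' @param catalog The `RegionCatalog` built from it.
#' @param config Optional [simulation_config()] override (defaults to
#'   `sim$config`).
#' @param lib_factors Optional override of the true library-size factors.
#' @return List of class `SimulatedCounts`: `counts` (matrix), `sample_sheet`,
#'   `q` (baseline means), `fold` (per-region mutant multiplier),
#'   `lib_factors`.
#' @export
simulate_counts <- function(sim, catalog, config = sim$config,
                            lib_factors = NULL) {
  # baseline means are a property of the simulated genome (its own seed);
  # the sampling noise follows the seed of the supplied config
  set.seed(sim$config$seed + 1L)
  model <- .region_model(sim, catalog)
  set.seed(config$seed + 1L)
  R <- config$replicates
  samples <- c(sprintf("wildtype_%d", seq_len(R)),
               sprintf("mutant_%d", seq_len(R)))
  cond <- rep(c("wildtype", "mutant"), each = R)
  sf <- if (is.null(lib_factors)) rep_len(config$lib_factors, 2L * R)
        else rep_len(lib_factors, 2L * R)
  n <- length(model$q)
  draw <- function(mu) {
    if (config$dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    else
      stats::rpois(n, lambda = mu)
  }
  cols <- lapply(seq_along(samples), function(j) {
    mu <- sf[j] * model$q * (if (cond[j] == "mutant") model$fold else 1)
    draw(mu)
  })
  counts <- do.call(cbind, cols)
  storage.mode(counts) <- "integer"
  rownames(counts) <- catalog$regions$id
  colnames(counts) <- samples
  structure(list(counts = counts,
                 sample_sheet = data.frame(sample = samples,
                                           condition = cond,
                                           replicate = rep(seq_len(R), 2L),
                                           stringsAsFactors = FALSE),
                 q = model$q, fold = model$fold, lib_factors = sf),
            class = "SimulatedCounts")
}

#' Simulate stranded alignment records realizing a count matrix
#'
#' Emits, per sample, `read_length`-base stranded alignment records whose
#' per-region totals are exactly the given counts: each record's 5' position
#' is uniform within its region, on the region's strand, so re-counting the
#' records reproduces the matrix exactly.
#'
#' @param counts Count matrix (e.g. `SimulatedCounts$counts`).
#' @param catalog The matching `RegionCatalog`.
#' @param config A [simulation_config()] (seed, read length).
#' @param dir Output directory for one BED6 file per sample.
#' @return Named character vector of BED paths (one per sample).
#' @export
simulate_reads <- function(counts, catalog, config, dir) {
  set.seed(config$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- catalog$regions
  rl <- config$read_length
  chrlen <- catalog$chrom_sizes
  paths <- character(0)
  for (smp in colnames(counts)) {
    k <- counts[, smp]
    idx <- rep.int(seq_along(k), k)
    rs <- BiocGenerics::start(regions)[idx]
    rw <- BiocGenerics::width(regions)[idx]
    chrom <- as.character(GenomeInfoDb::seqnames(regions))[idx]
    strand <- as.character(BiocGenerics::strand(regions))[idx]
    fp <- rs + floor(stats::runif(length(idx)) * rw)
    plus <- strand == "+"
    start <- ifelse(plus, fp, pmax(1L, fp - rl + 1L))
    end <- ifelse(plus, pmin(chrlen[chrom], fp + rl - 1L), fp)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    gr$name <- sprintf("%s_r%06d", smp, seq_along(gr))
    gr$score <- 255L
    path <- file.path(dir, paste0(smp, ".bed"))
    rtracklayer::export.bed(gr, path)
    paths[smp] <- path
  }
  paths
}

#' Evaluate recovery of planted events
#'
#' A planted intergenic event is recovered when a called chain of the same
#' class overlaps its span on the same strand; a trans-acting gene event is
#' recovered when the gene is called significantly up-regulated. Called
#' chains overlapping no planted span count as false positives of their
#' called class.
#'
#' @param classified Output of [classify_regions()].
#' @param de DE table from [run_de()].
#' @param truth Truth table (from a `SimulatedGenome` or [read_truth()]).
#' @return List of class `RecoveryReport`: `per_class` (data.frame with
#'   n_truth, n_called, tp, precision, recall, f1) and `confusion`
#'   (planted class x called class table, with "missed").
#' @export
evaluate_recovery <- function(classified, de, truth) {
  ig_classes <- CATEGORY_LEVELS
  rows <- list(); conf <- list()
  overlap <- function(tr, cl)
    cl$chrom == tr$chrom & cl$strand == tr$strand &
      cl$start <= tr$end & cl$end >= tr$start
  for (cls in ig_classes) {
    tr <- truth[truth$class == cls, , drop = FALSE]
    called <- classified[classified$category == cls, , drop = FALSE]
    tp_truth <- 0L
    for (i in seq_len(nrow(tr)))
      if (nrow(called) && any(overlap(tr[i, ], called)))
        tp_truth <- tp_truth + 1L
    tp_called <- 0L
    for (i in seq_len(nrow(called))) {
      anytr <- truth[truth$class != "trans_gene_up", , drop = FALSE]
      same <- anytr[anytr$class == cls, , drop = FALSE]
      if (nrow(same) && any(overlap_rows(called[i, ], same)))
        tp_called <- tp_called + 1L
    }
    rows[[cls]] <- data.frame(
      class = cls, n_truth = nrow(tr), n_called = nrow(called),
      tp = tp_truth,
      precision = if (nrow(called)) tp_called / nrow(called) else NA_real_,
      recall = if (nrow(tr)) tp_truth / nrow(tr) else NA_real_)
  }
  # trans-acting genes: recovery through the gene-level DE calls
  trg <- truth[truth$class == "trans_gene_up", , drop = FALSE]
  deg <- de[de$role %in% GENE_ROLES & de$significant &
              !is.na(de$direction) & de$direction == "up", , drop = FALSE]
  in_called <- vapply(trg$gene_id, function(g)
    any(vapply(strsplit(deg$id, "+", fixed = TRUE),
               function(p) g %in% p, TRUE)), TRUE)
  tp <- sum(in_called)
  rows[["trans_gene_up"]] <- data.frame(
    class = "trans_gene_up", n_truth = nrow(trg), n_called = nrow(deg),
    tp = tp,
    precision = if (nrow(deg)) tp / nrow(deg) else NA_real_,
    recall = if (nrow(trg)) tp / nrow(trg) else NA_real_)
  per_class <- do.call(rbind, rows)
  per_class$f1 <- with(per_class, ifelse(
    !is.na(precision) & !is.na(recall) & (precision + recall) > 0,
    2 * precision * recall / (precision + recall), NA_real_))
  rownames(per_class) <- NULL

  # confusion: planted class x class of an overlapping called chain
  ig_truth <- truth[truth$class != "trans_gene_up", , drop = FALSE]
  called_cls <- character(nrow(ig_truth))
  for (i in seq_len(nrow(ig_truth))) {
    hit <- classified[overlap(ig_truth[i, ], classified), , drop = FALSE]
    called_cls[i] <- if (nrow(hit)) hit$category[1] else "missed"
  }
  confusion <- table(planted = factor(ig_truth$class, levels = ig_classes),
                     called = factor(called_cls,
                                     levels = c(ig_classes, "missed")))
  structure(list(per_class = per_class, confusion = confusion),
            class = "RecoveryReport")
}

# row-wise overlap of one called chain against a truth table
overlap_rows <- function(cl, tr)
  tr$chrom == cl$chrom & tr$strand == cl$strand &
    tr$start <= cl$end & tr$end >= cl$start

#' @export
print.RecoveryReport <- function(x, ...) {
  cat("Planted-event recovery:\n")
  print(x$per_class, row.names = FALSE)
  cat("\nConfusion (planted x called):\n")
  print(x$confusion)
  invisible(x)
}
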