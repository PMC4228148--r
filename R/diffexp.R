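#' Differential-expression configuration
#'
#' @param padj_cutoff Significance cutoff on the Benjamini-Hochberg adjusted
#'   p-value. Default 0.05.
#' @param pseudocount Pseudocount (in normalized-count units) added to both
#'   condition means when forming fold changes, so de-repression from zero
#'   yields finite values. Default 1.
#' @param dispersion_floor Lower bound on the per-region dispersion used in
#'   the exact test. Default 1e-8.
#' @param scope Which region classes to test: `"both"` (genes and intergenic
#'   windows, each as its own multiple-testing family), `"genes"`, or
#'   `"intergenic"`.
#' @param joint_bh If `TRUE`, adjust genes and intergenic windows as a single
#'   family instead of separately.
#' @return List of class `DEConfig`.
#' @export
de_config <- function(padj_cutoff = 0.05, pseudocount = 1,
                      dispersion_floor = 1e-8,
                      scope = c("both", "genes", "intergenic"),
                      joint_bh = FALSE) {
  stopifnot(padj_cutoff > 0, padj_cutoff < 1, dispersion_floor >= 0)
  structure(list(padj_cutoff = padj_cutoff, pseudocount = pseudocount,
                 dispersion_floor = dispersion_floor,
                 scope = match.arg(scope), joint_bh = isTRUE(joint_bh)),
            class = "DEConfig")
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over regions (with
#' all-positive counts) of the ratio of the sample's count to the region's
#' geometric mean across samples. When no region has all-positive counts, the
#' median for sample j is taken over regions with a positive count in sample
#' j, using the geometric mean over the positive entries of each such region
#' (with a warning).
#'
#' @param counts Count matrix (regions x samples).
#' @return List of class `NormalizationResult` with `size_factors` (named,
#'   all positive) and `log_geo_means` (the reference pseudo-sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (any(ok)) {
    geo <- exp(lg)
    sf <- apply(counts, 2, function(k) stats::median(k[ok] / geo[ok]))
  } else {
    warning("no region with all-positive counts; falling back to per-sample ",
            "positive-count median-of-ratios")
    lgp <- apply(counts, 1, function(k) mean(log(k[k > 0])))
    sf <- apply(counts, 2, function(k) {
      use <- k > 0 & is.finite(lgp)
      if (!any(use)) stop("a sample has no positive counts")
      stats::median(k[use] / exp(lgp[use]))
    })
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated")
  structure(list(size_factors = stats::setNames(sf, colnames(counts)),
                 log_geo_means = lg),
            class = "NormalizationResult")
}

#' Estimate per-region dispersions
#'
#' Method-of-moments empirical dispersion on normalized counts, pooled across
#' within-condition replicates:
#' `alpha_i = max(0, (v_i - mu_i * xi) / mu_i^2)`,
#' with `v_i` the pooled within-condition sample variance of normalized
#' counts, `mu_i` their overall mean and `xi = mean(1/s_j)` the shot-noise
#' scale. A mean-dispersion function `alpha(mu) = a0 + a1/mu` is fitted by
#' unweighted least squares over regions with positive mean, negative fits
#' clipped to the floor. The final dispersion is the maximum of empirical,
#' fitted, and floor (the conservative sharing mode).
#'
#' @param counts Count matrix.
#' @param normalization A `NormalizationResult` (or `NULL` to compute).
#' @param sample_sheet Sample sheet with `sample` and `condition`.
#' @param floor Dispersion floor (default 1e-8).
#' @return List of class `DispersionModel` with `empirical`, `fitted_coef`
#'   (a0, a1), `fitted`, `final`, `floor`.
#' @export
estimate_dispersions <- function(counts, normalization = NULL, sample_sheet,
                                 floor = 1e-8) {
  counts <- as.matrix(counts)
  if (is.null(normalization)) normalization <- size_factors(counts)
  sf <- normalization$size_factors[colnames(counts)]
  conds <- split(seq_len(ncol(counts)), sample_sheet$condition[
    match(colnames(counts), sample_sheet$sample)])
  if (!any(vapply(conds, length, 1L) >= 2L))
    stop("dispersion estimation needs >=2 replicates in some condition")
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  num <- 0; den <- 0
  for (idx in conds) {
    if (length(idx) < 2L) next
    v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    num <- num + v * (length(idx) - 1L)
    den <- den + (length(idx) - 1L)
  }
  v <- num / den
  xi <- mean(1 / sf)
  emp <- ifelse(mu > 0, pmax(0, (v - mu * xi) / mu^2), floor)
  use <- mu > 0
  fit_coef <- c(a0 = NA_real_, a1 = NA_real_)
  fitted_d <- rep(floor, length(mu))
  if (sum(use) >= 2L) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), emp[use])
    fit_coef <- stats::setNames(fit$coefficients, c("a0", "a1"))
    fitted_d <- ifelse(use, pmax(floor, fit_coef[1] + fit_coef[2] / mu),
                       floor)
  }
  final <- pmax(emp, fitted_d, floor)
  structure(list(empirical = emp, fitted_coef = fit_coef, fitted = fitted_d,
                 final = final, floor = floor),
            class = "DispersionModel")
}

# NB pmf with mean mu and variance var (>= mu); Poisson limit when var <= mu.
.dnb_mv <- function(x, mu, var) {
  if (var > mu * (1 + 1e-12)) {
    size <- mu^2 / (var - mu)
    stats::dnbinom(x, mu = mu, size = size)
  } else {
    stats::dpois(x, lambda = mu)
  }
}

#' Conditional negative-binomial exact test for one region
#'
#' Given the summed counts of the two conditions, all splits `(a, K - a)` of
#' the total `K = kA + kB` are enumerated; each condition sum is modelled as
#' negative binomial with mean `sum(s_j) * q` under the pooled null mean
#' `q = K / sum(all s_j)` and variance `sum(s_j q + alpha (s_j q)^2)`. The
#' p-value is the probability, conditional on the total, of all splits at
#' most as probable as the observed one. Dispersion 0 is the Poisson limit.
#' For very large totals the enumeration is pruned outward from the mode
#' until the neglected tail mass is below 1e-12 of the conditional total.
#'
#' @param kA,kB Summed counts in conditions A and B.
#' @param size_factors_a,size_factors_b Per-sample size factors of each
#'   condition.
#' @param dispersion Per-region NB dispersion (alpha >= 0).
#' @param prune_above Totals above this are pruned rather than fully
#'   enumerated (default 10000).
#' @return p-value in `[0, 1]`; `K = 0` returns 1 by convention.
#' @export
nb_exact_test <- function(kA, kB, size_factors_a, size_factors_b,
                          dispersion, prune_above = 10000L) {
  K <- kA + kB
  if (K == 0) return(1)
  sA <- sum(size_factors_a); sB <- sum(size_factors_b)
  q <- K / (sA + sB)
  muA <- sA * q; muB <- sB * q
  varA <- muA + dispersion * q^2 * sum(size_factors_a^2)
  varB <- muB + dispersion * q^2 * sum(size_factors_b^2)
  p_obs <- .dnb_mv(kA, muA, varA) * .dnb_mv(kB, muB, varB)
  if (K <= prune_above) {
    a <- 0:K
    pa <- .dnb_mv(a, muA, varA) * .dnb_mv(K - a, muB, varB)
    tot <- sum(pa)
    if (tot == 0) return(1)
    return(min(1, sum(pa[pa <= p_obs * (1 + 1e-7)]) / tot))
  }
  # prune outward from the mode in blocks; the conditional pmf is unimodal so
  # once a block's mass is negligible the remaining tail is too
  mode <- round(K * sA / (sA + sB))
  block <- 1024L
  tot <- 0; num <- 0
  lo <- mode; hi <- mode  # lo block includes the mode; hi blocks start above
  repeat {
    added <- 0
    if (lo >= 0L) {
      a <- max(0L, lo - block + 1L):lo
      pa <- .dnb_mv(a, muA, varA) * .dnb_mv(K - a, muB, varB)
      tot <- tot + sum(pa); num <- num + sum(pa[pa <= p_obs * (1 + 1e-7)])
      added <- added + sum(pa)
      lo <- max(0L, lo - block + 1L) - 1L
    }
    if (hi < K) {
      a <- (hi + 1L):min(K, hi + block)
      pa <- .dnb_mv(a, muA, varA) * .dnb_mv(K - a, muB, varB)
      tot <- tot + sum(pa); num <- num + sum(pa[pa <= p_obs * (1 + 1e-7)])
      added <- added + sum(pa)
      hi <- min(K, hi + block)
    }
    if ((lo < 0L && hi >= K) || (tot > 0 && added < 1e-12 * tot)) break
  }
  if (tot == 0) return(1)
  min(1, num / tot)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; missing values are excluded from
#' the family and returned as `NA`.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Vector of adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# Core two-condition DE on a plain count matrix; regions are rows.
# Returns the per-region table without multiple-testing adjustment scoping.
#' Two-condition differential expression table for a count matrix
#'
#' Lower-level worker behind [run_de()]: median-of-ratios normalization,
#' dispersion estimation, one conditional NB exact test per region, BH
#' adjustment over the supplied rows as one family.
#'
#' @param counts Count matrix (regions x samples).
#' @param sample_sheet Sample sheet; the first condition in order of
#'   appearance is the reference (condition A, e.g. wildtype).
#' @param config A [de_config()].
#' @param normalization Optional precomputed `NormalizationResult` (so genes
#'   and intergenic windows can share library size factors).
#' @return data.frame with id, baseMean, meanA, meanB, foldChange, log2FC,
#'   pval, padj, significant, direction.
#' @export
de_table <- function(counts, sample_sheet, config = de_config(),
                     normalization = NULL) {
  counts <- as.matrix(counts)
  conds <- unique(sample_sheet$condition)
  if (length(conds) != 2L)
    stop("exactly two conditions required, got: ",
         paste(conds, collapse = ", "))
  a_ids <- sample_sheet$sample[sample_sheet$condition == conds[1]]
  b_ids <- sample_sheet$sample[sample_sheet$condition == conds[2]]
  if (is.null(normalization)) normalization <- size_factors(counts)
  sf <- normalization$size_factors[colnames(counts)]
  disp <- estimate_dispersions(counts, normalization, sample_sheet,
                               floor = config$dispersion_floor)
  norm <- sweep(counts, 2, sf, "/")
  meanA <- rowMeans(norm[, a_ids, drop = FALSE])
  meanB <- rowMeans(norm[, b_ids, drop = FALSE])
  baseMean <- rowMeans(norm)
  kA <- as.integer(round(rowSums(counts[, a_ids, drop = FALSE])))
  kB <- as.integer(round(rowSums(counts[, b_ids, drop = FALSE])))
  sfa <- sf[a_ids]; sfb <- sf[b_ids]
  pval <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_test(kA[i], kB[i], sfa, sfb, disp$final[i]), numeric(1))
  padj <- bh_adjust(pval)
  c0 <- config$pseudocount
  fc <- ifelse(baseMean > 0, (meanB + c0) / (meanA + c0), NA_real_)
  data.frame(
    id = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
         else rownames(counts),
    baseMean = baseMean, meanA = meanA, meanB = meanB,
    foldChange = fc, log2FC = log2(fc), pval = pval, padj = padj,
    significant = !is.na(padj) & padj < config$padj_cutoff,
    direction = ifelse(baseMean == 0, NA_character_,
                       ifelse(meanB >= meanA, "up", "down")),
    dispersion = disp$final,
    stringsAsFactors = FALSE)
}

#' Run differential expression over a region catalog
#'
#' Genes (coding and non-coding) and intergenic windows are tested as
#' separate multiple-testing families (mirroring an analysis run on coding
#' sequence and intergenic regions separately); library size factors are
#' estimated once from the full matrix. Scope and a joint-family mode are
#' configurable.
#'
#' @param counts Count matrix whose rows match `catalog$regions$id`.
#' @param sample_sheet Sample sheet (first condition = reference).
#' @param catalog A `RegionCatalog`.
#' @param config A [de_config()].
#' @return data.frame in catalog order with a `role` and `scope` column added
#'   to the [de_table()] columns.
#' @export
run_de <- function(counts, sample_sheet, catalog, config = de_config()) {
  counts <- as.matrix(counts)
  regions <- catalog$regions
  if (!identical(rownames(counts), regions$id)) {
    if (is.null(rownames(counts)) || !all(regions$id %in% rownames(counts)))
      stop("count matrix rows do not match the region catalog")
    counts <- counts[regions$id, , drop = FALSE]
  }
  normalization <- size_factors(counts)
  scope_of <- ifelse(regions$role == "intergenic_window", "intergenic",
                     "genes")
  scopes <- switch(config$scope, both = c("genes", "intergenic"),
                   genes = "genes", intergenic = "intergenic")
  if (config$joint_bh) {
    sub <- scope_of %in% scopes
    res <- de_table(counts[sub, , drop = FALSE], sample_sheet, config,
                    normalization)
    res$role <- regions$role[sub]
    res$scope <- scope_of[sub]
  } else {
    parts <- lapply(scopes, function(sc) {
      sub <- scope_of == sc
      r <- de_table(counts[sub, , drop = FALSE], sample_sheet, config,
                    normalization)
      r$role <- regions$role[sub]
      r$scope <- sc
      r
    })
    res <- do.call(rbind, parts)
  }
  res <- res[match(regions$id[regions$id %in% res$id], res$id), ]
  rownames(res) <- NULL
  res
}

#' Write a DE result table as TSV
#' @param de data.frame from [run_de()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DE result table written by [write_de_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
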