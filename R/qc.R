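#' Remove SNPs with too many missing genotypes
#'
#' A SNP is removed when its missing fraction is strictly greater than
#' `max_rate` (a SNP missing in exactly `max_rate` of samples is kept).
#'
#' @param m a [genotype_matrix()].
#' @param max_rate maximum tolerated per-SNP missing fraction (default 0.05).
#' @return list with elements `matrix` (filtered [genotype_matrix()]) and
#'   `report` (removed count, ids and threshold).
#' @export
filter_snp_missingness <- function(m, max_rate = 0.05) {
  stopifnot(max_rate >= 0, max_rate <= 1)
  rate <- colMeans(is.na(m$dosage))
  drop <- rate > max_rate
  list(matrix = subset_genotypes(m, variants = !drop),
       report = list(step = "snp_missingness", threshold = max_rate,
                     n_removed = sum(drop), removed = m$variants$id[drop]))
}

#' Remove SNPs with low minor allele frequency
#'
#' MAF is computed on non-missing alleles. A SNP is removed when its MAF is
#' strictly below `min_maf`; a SNP at exactly `min_maf` is kept. SNPs with no
#' observed genotypes are removed with a warning.
#'
#' @param m a [genotype_matrix()].
#' @param min_maf minimum tolerated minor allele frequency (default 0.01).
#' @inherit filter_snp_missingness return
#' @export
filter_maf <- function(m, min_maf = 0.01) {
  maf <- minor_allele_frequency(m)
  allmiss <- is.nan(maf)
  if (any(allmiss))
    warning(sum(allmiss), " SNP(s) with all genotypes missing removed")
  drop <- allmiss | maf < min_maf
  list(matrix = subset_genotypes(m, variants = !drop),
       report = list(step = "maf", threshold = min_maf,
                     n_removed = sum(drop), removed = m$variants$id[drop]))
}

#' Remove samples with too many missing genotypes
#'
#' A sample is removed when its missing fraction across SNPs is strictly
#' greater than `max_rate`.
#'
#' @param m a [genotype_matrix()].
#' @param max_rate maximum tolerated per-sample missing fraction (default 0.1).
#' @inherit filter_snp_missingness return
#' @export
filter_sample_missingness <- function(m, max_rate = 0.1) {
  stopifnot(max_rate >= 0, max_rate <= 1)
  rate <- rowMeans(is.na(m$dosage))
  drop <- rate > max_rate
  list(matrix = subset_genotypes(m, samples = !drop),
       report = list(step = "sample_missingness", threshold = max_rate,
                     n_removed = sum(drop), removed = m$samples$sample_id[drop]))
}

#' Prune SNPs in high linkage disequilibrium
#'
#' Greedy within-chromosome scan in position order: a SNP is dropped when its
#' squared Pearson correlation (over samples non-missing at both SNPs)
#' with any previously retained SNP among the last `window_snps - 1` retained
#' SNPs exceeds `r2_max`; of an offending pair, the later variant by position
#' is the one removed. This guarantees that no pair within any window of
#' `window_snps` consecutive retained SNPs exceeds `r2_max`. Zero-variance
#' pairs have r^2 defined as 0.
#'
#' @param m a [genotype_matrix()]; variants need not be pre-sorted.
#' @param window_snps window size in SNP count (default 1500).
#' @param step_snps nominal scan step, retained for interface compatibility
#'   with the usual windowed pruners; the scan here advances one SNP at a
#'   time, which is strictly more conservative.
#' @param r2_max maximum tolerated squared correlation (default 0.2).
#' @inherit filter_snp_missingness return
#' @export
ld_prune <- function(m, window_snps = 1500, step_snps = 150, r2_max = 0.2) {
  v <- m$variants
  ord <- order(v$chrom, v$pos)
  keep <- logical(ncol(m$dosage))
  for (chr in unique(v$chrom[ord])) {
    idx <- ord[v$chrom[ord] == chr]
    kept <- integer(0)
    X <- m$dosage[, idx, drop = FALSE]
    storage.mode(X) <- "double"
    for (k in seq_along(idx)) {
      win <- kept[max(1L, length(kept) - window_snps + 2L):length(kept)]
      if (length(kept) == 0L) win <- integer(0)
      if (length(win)) {
        r <- suppressWarnings(
          stats::cor(X[, k], X[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0  # zero variance or no shared calls
        if (any(r^2 > r2_max)) next
      }
      kept <- c(kept, k)
      keep[idx[k]] <- TRUE
    }
  }
  list(matrix = subset_genotypes(m, variants = keep),
       report = list(step = "ld_prune",
                     threshold = r2_max, window_snps = window_snps,
                     step_snps = step_snps,
                     n_removed = sum(!keep), removed = v$id[!keep]))
}

#' Impute missing genotypes by the per-SNP modal dosage
#'
#' The mode is the most frequent observed dosage of the SNP; ties are broken
#' toward the lowest dosage code so that imputation is deterministic. When a
#' stored mode table is supplied (prediction time), it overrides
#' recomputation. Non-missing cells are never altered.
#'
#' @param m a [genotype_matrix()].
#' @param modes optional named integer vector of per-SNP modes (names are
#'   SNP ids), as returned by a previous call.
#' @return list with `matrix` (fully imputed [genotype_matrix()]) and `modes`
#'   (named integer vector reusable on new samples).
#' @export
impute_mode <- function(m, modes = NULL) {
  dos <- m$dosage
  if (is.null(modes)) {
    modes <- apply(dos, 2, function(x) {
      tab <- tabulate(x + 1L, nbins = 3L)
      if (sum(tab) == 0L) return(NA_integer_)
      which.max(tab) - 1L  # which.max takes the first (lowest) on ties
    })
    modes <- as.integer(modes)
    names(modes) <- m$variants$id
  } else {
    i <- match(m$variants$id, names(modes))
    if (anyNA(i)) stop("stored modes missing for ",
                       sum(is.na(i)), " SNP(s)")
    modes <- as.integer(modes[i])
    names(modes) <- m$variants$id
  }
  allmiss <- is.na(modes)
  if (any(allmiss))
    stop("SNP(s) entirely missing and no stored mode: ",
         paste(utils::head(m$variants$id[allmiss], 5), collapse = ", "))
  miss <- which(is.na(dos))
  if (length(miss)) {
    cols <- (miss - 1L) %/% nrow(dos) + 1L
    dos[miss] <- modes[cols]
  }
  out <- m
  out$dosage <- dos
  list(matrix = out, modes = modes)
}

#' Pairwise KING-robust kinship coefficients
#'
#' For samples i and j, over SNPs non-missing in both:
#' \deqn{\hat\phi_{ij} = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where \eqn{N_{Aa,Aa}} counts SNPs heterozygous in both, \eqn{N_{AA,aa}}
#' counts opposite homozygotes, and \eqn{N_{Aa}(\cdot)} counts heterozygous
#' SNPs of each sample. The estimator is robust to population structure.
#' Monozygotic twins/duplicates give 0.5, full sibs about 0.25.
#'
#' @param m a [genotype_matrix()]; missing genotypes are tolerated.
#' @return data.frame with columns `id1`, `id2`, `n_snps` (shared non-missing
#'   count) and `kinship` (`NA` when a pair shares no heterozygous SNP).
#' @export
estimate_kinship <- function(m) {
  M <- !is.na(m$dosage)
  het <- m$dosage == 1L & M
  hom0 <- m$dosage == 0L & M
  hom2 <- m$dosage == 2L & M
  mode(M) <- "double"; mode(het) <- "double"
  mode(hom0) <- "double"; mode(hom2) <- "double"
  n_hethet <- het %*% t(het)
  n_opp <- hom0 %*% t(hom2) + hom2 %*% t(hom0)
  het_shared <- het %*% t(M)  # SNPs het in i and observed in j
  denom <- het_shared + t(het_shared)
  shared <- M %*% t(M)
  phi <- (n_hethet - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  ids <- m$samples$sample_id
  pr <- which(upper.tri(phi), arr.ind = TRUE)
  data.frame(id1 = ids[pr[, 1]], id2 = ids[pr[, 2]],
             n_snps = shared[pr], kinship = phi[pr],
             stringsAsFactors = FALSE)
}

#' Remove related samples
#'
#' Greedily removes samples until no retained pair has kinship at or above
#' `threshold` (default 0.0884, the usual 3rd-degree cutoff). At each step the
#' sample involved in the most offending pairs is removed; ties are broken
#' toward the sample with higher missingness, then toward later input order.
#'
#' @param m a [genotype_matrix()].
#' @param threshold kinship cutoff (default 0.0884).
#' @param kinship optional precomputed table from [estimate_kinship()].
#' @inherit filter_snp_missingness return
#' @export
remove_related <- function(m, threshold = 0.0884, kinship = NULL) {
  if (is.null(kinship)) kinship <- estimate_kinship(m)
  miss_rate <- rowMeans(is.na(m$dosage))
  names(miss_rate) <- m$samples$sample_id
  order_idx <- stats::setNames(seq_len(nrow(m$samples)), m$samples$sample_id)
  off <- kinship[!is.na(kinship$kinship) & kinship$kinship >= threshold, , drop = FALSE]
  removed <- character(0)
  while (nrow(off)) {
    cnt <- table(c(off$id1, off$id2))
    cand <- names(cnt)[cnt == max(cnt)]
    if (length(cand) > 1) {
      mr <- miss_rate[cand]
      cand <- cand[mr == max(mr)]
      if (length(cand) > 1) cand <- cand[which.max(order_idx[cand])]
    }
    removed <- c(removed, cand)
    off <- off[off$id1 != cand & off$id2 != cand, , drop = FALSE]
  }
  keep <- !(m$samples$sample_id %in% removed)
  list(matrix = subset_genotypes(m, samples = keep),
       report = list(step = "relatedness", threshold = threshold,
                     n_removed = length(removed), removed = removed))
}

#' Run the standard genotype QC pipeline
#'
#' Applies, in order: per-SNP missingness filter, MAF filter, per-sample
#' missingness filter, LD pruning, and (optionally) relatedness removal.
#'
#' @param m a [genotype_matrix()].
#' @param geno,maf,mind thresholds of the three marginal filters.
#' @param window_snps,step_snps,r2 LD-pruning parameters ([ld_prune()]).
#' @param kinship_threshold kinship cutoff, or `NULL` to skip relatedness
#'   removal (useful when the matrix has no near relatives by construction).
#' @return list with `matrix` (the QC'd [genotype_matrix()]) and `report`
#'   (a `qc_report` summarizing each step).
#' @export
qc_pipeline <- function(m, geno = 0.05, maf = 0.01, mind = 0.1,
                        window_snps = 1500, step_snps = 150, r2 = 0.2,
                        kinship_threshold = 0.0884) {
  steps <- list()
  s <- filter_snp_missingness(m, geno); steps$geno <- s$report
  s <- filter_maf(s$matrix, maf); steps$maf <- s$report
  s <- filter_sample_missingness(s$matrix, mind); steps$mind <- s$report
  s <- ld_prune(s$matrix, window_snps, step_snps, r2); steps$ld <- s$report
  if (!is.null(kinship_threshold)) {
    s <- remove_related(s$matrix, kinship_threshold)
    steps$kinship <- s$report
  }
  rep <- structure(list(
    n_snps_removed_geno = steps$geno$n_removed,
    n_snps_removed_maf = steps$maf$n_removed,
    n_samples_removed_mind = steps$mind$n_removed,
    n_snps_removed_ld = steps$ld$n_removed,
    n_samples_removed_kinship = if (is.null(kinship_threshold)) 0L else steps$kinship$n_removed,
    thresholds = list(geno = geno, maf = maf, mind = mind,
                      ld = c(window_snps = window_snps, step_snps = step_snps, r2 = r2),
                      kinship = kinship_threshold),
    steps = steps), class = "qc_report")
  list(matrix = s$matrix, report = rep)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  SNPs removed  - missingness:", x$n_snps_removed_geno,
      "| MAF:", x$n_snps_removed_maf, "| LD:", x$n_snps_removed_ld, "\n")
  cat("  samples removed - missingness:", x$n_samples_removed_mind,
      "| relatedness:", x$n_samples_removed_kinship, "\n")
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [qc_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
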