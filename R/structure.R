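#' PCA of a genotype matrix with iterative outlier removal
#'
#' Each SNP is standardized by its estimated allele frequency: centred at
#' \eqn{2\hat p} and scaled by \eqn{\sqrt{2\hat p(1-\hat p)}} (the usual
#' genotype-PCA normalization). Up to `n_iterations` rounds, samples whose
#' absolute score on any of the computed components exceeds `sigma` standard
#' deviations of that component are removed and the PCA is recomputed; the
#' loop stops early when no outlier is found. Zero-variance SNPs are dropped
#' with a warning.
#'
#' @param m an imputed [genotype_matrix()] (no missing cells).
#' @param n_components number of principal components (default 3).
#' @param n_iterations maximum outlier-removal rounds (default 3).
#' @param sigma outlier threshold in component standard deviations
#'   (default 6).
#' @return An object of class `pca_result`: `scores` (retained samples x
#'   components), `eigenvalues`, `removed_outliers` (list of sample-id
#'   vectors, one per iteration), `center`/`scale` (per-SNP standardization
#'   of the final fit), and `samples` (retained metadata).
#' @export
pca_with_outlier_removal <- function(m, n_components = 3, n_iterations = 3,
                                     sigma = 6.0) {
  if (anyNA(m$dosage)) stop("matrix must be imputed before PCA")
  dos <- m$dosage
  storage.mode(dos) <- "double"
  keep <- seq_len(nrow(dos))
  removed <- list()
  fit_once <- function(rows) {
    X <- dos[rows, , drop = FALSE]
    p <- colMeans(X) / 2
    ok <- p > 0 & p < 1
    if (!all(ok)) warning(sum(!ok), " zero-variance SNP(s) dropped from PCA")
    if (sum(ok) < n_components)
      stop("fewer non-degenerate SNPs than components")
    X <- sweep(X[, ok, drop = FALSE], 2, 2 * p[ok])
    X <- sweep(X, 2, sqrt(2 * p[ok] * (1 - p[ok])), "/")
    G <- tcrossprod(X) / ncol(X)
    e <- eigen(G, symmetric = TRUE)
    k <- n_components
    scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    # deterministic sign: largest-magnitude loading positive
    for (j in seq_len(k)) {
      i0 <- which.max(abs(scores[, j]))
      if (scores[i0, j] < 0) scores[, j] <- -scores[, j]
    }
    colnames(scores) <- paste0("PC", seq_len(k))
    rownames(scores) <- m$samples$sample_id[rows]
    list(scores = scores, values = e$values[seq_len(k)],
         center = 2 * p[ok], scale = sqrt(2 * p[ok] * (1 - p[ok])),
         snps = m$variants$id[ok])
  }
  fit <- fit_once(keep)
  for (it in seq_len(n_iterations)) {
    sds <- apply(fit$scores, 2, stats::sd)
    out <- rowSums(abs(fit$scores) > sigma * rep(sds, each = nrow(fit$scores))) > 0
    if (!any(out)) break
    removed[[length(removed) + 1]] <- rownames(fit$scores)[out]
    keep <- keep[!out]
    if (length(keep) == 0) stop("all samples removed as outliers")
    fit <- fit_once(keep)
  }
  structure(list(scores = fit$scores, eigenvalues = fit$values,
                 removed_outliers = removed,
                 center = stats::setNames(fit$center, fit$snps),
                 scale = stats::setNames(fit$scale, fit$snps),
                 samples = m$samples[keep, , drop = FALSE]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples x", ncol(x$scores),
      "components;", length(unlist(x$removed_outliers)),
      "outlier(s) removed in", length(x$removed_outliers), "iteration(s)\n")
  invisible(x)
}

#' Per-population mean principal-component coordinates
#'
#' @param pca a [pca_with_outlier_removal()] result.
#' @return data.frame: `population`, `n_samples`, and one column per
#'   component holding the arithmetic mean score of member samples.
#' @export
population_mean_pcs <- function(pca) {
  pop <- pca$samples$population
  agg <- stats::aggregate(pca$scores, by = list(population = pop), FUN = mean)
  n <- as.vector(table(pop)[agg$population])
  cbind(agg[, "population", drop = FALSE], n_samples = n,
        agg[, -1, drop = FALSE])
}

#' Cluster population centroids into ancestry groups by K-means
#'
#' Standard K-means (10 random restarts under a fixed seed) on population
#' mean-PC coordinates; group size is the summed sample count of member
#' populations.
#'
#' @param centroids data.frame from [population_mean_pcs()].
#' @param k number of clusters (default 30); must not exceed the number of
#'   populations.
#' @param seed integer seed.
#' @return An object of class `group_assignment`: `assignment` (data.frame
#'   `population`, `group`, `n_samples`), `group_sizes`, `group_centroids`
#'   (group x PC matrix), `dropped` (empty here; filled by
#'   [rebalance_groups()]), and `log`.
#' @export
kmeans_group <- function(centroids, k = 30, seed = 1L) {
  pcs <- as.matrix(centroids[, grep("^PC", names(centroids)), drop = FALSE])
  if (k > nrow(pcs)) stop("k exceeds the number of populations")
  set.seed(seed)
  if (k == nrow(pcs)) {
    cluster <- seq_len(k)  # every population its own group
  } else {
    cluster <- stats::kmeans(pcs, centers = k, nstart = 10,
                             iter.max = 100)$cluster
  }
  grp <- sprintf("EGG%02d", cluster)
  new_group_assignment(
    data.frame(population = centroids$population, group = grp,
               n_samples = centroids$n_samples, stringsAsFactors = FALSE),
    pcs)
}

new_group_assignment <- function(assignment, pcs, dropped = NULL, log = character()) {
  sizes <- tapply(assignment$n_samples, assignment$group, sum)
  cent <- do.call(rbind, lapply(split(seq_len(nrow(assignment)), assignment$group),
                                function(i) colMeans(pcs[i, , drop = FALSE])))
  structure(list(assignment = assignment,
                 group_sizes = sizes[rownames(cent)],
                 group_centroids = cent,
                 population_pcs = pcs,
                 dropped = if (is.null(dropped))
                   data.frame(population = character(), n_samples = integer())
                 else dropped,
                 log = log),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment: ", length(x$group_sizes), " groups over ",
      nrow(x$assignment), " populations (sizes ",
      min(x$group_sizes), "-", max(x$group_sizes), ")\n", sep = "")
  if (nrow(x$dropped))
    cat("  dropped populations:", nrow(x$dropped),
        "(", sum(x$dropped$n_samples), "samples )\n")
  invisible(x)
}

#' Rebalance ancestry groups to a target size range
#'
#' Iteratively enforces `min_size <= group size <= max_size` (sizes in
#' samples): an undersized group is merged into the group with the nearest
#' centroid in PC space provided the merged size stays within `max_size`;
#' an undersized group with no feasible merge is dropped (its populations
#' and sample count recorded); an oversized group with at least two
#' populations is split by 2-means on its population centroids. Every merge,
#' split and drop is recorded in `log` so the result can be reviewed. Stops
#' after `max_iter` rounds, flagging any still-unresolved group.
#'
#' @param g a `group_assignment` from [kmeans_group()].
#' @param min_size,max_size group size bounds in samples (defaults 25, 150).
#' @param seed seed for the 2-means splits.
#' @param max_iter safety bound on rebalancing rounds (default 50).
#' @return A rebalanced `group_assignment`.
#' @export
rebalance_groups <- function(g, min_size = 25, max_size = 150, seed = 1L,
                             max_iter = 50) {
  asg <- g$assignment
  pcs <- g$population_pcs
  dropped <- g$dropped
  log <- g$log
  set.seed(seed)
  split_counter <- 0L
  for (iter in seq_len(max_iter)) {
    sizes <- tapply(asg$n_samples, asg$group, sum)
    cents <- do.call(rbind, lapply(split(seq_len(nrow(asg)), asg$group),
                                   function(i) colMeans(pcs[i, , drop = FALSE])))
    over <- names(sizes)[sizes > max_size]
    over <- over[vapply(over, function(gr) sum(asg$group == gr) > 1, TRUE)]
    if (length(over)) {
      gr <- over[which.max(sizes[over])]
      i <- which(asg$group == gr)
      km <- stats::kmeans(pcs[i, , drop = FALSE], centers = 2, nstart = 10)
      split_counter <- split_counter + 1L
      new_names <- sprintf("%s.%d%s", gr, split_counter, c("a", "b"))
      asg$group[i] <- new_names[km$cluster]
      log <- c(log, sprintf("split %s (%d samples) -> %s + %s", gr, sizes[gr],
                            new_names[1], new_names[2]))
      next
    }
    under <- names(sizes)[sizes < min_size]
    if (length(under)) {
      gr <- under[which.min(sizes[under])]
      others <- setdiff(names(sizes), gr)
      d <- sqrt(colSums((t(cents[others, , drop = FALSE]) - cents[gr, ])^2))
      feasible <- others[sizes[others] + sizes[gr] <= max_size]
      if (length(feasible)) {
        tgt <- feasible[which.min(d[match(feasible, others)])]
        asg$group[asg$group == gr] <- tgt
        log <- c(log, sprintf("merge %s (%d) into %s (%d)", gr, sizes[gr],
                              tgt, sizes[tgt]))
      } else {
        i <- which(asg$group == gr)
        dropped <- rbind(dropped,
                         data.frame(population = asg$population[i],
                                    n_samples = asg$n_samples[i]))
        log <- c(log, sprintf("drop %s (%d samples, no feasible merge)",
                              gr, sizes[gr]))
        asg <- asg[-i, , drop = FALSE]
        pcs <- pcs[-i, , drop = FALSE]
      }
      next
    }
    break
  }
  sizes <- tapply(asg$n_samples, asg$group, sum)
  unresolved <- names(sizes)[sizes < min_size | sizes > max_size]
  if (length(unresolved))
    log <- c(log, sprintf("unresolved group %s (size %d)", unresolved,
                          sizes[unresolved]))
  # stable relabel in order of appearance
  relab <- stats::setNames(sprintf("EGG%02d", seq_along(unique(asg$group))),
                           unique(asg$group))
  asg$group <- unname(relab[asg$group])
  new_group_assignment(asg, pcs, dropped = dropped, log = log)
}

#' Pairwise Hudson FST between labelled sample sets
#'
#' Ratio-of-averages Hudson estimator over SNPs j:
#' \deqn{F_{ST} = \sum_j N_j / \sum_j D_j}
#' with \eqn{N_j = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' \eqn{D_j = p_1(1-p_2) + p_2(1-p_1)}, where p are alt-allele frequencies
#' and n the observed allele counts (2 x non-missing samples). SNPs with
#' fewer than 2 observed alleles in either set are skipped.
#'
#' @param m a [genotype_matrix()].
#' @param labels character vector over samples (population or group labels);
#'   defaults to the population column.
#' @return An object of class `fst_matrix`: symmetric matrix with zero
#'   diagonal, labelled by group.
#' @export
pairwise_fst <- function(m, labels = m$samples$population) {
  labels <- as.character(labels)
  lv <- unique(labels)
  cnt <- table(labels)
  if (any(cnt < 2)) stop("every labelled set needs >= 2 samples: ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))
  # per-label alt counts and observed allele numbers
  p <- matrix(0, length(lv), ncol(m$dosage))
  nall <- matrix(0, length(lv), ncol(m$dosage))
  for (i in seq_along(lv)) {
    rows <- labels == lv[i]
    sub <- m$dosage[rows, , drop = FALSE]
    nall[i, ] <- 2 * colSums(!is.na(sub))
    p[i, ] <- colSums(sub, na.rm = TRUE) / pmax(nall[i, ], 1)
  }
  fst <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (j > i) {
    ok <- nall[i, ] >= 2 & nall[j, ] >= 2
    p1 <- p[i, ok]; p2 <- p[j, ok]
    n1 <- nall[i, ok]; n2 <- nall[j, ok]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst[i, j] <- fst[j, i] <- sum(num) / sum(den)
  }
  structure(fst, class = c("fst_matrix", "matrix"))
}

#' Hudson FST between two labelled sets
#'
#' Convenience scalar wrapper around [pairwise_fst()].
#'
#' @param m a [genotype_matrix()].
#' @param labels two-level label vector over samples.
#' @return Single Hudson FST value.
#' @export
hudson_fst <- function(m, labels) {
  f <- pairwise_fst(m, labels)
  f[1, 2]
}

#' Write a group assignment as TSV
#'
#' @param g a `group_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_assignment <- function(g, path) {
  utils::write.table(g$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
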