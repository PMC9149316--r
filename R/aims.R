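#' Per-class chi-square prefilter of candidate SNPs
#'
#' For every class c and SNP j, a 2x2 allele-count table (class vs rest) x
#' (ref vs alt) is formed from the dosages and the Pearson chi-square
#' statistic computed. The `top_n` highest-scoring SNPs of each class are
#' retained and the union over classes returned. SNPs with a zero margin
#' (monomorphic, or a class with no observed alleles) score 0.
#'
#' @param m an imputed [genotype_matrix()].
#' @param labels class label per sample (>= 2 classes).
#' @param top_n SNPs kept per class (default 2000).
#' @return list with `candidates` (character vector, union of per-class top
#'   sets in matrix column order), `scores` (classes x SNPs statistic
#'   matrix) and `per_class` (list of per-class top id vectors).
#' @export
chi2_per_class <- function(m, labels, top_n = 2000) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (anyNA(m$dosage)) stop("matrix must be imputed")
  dos <- m$dosage
  storage.mode(dos) <- "double"
  n_tot_alleles <- 2 * nrow(dos)
  alt_tot <- colSums(dos)
  scores <- matrix(0, length(classes), ncol(dos),
                   dimnames = list(classes, m$variants$id))
  for (c in classes) {
    rows <- labels == c
    a <- colSums(dos[rows, , drop = FALSE])         # alt in class
    n_c <- 2 * sum(rows)
    b <- n_c - a                                    # ref in class
    cc <- alt_tot - a                               # alt in rest
    d <- (n_tot_alleles - n_c) - cc                 # ref in rest
    N <- n_tot_alleles
    num <- N * (a * d - b * cc)^2
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    s <- ifelse(den > 0, num / den, 0)
    scores[c, ] <- s
  }
  per_class <- lapply(classes, function(c) {
    ord <- order(scores[c, ], decreasing = TRUE)
    m$variants$id[ord[seq_len(min(top_n, ncol(dos)))]]
  })
  names(per_class) <- classes
  cand <- m$variants$id[m$variants$id %in% unique(unlist(per_class))]
  list(candidates = cand, scores = scores, per_class = per_class)
}

#' Two-class chi-square scores
#'
#' Allele-count Pearson chi-square restricted to the samples of two classes;
#' used by the confusion-driven augmentation.
#'
#' @param m an imputed [genotype_matrix()].
#' @param labels class label per sample.
#' @param class_a,class_b label values, or character vectors of labels to be
#'   pooled (e.g. two groups of a triplet against the third).
#' @return Named numeric vector of statistics over all SNPs.
#' @export
chi2_two_class <- function(m, labels, class_a, class_b) {
  sel <- labels %in% c(class_a, class_b)
  sub <- subset_genotypes(m, samples = sel)
  lab <- ifelse(labels[sel] %in% class_a, "A", "B")
  chi2_per_class(sub, lab, top_n = 1)$scores["A", ]
}

stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (c in unique(labels)) {
    i <- sample(which(labels == c))
    if (length(i) < n_folds)
      stop("class '", c, "' has fewer samples (", length(i),
           ") than folds (", n_folds, "); use fewer folds")
    fold[i] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

balanced_weights <- function(labels) {
  n <- length(labels)
  tab <- table(labels)
  w <- n / (length(tab) * as.vector(tab[labels]))
  w
}

#' Stability selection of SNPs by randomized-tree importance
#'
#' Fits an extremely-randomized-trees classifier (class-balanced weights, no
#' bootstrap, one random split point per candidate feature) on each of
#' `n_folds` stratified training splits and keeps a SNP only when its
#' normalized impurity importance exceeds `threshold` in every fit.
#' Importances of each fit are normalized to sum to 1 so the threshold is
#' comparable across panels. The default threshold 2.7e-5 is referenced to a
#' candidate set of 54,522 SNPs and rescaled by `54522 / n_candidates`
#' (importances sum to 1, so a meaningful cutoff scales with feature count);
#' `rescale_threshold = FALSE` applies the raw constant.
#'
#' @param m an imputed [genotype_matrix()] restricted to candidate SNPs.
#' @param labels class label per sample.
#' @param n_folds stratified folds (default 5).
#' @param n_estimators trees per fit (default 320).
#' @param threshold importance cutoff (default 2.7e-5 before rescaling).
#' @param rescale_threshold rescale the cutoff by `54522 / n_candidates`
#'   (default `TRUE`).
#' @param seed integer seed; governs folds and tree randomness.
#' @return list with `selected` (character vector of surviving SNP ids),
#'   `importance` (folds x SNPs matrix of normalized importances),
#'   `mean_importance` (named vector), `threshold_used` and `folds`.
#' @export
stability_select <- function(m, labels, n_folds = 5, n_estimators = 320,
                             threshold = 2.7e-5, rescale_threshold = TRUE,
                             seed = 1L) {
  labels <- as.character(labels)
  if (anyNA(m$dosage)) stop("matrix must be imputed")
  fold <- stratified_folds(labels, n_folds, seed)
  p <- ncol(m$dosage)
  thr <- if (rescale_threshold) threshold * 54522 / p else threshold
  imp <- matrix(0, n_folds, p, dimnames = list(NULL, m$variants$id))
  df <- as.data.frame(m$dosage)
  colnames(df) <- paste0("x", seq_len(p))  # ranger-safe names
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    dtr <- df[tr, , drop = FALSE]
    dtr$.class <- factor(labels[tr])
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = dtr,
      num.trees = n_estimators, splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      importance = "impurity", case.weights = balanced_weights(labels[tr]),
      seed = seed + f, num.threads = 1)
    v <- fit$variable.importance
    tot <- sum(v)
    imp[f, ] <- if (tot > 0) v / tot else 0
  }
  surv <- colSums(imp > thr) == n_folds
  list(selected = m$variants$id[surv], importance = imp,
       mean_importance = stats::setNames(colMeans(imp), m$variants$id),
       threshold_used = thr, folds = fold)
}

#' Flag class pairs and triplets the classifier confuses
#'
#' A pair (a, b) is flagged when the mutual confusion count
#' `conf[a, b] + conf[b, a]` reaches `frac` of the smaller class support.
#' Flagged pairs are then joined transitively: a connected component of
#' exactly three classes becomes a triplet (replacing its member pairs);
#' other components are reported as their individual pairs.
#'
#' @param confusion square class x class count matrix, rows = true class,
#'   columns = predicted class.
#' @param frac confusion fraction that triggers a flag (default 0.2).
#' @return list with `pairs` (list of 2-vectors) and `triplets` (list of
#'   lists: `classes` 3-vector, `core_pair` the most mutually confused pair).
#' @export
detect_confusions <- function(confusion, frac = 0.2) {
  classes <- rownames(confusion)
  support <- rowSums(confusion)
  flagged <- list()
  for (i in seq_along(classes)) for (j in seq_along(classes)) if (j > i) {
    mut <- confusion[i, j] + confusion[j, i]
    if (min(support[i], support[j]) > 0 &&
        mut >= frac * min(support[i], support[j]))
      flagged[[length(flagged) + 1]] <- c(classes[i], classes[j])
  }
  if (!length(flagged)) return(list(pairs = list(), triplets = list()))
  # connected components over flagged edges
  comp <- stats::setNames(seq_along(classes), classes)
  for (e in flagged) {
    a <- comp[e[1]]; b <- comp[e[2]]
    comp[comp == b] <- a
  }
  pairs <- list(); triplets <- list()
  for (cid in unique(comp[unlist(flagged)])) {
    members <- names(comp)[comp == cid]
    edges <- Filter(function(e) all(e %in% members), flagged)
    if (length(members) == 3) {
      muts <- vapply(edges, function(e) confusion[e[1], e[2]] + confusion[e[2], e[1]], 1)
      triplets[[length(triplets) + 1]] <-
        list(classes = sort(members), core_pair = edges[[which.max(muts)]])
    } else {
      pairs <- c(pairs, edges)
    }
  }
  list(pairs = pairs, triplets = triplets)
}

#' Extra markers for confused class pairs and triplets
#'
#' For a flagged pair, the `n_add` SNPs with the highest two-class
#' chi-square on the pair's samples are returned. For a triplet, the two
#' most mutually confused classes are contrasted against the third
#' (`n_add` SNPs) and against each other (`n_add` more).
#'
#' @param m an imputed [genotype_matrix()] (full SNP set).
#' @param labels class label per sample.
#' @param flagged result of [detect_confusions()].
#' @param n_add markers per contrast (default 100).
#' @return data.frame `snp_id`, `provenance` (`pair_augment` /
#'   `triplet_augment`), deduplicated; zero rows when nothing is flagged.
#' @export
augment_confused <- function(m, labels, flagged, n_add = 100) {
  out <- list()
  top_ids <- function(sc, n) names(sort(sc, decreasing = TRUE))[seq_len(min(n, length(sc)))]
  for (pr in flagged$pairs) {
    sc <- chi2_two_class(m, labels, pr[1], pr[2])
    out[[length(out) + 1]] <- data.frame(snp_id = top_ids(sc, n_add),
                                         provenance = "pair_augment")
  }
  for (tp in flagged$triplets) {
    ab <- tp$core_pair
    third <- setdiff(tp$classes, ab)
    sc1 <- chi2_two_class(m, labels, ab, third)     # {a,b} vs c
    sc2 <- chi2_two_class(m, labels, ab[1], ab[2])  # a vs b
    out[[length(out) + 1]] <- data.frame(snp_id = c(top_ids(sc1, n_add),
                                                    top_ids(sc2, n_add)),
                                         provenance = "triplet_augment")
  }
  if (!length(out)) return(data.frame(snp_id = character(),
                                      provenance = character()))
  res <- do.call(rbind, out)
  res[!duplicated(res$snp_id), , drop = FALSE]
}

#' Macro-F1 as a function of panel size
#'
#' Ranks SNPs by mean stability importance, then for each requested size
#' trains the one-vs-rest logistic classifier on the top SNPs under
#' stratified 5-fold cross-validation and records the mean macro-F1. The
#' curve is noisy but saturates: past a few thousand markers additional SNPs
#' buy little accuracy.
#'
#' @param m an imputed [genotype_matrix()].
#' @param labels class label per sample.
#' @param sizes integer vector of panel sizes.
#' @param mean_importance named importance vector (from
#'   [stability_select()]); defaults to pooled chi-square scores.
#' @param n_folds,seed cross-validation controls.
#' @return data.frame `size`, `macro_f1`, sorted by size.
#' @export
panel_size_curve <- function(m, labels, sizes, mean_importance = NULL,
                             n_folds = 5, seed = 1L) {
  if (is.null(mean_importance)) {
    sc <- chi2_per_class(m, labels, top_n = ncol(m$dosage))$scores
    mean_importance <- stats::setNames(colMeans(sc), m$variants$id)
  }
  ranked <- names(sort(mean_importance, decreasing = TRUE))
  res <- lapply(sort(unique(sizes)), function(s) {
    ids <- ranked[seq_len(min(s, length(ranked)))]
    cv <- cross_validate(subset_genotypes(m, variants = ids), labels,
                         n_folds = n_folds, seed = seed)
    data.frame(size = s, macro_f1 = cv$mean_metrics["macro_f1"])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[match(sizes, out$size), , drop = FALSE]
}

#' Build an ancestry-informative SNP panel
#'
#' Orchestrates the full selection pipeline: per-class chi-square prefilter,
#' randomized-tree stability selection across stratified folds,
#' cross-validated confusion analysis of a classifier trained on the
#' survivors, chi-square augmentation of confused pairs/triplets, and the
#' final union. Per-SNP imputation modes of the training matrix are stored
#' in the panel so new samples can be imputed identically at prediction
#' time.
#'
#' @param m an imputed [genotype_matrix()] (training/reference panel).
#' @param labels class label per sample (ancestry group).
#' @param top_n_per_class chi-square prefilter size (default 2000).
#' @param n_folds,n_estimators,threshold,rescale_threshold passed to
#'   [stability_select()].
#' @param confusion_frac passed to [detect_confusions()].
#' @param n_augment markers per augmentation contrast (default 100).
#' @param seed one seed governing folds, trees and CV.
#' @return list with `panel` (a `snp_panel` data.frame: `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `provenance`, `imputation_mode`; selection
#'   parameters attached as the `params` attribute) and `report` (a
#'   `selection_report`: stage counts, flagged confusions, CV macro-F1 of
#'   the survivor panel).
#' @export
build_panel <- function(m, labels, top_n_per_class = 2000, n_folds = 5,
                        n_estimators = 320, threshold = 2.7e-5,
                        rescale_threshold = TRUE, confusion_frac = 0.2,
                        n_augment = 100, seed = 1L) {
  labels <- as.character(labels)
  pre <- chi2_per_class(m, labels, top_n = top_n_per_class)
  m_cand <- subset_genotypes(m, variants = pre$candidates)
  st <- stability_select(m_cand, labels, n_folds = n_folds,
                         n_estimators = n_estimators, threshold = threshold,
                         rescale_threshold = rescale_threshold, seed = seed)
  if (!length(st$selected))
    stop("no SNP passed stability selection in all folds; ",
         "lower the threshold or enlarge the panel")
  cv <- cross_validate(subset_genotypes(m, variants = st$selected), labels,
                       n_folds = n_folds, seed = seed)
  flagged <- detect_confusions(cv$confusion, frac = confusion_frac)
  aug <- augment_confused(m, labels, flagged, n_add = n_augment)
  aug <- aug[!aug$snp_id %in% st$selected, , drop = FALSE]
  ids <- c(st$selected, aug$snp_id)
  prov <- c(rep("stability", length(st$selected)), aug$provenance)
  modes <- impute_mode(subset_genotypes(m, variants = ids))$modes
  vi <- match(ids, m$variants$id)
  panel <- data.frame(snp_id = ids,
                      chrom = m$variants$chrom[vi], pos = m$variants$pos[vi],
                      ref = m$variants$ref[vi], alt = m$variants$alt[vi],
                      provenance = prov,
                      imputation_mode = as.integer(modes[ids]),
                      stringsAsFactors = FALSE)
  attr(panel, "params") <- list(top_n_per_class = top_n_per_class,
                                n_folds = n_folds,
                                n_estimators = n_estimators,
                                threshold = threshold,
                                threshold_used = st$threshold_used,
                                rescale_threshold = rescale_threshold,
                                confusion_frac = confusion_frac,
                                n_augment = n_augment, seed = seed)
  class(panel) <- c("snp_panel", "data.frame")
  report <- structure(list(
    n_candidates = length(pre$candidates),
    n_stability = length(st$selected),
    n_augmented = nrow(aug),
    n_panel = nrow(panel),
    flagged = flagged,
    survivor_cv_macro_f1 = unname(cv$mean_metrics["macro_f1"]),
    threshold_used = st$threshold_used), class = "selection_report")
  list(panel = panel, report = report,
       mean_importance = st$mean_importance)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("SNP selection report\n")
  cat("  chi-square candidates :", x$n_candidates, "\n")
  cat("  stability survivors   :", x$n_stability,
      sprintf("(threshold %.3g)", x$threshold_used), "\n")
  cat("  augmentation additions:", x$n_augmented,
      sprintf("(%d pair(s), %d triplet(s))", length(x$flagged$pairs),
              length(x$flagged$triplets)), "\n")
  cat("  final panel           :", x$n_panel, "SNPs\n")
  cat("  survivor CV macro-F1  :", round(x$survivor_cv_macro_f1, 3), "\n")
  invisible(x)
}

#' Write / read a SNP panel as TSV (+ JSON parameter block)
#'
#' @param panel a `snp_panel` from [build_panel()].
#' @param path output TSV path; parameters go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_snp_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(panel, "params"), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snp_panel
#' @export
read_snp_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  pj <- paste0(path, ".json")
  if (file.exists(pj))
    attr(panel, "params") <- jsonlite::read_json(pj, simplifyVector = TRUE)
  class(panel) <- c("snp_panel", "data.frame")
  panel
}
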