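#' Train the one-vs-rest logistic ancestry classifier
#'
#' One L2-penalized binary logistic regression per ancestry group (group vs
#' rest) with balanced class weights `n / (n_classes * n_c)`. The inverse
#' regularization strength `C` follows the common ML convention: the
#' penalized objective is `sum(w_i * logloss_i) + ||beta||^2 / (2C)`, so the
#' ridge fit uses `lambda = 1 / (n * C)`. Intercepts are unpenalized.
#'
#' @param m an imputed [genotype_matrix()] restricted to the panel SNPs (or
#'   a plain dosage matrix).
#' @param labels ancestry group per sample (>= 2 groups, each >= 2 samples).
#' @param C inverse regularization strength (default 1).
#' @param panel optional `snp_panel` to embed (enables stand-alone
#'   prediction with stored imputation modes).
#' @param seed recorded in metadata; the fit itself is deterministic.
#' @param tol,maxit convergence controls of the coordinate-descent solver.
#' @return An object of class `ancestry_model`: `classes`, `coefficients`
#'   (classes x SNPs), `intercepts`, `snp_ids`, `C`, `panel`, `metadata`.
#' @export
train_ancestry_model <- function(m, labels, C = 1.0, panel = NULL, seed = 1L,
                                 tol = 1e-9, maxit = 1e5) {
  X <- if (inherits(m, "genotype_matrix")) m$dosage else as.matrix(m)
  if (anyNA(X)) stop("matrix must be imputed before training")
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 samples")
  n <- nrow(X)
  w <- balanced_weights(labels)
  lambda <- 1 / (n * C)
  coefs <- matrix(0, length(classes), ncol(X),
                  dimnames = list(classes, colnames(X)))
  icept <- stats::setNames(numeric(length(classes)), classes)
  for (c in classes) {
    y <- as.integer(labels == c)
    fit <- glmnet::glmnet(X, factor(y, levels = 0:1), family = "binomial",
                          alpha = 0, lambda = lambda, weights = w,
                          standardize = FALSE, thresh = tol, maxit = maxit)
    if (fit$jerr != 0)
      warning("solver flagged incomplete convergence for class ", c,
              " (code ", fit$jerr, ")")
    b <- as.numeric(fit$beta[, 1])
    coefs[c, ] <- b
    icept[c] <- fit$a0[1]
  }
  structure(list(classes = classes, coefficients = coefs,
                 intercepts = icept, snp_ids = colnames(X),
                 C = C, panel = panel,
                 metadata = list(n_samples = n, n_snps = ncol(X),
                                 seed = seed, date = format(Sys.Date()),
                                 version = "1")),
            class = "ancestry_model")
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat("ancestry_model:", length(x$classes), "groups x",
      length(x$snp_ids), "SNPs (one-vs-rest logistic, C =", x$C, ")\n")
  invisible(x)
}

#' Per-group ancestry probabilities for new genotypes
#'
#' Input SNPs are matched to the model panel by id. Panel SNPs absent from
#' the input, and missing cells, are imputed from the modes stored in the
#' embedded panel; prediction is refused when more than `max_missing` of the
#' panel is absent, so mode imputation can never dominate a score. Per-group
#' sigmoid scores are normalized to sum to one; the top group is the argmax
#' with ties broken toward the lexicographically smallest label.
#'
#' @param model an [train_ancestry_model()] fit.
#' @param newdata a [genotype_matrix()] or dosage matrix with SNP ids as
#'   column names.
#' @param max_missing maximum tolerated fraction of panel SNPs absent from
#'   the input (default 0.1).
#' @return An object of class `prediction_result`: data.frame `sample_id`,
#'   `top_group`, `top_probability`, plus a `probabilities` attribute
#'   (samples x groups matrix, rows summing to 1).
#' @export
predict_proba <- function(model, newdata, max_missing = 0.1) {
  X <- if (inherits(newdata, "genotype_matrix")) newdata$dosage else as.matrix(newdata)
  ids <- model$snp_ids
  pos <- match(ids, colnames(X))
  absent <- is.na(pos)
  if (mean(absent) > max_missing)
    stop(sum(absent), " of ", length(ids), " panel SNPs absent from input (",
         round(100 * mean(absent), 1), "% > ", 100 * max_missing, "% cap)")
  full <- matrix(NA_real_, nrow(X), length(ids),
                 dimnames = list(rownames(X), ids))
  full[, !absent] <- X[, pos[!absent], drop = FALSE]
  if (anyNA(full)) {
    if (is.null(model$panel))
      stop("missing genotypes but model has no embedded imputation modes")
    modes <- stats::setNames(model$panel$imputation_mode, model$panel$snp_id)
    mm <- matrix(rep(as.numeric(modes[ids]), each = nrow(full)), nrow(full))
    full[is.na(full)] <- mm[is.na(full)]
  }
  eta <- full %*% t(model$coefficients) +
    rep(model$intercepts, each = nrow(full))
  sc <- stats::plogis(eta)
  prob <- sc / rowSums(sc)
  top_i <- apply(prob, 1, function(p) which(p == max(p))[1])  # cols sorted lexicographically
  res <- data.frame(sample_id = rownames(full) %||% seq_len(nrow(full)),
                    top_group = model$classes[top_i],
                    top_probability = prob[cbind(seq_len(nrow(prob)), top_i)],
                    stringsAsFactors = FALSE)
  attr(res, "probabilities") <- prob
  class(res) <- c("prediction_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classification metrics against true labels
#'
#' Per-class precision, recall, F1 and support, the confusion matrix, and
#' macro / weighted aggregates (see [aggregate_metrics()]). Undefined
#' precision (a class never predicted) is reported as 0.
#'
#' @param predicted predicted class labels (or a `prediction_result`).
#' @param truth true class labels.
#' @param classes optional fixed class universe (default: union observed).
#' @return An object of class `metrics_report`: `per_class` data.frame,
#'   `macro_*`, `weighted_*`, `accuracy`, `confusion`.
#' @export
evaluate_predictions <- function(predicted, truth, classes = NULL) {
  if (inherits(predicted, "prediction_result")) predicted <- predicted$top_group
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  conf <- table(factor(truth, classes), factor(predicted, classes))
  conf <- unclass(conf)
  storage.mode(conf) <- "integer"
  tp <- diag(conf)
  support <- as.integer(rowSums(conf))
  pred_n <- colSums(conf)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL, stringsAsFactors = FALSE)
  agg <- aggregate_metrics(per_class)
  structure(c(list(per_class = per_class, confusion = conf), agg),
            class = "metrics_report")
}

#' Aggregate per-class metrics into macro and weighted rows
#'
#' Macro averages are unweighted means over classes; weighted averages are
#' support-weighted. For single-label multiclass prediction the
#' support-weighted recall is identically the overall accuracy
#' (`sum(TP) / n`), which is how accuracy is reported here.
#'
#' @param per_class data.frame with columns `precision`, `recall`, `f1`,
#'   `support` (one row per class), e.g. the per-class block of a published
#'   validation table.
#' @return list: `macro_precision`, `macro_recall`, `macro_f1`,
#'   `weighted_precision`, `weighted_recall`, `weighted_f1`, `accuracy`,
#'   `n_test`.
#' @export
aggregate_metrics <- function(per_class) {
  s <- per_class$support
  list(macro_precision = mean(per_class$precision),
       macro_recall = mean(per_class$recall),
       macro_f1 = mean(per_class$f1),
       weighted_precision = stats::weighted.mean(per_class$precision, s),
       weighted_recall = stats::weighted.mean(per_class$recall, s),
       weighted_f1 = stats::weighted.mean(per_class$f1, s),
       accuracy = stats::weighted.mean(per_class$recall, s),
       n_test = sum(s))
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  pc <- x$per_class
  w <- max(nchar(c(pc$class, "weighted avg")))
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  line <- function(name, p, r, f, s)
    cat(sprintf("%-*s  %9s  %6s  %8s  %7s\n", w, name, p, r, f, s))
  line("", "precision", "recall", "f1-score", "support")
  for (i in seq_len(nrow(pc)))
    line(pc$class[i], fmt(pc$precision[i]), fmt(pc$recall[i]),
         fmt(pc$f1[i]), pc$support[i])
  line("accuracy", "", "", fmt(x$accuracy), x$n_test)
  line("macro avg", fmt(x$macro_precision), fmt(x$macro_recall),
       fmt(x$macro_f1), x$n_test)
  line("weighted avg", fmt(x$weighted_precision), fmt(x$weighted_recall),
       fmt(x$weighted_f1), x$n_test)
  invisible(x)
}

#' Stratified k-fold cross-validation of the ancestry classifier
#'
#' @param m an imputed [genotype_matrix()] restricted to the panel.
#' @param labels ancestry group per sample.
#' @param n_folds stratified folds (default 5).
#' @param C inverse regularization strength.
#' @param seed governs the fold split.
#' @return list: `mean_metrics` (named vector of fold-averaged macro /
#'   weighted metrics and accuracy), `fold_metrics` (data.frame, one row per
#'   fold), `confusion` (pooled class x class counts over all folds).
#' @export
cross_validate <- function(m, labels, n_folds = 5, C = 1.0, seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  fold <- stratified_folds(labels, n_folds, seed)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  rows <- list()
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- train_ancestry_model(subset_genotypes(m, samples = tr),
                                labels[tr], C = C, seed = seed)
    pred <- predict_proba(fit, subset_genotypes(m, samples = !tr))
    mt <- evaluate_predictions(pred, labels[!tr], classes = classes)
    pooled <- pooled + mt$confusion
    rows[[f]] <- data.frame(fold = f, macro_precision = mt$macro_precision,
                            macro_recall = mt$macro_recall,
                            macro_f1 = mt$macro_f1,
                            weighted_f1 = mt$weighted_f1,
                            accuracy = mt$accuracy)
  }
  fm <- do.call(rbind, rows)
  list(mean_metrics = colMeans(fm[, -1]), fold_metrics = fm,
       confusion = pooled)
}

#' Stratified train/test split
#'
#' Within every class, `train_fraction` of the samples (rounded) go to the
#' training set; the split is reproducible under `seed`.
#'
#' @param m a [genotype_matrix()].
#' @param labels class label per sample.
#' @param train_fraction training share (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` logical masks over samples.
#' @export
holdout_split <- function(m, labels, train_fraction = 0.7, seed = 1L) {
  labels <- as.character(labels)
  set.seed(seed)
  train <- logical(length(labels))
  for (c in unique(labels)) {
    i <- sample(which(labels == c))
    n_tr <- round(train_fraction * length(i))
    n_tr <- min(max(n_tr, 1L), length(i) - 1L)
    train[i[seq_len(n_tr)]] <- TRUE
  }
  list(train = train, test = !train)
}

#' Save / load an ancestry model
#'
#' JSON serialization (full double precision) of coefficients, intercepts
#' and the embedded SNP panel; a loaded model predicts without access to
#' the training matrix, and round-trips yield identical predictions.
#'
#' @param model an `ancestry_model`.
#' @param path file path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_ancestry_model <- function(model, path) {
  out <- list(format = "geoancestry_model", version = model$metadata$version,
              classes = model$classes,
              intercepts = as.list(model$intercepts),
              coefficients = apply(model$coefficients, 1, identity,
                                   simplify = FALSE),
              snp_ids = model$snp_ids, C = model$C,
              panel = if (is.null(model$panel)) NULL else
                as.data.frame(model$panel),
              panel_params = attr(model$panel, "params"),
              metadata = model$metadata)
  # digits = I(17): significant digits, enough to round-trip binary64 exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ancestry_model
#' @export
read_ancestry_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format) || x$format != "geoancestry_model")
    stop("not an ancestry model file: ", path)
  if (!identical(as.character(x$version), "1"))
    stop("unsupported model version: ", x$version)
  coefs <- do.call(rbind, x$coefficients[x$classes])
  colnames(coefs) <- x$snp_ids
  panel <- x$panel
  if (!is.null(panel)) {
    class(panel) <- c("snp_panel", "data.frame")
    attr(panel, "params") <- x$panel_params
  }
  structure(list(classes = x$classes, coefficients = coefs,
                 intercepts = unlist(x$intercepts)[x$classes],
                 snp_ids = x$snp_ids, C = x$C, panel = panel,
                 metadata = x$metadata),
            class = "ancestry_model")
}
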