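test_that("a linearly separable two-class toy is fit to training accuracy 1", {
  d <- cbind(c(rep(0L, 10), rep(2L, 10)), rep(c(0L, 1L, 2L, 1L), 5))
  m <- toy_matrix(d)
  labs <- rep(c("A", "B"), each = 10)
  fit <- train_ancestry_model(m, labs)
  pred <- predict_proba(fit, m)
  expect_identical(pred$top_group, labs)
  expect_identical(sort(fit$classes), c("A", "B"))
})

test_that("balanced weights neutralize class imbalance (duplication
           equivalence)", {
  set.seed(12)
  d <- rbind(matrix(rbinom(40 * 60, 2, 0.3), 40),
             matrix(rbinom(10 * 60, 2, 0.6), 10))
  labs <- rep(c("big", "small"), c(40, 10))
  m1 <- toy_matrix(d)
  fit1 <- train_ancestry_model(m1, labs)
  # duplicate the minority class 4x -> balanced dataset
  d2 <- rbind(d, d[41:50, ][rep(1:10, 3), ])
  m2 <- genotype_matrix(d2, m1$variants,
                        data.frame(sample_id = sprintf("r%03d", 1:80),
                                   population = "p", latitude = 0,
                                   longitude = 0))
  fit2 <- train_ancestry_model(m2, c(labs, rep("small", 30)))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gte(cosine(fit1$coefficients["small", ],
                    fit2$coefficients["small", ]), 0.99)
})

test_that("stronger regularization shrinks coefficients monotonically", {
  m <- subset_genotypes(small_m(), variants = 1:200)
  norms <- sapply(c(1, 0.1, 0.01), function(C)
    sqrt(sum(train_ancestry_model(m, small_labels(), C = C)$coefficients^2)))
  expect_true(all(diff(norms) < 0))
})

test_that("probabilities normalize, degenerate models are uniform, ties break
           lexicographically", {
  m <- subset_genotypes(small_m(), variants = 1:300)
  fit <- train_ancestry_model(m, small_labels())
  pred <- predict_proba(fit, m)
  prob <- attr(pred, "probabilities")
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-9)
  zero <- fit
  zero$coefficients[] <- 0
  zero$intercepts[] <- 0
  pz <- predict_proba(zero, m)
  expect_equal(unname(attr(pz, "probabilities")[1, ]),
               rep(1 / 4, 4), tolerance = 1e-12)
  expect_identical(unique(pz$top_group), "G01")  # smallest label on ties
})

test_that("prediction refuses inputs missing too much of the panel and
           mode-imputes the rest", {
  m <- subset_genotypes(small_m(), variants = 1:200)
  panel <- data.frame(snp_id = m$variants$id,
                      imputation_mode = impute_mode(m)$modes)
  fit <- train_ancestry_model(m, small_labels(), panel = panel)
  few <- subset_genotypes(m, variants = 1:150)       # 25% absent
  expect_error(predict_proba(fit, few), "absent")
  most <- subset_genotypes(m, variants = 1:185)      # 7.5% absent -> imputed
  pred <- predict_proba(fit, most)
  expect_identical(nrow(pred), nrow(m$dosage))
  holey <- inject_missing(m, 0.05, seed = 4)         # cell-level missingness
  expect_silent(predict_proba(fit, holey))
})

test_that("metric report satisfies the multiclass identities", {
  truth <- c("a", "a", "a", "b", "b", "c", "c", "c", "c")
  pred <- c("a", "b", "a", "b", "b", "c", "a", "c", "c")
  r <- evaluate_predictions(pred, truth)
  expect_equal(r$accuracy, mean(pred == truth))
  expect_equal(r$weighted_recall, r$accuracy)       # identity
  with(r$per_class, expect_equal(f1, ifelse(precision + recall > 0,
                                            2 * precision * recall /
                                              (precision + recall), 0)))
  expect_identical(sum(r$per_class$support), length(truth))
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$accuracy, 1)
  # class never predicted -> precision reported as 0
  r2 <- evaluate_predictions(c("a", "a"), c("a", "b"))
  expect_equal(r2$per_class$precision[r2$per_class$class == "b"], 0)
})

test_that("published per-class rows obey the F1 harmonic-mean identity at
           printed precision", {
  tab <- north_eurasia_validation_metrics()
  expect_identical(nrow(tab), 29L)
  hm <- 2 * tab$precision * tab$recall / (tab$precision + tab$recall)
  expect_lt(max(abs(hm - tab$f1)), 0.01)
})

test_that("cross-validation is deterministic and folds partition the data", {
  m <- subset_genotypes(small_m(), variants = 1:300)
  labs <- small_labels()
  a <- cross_validate(m, labs, seed = 3)
  b <- cross_validate(m, labs, seed = 3)
  expect_identical(a$mean_metrics, b$mean_metrics)
  expect_identical(sum(a$confusion), length(labs))  # pooled over all folds
  folds <- getFromNamespace("stratified_folds", "geoancestry")(labs, 5, 3)
  expect_identical(sort(unique(folds)), 1:5)
  expect_true(all(table(folds, labs) >= 1))  # every class in every fold
})

test_that("holdout split is stratified, disjoint and reproducible", {
  labs <- small_labels()
  m <- small_m()
  sp <- holdout_split(m, labs, 0.7, seed = 5)
  expect_identical(sp$train & sp$test, rep(FALSE, length(labs)))
  expect_identical(sp$train | sp$test, rep(TRUE, length(labs)))
  for (c in unique(labs)) {
    n_c <- sum(labs == c)
    expect_lte(abs(sum(sp$train & labs == c) - 0.7 * n_c), 1)
  }
  sp2 <- holdout_split(m, labs, 0.7, seed = 5)
  expect_identical(sp, sp2)
})

test_that("model serialization round-trips predictions exactly", {
  m <- subset_genotypes(small_m(), variants = 1:250)
  panel <- data.frame(snp_id = m$variants$id, chrom = m$variants$chrom,
                      pos = m$variants$pos, ref = m$variants$ref,
                      alt = m$variants$alt, provenance = "stability",
                      imputation_mode = impute_mode(m)$modes)
  fit <- train_ancestry_model(m, small_labels(), panel = panel)
  f <- tempfile(fileext = ".json")
  write_ancestry_model(fit, f)
  back <- read_ancestry_model(f)
  p1 <- predict_proba(fit, m)
  p2 <- predict_proba(back, m)   # no training matrix needed
  expect_identical(attr(p1, "probabilities"), attr(p2, "probabilities"))
  # version guard
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  raw$version <- "999"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_ancestry_model(f2), "version")
})

test_that("high-confidence calls are accurate on simulated data", {
  sim <- small_sim()
  m <- sim$matrix; labs <- small_labels()
  sel <- chi2_per_class(m, labs, top_n = 100)$candidates
  sp <- holdout_split(m, labs, 0.7, seed = 8)
  fit <- train_ancestry_model(subset_genotypes(m, samples = sp$train,
                                               variants = sel),
                              labs[sp$train], seed = 8)
  pred <- predict_proba(fit, subset_genotypes(m, samples = sp$test,
                                              variants = sel))
  conf <- pred$top_probability > 0.9
  expect_gte(mean((pred$top_group == labs[sp$test])[conf]), 0.9)
})
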