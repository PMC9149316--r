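test_that("PCA standardizes by allele frequency and finds no spurious outliers", {
  m <- small_m()
  pca <- pca_with_outlier_removal(m)
  expect_length(pca$removed_outliers, 0)
  expect_identical(nrow(pca$scores), nrow(m$dosage))
  expect_lt(abs(stats::cor(pca$scores[, 1], pca$scores[, 2])), 1e-8)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
})

test_that("a planted extreme sample is removed in the first iteration", {
  m <- subset_genotypes(small_m(), variants = 1:1000)
  p <- allele_frequency(m)
  # drive one sample far along the rare-allele direction
  shifted <- m$dosage
  shifted[5, ] <- ifelse(p < 0.5, 2L, 0L)
  m2 <- genotype_matrix(shifted, m$variants, m$samples)
  pca <- pca_with_outlier_removal(m2, sigma = 6)
  expect_gte(length(pca$removed_outliers), 1)
  expect_true(m$samples$sample_id[5] %in% pca$removed_outliers[[1]])
  expect_false(m$samples$sample_id[5] %in% rownames(pca$scores))
})

test_that("population centroids equal the member-sample score means", {
  pca <- pca_with_outlier_removal(small_m())
  cent <- population_mean_pcs(pca)
  for (i in sample(nrow(cent), 3)) {
    rows <- pca$samples$population == cent$population[i]
    expect_equal(unname(as.numeric(cent[i, c("PC1", "PC2", "PC3")])),
                 unname(colMeans(pca$scores[rows, , drop = FALSE])))
  }
  one <- pca$scores[1, , drop = FALSE]
  cent1 <- population_mean_pcs(
    structure(list(scores = one,
                   samples = pca$samples[1, , drop = FALSE]),
              class = "pca_result"))
  expect_equal(as.numeric(cent1[, c("PC1", "PC2", "PC3")]), as.numeric(one))
})

test_that("K-means separates well-separated blobs and beats random labels", {
  cent <- data.frame(population = sprintf("p%02d", 1:10),
                     n_samples = 30,
                     PC1 = c(rnorm(5, -10, .2), rnorm(5, 10, .2)),
                     PC2 = 0, PC3 = 0)
  g <- kmeans_group(cent, k = 2, seed = 1)
  split1 <- g$assignment$group[1:5]
  split2 <- g$assignment$group[6:10]
  expect_length(unique(split1), 1)
  expect_length(unique(split2), 1)
  expect_false(split1[1] == split2[1])
  # k = n populations -> singleton groups
  gn <- kmeans_group(cent, k = 10, seed = 1)
  expect_length(unique(gn$assignment$group), 10)
  expect_error(kmeans_group(cent, k = 11), "exceeds")
  # objective sanity: within-cluster SS under k-means <= random assignment
  pcs <- as.matrix(cent[, c("PC1", "PC2", "PC3")])
  wss <- function(asg) sum(sapply(split(seq_len(10), asg), function(i)
    sum(scale(pcs[i, , drop = FALSE], scale = FALSE)^2)))
  set.seed(2)
  expect_lte(wss(g$assignment$group), wss(sample(rep(c("a", "b"), 5))))
})

test_that("rebalancing merges small groups, drops unmergeable ones,
           preserves sample counts", {
  cent <- data.frame(population = c("tiny", "near", "far1", "far2"),
                     n_samples = c(10L, 30L, 145L, 148L),
                     PC1 = c(0, 1, 50, 60), PC2 = 0, PC3 = 0)
  g <- kmeans_group(cent, k = 4, seed = 1)
  r <- rebalance_groups(g, min_size = 25, max_size = 150)
  merged <- r$assignment$group[r$assignment$population == "tiny"]
  expect_identical(merged,
                   r$assignment$group[r$assignment$population == "near"])
  expect_true(all(r$group_sizes >= 25 & r$group_sizes <= 150))
  expect_identical(sum(r$group_sizes) + sum(r$dropped$n_samples), 333L)

  # isolated small group with saturated neighbours is dropped
  cent2 <- data.frame(population = c("tiny", "big1", "big2"),
                      n_samples = c(10L, 145L, 145L),
                      PC1 = c(0, 40, 80), PC2 = 0, PC3 = 0)
  g2 <- rebalance_groups(kmeans_group(cent2, k = 3, seed = 1),
                         min_size = 25, max_size = 150)
  expect_identical(g2$dropped$population, "tiny")
  expect_identical(sum(g2$group_sizes) + sum(g2$dropped$n_samples), 300L)

  # all groups in bounds -> identity
  cent3 <- data.frame(population = c("a", "b"), n_samples = c(40L, 60L),
                      PC1 = c(0, 50), PC2 = 0, PC3 = 0)
  g3 <- kmeans_group(cent3, k = 2, seed = 1)
  r3 <- rebalance_groups(g3, 25, 150)
  expect_identical(sort(unname(r3$group_sizes)), c(40L, 60L))
  expect_identical(length(r3$log), 0L)
})

test_that("oversized multi-population groups are split to within bounds", {
  cent <- data.frame(population = sprintf("p%d", 1:4),
                     n_samples = c(80L, 80L, 90L, 85L),
                     PC1 = c(0, 0.5, 20, 20.5), PC2 = 0, PC3 = 0)
  g <- kmeans_group(cent, k = 1, seed = 1)  # one group of 335
  r <- rebalance_groups(g, min_size = 25, max_size = 200)
  expect_true(all(r$group_sizes <= 200))
  expect_gt(length(r$group_sizes), 1)
})

test_that("Hudson FST hits the analytic extremes and is label-symmetric", {
  d <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  pops <- rep(c("a", "b"), each = 10)
  m <- toy_matrix(d, populations = pops)
  f <- pairwise_fst(m)
  expect_equal(unname(f["a", "b"]), 1)          # opposite fixation
  expect_identical(unname(diag(f)), c(0, 0))
  # two halves of one simulated population: identical true frequencies
  m1 <- subset_genotypes(small_m(),
                         samples = small_m()$samples$population == "G01_pop1")
  expect_lt(abs(hudson_fst(m1, rep(c("a", "b"), length.out = nrow(m1$dosage)))),
            0.02)
  m2 <- small_m()
  f1 <- hudson_fst(m2, ifelse(m2$samples$group_label == "G01", "x", "y"))
  f2 <- hudson_fst(m2, ifelse(m2$samples$group_label == "G01", "y", "x"))
  expect_equal(f1, f2)
  expect_error(pairwise_fst(toy_matrix(d, populations = c("solo", pops[-1]))),
               ">= 2 samples")
})
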