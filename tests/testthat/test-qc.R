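test_that("SNP missingness filter uses strict 'over threshold' semantics", {
  d <- matrix(0L, 100, 3)
  d[1:6, 1] <- NA   # 6% missing -> removed
  d[1:5, 2] <- NA   # 5% missing -> kept (rule is strictly over 5%)
  m <- toy_matrix(d)
  r <- filter_snp_missingness(m, 0.05)
  expect_identical(r$matrix$variants$id, c("v002", "v003"))
  expect_identical(r$report$n_removed, 1L)
})

test_that("MAF filter removes below-threshold and monomorphic SNPs, keeps boundary", {
  d <- matrix(0L, 100, 4)
  d[1, 1] <- 1L            # MAF 0.005 -> removed
  d[1:2, 2] <- 1L          # MAF 0.01 exactly -> kept
  d[, 3] <- 1L             # MAF 0.5 -> kept
  # column 4 monomorphic -> removed
  r <- filter_maf(toy_matrix(d), 0.01)
  expect_identical(r$matrix$variants$id, c("v002", "v003"))
})

test_that("sample missingness filter keeps the boundary sample", {
  d <- matrix(0L, 3, 100)
  d[1, 1:11] <- NA   # 11% -> removed
  d[2, 1:10] <- NA   # 10% exactly -> kept
  r <- filter_sample_missingness(toy_matrix(d), 0.1)
  expect_identical(r$matrix$samples$sample_id, c("s002", "s003"))
})

test_that("filters are idempotent", {
  m <- inject_missing(subset_genotypes(small_m(), variants = 1:300), 0.04, seed = 9)
  once <- filter_snp_missingness(m, 0.03)$matrix
  twice <- filter_snp_missingness(once, 0.03)$matrix
  expect_identical(twice$dosage, once$dosage)
  once <- filter_maf(m, 0.05)$matrix
  expect_identical(filter_maf(once, 0.05)$matrix$dosage, once$dosage)
})

test_that("LD pruning removes duplicates, keeps independents, satisfies the
           brute-force in-window post-condition", {
  # exclude planted AIMs: strong shared differentiation induces genuine
  # structure LD; the independence check needs background SNPs only
  bg <- setdiff(small_m()$variants$id, planted_ids(small_sim()$truth))
  m <- subset_genotypes(small_m(), variants = bg[1:400])
  dup <- add_ld_blocks(m, n_blocks = 15, block_size = 3, flip_rate = 0,
                       seed = 4)  # exact copies, r^2 = 1
  r <- ld_prune(dup, window_snps = 50, step_snps = 5, r2_max = 0.2)
  expect_true(all(table(sub("_ld[0-9]+$", "", r$matrix$variants$id)) == 1))

  noisy <- add_ld_blocks(m, n_blocks = 25, block_size = 4, flip_rate = 0.05,
                         seed = 5)
  pruned <- ld_prune(noisy, window_snps = 50, step_snps = 5, r2_max = 0.2)$matrix
  # exhaustive oracle: no retained in-window pair exceeds the cutoff
  for (chr in unique(pruned$variants$chrom)) {
    idx <- which(pruned$variants$chrom == chr)
    idx <- idx[order(pruned$variants$pos[idx])]
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(pruned$dosage[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    pr <- which(upper.tri(cc) & cc^2 > 0.2, arr.ind = TRUE)
    if (nrow(pr)) expect_true(all(pr[, 2] - pr[, 1] >= 50))
    else succeed()
  }
  # truly independent SNPs (no population structure) are untouched
  set.seed(77)
  iid <- toy_matrix(matrix(rbinom(200 * 400, 2, rep(runif(400, 0.2, 0.8),
                                                    each = 200)), 200))
  r0 <- ld_prune(iid, window_snps = 50, step_snps = 5, r2_max = 0.2)
  expect_identical(r0$report$n_removed, 0L)
})

test_that("mode imputation fills with the modal dosage, lowest wins ties,
           and never alters observed cells", {
  d <- rbind(c(0L, 2L, 0L), c(0L, 2L, 0L), c(1L, NA, 1L), c(NA, NA, 1L))
  m <- toy_matrix(d)
  r <- impute_mode(m)
  expect_identical(unname(r$matrix$dosage[4, 1]), 0L)   # mode 0
  expect_identical(unname(r$matrix$dosage[3:4, 2]), c(2L, 2L))
  expect_identical(unname(r$modes), c(0L, 2L, 0L))  # col 3 ties 0/1 -> 0
  obs <- !is.na(d)
  expect_identical(r$matrix$dosage[obs], d[obs])
  # tie 0,0,1,1 -> 0
  tie <- impute_mode(toy_matrix(cbind(c(0L, 0L, 1L, 1L, NA))))
  expect_identical(unname(tie$matrix$dosage[5, 1]), 0L)
  # stored modes override recomputation
  r2 <- impute_mode(m, modes = c(v001 = 2L, v002 = 0L, v003 = 2L))
  expect_identical(unname(r2$matrix$dosage[4, 1]), 2L)
  expect_error(impute_mode(toy_matrix(cbind(c(NA_integer_, NA)))),
               "entirely missing")
})

test_that("KING-robust kinship: duplicates at 0.5, unrelated near 0,
           no self pairs", {
  m <- subset_genotypes(small_m(), samples = 1:30)
  dup <- genotype_matrix(rbind(m$dosage, m$dosage[1, , drop = FALSE] ),
                         m$variants,
                         rbind(m$samples,
                               transform(m$samples[1, ], sample_id = "dup")))
  kin <- estimate_kinship(dup)
  expect_false(any(kin$id1 == kin$id2))
  phi_dup <- kin$kinship[kin$id1 == m$samples$sample_id[1] & kin$id2 == "dup"]
  expect_equal(phi_dup, 0.5, tolerance = 1e-12)
  # samples from the same population are unrelated by construction
  same_pop <- kin[kin$id1 != "dup" & kin$id2 != "dup", ]
  pops <- m$samples$population
  names(pops) <- m$samples$sample_id
  within <- same_pop[pops[same_pop$id1] == pops[same_pop$id2], ]
  expect_lt(max(abs(within$kinship)), 0.0884)
})

test_that("injected full sibs show kinship near 0.25", {
  m <- subset_genotypes(small_m(), samples = 1:30, variants = 1:2000)
  rel <- inject_relatives(m, n_pairs = 2, seed = 8)
  kin <- estimate_kinship(rel$matrix)
  for (i in seq_len(nrow(rel$pairs))) {
    phi <- kin$kinship[(kin$id1 == rel$pairs$id1[i] & kin$id2 == rel$pairs$id2[i]) |
                       (kin$id2 == rel$pairs$id1[i] & kin$id1 == rel$pairs$id2[i])]
    expect_equal(phi, 0.25, tolerance = 0.05)
  }
})

test_that("remove_related leaves no pair at or above the cutoff, greedily", {
  m <- subset_genotypes(small_m(), samples = 1:20)
  # chain: B duplicates A, C is B with a few edits -> A~B, B~C strongly related
  A <- m$dosage[1, ]
  B <- A; C <- A; C[1:300] <- pmin(2L, C[1:300] + 1L)
  dos <- rbind(m$dosage, B, C)
  sam <- rbind(m$samples,
               transform(m$samples[1:2, ], sample_id = c("relB", "relC")))
  big <- genotype_matrix(dos, m$variants, sam)
  r <- remove_related(big, threshold = 0.0884)
  kin <- estimate_kinship(r$matrix)
  expect_true(all(kin$kinship < 0.0884, na.rm = TRUE))  # brute-force check
  # one planted duplicate -> exactly one removal
  dup <- genotype_matrix(rbind(m$dosage, m$dosage[1, , drop = FALSE]),
                         m$variants,
                         rbind(m$samples,
                               transform(m$samples[1, ], sample_id = "dup")))
  expect_identical(remove_related(dup)$report$n_removed, 1L)
  expect_identical(remove_related(m)$report$n_removed, 0L)
})
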