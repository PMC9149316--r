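#' Configuration for the hierarchical genotype simulator
#'
#' Defines a two-level Balding-Nichols panel: ancestry groups diverge from a
#' common ancestral pool at `fst_between_group`, and populations within a
#' group diverge from the group at `fst_within_group` (set 0 for a
#' single-level panel). The defaults describe the standard recovery panel
#' used throughout the package's validation: 8 groups of 3 populations with
#' 25 samples each, 20,000 independent SNPs, 500 planted
#' ancestry-informative markers, and moderate between-group differentiation
#' (F = 0.05) typical of well-separated continental-scale subdivisions.
#'
#' @param n_groups number of ancestry groups.
#' @param populations_per_group populations nested in each group.
#' @param samples_per_population diploid samples per population.
#' @param n_snps number of independent biallelic SNPs.
#' @param n_planted_aims number of SNPs to turn into planted
#'   ancestry-informative markers (split evenly across groups).
#' @param aim_effect allele-frequency offset applied to planted AIMs in
#'   their target group (default 0.4).
#' @param fst_within_group,fst_between_group Balding-Nichols divergence of
#'   the two hierarchy levels; `fst_within_group < fst_between_group` and
#'   `fst_within_group = 0` collapses to one level.
#' @param missing_rate probability that any genotype cell is set missing.
#' @param n_related_pairs number of full-sib pairs to append.
#' @param seed integer seed governing every random draw.
#' @param geography optional data.frame (`population`, `latitude`,
#'   `longitude`); by default populations of one group are laid out in a
#'   compact disc on the lat/lon plane so groups occupy contiguous areas.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_groups = 8, populations_per_group = 3,
                       samples_per_population = 25, n_snps = 20000,
                       n_planted_aims = 500, aim_effect = 0.4,
                       fst_within_group = 0.01, fst_between_group = 0.05,
                       missing_rate = 0, n_related_pairs = 0, seed = 1,
                       geography = NULL) {
  stopifnot(fst_between_group > 0, fst_between_group < 1,
            fst_within_group >= 0, fst_within_group < 1,
            fst_within_group < fst_between_group,
            n_planted_aims <= n_snps, missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

bn_freq <- function(p, f) {
  # Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 means no drift
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

auto_geography <- function(groups, pops_per_group) {
  # group centres on a coarse grid; member populations jittered in a disc
  ng <- length(groups)
  ncol_g <- ceiling(sqrt(ng))
  gx <- ((seq_len(ng) - 1) %% ncol_g) * 24 + 30      # lon
  gy <- ((seq_len(ng) - 1) %/% ncol_g) * 16 + 42     # lat
  out <- vector("list", ng)
  for (g in seq_len(ng)) {
    ang <- 2 * pi * (seq_len(pops_per_group) - 1) / max(1, pops_per_group)
    r <- if (pops_per_group == 1) 0 else 3
    out[[g]] <- data.frame(
      population = sprintf("%s_pop%d", groups[g], seq_len(pops_per_group)),
      latitude = gy[g] + r * sin(ang),
      longitude = gx[g] + r * cos(ang),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a hierarchically structured genotype panel
#'
#' Per SNP, an ancestral frequency p ~ Uniform(0.05, 0.95) is drawn; each
#' group's frequency is a Balding-Nichols Beta draw around p at
#' `fst_between_group`; each population's frequency is a Beta draw around its
#' group frequency at `fst_within_group`; genotypes are Binomial(2, p_pop).
#' Fully deterministic under `cfg$seed`. Planted AIMs, missingness and
#' relatives are added by [plant_aims()], [inject_missing()] and
#' [inject_relatives()] (see [simulate_ancestry_panel()] for the one-call
#' wrapper).
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a [genotype_matrix()] with group labels and
#'   geography filled in) and `truth` (a `sim_truth`: `group` per sample,
#'   `planted` ids per group, `pop_freq` populations x SNPs, nominal FST
#'   values, `related_pairs`, and the generating `config`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  groups <- sprintf("G%02d", seq_len(cfg$n_groups))
  geo <- if (is.null(cfg$geography))
    auto_geography(groups, cfg$populations_per_group) else cfg$geography
  pops <- geo$population
  pop_group <- rep(groups, each = cfg$populations_per_group)
  n_pops <- length(pops)
  p_anc <- stats::runif(cfg$n_snps, 0.05, 0.95)
  grp_freq <- matrix(0, cfg$n_groups, cfg$n_snps)
  for (g in seq_len(cfg$n_groups))
    grp_freq[g, ] <- bn_freq(p_anc, cfg$fst_between_group)
  pop_freq <- matrix(0, n_pops, cfg$n_snps,
                     dimnames = list(pops, sprintf("snp%05d", seq_len(cfg$n_snps))))
  for (k in seq_len(n_pops))
    pop_freq[k, ] <- bn_freq(grp_freq[match(pop_group[k], groups), ],
                             cfg$fst_within_group)
  n_samples <- n_pops * cfg$samples_per_population
  dos <- matrix(0L, n_samples, cfg$n_snps)
  samp_pop <- rep(pops, each = cfg$samples_per_population)
  for (k in seq_len(n_pops)) {
    rows <- which(samp_pop == pops[k])
    dos[rows, ] <- matrix(
      stats::rbinom(length(rows) * cfg$n_snps, 2L,
                    rep(pop_freq[k, ], each = length(rows))),
      nrow = length(rows))
  }
  samp_group <- pop_group[match(samp_pop, pops)]
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    population = samp_pop,
    latitude = geo$latitude[match(samp_pop, pops)],
    longitude = geo$longitude[match(samp_pop, pops)],
    group_label = samp_group, stringsAsFactors = FALSE)
  chrom_of <- ((seq_len(cfg$n_snps) - 1) %/% ceiling(cfg$n_snps / 22)) + 1
  variants <- data.frame(
    id = colnames(pop_freq), chrom = as.character(chrom_of),
    pos = as.integer(stats::ave(seq_len(cfg$n_snps), chrom_of,
                                FUN = seq_along) * 1000L),
    ref = "A", alt = "C", stringsAsFactors = FALSE)
  m <- genotype_matrix(dos, variants, samples)
  truth <- structure(list(
    group = stats::setNames(samp_group, samples$sample_id),
    population_group = stats::setNames(pop_group, pops),
    planted = stats::setNames(vector("list", cfg$n_groups), groups),
    ancestral_freq = stats::setNames(p_anc, variants$id),
    pop_freq = pop_freq,
    fst_within = cfg$fst_within_group,
    fst_between = cfg$fst_between_group,
    related_pairs = data.frame(id1 = character(), id2 = character()),
    config = cfg), class = "sim_truth")
  list(matrix = m, truth = truth)
}

#' Plant ancestry-informative markers
#'
#' For each group, `n_planted_aims / n_groups` distinct SNPs (chosen at
#' random, disjoint across groups) have their allele frequency shifted by
#' `effect` in that group's populations — in the direction that accommodates
#' the full offset, so every planted AIM carries the nominal effect — then
#' clipped to [0.02, 0.98]. Genotypes of the affected group x SNP cells are
#' redrawn from the shifted frequencies; all other cells are untouched.
#' `effect = 0` returns the input unchanged.
#'
#' @param m a [genotype_matrix()] from [simulate_panel()].
#' @param truth the matching `sim_truth`.
#' @param effect allele-frequency offset (default taken from the config).
#' @param seed seed for SNP choice and redraws (default `config seed + 1`).
#' @return list with updated `matrix` and `truth` (`planted` filled in,
#'   `pop_freq` updated).
#' @export
plant_aims <- function(m, truth, effect = truth$config$aim_effect,
                       seed = truth$config$seed + 1L) {
  if (effect == 0) return(list(matrix = m, truth = truth))
  set.seed(seed)
  cfg <- truth$config
  groups <- names(truth$planted)
  per_group <- cfg$n_planted_aims %/% length(groups)
  chosen <- sample(ncol(m$dosage), per_group * length(groups))
  pf <- truth$pop_freq
  for (g in seq_along(groups)) {
    snps <- chosen[((g - 1) * per_group + 1):(g * per_group)]
    gpops <- names(truth$population_group)[truth$population_group == groups[g]]
    # one shift direction per SNP for the whole group, from the group mean
    gmean <- colMeans(pf[gpops, snps, drop = FALSE])
    dir <- ifelse(gmean + effect <= 0.98, 1, -1)
    for (pop in gpops) {
      p0 <- pf[pop, snps]
      p1 <- pmin(0.98, pmax(0.02, p0 + dir * effect))
      pf[pop, snps] <- p1
      rows <- which(m$samples$population == pop)
      m$dosage[rows, snps] <- matrix(
        stats::rbinom(length(rows) * length(snps), 2L,
                      rep(p1, each = length(rows))),
        nrow = length(rows))
    }
    truth$planted[[groups[g]]] <- m$variants$id[snps]
  }
  truth$pop_freq <- pf
  list(matrix = m, truth = truth)
}

#' Set genotype cells missing at random
#'
#' Each cell is independently set to `NA` with probability `rate`.
#'
#' @param m a [genotype_matrix()].
#' @param rate per-cell missingness probability.
#' @param seed integer seed.
#' @return A [genotype_matrix()] with missing cells.
#' @export
inject_missing <- function(m, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(m)
  set.seed(seed)
  mask <- stats::runif(length(m$dosage)) < rate
  m$dosage[mask] <- NA_integer_
  m
}

#' Append full-sib sample pairs
#'
#' For each pair, two parents are drawn from one population and two
#' offspring are generated by Mendelian transmission (each parent passes one
#' allele per SNP; heterozygous parents transmit either allele with equal
#' probability). The two offspring are full sibs with expected KING-robust
#' kinship 0.25.
#'
#' @param m a [genotype_matrix()]; must be fully observed.
#' @param n_pairs number of sib pairs to append.
#' @param seed integer seed.
#' @return list with `matrix` (relatives appended) and `pairs` (data.frame of
#'   sib sample-id pairs).
#' @export
inject_relatives <- function(m, n_pairs, seed = 1L) {
  if (n_pairs == 0)
    return(list(matrix = m, pairs = data.frame(id1 = character(), id2 = character())))
  set.seed(seed)
  transmit <- function(parent) {
    # one allele per SNP from a diploid dosage vector
    a <- integer(length(parent))
    a[parent == 2L] <- 1L
    het <- parent == 1L
    a[het] <- stats::rbinom(sum(het), 1L, 0.5)
    a
  }
  new_rows <- list(); new_meta <- list(); pairs <- list()
  pops <- unique(m$samples$population)
  for (k in seq_len(n_pairs)) {
    pop <- sample(pops, 1)
    cand <- which(m$samples$population == pop)
    par_idx <- sample(cand, 2)
    p1 <- m$dosage[par_idx[1], ]; p2 <- m$dosage[par_idx[2], ]
    sib1 <- transmit(p1) + transmit(p2)
    sib2 <- transmit(p1) + transmit(p2)
    ids <- sprintf("SIB%03d_%d", k, 1:2)
    new_rows[[k]] <- rbind(sib1, sib2)
    meta <- m$samples[rep(par_idx[1], 2), ]
    meta$sample_id <- ids
    new_meta[[k]] <- meta
    pairs[[k]] <- data.frame(id1 = ids[1], id2 = ids[2], stringsAsFactors = FALSE)
  }
  dos <- rbind(m$dosage, do.call(rbind, new_rows))
  samples <- rbind(m$samples, do.call(rbind, new_meta))
  list(matrix = genotype_matrix(dos, m$variants, samples),
       pairs = do.call(rbind, pairs))
}

#' Insert linkage-disequilibrium blocks by noisy column duplication
#'
#' The default simulator draws independent SNPs; this helper creates local
#' LD for testing the pruner: `n_blocks` source SNPs each receive
#' `block_size - 1` noisy copies placed immediately after them in position
#' order. Each copied cell is replaced by a fresh Binomial(2, 0.5) draw with
#' probability `flip_rate`, so within-block r^2 is high but below 1.
#'
#' @param m a [genotype_matrix()].
#' @param n_blocks number of LD blocks (default 20).
#' @param block_size SNPs per block including the source (default 3).
#' @param flip_rate per-cell perturbation probability (default 0.05).
#' @param seed integer seed.
#' @return A [genotype_matrix()] with `n_blocks * (block_size - 1)` extra
#'   SNPs; copies are named `<source>_ld<k>`.
#' @export
add_ld_blocks <- function(m, n_blocks = 20, block_size = 3, flip_rate = 0.05,
                          seed = 1L) {
  set.seed(seed)
  src <- sort(sample(ncol(m$dosage), n_blocks))
  n <- nrow(m$dosage)
  cols <- list(); vars <- list()
  for (j in seq_len(ncol(m$dosage))) {
    cols[[length(cols) + 1]] <- m$dosage[, j]
    vars[[length(vars) + 1]] <- m$variants[j, ]
    if (j %in% src) {
      for (k in seq_len(block_size - 1)) {
        cp <- m$dosage[, j]
        flip <- stats::runif(n) < flip_rate
        cp[flip] <- stats::rbinom(sum(flip), 2L, 0.5)
        cols[[length(cols) + 1]] <- cp
        v <- m$variants[j, ]
        v$id <- sprintf("%s_ld%d", v$id, k)
        v$pos <- v$pos + k
        vars[[length(vars) + 1]] <- v
      }
    }
  }
  genotype_matrix(do.call(cbind, cols), do.call(rbind, vars), m$samples)
}

#' Simulate a complete study panel in one call
#'
#' Runs [simulate_panel()], then [plant_aims()], [inject_relatives()] and
#' [inject_missing()] according to the configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` and `truth` as in [simulate_panel()];
#'   `truth$related_pairs` lists any injected sib pairs.
#' @export
simulate_ancestry_panel <- function(cfg = sim_config()) {
  sim <- simulate_panel(cfg)
  sim <- plant_aims(sim$matrix, sim$truth)
  if (cfg$n_related_pairs > 0) {
    rel <- inject_relatives(sim$matrix, cfg$n_related_pairs,
                            seed = cfg$seed + 2L)
    sim$matrix <- rel$matrix
    sim$truth$related_pairs <- rel$pairs
    grp <- sim$matrix$samples$group_label
    sim$truth$group <- stats::setNames(grp, sim$matrix$samples$sample_id)
  }
  if (cfg$missing_rate > 0)
    sim$matrix <- inject_missing(sim$matrix, cfg$missing_rate,
                                 seed = cfg$seed + 3L)
  sim
}

#' All planted AIM ids of a simulation truth
#'
#' @param truth a `sim_truth`.
#' @return character vector of planted SNP ids (all groups pooled).
#' @export
planted_ids <- function(truth) unlist(truth$planted, use.names = FALSE)

#' Write a simulation truth as JSON
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  out <- list(group = as.list(truth$group),
              population_group = as.list(truth$population_group),
              planted = truth$planted,
              fst_within = truth$fst_within,
              fst_between = truth$fst_between,
              related_pairs = truth$related_pairs,
              seed = truth$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
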