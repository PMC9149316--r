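#' Genotype matrix container
#'
#' The central data structure of the package: a samples x variants matrix of
#' alternate-allele dosages (0, 1, 2) for diploid biallelic SNPs, with
#' `NA_integer_` as the reserved missing-genotype sentinel, plus per-variant
#' and per-sample metadata.
#'
#' @param dosage integer matrix, samples in rows, variants in columns.
#'   Values must be 0, 1, 2 or `NA`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per dosage column, `id` unique, `pos >= 1`.
#' @param samples data.frame with columns `sample_id`, `population`,
#'   `latitude`, `longitude` and optionally `group_label`; one row per dosage
#'   row, `sample_id` unique, coordinates in WGS84 decimal degrees (may be
#'   `NA` when geography is unknown).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosage values must be 0, 1, 2 or NA")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples  <- as.data.frame(samples, stringsAsFactors = FALSE)
  req_v <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req_v %in% names(variants)))
    stop("variants must have columns: ", paste(req_v, collapse = ", "))
  if (!"group_label" %in% names(samples)) samples$group_label <- NA_character_
  req_s <- c("sample_id", "population", "latitude", "longitude")
  if (!all(req_s %in% names(samples)))
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop("variants rows (", nrow(variants), ") != dosage columns (", ncol(dosage), ")")
  if (nrow(samples) != nrow(dosage))
    stop("samples rows (", nrow(samples), ") != dosage rows (", nrow(dosage), ")")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (any(variants$pos < 1, na.rm = TRUE)) stop("variant pos must be >= 1")
  lat <- samples$latitude; lon <- samples$longitude
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]")
  dimnames(dosage) <- list(samples$sample_id, variants$id)
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$dosage))
  cat("genotype_matrix: ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " SNPs (", format(100 * nm / length(x$dosage), digits = 3),
      "% missing)\n", sep = "")
  np <- length(unique(x$samples$population))
  ng <- length(unique(stats::na.omit(x$samples$group_label)))
  cat("  populations: ", np, if (ng) paste0("; groups: ", ng), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param m a [genotype_matrix()].
#' @param samples,variants indices, logical masks or id character vectors;
#'   `NULL` keeps everything.
#' @return A `genotype_matrix` with metadata subset consistently.
#' @export
subset_genotypes <- function(m, samples = NULL, variants = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(m$dosage)) else resolve_idx(samples, m$samples$sample_id, "sample")
  vi <- if (is.null(variants)) seq_len(ncol(m$dosage)) else resolve_idx(variants, m$variants$id, "variant")
  genotype_matrix(m$dosage[si, vi, drop = FALSE],
                  m$variants[vi, , drop = FALSE],
                  m$samples[si, , drop = FALSE])
}

resolve_idx <- function(idx, ids, what) {
  if (is.character(idx)) {
    i <- match(idx, ids)
    if (anyNA(i)) stop("unknown ", what, " id(s): ",
                       paste(utils::head(idx[is.na(i)], 5), collapse = ", "))
    i
  } else if (is.logical(idx)) {
    if (length(idx) != length(ids)) stop(what, " mask length mismatch")
    which(idx)
  } else as.integer(idx)
}

#' Per-SNP alternate allele frequency
#'
#' Computed over non-missing genotypes only (each sample contributes two
#' alleles).
#'
#' @param m a [genotype_matrix()].
#' @return Named numeric vector of alt-allele frequencies; `NaN` for SNPs with
#'   no observed genotypes.
#' @export
allele_frequency <- function(m) {
  colMeans(m$dosage, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#'
#' @param m a [genotype_matrix()].
#' @return Named numeric vector, `pmin(p, 1 - p)` of the alt-allele frequency.
#' @export
minor_allele_frequency <- function(m) {
  p <- allele_frequency(m)
  pmin(p, 1 - p)
}
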