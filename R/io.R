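#' Read a sample manifest
#'
#' A tab-separated file with columns `sample_id`, `population`, `latitude`,
#' `longitude` and optionally `group_label`.
#'
#' @param path path to a TSV file.
#' @return data.frame of sample records.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "latitude", "longitude")
  if (!all(req %in% names(man)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(man$sample_id)) stop("manifest sample ids must be unique")
  if (!"group_label" %in% names(man)) man$group_label <- NA_character_
  man
}

#' Read genotypes from a VCF file
#'
#' Converts GT calls of diploid biallelic records into alt-allele dosages:
#' `0/0 -> 0`, `0/1`/`1/0 -> 1`, `1/1 -> 2`, `./.` (or any call with a
#' missing allele) -> `NA`. Multiallelic records are skipped with a warning.
#' Sample order follows the VCF header.
#'
#' @param path path to a VCF (v4.x) file, plain or bgzipped.
#' @param manifest optional path to a sample manifest TSV (see
#'   [read_manifest()]); when given it must cover every VCF sample.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, manifest = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0) stop("VCF contains no genotype records: ", path)
  if (!"GT" %in% unlist(strsplit(vcf@gt[1, "FORMAT"], ":")))
    stop("VCF has no GT field: ", path)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warning(sum(!bi), " multiallelic record(s) skipped")
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alleles <- gsub("[|/]", "", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[alleles == "00"] <- 0L
  dos[alleles %in% c("01", "10")] <- 1L
  dos[alleles == "11"] <- 2L
  unknown <- !is.na(gt) & is.na(dos) & !grepl("\\.", gt)
  if (any(unknown))
    stop("unparseable GT call(s), e.g. '", gt[which(unknown)[1]], "'")
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  samp_ids <- colnames(gt)
  samples <- data.frame(sample_id = samp_ids, population = NA_character_,
                        latitude = NA_real_, longitude = NA_real_,
                        group_label = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(manifest)) samples <- join_manifest(samp_ids, read_manifest(manifest))
  genotype_matrix(t(dos), variants, samples)
}

join_manifest <- function(sample_ids, man) {
  i <- match(sample_ids, man$sample_id)
  if (anyNA(i))
    stop("manifest is missing sample id(s): ",
         paste(utils::head(sample_ids[is.na(i)], 5), collapse = ", "))
  man[i, c("sample_id", "population", "latitude", "longitude", "group_label"),
      drop = FALSE]
}

#' Read genotypes from a dosage CSV plus a sample manifest
#'
#' The CSV has a header row of SNP ids, a first column of sample ids and
#' cells in `{0, 1, 2, NA}` (count of alternate alleles). Variant positions
#' are not carried by this format; ids of the form `chr:pos` are parsed back
#' into coordinates when possible.
#'
#' @param path path to the dosage CSV.
#' @param manifest path to a sample manifest TSV covering every CSV sample.
#' @return A [genotype_matrix()].
#' @export
read_dosage_csv <- function(path, manifest) {
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1), data.table = FALSE,
                          na.strings = "NA")
  sample_ids <- dt[[1]]
  dos <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(dos)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(dos), dim(dos)))) &
                   !is.na(dos) & dos != "NA", arr.ind = TRUE)
    stop("non-numeric dosage cell at row ", bad[1, 1], ", column ", bad[1, 2] + 1)
  }
  off <- which(!is.na(dos) & !(dos %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(off))
    stop("dosage cell outside {0,1,2,NA} at row ", off[1, 1],
         ", column ", off[1, 2] + 1, " (value ", dos[off[1, , drop = FALSE]], ")")
  ids <- colnames(dos)
  cp <- regmatches(ids, regexec("^([^:]+):([0-9]+)$", ids))
  chrom <- vapply(cp, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  pos <- vapply(cp, function(x) if (length(x) == 3) as.integer(x[3]) else NA_integer_, 1L)
  variants <- data.frame(id = ids,
                         chrom = ifelse(is.na(chrom), "0", chrom),
                         pos = ifelse(is.na(pos), seq_along(ids), pos),
                         ref = "A", alt = "B", stringsAsFactors = FALSE)
  samples <- join_manifest(sample_ids, read_manifest(manifest))
  genotype_matrix(dos, variants, samples)
}

#' Write a genotype matrix as a dosage CSV (+ manifest)
#'
#' Inverse of [read_dosage_csv()]: header row of SNP ids, one row per sample,
#' missing genotypes written as `NA`.
#'
#' @param m a [genotype_matrix()].
#' @param path output CSV path.
#' @param manifest_path optional path to also write the sample manifest TSV.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(m, path, manifest_path = NULL) {
  df <- data.frame(sample_id = m$samples$sample_id, m$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, na = "NA", quote = FALSE)
  if (!is.null(manifest_path))
    utils::write.table(m$samples, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF v4.2 file with GT-only genotype columns (`0/0`, `0/1`, `1/1`,
#' `./.`), suitable for interchange with standard tooling.
#'
#' @param m a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=geoancestry",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", m$samples$sample_id), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  v <- m$variants
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    d <- m$dosage[, j]
    calls <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}
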