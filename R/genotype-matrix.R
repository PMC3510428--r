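#' Construct a genotype matrix
#'
#' The container used by every stage of the package: a subjects x SNPs
#' dosage matrix counting alternate alleles (0, 1, 2, or `NA` for missing)
#' together with per-SNP metadata.
#'
#' @param dosage numeric or integer matrix, subjects in rows and SNPs in
#'   columns; every non-missing entry must be 0, 1 or 2. Row names are
#'   subject ids and column names SNP ids (supplied names win over
#'   `subjects`/`snps` arguments if both are given).
#' @param snps data frame of SNP metadata with columns `snp_id`,
#'   `chromosome`, `position` (1-based), `allele_ref`, `allele_alt`. If
#'   `NULL`, minimal metadata is fabricated from the column names.
#' @param subjects character vector of subject ids; defaults to the dosage
#'   row names.
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage` (integer matrix with dimnames) and `snps` (metadata frame).
#' @export
genotype_matrix <- function(dosage, snps = NULL, subjects = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- if (!is.null(subjects)) subjects else
      sprintf("S%04d", seq_len(nrow(dosage)))
  }
  if (is.null(snps)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(ncol(dosage)))
    snps <- data.frame(snp_id = ids, chromosome = "1",
                       position = seq_len(ncol(dosage)),
                       allele_ref = "A", allele_alt = "G",
                       stringsAsFactors = FALSE)
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp_id
  obj <- structure(list(dosage = dosage, snps = snps),
                   class = "genotype_matrix")
  validate_genotype_matrix(obj)
}

validate_genotype_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  req <- c("snp_id", "chromosome", "position", "allele_ref", "allele_alt")
  missing_cols <- setdiff(req, names(x$snps))
  if (length(missing_cols))
    stop("SNP metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x$snps) != ncol(x$dosage))
    stop("SNP metadata rows (", nrow(x$snps), ") do not match dosage columns (",
         ncol(x$dosage), ")")
  if (anyDuplicated(x$snps$snp_id))
    stop("duplicate snp_id in genotype matrix: ",
         paste(unique(x$snps$snp_id[duplicated(x$snps$snp_id)]), collapse = ", "))
  if (anyDuplicated(rownames(x$dosage)))
    stop("duplicate subject id in genotype matrix")
  if (any(x$snps$position < 1, na.rm = TRUE))
    stop("SNP positions must be >= 1 (1-based coordinates)")
  bad <- x$dosage[!is.na(x$dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or NA")
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "subjects x", ncol(x$dosage),
      "SNPs\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subject ids of a genotype matrix
#' @param x a `genotype_matrix`
#' @return character vector of subject ids (dosage row order)
#' @export
subjects <- function(x) rownames(x$dosage)

#' Read genotypes from VCF or TSV
#'
#' VCF records must carry a `GT` field; the dosage is the count of
#' alternate alleles in the genotype call, with partial or missing calls
#' (`./.`) mapped to `NA`. Multi-allelic records are rejected unless
#' `split_multiallelic = TRUE`, in which case each alternate allele becomes
#' its own biallelic pseudo-SNP (id suffixed `_alt<k>`). The TSV dialect
#' stores subjects as rows and SNPs as columns: a header row of SNP ids, a
#' first column `subject_id`, and `NA` for missing.
#'
#' @param path file path
#' @param format `"vcf"` or `"tsv"`; guessed from the file extension when
#'   omitted
#' @param split_multiallelic split multi-allelic VCF records instead of
#'   erroring (default `FALSE`)
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           split_multiallelic = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path, split_multiallelic)
  else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path, split_multiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF lacks GT genotype field: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]

  gt_to_dosage <- function(calls, alt_index = 1L) {
    # count how many called alleles equal the alt allele index
    alleles <- strsplit(gsub("\\|", "/", calls), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (any(a %in% c(".", "")) || length(a) < 2) return(NA_integer_)
      sum(a == as.character(alt_index))
    }, integer(1))
  }

  rows <- list()
  meta <- list()
  for (i in seq_len(nrow(fix))) {
    if (multi[i]) {
      if (!split_multiallelic)
        stop("multi-allelic VCF record at line for ", ids[i],
             " (", fix$CHROM[i], ":", fix$POS[i],
             "); set split_multiallelic = TRUE to split")
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      for (k in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- gt_to_dosage(gt_raw[i, ], k)
        meta[[length(meta) + 1L]] <- data.frame(
          snp_id = paste0(ids[i], "_alt", k), chromosome = fix$CHROM[i],
          position = as.integer(fix$POS[i]), allele_ref = fix$REF[i],
          allele_alt = alts[k], stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- gt_to_dosage(gt_raw[i, ], 1L)
      meta[[length(meta) + 1L]] <- data.frame(
        snp_id = ids[i], chromosome = fix$CHROM[i],
        position = as.integer(fix$POS[i]), allele_ref = fix$REF[i],
        allele_alt = fix$ALT[i], stringsAsFactors = FALSE)
    }
  }
  dosage <- t(do.call(rbind, rows))  # subjects x snps
  rownames(dosage) <- colnames(gt_raw)
  snps <- do.call(rbind, meta)
  colnames(dosage) <- snps$snp_id
  genotype_matrix(dosage, snps)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(tab))
    stop("TSV genotype file must have a first column 'subject_id': ", path)
  ids <- as.character(tab$subject_id)
  dos <- as.matrix(tab[, setdiff(names(tab), "subject_id"), drop = FALSE])
  bad <- which(!is.na(dos) & !(dos %in% c("0", "1", "2", 0, 1, 2)))
  if (length(bad)) {
    line <- (bad[1] - 1) %% nrow(dos) + 2  # +1 header, +1 one-based
    stop("non-genotype value '", dos[bad[1]], "' in ", path,
         " around line ", line)
  }
  storage.mode(dos) <- "integer"
  rownames(dos) <- ids
  genotype_matrix(dos)
}

#' Write genotypes to TSV or a minimal VCF
#'
#' The TSV dialect round-trips exactly through [read_genotypes()]. The VCF
#' writer emits unphased diploid GT calls (`0/0`, `0/1`, `1/1`, `./.`) and
#' only the fields this package reads.
#'
#' @param x a [genotype_matrix()]
#' @param path output file path
#' @param format `"tsv"` (default) or `"vcf"`
#' @return `path`, invisibly
#' @export
write_genotypes <- function(x, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  validate_genotype_matrix(x)
  if (format == "tsv") {
    out <- data.frame(subject_id = rownames(x$dosage), x$dosage,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(x$dosage)),
                       collapse = "\t")), con)
    for (j in seq_len(ncol(x$dosage))) {
      g <- x$dosage[, j]
      calls <- ifelse(is.na(g), "./.", gt_codes[as.character(g)])
      writeLines(paste(c(x$snps$chromosome[j], x$snps$position[j],
                         x$snps$snp_id[j], x$snps$allele_ref[j],
                         x$snps$allele_alt[j], ".", "PASS", ".", "GT",
                         calls), collapse = "\t"), con)
    }
  }
  invisible(path)
}
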