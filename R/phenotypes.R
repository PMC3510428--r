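#' Read a phenotype table
#'
#' Expects a CSV or TSV file with columns `subject_id`, `label`
#' (`case`/`control`), `sex` (`F`/`M`/`unknown`) and `extremity_class`
#' (`control` or an age band such as `100-104`, `105-109`, `110+`).
#' Additional columns named `onset_<disease>` are read as numeric ages of
#' disease onset. Subjects present in the phenotype file but absent from
#' `genotypes` (when supplied) are dropped with a warning.
#'
#' @param path file path (separator guessed from the extension: `.csv` ->
#'   comma, otherwise tab)
#' @param genotypes optional [genotype_matrix()] used to cross-check
#'   subject ids
#' @param class_levels ordered extremity classes, lowest first; defaults to
#'   `control < 100-104 < 105-109 < 110+`
#' @return a data frame of class `phenotype_table` with `extremity_class`
#'   as an ordered factor
#' @export
read_phenotypes <- function(path, genotypes = NULL,
                            class_levels = c("control", "100-104",
                                             "105-109", "110+")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  phenotype_table(tab, genotypes = genotypes, class_levels = class_levels)
}

#' Validate / construct a phenotype table
#'
#' @param tab data frame with the columns described in [read_phenotypes()]
#' @inheritParams read_phenotypes
#' @return a validated `phenotype_table` data frame
#' @export
phenotype_table <- function(tab, genotypes = NULL,
                            class_levels = c("control", "100-104",
                                             "105-109", "110+")) {
  req <- c("subject_id", "label", "sex", "extremity_class")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop("duplicated subject_id in phenotype table: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  bad_label <- setdiff(unique(tab$label), c("case", "control"))
  if (length(bad_label))
    stop("unknown label token(s): ", paste(bad_label, collapse = ", "))
  bad_sex <- setdiff(unique(tab$sex), c("F", "M", "unknown"))
  if (length(bad_sex))
    stop("unknown sex token(s): ", paste(bad_sex, collapse = ", "))
  bad_class <- setdiff(unique(as.character(tab$extremity_class)), class_levels)
  if (length(bad_class))
    stop("unknown extremity_class token(s): ",
         paste(bad_class, collapse = ", "))
  tab$extremity_class <- factor(tab$extremity_class, levels = class_levels,
                                ordered = TRUE)
  above <- tab$extremity_class > class_levels[1]
  if (any(above & tab$label != "case"))
    stop("extremity_class above '", class_levels[1],
         "' requires label = case (subject ",
         tab$subject_id[which(above & tab$label != "case")[1]], ")")
  onset_cols <- grep("^onset_", names(tab), value = TRUE)
  for (cc in onset_cols) tab[[cc]] <- as.numeric(tab[[cc]])
  if (!is.null(genotypes)) {
    keep <- tab$subject_id %in% subjects(genotypes)
    if (!all(keep)) {
      warning(sum(!keep), " phenotype subject(s) absent from genotypes; dropped")
      tab <- tab[keep, , drop = FALSE]
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Write a phenotype table to CSV
#' @param tab a `phenotype_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# align phenotypes to the genotype subject order; errors on absent subjects
align_phenotypes <- function(genotypes, phenotypes) {
  idx <- match(subjects(genotypes), phenotypes$subject_id)
  if (anyNA(idx))
    stop("genotyped subject(s) missing from phenotype table: ",
         paste(utils::head(subjects(genotypes)[is.na(idx)], 5), collapse = ", "))
  phenotypes[idx, , drop = FALSE]
}
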