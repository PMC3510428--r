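#' Save and load fitted artifacts as JSON
#'
#' Plain-text serialization for the classifier family and the signature
#' clustering, so fitted artifacts can be moved between the command-line
#' stages (build -> predict -> profile -> cluster).
#'
#' @param model_set a `nested_model_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
save_model <- function(model_set, path) {
  stopifnot(inherits(model_set, "nested_model_set"))
  x <- list(panel = model_set$panel,
            tables = list(case = unclass(model_set$tables$case),
                          control = unclass(model_set$tables$control)),
            k_max = model_set$k_max, class_prior = model_set$class_prior,
            smoothing = model_set$smoothing, threshold = model_set$threshold,
            performance = model_set$performance,
            explored = model_set$explored)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param path path of a JSON file written by [save_model()]
#' @return `load_model`: the restored `nested_model_set`
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(genotype = 0:2, snp_id = x$panel)
    m
  }
  structure(list(panel = x$panel,
                 tables = list(case = fix(x$tables$case),
                               control = fix(x$tables$control)),
                 k_max = x$k_max, class_prior = x$class_prior,
                 smoothing = x$smoothing, threshold = x$threshold,
                 performance = as.data.frame(x$performance),
                 explored = x$explored),
            class = "nested_model_set")
}

#' @rdname save_model
#' @param clustering a `signature_clustering`
#' @export
save_clustering <- function(clustering, path) {
  stopifnot(inherits(clustering, "signature_clustering"))
  x <- list(partition = as.list(clustering$partition),
            cluster_means = unclass(clustering$cluster_means),
            log_marginal = clustering$log_marginal,
            min_bf = clustering$min_bf, prior = clustering$prior)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
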