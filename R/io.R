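#' Read / write a genus count table (TSV, samples as rows)
#'
#' The TSV dialect: tab-separated, header row of genus names, first
#' column `sample_id`. Counts must be non-negative integers and sample
#' ids unique; violations raise errors naming the offending row/column.
#'
#' @param path file path.
#' @return integer matrix with sample-id rownames and genus colnames.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("count table needs a sample_id column plus genera")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stopf("duplicated sample id: %s",
                                ids[duplicated(ids)][1])
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stopf("non-numeric entries in count table")
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stopf("invalid count at row '%s', column '%s'",
          ids[bad[1, 1]], colnames(m)[bad[1, 2]])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_count_table
#' @param table integer matrix, samples x genera.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table (TSV)
#'
#' @param path file path; first column must be `sample_id`.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stopf("first metadata column must be sample_id")
  if (anyDuplicated(df$sample_id)) stopf("duplicated sample id in metadata")
  df
}

#' Serialize / restore a deployable risk bundle as JSON
#'
#' The bundle packs everything needed to score a new count table: the
#' measurement submodel (taxa, loadings, residual variances, latent
#' correlations, standardization constants) and the logistic risk model
#' (feature names, coefficients, CV summary). Numeric precision is
#' preserved to full double resolution.
#'
#' @param model `risk_model`, `measurement_model`, `sem_fit`, or a
#'   bundle list of these.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path,
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model
#' @return the restored object, with classes reattached.
#' @export
read_model <- function(path) {
  deserialize_model(jsonlite::read_json(path, simplifyVector = TRUE))
}

serialize_model <- function(x) {
  if (inherits(x, "measurement_model")) {
    list(.class = "measurement_model",
         latents = lapply(x$latents, as.list),
         direct = as.list(x$direct),
         loadings = as.list(x$loadings), theta = as.list(x$theta),
         psi = list(values = as.vector(x$psi), names = rownames(x$psi)),
         means = as.list(x$means), sds = as.list(x$sds))
  } else if (inherits(x, "risk_model")) {
    list(.class = "risk_model",
         coefficients = as.list(x$coefficients),
         feature_names = as.list(x$feature_names),
         cv_auc = x$cv_auc, fold_auc = x$fold_auc,
         resubstitution_auc = x$resubstitution_auc, meta = x$meta)
  } else if (inherits(x, "sem_fit")) {
    list(.class = "sem_fit",
         latents = lapply(x$spec$latents, as.list),
         direct = as.list(x$spec$direct), outcome = x$spec$outcome,
         loadings = as.list(x$loadings), theta = as.list(x$theta),
         psi = list(values = as.vector(x$psi), names = rownames(x$psi)),
         phi = list(values = as.vector(x$phi), lv = rownames(x$phi),
                    direct = colnames(x$phi)),
         gamma = as.list(x$gamma), beta = as.list(x$beta),
         threshold = x$threshold, chisq = x$chisq, df = x$df,
         gfi = x$gfi, agfi = x$agfi, rmsea = x$rmsea, n = x$n,
         Fmin = x$Fmin, means = as.list(x$means), sds = as.list(x$sds))
  } else if (is.list(x)) {
    lapply(x, serialize_model)
  } else x
}

deserialize_model <- function(j) {
  if (!is.list(j)) return(j)
  cls <- j$.class
  named_vec <- function(l) unlist(l)
  sym_mat <- function(m) {
    k <- length(m$names)
    out <- matrix(m$values, k, k, dimnames = list(m$names, m$names))
    out
  }
  if (identical(cls, "measurement_model")) {
    structure(list(
      latents = lapply(j$latents, unlist),
      direct = as.character(unlist(j$direct)),
      loadings = named_vec(j$loadings), theta = named_vec(j$theta),
      psi = sym_mat(j$psi), means = named_vec(j$means),
      sds = named_vec(j$sds)), class = "measurement_model")
  } else if (identical(cls, "risk_model")) {
    structure(list(
      coefficients = named_vec(j$coefficients),
      feature_names = as.character(unlist(j$feature_names)),
      cv_auc = j$cv_auc, fold_auc = unlist(j$fold_auc),
      resubstitution_auc = j$resubstitution_auc, meta = j$meta),
      class = "risk_model")
  } else if (identical(cls, "sem_fit")) {
    spec <- sem_spec(latents = lapply(j$latents, unlist),
                     direct = as.character(unlist(j$direct)),
                     outcome = j$outcome)
    phi <- matrix(unlist(j$phi$values) %||% numeric(0),
                  length(j$phi$lv), length(unlist(j$phi$direct)),
                  dimnames = list(j$phi$lv, unlist(j$phi$direct)))
    structure(list(
      spec = spec, loadings = named_vec(j$loadings),
      theta = named_vec(j$theta), psi = sym_mat(j$psi), phi = phi,
      gamma = named_vec(j$gamma), beta = named_vec(j$beta),
      r_direct = NULL, threshold = j$threshold, chisq = j$chisq,
      df = j$df, gfi = j$gfi, agfi = j$agfi, rmsea = j$rmsea,
      n = j$n, Fmin = j$Fmin, means = named_vec(j$means),
      sds = named_vec(j$sds), converged = TRUE), class = "sem_fit")
  } else {
    lapply(j, deserialize_model)
  }
}

#' Write a cohort configuration as YAML
#' @param config a [cohort_config()].
#' @param path file path.
#' @export
write_cohort_config <- function(config, path) {
  cfg <- unclass(config)
  # YAML maps keep the planted-taxon names; bare numeric vectors would not
  cfg$planted_up <- as.list(cfg$planted_up)
  cfg$planted_down <- as.list(cfg$planted_down)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$planted_up <- unlist(cfg$planted_up) %||% numeric(0)
  cfg$planted_down <- unlist(cfg$planted_down) %||% numeric(0)
  if (!is.null(cfg$covariate_params))
    cfg$covariate_params <- lapply(cfg$covariate_params, function(sx)
      lapply(sx, function(gr) lapply(gr, unlist)))
  do.call(cohort_config, cfg)
}
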