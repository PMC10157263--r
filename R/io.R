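# File formats: tab-separated matrices (features x subjects, header row of
# subject ids, first column `feature_id`), a tab-separated cohort table with
# a typed column dictionary, and a YAML pipeline configuration that
# round-trips losslessly. TSV with '.' decimal separator throughout; serum
# IgM is strictly g/L and readers reject any other unit annotation.

#' Write / read an expression matrix as TSV
#'
#' @param x an [expression_matrix()].
#' @param path file path.
#' @return `write_expression_matrix()`: the path, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_expression_matrix
#' @param layer layer label for the object read back.
#' @return `read_expression_matrix()`: an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, layer = c("proteome", "transcriptome")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (names(df)[1] != "feature_id")
    stop("first column must be `feature_id`", call. = FALSE)
  fid <- df[[1]]
  if (anyDuplicated(fid))
    stop("duplicate feature id: ", fid[duplicated(fid)][1], call. = FALSE)
  sub <- names(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d (feature %s), column %s",
                 bad[1], fid[bad[1]], sub[bad[2]]), call. = FALSE)
  }
  expression_matrix(num, feature_ids = fid, subject_ids = sub, layer = layer)
}

.cohort_columns <- list(
  subject_id = "character", diagnosis_class = "character",
  igm_g_per_l = "numeric", iga_g_per_l = "numeric", igg_g_per_l = "numeric",
  ige_g_per_l = "numeric", age_years = "numeric", sex = "character",
  date_of_diagnosis = "Date", bilateral = "logical",
  disease_site = "character", lacrimal_involvement = "logical",
  igm_post_treatment = "numeric", ki67 = "numeric",
  ann_arbor = "character", ipi = "character", igm_unit = "character"
)

#' Write / read a cohort table as TSV
#'
#' Dates are written ISO-8601; missing optional values as empty cells. On
#' reading, the diagnosis class must be one of the four known classes, IgM
#' must be positive, age within \[0, 120\], and an `igm_unit` column — if
#' present — must say `g/L` (no silent unit conversion).
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @param path file path.
#' @return `write_cohort()`: the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$date_of_diagnosis <- format(out$date_of_diagnosis, "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort()`: a typed cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("", "NA"))
  need <- c("subject_id", "diagnosis_class", "igm_g_per_l", "age_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if ("igm_unit" %in% names(df)) {
    u <- unique(stats::na.omit(df$igm_unit))
    if (length(u) && !all(u == "g/L"))
      stop("IgM unit must be g/L, found: ", paste(u, collapse = ", "),
           call. = FALSE)
    df$igm_unit <- NULL
  }
  bad_cls <- setdiff(unique(df$diagnosis_class), diagnosis_classes())
  if (length(bad_cls))
    stop("unknown diagnosis class: ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  df$diagnosis_class <- factor(df$diagnosis_class, levels = diagnosis_classes())
  if ("date_of_diagnosis" %in% names(df)) {
    d <- as.Date(df$date_of_diagnosis, format = "%Y-%m-%d")
    if (any(is.na(d) & !is.na(df$date_of_diagnosis)))
      stop("unparseable date (expected ISO-8601): ",
           df$date_of_diagnosis[which(is.na(d) & !is.na(df$date_of_diagnosis))[1]],
           call. = FALSE)
    df$date_of_diagnosis <- d
  }
  for (nm in c("sex", "disease_site"))
    if (nm %in% names(df)) df[[nm]] <- factor(df[[nm]])
  for (nm in c("bilateral", "lacrimal_involvement"))
    if (nm %in% names(df)) df[[nm]] <- as.logical(df[[nm]])
  if (any(!is.na(df$igm_g_per_l) & df$igm_g_per_l <= 0))
    stop("serum IgM must be positive (g/L)", call. = FALSE)
  if (any(df$age_years < 0 | df$age_years > 120, na.rm = TRUE))
    stop("age out of range [0, 120]", call. = FALSE)
  df
}

.config_schema <- function() list(
  seed = NULL, outdir = NULL,
  simulate = list(omics = names(formals(omics_sim_config)),
                  cohort = names(formals(cohort_sim_config)),
                  clonality = names(formals(clonality_sim_config))),
  crossomics = c("prot_log2fc_min", "trans_log2fc_min", "alpha_de",
                 "alpha_corr", "adjust_corr", "require_concordant_direction",
                 "min_n"),
  evaluate = c("n_knots", "cutoff_strategy", "boot"),
  model = c("covariates", "derivation_fraction", "calibration_bins",
            "calibration_boot", "caliper")
)

#' Read / write the pipeline configuration (YAML)
#'
#' Unknown keys anywhere in the file are rejected with an error naming the
#' key, so typos cannot silently fall back to defaults. The configuration
#' round-trips losslessly through [write_pipeline_config()].
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()`: a named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- .config_schema()
  check <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown))
      stop(sprintf("unknown config key `%s` in %s", unknown[1], where),
           call. = FALSE)
  }
  check(cfg, names(schema), "top level")
  for (blk in c("crossomics", "evaluate", "model"))
    if (!is.null(cfg[[blk]])) check(cfg[[blk]], schema[[blk]], blk)
  if (!is.null(cfg$simulate)) {
    check(cfg$simulate, names(schema$simulate), "simulate")
    for (sub in names(schema$simulate))
      if (!is.null(cfg$simulate[[sub]]))
        check(cfg$simulate[[sub]], schema$simulate[[sub]],
              paste0("simulate$", sub))
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param config a configuration list.
#' @return `write_pipeline_config()`: the path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
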