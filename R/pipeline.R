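#' Configuration of the end-to-end analysis pipeline
#'
#' Collects paths and stage options. Defaults reproduce the canonical
#' analysis settings: 960-minute (16-hour) day validity, the
#' weekday-plus-weekend inclusion rule, a nine-function Fourier basis,
#' retention of components up to 75% cumulative variance, exchangeable GEE
#' with FDR 0.05, and 10-minute FoSR bins with a 10-function coefficient
#' basis.
#'
#' @param minute_csv Path to the long-format minute records.
#' @param subject_csv,day_csv Paths to the covariate tables.
#' @param out_dir Output directory.
#' @param min_minutes Day validity threshold in observed minutes.
#' @param apply_inclusion Apply the weekday+weekend subject inclusion rule.
#' @param n_basis Fourier basis size.
#' @param variance_threshold Cumulative variance required of retained
#'   components, in (0, 1].
#' @param corstr GEE working correlation.
#' @param fdr_alpha FDR level for q-values.
#' @param clinical Clinical covariates to model separately.
#' @param fosr_bin FoSR bin width in minutes.
#' @param fosr_basis FoSR coefficient-basis size.
#' @param fosr_bootstrap Bootstrap draws for the robust FoSR global test
#'   (0 = analytic test only).
#' @param make_plots Write figure files.
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(minute_csv = NULL, subject_csv = NULL,
                            day_csv = NULL, out_dir = "actfda-output",
                            min_minutes = 960L, apply_inclusion = TRUE,
                            n_basis = 9L, variance_threshold = 0.75,
                            corstr = "exchangeable", fdr_alpha = 0.05,
                            clinical = c("none", "group", "ids", "antidep"),
                            fosr_bin = 10L, fosr_basis = 10L,
                            fosr_bootstrap = 0L, make_plots = TRUE,
                            seed = 1L) {
  if (min_minutes < 0L || min_minutes > 1440L)
    stop("invalid config: min_minutes must lie in [0, 1440]")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("invalid config: variance_threshold must lie in (0, 1]")
  if (fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("invalid config: fdr_alpha must lie in (0, 1)")
  if (1440L %% fosr_bin != 0L)
    stop("invalid config: fosr_bin must divide 1440")
  if (fosr_basis < 4L || fosr_basis > 1440L %/% fosr_bin)
    stop("invalid config: fosr_basis must lie in [4, grid size]")
  structure(list(minute_csv = minute_csv, subject_csv = subject_csv,
                 day_csv = day_csv, out_dir = out_dir,
                 min_minutes = as.integer(min_minutes),
                 apply_inclusion = isTRUE(apply_inclusion),
                 n_basis = as.integer(n_basis),
                 variance_threshold = variance_threshold,
                 corstr = corstr, fdr_alpha = fdr_alpha,
                 clinical = clinical, fosr_bin = as.integer(fosr_bin),
                 fosr_basis = as.integer(fosr_basis),
                 fosr_bootstrap = as.integer(fosr_bootstrap),
                 make_plots = isTRUE(make_plots), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and validate long-format minute records
#'
#' Schema: `subject_id,date,minute_of_day,activity,observed` (`observed`
#' optional). Dates must parse as ISO-8601, `minute_of_day` must lie in
#' 0-1439, observed activity must be nonnegative, and (subject, date,
#' minute) must be unique.
#'
#' @param path CSV path (LF or CRLF line endings).
#' @return A validated minute-record `data.table`.
#' @export
read_minute_csv <- function(path) {
  mr <- data.table::fread(path)
  need <- c("subject_id", "date", "minute_of_day", "activity")
  miss <- setdiff(need, names(mr))
  if (length(miss))
    stop("parse error: minute CSV is missing column(s) ",
         paste(miss, collapse = ", "))
  mr$date <- as.Date(mr$date)
  if (anyNA(mr$date)) stop("parse error: unparseable dates in minute CSV")
  bad <- which(mr$minute_of_day < 0L | mr$minute_of_day > 1439L)
  if (length(bad))
    stop("validation error: minute_of_day outside [0, 1439] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!"observed" %in% names(mr)) mr$observed <- !is.na(mr$activity)
  bad <- which(mr$observed & (is.na(mr$activity) | mr$activity < 0))
  if (length(bad))
    stop("validation error: negative or missing observed activity at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(mr, by = c("subject_id", "date", "minute_of_day")))
    stop("validation error: duplicate (subject, date, minute) records")
  mr
}

#' Read a covariate table
#'
#' @param path CSV path.
#' @param kind `"subject"` (requires `subject_id`) or `"day"` (requires
#'   `subject_id`, `date`, `workday`).
#' @return A data.frame.
#' @export
read_covariates <- function(path, kind = c("subject", "day")) {
  kind <- match.arg(kind)
  x <- as.data.frame(data.table::fread(path))
  need <- if (kind == "subject") "subject_id" else
    c("subject_id", "date", "workday")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parse error: ", kind, " covariate CSV is missing column(s) ",
         paste(miss, collapse = ", "))
  if (kind == "day") {
    x$date <- as.Date(x$date)
    if (anyNA(x$date)) stop("parse error: unparseable dates in day CSV")
  }
  if ("group" %in% names(x))
    x$group <- factor(x$group, levels = c("none", "remitted", "current"))
  x
}

#' Write day curves as a wide CSV
#'
#' One row per subject-day: metadata columns then the 1440 minute values.
#'
#' @param day_curves A `day_curves` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_day_curves_csv <- function(day_curves, path) {
  stopifnot(inherits(day_curves, "day_curves"))
  V <- day_curves$values
  colnames(V) <- paste0("m", seq_len(ncol(V)) - 1L)
  out <- cbind(day_curves$meta, as.data.frame(V))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Run the full pipeline: preprocess, fPCA, GEE associations, FoSR
#'
#' Sequences the analysis stages on a minute-record dataset, writes all
#' result tables, model dumps and figures under `config$out_dir`, and
#' records a manifest (configuration, seed, package version, attrition
#' counts, output checksums). Identical configuration and inputs produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional `sim_dataset`; when supplied, input CSVs are not
#'   read and the dataset's tables are used directly.
#' @return Invisibly, a list with every intermediate object (`day_curves`,
#'   `inclusion`, `fpca`, `scores`, `assoc`, `fosr`, `manifest`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ## ingest
  if (is.null(dataset)) {
    minute_records <- stage("read", read_minute_csv(config$minute_csv))
    subject_cov <- stage("read", read_covariates(config$subject_csv,
                                                 "subject"))
    day_cov <- stage("read", read_covariates(config$day_csv, "day"))
  } else {
    minute_records <- dataset$minute_records
    subject_cov <- dataset$subject_covariates
    day_cov <- dataset$day_covariates
  }
  n_days_read <- nrow(unique(minute_records[, c("subject_id", "date")]))
  message(sprintf("read %d minute records over %d subject-days",
                  nrow(minute_records), n_days_read))
  ## preprocess
  dc <- stage("preprocess", {
    x <- build_day_curves(minute_records, day_cov)
    flag_valid_days(x, config$min_minutes)
  })
  n_valid <- sum(dc$meta$valid)
  if (config$apply_inclusion) {
    inc <- stage("preprocess", check_inclusion(dc))
    dc <- inc$day_curves
    inclusion <- inc$inclusion
  } else {
    inclusion <- data.frame(subject_id = unique(dc$meta$subject_id),
                            included = TRUE, reason = "")
  }
  dc <- stage("preprocess", impute_missing(dc))
  n_excluded <- sum(!inclusion$included)
  message(sprintf("%d valid days; %d subject(s) excluded; %d subjects in",
                  n_valid, n_excluded, length(unique(dc$meta$subject_id))))
  write_day_curves_csv(dc, file.path(out, "day_curves.csv"))
  data.table::fwrite(inclusion, file.path(out, "exclusion_log.csv"))
  ## fPCA
  basis <- fourier_basis(config$n_basis)
  valid <- which(dc$meta$valid)
  coefs <- stage("fpca", project_to_basis(dc$values[valid, , drop = FALSE],
                                          basis))
  fp <- stage("fpca", fit_fpca(coefs, threshold = config$variance_threshold,
                               basis = basis))
  message(sprintf("fPCA: retained %d components, cumulative variance %.1f%%",
                  fp$n_retained,
                  100 * sum(fp$variance_proportions[seq_len(fp$n_retained)])))
  write_fpca_model(fp, file.path(out, "fpca_model.json"))
  scores <- stage("fpca", compute_scores(fp, coefs,
                                         meta = dc$meta[valid,
                                                        c("subject_id",
                                                          "date")]))
  data.table::fwrite(scores, file.path(out, "scores.csv"))
  ## GEE associations
  clin <- intersect(config$clinical,
                    c("none", intersect(c("group", "ids", "antidep",
                                          "benzo"), names(subject_cov))))
  frame <- stage("gee", build_analysis_frame(scores, subject_cov, day_cov))
  assoc <- stage("gee", fit_associations(frame,
                                         components =
                                           seq_len(fp$n_retained),
                                         clinical = clin,
                                         corstr = config$corstr,
                                         fdr_alpha = config$fdr_alpha))
  message(sprintf("GEE: %d model fits", length(assoc$fits)))
  data.table::fwrite(assoc$table, file.path(out,
                                            "association_results.csv"))
  ## FoSR
  sc <- stage("fosr", build_subject_curves(dc, bin_width = config$fosr_bin))
  fframe <- stage("fosr", prepare_fosr_frame(sc, subject_cov))
  base_terms <- c("age", "sex", "education", "partner", "bmi", "chronic",
                  "cigarettes", "drinks", "prop_workdays", "modal_season")
  base_terms <- intersect(base_terms, names(fframe))
  fosr_fits <- list()
  for (cv in clin) {
    rhs <- paste(base_terms, collapse = " + ")
    if (cv != "none") rhs <- paste(rhs, "+", cv)
    fosr_fits[[cv]] <- stage("fosr",
      fit_fosr(sc, stats::as.formula(paste("~", rhs)), fframe,
               n_basis = config$fosr_basis))
  }
  fosr_main <- fosr_fits[[1]]
  data.table::fwrite(pointwise_bands(fosr_main),
                     file.path(out, "fosr_coefficients.csv"))
  glob <- do.call(rbind, lapply(names(fosr_fits), function(cv)
    cbind(model = cv, fosr_fits[[cv]]$global)))
  data.table::fwrite(glob, file.path(out, "fosr_global.csv"))
  message(sprintf("FoSR: %d model fits on %d subject curves",
                  length(fosr_fits), fosr_main$n))
  ## figures
  if (config$make_plots) {
    for (k in seq_len(fp$n_retained)) {
      grDevices::png(file.path(out, sprintf("component_%d.png", k)),
                     width = 900, height = 600, res = 120)
      print(plot_component(fp, k))
      grDevices::dev.off()
    }
    grDevices::png(file.path(out, "fosr_effects.png"), width = 1200,
                   height = 900, res = 120)
    print(plot_fosr(fosr_main))
    grDevices::dev.off()
  }
  ## manifest
  cfg <- unclass(config)
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(cfg, cfg_path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  tables <- c("day_curves.csv", "exclusion_log.csv", "fpca_model.json",
              "scores.csv", "association_results.csv",
              "fosr_coefficients.csv", "fosr_global.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("actfda")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    counts = list(subject_days_read = n_days_read, valid_days = n_valid,
                  subjects_excluded = n_excluded,
                  subjects_analyzed = length(unique(dc$meta$subject_id)),
                  components_retained = fp$n_retained,
                  gee_fits = length(assoc$fits),
                  fosr_fits = length(fosr_fits)),
    outputs = as.list(tools::md5sum(file.path(out, tables))))
  names(manifest$outputs) <- tables
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(day_curves = dc, inclusion = inclusion, fpca = fp,
                 scores = scores, assoc = assoc, subject_curves = sc,
                 fosr = fosr_fits, manifest = manifest))
}
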