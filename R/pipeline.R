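# End-to-end orchestration: core images -> per-patient TSR -> cutoff ->
# groups -> association + survival reports, with structured exclusion
# logging and seed-reproducible outputs.

#' Molecular subtype from receptor statuses
#'
#' ER-/PR-/HER2- is triple-negative (TNBC); HER2+ with any ER/PR is
#' HER2-positive; hormone-receptor-positive and HER2- is
#' luminal-HER2-negative. Missing statuses give `NA` (the caller excludes
#' and logs such patients).
#'
#' @param er,pr,her2 Logical (or "Positive"/"Negative") statuses.
#' @return Factor with levels TNBC, HER2-positive, Luminal-HER2-negative.
#' @export
assign_subtype <- function(er, pr, her2) {
  as_pos <- function(x) {
    if (is.character(x) || is.factor(x)) x == "Positive" else as.logical(x)
  }
  er <- as_pos(er); pr <- as_pos(pr); her2 <- as_pos(her2)
  out <- ifelse(is.na(er) | is.na(pr) | is.na(her2), NA_character_,
         ifelse(her2, "HER2-positive",
         ifelse(er | pr, "Luminal-HER2-negative", "TNBC")))
  factor(out, levels = c("TNBC", "HER2-positive", "Luminal-HER2-negative"))
}

#' Pipeline configuration
#'
#' @param image_dir Directory of `<patient_id>_core<1|2>.png` images, or
#'   `NULL` when the clinical table already carries a `tsr` column.
#' @param clinical_csv Path to the clinical CSV (see [read_cohort_csv()]),
#'   or `NULL` when a cohort data.frame is passed to [run_pipeline()].
#' @param output_dir Directory for all reports.
#' @param horizon_months Administrative censoring horizon (default 60).
#' @param min_group_fraction Minimum group fraction for the cutpoint scan.
#' @param fixed_cutoff Optional TSR percent overriding the maximally
#'   selected cutoff (e.g. 33.5, or the 50 used by visual scoring).
#' @param segmentation A [segmentation_config()].
#' @param age_encoding `"binary"` (<=50 vs >50) or `"continuous"` (years).
#' @param covariates Covariate columns for the multivariate Cox model.
#' @param seed Seed recorded in the run log and used for any resampling.
#' @return List of class `tsr_pipeline_config`.
#' @export
pipeline_config <- function(image_dir = NULL, clinical_csv = NULL,
                            output_dir = tempfile("tsr_run_"),
                            horizon_months = 60,
                            min_group_fraction = 0.10,
                            fixed_cutoff = NULL,
                            segmentation = segmentation_config(),
                            age_encoding = c("binary", "continuous"),
                            covariates = c("age", "grade", "nodal", "er",
                                           "pr", "her2", "menopausal",
                                           "tumor_size"),
                            seed = 1L) {
  if (!is.null(fixed_cutoff) &&
      (fixed_cutoff <= 0 || fixed_cutoff >= 100))
    stop_validation("fixed_cutoff must be in (0, 100)")
  if (horizon_months <= 0) stop_validation("horizon_months must be > 0")
  structure(list(image_dir = image_dir, clinical_csv = clinical_csv,
                 output_dir = output_dir,
                 horizon_months = horizon_months,
                 min_group_fraction = min_group_fraction,
                 fixed_cutoff = fixed_cutoff,
                 segmentation = segmentation,
                 age_encoding = match.arg(age_encoding),
                 covariates = covariates, seed = seed),
            class = "tsr_pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json` file
#'   whose keys are [pipeline_config()] arguments.
#' @return A `tsr_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs require the 'yaml' package")
      yaml::read_yaml(path)
    },
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext))
  seg <- do.call(segmentation_config, raw$segmentation %||% list())
  raw$segmentation <- seg
  do.call(pipeline_config, raw)
}

#' Segment every core image in a directory
#'
#' Expects files named `<patient_id>_core<1|2>.png` (or `.tif`). Failures
#' are logged per core, not fatal.
#'
#' @param image_dir Image directory.
#' @param config A [segmentation_config()].
#' @return List with `per_core` (data.frame: patient_id, core_index,
#'   areas, tsr, otsu_threshold, flags), `patient_tsr` (aggregated
#'   minimum-TSR per patient) and `log` (list of exclusion records).
#' @export
segment_directory <- function(image_dir, config = segmentation_config()) {
  files <- list.files(image_dir,
                      pattern = "_core[12]\\.(png|tif|tiff)$",
                      full.names = TRUE)
  if (length(files) == 0)
    stop_validation("no core images found in ", image_dir)
  log <- list(); rows <- list()
  for (f in files) {
    base <- sub("\\.(png|tif|tiff)$", "", basename(f))
    pid <- sub("_core[12]$", "", base)
    core <- as.integer(sub(".*_core([12])$", "\\1", base))
    seg <- tryCatch(segment_core(read_core_image(f), config),
                    error = function(e) e)
    if (inherits(seg, "error")) {
      log[[length(log) + 1]] <- list(stage = "segmentation",
                                     patient_id = pid, core_index = core,
                                     reason = conditionMessage(seg))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = pid, core_index = core,
      area_tissue = seg$area_tissue, area_tumor = seg$area_tumor,
      area_stroma = seg$area_stroma, tsr = seg$tsr,
      otsu_threshold = seg$otsu_threshold,
      orientation_flipped = isTRUE(seg$orientation_flipped),
      stringsAsFactors = FALSE)
  }
  per_core <- do.call(rbind, rows)
  if (is.null(per_core))
    stop_validation("every core failed segmentation")
  agg <- vapply(split(per_core$tsr, per_core$patient_id), min, numeric(1))
  list(per_core = per_core,
       patient_tsr = data.frame(patient_id = names(agg), tsr = unname(agg),
                                stringsAsFactors = FALSE),
       log = log)
}

cox_models_for <- function(data, covariates, label, min_events = 10) {
  # drop covariates that are constant in this (sub)cohort
  usable <- covariates[vapply(covariates, function(cv) {
    x <- data[[cv]]
    !is.null(x) && length(unique(x[!is.na(x)])) >= 2
  }, logical(1))]
  dropped <- setdiff(covariates, usable)
  res <- list(dropped = dropped)
  uni <- lapply(c("tsr_group", "tsr_stroma_per10"), function(term) {
    tryCatch(cox_report(cox_fit(data, covariates = term),
                        model = paste0(label, ":univariate")),
             error = function(e) NULL)
  })
  multi <- lapply(c("tsr_group", "tsr_stroma_per10"), function(term) {
    tryCatch(cox_report(cox_fit(data, covariates = c(term, usable)),
                        model = paste0(label, ":multivariate")),
             error = function(e) NULL)
  })
  res$table <- do.call(rbind, c(uni, multi))
  res
}

#' Run the full TSR pipeline
#'
#' Stages: image segmentation (or a supplied per-patient TSR column) ->
#' two-core aggregation -> administrative censoring at the horizon ->
#' cutoff (maximally selected rank statistic, or `fixed_cutoff`) ->
#' dichotomization -> baseline association report -> Kaplan-Meier curves,
#' log-rank tests and Cox models (TSR categorical and continuous,
#' univariate and multivariate) for the total cohort and the three
#' molecular subtypes. All reports are written under
#' `config$output_dir`; every excluded patient or core appears in the run
#' log with a reason. Deterministic given config and seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional cohort data.frame (otherwise read from
#'   `config$clinical_csv`).
#' @return Invisibly, a list of class `tsr_run_report` with elements
#'   `per_core`, `patient_tsr`, `cutpoint`, `cohort` (analysis rows),
#'   `table1`, `cox`, `km`, `logrank`, `log`, `paths`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "tsr_pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  if (is.null(cohort)) {
    if (is.null(config$clinical_csv))
      stop_validation("either a cohort or clinical_csv is required")
    cohort <- read_cohort_csv(config$clinical_csv)
  }
  cohort <- as.data.frame(cohort)

  per_core <- NULL
  if (!is.null(config$image_dir)) {
    seg <- segment_directory(config$image_dir, config$segmentation)
    per_core <- seg$per_core
    log <- c(log, seg$log)
    cohort$tsr <- NULL
    cohort <- merge(cohort, seg$patient_tsr, by = "patient_id")
  }
  if (is.null(cohort$tsr))
    stop_validation("no TSR available: supply images or a tsr column")

  drop <- is.na(cohort$tsr) | is.na(cohort$time_months) |
    is.na(cohort$event)
  if (any(drop)) {
    for (pid in cohort$patient_id[drop])
      log[[length(log) + 1]] <- list(stage = "validation",
                                     patient_id = pid,
                                     reason = "missing TSR or follow-up")
    cohort <- cohort[!drop, ]
  }
  if (nrow(cohort) < 2) stop_validation(">= 2 analysable patients required")

  cens <- censor_at_horizon(cohort$time_months, cohort$event,
                            config$horizon_months)
  cohort$time_months <- cens$time
  cohort$event <- cens$event

  if (!is.null(config$fixed_cutoff)) {
    cutpoint <- list(selected_cutoff = config$fixed_cutoff,
                     fixed = TRUE)
  } else {
    cutpoint <- max_selected_rank(cohort$tsr, cohort$time_months,
                                  cohort$event,
                                  config$min_group_fraction)
  }
  cohort$tsr_group <- dichotomize(cohort$tsr, cutpoint$selected_cutoff)
  cohort$tsr_stroma_per10 <- continuous_tsr_covariate(cohort$tsr)
  if (is.null(cohort$subtype) && all(c("er", "pr", "her2") %in%
                                     names(cohort)))
    cohort$subtype <- assign_subtype(cohort$er, cohort$pr, cohort$her2)
  cohort$age <- if (config$age_encoding == "binary")
    cohort$age_group else cohort$age_years

  table1 <- build_table1(cohort, cohort$tsr_group)

  groups <- c(list(total = cohort),
              split(cohort, cohort$subtype))
  cox_tabs <- list(); km_tabs <- list(); lr_rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    if (nrow(d) < 10 || sum(d$event) < 5 ||
        nlevels(droplevels(d$tsr_group)) < 2) {
      log[[length(log) + 1]] <- list(stage = "survival", subgroup = g,
                                     reason = "too few patients or events")
      next
    }
    cm <- cox_models_for(d, config$covariates, g)
    if (length(cm$dropped))
      log[[length(log) + 1]] <- list(stage = "cox", subgroup = g,
        reason = paste("constant covariates dropped:",
                       paste(cm$dropped, collapse = ", ")))
    cox_tabs[[g]] <- cm$table
    km <- km_by_group(d$time_months, d$event, d$tsr_group)
    if (!is.null(km)) km$subgroup <- g
    km_tabs[[g]] <- km
    lt <- tryCatch(logrank_test(d$time_months, d$event, d$tsr_group),
                   error = function(e) NULL)
    if (!is.null(lt))
      lr_rows[[g]] <- data.frame(subgroup = g, chi_square = lt$chi_square,
                                 df = lt$df, p = lt$p,
                                 p_formatted = format_pvalue(lt$p),
                                 stringsAsFactors = FALSE)
  }
  cox_table <- do.call(rbind, unname(cox_tabs))
  km_table <- do.call(rbind, unname(km_tabs))
  logrank_table <- do.call(rbind, unname(lr_rows))

  # ---- write reports -------------------------------------------------
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(per_core)) wr(per_core, "per_core_segmentation.csv")
  wr(cohort[, c("patient_id", "tsr", "tsr_group")], "patient_tsr.csv")
  wr(table1, "table1_association.csv")
  if (!is.null(cox_table)) wr(cox_table, "cox_models.csv")
  if (!is.null(km_table)) wr(km_table, "km_curves.csv")
  if (!is.null(logrank_table)) wr(logrank_table, "logrank_tests.csv")
  cp_path <- file.path(config$output_dir, "cutpoint.json")
  jsonlite::write_json(cutpoint[setdiff(names(cutpoint), "fit")],
                       cp_path, auto_unbox = TRUE, digits = NA)
  paths[["cutpoint.json"]] <- cp_path

  cfg_flat <- config
  cfg_flat$segmentation <- unclass(cfg_flat$segmentation)
  cfg_json <- jsonlite::toJSON(unclass(cfg_flat), auto_unbox = TRUE,
                               null = "null", digits = NA)
  cfg_file <- file.path(config$output_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  run_log <- file.path(config$output_dir, "run_log.jsonl")
  lines <- c(
    jsonlite::toJSON(list(stage = "run",
                          r_version = as.character(getRversion()),
                          package_version =
                            as.character(utils::packageVersion("tsrquant")),
                          config_md5 = unname(tools::md5sum(cfg_file)),
                          seed = config$seed,
                          n_patients = nrow(cohort)),
                     auto_unbox = TRUE),
    vapply(log, function(l) as.character(jsonlite::toJSON(l,
                                                 auto_unbox = TRUE)),
           character(1)))
  writeLines(lines, run_log)
  paths[["run_log.jsonl"]] <- run_log

  invisible(structure(list(per_core = per_core,
                           patient_tsr = cohort[, c("patient_id", "tsr",
                                                    "tsr_group")],
                           cutpoint = cutpoint, cohort = cohort,
                           table1 = table1, cox = cox_table,
                           km = km_table, logrank = logrank_table,
                           log = log, paths = paths),
                      class = "tsr_run_report"))
}
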