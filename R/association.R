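# Pearson chi-square association between the TSR group and
# clinicopathological parameters, and the baseline-characteristics report
# built from a cohort.

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`; no Yates continuity correction and no Fisher
#' fallback (cells with expected counts below 5 produce a warning, not a
#' different test).
#'
#' @param counts r x c matrix of non-negative integer counts, at least
#'   2 x 2, without all-zero rows or columns.
#' @return An object of class `tsr_chisq`: `chi_square`, `df`, `p`,
#'   `expected`, `min_expected`, `observed`.
#' @export
chisq_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop_validation("contingency table must be at least 2 x 2")
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (sum(counts) <= 0) stop_validation("grand total must be positive")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_validation("all-zero row or column in contingency table")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  min_exp <- min(res$expected)
  if (min_exp < 5)
    warning(sprintf("minimum expected count %.2f is below 5", min_exp),
            call. = FALSE)
  structure(list(chi_square = unname(res$statistic),
                 df = unname(res$parameter),
                 p = unname(res$p.value),
                 expected = res$expected, min_expected = min_exp,
                 observed = counts),
            class = "tsr_chisq")
}

#' @export
print.tsr_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %s\n",
              x$chi_square, x$df, format_pvalue(x$p)))
  invisible(x)
}

#' Baseline association report (Table-1 style)
#'
#' For each covariate, cross-tabulates its levels against the TSR group,
#' reports per-level counts with within-group percentages (denominator =
#' group size, rounded to one decimal as conventionally printed) and the
#' uncorrected Pearson chi-square with its p-value. Covariates with a
#' single observed level are skipped with a warning.
#'
#' @param cohort data.frame with the covariate columns.
#' @param group Factor of TSR groups (levels stroma-low, stroma-high).
#' @param covariates Character vector of covariate column names.
#' @return data.frame with one row per covariate level; the chi-square and
#'   p are attached to each covariate's rows. The underlying `tsr_chisq`
#'   objects are available as `attr(, "tests")`.
#' @export
build_table1 <- function(cohort, group,
                         covariates = c("age_group", "grade", "subtype",
                                        "nodal", "er", "her2", "pr",
                                        "menopausal", "tumor_size")) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2)
    stop_validation("need at least two TSR groups")
  gsize <- table(group)
  rows <- list(); tests <- list()
  for (cv in covariates) {
    x <- droplevels(as.factor(cohort[[cv]]))
    if (nlevels(x) < 2) {
      warning("covariate '", cv, "' has a single observed level; skipped",
              call. = FALSE)
      next
    }
    tab <- table(x, group)  # levels x groups
    ct <- chisq_table(tab)
    tests[[cv]] <- ct
    rows[[cv]] <- data.frame(
      characteristic = cv, level = rownames(tab),
      n_total = as.integer(rowSums(tab)),
      n_stroma_low = as.integer(tab[, 1]),
      pct_stroma_low = round(100 * tab[, 1] / gsize[1], 1),
      n_stroma_high = as.integer(tab[, 2]),
      pct_stroma_high = round(100 * tab[, 2] / gsize[2], 1),
      chi_square = ct$chi_square, p = ct$p,
      p_formatted = format_pvalue(ct$p),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  attr(out, "group_sizes") <- gsize
  out
}

#' Published reference counts for the association module
#'
#' Cross-tabulated counts of TSR group (stroma-low / stroma-high at the
#' 33.5 percent cutoff) against nine clinicopathological parameters,
#' transcribed from the published baseline table of a 240-patient
#' breast-cancer TMA cohort. Shipped as plain-text CSV in
#' `inst/extdata/reference_table1_counts.csv`; used to validate the
#' chi-square route against the printed statistics.
#'
#' @return Named list of level x group count matrices.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_table1_counts.csv",
                      package = "tsrquant", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, factor(df$characteristic,
                                 levels = unique(df$characteristic))),
                function(d) {
    m <- as.matrix(d[, c("stroma_low", "stroma_high")])
    rownames(m) <- d$level
    m
  })
  out
}
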