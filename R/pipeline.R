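# End-to-end orchestration: validation -> income imputation -> ranking ->
# indices -> decomposition -> descriptive tables, with delimited-text
# outputs and a run log.

#' Analysis configuration
#'
#' Collects everything [run_full_analysis()] needs. Paths may point at
#' files written by [generate_population()] + [readr::write_csv()] or at
#' any delimited extract following [survey_dictionary()].
#'
#' @param input_path CSV of respondent records (canonical columns).
#' @param cpi_table_path Two-column CSV `year,cpi` with the consumer price
#'   index of every survey year and of `base_year`.
#' @param output_dir Directory for the output tables and run log.
#' @param base_year Price-level base year for equivalised income.
#' @param band_bounds Interior income band bounds (currency), length 9.
#' @param strata Data frame with columns `sex` and `year` listing the
#'   stratified models to fit; `NULL` fits every sex-year cell present.
#' @param cesd_cutoff CES-D score at and above which a respondent is coded
#'   as having depressive tendency (default 10).
#' @param income_floor Lower clamp for predicted income (currency).
#' @param seed Integer seed (recorded in the log; the estimation itself is
#'   deterministic).
#' @param variable_map Optional named character vector mapping canonical
#'   column names to the input file's column names.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(input_path, cpi_table_path, output_dir,
                            base_year = 2009L,
                            band_bounds = 3000 * 2^(0:8),
                            strata = NULL, cesd_cutoff = 10L,
                            income_floor = 1, seed = 1L,
                            variable_map = NULL) {
  cfg <- list(input_path = input_path, cpi_table_path = cpi_table_path,
              output_dir = output_dir, base_year = as.integer(base_year),
              band_bounds = band_bounds, strata = strata,
              cesd_cutoff = as.integer(cesd_cutoff),
              income_floor = income_floor, seed = as.integer(seed),
              variable_map = variable_map)
  if (!is.null(strata) && !all(c("sex", "year") %in% names(strata))) {
    abort_ui("`strata` must have `sex` and `year` columns.",
             "utilineq_error_validation")
  }
  if (!is.null(strata) && !all(strata$sex %in% factor_levels$sex)) {
    abort_ui(sprintf("Unknown stratum sex label(s): %s",
                     paste(setdiff(strata$sex, factor_levels$sex),
                           collapse = ", ")),
             "utilineq_error_validation")
  }
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$strata)) y$strata <- dplyr::bind_rows(y$strata)
  do.call(analysis_config, y)
}

#' Load and validate a survey extract
#'
#' Reads a delimited respondent file, renames columns through the optional
#' variable map, checks every canonical column is present with legal
#' categories, derives the depression indicator from the CES-D score, and
#' listwise-deletes records with missing model variables (counts per
#' variable are reported as a warning and in the returned attribute
#' `"missing_counts"`).
#'
#' @param path CSV file of respondent records.
#' @param variable_map Optional named character vector, canonical name ->
#'   input column name.
#' @param cesd_cutoff CES-D cutoff for the depression indicator.
#' @return Validated tibble with canonical types; attribute
#'   `"missing_counts"` holds per-variable missing-value counts.
#' @export
load_survey <- function(path, variable_map = NULL, cesd_cutoff = 10L) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(variable_map)) {
    raw <- dplyr::rename(raw, !!!rlang::set_names(unname(variable_map),
                                                  names(variable_map)))
  }
  validate_survey(raw, cesd_cutoff = cesd_cutoff)
}

#' Validate an in-memory survey table
#'
#' @param data Data frame of respondent records (canonical column names).
#' @inheritParams load_survey
#' @return Validated tibble; see [load_survey()].
#' @export
validate_survey <- function(data, cesd_cutoff = 10L) {
  dict <- survey_dictionary()
  needed <- setdiff(dict$variable, "depressed")  # derivable from cesd_score
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort_ui(paste0("Input is missing canonical column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "utilineq_error_validation")
  }
  d <- tibble::as_tibble(data)
  for (v in names(factor_levels)) {
    vals <- as.character(d[[v]])
    bad <- !is.na(vals) & !vals %in% factor_levels[[v]]
    if (any(bad)) {
      i <- which(bad)[1]
      abort_ui(sprintf(
        "Illegal category \"%s\" in column `%s` (first at row %d); legal: %s",
        vals[i], v, i, paste(factor_levels[[v]], collapse = ", ")),
        "utilineq_error_validation")
    }
    d[[v]] <- factor(vals, levels = factor_levels[[v]])
  }
  for (v in c("outpatient_use", "married_ever", "chronic_disease",
              "mobility_difficulty", "exercise_2wk")) {
    if (!all(d[[v]] %in% c(0, 1) | is.na(d[[v]]))) {
      abort_ui(sprintf("Column `%s` must be binary 0/1.", v),
               "utilineq_error_validation")
    }
  }
  if (any(!is.na(d$weight) & d$weight <= 0)) {
    abort_ui("Column `weight` must be strictly positive.",
             "utilineq_error_validation")
  }
  if (any(!is.na(d$income_band) & (d$income_band < 1 | d$income_band > 10))) {
    abort_ui("Column `income_band` must lie in 1..10.",
             "utilineq_error_validation")
  }
  d$depressed <- as.integer(d$cesd_score >= cesd_cutoff)

  model_vars <- setdiff(survey_dictionary()$variable, "cesd_score")
  miss <- vapply(d[model_vars], function(x) sum(is.na(x)), integer(1))
  keep <- stats::complete.cases(d[model_vars])
  if (any(!keep)) {
    warning(sprintf(
      "Listwise deletion of %d record(s) with missing model variables (%s).",
      sum(!keep),
      paste(sprintf("%s: %d", names(miss[miss > 0]), miss[miss > 0]),
            collapse = ", ")))
  }
  out <- d[keep, ]
  if (nrow(out) == 0L) {
    abort_ui("No complete records remain after listwise deletion.",
             "utilineq_error_validation")
  }
  attr(out, "missing_counts") <- miss
  out
}

#' Descriptive cross-tabulations with chi-square tests
#'
#' For each categorical explanatory variable, cross-tabulates outpatient
#' use against non-use (unweighted counts with row percentages) and
#' reports the Pearson chi-square statistic without continuity correction
#' and its p value — the goodness-of-fit layout of a survey descriptives
#' table.
#'
#' @param data One survey wave of canonical records.
#' @param variables Character vector of columns to tabulate.
#' @return A tibble with columns `variable`, `category`, `n_use`,
#'   `pct_use`, `n_nonuse`, `pct_nonuse`, `chi_square`, `p_value` (the test
#'   statistic repeated on each row of its variable; `NA` when a margin is
#'   empty).
#' @export
descriptive_summary <- function(data,
                                variables = c("sex", "age_group",
                                              "married_ever", "education",
                                              "self_rated_health",
                                              "chronic_disease",
                                              "mobility_difficulty",
                                              "depressed", "exercise_2wk",
                                              "region", "physician_band")) {
  if (nrow(data) == 0L) {
    abort_ui("Cannot summarise an empty stratum.", "utilineq_error_domain")
  }
  purrr::map_dfr(variables, function(v) {
    tab <- table(data[[v]], factor(data$outpatient_use, levels = c(1, 0)))
    stat <- p <- NA_real_
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) && nrow(tab) > 1) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic)
      p <- ct$p.value
    }
    tibble::tibble(
      variable = v,
      category = rownames(tab),
      n_use = as.integer(tab[, 1]),
      pct_use = as.numeric(100 * tab[, 1] / pmax(rowSums(tab), 1)),
      n_nonuse = as.integer(tab[, 2]),
      pct_nonuse = as.numeric(100 * tab[, 2] / pmax(rowSums(tab), 1)),
      chi_square = stat,
      p_value = p
    )
  })
}

#' Pearson chi-square from a 2 x k count table
#'
#' Convenience wrapper used for checking printed descriptive tables:
#' Pearson's statistic without continuity correction.
#'
#' @param counts Matrix (or vector coercible to a 2-row matrix, filled by
#'   row) of cross-tab counts.
#' @return A one-row tibble with `chi_square`, `df`, `p_value`.
#' @examples
#' chi_square_counts(c(795, 729, 505, 386))  # 2x2, by row
#' @export
chi_square_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(chi_square = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

read_cpi_table <- function(path, years_needed) {
  cpi <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("year", "cpi") %in% names(cpi))) {
    abort_ui("CPI table must have columns `year` and `cpi`.",
             "utilineq_error_validation")
  }
  missing_years <- setdiff(years_needed, cpi$year)
  if (length(missing_years)) {
    abort_ui(paste0("CPI table lacks year(s): ",
                    paste(missing_years, collapse = ", ")),
             "utilineq_error_validation")
  }
  if (any(cpi$cpi <= 0)) {
    abort_ui("CPI values must be positive.", "utilineq_error_validation")
  }
  cpi
}

#' Run the full inequality analysis
#'
#' Orchestrates the pipeline over every configured sex-year stratum:
#' validation, interval-regression income imputation, modified-OECD
#' equivalisation, CPI rescaling to the base year, fractional ranking,
#' concentration indices with Erreygers correction, cross-year index
#' comparisons, probit decomposition, and descriptive tables. All outputs
#' are delimited text plus a run log; a failed stage removes any partial
#' outputs before rethrowing.
#'
#' @param config An [analysis_config()].
#' @return (Invisibly) a list with elements `descriptives`, `indices`,
#'   `comparisons`, `decompositions` (named `<sex>_<year>`), and the
#'   output `files` written.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail <- function(stage, err) {
    file.remove(written[file.exists(written)])
    abort_ui(sprintf("Pipeline failed at stage \"%s\": %s", stage,
                     conditionMessage(err)),
             "utilineq_error_pipeline", parent = err)
  }
  emit <- function(x, name) {
    path <- file.path(config$output_dir, name)
    readr::write_csv(x, path)
    written <<- c(written, path)
    path
  }
  set.seed(config$seed)

  data <- tryCatch(
    load_survey(config$input_path, config$variable_map, config$cesd_cutoff),
    error = function(e) on_fail("load_and_validate", e))
  strata <- config$strata %||%
    dplyr::distinct(dplyr::count(data, sex, year)[c("sex", "year")])
  cpi <- tryCatch(
    read_cpi_table(config$cpi_table_path,
                   unique(c(strata$year, config$base_year))),
    error = function(e) on_fail("cpi_table", e))
  cpi_of <- function(y) cpi$cpi[match(y, cpi$year)]

  descriptives <- tryCatch(
    purrr::map_dfr(unique(strata$year), function(y) {
      dplyr::mutate(descriptive_summary(dplyr::filter(data, year == y)),
                    year = y, .before = 1)
    }),
    error = function(e) on_fail("descriptive_summary", e))
  emit(descriptives, "table1_descriptives.csv")

  results <- purrr::pmap(strata, function(sex, year, ...) {
    s <- sex; y <- year
    tryCatch(
      analyse_stratum(dplyr::filter(data, sex == s, year == y),
                      band_bounds = config$band_bounds,
                      cpi_survey_year = cpi_of(y),
                      cpi_base_year = cpi_of(config$base_year)),
      error = function(e) on_fail(sprintf("analyse_%s_%s", s, y), e))
  })
  names(results) <- sprintf("%s_%s", strata$sex, strata$year)

  indices <- purrr::imap_dfr(results, function(res, nm) {
    dplyr::mutate(attr(res, "concentration"),
                  stratum = nm, sex = strsplit(nm, "_")[[1]][1],
                  year = as.integer(strsplit(nm, "_")[[1]][2]), .before = 1)
  })
  comparisons <- purrr::map_dfr(unique(strata$sex), function(s) {
    yrs <- sort(unique(strata$year[strata$sex == s]))
    if (length(yrs) < 2) return(tibble::tibble())
    a <- indices[indices$sex == s & indices$year == yrs[1], ]
    b <- indices[indices$sex == s & indices$year == yrs[2], ]
    dplyr::mutate(compare_indices(a, b), sex = s,
                  year_a = yrs[1], year_b = yrs[2], .before = 1)
  })
  emit(indices, "table2_indices.csv")
  if (nrow(comparisons)) emit(comparisons, "table2_comparison.csv")

  for (nm in names(results)) {
    out <- dplyr::bind_rows(
      tidy(results[[nm]]),
      tibble::tibble(term = "residual",
                     contribution = attr(results[[nm]], "residual")),
      tibble::tibble(term = "total_corrected_ci",
                     contribution = attr(results[[nm]], "total"))
    )
    emit(out, sprintf("table3_decomposition_%s.csv", nm))
  }

  log_path <- file.path(config$output_dir, "run.log")
  cfg_flat <- utils::capture.output(utils::str(unclass(config)))
  writeLines(c(
    sprintf("utilineq %s", as.character(utils::packageVersion("utilineq"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed: %d", config$seed),
    sprintf("config hash: %s", rlang::hash(unclass(config))),
    sprintf("records analysed: %d", nrow(data)),
    sprintf("strata: %s", paste(names(results), collapse = ", ")),
    "config:", cfg_flat
  ), log_path)
  written <- c(written, log_path)

  invisible(list(descriptives = descriptives, indices = indices,
                 comparisons = comparisons, decompositions = results,
                 files = written))
}
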