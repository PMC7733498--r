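#' Study-design and estimator labels
#'
#' `design_labels()` returns the six study-design categories used to classify
#' intervention studies: uncontrolled designs (`After`, `BA`), controlled
#' observational designs (`CI`, `BACI`) and their randomised counterparts
#' (`R-CI`, `R-BACI`). `estimator_labels()` returns the four within-study
#' effect estimators that can be mimicked inside a (R-)BACI dataset, in the
#' fixed column order used throughout the package:
#' `BACI_DiD` (difference in differences), `BACI_CA` (covariance adjustment),
#' `CI` and `BA`.
#'
#' @return A character vector of labels.
#' @export
design_labels <- function() {
  c("After", "BA", "CI", "BACI", "R-CI", "R-BACI")
}

#' @rdname design_labels
#' @export
estimator_labels <- function() {
  c("BACI_DiD", "BACI_CA", "CI", "BA")
}

#' Classify a study design from its three defining components
#'
#' A study design is determined by whether a control group was monitored,
#' whether sampling took place before the impact occurred, and whether
#' replicates were randomly allocated to the impact and control groups.
#' The six valid combinations map one-to-one onto the labels of
#' [design_labels()]. Randomisation without a control group is not a design:
#' no randomised equivalents of the uncontrolled After and BA designs exist.
#'
#' @param controlled logical: was a control group sampled?
#' @param before_sampling logical: was sampling conducted before the impact?
#' @param randomised logical: were replicates randomly allocated to groups?
#'
#' @return A character vector of design labels (one per input triple).
#' @examples
#' classify_design(FALSE, FALSE, FALSE)  # "After"
#' classify_design(TRUE, TRUE, TRUE)     # "R-BACI"
#' @export
classify_design <- function(controlled, before_sampling, randomised) {
  stopifnot(is.logical(controlled), is.logical(before_sampling),
            is.logical(randomised))
  n <- max(length(controlled), length(before_sampling), length(randomised))
  controlled <- rep_len(controlled, n)
  before_sampling <- rep_len(before_sampling, n)
  randomised <- rep_len(randomised, n)
  if (anyNA(controlled) || anyNA(before_sampling) || anyNA(randomised))
    db_stop("InvalidDesign", "design components must be TRUE or FALSE, not NA")
  if (any(randomised & !controlled))
    db_stop("InvalidDesign",
            "randomised = TRUE requires controlled = TRUE (uncontrolled designs have no randomised equivalent)")
  out <- ifelse(!controlled,
                ifelse(before_sampling, "BA", "After"),
                ifelse(randomised,
                       ifelse(before_sampling, "R-BACI", "R-CI"),
                       ifelse(before_sampling, "BACI", "CI")))
  out
}

#' Prevalence of study designs across a literature
#'
#' Summarises how often each study design occurs in a collection of
#' classified studies. Two modes mirror the two ways large literatures are
#' summarised: `"absolute"` pools all studies into a single set of
#' proportions; `"per_source_mean"` computes the proportion of each design
#' within every source (e.g. each systematic review) and reports the mean
#' across sources with a Student-t 95% confidence interval.
#'
#' @param design character vector of design labels (see [design_labels()]).
#' @param source optional vector identifying the source (review/database) of
#'   each study; required for `mode = "per_source_mean"`.
#' @param mode `"absolute"` or `"per_source_mean"`.
#' @param conf_level confidence level for the per-source interval.
#'
#' @return A data frame with columns `design`, `proportion`, `ci_low`,
#'   `ci_high` and `source_n`. In absolute mode the interval columns are `NA`
#'   and the proportions sum to 1.
#' @export
prevalence_summary <- function(design, source = NULL,
                               mode = c("absolute", "per_source_mean"),
                               conf_level = 0.95) {
  mode <- match.arg(mode)
  if (length(design) == 0L)
    db_stop("EmptyInput", "no studies supplied")
  bad <- setdiff(unique(design), design_labels())
  if (length(bad))
    db_stop("InvalidDesign",
            paste0("unknown design label(s): ", paste(bad, collapse = ", ")))
  labs <- design_labels()
  if (mode == "absolute") {
    tab <- table(factor(design, levels = labs))
    out <- data.frame(design = labs,
                      proportion = as.numeric(tab) / length(design),
                      ci_low = NA_real_, ci_high = NA_real_,
                      source_n = if (is.null(source)) 1L
                                 else length(unique(source)),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(source))
    db_stop("SingleSource", "per_source_mean requires a 'source' vector")
  source <- rep_len(source, length(design))
  srcs <- unique(source)
  if (length(srcs) < 2L)
    db_stop("SingleSource", "per_source_mean requires at least 2 sources")
  # per-source proportion of each design, then mean +/- t interval
  props <- sapply(srcs, function(s) {
    d <- design[source == s]
    as.numeric(table(factor(d, levels = labs))) / length(d)
  })  # labs x sources
  m <- rowMeans(props)
  se <- apply(props, 1L, sd) / sqrt(length(srcs))
  tq <- qt(1 - (1 - conf_level) / 2, df = length(srcs) - 1L)
  data.frame(design = labs, proportion = m,
             ci_low = m - tq * se, ci_high = m + tq * se,
             source_n = length(srcs), stringsAsFactors = FALSE)
}

## ---- monitoring data ------------------------------------------------------

measure_levels <- function() c("count", "density", "percentage", "size")

monitoring_columns <- function() {
  c("dataset_id", "response_id", "measure", "randomised", "site",
    "subsample", "treatment", "period", "time", "value")
}

#' Construct a response dataset
#'
#' A response dataset holds all monitoring records for one response variable
#' within one dataset: the unit whose true effect the design estimators try
#' to recover. Records carry the site/subsample sampling structure, the
#' control/impact treatment arm, the before/after period and a numeric value
#' whose family is set by `measure`.
#'
#' @param records data frame with columns `dataset_id`, `response_id`,
#'   `measure`, `randomised`, `site`, `subsample`, `treatment`, `period`,
#'   `time`, `value`.
#' @param validate check invariants (non-negative counts, percentages in
#'   \[0, 100\], a single measure, valid enums)?
#'
#' @return An object of class `response_dataset`: a list with elements
#'   `response_id`, `dataset_id`, `measure`, `randomised` and `records`.
#' @export
response_dataset <- function(records, validate = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(monitoring_columns(), names(records))
  if (length(missing_cols))
    db_stop("MissingColumn",
            paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  records <- records[monitoring_columns()]
  records$treatment <- as.character(records$treatment)
  records$period <- as.character(records$period)
  if (validate) validate_monitoring_records(records)
  structure(list(response_id = as.character(records$response_id[1L]),
                 dataset_id = as.character(records$dataset_id[1L]),
                 measure = as.character(records$measure[1L]),
                 randomised = isTRUE(records$randomised[1L]),
                 records = records),
            class = "response_dataset")
}

validate_monitoring_records <- function(records) {
  if (nrow(records) == 0L)
    db_stop("EmptyInput", "no monitoring records")
  if (length(unique(records$response_id)) != 1L)
    db_stop("InvalidRecords", "records must all share one response_id")
  if (length(unique(records$measure)) != 1L)
    db_stop("InvalidRecords", "records must all share one measure")
  meas <- records$measure[1L]
  if (!meas %in% measure_levels())
    db_stop("UnknownMeasure", paste0("unknown measure: ", meas))
  if (!all(records$treatment %in% c("control", "impact")))
    db_stop("InvalidRecords", "treatment must be 'control' or 'impact'")
  if (!all(records$period %in% c("before", "after")))
    db_stop("InvalidRecords", "period must be 'before' or 'after'")
  if (anyNA(records$value))
    db_stop("InvalidRecords", "missing values in 'value'")
  if (meas %in% c("count", "density", "percentage") && any(records$value < 0))
    db_stop("NegativeValue",
            paste0("negative values are invalid for measure '", meas, "'"))
  if (meas == "percentage" && any(records$value > 100))
    db_stop("InvalidRecords", "percentage values must lie in [0, 100]")
  if (meas == "count" && any(abs(records$value - round(records$value)) > 1e-8))
    db_stop("InvalidRecords", "count values must be non-negative integers")
  invisible(TRUE)
}

#' @export
print.response_dataset <- function(x, ...) {
  cat("<response_dataset> ", x$dataset_id, "/", x$response_id,
      "  (", x$measure, if (x$randomised) ", randomised" else "", ")\n", sep = "")
  cnt <- subset_counts(x)
  cat("  records:", nrow(x$records), " sites:",
      length(unique(x$records$site)), "\n")
  cat("  cells (n): BC=", cnt["before.control"], " BI=", cnt["before.impact"],
      " AC=", cnt["after.control"], " AI=", cnt["after.impact"], "\n", sep = "")
  invisible(x)
}

# record counts in the four period x treatment cells
subset_counts <- function(d) {
  r <- d$records
  out <- c(before.control = sum(r$period == "before" & r$treatment == "control"),
           before.impact = sum(r$period == "before" & r$treatment == "impact"),
           after.control = sum(r$period == "after" & r$treatment == "control"),
           after.impact = sum(r$period == "after" & r$treatment == "impact"))
  out
}

#' Read a long-format monitoring CSV
#'
#' Reads a monitoring table with one row per measurement and the ten
#' standard columns (`dataset_id`, `response_id`, `measure`, `randomised`,
#' `site`, `subsample`, `treatment`, `period`, `time`, `value`), validates
#' it, and splits it into one [response_dataset()] per response. A
#' validation report (flags for empty period/treatment cells and for
#' responses without repeated measurements per site) is attached as the
#' `"validation"` attribute; flagged responses are kept, not dropped —
#' exclusion is a separate, explicit step ([apply_exclusion_filter()]).
#'
#' @param path path to a CSV file (UTF-8, `.` decimal separator).
#' @param schema_config optional named character vector mapping standard
#'   column names to the names used in the file, e.g.
#'   `c(value = "abundance")`.
#'
#' @return A list of `response_dataset` objects with attribute
#'   `"validation"` (a data frame of response-level flags).
#' @export
read_monitoring_csv <- function(path, schema_config = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema_config)) {
    for (std in names(schema_config)) {
      j <- match(schema_config[[std]], names(raw))
      if (!is.na(j)) names(raw)[j] <- std
    }
  }
  missing_cols <- setdiff(monitoring_columns(), names(raw))
  if (length(missing_cols))
    db_stop("MissingColumn",
            paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  raw$randomised <- as.logical(raw$randomised)
  raw$time <- as.integer(raw$time)
  raw$value <- as.numeric(raw$value)
  key <- interaction(raw$dataset_id, raw$response_id, drop = TRUE)
  datasets <- lapply(split(raw, key), response_dataset)
  names(datasets) <- vapply(datasets, function(d)
    paste(d$dataset_id, d$response_id, sep = "/"), character(1L))
  flags <- do.call(rbind, lapply(datasets, function(d) {
    cnt <- subset_counts(d)
    per_site_before <- with(d$records[d$records$period == "before", , drop = FALSE],
                            if (length(site)) mean(table(site)) else 0)
    per_site_after <- with(d$records[d$records$period == "after", , drop = FALSE],
                           if (length(site)) mean(table(site)) else 0)
    data.frame(dataset_id = d$dataset_id, response_id = d$response_id,
               empty_cells = sum(cnt == 0L),
               repeated_measurements = per_site_before >= 2 && per_site_after >= 2,
               stringsAsFactors = FALSE)
  }))
  rownames(flags) <- NULL
  if (any(flags$empty_cells > 0L))
    db_warn("ValidationFlag",
            paste0(sum(flags$empty_cells > 0L),
                   " response(s) have empty period x treatment cells"))
  if (any(!flags$repeated_measurements))
    db_warn("ValidationFlag",
            paste0(sum(!flags$repeated_measurements),
                   " response(s) lack repeated measurements per site in both periods"))
  attr(datasets, "validation") <- flags
  datasets
}

#' Write response datasets back to a monitoring CSV
#'
#' Inverse of [read_monitoring_csv()]: concatenates the records of the given
#' response datasets into one long-format table.
#'
#' @param datasets a `response_dataset` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(datasets, path) {
  if (inherits(datasets, "response_dataset")) datasets <- list(datasets)
  tab <- do.call(rbind, lapply(datasets, `[[`, "records"))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
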