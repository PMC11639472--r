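#' Packaged survival and epidemic-count datasets
#'
#' Three published datasets, shipped verbatim as single-column CSV files:
#' \describe{
#'   \item{`bladder_cancer`}{remission times (months) of 128 bladder-cancer
#'     patients; a classic heavy-tailed survival benchmark.}
#'   \item{`pakistan_covid_cases`}{daily confirmed COVID-19 cases in
#'     Pakistan over 36 days (March-April 2020).}
#'   \item{`who_covid_deaths`}{daily COVID-19 fatalities reported to the
#'     WHO for 104 countries on 26 October 2021.  Note: the descriptive
#'     statistics sometimes quoted alongside this dataset (mean 94.64,
#'     sd 538.86) are inconsistent with the values themselves (which have
#'     mean 42.96, sd 100.33); the data are shipped as printed and
#'     [descriptive_stats()] reports what they imply.}
#' }
#'
#' @param name one of `"bladder_cancer"`, `"pakistan_covid_cases"`,
#'   `"who_covid_deaths"`.
#' @return A numeric vector of positive observations, with attribute
#'   `label` set to the dataset name.
#' @examples
#' length(nefr_data("bladder_cancer"))
#' descriptive_stats(nefr_data("pakistan_covid_cases"))
#' @export
nefr_data <- function(name) {
  registry <- c("bladder_cancer", "pakistan_covid_cases", "who_covid_deaths")
  if (!is.character(name) || length(name) != 1L || !(name %in% registry)) {
    stop("unknown dataset; available: ", paste(registry, collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "nefr",
                      mustWork = TRUE)
  x <- read_sample(path)
  attr(x, "label") <- name
  x
}

#' Read a univariate sample from a delimited text file
#'
#' Reads one numeric column of strictly positive values from a CSV or
#' plain-text file.  A header line is auto-detected (a first field that
#' does not parse as a number is treated as a column name).
#'
#' @param path path to the file.
#' @param column column name or index to read (default: first column).
#' @param delimiter field delimiter (default comma; use `""` for
#'   whitespace).
#' @return Numeric vector of positive values.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("value", "1.5", "2.5"), f)
#' read_sample(f)
#' @export
read_sample <- function(path, column = 1L, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, if (nzchar(delimiter)) delimiter else "[[:space:]]+")[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(fields))))
  df <- utils::read.table(path, header = header, sep = delimiter,
                          stringsAsFactors = FALSE)
  if (is.character(column)) {
    if (!(column %in% names(df))) {
      stop("column '", column, "' not found; available: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    }
    x <- df[[column]]
  } else {
    x <- df[[as.integer(column)]]
  }
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x))))[1]
    stop(sprintf("non-numeric entry in row %d: %s", bad, x[bad]), call. = FALSE)
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive or missing value in row %d: %s",
                 bad[1], format(x[bad[1]])), call. = FALSE)
  }
  x
}

#' Write a report or sample to CSV or JSON
#'
#' Serialises a named vector, list, fitted-model summary or data frame to
#' disk with a fixed key order.  JSON output requires the 'jsonlite'
#' package.
#'
#' @param x a named numeric vector, list, data frame, `nefr_fit` or
#'   `nefr_gof` object.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param digits significant digits for CSV output (`NA` for full
#'   precision).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_report(c(a = 1, b = 2), f)
#' readLines(f)
#' @export
write_report <- function(x, path, format = c("csv", "json"), digits = 6) {
  format <- match.arg(format)
  if (inherits(x, "nefr_fit")) {
    x <- c(as.list(x$par),
           list(se_alpha = x$se[["alpha"]], se_beta = x$se[["beta"]]),
           if (x$distribution == "nefr") list(se_lambda = x$se[["lambda"]]),
           list(objective = x$objective, loglik = x$loglik,
                method = x$method, distribution = x$distribution, n = x$n))
  } else if (inherits(x, "nefr_gof")) {
    x <- c(as.list(x$tau), list(n = x$n, k = x$k))
  }
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("JSON output requires the 'jsonlite' package", call. = FALSE)
    }
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (is.data.frame(x)) {
      utils::write.csv(x, path, row.names = FALSE)
    } else {
      vals <- vapply(x, function(v) {
        if (is.numeric(v) && !is.na(digits)) format(signif(v, digits)) else
          as.character(v)
      }, character(1))
      utils::write.csv(data.frame(key = names(x), value = unname(vals)),
                       path, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Tabulated reference mean-squared errors for the estimator comparison
#'
#' Reference Monte-Carlo MSE values for the four estimation methods across
#' the six simulation scenarios and ten sample sizes of the estimator
#' comparison study (720 cells: 6 scenarios x 10 sample sizes x 4 methods
#' x 3 parameters, each with the reported mean, relative bias and MSE).
#' Used by the rank-aggregation utilities to reproduce the published
#' method ordering; see [rank_methods()].
#'
#' @return A data frame with columns `scenario`, `alpha`, `beta`, `lambda`
#'   (true values), `n`, `method`, `parameter`, `mean`, `rbias`, `mse`.
#' @examples
#' ref <- reference_sim_table()
#' rank_methods(ref)$totals_per_cell
#' @export
reference_sim_table <- function() {
  path <- system.file("extdata", "reference_sim_mse.csv", package = "nefr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
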