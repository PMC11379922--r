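#' Construct and validate a sample table
#'
#' A sample table holds per-sample measured indicator values for one or
#' more plots: a `plot_id` column, a `sample_id` column and one numeric
#' column per indicator. Columns are reordered to the canonical indicator
#' order of `specs`. Validation rejects duplicate (plot_id, sample_id)
#' keys, non-finite values, negative concentrations, and pH outside
#' (0, 14).
#'
#' @param df A data frame with `plot_id`, `sample_id` and indicator columns.
#' @param specs Named list of [indicator_spec]; defines the expected
#'   indicator columns and their order.
#' @return A `sample_table` (a validated data frame).
#' @export
sample_table <- function(df, specs = default_indicator_specs()) {
  ind <- names(specs)
  missing <- setdiff(c("plot_id", "sample_id", ind), names(df))
  if (length(missing) > 0) {
    stop_mdsqi("missing column(s): ", paste(missing, collapse = ", "),
               class = "schema_error")
  }
  df <- df[, c("plot_id", "sample_id", ind)]
  df$plot_id <- as.character(df$plot_id)
  df$sample_id <- as.character(df$sample_id)
  for (j in ind) {
    if (!is.numeric(df[[j]])) {
      stop_mdsqi("column '", j, "' is not numeric", class = "parse_error")
    }
  }
  key <- paste(df$plot_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("plot_id", "sample_id"), drop = FALSE]
    stop_mdsqi("duplicate (plot_id, sample_id) key: ",
               paste(dup$plot_id[1], dup$sample_id[1]),
               class = "validation_error")
  }
  vals <- as.matrix(df[, ind])
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop_mdsqi("non-finite value at row ", bad[1], ", indicator '",
               ind[bad[2]], "'", class = "validation_error")
  }
  for (j in ind) {
    if (j == "pH") {
      if (any(df[[j]] <= 0 | df[[j]] >= 14)) {
        stop_mdsqi("pH values must lie in (0, 14)",
                   class = "validation_error")
      }
    } else if (any(df[[j]] < 0)) {
      stop_mdsqi("negative value in indicator '", j, "'",
                 class = "validation_error")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from a CSV file
#'
#' Expects a comma-separated file with a header row containing `plot_id`,
#' `sample_id` and one column per indicator in `specs` (any column order;
#' output is normalised to the canonical order).
#'
#' @param path Path to a CSV file.
#' @param specs Named list of [indicator_spec].
#' @return A validated [sample_table].
#' @export
read_sample_table <- function(path, specs = default_indicator_specs()) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  ind <- intersect(names(specs), names(df))
  for (j in ind) {
    if (is.character(df[[j]])) {
      suppressWarnings(num <- as.numeric(df[[j]]))
      bad <- which(is.na(num) & !is.na(df[[j]]) & nzchar(df[[j]]))
      if (length(bad) > 0) {
        stop_mdsqi("non-numeric cell at row ", bad[1], ", column '", j,
                   "': '", df[[j]][bad[1]], "'", class = "parse_error")
      }
      df[[j]] <- num
    }
  }
  sample_table(df, specs)
}

#' Write a table to CSV
#'
#' Writes any of the package's tabular objects (sample tables, membership
#' tables, plot summaries, weight tables, ...) as comma-separated text
#' with a header row. Numeric values round-trip losslessly through
#' [read_sample_table()] at better than 12 significant digits.
#'
#' @param table A data frame (possibly classed).
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  df <- as.data.frame(table)
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) {
      stop_mdsqi("cannot write to '", path, "': ", conditionMessage(e),
                 class = "io_error")
    }
  )
  invisible(path)
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples, %d plots, %d indicators\n",
              nrow(x), length(unique(x$plot_id)), ncol(x) - 2L))
  print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

# numeric indicator matrix (samples x indicators) from a sample_table
indicator_matrix <- function(samples) {
  ind <- setdiff(names(samples), c("plot_id", "sample_id"))
  m <- as.matrix(as.data.frame(samples)[, ind, drop = FALSE])
  rownames(m) <- paste(samples$plot_id, samples$sample_id, sep = ":")
  m
}
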