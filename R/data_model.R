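#' Assemble a count-data dataset
#'
#' Bundles a rectangular table of observations into the container the rest of
#' the package works with: one non-negative integer response (events per unit,
#' e.g. crashes per road segment), a set of numeric candidate contributing
#' factors, and an optional log-exposure offset.
#'
#' Non-numeric candidate columns are dropped with a warning (the analyst is
#' expected to prepare dummies beforehand). Missing values in the response or
#' in any retained factor are an error: the estimation engine has no notion of
#' imputation.
#'
#' @param data A data frame: the response column plus candidate factors.
#' @param response Name of the response column.
#' @param offset Optional name of a column holding a log-exposure offset, or a
#'   numeric vector of length `nrow(data)`.
#' @return An object of class `count_dataset` with elements `response`
#'   (integer vector), `factors` (tibble of numeric candidates), `offset`
#'   (numeric vector or `NULL`), `response_name` and `n`.
#' @examples
#' d <- count_dataset(data.frame(y = c(0, 1, 2), A = 1:3, B = c(2, 1, 0)), "y")
#' d$n
#' factor_names(d)
#' @export
count_dataset <- function(data, response, offset = NULL) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    cs_abort(sprintf("response column '%s' not found", response), "countspec_config_error")
  }
  y <- data[[response]]
  if (!is.numeric(y)) cs_abort("response column must be numeric", "countspec_validation_error")
  bad <- which(is.na(y) | y < 0 | y != round(y))
  if (length(bad)) {
    cs_abort(sprintf("response must be a non-negative integer; offending rows: %s",
                     paste(head(bad, 10L), collapse = ", ")),
             "countspec_validation_error")
  }

  offset_vec <- NULL
  offset_name <- NULL
  if (!is.null(offset)) {
    if (is.character(offset) && length(offset) == 1L) {
      if (!offset %in% names(data)) {
        cs_abort(sprintf("offset column '%s' not found", offset), "countspec_config_error")
      }
      offset_vec <- as.numeric(data[[offset]])
      offset_name <- offset
    } else {
      offset_vec <- as.numeric(offset)
    }
    if (length(offset_vec) != nrow(data) || anyNA(offset_vec)) {
      cs_abort("offset must be a complete numeric vector of length nrow(data)",
               "countspec_validation_error")
    }
  }

  cand <- data[setdiff(names(data), c(response, offset_name))]
  numeric_ok <- vapply(cand, is.numeric, logical(1))
  if (any(!numeric_ok)) {
    warning(sprintf("dropping non-numeric candidate column(s): %s",
                    paste(names(cand)[!numeric_ok], collapse = ", ")),
            call. = FALSE)
  }
  factors <- cand[numeric_ok]
  if (ncol(factors) == 0L) cs_abort("no numeric candidate factors found", "countspec_validation_error")
  if (anyDuplicated(names(factors))) cs_abort("factor names must be unique", "countspec_validation_error")
  all_na <- vapply(factors, function(x) all(is.na(x)), logical(1))
  if (any(all_na)) {
    cs_abort(sprintf("factor(s) entirely missing: %s", paste(names(factors)[all_na], collapse = ", ")),
             "countspec_validation_error")
  }
  some_na <- vapply(factors, anyNA, logical(1))
  if (any(some_na)) {
    cs_abort(sprintf("missing values in factor(s): %s", paste(names(factors)[some_na], collapse = ", ")),
             "countspec_validation_error")
  }
  if (nrow(data) < 1L) cs_abort("need at least one observation", "countspec_validation_error")

  structure(
    list(response = as.integer(round(y)), factors = factors,
         offset = offset_vec, response_name = response, n = nrow(data)),
    class = "count_dataset"
  )
}

#' Load a delimited table as a count dataset
#'
#' Thin wrapper around [readr::read_delim()] feeding [count_dataset()]: every
#' numeric column other than the response (and offset) becomes a candidate
#' contributing factor; row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param response Name of the response column.
#' @param offset Optional offset column name.
#' @param delim Field delimiter; `NULL` (default) lets readr guess.
#' @inheritParams count_dataset
#' @return A `count_dataset`.
#' @export
load_dataset <- function(path, response, offset = NULL, delim = NULL) {
  if (!file.exists(path)) cs_abort(sprintf("file not found: %s", path), "countspec_config_error")
  tbl <- if (is.null(delim)) {
    readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  }
  count_dataset(tbl, response = response, offset = offset)
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("<count_dataset> %d observations, response '%s', %d candidate factors\n",
              x$n, x$response_name, ncol(x$factors)))
  cat("  factors:", paste(names(x$factors), collapse = ", "), "\n")
  if (!is.null(x$offset)) cat("  offset: present\n")
  invisible(x)
}

#' Candidate factor names of a dataset
#' @param dataset A `count_dataset`.
#' @export
factor_names <- function(dataset) names(dataset$factors)

#' Number of observations
#' @param dataset A `count_dataset`.
#' @export
n_obs <- function(dataset) dataset$n
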