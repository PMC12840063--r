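#' Build a dataset from a long-format data frame
#'
#' The expected layout is one row per (subject, measurement): a subject id
#' column, a 1-based time index, the outcome and the covariate columns.
#' Every subject must have exactly the same set of time indices (balanced
#' design); missing values are rejected. Categorical covariates (declared
#' by name, or any non-numeric column) are coded by order of first
#' appearance.
#'
#' @param df Data frame in long format.
#' @param subject_col,time_col,outcome_col Column names (defaults
#'   `"subject_id"`, `"time_index"`, `"y"`).
#' @param categorical Character vector of covariate columns to treat as
#'   categorical.
#' @param outcome_categorical Treat the outcome as categorical.
#' @return A [vada_data()] object.
#' @export
as_vada_data <- function(df, subject_col = "subject_id", time_col = "time_index",
                         outcome_col = "y", categorical = character(0L),
                         outcome_categorical = FALSE) {
  stopifnot(all(c(subject_col, time_col, outcome_col) %in% names(df)))
  df <- dplyr::arrange(df, match(.data[[subject_col]], unique(df[[subject_col]])),
                       .data[[time_col]])
  ids <- unique(df[[subject_col]])
  L <- length(unique(df[[time_col]]))
  N <- length(ids)
  if (nrow(df) != N * L) stop("unbalanced design: every subject needs exactly L rows")
  cov_cols <- setdiff(names(df), c(subject_col, time_col, outcome_col))
  P <- length(cov_cols)
  if (P < 1L) stop("no covariate columns found")
  fk <- vector("list", P)
  X <- matrix(0, N * L, P)
  for (p in seq_len(P)) {
    v <- df[[cov_cols[p]]]
    if (cov_cols[p] %in% categorical || !is.numeric(v)) {
      lev <- unique(as.character(v))  # order of first appearance
      X[, p] <- match(as.character(v), lev)
      fk[[p]] <- list(kind = "categorical", levels = lev)
    } else {
      X[, p] <- v
      fk[[p]] <- list(kind = "continuous")
    }
  }
  yv <- df[[outcome_col]]
  if (outcome_categorical || !is.numeric(yv)) {
    lev <- unique(as.character(yv))
    y <- matrix(match(as.character(yv), lev), N, L, byrow = TRUE)
    ok <- list(kind = "categorical", levels = lev)
  } else {
    y <- matrix(yv, N, L, byrow = TRUE)
    ok <- "real"
  }
  out <- vada_data(ids, X, y, fk, ok)
  attr(out, "cov_names") <- cov_cols
  out
}

#' Convert a dataset back to a long tibble
#'
#' Inverse of [as_vada_data()]: one row per (subject, measurement), with
#' categorical codes mapped back to their levels. Ground-truth cluster
#' labels (when present) are attached as a `c_true` column.
#'
#' @param x A [vada_data()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method as_tibble vada_data
#' @export
as_tibble.vada_data <- function(x, ...) {
  cov_names <- attr(x, "cov_names")
  if (is.null(cov_names)) cov_names <- paste0("x", seq_len(x$P))
  df <- tibble::tibble(subject_id = rep(x$subject_ids, each = x$L),
                       time_index = rep(seq_len(x$L), x$N))
  yv <- as.numeric(t(x$y))
  if (is.list(x$outcome_kind)) yv <- x$outcome_kind$levels[yv]
  df$y <- yv
  for (p in seq_len(x$P)) {
    v <- x$X[, p]
    fk <- x$feature_kinds[[p]]
    if (fk$kind == "categorical") v <- fk$levels[v]
    df[[cov_names[p]]] <- v
  }
  if (!is.null(x$truth)) df$c_true <- rep(x$truth$c_true, each = x$L)
  df
}

#' Read a long-format delimited file
#'
#' Tab- or comma-delimited with a header; columns `subject_id`,
#' `time_index`, `y`, then covariates. An optional JSON schema sidecar may
#' declare `categorical` covariate names and `outcome` (`"real"` or
#' `"categorical"`).
#'
#' @param file Path to the delimited file.
#' @param schema Optional path to a JSON schema file.
#' @return A [vada_data()] object.
#' @export
read_longitudinal <- function(file, schema = NULL) {
  first <- readLines(file, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(file, delim = delim, show_col_types = FALSE)
  cat_cols <- character(0L); out_cat <- FALSE
  if (!is.null(schema)) {
    sc <- jsonlite::read_json(schema, simplifyVector = TRUE)
    if (!is.null(sc$categorical)) cat_cols <- sc$categorical
    if (identical(sc$outcome, "categorical")) out_cat <- TRUE
  }
  as_vada_data(df, categorical = cat_cols, outcome_categorical = out_cat)
}

#' Write a dataset as a long-format delimited file
#'
#' @param data A [vada_data()] object.
#' @param file Output path.
#' @param delim Delimiter (tab by default).
#' @param truth_file Optional path for a truth sidecar
#'   (subject_id, c_true), written when ground truth is attached.
#' @return `file`, invisibly.
#' @export
write_longitudinal <- function(data, file, delim = "\t", truth_file = NULL) {
  df <- as_tibble.vada_data(data)
  df$c_true <- NULL
  readr::write_delim(df, file, delim = delim)
  if (!is.null(truth_file) && !is.null(data$truth)) {
    readr::write_delim(tibble::tibble(subject_id = data$subject_ids,
                                      c_true = data$truth$c_true),
                       truth_file, delim = delim)
  }
  invisible(file)
}
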