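#' Balanced multi-variable panel
#'
#' A `balanced_panel` holds one or more numeric variables observed on the
#' same N units (countries) over the same T consecutive integer periods
#' (years). Internally each variable is stored as an N x T matrix with unit
#' and period dimnames; all downstream estimation consumes these matrices.
#'
#' @param values named list of N x T numeric matrices, one per variable.
#'   All matrices must share identical dimensions and dimnames.
#' @param units character vector of unit labels (rows).
#' @param periods integer vector of strictly increasing, consecutive period
#'   labels (columns).
#'
#' @return An object of class `balanced_panel` with fields `units`,
#'   `periods`, `values`, `N`, `T`.
#' @export
balanced_panel <- function(values, units = NULL, periods = NULL) {
  if (!is.list(values) || length(values) == 0L)
    stop("`values` must be a non-empty named list of matrices", call. = FALSE)
  vn <- names(values)
  if (is.null(vn) || anyNA(vn) || any(vn == "") || anyDuplicated(vn))
    stop("variable names must be unique and nonempty", call. = FALSE)
  values <- lapply(values, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  d <- dim(values[[1L]])
  if (is.null(units)) units <- rownames(values[[1L]])
  if (is.null(periods) && !is.null(colnames(values[[1L]])))
    periods <- as.integer(colnames(values[[1L]]))
  if (is.null(units)) units <- paste0("unit", seq_len(d[1L]))
  if (is.null(periods) || length(periods) == 0L) periods <- seq_len(d[2L])
  units <- as.character(units)
  periods <- as.integer(periods)
  for (v in vn) {
    if (!identical(dim(values[[v]]), d))
      stop("variable '", v, "' has mismatched dimensions", call. = FALSE)
    dimnames(values[[v]]) <- list(units, as.character(periods))
  }
  obj <- structure(
    list(units = units, periods = periods, values = values,
         N = d[1L], T = d[2L]),
    class = "balanced_panel")
  validate_balanced_panel(obj)
  obj
}

#' @rdname balanced_panel
#' @param x object to validate.
#' @export
validate_balanced_panel <- function(x) {
  stopifnot(inherits(x, "balanced_panel"))
  if (x$N < 2L) stop("a balanced panel needs N >= 2 units", call. = FALSE)
  if (x$T < 5L) stop("a balanced panel needs T >= 5 periods", call. = FALSE)
  if (anyDuplicated(x$units)) stop("duplicate unit labels", call. = FALSE)
  dp <- diff(x$periods)
  if (any(dp != 1L))
    stop("periods must be strictly increasing consecutive integers",
         call. = FALSE)
  for (v in names(x$values)) {
    m <- x$values[[v]]
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf(
        "unbalanced panel: variable '%s' missing or non-finite at unit '%s', period %s",
        v, x$units[bad[1L, 1L]], x$periods[bad[1L, 2L]]), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.balanced_panel <- function(x, ...) {
  cat(sprintf("Balanced panel: N = %d units, T = %d periods (%d-%d)\n",
              x$N, x$T, x$periods[1L], x$periods[x$T]))
  cat("Variables:", paste(names(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one variable of a panel as an N x T matrix
#'
#' @param panel a `balanced_panel`.
#' @param variable variable name.
#' @return N x T numeric matrix (units in rows, periods in columns).
#' @export
panel_matrix <- function(panel, variable) {
  stopifnot(inherits(panel, "balanced_panel"))
  if (!variable %in% names(panel$values))
    stop("unknown variable '", variable, "'", call. = FALSE)
  panel$values[[variable]]
}

#' Read a long-format delimited panel file
#'
#' Reads a delimited text file with one row per (unit, period) and one
#' column per variable, validates balance, and returns a `balanced_panel`.
#' Row order in the file is irrelevant.
#'
#' @param path path to a CSV or TSV file with a header row.
#' @param unit_col,period_col names of the unit and period columns.
#' @param var_cols character vector of variable column names; `NULL` takes
#'   every remaining column.
#' @param sep field separator; `NULL` infers `"\t"` for `.tsv`/`.tab`
#'   files and `","` otherwise.
#' @return a `balanced_panel`.
#' @export
read_long_panel <- function(path, unit_col = "country", period_col = "year",
                            var_cols = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  as_balanced_panel(df, unit_col = unit_col, period_col = period_col,
                    var_cols = var_cols)
}

#' Build a balanced panel from a long-format data frame
#'
#' @param df data frame with unit, period and variable columns.
#' @inheritParams read_long_panel
#' @return a `balanced_panel`.
#' @export
as_balanced_panel <- function(df, unit_col = "country", period_col = "year",
                              var_cols = NULL) {
  for (col in c(unit_col, period_col))
    if (!col %in% names(df))
      stop("column '", col, "' not found", call. = FALSE)
  if (is.null(var_cols))
    var_cols <- setdiff(names(df), c(unit_col, period_col))
  if (length(var_cols) == 0L) stop("no variable columns", call. = FALSE)
  missing_vars <- setdiff(var_cols, names(df))
  if (length(missing_vars) > 0L)
    stop("variable column(s) not found: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)

  unit <- as.character(df[[unit_col]])
  per_raw <- trimws(as.character(df[[period_col]]))
  per <- suppressWarnings(as.integer(per_raw))
  if (anyNA(per))
    stop("non-integer period value '", per_raw[which(is.na(per))[1L]],
         "' in column '", period_col, "'", call. = FALSE)

  key <- paste(unit, per, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    kk <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicate row for unit '%s', period %s", kk[1L], kk[2L]),
         call. = FALSE)
  }

  units <- sort(unique(unit))
  periods <- sort(unique(per))
  ri <- match(unit, units)
  ci <- match(per, periods)

  values <- vector("list", length(var_cols))
  names(values) <- var_cols
  for (v in var_cols) {
    raw <- trimws(as.character(df[[v]]))
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !(raw %in% c("NA", "")))
    if (length(bad) > 0L)
      stop(sprintf(
        "non-numeric value '%s' for variable '%s' at unit '%s', period %d",
        raw[bad[1L]], v, unit[bad[1L]], per[bad[1L]]), call. = FALSE)
    m <- matrix(NA_real_, length(units), length(periods),
                dimnames = list(units, as.character(periods)))
    m[cbind(ri, ci)] <- num
    miss <- which(is.na(m), arr.ind = TRUE)
    if (nrow(miss) > 0L)
      stop(sprintf(
        "unbalanced panel: variable '%s' missing at unit '%s', period %s",
        v, units[miss[1L, 1L]], periods[miss[1L, 2L]]), call. = FALSE)
    values[[v]] <- m
  }
  balanced_panel(values, units = units, periods = periods)
}

#' Convert a balanced panel to a long-format data frame
#'
#' @param x a `balanced_panel`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @param unit_col,period_col output column names.
#' @return data frame with one row per (unit, period), sorted by unit then
#'   period.
#' @export
as.data.frame.balanced_panel <- function(x, row.names = NULL,
                                         optional = FALSE, ...,
                                         unit_col = "country",
                                         period_col = "year") {
  grid <- expand.grid(period = x$periods, unit = x$units,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(unit = grid$unit, period = grid$period,
                    stringsAsFactors = FALSE)
  names(out) <- c(unit_col, period_col)
  for (v in names(x$values))
    out[[v]] <- as.vector(t(x$values[[v]]))
  out
}

#' Write a balanced panel as a long-format delimited file
#'
#' @inheritParams read_long_panel
#' @param panel a `balanced_panel`.
#' @export
write_long_panel <- function(panel, path, unit_col = "country",
                             period_col = "year", sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(panel, unit_col = unit_col, period_col = period_col)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' First-difference one or more panel variables
#'
#' Returns a new panel with T - 1 periods in which each requested variable
#' is replaced by its first difference; unrequested variables are dropped.
#'
#' @param panel a `balanced_panel`.
#' @param variables variable names to difference; default all.
#' @return a `balanced_panel` with `T - 1` periods.
#' @export
first_difference <- function(panel, variables = names(panel$values)) {
  stopifnot(inherits(panel, "balanced_panel"))
  for (v in variables)
    if (!v %in% names(panel$values))
      stop("unknown variable '", v, "'", call. = FALSE)
  if (panel$T < 2L) stop("need T >= 2 to difference", call. = FALSE)
  values <- lapply(panel$values[variables], function(m) {
    m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  })
  balanced_panel(values, units = panel$units, periods = panel$periods[-1L])
}

# Column-wise cross-sectional average of one variable: length-T vector.
cross_average <- function(panel, variable) {
  colMeans(panel_matrix(panel, variable))
}

#' Variable metadata
#'
#' Describes a panel variable: display name, measurement units and an
#' optional data-source indicator code.
#'
#' @param name nonempty variable name.
#' @param units measurement units (free text).
#' @param indicator_code optional source indicator code.
#' @return list of class `variable_spec`.
#' @export
variable_spec <- function(name, units = "", indicator_code = NA_character_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("variable name must be a nonempty string", call. = FALSE)
  structure(list(name = name, units = units,
                 indicator_code = indicator_code),
            class = "variable_spec")
}

#' Default variable set of the emissions-health-migration panel
#'
#' The three World Development Indicators series the motivating analysis
#' uses: CO2 emissions per capita, current health expenditure per capita
#' and net migration (five-year estimates assigned to years).
#'
#' @return named list of [variable_spec()] objects keyed `co2`, `hexp`,
#'   `migr`.
#' @export
default_variables <- function() {
  list(
    co2 = variable_spec("co2", "metric tons per capita", "EN.ATM.CO2E.PC"),
    hexp = variable_spec("hexp", "current US$ per capita",
                         "SH.XPD.CHEX.PC.CD"),
    migr = variable_spec("migr", "persons (5-year estimates)",
                         "SM.POP.NETM"))
}
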