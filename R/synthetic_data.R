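#' Configuration for the synthetic panel generator
#'
#' Describes a data-generating process for a balanced N x T panel with the
#' statistical structure the analysis pipeline assumes: integrated or
#' stationary unit-level series, cross-sectional dependence through a
#' common factor with heterogeneous loadings, optional directional
#' (Granger-causal) links between variables, and an optional
#' "migration-like" variable that is sign-unrestricted and can carry the
#' block-interpolation smoothness artifact of five-year demographic
#' estimates assigned to individual years.
#'
#' @param N,T panel dimensions (N >= 2, T >= 10).
#' @param variables character vector of variable names.
#' @param process named character vector/list giving each variable's
#'   process: `"random_walk"`, `"ar1"` or `"trend_stationary"`.
#' @param ar1_rho AR(1) coefficient used by `"ar1"` processes (|rho| < 1).
#' @param trend_slope slope used by `"trend_stationary"` processes.
#' @param innovation_sd named vector of innovation standard deviations
#'   (recycled across variables if unnamed scalar).
#' @param factor_loading_range length-2 numeric: per-unit loadings on the
#'   common factor are drawn uniformly from this range. Use `c(0, 0)` for
#'   cross-sectionally independent panels.
#' @param factor_process process of the common factor f_t: `"random_walk"`
#'   or `"ar1"`.
#' @param factor_ar1_rho AR(1) coefficient of the factor when `"ar1"`.
#' @param causal_links list of links, each a list with fields `source`,
#'   `target`, `coef`, `lag` (default 1) and `units` (unit indices,
#'   default all). A link adds `coef` times the lagged *innovation-scale*
#'   movement of the source (its first difference for integrated sources,
#'   its level otherwise) to the target's innovation, so both series keep
#'   their stated integration order.
#' @param migration_like name of a variable to treat as migration-like
#'   (scaled up and sign-unrestricted), or `NULL`.
#' @param migration_scale multiplier applied to the migration-like series.
#' @param block_interpolation integer window w; when > 1 the
#'   migration-like series is made piecewise constant within w-period
#'   blocks (the artificial smoothness of interpolated five-year totals).
#'   1 disables.
#' @param seed integer seed; the generator is fully deterministic given
#'   the config. Per-(unit, variable) streams are derived from the seed so
#'   enlarging N leaves earlier units' draws unchanged.
#'
#' @return a list of class `dgp_config`.
#' @export
dgp_config <- function(N = 27L, T = 21L,
                       variables = c("co2", "hexp", "migr"),
                       process = "random_walk",
                       ar1_rho = 0.5,
                       trend_slope = 0.1,
                       innovation_sd = 1,
                       factor_loading_range = c(0.5, 1.5),
                       factor_process = "random_walk",
                       factor_ar1_rho = 0.5,
                       causal_links = list(),
                       migration_like = NULL,
                       migration_scale = 1e4,
                       block_interpolation = 1L,
                       seed = 1L) {
  N <- as.integer(N); T <- as.integer(T)
  if (is.na(N) || N < 2L) stop("invalid config field N: need N >= 2", call. = FALSE)
  if (is.na(T) || T < 10L) stop("invalid config field T: need T >= 10", call. = FALSE)
  variables <- as.character(variables)
  if (length(variables) < 1L || anyDuplicated(variables))
    stop("invalid config field variables", call. = FALSE)
  proc <- rep_len(unlist(process), length(variables))
  if (is.null(names(process)) || length(process) == 1L) {
    names(proc) <- variables
  } else {
    proc <- unlist(process)[variables]
  }
  if (!all(proc %in% c("random_walk", "ar1", "trend_stationary")))
    stop("invalid config field process", call. = FALSE)
  if (abs(ar1_rho) >= 1) stop("invalid config field ar1_rho: |rho| < 1 required", call. = FALSE)
  sd_ <- rep_len(unlist(innovation_sd), length(variables))
  if (!is.null(names(innovation_sd)) && length(innovation_sd) > 1L)
    sd_ <- unlist(innovation_sd)[variables]
  names(sd_) <- variables
  if (any(!is.finite(sd_) | sd_ <= 0))
    stop("invalid config field innovation_sd", call. = FALSE)
  if (length(factor_loading_range) != 2L || any(!is.finite(factor_loading_range)))
    stop("invalid config field factor_loading_range", call. = FALSE)
  for (lk in causal_links) {
    if (!all(c("source", "target", "coef") %in% names(lk)))
      stop("invalid config field causal_links: each link needs source, target, coef",
           call. = FALSE)
    if (!lk$source %in% variables || !lk$target %in% variables)
      stop("invalid config field causal_links: unknown variable", call. = FALSE)
    if (!is.finite(lk$coef))
      stop("invalid config field causal_links: non-finite coef", call. = FALSE)
  }
  if (!is.null(migration_like) && !migration_like %in% variables)
    stop("invalid config field migration_like: unknown variable", call. = FALSE)
  structure(list(
    N = N, T = T, variables = variables, process = proc,
    ar1_rho = ar1_rho, trend_slope = trend_slope, innovation_sd = sd_,
    factor_loading_range = factor_loading_range,
    factor_process = factor_process, factor_ar1_rho = factor_ar1_rho,
    causal_links = causal_links, migration_like = migration_like,
    migration_scale = migration_scale,
    block_interpolation = as.integer(block_interpolation),
    seed = as.integer(seed)), class = "dgp_config")
}

# Deterministic sub-seed for a named stream, derived from the master seed.
# Kept below 2^31 so it is a valid R integer on every platform.
stream_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 10007 + h * 31 + 17) %% 2147483629)
}

rnorm_stream <- function(master, stream, n, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(stream_seed(master, stream))
  stats::rnorm(n, sd = sd)
}

runif_stream <- function(master, stream, n, min = 0, max = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(stream_seed(master, stream))
  stats::runif(n, min = min, max = max)
}

#' Generate a synthetic balanced panel
#'
#' Each variable v of unit i is built from an innovation
#' \eqn{u^v_{it} = link terms + \gamma_i f^v_t + \epsilon^v_{it}}, where
#' \eqn{f^v_t} is a variable-specific common factor and \eqn{\gamma_i} a
#' unit loading. Random-walk variables cumulate the innovations (so they
#' are I(1)); AR(1) variables recurse on them; trend-stationary variables
#' add a linear trend to white noise. Identical configs (including the
#' seed) give bit-identical panels.
#'
#' @param config a [dgp_config()].
#' @return a [balanced_panel()].
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  N <- config$N; T <- config$T
  units <- sprintf("U%02d", seq_len(N))

  # common factors, one per variable, shared across units
  factors <- list()
  for (v in config$variables) {
    fe <- rnorm_stream(config$seed, paste0("factor:", v), T)
    factors[[v]] <- switch(config$factor_process,
      random_walk = cumsum(fe),
      ar1 = as.vector(stats::filter(fe, config$factor_ar1_rho,
                                    method = "recursive")),
      stop("invalid config field factor_process", call. = FALSE))
  }
  loadings <- runif_stream(config$seed, "loadings", N,
                           min = config$factor_loading_range[1L],
                           max = config$factor_loading_range[2L])

  # idiosyncratic innovations per (unit, variable) stream
  innov <- list()
  for (v in config$variables) {
    m <- matrix(0, N, T)
    for (i in seq_len(N))
      m[i, ] <- rnorm_stream(config$seed, sprintf("eps:%s:%03d", v, i), T,
                             sd = config$innovation_sd[[v]])
    innov[[v]] <- m + outer(loadings, diff(c(0, factors[[v]])))
  }

  # directional links feed the lagged innovation-scale movement of the
  # source into the target's innovation, preserving integration orders
  for (lk in config$causal_links) {
    lag <- if (is.null(lk$lag)) 1L else as.integer(lk$lag)
    uns <- if (is.null(lk$units)) seq_len(N) else as.integer(lk$units)
    src <- innov[[lk$source]]
    if (lag >= T) stop("invalid config field causal_links: lag >= T", call. = FALSE)
    shifted <- cbind(matrix(0, N, lag), src[, seq_len(T - lag), drop = FALSE])
    innov[[lk$target]][uns, ] <- innov[[lk$target]][uns, , drop = FALSE] +
      lk$coef * shifted[uns, , drop = FALSE]
  }

  values <- list()
  for (v in config$variables) {
    u <- innov[[v]]
    y <- switch(config$process[[v]],
      random_walk = t(apply(u, 1L, cumsum)),
      ar1 = t(apply(u, 1L, function(e)
        as.vector(stats::filter(e, config$ar1_rho, method = "recursive")))),
      trend_stationary = u + matrix(config$trend_slope * seq_len(T),
                                    N, T, byrow = TRUE))
    values[[v]] <- y
  }

  mv <- config$migration_like
  if (!is.null(mv)) {
    y <- values[[mv]] * config$migration_scale
    w <- config$block_interpolation
    if (w > 1L) {
      blk <- ((seq_len(T) - 1L) %/% w)
      for (b in unique(blk)) {
        idx <- which(blk == b)
        y[, idx] <- rowMeans(y[, idx, drop = FALSE])
      }
    }
    values[[mv]] <- y
  }

  balanced_panel(values, units = units, periods = 2000L + seq_len(T) - 1L)
}

#' Printed country-level causality p-values (transcribed fixture)
#'
#' Returns the published country-level Wald statistics and p-values for
#' the six directional tests among CO2 emissions per capita, health
#' expenditure per capita and net migration in the EU-27 panel, together
#' with the printed panel-level Fisher statistics. These are transcribed,
#' three-decimal *printed* values shipped as a plain-text fixture; they
#' allow the p-value combination and typology stages to be exercised and
#' checked without any external data download.
#'
#' @return list with elements `countries` (data frame: country, direction,
#'   statistic, p_value) and `fisher` (data frame: direction, lambda,
#'   p_value).
#' @export
fixture_printed_tables <- function() {
  path <- system.file("extdata", "ek_printed_pvalues.csv",
                      package = "panelcausal", mustWork = TRUE)
  fpath <- system.file("extdata", "ek_printed_fisher.csv",
                       package = "panelcausal", mustWork = TRUE)
  countries <- utils::read.csv(path, stringsAsFactors = FALSE)
  fisher <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  stopifnot(nrow(countries) == 27L * 6L, nrow(fisher) == 6L)
  list(countries = countries, fisher = fisher)
}
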