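# Shared fixtures built in code.

# small deterministic panel: 2 variables, N units, T periods
toy_panel <- function(N = 3, T = 8, seed = 42) {
  set.seed(seed)
  balanced_panel(list(
    y = matrix(rnorm(N * T), N, T),
    x = matrix(rnorm(N * T), N, T)))
}

# write a long CSV for a panel and return the path
toy_panel_csv <- function(panel, path = tempfile(fileext = ".csv")) {
  write_long_panel(panel, path)
  path
}

# random-walk bivariate block (2 x T): independent I(1) series
rw_block <- function(T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rbind(cumsum(rnorm(T)), cumsum(rnorm(T)))
}
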