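# Seeded synthetic titration data with known ground truth, and the two
# published raw datasets shipped as plain-text fixtures.

#' Generate noisy synthetic titration data with known truth
#'
#' Evaluates a model curve on a log-spaced x design and adds seeded
#' additive Gaussian noise on the observed scale; fractions are clipped to
#' `[0, 1]`. With `sd = 0` the points lie exactly on the curve, so any fit
#' method recovers the generating parameters.
#'
#' @inheritParams binding_fit
#' @param params named list of the true model parameters.
#' @param n number of points (default 12).
#' @param x_range length-2 x design range in mol/L; default two decades
#'   centred on the true `K_D` (`K_D * c(0.1, 10)`).
#' @param sd standard deviation of the additive Gaussian noise on the y
#'   scale (default 0.02, a typical fractional-readout error).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A tibble with columns `x`, `y`; the generating parameters and
#'   curve are attached as attribute `"truth"`.
#' @examples
#' d <- generate_binding_data("homodimer", list(c_P = 1e-4, K_D = 8e-4),
#'                            curve = "P", x_var = "c_P",
#'                            y_mode = "relative", seed = 1)
#' @export
generate_binding_data <- function(system, params, curve, x_var, y_mode,
                                  n = 12, x_range = NULL, sd = 0.02,
                                  seed = NULL) {
  system <- match.arg(system, .systems)
  stopifnot(n >= 2, sd >= 0)
  if (is.null(x_range)) x_range <- params$K_D * c(0.1, 10)
  x <- 10^seq(log10(x_range[1]), log10(x_range[2]), length.out = n)
  y <- eval_curve(system, params, curve, x_var,
                  if (identical(y_mode, "relative")) "relative" else "absolute",
                  x)
  if (!is.null(seed)) set.seed(seed)
  if (sd > 0) {
    y <- y + stats::rnorm(n, sd = sd)
    if (identical(y_mode, "relative")) y <- pmin(pmax(y, 0), 1)
  }
  out <- tibble(x = x, y = y)
  attr(out, "truth") <- list(system = system, params = params, curve = curve,
                             x_var = x_var, y_mode = y_mode, sd = sd)
  out
}

#' Published raw titration datasets
#'
#' Two small datasets shipped as plain-text fixtures, digit-for-digit as
#' published: `"table2"`, the relative xylonolactonase--iron complex amount
#' against free iron concentration (8 points); `"table3"`, the free Equ c 1
#' allergen monomer concentration against total protein concentration
#' (7 points).
#'
#' @param name `"table2"` or `"table3"`.
#' @return A tibble with columns `x` and `y` (mol/L on x; `table2` y is a
#'   fraction, `table3` y is mol/L).
#' @examples
#' binding_fixture("table3")
#' @export
binding_fixture <- function(name) {
  file <- switch(name,
    table2 = "table2_xylonolactonase_iron.csv",
    table3 = "table3_equc1_dimer.csv",
    abort(sprintf("unknown fixture `%s` (use \"table2\" or \"table3\").",
                  name)))
  path <- system.file("extdata", file, package = "bindsim", mustWork = TRUE)
  read_binding_data(path)
}
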