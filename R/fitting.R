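# Least-squares fitting of model curves to titration data: grid searches
# over the slider positions (two-pass, single-pass, iterative) and a
# continuous refiner in log-parameter space.

#' Parse two-column titration data from text
#'
#' Each non-blank row gives one data point as two numbers separated by
#' whitespace and/or a comma; plain decimals and E notation are equivalent
#' (`"0.00028"` and `"2.8e-4"` parse identically).
#'
#' @param text a character scalar (possibly multi-line) or character vector
#'   of lines.
#' @return A tibble with numeric columns `x` and `y`.
#' @examples
#' parse_binding_data("2.8e-4 1.0\n0.00056, 0.8")
#' @export
parse_binding_data <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- which(!grepl("^\\s*$", lines))
  pts <- purrr::map(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals)) {
      abort(sprintf("row %d is not a pair of numbers: \"%s\"", i, lines[i]),
            class = "bindsim_error_parse")
    }
    vals
  })
  tibble(x = purrr::map_dbl(pts, 1), y = purrr::map_dbl(pts, 2))
}

#' Read two-column titration data from a file
#'
#' @param path path to a plain-text/CSV file in the format accepted by
#'   [parse_binding_data()]. A non-numeric first line (header) is skipped.
#' @return A tibble with columns `x` and `y`.
#' @export
read_binding_data <- function(path) {
  lines <- readLines(path)
  first <- which(!grepl("^\\s*$", lines))[1]
  if (!is.na(first)) {
    fields <- strsplit(trimws(lines[first]), "[,[:space:]]+")[[1]]
    if (anyNA(suppressWarnings(as.numeric(fields)))) lines <- lines[-first]
  }
  parse_binding_data(lines)
}

#' Discrete slider-position grid for the grid-search fits
#'
#' Positions are the two-significant-figure values per decade (mantissa 1.0
#' to 9.9 in steps of `mantissa_step`) over `10^exp_range`, plus the upper
#' endpoint. The coarse pass uses quarter-decade mantissas.
#'
#' @param exp_range integer range of decade exponents, default `c(-9, -1)`
#'   (the slider range).
#' @param mantissa_step mantissa step, default 0.1.
#' @param coarse_mantissas mantissas of the coarse pass, default
#'   `c(1, 1.8, 3.2, 5.6)`.
#' @return An object of class `slider_grid` with elements `positions` and
#'   `coarse` (sorted numeric vectors).
#' @export
slider_grid <- function(exp_range = c(-9, -1), mantissa_step = 0.1,
                        coarse_mantissas = c(1, 1.8, 3.2, 5.6)) {
  stopifnot(exp_range[1] < exp_range[2], mantissa_step > 0)
  decades <- seq(exp_range[1], exp_range[2] - 1L)
  m <- round(seq(1, 10 - mantissa_step, by = mantissa_step), 10)
  positions <- c(as.vector(outer(m, 10^decades)), 10^exp_range[2])
  coarse <- c(as.vector(outer(sort(coarse_mantissas), 10^decades)),
              10^exp_range[2])
  structure(list(positions = sort(positions), coarse = sort(coarse),
                 exp_range = exp_range, mantissa_step = mantissa_step),
            class = "slider_grid")
}

# assemble and validate a fitting problem
fit_problem <- function(data, system, curve, x_var, y_mode, free, fixed) {
  system <- match.arg(system, .systems)
  y_mode <- match.arg(y_mode, c("relative", "absolute"))
  data <- as_tibble(as.data.frame(data))
  if (ncol(data) < 2) abort("`data` needs two columns (x, y).")
  data <- stats::setNames(data[, 1:2], c("x", "y"))
  if (nrow(data) < 1 || !all(is.finite(data$x)) || !all(is.finite(data$y))) {
    abort("`data` must contain at least one finite (x, y) pair.")
  }
  all_p <- system_params(system)
  if (length(free) < 1) abort("at least one free parameter is required.")
  if (length(free) > 3) {
    abort("grid fitting supports at most three free parameters.")
  }
  if (!all(free %in% all_p)) {
    abort(sprintf("unknown free parameter(s): %s",
                  paste(setdiff(free, all_p), collapse = ", ")))
  }
  if (!x_var %in% system_x_vars(system)) {
    abort(sprintf("x variable `%s` is not available for the %s system.",
                  x_var, system),
          class = "bindsim_error_configuration")
  }
  need <- setdiff(all_p, c(free, if (!grepl("^free_", x_var)) x_var))
  # a free-concentration x makes some totals irrelevant to the curve shape
  if (grepl("^free_", x_var)) {
    need <- switch(system,
      homodimer = intersect(need, "K_D"),
      ligand_binding = intersect(need, c("c_P", "K_D")),
      competing_receptors = need)
    need <- setdiff(need, "c_L")
  }
  miss <- setdiff(need, names(fixed))
  if (length(miss)) {
    abort(sprintf("missing fixed parameter(s): %s",
                  paste(miss, collapse = ", ")))
  }
  list(data = data, system = system, curve = curve, x_var = x_var,
       y_mode = y_mode, free = free, fixed = fixed[intersect(names(fixed), all_p)])
}

problem_ssr <- function(prob, par) {
  params <- utils::modifyList(as.list(prob$fixed), as.list(par))
  yhat <- eval_curve(prob$system, params, prob$curve, prob$x_var,
                     prob$y_mode, prob$data$x)
  sum((yhat - prob$data$y)^2)
}

#' Sum of squared residuals of a model curve against data
#'
#' The unweighted least-squares objective used by every fitting strategy:
#' the model curve is evaluated exactly as the corresponding sweep would be
#' at each data x, on the selected y scale.
#'
#' @param data data frame whose first two columns are x and y.
#' @inheritParams binding_fit
#' @param params named list of all model parameter values.
#' @return The scalar sum of squared residuals.
#' @export
binding_ssr <- function(data, system, curve, x_var, y_mode, params) {
  prob <- fit_problem(data, system, curve, x_var, y_mode,
                      free = names(params)[1], fixed = params)
  problem_ssr(prob, params[0])
}

# grid rows in lexicographic order of the free-parameter tuple, so that
# which.min() tie-breaks toward the smallest values
grid_rows <- function(pos_list) {
  g <- do.call(expand.grid, c(rev(pos_list), KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_along(pos_list)), drop = FALSE]
  names(g) <- names(pos_list)
  g
}

scan_grid <- function(prob, rows) {
  ssr <- vapply(seq_len(nrow(rows)), function(i) {
    problem_ssr(prob, as.list(rows[i, , drop = FALSE]))
  }, numeric(1))
  best <- which.min(ssr)
  list(par = unlist(rows[best, , drop = FALSE]), ssr = ssr[best],
       n_eval = nrow(rows))
}

snap_to_grid <- function(x, positions) {
  positions[max.col(-abs(outer(log10(x), log10(positions), "-")))]
}

#' Fit model parameters to titration data by least squares
#'
#' Finds the free-parameter values minimizing the sum of squared residuals
#' between a model curve and the data. Four strategies are available:
#'
#' * `"two_pass"` (default): coarse scan over quarter-decade slider
#'   positions, then a full-resolution scan within one decade of the coarse
#'   optimum. Fast, but can land on the wrong basin when the residual
#'   surface is multimodal; the coarse optimum is recorded in `trace`.
#' * `"single_pass"`: exhaustive scan of every combination of slider
#'   positions; always finds the grid optimum.
#' * `"iterative"`: coordinate descent over neighbouring slider positions
#'   from `start` until no single-parameter move improves the fit (a local
#'   minimum of the residual surface).
#' * `"continuous"`: local minimization in log10-parameter space starting
#'   from the grid optimum, free of the slider discretization.
#'
#' Grid methods report values on the two-significant-figure slider grid;
#' ties in the residual are broken toward the smallest parameter values.
#'
#' @param data data frame whose first two columns are the x values (mol/L)
#'   and observed y values.
#' @param system model system name (see [binding_sweep()]).
#' @param curve species whose curve is fitted, e.g. `"PL"` or `"P"`.
#' @param x_var x variable of the data (a total-concentration parameter or
#'   a free-concentration axis).
#' @param y_mode `"relative"` (fractions of the protein total) or
#'   `"absolute"` (concentrations, mol/L).
#' @param free character vector (length 1--3) of parameters to fit.
#' @param fixed named list of values for the remaining parameters.
#' @param method search strategy, see above.
#' @param grid a [slider_grid()].
#' @param start named vector of initial values (required for
#'   `"iterative"`, optional for `"continuous"`).
#' @param temperature temperature in K for the derived free energies.
#' @return A `binding_fit` object; see [tidy.binding_fit()],
#'   [glance.binding_fit()] and [autoplot.binding_fit()].
#' @examples
#' tbl <- binding_fixture("table3")
#' fit <- binding_fit(tbl, "homodimer", curve = "P", x_var = "c_P",
#'                    y_mode = "absolute", free = "K_D")
#' coef(fit)   # K_D = 1.6e-8
#' @export
binding_fit <- function(data, system, curve, x_var, y_mode, free,
                        fixed = list(),
                        method = c("two_pass", "single_pass", "iterative",
                                   "continuous"),
                        grid = slider_grid(), start = NULL,
                        temperature = 298.15) {
  method <- match.arg(method)
  prob <- fit_problem(data, system, curve, x_var, y_mode, free, fixed)
  free <- prob$free
  res <- switch(method,
    single_pass = fit_single_pass_impl(prob, grid),
    two_pass = fit_two_pass_impl(prob, grid),
    iterative = fit_iterative_impl(prob, grid, start),
    continuous = fit_continuous_impl(prob, grid, start))
  kd_terms <- intersect(free, c("K_D", "K_Dp"))
  thermo <- if (length(kd_terms)) {
    thermo_rows(unname(res$par[kd_terms]), kd_terms, temperature = temperature)
  } else {
    thermo_rows(numeric(0), character(0))[0, ]
  }
  structure(list(par = res$par, ssr = res$ssr, method = method,
                 free = free, fixed = prob$fixed, system = prob$system,
                 curve = prob$curve, x_var = prob$x_var,
                 y_mode = prob$y_mode, data = prob$data, grid = grid,
                 trace = res$trace %||% list(n_eval = res$n_eval),
                 thermo = thermo, temperature = temperature),
            class = "binding_fit")
}

fit_single_pass_impl <- function(prob, grid) {
  pos <- stats::setNames(rep(list(grid$positions), length(prob$free)),
                         prob$free)
  out <- scan_grid(prob, grid_rows(pos))
  out$trace <- list(n_eval = out$n_eval)
  out
}

fit_two_pass_impl <- function(prob, grid) {
  coarse_pos <- stats::setNames(rep(list(grid$coarse), length(prob$free)),
                                prob$free)
  coarse <- scan_grid(prob, grid_rows(coarse_pos))
  fine_pos <- lapply(prob$free, function(nm) {
    centre <- coarse$par[[nm]]
    grid$positions[grid$positions >= centre / 10 &
                   grid$positions <= centre * 10]
  })
  names(fine_pos) <- prob$free
  fine <- scan_grid(prob, grid_rows(fine_pos))
  fine$trace <- list(coarse_par = coarse$par, coarse_ssr = coarse$ssr,
                     n_eval = coarse$n_eval + fine$n_eval)
  fine
}

fit_iterative_impl <- function(prob, grid, start, max_moves = 5000L) {
  if (is.null(start)) {
    abort("`start` (initial guess) is required for the iterative search.")
  }
  start <- unlist(start)[prob$free]
  if (anyNA(start)) abort("`start` must name every free parameter.")
  pos <- grid$positions
  idx <- vapply(start, function(v) which.min(abs(log10(pos) - log10(v))),
                integer(1))
  cur_ssr <- problem_ssr(prob, as.list(stats::setNames(pos[idx], prob$free)))
  n_eval <- 1L
  for (move in seq_len(max_moves)) {
    best <- NULL
    for (k in seq_along(idx)) {
      for (d in c(-1L, 1L)) {
        j <- idx[k] + d
        if (j < 1L || j > length(pos)) next
        cand <- idx; cand[k] <- j
        s <- problem_ssr(prob,
                         as.list(stats::setNames(pos[cand], prob$free)))
        n_eval <- n_eval + 1L
        better <- s < cur_ssr && (is.null(best) || s < best$ssr ||
          (s == best$ssr && all(pos[cand] <= pos[best$idx])))
        if (better) best <- list(idx = cand, ssr = s)
      }
    }
    if (is.null(best)) {
      return(list(par = stats::setNames(pos[idx], prob$free), ssr = cur_ssr,
                  trace = list(n_eval = n_eval, moves = move - 1L)))
    }
    idx <- best$idx
    cur_ssr <- best$ssr
  }
  abort("iterative search exceeded the move cap without converging.",
        class = "bindsim_error_numerical_failure")
}

fit_continuous_impl <- function(prob, grid, start) {
  k <- length(prob$free)
  if (is.null(start)) {
    start_fit <- if (k == 1) fit_single_pass_impl(prob, grid)
                 else fit_two_pass_impl(prob, grid)
    start <- start_fit$par
    start_ssr <- start_fit$ssr
  } else {
    start <- unlist(start)[prob$free]
    if (anyNA(start)) abort("`start` must name every free parameter.")
    start_ssr <- problem_ssr(prob, as.list(start))
  }
  lo <- log10(min(grid$positions))
  hi <- log10(max(grid$positions))
  obj <- function(lp) {
    problem_ssr(prob, as.list(stats::setNames(10^lp, prob$free)))
  }
  opt <- if (k == 1) {
    # local refinement within one decade of the grid optimum
    o <- stats::optimize(obj, c(max(lo, log10(start) - 1),
                                min(hi, log10(start) + 1)), tol = 1e-10)
    list(par = o$minimum, value = o$objective, convergence = 0L)
  } else {
    stats::optim(log10(start), obj, method = "L-BFGS-B",
                 lower = rep(lo, k), upper = rep(hi, k),
                 control = list(factr = 1e3))
  }
  if (opt$value <= start_ssr) {
    list(par = stats::setNames(10^as.vector(opt$par), prob$free),
         ssr = opt$value,
         trace = list(start_par = start, start_ssr = start_ssr,
                      optim_convergence = opt$convergence))
  } else {
    list(par = start, ssr = start_ssr,
         trace = list(start_par = start, start_ssr = start_ssr,
                      optim_convergence = opt$convergence))
  }
}

#' @export
coef.binding_fit <- function(object, ...) object$par

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: %s curve `%s` vs %s (%s), method %s>\n",
              x$system, x$curve, x$x_var, x$y_mode, x$method))
  for (nm in x$free) {
    cat(sprintf("  %-5s = %s mol/L\n", nm, format_sig2(x$par[[nm]])))
  }
  cat(sprintf("  SSR   = %.6g over %d points\n", x$ssr, nrow(x$data)))
  if (nrow(x$thermo)) {
    for (i in seq_len(nrow(x$thermo))) {
      cat(sprintf("  %s: K_A = %s L/mol, dG = %s kJ/mol\n",
                  x$thermo$constant[i], format_sig2(x$thermo$K_A[i]),
                  format_sig2(x$thermo$delta_G[i] / 1000)))
    }
  }
  invisible(x)
}

#' Tidy the free parameters of a binding fit
#'
#' @param x a `binding_fit`.
#' @param ... ignored.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   and for dissociation constants the derived `K_A` (L/mol) and
#'   `delta_G` (J/mol).
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  out <- tibble(term = x$free, estimate = unname(x$par[x$free]))
  dplyr::left_join(out, dplyr::rename(x$thermo, term = "constant",
                                      estimate2 = "K_D"),
                   by = "term")[, c("term", "estimate", "K_A", "delta_G")]
}

#' One-row summary of a binding fit
#'
#' @param x a `binding_fit`.
#' @param ... ignored.
#' @return A tibble with `ssr`, `n_obs`, `n_free`, `method` and the number
#'   of objective evaluations.
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(ssr = x$ssr, n_obs = nrow(x$data), n_free = length(x$free),
         method = x$method, n_eval = x$trace$n_eval %||% NA_integer_)
}

#' Plot a binding fit: data points and the fitted curve
#'
#' @param object a `binding_fit`.
#' @param n_points number of curve points.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, n_points = 200, ...) {
  xr <- range(object$data$x)
  xs <- 10^seq(log10(xr[1]), log10(xr[2]), length.out = n_points)
  params <- utils::modifyList(as.list(object$fixed), as.list(object$par))
  ys <- eval_curve(object$system, params, object$curve, object$x_var,
                   object$y_mode, xs)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = tibble(x = xs, y = ys), colour = "red") +
    ggplot2::geom_point(shape = 4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(object$x_var, " (mol/L)"),
                  y = paste0(object$curve,
                             if (object$y_mode == "relative") " (fraction)"
                             else " (mol/L)")) +
    ggplot2::theme_minimal()
}
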