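# Concentration sweeps: the graphical output of the simulators as tidy data.

#' Sweep an equilibrium system along a concentration axis
#'
#' Computes the equilibrium species concentrations over a log-spaced grid of
#' the chosen x variable. For a total-concentration axis each grid point is
#' an independent equilibrium solve; for a free-concentration axis
#' (`free_P` for the homodimer, `free_L` for ligand binding and competing
#' receptors) the species follow directly from the free value.
#'
#' @param system one of `"homodimer"`, `"ligand_binding"`,
#'   `"competing_ligands"`, `"competing_receptors"`.
#' @param params named list of model parameters (`c_P`, `c_L`, `c_Lp`,
#'   `c_Pp`, `K_D`, `K_Dp` as applicable). The parameter swept by `x_var`
#'   may be omitted.
#' @param x_var x-axis variable: a total-concentration parameter name or a
#'   free-concentration axis where the model allows one.
#' @param x_range length-2 range of the x axis in mol/L; default the slider
#'   range `c(1e-9, 1e-1)`.
#' @param n_points number of log-uniform grid points (endpoints included);
#'   default 300.
#' @param y_mode `"relative"` (fractions of the protein total, linear
#'   scale; not available for competing receptors), `"log"` (absolute
#'   concentrations, log display) or `"linear"` (absolute, linear display).
#' @param set_point optional x value at which the full equilibrium state is
#'   attached to the result (the marker point).
#' @return A tibble with columns `x`, `species`, `value` and class
#'   `binding_sweep`; the set-point state is in `attr(., "set_state")`.
#' @examples
#' sw <- binding_sweep("homodimer", list(K_D = 8.0e-4), x_var = "c_P",
#'                     y_mode = "relative", set_point = 1.2e-4)
#' set_point_fractions(sw)   # P 0.805, P2 0.195
#' @export
binding_sweep <- function(system, params, x_var,
                          x_range = c(1e-9, 1e-1), n_points = 300,
                          y_mode = c("relative", "log", "linear"),
                          set_point = NULL) {
  system <- match.arg(system, .systems)
  y_mode <- match.arg(y_mode)
  if (!x_var %in% system_x_vars(system)) {
    abort(sprintf("x variable `%s` is not available for the %s system.",
                  x_var, system),
          class = "bindsim_error_configuration")
  }
  if (y_mode == "relative" && system == "competing_receptors") {
    abort("the competing-receptors system offers absolute scales only.",
          class = "bindsim_error_configuration")
  }
  stopifnot(length(x_range) == 2, x_range[1] > 0, x_range[1] < x_range[2],
            n_points >= 2)
  for (nm in intersect(names(params), system_params(system))) {
    check_conc(params[[nm]], nm, positive = grepl("^K_", nm))
  }
  x <- 10^seq(log10(x_range[1]), log10(x_range[2]), length.out = n_points)
  sp <- eval_species(system, params, x_var, x)
  if (y_mode == "relative") {
    w <- species_weights(system, "P")
    sp <- sp[, names(w), drop = FALSE]
    total <- as.vector(as.matrix(sp) %*% w)
    for (nm in names(w)) {
      sp[[nm]] <- ifelse(total > 0, w[[nm]] * sp[[nm]] / total, 0)
    }
  }
  long <- tidyr::pivot_longer(dplyr::bind_cols(tibble(x = x), sp),
                              -"x", names_to = "species",
                              values_to = "value")
  long <- dplyr::arrange(long, .data$species, .data$x)
  set_state <- NULL
  if (!is.null(set_point)) {
    stopifnot(is.numeric(set_point), set_point > 0)
    set_state <- if (grepl("^free_", x_var)) {
      state_from_free(system, params, set_point)
    } else {
      solve_system(system, utils::modifyList(params,
                                             stats::setNames(list(set_point), x_var)))
    }
  }
  structure(long,
            system = system, params = params, x_var = x_var,
            y_mode = y_mode, set_point = set_point, set_state = set_state,
            class = c("binding_sweep", class(long)))
}

#' Protein fractions at the sweep's set point
#'
#' @param sweep a `binding_sweep` created with a `set_point`.
#' @param component base component whose fractions are reported (default
#'   the receptor protein `"P"`).
#' @return A tibble of species and fractions (see [pie_fractions()]).
#' @export
set_point_fractions <- function(sweep, component = "P") {
  st <- attr(sweep, "set_state")
  if (is.null(st)) abort("this sweep has no set point.")
  pie_fractions(st, component)
}

#' Proportional amounts of one component across its species
#'
#' The pie-diagram fractions: how a component's total concentration is
#' distributed over its free and complexed forms. Homodimer fractions are in
#' monomer-equivalents (the dimer counts twice), so fractions always sum
#' to 1.
#'
#' @param state a `binding_state`.
#' @param component base component name (`"P"`, `"Pp"`, `"L"` or `"Lp"` as
#'   applicable).
#' @return A tibble with columns `species` and `fraction`.
#' @examples
#' pie_fractions(solve_homodimer(4.0e-5, 1.6e-8))  # P2 0.986, P 0.014
#' @export
pie_fractions <- function(state, component = "P") {
  stopifnot(inherits(state, "binding_state"))
  system <- attr(state, "system")
  w <- species_weights(system, component)
  amounts <- w * conc(state, names(w))
  total <- sum(amounts)
  tibble(species = names(w),
         fraction = if (total > 0) as.numeric(amounts / total)
                    else rep(0, length(w)))
}

#' Equilibrium concentration table in molar and mass units
#'
#' One row per species with the molar concentration and, when molar masses
#' of the base components are supplied, the mass concentration in g/L. A
#' complex's molar mass is the sum of its constituents' masses (the dimer is
#' twice the monomer), which conserves total mass.
#'
#' @param state a `binding_state`.
#' @param masses optional named numeric vector of molar masses in g/mol for
#'   the base components present (`P`, `L`, `Pp`, `Lp` as applicable).
#' @return A tibble with columns `species`, `concentration` and (when
#'   masses are given) `molar_mass` and `mass_concentration`.
#' @examples
#' concentration_table(solve_homodimer(1.0e-4, 1.0e-5), masses = c(P = 20000))
#' @export
concentration_table <- function(state, masses = NULL) {
  stopifnot(inherits(state, "binding_state"))
  out <- as_tibble(state)[, c("species", "concentration")]
  if (is.null(masses)) return(out)
  if (any(masses <= 0) || any(!is.finite(masses))) {
    abort("molar masses must be finite and > 0.",
          class = "bindsim_error_invalid_parameter")
  }
  composition <- list(P = c(P = 1), Pp = c(Pp = 1), L = c(L = 1),
                      Lp = c(Lp = 1), P2 = c(P = 2), PL = c(P = 1, L = 1),
                      PLp = c(P = 1, Lp = 1), PpL = c(Pp = 1, L = 1))
  mm <- purrr::map_dbl(out$species, function(sp) {
    comp <- composition[[sp]]
    need <- names(comp)
    if (!all(need %in% names(masses))) {
      abort(sprintf("molar mass missing for component(s): %s",
                    paste(setdiff(need, names(masses)), collapse = ", ")),
            class = "bindsim_error_invalid_parameter")
    }
    sum(comp * masses[need])
  })
  out$molar_mass <- mm
  out$mass_concentration <- out$concentration * mm
  out
}

#' @rdname binding_sweep
#' @param object,x a `binding_sweep`.
#' @param ... ignored.
#' @method autoplot binding_sweep
#' @export
autoplot.binding_sweep <- function(object, ...) {
  y_mode <- attr(object, "y_mode")
  x_var <- attr(object, "x_var")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$x, y = .data$value,
                                    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(x_var, " (mol/L)"),
                  y = switch(y_mode,
                             relative = "fraction of total",
                             "concentration (mol/L)")) +
    ggplot2::theme_minimal()
  if (y_mode == "log") {
    floor_y <- 1e-18   # keeps zero concentrations displayable on log scale
    p$data$value <- pmax(p$data$value, floor_y)
    p <- p + ggplot2::scale_y_log10()
  }
  sp <- attr(object, "set_point")
  if (!is.null(sp)) {
    p <- p + ggplot2::geom_vline(xintercept = sp, linetype = "dashed")
  }
  p
}

#' @export
print.binding_sweep <- function(x, ...) {
  cat(sprintf("<binding_sweep: %s over %s, y = %s>\n", attr(x, "system"),
              attr(x, "x_var"), attr(x, "y_mode")))
  NextMethod()
}
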