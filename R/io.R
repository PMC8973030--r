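# Writers: sweep curves as CSV, set-point states as JSON, graphs as SVG.
# Output is deterministic (full-precision %.17g numbers, no timestamps), so
# identical inputs give byte-identical files.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a sweep as CSV
#'
#' One row per x grid point, one column per species, values on the sweep's
#' y scale. Round-trip safe: a column re-read as fit data reproduces the
#' curve with zero residual.
#'
#' @param sweep a [binding_sweep()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "binding_sweep"))
  wide <- tidyr::pivot_wider(as_tibble(sweep), names_from = "species",
                             values_from = "value")
  lines <- c(paste(c("x", setdiff(names(wide), "x")), collapse = ","),
             vapply(seq_len(nrow(wide)), function(i) {
               paste(fmt_num(unlist(wide[i, ])), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write an equilibrium state (plus thermodynamics) as JSON
#'
#' Full-precision values together with two-significant-figure display
#' strings, the pie fractions of the receptor protein, and `K_A` and
#' `Delta G` for every dissociation constant.
#'
#' @param state a `binding_state`.
#' @param path output file path.
#' @param temperature temperature in K for the free energies.
#' @return `path`, invisibly.
#' @export
write_state_json <- function(state, path, temperature = 298.15) {
  stopifnot(inherits(state, "binding_state"))
  params <- attr(state, "params")
  kd_names <- intersect(names(params), c("K_D", "K_Dp"))
  th <- thermo_rows(unlist(params[kd_names]), kd_names,
                    temperature = temperature)
  pie <- pie_fractions(state, "P")
  obj <- list(
    system = attr(state, "system"),
    parameters = params,
    equilibrium = as.list(stats::setNames(state$concentration,
                                          state$species)),
    equilibrium_display = as.list(stats::setNames(
      format_sig2(state$concentration), state$species)),
    fractions_P = as.list(stats::setNames(pie$fraction, pie$species)),
    thermodynamics = lapply(seq_len(nrow(th)), function(i) {
      list(constant = th$constant[i], K_D = th$K_D[i], K_A = th$K_A[i],
           delta_G_J_mol = th$delta_G[i],
           display = list(K_D = format_sig2(th$K_D[i]),
                          K_A = format_sig2(th$K_A[i]),
                          delta_G_kJ_mol = format_sig2(th$delta_G[i] / 1000)))
    }),
    temperature_K = temperature)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' @param fit a `binding_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "binding_fit"))
  obj <- list(
    system = fit$system, curve = fit$curve, x_var = fit$x_var,
    y_mode = fit$y_mode, method = fit$method,
    estimates = as.list(fit$par),
    estimates_display = as.list(stats::setNames(format_sig2(fit$par),
                                                names(fit$par))),
    ssr = fit$ssr, n_obs = nrow(fit$data),
    thermodynamics = lapply(seq_len(nrow(fit$thermo)), function(i) {
      list(constant = fit$thermo$constant[i], K_D = fit$thermo$K_D[i],
           K_A = fit$thermo$K_A[i], delta_G_J_mol = fit$thermo$delta_G[i])
    }),
    trace = fit$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- minimal standalone SVG writer -----------------------------------------

svg_palette <- c("#2166ac", "#b2182b", "#1b7837", "#e08214", "#762a83")

#' Export a sweep as a standalone SVG graph
#'
#' A small dependency-free writer producing a well-formed SVG with a
#' log-scaled x axis, one path per species, decade tick marks and the
#' set-point marker. Zero concentrations are floored at 1e-18 on the
#' logarithmic y scale so they stay displayable.
#'
#' @param sweep a [binding_sweep()] result.
#' @param path output file path.
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
write_sweep_svg <- function(sweep, path, width = 640, height = 480) {
  stopifnot(inherits(sweep, "binding_sweep"), nrow(sweep) > 0)
  y_mode <- attr(sweep, "y_mode")
  margin <- c(40, 70, 45, 20)  # top, left, bottom, right
  x0 <- margin[2]; x1 <- width - margin[4]
  y0 <- height - margin[3]; y1 <- margin[1]
  lx <- log10(range(sweep$x))
  sx <- function(x) x0 + (log10(x) - lx[1]) / diff(lx) * (x1 - x0)
  if (y_mode == "relative") {
    yr <- c(0, 1)
    sy <- function(v) y0 + (pmin(pmax(v, 0), 1) - yr[1]) / diff(yr) * (y1 - y0)
    yticks <- seq(0, 1, 0.2)
    ylab <- sprintf("%.1f", yticks)
  } else if (y_mode == "log") {
    v <- pmax(sweep$value, 1e-18)
    yr <- log10(range(v))
    if (diff(yr) == 0) yr <- yr + c(-1, 1)
    sy <- function(v) {
      lv <- log10(pmax(v, 1e-18))
      y0 + (pmin(pmax(lv, yr[1]), yr[2]) - yr[1]) / diff(yr) * (y1 - y0)
    }
    yticks <- 10^seq(ceiling(yr[1]), floor(yr[2]))
    ylab <- sprintf("1e%d", as.integer(log10(yticks)))
  } else {
    yr <- range(c(0, sweep$value))
    sy <- function(v) y0 + (pmin(pmax(v, yr[1]), yr[2]) - yr[1]) /
      diff(yr) * (y1 - y0)
    yticks <- pretty(yr, 5)
    yticks <- yticks[yticks >= yr[1] & yticks <= yr[2]]
    ylab <- sprintf("%.2g", yticks)
  }
  xticks <- 10^seq(ceiling(lx[1]), floor(lx[2]))
  species <- unique(sweep$species)
  cols <- stats::setNames(rep_len(svg_palette, length(species)), species)
  el <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect x="%g" y="%g" width="%g" height="%g" fill="white" stroke="black"/>',
            x0, y1, x1 - x0, y0 - y1))
  for (tx in xticks) {
    px <- sx(tx)
    el <- c(el,
      sprintf('<line x1="%.2f" y1="%g" x2="%.2f" y2="%g" stroke="black"/>',
              px, y0, px, y0 + 5),
      sprintf('<text x="%.2f" y="%g" font-size="11" text-anchor="middle">1e%d</text>',
              px, y0 + 18, as.integer(round(log10(tx)))))
  }
  yt <- if (y_mode == "log") yticks else yticks
  for (i in seq_along(yt)) {
    py <- sy(yt[i])
    el <- c(el,
      sprintf('<line x1="%g" y1="%.2f" x2="%g" y2="%.2f" stroke="black"/>',
              x0 - 5, py, x0, py),
      sprintf('<text x="%g" y="%.2f" font-size="11" text-anchor="end">%s</text>',
              x0 - 8, py + 4, ylab[i]))
  }
  for (sp in species) {
    d <- sweep[sweep$species == sp, ]
    pts <- sprintf("%.2f %.2f", sx(d$x), sy(d$value))
    el <- c(el,
      sprintf('<path d="M%s" fill="none" stroke="%s" stroke-width="1.5"/>',
              paste(pts, collapse = " L"), cols[[sp]]),
      sprintf('<text x="%g" y="%g" font-size="12" fill="%s">%s</text>',
              x1 - 60, y1 + 15 * match(sp, species), cols[[sp]], sp))
  }
  set_point <- attr(sweep, "set_point")
  if (!is.null(set_point) && set_point >= min(sweep$x) &&
      set_point <= max(sweep$x)) {
    px <- sx(set_point)
    el <- c(el, sprintf(
      '<line x1="%.2f" y1="%g" x2="%.2f" y2="%g" stroke="grey" stroke-dasharray="4 3"/>',
      px, y0, px, y1))
    for (sp in species) {
      d <- sweep[sweep$species == sp, ]
      vy <- stats::approx(log10(d$x), d$value, xout = log10(set_point))$y
      el <- c(el, sprintf(
        '<circle cx="%.2f" cy="%.2f" r="3" fill="%s"/>', px, sy(vy),
        cols[[sp]]))
    }
  }
  el <- c(el,
    sprintf('<text x="%g" y="%g" font-size="12" text-anchor="middle">%s (mol/L)</text>',
            (x0 + x1) / 2, height - 8, attr(sweep, "x_var")),
    "</svg>")
  writeLines(el, path)
  invisible(path)
}
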