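# System metadata shared by sweeps, pies, tables and fitting.

.systems <- c("homodimer", "ligand_binding", "competing_ligands",
              "competing_receptors")

system_params <- function(system) {
  switch(system,
    homodimer = c("c_P", "K_D"),
    ligand_binding = c("c_P", "c_L", "K_D"),
    competing_ligands = c("c_P", "c_L", "c_Lp", "K_D", "K_Dp"),
    competing_receptors = c("c_P", "c_Pp", "c_L", "K_D", "K_Dp"),
    abort(sprintf("unknown system `%s`.", system)))
}

system_species <- function(system) {
  switch(system,
    homodimer = c("P", "P2"),
    ligand_binding = c("P", "L", "PL"),
    competing_ligands = c("P", "L", "Lp", "PL", "PLp"),
    competing_receptors = c("P", "Pp", "L", "PL", "PpL"))
}

# stoichiometric weights of each species toward the total of one base
# component (dimer counts twice toward the protein total)
species_weights <- function(system, component) {
  w <- switch(system,
    homodimer = list(P = c(P = 1, P2 = 2)),
    ligand_binding = list(P = c(P = 1, PL = 1), L = c(L = 1, PL = 1)),
    competing_ligands = list(P = c(P = 1, PL = 1, PLp = 1),
                             L = c(L = 1, PL = 1),
                             Lp = c(Lp = 1, PLp = 1)),
    competing_receptors = list(P = c(P = 1, PL = 1),
                               Pp = c(Pp = 1, PpL = 1),
                               L = c(L = 1, PL = 1, PpL = 1)))
  out <- w[[component]]
  if (is.null(out)) {
    abort(sprintf("`%s` is not a component of the %s system.",
                  component, system))
  }
  out
}

# total-concentration parameter for a base component
component_total_param <- function(system, component) {
  switch(component, P = "c_P", Pp = "c_Pp", L = "c_L", Lp = "c_Lp")
}

# x-axis variables permitted per system: any total, plus the one free
# concentration the applets expose ([P], [L] and [L] respectively; the
# competing-ligands applet has no free axis)
system_x_vars <- function(system) {
  totals <- grep("^c_", system_params(system), value = TRUE)
  free <- switch(system,
    homodimer = "free_P",
    ligand_binding = "free_L",
    competing_receptors = "free_L",
    character(0))
  c(totals, free)
}

solve_system <- function(system, params) {
  p <- params
  switch(system,
    homodimer = solve_homodimer(p$c_P, p$K_D),
    ligand_binding = solve_ligand_binding(p$c_P, p$c_L, p$K_D),
    competing_ligands =
      solve_competing_ligands(p$c_P, p$c_L, p$c_Lp, p$K_D, p$K_Dp),
    competing_receptors =
      solve_competing_receptors(p$c_P, p$c_Pp, p$c_L, p$K_D, p$K_Dp))
}

# construct a state directly from a free-concentration value (the free-axis
# formulas: [P2] = [P]^2/K_D; bound fraction = [L]/([L]+K_D); and the two
# complexes of the competing-receptors model from free [L])
state_from_free <- function(system, params, x_free) {
  p <- params
  switch(system,
    homodimer = {
      P2 <- x_free^2 / p$K_D
      new_binding_state(c("P", "P2"), c(x_free, P2), system,
                        c(p, list(c_P = x_free + 2 * P2)))
    },
    ligand_binding = {
      PL <- p$c_P * x_free / (x_free + p$K_D)
      new_binding_state(c("P", "L", "PL"), c(p$c_P - PL, x_free, PL),
                        system, c(p, list(c_L = x_free + PL)))
    },
    competing_receptors = {
      PL <- p$c_P * x_free / (p$K_D + x_free)
      PpL <- p$c_Pp * x_free / (p$K_Dp + x_free)
      new_binding_state(c("P", "Pp", "L", "PL", "PpL"),
                        c(p$c_P - PL, p$c_Pp - PpL, x_free, PL, PpL),
                        system, c(p, list(c_L = x_free + PL + PpL)))
    },
    abort(sprintf("the %s system has no free-concentration axis.", system)))
}

# Vectorized species concentrations along an axis. `x` replaces the
# parameter named by `x_var` ("c_*" totals or "free_*"). Returns a tibble
# with one column per species, nrow = length(x).
eval_species <- function(system, params, x_var, x) {
  p <- params
  n <- length(x)
  val <- function(name) if (identical(x_var, name)) x else rep_len(p[[name]], n)
  if (x_var %in% c("free_P", "free_L")) {
    if (!x_var %in% system_x_vars(system)) {
      abort(sprintf("x variable `%s` is not available for the %s system.",
                    x_var, system))
    }
    return(switch(system,
      homodimer = tibble(P = x, P2 = x^2 / p$K_D),
      ligand_binding = {
        PL <- p$c_P * x / (x + p$K_D)
        tibble(P = p$c_P - PL, L = x, PL = PL)
      },
      competing_receptors = {
        PL <- p$c_P * x / (p$K_D + x)
        PpL <- p$c_Pp * x / (p$K_Dp + x)
        tibble(P = p$c_P - PL, Pp = p$c_Pp - PpL, L = x, PL = PL, PpL = PpL)
      }))
  }
  switch(system,
    homodimer = {
      cP <- val("c_P")
      P <- stable_quad_root(p$K_D / 2, p$K_D * cP / 2)
      tibble(P = P, P2 = P^2 / p$K_D)
    },
    ligand_binding = {
      cP <- val("c_P"); cL <- val("c_L"); KD <- p$K_D
      P <- stable_quad_root(cL - cP + KD, KD * cP)
      L <- stable_quad_root(cP - cL + KD, KD * cL)
      S <- cP + cL + KD
      PL <- 2 * cP * cL / (S + sqrt(S * S - 4 * cP * cL))
      tibble(P = P, L = L, PL = PL)
    },
    competing_ligands = {
      cP <- val("c_P"); cL <- val("c_L"); cLp <- val("c_Lp")
      P <- free_root_vec(cP, cL, p$K_D, cLp, p$K_Dp)
      L <- cL * p$K_D / (p$K_D + P)
      Lp <- cLp * p$K_Dp / (p$K_Dp + P)
      tibble(P = P, L = L, Lp = Lp, PL = P * L / p$K_D, PLp = P * Lp / p$K_Dp)
    },
    competing_receptors = {
      cP <- val("c_P"); cPp <- val("c_Pp"); cL <- val("c_L")
      L <- free_root_vec(cL, cP, p$K_D, cPp, p$K_Dp)
      PL <- cP * L / (p$K_D + L)
      PpL <- cPp * L / (p$K_Dp + L)
      tibble(P = cP * p$K_D / (p$K_D + L), Pp = cPp * p$K_Dp / (p$K_Dp + L),
             L = L, PL = PL, PpL = PpL)
    })
}

# Predicted y for one named curve on the fitting/sweep scale.
# y_mode "relative": fraction of the protein-P total (monomer-equivalents
# for the homodimer); anything else: absolute concentration in mol/L.
eval_curve <- function(system, params, curve, x_var, y_mode, x) {
  sp <- eval_species(system, params, x_var, x)
  if (!curve %in% names(sp)) {
    abort(sprintf("curve `%s` is not a species of the %s system.",
                  curve, system))
  }
  y <- sp[[curve]]
  if (identical(y_mode, "relative")) {
    w <- species_weights(system, "P")
    if (!curve %in% names(w)) {
      abort(sprintf(
        "curve `%s` has no relative scale (not a protein-P species).", curve))
    }
    total <- as.vector(as.matrix(sp[, names(w), drop = FALSE]) %*% w)
    y <- ifelse(total > 0, w[[curve]] * y / total, 0)
  }
  y
}
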