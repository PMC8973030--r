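# Equilibrium solvers for the four mass-action systems.
#
# Quadratic systems (homodimer, 1:1 binding) are solved in closed form; each
# species is computed from its own quadratic using the cancellation-free
# conjugate branch, so conservation and mass-action residuals stay near
# machine precision even for K_D as small as 1e-18 or totals as large as 1e3.
# The competition systems reduce to a monotone scalar equation in one free
# concentration, solved by safeguarded Newton on a guaranteed bracket.

# stable positive root of x^2 + b x - c = 0 (c >= 0): picks the branch that
# avoids subtracting nearly equal numbers
stable_quad_root <- function(b, c) {
  n <- max(length(b), length(c))
  b <- rep_len(b, n)
  c <- rep_len(c, n)
  disc <- sqrt(b * b + 4 * c)
  ifelse(b >= 0, 2 * c / (b + disc), (disc - b) / 2)
}

new_binding_state <- function(species, conc, system, params) {
  out <- tibble(species = species, concentration = pmax(conc, 0))
  attr(out, "system") <- system
  attr(out, "params") <- params
  class(out) <- c("binding_state", class(out))
  out
}

#' Extract one species concentration from a binding state
#'
#' @param state a `binding_state` as returned by the `solve_*()` functions.
#' @param species species name, e.g. `"PL"`.
#' @return Concentration in mol/L.
#' @export
conc <- function(state, species) {
  stopifnot(inherits(state, "binding_state"))
  i <- match(species, state$species)
  if (anyNA(i)) {
    abort(sprintf("species `%s` not present in this state.",
                  paste(species[is.na(i)], collapse = ", ")))
  }
  state$concentration[i]
}

#' @export
print.binding_state <- function(x, ...) {
  cat(sprintf("<binding_state: %s>\n", attr(x, "system")))
  NextMethod()
}

#' Homodimerization equilibrium
#'
#' Solves the monomer--dimer equilibrium 2P = P2 with dissociation constant
#' `K_D = [P]^2 / [P2]`. The total protein concentration `c_P` counts
#' monomer-equivalents, so conservation reads `[P] + 2[P2] = c_P`. The free
#' monomer is the positive root of `2[P]^2 + K_D [P] - K_D c_P = 0`,
#' i.e. `[P] = (-K_D + sqrt(K_D^2 + 8 K_D c_P)) / 4`, evaluated in the
#' conjugate form `2 K_D c_P / (K_D + sqrt(K_D^2 + 8 K_D c_P))`.
#'
#' @param c_P total protein concentration, mol/L (monomer-equivalents).
#' @param K_D dimer dissociation constant, mol/L.
#' @return A `binding_state` tibble with species `P` and `P2`.
#' @examples
#' st <- solve_homodimer(c_P = 1.0e-4, K_D = 1.0e-5)
#' 2 * conc(st, "P2") / 1.0e-4   # dimer-bound fraction, 0.8
#' @export
solve_homodimer <- function(c_P, K_D) {
  check_conc(c_P, "c_P")
  check_conc(K_D, "K_D", positive = TRUE)
  P <- stable_quad_root(K_D / 2, K_D * c_P / 2)
  P2 <- P * P / K_D
  new_binding_state(c("P", "P2"), c(P, P2), "homodimer",
                    list(c_P = c_P, K_D = K_D))
}

#' 1:1 ligand binding equilibrium
#'
#' Solves P + L = PL with `K_D = [P][L] / [PL]`. The complex is the smaller
#' root of `x^2 - (c_P + c_L + K_D) x + c_P c_L = 0`; all three species are
#' computed from numerically stable closed forms.
#'
#' @param c_P total protein, mol/L.
#' @param c_L total ligand, mol/L.
#' @param K_D complex dissociation constant, mol/L.
#' @return A `binding_state` tibble with species `P`, `L` and `PL`.
#' @examples
#' st <- solve_ligand_binding(c_P = 1.2e-6, c_L = 4.5e-6, K_D = 4.5e-7)
#' conc(st, "PL") / 1.2e-6   # bound fraction of protein, 0.884
#' @export
solve_ligand_binding <- function(c_P, c_L, K_D) {
  check_conc(c_P, "c_P")
  check_conc(c_L, "c_L")
  check_conc(K_D, "K_D", positive = TRUE)
  P <- stable_quad_root(c_L - c_P + K_D, K_D * c_P)
  L <- stable_quad_root(c_P - c_L + K_D, K_D * c_L)
  S <- c_P + c_L + K_D
  PL <- 2 * c_P * c_L / (S + sqrt(S * S - 4 * c_P * c_L))
  new_binding_state(c("P", "L", "PL"), c(P, L, PL), "ligand_binding",
                    list(c_P = c_P, c_L = c_L, K_D = K_D))
}

#' Fraction of receptor bound at a given free ligand concentration
#'
#' The 1:1 binding isotherm `[L] / ([L] + K_D)`: the free ligand
#' concentration at which the protein is half saturated equals `K_D`.
#'
#' @param L_free free (equilibrium) ligand concentration, mol/L; may be a
#'   vector.
#' @param K_D dissociation constant, mol/L.
#' @return Bound fraction(s) in `[0, 1)`.
#' @export
bound_fraction_at_free_ligand <- function(L_free, K_D) {
  if (any(!is.finite(L_free)) || any(L_free < 0)) {
    abort("`L_free` must be finite and >= 0.",
          class = "bindsim_error_invalid_parameter")
  }
  check_conc(K_D, "K_D", positive = TRUE)
  L_free / (L_free + K_D)
}

#' Two ligands competing for one receptor
#'
#' Solves P + L = PL and P + L' = PL' with constants `K_D` and `K_Dp`.
#' Eliminating the complexes gives a cubic in the free protein; it is solved
#' as the unique root of the strictly increasing
#' `g([P]) = [P] (1 + c_L/(K_D+[P]) + c_Lp/(K_Dp+[P])) - c_P`
#' on `(0, c_P]` by safeguarded Newton iteration (bisection fallback).
#'
#' @param c_P total receptor, mol/L.
#' @param c_L,c_Lp total concentrations of the two ligands, mol/L.
#' @param K_D,K_Dp dissociation constants of PL and PL', mol/L.
#' @return A `binding_state` with species `P`, `L`, `Lp`, `PL`, `PLp`.
#' @examples
#' st <- solve_competing_ligands(1.0e-6, 5.0e-6, 1.0e-4, 1.0e-7, 2.0e-5)
#' conc(st, c("PL", "PLp")) / 1.0e-6   # 0.873, 0.106
#' @export
solve_competing_ligands <- function(c_P, c_L, c_Lp, K_D, K_Dp) {
  check_conc(c_P, "c_P"); check_conc(c_L, "c_L"); check_conc(c_Lp, "c_Lp")
  check_conc(K_D, "K_D", positive = TRUE)
  check_conc(K_Dp, "K_Dp", positive = TRUE)
  if (c_P == 0) {
    P <- 0
  } else {
    g <- function(P) P * (1 + c_L / (K_D + P) + c_Lp / (K_Dp + P)) - c_P
    dg <- function(P) 1 + c_L * K_D / (K_D + P)^2 + c_Lp * K_Dp / (K_Dp + P)^2
    P <- solve_bracketed_root(g, 0, c_P, df = dg)
  }
  L <- c_L * K_D / (K_D + P)
  Lp <- c_Lp * K_Dp / (K_Dp + P)
  new_binding_state(
    c("P", "L", "Lp", "PL", "PLp"),
    c(P, L, Lp, P * L / K_D, P * Lp / K_Dp),
    "competing_ligands",
    list(c_P = c_P, c_L = c_L, c_Lp = c_Lp, K_D = K_D, K_Dp = K_Dp))
}

#' One ligand competing for two receptors
#'
#' Solves P + L = PL and P' + L = P'L with constants `K_D` and `K_Dp`. The
#' free ligand is the unique root of the strictly increasing
#' `h([L]) = [L] (1 + c_P/(K_D+[L]) + c_Pp/(K_Dp+[L])) - c_L`
#' on `(0, c_L]`, solved as in [solve_competing_ligands()].
#'
#' @param c_P,c_Pp total concentrations of the two receptors, mol/L.
#' @param c_L total ligand, mol/L.
#' @param K_D,K_Dp dissociation constants of PL and P'L, mol/L.
#' @return A `binding_state` with species `P`, `Pp`, `L`, `PL`, `PpL`.
#' @examples
#' st <- solve_competing_receptors(1.0e-6, 4.5e-5, 2.0e-6, 1.0e-7, 8.0e-5)
#' conc(st, "PL") / 1.0e-6    # 0.878: high-affinity receptor saturation
#' @export
solve_competing_receptors <- function(c_P, c_Pp, c_L, K_D, K_Dp) {
  check_conc(c_P, "c_P"); check_conc(c_Pp, "c_Pp"); check_conc(c_L, "c_L")
  check_conc(K_D, "K_D", positive = TRUE)
  check_conc(K_Dp, "K_Dp", positive = TRUE)
  if (c_L == 0) {
    L <- 0
  } else {
    h <- function(L) L * (1 + c_P / (K_D + L) + c_Pp / (K_Dp + L)) - c_L
    dh <- function(L) 1 + c_P * K_D / (K_D + L)^2 + c_Pp * K_Dp / (K_Dp + L)^2
    L <- solve_bracketed_root(h, 0, c_L, df = dh)
  }
  PL <- c_P * L / (K_D + L)
  PpL <- c_Pp * L / (K_Dp + L)
  new_binding_state(
    c("P", "Pp", "L", "PL", "PpL"),
    c(c_P * K_D / (K_D + L), c_Pp * K_Dp / (K_Dp + L), L, PL, PpL),
    "competing_receptors",
    list(c_P = c_P, c_Pp = c_Pp, c_L = c_L, K_D = K_D, K_Dp = K_Dp))
}

#' Binding specificity factor
#'
#' For a competing-receptors state, the ratio of high-affinity to
#' low-affinity complex, `alpha_s = [PL] / [P'L]`. Specificity is high at low
#' ligand concentration (limit `c_P K_Dp / (c_Pp K_D)`) and decays toward
#' `c_P / c_Pp` as the ligand saturates both receptors.
#'
#' @param state a `binding_state` from [solve_competing_receptors()].
#' @return The dimensionless specificity factor.
#' @export
specificity <- function(state) {
  stopifnot(inherits(state, "binding_state"))
  if (attr(state, "system") != "competing_receptors") {
    abort("specificity is defined for competing-receptors states only.")
  }
  PpL <- conc(state, "PpL")
  if (PpL == 0) {
    abort("specificity is undefined: [P'L] = 0 (no low-affinity complex).",
          class = "bindsim_error_undefined_specificity")
  }
  conc(state, "PL") / PpL
}

#' Free ligand concentration where the two complexes cross
#'
#' In the competing-receptors model the complex concentrations as functions
#' of free ligand, `c_P [L]/(K_D+[L])` and `c_Pp [L]/(K_Dp+[L])`, intersect
#' at a nonzero free-ligand value
#' `x = (c_P K_Dp - c_Pp K_D) / (c_Pp - c_P)` when that value is positive;
#' otherwise the curves never meet at finite nonzero `[L]`.
#'
#' @param c_P,c_Pp total receptor concentrations, mol/L.
#' @param K_D,K_Dp dissociation constants, mol/L.
#' @return The crossover free ligand concentration in mol/L, or `NA_real_`
#'   when there is no crossover.
#' @examples
#' crossover_free_ligand(1.0e-6, 4.5e-5, 1.0e-7, 8.0e-5)  # 1.716e-6
#' @export
crossover_free_ligand <- function(c_P, c_Pp, K_D, K_Dp) {
  check_conc(c_P, "c_P"); check_conc(c_Pp, "c_Pp")
  check_conc(K_D, "K_D", positive = TRUE)
  check_conc(K_Dp, "K_Dp", positive = TRUE)
  if (c_P == c_Pp) return(NA_real_)
  x <- (c_P * K_Dp - c_Pp * K_D) / (c_Pp - c_P)
  if (!is.finite(x) || x <= 0) NA_real_ else x
}
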