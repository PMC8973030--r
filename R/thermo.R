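# Thermodynamic conversions between K_D, K_A and the binding free energy.

#' Association constant from a dissociation constant
#'
#' `K_A = 1 / K_D`, in L/mol.
#'
#' @param K_D dissociation constant, mol/L; may be a vector.
#' @return Association constant(s), L/mol.
#' @export
assoc_const <- function(K_D) {
  if (any(!is.finite(K_D)) || any(K_D <= 0)) {
    abort("`K_D` must be finite and > 0.",
          class = "bindsim_error_invalid_parameter")
  }
  1 / K_D
}

#' Dissociation constant from an association constant
#'
#' `K_D = 1 / K_A`, in mol/L.
#'
#' @param K_A association constant, L/mol; may be a vector.
#' @return Dissociation constant(s), mol/L.
#' @export
dissoc_const <- function(K_A) {
  if (any(!is.finite(K_A)) || any(K_A <= 0)) {
    abort("`K_A` must be finite and > 0.",
          class = "bindsim_error_invalid_parameter")
  }
  1 / K_A
}

#' Gibbs free energy of association
#'
#' `Delta G = R T ln(K_D)` with `K_D` taken numerically in mol/L (the unit is
#' discarded inside the logarithm, by convention). Negative for favourable
#' association (`K_D < 1` mol/L).
#'
#' @param K_D dissociation constant, mol/L; may be a vector.
#' @param temperature temperature in K (default 298.15, i.e. 25 C).
#' @param gas_constant molar gas constant in J K^-1 mol^-1 (default 8.314).
#' @return Free energy in J/mol.
#' @examples
#' gibbs_energy(1.6e-8) / 1000   # -44.5 kJ/mol
#' @export
gibbs_energy <- function(K_D, temperature = 298.15, gas_constant = 8.314) {
  if (any(!is.finite(K_D)) || any(K_D <= 0)) {
    abort("`K_D` must be finite and > 0.",
          class = "bindsim_error_invalid_parameter")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be > 0 K.",
          class = "bindsim_error_invalid_parameter")
  }
  gas_constant * temperature * log(K_D)
}

# two-significant-figure display string, matching the applet-style labels
format_sig2 <- function(x) {
  ifelse(is.finite(x), formatC(signif(x, 2), format = "g", digits = 2),
         as.character(x))
}

# thermodynamic summary rows for every dissociation constant in a parameter
# set; used by the JSON writer and the fit report
thermo_rows <- function(K_D, names, temperature = 298.15) {
  tibble(
    constant = names,
    K_D = K_D,
    K_A = assoc_const(K_D),
    delta_G = gibbs_energy(K_D, temperature = temperature)
  )
}
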