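# Independent oracles: naive bisection on the scalar conservation equations,
# direct residual summation, and shared property checkers. These never call
# the package's solvers.

bisect <- function(f, lo, hi, iter = 200L) {
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# free monomer from [P] + 2 [P]^2 / K_D = c_P
oracle_homodimer_P <- function(c_P, K_D) {
  if (c_P == 0) return(0)
  bisect(function(P) P + 2 * P^2 / K_D - c_P, 0, c_P)
}

# complex from ([PL] - c_P)([PL] - c_L) = K_D [PL], smaller root
oracle_ligand_PL <- function(c_P, c_L, K_D) {
  if (c_P == 0 || c_L == 0) return(0)
  bisect(function(x) x * (K_D + c_P + c_L - x) - c_P * c_L, 0, min(c_P, c_L))
}

# free receptor in the two-ligand competition
oracle_cl_P <- function(c_P, c_L, c_Lp, K_D, K_Dp) {
  if (c_P == 0) return(0)
  bisect(function(P) P * (1 + c_L / (K_D + P) + c_Lp / (K_Dp + P)) - c_P,
         0, c_P)
}

# free ligand in the two-receptor competition
oracle_cr_L <- function(c_P, c_Pp, c_L, K_D, K_Dp) {
  if (c_L == 0) return(0)
  bisect(function(L) L * (1 + c_P / (K_D + L) + c_Pp / (K_Dp + L)) - c_L,
         0, c_L)
}

# log-uniform draw over the slider range
runif_conc <- function(n, lo = 1e-9, hi = 1e-1) {
  10^stats::runif(n, log10(lo), log10(hi))
}

# totals implied by a state: named vector, dimer counted twice
state_totals <- function(state) {
  s <- stats::setNames(state$concentration, state$species)
  switch(attr(state, "system"),
    homodimer = c(c_P = unname(s["P"] + 2 * s["P2"])),
    ligand_binding = c(c_P = unname(s["P"] + s["PL"]),
                       c_L = unname(s["L"] + s["PL"])),
    competing_ligands = c(c_P = unname(s["P"] + s["PL"] + s["PLp"]),
                          c_L = unname(s["L"] + s["PL"]),
                          c_Lp = unname(s["Lp"] + s["PLp"])),
    competing_receptors = c(c_P = unname(s["P"] + s["PL"]),
                            c_Pp = unname(s["Pp"] + s["PpL"]),
                            c_L = unname(s["L"] + s["PL"] + s["PpL"])))
}

# mass-action ratios (free*free/complex) actually realized in a state,
# paired with the K_D each should reproduce
state_mass_action <- function(state) {
  s <- stats::setNames(state$concentration, state$species)
  p <- attr(state, "params")
  switch(attr(state, "system"),
    homodimer = list(list(ratio = s[["P"]]^2 / s[["P2"]], K = p$K_D)),
    ligand_binding = list(
      list(ratio = s[["P"]] * s[["L"]] / s[["PL"]], K = p$K_D)),
    competing_ligands = list(
      list(ratio = s[["P"]] * s[["L"]] / s[["PL"]], K = p$K_D),
      list(ratio = s[["P"]] * s[["Lp"]] / s[["PLp"]], K = p$K_Dp)),
    competing_receptors = list(
      list(ratio = s[["P"]] * s[["L"]] / s[["PL"]], K = p$K_D),
      list(ratio = s[["Pp"]] * s[["L"]] / s[["PpL"]], K = p$K_Dp)))
}

expect_state_consistent <- function(state, cons_tol = 1e-9, ma_tol = 1e-6) {
  expect_true(all(state$concentration >= 0))
  expect_true(all(is.finite(state$concentration)))
  totals <- state_totals(state)
  declared <- unlist(attr(state, "params")[names(totals)])
  for (nm in names(totals)) {
    if (declared[[nm]] > 0) {
      expect_lt(abs(totals[[nm]] - declared[[nm]]) / declared[[nm]], cons_tol)
    } else {
      expect_equal(totals[[nm]], 0)
    }
  }
  for (ma in state_mass_action(state)) {
    if (is.finite(ma$ratio)) {          # complex may be 0 in degenerate cases
      expect_lt(abs(ma$ratio - ma$K) / ma$K, ma_tol)
    }
  }
  invisible(state)
}

# parameter-recovery run: continuous fit of K_D on noisy synthetic fractions
# (12 points, two decades around the truth, sd 0.02) over several seeds;
# returns the relative errors
recovery_errors <- function(system, truth, fixed, x_var, curve, seeds) {
  vapply(seeds, function(seed) {
    d <- generate_binding_data(system, c(fixed, list(K_D = truth)),
                               curve = curve, x_var = x_var,
                               y_mode = "relative", n = 12,
                               x_range = truth * c(0.1, 10), sd = 0.02,
                               seed = seed)
    fit <- binding_fit(d, system, curve = curve, x_var = x_var,
                       y_mode = "relative", free = "K_D", fixed = fixed,
                       method = "continuous")
    abs(coef(fit)[["K_D"]] - truth) / truth
  }, numeric(1))
}
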