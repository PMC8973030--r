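# The two cubic competition systems, the specificity factor and the
# complex-crossover point.

fig3 <- list(c_P = 1.0e-6, c_L = 5.0e-6, c_Lp = 1.0e-4,
             K_D = 1.0e-7, K_Dp = 2.0e-5)
fig4 <- list(c_P = 1.0e-6, c_Pp = 4.5e-5, c_L = 2.0e-6,
             K_D = 1.0e-7, K_Dp = 8.0e-5)

test_that("competing ligands reproduces the worked receptor-occupancy pie", {
  st <- do.call(solve_competing_ligands, fig3)
  expect_equal(conc(st, "PL") / fig3$c_P, 0.873, tolerance = 6e-4)
  expect_equal(conc(st, "PLp") / fig3$c_P, 0.106, tolerance = 4e-3)
  expect_equal(conc(st, "P") / fig3$c_P, 0.021, tolerance = 1e-2)
  expect_state_consistent(st)
})

test_that("carbon monoxide displaces oxygen at the reported level", {
  st <- solve_competing_ligands(c_P = 9.0e-3, c_L = 9.0e-4, c_Lp = 8.6e-3,
                                K_D = 1.3e-9, K_Dp = 3.1e-7)
  expect_equal(conc(st, "PL") / 9.0e-3, 0.10, tolerance = 5e-3)
  expect_state_consistent(st)
})

test_that("zero competitor reduces competing ligands to 1:1 binding", {
  set.seed(41)
  for (i in 1:10) {
    p <- runif_conc(3)
    st2 <- solve_ligand_binding(p[1], p[2], p[3])
    st3 <- solve_competing_ligands(p[1], p[2], 0, p[3], 1e-4)
    for (sp in c("P", "L", "PL")) {
      expect_equal(conc(st3, sp), conc(st2, sp), tolerance = 1e-9)
    }
  }
})

test_that("competing receptors reproduces the worked saturations", {
  st <- do.call(solve_competing_receptors, fig4)
  expect_equal(conc(st, "PL") / fig4$c_P, 0.878, tolerance = 3e-4)
  expect_equal(conc(st, "PpL") / fig4$c_Pp, 0.009, tolerance = 1e-2)
  # free ligand at this point, frozen from the bisection oracle
  expect_equal(conc(st, "L"), 7.203314e-7, tolerance = 1e-5)
  expect_state_consistent(st)
})

test_that("zero second receptor reduces competing receptors to 1:1 binding", {
  set.seed(42)
  for (i in 1:10) {
    p <- runif_conc(3)
    st2 <- solve_ligand_binding(p[1], p[2], p[3])
    st3 <- solve_competing_receptors(p[1], 0, p[2], p[3], 1e-4)
    for (sp in c("P", "L", "PL")) {
      expect_equal(conc(st3, sp), conc(st2, sp), tolerance = 1e-9)
    }
  }
})

test_that("specificity factor matches the worked value and its symmetry", {
  st <- do.call(solve_competing_receptors, fig4)
  expect_equal(specificity(st), 2.2, tolerance = 0.025)
  # equal affinities: alpha_s = c_P / c_Pp at any ligand concentration
  for (cL in c(1e-8, 1e-6, 1e-3)) {
    st <- solve_competing_receptors(2e-6, 8e-6, cL, 3e-7, 3e-7)
    expect_equal(specificity(st), 2e-6 / 8e-6, tolerance = 1e-9)
  }
})

test_that("specificity is decreasing in ligand with the analytic limits", {
  cLs <- 10^seq(-12, 1, length.out = 40)
  a <- vapply(cLs, function(cL) {
    specificity(solve_competing_receptors(fig4$c_P, fig4$c_Pp, cL,
                                          fig4$K_D, fig4$K_Dp))
  }, numeric(1))
  expect_true(all(diff(a) < 0))
  lim0 <- fig4$c_P * fig4$K_Dp / (fig4$c_Pp * fig4$K_D)  # 17.8
  expect_equal(a[1], lim0, tolerance = 1e-3)
  expect_equal(a[1], 17.778, tolerance = 1e-3)
  expect_gt(a[length(a)], fig4$c_P / fig4$c_Pp * (1 - 1e-3))
})

test_that("undefined specificity is an error, not a silent division", {
  st <- solve_competing_receptors(1e-6, 0, 1e-6, 1e-7, 8e-5)
  expect_error(specificity(st),
               class = "bindsim_error_undefined_specificity")
  st <- solve_ligand_binding(1e-6, 1e-6, 1e-7)
  expect_error(specificity(st))
})

test_that("crossover free-ligand matches the closed form and its edge cases", {
  x <- crossover_free_ligand(1.0e-6, 4.5e-5, 1.0e-7, 8.0e-5)
  expect_equal(x, 1.715909e-6, tolerance = 1e-6)
  expect_equal(signif(x, 2), 1.7e-6)
  # the closed form is where the two complex-vs-free-[L] curves really cross
  f <- function(L) 1.0e-6 * L / (1.0e-7 + L) - 4.5e-5 * L / (8.0e-5 + L)
  expect_equal(bisect(function(L) -f(L), 1e-9, 1e-3), x, tolerance = 1e-9)
  # equal receptor totals: no finite crossover
  expect_true(is.na(crossover_free_ligand(1e-6, 1e-6, 1e-7, 8e-5)))
  # closed form negative: rejected
  expect_true(is.na(crossover_free_ligand(1e-6, 2e-6, 1e-7, 1e-7)))
})

test_that("a non-converging bracket errors instead of returning silently", {
  expect_error(solve_bracketed_root(function(x) x - 0.3, 0, 1, max_iter = 1),
               class = "bindsim_error_numerical_failure")
  expect_error(solve_bracketed_root(function(x) x + 10, 0, 1),
               class = "bindsim_error_bracket")
})
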