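# The least-squares tool: objective, the three grid strategies and the
# continuous refiner.

table2_prob <- function() {
  list(data = binding_fixture("table2"), system = "ligand_binding",
       curve = "PL", x_var = "free_L", y_mode = "relative",
       fixed = list(c_P = 1.2e-6))
}

table3_prob <- function() {
  list(data = binding_fixture("table3"), system = "homodimer",
       curve = "P", x_var = "c_P", y_mode = "absolute", fixed = list())
}

test_that("the residual objective matches direct summation", {
  # data generated exactly on the curve: zero residual
  x <- 10^seq(-7, -5, length.out = 6)
  y <- x / (x + 4.5e-7)
  d <- data.frame(x, y)
  expect_equal(binding_ssr(d, "ligand_binding", "PL", "free_L", "relative",
                           list(c_P = 1e-6, K_D = 4.5e-7)), 0)
  # the published iron dataset against K_D = 4.5e-7: direct oracle sum
  t2 <- binding_fixture("table2")
  oracle <- sum((t2$x / (t2$x + 4.5e-7) - t2$y)^2)
  expect_equal(oracle, 0.056786, tolerance = 1e-4)
  expect_equal(binding_ssr(t2, "ligand_binding", "PL", "free_L", "relative",
                           list(c_P = 1.2e-6, K_D = 4.5e-7)),
               oracle, tolerance = 1e-12)
  # duplicating a point doubles its residual contribution
  d2 <- rbind(t2, t2[3, ])
  delta <- binding_ssr(d2, "ligand_binding", "PL", "free_L", "relative",
                       list(c_P = 1.2e-6, K_D = 4.5e-7)) - oracle
  expect_equal(delta, (t2$x[3] / (t2$x[3] + 4.5e-7) - t2$y[3])^2,
               tolerance = 1e-12)
})

test_that("single-pass search finds the dimer dissociation constant", {
  p <- table3_prob()
  fit <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                     free = "K_D", method = "single_pass")
  expect_equal(coef(fit)[["K_D"]], 1.6e-8, tolerance = 1e-12)
  # grid optimality: no grid position does better
  g <- slider_grid()
  all_ssr <- vapply(g$positions, function(kd) {
    binding_ssr(p$data, p$system, p$curve, p$x_var, p$y_mode,
                list(K_D = kd))
  }, numeric(1))
  expect_equal(fit$ssr, min(all_ssr), tolerance = 1e-12)
})

test_that("noiseless data generated at a grid position is recovered exactly", {
  d <- generate_binding_data("ligand_binding",
                             list(c_P = 1e-8, K_D = 3.2e-6), curve = "PL",
                             x_var = "c_L", y_mode = "relative", sd = 0)
  for (m in c("single_pass", "two_pass")) {
    fit <- binding_fit(d, "ligand_binding", "PL", "c_L", "relative",
                       free = "K_D", fixed = list(c_P = 1e-8), method = m)
    expect_equal(coef(fit)[["K_D"]], 3.2e-6, tolerance = 1e-12)
    expect_lt(fit$ssr, 1e-20)
  }
})

test_that("two-pass equals single-pass on well-behaved problems", {
  p2 <- table2_prob()
  p3 <- table3_prob()
  for (p in list(p2, p3)) {
    f1 <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                      free = "K_D", fixed = p$fixed, method = "single_pass")
    f2 <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                      free = "K_D", fixed = p$fixed, method = "two_pass")
    expect_equal(coef(f1), coef(f2))
    expect_lte(f2$ssr, f2$trace$coarse_ssr)
  }
  set.seed(61)
  for (i in 1:5) {
    kd <- runif_conc(1, 1e-8, 1e-3)
    d <- generate_binding_data("homodimer", list(K_D = kd), curve = "P",
                               x_var = "c_P", y_mode = "relative",
                               sd = 0.02, seed = 100 + i)
    f1 <- binding_fit(d, "homodimer", "P", "c_P", "relative", free = "K_D",
                      method = "single_pass")
    f2 <- binding_fit(d, "homodimer", "P", "c_P", "relative", free = "K_D",
                      method = "two_pass")
    expect_equal(coef(f1), coef(f2))
  }
})

test_that("the dimer data fit reports the published grid value 1.6e-8", {
  p <- table3_prob()
  for (m in c("two_pass", "single_pass")) {
    fit <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                       free = "K_D", method = m)
    expect_equal(signif(coef(fit)[["K_D"]], 2), 1.6e-8)
    expect_equal(signif(fit$thermo$K_A, 2), 6.2e7)
    expect_equal(round(fit$thermo$delta_G / 1000, 1), -44.5)
  }
})

test_that("iterative search descends to the optimum and respects fixed points", {
  p <- table3_prob()
  single <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                        free = "K_D", method = "single_pass")
  # starting at the optimum: returned unchanged
  fit <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                     free = "K_D", method = "iterative",
                     start = coef(single))
  expect_identical(coef(fit), coef(single))
  # descending from two decades away reaches the same optimum
  fit <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                     free = "K_D", method = "iterative",
                     start = c(K_D = 1e-7))
  expect_equal(coef(fit)[["K_D"]], 1.6e-8)
  expect_error(binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                           free = "K_D", method = "iterative"))
})

test_that("iterative search stays in a constructed local minimum", {
  # two x clusters, each generated exactly from a different K_D, make the
  # residual surface bimodal in K_D
  x <- c(1e-7, 2e-7, 1e-3, 2e-3)
  y <- c(x[1:2] / (x[1:2] + 1e-7), x[3:4] / (x[3:4] + 1e-3))
  d <- data.frame(x, y)
  g <- slider_grid()
  ssr <- vapply(g$positions, function(kd) {
    binding_ssr(d, "ligand_binding", "PL", "free_L", "relative",
                list(c_P = 1e-8, K_D = kd))
  }, numeric(1))
  n <- length(ssr)
  local_min <- which(ssr < c(Inf, ssr[-n]) & ssr < c(ssr[-1], Inf))
  expect_gte(length(local_min), 2)  # genuinely multimodal
  non_global <- setdiff(local_min, which.min(ssr))[1]
  fit <- binding_fit(d, "ligand_binding", "PL", "free_L", "relative",
                     free = "K_D", fixed = list(c_P = 1e-8),
                     method = "iterative",
                     start = c(K_D = g$positions[non_global]))
  expect_identical(coef(fit)[["K_D"]], g$positions[non_global])
  expect_gt(fit$ssr, min(ssr))
})

test_that("continuous refinement matches a dense brute-force oracle", {
  # dimer data: the refined optimum, free of the slider grid
  p <- table3_prob()
  fit <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                     free = "K_D", method = "continuous")
  expect_equal(signif(coef(fit)[["K_D"]], 2), 1.6e-8)
  expect_equal(coef(fit)[["K_D"]], 1.56e-8, tolerance = 5e-3)
  single <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                        free = "K_D", method = "single_pass")
  expect_lte(fit$ssr, single$ssr)

  # iron data: dense mantissa-0.01 brute force around the optimum
  p <- table2_prob()
  fit <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                     free = "K_D", fixed = p$fixed, method = "continuous")
  dense <- 10^seq(-7, -6, by = 0.00025)
  dssr <- vapply(dense, function(kd) {
    sum((p$data$x / (p$data$x + kd) - p$data$y)^2)
  }, numeric(1))
  oracle_opt <- dense[which.min(dssr)]
  expect_equal(coef(fit)[["K_D"]], oracle_opt, tolerance = 1e-3)
  expect_lte(fit$ssr, min(dssr))
})

test_that("noiseless synthetic data is recovered to high precision", {
  d <- generate_binding_data("homodimer", list(K_D = 3.7e-5), curve = "P",
                             x_var = "c_P", y_mode = "relative", sd = 0)
  fit <- binding_fit(d, "homodimer", "P", "c_P", "relative", free = "K_D",
                     method = "continuous")
  expect_equal(coef(fit)[["K_D"]], 3.7e-5, tolerance = 1e-6)
})

test_that("fitted concentration parameters scale with the problem", {
  for (s in c(1, 10)) {
    d <- generate_binding_data("ligand_binding",
                               list(c_P = 1e-8 * s, K_D = 3.2e-6 * s),
                               curve = "PL", x_var = "c_L",
                               y_mode = "relative",
                               x_range = 3.2e-6 * s * c(0.1, 10), sd = 0)
    fit <- binding_fit(d, "ligand_binding", "PL", "c_L", "relative",
                       free = "K_D", fixed = list(c_P = 1e-8 * s),
                       method = "single_pass")
    expect_equal(coef(fit)[["K_D"]], 3.2e-6 * s, tolerance = 1e-12)
  }
})

test_that("fit accessors expose tidy summaries", {
  p <- table3_prob()
  fit <- binding_fit(p$data, p$system, p$curve, p$x_var, p$y_mode,
                     free = "K_D", method = "two_pass")
  td <- tidy(fit)
  expect_equal(td$term, "K_D")
  expect_equal(td$K_A, 1 / td$estimate)
  gl <- glance(fit)
  expect_equal(gl$n_obs, 7L)
  expect_equal(gl$method, "two_pass")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("fit problem validation catches bad configurations", {
  d <- data.frame(x = 1e-6, y = 0.5)
  expect_error(binding_fit(d, "homodimer", "P", "c_P", "absolute",
                           free = character(0)))
  expect_error(binding_fit(d, "homodimer", "P", "c_P", "absolute",
                           free = "K_Dp"))
  expect_error(binding_fit(d, "ligand_binding", "PL", "c_L", "relative",
                           free = "K_D"))   # c_P missing
  expect_error(binding_fit(data.frame(x = numeric(0), y = numeric(0)),
                           "homodimer", "P", "c_P", "absolute",
                           free = "K_D"))
})
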