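# simulate categorical ratings from an equal-variance binormal model and
# bin them at the anchor cutpoints (scores mapped onto 0-100 by the probit
# link, so c = 0 data are exactly binormal on the latent scale)
simulate_binormal_counts <- function(n1, n0, d_a, seed) {
  set.seed(seed)
  d <- 100 * pnorm(rnorm(n1, mean = d_a, sd = 1) / 2)
  n <- 100 * pnorm(rnorm(n0, mean = 0, sd = 1) / 2)
  bin_scores(d, nondiseased_scores = n)
}

test_that("binning respects the half-open convention and conserves totals", {
  ct <- bin_scores(c(41, 60.99, 61, 81, -Inf), nondiseased_scores = c(0, 20.99, 21, 40.99))
  # 41 lands in [41,61), -Inf in the bottom category
  expect_identical(ct$n_diseased, c(1L, 0L, 2L, 1L, 1L))
  expect_identical(ct$n_nondiseased, c(2L, 2L, 0L, 0L, 0L))
  set.seed(88)
  for (i in 1:20) {
    d <- runif(30, 0, 100); n <- runif(40, 0, 100)
    d[1:3] <- -Inf
    ct <- bin_scores(d, nondiseased_scores = n)
    expect_identical(sum(ct$n_diseased), 30L)
    expect_identical(sum(ct$n_nondiseased), 40L)
  }
  expect_error(bin_scores(numeric(0), nondiseased_scores = 1),
               class = "cadmrmc_input_error")
  expect_error(bin_scores(1, boundaries = c(41, 21), nondiseased_scores = 1),
               class = "cadmrmc_input_error")
})

test_that("the c = 0 curve equals the equal-variance binormal closed form", {
  grid <- seq(0, 1, length.out = 11)
  for (d_a in c(0.5, 1.5, 2.5)) {
    crv <- proproc_curve(list(c = 0, d_a = d_a), grid)
    closed <- ifelse(grid %in% c(0, 1), grid, pnorm(d_a + qnorm(grid)))
    expect_lt(max(abs(crv$tpf - closed)), 1e-6)
  }
})

test_that("the chance fit gives the exact reference values", {
  chance <- list(c = 0, d_a = 0)
  crv <- proproc_curve(chance, seq(0, 1, by = 0.1))
  expect_equal(crv$tpf, crv$fpf, tolerance = 1e-12)
  expect_equal(pauc(chance), 0.02, tolerance = 1e-12)
  expect_equal(sens_at_spec(chance, 0.90), 0.10, tolerance = 1e-12)
  expect_equal(full_auc(chance), 0.5, tolerance = 1e-12)
  # perfect curve limits
  expect_equal(pauc(list(c = 0, d_a = 8)), 0.2, tolerance = 1e-4)
  expect_equal(sens_at_spec(list(c = 0, d_a = 8)), 1, tolerance = 1e-6)
})

test_that("fitted curves are proper: monotone with non-increasing slope", {
  grid <- seq(0.001, 0.999, length.out = 400)
  for (p in list(list(c = 0.6, d_a = 1.2), list(c = -0.6, d_a = 1.2),
                 list(c = 0.2, d_a = 2.5), list(c = -0.9, d_a = 0.5))) {
    tpf <- proproc_curve(p, grid)$tpf
    expect_true(all(diff(tpf) >= -1e-10))
    expect_true(all(tpf >= grid - 1e-8))          # never below chance
    slope <- diff(tpf) / diff(grid)
    expect_true(all(diff(slope) <= 1e-6))         # concave (no hook)
  }
})

test_that("the analytic AUC agrees with numerical curve integration", {
  for (p in list(list(c = 0, d_a = 1.5), list(c = 0.45, d_a = 0.8),
                 list(c = -0.45, d_a = 0.8), list(c = 0.8, d_a = 2),
                 list(c = -0.3, d_a = 0))) {
    a_closed <- full_auc(p)
    a_num <- integrate(function(f) proproc_curve(p, f)$tpf, 0, 1,
                       rel.tol = 1e-10, subdivisions = 400L)$value
    expect_equal(a_closed, a_num, tolerance = 1e-8)
  }
  # c = 0 closed form
  expect_equal(full_auc(list(c = 0, d_a = 1.5)), pnorm(1.5 / sqrt(2)),
               tolerance = 1e-10)
  # d_a = 0 with variance asymmetry: AUC = 1 - asin((1-c^2)/(1+c^2))/pi
  expect_equal(full_auc(list(c = 0.3, d_a = 0)), 1 - asin((1 - 0.09) / (1 + 0.09)) / pi,
               tolerance = 1e-8)
})

test_that("partial areas match an independent quadrature oracle", {
  # c = 0: integrand has the binormal closed form, integrated independently
  oracle <- integrate(function(f) pnorm(1.5 + qnorm(f)), 0, 0.2,
                      rel.tol = 1e-12)$value
  expect_equal(pauc(list(c = 0, d_a = 1.5)), oracle, tolerance = 1e-8)
  # sens at 90% specificity equals the closed-form TPF at FPF = 0.1
  expect_equal(sens_at_spec(list(c = 0, d_a = 1.5), 0.90),
               pnorm(1.5 + qnorm(0.1)), tolerance = 1e-8)
  # pauc over the whole unit interval is the full AUC
  for (p in list(list(c = 0.4, d_a = 1), list(c = -0.5, d_a = 1.8))) {
    expect_equal(pauc(p, c(0, 1)), full_auc(p), tolerance = 1e-7)
  }
  # pauc bounds
  expect_lte(pauc(list(c = 0.4, d_a = 1)), 0.2)
  expect_lte(pauc(list(c = 0.4, d_a = 1)), full_auc(list(c = 0.4, d_a = 1)))
})

test_that("AUC increases with d_a at fixed c", {
  for (cc in c(-0.5, 0, 0.5)) {
    aucs <- vapply(c(0.2, 0.8, 1.5, 2.5), function(d) full_auc(list(c = cc, d_a = d)),
                   numeric(1))
    expect_true(all(diff(aucs) > 0))
  }
})

test_that("maximum likelihood recovers known binormal parameters", {
  ct <- simulate_binormal_counts(500, 500, d_a = 1.5, seed = 2024)
  fit <- fit_proproc(ct)
  expect_true(fit$converged)
  expect_lt(abs(fit$c - 0), 0.1)
  expect_lt(abs(fit$d_a - 1.5), 0.15)
  expect_true(all(diff(fit$cutpoints$fpf) < 0))
  expect_true(is.finite(fit$loglik))
})

test_that("identical diseased and nondiseased counts fit near chance", {
  ct <- structure(tibble::tibble(category = 1:5,
                                 n_diseased = c(30L, 25L, 20L, 15L, 10L),
                                 n_nondiseased = c(30L, 25L, 20L, 15L, 10L)),
                  class = c("rating_counts", class(tibble::tibble())),
                  boundaries = c(21, 41, 61, 81))
  fit <- fit_proproc(ct)
  expect_lt(abs(full_auc(fit) - 0.5), 0.02)
})

test_that("perfect separation is flagged degenerate at the d_a bound", {
  ct <- bin_scores(c(85, 90, 95, 99), nondiseased_scores = c(5, 10, 15, 25))
  fit <- fit_proproc(ct)
  expect_false(fit$converged)
  expect_identical(fit$reason, "degenerate")
  expect_gte(fit$d_a, 6)
  expect_error(
    fit_proproc(bin_scores(rep(50, 4), nondiseased_scores = rep(50, 3))),
    class = "cadmrmc_input_error")
})

test_that("tidy and glance expose the fit in broom style", {
  ct <- simulate_binormal_counts(200, 200, d_a = 1.2, seed = 7)
  fit <- fit_proproc(ct)
  td <- tidy(fit)
  expect_identical(td$term, c("c", "d_a"))
  gl <- glance(fit)
  expect_true(all(c("auc", "pauc", "sens_at_spec90", "logLik", "converged")
                  %in% names(gl)))
  expect_equal(gl$auc, full_auc(fit))
})

test_that("median parameter recovery holds over replicated fits", {
  set.seed(140100)
  err_c <- err_d <- numeric(40)
  for (i in 1:40) {
    d <- 100 * pnorm(rnorm(500, mean = 1.5) / 2)
    n <- 100 * pnorm(rnorm(500, mean = 0) / 2)
    fit <- fit_proproc(bin_scores(d, nondiseased_scores = n))
    err_c[i] <- abs(fit$c); err_d[i] <- abs(fit$d_a - 1.5)
  }
  expect_lt(median(err_c), 0.1)
  expect_lt(median(err_d), 0.15)
})
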