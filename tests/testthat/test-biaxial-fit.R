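test_that("residual SSE matches its definition", {
  p <- table1$mid_flap_3
  d0 <- generate_biaxial_dataset(p, biaxial_protocol())
  expect_equal(residual_sse(p, d0), 0)

  # one record offset by (+10, -10) Pa -> SSE = 200 Pa^2
  s <- biaxial_cauchy_stress(p, 1.2, 1.1)
  rec <- data.frame(protocol = c(1, 1, 2), lambda_c = c(1.2, 1.01, 1.02),
                    lambda_a = c(1.1, 1.01, 1.0))
  sm <- biaxial_cauchy_stress(p, rec$lambda_c, rec$lambda_a)
  rec$sigma_cc_pa <- sm[, 1] + c(10, 0, 0)
  rec$sigma_aa_pa <- sm[, 2] + c(-10, 0, 0)
  expect_equal(residual_sse(p, biaxial_dataset(rec)), 200)
})

test_that("SSE of mismatched parameter sets equals the direct-evaluation oracle", {
  gen <- table1$distal_flap_4
  trial <- table1$distal_flap_2
  d <- generate_biaxial_dataset(gen, biaxial_protocol())
  v <- residual_sse(trial, d)
  expect_gt(v, 0)
  expect_equal(v, oracle_sse(trial, d), tolerance = 1e-5)
})

test_that("SSE and fit are invariant to record order", {
  p <- table1$mid_flap_5
  d <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.02, seed = 9))
  set.seed(1)
  perm <- sample(nrow(d))
  dp <- biaxial_dataset(as.data.frame(d)[perm, ])
  expect_equal(residual_sse(p, d), residual_sse(p, dp))
  f1 <- fit_goh(d, restarts = 2, seed = 4)
  f2 <- fit_goh(dp, restarts = 2, seed = 4)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("best objective is monotone non-increasing across restarts", {
  p <- table1$mid_flap_4
  d <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.02, seed = 21))
  f <- fit_goh(d, restarts = 5, seed = 2)
  expect_true(all(diff(f$trace) <= 0))
  expect_equal(f$sse, min(f$restart_sse))
})

test_that("noise-free data is recovered to sub-Pa^2 residuals", {
  p <- table1$mid_flap_3
  d <- generate_biaxial_dataset(p, biaxial_protocol())
  f <- fit_goh(d, restarts = 4, seed = 1)
  expect_lt(f$sse / nrow(d), 1)
  expect_true(f$converged)
  # stress-space recovery
  expect_lt(max(abs(predict(f) - predict(f, d))), 1e-9)
  pred <- biaxial_cauchy_stress(f$params, d$lambda_c, d$lambda_a)
  gen <- biaxial_cauchy_stress(p, d$lambda_c, d$lambda_a)
  expect_lt(max(abs(pred - gen)), 1)  # Pa
})

test_that("a generator at the isotropic-dispersion limit leaves alpha free", {
  p <- goh_params(6e4, 1.5e5, 4, alpha = 35, kappa = 1 / 3, label = "iso")
  d <- generate_biaxial_dataset(p, biaxial_protocol())
  # predictions of the generating model do not depend on alpha at all
  p2 <- p; p2$alpha <- 80
  expect_equal(residual_sse(p2, d), 0, tolerance = 1e-14)
  f <- fit_goh(d, restarts = 4, seed = 3)
  expect_lt(f$sse / nrow(d), 1)
})

test_that("fit object methods behave like a standard model fit", {
  p <- table1$distal_flap_3
  d <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.02, seed = 5))
  f <- fit_goh(d, restarts = 3, seed = 1)
  expect_named(coef(f), c("c10", "k1", "k2", "alpha", "kappa"))
  expect_equal(dim(residuals(f)), c(nrow(d), 2L))
  expect_equal(unname(fitted(f) + residuals(f)),
               unname(cbind(d$sigma_cc_pa, d$sigma_aa_pa)), tolerance = 1e-9)
  sm <- summary(f)
  expect_s3_class(sm, "summary.goh_fit")
  expect_equal(sm$sse, f$sse)
  sims <- simulate(f, nsim = 2, seed = 11)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "biaxial_dataset")
  expect_output(print(f), "Nelder-Mead")
})

test_that("degenerate datasets are rejected", {
  p <- table1$mid_flap_1
  d <- generate_biaxial_dataset(p, biaxial_protocol())
  expect_error(residual_sse(p, d[0, ]), "empty|biaxial")
  one_proto <- biaxial_dataset(as.data.frame(d)[d$protocol == 1, ])
  expect_error(fit_goh(one_proto), "protocols")
  tiny <- biaxial_dataset(as.data.frame(d)[c(1:4, 16:19), ])
  expect_error(fit_goh(tiny), "10 records")
})
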