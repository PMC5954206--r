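test_that("noise-free generation reproduces the model exactly", {
  p <- table1$mid_flap_1
  d <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0))
  expect_equal(residual_sse(p, d), 0)
  expect_equal(nrow(d), 45)          # 3 protocols x 15 points
  expect_length(unique(d$protocol), 3)
  expect_true(all(d$lambda_c <= 1.30 + 1e-12))
})

test_that("generation is reproducible from the seed", {
  p <- table1$distal_flap_2
  d1 <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.05, seed = 17))
  d2 <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.05, seed = 17))
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.05, seed = 18))
  expect_false(identical(d1$sigma_cc_pa, d3$sigma_cc_pa))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); a <- rnorm(1)
  set.seed(99)
  invisible(generate_biaxial_dataset(p, biaxial_protocol(cv = 0.05, seed = 17)))
  expect_identical(rnorm(1), a)
})

test_that("empirical noise level matches the requested cv", {
  p <- table1$mid_flap_1
  d <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.02, seed = 17))
  truth <- biaxial_cauchy_stress(p, d$lambda_c, d$lambda_a)
  ratio <- c(d$sigma_cc_pa / truth[, 1], d$sigma_aa_pa / truth[, 2]) - 1
  n <- length(ratio)
  # sd of the multiplicative perturbation within 3 sigma of cv = 0.02
  se_sd <- 0.02 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(ratio) - 0.02), 3 * se_sd)
  expect_lt(abs(mean(ratio)), 3 * 0.02 / sqrt(n))
})

test_that("material variants respect ranges, seeds and bounds", {
  base <- table2$tl_wall
  expect_identical(generate_material_variants(base, n = 1)[[1]], base)
  zeros <- generate_material_variants(base, list(c10 = 0, k1 = 0), n = 5, seed = 2)
  for (v in zeros[-1]) {
    expect_equal(v$c10, base$c10)
    expect_equal(v$k1, base$k1)
  }
  vs <- generate_material_variants(base, list(c10 = 0.2, k1 = 0.2),
                                   n = 101, seed = 3)
  c10s <- vapply(vs[-1], function(v) v$c10, 0)
  expect_true(all(c10s >= base$c10 * 0.8 & c10s <= base$c10 * 1.2))
  expect_lt(abs(mean(c10s) / base$c10 - 1), 0.02)
  expect_identical(generate_material_variants(base, list(c10 = 0.2), n = 4, seed = 5),
                   generate_material_variants(base, list(c10 = 0.2), n = 4, seed = 5))
  # kappa = 0.3 cannot take a +20% perturbation without leaving [0, 1/3]
  expect_error(generate_material_variants(table2$mid_fl_wall,
                                          list(kappa = 0.2), n = 3),
               "bounds")
})

test_that("protocol invariants are enforced", {
  expect_error(biaxial_protocol(max_stretch = 1), "max_stretch")
  expect_error(biaxial_protocol(points = 2), "points")
  expect_error(biaxial_protocol(cv = -0.1), "cv")
  expect_error(biaxial_dataset(data.frame(protocol = 1, lambda_c = 0.5,
                                          lambda_a = 1, sigma_cc_pa = 0,
                                          sigma_aa_pa = 0)),
               "stretches")
})

test_that("biaxial dataset CSV round-trips", {
  p <- table1$mid_flap_4
  d <- generate_biaxial_dataset(p, biaxial_protocol(cv = 0.01, seed = 2))
  f <- tempfile(fileext = ".csv")
  write_biaxial_csv(d, f)
  back <- read_biaxial_csv(f)
  for (cn in c("protocol", "lambda_c", "lambda_a", "sigma_cc_pa", "sigma_aa_pa"))
    expect_equal(back[[cn]], d[[cn]], tolerance = 1e-9)
  unlink(f)
})
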