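test_that("energy vanishes at the reference state and is non-negative", {
  for (p in all_rows) {
    expect_identical(goh_energy(p, 1, 1), 0)
    set.seed(7)
    lc <- runif(20, 1, 1.3); la <- runif(20, 1, 1.3)
    expect_true(all(goh_energy(p, lc, la) >= 0))
  }
})

test_that("energy matches an arbitrary-precision evaluation of the closed form", {
  # pig 1 mid flap at (1.10, 1.05); reference value from a symbolic
  # evaluation of the closed form at 20 significant digits
  expect_equal(goh_energy(table1$mid_flap_1, 1.10, 1.05),
               5881.0757043546346506, tolerance = 1e-12)
})

test_that("kappa = 1/3 removes the fiber-angle dependence", {
  p0 <- goh_params(5e4, 2e5, 5, alpha = 0, kappa = 1 / 3)
  p90 <- goh_params(5e4, 2e5, 5, alpha = 90, kappa = 1 / 3)
  expect_equal(goh_energy(p0, 1.2, 1.0), goh_energy(p90, 1.2, 1.0),
               tolerance = 1e-12)
  expect_equal(biaxial_cauchy_stress(p0, 1.2, 1.07),
               biaxial_cauchy_stress(p90, 1.2, 1.07), tolerance = 1e-12)
})

test_that("kappa = 0 fiber term depends on the deformation only through I4", {
  p <- goh_params(5e4, 2e5, 5, alpha = 30, kappa = 0)
  # two stretch states sharing I4 = lc^2 cos^2 a + la^2 sin^2 a
  a <- 30 * pi / 180
  lc1 <- 1.2; la1 <- 1.1
  i4 <- lc1^2 * cos(a)^2 + la1^2 * sin(a)^2
  lc2 <- 1.15
  la2 <- sqrt((i4 - lc2^2 * cos(a)^2) / sin(a)^2)
  # remove the matrix part exactly
  m <- function(lc, la) 5e4 * (lc^2 + la^2 + 1 / (lc * la)^2 - 3)
  expect_equal(goh_energy(p, lc1, la1) - m(lc1, la1),
               goh_energy(p, lc2, la2) - m(lc2, la2), tolerance = 1e-9)
})

test_that("biaxial stresses are zero at identity and symmetric when expected", {
  for (p in all_rows)
    expect_equal(max(abs(biaxial_cauchy_stress(p, 1, 1))), 0)
  p45 <- goh_params(6e4, 1e5, 3, alpha = 45, kappa = 0)
  s <- biaxial_cauchy_stress(p45, 1.15, 1.15)
  expect_equal(unname(s[1, 1]), unname(s[1, 2]), tolerance = 1e-12)
})

test_that("analytic stresses equal numeric differentiation of the energy", {
  set.seed(11)
  for (p in all_rows) {
    lc <- runif(100, 1.0, 1.28); la <- runif(100, 1.0, 1.28)
    s_an <- biaxial_cauchy_stress(p, lc, la)
    for (i in seq_len(100)) {
      s_fd <- oracle_stress(p, lc[i], la[i])
      denom <- max(abs(s_fd), 1)
      expect_lt(max(abs(s_an[i, ] - s_fd)) / denom, 1e-6)
    }
  }
})

test_that("fixed biaxial stress pair matches the differentiation oracle", {
  # pig 3 mid flap at (1.15, 1.10); values frozen from a symbolic
  # derivative of the closed form
  s <- biaxial_cauchy_stress(table1$mid_flap_3, 1.15, 1.10)
  expect_equal(unname(s[1, 1]), 103839.89057352703, tolerance = 1e-9)
  expect_equal(unname(s[1, 2]), 85490.544860470366, tolerance = 1e-9)
})

test_that("fiber term switches off in dispersion-weighted compression", {
  p <- goh_params(5e4, 2e5, 5, alpha = 0, kappa = 0)
  pm <- goh_params(5e4, 1e-9, 5, alpha = 0, kappa = 0)
  # circumferential compression: I4 < 1, E < 0 for kappa = 0, alpha = 0
  s <- biaxial_cauchy_stress(p, 0.95, 1.02)
  sm <- biaxial_cauchy_stress(pm, 0.95, 1.02)
  expect_equal(s, sm, tolerance = 1e-9)
})

test_that("parameter invariants are enforced with informative errors", {
  expect_error(goh_params(-1, 1e5, 1, 30, 0.1), "c10")
  expect_error(goh_params(1e4, -1, 1, 30, 0.1), "k1")
  expect_error(goh_params(1e4, 1e5, 0, 30, 0.1), "k2")
  expect_error(goh_params(1e4, 1e5, 1, 91, 0.1), "alpha")
  expect_error(goh_params(1e4, 1e5, 1, 30, 0.4), "kappa")
  expect_error(goh_params(1e4, 1e5, 1, 30, 0.1, thickness = 0), "thickness")
  expect_error(biaxial_cauchy_stress(table1$mid_flap_1, -0.2, 1), "positive")
  p_stiff <- goh_params(1e4, 1e5, 50, 0, 0)
  expect_error(goh_energy(p_stiff, 2.8, 1), "overflow|stretch")
})

test_that("plane-strain kernel: stress-free reference and objectivity", {
  p <- table1$distal_flap_1
  out <- plane_strain_stress_tangent(p, diag(2))
  expect_equal(max(abs(out$sigma)), 0, tolerance = 1e-12)
  set.seed(3)
  F <- diag(2) + matrix(rnorm(4, 0, 0.05), 2, 2)
  e0 <- plane_strain_stress_tangent(p, F, tref = c(0.6, 0.8))$energy
  for (th in runif(5, -pi, pi)) {
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    eq <- plane_strain_stress_tangent(p, Q %*% F, tref = c(0.6, 0.8))$energy
    expect_lt(abs(eq - e0) / abs(e0), 1e-10)
    sq <- plane_strain_stress_tangent(p, Q, tref = c(0.6, 0.8))$sigma
    expect_lt(max(abs(sq)), 1e-8 * p$c10)
  }
})

test_that("plane-strain consistent tangent matches finite differences", {
  set.seed(5)
  for (p in list(table1$distal_flap_1, table1$mid_flap_1, table2$mid_fl_wall)) {
    for (rep in 1:5) {
      repeat {
        F <- diag(2) + matrix(rnorm(4, 0, 0.04), 2, 2)
        if (det(F) > 0.9 && det(F) < 1.1) break
      }
      tref <- c(0.6, 0.8)
      out <- plane_strain_stress_tangent(p, F, tref = tref)
      h <- 1e-6
      fd <- matrix(0, 4, 4)
      for (k in 1:2) for (L in 1:2) {
        Fp <- F; Fp[k, L] <- Fp[k, L] + h
        Fm <- F; Fm[k, L] <- Fm[k, L] - h
        dP <- (plane_strain_stress_tangent(p, Fp, tref = tref)$P -
               plane_strain_stress_tangent(p, Fm, tref = tref)$P) / (2 * h)
        fd[, (k - 1) + 2 * (L - 1) + 1] <- as.vector(dP)
      }
      expect_lt(max(abs(fd - out$tangent)) / max(abs(out$tangent)), 1e-4)
    }
  }
  expect_error(plane_strain_stress_tangent(table1$mid_flap_1,
                                           matrix(c(1, 0, 0, -1), 2, 2)),
               "det")
})

test_that("parameter CSV round-trips and the shipped tables load", {
  expect_length(table1, 9)
  expect_length(table2, 3)
  expect_equal(table1$mid_flap_1$c10, 92963)
  expect_equal(table2$distal_fl_wall$kappa, 0)
  f <- tempfile(fileext = ".csv")
  write_goh_csv(table1, f)
  back <- read_goh_csv(f)
  expect_equal(back$mid_flap_3$k2, table1$mid_flap_3$k2)
  unlink(f)
})

test_that("deformation state reports consistent invariants", {
  p <- table1$mid_flap_2
  st <- deformation_state(1.2, 1.1, p)
  expect_equal(st$lambda_c * st$lambda_a * st$lambda_r, 1, tolerance = 1e-10)
  expect_gte(st$i1, 3 - 1e-10)
  expect_gt(st$i4, 0)
})
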