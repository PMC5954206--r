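#' @useDynLib reappose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Unit conversion between mmHg and Pa
#'
#' All internal mechanics run in Pa and mm; pressures are reported in mmHg
#' using 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' Material parameters of the dispersed two-fiber-family hyperelastic model
#'
#' Constructs and validates one tissue layer's parameter set for the
#' Gasser-Ogden-Holzapfel (GOH) structural strain-energy function
#' \deqn{\Psi = C_{10}(I_1 - 3) + \frac{k_1}{2 k_2}
#'   \sum_{i=4,6}\left[e^{k_2 E_i^2} - 1\right],}
#' with the dispersion-weighted fiber strain
#' \eqn{E = \kappa (I_1 - 3) + (1 - 3\kappa)(I_4 - 1)} and two symmetric
#' fiber families at \eqn{\pm\alpha} from the circumferential axis. The fiber
#' term is active only in fiber extension (\eqn{E > 0}).
#'
#' @param c10 ground-matrix stiffness (Pa), > 0.
#' @param k1 fiber stiffness (Pa), >= 0.
#' @param k2 dimensionless fiber exponent, > 0.
#' @param alpha fiber angle from the circumferential axis (degrees), in
#'   \[0, 90\].
#' @param kappa dispersion parameter in \[0, 1/3\]; 1/3 is fully isotropic
#'   dispersion, 0 perfectly aligned fibers.
#' @param thickness layer thickness (mm), > 0.
#' @param label layer/region identifier string.
#' @return an object of class `goh_params` (a named list).
#' @export
goh_params <- function(c10, k1, k2, alpha, kappa, thickness = 1, label = "layer") {
  p <- list(c10 = as.numeric(c10), k1 = as.numeric(k1), k2 = as.numeric(k2),
            alpha = as.numeric(alpha), kappa = as.numeric(kappa),
            thickness = as.numeric(thickness), label = as.character(label))
  class(p) <- "goh_params"
  validate_goh_params(p)
  p
}

validate_goh_params <- function(p) {
  stopifnot(inherits(p, "goh_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid GOH parameters: ", msg, call. = FALSE)
  chk(is.finite(p$c10) && p$c10 > 0, "c10 must be > 0")
  chk(is.finite(p$k1) && p$k1 >= 0, "k1 must be >= 0")
  chk(is.finite(p$k2) && p$k2 > 0, "k2 must be > 0")
  chk(is.finite(p$alpha) && p$alpha >= 0 && p$alpha <= 90, "alpha must lie in [0, 90] degrees")
  chk(is.finite(p$kappa) && p$kappa >= 0 && p$kappa <= 1 / 3 + 1e-12, "kappa must lie in [0, 1/3]")
  chk(is.finite(p$thickness) && p$thickness > 0, "thickness must be > 0")
  invisible(p)
}

#' @export
print.goh_params <- function(x, ...) {
  cat(sprintf("GOH material '%s'\n", x$label))
  cat(sprintf("  C10 = %.0f Pa, k1 = %.0f Pa, k2 = %.3g\n", x$c10, x$k1, x$k2))
  cat(sprintf("  alpha = %.1f deg (from circumferential), kappa = %.3g\n", x$alpha, x$kappa))
  cat(sprintf("  thickness = %.3g mm\n", x$thickness))
  invisible(x)
}

#' Read and write GOH parameter tables
#'
#' CSV layout: columns `label, c10_pa, k1_pa, k2, alpha_deg, kappa,
#' thickness_mm`, one tissue layer per row.
#'
#' @param path CSV file path.
#' @return `read_goh_csv`: a named list of [goh_params] objects.
#' @export
read_goh_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "c10_pa", "k1_pa", "k2", "alpha_deg", "kappa", "thickness_mm")
  if (!all(need %in% names(d)))
    stop("parameter CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(d)), function(i)
    goh_params(d$c10_pa[i], d$k1_pa[i], d$k2[i], d$alpha_deg[i], d$kappa[i],
               d$thickness_mm[i], d$label[i]))
  names(out) <- d$label
  out
}

#' @rdname read_goh_csv
#' @param params a [goh_params] object or list of them.
#' @export
write_goh_csv <- function(params, path) {
  if (inherits(params, "goh_params")) params <- list(params)
  d <- do.call(rbind, lapply(params, function(p)
    data.frame(label = p$label, c10_pa = p$c10, k1_pa = p$k1, k2 = p$k2,
               alpha_deg = p$alpha, kappa = p$kappa, thickness_mm = p$thickness)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Porcine aortic tissue parameter sets
#'
#' Planar-biaxial GOH parameter estimates for the dissected porcine thoracic
#' aorta: per-pig intimal flap rows for the mid (5 pigs) and distal (4 pigs)
#' regions, and one set each for the true-lumen (TL) wall, mid false-lumen
#' (FL) wall and distal FL wall. Shipped as CSV fixtures under
#' `inst/extdata`.
#'
#' @param set `"flap"` or `"wall"`.
#' @return named list of [goh_params].
#' @export
#' @examples
#' aorta_materials("wall")$tl_wall
aorta_materials <- function(set = c("flap", "wall")) {
  set <- match.arg(set)
  f <- system.file("extdata", paste0(set, "_params.csv"), package = "reappose",
                   mustWork = TRUE)
  read_goh_csv(f)
}

#' Kinematic state of an incompressible biaxial deformation
#'
#' For circumferential/axial stretches \eqn{\lambda_c, \lambda_a} with
#' incompressibility \eqn{\lambda_r = 1/(\lambda_c \lambda_a)}, computes the
#' invariants used by the structural model: \eqn{I_1}, the squared fiber
#' stretch \eqn{I_4 = \lambda_c^2\cos^2\alpha + \lambda_a^2\sin^2\alpha}
#' (identical for both \eqn{\pm\alpha} families), and the dispersion-weighted
#' fiber strain \eqn{E = \kappa(I_1-3) + (1-3\kappa)(I_4-1)}.
#'
#' @param lambda_c,lambda_a circumferential and axial stretches (> 0).
#' @param params a [goh_params] object (supplies alpha and kappa).
#' @return object of class `deformation_state` with fields `lambda_c`,
#'   `lambda_a`, `lambda_r`, `i1`, `i4`, `e_fiber`.
#' @export
deformation_state <- function(lambda_c, lambda_a, params) {
  validate_goh_params(params)
  if (any(!is.finite(lambda_c)) || any(!is.finite(lambda_a)) ||
      any(lambda_c <= 0) || any(lambda_a <= 0))
    stop("stretches must be positive and finite")
  lr <- 1 / (lambda_c * lambda_a)
  a <- params$alpha * pi / 180
  i1 <- lambda_c^2 + lambda_a^2 + lr^2
  i4 <- lambda_c^2 * cos(a)^2 + lambda_a^2 * sin(a)^2
  e <- params$kappa * (i1 - 3) + (1 - 3 * params$kappa) * (i4 - 1)
  s <- list(lambda_c = lambda_c, lambda_a = lambda_a, lambda_r = lr,
            i1 = i1, i4 = i4, e_fiber = e)
  class(s) <- "deformation_state"
  s
}

# guard for exp(k2 E^2): beyond this the energy overflows double precision
.goh_exp_cap <- 500

#' GOH strain-energy density under incompressible biaxial stretch
#'
#' Evaluates the structural strain-energy density \eqn{\Psi} (Pa) at the
#' given stretch pair, with the fiber term active only when the
#' dispersion-weighted fiber strain is tensile (`E > 0`).
#'
#' @inheritParams deformation_state
#' @param params a [goh_params] object.
#' @return energy density in Pa, vectorized over the stretches.
#' @export
#' @examples
#' p <- aorta_materials("flap")$mid_flap_1
#' goh_energy(p, 1.1, 1.05)
goh_energy <- function(params, lambda_c, lambda_a) {
  st <- deformation_state(lambda_c, lambda_a, params)
  arg <- params$k2 * st$e_fiber^2
  if (any(arg > .goh_exp_cap))
    stop("fiber exponent k2*E^2 exceeds ", .goh_exp_cap,
         ": energy would overflow; check the stretch range")
  fib <- ifelse(st$e_fiber > 0, (params$k1 / params$k2) * (exp(arg) - 1), 0)
  params$c10 * (st$i1 - 3) + fib
}

#' In-plane Cauchy stresses under incompressible plane-stress biaxial loading
#'
#' Radial stress is eliminated through the incompressibility pressure
#' (\eqn{\sigma_{rr} = 0}), giving
#' \eqn{\sigma_{cc} = \lambda_c \,\partial\hat\Psi/\partial\lambda_c} and
#' \eqn{\sigma_{aa} = \lambda_a \,\partial\hat\Psi/\partial\lambda_a}, where
#' \eqn{\hat\Psi(\lambda_c,\lambda_a)} is the energy with
#' \eqn{\lambda_r = 1/(\lambda_c\lambda_a)} substituted. Both \eqn{\pm\alpha}
#' fiber families contribute (they share \eqn{I_4}).
#'
#' @inheritParams goh_energy
#' @return two-column matrix `cbind(sigma_cc, sigma_aa)` in Pa.
#' @export
biaxial_cauchy_stress <- function(params, lambda_c, lambda_a) {
  st <- deformation_state(lambda_c, lambda_a, params)
  a <- params$alpha * pi / 180
  kap <- params$kappa
  lc <- st$lambda_c; la <- st$lambda_a
  arg <- params$k2 * st$e_fiber^2
  if (any(arg > .goh_exp_cap))
    stop("fiber exponent k2*E^2 exceeds ", .goh_exp_cap,
         ": stress would overflow; check the stretch range")
  # total fiber factor for the two families: dPsi_f/dE = 2 k1 E exp(k2 E^2)
  g1 <- ifelse(st$e_fiber > 0, 2 * params$k1 * st$e_fiber * exp(arg), 0)
  di1_dlc <- 2 * lc - 2 / (lc^3 * la^2)
  di1_dla <- 2 * la - 2 / (la^3 * lc^2)
  di4_dlc <- 2 * lc * cos(a)^2
  di4_dla <- 2 * la * sin(a)^2
  de_dlc <- kap * di1_dlc + (1 - 3 * kap) * di4_dlc
  de_dla <- kap * di1_dla + (1 - 3 * kap) * di4_dla
  scc <- lc * (params$c10 * di1_dlc + g1 * de_dlc)
  saa <- la * (params$c10 * di1_dla + g1 * de_dla)
  cbind(sigma_cc = scc, sigma_aa = saa)
}

#' Plane-strain stress and consistent tangent at a material point
#'
#' Element-level kernel for the cross-section solver: near-incompressible
#' plane-strain response (out-of-plane stretch fixed at 1) of the GOH model
#' with a volumetric penalty \eqn{U = (K/2)(J-1)^2}. The \eqn{\pm\alpha}
#' fiber families are projected from their 3D orientation: circumferential
#' component in-plane along `tref`, axial component out-of-plane.
#'
#' @param params a [goh_params] object.
#' @param F 2x2 in-plane deformation gradient with positive determinant.
#' @param tref in-plane reference circumferential direction (unit 2-vector).
#' @param kvol_factor volumetric penalty modulus as a multiple of `c10`
#'   (default 1e4).
#' @return list with `sigma` (Cauchy, 2x2), `P` (first Piola-Kirchhoff,
#'   2x2), `tangent` (4x4 matrix `dP/dF`, column-major pairing `(i,J)`),
#'   `J`, and `energy` (Pa).
#' @export
plane_strain_stress_tangent <- function(params, F, tref = c(1, 0),
                                        kvol_factor = 1e4) {
  validate_goh_params(params)
  F <- matrix(as.numeric(F), 2, 2)
  if (det(F) <= 0) stop("inverted state: det(F) must be > 0")
  tref <- tref / sqrt(sum(tref^2))
  a <- params$alpha * pi / 180
  out <- ps_point_kernel(F, params$c10, params$k1, params$k2, params$kappa,
                         cos(a)^2, sin(a)^2, tref, kvol_factor * params$c10)
  if (!out$ok)
    stop("fiber exponent overflow at this deformation; check the stretch range")
  out
}
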