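# End-to-end studies: pressure sweeps, wall-material sensitivity and mesh
# convergence.
#
# Sweeps are chained: the first (lowest) pressure point pays for the full
# two-step simulation including the slack-flap drape; each later point is
# continued from the previous fully-apposed state by raising the pressure
# with the member held and then growing the member the short remaining
# distance. The final state at each point is the same equilibrium the
# standalone simulation reaches (elastic, frictionless), at a fraction of
# the cost.

region_wall_set <- function(region, walls = aorta_materials("wall")) {
  list(fl_wall = walls[[if (region == "mid") "mid_fl_wall" else "distal_fl_wall"]],
       tl_wall = walls$tl_wall)
}

# package a converged (model, u, Rm) state as a reapposition_result
as_reapposition_result <- function(model, u, sys, Rm, p_aorta, logs = NULL) {
  mesh <- model$mesh
  ids <- tl_facing_nodes(mesh)
  xd <- mesh$nodes[ids, , drop = FALSE] + cbind(u[2 * ids - 1], u[2 * ids])
  structure(list(
    p_aorta = p_aorta,
    radial_pressure = pa_to_mmhg(max(member_avg_pressure(
      sys$mem, Rm, model$opts$avg_over, half = !mesh$geom$intact), 0)),
    member_radius = Rm,
    final_diameter = 2 * mean(sqrt(xd[, 1]^2 + xd[, 2]^2)),
    contact_fraction = contact_fraction(model, u),
    newton_log = logs,
    converged = TRUE,
    max_gap = if (mesh$geom$intact) NA_real_ else max(flap_gaps(model, u)),
    g_tol_abs = model$opts$g_tol * mesh$geom$flap_thickness,
    maxJdev = sys$maxJdev,
    strain_energy = sys$strain_energy,
    contact_energy = sys$contact_energy,
    work_external = NA_real_,
    u = u, model = model, sys = sys,
    assumed_lumen_radius = mesh$geom$inner_radius),
    class = "reapposition_result")
}

# continue a fully-apposed state to a new aortic pressure: raise the
# pressure with the member held, then adjust the member radius to the new
# smallest fully-apposing value
continue_reapposition <- function(prev, p_new, options) {
  model <- prev$model
  mesh <- model$mesh
  gtol_abs <- options$g_tol * mesh$geom$flap_thickness
  apposed <- function(u) all(flap_gaps(model, u) <= gtol_abs)
  u <- prev$u; Rm <- prev$member_radius
  p_old_pa <- mmhg_to_pa(prev$p_aorta); p_new_pa <- mmhg_to_pa(p_new)
  # pressure ramp with the member held (usually one step suffices)
  frac <- 0; step <- 1
  while (frac < 1 - 1e-12) {
    f_try <- min(1, frac + step)
    pp <- p_old_pa + f_try * (p_new_pa - p_old_pa)
    res <- newton_solve(model, u, pp, Rm)
    if (!res$converged) {
      step <- step / 2
      if (step < 1 / 64) stop("pressure continuation failed at ", p_new, " mmHg")
      next
    }
    u <- res$u; frac <- f_try
  }
  rtol <- max(0.001, options$member_step / 256)
  if (!apposed(u)) {
    # higher pressure dilated the wall: grow the member the short rest
    lo <- Rm; step <- options$member_step
    repeat {
      Rm_try <- Rm + step
      res2 <- newton_solve(model, u, p_new_pa, Rm_try)
      if (!res2$converged) {
        step <- step / 2
        if (step < options$member_step / 512)
          stop("member continuation failed at ", p_new, " mmHg")
        next
      }
      lo <- Rm; Rm <- Rm_try; u <- res2$u; res <- res2
      if (apposed(u)) break
      step <- min(step * 1.25, options$member_step)
    }
    hi <- Rm
  } else {
    # already apposed: the smallest apposing radius may be below Rm
    lo <- Rm - options$member_step; hi <- Rm
    rdown <- newton_solve(model, u, p_new_pa, lo)
    if (rdown$converged && apposed(rdown$u)) {
      # keep stepping down until the flap opens
      while (rdown$converged && apposed(rdown$u)) {
        hi <- lo; u <- rdown$u; res <- rdown
        lo <- lo - options$member_step
        rdown <- newton_solve(model, u, p_new_pa, lo)
      }
    }
  }
  u_hi <- u; res_hi <- res
  while (hi - lo > rtol) {
    mid <- (hi + lo) / 2
    rmid <- newton_solve(model, u_hi, p_new_pa, mid)
    if (!rmid$converged) break
    if (apposed(rmid$u)) { hi <- mid; u_hi <- rmid$u; res_hi <- rmid }
    else lo <- mid
  }
  as_reapposition_result(model, u_hi, res_hi$sys, hi, p_new)
}

#' Radial re-apposition pressure sweep over the aortic pressure ladder
#'
#' Runs the two-step re-apposition simulation at each static aortic
#' pressure (default 70-140 mmHg in 10 mmHg increments, the bench
#' protocol) for one region and flap parameter set. Points after the
#' first are continued from the previous fully-apposed equilibrium, which
#' avoids re-solving the slack-flap phase; the end state per point is the
#' same equilibrium the standalone run reaches.
#'
#' @param region `"mid"` or `"distal"`.
#' @param flap a [goh_params] for the intimal flap (per-pig row).
#' @param walls list with `fl_wall` and `tl_wall` [goh_params]; defaults
#'   to the measured wall set for the region.
#' @param pressures increasing vector of aortic pressures (mmHg).
#' @param h element size (mm).
#' @param options a [solver_options] list.
#' @param geom optional [dissection_geometry] override.
#' @return object of class `sweep_result`: list with `region`, `label`,
#'   `results` (one `reapposition_result` per pressure), `table`
#'   (data.frame summary), `failed` (character), `valid`.
#' @export
run_sweep <- function(region = c("mid", "distal"), flap,
                      walls = region_wall_set(region),
                      pressures = seq(70, 140, by = 10), h = 0.3,
                      options = solver_options(), geom = NULL) {
  region <- match.arg(region)
  stopifnot(!is.unsorted(pressures, strictly = TRUE))
  if (is.null(geom))
    geom <- dissection_geometry(region, flap_thickness = flap$thickness)
  mats <- list(flap = flap, fl_wall = walls$fl_wall, tl_wall = walls$tl_wall)
  results <- vector("list", length(pressures))
  failed <- character(0)
  prev <- NULL
  for (k in seq_along(pressures)) {
    r <- tryCatch({
      if (is.null(prev)) {
        r0 <- run_reapposition(geom, mats, pressures[k], h, options)
        # settle the first point through the same approach-from-apposed
        # refinement used for the later points, so all points share one
        # termination-state bias
        continue_reapposition(r0, pressures[k], options)
      } else continue_reapposition(prev, pressures[k], options)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      failed <- c(failed, sprintf("%g mmHg: %s", pressures[k], conditionMessage(r)))
      results[k] <- list(NULL)
    } else {
      results[[k]] <- r
      prev <- r
    }
  }
  ok <- !vapply(results, is.null, TRUE)
  tab <- data.frame(
    region = region, label = flap$label,
    p_aorta_mmhg = pressures[ok],
    radial_pressure_mmhg = vapply(results[ok], function(r) r$radial_pressure, 0),
    final_diameter_mm = vapply(results[ok], function(r) r$final_diameter, 0),
    member_radius_mm = vapply(results[ok], function(r) r$member_radius, 0),
    converged = vapply(results[ok], function(r) r$converged, TRUE))
  slope <- if (sum(ok) >= 2)
    stats::coef(stats::lm(radial_pressure_mmhg ~ p_aorta_mmhg, data = tab))[2]
  else NA_real_
  out <- list(region = region, label = flap$label, results = results[ok],
              table = tab, failed = failed, valid = length(failed) <= 2,
              mean_radial_pressure = mean(tab$radial_pressure_mmhg),
              slope = unname(slope),
              assumed_lumen_radius = geom$inner_radius, h = h)
  class(out) <- "sweep_result"
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Re-apposition sweep: %s region, flap '%s' (h = %g mm)\n",
              x$region, x$label, x$h))
  print(x$table[, c("p_aorta_mmhg", "radial_pressure_mmhg",
                    "final_diameter_mm")], row.names = FALSE)
  if (is.na(x$slope)) cat("  slope undefined (single-point sweep)\n")
  else cat(sprintf("  mean radial pressure %.2f mmHg, slope %.3f mmHg/mmHg\n",
                   x$mean_radial_pressure, x$slope))
  if (length(x$failed)) cat("  failed points:", paste(x$failed, collapse = "; "), "\n")
  cat(sprintf("  (assumed unloaded lumen radius: %g mm)\n", x$assumed_lumen_radius))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, which = c("pressure", "diameter"), ...) {
  which <- match.arg(which)
  y <- if (which == "pressure") x$table$radial_pressure_mmhg
       else x$table$final_diameter_mm
  graphics::plot(x$table$p_aorta_mmhg, y, type = "b", pch = 16,
                 xlab = "aortic pressure (mmHg)",
                 ylab = if (which == "pressure") "radial re-apposition pressure (mmHg)"
                        else "final inner diameter (mm)",
                 main = sprintf("%s region, %s", x$region, x$label), ...)
  invisible(x)
}

#' Wall-material sensitivity study
#'
#' Re-runs the re-apposition simulation with perturbed wall parameter sets
#' (the flap held at the baseline row) at aortic pressures of 70, 100 and
#' 140 mmHg, and with the alternative flap rows (walls held at baseline)
#' as the flap-variation arm. Wall variants are seeded +/-`rel` uniform
#' perturbations of `c10` and `k1` generated by
#' [generate_material_variants].
#'
#' @param region `"mid"` or `"distal"`.
#' @param baseline_flap baseline flap row (default pig 1 of the region).
#' @param flap_rows list of flap rows for the flap-variation arm (default
#'   all rows of the region).
#' @param pressures aortic pressures (mmHg).
#' @param n_variants seeded variants per wall layer (default 3, excluding
#'   the base).
#' @param rel relative perturbation half-width (default 0.2).
#' @param seed RNG seed for the variant draw.
#' @param h element size (mm).
#' @param options a [solver_options] list.
#' @return object of class `sensitivity_result`: per-arm radial-pressure
#'   tables, the mean absolute relative change of the wall arm
#'   (`wall_mean_rel_change`), and the spreads of both arms.
#' @export
run_sensitivity <- function(region = c("mid", "distal"),
                            baseline_flap = NULL, flap_rows = NULL,
                            pressures = c(70, 100, 140),
                            n_variants = 3, rel = 0.2, seed = 1,
                            h = 0.3, options = solver_options()) {
  region <- match.arg(region)
  flaps <- aorta_materials("flap")
  flaps <- flaps[grep(paste0("^", region, "_"), names(flaps))]
  if (is.null(baseline_flap)) baseline_flap <- flaps[[1]]
  if (is.null(flap_rows)) flap_rows <- flaps
  walls0 <- region_wall_set(region)
  sweep0 <- run_sweep(region, baseline_flap, walls0, pressures, h, options)
  base_p <- sweep0$table$radial_pressure_mmhg
  if (length(base_p) < length(pressures)) stop("baseline sweep failed")

  # wall-variation arm: perturb each wall layer separately
  wall_tab <- list()
  for (wl in c("fl_wall", "tl_wall")) {
    vars <- generate_material_variants(walls0[[wl]],
                                       rel_ranges = list(c10 = rel, k1 = rel),
                                       n = n_variants + 1, seed = seed)
    for (vi in seq_along(vars)[-1]) {
      w2 <- walls0; w2[[wl]] <- vars[[vi]]
      sv <- run_sweep(region, baseline_flap, w2, pressures, h, options)
      wall_tab[[length(wall_tab) + 1]] <- data.frame(
        arm = "wall", layer = wl, variant = vars[[vi]]$label,
        p_aorta_mmhg = sv$table$p_aorta_mmhg,
        radial_pressure_mmhg = sv$table$radial_pressure_mmhg,
        rel_change = sv$table$radial_pressure_mmhg / base_p - 1)
    }
  }
  wall_tab <- do.call(rbind, wall_tab)

  # flap-variation arm: the other measured flap rows
  flap_tab <- list()
  for (fr in flap_rows) {
    if (identical(fr$label, baseline_flap$label)) {
      sv_tab <- sweep0$table
    } else {
      sv_tab <- run_sweep(region, fr, walls0, pressures, h, options)$table
    }
    flap_tab[[length(flap_tab) + 1]] <- data.frame(
      arm = "flap", layer = "flap", variant = fr$label,
      p_aorta_mmhg = sv_tab$p_aorta_mmhg,
      radial_pressure_mmhg = sv_tab$radial_pressure_mmhg,
      rel_change = sv_tab$radial_pressure_mmhg / base_p - 1)
  }
  flap_tab <- do.call(rbind, flap_tab)

  spread <- function(tab) {
    sp <- tapply(tab$radial_pressure_mmhg, tab$p_aorta_mmhg,
                 function(v) diff(range(c(v))))
    mean(sp)
  }
  out <- list(region = region, baseline = baseline_flap$label,
              base_table = sweep0$table,
              wall_table = wall_tab, flap_table = flap_tab,
              wall_mean_rel_change = mean(abs(wall_tab$rel_change)),
              wall_spread = spread(rbind(wall_tab,
                data.frame(arm = "base", layer = "base", variant = "base",
                           p_aorta_mmhg = pressures,
                           radial_pressure_mmhg = base_p, rel_change = 0))),
              flap_spread = spread(flap_tab),
              pressures = pressures, seed = seed, rel = rel)
  class(out) <- "sensitivity_result"
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Wall-sensitivity study, %s region (baseline %s)\n",
              x$region, x$baseline))
  cat(sprintf("  wall arm (+/-%.0f%% c10,k1): mean |relative change| = %.2f%%\n",
              100 * x$rel, 100 * x$wall_mean_rel_change))
  cat(sprintf("  spread across variants: wall %.2f mmHg, flap rows %.2f mmHg\n",
              x$wall_spread, x$flap_spread))
  invisible(x)
}

#' Mesh-convergence study of the radial re-apposition pressure
#'
#' @param region `"mid"` or `"distal"`.
#' @param flap flap parameter row (default pig 1 of the region).
#' @param p_aorta aortic pressure (mmHg, default 100).
#' @param sizes decreasing element sizes (mm); default `c(0.3, 0.2, 0.15)`.
#' @param options a [solver_options] list.
#' @return object of class `mesh_convergence_result` with the radial
#'   pressure per size and relative differences against the finest mesh.
#' @export
run_mesh_convergence <- function(region = c("mid", "distal"), flap = NULL,
                                 p_aorta = 100,
                                 sizes = c(0.3, 0.3 / 1.5, 0.15),
                                 options = solver_options()) {
  region <- match.arg(region)
  if (any(diff(sizes) >= 0)) stop("element sizes must strictly decrease")
  if (is.null(flap))
    flap <- aorta_materials("flap")[[paste0(region, "_flap_1")]]
  walls <- region_wall_set(region)
  geom <- dissection_geometry(region, flap_thickness = flap$thickness)
  mats <- list(flap = flap, fl_wall = walls$fl_wall, tl_wall = walls$tl_wall)
  rp <- vapply(sizes, function(h)
    run_reapposition(geom, mats, p_aorta, h, options)$radial_pressure, 0)
  rel <- rp / rp[length(rp)] - 1
  out <- list(region = region, label = flap$label, p_aorta = p_aorta,
              sizes = sizes, radial_pressure = rp, rel_diff = rel,
              coarse_vs_fine = abs(rp[1] - rp[length(rp)]) / rp[length(rp)],
              converging = all(abs(diff(abs(rel))) <= 0 | diff(abs(rel)) <= 1e-12) ||
                length(sizes) <= 2)
  class(out) <- "mesh_convergence_result"
  out
}

#' @export
print.mesh_convergence_result <- function(x, ...) {
  cat(sprintf("Mesh convergence: %s region, %g mmHg\n", x$region, x$p_aorta))
  print(data.frame(h_mm = x$sizes, radial_pressure_mmhg = x$radial_pressure,
                   rel_vs_finest = x$rel_diff), row.names = FALSE)
  cat(sprintf("  coarse vs finest: %.2f%%\n", 100 * x$coarse_vs_fine))
  invisible(x)
}
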