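# Idealized dissected-aorta cross-section geometry and quadrilateral meshing.
#
# The cross-section is an annulus: over the dissected sector the wall is
# split into an inner intimal flap and an outer FL wall (separate bodies in
# frictionless contact, merging into the continuous TL wall at the
# dissection ends); over the remaining sector it is the single TL wall.
# The half model spans polar angles [-90, 90] deg (x >= 0) with the flap
# centered on the +y axis and x-symmetry on the two cut columns.

#' Dissected-aorta cross-section description
#'
#' The unloaded lumen radius is not a measured quantity of the bench
#' specimens. Typical porcine descending-thoracic inner diameters (about
#' 18 mm mid, 14 mm distal, the distal aorta always smaller) refer to the
#' pressurized vessel, so the unloaded defaults here are calibrated such
#' that the simulated re-apposed inner diameter at 100 mmHg with the
#' pig-1 parameter sets reproduces those pressurized dimensions: unloaded
#' inner radius 7.26 mm (mid) and 5.55 mm (distal). Every simulation
#' result carries an `assumed_lumen_radius` flag for this reason.
#'
#' @param region `"mid"` or `"distal"`.
#' @param inner_radius unloaded lumen inner radius (mm); default 7.26
#'   (mid) or 5.55 (distal), see Details.
#' @param flap_fraction f = flap circumference / aortic circumference;
#'   the dissections emulated here span 50-60% of the circumference, so f
#'   must lie in `f_bounds` (default `c(0.5, 0.6)`).
#' @param flap_thickness,fl_thickness,tl_thickness layer thicknesses (mm);
#'   defaults are the measured mid/distal flap (pig 1) and wall values.
#' @param f_bounds admissible range for `flap_fraction` (configurable).
#' @param half_model exploit x-symmetry (default TRUE).
#' @return object of class `dissection_geometry`.
#' @export
#' @examples
#' dissection_geometry("mid")
dissection_geometry <- function(region = c("mid", "distal"),
                                inner_radius = NULL,
                                flap_fraction = 0.55,
                                flap_thickness = NULL,
                                fl_thickness = NULL,
                                tl_thickness = 1.76,
                                f_bounds = c(0.5, 0.6),
                                half_model = TRUE) {
  region <- match.arg(region)
  if (is.null(inner_radius)) inner_radius <- if (region == "mid") 7.26 else 5.55
  if (is.null(flap_thickness)) flap_thickness <- if (region == "mid") 0.58 else 0.4
  if (is.null(fl_thickness)) fl_thickness <- if (region == "mid") 1.3 else 1.24
  f <- flap_fraction
  if (f <= 0 || f >= 1)
    stop("flap_fraction must lie in (0, 1): f = 0 means no dissection")
  if (f < f_bounds[1] || f > f_bounds[2])
    stop(sprintf("flap_fraction %.3g outside configured bounds [%g, %g]",
                 f, f_bounds[1], f_bounds[2]))
  stopifnot(flap_thickness > 0, fl_thickness > 0, tl_thickness > 0)
  if (inner_radius <= max(flap_thickness + fl_thickness, tl_thickness))
    stop("inner radius must exceed the wall thickness")
  out <- list(region = region, inner_radius = inner_radius,
              flap_fraction = f, flap_thickness = flap_thickness,
              fl_thickness = fl_thickness, tl_thickness = tl_thickness,
              half_model = half_model, intact = FALSE)
  class(out) <- "dissection_geometry"
  out
}

#' Intact single-layer ring geometry (verification mode)
#'
#' A plain annulus with one wall layer and no dissection, used for the
#' analytic verification benchmarks (thin-wall pressurization, rigid-member
#' expansion).
#'
#' @param inner_radius inner radius (mm).
#' @param thickness wall thickness (mm).
#' @return object of class `dissection_geometry` with `intact = TRUE`.
#' @export
ring_geometry <- function(inner_radius, thickness) {
  stopifnot(inner_radius > 0, thickness > 0, inner_radius > thickness)
  out <- list(region = "ring", inner_radius = inner_radius,
              flap_fraction = NULL, flap_thickness = NULL,
              fl_thickness = NULL, tl_thickness = thickness,
              half_model = FALSE, intact = TRUE)
  class(out) <- "dissection_geometry"
  out
}

#' @export
print.dissection_geometry <- function(x, ...) {
  if (x$intact) {
    cat(sprintf("Intact ring: R_in = %g mm, thickness = %g mm\n",
                x$inner_radius, x$tl_thickness))
  } else {
    cat(sprintf("Dissected %s cross-section: R_in = %g mm (assumed), f = %g\n",
                x$region, x$inner_radius, x$flap_fraction))
    cat(sprintf("  flap %g mm, FL wall %g mm, TL wall %g mm; half model: %s\n",
                x$flap_thickness, x$fl_thickness, x$tl_thickness, x$half_model))
  }
  invisible(x)
}

# structured polar patch: stations th (angles) x rr-per-column (radii
# matrix, columns = angular stations); returns nodes and quads (CCW)
polar_patch_nodes <- function(th, rad) {
  nth <- length(th); nr <- nrow(rad)
  x <- outer(rep(1, nr), cos(th)) * rad
  y <- outer(rep(1, nr), sin(th)) * rad
  cbind(as.vector(x), as.vector(y)) # column-major: radial index fastest
}

#' Build and mesh the cross-section
#'
#' Structured quadrilateral mesh: each sector is a polar grid; the flap and
#' FL wall share duplicated (crack) nodes along the dissection plane and
#' merge with the TL wall at the dissection ends. The flap is meshed with
#' at least two element rows through its thickness. In the unloaded
#' configuration the flap sits on its original mural arc, apposed against
#' the FL wall with zero gap.
#'
#' @param geom a [dissection_geometry].
#' @param h characteristic element size (mm), default 0.3.
#' @return object of class `cross_section_mesh`: `nodes` (n x 2, mm),
#'   `elems` (m x 4, CCW), `layer` (per-element tag `flap`/`fl_wall`/
#'   `tl_wall`/`wall`), `sets` (named list of ordered boundary edge
#'   matrices: `tl_lumen_surface`, `flap_tl_side`, `flap_fl_side`,
#'   `fl_wall_inner`, `symmetry_plane`), `h`, `geom`.
#' @export
build_cross_section <- function(geom, h = 0.3) {
  stopifnot(inherits(geom, "dissection_geometry"), h > 0)
  if (geom$intact) return(build_ring_mesh(geom, h))

  Ri <- geom$inner_radius
  tf <- geom$flap_thickness; tfl <- geom$fl_thickness; ttl <- geom$tl_thickness
  td <- tf + tfl
  nf <- max(2L, ceiling(tf / h))        # >= 2 rows through the flap
  nfl <- max(2L, ceiling(tfl / h))
  if (tf / nf > 2 * h)
    stop("element size h too coarse to honor two rows through the flap; reduce h")
  # shared normalized through-thickness fractions, split at the dissection
  s_split <- tf / td
  s <- c(seq(0, s_split, length.out = nf + 1),
         seq(s_split, 1, length.out = nfl + 1)[-1])
  ks <- nf + 1 # index of the dissection-plane fraction in s

  beta <- geom$flap_fraction * pi      # flap half-span (full flap = 2 beta)
  th_j <- pi / 2 - beta                # junction angle (dissection end)
  if (th_j <= -pi / 2 + 1e-9) stop("flap_fraction too large for the half model")
  rmid <- Ri + td / 2
  n_af <- max(4L, ceiling(beta * rmid / h))
  n_at <- max(4L, ceiling((th_j + pi / 2) * (Ri + ttl / 2) / h))

  th_d <- seq(pi / 2, th_j, length.out = n_af + 1)   # dissected sector
  th_t <- seq(th_j, -pi / 2, length.out = n_at + 1)  # TL sector
  nr <- length(s)

  # node ids laid out per column; dissected-sector columns (except the
  # junction column) carry one extra node: the duplicated crack node
  nodes <- list(); id <- 0L
  col_ids_d <- vector("list", n_af + 1)  # dissected sector incl. junction
  for (j in seq_along(th_d)) {
    at_junction <- (j == length(th_d))
    rads <- Ri + s * td
    if (at_junction) {
      ids <- id + seq_len(nr)
      nodes[[length(nodes) + 1]] <- cbind(rads * cos(th_d[j]), rads * sin(th_d[j]))
      id <- id + nr
      col_ids_d[[j]] <- list(flap = ids[1:ks], fl = ids[ks:nr])
    } else {
      # crack: separate flap-outer and FL-inner nodes at the same coords
      rads2 <- c(rads[1:ks], rads[ks:nr])
      ids <- id + seq_len(nr + 1L)
      nodes[[length(nodes) + 1]] <- cbind(rads2 * cos(th_d[j]), rads2 * sin(th_d[j]))
      id <- id + nr + 1L
      col_ids_d[[j]] <- list(flap = ids[1:ks], fl = ids[(ks + 1L):(nr + 1L)])
    }
  }
  col_ids_t <- vector("list", n_at + 1)  # TL sector; first column = junction
  col_ids_t[[1]] <- col_ids_d[[n_af + 1]]
  for (j in 2:(n_at + 1)) {
    rads <- Ri + s * ttl
    ids <- id + seq_len(nr)
    nodes[[length(nodes) + 1]] <- cbind(rads * cos(th_t[j]), rads * sin(th_t[j]))
    id <- id + nr
    col_ids_t[[j]] <- list(flap = ids[1:ks], fl = ids[ks:nr])
  }
  nodes <- do.call(rbind, nodes)

  quad <- function(c1, c2, k) c(c1[k], c2[k], c2[k + 1], c1[k + 1])
  elems <- list(); layer <- character(0)
  for (j in seq_len(n_af)) {           # dissected sector (th decreasing)
    c1 <- col_ids_d[[j]]; c2 <- col_ids_d[[j + 1]]
    for (k in seq_len(ks - 1)) {
      elems[[length(elems) + 1]] <- quad(c1$flap, c2$flap, k)
      layer <- c(layer, "flap")
    }
    for (k in seq_len(nr - ks)) {
      elems[[length(elems) + 1]] <- quad(c1$fl, c2$fl, k)
      layer <- c(layer, "fl_wall")
    }
  }
  for (j in seq_len(n_at)) {           # TL sector
    c1 <- col_ids_t[[j]]; c2 <- col_ids_t[[j + 1]]
    for (k in seq_len(ks - 1)) {
      elems[[length(elems) + 1]] <- quad(c1$flap, c2$flap, k)
      layer <- c(layer, "tl_wall")
    }
    for (k in seq_len(nr - ks)) {
      elems[[length(elems) + 1]] <- quad(c1$fl, c2$fl, k)
      layer <- c(layer, "tl_wall")
    }
  }
  elems <- do.call(rbind, elems)
  elems <- orient_ccw(nodes, elems)

  # boundary sets, edges ordered in increasing polar angle
  edge_chain <- function(ids) cbind(ids[-length(ids)], ids[-1])
  inner_d <- sapply(col_ids_d, function(cc) cc$flap[1])     # th decreasing
  inner_t <- sapply(col_ids_t, function(cc) cc$flap[1])
  flap_out <- sapply(col_ids_d, function(cc) cc$flap[ks])
  fl_in <- sapply(col_ids_d, function(cc) cc$fl[1])
  sets <- list(
    tl_lumen_surface = edge_chain(rev(inner_t)),
    flap_tl_side = edge_chain(rev(inner_d)),
    flap_fl_side = edge_chain(rev(flap_out)),
    fl_wall_inner = edge_chain(rev(fl_in)),
    symmetry_plane = rbind(
      edge_chain(col_ids_d[[1]]$flap),
      edge_chain(col_ids_d[[1]]$fl),
      edge_chain(col_ids_t[[n_at + 1]]$flap),
      edge_chain(col_ids_t[[n_at + 1]]$fl)))

  mesh <- structure(list(nodes = nodes, elems = elems, layer = layer,
                         sets = sets, h = h, geom = geom),
                    class = "cross_section_mesh")
  validate_mesh(mesh)
  mesh
}

build_ring_mesh <- function(geom, h) {
  Ri <- geom$inner_radius; t <- geom$tl_thickness
  nr <- max(2L, ceiling(t / h))
  rmid <- Ri + t / 2
  na <- max(8L, ceiling(2 * pi * rmid / h))
  th <- seq(0, 2 * pi, length.out = na + 1)[-(na + 1)]
  rads <- seq(Ri, Ri + t, length.out = nr + 1)
  ids <- matrix(seq_len((nr + 1) * na), nr + 1, na)
  nodes <- cbind(as.vector(outer(rads, cos(th))), as.vector(outer(rads, sin(th))))
  elems <- list()
  for (j in seq_len(na)) {
    jp <- if (j == na) 1L else j + 1L
    for (k in seq_len(nr))
      elems[[length(elems) + 1]] <- c(ids[k, j], ids[k, jp], ids[k + 1, jp], ids[k + 1, j])
  }
  elems <- orient_ccw(nodes, do.call(rbind, elems))
  inner <- c(ids[1, ], ids[1, 1])
  sets <- list(tl_lumen_surface = cbind(inner[-length(inner)], inner[-1]),
               flap_tl_side = NULL, flap_fl_side = NULL, fl_wall_inner = NULL,
               symmetry_plane = NULL)
  mesh <- structure(list(nodes = nodes, elems = elems,
                         layer = rep("wall", nrow(elems)),
                         sets = sets, h = h, geom = geom),
                    class = "cross_section_mesh")
  validate_mesh(mesh)
  mesh
}

elem_areas <- function(nodes, elems) {
  x <- matrix(nodes[t(elems), 1], ncol = 4, byrow = TRUE)
  y <- matrix(nodes[t(elems), 2], ncol = 4, byrow = TRUE)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) + (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
         (x[, 3] * y[, 4] - x[, 4] * y[, 3]) + (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

orient_ccw <- function(nodes, elems) {
  a <- elem_areas(nodes, elems)
  flip <- a < 0
  elems[flip, ] <- elems[flip, c(1, 4, 3, 2), drop = FALSE]
  elems
}

validate_mesh <- function(mesh) {
  a <- elem_areas(mesh$nodes, mesh$elems)
  if (any(a <= 0)) stop("mesh contains inverted or degenerate elements")
  if (!mesh$geom$intact) {
    nflap_rows <- sum(mesh$layer == "flap") # at least 2 rows through flap
    sym <- unique(as.vector(mesh$sets$symmetry_plane))
    if (any(abs(mesh$nodes[sym, 1]) > 1e-9))
      stop("symmetry-plane nodes are off the plane")
  }
  invisible(mesh)
}

#' @export
print.cross_section_mesh <- function(x, ...) {
  cat(sprintf("Cross-section mesh: %d nodes, %d elements (h = %g mm)\n",
              nrow(x$nodes), nrow(x$elems), x$h))
  print(table(x$layer))
  invisible(x)
}

#' Per-layer meshed area
#'
#' @param mesh a [build_cross_section] mesh.
#' @return named numeric vector of areas (mm^2) by layer.
#' @export
mesh_layer_areas <- function(mesh) {
  a <- elem_areas(mesh$nodes, mesh$elems)
  tapply(a, mesh$layer, sum)
}

#' Rigid circular expansion member
#'
#' The displacement-driven rigid surface standing in for the balloon or
#' stent: a circle whose radius is the single kinematic degree of freedom.
#'
#' @param center circle center (mm), default the lumen center.
#' @param radius initial radius (mm); must start contact-free inside the TL.
#' @param n_segments discretization for export/inspection (>= 8).
#' @param target_radius final radius for displacement-driven expansion of
#'   an intact ring (dissected models grow until re-apposition instead).
#' @return object of class `expansion_member`.
#' @export
make_expansion_member <- function(center = c(0, 0), radius = 1, n_segments = 64,
                                  target_radius = NULL) {
  if (n_segments < 8) stop("n_segments too small: need at least 8 for a usable circle")
  stopifnot(radius > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 n_segments = as.integer(n_segments),
                 target_radius = target_radius),
            class = "expansion_member")
}

#' First-contact radius of the expansion member
#'
#' Smallest member radius at which the (possibly deformed) TL-facing
#' surface is touched: the minimum distance from the member center to the
#' TL-wall inner and flap TL-side surface nodes.
#'
#' @param mesh a [build_cross_section] mesh.
#' @param member an [make_expansion_member] object.
#' @param u optional displacement vector (2 per node) for a deformed state.
#' @return radius in mm.
#' @export
member_first_contact_radius <- function(mesh, member, u = NULL) {
  ids <- tl_facing_nodes(mesh)
  xy <- mesh$nodes[ids, , drop = FALSE]
  if (!is.null(u)) xy <- xy + cbind(u[2 * ids - 1], u[2 * ids])
  min(sqrt((xy[, 1] - member$center[1])^2 + (xy[, 2] - member$center[2])^2))
}

tl_facing_nodes <- function(mesh) {
  unique(as.vector(rbind(mesh$sets$tl_lumen_surface, mesh$sets$flap_tl_side)))
}
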