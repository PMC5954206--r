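# Quasi-static finite-strain solver for the cross-section re-apposition
# problem.
#
# Two steps, mirroring the bench protocol: (1) ramp a follower pressure on
# the luminal surfaces to the static aortic pressure; (2) grow the rigid
# expansion member until the intimal flap is fully re-apposed against the
# FL wall. Frictionless penalty contact on three pairs: member-flap,
# member-TL wall, flap-FL wall. The residual is the gradient of total
# potential energy (internal + penalty contact + stabilization springs -
# pressure work); the tangent is consistent at the element level.

#' Solver controls for the re-apposition simulation
#'
#' @param load_steps pressure ramp increments for Step 1 (default 8).
#' @param member_step member radius increment per Step-2 march increment
#'   (mm, default 0.25); the termination radius is then refined to
#'   max(0.01, member_step/32) mm by bisection.
#' @param newton_tol relative residual tolerance.
#' @param max_newton Newton iteration cap per increment.
#' @param contact_penalty penalty stiffness (Pa/mm); `NULL` selects
#'   100 x (initial shear modulus 2*c10 of the stiffest layer) / h.
#' @param g_tol full re-apposition gap tolerance as a fraction of flap
#'   thickness (must be <= 0.05; default 0.01).
#' @param kvol_factor volumetric penalty modulus as a multiple of each
#'   layer's c10 (default 1e4).
#' @param stab_spring grounded-spring stiffness as a fraction of max c10
#'   (regularizes the rigid translation mode of the half model until
#'   member contact supports it; default 1e-8, negligible at convergence).
#' @param pressurize_fl apply the static pressure to the FL-facing
#'   surfaces as well as the TL lumen (default TRUE). On the bench the
#'   true and false lumens communicate through the entry/re-entry tears,
#'   so both see the static pressure; with the false lumen unpressurized
#'   the flap would simply stay pinned against the FL wall and no
#'   re-apposition pressure would be needed. The member itself stays
#'   unloaded either way, so its contact pressure remains the analog of
#'   the bench balloon-minus-aortic pressure.
#' @param avg_over average member contact pressure over the `"contacting"`
#'   surface only (default) or the `"full"` member surface.
#' @param du_cap cap on the displacement increment per Newton iteration,
#'   as a multiple of the element size h (default 5); guards against
#'   element inversion on wild trial steps.
#' @param verbose print per-increment progress.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(load_steps = 8, member_step = 0.25,
                           newton_tol = 1e-6, max_newton = 40,
                           contact_penalty = NULL, g_tol = 0.01,
                           kvol_factor = 1e4, stab_spring = 1e-8,
                           pressurize_fl = TRUE,
                           avg_over = c("contacting", "full"),
                           du_cap = 5, verbose = FALSE) {
  stopifnot(load_steps >= 1, member_step > 0, newton_tol > 0, max_newton > 0,
            g_tol > 0, kvol_factor > 0, stab_spring >= 0, du_cap > 0)
  if (g_tol > 0.05) stop("g_tol must be <= 0.05 (fraction of flap thickness)")
  structure(list(load_steps = load_steps, member_step = member_step,
                 newton_tol = newton_tol, max_newton = max_newton,
                 contact_penalty = contact_penalty, g_tol = g_tol,
                 kvol_factor = kvol_factor, stab_spring = stab_spring,
                 pressurize_fl = pressurize_fl,
                 avg_over = match.arg(avg_over), du_cap = du_cap,
                 verbose = verbose),
            class = "solver_options")
}

# ---- model setup -----------------------------------------------------------

fe_model <- function(mesh, materials, opts = solver_options()) {
  stopifnot(inherits(mesh, "cross_section_mesh"))
  layers <- unique(mesh$layer)
  if (!all(layers %in% names(materials)))
    stop("materials must be a named list covering layers: ",
         paste(layers, collapse = ", "))
  for (l in layers) validate_goh_params(materials[[l]])
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  matp <- matrix(0, m, 7); tref <- matrix(0, m, 2)
  cx <- rowMeans(matrix(mesh$nodes[t(mesh$elems), 1], ncol = 4, byrow = TRUE))
  cy <- rowMeans(matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE))
  thc <- atan2(cy, cx)
  tref[, 1] <- -sin(thc); tref[, 2] <- cos(thc)  # reference circumferential
  for (l in layers) {
    i <- mesh$layer == l; p <- materials[[l]]
    a <- p$alpha * pi / 180
    matp[i, ] <- matrix(c(p$c10, p$k1, p$k2, p$kappa, cos(a)^2, sin(a)^2,
                          opts$kvol_factor * p$c10), sum(i), 7, byrow = TRUE)
  }
  maxc10 <- max(vapply(materials[layers], function(p) p$c10, 0))
  kc <- if (is.null(opts$contact_penalty)) 100 * 2 * maxc10 / mesh$h
        else opts$contact_penalty
  sym_nodes <- unique(as.vector(mesh$sets$symmetry_plane))
  fixed <- if (length(sym_nodes)) 2L * sym_nodes - 1L else integer(0) # u_x = 0
  free <- setdiff(seq_len(2L * n), fixed)
  # pressurized surface: TL lumen + flap TL side (edges ordered +theta)
  pedges <- rbind(mesh$sets$tl_lumen_surface, mesh$sets$flap_tl_side)
  if (opts$pressurize_fl && !is.null(mesh$sets$flap_fl_side))
    # FL pocket: outward on the FL wall inner face, inward on the flap's
    # FL-facing face (edge order reversed so the normal flips)
    pedges <- rbind(pedges, mesh$sets$flap_fl_side[, 2:1, drop = FALSE],
                    mesh$sets$fl_wall_inner)
  member_chain <- node_chain(rbind(mesh$sets$tl_lumen_surface,
                                   mesh$sets$flap_tl_side))
  slave_chain <- node_chain(mesh$sets$flap_fl_side)
  list(mesh = mesh, materials = materials, matp = matp, tref = tref,
       n = n, ndof = 2L * n, free = free, kc = kc,
       du_cap = opts$du_cap * mesh$h,
       spring = opts$stab_spring * maxc10,
       pedges = pedges, member_chain = member_chain,
       slave_chain = slave_chain, master_segs = mesh$sets$fl_wall_inner,
       master_nodes = if (is.null(mesh$sets$fl_wall_inner)) integer(0)
                      else sort(unique(as.vector(mesh$sets$fl_wall_inner))),
       opts = opts)
}

# ordered node chains (lists of consecutive node ids) from edge matrices
node_chain <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(NULL)
  chains <- list(); cur <- edges[1, ]
  if (nrow(edges) > 1) for (i in 2:nrow(edges)) {
    if (edges[i, 1] == cur[length(cur)]) cur <- c(cur, edges[i, 2])
    else { chains[[length(chains) + 1]] <- cur; cur <- edges[i, ] }
  }
  chains[[length(chains) + 1]] <- cur
  chains
}

# slave nodes with tributary lengths, excluding nodes shared with the
# master chain (the crack-tip node belongs to both faces)
slave_nodes_trib <- function(model, xd) {
  st <- chain_nodes_trib(model$slave_chain, xd)
  keep <- !(st$ids %in% model$master_nodes)
  list(ids = st$ids[keep], trib = st$trib[keep])
}

chain_nodes_trib <- function(chains, xd) {
  ids <- integer(0); trib <- numeric(0)
  for (ch in chains) {
    xy <- xd[ch, , drop = FALSE]
    el <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    tr <- c(el / 2, 0) + c(0, el / 2)
    ids <- c(ids, ch); trib <- c(trib, tr)
  }
  # nodes shared by two chains accumulate both halves
  agg <- rowsum(trib, ids)
  list(ids = as.integer(rownames(agg)), trib = as.numeric(agg))
}

# ---- load and contact contributions ---------------------------------------

# follower pressure on edges (ordered so that (t_y, -t_x) points from the
# lumen into the material): forces on nodes plus tangent triplets
pressure_contrib <- function(xd, edges, p) {
  n1 <- edges[, 1]; n2 <- edges[, 2]
  tx <- xd[n2, 1] - xd[n1, 1]; ty <- xd[n2, 2] - xd[n1, 2]
  fx <- p / 2 * ty; fy <- -p / 2 * tx     # per node, both nodes alike
  f <- numeric(2 * nrow(xd))
  idx <- c(2 * n1 - 1, 2 * n1, 2 * n2 - 1, 2 * n2)
  val <- c(fx, fy, fx, fy)
  agg <- rowsum(val, idx)
  f[as.integer(rownames(agg))] <- as.numeric(agg)
  # df/dt = p/2 * [[0,1],[-1,0]]; dt/dx2 = I, dt/dx1 = -I
  ne <- length(n1)
  ii <- jj <- vv <- vector("list", 8)
  k <- 0
  for (a in list(n1, n2)) for (b in list(list(n1, -1), list(n2, 1))) {
    bn <- b[[1]]; s <- b[[2]]
    k <- k + 1
    ii[[k]] <- c(2 * a - 1, 2 * a)
    jj[[k]] <- c(2 * bn, 2 * bn - 1)
    vv[[k]] <- c(rep(s * p / 2, ne), rep(-s * p / 2, ne))
  }
  list(f = f, ki = unlist(ii), kj = unlist(jj), kv = unlist(vv))
}

# rigid-member penalty contact on the TL-facing surface nodes. With an
# explicit active set the springs are bilateral (force kc*pen also in
# tension), keeping the linearized problem smooth; the set is updated by
# releasing tension nodes and adding penetrating ones.
member_contrib <- function(xd, ids, trib, center, Rm, kc, active = NULL) {
  dx <- xd[ids, 1] - center[1]; dy <- xd[ids, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  pen <- Rm - r
  actk <- if (is.null(active)) pen > 0 else active
  act <- actk & pen > 0
  out <- list(f = numeric(2 * nrow(xd)), ki = integer(0), kj = integer(0),
              kv = numeric(0), ids = ids[act], pressure = kc * pen[act],
              trib = trib[act], energy = 0.5 * kc * sum(trib[act] * pen[act]^2),
              n_active = sum(act), pen = pen)
  if (!any(actk)) return(out)
  i <- ids[actk]; l <- trib[actk]; rr <- r[actk]
  ux <- dx[actk] / rr; uy <- dy[actk] / rr
  pc <- if (is.null(active)) kc * pmax(pen[actk], 0) else kc * pen[actk]
  out$f[2 * i - 1] <- pc * l * ux; out$f[2 * i] <- pc * l * uy
  # d2E/du2 = l [ kc r r^T - pc (I - r r^T)/r ]
  kxx <- l * (kc * ux * ux - pc * (1 - ux * ux) / rr)
  kyy <- l * (kc * uy * uy - pc * (1 - uy * uy) / rr)
  kxy <- l * (kc * ux * uy + pc * ux * uy / rr)
  out$ki <- c(2 * i - 1, 2 * i, 2 * i - 1, 2 * i)
  out$kj <- c(2 * i - 1, 2 * i, 2 * i, 2 * i - 1)
  out$kv <- c(kxx, kyy, kxy, kxy)
  out
}

# node-to-segment penalty contact: flap outer nodes (slave) against the FL
# wall inner surface (master). Averaged nodal normals give a continuous
# normal field along the chain, so the contact force direction cannot flip
# when a slave projection crosses a master node (the two crack faces are
# conforming and initially coincident). `active` (logical per slave)
# switches to bilateral springs as above.
n2s_contrib <- function(xd, slave_ids, slave_trib, segs, kc, active = NULL) {
  ns <- length(slave_ids)
  a <- segs[, 1]; b <- segs[, 2]
  ax <- xd[a, 1]; ay <- xd[a, 2]
  tx <- xd[b, 1] - ax; ty <- xd[b, 2] - ay
  L2 <- tx^2 + ty^2; L <- sqrt(L2)
  nx <- -ty / L; ny <- tx / L          # points toward the lumen / flap
  nseg <- length(a)
  n1x <- nx; n1y <- ny; n2x <- nx; n2y <- ny
  if (nseg > 1) {
    n1x[-1] <- (nx[-1] + nx[-nseg]) / 2; n1y[-1] <- (ny[-1] + ny[-nseg]) / 2
    n2x[-nseg] <- n1x[-1]; n2y[-nseg] <- n1y[-1]
  }
  sx <- xd[slave_ids, 1]; sy <- xd[slave_ids, 2]
  # closest-point projection of each slave on each segment
  xi <- (outer(sx, ax, "-") * rep(tx, each = ns) +
         outer(sy, ay, "-") * rep(ty, each = ns)) / rep(L2, each = ns)
  xi <- pmin(pmax(xi, 0), 1)
  px <- rep(ax, each = ns) + xi * rep(tx, each = ns)
  py <- rep(ay, each = ns) + xi * rep(ty, each = ns)
  d2 <- (sx - px)^2 + (sy - py)^2
  dim(d2) <- c(ns, nseg)
  seg <- max.col(-d2, ties.method = "first")
  k <- cbind(seq_len(ns), seg)
  dim(xi) <- dim(px) <- dim(py) <- c(ns, nseg)
  xis <- xi[k]; pxs <- px[k]; pys <- py[k]
  nxs <- (1 - xis) * n1x[seg] + xis * n2x[seg]
  nys <- (1 - xis) * n1y[seg] + xis * n2y[seg]
  nl <- sqrt(nxs^2 + nys^2)
  nxs <- nxs / nl; nys <- nys / nl
  gap <- -((sx - pxs) * nxs + (sy - pys) * nys)  # >0 means penetration
  actk <- if (is.null(active)) gap > 0 else active
  act <- actk & gap > 0
  out <- list(f = numeric(2 * nrow(xd)), ki = integer(0), kj = integer(0),
              kv = numeric(0), gap = -gap, pen = gap, energy = 0,
              n_active = sum(act))
  if (!any(actk)) return(out)
  s <- slave_ids[actk]; l <- slave_trib[actk]
  g <- if (is.null(active)) pmax(gap[actk], 0) else gap[actk]
  m1 <- a[seg[actk]]; m2 <- b[seg[actk]]
  w1 <- 1 - xis[actk]; w2 <- xis[actk]
  nxa <- nxs[actk]; nya <- nys[actk]
  pc <- kc * g
  out$energy <- 0.5 * kc * sum(l * pmax(g, 0)^2)
  # force on slave along +n, reactions on master nodes (accumulated:
  # several slaves may load the same master node)
  idx <- c(2 * s - 1, 2 * s, 2 * m1 - 1, 2 * m1, 2 * m2 - 1, 2 * m2)
  val <- c(pc * l * nxa, pc * l * nya,
           -w1 * pc * l * nxa, -w1 * pc * l * nya,
           -w2 * pc * l * nxa, -w2 * pc * l * nya)
  agg <- rowsum(val, idx)
  out$f[as.integer(rownames(agg))] <- as.numeric(agg)
  # Gauss-Newton stiffness: kc l (dg)(dg)^T with dg = (-n; w1 n; w2 n)
  nodes3 <- list(cbind(s, -1), cbind(m1, w1), cbind(m2, w2))
  ii <- jj <- vv <- list()
  for (A in nodes3) for (B in nodes3) {
    wa <- A[, 2]; wb <- B[, 2]
    na_ <- A[, 1]; nb_ <- B[, 1]
    cf <- kc * l * wa * wb
    ii <- c(ii, list(2 * na_ - 1, 2 * na_ - 1, 2 * na_, 2 * na_))
    jj <- c(jj, list(2 * nb_ - 1, 2 * nb_, 2 * nb_ - 1, 2 * nb_))
    vv <- c(vv, list(cf * nxa * nxa, cf * nxa * nya, cf * nya * nxa, cf * nya * nya))
  }
  out$ki <- unlist(ii); out$kj <- unlist(jj); out$kv <- unlist(vv)
  out
}

# ---- assembly and Newton solve at fixed load ------------------------------

assemble_system <- function(model, u, p_pa, Rm, act_mem = NULL, act_n2s = NULL,
                            need_K = TRUE, spring_scale = 1) {
  mesh <- model$mesh
  xd <- mesh$nodes + cbind(u[seq(1, model$ndof, 2)], u[seq(2, model$ndof, 2)])
  core <- asm_internal(mesh$nodes, mesh$elems, model$matp, model$tref, u, need_K)
  if (!isTRUE(core$ok))
    return(list(ok = FALSE, why = core$why, bad_elem = core$bad_elem))
  spr <- model$spring * spring_scale
  R <- core$f + spr * u
  if (need_K) {
    ki <- list(core$i, seq_len(model$ndof))
    kj <- list(core$j, seq_len(model$ndof))
    kv <- list(core$v, rep(spr, model$ndof))
  }
  fp <- NULL
  if (p_pa > 0 && !is.null(model$pedges)) {
    pc <- pressure_contrib(xd, model$pedges, p_pa)
    R <- R - pc$f
    fp <- pc$f
    if (need_K) {
      ki <- c(ki, list(pc$ki)); kj <- c(kj, list(pc$kj)); kv <- c(kv, list(-pc$kv))
    }
  }
  mem <- NULL
  if (!is.null(Rm)) {
    ct <- chain_nodes_trib(model$member_chain, xd)
    mem <- member_contrib(xd, ct$ids, ct$trib, c(0, 0), Rm, model$kc, act_mem)
    # mem$kv is d2E/du2 of the penalty energy: enters K with +
    R <- R - mem$f
    if (need_K) {
      ki <- c(ki, list(mem$ki)); kj <- c(kj, list(mem$kj)); kv <- c(kv, list(mem$kv))
    }
  }
  n2s <- NULL
  if (!is.null(model$slave_chain)) {
    st <- slave_nodes_trib(model, xd)
    n2s <- n2s_contrib(xd, st$ids, st$trib, model$master_segs, model$kc, act_n2s)
    R <- R - n2s$f
    if (need_K) {
      ki <- c(ki, list(n2s$ki)); kj <- c(kj, list(n2s$kj)); kv <- c(kv, list(n2s$kv))
    }
  }
  K <- if (need_K)
    Matrix::sparseMatrix(i = unlist(ki), j = unlist(kj), x = unlist(kv),
                         dims = c(model$ndof, model$ndof))
  else NULL
  list(ok = TRUE, R = R, K = K, fp = fp, mem = mem, n2s = n2s,
       strain_energy = core$energy, maxJdev = core$maxJdev,
       sigma_centroid = core$sigma_centroid, elem_area = core$elem_area,
       contact_energy = (if (is.null(mem)) 0 else mem$energy) +
         (if (is.null(n2s)) 0 else n2s$energy) +
         0.5 * spr * sum(u^2))
}

resid_norm <- function(R, free) sqrt(sum(R[free]^2))

# current signed penetrations, used to seed/update the contact active sets
contact_pens <- function(model, u, Rm) {
  xd <- model$mesh$nodes +
    cbind(u[seq(1, model$ndof, 2)], u[seq(2, model$ndof, 2)])
  pen_mem <- NULL; pen_n2s <- NULL
  if (!is.null(Rm)) {
    ct <- chain_nodes_trib(model$member_chain, xd)
    pen_mem <- member_contrib(xd, ct$ids, ct$trib, c(0, 0), Rm, 0)$pen
  }
  if (!is.null(model$slave_chain)) {
    st <- slave_nodes_trib(model, xd)
    pen_n2s <- n2s_contrib(xd, st$ids, st$trib, model$master_segs, 0)$pen
  }
  list(mem = pen_mem, n2s = pen_n2s)
}

# Newton iteration with bilateral contact springs on an active set that is
# updated in-loop with hysteresis (released on tension, added on
# penetration). A floppy flap with one-node contact can make the tangent
# indefinite (snap-through, neutral sliding modes); adaptive Levenberg
# damping of the iteration matrix stabilizes those phases without changing
# the converged solution. The set is frozen while damping is engaged.
newton_inner <- function(model, u, p_pa, Rm, act_mem, act_n2s,
                         spring_scale = 1, tol_scale = 1) {
  opts <- model$opts
  free <- model$free
  sys <- assemble_system(model, u, p_pa, Rm, act_mem, act_n2s,
                         spring_scale = spring_scale)
  if (!sys$ok) return(list(converged = FALSE, u = u, why = sys$why))
  scale <- max(1, if (!is.null(sys$fp)) sqrt(sum(sys$fp^2)) else 0,
               if (!is.null(sys$mem)) sqrt(sum(sys$mem$f^2)) else 0)
  rn <- resid_norm(sys$R, free)
  tol <- opts$newton_tol * tol_scale
  it <- 0
  lam <- 0
  lm_mode <- FALSE
  dref <- NULL
  rn_hist <- rn
  attempts <- 0
  relite <- function(un) assemble_system(model, un, p_pa, Rm, act_mem, act_n2s,
                                         need_K = FALSE, spring_scale = spring_scale)
  while (rn > tol * scale && it < opts$max_newton &&
         attempts < 3 * opts$max_newton) {
    attempts <- attempts + 1
    Kf <- sys$K[free, free]
    if (lm_mode && lam > 0) {
      if (is.null(dref)) dref <- mean(abs(Matrix::diag(sys$K)[free]))
      Kf <- Kf + lam * dref * Matrix::Diagonal(length(free))
    }
    fac <- tryCatch(Matrix::lu(Kf), error = function(e) NULL)
    if (is.null(fac)) {
      if (lm_mode && lam >= 1e4)
        return(list(converged = FALSE, u = u, why = "singular tangent"))
      lm_mode <- TRUE; lam <- max(10 * lam, 1e-6); next
    }
    du <- numeric(model$ndof)
    sol <- tryCatch(Matrix::solve(fac, -sys$R[free]), error = function(e) NULL)
    if (is.null(sol)) return(list(converged = FALSE, u = u, why = "singular tangent"))
    du[free] <- as.numeric(sol)
    alpha <- min(1, model$du_cap / max(abs(du)))
    acc <- NULL
    if (!lm_mode) {
      # fast phase: nonmonotone acceptance (transient residual spikes from
      # contact engagement are normal; Newton recovers quadratically)
      for (ls in 1:6) {
        un <- u + alpha * du
        syn <- relite(un)
        if (syn$ok) {
          rnn <- resid_norm(syn$R, free)
          if (is.null(acc) || rnn < acc$rn) acc <- list(u = un, rn = rnn, sys = syn)
          if (rnn < 1e4 * rn) break
        }
        alpha <- alpha / 2
      }
      if (is.null(acc)) return(list(converged = FALSE, u = u, why = "line search failed"))
      # stagnation over a window: engage damped monotone iterations
      if (it >= 6 && rn > 0.9 * rn_hist[max(1, it - 5)]) {
        lm_mode <- TRUE; lam <- 1e-4
      }
    } else {
      # damped phase: monotone acceptance under Levenberg regularization
      for (ls in 1:4) {
        un <- u + alpha * du
        syn <- relite(un)
        if (syn$ok) {
          rnn <- resid_norm(syn$R, free)
          if (rnn < rn * 0.999) { acc <- list(u = un, rn = rnn, sys = syn); break }
        }
        alpha <- alpha / 2
      }
      if (is.null(acc)) {
        if (lam >= 1e4)
          return(list(converged = FALSE, u = u, why = "no progress under damping"))
        lam <- max(10 * lam, 1e-6)
        next
      }
      lam <- lam / 5
      if (lam < 1e-8) { lam <- 0; lm_mode <- FALSE }
    }
    it <- it + 1
    u <- acc$u
    rn_hist <- c(rn_hist, acc$rn)
    # update the contact active sets from the accepted iterate (hysteresis
    # band 1e-9 mm); frozen while Levenberg damping is engaged
    if (!lm_mode) {
      lsys <- acc$sys
      if (!is.null(act_mem) && !is.null(lsys$mem))
        act_mem <- lsys$mem$pen > ifelse(act_mem, -1e-9, 1e-9)
      if (!is.null(act_n2s) && !is.null(lsys$n2s))
        act_n2s <- lsys$n2s$pen > ifelse(act_n2s, -1e-9, 1e-9)
    }
    sys <- assemble_system(model, u, p_pa, Rm, act_mem, act_n2s,
                           spring_scale = spring_scale)
    if (!sys$ok) return(list(converged = FALSE, u = u, why = sys$why))
    rn <- resid_norm(sys$R, free)
  }
  list(converged = rn <= tol * scale, u = u, iters = it,
       resid = rn / scale, sys = sys,
       act_mem = act_mem, act_n2s = act_n2s)
}

# outer wrapper: seeds the active sets from the current gaps and verifies
# set stability at convergence
newton_solve <- function(model, u, p_pa, Rm = NULL,
                         spring_scale = 1, tol_scale = 1) {
  pens <- contact_pens(model, u, Rm)
  act_mem <- if (!is.null(pens$mem)) pens$mem >= -1e-9 else NULL
  act_n2s <- if (!is.null(pens$n2s)) pens$n2s >= -1e-9 else NULL
  iters <- 0
  res <- NULL
  for (outer in 1:8) {
    res <- newton_inner(model, u, p_pa, Rm, act_mem, act_n2s,
                        spring_scale = spring_scale, tol_scale = tol_scale)
    if (!res$converged) return(res)
    iters <- iters + res$iters
    u <- res$u
    act_mem <- res$act_mem; act_n2s <- res$act_n2s
    changed <- FALSE
    if (!is.null(act_mem)) {
      new_mem <- res$sys$mem$pen > ifelse(act_mem, -1e-9, 1e-9)
      changed <- changed || any(new_mem != act_mem)
      act_mem <- new_mem
    }
    if (!is.null(act_n2s)) {
      new_n2s <- res$sys$n2s$pen > ifelse(act_n2s, -1e-9, 1e-9)
      changed <- changed || any(new_n2s != act_n2s)
      act_n2s <- new_n2s
    }
    if (!changed) { res$iters <- iters; return(res) }
  }
  res$converged <- FALSE
  res$why <- "contact active set did not stabilize"
  res
}

# ---- Step 1: pressurization ------------------------------------------------

#' Pressurize the dissected cross-section (Step 1)
#'
#' Ramps a follower (deformation-dependent) pressure on the luminal
#' surfaces to the static aortic pressure, in `load_steps` increments with
#' adaptive halving on Newton failure and secant warm starts.
#'
#' @param mesh a [build_cross_section] mesh.
#' @param materials named list of [goh_params] keyed by layer
#'   (`flap`, `fl_wall`, `tl_wall`; or `wall` for an intact ring).
#' @param p_aorta static aortic pressure in mmHg (>= 0).
#' @param options a [solver_options] list.
#' @return object of class `pressurized_state`.
#' @export
pressurize <- function(mesh, materials, p_aorta, options = solver_options()) {
  stopifnot(p_aorta >= 0)
  model <- fe_model(mesh, materials, options)
  p_pa <- mmhg_to_pa(p_aorta)
  u <- numeric(model$ndof)
  work <- 0; f_prev <- numeric(model$ndof); u_prev <- u
  log <- list()
  if (p_pa > 0) {
    frac <- 0; step <- 1 / options$load_steps
    u_old <- NULL; frac_old <- 0
    res <- NULL
    while (frac < 1 - 1e-12) {
      f_try <- min(1, frac + step)
      # secant warm start from the two previous converged states
      u0 <- if (!is.null(u_old) && frac > frac_old)
        u + (u - u_old) * (f_try - frac) / (frac - frac_old) else u
      res <- newton_solve(model, u0, f_try * p_pa, NULL)
      if (!res$converged && !identical(u0, u))
        res <- newton_solve(model, u, f_try * p_pa, NULL)
      if (!res$converged) {
        step <- step / 2
        if (step < 1e-3 / options$load_steps)
          stop(sprintf(
            "Newton divergence in pressurization; last converged load fraction %.4f",
            frac))
        next
      }
      if (options$verbose)
        message(sprintf("  pressurize: %.0f%%, %d iterations", 100 * f_try, res$iters))
      u_old <- u; frac_old <- frac
      f_now <- if (is.null(res$sys$fp)) numeric(model$ndof) else res$sys$fp
      work <- work + sum(0.5 * (f_prev + f_now) * (res$u - u_prev))
      f_prev <- f_now; u_prev <- res$u
      u <- res$u; frac <- f_try
      log[[length(log) + 1]] <- c(frac = frac, iters = res$iters, resid = res$resid)
      step <- min(step * 1.5, 1 / options$load_steps)
    }
    sys <- res$sys
  } else {
    sys <- assemble_system(model, u, 0, NULL)
  }
  if (sys$maxJdev > 1e-3)
    warning(sprintf("volumetric constraint |J-1| = %.2e exceeds 1e-3", sys$maxJdev))
  structure(list(model = model, u = u, p_aorta = p_aorta, sys = sys,
                 work_pressure = work, work_member = 0,
                 f_press_prev = f_prev, f_mem_prev = numeric(model$ndof),
                 u_prev = u_prev, log = log),
            class = "pressurized_state")
}

#' @export
print.pressurized_state <- function(x, ...) {
  cat(sprintf("Pressurized state: %g mmHg, %d increments, max|J-1| = %.2e\n",
              x$p_aorta, length(x$log), x$sys$maxJdev))
  invisible(x)
}

# current gaps of the flap outer surface to the FL wall (positive = open)
flap_gaps <- function(model, u) {
  xd <- model$mesh$nodes + cbind(u[seq(1, model$ndof, 2)], u[seq(2, model$ndof, 2)])
  st <- slave_nodes_trib(model, xd)
  n2s <- n2s_contrib(xd, st$ids, st$trib, model$master_segs, model$kc)
  n2s$gap
}

# ---- Step 2: member expansion ----------------------------------------------

#' Dilate the expansion member to full flap re-apposition (Step 2)
#'
#' Grows the rigid member radius incrementally from first contact while
#' maintaining the aortic pressure, until every flap outer-surface node is
#' within the gap tolerance of the FL wall, then refines the termination
#' radius by bisection. The radial re-apposition pressure is the
#' area-weighted average contact pressure on the member.
#'
#' @param state a [pressurize] result.
#' @param member an [make_expansion_member] object.
#' @param options a [solver_options] list (defaults to the options the
#'   state was built with).
#' @return object of class `reapposition_result` with fields `p_aorta`
#'   (mmHg), `radial_pressure` (mmHg), `member_radius` (mm),
#'   `final_diameter` (mm), `contact_fraction` history, `newton_log`,
#'   `converged`, energy bookkeeping and assumption flags.
#' @export
expand_member <- function(state, member = make_expansion_member(),
                          options = NULL) {
  stopifnot(inherits(state, "pressurized_state"))
  model <- state$model
  if (is.null(options)) options <- model$opts
  mesh <- model$mesh
  if (is.null(model$slave_chain) && !mesh$geom$intact)
    stop("state has no flap surfaces")
  u <- state$u
  r_first <- member_first_contact_radius(mesh, member, u)
  if (member$radius > r_first + 1e-9)
    stop(sprintf("member (radius %.3f mm) interpenetrates the structure (first contact at %.3f mm)",
                 member$radius, r_first))
  gtol_abs <- if (mesh$geom$intact) Inf
              else options$g_tol * mesh$geom$flap_thickness
  work_m <- state$work_member; work_p <- state$work_pressure
  f_p_prev <- state$f_press_prev; f_m_prev <- state$f_mem_prev
  u_prev <- u
  p_pa <- mmhg_to_pa(state$p_aorta)

  apposed <- function(u) {
    if (mesh$geom$intact) return(FALSE)
    all(flap_gaps(model, u) <= gtol_abs)
  }
  # guard radius: outermost deformed FL-wall inner radius plus margin
  guard_radius <- function(u) {
    ids <- if (mesh$geom$intact) tl_facing_nodes(mesh)
           else unique(as.vector(model$master_segs))
    xd <- mesh$nodes[ids, , drop = FALSE] + cbind(u[2 * ids - 1], u[2 * ids])
    max(sqrt(xd[, 1]^2 + xd[, 2]^2)) + 2 * mesh$h
  }

  logs <- list(); cfrac <- numeric(0)
  Rm <- max(member$radius, r_first - 1e-6) # free growth up to first contact
  done <- apposed(u)
  res <- NULL
  step <- options$member_step
  Rm_last_open <- Rm
  target <- if (mesh$geom$intact) {
    if (is.null(member$target_radius))
      stop("intact-ring expansion needs an explicit member target_radius")
    member$target_radius
  } else Inf
  u_old <- NULL; Rm_old <- Rm
  while (!done) {
    if (Rm >= target - 1e-9) break
    Rm_try <- min(Rm + step, target)
    if (Rm_try > guard_radius(u))
      stop("member radius exceeded the FL wall without full re-apposition")
    # secant warm start along the member-radius continuation
    u0 <- if (!is.null(u_old) && Rm > Rm_old)
      u + (u - u_old) * (Rm_try - Rm) / (Rm - Rm_old) else u
    res <- newton_solve(model, u0, p_pa, Rm_try)
    if (!res$converged && !identical(u0, u))
      res <- newton_solve(model, u, p_pa, Rm_try)
    if (!res$converged) {
      step <- step / 2
      if (step < options$member_step / 512)
        stop(sprintf("Newton divergence in member expansion at radius %.4f mm", Rm))
      next
    }
    if (options$verbose)
      message(sprintf("  member at %.3f mm, %d iterations", Rm_try, res$iters))
    u_old <- u; Rm_old <- Rm
    f_p_now <- if (is.null(res$sys$fp)) numeric(model$ndof) else res$sys$fp
    f_m_now <- if (is.null(res$sys$mem)) numeric(model$ndof) else res$sys$mem$f
    work_p <- work_p + sum(0.5 * (f_p_prev + f_p_now) * (res$u - u_prev))
    work_m <- work_m + sum(0.5 * (f_m_prev + f_m_now) * (res$u - u_prev))
    f_p_prev <- f_p_now; f_m_prev <- f_m_now; u_prev <- res$u
    Rm_last_open <- Rm; Rm <- Rm_try; u <- res$u
    nact <- if (is.null(res$sys$mem)) 0 else res$sys$mem$n_active
    cfrac <- c(cfrac, contact_fraction(model, u))
    logs[[length(logs) + 1]] <- c(Rm = Rm, iters = res$iters, active = nact)
    done <- apposed(u)
    step <- min(step * 1.25, options$member_step)
  }
  # bisection for the smallest radius achieving full re-apposition
  if (!mesh$geom$intact && length(logs) > 0 && (Rm - Rm_last_open) > 1e-6) {
    rtol <- max(0.001, options$member_step / 256)
    lo <- Rm_last_open; hi <- Rm
    u_hi <- u; res_hi <- res
    while (hi - lo > rtol) {
      mid <- (hi + lo) / 2
      rmid <- newton_solve(model, u_hi, p_pa, mid)
      if (!rmid$converged) break
      if (apposed(rmid$u)) {
        hi <- mid; u_hi <- rmid$u; res_hi <- rmid
      } else lo <- mid
    }
    Rm <- hi; u <- u_hi; res <- res_hi
    # close the work integral with one trapezoid from the last march state
    work_p <- work_p + sum(0.5 * (f_p_prev + res$sys$fp) * (u - u_prev))
    work_m <- work_m + sum(0.5 * (f_m_prev + res$sys$mem$f) * (u - u_prev))
    f_p_prev <- res$sys$fp; f_m_prev <- res$sys$mem$f; u_prev <- u
  }
  if (is.null(res)) { # already apposed before any expansion
    res <- newton_solve(model, u, p_pa, Rm)
    u <- res$u
  }
  sys <- res$sys
  rp_pa <- member_avg_pressure(sys$mem, Rm, model$opts$avg_over,
                               half = !mesh$geom$intact)
  ids <- tl_facing_nodes(mesh)
  xd <- mesh$nodes[ids, , drop = FALSE] + cbind(u[2 * ids - 1], u[2 * ids])
  final_d <- 2 * mean(sqrt(xd[, 1]^2 + xd[, 2]^2))
  structure(list(
    p_aorta = state$p_aorta,
    radial_pressure = pa_to_mmhg(max(rp_pa, 0)),
    member_radius = Rm,
    final_diameter = final_d,
    contact_fraction = cfrac,
    newton_log = do.call(rbind, logs),
    converged = isTRUE(res$converged),
    max_gap = if (mesh$geom$intact) NA_real_ else max(flap_gaps(model, u)),
    g_tol_abs = gtol_abs,
    maxJdev = sys$maxJdev,
    strain_energy = sys$strain_energy,
    contact_energy = sys$contact_energy,
    work_external = work_p + work_m,
    u = u, model = model, sys = sys,
    assumed_lumen_radius = mesh$geom$inner_radius),
    class = "reapposition_result")
}

contact_fraction <- function(model, u) {
  if (is.null(model$slave_chain)) return(NA_real_)
  g <- flap_gaps(model, u)
  mean(g <= 0.05 * model$mesh$geom$flap_thickness)
}

member_avg_pressure <- function(mem, Rm, avg_over, half = TRUE) {
  if (is.null(mem) || mem$n_active == 0) return(0)
  tot <- sum(mem$pressure * mem$trib)
  den <- if (avg_over == "contacting") sum(mem$trib)
         else (if (half) pi else 2 * pi) * Rm
  tot / den
}

#' Average contact pressure on the expansion member
#'
#' Area-weighted average of the penalty contact pressures over the
#' member's contacting surface (or over the full member surface if the
#' solver options say so), converted to mmHg. This is the simulation
#' analog of the bench balloon-minus-aortic re-apposition pressure.
#'
#' @param result a [expand_member] result (carries the converged contact
#'   state).
#' @return pressure in mmHg.
#' @export
radial_pressure_from_contact <- function(result) {
  stopifnot(inherits(result, "reapposition_result"))
  mem <- result$sys$mem
  if (is.null(mem) || mem$n_active == 0)
    stop("empty contact set: the member is not in contact")
  pa_to_mmhg(member_avg_pressure(mem, result$member_radius,
                                 result$model$opts$avg_over,
                                 half = !result$model$mesh$geom$intact))
}

#' @export
print.reapposition_result <- function(x, ...) {
  cat(sprintf("Re-apposition at %g mmHg aortic pressure\n", x$p_aorta))
  cat(sprintf("  radial pressure: %.2f mmHg   member radius: %.3f mm\n",
              x$radial_pressure, x$member_radius))
  cat(sprintf("  final inner diameter: %.2f mm   converged: %s\n",
              x$final_diameter, x$converged))
  cat(sprintf("  (assumed unloaded lumen radius: %g mm)\n", x$assumed_lumen_radius))
  invisible(x)
}

#' Full two-step re-apposition simulation
#'
#' Convenience composition of [build_cross_section], [pressurize] and
#' [expand_member]. Deterministic: identical inputs give identical
#' results (there are no stochastic elements).
#'
#' @param geom a [dissection_geometry].
#' @param materials named list of [goh_params] keyed by layer.
#' @param p_aorta static aortic pressure (mmHg).
#' @param h element size (mm).
#' @param options a [solver_options] list.
#' @param member optional [make_expansion_member]; default starts at 30%
#'   of the lumen radius.
#' @return a `reapposition_result`.
#' @export
#' @examples
#' \donttest{
#' geom <- dissection_geometry("mid")
#' mats <- list(flap = aorta_materials("flap")$mid_flap_1,
#'              fl_wall = aorta_materials("wall")$mid_fl_wall,
#'              tl_wall = aorta_materials("wall")$tl_wall)
#' res <- run_reapposition(geom, mats, p_aorta = 100)
#' }
run_reapposition <- function(geom, materials, p_aorta, h = 0.3,
                             options = solver_options(), member = NULL) {
  mesh <- build_cross_section(geom, h)
  if (is.null(member))
    member <- make_expansion_member(radius = 0.3 * geom$inner_radius)
  st <- pressurize(mesh, materials, p_aorta, options)
  expand_member(st, member, options)
}
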