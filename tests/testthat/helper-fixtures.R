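# shared fixtures and cached expensive computations -------------------------

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# single hex8 element on the unit cube (node order: bottom quad CCW, top)
hex_unit_mesh <- function() {
  nodes <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1),
                                 z = c(0, 1)))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  dimnames(nodes) <- NULL
  structure(list(nodes = nodes, elems = matrix(1:8, 1, 8),
                 sets = list(), lumen_facets = NULL, dim = 3L,
                 center = c(0, 0)),
            class = "artery_mesh")
}

# two quad elements sharing no nodes
disconnected_mesh <- function() {
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
                 c(3, 0), c(4, 0), c(4, 1), c(3, 1))
  structure(list(nodes = nodes, elems = rbind(1:4, 5:8),
                 sets = list(), lumen_facets = NULL, dim = 2L,
                 center = c(0, 0)),
            class = "artery_mesh")
}

# boundary conditions pinning whole fields at constant values; fields set
# to NULL stay free
bc_fix_fields <- function(mesh, u = 0, c = 0, phi = 0, d = 0,
                          extra_fixed = integer(0),
                          extra_vals = numeric(0)) {
  fixed <- extra_fixed
  vals <- extra_vals
  add <- function(field, value) {
    if (is.null(value)) return()
    ids <- dof_ids(mesh, field = field)
    fixed <<- c(fixed, ids)
    vals <<- c(vals, rep(value, length(ids)))
  }
  if (!is.null(u)) {
    add("ux", u); add("uy", u)
    if (mesh$dim == 3L) add("uz", u)
  }
  add("c", c); add("phi", phi); add("d", d)
  keep <- !duplicated(fixed)
  list(fixed = fixed[keep], vals = vals[keep], Trot = NULL)
}

# stationary solve of the damage screening equation d - l^2 lap(d) = 0 on
# a strip [0, L] x [0, h], d pinned to 1 at the two mid-span nodes;
# returns nodal profile, L2 error against the closed-form cosh solution
# and the total crack surface energy per unit strip width
damage_strip <- function(nx, l, L = 10 * l) {
  h <- L / nx
  mesh <- mesh_rectangle(nx, 1, L, h)
  params <- material_params(l = l, eps = 1, G_f = 1e12)
  mid <- which(abs(mesh$nodes[, 1] - L / 2) < 1e-9)
  bc <- bc_fix_fields(mesh, u = 0, c = 1, phi = 0, d = NULL,
                      extra_fixed = dof_ids(mesh, mid, "d"),
                      extra_vals = rep(1, length(mid)))
  sol <- newton_solve(mesh, new_state(mesh), params, dt = Inf, bc = bc,
                      control = solver_config(newton_max_iter = 30),
                      mode = "none", pressure = 0)
  stopifnot(sol$ok)
  bottom <- order(mesh$nodes[mesh$sets$bottom, 1])
  nodes_b <- mesh$sets$bottom[bottom]
  x <- mesh$nodes[nodes_b, 1]
  d <- sol$state$D[dof_ids(mesh, nodes_b, "d")]
  dex <- cosh((L / 2 - abs(x - L / 2)) / l) / cosh((L / 2) / l)
  l2 <- sqrt(sum((d - dex)^2 * h) / L)
  # crack surface energy from the 1D nodal profile (trapezoid)
  g <- diff(d) / diff(x)
  xm <- (head(x, -1) + tail(x, -1)) / 2
  dm <- (head(d, -1) + tail(d, -1)) / 2
  gam <- vapply(seq_along(g), function(i)
    crack_surface_density(dm[i], g[i], l), numeric(1))
  list(x = x, d = d, l2 = l2, energy = sum(gam * diff(x)))
}

# steady nutrient balance on a strip with c = 1 at both ends; the exact
# solution is the parabola c = 1 - (R_c / 2 D) x (L - x)
nutrient_strip <- function(nx, R_c = 0.04, D = 1, L = 10) {
  h <- L / nx
  mesh <- mesh_rectangle(nx, 1, L, h)
  params <- material_params(R_c = R_c, D_max = D, D_min = D, l = 1, eps = 1)
  ends <- c(mesh$sets$left, mesh$sets$right)
  bc <- bc_fix_fields(mesh, u = 0, c = NULL, phi = 0, d = 0,
                      extra_fixed = dof_ids(mesh, ends, "c"),
                      extra_vals = rep(1, length(ends)))
  sol <- newton_solve(mesh, new_state(mesh), params, dt = Inf, bc = bc,
                      control = solver_config(newton_max_iter = 30),
                      mode = "none", pressure = 0)
  stopifnot(sol$ok)
  bottom <- order(mesh$nodes[mesh$sets$bottom, 1])
  nodes_b <- mesh$sets$bottom[bottom]
  x <- mesh$nodes[nodes_b, 1]
  cn <- sol$state$D[dof_ids(mesh, nodes_b, "c")]
  cex <- function(x) 1 - (R_c / (2 * D)) * x * (L - x)
  # field error sampled at element midpoints (nodal values of this
  # constant-load balance are superconvergent)
  xm <- (head(x, -1) + tail(x, -1)) / 2
  cm <- (head(cn, -1) + tail(cn, -1)) / 2
  list(x = x, c = cn, exact = cex(x),
       l2 = sqrt(sum((cm - cex(xm))^2 * h) / L))
}

# small-strain pressurized half annulus against the Lame thick-wall
# solution, sampled along a radial path
lame_annulus <- function() {
  cached("lame", {
    geom <- geometry_params(h_coarse = 20, h_fine = 20,
                            refine_center_angle = 0)
    mesh <- build_annulus_mesh(geom)
    params <- material_params(l = 40, eps = 25)
    p <- 0.01  # kPa; strains ~ 1e-4
    sym <- mesh$sets$symmetry
    th <- atan2(mesh$nodes[sym, 2], mesh$nodes[sym, 1])
    pin <- mesh$sets$outer[which.min(abs(
      atan2(mesh$nodes[mesh$sets$outer, 2],
            mesh$nodes[mesh$sets$outer, 1]) - pi / 2))]
    bc <- bc_fix_fields(mesh, u = NULL, c = 1, phi = 0, d = 0,
                        extra_fixed = c(dof_ids(mesh, sym, "uy"),
                                        dof_ids(mesh, pin, "ux")),
                        extra_vals = rep(0, length(sym) + 1))
    bc$Trot <- arterysim:::rotation_matrix(mesh, sym, th)
    sol <- newton_solve(mesh, new_state(mesh), params, dt = Inf, bc = bc,
                        control = solver_config(newton_max_iter = 30),
                        mode = "none", pressure = p)
    stopifnot(sol$ok)
    run <- list(mesh = mesh, state = sol$state, params = params,
                mode = "none")
    prof <- extract_path(run, c(0, 620), c(0, 980), 50)
    a <- 600; b <- 1000
    k <- p * a^2 / (b^2 - a^2)
    list(profile = prof,
         exact_rr = k * (1 - b^2 / prof$r^2),
         exact_tt = k * (1 + b^2 / prof$r^2),
         p = p, sol = sol)
  })
}

# scenario runs on the desk-scale fixture (~10^3 elements, shared by the
# scenario and acceptance tests); geometry is full coronary scale with
# 20 um fine elements
scenario_runs <- function() {
  cached("runs", {
    geo <- list(h_coarse = 60, h_fine = 20)
    dis <- run_scenario(scenario_config(mode = "dissection",
                                        geometry = geo, output_stride = 2))
    dis_matched <- run_scenario(scenario_config(
      mode = "dissection", geometry = geo, solver = list(t_end = 1e-3)))
    ath <- run_scenario(scenario_config(mode = "atherosclerosis",
                                        geometry = geo, output_stride = 2))
    list(dis = dis, dis_matched = dis_matched, ath = ath)
  })
}

# gauss-point cylindrical stress components and region masks of a run
gauss_cyl <- function(run) {
  gs <- gauss_stress(run$mesh, run$state, run$params, run$mode)
  th <- atan2(gs$x_gp[2, ], gs$x_gp[1, ])
  sxx <- gs$sigma_gp[1, ]; syy <- gs$sigma_gp[2, ]; sxy <- gs$sigma_gp[4, ]
  list(gs = gs,
       srr = sxx * cos(th)^2 + 2 * sxy * cos(th) * sin(th) + syy * sin(th)^2,
       stt = sxx * sin(th)^2 - 2 * sxy * cos(th) * sin(th) + syy * cos(th)^2,
       vm = apply(gs$sigma_gp, 2, von_mises),
       pressure = -(gs$sigma_gp[1, ] + gs$sigma_gp[2, ] +
                      gs$sigma_gp[3, ]) / 3)
}

# nodal field averaged onto gauss points (element mean)
gp_field <- function(run, field) {
  v <- run$state$D[dof_ids(run$mesh, field = field)]
  unlist(lapply(seq_len(nrow(run$mesh$elems)), function(e)
    rep(mean(v[run$mesh$elems[e, ]]), if (run$mesh$dim == 2L) 4L else 8L)))
}

# rupture area (current volume of elements with mean damage > 0.5)
rupture_area <- function(run, state) {
  gs <- gauss_stress(run$mesh, state, run$params, run$mode)
  ngp <- if (run$mesh$dim == 2L) 4L else 8L
  dn <- state$D[dof_ids(run$mesh, field = "d")]
  vapply(seq_len(nrow(run$mesh$elems)), function(e) {
    if (mean(dn[run$mesh$elems[e, ]]) > 0.5)
      sum(gs$vol_gp[(e - 1L) * ngp + seq_len(ngp)]) else 0
  }, numeric(1)) |> sum()
}

# deterministic pseudo-random 3x3 elastic deformation gradients with
# det > 0 and J_e away from the tension/compression switch
random_Fe <- function(n, seed = 11) {
  withr::with_seed(seed, {
    out <- list()
    while (length(out) < n) {
      Fe <- diag(3) + matrix(runif(9, -0.3, 0.3), 3, 3)
      J <- det(Fe)
      if (J > 0.3 && abs(J - 1) > 0.02) out[[length(out) + 1]] <- Fe
    }
    out
  })
}
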