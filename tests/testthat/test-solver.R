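test_that("global dof layout is node-major with fields in declared order", {
  fx <- make_fixture("unit")
  expect_equal(dofs_per_node(fx$mesh), 5L)
  expect_equal(dof_ids(fx$mesh, 1, "ux"), 1L)
  expect_equal(dof_ids(fx$mesh, 1, "d"), 5L)
  expect_equal(dof_ids(fx$mesh, 2, "c"), 8L)
  expect_error(dof_ids(fx$mesh, 1, "uz"), "no uz dof")
  m3 <- hex_unit_mesh()
  expect_equal(dofs_per_node(m3), 6L)
  expect_equal(dof_ids(m3, 2, "uz"), 9L)
})

test_that("assembly is block diagonal for disconnected elements and matches connectivity", {
  mesh <- disconnected_mesh()
  st <- new_state(mesh)
  st$D <- withr::with_seed(21, st$D + runif(length(st$D), 0, 0.02))
  asm <- assemble_system(mesh, st, material_params(l = 0.5, eps = 0.5),
                         dt = 0.1, mode = "hematoma")
  K <- as.matrix(asm$K)
  expect_equal(max(abs(K[1:20, 21:40])), 0)
  expect_equal(max(abs(K[21:40, 1:20])), 0)

  # sparsity: nonzeros only between dofs whose nodes share an element
  fx <- make_fixture("tiny")
  st2 <- new_state(fx$mesh)
  asm2 <- assemble_system(fx$mesh, st2, material_params(), dt = 0.1)
  Ks <- asm2$K
  adj <- Matrix::sparseMatrix(
    i = rep(fx$mesh$elems, times = 4),
    j = as.integer(fx$mesh$elems[, rep(1:4, each = 4)]),
    x = 1, dims = rep(nrow(fx$mesh$nodes), 2))
  ij <- which(as.matrix(Ks) != 0, arr.ind = TRUE)
  nd <- (ij - 1L) %/% 5L + 1L
  expect_true(all(adj[nd] > 0))
})

test_that("newton converges in one iteration on the linear nutrient problem", {
  r <- nutrient_strip(8)
  mesh <- mesh_rectangle(8, 1, 10, 1.25)
  params <- material_params(R_c = 0.04, D_max = 1, D_min = 1, l = 1,
                            eps = 1)
  ends <- c(mesh$sets$left, mesh$sets$right)
  bc <- bc_fix_fields(mesh, u = 0, c = NULL, phi = 0, d = 0,
                      extra_fixed = dof_ids(mesh, ends, "c"),
                      extra_vals = rep(1, length(ends)))
  st <- new_state(mesh)
  st$D[dof_ids(mesh, field = "c")] <- 0.8  # nonzero linear start
  sol <- newton_solve(mesh, st, params, dt = Inf, bc = bc,
                      control = solver_config(), mode = "none",
                      pressure = 0)
  expect_true(sol$ok)
  expect_lte(sol$iters, 2)  # one update plus the convergence check
})

test_that("hyperelastic inflation converges quadratically at moderate load", {
  geom <- geometry_params(h_coarse = 80, h_fine = 80,
                          refine_center_angle = 0)
  mesh <- build_annulus_mesh(geom)
  sym <- mesh$sets$symmetry
  th <- atan2(mesh$nodes[sym, 2], mesh$nodes[sym, 1])
  pin <- mesh$sets$outer[1]
  bc <- bc_fix_fields(mesh, u = NULL, c = 1, phi = 0, d = 0,
                      extra_fixed = c(dof_ids(mesh, sym, "uy"),
                                      dof_ids(mesh, pin, "ux")),
                      extra_vals = rep(0, length(sym) + 1))
  bc$Trot <- arterysim:::rotation_matrix(mesh, sym, th)
  sol <- newton_solve(mesh, new_state(mesh), material_params(l = 160),
                      dt = Inf, bc = bc, control = solver_config(),
                      mode = "none", pressure = 2)
  expect_true(sol$ok)
  r <- sol$res_hist
  n <- length(r)
  expect_gte(n, 3)
  # residual ratios ||R_{k+1}|| / ||R_k||^2 stay bounded near the root
  ratios <- r[(n - 1):n] / r[(n - 2):(n - 1)]^2
  expect_true(all(ratios < 100))

  # pathological growth increment signals failure without state mutation
  st <- sol$state
  st$D[dof_ids(mesh, field = "phi")] <- 0.5  # k_g * dphi = 5 >= 1
  bc_free_phi <- bc_fix_fields(mesh, u = NULL, c = 1, phi = NULL, d = 0,
                               extra_fixed = c(dof_ids(mesh, sym, "uy"),
                                               dof_ids(mesh, pin, "ux")),
                               extra_vals = rep(0, length(sym) + 1))
  bc_free_phi$Trot <- bc$Trot
  bad <- newton_solve(mesh, st, material_params(l = 160), dt = 1e-3,
                      bc = bc_free_phi, control = solver_config(),
                      mode = "none", pressure = 2)
  expect_false(bad$ok)
  expect_match(bad$reason, "k_g\\*dphi")
  expect_identical(bad$state$D, st$D)
})

test_that("equilibrium states stay constant in time without sources or load", {
  fx <- make_fixture("unit")
  mesh <- fx$mesh
  bc <- bc_fix_fields(mesh, u = NULL, c = NULL, phi = NULL, d = NULL,
                      extra_fixed = c(1:2, dof_ids(mesh, 2, "uy"),
                                      dof_ids(mesh, 1, "c")),
                      extra_vals = c(0, 0, 0, 1))
  out <- time_march(mesh, material_params(R_c = 0, l = 0.5, eps = 0.5), bc,
                    solver_config(dt = 1e-3, t_end = 3e-3,
                                  load_ramp_steps = 0),
                    mode = "none", p_max = 0)
  expect_equal(out$state$D[dof_ids(mesh, field = "c")], rep(1, 4),
               tolerance = 1e-9)
  expect_equal(max(abs(out$state$D[c(dof_ids(mesh, field = "ux"),
                                     dof_ids(mesh, field = "uy"),
                                     dof_ids(mesh, field = "phi"),
                                     dof_ids(mesh, field = "d"))])), 0,
               tolerance = 1e-9)
})

test_that("a free element with prescribed phi grows to exp(k_g) volume stretch", {
  fx <- make_fixture("unit")
  mesh <- fx$mesh
  params <- material_params(k_g = 1, l = 0.5, eps = 0.5)
  phi_dofs <- dof_ids(mesh, field = "phi")
  n_steps <- 100
  state <- new_state(mesh)
  ctrl <- solver_config(newton_max_iter = 40)
  for (s in seq_len(n_steps)) {
    phi_s <- s / n_steps
    bc <- bc_fix_fields(mesh, u = NULL, c = 1, phi = NULL, d = 0,
                        extra_fixed = c(1:2, dof_ids(mesh, 2, "uy"),
                                        phi_dofs),
                        extra_vals = c(0, 0, 0, rep(phi_s, 4)))
    sol <- newton_solve(mesh, state, params, dt = 1e-2, bc = bc,
                        control = ctrl, mode = "none", pressure = 0)
    expect_true(sol$ok)
    state <- sol$state
    state$phi_prev <- state$D[phi_dofs]
    state$d_prev <- state$D[dof_ids(mesh, field = "d")]
  }
  expect_equal(mean(1 + state$alpha), exp(1), tolerance = 0.01)
  # plane strain blocks the out-of-plane stretch, so the nearly
  # incompressible element carries the full volumetric growth (1+alpha)^3
  # in-plane: each edge stretches by about (1+alpha)^(3/2)
  ux <- state$D[dof_ids(mesh, 2, "ux")] - state$D[dof_ids(mesh, 1, "ux")]
  expect_equal(1 + ux, exp(1.5), tolerance = 0.03)
})

test_that("backward Euler time marching converges first order in dt", {
  fx <- make_fixture("unit")
  mesh <- fx$mesh
  params <- material_params(R_s = 3, k_g = 0.1, l = 0.5, eps = 0.5)
  final_phi <- function(dt) {
    bc <- bc_fix_fields(mesh, u = 0, c = NULL, phi = NULL, d = NULL,
                        extra_fixed = c(dof_ids(mesh, field = "c"),
                                        dof_ids(mesh, field = "d")),
                        extra_vals = c(rep(1, 4), rep(0.5, 4)))
    out <- time_march(mesh, params, bc,
                      solver_config(dt = dt, t_end = 0.2,
                                    load_ramp_steps = 0),
                      mode = "hematoma", p_max = 0, output_stride = 0)
    mean(out$state$D[dof_ids(mesh, field = "phi")])
  }
  p1 <- final_phi(0.05)
  p2 <- final_phi(0.025)
  p3 <- final_phi(0.0125)
  rate <- (p1 - p2) / (p2 - p3)
  expect_gt(rate, 1.5)
  expect_lt(rate, 2.6)
})

test_that("checkpoints round-trip the full state", {
  fx <- make_fixture("tiny")
  st <- new_state(fx$mesh)
  st$D <- withr::with_seed(2, runif(length(st$D)))
  st$phi_prev <- withr::with_seed(3, runif(nrow(fx$mesh$nodes)))
  st$alpha[] <- withr::with_seed(4, runif(length(st$alpha)))
  st$time <- 0.123
  st$step <- 7L
  f <- tempfile(fileext = ".rds")
  checkpoint_write(st, fx$mesh, f)
  st2 <- checkpoint_read(f, fx$mesh)
  expect_equal(st2$D, st$D)
  expect_equal(st2$alpha, st$alpha)
  expect_equal(st2$phi_prev, st$phi_prev)
  expect_equal(st2$time, st$time)
  expect_equal(st2$step, st$step)
})
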