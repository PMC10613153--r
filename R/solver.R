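#' Global degree-of-freedom indices
#'
#' Node-major DOF layout with per-node order `(u_x, u_y[, u_z], c, phi, d)`
#' (5 DOF per node in 2D plane strain, 6 in 3D).
#'
#' @param mesh `artery_mesh`.
#' @param nodes node indices (default all).
#' @param field one of `"ux"`, `"uy"`, `"uz"`, `"c"`, `"phi"`, `"d"`.
#' @return integer vector of global DOF indices.
#' @export
dof_ids <- function(mesh, nodes = seq_len(nrow(mesh$nodes)), field) {
  ndofn <- mesh$dim + 3L
  off <- switch(field, ux = 0L, uy = 1L,
                uz = if (mesh$dim == 3L) 2L else
                  stop("no uz dof in a 2D mesh"),
                c = mesh$dim, phi = mesh$dim + 1L, d = mesh$dim + 2L,
                stop("unknown field '", field, "'"))
  (as.integer(nodes) - 1L) * ndofn + off + 1L
}

#' Number of degrees of freedom per node
#' @param mesh `artery_mesh`.
#' @export
dofs_per_node <- function(mesh) mesh$dim + 3L

#' Initial global state
#'
#' Zero displacement and phase fields, nutrient initialized at the lumen
#' value 1 (the first Newton solve relaxes it to the steady
#' diffusion-consumption balance), pristine Gauss state.
#'
#' @param mesh `artery_mesh`.
#' @return list of class `artery_state` with the global DOF vector `D`,
#'   previous-step nodal `phi_prev`/`d_prev`, per-Gauss-point `alpha` and
#'   `psi_max`, and `time`.
#' @export
new_state <- function(mesh) {
  nnode <- nrow(mesh$nodes)
  ngp <- if (mesh$dim == 2L) 4L else 8L
  D <- numeric(nnode * dofs_per_node(mesh))
  D[dof_ids(mesh, field = "c")] <- 1
  structure(list(D = D, phi_prev = numeric(nnode), d_prev = numeric(nnode),
                 alpha = matrix(0, ngp, nrow(mesh$elems)),
                 psi_max = matrix(0, ngp, nrow(mesh$elems)),
                 time = 0, step = 0L),
            class = "artery_state")
}

# parameter vector for the C++ kernels, with the phase-field source mode
# appended (0 none, 1 hematoma, 2 inflammation)
params_for_cpp <- function(params, mode = c("none", "hematoma",
                                            "inflammation")) {
  mode <- match.arg(mode)
  c(unclass(params), phi_source = match(mode, c("none", "hematoma",
                                                "inflammation")) - 1)
}

#' Assemble the global residual and tangent
#'
#' Scatter-adds all element contributions (and the follower pressure on
#' the lumen facets) into the global residual vector and sparse tangent
#' matrix. The element tangent is a central-difference perturbation of the
#' element residual, so it carries the consistent local sensitivity of the
#' Gauss-point growth variable.
#'
#' @param mesh `artery_mesh`.
#' @param state `artery_state` (uses `D`, `phi_prev`, `d_prev`, `alpha`,
#'   `psi_max`).
#' @param params [material_params()].
#' @param dt time step (may be `Inf` for stationary solves).
#' @param mode phase-field source mode.
#' @param pressure lumen pressure (kPa) applied on `mesh$lumen_facets`.
#' @param tangent,stress logical: compute the sparse tangent / Gauss
#'   stresses.
#' @param fd_eps relative perturbation of the tangent differencing.
#' @return list with `R`, sparse `K` (when requested), updated Gauss
#'   `alpha`/`psi_max`, and Gauss stress data when requested.
#' @export
assemble_system <- function(mesh, state, params, dt, mode = "none",
                            pressure = 0, tangent = TRUE, stress = FALSE,
                            fd_eps = 3e-6) {
  p <- params_for_cpp(params, mode)
  out <- cpp_assemble(mesh$nodes, mesh$elems, state$D, state$phi_prev,
                      state$d_prev, state$alpha, state$psi_max, p, dt,
                      pressure,
                      if (is.null(mesh$lumen_facets)) NULL else
                        mesh$lumen_facets,
                      tangent, stress, fd_eps)
  res <- list(R = out$R, alpha = out$alpha, psi_max = out$psi_max)
  if (tangent) {
    n <- length(out$R)
    res$K <- Matrix::sparseMatrix(i = out$Ki, j = out$Kj, x = out$Kx,
                                  dims = c(n, n))
  }
  if (stress) {
    res$sigma_gp <- out$sigma_gp
    res$x_gp <- out$x_gp
    res$vol_gp <- out$vol_gp
  }
  res
}

#' Solver configuration
#'
#' @param dt time step (model time units).
#' @param t_end end of the coupled evolution (after the pressure ramp).
#' @param newton_tol relative tolerance on the per-field RMS-scaled
#'   residual.
#' @param newton_max_iter maximum Newton iterations per step.
#' @param step_cut_factor time-step reduction on Newton failure.
#' @param max_step_cuts maximum consecutive reductions before aborting.
#' @param load_ramp_steps pressure ramp steps before the evolution (the
#'   phase fields are held frozen while the lumen pressure is ramped
#'   linearly to its full value).
#' @param seed RNG seed recorded with the run.
#' @export
solver_config <- function(dt = 2e-4, t_end = 1e-3, newton_tol = 1e-8,
                          newton_max_iter = 25, step_cut_factor = 0.5,
                          max_step_cuts = 8, load_ramp_steps = 5,
                          seed = 1L) {
  stopifnot(dt > 0, newton_tol > 0, newton_max_iter >= 1,
            step_cut_factor > 0, step_cut_factor < 1, max_step_cuts >= 0,
            load_ramp_steps >= 0)
  structure(list(dt = dt, t_end = t_end, newton_tol = newton_tol,
                 newton_max_iter = newton_max_iter,
                 step_cut_factor = step_cut_factor,
                 max_step_cuts = max_step_cuts,
                 load_ramp_steps = load_ramp_steps, seed = as.integer(seed)),
            class = "solver_config")
}

# per-field masks of the global dof vector
field_masks <- function(mesh) {
  list(u = sort(c(dof_ids(mesh, field = "ux"), dof_ids(mesh, field = "uy"),
                  if (mesh$dim == 3L) dof_ids(mesh, field = "uz"))),
       c = dof_ids(mesh, field = "c"),
       phi = dof_ids(mesh, field = "phi"),
       d = dof_ids(mesh, field = "d"))
}

# Build the rotation transformation for skew symmetry faces: at each
# listed node the displacement dofs are rotated to (radial, tangential)
# so that the tangential component can be fixed by ordinary elimination.
# Returns NULL when no rotation is required.
rotation_matrix <- function(mesh, rot_nodes, angles) {
  if (length(rot_nodes) == 0) return(NULL)
  ndof <- nrow(mesh$nodes) * dofs_per_node(mesh)
  i <- seq_len(ndof); j <- seq_len(ndof); x <- rep(1, ndof)
  ux <- dof_ids(mesh, rot_nodes, "ux")
  uy <- dof_ids(mesh, rot_nodes, "uy")
  ct <- cos(angles); st <- sin(angles)
  drop <- c(ux, uy)
  keep <- !(i %in% drop)
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  # columns: ux-slot = radial dof, uy-slot = tangential dof
  i2 <- c(ux, uy, ux, uy)
  j2 <- c(ux, ux, uy, uy)
  x2 <- c(ct, st, -st, ct)
  Matrix::sparseMatrix(i = c(i, i2), j = c(j, j2), x = c(x, x2),
                       dims = c(ndof, ndof))
}

#' Monolithic Newton-Raphson solve of one time step
#'
#' Iterates `delta = -K^-1 R` on the coupled four-field system until the
#' per-field scaled residual drops below `newton_tol`. On failure
#' (non-convergence or a degenerate element state) the input state is
#' returned unchanged with `ok = FALSE`, signalling a time-step cut.
#'
#' @param mesh,state,params,dt,mode,pressure as in [assemble_system()].
#' @param bc list with `fixed` (global DOF indices), `vals` (prescribed
#'   values) and optionally `Trot` (sparse rotation for skew constraints).
#' @param control [solver_config()].
#' @return list with `ok`, updated `state` (on success), Newton iteration
#'   count `iters` and the residual-norm history `res_hist`.
#' @export
newton_solve <- function(mesh, state, params, dt, bc, control,
                         mode = "none", pressure = 0) {
  D <- state$D
  D[bc$fixed] <- bc$vals
  masks <- field_masks(mesh)
  ndof <- length(D)
  free <- setdiff(seq_len(ndof), bc$fixed)
  Trot <- bc$Trot
  scale <- NULL
  res_hist <- numeric(0)
  st <- state
  st$D <- D
  field_rms <- function(Rv) {
    vapply(masks, function(m) {
      m <- m[m %in% free]
      if (length(m) == 0) return(0)
      sqrt(sum(Rv[m]^2) / length(m))
    }, numeric(1))
  }
  try_assemble <- function(D, tangent = TRUE) {
    st$D <- D
    tryCatch(assemble_system(mesh, st, params, dt, mode, pressure,
                             tangent = tangent),
             error = function(e) e)
  }
  asm <- try_assemble(D)
  if (inherits(asm, "error"))
    return(list(ok = FALSE, state = state, iters = 0L,
                reason = conditionMessage(asm), res_hist = res_hist))
  hat <- function(Rv) if (is.null(Trot)) Rv else
    as.numeric(Matrix::crossprod(Trot, Rv))
  rms <- field_rms(hat(asm$R))
  scale <- pmax(1, rms)
  nrm <- max(rms / scale)
  res_hist <- nrm
  for (it in seq_len(control$newton_max_iter)) {
    if (nrm <= control$newton_tol) {
      out <- state
      out$D <- D
      out$alpha <- asm$alpha
      out$psi_max <- asm$psi_max
      return(list(ok = TRUE, state = out, iters = it, res_hist = res_hist))
    }
    K <- asm$K
    if (!is.null(Trot)) K <- Matrix::crossprod(Trot, K %*% Trot)
    dx <- tryCatch(
      as.numeric(Matrix::solve(K[free, free, drop = FALSE],
                               -hat(asm$R)[free])),
      error = function(e) e)
    if (inherits(dx, "error") || any(!is.finite(dx)))
      return(list(ok = FALSE, state = state, iters = it,
                  reason = "linear solve failed", res_hist = res_hist))
    dfull <- numeric(ndof)
    dfull[free] <- dx
    if (!is.null(Trot)) dfull <- as.numeric(Trot %*% dfull)
    # residual-based line search: accept the largest step in
    # {1, 1/2, ...} whose residual is not substantially worse (the
    # tension indicator and history kinks allow mild increases)
    lam <- 1
    accepted <- FALSE
    for (ls in 1:10) {
      asm_t <- try_assemble(D + lam * dfull, tangent = FALSE)
      if (!inherits(asm_t, "error")) {
        nrm_t <- max(field_rms(hat(asm_t$R)) / scale)
        if (nrm_t <= max(1.5 * nrm, control$newton_tol)) {
          D <- D + lam * dfull
          nrm <- nrm_t
          accepted <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (!accepted)
      return(list(ok = FALSE, state = state, iters = it,
                  reason = "line search failed", res_hist = res_hist))
    asm <- try_assemble(D)
    if (inherits(asm, "error"))
      return(list(ok = FALSE, state = state, iters = it,
                  reason = conditionMessage(asm), res_hist = res_hist))
    res_hist <- c(res_hist, nrm)
  }
  if (nrm <= control$newton_tol) {
    out <- state
    out$D <- D
    out$alpha <- asm$alpha
    out$psi_max <- asm$psi_max
    return(list(ok = TRUE, state = out,
                iters = control$newton_max_iter, res_hist = res_hist))
  }
  list(ok = FALSE, state = state, iters = control$newton_max_iter,
       reason = "newton did not converge", res_hist = res_hist)
}

#' Backward-Euler time marching of the coupled evolution
#'
#' Ramps the lumen pressure linearly over `load_ramp_steps` (phase fields
#' frozen), then advances the coupled system with fixed `dt`. On Newton
#' failure the step is retried with `dt * step_cut_factor`, up to
#' `max_step_cuts` times. After each accepted step the nodal damage is
#' clamped to its running maximum (irreversibility) and the Gauss history
#' is committed.
#'
#' @param mesh,params,bc,control,mode as in [newton_solve()].
#' @param state0 initial state (default [new_state()]).
#' @param p_max full lumen pressure (kPa).
#' @param output_stride store a snapshot every this many accepted steps.
#' @param on_step optional callback `function(state, step)` run after each
#'   accepted evolution step (e.g. VTK output).
#' @return list with final `state`, `snapshots` (list of `artery_state`),
#'   and a step `log` data frame.
#' @export
time_march <- function(mesh, params, bc, control, mode = "none",
                       p_max = 0, state0 = NULL, output_stride = 1,
                       on_step = NULL) {
  if (is.null(state0)) state0 <- new_state(mesh)
  state <- state0
  log <- list()
  snapshots <- list()
  phi_dofs <- dof_ids(mesh, field = "phi")
  d_dofs <- dof_ids(mesh, field = "d")

  # pressure ramp: phase fields frozen at their initial values, except
  # dofs carrying a Dirichlet value in bc (e.g. the damage nucleus),
  # which are ramped to their prescribed value together with the load
  if (control$load_ramp_steps > 0) {
    hold <- c(phi_dofs, d_dofs)
    base_vals <- c(state$phi_prev, state$d_prev)
    in_bc <- match(hold, bc$fixed)
    other <- !(bc$fixed %in% hold)
    ramp_bc <- function(frac_n) {
      vals_s <- base_vals
      idx <- which(!is.na(in_bc))
      vals_s[idx] <- base_vals[idx] +
        frac_n * (bc$vals[in_bc[idx]] - base_vals[idx])
      list(fixed = c(bc$fixed[other], hold),
           vals = c(bc$vals[other], vals_s), Trot = bc$Trot)
    }
    # two continuation legs: lumen pressure on the intact wall, then the
    # prescribed phase-field values (damage nucleus) at full pressure
    ramp_leg <- function(state, leg, phase_name) {
      frac <- 0
      dfrac0 <- 1 / control$load_ramp_steps
      dfrac <- dfrac0
      cuts_total <- 0L
      while (frac < 1 - 1e-12) {
        f_try <- min(frac + dfrac, 1)
        p <- if (leg == "pressure") p_max * f_try else p_max
        fb <- ramp_bc(if (leg == "pressure") 0 else f_try)
        sol <- newton_solve(mesh, state, params, dt = Inf, bc = fb,
                            control = control, mode = mode, pressure = p)
        if (!sol$ok) {
          cuts_total <- cuts_total + 1L
          if (cuts_total > control$max_step_cuts + 8L)
            stop(phase_name, " ramp failed at fraction ",
                 format(f_try), ": ", sol$reason)
          dfrac <- dfrac / 2
          next
        }
        frac <- f_try
        dfrac <- min(dfrac * 1.5, dfrac0)
        state <- sol$state
        state$step <- state$step + 1L
        log[[length(log) + 1]] <<-
          data.frame(phase = phase_name, step = state$step,
                     time = state$time, dt = NA_real_, iters = sol$iters,
                     cuts = cuts_total, pressure = p,
                     max_phi = max(state$D[phi_dofs]),
                     max_d = max(state$D[d_dofs]),
                     min_c = min(state$D[dof_ids(mesh, field = "c")]))
      }
      state
    }
    state <- ramp_leg(state, "pressure", "ramp")
    if (any(!is.na(in_bc)))
      state <- ramp_leg(state, "nucleus", "nucleus")
    state$phi_prev <- state$D[phi_dofs]
    state$d_prev <- state$D[d_dofs]
  }

  # coupled evolution
  guard <- 0L
  while (state$time < control$t_end - 1e-15) {
    guard <- guard + 1L
    if (guard > 100000L) stop("time marching exceeded the iteration guard")
    dt_try <- min(control$dt, control$t_end - state$time)
    cuts <- 0L
    repeat {
      sol <- newton_solve(mesh, state, params, dt = dt_try, bc = bc,
                          control = control, mode = mode, pressure = p_max)
      if (sol$ok) break
      cuts <- cuts + 1L
      if (cuts > control$max_step_cuts)
        stop("time step failed after ", control$max_step_cuts,
             " cuts at t = ", format(state$time), ": ", sol$reason)
      dt_try <- dt_try * control$step_cut_factor
    }
    state <- sol$state
    # damage irreversibility: nodal clamp on accepted steps
    dn <- pmax(state$D[d_dofs], state$d_prev)
    state$D[d_dofs] <- dn
    state$phi_prev <- state$D[phi_dofs]
    state$d_prev <- dn
    state$time <- state$time + dt_try
    state$step <- state$step + 1L
    log[[length(log) + 1]] <-
      data.frame(phase = "evolve", step = state$step, time = state$time,
                 dt = dt_try, iters = sol$iters, cuts = cuts,
                 pressure = p_max, max_phi = max(state$phi_prev),
                 max_d = max(dn),
                 min_c = min(state$D[dof_ids(mesh, field = "c")]))
    if (output_stride > 0 && state$step %% output_stride == 0)
      snapshots[[length(snapshots) + 1]] <- state
    if (!is.null(on_step)) on_step(state, state$step)
  }
  list(state = state, snapshots = snapshots,
       log = do.call(rbind, log))
}

#' Write / restore a solver checkpoint
#'
#' Stores the named field and Gauss arrays (`u`, `c`, `phi`, `dmg`,
#' `alpha`, `psi_max`, `time`) in R's portable serialization format.
#'
#' @param state `artery_state`.
#' @param mesh `artery_mesh`.
#' @param path file path.
#' @export
checkpoint_write <- function(state, mesh, path) {
  u <- cbind(state$D[dof_ids(mesh, field = "ux")],
             state$D[dof_ids(mesh, field = "uy")])
  if (mesh$dim == 3L) u <- cbind(u, state$D[dof_ids(mesh, field = "uz")])
  saveRDS(list(u = u, c = state$D[dof_ids(mesh, field = "c")],
               phi = state$D[dof_ids(mesh, field = "phi")],
               dmg = state$D[dof_ids(mesh, field = "d")],
               phi_prev = state$phi_prev, d_prev = state$d_prev,
               alpha = state$alpha, psi_max = state$psi_max,
               time = state$time, step = state$step),
          path, version = 2)
  invisible(path)
}

#' @rdname checkpoint_write
#' @export
checkpoint_read <- function(path, mesh) {
  x <- readRDS(path)
  state <- new_state(mesh)
  for (k in seq_len(mesh$dim))
    state$D[dof_ids(mesh, field = c("ux", "uy", "uz")[k])] <- x$u[, k]
  state$D[dof_ids(mesh, field = "c")] <- x$c
  state$D[dof_ids(mesh, field = "phi")] <- x$phi
  state$D[dof_ids(mesh, field = "d")] <- x$dmg
  state$phi_prev <- x$phi_prev
  state$d_prev <- x$d_prev
  state$alpha <- x$alpha
  state$psi_max <- x$psi_max
  state$time <- x$time
  state$step <- x$step
  state
}
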