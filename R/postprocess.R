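#' Gauss-point stresses of a state
#'
#' Re-evaluates the constitutive law at every Gauss point of the current
#' state (no tangent). Columns follow the element-major, Gauss-minor
#' ordering; stress components are `(xx, yy, zz, xy, yz, xz)` in kPa.
#'
#' @param mesh,state,params,mode as in [assemble_system()].
#' @return list with `sigma_gp` (6 x ngauss), `x_gp` (reference Gauss
#'   coordinates), `vol_gp` (current Gauss volumes).
#' @export
gauss_stress <- function(mesh, state, params, mode = "none") {
  asm <- assemble_system(mesh, state, params, dt = Inf, mode = mode,
                         pressure = 0, tangent = FALSE, stress = TRUE)
  list(sigma_gp = asm$sigma_gp, x_gp = asm$x_gp, vol_gp = asm$vol_gp)
}

#' Recover nodal stresses by volume-weighted patch averaging
#'
#' Each node receives the volume-weighted mean of the Gauss-point
#' stresses of all elements sharing it.
#'
#' @inheritParams gauss_stress
#' @return nnode x 6 matrix of stress components.
#' @export
recover_nodal_stress <- function(mesh, state, params, mode = "none") {
  gs <- gauss_stress(mesh, state, params, mode)
  ngp <- if (mesh$dim == 2L) 4L else 8L
  nnode <- nrow(mesh$nodes)
  acc <- matrix(0, nnode, 6)
  wsum <- numeric(nnode)
  for (e in seq_len(nrow(mesh$elems))) {
    cols <- (e - 1L) * ngp + seq_len(ngp)
    w <- sum(gs$vol_gp[cols])
    sbar <- as.numeric(gs$sigma_gp[, cols, drop = FALSE] %*%
                         gs$vol_gp[cols]) / max(w, .Machine$double.eps)
    nd <- mesh$elems[e, ]
    acc[nd, ] <- acc[nd, ] + rep(w, each = length(nd)) *
      matrix(sbar, length(nd), 6, byrow = TRUE)
    wsum[nd] <- wsum[nd] + w
  }
  acc / pmax(wsum, .Machine$double.eps)
}

# bilinear point location: returns list(elem, N) or NULL
locate_point <- function(mesh, p, tol = 1e-8) {
  X <- mesh$nodes
  el <- mesh$elems
  lo1 <- pmin(X[el[, 1], 1], X[el[, 2], 1], X[el[, 3], 1], X[el[, 4], 1])
  hi1 <- pmax(X[el[, 1], 1], X[el[, 2], 1], X[el[, 3], 1], X[el[, 4], 1])
  lo2 <- pmin(X[el[, 1], 2], X[el[, 2], 2], X[el[, 3], 2], X[el[, 4], 2])
  hi2 <- pmax(X[el[, 1], 2], X[el[, 2], 2], X[el[, 3], 2], X[el[, 4], 2])
  pad <- 1e-6 * max(hi1 - lo1, hi2 - lo2)
  cand <- which(p[1] >= lo1 - pad & p[1] <= hi1 + pad &
                  p[2] >= lo2 - pad & p[2] <= hi2 + pad)
  sg <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), 4, 2, byrow = TRUE)
  for (e in cand) {
    Xe <- X[el[e, ], 1:2]
    xi <- c(0, 0)
    for (it in 1:30) {
      N <- 0.25 * (1 + sg[, 1] * xi[1]) * (1 + sg[, 2] * xi[2])
      dN <- cbind(0.25 * sg[, 1] * (1 + sg[, 2] * xi[2]),
                  0.25 * sg[, 2] * (1 + sg[, 1] * xi[1]))
      r <- as.numeric(t(Xe) %*% N) - p
      if (sqrt(sum(r^2)) < 1e-10 * (1 + sqrt(sum(p^2)))) break
      J <- t(Xe) %*% dN
      xi <- xi - as.numeric(solve(J, r))
    }
    if (all(abs(xi) <= 1 + tol)) {
      N <- 0.25 * (1 + sg[, 1] * xi[1]) * (1 + sg[, 2] * xi[2])
      return(list(elem = e, N = N))
    }
  }
  NULL
}

#' Sample fields and stresses along a radial path
#'
#' Interpolates the recovered nodal stresses and the primary fields along
#' the straight segment from `point1` to `point2` (typically across the
#' wall through the lesion center). Cylindrical components `sigma_rr`,
#' `sigma_tt` and the radial displacement `u_r` are computed about the
#' annulus center.
#'
#' @param run a [run_scenario()] result, or any list with `mesh`,
#'   `state`, `params` and `mode`.
#' @param point1,point2 segment end points (um, reference configuration).
#' @param n_samples number of sample points.
#' @return data frame with columns `s, x, y, r, sigma_rr, sigma_tt,
#'   von_mises, u_r, c, phi, dmg`.
#' @export
extract_path <- function(run, point1, point2, n_samples = 100) {
  mesh <- run$mesh
  state <- run$state
  stopifnot(mesh$dim == 2L)
  Sn <- recover_nodal_stress(mesh, state, run$params, run$mode)
  ux <- state$D[dof_ids(mesh, field = "ux")]
  uy <- state$D[dof_ids(mesh, field = "uy")]
  cn <- state$D[dof_ids(mesh, field = "c")]
  pn <- state$D[dof_ids(mesh, field = "phi")]
  dn <- state$D[dof_ids(mesh, field = "d")]
  ts <- seq(0, 1, length.out = n_samples)
  out <- vector("list", n_samples)
  ctr <- if (is.null(mesh$center)) c(0, 0) else mesh$center
  L <- sqrt(sum((point2 - point1)^2))
  found_any <- FALSE
  for (k in seq_len(n_samples)) {
    p <- point1 + ts[k] * (point2 - point1)
    loc <- locate_point(mesh, p)
    if (is.null(loc)) next
    found_any <- TRUE
    nd <- mesh$elems[loc$elem, ]
    N <- loc$N
    s6 <- as.numeric(t(Sn[nd, , drop = FALSE]) %*% N)
    rv <- p - ctr
    rr <- sqrt(sum(rv^2))
    er <- if (rr > 0) rv / rr else c(1, 0)
    et <- c(-er[2], er[1])
    S2 <- matrix(c(s6[1], s6[4], s6[4], s6[2]), 2, 2)
    out[[k]] <- data.frame(
      s = ts[k] * L, x = p[1], y = p[2], r = rr,
      sigma_rr = as.numeric(t(er) %*% S2 %*% er),
      sigma_tt = as.numeric(t(et) %*% S2 %*% et),
      von_mises = von_mises(s6),
      u_r = sum(c(sum(N * ux[nd]), sum(N * uy[nd])) * er),
      c = sum(N * cn[nd]), phi = sum(N * pn[nd]), dmg = sum(N * dn[nd]))
  }
  if (!found_any) stop("path segment does not intersect the mesh")
  do.call(rbind, out)
}

#' Write a path profile as CSV
#'
#' @param profile [extract_path()] output.
#' @param path file path.
#' @export
write_path_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

# number formatting shared by the VTK writer (deterministic round-trip)
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a state as a legacy ASCII VTK unstructured grid
#'
#' Point data: displacement vector `u`, scalars `c`, `phi`, `dmg`.
#' Cell data: mean Gauss stress components `sigma_*`, `von_mises` and the
#' growth scalar `alpha`. Output is byte-identical across reruns of the
#' same seeded simulation.
#'
#' @param state `artery_state`.
#' @param mesh `artery_mesh`.
#' @param path output file.
#' @param params,mode constitutive context for the stress evaluation;
#'   when `params` is `NULL` the stress cell data are omitted.
#' @export
write_vtk <- function(state, mesh, path, params = NULL, mode = "none") {
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  nn <- ncol(mesh$elems)
  pts <- cbind(mesh$nodes, matrix(0, n, 3 - mesh$dim))
  lines <- c("# vtk DataFile Version 3.0",
             sprintf("arterysim state step=%d time=%s", state$step,
                     fmt_num(state$time)),
             "ASCII", "DATASET UNSTRUCTURED_GRID",
             sprintf("POINTS %d double", n),
             apply(pts, 1, function(r) paste(fmt_num(r), collapse = " ")),
             sprintf("CELLS %d %d", ne, ne * (nn + 1)),
             apply(mesh$elems, 1, function(r)
               paste(c(nn, r - 1L), collapse = " ")),
             sprintf("CELL_TYPES %d", ne),
             rep(if (nn == 4) "9" else "12", ne))
  u <- cbind(state$D[dof_ids(mesh, field = "ux")],
             state$D[dof_ids(mesh, field = "uy")],
             if (mesh$dim == 3L) state$D[dof_ids(mesh, field = "uz")] else
               rep(0, n))
  scal <- function(name, v)
    c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default",
      fmt_num(v))
  lines <- c(lines, sprintf("POINT_DATA %d", n), "VECTORS u double",
             apply(u, 1, function(r) paste(fmt_num(r), collapse = " ")),
             scal("c", state$D[dof_ids(mesh, field = "c")]),
             scal("phi", state$D[dof_ids(mesh, field = "phi")]),
             scal("dmg", state$D[dof_ids(mesh, field = "d")]))
  if (!is.null(params)) {
    gs <- gauss_stress(mesh, state, params, mode)
    ngp <- if (mesh$dim == 2L) 4L else 8L
    idx <- rep(seq_len(ne), each = ngp)
    smean <- t(vapply(seq_len(ne), function(e)
      rowMeans(gs$sigma_gp[, idx == e, drop = FALSE]), numeric(6)))
    vm <- apply(smean, 1, von_mises)
    amean <- colMeans(matrix(state$alpha, nrow = ngp))
    lines <- c(lines, sprintf("CELL_DATA %d", ne),
               scal("sigma_xx", smean[, 1]), scal("sigma_yy", smean[, 2]),
               scal("sigma_zz", smean[, 3]), scal("sigma_xy", smean[, 4]),
               scal("sigma_yz", smean[, 5]), scal("sigma_xz", smean[, 6]),
               scal("von_mises", vm), scal("alpha", amean))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_vtk()]
#'
#' @param path VTK file.
#' @return list with `points`, `cells` (1-based), `point_data` and
#'   `cell_data` named lists.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  i <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[i], " ")[[1]][2])
  pts <- do.call(rbind, lapply(lines[(i + 1):(i + n)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  i <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[i], " ")[[1]][2])
  cells <- do.call(rbind, lapply(lines[(i + 1):(i + ne)], function(l)
    as.integer(strsplit(l, " ")[[1]])))
  cells <- cells[, -1, drop = FALSE] + 1L
  read_block <- function(start, count) {
    out <- list()
    j <- start
    while (j <= length(lines)) {
      l <- lines[j]
      if (grepl("^(POINT_DATA|CELL_DATA)", l)) break
      if (grepl("^VECTORS", l)) {
        nm <- strsplit(l, " ")[[1]][2]
        out[[nm]] <- do.call(rbind, lapply(lines[(j + 1):(j + count)],
                                           function(x)
                                             as.numeric(strsplit(x, " ")[[1]])))
        j <- j + count + 1
      } else if (grepl("^SCALARS", l)) {
        nm <- strsplit(l, " ")[[1]][2]
        out[[nm]] <- as.numeric(lines[(j + 2):(j + 1 + count)])
        j <- j + count + 2
      } else j <- j + 1
    }
    out
  }
  pd <- list(); cd <- list()
  ip <- grep("^POINT_DATA", lines)
  if (length(ip) > 0) pd <- read_block(ip[1] + 1, n)
  ic <- grep("^CELL_DATA", lines)
  if (length(ic) > 0) cd <- read_block(ic[1] + 1, ne)
  list(points = pts, cells = cells, point_data = pd, cell_data = cd)
}
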