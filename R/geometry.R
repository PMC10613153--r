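#' Geometry parameters of the annular artery section
#'
#' @param D inner (lumen) diameter (um).
#' @param t wall thickness (um).
#' @param h_coarse,h_fine target element sizes (um); the fine size is used
#'   inside the refined sector containing the VV tree.
#' @param refine_center_angle half-angle (rad) of the refined sector.
#' @param refine_arc_margin extra arclength margin (um) added to the
#'   refined sector on both sides.
#' @param axial_length axial extrusion length (um, 3D meshes only).
#' @param sector_halfangle half-angle (rad) of the computational sector;
#'   `pi/2` gives the default half annulus with symmetry faces on the
#'   horizontal axis, `pi` the full annulus.
#' @param theta_center angular position (rad) of the sector/VV-tree center.
#' @return list of class `geometry_params`.
#' @export
geometry_params <- function(D = 1200, t = 400, h_coarse = 20, h_fine = 2,
                            refine_center_angle = 0.3,
                            refine_arc_margin = 50, axial_length = 100,
                            sector_halfangle = pi / 2,
                            theta_center = pi / 2) {
  stopifnot(D > 0, t > 0, h_fine > 0, h_fine <= h_coarse,
            refine_center_angle >= 0, refine_arc_margin >= 0,
            sector_halfangle > 0, sector_halfangle <= pi)
  structure(list(D = D, t = t, h_coarse = h_coarse, h_fine = h_fine,
                 refine_center_angle = refine_center_angle,
                 refine_arc_margin = refine_arc_margin,
                 axial_length = axial_length,
                 sector_halfangle = sector_halfangle,
                 theta_center = theta_center),
            class = "geometry_params")
}

#' Parameters of the vasa vasorum tree fractal
#'
#' A binary tree fractal rooted on the outer wall: a trunk of length `L0`
#' pointing radially inward, then three branching generations with length
#' ratios `lambda` and sibling opening angles `gamma` (the two children of
#' a tip leave at `+gamma/2` and `-gamma/2` from the parent axis). Only
#' the branch angles are stochastic: each child angle is perturbed by a
#' uniform jitter in `[-angle_jitter, +angle_jitter]` drawn from a
#' generator seeded with `seed`.
#'
#' @param L0 trunk length (um).
#' @param lambda length ratios of generations 2-4.
#' @param gamma sibling branch angles of generations 2-4 (rad).
#' @param S occlusion arclength along the trunk, measured from its root on
#'   the outer wall (um).
#' @param angle_jitter jitter amplitude (rad).
#' @param seed integer seed of the tree generator.
#' @return list of class `vv_tree_params`.
#' @export
vv_tree_params <- function(L0 = 80, lambda = c(1, 1, 1),
                           gamma = c(2 * pi / 3, 2 * pi / 3, 2 * pi / 3),
                           S = 30, angle_jitter = pi / 36, seed = 42) {
  stopifnot(L0 > 0, length(lambda) == 3, all(lambda > 0),
            length(gamma) == 3, S >= 0, S <= L0, angle_jitter >= 0)
  structure(list(L0 = L0, lambda = lambda, gamma = gamma, S = S,
                 angle_jitter = angle_jitter, seed = as.integer(seed)),
            class = "vv_tree_params")
}

rot2 <- function(v, a) {
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

# first parameter s in (0, 1] at which the segment start + s*L*dir leaves
# the radial band [r_min, r_max]; 1 if it stays inside, 0 if it starts
# outside the band heading further out.
clip_param <- function(start, dir, len, r_min, r_max) {
  if (len <= 0) return(0)
  r0 <- sqrt(sum(start^2))
  s_hit <- 1
  for (rb in c(r_min, r_max)) {
    # |start + s len dir|^2 = rb^2  ->  quadratic in s
    a <- len^2
    b <- 2 * len * sum(start * dir)
    cc <- sum(start^2) - rb^2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) next
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    roots <- roots[roots > 1e-12 & roots <= 1]
    if (length(roots) == 0) next
    # only a genuine exit counts: just past the root we must be outside
    for (s in sort(roots)) {
      p <- start + (s + 1e-9) * len * dir
      r <- sqrt(sum(p^2))
      if (r < r_min - 1e-9 || r > r_max + 1e-9) {
        s_hit <- min(s_hit, s)
        break
      }
    }
  }
  if (r0 < r_min - 1e-9 || r0 > r_max + 1e-9) return(0)
  s_hit
}

#' Generate the stochastic vasa vasorum tree fractal
#'
#' @param params [vv_tree_params()].
#' @param root root point on the outer wall (length-2, um). If `geom` is
#'   given and `root` is `NULL`, the root is placed on the outer wall at
#'   `geom$theta_center`.
#' @param direction unit growth direction of the trunk; defaults to
#'   radially inward.
#' @param geom optional [geometry_params()]; when supplied the root is
#'   validated to lie on the outer wall and all segments are clipped to
#'   the outer half of the wall (the tree permeates at most to mid-wall
#'   depth).
#' @return data frame of class `vv_tree` with columns
#'   `x1, y1, x2, y2, level, parent, occluded` (root segment first,
#'   parent index 0).
#' @export
generate_vv_tree <- function(params, root = NULL, direction = NULL,
                             geom = NULL) {
  clip <- NULL
  if (!is.null(geom)) {
    r_out <- geom$D / 2 + geom$t
    r_mid <- geom$D / 2 + geom$t / 2
    if (is.null(root))
      root <- r_out * c(cos(geom$theta_center), sin(geom$theta_center))
    if (abs(sqrt(sum(root^2)) - r_out) > 1e-6 * r_out)
      stop("geometry error: VV root does not lie on the outer wall")
    if (is.null(direction)) direction <- -root / sqrt(sum(root^2))
    if (sum(direction * root) >= 0)
      stop("geometry error: VV trunk direction must point radially inward")
    clip <- c(r_mid, r_out)
  } else {
    if (is.null(root)) root <- c(0, 0)
    if (is.null(direction)) direction <- c(0, -1)
  }
  direction <- direction / sqrt(sum(direction^2))

  segs <- list()
  build <- function(start, dir, len, level, parent) {
    s <- if (is.null(clip)) 1 else clip_param(start, dir, len, clip[1], clip[2])
    end <- start + s * len * dir
    segs[[length(segs) + 1]] <<- c(start, end, level, parent)
    idx <- length(segs)
    if (level < 4) {
      k <- level + 1
      g <- params$gamma[k - 1]
      ln <- params$lambda[k - 1] * len
      for (sgn in c(1, -1)) {
        jit <- if (params$angle_jitter > 0)
          runif(1, -params$angle_jitter, params$angle_jitter) else 0
        build(end, rot2(dir, sgn * g / 2 + jit), ln, k, idx)
      }
    }
  }
  withr::with_seed(params$seed, build(root, direction, params$L0, 1L, 0L))

  m <- do.call(rbind, segs)
  tree <- data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4],
                     level = as.integer(m[, 5]), parent = as.integer(m[, 6]),
                     occluded = FALSE)
  class(tree) <- c("vv_tree", "data.frame")
  attr(tree, "params") <- params
  tree
}

seg_length <- function(tree, i) {
  sqrt((tree$x2[i] - tree$x1[i])^2 + (tree$y2[i] - tree$y1[i])^2)
}

descendants_of <- function(tree, idx) {
  out <- integer(0)
  frontier <- idx
  while (length(frontier) > 0) {
    kids <- which(tree$parent %in% frontier)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Apply the initial occlusion to a VV tree
#'
#' The trunk is split at arclength `S` from its root on the outer wall;
#' the distal part and all its descendants are flagged occluded, so they
#' no longer deliver nutrients to the wall.
#'
#' @param tree [generate_vv_tree()] output.
#' @param S occlusion arclength along the trunk (um).
#' @return the tree with the `occluded` flags set (and the trunk split in
#'   two segments when `0 < S < trunk length`).
#' @export
apply_occlusion <- function(tree, S) {
  trunk <- which(tree$level == 1L & tree$parent == 0L)
  stopifnot(length(trunk) == 1)
  L <- seg_length(tree, trunk)
  if (S < 0 || S > L + 1e-9)
    stop("parameter error: occlusion arclength S outside the trunk")
  if (S <= 1e-12) {
    tree$occluded <- TRUE
  } else if (S >= L - 1e-12) {
    tree$occluded[descendants_of(tree, trunk)] <- TRUE
  } else {
    u <- c(tree$x2[trunk] - tree$x1[trunk], tree$y2[trunk] - tree$y1[trunk]) / L
    mid <- c(tree$x1[trunk], tree$y1[trunk]) + S * u
    distal <- tree[trunk, ]
    distal$x1 <- mid[1]; distal$y1 <- mid[2]
    distal$parent <- trunk
    tree$x2[trunk] <- mid[1]; tree$y2[trunk] <- mid[2]
    tree <- rbind(tree, distal)
    n <- nrow(tree)
    kids <- which(tree$parent == trunk & seq_len(n) != n & tree$level > 1L)
    tree$parent[kids] <- n
    tree$occluded[c(n, descendants_of(tree, n))] <- TRUE
    class(tree) <- c("vv_tree", "data.frame")
  }
  attr(tree, "occlusion_S") <- S
  tree
}

#' Location of the occlusion point on the trunk
#'
#' @param tree occluded VV tree.
#' @return length-2 coordinates (um) of the point at arclength `S` along
#'   the trunk, used to center the damage nucleus in the dissection
#'   scenario.
#' @export
occlusion_point <- function(tree) {
  S <- attr(tree, "occlusion_S")
  if (is.null(S)) stop("tree carries no occlusion")
  trunk <- which(tree$level == 1L & tree$parent == 0L)
  L <- seg_length(tree, trunk)
  u <- c(tree$x2[trunk] - tree$x1[trunk], tree$y2[trunk] - tree$y1[trunk]) /
    max(L, .Machine$double.eps)
  c(tree$x1[trunk], tree$y1[trunk]) + min(S, L) * u
}

#' Structured annulus mesh with local angular refinement
#'
#' Builds a structured quad4 mesh of the annular sector (inner radius
#' `D/2`, outer radius `D/2 + t`). The radial spacing follows `h_fine`;
#' the angular spacing is `h_fine` (at mid-wall radius) inside the refined
#' sector around `theta_center` and `h_coarse` outside. For `dim = 3` the
#' section is extruded along the axis into hex8 elements.
#'
#' @param geom [geometry_params()].
#' @param dim 2 or 3.
#' @return list of class `artery_mesh` with `nodes` (n x dim, um),
#'   `elems` (nelem x 4 or 8, 1-based), `sets` (node index vectors
#'   `lumen`, `outer`, `symmetry`, `vv_supply`), `lumen_facets`
#'   (counter-clockwise facet node matrix) and geometry metadata.
#' @export
build_annulus_mesh <- function(geom, dim = 2) {
  stopifnot(inherits(geom, "geometry_params"), dim %in% c(2, 3))
  r_in <- geom$D / 2
  r_out <- r_in + geom$t
  if (geom$h_fine > geom$t)
    stop("meshing error: h_fine exceeds the wall thickness")
  r_mid <- (r_in + r_out) / 2
  full <- abs(geom$sector_halfangle - pi) < 1e-12

  n_r <- max(1L, as.integer(ceiling(geom$t / geom$h_fine)))
  r_breaks <- seq(r_in, r_out, length.out = n_r + 1)

  th_c <- geom$theta_center
  th_lo <- th_c - geom$sector_halfangle
  th_hi <- th_c + geom$sector_halfangle
  band <- geom$refine_center_angle + geom$refine_arc_margin / r_mid
  dth_f <- geom$h_fine / r_mid
  dth_c <- geom$h_coarse / r_mid
  seg_breaks <- function(a, b, dth) {
    if (b - a < 1e-12) return(numeric(0))
    n <- max(1L, as.integer(ceiling((b - a) / dth)))
    seq(a, b, length.out = n + 1)
  }
  if (band >= geom$sector_halfangle - 1e-12) {
    th_breaks <- seg_breaks(th_lo, th_hi, dth_f)
  } else {
    th_breaks <- sort(unique(c(
      seg_breaks(th_lo, th_c - band, dth_c),
      seg_breaks(th_c - band, th_c + band, dth_f),
      seg_breaks(th_c + band, th_hi, dth_c))))
  }
  n_th <- length(th_breaks) - 1L
  if (full) th_breaks <- th_breaks[-length(th_breaks)]  # wrap seam
  n_th_nodes <- length(th_breaks)

  nid <- function(ir, jt) ir * n_th_nodes + jt + 1L  # ir 0..n_r, jt 0-based
  nodes2 <- matrix(0, (n_r + 1) * n_th_nodes, 2)
  for (ir in 0:n_r)
    for (jt in seq_len(n_th_nodes) - 1L)
      nodes2[nid(ir, jt), ] <- r_breaks[ir + 1] *
        c(cos(th_breaks[jt + 1]), sin(th_breaks[jt + 1]))

  jnext <- function(jt) if (full) (jt + 1L) %% n_th_nodes else jt + 1L
  elems2 <- matrix(0L, n_r * n_th, 4)
  k <- 0L
  for (ir in seq_len(n_r) - 1L)
    for (jt in seq_len(n_th) - 1L) {
      k <- k + 1L
      elems2[k, ] <- c(nid(ir, jt), nid(ir + 1, jt),
                       nid(ir + 1, jnext(jt)), nid(ir, jnext(jt)))
    }

  lumen <- sapply(seq_len(n_th_nodes) - 1L, function(j) nid(0L, j))
  outer <- sapply(seq_len(n_th_nodes) - 1L, function(j) nid(n_r, j))
  symmetry <- if (full) integer(0) else
    c(sapply(0:n_r, nid, jt = 0L), sapply(0:n_r, nid, jt = n_th_nodes - 1L))
  facets2 <- cbind(lumen[seq_len(n_th)],
                   lumen[vapply(seq_len(n_th) - 1L, function(j) jnext(j) + 1L,
                                integer(1))])

  mesh <- list(nodes = nodes2, elems = elems2,
               sets = list(lumen = as.integer(lumen),
                           outer = as.integer(outer),
                           symmetry = as.integer(symmetry),
                           vv_supply = integer(0)),
               lumen_facets = facets2, dim = 2L,
               r_in = r_in, r_out = r_out, center = c(0, 0), geom = geom)
  class(mesh) <- "artery_mesh"

  if (dim == 3) {
    dz <- geom$h_coarse
    n_z <- max(1L, as.integer(round(geom$axial_length / dz)))
    zb <- seq(0, geom$axial_length, length.out = n_z + 1)
    n2 <- nrow(nodes2)
    nodes3 <- do.call(rbind, lapply(zb, function(z) cbind(nodes2, z)))
    elems3 <- do.call(rbind, lapply(seq_len(n_z) - 1L, function(kz) {
      off <- kz * n2
      cbind(elems2 + off, elems2 + off + n2)
    }))
    facets3 <- do.call(rbind, lapply(seq_len(n_z) - 1L, function(kz) {
      off <- kz * n2
      cbind(facets2[, 1] + off, facets2[, 2] + off,
            facets2[, 2] + off + n2, facets2[, 1] + off + n2)
    }))
    lift <- function(s) as.integer(outer(s, (0:n_z) * n2, `+`))
    mesh$nodes <- nodes3
    mesh$elems <- elems3
    mesh$lumen_facets <- facets3
    mesh$sets <- list(lumen = lift(lumen), outer = lift(outer),
                      symmetry = lift(symmetry), vv_supply = integer(0),
                      z_lo = as.integer(seq_len(n2)),
                      z_hi = as.integer(seq_len(n2) + n_z * n2))
    mesh$dim <- 3L
  }
  mesh
}

#' Structured rectangle mesh (test fixture)
#'
#' @param nx,ny element counts.
#' @param Lx,Ly side lengths (um).
#' @param x0,y0 origin.
#' @return `artery_mesh` with boundary sets `left`, `right`, `bottom`,
#'   `top`.
#' @export
mesh_rectangle <- function(nx, ny, Lx = 1, Ly = 1, x0 = 0, y0 = 0) {
  xb <- seq(x0, x0 + Lx, length.out = nx + 1)
  yb <- seq(y0, y0 + Ly, length.out = ny + 1)
  nid <- function(i, j) j * (nx + 1L) + i + 1L
  nodes <- as.matrix(expand.grid(x = xb, y = yb))
  dimnames(nodes) <- NULL
  elems <- matrix(0L, nx * ny, 4)
  k <- 0L
  for (j in seq_len(ny) - 1L)
    for (i in seq_len(nx) - 1L) {
      k <- k + 1L
      elems[k, ] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L),
                      nid(i, j + 1L))
    }
  allid <- seq_len(nrow(nodes))
  mesh <- list(nodes = nodes, elems = elems,
               sets = list(left = allid[abs(nodes[, 1] - x0) < 1e-12],
                           right = allid[abs(nodes[, 1] - x0 - Lx) < 1e-12],
                           bottom = allid[abs(nodes[, 2] - y0) < 1e-12],
                           top = allid[abs(nodes[, 2] - y0 - Ly) < 1e-12],
                           vv_supply = integer(0)),
               lumen_facets = NULL, dim = 2L, center = c(x0, y0))
  class(mesh) <- "artery_mesh"
  mesh
}

point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  if (L2 < .Machine$double.eps) return(sqrt((px - x1)^2 + (py - y1)^2))
  s <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
  sqrt((px - x1 - s * vx)^2 + (py - y1 - s * vy)^2)
}

#' Mark mesh nodes supplied by the (unoccluded) VV network
#'
#' Returns the nodes lying within `tol` of any non-occluded tree segment;
#' these receive the maximum nutrient concentration as a Dirichlet
#' condition. The result is also stored in `mesh$sets$vv_supply`.
#'
#' @param mesh [build_annulus_mesh()] output.
#' @param tree occluded [generate_vv_tree()] output.
#' @param tol capture distance (um); defaults to the fine element size.
#' @return the mesh with the `vv_supply` node set populated.
#' @export
mark_vv_supply_nodes <- function(mesh, tree, tol = NULL) {
  if (is.null(tol)) tol <- mesh$geom$h_fine
  live <- which(!tree$occluded &
                  (tree$x1 != tree$x2 | tree$y1 != tree$y2))
  hit <- rep(FALSE, nrow(mesh$nodes))
  for (i in live) {
    d <- point_segment_distance(mesh$nodes[, 1], mesh$nodes[, 2],
                                tree$x1[i], tree$y1[i],
                                tree$x2[i], tree$y2[i])
    hit <- hit | (d <= tol + 1e-12)
  }
  mesh$sets$vv_supply <- which(hit)
  mesh
}

#' Deterministic miniature mesh/tree fixtures
#'
#' @param level `"unit"` (one element), `"tiny"` (~10^2 elements) or
#'   `"small"` (~10^3 elements). All fixtures use the full-scale coronary
#'   geometry with coarsened element sizes so that nutrient gradients and
#'   wall curvature are representative.
#' @return list with `mesh` (VV-supply nodes marked), `tree` (occlusion
#'   applied) and `geom`.
#' @export
make_fixture <- function(level = c("tiny", "unit", "small")) {
  level <- match.arg(level)
  if (level == "unit") {
    mesh <- mesh_rectangle(1, 1, 1, 1)
    tp <- vv_tree_params(L0 = 1, S = 0.5, angle_jitter = 0, seed = 1L)
    tree <- apply_occlusion(
      generate_vv_tree(tp, root = c(0.5, 1), direction = c(0, -1)), 0.5)
    return(list(mesh = mesh, tree = tree, geom = NULL))
  }
  h <- if (level == "tiny") c(80, 40) else c(60, 20)
  geom <- geometry_params(h_coarse = h[1], h_fine = h[2],
                          refine_center_angle = 0.3, refine_arc_margin = 50)
  mesh <- build_annulus_mesh(geom, dim = 2)
  tp <- vv_tree_params()
  tree <- apply_occlusion(generate_vv_tree(tp, geom = geom), tp$S)
  mesh <- mark_vv_supply_nodes(mesh, tree, tol = geom$h_fine)
  list(mesh = mesh, tree = tree, geom = geom)
}

#' @export
print.artery_mesh <- function(x, ...) {
  cat(sprintf("artery_mesh: %d nodes, %d %s elements (%dD)\n",
              nrow(x$nodes), nrow(x$elems),
              if (x$dim == 2) "quad4" else "hex8", x$dim))
  for (s in names(x$sets))
    cat(sprintf("  set %-10s %d nodes\n", s, length(x$sets[[s]])))
  invisible(x)
}

# plain-text serialization ---------------------------------------------------

#' Write / read a VV tree as a plain-text segment list
#'
#' Columns: `x1 y1 x2 y2 level parent occluded`.
#' @param tree VV tree data frame.
#' @param path file path.
#' @export
write_vv_tree <- function(tree, path) {
  rows <- vapply(seq_len(nrow(tree)), function(i)
    paste(c(sprintf("%.17g", c(tree$x1[i], tree$y1[i], tree$x2[i],
                               tree$y2[i])),
            sprintf("%d", c(tree$level[i], tree$parent[i],
                            as.integer(tree$occluded[i])))),
          collapse = " "), character(1))
  writeLines(c("# vv_tree: x1 y1 x2 y2 level parent occluded", rows), path)
  invisible(path)
}

#' @rdname write_vv_tree
#' @export
read_vv_tree <- function(path) {
  m <- utils::read.table(path, comment.char = "#",
                         col.names = c("x1", "y1", "x2", "y2", "level",
                                       "parent", "occluded"))
  m$level <- as.integer(m$level)
  m$parent <- as.integer(m$parent)
  m$occluded <- as.logical(m$occluded)
  class(m) <- c("vv_tree", "data.frame")
  m
}

#' Write / read a mesh in a minimal plain-text format
#'
#' Nodes, element connectivity and named node sets; used for small test
#' fixtures ([write_vtk()] handles simulation output).
#' @param mesh `artery_mesh`.
#' @param path file path.
#' @export
write_mesh_txt <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("mesh %d %d %d", mesh$dim, nrow(mesh$nodes),
                     nrow(mesh$elems)), con)
  writeLines(apply(mesh$nodes, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(apply(mesh$elems, 1, paste, collapse = " "), con)
  nf <- if (is.null(mesh$lumen_facets)) 0L else nrow(mesh$lumen_facets)
  writeLines(sprintf("facets %d", nf), con)
  if (nf > 0)
    writeLines(apply(mesh$lumen_facets, 1, paste, collapse = " "), con)
  writeLines(sprintf("sets %d", length(mesh$sets)), con)
  for (s in names(mesh$sets)) {
    writeLines(sprintf("set %s %d", s, length(mesh$sets[[s]])), con)
    if (length(mesh$sets[[s]]) > 0)
      writeLines(paste(mesh$sets[[s]], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_mesh_txt
#' @export
read_mesh_txt <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]][-1])
  dim <- hdr[1]; nn <- hdr[2]; ne <- hdr[3]
  at <- 2
  nodes <- do.call(rbind, lapply(lines[at:(at + nn - 1)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  at <- at + nn
  elems <- do.call(rbind, lapply(lines[at:(at + ne - 1)], function(l)
    as.integer(strsplit(l, " ")[[1]])))
  at <- at + ne
  nf <- as.integer(strsplit(lines[at], " ")[[1]][2]); at <- at + 1
  facets <- NULL
  if (nf > 0) {
    facets <- do.call(rbind, lapply(lines[at:(at + nf - 1)], function(l)
      as.integer(strsplit(l, " ")[[1]])))
    at <- at + nf
  }
  ns <- as.integer(strsplit(lines[at], " ")[[1]][2]); at <- at + 1
  sets <- list()
  for (i in seq_len(ns)) {
    h <- strsplit(lines[at], " ")[[1]]; at <- at + 1
    cnt <- as.integer(h[3])
    idx <- integer(0)
    if (cnt > 0) {
      idx <- as.integer(strsplit(lines[at], " ")[[1]])
      at <- at + 1
    }
    sets[[h[2]]] <- idx
  }
  mesh <- list(nodes = nodes, elems = elems, sets = sets,
               lumen_facets = facets, dim = dim, center = c(0, 0))
  class(mesh) <- "artery_mesh"
  mesh
}
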