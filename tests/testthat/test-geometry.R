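test_that("tree fractal recursion produces the expected segment counts and lengths", {
  tp <- vv_tree_params(angle_jitter = 0)
  tr <- generate_vv_tree(tp)
  expect_equal(nrow(tr), 15)  # 1 + 2 + 4 + 8
  len <- sqrt((tr$x2 - tr$x1)^2 + (tr$y2 - tr$y1)^2)
  expect_equal(len, rep(80, 15), tolerance = 1e-12)
  expect_equal(sort(unique(tr$level)), 1:4)
  expect_equal(sum(tr$level == 4L), 8)
})

test_that("seeded tree generation is deterministic and jitter-free trees are mirror symmetric", {
  tp <- vv_tree_params(seed = 7, angle_jitter = pi / 36)
  t1 <- generate_vv_tree(tp)
  t2 <- generate_vv_tree(tp)
  expect_identical(t1, t2)
  t3 <- generate_vv_tree(vv_tree_params(seed = 8, angle_jitter = pi / 36))
  expect_false(isTRUE(all.equal(t1$x2, t3$x2)))

  # mirror about the trunk axis (x = 0 for a trunk rooted at (0, 800)
  # pointing straight down)
  t0 <- generate_vv_tree(vv_tree_params(angle_jitter = 0),
                         root = c(0, 800), direction = c(0, -1))
  key <- function(x1, y1, x2, y2)
    sort(paste(round(x1, 6), round(y1, 6), round(x2, 6), round(y2, 6)))
  expect_equal(key(t0$x1, t0$y1, t0$x2, t0$y2),
               key(-t0$x1, t0$y1, -t0$x2, t0$y2))
})

test_that("tree is clipped to the outer half of the wall and validates its root", {
  geom <- geometry_params(h_coarse = 80, h_fine = 40)
  tr <- generate_vv_tree(vv_tree_params(angle_jitter = 0), geom = geom)
  r <- sqrt(c(tr$x1, tr$x2)^2 + c(tr$y1, tr$y2)^2)
  r_mid <- geom$D / 2 + geom$t / 2
  r_out <- geom$D / 2 + geom$t
  expect_true(all(r >= r_mid - 1e-6 & r <= r_out + 1e-6))
  expect_error(generate_vv_tree(vv_tree_params(), root = c(0, 500),
                                direction = c(0, -1), geom = geom),
               "outer wall")
})

test_that("occlusion splits the trunk and closes over descendants", {
  tp <- vv_tree_params(angle_jitter = 0)
  tr <- generate_vv_tree(tp)

  t0 <- apply_occlusion(tr, 0)
  expect_true(all(t0$occluded))

  t80 <- apply_occlusion(tr, 80)  # occlusion at the trunk tip
  expect_false(t80$occluded[1])
  expect_equal(sum(t80$occluded), 14)

  t30 <- apply_occlusion(tr, 30)
  trunk <- which(t30$level == 1L & t30$parent == 0L)
  expect_equal(arterysim:::seg_length(t30, trunk[1]), 30)
  expect_false(t30$occluded[trunk[1]])
  expect_equal(sum(!t30$occluded), 1)

  expect_error(apply_occlusion(tr, 81), "outside the trunk")

  # closure: descendants of occluded segments are occluded
  tj <- apply_occlusion(generate_vv_tree(vv_tree_params(seed = 3)), 30)
  occ <- which(tj$occluded)
  for (i in occ) {
    kids <- which(tj$parent == i)
    expect_true(all(tj$occluded[kids]))
  }
  expect_equal(unname(occlusion_point(t30)),
               c(tr$x1[1], tr$y1[1]) + 30 * c(tr$x2[1] - tr$x1[1],
                                              tr$y2[1] - tr$y1[1]) / 80)
})

test_that("annulus mesh has the printed radii, valid Jacobians and populated sets", {
  geom <- geometry_params(h_coarse = 80, h_fine = 40)
  mesh <- build_annulus_mesh(geom)
  r <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  expect_equal(min(r), 600, tolerance = 1e-9)    # inner radius D/2
  expect_equal(max(r), 1000, tolerance = 1e-9)   # outer radius D/2 + t
  expect_true(all(abs(r[mesh$sets$lumen] - 600) < geom$h_fine))
  expect_true(all(abs(r[mesh$sets$outer] - 1000) < 1e-9))
  expect_gt(length(mesh$sets$symmetry), 0)

  # positive Jacobian at every Gauss point of every element
  sq <- shape_quadrature("quad4")
  for (e in seq_len(nrow(mesh$elems))) {
    X <- t(mesh$nodes[mesh$elems[e, ], ])
    for (q in 1:4)
      expect_gt(det(X %*% sq$dN[[q]]), 0)
  }
  expect_error(build_annulus_mesh(geometry_params(h_fine = 500,
                                                  h_coarse = 500)),
               "meshing error")
})

test_that("uniform target size is met within a factor two", {
  geom <- geometry_params(h_coarse = 40, h_fine = 40,
                          refine_center_angle = 0)
  mesh <- build_annulus_mesh(geom)
  sq <- shape_quadrature("quad4")
  for (e in seq_len(nrow(mesh$elems))) {
    X <- t(mesh$nodes[mesh$elems[e, ], ])
    area <- sum(vapply(1:4, function(q) det(X %*% sq$dN[[q]]), numeric(1)))
    size <- sqrt(area)
    expect_gt(size, 40 / 2)
    expect_lt(size, 40 * 2)
  }
})

test_that("halving the fine size quadruples the refined-sector element count", {
  count_refined <- function(h_fine) {
    geom <- geometry_params(h_coarse = 80, h_fine = h_fine,
                            refine_center_angle = 0.3,
                            refine_arc_margin = 50)
    mesh <- build_annulus_mesh(geom)
    band <- geom$refine_center_angle + geom$refine_arc_margin / 800
    cx <- vapply(seq_len(nrow(mesh$elems)), function(e)
      mean(mesh$nodes[mesh$elems[e, ], 1]), numeric(1))
    cy <- vapply(seq_len(nrow(mesh$elems)), function(e)
      mean(mesh$nodes[mesh$elems[e, ], 2]), numeric(1))
    sum(abs(atan2(cy, cx) - pi / 2) < band)
  }
  ratio <- count_refined(20) / count_refined(40)
  expect_gte(ratio, 3.5)
  expect_lte(ratio, 4.5)
})

test_that("VV supply marking matches brute-force point-to-segment distances", {
  fx <- make_fixture("tiny")
  mesh <- fx$mesh
  tree <- fx$tree
  tol <- fx$geom$h_fine
  live <- which(!tree$occluded)
  expect_equal(length(live), 1)  # only the proximal 30 um of the trunk
  brute <- which(vapply(seq_len(nrow(mesh$nodes)), function(i) {
    any(vapply(live, function(s) arterysim:::point_segment_distance(
      mesh$nodes[i, 1], mesh$nodes[i, 2], tree$x1[s], tree$y1[s],
      tree$x2[s], tree$y2[s]) <= tol + 1e-12, logical(1)))
  }, logical(1)))
  expect_equal(mesh$sets$vv_supply, brute)
  expect_gt(length(brute), 0)

  # fully occluded tree -> empty supply set
  m2 <- mark_vv_supply_nodes(mesh, apply_occlusion(fx$tree, 0), tol)
  expect_length(m2$sets$vv_supply, 0)

  # tol = 0 captures only nodes exactly on a segment
  mr <- mesh_rectangle(2, 2, 1, 1)
  tr <- data.frame(x1 = 0.5, y1 = 0, x2 = 0.5, y2 = 1, level = 1L,
                   parent = 0L, occluded = FALSE)
  mr$geom <- list(h_fine = 0.5)
  m0 <- mark_vv_supply_nodes(mr, tr, tol = 0)
  expect_equal(sort(mr$nodes[m0$sets$vv_supply, 1]), rep(0.5, 3))
})

test_that("fixtures are deterministic with non-empty boundary sets", {
  u <- make_fixture("unit")
  expect_equal(nrow(u$mesh$elems), 1)
  expect_equal(nrow(u$mesh$nodes), 4)
  t1 <- make_fixture("tiny")
  t2 <- make_fixture("tiny")
  expect_identical(t1$mesh$nodes, t2$mesh$nodes)
  expect_identical(t1$tree, t2$tree)
  s <- make_fixture("small")
  expect_gt(nrow(s$mesh$elems), 800)
  for (nm in c("lumen", "outer", "symmetry", "vv_supply"))
    expect_gt(length(s$mesh$sets[[nm]]), 0)
})

test_that("tree and mesh plain-text round trips preserve the data", {
  fx <- make_fixture("tiny")
  tf <- tempfile(fileext = ".txt")
  write_vv_tree(fx$tree, tf)
  tr2 <- read_vv_tree(tf)
  expect_equal(tr2$x2, fx$tree$x2, tolerance = 1e-14)
  expect_equal(tr2$occluded, fx$tree$occluded)
  expect_equal(tr2$parent, fx$tree$parent)

  mf <- tempfile(fileext = ".txt")
  write_mesh_txt(fx$mesh, mf)
  m2 <- read_mesh_txt(mf)
  expect_equal(m2$nodes, fx$mesh$nodes, tolerance = 1e-14)
  expect_equal(m2$elems, fx$mesh$elems)
  expect_equal(m2$sets$lumen, fx$mesh$sets$lumen)
  expect_equal(m2$sets$vv_supply, fx$mesh$sets$vv_supply)
})

test_that("3D extrusion produces hex elements with consistent sets", {
  geom <- geometry_params(h_coarse = 100, h_fine = 100, axial_length = 200,
                          refine_center_angle = 0)
  mesh <- build_annulus_mesh(geom, dim = 3)
  expect_equal(ncol(mesh$elems), 8)
  expect_equal(mesh$dim, 3L)
  expect_equal(ncol(mesh$lumen_facets), 4)
  sq <- shape_quadrature("hex8")
  for (e in seq_len(min(nrow(mesh$elems), 50))) {
    X <- t(mesh$nodes[mesh$elems[e, ], ])
    for (q in c(1, 8))
      expect_gt(det(X %*% sq$dN[[q]]), 0)
  }
  expect_gt(length(mesh$sets$z_lo), 0)
})
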