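mp <- material_params()

test_that("kinematics reproduces identity, inversion and pure-growth states", {
  k0 <- kinematics(matrix(0, 3, 3), 0)
  expect_equal(k0$F, diag(3))
  expect_equal(k0$F_e, diag(3))
  expect_equal(k0$J_e, 1)
  expect_equal(k0$I1_iso, 3)

  k1 <- kinematics(diag(c(0.5, 0, 0)), 0)
  expect_equal(k1$F, diag(c(2, 1, 1)), tolerance = 1e-14)

  k2 <- kinematics(matrix(0, 3, 3), 0.1)
  expect_equal(k2$F_e, diag(3) / 1.1, tolerance = 1e-14)
  expect_equal(k2$J_e, 1.1^-3, tolerance = 1e-12)
  expect_equal(det(k2$C_e_iso), 1, tolerance = 1e-10)

  expect_error(kinematics(diag(c(2, 0, 0)), 0), "degenerate")
})

test_that("growth update solves the scalar residual in closed form", {
  expect_equal(update_alpha(0.3, 0.2, 0.2, 10)$alpha, 0.3)
  up <- update_alpha(0, 0, 0.01, 10)
  expect_equal(up$alpha, 0.1 / 0.9, tolerance = 1e-14)
  expect_error(update_alpha(0, 0, 0.2, 10), "k_g\\*dphi >= 1")

  # residual check: the returned root satisfies R_alpha = 0
  a <- update_alpha(0.15, 0.3, 0.37, 10)$alpha
  expect_equal((a - 0.15) / (1 + a) - 10 * 0.07, 0, tolerance = 1e-12)

  # sensitivity matches finite differences
  h <- 1e-7
  num <- (update_alpha(0.15, 0.3, 0.37 + h, 10)$alpha -
            update_alpha(0.15, 0.3, 0.37 - h, 10)$alpha) / (2 * h)
  expect_equal(update_alpha(0.15, 0.3, 0.37, 10)$dalpha_dphi, num,
               tolerance = 1e-6)
})

test_that("sub-stepped growth converges first order to exp(k_g phi)", {
  integrate_alpha <- function(k_g, n) {
    a <- 0
    for (i in seq_len(n)) a <- update_alpha(a, (i - 1) / n, i / n, k_g)$alpha
    a
  }
  # k_g = 1: 0.05% error at 1000 sub-steps (well within 1%)
  expect_equal(1 + integrate_alpha(1, 1000), exp(1), tolerance = 1e-2)
  # k_g = 10: the implicit update overshoots by ~ k_g^2 / (2 n)
  e1 <- abs(log(1 + integrate_alpha(10, 1000)) - 10)
  e4 <- abs(log(1 + integrate_alpha(10, 4000)) - 10)
  expect_equal(e1, 10^2 / (2 * 1000), tolerance = 0.01)
  expect_gt(e1 / e4, 3)   # first order in the sub-step
  expect_lt(e1 / e4, 5)
})

test_that("degradation, barrier, indicator and diffusivity evaluate the printed formulas", {
  expect_equal(degradation_g(0), 1)
  expect_equal(degradation_g(1, 1e-4), 1e-4)
  expect_equal(degradation_g(0.5, 1e-4), 0.25005)
  d <- seq(0, 1, by = 0.05)
  expect_true(all(diff(degradation_g(d)) < 0))

  expect_equal(tension_indicator(0.9), 1L)
  expect_equal(tension_indicator(1.0), 1L)
  expect_equal(tension_indicator(1.1), 0L)

  expect_equal(barrier_f(0, 3)$f, 0)
  expect_equal(barrier_f(1, 3)$f, 0)
  expect_equal(barrier_f(0.5, 3)$f, 3)       # f(1/2) = M
  expect_equal(barrier_f(0.5, 3)$dfdphi, 0)
  h <- 1e-6
  expect_equal(barrier_f(0.3, 2)$dfdphi,
               (barrier_f(0.3 + h, 2)$f - barrier_f(0.3 - h, 2)$f) / (2 * h),
               tolerance = 1e-6)

  expect_equal(diffusivity(0), 1e3)
  expect_equal(diffusivity(1), 1)
  expect_equal(diffusivity(0.5), (1e3 + 1) / 2)
})

test_that("stress vanishes in the reference state and under stress-free growth", {
  se <- energy_and_stress(kinematics(matrix(0, 3, 3), 0), 0.7, mp)
  expect_equal(se$psi_iso, 0, tolerance = 1e-14)
  expect_equal(se$psi_vol, 0, tolerance = 1e-14)
  expect_equal(max(abs(se$sigma)), 0, tolerance = 1e-12)

  # total deformation free to follow growth: F = F_g, sigma = 0
  for (a in c(0.05, 0.4, 2)) {
    gu <- diag(3) * (1 - 1 / (1 + a))  # grad_u such that F = (1+a) I
    se <- energy_and_stress(kinematics(gu, a), 0.3, mp)
    expect_equal(max(abs(se$sigma)), 0, tolerance = 1e-10)
  }
})

test_that("Cauchy stress matches finite differences of the degraded energy", {
  Fes <- random_Fe(50)
  ds <- withr::with_seed(12, runif(50))
  worst <- 0
  for (i in seq_along(Fes)) {
    Fe <- Fes[[i]]
    se <- cpp_energy_stress(Fe, ds[i], mp[["mu"]], mp[["nu"]], mp[["d_min"]])
    P <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3) {
      h <- 1e-6 * max(1, abs(Fe[r, cc]))
      Fp <- Fe; Fp[r, cc] <- Fe[r, cc] + h
      Fm <- Fe; Fm[r, cc] <- Fe[r, cc] - h
      P[r, cc] <- (cpp_energy_stress(Fp, ds[i], mp[["mu"]], mp[["nu"]],
                                     mp[["d_min"]])$psi_deg -
                     cpp_energy_stress(Fm, ds[i], mp[["mu"]], mp[["nu"]],
                                       mp[["d_min"]])$psi_deg) / (2 * h)
    }
    sig_fd <- P %*% t(Fe) / det(Fe)
    sig_fd <- (sig_fd + t(sig_fd)) / 2
    worst <- max(worst, max(abs(se$sigma - sig_fd)) / max(abs(se$sigma)))
  }
  expect_lt(worst, 1e-6)
})

test_that("energy is objective and the isochoric part volume-invariant", {
  Fe <- random_Fe(1, seed = 4)[[1]]
  base <- cpp_energy_stress(Fe, 0.4, mp[["mu"]], mp[["nu"]], mp[["d_min"]])
  Qs <- withr::with_seed(5, lapply(1:20, function(i)
    qr.Q(qr(matrix(rnorm(9), 3, 3)))))
  for (Q in Qs) {
    if (det(Q) < 0) Q <- -Q
    rot <- cpp_energy_stress(Q %*% Fe, 0.4, mp[["mu"]], mp[["nu"]],
                             mp[["d_min"]])
    expect_equal(rot$psi_deg, base$psi_deg, tolerance = 1e-10)
    expect_equal(rot$psi_iso, base$psi_iso, tolerance = 1e-10)
  }
  for (s in c(0.7, 1.3, 2)) {
    scl <- cpp_energy_stress(s * Fe, 0.4, mp[["mu"]], mp[["nu"]],
                             mp[["d_min"]])
    expect_equal(scl$psi_iso, base$psi_iso, tolerance = 1e-10)
  }
})

test_that("small-strain stress matches linear elasticity with E = 2 mu (1+nu)", {
  eps <- matrix(c(4e-5, 1e-5, 0, 1e-5, -2e-5, 0, 0, 0, 3e-5), 3, 3)
  se <- energy_and_stress(kinematics(eps, 0), 0, mp)
  mu <- mp[["mu"]]; nu <- mp[["nu"]]
  lam <- 2 * mu * nu / (1 - 2 * nu)
  sig_lin <- lam * sum(diag(eps)) * diag(3) + 2 * mu * (eps + t(eps)) / 2
  expect_lt(max(abs(se$sigma - sig_lin)) / max(abs(sig_lin)), 0.01)
})

test_that("degradation lowers the energy monotonically and confined growth is hydrostatic", {
  Fe <- diag(3) + matrix(c(0, 0.2, 0, 0, 0, 0.1, 0, 0, 0.15), 3, 3)
  psis <- vapply(seq(0, 1, by = 0.1), function(d)
    cpp_energy_stress(Fe, d, mp[["mu"]], mp[["nu"]], mp[["d_min"]])$psi_deg,
    numeric(1))
  expect_true(all(diff(psis) <= 1e-12))

  # fully damaged, volumetrically compressed with shear: deviatoric
  # response carries d_min while the compressive pressure is undegraded
  Fe2 <- 0.8 * (diag(3) + matrix(c(0, 0.3, 0, 0, 0, 0, 0, 0, 0), 3, 3))
  se <- cpp_energy_stress(Fe2, 1, mp[["mu"]], mp[["nu"]], mp[["d_min"]])
  expect_equal(se$H_J, 1L)
  pres <- -sum(diag(se$sigma)) / 3
  expect_gt(pres, 0)
  expect_lt(von_mises(se$sigma) / pres, 10 * mp[["d_min"]])
})

test_that("phase-field sources follow the printed forms", {
  expect_equal(source_hematoma(0, 1), 0)
  expect_equal(source_hematoma(1, 0), 0)
  expect_equal(source_hematoma(1, 1, 100), 100)
  expect_equal(source_hematoma(0.5, 0.25, 100), 12.5)

  expect_equal(source_inflammation(0.7, c_th = 0.5), 0)
  expect_equal(source_inflammation(0, c_th = 0.5, R_s = 100), 100)
  expect_equal(source_inflammation(0.25, c_th = 0.5, R_s = 100), 50)
  expect_error(source_inflammation(0.5, c_th = 0), "c_th")

  expect_equal(source_damage(0.3, 0), 0)
  expect_equal(source_damage(0, 100, G_f = 100, d_min = 1e-4), 2 - 1e-4)
  psis <- c(1, 5, 20, 80)
  sd <- source_damage(0.4, psis, G_f = 100)
  expect_true(all(diff(sd) > 0))
  expect_equal(sd / psis, rep(sd[1] / psis[1], 4))  # linear in Psi_max
})

test_that("history variable is a running maximum", {
  expect_equal(update_history(1, 3), 3)
  expect_equal(update_history(3, 1), 3)
  seqv <- c(0, 2, 1, 5, 4)
  run <- Reduce(function(h, x) update_history(x, h), seqv, accumulate = TRUE,
                init = 0)[-1]
  expect_equal(run, c(0, 2, 2, 5, 5))
})

test_that("crack surface density integrates to the length scale on the optimal profile", {
  expect_equal(crack_surface_density(0, 0, 2), 0)
  expect_equal(crack_surface_density(1, 0, 2), 0.5)
  l <- 3
  x <- seq(-12 * l, 12 * l, length.out = 40001)
  d <- exp(-abs(x) / l)
  g <- -sign(x) * d / l
  gam <- d^2 / 2 + l^2 / 2 * g^2
  expect_equal(sum((head(gam, -1) + tail(gam, -1)) / 2 * diff(x)), l,
               tolerance = 1e-3)
})

test_that("von Mises stress handles hydrostatic, uniaxial and shear states", {
  expect_equal(von_mises(-5 * diag(3)), 0)
  expect_equal(von_mises(diag(c(7, 0, 0))), 7)
  tau <- matrix(0, 3, 3); tau[1, 2] <- tau[2, 1] <- 2.5
  expect_equal(von_mises(tau), sqrt(3) * 2.5)
  expect_equal(von_mises(c(1, 1, 1, 0, 0, 0)), 0)
})
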