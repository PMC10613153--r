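#' Material and numerical parameters
#'
#' Builds the full parameter set of the coupled model with literature
#' defaults for a human coronary artery. Units: lengths in micrometres,
#' stresses and energy densities in kilopascal, time in model time units
#' (the pseudo-time of the phase-field evolution).
#'
#' @param mu shear modulus (kPa).
#' @param nu Poisson ratio (near-incompressible tissue).
#' @param k_g growth coupling between the phase field and the volumetric
#'   overgrowth; the saturated overgrowth obeys `log(1+alpha) = k_g * phi`.
#' @param R_c constant nutrient consumption rate of wall cells.
#' @param D_max,D_min nutrient diffusivity in healthy and inflamed tissue
#'   (um^2 per time unit).
#' @param R_s source magnitude of the inflammation/hematoma phase field.
#' @param M barrier height of the Allen-Cahn double well.
#' @param eps phase-field interface parameter (um).
#' @param l damage regularization length (um); the printed value is twice
#'   the fine mesh size.
#' @param eta_d artificial damage viscosity.
#' @param d_min residual stiffness fraction retained at full damage.
#' @param G_f fracture resistance Psi_cri / l (kPa).
#' @param p_max lumen pressure (kPa); see [mmHg_to_kPa()] for conversion
#'   from mmHg.
#' @param c_th nutrient threshold below which inflammation is triggered
#'   (atherosclerosis source only, dimensionless).
#' @param K_c,K_phi,K_d conditioning scalings of the weak-form blocks.
#' @param c_cut width of the smooth cutoff that switches the consumption
#'   sink off as `c` approaches zero.
#' @return a named numeric vector of class `material_params`.
#' @export
material_params <- function(mu = 30, nu = 0.49, k_g = 10, R_c = 1e-2,
                            D_max = 1e3, D_min = 1, R_s = 100, M = 1,
                            eps = 25, l = 4, eta_d = 0.01, d_min = 1e-4,
                            G_f = 100, p_max = mmHg_to_kPa(120), c_th = 0.5,
                            K_c = 1, K_phi = 1, K_d = 1, c_cut = 0.05) {
  p <- c(mu = mu, nu = nu, k_g = k_g, R_c = R_c, D_max = D_max,
         D_min = D_min, R_s = R_s, M = M, eps = eps, l = l, eta_d = eta_d,
         d_min = d_min, G_f = G_f, p_max = p_max, c_th = c_th, K_c = K_c,
         K_phi = K_phi, K_d = K_d, c_cut = c_cut)
  stopifnot(p["mu"] > 0, p["nu"] > 0, p["nu"] < 0.5,
            p["D_min"] <= p["D_max"], p["d_min"] > 0, p["d_min"] < 1,
            p["G_f"] > 0, p["l"] > 0, p["c_th"] >= 0, p["c_th"] <= 1,
            p["eps"] > 0, p["eta_d"] >= 0)
  class(p) <- c("material_params", "numeric")
  p
}

#' Convert a pressure from mmHg to kPa
#'
#' @param p pressure in mmHg.
#' @return pressure in kPa (1 mmHg = 0.133322 kPa).
#' @export
mmHg_to_kPa <- function(p) p * 0.133322

#' Finite-strain kinematics with multiplicative growth
#'
#' Computes the total, growth and elastic deformation gradients from the
#' spatial displacement gradient: `F = (I - grad_u)^-1`,
#' `F_g = (1+alpha) I`, `F_e = F F_g^-1`, together with the elastic
#' Jacobian `J_e` and the isochoric right Cauchy-Green tensor.
#'
#' @param grad_u 3x3 spatial displacement gradient.
#' @param alpha growth scalar (internal variable, >= 0 under growth).
#' @return list with `F`, `F_g`, `F_e`, `J_e`, `C_e_iso`, `I1_iso`, `alpha`.
#' @export
kinematics <- function(grad_u, alpha = 0) {
  grad_u <- as_tensor3(grad_u)
  cpp_kinematics(grad_u, alpha)
}

#' Implicit update of the growth internal variable
#'
#' Solves the local residual
#' `(alpha_np1 - alpha_n)/(1 + alpha_np1) - k_g (phi_np1 - phi_n) = 0`
#' in closed form: `alpha_np1 = (alpha_n + k)/(1 - k)` with
#' `k = k_g (phi_np1 - phi_n)`. In the continuous limit the update
#' integrates to `log(1 + alpha) = k_g * phi`.
#'
#' @param alpha_n growth scalar at the previous step.
#' @param phi_n,phi_np1 phase-field values at the previous/current step.
#' @param k_g growth coupling.
#' @return list with `alpha` and the local sensitivity `dalpha_dphi` used
#'   in consistent tangent assembly.
#' @export
update_alpha <- function(alpha_n, phi_n, phi_np1, k_g) {
  cpp_update_alpha(alpha_n, phi_np1 - phi_n, k_g)
}

#' Degradation function of the damage field
#'
#' `g(d) = (1-d)^2 + d * d_min`, monotone decreasing on `[0, 1]`; the
#' residual stiffness `d_min` avoids a singular tangent at full damage.
#'
#' @param d damage in `[0,1]` (clamped).
#' @param d_min residual stiffness fraction.
#' @export
degradation_g <- function(d, d_min = 1e-4) {
  d <- pmin(pmax(d, 0), 1)
  (1 - d)^2 + d * d_min
}

#' Volumetric tension indicator
#'
#' Returns 1 when the elastic Jacobian indicates compression
#' (`J_e <= 1`, fracture-insensitive) and 0 in volumetric tension.
#'
#' @param J_e elastic Jacobian (> 0).
#' @export
tension_indicator <- function(J_e) {
  stopifnot(all(J_e > 0))
  as.integer(J_e <= 1)
}

#' Double-well barrier of the Allen-Cahn phase field
#'
#' `f(phi) = 16 M phi^2 (1-phi)^2` with local maximum `f(1/2) = M`.
#'
#' @param phi phase-field value.
#' @param M barrier height.
#' @return list with `f` and its derivative `dfdphi`.
#' @export
barrier_f <- function(phi, M = 1) {
  list(f = 16 * M * phi^2 * (1 - phi)^2,
       dfdphi = 32 * M * phi * (1 - phi) * (1 - 2 * phi))
}

#' Nutrient diffusivity interpolation
#'
#' Linear blend between the healthy (`D_max`) and inflamed (`D_min`)
#' diffusivity: `D = phi D_min + (1-phi) D_max`.
#'
#' @param phi phase field, clamped to `[0,1]`.
#' @param D_max,D_min diffusivities.
#' @export
diffusivity <- function(phi, D_max = 1e3, D_min = 1) {
  phi <- pmin(pmax(phi, 0), 1)
  phi * D_min + (1 - phi) * D_max
}

#' Degraded energy and Cauchy stress
#'
#' Evaluates the nearly incompressible neo-Hookean free energy with the
#' tension/compression volumetric split, the degradation by the damage
#' field, the undegraded crack-driving energy, and the Cauchy stress from
#' the analytic derivative of the degraded energy.
#'
#' @param kin kinematics list from [kinematics()] (or any list holding a
#'   3x3 elastic deformation gradient `F_e`).
#' @param d damage value (clamped to `[0,1]`).
#' @param params [material_params()] vector (uses `mu`, `nu`, `d_min`).
#' @return list with `psi_iso`, `psi_vol`, `psi_deg`, `psi_drive`, `g_d`,
#'   `H_J`, `J_e` and the symmetric 3x3 `sigma` (kPa).
#' @export
energy_and_stress <- function(kin, d, params) {
  Fe <- as_tensor3(if (is.list(kin)) kin$F_e else kin)
  cpp_energy_stress(Fe, d, params[["mu"]], params[["nu"]], params[["d_min"]])
}

#' Hematoma source term (dissection)
#'
#' `S_phi = R_s * c * d`: blood perfuses only where tissue is ruptured
#' (`d`) and nutrients/blood are available (`c`).
#'
#' @param c nutrient concentration.
#' @param d damage.
#' @param R_s source magnitude.
#' @export
source_hematoma <- function(c, d, R_s = 100) {
  R_s * pmin(pmax(c, 0), 1) * pmin(pmax(d, 0), 1)
}

#' Inflammation source term (atherosclerosis)
#'
#' Threshold ramp: inflammation grows only where the nutrient falls below
#' `c_th`, saturating at `R_s` for fully starved tissue:
#' `S_phi = R_s * max(c_th - c, 0) / c_th`.
#'
#' @param c nutrient concentration.
#' @param c_th nutrient threshold in `(0, 1]`.
#' @param R_s source magnitude.
#' @export
source_inflammation <- function(c, c_th = 0.5, R_s = 100) {
  stopifnot(c_th > 0, c_th <= 1)
  R_s * pmax(c_th - pmin(pmax(c, 0), 1), 0) / c_th
}

#' Damage source term
#'
#' `S_d = -g'(d) Psi_max / G_f = (2(1-d) - d_min) Psi_max / G_f`, the
#' crack driving force from the stored tensile energy history.
#'
#' @param d damage (clamped).
#' @param psi_max energy history (kPa, >= 0).
#' @param G_f fracture resistance `Psi_cri / l` (kPa).
#' @param d_min residual stiffness fraction.
#' @export
source_damage <- function(d, psi_max, G_f = 100, d_min = 1e-4) {
  stopifnot(all(psi_max >= 0))
  d <- pmin(pmax(d, 0), 1)
  (2 * (1 - d) - d_min) * psi_max / G_f
}

#' Update the energy history variable
#'
#' Running maximum enforcing damage irreversibility: increasing during
#' loading, frozen during unloading.
#'
#' @param psi_drive_now current crack-driving energy (kPa).
#' @param psi_max_prev previous history value (kPa).
#' @export
update_history <- function(psi_drive_now, psi_max_prev) {
  stopifnot(all(psi_drive_now >= 0), all(psi_max_prev >= 0))
  pmax(psi_drive_now, psi_max_prev)
}

#' Regularized crack surface density
#'
#' `gamma = d^2/2 + (l^2/2) |grad d|^2`; integrated over the optimal 1D
#' profile `d(x) = exp(-|x|/l)` it yields the length-scale `l`.
#'
#' @param d damage value.
#' @param grad_d damage gradient (vector or scalar, 1/um).
#' @param l damage length scale (um).
#' @export
crack_surface_density <- function(d, grad_d, l) {
  d^2 / 2 + (l^2 / 2) * sum(grad_d^2)
}

#' von Mises equivalent stress
#'
#' @param sigma symmetric 3x3 stress tensor, or a length-6 vector
#'   `(xx, yy, zz, xy, yz, xz)`.
#' @return `sqrt(3/2 * dev(sigma) : dev(sigma))` (kPa).
#' @export
von_mises <- function(sigma) {
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == 3, ncol(sigma) == 3,
              isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)))
    s <- c(sigma[1, 1], sigma[2, 2], sigma[3, 3],
           sigma[1, 2], sigma[2, 3], sigma[1, 3])
  } else {
    stopifnot(length(sigma) == 6)
    s <- sigma
  }
  m <- (s[1] + s[2] + s[3]) / 3
  sqrt(1.5 * ((s[1] - m)^2 + (s[2] - m)^2 + (s[3] - m)^2 +
                2 * (s[4]^2 + s[5]^2 + s[6]^2)))
}

# coerce 2x2 (plane strain, zero out-of-plane entry) or 3x3 input to 3x3
as_tensor3 <- function(A) {
  A <- as.matrix(A)
  if (all(dim(A) == c(3, 3))) return(A)
  if (all(dim(A) == c(2, 2))) {
    B <- matrix(0, 3, 3)
    B[1:2, 1:2] <- A
    return(B)
  }
  stop("expected a 2x2 or 3x3 matrix")
}
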