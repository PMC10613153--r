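#' Shape functions and quadrature of the isoparametric elements
#'
#' Bilinear quad4 (2x2 Gauss points) and trilinear hex8 (2x2x2) bases.
#'
#' @param element_type `"quad4"` or `"hex8"`.
#' @return list with Gauss `points` (ngp x dim), `weights`, basis values
#'   `N` (ngp x nn) and a list `dN` of nn x dim reference gradients.
#' @export
shape_quadrature <- function(element_type = c("quad4", "hex8")) {
  cpp_shape_quadrature(match.arg(element_type))
}

#' Element residual of the coupled four-field weak form
#'
#' Evaluates, per Gauss point, the mechanical block
#' `sigma : grad_sym(du)`, the nutrient block
#' `K_c [D grad c . grad dc + R_c dc]`, the inflammation block
#' `K_phi [eps^2 grad phi . grad dphi + M f'(phi) dphi + phi_dot dphi -
#' S_phi dphi]` and the damage block
#' `K_d [d dd + l^2 grad d . grad dd + eta_d d_dot dd - S_d dd]`, with
#' all integrals pulled back exactly to the reference configuration
#' (`dv = J dV`, spatial gradients via `F^-T`; the damage gradient uses
#' material gradients). The growth variable is re-solved locally and the
#' energy history updated inside the loop.
#'
#' @param X element node coordinates, dim x nn (2x4 quad4 or 3x8 hex8).
#' @param dofs current nodal unknowns, node-major `(u, c, phi, d)`.
#' @param phi_prev,d_prev nodal values at the previous time step.
#' @param alpha_n,psi_max_n committed Gauss state (length ngp).
#' @param params [material_params()].
#' @param dt time step (`Inf` for stationary).
#' @param mode phase-field source mode (`"none"`, `"hematoma"`,
#'   `"inflammation"`).
#' @return list with `residual` (node-major, DOF-minor), updated Gauss
#'   `alpha` and `psi_max`, Gauss stresses `sigma_gp`, volumes `vol_gp`
#'   and reference positions `x_gp`.
#' @export
element_residual <- function(X, dofs, phi_prev, d_prev, alpha_n,
                             psi_max_n, params, dt, mode = "none") {
  cpp_element_residual(X, dofs, phi_prev, d_prev, alpha_n, psi_max_n,
                       params_for_cpp(params, mode), dt)
}

#' Element tangent by central-difference perturbation of the residual
#'
#' @inheritParams element_residual
#' @param fd_eps relative perturbation size.
#' @return square tangent matrix in the residual's DOF ordering,
#'   including the consistent sensitivity of the local growth update.
#' @export
element_tangent <- function(X, dofs, phi_prev, d_prev, alpha_n,
                            psi_max_n, params, dt, mode = "none",
                            fd_eps = 3e-6) {
  cpp_element_tangent(X, dofs, phi_prev, d_prev, alpha_n, psi_max_n,
                      params_for_cpp(params, mode), dt, fd_eps)
}

#' Follower pressure residual on a lumen facet
#'
#' Traction `t = -p n` on the current (deformed) facet geometry. Facet
#' nodes follow the counter-clockwise lumen traversal (2 nodes in 2D,
#' 4 in 3D).
#'
#' @param X facet node coordinates (dim x nfn, reference).
#' @param u facet displacements (node-major).
#' @param p pressure (kPa).
#' @return residual contribution to the facet displacement DOFs.
#' @export
follower_pressure_residual <- function(X, u, p) {
  as.numeric(cpp_facet_pressure(X, u, p))
}
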