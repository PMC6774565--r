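#' Default physical and numerical parameters
#'
#' Single authoritative list of model constants, with units. Any entry can be
#' overridden by passing a modified copy to the constructors, or through the
#' `params` block of a JSON config (see [load_config()]).
#'
#' \describe{
#'   \item{k_axial}{fiber segment axial stiffness, nN/um (default 1).}
#'   \item{k_bend}{fiber bending stiffness on the discrete curvature vector,
#'     nN/um (default 0.05).}
#'   \item{D_e}{ECM node damping, nN.s/um (default 10).}
#'   \item{k_edge}{membrane edge-spring stiffness, nN/um (default 1).}
#'   \item{gamma}{isotropic cortical tension per unit membrane area,
#'     nN/um (default 0.3); the cortical energy is `gamma * total area` so the
#'     membrane always contracts toward smaller area.}
#'   \item{D_c}{membrane node damping, nN.s/um (default 10).}
#'   \item{cell_radius}{membrane rest radius, um (default 7).}
#'   \item{cell_subdiv}{icosphere subdivision level (default 1, 42 nodes).}
#'   \item{k_FA}{focal-adhesion spring stiffness per bound integrin,
#'     nN/um (default 0.5).}
#'   \item{n_int}{bound integrins per adhesion (default 10).}
#'   \item{d_bind}{attachment distance, um (default 4).}
#'   \item{d_break}{detachment distance, um (default 10).}
#'   \item{p_on}{attachment probability per control step (default 0.5).}
#'   \item{kappa}{polarity rotation rate toward the maximum-stiffness
#'     direction, 1/s (default 0.002; deliberately slow compared with the
#'     mechanical relaxation).}
#'   \item{alpha_L}{half apex angle of the leading-edge cone, rad
#'     (default pi/6).}
#'   \item{f_L}{lamellipodial force magnitude per loaded node, nN
#'     (default 0.3).}
#'   \item{sensing_radius}{radius for local stiffness sensing, um
#'     (default 15).}
#' }
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
default_params <- function(...) {
  p <- list(
    k_axial = 1, k_bend = 0.05, D_e = 10,
    k_edge = 1, gamma = 0.3, D_c = 10,
    cell_radius = 7, cell_subdiv = 1,
    k_FA = 0.5, n_int = 10L, d_bind = 4, d_break = 10, p_on = 0.5,
    kappa = 0.002, alpha_L = pi / 6, f_L = 0.3, sensing_radius = 15)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p
}
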