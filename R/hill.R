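#' Hill-type muscle force curves
#'
#' Parameterised normalized force curves for a rigid-tendon Hill-type muscle:
#' a Gaussian active force-length curve, an exponential passive force-length
#' curve that is zero at and below optimal fiber length, and a hyperbolic
#' force-velocity curve that is 1 at zero velocity and 0 at the maximum
#' shortening velocity. The specific curve constants are modelling choices
#' exposed here (and in model configs) so that they can be pinned by tests.
#'
#' @param gamma Width parameter of the Gaussian active force-length curve.
#' @param kpe Exponential shape factor of the passive curve.
#' @param e0 Passive strain at which the passive curve reaches 1.
#' @param vmax Maximum shortening velocity in optimal fiber lengths per second.
#' @param af Hill force-velocity shape parameter (concentric).
#' @param flen Eccentric force plateau (multiple of isometric force).
#' @return An object of class `hill_curves` with elements `fl_active`,
#'   `fl_passive`, `fv` (vectorised functions of normalized length /
#'   normalized velocity) and the constants.
#' @export
#' @examples
#' hc <- hill_curves()
#' hc$fl_active(1)   # 1 at optimal length
#' hc$fv(0)          # 1 at zero velocity
hill_curves <- function(gamma = 0.45, kpe = 4, e0 = 0.6, vmax = 10,
                        af = 0.25, flen = 1.4) {
  stopifnot(gamma > 0, kpe > 0, e0 > 0, vmax > 0, af > 0, flen > 1)
  fl_active <- function(lnorm) exp(-(lnorm - 1)^2 / gamma)
  fl_passive <- function(lnorm) {
    ifelse(lnorm <= 1, 0, (exp(kpe * (lnorm - 1) / e0) - 1) / (exp(kpe) - 1))
  }
  # concentric branch: (1 + v)/(1 - v/af); slope at 0 is 1 + 1/af.
  # eccentric branch matched C1 at v = 0.
  kecc <- (1 + 1 / af) / (flen - 1)
  fv <- function(vnorm) {
    conc <- pmax(0, (1 + vnorm) / (1 - vnorm / af))
    ecc <- flen - (flen - 1) * exp(-kecc * vnorm)
    ifelse(vnorm < 0, ifelse(vnorm <= -1, 0, conc), ecc)
  }
  structure(list(fl_active = fl_active, fl_passive = fl_passive, fv = fv,
                 gamma = gamma, kpe = kpe, e0 = e0, vmax = vmax,
                 af = af, flen = flen),
            class = "hill_curves")
}

#' Rigid-tendon Hill-type tendon force
#'
#' Computes tendon force for a rigid-tendon muscle: the tendon is fixed at
#' its slack length, so fiber length follows directly from muscle-tendon
#' length through the constant-height pennation model
#' `l_fiber * cos(alpha) = l_mt - l_slack`. Force is
#' `F = f_max * (a * fL * fV + fP) * cos(alpha)`, clamped at zero.
#'
#' @param muscle A muscle spec list with `f_max`, `l_opt`, `l_slack`,
#'   `pennation` (rad at optimal fiber length).
#' @param curves A [hill_curves()] object.
#' @param a Activation in \[0, 1\] (vectorised).
#' @param l_mt Muscle-tendon length (m, vectorised).
#' @param v_mt Muscle-tendon lengthening velocity (m/s, vectorised).
#' @return Tendon force (N), with attribute `clamped` flagging samples where
#'   the fiber length hit its positive floor (`l_mt <= l_slack`).
#' @export
rigid_tendon_force <- function(muscle, curves, a, l_mt, v_mt = 0) {
  stopifnot(all(a >= -1e-9 & a <= 1 + 1e-9))
  comp <- rigid_tendon_state(muscle, l_mt, v_mt)
  fl <- curves$fl_active(comp$lnorm)
  fp <- curves$fl_passive(comp$lnorm)
  fv <- curves$fv(comp$vnorm / curves$vmax)
  F <- muscle$f_max * (a * fl * fv + fp) * comp$cos_alpha
  F <- pmax(F, 0)
  attr(F, "clamped") <- comp$clamped
  F
}

#' Fiber state under the rigid-tendon constraint
#'
#' @return list with `lnorm` (fiber length / l_opt), `vnorm` (fiber velocity
#'   in l_opt/s), `cos_alpha`, `clamped` flag vector.
#' @noRd
rigid_tendon_state <- function(muscle, l_mt, v_mt = 0) {
  h <- muscle$l_opt * sin(muscle$pennation %||% 0)
  proj <- l_mt - muscle$l_slack
  floor_proj <- 0.01 * muscle$l_opt
  clamped <- proj < floor_proj
  proj <- pmax(proj, floor_proj)
  lf <- sqrt(proj^2 + h^2)
  cos_alpha <- proj / lf
  vf <- v_mt * cos_alpha
  list(lnorm = lf / muscle$l_opt, vnorm = vf / muscle$l_opt,
       cos_alpha = cos_alpha, clamped = clamped)
}
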