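#' Foot-ground contact element
#'
#' One viscoelastic contact point on the sole of a foot: normal force from a
#' linear spring with non-linear (penetration-rate) damping, shear force
#' from a continuous stick-slip friction law.
#'
#' @param pos Position in the foot-segment frame (m, 3-vector).
#' @param k Spring stiffness (N/m).
#' @param c Damping coefficient (s/m).
#' @param mu_d Dynamic friction coefficient.
#' @param mu_v Viscous friction coefficient (s/m).
#' @param v_t Stick-slip transition velocity (m/s).
#' @export
contact_element <- function(pos, k = 2e4, c = 1.5, mu_d = 0.8,
                            mu_v = 0.5, v_t = 0.05) {
  stopifnot(k > 0, c >= 0, mu_d >= 0, v_t > 0)
  structure(list(pos = as.numeric(pos), k = k, c = c, mu_d = mu_d,
                 mu_v = mu_v, v_t = v_t),
            class = "contact_element")
}

#' Foot contact grid (rearfoot + toes sub-grids)
#'
#' @param side Foot side label (`"operated"` or `"non_operated"`).
#' @param segment Name of the foot segment the grid attaches to.
#' @param rear,toes Lists of [contact_element()]s (each non-empty).
#' @export
contact_grid <- function(side, segment, rear, toes) {
  stopifnot(length(rear) >= 1, length(toes) >= 1)
  structure(list(side = side, segment = segment, rear = rear, toes = toes),
            class = "contact_grid")
}

#' Smoothed positive part used by the contact normal-force law
#'
#' `eps * softplus(x / eps)`: C-infinity, equal to x for x >> eps and ~0 for
#' x << -eps, so collocation sees a C1 force across the contact boundary.
#' @noRd
softplus_pos <- function(x, eps = 1e-4) {
  z <- x / eps
  # numerically safe softplus
  eps * ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
}

#' Contact normal force
#'
#' `F_n = k * <delta> * (1 + c * delta_dot)`, clamped at zero, where
#' `<delta>` is the smoothed positive part of the penetration depth.
#'
#' @param element A [contact_element()].
#' @param delta Penetration depth (m, positive below ground; vectorised).
#' @param delta_dot Penetration rate (m/s, vectorised).
#' @param eps Positive-part smoothing half-width (m).
#' @return Normal force (N).
#' @export
normal_force <- function(element, delta, delta_dot = 0, eps = 1e-4) {
  pmax(0, element$k * softplus_pos(delta, eps) * (1 + element$c * delta_dot))
}

#' Continuous stick-slip friction force
#'
#' Magnitude `F_n * (mu_d * tanh(|v|/v_t) + mu_v * |v|)` opposing the slip
#' direction; exactly zero at zero slip and odd under v -> -v.
#'
#' @param element A [contact_element()].
#' @param F_n Normal force (N, >= 0; vectorised).
#' @param v Slip velocity: a 2-row or 3-row matrix of tangential velocity
#'   components (columns are samples), or a vector treated as one component.
#' @return Matrix of tangential force components matching `v`.
#' @export
friction_force <- function(element, F_n, v) {
  if (is.vector(v)) v <- matrix(v, 1)
  stopifnot(all(F_n >= -1e-12))
  speed <- sqrt(colSums(v^2))
  mag <- F_n * (element$mu_d * tanh(speed / element$v_t) + element$mu_v * speed)
  scale <- ifelse(speed > 0, -mag / speed, 0)
  sweep(v, 2, scale, `*`)
}

#' Aggregate ground reactions for one foot
#'
#' Sums contact-element forces over the rearfoot and toes grids given the
#' foot pose and velocity, and reports the resultant force, the moment about
#' the lab origin, and the center of pressure on the ground plane (y = 0).
#'
#' @param grid A [contact_grid()].
#' @param R Foot orientation, 3 x 3 x T array (body to world).
#' @param o Foot origin position, 3 x T (world).
#' @param omega Foot angular velocity, 3 x T (world).
#' @param v Foot origin velocity, 3 x T (world).
#' @param eps Positive-part smoothing half-width (m).
#' @return list with `force` (3 x T), `moment` (3 x T, about the lab
#'   origin), `cop` (3 x T, NA where total vertical force <= 0, flagged in
#'   `cop_defined`).
#' @export
grid_reactions <- function(grid, R, o, omega, v, eps = 1e-4) {
  if (is.matrix(R)) R <- array(R, c(3, 3, 1))
  o <- as.matrix(o); omega <- as.matrix(omega); v <- as.matrix(v)
  Tn <- dim(R)[3]
  Ftot <- matrix(0, 3, Tn); Mtot <- matrix(0, 3, Tn)
  for (el in c(grid$rear, grid$toes)) {
    pw <- o + rot_apply(R, el$pos)
    vw <- v + cross3(omega, rot_apply(R, el$pos))
    delta <- -pw[2, ]
    ddot <- -vw[2, ]
    Fn <- normal_force(el, delta, ddot, eps)
    Ftan <- friction_force(el, Fn, vw[c(1, 3), , drop = FALSE])
    f <- rbind(Ftan[1, ], Fn, Ftan[2, ])
    Ftot <- Ftot + f
    Mtot <- Mtot + cross3(pw, f)
  }
  dimnames(Ftot) <- NULL; dimnames(Mtot) <- NULL
  Fy <- Ftot[2, ]
  ok <- Fy > 1e-9
  cop <- matrix(NA_real_, 3, Tn)
  cop[1, ok] <- Mtot[3, ok] / Fy[ok]
  cop[2, ok] <- 0
  cop[3, ok] <- -Mtot[1, ok] / Fy[ok]
  list(force = Ftot, moment = Mtot, cop = cop, cop_defined = ok)
}
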