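#' Body kinematics over the tree, vectorised over time
#'
#' Propagates position, orientation, velocity and acceleration through the
#' branched kinematic tree for a trajectory of coordinates. Each segment is
#' attached to its parent by an ordered chain of 1-DOF transforms
#' (translations along / rotations about axes fixed in the running joint
#' frame), so a 6-DOF floating base is three translations followed by an
#' Euler rotation sequence.
#'
#' @param model A [walker_model()].
#' @param q,qd,qdd Coordinate position/velocity/acceleration, nDOF x T.
#' @return list per segment with `R` (3 x 3 x T), `o`, `v`, `a` (origin
#'   position/velocity/acceleration, 3 x T), `omega`, `alpha` (angular
#'   velocity/acceleration, 3 x T), plus `dof_axis`/`dof_point` records
#'   (world axis and application point per DOF, 3 x T) used by inverse
#'   dynamics.
#' @export
body_kinematics <- function(model, q, qd = NULL, qdd = NULL) {
  q <- as.matrix(q)
  Tn <- ncol(q)
  nd <- nrow(q)
  if (nd != length(model$dofs)) stop("state dimension mismatch")
  if (is.null(qd)) qd <- matrix(0, nd, Tn)
  if (is.null(qdd)) qdd <- matrix(0, nd, Tn)
  qd <- as.matrix(qd); qdd <- as.matrix(qdd)
  if (!all(is.finite(q)) || !all(is.finite(qd)) || !all(is.finite(qdd)))
    stop("non-finite state supplied to kinematics")
  dof_idx <- setNames(seq_along(model$dofs), model$dof_names)
  bodies <- list()
  dof_axis <- vector("list", nd); dof_point <- vector("list", nd)
  zero <- matrix(0, 3, Tn)
  for (s in model$segments) {
    if (s$parent == "ground") {
      R <- rot_identity(Tn); pos <- zero; vel <- zero; acc <- zero
      om <- zero; al <- zero
      jl <- as.numeric(s$joint_loc)
      pos <- matrix(jl, 3, Tn)
    } else {
      p <- bodies[[s$parent]]
      d <- rot_apply(p$R, s$joint_loc)
      R <- p$R
      pos <- p$o + d
      vel <- p$v + cross3(p$omega, d)
      acc <- p$a + cross3(p$alpha, d) + cross3(p$omega, cross3(p$omega, d))
      om <- p$omega; al <- p$alpha
    }
    for (dspec in s$dofs) {
      i <- dof_idx[[dspec$name]]
      u_w <- rot_apply(R, dspec$axis)       # world axis before this DOF moves
      qi <- q[i, ]; qdi <- qd[i, ]; qddi <- qdd[i, ]
      dof_axis[[i]] <- u_w
      dof_point[[i]] <- pos
      if (dspec$type == "trans") {
        dvec <- u_w * rep(qi, each = 3)
        pos <- pos + dvec
        vel <- vel + u_w * rep(qdi, each = 3) + cross3(om, dvec)
        acc <- acc + u_w * rep(qddi, each = 3) +
          2 * cross3(om, u_w * rep(qdi, each = 3)) +
          cross3(al, dvec) + cross3(om, cross3(om, dvec))
      } else {
        R <- rot_compose(R, rot_axis(dspec$axis, qi))
        al <- al + u_w * rep(qddi, each = 3) +
          cross3(om, u_w * rep(qdi, each = 3))
        om <- om + u_w * rep(qdi, each = 3)
      }
    }
    bodies[[s$name]] <- list(R = R, o = pos, v = vel, a = acc,
                             omega = om, alpha = al)
  }
  list(bodies = bodies, dof_axis = dof_axis, dof_point = dof_point,
       q = q, qd = qd, qdd = qdd)
}

#' Ground reactions produced by the model's contact grids
#'
#' @param model A [walker_model()].
#' @param kin Output of [body_kinematics()], or NULL to compute from `q`,`qd`.
#' @param q,qd Coordinates if `kin` is NULL.
#' @param eps Contact smoothing half-width (m).
#' @return Named list per contact grid side with [grid_reactions()] output.
#' @export
model_ground_reactions <- function(model, kin = NULL, q = NULL, qd = NULL,
                                   eps = 1e-4) {
  if (is.null(kin)) kin <- body_kinematics(model, q, qd)
  out <- list()
  for (g in model$contact) {
    b <- kin$bodies[[g$segment]]
    out[[g$side]] <- grid_reactions(g, b$R, b$o, b$omega, b$v, eps)
  }
  out
}

#' Inverse dynamics by recursive Newton-Euler over the tree
#'
#' Computes the generalized force at every coordinate for a given motion and
#' set of external wrenches. Entries for the floating-base (pelvis ground
#' joint) coordinates are the residual loads: they vanish for a dynamically
#' consistent motion.
#'
#' @param model A [walker_model()].
#' @param q,qd,qdd Coordinate trajectories, nDOF x T.
#' @param external Named list (by segment name) of external wrenches, each
#'   `list(force = 3 x T, moment = 3 x T)` with the moment about the lab
#'   origin (the convention of [grid_reactions()]).
#' @param kin Optional precomputed [body_kinematics()] output.
#' @return nDOF x T matrix of generalized forces (N m or N), row names the
#'   DOF names.
#' @export
inverse_dynamics <- function(model, q, qd, qdd, external = list(), kin = NULL) {
  q <- as.matrix(q)
  Tn <- ncol(q)
  if (is.null(kin)) kin <- body_kinematics(model, q, qd, qdd)
  g <- model$gravity
  seg_names <- names(model$segments)
  # Newton-Euler net loads per body (about body origin)
  f_net <- list(); n_net <- list()
  for (s in model$segments) {
    b <- kin$bodies[[s$name]]
    rc <- rot_apply(b$R, s$com)
    c_acc <- b$a + cross3(b$alpha, rc) + cross3(b$omega, cross3(b$omega, rc))
    Fi <- s$mass * (c_acc - matrix(g, 3, Tn))
    Iw_om <- matrix(0, 3, Tn); Iw_al <- matrix(0, 3, Tn)
    # I_world = R I R^T applied to omega/alpha
    om_b <- rot_apply_t(b$R, b$omega)
    al_b <- rot_apply_t(b$R, b$alpha)
    Iw_om <- rot_apply(b$R, s$inertia %*% om_b)
    Iw_al <- rot_apply(b$R, s$inertia %*% al_b)
    Ni <- Iw_al + cross3(b$omega, Iw_om)
    # external wrench on this body (moment given about lab origin)
    fe <- matrix(0, 3, Tn); ne <- matrix(0, 3, Tn)
    if (!is.null(external[[s$name]])) {
      fe <- as.matrix(external[[s$name]]$force)
      ne <- as.matrix(external[[s$name]]$moment) - cross3(b$o, fe)
    }
    f_net[[s$name]] <- Fi - fe
    n_net[[s$name]] <- Ni + cross3(rc, Fi) - ne
  }
  # backward pass: joint wrench transmitted to each body from its parent
  children <- lapply(seg_names, function(nm)
    seg_names[vapply(model$segments, `[[`, "", "parent") == nm])
  names(children) <- seg_names
  f_joint <- list(); n_joint <- list()
  for (nm in rev(seg_names)) {
    f <- f_net[[nm]]; n <- n_net[[nm]]
    for (ch in children[[nm]]) {
      f <- f + f_joint[[ch]]
      n <- n + n_joint[[ch]] +
        cross3(kin$bodies[[ch]]$o - kin$bodies[[nm]]$o, f_joint[[ch]])
    }
    f_joint[[nm]] <- f
    n_joint[[nm]] <- n
  }
  # project transmitted wrenches onto DOF axes
  tau <- matrix(0, length(model$dofs), Tn,
                dimnames = list(model$dof_names, NULL))
  dof_idx <- setNames(seq_along(model$dofs), model$dof_names)
  for (s in model$segments) {
    fw <- f_joint[[s$name]]
    nw <- n_joint[[s$name]]
    o_s <- kin$bodies[[s$name]]$o
    for (dspec in s$dofs) {
      i <- dof_idx[[dspec$name]]
      u <- kin$dof_axis[[i]]
      if (dspec$type == "trans") {
        tau[i, ] <- colSums(u * fw)
      } else {
        n_at <- nw + cross3(o_s - kin$dof_point[[i]], fw)
        tau[i, ] <- colSums(u * n_at)
      }
    }
  }
  tau
}

#' Apply transposed rotations (world to body), vectorised
#' @noRd
rot_apply_t <- function(R, x) {
  if (is.vector(x)) x <- matrix(x, 3, dim(R)[3])
  rbind(
    R[1, 1, ] * x[1, ] + R[2, 1, ] * x[2, ] + R[3, 1, ] * x[3, ],
    R[1, 2, ] * x[1, ] + R[2, 2, ] * x[2, ] + R[3, 2, ] * x[3, ],
    R[1, 3, ] * x[1, ] + R[2, 3, ] * x[2, ] + R[3, 3, ] * x[3, ]
  )
}

#' Residual loads at the pelvis ground joint
#'
#' @param model A [walker_model()].
#' @param tau Generalized-force matrix from [inverse_dynamics()].
#' @return Matrix of the floating-base rows of `tau` (forces N, torques N m).
#' @export
residual_loads <- function(model, tau) {
  root <- model$segments[["pelvis"]]
  idx <- match(vapply(root$dofs, `[[`, "", "name"), model$dof_names)
  tau[idx, , drop = FALSE]
}

#' Jerk-as-control state derivative
#'
#' Triple-integrator chain per DOF: d/dt (q, qd, qdd) = (qd, qdd, u).
#'
#' @param x list with `q`, `qd`, `qdd` (equal-length numeric vectors).
#' @param u Jerk control vector.
#' @return list with the time derivatives `q`, `qd`, `qdd`.
#' @export
jerk_state_derivative <- function(x, u) {
  stopifnot(length(x$q) == length(u))
  list(q = x$qd, qd = x$qdd, qdd = u)
}
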