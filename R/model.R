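#' Muscle specification
#'
#' Hill-type rigid-tendon parameters plus EMG-to-activation parameters and
#' surrogate geometry for one muscle-tendon actuator (one head).
#'
#' @param name Actuator name.
#' @param side One of `"operated"`, `"non_operated"`, `"central"`.
#' @param group Functional muscle group (heads of one anatomical muscle
#'   share a group, e.g. `"psoas"`).
#' @param f_max Peak isometric force (N).
#' @param l_opt Optimal fiber length (m).
#' @param l_slack Tendon slack length (m).
#' @param pennation Pennation angle at optimal fiber length (rad).
#' @param emg_scale EMG scale factor in (0, 1].
#' @param emg_delay Electromechanical delay (s).
#' @param tau_act,tau_deact Activation dynamics time constants (s).
#' @param shape_A Activation non-linearisation shape factor in \[-3, -0.01\].
#' @param geometry A [surrogate_geometry()].
#' @export
muscle_spec <- function(name, side, group = name, f_max, l_opt, l_slack,
                        pennation = 0, emg_scale = 0.9, emg_delay = 0.04,
                        tau_act = 0.015, tau_deact = 0.06, shape_A = -2,
                        geometry = NULL) {
  stopifnot(f_max >= 0, l_opt > 0, l_slack >= 0,
            tau_act > 0, tau_deact > 0,
            emg_scale > 0, emg_scale <= 1,
            shape_A >= -3, shape_A <= -0.01)
  structure(list(name = name, side = side, group = group, f_max = f_max,
                 l_opt = l_opt, l_slack = l_slack, pennation = pennation,
                 emg_scale = emg_scale, emg_delay = emg_delay,
                 tau_act = tau_act, tau_deact = tau_deact, shape_A = shape_A,
                 geometry = geometry),
            class = "muscle_spec")
}

#' Reduced musculoskeletal walker model
#'
#' A branched kinematic tree rooted at the pelvis with a floating ground
#' joint, a list of 1-DOF joint coordinates, Hill-type muscles with
#' surrogate geometry, and foot-ground contact grids. Coordinates are SI
#' with x forward, y up, z toward the operated (right) side; angles are
#' radians internally.
#'
#' @param name Model name.
#' @param segments Named list of segment specs; each a list with `name`,
#'   `parent` ("ground" for the pelvis root), `joint_loc` (3-vector in the
#'   parent frame), `mass` (kg), `com` (3-vector, body frame), `inertia`
#'   (3 x 3 about the COM, body frame), and `dofs`: ordered list of
#'   1-DOF joint coordinates, each `list(name, type = "rot"|"trans",
#'   axis, bounds)`.
#' @param muscles List of [muscle_spec()] objects; their geometries refer to
#'   DOF names which are resolved to indices here.
#' @param contact List of contact grids (see [contact_grid()]).
#' @param gravity Gravitational acceleration vector (m/s^2).
#' @param curves A [hill_curves()] object shared by all muscles.
#' @return Object of class `walker_model`.
#' @export
walker_model <- function(name, segments, muscles = list(), contact = list(),
                         gravity = c(0, -9.80665, 0), curves = hill_curves()) {
  seg_names <- vapply(segments, `[[`, "", "name")
  names(segments) <- seg_names
  # topological order + tree check
  parents <- vapply(segments, `[[`, "", "parent")
  roots <- seg_names[parents == "ground"]
  if (length(roots) != 1L || roots != "pelvis")
    stop("segment graph must be a tree rooted at the pelvis (ground parent)")
  order <- character(0); frontier <- "pelvis"
  while (length(frontier)) {
    order <- c(order, frontier)
    frontier <- seg_names[parents %in% frontier]
  }
  if (length(order) != length(seg_names) || anyDuplicated(order))
    stop("segment graph is not a tree")
  segments <- segments[order]
  # DOF registry in tree order
  dofs <- list()
  for (s in segments) {
    if (length(s$dofs) == 0)
      stop("segment ", s$name, " has no joint coordinates")
    for (d in s$dofs) {
      d$segment <- s$name
      if (is.null(d$bounds)) d$bounds <- c(-pi, pi)
      if (!all(is.finite(d$bounds)) || d$bounds[1] >= d$bounds[2])
        stop("DOF ", d$name, " has invalid bounds")
      if (abs(sqrt(sum(d$axis^2)) - 1) > 1e-9)
        stop("DOF ", d$name, " axis must be a unit vector")
      dofs[[d$name]] <- d
    }
  }
  dof_names <- names(dofs)
  # segment invariants
  for (s in segments) {
    if (s$mass < 0) stop("segment ", s$name, " has negative mass")
    ev <- eigen(s$inertia, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9) stop("segment ", s$name, " inertia not PSD")
  }
  # resolve muscle geometry DOF names to indices
  for (i in seq_along(muscles)) {
    g <- muscles[[i]]$geometry
    if (is.null(g)) stop("muscle ", muscles[[i]]$name, " has no geometry")
    if (is.character(g$dofs)) {
      idx <- match(g$dofs, dof_names)
      if (anyNA(idx))
        stop("muscle ", muscles[[i]]$name, " spans unknown DOF: ",
             paste(g$dofs[is.na(idx)], collapse = ", "))
      muscles[[i]]$geometry$dof_names <- g$dofs
      muscles[[i]]$geometry$dofs <- idx
    }
  }
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  m <- structure(list(name = name, segments = segments, dofs = dofs,
                      dof_names = dof_names, muscles = muscles,
                      contact = contact, gravity = gravity, curves = curves),
                 class = "walker_model")
  m
}

#' @export
print.walker_model <- function(x, ...) {
  cat("<walker_model>", x$name, "\n")
  cat("  segments:", length(x$segments),
      " DOFs:", length(x$dofs),
      " muscles:", length(x$muscles),
      " contact feet:", length(x$contact), "\n")
  cat("  total mass:", round(model_mass(x), 2), "kg\n")
  invisible(x)
}

#' Total model mass (kg)
#' @param model A [walker_model()].
#' @export
model_mass <- function(model) {
  sum(vapply(model$segments, `[[`, 0, "mass"))
}

#' Indices of muscle-actuated DOFs
#' @param model A [walker_model()].
#' @export
actuated_dofs <- function(model) {
  sort(unique(unlist(lapply(model$muscles, function(m) m$geometry$dofs))))
}

#' DOF bounds matrix (nDOF x 2)
#' @param model A [walker_model()].
#' @export
dof_bounds <- function(model) {
  t(vapply(model$dofs, `[[`, numeric(2), "bounds"))
}

#' Muscle moment decomposition at given kinematics
#'
#' At fixed kinematics, joint moments are affine in the activation vector:
#' `M(t) = B(t) a(t) + p(t)` where column m of `B` holds the moment
#' contribution per unit activation of muscle m (moment arm times active
#' force scale) and `p` collects passive-force moments. This linearity is
#' what makes synergy-weight estimation and the generator's activation
#' construction exact least-squares problems.
#'
#' @param model A [walker_model()].
#' @param q,qdot Coordinate positions/velocities, nDOF x T matrices.
#' @return list with `B` (nDOF x nMuscle x T array), `p` (nDOF x T),
#'   plus per-muscle fiber state lists (`lnorm`, `vnorm`, `force_scale`).
#' @export
muscle_moment_arrays <- function(model, q, qdot) {
  q <- as.matrix(q); qdot <- as.matrix(qdot)
  nd <- length(model$dofs); Tn <- ncol(q); nm <- length(model$muscles)
  B <- array(0, c(nd, nm, Tn))
  p <- matrix(0, nd, Tn)
  lnorm <- vnorm <- matrix(0, nm, Tn)
  curves <- model$curves
  for (m in seq_len(nm)) {
    mus <- model$muscles[[m]]
    g <- mus$geometry
    geo <- mtu_length_and_moment_arms(g, q)
    v_mt <- mtu_velocity(geo$moment_arms, qdot[g$dofs, , drop = FALSE])
    st <- rigid_tendon_state(mus, geo$length, v_mt)
    fl <- curves$fl_active(st$lnorm)
    fv <- curves$fv(st$vnorm / curves$vmax)
    fp <- curves$fl_passive(st$lnorm)
    act_scale <- mus$f_max * fl * fv * st$cos_alpha   # dF/da
    pas <- mus$f_max * fp * st$cos_alpha
    for (j in seq_along(g$dofs)) {
      B[g$dofs[j], m, ] <- geo$moment_arms[j, ] * act_scale
      p[g$dofs[j], ] <- p[g$dofs[j], ] + geo$moment_arms[j, ] * pas
    }
    lnorm[m, ] <- st$lnorm; vnorm[m, ] <- st$vnorm
  }
  dimnames(B) <- list(model$dof_names, names(model$muscles), NULL)
  rownames(p) <- model$dof_names
  list(B = B, p = p, lnorm = lnorm, vnorm = vnorm)
}

#' Net joint moments generated by muscle activations
#'
#' Sums moment-arm times tendon-force contributions over all muscles:
#' linear in each muscle's peak isometric strength at fixed kinematics and
#' activation.
#'
#' @param model A [walker_model()].
#' @param q,qdot Coordinate positions/velocities (vectors or nDOF x T).
#' @param a Activation vector (nMuscle) or nMuscle x T matrix.
#' @return nDOF x T matrix of joint moments (N m).
#' @export
joint_moments_from_activations <- function(model, q, qdot, a) {
  q <- as.matrix(q); qdot <- as.matrix(qdot)
  a <- if (is.matrix(a)) a else matrix(a, length(model$muscles), ncol(q))
  if (any(a < -1e-9 | a > 1 + 1e-9))
    stop("activations outside [0, 1]")
  arr <- muscle_moment_arrays(model, q, qdot)
  M <- arr$p
  for (t in seq_len(ncol(q)))
    M[, t] <- M[, t] + arr$B[, , t] %*% a[, t]
  M
}

#' Export a compiled model as JSON (provenance record)
#'
#' @param model A [walker_model()].
#' @param path Output file path.
#' @export
model_to_json <- function(model, path) {
  x <- list(
    name = model$name,
    gravity = model$gravity,
    segments = lapply(unname(model$segments), function(s)
      list(name = s$name, parent = s$parent, mass = s$mass,
           com = s$com, joint_loc = s$joint_loc, inertia = s$inertia,
           dofs = lapply(s$dofs, function(d)
             list(name = d$name, type = d$type, axis = d$axis,
                  bounds = d$bounds)))),
    muscles = lapply(unname(model$muscles), function(m)
      list(name = m$name, side = m$side, group = m$group, f_max = m$f_max,
           l_opt = m$l_opt, l_slack = m$l_slack, pennation = m$pennation,
           emg_scale = m$emg_scale, emg_delay = m$emg_delay,
           tau_act = m$tau_act, tau_deact = m$tau_deact,
           shape_A = m$shape_A,
           geometry = list(dofs = m$geometry$dof_names %||% m$geometry$dofs,
                           expon = m$geometry$expon,
                           coef = m$geometry$coef))),
    curves = model$curves[c("gamma", "kpe", "e0", "vmax", "af", "flen")],
    contact = lapply(model$contact, function(g)
      list(side = g$side, segment = g$segment,
           rear = lapply(g$rear, unclass), toes = lapply(g$toes, unclass)))
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a walker model from a YAML config
#'
#' The config mirrors the structure documented in [walker_model()]:
#' top-level keys `name`, `gravity`, `curves`, `segments`, `muscles`,
#' `contact`.
#'
#' @param path YAML file path.
#' @return A [walker_model()].
#' @export
model_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  curves <- do.call(hill_curves, cfg$curves %||% list())
  segments <- lapply(cfg$segments, function(s) {
    s$joint_loc <- as.numeric(s$joint_loc)
    s$com <- as.numeric(s$com)
    s$inertia <- matrix(as.numeric(unlist(s$inertia)), 3, 3)
    s$dofs <- lapply(s$dofs, function(d) {
      d$axis <- as.numeric(d$axis)
      d$bounds <- as.numeric(d$bounds %||% c(-pi, pi))
      d
    })
    s
  })
  muscles <- lapply(cfg$muscles, function(m) {
    g <- surrogate_geometry(
      dofs = unlist(m$geometry$dofs),
      expon = matrix(as.numeric(unlist(m$geometry$expon)),
                     ncol = length(m$geometry$dofs), byrow = TRUE),
      coef = as.numeric(m$geometry$coef))
    muscle_spec(name = m$name, side = m$side, group = m$group %||% m$name,
                f_max = m$f_max, l_opt = m$l_opt, l_slack = m$l_slack,
                pennation = m$pennation %||% 0,
                emg_scale = m$emg_scale %||% 0.9,
                emg_delay = m$emg_delay %||% 0.04,
                tau_act = m$tau_act %||% 0.015,
                tau_deact = m$tau_deact %||% 0.06,
                shape_A = m$shape_A %||% -2,
                geometry = g)
  })
  contact <- lapply(cfg$contact %||% list(), function(g) {
    mk <- function(e) do.call(contact_element, lapply(e, function(v)
      if (length(v) > 1) as.numeric(v) else v))
    contact_grid(side = g$side, segment = g$segment,
                 rear = lapply(g$rear, mk), toes = lapply(g$toes, mk))
  })
  walker_model(name = cfg$name %||% "config_model", segments = segments,
               muscles = muscles, contact = contact,
               gravity = as.numeric(cfg$gravity %||% c(0, -9.80665, 0)),
               curves = curves)
}
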