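#' Fixture model catalog
#'
#' Deterministic reduced walker models standing in for a full personalized
#' musculoskeletal model:
#' \describe{
#'   \item{planar9}{Sagittal 9-DOF walker: planar pelvis (2 translations +
#'     tilt), hip, knee and ankle per leg; 10 Hill-type actuators per leg
#'     in 8 functional groups, including a 3-head psoas hip-flexor group.}
#'   \item{frontal3d}{Reduced 3-D walker: 6-DOF pelvis, lumbar extension +
#'     bending, 3-DOF hips, knees, ankle + subtalar; 22 actuators per leg
#'     including a hip abductor group and 3-head psoas, plus 9 trunk
#'     actuators per side with multi-head groups.}
#' }
#' The operated side is the right (+z).
#'
#' @param name `"planar9"` or `"frontal3d"`.
#' @return A [walker_model()] carrying a `gait_template` attribute used by
#'   [generate_gait()].
#' @export
make_fixture <- function(name = c("planar9", "frontal3d")) {
  name <- match.arg(name)
  switch(name, planar9 = fixture_planar9(), frontal3d = fixture_frontal3d())
}

#' @noRd
foot_contact_elements <- function() {
  rear <- list()
  for (x in c(-0.06, 0.02)) for (z in c(-0.03, 0, 0.03))
    rear <- c(rear, list(contact_element(c(x, -0.07, z))))
  toes <- list()
  for (x in c(0.12, 0.18)) for (z in c(-0.02, 0.02))
    toes <- c(toes, list(contact_element(c(x, -0.07, z))))
  list(rear = rear, toes = toes)
}

#' @noRd
leg_segments <- function(side, hip_z, dofs3d = FALSE) {
  sgn <- if (side == "r") 1 else -1
  hipdofs <- list(list(name = paste0("hip_flexion_", side), type = "rot",
                       axis = c(0, 0, 1), bounds = c(-1.2, 1.4)))
  if (dofs3d) {
    hipdofs <- c(hipdofs, list(
      list(name = paste0("hip_adduction_", side), type = "rot",
           axis = c(sgn, 0, 0), bounds = c(-0.7, 0.7)),
      list(name = paste0("hip_rotation_", side), type = "rot",
           axis = c(0, sgn, 0), bounds = c(-0.7, 0.7))))
  }
  ankledofs <- list(list(name = paste0("ankle_angle_", side), type = "rot",
                         axis = c(0, 0, 1), bounds = c(-1.0, 0.8)))
  if (dofs3d) {
    ankledofs <- c(ankledofs, list(
      list(name = paste0("subtalar_", side), type = "rot",
           axis = c(sgn, 0, 0), bounds = c(-0.7, 0.7))))
  }
  list(
    list(name = paste0("thigh_", side), parent = "pelvis",
         joint_loc = c(0, -0.07, hip_z), mass = 6.67,
         com = c(0, -0.19, 0), inertia = diag(c(0.13, 0.03, 0.13)),
         dofs = hipdofs),
    list(name = paste0("shank_", side), parent = paste0("thigh_", side),
         joint_loc = c(0, -0.46, 0), mass = 3.10,
         com = c(0, -0.20, 0), inertia = diag(c(0.055, 0.008, 0.055)),
         dofs = list(list(name = paste0("knee_angle_", side), type = "rot",
                          axis = c(0, 0, 1), bounds = c(-2.2, 0.1)))),
    list(name = paste0("foot_", side), parent = paste0("shank_", side),
         joint_loc = c(0, -0.46, 0), mass = 0.97,
         com = c(0.07, -0.03, 0), inertia = diag(c(0.002, 0.005, 0.004)),
         dofs = ankledofs)
  )
}

#' Reference mid-gait posture used to center fiber operating ranges
#' @noRd
reference_pose <- function(dof_name) {
  if (startsWith(dof_name, "hip_flexion")) return(0.1)
  if (startsWith(dof_name, "knee_angle")) return(-1.0)
  if (startsWith(dof_name, "ankle_angle")) return(0.3)
  0
}

#' Build a polynomial-in-angles muscle from a compact term table
#'
#' `terms` is a named list dof_name -> c(linear, quadratic) coefficients of
#' the LENGTH polynomial (moment arm = -derivative). Optimal fiber length
#' and tendon slack length are set so the fiber operates near (slightly
#' below) its optimal length at a mid-gait reference posture, which keeps
#' passive forces small over the gait range.
#' @noRd
fix_muscle <- function(name, side_lab, group, f_max, l0, terms, par = list()) {
  dn <- names(terms)
  d <- length(dn)
  ex <- matrix(0, 1, d)   # constant term
  cf <- l0
  for (j in seq_len(d)) {
    tj <- terms[[j]]
    e1 <- rep(0, d); e1[j] <- 1
    ex <- rbind(ex, e1); cf <- c(cf, tj[1])
    if (length(tj) > 1 && tj[2] != 0) {
      e2 <- rep(0, d); e2[j] <- 2
      ex <- rbind(ex, e2); cf <- c(cf, tj[2])
    }
  }
  g <- surrogate_geometry(dn, ex, cf)
  q_ref <- vapply(dn, reference_pose, 0)
  l_ref <- mtu_length_and_moment_arms(g, matrix(q_ref, d, 1))$length
  l_opt <- 0.55 * l_ref
  l_slack <- l_ref - 0.95 * l_opt
  do.call(muscle_spec, c(list(name = name, side = side_lab, group = group,
                              f_max = f_max, l_opt = l_opt,
                              l_slack = l_slack, geometry = g), par))
}

#' Deterministic per-muscle EMG-to-activation parameter variation
#' @noRd
emg_param_set <- function(i) {
  list(emg_scale = 0.80 + 0.02 * (i %% 5),
       emg_delay = 0.030 + 0.004 * (i %% 4),
       tau_act = 0.012 + 0.002 * (i %% 3),
       tau_deact = 0.050 + 0.010 * (i %% 3),
       shape_A = -2.5 + 0.3 * (i %% 5))
}

#' @noRd
leg_muscles_sagittal <- function(side, dofs3d = FALSE, i0 = 0) {
  sl <- if (side == "r") "operated" else "non_operated"
  hf <- paste0("hip_flexion_", side); kn <- paste0("knee_angle_", side)
  ak <- paste0("ankle_angle_", side)
  lb <- "lumbar_bending"
  bsgn <- if (side == "r") -1 else 1   # right psoas shortens bending right
  mk <- function(i, name, group, f_max, l0, terms)
    fix_muscle(paste0(name, "_", side), sl, paste0(group, "_", side),
               f_max, l0, terms, emg_param_set(i0 + i))
  ms <- list(
    mk(1, "glut_max", "glut_max", 11000, 0.32,
       setNames(list(c(0.060, 0.005)), hf)),
    mk(2, "psoas_1", "psoas", 8000, 0.20,
       c(setNames(list(c(-0.045)), hf),
         if (dofs3d) setNames(list(c(bsgn * 0.015)), lb))),
    mk(3, "psoas_2", "psoas", 8000, 0.21,
       c(setNames(list(c(-0.050, 0.003)), hf),
         if (dofs3d) setNames(list(c(bsgn * 0.015)), lb))),
    mk(4, "psoas_3", "psoas", 8000, 0.22,
       c(setNames(list(c(-0.055)), hf),
         if (dofs3d) setNames(list(c(bsgn * 0.012)), lb))),
    mk(5, "hamstrings", "hamstrings", 15000, 0.47,
       setNames(list(c(0.055), c(0.035)), c(hf, kn))),
    mk(6, "rect_fem", "rect_fem", 8500, 0.42,
       setNames(list(c(-0.040), c(-0.040)), c(hf, kn))),
    mk(7, "vasti", "vasti", 18000, 0.25,
       setNames(list(c(-0.045, 0.004)), kn)),
    mk(8, "gastroc", "gastroc", 12000, 0.44,
       setNames(list(c(0.020), c(0.045)), c(kn, ak))),
    mk(9, "soleus", "soleus", 16000, 0.30,
       setNames(list(c(0.050, 0.004)), ak)),
    mk(10, "tib_ant", "tib_ant", 8000, 0.31,
       setNames(list(c(-0.040)), ak))
  )
  ms
}

#' @noRd
leg_muscles_frontal <- function(side, i0 = 0) {
  sl <- if (side == "r") "operated" else "non_operated"
  hf <- paste0("hip_flexion_", side); ha <- paste0("hip_adduction_", side)
  hr <- paste0("hip_rotation_", side)
  ak <- paste0("ankle_angle_", side); st <- paste0("subtalar_", side)
  mk <- function(i, name, group, f_max, l0, terms)
    fix_muscle(paste0(name, "_", side), sl, paste0(group, "_", side),
               f_max, l0, terms, emg_param_set(i0 + i))
  list(
    mk(1, "glut_med_ant", "glut_med", 2600, 0.15,
       setNames(list(c(0.050), c(-0.010)), c(ha, hf))),
    mk(2, "glut_med_mid", "glut_med", 2600, 0.14,
       setNames(list(c(0.055)), ha)),
    mk(3, "glut_med_post", "glut_med", 2600, 0.15,
       setNames(list(c(0.050), c(0.010)), c(ha, hf))),
    mk(4, "glut_min", "glut_min", 1600, 0.11,
       setNames(list(c(0.040)), ha)),
    mk(5, "tfl", "tfl", 1000, 0.45,
       setNames(list(c(0.045), c(-0.020)), c(ha, hf))),
    mk(6, "adductor", "adductor", 5500, 0.28,
       setNames(list(c(-0.045)), ha)),
    mk(7, "iliacus", "iliacus", 2600, 0.18,
       setNames(list(c(-0.045)), hf)),
    mk(8, "piriformis", "piriformis", 4000, 0.12,
       setNames(list(c(0.012)), ha)),
    mk(9, "quadratus_femoris", "quadratus_femoris", 3200, 0.08,
       setNames(list(c(-0.030)), ha)),
    mk(10, "gemelli", "gemelli", 800, 0.07,
       setNames(list(c(0.010)), ha)),
    mk(11, "tib_post", "tib_post", 4500, 0.32,
       setNames(list(c(0.030)), ak)),
    mk(12, "peroneus", "peroneus", 3500, 0.33,
       setNames(list(c(0.025)), ak))
  )
}

#' @noRd
trunk_muscles <- function(side, i0 = 0) {
  sl <- if (side == "r") "operated" else "non_operated"
  bs <- if (side == "r") 1 else -1   # right trunk muscles bend right
  mk <- function(i, name, group, f_max, l0, re, rb)
    fix_muscle(paste0(name, "_", side), sl, paste0(group, "_", side),
               f_max, l0,
               setNames(list(c(-re), c(-bs * rb)),
                        c("lumbar_extension", "lumbar_bending")),
               emg_param_set(i0 + i))
  list(
    mk(1, "erector_spinae_1", "erector_spinae", 4500, 0.22, 0.055, 0.035),
    mk(2, "erector_spinae_2", "erector_spinae", 4500, 0.24, 0.060, 0.040),
    mk(3, "erector_spinae_3", "erector_spinae", 4500, 0.23, 0.050, 0.045),
    mk(4, "multifidus_1", "multifidus", 2000, 0.12, 0.030, 0.015),
    mk(5, "multifidus_2", "multifidus", 2000, 0.13, 0.035, 0.020),
    mk(6, "quadratus_lumborum", "quadratus_lumborum", 2200, 0.16, 0.010, 0.055),
    mk(7, "oblique_int", "oblique_int", 3000, 0.20, -0.035, 0.040),
    mk(8, "oblique_ext", "oblique_ext", 3000, 0.22, -0.040, 0.035),
    mk(9, "rectus_abd", "rectus_abd", 2500, 0.30, -0.055, 0.008)
  )
}

#' @noRd
fixture_planar9 <- function() {
  segs <- c(
    list(list(name = "pelvis", parent = "ground", joint_loc = c(0, 0, 0),
              mass = 45.22, com = c(0, 0.25, 0),
              inertia = diag(c(2.5, 1.0, 2.6)),
              dofs = list(
                list(name = "pelvis_tx", type = "trans", axis = c(1, 0, 0),
                     bounds = c(-100, 100)),
                list(name = "pelvis_ty", type = "trans", axis = c(0, 1, 0),
                     bounds = c(0.3, 1.4)),
                list(name = "pelvis_tilt", type = "rot", axis = c(0, 0, 1),
                     bounds = c(-0.7, 0.7))))),
    leg_segments("r", 0.09), leg_segments("l", -0.09))
  ce <- foot_contact_elements()
  contact <- list(
    contact_grid("operated", "foot_r", ce$rear, ce$toes),
    contact_grid("non_operated", "foot_l", ce$rear, ce$toes))
  muscles <- c(leg_muscles_sagittal("r", FALSE, 0),
               leg_muscles_sagittal("l", FALSE, 10))
  m <- walker_model("planar9", segs, muscles, contact)
  attr(m, "gait_template") <- gait_template(dofs3d = FALSE)
  m
}

#' @noRd
fixture_frontal3d <- function() {
  segs <- c(
    list(list(name = "pelvis", parent = "ground", joint_loc = c(0, 0, 0),
              mass = 11.78, com = c(0, 0.02, 0),
              inertia = diag(c(0.08, 0.09, 0.07)),
              dofs = list(
                list(name = "pelvis_tx", type = "trans", axis = c(1, 0, 0),
                     bounds = c(-100, 100)),
                list(name = "pelvis_ty", type = "trans", axis = c(0, 1, 0),
                     bounds = c(0.3, 1.4)),
                list(name = "pelvis_tz", type = "trans", axis = c(0, 0, 1),
                     bounds = c(-1, 1)),
                list(name = "pelvis_tilt", type = "rot", axis = c(0, 0, 1),
                     bounds = c(-0.7, 0.7)),
                list(name = "pelvis_list", type = "rot", axis = c(1, 0, 0),
                     bounds = c(-0.7, 0.7)),
                list(name = "pelvis_rotation", type = "rot", axis = c(0, 1, 0),
                     bounds = c(-0.7, 0.7)))),
         list(name = "torso", parent = "pelvis", joint_loc = c(0, 0.08, 0),
              mass = 33.44, com = c(0, 0.32, 0),
              inertia = diag(c(1.9, 0.7, 1.5)),
              dofs = list(
                list(name = "lumbar_extension", type = "rot",
                     axis = c(0, 0, 1), bounds = c(-0.6, 0.6)),
                list(name = "lumbar_bending", type = "rot",
                     axis = c(1, 0, 0), bounds = c(-0.7, 0.7))))),
    leg_segments("r", 0.09, TRUE), leg_segments("l", -0.09, TRUE))
  ce <- foot_contact_elements()
  contact <- list(
    contact_grid("operated", "foot_r", ce$rear, ce$toes),
    contact_grid("non_operated", "foot_l", ce$rear, ce$toes))
  muscles <- c(leg_muscles_sagittal("r", TRUE, 0),
               leg_muscles_frontal("r", 20),
               trunk_muscles("r", 32),
               leg_muscles_sagittal("l", TRUE, 5),
               leg_muscles_frontal("l", 26),
               trunk_muscles("l", 37))
  m <- walker_model("frontal3d", segs, muscles, contact)
  attr(m, "gait_template") <- gait_template(dofs3d = TRUE)
  m
}

#' Gait-template metadata shared by the generator
#' @noRd
gait_template <- function(dofs3d) {
  list(dofs3d = dofs3d,
       l1 = 0.46, l2 = 0.46, ankle_h = 0.07, hip_drop = 0.07, hip_z = 0.09,
       heel_local = c(-0.06, -0.07, 0), toe_local = c(0.18, -0.07, 0),
       stance_frac = 0.65, ramp_frac = 0.15,
       pelvis_ty0 = 0.86, swing_h = 0.095, sink0 = 0.0035,
       pitch_max = 0.42, heel_pitch = 0.18)
}

#' Default surgical resection roster for a fixture model
#'
#' The operated-side muscles removed in the reference scenario: the full
#' hip abductor group plus iliacus, rectus femoris, tensor fascia latae,
#' the small external rotators, and most of the operated-side trunk
#' muscles (a few erector spinae / multifidus heads remain). Psoas is
#' handled by the strength factor, not the list.
#'
#' @param model A fixture [walker_model()].
#' @return Character vector of muscle names present in the model.
#' @export
default_resection_list <- function(model) {
  cand <- c("glut_med_ant_r", "glut_med_mid_r", "glut_med_post_r",
            "glut_min_r", "tfl_r", "iliacus_r", "rect_fem_r",
            "quadratus_femoris_r", "gemelli_r", "quadratus_lumborum_r",
            "oblique_int_r", "oblique_ext_r", "multifidus_2_r",
            "erector_spinae_3_r")
  intersect(cand, names(model$muscles))
}

# ---------------------------------------------------------------------------
# trajectory building blocks

#' Damped Gauss-Newton with a reused (chord) finite-difference Jacobian
#'
#' The residual map here is smooth and mildly non-linear, so the Jacobian is
#' rebuilt only `n_jacobian` times; between rebuilds, damped Gauss-Newton
#' steps reuse it (each costing a single residual evaluation instead of one
#' evaluation per parameter).
#' @noRd
chord_gauss_newton <- function(fn, th0, n_jacobian = 6, max_steps = 120,
                               fd_step = 1e-6, tol = 1e-9, step_max = 0.03) {
  th <- th0
  r <- fn(th)
  rss <- sum(r^2)
  np <- length(th)
  J <- matrix(0, length(r), np)
  build_jacobian <- function(th, r) {
    for (i in seq_len(np)) {
      thp <- th; thp[i] <- thp[i] + fd_step
      J[, i] <- (fn(thp) - r) / fd_step
    }
    J
  }
  J <- build_jacobian(th, r)
  JtJ <- crossprod(J)
  lam0 <- 1e-3
  lam <- lam0
  jb_used <- 1
  fails <- 0
  for (step in seq_len(max_steps)) {
    g <- crossprod(J, r)
    dx <- tryCatch(as.numeric(solve(JtJ + lam * diag(pmax(diag(JtJ), 1e-12)),
                                    -g)),
                   error = function(e) NULL)
    if (is.null(dx)) { lam <- lam * 10; next }
    if (max(abs(dx)) > step_max) dx <- dx * (step_max / max(abs(dx)))
    r_new <- fn(th + dx)
    rss_new <- sum(r_new^2)
    if (rss_new < rss) {
      improve <- (rss - rss_new) / rss
      # Broyden rank-1 update keeps the reused Jacobian honest
      dr <- r_new - r
      J <- J + tcrossprod(dr - J %*% dx, dx) / sum(dx^2)
      JtJ <- crossprod(J)
      th <- th + dx
      r <- r_new; rss <- rss_new
      lam <- max(lam / 3, 1e-6)
      fails <- 0
      if (improve < tol) break
    } else {
      lam <- lam * 10
      fails <- fails + 1
      if (fails >= 3) {
        if (jb_used >= n_jacobian) break
        J <- build_jacobian(th, r)
        JtJ <- crossprod(J)
        jb_used <- jb_used + 1
        lam <- lam0
        fails <- 0
      }
    }
  }
  list(par = th, rss = rss, info = 0, deviance = rss)
}

#' Quintic smoothstep (C2)
#' @noRd
smooth5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Stance sink profile over stance-local phase u in [0,1]
#'
#' Asymmetric: quick loading after heel strike, earlier and more gradual
#' unloading through terminal stance (which keeps the trailing-limb joint
#' moment demands physiological).
#' @noRd
sink_profile <- function(u, ramp, ramp_out = 0.30) {
  smooth5(u / ramp) - smooth5((u - (1 - ramp_out)) / ramp_out)
}

#' Swing forward progression profile (zero end velocities, fast early
#' catch-up so the trailing leg never outruns its reach)
#' @noRd
swing_forward <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^2 * (3 - 2 * u)
}

#' Swing height bump with a broad plateau (toe clearance while the foot
#' pitch follows the shank through mid-swing)
#' @noRd
swing_height <- function(u) {
  w <- pmin(pmax(u, 0), 1)^0.85
  tanh(2.2 * sin(pi * w)^2) / tanh(2.2)
}

#' Evaluate a Fourier deviation series at phases s
#' @noRd
fourier_eval <- function(coef, s, const = TRUE) {
  if (!length(coef)) return(rep(0, length(s)))
  out <- rep(0, length(s))
  i <- 1
  if (const) { out <- out + coef[1]; i <- 2 }
  k <- 1
  while (i < length(coef) + 1) {
    out <- out + coef[i] * cos(2 * pi * k * s)
    if (i + 1 <= length(coef)) out <- out + coef[i + 1] * sin(2 * pi * k * s)
    i <- i + 2; k <- k + 1
  }
  out
}

#' Spectral derivative of a periodic channel sampled on [0, T] inclusive
#'
#' `x` has n samples with x[n] == x[1] (periodic); returns the derivative at
#' the same samples.
#' @noRd
periodic_derivative <- function(x, T_per, order = 1) {
  n1 <- length(x) - 1
  xf <- fft(x[seq_len(n1)])
  k <- c(0:(n1 %/% 2), -rev(seq_len((n1 - 1) %/% 2)))
  w <- 2 * pi / T_per * k
  mult <- (1i * w)^order
  if (n1 %% 2 == 0 && order %% 2 == 1) mult[n1 %/% 2 + 1] <- 0
  d <- Re(fft(xf * mult, inverse = TRUE)) / n1
  c(d, d[1])
}

#' Foot target trajectories over one cycle
#'
#' Returns ankle-position targets and stance masks for both feet given the
#' cycle parameters and micro-deviation Fourier coefficients.
#' @noRd
foot_targets <- function(s, tpl, L, asym, sink_scale, devs) {
  stf <- tpl$stance_frac; ramp <- tpl$ramp_frac / stf
  sink <- tpl$sink0 * sink_scale
  one_foot <- function(phase0, x_land, dx_dev, dz_dev, z0,
                       drift = 0, pbias = 0, zdrift = 0) {
    sl <- (s - phase0) %% 1
    stance <- sl < stf
    u_st <- sl / stf
    u_sw <- (sl - stf) / (1 - stf)
    # constant-rate stance drift produces a controllable mean shear force;
    # the swing path returns the offset for periodicity
    x <- ifelse(stance,
                x_land + drift * (u_st - 0.5),
                x_land + L * swing_forward(u_sw) +
                  drift * (0.5 - smooth5(u_sw)))
    yoff <- ifelse(stance, -sink * sink_profile(u_st, ramp),
                   tpl$swing_h * swing_height(u_sw))
    # heel and toe rockers: land slightly toes-up pivoting about the heel,
    # lift the heel over the last 30% of stance pivoting about the toes.
    # Net world foot pitch P > 0 is toes-up (heel pivot), P < 0 heel-up
    # (toe pivot); the center of pressure then travels heel to toe.
    heel_up <- tpl$pitch_max *
      ifelse(stance, smooth5((u_st - 0.70) / 0.30),
             1 - smooth5(u_sw / 1.00))
    toe_up <- tpl$heel_pitch *
      ifelse(stance, 1 - smooth5(u_st / 0.20),
             smooth5((u_sw - 0.6) / 0.4))
    # a small stance pitch bias shifts the mean center of pressure
    P <- toe_up - heel_up + pbias * ifelse(stance, sink_profile(u_st, ramp), 0)
    ah <- tpl$ankle_h
    px <- ifelse(P >= 0, tpl$heel_local[1], tpl$toe_local[1])
    dxc <- -px * (cos(P) - 1) - ah * sin(P)
    dyc <- -px * sin(P) + ah * (cos(P) - 1)
    z_ <- rep(z0, length(s)) + dz_dev +
      ifelse(stance, zdrift * (u_st - 0.5), zdrift * (0.5 - smooth5(u_sw)))
    list(x = x + dx_dev + dxc, y = tpl$ankle_h + yoff + dyc,
         z = z_,
         pitch = -P, stance = stance,
         flat = stance & u_st > ramp & u_st < 1 - ramp & abs(P) < 0.03)
  }
  # right (operated) heel strike at s = 0; stance position x advances by L
  # per cycle; within [0,1) right stance is at 0, then swings to L.
  z_base <- tpl$foot_z %||% tpl$hip_z
  r <- one_foot(0, 0, devs$foot_x_r, devs$foot_z_r, z_base,
                devs$drift_r, devs$pbias_r, devs$zdrift_r)
  lphase <- 0.5 + asym$temporal
  xl <- L * (0.5 + asym$spatial)
  l <- one_foot(lphase, xl - L * (s >= 0 & s < lphase), devs$foot_x_l,
                devs$foot_z_l, -z_base, devs$drift_l, devs$pbias_l,
                devs$zdrift_l)
  # left foot: stance during [lphase, 1] at xl; during [0, lphase - stf]
  # the early-cycle stance continues from the previous cycle at xl - L.
  # the s = 1 sample is the periodic image of s = 0 advanced by one stride
  # (phase wrap would otherwise snap the landing foot back by L)
  n <- length(s)
  fix_end <- function(ft) {
    ft$x[n] <- ft$x[1] + L
    ft$y[n] <- ft$y[1]; ft$z[n] <- ft$z[1]; ft$pitch[n] <- ft$pitch[1]
    ft$stance[n] <- ft$stance[1]; ft$flat[n] <- ft$flat[1]
    ft
  }
  list(r = fix_end(r), l = fix_end(l))
}

#' Closed-form leg inverse kinematics (hip flexion/adduction, knee, ankle)
#'
#' Solves hip and knee angles so the ankle lands exactly on its target, and
#' ankle/subtalar angles that keep the foot level (ZX extraction of the
#' shank orientation).
#' @noRd
leg_ik <- function(d_pelvis, tpl, side, dofs3d) {
  l1 <- tpl$l1; l2 <- tpl$l2
  Tn <- ncol(d_pelvis)
  r <- sqrt(colSums(d_pelvis^2))
  rmax <- 0.985 * (l1 + l2)
  # smooth reach clamp: identity below the limit, saturating at rmax,
  # kept away from the straight-knee singularity (a hard clamp puts kinks
  # in q(t) that blow up spectral accelerations)
  u <- r / rmax
  w <- 0.015
  z <- (u - 1) / w
  r <- rmax * (u - w * ifelse(z > 30, z, log1p(exp(pmin(z, 30)))))
  cosk <- (l1^2 + l2^2 - r^2) / (2 * l1 * l2)
  cosk <- pmin(pmax(cosk, -1), 1)
  kint <- acos(cosk)                     # interior knee angle
  th_k <- -(pi - kint)                   # knee flexion negative
  ux <- l2 * sin(th_k)
  uy <- -(l1 + l2 * cos(th_k))
  sgn <- if (side == "r") 1 else -1
  if (dofs3d) {
    th_a <- asin(pmin(pmax(sgn * d_pelvis[3, ] / uy, -0.99), 0.99))
  } else th_a <- rep(0, Tn)
  # planar rotation: (d_x, d_y) = Rz(th_h) (ux, uy cos(th_a))
  th_h <- atan2(d_pelvis[2, ], d_pelvis[1, ]) - atan2(uy * cos(th_a), ux)
  th_h <- ((th_h + pi) %% (2 * pi)) - pi
  list(hip = th_h, add = th_a, knee = th_k)
}

#' Ankle angles that realise a target foot pitch with level roll
#'
#' Decomposes `R_shank^T R_target` as Rz(ankle) Rx(subtalar) Ry(residual),
#' dropping the residual yaw.
#' @noRd
ankle_ik <- function(R_shank, side, dofs3d, pitch = NULL) {
  Tn <- dim(R_shank)[3]
  M <- rot_transpose(R_shank)
  if (!is.null(pitch)) M <- rot_compose(M, rot_axis(c(0, 0, 1), -pitch))
  b <- asin(pmin(pmax(M[3, 2, ], -1), 1))
  a <- atan2(-M[1, 2, ], M[2, 2, ])
  sgn <- if (side == "r") 1 else -1
  if (!dofs3d) return(list(ankle = a, subtalar = NULL))
  list(ankle = a, subtalar = sgn * b)
}

#' Assemble the full coordinate trajectory from pelvis + foot targets
#' @noRd
assemble_q <- function(model, tpl, s, Tn, pelvis_traj, feet) {
  dn <- model$dof_names
  q <- matrix(0, length(dn), Tn, dimnames = list(dn, NULL))
  dofs3d <- tpl$dofs3d
  q["pelvis_tx", ] <- pelvis_traj$tx
  q["pelvis_ty", ] <- pelvis_traj$ty
  q["pelvis_tilt", ] <- pelvis_traj$tilt
  if (dofs3d) {
    q["pelvis_tz", ] <- pelvis_traj$tz
    q["pelvis_list", ] <- pelvis_traj$list
    q["pelvis_rotation", ] <- pelvis_traj$rot
    q["lumbar_extension", ] <- pelvis_traj$lumb_e
    q["lumbar_bending", ] <- pelvis_traj$lumb_b
  }
  # pelvis orientation (Z then X then Y as in the model)
  Rp <- rot_axis(c(0, 0, 1), pelvis_traj$tilt)
  if (dofs3d) {
    Rp <- rot_compose(Rp, rot_axis(c(1, 0, 0), pelvis_traj$list))
    Rp <- rot_compose(Rp, rot_axis(c(0, 1, 0), pelvis_traj$rot))
  }
  o <- rbind(pelvis_traj$tx, pelvis_traj$ty,
             if (dofs3d) pelvis_traj$tz else rep(0, Tn))
  for (side in c("r", "l")) {
    ft <- feet[[side]]
    hz <- if (side == "r") tpl$hip_z else -tpl$hip_z
    hip_w <- o + rot_apply(Rp, c(0, -tpl$hip_drop, hz))
    ank_w <- rbind(ft$x, ft$y, ft$z)
    d_w <- ank_w - hip_w
    d_p <- rot_apply_t(Rp, d_w)
    ik <- leg_ik(d_p, tpl, side, dofs3d)
    q[paste0("hip_flexion_", side), ] <- ik$hip
    if (dofs3d) q[paste0("hip_adduction_", side), ] <- ik$add
    q[paste0("knee_angle_", side), ] <- ik$knee
    # shank orientation for the level-foot ankle solve
    sgn <- if (side == "r") 1 else -1
    Rth <- rot_compose(Rp, rot_axis(c(0, 0, 1), ik$hip))
    if (dofs3d) Rth <- rot_compose(Rth, rot_axis(c(sgn, 0, 0), ik$add))
    Rsh <- rot_compose(Rth, rot_axis(c(0, 0, 1), ik$knee))
    aik <- ankle_ik(Rsh, side, dofs3d, pitch = ft$pitch)
    # level-foot ankle angles are meaningful only on the ground; fill the
    # swing gap with a smooth interpolant (the airborne foot orientation is
    # dynamically almost free, and foot levelling there would demand
    # extreme dorsiflexion that passively loads the plantarflexors)
    q[paste0("ankle_angle_", side), ] <- fill_swing(aik$ankle, ft$stance, s)
    if (dofs3d)
      q[paste0("subtalar_", side), ] <- fill_swing(aik$subtalar, ft$stance, s)
  }
  q
}

#' Replace swing-phase samples of a periodic channel by a cubic Hermite
#' interpolant matched to the stance boundary values and slopes
#' @noRd
fill_swing <- function(x, stance, s) {
  n <- length(x)
  x2 <- c(x[-n], x[-n]); st2 <- c(stance[-n], stance[-n])
  n1 <- n - 1
  runs <- rle(st2)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in which(!runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == 2 * n1) next   # handled by the shifted copy
    a <- i0 - 1; b <- i1 + 1            # stance anchors
    h <- (b - a)
    va <- x2[a]; vb <- x2[b]
    da <- x2[a] - x2[a - 1]
    db <- x2[b + 1] - x2[b]
    u <- (seq(i0, i1) - a) / h
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h11 <- u^3 - u^2
    fill <- h00 * va + h10 * (da * h) + h01 * vb + h11 * (db * h)
    # soft-clip interpolation overshoot (boundary values stay untouched)
    fill <- fill - softplus_pos(fill - 0.75, 0.04) +
      softplus_pos(-0.55 - fill, 0.04)
    x2[i0:i1] <- fill
  }
  out <- x2[1:n1]
  miss <- !stance[1:n1] & st2[1:n1] == stance[1:n1] & FALSE
  # prefer values from the copy where the first run was skipped
  wrap <- x2[(n1 + 1):(2 * n1)]
  first_run <- rle(stance[-n])
  if (!first_run$values[1]) {
    len <- first_run$lengths[1]
    out[seq_len(len)] <- wrap[seq_len(len)]
  }
  c(out, out[1])
}

#' Differentiate the coordinate trajectory (periodic channels spectrally)
#' @noRd
differentiate_q <- function(q, T_cycle, speed) {
  qd <- q * 0; qdd <- q * 0
  for (i in seq_len(nrow(q))) {
    x <- q[i, ]
    drift <- if (rownames(q)[i] == "pelvis_tx") speed else 0
    xp <- x - drift * seq(0, T_cycle, length.out = ncol(q))
    qd[i, ] <- periodic_derivative(xp, T_cycle, 1) + drift
    qdd[i, ] <- periodic_derivative(xp, T_cycle, 2)
  }
  list(qd = qd, qdd = qdd)
}

# ---------------------------------------------------------------------------
# ground-truth synergies

#' Ground-truth synergy basis for a fixture model (one side)
#'
#' Structured, field-plausible functional groupings; columns unit-norm.
#' @noRd
truth_synergy_W <- function(model, side) {
  mus <- names(model$muscles)
  mine <- mus[endsWith(mus, paste0("_", side))]
  base <- sub(paste0("_", side, "$"), "", mine)
  has_trunk <- any(base == "erector_spinae_1")
  W <- matrix(0, length(mine), 6, dimnames = list(mine, NULL))
  put <- function(k, weights) {
    for (nm in names(weights)) {
      i <- which(base == nm)
      if (length(i)) W[i, k] <<- weights[[nm]]
    }
  }
  put(1, list(glut_max = .55, vasti = .3, hamstrings = .15, tib_ant = .25,
              glut_med_ant = .35, glut_med_mid = .4, glut_med_post = .35,
              glut_min = .2, piriformis = .12, gemelli = .08))
  put(2, list(vasti = .5, rect_fem = .3, adductor = .45,
              quadratus_femoris = .4))
  put(3, list(soleus = .65, gastroc = .5, peroneus = .3, tib_post = .25))
  put(4, list(psoas_1 = .45, psoas_2 = .45, psoas_3 = .45, iliacus = .4,
              rect_fem = .15, tib_ant = .2,
              rectus_abd = .2, oblique_int = .2, oblique_ext = .2))
  put(5, list(hamstrings = .8, gastroc = .25, tib_ant = .3))
  if (has_trunk) {
    # a dedicated trunk synergy per side: the two sides together produce
    # pure lumbar extension, one side alone bends toward that side
    put(6, list(erector_spinae_1 = .4, erector_spinae_2 = .4,
                erector_spinae_3 = .3, multifidus_1 = .2, multifidus_2 = .2,
                quadratus_lumborum = .35))
  } else {
    put(6, list(tib_ant = .6))
  }
  nz <- sqrt(colSums(W^2)); nz[nz == 0] <- 1
  sweep(W, 2, nz, `/`)
}

#' Smooth periodic bump templates for the 6 synergy activations
#' @noRd
truth_synergy_C <- function(s, phase0 = 0) {
  bump <- function(center, width, amp) {
    d <- (s - phase0 - center) %% 1
    d <- pmin(d, 1 - d)
    amp * exp(-(d / width)^2)
  }
  rbind(
    bump(0.04, 0.08, 0.45),
    bump(0.14, 0.09, 0.40),
    bump(0.44, 0.08, 0.50),
    bump(0.62, 0.09, 0.40),
    bump(0.80, 0.10, 0.30) + bump(0.93, 0.08, 0.40),
    bump(0.05, 0.10, 0.30) + bump(0.55, 0.10, 0.30)
  )
}

# ---------------------------------------------------------------------------
# the generator

#' Generate a self-consistent synthetic gait dataset with known ground truth
#'
#' Builds a near-periodic treadmill-style walking cycle at the requested
#' speed for a fixture model: prescribed foot and pelvis trajectories with
#' exact leg inverse kinematics, foot-ground contact forces from the model's
#' own contact grids, a Gauss-Newton adjustment of the pelvis trajectory
#' (and stance micro-motion) that drives the pelvis residual loads to zero,
#' inverse-dynamics joint moments, muscle activations constructed from a
#' known 6-per-side synergy basis (scaled by non-negative least squares so
#' muscle moments reproduce the inverse-dynamics moments), and EMG obtained
#' by inverting each muscle's activation dynamics plus seeded noise.
#'
#' @param model A fixture model from [make_fixture()].
#' @param speed Average walking speed (m/s).
#' @param stride_time Gait-cycle period (s).
#' @param asymmetry list with `temporal` (left heel-strike phase offset from
#'   0.5, fraction of cycle) and `spatial` (left foot placement offset,
#'   fraction of stride).
#' @param stance_extra Extra lateral foot offset per side (m) widening the
#'   stance beyond the hip spacing (used e.g. to build physically informed
#'   post-surgery initial guesses).
#' @param trunk_lean Constant lumbar bending toward the operated side (rad)
#'   added to the trunk posture (3-D models only; the other half of the
#'   post-surgery compensation pattern).
#' @param noise list with `emg_mult` (multiplicative EMG noise sd),
#'   `emg_add` (additive EMG noise sd).
#' @param seed RNG seed; the same seed reproduces the bundle bit-identically.
#' @param n Samples per cycle (101 by convention).
#' @param gn_iter Gauss-Newton iterations for the residual-zeroing pass.
#' @param quiet Suppress progress output.
#' @return Object of class `gait_bundle`: ground-truth kinematics (`q`,
#'   `qd`, `qdd`), `tau` (inverse-dynamics generalized forces), `grf`,
#'   `activations`, `emg`, synergy ground truth (`W`, `C`), `events`,
#'   heel trajectories, diagnostics, and the model.
#' @export
generate_gait <- function(model, speed = 1.4, stride_time = 1.1,
                          asymmetry = list(temporal = 0, spatial = 0),
                          noise = list(emg_mult = 0.05, emg_add = 0.02),
                          stance_extra = 0, trunk_lean = 0,
                          seed = 1, n = 101, gn_iter = 120, quiet = TRUE) {
  tpl <- attr(model, "gait_template")
  if (is.null(tpl)) stop("model carries no gait template; use make_fixture()")
  tpl$foot_z <- tpl$hip_z + stance_extra
  asymmetry <- modifyList(list(temporal = 0, spatial = 0), asymmetry)
  noise <- modifyList(list(emg_mult = 0.05, emg_add = 0.02), noise)
  T_cycle <- stride_time
  L <- speed * stride_time
  s <- seq(0, 1, length.out = n)
  time <- s * T_cycle
  dofs3d <- tpl$dofs3d

  # ---- unknown parameter layout for the residual-zeroing pass:
  # pelvis (and lumbar) deviation channels are parameterised per sample
  # (periodic; the needed high-harmonic amplitudes are micrometres), foot
  # micro-slip by a low-harmonic Fourier basis plus stance drift, and the
  # contact depth / pitch-bias scalars.
  Kf <- 8
  nps <- n - 1
  layout <- list(tx = nps, ty = nps, tilt = nps)
  if (dofs3d) layout <- c(layout, list(tz = nps, list = nps, rot = nps,
                                       lumb_e = nps, lumb_b = nps))
  layout <- c(layout, list(foot_x_r = 2 * Kf, foot_x_l = 2 * Kf))
  if (dofs3d) layout <- c(layout, list(foot_z_r = 2 * Kf, foot_z_l = 2 * Kf))
  layout <- c(layout, list(sink = 1, drift_r = 1, drift_l = 1,
                           pbias_r = 1, pbias_l = 1))
  if (dofs3d) layout <- c(layout, list(zdrift_r = 1, zdrift_l = 1))
  nu <- sum(unlist(layout))
  unpack <- function(th) {
    out <- list(); i <- 1
    for (nm in names(layout)) {
      out[[nm]] <- th[i:(i + layout[[nm]] - 1)]
      i <- i + layout[[nm]]
    }
    out
  }

  build_state <- function(th) {
    p <- unpack(th)
    devs <- list(
      foot_x_r = fourier_eval(p$foot_x_r, s, const = FALSE),
      foot_x_l = fourier_eval(p$foot_x_l, s, const = FALSE),
      foot_z_r = if (dofs3d) fourier_eval(p$foot_z_r, s, const = FALSE) else 0,
      foot_z_l = if (dofs3d) fourier_eval(p$foot_z_l, s, const = FALSE) else 0,
      drift_r = p$drift_r, drift_l = p$drift_l,
      pbias_r = p$pbias_r, pbias_l = p$pbias_l,
      zdrift_r = if (dofs3d) p$zdrift_r else 0,
      zdrift_l = if (dofs3d) p$zdrift_l else 0)
    feet <- foot_targets(s, tpl, L, asymmetry, 1 + p$sink, devs)
    per <- function(v) c(v, v[1])   # periodic per-sample channel
    pelvis <- list(
      tx = -0.36 + speed * time + per(p$tx),
      ty = tpl$pelvis_ty0 + 0.012 * cos(4 * pi * s) + per(p$ty),
      tilt = per(p$tilt))
    if (dofs3d) {
      pelvis$tz <- per(p$tz)
      pelvis$list <- per(p$list)
      pelvis$rot <- per(p$rot)
      pelvis$lumb_e <- per(p$lumb_e)
      pelvis$lumb_b <- trunk_lean + per(p$lumb_b)
    }
    q <- assemble_q(model, tpl, s, n, pelvis, feet)
    der <- differentiate_q(q, T_cycle, speed)
    kin <- body_kinematics(model, q, der$qd, der$qdd)
    grf <- model_ground_reactions(model, kin)
    ext <- list()
    for (g in model$contact)
      ext[[g$segment]] <- grf[[g$side]][c("force", "moment")]
    tau <- inverse_dynamics(model, q, der$qd, der$qdd, ext, kin)
    list(q = q, qd = der$qd, qdd = der$qdd, kin = kin, grf = grf, tau = tau,
         feet = feet)
  }

  # per-group regularisation (N per unit coefficient): pelvis deviations may
  # reach centimetres; stance micro-slip must stay at millimetres (the
  # stick-slip law turns mm/s of slip into hundreds of newtons); constant
  # offsets of posture channels are pinned hard so the GN cannot wander into
  # a crouched local optimum.
  reg_w <- unlist(lapply(names(layout), function(nm) {
    n_ <- layout[[nm]]
    if (nm %in% c("tx", "ty", "tilt", "tz", "list", "rot",
                  "lumb_e", "lumb_b")) {
      rep(20, n_)
    } else if (startsWith(nm, "foot")) {
      # stick-slip friction turns high-frequency mm-scale stance motion
      # into huge shear forces; allow only low-harmonic propulsion/braking,
      # and keep lateral slip (whose moments whip the hip ab/adduction
      # demands) smoother still
      k <- rep(seq_len(n_ / 2), each = 2)
      2000 * k^2
    } else if (startsWith(nm, "drift") || startsWith(nm, "zdrift"))
      rep(50, n_)
    else if (startsWith(nm, "pbias")) rep(20, n_)
    else rep(10, n_)   # sink scale
  }))

  # curvature (periodic second-difference) penalties keep the per-sample
  # posture channels smooth: without them the solver balances the residuals
  # with high-frequency trunk/pelvis wobble whose inertial moments dwarf
  # the muscles
  per_sample <- intersect(names(layout),
                          c("tx", "ty", "tz", "tilt", "list", "rot",
                            "lumb_e", "lumb_b"))
  curv_w <- c(tx = 100, ty = 100, tz = 100, tilt = 600, list = 600,
              rot = 600, lumb_e = 600, lumb_b = 600)
  d2_periodic <- function(v) {
    nn <- length(v)
    v[c(2:nn, 1)] - 2 * v + v[c(nn, 1:(nn - 1))]
  }
  resid_fn <- function(th) {
    p <- unpack(th)
    st <- build_state(th)
    res <- residual_loads(model, st$tau)
    curv <- unlist(lapply(per_sample, function(nm)
      curv_w[[nm]] * d2_periodic(p[[nm]])))
    c(as.numeric(res), reg_w * th, curv)
  }

  fit <- chord_gauss_newton(resid_fn, numeric(nu),
                            n_jacobian = max(2, ceiling(gn_iter / 15)),
                            max_steps = 2 * gn_iter)
  st <- build_state(fit$par)
  resid <- residual_loads(model, st$tau)
  force_rows <- vapply(model$segments$pelvis$dofs, function(d)
    d$type == "trans", TRUE)
  resid_force_rms <- rms(resid[force_rows, ])
  resid_moment_rms <- rms(resid[!force_rows, ])

  # ---- impulse check
  Fy_tot <- st$grf$operated$force[2, ] + st$grf$non_operated$force[2, ]
  impulse_ratio <- trapz_int(time, Fy_tot) /
    (model_mass(model) * 9.80665 * T_cycle)

  # ---- activations from ground-truth synergies + NNLS moment matching
  act_idx <- actuated_dofs(model)
  arr <- muscle_moment_arrays(model, st$q, st$qd)
  mus_names <- names(model$muscles)
  Wr <- truth_synergy_W(model, "r")
  Wl <- truth_synergy_W(model, "l")
  W <- matrix(0, length(mus_names), 12,
              dimnames = list(mus_names,
                              c(paste0("syn_r", 1:6), paste0("syn_l", 1:6))))
  W[rownames(Wr), 1:6] <- Wr
  W[rownames(Wl), 7:12] <- Wl
  Ctmpl <- rbind(truth_synergy_C(s, 0),
                 truth_synergy_C(s, 0.5 + asymmetry$temporal))
  Mtarget <- st$tau[act_idx, , drop = FALSE] - arr$p[act_idx, , drop = FALSE]

  # per-node non-negative least squares: match the inverse-dynamics moments,
  # stay near the synergy-activation templates, and prefer the
  # low-activation route among near-exact solutions so that a = W C stays
  # inside [0, 1] (enforced by escalating penalties)
  sqrt_lam <- 2
  sqrt_mu <- 2
  C <- matrix(0, 12, n)
  for (t in seq_len(n)) {
    BW <- arr$B[act_idx, , t, drop = TRUE] %*% W
    A0 <- rbind(BW, diag(12) * sqrt_lam, sqrt_mu * W)
    b0 <- c(Mtarget[, t], sqrt_lam * Ctmpl[, t], numeric(nrow(W)))
    Ct <- pracma::lsqnonneg(A0, b0)$x
    rho <- 30
    for (k in 1:8) {
      viol <- which(W %*% Ct > 1.01)
      if (!length(viol)) break
      A <- rbind(A0, rho * W[viol, , drop = FALSE])
      b <- c(b0, rho * rep(1, length(viol)))
      Ct <- pracma::lsqnonneg(A, b)$x
      rho <- rho * 2.5
    }
    C[, t] <- Ct
  }
  a <- W %*% C
  clamp_frac <- mean(a > 1)
  a <- pmin(a, 1)
  Mach <- matrix(0, length(act_idx), n)
  for (t in seq_len(n))
    Mach[, t] <- arr$B[act_idx, , t, drop = TRUE] %*% a[, t] +
      arr$p[act_idx, t]
  moment_match_rms <- rms(Mach - st$tau[act_idx, , drop = FALSE])

  # ---- EMG by inverting activation dynamics + seeded noise
  set.seed(seed)
  dt_f <- 0.002
  tfine <- seq(0, T_cycle, by = dt_f)
  emg <- matrix(0, nrow(a), n, dimnames = dimnames(a))
  for (m in seq_len(nrow(a))) {
    a_per <- a[m, ]
    a_per[n] <- a_per[1]
    af <- spline(time, a_per, xout = tfine, method = "periodic")$y
    af <- pmin(pmax(af, 0), 1)
    ef <- activation_to_excitation(af, dt_f, model$muscles[[m]])
    e <- approx(tfine, ef, xout = time, rule = 2)$y
    e <- e * (1 + noise$emg_mult * rnorm(n)) + noise$emg_add * abs(rnorm(n))
    emg[m, ] <- pmin(pmax(e, 0), 1)
  }

  # ---- events and heel trajectories (ground truth)
  heel <- list()
  for (side in c("r", "l")) {
    b <- st$kin$bodies[[paste0("foot_", side)]]
    heel[[side]] <- b$o + rot_apply(b$R, tpl$heel_local)
  }
  flat_masks <- list(r = st$feet$r$flat, l = st$feet$l$flat)
  lphase <- 0.5 + asymmetry$temporal
  events <- list(
    operated = list(times = c(0, T_cycle),
                    heel_x = c(heel$r[1, 1], heel$r[1, 1] + L)),
    non_operated = list(times = lphase * T_cycle,
                        heel_x = heel$l[1, 1] + L * (0.5 + asymmetry$spatial) +
                          (heel$l[1, 1] - heel$l[1, 1])))
  # non-operated heel x at its strike: interpolate the trace
  idx <- which.min(abs(s - lphase))
  events$non_operated$heel_x <- heel$l[1, idx]

  structure(list(
    model = model, time = time, s = s, T_cycle = T_cycle, speed = speed,
    stride_length = L,
    q = st$q, qd = st$qd, qdd = st$qdd, tau = st$tau, grf = st$grf,
    activations = a, emg = emg, W = W, C = C, C_template = Ctmpl,
    events = events, heel = heel, flat = flat_masks,
    act_idx = act_idx,
    params = list(speed = speed, stride_time = stride_time,
                  asymmetry = asymmetry, noise = noise, seed = seed),
    diag = list(residual_force_rms = resid_force_rms,
                residual_moment_rms = resid_moment_rms,
                impulse_ratio = impulse_ratio,
                moment_match_rms = moment_match_rms,
                clamp_fraction = clamp_frac,
                gn_info = fit$info, gn_rss = fit$deviance)),
    class = "gait_bundle")
}

#' @export
print.gait_bundle <- function(x, ...) {
  cat("<gait_bundle>", x$model$name, " T =", x$T_cycle, "s, speed =",
      x$speed, "m/s\n")
  d <- x$diag
  cat(sprintf("  residual RMS: %.3g N / %.3g N m; GRF impulse ratio %.4f\n",
              d$residual_force_rms, d$residual_moment_rms, d$impulse_ratio))
  cat(sprintf("  synergy moment-match RMS: %.3g N m; clamped activations: %.2g%%\n",
              d$moment_match_rms, 100 * d$clamp_fraction))
  invisible(x)
}

#' Hide channels the study could not measure
#'
#' Emulates the experimental data gaps: EMG available only for the operated
#' (right) leg, none for the contralateral leg or the trunk. Optionally adds
#' seeded measurement noise to the inverse-dynamics moments.
#'
#' @param bundle A [generate_gait()] bundle.
#' @param drop Character vector among `"nonoperated_leg_emg"`,
#'   `"trunk_emg"`.
#' @param moment_sd Moment noise sd (N m); 0 disables.
#' @param seed RNG seed for the noise.
#' @return list with `observed` (emg subset, moments, kinematics, grf) and
#'   `manifest` (exactly which channels were hidden).
#' @export
degrade_to_observed <- function(bundle,
                                drop = c("nonoperated_leg_emg", "trunk_emg"),
                                moment_sd = 0, seed = 1) {
  mus <- names(bundle$model$muscles)
  trunk_groups <- c("erector_spinae", "multifidus", "quadratus_lumborum",
                    "oblique_int", "oblique_ext", "rectus_abd")
  is_trunk <- vapply(bundle$model$muscles, function(m)
    any(startsWith(m$group, trunk_groups)), TRUE)
  hidden <- rep(FALSE, length(mus))
  if ("nonoperated_leg_emg" %in% drop)
    hidden <- hidden | (endsWith(mus, "_l") & !is_trunk)
  if ("trunk_emg" %in% drop)
    hidden <- hidden | is_trunk
  tau <- bundle$tau
  if (moment_sd > 0) {
    set.seed(seed)
    tau <- tau + matrix(rnorm(length(tau), sd = moment_sd),
                        nrow(tau), ncol(tau))
  }
  list(observed = list(
    emg = bundle$emg[!hidden, , drop = FALSE],
    moments = tau,
    q = bundle$q, qd = bundle$qd, qdd = bundle$qdd,
    grf = bundle$grf, time = bundle$time),
    manifest = list(hidden_channels = mus[hidden],
                    observed_channels = mus[!hidden],
                    moment_sd = moment_sd, seed = seed))
}

#' Gait measures computed from a bundle via event detection
#'
#' Tiles the generated cycle periodically over two cycles, detects heel
#' strikes from each foot's vertical GRF, reads heel positions from the
#' (periodically advanced) heel trajectories, and computes the
#' spatiotemporal measures.
#'
#' @param bundle A [generate_gait()] bundle.
#' @param threshold Heel-strike force threshold (N).
#' @return Output of [spatiotemporal_from_events()].
#' @export
measures_from_bundle <- function(bundle, threshold = 20) {
  n <- length(bundle$time)
  Tc <- bundle$T_cycle
  L <- bundle$stride_length
  tile_t <- c(bundle$time[-n], bundle$time[-n] + Tc, 2 * Tc)
  tile <- function(x, adv = 0) c(x[-n], x[-n] + adv, x[1] + 2 * adv)
  ev <- list()
  sides <- c(operated = "operated", non_operated = "non_operated")
  foot_of <- c(operated = "r", non_operated = "l")
  for (sd_ in names(sides)) {
    fy <- tile(bundle$grf[[sd_]]$force[2, ])
    hx <- tile(bundle$heel[[foot_of[[sd_]]]][1, ], adv = L)
    hs <- detect_heel_strikes(tile_t, fy, threshold = threshold)
    ev[[sd_]] <- list(times = hs,
                      heel_x = approx(tile_t, hx, xout = hs, rule = 2)$y)
  }
  heel_z <- list(operated = bundle$heel$r[3, ],
                 non_operated = bundle$heel$l[3, ],
                 flat_operated = bundle$flat$r,
                 flat_non_operated = bundle$flat$l)
  spatiotemporal_from_events(ev, heel_z = heel_z)
}
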