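#' Spatial gait symmetry
#'
#' Operated-side step length divided by stride length; 0.5 is perfect
#' symmetry. Note the printed clinical convention states that a LONGER
#' operated step gives a value BELOW 0.5, which is internally inconsistent
#' with the ratio as defined; the ratio is implemented as defined and the
#' convention note is documentation only.
#'
#' @param operated_step_length Operated-side step length (m).
#' @param stride_length Stride length (m, > 0).
#' @return Unitless ratio.
#' @export
spatial_symmetry <- function(operated_step_length, stride_length) {
  if (any(stride_length <= 0)) stop("stride length must be positive")
  operated_step_length / stride_length
}

#' Temporal gait symmetry
#'
#' Operated-side step time divided by stride time; 0.5 is perfect symmetry.
#' @param operated_step_time Operated-side step time (s).
#' @param stride_time Stride time (s, > 0).
#' @return Unitless ratio.
#' @export
temporal_symmetry <- function(operated_step_time, stride_time) {
  if (any(stride_time <= 0)) stop("stride time must be positive")
  operated_step_time / stride_time
}

#' Cost of transport
#'
#' Metabolic energy expended per unit body mass per unit distance.
#' @param metabolic_cost Energy per cycle (J).
#' @param body_mass Body mass (kg, > 0).
#' @param distance Distance travelled over the cycle (m, > 0).
#' @return J/(kg m).
#' @export
cost_of_transport <- function(metabolic_cost, body_mass, distance) {
  if (any(body_mass <= 0) || any(distance <= 0))
    stop("body mass and distance must be positive")
  metabolic_cost / (body_mass * distance)
}

#' Spatiotemporal gait metrics from events
#'
#' Stride/step lengths and times from heel-strike events of both feet, plus
#' stance width from lateral heel separation during double-foot-flat
#' samples. The operated-side step runs from the preceding non-operated
#' heel strike to the operated heel strike. Forward is x, lateral is z.
#'
#' @param events list with `operated` and `non_operated`, each a list with
#'   `times` (heel-strike times, >= 2 for the ipsilateral side) and
#'   `heel_x` (forward heel positions at those events).
#' @param heel_z Optional list with `operated`, `non_operated` lateral heel
#'   position traces and `flat_operated`, `flat_non_operated` (logical
#'   foot-flat masks per side) for stance width: the lateral separation is
#'   taken between each foot's mean heel position over its own foot-flat
#'   window (with rockered feet the two feet are never flat simultaneously).
#' @param belt_speed Treadmill belt speed (m/s); 0 for overground. Belt
#'   compensation adds `belt_speed * dt` to forward displacements.
#' @return list of metrics: `stride_length`, `stride_time`, `step_length`
#'   and `step_time` per side, `stance_width`, `spatial_symmetry`,
#'   `temporal_symmetry`.
#' @export
spatiotemporal_from_events <- function(events, heel_z = NULL, belt_speed = 0) {
  op <- events$operated; no <- events$non_operated
  if (length(op$times) < 2) stop("need at least 2 operated-side heel strikes")
  t0 <- op$times[1]; t1 <- op$times[2]
  stride_time <- t1 - t0
  stride_length <- (op$heel_x[2] - op$heel_x[1]) + belt_speed * stride_time
  # contralateral event inside the cycle
  in_cycle <- which(no$times > t0 & no$times < t1)
  if (!length(in_cycle)) {
    warning("no contralateral heel strike inside the cycle; step metrics undefined")
    step <- list(operated = NA_real_, non_operated = NA_real_)
    stept <- list(operated = NA_real_, non_operated = NA_real_)
  } else {
    ic <- in_cycle[1]
    tc <- no$times[ic]; xc <- no$heel_x[ic]
    # non-operated step: operated HS -> non-operated HS
    stept <- list(operated = t1 - tc, non_operated = tc - t0)
    step <- list(operated = (op$heel_x[2] - xc) + belt_speed * (t1 - tc),
                 non_operated = (xc - op$heel_x[1]) + belt_speed * (tc - t0))
  }
  stance_width <- NA_real_
  if (!is.null(heel_z)) {
    fo <- heel_z$flat_operated %||% heel_z$flat
    fn <- heel_z$flat_non_operated %||% heel_z$flat
    if (any(fo) && any(fn)) {
      stance_width <- abs(mean(heel_z$operated[fo]) -
                            mean(heel_z$non_operated[fn]))
    }
  }
  list(stride_length = stride_length, stride_time = stride_time,
       step_length = step, step_time = stept, stance_width = stance_width,
       spatial_symmetry = spatial_symmetry(step$operated, stride_length),
       temporal_symmetry = temporal_symmetry(stept$operated, stride_time))
}

#' Muscle metabolic model specification
#'
#' Coefficients of the Bhargava-style muscle energetics model plus the
#' constants that derive muscle mass from strength
#' (`mass = rho * (f_max / sigma) * l_opt`).
#'
#' @param sigma Specific tension (Pa).
#' @param rho Muscle density (kg/m^3).
#' @param frac_slow Slow-twitch fiber fraction (recruitment model).
#' @param decay_act,decay_maint Activation / maintenance heat coefficients
#'   (W/kg) for slow and fast fibers, `c(slow, fast)`.
#' @param basal Basal heat rate (W/kg body mass); 0 disables it.
#' @return Object of class `metabolic_spec`.
#' @export
metabolic_spec <- function(sigma = 0.25e6, rho = 1059.7, frac_slow = 0.5,
                           decay_act = c(40, 133), decay_maint = c(74, 111),
                           basal = 0) {
  stopifnot(sigma > 0, rho > 0, frac_slow >= 0, frac_slow <= 1)
  structure(list(sigma = sigma, rho = rho, frac_slow = frac_slow,
                 decay_act = decay_act, decay_maint = decay_maint,
                 basal = basal),
            class = "metabolic_spec")
}

#' Maintenance-heat fiber-length dependence (piecewise linear)
#' @noRd
maintenance_length_scale <- function(lnorm) {
  ifelse(lnorm <= 0.5, 0.5,
         ifelse(lnorm <= 1, lnorm,
                ifelse(lnorm <= 1.5, -2 * lnorm + 3, 0)))
}

#' Muscle metabolic cost over a cycle (Bhargava-style)
#'
#' Per-muscle instantaneous rate = activation heat + maintenance heat +
#' shortening/lengthening heat + positive mechanical work rate; total cost
#' is the time integral over the cycle summed over muscles. Muscle mass is
#' `rho * (f_max/sigma) * l_opt`.
#'
#' @param model A [walker_model()].
#' @param q,qd nDOF x T kinematics over the cycle.
#' @param a nMuscle x T activations.
#' @param time Time vector (s, length T).
#' @param spec A [metabolic_spec()].
#' @param body_mass Total body mass (kg), used only for the basal term.
#' @return list with `total` (J per cycle), `rate` (nMuscle x T W),
#'   `per_muscle` (J).
#' @export
metabolic_cost <- function(model, q, qd, a, time, spec = metabolic_spec(),
                           body_mass = model_mass(model)) {
  q <- as.matrix(q); qd <- as.matrix(qd); a <- as.matrix(a)
  Tn <- ncol(q)
  if (ncol(a) != Tn || length(time) != Tn) stop("dimension mismatch")
  nm <- length(model$muscles)
  curves <- model$curves
  rate <- matrix(0, nm, Tn, dimnames = list(names(model$muscles), NULL))
  per_muscle <- numeric(nm)
  fs <- spec$frac_slow; ff <- 1 - fs
  for (m in seq_len(nm)) {
    mus <- model$muscles[[m]]
    g <- mus$geometry
    geo <- mtu_length_and_moment_arms(g, q)
    v_mt <- mtu_velocity(geo$moment_arms, qd[g$dofs, , drop = FALSE])
    st <- rigid_tendon_state(mus, geo$length, v_mt)
    if (is.null(st$vnorm) || length(st$vnorm) != Tn)
      stop("missing fiber-velocity trace for muscle ", mus$name)
    mass <- spec$rho * (mus$f_max / spec$sigma) * mus$l_opt
    u <- a[m, ]
    # activation heat (recruitment-weighted slow/fast decay)
    h_act <- mass * (spec$decay_act[1] * fs * sin(pi / 2 * u) +
                       spec$decay_act[2] * ff * (1 - cos(pi / 2 * u)))
    # maintenance heat with fiber-length dependence
    h_mnt <- mass * maintenance_length_scale(st$lnorm) *
      (spec$decay_maint[1] * fs * sin(pi / 2 * u) +
         spec$decay_maint[2] * ff * (1 - cos(pi / 2 * u)))
    # shortening/lengthening heat: alpha * (-v_fiber)
    fl <- curves$fl_active(st$lnorm)
    fv <- curves$fv(st$vnorm / curves$vmax)
    F_ce <- mus$f_max * u * fl * fv            # fiber (contractile) force
    F_iso <- mus$f_max * u * fl                # isometric force at this a, l
    v_fiber <- st$vnorm * mus$l_opt            # m/s, + lengthening
    alpha <- ifelse(v_fiber <= 0, 0.16 * F_iso + 0.18 * F_ce, 0.157 * F_ce)
    h_sl <- -alpha * v_fiber
    # positive mechanical work rate of the fiber
    w_pos <- pmax(0, -F_ce * v_fiber)
    r <- h_act + h_mnt + h_sl + w_pos
    r <- pmax(r, 0)
    rate[m, ] <- r
    per_muscle[m] <- trapz_int(time, r)
  }
  total <- sum(per_muscle)
  if (spec$basal > 0)
    total <- total + spec$basal * body_mass * (time[Tn] - time[1])
  list(total = total, rate = rate,
       per_muscle = setNames(per_muscle, names(model$muscles)))
}

#' @noRd
trapz_int <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Clinical gait measures for one walking cycle
#'
#' Assembles the comparison-table schema: cost of transport, metabolic cost,
#' spatial/temporal symmetry, stance width, stride length, stride time.
#'
#' @param st Output of [spatiotemporal_from_events()].
#' @param metabolic Output of [metabolic_cost()] (or NULL to skip).
#' @param body_mass Body mass (kg).
#' @param condition Label for the condition column.
#' @param psoas_strength Psoas strength as fraction of pre-surgery.
#' @return Object of class `gait_measures` (a one-row data.frame).
#' @export
gait_measures <- function(st, metabolic = NULL, body_mass,
                          condition = "pre_surgery", psoas_strength = 1) {
  e <- if (is.null(metabolic)) NA_real_ else metabolic$total
  cot <- if (is.null(metabolic)) NA_real_ else
    cost_of_transport(e, body_mass, st$stride_length)
  out <- data.frame(
    condition = condition,
    psoas_strength = psoas_strength,
    cost_of_transport = cot,
    metabolic_cost = e,
    spatial_symmetry = st$spatial_symmetry,
    temporal_symmetry = st$temporal_symmetry,
    stance_width = st$stance_width,
    stride_length = st$stride_length,
    stride_time = st$stride_time
  )
  class(out) <- c("gait_measures", "data.frame")
  out
}

#' @export
print.gait_measures <- function(x, ...) {
  cat("<gait_measures>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
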