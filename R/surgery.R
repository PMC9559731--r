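#' Surgical scenario
#'
#' A virtual internal-hemipelvectomy scenario: the operated-side muscles
#' resected (worst case: no remaining biomechanical function) and the
#' retained psoas strength as a fraction of its pre-surgery value
#' (0 removes it, 0.5 weakens, 1 maintains, 1.5 strengthens).
#'
#' @param removed Muscle names removed from the operated side (default:
#'   resolved against the model by [apply_surgery()] via
#'   [default_resection_list()]).
#' @param psoas_factor Ipsilateral psoas strength factor (>= 0).
#' @param side Operated side label.
#' @return Object of class `surgical_scenario`.
#' @export
surgical_scenario <- function(removed = NULL, psoas_factor = 1,
                              side = "operated", removed_strength = 0) {
  stopifnot(psoas_factor >= 0, removed_strength >= 0, removed_strength <= 1)
  structure(list(removed = removed, psoas_factor = psoas_factor,
                 side = side, removed_strength = removed_strength),
            class = "surgical_scenario")
}

#' @export
print.surgical_scenario <- function(x, ...) {
  cat("<surgical_scenario> psoas", sprintf("%d%%", round(100 * x$psoas_factor)),
      " removed:", length(x$removed %||% character(0)), "muscles\n")
  invisible(x)
}

#' Apply a surgical scenario to a model
#'
#' Removes the listed operated-side muscles from the actuator set and
#' scales the ipsilateral psoas peak isometric strength; a factor of zero
#' removes the psoas heads as well. The contralateral side is untouched and
#' the input model is not modified. A non-zero `removed_strength` keeps the
#' resected muscles at that fraction of their strength instead (the
#' partial-function reattachment hook; the worst-case default removes them
#' outright), which also serves as the continuation path for the
#' post-surgery solves.
#'
#' @param model A [walker_model()].
#' @param scenario A [surgical_scenario()].
#' @return A new [walker_model()] with the post-surgery actuator set.
#' @export
apply_surgery <- function(model, scenario) {
  removed <- scenario$removed %||% default_resection_list(model)
  unknown <- setdiff(removed, names(model$muscles))
  if (length(unknown)) {
    near <- unlist(lapply(unknown, function(u)
      agrep(u, names(model$muscles), max.distance = 0.3, value = TRUE)))
    stop("unknown muscle(s) in scenario: ", paste(unknown, collapse = ", "),
         if (length(near)) paste0("; did you mean: ",
                                  paste(unique(near), collapse = ", "), "?"))
  }
  side_of <- vapply(model$muscles, `[[`, "", "side")
  not_operated <- removed[side_of[removed] != scenario$side]
  if (length(not_operated))
    stop("scenario removes non-operated muscles: ",
         paste(not_operated, collapse = ", "))
  m2 <- model
  if (scenario$removed_strength > 0) {
    for (nm in removed)
      m2$muscles[[nm]]$f_max <- m2$muscles[[nm]]$f_max *
        scenario$removed_strength
  } else {
    m2$muscles <- m2$muscles[setdiff(names(m2$muscles), removed)]
  }
  psoas <- names(m2$muscles)[vapply(m2$muscles, function(m)
    startsWith(m$group, "psoas") && m$side == scenario$side, TRUE)]
  if (scenario$psoas_factor == 0) {
    m2$muscles <- m2$muscles[setdiff(names(m2$muscles), psoas)]
  } else {
    for (nm in psoas)
      m2$muscles[[nm]]$f_max <- m2$muscles[[nm]]$f_max * scenario$psoas_factor
  }
  attr(m2, "scenario") <- scenario
  m2
}

#' Restrict a synergy weight matrix to a post-surgery muscle set
#'
#' @param W Pre-surgery weight matrix (rows named by muscle).
#' @param model Post-surgery [walker_model()].
#' @return W with only the remaining muscles' rows.
#' @export
restrict_synergy_weights <- function(W, model) {
  W[names(model$muscles), , drop = FALSE]
}

#' Run the post-surgery treatment sweep
#'
#' For each scenario: applies the virtual surgery, solves the post-surgery
#' prediction problem (free final time, activation bounds, synergy
#' activations tracked to the pre-surgery solution) with multi-start, and
#' computes the clinical gait measures. Emits a comparison table in the
#' standard schema (condition, psoas strength, cost of transport, metabolic
#' cost, symmetries, stance width, stride length/time) plus RMS-difference
#' reports of joint angles and moments against the pre-surgery solution.
#' Non-convergence of an individual scenario is recorded and the sweep
#' continues.
#'
#' @param model Pre-surgery [walker_model()].
#' @param bundle Reference cycle ([generate_gait()] bundle).
#' @param pre_solution Pre-surgery prediction solution ([solve_ocp()]).
#' @param scenarios List of [surgical_scenario()]s.
#' @param seeds Multi-start seeds per scenario.
#' @param N Mesh intervals.
#' @param max_iter,n_outer Solver budget.
#' @param body_mass Body mass (kg) for the measures.
#' @return list with `results` (one `treatment_result` per scenario),
#'   `comparison` (data.frame in the standard comparison schema), `rms_angles`,
#'   `rms_moments` (data.frames of RMS differences vs pre-surgery).
#' @export
run_treatment_sweep <- function(model, bundle, pre_solution, scenarios,
                                seeds = 1, N = pre_solution$spec$N,
                                max_iter = 30, n_outer = 1,
                                continuation = numeric(0),
                                body_mass = model_mass(model)) {
  results <- list()
  comp <- NULL
  rms_ang <- NULL; rms_mom <- NULL
  pre_measures <- solution_measures(pre_solution, bundle,
                                    condition = "pre_surgery",
                                    psoas_strength = 1,
                                    body_mass = body_mass)
  comp <- rbind(comp, pre_measures)
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    solve_stage <- function(stage_sc, from_ref, iters, use_multistart) {
      post_model <- apply_surgery(model, stage_sc)
      attr(post_model, "gait_template") <- attr(model, "gait_template")
      targets <- bundle
      targets$model <- post_model
      targets$W <- restrict_synergy_weights(bundle$W, post_model)
      # synergy-activation targets come from the pre-surgery solution
      targets$C <- pre_solution$C
      targets$q <- from_ref$q
      targets$qd <- from_ref$qd
      targets$qdd <- from_ref$qdd
      targets$tau <- from_ref$tau
      targets$T_cycle <- from_ref$T %||% from_ref$T_cycle
      spec <- ocp_spec("treatment_predict", N = N,
                       speed = bundle$speed,
                       T_bounds = pre_solution$T * c(0.85, 1.15),
                       weights = pre_solution$spec$weights)
      problem <- transcribe(spec, post_model, targets)
      if (use_multistart)
        solve_ocp_multistart(problem, seeds = seeds, from = targets,
                             max_iter = iters, n_outer = n_outer)
      else solve_ocp(problem, guess = ocp_initial_guess(problem,
                                                        from = targets),
                     max_iter = iters, n_outer = n_outer)
    }
    # continuation: solve with the resected muscles progressively weakened
    # (partial-function strengths) before removing them outright, chaining
    # each stage's solution into the next stage's initial guess
    ref <- pre_solution
    for (fr in continuation) {
      stage_sc <- sc
      stage_sc$removed_strength <- fr
      stage <- solve_stage(stage_sc, ref, max_iter, FALSE)
      ref <- stage
    }
    sol <- solve_stage(sc, ref, max_iter, TRUE)
    res <- structure(list(scenario = sc, status = sol$status,
                          solution = sol,
                          measures = NULL),
                     class = "treatment_result")
    if (sol$status == "success") {
      res$measures <- solution_measures(sol, bundle,
                                        condition = "post_surgery",
                                        psoas_strength = sc$psoas_factor,
                                        body_mass = body_mass)
      comp <- rbind(comp, res$measures)
      ra <- rms_diff_report(sol$q, pre_solution$q, model$dof_names,
                            scale = 180 / pi)
      rm_ <- rms_diff_report(sol$tau, pre_solution$tau, model$dof_names)
      lab <- sprintf("%d%% Fmax", round(100 * sc$psoas_factor))
      ra$condition <- lab; rm_$condition <- lab
      rms_ang <- rbind(rms_ang, ra)
      rms_mom <- rbind(rms_mom, rm_)
    }
    results[[i]] <- res
  }
  list(results = results, comparison = comp,
       rms_angles = rms_ang, rms_moments = rms_mom)
}

#' @export
print.treatment_result <- function(x, ...) {
  cat("<treatment_result> psoas",
      sprintf("%d%%", round(100 * x$scenario$psoas_factor)),
      " status:", x$status, "\n")
  if (!is.null(x$measures)) print(x$measures)
  invisible(x)
}

#' RMS differences between two trajectories, per channel
#' @noRd
rms_diff_report <- function(x, ref, names, scale = 1) {
  stopifnot(nrow(x) == nrow(ref))
  data.frame(channel = names,
             rms_difference = apply((x - ref) * scale, 1, rms))
}

#' Clinical gait measures of an optimal-control solution
#'
#' Detects gait events from the solution's own ground reactions (tiled over
#' two cycles), reads heel trajectories from forward kinematics, and
#' assembles metabolic cost and the comparison-schema measures.
#'
#' @param sol An `ocp_solution`.
#' @param bundle Reference bundle (only for the foot-flat template
#'   geometry).
#' @param condition,psoas_strength Labels for the measures row.
#' @param body_mass Body mass (kg).
#' @param met_spec A [metabolic_spec()].
#' @return A [gait_measures()] row.
#' @export
solution_measures <- function(sol, bundle, condition = "solution",
                              psoas_strength = 1,
                              body_mass = model_mass(sol$model),
                              met_spec = metabolic_spec()) {
  model <- sol$model
  M <- ncol(sol$q)
  Tc <- sol$T
  tpl <- attr(model, "gait_template") %||% attr(bundle$model, "gait_template")
  kin <- body_kinematics(model, sol$q, sol$qd)
  heel <- list()
  for (side in c("r", "l")) {
    bkin <- kin$bodies[[paste0("foot_", side)]]
    heel[[side]] <- bkin$o + rot_apply(bkin$R, tpl$heel_local)
  }
  L <- sol$q["pelvis_tx", M] - sol$q["pelvis_tx", 1]
  tile_t <- c(sol$time[-M], sol$time[-M] + Tc, 2 * Tc)
  tile <- function(x, adv = 0) c(x[-M], x[-M] + adv, x[1] + 2 * adv)
  foot_of <- c(operated = "r", non_operated = "l")
  ev <- list()
  for (sd_ in names(foot_of)) {
    fy <- tile(sol$grf[[sd_]]$force[2, ])
    hx <- tile(heel[[foot_of[[sd_]]]][1, ], adv = L)
    hs <- detect_heel_strikes(tile_t, fy, threshold = 20)
    ev[[sd_]] <- list(times = hs,
                      heel_x = approx(tile_t, hx, xout = hs, rule = 2)$y)
  }
  # foot-flat: sole level and loaded
  flat_mask <- function(side, sd_) {
    bkin <- kin$bodies[[paste0("foot_", side)]]
    pitch <- asin(pmin(pmax(-bkin$R[2, 1, ], -1), 1))
    loaded <- sol$grf[[sd_]]$force[2, ] >
      0.3 * body_mass * 9.80665
    abs(pitch) < 0.05 & loaded
  }
  heel_z <- list(operated = heel$r[3, ], non_operated = heel$l[3, ],
                 flat_operated = flat_mask("r", "operated"),
                 flat_non_operated = flat_mask("l", "non_operated"))
  st <- spatiotemporal_from_events(ev, heel_z = heel_z)
  met <- metabolic_cost(model, sol$q, sol$qd, sol$activations, sol$time,
                        spec = met_spec, body_mass = body_mass)
  gait_measures(st, metabolic = met, body_mass = body_mass,
                condition = condition, psoas_strength = psoas_strength)
}
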