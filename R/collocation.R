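#' Optimal control problem specification
#'
#' One of the direct-collocation problem formulations used for model
#' personalization and treatment prediction:
#' \describe{
#'   \item{contact_calibration}{Track joint angles and ground reactions with
#'     foot-ground contact parameters as static unknowns.}
#'   \item{neural_calibration}{Track angles, ground reactions, moments and
#'     activations with the synergy vector weights as static unknowns
#'     (unit-magnitude synergy vectors enforced).}
#'   \item{verification_track}{Track angles, ground reactions, moments and
#'     activations with fixed final time.}
#'   \item{verification_predict}{Track only the synergy activations (and
#'     trunk angles) with free final time.}
#'   \item{treatment_predict}{As verification_predict after virtual surgery,
#'     with muscle activations bounded in \[0, 1\].}
#' }
#' All formulations satisfy skeletal dynamics (zero pelvis residual loads),
#' match inverse-dynamics moments at muscle-actuated coordinates using
#' synergy-constructed activations, minimize joint jerk, and enforce
#' joint-angle (and ground-reaction) periodicity.
#'
#' @param kind Problem kind (see above).
#' @param N Number of mesh intervals (Hermite-Simpson, compressed).
#' @param weights Named list overriding default cost weights: `q_track`,
#'   `grf_track`, `mom_track`, `act_track`, `c_track`, `jerk`.
#' @param free_time Free final time (defaults by kind).
#' @param speed Average forward speed target (m/s) for free-time problems.
#' @param activation_bounds Enforce a in \[0, 1\] as a path constraint
#'   (defaults TRUE for treatment_predict).
#' @param T_bounds Final-time bounds (s) for free-time problems.
#' @param feas_tol Named list of feasibility tolerances: `resid_force` (N),
#'   `resid_moment` (N m), `moment_match` (N m), `periodicity` (rad).
#' @param penalty Named list of constraint penalty weights.
#' @return Object of class `ocp_spec`.
#' @export
ocp_spec <- function(kind = c("verification_track", "verification_predict",
                              "treatment_predict", "neural_calibration",
                              "contact_calibration"),
                     N = 15, weights = list(), free_time = NULL,
                     speed = 1.4, activation_bounds = NULL,
                     T_bounds = c(0.5, 2.0),
                     feas_tol = list(), penalty = list()) {
  kind <- match.arg(kind)
  stopifnot(N >= 10)
  w <- modifyList(list(q_track = 5, grf_track = 2, mom_track = 0.5,
                       act_track = 2, c_track = 2, jerk = 2e-5,
                       reserve = 0.1), weights)
  stopifnot(all(unlist(w) >= 0))
  if (is.null(free_time))
    free_time <- kind %in% c("verification_predict", "treatment_predict")
  if (is.null(activation_bounds))
    activation_bounds <- kind == "treatment_predict"
  tol <- modifyList(list(resid_force = 1, resid_moment = 1,
                         moment_match = 2.5, periodicity = 1e-3),
                    feas_tol)
  pen <- modifyList(list(resid = 0.5, mom = 0.5, resid_mid = 0,
                         bound = 100, per_q = 300,
                         per_qd = 30, per_grf = 0.5, speed = 1000,
                         norm_w = 100), penalty)
  structure(list(kind = kind, N = N, weights = w, free_time = free_time,
                 speed = speed, activation_bounds = activation_bounds,
                 T_bounds = T_bounds, feas_tol = tol, penalty = pen),
            class = "ocp_spec")
}

#' @export
print.ocp_spec <- function(x, ...) {
  cat("<ocp_spec>", x$kind, " N =", x$N,
      if (x$free_time) "(free final time)" else "(fixed final time)", "\n")
  invisible(x)
}

#' Which cost terms each problem kind tracks
#' @noRd
kind_tracks <- function(kind) {
  switch(kind,
    contact_calibration = c("q", "grf"),
    neural_calibration = c("q", "grf", "mom", "act"),
    verification_track = c("q", "grf", "mom", "act"),
    verification_predict = c("c", "trunk"),
    treatment_predict = c("c", "trunk"))
}

#' Resample 101-point cycle targets onto the mesh nodes
#' @noRd
resample_targets <- function(x, M) {
  if (is.null(x)) return(NULL)
  x <- as.matrix(x)
  n <- ncol(x)
  s_in <- seq(0, 1, length.out = n)
  s_out <- seq(0, 1, length.out = M)
  t(apply(x, 1, function(row) spline(s_in, row, xout = s_out)$y))
}

#' Band-limited (truncated Fourier) evaluation of periodic cycle channels
#'
#' Fits each row (linear drift plus harmonics up to `K`) on the fine grid
#' and evaluates value and time-derivatives on the mesh. Keeping the whole
#' state seed consistent with one band-limited trajectory is what makes the
#' Hermite-Simpson defects of the seed small: interpolating the fine grid
#' directly aliases the high-harmonic content and violates the defects
#' badly.
#' @return list of matrices: `f`, `d1`, `d2`, `d3` (rows x M).
#' @noRd
fourier_resample <- function(x, M, T_per, K) {
  x <- as.matrix(x)
  n1 <- ncol(x) - 1
  s_out <- seq(0, 1, length.out = M)
  K <- min(K, n1 %/% 2 - 1)
  w0 <- 2 * pi / T_per
  out <- list(f = NULL, d1 = NULL, d2 = NULL, d3 = NULL)
  for (nm in names(out)) out[[nm]] <- matrix(0, nrow(x), M)
  for (i in seq_len(nrow(x))) {
    drift <- x[i, n1 + 1] - x[i, 1]
    xp <- x[i, seq_len(n1)] - drift * (seq_len(n1) - 1) / n1
    cf <- fft(xp) / n1
    f <- rep(Re(cf[1]), M) + drift * s_out
    d1 <- rep(drift / T_per, M); d2 <- numeric(M); d3 <- numeric(M)
    for (k in seq_len(K)) {
      ak <- 2 * Re(cf[k + 1]); bk <- -2 * Im(cf[k + 1])
      ph <- 2 * pi * k * s_out
      wk <- w0 * k
      f <- f + ak * cos(ph) + bk * sin(ph)
      d1 <- d1 + wk * (-ak * sin(ph) + bk * cos(ph))
      d2 <- d2 + wk^2 * (-ak * cos(ph) - bk * sin(ph))
      d3 <- d3 + wk^3 * (ak * sin(ph) - bk * cos(ph))
    }
    out$f[i, ] <- f; out$d1[i, ] <- d1; out$d2[i, ] <- d2; out$d3[i, ] <- d3
  }
  out
}

#' Transcribe an optimal control problem
#'
#' Builds the nonlinear program for a [ocp_spec()]: decision variables are
#' the coordinate positions, velocities and accelerations at the mesh nodes,
#' the joint jerk controls, the synergy activation controls, any static
#' parameters, and the final time when free. Defect constraints apply the
#' compressed Hermite-Simpson rule to the triple-integrator (jerk-chain)
#' dynamics and are exactly linear in the variables; skeletal-dynamics
#' residuals, synergy moment matching, activation bounds and tracking terms
#' are node-local nonlinear residuals.
#'
#' @param spec A [ocp_spec()].
#' @param model A [walker_model()].
#' @param targets list with the reference cycle: `T_cycle`, `W` (synergy
#'   weight matrix, muscles x 2k), and the tracked channels `q`, `grf`
#'   (list per side with `force`), `moments`, `activations`, `C` on the
#'   101-point grid (a [generate_gait()] bundle works directly).
#' @return Problem object of class `ocp_problem` with index maps, residual
#'   functions, and an initial-guess builder.
#' @export
transcribe <- function(spec, model, targets) {
  d <- length(model$dofs)
  M <- spec$N + 1
  nsyn <- ncol(targets$W)
  W <- as.matrix(targets$W)
  if (nrow(W) != length(model$muscles))
    stop("synergy weight matrix does not match the model muscle set")
  act_idx <- actuated_dofs(model)
  nact <- length(act_idx)
  root_idx <- match(vapply(model$segments$pelvis$dofs, `[[`, "", "name"),
                    model$dof_names)
  # non-root coordinates without any spanning muscle carry an explicit
  # reserve torque control (penalised in the cost): without it they would
  # be free ideal actuators the optimizer can exploit
  unact_idx <- setdiff(seq_len(d), c(act_idx, root_idx))
  nres <- length(unact_idx)
  tx_idx <- match("pelvis_tx", model$dof_names)
  ns <- if (spec$kind == "contact_calibration") 3L else 0L
  # variable layout (column-major by node inside each block)
  nx_nodes <- 3 * d * M
  nu <- d * M
  nc <- nsyn * M
  nr <- nres * M
  nvar <- nx_nodes + nu + nc + nr + ns + as.integer(spec$free_time)
  idx <- list(
    statics = if (ns) nx_nodes + nu + nc + nr + seq_len(ns) else integer(0),
    T = if (spec$free_time) nvar else integer(0)
  )
  unpack <- function(X) {
    list(q = matrix(X[seq_len(d * M)], d, M,
                    dimnames = list(model$dof_names, NULL)),
         qd = matrix(X[d * M + seq_len(d * M)], d, M),
         qdd = matrix(X[2 * d * M + seq_len(d * M)], d, M),
         u = matrix(X[3 * d * M + seq_len(d * M)], d, M),
         C = matrix(X[4 * d * M + seq_len(nsyn * M)], nsyn, M),
         R = if (nres) matrix(X[4 * d * M + nsyn * M + seq_len(nres * M)],
                              nres, M) else matrix(0, 0, M),
         statics = if (ns) X[idx$statics] else numeric(0),
         T = if (spec$free_time) X[nvar] else targets$T_cycle)
  }

  # ---- targets on the mesh
  tr <- kind_tracks(spec$kind)
  ref <- list()
  K_band <- max(4, (M - 1) %/% 2 - 2)
  ref$q <- if (!is.null(targets$q))
    fourier_resample(targets$q, M, targets$T_cycle %||% targets$T,
                     K_band)$f
  else NULL
  if (!is.null(targets$grf))
    ref$grf <- lapply(targets$grf, function(g)
      resample_targets(g$force, M))
  ref$mom <- resample_targets(targets$tau %||% targets$moments, M)
  ref$act <- resample_targets(targets$activations, M)
  ref$C <- resample_targets(targets$C, M)
  # reserve-torque reference: passive-joint loads are tracked toward the
  # reference cycle (they belong to unchanged passive structures, and an
  # untracked reserve is a free actuator the optimizer will exploit)
  ref$R <- if (nres) {
    tau_ref <- targets$tau %||% targets$moments
    if (!is.null(tau_ref))
      resample_targets(as.matrix(tau_ref)[unact_idx, , drop = FALSE], M)
    else matrix(0, nres, M)
  }
  # variance-normalised channel weights
  wchan <- function(refmat, base) {
    if (is.null(refmat)) return(NULL)
    base / (apply(refmat, 1, sd) + 0.05 * max(apply(refmat, 1, sd)) + 1e-9)
  }
  w <- spec$weights
  wq <- wchan(ref$q, w$q_track)
  wgrf <- if (!is.null(ref$grf)) lapply(ref$grf, wchan, base = w$grf_track)
  wmom <- wchan(ref$mom, w$mom_track)
  wact <- if (!is.null(ref$act)) rep(w$act_track, nrow(ref$act))
  wc <- if (!is.null(ref$C)) rep(w$c_track, nrow(ref$C))
  trunk_idx <- grep("lumbar|pelvis_list|pelvis_rotation", model$dof_names)
  if (!length(grep("lumbar", model$dof_names)))
    trunk_idx <- sort(c(trunk_idx, grep("pelvis_tilt", model$dof_names)))
  pen <- spec$penalty

  # ---- linear equality constraints: defects + periodicity + speed
  # defect_q   = dq  - h/2 (qd_k + qd_k1)  - h^2/12 (qdd_k - qdd_k1)
  # defect_qd  = dqd - h/2 (qdd_k + qdd_k1) - h^2/12 (u_k - u_k1)
  # defect_qdd = dqdd - h/2 (u_k + u_k1)
  # (exactly linear in the variables at fixed T; handled as hard equality
  # constraints in the solver, not penalties)
  lin_constraints <- function(P) {
    h <- P$T / spec$N
    k0 <- seq_len(spec$N); k1 <- k0 + 1
    dq <- P$q[, k1, drop = FALSE] - P$q[, k0, drop = FALSE]
    dv <- P$qd[, k1, drop = FALSE] - P$qd[, k0, drop = FALSE]
    da <- P$qdd[, k1, drop = FALSE] - P$qdd[, k0, drop = FALSE]
    r1 <- dq - h / 2 * (P$qd[, k0] + P$qd[, k1]) -
      h^2 / 12 * (P$qdd[, k0] - P$qdd[, k1])
    r2 <- dv - h / 2 * (P$qdd[, k0] + P$qdd[, k1]) -
      h^2 / 12 * (P$u[, k0] - P$u[, k1])
    r3 <- da - h / 2 * (P$u[, k0] + P$u[, k1])
    per_q <- (P$q[, M] - P$q[, 1])[-tx_idx]
    per_qd <- P$qd[, M] - P$qd[, 1]
    out <- c(r1, r2, r3, per_q, per_qd)
    if (spec$free_time)
      out <- c(out, P$q[tx_idx, M] - P$q[tx_idx, 1] - spec$speed * P$T)
    out
  }

  # ---- node-local nonlinear residuals
  scaled_model <- function(statics) {
    if (!ns || !length(statics)) return(model)
    m2 <- model
    sc <- exp(statics)   # log-parameterised positive contact scales
    for (g in seq_along(m2$contact)) {
      for (part in c("rear", "toes")) {
        for (e in seq_along(m2$contact[[g]][[part]])) {
          el <- m2$contact[[g]][[part]][[e]]
          el$k <- el$k * sc[1]; el$c <- el$c * sc[2]
          el$mu_d <- el$mu_d * sc[3]
          m2$contact[[g]][[part]][[e]] <- el
        }
      }
    }
    m2
  }

  use_mid <- spec$penalty$resid_mid > 0
  nl_eval <- function(P) {
    mdl <- scaled_model(P$statics)
    if (use_mid) {
      # midpoint states of the Hermite interpolant: evaluating the dynamics
      # residual there as well suppresses the parasitic node-to-node
      # oscillation mode of the pure-integrator defects
      h <- P$T / spec$N
      k0 <- seq_len(spec$N); k1 <- k0 + 1
      qm <- (P$q[, k0, drop = FALSE] + P$q[, k1, drop = FALSE]) / 2 +
        h / 8 * (P$qd[, k0, drop = FALSE] - P$qd[, k1, drop = FALSE])
      qdm <- (P$qd[, k0, drop = FALSE] + P$qd[, k1, drop = FALSE]) / 2 +
        h / 8 * (P$qdd[, k0, drop = FALSE] - P$qdd[, k1, drop = FALSE])
      qddm <- (P$qdd[, k0, drop = FALSE] + P$qdd[, k1, drop = FALSE]) / 2 +
        h / 8 * (P$u[, k0, drop = FALSE] - P$u[, k1, drop = FALSE])
      qa <- cbind(P$q, qm); qda <- cbind(P$qd, qdm); qdda <- cbind(P$qdd, qddm)
    } else {
      qa <- P$q; qda <- P$qd; qdda <- P$qdd
    }
    kin <- body_kinematics(mdl, qa, qda, qdda)
    grf_all <- model_ground_reactions(mdl, kin)
    ext <- list()
    for (g in mdl$contact)
      ext[[g$segment]] <- grf_all[[g$side]][c("force", "moment")]
    tau_all <- inverse_dynamics(mdl, qa, qda, qdda, ext, kin)
    arr <- muscle_moment_arrays(mdl, P$q, P$qd)
    a <- pmax(W %*% P$C, 0)
    mus_mom <- arr$p[act_idx, , drop = FALSE]
    for (k in seq_len(M))
      mus_mom[, k] <- mus_mom[, k] +
        arr$B[act_idx, , k, drop = TRUE] %*% a[, k]
    grf <- lapply(grf_all, function(g)
      list(force = g$force[, seq_len(M), drop = FALSE],
           moment = g$moment[, seq_len(M), drop = FALSE],
           cop = g$cop[, seq_len(M), drop = FALSE]))
    resid_all <- residual_loads(mdl, tau_all)
    list(tau = tau_all[, seq_len(M), drop = FALSE], grf = grf, a = a,
         mus_mom = mus_mom,
         resid = resid_all[, seq_len(M), drop = FALSE],
         resid_mid = if (use_mid)
           resid_all[, M + seq_len(spec$N), drop = FALSE]
         else matrix(0, nrow(resid_all), spec$N))
  }

  nl_residual <- function(P, ev = NULL) {
    if (is.null(ev)) ev <- nl_eval(P)
    rows <- list(); nodes <- list()
    add <- function(mat, node_ids) {
      rows[[length(rows) + 1]] <<- as.numeric(mat)
      nodes[[length(nodes) + 1]] <<- rep(node_ids,
                                         each = length(mat) /
                                           length(node_ids))
    }
    # constraints
    add(pen$resid * ev$resid, seq_len(M))
    add(pen$resid_mid * ev$resid_mid, M + seq_len(spec$N))
    add(pen$mom * (ev$tau[act_idx, , drop = FALSE] - ev$mus_mom), seq_len(M))
    if (nres)
      add(pen$mom * (ev$tau[unact_idx, , drop = FALSE] - P$R), seq_len(M))
    if (spec$activation_bounds)
      add(pen$bound * pmax(ev$a - 1, 0), seq_len(M))
    # GRF periodicity (depends on the two endpoint nodes jointly)
    gper <- unlist(lapply(ev$grf, function(g) g$force[, M] - g$force[, 1]))
    rows[[length(rows) + 1]] <- pen$per_grf * gper
    nodes[[length(nodes) + 1]] <- rep(0L, length(gper))
    # tracking
    if ("q" %in% tr)
      add(wq * (P$q - ref$q), seq_len(M))
    if ("grf" %in% tr && !is.null(ref$grf)) {
      for (sd_ in names(ref$grf))
        add(wgrf[[sd_]] * (ev$grf[[sd_]]$force - ref$grf[[sd_]]), seq_len(M))
    }
    if ("mom" %in% tr)
      add(wmom[act_idx] * (ev$tau[act_idx, , drop = FALSE] -
                             ref$mom[act_idx, , drop = FALSE]), seq_len(M))
    if ("act" %in% tr && !is.null(ref$act))
      add(wact * (ev$a - ref$act), seq_len(M))
    if ("c" %in% tr && !is.null(ref$C))
      add(wc * (P$C - ref$C), seq_len(M))
    if ("trunk" %in% tr && length(trunk_idx) && !is.null(ref$q))
      add(w$q_track / 0.05 *
            (P$q[trunk_idx, , drop = FALSE] -
               ref$q[trunk_idx, , drop = FALSE]), seq_len(M))
    if (nres)
      add(w$reserve * (P$R - ref$R), seq_len(M))
    list(r = unlist(rows), node = unlist(nodes))
  }

  structure(list(spec = spec, model = model, targets = targets, W = W,
                 d = d, M = M, nsyn = nsyn, ns = ns, nres = nres,
                 nvar = nvar, idx = idx,
                 act_idx = act_idx, unact_idx = unact_idx,
                 tx_idx = tx_idx, unpack = unpack,
                 lin_constraints = lin_constraints,
                 nl_residual = nl_residual,
                 nl_eval = nl_eval, ref = ref,
                 scaled_model = scaled_model),
            class = "ocp_problem")
}

#' Number of decision variables of a transcription
#' @param problem An [transcribe()] output.
#' @export
n_ocp_variables <- function(problem) problem$nvar

#' Initial guess from a reference cycle
#'
#' Seeds states from the reference kinematics, jerk from the spectral
#' derivative of the accelerations, and synergy activations from the
#' reference; tracking problems seed from data, prediction problems from a
#' preceding solution.
#'
#' @param problem An [transcribe()] output.
#' @param from Reference with `q`, `qd`, `qdd`, `C`, `T_cycle` on a cycle
#'   grid (a [generate_gait()] bundle or an `ocp_solution`).
#' @param perturb Standard deviation of seeded Gaussian multi-start noise.
#' @param seed RNG seed for the perturbation.
#' @return Numeric vector of decision variables.
#' @export
ocp_initial_guess <- function(problem, from = problem$targets,
                              perturb = 0, seed = 1) {
  M <- problem$M; d <- problem$d
  Tc <- from$T_cycle %||% from$T
  K_band <- max(4, (M - 1) %/% 2 - 2)
  fr <- fourier_resample(from$q, M, Tc, K_band)
  q <- fr$f; qd <- fr$d1; qdd <- fr$d2; u <- fr$d3
  C <- resample_targets(from$C, M)
  R <- if (problem$nres) {
    tau_ref <- from$tau %||% from$moments
    if (!is.null(tau_ref))
      resample_targets(as.matrix(tau_ref)[problem$unact_idx, , drop = FALSE],
                       M)
    else matrix(0, problem$nres, M)
  }
  X <- c(as.numeric(q), as.numeric(qd), as.numeric(qdd), as.numeric(u),
         as.numeric(pmax(C, 0)),
         if (problem$nres) as.numeric(R),
         if (problem$ns) numeric(problem$ns),
         if (problem$spec$free_time) Tc)
  if (perturb > 0) {
    set.seed(seed)
    X <- X + rnorm(length(X), sd = perturb * pmax(abs(X), 0.01))
    # keep activations controls non-negative and T positive
    ci <- 4 * d * M + seq_len(problem$nsyn * M)
    X[ci] <- pmax(X[ci], 0)
    if (problem$spec$free_time) X[problem$nvar] <- abs(X[problem$nvar])
  }
  X
}

#' Solve a transcribed optimal control problem
#'
#' Sequential Gauss-Newton with hard linear equality constraints: the
#' Hermite-Simpson defects, state periodicity and the average-speed
#' constraint are exactly linear in the decision variables (at fixed final
#' time) and are satisfied at every iterate through KKT steps; the
#' node-local nonlinear constraints (pelvis residual loads, synergy moment
#' matching, activation bounds, ground-reaction periodicity) enter as
#' penalty-scaled residuals whose penalties escalate in outer rounds until
#' the unweighted feasibility tolerances are met. The objective Jacobian is
#' built by grouped finite differences exploiting node-locality.
#'
#' @param problem An [transcribe()] output.
#' @param guess Initial decision vector (default: seeded from targets).
#' @param max_iter Gauss-Newton iterations per outer round.
#' @param n_outer Penalty escalation rounds.
#' @param verbose Print per-iteration progress.
#' @return Object of class `ocp_solution`.
#' @export
solve_ocp <- function(problem, guess = NULL, max_iter = 25, n_outer = 2,
                      verbose = FALSE) {
  if (is.null(guess)) guess <- ocp_initial_guess(problem)
  spec <- problem$spec
  X <- guess
  pen_scale <- 1
  total_iter <- 0
  for (outer in seq_len(n_outer)) {
    sol <- gn_solve(problem, X, pen_scale, max_iter = max_iter,
                    verbose = verbose)
    X <- sol$X
    total_iter <- total_iter + sol$iter
    feas <- ocp_feasibility(problem, X)
    if (feasible_enough(feas, spec$feas_tol)) break
    pen_scale <- pen_scale * 10
  }
  P <- problem$unpack(X)
  ev <- problem$nl_eval(P)
  feas <- ocp_feasibility(problem, X, ev = ev)
  obj <- tracking_objective(problem, P, ev)
  status <- if (feasible_enough(feas, spec$feas_tol)) "success" else "failed"
  structure(list(
    X = X, q = P$q, qd = P$qd, qdd = P$qdd, u = P$u, C = P$C, R = P$R,
    activations = ev$a, statics = P$statics, T = P$T,
    time = seq(0, P$T, length.out = problem$M),
    tau = ev$tau, grf = ev$grf,
    objective = obj, feasibility = feas, status = status,
    iterations = total_iter, spec = spec, W = problem$W,
    model = problem$model),
    class = "ocp_solution")
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat("<ocp_solution>", x$spec$kind, " status:", x$status,
      " T =", round(x$T, 4), "s\n")
  f <- x$feasibility
  cat(sprintf("  residuals %.3g N / %.3g N m; moment match %.3g N m; periodicity %.2g\n",
              f$resid_force, f$resid_moment, f$moment_match, f$periodicity))
  cat("  objective:", signif(x$objective, 6),
      " iterations:", x$iterations, "\n")
  invisible(x)
}

#' Unweighted constraint-violation norms of a candidate solution
#' @noRd
ocp_feasibility <- function(problem, X, ev = NULL) {
  P <- problem$unpack(X)
  if (is.null(ev)) ev <- problem$nl_eval(P)
  root_force <- vapply(problem$model$segments$pelvis$dofs,
                       function(dd) dd$type == "trans", TRUE)
  mm <- ev$tau[problem$act_idx, , drop = FALSE] - ev$mus_mom
  if (problem$nres)
    mm <- rbind(mm, ev$tau[problem$unact_idx, , drop = FALSE] - P$R)
  per_q <- max(abs((P$q[, problem$M] - P$q[, 1])[-problem$tx_idx]))
  h <- P$T / problem$spec$N
  k0 <- seq_len(problem$spec$N); k1 <- k0 + 1
  r1 <- (P$q[, k1] - P$q[, k0]) - h / 2 * (P$qd[, k0] + P$qd[, k1]) -
    h^2 / 12 * (P$qdd[, k0] - P$qdd[, k1])
  list(resid_force = rms(ev$resid[root_force, ]),
       resid_moment = rms(ev$resid[!root_force, ]),
       moment_match = rms(mm),
       periodicity = per_q,
       defect_max = max(abs(r1)),
       act_bound = if (problem$spec$activation_bounds)
         max(0, max(ev$a) - 1) else 0)
}

#' @noRd
feasible_enough <- function(feas, tol) {
  feas$resid_force <= tol$resid_force &&
    feas$resid_moment <= tol$resid_moment &&
    feas$moment_match <= tol$moment_match &&
    feas$periodicity <= tol$periodicity
}

#' Tracking-only part of the objective (constraint penalties excluded)
#' @noRd
tracking_objective <- function(problem, P, ev) {
  nl <- problem$nl_residual(P, ev)
  ncon <- constraint_row_count(problem)
  sum(nl$r[-seq_len(ncon)]^2) +
    sum((problem$spec$weights$jerk * P$u)^2)
}

#' @noRd
constraint_row_count <- function(problem) {
  nroot <- length(problem$model$segments$pelvis$dofs)
  problem$M * (nroot + length(problem$act_idx) + length(problem$unact_idx)) +
    problem$spec$N * nroot +
    (if (problem$spec$activation_bounds)
      problem$M * length(problem$model$muscles) else 0) +
    3 * length(problem$model$contact)
}

#' Build the linear-constraint matrix A and offset so that c(X) = A X + b0
#' @noRd
build_constraint_matrix <- function(problem, Tval) {
  nvar <- problem$nvar
  Xz <- numeric(nvar)
  if (problem$spec$free_time) Xz[nvar] <- Tval
  Pz <- problem$unpack(Xz)
  c0 <- problem$lin_constraints(Pz)
  ncon <- length(c0)
  # affine in states/controls at fixed T: unit-perturbation columns
  cols <- seq_len(4 * problem$d * problem$M)
  A <- matrix(0, ncon, nvar)
  for (i in cols) {
    Xp <- Xz; Xp[i] <- 1
    A[, i] <- problem$lin_constraints(problem$unpack(Xp)) - c0
  }
  if (problem$spec$free_time) {
    fd <- 1e-6
    Xp <- Xz; Xp[nvar] <- Tval + fd
    A[, nvar] <- (problem$lin_constraints(problem$unpack(Xp)) - c0) / fd
    # bilinear in (T, states): the T column built at X = 0 misses the
    # state-dependent part; it is refreshed at the current iterate inside
    # the solver instead
  }
  list(A = A, c0 = c0)
}

#' Damped Gauss-Newton with hard linear constraints (KKT steps)
#' @noRd
gn_solve <- function(problem, X0, pen_scale = 1, max_iter = 25, fd = 1e-6,
                     verbose = FALSE, tol = 1e-7) {
  d <- problem$d; M <- problem$M; nsyn <- problem$nsyn
  nvar <- problem$nvar
  spec <- problem$spec
  ncon_nl <- constraint_row_count(problem)
  w_jerk <- spec$weights$jerk
  u_cols <- 3 * d * M + seq_len(d * M)
  c_cols <- 4 * d * M + seq_len(nsyn * M)

  obj_res <- function(P, ev = NULL) {
    nl <- problem$nl_residual(P, ev)
    r <- nl$r
    if (pen_scale != 1)
      r[seq_len(ncon_nl)] <- r[seq_len(ncon_nl)] * pen_scale
    list(r = c(r, w_jerk * as.numeric(P$u)), node = nl$node)
  }

  X <- X0
  P <- problem$unpack(X)
  r0 <- obj_res(P)
  nnl <- length(r0$r) - d * M
  node_of_row <- r0$node

  # constraint matrix (constant at fixed T; refreshed when T moves)
  Tcur <- P$T
  cm <- build_constraint_matrix(problem, Tcur)
  A <- cm$A
  ncon <- nrow(A)
  cvec <- function(P) problem$lin_constraints(P)

  # roles for grouped FD on the nonlinear block
  use_mid <- problem$spec$penalty$resid_mid > 0
  nres <- problem$nres
  role_offsets <- c(lapply(seq_len(d), function(i) list(block = 0L, i = i)),
                    lapply(seq_len(d), function(i) list(block = 1L, i = i)),
                    lapply(seq_len(d), function(i) list(block = 2L, i = i)),
                    if (use_mid)
                      lapply(seq_len(d), function(i) list(block = 4L, i = i)),
                    lapply(seq_len(nsyn), function(i) list(block = 3L, i = i)),
                    if (nres)
                      lapply(seq_len(nres), function(i) list(block = 5L, i = i)))
  col_of <- function(role, k) {
    b <- role$block
    as.integer(if (b < 3) b * d * M + (k - 1) * d + role$i
               else if (b == 4L) 3 * d * M + (k - 1) * d + role$i
               else if (b == 5L) 4 * d * M + nsyn * M + (k - 1) * nres + role$i
               else 4 * d * M + (k - 1) * nsyn + role$i)
  }
  # interior nodes split by parity when midpoint rows are active (midpoint
  # rows couple adjacent nodes, whose parities always differ, keeping the
  # grouped-FD attribution exact); a single interior group otherwise
  interior <- if (M > 2) 2:(M - 1) else integer(0)
  node_groups <- if (use_mid)
    list(1L, interior[interior %% 2 == 0],
         interior[interior %% 2 == 1], M)
  else list(1L, interior, M)
  rows_of_node <- function(k) {
    sel <- node_of_row == k
    if (use_mid) {
      if (k > 1) sel <- sel | node_of_row == M + (k - 1)
      if (k < M) sel <- sel | node_of_row == M + k
    }
    if (k == 1L || k == M) sel <- sel | node_of_row == 0L
    sel
  }

  build_J <- function(X, r0) {
    J <- matrix(0, nnl + d * M, nvar)
    for (role in role_offsets) {
      for (gr in node_groups) {
        if (!length(gr)) next
        Xp <- X
        colsg <- vapply(gr, function(k) col_of(role, k), 0L)
        Xp[colsg] <- Xp[colsg] + fd
        rp <- obj_res(problem$unpack(Xp))
        dr <- (rp$r[seq_len(nnl)] - r0$r[seq_len(nnl)]) / fd
        for (k in gr) {
          sel <- rows_of_node(k)
          J[which(sel), col_of(role, k)] <- dr[sel]
        }
      }
    }
    if (problem$ns) {
      for (j in seq_len(problem$ns)) {
        i <- problem$idx$statics[j]
        Xp <- X; Xp[i] <- Xp[i] + fd
        rp <- obj_res(problem$unpack(Xp))
        J[seq_len(nnl), i] <- (rp$r[seq_len(nnl)] - r0$r[seq_len(nnl)]) / fd
      }
    }
    # analytic jerk-cost rows
    J[cbind(nnl + seq_len(d * M), u_cols)] <- w_jerk
    J
  }

  merit <- function(r, cv) sum(r^2) + 1e4 * sum(cv^2)
  cv <- cvec(P)
  m0 <- merit(r0$r, cv)
  # variable scaling: typical magnitudes per block (q rad, qd rad/s,
  # qdd rad/s^2, jerk rad/s^3, C, statics, T) keep the KKT system
  # numerically sane
  sv <- rep(1, nvar)
  sv[d * M + seq_len(d * M)] <- 10
  sv[2 * d * M + seq_len(d * M)] <- 100
  sv[3 * d * M + seq_len(d * M)] <- 5000
  lam <- 1e-3
  iter_done <- 0
  J <- NULL
  since_rebuild <- Inf
  jac_every <- 1   # rebuilds are cheap and keep JtJ block-sparse
  for (it in seq_len(max_iter)) {
    if (spec$free_time && abs(P$T - Tcur) > 1e-9) {
      Tcur <- P$T
      cm <- build_constraint_matrix(problem, Tcur)
      A <- cm$A
      # refresh the T column at the current state (bilinear term)
      Xp <- X; Xp[nvar] <- Xp[nvar] + fd
      A[, nvar] <- (cvec(problem$unpack(Xp)) - cvec(P)) / fd
    }
    if (is.null(J) || since_rebuild >= jac_every) {
      J <- build_J(X, r0)
      since_rebuild <- 0
    }
    Js <- sweep(J, 2, sv, `*`)
    As <- sweep(A, 2, sv, `*`)
    rn_A <- pmax(sqrt(rowSums(As^2)), 1e-12)
    As <- As / rn_A
    JtJ <- crossprod(Js)
    g <- crossprod(Js, r0$r)
    # normalise the objective block to O(1) so it does not swamp the
    # unit-norm constraint rows (the KKT solution is invariant)
    mu <- mean(diag(JtJ)) + 1e-12
    JtJn <- JtJ / mu
    gn_ <- g / mu
    improved <- FALSE
    dfloor <- 1e-6
    JtJs <- Matrix::Matrix(JtJn, sparse = TRUE)
    Ass <- Matrix::Matrix(As, sparse = TRUE)
    Zc <- Matrix::Matrix(0, ncon, ncon, sparse = TRUE)
    dJ <- pmax(Matrix::diag(JtJs), dfloor)
    for (try in 1:8) {
      K <- rbind(cbind(JtJs + lam * Matrix::Diagonal(x = dJ), Matrix::t(Ass)),
                 cbind(Ass, Zc))
      rhs <- c(-gn_, -cv / rn_A)
      step <- tryCatch(as.numeric(Matrix::solve(K, rhs)),
                       error = function(e) NULL)
      if (is.null(step)) { lam <- lam * 10; next }
      dx <- sv * step[seq_len(nvar)]
      Xn <- X + dx
      Xn[c_cols] <- pmax(Xn[c_cols], 0)
      if (spec$free_time)
        Xn[nvar] <- min(max(Xn[nvar], spec$T_bounds[1]), spec$T_bounds[2])
      Pn <- problem$unpack(Xn)
      rn <- obj_res(Pn)
      cn <- cvec(Pn)
      mn <- merit(rn$r, cn)
      if (mn < m0) {
        improve <- (m0 - mn) / max(m0, 1e-12)
        since_rebuild <- since_rebuild + 1
        X <- Xn; P <- Pn; r0 <- rn; cv <- cn; m0 <- mn
        lam <- max(lam / 3, 1e-9)
        improved <- TRUE
        iter_done <- it
        if (verbose)
          cat("  it", it, "merit", signif(m0, 6), "|c|",
              signif(sqrt(sum(cv^2)), 3), "\n")
        if (improve < tol) return(list(X = X, iter = iter_done))
        break
      } else lam <- lam * 10
    }
    if (!improved) {
      if (since_rebuild > 0) { since_rebuild <- Inf } else break
    }
  }
  list(X = X, iter = iter_done)
}

#' Calibrate foot-ground contact parameters by tracking a walking cycle
#'
#' Contact stiffness, damping and friction scale factors enter the tracking
#' problem as static unknowns (log-parameterised, so they stay positive);
#' the solution reproduces the target ground reactions while satisfying
#' skeletal dynamics and near-periodicity.
#'
#' @param model A [walker_model()].
#' @param targets Reference cycle (a [generate_gait()] bundle).
#' @param N Mesh intervals.
#' @param guess_scales Initial multiplicative guesses for (stiffness,
#'   damping, friction), e.g. perturbed values to recover from.
#' @param weights,max_iter,n_outer Passed through.
#' @return list with `scales` (recovered multipliers), `solution` (the
#'   [solve_ocp()] result), and `identifiable` (FALSE with a warning when
#'   the ground-reaction tracking weight is zero).
#' @export
calibrate_contact <- function(model, targets, N = 12,
                              guess_scales = c(1, 1, 1),
                              weights = list(), max_iter = 15, n_outer = 1) {
  spec <- ocp_spec("contact_calibration", N = N, weights = weights,
                   free_time = FALSE)
  identifiable <- spec$weights$grf_track > 0
  if (!identifiable)
    warning("zero ground-reaction tracking weight: contact parameters ",
            "are unidentifiable (flat objective)")
  problem <- transcribe(spec, model, targets)
  X0 <- ocp_initial_guess(problem)
  X0[problem$idx$statics] <- log(guess_scales)
  sol <- solve_ocp(problem, guess = X0, max_iter = max_iter,
                   n_outer = n_outer)
  list(scales = exp(sol$statics), solution = sol,
       identifiable = identifiable)
}

#' Solve with multiple perturbed initial guesses, keep the best
#'
#' @param problem An [transcribe()] output.
#' @param seeds Integer seeds; one solve per seed (the first uses the
#'   unperturbed guess).
#' @param from Reference used to build the guesses.
#' @param perturb Relative perturbation of the multi-start guesses.
#' @param ... Passed to [solve_ocp()].
#' @return Best `ocp_solution` by objective among successful solves (or the
#'   best failed iterate when none converges).
#' @export
solve_ocp_multistart <- function(problem, seeds = 1, from = problem$targets,
                                 perturb = 0.02, ...) {
  best <- NULL
  for (i in seq_along(seeds)) {
    g <- ocp_initial_guess(problem, from = from,
                           perturb = if (i == 1) 0 else perturb,
                           seed = seeds[i])
    sol <- solve_ocp(problem, guess = g, ...)
    better <- is.null(best) ||
      (sol$status == "success" && best$status != "success") ||
      (sol$status == best$status && sol$objective < best$objective)
    if (better) best <- sol
  }
  best
}
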