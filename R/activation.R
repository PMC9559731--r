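#' EMG-to-activation dynamics
#'
#' Converts an excitation (processed EMG envelope) series into a muscle
#' activation series: the excitation is scaled and electromechanically
#' delayed, passed through first-order activation dynamics with distinct
#' activation and deactivation time constants, and finally non-linearised
#' with an exponential shape function.
#'
#' The ODE `da/dt = (u - a)/tau` is integrated with an exact exponential
#' update per step (the ODE is linear within a step for piecewise-constant
#' excitation), which is unconditionally stable; the step-size guard below
#' protects the fidelity of the tau switching, not stability.
#'
#' @param e Excitation series in \[0, 1\].
#' @param dt Sample interval (s).
#' @param muscle Muscle spec list with `emg_scale`, `emg_delay`, `tau_act`,
#'   `tau_deact`, `shape_A` (in \[-3, -0.01\]; -0.01 is treated as the
#'   linear limit).
#' @return Activation series in \[0, 1\], same length as `e`.
#' @export
excitation_to_activation <- function(e, dt, muscle) {
  stopifnot(dt > 0)
  if (any(e < -1e-9 | e > 1 + 1e-9))
    stop("excitation outside [0, 1]")
  tau_a <- muscle$tau_act; tau_d <- muscle$tau_deact
  stopifnot(tau_a > 0, tau_d > 0)
  if (dt > min(tau_a, tau_d) / 2)
    stop("dt = ", dt, " exceeds min(tau)/2 = ", min(tau_a, tau_d) / 2,
         "; resample the excitation to a finer grid")
  n <- length(e)
  # delay by linear interpolation into the past; pad history with e[1]
  u <- delay_series(e, muscle$emg_delay, dt) * muscle$emg_scale
  a <- numeric(n)
  a[1] <- u[1]
  # exact update for an input varying linearly across the step:
  # da/dt = (u - a)/tau  =>  a1 = u1 - s*tau + (a0 - u0 + s*tau) e^(-dt/tau)
  ea <- exp(-dt / tau_a); ed <- exp(-dt / tau_d)
  for (k in seq_len(n - 1L)) {
    u_mid <- (u[k] + u[k + 1L]) / 2
    up <- u_mid > a[k]
    tau <- if (up) tau_a else tau_d
    decay <- if (up) ea else ed
    s_tau <- (u[k + 1L] - u[k]) / dt * tau
    a[k + 1L] <- u[k + 1L] - s_tau + (a[k] - u[k] + s_tau) * decay
  }
  a <- pmin(pmax(a, 0), 1)
  activation_nonlin(a, muscle$shape_A %||% -0.01)
}

#' @noRd
delay_series <- function(e, delay, dt) {
  if (abs(delay) < 1e-12) return(e)
  n <- length(e)
  t <- (seq_len(n) - 1) * dt
  approx(t, e, xout = t - delay, rule = 2)$y
}

#' Exponential activation non-linearisation
#'
#' `a' = (exp(A a) - 1)/(exp(A) - 1)` for shape factor A in \[-3, -0.01\];
#' A = -0.01 and larger magnitudes below 1e-2 are treated as linear.
#' @noRd
activation_nonlin <- function(a, A) {
  if (abs(A) < 0.0100001) return(a)
  (exp(A * a) - 1) / (exp(A) - 1)
}

#' @noRd
activation_nonlin_inverse <- function(ap, A) {
  if (abs(A) < 0.0100001) return(ap)
  log(1 + ap * (exp(A) - 1)) / A
}

#' Invert activation dynamics to recover an excitation series
#'
#' Used by the synthetic-data generator to manufacture EMG that reproduces a
#' known activation trace: undoes the non-linearisation, estimates the
#' first-order ODE input from the activation derivative (tau chosen by the
#' sign of da/dt, consistent with u > a during activation), then undoes the
#' scale and delay. The result is clipped to \[0, 1\].
#' @noRd
activation_to_excitation <- function(a, dt, muscle) {
  ab <- activation_nonlin_inverse(pmin(pmax(a, 0), 1), muscle$shape_A %||% -0.01)
  n <- length(ab)
  da <- c(ab[2] - ab[1], (ab[3:n] - ab[1:(n - 2)]) / 2, ab[n] - ab[n - 1]) / dt
  tau <- ifelse(da > 0, muscle$tau_act, muscle$tau_deact)
  u <- ab + tau * da
  u <- pmin(pmax(u, 0), 1)
  e <- delay_series(u, -muscle$emg_delay, dt) / muscle$emg_scale
  pmin(pmax(e, 0), 1)
}
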