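#' @importFrom stats approx coef fft lm optim qnorm rnorm runif sd setNames spline splinefun var
#' @importFrom utils head modifyList read.table tail write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross product of 3-vectors, vectorised over columns
#'
#' Both arguments are 3 x T matrices (or length-3 vectors, recycled).
#' @noRd
cross3 <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, 3, max(1L, NCOL(b)))
  if (is.vector(b)) b <- matrix(b, 3, ncol(a))
  rbind(
    a[2, ] * b[3, ] - a[3, ] * b[2, ],
    a[3, ] * b[1, ] - a[1, ] * b[3, ],
    a[1, ] * b[2, ] - a[2, ] * b[1, ]
  )
}

#' Rotation matrices about a fixed axis, vectorised over angle
#'
#' Rodrigues formula; returns a 3 x 3 x T array for a unit axis `u` and
#' angle vector `theta`.
#' @noRd
rot_axis <- function(u, theta) {
  T <- length(theta)
  ct <- cos(theta); st <- sin(theta); vt <- 1 - ct
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- array(0, c(3, 3, T))
  R[1, 1, ] <- ct + ux * ux * vt
  R[1, 2, ] <- ux * uy * vt - uz * st
  R[1, 3, ] <- ux * uz * vt + uy * st
  R[2, 1, ] <- uy * ux * vt + uz * st
  R[2, 2, ] <- ct + uy * uy * vt
  R[2, 3, ] <- uy * uz * vt - ux * st
  R[3, 1, ] <- uz * ux * vt - uy * st
  R[3, 2, ] <- uz * uy * vt + ux * st
  R[3, 3, ] <- ct + uz * uz * vt
  R
}

#' Compose two stacks of rotation matrices (3 x 3 x T)
#' @noRd
rot_compose <- function(A, B) {
  T <- dim(A)[3]
  C <- array(0, c(3, 3, T))
  for (i in 1:3) for (j in 1:3) {
    C[i, j, ] <- A[i, 1, ] * B[1, j, ] + A[i, 2, ] * B[2, j, ] + A[i, 3, ] * B[3, j, ]
  }
  C
}

#' Apply a stack of rotations to 3 x T columns (or a fixed 3-vector)
#' @noRd
rot_apply <- function(R, x) {
  T <- dim(R)[3]
  if (is.vector(x)) x <- matrix(x, 3, T)
  rbind(
    R[1, 1, ] * x[1, ] + R[1, 2, ] * x[2, ] + R[1, 3, ] * x[3, ],
    R[2, 1, ] * x[1, ] + R[2, 2, ] * x[2, ] + R[2, 3, ] * x[3, ],
    R[3, 1, ] * x[1, ] + R[3, 2, ] * x[2, ] + R[3, 3, ] * x[3, ]
  )
}

#' Transpose a stack of rotation matrices
#' @noRd
rot_transpose <- function(R) aperm(R, c(2, 1, 3))

#' Identity rotation stack
#' @noRd
rot_identity <- function(T) {
  R <- array(0, c(3, 3, T))
  R[1, 1, ] <- 1; R[2, 2, ] <- 1; R[3, 3, ] <- 1
  R
}

#' Periodic linear interpolation of rows of a matrix at shifted times
#'
#' `x` has one column per sample on an equally spaced grid covering one
#' period `T_per` (first sample at t = 0, last at t = T_per, with
#' x[, 1] == x[, n] assumed only approximately). Negative delays look into
#' the previous (periodic) cycle.
#' @noRd
periodic_shift <- function(x, delay, T_per) {
  n <- ncol(x)
  tg <- seq(0, T_per, length.out = n)
  tq <- (tg - delay) %% T_per
  idx <- tq / (T_per / (n - 1))
  i0 <- pmin(floor(idx) + 1L, n - 1L)
  w <- idx - (i0 - 1L)
  x[, i0, drop = FALSE] * rep(1 - w, each = nrow(x)) +
    x[, i0 + 1L, drop = FALSE] * rep(w, each = nrow(x))
}

#' RMS helper
#' @noRd
rms <- function(x) sqrt(mean(x^2))
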