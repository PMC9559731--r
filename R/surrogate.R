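#' Surrogate muscle-tendon geometry
#'
#' Muscle-tendon length as a polynomial in the spanned joint coordinates.
#' Moment arms are minus the analytic partial derivatives of length with
#' respect to each spanned coordinate, so the moment-arm/length derivative
#' identity holds by construction.
#'
#' @param dofs Integer indices (into the model DOF ordering) of the spanned
#'   coordinates, or character DOF names resolved later against a model.
#' @param expon Integer matrix (n_terms x n_dofs) of exponents per term.
#' @param coef Numeric coefficients, one per term.
#' @param bounds Optional matrix (n_dofs x 2) of coordinate bounds used for
#'   extrapolation warnings.
#' @return Object of class `surrogate_geometry`.
#' @export
surrogate_geometry <- function(dofs, expon, coef, bounds = NULL) {
  expon <- as.matrix(expon)
  storage.mode(expon) <- "double"
  if (length(coef) != nrow(expon))
    stop("coef length must match the number of basis terms")
  if (ncol(expon) != length(dofs))
    stop("exponent matrix must have one column per spanned DOF")
  structure(list(dofs = dofs, expon = expon, coef = as.numeric(coef),
                 bounds = bounds),
            class = "surrogate_geometry")
}

#' Full polynomial exponent basis up to a degree
#'
#' All exponent tuples in `d` variables with total degree <= `degree`.
#' @param d Number of variables.
#' @param degree Maximum total degree (default 3).
#' @return Integer matrix with one row per term.
#' @export
poly_basis <- function(d, degree = 3) {
  grid <- as.matrix(expand.grid(rep(list(0:degree), d)))
  grid <- grid[rowSums(grid) <= degree, , drop = FALSE]
  grid <- grid[order(rowSums(grid)), , drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

#' Evaluate monomial design matrix at coordinates
#' @param qs d x T matrix of spanned coordinate values.
#' @noRd
monomial_matrix <- function(expon, qs) {
  Tn <- ncol(qs)
  n_terms <- nrow(expon)
  M <- matrix(1, Tn, n_terms)
  for (j in seq_len(ncol(expon))) {
    e <- expon[, j]
    nz <- which(e > 0)
    if (length(nz)) {
      qj <- qs[j, ]
      for (i in nz) M[, i] <- M[, i] * qj^e[i]
    }
  }
  M
}

#' Muscle-tendon length and moment arms from surrogate geometry
#'
#' @param geometry A [surrogate_geometry()].
#' @param q Joint coordinates: either the full model coordinate vector
#'   (indexed by `geometry$dofs`) or a vector/matrix of just the spanned
#'   coordinates (d x T).
#' @return list with `length` (vector over T) and `moment_arms`
#'   (d x T matrix; moment arm about DOF j equals `-d length / d q_j`).
#' @export
mtu_length_and_moment_arms <- function(geometry, q) {
  d <- length(geometry$dofs)
  qs <- spanned_coords(geometry, q)
  if (!is.null(geometry$bounds)) {
    lo <- geometry$bounds[, 1]; hi <- geometry$bounds[, 2]
    if (any(qs < lo - 1e-9) || any(qs > hi + 1e-9))
      warning("coordinates outside the surrogate bound box; extrapolating")
  }
  M <- monomial_matrix(geometry$expon, qs)
  len <- as.numeric(M %*% geometry$coef)
  if (any(len <= 0))
    warning("surrogate muscle-tendon length non-positive inside evaluation")
  ma <- matrix(0, d, ncol(qs))
  for (j in seq_len(d)) {
    e <- geometry$expon[, j]
    nz <- which(e > 0)
    if (!length(nz)) next
    Ed <- geometry$expon[nz, , drop = FALSE]
    Ed[, j] <- Ed[, j] - 1
    Md <- monomial_matrix(Ed, qs)
    ma[j, ] <- -as.numeric(Md %*% (geometry$coef[nz] * e[nz]))
  }
  list(length = len, moment_arms = ma)
}

#' @noRd
spanned_coords <- function(geometry, q) {
  d <- length(geometry$dofs)
  if (is.matrix(q)) {
    if (nrow(q) == d) return(q)
    if (is.numeric(geometry$dofs) && nrow(q) >= max(geometry$dofs))
      return(q[geometry$dofs, , drop = FALSE])
    stop("unknown DOF index in surrogate geometry (", nrow(q), " coordinates supplied)")
  }
  if (length(q) == d) return(matrix(q, d, 1))
  if (is.numeric(geometry$dofs)) {
    if (max(geometry$dofs) > length(q))
      stop("unknown DOF index in surrogate geometry: ", max(geometry$dofs))
    return(matrix(q[geometry$dofs], d, 1))
  }
  stop("cannot resolve spanned coordinates; supply spanned values directly")
}

#' Muscle-tendon velocity from moment arms
#'
#' `v_mt = d l / d t = -sum_j (moment arm_j) * qdot_j`.
#' @noRd
mtu_velocity <- function(moment_arms, qdot_spanned) {
  -colSums(moment_arms * qdot_spanned)
}

#' Fit surrogate geometry coefficients by least squares
#'
#' @param q Sample coordinates, n x d matrix (one pose per row) of the
#'   spanned coordinates.
#' @param length Sampled muscle-tendon lengths (length n).
#' @param basis Exponent matrix (n_terms x d), e.g. [poly_basis()].
#' @param dofs DOF indices/names for the resulting geometry.
#' @return A `surrogate_geometry` with attributes `rms_residual` and
#'   `coef_se` (coefficient standard errors).
#' @export
fit_surrogate <- function(q, length, basis, dofs = seq_len(ncol(q))) {
  q <- as.matrix(q)
  n <- nrow(q)
  if (n < 2 * nrow(basis))
    stop("need at least 2x as many samples as coefficients (",
         n, " < ", 2 * nrow(basis), ")")
  X <- monomial_matrix(basis, t(q))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    stop("rank-deficient surrogate design matrix; degenerate basis terms: ",
         paste(apply(basis[bad, , drop = FALSE], 1, paste, collapse = ","),
               collapse = "; "))
  }
  cf <- qr.coef(qr_x, length)
  res <- length - X %*% cf
  rmse <- rms(res)
  dof_res <- max(1, n - ncol(X))
  sigma2 <- sum(res^2) / dof_res
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(0, diag(XtXinv) * sigma2))
  g <- surrogate_geometry(dofs, basis, cf,
                          bounds = cbind(apply(q, 2, min), apply(q, 2, max)))
  attr(g, "rms_residual") <- rmse
  attr(g, "coef_se") <- se
  g
}
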