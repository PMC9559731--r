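#' Least-squares affine landmark mapping
#'
#' Finds the 12-parameter affine transform `p' = A p + b` minimising the sum
#' of squared landmark distances between mapped source points and target
#' points. Used to transfer muscle attachment points between skeletal models
#' that share a set of bony landmarks.
#'
#' @param source n x 3 matrix of source landmarks (n >= 4, non-coplanar).
#' @param target n x 3 matrix of corresponding target landmarks.
#' @return list with `A` (3 x 3), `b` (length 3), `rms` landmark error, and
#'   `transform(p)` applying the map to an n x 3 matrix of points.
#' @export
fit_affine_landmarks <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target))
    stop("source and target must have the same number of landmarks")
  if (nrow(source) < 4)
    stop("need at least 4 landmarks to determine an affine transform")
  X <- cbind(source, 1)
  if (qr(scale(source, scale = FALSE))$rank < 3)
    stop("source landmarks are coplanar; affine transform is not determined")
  B <- qr.coef(qr(X), target)   # 4 x 3
  A <- t(B[1:3, , drop = FALSE])
  b <- as.numeric(B[4, ])
  mapped <- X %*% B
  rms_err <- sqrt(mean(rowSums((mapped - target)^2)))
  list(A = A, b = b, rms = rms_err,
       transform = function(p) sweep(as.matrix(p) %*% t(A), 2, -b))
}
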