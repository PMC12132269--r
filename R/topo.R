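#' Thin-plate spline interpolation over the unit head disc
#'
#' Classical 2-D thin-plate spline through scattered electrode values:
#' radial basis `U(r) = r^2 log(r)` plus an affine term, with the usual
#' orthogonality constraints on the radial weights. The interpolant is
#' exact at the electrode positions (no smoothing penalty). Grid cells
#' outside the unit head circle are set to `NA`.
#'
#' @param positions Numeric matrix (n x 2) of electrode (x, y) coordinates.
#' @param values Numeric vector of per-electrode scalars.
#' @param grid_n Grid resolution per axis over `[-1, 1]`.
#' @return List with grid axes `x`, `y` (length `grid_n`) and matrix `z`
#'   (`grid_n` x `grid_n`, `z[i, j]` at `(x[i], y[j])`).
#' @export
tps_interpolate <- function(positions, values, grid_n = 67) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (length(values) != n) {
    stop_validation("tps_interpolate: %d values for %d positions",
                    length(values), n)
  }
  u_fun <- function(r2) ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)  # r^2 log r
  d2 <- as.matrix(stats::dist(positions))^2
  K <- u_fun(d2)
  P <- cbind(1, positions)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coefs <- solve(A, c(values, numeric(3)))
  w <- coefs[seq_len(n)]
  a <- coefs[n + 1:3]
  gx <- seq(-1, 1, length.out = grid_n)
  gy <- seq(-1, 1, length.out = grid_n)
  z <- matrix(NA_real_, grid_n, grid_n)
  for (j in seq_len(grid_n)) {
    inside <- gx^2 + gy[j]^2 <= 1
    if (!any(inside)) next
    px <- gx[inside]
    py <- gy[j]
    r2 <- outer(px, positions[, 1], `-`)^2 +
      matrix((py - positions[, 2])^2, nrow = length(px), ncol = n,
             byrow = TRUE)
    z[inside, j] <- u_fun(r2) %*% w + a[1] + a[2] * px + a[3] * py
  }
  list(x = gx, y = gy, z = z)
}

# Evaluate a fitted map at arbitrary points (used by tests for
# node-exactness); refits internally since fits are cheap at 8 electrodes.
tps_eval <- function(positions, values, at) {
  positions <- as.matrix(positions)
  at <- matrix(as.numeric(at), ncol = 2)
  n <- nrow(positions)
  u_fun <- function(r2) ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)
  d2 <- as.matrix(stats::dist(positions))^2
  K <- u_fun(d2)
  P <- cbind(1, positions)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coefs <- solve(A, c(values, numeric(3)))
  w <- coefs[seq_len(n)]
  a <- coefs[n + 1:3]
  r2 <- outer(at[, 1], positions[, 1], `-`)^2 +
    outer(at[, 2], positions[, 2], `-`)^2
  as.numeric(u_fun(r2) %*% w + a[1] + a[2] * at[, 1] + a[3] * at[, 2])
}
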