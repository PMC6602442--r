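# Low-level vector algebra and shared helpers. All angles at API boundaries
# are in degrees; coordinates are in Angstrom.

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  a / n
}

row_cross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

row_norm <- function(A) sqrt(rowSums(A * A))

# Wrap angle (degrees) into (-180, 180].
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Smallest circular difference |a - b| in degrees, in [0, 180].
circ_absdiff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Rotate points (rows of X) about the line through `origin` with unit
# direction `axis` by `theta` radians (Rodrigues).
rotate_about_axis <- function(X, origin, axis, theta) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 3L)
  Xc <- sweep(X, 2L, origin)
  ct <- cos(theta); st <- sin(theta)
  K <- row_cross(matrix(axis, nrow(Xc), 3L, byrow = TRUE), Xc)
  dotp <- drop(Xc %*% axis)
  Xr <- Xc * ct + K * st + outer(dotp, axis) * (1 - ct)
  sweep(Xr, 2L, origin, `+`)
}

# Evaluate an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed fan-out. Keeps results in [1, 2^31 - 20); arithmetic stays
# within exact double range.
split_seed <- function(master, k) {
  m <- as.double(master) %% 94906249
  as.integer((m * 22695477 + as.double(k) * 7919 + 12345) %% 2147483609) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
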