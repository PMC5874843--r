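# Internal geometry and RNG helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All exported stochastic operations funnel
# through this so identical seeds give identical results regardless of the
# surrounding session state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

vec_norm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# Rotation matrix from a unit quaternion stored as c(x, y, z, w).
quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Shoemake's subgroup-algorithm draw: uniform on SO(3).
random_quaternion <- function(n = 1) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
}

# Squared cross-distances between two coordinate matrices (n x 3, m x 3).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Minimum atom-atom distance between two coordinate sets, chunked so the
# intermediate matrix stays small for large systems.
min_cross_dist <- function(a, b, chunk = 2000L) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  best <- Inf
  for (start in seq(1L, nrow(b), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(b))
    best <- min(best, min(cross_dist2(a, b[idx, , drop = FALSE])))
  }
  sqrt(best)
}

# Rodrigues rotation about a unit axis by `angle` radians.
rotation_about <- function(axis, angle) {
  a <- normalize(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Deterministic Fibonacci spiral lattice on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gf <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gelforge_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
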