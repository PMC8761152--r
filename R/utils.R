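`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Elementary rotation matrices (radians).
rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

## Uniform random proper rotation from a random unit quaternion
## (draws 4 normals from the current RNG stream).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),  2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),  2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),  1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

## Apply rigid transform x -> R x + t to an n x 3 coordinate matrix.
transform_coords <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, -translation)
}
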