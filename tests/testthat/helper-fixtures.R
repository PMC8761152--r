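extdata <- function(f) system.file("extdata", f, package = "memqa")

make_bundle <- function(seed = 1, ...) generate_bundle(bundle_spec(seed = seed, ...))

## Balanced zig-zag pair: wide, non-collinear reference with zero-net-force,
## zero-net-torque z displacements of magnitude `delta`, so the full-set
## Kabsch optimum is exactly the identity and every pair sits at `delta`.
balanced_offset_pair <- function(n = 24, delta, spread = 20) {
  i <- seq_len(n) - 1
  r <- cbind(spread * i, 5 * (i %% 2), 0)
  sgn <- rep(c(1, -1, -1, 1), length.out = n)
  q <- r + cbind(0, 0, sgn * delta)
  sq <- new_structure(data.frame(chain = "A", resno = seq_len(n),
                                 ins = NA, resid = "ALA",
                                 x = q[, 1], y = q[, 2], z = q[, 3],
                                 plddt = 90), id = "offset_query")
  sr <- new_structure(data.frame(chain = "A", resno = seq_len(n),
                                 ins = NA, resid = "ALA",
                                 x = r[, 1], y = r[, 2], z = r[, 3],
                                 plddt = 90), id = "offset_ref")
  list(query = sq, reference = sr)
}

## Structure from a bare coordinate matrix.
coords_structure <- function(xyz, id = "pts", plddt = 90) {
  new_structure(data.frame(chain = "A", resno = seq_len(nrow(xyz)),
                           ins = NA, resid = "ALA",
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           plddt = plddt), id = id)
}

random_cloud <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  matrix(rnorm(n * 3, sd = 8), ncol = 3)
}
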