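## Independent oracles, kept deliberately separate from the production code
## paths they check.

## Horn's closed-form quaternion solution of the optimal-rotation problem
## (independent of the SVD route used by kabsch_superpose).
horn_superpose <- function(q, r) {
  cq <- colMeans(q); cr <- colMeans(r)
  qc <- sweep(q, 2, cq); rc <- sweep(r, 2, cr)
  s <- crossprod(qc, rc)  # sum over i of q_i r_i^T
  n4 <- matrix(0, 4, 4)
  n4[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  n4[1, 2] <- n4[2, 1] <- s[2, 3] - s[3, 2]
  n4[1, 3] <- n4[3, 1] <- s[3, 1] - s[1, 3]
  n4[1, 4] <- n4[4, 1] <- s[1, 2] - s[2, 1]
  n4[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  n4[2, 3] <- n4[3, 2] <- s[1, 2] + s[2, 1]
  n4[2, 4] <- n4[4, 2] <- s[1, 3] + s[3, 1]
  n4[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  n4[3, 4] <- n4[4, 3] <- s[2, 3] + s[3, 2]
  n4[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  ev <- eigen(n4, symmetric = TRUE)
  p <- ev$vectors[, 1]
  w <- p[1]; x <- p[2]; y <- p[3]; z <- p[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),  2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),  2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),  1 - 2 * (x^2 + y^2)
  ), 3, 3)
  rmsd <- sqrt(mean(rowSums((qc %*% t(rot) - rc)^2)))
  list(rotation = rot, rmsd = rmsd)
}

## Brute-force rotation-space minimizer: Horn plus a large random rotation
## sample (any sampled rotation that beats the analytic optimum would expose
## an error in either route).
oracle_min_rmsd <- function(q, r, n_sample = 2000, seed = 99) {
  analytic <- horn_superpose(q, r)$rmsd
  cq <- colMeans(q); cr <- colMeans(r)
  qc <- sweep(q, 2, cq); rc <- sweep(r, 2, cr)
  sampled <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    best <- Inf
    for (i in seq_len(n_sample)) {
      qt <- rnorm(4); qt <- qt / sqrt(sum(qt^2))
      w <- qt[1]; x <- qt[2]; y <- qt[3]; z <- qt[4]
      rot <- matrix(c(
        1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),  2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),  2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x),  1 - 2 * (x^2 + y^2)
      ), 3, 3)
      best <- min(best, sqrt(mean(rowSums((qc %*% t(rot) - rc)^2))))
    }
    best
  })
  min(analytic, sampled)
}

## Brute-force centroid arithmetic for the thickness statistic, written as
## plain loops over the raw residue table.
oracle_thickness <- function(s, annotation) {
  segs <- annotation$segments
  df <- as.data.frame(s)
  side_pts <- list(side1 = NULL, side2 = NULL)
  for (i in seq_len(nrow(segs))) {
    for (which_end in c("start", "end")) {
      pos <- segs[[which_end]][i]
      side <- segs[[paste0(which_end, "_side")]][i]
      row <- df[df$resno == pos, ]
      side_pts[[side]] <- rbind(side_pts[[side]],
                                c(row$x, row$y, row$z))
    }
  }
  c1 <- apply(side_pts$side1, 2, mean)
  c2 <- apply(side_pts$side2, 2, mean)
  sqrt(sum((c1 - c2)^2))
}

## Exhaustive-seed TM-score oracle for small problems: every contiguous
## window of length >= 4 seeds a superposition (via the Horn route, not the
## production SVD code) which is refined with the documented shrinking
## inclusion cutoff (d0 down to d0/2 + 1, floor 3 A, 20 rounds) until
## stable; the TM sum over all pairs is maximized over everything visited.
oracle_tm_exhaustive <- function(qc, rc, d0_value, l_norm) {
  n <- nrow(qc)
  best <- -Inf
  apply_fit <- function(idx) {
    h <- horn_superpose(qc[idx, , drop = FALSE], rc[idx, , drop = FALSE])
    cqs <- colMeans(qc[idx, , drop = FALSE])
    crs <- colMeans(rc[idx, , drop = FALSE])
    tr <- crs - as.numeric(h$rotation %*% cqs)
    sweep(qc %*% t(h$rotation), 2, -tr)
  }
  for (len in 4:n) {
    for (s0 in 1:(n - len + 1)) {
      idx <- seq(s0, s0 + len - 1)
      prev <- integer()
      for (iter in 1:20) {
        fitted <- apply_fit(idx)
        d <- sqrt(rowSums((fitted - rc)^2))
        best <- max(best, sum(1 / (1 + (d / d0_value)^2)))
        cut <- max(3, d0_value + (d0_value / 2 + 1 - d0_value) * (iter - 1) / 19)
        sel <- which(d <= cut)
        if (length(sel) < 4) sel <- order(d)[seq_len(min(4, n))]
        if (identical(sel, prev)) break
        prev <- sel
        idx <- sel
      }
    }
  }
  best / l_norm
}
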