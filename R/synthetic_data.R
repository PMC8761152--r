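#' Specification of a synthetic TM helix bundle
#'
#' Parameters for [generate_bundle()].  Geometry uses an ideal alpha-helix
#' C-alpha trace (rise 1.5 A/residue, 100 degree twist, 2.3 A radius); the
#' helix is compressed axially by the factor needed to put its boundary
#' residues exactly at z = +/- `target_thickness` / 2, which requires
#' `1.5 * (helix_length - 1) * cos(tilt) >= target_thickness`.
#'
#' @param n_helices number of membrane-spanning helices (>= 1).
#' @param helix_length residues per helix; the default 21 spans 30 A at the
#'   ideal 1.5 A rise, a typical membrane-spanning helix.
#' @param target_thickness hydrophobic thickness in Angstrom.
#' @param tilt_deg helix tilt from the membrane normal, degrees in
#'   \[0, 45\]; tilt azimuths are spread evenly around the bundle.
#' @param loop_length residues per connecting loop.
#' @param radius bundle circumradius in Angstrom (helix axis placement).
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @param seed integer RNG seed; every random draw in the generator comes
#'   from this seed.
#' @param plddt_tm,plddt_loop confidence painted on TM and loop residues.
#' @param reliability topology reliability recorded in the annotation.
#' @return a `memqa_bundle_spec` list.
#' @export
bundle_spec <- function(n_helices = 4, helix_length = 21,
                        target_thickness = 30, tilt_deg = 0,
                        loop_length = 4, radius = 8, noise_sigma = 0,
                        seed = 1, plddt_tm = 90, plddt_loop = 60,
                        reliability = 95) {
  stopifnot(n_helices >= 1, helix_length >= 4, target_thickness > 0,
            tilt_deg >= 0, tilt_deg <= 45, loop_length >= 1, radius > 0,
            noise_sigma >= 0, plddt_tm >= 0, plddt_tm <= 100,
            plddt_loop >= 0, plddt_loop <= 100)
  span <- 1.5 * (helix_length - 1) * cos(tilt_deg * pi / 180)
  if (span < target_thickness)
    stop(sprintf(
      "unachievable spec: helix span %.1f A (rise x length x cos tilt) < target thickness %.1f A",
      span, target_thickness))
  structure(list(n_helices = n_helices, helix_length = helix_length,
                 target_thickness = target_thickness, tilt_deg = tilt_deg,
                 loop_length = loop_length, radius = radius,
                 noise_sigma = noise_sigma, seed = seed,
                 plddt_tm = plddt_tm, plddt_loop = plddt_loop,
                 reliability = reliability),
            class = "memqa_bundle_spec")
}

## Align the endpoint-centroid axis with z and rescale it so the distance
## between the two endpoint-set centroids is exactly the target thickness.
## For symmetric bundles this is a near-identity touch-up; it guarantees an
## exact ground truth for every achievable spec.
calibrate_thickness <- function(xyz, segs, target) {
  side1 <- c(segs$start[segs$start_side == "side1"],
             segs$end[segs$end_side == "side1"])
  side2 <- c(segs$start[segs$start_side == "side2"],
             segs$end[segs$end_side == "side2"])
  c1 <- colMeans(xyz[side1, , drop = FALSE])
  c2 <- colMeans(xyz[side2, , drop = FALSE])
  v <- c2 - c1
  len <- sqrt(sum(v^2))
  mid <- (c1 + c2) / 2
  u <- v / len
  ## rotation taking u to +z (Rodrigues; identity when already aligned)
  ez <- c(0, 0, 1)
  ax <- c(u[2] * ez[3] - u[3] * ez[2], u[3] * ez[1] - u[1] * ez[3],
          u[1] * ez[2] - u[2] * ez[1])
  s <- sqrt(sum(ax^2)); cth <- sum(u * ez)
  rot <- if (s < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    k <- ax / s
    kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + s * kx + (1 - cth) * kx %*% kx
  }
  out <- sweep(xyz, 2, mid) %*% t(rot)
  out[, 3] <- out[, 3] * target / len
  out
}

HELIX_RISE <- 1.5
HELIX_TWIST_DEG <- 100
HELIX_CA_RADIUS <- 2.3

## Ideal helix C-alpha trace along +z, centered at the origin, axially
## compressed so the end residues sit at z = +/- half_span.
ideal_helix <- function(n_res, half_span) {
  k <- seq_len(n_res) - 1
  theta <- k * HELIX_TWIST_DEG * pi / 180
  z <- HELIX_RISE * (k - (n_res - 1) / 2)
  z <- z * half_span / (HELIX_RISE * (n_res - 1) / 2)
  cbind(HELIX_CA_RADIUS * cos(theta), HELIX_CA_RADIUS * sin(theta), z)
}

#' Generate a synthetic membrane helix bundle with known ground truth
#'
#' Builds `n_helices` antiparallel ideal helices on a circle of the given
#' radius, alternating direction, each tilted by `tilt_deg` with tilt
#' azimuths spread evenly so endpoint x,y offsets cancel across the bundle.
#' Helix boundary residues sit at z = +/- `target_thickness` / 2 and a
#' final calibration (rotating the endpoint-centroid axis onto z and
#' rescaling it) makes the pre-noise ground-truth thickness exactly
#' `target_thickness` for every valid spec; connecting loops arc outside
#' the membrane slab.  Confidence is painted `plddt_tm` on helix residues
#' and `plddt_loop` on loops, and a matching topology annotation
#' (alternating sides, N-terminus inside) is returned.
#'
#' @param spec a [bundle_spec()].
#' @return list with `structure` (a `memqa_structure`), `topology`
#'   (a `memqa_topology`) and `ground_truth` (spec plus the nominal
#'   thickness).
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "memqa_bundle_spec"))
  half <- spec$target_thickness / 2
  tilt <- spec$tilt_deg * pi / 180
  hl <- spec$helix_length; ll <- spec$loop_length
  coords <- list(); labels <- character(); seg_rows <- list()
  pos <- 0L
  for (h in seq_len(spec$n_helices)) {
    up <- h %% 2 == 1
    azim <- 2 * pi * (h - 1) / spec$n_helices
    center <- c(spec$radius * cos(azim), spec$radius * sin(azim), 0)
    ## axial half-span before tilt such that the tilted span is the slab
    hel <- ideal_helix(hl, half / cos(tilt))
    if (!up) hel <- hel %*% t(rot_x(pi))
    hel <- hel %*% t(rot_z(azim) %*% rot_y(tilt) %*% rot_z(-azim))
    hel <- sweep(hel, 2, -center)
    start_side <- if (up) "side1" else "side2"
    seg_rows[[h]] <- data.frame(start = pos + 1L, end = pos + hl,
                                start_side = start_side,
                                end_side = flip_side(start_side),
                                stringsAsFactors = FALSE)
    ## N-terminal loop before the first helix, on its start side
    if (h == 1) {
      lz <- if (up) -(half + 3) else half + 3
      nt <- cbind(center[1] + seq(-3 * ll, -3, length.out = ll),
                  center[2], lz)
      coords <- c(coords, list(nt))
      labels <- c(labels, rep(if (up) "I" else "O", ll))
      pos <- pos + ll
      seg_rows[[h]]$start <- pos + 1L
      seg_rows[[h]]$end <- pos + hl
    }
    coords <- c(coords, list(hel))
    labels <- c(labels, rep("M", hl))
    pos <- pos + hl
    ## loop after the helix, bulging past the slab on the end side
    end_up <- up  # helix ends at +z when built upward
    lz <- if (end_up) half + 3 else -(half + 3)
    from <- hel[hl, ]
    nxt_center <- c(spec$radius * cos(2 * pi * h / spec$n_helices),
                    spec$radius * sin(2 * pi * h / spec$n_helices), 0)
    to <- if (h < spec$n_helices) c(nxt_center[1:2], lz) else from + c(6, 0, 0)
    tloop <- seq(0, 1, length.out = ll + 2)[2:(ll + 1)]
    loop <- cbind(from[1] + (to[1] - from[1]) * tloop,
                  from[2] + (to[2] - from[2]) * tloop,
                  lz + 2 * sin(pi * tloop))
    coords <- c(coords, list(loop))
    labels <- c(labels, rep(if (end_up) "O" else "I", ll))
    pos <- pos + ll
  }
  xyz <- do.call(rbind, coords)
  segs <- do.call(rbind, seg_rows)
  xyz <- calibrate_thickness(xyz, segs, spec$target_thickness)
  if (spec$noise_sigma > 0)
    xyz <- xyz + local_seed(spec$seed,
                            matrix(rnorm(length(xyz), sd = spec$noise_sigma),
                                   ncol = 3))
  n <- nrow(xyz)
  plddt <- ifelse(labels == "M", spec$plddt_tm, spec$plddt_loop)
  id <- sprintf("bundle_n%d_t%g_seed%d", spec$n_helices,
                spec$target_thickness, spec$seed)
  s <- new_structure(data.frame(chain = "A", resno = seq_len(n),
                                ins = NA_character_, resid = "ALA",
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                plddt = plddt, stringsAsFactors = FALSE),
                     id = id, source_format = "synthetic")
  topo <- new_topology(id, n, segs, reliability = spec$reliability)
  list(structure = s, topology = topo,
       ground_truth = c(unclass(spec), list(thickness = spec$target_thickness)))
}

#' Build a decoy (deliberately mis-built) structure
#'
#' Emulates characteristic AlphaFold2 failure modes while keeping the
#' original topology annotation, so the thickness statistic sees the
#' mismatch: `invert_helix` reflects one helix through the membrane
#' midplane (its endpoints land on the wrong sides, shortening the
#' side1-side2 distance), `collapse` rescales all z by 0.4 (thickness
#' drops below the 15 A flag), `shear` translates half the helices along z.
#'
#' @param s a `memqa_structure` from [generate_bundle()].
#' @param annotation the matching `memqa_topology`.
#' @param mode `"invert_helix"`, `"collapse"` or `"shear"`.
#' @param helix index of the helix to invert (default 1).
#' @param shear_dz z-shift in Angstrom for `"shear"` (default 20).
#' @return the decoy `memqa_structure`.
#' @export
make_decoy <- function(s, annotation, mode = c("invert_helix", "collapse", "shear"),
                       helix = 1L, shear_dz = 20) {
  mode <- match.arg(mode)
  segs <- annotation$segments
  if (!nrow(segs)) stop("annotation has no TM segments")
  df <- as.data.frame(s)
  ends <- match(c(segs$start, segs$end), df$resno)
  mid <- mean(df$z[ends])
  if (mode == "invert_helix") {
    idx <- df$resno >= segs$start[helix] & df$resno <= segs$end[helix]
    df$z[idx] <- 2 * mid - df$z[idx]
  } else if (mode == "collapse") {
    df$z <- mid + 0.4 * (df$z - mid)
  } else {
    nh <- nrow(segs)
    moved <- seq_len(ceiling(nh / 2))
    idx <- rep(FALSE, nrow(df))
    for (h in moved)
      idx <- idx | (df$resno >= segs$start[h] & df$resno <= segs$end[h])
    df$z[idx] <- df$z[idx] + shear_dz
  }
  new_structure(df, id = paste0(attr(s, "id"), "_", mode),
                source_format = "synthetic")
}

#' Randomly rotate, translate and perturb a structure
#'
#' Applies a uniformly random proper rotation, a random translation in
#' \[-50, 50\]^3 Angstrom and i.i.d. Gaussian coordinate noise, all drawn
#' deterministically from `rotation_seed`.
#'
#' @param s a `memqa_structure`.
#' @param rotation_seed integer seed.
#' @param noise_sigma noise standard deviation in Angstrom (default 0).
#' @return the transformed `memqa_structure`.
#' @export
perturb_structure <- function(s, rotation_seed, noise_sigma = 0) {
  df <- as.data.frame(s)
  has <- !is.na(df$x)
  xyz <- as.matrix(df[has, c("x", "y", "z")])
  xyz <- local_seed(rotation_seed, {
    rot <- random_rotation()
    tr <- runif(3, -50, 50)
    out <- transform_coords(xyz, rot, tr)
    if (noise_sigma > 0)
      out <- out + matrix(rnorm(length(out), sd = noise_sigma), ncol = 3)
    out
  })
  df[has, c("x", "y", "z")] <- xyz
  new_structure(df, id = attr(s, "id"), source_format = attr(s, "source_format"))
}

#' Generate a seeded random coil
#'
#' A C-alpha random walk with 3.8 A steps and a mild excluded-volume
#' rejection, used as an "unrelated structure" negative control.
#'
#' @param n_res number of residues.
#' @param seed integer seed.
#' @param plddt confidence painted on all residues.
#' @return a `memqa_structure`.
#' @export
generate_coil <- function(n_res, seed, plddt = 50) {
  xyz <- local_seed(seed, {
    out <- matrix(0, n_res, 3)
    for (i in 2:n_res) {
      repeat {
        step <- rnorm(3)
        cand <- out[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
        if (i < 4 || min(dist_matrix(matrix(cand, 1),
                                     out[seq_len(i - 3), , drop = FALSE])) > 4)
          break
      }
      out[i, ] <- cand
    }
    out
  })
  new_structure(data.frame(chain = "A", resno = seq_len(n_res),
                           ins = NA_character_, resid = "GLY",
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           plddt = plddt, stringsAsFactors = FALSE),
                id = sprintf("coil_n%d_seed%d", n_res, seed),
                source_format = "synthetic")
}

#' Write a fabricated hmmsearch per-domain table
#'
#' Emits a format-valid HMMER `--domtblout` file that [parse_domtbl()]
#' round-trips; non-essential columns carry placeholder values.
#'
#' @param hits data frame as returned by [parse_domtbl()] (columns
#'   `target_id`, `hmm_name`, `hmm_length`, `e_value`, `full_e_value`
#'   (optional), `hmm_from`, `hmm_to`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_domtbl <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(hits)) {
    full_e <- if ("full_e_value" %in% names(hits)) hits$full_e_value
              else hits$e_value
    for (i in seq_len(nrow(hits))) {
      ali_len <- hits$hmm_to[i] - hits$hmm_from[i] + 1
      writeLines(sprintf(
        "%-20s -          %5d %-20s PF%05d.1  %5d %9.3g %6.1f %5.1f %3d %3d %9.3g %9.3g %6.1f %5.1f %5d %5d %5d %5d %5d %5d 0.95 -",
        hits$target_id[i], 400L, hits$hmm_name[i], i, hits$hmm_length[i],
        full_e[i], 100, 0.1, 1L, 1L, hits$e_value[i], hits$e_value[i],
        95, 0.1, hits$hmm_from[i], hits$hmm_to[i],
        10L, 10L + ali_len - 1L, 8L, 12L + ali_len - 1L), con)
    }
  }
  invisible(path)
}
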