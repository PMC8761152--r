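#' Residue correspondence between two structures
#'
#' An ordered, strictly monotone mapping of query residue numbers onto
#' reference residue numbers, the mapping under which TM-score, GDT_TS and
#' RMSD are computed.
#'
#' @param qpos,rpos integer residue numbers, strictly increasing.
#' @param query_id,reference_id identifiers.
#' @return a `memqa_correspondence` data frame with columns `qpos`, `rpos`.
#' @export
new_correspondence <- function(qpos, rpos, query_id = "query",
                               reference_id = "reference") {
  if (length(qpos) != length(rpos)) stop("unequal correspondence columns")
  if (length(qpos)) {
    if (is.unsorted(qpos, strictly = TRUE) ||
        is.unsorted(rpos, strictly = TRUE))
      stop("correspondence must be strictly increasing in both columns")
  }
  structure(data.frame(qpos = as.integer(qpos), rpos = as.integer(rpos)),
            query_id = query_id, reference_id = reference_id,
            class = c("memqa_correspondence", "data.frame"))
}

#' Identity correspondence for equal-numbering structures
#' @param s a `memqa_structure`.
#' @return a [new_correspondence()] mapping each residue to itself.
#' @export
identity_correspondence <- function(s) {
  pos <- s$resno[!is.na(s$x)]
  new_correspondence(pos, pos, attr(s, "id"), attr(s, "id"))
}

## Paired coordinate matrices for a correspondence.
corr_coords <- function(query, reference, corr) {
  qxyz <- ca_coords(query); rxyz <- ca_coords(reference)
  qi <- match(corr$qpos, as.integer(rownames(qxyz)))
  ri <- match(corr$rpos, as.integer(rownames(rxyz)))
  if (anyNA(qi) || anyNA(ri))
    stop("correspondence refers to residues without C-alpha coordinates")
  list(q = qxyz[qi, , drop = FALSE], r = rxyz[ri, , drop = FALSE])
}

#' Optimal rigid superposition (Kabsch)
#'
#' Closed-form least-squares fit of paired point sets over proper rotations
#' via SVD of the cross-covariance matrix.  The returned transform maps a
#' query point x to `rotation %*% x + translation` on the reference frame.
#'
#' @param query_coords,reference_coords equal-size n x 3 matrices, n >= 3,
#'   not collinear.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3) and `rmsd` (the minimized value, Angstrom).
#' @export
kabsch_superpose <- function(query_coords, reference_coords) {
  q <- as.matrix(query_coords); r <- as.matrix(reference_coords)
  if (!is.numeric(q) || !is.numeric(r) || ncol(q) != 3 || ncol(r) != 3 ||
      nrow(q) != nrow(r)) stop("need equal-size n x 3 coordinate matrices")
  n <- nrow(q)
  if (n < 3) stop("underdetermined: need at least 3 point pairs")
  cq <- colMeans(q); cr <- colMeans(r)
  qc <- sweep(q, 2, cq); rc <- sweep(r, 2, cr)
  h <- crossprod(qc, rc)
  sv <- svd(h)
  if (sv$d[1] > 0 && sv$d[2] / sv$d[1] < 1e-10)
    stop("underdetermined: degenerate (collinear) geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cq)
  fitted <- qc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' TM-score distance scale d0
#'
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom for short
#' lengths, the length-dependent scale that makes TM-score independent of
#' protein size.
#'
#' @param L normalization length (>= 1).
#' @return d0 in Angstrom.
#' @export
d0 <- function(L) {
  stopifnot(L >= 1)
  raw <- ifelse(L > 15, 1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
  pmax(raw, 0.5)
}

tm_sum <- function(d, d0_value) sum(1 / (1 + (d / d0_value)^2))

pair_dist <- function(a, b) sqrt(rowSums((a - b)^2))

## Iterative seed-and-extend TM search from one seed index set: superpose on
## the seed, then repeatedly re-superpose on the pairs within a shrinking
## distance cutoff (d0 down to d0/2 + 1, floor 3 A) until the inclusion set
## stabilizes.  Returns the best transform found, scored by the TM sum over
## all pairs.
refine_superposition <- function(q, r, seed_idx, d0_value, max_iter = 20,
                                 cutoff = NULL) {
  n <- nrow(q)
  fit <- tryCatch(kabsch_superpose(q[seed_idx, , drop = FALSE],
                                   r[seed_idx, , drop = FALSE]),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  best <- NULL
  prev_sel <- integer()
  for (j in seq_len(max_iter)) {
    d <- pair_dist(transform_coords(q, fit$rotation, fit$translation), r)
    score <- tm_sum(d, d0_value)
    if (is.null(best) || score > best$score)
      best <- list(score = score, rotation = fit$rotation,
                   translation = fit$translation, d = d)
    cut <- cutoff %||%
      max(3, d0_value + (d0_value / 2 + 1 - d0_value) * (j - 1) / (max_iter - 1))
    sel <- which(d <= cut)
    if (length(sel) < 4) sel <- order(d)[seq_len(min(4, n))]
    if (identical(sel, prev_sel)) break
    prev_sel <- sel
    fit <- tryCatch(kabsch_superpose(q[sel, , drop = FALSE],
                                     r[sel, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) break
  }
  best
}

## Seed index windows.  Small problems (n <= 32) are seeded exhaustively
## with every contiguous window of length >= 4; larger ones use fragment
## lengths L, L/2, L/4 (>= 4) with starts every half fragment.
seed_windows <- function(n) {
  out <- list()
  if (n <= 32) {
    for (len in 4:n)
      for (s0 in 1:(n - len + 1))
        out[[length(out) + 1]] <- seq(s0, s0 + len - 1)
    return(out)
  }
  lens <- unique(pmax(4, floor(n / c(1, 2, 4))))
  lens <- lens[lens <= n]
  for (len in lens) {
    starts <- unique(c(seq(1, n - len + 1, by = max(1, floor(len / 2))),
                       n - len + 1))
    for (s0 in starts) out[[length(out) + 1]] <- seq(s0, s0 + len - 1)
  }
  out
}

#' TM-score of a correspondence
#'
#' Template-modeling score: the superposition-maximized value of
#' `(1/L_norm) * sum_i 1 / (1 + (d_i / d0(L_norm))^2)` over the aligned
#' pairs, where `L_norm` is the full residue count of the normalization
#' structure.  The maximization uses the standard iterative fragment-seeded
#' search (seed windows of length L, L/2, L/4, iterative re-superposition on
#' a shrinking distance cutoff).  Scores above 0.5 indicate the same fold,
#' below 0.3 structurally unrelated chains.
#'
#' @param query,reference `memqa_structure` objects.
#' @param corr a [new_correspondence()]; all paired residues need C-alpha
#'   coordinates.
#' @param normalization `"reference"` (default, fold-library convention) or
#'   `"query"`.
#' @param d0_value optional override of the [d0()] scale (used e.g. to
#'   compare normalizations with a common per-pair weight).
#' @param compute_gdt also run the GDT_TS search (default `TRUE`).
#' @param superposition optional fixed transform `list(rotation,
#'   translation)`; when given the score is evaluated at that superposition
#'   with no search (the maximizing search will otherwise exploit the
#'   convexity of the per-pair weight, e.g. an all-pairs-at-d0 construction
#'   scores exactly 0.5 at its least-squares optimum but more under the
#'   free maximization).
#' @return a `memqa_superposition` list: `rotation`, `translation` (best
#'   TM transform), `rmsd` (Kabsch RMSD over all aligned pairs), `tm_score`,
#'   `gdt_ts`, `n_aligned`, `normalization_length`, `d0`.
#' @export
tm_score <- function(query, reference, corr,
                     normalization = c("reference", "query"),
                     d0_value = NULL, compute_gdt = TRUE,
                     superposition = NULL) {
  normalization <- match.arg(normalization)
  if (!nrow(corr)) stop("empty correspondence")
  cc <- corr_coords(query, reference, corr)
  l_norm <- if (normalization == "reference") n_residues(reference)
            else n_residues(query)
  d0v <- d0_value %||% d0(l_norm)
  if (!is.null(superposition)) {
    d <- pair_dist(transform_coords(cc$q, superposition$rotation,
                                    superposition$translation), cc$r)
    best <- list(score = tm_sum(d, d0v),
                 rotation = superposition$rotation,
                 translation = superposition$translation)
  } else {
    best <- NULL
    for (idx in seed_windows(nrow(cc$q))) {
      cand <- refine_superposition(cc$q, cc$r, idx, d0v)
      if (!is.null(cand) && (is.null(best) || cand$score > best$score))
        best <- cand
    }
    if (is.null(best)) stop("degenerate geometry: no seed could be superposed")
  }
  full <- tryCatch(kabsch_superpose(cc$q, cc$r), error = function(e) NULL)
  structure(list(rotation = best$rotation, translation = best$translation,
                 rmsd = if (is.null(full)) NA_real_ else full$rmsd,
                 tm_score = best$score / l_norm,
                 gdt_ts = if (compute_gdt)
                   gdt_search(cc$q, cc$r, d0v, superposition = superposition)
                 else NA_real_,
                 n_aligned = nrow(corr),
                 normalization_length = l_norm, d0 = d0v),
            class = "memqa_superposition")
}

#' @export
print.memqa_superposition <- function(x, ...) {
  gdt <- if (is.na(x$gdt_ts)) "-" else sprintf("%.2f", x$gdt_ts)
  cat(sprintf("<memqa_superposition> n_aligned %d | TM-score %.4f (L_norm %d) | RMSD %.3f A | GDT_TS %s\n",
              x$n_aligned, x$tm_score, x$normalization_length, x$rmsd, gdt))
  invisible(x)
}

## Shared GDT search: for each cutoff, maximize the number of pairs
## simultaneously under the cutoff with the same seed-and-extend scheme.
gdt_search <- function(q, r, d0_value, cutoffs = c(1, 2, 4, 8),
                       superposition = NULL) {
  n <- nrow(q)
  if (!is.null(superposition)) {
    d <- pair_dist(transform_coords(q, superposition$rotation,
                                    superposition$translation), r)
    return(mean(vapply(cutoffs, function(cut) 100 * sum(d <= cut) / n,
                       numeric(1))))
  }
  seeds <- seed_windows(n)
  pct <- vapply(cutoffs, function(cut) {
    best_count <- 0L
    for (idx in seeds) {
      fit <- tryCatch(kabsch_superpose(q[idx, , drop = FALSE],
                                       r[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      prev_sel <- integer()
      for (j in 1:20) {
        d <- pair_dist(transform_coords(q, fit$rotation, fit$translation), r)
        best_count <- max(best_count, sum(d <= cut))
        sel <- which(d <= cut)
        if (length(sel) < 4) sel <- order(d)[seq_len(min(4, n))]
        if (identical(sel, prev_sel)) break
        prev_sel <- sel
        fit <- tryCatch(kabsch_superpose(q[sel, , drop = FALSE],
                                         r[sel, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(fit)) break
      }
    }
    100 * best_count / n
  }, numeric(1))
  mean(pct)
}

#' GDT_TS of a correspondence
#'
#' Global distance test (total score): the mean over the 1, 2, 4 and 8
#' Angstrom cutoffs of the maximum percentage of aligned pairs that can be
#' superposed simultaneously within the cutoff, found with the same
#' seed-and-extend search as [tm_score()].
#'
#' @inheritParams tm_score
#' @return GDT_TS in \[0, 100\].
#' @export
gdt_ts <- function(query, reference, corr, superposition = NULL) {
  if (!nrow(corr)) stop("empty correspondence")
  cc <- corr_coords(query, reference, corr)
  gdt_search(cc$q, cc$r, d0(nrow(cc$q)), superposition = superposition)
}

#' Sequence-independent structural alignment
#'
#' Finds a monotone residue correspondence between two C-alpha traces
#' without using sequence information (TM folds share the same architecture
#' at sequence identities well below 30%, so sequence alignment is not an
#' option).  Seeds come from gapless threading of the shorter chain onto the
#' longer at a scan of offsets; each seed superposition is refined by
#' alternating (i) dynamic programming over the similarity matrix
#' `S_ij = 1 / (1 + (d_ij / d0)^2)` with an affine gap penalty (open 0.6,
#' extension 0, free end gaps) and (ii) TM-style re-superposition on the
#' current correspondence, until the correspondence is stable or
#' `max_iter` rounds.  The correspondence with the best TM sum wins.
#'
#' @param query,reference `memqa_structure` objects with >= 8 C-alpha.
#' @param max_iter maximum DP/superposition rounds per seed (default 30).
#' @param max_seeds cap on the number of threading offsets scanned
#'   (default 15, always including the zero offset).
#' @return a [new_correspondence()].
#' @export
structural_align <- function(query, reference, max_iter = 30, max_seeds = 15) {
  qxyz <- ca_coords(query); rxyz <- ca_coords(reference)
  nq <- nrow(qxyz); nr <- nrow(rxyz)
  if (nq < 8 || nr < 8) stop("structures must have at least 8 C-alpha each")
  d0s <- d0(min(nq, nr))
  offsets <- seq(-(nr - 8), nq - 8)
  if (length(offsets) > max_seeds) {
    offsets <- unique(c(0, round(seq(min(offsets), max(offsets),
                                     length.out = max_seeds))))
  }
  best <- NULL
  for (off in offsets) {
    i <- seq(max(1, 1 + off), min(nq, nr + off))
    j <- i - off
    if (length(i) < 8) next
    fit <- tryCatch(kabsch_superpose(qxyz[i, , drop = FALSE],
                                     rxyz[j, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pairs <- cbind(i, j)
    for (it in seq_len(max_iter)) {
      dm <- dist_matrix(transform_coords(qxyz, fit$rotation, fit$translation),
                        rxyz)
      s <- 1 / (1 + (dm / d0s)^2)
      new_pairs <- gotoh_align(s, 0.6)
      if (!nrow(new_pairs)) break
      ref <- refine_superposition(qxyz[new_pairs[, 1], , drop = FALSE],
                                  rxyz[new_pairs[, 2], , drop = FALSE],
                                  seq_len(nrow(new_pairs)), d0s, max_iter = 10)
      if (is.null(ref)) break
      fit <- list(rotation = ref$rotation, translation = ref$translation)
      stable <- nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)
      pairs <- new_pairs
      if (stable) break
    }
    d <- pair_dist(transform_coords(qxyz[pairs[, 1], , drop = FALSE],
                                    fit$rotation, fit$translation),
                   rxyz[pairs[, 2], , drop = FALSE])
    score <- tm_sum(d, d0s)
    if (is.null(best) || score > best$score)
      best <- list(score = score, pairs = pairs)
  }
  if (is.null(best)) stop("no alignment seed could be superposed")
  new_correspondence(as.integer(rownames(qxyz))[best$pairs[, 1]],
                     as.integer(rownames(rxyz))[best$pairs[, 2]],
                     attr(query, "id"), attr(reference, "id"))
}

## Full pairwise Euclidean distance matrix between two n x 3 point sets.
dist_matrix <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
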