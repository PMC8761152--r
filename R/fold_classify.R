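#' Reference fold library entry
#'
#' @param fold_name fold family name (defaults follow the eight ABC
#'   transporter TM folds: Pgp, ABCG2, MalFG, BtuC, EcfT, LptFG, MacB,
#'   MlaE).
#' @param structure a `memqa_structure` carrying the TM domain only.
#' @param source_id identifier of the source model.
#' @param tm_ranges optional residue ranges used to carve the TM domain.
#' @return a `memqa_reference_fold` list.
#' @export
reference_fold <- function(fold_name, structure, source_id = fold_name,
                           tm_ranges = NULL) {
  if (!nrow(structure)) stop("empty reference structure")
  structure(list(fold_name = fold_name, structure = structure,
                 source_id = source_id, tm_ranges = tm_ranges),
            class = "memqa_reference_fold")
}

#' Default ABC TM fold family names
#' @export
abc_fold_names <- function() {
  c("Pgp", "ABCG2", "MalFG", "BtuC", "EcfT", "LptFG", "MacB", "MlaE")
}

#' Synthetic reference fold library
#'
#' Builds eight structurally distinct synthetic helix bundles (varying helix
#' count, radius, tilt and helix length) named after the ABC TM fold
#' families, for testing the classification machinery without external
#' structure downloads.  Real libraries are supplied as a list of
#' [reference_fold()] entries carved from experimental structures.
#'
#' @param seed integer seed; each fold derives its own sub-seed.
#' @param fold_names names for the entries (default [abc_fold_names()]).
#' @return named list of `memqa_reference_fold` entries.
#' @export
synthetic_reference_library <- function(seed = 100, fold_names = abc_fold_names()) {
  n <- length(fold_names)
  params <- data.frame(
    n_helices = c(6, 2, 4, 5, 3, 4, 4, 5)[seq_len(n)],
    helix_length = c(21, 25, 21, 17, 23, 21, 25, 21)[seq_len(n)],
    radius = c(9, 6, 11, 8, 7, 14, 10, 12)[seq_len(n)],
    tilt_deg = c(0, 10, 20, 5, 15, 0, 25, 12)[seq_len(n)],
    target_thickness = c(30, 28, 24, 22, 27, 30, 26, 24)[seq_len(n)]
  )
  out <- lapply(seq_len(n), function(i) {
    spec <- bundle_spec(n_helices = params$n_helices[i],
                        helix_length = params$helix_length[i],
                        radius = params$radius[i],
                        tilt_deg = params$tilt_deg[i],
                        target_thickness = params$target_thickness[i],
                        seed = seed + i)
    b <- generate_bundle(spec)
    reference_fold(fold_names[i], b$structure,
                   source_id = attr(b$structure, "id"))
  })
  names(out) <- fold_names
  out
}

#' Classify a TM domain against a reference fold library
#'
#' Aligns the query against every reference with [structural_align()],
#' scores each with [tm_score()] (normalized by the reference length), and
#' assigns the best-scoring fold.  Verdicts follow the TM-score scale:
#' best score >= 0.5 `same_fold`, <= 0.3 `unrelated`, in between
#' `twilight`.  Equal best scores break deterministically by fold name
#' order within the library.
#'
#' @param query a `memqa_structure` with >= 8 C-alpha.
#' @param library list of [reference_fold()] entries with unique names.
#' @param thresholds numeric `c(unrelated = 0.3, same_fold = 0.5)`.
#' @return a `memqa_fold_assignment` list: `query_id`, `scores` (named),
#'   `best_fold`, `best_score`, `verdict`.
#' @export
classify_fold <- function(query, library,
                          thresholds = c(unrelated = 0.3, same_fold = 0.5)) {
  if (!length(library)) stop("empty reference library")
  nm <- vapply(library, `[[`, "", "fold_name")
  if (anyDuplicated(nm)) stop("duplicate fold names in library")
  scores <- vapply(library, function(ref) {
    corr <- structural_align(query, ref$structure)
    tm_score(query, ref$structure, corr, normalization = "reference",
             compute_gdt = FALSE)$tm_score
  }, numeric(1))
  names(scores) <- nm
  best_i <- which(scores == max(scores))[1]
  best <- scores[best_i]
  verdict <- if (best >= thresholds[["same_fold"]]) "same_fold"
             else if (best <= thresholds[["unrelated"]]) "unrelated"
             else "twilight"
  structure(list(query_id = attr(query, "id"), scores = scores,
                 best_fold = unname(nm[best_i]), best_score = unname(best),
                 verdict = verdict),
            class = "memqa_fold_assignment")
}

#' @export
print.memqa_fold_assignment <- function(x, ...) {
  cat(sprintf("<memqa_fold_assignment> %s -> %s (TM-score %.3f, %s)\n",
              x$query_id, x$best_fold, x$best_score, x$verdict))
  invisible(x)
}

#' Parse an HMMER per-domain table (domtblout)
#'
#' Reads `hmmsearch --domtblout` output: one hit per domain line, using the
#' domain's independent E-value (column 13) by default and the hmm profile
#' coordinates (columns 16--17).
#'
#' @param path file path.
#' @param evalue `"domain"` (independent i-Evalue, default) or `"full"`
#'   (full-sequence E-value, column 7).
#' @return data frame with columns `target_id`, `hmm_name`, `hmm_length`,
#'   `e_value`, `full_e_value`, `hmm_from`, `hmm_to`.
#' @export
parse_domtbl <- function(path, evalue = c("domain", "full")) {
  evalue <- match.arg(evalue)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 22)
      stop("malformed domtbl line ", i, ": expected >= 22 fields, got ",
           length(f))
    data.frame(target_id = f[1], hmm_name = f[4],
               hmm_length = as.integer(f[6]),
               e_value = as.numeric(if (evalue == "domain") f[13] else f[7]),
               full_e_value = as.numeric(f[7]),
               hmm_from = as.integer(f[16]), hmm_to = as.integer(f[17]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(target_id = character(), hmm_name = character(),
                         hmm_length = integer(), e_value = numeric(),
                         full_e_value = numeric(), hmm_from = integer(),
                         hmm_to = integer(), stringsAsFactors = FALSE)
  bad <- out$e_value <= 0 | out$hmm_from < 1 | out$hmm_from > out$hmm_to |
    out$hmm_to > out$hmm_length
  if (any(bad)) stop("invalid hit fields in domtbl (E-value or hmm coords)")
  out
}

#' PFAM-based target selection filter
#'
#' Keeps hits with E-value at most `max_e` and profile coverage
#' `(hmm_to - hmm_from + 1) / hmm_length` of at least `min_cov` (both
#' boundaries inclusive, i.e. coverage exactly 90% of the profile passes
#' the default).  Optionally deduplicates per target, keeping the
#' lowest-E hit (ties broken by hmm name).  Output order is sorted by
#' target then hmm name, so the result is independent of input order and
#' the filter is idempotent.
#'
#' @param hits data frame as from [parse_domtbl()].
#' @param max_e maximum E-value (default 0.001).
#' @param min_cov minimum profile-length coverage fraction (default 0.9).
#' @param dedupe keep only the best hit per target (default `TRUE`).
#' @return the filtered data frame.
#' @export
pfam_filter <- function(hits, max_e = 0.001, min_cov = 0.9, dedupe = TRUE) {
  if (!nrow(hits)) return(hits)
  cov_ok <- (hits$hmm_to - hits$hmm_from + 1) >= min_cov * hits$hmm_length
  out <- hits[hits$e_value <= max_e & cov_ok, , drop = FALSE]
  out <- out[order(out$target_id, out$e_value, out$hmm_name, out$hmm_from), ,
             drop = FALSE]
  if (dedupe) out <- out[!duplicated(out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Concatenate two chains with a disordered linker
#'
#' Builds the single-chain dimer construct used when a predictor accepts
#' only one chain: `seq_a + linker + seq_b`, with the coordinate ranges of
#' the three segments recorded for downstream chain splitting.  The linker
#' is typically a long intrinsically disordered sequence (e.g. the
#' 126-residue CFTR R-domain fragment, residues 675--800) so the two chains
#' are not conformationally constrained.
#'
#' @param seq_a,seq_b,linker one-letter amino-acid strings (linker may be
#'   empty).
#' @return list with `sequence` and `ranges` (data frame `segment`,
#'   `start`, `end`, 1-based inclusive).
#' @export
prepare_dimer_sequence <- function(seq_a, seq_b, linker = "") {
  check <- function(x, what) {
    ch <- strsplit(toupper(x), "")[[1]]
    if (length(ch) && !all(ch %in% AA_LETTERS))
      stop("invalid amino-acid character in ", what, ": ",
           paste(setdiff(unique(ch), AA_LETTERS), collapse = ","))
    paste(ch, collapse = "")
  }
  a <- check(seq_a, "seq_a"); l <- check(linker, "linker")
  b <- check(seq_b, "seq_b")
  if (!nchar(a) || !nchar(b)) stop("seq_a and seq_b must be non-empty")
  na <- nchar(a); nl <- nchar(l); nb <- nchar(b)
  ranges <- data.frame(
    segment = c("chain_a", "linker", "chain_b"),
    start = c(1L, if (nl) na + 1L else NA_integer_, na + nl + 1L),
    end = c(na, if (nl) na + nl else NA_integer_, na + nl + nb),
    stringsAsFactors = FALSE)
  if (!nl) ranges <- ranges[ranges$segment != "linker", ]
  list(sequence = paste0(a, l, b), ranges = ranges)
}
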