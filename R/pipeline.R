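## Deterministic TSV writer: '#'-prefixed header block echoing the
## configuration, then tab-separated rows.  No timestamps, so repeated runs
## are byte-identical.
write_tsv_report <- function(df, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# memqa %s", as.character(utils::packageVersion("memqa"))),
             con)
  for (nm in names(config))
    writeLines(sprintf("# %s = %s", nm,
                       paste(format(config[[nm]], digits = 10), collapse = ",")),
               con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "g"))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Proteome-scale structure QC
#'
#' Runs the per-protein quality assessment over a directory of predicted
#' structures and a topology XML: mean pLDDT (all / TM / non-TM),
#' reliability-bin fractions, hydrophobic thickness with its flag and
#' confidence class.  Structures are joined to topology entries by file
#' stem; structures without a topology entry are reported with status
#' `no_topology`.  Row order is sorted by `protein_id`, and written outputs
#' are byte-identical across reruns.
#'
#' @param structure_dir directory of `.pdb` / `.cif` files.
#' @param topology_xml path to a topology XML ([parse_topology_xml()]).
#' @param out_dir optional output directory; when given, writes
#'   `qc_per_protein.tsv`, `qc_summary.tsv` and `qc_manifest.json`.
#' @param band thickness ok-band (default `c(15, 35)` Angstrom).
#' @param reliability_threshold topology reliability cutoff (default 90).
#' @param edges pLDDT bin edges.
#' @return list with `per_protein` (data frame) and `aggregate` (one-row
#'   data frame: counts, fraction flagged, mean bin fractions).
#' @export
run_proteome_qc <- function(structure_dir, topology_xml, out_dir = NULL,
                            band = c(15, 35), reliability_threshold = 90,
                            edges = c(0, 50, 70, 90, 100)) {
  files <- sort(list.files(structure_dir, pattern = "\\.(pdb|cif|mmcif)$",
                           full.names = TRUE))
  if (!length(files)) stop("no structure files in ", structure_dir)
  topo <- parse_topology_xml(topology_xml)
  rows <- lapply(files, function(f) {
    s <- load_structure(f)
    id <- attr(s, "id")
    ps <- plddt_summary(s, topo[[id]], edges)
    base <- data.frame(protein_id = id, status = "ok",
                       stringsAsFactors = FALSE)
    if (is.null(topo[[id]])) {
      base$status <- "no_topology"
      th <- data.frame(thickness = NA_real_, n_side1 = NA_integer_,
                       n_side2 = NA_integer_, flag = NA_character_,
                       confidence_class = NA_character_,
                       cctop_reliability = NA_real_)
    } else if (!nrow(topo[[id]]$segments)) {
      base$status <- "no_tm_segments"
      th <- data.frame(thickness = NA_real_, n_side1 = NA_integer_,
                       n_side2 = NA_integer_, flag = NA_character_,
                       confidence_class = NA_character_,
                       cctop_reliability = topo[[id]]$reliability)
    } else {
      t0 <- hydrophobic_thickness(s, topo[[id]], band, reliability_threshold)
      th <- t0[setdiff(names(t0), "protein_id")]
    }
    cbind(base, ps[setdiff(names(ps), "protein_id")], th)
  })
  per_protein <- do.call(rbind, rows)
  per_protein <- per_protein[order(per_protein$protein_id), , drop = FALSE]
  rownames(per_protein) <- NULL
  scored <- !is.na(per_protein$flag)
  frac_cols <- grep("^frac_", names(per_protein), value = TRUE)
  aggregate <- data.frame(
    n_structures = nrow(per_protein),
    n_scored = sum(scored),
    n_flagged = sum(per_protein$flag[scored] == "suspect"),
    fraction_flagged = if (any(scored))
      sum(per_protein$flag[scored] == "suspect") / sum(scored) else NA_real_)
  for (fc in frac_cols) aggregate[[fc]] <- mean(per_protein[[fc]])
  config <- list(band = band, reliability_threshold = reliability_threshold,
                 bin_edges = edges)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_report(per_protein, file.path(out_dir, "qc_per_protein.tsv"),
                     config)
    write_tsv_report(aggregate, file.path(out_dir, "qc_summary.tsv"), config)
    jsonlite::write_json(
      list(inputs = list(structure_dir = basename(structure_dir),
                         n_files = length(files),
                         topology_xml = basename(topology_xml)),
           thresholds = config,
           counts = list(n_structures = aggregate$n_structures,
                         n_flagged = aggregate$n_flagged)),
      file.path(out_dir, "qc_manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(per_protein = per_protein, aggregate = aggregate)
}

#' Fold-library survey of a structure set
#'
#' Classifies every query structure against a reference fold library and
#' tabulates per-fold counts and best-score distributions (the boxplot
#' summaries).  An optional hmmsearch domain table restricts the survey to
#' the targets surviving the PFAM filter.
#'
#' @param query_dir directory of query structure files.
#' @param library list of [reference_fold()] entries.
#' @param domtbl optional path to a domtblout file; queries absent from the
#'   filtered table are dropped (and listed in the return value).
#' @param out_dir optional output directory (`survey_per_query.tsv`,
#'   `survey_by_fold.tsv`).
#' @param thresholds TM-score verdict bounds, as in [classify_fold()].
#' @param max_e,min_cov PFAM filter settings (defaults 0.001 and 0.9).
#' @return list with `per_query`, `by_fold` (per-fold count and five-number
#'   summary of best scores among `same_fold`/`twilight` assignments) and
#'   `excluded` (query ids removed by the PFAM filter).
#' @export
run_fold_survey <- function(query_dir, library, domtbl = NULL, out_dir = NULL,
                            thresholds = c(unrelated = 0.3, same_fold = 0.5),
                            max_e = 0.001, min_cov = 0.9) {
  files <- sort(list.files(query_dir, pattern = "\\.(pdb|cif|mmcif)$",
                           full.names = TRUE))
  if (!length(files)) stop("no structure files in ", query_dir)
  excluded <- character()
  if (!is.null(domtbl)) {
    kept <- pfam_filter(parse_domtbl(domtbl), max_e, min_cov)$target_id
    stems <- tools::file_path_sans_ext(basename(files))
    excluded <- stems[!stems %in% kept]
    files <- files[stems %in% kept]
    if (!length(files)) stop("PFAM filter removed every query")
  }
  nm <- vapply(library, `[[`, "", "fold_name")
  rows <- lapply(files, function(f) {
    fa <- classify_fold(load_structure(f), library, thresholds)
    out <- data.frame(query_id = fa$query_id, best_fold = fa$best_fold,
                      best_score = fa$best_score, verdict = fa$verdict,
                      stringsAsFactors = FALSE)
    out[paste0("tm_", nm)] <- as.list(unname(fa$scores))
    out
  })
  per_query <- do.call(rbind, rows)
  per_query <- per_query[order(per_query$query_id), , drop = FALSE]
  rownames(per_query) <- NULL
  matched <- per_query[per_query$verdict != "unrelated", , drop = FALSE]
  by_fold <- do.call(rbind, lapply(nm, function(f) {
    sc <- matched$best_score[matched$best_fold == f]
    data.frame(fold = f, n_matched = length(sc),
               min = if (length(sc)) min(sc) else NA_real_,
               q1 = if (length(sc)) unname(quantile(sc, 0.25)) else NA_real_,
               median = if (length(sc)) stats::median(sc) else NA_real_,
               q3 = if (length(sc)) unname(quantile(sc, 0.75)) else NA_real_,
               max = if (length(sc)) max(sc) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  config <- list(thresholds = thresholds, max_e = max_e, min_cov = min_cov)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_report(per_query, file.path(out_dir, "survey_per_query.tsv"),
                     config)
    write_tsv_report(by_fold, file.path(out_dir, "survey_by_fold.tsv"), config)
  }
  list(per_query = per_query, by_fold = by_fold, excluded = excluded)
}

#' Pairwise structural comparison report
#'
#' Loads two structures, optionally carves residue ranges (e.g. TM
#' domains), aligns them sequence-independently and reports RMSD, TM-score
#' under both normalizations, GDT_TS and the alignment size.  Optionally
#' writes the superposed query as a PDB.
#'
#' @param query_path,reference_path structure file paths (or
#'   `memqa_structure` objects).
#' @param query_ranges,reference_ranges optional ranges for
#'   [select_residues()].
#' @param out_pdb optional path for the superposed query.
#' @return list: `query_id`, `reference_id`, `n_aligned`, `rmsd`,
#'   `tm_score_ref_norm`, `tm_score_query_norm`, `gdt_ts`.
#' @export
run_pairwise <- function(query_path, reference_path, query_ranges = NULL,
                         reference_ranges = NULL, out_pdb = NULL) {
  q <- if (inherits(query_path, "memqa_structure")) query_path
       else load_structure(query_path)
  r <- if (inherits(reference_path, "memqa_structure")) reference_path
       else load_structure(reference_path)
  if (!is.null(query_ranges)) q <- select_residues(q, query_ranges)
  if (!is.null(reference_ranges)) r <- select_residues(r, reference_ranges)
  corr <- structural_align(q, r)
  res_r <- tm_score(q, r, corr, normalization = "reference")
  res_q <- tm_score(q, r, corr, normalization = "query", compute_gdt = FALSE)
  if (!is.null(out_pdb)) {
    df <- as.data.frame(q)
    has <- !is.na(df$x)
    df[has, c("x", "y", "z")] <-
      transform_coords(as.matrix(df[has, c("x", "y", "z")]),
                       res_r$rotation, res_r$translation)
    write_structure(new_structure(df, id = attr(q, "id")), out_pdb)
  }
  list(query_id = attr(q, "id"), reference_id = attr(r, "id"),
       n_aligned = res_r$n_aligned, rmsd = res_r$rmsd,
       tm_score_ref_norm = res_r$tm_score,
       tm_score_query_norm = res_q$tm_score, gdt_ts = res_r$gdt_ts)
}
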