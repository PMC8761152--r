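#' Mean pLDDT over a structure or region
#'
#' Unweighted arithmetic mean of per-residue confidences, optionally
#' restricted to a set of residue numbers (e.g. the TM segment positions).
#' Residues without a confidence value are excluded from the mean; their
#' count is attached as attribute `n_missing`.
#'
#' @param s a `memqa_structure`.
#' @param region optional integer vector of residue numbers.
#' @return the mean confidence.
#' @export
mean_plddt <- function(s, region = NULL) {
  v <- s$plddt
  if (!is.null(region)) {
    keep <- s$resno %in% region
    if (!any(keep)) stop("region does not intersect the residue set")
    v <- v[keep]
  }
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (!length(v)) stop("no residues with confidence in the requested region")
  structure(mean(v), n_missing = n_missing)
}

default_bin_labels <- c("very_low", "low", "confident", "very_high")

#' pLDDT reliability-bin fractions
#'
#' Fractions of values in half-open bins `[lo, hi)`, last bin closed.  The
#' default edges `0/50/70/90/100` are the reliability ranges used for the
#' AlphaFold2 human-proteome release (very low < 50, low 50--70, confident
#' 70--90, very high >= 90).
#'
#' @param values confidence scores in \[0, 100\].
#' @param edges increasing bin edges spanning the value range.
#' @return named numeric vector of fractions summing to 1.
#' @export
plddt_bins <- function(values, edges = c(0, 50, 70, 90, 100)) {
  if (!length(values)) stop("no values to bin")
  if (any(values < 0 | values > 100)) stop("confidence values outside [0, 100]")
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  nb <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  if (any(idx < 1 | idx > nb)) stop("values outside the binning range")
  counts <- tabulate(idx, nbins = nb)
  labels <- if (identical(edges, c(0, 50, 70, 90, 100))) default_bin_labels
            else paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  setNames(counts / length(values), labels)
}

#' Per-protein pLDDT summary
#'
#' Mean confidence over the whole chain, over TM-segment residues, and over
#' non-TM residues, plus reliability-bin fractions.
#'
#' @param s a `memqa_structure`.
#' @param annotation optional `memqa_topology`; without it (or without
#'   segments) the TM/non-TM means are `NA`.
#' @param edges bin edges for [plddt_bins()].
#' @return one-row data frame: `protein_id`, `mean_all`, `mean_tm`,
#'   `mean_non_tm`, one `frac_*` column per bin.
#' @export
plddt_summary <- function(s, annotation = NULL, edges = c(0, 50, 70, 90, 100)) {
  mean_all <- as.numeric(mean_plddt(s))
  mean_tm <- mean_non_tm <- NA_real_
  if (!is.null(annotation) && nrow(annotation$segments)) {
    tm_pos <- unlist(mapply(seq, annotation$segments$start,
                            annotation$segments$end, SIMPLIFY = FALSE))
    in_tm <- s$resno %in% tm_pos
    if (any(in_tm & !is.na(s$plddt)))
      mean_tm <- as.numeric(mean_plddt(s, region = s$resno[in_tm]))
    if (any(!in_tm & !is.na(s$plddt)))
      mean_non_tm <- as.numeric(mean_plddt(s, region = s$resno[!in_tm]))
  }
  fr <- plddt_bins(s$plddt[!is.na(s$plddt)], edges)
  out <- data.frame(protein_id = attr(s, "id"), mean_all = mean_all,
                    mean_tm = mean_tm, mean_non_tm = mean_non_tm,
                    stringsAsFactors = FALSE)
  out[paste0("frac_", names(fr))] <- as.list(fr)
  out
}

#' Thickness/reliability confidence class
#'
#' Cross-classifies the thickness statistic with the topology-prediction
#' reliability: a thickness inside the physiological band is `consistent`;
#' outside the band with high topology reliability the structure itself is
#' the `likely_af2_error`; outside the band with low reliability the case
#' falls in the `twilight` zone where either the structure or the topology
#' may be wrong.
#'
#' @param thickness hydrophobic thickness in Angstrom.
#' @param reliability topology prediction reliability in \[0, 100\].
#' @param reliability_threshold reliability at or above which topology is
#'   called high-confidence (default 90).
#' @param band closed ok-band in Angstrom, default `c(15, 35)`.
#' @return `"consistent"`, `"likely_af2_error"` or `"twilight"`.
#' @export
classify_confidence <- function(thickness, reliability,
                                reliability_threshold = 90,
                                band = c(15, 35)) {
  stopifnot(is.finite(thickness), is.finite(reliability))
  if (thickness >= band[1] && thickness <= band[2]) return("consistent")
  if (reliability >= reliability_threshold) "likely_af2_error" else "twilight"
}

#' Hydrophobic thickness of a predicted TM structure
#'
#' The thickness statistic: Euclidean distance between the unweighted
#' centroids of the C-alpha atoms of the TM-helix endpoints assigned to the
#' two membrane sides.  Values below 15 or above 35 Angstrom fall outside
#' the physiological hydrophobic-thickness range and flag the model as
#' `suspect` (the band boundaries count as ok).
#'
#' @param s a `memqa_structure`.
#' @param annotation a `memqa_topology` for the same protein.
#' @param band closed ok-band in Angstrom, default `c(15, 35)`.
#' @param reliability_threshold passed to [classify_confidence()].
#' @return one-row data frame: `protein_id`, `thickness`, `n_side1`,
#'   `n_side2`, `flag` (`ok`/`suspect`), `confidence_class`,
#'   `cctop_reliability`.
#' @export
hydrophobic_thickness <- function(s, annotation, band = c(15, 35),
                                  reliability_threshold = 90) {
  sides <- assign_membrane_sides(annotation)
  xyz <- ca_coords(s)
  pick <- function(pos, label) {
    hit <- match(pos, as.integer(rownames(xyz)))
    if (anyNA(hit))
      warning(sum(is.na(hit)), " ", label,
              " endpoint(s) without C-alpha skipped")
    hit <- hit[!is.na(hit)]
    if (!length(hit)) stop("all ", label, " endpoints lack coordinates")
    xyz[hit, , drop = FALSE]
  }
  p1 <- pick(sides$side1, "side1")
  p2 <- pick(sides$side2, "side2")
  thickness <- sqrt(sum((colMeans(p1) - colMeans(p2))^2))
  flag <- if (thickness >= band[1] && thickness <= band[2]) "ok" else "suspect"
  rel <- annotation$reliability %||% NA_real_
  cls <- if (is.na(rel)) NA_character_
         else classify_confidence(thickness, rel, reliability_threshold, band)
  data.frame(protein_id = annotation$protein_id, thickness = thickness,
             n_side1 = nrow(p1), n_side2 = nrow(p2), flag = flag,
             confidence_class = cls,
             cctop_reliability = annotation$reliability,
             stringsAsFactors = FALSE)
}
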