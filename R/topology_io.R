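#' Topology annotation container
#'
#' Per-protein membrane topology: transmembrane segments in 1-based
#' inclusive residue numbering, which membrane side each segment endpoint
#' faces, and the consensus-prediction reliability score.  Side labels use
#' the fixed mapping side1 = "inside", side2 = "outside".
#'
#' @param protein_id identifier.
#' @param sequence_length protein length.
#' @param segments data frame with columns `start`, `end`, `start_side`,
#'   `end_side` (values `"side1"` / `"side2"`); zero rows for a soluble
#'   protein.
#' @param reliability topology prediction reliability in \[0, 100\].
#' @param diagnostics character vector of consistency notes (e.g. segments
#'   whose two endpoints resolve to the same side).
#' @return a `memqa_topology` object.
#' @export
new_topology <- function(protein_id, sequence_length, segments,
                         reliability = NA_real_, diagnostics = character()) {
  if (nrow(segments)) {
    if (any(segments$start > segments$end)) stop("segment with start > end")
    if (any(segments$start < 1 | segments$end > sequence_length))
      stop("segment bounds outside [1, sequence_length]")
    if (is.unsorted(segments$start, strictly = TRUE))
      stop("segments must be sorted by start")
    if (any(utils::head(segments$end, -1) >= utils::tail(segments$start, -1)))
      stop("segments overlap")
  }
  structure(list(protein_id = protein_id,
                 sequence_length = as.integer(sequence_length),
                 segments = segments, reliability = reliability,
                 diagnostics = diagnostics),
            class = "memqa_topology")
}

#' @export
print.memqa_topology <- function(x, ...) {
  cat(sprintf("<memqa_topology> %s: length %d, %d TM segment(s), reliability %s\n",
              x$protein_id, x$sequence_length, nrow(x$segments),
              format(x$reliability)))
  invisible(x)
}

side_of_label <- function(lab) c(I = "side1", O = "side2")[lab]
label_of_side <- function(side) c(side1 = "I", side2 = "O")[side]
flip_side <- function(side) ifelse(side == "side1", "side2", "side1")

## Collapse a per-residue label vector (I/O/M/L) into a memqa_topology.
## L (re-entrant membrane loop) regions are excluded from segments and
## reported in diagnostics: the thickness statistic is defined on
## membrane-spanning helices only.
labels_to_topology <- function(labels, protein_id, reliability = NA_real_) {
  n <- length(labels)
  if (!all(labels %in% c("I", "O", "M", "L")))
    stop("unknown topology label(s): ",
         paste(setdiff(unique(labels), c("I", "O", "M", "L")), collapse = ","))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  diagnostics <- character()
  if (any(r$values == "L"))
    diagnostics <- c(diagnostics, sprintf(
      "%d re-entrant (L) region(s) excluded from side assignment",
      sum(r$values == "L")))
  mi <- which(r$values == "M")
  segs <- data.frame(start = integer(), end = integer(),
                     start_side = character(), end_side = character(),
                     stringsAsFactors = FALSE)
  for (k in mi) {
    prev <- rev(r$values[seq_len(k - 1)])
    prev <- prev[prev %in% c("I", "O")][1]
    nxt <- r$values[-seq_len(k)]
    nxt <- nxt[nxt %in% c("I", "O")][1]
    if (is.na(prev) && is.na(nxt))
      stop("TM segment with no flanking loop labels")
    start_side <- if (!is.na(prev)) unname(side_of_label(prev))
                  else flip_side(unname(side_of_label(nxt)))
    end_side <- if (!is.na(nxt)) unname(side_of_label(nxt))
                else flip_side(start_side)
    if (start_side == end_side)
      diagnostics <- c(diagnostics, sprintf(
        "segment %d-%d has both endpoints on %s (topology inconsistency)",
        starts[k], ends[k], start_side))
    segs <- rbind(segs, data.frame(start = starts[k], end = ends[k],
                                   start_side = start_side,
                                   end_side = end_side,
                                   stringsAsFactors = FALSE))
  }
  new_topology(protein_id, n, segs, reliability, diagnostics)
}

## Re-expand a topology into its per-residue label string.  Inverse of
## labels_to_topology for annotations without re-entrant regions.
topology_to_labels <- function(annotation) {
  n <- annotation$sequence_length
  segs <- annotation$segments
  labels <- character(n)
  if (!nrow(segs)) return(rep("I", n))
  prev_end <- 0L
  for (i in seq_len(nrow(segs))) {
    loop <- unname(label_of_side(segs$start_side[i]))
    if (segs$start[i] > prev_end + 1L)
      labels[(prev_end + 1L):(segs$start[i] - 1L)] <- loop
    labels[segs$start[i]:segs$end[i]] <- "M"
    prev_end <- segs$end[i]
  }
  if (prev_end < n)
    labels[(prev_end + 1L):n] <- unname(label_of_side(segs$end_side[nrow(segs)]))
  labels
}

#' Parse topology annotations from XML
#'
#' Reads the bundled HTP/CCTOP-like XML dialect (see
#' `system.file("extdata", "example_topology.xml", package = "memqa")`):
#' a `<topologies>` root with one `<protein id= length= reliability=>`
#' element per entry, containing `<region start= end= label=>` children
#' whose labels are `I` (inside loop), `O` (outside loop), `M`
#' (membrane-spanning segment) or `L` (re-entrant membrane loop).  Entries
#' without any `M` region are returned with zero segments (soluble), not
#' dropped.
#'
#' @param path XML file path.
#' @return named list of [new_topology()] annotations.
#' @export
parse_topology_xml <- function(path) {
  doc <- xml2::read_xml(path)
  prots <- xml2::xml_find_all(doc, ".//protein")
  out <- lapply(prots, function(p) {
    id <- xml2::xml_attr(p, "id")
    len <- as.integer(xml2::xml_attr(p, "length"))
    rel <- as.numeric(xml2::xml_attr(p, "reliability"))
    regions <- xml2::xml_find_all(p, "./region")
    labels <- rep(NA_character_, len)
    for (rg in regions) {
      a <- as.integer(xml2::xml_attr(rg, "start"))
      b <- as.integer(xml2::xml_attr(rg, "end"))
      if (is.na(a) || is.na(b) || a < 1 || b > len || a > b)
        stop("bad region bounds in entry ", id)
      labels[a:b] <- xml2::xml_attr(rg, "label")
    }
    if (anyNA(labels)) stop("regions do not tile entry ", id)
    labels_to_topology(labels, id, rel)
  })
  names(out) <- vapply(out, `[[`, "", "protein_id")
  out
}

#' Write topology annotations as XML
#'
#' Emits the same dialect [parse_topology_xml()] reads (closed loop with the
#' synthetic generator).
#'
#' @param annotations a `memqa_topology` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology_xml <- function(annotations, path) {
  if (inherits(annotations, "memqa_topology")) annotations <- list(annotations)
  doc <- xml2::xml_new_root("topologies")
  for (ann in annotations) {
    labels <- topology_to_labels(ann)
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    p <- xml2::xml_add_child(doc, "protein", id = ann$protein_id,
                             length = as.character(ann$sequence_length),
                             reliability = format(ann$reliability, digits = 10))
    for (k in seq_along(r$values))
      xml2::xml_add_child(p, "region", start = as.character(starts[k]),
                          end = as.character(ends[k]), label = r$values[k])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Assign TM-segment endpoints to the two membrane sides
#'
#' Each membrane-spanning segment contributes its start position to the side
#' of the preceding loop and its end position to the side of the following
#' loop, giving the two endpoint residue sets between whose C-alpha
#' centroids the hydrophobic thickness is measured.
#'
#' @param annotation a `memqa_topology` with at least one segment.
#' @return list with integer vectors `side1` and `side2` and a character
#'   vector `diagnostics` (non-empty when a segment has both endpoints on
#'   one side; such endpoints are still assigned by the adjacent-loop rule).
#' @export
assign_membrane_sides <- function(annotation) {
  segs <- annotation$segments
  if (!nrow(segs)) stop("annotation has no TM segments (not a TM protein)")
  side1 <- c(segs$start[segs$start_side == "side1"],
             segs$end[segs$end_side == "side1"])
  side2 <- c(segs$start[segs$start_side == "side2"],
             segs$end[segs$end_side == "side2"])
  list(side1 = sort(side1), side2 = sort(side2),
       diagnostics = annotation$diagnostics)
}

#' Parse experimental hydrophobic thickness records
#'
#' Reads the bundled PDBTM-like XML dialect: `<pdbtm>` root with
#' `<entry id=>` elements each carrying a `<membrane><half_thickness>`
#' element, the fitted membrane half-thickness in Angstrom.  The stored
#' half-thickness is doubled to a full hydrophobic thickness so the
#' experimental values are directly comparable with the predicted-structure
#' statistic.  Entries without a thickness element are skipped with a
#' warning and counted.
#'
#' @param path XML file path.
#' @return data frame with columns `pdb_id`, `thickness` (Angstrom) and
#'   `source`; attribute `n_skipped` counts skipped entries.
#' @export
parse_pdbtm_thickness <- function(path) {
  doc <- xml2::read_xml(path)
  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- character(); th <- numeric(); skipped <- 0L
  for (e in entries) {
    ht <- xml2::xml_find_first(e, ".//half_thickness")
    v <- suppressWarnings(as.numeric(xml2::xml_text(ht)))
    if (is.na(v)) { skipped <- skipped + 1L; next }
    if (v <= 0 || !is.finite(v))
      stop("non-positive half thickness in entry ", xml2::xml_attr(e, "id"))
    ids <- c(ids, xml2::xml_attr(e, "id"))
    th <- c(th, 2 * v)
  }
  if (skipped)
    warning(skipped, " entr(y/ies) lacking a thickness element skipped")
  out <- data.frame(pdb_id = ids, thickness = th,
                    source = rep("pdbtm", length(ids)),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}
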