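#' Structure container
#'
#' A `memqa_structure` is a data frame of residues, one row per residue in
#' file order, with columns `chain`, `resno` (author numbering), `ins`
#' (insertion code, `NA` if none), `resid` (3-letter name), `x`, `y`, `z`
#' (C-alpha coordinates in Angstrom, `NA` when the residue has no C-alpha)
#' and `plddt` (per-residue confidence in \[0, 100\] taken from the C-alpha
#' B-factor field, `NA` when absent).  Attributes `id` and `source_format`
#' identify the model.
#'
#' @param residues data frame with the columns above.
#' @param id model identifier.
#' @param source_format one of `"pdb"`, `"mmcif"`, `"synthetic"`.
#' @return a `memqa_structure`.
#' @export
new_structure <- function(residues, id = "structure", source_format = "synthetic") {
  required <- c("chain", "resno", "ins", "resid", "x", "y", "z", "plddt")
  missing <- setdiff(required, names(residues))
  if (length(missing))
    stop("residue table lacks column(s): ", paste(missing, collapse = ", "))
  residues <- as.data.frame(residues)[required]
  residues$resno <- as.integer(residues$resno)
  key <- paste(residues$chain, residues$resno, residues$ins, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, insertion) residue keys")
  bad <- !is.na(residues$plddt) &
    (residues$plddt < 0 | residues$plddt > 100)
  if (any(bad)) {
    warning(sum(bad), " residue(s) with B-factor outside [0, 100]; ",
            "not a confidence score, stored as NA")
    residues$plddt[bad] <- NA_real_
  }
  rownames(residues) <- NULL
  structure(residues, id = id, source_format = source_format,
            class = c("memqa_structure", "data.frame"))
}

#' @export
print.memqa_structure <- function(x, ...) {
  cat(sprintf("<memqa_structure> %s [%s]: %d residues, %d chain(s), %d with C-alpha\n",
              attr(x, "id"), attr(x, "source_format"), nrow(x),
              length(unique(x$chain)), sum(!is.na(x$x))))
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `memqa_structure`.
#' @return integer count.
#' @export
n_residues <- function(s) nrow(s)

#' C-alpha coordinate matrix
#'
#' @param s a `memqa_structure`.
#' @param drop_missing drop residues without a C-alpha (default `TRUE`).
#' @return an n x 3 matrix with rownames set to residue numbers.
#' @export
ca_coords <- function(s, drop_missing = TRUE) {
  keep <- if (drop_missing) !is.na(s$x) else rep(TRUE, nrow(s))
  m <- as.matrix(as.data.frame(s)[keep, c("x", "y", "z")])
  rownames(m) <- s$resno[keep]
  m
}

#' Read a structure from PDB or mmCIF
#'
#' Reads all polymer (`ATOM`) residues of the first model.  The per-residue
#' confidence (AlphaFold2 writes pLDDT there) is taken from the B-factor /
#' isotropic-displacement field of the C-alpha atom only; residues lacking a
#' C-alpha are retained with missing coordinates.  For atoms with alternate
#' locations the first-listed location is kept; hetero residues are skipped.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension: `.cif` /
#'   `.mmcif` are mmCIF, anything else PDB).
#' @return a [new_structure()] object; its `id` is the file stem.
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path))
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- obj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at) || !any(at$elety == "CA"))
    stop("no C-alpha atoms in ", path)
  ## first-listed altloc wins, per atom name within a residue
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[!duplicated(akey), , drop = FALSE]
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first <- !duplicated(rkey)
  res <- data.frame(chain = at$chain[first],
                    resno = at$resno[first],
                    ins = at$insert[first],
                    resid = at$resid[first],
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    plddt = NA_real_,
                    stringsAsFactors = FALSE)
  ca <- at[at$elety == "CA", , drop = FALSE]
  idx <- match(paste(ca$chain, ca$resno, ca$insert, sep = "\r"),
               paste(res$chain, res$resno, res$ins, sep = "\r"))
  res$x[idx] <- ca$x; res$y[idx] <- ca$y; res$z[idx] <- ca$z
  res$plddt[idx] <- ca$b
  new_structure(res, id = tools::file_path_sans_ext(basename(path)),
                source_format = format)
}

#' Select residues by chain and residue-number ranges
#'
#' Carves a sub-structure (e.g. a manually selected TM domain) out of a
#' model.  Ranges use inclusive 1-based author numbering.
#'
#' @param s a `memqa_structure`.
#' @param ranges a data frame with columns `chain`, `start`, `end`, or a list
#'   of `c(chain, start, end)` triples.
#' @return a `memqa_structure` with the matching residues in file order; an
#'   empty selection is returned with a warning.
#' @export
select_residues <- function(s, ranges) {
  if (is.list(ranges) && !is.data.frame(ranges))
    ranges <- do.call(rbind, lapply(ranges, function(r)
      data.frame(chain = as.character(r[1]), start = as.integer(r[2]),
                 end = as.integer(r[3]), stringsAsFactors = FALSE)))
  if (!nrow(ranges)) stop("no ranges given")
  if (any(ranges$start > ranges$end)) stop("range with start > end")
  keep <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(ranges)))
    keep <- keep | (s$chain == ranges$chain[i] &
                      s$resno >= ranges$start[i] & s$resno <= ranges$end[i])
  if (!any(keep))
    warning("selection matched zero residues")
  new_structure(as.data.frame(s)[keep, , drop = FALSE],
                id = attr(s, "id"), source_format = attr(s, "source_format"))
}

#' Write a structure as a C-alpha PDB trace
#'
#' Emits a minimal valid PDB (one `CA` atom per residue) that round-trips
#' through [load_structure()].  Residues without confidence are written with
#' B-factor 0.00 by convention.
#'
#' @param s a `memqa_structure`; every residue must have coordinates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  if (!nrow(s)) stop("refusing to write an empty structure")
  if (any(is.na(s$x))) stop("cannot write residues without C-alpha coordinates")
  b <- ifelse(is.na(s$plddt), 0, s$plddt)
  xyz <- as.numeric(t(as.matrix(as.data.frame(s)[, c("x", "y", "z")])))
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, type = "ATOM", resno = s$resno,
    resid = s$resid, chain = s$chain,
    insert = ifelse(is.na(s$ins), "", s$ins),
    elety = rep("CA", nrow(s)), b = b, o = rep(1, nrow(s))))
  invisible(path)
}
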