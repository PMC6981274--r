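#' Read an atomistic structure (PDB or mmCIF)
#'
#' Parses coordinates through bio3d, preserving author residue numbering,
#' chain identifiers, element symbols and temperature factors. The format is
#' chosen from the file extension (`.cif` / `.mmcif` for mmCIF, anything else
#' is treated as PDB).
#'
#' @param path file to read.
#' @return An object of class `atom_model`: a data frame with one row per
#'   atom and columns `chain`, `resno` (author numbering), `resid`, `atom`,
#'   `elem`, `x`, `y`, `z`, `b`, plus a `source` attribute.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop(sprintf("could not parse structure '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  a <- pdb$atom
  model <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    resid = a$resid,
    atom  = a$elety,
    elem  = a$elesy,
    x = a$x, y = a$y, z = a$z,
    b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  if (any(!is.finite(model$x) | !is.finite(model$y) | !is.finite(model$z)))
    stop("non-finite coordinates in ", path)
  atom_model(model, source = basename(path))
}

#' Construct an atom model from a data frame
#'
#' @param atoms data frame with columns `chain`, `resno`, `resid`, `atom`,
#'   `elem`, `x`, `y`, `z`, `b`.
#' @param source free-text provenance string.
#' @return An `atom_model`.
#' @export
atom_model <- function(atoms, source = "") {
  need <- c("chain", "resno", "resid", "atom", "elem", "x", "y", "z", "b")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records: ",
         key[which(duplicated(key))[1]])
  structure(as.data.frame(atoms)[need], source = source,
            class = c("atom_model", "data.frame"))
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("Atom model '%s': %d atoms, %d chain(s), residues %d-%d\n",
              attr(x, "source"), nrow(x), length(unique(x$chain)),
              min(x$resno), max(x$resno)))
  invisible(x)
}

#' Write an atom model to a PDB file
#'
#' @param model an `atom_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "atom_model"))
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = model$resno,
                   resid = model$resid, chain = model$chain,
                   elety = model$atom, elesy = model$elem, b = model$b)
  invisible(path)
}

# Normalise a residue-range specification into a data frame with columns
# chain, start, end. Accepts a data frame, a list of c(chain, start, end)
# triplets, or list(chain=, start=, end=) records. Intervals are inclusive
# and in author (1-based) numbering.
as_ranges <- function(ranges) {
  if (is.data.frame(ranges)) {
    stopifnot(all(c("chain", "start", "end") %in% names(ranges)))
    return(data.frame(chain = as.character(ranges$chain),
                      start = as.integer(ranges$start),
                      end = as.integer(ranges$end),
                      stringsAsFactors = FALSE))
  }
  if (!is.list(ranges)) stop("ranges must be a data frame or list")
  do.call(rbind, lapply(ranges, function(r) {
    if (is.null(names(r))) {
      data.frame(chain = as.character(r[[1]]), start = as.integer(r[[2]]),
                 end = as.integer(r[[3]]), stringsAsFactors = FALSE)
    } else {
      data.frame(chain = as.character(r$chain), start = as.integer(r$start),
                 end = as.integer(r$end), stringsAsFactors = FALSE)
    }
  }))
}

#' Select C-alpha coordinates for residue ranges
#'
#' Ranges are inclusive on both ends and use author residue numbering.
#' Residues absent from the model (disordered gaps) are skipped silently;
#' the number skipped is reported in the `skipped` attribute. Disjoint
#' ranges are concatenated in the order given.
#'
#' @param model an `atom_model`.
#' @param ranges residue ranges: a data frame with columns
#'   `chain`, `start`, `end`, or a list of `c(chain, start, end)` triplets.
#' @return A numeric matrix (n x 3) of C-alpha positions in residue order,
#'   with attributes `resno`, `chain` and `skipped`, and rownames
#'   `chain:resno`.
#' @export
select_calpha <- function(model, ranges) {
  stopifnot(inherits(model, "atom_model"))
  rg <- as_ranges(ranges)
  ca <- model[model$atom == "CA", , drop = FALSE]
  rows <- integer(0)
  skipped <- 0L
  for (i in seq_len(nrow(rg))) {
    want <- rg$start[i]:rg$end[i]
    hit <- match(paste(rg$chain[i], want), paste(ca$chain, ca$resno))
    skipped <- skipped + sum(is.na(hit))
    rows <- c(rows, hit[!is.na(hit)])
  }
  if (length(rows) == 0) stop("selection is empty: no C-alpha atoms in the given ranges")
  out <- as.matrix(ca[rows, c("x", "y", "z")])
  rownames(out) <- paste(ca$chain[rows], ca$resno[rows], sep = ":")
  attr(out, "resno") <- ca$resno[rows]
  attr(out, "chain") <- ca$chain[rows]
  attr(out, "skipped") <- skipped
  out
}
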