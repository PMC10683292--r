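#' Construct a single-molecule shift record
#'
#' A `shift_record` holds one molecule together with one assigned
#' spectrum: the atoms (element symbols, coordinates, formal charges),
#' the bonds, and the per-atom chemical shifts of one nucleus.
#' Atom indices in `bonds` and `shifts` are 0-based, matching the
#' convention of nmrshiftdb2 spectrum property blocks; conversion from
#' the 1-based molfile bond block happens once, at the parser boundary.
#'
#' @param molecule_id Opaque identifier string.
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric matrix (n x 3) of atom coordinates in Angstrom,
#'   or `NULL` for records without geometry (all-zero coordinates are
#'   treated as absent geometry downstream).
#' @param charges Integer vector of formal charges (default all 0).
#' @param bonds data.frame with columns `a`, `b` (0-based atom indices)
#'   and `order` (one of `"single"`, `"double"`, `"triple"`,
#'   `"aromatic"`).
#' @param shifts data.frame with columns `atom` (0-based index) and
#'   `ppm` (assigned chemical shift).
#' @param nucleus Nucleus label such as `"13C"` or `"19F"`.
#' @param solvent Canonical solvent name or `"unknown"`.
#' @return An object of class `shift_record`.
#' @export
shift_record <- function(molecule_id, elements, coords = NULL,
                         charges = NULL, bonds, shifts,
                         nucleus, solvent = "unknown") {
  n <- length(elements)
  if (n < 1L) stop("record must contain at least one atom", call. = FALSE)
  if (is.null(coords)) coords <- matrix(0, n, 3L)
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix", call. = FALSE)
  if (is.null(charges)) charges <- integer(n)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    stopifnot(all(c("a", "b", "order") %in% names(bonds)))
    bonds$a <- as.integer(bonds$a); bonds$b <- as.integer(bonds$b)
    if (any(bonds$a == bonds$b))
      stop("bond endpoints must be distinct", call. = FALSE)
    if (any(bonds$a < 0L | bonds$a >= n | bonds$b < 0L | bonds$b >= n))
      stop("bond endpoint out of range", call. = FALSE)
    if (!all(bonds$order %in% c("single", "double", "triple", "aromatic")))
      stop("unknown bond order", call. = FALSE)
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0),
                        order = character(0), stringsAsFactors = FALSE)
  }
  shifts <- as.data.frame(shifts)
  if (nrow(shifts) > 0L) {
    stopifnot(all(c("atom", "ppm") %in% names(shifts)))
    shifts$atom <- as.integer(shifts$atom)
    if (any(shifts$atom < 0L | shifts$atom >= n))
      stop("shift atom index out of range", call. = FALSE)
    el <- nucleus_element(nucleus)
    bad <- elements[shifts$atom + 1L] != el
    if (any(bad))
      stop("shift assigned to atom whose element does not match nucleus ",
           nucleus, call. = FALSE)
  } else {
    shifts <- data.frame(atom = integer(0), ppm = numeric(0))
  }
  structure(list(molecule_id = as.character(molecule_id),
                 elements = as.character(elements),
                 coords = coords,
                 charges = as.integer(charges),
                 bonds = bonds,
                 shifts = shifts,
                 nucleus = nucleus,
                 solvent = solvent),
            class = "shift_record")
}

#' @export
print.shift_record <- function(x, ...) {
  cat(sprintf("<shift_record %s: %d atoms, %d bonds, %d %s shifts, solvent %s>\n",
              x$molecule_id, length(x$elements), nrow(x$bonds),
              nrow(x$shifts), x$nucleus, x$solvent))
  invisible(x)
}

#' Construct a shift dataset
#'
#' A `shift_dataset` is a collection of [shift_record()] objects sharing
#' one nucleus, the unit every estimator in the package trains on.
#'
#' @param records List of `shift_record` objects.
#' @param nucleus Nucleus label; all records must carry it.
#' @param solvent_filter Optional canonical solvent name recording that
#'   the dataset was restricted to one solvent.
#' @return An object of class `shift_dataset`.
#' @export
shift_dataset <- function(records, nucleus, solvent_filter = NULL) {
  stopifnot(is.list(records))
  for (r in records) {
    if (!inherits(r, "shift_record"))
      stop("all records must be shift_record objects", call. = FALSE)
    if (r$nucleus != nucleus)
      stop("record ", r$molecule_id, " has nucleus ", r$nucleus,
           ", dataset expects ", nucleus, call. = FALSE)
  }
  structure(list(records = records, nucleus = nucleus,
                 solvent_filter = solvent_filter),
            class = "shift_dataset")
}

#' @export
length.shift_dataset <- function(x) length(x$records)

#' @export
`[.shift_dataset` <- function(x, i) {
  shift_dataset(x$records[i], x$nucleus, x$solvent_filter)
}

#' @export
print.shift_dataset <- function(x, ...) {
  ns <- sum(vapply(x$records, function(r) nrow(r$shifts), integer(1)))
  cat(sprintf("<shift_dataset: %d records, nucleus %s, %d assigned shifts%s>\n",
              length(x$records), x$nucleus, ns,
              if (is.null(x$solvent_filter)) ""
              else paste0(", solvent ", x$solvent_filter)))
  invisible(x)
}

#' @export
summary.shift_dataset <- function(object, ...) {
  shifts <- unlist(lapply(object$records, function(r) r$shifts$ppm))
  natoms <- vapply(object$records, function(r) length(r$elements), integer(1))
  solv <- vapply(object$records, function(r) r$solvent, character(1))
  out <- list(n_records = length(object$records),
              nucleus = object$nucleus,
              n_shifts = length(shifts),
              shift_range = if (length(shifts)) range(shifts) else c(NA, NA),
              shift_mean = if (length(shifts)) mean(shifts) else NA_real_,
              atoms_per_molecule = summary(natoms),
              solvents = sort(table(solv), decreasing = TRUE))
  class(out) <- "summary.shift_dataset"
  out
}

#' @export
print.summary.shift_dataset <- function(x, ...) {
  cat(sprintf("Shift dataset: %d records (%s), %d assigned shifts\n",
              x$n_records, x$nucleus, x$n_shifts))
  if (x$n_shifts > 0)
    cat(sprintf("  shift range %.2f .. %.2f ppm, mean %.2f ppm\n",
                x$shift_range[1], x$shift_range[2], x$shift_mean))
  cat("  atoms per molecule:\n")
  print(x$atoms_per_molecule)
  cat("  solvents:\n")
  print(x$solvents)
  invisible(x)
}

molecule_ids <- function(dataset) {
  vapply(dataset$records, function(r) r$molecule_id, character(1))
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Adjacency as parallel lists over atoms (1-based internally):
# neighbour atom indices and matching bond orders.
record_adjacency <- function(record) {
  n <- length(record$elements)
  b <- record$bonds
  if (nrow(b) == 0L) {
    empty_i <- replicate(n, integer(0), simplify = FALSE)
    empty_c <- replicate(n, character(0), simplify = FALSE)
    return(list(neighbours = empty_i, orders = empty_c))
  }
  f <- factor(c(b$a, b$b) + 1L, levels = seq_len(n))
  list(neighbours = unname(split(c(b$b, b$a) + 1L, f)),
       orders = unname(split(c(b$order, b$order), f)))
}
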