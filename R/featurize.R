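# Molecular-graph featurization.
#
# Node features: one-hot element over the training vocabulary, then four
# scalars -- Slater atomic radius (pm), neutron count of the most
# abundant isotope, Pauling electronegativity, electron affinity (eV).
# Edge features: bond length (Angstrom) then one-hot bond type
# (single, double, triple, aromatic).  Every chemical bond becomes two
# directed edges with identical features.

#' Build the element vocabulary of a dataset
#'
#' The sorted unique element symbols over all atoms of all records
#' (explicit hydrogens included).  The one-hot block of every node
#' feature vector is indexed against this vocabulary, so it is fixed at
#' training time and stored with fitted models.
#'
#' @param dataset A [shift_dataset()].
#' @return Character vector of class `element_vocabulary`.
#' @export
build_element_vocabulary <- function(dataset) {
  stopifnot(inherits(dataset, "shift_dataset"), length(dataset) > 0L)
  vocab <- sort(unique(unlist(lapply(dataset$records,
                                     function(r) r$elements))))
  structure(vocab, class = "element_vocabulary")
}

#' Atom feature vector
#'
#' Concatenates the one-hot element encoding with the four scalar
#' properties of the element.  Elements whose electron affinity is not
#' tabulated are encoded as 0 with a warning.
#'
#' @param element Element symbol.
#' @param vocabulary An `element_vocabulary`.
#' @return Numeric vector of length `length(vocabulary) + 4`:
#'   one-hot, radius (pm), neutrons, electronegativity, electron
#'   affinity (eV).
#' @export
#' @examples
#' v <- structure(c("C", "F", "H", "O"), class = "element_vocabulary")
#' atom_feature_vector("C", v)
atom_feature_vector <- function(element, vocabulary) {
  idx <- match(element, vocabulary)
  if (is.na(idx))
    stop("element ", element, " not in the model vocabulary", call. = FALSE)
  p <- element_properties(element)
  one_hot <- numeric(length(vocabulary))
  one_hot[idx] <- 1
  ea <- p$electron_affinity
  if (is.na(ea)) {
    warning("no tabulated electron affinity for ", element,
            "; encoding 0", call. = FALSE)
    ea <- 0
  }
  c(one_hot, p$radius_slater_pm, p$neutrons, p$en_pauling, ea)
}

#' Bond feature vector
#'
#' Euclidean distance between the two atom centers followed by the
#' one-hot bond type.
#'
#' @param order Bond order: `"single"`, `"double"`, `"triple"` or
#'   `"aromatic"`.
#' @param coord_a,coord_b Numeric length-3 coordinates in Angstrom.
#' @return Numeric vector of length 5.
#' @export
#' @examples
#' bond_feature_vector("single", c(0, 0, 0), c(1.54, 0, 0))
bond_feature_vector <- function(order, coord_a, coord_b) {
  d <- sqrt(sum((coord_a - coord_b)^2))
  if (d <= 0)
    stop("degenerate geometry: coincident atom centers", call. = FALSE)
  idx <- match(order, .bond_order_names)
  if (is.na(idx)) stop("unknown bond order: ", order, call. = FALSE)
  one_hot <- numeric(4L)
  one_hot[idx] <- 1
  c(d, one_hot)
}

# A record "has geometry" when no bonded atom pair is coincident and at
# least one coordinate is non-zero.  Synthetic and 2D records fail this
# and get deterministic fallback bond lengths (sum of covalent radii).
.has_geometry <- function(record) {
  if (all(record$coords == 0)) return(FALSE)
  b <- record$bonds
  if (nrow(b) == 0L) return(TRUE)
  d2 <- rowSums((record$coords[b$a + 1L, , drop = FALSE] -
                 record$coords[b$b + 1L, , drop = FALSE])^2)
  all(d2 > 0)
}

#' Convert a shift record to a featurized molecular graph
#'
#' Builds the graph the network consumes: per-atom node feature vectors,
#' per-bond edge feature vectors with each bond emitted as two directed
#' edges, the shift targets and the target mask.  Node order equals atom
#' order in the record; edge endpoints use 1-based indices for direct R
#' matrix indexing.  Records without usable 3D coordinates get fallback
#' bond lengths equal to the sum of the two covalent radii.
#'
#' @param record A [shift_record()].
#' @param vocabulary An `element_vocabulary` covering the record.
#' @return An object of class `mol_graph` with fields `node_features`
#'   (n x (|vocab|+4)), `edge_features` (m x 5), `senders`, `receivers`
#'   (1-based, length m), `targets` (ppm, `NA` where unassigned),
#'   `target_mask`, `elements`, `molecule_id`.
#' @export
molecule_to_graph <- function(record, vocabulary) {
  stopifnot(inherits(record, "shift_record"))
  n <- length(record$elements)
  node_features <- t(vapply(record$elements, atom_feature_vector,
                            numeric(length(vocabulary) + 4L),
                            vocabulary = vocabulary))
  rownames(node_features) <- NULL
  b <- record$bonds
  m <- 2L * nrow(b)
  use_geom <- .has_geometry(record)
  edge_features <- matrix(0, m, 5L)
  senders <- integer(m); receivers <- integer(m)
  if (nrow(b) > 0L) {
    if (use_geom) {
      len <- sqrt(rowSums((record$coords[b$a + 1L, , drop = FALSE] -
                           record$coords[b$b + 1L, , drop = FALSE])^2))
    } else {
      cov <- element_properties()$covalent_radius_A
      names(cov) <- element_properties()$symbol
      len <- cov[record$elements[b$a + 1L]] + cov[record$elements[b$b + 1L]]
    }
    type <- match(b$order, .bond_order_names)
    feat <- matrix(0, nrow(b), 5L)
    feat[, 1] <- len
    feat[cbind(seq_len(nrow(b)), type + 1L)] <- 1
    edge_features <- feat[rep(seq_len(nrow(b)), each = 2L), , drop = FALSE]
    senders   <- as.integer(rbind(b$a + 1L, b$b + 1L))
    receivers <- as.integer(rbind(b$b + 1L, b$a + 1L))
  }
  targets <- rep(NA_real_, n)
  targets[record$shifts$atom + 1L] <- record$shifts$ppm
  structure(list(node_features = node_features,
                 edge_features = edge_features,
                 senders = senders, receivers = receivers,
                 targets = targets,
                 target_mask = !is.na(targets),
                 elements = record$elements,
                 molecule_id = record$molecule_id),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph %s: %d nodes (dim %d), %d directed edges, %d targets>\n",
              x$molecule_id, nrow(x$node_features), ncol(x$node_features),
              length(x$senders), sum(x$target_mask)))
  invisible(x)
}

#' Dump a molecular graph as JSON
#'
#' Debug/serialization helper used by the test suite to compare graphs
#' structurally.
#'
#' @param graph A `mol_graph`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
graph_to_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "mol_graph"))
  js <- jsonlite::toJSON(unclass(graph), digits = NA, na = "null",
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
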