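# HOSE codes: canonical hierarchically-ordered spherical environment
# strings, and the table-lookup predictor built on them.
#
# Dialect (self-consistent, not byte-compatible with the CDK strings):
#   center        "El-degree;"          e.g. "C-4;"
#   spheres       joined by "/"; within a sphere, sibling tokens joined
#                 by ",", groups under distinct parents joined by ";"
#   token         bondsymbol + element, bond symbols "" single,
#                 "=" double, "%" triple, "*" aromatic
#   ring closure  re-encountered atoms emit "&" instead of an element
# Spheres are breadth-first shells: an atom appears once, at its bond
# distance from the center; any further edge to it is a ring closure.
# Sibling order is (bond rank single<double<triple<aromatic, element,
# canonical subtree), which makes the string invariant under atom
# relabeling, and level-wise comparison makes an s-sphere code a prefix
# of the (s+1)-sphere code.

.bond_symbols <- c(single = "", double = "=", triple = "%", aromatic = "*")

# Breadth-first bond distances from `start` (1-based); unreachable = NA.
.bfs_dist <- function(adj, start, n) {
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue) > 0L) {
    a <- queue[1L]; queue <- queue[-1L]
    for (j in adj$neighbours[[a]]) {
      if (is.na(dist[j])) {
        dist[j] <- dist[a] + 1L
        queue <- c(queue, j)
      }
    }
  }
  dist
}

# Relabeling-invariant atom ranks by iterative neighbourhood refinement
# (Morgan-style): start from (element, degree, sorted bond orders),
# refine with sorted (bond, neighbour-rank) signatures until the
# partition stabilises.
.atom_ranks <- function(record, adj) {
  n <- length(record$elements)
  nb <- adj$neighbours
  bo <- lapply(adj$orders, match, table = .bond_order_names)
  key <- vapply(seq_len(n), function(i) {
    paste(record$elements[i], length(nb[[i]]),
          paste(sort.int(bo[[i]]), collapse = ","), sep = "|")
  }, character(1))
  rank <- match(key, sort(unique(key), method = "radix"))
  for (iter in seq_len(n)) {
    sig <- vapply(seq_len(n), function(i) {
      paste(rank[i],
            paste(sort.int(rank[nb[[i]]] * 8L + bo[[i]]), collapse = ","),
            sep = "|")
    }, character(1))
    new_rank <- match(sig, sort(unique(sig), method = "radix"))
    if (length(unique(new_rank)) == length(unique(rank))) {
      rank <- new_rank
      break
    }
    rank <- new_rank
  }
  rank
}

# Cumulative codes (spheres 1..s) for several centers at once, via the
# compiled tree/string kernel; canonical ranks computed once per call.
.hose_codes_matrix <- function(record, centers, s, adj = NULL,
                               ranks = NULL) {
  if (is.null(adj)) adj <- record_adjacency(record)
  if (is.null(ranks)) ranks <- .atom_ranks(record, adj)
  branks <- lapply(adj$orders, match, table = .bond_order_names)
  .cpp_hose_codes(record$elements, adj$neighbours, branks,
                  as.integer(ranks), as.integer(centers), as.integer(s))
}

# Reference R implementation of the sphere tree and string assembly
# (the compiled kernel mirrors it; kept for clarity and cross-checks).
.hose_spheres <- function(record, center, s, adj, ranks) {
  n <- length(record$elements)
  dist <- .bfs_dist(adj, center, n)
  # growing node table; root is node 1
  node_atom <- center          # NA for ring-closure nodes
  node_brank <- 0L
  node_elem <- record$elements[center]
  node_parent_atom <- 0L
  node_children <- list(integer(0))
  assigned <- logical(n); assigned[center] <- TRUE
  level_nodes <- vector("list", s + 1L)
  level_nodes[[1L]] <- 1L
  for (d in seq_len(s)) {
    new_level <- integer(0)
    for (nd in level_nodes[[d]]) {
      a <- node_atom[nd]
      if (is.na(a)) { node_children[[nd]] <- integer(0); next }
      nbrs <- adj$neighbours[[a]]
      ords <- adj$orders[[a]]
      keep <- nbrs != node_parent_atom[nd]
      nbrs <- nbrs[keep]; ords <- ords[keep]
      if (length(nbrs) == 0L) { node_children[[nd]] <- integer(0); next }
      brank <- match(ords, .bond_order_names)
      is_child <- (dist[nbrs] == d) & !assigned[nbrs]
      elem_key <- ifelse(is_child, record$elements[nbrs], "&")
      ord_idx <- order(brank, elem_key, ranks[nbrs], method = "radix")
      kids <- integer(0)
      for (t in ord_idx) {
        j <- nbrs[t]
        child <- (dist[j] == d) && !assigned[j]
        node_atom <- c(node_atom, if (child) j else NA_integer_)
        node_brank <- c(node_brank, brank[t])
        node_elem <- c(node_elem, if (child) record$elements[j] else "&")
        node_parent_atom <- c(node_parent_atom, a)
        node_children <- c(node_children, list(integer(0)))
        id <- length(node_atom)
        kids <- c(kids, id)
        if (child) assigned[j] <- TRUE
      }
      node_children[[nd]] <- kids
      new_level <- c(new_level, kids)
    }
    level_nodes[[d + 1L]] <- new_level
  }
  # canonical per-node level strings, bottom-up; node at depth d has a
  # levels vector of length (s - d + 1), padded with "" below the leaves
  n_nodes <- length(node_atom)
  tokens <- paste0(c("", .bond_symbols[.bond_order_names])[node_brank + 1L],
                   node_elem)
  node_levels <- vector("list", n_nodes)
  for (d in rev(seq_len(s + 1L))) {
    for (nd in level_nodes[[d]]) {
      len <- s - (d - 1L) + 1L
      lv <- character(len)
      lv[1L] <- tokens[nd]
      ch <- node_children[[nd]]
      if (length(ch) > 0L) {
        keys <- vapply(ch, function(cn) {
          paste0(node_brank[cn], "\x02", node_elem[cn],
                 "\x02", paste(node_levels[[cn]], collapse = "\x01"))
        }, character(1))
        ch <- ch[order(keys, method = "radix")]
        node_children[[nd]] <- ch
        if (len >= 2L) {
          for (k in 2L:len) {
            lv[k] <- paste(vapply(ch, function(cn) node_levels[[cn]][k - 1L],
                                  character(1)), collapse = ",")
          }
        }
      }
      node_levels[[nd]] <- lv
    }
  }
  # emit sphere strings in canonical traversal order
  spheres <- character(s)
  prev <- 1L
  for (d in seq_len(s)) {
    groups <- vapply(prev, function(nd) {
      paste(tokens[node_children[[nd]]], collapse = ",")
    }, character(1))
    spheres[d] <- paste(groups, collapse = ";")
    prev <- unlist(lapply(prev, function(nd) node_children[[nd]]))
    if (length(prev) == 0L) prev <- integer(0)
  }
  list(center = paste0(record$elements[center], "-",
                       length(adj$neighbours[[center]]), ";"),
       spheres = spheres)
}

#' HOSE code of one atom
#'
#' Computes the canonical concentric-sphere environment string of an
#' atom to a given sphere depth.  Two atoms with isomorphic `s`-sphere
#' environments receive identical strings, and truncating a deeper code
#' at a sphere boundary equals the directly computed shallower code.
#'
#' @param record A [shift_record()].
#' @param atom 0-based atom index; may be a vector (the molecule-level
#'   canonicalization is shared across the queried atoms).
#' @param spheres Sphere depth `s >= 1`.
#' @return Character vector of HOSE code strings, one per queried atom.
#' @export
#' @examples
#' r <- shift_record("methane", c("C", "H", "H", "H", "H"),
#'                   bonds = data.frame(a = 0, b = 1:4, order = "single"),
#'                   shifts = data.frame(atom = 0, ppm = -2.3),
#'                   nucleus = "13C")
#' hose_code(r, 0, spheres = 1)
hose_code <- function(record, atom, spheres = 6L) {
  stopifnot(spheres >= 1L, length(atom) >= 1L)
  idx <- as.integer(atom) + 1L
  if (any(idx < 1L | idx > length(record$elements)))
    stop("atom index out of range", call. = FALSE)
  m <- .hose_codes_matrix(record, idx, as.integer(spheres))
  as.character(m[, ncol(m)])
}

# Codes of one atom at every depth 1..s (cumulative sphere prefixes).
.hose_code_levels <- function(record, center, s, adj, ranks) {
  as.character(.hose_codes_matrix(record, center, s, adj, ranks)[1L, ])
}

#' Fit a HOSE-code lookup model
#'
#' Builds the nearest-neighbour prediction table: for every labeled atom
#' of the training set and every sphere depth `1..s_max`, the atom's
#' shift is recorded under its HOSE code at that depth.  Prediction
#' looks an atom up at the deepest sphere first and falls back to
#' shallower spheres; if even the one-sphere environment is unseen, the
#' model abstains (a missing prediction) rather than guessing.
#'
#' @param data A [shift_dataset()] of training molecules.
#' @param s_max Maximum sphere depth (default 6).
#' @return An object of class `hose_model`.
#' @seealso [predict.hose_model()], [missing_fraction()],
#'   [write_hose_table()]
#' @export
hose_model <- function(data, s_max = 6L) {
  stopifnot(inherits(data, "shift_dataset"), length(data) > 0L, s_max >= 1L)
  s_max <- as.integer(s_max)
  tables <- lapply(seq_len(s_max), function(s) new.env(hash = TRUE,
                                                       parent = emptyenv()))
  n_shifts <- 0L
  for (r in data$records) {
    if (nrow(r$shifts) == 0L) next
    codes <- .hose_codes_matrix(r, r$shifts$atom + 1L, s_max)
    for (k in seq_len(nrow(r$shifts))) {
      for (s in seq_len(s_max)) {
        code <- codes[k, s]
        tables[[s]][[code]] <- c(tables[[s]][[code]], r$shifts$ppm[k])
      }
      n_shifts <- n_shifts + 1L
    }
  }
  structure(list(tables = tables, s_max = s_max, nucleus = data$nucleus,
                 n_shifts = n_shifts, n_molecules = length(data),
                 train_mean = mean(unlist(lapply(data$records,
                                                 function(r) r$shifts$ppm)))),
            class = "hose_model")
}

#' @export
print.hose_model <- function(x, ...) {
  cat(sprintf("<hose_model: %s, %d training shifts from %d molecules, %d spheres, %d distinct max-depth environments>\n",
              x$nucleus, x$n_shifts, x$n_molecules, x$s_max,
              length(ls(x$tables[[x$s_max]]))))
  invisible(x)
}

#' @export
summary.hose_model <- function(object, ...) {
  counts <- vapply(object$tables, function(e) length(ls(e)), integer(1))
  cat(sprintf("HOSE lookup model (%s): %d shifts, %d molecules, S_max = %d\n",
              object$nucleus, object$n_shifts, object$n_molecules,
              object$s_max))
  cat("distinct environments per sphere depth:\n")
  print(stats::setNames(counts, paste0("s", seq_along(counts))))
  invisible(object)
}

#' Predict shifts by HOSE-code lookup
#'
#' For each query atom the code is tried at depth `s_max`, then
#' `s_max - 1`, down to 1; the first depth with training entries returns
#' the arithmetic mean of the recorded shifts.  An atom whose one-sphere
#' environment is unseen gets `NA` with `missing_flag = TRUE`.
#'
#' @param object A [hose_model()].
#' @param newdata A [shift_dataset()] or single [shift_record()].
#' @param atoms `"labeled"` (default) to query the atoms carrying shift
#'   assignments, or `"element"` to query every atom of the nucleus's
#'   element.
#' @param ... Unused.
#' @return data.frame with columns `molecule_id`, `atom_index` (0-based),
#'   `true_shift_ppm` (`NA` when unassigned), `predicted_shift_ppm`,
#'   `matched_spheres`, `method`, `missing_flag`.
#' @export
predict.hose_model <- function(object, newdata,
                               atoms = c("labeled", "element"), ...) {
  atoms <- match.arg(atoms)
  if (inherits(newdata, "shift_record"))
    newdata <- shift_dataset(list(newdata), newdata$nucleus)
  stopifnot(inherits(newdata, "shift_dataset"))
  el <- nucleus_element(object$nucleus)
  out <- lapply(newdata$records, function(r) {
    if (atoms == "labeled") {
      q <- r$shifts$atom
      truth <- r$shifts$ppm
    } else {
      q <- which(r$elements == el) - 1L
      truth <- rep(NA_real_, length(q))
      truth[match(r$shifts$atom, q)] <- r$shifts$ppm
    }
    if (length(q) == 0L) return(NULL)
    codes <- .hose_codes_matrix(r, q + 1L, object$s_max)
    pred <- rep(NA_real_, length(q))
    depth <- rep(NA_integer_, length(q))
    for (k in seq_along(q)) {
      for (s in rev(seq_len(object$s_max))) {
        hits <- object$tables[[s]][[codes[k, s]]]
        if (!is.null(hits)) {
          pred[k] <- mean(hits)
          depth[k] <- s
          break
        }
      }
    }
    data.frame(molecule_id = r$molecule_id, atom_index = q,
               true_shift_ppm = truth, predicted_shift_ppm = pred,
               matched_spheres = depth, method = "hose",
               missing_flag = is.na(pred), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Missing-prediction fraction
#'
#' Percentage of HOSE queries that found no match even at one sphere.
#' The headline convention is per atom; a per-molecule variant
#' (molecules with at least one missing atom) is also available.
#'
#' @param predictions Prediction data.frame from [predict.hose_model()].
#' @param per `"atom"` (default) or `"molecule"`.
#' @return Percentage in `[0, 100]`.
#' @export
missing_fraction <- function(predictions, per = c("atom", "molecule")) {
  per <- match.arg(per)
  if (is.null(predictions) || nrow(predictions) == 0L)
    stop("empty prediction set", call. = FALSE)
  if (per == "atom") return(100 * mean(predictions$missing_flag))
  any_missing <- tapply(predictions$missing_flag,
                        predictions$molecule_id, any)
  100 * mean(any_missing)
}

#' Serialize a HOSE table to JSON lines
#'
#' One header line with format version and metadata, then one line per
#' (sphere depth, code) entry with its observed training shifts, so a
#' table can be reused without rebuilding.
#'
#' @param model A [hose_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hose_table <- function(model, path) {
  stopifnot(inherits(model, "hose_model"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(
    list(format = "nmrgraph-hose-1", s_max = model$s_max,
         nucleus = model$nucleus, n_shifts = model$n_shifts,
         n_molecules = model$n_molecules, train_mean = model$train_mean),
    auto_unbox = TRUE, digits = NA), con)
  for (s in seq_len(model$s_max)) {
    for (code in sort(ls(model$tables[[s]]))) {
      writeLines(jsonlite::toJSON(
        list(spheres = s, code = code,
             shifts = as.numeric(model$tables[[s]][[code]])),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read a serialized HOSE table
#'
#' @param path Path written by [write_hose_table()].
#' @return A [hose_model()].
#' @export
read_hose_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty HOSE table file", call. = FALSE)
  hdr <- jsonlite::fromJSON(lines[1L])
  if (!identical(hdr$format, "nmrgraph-hose-1"))
    stop("unrecognized HOSE table format", call. = FALSE)
  tables <- lapply(seq_len(hdr$s_max), function(s) new.env(hash = TRUE,
                                                           parent = emptyenv()))
  for (ln in lines[-1L]) {
    e <- jsonlite::fromJSON(ln)
    tables[[e$spheres]][[e$code]] <- as.numeric(e$shifts)
  }
  structure(list(tables = tables, s_max = hdr$s_max, nucleus = hdr$nucleus,
                 n_shifts = hdr$n_shifts, n_molecules = hdr$n_molecules,
                 train_mean = hdr$train_mean),
            class = "hose_model")
}
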