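# Synthetic molecules with a known local-environment shift rule.
#
# The generator emulates the locality premise behind both predictors:
# each target-element atom's shift is a deterministic additive function
# of the elements in its 1-bond and 2-bond shells plus Gaussian noise.
# With zero noise, any predictor that resolves the 2-bond environment
# (a HOSE match at depth >= 2, or a graph network with >= 2 rounds) can
# in principle predict exactly; this is what the test suite exploits.

#' Specification for synthetic shift data
#'
#' Defines the generative conditions: molecule count, heavy-atom
#' palette, size range, and the additive shift rule.  Shift of a
#' target-element atom = `base_shift` + sum of `contrib1[element]` over
#' atoms in its 1-bond shell + sum of `contrib2[element]` over atoms in
#' its 2-bond shell + `aromatic_bonus` per aromatic bond at the atom +
#' Gaussian noise.  Contribution values are arbitrary test constants
#' loosely scaled like 13C behaviour, not chemistry claims.
#'
#' @param n_molecules Number of molecules to generate.
#' @param elements Named numeric vector of heavy-atom sampling weights.
#' @param size_range Integer range of heavy-atom counts per molecule.
#' @param nucleus Target nucleus label (its element gets the shifts).
#' @param base_shift Base shift of the target element, ppm.
#' @param contrib1,contrib2 Named numeric vectors: additive ppm
#'   contribution per neighbour element in the 1- and 2-bond shells.
#' @param aromatic_bonus Additive ppm per aromatic bond at the atom.
#' @param noise_sd Gaussian noise standard deviation, ppm.
#' @param ring_prob Probability that a molecule receives one ring
#'   closure (where valences permit).
#' @param solvents Named numeric vector of solvent sampling weights.
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_molecules = 100L,
                       elements = c(C = 0.6, O = 0.2, N = 0.2),
                       size_range = c(4L, 9L),
                       nucleus = "13C",
                       base_shift = 100,
                       contrib1 = c(C = 5, H = -2, O = 40, N = 20, F = 25),
                       contrib2 = c(C = 1, H = -0.5, O = 8, N = 4, F = 6),
                       aromatic_bonus = 30,
                       noise_sd = 1,
                       ring_prob = 0.3,
                       solvents = c("Chloroform-D1" = 1),
                       seed = 1L) {
  stopifnot(n_molecules >= 1L, all(elements > 0), length(size_range) == 2L,
            size_range[1] >= 1L, size_range[2] >= size_range[1],
            noise_sd >= 0, ring_prob >= 0, ring_prob <= 1,
            all(is.finite(contrib1)), all(is.finite(contrib2)))
  el <- nucleus_element(nucleus)
  if (!el %in% names(elements))
    stop("palette must contain the target element ", el, call. = FALSE)
  known <- element_properties()$symbol
  bad <- setdiff(names(elements), known)
  if (length(bad) > 0L)
    stop("palette element(s) without tabulated properties: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_molecules = as.integer(n_molecules), elements = elements,
                 size_range = as.integer(size_range), nucleus = nucleus,
                 target_element = el, base_shift = base_shift,
                 contrib1 = contrib1, contrib2 = contrib2,
                 aromatic_bonus = aromatic_bonus, noise_sd = noise_sd,
                 ring_prob = ring_prob, solvents = solvents,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec: %d molecules, %d-%d heavy atoms over {%s}, %s, noise %.2g ppm, seed %d>\n",
              x$n_molecules, x$size_range[1], x$size_range[2],
              paste(names(x$elements), collapse = ","), x$nucleus,
              x$noise_sd, x$seed))
  invisible(x)
}

# Grow one random valence-valid molecule: a random tree over heavy
# atoms, optionally one ring closure, then hydrogen fill.
.grow_molecule <- function(spec) {
  vals <- element_properties()$max_valence
  names(vals) <- element_properties()$symbol
  n_heavy <- sample(seq(spec$size_range[1], spec$size_range[2]), 1L)
  pal <- names(spec$elements)
  w <- spec$elements / sum(spec$elements)
  # first atom is the target element so every molecule carries a label
  elements <- spec$target_element
  free <- unname(vals[elements])
  bonds_a <- integer(0); bonds_b <- integer(0)
  for (i in seq_len(n_heavy - 1L)) {
    open <- which(free >= 1L)
    if (length(open) == 0L) break
    parent <- open[sample.int(length(open), 1L)]
    newel <- sample(pal, 1L, prob = w)
    elements <- c(elements, newel)
    j <- length(elements)
    free[parent] <- free[parent] - 1L
    free <- c(free, vals[[newel]] - 1L)
    bonds_a <- c(bonds_a, parent); bonds_b <- c(bonds_b, j)
  }
  n <- length(elements)
  # optional single ring closure between non-adjacent atoms with free valence
  if (n >= 3L && stats::runif(1) < spec$ring_prob) {
    open <- which(free >= 1L)
    if (length(open) >= 2L) {
      adj <- cbind(c(bonds_a, bonds_b), c(bonds_b, bonds_a))
      pairs <- utils::combn(open, 2L)
      ok <- apply(pairs, 2L, function(p) {
        !any(adj[, 1] == p[1] & adj[, 2] == p[2])
      })
      if (any(ok)) {
        pick <- which(ok)[sample.int(sum(ok), 1L)]
        p <- pairs[, pick]
        bonds_a <- c(bonds_a, p[1]); bonds_b <- c(bonds_b, p[2])
        free[p] <- free[p] - 1L
      }
    }
  }
  # hydrogen fill
  for (i in seq_len(n)) {
    nh <- free[i]
    if (nh > 0L) {
      for (k in seq_len(nh)) {
        elements <- c(elements, "H")
        bonds_a <- c(bonds_a, i); bonds_b <- c(bonds_b, length(elements))
      }
    }
  }
  list(elements = elements,
       bonds = data.frame(a = bonds_a - 1L, b = bonds_b - 1L,
                          order = "single", stringsAsFactors = FALSE))
}

#' Noiseless shift under the synthetic additive rule
#'
#' The independent ground truth for tests: recomputes the additive rule
#' for one atom directly from the molecular graph (1- and 2-bond shells
#' by breadth-first search).
#'
#' @param record A [shift_record()].
#' @param atom 0-based atom index; must be the target element.
#' @param spec The [synth_spec()] that defines the rule.
#' @return Noiseless shift in ppm.
#' @export
oracle_shift <- function(record, atom, spec) {
  i <- atom + 1L
  if (record$elements[i] != spec$target_element)
    stop("atom ", atom, " is ", record$elements[i], ", not the target element ",
         spec$target_element, call. = FALSE)
  adj <- record_adjacency(record)
  n1 <- adj$neighbours[[i]]
  n2 <- setdiff(unique(unlist(adj$neighbours[n1])), c(i, n1))
  v <- spec$base_shift
  for (j in n1) {
    cc <- spec$contrib1[record$elements[j]]
    if (!is.na(cc)) v <- v + cc
  }
  for (j in n2) {
    cc <- spec$contrib2[record$elements[j]]
    if (!is.na(cc)) v <- v + cc
  }
  unname(v + spec$aromatic_bonus * sum(adj$orders[[i]] == "aromatic"))
}

#' Generate a synthetic shift dataset
#'
#' Draws random valence-valid molecules (random heavy-atom trees with an
#' optional ring closure, hydrogen-filled) and assigns every
#' target-element atom a shift by the spec's additive local rule plus
#' Gaussian noise.  Deterministic for a given spec (the spec's seed is
#' used; molecules carry no geometry, so bond lengths downstream come
#' from the covalent-radius fallback).
#'
#' @param spec A [synth_spec()].
#' @return A [shift_dataset()] of `spec$n_molecules` records with ids
#'   `synth_000001, ...`.
#' @seealso [oracle_shift()] for the noiseless ground truth.
#' @export
generate_shift_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  solv_names <- names(spec$solvents)
  solv_w <- spec$solvents / sum(spec$solvents)
  records <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_molecules), function(m) {
      g <- .grow_molecule(spec)
      rec <- shift_record(molecule_id = sprintf("synth_%06d", m),
                          elements = g$elements, bonds = g$bonds,
                          shifts = data.frame(atom = integer(0),
                                              ppm = numeric(0)),
                          nucleus = spec$nucleus,
                          solvent = solv_names[
                            sample.int(length(solv_names), 1L, prob = solv_w)])
      targets <- which(g$elements == spec$target_element) - 1L
      ppm <- vapply(targets, function(a) oracle_shift(rec, a, spec),
                    numeric(1))
      if (spec$noise_sd > 0)
        ppm <- ppm + stats::rnorm(length(ppm), 0, spec$noise_sd)
      rec$shifts <- data.frame(atom = as.integer(targets), ppm = ppm)
      rec
    })
  })
  shift_dataset(records, spec$nucleus)
}
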