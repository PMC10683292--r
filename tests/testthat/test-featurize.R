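test_that("element vocabulary is the sorted union over all atoms", {
  d <- shift_dataset(list(ethanol_record(),
                          {
                            r <- fluoromethane_record()
                            r$nucleus <- "13C"
                            r$shifts <- data.frame(atom = 0L, ppm = 71.6)
                            r
                          }), "13C")
  expect_identical(as.character(build_element_vocabulary(d)),
                   c("C", "F", "H", "O"))
  d1 <- shift_dataset(list(methane_record()), "13C")
  expect_identical(as.character(build_element_vocabulary(d1)), c("C", "H"))
  expect_identical(build_element_vocabulary(d), build_element_vocabulary(d))
})

test_that("atom feature vectors carry one-hot plus the tabulated scalars", {
  v <- structure(c("C", "F", "H", "O"), class = "element_vocabulary")
  fc <- atom_feature_vector("C", v)
  expect_equal(fc[1:4], c(1, 0, 0, 0))
  expect_equal(fc[5:8], c(70, 6, 2.55, 1.2621), tolerance = 1e-4)
  ff <- atom_feature_vector("F", v)
  expect_equal(ff[1:4], c(0, 1, 0, 0))
  expect_equal(ff[5:8], c(50, 10, 3.98, 3.4012), tolerance = 1e-4)
  expect_error(atom_feature_vector("Xx", v), "not in the model vocabulary")
})

test_that("bond feature vectors are distance plus one-hot type", {
  expect_equal(bond_feature_vector("single", c(0, 0, 0), c(1.54, 0, 0)),
               c(1.54, 1, 0, 0, 0))
  expect_equal(bond_feature_vector("aromatic", c(0, 0, 0), c(0, 1.39, 0)),
               c(1.39, 0, 0, 0, 1))
  expect_error(bond_feature_vector("single", c(1, 1, 1), c(1, 1, 1)),
               "degenerate geometry")
  expect_error(bond_feature_vector("quadruple", c(0, 0, 0), c(1, 0, 0)),
               "unknown bond order")
})

test_that("molecular graphs satisfy their structural invariants", {
  d <- shift_dataset(list(methane_record()), "13C")
  vocab <- build_element_vocabulary(d)
  g <- molecule_to_graph(methane_record(), vocab)
  expect_equal(nrow(g$node_features), 5L)
  expect_equal(length(g$senders), 8L)       # 4 bonds x 2 directions
  expect_equal(ncol(g$node_features), length(vocab) + 4L)
  expect_equal(ncol(g$edge_features), 5L)
  # one-hot blocks sum to exactly 1
  expect_true(all(rowSums(g$node_features[, seq_along(vocab),
                                          drop = FALSE]) == 1))
  expect_true(all(rowSums(g$edge_features[, 2:5, drop = FALSE]) == 1))
  # target mask exactly where shifts were assigned
  e <- ethanol_record()
  ge <- molecule_to_graph(e, build_element_vocabulary(
    shift_dataset(list(e), "13C")))
  expect_identical(which(ge$target_mask), c(1L, 2L))
  # reverse edge has identical features
  for (k in seq_along(g$senders)) {
    rev <- which(g$senders == g$receivers[k] & g$receivers == g$senders[k])
    expect_equal(g$edge_features[k, ], g$edge_features[rev, ])
  }
  # determinism
  expect_identical(g, molecule_to_graph(methane_record(), vocab))
})

test_that("graphs of relabeled molecules are the same graph under the permutation", {
  r <- ethanol_record()
  vocab <- build_element_vocabulary(shift_dataset(list(r), "13C"))
  set.seed(42)
  for (i in 1:5) {
    perm <- sample(0:8)
    rp <- permute_record(r, perm)
    g <- molecule_to_graph(r, vocab)
    gp <- molecule_to_graph(rp, vocab)
    # node features move with the permutation
    expect_equal(gp$node_features[perm + 1L, ], g$node_features)
    expect_equal(gp$targets[perm + 1L], g$targets)
    # directed edge multisets coincide after relabeling
    key <- function(s, r, f) {
      o <- order(s, r)
      list(cbind(s, r)[o, ], f[o, ])
    }
    a <- key(perm[g$senders] + 1L, perm[g$receivers] + 1L, g$edge_features)
    b <- key(gp$senders, gp$receivers, gp$edge_features)
    expect_equal(a, b)
  }
})

test_that("records without geometry fall back to covalent-radius bond lengths", {
  r <- methane_record()   # all-zero coordinates
  vocab <- structure(c("C", "H"), class = "element_vocabulary")
  g <- molecule_to_graph(r, vocab)
  expect_equal(unique(g$edge_features[, 1]), 0.75 + 0.32)
  # with usable 3D coordinates the true distance is used
  r$coords[2, ] <- c(1.09, 0, 0)
  r$coords[3, ] <- c(0, 1.09, 0)
  r$coords[4, ] <- c(0, 0, 1.09)
  r$coords[5, ] <- c(-0.63, -0.63, -0.63)
  g2 <- molecule_to_graph(r, vocab)
  expect_equal(g2$edge_features[1, 1], 1.09)
})

test_that("graph JSON dump round-trips structurally", {
  r <- methane_record()
  vocab <- structure(c("C", "H"), class = "element_vocabulary")
  g <- molecule_to_graph(r, vocab)
  js <- jsonlite::fromJSON(graph_to_json(g))
  expect_equal(js$senders, g$senders)
  expect_equal(unname(as.matrix(js$node_features)), unname(g$node_features))
})
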