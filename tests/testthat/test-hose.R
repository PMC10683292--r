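test_that("HOSE codes follow the dialect on hand-checked molecules", {
  m <- methane_record()
  expect_identical(hose_code(m, 0, spheres = 1), "C-4;H,H,H,H")
  # terminal propane carbons are symmetric at any depth
  p <- propane_record()
  expect_identical(hose_code(p, 0, spheres = 3), hose_code(p, 2, spheres = 3))
  expect_false(hose_code(p, 0, spheres = 1) == hose_code(p, 1, spheres = 1))
  # sphere-1 of a terminal carbon: the heavier neighbour first
  expect_identical(hose_code(p, 0, spheres = 1), "C-4;C,H,H,H")
})

test_that("deeper codes truncate to the directly computed shallower codes", {
  d <- tiny_synth(10, seed = 21, ring_prob = 0.6)
  for (r in d$records) {
    for (atom in seq_along(r$elements) - 1L) {
      full <- hose_code(r, atom, spheres = 6)
      parts <- strsplit(full, "/", fixed = TRUE)[[1]]
      for (s in 1:5) {
        expect_identical(hose_code(r, atom, spheres = s),
                         paste(parts[seq_len(s)], collapse = "/"))
      }
    }
  }
})

test_that("the compiled sphere kernel matches the R reference assembly", {
  d <- tiny_synth(5, seed = 41, ring_prob = 0.6)
  for (r in d$records) {
    adj <- nmrgraph:::record_adjacency(r)
    ranks <- nmrgraph:::.atom_ranks(r, adj)
    n <- length(r$elements)
    m <- nmrgraph:::.hose_codes_matrix(r, seq_len(n), 6L, adj, ranks)
    for (i in seq_len(n)) {
      hs <- nmrgraph:::.hose_spheres(r, i, 6L, adj, ranks)
      ref <- vapply(1:6, function(k) {
        paste0(hs$center, paste(hs$spheres[seq_len(k)], collapse = "/"))
      }, character(1))
      expect_identical(as.character(m[i, ]), ref)
    }
  }
})

test_that("codes are invariant under atom relabeling", {
  set.seed(99)
  d <- tiny_synth(6, seed = 31, ring_prob = 0.5)
  for (r in d$records) {
    n <- length(r$elements)
    ref <- vapply(seq_len(n) - 1L, function(a) hose_code(r, a, 6),
                  character(1))
    for (k in 1:8) {
      perm <- sample(0:(n - 1L))
      rp <- permute_record(r, perm)
      got <- vapply(perm + 1L, function(np) hose_code(rp, np - 1L, 6),
                    character(1))
      expect_identical(got, ref)
    }
  }
})

test_that("the lookup table records every labeled shift once per sphere level", {
  e <- ethanol_record()
  d <- shift_dataset(list(e), "13C")
  tab <- hose_model(d, s_max = 6)
  n_entries <- sum(vapply(tab$tables, function(env) {
    sum(vapply(ls(env), function(k) length(env[[k]]), integer(1)))
  }, integer(1)))
  expect_equal(n_entries, 2L * 6L)   # 2 labeled atoms x 6 sphere levels

  # symmetric atoms share codes; their shifts pool in one entry
  p <- propane_record(ppm = c(10, 30, 20))
  tp <- hose_model(shift_dataset(list(p), "13C"), s_max = 3)
  pooled <- lapply(ls(tp$tables[[3]]), function(k) sort(tp$tables[[3]][[k]]))
  expect_true(any(vapply(pooled, identical, logical(1), y = c(10, 20))))

  # rebuilding is deterministic
  tab2 <- hose_model(d, s_max = 6)
  expect_identical(lapply(sort(ls(tab$tables[[6]])),
                          function(k) tab$tables[[6]][[k]]),
                   lapply(sort(ls(tab2$tables[[6]])),
                          function(k) tab2$tables[[6]][[k]]))
})

test_that("prediction matches at the deepest available sphere and averages entries", {
  train <- shift_dataset(list(ethanol_record(), methane_record(77.0)), "13C")
  tab <- hose_model(train, s_max = 6)
  # identical environment -> exact value at full depth
  pred <- predict(tab, methane_record(0))
  expect_equal(pred$predicted_shift_ppm, 77.0)
  expect_equal(pred$matched_spheres, 6L)
  expect_false(pred$missing_flag)
  # two entries under one matched code -> their mean
  train2 <- shift_dataset(list(methane_record(10), {
    r <- methane_record(20); r$molecule_id <- "methane2"; r
  }), "13C")
  tab2 <- hose_model(train2, s_max = 6)
  expect_equal(predict(tab2, methane_record(0))$predicted_shift_ppm, 15.0)
  # element environment absent even at one sphere -> missing
  p19 <- fluoromethane_record()
  tab19 <- hose_model(shift_dataset(list(p19), "19F"), s_max = 6)
  # fluorine on sulfur: even the one-sphere environment is unseen
  query <- shift_record("sf", c("S", "F", "H"),
                        bonds = data.frame(a = c(0L, 0L), b = c(1L, 2L),
                                           order = "single"),
                        shifts = data.frame(atom = 1L, ppm = -60),
                        nucleus = "19F")
  prq <- predict(tab19, query)
  expect_true(prq$missing_flag)
  expect_true(is.na(prq$predicted_shift_ppm))
})

test_that("shallower matches fall back gracefully", {
  # train: ethanol; query: methanol CH3OH -- its C has O,H,H,H sphere 1,
  # unseen as such, but prediction should still fall back if any sphere
  # matches, or be missing otherwise; here sphere-1 C-4;H,H,H,O unseen
  # in training except via ethanol C2 (C,H,H,O at sphere 1) -> missing
  train <- shift_dataset(list(ethanol_record()), "13C")
  tab <- hose_model(train, s_max = 4)
  methanol <- shift_record("methanol", c("C", "O", "H", "H", "H", "H"),
                           bonds = data.frame(a = c(0L, 0L, 0L, 0L, 1L),
                                              b = c(1L, 2L, 3L, 4L, 5L),
                                              order = "single"),
                           shifts = data.frame(atom = 0L, ppm = 50.4),
                           nucleus = "13C")
  expect_true(predict(tab, methanol)$missing_flag)
  # but a methyl carbon bonded exactly like ethanol's C0 matches deep
  propanol_like <- ethanol_record()
  propanol_like$molecule_id <- "ethanol_copy"
  got <- predict(tab, propanol_like)
  expect_equal(got$matched_spheres, c(4L, 4L))
  expect_equal(got$predicted_shift_ppm, got$true_shift_ppm)
})

test_that("missing fractions count abstentions per atom and per molecule", {
  pred <- data.frame(molecule_id = rep(c("a", "b"), each = 2),
                     missing_flag = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(missing_fraction(pred), 25)
  expect_equal(missing_fraction(pred, per = "molecule"), 50)
  none <- data.frame(molecule_id = letters[1:5],
                     missing_flag = rep(FALSE, 5))
  expect_equal(missing_fraction(none), 0)
  expect_error(missing_fraction(none[0, ]), "empty")
})

test_that("enlarging the training set never increases the missing fraction", {
  d <- tiny_synth(120, seed = 77, noise_sd = 0)
  test <- d[101:120]
  for (seed in 1:3) {
    ord <- withr::with_seed(seed, sample(100))
    small <- hose_model(d[ord[1:25]])
    large <- hose_model(d[ord[1:70]])
    mf_small <- missing_fraction(predict(small, test))
    mf_large <- missing_fraction(predict(large, test))
    expect_lte(mf_large, mf_small)
  }
})

test_that("serialized tables reload to identical predictions", {
  d <- tiny_synth(15, seed = 5)
  tab <- hose_model(d[1:10])
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_hose_table(tab, path)
  back <- read_hose_table(path)
  expect_equal(predict(back, d[11:15]), predict(tab, d[11:15]))
  expect_equal(back$train_mean, tab$train_mean)
})
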