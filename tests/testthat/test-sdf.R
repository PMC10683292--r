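test_that("spectrum property values parse per the nmrshiftdb2 dialect", {
  out <- parse_spectrum_property("Spectrum 13C 0", "17.6;0.0Q;0|128.5;0.0D;3|")
  expect_equal(out$atom, c(0L, 3L))
  expect_equal(out$ppm, c(17.6, 128.5))

  expect_equal(nrow(parse_spectrum_property("Spectrum 13C 0", "")), 0L)

  dup <- parse_spectrum_property("Spectrum 13C 1", "10.0;0.0;2|12.0;0.0;2|")
  expect_equal(dup$atom, 2L)
  expect_equal(dup$ppm, 11.0)

  expect_error(parse_spectrum_property("Solvent", "x"), "not a spectrum tag")
  expect_error(parse_spectrum_property("Spectrum 13C 0", "17.6;0.0Q"),
               "malformed")
})

test_that("SD round trip preserves atoms, bonds, shifts and solvent", {
  d <- tiny_synth(8, seed = 4,
                  solvents = c("Chloroform-D1" = 2, "Methanol-D4" = 1))
  path <- withr::local_tempfile(fileext = ".sd")
  write_sd_dataset(d, path)
  back <- read_sd_dataset(path, "13C")
  expect_equal(length(back), length(d))
  for (i in seq_along(d$records)) {
    a <- d$records[[i]]; b <- back$records[[i]]
    expect_identical(b$molecule_id, a$molecule_id)
    expect_identical(b$elements, a$elements)
    expect_identical(b$bonds[c("a", "b", "order")],
                     a$bonds[c("a", "b", "order")])
    expect_equal(b$shifts$atom, a$shifts$atom)
    expect_equal(b$shifts$ppm, a$shifts$ppm, tolerance = 1e-5)
    expect_identical(b$solvent, a$solvent)
  }
})

test_that("records without the requested nucleus are skipped, empty datasets error", {
  d13 <- tiny_synth(2, seed = 1)
  d19 <- generate_shift_dataset(synth_spec(
    n_molecules = 1, elements = c(C = 0.5, F = 0.5), nucleus = "19F",
    base_shift = -150, seed = 9))
  path <- withr::local_tempfile(fileext = ".sd")
  write_sd_dataset(d13, path)
  # append the 19F record to the same file
  tmp19 <- withr::local_tempfile(fileext = ".sd")
  write_sd_dataset(d19, tmp19)
  file.append(path, tmp19)
  got13 <- read_sd_dataset(path, "13C")
  expect_equal(length(got13), 2L)
  got19 <- read_sd_dataset(path, "19F")
  expect_equal(length(got19), 1L)
  expect_error(read_sd_dataset(path, "1H"), "empty dataset")

  empty <- withr::local_tempfile(fileext = ".sd")
  writeLines(character(0), empty)
  expect_error(read_sd_dataset(empty, "13C"))
  expect_error(read_sd_dataset(file.path(tempdir(), "no_such.sd"), "13C"),
               "cannot read")
})

test_that("deduplication keeps one spectrum per compound, deterministically", {
  d <- tiny_synth(10, seed = 2)
  # identity when already unique
  expect_equal(molecule_ids(deduplicate_spectra(d, seed = 5)),
               molecule_ids(d))
  # duplicate one molecule 4x with distinct shifts
  dup <- d$records[[3]]
  extra <- lapply(1:3, function(k) {
    r <- dup
    r$shifts$ppm <- r$shifts$ppm + k
    r
  })
  dd <- shift_dataset(c(d$records, extra), "13C")
  out1 <- deduplicate_spectra(dd, seed = 7)
  out2 <- deduplicate_spectra(dd, seed = 7)
  expect_equal(length(out1), 10L)
  expect_equal(anyDuplicated(molecule_ids(out1)), 0L)
  expect_identical(out1$records, out2$records)
  # idempotent
  expect_identical(deduplicate_spectra(out1, seed = 7)$records, out1$records)
  # a different seed may keep a different spectrum but the same ids
  expect_setequal(molecule_ids(deduplicate_spectra(dd, seed = 8)),
                  molecule_ids(d))
})

test_that("solvent filtering respects the synonym map and excludes unknowns", {
  recs <- c(lapply(1:5, function(i) {
    r <- methane_record(); r$molecule_id <- paste0("c", i)
    r$solvent <- "Chloroform-D1"; r
  }), lapply(1:3, function(i) {
    r <- methane_record(); r$molecule_id <- paste0("d", i)
    r$solvent <- "Dimethylsulphoxide-D6"; r
  }), list({
    r <- methane_record(); r$molecule_id <- "u"; r$solvent <- "unknown"; r
  }))
  d <- shift_dataset(recs, "13C")
  got <- filter_by_solvent(d, "CDCl3")
  expect_equal(length(got), 5L)
  expect_identical(got$solvent_filter, "Chloroform-D1")
  expect_identical(molecule_ids(filter_by_solvent(d, "Chloroform-D1")),
                   molecule_ids(got))
  expect_warning(empty <- filter_by_solvent(d, "Methanol-D4"),
                 "no records")
  expect_equal(length(empty), 0L)
  # distinct canonical solvents give disjoint subsets; unknown never appears
  a <- molecule_ids(filter_by_solvent(d, "CDCl3"))
  b <- molecule_ids(filter_by_solvent(d, "DMSO-D6"))
  expect_length(intersect(a, b), 0L)
  expect_false("u" %in% c(a, b))
})

test_that("prediction tables write with the fixed column set", {
  d <- tiny_synth(6, seed = 3)
  fit <- naive_shift_model(d)
  pred <- predict(fit, d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions_csv(pred, path)
  back <- read.csv(path)
  expect_named(back, c("molecule_id", "atom_index", "true_shift_ppm",
                       "predicted_shift_ppm", "method", "missing_flag"))
  expect_equal(nrow(back), nrow(pred))
  expect_error(write_predictions_csv(pred[, 1:2], path), "lacks column")
})
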