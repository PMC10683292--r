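# SD-file input/output for nmrshiftdb2-style assigned spectra.
#
# Molfile parsing itself is delegated to ChemmineR; this file owns the
# nmrshiftdb2 property-block dialect: spectra live in tags named
# "Spectrum <nucleus> <k>" whose value is a "|"-separated list of
# "shift;aux;atomindex" triples with 0-based atom indices.  Molfile
# bond-block indices are 1-based and converted here, once.

.solvent_synonyms <- list(
  "Chloroform-D1"        = c("chloroform-d1", "cdcl3", "chloroform-d",
                             "deuterochloroform"),
  "Dimethylsulphoxide-D6" = c("dimethylsulphoxide-d6", "dmso-d6", "c2d6so",
                              "dimethylsulfoxide-d6", "dmso"),
  "Methanol-D4"          = c("methanol-d4", "cd3od", "methanol-d")
)

#' Normalize a solvent name
#'
#' Maps common synonyms (e.g. `"CDCl3"`) to a canonical name
#' (`"Chloroform-D1"`); empty or unreported values become `"unknown"`.
#' Unrecognized but non-empty names are kept verbatim (trimmed), so
#' solvents outside the synonym map can still be filtered on exactly.
#'
#' @param x Character vector of solvent strings.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' normalize_solvent(c("CDCl3", "Chloroform-D1", "", "DMSO-D6"))
normalize_solvent <- function(x) {
  x <- trimws(as.character(x))
  out <- x
  low <- tolower(x)
  out[is.na(x) | low %in% c("", "unknown", "unreported", "n/a", "na")] <- "unknown"
  for (canon in names(.solvent_synonyms)) {
    out[low %in% c(tolower(canon), .solvent_synonyms[[canon]])] <- canon
  }
  out
}

#' Parse one spectrum property block
#'
#' Parses the value of an nmrshiftdb2 `"Spectrum <nucleus> <k>"` SD tag
#' into atom-indexed shift assignments.  Entries are separated by `"|"`;
#' each entry is `"shift;aux;atomindex"` where the auxiliary field
#' (intensity or multiplicity) and anything after it are ignored.  Atom
#' indices in the tag are already 0-based.  Duplicate assignments to the
#' same atom are averaged.
#'
#' @param tag_name Tag name, must match `"Spectrum <nucleus> <k>"`.
#' @param tag_value Tag value string.
#' @return data.frame with columns `atom` (0-based integer) and `ppm`,
#'   ordered by atom index.
#' @export
#' @examples
#' parse_spectrum_property("Spectrum 13C 0", "17.6;0.0Q;0|128.5;0.0D;3|")
parse_spectrum_property <- function(tag_name, tag_value) {
  if (!grepl("^Spectrum [A-Za-z0-9]+ [0-9]+$", tag_name))
    stop("not a spectrum tag: ", tag_name, call. = FALSE)
  tag_value <- trimws(tag_value)
  if (!nzchar(tag_value)) return(data.frame(atom = integer(0), ppm = numeric(0)))
  entries <- strsplit(tag_value, "|", fixed = TRUE)[[1]]
  entries <- entries[nzchar(trimws(entries))]
  atoms <- integer(length(entries)); ppm <- numeric(length(entries))
  for (i in seq_along(entries)) {
    f <- strsplit(entries[i], ";", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed spectrum entry: '", entries[i], "'", call. = FALSE)
    s <- suppressWarnings(as.numeric(f[1]))
    a <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(a))
      stop("malformed spectrum entry: '", entries[i], "'", call. = FALSE)
    atoms[i] <- a; ppm[i] <- s
  }
  agg <- tapply(ppm, atoms, mean)
  out <- data.frame(atom = as.integer(names(agg)), ppm = as.numeric(agg))
  out[order(out$atom), , drop = FALSE]
}

.bond_order_names <- c("single", "double", "triple", "aromatic")

# legacy V2000 charge codes: 0 none, 1..3 => +3..+1, 5..7 => -1..-3
.decode_charge <- function(code) {
  ch <- integer(length(code))
  ch[code == 1] <- 3L; ch[code == 2] <- 2L; ch[code == 3] <- 1L
  ch[code == 5] <- -1L; ch[code == 6] <- -2L; ch[code == 7] <- -3L
  ch
}
.encode_charge <- function(charge) {
  code <- integer(length(charge))
  code[charge == 3] <- 1L; code[charge == 2] <- 2L; code[charge == 1] <- 3L
  code[charge == -1] <- 5L; code[charge == -2] <- 6L; code[charge == -3] <- 7L
  code
}

# Convert one ChemmineR SDF record + one spectrum tag into a shift_record.
.sdf_to_record <- function(sdf, molecule_id, spectrum_tag, nucleus) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  db <- ChemmineR::datablock(sdf)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charges <- if ("C6" %in% colnames(ab)) .decode_charge(ab[, "C6"]) else NULL
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = NROW(bb))
  if (nrow(bb) > 0L) {
    ord_code <- as.integer(bb[, 3])
    if (any(ord_code < 1L | ord_code > 4L))
      stop("unsupported bond order code in record ", molecule_id, call. = FALSE)
    bonds <- data.frame(a = as.integer(bb[, 1]) - 1L,
                        b = as.integer(bb[, 2]) - 1L,
                        order = .bond_order_names[ord_code],
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = character(0))
  }
  shifts <- parse_spectrum_property(spectrum_tag, db[[spectrum_tag]])
  if (nrow(shifts) == 0L)
    stop("spectrum tag ", spectrum_tag, " carries no assignments", call. = FALSE)
  k <- sub("^Spectrum [A-Za-z0-9]+ ", "", spectrum_tag)
  solv_tag <- paste("Solvent", nucleus, k)
  solvent <- if (solv_tag %in% names(db)) db[[solv_tag]]
             else if ("Solvent" %in% names(db)) db[["Solvent"]]
             else "unknown"
  shift_record(molecule_id = molecule_id, elements = elements,
               coords = coords, charges = charges, bonds = bonds,
               shifts = shifts, nucleus = nucleus,
               solvent = normalize_solvent(solvent))
}

# TRUE when a datablock marks the record/spectrum as ab-initio calculated.
.is_calculated <- function(db) {
  nm <- names(db)
  hit <- grepl("calculat", nm, ignore.case = TRUE)
  if (!any(hit)) return(FALSE)
  any(grepl("true|yes|ab.?initio|calculated", unlist(db[hit]),
            ignore.case = TRUE))
}

#' Read an nmrshiftdb2-style SD file
#'
#' Reads a V2000 SD file whose property blocks carry assigned spectra in
#' `"Spectrum <nucleus> <k>"` tags, returning one [shift_record()] per
#' spectrum of the requested nucleus.  Records without such a tag are
#' skipped silently; records that fail to parse are skipped with a
#' message and counted.  Records whose property block marks them as
#' ab-initio calculated are dropped.  A molecule with several spectra of
#' the nucleus yields several records sharing one `molecule_id`; use
#' [deduplicate_spectra()] to retain one spectrum per compound.
#'
#' @param path Path to the SD file.
#' @param nucleus Nucleus label, e.g. `"13C"` or `"19F"`.
#' @return A [shift_dataset()].
#' @seealso [write_sd_dataset()], [filter_by_solvent()]
#' @export
read_sd_dataset <- function(path, nucleus) {
  if (!file.exists(path)) stop("cannot read SD file: ", path, call. = FALSE)
  sdfset <- ChemmineR::read.SDFset(path)
  records <- list()
  n_failed <- 0L
  pattern <- paste0("^Spectrum ", nucleus, " [0-9]+$")
  for (i in seq_along(sdfset)) {
    rec <- tryCatch({
      sdf <- sdfset[[i]]
      db <- ChemmineR::datablock(sdf)
      if (.is_calculated(db)) list() else {
        tags <- grep(pattern, names(db), value = TRUE)
        if (length(tags) == 0L) list() else {
          hdr <- ChemmineR::header(sdf)
          id <- trimws(hdr[["Molecule_Name"]])
          if (!nzchar(id)) id <- paste0("record_", i)
          lapply(tags, function(tg) .sdf_to_record(sdf, id, tg, nucleus))
        }
      }
    }, error = function(e) {
      message("skipping record ", i, ": ", conditionMessage(e))
      n_failed <<- n_failed + 1L
      list()
    })
    records <- c(records, rec)
  }
  if (n_failed > 0L)
    message(n_failed, " record(s) skipped due to parse failures")
  if (length(records) == 0L)
    stop("empty dataset: no usable ", nucleus, " records in ", path,
         call. = FALSE)
  shift_dataset(records, nucleus)
}

#' Write a shift dataset as an SD file
#'
#' Writes each record as a V2000 molfile with a
#' `"Spectrum <nucleus> 0"` property carrying its shift assignments
#' (0-based atom indices) and a `"Solvent"` property.  Reading the file
#' back with [read_sd_dataset()] reproduces atoms, bonds and shift
#' assignments exactly.
#'
#' @param dataset A [shift_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sd_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "shift_dataset"))
  sdfs <- lapply(dataset$records, function(r) {
    n <- length(r$elements); nb <- nrow(r$bonds)
    ab <- matrix(0, n, 15L,
                 dimnames = list(paste0(r$elements, "_", seq_len(n)),
                                 c("C1", "C2", "C3", paste0("C", 5:16))))
    ab[, 1:3] <- r$coords
    ab[, "C6"] <- .encode_charge(r$charges)
    bb <- matrix(0, nb, 7L,
                 dimnames = list(seq_len(nb), paste0("C", 1:7)))
    if (nb > 0L) {
      bb[, 1] <- r$bonds$a + 1L
      bb[, 2] <- r$bonds$b + 1L
      bb[, 3] <- match(r$bonds$order, .bond_order_names)
    }
    spec <- paste0(sprintf("%.6g;0.0;%d", r$shifts$ppm, r$shifts$atom),
                   collapse = "|")
    db <- c(spec, r$solvent)
    names(db) <- c(paste("Spectrum", r$nucleus, "0"), "Solvent")
    methods::new("SDF",
                 header = c(Molecule_Name = r$molecule_id,
                            Source = "  nmrgraph", Comment = "",
                            Counts_Line = sprintf(
                              "%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                              n, nb)),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
  sdfset <- methods::new("SDFset", SDF = sdfs,
                         ID = molecule_ids(dataset))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Retain one spectrum per compound
#'
#' Molecules can carry several measured spectra of the same nucleus; for
#' evaluation a single spectrum per compound is retained, chosen
#' uniformly at random but deterministically for a given seed.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param dataset A [shift_dataset()].
#' @param seed Integer seed controlling which spectrum is retained.
#' @return A [shift_dataset()] with unique `molecule_id`s.
#' @export
deduplicate_spectra <- function(dataset, seed = 1L) {
  ids <- molecule_ids(dataset)
  keep <- with_seed(seed, {
    vapply(split(seq_along(ids), factor(ids, levels = unique(ids))),
           function(idx) {
             if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
           }, integer(1))
  })
  dataset[sort(unname(keep))]
}

#' Restrict a dataset to one solvent
#'
#' Keeps records whose solvent normalizes to the query (synonyms such as
#' `"CDCl3"` and `"Chloroform-D1"` are equivalent).  Records with
#' unknown solvent are excluded.
#'
#' @param dataset A [shift_dataset()].
#' @param solvent Solvent name or synonym.
#' @return A filtered [shift_dataset()] with `solvent_filter` set; warns
#'   when the result is empty.
#' @export
filter_by_solvent <- function(dataset, solvent) {
  canon <- normalize_solvent(solvent)
  solv <- normalize_solvent(vapply(dataset$records,
                                   function(r) r$solvent, character(1)))
  sel <- which(solv == canon & solv != "unknown")
  if (length(sel) == 0L)
    warning("no records with solvent ", canon, call. = FALSE)
  out <- dataset[sel]
  out$solvent_filter <- canon
  out
}

#' Write a prediction table as CSV
#'
#' @param predictions data.frame as returned by the `predict()` methods,
#'   with columns `molecule_id`, `atom_index`, `true_shift_ppm`,
#'   `predicted_shift_ppm`, `method`, `missing_flag`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, path) {
  cols <- c("molecule_id", "atom_index", "true_shift_ppm",
            "predicted_shift_ppm", "method", "missing_flag")
  missing_cols <- setdiff(cols, names(predictions))
  if (length(missing_cols) > 0L)
    stop("prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(predictions[, cols], path, row.names = FALSE)
  invisible(path)
}
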