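# Small molecules and datasets built in code; no fixture files.

methane_record <- function(shift = -2.3, nucleus = "13C") {
  shift_record("methane", c("C", "H", "H", "H", "H"),
               bonds = data.frame(a = 0L, b = 1:4, order = "single"),
               shifts = data.frame(atom = 0L, ppm = shift),
               nucleus = nucleus)
}

# CH3-CH2-OH with explicit hydrogens; shifts on both carbons
ethanol_record <- function(solvent = "unknown") {
  shift_record("ethanol",
               c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
               bonds = data.frame(
                 a = c(0L, 1L, 0L, 0L, 0L, 1L, 1L, 2L),
                 b = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
                 order = "single"),
               shifts = data.frame(atom = c(0L, 1L), ppm = c(18.3, 57.8)),
               nucleus = "13C", solvent = solvent)
}

# CH3-CH2-CH3; the two terminal carbons are symmetric
propane_record <- function(ppm = c(15.6, 16.1, 15.6)) {
  shift_record("propane",
               c("C", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H"),
               bonds = data.frame(
                 a = c(0L, 1L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L),
                 b = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
                 order = "single"),
               shifts = data.frame(atom = 0:2, ppm = ppm),
               nucleus = "13C")
}

fluoromethane_record <- function(shift = -271.9) {
  shift_record("fluoromethane", c("C", "F", "H", "H", "H"),
               bonds = data.frame(a = 0L, b = 1:4, order = "single"),
               shifts = data.frame(atom = 1L, ppm = shift),
               nucleus = "19F")
}

# Relabel atoms: perm[old + 1] = new 0-based index of old atom `old`
permute_record <- function(record, perm) {
  n <- length(record$elements)
  stopifnot(length(perm) == n, setequal(perm, 0:(n - 1L)))
  inv <- integer(n)
  inv[perm + 1L] <- seq_len(n)    # inv[new+1] = old 1-based
  shift_record(paste0(record$molecule_id, "_perm"),
               elements = record$elements[inv],
               coords = record$coords[inv, , drop = FALSE],
               charges = record$charges[inv],
               bonds = data.frame(a = perm[record$bonds$a + 1L],
                                  b = perm[record$bonds$b + 1L],
                                  order = record$bonds$order),
               shifts = data.frame(atom = perm[record$shifts$atom + 1L],
                                   ppm = record$shifts$ppm),
               nucleus = record$nucleus, solvent = record$solvent)
}

tiny_synth <- function(n = 20, seed = 1, noise_sd = 1, ...) {
  generate_shift_dataset(synth_spec(n_molecules = n, seed = seed,
                                    noise_sd = noise_sd, ...))
}

fast_config <- function(...) {
  args <- list(hidden_width = 8L, epochs = 5L, batch_size = 8L,
               val_fraction = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gnn_config, args)
}
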