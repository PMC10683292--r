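# Static element property table.
#
# Values are vendored rather than looked up at run time so that feature
# vectors are reproducible against reference-library version drift.
# Sources: Slater (1964) empirical atomic radii [pm]; IUPAC standard
# atomic weights -> most abundant isotope mass number; Pauling
# electronegativities; electron affinities [eV] as tabulated in the
# mendeleev reference tables; Pyykko single-bond covalent radii [Angstrom].
# Nitrogen's anion is unbound; its electron affinity is the conventional
# -0.07 eV estimate.

.element_table <- data.frame(
  symbol            = c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                        "Cl", "Br", "I"),
  atomic_number     = c(1L, 5L, 6L, 7L, 8L, 9L, 14L, 15L, 16L, 17L, 35L, 53L),
  mass_number       = c(1L, 11L, 12L, 14L, 16L, 19L, 28L, 31L, 32L,
                        35L, 79L, 127L),
  radius_slater_pm  = c(25, 85, 70, 65, 60, 50, 110, 100, 100, 100, 115, 140),
  en_pauling        = c(2.20, 2.04, 2.55, 3.04, 3.44, 3.98, 1.90, 2.19,
                        2.58, 3.16, 2.96, 2.66),
  electron_affinity = c(0.754195, 0.279723, 1.262119, -0.07, 1.4611136,
                        3.4011898, 1.3895211, 0.746607, 2.0771029,
                        3.612725, 3.363588, 3.0590463),
  covalent_radius_A = c(0.32, 0.85, 0.75, 0.71, 0.63, 0.64, 1.16, 1.11,
                        1.03, 0.99, 1.14, 1.33),
  max_valence       = c(1L, 3L, 4L, 3L, 2L, 1L, 4L, 3L, 2L, 1L, 1L, 1L),
  stringsAsFactors  = FALSE
)
rownames(.element_table) <- .element_table$symbol

#' Element property lookup
#'
#' Returns the vendored per-element property table used to build atom
#' features: Slater atomic radius (pm), neutron count of the most
#' abundant isotope, Pauling electronegativity, electron affinity (eV),
#' plus the covalent radius (Angstrom) used as bond-length fallback and
#' the standard valence used by the synthetic-molecule generator.
#'
#' @param symbols Optional character vector of element symbols; when
#'   omitted the full table is returned.
#' @return A data.frame with one row per element.  Neutron count is
#'   derived as mass number of the most abundant isotope minus atomic
#'   number.
#' @export
#' @examples
#' element_properties(c("C", "F"))
element_properties <- function(symbols = NULL) {
  tab <- .element_table
  tab$neutrons <- tab$mass_number - tab$atomic_number
  if (is.null(symbols)) return(tab)
  unknown <- setdiff(symbols, tab$symbol)
  if (length(unknown) > 0L) {
    stop("no tabulated properties for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab[symbols, , drop = FALSE]
}

# Element a nucleus label refers to, e.g. "13C" -> "C", "19F" -> "F".
nucleus_element <- function(nucleus) {
  el <- sub("^[0-9]*", "", nucleus)
  if (!nzchar(el)) stop("cannot parse nucleus label: ", nucleus, call. = FALSE)
  el
}
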