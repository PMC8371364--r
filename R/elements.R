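# Element tables: atomic masses (amu) and van der Waals radii (Angstrom).
# Radii are the Bondi (1964) consensus values commonly used for SASA;
# metals use Batsanov-style estimates. Keys are upper-case element symbols.

.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  `NA` = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
  FE = 55.845, ZN = 65.38, CU = 63.546, SE = 78.971
)

.element_vdw <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  `NA` = 2.27, K = 2.75, MG = 1.73, CA = 2.31, MN = 2.05,
  FE = 2.05, ZN = 1.39, CU = 1.40, SE = 1.90
)

element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- unname(.element_masses[key])
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    abort(sprintf("No atomic mass known for element(s): %s",
                  paste(bad, collapse = ", ")),
          class = "btkloop_element_error")
  }
  m
}

#' Default van der Waals radii for surface-area calculations
#'
#' Returns the element-keyed van der Waals radius set (Angstrom) used by
#' [sasa_frame()]. Individual radii can be overridden by name before passing
#' the vector on.
#'
#' @return A named numeric vector of radii in Angstrom, keyed by upper-case
#'   element symbol.
#' @examples
#' r <- default_vdw_radii()
#' r[["C"]]
#' @export
default_vdw_radii <- function() {
  .element_vdw
}

# Infer an element symbol from a PDB atom name when the element column is
# blank. Handles the common two-character cases (CL, NA, MG, ...) that appear
# left-justified in column 13 of hetero records.
.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "MN", "SE", "NA", "K "),
                trimws(two), substr(nm, 1, 1))
  # digits first (e.g. "1HB") -> first letter
  digit_lead <- grepl("^[0-9]", out)
  out[digit_lead] <- substr(gsub("[0-9]", "", nm[digit_lead]), 1, 1)
  out
}
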