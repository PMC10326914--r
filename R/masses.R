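#' Monoisotopic mass bookkeeping
#'
#' Monoisotopic residue masses for the 20 standard amino acids and the
#' physical constants used throughout fragment m/z arithmetic.  All values
#' are in daltons (Da) and follow the IUPAC 2021 atomic masses; m/z values
#' derived from them are in thomson (Th).
#'
#' @format `residue_masses()` returns a named numeric vector mapping
#'   single-letter residue codes to monoisotopic residue (i.e. dehydrated)
#'   masses.
#' @name masses
NULL

# monoisotopic residue masses, Da (residue = amino acid - H2O)
.RESIDUE_MASSES <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918496, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048491, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' @rdname masses
#' @export
residue_masses <- function() .RESIDUE_MASSES

#' @rdname masses
#' @export
PROTON_MASS <- 1.00727646688

#' @rdname masses
#' @export
WATER_MASS <- 18.01056468

#' @rdname masses
#' @export
CO_MASS <- 27.99491462

# residue masses for a sequence string, with a helpful error on unknowns
.sequence_masses <- function(sequence) {
  if (!nzchar(sequence)) return(numeric(0))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- .RESIDUE_MASSES[res]
  if (anyNA(m)) {
    bad <- unique(res[is.na(m)])
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}
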