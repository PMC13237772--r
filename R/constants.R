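# Physical constants and fixed lookup tables.
#
# Isotope masses and abundances are pinned here (IUPAC/CODATA values) so that
# envelope arithmetic is reproducible and independent of external libraries.

#' Physical constants used throughout the package
#'
#' @format A named list:
#' \describe{
#'   \item{mass_h_to_d}{Mass difference between deuterium and protium, Da
#'     (1.006277).}
#'   \item{mass_proton}{Charge-carrier proton mass, Da (1.007276).}
#' }
#' @export
hdx_constants <- list(
  mass_h_to_d = 1.006277,
  mass_proton = 1.007276
)

# Per-element isotope tables: mass (Da) and abundance, lightest first.
.isotopes <- list(
  C = list(mass = c(12.000000, 13.003355), abund = c(0.9893, 0.0107)),
  H = list(mass = c(1.007825, 2.014102), abund = c(0.999885, 0.000115)),
  N = list(mass = c(14.003074, 15.000109), abund = c(0.99636, 0.00364)),
  O = list(
    mass = c(15.994915, 16.999132, 17.999160),
    abund = c(0.99757, 0.00038, 0.00205)
  ),
  S = list(
    mass = c(31.972071, 32.971459, 33.967867, 35.967081),
    abund = c(0.9499, 0.0075, 0.0425, 0.0001)
  )
)

# Residue elemental compositions (residue = amino acid minus one water),
# canonical 20, columns C,H,N,O,S.
.residue_comp <- matrix(
  c(
    3, 5, 1, 1, 0, # A
    6, 12, 4, 1, 0, # R
    4, 6, 2, 2, 0, # N
    4, 5, 1, 3, 0, # D
    3, 5, 1, 1, 1, # C
    5, 8, 2, 2, 0, # Q
    5, 7, 1, 3, 0, # E
    2, 3, 1, 1, 0, # G
    6, 7, 3, 1, 0, # H
    6, 11, 1, 1, 0, # I
    6, 11, 1, 1, 0, # L
    6, 12, 2, 1, 0, # K
    5, 9, 1, 1, 1, # M
    9, 9, 1, 1, 0, # F
    5, 7, 1, 1, 0, # P
    3, 5, 1, 2, 0, # S
    4, 7, 1, 2, 0, # T
    11, 10, 2, 1, 0, # W
    9, 9, 1, 2, 0, # Y
    5, 9, 1, 1, 0 # V
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c(
      "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
    ),
    c("C", "H", "N", "O", "S")
  )
)

# Side-chain exchangeable (labile) hydrogen counts per residue, used when
# modelling full hydrogen scrambling, which redistributes deuterium over all
# labile sites, not just backbone amides. Neutral-form counts.
.side_chain_labile <- c(
  A = 0, R = 4, N = 2, D = 1, C = 1, Q = 2, E = 1, G = 0, H = 1, I = 0,
  L = 0, K = 2, M = 0, F = 0, P = 0, S = 1, T = 1, W = 1, Y = 1, V = 0
)

.valid_aa <- rownames(.residue_comp)

#' Count labile (exchangeable) hydrogens per residue of a sequence
#'
#' Backbone amide hydrogens (one per residue, none for proline, two for the
#' free N-terminal amine of residue 1) plus side-chain exchangeable
#' hydrogens from a fixed internal table. Used for the fully-scrambled
#' deuterium distribution in scrambling QC and simulation.
#'
#' @param sequence One-letter amino-acid string.
#' @return Integer vector, one count per residue.
#' @export
labile_hydrogens <- function(sequence) {
  aa <- validate_sequence(sequence)
  n <- length(aa)
  backbone <- ifelse(aa == "P", 0L, 1L)
  backbone[1] <- 2L # free alpha-amine
  unname(backbone + .side_chain_labile[aa])
}

# Split and validate a one-letter sequence; returns the residue vector.
validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
    nchar(sequence) == 0) {
    stop("`sequence` must be a single non-empty amino-acid string",
      call. = FALSE
    )
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), .valid_aa)
  if (length(bad) > 0) {
    stop(
      "invalid residue(s) in sequence: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  aa
}
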