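# Amino-acid alphabets and physicochemical property tables used by the
# sequence- and profile-based encoders. All matrices are built at load time
# from the primary property scales so every value is traceable to a formula.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in alphabetical one-letter order. All feature
#' vectors and internal profile columns are indexed in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column order emitted by PSI-BLAST ASCII PSSM headers (differs from
# alphabetical; profiles are re-mapped to AA_ALPHABET at parse time).
PSIBLAST_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Noncanonical letters tolerated in input sequences. They contribute zero to
# sequence-derived encodings; profiles keep their rows so the L-row invariant
# holds. Strict mode rejects them at read time.
AA_NONCANONICAL <- c("X", "B", "Z", "U")

# ---------------------------------------------------------------------------
# Grantham (1974) chemical distance, computed from the published composition,
# polarity and molecular-volume properties with weights alpha = 1.833,
# beta = 0.1018, gamma = 0.000399 and the mean inter-residue distance scaled
# to 100. Spot checks against the published rounded table: L-I = 5, D-E = 45,
# W-C = 215.
.grantham_properties <- local({
  # order: AA_ALPHABET
  comp <- c(A = 0,    C = 2.75, D = 1.38, E = 0.92, F = 0,    G = 0.74,
            H = 0.58, I = 0,    K = 0.33, L = 0,    M = 0,    N = 1.33,
            P = 0.39, Q = 0.89, R = 0.65, S = 1.42, T = 0.71, V = 0,
            W = 0.13, Y = 0.20)
  pol  <- c(A = 8.1,  C = 5.5,  D = 13.0, E = 12.3, F = 5.2,  G = 9.0,
            H = 10.4, I = 5.2,  K = 11.3, L = 4.9,  M = 5.7,  N = 11.6,
            P = 8.0,  Q = 10.5, R = 10.5, S = 9.2,  T = 8.6,  V = 5.9,
            W = 5.4,  Y = 6.2)
  vol  <- c(A = 31,   C = 55,   D = 54,   E = 83,   F = 132,  G = 3,
            H = 96,   I = 111,  K = 119,  L = 111,  M = 105,  N = 56,
            P = 32.5, Q = 85,   R = 124,  S = 32,   T = 61,   V = 84,
            W = 170,  Y = 136)
  list(comp = comp[AA_ALPHABET], pol = pol[AA_ALPHABET], vol = vol[AA_ALPHABET])
})

.build_grantham_matrix <- function() {
  p <- .grantham_properties
  d2 <- 1.833 * outer(p$comp, p$comp, "-")^2 +
        0.1018 * outer(p$pol, p$pol, "-")^2 +
        0.000399 * outer(p$vol, p$vol, "-")^2
  d <- sqrt(d2)
  # rho scales the mean off-diagonal distance to 100 (Grantham's convention)
  rho <- 100 / mean(d[upper.tri(d)])
  m <- rho * d
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

#' Grantham chemical distance matrix
#'
#' 20x20 symmetric matrix of Grantham's (1974) amino-acid chemical distances,
#' computed from the composition, polarity and molecular-volume properties
#' with the original weights and the mean distance scaled to 100. Used by the
#' quasi-sequence-order encoder.
#'
#' @return Numeric 20x20 matrix with residues in [AA_ALPHABET] order.
#' @export
grantham_matrix <- function() .virionpred_env$grantham

# ---------------------------------------------------------------------------
# SYNTHETIC surrogate physicochemical distance matrix. The quasi-sequence-
# order descriptor canonically pairs Grantham's matrix with the Schneider-
# Wrede physicochemical distance matrix; the exact published Schneider-Wrede
# table is not redistributed here, so this surrogate is CONSTRUCTED from
# standardized hydrophobicity (Kyte-Doolittle), hydrophilicity (Hopp-Woods)
# and side-chain-mass scales as a Euclidean distance rescaled to [0, 1].
# It is a labelled synthetic stand-in, not the Schneider-Wrede values.
.build_physchem_surrogate_matrix <- function() {
  kd <- c(A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,  G = -0.4,
          H = -3.2, I = 4.5,  K = -3.9, L = 3.8,  M = 1.9,  N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)[AA_ALPHABET]
  hw <- .paac_scales$hydrophilicity
  mass <- .paac_scales$sidechain_mass
  z <- function(x) (x - mean(x)) / stats::sd(x)
  d <- sqrt(outer(z(kd), z(kd), "-")^2 +
            outer(z(hw), z(hw), "-")^2 +
            outer(z(mass), z(mass), "-")^2)
  m <- d / max(d)
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

#' Surrogate physicochemical distance matrix (synthetic)
#'
#' A constructed 20x20 physicochemical distance matrix standing in for the
#' Schneider-Wrede distance matrix in the quasi-sequence-order encoder:
#' Euclidean distance over standardized Kyte-Doolittle hydrophobicity,
#' Hopp-Woods hydrophilicity and side-chain mass, rescaled so the maximum
#' distance is 1. Clearly a synthetic surrogate; substitute the genuine
#' Schneider-Wrede table via the `dmat1` argument of [encode_qsorder()] to
#' reproduce the canonical descriptor exactly.
#'
#' @return Numeric 20x20 matrix with residues in [AA_ALPHABET] order.
#' @export
physchem_surrogate_matrix <- function() .virionpred_env$physchem

# ---------------------------------------------------------------------------
# Property scales for the pseudo amino-acid composition encoder: the classic
# hydrophobicity scale used by pseudo-AAC (Tanford-style transfer free
# energies), Hopp-Woods hydrophilicity, and side-chain masses.
.paac_scales <- local({
  hydrophobicity <- c(
    A = 0.62,  C = 0.29,  D = -0.90, E = -0.74, F = 1.19,  G = 0.48,
    H = -0.40, I = 1.38,  K = -1.50, L = 1.06,  M = 0.64,  N = -0.78,
    P = 0.12,  Q = -0.85, R = -2.53, S = -0.18, T = -0.26, V = 1.08,
    W = 0.81,  Y = 0.26)
  hydrophilicity <- c(
    A = -0.5, C = -1.0, D = 3.0,  E = 3.0,  F = -2.5, G = 0.0,
    H = -0.5, I = -1.8, K = 3.0,  L = -1.8, M = -1.3, N = 0.2,
    P = 0.0,  Q = 0.2,  R = 3.0,  S = 0.3,  T = -0.4, V = -1.5,
    W = -3.4, Y = -2.3)
  sidechain_mass <- c(
    A = 15,  C = 47,  D = 59,  E = 73,  F = 91,  G = 1,
    H = 82,  I = 57,  K = 73,  L = 57,  M = 75,  N = 58,
    P = 42,  Q = 72,  R = 101, S = 31,  T = 45,  V = 43,
    W = 130, Y = 107)
  list(hydrophobicity = hydrophobicity[AA_ALPHABET],
       hydrophilicity = hydrophilicity[AA_ALPHABET],
       sidechain_mass = sidechain_mass[AA_ALPHABET])
})

# standardized (zero-mean, unit-sd over the 20 residues) versions used in the
# pseudo-AAC correlation function
.paac_standardized_scales <- function() {
  lapply(.paac_scales, function(x) (x - mean(x)) / stats::sd(x))
}

.virionpred_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .virionpred_env$grantham <- .build_grantham_matrix()
  .virionpred_env$physchem <- .build_physchem_surrogate_matrix()
}
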