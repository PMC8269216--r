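# Feature encoders. Five profile-based encodings feed the final ensemble
# (AAC-PSSM, PSSM composition, DPC-PSSM, AADP-PSSM, MEDP); four sequence-
# based encodings (AAC, DPC, QSOrder, PAAC) are provided for comparison.
# p[k, j] below is the normalized profile entry for position k, residue j,
# with residues in AA_ALPHABET order.

#' Encoder identifiers
#'
#' `EVOLUTIONARY_ENCODERS` are the five profile-based encodings integrated in
#' the final ensemble; `COMPARISON_ENCODERS` are the four sequence-based
#' encodings used for benchmarking only.
#'
#' @format Character vectors.
#' @export
EVOLUTIONARY_ENCODERS <- c("AAC_PSSM", "PSSM_COMP", "DPC_PSSM",
                           "AADP_PSSM", "MEDP")

#' @rdname EVOLUTIONARY_ENCODERS
#' @export
COMPARISON_ENCODERS <- c("AAC", "DPC", "QSORDER", "PAAC")

.new_feature_vector <- function(encoder_id, values) {
  stopifnot(all(is.finite(values)))
  structure(list(encoder_id = encoder_id, values = values,
                 dim = length(values)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s (%d components)\n", x$encoder_id, x$dim))
  invisible(x)
}

# ---------------------------------------------------------------------------
# profile-based encoders

#' Amino-acid composition of a profile (AAC-PSSM)
#'
#' Averages all rows of the normalized profile: component j is
#' `(1/L) * sum_k p[k, j]`, a 20-dimensional summary of the evolutionary
#' residue propensities.
#'
#' @param profile A normalized `pssm_profile`.
#' @return A `feature_vector` of dimension 20.
#' @export
encode_aac_pssm <- function(profile) {
  p <- .norm_matrix(profile)
  v <- colMeans(p)
  names(v) <- paste0("aac_pssm.", AA_ALPHABET)
  .new_feature_vector("AAC_PSSM", v)
}

#' Residue-grouped profile composition (PSSM composition)
#'
#' Groups profile rows by the residue at each sequence position, sums each
#' group's rows and divides by the sequence length L, yielding a 20x20 matrix
#' (group x profile column) flattened row-wise into a 400-dimensional vector.
#' Residues absent from the sequence contribute exact zero rows; noncanonical
#' positions belong to no group.
#'
#' @param profile A normalized `pssm_profile`.
#' @param record The matching [protein_record()] (sequence length must equal
#'   the profile length).
#' @return A `feature_vector` of dimension 400.
#' @export
encode_pssm_composition <- function(profile, record) {
  p <- .norm_matrix(profile)
  .check_profile(profile, record$sequence)
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  L <- nrow(p)
  M <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (g in seq_along(AA_ALPHABET)) {
    rows <- which(chars == AA_ALPHABET[g])
    if (length(rows) > 0L) {
      M[g, ] <- colSums(p[rows, , drop = FALSE]) / L
    }
  }
  v <- as.vector(t(M))
  names(v) <- paste0("comp.", rep(AA_ALPHABET, each = 20L), ".",
                     rep(AA_ALPHABET, times = 20L))
  .new_feature_vector("PSSM_COMP", v)
}

#' Dipeptide composition of a profile (DPC-PSSM)
#'
#' Captures local order in the profile: component (i, j) is
#' `(1/(L-1)) * sum_{k=1}^{L-1} p[k, i] * p[k+1, j]`, flattened row-wise
#' (i varying slowest) into a 400-dimensional vector.
#'
#' @param profile A normalized `pssm_profile` with L >= 2.
#' @return A `feature_vector` of dimension 400.
#' @export
encode_dpc_pssm <- function(profile) {
  p <- .norm_matrix(profile)
  L <- nrow(p)
  if (L < 2L) {
    stop("DPC-PSSM is undefined for a single-row profile ('",
         profile$protein_id, "')", call. = FALSE)
  }
  Y <- crossprod(p[-L, , drop = FALSE], p[-1L, , drop = FALSE]) / (L - 1)
  v <- as.vector(t(Y))
  names(v) <- paste0("dpc_pssm.", rep(AA_ALPHABET, each = 20L), ".",
                     rep(AA_ALPHABET, times = 20L))
  .new_feature_vector("DPC_PSSM", v)
}

#' Combined composition and dipeptide profile encoding (AADP-PSSM)
#'
#' Concatenation of [encode_aac_pssm()] and [encode_dpc_pssm()];
#' 20 + 400 = 420 components.
#'
#' @inheritParams encode_dpc_pssm
#' @return A `feature_vector` of dimension 420.
#' @export
encode_aadp_pssm <- function(profile) {
  v <- c(encode_aac_pssm(profile)$values, encode_dpc_pssm(profile)$values)
  .new_feature_vector("AADP_PSSM", v)
}

#' Evolutionary-difference profile encoding (MEDP)
#'
#' Combines a 20x20 evolutionary-difference dipeptide matrix (EEDP) with its
#' row-average (EDP). The adopted EEDP transform is
#' `EEDP[i, j] = (1/(L-2)) * sum_{k=2}^{L-1} ((p[k-1, i] - p[k+1, j]) / 2)^2`,
#' i.e. squared half-differences between the profile columns one position
#' before and one after each interior position; `EDP[j]` averages EEDP over
#' its 20 rows. The vector is `[EEDP flattened row-wise, EDP]`,
#' 400 + 20 = 420 components. The transform is isolated here so an
#' alternative difference kernel can be swapped in.
#'
#' @param profile A normalized `pssm_profile` with L >= 3.
#' @return A `feature_vector` of dimension 420.
#' @export
encode_medp <- function(profile) {
  p <- .norm_matrix(profile)
  L <- nrow(p)
  if (L < 3L) {
    stop("MEDP requires L >= 3 (profile '", profile$protein_id, "' has L = ",
         L, ")", call. = FALSE)
  }
  A <- p[1:(L - 2L), , drop = FALSE]   # rows k-1, k = 2..L-1
  B <- p[3:L, , drop = FALSE]          # rows k+1
  # sum_k (A[k,i] - B[k,j])^2 expanded to avoid an explicit i,j,k loop
  S <- outer(colSums(A^2), rep(1, 20L)) + outer(rep(1, 20L), colSums(B^2)) -
    2 * crossprod(A, B)
  EEDP <- S / (4 * (L - 2L))
  EDP <- colMeans(EEDP)
  v <- c(as.vector(t(EEDP)), EDP)
  names(v) <- c(paste0("eedp.", rep(AA_ALPHABET, each = 20L), ".",
                       rep(AA_ALPHABET, times = 20L)),
                paste0("edp.", AA_ALPHABET))
  .new_feature_vector("MEDP", v)
}

# ---------------------------------------------------------------------------
# sequence-based comparison encoders

.seq_chars <- function(record) strsplit(record$sequence, "", fixed = TRUE)[[1L]]

#' Amino-acid composition (AAC)
#'
#' Frequency of each canonical residue, `count / L`. Noncanonical residues
#' contribute zero (the 20 entries then sum to less than 1).
#'
#' @param record A [protein_record()].
#' @return A `feature_vector` of dimension 20.
#' @export
encode_aac <- function(record) {
  chars <- .seq_chars(record)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  v <- as.numeric(counts) / length(chars)
  names(v) <- paste0("aac.", AA_ALPHABET)
  .new_feature_vector("AAC", v)
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 canonical dipeptides in a sliding window,
#' `count / (L - 1)`. Dipeptides containing a noncanonical residue contribute
#' zero.
#'
#' @param record A [protein_record()] with L >= 2.
#' @return A `feature_vector` of dimension 400.
#' @export
encode_dpc <- function(record) {
  chars <- .seq_chars(record)
  L <- length(chars)
  if (L < 2L) {
    stop("DPC is undefined for a single-residue sequence ('", record$id, "')",
         call. = FALSE)
  }
  first <- factor(chars[-L], levels = AA_ALPHABET)
  second <- factor(chars[-1L], levels = AA_ALPHABET)
  counts <- table(first, second)
  v <- as.vector(t(counts)) / (L - 1)
  names(v) <- paste0("dpc.", rep(AA_ALPHABET, each = 20L),
                     rep(AA_ALPHABET, times = 20L))
  .new_feature_vector("DPC", v)
}

#' Quasi-sequence-order descriptor (QSOrder)
#'
#' Computes the quasi-sequence-order descriptor twice, once per residue
#' distance matrix (by default the synthetic surrogate physicochemical matrix
#' and the Grantham chemical distance matrix). For each matrix `d`, the
#' coupling terms are `tau_l = sum_{k=1}^{L-l} d(R_k, R_{k+l})^2` for
#' `l = 1..nlag`, and the descriptor is `f_r / (sum(f) + w * sum(tau))` for
#' the 20 residue counts `f_r` followed by `w * tau_l / (sum(f) + w *
#' sum(tau))`. Pairs involving noncanonical residues contribute zero.
#' Dimension `2 * (20 + nlag)`.
#'
#' @param record A [protein_record()] with L > `nlag`.
#' @param nlag Maximum coupling lag (default 30).
#' @param w Weighting factor for the coupling terms (default 0.1).
#' @param dmat1,dmat2 20x20 residue distance matrices in [AA_ALPHABET] order.
#' @return A `feature_vector` of dimension `2 * (20 + nlag)`.
#' @export
encode_qsorder <- function(record, nlag = 30L, w = 0.1,
                           dmat1 = physchem_surrogate_matrix(),
                           dmat2 = grantham_matrix()) {
  chars <- .seq_chars(record)
  L <- length(chars)
  if (L <= nlag) {
    stop("QSOrder needs sequence length > nlag; '", record$id, "' has L = ",
         L, " <= nlag = ", nlag, "; use a smaller nlag", call. = FALSE)
  }
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET)))
  idx <- match(chars, AA_ALPHABET)  # NA for noncanonical
  one_matrix <- function(d, tag) {
    tau <- vapply(seq_len(nlag), function(l) {
      a <- idx[1:(L - l)]
      b <- idx[(1 + l):L]
      ok <- !is.na(a) & !is.na(b)
      sum(d[cbind(a[ok], b[ok])]^2)
    }, numeric(1))
    denom <- sum(f) + w * sum(tau)
    v <- c(f / denom, w * tau / denom)
    names(v) <- c(paste0("qso.", tag, ".comp.", AA_ALPHABET),
                  paste0("qso.", tag, ".tau.", seq_len(nlag)))
    v
  }
  v <- c(one_matrix(dmat1, "d1"), one_matrix(dmat2, "d2"))
  .new_feature_vector("QSORDER", v)
}

#' Pseudo amino-acid composition (PAAC)
#'
#' The classic pseudo amino-acid composition using three standardized
#' property scales (hydrophobicity, Hopp-Woods hydrophilicity, side-chain
#' mass). The sequence-order correlation of two residues is the mean squared
#' difference of their standardized property values; `theta_l` averages that
#' correlation over all pairs at lag `l = 1..lambda`. The descriptor is
#' `f_u / (sum(f) + w * sum(theta))` for the 20 residue frequencies followed
#' by `w * theta_l / (sum(f) + w * sum(theta))`. Pairs involving noncanonical
#' residues contribute zero. Dimension `20 + lambda`.
#'
#' @param record A [protein_record()] with L > `lambda`.
#' @param lambda Maximum correlation tier (default 30).
#' @param w Weighting factor (default 0.05).
#' @return A `feature_vector` of dimension `20 + lambda`.
#' @export
encode_paac <- function(record, lambda = 30L, w = 0.05) {
  chars <- .seq_chars(record)
  L <- length(chars)
  if (L <= lambda) {
    stop("PAAC needs sequence length > lambda; '", record$id, "' has L = ",
         L, " <= lambda = ", lambda, call. = FALSE)
  }
  scales <- .paac_standardized_scales()
  idx <- match(chars, AA_ALPHABET)
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  theta <- vapply(seq_len(lambda), function(l) {
    a <- idx[1:(L - l)]
    b <- idx[(1 + l):L]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(0)
    corr <- (scales$hydrophobicity[a[ok]] - scales$hydrophobicity[b[ok]])^2 +
      (scales$hydrophilicity[a[ok]] - scales$hydrophilicity[b[ok]])^2 +
      (scales$sidechain_mass[a[ok]] - scales$sidechain_mass[b[ok]])^2
    sum(corr / 3) / (L - l)
  }, numeric(1))
  denom <- sum(f) + w * sum(theta)
  v <- c(f / denom, w * theta / denom)
  names(v) <- c(paste0("paac.f.", AA_ALPHABET),
                paste0("paac.theta.", seq_len(lambda)))
  .new_feature_vector("PAAC", v)
}

# ---------------------------------------------------------------------------

#' Encode one protein under a named encoder
#'
#' Dispatcher used by the batch and ensemble layers. Profile-based encoders
#' require `profile`; sequence-based encoders require only `record`.
#'
#' @param encoder_id One of [EVOLUTIONARY_ENCODERS] or [COMPARISON_ENCODERS].
#' @param record A [protein_record()].
#' @param profile A `pssm_profile` (needed for the profile-based encoders).
#' @param ... Passed to the encoder (e.g. `nlag`, `lambda`, `w`).
#' @return A `feature_vector`.
#' @export
encode_protein <- function(encoder_id, record, profile = NULL, ...) {
  encoder_id <- match.arg(encoder_id,
                          c(EVOLUTIONARY_ENCODERS, COMPARISON_ENCODERS))
  needs_profile <- encoder_id %in% EVOLUTIONARY_ENCODERS
  if (needs_profile && is.null(profile)) {
    stop("encoder ", encoder_id, " requires a PSSM profile for protein '",
         record$id, "'", call. = FALSE)
  }
  switch(encoder_id,
         AAC_PSSM = encode_aac_pssm(profile),
         PSSM_COMP = encode_pssm_composition(profile, record),
         DPC_PSSM = encode_dpc_pssm(profile),
         AADP_PSSM = encode_aadp_pssm(profile),
         MEDP = encode_medp(profile),
         AAC = encode_aac(record),
         DPC = encode_dpc(record),
         QSORDER = encode_qsorder(record, ...),
         PAAC = encode_paac(record, ...))
}

#' Declared encoder dimensions
#'
#' @param nlag,lambda Parameters entering the QSOrder / PAAC dimensions.
#' @return Named integer vector of output dimensions per encoder.
#' @export
encoder_dims <- function(nlag = 30L, lambda = 30L) {
  c(AAC_PSSM = 20L, PSSM_COMP = 400L, DPC_PSSM = 400L, AADP_PSSM = 420L,
    MEDP = 420L, AAC = 20L, DPC = 400L, QSORDER = 2L * (20L + nlag),
    PAAC = 20L + lambda)
}

#' Feature table for a set of proteins
#'
#' @param records List of [protein_record()] objects.
#' @param profiles Named list of `pssm_profile` objects keyed by protein id
#'   (may be `NULL` for sequence-only encoders).
#' @param encoder_id Encoder name.
#' @param ... Passed to the encoder.
#' @return Numeric matrix, one row per protein (rownames = ids), one column
#'   per named feature component.
#' @export
encode_feature_matrix <- function(records, profiles = NULL, encoder_id, ...) {
  rows <- lapply(records, function(rec) {
    fv <- tryCatch(
      encode_protein(encoder_id, rec, profile = profiles[[rec$id]], ...),
      error = function(e) {
        stop("feature computation failed for protein '", rec$id,
             "' under encoder ", encoder_id, ": ", conditionMessage(e),
             call. = FALSE)
      })
    fv$values
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(records, `[[`, character(1), "id")
  m
}

#' Write a feature table as TSV
#'
#' Header row: `id` followed by the encoder's named components. One row per
#' protein, full precision.
#'
#' @param features Matrix from [encode_feature_matrix()] (or several bound
#'   column-wise).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
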