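# Synthetic sequence/profile generator. Emulates what the predictor consumes
# in the wild: variable-length protein sequences, matching L x 20 integer
# log-odds profiles, and a tunable class signal injected into designated
# profile columns of the positive class. Because all five ensemble features
# are profile-derived, the class signal lives at the profile level.

#' Specification for a synthetic labeled dataset
#'
#' Defaults define the package's reference study conditions: 60 positives vs
#' 170 negatives (imbalance ratio 2.83, within the 1.5-3 range typical of
#' virion:nonvirion proportions), lengths uniform on 50-150 residues,
#' integer log-odds noise with standard deviation 2, and a class shift
#' `delta` added to four designated profile columns of the positives
#' (`delta = 6`, i.e. three noise standard deviations, gives a cleanly
#' separable regime; `delta = 0` gives an exact null).
#'
#' @param n_pos,n_neg Class sizes (nonnegative).
#' @param length_range Integer interval of sequence lengths (min >= 3).
#' @param delta Nonnegative shift applied to `signal_cols` of positive
#'   profiles before rounding.
#' @param noise_sd Standard deviation of the centered Gaussian noise from
#'   which raw scores are drawn (then rounded to integers).
#' @param signal_cols Indices (in [AA_ALPHABET] order) of the shifted
#'   columns.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param id_prefix Prefix for generated protein ids, so independently drawn
#'   datasets (e.g. a training set and a held-out test set) have disjoint id
#'   namespaces.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_pos = 60L, n_neg = 170L, length_range = c(50L, 150L),
                       delta = 6, noise_sd = 2, signal_cols = 1:4,
                       seed = 1L, id_prefix = "") {
  stopifnot(n_pos >= 0L, n_neg >= 0L,
            length(length_range) == 2L, length_range[1] >= 3L,
            length_range[1] <= length_range[2],
            delta >= 0, noise_sd > 0,
            all(signal_cols %in% 1:20))
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range), delta = delta,
                 noise_sd = noise_sd, signal_cols = as.integer(signal_cols),
                 seed = as.integer(seed), id_prefix = id_prefix),
            class = "synth_spec")
}

.random_sequence <- function(L) {
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

.synth_profile <- function(id, sequence, delta, noise_sd, signal_cols,
                           positive) {
  L <- nchar(sequence)
  raw <- matrix(stats::rnorm(L * 20L, 0, noise_sd), L, 20L)
  if (positive && delta > 0) {
    raw[, signal_cols] <- raw[, signal_cols] + delta
  }
  raw <- round(raw)  # fixtures look like genuine integer log-odds files
  prof <- .new_pssm_profile(id, raw, sequence = sequence)
  normalize_pssm(prof)
}

#' Generate a synthetic labeled dataset
#'
#' Sequences are i.i.d. uniform over the 20 canonical residues; raw profile
#' scores are rounded centered Gaussian draws, with `delta` added to the
#' designated columns of positives before rounding. When `dir` is given the
#' dataset is also written to disk (`pos.fasta`, `neg.fasta`,
#' `pssm/<id>.pssm`, `truth.tsv`) so the I/O layer can be exercised
#' end-to-end.
#'
#' @param spec A [synth_spec()].
#' @param dir Optional output directory.
#' @return A `labeled_dataset` (profiles normalized with the sigmoid map).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  make_class <- function(n, prefix, positive) {
    lapply(seq_len(n), function(i) {
      id <- sprintf("%s%s_%03d", spec$id_prefix, prefix, i)
      L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
      sequence <- .random_sequence(L)
      prof <- .synth_profile(id, sequence, spec$delta, spec$noise_sd,
                             spec$signal_cols, positive)
      list(record = protein_record(id, sequence,
                                   label = if (positive) "virion" else "nonvirion"),
           profile = prof)
    })
  }
  pos <- make_class(spec$n_pos, "pos", TRUE)
  neg <- make_class(spec$n_neg, "neg", FALSE)
  both <- c(pos, neg)
  records <- lapply(both, `[[`, "record")
  profiles <- lapply(both, `[[`, "profile")
  names(profiles) <- vapply(records, `[[`, character(1), "id")
  ds <- .new_labeled_dataset(records, profiles)
  if (!is.null(dir)) write_dataset_files(ds, dir)
  ds
}

#' Write a labeled dataset as FASTA + ASCII PSSM files + truth table
#'
#' Emits `pos.fasta`, `neg.fasta`, one `pssm/<id>.pssm` per protein, and
#' `truth.tsv` (columns `id`, `label`).
#'
#' @param ds A `labeled_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset_files <- function(ds, dir) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  labels <- .dataset_labels(ds)
  write_fasta(ds$records[labels == "virion"], file.path(dir, "pos.fasta"))
  write_fasta(ds$records[labels == "nonvirion"], file.path(dir, "neg.fasta"))
  for (rec in ds$records) {
    prof <- ds$profiles[[rec$id]]
    if (!is.null(prof)) {
      write_ascii_pssm(prof, file.path(dir, "pssm", paste0(rec$id, ".pssm")))
    }
  }
  utils::write.table(data.frame(id = .dataset_ids(ds), label = labels),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Generate a structured profile fixture
#'
#' Small profiles with known structure for tests: `zero` (all raw scores 0,
#' normalized entries all 0.5), `constant` (all raw scores equal to `value`),
#' `onehot` (normalized matrix set directly to one-hot rows -- a constructed
#' test profile whose raw scores are large +/- stand-ins), or `random`
#' (rounded Gaussian scores). When `path` is given, a valid ASCII PSSM
#' rendering is written alongside.
#'
#' @param L Number of rows (>= 1).
#' @param mode One of `"zero"`, `"constant"`, `"onehot"`, `"random"`.
#' @param seed Seed for `random` mode and the fixture sequence.
#' @param value Raw score used by `constant` mode.
#' @param hot Residue indices (length L, recycled) carrying the 1 in
#'   `onehot` mode.
#' @param path Optional ASCII PSSM output path.
#' @return A normalized `pssm_profile`.
#' @export
generate_pssm_fixture <- function(L, mode = c("zero", "constant", "onehot",
                                              "random"),
                                  seed = 1L, value = 2L, hot = NULL,
                                  path = NULL) {
  stopifnot(L >= 1L)
  mode <- match.arg(mode)
  set.seed(seed)
  sequence <- .random_sequence(L)
  raw <- switch(mode,
                zero = matrix(0L, L, 20L),
                constant = matrix(as.integer(value), L, 20L),
                onehot = matrix(-20L, L, 20L),
                random = matrix(as.integer(round(stats::rnorm(L * 20L, 0, 3))),
                                L, 20L))
  if (mode == "onehot") {
    if (is.null(hot)) hot <- rep_len(seq_len(20L), L)
    hot <- rep_len(hot, L)
    raw[cbind(seq_len(L), hot)] <- 20L
  }
  prof <- .new_pssm_profile(sprintf("fixture_%s_L%d", mode, L), raw,
                            sequence = sequence)
  prof <- normalize_pssm(prof)
  if (mode == "onehot") {
    norm <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
    norm[cbind(seq_len(L), hot)] <- 1
    prof$norm <- norm  # exact one-hot, bypassing the sigmoid
  }
  if (!is.null(path)) write_ascii_pssm(prof, path)
  prof
}
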