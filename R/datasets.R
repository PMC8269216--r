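# Labeled dataset assembly, majority-class undersampling into balanced
# subsets, and redundancy reduction of sequence collections.

.new_labeled_dataset <- function(records, profiles, missing_profiles = character(0)) {
  labels <- vapply(records, `[[`, character(1), "label")
  structure(list(records = records,
                 profiles = profiles,
                 n_pos = sum(labels == "virion"),
                 n_neg = sum(labels == "nonvirion"),
                 missing_profiles = missing_profiles),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d virion + %d nonvirion (%d profiles%s)\n",
              x$n_pos, x$n_neg, length(x$profiles),
              if (length(x$missing_profiles))
                sprintf(", %d missing", length(x$missing_profiles)) else ""))
  invisible(x)
}

.dataset_ids <- function(ds) vapply(ds$records, `[[`, character(1), "id")
.dataset_labels <- function(ds) vapply(ds$records, `[[`, character(1), "label")

#' Assemble a labeled dataset from FASTA files and a profile directory
#'
#' Reads positive (virion) and negative (nonvirion) FASTA files, attaches the
#' per-protein ASCII PSSM `<id>.pssm` from `pssm_dir`, normalizes profiles,
#' and cross-checks each profile length against its sequence. Proteins
#' lacking a profile file are kept and listed in `missing_profiles`; an id
#' appearing in both classes is an error.
#'
#' @param pos_fasta,neg_fasta FASTA paths for the two classes.
#' @param pssm_dir Directory of ASCII PSSM files named `<protein id>.pssm`
#'   (`NULL` to skip profile attachment).
#' @param normalize_method Passed to [normalize_pssm()].
#' @param strict Reject noncanonical residues at read time.
#' @return A `labeled_dataset` with fields `records`, `profiles` (named
#'   list), `n_pos`, `n_neg`, `missing_profiles`.
#' @export
build_dataset <- function(pos_fasta, neg_fasta, pssm_dir = NULL,
                          normalize_method = "sigmoid", strict = FALSE) {
  pos <- read_fasta(pos_fasta, label = "virion", strict = strict)
  neg <- read_fasta(neg_fasta, label = "nonvirion", strict = strict)
  pos_ids <- vapply(pos, `[[`, character(1), "id")
  neg_ids <- vapply(neg, `[[`, character(1), "id")
  clash <- intersect(pos_ids, neg_ids)
  if (length(clash) > 0L) {
    stop("label conflict: id(s) present in both classes: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  records <- c(pos, neg)
  profiles <- list()
  missing <- character(0)
  if (!is.null(pssm_dir)) {
    for (rec in records) {
      path <- file.path(pssm_dir, paste0(rec$id, ".pssm"))
      if (!file.exists(path)) {
        missing <- c(missing, rec$id)
        next
      }
      prof <- normalize_pssm(parse_ascii_pssm(path, protein_id = rec$id),
                             method = normalize_method)
      .check_profile(prof, rec$sequence)
      if (!identical(prof$sequence, rec$sequence)) {
        warning("profile residues differ from the FASTA sequence for '",
                rec$id, "'", call. = FALSE)
      }
      profiles[[rec$id]] <- prof
    }
  }
  ds <- .new_labeled_dataset(records, profiles, missing)
  ratio <- if (ds$n_pos > 0) ds$n_neg / ds$n_pos else NA_real_
  if (is.finite(ratio) && (ratio < 1.5 || ratio > 3)) {
    warning(sprintf(
      "negative:positive ratio %.2f is outside the 1.5-3 range typical of ",
      ratio), "virion/nonvirion proportions in a phage genome", call. = FALSE)
  }
  ds
}

#' Restrict a dataset to a subset of protein ids
#'
#' @param ds A `labeled_dataset`.
#' @param ids Character vector of ids to keep (order respected).
#' @return A `labeled_dataset`.
#' @export
subset_dataset <- function(ds, ids) {
  all_ids <- .dataset_ids(ds)
  miss <- setdiff(ids, all_ids)
  if (length(miss) > 0L) {
    stop("unknown protein id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- ds$records[match(ids, all_ids)]
  .new_labeled_dataset(records, ds$profiles[intersect(ids, names(ds$profiles))],
                       intersect(ds$missing_profiles, ids))
}

#' Undersample the majority class into balanced subsets
#'
#' Each subset combines all positives with an equal number of negatives drawn
#' without replacement; draws are independent across subsets (subsets may
#' share negatives). One top-level seed determines everything: subset `i`
#' draws with the derived seed `seed + i`, so membership is reproducible
#' bit-for-bit from a single integer.
#'
#' @param ds A `labeled_dataset` with `n_neg >= n_pos >= 1`.
#' @param n_subsets Number of balanced subsets (default 5).
#' @param seed Integer seed.
#' @return List of `balanced_subset` objects with fields `pos_ids`,
#'   `neg_ids`, `seed`.
#' @export
undersample_subsets <- function(ds, n_subsets = 5L, seed = 1L) {
  if (ds$n_pos < 1L) stop("undersampling needs at least one positive",
                          call. = FALSE)
  if (ds$n_neg < ds$n_pos) {
    stop("undersampling impossible: ", ds$n_neg, " negatives < ", ds$n_pos,
         " positives", call. = FALSE)
  }
  ids <- .dataset_ids(ds)
  labels <- .dataset_labels(ds)
  pos_ids <- ids[labels == "virion"]
  neg_ids <- ids[labels == "nonvirion"]
  lapply(seq_len(n_subsets), function(i) {
    sub_seed <- as.integer(seed) + i
    set.seed(sub_seed)
    draw <- sample(neg_ids, length(pos_ids), replace = FALSE)
    structure(list(pos_ids = pos_ids, neg_ids = draw, seed = sub_seed),
              class = "balanced_subset")
  })
}

#' @export
print.balanced_subset <- function(x, ...) {
  cat(sprintf("<balanced_subset> %d + %d (seed %d)\n", length(x$pos_ids),
              length(x$neg_ids), x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch alignment (BLOSUM62, gap open 10, extend 0.5) with
#' identity defined as matches divided by the shorter sequence length, the
#' convention of greedy clustering tools.
#'
#' @param a,b Amino-acid sequences (strings).
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .blosum62(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# cached BLOSUM62 substitution matrix from Biostrings
.blosum62 <- function() {
  if (is.null(.virionpred_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .virionpred_env$blosum62 <- get("BLOSUM62", envir = e)
  }
  .virionpred_env$blosum62
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Internal greedy incremental clustering in the style of CD-HIT: sequences
#' are sorted longest-first (ties broken by input order) and each is compared
#' against the current cluster representatives; a sequence joins the first
#' representative with identity at or above `threshold`, otherwise it founds
#' a new cluster. Returns the representatives in input order. Deterministic
#' for a fixed input order. When the external `cd-hit` binary is requested it
#' is invoked instead (results are not guaranteed identical to the internal
#' clustering, which uses exhaustive global alignment rather than word
#' filtering).
#'
#' @param records List of [protein_record()] objects.
#' @param threshold Identity cutoff in (0, 1\] (default 0.4).
#' @param backend `"internal"` (default) or `"cdhit"`.
#' @return List of representative [protein_record()] objects.
#' @export
redundancy_reduce <- function(records, threshold = 0.4,
                              backend = c("internal", "cdhit")) {
  stopifnot(threshold > 0, threshold <= 1)
  backend <- match.arg(backend)
  if (length(records) == 0L) return(list())
  if (backend == "cdhit") return(.redundancy_reduce_cdhit(records, threshold))
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  ord <- order(-lens, seq_along(records))
  reps <- list()
  for (k in ord) {
    rec <- records[[k]]
    hit <- FALSE
    for (rep_rec in reps) {
      if (sequence_identity(rec$sequence, rep_rec$sequence) >= threshold) {
        hit <- TRUE
        break
      }
    }
    if (!hit) reps[[length(reps) + 1L]] <- rec
  }
  rep_ids <- vapply(reps, `[[`, character(1), "id")
  ids <- vapply(records, `[[`, character(1), "id")
  records[ids %in% rep_ids]
}

.redundancy_reduce_cdhit <- function(records, threshold) {
  exe <- Sys.which("cd-hit")
  if (!nzchar(exe)) {
    stop("backend 'cdhit' requested but the cd-hit executable is not on ",
         "PATH; use backend = 'internal' or install CD-HIT", call. = FALSE)
  }
  dir <- tempfile("cdhit")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fin <- file.path(dir, "in.fasta")
  fout <- file.path(dir, "out.fasta")
  write_fasta(records, fin)
  # word size must shrink with the threshold; 2 is the documented choice
  # for thresholds in [0.4, 0.5)
  n_word <- if (threshold >= 0.7) 5L else if (threshold >= 0.6) 4L
            else if (threshold >= 0.5) 3L else 2L
  status <- system2(exe, c("-i", fin, "-o", fout, "-c", threshold,
                           "-n", n_word), stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) {
    stop("cd-hit failed with status ", status, call. = FALSE)
  }
  kept <- vapply(read_fasta(fout), `[[`, character(1), "id")
  ids <- vapply(records, `[[`, character(1), "id")
  records[ids %in% kept]
}
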