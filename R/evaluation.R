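# Performance metrics, the repeated cross-validation and independent-test
# protocols, and the sequence-similarity (BLAST hit) baseline classifier.

#' Confusion counts for binary virion/nonvirion calls
#'
#' @param truth,calls Character vectors of `"virion"`/`"nonvirion"` labels.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, calls) {
  stopifnot(length(truth) == length(calls))
  structure(list(TP = sum(truth == "virion" & calls == "virion"),
                 FP = sum(truth == "nonvirion" & calls == "virion"),
                 TN = sum(truth == "nonvirion" & calls == "nonvirion"),
                 FN = sum(truth == "virion" & calls == "nonvirion")),
            class = "confusion_counts")
}

#' Binary classification metrics from confusion counts
#'
#' Computes the five standard metrics: sensitivity `SN = TP/(TP+FN)`,
#' specificity `SP = TN/(TN+FP)`, accuracy `ACC = (TP+TN)/total`, F-value
#' (harmonic mean of precision `TP/(TP+FP)` and sensitivity), and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; plus the
#' false-positive rate `FPR = FP/(FP+TN)` (the complement of specificity).
#' Any metric with a zero denominator is reported as 0 and flagged in
#' `degenerate`.
#'
#' @param counts A `confusion_counts` (or list with `TP`, `FP`, `TN`, `FN`).
#' @return A `metrics_report` list: `SN`, `SP`, `ACC`, `F`, `MCC`, `FPR`,
#'   `counts`, `degenerate` (character vector of flagged metrics).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  total <- TP + FP + TN + FN
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  SN <- safe(TP, TP + FN, "SN")
  SP <- safe(TN, TN + FP, "SP")
  ACC <- (TP + TN) / total
  precision <- safe(TP, TP + FP, "precision")
  Fv <- if (precision + SN == 0) {
    degenerate <- c(degenerate, "F"); 0
  } else 2 * precision * SN / (precision + SN)
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  MCC <- if (mcc_den == 0) {
    degenerate <- c(degenerate, "MCC"); 0
  } else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  FPR <- safe(FP, FP + TN, "FPR")
  structure(list(SN = SN, SP = SP, ACC = ACC, F = Fv, MCC = MCC, FPR = FPR,
                 counts = counts, degenerate = unique(degenerate)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3L, ...) {
  # three decimals is the conventional reporting precision; full precision
  # is retained in the object
  cat(sprintf("SN = %.*f  SP = %.*f  ACC = %.*f  F = %.*f  MCC = %.*f\n",
              digits, x$SN, digits, x$SP, digits, x$ACC, digits, x$F,
              digits, x$MCC))
  cat(sprintf("TP = %d  FP = %d  TN = %d  FN = %d  (FPR = %.*f)\n",
              x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN,
              digits, x$FPR))
  if (length(x$degenerate)) {
    cat("degenerate (zero-denominator) metrics:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

# mean +/- sd across a list of metrics_report objects
.aggregate_reports <- function(reports) {
  keys <- c("SN", "SP", "ACC", "F", "MCC", "FPR")
  m <- sapply(keys, function(k) vapply(reports, `[[`, numeric(1), k))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, keys))
  list(mean = colMeans(m), sd = apply(m, 2L, stats::sd))
}

#' Repeated fivefold cross-validation on the balanced training sets
#'
#' Draws the five balanced subsets, then runs a stratified fivefold
#' cross-validation within each: on the training folds one grid-searched,
#' Platt-calibrated SVM is fitted per evolutionary feature, the test-fold
#' feature scores are averaged into the final score, and calls are made at
#' `threshold`. Each balanced set yields one metrics report from its pooled
#' out-of-fold predictions; the final result averages the five reports and
#' reports their standard deviations.
#'
#' @param ds A `labeled_dataset` with profiles.
#' @param seed Integer seed (subsets, folds and calibration).
#' @param encoders Feature encodings to integrate.
#' @param n_subsets Balanced subsets (default 5).
#' @param folds Cross-validation folds within each balanced set (default 5).
#' @param exponents Grid-search exponent range.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `mean`, `sd` (named metric vectors), `per_subset`
#'   (list of `metrics_report`), `n_subsets`, `folds`.
#' @export
fivefold_cv <- function(ds, seed = 1L, encoders = EVOLUTIONARY_ENCODERS,
                        n_subsets = 5L, folds = 5L, exponents = -10:10,
                        threshold = 0.5) {
  subsets <- undersample_subsets(ds, n_subsets = n_subsets, seed = seed)
  feature_cache <- lapply(encoders, function(enc) {
    encode_feature_matrix(ds$records, ds$profiles, enc)
  })
  names(feature_cache) <- encoders

  per_subset <- lapply(seq_along(subsets), function(b) {
    sub <- subsets[[b]]
    ids <- c(sub$pos_ids, sub$neg_ids)
    y <- .as_label_factor(c(rep("virion", length(sub$pos_ids)),
                            rep("nonvirion", length(sub$neg_ids))))
    fold_id <- .stratified_folds(y, folds, seed + 100L * b)
    score <- rep(NA_real_, length(ids))
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      enc_scores <- vapply(encoders, function(enc) {
        x <- feature_cache[[enc]][ids, , drop = FALSE]
        member <- .fit_member(x[tr, , drop = FALSE], y[tr], exponents,
                              folds, seed + 100L * b + f)
        .member_score(member, x[te, , drop = FALSE])
      }, numeric(length(te)))
      if (is.null(dim(enc_scores))) {
        enc_scores <- matrix(enc_scores, nrow = 1L)
      }
      score[te] <- rowMeans(enc_scores)
    }
    calls <- ifelse(score >= threshold, "virion", "nonvirion")
    compute_metrics(confusion_counts(as.character(y), calls))
  })
  agg <- .aggregate_reports(per_subset)
  list(mean = agg$mean, sd = agg$sd, per_subset = per_subset,
       n_subsets = n_subsets, folds = folds)
}

#' Evaluate a trained model on an independent test set
#'
#' Verifies that the test ids are disjoint from the training ids (data
#' leakage guard), predicts every test protein in a single pass, and returns
#' the metrics plus the per-protein score table.
#'
#' @param model A `virion_ensemble`.
#' @param test A `labeled_dataset` with profiles and labels.
#' @param threshold Override the model's threshold.
#' @return List with `metrics` (a `metrics_report`) and `scores` (the
#'   [predict.virion_ensemble()] table plus a `label` column).
#' @export
independent_test <- function(model, test, threshold = model$threshold) {
  overlap <- intersect(model$train_ids, .dataset_ids(test))
  if (length(overlap) > 0L) {
    stop("data leakage: test id(s) also present in training: ",
         paste(utils::head(overlap, 10L), collapse = ", "),
         if (length(overlap) > 10L) ", ..." else "", call. = FALSE)
  }
  scores <- predict(model, test, threshold = threshold)
  scores$label <- .dataset_labels(test)
  ok <- !is.na(scores$call)
  metrics <- compute_metrics(confusion_counts(scores$label[ok],
                                              scores$call[ok]))
  list(metrics = metrics, scores = scores)
}

# ---------------------------------------------------------------------------
# BLAST-hit baseline classifier

# Karlin-Altschul parameters for gapped BLOSUM62 (open 11, extend 1); used by
# the internal alignment backend's E-value approximation.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Sequence-similarity baseline classifier
#'
#' Predicts a query as virion iff it has at least one hit against the
#' positive (virion) training sequences with E-value at or below
#' `evalue_cutoff` (default 0.01). Backend `"blast"` formats the positives as
#' a protein BLAST database and runs `blastp`; backend `"internal"` is a
#' clearly-labelled approximation using exhaustive Smith-Waterman local
#' alignments (BLOSUM62, gap open 11 / extend 1) with Karlin-Altschul
#' E-values `E = K * m * n * exp(-lambda * S)`. `"auto"` picks BLAST when
#' `blastp` and `makeblastdb` are on the PATH.
#'
#' @param queries List of [protein_record()] objects (or a single record).
#' @param positives List of positive-class [protein_record()] objects.
#' @param evalue_cutoff E-value threshold (default 0.01).
#' @param backend `"auto"`, `"blast"` or `"internal"`.
#' @return Data frame with columns `id`, `best_evalue`, `call`.
#' @export
blast_baseline <- function(queries, positives, evalue_cutoff = 0.01,
                           backend = c("auto", "blast", "internal")) {
  backend <- match.arg(backend)
  if (inherits(queries, "protein_record")) queries <- list(queries)
  if (length(positives) == 0L) {
    warning("empty positive set: every query is called nonvirion",
            call. = FALSE)
    return(data.frame(id = vapply(queries, `[[`, character(1), "id"),
                      best_evalue = Inf, call = "nonvirion",
                      stringsAsFactors = FALSE))
  }
  if (backend == "auto") {
    backend <- if (nzchar(Sys.which("blastp")) &&
                   nzchar(Sys.which("makeblastdb"))) "blast" else "internal"
  }
  best <- switch(backend,
                 blast = .blast_best_evalues(queries, positives),
                 internal = .internal_best_evalues(queries, positives))
  data.frame(id = vapply(queries, `[[`, character(1), "id"),
             best_evalue = best,
             call = ifelse(best <= evalue_cutoff, "virion", "nonvirion"),
             stringsAsFactors = FALSE)
}

.blast_best_evalues <- function(queries, positives) {
  for (exe in c("makeblastdb", "blastp")) {
    if (!nzchar(Sys.which(exe))) {
      stop("backend 'blast' requires '", exe, "' on the PATH; ",
           "use backend = 'internal'", call. = FALSE)
    }
  }
  dir <- tempfile("blastdb")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  db_fasta <- file.path(dir, "pos.fasta")
  q_fasta <- file.path(dir, "query.fasta")
  write_fasta(positives, db_fasta)
  write_fasta(queries, q_fasta)
  status <- system2("makeblastdb", c("-in", db_fasta, "-dbtype", "prot",
                                     "-out", file.path(dir, "db")),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("makeblastdb failed (status ", status, ")",
                         call. = FALSE)
  hits_file <- file.path(dir, "hits.tsv")
  status <- system2("blastp", c("-query", q_fasta, "-db", file.path(dir, "db"),
                                "-outfmt", "'6 qseqid sseqid evalue'",
                                "-evalue", "1000", "-out", hits_file),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastp failed (status ", status, ")", call. = FALSE)
  ids <- vapply(queries, `[[`, character(1), "id")
  best <- rep(Inf, length(ids))
  names(best) <- ids
  if (file.exists(hits_file) && file.size(hits_file) > 0) {
    hits <- utils::read.table(hits_file, sep = "\t", header = FALSE,
                              col.names = c("query", "subject", "evalue"),
                              stringsAsFactors = FALSE)
    agg <- tapply(hits$evalue, hits$query, min)
    best[names(agg)] <- pmin(best[names(agg)], agg)
  }
  unname(best)
}

.internal_best_evalues <- function(queries, positives) {
  db_len <- sum(vapply(positives, function(p) nchar(p$sequence), integer(1)))
  vapply(queries, function(q) {
    m <- nchar(q$sequence)
    best <- Inf
    for (p in positives) {
      s <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q$sequence), Biostrings::AAString(p$sequence),
        substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
        type = "local", scoreOnly = TRUE)
      e <- .KA_K * m * db_len * exp(-.KA_LAMBDA * s)
      best <- min(best, e)
    }
    best
  }, numeric(1))
}
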