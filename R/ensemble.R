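# RBF-SVM ensemble training and prediction. Per feature encoding, one SVM is
# trained on each balanced subset (cost/gamma grid-searched, scores Platt-
# calibrated to [0, 1]) and the member scores are averaged into a per-feature
# ensemble; the five per-feature ensembles are averaged into the final score,
# thresholded at 0.5.

MODEL_FORMAT_VERSION <- "virionpred-model/1"

.class_levels <- c("nonvirion", "virion")

.as_label_factor <- function(labels) factor(labels, levels = .class_levels)

# Stratified fold assignment; both classes appear in every fold. Deterministic
# given the seed (R's RNG only).
.stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  set.seed(seed)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < k) {
      stop("stratification error: class '", lev, "' has ", length(idx),
           " samples, fewer than ", k, " folds", call. = FALSE)
    }
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

.fit_rbf_svm <- function(x, y, cost, gamma) {
  suppressWarnings(e1071::svm(x, y, type = "C-classification",
                              kernel = "radial", cost = cost, gamma = gamma,
                              scale = TRUE))
}

# Decision values oriented so positive = "virion". libsvm orients the margin
# toward the first class label it encounters; the attribute column name
# ("a/b") records that orientation.
.decision_values <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv_mat <- attr(pr, "decision.values")
  dv <- as.numeric(dv_mat)
  first <- strsplit(colnames(dv_mat)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (first != "virion") dv <- -dv
  dv
}

#' Grid search for SVM cost and gamma
#'
#' Enumerates every `(cost, gamma) = (2^a, 2^b)` pair over the exponent grid
#' (default integers -10..10, i.e. 21 x 21 = 441 pairs) and scores each by
#' stratified `folds`-fold cross-validated accuracy on the given data; the
#' pair with the highest mean accuracy wins, ties resolved toward the
#' earliest pair in enumeration order (cost exponent varying slowest).
#' Deterministic given `seed`.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels (`"virion"`/`"nonvirion"`, factor or character).
#' @param exponents Integer exponents defining the grid (both parameters).
#' @param folds Internal cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `cost`, `gamma`, `cv_acc`, `n_evaluated` and the full
#'   accuracy `table` (data frame: cost_exp, gamma_exp, acc).
#' @export
grid_search_svm <- function(x, y, exponents = -10:10, folds = 5L, seed = 1L) {
  y <- .as_label_factor(as.character(y))
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("grid search needs samples from both classes", call. = FALSE)
  }
  fold_id <- .stratified_folds(y, folds, seed)
  splits <- lapply(seq_len(folds), function(f) {
    list(train = which(fold_id != f), test = which(fold_id == f))
  })
  grid <- expand.grid(gamma_exp = exponents, cost_exp = exponents,
                      KEEP.OUT.ATTRS = FALSE)[, c("cost_exp", "gamma_exp")]
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cost <- 2^grid$cost_exp[i]
    gamma <- 2^grid$gamma_exp[i]
    correct <- 0L
    for (sp in splits) {
      fit <- .fit_rbf_svm(x[sp$train, , drop = FALSE], y[sp$train],
                          cost, gamma)
      pred <- stats::predict(fit, x[sp$test, , drop = FALSE])
      correct <- correct + sum(pred == y[sp$test])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)  # first maximum = earliest pair in enumeration order
  list(cost = 2^grid$cost_exp[best], gamma = 2^grid$gamma_exp[best],
       cv_acc = acc[best], n_evaluated = nrow(grid),
       table = cbind(grid, acc = acc))
}

# Platt sigmoid calibration: fit P(virion | dv) = plogis(a + b * dv) on
# out-of-fold decision values with Platt's smoothed targets, so member scores
# are comparable across members and feature spaces.
.platt_fit <- function(dv, y) {
  pos <- y == "virion"
  t_pos <- (sum(pos) + 1) / (sum(pos) + 2)
  t_neg <- 1 / (sum(!pos) + 2)
  target <- ifelse(pos, t_pos, t_neg)
  fit <- tryCatch(
    suppressWarnings(stats::glm(target ~ dv,
                                family = stats::quasibinomial())),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    # degenerate decision values: constant score at the positive rate
    return(list(a = stats::qlogis(mean(pos)), b = 0))
  }
  co <- stats::coef(fit)
  list(a = unname(co[1L]), b = unname(co[2L]))
}

# Train one ensemble member on a balanced subset: grid search, out-of-fold
# Platt calibration, final refit on all subset data.
.fit_member <- function(x, y, exponents, folds, seed) {
  y <- .as_label_factor(as.character(y))
  gs <- grid_search_svm(x, y, exponents = exponents, folds = folds,
                        seed = seed)
  fold_id <- .stratified_folds(y, folds, seed + 1L)
  dv <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    fit_f <- .fit_rbf_svm(x[tr, , drop = FALSE], y[tr], gs$cost, gs$gamma)
    dv[te] <- .decision_values(fit_f, x[te, , drop = FALSE])
  }
  platt <- .platt_fit(dv, y)
  fit <- .fit_rbf_svm(x, y, gs$cost, gs$gamma)
  structure(list(fit = fit, platt = platt, cost = gs$cost, gamma = gs$gamma,
                 cv_acc = gs$cv_acc, seed = seed),
            class = "svm_member")
}

# Calibrated score in [0, 1] for one member.
.member_score <- function(member, x) {
  dv <- .decision_values(member$fit, x)
  stats::plogis(member$platt$a + member$platt$b * dv)
}

#' Train a per-feature ensemble on balanced subsets
#'
#' One calibrated SVM per balanced subset, each with its own grid search;
#' the ensemble score is the mean of the member scores.
#'
#' @param encoder_id One of [EVOLUTIONARY_ENCODERS] (or a comparison
#'   encoder).
#' @param subsets List of `balanced_subset` objects from
#'   [undersample_subsets()].
#' @param ds The `labeled_dataset` the subsets index into.
#' @param exponents Grid-search exponent range.
#' @param folds Internal cross-validation folds.
#' @param seed Base seed; member `i` uses `seed + 10 * i`.
#' @param features Optional precomputed feature matrix for all dataset
#'   records (rows keyed by id); computed when `NULL`.
#' @return A `baseline_ensemble` with `encoder_id` and `members`.
#' @export
train_baseline <- function(encoder_id, subsets, ds, exponents = -10:10,
                           folds = 5L, seed = 1L, features = NULL) {
  if (is.null(features)) {
    features <- encode_feature_matrix(ds$records, ds$profiles, encoder_id)
  }
  members <- lapply(seq_along(subsets), function(i) {
    sub <- subsets[[i]]
    ids <- c(sub$pos_ids, sub$neg_ids)
    y <- c(rep("virion", length(sub$pos_ids)),
           rep("nonvirion", length(sub$neg_ids)))
    .fit_member(features[ids, , drop = FALSE], y, exponents, folds,
                seed + 10L * i)
  })
  structure(list(encoder_id = encoder_id, members = members),
            class = "baseline_ensemble")
}

# Mean member score for a feature matrix.
.baseline_score <- function(baseline, x) {
  scores <- vapply(baseline$members, .member_score, numeric(nrow(x)), x = x)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  rowMeans(scores)
}

#' Train the full ensemble predictor
#'
#' Draws `n_subsets` balanced subsets once and trains one per-feature
#' ensemble per evolutionary encoder on those same subsets; the final score
#' of a protein is the unweighted mean of the per-feature ensemble scores,
#' called virion when it reaches `threshold`.
#'
#' @param ds A `labeled_dataset` with profiles for all records.
#' @param seed Integer seed governing subsets, folds and calibration.
#' @param encoders Encoders to integrate (default the five evolutionary
#'   encoders).
#' @param n_subsets Balanced subsets (default 5).
#' @param exponents Grid-search exponent range (default -10..10).
#' @param folds Internal cross-validation folds (default 5).
#' @param threshold Decision threshold on the final score (default 0.5,
#'   inclusive).
#' @return A `virion_ensemble` model object.
#' @export
train_virion_ensemble <- function(ds, seed = 1L, encoders = EVOLUTIONARY_ENCODERS,
                        n_subsets = 5L, exponents = -10:10, folds = 5L,
                        threshold = 0.5) {
  no_prof <- setdiff(.dataset_ids(ds), names(ds$profiles))
  if (length(no_prof) > 0L) {
    stop("training requires a profile for every record; missing: ",
         paste(utils::head(no_prof, 5L), collapse = ", "),
         if (length(no_prof) > 5L) ", ..." else "", call. = FALSE)
  }
  subsets <- undersample_subsets(ds, n_subsets = n_subsets, seed = seed)
  baselines <- list()
  for (j in seq_along(encoders)) {
    enc <- encoders[[j]]
    features <- encode_feature_matrix(ds$records, ds$profiles, enc)
    baselines[[enc]] <- train_baseline(enc, subsets, ds,
                                       exponents = exponents, folds = folds,
                                       seed = seed + 1000L * j,
                                       features = features)
  }
  structure(list(baselines = baselines,
                 encoders = encoders,
                 threshold = threshold,
                 subsets = subsets,
                 seed = as.integer(seed),
                 exponents = exponents,
                 folds = as.integer(folds),
                 train_ids = .dataset_ids(ds),
                 version = MODEL_FORMAT_VERSION),
            class = "virion_ensemble")
}

#' @export
print.virion_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<virion_ensemble> %d feature ensembles x %d members, ",
                     "threshold %.2f (seed %d)\n"),
              length(x$baselines), length(x$baselines[[1L]]$members),
              x$threshold, x$seed))
  invisible(x)
}

#' Predict virion proteins with a trained ensemble
#'
#' Per protein: one score per feature ensemble, their unweighted mean as the
#' final score, and the binary call (`virion` iff final score >= threshold;
#' the threshold itself is inclusive). Proteins lacking a profile yield an
#' error entry and the run continues.
#'
#' @param object A `virion_ensemble`.
#' @param newdata A `labeled_dataset`, or a list of [protein_record()]
#'   objects (then supply `profiles`).
#' @param profiles Named list of normalized `pssm_profile`s keyed by id
#'   (ignored when `newdata` is a `labeled_dataset`).
#' @param threshold Override the model's decision threshold.
#' @param ... Unused.
#' @return Data frame with columns `id`, one `score_<encoder>` per feature
#'   ensemble, `score_final`, `call`, `error`.
#' @export
predict.virion_ensemble <- function(object, newdata, profiles = NULL,
                                   threshold = object$threshold, ...) {
  if (inherits(newdata, "labeled_dataset")) {
    records <- newdata$records
    profiles <- newdata$profiles
  } else {
    records <- newdata
  }
  ids <- vapply(records, `[[`, character(1), "id")
  ok <- ids %in% names(profiles)
  score_cols <- paste0("score_", object$encoders)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (cn in score_cols) out[[cn]] <- NA_real_
  out$score_final <- NA_real_
  out$call <- NA_character_
  out$error <- ifelse(ok, "", "missing PSSM profile")

  if (any(ok)) {
    recs_ok <- records[ok]
    for (enc in object$encoders) {
      x <- encode_feature_matrix(recs_ok, profiles, enc)
      out[[paste0("score_", enc)]][ok] <-
        .baseline_score(object$baselines[[enc]], x)
    }
    out$score_final[ok] <- rowMeans(as.matrix(out[ok, score_cols,
                                                  drop = FALSE]))
    out$call[ok] <- ifelse(out$score_final[ok] >= threshold, "virion",
                           "nonvirion")
  }
  out
}

#' Save / load a trained model bundle
#'
#' The bundle records a format version, the training configuration and seed;
#' loading refuses a bundle whose format version differs from the package's.
#'
#' @param model A `virion_ensemble`.
#' @param path Bundle path (RDS).
#' @return `save_virion_ensemble`: `path`, invisibly. `load_virion_ensemble`: the model.
#' @export
save_virion_ensemble <- function(model, path) {
  stopifnot(inherits(model, "virion_ensemble"))
  saveRDS(list(format = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_virion_ensemble
#' @export
load_virion_ensemble <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, MODEL_FORMAT_VERSION)) {
    stop("model bundle format '", bundle$format,
         "' does not match this package's '", MODEL_FORMAT_VERSION,
         "'; refusing to load", call. = FALSE)
  }
  bundle$model
}
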