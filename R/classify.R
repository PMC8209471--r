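#' Fuse per-subject connectivity matrices into a feature table
#'
#' Columns are the [vectorize_upper()] PLI features followed by the
#' [vectorize_directed()] PDC features in fixed order (190 + 380 = 570 for a
#' 20-channel montage). Descriptors make the column order invertible.
#'
#' @param pli_list List of `pli_matrix`, one per subject.
#' @param pdc_list List of `pdc_matrix`, same subjects, same order.
#' @param labels Per-subject group labels (two classes).
#' @param subject_ids Optional subject identifiers.
#' @return An object of class `feature_table`: `values`
#'   (subjects x features), `descriptors` (per-feature data frame with
#'   `estimator`, `ch_a`/`source`, `ch_b`/`target`, `name`), `labels`
#'   (factor), `subject_ids`, `montage`.
#' @export
build_feature_table <- function(pli_list, pdc_list, labels,
                                subject_ids = NULL) {
  n_subj <- length(pli_list)
  if (length(pdc_list) != n_subj || length(labels) != n_subj) {
    stop("validation error: pli_list, pdc_list and labels must have equal length")
  }
  montage <- pli_list[[1]]$montage
  for (x in c(pli_list, pdc_list)) {
    if (!identical(x$montage, montage)) {
      stop("validation error: montage mismatch across subjects/estimators")
    }
  }
  pli0 <- vectorize_upper(pli_list[[1]])
  pdc0 <- vectorize_directed(pdc_list[[1]])
  desc <- data.frame(
    estimator = c(pli0$estimator, pdc0$estimator),
    ch_a = c(pli0$ch_a, pdc0$source),
    ch_b = c(pli0$ch_b, pdc0$target),
    name = c(paste0("PLI:", pli0$ch_a, "-", pli0$ch_b),
             paste0("PDC:", pdc0$source, "->", pdc0$target)),
    stringsAsFactors = FALSE
  )
  values <- t(vapply(seq_len(n_subj), function(s) {
    c(vectorize_upper(pli_list[[s]])$value,
      vectorize_directed(pdc_list[[s]])$value)
  }, numeric(nrow(desc))))
  colnames(values) <- desc$name
  if (any(!is.finite(values))) {
    stop("validation error: non-finite feature values")
  }
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n_subj))
  rownames(values) <- subject_ids
  structure(list(values = values, descriptors = desc,
                 labels = factor(labels), subject_ids = subject_ids,
                 montage = montage),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<feature_table> %d subjects (%s) x %d features (%d PLI + %d PDC)\n",
              nrow(x$values), paste(names(tab), tab, sep = "=", collapse = ", "),
              ncol(x$values), sum(x$descriptors$estimator == "PLI"),
              sum(x$descriptors$estimator == "PDC")))
  invisible(x)
}

#' Fisher scores for two-class feature ranking
#'
#' `F = (mu_1 - mu_2)^2 / (s_1^2 + s_2^2)` per feature, with unbiased class
#' variances. Degenerate guards: both variances zero with equal means gives 0;
#' zero variances with different means gives a large-constant cap (1e12).
#'
#' @param values Numeric matrix subjects x features.
#' @param labels Two-class factor/vector, both classes non-empty.
#' @return An object of class `fisher_ranking`: `scores` (per feature) and
#'   `order` (feature indices by descending score, ties by index).
#' @export
fisher_score <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) == 0L)) {
    stop("validation error: exactly two non-empty classes required")
  }
  values <- as.matrix(values)
  g1 <- labels == levels(labels)[1]
  m1 <- colMeans(values[g1, , drop = FALSE])
  m2 <- colMeans(values[!g1, , drop = FALSE])
  v1 <- apply(values[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(values[!g1, , drop = FALSE], 2, stats::var)
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0    # single-subject class
  denom <- v1 + v2
  scores <- ifelse(denom > 0, (m1 - m2)^2 / denom,
                   ifelse(m1 == m2, 0, 1e12))
  structure(list(scores = as.numeric(scores),
                 order = order(-scores, seq_along(scores))),
            class = "fisher_ranking")
}

standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sd_ <- apply(train, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd_, "/"),
       test = sweep(sweep(test, 2, mu), 2, sd_, "/"))
}

# Train a linear SVM on (x, y) and return the held-out decision value oriented
# so that larger means more "positive_class", plus the predicted label. The
# decision value is computed directly from the support vectors
# (w = coefs' SV, dv = x w' - rho), which matches predict(decision.values)
# exactly and avoids its per-call overhead in the LOOCV loops.
svm_fold <- function(x_train, y_train, x_test, positive_class, cost) {
  fit <- e1071::svm(x = x_train, y = y_train, kernel = "linear", cost = cost,
                    scale = FALSE, fitted = FALSE, na.action = stats::na.pass)
  w <- crossprod(fit$coefs, fit$SV)
  dv <- as.numeric(x_test %*% t(w)) - fit$rho
  lv <- fit$levels[fit$labels]    # pair order of the decision values
  pred <- lv[ifelse(dv > 0, 1L, 2L)]
  orient <- if (identical(lv[1], positive_class)) 1 else -1
  list(pred = pred, dv = orient * dv)
}

# Accuracy-only LOOCV (no AUC, no bookkeeping); the workhorse of the
# permutation null, where only the accuracy is recorded.
fast_loocv_acc <- function(values, labels, cost) {
  n <- nrow(values)
  correct <- 0L
  labels_chr <- as.character(labels)
  for (i in seq_len(n)) {
    st <- standardize_train_test(values[-i, , drop = FALSE],
                                 values[i, , drop = FALSE])
    out <- svm_fold(st$train, labels[-i], st$test, labels_chr[i], cost)
    if (out$pred == labels_chr[i]) correct <- correct + 1L
  }
  100 * correct / n
}

#' Leave-one-out cross-validated linear SVM
#'
#' Each subject is held out once; the SVM is trained on the remaining
#' subjects with features standardized by the training fold's mean and SD.
#' Accuracy, specificity and sensitivity are computed from the pooled
#' predictions with the declared positive class (the patient group); AUC from
#' the pooled decision values.
#'
#' @param values Numeric matrix subjects x features (the selected features).
#' @param labels Two-class labels, >= 2 subjects per class.
#' @param positive_class Label counted as positive for SEN/SPE (default
#'   `"SZ"` when present, else the first level).
#' @param cost SVM regularization constant C.
#' @return An object of class `cv_result` with `acc`, `spe`, `sen`
#'   (percentages), `auc`, per-subject `predictions` (label, prediction,
#'   decision value), `positive_class`, `n_features`.
#' @export
loocv_svm <- function(values, labels, positive_class = NULL, cost = 1) {
  values <- as.matrix(values)
  labels <- factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
    stop("validation error: need >= 2 subjects in each of two classes")
  }
  if (is.null(positive_class)) {
    positive_class <- if ("SZ" %in% levels(labels)) "SZ" else levels(labels)[1]
  }
  n <- nrow(values)
  preds <- character(n)
  dvs <- numeric(n)
  for (i in seq_len(n)) {
    y_tr <- labels[-i]
    if (nlevels(droplevels(y_tr)) < 2L) {
      stop("validation error: degenerate training fold (single class)")
    }
    st <- standardize_train_test(values[-i, , drop = FALSE],
                                 values[i, , drop = FALSE])
    out <- svm_fold(st$train, y_tr, st$test, positive_class, cost)
    preds[i] <- out$pred
    dvs[i] <- out$dv
  }
  cv_metrics(labels, preds, dvs, positive_class,
             n_features = ncol(values))
}

cv_metrics <- function(labels, preds, dvs, positive_class, n_features,
                       strategy = NA_character_, selection = NULL) {
  pos <- labels == positive_class
  acc <- 100 * mean(preds == as.character(labels))
  sen <- 100 * mean(preds[pos] == positive_class)
  spe <- 100 * mean(preds[!pos] != positive_class)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = dvs, levels = c(FALSE, TRUE),
    direction = "<", quiet = TRUE)))
  structure(list(acc = acc, spe = spe, sen = sen, auc = auc,
                 predictions = data.frame(label = as.character(labels),
                                          prediction = preds,
                                          decision_value = dvs,
                                          stringsAsFactors = FALSE),
                 positive_class = positive_class, n_features = n_features,
                 strategy = strategy, selection = selection),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result>%s ACC %.2f%%  SPE %.2f%%  SEN %.2f%%  AUC %.3f\n",
              if (is.na(x$strategy)) "" else paste0(" [", x$strategy, "]"),
              x$acc, x$spe, x$sen, x$auc))
  if (!is.null(x$selection$L)) {
    cat(sprintf("  %d features (n = %d PLI + m = %d PDC)\n",
                x$selection$L, x$selection$n, x$selection$m))
  } else {
    cat(sprintf("  %d features\n", x$n_features))
  }
  invisible(x)
}

# Per-fold Fisher rankings of the columns `cols`, as column indices into the
# full table. mode "within_fold" ranks on the training rows of each fold (no
# leakage); "whole_data" ranks once on all subjects (mirrors the publication
# practice of ranking before LOOCV).
fold_rankings <- function(values, labels, cols, mode) {
  n <- nrow(values)
  if (mode == "whole_data") {
    rk <- cols[fisher_score(values[, cols, drop = FALSE], labels)$order]
    return(replicate(n, rk, simplify = FALSE))
  }
  lapply(seq_len(n), function(i) {
    cols[fisher_score(values[-i, cols, drop = FALSE], labels[-i])$order]
  })
}

# LOOCV predictions where fold i uses feature columns feats[[i]].
loocv_selected <- function(values, labels, feats, positive_class, cost) {
  n <- nrow(values)
  preds <- character(n)
  dvs <- numeric(n)
  for (i in seq_len(n)) {
    st <- standardize_train_test(values[-i, feats[[i]], drop = FALSE],
                                 values[i, feats[[i]], drop = FALSE])
    out <- svm_fold(st$train, labels[-i], st$test, positive_class, cost)
    preds[i] <- out$pred
    dvs[i] <- out$dv
  }
  list(preds = preds, dvs = dvs)
}

resolve_positive <- function(labels, positive_class) {
  if (!is.null(positive_class)) return(positive_class)
  if ("SZ" %in% levels(labels)) "SZ" else levels(labels)[1]
}

#' Single-estimator selection strategy
#'
#' For `N = 1..n_max`, runs the LOOCV linear SVM on the top-`N` Fisher-ranked
#' features of one estimator and returns the result maximizing accuracy
#' (ties: smaller `N`, then higher AUC). With `rank_mode = "within_fold"`
#' (default) the ranking is recomputed on each training fold so the held-out
#' subject never informs selection; `"whole_data"` ranks once on the full
#' table, mirroring the common published practice.
#'
#' @param table A `feature_table`.
#' @param estimator `"PLI"` or `"PDC"`.
#' @param n_max Largest feature count tried (default 50).
#' @param rank_mode `"within_fold"` or `"whole_data"`.
#' @param positive_class Positive label for SEN/SPE.
#' @param cost SVM regularization constant.
#' @return The best `cv_result`; `$selection` records the strategy grid and
#'   the top-`N` descriptors ranked on the full data; `$grid` holds per-`N`
#'   accuracies.
#' @export
select_and_classify_single <- function(table, estimator = c("PLI", "PDC"),
                                       n_max = 50L,
                                       rank_mode = c("within_fold", "whole_data"),
                                       positive_class = NULL, cost = 1) {
  estimator <- match.arg(estimator)
  rank_mode <- match.arg(rank_mode)
  stopifnot(inherits(table, "feature_table"))
  cols <- which(table$descriptors$estimator == estimator)
  if (n_max < 1L) stop("validation error: n_max must be >= 1")
  if (n_max > length(cols)) {
    stop("validation error: n_max exceeds the estimator's feature count")
  }
  labels <- table$labels
  positive_class <- resolve_positive(labels, positive_class)
  rks <- fold_rankings(table$values, labels, cols, rank_mode)
  grid <- vector("list", n_max)
  for (nn in seq_len(n_max)) {
    feats <- lapply(rks, function(rk) rk[seq_len(nn)])
    out <- loocv_selected(table$values, labels, feats, positive_class, cost)
    grid[[nn]] <- cv_metrics(labels, out$preds, out$dvs, positive_class,
                             n_features = nn, strategy = estimator)
  }
  accs <- vapply(grid, `[[`, 1, "acc")
  aucs <- vapply(grid, `[[`, 1, "auc")
  best_n <- order(-accs, seq_len(n_max), -aucs)[1]
  best <- grid[[best_n]]
  full_rank <- cols[fisher_score(table$values[, cols, drop = FALSE],
                                 labels)$order]
  best$selection <- list(
    strategy = estimator, n_features = best_n, rank_mode = rank_mode,
    descriptors = table$descriptors[full_rank[seq_len(best_n)], , drop = FALSE],
    feature_cols = full_rank[seq_len(best_n)])
  best$grid <- data.frame(n_features = seq_len(n_max), acc = accs, auc = aucs)
  best
}

#' Combined-estimator selection strategy
#'
#' For each total feature count `L = 2..l_max` and each split
#' `n = 1..L-1`, `m = L - n`, runs the LOOCV linear SVM on the top-`n`
#' Fisher-ranked PLI features plus the top-`m` PDC features, and returns the
#' maximizing result (ties: smaller `L`, then smaller `n`, then higher AUC).
#'
#' @inheritParams select_and_classify_single
#' @param l_max Largest total feature count tried (default 50, >= 2).
#' @return The best `cv_result`; `$selection` records `(L, n, m)` and the
#'   selected descriptors ranked on the full data; `$grid` holds every
#'   `(L, n, m)` accuracy.
#' @export
select_and_classify_combined <- function(table, l_max = 50L,
                                         rank_mode = c("within_fold", "whole_data"),
                                         positive_class = NULL, cost = 1) {
  rank_mode <- match.arg(rank_mode)
  stopifnot(inherits(table, "feature_table"))
  if (l_max < 2L) stop("validation error: l_max must be >= 2")
  if (l_max > ncol(table$values)) {
    stop("validation error: l_max exceeds the total feature count")
  }
  cols_pli <- which(table$descriptors$estimator == "PLI")
  cols_pdc <- which(table$descriptors$estimator == "PDC")
  labels <- table$labels
  positive_class <- resolve_positive(labels, positive_class)
  rk_pli <- fold_rankings(table$values, labels, cols_pli, rank_mode)
  rk_pdc <- fold_rankings(table$values, labels, cols_pdc, rank_mode)
  rows <- list()
  results <- list()
  for (l in 2:l_max) {
    for (nn in seq_len(l - 1L)) {
      mm <- l - nn
      if (nn > length(cols_pli) || mm > length(cols_pdc)) next
      feats <- lapply(seq_len(nrow(table$values)), function(i) {
        c(rk_pli[[i]][seq_len(nn)], rk_pdc[[i]][seq_len(mm)])
      })
      out <- loocv_selected(table$values, labels, feats, positive_class, cost)
      res <- cv_metrics(labels, out$preds, out$dvs, positive_class,
                        n_features = l, strategy = "combined")
      key <- length(results) + 1L
      results[[key]] <- res
      rows[[key]] <- data.frame(L = l, n = nn, m = mm, acc = res$acc,
                                auc = res$auc)
    }
  }
  grid <- do.call(rbind, rows)
  best_i <- order(-grid$acc, grid$L, grid$n, -grid$auc)[1]
  best <- results[[best_i]]
  nn <- grid$n[best_i]; mm <- grid$m[best_i]
  full_pli <- cols_pli[fisher_score(table$values[, cols_pli, drop = FALSE],
                                    labels)$order][seq_len(nn)]
  full_pdc <- cols_pdc[fisher_score(table$values[, cols_pdc, drop = FALSE],
                                    labels)$order][seq_len(mm)]
  sel_cols <- c(full_pli, full_pdc)
  best$selection <- list(
    strategy = "combined", L = grid$L[best_i], n = nn, m = mm,
    rank_mode = rank_mode,
    descriptors = table$descriptors[sel_cols, , drop = FALSE],
    feature_cols = sel_cols)
  best$grid <- grid
  best
}

#' Modified permutation test of classifier accuracy
#'
#' Each permutation independently shuffles the rows of every feature column
#' (breaking both feature-label and feature-feature alignment), reruns the
#' full LOOCV linear SVM and records the null accuracy. The p value is the
#' add-one-smoothed fraction of null accuracies at or above the observed one;
#' `smooth = FALSE` gives the raw ratio.
#'
#' @param values Numeric matrix subjects x selected features.
#' @param labels Two-class labels.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @param positive_class,cost Passed to [loocv_svm()].
#' @param smooth Use `(1 + count) / (1 + n_perm)` (default) instead of
#'   `count / n_perm`.
#' @return An object of class `perm_test`: `p_value`, `observed_acc`,
#'   `null_accs` (length `n_perm`).
#' @export
modified_permutation_test <- function(values, labels, n_perm = 10000L,
                                      seed = NULL, positive_class = NULL,
                                      cost = 1, smooth = TRUE) {
  if (n_perm < 100L) stop("validation error: n_perm must be >= 100")
  values <- as.matrix(values)
  labels <- factor(labels)
  positive_class <- resolve_positive(labels, positive_class)
  observed <- loocv_svm(values, labels, positive_class, cost)$acc
  if (!is.null(seed)) set.seed(seed)
  null_accs <- vapply(seq_len(n_perm), function(b) {
    vp <- apply(values, 2, sample)
    fast_loocv_acc(vp, labels, cost)
  }, numeric(1))
  count <- sum(null_accs >= observed)
  p <- if (smooth) (1 + count) / (1 + n_perm) else count / n_perm
  structure(list(p_value = p, observed_acc = observed, null_accs = null_accs,
                 n_perm = n_perm, smoothed = smooth),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> observed ACC %.2f%%, p = %.4g (%d permutations%s)\n",
              x$observed_acc, x$p_value, x$n_perm,
              if (x$smoothed) ", add-one smoothed" else ""))
  invisible(x)
}

#' Group comparison of selected features with FDR correction
#'
#' Per feature, a two-sample Mann-Whitney rank-sum test between the
#' independent groups with Benjamini-Hochberg adjustment across the selected
#' set. Direction is the sign of the group-median difference (positive class
#' minus the other), "up" meaning higher in the positive (patient) group.
#' Features with all-identical values get `p = 1` by convention.
#'
#' @param values Numeric matrix subjects x selected features.
#' @param labels Two-class labels.
#' @param alpha_fdr FDR threshold used for the `significant` flag.
#' @param positive_class Group whose median is reported first.
#' @return Data frame with one row per feature: `direction` (`"up"`, `"down"`
#'   or `"="`), `p_raw`, `p_fdr`, `significant`, plus per-group
#'   `mean`/`sem` columns.
#' @export
compare_selected_features <- function(values, labels, alpha_fdr = 0.05,
                                      positive_class = NULL) {
  values <- as.matrix(values)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("validation error: two groups required")
  positive_class <- resolve_positive(labels, positive_class)
  other <- setdiff(levels(labels), positive_class)
  g1 <- labels == positive_class
  p_raw <- numeric(ncol(values))
  direction <- character(ncol(values))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    if (length(unique(v)) == 1L) {
      p_raw[j] <- 1
      direction[j] <- "="
      next
    }
    p_raw[j] <- stats::wilcox.test(v[g1], v[!g1], exact = FALSE)$p.value
    dm <- stats::median(v[g1]) - stats::median(v[!g1])
    direction[j] <- if (dm > 0) "up" else if (dm < 0) "down" else "="
  }
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- data.frame(
    feature = colnames(values) %||% paste0("f", seq_len(ncol(values))),
    direction = direction, p_raw = p_raw, p_fdr = p_fdr,
    significant = p_fdr < alpha_fdr,
    stringsAsFactors = FALSE
  )
  out[[paste0("mean_", positive_class)]] <- colMeans(values[g1, , drop = FALSE])
  out[[paste0("sem_", positive_class)]] <-
    apply(values[g1, , drop = FALSE], 2, sem)
  out[[paste0("mean_", other)]] <- colMeans(values[!g1, , drop = FALSE])
  out[[paste0("sem_", other)]] <- apply(values[!g1, , drop = FALSE], 2, sem)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
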