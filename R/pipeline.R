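#' Balanced random k-fold assignment
#'
#' Random partition into `k` disjoint test sets whose sizes differ by at
#' most one and whose union covers all samples; reproducible from `seed`.
#'
#' @param n Sample count, >= k.
#' @param k Number of folds, default 4.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1:k`, length `n`.
#' @export
kfold_split <- function(n, k = 4L, seed = 1L) {
  if (n < k) stop("need at least k samples for k folds", call. = FALSE)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  withr::with_seed(seed, sample(rep(seq_len(k), times = sizes)))
}

#' Regression evaluation metrics
#'
#' Computes the metric triple used throughout: `rmse`, the root mean
#' squared prediction error; `re`, the relative error
#' `100 * rmse / mean(observed)` in percent; and `r2`, the squared
#' Pearson correlation between predictions and observations (the R^2 of
#' the linear regression of predicted on measured values). The identity-
#' line convention `1 - SS_res/SS_tot` is also returned as `r2_identity`
#' for completeness.
#'
#' @param predictions,observed Numeric vectors of equal length >= 2;
#'   `mean(observed)` must be > 0 for `re`.
#' @return List with `r2`, `rmse`, `re`, `r2_identity`, `n`.
#' @export
#' @examples
#' regression_metrics(c(2, 4), c(1, 3))  # rmse 1, re 50
regression_metrics <- function(predictions, observed) {
  if (length(predictions) != length(observed)) {
    stop("predictions and observed must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (mean(observed) <= 0) {
    stop("relative error undefined for non-positive observed mean",
         call. = FALSE)
  }
  rmse <- sqrt(mean((predictions - observed)^2))
  re <- 100 * rmse / mean(observed)
  if (stats::sd(predictions) == 0 || stats::sd(observed) == 0) {
    warning("zero-variance predictions or observations; r2 set to 0",
            call. = FALSE)
    r2 <- 0
  } else {
    r2 <- stats::cor(predictions, observed)^2
  }
  ss_tot <- sum((observed - mean(observed))^2)
  r2_id <- if (ss_tot == 0) 0 else 1 - sum((predictions - observed)^2) / ss_tot
  list(r2 = r2, rmse = rmse, re = re, r2_identity = r2_id, n = n)
}

#' Assemble the full feature table for a set of samples
#'
#' Concatenates the 67 vegetation indices (from replicate-averaged,
#' optionally denoised reflectance) and the 7 fluorescence parameters
#' into one table.
#'
#' @param samples List of `lnc_sample` records.
#' @param catalog Vegetation index catalog, default the built-in 67.
#' @param denoise_reflectance [denoise_config()] for reflectance spectra.
#' @param denoise_fluorescence [denoise_config()] for fluorescence
#'   spectra; disabled by default.
#' @param far_red_center Far-red fluorescence band center (740 or 735).
#' @return A [feature_table()] with 74 columns under the defaults.
#' @export
assemble_features <- function(samples, catalog = builtin_index_catalog(),
                              denoise_reflectance = denoise_config(),
                              denoise_fluorescence = denoise_config(enabled = FALSE),
                              far_red_center = 740) {
  vi <- compute_all_indices(samples, catalog, denoise = denoise_reflectance)
  fl <- compute_fluorescence_params(samples, far_red_center = far_red_center,
                                    denoise = denoise_fluorescence)
  cbind_features(vi, fl)
}

#' Extract LNC labels from sample records
#'
#' @param samples List of `lnc_sample` records.
#' @return Numeric vector of LNC labels (`NA` where unlabeled).
#' @export
sample_labels <- function(samples) {
  vapply(samples, function(x) if (is.null(x$lnc)) NA_real_ else x$lnc,
         numeric(1))
}

#' Default feature sets for the three-way comparison
#'
#' `vi4` is the optimal vegetation-index quartet (TVI, MTVI1, MTVI2,
#' MSAVI), `fluor2` the optimal fluorescence pair (far-red/F460 and
#' F685/F460), `combined` their union.
#'
#' @param far_red_center Far-red band center used when the fluorescence
#'   table was built.
#' @return Named list of character vectors of feature names.
#' @export
default_feature_sets <- function(far_red_center = 740) {
  fr <- paste0("F", far_red_center, "_F460")
  list(vi4 = c("TVI", "MTVI1", "MTVI2", "MSAVI"),
       fluor2 = c(fr, "F685_F460"),
       combined = c("TVI", "MTVI1", "MTVI2", "MSAVI", fr, "F685_F460"))
}

# Pooled k-fold CV for one feature subset. Rows with sentinels in the
# selected columns are dropped (count recorded); folds are taken from the
# supplied assignment so different subsets stay paired on shared rows.
.cv_pooled <- function(values, labels, cols, folds, cfg) {
  missing_cols <- setdiff(cols, colnames(values))
  if (length(missing_cols)) {
    stop("unknown feature name(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- values[, cols, drop = FALSE]
  keep <- stats::complete.cases(x) & !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- labels[keep]
  f <- folds[keep]
  preds <- rep(NA_real_, length(y))
  for (fold in sort(unique(f))) {
    te <- f == fold
    if (!any(te) || sum(!te) < 2L) next
    preds[te] <- fit_predict_svr(x[!te, , drop = FALSE], y[!te],
                                 x[te, , drop = FALSE], cfg)
  }
  ok <- !is.na(preds)
  list(predictions = preds[ok], observed = y[ok], folds = f[ok],
       keep = which(keep)[ok], n_dropped = sum(!keep))
}

#' Rank features by single-feature cross-validated skill
#'
#' Runs the full k-fold SVR cross-validation with each feature column as
#' the single input variable and records the pooled-prediction R^2
#' (squared Pearson correlation of out-of-fold predictions with observed
#' LNC). Features are returned sorted by decreasing R^2, ties broken by
#' name for determinism. Columns that are entirely sentinel (or constant
#' on the labeled rows) are excluded with a warning.
#'
#' @param features A [feature_table()].
#' @param labels Numeric LNC labels, one per row of `features`.
#' @param cfg An [svr_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold assignment (shared by all features).
#' @return A data.frame with columns `feature`, `r2`, `rmse`, `re`, `n`.
#' @export
rank_single_features <- function(features, labels, cfg = svr_config(),
                                 k = 4L, seed = 1L) {
  stopifnot(inherits(features, "feature_table"))
  labeled <- !is.na(labels)
  if (sum(labeled) < 2L * k) {
    stop("need at least 2k labeled samples", call. = FALSE)
  }
  folds <- rep(NA_integer_, length(labels))
  folds[labeled] <- kfold_split(sum(labeled), k, seed)
  rows <- lapply(features$feature_names, function(nm) {
    col <- features$values[, nm]
    usable <- labeled & !is.na(col)
    if (sum(usable) < 2L * k || stats::sd(col[usable]) == 0) {
      warning("feature ", nm, " excluded from ranking (all-sentinel or constant)",
              call. = FALSE)
      return(NULL)
    }
    cv <- .cv_pooled(features$values, labels, nm, folds, cfg)
    m <- suppressWarnings(regression_metrics(cv$predictions, cv$observed))
    data.frame(feature = nm, r2 = m$r2, rmse = m$rmse, re = m$re, n = m$n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-way feature-set comparison under shared cross-validation folds
#'
#' Evaluates each named feature subset with pooled k-fold SVR
#' cross-validation, all subsets sharing one fold assignment so results
#' are paired. Per subset, rows carrying sentinels in that subset's
#' columns are dropped with a recorded count, so subsets may differ in
#' `n`.
#'
#' @param samples List of labeled `lnc_sample` records, or `NULL` when
#'   `features` and `labels` are given directly.
#' @param feature_sets Named list of character vectors of feature names;
#'   default [default_feature_sets()].
#' @param cfg An [svr_config()].
#' @param k Number of folds.
#' @param seed Seed for the shared fold assignment.
#' @param features,labels Optional precomputed [feature_table()] and
#'   label vector (bypasses feature assembly).
#' @param far_red_center Passed to [assemble_features()].
#' @return Named list of `lnc_eval` results, one per feature set, each
#'   with the pooled predictions, fold assignment and metric triple.
#' @export
run_experiment <- function(samples = NULL, feature_sets = NULL,
                           cfg = svr_config(), k = 4L, seed = 1L,
                           features = NULL, labels = NULL,
                           far_red_center = 740) {
  if (is.null(features)) {
    stopifnot(!is.null(samples))
    features <- assemble_features(samples, far_red_center = far_red_center)
    labels <- sample_labels(samples)
  }
  if (is.null(feature_sets)) {
    feature_sets <- default_feature_sets(far_red_center)
  }
  labeled <- !is.na(labels)
  if (sum(labeled) < k) stop("not enough labeled samples", call. = FALSE)
  folds <- rep(NA_integer_, length(labels))
  folds[labeled] <- kfold_split(sum(labeled), k, seed)
  out <- lapply(names(feature_sets), function(nm) {
    cv <- .cv_pooled(features$values, labels, feature_sets[[nm]], folds, cfg)
    m <- suppressWarnings(regression_metrics(cv$predictions, cv$observed))
    structure(list(feature_set_name = nm,
                   feature_names = feature_sets[[nm]],
                   fold_assignments = folds,
                   predictions = cv$predictions, observed = cv$observed,
                   r2 = m$r2, rmse = m$rmse, re = m$re,
                   r2_identity = m$r2_identity, n = m$n,
                   n_dropped = cv$n_dropped),
              class = "lnc_eval")
  })
  names(out) <- names(feature_sets)
  out
}

#' @export
print.lnc_eval <- function(x, ...) {
  cat(sprintf("<lnc_eval %s: n = %d, R2 = %.3f, RMSE = %.3f %%N, RE = %.1f %%>\n",
              x$feature_set_name, x$n, x$r2, x$rmse, x$re))
  invisible(x)
}
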