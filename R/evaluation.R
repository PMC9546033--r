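#' @title Model evaluation statistics
#' @description Discrimination and calibration statistics for
#'   presence-background models: AUC (rank / Mann-Whitney formulation,
#'   ties counted one half), maximized TSS with background points as
#'   pseudo-absences, percentile thresholds on training presences, and
#'   omission rates, plus a train/test consistency report.
#' @name evaluation
NULL

#' Presence-background AUC
#'
#' Probability that a random presence outscores a random background
#' point, with ties counted one half (Mann-Whitney / rank formulation).
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return value in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  stopifnot(np >= 1, nb >= 1)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximized True Skill Statistic
#'
#' Scans thresholds at midpoints between adjacent distinct pooled scores
#' (plus the extremes) and returns the maximum of sensitivity +
#' specificity - 1, with sensitivity the fraction of presences scoring
#' above the threshold and specificity the fraction of background at or
#' below it.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return value in `[-1, 1]`.
#' @export
tss <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) >= 1,
            length(background_scores) >= 1)
  s <- sort(unique(c(presence_scores, background_scores)))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  best <- -1
  for (t in thr) {
    sens <- mean(presence_scores > t)
    spec <- mean(background_scores <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

#' Percentile threshold on training presence scores
#'
#' Linear-interpolation empirical quantile (order-statistic position
#' `h = (m - 1) q/100 + 1`); `q = 0` gives the minimum training presence
#' threshold.
#'
#' @param train_presence_scores training presence scores.
#' @param q percentile (default 10).
#' @return threshold value.
#' @export
percentile_threshold <- function(train_presence_scores, q = 10) {
  if (length(train_presence_scores) == 0)
    stop("no training presence scores")
  if (q > 0 && length(train_presence_scores) < 2)
    stop("need at least 2 scores for a positive percentile")
  unname(stats::quantile(train_presence_scores, q / 100, type = 7))
}

#' Omission rate at a threshold
#'
#' Fraction of presence scores strictly below `tau`; at the minimum
#' training presence threshold evaluated on the training scores this is
#' exactly 0.
#'
#' @param presence_scores numeric score vector.
#' @param tau threshold.
#' @return proportion in `[0, 1]`.
#' @export
omission_rate <- function(presence_scores, tau) {
  stopifnot(length(presence_scores) >= 1)
  mean(presence_scores < tau)
}

#' Evaluate a fitted model on training and testing partitions
#'
#' Computes AUC and TSS on both partitions from cloglog scores, the
#' 10th-percentile and minimum-training-presence thresholds, the
#' corresponding omission rates, and flags potential overfitting when
#' the train-test AUC gap exceeds `warn_gap`.
#'
#' @param model a fitted [maxent()] model.
#' @param swd_train,swd_test `swd` tables.
#' @param warn_gap AUC gap triggering the overfitting flag (default
#'   0.05).
#' @return object of class `sdm_evaluation`: list with `auc_train`,
#'   `auc_test`, `tss_train`, `tss_test`, `tau10`, `tau_mtp`,
#'   `omission10_train`, `omission10_test`, `omission_mtp_test`,
#'   `overfit_flag`.
#' @export
evaluate <- function(model, swd_train, swd_test, warn_gap = 0.05) {
  if (!any(swd_test$class == "presence"))
    stop("test set has no presences")
  sc_tr <- predict(model, swd_train, type = "cloglog")
  sc_te <- predict(model, swd_test, type = "cloglog")
  p_tr <- sc_tr[swd_train$class == "presence"]
  b_tr <- sc_tr[swd_train$class == "background"]
  p_te <- sc_te[swd_test$class == "presence"]
  b_te <- sc_te[swd_test$class == "background"]
  tau10 <- percentile_threshold(p_tr, 10)
  tau_mtp <- percentile_threshold(p_tr, 0)
  out <- list(auc_train = auc(p_tr, b_tr), auc_test = auc(p_te, b_te),
              tss_train = tss(p_tr, b_tr), tss_test = tss(p_te, b_te),
              tau10 = tau10, tau_mtp = tau_mtp,
              omission10_train = omission_rate(p_tr, tau10),
              omission10_test = omission_rate(p_te, tau10),
              omission_mtp_test = omission_rate(p_te, tau_mtp))
  out$overfit_flag <- (out$auc_train - out$auc_test) > warn_gap
  structure(out, class = "sdm_evaluation")
}

#' @export
print.sdm_evaluation <- function(x, ...) {
  cat(sprintf(paste0("model evaluation\n  AUC  train %.3f  test %.3f\n",
                     "  TSS  train %.3f  test %.3f\n",
                     "  thresholds: tau10 = %.4f, MTP = %.4f\n",
                     "  omission: train@10p %.3f, test@10p %.3f,",
                     " test@MTP %.3f\n%s"),
              x$auc_train, x$auc_test, x$tss_train, x$tss_test,
              x$tau10, x$tau_mtp, x$omission10_train, x$omission10_test,
              x$omission_mtp_test,
              if (x$overfit_flag)
                "  WARNING: train-test AUC gap exceeds limit\n" else ""))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report an `sdm_evaluation`.
#' @param path JSON file path.
#' @export
write_evaluation <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
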