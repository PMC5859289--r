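#' Age-adaptive dimorphism score
#'
#' Projects a configuration onto the axis joining the two groups' expected
#' heads at the case's age, normalized by half the Procrustes distance
#' between them:
#' \deqn{s(x) = \frac{\langle x - (m_- + m_+)/2,\; u\rangle}{\|m_+ - m_-\| / 2}}
#' with \eqn{u} the unit vector from the negative to the positive expected
#' head. A score of \eqn{-1} means the case sits at the negative group's
#' expected head, \eqn{+1} at the positive group's; values beyond \eqn{\pm 1}
#' are more extreme than either group average and values near zero indicate
#' an intermediate (androgynous) head.
#'
#' @param x `p x 3` configuration in the common frame.
#' @param m_neg,m_pos the two groups' expected configurations at the case's
#'   age (score anchors \eqn{-1} and \eqn{+1}).
#' @return scalar score.
#' @export
dimorphism_score <- function(x, m_neg, m_pos) {
  if (!all(dim(x) == dim(m_neg)) || !all(dim(x) == dim(m_pos)))
    stopf("configurations must match in size")
  d <- as.vector(m_pos - m_neg)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-300) stopf("expected heads coincide: score direction undefined")
  mid <- as.vector(m_neg + m_pos) / 2
  sum((as.vector(x) - mid) * (d / nd)) / (nd / 2)
}

#' Age- and group-stratified fold assignment
#'
#' Partitions a cohort into `k` cross-validation folds so that the
#' composition of the two groups at each (integer-year) age matches the
#' whole sample: within every group-by-age stratum the per-fold counts
#' differ by at most one.
#'
#' @param x a [cohort()].
#' @param k number of folds (>= 2).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @param quiet suppress the small-stratum warning?
#' @return integer vector of fold labels in `1..k`, one per case.
#' @export
stratified_folds <- function(x, k = 10L, seed = 1L, quiet = FALSE) {
  stopifnot(inherits(x, "cohort"))
  if (k < 2L) stopf("k must be >= 2")
  strata <- interaction(x$groups, floor(x$ages), drop = TRUE)
  set.seed(seed)
  folds <- integer(length(x$ages))
  small <- 0L
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < k) small <- small + 1L
    folds[idx[sample.int(length(idx))]] <- rep_len(sample.int(k), length(idx))
  }
  if (small > 0L && !quiet)
    warnf("%d strata have fewer cases than folds; their cases were spread over a subset of folds",
          small)
  folds
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (the Mann--Whitney
#' statistic): the probability that a random positive case scores above a
#' random negative one, with ties counting one half.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical or two-level vector; `TRUE`/second level is the
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- as.logical(if (is.logical(labels)) labels
                    else factor(labels) == levels(factor(labels))[2L])
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-group correct-classification rates at a threshold
#'
#' Percentage of positive cases scoring strictly above the threshold and of
#' negative cases scoring strictly below it; a score exactly at the
#' threshold counts as incorrect for either group.
#'
#' @inheritParams auc
#' @param threshold decision threshold (default 0).
#' @return named numeric vector `c(pos_correct, neg_correct)`, in percent.
#' @export
classification_rates <- function(scores, labels, threshold = 0) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  pos <- as.logical(if (is.logical(labels)) labels
                    else factor(labels) == levels(factor(labels))[2L])
  c(pos_correct = 100 * mean(scores[pos] > threshold),
    neg_correct = 100 * mean(scores[!pos] < threshold))
}

#' Repeated stratified k-fold cross-validated classification
#'
#' Assesses the age-adaptive classifier by repeated stratified k-fold
#' cross-validation: for each repetition the sample is split into `k`
#' age-and-group-stratified folds; each held-out case is scored
#' ([dimorphism_score()]) against the two groups' expected heads at the
#' case's age, fitted on the remaining `k - 1` folds. Cases whose age falls
#' outside a training set's evaluation range are scored at the nearest
#' in-range age and flagged. The first group level anchors score \eqn{-1},
#' the second \eqn{+1}.
#'
#' Alignment is assumed done once on the full cohort beforehand (the
#' pipeline order of the underlying study); the leakage through the shared
#' Procrustes frame is negligible but real.
#'
#' @param x an aligned [cohort()].
#' @param k folds per repetition (default 10).
#' @param repetitions number of repetitions (study-scale default 100).
#' @param width shape kernel width in years (default 2.75).
#' @param support_threshold passed to [evaluation_range()].
#' @param seed integer seed.
#' @return list of class `repeated_cv` with `records` (one row per case per
#'   repetition: id, age, group, score, repetition, fold, clamped) and
#'   `fold_metrics` (per repetition x fold: overall AUC and per-group
#'   correct rates at threshold zero).
#' @export
repeated_cv <- function(x, k = 10L, repetitions = 100L, width = 2.75,
                        support_threshold = 0.4, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (!x$aligned) warnf("cohort is not aligned; scores assume a common frame")
  lv <- levels(x$groups)
  Y <- flatten_configs(x$coords)
  n <- length(x)
  p <- dim(x$coords)[1L]

  rec <- vector("list", repetitions * k)
  met <- vector("list", repetitions * k)
  ri <- 0L
  for (rep_i in seq_len(repetitions)) {
    folds <- stratified_folds(x, k, seed = seed + rep_i - 1L, quiet = TRUE)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      te <- which(!tr)
      scores <- numeric(length(te))
      clamped <- logical(length(te))
      ok <- TRUE
      for (g in lv) {
        if (!any(tr & x$groups == g)) {
          warnf("repetition %d fold %d: group '%s' empty in training set; fold skipped",
                rep_i, f, g)
          ok <- FALSE
        }
      }
      if (!ok) next
      tr_idx <- split(which(tr), x$groups[tr])
      rngs <- lapply(tr_idx, function(ii)
        evaluation_range(x$ages[ii], width, threshold = support_threshold))
      lo <- max(rngs[[1L]]$a_min, rngs[[2L]]$a_min)
      hi <- min(rngs[[1L]]$a_max, rngs[[2L]]$a_max)
      for (j in seq_along(te)) {
        a <- x$ages[te[j]]
        a_eff <- min(max(a, lo), hi)
        clamped[j] <- a_eff != a
        preds <- lapply(tr_idx, function(ii) {
          w <- kernel_weights(x$ages[ii], a_eff, width)
          fit <- weighted_pls_fit(Y[ii, , drop = FALSE], x$ages[ii], w)
          fit$intercept + fit$coef * (a_eff - fit$age_center)
        })
        scores[j] <- dimorphism_score(x$coords[, , te[j]],
                                      unflatten_config(preds[[lv[1L]]], p),
                                      unflatten_config(preds[[lv[2L]]], p))
      }
      ri <- ri + 1L
      rec[[ri]] <- data.frame(
        id = x$ids[te], age = x$ages[te],
        group = as.character(x$groups[te]), score = scores,
        repetition = rep_i, fold = f, clamped = clamped,
        stringsAsFactors = FALSE)
      rates <- classification_rates(scores, x$groups[te])
      met[[ri]] <- data.frame(
        repetition = rep_i, fold = f,
        auc = auc(scores, x$groups[te]),
        pos_correct = rates[["pos_correct"]],
        neg_correct = rates[["neg_correct"]])
    }
  }
  structure(list(records = do.call(rbind, rec[seq_len(ri)]),
                 fold_metrics = do.call(rbind, met[seq_len(ri)]),
                 groups = lv, k = k, repetitions = repetitions,
                 width = width),
            class = "repeated_cv")
}

#' @export
print.repeated_cv <- function(x, ...) {
  cat(sprintf(
    "Repeated stratified CV: %d repetitions x %d folds (width %.2f y); mean overall AUC %.3f\n",
    x$repetitions, x$k, x$width, mean(x$fold_metrics$auc)))
  invisible(x)
}

#' Age-bracketed cross-validation report
#'
#' Aggregates [repeated_cv()] results into age brackets (default: under 5,
#' 5--10, 10--15, 15--20 years): per bracket the fold-level AUC and
#' per-group correct-rate values are recomputed on the fold's cases in that
#' bracket, then summarized as the mean and 95% percentile interval over
#' all repetitions-times-folds values. Fold-bracket cells missing a class
#' are skipped; brackets with no usable folds are reported as `NA`. Also
#' returns each case's mean score over repetitions (for score histograms).
#'
#' @param cv a [repeated_cv()] result.
#' @param brackets increasing numeric break points (years).
#' @param level confidence level for the percentile intervals.
#' @return list of class `cv_report` with `metrics` (one row per bracket:
#'   n_folds, auc mean/low/high, per-group rate mean/low/high) and
#'   `case_scores` (id, age, group, mean_score, n_scored).
#' @export
bracket_report <- function(cv, brackets = c(0, 5, 10, 15, 20), level = 0.95) {
  stopifnot(inherits(cv, "repeated_cv"))
  rec <- cv$records
  if (max(rec$age) > max(brackets) || min(rec$age) < min(brackets))
    stopf("brackets must cover all observed ages")
  labs <- paste0("[", utils::head(brackets, -1L), ",", brackets[-1L], ")")
  rec$bracket <- cut(rec$age, brackets, labels = labs, right = FALSE,
                     include.lowest = TRUE)
  alpha <- (1 - level) / 2
  qfun <- function(v) stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)

  rows <- lapply(labs, function(bl) {
    sub <- rec[rec$bracket == bl, ]
    if (nrow(sub) == 0L)
      return(data.frame(bracket = bl, n_folds = 0L, auc = NA_real_,
                        auc_low = NA_real_, auc_high = NA_real_,
                        pos_correct = NA_real_, pos_low = NA_real_,
                        pos_high = NA_real_, neg_correct = NA_real_,
                        neg_low = NA_real_, neg_high = NA_real_))
    per_fold <- lapply(split(sub, list(sub$repetition, sub$fold), drop = TRUE),
      function(ff) {
        if (length(unique(ff$group)) < 2L) return(NULL)
        rates <- classification_rates(ff$score, factor(ff$group, levels = cv$groups))
        c(auc = auc(ff$score, factor(ff$group, levels = cv$groups)),
          pos = rates[["pos_correct"]], neg = rates[["neg_correct"]])
      })
    per_fold <- do.call(rbind, Filter(Negate(is.null), per_fold))
    if (is.null(per_fold))
      return(data.frame(bracket = bl, n_folds = 0L, auc = NA_real_,
                        auc_low = NA_real_, auc_high = NA_real_,
                        pos_correct = NA_real_, pos_low = NA_real_,
                        pos_high = NA_real_, neg_correct = NA_real_,
                        neg_low = NA_real_, neg_high = NA_real_))
    qa <- qfun(per_fold[, "auc"]); qp <- qfun(per_fold[, "pos"])
    qn <- qfun(per_fold[, "neg"])
    data.frame(bracket = bl, n_folds = nrow(per_fold),
               auc = mean(per_fold[, "auc"]), auc_low = qa[1L], auc_high = qa[2L],
               pos_correct = mean(per_fold[, "pos"]), pos_low = qp[1L],
               pos_high = qp[2L],
               neg_correct = mean(per_fold[, "neg"]), neg_low = qn[1L],
               neg_high = qn[2L])
  })
  metrics <- do.call(rbind, rows)

  agg <- stats::aggregate(score ~ id + age + group, data = rec, FUN = mean)
  cnt <- stats::aggregate(score ~ id, data = rec, FUN = length)
  case_scores <- merge(agg, cnt, by = "id", suffixes = c("", "_n"))
  names(case_scores) <- c("id", "age", "group", "mean_score", "n_scored")

  structure(list(metrics = metrics, case_scores = case_scores,
                 brackets = brackets, groups = cv$groups),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Classifier performance by age bracket (positive group: %s)\n",
              x$groups[2L]))
  print(x$metrics, row.names = FALSE, digits = 3L)
  invisible(x)
}
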