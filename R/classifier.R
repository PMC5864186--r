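#' Score profiles by cumulative abundance over an ORF subset
#'
#' The classifier's score for a data set is the raw (untransformed)
#' cumulative relative abundance over an ORF subset; pollution adds
#' abundance, so higher scores indicate pollution.
#'
#' @param profiles A `profile_matrix`.
#' @param subset An [orf_subset()] (or character/integer ORF ids); `NULL`
#'   scores over all ORFs.
#' @return Named numeric vector of scores, one per data set, order preserved.
#' @export
score_profiles <- function(profiles, subset = NULL) {
  cumulative_abundance(profiles, subset)
}

#' Construct a ROC curve
#'
#' Thresholds sweep over the distinct observed scores plus `-Inf` and `Inf`;
#' at threshold `t` a data set is predicted positive iff its score is `>= t`.
#' Sensitivity is `TP / (TP + FN)` and specificity `TN / (TN + FP)`. The AUC
#' is the trapezoidal area over `(1 - specificity, sensitivity)`, equal to
#' the probability that a random positive outscores a random negative with
#' ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Vector of class labels, same length.
#' @param positive The label of the positive class.
#' @return A `roc_curve`: list with `points` (data.frame `threshold`,
#'   `sensitivity`, `specificity`), `auc` and `positive_label`.
#' @export
roc_curve <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_curve needs both classes present")
  }
  thresholds <- c(-Inf, sort(unique(scores)), Inf)
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred_pos <- scores >= thresholds[i]
    sens[i] <- sum(pred_pos & is_pos) / n_pos
    spec[i] <- sum(!pred_pos & !is_pos) / n_neg
  }
  fpr <- 1 - spec
  # points ordered by increasing threshold => fpr decreasing
  auc <- sum(-diff(fpr) * (sens[-length(sens)] + sens[-1L]) / 2)
  structure(list(points = data.frame(threshold = thresholds,
                                     sensitivity = sens,
                                     specificity = spec),
                 auc = auc, positive_label = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (positive = %s): %d points, AUC = %.4f\n",
              x$positive_label, nrow(x$points), x$auc))
  invisible(x)
}

#' Select a classification threshold from a ROC curve
#'
#' Among ROC points with sensitivity at or above `min_sensitivity`, returns
#' the threshold with the best specificity — the published selection rule
#' ("best possible sensitivity and specificity, but with a minimum
#' sensitivity of 0.91"). Ties are broken toward higher sensitivity, then
#' higher threshold.
#'
#' @param roc A `roc_curve`.
#' @param min_sensitivity Sensitivity floor (default 0.91).
#' @return The selected threshold (hits/Mb), with the achieved sensitivity
#'   and specificity attached as attributes.
#' @export
select_threshold <- function(roc, min_sensitivity = 0.91) {
  pts <- roc$points
  ok <- pts$sensitivity >= min_sensitivity
  if (!any(ok)) {
    stop(sprintf("no ROC point reaches sensitivity %.3f (best attainable: %.3f)",
                 min_sensitivity, max(pts$sensitivity)))
  }
  cand <- pts[ok, , drop = FALSE]
  cand <- cand[order(-cand$specificity, -cand$sensitivity, -cand$threshold), ,
               drop = FALSE]
  thr <- cand$threshold[1L]
  attr(thr, "sensitivity") <- cand$sensitivity[1L]
  attr(thr, "specificity") <- cand$specificity[1L]
  thr
}

#' Two-step source-tracking model
#'
#' Step 1 bins data sets as polluted vs non-polluted by a cumulative-
#' abundance threshold on one ORF subset; step 2 bins the polluted ones as
#' human vs non-human polluted by a second subset and threshold.
#'
#' @param step1_subset,step2_subset [orf_subset()] objects (defaults:
#'   published subsets 1 and 2).
#' @param thr1,thr2 Non-negative thresholds in hits/Mb.
#' @return A `two_step_model`.
#' @export
two_step_model <- function(step1_subset, thr1, step2_subset, thr2) {
  stopifnot(inherits(step1_subset, "orf_subset"),
            inherits(step2_subset, "orf_subset"))
  if (thr1 < 0 || thr2 < 0) {
    stop("thresholds must be non-negative")
  }
  structure(list(step1 = list(subset = step1_subset, threshold = as.numeric(thr1)),
                 step2 = list(subset = step2_subset, threshold = as.numeric(thr2))),
            class = "two_step_model")
}

#' @export
print.two_step_model <- function(x, ...) {
  cat(sprintf("two-step model:\n  step 1 (%s, %d ORFs): polluted iff score >= %.4g\n  step 2 (%s, %d ORFs): human iff score >= %.4g\n",
              x$step1$subset$name, length(x$step1$subset$orf_ids), x$step1$threshold,
              x$step2$subset$name, length(x$step2$subset$orf_ids), x$step2$threshold))
  invisible(x)
}

#' Calibrate the two-step model on one Monte-Carlo iteration
#'
#' Builds the step-1 ROC (any polluted type vs `ENV_U`, scored on
#' `step1_subset`) and the step-2 ROC (`ENV_HGV` vs the other polluted types,
#' among truly polluted data sets, scored on `step2_subset`) from a single
#' calibration iteration, then selects both thresholds under the
#' minimum-sensitivity constraint.
#'
#' @param iteration One element of [run_monte_carlo()] output.
#' @param step1_subset,step2_subset [orf_subset()] objects; defaults are the
#'   published subsets.
#' @param min_sensitivity Sensitivity floor for both thresholds (default
#'   0.91).
#' @return A `two_step_model`; the underlying `roc_curve` objects are
#'   attached as attribute `"rocs"`.
#' @export
calibrate_two_step <- function(iteration,
                               step1_subset = subset1_orfs(),
                               step2_subset = subset2_orfs(),
                               min_sensitivity = 0.91) {
  profiles <- iteration$profiles
  types <- iteration$labels$type
  polluted <- types != "ENV_U"
  s1 <- score_profiles(profiles, step1_subset)
  roc1 <- roc_curve(s1, ifelse(polluted, "polluted", "unpolluted"), "polluted")
  thr1 <- select_threshold(roc1, min_sensitivity)

  pm_poll <- profile_matrix(unclass(profiles)[polluted, , drop = FALSE],
                            profile_meta(profiles)[polluted, , drop = FALSE])
  s2 <- score_profiles(pm_poll, step2_subset)
  roc2 <- roc_curve(s2, types[polluted], "ENV_HGV")
  thr2 <- select_threshold(roc2, min_sensitivity)

  model <- two_step_model(step1_subset, thr1, step2_subset, thr2)
  attr(model, "rocs") <- list(step1 = roc1, step2 = roc2)
  model
}

#' Classify profiles with a two-step model
#'
#' A data set whose step-1 score is below the step-1 threshold is
#' `unpolluted`; otherwise it is `human_polluted` if its step-2 score reaches
#' the step-2 threshold and `nonhuman_polluted` if not.
#'
#' @param profiles A `profile_matrix` (or a single `abundance_profile`).
#' @param model A [two_step_model()].
#' @return Character vector of `unpolluted`, `human_polluted` or
#'   `nonhuman_polluted`, one per data set.
#' @export
two_step_classify <- function(profiles, model) {
  if (inherits(profiles, "abundance_profile")) {
    profiles <- bind_profiles(list(profiles))
  }
  s1 <- score_profiles(profiles, model$step1$subset)
  s2 <- score_profiles(profiles, model$step2$subset)
  out <- ifelse(s1 < model$step1$threshold, "unpolluted",
                ifelse(s2 >= model$step2$threshold,
                       "human_polluted", "nonhuman_polluted"))
  stats::setNames(out, rownames(profiles))
}

correct_class <- c(ENV_U = "unpolluted", ENV_HGV = "human_polluted",
                   ENV_BOV = "nonhuman_polluted", ENV_PORC = "nonhuman_polluted")

#' Evaluate a two-step model over Monte-Carlo iterations
#'
#' Per iteration and per true type, the proportion of data sets correctly
#' classified (`ENV_U` as unpolluted, `ENV_HGV` as human-polluted,
#' `ENV_BOV`/`ENV_PORC` as non-human polluted), summarised as mean and
#' standard error of the mean across iterations. Also reports pooled step-1
#' sensitivity (truly polluted data sets of any type classified as polluted,
#' over all iterations), pooled step-1 specificity, and pooled step-2
#' sensitivity/specificity among truly polluted data sets.
#'
#' @param iterations Output of [run_monte_carlo()] (or a subset of it).
#' @param model A [two_step_model()].
#' @return A `performance_summary`: list with `per_type` (data.frame `type`,
#'   `mean`, `sem`, `n_iterations`), `per_iteration` (iterations x types
#'   accuracy matrix), and pooled `step1_sensitivity`, `step1_specificity`,
#'   `step2_sensitivity`, `step2_specificity`.
#' @export
evaluate_iterations <- function(iterations, model) {
  if (length(iterations) == 0L) {
    stop("need at least one iteration")
  }
  types_order <- c("ENV_U", "ENV_HGV", "ENV_BOV", "ENV_PORC")
  acc <- matrix(NA_real_, length(iterations), length(types_order),
                dimnames = list(NULL, types_order))
  tallies <- c(step1_tp = 0, step1_fn = 0, step1_tn = 0, step1_fp = 0,
               step2_tp = 0, step2_fn = 0, step2_tn = 0, step2_fp = 0)
  for (i in seq_along(iterations)) {
    it <- iterations[[i]]
    pred <- two_step_classify(it$profiles, model)
    truth <- it$labels$type
    for (ty in intersect(types_order, unique(truth))) {
      sel <- truth == ty
      acc[i, ty] <- mean(pred[sel] == correct_class[[ty]])
    }
    polluted <- truth != "ENV_U"
    pred_polluted <- pred != "unpolluted"
    tallies["step1_tp"] <- tallies["step1_tp"] + sum(polluted & pred_polluted)
    tallies["step1_fn"] <- tallies["step1_fn"] + sum(polluted & !pred_polluted)
    tallies["step1_tn"] <- tallies["step1_tn"] + sum(!polluted & !pred_polluted)
    tallies["step1_fp"] <- tallies["step1_fp"] + sum(!polluted & pred_polluted)
    # step 2 is assessed among truly polluted data sets that passed step 1
    s2sel <- polluted & pred_polluted
    human <- truth == "ENV_HGV"
    pred_human <- pred == "human_polluted"
    tallies["step2_tp"] <- tallies["step2_tp"] + sum(s2sel & human & pred_human)
    tallies["step2_fn"] <- tallies["step2_fn"] + sum(s2sel & human & !pred_human)
    tallies["step2_tn"] <- tallies["step2_tn"] + sum(s2sel & !human & !pred_human)
    tallies["step2_fp"] <- tallies["step2_fp"] + sum(s2sel & !human & pred_human)
  }
  present <- colSums(!is.na(acc)) > 0
  acc <- acc[, present, drop = FALSE]
  n_it <- length(iterations)
  per_type <- data.frame(
    type = colnames(acc),
    mean = colMeans(acc),
    sem = apply(acc, 2L, function(v) {
      if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
    }),
    n_iterations = n_it,
    row.names = NULL, stringsAsFactors = FALSE
  )
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  structure(list(
    per_type = per_type,
    per_iteration = acc,
    step1_sensitivity = rate(tallies[["step1_tp"]], tallies[["step1_fn"]]),
    step1_specificity = rate(tallies[["step1_tn"]], tallies[["step1_fp"]]),
    step2_sensitivity = rate(tallies[["step2_tp"]], tallies[["step2_fn"]]),
    step2_specificity = rate(tallies[["step2_tn"]], tallies[["step2_fp"]])
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("two-step classification performance\n")
  for (i in seq_len(nrow(x$per_type))) {
    cat(sprintf("  %-8s accuracy %.3f (SEM %.3f)\n",
                x$per_type$type[i], x$per_type$mean[i], x$per_type$sem[i]))
  }
  cat(sprintf("  pooled step-1 sensitivity %.3f, specificity %.3f\n",
              x$step1_sensitivity, x$step1_specificity))
  cat(sprintf("  pooled step-2 sensitivity %.3f, specificity %.3f\n",
              x$step2_sensitivity, x$step2_specificity))
  invisible(x)
}

#' Serialize / deserialize a two-step model as JSON
#'
#' @param model A [two_step_model()].
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `two_step_model`.
#' @export
write_model_json <- function(model, path) {
  obj <- list(step1 = list(name = model$step1$subset$name,
                           orfs = model$step1$subset$orf_ids,
                           threshold = model$step1$threshold),
              step2 = list(name = model$step2$subset$name,
                           orfs = model$step2$subset$orf_ids,
                           threshold = model$step2$threshold))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  two_step_model(orf_subset(obj$step1$name, obj$step1$orfs), obj$step1$threshold,
                 orf_subset(obj$step2$name, obj$step2$orfs), obj$step2$threshold)
}
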