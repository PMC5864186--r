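test_that("roc_curve reproduces hand-computed AUCs and the ties convention", {
  # perfect separation
  r1 <- roc_curve(c(10, 9, 1, 2), c("p", "p", "n", "n"), "p")
  expect_equal(r1$auc, 1.0)
  # 3 of 4 pairs correctly ordered
  r2 <- roc_curve(c(3, 5, 1, 4), c("p", "p", "n", "n"), "p")
  expect_equal(r2$auc, 0.75)
  # identical score multiset -> 0.5 by the half-tie convention
  r3 <- roc_curve(c(7, 7, 7, 7), c("p", "p", "n", "n"), "p")
  expect_equal(r3$auc, 0.5)
  # sensitivity is non-increasing as the threshold increases
  expect_true(all(diff(r2$points$sensitivity) <= 0))
  expect_error(roc_curve(c(1, 2), c("p", "p"), "p"), "both classes")
})

test_that("trapezoidal AUC equals the rank-sum oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:200) {
    n_pos <- sample(2:10, 1)
    n_neg <- sample(2:10, 1)
    # integer scores force frequent ties
    scores <- sample(0:6, n_pos + n_neg, replace = TRUE)
    labels <- c(rep("pos", n_pos), rep("neg", n_neg))
    roc <- roc_curve(scores, labels, "pos")
    expect_equal(roc$auc, naive_auc(scores, labels, "pos"))
  }
})

test_that("select_threshold maximises specificity under the sensitivity floor", {
  roc <- structure(list(points = data.frame(
    threshold = c(1, 5, 9),
    sensitivity = c(1.0, 0.95, 0.5),
    specificity = c(0.2, 0.8, 0.99)
  ), auc = NA, positive_label = "p"), class = "roc_curve")
  thr <- select_threshold(roc, min_sensitivity = 0.91)
  expect_equal(as.numeric(thr), 5)
  expect_equal(attr(thr, "specificity"), 0.8)
  # no point meets the constraint -> error naming the best attainable
  roc$points$sensitivity <- c(0.9, 0.85, 0.5)
  expect_error(select_threshold(roc, 0.91), "0.900")
  # perfect separation selects a perfect operating point
  perfect <- roc_curve(c(10, 9, 1, 2), c("p", "p", "n", "n"), "p")
  thr2 <- select_threshold(perfect, 0.91)
  expect_equal(attr(thr2, "sensitivity"), 1)
  expect_equal(attr(thr2, "specificity"), 1)
})

test_that("two_step_classify applies the two binning rules", {
  m <- rbind(zero = c(ORF_5 = 0, ORF_16 = 0, ORF_34 = 0, ORF_56 = 0),
             human = c(ORF_5 = 5, ORF_16 = 4, ORF_34 = 3, ORF_56 = 2),
             animal = c(ORF_5 = 8, ORF_16 = 0.1, ORF_34 = 0.1, ORF_56 = 0))
  pm <- profile_matrix(m)
  model <- two_step_model(orf_subset("s1", c("ORF_5", "ORF_16")), 2,
                          orf_subset("s2", c("ORF_16", "ORF_34", "ORF_56")), 5)
  out <- two_step_classify(pm, model)
  expect_equal(unname(out), c("unpolluted", "human_polluted", "nonhuman_polluted"))
  # thresholds are inclusive (score >= threshold is positive)
  model_edge <- two_step_model(orf_subset("s1", "ORF_5"), 8,
                               orf_subset("s2", "ORF_16"), 0.1)
  expect_equal(unname(two_step_classify(pm, model_edge)["animal"]),
               "human_polluted")
  expect_error(two_step_model(orf_subset("a", 1), -1, orf_subset("b", 2), 0),
               "non-negative")
})

test_that("degenerate thresholds force the documented classifications", {
  env_max <- stats::setNames(rep(1, 6), orf_id(1:6))
  src <- stats::setNames(rep(2, 6), orf_id(1:6))
  cfg <- monte_carlo_config(env_max, list(human = src, bovine = src,
                                          porcine = src),
                            n_iterations = 1, n_env_per_iteration = 5,
                            n_polluted_per_type = 5, seed = 2)
  it <- run_monte_carlo(cfg)[[1]]
  # thr1 = 0 marks everything polluted; thr2 = Inf forbids the human call
  model <- two_step_model(orf_subset("all", orf_id(1:6)), 0,
                          orf_subset("s2", orf_id(1:3)), Inf)
  perf <- evaluate_iterations(list(it), model)
  acc <- perf$per_type
  expect_equal(acc$mean[acc$type == "ENV_U"], 0)     # nothing can be unpolluted
  expect_equal(acc$mean[acc$type == "ENV_HGV"], 0)   # human call impossible
  expect_equal(acc$mean[acc$type == "ENV_BOV"], 1)
  expect_equal(acc$mean[acc$type == "ENV_PORC"], 1)
})

test_that("evaluate_iterations summarises accuracy with SEM across iterations", {
  env_max <- stats::setNames(rep(0.01, 6), orf_id(1:6))
  human <- stats::setNames(c(10, 10, 10, 0, 0, 0), orf_id(1:6))
  animal <- stats::setNames(c(0, 0, 0, 10, 10, 10), orf_id(1:6))
  cfg <- monte_carlo_config(env_max, list(human = human, bovine = animal,
                                          porcine = animal),
                            n_iterations = 2, n_env_per_iteration = 6,
                            n_polluted_per_type = 6, seed = 5)
  its <- run_monte_carlo(cfg)
  model <- two_step_model(orf_subset("s1", orf_id(1:6)), 0.5,
                          orf_subset("s2", orf_id(1:3)), 0.5)
  perf <- evaluate_iterations(its, model)
  expect_true(all(perf$per_type$mean >= 0 & perf$per_type$mean <= 1))
  expect_true(all(perf$per_type$sem >= 0))
  # two identical iterations -> SEM 0
  perf_same <- evaluate_iterations(list(its[[1]], its[[1]]), model)
  expect_equal(perf_same$per_type$sem, rep(0, 4))
  # single iteration -> SEM 0 by convention
  perf_one <- evaluate_iterations(its[1], model)
  expect_equal(perf_one$per_type$sem, rep(0, 4))
  expect_error(evaluate_iterations(list(), model), "at least one")
  # classification is invariant to profile order within an iteration
  it <- its[[1]]
  perm <- sample(nrow(it$profiles))
  it_perm <- list(profiles = profile_matrix(unclass(it$profiles)[perm, ],
                                            profile_meta(it$profiles)[perm, ]),
                  labels = it$labels[perm, ], iteration = 1)
  p1 <- evaluate_iterations(list(it), model)
  p2 <- evaluate_iterations(list(it_perm), model)
  expect_equal(p1$per_type, p2$per_type)
})

test_that("raising the step-1 threshold never increases step-1 sensitivity", {
  env_max <- stats::setNames(stats::runif(8, 0, 1), orf_id(1:8))
  src <- stats::setNames(stats::runif(8, 1, 4), orf_id(1:8))
  cfg <- monte_carlo_config(env_max, list(human = src, bovine = src,
                                          porcine = src),
                            n_iterations = 1, n_env_per_iteration = 20,
                            n_polluted_per_type = 20, seed = 12)
  it <- run_monte_carlo(cfg)[[1]]
  s2 <- orf_subset("s2", orf_id(1:4))
  sens <- vapply(c(0, 0.5, 1, 2, 4, 8), function(thr) {
    model <- two_step_model(orf_subset("s1", orf_id(1:8)), thr, s2, 1)
    evaluate_iterations(list(it), model)$step1_sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("calibration honours the sensitivity floor and models round-trip JSON", {
  co <- generate_cohort(cohort_spec(seed = 77))
  w <- mc_world_from_cohort(co)
  cfg <- monte_carlo_config(w$env_max, w$source_means, n_iterations = 1,
                            n_env_per_iteration = 40, n_polluted_per_type = 40,
                            seed = 6)
  it <- run_monte_carlo(cfg)[[1]]
  model <- calibrate_two_step(it)
  rocs <- attr(model, "rocs")
  s1 <- score_profiles(it$profiles, subset1_orfs())
  truth <- ifelse(it$labels$type == "ENV_U", "unpolluted", "polluted")
  achieved_sens <- mean(s1[truth == "polluted"] >= model$step1$threshold)
  expect_gte(achieved_sens, 0.91)
  expect_gte(rocs$step1$auc, 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$step1$threshold, model$step1$threshold)
  expect_equal(back$step2$subset$orf_ids, model$step2$subset$orf_ids)
})

test_that("combining the two subsets beats either single-subset model", {
  # built so subset-1 scores separate polluted from unpolluted and subset-2
  # scores separate human from animal pollution
  co <- generate_cohort(cohort_spec(seed = 505))
  w <- mc_world_from_cohort(co)
  cfg <- monte_carlo_config(w$env_max, w$source_means, n_iterations = 4,
                            n_env_per_iteration = 50, n_polluted_per_type = 50,
                            seed = 14)
  its <- run_monte_carlo(cfg)
  combined <- calibrate_two_step(its[[1]])
  s1_only <- calibrate_two_step(its[[1]], step2_subset = subset1_orfs())
  s2_only <- calibrate_two_step(its[[1]], step1_subset = subset2_orfs())
  held_out <- its[-1]
  acc_of <- function(model, type) {
    pt <- evaluate_iterations(held_out, model)$per_type
    pt$mean[pt$type == type]
  }
  expect_gte(acc_of(combined, "ENV_HGV"), acc_of(s1_only, "ENV_HGV"))
  expect_gte(acc_of(combined, "ENV_U"), acc_of(s2_only, "ENV_U"))
})
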