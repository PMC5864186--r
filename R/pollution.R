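#' Mean (source) profile of a group of data sets
#'
#' Element-wise arithmetic mean of per-ORF abundances, used to summarise a
#' source habitat (e.g. the average human gut virome signature over n = 12
#' data sets) before it is spiked into environmental profiles.
#'
#' @param x A `profile_matrix` (optionally restricted with `group`), or a
#'   list of `abundance_profile` objects.
#' @param group Optional habitat group label: average only the data sets
#'   whose `habitat_group` metadata matches.
#' @return Named numeric vector of mean hits/Mb per ORF.
#' @export
mean_profile <- function(x, group = NULL) {
  if (is.list(x) && !inherits(x, "profile_matrix") && !is.data.frame(x)) {
    x <- bind_profiles(x)
  }
  m <- unclass(as.matrix(x))
  if (!is.null(group)) {
    meta <- profile_meta(x)
    keep <- meta$habitat_group == group
    if (!any(keep)) {
      stop("no data sets with habitat_group = ", group)
    }
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    stop("cannot average zero profiles")
  }
  colMeans(m)
}

#' Per-ORF maxima over environmental viromes
#'
#' The per-ORF maximum relative abundance observed across environmental
#' viromes; the upper bound of the uniform distribution from which permuted
#' environmental baselines are drawn.
#'
#' @inheritParams mean_profile
#' @return Named numeric vector of maxima (hits/Mb).
#' @export
env_max_vector <- function(x, group = NULL) {
  m <- unclass(as.matrix(x))
  if (!is.null(group)) {
    meta <- profile_meta(x)
    keep <- meta$habitat_group == group
    if (!any(keep)) {
      stop("no data sets with habitat_group = ", group)
    }
    m <- m[keep, , drop = FALSE]
  }
  apply(m, 2L, max)
}

#' Simulate faecal pollution of an environmental profile
#'
#' Adds `strength` times the source-habitat mean profile to an environmental
#' profile, gene by gene: `out_i = env_i + strength * source_mean_i`.
#' Strength is a fraction in `[0, 1]`; the published "%" convention maps
#' 100% to 1.0.
#'
#' @param env Named numeric vector (or `abundance_profile`) of environmental
#'   per-ORF abundances.
#' @param source_mean Named numeric vector over the same ORF universe.
#' @param strength Fraction of the source mean to add, in `[0, 1]`.
#' @param source_label Label recorded with the output (e.g. `"human"`).
#' @return Named numeric vector with attributes `strength` and
#'   `source_label`.
#' @export
contaminate <- function(env, source_mean, strength, source_label = "human") {
  if (inherits(env, "abundance_profile")) {
    env <- env$abundance
  }
  if (!is.numeric(strength) || length(strength) != 1L ||
      strength < 0 || strength > 1) {
    stop("strength must be a single fraction in [0, 1]")
  }
  if (!setequal(names(env), names(source_mean))) {
    stop("environmental and source profiles must share an ORF universe")
  }
  out <- env + strength * source_mean[names(env)]
  attr(out, "strength") <- strength
  attr(out, "source_label") <- source_label
  out
}

#' Contamination dilution series
#'
#' One contaminated copy of every environmental profile at every strength,
#' emulating the published dilution experiment in which the human gut
#' signature was added to selected environmental viromes at strengths from
#' 100% down to 0.01%. The default grid uses decade steps over that range.
#'
#' @param env_profiles A `profile_matrix` of environmental viromes.
#' @param source_mean Named numeric source mean over the same ORF universe.
#' @param strengths Fractions in `[0, 1]`; default
#'   `c(1, 0.1, 0.01, 0.001, 1e-04)`.
#' @param source_label Source label recorded in the metadata.
#' @return A `profile_matrix` with `length(strengths) * nrow(env_profiles)`
#'   rows and metadata columns `source_label` and `strength`.
#' @export
contamination_series <- function(env_profiles, source_mean,
                                 strengths = c(1, 0.1, 0.01, 0.001, 1e-04),
                                 source_label = "human") {
  if (length(strengths) == 0L) {
    stop("strengths must be non-empty")
  }
  if (any(strengths < 0 | strengths > 1)) {
    stop("every strength must lie in [0, 1]")
  }
  m <- unclass(as.matrix(env_profiles))
  rows <- list()
  ids <- character(0)
  meta_strength <- numeric(0)
  meta_env <- character(0)
  for (s in strengths) {
    cont <- sweep(m, 2L, s * source_mean[colnames(m)], "+")
    rownames(cont) <- sprintf("%s_%s_s%g", rownames(m), source_label, s)
    rows[[length(rows) + 1L]] <- cont
    ids <- c(ids, rownames(cont))
    meta_strength <- c(meta_strength, rep(s, nrow(m)))
    meta_env <- c(meta_env, rownames(m))
  }
  out <- do.call(rbind, rows)
  profile_matrix(out, data.frame(
    dataset_id = ids,
    habitat_group = "contaminated",
    source_label = source_label,
    strength = meta_strength,
    env_dataset = meta_env,
    stringsAsFactors = FALSE
  ))
}

#' Randomly permuted environmental baseline profiles
#'
#' Each ORF's value is drawn independently from `Uniform[0, max_i]`, where
#' `max_i` is the maximum relative abundance observed for that ORF across
#' environmental viromes — the Monte-Carlo generator of synthetic
#' environmental backgrounds.
#'
#' @param env_max Named numeric vector of per-ORF maxima (hits/Mb).
#' @param n Number of profiles to draw (default 1).
#' @return If `n == 1`, a named numeric vector; otherwise an `n` x ORF
#'   matrix.
#' @export
permute_environmental_profile <- function(env_max, n = 1) {
  if (any(env_max < 0)) {
    stop("env_max must be non-negative")
  }
  p <- length(env_max)
  m <- matrix(stats::runif(n * p), n, p)
  m <- sweep(m, 2L, env_max, "*")
  colnames(m) <- names(env_max)
  if (n == 1L) m[1L, ] else m
}

#' Monte-Carlo pollution simulation configuration
#'
#' @param env_max Named per-ORF maxima over environmental viromes (the
#'   uniform upper bounds for permuted baselines).
#' @param source_means Named list of source mean profiles; default types are
#'   `human`, `bovine` and `porcine`.
#' @param n_iterations Number of iterations (published setting: 100).
#' @param n_env_per_iteration Uncontaminated permuted environmental profiles
#'   per iteration (published setting: 100).
#' @param n_polluted_per_type Polluted data sets per pollution type per
#'   iteration (published setting: 100).
#' @param seed Optional integer seed.
#' @return A `monte_carlo_config` list.
#' @export
monte_carlo_config <- function(env_max, source_means,
                               n_iterations = 100,
                               n_env_per_iteration = 100,
                               n_polluted_per_type = 100,
                               seed = NULL) {
  stopifnot(n_iterations >= 1, n_env_per_iteration >= 1,
            n_polluted_per_type >= 1)
  if (is.null(names(source_means)) || length(source_means) == 0L) {
    stop("source_means must be a named list of profiles")
  }
  for (sm in source_means) {
    if (!setequal(names(sm), names(env_max))) {
      stop("source means must share the ORF universe of env_max")
    }
  }
  structure(list(env_max = env_max, source_means = source_means,
                 n_iterations = as.integer(n_iterations),
                 n_env_per_iteration = as.integer(n_env_per_iteration),
                 n_polluted_per_type = as.integer(n_polluted_per_type),
                 seed = seed),
            class = "monte_carlo_config")
}

type_label <- function(source) {
  switch(source,
         human = "ENV_HGV", bovine = "ENV_BOV", porcine = "ENV_PORC",
         paste0("ENV_", toupper(source)))
}

#' Run the Monte-Carlo pollution simulation
#'
#' Per iteration: `n_env_per_iteration` uncontaminated permuted environmental
#' profiles (`ENV_U`), and for each pollution type `n_polluted_per_type`
#' profiles built by contaminating a freshly permuted environmental baseline
#' with that type's source mean at a strength drawn from `Uniform[0, 1]`.
#' All randomness is reproducible from the config seed.
#'
#' @param config A [monte_carlo_config()].
#' @return List of iterations; each a list with `profiles` (a
#'   `profile_matrix`) and `labels` (data.frame `dataset_id`, `type`,
#'   `strength`; `type` is `ENV_U`, `ENV_HGV`, `ENV_BOV` or `ENV_PORC`).
#' @export
run_monte_carlo <- function(config) {
  stopifnot(inherits(config, "monte_carlo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  env_max <- config$env_max
  lapply(seq_len(config$n_iterations), function(it) {
    env_u <- permute_environmental_profile(env_max, config$n_env_per_iteration)
    if (config$n_env_per_iteration == 1L) env_u <- matrix(env_u, 1L,
                                                          dimnames = list(NULL, names(env_max)))
    rownames(env_u) <- sprintf("it%d_ENV_U_%d", it,
                               seq_len(config$n_env_per_iteration))
    blocks <- list(env_u)
    types <- rep("ENV_U", nrow(env_u))
    strengths <- rep(0, nrow(env_u))
    for (source in names(config$source_means)) {
      base <- permute_environmental_profile(env_max, config$n_polluted_per_type)
      if (config$n_polluted_per_type == 1L) base <- matrix(base, 1L,
                                                           dimnames = list(NULL, names(env_max)))
      s <- stats::runif(config$n_polluted_per_type)
      polluted <- base + outer(s, config$source_means[[source]][colnames(base)])
      lab <- type_label(source)
      rownames(polluted) <- sprintf("it%d_%s_%d", it, lab,
                                    seq_len(nrow(polluted)))
      blocks[[length(blocks) + 1L]] <- polluted
      types <- c(types, rep(lab, nrow(polluted)))
      strengths <- c(strengths, s)
    }
    m <- do.call(rbind, blocks)
    labels <- data.frame(dataset_id = rownames(m), type = types,
                         strength = strengths, stringsAsFactors = FALSE)
    profiles <- profile_matrix(m, data.frame(
      dataset_id = rownames(m), habitat_group = types,
      strength = strengths, stringsAsFactors = FALSE))
    list(profiles = profiles, labels = labels, iteration = it)
  })
}
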