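#' Shifted log10 transform of relative abundances
#'
#' `log10(x + epsilon)` with a pseudocount of 1e-5 hits/Mb, so that absent
#' ORFs (x = 0) map to -5 rather than -Inf. Used for reporting group means
#' and for display; rank-based tests are unaffected by this strictly
#' monotone transform.
#'
#' @param x Non-negative numeric vector/matrix of hits/Mb values.
#' @param epsilon Pseudocount (default 1e-5).
#' @return Transformed values, in log10 hits/Mb.
#' @export
log10_shift <- function(x, epsilon = 1e-5) {
  if (any(x < 0)) {
    stop("log10_shift requires non-negative values")
  }
  stopifnot(epsilon > 0)
  log10(x + epsilon)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based comparison of two or more groups with the standard tie
#' correction; the H statistic is referred to a chi-square distribution with
#' `k - 1` degrees of freedom.
#'
#' @param groups List of numeric vectors, one per group (at least two
#'   groups, three values in total).
#' @return List with `statistic` (H), `p_value` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) {
    stop("need at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L)) {
    stop("every group needs at least one value")
  }
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3L) {
    stop("need at least three values in total")
  }
  k <- length(groups)
  if (length(unique(x)) == 1L) {
    warning("all values identical; H = 0, p = 1")
    return(list(statistic = 0, p_value = 1, df = k - 1L))
  }
  r <- rank(x)
  g <- rep(seq_len(k), sizes)
  rank_sums <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / tie_corr
  list(statistic = H,
       p_value = stats::pchisq(H, df = k - 1L, lower.tail = FALSE),
       df = k - 1L)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z-statistics from the pooled ranks with tie correction,
#' following a significant Kruskal-Wallis test. Two-sided p-values are
#' adjusted for the number of pairwise comparisons by Bonferroni
#' multiplication (capped at 1) by default; Holm and no adjustment are
#' available.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param method `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return data.frame with columns `group1`, `group2`, `z`, `mean_rank_diff`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, method = c("bonferroni", "holm", "none")) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2L) {
    stop("need at least two groups")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_len(k))
  }
  sizes <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_len(k), sizes)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  out <- data.frame(
    group1 = names(groups)[pairs[1L, ]],
    group2 = names(groups)[pairs[2L, ]],
    z = NA_real_, mean_rank_diff = NA_real_,
    p_unadjusted = NA_real_, p_adjusted = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_comp)) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    diff <- mean_ranks[i1] - mean_ranks[i2]
    se <- sqrt(var_term * (1 / sizes[i1] + 1 / sizes[i2]))
    z <- if (se == 0) 0 else diff / se
    out$z[j] <- z
    out$mean_rank_diff[j] <- diff
    out$p_unadjusted[j] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adjusted <- switch(method,
    bonferroni = pmin(1, out$p_unadjusted * n_comp),
    holm = stats::p.adjust(out$p_unadjusted, method = "holm"),
    none = out$p_unadjusted
  )
  out
}

#' Per-ORF habitat affiliation table
#'
#' For every ORF, compares its relative abundance across habitat groups
#' (Kruskal-Wallis followed by Dunn's pairwise comparisons on the pooled
#' ranks; the shifted log10 transform is applied for the reported group
#' means and leaves the rank-based tests unchanged) and flags:
#'
#' * `sig_vs_env` ("subset-1 analogue"): the omnibus Kruskal-Wallis test is
#'   significant at `alpha`, the focal group's mean abundance is greater
#'   than the environmental group's, and the Dunn-adjusted p-value of that
#'   comparison is at most `alpha`;
#' * `sig_vs_all` ("subset-2 analogue"): as above against *every* other
#'   group;
#' * `cosmopolitan`: the ORF is detected (abundance > 0) in at least half of
#'   all data sets.
#'
#' @param profiles A `profile_matrix` whose metadata has `habitat_group`.
#' @param focal_group The group of interest (default `"human_gut_virome"`).
#' @param env_group The environmental comparison group (default
#'   `"env_virome"`).
#' @param alpha Significance level for the flags (default 0.05).
#' @param method Dunn adjustment method (see [dunn_posthoc()]).
#' @return data.frame with one row per ORF: per-group mean log10 abundances
#'   (`mean_<group>` columns), `representation`, `p_vs_env`, `p_vs_all_max`
#'   (largest adjusted p over the other groups), and the three flags.
#' @export
orf_affiliation <- function(profiles, focal_group = "human_gut_virome",
                            env_group = "env_virome", alpha = 0.05,
                            method = "bonferroni") {
  meta <- profile_meta(profiles)
  if (is.null(meta$habitat_group)) {
    stop("profiles must carry habitat_group metadata")
  }
  groups_all <- unique(meta$habitat_group)
  if (!focal_group %in% groups_all) {
    stop("focal group not present: ", focal_group)
  }
  if (!env_group %in% groups_all) {
    stop("environmental group not present: ", env_group)
  }
  others <- setdiff(groups_all, focal_group)
  m <- unclass(profiles)
  out <- data.frame(orf_id = colnames(m), stringsAsFactors = FALSE)
  for (grp in groups_all) {
    out[[paste0("mean_", grp)]] <-
      colMeans(log10_shift(m[meta$habitat_group == grp, , drop = FALSE]))
  }
  out$representation <- colMeans(m > 0)
  out$kw_p <- NA_real_
  out$p_vs_env <- NA_real_
  out$p_vs_all_max <- NA_real_
  out$sig_vs_env <- FALSE
  out$sig_vs_all <- FALSE
  for (j in seq_len(ncol(m))) {
    vals <- split(m[, j], meta$habitat_group)
    vals <- vals[c(focal_group, others)]       # stable order, focal first
    if (length(unique(unlist(vals))) == 1L) {
      out$kw_p[j] <- 1
      out$p_vs_env[j] <- 1
      out$p_vs_all_max[j] <- 1
      next
    }
    kw <- suppressWarnings(kruskal_wallis(vals))
    out$kw_p[j] <- kw$p_value
    dunn <- suppressWarnings(dunn_posthoc(vals, method = method))
    focal_rows <- dunn$group1 == focal_group | dunn$group2 == focal_group
    dd <- dunn[focal_rows, , drop = FALSE]
    other_of <- ifelse(dd$group1 == focal_group, dd$group2, dd$group1)
    focal_mean <- mean(m[meta$habitat_group == focal_group, j])
    greater <- vapply(other_of, function(o) {
      focal_mean > mean(m[meta$habitat_group == o, j])
    }, logical(1))
    p_env <- dd$p_adjusted[other_of == env_group]
    out$p_vs_env[j] <- p_env
    out$p_vs_all_max[j] <- max(dd$p_adjusted)
    omnibus <- kw$p_value <= alpha   # post hoc only after a significant omnibus
    out$sig_vs_env[j] <- omnibus && p_env <= alpha && greater[other_of == env_group]
    out$sig_vs_all[j] <- omnibus && all(dd$p_adjusted <= alpha) && all(greater)
  }
  out$cosmopolitan <- out$representation >= 0.5
  out
}
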