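#' Square-root transform abundance profiles
#'
#' Relative abundance data are square-root transformed before Bray-Curtis
#' dissimilarities are computed, damping the influence of the most abundant
#' ORFs; shape, labels and metadata are unchanged.
#'
#' @param x A `profile_matrix` or non-negative numeric matrix.
#' @return Object of the same class with element-wise square roots.
#' @export
sqrt_transform <- function(x) {
  if (any(unclass(x) < 0)) {
    stop("sqrt_transform requires non-negative values")
  }
  if (inherits(x, "profile_matrix")) {
    profile_matrix(sqrt(unclass(x)), profile_meta(x))
  } else {
    sqrt(x)
  }
}

#' Bray-Curtis dissimilarity matrix
#'
#' For non-negative abundance vectors u, v the Bray-Curtis dissimilarity is
#' `sum(|u_i - v_i|) / sum(u_i + v_i)`, bounded in `[0, 1]`. A pair of
#' all-zero profiles has an undefined ratio and is assigned distance 0 by
#' convention, with a warning.
#'
#' @param x A `profile_matrix` or non-negative numeric matrix with at least
#'   two rows.
#' @return A [stats::dist] object with data set labels.
#' @export
bray_curtis <- function(x) {
  m <- unclass(as.matrix(x))
  if (nrow(m) < 2L) {
    stop("need at least two profiles to form a distance matrix")
  }
  if (any(m < 0)) {
    stop("Bray-Curtis requires non-negative abundances")
  }
  rs <- rowSums(m)
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    ji <- (i + 1L):n
    num <- colSums(abs(t(m[ji, , drop = FALSE]) - m[i, ]))
    den <- rs[ji] + rs[i]
    dij <- ifelse(den == 0, 0, num / den)
    d[ji, i] <- d[i, ji] <- dij
  }
  if (any(rs == 0) && sum(rs == 0) >= 2L) {
    warning("all-zero profile pair(s): Bray-Curtis set to 0 by convention")
  }
  stats::as.dist(structure(d, dimnames = list(rownames(m), rownames(m))))
}

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions by minimising Kruskal's
#' stress-1, `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `d` are
#' configuration distances and `dhat` the disparities obtained by isotonic
#' (monotone) regression of `d` on the rank order of the input
#' dissimilarities (primary treatment of ties). Each random start is refined
#' by alternating isotonic regression with a Guttman-transform (SMACOF)
#' update; the best configuration over `n_starts` starts is returned,
#' centred at the origin.
#'
#' @param d A [stats::dist] or symmetric zero-diagonal matrix.
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of random starts (default 1000, matching the
#'   stringent published setting; reduce for exploratory work).
#' @param max_iter Maximum iterations per start (default 300).
#' @param tol Convergence tolerance on the change in stress (default 1e-6).
#' @param seed Optional integer seed for reproducible starts.
#' @return An `nmds_fit`: list with `points` (n x k matrix), `stress`,
#'   `n_starts` and `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 1000, max_iter = 300, tol = 1e-6,
                 seed = NULL) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D)) || any(diag(D) != 0) || any(D < 0)) {
    stop("d must be a symmetric, non-negative, zero-diagonal dissimilarity matrix")
  }
  n <- nrow(D)
  stopifnot(k >= 1, n_starts >= 1, n > k)
  if (!is.null(seed)) set.seed(seed)

  low <- lower.tri(D)
  delta <- D[low]
  ord <- order(delta)                      # ties resolved later against d
  best <- NULL
  for (s in seq_len(n_starts)) {
    X <- matrix(stats::rnorm(n * k), n, k)
    fit <- nmds_one_start(X, D, delta, low, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
    }
  }
  pts <- scale(best$X, center = TRUE, scale = FALSE)
  rownames(pts) <- rownames(D)
  structure(list(points = pts, stress = best$stress, n_starts = n_starts,
                 converged = best$converged),
            class = "nmds_fit")
}

nmds_one_start <- function(X, D, delta, low, max_iter, tol) {
  n <- nrow(X)
  prev_stress <- Inf
  converged <- FALSE
  stress <- NA_real_
  for (it in seq_len(max_iter)) {
    dX <- as.matrix(stats::dist(X))
    dv <- dX[low]
    # primary tie treatment: order by dissimilarity, breaking ties by the
    # current configuration distance, then pool-adjacent-violators
    o <- order(delta, dv)
    dhat <- numeric(length(dv))
    dhat[o] <- stats::isoreg(dv[o])$yf
    ss_d <- sum(dv^2)
    if (ss_d == 0) {
      stress <- 0
      converged <- TRUE
      break
    }
    stress <- sqrt(sum((dv - dhat)^2) / ss_d)
    if (abs(prev_stress - stress) < tol) {
      converged <- TRUE
      break
    }
    prev_stress <- stress
    # Guttman transform with disparities dhat
    B <- matrix(0, n, n)
    ratio <- matrix(0, n, n)
    full_dhat <- matrix(0, n, n)
    full_dhat[low] <- dhat
    full_dhat <- full_dhat + t(full_dhat)
    nz <- dX > 0
    ratio[nz] <- full_dhat[nz] / dX[nz]
    B <- -ratio
    diag(B) <- rowSums(ratio)
    X <- B %*% X / n
  }
  list(X = X, stress = stress, converged = converged)
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("nMDS: %d points in %d dimensions, stress-1 = %.4f (%d starts%s)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts,
              if (x$converged) "" else ", best start not converged"))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of separation between a-priori groups on a dissimilarity
#' matrix. The statistic is `R = (mean rank between - mean rank within) /
#' (M/2)`, where `M = n(n-1)/2` is the number of pairwise dissimilarities and
#' ranks use mean values for ties. R approaches 1 as groups separate
#' completely and is near 0 when grouping is arbitrary. Significance comes
#' from permuting the group labels: `p = (1 + #{R_perm >= R_obs}) /
#' (1 + n_permutations)`. With `n_permutations = "exact"` all distinct label
#' arrangements are enumerated and `p` is the exact proportion (the observed
#' arrangement included).
#'
#' @param d A [stats::dist] or symmetric dissimilarity matrix.
#' @param groups Group labels, one per observation; at least two groups with
#'   at least two members each.
#' @param n_permutations Number of random permutations (default 999), or
#'   `"exact"` for exhaustive enumeration (small n only).
#' @param seed Optional integer seed.
#' @return An `anosim_result`: list with `R`, `p_value`, `n_permutations`,
#'   `group_labels` and the permutation distribution `perm_R`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) {
    stop("need one group label per observation")
  }
  sizes <- table(groups)
  if (length(sizes) < 2L) {
    stop("ANOSIM needs at least two groups")
  }
  if (any(sizes < 2L)) {
    stop("every group must have at least two members")
  }
  low <- lower.tri(D)
  dv <- D[low]
  if (length(unique(dv)) == 1L) {
    warning("all dissimilarities identical; R = 0 by convention")
  }
  r <- rank(dv)                     # mean ranks for ties
  M <- length(r)
  pair_i <- row(D)[low]
  pair_j <- col(D)[low]
  R_of <- function(lab) {
    within <- lab[pair_i] == lab[pair_j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- R_of(groups)

  exact <- identical(n_permutations, "exact")
  if (exact) {
    perms <- multiset_permutations(groups)
    perm_R <- vapply(perms, R_of, numeric(1))
    p <- mean(perm_R >= R_obs)      # observed arrangement is enumerated
    n_perm <- length(perm_R)
  } else {
    if (!is.null(seed)) set.seed(seed)
    n_perm <- as.integer(n_permutations)
    stopifnot(n_perm >= 1L)
    perm_R <- vapply(seq_len(n_perm), function(i) R_of(sample(groups)),
                     numeric(1))
    p <- (1 + sum(perm_R >= R_obs)) / (1 + n_perm)
  }
  structure(list(R = R_obs, p_value = p, n_permutations = n_perm,
                 group_labels = groups, perm_R = perm_R, exact = exact),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s%d permutations)\n",
              x$R, x$p_value, if (x$exact) "exact, " else "", x$n_permutations))
  invisible(x)
}

# all distinct arrangements of a label multiset (exhaustive ANOSIM null)
multiset_permutations <- function(labels) {
  uniq <- unique(labels)
  counts <- as.integer(table(factor(labels, levels = uniq)))
  n <- length(labels)
  out <- list()
  recur <- function(prefix, counts) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (k in seq_along(uniq)) {
      if (counts[k] > 0L) {
        counts[k] <- counts[k] - 1L
        recur(c(prefix, uniq[k]), counts)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  recur(character(0), counts)
  out
}
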