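# Independent brute-force oracles used across the suite. These deliberately
# use naive loop-based formulations, not the package's vectorised code paths.

# ANOSIM R by direct loops over the distance matrix
naive_anosim_R <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  dv <- c()
  within <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dv <- c(dv, D[i, j])
      within <- c(within, labels[i] == labels[j])
    }
  }
  r <- rank(dv)
  M <- length(r)
  (mean(r[!within]) - mean(r[within])) / (M / 2)
}

# exhaustive enumeration of all distinct label arrangements (multiset),
# built from nested combn choices, independent of the package's recursion
enumerate_label_arrangements <- function(labels) {
  uniq <- unique(labels)
  counts <- table(factor(labels, levels = uniq))
  n <- length(labels)
  place <- function(positions, remaining_labels) {
    if (length(remaining_labels) == 1L) {
      out <- character(n)
      out[positions[[1L]]] <- remaining_labels[1L]
      return(list(out))
    }
    lab <- remaining_labels[1L]
    k <- counts[[lab]]
    free <- positions[[1L]]
    choices <- utils::combn(free, k, simplify = FALSE)
    res <- list()
    for (ch in choices) {
      rest <- place(list(setdiff(free, ch)), remaining_labels[-1L])
      for (r in rest) {
        r[ch] <- lab
        res[[length(res) + 1L]] <- r
      }
    }
    res
  }
  place(list(seq_len(n)), uniq)
}

# pairwise-probability AUC oracle: P(score_pos > score_neg) + 0.5 P(equal)
naive_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Bray-Curtis by direct per-pair formula evaluation
naive_bray_curtis <- function(u, v) {
  sum(abs(u - v)) / sum(u + v)
}

# small labelled profile matrix for reuse
tiny_profile_matrix <- function() {
  m <- rbind(
    a = c(ORF_1 = 1.5, ORF_2 = 0.5, ORF_3 = 0),
    b = c(ORF_1 = 0, ORF_2 = 2, ORF_3 = 1),
    c = c(ORF_1 = 4, ORF_2 = 0, ORF_3 = 0.25),
    d = c(ORF_1 = 0, ORF_2 = 0, ORF_3 = 0)
  )
  profile_matrix(m, data.frame(
    dataset_id = rownames(m),
    habitat_group = c("env_virome", "env_virome", "human_gut_virome",
                      "human_gut_virome"),
    stringsAsFactors = FALSE
  ))
}

write_hit_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
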