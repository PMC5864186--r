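#' Synthetic cohort specification
#'
#' Describes a habitat-structured cohort of per-ORF abundance profiles with
#' the statistical features the source-tracking analysis assumes: a sparse
#' environmental background, ORF subsets enriched in gut viromes, and high
#' inter-individual variability (zero-inflated lognormal draws). Each ORF is
#' assigned one of four archetypes:
#'
#' * `human_gut_specific` — elevated occurrence and abundance only in human
#'   gut viromes (defaults at ORFs 16, 34 and 56, the subset-2 analogues);
#' * `gut_shared` — elevated in all gut viromes, human and animal (defaults
#'   at the remaining subset-1 ORF ids);
#' * `cosmopolitan` — moderate abundance in every habitat;
#' * `background` — sparse and weak everywhere (all remaining ORFs).
#'
#' @param n_orfs Number of ORFs (default 70, ids `ORF_1..ORF_70`).
#' @param group_sizes Named integer vector of data sets per habitat group.
#'   The default uses 12 human gut viromes (the published human-gut cohort
#'   size) and 12 data sets in each other virome group.
#' @param archetypes Named list mapping archetype name to integer ORF
#'   numbers; unassigned ORFs are `background`.
#' @param params Archetype/group generative parameters; see
#'   [default_archetype_params()].
#' @param total_bp Nominal data set size in bp recorded in the metadata.
#' @param seed Optional integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_orfs = 70,
                        group_sizes = c(human_gut_virome = 12,
                                        bovine_virome = 12,
                                        porcine_virome = 12,
                                        env_virome = 12),
                        archetypes = default_archetypes(),
                        params = default_archetype_params(),
                        total_bp = 1e8,
                        seed = NULL) {
  stopifnot(n_orfs >= 1)
  if (is.null(names(group_sizes)) || any(group_sizes < 1)) {
    stop("group_sizes must be a named vector of positive counts")
  }
  arch <- rep("background", n_orfs)
  for (a in names(archetypes)) {
    ids <- archetypes[[a]]
    if (any(ids > n_orfs)) {
      stop("archetype ", a, " references ORFs beyond n_orfs")
    }
    arch[ids] <- a
  }
  structure(list(n_orfs = as.integer(n_orfs),
                 group_sizes = group_sizes,
                 orf_archetype = stats::setNames(arch, orf_id(seq_len(n_orfs))),
                 params = params, total_bp = total_bp, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_archetypes <- function() {
  list(
    human_gut_specific = c(16, 34, 56),
    gut_shared = c(5, 18, 20, 21, 22, 23, 25, 36, 43, 44, 59, 61, 67),
    cosmopolitan = c(1, 2, 3, 4, 6, 7, 8, 9, 10, 11)
  )
}

#' Default generative parameters for synthetic cohorts
#'
#' One row per (archetype, habitat group) combination; `group = "*"` is a
#' wildcard matched when no exact row exists. `occurrence` is the
#' probability an ORF is detected at all in a data set (zero inflation);
#' `mean_abundance` is the lognormal scale in hits/Mb (the exact value
#' recovered as dispersion tends to 0); `sdlog` the lognormal dispersion,
#' set to 1 in gut groups to emulate the high inter-individual variability
#' of human gut viromes.
#'
#' @return data.frame with columns `archetype`, `group`, `occurrence`,
#'   `mean_abundance`, `sdlog`.
#' @export
default_archetype_params <- function() {
  rbind(
    data.frame(archetype = "human_gut_specific",
               group = c("human_gut_virome", "bovine_virome", "porcine_virome", "*"),
               occurrence = c(0.9, 0.2, 0.2, 0.05),
               mean_abundance = c(20, 0.5, 0.5, 0.05),
               sdlog = c(1, 1, 1, 1)),
    data.frame(archetype = "gut_shared",
               group = c("human_gut_virome", "bovine_virome", "porcine_virome", "*"),
               occurrence = c(0.8, 0.8, 0.8, 0.05),
               mean_abundance = c(8, 8, 8, 0.05),
               sdlog = c(1, 1, 1, 1)),
    data.frame(archetype = "cosmopolitan", group = "*",
               occurrence = 0.9, mean_abundance = 2, sdlog = 0.7),
    data.frame(archetype = "background", group = "*",
               occurrence = 0.15, mean_abundance = 0.2, sdlog = 1)
  )
}

#' Null cohort specification (no group structure)
#'
#' Identical generative parameters in every habitat group; used to check
#' type-I error calibration of the ordination and affiliation statistics.
#'
#' @param n_orfs Number of ORFs (default 10).
#' @param group_sizes Named group sizes (default four groups of 8).
#' @param seed Optional seed.
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(n_orfs = 10,
                             group_sizes = c(human_gut_virome = 8,
                                             bovine_virome = 8,
                                             porcine_virome = 8,
                                             env_virome = 8),
                             seed = NULL) {
  cohort_spec(
    n_orfs = n_orfs, group_sizes = group_sizes,
    archetypes = list(),
    params = data.frame(archetype = "background", group = "*",
                        occurrence = 0.6, mean_abundance = 1, sdlog = 1),
    seed = seed
  )
}

param_lookup <- function(params, archetype, group) {
  rows <- params[params$archetype == archetype, , drop = FALSE]
  hit <- rows[rows$group == group, , drop = FALSE]
  if (nrow(hit) == 0L) {
    hit <- rows[rows$group == "*", , drop = FALSE]
  }
  if (nrow(hit) == 0L) {
    stop("no parameters for archetype ", archetype, " in group ", group)
  }
  hit[1L, ]
}

#' Generate a synthetic habitat-structured cohort
#'
#' For every data set and ORF, the abundance is 0 with probability
#' `1 - occurrence` and otherwise a lognormal draw with median
#' `mean_abundance` and dispersion `sdlog`, per the ORF's archetype and the
#' data set's habitat group. Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `profile_matrix` with `habitat_group` and `total_bp` metadata.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  orfs <- names(spec$orf_archetype)
  groups <- names(spec$group_sizes)
  rows <- list()
  ids <- character(0)
  habs <- character(0)
  for (g in groups) {
    n_g <- spec$group_sizes[[g]]
    occ <- numeric(spec$n_orfs)
    mu <- numeric(spec$n_orfs)
    sdl <- numeric(spec$n_orfs)
    for (j in seq_len(spec$n_orfs)) {
      p <- param_lookup(spec$params, spec$orf_archetype[[j]], g)
      occ[j] <- p$occurrence
      mu[j] <- log(p$mean_abundance)
      sdl[j] <- p$sdlog
    }
    for (i in seq_len(n_g)) {
      present <- stats::runif(spec$n_orfs) < occ
      vals <- stats::rlnorm(spec$n_orfs, meanlog = mu, sdlog = sdl)
      rows[[length(rows) + 1L]] <- ifelse(present, vals, 0)
      ids <- c(ids, sprintf("%s_%02d", g, i))
      habs <- c(habs, g)
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  colnames(m) <- orfs
  profile_matrix(m, data.frame(dataset_id = ids, habitat_group = habs,
                               total_bp = spec$total_bp, assembled = FALSE,
                               stringsAsFactors = FALSE))
}

#' Derive the Monte-Carlo world from a cohort
#'
#' Computes the per-ORF environmental maxima and the per-source mean
#' profiles that parameterise [run_monte_carlo()].
#'
#' @param cohort A `profile_matrix` with `habitat_group` metadata.
#' @param env_group Environmental virome group label.
#' @param source_groups Named character vector mapping source type to
#'   habitat group.
#' @return List with `env_max` and `source_means` (named list).
#' @export
mc_world_from_cohort <- function(cohort, env_group = "env_virome",
                                 source_groups = c(human = "human_gut_virome",
                                                   bovine = "bovine_virome",
                                                   porcine = "porcine_virome")) {
  list(
    env_max = env_max_vector(cohort, env_group),
    source_means = lapply(as.list(source_groups), function(g) {
      mean_profile(cohort, g)
    })
  )
}

#' Emit a hit-table fixture that reproduces a target profile matrix
#'
#' Writes, per data set, a 12-column hit table containing exactly the valid
#' alignments needed to reproduce the target hits/Mb values through
#' [compute_profile()], plus decoy rows that each violate exactly one
#' validity threshold (identity 34.9, query coverage 0.49, or e-value
#' 1.1e-5). Valid rows sit exactly on the published thresholds (identity
#' 35.0, coverage 0.50, e-value 1e-5), so a successful round trip also
#' establishes that the filter boundaries are inclusive. The data set size
#' (total_bp) is chosen so that every target abundance corresponds to an
#' integer hit count; non-representable targets are an error.
#'
#' @param target A `profile_matrix` of desired hits/Mb values.
#' @param out_dir Directory for the fixture files (created if needed).
#' @param n_decoys Decoy rows per data set (default 3, one per threshold).
#' @param max_mb Largest data set size (in Mb) tried when searching for an
#'   exact integer representation (default 10000).
#' @return A `fixture_bundle`: list with `hit_paths` (named by dataset),
#'   `lengths_path`, `metadata_path`, `orf_ids` and `target`.
#' @export
generate_hit_table_fixture <- function(target, out_dir, n_decoys = 3,
                                       max_mb = 10000) {
  stopifnot(inherits(target, "profile_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  orfs <- colnames(target)
  meta_in <- profile_meta(target)
  qlen <- 100L
  read_len_rows <- character(0)
  hit_paths <- character(0)
  total_bps <- numeric(nrow(target))

  decoy_row <- function(read, orf, kind) {
    # each decoy violates exactly one threshold
    switch(kind,
      identity = sprintf("%s\t%s\t34.9\t50\t10\t0\t1\t100\t1\t50\t1e-20\t80.0",
                         read, orf),
      coverage = sprintf("%s\t%s\t80.0\t49\t5\t0\t1\t49\t1\t49\t1e-20\t80.0",
                         read, orf),
      evalue = sprintf("%s\t%s\t80.0\t50\t5\t0\t1\t100\t1\t50\t1.1e-5\t30.0",
                       read, orf)
    )
  }

  for (i in seq_len(nrow(target))) {
    ds <- rownames(target)[i]
    ab <- unclass(target)[i, ]
    mb <- representable_mb(ab, max_mb)
    if (is.na(mb)) {
      stop("target abundances for ", ds, " are not representable as integer ",
           "hit counts at any size up to ", max_mb,
           " Mb; choose rational hits/Mb values")
    }
    counts <- round(ab * mb)
    lines <- character(0)
    read_no <- 0L
    for (j in seq_along(orfs)) {
      if (counts[j] > 0) {
        for (h in seq_len(counts[j])) {
          read_no <- read_no + 1L
          read <- sprintf("%s_read%d", ds, read_no)
          # exactly on the validity boundary: 35.0% identity, 50/100
          # coverage, e-value 1e-5
          lines <- c(lines, sprintf(
            "%s\t%s\t35.0\t50\t25\t0\t1\t50\t1\t50\t1e-5\t60.0", read, orfs[j]))
          read_len_rows <- c(read_len_rows, sprintf("%s\t%d", read, qlen))
        }
      }
    }
    for (dk in seq_len(n_decoys)) {
      read_no <- read_no + 1L
      read <- sprintf("%s_read%d", ds, read_no)
      kind <- c("identity", "coverage", "evalue")[(dk - 1L) %% 3L + 1L]
      lines <- c(lines, decoy_row(read, orfs[((dk - 1L) %% length(orfs)) + 1L], kind))
      read_len_rows <- c(read_len_rows, sprintf("%s\t%d", read, qlen))
    }
    path <- file.path(out_dir, paste0("hits_", ds, ".tsv"))
    writeLines(c("# synthetic fixture hit table", lines), path)
    hit_paths[ds] <- path
    total_bps[i] <- mb * 1e6
  }

  lengths_path <- file.path(out_dir, "read_lengths.tsv")
  writeLines(read_len_rows, lengths_path)
  metadata_path <- file.path(out_dir, "metadata.csv")
  meta_out <- data.frame(
    dataset_id = rownames(target),
    habitat_group = if ("habitat_group" %in% names(meta_in))
      meta_in$habitat_group else "unknown",
    total_bp = total_bps,
    assembled = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.csv(meta_out, metadata_path, row.names = FALSE)
  structure(list(hit_paths = hit_paths, lengths_path = lengths_path,
                 metadata_path = metadata_path, orf_ids = orfs,
                 target = target),
            class = "fixture_bundle")
}

# smallest Mb size (integer) for which all abundances become integer counts
representable_mb <- function(ab, max_mb) {
  for (mb in seq_len(max_mb)) {
    k <- ab * mb
    if (all(abs(k - round(k)) < 1e-9)) {
      return(mb)
    }
  }
  NA_integer_
}

#' Recompute a profile matrix from a fixture bundle
#'
#' Runs the full profiling stage (hit-table parsing, validity filtering,
#' hits/Mb normalisation) over every data set of a fixture bundle.
#'
#' @param bundle A `fixture_bundle` from [generate_hit_table_fixture()].
#' @param ... Passed to [compute_profile()] (e.g. relaxed thresholds).
#' @return A `profile_matrix` over the bundle's ORF universe.
#' @export
profiles_from_fixture <- function(bundle, ...) {
  lengths <- read_length_table(bundle$lengths_path)
  meta <- read_metadata(bundle$metadata_path)
  profs <- lapply(seq_len(nrow(meta)), function(i) {
    ds <- meta$dataset_id[i]
    hits <- read_hit_table(bundle$hit_paths[[ds]], orientation = "read_query")
    compute_profile(hits, lengths, bundle$orf_ids,
                    meta = as.list(meta[i, , drop = FALSE]), ...)
  })
  bind_profiles(profs)
}
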