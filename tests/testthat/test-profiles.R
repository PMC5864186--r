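test_that("read_hit_table parses 12-column tables and rejects malformed rows", {
  path <- write_hit_lines(c(
    "# comment line",
    "read1\tORF_16\t40.0\t50\t30\t0\t1\t150\t1\t50\t1e-10\t80.1",
    "read2\tORF_34\t90.0\t60\t6\t1\t5\t64\t2\t61\t2.5e-8\t120.7"
  ))
  hits <- read_hit_table(path, orientation = "read_query")
  expect_s3_class(hits, "hit_table")
  expect_equal(nrow(hits), 2L)
  expect_identical(attr(hits, "orientation"), "read_query")
  expect_equal(hits$percent_identity, c(40.0, 90.0))
  expect_equal(hits$evalue, c(1e-10, 2.5e-8))
  expect_equal(hits$query_start, c(1, 5))
  expect_equal(hits$query_end, c(150, 64))
  expect_equal(hits$bit_score, c(80.1, 120.7))

  # empty file (comments only) -> zero rows, not an error
  empty <- read_hit_table(write_hit_lines("# nothing"), "read_query")
  expect_equal(nrow(empty), 0L)

  # wrong column count names the offending line
  bad <- write_hit_lines(c(
    "read1\tORF_16\t40.0\t50\t30\t0\t1\t150\t1\t50\t1e-10\t80.1",
    "read2\tORF_16\t40.0\t50\t30\t0\t1\t150\t1\t50\t1e-10"
  ))
  expect_error(read_hit_table(bad, "read_query"), "line 2")
  # non-numeric value in a numeric column
  nonnum <- write_hit_lines("read1\tORF_16\tabc\t50\t30\t0\t1\t150\t1\t50\t1e-10\t80.1")
  expect_error(read_hit_table(nonnum, "read_query"), "non-numeric")
})

test_that("hit validity thresholds are inclusive at the published boundaries", {
  mk <- function(pid, qs, qe, ev) {
    data.frame(query_id = "q", subject_id = "ORF_1", percent_identity = pid,
               alignment_length = qe - qs + 1, mismatches = 0, gap_opens = 0,
               query_start = qs, query_end = qe, subject_start = 1,
               subject_end = 50, evalue = ev, bit_score = 50)
  }
  qlen <- c(q = 100)
  # exactly on every boundary: valid
  expect_true(is_valid_hit(mk(35.0, 1, 50, 1e-5), qlen))
  # each criterion failing alone: invalid
  expect_false(is_valid_hit(mk(34.9, 1, 90, 1e-20), qlen))
  expect_false(is_valid_hit(mk(90, 1, 49, 1e-20), qlen))
  expect_false(is_valid_hit(mk(90, 1, 90, 1.1e-5), qlen))
  # unknown query length is an error, not silently invalid
  expect_error(is_valid_hit(mk(90, 1, 90, 1e-20), c(other = 100)),
               "no length entry")
})

test_that("compute_profile counts valid hits per ORF and normalises per Mb", {
  lines <- c(
    sprintf("r%d\tORF_16\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-20\t90", 1:3),
    "r4\tORF_34\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-20\t90",
    # invalid rows must not count
    "r5\tORF_16\t34.9\t100\t20\t0\t1\t100\t1\t100\t1e-20\t90",
    "r6\tORF_16\t80.0\t49\t10\t0\t1\t49\t1\t49\t1e-20\t90"
  )
  hits <- read_hit_table(write_hit_lines(lines), "read_query")
  qlen <- stats::setNames(rep(100, 6), paste0("r", 1:6))
  orfs <- orf_id(c(16, 34, 56))
  meta <- list(dataset_id = "d1", total_bp = 2e6)
  p <- compute_profile(hits, qlen, orfs, meta)
  expect_equal(p$abundance, c(ORF_16 = 1.5, ORF_34 = 0.5, ORF_56 = 0))
  expect_equal(cumulative_abundance(p), 2.0)

  # doubling total_bp halves every abundance (exact scale invariance)
  p2 <- compute_profile(hits, qlen, orfs, list(dataset_id = "d1", total_bp = 4e6))
  expect_equal(p2$abundance, p$abundance / 2)

  # duplicating identical rows never changes the profile (best-per-pair collapse)
  dup <- read_hit_table(write_hit_lines(c(lines, lines)), "read_query")
  p3 <- compute_profile(dup, qlen, orfs, meta)
  expect_equal(p3$abundance, p$abundance)

  # no valid hits -> all-zero profile
  none <- read_hit_table(write_hit_lines(lines[5:6]), "read_query")
  p0 <- compute_profile(none, qlen, orfs, meta)
  expect_equal(unname(p0$abundance), c(0, 0, 0))

  # hit to an ORF outside the declared universe is an error
  expect_error(compute_profile(hits, qlen, orf_id(c(16, 56)), meta),
               "outside the declared universe")
})

test_that("a query hitting several ORFs counts once per ORF unless best_orf_only", {
  lines <- c(
    "r1\tORF_16\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-20\t90",
    "r1\tORF_34\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-10\t70"
  )
  hits <- read_hit_table(write_hit_lines(lines), "read_query")
  qlen <- c(r1 = 100)
  meta <- list(dataset_id = "d", total_bp = 1e6)
  p <- compute_profile(hits, qlen, orf_id(c(16, 34)), meta)
  expect_equal(p$abundance, c(ORF_16 = 1, ORF_34 = 1))
  pb <- compute_profile(hits, qlen, orf_id(c(16, 34)), meta,
                        best_orf_only = TRUE)
  expect_equal(pb$abundance, c(ORF_16 = 1, ORF_34 = 0))  # lower e-value wins
})

test_that("orf_query orientation measures coverage on the ORF protein side", {
  # ORF protein of length 200 as query; alignment covers 100/200 = 0.5
  lines <- "ORF_16\tcontig7\t45.0\t100\t55\t0\t1\t100\t10\t109\t1e-8\t88"
  hits <- read_hit_table(write_hit_lines(lines), "orf_query")
  p <- compute_profile(hits, c(ORF_16 = 200), orf_id(16),
                       list(dataset_id = "wc", total_bp = 1e6))
  expect_equal(unname(p$abundance), 1)
  # at 201 residues coverage drops below half and the hit is invalid
  p2 <- compute_profile(hits, c(ORF_16 = 201), orf_id(16),
                        list(dataset_id = "wc", total_bp = 1e6))
  expect_equal(unname(p2$abundance), 0)
})

test_that("cumulative_abundance sums over subsets and validates membership", {
  pm <- tiny_profile_matrix()
  expect_equal(unname(cumulative_abundance(pm)), c(2, 3, 4.25, 0))
  expect_equal(unname(cumulative_abundance(pm, c("ORF_1", "ORF_3"))),
               c(1.5, 1, 4.25, 0))
  expect_equal(unname(cumulative_abundance(pm, character(0))), rep(0, 4))
  expect_error(cumulative_abundance(pm, "ORF_99"), "not in profile universe")
})

test_that("filter_min_orf_representation applies the two-distinct-ORF rule", {
  pm <- tiny_profile_matrix()   # positives per row: 2, 2, 2, 0
  m <- unclass(pm)
  m["b", ] <- c(0, 2, 0)        # row with one positive
  pm <- profile_matrix(m, profile_meta(pm))
  kept <- filter_min_orf_representation(pm, 2)
  expect_equal(rownames(kept), c("a", "c"))
  expect_equal(profile_meta(kept)$dataset_id, c("a", "c"))
  # min_distinct = 1 keeps every profile with any positive; 0 is the identity
  expect_equal(rownames(filter_min_orf_representation(pm, 1)), c("a", "b", "c"))
  expect_equal(rownames(filter_min_orf_representation(pm, 0)), rownames(pm))
})

test_that("profile matrix CSV round-trips", {
  pm <- tiny_profile_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_matrix(pm, path)
  back <- read_profile_matrix(path)
  expect_equal(unclass(back)[, colnames(pm)], unclass(pm)[, ],
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(pm))
})

test_that("metadata reader enforces unique ids and positive sizes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dataset_id,habitat_group,total_bp,assembled",
               "d1,env_virome,2000000,FALSE",
               "d2,human_gut_virome,1000000,TRUE"), path)
  meta <- read_metadata(path)
  expect_equal(meta$total_bp, c(2e6, 1e6))
  writeLines(c("dataset_id,habitat_group,total_bp,assembled",
               "d1,env_virome,0,FALSE"), path)
  expect_error(read_metadata(path), "positive")
  writeLines(c("dataset_id,habitat_group,total_bp,assembled",
               "d1,env_virome,10,FALSE", "d1,env_virome,20,FALSE"), path)
  expect_error(read_metadata(path), "unique")
})
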