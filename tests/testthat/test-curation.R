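test_that("mismatch score costs H/E = 2, C vs structured = 1, gaps and matches 0", {
  expect_equal(ss_mismatch_score("HHHH", "HHHH"), 0)
  expect_equal(ss_mismatch_score("HHHH", "EEEE"), 8)
  expect_equal(ss_mismatch_score("HCE", "CCH"), 3)
  expect_equal(ss_mismatch_score("H-E", "HE-"), 0)
  expect_equal(ss_mismatch_score("", ""), 0)
  expect_error(ss_mismatch_score("HE", "H"), "length")
  expect_error(ss_mismatch_score("HX", "HH"), "column 2")
})

test_that("mismatch score is symmetric, windowed, and reduces to the plain sum", {
  set.seed(6)
  alph <- c("H", "E", "C", "-")
  for (i in 1:25) {
    L <- sample(5:80, 1)
    a <- paste(sample(alph, L, replace = TRUE), collapse = "")
    b <- paste(sample(alph, L, replace = TRUE), collapse = "")
    w <- sample(3:40, 1)
    expect_equal(ss_mismatch_score(a, b, w), ss_mismatch_score(b, a, w))
    expect_gte(ss_mismatch_score(a, b, w), 0)
    expect_equal(ss_mismatch_score(a, a, w), 0)
  }
  # window = length is the full sum; maximum over sliding windows otherwise
  a <- "HHHHCCCCHHHH"
  b <- "EEEECCCCHHHH"
  expect_equal(ss_mismatch_score(a, b, window = nchar(a)), 8)
  expect_equal(ss_mismatch_score(a, b, window = 4), 8)
  expect_equal(ss_mismatch_score(a, b, window = 2), 4)
  # alignment shorter than the window scores the full alignment
  expect_equal(ss_mismatch_score("HE", "EH", window = 30), 4)
})

test_that("superposed RMSD is zero under rigid motions and symmetric", {
  set.seed(12)
  a <- matrix(rnorm(45, sd = 6), ncol = 3)
  expect_equal(pairwise_rmsd(a, a), 0, tolerance = 1e-9)
  b <- rigid_motion(a, angle = pi / 6, axis = c(0, 0, 1), shift = c(5, 5, 5))
  expect_equal(pairwise_rmsd(a, b), 0, tolerance = 1e-9)
  b2 <- rigid_motion(a, angle = 2.1, axis = c(1, -2, 0.5), shift = c(-9, 0, 14))
  expect_equal(pairwise_rmsd(a, b2), 0, tolerance = 1e-9)
  pert <- a + matrix(rnorm(45, sd = 0.8), ncol = 3)
  expect_equal(pairwise_rmsd(a, pert), pairwise_rmsd(pert, a),
               tolerance = 1e-9)
  expect_gt(pairwise_rmsd(a, pert), 0)
})

test_that("superposed RMSD matches a quaternion brute-force oracle on toy coordinates", {
  set.seed(77)
  a <- matrix(c(0, 0, 0,
                3.8, 0, 0,
                3.8, 3.8, 0,
                0, 3.8, 3.8), ncol = 3, byrow = TRUE)
  b <- rigid_motion(a + matrix(rnorm(12, sd = 0.4), ncol = 3),
                    angle = 1.2, axis = c(1, 1, 0), shift = c(2, -1, 4))
  expect_equal(pairwise_rmsd(a, b), brute_force_rmsd(a, b), tolerance = 1e-3)
})

test_that("RMSD input validation rejects degenerate coordinate sets", {
  expect_error(pairwise_rmsd(matrix(rnorm(6), ncol = 3),
                             matrix(rnorm(6), ncol = 3)), "3 aligned points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))  # collinear
  expect_error(pairwise_rmsd(line, line), "collinear")
  a <- matrix(rnorm(15), ncol = 3)
  b <- matrix(rnorm(12), ncol = 3)
  expect_error(pairwise_rmsd(a, b), "differ in length")
})

test_that("metadata filter applies all four criteria with strict printed bounds", {
  meta <- tibble::tibble(
    structure_id = sprintf("S%d", 1:6),
    deposition_age_years = c(12, 5, 12, 12, 12, 12),
    resolution_angstrom = c(1.8, 1.8, 2.3, NA, 1.8, 1.8),
    n_children_50pct = c(45, 45, 45, 45, 30, 45),
    sequence_length = c(120, 120, 120, 120, 120, 250))
  out <- monomorphic_metadata_filter(meta)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_match(out$reason[2], "years")
  expect_match(out$reason[3], "resolution")
  expect_match(out$reason[5], "similarity")
  expect_match(out$reason[6], "length")
  # resolution 2.2 exactly passes; non-X-ray (NA resolution) passes the gate
  exact <- monomorphic_metadata_filter(
    tibble::tibble(structure_id = "E", deposition_age_years = 10,
                   resolution_angstrom = 2.2, n_children_50pct = 31,
                   sequence_length = 41))
  expect_true(exact$keep)
})

test_that("structure filter drops on strict RMSD / mismatch exceedance only", {
  base <- matrix(rnorm(60, sd = 5), ncol = 3)
  ss <- paste(rep("H", 20), collapse = "")
  ok_pair <- list(parent_id = "p", child_id = "c1",
                  aligned_ss_a = ss, aligned_ss_b = ss,
                  ca_a = base, ca_b = rigid_motion(base))
  expect_true(monomorphic_structure_filter(list(ok_pair))$keep)
  # SS mismatch 10 > 9 with identical coordinates: the SS rule fires
  ss_bad <- paste(c(rep("E", 5), rep("H", 15)), collapse = "")
  ss_pair <- list(parent_id = "p", child_id = "c2",
                  aligned_ss_a = ss, aligned_ss_b = ss_bad,
                  ca_a = base, ca_b = base)
  res <- monomorphic_structure_filter(list(ok_pair, ss_pair))
  expect_false(res$keep)
  expect_equal(res$rule, "ss_mismatch")
  expect_equal(res$child_id, "c2")
  expect_equal(res$value, 10)
  # RMSD above 2.4 fires the RMSD rule and is reported first
  far <- base + matrix(rnorm(60, sd = 3), ncol = 3)
  rmsd_pair <- list(parent_id = "p", child_id = "c3",
                    aligned_ss_a = ss, aligned_ss_b = ss,
                    ca_a = base, ca_b = far)
  res2 <- monomorphic_structure_filter(list(ok_pair, rmsd_pair))
  expect_false(res2$keep)
  expect_equal(res2$rule, "rmsd")
  expect_gt(res2$value, 2.4)
})

test_that("keyword screen is case-insensitive substring matching", {
  out <- keyword_screen(c("a metamorphic protein that switches",
                          "a stable single-domain enzyme",
                          "Fold Switching was observed",
                          ""))
  expect_equal(out$flagged, c(TRUE, FALSE, TRUE, FALSE))
  expect_match(out$matched[1], "metamorphic")
  expect_match(out$matched[3], "fold switching")
})

test_that("metamorphic eligibility drops short sequences and terminal switch regions", {
  cand <- tibble::tibble(
    structure_id = c("a", "b", "c", "d", "e"),
    sequence_length = c(39, 100, 100, 100, 100),
    switch_region_start = c(NA, 85, 40, 5, NA),
    switch_region_end = c(NA, 98, 60, 18, NA))
  out <- metamorphic_eligibility(cand)
  expect_equal(out$keep, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_match(out$reason[1], "shorter")
  expect_match(out$reason[2], "terminus")
  expect_match(out$reason[4], "terminus")
  expect_error(metamorphic_eligibility(
    tibble::tibble(structure_id = "x", sequence_length = 50,
                   switch_region_start = 30, switch_region_end = 60)),
    "bounds")
})

test_that("list-edit accounting reproduces counts and audits every edit", {
  removals <- tibble::tibble(
    identifier = sprintf("rm%d", 1:8),
    reason = c("unavailable entry", rep("terminal region", 3),
               rep("short sequence", 4)))
  additions <- tibble::tibble(
    identifier = sprintf("add%d", 1:17),
    reason = c(rep("single-structure evidence", 15), rep("designed pair", 2)))
  res <- apply_list_edits(192, removals, additions)
  expect_equal(res$final_count, 201)
  expect_equal(nrow(res$ledger), 25)
  expect_equal(apply_list_edits(10)$final_count, 10)
  empty <- apply_list_edits(10, removals[0, ], additions[0, ])
  expect_equal(empty$final_count, 10)
  all_gone <- apply_list_edits(
    10, tibble::tibble(identifier = sprintf("x%d", 1:10), reason = "gone"), NULL)
  expect_equal(all_gone$final_count, 0)
  expect_equal(nrow(all_gone$ledger), 10)
  expect_error(
    apply_list_edits(5, removals = tibble::tibble(identifier = "a", reason = "r"),
                     additions = tibble::tibble(identifier = "a", reason = "r")),
    "duplicate")
})

test_that("alignment utility produces equal-length gapped strings", {
  aln <- align_sequences("MKVLITAGPT", "MKVITAGPT")
  expect_equal(nchar(aln$aligned_a), nchar(aln$aligned_b))
  expect_equal(gsub("-", "", aln$aligned_a), "MKVLITAGPT")
  expect_equal(gsub("-", "", aln$aligned_b), "MKVITAGPT")
})
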