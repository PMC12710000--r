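test_that("voxel threshold conversion multiplies", {
  expect_equal(voxel_threshold_to_cm(15, 0.05), 0.75)
  expect_equal(voxel_threshold_to_cm(15, 1.0), 15)
  expect_equal(voxel_threshold_to_cm(1, 0.027), 0.027)
  expect_error(voxel_threshold_to_cm(0, 0.05), class = "rsaeval_parameter_error")
  expect_error(voxel_threshold_to_cm(15, -1), class = "rsaeval_parameter_error")
})

test_that("segment matching on identical systems pairs everything at 0", {
  segs <- to_segments(simple_gt())
  D <- distance_matrix(segs, segs)
  corr <- match_segments(D, 0.75)
  expect_length(corr$unmatched_traced, 0L)
  # every traced segment sits at distance 0 from its assigned GT segment
  # (consecutive segments touch, so ties go to the lowest row index)
  expect_true(all(unlist(corr$distance) == 0))
  expect_equal(D[cbind(corr$owner, seq_len(ncol(D)))], rep(0, ncol(D)),
               ignore_attr = TRUE)
})

test_that("segments displaced far beyond the threshold stay unmatched", {
  gt <- simple_gt()
  far <- apply_rigid(gt, diag(3), c(15, 15, 0))  # far beyond the 1.5 cm threshold
  D <- distance_matrix(to_segments(gt), to_segments(far))
  corr <- match_segments(D, 1.5)
  expect_length(corr$unmatched_traced, ncol(D))
  expect_true(all(lengths(corr$assigned) == 0L))
})

test_that("two-phase segment rule equals a plain-loop evaluation on toys", {
  set.seed(52)
  for (i in 1:20) {
    D <- matrix(runif(12, 0, 2), 3L, 4L)
    corr <- match_segments(D, 1)
    brute <- bruteforce_match_segments(D, 1)
    expect_identical(corr$owner, brute)
    # partition property: every traced segment in exactly one place
    assigned_cols <- unlist(corr$assigned)
    expect_identical(sort(c(assigned_cols, corr$unmatched_traced)), 1:4)
  }
})

test_that("cumulative root distance: zero on identity, offset on rigid shift", {
  gt <- simple_gt()
  segs <- to_segments(gt)
  D <- distance_matrix(segs, segs)
  rows <- which(segs$root_id == "lat1")
  expect_equal(cumulative_root_distance(D, rows, rows,
                                        weights = segs$length[rows]), 0)
  # parallel offset: every per-segment minimum equals the offset
  delta <- 0.3
  shifted <- apply_rigid(gt, diag(3), c(0, 0, delta))
  segs2 <- to_segments(shifted)
  D2 <- distance_matrix(segs, segs2)
  expect_equal(cumulative_root_distance(D2, rows, which(segs2$root_id == "lat1"),
                                        weights = segs$length[rows]),
               delta, tolerance = 1e-9)
})

test_that("cumulative root distance matches a direct loop on uneven roots", {
  gt <- root_system(list(root("g", rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0)))))
  tr <- root_system(list(root("t", rbind(c(0, 0.5, 0), c(1, 0.5, 0),
                                         c(1.5, 0.5, 0), c(1.5, 3, 0)))))
  sg <- to_segments(gt); st <- to_segments(tr)
  D <- distance_matrix(sg, st)
  # independent: per GT segment take min over traced, weight by length
  mins <- apply(D, 1L, min)
  expected <- sum(mins * sg$length) / sum(sg$length)
  expect_equal(cumulative_root_distance(D, 1:2, 1:3, weights = sg$length),
               expected)
  expect_equal(cumulative_root_distance(D, 1:2, 1:3, mode = "mean"),
               mean(mins))
  expect_equal(cumulative_root_distance(D, 1:2, 1:3, mode = "sum"),
               sum(mins))
})

test_that("self-match pairs every root with itself at distance 0", {
  gt <- simple_gt()
  m <- match_roots(gt, gt, 0.75)
  expect_setequal(m$I_GC, root_ids(gt))
  expect_setequal(m$I_TC, root_ids(gt))
  expect_length(m$false_negative_roots, 0L)
  expect_length(m$false_positive_roots, 0L)
  expect_equal(max(m$pairs$distance), 0)
  expect_equal(m$pairs$gt_root, m$pairs$traced_root)
})

test_that("a missing lateral becomes a false negative, the rest still pair", {
  gt <- simple_gt()
  traced <- drop_roots(gt, "lat2")
  m <- match_roots(gt, traced, 0.75)
  expect_identical(m$false_negative_roots, "lat2")
  expect_setequal(m$I_GC, c("tap", "lat1"))
  expect_length(m$false_positive_roots, 0L)
})

test_that("an empty tracing yields all ground-truth roots as false negatives", {
  gt <- simple_gt()
  m <- match_roots(gt, root_system(), 0.75)
  expect_setequal(m$false_negative_roots, root_ids(gt))
  expect_length(m$I_TC, 0L)
})

test_that("a lateral traced as two fragments joins one 1-to-n pair", {
  gt <- root_system(list(
    straight_root("tap", c(0, 0, 0), c(0, 0, 10), n = 11L),
    straight_root("lat", c(0, 0, 2), c(6, 0, 2), n = 7L, order = 1L,
                  parent = "tap", attachment = 2)))
  tr <- root_system(list(
    straight_root("tap", c(0, 0, 0), c(0, 0, 10), n = 11L),
    straight_root("frag_a", c(0, 0, 2), c(3, 0, 2), n = 4L),
    straight_root("frag_b", c(3.2, 0, 2), c(6, 0, 2), n = 4L)))
  m <- match_roots(gt, tr, 0.75)
  lat_pair <- m$pairs[m$pairs$gt_root == "lat", ]
  expect_setequal(lat_pair$traced_root, c("frag_a", "frag_b"))
  expect_length(m$false_positive_roots, 0L)
  expect_setequal(m$I_TC, c("tap", "frag_a", "frag_b"))
})

test_that("partition and threshold-monotonicity invariants hold under perturbation", {
  set.seed(53)
  for (i in 1:5) {
    gt <- random_small_rsa(4L)
    tr <- perturb_tracing(gt, perturbation_params(
      node_jitter_sd = 0.15, drop_root_prob = 0.2,
      false_positive_count = 1L, seed = i))
    prev_gc <- -1L
    for (thr in c(0.3, 0.75, 1.5, 3)) {
      m <- match_roots(gt, tr, thr)
      expect_setequal(c(m$I_GC, m$false_negative_roots), root_ids(gt))
      expect_setequal(c(m$I_TC, m$false_positive_roots), root_ids(tr))
      expect_true(all(m$pairs$distance <= thr))
      expect_gte(length(m$I_GC), prev_gc)
      prev_gc <- length(m$I_GC)
    }
  }
})

test_that("stage-1 assignment is globally optimal on small instances", {
  set.seed(54)
  for (i in 1:8) {
    n <- sample(2:5, 1L); m <- sample(2:5, 1L)
    C <- matrix(runif(n * m, 0, 3), n, m)
    sel <- rsaeval:::solve_assignment(C)
    expect_equal(nrow(sel), min(n, m))
    expect_equal(sum(C[sel]), enumerate_min_assignment(C), tolerance = 1e-9)
  }
})

test_that("greedy mode is available and respects the threshold", {
  gt <- simple_gt()
  m <- match_roots(gt, gt, 0.75, assignment = "greedy")
  expect_setequal(m$I_GC, root_ids(gt))
  expect_equal(max(m$pairs$distance), 0)
})

test_that("match_roots validates its threshold", {
  gt <- simple_gt()
  expect_error(match_roots(gt, gt, 0), class = "rsaeval_parameter_error")
  expect_error(match_roots(gt, gt, -1), class = "rsaeval_parameter_error")
})
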