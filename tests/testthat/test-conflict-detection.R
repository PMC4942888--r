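make_pair_grid <- function(row_c, row_d) {
  repgrid(rbind(row_c, row_d),
          elements = c("Self", "Ideal",
                       sprintf("O%d", seq_len(length(row_c) - 2L))),
          roles = c("self", "ideal", rep("other", length(row_c) - 2L)),
          constructs = c("a - b", "c - d"))
}

test_that("construct classification follows the gap and midpoint rules", {
  cases <- list(
    list(self = 2L, ideal = 1L, expected = "congruent"),
    list(self = 2L, ideal = 7L, expected = "discrepant"),
    list(self = 1L, ideal = 4L, expected = "dilemmatic"),
    list(self = 7L, ideal = 4L, expected = "dilemmatic"),
    list(self = 4L, ideal = 4L, expected = "dilemmatic"),
    list(self = 3L, ideal = 6L, expected = "neutral"),
    list(self = 5L, ideal = 5L, expected = "congruent"),
    list(self = 1L, ideal = 5L, expected = "discrepant")
  )
  for (cs in cases) {
    g <- make_pair_grid(c(cs$self, cs$ideal, 3L, 5L, 2L),
                        c(2L, 1L, 1L, 2L, 3L))
    cl <- classify_construct(g, 1)
    expect_identical(cl$category, cs$expected)
    expect_identical(cl$gap, abs(cs$self - cs$ideal))
  }
})

test_that("the dilemmatic rule fires at exactly the midpoint ideal", {
  hits <- vapply(1:7, function(ideal) {
    g <- make_pair_grid(c(2L, ideal, 3L, 5L, 2L), c(2L, 1L, 1L, 2L, 3L))
    classify_construct(g, 1)$category == "dilemmatic"
  }, logical(1))
  expect_identical(which(hits), 4L)
  expect_identical(detect_dilemmatic_constructs(
    make_pair_grid(c(2L, 4L, 3L, 5L, 2L), c(2L, 1L, 1L, 2L, 3L))), 1L)
})

test_that("the worked example reproduces its hand-derived correlation", {
  g <- g1()
  expect_equal(oriented_correlation(g, 1, 2), G1_R, tolerance = 1e-12)
  # orientation undoes a reflection of either construct
  expect_equal(oriented_correlation(reflect_construct(g, 2), 1, 2),
               G1_R, tolerance = 1e-12)
  expect_equal(oriented_correlation(reflect_construct(g, 1), 1, 2),
               G1_R, tolerance = 1e-12)
})

test_that("identical oriented rows correlate exactly 1", {
  g <- make_pair_grid(c(2L, 1L, 5L, 3L, 6L), c(2L, 1L, 5L, 3L, 6L))
  expect_equal(oriented_correlation(g, 1, 2), 1)
  # and a row against its own reflection, once oriented, is also 1
  gr <- reflect_construct(g, 2)
  expect_equal(oriented_correlation(gr, 1, 2), 1)
})

test_that("zero-variance rows yield NA with a warning, never a silent 0", {
  g <- make_pair_grid(c(2L, 2L, 2L, 2L, 2L), c(2L, 7L, 1L, 6L, 5L))
  expect_warning(r <- oriented_correlation(g, 1, 2), "zero rating variance")
  expect_true(is.na(r))
  expect_warning(d <- detect_implicative_dilemmas(g), "zero rating variance")
  expect_equal(nrow(d), 0L)
})

test_that("the worked example yields exactly one dilemma, laid out as the
           current position against the implication of change", {
  d <- detect_implicative_dilemmas(g1())
  expect_equal(nrow(d), 1L)
  expect_equal(d$congruent_index, 1L)
  expect_equal(d$discrepant_index, 2L)
  expect_equal(d$oriented_r, G1_R, tolerance = 1e-12)
  expect_identical(d$self_pole_congruent, "generous")
  expect_identical(d$undesired_pole_congruent, "selfish")
  expect_identical(d$present_pole_discrepant, "depressed")
  expect_identical(d$desired_pole_discrepant, "happy")
})

test_that("pairs correlated below threshold and ineligible pairs are not flagged", {
  # same anchors as the worked example, others chosen so r sits below 0.35
  g <- make_pair_grid(c(2L, 1L, 1L, 5L, 1L), c(2L, 7L, 1L, 5L, 2L))
  r <- oracle_oriented_r(g, 1, 2)
  expect_lt(r, 0.35)
  expect_gt(r, 0)
  expect_equal(nrow(detect_implicative_dilemmas(g)), 0L)

  # no discrepant construct -> no eligible pair at all
  g2 <- make_pair_grid(c(2L, 1L, 2L, 6L, 5L), c(2L, 2L, 1L, 6L, 6L))
  expect_equal(nrow(detect_implicative_dilemmas(g2)), 0L)

  # dilemmatic constructs never participate, even when highly correlated
  g3 <- make_pair_grid(c(2L, 4L, 2L, 6L, 5L), c(2L, 7L, 2L, 6L, 5L))
  expect_equal(nrow(detect_implicative_dilemmas(g3)), 0L)
  expect_identical(detect_dilemmatic_constructs(g3), 1L)
})

test_that("dilemmatic detection is exhaustive and ordered", {
  g <- repgrid(rbind(c(1L, 4L, 3L), c(2L, 4L, 5L), c(2L, 1L, 6L)),
               elements = c("S", "I", "O"),
               roles = c("self", "ideal", "other"),
               constructs = c("a - b", "c - d", "e - f"))
  expect_identical(detect_dilemmatic_constructs(g), c(1L, 2L))
  g_all17 <- repgrid(rbind(c(1L, 7L, 3L), c(2L, 1L, 5L)),
                     elements = c("S", "I", "O"),
                     roles = c("self", "ideal", "other"),
                     constructs = c("a - b", "c - d"))
  expect_length(detect_dilemmatic_constructs(g_all17), 0L)
})

test_that("prototypical figures split the others into the two positions", {
  g <- g1()
  d <- detect_implicative_dilemmas(g)
  fig <- find_prototypical_figures(g, d[1, ])
  expect_identical(fig$current_side_labels, "Mother")
  expect_identical(fig$change_side_labels, c("Father", "Friend"))
  expect_length(intersect(fig$current_side, fig$change_side), 0L)
  expect_false(self_index(g) %in% c(fig$current_side, fig$change_side))
  expect_false(ideal_index(g) %in% c(fig$current_side, fig$change_side))

  # an element at the midpoint of either construct joins neither side
  g_mid <- make_pair_grid(c(2L, 1L, 4L, 2L, 6L), c(2L, 7L, 1L, 4L, 6L))
  d2 <- suppressWarnings(detect_implicative_dilemmas(
    g_mid, detection_parameters(correlation_threshold = 0.01)))
  if (nrow(d2) > 0) {
    f2 <- find_prototypical_figures(g_mid, d2[1, ])
    expect_false(3L %in% c(f2$current_side, f2$change_side))
    expect_false(4L %in% c(f2$current_side, f2$change_side))
  }

  # nobody polarized -> both sides empty
  g_flat <- make_pair_grid(c(2L, 1L, 4L, 4L, 4L), c(2L, 7L, 4L, 4L, 4L))
  dflat <- list(congruent_index = 1L, discrepant_index = 2L)
  f3 <- find_prototypical_figures(g_flat, dflat)
  expect_length(f3$current_side, 0L)
  expect_length(f3$change_side, 0L)
})

test_that("dilemmatic prototypes use the person's own extreme scores", {
  g <- make_pair_grid(c(4L, 4L, 2L, 3L, 6L), c(2L, 7L, 1L, 2L, 3L))
  pr <- find_dilemmatic_prototypes(g, 1)
  expect_identical(pr$left_side_labels, "O1")   # rated 2, the used minimum
  expect_identical(pr$right_side_labels, "O3")  # rated 6, the used maximum
  expect_identical(pr$left_extreme, 2L)
  expect_identical(pr$right_extreme, 6L)

  # ties at the used extreme are all kept
  g_tie <- make_pair_grid(c(4L, 4L, 2L, 2L, 6L), c(2L, 7L, 1L, 2L, 3L))
  expect_identical(find_dilemmatic_prototypes(g_tie, 1)$left_side_labels,
                   c("O1", "O2"))

  # all others at the midpoint -> both sides empty
  g_mid <- make_pair_grid(c(4L, 4L, 4L, 4L, 4L), c(2L, 7L, 1L, 2L, 3L))
  pr_mid <- find_dilemmatic_prototypes(g_mid, 1)
  expect_length(pr_mid$left_side, 0L)
  expect_length(pr_mid$right_side, 0L)
  expect_true(is.na(pr_mid$left_extreme))

  expect_error(find_dilemmatic_prototypes(g, 2), "not dilemmatic")
})

test_that("oriented_correlation agrees with the brute-force oracle", {
  set.seed(41)
  for (i in 1:200) {
    g <- random_grid()
    ks <- sample(n_constructs(g), 2)
    for (inc in c(TRUE, FALSE)) {
      params <- detection_parameters(include_self_ideal = inc)
      r <- suppressWarnings(oriented_correlation(g, ks[1], ks[2], params))
      ro <- oracle_oriented_r(g, ks[1], ks[2], inc)
      if (is.na(r)) expect_true(is.na(ro) || is.nan(ro))
      else expect_equal(r, ro, tolerance = 1e-12)
    }
  }
})

test_that("detection is invariant under construct reflection", {
  set.seed(43)
  for (i in 1:60) {
    g <- random_grid()
    d <- suppressWarnings(detect_implicative_dilemmas(g))
    k <- sample(n_constructs(g), 1)
    gr <- reflect_construct(g, k)
    dr <- suppressWarnings(detect_implicative_dilemmas(gr))
    expect_equal(dilemma_key(d), dilemma_key(dr))
    if (nrow(d) > 0) {
      fig <- find_prototypical_figures(g, d[1, ])
      figr <- find_prototypical_figures(gr, dr[match(
        paste(d$congruent_index[1], d$discrepant_index[1]),
        paste(dr$congruent_index, dr$discrepant_index)), ])
      expect_identical(fig$current_side, figr$current_side)
      expect_identical(fig$change_side, figr$change_side)
    }
  }
})

test_that("permuting the other elements permutes figures and nothing else", {
  set.seed(47)
  for (i in 1:40) {
    g <- random_grid()
    others <- other_indices(g)
    perm <- sample(others)
    gp <- g
    gp$ratings[, others] <- g$ratings[, perm]
    gp$elements[others, ] <- g$elements[perm, ]

    expect_identical(classify_constructs(gp), classify_constructs(g))
    d <- suppressWarnings(detect_implicative_dilemmas(g))
    dp <- suppressWarnings(detect_implicative_dilemmas(gp))
    expect_equal(dilemma_key(d), dilemma_key(dp))
    if (nrow(d) > 0) {
      f <- find_prototypical_figures(g, d[1, ])
      fp <- find_prototypical_figures(gp, dp[match(
        paste(d$congruent_index[1], d$discrepant_index[1]),
        paste(dp$congruent_index, dp$discrepant_index)), ])
      expect_identical(sort(f$current_side_labels),
                       sort(fp$current_side_labels))
      expect_identical(sort(f$change_side_labels),
                       sort(fp$change_side_labels))
    }
  }
})

test_that("no construct is both dilemmatic and part of a dilemma", {
  set.seed(53)
  for (i in 1:40) {
    g <- random_grid()
    d <- suppressWarnings(detect_implicative_dilemmas(g))
    dil <- detect_dilemmatic_constructs(g)
    expect_length(intersect(dil, c(d$congruent_index, d$discrepant_index)), 0L)
  }
})

test_that("lowering the threshold never removes a dilemma", {
  set.seed(59)
  for (i in 1:30) {
    g <- random_grid()
    hi <- suppressWarnings(detect_implicative_dilemmas(
      g, detection_parameters(correlation_threshold = 0.5)))
    lo <- suppressWarnings(detect_implicative_dilemmas(
      g, detection_parameters(correlation_threshold = 0.2)))
    key <- function(d) paste(d$congruent_index, d$discrepant_index)
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("dilemma output is sorted by descending correlation", {
  set.seed(61)
  for (i in 1:20) {
    g <- random_grid(n_elements = 10, n_constructs = 8)
    d <- suppressWarnings(detect_implicative_dilemmas(
      g, detection_parameters(correlation_threshold = 0.05)))
    if (nrow(d) > 1) {
      expect_true(all(diff(d$oriented_r) <= 0))
    }
  }
})
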