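test_that("the worked example reproduces its hand-computed indices", {
  g <- g1()
  expect_equal(self_ideal_discrepancy(g), (1 + 5) / (2 * 6))
  expect_equal(self_isolation(g), mean(c(1, 8, 7) / 12))
  expect_equal(adequacy_of_others(g), 1 - mean(c(7, 6, 5) / 12))
  expect_equal(polarization(g), 30)
})

test_that("each index reaches its bounds on the constructed extremes", {
  # self column equals ideal column -> zero discrepancy
  g0 <- repgrid(rbind(c(3L, 3L, 5L), c(6L, 6L, 1L)),
                elements = c("S", "I", "O"),
                roles = c("self", "ideal", "other"),
                constructs = c("a - b", "c - d"))
  expect_equal(self_ideal_discrepancy(g0), 0)

  # self all 1, ideal all 7 -> maximal discrepancy
  g1x <- repgrid(rbind(c(1L, 7L, 5L), c(1L, 7L, 2L)),
                 elements = c("S", "I", "O"),
                 roles = c("self", "ideal", "other"),
                 constructs = c("a - b", "c - d"))
  expect_equal(self_ideal_discrepancy(g1x), 1)

  # the single other equals self -> no isolation; opposite extreme -> full
  g_same <- repgrid(rbind(c(2L, 1L, 2L), c(5L, 1L, 5L)),
                    elements = c("S", "I", "O"),
                    roles = c("self", "ideal", "other"),
                    constructs = c("a - b", "c - d"))
  expect_equal(self_isolation(g_same), 0)
  g_far <- repgrid(rbind(c(1L, 2L, 7L), c(7L, 2L, 1L)),
                   elements = c("S", "I", "O"),
                   roles = c("self", "ideal", "other"),
                   constructs = c("a - b", "c - d"))
  expect_equal(self_isolation(g_far), 1)

  # others identical to ideal -> fully adequate
  g_ad <- repgrid(rbind(c(2L, 1L, 1L), c(5L, 6L, 6L)),
                  elements = c("S", "I", "O"),
                  roles = c("self", "ideal", "other"),
                  constructs = c("a - b", "c - d"))
  expect_equal(adequacy_of_others(g_ad), 1)
  g_inad <- repgrid(rbind(c(2L, 1L, 7L), c(5L, 7L, 1L)),
                    elements = c("S", "I", "O"),
                    roles = c("self", "ideal", "other"),
                    constructs = c("a - b", "c - d"))
  expect_equal(adequacy_of_others(g_inad), 0)

  # all ratings at the extremes / none at the extremes
  g_pol <- repgrid(rbind(c(1L, 7L, 1L), c(7L, 1L, 7L)),
                   elements = c("S", "I", "O"),
                   roles = c("self", "ideal", "other"),
                   constructs = c("a - b", "c - d"))
  expect_equal(polarization(g_pol), 100)
  g_mild <- repgrid(rbind(c(2L, 3L, 4L), c(5L, 6L, 2L)),
                    elements = c("S", "I", "O"),
                    roles = c("self", "ideal", "other"),
                    constructs = c("a - b", "c - d"))
  expect_equal(polarization(g_mild), 0)
})

test_that("indices stay in bounds and are invariant to reflection and
           permutation of others", {
  set.seed(67)
  for (i in 1:40) {
    g <- random_grid()
    ix <- grid_indices(g)
    expect_true(ix$self_ideal_discrepancy >= 0 && ix$self_ideal_discrepancy <= 1)
    expect_true(ix$self_isolation >= 0 && ix$self_isolation <= 1)
    expect_true(ix$adequacy_of_others >= 0 && ix$adequacy_of_others <= 1)
    expect_true(ix$polarization >= 0 && ix$polarization <= 100)

    gr <- reflect_construct(g, sample(n_constructs(g), 1))
    expect_equal(grid_indices(gr), ix)

    others <- other_indices(g)
    gp <- g
    perm <- sample(others)
    gp$ratings[, others] <- g$ratings[, perm]
    gp$elements[others, ] <- g$elements[perm, ]
    expect_equal(grid_indices(gp), ix)
  }
})

test_that("comparing a grid with itself reports zero change, nothing resolved", {
  g <- g1()
  rep0 <- compare_pre_post(g, g)
  expect_equal(nrow(rep0), 1L)
  expect_equal(rep0$delta_self_ideal_discrepancy, 0)
  expect_equal(rep0$delta_association_strength, 0)
  expect_false(rep0$resolved)

  set.seed(73)
  for (i in 1:10) {
    g <- random_grid()
    r <- suppressWarnings(compare_pre_post(g, g))
    expect_true(all(r$delta_self_ideal_discrepancy == 0))
    expect_true(all(r$delta_association_strength == 0))
    expect_false(any(r$resolved))
  }
})

test_that("pathway 1: moving the self towards the ideal resolves the dilemma", {
  pre <- g1()
  post <- pre
  # the self now rates itself at the desired pole of the discrepant construct
  post$ratings[2, self_index(post)] <- post$ratings[2, ideal_index(post)]
  rep1 <- compare_pre_post(pre, post)
  expect_equal(nrow(rep1), 1L)
  expect_lt(rep1$delta_self_ideal_discrepancy, 0)
  # the construct is no longer discrepant, so the pair cannot be flagged
  expect_identical(classify_construct(post, 2)$category, "congruent")
  expect_true(rep1$resolved)
})

test_that("pathway 2: decorrelating the pair resolves the dilemma", {
  pre <- generate_grid(simulation_spec(
    n_other_elements = 13,
    plants = list(plant_spec("implicative_dilemma", target_r = 0.95)),
    seed = 301))
  expect_gt(nrow(detect_implicative_dilemmas(pre)), 0L)
  post <- generate_grid(simulation_spec(
    n_other_elements = 13,
    plants = list(plant_spec("null_pair")),
    seed = 302))
  rep2 <- compare_pre_post(pre, post)
  post_flagged <- nrow(detect_implicative_dilemmas(post)) > 0L
  expect_identical(rep2$resolved[1], !post_flagged)
  expect_lt(rep2$post_oriented_r, 0.35)
  expect_lt(rep2$delta_association_strength, 0)
  # self/ideal anchors are identical pre and post: pathway 2 leaves the
  # self-ideal discrepancy untouched
  expect_equal(rep2$delta_self_ideal_discrepancy, 0)
})

test_that("structurally incompatible grids are rejected", {
  g <- g1()
  other <- repgrid(rbind(c(2L, 1L, 5L), c(2L, 7L, 3L), c(1L, 2L, 4L)),
                   elements = c("S", "I", "O"),
                   roles = c("self", "ideal", "other"),
                   constructs = c("a - b", "c - d", "e - f"))
  expect_error(compare_pre_post(g, other), "construct counts")
  relabeled <- g
  relabeled$constructs$left_pole[1] <- "different"
  expect_error(compare_pre_post(g, relabeled), "labels")
})
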