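#' Self-ideal discrepancy
#'
#' Mean absolute difference between the self and ideal rating columns,
#' normalized by the scale span: 0 when the person already is exactly who
#' they want to be on every construct, 1 when self and ideal sit at
#' opposite scale extremes everywhere.
#'
#' @param grid A `repgrid`.
#' @return A number in `[0, 1]`.
#' @examples
#' self_ideal_discrepancy(example_grid())  # (1 + 5) / (2 * 6) = 0.5
#' @export
self_ideal_discrepancy <- function(grid) {
  s <- grid$ratings[, self_index(grid)]
  i <- grid$ratings[, ideal_index(grid)]
  mean(abs(s - i)) / scale_span(grid$scale)
}

# mean normalized city-block distance from a reference column to every
# other-role element column; shared by the isolation and adequacy indices
.mean_other_distance <- function(grid, ref_col) {
  others <- other_indices(grid)
  if (length(others) == 0L) {
    stop("grid has no other-role elements", call. = FALSE)
  }
  ref <- grid$ratings[, ref_col]
  denom <- n_constructs(grid) * scale_span(grid$scale)
  d <- vapply(others, function(e) {
    sum(abs(grid$ratings[, e] - ref)) / denom
  }, numeric(1))
  mean(d)
}

#' Self-perceived social isolation
#'
#' Mean normalized city-block distance between the self column and each
#' significant other's column: 0 when everyone is rated exactly like the
#' self, 1 when every other sits at the opposite scale extreme on every
#' construct. High values read as "nobody is like me".
#'
#' @param grid A `repgrid` with at least one other-role element.
#' @return A number in `[0, 1]`.
#' @export
self_isolation <- function(grid) {
  .mean_other_distance(grid, self_index(grid))
}

#' Perceived adequacy of others
#'
#' One minus the mean normalized city-block distance between the ideal
#' column and each significant other's column, so that higher means
#' others are seen as closer to the ideal (more adequate).
#'
#' @param grid A `repgrid` with at least one other-role element.
#' @return A number in `[0, 1]`.
#' @export
adequacy_of_others <- function(grid) {
  1 - .mean_other_distance(grid, ideal_index(grid))
}

#' Polarization
#'
#' Percentage of all ratings in the grid sitting at either scale extreme.
#' Highly polarized grids use the scale in an all-or-nothing fashion.
#'
#' @param grid A `repgrid`.
#' @return A percentage in `[0, 100]`.
#' @examples
#' polarization(example_grid())  # 3 extreme cells of 10 -> 30
#' @export
polarization <- function(grid) {
  r <- grid$ratings
  100 * mean(r == grid$scale$min_rating | r == grid$scale$max_rating)
}

#' All four summary indices of a grid
#'
#' @param grid A `repgrid`.
#' @return A list with `self_ideal_discrepancy`, `self_isolation`,
#'   `adequacy_of_others` (each in `[0, 1]`) and `polarization`
#'   (percent). The two distance-based indices require at least one
#'   other-role element and are `NA` otherwise.
#' @export
grid_indices <- function(grid) {
  has_others <- length(other_indices(grid)) > 0L
  list(
    self_ideal_discrepancy = self_ideal_discrepancy(grid),
    self_isolation = if (has_others) self_isolation(grid) else NA_real_,
    adequacy_of_others = if (has_others) adequacy_of_others(grid) else NA_real_,
    polarization = polarization(grid)
  )
}

#' Compare a pre-intervention and a post-intervention grid
#'
#' Dilemmas resolve through two pathways: the person's self moves towards
#' the ideal (the discrepant construct stops being discrepant), or the
#' association between the congruent and the discrepant construct
#' weakens below threshold. For every dilemma detected in the pre grid
#' this reports the change in overall self-ideal discrepancy, the change
#' in the pair's oriented correlation, and whether the pair is still
#' flagged in the post grid.
#'
#' @param pre,post Two `repgrid`s with the same constructs (matched by
#'   index; pole labels must be verbatim identical).
#' @param params A [detection_parameters()].
#' @return A data.frame of class `resolution_pathways` with one row per
#'   pre-grid dilemma: `congruent_index`, `discrepant_index`,
#'   `pre_oriented_r`, `post_oriented_r`, `delta_association_strength`,
#'   `delta_self_ideal_discrepancy`, `resolved`.
#' @examples
#' g <- example_grid()
#' compare_pre_post(g, g)  # zero deltas, nothing resolved
#' @export
compare_pre_post <- function(pre, post, params = detection_parameters()) {
  if (n_constructs(pre) != n_constructs(post)) {
    stop("pre and post grids have different construct counts", call. = FALSE)
  }
  if (!identical(pre$constructs, post$constructs)) {
    stop("pre and post construct pole labels differ; grids are matched ",
         "by index with verbatim label equality", call. = FALSE)
  }
  pre_dil <- detect_implicative_dilemmas(pre, params)
  post_dil <- detect_implicative_dilemmas(post, params)
  d_sid <- self_ideal_discrepancy(post) - self_ideal_discrepancy(pre)
  rows <- lapply(seq_len(nrow(pre_dil)), function(i) {
    ci <- pre_dil$congruent_index[i]
    di <- pre_dil$discrepant_index[i]
    post_r <- suppressWarnings(oriented_correlation(post, ci, di, params))
    still <- any(post_dil$congruent_index == ci &
                 post_dil$discrepant_index == di)
    data.frame(congruent_index = ci,
               discrepant_index = di,
               pre_oriented_r = pre_dil$oriented_r[i],
               post_oriented_r = post_r,
               delta_association_strength = post_r - pre_dil$oriented_r[i],
               delta_self_ideal_discrepancy = d_sid,
               resolved = !still,
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows) == 0L) {
    data.frame(congruent_index = integer(), discrepant_index = integer(),
               pre_oriented_r = numeric(), post_oriented_r = numeric(),
               delta_association_strength = numeric(),
               delta_self_ideal_discrepancy = numeric(),
               resolved = logical(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(res) <- c("resolution_pathways", "data.frame")
  res
}
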