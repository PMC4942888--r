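# Shared fixtures and independent oracles. Everything here is written
# against the definitions, not against the package's internals, so the
# oracles stay independent of the code paths they check.

# the worked 5-element, 2-construct grid with one dilemma
g1 <- function() example_grid()

# hand-derived constants for g1 (two-pass Pearson by explicit sums):
# C1 (2,1,2,6,5), C2 (2,7,1,6,6): covariance sum 8.6, squared deviation
# sums 18.8 and 29.2 -> r = 8.6 / sqrt(18.8 * 29.2)
G1_R <- 8.6 / sqrt(18.8 * 29.2)

# brute-force two-pass Pearson correlation, straight from the definition
brute_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# independent oriented-correlation oracle: reflect a row about the scale
# midpoint when its reference element's rating lies above it, then
# brute-force Pearson over the chosen element set
oracle_oriented_r <- function(grid, ci, di, include_self_ideal = TRUE) {
  sc <- grid$scale
  orient <- function(k, ref_col) {
    row <- grid$ratings[k, ]
    if (row[ref_col] > sc$midpoint) sc$min_rating + sc$max_rating - row
    else row
  }
  x <- orient(ci, ideal_index(grid))
  y <- orient(di, self_index(grid))
  cols <- if (include_self_ideal) seq_len(n_elements(grid))
          else other_indices(grid)
  brute_pearson(x[cols], y[cols])
}

# random valid grid; dimensions and role positions randomized, ratings
# uniform over the scale
random_grid <- function(n_elements = sample(4:12, 1),
                        n_constructs = sample(2:10, 1),
                        scale = rating_scale()) {
  roles <- c("self", "ideal", rep("other", n_elements - 2L))
  roles <- sample(roles)
  repgrid(
    ratings = matrix(sample(scale$min_rating:scale$max_rating,
                            n_constructs * n_elements, replace = TRUE),
                     nrow = n_constructs),
    elements = sprintf("E%02d", seq_len(n_elements)),
    roles = roles,
    constructs = data.frame(
      left_pole = sprintf("L%02d", seq_len(n_constructs)),
      right_pole = sprintf("R%02d", seq_len(n_constructs)),
      stringsAsFactors = FALSE
    ),
    scale = scale
  )
}

# comparable view of a dilemma set: index pair plus correlation, sorted
dilemma_key <- function(d) {
  k <- data.frame(ci = d$congruent_index, di = d$discrepant_index,
                  r = d$oriented_r)
  k[order(k$ci, k$di), , drop = FALSE]
}

# bypass the constructor to build deliberately broken grids
raw_grid <- function(ratings, roles, scale = rating_scale()) {
  E <- ncol(ratings); C <- nrow(ratings)
  structure(
    list(ratings = ratings,
         elements = data.frame(label = sprintf("E%d", seq_len(E)),
                               role = roles, stringsAsFactors = FALSE),
         constructs = data.frame(left_pole = sprintf("L%d", seq_len(C)),
                                 right_pole = sprintf("R%d", seq_len(C)),
                                 stringsAsFactors = FALSE),
         scale = scale),
    class = "repgrid"
  )
}
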