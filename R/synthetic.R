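#' Specification of one planted conflict structure
#'
#' A plant describes a structure the synthetic generator must realize in
#' a grid: an eligible congruent-discrepant construct pair with a chosen
#' latent correlation (`implicative_dilemma`), the same pair with zero
#' latent correlation (`null_pair`), or a single construct whose ideal
#' sits at the scale midpoint (`dilemmatic`).
#'
#' @param kind One of `"implicative_dilemma"`, `"null_pair"`,
#'   `"dilemmatic"`.
#' @param target_r Latent correlation in `(-1, 1)` between the pair's
#'   rating rows over the other-role elements (pair kinds only; forced to
#'   0 for `null_pair`). Discretization to the rating scale attenuates
#'   the realized correlation, which the generator reports per grid.
#' @param congruent_self,congruent_ideal Self/ideal ratings of the
#'   congruent member (defaults 2, 1).
#' @param discrepant_self,discrepant_ideal Self/ideal ratings of the
#'   discrepant member (defaults 2, 7).
#' @param dilemmatic_self Self rating of a dilemmatic plant (default 3);
#'   its ideal rating is always the scale midpoint.
#' @param scale The [rating_scale()] the ratings must respect.
#' @return An object of class `plant_spec`. Construction fails unless the
#'   chosen self/ideal ratings produce the intended classification under
#'   default [detection_parameters()].
#' @export
plant_spec <- function(kind = c("implicative_dilemma", "null_pair", "dilemmatic"),
                       target_r = NULL,
                       congruent_self = 2L, congruent_ideal = 1L,
                       discrepant_self = 2L, discrepant_ideal = 7L,
                       dilemmatic_self = 3L,
                       scale = rating_scale()) {
  kind <- match.arg(kind)
  params <- detection_parameters()
  check_rating <- function(x, what) {
    if (x < scale$min_rating || x > scale$max_rating) {
      stop(sprintf("%s rating %d outside scale bounds", what, x),
           call. = FALSE)
    }
    as.integer(x)
  }
  if (kind == "dilemmatic") {
    dilemmatic_self <- check_rating(dilemmatic_self, "dilemmatic self")
    spec <- list(kind = kind, dilemmatic_self = dilemmatic_self,
                 dilemmatic_ideal = scale$midpoint)
  } else {
    if (kind == "null_pair") target_r <- 0
    if (is.null(target_r) || !(target_r > -1 && target_r < 1)) {
      stop("target_r in (-1, 1) required for pair plants", call. = FALSE)
    }
    congruent_self <- check_rating(congruent_self, "congruent self")
    congruent_ideal <- check_rating(congruent_ideal, "congruent ideal")
    discrepant_self <- check_rating(discrepant_self, "discrepant self")
    discrepant_ideal <- check_rating(discrepant_ideal, "discrepant ideal")
    # the plant must classify as intended, or every downstream test lies
    if (congruent_ideal == scale$midpoint ||
        abs(congruent_self - congruent_ideal) > params$congruent_gap_max) {
      stop("congruent_self/congruent_ideal do not classify as congruent",
           call. = FALSE)
    }
    if (discrepant_ideal == scale$midpoint ||
        abs(discrepant_self - discrepant_ideal) < params$discrepant_gap_min) {
      stop("discrepant_self/discrepant_ideal do not classify as discrepant",
           call. = FALSE)
    }
    spec <- list(kind = kind, target_r = target_r,
                 congruent_self = congruent_self,
                 congruent_ideal = congruent_ideal,
                 discrepant_self = discrepant_self,
                 discrepant_ideal = discrepant_ideal)
  }
  structure(spec, class = "plant_spec")
}

#' Specification of one synthetic grid
#'
#' @param n_other_elements Number of significant others (default 12, the
#'   realistic size of a clinical grid's element roster).
#' @param plants List of [plant_spec()] objects realized in order; pair
#'   plants contribute two construct rows each, dilemmatic plants one.
#' @param background_constructs Number of additional constructs with
#'   uniformly random ratings (default 0).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param scale The [rating_scale()] of the generated grid.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_other_elements = 12L, plants = list(),
                            background_constructs = 0L, seed = 1L,
                            scale = rating_scale()) {
  n_other_elements <- as.integer(n_other_elements)
  background_constructs <- as.integer(background_constructs)
  if (n_other_elements < 1L) {
    stop("n_other_elements must be at least 1", call. = FALSE)
  }
  has_pair <- any(vapply(plants, function(p) p$kind != "dilemmatic",
                         logical(1)))
  if (has_pair && n_other_elements < 3L) {
    stop("pair plants need at least 3 other elements for a meaningful ",
         "correlation", call. = FALSE)
  }
  n_constructs <- sum(vapply(plants, function(p) {
    if (p$kind == "dilemmatic") 1L else 2L
  }, integer(1))) + background_constructs
  if (n_constructs < 2L) {
    stop("spec yields fewer than 2 constructs; add plants or background",
         call. = FALSE)
  }
  structure(
    list(n_other_elements = n_other_elements, plants = plants,
         background_constructs = background_constructs,
         seed = as.integer(seed), scale = scale),
    class = "simulation_spec"
  )
}

# latent value -> integer rating: center at the midpoint, spread by a
# quarter of the span (1.5 points on a 1-7 scale), round, clamp
.discretize <- function(z, scale) {
  sigma <- scale_span(scale) / 4
  r <- round(scale$midpoint + sigma * z)
  as.integer(pmin(pmax(r, scale$min_rating), scale$max_rating))
}

#' Generate a synthetic repertory grid
#'
#' Builds a valid grid realizing every plant of the spec. For a pair
#' plant the two rating rows over the other-role elements are drawn from
#' a shared latent factor mixed with independent noise (weights chosen so
#' the latent correlation equals `target_r`), then discretized to the
#' scale by rounding and clamping; the self and ideal cells come from the
#' plant. Background constructs are rated uniformly at random, with the
#' ideal kept off the midpoint so that background rows never masquerade
#' as dilemmatic. Generation is fully deterministic given the spec,
#' including its seed, and does not disturb the caller's RNG state.
#'
#' @param spec A [simulation_spec()].
#' @return A `repgrid`. The attribute `"plant_info"` is a data.frame with
#'   one row per plant: kind, the construct indices it occupies, and for
#'   pair plants `realized_r`, the oriented Pearson correlation of the
#'   discretized rows over the other-role elements (the honest,
#'   attenuation-aware value tests should assert against).
#' @examples
#' spec <- simulation_spec(
#'   plants = list(plant_spec("implicative_dilemma", target_r = 0.9)),
#'   seed = 1234
#' )
#' g <- generate_grid(spec)
#' attr(g, "plant_info")
#' @export
generate_grid <- function(spec) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  sc <- spec$scale
  n_other <- spec$n_other_elements
  self_col <- 1L; ideal_col <- 2L
  other_cols <- 2L + seq_len(n_other)
  E <- 2L + n_other

  rows <- list()
  poles <- list()
  info <- list()
  k <- 0L
  for (p in spec$plants) {
    if (p$kind == "dilemmatic") {
      row <- integer(E)
      row[self_col] <- p$dilemmatic_self
      row[ideal_col] <- p$dilemmatic_ideal
      row[other_cols] <- sample(sc$min_rating:sc$max_rating, n_other,
                                replace = TRUE)
      k <- k + 1L
      rows[[k]] <- row
      poles[[k]] <- c(sprintf("pole%dL", k), sprintf("pole%dR", k))
      info[[length(info) + 1L]] <- data.frame(
        kind = p$kind, congruent_index = NA_integer_,
        discrepant_index = NA_integer_, construct_index = k,
        target_r = NA_real_, realized_r = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      z1 <- stats::rnorm(n_other)
      eps <- stats::rnorm(n_other)
      z2 <- p$target_r * z1 + sqrt(1 - p$target_r^2) * eps
      row_c <- integer(E); row_d <- integer(E)
      row_c[self_col] <- p$congruent_self
      row_c[ideal_col] <- p$congruent_ideal
      row_d[self_col] <- p$discrepant_self
      row_d[ideal_col] <- p$discrepant_ideal
      # latent factors describe movement away from each construct's
      # reference pole, so orient them to that pole's end of the scale
      orient <- function(vals, anchor) {
        if (anchor > sc$midpoint) sc$min_rating + sc$max_rating - vals
        else vals
      }
      row_c[other_cols] <- orient(.discretize(z1, sc), p$congruent_ideal)
      row_d[other_cols] <- orient(.discretize(z2, sc), p$discrepant_self)
      ci <- k + 1L; di <- k + 2L
      k <- k + 2L
      rows[[ci]] <- row_c
      rows[[di]] <- row_d
      poles[[ci]] <- c(sprintf("pole%dL", ci), sprintf("pole%dR", ci))
      poles[[di]] <- c(sprintf("pole%dL", di), sprintf("pole%dR", di))
      # realized association over others, in dilemma orientation
      oc <- orient(row_c[other_cols], p$congruent_ideal)
      od <- orient(row_d[other_cols], p$discrepant_self)
      info[[length(info) + 1L]] <- data.frame(
        kind = p$kind, congruent_index = ci, discrepant_index = di,
        construct_index = NA_integer_, target_r = p$target_r,
        realized_r = .pearson_int(oc, od),
        stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(spec$background_constructs)) {
    row <- integer(E)
    row[self_col] <- sample(sc$min_rating:sc$max_rating, 1L)
    ideal_choices <- setdiff(sc$min_rating:sc$max_rating, sc$midpoint)
    row[ideal_col] <- sample(ideal_choices, 1L)
    row[other_cols] <- sample(sc$min_rating:sc$max_rating, n_other,
                              replace = TRUE)
    k <- k + 1L
    rows[[k]] <- row
    poles[[k]] <- c(sprintf("pole%dL", k), sprintf("pole%dR", k))
  }

  ratings <- do.call(rbind, rows)
  pole_df <- do.call(rbind, lapply(poles, function(p) {
    data.frame(left_pole = p[1L], right_pole = p[2L],
               stringsAsFactors = FALSE)
  }))
  g <- repgrid(
    ratings = ratings,
    elements = c("Self", "Ideal", sprintf("Other%02d", seq_len(n_other))),
    roles = c("self", "ideal", rep("other", n_other)),
    constructs = pole_df,
    scale = sc
  )
  plant_info <- if (length(info) > 0L) do.call(rbind, info) else
    data.frame(kind = character(), congruent_index = integer(),
               discrepant_index = integer(), construct_index = integer(),
               target_r = numeric(), realized_r = numeric(),
               stringsAsFactors = FALSE)
  attr(g, "plant_info") <- plant_info
  g
}

#' Empirical false-positive rate of the dilemma rule on null pairs
#'
#' Generates grids whose single pair plant has latent correlation zero
#' and measures how often the strictly-positive-correlation rule still
#' flags the pair: a Monte-Carlo estimate of the one-sided tail
#' probability of the oriented sample correlation exceeding the threshold
#' at this element count. Replicate streams use seeds `seed + 1`,
#' `seed + 2`, ..., so runs are reproducible and extensible.
#'
#' @param n_other_elements Significant others per grid (total elements is
#'   this plus self and ideal).
#' @param n_replicates Number of independent grids (at least 100).
#' @param seed Base integer seed.
#' @param params A [detection_parameters()].
#' @return Fraction of replicates in which the planted null pair is
#'   flagged as an implicative dilemma.
#' @export
null_detection_rate <- function(n_other_elements = 13L,
                                n_replicates = 500L, seed = 1L,
                                params = detection_parameters()) {
  if (n_replicates < 100L) {
    stop("n_replicates must be at least 100", call. = FALSE)
  }
  hits <- 0L
  for (i in seq_len(n_replicates)) {
    spec <- simulation_spec(
      n_other_elements = n_other_elements,
      plants = list(plant_spec("null_pair")),
      seed = seed + i
    )
    g <- generate_grid(spec)
    r <- suppressWarnings(oriented_correlation(g, 1L, 2L, params))
    if (!is.na(r) && r > params$correlation_threshold) hits <- hits + 1L
  }
  hits / n_replicates
}

# greatest-common-divisor rationalization of the threshold: smallest
# denominator q <= 1000 with |threshold - p/q| < 1e-9, or NULL
.rationalize <- function(x, max_q = 1000L, tol = 1e-9) {
  for (q in seq_len(max_q)) {
    p <- round(x * q)
    if (abs(x - p / q) < tol) return(c(p = p, q = q))
  }
  NULL
}

# integer sums of a candidate pair (anchors + other cells); the exactness
# test q^2 * covn^2 == p^2 * v1 * v2 is pure integer arithmetic, so a hit
# means the Pearson correlation is exactly p/q, no rounding involved
.pair_sums <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  covn <- n * sum(x * y) - sx * sy
  v1 <- n * sum(x * x) - sx * sx
  v2 <- n * sum(y * y) - sy * sy
  c(covn = covn, v1 = v1, v2 = v2)
}

#' Locate the dilemma rule's decision boundary empirically
#'
#' Searches over integer rating-row pairs (with self/ideal anchors fixed
#' so the pair classifies congruent/discrepant) for correlations that
#' bracket the configured threshold, runs the detector on each candidate
#' grid, and returns the supremum of correlations the detector did NOT
#' flag. When the threshold is a ratio of small integers (0.35 = 7/20,
#' 0.5 = 1/2, ...), an integer hill-climb finds rows whose Pearson
#' correlation equals the threshold exactly — verifying that the rule is
#' strict: a pair exactly at the threshold is never a dilemma.
#'
#' @param params A [detection_parameters()].
#' @param seed Integer seed for the search.
#' @param n_other Number of other-role elements in the candidate rows
#'   (default 8).
#' @param n_random Random bracketing candidates to try (default 3000).
#' @return The boundary estimate: the largest oriented correlation found
#'   that the detector does not flag. Equals the configured threshold
#'   when an exactly-at-threshold pair exists in the search space.
#' @export
bracket_threshold <- function(params = detection_parameters(), seed = 1L,
                              n_other = 8L, n_random = 3000L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  sc <- rating_scale()
  lv <- sc$min_rating:sc$max_rating
  anchors_x <- c(2L, 1L)  # congruent: self 2, ideal 1
  anchors_y <- c(2L, 7L)  # discrepant: self 2, ideal 7
  make_grid <- function(xo, yo) {
    repgrid(
      ratings = rbind(c(anchors_x, xo), c(anchors_y, yo)),
      elements = c("Self", "Ideal", sprintf("O%d", seq_along(xo))),
      roles = c("self", "ideal", rep("other", length(xo))),
      constructs = data.frame(left_pole = c("c1L", "c2L"),
                              right_pole = c("c1R", "c2R"),
                              stringsAsFactors = FALSE),
      scale = sc
    )
  }
  flagged <- function(xo, yo) {
    d <- suppressWarnings(detect_implicative_dilemmas(make_grid(xo, yo),
                                                      params))
    nrow(d) > 0L
  }
  oracle_r <- function(xo, yo) {
    s <- .pair_sums(c(anchors_x, xo), c(anchors_y, yo))
    if (s["v1"] <= 0 || s["v2"] <= 0) return(NA_real_)
    unname(s["covn"] / sqrt(s["v1"] * s["v2"]))
  }

  best_unflagged <- -Inf

  # 1) exact-threshold pair via integer hill-climb, when the threshold
  #    is rational with a small denominator. The row length varies per
  #    restart (the attainable-correlation lattice differs with n, which
  #    multiplies the chances of an exact hit) and occasional uphill
  #    moves keep the climb out of local minima.
  pq <- .rationalize(params$correlation_threshold)
  if (!is.null(pq)) {
    p <- pq[["p"]]; q <- pq[["q"]]
    objective <- function(xo, yo) {
      s <- .pair_sums(c(anchors_x, xo), c(anchors_y, yo))
      if (s[["covn"]] <= 0 || s[["v1"]] <= 0 || s[["v2"]] <= 0) return(Inf)
      abs(q^2 * s[["covn"]]^2 - p^2 * s[["v1"]] * s[["v2"]])
    }
    done <- FALSE
    for (restart in 1:300) {
      if (done) break
      m <- 5L + (restart %% 6L)
      xo <- sample(lv, m, replace = TRUE)
      yo <- sample(lv, m, replace = TRUE)
      cur <- objective(xo, yo)
      for (it in 1:2000) {
        if (cur == 0) break
        i <- sample.int(m, 1L)
        v <- sample(lv, 1L)
        if (stats::runif(1) < 0.5) {
          cand_x <- xo; cand_x[i] <- v
          val <- objective(cand_x, yo)
          if (val <= cur || stats::runif(1) < 0.02) { xo <- cand_x; cur <- val }
        } else {
          cand_y <- yo; cand_y[i] <- v
          val <- objective(xo, cand_y)
          if (val <= cur || stats::runif(1) < 0.02) { yo <- cand_y; cur <- val }
        }
      }
      if (cur == 0 && !flagged(xo, yo)) {
        best_unflagged <- max(best_unflagged, oracle_r(xo, yo))
        done <- TRUE
      }
    }
  }

  # 2) random bracketing from below: tighten the supremum of unflagged
  #    correlations towards the threshold
  thr <- params$correlation_threshold
  for (i in seq_len(n_random)) {
    xo <- sample(lv, n_other, replace = TRUE)
    yo <- sample(lv, n_other, replace = TRUE)
    r <- oracle_r(xo, yo)
    if (is.na(r) || r > thr || r <= best_unflagged) next
    if (!flagged(xo, yo)) best_unflagged <- max(best_unflagged, r)
  }
  best_unflagged
}
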