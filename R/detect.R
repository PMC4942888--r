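#' Parameters of the conflict-detection procedure
#'
#' @param correlation_threshold Strictly positive correlation above which a
#'   congruent-discrepant pair is flagged as an implicative dilemma. The
#'   comparison is strict (`r > threshold`, not `>=`). Default 0.35.
#' @param congruent_gap_max Largest `|self - ideal|` gap still counted as
#'   "rated similarly" (congruent). Default 1.
#' @param discrepant_gap_min Smallest gap counted as "opposite poles"
#'   (discrepant). Default 4; on a 1-7 scale a gap of 4 forces self and
#'   ideal onto opposite sides of the midpoint.
#' @param include_self_ideal Should the self and ideal columns enter the
#'   correlation? Default `TRUE` (all elements). Set `FALSE` to correlate
#'   over significant others only.
#' @param pole_membership_margin Minimal distance from the midpoint for an
#'   element to count as sitting on a pole when prototypical figures are
#'   identified. Default 1 (any rating strictly off the midpoint).
#' @return An object of class `detection_parameters`.
#' @export
detection_parameters <- function(correlation_threshold = 0.35,
                                 congruent_gap_max = 1L,
                                 discrepant_gap_min = 4L,
                                 include_self_ideal = TRUE,
                                 pole_membership_margin = 1L) {
  congruent_gap_max <- as.integer(congruent_gap_max)
  discrepant_gap_min <- as.integer(discrepant_gap_min)
  if (!(correlation_threshold > 0 && correlation_threshold < 1)) {
    stop("correlation_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (congruent_gap_max >= discrepant_gap_min) {
    stop("congruent_gap_max must be smaller than discrepant_gap_min",
         call. = FALSE)
  }
  if (pole_membership_margin < 1L) {
    stop("pole_membership_margin must be at least 1", call. = FALSE)
  }
  structure(
    list(correlation_threshold = correlation_threshold,
         congruent_gap_max = congruent_gap_max,
         discrepant_gap_min = discrepant_gap_min,
         include_self_ideal = isTRUE(include_self_ideal),
         pole_membership_margin = as.integer(pole_membership_margin)),
    class = "detection_parameters"
  )
}

#' Classify one construct from its self and ideal ratings
#'
#' The dilemmatic rule takes precedence: a construct whose ideal-self
#' rating equals the scale midpoint is dilemmatic regardless of the self
#' rating (neither pole is a clear direction of change). Otherwise the
#' absolute self-ideal gap decides: small gaps are congruent (no change
#' wished), large gaps discrepant (change wished), intermediate gaps
#' neutral and ineligible for dilemma detection.
#'
#' @param grid A `repgrid`.
#' @param construct_index 1-based construct row.
#' @param params A [detection_parameters()].
#' @return A list with `construct_index`, `category` (one of `congruent`,
#'   `discrepant`, `dilemmatic`, `neutral`), `self_rating`, `ideal_rating`
#'   and `gap`.
#' @export
classify_construct <- function(grid, construct_index,
                               params = detection_parameters()) {
  if (construct_index < 1L || construct_index > n_constructs(grid)) {
    stop("construct_index out of range", call. = FALSE)
  }
  s <- grid$ratings[construct_index, self_index(grid)]
  i <- grid$ratings[construct_index, ideal_index(grid)]
  gap <- abs(s - i)
  category <-
    if (i == grid$scale$midpoint) "dilemmatic"
    else if (gap <= params$congruent_gap_max) "congruent"
    else if (gap >= params$discrepant_gap_min) "discrepant"
    else "neutral"
  list(construct_index = as.integer(construct_index),
       category = category,
       self_rating = as.integer(s),
       ideal_rating = as.integer(i),
       gap = as.integer(gap))
}

#' Classify every construct of a grid
#'
#' @inheritParams classify_construct
#' @return A data.frame with one row per construct: `construct_index`,
#'   `left_pole`, `right_pole`, `category`, `self_rating`, `ideal_rating`,
#'   `gap`.
#' @export
classify_constructs <- function(grid, params = detection_parameters()) {
  rows <- lapply(seq_len(n_constructs(grid)), function(k) {
    cl <- classify_construct(grid, k, params)
    data.frame(construct_index = cl$construct_index,
               left_pole = grid$constructs$left_pole[k],
               right_pole = grid$constructs$right_pole[k],
               category = cl$category,
               self_rating = cl$self_rating,
               ideal_rating = cl$ideal_rating,
               gap = cl$gap,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Pearson correlation from exact integer sums. Ratings are small integers,
# so every accumulated sum is exact in double precision; one correctly-
# rounded sqrt and one division leave the result within 2 ulp of the true
# value and bit-reproducible across element orderings, which matters
# because the dilemma rule compares r against a strict threshold.
.pearson_int <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  covn <- n * sum(x * y) - sx * sy
  v1 <- n * sum(x * x) - sx * sx
  v2 <- n * sum(y * y) - sy * sy
  if (v1 <= 0 || v2 <= 0) return(NA_real_)
  covn / sqrt(v1 * v2)
}

# Orient a construct's rating row so that its reference pole lies at the
# low end of the scale; reflect when the reference element's rating sits
# above the midpoint. reference: "ideal" for congruent constructs (the
# desired pole, which self shares), "self" for discrepant constructs (the
# present/symptom pole). Returns the oriented row plus which original side
# ("left"/"right") ended up low.
.orient_row <- function(grid, construct_index, reference) {
  row <- grid$ratings[construct_index, ]
  ref_col <- if (reference == "ideal") ideal_index(grid) else self_index(grid)
  ref_rating <- row[ref_col]
  sc <- grid$scale
  if (ref_rating > sc$midpoint) {
    list(row = sc$min_rating + sc$max_rating - row, low_side = "right")
  } else {
    list(row = row, low_side = "left")
  }
}

#' Oriented correlation between a congruent and a discrepant construct
#'
#' Computes the Pearson correlation between two construct rating rows
#' after fixing each row's direction so that its sign carries the meaning
#' of an implicative dilemma: the congruent construct is oriented with the
#' ideal element's pole (the desired pole, which the self shares) at the
#' low end of the scale, and the discrepant construct with the self
#' element's pole (the present/symptom pole) at the low end. A positive
#' oriented correlation then means that moving towards the desired pole of
#' the discrepant construct co-varies with moving away from the desired
#' pole of the congruent one.
#'
#' @param grid A `repgrid`.
#' @param congruent_index,discrepant_index 1-based construct rows.
#' @param params A [detection_parameters()]; `include_self_ideal` selects
#'   the element set the correlation runs over.
#' @return The oriented Pearson correlation in `[-1, 1]`, or `NA` with a
#'   warning when either row has zero variance over the chosen element
#'   set (the caller treats `NA` as "no dilemma").
#' @examples
#' g <- example_grid()
#' oriented_correlation(g, 1, 2)  # about 0.367
#' @export
oriented_correlation <- function(grid, congruent_index, discrepant_index,
                                 params = detection_parameters()) {
  oc <- .orient_row(grid, congruent_index, "ideal")
  od <- .orient_row(grid, discrepant_index, "self")
  cols <- if (params$include_self_ideal) seq_len(n_elements(grid))
          else other_indices(grid)
  x <- oc$row[cols]
  y <- od$row[cols]
  r <- .pearson_int(x, y)
  if (is.na(r)) {
    warning(sprintf(
      "undefined correlation for constructs %d and %d: zero rating variance",
      congruent_index, discrepant_index), call. = FALSE)
  }
  r
}

# Pole labels of a construct as seen from an element's rating side.
.pole_label <- function(grid, construct_index, side) {
  if (side == "left") grid$constructs$left_pole[construct_index]
  else grid$constructs$right_pole[construct_index]
}

.opposite_side <- function(side) if (side == "left") "right" else "left"

#' Detect implicative dilemmas
#'
#' Scans every (congruent, discrepant) construct pair and flags the pair
#' as an implicative dilemma when its oriented correlation strictly
#' exceeds the threshold: the change the person desires on the discrepant
#' construct is associated with an undesired change on a construct they do
#' not wish to move on. Dilemmatic and neutral constructs never
#' participate.
#'
#' @inheritParams classify_constructs
#' @return A data.frame of class `implicative_dilemmas`, sorted by
#'   descending oriented correlation (ties by index pair), with columns
#'   `congruent_index`, `discrepant_index`, `oriented_r`, and the four
#'   pole labels `self_pole_congruent` (the desired pole the self sits
#'   on), `undesired_pole_congruent`, `present_pole_discrepant` (the
#'   symptom pole) and `desired_pole_discrepant`. Zero rows when no pair
#'   qualifies. Pairs with undefined correlation are skipped with a
#'   warning.
#' @examples
#' detect_implicative_dilemmas(example_grid())
#' @export
detect_implicative_dilemmas <- function(grid,
                                        params = detection_parameters()) {
  cls <- classify_constructs(grid, params)
  congruent <- cls$construct_index[cls$category == "congruent"]
  discrepant <- cls$construct_index[cls$category == "discrepant"]
  out <- list()
  sc <- grid$scale
  for (ci in congruent) {
    for (di in discrepant) {
      r <- oriented_correlation(grid, ci, di, params)
      if (is.na(r) || r <= params$correlation_threshold) next
      ideal_side <- pole_of_rating(grid$ratings[ci, ideal_index(grid)], sc)
      self_side <- pole_of_rating(grid$ratings[di, self_index(grid)], sc)
      out[[length(out) + 1L]] <- data.frame(
        congruent_index = ci,
        discrepant_index = di,
        oriented_r = r,
        self_pole_congruent = .pole_label(grid, ci, ideal_side),
        undesired_pole_congruent = .pole_label(grid, ci, .opposite_side(ideal_side)),
        present_pole_discrepant = .pole_label(grid, di, self_side),
        desired_pole_discrepant = .pole_label(grid, di, .opposite_side(self_side)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(congruent_index = integer(), discrepant_index = integer(),
                      oriented_r = numeric(), self_pole_congruent = character(),
                      undesired_pole_congruent = character(),
                      present_pole_discrepant = character(),
                      desired_pole_discrepant = character(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(-res$oriented_r, res$congruent_index,
                     res$discrepant_index), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("implicative_dilemmas", "data.frame")
  res
}

#' Detect dilemmatic constructs
#'
#' A construct is dilemmatic when the ideal self is rated exactly at the
#' scale midpoint: neither pole appears preferable, so the construct
#' offers no clear course of action.
#'
#' @param grid A `repgrid`.
#' @return Ascending integer vector of dilemmatic construct indices.
#' @export
detect_dilemmatic_constructs <- function(grid) {
  ideal <- grid$ratings[, ideal_index(grid)]
  which(ideal == grid$scale$midpoint)
}

# TRUE when the element's rating sits on the given side of the midpoint
# by at least `margin` scale points.
.on_pole <- function(rating, side, scale, margin) {
  if (side == "left") rating <= scale$midpoint - margin
  else rating >= scale$midpoint + margin
}

#' Prototypical figures of an implicative dilemma
#'
#' Splits the significant others into the "two kinds of people" a dilemma
#' describes: elements rated on the self/desired pole of the congruent
#' construct and the present pole of the discrepant construct exemplify
#' the person's current position; elements on the undesired pole of the
#' congruent and the desired pole of the discrepant exemplify what change
#' would look like. Self and ideal are never included; an element rated at
#' the midpoint of either construct belongs to neither side.
#'
#' @param grid A `repgrid`.
#' @param dilemma One row of the data.frame returned by
#'   [detect_implicative_dilemmas()] (a one-row data.frame or a list with
#'   `congruent_index` and `discrepant_index`).
#' @param params A [detection_parameters()]; `pole_membership_margin`
#'   sets how far from the midpoint a rating must be to count.
#' @return A list with integer vectors `current_side` and `change_side`
#'   (element column indices) and matching label vectors
#'   `current_side_labels`, `change_side_labels`.
#' @examples
#' g <- example_grid()
#' d <- detect_implicative_dilemmas(g)
#' find_prototypical_figures(g, d[1, ])
#' @export
find_prototypical_figures <- function(grid, dilemma,
                                      params = detection_parameters()) {
  ci <- dilemma$congruent_index
  di <- dilemma$discrepant_index
  sc <- grid$scale
  m <- params$pole_membership_margin
  ideal_side <- pole_of_rating(grid$ratings[ci, ideal_index(grid)], sc)
  self_side <- pole_of_rating(grid$ratings[di, self_index(grid)], sc)
  others <- other_indices(grid)
  rc <- grid$ratings[ci, others]
  rd <- grid$ratings[di, others]
  current <- others[.on_pole(rc, ideal_side, sc, m) &
                    .on_pole(rd, self_side, sc, m)]
  change <- others[.on_pole(rc, .opposite_side(ideal_side), sc, m) &
                   .on_pole(rd, .opposite_side(self_side), sc, m)]
  list(current_side = current,
       change_side = change,
       current_side_labels = grid$elements$label[current],
       change_side_labels = grid$elements$label[change])
}

#' Prototypical figures of a dilemmatic construct
#'
#' For a dilemmatic construct the prototypes are the significant others
#' rated at either pole with the most extreme score the person actually
#' used on that side of the midpoint (the used range, not the theoretical
#' scale extremes). Ties are kept; a side with no off-midpoint rating is
#' empty.
#'
#' @param grid A `repgrid`.
#' @param construct_index Index of a dilemmatic construct (ideal rating at
#'   the midpoint); anything else is an error.
#' @return A list with integer vectors `left_side` and `right_side`
#'   (element column indices) plus matching `left_side_labels`,
#'   `right_side_labels`, and the extreme ratings used
#'   (`left_extreme`, `right_extreme`, `NA` for an empty side).
#' @export
find_dilemmatic_prototypes <- function(grid, construct_index) {
  if (!(construct_index %in% detect_dilemmatic_constructs(grid))) {
    stop(sprintf("construct %d is not dilemmatic (ideal rating != midpoint)",
                 construct_index), call. = FALSE)
  }
  sc <- grid$scale
  others <- other_indices(grid)
  r <- grid$ratings[construct_index, others]
  left_vals <- r[r < sc$midpoint]
  right_vals <- r[r > sc$midpoint]
  left_extreme <- if (length(left_vals) > 0L) min(left_vals) else NA_integer_
  right_extreme <- if (length(right_vals) > 0L) max(right_vals) else NA_integer_
  left_side <- if (is.na(left_extreme)) integer() else others[r == left_extreme]
  right_side <- if (is.na(right_extreme)) integer() else others[r == right_extreme]
  list(left_side = left_side,
       right_side = right_side,
       left_side_labels = grid$elements$label[left_side],
       right_side_labels = grid$elements$label[right_side],
       left_extreme = left_extreme,
       right_extreme = right_extreme)
}

#' Run the full conflict analysis of one grid
#'
#' Convenience pipeline: classification of every construct, implicative
#' dilemma detection with prototypical figures, dilemmatic constructs with
#' their pole prototypes, and the four summary indices.
#'
#' @inheritParams classify_constructs
#' @return A list of class `grid_analysis` with components
#'   `classifications`, `dilemmas`, `figures` (one entry per dilemma),
#'   `dilemmatic_constructs`, `dilemmatic_prototypes`, `indices`,
#'   `params` and `grid`.
#' @examples
#' a <- analyze_grid(example_grid())
#' a$dilemmas
#' a$indices
#' @export
analyze_grid <- function(grid, params = detection_parameters()) {
  dil <- detect_implicative_dilemmas(grid, params)
  figures <- lapply(seq_len(nrow(dil)), function(i) {
    find_prototypical_figures(grid, dil[i, ], params)
  })
  dilemmatic <- detect_dilemmatic_constructs(grid)
  dil_proto <- lapply(dilemmatic, function(k) {
    find_dilemmatic_prototypes(grid, k)
  })
  names(dil_proto) <- as.character(dilemmatic)
  structure(
    list(classifications = classify_constructs(grid, params),
         dilemmas = dil,
         figures = figures,
         dilemmatic_constructs = dilemmatic,
         dilemmatic_prototypes = dil_proto,
         indices = grid_indices(grid),
         params = params,
         grid = grid),
    class = "grid_analysis"
  )
}

#' @export
print.grid_analysis <- function(x, ...) {
  cat(render_report(x))
  invisible(x)
}
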