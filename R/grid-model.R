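#' Rating scale of a repertory grid
#'
#' A symmetric Likert scale with an explicit midpoint. The midpoint is the
#' anchor of the dilemmatic-construct rule: a construct whose ideal-self
#' rating sits exactly at the midpoint offers no preferred pole.
#'
#' @param min_rating Integer, lowest admissible rating (default 1).
#' @param max_rating Integer, highest admissible rating (default 7).
#' @return An object of class `rating_scale` with fields `min_rating`,
#'   `max_rating` and `midpoint`.
#' @details Only symmetric scales are accepted: the midpoint must equal
#'   `(min_rating + max_rating) / 2` exactly, which requires an odd number
#'   of levels. Asymmetric scales are rejected because the dilemmatic rule
#'   is defined by the midpoint.
#' @examples
#' rating_scale()          # the standard 1-7 scale, midpoint 4
#' rating_scale(1, 5)      # a 5-point scale, midpoint 3
#' @export
rating_scale <- function(min_rating = 1L, max_rating = 7L) {
  min_rating <- as.integer(min_rating)
  max_rating <- as.integer(max_rating)
  if (is.na(min_rating) || is.na(max_rating)) {
    stop("scale bounds must be integers", call. = FALSE)
  }
  if (max_rating <= min_rating) {
    stop("max_rating must exceed min_rating", call. = FALSE)
  }
  if ((min_rating + max_rating) %% 2L != 0L) {
    stop("scale must be symmetric: min_rating + max_rating must be even ",
         "so that the midpoint is an attainable integer rating",
         call. = FALSE)
  }
  midpoint <- (min_rating + max_rating) %/% 2L
  structure(
    list(min_rating = min_rating, max_rating = max_rating,
         midpoint = midpoint),
    class = "rating_scale"
  )
}

#' @export
print.rating_scale <- function(x, ...) {
  cat(sprintf("<rating_scale %d-%d, midpoint %d>\n",
              x$min_rating, x$max_rating, x$midpoint))
  invisible(x)
}

#' Width of a rating scale
#'
#' @param scale A [rating_scale()].
#' @return Integer, `max_rating - min_rating`.
#' @export
scale_span <- function(scale) {
  scale$max_rating - scale$min_rating
}

#' Construct a repertory grid
#'
#' A repertory grid holds integer ratings of E elements (significant
#' people, always including the current self and the ideal self) on C
#' bipolar personal constructs, each with a left and a right verbal pole.
#' Rows are constructs, columns are elements.
#'
#' @param ratings Integer matrix, C rows (constructs) by E columns
#'   (elements).
#' @param elements Either a data.frame with columns `label` and `role`
#'   (roles: `"self"`, `"ideal"`, `"other"`), or a character vector of
#'   labels combined with the `roles` argument.
#' @param constructs Either a data.frame with columns `left_pole` and
#'   `right_pole`, or a character vector of `"left - right"` labels split
#'   on `" - "`.
#' @param scale A [rating_scale()]; defaults to the 7-point scale.
#' @param roles Optional character vector of roles, used when `elements`
#'   is a plain character vector.
#' @return A validated object of class `repgrid`.
#' @examples
#' g <- repgrid(
#'   ratings = rbind(c(2, 1, 2, 6, 5), c(2, 7, 1, 6, 6)),
#'   elements = c("Self", "Ideal", "Mother", "Father", "Friend"),
#'   roles = c("self", "ideal", "other", "other", "other"),
#'   constructs = data.frame(left_pole = c("generous", "depressed"),
#'                           right_pole = c("selfish", "happy"))
#' )
#' g
#' @seealso [validate_grid()], [read_grid()]
#' @export
repgrid <- function(ratings, elements, constructs, scale = rating_scale(),
                    roles = NULL) {
  if (is.character(elements)) {
    if (is.null(roles)) stop("roles required when elements is a character vector",
                             call. = FALSE)
    elements <- data.frame(label = elements, role = roles,
                           stringsAsFactors = FALSE)
  }
  if (is.character(constructs)) {
    parts <- strsplit(constructs, " - ", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("construct labels must have the form \"left - right\"",
           call. = FALSE)
    }
    constructs <- data.frame(
      left_pole = vapply(parts, `[[`, "", 1L),
      right_pole = vapply(parts, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
  }
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "integer"
  dimnames(ratings) <- NULL
  g <- structure(
    list(ratings = ratings,
         elements = data.frame(label = as.character(elements$label),
                               role = as.character(elements$role),
                               stringsAsFactors = FALSE),
         constructs = data.frame(left_pole = as.character(constructs$left_pole),
                                 right_pole = as.character(constructs$right_pole),
                                 stringsAsFactors = FALSE),
         scale = scale),
    class = "repgrid"
  )
  problems <- validate_grid(g)
  if (length(problems) > 0L) {
    stop("invalid grid:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  g
}

#' Number of constructs / elements in a grid
#' @param grid A `repgrid`.
#' @return Integer count.
#' @export
n_constructs <- function(grid) nrow(grid$ratings)

#' @rdname n_constructs
#' @export
n_elements <- function(grid) ncol(grid$ratings)

#' Locate the self, ideal and other elements
#'
#' @param grid A `repgrid`.
#' @return `self_index()` and `ideal_index()` return a single column index;
#'   `other_indices()` returns the (possibly empty) ascending vector of
#'   columns whose role is `"other"`.
#' @export
self_index <- function(grid) which(grid$elements$role == "self")[1L]

#' @rdname self_index
#' @export
ideal_index <- function(grid) which(grid$elements$role == "ideal")[1L]

#' @rdname self_index
#' @export
other_indices <- function(grid) which(grid$elements$role == "other")

#' Validate a repertory grid
#'
#' Checks every structural invariant and returns diagnostics instead of
#' raising: exactly one self and one ideal element, all ratings integer
#' and within the scale bounds, no missing cells, at least 3 elements and
#' 2 constructs, and matching dimensions between ratings, elements and
#' constructs.
#'
#' @param grid A `repgrid` (or a list shaped like one; the validator is
#'   tolerant so it can diagnose malformed input).
#' @return Character vector of violation descriptions; empty when the
#'   grid is valid.
#' @export
validate_grid <- function(grid) {
  problems <- character()
  r <- grid$ratings
  if (!is.matrix(r)) {
    return("ratings is not a matrix")
  }
  C <- nrow(r); E <- ncol(r)
  if (C < 2L) problems <- c(problems, sprintf(
    "grid has %d construct(s); at least 2 are required", C))
  if (E < 3L) problems <- c(problems, sprintf(
    "grid has %d element(s); at least 3 are required", E))
  if (!is.null(grid$elements) && nrow(grid$elements) != E) {
    problems <- c(problems, sprintf(
      "element table has %d rows but ratings has %d columns",
      nrow(grid$elements), E))
  }
  if (!is.null(grid$constructs) && nrow(grid$constructs) != C) {
    problems <- c(problems, sprintf(
      "construct table has %d rows but ratings has %d rows",
      nrow(grid$constructs), C))
  }

  roles <- grid$elements$role
  n_self <- sum(roles == "self")
  n_ideal <- sum(roles == "ideal")
  if (n_self != 1L) problems <- c(problems, sprintf(
    "grid must have exactly one self element (found %d)", n_self))
  if (n_ideal != 1L) problems <- c(problems, sprintf(
    if (n_ideal > 1L) "duplicate ideal element (found %d)"
    else "no ideal element (found %d)", n_ideal))
  bad_role <- setdiff(unique(roles), c("self", "ideal", "other"))
  if (length(bad_role) > 0L) problems <- c(problems, sprintf(
    "unknown element role(s): %s", paste(bad_role, collapse = ", ")))
  if (any(!nzchar(grid$elements$label))) {
    problems <- c(problems, "element labels must be nonempty")
  }
  if (!is.null(grid$constructs)) {
    if (any(!nzchar(grid$constructs$left_pole)) ||
        any(!nzchar(grid$constructs$right_pole))) {
      problems <- c(problems, "construct pole labels must be nonempty")
    }
  }

  if (anyNA(r)) {
    nas <- which(is.na(r), arr.ind = TRUE)
    problems <- c(problems, sprintf(
      "missing rating at construct %d, element %d",
      nas[, 1L], nas[, 2L]))
  }
  sc <- grid$scale
  oob <- which(!is.na(r) & (r < sc$min_rating | r > sc$max_rating),
               arr.ind = TRUE)
  if (nrow(oob) > 0L) {
    problems <- c(problems, sprintf(
      "rating out of bounds (%d-%d): value %d at construct %d, element %d",
      sc$min_rating, sc$max_rating,
      r[oob], oob[, 1L], oob[, 2L]))
  }
  problems
}

#' Map a rating onto a construct pole
#'
#' Ratings below the scale midpoint indicate the left pole, ratings above
#' it the right pole; the midpoint itself indicates neither.
#'
#' @param rating Integer rating(s) within the scale bounds.
#' @param scale A [rating_scale()].
#' @return Character vector over `{"left", "right", "midpoint"}`.
#' @examples
#' pole_of_rating(c(2, 6, 4), rating_scale())
#' @export
pole_of_rating <- function(rating, scale = rating_scale()) {
  if (any(rating < scale$min_rating | rating > scale$max_rating)) {
    stop(sprintf("rating outside scale bounds %d-%d",
                 scale$min_rating, scale$max_rating), call. = FALSE)
  }
  ifelse(rating < scale$midpoint, "left",
         ifelse(rating > scale$midpoint, "right", "midpoint"))
}

#' Reflect a construct
#'
#' Swaps a construct's pole labels and mirrors its ratings about the scale
#' midpoint (`x -> min_rating + max_rating - x`). The represented meaning
#' is unchanged: a grid and its reflection describe the same person, so
#' every analysis in this package is invariant under reflection (up to the
#' corresponding pole-label swap).
#'
#' @param grid A `repgrid`.
#' @param construct_index 1-based construct row to reflect.
#' @return A new `repgrid`; the input is not modified.
#' @examples
#' g <- example_grid()
#' identical(reflect_construct(reflect_construct(g, 1), 1), g)  # involution
#' @export
reflect_construct <- function(grid, construct_index) {
  construct_index <- as.integer(construct_index)
  if (is.na(construct_index) || construct_index < 1L ||
      construct_index > n_constructs(grid)) {
    stop(sprintf("construct_index %s out of range 1-%d",
                 construct_index, n_constructs(grid)), call. = FALSE)
  }
  sc <- grid$scale
  g <- grid
  g$ratings[construct_index, ] <-
    sc$min_rating + sc$max_rating - g$ratings[construct_index, ]
  lp <- g$constructs$left_pole[construct_index]
  g$constructs$left_pole[construct_index] <- g$constructs$right_pole[construct_index]
  g$constructs$right_pole[construct_index] <- lp
  g
}

#' Worked example grid
#'
#' A small 5-element, 2-construct grid containing one implicative dilemma:
#' the person sees herself (and wants to remain) "generous" rather than
#' "selfish", wants to move from "depressed" to "happy", and the two
#' constructs correlate positively, so the desired change implies becoming
#' selfish. Used throughout the documentation and tests.
#'
#' @return A `repgrid` with elements Self, Ideal, Mother, Father, Friend.
#' @export
example_grid <- function() {
  repgrid(
    ratings = rbind(c(2L, 1L, 2L, 6L, 5L),
                    c(2L, 7L, 1L, 6L, 6L)),
    elements = c("Self", "Ideal", "Mother", "Father", "Friend"),
    roles = c("self", "ideal", "other", "other", "other"),
    constructs = data.frame(left_pole = c("generous", "depressed"),
                            right_pole = c("selfish", "happy"),
                            stringsAsFactors = FALSE)
  )
}

#' @export
print.repgrid <- function(x, ...) {
  C <- n_constructs(x); E <- n_elements(x)
  cat(sprintf("<repgrid: %d constructs x %d elements, scale %d-%d>\n",
              C, E, x$scale$min_rating, x$scale$max_rating))
  hdr <- x$elements$label
  hdr[self_index(x)] <- paste0(hdr[self_index(x)], "*")
  hdr[ideal_index(x)] <- paste0(hdr[ideal_index(x)], "**")
  m <- x$ratings
  dimnames(m) <- list(
    paste(x$constructs$left_pole, x$constructs$right_pole, sep = " - "),
    hdr
  )
  print(m)
  cat("(* self, ** ideal)\n")
  invisible(x)
}
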