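#' Grid file dialect
#'
#' The plain-text grid format is deliberately minimal:
#' \preformatted{
#' # optional comment lines
#' scale 1 7
#' SELF:Self<TAB>IDEAL:Ideal<TAB>Mother<TAB>Father<TAB>Friend
#' generous<TAB>2<TAB>1<TAB>2<TAB>6<TAB>5<TAB>selfish
#' depressed<TAB>2<TAB>7<TAB>1<TAB>6<TAB>6<TAB>happy
#' }
#' Line 1 (after comments) declares the scale bounds; line 2 lists the
#' element headers, exactly one carrying the `SELF:` prefix and one the
#' `IDEAL:` prefix; each further line is a construct: left pole, one
#' integer rating per element, right pole. Fields containing the
#' delimiter or a double quote are quoted CSV-style (doubled quotes
#' escape). Files are UTF-8.
#'
#' @param delimiter Single field-separator character (default TAB).
#' @param comment_prefix Lines starting with this prefix are skipped
#'   (default `"#"`).
#' @return An object of class `grid_dialect`.
#' @export
grid_dialect <- function(delimiter = "\t", comment_prefix = "#") {
  if (nchar(delimiter) != 1L) {
    stop("delimiter must be a single character", call. = FALSE)
  }
  structure(list(delimiter = delimiter, comment_prefix = comment_prefix),
            class = "grid_dialect")
}

# condition constructor for anything wrong with a grid file; carries the
# 1-based line (and column when known) of the offending content.
# validation = TRUE marks grid-invariant violations (a syntactically fine
# file describing an invalid grid), which the CLI maps to its own exit code
format_error <- function(message, line = NA_integer_, col = NA_integer_,
                         validation = FALSE) {
  where <- if (!is.na(line) && !is.na(col)) sprintf(" (line %d, column %d)", line, col)
           else if (!is.na(line)) sprintf(" (line %d)", line)
           else ""
  cls <- c(if (validation) "gridconflict_validation_error",
           "gridconflict_format_error", "error", "condition")
  stop(structure(
    class = cls,
    list(message = paste0(message, where), call = NULL,
         line = line, col = col)
  ))
}

.parse_delimited <- function(text, dialect, line_no) {
  out <- tryCatch(
    utils::read.table(text = text, sep = dialect$delimiter, quote = "\"",
                      colClasses = "character", header = FALSE,
                      comment.char = "", stringsAsFactors = FALSE),
    error = function(e) format_error(conditionMessage(e), line = line_no)
  )
  as.character(out[1L, ])
}

#' Read a repertory grid from a delimited text file
#'
#' @param path File path or connection in the [grid_dialect()] format.
#' @param dialect A [grid_dialect()].
#' @return A validated `repgrid`.
#' @details Parse failures and grid-invariant violations raise a
#'   condition of class `gridconflict_format_error` whose message names
#'   the offending line (and column for cell-level problems).
#' @seealso [write_grid()]
#' @export
read_grid <- function(path, dialect = grid_dialect()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(trimws(lines, "left"), dialect$comment_prefix) &
          nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 3L) {
    format_error("file must contain a scale line, a header line and at least one construct line")
  }

  scale_line <- trimws(lines[idx[1L]])
  m <- regmatches(scale_line,
                  regexec("^scale[ \t]+(-?[0-9]+)[ \t]+(-?[0-9]+)$", scale_line))[[1L]]
  if (length(m) != 3L) {
    format_error("expected 'scale <min> <max>'", line = idx[1L])
  }
  scale <- tryCatch(
    rating_scale(as.integer(m[2L]), as.integer(m[3L])),
    error = function(e) format_error(conditionMessage(e), line = idx[1L])
  )

  headers <- .parse_delimited(lines[idx[2L]], dialect, idx[2L])
  roles <- rep("other", length(headers))
  labels <- headers
  roles[startsWith(headers, "SELF:")] <- "self"
  roles[startsWith(headers, "IDEAL:")] <- "ideal"
  labels <- sub("^(SELF:|IDEAL:)", "", headers)
  if (sum(roles == "self") != 1L) {
    format_error("header must contain exactly one SELF: element", line = idx[2L])
  }
  if (sum(roles == "ideal") != 1L) {
    format_error("no ideal element: header must contain exactly one IDEAL: element",
                 line = idx[2L])
  }
  E <- length(headers)

  construct_lines <- idx[-(1:2)]
  left <- character(0); right <- character(0)
  ratings <- matrix(NA_integer_, nrow = length(construct_lines), ncol = E)
  for (i in seq_along(construct_lines)) {
    ln <- construct_lines[i]
    fields <- .parse_delimited(lines[ln], dialect, ln)
    if (length(fields) != E + 2L) {
      format_error(sprintf("expected %d fields (left pole, %d ratings, right pole) but found %d",
                           E + 2L, E, length(fields)), line = ln)
    }
    left[i] <- fields[1L]
    right[i] <- fields[E + 2L]
    for (j in seq_len(E)) {
      cell <- trimws(fields[j + 1L])
      if (!grepl("^-?[0-9]+$", cell)) {
        format_error(sprintf("rating '%s' is not an integer", cell),
                     line = ln, col = j + 1L)
      }
      ratings[i, j] <- as.integer(cell)
    }
  }

  g <- list(ratings = ratings,
            elements = data.frame(label = labels, role = roles,
                                  stringsAsFactors = FALSE),
            constructs = data.frame(left_pole = left, right_pole = right,
                                    stringsAsFactors = FALSE),
            scale = scale)
  class(g) <- "repgrid"
  problems <- validate_grid(g)
  if (length(problems) > 0L) {
    format_error(paste0("invalid grid: ",
                        paste(problems, collapse = "; ")),
                 validation = TRUE)
  }
  g
}

# CSV-convention quoting for one field
.quote_field <- function(x, delimiter) {
  needs <- grepl(delimiter, x, fixed = TRUE) | grepl("\"", x, fixed = TRUE) |
    grepl("^\\s|\\s$", x) | startsWith(x, "#")
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs], fixed = TRUE), "\"")
  x
}

#' Write a repertory grid to a delimited text file
#'
#' The written file reads back bit-identically: labels, roles, ratings
#' and scale all survive the round trip (`read_grid(write_grid(g)) == g`).
#'
#' @param grid A valid `repgrid`; invalid grids are rejected before
#'   anything is written.
#' @param path File path or connection.
#' @param dialect A [grid_dialect()].
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path, dialect = grid_dialect()) {
  problems <- validate_grid(grid)
  if (length(problems) > 0L) {
    stop("refusing to write invalid grid:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  d <- dialect$delimiter
  prefix <- c(self = "SELF:", ideal = "IDEAL:", other = "")
  headers <- paste0(prefix[grid$elements$role], grid$elements$label)
  lines <- c(
    sprintf("scale %d %d", grid$scale$min_rating, grid$scale$max_rating),
    paste(.quote_field(headers, d), collapse = d)
  )
  for (k in seq_len(n_constructs(grid))) {
    fields <- c(.quote_field(grid$constructs$left_pole[k], d),
                as.character(grid$ratings[k, ]),
                .quote_field(grid$constructs$right_pole[k], d))
    lines <- c(lines, paste(fields, collapse = d))
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

# round every numeric scalar in a nested list to 6 decimals (the only
# floats in a results document are correlations and indices)
.round_floats <- function(x) {
  if (is.list(x)) return(lapply(x, .round_floats))
  if (is.double(x)) return(round(x, 6L))
  x
}

.df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Build the structured results document of an analysis
#'
#' Collects everything [analyze_grid()] computed — grid summary,
#' classifications, dilemmas with their prototypical figures, dilemmatic
#' constructs with their pole prototypes, the four indices — together
#' with the exact parameters used, so every number in the document is
#' reproducible from the document alone.
#'
#' @param analysis A `grid_analysis` from [analyze_grid()].
#' @return A nested list mirroring the JSON schema shipped at
#'   `system.file("schema", "results-schema.json", package = "gridconflict")`.
#' @export
results_document <- function(analysis) {
  grid <- analysis$grid
  params <- analysis$params
  dil <- analysis$dilemmas
  dilemma_records <- lapply(seq_len(nrow(dil)), function(i) {
    fig <- analysis$figures[[i]]
    c(as.list(dil[i, , drop = FALSE]),
      list(prototypical_figures = list(
        current_side = as.list(fig$current_side_labels),
        change_side = as.list(fig$change_side_labels)
      )))
  })
  dilemmatic_records <- lapply(seq_along(analysis$dilemmatic_constructs),
                               function(i) {
    k <- analysis$dilemmatic_constructs[i]
    pr <- analysis$dilemmatic_prototypes[[i]]
    list(construct_index = k,
         left_pole = grid$constructs$left_pole[k],
         right_pole = grid$constructs$right_pole[k],
         left_prototypes = as.list(pr$left_side_labels),
         right_prototypes = as.list(pr$right_side_labels),
         left_extreme = pr$left_extreme,
         right_extreme = pr$right_extreme)
  })
  doc <- list(
    tool = "gridconflict",
    version = as.character(utils::packageVersion("gridconflict")),
    parameters = list(
      correlation_threshold = params$correlation_threshold,
      congruent_gap_max = params$congruent_gap_max,
      discrepant_gap_min = params$discrepant_gap_min,
      include_self_ideal = params$include_self_ideal,
      pole_membership_margin = params$pole_membership_margin
    ),
    grid = list(
      n_constructs = n_constructs(grid),
      n_elements = n_elements(grid),
      scale = list(min_rating = grid$scale$min_rating,
                   max_rating = grid$scale$max_rating,
                   midpoint = grid$scale$midpoint),
      elements = .df_to_records(grid$elements),
      constructs = .df_to_records(grid$constructs)
    ),
    classifications = .df_to_records(analysis$classifications),
    dilemmas = dilemma_records,
    dilemmatic_constructs = dilemmatic_records,
    indices = analysis$indices
  )
  .round_floats(doc)
}

#' Write analysis results as JSON
#'
#' @param result A `grid_analysis` (converted via [results_document()])
#'   or an already-built results document list.
#' @param path File path or connection.
#' @return Invisibly, `path`.
#' @details Key order is fixed by construction and floats are written at
#'   6 decimals, so identical analyses produce byte-identical documents.
#' @export
write_results <- function(result, path) {
  doc <- if (inherits(result, "grid_analysis")) results_document(result)
         else result
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

# ---- minimal JSON-schema subset validation -------------------------------

.js_type_ok <- function(value, type) {
  switch(type,
    object = is.list(value) && (length(value) == 0L || !is.null(names(value))),
    array = is.list(value) && is.null(names(value)),
    string = is.character(value) && length(value) == 1L,
    number = is.numeric(value) && length(value) == 1L,
    integer = is.numeric(value) && length(value) == 1L &&
      (is.na(value) || value == round(value)),
    boolean = is.logical(value) && length(value) == 1L,
    null = is.null(value),
    FALSE)
}

.js_validate <- function(value, schema, path) {
  problems <- character()
  if (!is.null(schema$type)) {
    types <- unlist(schema$type)
    if (!any(vapply(types, .js_type_ok, logical(1), value = value))) {
      return(sprintf("%s: expected type %s", path,
                     paste(types, collapse = "|")))
    }
  }
  if (!is.null(schema$enum)) {
    if (!(value %in% unlist(schema$enum))) {
      problems <- c(problems, sprintf("%s: value '%s' not in enum", path, value))
    }
  }
  if (!is.null(schema$required)) {
    missing <- setdiff(unlist(schema$required), names(value))
    if (length(missing) > 0L) {
      problems <- c(problems, sprintf("%s: missing required key '%s'",
                                      path, missing))
    }
  }
  if (!is.null(schema$properties) && is.list(value)) {
    for (key in intersect(names(schema$properties), names(value))) {
      problems <- c(problems, .js_validate(value[[key]],
                                           schema$properties[[key]],
                                           paste0(path, ".", key)))
    }
  }
  if (!is.null(schema$items) && is.list(value) && is.null(names(value))) {
    for (i in seq_along(value)) {
      problems <- c(problems, .js_validate(value[[i]], schema$items,
                                           sprintf("%s[%d]", path, i)))
    }
  }
  problems
}

#' Validate a results document against the shipped schema
#'
#' Checks a results document (a list, or a path to a JSON file) against
#' the JSON schema at `inst/schema/results-schema.json`. The checker
#' implements the schema subset the shipped schema uses: `type`,
#' `required`, `properties`, `items` and `enum`.
#'
#' @param doc A results-document list or a path to a JSON file.
#' @param schema_path Path to the schema; defaults to the shipped one.
#' @return Character vector of violations; empty when valid.
#' @export
validate_results_document <- function(doc,
    schema_path = system.file("schema", "results-schema.json",
                              package = "gridconflict")) {
  if (is.character(doc) && length(doc) == 1L) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  .js_validate(doc, schema, path = "$")
}
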