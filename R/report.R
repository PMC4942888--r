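#' Render a human-readable case-formulation report
#'
#' Produces the plain-text report a practitioner would read: the
#' construct classification, every implicative dilemma laid out as two
#' columns — the person's current position against what change would
#' imply, each side with its prototypical figures — the dilemmatic
#' constructs with their pole prototypes, the four summary indices and a
#' parameters footer. The wording is deliberately descriptive
#' ("associated with"), since a detected dilemma is a hypothesis to
#' explore with the person, not a diagnosis.
#'
#' @param result A `grid_analysis` from [analyze_grid()] or a results
#'   document (list, or path to a JSON file written by
#'   [write_results()]). Rendering from the JSON document reproduces the
#'   report byte-identically.
#' @return A single character string (the report, ending in a newline).
#' @examples
#' cat(render_report(analyze_grid(example_grid())))
#' @export
render_report <- function(result) {
  doc <- if (inherits(result, "grid_analysis")) results_document(result)
         else if (is.character(result) && length(result) == 1L)
           jsonlite::fromJSON(result, simplifyVector = FALSE)
         else result

  num <- function(x, digits = 3L) formatC(x, format = "f", digits = digits)
  pad <- function(x, width) formatC(x, width = -width)
  out <- character()
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  push("Repertory grid conflict report (gridconflict ", doc$version, ")")
  push(strrep("=", nchar(out[[1L]])))
  push("")
  roles <- vapply(doc$grid$elements, `[[`, "", "role")
  labels <- vapply(doc$grid$elements, `[[`, "", "label")
  push(sprintf("Grid: %d constructs x %d elements, scale %d-%d",
               doc$grid$n_constructs, doc$grid$n_elements,
               doc$grid$scale$min_rating, doc$grid$scale$max_rating))
  push(sprintf("Self: %s | Ideal: %s | Others: %s",
               labels[roles == "self"], labels[roles == "ideal"],
               paste(labels[roles == "other"], collapse = ", ")))
  push("")

  push("Construct classification")
  for (cl in doc$classifications) {
    push(sprintf("  %2d. %s  %s (self %d, ideal %d, gap %d)",
                 cl$construct_index,
                 pad(paste(cl$left_pole, cl$right_pole, sep = " - "), 30L),
                 pad(cl$category, 11L),
                 cl$self_rating, cl$ideal_rating, cl$gap))
  }
  push("")

  n_dil <- length(doc$dilemmas)
  push(sprintf("Implicative dilemmas (%d)", n_dil))
  if (n_dil == 0L) {
    push("  no implicative dilemmas detected")
  }
  for (i in seq_len(n_dil)) {
    d <- doc$dilemmas[[i]]
    cur <- vapply(d$prototypical_figures$current_side, identity, "")
    chg <- vapply(d$prototypical_figures$change_side, identity, "")
    push(sprintf("  Dilemma %d: constructs %d and %d, oriented r = %s",
                 i, d$congruent_index, d$discrepant_index,
                 num(d$oriented_r)))
    push(sprintf("    staying \"%s\" is associated with staying \"%s\";",
                 d$self_pole_congruent, d$present_pole_discrepant))
    push(sprintf("    becoming \"%s\" is associated with becoming \"%s\"",
                 d$desired_pole_discrepant, d$undesired_pole_congruent))
    push(sprintf("    %s%s", pad("Current position", 34L),
                 "Implication of change"))
    push(sprintf("    %s%s", pad(d$self_pole_congruent, 34L),
                 d$undesired_pole_congruent))
    push(sprintf("    %s%s", pad(d$present_pole_discrepant, 34L),
                 d$desired_pole_discrepant))
    push(sprintf("    %s%s",
                 pad(paste0("Figures: ",
                            if (length(cur)) paste(cur, collapse = ", ")
                            else "(none)"), 34L),
                 paste0("Figures: ",
                        if (length(chg)) paste(chg, collapse = ", ")
                        else "(none)")))
  }
  push("")

  n_dtic <- length(doc$dilemmatic_constructs)
  push(sprintf("Dilemmatic constructs (%d)", n_dtic))
  if (n_dtic == 0L) push("  none")
  for (dc in doc$dilemmatic_constructs) {
    lp <- vapply(dc$left_prototypes, identity, "")
    rp <- vapply(dc$right_prototypes, identity, "")
    push(sprintf("  %2d. %s - %s (ideal at midpoint)",
                 dc$construct_index, dc$left_pole, dc$right_pole))
    push(sprintf("      \"%s\" prototypes: %s", dc$left_pole,
                 if (length(lp)) paste(lp, collapse = ", ") else "(none)"))
    push(sprintf("      \"%s\" prototypes: %s", dc$right_pole,
                 if (length(rp)) paste(rp, collapse = ", ") else "(none)"))
  }
  push("")

  ix <- doc$indices
  fmt_ix <- function(x, ...) if (is.null(x) || is.na(x)) "n/a" else num(x, ...)
  push("Indices")
  push(sprintf("  self-ideal discrepancy : %s", fmt_ix(ix$self_ideal_discrepancy)))
  push(sprintf("  self isolation         : %s", fmt_ix(ix$self_isolation)))
  push(sprintf("  adequacy of others     : %s", fmt_ix(ix$adequacy_of_others)))
  push(sprintf("  polarization           : %s %%", fmt_ix(ix$polarization, 1L)))
  push("")

  p <- doc$parameters
  push(sprintf(paste0("Parameters: dilemma rule r > %s; congruent gap <= %d; ",
                      "discrepant gap >= %d; correlation over %s; ",
                      "pole margin %d"),
               format(p$correlation_threshold),
               p$congruent_gap_max, p$discrepant_gap_min,
               if (isTRUE(p$include_self_ideal)) "all elements"
               else "other elements only",
               p$pole_membership_margin))
  paste0(paste(out, collapse = "\n"), "\n")
}
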