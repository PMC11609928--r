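#' Acupoint registry: the declarative rule table
#'
#' The registry is a versioned, human-editable JSON table
#' (`acumap-rules/1` format) holding one entry per acupoint: code, full name,
#' meridian, body region, the postures/poses under which the point is
#' locatable, and an ordered list of proportional-geometry steps evaluated by
#' [apply_rule()]. Rules are data, not code: all 38 shipped points live in one
#' reviewable file, and each entry carries a provenance note because only one
#' recipe (HT-8) is published; the rest encode textbook anatomical
#' descriptions as approximations.
#'
#' Step language (each step yields a point; operands reference a landmark slot
#' `{"lm": i}` or an earlier step `{"step": k}`, 1-based):
#' \describe{
#'   \item{anchor}{`{"op":"anchor","lm":i}` — the landmark itself.}
#'   \item{midpoint}{`{"op":"midpoint","a":ref,"b":ref}` — componentwise mean.}
#'   \item{fraction}{`{"op":"fraction","a":ref,"b":ref,"t":f}` — `a + t (b-a)`.}
#'   \item{toward}{`{"op":"toward","origin":ref,"target":ref,"scale":f,
#'     "base_a":ref,"base_b":ref}` — from `origin`, move
#'     `scale * dist(base_a, base_b)` along the ray to `target`.}
#'   \item{offset}{`{"op":"offset","from":ref,"dir_a":ref,"dir_b":ref,
#'     "scale":f,"base_a":ref,"base_b":ref}` — from `from`, move
#'     `scale * dist(base_a, base_b)` along the unit vector `dir_b - dir_a`.}
#' }
#' The final step is the rule's result. Rule evaluation is 2D (z ignored);
#' z only participates in posture classification.
#'
#' @param source Path to a rule-table JSON file. `load_registry()` with no
#'   argument loads the shipped default table (38 points: 18 hand, 20 face).
#' @return `load_registry()` returns a validated `acumap_registry` object: a
#'   list with `entries` (named list of acupoint definitions), `version`,
#'   `format` and `notes`.
#' @examples
#' reg <- load_registry()
#' length(reg$entries)            # 38
#' rules_for(reg, "HT-8", "front")
#' @export
load_registry <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "acupoint_rules.json", package = "acumap")
  }
  if (!file.exists(source)) abort_parse(sprintf("rule table not found: %s", source))
  raw <- tryCatch(
    jsonlite::fromJSON(source, simplifyVector = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse rule table %s: %s",
                                            source, conditionMessage(e)))
  )
  if (!identical(raw$format, "acumap-rules/1")) {
    abort_parse("rule table must declare format 'acumap-rules/1'")
  }
  entries <- raw$acupoints %||% list()
  codes <- vapply(entries, function(e) e$code %||% "", character(1))
  if (any(codes == "")) abort_parse("every rule-table entry needs a 'code' field")
  if (anyDuplicated(codes)) {
    abort_validation(sprintf("duplicate acupoint code(s): %s",
                             paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  }
  names(entries) <- codes
  reg <- structure(
    list(entries = entries,
         version = raw$version %||% "unversioned",
         format = raw$format,
         notes = raw$notes %||% ""),
    class = "acumap_registry"
  )
  report <- validate_registry(reg)
  if (nrow(report) > 0) {
    abort_validation(sprintf(
      "rule table %s has %d violation(s); first: [%s] %s",
      source, nrow(report), report$code[1], report$problem[1]))
  }
  if (length(entries) == 0) warning("loaded an empty acupoint registry")
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Slot counts of the two landmark schemas.
region_slots <- function(region) {
  switch(region,
         hand = 21L,
         face = 468L,
         abort_invalid_input(sprintf("unknown region '%s'", region)))
}

region_postures <- function(region) {
  switch(region,
         hand = c("front", "back", "inside", "outside"),
         face = c("center", "left", "right"),
         abort_invalid_input(sprintf("unknown region '%s'", region)))
}

#' Look up the mapping rule for an acupoint under a posture
#'
#' @param registry An `acumap_registry`.
#' @param code Acupoint code, e.g. `"HT-8"`.
#' @param posture Posture/pose label (`front|back|inside|outside` for hand
#'   codes, `center|left|right` for face codes).
#' @return The rule (list with `steps`) when the point is locatable under the
#'   posture, otherwise the `acumap_not_visible` sentinel (test with
#'   [is_not_visible()]).
#' @export
rules_for <- function(registry, code, posture) {
  stopifnot(inherits(registry, "acumap_registry"))
  entry <- registry$entries[[code]]
  if (is.null(entry)) abort_lookup(sprintf("unknown acupoint code '%s'", code))
  postures <- unlist(entry$postures)
  if (!posture %in% postures) {
    return(structure(list(code = code, posture = posture),
                     class = "acumap_not_visible"))
  }
  structure(list(code = code, posture = posture, steps = entry$steps),
            class = "acumap_rule")
}

#' @rdname rules_for
#' @param x Object returned by `rules_for()`.
#' @export
is_not_visible <- function(x) inherits(x, "acumap_not_visible")

# Collect all {"lm": i} references inside a step list.
rule_landmark_refs <- function(steps) {
  refs <- integer(0)
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$lm)) refs[[length(refs) + 1L]] <<- as.integer(x$lm)
      for (el in x) walk(el)
    }
  }
  walk(steps)
  refs
}

#' Validate a registry against the rule-table contract
#'
#' Checks landmark indices against the region schema (0–20 hand, 0–467 face),
#' posture labels, finiteness of every numeric constant, step-reference order
#' and per-entry metadata. Report-based: never throws.
#'
#' @param registry An `acumap_registry`.
#' @return A data.frame with columns `code` and `problem`; zero rows for the
#'   shipped default table.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "acumap_registry"))
  problems <- list()
  note <- function(code, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(code = code, problem = problem)
  }
  for (entry in registry$entries) {
    code <- entry$code
    region <- entry$region %||% ""
    if (!region %in% c("hand", "face")) {
      note(code, sprintf("invalid region '%s'", region))
      next
    }
    n_slots <- region_slots(region)
    postures <- unlist(entry$postures)
    if (length(postures) == 0) note(code, "no postures: every acupoint needs >= 1 rule")
    bad_post <- setdiff(postures, region_postures(region))
    if (length(bad_post) > 0) {
      note(code, sprintf("posture(s) invalid for region %s: %s",
                         region, paste(bad_post, collapse = ", ")))
    }
    steps <- entry$steps
    if (length(steps) == 0) {
      note(code, "empty step list")
      next
    }
    lms <- rule_landmark_refs(steps)
    oob <- lms[lms < 0 | lms >= n_slots]
    if (length(oob) > 0) {
      note(code, sprintf("landmark index out of range for %s schema: %s",
                         region, paste(unique(oob), collapse = ", ")))
    }
    for (k in seq_along(steps)) {
      st <- steps[[k]]
      for (field in c("t", "scale")) {
        if (!is.null(st[[field]]) && !is.finite(as.numeric(st[[field]]))) {
          note(code, sprintf("step %d: non-finite constant '%s'", k, field))
        }
      }
      step_refs <- c()
      walk <- function(x) {
        if (is.list(x)) {
          if (!is.null(x$step)) step_refs <<- c(step_refs, as.integer(x$step))
          for (el in x) walk(el)
        }
      }
      walk(st)
      if (any(step_refs >= k | step_refs < 1)) {
        note(code, sprintf("step %d references a non-earlier step", k))
      }
    }
  }
  if (length(problems) == 0) {
    data.frame(code = character(0), problem = character(0))
  } else {
    do.call(rbind, problems)
  }
}

#' Save a registry back to its JSON file format
#'
#' Round-trips with [load_registry()]: load, save and re-load yield an equal
#' registry.
#'
#' @param registry An `acumap_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path) {
  stopifnot(inherits(registry, "acumap_registry"))
  out <- list(format = registry$format,
              version = registry$version,
              notes = registry$notes,
              acupoints = unname(registry$entries))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Summarize a registry as a data.frame
#'
#' One row per acupoint: code, name, meridian, region and the covered
#' postures (comma-separated). Suitable for CSV export.
#'
#' @param registry An `acumap_registry`.
#' @return A data.frame.
#' @export
registry_summary <- function(registry) {
  stopifnot(inherits(registry, "acumap_registry"))
  entries <- registry$entries
  data.frame(
    code = vapply(entries, function(e) e$code, character(1)),
    name = vapply(entries, function(e) e$name %||% "", character(1)),
    meridian = vapply(entries, function(e) e$meridian %||% "", character(1)),
    region = vapply(entries, function(e) e$region, character(1)),
    postures = vapply(entries, function(e) paste(unlist(e$postures), collapse = ","),
                      character(1)),
    row.names = NULL
  )
}

#' @export
print.acumap_registry <- function(x, ...) {
  s <- registry_summary(x)
  cat(sprintf("<acumap_registry v%s> %d acupoints (%d hand, %d face)\n",
              x$version, nrow(s), sum(s$region == "hand"), sum(s$region == "face")))
  invisible(x)
}
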