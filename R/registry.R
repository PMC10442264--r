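#' Build a multi-level alliance registry
#'
#' The registry is the asserted ground truth about alliance structure at the
#' three levels observed in Shark Bay male dolphins: every focal individual
#' belongs to exactly one second-order alliance; within a study period the
#' second-order alliance is organised into first-order units (pairs or trios
#' that jointly consort females); and some second-order alliances maintain a
#' third-order alliance with another second-order alliance.
#'
#' @param second_order named character vector mapping individual id to
#'   second-order alliance id.
#' @param first_order_units named list, one element per period id; each
#'   element is a list of character vectors of 2-3 individual ids. All
#'   members of a unit must share one second-order alliance.
#' @param third_order_pairs named list, one element per period id; each
#'   element is a list of length-2 character vectors of alliance ids that
#'   maintain a third-order alliance in that period.
#' @param first_seen,last_seen optional named integer vectors (by individual
#'   id) giving first/last year each individual was seen; used to derive
#'   period rosters.
#'
#' @return an object of class \code{alliance_registry}.
#' @export
alliance_registry <- function(second_order,
                              first_order_units = list(),
                              third_order_pairs = list(),
                              first_seen = NULL,
                              last_seen = NULL) {
  if (is.null(names(second_order)) || any(!nzchar(names(second_order))))
    stop("`second_order` must be a named character vector (id -> alliance)")
  if (anyDuplicated(names(second_order)))
    stop("duplicate individual ids in `second_order`: ",
         paste(unique(names(second_order)[duplicated(names(second_order))]),
               collapse = ", "))
  second_order <- vapply(second_order, as.character, character(1))
  alliances <- unique(unname(second_order))

  first_order_units <- lapply(first_order_units, function(units) {
    lapply(units, function(u) sort(as.character(u)))
  })
  for (period in names(first_order_units)) {
    units <- first_order_units[[period]]
    seen <- character(0)
    for (u in units) {
      if (length(u) < 2L || length(u) > 3L)
        stop("first-order units must have 2-3 members (period ", period, ")")
      if (!all(u %in% names(second_order)))
        stop("unit member(s) not in `second_order` (period ", period, "): ",
             paste(setdiff(u, names(second_order)), collapse = ", "))
      if (length(unique(second_order[u])) != 1L)
        stop("unit {", paste(u, collapse = ","),
             "} spans more than one second-order alliance (period ", period, ")")
      if (any(u %in% seen))
        stop("individual(s) in more than one first-order unit (period ",
             period, "): ", paste(intersect(u, seen), collapse = ", "))
      seen <- c(seen, u)
    }
  }

  third_order_pairs <- lapply(third_order_pairs, function(pairs) {
    lapply(pairs, function(p) sort(as.character(p)))
  })
  for (period in names(third_order_pairs)) {
    for (p in third_order_pairs[[period]]) {
      if (length(p) != 2L || p[1] == p[2])
        stop("third-order pairs must name two distinct alliances (period ",
             period, ")")
      if (!all(p %in% alliances))
        stop("third-order pair references unknown alliance (period ", period,
             "): ", paste(setdiff(p, alliances), collapse = ", "))
    }
  }

  structure(
    list(second_order = second_order,
         alliances = alliances,
         first_order_units = first_order_units,
         third_order_pairs = third_order_pairs,
         first_seen = first_seen,
         last_seen = last_seen),
    class = "alliance_registry")
}

#' Read an alliance registry from YAML or JSON
#'
#' Expects top-level keys \code{second_order} (map id -> alliance),
#' \code{first_order_units} (map period -> list of member-id lists) and
#' \code{third_order_pairs} (map period -> list of alliance-id pairs), plus
#' optional \code{first_seen}/\code{last_seen} year maps.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return an \code{alliance_registry}.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported registry format: .", ext, " (use YAML or JSON)"))
  so <- unlist(raw$second_order)
  fou <- lapply(raw$first_order_units %||% list(),
                function(units) lapply(units, unlist))
  top <- lapply(raw$third_order_pairs %||% list(),
                function(pairs) lapply(pairs, unlist))
  alliance_registry(
    second_order = so,
    first_order_units = fou,
    third_order_pairs = top,
    first_seen = if (!is.null(raw$first_seen)) unlist(raw$first_seen),
    last_seen = if (!is.null(raw$last_seen)) unlist(raw$last_seen))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alliance_registry <- function(x, ...) {
  cat("Alliance registry:", length(x$second_order), "individuals in",
      length(x$alliances), "second-order alliances (",
      paste(x$alliances, collapse = ", "), ")\n")
  for (period in union(names(x$first_order_units), names(x$third_order_pairs))) {
    n_units <- length(x$first_order_units[[period]])
    pairs <- vapply(x$third_order_pairs[[period]] %||% list(),
                    paste, character(1), collapse = "-")
    cat("  period ", period, ": ", n_units, " first-order units; ",
        "third-order: ", if (length(pairs)) paste(pairs, collapse = ", ")
        else "none", "\n", sep = "")
  }
  invisible(x)
}

#' Alliances third-order-allied to a given alliance in a period
#'
#' @param registry an \code{alliance_registry}.
#' @param alliance alliance id.
#' @param period period id.
#' @return character vector of partner alliance ids (possibly empty).
#' @export
third_order_partners <- function(registry, alliance, period) {
  pairs <- registry$third_order_pairs[[period]]
  if (is.null(pairs)) {
    if (!period %in% names(registry$third_order_pairs) &&
        length(registry$third_order_pairs))
      stop("unknown period: ", period)
    return(character(0))
  }
  out <- character(0)
  for (p in pairs) if (alliance %in% p) out <- c(out, setdiff(p, alliance))
  unique(out)
}

#' Members of a second-order alliance
#'
#' @param registry an \code{alliance_registry}.
#' @param alliance alliance id.
#' @return character vector of individual ids.
#' @export
alliance_members <- function(registry, alliance) {
  names(registry$second_order)[registry$second_order == alliance]
}
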