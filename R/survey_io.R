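#' Read group-composition surveys from CSV
#'
#' A survey is one timestamped snapshot of group composition together with
#' the group's predominant activity; it is the sampling unit for all
#' association analyses. The expected file is a UTF-8 CSV with a header row
#' and (at least) columns for survey id, date, activity and a delimited list
#' of member codes.
#'
#' Activity strings are normalised to the set \code{rest, travel, social,
#' forage, unknown, competitive}; anything unrecognised (after applying
#' \code{activity_aliases}) maps to \code{unknown} with a warning.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical column names
#'   \code{survey_id}, \code{date}, \code{activity}, \code{members} to the
#'   column names used in the file.
#' @param delim delimiter inside the members cell (default \code{";"}).
#' @param activity_aliases optional named character vector mapping
#'   nonstandard activity strings to canonical ones, e.g.
#'   \code{c(foraging = "forage")}.
#' @return a \code{data.frame} of class \code{survey_set} with columns
#'   \code{survey_id} (character), \code{date} (\code{Date}),
#'   \code{activity} (character) and \code{members} (list of character
#'   vectors), plus \code{conflict} (logical) if present in the file.
#' @export
read_surveys <- function(path,
                         schema = c(survey_id = "survey_id", date = "date",
                                    activity = "activity", members = "members"),
                         delim = ";",
                         activity_aliases = character(0)) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  required <- c("survey_id", "date", "activity", "members")
  if (!all(required %in% names(schema)))
    stop("schema must map all of: ", paste(required, collapse = ", "))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(unname(schema[required]), names(raw))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df <- data.frame(survey_id = raw[[schema[["survey_id"]]]],
                   stringsAsFactors = FALSE)
  df$date_raw <- raw[[schema[["date"]]]]
  df$activity_raw <- raw[[schema[["activity"]]]]
  df$members_raw <- raw[[schema[["members"]]]]

  make_surveys(survey_id = df$survey_id, date = df$date_raw,
               activity = df$activity_raw, members = df$members_raw,
               delim = delim, activity_aliases = activity_aliases,
               conflict = if ("conflict" %in% names(raw))
                 as.logical(raw$conflict))
}

#' Assemble a validated survey set from vectors
#'
#' Programmatic counterpart of [read_surveys()]; used by the society
#' simulator and by tests.
#'
#' @param survey_id character vector of unique ids.
#' @param date \code{Date} vector or ISO-8601 strings.
#' @param activity character vector of activity states.
#' @param members list of character vectors, or a character vector of
#'   delimited member strings.
#' @param delim member delimiter when \code{members} is character.
#' @param activity_aliases see [read_surveys()].
#' @param conflict optional logical vector flagging large inter-group
#'   conflicts.
#' @return a \code{survey_set} data frame.
#' @export
make_surveys <- function(survey_id, date, activity, members, delim = ";",
                         activity_aliases = character(0), conflict = NULL) {
  survey_id <- as.character(survey_id)
  if (anyDuplicated(survey_id))
    stop("duplicate survey_id: ",
         paste(unique(survey_id[duplicated(survey_id)]), collapse = ", "))

  if (!inherits(date, "Date")) {
    parsed <- as.Date(as.character(date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad))
      stop("unparseable date(s) in row(s): ", paste(bad, collapse = ", "),
           " (expected ISO-8601 YYYY-MM-DD)")
    date <- parsed
  }

  if (is.character(members))
    members <- strsplit(members, delim, fixed = TRUE)
  members <- lapply(members, function(m) unique(trimws(m[nzchar(trimws(m))])))
  empty <- which(lengths(members) == 0L)
  if (length(empty))
    stop("empty member list in row(s): ", paste(empty, collapse = ", "))

  activity <- trimws(tolower(as.character(activity)))
  if (length(activity_aliases)) {
    hit <- activity %in% names(activity_aliases)
    activity[hit] <- unname(activity_aliases[activity[hit]])
  }
  unknown <- !activity %in% survey_activities()
  if (any(unknown)) {
    warning("unrecognised activity value(s) mapped to 'unknown': ",
            paste(unique(activity[unknown]), collapse = ", "))
    activity[unknown] <- "unknown"
  }

  out <- data.frame(survey_id = survey_id, date = date, activity = activity,
                    stringsAsFactors = FALSE)
  out$members <- members
  out$conflict <- if (is.null(conflict)) FALSE else as.logical(conflict)
  class(out) <- c("survey_set", "data.frame")
  out
}

#' Recognised survey activity states
#' @return character vector of the activity enum.
#' @export
survey_activities <- function() {
  c("rest", "travel", "social", "forage", "unknown", "competitive")
}

#' Survey filtering configuration
#'
#' Defaults mirror the standard restriction of association data: keep only
#' surveys whose predominant activity is resting, travelling or socialising
#' (so co-occurrence at shared food patches is not read as association),
#' keep only the August-December window where mating and field seasons
#' overlap, drop same-day resights of the same group, and exclude large
#' inter-group conflicts.
#'
#' @param allowed_activities activities to retain.
#' @param month_window inclusive (first, last) month numbers; a window with
#'   first > last wraps the year end.
#' @param drop_same_day_resights drop later same-day surveys whose
#'   membership heavily overlaps an earlier retained survey.
#' @param resight_overlap_threshold Jaccard overlap above which a later
#'   same-day survey counts as a resight, in \code{[0, 1]}.
#' @param exclude_conflicts drop surveys flagged as conflicts (the
#'   \code{conflict} column, plus the \code{competitive} activity).
#' @return a \code{survey_filter_config} list.
#' @export
survey_filter_config <- function(allowed_activities = c("rest", "travel", "social"),
                                 month_window = c(8L, 12L),
                                 drop_same_day_resights = TRUE,
                                 resight_overlap_threshold = 0.5,
                                 exclude_conflicts = TRUE) {
  stopifnot(all(allowed_activities %in% survey_activities()),
            length(month_window) == 2L,
            all(month_window %in% 1:12),
            is.numeric(resight_overlap_threshold),
            resight_overlap_threshold >= 0, resight_overlap_threshold <= 1)
  structure(list(allowed_activities = allowed_activities,
                 month_window = as.integer(month_window),
                 drop_same_day_resights = isTRUE(drop_same_day_resights),
                 resight_overlap_threshold = resight_overlap_threshold,
                 exclude_conflicts = isTRUE(exclude_conflicts)),
            class = "survey_filter_config")
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Filter surveys for association analysis
#'
#' Applies, in order: the activity restriction, the month window, the
#' conflict exclusion, and the same-day resight rule. The resight rule
#' walks each date's surveys in input order and drops a survey whose member
#' overlap (Jaccard) with any earlier \emph{retained} survey of the same
#' date exceeds \code{resight_overlap_threshold}; the first survey of a
#' date is always kept. The operation is idempotent and preserves order.
#'
#' @param surveys a \code{survey_set}.
#' @param cfg a [survey_filter_config()].
#' @return the retained \code{survey_set} (possibly empty, with a message).
#' @export
filter_surveys <- function(surveys, cfg = survey_filter_config()) {
  stopifnot(inherits(cfg, "survey_filter_config"))
  keep <- surveys$activity %in% cfg$allowed_activities
  m <- as.integer(format(surveys$date, "%m"))
  mw <- cfg$month_window
  in_window <- if (mw[1] <= mw[2]) m >= mw[1] & m <= mw[2]
               else m >= mw[1] | m <= mw[2]
  keep <- keep & in_window
  if (cfg$exclude_conflicts)
    keep <- keep & !surveys$conflict & surveys$activity != "competitive"

  out <- surveys[keep, , drop = FALSE]
  if (cfg$drop_same_day_resights && nrow(out) > 1L) {
    retain <- rep(TRUE, nrow(out))
    for (d in unique(as.character(out$date))) {
      idx <- which(as.character(out$date) == d)
      kept_members <- list()
      for (i in idx) {
        is_resight <- any(vapply(kept_members, function(prev)
          jaccard(prev, out$members[[i]]) > cfg$resight_overlap_threshold,
          logical(1)))
        if (is_resight) retain[i] <- FALSE
        else kept_members[[length(kept_members) + 1L]] <- out$members[[i]]
      }
    }
    out <- out[retain, , drop = FALSE]
  }
  if (nrow(out) == 0L) message("filter_surveys: no surveys retained")
  rownames(out) <- NULL
  class(out) <- c("survey_set", "data.frame")
  out
}

#' Classify a survey by the alliance levels it spans
#'
#' A survey is a \code{third_order} association if its members span at
#' least two second-order alliances and every spanned alliance pair is a
#' registered third-order alliance for the period; \code{mixed_nonallied}
#' if some spanned pair is not registered; \code{within_alliance} when all
#' registered members share one alliance. Members absent from the registry
#' are ignored (with a warning); a survey with fewer than one registered
#' member is classified \code{no_focal}.
#'
#' @param members character vector of member ids (or a single-row
#'   \code{survey_set}).
#' @param registry an [alliance_registry()].
#' @param period period id used to look up third-order pairs.
#' @return list with \code{level} (one of \code{within_alliance},
#'   \code{third_order}, \code{mixed_nonallied}, \code{no_focal}) and
#'   \code{pairs}, a list of spanned alliance-id pairs.
#' @export
classify_survey_level <- function(members, registry, period) {
  if (inherits(members, "survey_set")) {
    stopifnot(nrow(members) == 1L)
    members <- members$members[[1]]
  }
  if (length(registry$third_order_pairs) &&
      !period %in% names(registry$third_order_pairs))
    stop("unknown period: ", period)
  known <- members %in% names(registry$second_order)
  if (any(!known))
    warning("ignoring individual(s) not in registry: ",
            paste(members[!known], collapse = ", "))
  members <- members[known]
  if (length(members) < 1L)
    return(list(level = "no_focal", pairs = list()))
  alliances <- sort(unique(unname(registry$second_order[members])))
  if (length(alliances) < 2L)
    return(list(level = "within_alliance", pairs = list()))
  spanned <- utils::combn(alliances, 2, simplify = FALSE)
  registered <- registry$third_order_pairs[[period]] %||% list()
  reg_keys <- vapply(registered, paste, character(1), collapse = "\r")
  ok <- vapply(spanned, function(p) paste(p, collapse = "\r") %in% reg_keys,
               logical(1))
  list(level = if (all(ok)) "third_order" else "mixed_nonallied",
       pairs = spanned)
}

#' Classify every survey in a set
#'
#' @param surveys a \code{survey_set}.
#' @inheritParams classify_survey_level
#' @return character vector of levels, one per survey.
#' @export
classify_surveys <- function(surveys, registry, period) {
  vapply(surveys$members,
         function(m) classify_survey_level(m, registry, period)$level,
         character(1))
}
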