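#' Recognised behavior codes for fusion-event records
#'
#' \code{PET} petting (pectoral-fin contact), \code{RUB} body rubbing,
#' \code{D0} within touching distance but contact not discernible on video,
#' \code{SYNCH} synchronous surfacing/diving of two or three males,
#' \code{AGG} aggression, \code{CONSORT_FORMATION} swimming in formation
#' behind another alliance's consorted female, \code{CONSORT_CONTACT}
#' petting/rubbing with a consorted female. Aggression and consort-directed
#' behaviors are carried through but not tallied into the affiliative pair
#' categories.
#'
#' @return character vector of behavior codes.
#' @export
behavior_codes <- function() {
  c("PET", "RUB", "D0", "SYNCH", "AGG", "CONSORT_FORMATION", "CONSORT_CONTACT")
}

#' Read a fusion-event behavior log from CSV
#'
#' Columns: \code{event_id,timestamp,behavior,actors,target} with actors
#' delimited by \code{delim}. Validates the behavior enum and actor
#' arities: PET/RUB/D0 have exactly 2 actors; SYNCH has 2 or 3.
#'
#' @param path CSV path.
#' @param delim actor delimiter (default \code{";"}).
#' @return a \code{data.frame} with an \code{actors} list-column.
#' @export
read_behavior_log <- function(path, delim = ";") {
  if (!file.exists(path)) stop("behavior log not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("event_id", "behavior", "actors")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  behavior_records(event_id = raw$event_id, behavior = raw$behavior,
                   actors = strsplit(raw$actors, delim, fixed = TRUE),
                   target = raw$target %||% NA_character_,
                   timestamp = raw$timestamp %||% NA_character_)
}

#' Assemble validated behavior records
#'
#' @param event_id character vector.
#' @param behavior character vector of [behavior_codes()].
#' @param actors list of character vectors of distinct individual ids.
#' @param target optional female id vector.
#' @param timestamp optional.
#' @return a \code{data.frame} of class \code{behavior_log}.
#' @export
behavior_records <- function(event_id, behavior, actors,
                             target = NA_character_, timestamp = NA_character_) {
  behavior <- toupper(trimws(behavior))
  bad <- setdiff(unique(behavior), behavior_codes())
  if (length(bad))
    stop("unknown behavior code(s): ", paste(bad, collapse = ", "))
  actors <- lapply(actors, function(a) trimws(a[nzchar(trimws(a))]))
  if (any(vapply(actors, anyDuplicated, integer(1)) > 0L))
    stop("actors within a record must be distinct")
  n_act <- lengths(actors)
  two_only <- behavior %in% c("PET", "RUB", "D0")
  if (any(two_only & n_act != 2L))
    stop("PET/RUB/D0 records must have exactly 2 actors (rows: ",
         paste(which(two_only & n_act != 2L), collapse = ", "), ")")
  if (any(behavior == "SYNCH" & !n_act %in% 2:3))
    stop("SYNCH records must have 2 or 3 actors (rows: ",
         paste(which(behavior == "SYNCH" & !n_act %in% 2:3), collapse = ", "), ")")
  out <- data.frame(event_id = as.character(event_id), behavior = behavior,
                    stringsAsFactors = FALSE)
  out$actors <- actors
  out$target <- rep_len(as.character(target), nrow(out))
  out$timestamp <- rep_len(as.character(timestamp), nrow(out))
  class(out) <- c("behavior_log", "data.frame")
  out
}

#' Classify a dyad's alliance relationship
#'
#' @param pair character vector of two individual ids.
#' @param registry an [alliance_registry()].
#' @param period period id.
#' @return \code{"second_order"} if both share a second-order alliance,
#'   \code{"third_order"} if their alliances form a registered third-order
#'   pair in the period, else \code{"non_allied"}.
#' @export
classify_pair <- function(pair, registry, period) {
  stopifnot(length(pair) == 2L)
  unreg <- setdiff(pair, names(registry$second_order))
  if (length(unreg))
    stop("unregistered individual(s): ", paste(unreg, collapse = ", "))
  a <- registry$second_order[[pair[1]]]
  b <- registry$second_order[[pair[2]]]
  if (a == b) return("second_order")
  key <- paste(sort(c(a, b)), collapse = "\r")
  reg <- vapply(registry$third_order_pairs[[period]] %||% list(),
                paste, character(1), collapse = "\r")
  if (key %in% reg) "third_order" else "non_allied"
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# unique unordered pairs touched by a set of records, decomposing >2-actor
# records into constituent pairs
record_pairs <- function(records, decompose = TRUE) {
  if (nrow(records) == 0L) return(character(0))
  keys <- unlist(lapply(records$actors, function(a) {
    if (length(a) == 2L) return(pair_key(a[1], a[2]))
    if (!decompose) return(character(0))
    cmb <- utils::combn(sort(a), 2)
    pair_key(cmb[1, ], cmb[2, ])
  }))
  unique(keys)
}

tally_pairs_by_class <- function(keys, registry, period) {
  if (length(keys) == 0L)
    return(data.frame(pair = character(0), class = character(0),
                      alliances = character(0), stringsAsFactors = FALSE))
  ids <- strsplit(keys, "|", fixed = TRUE)
  cls <- character(length(keys)); al <- character(length(keys))
  for (i in seq_along(keys)) {
    p <- ids[[i]]
    unreg <- setdiff(p, names(registry$second_order))
    if (length(unreg)) {
      message("pair with unregistered individual(s) counted as non_allied: ",
              keys[i])
      cls[i] <- "non_allied"; al[i] <- NA_character_
    } else {
      cls[i] <- classify_pair(p, registry, period)
      al[i] <- paste(sort(unique(unname(registry$second_order[p]))),
                     collapse = "-")
    }
  }
  data.frame(pair = keys, class = cls, alliances = al,
             stringsAsFactors = FALSE)
}

#' Tally one fusion event's unique affiliative pairs
#'
#' For one event: \emph{PR pairs} are unique unordered pairs with at least
#' one petting or rubbing record; \emph{PR + D0} additionally admits
#' touching-distance (\code{D0}) records; \emph{synch pairs} come from
#' SYNCH records, a 3-actor synch contributing its 3 constituent pairs
#' (set \code{decompose_trio_synch = FALSE} to suppress). Each pair is
#' counted once per event per category, split by [classify_pair()] into
#' third-order versus second-order (second-order synch additionally by
#' alliance).
#'
#' @param records a \code{behavior_log} restricted to one event.
#' @param registry an [alliance_registry()].
#' @param period period id.
#' @param decompose_trio_synch decompose 3-actor synchs into pairs
#'   (default TRUE).
#' @return one-row \code{data.frame}: \code{event_id},
#'   \code{third_order_pr}, \code{third_order_pr_d0},
#'   \code{second_order_pr}, \code{second_order_pr_d0},
#'   \code{third_order_synch}, \code{second_order_synch}, plus list-columns
#'   \code{second_order_synch_by_alliance} and \code{pair_sets} (the unique
#'   pair keys per category, used for cross-event deduplication).
#' @export
tally_event <- function(records, registry, period,
                        decompose_trio_synch = TRUE) {
  ev <- unique(records$event_id)
  if (length(ev) > 1L)
    stop("records span multiple events: ", paste(ev, collapse = ", "))
  if (length(ev) == 0L) ev <- NA_character_

  pr_keys <- record_pairs(records[records$behavior %in% c("PET", "RUB"), ,
                                  drop = FALSE])
  prd_keys <- record_pairs(records[records$behavior %in% c("PET", "RUB", "D0"), ,
                                   drop = FALSE])
  sy_keys <- record_pairs(records[records$behavior == "SYNCH", , drop = FALSE],
                          decompose = decompose_trio_synch)

  pr <- tally_pairs_by_class(pr_keys, registry, period)
  prd <- tally_pairs_by_class(prd_keys, registry, period)
  sy <- tally_pairs_by_class(sy_keys, registry, period)

  so_sy <- sy[sy$class == "second_order", , drop = FALSE]
  by_alliance <- if (nrow(so_sy)) table(so_sy$alliances) else table(character(0))

  out <- data.frame(
    event_id = ev,
    third_order_pr = sum(pr$class == "third_order"),
    third_order_pr_d0 = sum(prd$class == "third_order"),
    second_order_pr = sum(pr$class == "second_order"),
    second_order_pr_d0 = sum(prd$class == "second_order"),
    third_order_synch = sum(sy$class == "third_order"),
    second_order_synch = sum(sy$class == "second_order"),
    stringsAsFactors = FALSE)
  out$second_order_synch_by_alliance <- list(by_alliance)
  out$pair_sets <- list(list(pr = pr, pr_d0 = prd, synch = sy))
  class(out) <- c("pair_tally", "data.frame")
  out
}

#' Summarise fusion-event tallies across events
#'
#' Produces the per-event table of unique-pair counts, its column totals,
#' and the cross-event unique-pair counts (deduplicating pairs that
#' appear in several events) by category and by alliance composition.
#' Published text totals sometimes mix the two framings, so both are
#' reported rather than reconciled.
#'
#' @param records a \code{behavior_log} covering one or more events.
#' @param registry an [alliance_registry()].
#' @param period period id.
#' @param decompose_trio_synch see [tally_event()].
#' @return list with \code{per_event} (data frame, one row per event),
#'   \code{column_totals} (named numeric), \code{unique_across_events}
#'   (named numeric per category), and
#'   \code{unique_across_events_by_alliance} (list of tables).
#' @export
summarize_tallies <- function(records, registry, period,
                              decompose_trio_synch = TRUE) {
  if (nrow(records) == 0L) stop("no behavior records to summarise")
  evs <- unique(records$event_id)
  rows <- lapply(evs, function(e)
    tally_event(records[records$event_id == e, , drop = FALSE],
                registry, period, decompose_trio_synch))
  per_event <- do.call(rbind, rows)

  count_cols <- c("third_order_pr", "third_order_pr_d0", "second_order_pr",
                  "second_order_pr_d0", "third_order_synch",
                  "second_order_synch")
  column_totals <- colSums(per_event[, count_cols, drop = FALSE])

  pool <- function(slot, class) {
    do.call(rbind, lapply(per_event$pair_sets, function(ps) {
      d <- ps[[slot]]
      d[d$class == class, , drop = FALSE]
    }))
  }
  uniq <- function(slot, class) {
    d <- pool(slot, class)
    if (is.null(d) || nrow(d) == 0L) return(0L)
    length(unique(d$pair))
  }
  uniq_by_alliance <- function(slot, class) {
    d <- pool(slot, class)
    if (is.null(d) || nrow(d) == 0L) return(table(character(0)))
    table(d$alliances[!duplicated(d$pair)])
  }

  unique_across_events <- c(
    third_order_pr = uniq("pr", "third_order"),
    third_order_pr_d0 = uniq("pr_d0", "third_order"),
    second_order_pr = uniq("pr", "second_order"),
    second_order_pr_d0 = uniq("pr_d0", "second_order"),
    third_order_synch = uniq("synch", "third_order"),
    second_order_synch = uniq("synch", "second_order"))

  list(per_event = per_event,
       column_totals = column_totals,
       unique_across_events = unique_across_events,
       unique_across_events_by_alliance = list(
         third_order_pr = uniq_by_alliance("pr", "third_order"),
         second_order_pr = uniq_by_alliance("pr", "second_order"),
         third_order_synch = uniq_by_alliance("synch", "third_order"),
         second_order_synch = uniq_by_alliance("synch", "second_order")))
}

#' Write the per-event tally table as CSV
#'
#' @param summary a [summarize_tallies()] result.
#' @param path output path.
#' @export
write_tally_csv <- function(summary, path) {
  cols <- c("event_id", "third_order_pr", "third_order_pr_d0",
            "second_order_pr", "second_order_pr_d0", "third_order_synch",
            "second_order_synch")
  utils::write.csv(summary$per_event[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Cohen's kappa for two coders
#'
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o} the observed
#' agreement and \eqn{p_e} the chance agreement expected from the two
#' coders' marginal label frequencies.
#'
#' @param labels_a,labels_b equal-length vectors of category labels.
#' @return kappa in \code{[-1, 1]}; when both coders use a single identical
#'   label throughout (\eqn{p_e = 1}), kappa is returned as 1 by convention
#'   with a warning.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 1L)
    stop("label vectors must have equal positive length")
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev); b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("chance agreement is 1 (single label); kappa reported as 1 by ",
            "convention")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Mean pairwise Cohen's kappa across several coders
#'
#' @param labels list of >= 2 equal-length label vectors, one per coder.
#' @return unweighted mean of all pairwise kappas.
#' @export
cohens_kappa_multi <- function(labels) {
  stopifnot(is.list(labels), length(labels) >= 2L)
  pairs <- utils::combn(length(labels), 2)
  mean(apply(pairs, 2, function(p)
    cohens_kappa(labels[[p[1]]], labels[[p[2]]])))
}
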