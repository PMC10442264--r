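#' Configure a planted three-level alliance society
#'
#' The generator emulates the grouping process behind field surveys of a
#' multi-level male alliance society. First-order units (pairs/trios) are
#' the behavioral atoms: each simulated survey is seeded by one unit; every
#' other unit of the same second-order alliance joins independently with
#' probability \code{p2} (fission-fusion groups often contain several units
#' of an alliance), and, for each third-order alliance the seed's alliance
#' maintains, may attract one unit from the partner alliance (probability
#' \code{p3} per pair), chosen with weight \code{bridge_bias} for that
#' alliance's designated bridge unit. Unit members join a group their unit
#' is in with probability \code{p_unit_cohesion}, so within-unit
#' association is high, within-alliance moderate, and between-alliance weak
#' and concentrated on bridge units.
#'
#' @param alliances named list: alliance id -> list of character vectors of
#'   2-3 member ids (the first-order units; disjoint).
#' @param third_order list of length-2 character vectors of allied alliance
#'   ids.
#' @param p3 probability a survey seeded in one member of a third-order
#'   pair attaches a unit from the other; scalar, or named per pair
#'   (\code{"A|B"} with ids sorted). Default 0.12 (about the fraction of
#'   surveys that capture third-order associations in the field).
#' @param p_unit_cohesion probability each unit member joins a group its
#'   unit is part of (default 0.95).
#' @param p2 probability each other same-alliance unit joins (default 0.35).
#' @param bridge_units named integer vector: alliance id -> index of its
#'   bridge unit (defaults to the first unit of every alliance involved in
#'   a third-order pair).
#' @param bridge_bias selection weight multiplier for bridge units
#'   (default 3).
#' @param activity_probs named probability vector over
#'   [survey_activities()].
#' @param years integer vector of survey years; dates are drawn uniformly
#'   within August-December of each year.
#' @param surveys_per_year default number of surveys per year when
#'   \code{n_surveys} is not given to [generate_surveys()].
#' @param mortality named character vector: individual id -> last date
#'   (ISO-8601) after which the individual is never sighted.
#' @param seed default integer seed for [generate_surveys()].
#' @return a \code{society_config}.
#' @export
society_config <- function(alliances, third_order = list(),
                           p3 = 0.12,
                           p_unit_cohesion = 0.95,
                           p2 = 0.35,
                           bridge_units = NULL,
                           bridge_bias = 3,
                           activity_probs = c(rest = 0.25, travel = 0.35,
                                              social = 0.25, forage = 0.10,
                                              unknown = 0.03, competitive = 0.02),
                           years = 2009:2010,
                           surveys_per_year = 50L,
                           mortality = character(0),
                           seed = 1L) {
  stopifnot(is.list(alliances), length(alliances) >= 1L,
            p_unit_cohesion >= 0, p_unit_cohesion <= 1,
            p2 >= 0, p2 <= 1, all(p3 >= 0), all(p3 <= 1),
            bridge_bias > 0)
  all_ids <- unlist(alliances)
  if (anyDuplicated(all_ids))
    stop("units must be disjoint across the society")
  for (al in names(alliances))
    for (u in alliances[[al]])
      if (!length(u) %in% 2:3)
        stop("units must have 2-3 members (alliance ", al, ")")
  third_order <- lapply(third_order, function(p) sort(as.character(p)))
  for (p in third_order)
    if (!all(p %in% names(alliances)))
      stop("third-order pair references unknown alliance: ",
           paste(p, collapse = "-"))
  involved <- unique(unlist(third_order))
  if (is.null(bridge_units))
    bridge_units <- stats::setNames(rep(1L, length(involved)), involved)
  for (al in names(bridge_units))
    if (bridge_units[[al]] > length(alliances[[al]]))
      stop("bridge unit index out of range for alliance ", al)
  activity_probs <- activity_probs / sum(activity_probs)
  stopifnot(all(names(activity_probs) %in% survey_activities()))
  structure(list(alliances = alliances, third_order = third_order,
                 p3 = p3, p_unit_cohesion = p_unit_cohesion, p2 = p2,
                 bridge_units = bridge_units, bridge_bias = bridge_bias,
                 activity_probs = activity_probs, years = as.integer(years),
                 surveys_per_year = as.integer(surveys_per_year),
                 mortality = mortality, seed = as.integer(seed)),
            class = "society_config")
}

pair_name <- function(a, b) paste(sort(c(a, b)), collapse = "|")

p3_for <- function(cfg, a, b) {
  if (length(cfg$p3) == 1L && is.null(names(cfg$p3))) return(unname(cfg$p3))
  key <- pair_name(a, b)
  if (!key %in% names(cfg$p3))
    stop("no p3 configured for third-order pair ", key)
  unname(cfg$p3[[key]])
}

#' Named presets mirroring the Shark Bay study structure
#'
#' \code{"T1"}: three second-order alliances of 12 (KS), 7 (PD) and 5 (RR)
#' members built from pairs/trios, with a single third-order alliance
#' KS-PD, over 2009-2010. \code{"T3"}: 10 (KS), 5 (PD) and 5 (RR) members
#' with third-order pairs KS-PD and KS-RR, over 2013-2014. Structure only
#' (alliance sizes, unit composition, which alliances are allied); member
#' ids are synthetic and no field parameter values are claimed.
#'
#' @param name \code{"T1"} or \code{"T3"}.
#' @param ... overrides passed on to [society_config()].
#' @return a \code{society_config}.
#' @export
society_preset <- function(name = c("T1", "T3"), ...) {
  name <- match.arg(name)
  mk <- function(prefix, sizes) {
    ids <- sprintf("%s%02d", prefix, seq_len(sum(sizes)))
    split(ids, rep(seq_along(sizes), sizes))
  }
  args <- switch(name,
    T1 = list(alliances = list(KS = mk("KS", c(3, 3, 3, 3)),
                               PD = mk("PD", c(3, 2, 2)),
                               RR = mk("RR", c(3, 2))),
              third_order = list(c("KS", "PD")),
              years = 2009:2010),
    T3 = list(alliances = list(KS = mk("KS", c(3, 3, 2, 2)),
                               PD = mk("PD", c(3, 2)),
                               RR = mk("RR", c(3, 2))),
              third_order = list(c("KS", "PD"), c("KS", "RR")),
              years = 2013:2014))
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(society_config, args)
}

#' Build an alliance registry from a society configuration
#'
#' @param cfg a [society_config()].
#' @param period period id the units/third-order pairs are registered under.
#' @return an [alliance_registry()].
#' @export
registry_from_config <- function(cfg, period = "P1") {
  so <- unlist(lapply(names(cfg$alliances), function(al)
    stats::setNames(rep(al, length(unlist(cfg$alliances[[al]]))),
                    unlist(cfg$alliances[[al]]))))
  units <- unlist(lapply(cfg$alliances, function(us) us), recursive = FALSE)
  alliance_registry(
    second_order = so,
    first_order_units = stats::setNames(list(unname(units)), period),
    third_order_pairs = stats::setNames(list(cfg$third_order), period))
}

alive_at <- function(cfg, ids, date) {
  if (length(cfg$mortality) == 0L) return(ids)
  last <- cfg$mortality[ids]
  ids[is.na(last) | date <= as.Date(unname(last))]
}

#' Generate surveys from a planted society
#'
#' Per survey: a date is drawn uniformly within August-December of a
#' uniformly chosen year; a seed unit is drawn uniformly among units with
#' at least one living member; each living member of a chosen unit joins
#' with probability \code{p_unit_cohesion}; every other living
#' same-alliance unit joins independently with probability \code{p2}; and
#' for each third-order pair
#' involving the seed's alliance, with probability \code{p3} one living
#' unit of the partner alliance joins (bridge units weighted by
#' \code{bridge_bias}). A survey whose group comes out empty is redrawn.
#' All randomness flows from \code{seed}.
#'
#' @param cfg a [society_config()].
#' @param n_surveys number of surveys (default
#'   \code{surveys_per_year * length(years)}).
#' @param seed integer seed (default \code{cfg$seed}).
#' @return list with \code{surveys} (a \code{survey_set}) and \code{truth}
#'   (the config, the planted individual -> alliance map, and expected HWI
#'   per dyad class from [expected_hwi()]).
#' @export
generate_surveys <- function(cfg, n_surveys = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "society_config"))
  if (is.null(n_surveys))
    n_surveys <- cfg$surveys_per_year * length(cfg$years)

  unit_tab <- data.frame(alliance = rep(names(cfg$alliances),
                                        lengths(cfg$alliances)),
                         stringsAsFactors = FALSE)
  unit_tab$members <- unlist(cfg$alliances, recursive = FALSE)
  unit_tab$idx_in_alliance <- unlist(lapply(lengths(cfg$alliances), seq_len))
  unit_tab$is_bridge <- mapply(function(al, i)
    al %in% names(cfg$bridge_units) && cfg$bridge_units[[al]] == i,
    unit_tab$alliance, unit_tab$idx_in_alliance)
  n_units <- nrow(unit_tab)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  span_start <- as.Date(sprintf("%d-08-01", cfg$years))
  span_end <- as.Date(sprintf("%d-12-15", cfg$years))
  span_len <- as.integer(span_end - span_start)

  draw_unit_members <- function(u, date) {
    living <- alive_at(cfg, unit_tab$members[[u]], date)
    living[stats::runif(length(living)) < cfg$p_unit_cohesion]
  }

  ids <- character(n_surveys); dates <- as.Date(rep(NA, n_surveys))
  acts <- character(n_surveys); members <- vector("list", n_surveys)
  for (s in seq_len(n_surveys)) {
    repeat {
      yi <- sample.int(length(cfg$years), 1L)
      date <- span_start[yi] + sample.int(span_len[yi] + 1L, 1L) - 1L
      living_units <- which(vapply(unit_tab$members, function(mm)
        length(alive_at(cfg, mm, date)) > 0L, logical(1)))
      if (!length(living_units)) stop("no living units at ", date)
      for (al in names(cfg$alliances))
        if (!any(unit_tab$alliance[living_units] == al))
          stop("alliance ", al, " has no living members at ", date)
      seed_u <- living_units[sample.int(length(living_units), 1L)]
      grp <- draw_unit_members(seed_u, date)
      al <- unit_tab$alliance[seed_u]
      same <- setdiff(living_units[unit_tab$alliance[living_units] == al],
                      seed_u)
      for (u2 in same)
        if (stats::runif(1) < cfg$p2)
          grp <- c(grp, draw_unit_members(u2, date))
      for (p in cfg$third_order) {
        if (!al %in% p) next
        partner <- setdiff(p, al)
        cand <- living_units[unit_tab$alliance[living_units] == partner]
        if (!length(cand)) next
        if (stats::runif(1) < p3_for(cfg, p[1], p[2])) {
          wts <- ifelse(unit_tab$is_bridge[cand], cfg$bridge_bias, 1)
          u3 <- cand[sample.int(length(cand), 1L, prob = wts)]
          grp <- c(grp, draw_unit_members(u3, date))
        }
      }
      if (length(grp)) break
    }
    ids[s] <- sprintf("SIM%05d", s)
    dates[s] <- date
    acts[s] <- sample(names(cfg$activity_probs), 1L,
                      prob = cfg$activity_probs)
    members[[s]] <- unique(grp)
  }

  surveys <- make_surveys(survey_id = ids, date = dates, activity = acts,
                          members = members)
  truth <- list(
    config = cfg,
    membership = registry_from_config(cfg)$second_order,
    expected_hwi = vapply(dyad_classes(), function(cl)
      expected_hwi(cfg, cl), numeric(1)))
  list(surveys = surveys, truth = truth)
}

#' Dyad classes of the planted society
#' @return character vector of class names.
#' @export
dyad_classes <- function() {
  c("within_unit", "within_alliance", "third_order_bridge",
    "third_order_nonbridge", "non_allied")
}

unit_lookup <- function(cfg) {
  tab <- data.frame(alliance = rep(names(cfg$alliances),
                                   lengths(cfg$alliances)),
                    stringsAsFactors = FALSE)
  tab$members <- unlist(cfg$alliances, recursive = FALSE)
  tab$idx_in_alliance <- unlist(lapply(lengths(cfg$alliances), seq_len))
  tab$is_bridge <- mapply(function(al, i)
    al %in% names(cfg$bridge_units) && cfg$bridge_units[[al]] == i,
    tab$alliance, tab$idx_in_alliance)
  tab$weight <- ifelse(tab$is_bridge, cfg$bridge_bias, 1)
  tab
}

# closed-form P(unit in group) and P(two units jointly in group) under the
# generative model, ignoring mortality (full roster); same-alliance units
# join independently, cross-alliance at most one unit per allied pair
unit_presence_probs <- function(cfg) {
  tab <- unit_lookup(cfg)
  U <- nrow(tab)
  k <- table(tab$alliance)
  W <- tapply(tab$weight, tab$alliance, sum)
  allied_pairs <- cfg$third_order

  partners_of <- function(al) {
    out <- character(0)
    for (p in allied_pairs) if (al %in% p) out <- c(out, setdiff(p, al))
    out
  }

  p_unit <- numeric(U)
  for (u in seq_len(U)) {
    al <- tab$alliance[u]
    p <- (1 + (k[[al]] - 1L) * cfg$p2) / U
    for (B in partners_of(al))
      p <- p + (k[[B]] / U) * p3_for(cfg, al, B) * tab$weight[u] / W[[al]]
    p_unit[u] <- p
  }

  p_joint <- matrix(0, U, U)
  for (u in seq_len(U)) for (v in seq_len(U)) {
    if (v <= u) next
    A <- tab$alliance[u]; B <- tab$alliance[v]
    if (A == B) {
      p_joint[u, v] <- (2 * cfg$p2 + (k[[A]] - 2L) * cfg$p2^2) / U
    } else if (any(vapply(allied_pairs, function(p) all(c(A, B) %in% p),
                          logical(1)))) {
      p3 <- p3_for(cfg, A, B)
      pj <- (1 / U) * p3 * tab$weight[v] / W[[B]] +
            (1 / U) * p3 * tab$weight[u] / W[[A]] +
            ((k[[A]] - 1L) / U) * cfg$p2 * p3 * tab$weight[v] / W[[B]] +
            ((k[[B]] - 1L) / U) * cfg$p2 * p3 * tab$weight[u] / W[[A]]
      # seeds in an alliance allied to both sides attach one unit from each
      for (C in setdiff(names(cfg$alliances), c(A, B)))
        if (A %in% partners_of(C) && B %in% partners_of(C))
          pj <- pj + (k[[C]] / U) * p3_for(cfg, C, A) * p3_for(cfg, C, B) *
            (tab$weight[u] / W[[A]]) * (tab$weight[v] / W[[B]])
      p_joint[u, v] <- pj
    } else {
      for (C in setdiff(names(cfg$alliances), c(A, B)))
        if (A %in% partners_of(C) && B %in% partners_of(C))
          p_joint[u, v] <- p_joint[u, v] +
            (k[[C]] / U) * p3_for(cfg, C, A) * p3_for(cfg, C, B) *
            (tab$weight[u] / W[[A]]) * (tab$weight[v] / W[[B]])
    }
    p_joint[v, u] <- p_joint[u, v]
  }
  list(tab = tab, p_unit = p_unit, p_joint = p_joint)
}

#' Expected half-weight index per planted dyad class
#'
#' Closed-form expectation under the generative model: per survey,
#' \eqn{E[x]} is the probability both individuals are in the group and
#' \eqn{E[n_A]} the probability one is; these combine as
#' \eqn{2E[x] / (E[n_A] + E[n_B])}, a consistent large-sample
#' approximation to the realised HWI. Mortality is ignored (full roster).
#'
#' @param cfg a [society_config()].
#' @param class one of [dyad_classes()]; \code{"third_order_bridge"} means
#'   both members sit in their alliances' bridge units.
#' @return expected HWI, averaged over all dyads of the class (\code{NA}
#'   if the class is empty in this society).
#' @export
expected_hwi <- function(cfg, class = dyad_classes()) {
  class <- match.arg(class)
  pr <- unit_presence_probs(cfg)
  tab <- pr$tab
  pc <- cfg$p_unit_cohesion
  allied <- function(A, B) any(vapply(cfg$third_order, function(p)
    all(c(A, B) %in% p), logical(1)))

  vals <- numeric(0)
  U <- nrow(tab)
  for (u in seq_len(U)) for (v in u:U) {
    A <- tab$alliance[u]; B <- tab$alliance[v]
    if (u == v) {
      if (class != "within_unit") next
      if (length(tab$members[[u]]) < 2L) next
      ex <- pr$p_unit[u] * pc^2
      en <- pr$p_unit[u] * pc
      vals <- c(vals, 2 * ex / (2 * en))
      next
    }
    cl <- if (A == B) "within_alliance"
      else if (allied(A, B)) {
        if (tab$is_bridge[u] && tab$is_bridge[v]) "third_order_bridge"
        else "third_order_nonbridge"
      } else "non_allied"
    if (cl != class) next
    ex <- pr$p_joint[u, v] * pc^2
    en_u <- pr$p_unit[u] * pc; en_v <- pr$p_unit[v] * pc
    n_dyads <- length(tab$members[[u]]) * length(tab$members[[v]])
    vals <- c(vals, rep(2 * ex / (en_u + en_v), n_dyads))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Generate a synthetic fusion-event behavior log
#'
#' Each event joins one unit from each side of a (uniformly chosen)
#' third-order alliance pair, units drawn with bridge weighting. Every
#' cross-alliance pair of participants, and every within-unit pair on each
#' side, independently emits a PET, RUB, D0 and SYNCH record with the
#' stated per-category probabilities. The generator records its own true
#' per-event unique-pair tally by direct set construction, for comparison
#' with [summarize_tallies()].
#'
#' @param cfg a [society_config()] with at least one third-order pair.
#' @param n_events number of fusion events.
#' @param rates named probabilities \code{c(pet=, rub=, d0=, synch=)}.
#' @param seed integer seed.
#' @return list with \code{events} (data frame), \code{records} (a
#'   \code{behavior_log}) and \code{truth} (per-event data frame of the
#'   six pair-count categories).
#' @export
generate_fusion_log <- function(cfg, n_events = 10L,
                                rates = c(pet = 0.12, rub = 0.10,
                                          d0 = 0.15, synch = 0.10),
                                seed = cfg$seed) {
  stopifnot(inherits(cfg, "society_config"),
            all(rates >= 0), all(rates <= 1),
            all(c("pet", "rub", "d0", "synch") %in% names(rates)))
  if (length(cfg$third_order) == 0L)
    stop("no third-order pairs configured; cannot generate fusion events")
  tab <- unit_lookup(cfg)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  ev_rows <- list(); rec <- list(); truth_rows <- list()
  for (e in seq_len(n_events)) {
    ev_id <- sprintf("F%03d", e)
    p <- cfg$third_order[[sample.int(length(cfg$third_order), 1L)]]
    pick_unit <- function(al) {
      cand <- which(tab$alliance == al)
      cand[sample.int(length(cand), 1L, prob = tab$weight[cand])]
    }
    ua <- pick_unit(p[1]); ub <- pick_unit(p[2])
    mem_a <- tab$members[[ua]]; mem_b <- tab$members[[ub]]

    cross <- expand.grid(a = mem_a, b = mem_b, stringsAsFactors = FALSE)
    within <- rbind(
      if (length(mem_a) >= 2) {
        cmb <- utils::combn(mem_a, 2)
        data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
      },
      if (length(mem_b) >= 2) {
        cmb <- utils::combn(mem_b, 2)
        data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
      })
    pairs <- rbind(cross, within)
    pairs$cross <- c(rep(TRUE, nrow(cross)), rep(FALSE, nrow(within)))

    pr_set <- prd_set <- sy_set <- list(cross = character(0),
                                        within = character(0))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      side <- if (pairs$cross[i]) "cross" else "within"
      key <- pair_key(a, b)
      emitted_contact <- FALSE
      if (stats::runif(1) < rates[["pet"]]) {
        rec[[length(rec) + 1L]] <- list(ev_id, "PET", c(a, b))
        emitted_contact <- TRUE
      }
      if (stats::runif(1) < rates[["rub"]]) {
        rec[[length(rec) + 1L]] <- list(ev_id, "RUB", c(a, b))
        emitted_contact <- TRUE
      }
      emitted_d0 <- FALSE
      if (stats::runif(1) < rates[["d0"]]) {
        rec[[length(rec) + 1L]] <- list(ev_id, "D0", c(a, b))
        emitted_d0 <- TRUE
      }
      if (emitted_contact)
        pr_set[[side]] <- union(pr_set[[side]], key)
      if (emitted_contact || emitted_d0)
        prd_set[[side]] <- union(prd_set[[side]], key)
      if (stats::runif(1) < rates[["synch"]]) {
        rec[[length(rec) + 1L]] <- list(ev_id, "SYNCH", c(a, b))
        sy_set[[side]] <- union(sy_set[[side]], key)
      }
    }

    ev_rows[[e]] <- data.frame(event_id = ev_id,
                               alliance_a = p[1], alliance_b = p[2],
                               unit_a = paste(mem_a, collapse = ";"),
                               unit_b = paste(mem_b, collapse = ";"),
                               stringsAsFactors = FALSE)
    truth_rows[[e]] <- data.frame(
      event_id = ev_id,
      third_order_pr = length(pr_set$cross),
      third_order_pr_d0 = length(prd_set$cross),
      second_order_pr = length(pr_set$within),
      second_order_pr_d0 = length(prd_set$within),
      third_order_synch = length(sy_set$cross),
      second_order_synch = length(sy_set$within),
      stringsAsFactors = FALSE)
  }

  records <- if (length(rec))
    behavior_records(event_id = vapply(rec, `[[`, character(1), 1),
                     behavior = vapply(rec, `[[`, character(1), 2),
                     actors = lapply(rec, `[[`, 3))
  else behavior_records(character(0), character(0), list())

  list(events = do.call(rbind, ev_rows),
       records = records,
       truth = do.call(rbind, truth_rows))
}

#' Read / write a society configuration as YAML
#'
#' The on-disk form mirrors the [society_config()] arguments: maps
#' \code{alliances} (alliance -> list of member-id lists), lists
#' \code{third_order} (pairs of alliance ids), scalars for the
#' probabilities and bias, \code{bridge_units} (alliance -> unit index),
#' \code{activity_probs}, \code{years}, \code{surveys_per_year},
#' \code{mortality} (id -> last date) and \code{seed}.
#'
#' @param path YAML file path.
#' @return \code{read_society_config}: a \code{society_config}.
#' @export
read_society_config <- function(path) {
  if (!file.exists(path)) stop("society config not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$alliances)) stop("society config needs an `alliances` map")
  args <- list(
    alliances = lapply(raw$alliances, function(us) lapply(us, unlist)),
    third_order = lapply(raw$third_order %||% list(), unlist))
  for (nm in c("p3", "p_unit_cohesion", "p2", "bridge_bias",
               "surveys_per_year", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$bridge_units)) args$bridge_units <- unlist(raw$bridge_units)
  if (!is.null(raw$activity_probs)) args$activity_probs <- unlist(raw$activity_probs)
  if (!is.null(raw$years)) args$years <- unlist(raw$years)
  if (!is.null(raw$mortality)) args$mortality <- unlist(raw$mortality)
  do.call(society_config, args)
}

#' @rdname read_society_config
#' @param cfg a [society_config()].
#' @export
write_society_config <- function(cfg, path) {
  yaml::write_yaml(list(
    alliances = lapply(cfg$alliances, function(us) lapply(us, as.list)),
    third_order = lapply(cfg$third_order, as.list),
    p3 = as.list(cfg$p3),
    p_unit_cohesion = cfg$p_unit_cohesion,
    p2 = cfg$p2,
    bridge_units = as.list(cfg$bridge_units),
    bridge_bias = cfg$bridge_bias,
    activity_probs = as.list(cfg$activity_probs),
    years = cfg$years,
    surveys_per_year = cfg$surveys_per_year,
    mortality = as.list(cfg$mortality),
    seed = cfg$seed), path)
  invisible(path)
}

#' Write a generator's ground truth as JSON
#'
#' Stores the planted individual -> alliance map, the expected HWI per dyad
#' class, and the generator parameters, for comparison with pipeline
#' output.
#'
#' @param truth the \code{truth} component of [generate_surveys()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    membership = as.list(truth$membership),
    expected_hwi = as.list(truth$expected_hwi),
    parameters = list(p_unit_cohesion = truth$config$p_unit_cohesion,
                      p2 = truth$config$p2,
                      p3 = as.list(truth$config$p3),
                      bridge_bias = truth$config$bridge_bias)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write surveys in the survey CSV schema
#'
#' @param surveys a \code{survey_set}.
#' @param path output CSV path.
#' @param delim member delimiter.
#' @export
write_surveys <- function(surveys, path, delim = ";") {
  df <- data.frame(survey_id = surveys$survey_id,
                   date = format(surveys$date, "%Y-%m-%d"),
                   activity = surveys$activity,
                   members = vapply(surveys$members, paste, character(1),
                                    collapse = delim),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
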