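#' Summed association strength of an individual towards a subset
#'
#' Strength (weighted degree) restricted to a subset of the network: the
#' sum of the individual's HWI values to every member of \code{subset},
#' excluding itself. Partitioning the rest of the network and summing the
#' per-part strengths recovers the individual's total strength.
#'
#' @param m an \code{association_matrix}.
#' @param id focal individual id.
#' @param subset character vector of ids (may include \code{id}; the self
#'   term is excluded).
#' @return numeric strength value (0 for an empty subset).
#' @export
subgroup_strength <- function(m, id, subset) {
  if (!id %in% rownames(m)) stop("individual not in matrix: ", id)
  subset <- setdiff(subset, id)
  missing <- setdiff(subset, rownames(m))
  if (length(missing))
    stop("subset id(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(subset) == 0L) return(0)
  sum(unclass(m)[id, subset])
}

#' Within- and between-alliance strength table
#'
#' For every individual in the matrix: \code{wStrength} is the summed HWI
#' to members of its own second-order alliance, and \code{bStrength} the
#' summed HWI to members of the alliances that are its third-order allies
#' in the period (the union, when there are several partners). Because raw
#' strength scales with network size, each measure is normalised by the
#' maximum of that measure among members of the individual's own
#' second-order alliance (\code{wStrength_N}, \code{bStrength_N} in
#' \code{[0, 1]}; exactly one individual per alliance attains 1, barring
#' ties). \code{normalization = "network"} instead divides by the global
#' maximum. A per-partner-alliance breakdown of \code{bStrength} is
#' attached as attribute \code{"partner_breakdown"}.
#'
#' @param m an \code{association_matrix} whose individuals are all
#'   registered.
#' @param registry an [alliance_registry()].
#' @param period period id (for third-order partner lookup).
#' @param normalization \code{"alliance"} (default) or \code{"network"}.
#' @return a \code{data.frame} with columns \code{id}, \code{alliance},
#'   \code{period}, \code{wStrength}, \code{bStrength}, \code{wStrength_N},
#'   \code{bStrength_N}.
#' @export
strength_table <- function(m, registry, period,
                           normalization = c("alliance", "network")) {
  normalization <- match.arg(normalization)
  ids <- rownames(m)
  unreg <- setdiff(ids, names(registry$second_order))
  if (length(unreg))
    stop("individual(s) not registered: ", paste(unreg, collapse = ", "))
  alliance <- unname(registry$second_order[ids])

  w <- b <- numeric(length(ids))
  breakdown <- list()
  for (i in seq_along(ids)) {
    own <- intersect(alliance_members(registry, alliance[i]), ids)
    w[i] <- subgroup_strength(m, ids[i], own)
    partners <- third_order_partners(registry, alliance[i], period)
    allied <- unlist(lapply(partners, function(a)
      intersect(alliance_members(registry, a), ids)))
    b[i] <- subgroup_strength(m, ids[i], allied)
    breakdown[[ids[i]]] <- vapply(partners, function(a)
      subgroup_strength(m, ids[i], intersect(alliance_members(registry, a), ids)),
      numeric(1))
  }

  norm_by <- function(v) {
    out <- numeric(length(v))
    if (normalization == "network") {
      mx <- max(v)
      if (mx == 0) {
        warning("normalisation maximum is 0; normalised values undefined")
        return(rep(NA_real_, length(v)))
      }
      return(v / mx)
    }
    for (al in unique(alliance)) {
      idx <- alliance == al
      mx <- max(v[idx])
      if (mx == 0) {
        if (any(v[idx] != 0) || sum(idx) > 0)
          out[idx] <- NA_real_
      } else out[idx] <- v[idx] / mx
    }
    if (anyNA(out))
      warning("normalisation maximum is 0 for some alliance(s); ",
              "normalised values undefined there")
    out
  }

  out <- data.frame(id = ids, alliance = alliance, period = period,
                    wStrength = w, bStrength = b,
                    wStrength_N = norm_by(w), bStrength_N = norm_by(b),
                    stringsAsFactors = FALSE)
  attr(out, "partner_breakdown") <- breakdown
  out
}

#' Write a strength table as CSV
#'
#' @param tab a [strength_table()] result.
#' @param path output path.
#' @export
write_strength_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean association between two first-order units
#'
#' Arithmetic mean of the dyadic HWI values across two disjoint sets of
#' individuals (e.g. the pair and the trio within one alliance).
#'
#' @param m an \code{association_matrix}.
#' @param unit_a,unit_b disjoint non-empty character vectors of ids.
#' @return mean cross-unit HWI.
#' @export
unit_mean_hwi <- function(m, unit_a, unit_b) {
  if (length(intersect(unit_a, unit_b)))
    stop("units overlap: ", paste(intersect(unit_a, unit_b), collapse = ", "))
  if (!length(unit_a) || !length(unit_b)) stop("units must be non-empty")
  missing <- setdiff(c(unit_a, unit_b), rownames(m))
  if (length(missing))
    stop("unit id(s) not in matrix: ", paste(missing, collapse = ", "))
  mean(unclass(m)[unit_a, unit_b])
}

#' Define the temporal snapshot periods
#'
#' @param periods data frame with columns \code{period}, \code{start_year},
#'   \code{end_year} (non-overlapping intervals), e.g. the three 2-year
#'   windows T1 2009-2010, T2 2011-2012, T3 2013-2014.
#' @param rosters optional named list (by period) of id vectors overriding
#'   the per-period roster; by default the roster is every registered
#'   individual sighted in the period's surveys.
#' @return a \code{snapshot_spec}.
#' @export
snapshot_spec <- function(periods, rosters = NULL) {
  stopifnot(all(c("period", "start_year", "end_year") %in% names(periods)),
            all(periods$start_year <= periods$end_year))
  o <- order(periods$start_year)
  p <- periods[o, , drop = FALSE]
  if (nrow(p) > 1L && any(p$start_year[-1] <= p$end_year[-nrow(p)]))
    stop("snapshot periods overlap")
  structure(list(periods = p, rosters = rosters), class = "snapshot_spec")
}

#' Recompute the analysis chain per temporal snapshot
#'
#' Subsets the surveys to each period's years, applies the period roster,
#' and recomputes HWI, cluster diagnostics and the strength table. A period
#' in which fewer than 2 rostered individuals are sighted is skipped with a
#' warning.
#'
#' @param surveys a filtered \code{survey_set}.
#' @param spec a [snapshot_spec()].
#' @param registry an [alliance_registry()].
#' @param min_sightings passed to [half_weight_index()].
#' @param variant modularity variant for [best_partition()].
#' @return named list (by period id) of lists with \code{matrix},
#'   \code{diagnostics}, \code{strength}, \code{n_surveys}.
#' @export
temporal_snapshots <- function(surveys, spec, registry, min_sightings = 1L,
                               variant = "weighted") {
  stopifnot(inherits(spec, "snapshot_spec"))
  out <- list()
  yr <- as.integer(format(surveys$date, "%Y"))
  for (r in seq_len(nrow(spec$periods))) {
    period <- spec$periods$period[r]
    sub <- surveys[yr >= spec$periods$start_year[r] &
                   yr <= spec$periods$end_year[r], , drop = FALSE]
    class(sub) <- c("survey_set", "data.frame")
    roster <- spec$rosters[[period]] %||%
      intersect(names(registry$second_order), unique(unlist(sub$members)))
    sighted <- intersect(roster, unique(unlist(sub$members)))
    if (length(sighted) < 2L || nrow(sub) == 0L) {
      warning("period ", period, " skipped: fewer than 2 rostered ",
              "individuals sighted")
      next
    }
    counts <- count_sightings(sub, ids = sighted)
    mat <- half_weight_index(counts, min_sightings = min_sightings,
                             period = period)
    out[[period]] <- list(
      matrix = mat,
      diagnostics = best_partition(mat, variant = variant),
      strength = strength_table(mat, registry, period),
      n_surveys = nrow(sub))
  }
  out
}
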