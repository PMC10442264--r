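#' Run the full alliance analysis chain and (optionally) write a report
#'
#' Orchestrates filter -> HWI -> clustering -> strength -> temporal
#' snapshots over a survey set and registry, returning everything as one
#' structured result. When \code{out_dir} is given, the pooled association
#' matrix, strength table, diagnostics JSON, edge list and newick
#' dendrogram are written there, together with a single \code{summary.json}
#' holding the headline statistics (Q, cut level, CCC, community
#' membership, per-period diagnostics and survey classification counts).
#'
#' @param surveys a \code{survey_set} (unfiltered; filtering is applied
#'   here).
#' @param registry an [alliance_registry()].
#' @param period period id for strength/classification on the pooled
#'   matrix.
#' @param spec optional [snapshot_spec()]; when given, per-period analyses
#'   are included.
#' @param filter_cfg a [survey_filter_config()].
#' @param min_sightings passed to [half_weight_index()].
#' @param variant modularity variant.
#' @param out_dir optional output directory (created if absent).
#' @return list with \code{n_surveys_total}, \code{n_surveys_retained},
#'   \code{classification} (table of survey levels), \code{matrix},
#'   \code{diagnostics}, \code{strength}, and \code{snapshots} (possibly
#'   NULL).
#' @export
alliance_report <- function(surveys, registry, period,
                            spec = NULL,
                            filter_cfg = survey_filter_config(),
                            min_sightings = 1L,
                            variant = "weighted",
                            out_dir = NULL) {
  retained <- filter_surveys(surveys, filter_cfg)
  if (nrow(retained) == 0L) stop("no surveys retained after filtering")
  classification <- table(classify_surveys(retained, registry, period))

  ids <- intersect(names(registry$second_order),
                   unique(unlist(retained$members)))
  if (length(ids) < 2L) stop("fewer than 2 registered individuals sighted")
  counts <- count_sightings(retained, ids = ids)
  m <- half_weight_index(counts, min_sightings = min_sightings,
                         period = period)
  diagnostics <- best_partition(m, variant = variant)
  strength <- strength_table(m, registry, period)
  snapshots <- if (!is.null(spec))
    temporal_snapshots(retained, spec, registry,
                       min_sightings = min_sightings, variant = variant)

  out <- list(n_surveys_total = nrow(surveys),
              n_surveys_retained = nrow(retained),
              classification = classification,
              matrix = m,
              diagnostics = diagnostics,
              strength = strength,
              snapshots = snapshots)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_association_matrix(m, file.path(out_dir, "hwi_pooled.csv"))
    write_strength_table(strength, file.path(out_dir, "strength_pooled.csv"))
    write_diagnostics_json(diagnostics,
                           file.path(out_dir, "diagnostics_pooled.json"))
    export_edgelist(m, file.path(out_dir, "edges_pooled.csv"))
    export_newick(diagnostics$dendrogram,
                  file.path(out_dir, "dendrogram_pooled.nwk"))
    summary <- list(
      n_surveys_total = nrow(surveys),
      n_surveys_retained = nrow(retained),
      classification = as.list(classification),
      q_max = diagnostics$q_max,
      cut_at_qmax = diagnostics$cut_at_qmax,
      cut_midpoint = diagnostics$cut_midpoint,
      ccc = diagnostics$ccc,
      n_communities = diagnostics$n_communities,
      clusters = diagnostics$clusters,
      periods = lapply(out$snapshots %||% list(), function(sn) list(
        n_surveys = sn$n_surveys,
        q_max = sn$diagnostics$q_max,
        cut_at_qmax = sn$diagnostics$cut_at_qmax,
        ccc = sn$diagnostics$ccc,
        n_communities = sn$diagnostics$n_communities)))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (pid in names(out$snapshots %||% list())) {
      write_association_matrix(out$snapshots[[pid]]$matrix,
                               file.path(out_dir, sprintf("hwi_%s.csv", pid)))
      write_strength_table(out$snapshots[[pid]]$strength,
                           file.path(out_dir, sprintf("strength_%s.csv", pid)))
    }
  }
  out
}
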