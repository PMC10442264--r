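#' Locate transcribed supplementary HWI matrices
#'
#' The published study's dyadic HWI matrices (pooled and per-period) are
#' distributed in its electronic supplementary material and companion
#' repository, not with this package. To run the integration checks that
#' reproduce the published cluster diagnostics, transcribe each table once
#' into the square-CSV shape of [write_association_matrix()] and place the
#' files in the directory this function resolves (by default
#' \code{inst/extdata/supplementary}, overridable with
#' \code{options(alliancenet.supplementary_dir = ...)}). Expected file
#' names: \code{hwi_pooled.csv}, \code{hwi_T1.csv}, \code{hwi_T2.csv},
#' \code{hwi_T3.csv}.
#'
#' @return the directory path (which may not contain the files).
#' @export
supplementary_dir <- function() {
  getOption("alliancenet.supplementary_dir",
            system.file("extdata", "supplementary", package = "alliancenet"))
}

#' Read one transcribed supplementary HWI matrix
#'
#' @param table one of \code{"pooled"}, \code{"T1"}, \code{"T2"},
#'   \code{"T3"}.
#' @return an \code{association_matrix}.
#' @export
read_supplementary_matrix <- function(table = c("pooled", "T1", "T2", "T3")) {
  table <- match.arg(table)
  path <- file.path(supplementary_dir(), sprintf("hwi_%s.csv", table))
  if (!file.exists(path))
    stop("supplementary HWI matrix '", table, "' not transcribed: expected ",
         path, " (see ?supplementary_dir)", call. = FALSE)
  m <- read_association_matrix(path)
  attr(m, "period") <- if (table == "pooled") NULL else table
  m
}
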