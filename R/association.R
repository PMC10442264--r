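#' Tally dyadic sighting counts
#'
#' Counts, over a filtered survey set, how often each individual was seen
#' (\code{n}) and how often each dyad was seen together (\code{x}). Because
#' one survey is one sampling period (same-day resights having been removed
#' upstream) and a survey records a single group, the "seen in the same
#' period but in different groups" count \code{y_joint_apart} is identically
#' zero; it is kept as an explicit component so that day-based sampling
#' periods can be configured later without changing the index formula.
#'
#' @param surveys a \code{survey_set} (already filtered).
#' @param ids character vector of individual ids to tally; defaults to all
#'   ids appearing in the surveys.
#' @return an object of class \code{sighting_counts}: list with \code{n}
#'   (named integer vector), \code{x} and \code{y_joint_apart} (symmetric
#'   integer matrices), and \code{n_surveys}.
#' @export
count_sightings <- function(surveys, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(unlist(surveys$members)))
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("`ids` must be non-empty")
  k <- length(ids)
  inc <- matrix(0L, nrow = k, ncol = max(nrow(surveys), 1L),
                dimnames = list(ids, NULL))
  if (nrow(surveys) > 0L)
    for (s in seq_len(nrow(surveys))) {
      present <- ids %in% surveys$members[[s]]
      inc[present, s] <- 1L
    }
  else inc <- inc[, 0, drop = FALSE]
  x <- inc %*% t(inc)
  n <- diag(x)
  diag(x) <- 0L
  structure(list(n = stats::setNames(as.integer(n), ids),
                 x = x,
                 y_joint_apart = matrix(0L, k, k, dimnames = list(ids, ids)),
                 n_surveys = nrow(surveys)),
            class = "sighting_counts")
}

#' Half-weight association index matrix
#'
#' The half-weight index (HWI) for a dyad is
#' \deqn{HWI = x / (x + y_{AB} + (y_A + y_B)/2)}
#' where \eqn{x} is the number of sampling periods with both individuals in
#' the same group, \eqn{y_{AB}} the number with both seen but in different
#' groups, and \eqn{y_A}, \eqn{y_B} the numbers with only one of the two
#' seen. With one group per sampling period (\eqn{y_{AB} = 0}) this reduces
#' to \eqn{2x / (n_A + n_B)}. The index lies in \code{[0, 1]}: 1 when two
#' individuals are only ever seen together, 0 when never together.
#'
#' Individuals with fewer than \code{min_sightings} sightings are dropped
#' (with a message); the index is undefined for them.
#'
#' @param counts a [count_sightings()] result.
#' @param min_sightings minimum sightings to retain an individual
#'   (default 1).
#' @param period optional period id stored on the result.
#' @return an \code{association_matrix}: symmetric numeric matrix with
#'   individual ids as dimnames, zero diagonal (the diagonal is ignored by
#'   all downstream computations), and attributes \code{n_surveys} and
#'   \code{period}.
#' @export
half_weight_index <- function(counts, min_sightings = 1L, period = NULL) {
  stopifnot(inherits(counts, "sighting_counts"))
  keep <- counts$n >= min_sightings
  if (any(!keep))
    message("dropping ", sum(!keep), " individual(s) with fewer than ",
            min_sightings, " sighting(s): ",
            paste(names(counts$n)[!keep], collapse = ", "))
  ids <- names(counts$n)[keep]
  if (length(ids) < 2L)
    stop("fewer than 2 individuals with sufficient sightings")
  n <- counts$n[ids]
  x <- counts$x[ids, ids, drop = FALSE]
  yab <- counts$y_joint_apart[ids, ids, drop = FALSE]
  # denominator: x + yAB + (yA + yB)/2 with yA = n_A - x - yAB
  denom <- x + yab + (outer(n, n, "+") - 2 * x - 2 * yab) / 2
  hwi <- ifelse(denom > 0, x / denom, 0)
  diag(hwi) <- 0
  dimnames(hwi) <- list(ids, ids)
  association_matrix(hwi, n_surveys = counts$n_surveys, period = period)
}

#' Construct an association matrix object
#'
#' @param values symmetric numeric matrix in \code{[0, 1]} with individual
#'   ids as dimnames; the diagonal is ignored (stored as 0).
#' @param n_surveys number of surveys behind the matrix (optional).
#' @param period period id (optional).
#' @return an \code{association_matrix}.
#' @export
association_matrix <- function(values, n_surveys = NA_integer_, period = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("association matrix needs individual ids as dimnames")
  if (nrow(values) != ncol(values) ||
      !isTRUE(all.equal(unname(values), unname(t(values)), tolerance = 1e-8)))
    stop("association matrix must be square and symmetric")
  diag(values) <- 0
  if (any(values < -1e-12 | values > 1 + 1e-12))
    stop("association values must lie in [0, 1]")
  structure(values, class = c("association_matrix", "matrix"),
            n_surveys = n_surveys, period = period)
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix (HWI):", nrow(x), "individuals",
      if (!is.na(attr(x, "n_surveys")))
        paste0("from ", attr(x, "n_surveys"), " surveys"),
      if (!is.null(attr(x, "period"))) paste0("[period ", attr(x, "period"), "]"),
      "\n")
  off <- x[upper.tri(x)]
  cat(sprintf("  mean HWI %.3f, max %.3f, %d/%d dyads nonzero\n",
              mean(off), max(off), sum(off > 0), length(off)))
  invisible(x)
}

#' Write / read an association matrix as square CSV
#'
#' The on-disk shape matches published supplementary HWI tables: a square
#' CSV with a header row and an index column of individual codes, values to
#' 4 decimal places.
#'
#' @param m an \code{association_matrix}.
#' @param path output CSV path.
#' @export
write_association_matrix <- function(m, path) {
  out <- format(round(unclass(m), 4), nsmall = 4, trim = TRUE)
  df <- data.frame(id = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association_matrix
#' @return \code{read_association_matrix}: an \code{association_matrix}.
#' @export
read_association_matrix <- function(path) {
  if (!file.exists(path)) stop("association matrix file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(vals), ids))
    stop("matrix CSV is not square (header ids must match the index column)")
  rownames(vals) <- ids
  storage.mode(vals) <- "double"
  vals <- (vals + t(vals)) / 2  # tolerate asymmetric rounding in transcripts
  association_matrix(vals)
}

# attempt n_attempts random 2x2 checkerboard swaps on a binary incidence
# matrix; every applied swap preserves all row and column sums
checkerboard_swaps <- function(M, n_attempts) {
  nr <- nrow(M); nc <- ncol(M)
  made <- 0L
  for (a in seq_len(n_attempts)) {
    r <- sample.int(nr, 2L)
    cc <- sample.int(nc, 2L)
    m11 <- M[r[1], cc[1]]; m12 <- M[r[1], cc[2]]
    m21 <- M[r[2], cc[1]]; m22 <- M[r[2], cc[2]]
    if (m11 + m22 == 2L && m12 + m21 == 0L) {
      M[r[1], cc[1]] <- 0L; M[r[2], cc[2]] <- 0L
      M[r[1], cc[2]] <- 1L; M[r[2], cc[1]] <- 1L
      made <- made + 1L
    } else if (m12 + m21 == 2L && m11 + m22 == 0L) {
      M[r[1], cc[2]] <- 0L; M[r[2], cc[1]] <- 0L
      M[r[1], cc[1]] <- 1L; M[r[2], cc[2]] <- 1L
      made <- made + 1L
    }
  }
  list(M = M, made = made)
}

incidence_from_surveys <- function(surveys, ids) {
  k <- length(ids)
  inc <- matrix(0L, k, nrow(surveys), dimnames = list(ids, surveys$survey_id))
  for (s in seq_len(nrow(surveys)))
    inc[ids %in% surveys$members[[s]], s] <- 1L
  inc
}

hwi_from_incidence <- function(inc) {
  x <- inc %*% t(inc)
  n <- diag(x)
  diag(x) <- 0
  denom <- outer(n, n, "+")
  hwi <- ifelse(denom > 0, 2 * x / denom, 0)
  diag(hwi) <- 0
  hwi
}

#' Permutation test for preferential association
#'
#' Tests whether individuals associate non-randomly by comparing an
#' observed summary of the HWI distribution against a null generated by
#' sequential checkerboard swaps of the individual-by-survey incidence
#' matrix. Each swap exchanges a 2x2 checkerboard submatrix, so every
#' permuted dataset preserves each survey's group size and each
#' individual's total sighting count. A coefficient of variation of the
#' HWI above the null indicates preferred/avoided companionships.
#'
#' @param surveys a filtered \code{survey_set}.
#' @param n_perm number of null samples (>= 100).
#' @param seed integer seed; all randomness flows from it.
#' @param statistic summary statistic of the off-diagonal HWI values:
#'   coefficient of variation (default), mean, or standard deviation.
#' @param burn_in swaps discarded before sampling (default 1000).
#' @param thin attempted swaps between successive null samples
#'   (default 100).
#' @param ids individuals to include; defaults to all in \code{surveys}.
#' @return list with \code{observed}, \code{null} (numeric vector of length
#'   \code{n_perm}), \code{null_mean}, and permutation p-values
#'   \code{p_greater}, \code{p_less}, \code{p_two} (two-sided, doubled
#'   smaller tail, +1 corrected).
#' @export
permutation_null <- function(surveys, n_perm = 1000L, seed = 1L,
                             statistic = c("cv_hwi", "mean_hwi", "sd_hwi"),
                             burn_in = 1000L, thin = 100L, ids = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (nrow(surveys) < 2L) stop("need at least 2 surveys")
  if (is.null(ids)) ids <- sort(unique(unlist(surveys$members)))
  if (length(ids) < 3L) stop("need at least 3 individuals")
  inc <- incidence_from_surveys(surveys, ids)

  stat_fun <- switch(statistic,
    cv_hwi = function(h) { v <- h[upper.tri(h)]
      if (mean(v) == 0) 0 else stats::sd(v) / mean(v) },
    mean_hwi = function(h) mean(h[upper.tri(h)]),
    sd_hwi = function(h) stats::sd(h[upper.tri(h)]))

  observed <- stat_fun(hwi_from_incidence(inc))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  burn <- checkerboard_swaps(inc, burn_in)
  if (burn$made == 0L && burn_in > 0L)
    stop("no valid checkerboard swap found during burn-in: ",
         "the incidence matrix admits no degree-preserving rearrangement")
  M <- burn$M
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    M <- checkerboard_swaps(M, thin)$M
    null[i] <- stat_fun(hwi_from_incidence(M))
  }

  p_greater <- (sum(null >= observed) + 1) / (n_perm + 1)
  p_less <- (sum(null <= observed) + 1) / (n_perm + 1)
  list(statistic = statistic, observed = observed, null = null,
       null_mean = mean(null),
       p_greater = p_greater, p_less = p_less,
       p_two = min(1, 2 * min(p_greater, p_less)))
}
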