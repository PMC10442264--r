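# shared builders for test societies, matrices and survey sets

toy_registry <- function() {
  alliance_registry(
    second_order = c(A1 = "A", A2 = "A", A3 = "A", A4 = "A",
                     B1 = "B", B2 = "B", B3 = "B",
                     C1 = "C", C2 = "C"),
    first_order_units = list(
      P1 = list(c("A1", "A2"), c("A3", "A4"), c("B1", "B2", "B3"),
                c("C1", "C2"))),
    third_order_pairs = list(P1 = list(c("A", "B"))))
}

# association_matrix from a named upper-triangle spec, zero elsewhere
toy_matrix <- function(ids, ...) {
  vals <- list(...)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (key in names(vals)) {
    p <- strsplit(key, "_", fixed = TRUE)[[1]]
    m[p[1], p[2]] <- m[p[2], p[1]] <- vals[[key]]
  }
  association_matrix(m)
}

surveys_from_members <- function(members, dates = NULL, activity = "travel") {
  n <- length(members)
  make_surveys(
    survey_id = sprintf("S%03d", seq_len(n)),
    date = dates %||% rep(as.Date("2009-09-01"), n),
    activity = rep_len(activity, n),
    members = members)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random symmetric association matrix with distinct off-diagonal values
random_matrix <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("I%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- sample(seq(0.01, 0.99, length.out = n * (n - 1) / 2))
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  association_matrix(m)
}

# all partitions of the leaves consistent with the dendrogram (every
# internal node independently split or kept), as lists of id vectors
tree_partitions <- function(dend) {
  n <- length(dend$labels)
  rec <- function(code) {
    if (code < 0) {
      leaf <- dend$labels[-code]
      return(list(all = leaf, parts = list(list(leaf))))
    }
    a <- rec(dend$merge[code, 1]); b <- rec(dend$merge[code, 2])
    combos <- list()
    for (pa in a$parts) for (pb in b$parts)
      combos[[length(combos) + 1L]] <- c(pa, pb)
    combos[[length(combos) + 1L]] <- list(c(a$all, b$all))
    list(all = c(a$all, b$all), parts = combos)
  }
  rec(n - 1L)$parts
}

membership_from_parts <- function(parts) {
  out <- character(0)
  for (i in seq_along(parts))
    out[parts[[i]]] <- as.character(i)
  out
}
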