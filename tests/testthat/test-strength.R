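test_that("subgroup strength sums the focal individual's ties", {
  ids <- c("S", "X", "Y", "Z")
  m <- toy_matrix(ids, S_X = 0.5, S_Y = 0.5, S_Z = 0.5)
  expect_equal(subgroup_strength(m, "S", character(0)), 0)
  expect_equal(subgroup_strength(m, "S", c("X", "Y", "Z")), 1.5)
  # self term excluded even when the subset names the focal individual
  expect_equal(subgroup_strength(m, "S", ids), 1.5)
  expect_error(subgroup_strength(m, "Q", "X"), "not in matrix")
})

test_that("subgroup strengths are additive over a partition of the network", {
  m <- random_matrix(8, seed = 31)
  ids <- rownames(m)
  focal <- ids[1]
  parts <- split(ids[-1], rep(1:3, length.out = 7))
  total <- subgroup_strength(m, focal, ids)
  expect_equal(sum(vapply(parts, function(p)
    subgroup_strength(m, focal, p), numeric(1))), total)
})

test_that("strength table matches a hand-computed 5-individual society", {
  reg <- alliance_registry(
    second_order = c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B"),
    third_order_pairs = list(P1 = list(c("A", "B"))))
  m <- toy_matrix(c("A1", "A2", "A3", "B1", "B2"),
                  A1_A2 = 0.8, A1_A3 = 0.6, A2_A3 = 0.4,
                  B1_B2 = 0.9,
                  A1_B1 = 0.3, A1_B2 = 0.1, A2_B1 = 0.2, A3_B2 = 0.05)
  st <- strength_table(m, reg, "P1")
  rownames(st) <- st$id
  # within: A1 = 0.8 + 0.6, A2 = 0.8 + 0.4, A3 = 0.6 + 0.4
  expect_equal(st["A1", "wStrength"], 1.4)
  expect_equal(st["A2", "wStrength"], 1.2)
  expect_equal(st["A3", "wStrength"], 1.0)
  # between: A1 = 0.3 + 0.1, A2 = 0.2, A3 = 0.05; B1 = 0.3 + 0.2, B2 = 0.15
  expect_equal(st["A1", "bStrength"], 0.4)
  expect_equal(st["B1", "bStrength"], 0.5)
  # normalisation by the maximum within the own alliance
  expect_equal(st["A2", "wStrength_N"], 1.2 / 1.4)
  expect_equal(st["A1", "bStrength_N"], 1)
  expect_equal(st["A3", "bStrength_N"], 0.05 / 0.4)
  expect_equal(st["B2", "bStrength_N"], 0.15 / 0.5)
  # per-partner breakdown sums to bStrength
  bd <- attr(st, "partner_breakdown")
  expect_equal(unname(sum(bd[["A1"]])), 0.4)
})

test_that("each normalisation group has a maximum of exactly 1", {
  cfg <- society_preset("T3")
  reg <- registry_from_config(cfg, "P1")
  sim <- generate_surveys(cfg, n_surveys = 600, seed = 2)
  m <- half_weight_index(count_sightings(sim$surveys,
                                         names(reg$second_order)))
  st <- strength_table(m, reg, "P1")
  for (al in unique(st$alliance)) {
    sub <- st[st$alliance == al, ]
    expect_equal(max(sub$wStrength_N), 1)
    expect_equal(max(sub$bStrength_N), 1)
    expect_true(all(sub$wStrength_N >= 0 & sub$wStrength_N <= 1))
    expect_true(all(sub$bStrength_N >= 0 & sub$bStrength_N <= 1))
  }
})

test_that("equal dyadic weights normalise everyone to 1", {
  reg <- alliance_registry(
    second_order = c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B"),
    third_order_pairs = list(P1 = list(c("A", "B"))))
  ids <- c("A1", "A2", "A3", "B1", "B2")
  vals <- matrix(0.4, 5, 5, dimnames = list(ids, ids))
  diag(vals) <- 0
  st <- strength_table(association_matrix(vals), reg, "P1")
  expect_true(all(st$wStrength_N == 1))
  expect_true(all(st$bStrength_N == 1))
})

test_that("strength values are invariant to consistent alliance relabelling", {
  reg <- toy_registry()
  m <- random_matrix(9, seed = 5)
  dimnames(m) <- list(names(reg$second_order), names(reg$second_order))
  m <- association_matrix(unclass(m))
  st1 <- suppressWarnings(strength_table(m, reg, "P1"))
  relab <- c(A = "alpha", B = "beta", C = "gamma")
  reg2 <- alliance_registry(
    second_order = stats::setNames(relab[reg$second_order],
                                   names(reg$second_order)),
    third_order_pairs = list(P1 = list(c("alpha", "beta"))))
  st2 <- suppressWarnings(strength_table(m, reg2, "P1"))
  expect_equal(st2$wStrength, st1$wStrength)
  expect_equal(st2$bStrength, st1$bStrength)
  expect_equal(st2$bStrength_N, st1$bStrength_N)
})

test_that("an alliance without third-order partners has undefined bStrength_N", {
  reg <- toy_registry()  # C has no third-order partner in P1
  ids <- names(reg$second_order)
  vals <- matrix(0.3, 9, 9, dimnames = list(ids, ids))
  diag(vals) <- 0
  expect_warning(st <- strength_table(association_matrix(vals), reg, "P1"),
                 "normalisation maximum is 0")
  expect_true(all(is.na(st$bStrength_N[st$alliance == "C"])))
  expect_true(all(st$bStrength[st$alliance == "C"] == 0))
})

test_that("unit mean association averages the cross-unit dyads", {
  ids <- c("P1", "P2", "T1", "T2", "T3")
  m <- toy_matrix(ids, P1_T1 = 0.9, P1_T2 = 0.8, P1_T3 = 0.7,
                  P2_T1 = 0.6, P2_T2 = 0.5, P2_T3 = 0.3,
                  P1_P2 = 0.95)
  expect_equal(unit_mean_hwi(m, c("P1", "P2"), c("T1", "T2", "T3")),
               mean(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.3)))
  # constant cross dyads give that constant
  m2 <- toy_matrix(c("X1", "X2", "Y1"), X1_Y1 = 0.5, X2_Y1 = 0.5)
  expect_equal(unit_mean_hwi(m2, c("X1", "X2"), "Y1"), 0.5)
  expect_error(unit_mean_hwi(m, c("P1", "T1"), c("T1", "T2")), "overlap")
})

test_that("temporal snapshots subset by period and apply mortality rosters", {
  cfg <- society_preset("T1", years = 2009:2012,
                        mortality = c(KS01 = "2010-12-31"))
  reg <- registry_from_config(cfg, "ALL")
  reg$third_order_pairs <- list(T1 = list(c("KS", "PD")),
                                T2 = list(c("KS", "PD")))
  sim <- generate_surveys(cfg, n_surveys = 1200, seed = 3)
  spec <- snapshot_spec(data.frame(period = c("T1", "T2"),
                                   start_year = c(2009, 2011),
                                   end_year = c(2010, 2012)))
  # RR has no third-order partner here, so its bStrength_N warns as undefined
  snaps <- suppressWarnings(temporal_snapshots(sim$surveys, spec, reg))
  expect_setequal(names(snaps), c("T1", "T2"))
  expect_true("KS01" %in% rownames(snaps$T1$matrix))
  # KS01 dies after 2010 and is never sighted in T2
  expect_false("KS01" %in% rownames(snaps$T2$matrix))
  expect_s3_class(snaps$T1$diagnostics, "cluster_diagnostics")
  expect_equal(sort(unique(snaps$T1$strength$alliance)),
               c("KS", "PD", "RR"))
})

test_that("surveys confined to one period produce only that snapshot", {
  cfg <- society_preset("T1")  # years 2009:2010
  reg <- registry_from_config(cfg, "ALL")
  reg$third_order_pairs <- list(T1 = list(c("KS", "PD")),
                                T2 = list(c("KS", "PD")))
  sim <- generate_surveys(cfg, n_surveys = 400, seed = 4)
  spec <- snapshot_spec(data.frame(period = c("T1", "T2"),
                                   start_year = c(2009, 2011),
                                   end_year = c(2010, 2012)))
  suppressWarnings(  # RR's undefined bStrength_N also warns here
    expect_warning(snaps <- temporal_snapshots(sim$surveys, spec, reg),
                   "T2 skipped"))
  expect_equal(names(snaps), "T1")
})
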