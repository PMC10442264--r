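test_that("without unit attachments every survey is a single unit", {
  cfg <- society_preset("T1", p2 = 0, p3 = 0, p_unit_cohesion = 1)
  reg <- registry_from_config(cfg, "P1")
  sim <- generate_surveys(cfg, n_surveys = 150, seed = 1)
  units <- lapply(reg$first_order_units$P1, sort)
  unit_keys <- vapply(units, paste, character(1), collapse = ",")
  for (mm in sim$surveys$members)
    expect_true(paste(sort(mm), collapse = ",") %in% unit_keys)
})

test_that("without third-order joins cross-alliance association is zero", {
  cfg <- society_preset("T1", p3 = 0)
  reg <- registry_from_config(cfg, "P1")
  sim <- generate_surveys(cfg, n_surveys = 400, seed = 2)
  m <- half_weight_index(count_sightings(sim$surveys,
                                         names(reg$second_order)))
  al <- reg$second_order[rownames(m)]
  cross <- outer(al, al, "!=")
  expect_true(all(unclass(m)[cross] == 0))
  expect_equal(expected_hwi(cfg, "third_order_bridge"), 0)
})

test_that("planted dyad classes are ordered as designed", {
  cfg <- society_preset("T1")
  eh <- vapply(dyad_classes(), function(cl) expected_hwi(cfg, cl), numeric(1))
  expect_gt(eh[["within_unit"]], eh[["within_alliance"]])
  expect_gt(eh[["within_alliance"]], eh[["third_order_bridge"]])
  expect_gt(eh[["third_order_bridge"]], eh[["third_order_nonbridge"]])
  expect_equal(eh[["non_allied"]], 0)

  for (seed in 1:3) {
    sim <- generate_surveys(cfg, n_surveys = 2000, seed = seed)
    reg <- registry_from_config(cfg, "P1")
    m <- half_weight_index(count_sightings(sim$surveys,
                                           names(reg$second_order)))
    units <- reg$first_order_units$P1
    unit_of <- stats::setNames(rep(seq_along(units), lengths(units)),
                               unlist(units))
    al <- reg$second_order
    ids <- rownames(m)
    cls <- function(a, b) {
      if (unit_of[[a]] == unit_of[[b]]) return("within_unit")
      if (al[[a]] == al[[b]]) return("within_alliance")
      if (all(sort(c(al[[a]], al[[b]])) == c("KS", "PD"))) return("third")
      "non_allied"
    }
    sums <- c(within_unit = 0, within_alliance = 0, third = 0,
              non_allied = 0)
    cnts <- sums
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      k <- cls(ids[i], ids[j])
      sums[k] <- sums[k] + unclass(m)[i, j]
      cnts[k] <- cnts[k] + 1
    }
    means <- sums / cnts
    expect_gt(means[["within_unit"]], means[["within_alliance"]])
    expect_gt(means[["within_alliance"]], means[["third"]])
  }
})

test_that("closed-form expected HWI matches a large Monte-Carlo run", {
  cfg <- society_preset("T1")
  sim <- generate_surveys(cfg, n_surveys = 20000, seed = 10)
  reg <- registry_from_config(cfg, "P1")
  m <- half_weight_index(count_sightings(sim$surveys,
                                         names(reg$second_order)))
  units <- reg$first_order_units$P1
  unit_of <- stats::setNames(rep(seq_along(units), lengths(units)),
                             unlist(units))
  bridge_of <- function(id) {
    alc <- reg$second_order[[id]]
    alc %in% names(cfg$bridge_units) &&
      unit_of[[id]] == cfg$bridge_units[[alc]] +
        c(KS = 0, PD = 4, RR = 7)[[alc]]
  }
  al <- reg$second_order
  ids <- rownames(m)
  observed <- list(within_unit = c(), within_alliance = c(),
                   third_order_bridge = c(), third_order_nonbridge = c())
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- ids[i]; b <- ids[j]
    k <- if (unit_of[[a]] == unit_of[[b]]) "within_unit"
      else if (al[[a]] == al[[b]]) "within_alliance"
      else if (all(sort(c(al[[a]], al[[b]])) == c("KS", "PD"))) {
        if (bridge_of(a) && bridge_of(b)) "third_order_bridge"
        else "third_order_nonbridge"
      } else NA_character_
    if (is.na(k)) next
    observed[[k]] <- c(observed[[k]], unclass(m)[i, j])
  }
  for (cl in names(observed))
    expect_lt(abs(mean(observed[[cl]]) - expected_hwi(cfg, cl)), 0.02)
})

test_that("degenerate cohesion settings give the closed-form extremes", {
  cfg <- society_preset("T1", p_unit_cohesion = 1, p2 = 0, p3 = 0)
  expect_equal(expected_hwi(cfg, "within_unit"), 1)
  expect_equal(expected_hwi(cfg, "non_allied"), 0)
})

test_that("mortality removes individuals from later surveys", {
  cfg <- society_preset("T1", years = 2009:2012,
                        mortality = c(KS01 = "2010-12-31", PD07 = "2011-12-31"))
  sim <- generate_surveys(cfg, n_surveys = 800, seed = 6)
  yr <- as.integer(format(sim$surveys$date, "%Y"))
  seen <- function(id, years) any(vapply(
    sim$surveys$members[yr %in% years], function(mm) id %in% mm, logical(1)))
  expect_true(seen("KS01", 2009:2010))
  expect_false(seen("KS01", 2011:2012))
  expect_false(seen("PD07", 2012))
})

test_that("an alliance extinguished by mortality is a config error", {
  cfg <- society_preset("T1", years = 2009:2010,
                        mortality = c(RR01 = "2009-01-01", RR02 = "2009-01-01",
                                      RR03 = "2009-01-01", RR04 = "2009-01-01",
                                      RR05 = "2009-01-01"))
  expect_error(generate_surveys(cfg, n_surveys = 50, seed = 1),
               "no living members")
})

test_that("survey generation is reproducible under a fixed seed", {
  cfg <- society_preset("T3")
  a <- generate_surveys(cfg, n_surveys = 100, seed = 5)
  b <- generate_surveys(cfg, n_surveys = 100, seed = 5)
  expect_identical(a$surveys$members, b$surveys$members)
  expect_identical(a$surveys$date, b$surveys$date)
  c <- generate_surveys(cfg, n_surveys = 100, seed = 6)
  expect_false(identical(a$surveys$members, c$surveys$members))
})

test_that("fusion log generation matches its own recorded truth", {
  cfg <- society_preset("T3")
  reg <- registry_from_config(cfg, "P1")
  for (seed in c(1:8, 101:108)) {
    log <- generate_fusion_log(cfg, n_events = 8, seed = seed)
    if (nrow(log$records) == 0) next
    s <- summarize_tallies(log$records, reg, "P1")
    got <- s$per_event[match(log$truth$event_id, s$per_event$event_id),
                       names(log$truth)]
    rownames(got) <- NULL
    expect_equal(as.data.frame(got), log$truth)
  }
})

test_that("saturated behavior rates touch every pair exactly once", {
  cfg <- society_preset("T3")
  reg <- registry_from_config(cfg, "P1")
  log <- generate_fusion_log(cfg, n_events = 4, seed = 3,
                             rates = c(pet = 1, rub = 1, d0 = 1, synch = 1))
  s <- summarize_tallies(log$records, reg, "P1")
  expect_equal(s$per_event$third_order_pr, s$per_event$third_order_pr_d0)
  # every cross pair of the two participating units appears
  for (r in seq_len(nrow(log$events))) {
    na <- length(strsplit(log$events$unit_a[r], ";")[[1]])
    nb <- length(strsplit(log$events$unit_b[r], ";")[[1]])
    expect_equal(s$per_event$third_order_pr[
      s$per_event$event_id == log$events$event_id[r]], na * nb)
  }
  # zero rates produce an empty log
  log0 <- generate_fusion_log(cfg, n_events = 4, seed = 3,
                              rates = c(pet = 0, rub = 0, d0 = 0, synch = 0))
  expect_equal(nrow(log0$records), 0)
  expect_true(all(log0$truth[, -1] == 0))
})

test_that("a society without third-order pairs cannot host fusion events", {
  cfg <- society_preset("T1", third_order = list())
  expect_error(generate_fusion_log(cfg, n_events = 2, seed = 1),
               "no third-order pairs")
})

test_that("society configs round-trip through YAML with identical output", {
  cfg <- society_preset("T3", mortality = c(RR05 = "2013-12-31"),
                        p3 = c("KS|PD" = 0.1, "KS|RR" = 0.2))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_society_config(cfg, path)
  cfg2 <- read_society_config(path)
  expect_equal(cfg2$alliances, cfg$alliances)
  expect_equal(cfg2$third_order, cfg$third_order)
  expect_equal(cfg2$p3, cfg$p3)
  expect_equal(cfg2$mortality, cfg$mortality)
  a <- generate_surveys(cfg, n_surveys = 60, seed = 8)
  b <- generate_surveys(cfg2, n_surveys = 60, seed = 8)
  expect_identical(a$surveys$members, b$surveys$members)
  # ground truth is serialisable
  json <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(a$truth, json)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$expected_hwi$within_unit,
               unname(a$truth$expected_hwi[["within_unit"]]))
})

test_that("generated surveys round-trip through the survey CSV schema", {
  cfg <- society_preset("T3")
  sim <- generate_surveys(cfg, n_surveys = 40, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_surveys(sim$surveys, path)
  back <- read_surveys(path)
  expect_equal(back$survey_id, sim$surveys$survey_id)
  expect_equal(back$date, sim$surveys$date)
  expect_equal(lapply(back$members, sort), lapply(sim$surveys$members, sort))
})
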