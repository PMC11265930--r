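test_that("config validation names the offending field", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(prop_solvers = 1.4), "prop_solvers")
  expect_error(synthetic_config(preference_concentration = 0),
               "preference_concentration")
  expect_error(synthetic_config(competition_sharpening = 0),
               "competition_sharpening")
  expect_error(synthetic_config(latch_difficulty = c(S = 1, H = 1)),
               "latch_difficulty")
})

test_that("population generation is deterministic given the seed", {
  cfg <- synthetic_config(n_individuals = 10, seed = 99)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  p3 <- generate_population(synthetic_config(n_individuals = 10, seed = 100))
  expect_false(identical(p1$traits, p3$traits))
  # preference rows are simplex points
  th <- as.matrix(p1$traits[, paste0("theta_", latch_alphabet())])
  expect_equal(unname(rowSums(th)), rep(1, 10))
  expect_true(all(th >= 0))
})

test_that("prop_solvers = 0 yields a population that never opens a door", {
  cfg <- synthetic_config(n_individuals = 8, nights = 2, prop_solvers = 0,
                          seed = 3)
  d <- generate_dataset(cfg, tempfile())
  log <- read_event_log(d$events)
  expect_equal(sum(log$event_type == "door_open"), 0)
})

test_that("large preference concentration pulls preferences to the shared difficulty weights", {
  w <- c(S = 0.295, H = 0.269, V = 0.262, R = 0.174)
  w <- w[latch_alphabet()]
  cfg_tight <- synthetic_config(n_individuals = 200,
                                preference_concentration = 5000, seed = 8)
  th <- as.matrix(generate_population(cfg_tight)$traits[
    , paste0("theta_", latch_alphabet())])
  expect_lt(max(abs(sweep(th, 2, w / sum(w)))), 0.05)
  # small concentration: individuals deviate strongly
  cfg_loose <- synthetic_config(n_individuals = 200,
                                preference_concentration = 1, seed = 8)
  th2 <- as.matrix(generate_population(cfg_loose)$traits[
    , paste0("theta_", latch_alphabet())])
  expect_gt(max(abs(sweep(th2, 2, w / sum(w)))), 0.3)
})

test_that("full stickiness yields single-latch trials of zero complexity", {
  cfg <- synthetic_config(n_individuals = 12, nights = 3, stickiness = 1,
                          p_competitive = 0, prop_naive_solvers = 0,
                          openings_per_trial = 4:6, seed = 14)
  d <- generate_dataset(cfg, tempfile())
  log <- read_event_log(d$events)
  tr <- segment_trials(log)
  seqs <- tr$sequence[tr$n_openings > 0]
  expect_gt(length(seqs), 0)
  for (s in seqs) {
    expect_length(unique(strsplit(s, "")[[1]]), 1L)
    expect_identical(complexity_index(s)$C, 0)
  }
})

test_that("zero learning slope keeps work times stationary across experience", {
  cfg0 <- synthetic_config(n_individuals = 20, nights = 8,
                           learning_slope = 0, prop_solvers = 0.5,
                           seed = 6)
  d <- generate_dataset(cfg0, tempfile())
  op <- trial_openings(segment_trials(read_event_log(d$events)))
  half <- stats::median(op$door_number)
  early <- log(op$work_time_s[op$door_number <= half])
  late <- log(op$work_time_s[op$door_number > half])
  # log-normal with constant meanlog: no experience effect
  expect_lt(abs(mean(early) - mean(late)), 0.15)
})

test_that("generated datasets round-trip, agree with solver truth and respect the seed", {
  cfg <- synthetic_config(n_individuals = 15, nights = 4, seed = 77)
  dir1 <- tempfile()
  d1 <- generate_dataset(cfg, dir1)
  expect_silent(log <- read_event_log(d1$events))
  roster <- read_roster(d1$individuals)
  expect_equal(nrow(roster), 15)
  # solver truth matches the classifier (enough openings guarantee the
  # three-door criterion for every simulated solver)
  tr <- segment_trials(log)
  sv <- classify_solvers(tr)
  expect_setequal(sv$individual_id[sv$is_solver],
                  unlist(d1$truth_data$solver_ids))
  # same seed, byte-identical files
  dir2 <- tempfile()
  generate_dataset(cfg, dir2)
  expect_identical(readLines(file.path(dir1, "events.csv")),
                   readLines(file.path(dir2, "events.csv")))
  expect_identical(readLines(file.path(dir1, "truth.json")),
                   readLines(file.path(dir2, "truth.json")))
  # different seed: different log, identical schema
  d3 <- generate_dataset(synthetic_config(n_individuals = 15, nights = 4,
                                          seed = 78), tempfile())
  e1 <- utils::read.csv(d1$events)
  e3 <- utils::read.csv(d3$events)
  expect_identical(names(e1), names(e3))
  expect_false(identical(e1, e3))
})

test_that("adding nights never perturbs earlier nights", {
  cfg_short <- synthetic_config(n_individuals = 10, nights = 2, seed = 5)
  cfg_long <- synthetic_config(n_individuals = 10, nights = 4, seed = 5)
  d_s <- generate_dataset(cfg_short, tempfile())
  d_l <- generate_dataset(cfg_long, tempfile())
  e_s <- utils::read.csv(d_s$events, stringsAsFactors = FALSE)
  e_l <- utils::read.csv(d_l$events, stringsAsFactors = FALSE)
  expect_identical(e_s, e_l[e_l$night_id %in% c("N01", "N02"), ,
                            drop = FALSE])
})
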