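# Seeded generator of synthetic event logs and rosters. The generative
# model is this module's own construction: Dirichlet per-individual latch
# preferences, sticky (Markovian) latch switching, power-sharpening of
# preferences under competition, log-normal work times with a learning
# decline, and non-solver scrounging presence. All latent parameters are
# exported to truth.json so recovery tests are self-describing.

#' Configuration of the synthetic event-log generator
#'
#' Bundles and validates every parameter of the generative model.
#'
#' @param n_individuals number of individuals in the population.
#' @param prop_juvenile proportion of juveniles.
#' @param prop_solvers probability an individual is a solver.
#' @param preference_concentration Dirichlet concentration \eqn{\alpha}
#'   of per-individual latch preferences; preferences are drawn
#'   \eqn{\theta_i \sim Dirichlet(\alpha \cdot w)} with \eqn{w} the
#'   shared latch-difficulty weights. Small values give strongly
#'   individual preferences; as \eqn{\alpha \to \infty} everyone shares
#'   \eqn{w}.
#' @param stickiness probability \eqn{\kappa} of repeating the previous
#'   latch type at each opening (otherwise a fresh draw from the
#'   preference vector).
#' @param competition_sharpening \eqn{\tau \in (0, 1]}: during
#'   competitive trials preferences are raised to the power
#'   \eqn{1/\tau} and renormalised, so \eqn{\tau < 1} sharpens
#'   individual preference (more self-similar under competition) and
#'   \eqn{\tau = 1} leaves behaviour unchanged.
#' @param learning_slope \eqn{\lambda \ge 0}: per-opening decline of the
#'   expected log work time.
#' @param nights number of testing nights.
#' @param trials_per_night integer support from which each solver's
#'   nightly trial count is drawn uniformly.
#' @param openings_per_trial integer support for openings per trial.
#' @param p_competitive probability a solver bout is staged as
#'   competitive (a second solver overlaps; requires >= 2 solvers).
#' @param prop_naive_solvers proportion of solvers with a naive profile:
#'   they start with a single-latch repertoire that expands by one latch
#'   every \code{repertoire_growth} trials. The rest are "knowledgeable"
#'   (full repertoire from the start).
#' @param repertoire_growth trials per repertoire expansion for naive
#'   solvers; the default 3 mirrors a second latch type typically being
#'   learned within the first few visits.
#' @param latch_difficulty positive weights over the alphabet; easier
#'   latches get larger weights and hence higher expected preference.
#' @param work_time_log_mean,work_time_log_sd log-normal work-time
#'   parameters at zero experience (seconds scale).
#' @param site_id,box_id site and box labels.
#' @param start_year calendar year of the first night.
#' @param seed integer RNG seed; the generator derives one sub-stream
#'   per night from it, so earlier nights are unchanged when nights are
#'   added.
#' @return List of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_individuals = 30L,
                             prop_juvenile = 0.45,
                             prop_solvers = 0.25,
                             preference_concentration = 4,
                             stickiness = 0.3,
                             competition_sharpening = 0.5,
                             learning_slope = 0.02,
                             nights = 10L,
                             trials_per_night = 1:3,
                             openings_per_trial = 6:12,
                             p_competitive = 0.4,
                             prop_naive_solvers = 0.5,
                             repertoire_growth = 3L,
                             latch_difficulty = c(S = 0.295, H = 0.269,
                                                  V = 0.262, R = 0.174),
                             work_time_log_mean = log(20),
                             work_time_log_sd = 0.8,
                             site_id = "site1",
                             box_id = "1",
                             start_year = 2016L,
                             seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              prop_juvenile = prop_juvenile,
              prop_solvers = prop_solvers,
              preference_concentration = preference_concentration,
              stickiness = stickiness,
              competition_sharpening = competition_sharpening,
              learning_slope = learning_slope,
              nights = as.integer(nights),
              trials_per_night = as.integer(trials_per_night),
              openings_per_trial = as.integer(openings_per_trial),
              p_competitive = p_competitive,
              prop_naive_solvers = prop_naive_solvers,
              repertoire_growth = as.integer(repertoire_growth),
              latch_difficulty = latch_difficulty,
              work_time_log_mean = work_time_log_mean,
              work_time_log_sd = work_time_log_sd,
              site_id = site_id, box_id = as.character(box_id),
              start_year = as.integer(start_year),
              seed = as.integer(seed))
  chk <- function(ok, field) {
    if (!isTRUE(ok)) stop("invalid synthetic_config field: ", field,
                          call. = FALSE)
  }
  chk(cfg$n_individuals >= 1L, "n_individuals")
  for (f in c("prop_juvenile", "prop_solvers", "stickiness",
              "p_competitive", "prop_naive_solvers")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  }
  chk(cfg$preference_concentration > 0, "preference_concentration")
  chk(cfg$competition_sharpening > 0 && cfg$competition_sharpening <= 1,
      "competition_sharpening")
  chk(cfg$learning_slope >= 0, "learning_slope")
  chk(cfg$nights >= 1L, "nights")
  chk(length(cfg$trials_per_night) >= 1L && all(cfg$trials_per_night >= 0L),
      "trials_per_night")
  chk(length(cfg$openings_per_trial) >= 1L &&
        all(cfg$openings_per_trial >= 1L), "openings_per_trial")
  chk(cfg$repertoire_growth >= 1L, "repertoire_growth")
  chk(length(cfg$latch_difficulty) == length(latch_alphabet()) &&
        all(cfg$latch_difficulty > 0) &&
        setequal(names(cfg$latch_difficulty), latch_alphabet()),
      "latch_difficulty")
  chk(cfg$work_time_log_sd > 0, "work_time_log_sd")
  class(cfg) <- "synthetic_config"
  cfg
}

night_seed <- function(cfg, night_index) {
  as.integer((abs(cfg$seed) + night_index * 1000003) %% 2147483647)
}

# sample one value from an integer support (safe for length-1 supports)
draw1 <- function(v) v[sample.int(length(v), 1L)]

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha  # numerically degenerate draw
  g / sum(g)
}

#' Generate a synthetic population
#'
#' Draws the roster (id, sex, age, first test year, prior-knowledge
#' profile) and the latent behavioural traits: solver flag, latch
#' preference vector \eqn{\theta_i}, naive/knowledgeable profile and
#' stickiness. Deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return List with \code{roster} (data frame in the individuals.csv
#'   schema plus \code{prior_knowledge}) and \code{traits} (data frame
#'   with \code{solver}, \code{naive}, \code{kappa} and the preference
#'   columns \code{theta_H} ... \code{theta_S}).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  ab <- latch_alphabet()
  n <- cfg$n_individuals
  ids <- sprintf("R%02d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- ifelse(stats::runif(n) < cfg$prop_juvenile, "juvenile", "adult")
  solver <- stats::runif(n) < cfg$prop_solvers
  naive <- rep(TRUE, n)
  naive[solver] <- stats::runif(sum(solver)) < cfg$prop_naive_solvers
  w <- cfg$latch_difficulty[ab]
  w <- w / sum(w)
  theta <- t(vapply(seq_len(n), function(i)
    rdirichlet1(cfg$preference_concentration * w), numeric(length(ab))))
  colnames(theta) <- paste0("theta_", ab)
  roster <- data.frame(individual_id = ids, sex = sex, age = age,
                       first_test_year = cfg$start_year,
                       prior_knowledge = ifelse(solver & !naive,
                                                "knowledgeable", "naive"),
                       stringsAsFactors = FALSE)
  traits <- data.frame(individual_id = ids, solver = solver, naive = naive,
                       kappa = cfg$stickiness, stringsAsFactors = FALSE)
  traits <- cbind(traits, as.data.frame(theta))
  list(roster = roster, traits = traits)
}

# Preference vector restricted to the current repertoire and optionally
# sharpened for competition; returns a named probability vector.
effective_prefs <- function(theta, repertoire, competitive, tau) {
  p <- theta[repertoire]
  if (competitive && tau < 1) p <- p^(1 / tau)
  p / sum(p)
}

# Repertoire of a solver before its (n_prior + 1)-th trial:
# knowledgeable solvers know every latch from the start; naive solvers
# unlock latches in order of their own preference, one more every
# `growth` trials.
current_repertoire <- function(theta, naive, n_prior_trials, growth) {
  ab <- names(theta)
  if (!naive) return(ab)
  size <- min(length(ab), 1L + n_prior_trials %/% growth)
  ab[order(theta, decreasing = TRUE)][seq_len(size)]
}

# Sticky Markov draw of a trial's latch sequence over a fixed
# repertoire. `remaining` (named, over the alphabet) caps how often each
# latch can still be opened in the current bait cycle (six doors per
# mechanism on the box); the chain is forced off a latch whose doors are
# exhausted.
draw_trial_sequence <- function(theta, repertoire, kappa, competitive,
                                tau, n_open, remaining = NULL) {
  ab <- names(theta)
  if (is.null(remaining)) {
    remaining <- stats::setNames(rep(Inf, length(ab)), ab)
  }
  out <- character(n_open)
  prev <- NULL
  for (j in seq_len(n_open)) {
    avail <- ab[remaining[ab] > 0]
    choice <- intersect(repertoire, avail)
    # no door of any known latch type left closed: the animal cannot
    # open anything more this cycle, so the trial's openings end here
    if (length(choice) == 0L) break
    p <- effective_prefs(theta, choice, competitive, tau)
    if (!is.null(prev) && prev %in% choice && stats::runif(1) < kappa) {
      out[j] <- prev
    } else {
      out[j] <- if (length(choice) == 1L) choice else
        sample(names(p), 1L, prob = p)
    }
    remaining[out[j]] <- remaining[out[j]] - 1
    prev <- out[j]
  }
  out[nzchar(out)]
}

# door ids grouped by latch type: doors 1-6 are S, 7-12 H, 13-18 V,
# 19-24 R (six doors per mechanism, as on the physical box)
door_for_latch <- function(latch, open_doors) {
  base <- c(S = 0L, H = 6L, V = 12L, R = 18L)[latch]
  candidates <- setdiff(base + 1:6, open_doors)
  if (length(candidates) == 0L) candidates <- base + 1:6
  candidates[1L]
}

#' Simulate one testing night
#'
#' Stages a night as a series of bouts: each bout starts with a rebait,
#' then either a single solver visits alone (unrestricted) or a second
#' solver arrives first and overlaps the focal (competitive). Openings
#' follow a sticky Markov chain on the individual's (possibly
#' competition-sharpened) preferences; work times are log-normal with a
#' mean declining in cumulative experience; non-solvers and a few
#' unidentified animals contribute detection-only visits (scrounging
#' presence). Bouts are separated by gaps long enough that consecutive
#' visits by the same individual segment into separate trials.
#'
#' @param population output of [generate_population()].
#' @param night_index 1-based night number (drives the per-night RNG
#'   sub-stream and the calendar date).
#' @param cfg a [synthetic_config()].
#' @param state optional list carrying per-individual cumulative opening
#'   counts between nights (as returned by a previous call).
#' @return List with \code{events} (data frame in the events.csv
#'   schema) and \code{state}.
#' @export
simulate_night <- function(population, night_index, cfg, state = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(night_seed(cfg, night_index))
  ab <- latch_alphabet()
  tr <- population$traits
  if (is.null(state)) {
    state <- list(cum = stats::setNames(rep(0L, nrow(tr)),
                                        tr$individual_id),
                  ntrials = stats::setNames(rep(0L, nrow(tr)),
                                            tr$individual_id))
  }
  night_id <- sprintf("N%02d", night_index)
  base <- as.POSIXct(sprintf("%d-08-01 21:00:00", cfg$start_year),
                     tz = "UTC") + (night_index - 1) * 86400
  solver_ids <- tr$individual_id[tr$solver]
  rows <- list()
  add <- function(t, id, type, door = NA_integer_, latch = NA_character_,
                  wt = NA_real_, ed = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      timestamp = base + t, site_id = cfg$site_id, box_id = cfg$box_id,
      night_id = night_id, individual_id = id, event_type = type,
      door_id = door, latch_type = latch, work_time_s = wt,
      exploratory_diversity = ed, stringsAsFactors = FALSE)
  }
  t <- 0
  # solver bouts
  bouts <- list()
  for (id in solver_ids) {
    k <- draw1(cfg$trials_per_night)
    if (k > 0L) for (b in seq_len(k)) {
      competitive <- length(solver_ids) >= 2L &&
        stats::runif(1) < cfg$p_competitive
      partner <- if (competitive) {
        sample(setdiff(solver_ids, id), 1L)
      } else NA_character_
      bouts[[length(bouts) + 1L]] <- list(focal = id, partner = partner)
    }
  }
  if (length(bouts) > 1L) bouts <- bouts[sample.int(length(bouts))]
  emit_openings <- function(id, t0, n_open, competitive, open_doors) {
    i <- match(id, tr$individual_id)
    theta <- stats::setNames(as.numeric(tr[i, paste0("theta_", ab)]), ab)
    cum <- state$cum[[id]]
    remaining <- stats::setNames(rep(6, length(ab)), ab)
    if (length(open_doors) > 0L) {
      blk <- c("S", "H", "V", "R")[findInterval(open_doors, c(1, 7, 13, 19))]
      used <- table(factor(blk, levels = ab))
      remaining <- remaining - as.numeric(used[ab])
    }
    rep_now <- current_repertoire(theta, tr$naive[i],
                                  state$ntrials[[id]],
                                  cfg$repertoire_growth)
    seq_l <- draw_trial_sequence(theta, rep_now, tr$kappa[i],
                                 competitive, cfg$competition_sharpening,
                                 n_open, remaining = remaining)
    tt <- t0
    for (j in seq_along(seq_l)) {
      wt <- stats::rlnorm(1, cfg$work_time_log_mean -
                            cfg$learning_slope * (cum + j - 1L),
                          cfg$work_time_log_sd)
      ed <- 1L + stats::rpois(1, exp(log(5) - 0.02 * (cum + j - 1L)))
      door <- door_for_latch(seq_l[j], open_doors)
      open_doors <- c(open_doors, door)
      add(tt, id, "door_open", door = door, latch = seq_l[j],
          wt = round(wt, 1), ed = ed)
      tt <- tt + stats::runif(1, 20, 45)
    }
    state$cum[[id]] <<- state$cum[[id]] + length(seq_l)
    state$ntrials[[id]] <<- state$ntrials[[id]] + 1L
    list(t_end = tt, open_doors = open_doors)
  }
  for (b in bouts) {
    add(t, NA_character_, "rebait")
    open_doors <- integer(0)
    if (!is.na(b$partner)) {
      # partner arrives first and opens a few doors; the focal arrives
      # while the partner is still working, so each has an event inside
      # the other's trial window and both trials classify as competitive
      add(t + 10, b$partner, "detection")
      res_p <- emit_openings(b$partner, t + 15,
                             draw1(2:4), TRUE, open_doors)
      open_doors <- res_p$open_doors
      add(t + 30, b$focal, "detection")
      res_f <- emit_openings(b$focal, t + 45,
                             draw1(cfg$openings_per_trial), TRUE,
                             open_doors)
      t <- max(res_p$t_end, res_f$t_end) + 150
    } else {
      add(t + 15, b$focal, "detection")
      res_f <- emit_openings(b$focal, t + 25,
                             draw1(cfg$openings_per_trial), FALSE,
                             open_doors)
      t <- res_f$t_end + 150
    }
  }
  # non-solver scrounging visits and the odd unidentified animal
  non_solvers <- tr$individual_id[!tr$solver]
  for (id in non_solvers) {
    n_visits <- sample(0:2, 1L)
    if (n_visits > 0L) for (v in seq_len(n_visits)) {
      tv <- stats::runif(1, 0, max(t, 600))
      ed <- 1L + stats::rpois(1, 2)
      add(tv, id, "detection", ed = ed)
      add(tv + stats::runif(1, 10, 40), id, "detection")
    }
  }
  if (stats::runif(1) < 0.5) {
    tv <- stats::runif(1, 0, max(t, 600))
    add(tv, "UNKNOWN", "detection")
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$timestamp), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, state = state)
}

#' Generate a full synthetic dataset on disk
#'
#' Simulates every night, writes \code{events.csv} and
#' \code{individuals.csv} in the event-model schemas plus
#' \code{truth.json} recording the full configuration and all latent
#' traits, and returns the paths. Byte-identical across runs with the
#' same config.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with \code{events}, \code{individuals},
#'   \code{truth} (paths) and \code{truth_data} (the truth list).
#' @export
generate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pop <- generate_population(cfg)
  state <- NULL
  nights <- vector("list", cfg$nights)
  for (i in seq_len(cfg$nights)) {
    res <- simulate_night(pop, i, cfg, state)
    nights[[i]] <- res$events
    state <- res$state
  }
  events <- do.call(rbind, nights)
  events$timestamp <- format(events$timestamp, TS_FORMAT, tz = "UTC")
  events_path <- file.path(dir, "events.csv")
  roster_path <- file.path(dir, "individuals.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(events, events_path, row.names = FALSE, na = "",
                   quote = FALSE)
  utils::write.csv(pop$roster, roster_path, row.names = FALSE, na = "",
                   quote = FALSE)
  truth <- list(
    model = paste("Dirichlet latch preferences; sticky Markov switching;",
                  "power-sharpened preferences under competition;",
                  "log-normal work times with learning decline"),
    config = unclass(cfg),
    n_solvers = sum(pop$traits$solver),
    solver_ids = pop$traits$individual_id[pop$traits$solver],
    traits = pop$traits,
    cumulative_openings = as.list(state$cum))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(list(events = events_path, individuals = roster_path,
                 truth = truth_path, truth_data = truth))
}
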