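# Event-log plumbing: CSV I/O, trial segmentation, solver and
# social-condition classification, analysis-subset construction.

EVENT_COLS <- c("timestamp", "site_id", "box_id", "night_id",
                "individual_id", "event_type", "door_id", "latch_type",
                "work_time_s", "exploratory_diversity")
EVENT_TYPES <- c("detection", "door_open", "rebait")
TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_timestamps <- function(x) {
  out <- as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
  sp <- is.na(out) & !is.na(x)
  if (any(sp)) {
    out[sp] <- as.POSIXct(x[sp], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  out
}

#' Read a puzzle-box event log
#'
#' Parses a CSV of timestamped records (individual detections, door
#' openings, re-baiting events) into a validated event log sorted
#' chronologically within each (site, night). Malformed rows raise an
#' error naming the offending line; out-of-order timestamps are sorted
#' with a warning; records without an individual id are retained as
#' \code{"UNKNOWN"} (except rebaits, which carry no individual).
#'
#' @param path CSV file with columns \code{timestamp} (ISO 8601),
#'   \code{site_id}, \code{box_id}, \code{night_id},
#'   \code{individual_id}, \code{event_type} (\code{detection},
#'   \code{door_open}, \code{rebait}), \code{door_id} (1-24),
#'   \code{latch_type} (\code{H}, \code{R}, \code{V}, \code{S}),
#'   \code{work_time_s}, \code{exploratory_diversity}.
#' @return Data frame of class \code{"event_log"}.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(EVENT_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("event log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, EVENT_COLS]
  line_no <- function(i) i + 1L  # header is line 1
  bad_row <- function(rows, what) {
    stop("malformed event log row (", what, ") at line(s) ",
         paste(line_no(utils::head(rows, 5L)), collapse = ", "),
         if (length(rows) > 5L) " ..." else "", call. = FALSE)
  }
  ts <- parse_timestamps(raw$timestamp)
  if (any(is.na(ts))) bad_row(which(is.na(ts)), "unparseable timestamp")
  bad_type <- which(!(raw$event_type %in% EVENT_TYPES))
  if (length(bad_type) > 0L) bad_row(bad_type, "unknown event_type")
  is_open <- raw$event_type == "door_open"
  bad_latch <- which(is_open & !(raw$latch_type %in% latch_alphabet()))
  if (length(bad_latch) > 0L) bad_row(bad_latch, "unknown latch code")
  door <- suppressWarnings(as.integer(raw$door_id))
  bad_door <- which(is_open & (is.na(door) | door < 1L | door > 24L))
  if (length(bad_door) > 0L) bad_row(bad_door, "door_id outside 1-24")
  wt <- suppressWarnings(as.numeric(raw$work_time_s))
  bad_wt <- which(is_open & !is.na(raw$work_time_s) & (is.na(wt) | wt < 0))
  if (length(bad_wt) > 0L) bad_row(bad_wt, "negative or non-numeric work_time_s")
  ed <- suppressWarnings(as.integer(raw$exploratory_diversity))
  log <- data.frame(
    timestamp = ts,
    site_id = raw$site_id,
    box_id = ifelse(is.na(raw$box_id), "1", raw$box_id),
    night_id = raw$night_id,
    individual_id = ifelse(raw$event_type == "rebait", NA_character_,
                           ifelse(is.na(raw$individual_id), "UNKNOWN",
                                  raw$individual_id)),
    event_type = raw$event_type,
    door_id = ifelse(is_open, door, NA_integer_),
    latch_type = ifelse(is_open, raw$latch_type, NA_character_),
    work_time_s = ifelse(is_open, wt, NA_real_),
    exploratory_diversity = ed,
    stringsAsFactors = FALSE)
  ord <- order(log$site_id, log$night_id, log$timestamp)
  if (any(ord != seq_along(ord))) {
    warning("event log rows were not chronological within (site, night); ",
            "sorted", call. = FALSE)
    log <- log[ord, , drop = FALSE]
    rownames(log) <- NULL
  }
  class(log) <- c("event_log", "data.frame")
  log
}

#' Write a puzzle-box event log
#'
#' Inverse of [read_event_log()]: writes the documented CSV schema with
#' ISO 8601 timestamps. Reading the result back preserves all fields.
#'
#' @param log an \code{"event_log"} data frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_event_log <- function(log, path) {
  out <- as.data.frame(log)[, EVENT_COLS]
  out$timestamp <- format(out$timestamp, TS_FORMAT, tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read an individual roster
#'
#' @param path CSV with columns \code{individual_id}, \code{sex}
#'   (\code{male}/\code{female}/\code{unknown}), \code{age}
#'   (\code{adult}/\code{juvenile}/\code{unknown}),
#'   \code{first_test_year}; an optional \code{prior_knowledge} column
#'   (\code{naive}/\code{knowledgeable}, relative to the horizontal
#'   latch) is carried through and defaults to \code{"naive"}.
#' @return Data frame of class \code{"roster"}.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster not found: ", path, call. = FALSE)
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  need <- c("individual_id", "sex", "age", "first_test_year")
  missing_cols <- setdiff(need, names(r))
  if (length(missing_cols) > 0L) {
    stop("roster is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(r$individual_id) > 0L) {
    stop("duplicate individual_id in roster", call. = FALSE)
  }
  r$sex <- ifelse(is.na(r$sex), "unknown", r$sex)
  r$age <- ifelse(is.na(r$age), "unknown", r$age)
  if (!all(r$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be male/female/unknown", call. = FALSE)
  }
  if (!all(r$age %in% c("adult", "juvenile", "unknown"))) {
    stop("age must be adult/juvenile/unknown", call. = FALSE)
  }
  if (!"prior_knowledge" %in% names(r)) r$prior_knowledge <- "naive"
  r$prior_knowledge <- ifelse(is.na(r$prior_knowledge), "naive",
                              r$prior_knowledge)
  class(r) <- c("roster", "data.frame")
  r
}

#' Bin a door's work time into the ordinal scale
#'
#' Work time (seconds an individual spent working to open a door) is
#' analysed as an ordinal variable with four bins: \code{[0, 5)} is bin
#' 1, \code{[5, 16)} bin 2, \code{[16, 31)} bin 3 and \code{[31, Inf)}
#' bin 4. Vectorised; \code{NA} passes through.
#'
#' @param seconds non-negative numeric vector.
#' @return Integer bins 1-4.
#' @export
bin_work_time <- function(seconds) {
  if (any(seconds < 0, na.rm = TRUE)) {
    stop("work time must be non-negative", call. = FALSE)
  }
  out <- rep(NA_integer_, length(seconds))
  ok <- !is.na(seconds)
  out[ok] <- findInterval(seconds[ok], c(0, 5, 16, 31))
  out
}

#' Segment an event log into trials
#'
#' A trial is a single contiguous visit by one individual: within each
#' (site, night), an individual's consecutive events belong to the same
#' trial while the gap between them is below the absence threshold; a
#' gap of at least the threshold (default 60 s, i.e. absence for at
#' least one minute) starts a new trial. Trial indices are assigned
#' chronologically per individual across the whole log, and each trial
#' records the cumulative number of doors the individual opened in
#' strictly earlier trials (\code{doors_opened_to_date}). Events with
#' individual \code{"UNKNOWN"} and rebaits are not segmented.
#'
#' @param log an \code{"event_log"}.
#' @param absence_threshold seconds of absence that separate trials
#'   (> 0); default 60.
#' @return Data frame of class \code{"trial_set"}: one row per trial
#'   with \code{trial_id}, \code{individual_id}, \code{site_id},
#'   \code{box_id}, \code{night_id}, \code{start}, \code{end},
#'   \code{trial_index}, \code{n_events}, \code{n_openings},
#'   \code{sequence} (latch string) and \code{doors_opened_to_date}.
#'   The per-opening detail (door, latch, work time and its bin,
#'   exploratory diversity, trial id) is attached as attribute
#'   \code{"openings"}, retrievable with [trial_openings()].
#' @export
segment_trials <- function(log, absence_threshold = 60) {
  stopifnot(absence_threshold > 0)
  ev <- as.data.frame(log)
  ev <- ev[!is.na(ev$individual_id) & ev$individual_id != "UNKNOWN" &
             ev$event_type != "rebait", , drop = FALSE]
  empty <- data.frame(trial_id = character(0), individual_id = character(0),
                      site_id = character(0), box_id = character(0),
                      night_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      trial_index = integer(0), n_events = integer(0),
                      n_openings = integer(0), sequence = character(0),
                      doors_opened_to_date = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) {
    attr(empty, "openings") <- data.frame()
    class(empty) <- c("trial_set", "data.frame")
    return(empty)
  }
  ev <- ev[order(ev$individual_id, ev$site_id, ev$night_id, ev$timestamp), ,
           drop = FALSE]
  grp <- interaction(ev$individual_id, ev$site_id, ev$night_id, drop = TRUE)
  gap <- c(Inf, as.numeric(diff(ev$timestamp), units = "secs"))
  new_grp <- c(TRUE, grp[-1L] != grp[-length(grp)])
  new_trial <- new_grp | gap >= absence_threshold
  ev$trial_key <- cumsum(new_trial)
  agg <- split(seq_len(nrow(ev)), ev$trial_key)
  trials <- do.call(rbind, lapply(agg, function(idx) {
    e <- ev[idx, , drop = FALSE]
    op <- e[e$event_type == "door_open", , drop = FALSE]
    data.frame(individual_id = e$individual_id[1L],
               site_id = e$site_id[1L], box_id = e$box_id[1L],
               night_id = e$night_id[1L],
               start = min(e$timestamp), end = max(e$timestamp),
               n_events = nrow(e), n_openings = nrow(op),
               sequence = paste(op$latch_type, collapse = ""),
               trial_key = e$trial_key[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(trials) <- NULL
  # chronological trial index and cumulative prior openings per individual
  trials <- trials[order(trials$individual_id, trials$start), , drop = FALSE]
  trials$trial_index <- stats::ave(seq_len(nrow(trials)),
                                   trials$individual_id,
                                   FUN = seq_along)
  trials$doors_opened_to_date <- stats::ave(
    trials$n_openings, trials$individual_id,
    FUN = function(n) cumsum(c(0L, n[-length(n)])))
  trials$trial_id <- paste0(trials$individual_id, "-T",
                            sprintf("%03d", trials$trial_index))
  trials <- trials[order(trials$start, trials$individual_id), , drop = FALSE]
  rownames(trials) <- NULL
  openings <- ev[ev$event_type == "door_open", , drop = FALSE]
  openings$trial_id <- trials$trial_id[match(openings$trial_key,
                                             trials$trial_key)]
  openings$work_time_bin <- bin_work_time(openings$work_time_s)
  openings$trial_key <- NULL
  openings <- openings[order(openings$individual_id, openings$timestamp), ,
                       drop = FALSE]
  openings$door_number <- stats::ave(seq_len(nrow(openings)),
                                     openings$individual_id,
                                     FUN = seq_along)
  rownames(openings) <- NULL
  trials$trial_key <- NULL
  trials <- trials[, names(empty), drop = FALSE]
  attr(trials, "openings") <- openings
  class(trials) <- c("trial_set", "data.frame")
  trials
}

#' Per-opening detail of a trial set
#'
#' @param trials a \code{"trial_set"} from [segment_trials()].
#' @return Data frame of door-opening events with \code{trial_id},
#'   \code{work_time_bin} and per-individual cumulative
#'   \code{door_number}.
#' @export
trial_openings <- function(trials) {
  op <- attr(trials, "openings")
  if (is.null(op)) stop("trial set carries no opening detail", call. = FALSE)
  op
}

#' Classify solvers from a trial set
#'
#' An individual demonstrated innovation on a latch type once it opened
#' at least \code{min_doors} (default 3) doors of that type across all
#' of its trials; a solver solved at least one latch type, and a
#' flexible solver at least two.
#'
#' @param trials a \code{"trial_set"}.
#' @param min_doors doors of one latch type required to count it as
#'   solved; default 3.
#' @return Data frame of class \code{"solver_status"}: one row per
#'   individual with per-latch counts (\code{n_H}, \code{n_R},
#'   \code{n_V}, \code{n_S}), \code{solved_latches} (string),
#'   \code{n_latches_solved}, \code{is_solver}, \code{is_flexible}.
#' @export
classify_solvers <- function(trials, min_doors = 3) {
  ab <- latch_alphabet()
  ids <- sort(unique(trials$individual_id))
  counts <- matrix(0L, length(ids), length(ab),
                   dimnames = list(ids, ab))
  if (nrow(trials) > 0L) {
    op <- trial_openings(trials)
    if (nrow(op) > 0L) {
      tab <- table(factor(op$individual_id, levels = ids),
                   factor(op$latch_type, levels = ab))
      counts <- matrix(as.integer(tab), nrow = length(ids),
                       dimnames = dimnames(counts))
    }
  }
  solved <- counts >= min_doors
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (l in ab) out[[paste0("n_", l)]] <- counts[, l]
  out$solved_latches <- if (nrow(out) == 0L) character(0) else
    apply(solved, 1L, function(z) paste(ab[z], collapse = ""))
  out$n_latches_solved <- rowSums(solved)
  out$is_solver <- out$n_latches_solved >= 1L
  out$is_flexible <- out$n_latches_solved >= 2L
  rownames(out) <- NULL
  class(out) <- c("solver_status", "data.frame")
  out
}

#' Track per-event box state
#'
#' Walks each (site, box, night) chronologically, maintaining the set of
#' currently open doors: the box starts the night all-closed, door
#' openings add doors, and every rebait resets the box to all-closed and
#' begins a new bait cycle. A \code{door_open} for an already-open door
#' leaves the state unchanged with a warning.
#'
#' @param log an \code{"event_log"}.
#' @return The log with columns appended: \code{bait_cycle} (integer,
#'   increments at every rebait within a site/box/night),
#'   \code{doors_open_before} (count of open doors just before the
#'   event) and \code{box_unopened_before} (logical).
#' @export
track_box_state <- function(log) {
  ev <- as.data.frame(log)
  ev$.row <- seq_len(nrow(ev))
  ev <- ev[order(ev$site_id, ev$box_id, ev$night_id, ev$timestamp, ev$.row), ,
           drop = FALSE]
  grp <- interaction(ev$site_id, ev$box_id, ev$night_id, drop = TRUE)
  ev$bait_cycle <- NA_integer_
  ev$doors_open_before <- NA_integer_
  dup <- integer(0)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    open <- integer(0)
    cycle <- 1L
    for (i in idx) {
      ev$bait_cycle[i] <- cycle
      ev$doors_open_before[i] <- length(open)
      if (ev$event_type[i] == "rebait") {
        open <- integer(0)
        cycle <- cycle + 1L
        ev$bait_cycle[i] <- cycle   # rebait opens the next cycle
        ev$doors_open_before[i] <- 0L
      } else if (ev$event_type[i] == "door_open") {
        if (ev$door_id[i] %in% open) {
          dup <- c(dup, i)
        } else {
          open <- c(open, ev$door_id[i])
        }
      }
    }
  }
  if (length(dup) > 0L) {
    warning("door_open recorded for already-open door(s) in ",
            length(dup), " event(s); state unchanged", call. = FALSE)
  }
  ev$box_unopened_before <- ev$doors_open_before == 0L
  ev <- ev[order(ev$.row), , drop = FALSE]
  ev$.row <- NULL
  rownames(ev) <- NULL
  class(ev) <- c("event_log", "data.frame")
  ev
}

#' Classify the social condition of each trial
#'
#' A trial is \emph{unrestricted} when the focal individual was the
#' first solver to arrive at an unopened (freshly baited) box and was
#' not joined by another solver at any point during the trial; any other
#' solver trial is \emph{competitive} (another solver present and/or the
#' focal was not first, so the box may have been partially solved).
#' Presence is inferred from temporal overlap of logged events. Trials
#' by non-solvers receive the same labels but are flagged by
#' \code{is_solver = FALSE} and excluded from sequence analyses
#' downstream.
#'
#' @param trials a \code{"trial_set"}.
#' @param log the \code{"event_log"} the trials came from.
#' @param solvers a \code{"solver_status"} from [classify_solvers()].
#' @param unknown_counts_as_competitor should events by unidentified
#'   individuals count as competitor presence? Default \code{FALSE}
#'   (the condition definition names solvers).
#' @return The trial set with columns appended: \code{is_solver},
#'   \code{box_unopened_at_start}, \code{first_arrival} (first solver
#'   to arrive in the bait cycle, box unopened), \code{joined_by_solver}
#'   and \code{condition} (\code{"unrestricted"}/\code{"competitive"}).
#' @export
classify_condition <- function(trials, log, solvers,
                               unknown_counts_as_competitor = FALSE) {
  ann <- track_box_state(log)
  solver_ids <- solvers$individual_id[solvers$is_solver]
  comp_ids <- solver_ids
  is_comp_event <- ann$individual_id %in% comp_ids |
    (unknown_counts_as_competitor &
       !is.na(ann$individual_id) & ann$individual_id == "UNKNOWN")
  trials$is_solver <- trials$individual_id %in% solver_ids
  n <- nrow(trials)
  trials$box_unopened_at_start <- rep(NA, n)
  trials$first_arrival <- rep(NA, n)
  trials$joined_by_solver <- rep(NA, n)
  for (i in seq_len(n)) {
    tr <- trials[i, ]
    in_group <- ann$site_id == tr$site_id & ann$box_id == tr$box_id &
      ann$night_id == tr$night_id
    focal_start <- which(in_group & ann$timestamp == tr$start &
                           !is.na(ann$individual_id) &
                           ann$individual_id == tr$individual_id)[1L]
    cyc <- ann$bait_cycle[focal_start]
    unopened <- ann$box_unopened_before[focal_start]
    earlier_other <- any(in_group & ann$bait_cycle == cyc &
                           is_comp_event &
                           ann$individual_id != tr$individual_id &
                           ann$timestamp < tr$start, na.rm = TRUE)
    overlap <- any(in_group & is_comp_event &
                     ann$individual_id != tr$individual_id &
                     ann$timestamp >= tr$start & ann$timestamp <= tr$end,
                   na.rm = TRUE)
    trials$box_unopened_at_start[i] <- unopened
    trials$first_arrival[i] <- unopened && !earlier_other
    trials$joined_by_solver[i] <- overlap
  }
  trials$condition <- ifelse(
    trials$box_unopened_at_start & trials$first_arrival &
      !trials$joined_by_solver,
    "unrestricted", "competitive")
  trials
}

#' Extract qualifying latch sequences for the sequence analyses
#'
#' One sequence per qualifying trial: by default only solver trials with
#' at least \code{min_length} openings, by individuals that had already
#' opened at least \code{min_doors_to_date} doors before the trial
#' began (so not-yet-qualified solving is excluded), restricted to each
#' individual's first test year, and optionally restricted by social
#' condition.
#'
#' @param trials a condition-classified \code{"trial_set"}.
#' @param solvers a \code{"solver_status"}.
#' @param min_length minimum openings per sequence; default 6.
#' @param min_doors_to_date minimum prior cumulative openings; default 6.
#' @param condition \code{"unrestricted"}, \code{"competitive"} or
#'   \code{"both"} (default).
#' @param first_year_only restrict to each individual's first year of
#'   testing (from trial start dates)? Default \code{TRUE}.
#' @param solver_only restrict to solvers? Default \code{TRUE}.
#' @return Data frame with \code{individual_id}, \code{trial_index},
#'   \code{condition}, \code{sequence}, \code{n} (sequence length).
#' @export
extract_latch_sequences <- function(trials, solvers, min_length = 6,
                                    min_doors_to_date = 6,
                                    condition = c("both", "unrestricted",
                                                  "competitive"),
                                    first_year_only = TRUE,
                                    solver_only = TRUE) {
  condition <- match.arg(condition)
  if (!"condition" %in% names(trials)) {
    stop("trials must be condition-classified first", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(trials))
  if (solver_only) {
    keep <- keep & trials$individual_id %in%
      solvers$individual_id[solvers$is_solver]
  }
  keep <- keep & trials$n_openings >= min_length
  keep <- keep & trials$doors_opened_to_date >= min_doors_to_date
  if (condition != "both") keep <- keep & trials$condition == condition
  if (first_year_only && nrow(trials) > 0L) {
    yr <- as.integer(format(trials$start, "%Y"))
    first_yr <- stats::ave(yr, trials$individual_id, FUN = min)
    keep <- keep & yr == first_yr
  }
  out <- trials[keep, c("individual_id", "trial_index", "condition",
                        "sequence"), drop = FALSE]
  out$n <- nchar(out$sequence)
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    message("no trials satisfy the sequence filters (min_length = ",
            min_length, ", min_doors_to_date = ", min_doors_to_date,
            ", condition = ", condition, ")")
  }
  out
}

#' Final-trials subset for latch-preference tests
#'
#' For each solver, takes the last \code{k} chronological trials with at
#' least one opening in which the solver was the first individual to
#' arrive (all doors available), and tabulates the first-opened latch
#' and the total latch counts across the subset. These counts feed the
#' chi-squared tests of latch preference. A solver with fewer than
#' \code{k} qualifying trials contributes all it has, with a warning.
#'
#' @param trials a condition-classified \code{"trial_set"}.
#' @param solvers a \code{"solver_status"}.
#' @param k trials per solver; default 5.
#' @param require_first_arrival require the first-arrival flag? Default
#'   \code{TRUE}.
#' @return List of class \code{"final_trials"}: \code{trials} (the
#'   subset), \code{first_latch_counts} and \code{total_latch_counts}
#'   (named counts over the alphabet).
#' @export
final_trials_subset <- function(trials, solvers, k = 5,
                                require_first_arrival = TRUE) {
  ab <- latch_alphabet()
  solver_ids <- solvers$individual_id[solvers$is_solver]
  sub <- trials[trials$individual_id %in% solver_ids &
                  trials$n_openings >= 1L, , drop = FALSE]
  if (require_first_arrival) {
    if (!"first_arrival" %in% names(sub)) {
      stop("trials must be condition-classified first", call. = FALSE)
    }
    sub <- sub[sub$first_arrival, , drop = FALSE]
  }
  picked <- do.call(rbind, lapply(split(sub, sub$individual_id),
                                  function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < k) {
      warning("solver ", d$individual_id[1L], " has only ", nrow(d),
              " qualifying trial(s); using all", call. = FALSE)
    }
    utils::tail(d, k)
  }))
  if (is.null(picked)) picked <- sub
  rownames(picked) <- NULL
  first_latch <- substr(picked$sequence, 1L, 1L)
  all_latch <- unlist(strsplit(picked$sequence, "", fixed = TRUE))
  res <- list(
    trials = picked,
    first_latch_counts = as.integer(table(factor(first_latch, levels = ab))),
    total_latch_counts = as.integer(table(factor(all_latch, levels = ab))))
  names(res$first_latch_counts) <- ab
  names(res$total_latch_counts) <- ab
  class(res) <- "final_trials"
  res
}

#' @export
print.final_trials <- function(x, ...) {
  cat(sprintf("final-trials subset: %d trials from %d solver(s)\n",
              nrow(x$trials), length(unique(x$trials$individual_id))))
  cat("first-opened latch counts:\n")
  print(x$first_latch_counts)
  cat("total latch counts:\n")
  print(x$total_latch_counts)
  invisible(x)
}
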