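# In-code fixture builders: tiny event logs assembled row by row and
# written to temp CSVs in the documented schema.

BASE_T <- as.POSIXct("2016-08-01 21:00:00", tz = "UTC")

ev_row <- function(t, id, type = "door_open", latch = NA_character_,
                   door = NA_integer_, site = "A", box = "1",
                   night = "N1", wt = NA_real_, ed = NA_integer_,
                   day = match(night, paste0("N", 1:9)) - 1L) {
  if (type == "door_open" && is.na(door)) {
    door <- c(H = 7L, R = 19L, V = 13L, S = 1L)[latch]
  }
  if (is.na(day)) day <- 0L
  data.frame(timestamp = format(BASE_T + day * 86400 + t,
                                "%Y-%m-%dT%H:%M:%S"),
             site_id = site, box_id = box, night_id = night,
             individual_id = if (type == "rebait") NA_character_ else id,
             event_type = type, door_id = door, latch_type = latch,
             work_time_s = wt, exploratory_diversity = ed,
             stringsAsFactors = FALSE)
}

# openings need distinct doors within a bait cycle; cycle doors through
# each latch block
ev_openings <- function(t0, id, latches, gap = 30, ...) {
  used <- c(H = 0L, R = 0L, V = 0L, S = 0L)
  base <- c(S = 0L, H = 6L, V = 12L, R = 18L)
  do.call(rbind, lapply(seq_along(latches), function(j) {
    l <- latches[j]
    used[l] <<- used[l] + 1L
    ev_row(t0 + (j - 1) * gap, id, "door_open", latch = l,
           door = base[[l]] + used[[l]], ...)
  }))
}

write_events_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

write_roster_csv <- function(ids, path = tempfile(fileext = ".csv"),
                             sex = "female", age = "adult", year = 2016,
                             prior = NULL) {
  r <- data.frame(individual_id = ids, sex = sex, age = age,
                  first_test_year = year, stringsAsFactors = FALSE)
  if (!is.null(prior)) r$prior_knowledge <- prior
  utils::write.csv(r, path, row.names = FALSE, na = "")
  path
}

# a small but complete log: two solvers plus a non-solver across two
# nights, with rebaits; individual A unrestricted in cycle 1, B arrives
# later overlapping A in cycle 2
two_solver_log <- function() {
  rows <- rbind(
    ev_row(0, NA, "rebait"),
    ev_row(10, "A", "detection", ed = 5L),
    ev_openings(20, "A", c("S", "S", "S", "H", "H", "H"), wt = 12),
    # 200s gap -> new trial for A; B overlaps it
    ev_row(400, NA, "rebait"),
    ev_row(410, "A", "detection"),
    ev_openings(420, "A", c("S", "V", "S", "V", "V", "S"), wt = 8),
    ev_row(430, "B", "detection", ed = 3L),
    ev_openings(445, "B", c("H", "H", "H", "R", "R", "R"), wt = 20),
    # night 2: B alone on a fresh box
    ev_row(0, NA, "rebait", night = "N2"),
    ev_row(15, "B", "detection", night = "N2"),
    ev_openings(25, "B", c("R", "H", "R", "H", "H", "R"), night = "N2",
                wt = 5),
    # C only scrounges
    ev_row(900, "C", "detection", night = "N2", ed = 2L),
    ev_row(920, "C", "detection", night = "N2"))
  rows <- rows[order(rows$night_id, rows$timestamp), ]
  write_events_csv(rows)
}
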