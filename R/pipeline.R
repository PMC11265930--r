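# End-to-end orchestration: declarative configuration, file-based
# stages (segment, classify, sequences, complexity, distances, stats,
# report) and a thin command-line front end. run_pipeline() chains the
# same stage functions the CLI exposes, so running the stages by hand
# yields identical artifacts.

#' Pipeline configuration
#'
#' Bundles the input paths, output directory and every analysis
#' threshold. The defaults are the study profile: trials split by one
#' minute of absence, three same-latch doors to qualify as a solver,
#' sequences of at least six openings by individuals with at least six
#' prior openings, the final five first-arrival trials per solver for
#' the latch-preference tests, indel cost 1 with transition-rate
#' substitution costs pooled over all analysed sequences, and
#' normalisation by the longer sequence length.
#'
#' @param events path to events.csv.
#' @param individuals path to individuals.csv.
#' @param out_dir output directory for every artifact.
#' @param absence_threshold seconds separating trials; default 60.
#' @param solver_min_doors same-latch doors to count a latch as solved.
#' @param min_sequence_length minimum openings per analysed sequence.
#' @param min_doors_to_date minimum prior openings before a trial
#'   qualifies.
#' @param final_trials_k trials per solver in the preference subset.
#' @param normalization \code{"longest"}, \code{"sum"} or \code{"none"}.
#' @param cost_pooling \code{"pooled"} (substitution costs estimated
#'   from all analysed sequences) or \code{"per_condition"}.
#' @param indel insertion/deletion cost.
#' @param c_val substitution-cost constant.
#' @param first_year_only restrict sequences to each individual's first
#'   test year?
#' @param unknown_counts_as_competitor treat unidentified animals as
#'   competitors when labelling conditions?
#' @param block_size trials per block for complexity medians.
#' @param seed stamped into the report (the analysis itself is
#'   deterministic).
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(events, individuals, out_dir,
                            absence_threshold = 60,
                            solver_min_doors = 3,
                            min_sequence_length = 6,
                            min_doors_to_date = 6,
                            final_trials_k = 5,
                            normalization = c("longest", "sum", "none"),
                            cost_pooling = c("pooled", "per_condition"),
                            indel = 1,
                            c_val = 2,
                            first_year_only = TRUE,
                            unknown_counts_as_competitor = FALSE,
                            block_size = 3,
                            seed = 1L) {
  cfg <- list(events = events, individuals = individuals,
              out_dir = out_dir,
              absence_threshold = absence_threshold,
              solver_min_doors = solver_min_doors,
              min_sequence_length = min_sequence_length,
              min_doors_to_date = min_doors_to_date,
              final_trials_k = final_trials_k,
              normalization = match.arg(normalization),
              cost_pooling = match.arg(cost_pooling),
              indel = indel, c_val = c_val,
              first_year_only = isTRUE(first_year_only),
              unknown_counts_as_competitor =
                isTRUE(unknown_counts_as_competitor),
              block_size = as.integer(block_size),
              seed = as.integer(seed))
  for (f in c("absence_threshold", "solver_min_doors",
              "min_sequence_length", "min_doors_to_date",
              "final_trials_k", "indel", "c_val", "block_size")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("pipeline_config field must be positive: ", f, call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# stable fingerprint of the analysis parameters (I/O paths excluded so
# the same analysis on the same data hashes identically wherever it
# runs); polynomial rolling hash kept within 31 bits
config_hash <- function(cfg) {
  par <- unclass(cfg)
  par[c("events", "individuals", "out_dir")] <- NULL
  s <- paste(deparse(par), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

log_line <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
}

# ---- internal stage helpers -------------------------------------------

classified_trials <- function(cfg) {
  log <- read_event_log(cfg$events)
  trials <- segment_trials(log, cfg$absence_threshold)
  solvers <- classify_solvers(trials, cfg$solver_min_doors)
  trials <- classify_condition(trials, log, solvers,
                               cfg$unknown_counts_as_competitor)
  list(log = log, trials = trials, solvers = solvers)
}

write_artifact <- function(df, cfg, name) {
  path <- file.path(cfg$out_dir, name)
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (inherits(out[[col]], "POSIXct")) {
      out[[col]] <- format(out[[col]], TS_FORMAT, tz = "UTC")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  path
}

#' Run one pipeline stage
#'
#' File-based stages over a shared output directory. Later stages read
#' the artifacts of earlier ones (\code{complexity} and
#' \code{distances} read \code{sequences.csv}; \code{report} reads
#' \code{stats_report.json}), so chaining the stages manually is
#' identical to [run_pipeline()].
#'
#' @param stage one of \code{"segment"}, \code{"classify"},
#'   \code{"sequences"}, \code{"complexity"}, \code{"distances"},
#'   \code{"stats"}, \code{"report"}.
#' @param cfg a [pipeline_config()].
#' @return Path(s) of the artifact(s) written, invisibly.
#' @export
run_stage <- function(stage, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  switch(stage,
         segment = stage_segment(cfg),
         classify = stage_classify(cfg),
         sequences = stage_sequences(cfg),
         complexity = stage_complexity(cfg),
         distances = stage_distances(cfg),
         stats = stage_stats(cfg),
         report = stage_report(cfg),
         stop("unknown stage: ", stage, call. = FALSE))
}

stage_segment <- function(cfg) {
  log <- read_event_log(cfg$events)
  trials <- segment_trials(log, cfg$absence_threshold)
  op <- trial_openings(trials)
  tdf <- as.data.frame(trials)
  tdf$condition <- "undetermined"
  p1 <- write_artifact(tdf, cfg, "trials.csv")
  doors <- op[, c("individual_id", "site_id", "night_id", "trial_id",
                  "door_number", "door_id", "latch_type", "work_time_s",
                  "work_time_bin", "exploratory_diversity", "timestamp")]
  p2 <- write_artifact(doors, cfg, "doors.csv")
  log_line("segment: ", nrow(trials), " trials, ", nrow(doors),
           " openings")
  invisible(c(p1, p2))
}

stage_classify <- function(cfg) {
  ct <- classified_trials(cfg)
  ab <- latch_alphabet()
  tdf <- as.data.frame(ct$trials)
  for (l in ab) {
    tdf[[paste0("n_", l)]] <- vapply(strsplit(tdf$sequence, "", fixed = TRUE),
                                     function(s) sum(s == l), integer(1))
  }
  p1 <- write_artifact(tdf, cfg, "trials.csv")
  p2 <- write_artifact(as.data.frame(ct$solvers), cfg, "solvers.csv")
  log_line("classify: ", sum(ct$solvers$is_solver), " solver(s) of ",
           nrow(ct$solvers), " individuals")
  invisible(c(p1, p2))
}

stage_sequences <- function(cfg) {
  ct <- classified_trials(cfg)
  seqs <- extract_latch_sequences(ct$trials, ct$solvers,
                                  min_length = cfg$min_sequence_length,
                                  min_doors_to_date = cfg$min_doors_to_date,
                                  condition = "both",
                                  first_year_only = cfg$first_year_only)
  p <- write_artifact(seqs, cfg, "sequences.csv")
  log_line("sequences: ", nrow(seqs), " qualifying sequence(s)")
  invisible(p)
}

read_sequences_csv <- function(cfg) {
  path <- file.path(cfg$out_dir, "sequences.csv")
  if (!file.exists(path)) {
    stop("sequences.csv not found in ", cfg$out_dir,
         "; run the sequences stage first", call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sequence = "character"))
}

stage_complexity <- function(cfg) {
  seqs <- read_sequences_csv(cfg)
  roster <- read_roster(cfg$individuals)
  if (nrow(seqs) == 0L) {
    out <- data.frame(individual_id = character(0),
                      trial_index = integer(0),
                      condition = character(0),
                      prior_knowledge = character(0),
                      block = integer(0), h = numeric(0), q = integer(0),
                      C = numeric(0))
  } else {
    out <- sequence_complexity(seqs)
    out$prior_knowledge <- roster$prior_knowledge[
      match(out$individual_id, roster$individual_id)]
    out <- out[order(out$individual_id, out$condition, out$trial_index), ,
               drop = FALSE]
    rank_in_grp <- stats::ave(seq_len(nrow(out)),
                              out$individual_id, out$condition,
                              FUN = seq_along)
    out$block <- ceiling(rank_in_grp / cfg$block_size)
    out <- out[, c("individual_id", "trial_index", "condition",
                   "prior_knowledge", "block", "h", "q", "C")]
  }
  p <- write_artifact(out, cfg, "complexity.csv")
  log_line("complexity: ", nrow(out), " scored sequence(s)")
  invisible(p)
}

stage_distances <- function(cfg) {
  seqs <- read_sequences_csv(cfg)
  long <- data.frame(id1 = character(0), trial1 = integer(0),
                     id2 = character(0), trial2 = integer(0),
                     condition = character(0), d = numeric(0),
                     d_norm = numeric(0), pair_type = character(0))
  for (cond in c("unrestricted", "competitive")) {
    sub <- seqs[seqs$condition == cond, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sc <- if (cfg$cost_pooling == "pooled") {
      trate_costs(estimate_transition_rates(seqs), cfg$c_val)
    } else {
      trate_costs(estimate_transition_rates(sub), cfg$c_val)
    }
    dm <- pairwise_distances(sub, sc, indel = cfg$indel,
                             normalize = cfg$normalization != "none",
                             method = if (cfg$normalization == "none")
                               "longest" else cfg$normalization)
    ut <- which(upper.tri(dm$d), arr.ind = TRUE)
    long <- rbind(long, data.frame(
      id1 = sub$individual_id[ut[, 1L]],
      trial1 = sub$trial_index[ut[, 1L]],
      id2 = sub$individual_id[ut[, 2L]],
      trial2 = sub$trial_index[ut[, 2L]],
      condition = cond,
      d = dm$d[ut],
      d_norm = dm$d_norm[ut],
      pair_type = ifelse(sub$individual_id[ut[, 1L]] ==
                           sub$individual_id[ut[, 2L]],
                         "intra", "inter"),
      stringsAsFactors = FALSE))
  }
  p <- write_artifact(long, cfg, "distances.csv")
  log_line("distances: ", nrow(long), " pairwise comparison(s)")
  invisible(p)
}

stage_stats <- function(cfg) {
  ct <- classified_trials(cfg)
  roster <- read_roster(cfg$individuals)
  complexity <- utils::read.csv(file.path(cfg$out_dir, "complexity.csv"),
                                stringsAsFactors = FALSE)
  distances <- utils::read.csv(file.path(cfg$out_dir, "distances.csv"),
                               stringsAsFactors = FALSE)
  skipped <- character(0)
  cfg_stamp <- unclass(cfg)
  cfg_stamp[c("events", "individuals", "out_dir")] <- NULL
  report <- list(config = cfg_stamp,
                 config_hash = config_hash(cfg),
                 seed = cfg$seed)

  tested <- unique(ct$trials$individual_id)
  sv <- ct$solvers
  report$solvers <- list(
    n_individuals_tested = length(tested),
    n_solvers = sum(sv$is_solver),
    prop_solvers = if (nrow(sv) > 0) sum(sv$is_solver) / length(tested)
      else NA,
    n_flexible = sum(sv$is_flexible),
    solved_per_latch = as.list(colSums(
      sv[, paste0("n_", latch_alphabet()), drop = FALSE] >=
        cfg$solver_min_doors)))

  # latch preference over the final-k first-arrival trials per solver
  if (any(sv$is_solver)) {
    ft <- withCallingHandlers(
      final_trials_subset(ct$trials, sv, k = cfg$final_trials_k),
      warning = function(w) invokeRestart("muffleWarning"))
    pref <- list(n_trials = nrow(ft$trials),
                 first_latch_counts = as.list(ft$first_latch_counts),
                 total_latch_counts = as.list(ft$total_latch_counts))
    if (sum(ft$first_latch_counts) > 0) {
      g1 <- chisq_uniform_gof(ft$first_latch_counts)
      g2 <- chisq_uniform_gof(ft$total_latch_counts)
      pref$chisq_first <- list(statistic = g1$statistic, df = g1$df,
                               n = g1$n, p_value = g1$p_value)
      pref$chisq_total <- list(statistic = g2$statistic, df = g2$df,
                               n = g2$n, p_value = g2$p_value)
    }
    report$latch_preference <- pref
  } else {
    skipped <- c(skipped, "latch_preference: no solvers")
  }

  # complexity medians by prior knowledge and trial block (unrestricted)
  cx <- complexity[complexity$condition == "unrestricted", , drop = FALSE]
  if (nrow(cx) > 0L) {
    by_med <- stats::aggregate(C ~ prior_knowledge + block, data = cx,
                               FUN = stats::median)
    by_n <- stats::aggregate(C ~ prior_knowledge + block, data = cx,
                             FUN = length)
    names(by_med)[3] <- "median_C"
    by_med$n <- by_n$C
    ind_med <- stats::aggregate(C ~ individual_id, data = cx,
                                FUN = stats::median)
    report$complexity <- list(
      n_sequences = nrow(cx),
      n_individuals = length(unique(cx$individual_id)),
      median_by_group_block = by_med,
      individual_median_range = range(ind_med$C))
  } else {
    skipped <- c(skipped, "complexity: no unrestricted sequences")
  }

  # intra vs inter dissimilarity, per condition, and intra across
  # conditions
  diss <- list()
  for (cond in c("unrestricted", "competitive")) {
    d <- distances[distances$condition == cond, , drop = FALSE]
    if (nrow(d) == 0L) {
      skipped <- c(skipped, paste0("dissimilarity (", cond,
                                   "): no pairs"))
      next
    }
    intra <- d$d_norm[d$pair_type == "intra"]
    inter <- d$d_norm[d$pair_type == "inter"]
    entry <- list(n_intra = length(intra), n_inter = length(inter),
                  median_intra = if (length(intra)) stats::median(intra)
                    else NA,
                  median_inter = if (length(inter)) stats::median(inter)
                    else NA)
    if (length(intra) > 0L && length(inter) > 0L) {
      mw <- mann_whitney(intra, inter)
      entry$mann_whitney <- list(W = mw$statistic, p_value = mw$p_value,
                                 exact = mw$exact)
    }
    diss[[cond]] <- entry
  }
  iu <- distances$d_norm[distances$condition == "unrestricted" &
                           distances$pair_type == "intra"]
  ic <- distances$d_norm[distances$condition == "competitive" &
                           distances$pair_type == "intra"]
  if (length(iu) > 0L && length(ic) > 0L) {
    mw <- mann_whitney(iu, ic)
    diss$intra_unrestricted_vs_competitive <- list(
      W = mw$statistic, p_value = mw$p_value,
      median_unrestricted = stats::median(iu),
      median_competitive = stats::median(ic))
  }
  report$dissimilarity <- diss

  # forward-stepwise binomial GLM for solving success
  glm_data <- build_glm_table(ct, roster)
  cand <- c("exploratory_diversity_first", "age", "sex")
  cand <- cand[vapply(cand, function(v)
    sum(!is.na(glm_data[[v]])) == nrow(glm_data) &&
      length(unique(glm_data[[v]])) > 1L, logical(1))]
  if (nrow(glm_data) >= 10L && length(cand) > 0L &&
      length(unique(glm_data$is_solver)) > 1L) {
    st <- suppressWarnings(forward_stepwise(glm_data, "is_solver", cand))
    best <- st$best
    report$glm <- list(
      n = best$n,
      candidates = cand,
      models = st$models,
      best_model = paste(deparse(best$formula), collapse = ""),
      best_coefficients = as.list(best$coefficients),
      best_ci = apply(best$ci, 1L, as.list),
      lrt_vs_null = if (!is.null(st$lrt_vs_null)) list(
        statistic = st$lrt_vs_null$statistic,
        df = st$lrt_vs_null$df,
        p_value = st$lrt_vs_null$p_value) else NULL)
  } else {
    skipped <- c(skipped, "glm: too few individuals or no usable predictor")
  }

  report$skipped <- if (length(skipped)) skipped else NULL
  path <- file.path(cfg$out_dir, "stats_report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  log_line("stats: report written",
           if (length(skipped)) paste0(" (", length(skipped),
                                       " section(s) skipped)") else "")
  invisible(path)
}

# per-individual table for the success GLM: first-trial exploratory
# diversity, demographics, solver outcome
build_glm_table <- function(ct, roster) {
  ids <- unique(ct$trials$individual_id)
  op <- trial_openings(ct$trials)
  ev <- as.data.frame(ct$log)
  ev <- ev[!is.na(ev$individual_id) & ev$individual_id %in% ids, ,
           drop = FALSE]
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  first_div <- vapply(ids, function(id) {
    d <- ev$exploratory_diversity[ev$individual_id == id]
    d <- d[!is.na(d)]
    if (length(d)) as.numeric(d[1L]) else NA_real_
  }, numeric(1))
  first_bin <- vapply(ids, function(id) {
    b <- op$work_time_bin[op$individual_id == id]
    b <- b[!is.na(b)]
    if (length(b)) as.numeric(b[1L]) else NA_real_
  }, numeric(1))
  out <- data.frame(individual_id = ids,
                    is_solver = as.integer(ids %in%
                      ct$solvers$individual_id[ct$solvers$is_solver]),
                    exploratory_diversity_first = first_div,
                    work_time_bin_first = first_bin,
                    stringsAsFactors = FALSE)
  out$age <- roster$age[match(ids, roster$individual_id)]
  out$sex <- roster$sex[match(ids, roster$individual_id)]
  out
}

stage_report <- function(cfg) {
  path <- file.path(cfg$out_dir, "stats_report.json")
  if (!file.exists(path)) {
    stop("stats_report.json not found; run the stats stage first",
         call. = FALSE)
  }
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- file.path(cfg$out_dir, "summary.txt")
  con <- file(out, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("puzzle-box sequence analysis summary")
  w("config hash: ", r$config_hash, "  seed: ", r$seed)
  w("")
  w(sprintf("individuals tested: %d; solvers: %d (%.0f%%); flexible: %d",
            r$solvers$n_individuals_tested, r$solvers$n_solvers,
            100 * r$solvers$prop_solvers, r$solvers$n_flexible))
  if (!is.null(r$latch_preference)) {
    lp <- r$latch_preference
    w("")
    w(sprintf("latch preference (final %s first-arrival trials; n = %d):",
              r$config$final_trials_k, lp$n_trials))
    w("  first-opened counts  [HRVS order ",
      paste(names(lp$first_latch_counts), collapse = ""), "]: ",
      paste(unlist(lp$first_latch_counts), collapse = " "))
    w("  total counts: ",
      paste(unlist(lp$total_latch_counts), collapse = " "))
    if (!is.null(lp$chisq_first)) {
      w(sprintf("  chi-sq first: %.3f (df %d, n %d), p = %.3g",
                lp$chisq_first$statistic, lp$chisq_first$df,
                lp$chisq_first$n, lp$chisq_first$p_value))
      w(sprintf("  chi-sq total: %.3f (df %d, n %d), p = %.3g",
                lp$chisq_total$statistic, lp$chisq_total$df,
                lp$chisq_total$n, lp$chisq_total$p_value))
    }
  }
  if (!is.null(r$complexity)) {
    w("")
    w(sprintf("complexity (unrestricted): %d sequences, %d individuals",
              r$complexity$n_sequences, r$complexity$n_individuals))
    w(sprintf("  per-individual median range: %.2f-%.2f",
              r$complexity$individual_median_range[1],
              r$complexity$individual_median_range[2]))
    m <- r$complexity$median_by_group_block
    for (i in seq_len(nrow(m))) {
      w(sprintf("  %s, block %d: median C = %.2f (n = %d)",
                m$prior_knowledge[i], m$block[i], m$median_C[i], m$n[i]))
    }
  }
  for (cond in c("unrestricted", "competitive")) {
    dd <- r$dissimilarity[[cond]]
    if (is.null(dd)) next
    w("")
    w(sprintf("dissimilarity (%s): intra median = %.2f (n = %d), inter median = %.2f (n = %d)",
              cond, dd$median_intra, dd$n_intra, dd$median_inter,
              dd$n_inter))
    if (!is.null(dd$mann_whitney)) {
      w(sprintf("  intra vs inter: W = %.1f, p = %.3g",
                dd$mann_whitney$W, dd$mann_whitney$p_value))
    }
  }
  iuc <- r$dissimilarity$intra_unrestricted_vs_competitive
  if (!is.null(iuc)) {
    w(sprintf("intra-individual, unrestricted (%.2f) vs competitive (%.2f): W = %.1f, p = %.3g",
              iuc$median_unrestricted, iuc$median_competitive, iuc$W,
              iuc$p_value))
  }
  if (!is.null(r$glm)) {
    w("")
    w("solving-success model (forward stepwise binomial GLM):")
    w("  best: ", r$glm$best_model)
    if (!is.null(r$glm$lrt_vs_null)) {
      w(sprintf("  vs null: LRT = %.2f (df %d), p = %.3g",
                r$glm$lrt_vs_null$statistic, r$glm$lrt_vs_null$df,
                r$glm$lrt_vs_null$p_value))
    }
  }
  if (!is.null(r$skipped)) {
    w("")
    w("SKIPPED sections:")
    for (s in r$skipped) w("  - ", s)
  }
  log_line("report: summary written")
  invisible(out)
}

#' Run the full analysis pipeline
#'
#' Checks the inputs, then chains every stage: trial segmentation,
#' solver and condition classification, sequence extraction, complexity
#' scoring, pairwise optimal-matching distances, inferential statistics
#' and the human-readable summary. Artifacts (trials.csv, doors.csv,
#' solvers.csv, sequences.csv, complexity.csv, distances.csv,
#' stats_report.json, summary.txt) are written to the configured output
#' directory; every report is stamped with the config hash and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, the parsed stats report.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("events", "individuals")) {
    if (!file.exists(cfg[[f]])) {
      stop("input not found before any computation: ", cfg[[f]],
           call. = FALSE)
    }
  }
  for (stage in c("segment", "classify", "sequences", "complexity",
                  "distances", "stats", "report")) {
    run_stage(stage, cfg)
  }
  invisible(jsonlite::read_json(file.path(cfg$out_dir,
                                          "stats_report.json"),
                                simplifyVector = TRUE))
}
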