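#' Analyse one participant's binary dynamics under one stimulus
#'
#' Fits the pairwise maximum-entropy model and the independent baseline,
#' scores the fit with the accuracy index, builds the energy landscape, runs
#' the Metropolis walk, and extracts the attractor features.
#'
#' @param states a `binary_states` series (selected channels already).
#' @param n_steps random-walk iterations (default 20000).
#' @param seed seed for the walk's start state and proposals.
#' @param major_states optional major-state positions/strings for dwell
#'   statistics.
#' @param method pMEM fit mode, `"exact"` (default) or `"pl"`.
#' @return list with `model`, `mem`, `acc` (`accuracy_index`), `landscape`,
#'   `walk`, `features` (`el_features`).
#' @export
analyze_states <- function(states, n_steps = 20000L, seed = NULL,
                           major_states = NULL, method = "exact") {
  stats_e <- empirical_stats(states)
  model <- fit_pmem(stats_e, method = method)
  mem <- fit_independent_mem(stats_e)
  acc <- accuracy_index(stats_e$Pe, model, mem)
  land <- energy_landscape(model)
  walk <- random_walk(land, n_steps = n_steps, seed = seed)
  feats <- dwell_features(walk, land, major_states = major_states)
  list(model = model, mem = mem, acc = acc, landscape = land,
       walk = walk, features = feats)
}

#' Participant x stimulus feature table for a synthetic cohort
#'
#' Runs the full state-level analysis for every participant and stimulus
#' category (happy, calm, fear, and "full" = the concatenation of all
#' trials), then finds the per-stimulus major states (LMs shared by every
#' participant) and appends their dwell durations.  Returns the long-format
#' table used by the group statistics and the per-analysis objects used by
#' the classifiers.
#'
#' @param cohort output of [generate_cohort()] (state-level ground truth is
#'   used directly; thresholds and binarization are exercised separately by
#'   the continuous pipeline).
#' @param stimuli categories to analyse (default happy, calm, fear, full).
#' @param n_steps,method passed to [analyze_states()].
#' @param seed integer; per-analysis walk seeds are derived from it.
#' @return list with `table` (data frame: subject, group, stimulus, r, K1,
#'   K2, n_LM, mean_gap, basin_size_sd, gm_duration, gm_mean_dwell, and
#'   dwell columns per major state), `analyses` (nested list
#'   `[[stimulus]][[subject]]`), `major` (per-stimulus major-state info).
#' @export
cohort_features <- function(cohort, stimuli = c("happy", "calm", "fear", "full"),
                            n_steps = 20000L, method = "exact", seed = 1L) {
  truth <- cohort$truth
  n_subj <- length(truth)
  analyses <- list()
  rows <- list()
  major_info <- list()
  for (st in stimuli) {
    analyses[[st]] <- vector("list", n_subj)
    for (p in seq_len(n_subj)) {
      spins <- participant_states(truth[[p]], st)
      analyses[[st]][[p]] <- analyze_states(
        spins, n_steps = n_steps,
        seed = (seed * 1000L + p * 7L + match(st, stimuli)) %% .Machine$integer.max,
        method = method)
    }
    lands <- lapply(analyses[[st]], `[[`, "landscape")
    mj <- suppressWarnings(find_major_states(lands))
    major_info[[st]] <- mj
    for (p in seq_len(n_subj)) {
      a <- analyses[[st]][[p]]
      fe <- suppressWarnings(
        dwell_features(a$walk, a$landscape, major_states = mj$major))
      row <- data.frame(subject = truth[[p]]$subject_id,
                        group = truth[[p]]$group,
                        stimulus = st,
                        r = a$acc$r, K1 = a$acc$K1, K2 = a$acc$K2,
                        n_LM = fe$n_LM, mean_gap = fe$mean_gap,
                        basin_size_sd = fe$basin_size_sd,
                        gm_duration = fe$gm_duration,
                        gm_mean_dwell = fe$gm_mean_dwell)
      if (!is.null(fe$major)) {
        for (k in seq_len(nrow(fe$major))) {
          row[[paste0("dwell_", fe$major$label[k])]] <- fe$major$mean_dwell[k]
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  tab <- rbind_fill(rows)  # major-state columns may differ across stimuli
  tab$group <- factor(tab$group, levels = c("HC", "MDD"))
  tab$stimulus <- factor(tab$stimulus, levels = stimuli)
  list(table = tab, analyses = analyses, major = major_info)
}

# states for one participant and stimulus; "full" concatenates all four
# generating categories in paradigm order approximation (trial order within
# category preserved)
participant_states <- function(part, stimulus) {
  if (stimulus == "full") {
    spins <- do.call(rbind, lapply(part$categories, function(x) x$states$spins))
    binary_states(spins)
  } else {
    part$categories[[stimulus]]$states
  }
}

# rbind data frames with differing columns, filling NA
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}
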