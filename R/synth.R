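#' Configuration for a synthetic fNIRS cohort
#'
#' Describes the generative world the analysis assumes: a two-group cohort
#' whose selected-channel binary dynamics follow group-specific Boltzmann
#' distributions with planted energy-landscape differences.  The paradigm
#' mirrors a block design of 4 blocks x 4 trial types (happy, calm, fear,
#' white noise) in Latin-square order, 18 s trials separated by 20 s rests,
#' sampled at 7.81 Hz.  Informative channels carry the planted spin
#' dynamics; the remaining background channels are AR(1) noise with a small
#' per-subject shared component, giving tensor-based channel ranking a
#' nontrivial but solvable problem.
#'
#' The healthy-control generator uses a weak two-block ferromagnetic
#' coupling structure (channels 1-4 vs 5-7 of the selected set, positive
#' within blocks and negative across) plus a field bias along the
#' `1111000` pattern, so that the complementary patterns `1111000` and
#' `0000111` are planted local minima with a clear energy gap and a skewed
#' basin split.  The "MDD" group differs through `effect_knobs`:
#' \describe{
#'   \item{ruggedness}{multiplier (> 1) on the participant-level coupling
#'     noise sd `sigma_J`: sign-mixed rugged couplings plant additional
#'     local minima with near-degenerate energies, shrinking the mean
#'     LM-GM gap and equalising basin sizes.}
#'   \item{coupling}{multiplier (< 1) on the structured couplings and the
#'     field bias: compresses the planted asymmetry, further shrinking
#'     gaps and the basin-size spread.}
#'   \item{gm_bias}{extra field component along the `1111000` pattern for
#'     the MDD group (default 0): deepens and widens the global-minimum
#'     basin so the random walk dwells longer there.  Engaging it reverses
#'     the gap and basin-spread directions - within pairwise Boltzmann
#'     landscapes the four group directions cannot all be planted at once
#'     (see the methods vignette).}
#' }
#' Knob deviations from neutral are modulated per stimulus by
#' `stimulus_strength` (largest under fear, mirroring the strongest observed
#' group contrast under negative stimuli).
#'
#' @param n_per_group participants per group.
#' @param n_channels_full total channels in a recording (default 22).
#' @param n_selected informative channels carrying the planted dynamics
#'   (default 7).
#' @param sampling_rate_hz sampling rate (default 7.81).
#' @param trial_s,rest_s,n_blocks paradigm timing (defaults 18, 20, 4).
#' @param informative_channels indices of the informative channels within
#'   the full montage (default `c(2, 7, 9, 14, 16, 21, 22)`).
#' @param group_params list of generator distribution parameters:
#'   `j_in`, `j_out` (structured couplings), `h_bias` (field bias along the
#'   `1111000` pattern), `sigma_J` (participant coupling noise sd),
#'   `sigma_h` (field noise sd), `h_base` (field mean).
#' @param effect_knobs list: `ruggedness`, `coupling`, `gm_bias` (see
#'   above); all neutral (`1, 1, 0`) means identical group distributions.
#' @param stimulus_strength named vector in `[0, 1]` scaling knob deviations
#'   per generating category.
#' @param noise_sd continuous-signal Gaussian noise sd (fraction of the
#'   unit spin amplitude).
#' @param evoked_amp sustained stimulus-locked activation offset added to
#'   informative channels during trials (constant within each trial, so
#'   mean-threshold binarization of a stimulus segment is unaffected);
#'   shared across subjects up to a per-subject gain (sd 0.15).  This
#'   evoked component is what makes the informative channels cohere across
#'   subjects so that tensor-based ranking can find them; set 0 to disable.
#' @param markov_persistence probability of repeating the previous state
#'   before drawing fresh (0 = i.i.d. draws, the default: empirical state
#'   statistics treat samples exchangeably).
#' @param seed integer seed; all randomness flows from it.
#' @return a validated `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 30,
                          n_channels_full = 22,
                          n_selected = 7,
                          sampling_rate_hz = 7.81,
                          trial_s = 18, rest_s = 20, n_blocks = 4,
                          informative_channels = c(2, 7, 9, 14, 16, 21, 22),
                          group_params = list(j_in = 0.12, j_out = 0.10,
                                              h_bias = 0.20,
                                              sigma_J = 0.08, sigma_h = 0.05,
                                              h_base = 0),
                          effect_knobs = list(ruggedness = 2.4,
                                              coupling = 0.45,
                                              gm_bias = 0),
                          stimulus_strength = c(happy = 0.7, calm = 0.6,
                                                fear = 1, noise = 0.8),
                          noise_sd = 0.1,
                          evoked_amp = 1.2,
                          markov_persistence = 0,
                          seed = 1L) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid ", field, ": ", msg)
  chk(n_per_group >= 1, "n_per_group", "must be >= 1")
  chk(n_selected <= n_channels_full, "n_selected",
      "must be <= n_channels_full")
  chk(sampling_rate_hz > 0, "sampling_rate_hz", "must be > 0")
  chk(length(informative_channels) == n_selected, "informative_channels",
      "length must equal n_selected")
  chk(all(informative_channels >= 1 & informative_channels <= n_channels_full),
      "informative_channels", "indices out of montage range")
  chk(group_params$sigma_J >= 0, "group_params$sigma_J", "must be >= 0")
  chk(group_params$sigma_h >= 0, "group_params$sigma_h", "must be >= 0")
  chk(noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(evoked_amp >= 0, "evoked_amp", "must be >= 0")
  chk(effect_knobs$ruggedness > 0, "effect_knobs$ruggedness", "must be > 0")
  chk(effect_knobs$coupling > 0, "effect_knobs$coupling", "must be > 0")
  chk(markov_persistence >= 0 && markov_persistence < 1,
      "markov_persistence", "must be in [0, 1)")
  chk(all(c("happy", "calm", "fear", "noise") %in% names(stimulus_strength)),
      "stimulus_strength", "needs happy/calm/fear/noise entries")
  structure(as.list(environment())[c(
    "n_per_group", "n_channels_full", "n_selected", "sampling_rate_hz",
    "trial_s", "rest_s", "n_blocks", "informative_channels", "group_params",
    "effect_knobs", "stimulus_strength", "noise_sd", "evoked_amp",
    "markov_persistence", "seed")], class = "cohort_config")
}

#' Draw i.i.d. states from an exact Boltzmann distribution
#'
#' Enumerates the probabilities of all 2^C states for parameters `(h, J)`
#' and samples `n_samples` spin vectors i.i.d. from them (or, with
#' `persistence > 0`, from a sticky chain that repeats the previous state
#' with that probability and otherwise draws fresh - the marginal remains
#' Boltzmann).  Refuses C > 12 rather than approximating.
#'
#' @param h field vector (length C <= 12).
#' @param J symmetric coupling matrix, zero diagonal.
#' @param n_samples number of state vectors to draw (>= 1).
#' @param seed optional integer seed.
#' @param persistence see above (default 0).
#' @return a `binary_states` object `[n_samples x C]`.
#' @export
sample_pmem_states <- function(h, J = NULL, n_samples, seed = NULL,
                               persistence = 0) {
  C <- length(h)
  if (C > 12) stop("C = ", C, " > 12: exact enumeration refused")
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  model <- pmem_model(h, J)
  idx <- sample.int(2^C, n_samples, replace = TRUE, prob = model$P)
  if (persistence > 0 && n_samples > 1) {
    keep <- stats::runif(n_samples - 1) < persistence
    for (t in 2:n_samples) if (keep[t - 1]) idx[t] <- idx[t - 1]
  }
  S <- state_matrix(C)
  binary_states(S[idx, , drop = FALSE])
}

#' Continuous signals from planted spins
#'
#' Inverts mean-threshold binarization: each channel emits
#' `amplitude * spin` (optionally smoothed with a centred moving average)
#' plus Gaussian noise, so that thresholding the output at its mean
#' recovers the planted spins with high fidelity (exactly, when
#' `noise_sd = 0` and `smooth_window = 1`).
#'
#' @param states a `binary_states` object or spin matrix.
#' @param fs sampling rate (metadata only).
#' @param noise_sd Gaussian noise sd, in units of `amplitude`.
#' @param seed optional seed.
#' @param amplitude planted waveform amplitude (default 1).
#' @param smooth_window centred moving-average width in samples (odd;
#'   default 1 = no smoothing, appropriate for exchangeable state draws).
#' @return numeric matrix `[time x C]`.
#' @export
spins_to_continuous <- function(states, fs = 7.81, noise_sd = 0.1,
                                seed = NULL, amplitude = 1,
                                smooth_window = 1) {
  spins <- if (inherits(states, "binary_states")) states$spins else as.matrix(states)
  if (nrow(spins) == 0) stop("empty state series")
  stopifnot(noise_sd >= 0, smooth_window >= 1)
  if (!is.null(seed)) set.seed(seed)
  sig <- amplitude * spins
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sig <- apply(sig, 2, function(x)
      as.numeric(stats::filter(x, k, sides = 2, circular = TRUE)))
    sig <- matrix(sig, nrow = nrow(spins))
  }
  sig + matrix(stats::rnorm(length(sig), sd = noise_sd), nrow = nrow(spins))
}

# group- and stimulus-specific generating parameters for one participant;
# the coupling knob compresses both the structured couplings and the field
# bias, the ruggedness knob inflates the coupling noise sd
draw_participant_params <- function(config, group, category) {
  gp <- config$group_params
  C <- config$n_selected
  strength <- config$stimulus_strength[[category]]
  kn <- config$effect_knobs
  if (group == "MDD") {
    rugged <- 1 + (kn$ruggedness - 1) * strength
    coupl <- 1 + (kn$coupling - 1) * strength
    bias_extra <- kn$gm_bias * strength
  } else {
    rugged <- 1; coupl <- 1; bias_extra <- 0
  }
  blockA <- seq_len(min(4, C))
  pattern <- ifelse(seq_len(C) %in% blockA, 1, -1)  # the "1111000" direction
  J_struct <- outer(pattern, pattern) * gp$j_in
  # within-block +j_in, across-block -j_out
  J_struct[J_struct < 0] <- -gp$j_out
  diag(J_struct) <- 0
  noise <- matrix(stats::rnorm(C * C, sd = gp$sigma_J * rugged), C, C)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  J <- coupl * J_struct + noise
  h <- gp$h_base + (coupl * gp$h_bias + bias_extra) * pattern +
    stats::rnorm(C, sd = gp$sigma_h)
  list(h = h, J = J, pattern = pattern)
}

# Latin-square trial order: block b presents the 4 categories cyclically
# shifted by b-1
latin_square_order <- function(n_blocks) {
  cats <- c("happy", "calm", "fear", "noise")
  unlist(lapply(seq_len(n_blocks), function(b) {
    cats[((seq_along(cats) - 1 + (b - 1)) %% length(cats)) + 1]
  }))
}

#' Generate a synthetic two-group cohort
#'
#' Assembles `n_per_group` recordings per group.  For each participant and
#' generating category, fields and couplings are drawn around the group
#' structure (see [cohort_config()]), binary states are sampled from the
#' exact Boltzmann distribution, and (optionally) a 22-channel continuous
#' recording is synthesised: informative channels carry the planted spin
#' waveforms during their trials and baseline noise elsewhere; background
#' channels are AR(1) noise with a weak per-subject shared component.
#' Deterministic given `config$seed`.
#'
#' @param config a `cohort_config`.
#' @param continuous generate continuous recordings (`TRUE`, default) or
#'   only the state-level ground truth (fast path for state-level studies).
#' @return list with `recordings` (list of `recording`, or `NULL`) and
#'   `truth`: per participant a list with `subject_id`, `group`, and per
#'   category `params` (`h`, `J`) and `states` (`binary_states`).
#' @export
generate_cohort <- function(config, continuous = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate_hz
  spt <- round(config$trial_s * fs)            # samples per trial
  cats <- c("happy", "calm", "fear", "noise")
  order_all <- latin_square_order(config$n_blocks)
  n_trials <- length(order_all)
  slot_s <- config$trial_s + config$rest_s
  onsets <- (seq_len(n_trials) - 1) * slot_s
  total_samples <- ceiling(n_trials * slot_s * fs)
  ann <- data.frame(onset = onsets, duration = config$trial_s,
                    label = order_all)
  groups <- rep(c("MDD", "HC"), each = config$n_per_group)
  truth <- list()
  recordings <- if (continuous) list() else NULL
  for (p in seq_along(groups)) {
    grp <- groups[p]
    sid <- sprintf("%s%03d", tolower(grp), ((p - 1) %% config$n_per_group) + 1)
    per_cat <- list()
    for (cat in cats) {
      pars <- draw_participant_params(config, grp, cat)
      n_cat_trials <- sum(order_all == cat)
      st <- sample_pmem_states(pars$h, pars$J, n_samples = n_cat_trials * spt,
                               persistence = config$markov_persistence)
      per_cat[[cat]] <- list(params = pars, states = st)
    }
    truth[[p]] <- list(subject_id = sid, group = grp, categories = per_cat)
    if (continuous) {
      # channel polarity: block-B channels emit the NEGATIVE of their spin
      # (anticorrelated hemodynamics between the two regions), so all
      # informative channels are positively correlated in signal space.
      # This is a gauge transformation of the Ising family (flip sigma_B
      # together with h_B and J_AB signs), so every landscape quantity of
      # the binarized dynamics is unchanged; only the displayed state
      # labels differ between the generator gauge and the recording gauge.
      polarity <- per_cat[[cats[1]]]$params$pattern
      sig <- matrix(0, nrow = total_samples, ncol = config$n_channels_full)
      # background: AR(1) per channel + weak shared per-subject component,
      # scaled below the informative channels' amplitude.  A handful of
      # background channels additionally carry channel-specific coherent
      # oscillations (instrument/physiological artifacts at fixed
      # frequencies, time-locked across subjects): these reliably claim
      # their own tensor components without correlating with one another,
      # which keeps the channel ranking well-posed.
      bg_scale <- 0.5  # AR(1) phi=0.8 has stationary sd 1.67; -> sd ~0.85
      shared <- as.numeric(stats::arima.sim(list(ar = 0.8), total_samples))
      bg <- setdiff(seq_len(config$n_channels_full),
                    config$informative_channels)
      t_glob <- (seq_len(total_samples) - 1) / fs
      art_freqs <- seq(0.06, 0.18, length.out = min(5, length(bg)))
      for (k in seq_along(bg)) {
        ch <- bg[k]
        sig[, ch] <- bg_scale *
          (as.numeric(stats::arima.sim(list(ar = 0.8), total_samples)) +
             0.05 * shared)
        if (k <= length(art_freqs)) {
          sig[, ch] <- sig[, ch] +
            0.9 * sin(2 * pi * art_freqs[k] * t_glob + k)
        }
      }
      # informative channels: baseline noise everywhere, planted waveform
      # during trials
      info_noise <- matrix(stats::rnorm(total_samples * config$n_selected,
                                        sd = config$noise_sd),
                           total_samples, config$n_selected)
      sig[, config$informative_channels] <- info_noise
      # stimulus-locked evoked activation: sustained offset plus slow
      # trial-locked oscillations, shared across informative channels and
      # subjects up to a per-subject gain.  The offset is constant within
      # each trial (mean-threshold binarization of a segment is unaffected)
      # and the oscillation amplitudes stay well below the unit spin
      # amplitude; together they give the tensor decomposition several
      # all-positive informative-channel components to latch onto.
      gain <- max(0, stats::rnorm(1, 1, 0.15))
      tt <- (seq_len(spt) - 1) / fs
      env_trial <- gain * (config$evoked_amp +
                             0.45 * sin(2 * pi * 0.05 * tt) +
                             0.30 * sin(2 * pi * 0.11 * tt + 1))
      used <- stats::setNames(rep(0L, length(cats)), cats)
      for (tr in seq_len(n_trials)) {
        cat <- order_all[tr]
        rows_states <- used[[cat]] + seq_len(spt)
        used[[cat]] <- used[[cat]] + spt
        chunk <- sweep(per_cat[[cat]]$states$spins[rows_states, , drop = FALSE],
                       2, polarity, `*`) + env_trial
        t0 <- round(onsets[tr] * fs)
        sig[(t0 + 1):(t0 + spt), config$informative_channels] <-
          sig[(t0 + 1):(t0 + spt), config$informative_channels] + chunk
      }
      recordings[[p]] <- recording(sig, fs = fs,
                                   subject_id = sid, group = grp,
                                   annotations = ann)
    }
  }
  list(recordings = recordings, truth = truth,
       config = config, groups = groups)
}
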