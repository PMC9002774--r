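#' Parameters of a synthetic multi-modal FOG cohort
#'
#' Bundles every knob of the simulator. Defaults describe a cohort of
#' Parkinson's-disease-like walkers whose acceleration spectrum lies in the
#' locomotion band (0.5--3 Hz) during walking and shifts, with reduced
#' amplitude, to the freeze band (3--8 Hz) during freezing episodes. Episode
#' onsets follow a Poisson process (with a 2 s refractory gap between
#' episodes) and durations a truncated log-normal with median 8 s and log-sd
#' 1.1, giving roughly a third of episodes shorter than 5 s and half shorter
#' than 10 s, spanning about 1--200 s.
#'
#' @param n_subjects Number of subjects.
#' @param tasks_per_subject Walking tasks recorded per subject.
#' @param task_duration_s Duration of each task, seconds.
#' @param fog_rate Episode arrival rate, episodes per minute.
#' @param episode_median_s Median episode duration, seconds.
#' @param episode_sigma Log-sd of the episode-duration log-normal.
#' @param gait_freq_hz Range of per-subject cadence frequencies (Hz); one
#'   value per subject is drawn uniformly and shared across that subject's
#'   tasks.
#' @param freeze_freq_hz Range of per-subject trembling frequencies (Hz).
#' @param fog_amplitude_ratio Movement amplitude during FOG relative to
#'   walking, in (0, 1).
#' @param eeg_fog_band_shift Named power multipliers applied to the EEG
#'   band-limited oscillators inside episodes.
#' @param sc_phasic_gain Amplitude of anticipatory skin-conductance responses,
#'   microsiemens.
#' @param noise_sd Named per-modality additive Gaussian noise sd.
#' @param modalities Which modalities to generate (subset of the six).
#' @param seed Integer seed; together with the subject index it makes every
#'   recording bit-reproducible.
#' @return Object of class \code{fog_params}.
#' @export
cohort_params <- function(n_subjects = 8,
                          tasks_per_subject = 2,
                          task_duration_s = 120,
                          fog_rate = 2,
                          episode_median_s = 8,
                          episode_sigma = 1.1,
                          gait_freq_hz = c(1, 2.5),
                          freeze_freq_hz = c(4, 7),
                          fog_amplitude_ratio = 0.5,
                          eeg_fog_band_shift = c(delta = 1, theta = 2,
                                                 alpha = 0.7, beta1 = 1.5,
                                                 beta2 = 1.5),
                          sc_phasic_gain = 0.3,
                          noise_sd = c(inertial = 0.1, eeg = 1, sc = 0.01),
                          modalities = c("tibia_acc", "tibia_gyro",
                                         "wrist_acc", "wrist_gyro",
                                         "eeg", "sc"),
                          seed = 1L) {
  p <- list(n_subjects = n_subjects, tasks_per_subject = tasks_per_subject,
            task_duration_s = task_duration_s, fog_rate = fog_rate,
            episode_median_s = episode_median_s, episode_sigma = episode_sigma,
            gait_freq_hz = gait_freq_hz, freeze_freq_hz = freeze_freq_hz,
            fog_amplitude_ratio = fog_amplitude_ratio,
            eeg_fog_band_shift = eeg_fog_band_shift,
            sc_phasic_gain = sc_phasic_gain, noise_sd = noise_sd,
            modalities = match.arg(modalities, several.ok = TRUE),
            seed = as.integer(seed))
  validate_params(p)
  structure(p, class = "fog_params")
}

validate_params <- function(p) {
  num_pos <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      stop(sprintf("parameter '%s' must be positive and finite", nm), call. = FALSE)
  }
  num_pos(p$n_subjects, "n_subjects"); num_pos(p$tasks_per_subject, "tasks_per_subject")
  num_pos(p$task_duration_s, "task_duration_s"); num_pos(p$episode_median_s, "episode_median_s")
  num_pos(p$episode_sigma, "episode_sigma")
  if (!is.numeric(p$fog_rate) || !is.finite(p$fog_rate) || p$fog_rate < 0)
    stop("fog_rate must be non-negative and finite", call. = FALSE)
  if (p$fog_amplitude_ratio <= 0 || p$fog_amplitude_ratio >= 1)
    stop("fog_amplitude_ratio must lie in (0, 1)", call. = FALSE)
  invisible(p)
}

# Native sampling rates of the simulated hardware: the common 500 Hz rate is
# reached only at the preprocessing stage, so resampling is exercised.
native_fs <- c(tibia_acc = 100, tibia_gyro = 100, wrist_acc = 100,
               wrist_gyro = 100, eeg = 1000, sc = 100)

eeg_electrodes <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
                    "O1", "O2", "F7", "F8", "P7", "P8", "Fz", "Cz", "Pz",
                    "FC1", "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6",
                    "TP9", "TP10", "IO")

# --- episode placement ------------------------------------------------------

# Draw FOG episodes for one task: a Poisson number of episodes with truncated
# log-normal durations, placed uniformly at random subject to non-overlap and
# a >= 2 s refractory gap. Episodes that cannot fit are dropped, longest first.
draw_episodes <- function(duration_s, rate_per_min, median_s, sigma,
                          refractory_s = 2, dur_range = c(1, 200)) {
  n <- rpois(1, rate_per_min * duration_s / 60)
  if (n == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  durs <- pmin(pmax(rlnorm(n, meanlog = log(median_s), sdlog = sigma),
                    dur_range[1]), dur_range[2])
  durs <- sort(durs)  # drop longest first if needed
  repeat {
    slack <- duration_s - sum(durs) - refractory_s * (length(durs) - 1)
    if (slack >= 0 || length(durs) == 0) break
    durs <- durs[-length(durs)]
  }
  n <- length(durs)
  if (n == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  durs <- durs[sample.int(n)]             # random order for placement
  u <- sort(runif(n, 0, slack))
  starts <- u + c(0, cumsum(durs[-n] + refractory_s))
  data.frame(start_s = starts, end_s = starts + durs)
}

# --- signal builders --------------------------------------------------------

# 0/1 indicator over the sample grid for a set of [start, end) episodes
episode_indicator <- function(t, episodes) {
  ind <- rep(FALSE, length(t))
  for (i in seq_len(nrow(episodes)))
    ind <- ind | (t >= episodes$start_s[i] & t < episodes$end_s[i])
  ind
}

# Walking: cadence fundamental plus two decaying harmonics; FOG: trembling at
# the freeze frequency with attenuated amplitude.
inertial_channel <- function(t, fog, gait_f, freeze_f, amp_ratio, noise_sd,
                             base_amp = 1) {
  ph <- runif(4, 0, 2 * pi)
  walk <- base_amp * (sin(2 * pi * gait_f * t + ph[1]) +
                        0.3 * sin(2 * pi * 2 * gait_f * t + ph[2]) +
                        0.15 * sin(2 * pi * 3 * gait_f * t + ph[3]))
  frz <- base_amp * amp_ratio * sin(2 * pi * freeze_f * t + ph[4])
  x <- ifelse(fog, frz, walk) + rnorm(length(t), sd = noise_sd)
  x
}

# Pink (1/f-amplitude) background noise via spectral shaping
pink_noise <- function(n, sd = 1) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  x * sd / sd_pop(x)
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

eeg_band_osc <- c(delta = 2.5, theta = 6, alpha = 10, beta1 = 16, beta2 = 24)

# Electrodes carrying each oscillator; fronto-central sites carry the
# FOG-reactive theta/beta activity.
eeg_osc_sites <- list(
  delta = c("FP1", "FP2", "F3", "F4"),
  theta = c("Fz", "Cz", "FC1", "FC2", "C3", "C4"),
  alpha = c("O1", "O2", "P3", "P4", "P7", "P8"),
  beta1 = c("Cz", "Pz", "CP1", "CP2"),
  beta2 = c("FC5", "FC6", "CP5", "CP6"))

eeg_channel <- function(t, fog, electrode, band_shift, noise_sd) {
  x <- pink_noise(length(t), sd = noise_sd)
  for (band in names(eeg_band_osc)) {
    if (!(electrode %in% eeg_osc_sites[[band]])) next
    amp <- 0.6 * noise_sd
    gain <- ifelse(fog, sqrt(band_shift[[band]]), 1)
    x <- x + amp * gain * sin(2 * pi * eeg_band_osc[[band]] * t + runif(1, 0, 2 * pi))
  }
  x
}

# Skin conductance in microsiemens: slow tonic drift plus anticipatory phasic
# bumps starting within 2 s before each episode onset; returned as galvanic
# resistance (reciprocal), as delivered by the sensor.
sc_channel <- function(t, episodes, phasic_gain, noise_sd) {
  base <- 2 + 0.5 * t / max(t[length(t)], 1) +
    0.2 * sin(2 * pi * 0.01 * t + runif(1, 0, 2 * pi))
  phasic <- numeric(length(t))
  for (i in seq_len(nrow(episodes))) {
    onset <- episodes$start_s[i] - runif(1, 0, 2)
    rise <- 0.5; decay <- 2
    u <- t - onset
    bump <- ifelse(u > 0, (1 - exp(-u / rise)) * exp(-u / decay), 0)
    phasic <- phasic + phasic_gain * bump
  }
  cond <- base + phasic + rnorm(length(t), sd = noise_sd)
  cond <- pmax(cond, 0.05)
  1 / cond
}

# --- public simulation API --------------------------------------------------

#' Simulate all recordings of one subject
#'
#' Generates \code{tasks_per_subject} multi-modal recordings with ground-truth
#' FOG annotations. Per-subject characteristics (cadence frequency, trembling
#' frequency, wrist behaviour during FOG) are drawn once from
#' \code{(seed, subject_index)} and shared across the subject's tasks, so
#' repeated calls are bit-identical.
#'
#' @param params A \code{\link{cohort_params}} object.
#' @param subject_index 1-based subject index (<= \code{n_subjects}).
#' @return List with \code{recordings} (one \code{fog_recording} per task) and
#'   \code{annotations} (data frame \code{subject_id, task_id, start_s,
#'   end_s}).
#' @export
simulate_subject <- function(params, subject_index) {
  validate_params(params)
  if (subject_index < 1 || subject_index > params$n_subjects)
    stop("subject_index out of range", call. = FALSE)
  with_seed(child_seed(params$seed, subject_index), {
    subject_id <- sprintf("S%02d", subject_index)
    gait_f <- runif(1, params$gait_freq_hz[1], params$gait_freq_hz[2])
    freeze_f <- runif(1, params$freeze_freq_hz[1], params$freeze_freq_hz[2])
    wrist_trembles <- runif(1) < 0.5   # heterogeneous upper-limb behaviour
    recs <- vector("list", params$tasks_per_subject)
    anns <- list()
    for (k in seq_len(params$tasks_per_subject)) {
      task_id <- sprintf("T%02d", k)
      episodes <- if (params$fog_rate > 0)
        draw_episodes(params$task_duration_s, params$fog_rate,
                      params$episode_median_s, params$episode_sigma)
      else data.frame(start_s = numeric(0), end_s = numeric(0))
      mods <- list()
      for (mod in params$modalities) {
        fs <- native_fs[[mod]]
        t <- seq(0, params$task_duration_s - 1 / fs, by = 1 / fs)
        fog <- episode_indicator(t, episodes)
        if (mod %in% c("tibia_acc", "tibia_gyro")) {
          ch <- t(sapply(1:3, function(ax)
            inertial_channel(t, fog, gait_f, freeze_f,
                             params$fog_amplitude_ratio,
                             params$noise_sd[["inertial"]],
                             base_amp = c(1, 0.8, 0.9)[ax])))
          rownames(ch) <- NULL
          mods[[mod]] <- list(channel_names = c("x", "y", "z"), fs = fs,
                              samples = ch)
        } else if (mod %in% c("wrist_acc", "wrist_gyro")) {
          ch <- t(sapply(1:3, function(ax) {
            if (wrist_trembles)
              inertial_channel(t, fog, gait_f, freeze_f,
                               params$fog_amplitude_ratio,
                               params$noise_sd[["inertial"]],
                               base_amp = 0.7)
            else {
              # attenuation: arm swing nearly disappears during FOG
              w <- inertial_channel(t, rep(FALSE, length(t)), gait_f, freeze_f,
                                    1e-3, params$noise_sd[["inertial"]],
                                    base_amp = 0.7)
              ifelse(fog, 0.2 * w, w)
            }
          }))
          rownames(ch) <- NULL
          mods[[mod]] <- list(channel_names = c("x", "y", "z"), fs = fs,
                              samples = ch)
        } else if (mod == "eeg") {
          ch <- t(sapply(eeg_electrodes, function(el)
            eeg_channel(t, fog, el, params$eeg_fog_band_shift,
                        params$noise_sd[["eeg"]])))
          mods[[mod]] <- list(channel_names = eeg_electrodes, fs = fs,
                              samples = ch)
        } else if (mod == "sc") {
          ch <- matrix(sc_channel(t, episodes, params$sc_phasic_gain,
                                  params$noise_sd[["sc"]]), nrow = 1)
          mods[[mod]] <- list(channel_names = "sc", fs = fs, samples = ch)
        }
      }
      recs[[k]] <- structure(list(subject_id = subject_id, task_id = task_id,
                                  duration_s = params$task_duration_s,
                                  modalities = mods),
                             class = "fog_recording")
      if (nrow(episodes) > 0)
        anns[[length(anns) + 1]] <- data.frame(subject_id = subject_id,
                                               task_id = task_id,
                                               start_s = episodes$start_s,
                                               end_s = episodes$end_s)
    }
    annotations <- if (length(anns)) do.call(rbind, anns)
    else data.frame(subject_id = character(0), task_id = character(0),
                    start_s = numeric(0), end_s = numeric(0))
    rownames(annotations) <- NULL
    list(recordings = recs, annotations = annotations)
  })
}

#' Simulate a full synthetic cohort
#'
#' @param params A \code{\link{cohort_params}} object.
#' @return List with \code{recordings} (length \code{n_subjects x
#'   tasks_per_subject}) and a cohort-level \code{annotations} data frame.
#' @export
simulate_cohort <- function(params) {
  validate_params(params)
  recs <- list(); anns <- list()
  for (i in seq_len(params$n_subjects)) {
    s <- simulate_subject(params, i)
    recs <- c(recs, s$recordings)
    anns[[i]] <- s$annotations
  }
  annotations <- do.call(rbind, anns)
  rownames(annotations) <- NULL
  list(recordings = recs, annotations = annotations)
}

#' @export
print.fog_recording <- function(x, ...) {
  cat(sprintf("<fog_recording> subject %s task %s (%.1f s)\n",
              x$subject_id, x$task_id, x$duration_s))
  for (mod in names(x$modalities)) {
    m <- x$modalities[[mod]]
    cat(sprintf("  %-10s %2d ch @ %g Hz, %d samples\n", mod,
                nrow(m$samples), m$fs, ncol(m$samples)))
  }
  invisible(x)
}

# --- disk layout ------------------------------------------------------------

#' Write a cohort to a directory of delimited-text files
#'
#' One directory per subject/task with a CSV per modality (columns =
#' channels), a JSON manifest (channel names, sampling rates, units) and a
#' cohort-level \code{annotations.csv}.
#'
#' @param cohort List as returned by \code{\link{simulate_cohort}}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$recordings) {
    d <- file.path(dir, paste(rec$subject_id, rec$task_id, sep = "_"))
    dir.create(d, showWarnings = FALSE)
    manifest <- list(subject_id = rec$subject_id, task_id = rec$task_id,
                     duration_s = rec$duration_s,
                     processed = isTRUE(rec$processed),
                     modalities = lapply(rec$modalities, function(m)
                       list(channel_names = m$channel_names, fs = m$fs,
                            units = "a.u.")))
    jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (mod in names(rec$modalities)) {
      m <- rec$modalities[[mod]]
      df <- as.data.frame(t(m$samples))
      names(df) <- m$channel_names
      write.csv(df, file.path(d, paste0(mod, ".csv")), row.names = FALSE)
    }
  }
  write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir Directory produced by \code{\link{write_cohort}}.
#' @return List with \code{recordings} and \code{annotations}.
#' @export
read_cohort <- function(dir) {
  dirs <- list.dirs(dir, recursive = FALSE)
  recs <- lapply(dirs, function(d) {
    manifest <- jsonlite::read_json(file.path(d, "manifest.json"),
                                    simplifyVector = TRUE)
    mods <- lapply(names(manifest$modalities), function(mod) {
      mm <- manifest$modalities[[mod]]
      df <- read.csv(file.path(d, paste0(mod, ".csv")), check.names = FALSE)
      list(channel_names = mm$channel_names, fs = mm$fs,
           samples = t(as.matrix(df)))
    })
    names(mods) <- names(manifest$modalities)
    structure(list(subject_id = manifest$subject_id,
                   task_id = manifest$task_id,
                   duration_s = manifest$duration_s,
                   processed = isTRUE(manifest$processed),
                   modalities = mods),
              class = "fog_recording")
  })
  annotations <- read.csv(file.path(dir, "annotations.csv"))
  list(recordings = recs, annotations = annotations)
}
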