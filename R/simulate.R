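#' @include preprocess.R
NULL

#' Default simulator profiles for the six activities
#'
#' One [ActivityProfile] per class, chosen once for plausibility and
#' class structure rather than fitted to any subject:
#' \itemize{
#'   \item The three gait activities are periodic with distinct
#'     fundamental frequencies (walking 1.8 Hz, upstairs 1.4 Hz,
#'     downstairs 2.2 Hz), harmonic content and amplitude patterns, plus
#'     a matching periodic gyroscope component.
#'   \item Sitting and standing share the gravity orientation (y down)
#'     and differ only in noise scale and a small sway-amplitude offset —
#'     they are deliberately confusable, mirroring how similar the two
#'     postures look to a waist-worn sensor.
#'   \item Laying has gravity rotated off the y axis (device on its back)
#'     and a distinct, slightly livelier gyroscope signature.
#' }
#' Postures sway at a fixed 0.3 Hz instead of a gait frequency.
#'
#' @return Named list of six \linkS4class{ActivityProfile}s.
#' @export
defaultProfiles <- function() {
  prof <- function(label, name, gaitFreq, accelAmp, harmonics, gravity,
                   gyroAmp, noiseSd, gyroNoiseSd, driftSd) {
    gravity <- gravity / sqrt(sum(gravity^2))
    new("ActivityProfile", label = as.integer(label), name = name,
        gaitFreq = gaitFreq, accelAmp = accelAmp, harmonics = harmonics,
        gravity = gravity, gyroAmp = gyroAmp, noiseSd = noiseSd,
        gyroNoiseSd = gyroNoiseSd, driftSd = driftSd)
  }
  list(
    walking = prof(1, "walking", 1.8, c(0.10, 0.25, 0.15),
                   c(1, 0.5, 0.2), c(0, 1, 0), 40, 0.030, 3.0, 0.010),
    walking_upstairs = prof(2, "walking_upstairs", 1.4, c(0.12, 0.30, 0.10),
                            c(1, 0.35, 0.15), c(0, 1, 0), 50, 0.035, 4.0,
                            0.010),
    walking_downstairs = prof(3, "walking_downstairs", 2.2,
                              c(0.15, 0.35, 0.12), c(1, 0.6, 0.3),
                              c(0, 1, 0), 60, 0.040, 5.0, 0.010),
    sitting = prof(4, "sitting", 0, c(0.003, 0.003, 0.003), c(1, 0, 0),
                   c(0, 1, 0), 0, 0.006, 0.4, 0.002),
    standing = prof(5, "standing", 0, c(0.015, 0.008, 0.015), c(1, 0, 0),
                    c(0, 1, 0), 0, 0.018, 1.2, 0.003),
    laying = prof(6, "laying", 0, c(0.005, 0.004, 0.005), c(1, 0, 0),
                  c(0, 0.2, 0.98), 0, 0.010, 1.5, 0.002)
  )
}

STATIC_SWAY_HZ <- 0.3
AXIS_PHASES <- c(0, pi / 2, pi / 4)
GYRO_AXIS_WEIGHTS <- c(1, 0.6, 0.8)

# Slow baseline wander: a centered random walk rescaled to sd `driftSd`.
slowDrift <- function(n, driftSd) {
  if (driftSd <= 0 || n < 2L) return(numeric(n))
  w <- cumsum(rnorm(n))
  w <- w - mean(w)
  s <- sd(w)
  if (s < 1e-12) return(numeric(n))
  w / s * driftSd
}

#' Generate a synthetic six-axis recording
#'
#' Accelerometer: gravity (1 g along the profile orientation) plus a
#' harmonic gait (or slow sway) waveform, Gaussian noise and slow
#' baseline wander. Gyroscope: a periodic angular-rate component at the
#' gait frequency plus noise (near-zero mean for postures).
#' Inter-subject variation is modelled as a multiplicative amplitude
#' jitter ~ N(1, 0.05^2) seeded from (seed, participant) only, so a
#' participant's "style" is consistent across activities. The stream is
#' deterministic given (seed, participant, class).
#'
#' @param profile an \linkS4class{ActivityProfile}.
#' @param durationS recording duration in seconds (>= one window).
#' @param participant participant id (numeric or string; hashed into the
#'   seed).
#' @param seed global seed.
#' @param samplingRate samples per second (default 50).
#' @param smooth apply a 5 Hz low-pass (moving-average) emulating the
#'   sensor's on-chip filter; off by default since the analyzed device
#'   data were unfiltered.
#' @return A labelled \linkS4class{SixAxisRecording}.
#' @export
generateRecording <- function(profile, durationS, participant = 1L,
                              seed = 1L, samplingRate = 50, smooth = FALSE) {
  stopifnot(is(profile, "ActivityProfile"))
  if (durationS <= 0) stop("duration must be positive")
  n <- as.integer(round(durationS * samplingRate))
  if (n < 1L) stop("duration must cover at least one sample")
  pid <- if (is.numeric(participant)) participant else
    sum(utf8ToInt(as.character(participant)))
  jitter <- withr_seed(deriveSeed(seed, pid), abs(rnorm(1, 1, 0.05)))

  withr_seed(deriveSeed(seed, pid, profile@label), {
    t <- (seq_len(n) - 1L) / samplingRate
    f0 <- if (profile@gaitFreq > 0) profile@gaitFreq else STATIC_SWAY_HZ
    accel <- matrix(0, n, 3L)
    for (ax in 1:3) {
      w <- numeric(n)
      for (h in seq_along(profile@harmonics))
        if (profile@harmonics[h] != 0)
          w <- w + profile@harmonics[h] *
            sin(2 * pi * h * f0 * t + AXIS_PHASES[ax])
      accel[, ax] <- profile@gravity[ax] +
        jitter * profile@accelAmp[ax] * w +
        rnorm(n, 0, profile@noiseSd) +
        slowDrift(n, profile@driftSd)
    }
    gyro <- matrix(0, n, 3L)
    for (ax in 1:3) {
      periodic <- if (profile@gyroAmp > 0)
        jitter * profile@gyroAmp * GYRO_AXIS_WEIGHTS[ax] *
          sin(2 * pi * f0 * t + AXIS_PHASES[ax] + pi / 6)
      else 0
      gyro[, ax] <- periodic + rnorm(n, 0, profile@gyroNoiseSd)
    }
    sig <- cbind(accel, gyro)
    if (smooth) sig <- apply(sig, 2L, lowpassMA, samplingRate = samplingRate)
    SixAxisRecording(sig, samplingRate = samplingRate,
                     participant = as.character(participant),
                     source = "synthetic",
                     labels = profile@label)
  })
}

# Crude 5 Hz low-pass: centered moving average over samplingRate/10
# samples (10 Hz first null, ~5 Hz half-power) — a stand-in for the
# sensor's on-chip DLPF, not a calibrated filter.
lowpassMA <- function(x, samplingRate) {
  w <- max(3L, as.integer(round(samplingRate / 10)))
  if (w %% 2L == 0L) w <- w + 1L
  kern <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, kern, sides = 2))[(pad + 1L):(pad + length(x))]
}

#' Recording protocol for the synthetic dataset
#'
#' Defaults mirror the device campaign: 21 participants, 110 windows per
#' participant per activity, 50 Hz, 3-s windows — 21 x 6 x 110 = 13,860
#' windows of 150 x 6 samples (900 features when flattened).
#'
#' @param nParticipants number of participants.
#' @param windowsPerParticipant windows per participant per activity.
#' @param samplingRate samples per second.
#' @param windowSeconds window duration.
#' @param overlap fractional window overlap (default 0: back-to-back
#'   windows).
#' @param seed global seed.
#' @return A list of class `"ProtocolSpec"`.
#' @export
protocolSpec <- function(nParticipants = 21L, windowsPerParticipant = 110L,
                         samplingRate = 50, windowSeconds = 3,
                         overlap = 0, seed = 1L) {
  stopifnot(nParticipants >= 1L, windowsPerParticipant >= 1L,
            samplingRate > 0, windowSeconds > 0, overlap >= 0, overlap < 1)
  structure(list(nParticipants = as.integer(nParticipants),
                 windowsPerParticipant = as.integer(windowsPerParticipant),
                 samplingRate = samplingRate, windowSeconds = windowSeconds,
                 overlap = overlap, seed = as.integer(seed)),
            class = "ProtocolSpec")
}

#' Generate a labelled synthetic window set
#'
#' Runs [generateRecording()] for every (participant, activity) pair of
#' the protocol and segments the streams into windows. With the defaults
#' this reproduces the 13,860 x 900 geometry of the device campaign,
#' balanced by class (2,310 windows each) and participant (660 each).
#'
#' @param protocol a [protocolSpec()].
#' @param profiles activity profiles; defaults to [defaultProfiles()].
#' @param smooth passed to [generateRecording()].
#' @return A \linkS4class{WindowSet}.
#' @export
#' @examples
#' ws <- generateDataset(protocolSpec(nParticipants = 2,
#'                                    windowsPerParticipant = 10))
#' classCounts(ws)
generateDataset <- function(protocol = protocolSpec(),
                            profiles = defaultProfiles(), smooth = FALSE) {
  L <- as.integer(round(protocol$windowSeconds * protocol$samplingRate))
  stride <- max(1L, as.integer(round(L * (1 - protocol$overlap))))
  # duration long enough for exactly windowsPerParticipant windows
  nSamples <- L + (protocol$windowsPerParticipant - 1L) * stride
  durationS <- nSamples / protocol$samplingRate
  sets <- list()
  for (p in seq_len(protocol$nParticipants)) {
    for (prof in profiles) {
      rec <- generateRecording(prof, durationS, participant = p,
                               seed = protocol$seed,
                               samplingRate = protocol$samplingRate,
                               smooth = smooth)
      ws <- segmentRecording(rec, protocol$windowSeconds, protocol$overlap)
      ws <- ws[, seq_len(min(ncol(ws), protocol$windowsPerParticipant))]
      sets[[length(sets) + 1L]] <- ws
    }
  }
  combineWindowSets(sets)
}
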