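# Amplitude-threshold syllable segmentation and gap/amplitude measurement.
#
# The envelope convention follows the field's standard recipe: rectify the
# waveform, smooth with a 5 ms square (moving-average) window, and resample
# to 1 kHz. Syllables are maximal above-threshold runs; runs separated by
# less than 5 ms of silence are merged, since a syllable is by definition
# bounded by >= 5 ms of silence.

#' Compute an amplitude envelope
#'
#' Rectifies the waveform, smooths with a centred 5 ms square window
#' (reflect-padded at the edges), and resamples to 1 kHz by linear
#' interpolation at millisecond-bin centres.
#'
#' @param samples Numeric waveform.
#' @param rate Sampling rate in Hz (at least 8 kHz).
#' @param out_rate Output envelope rate, canonically 1000 Hz.
#' @param smooth_ms Width of the square smoothing window in ms.
#' @return An object of class `"song_envelope"`: list with `values`
#'   (non-negative amplitudes, one per output sample) and `rate`.
#' @export
compute_envelope <- function(samples, rate, out_rate = 1000, smooth_ms = 5) {
  if (length(samples) == 0) abort("empty waveform")
  if (rate < 8000) abort("sampling rate must be at least 8 kHz")
  rect <- abs(samples)
  win <- max(1L, round(rate * smooth_ms / 1000))
  if (win > 1L) {
    half <- ceiling(win / 2)
    padded <- c(rev(rect[seq_len(min(half, length(rect)))]),
                rect,
                rev(rect[seq.int(max(1L, length(rect) - half + 1L), length(rect))]))
    sm <- stats::filter(padded, rep(1 / win, win), sides = 2)
    sm <- as.numeric(sm)[half + seq_along(rect)]
  } else {
    sm <- rect
  }
  dur <- length(samples) / rate
  n_out <- ceiling(dur * out_rate)
  centres <- (seq_len(n_out) - 0.5) / out_rate
  vals <- approx(x = (seq_along(rect) - 0.5) / rate, y = sm,
                 xout = centres, rule = 2)$y
  structure(list(values = vals, rate = out_rate), class = "song_envelope")
}

#' @export
print.song_envelope <- function(x, ...) {
  cat(sprintf("<song_envelope> %d samples at %g Hz (%.3f s), peak %.4g\n",
              length(x$values), x$rate, length(x$values) / x$rate,
              max(x$values)))
  invisible(x)
}

#' Segment syllables from an envelope
#'
#' Maximal runs above `threshold` are candidate syllables; above-threshold
#' runs separated by below-threshold runs shorter than `min_silent_ms` are
#' merged (a syllable is bounded by at least 5 ms of silence); candidates
#' shorter than `min_syllable_ms` are discarded. Intervals are half-open
#' `[onset, offset)` in seconds. With `refine = TRUE` boundaries are placed
#' at the linearly interpolated threshold crossing between envelope samples,
#' giving sub-sample resolution.
#'
#' @param envelope A `"song_envelope"` (or numeric vector, assumed 1 kHz).
#' @param threshold Absolute amplitude threshold (> 0); see
#'   [corpus_threshold()] for the fraction-of-peak default.
#' @param min_silent_ms Minimum silent interval separating syllables (ms).
#' @param min_syllable_ms Minimum syllable duration (ms).
#' @param refine Interpolate boundary crossings between samples.
#' @return Tibble with `onset_s` and `offset_s`, one row per syllable
#'   (zero rows if the envelope never exceeds the threshold).
#' @export
segment_syllables <- function(envelope, threshold, min_silent_ms = 5,
                              min_syllable_ms = 10, refine = TRUE) {
  if (is.numeric(envelope)) {
    envelope <- structure(list(values = envelope, rate = 1000),
                          class = "song_envelope")
  }
  stopifnot(inherits(envelope, "song_envelope"))
  if (threshold <= 0) abort("threshold must be positive")
  v <- envelope$values
  rate <- envelope$rate
  above <- v > threshold
  if (!any(above)) return(tibble(onset_s = numeric(0), offset_s = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # merge short silent runs (interior only)
  min_sil_n <- min_silent_ms / 1000 * rate
  interior <- which(!r$values & seq_along(r$values) > 1 &
                      seq_along(r$values) < length(r$values))
  keep_sil <- interior[r$lengths[interior] >= min_sil_n]
  # rebuild runs: boundaries between syllable groups occur at kept silences
  on_idx <- which(r$values)
  groups <- findInterval(on_idx, keep_sil) + 1L
  seg <- vapply(split(on_idx, groups), function(ix) {
    c(starts[ix[1]], ends[ix[length(ix)]])
  }, numeric(2))
  onset_i <- unname(seg[1, ])
  offset_i <- unname(seg[2, ])
  dur_ms <- (offset_i - onset_i + 1L) / rate * 1000
  keep <- dur_ms >= min_syllable_ms
  onset_i <- onset_i[keep]; offset_i <- offset_i[keep]
  onset_s <- (onset_i - 1) / rate
  offset_s <- offset_i / rate
  if (refine) {
    for (k in seq_along(onset_i)) {
      i <- onset_i[k]
      if (i > 1 && v[i] > v[i - 1]) {
        frac <- (threshold - v[i - 1]) / (v[i] - v[i - 1])
        onset_s[k] <- ((i - 1 - 0.5) + frac) / rate
      }
      j <- offset_i[k]
      if (j < length(v) && v[j] > v[j + 1]) {
        frac <- (v[j] - threshold) / (v[j] - v[j + 1])
        offset_s[k] <- ((j - 0.5) + frac) / rate
      }
    }
  }
  tibble(onset_s = onset_s, offset_s = offset_s)
}

#' Corpus-level segmentation threshold
#'
#' The default segmentation threshold is a fraction (10%) of the median
#' syllable peak across a corpus of envelopes. Syllable peaks are found by a
#' provisional segmentation of each envelope at `frac` of its own maximum.
#' Specifying the threshold as a fraction of peak makes gap measurements
#' invariant to global waveform scaling.
#'
#' @param envelopes A list of `"song_envelope"` objects (or numeric vectors).
#' @param frac Fraction of the median syllable peak.
#' @param min_silent_ms,min_syllable_ms Passed to [segment_syllables()].
#' @return A single absolute threshold value.
#' @export
corpus_threshold <- function(envelopes, frac = 0.1, min_silent_ms = 5,
                             min_syllable_ms = 10) {
  if (inherits(envelopes, "song_envelope")) envelopes <- list(envelopes)
  peaks <- unlist(lapply(envelopes, function(e) {
    if (is.numeric(e)) e <- structure(list(values = e, rate = 1000),
                                      class = "song_envelope")
    segs <- segment_syllables(e, frac * max(e$values),
                              min_silent_ms = min_silent_ms,
                              min_syllable_ms = min_syllable_ms, refine = FALSE)
    if (nrow(segs) == 0) return(numeric(0))
    vapply(seq_len(nrow(segs)), function(i) {
      i0 <- max(1L, floor(segs$onset_s[i] * e$rate) + 1L)
      i1 <- min(length(e$values), ceiling(segs$offset_s[i] * e$rate))
      max(e$values[i0:i1])
    }, numeric(1))
  }))
  if (length(peaks) == 0) abort("no syllables found at the provisional threshold")
  frac * median(peaks)
}

#' Measure inter-syllable gaps
#'
#' For every adjacent pair of intervals within a rendition, the gap is the
#' interval from the offset of the first syllable to the onset of the next,
#' in ms. The transition is recorded with its order-1 context (the source
#' label), its order-2 context (previous + source label, `NA` at rendition
#' start) and its target label; attribution to resolved branch points happens
#' downstream (see [transition_timing()]).
#'
#' @param intervals Tibble with at least `rendition_id`, `label`, `onset_s`,
#'   `offset_s`; optional `bird_id`, `condition`, `amplitude` columns are
#'   carried through. Must be time-ordered within renditions.
#' @return Tibble with one row per transition: context columns, `target`,
#'   `gap_ms` and carried identifiers. Negative gaps (overlapping labels)
#'   raise an error.
#' @export
measure_gaps <- function(intervals) {
  req <- c("rendition_id", "label", "onset_s", "offset_s")
  miss <- setdiff(req, names(intervals))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  d <- intervals
  grp_cols <- intersect(c("bird_id", "condition"), names(d))
  d <- d[do.call(order, d[c(grp_cols, "rendition_id", "onset_s")]), ]
  n <- nrow(d)
  if (n < 2) {
    return(tibble(rendition_id = character(0), context = character(0),
                  context2 = character(0), target = character(0),
                  gap_ms = numeric(0)))
  }
  gid <- do.call(paste, c(d[c(grp_cols, "rendition_id")], sep = "\r"))
  same <- gid[-1] == gid[-n]
  gap_ms <- (d$onset_s[-1] - d$offset_s[-n]) * 1000
  bad <- same & gap_ms < 0
  if (any(bad)) {
    abort(sprintf("negative gap (overlapping syllables) at rendition %s, rows %s: corrupt labels",
                  d$rendition_id[-1][bad][1],
                  paste(head(which(bad), 5), collapse = ", ")))
  }
  out <- tibble(
    rendition_id = d$rendition_id[-n][same],
    context = d$label[-n][same],
    target = d$label[-1][same],
    gap_ms = gap_ms[same]
  )
  # previous-within-rendition label for the source syllable
  src_pos <- which(same)                       # row index of source syllable
  prev_lab <- rep(NA_character_, length(src_pos))
  has_prev <- src_pos > 1 & c(FALSE, same)[src_pos]
  prev_lab[has_prev] <- d$label[src_pos[has_prev] - 1L]
  out$context2 <- ifelse(is.na(prev_lab), NA_character_,
                         paste0(prev_lab, out$context))
  for (cc in grp_cols) out[[cc]] <- d[[cc]][src_pos]
  if ("amplitude" %in% names(d)) out$target_amplitude <- d$amplitude[src_pos + 1L]
  out
}

#' Normalise envelopes across recording epochs and re-measure one gap
#'
#' For comparing gap durations across recordings made years apart (e.g. young
#' vs older adult), per-instance envelopes of one branch-point transition are
#' aligned at the branch-point syllable onset, a pointwise median envelope is
#' computed per epoch, each median envelope is rescaled so the branch-point
#' syllable (the syllable transitioned from) has the same peak amplitude, and
#' one common threshold on the normalised traces re-derives the offset/onset
#' pair and hence one gap value per epoch.
#'
#' @param instances_a,instances_b Lists (>= 5 each) of numeric envelopes
#'   (1 kHz unless `rate` says otherwise), each aligned at the branch-point
#'   syllable onset.
#' @param threshold_frac Common threshold as a fraction of the (normalised)
#'   branch-syllable peak.
#' @param ref_peak Reference peak amplitude; defaults to 1.
#' @param rate Envelope rate in Hz.
#' @param min_instances Instance filter (the analysis requires >= 5).
#' @return List of class `"gap_normalization"`: normalised median envelopes,
#'   per-epoch gaps (`gap_a_ms`, `gap_b_ms`) and `gap_change_ms`.
#' @export
normalize_across_recordings <- function(instances_a, instances_b,
                                        threshold_frac = 0.1, ref_peak = 1,
                                        rate = 1000, min_instances = 5) {
  if (length(instances_a) < min_instances || length(instances_b) < min_instances) {
    abort(sprintf("need at least %d instances per epoch", min_instances))
  }
  med_env <- function(insts) {
    len <- min(lengths(insts))
    m <- vapply(insts, function(x) x[seq_len(len)], numeric(len))
    apply(m, 1, median)
  }
  one <- function(env) {
    if (max(env) <= 0) abort("zero peak amplitude in branch-point syllable")
    e <- structure(list(values = env, rate = rate), class = "song_envelope")
    segs <- segment_syllables(e, threshold_frac * max(env), refine = TRUE)
    if (nrow(segs) < 2) abort("fewer than two syllables in the median envelope")
    i0 <- max(1L, floor(segs$onset_s[1] * rate) + 1L)
    i1 <- min(length(env), ceiling(segs$offset_s[1] * rate))
    peak <- max(env[i0:i1])
    if (peak <= 0) abort("zero peak amplitude in branch-point syllable")
    peak
  }
  ma <- med_env(instances_a)
  mb <- med_env(instances_b)
  na <- ma * (ref_peak / one(ma))
  nb <- mb * (ref_peak / one(mb))
  thr <- threshold_frac * ref_peak
  gap_of <- function(env) {
    segs <- segment_syllables(structure(list(values = env, rate = rate),
                                        class = "song_envelope"), thr)
    if (nrow(segs) < 2) abort("common threshold finds fewer than two syllables")
    (segs$onset_s[2] - segs$offset_s[1]) * 1000
  }
  ga <- gap_of(na)
  gb <- gap_of(nb)
  structure(list(envelope_a = na, envelope_b = nb, rate = rate,
                 threshold = thr, gap_a_ms = ga, gap_b_ms = gb,
                 gap_change_ms = gb - ga),
            class = "gap_normalization")
}

#' Root-mean-square amplitude of a syllable
#'
#' RMS of the baseline(silence)-subtracted waveform over the half-open window
#' `[onset_s, offset_s)`.
#'
#' @param samples Numeric waveform.
#' @param rate Sampling rate (Hz).
#' @param onset_s,offset_s Window in seconds.
#' @param baseline Baseline (silence) level subtracted before squaring; see
#'   [baseline_level()].
#' @return RMS amplitude (single number).
#' @export
rms_amplitude <- function(samples, rate, onset_s, offset_s, baseline = 0) {
  if (offset_s <= onset_s) abort("offset must exceed onset")
  i0 <- floor(onset_s * rate) + 1L
  i1 <- ceiling(offset_s * rate)
  if (i0 < 1 || i1 > length(samples)) abort("window outside waveform")
  x <- samples[i0:i1] - baseline
  sqrt(mean(x^2))
}

#' Baseline (silence) level of a rendition
#'
#' Median envelope value over all inter-syllable regions of a rendition.
#'
#' @param envelope A `"song_envelope"` or numeric vector (1 kHz assumed).
#' @param intervals Tibble of syllable intervals (`onset_s`, `offset_s`).
#' @return Median silent-region envelope value (0 if no silent samples).
#' @export
baseline_level <- function(envelope, intervals) {
  if (is.numeric(envelope)) {
    envelope <- structure(list(values = envelope, rate = 1000),
                          class = "song_envelope")
  }
  v <- envelope$values
  silent <- rep(TRUE, length(v))
  for (i in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor(intervals$onset_s[i] * envelope$rate) + 1L)
    i1 <- min(length(v), ceiling(intervals$offset_s[i] * envelope$rate))
    silent[i0:i1] <- FALSE
  }
  if (!any(silent)) return(0)
  median(v[silent])
}

#' Normalise median RMS amplitudes within recording platforms
#'
#' Divides each transition syllable's median RMS by the maximum median RMS of
#' its recording platform, yielding values in (0, 1].
#'
#' @param df Tibble with a median-RMS column and a platform column.
#' @param rms_col,platform_col Column names.
#' @return `df` with an added `rms_norm` column.
#' @export
platform_normalize <- function(df, rms_col = "median_rms",
                               platform_col = "platform") {
  stopifnot(rms_col %in% names(df), platform_col %in% names(df))
  df %>%
    group_by(.data[[platform_col]]) %>%
    mutate(rms_norm = .data[[rms_col]] / max(.data[[rms_col]])) %>%
    ungroup()
}

#' Segment a rendition and attach labels
#'
#' Discovery-mode segmentation of an audio rendition followed by label
#' assignment from a label file: each detected segment takes the label of the
#' reference interval it overlaps most. When labels are provided they win on
#' conflict: reference intervals with no matching segment are kept with their
#' original boundaries.
#'
#' @param samples,rate Waveform and sampling rate.
#' @param labels Tibble from [read_label_file()] (`onset_s`, `offset_s`,
#'   `label`), or `NULL` for pure discovery.
#' @param threshold Absolute envelope threshold.
#' @param ... Passed to [segment_syllables()].
#' @return Tibble of labelled intervals (`label`, `onset_s`, `offset_s`).
#' @export
segment_rendition <- function(samples, rate, labels = NULL, threshold, ...) {
  env <- compute_envelope(samples, rate)
  segs <- segment_syllables(env, threshold, ...)
  if (is.null(labels)) {
    segs$label <- NA_character_
    return(segs[, c("label", "onset_s", "offset_s")])
  }
  out <- labels[, c("label", "onset_s", "offset_s")]
  for (i in seq_len(nrow(out))) {
    ov <- pmin(segs$offset_s, out$offset_s[i]) - pmax(segs$onset_s, out$onset_s[i])
    j <- which.max(ov)
    if (length(j) && ov[j] > 0) {
      out$onset_s[i] <- segs$onset_s[j]
      out$offset_s[i] <- segs$offset_s[j]
    }
  }
  out
}
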