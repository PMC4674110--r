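# Shared fixtures: tiny grammars and event builders used across test files.

# Build an event table from label strings, one string per rendition.
# Gaps default to 50 ms; `gaps` may be a list of per-rendition gap vectors.
events_from_strings <- function(renditions, bird_id = "bird01",
                                condition = "A", gaps = NULL,
                                syllable_s = 0.08) {
  out <- list()
  for (i in seq_along(renditions)) {
    labs <- strsplit(renditions[i], "")[[1]]
    n <- length(labs)
    g <- if (is.null(gaps)) rep(50, max(n - 1, 0)) else gaps[[i]]
    onset <- 0.05 + cumsum(c(0, g / 1000 + syllable_s))
    out[[i]] <- tibble::tibble(
      bird_id = bird_id, condition = condition,
      rendition_id = sprintf("r%03d", i),
      position = seq_len(n), label = labs,
      onset_s = onset, offset_s = onset + syllable_s,
      gap_to_next_ms = c(g, NA_real_)
    )
  }
  dplyr::bind_rows(out)
}

# Minimal single-bird looping grammar with one 90/10 branch point ('a') and
# a 5% chance of song termination per cycle.
loop_branch_config <- function(seed = 1, renditions = 100, ...) {
  song_config(
    n_birds = 1, renditions_per_bird = renditions,
    branch_specs = list(a = c(f = 0.855, k = 0.095, "*" = 0.05)),
    stereotyped_chains = c("ea", "fe", "ke"),
    bird_concentration = Inf,
    start_label = "e",
    seed = seed, ...
  )
}

# A small multi-bird configuration for fast pipeline tests.
small_config <- function(seed = 1, n_birds = 6, renditions = 20, ...) {
  song_config(n_birds = n_birds, renditions_per_bird = renditions,
              seed = seed, ...)
}

# Balanced coupling rows with zero random-effect variance: every bird sees
# the same predictor design, so the mixed-model fixed effects must agree
# with ordinary least squares.
balanced_rows <- function(n_birds = 6, noise_sd = 0.05, seed = 99,
                          slope = -0.3, intercept = 2.1) {
  set.seed(seed)
  p_levels <- seq(0.1, 0.9, by = 0.2)
  # two transitions per sequence, as branch points have multiple targets;
  # p varies between sequences only, so the design is fully balanced and
  # generalised least squares coincides with ordinary least squares
  d <- expand.grid(bird = seq_len(n_birds), seq = seq_along(p_levels),
                   target = c("x", "y"))
  d$p <- p_levels[d$seq]
  noise <- rnorm(nrow(d), 0, noise_sd)
  tibble::tibble(
    bird_id = sprintf("bird%02d", d$bird),
    sequence_id = sprintf("seq%02d", d$seq),
    target = d$target,
    p = d$p,
    log10_gap = intercept + slope * d$p + noise
  )
}
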