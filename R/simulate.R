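# Synthetic Bengalese-finch-like song corpora with full ground truth.
#
# A corpus is generated by walking a (possibly history-dependent) transition
# graph assembled from stereotyped chains (pairwise transitions at p = 1) and
# branch points (categorical target draws). Per-instance silent gaps follow
#   log10(gap_ms) = intercept + slope * p + u_bird + v_sequence + eps,
# where p is the termination-excluded probability of the transition taken,
# so the inverse sequencing/timing coupling is built in with known truth.

#' Default branch-point grammar
#'
#' A small song grammar with four analysable branch points (2-3 targets each),
#' a dedicated terminal state, and song terminations from two of the branch
#' points via the reserved end token.
#'
#' @param end_token Reserved label marking song termination.
#' @return Named list mapping context labels to named probability vectors.
#' @export
default_branch_specs <- function(end_token = "*") {
  list(
    d = c(e = 0.55, g = 0.45),
    a = c(f = 0.90, k = 0.10),
    f = setNames(c(0.66, 0.30, 0.04), c("g", "m", end_token)),
    j = setNames(c(0.53, 0.42, 0.05), c("b", "e", end_token)),
    m = setNames(1.0, end_token)
  )
}

#' Configuration for the synthetic song generator
#'
#' Bundles and validates every tunable of the generator: corpus size, the
#' transition grammar, the gap-duration model, the amplitude model, optional
#' paired-condition effects, and waveform rendering parameters. Defaults
#' emulate a study-scale corpus: 22 birds with 30 renditions each, branch
#' points with 2-3 targets, stereotyped chains, and an inverse coupling
#' between transition probability and log10 gap duration (slope -0.240).
#'
#' @param n_birds Number of birds.
#' @param renditions_per_bird Song renditions recorded per bird.
#' @param branch_specs Named list: context label(s) (one or two characters,
#'   two-character names define history-dependent contexts) to named vectors of
#'   target probabilities (must sum to 1). The reserved `end_token` as a target
#'   denotes song termination.
#' @param stereotyped_chains Character vector of label sequences; each adjacent
#'   pair becomes a deterministic (p = 1) transition.
#' @param gap_model List with `intercept` (log10 ms), `slope` (log10 ms per
#'   unit probability), and `bird_sd`, `sequence_sd`, `residual_sd` (log10 ms).
#' @param amplitude_model List with `base` (scalar or named per-label peak
#'   amplitude), `coupling` (log10 amplitude per unit probability) and
#'   `noise_sd` (log10 units).
#' @param condition_effect Optional list describing a paired condition "B":
#'   `mode` one of `"coupled"`, `"decoupled"`, `"null"`; `gap_factor`
#'   (multiplicative gap change, default 0.95); `couple_slope` (log10 gap
#'   change per unit probability change, coupled mode, default -0.4);
#'   `prob_shift_sd` (sd of random per-bird probability shifts) or explicit
#'   `prob_shifts` (named list context -> named shift vector summing to 0);
#'   `change_bird_sd`, `change_sequence_sd` (extra random change components).
#' @param waveform List with `sample_rate` (Hz), `syllable_ms`, `ramp_ms`
#'   (raised-cosine edge), `carrier_hz`, `noise_floor` (additive white-noise
#'   sd, linear amplitude units).
#' @param bird_concentration Dirichlet concentration multiplier for per-bird
#'   branch probabilities; `Inf` disables between-bird variation.
#' @param start_label First syllable of every rendition.
#' @param end_token Reserved termination label.
#' @param max_syllables Hard cap on rendition length.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return A validated list of class `"song_config"`.
#' @export
song_config <- function(n_birds = 22,
                        renditions_per_bird = 30,
                        branch_specs = default_branch_specs(),
                        stereotyped_chains = c("ib", "bcd", "ea", "kg", "ghj"),
                        gap_model = list(),
                        amplitude_model = list(),
                        condition_effect = NULL,
                        waveform = list(),
                        bird_concentration = 8,
                        start_label = "i",
                        end_token = "*",
                        max_syllables = 200,
                        seed = 1L) {
  gap_model <- modifyList(
    list(intercept = 2.15, slope = -0.240,
         bird_sd = 0.10, sequence_sd = 0.28, residual_sd = 0.25),
    gap_model)
  amplitude_model <- modifyList(
    list(base = 1.0, coupling = 0.2, noise_sd = 0.1),
    amplitude_model)
  waveform <- modifyList(
    list(sample_rate = 32000, syllable_ms = 80, ramp_ms = 4,
         carrier_hz = 3000, noise_floor = 0.005),
    waveform)
  if (!is.null(condition_effect)) {
    condition_effect <- modifyList(
      list(mode = "coupled", gap_factor = 0.95, couple_slope = -0.4,
           prob_shift_sd = 0.18, prob_shifts = NULL,
           change_bird_sd = 0.03, change_sequence_sd = 0.03),
      condition_effect)
    if (!condition_effect$mode %in% c("coupled", "decoupled", "null")) {
      abort("condition_effect$mode must be 'coupled', 'decoupled' or 'null'")
    }
  }
  if (length(branch_specs) == 0 && length(stereotyped_chains) == 0) {
    abort("configuration error: branch_specs and stereotyped_chains are both empty")
  }
  for (ctx in names(branch_specs)) {
    p <- branch_specs[[ctx]]
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      abort(sprintf("branch spec '%s': targets must be named", ctx))
    }
    if (any(p < 0)) abort(sprintf("branch spec '%s': negative probability", ctx))
    if (abs(sum(p) - 1) > 1e-12) {
      abort(sprintf("branch spec '%s': probabilities sum to %.15f, not 1", ctx, sum(p)))
    }
  }
  cfg <- list(
    n_birds = as.integer(n_birds),
    renditions_per_bird = as.integer(renditions_per_bird),
    branch_specs = branch_specs,
    stereotyped_chains = stereotyped_chains,
    gap_model = gap_model,
    amplitude_model = amplitude_model,
    condition_effect = condition_effect,
    waveform = waveform,
    bird_concentration = bird_concentration,
    start_label = start_label,
    end_token = end_token,
    max_syllables = as.integer(max_syllables),
    seed = as.integer(seed)
  )
  class(cfg) <- "song_config"
  # the assembled map is validated here so conflicts fail fast
  .transition_map(cfg)
  cfg
}

# Assemble context -> (targets, probs) map from chains and branch specs.
# Chain pairs are deterministic; a label may be source of exactly one rule.
.transition_map <- function(config) {
  map <- list()
  seq_of <- character(0)  # transition key -> sequence id
  for (chain in config$stereotyped_chains) {
    labs <- strsplit(chain, "")[[1]]
    if (length(labs) < 2) abort(sprintf("chain '%s' has fewer than 2 labels", chain))
    for (i in seq_len(length(labs) - 1)) {
      src <- labs[i]; tgt <- labs[i + 1]
      if (!is.null(map[[src]])) {
        abort(sprintf("label '%s' has conflicting transition rules", src))
      }
      map[[src]] <- setNames(1.0, tgt)
      seq_of[paste0(src, ">", tgt)] <- chain
    }
  }
  for (ctx in names(config$branch_specs)) {
    if (!is.null(map[[ctx]])) {
      abort(sprintf("context '%s' defined by both a chain and a branch spec", ctx))
    }
    map[[ctx]] <- config$branch_specs[[ctx]]
    for (tgt in names(config$branch_specs[[ctx]])) {
      seq_of[paste0(ctx, ">", tgt)] <- ctx
    }
  }
  list(map = map, seq_of = seq_of)
}

# Dirichlet draw around p with concentration kappa (Inf = no jitter).
.jitter_probs <- function(p, kappa) {
  if (!is.finite(kappa) || length(p) < 2) return(p)
  g <- rgamma(length(p), shape = kappa * p, rate = 1)
  if (sum(g) <= 0) return(p)
  setNames(g / sum(g), names(p))
}

# Termination-excluded probability vector for one context.
.p_excl <- function(p, end_token) {
  keep <- names(p) != end_token
  q <- p[keep]
  if (sum(q) <= 0) return(q[0])
  q / sum(q)
}

# Integer-code the grammar once per configuration: label codes, context
# lookup tables and flat rule target arrays for the compiled walk.
.code_grammar <- function(config, tm) {
  map <- tm$map
  ctxs <- names(map)
  lab_set <- unique(c(config$start_label,
                      unlist(strsplit(ctxs, ""), use.names = FALSE),
                      unlist(lapply(map, names), use.names = FALSE)))
  lab_set <- setdiff(lab_set, config$end_token)
  code <- setNames(seq_along(lab_set), lab_set)
  L <- length(lab_set)
  lookup1 <- integer(L)
  lookup2 <- matrix(0L, L, L)
  n_tgt <- lengths(map)
  rule_off <- c(0L, cumsum(n_tgt))
  rule_tgt <- integer(sum(n_tgt))
  for (r in seq_along(ctxs)) {
    ctx <- ctxs[r]
    if (nchar(ctx) == 1L) {
      lookup1[code[[ctx]]] <- r
    } else {
      lookup2[code[[substr(ctx, 1, 1)]], code[[substr(ctx, 2, 2)]]] <- r
    }
    tg <- names(map[[r]])
    tc <- ifelse(tg == config$end_token, 0L, code[tg])
    rule_tgt[rule_off[r] + seq_along(tg)] <- as.integer(tc)
  }
  list(labels = lab_set, code = code, contexts = ctxs,
       lookup1 = lookup1, lookup2 = lookup2,
       rule_off = as.integer(rule_off), rule_tgt = rule_tgt)
}

# Per-bird cumulative probabilities aligned with the coded rule layout.
.rule_cum <- function(coded, map, probs) {
  cum <- numeric(length(coded$rule_tgt))
  for (r in seq_along(coded$contexts)) {
    ctx <- coded$contexts[r]
    p <- if (ctx %in% names(probs)) probs[[ctx]] else map[[ctx]]
    p <- p[names(map[[ctx]])]          # align with the coded target order
    idx <- (coded$rule_off[r] + 1L):coded$rule_off[r + 1L]
    cum[idx] <- cumsum(p) / sum(p)
  }
  cum
}

# Walk all renditions of one bird (compiled kernel) and decode the result
# into flat label / generating-context vectors ordered by rendition.
.walk_bird <- function(coded, rule_cum, n_rend, start_label, max_syllables) {
  res <- .cpp_walk(n_rend, max_syllables, coded$code[[start_label]],
                   coded$lookup1, coded$lookup2,
                   coded$rule_off, coded$rule_tgt, rule_cum)
  list(
    labels = coded$labels[res$labels],
    gctx = c(NA_character_, coded$contexts)[res$ctxrule + 1L],
    rend_idx = rep(seq_len(n_rend), res$lengths),
    position = sequence(res$lengths)
  )
}

# Generate the event table for one bird under one condition.
# p_gap: named vector keyed "ctx>tgt" of probabilities used in the gap model;
# gap_shift: optional named per-transition-key additive log10 shift.
.bird_events <- function(config, tm, bird_id, condition, rendition_prefix,
                         p_gap, u_bird, v_seq, walk, gap_shift = NULL) {
  gm <- config$gap_model
  am <- config$amplitude_model
  syl_s <- config$waveform$syllable_ms / 1000
  labels <- walk$labels
  gctx <- walk$gctx
  position <- walk$position
  rend_idx <- walk$rend_idx
  n <- length(labels)
  tkey <- ifelse(is.na(gctx), NA_character_, paste0(gctx, ">", labels))
  p_in <- unname(p_gap[tkey])            # NA for rendition-initial syllables
  seq_in <- unname(tm$seq_of[tkey])

  # incoming gap per syllable (NA for first of a rendition)
  mu <- gm$intercept + gm$slope * p_in + u_bird + unname(v_seq[seq_in])
  if (!is.null(gap_shift)) {
    sh <- unname(gap_shift[tkey])
    sh[is.na(sh)] <- 0
    mu <- mu + sh
  }
  gap_in <- 10^(mu + rnorm(n, 0, gm$residual_sd))

  base <- am$base
  base_lab <- if (length(base) > 1 || !is.null(names(base))) {
    b <- unname(base[labels]); b[is.na(b)] <- 1; b
  } else rep(base, n)
  p_eff <- ifelse(is.na(p_in), 0.5, p_in)
  # amplitude noise is truncated at 2.5 sd: syllables have a finite dynamic
  # range (about 4x here at the default sd)
  amp_noise <- pmin(pmax(rnorm(n, 0, am$noise_sd), -2.5 * am$noise_sd),
                    2.5 * am$noise_sd)
  amplitude <- 10^(log10(base_lab) + am$coupling * (p_eff - 0.5) + amp_noise)

  first <- c(TRUE, rend_idx[-1] != rend_idx[-n])
  gap_in[first] <- NA_real_
  # onsets: cumulative within rendition (first step is the 50 ms lead-in)
  step_s <- syl_s + gap_in / 1000
  step_s[first] <- 0.05
  onset <- ave(step_s, rend_idx, FUN = cumsum)
  offset <- onset + syl_s

  last <- c(rend_idx[-1] != rend_idx[-n], TRUE)
  gap_next <- c(gap_in[-1], NA_real_)
  gap_next[last] <- NA_real_
  p_next <- c(p_in[-1], NA_real_); p_next[last] <- NA_real_
  seq_next <- c(seq_in[-1], NA_character_); seq_next[last] <- NA_character_
  ctx_next <- c(gctx[-1], NA_character_); ctx_next[last] <- NA_character_

  list(
    bird_id = rep(bird_id, n),
    condition = rep(condition, n),
    rendition_id = paste0(rendition_prefix, "_r",
                          formatC(rend_idx, width = 3, flag = "0")),
    position = as.integer(position),
    label = labels,
    onset_s = onset,
    offset_s = offset,
    amplitude = amplitude,
    gap_to_next_ms = gap_next,
    p_to_next = p_next,
    context_to_next = ctx_next,
    sequence_to_next = seq_next
  )
}

# rbind a list of .bird_events() results into one events tibble
.bind_events <- function(parts) {
  fields <- names(parts[[1]])
  as_tibble(setNames(lapply(fields, function(f) {
    unlist(lapply(parts, `[[`, f), use.names = FALSE)
  }), fields))
}

# Per-bird structural draws shared by both generator entry points.
.bird_params <- function(config, tm) {
  probs <- config$branch_specs
  for (ctx in names(probs)) {
    probs[[ctx]] <- .jitter_probs(probs[[ctx]], config$bird_concentration)
  }
  seq_ids <- unique(unname(tm$seq_of))
  list(
    probs = probs,
    u = rnorm(1, 0, config$gap_model$bird_sd),
    v = setNames(rnorm(length(seq_ids), 0, config$gap_model$sequence_sd), seq_ids)
  )
}

# Build the "ctx>tgt" -> termination-excluded probability lookup for one bird.
.p_lookup <- function(config, tm, probs) {
  out <- numeric(0)
  map <- tm$map
  for (ctx in names(map)) {
    p <- if (ctx %in% names(probs)) probs[[ctx]] else map[[ctx]]
    pe <- .p_excl(p, config$end_token)
    if (length(pe)) out[paste0(ctx, ">", names(pe))] <- pe
  }
  out
}

.truth_probs <- function(config, tm, bird_id, condition, probs) {
  ctx_v <- character(0); tgt_v <- character(0)
  spec_v <- numeric(0); true_v <- numeric(0)
  for (ctx in names(tm$map)) {
    p_spec <- tm$map[[ctx]]
    p_bird <- if (ctx %in% names(probs)) probs[[ctx]] else p_spec
    pe_spec <- .p_excl(p_spec, config$end_token)
    pe_bird <- .p_excl(p_bird, config$end_token)
    if (!length(pe_bird)) next
    ctx_v <- c(ctx_v, rep(ctx, length(pe_bird)))
    tgt_v <- c(tgt_v, names(pe_bird))
    spec_v <- c(spec_v, unname(pe_spec[names(pe_bird)]))
    true_v <- c(true_v, unname(pe_bird))
  }
  tibble(bird_id = bird_id, condition = condition, context = ctx_v,
         target = tgt_v, p_spec = spec_v, p_true = true_v,
         sequence_id = unname(tm$seq_of[paste0(ctx_v, ">", tgt_v)]))
}

#' Generate a synthetic song corpus
#'
#' Walks every rendition through the configured transition graph and draws
#' per-instance gap durations and syllable amplitudes from the configured
#' models. All randomness derives from `config$seed` through one root
#' generator with per-bird substreams, so a fixed seed gives byte-identical
#' output.
#'
#' @param config A [song_config()].
#' @return An object of class `"song_corpus"`: a list with `events` (one row
#'   per syllable instance: identifiers, label, nominal onset/offset in
#'   seconds, amplitude, and the true gap, probability, context and sequence
#'   of the outgoing transition), `truth` (per-bird true termination-excluded
#'   transition probabilities, bird and sequence random effects), and
#'   `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "song_config"))
  tm <- .transition_map(config)
  coded <- .code_grammar(config, tm)
  set.seed(config$seed)
  bird_seeds <- sample.int(2147483646L, config$n_birds)
  events <- vector("list", config$n_birds)
  truth_p <- vector("list", config$n_birds)
  u_all <- numeric(config$n_birds)
  v_all <- vector("list", config$n_birds)
  for (b in seq_len(config$n_birds)) {
    set.seed(bird_seeds[b])
    bird_id <- sprintf("bird%02d", b)
    par <- .bird_params(config, tm)
    p_gap <- .p_lookup(config, tm, par$probs)
    walk <- .walk_bird(coded, .rule_cum(coded, tm$map, par$probs),
                       config$renditions_per_bird, config$start_label,
                       config$max_syllables)
    events[[b]] <- .bird_events(config, tm, bird_id, "A",
                                sprintf("b%02d", b), p_gap, par$u, par$v, walk)
    truth_p[[b]] <- .truth_probs(config, tm, bird_id, "A", par$probs)
    u_all[b] <- par$u
    v_all[[b]] <- tibble(bird_id = bird_id, sequence_id = names(par$v),
                         v = unname(par$v))
  }
  structure(list(
    events = .bind_events(events),
    truth = list(
      probabilities = bind_rows(truth_p),
      bird_effects = tibble(bird_id = sprintf("bird%02d", seq_len(config$n_birds)),
                            u = u_all),
      sequence_effects = bind_rows(v_all)
    ),
    config = config
  ), class = "song_corpus")
}

# Shift a termination-excluded probability vector for condition B.
# Random mode: zero-centred normal shifts, clipped and renormalised.
# Explicit shifts: must keep probabilities in [0, 1] (else configuration error).
.shift_probs <- function(pe, shifts, shift_sd) {
  if (length(pe) < 2) return(pe)
  if (!is.null(shifts)) {
    d <- setNames(rep(0, length(pe)), names(pe))
    d[names(shifts)] <- shifts
    out <- pe + d
    if (any(out < 0) || any(out > 1)) {
      abort("configuration error: probability shifts produce values outside [0, 1]")
    }
    return(out / sum(out))
  }
  d <- rnorm(length(pe), 0, shift_sd)
  d <- d - mean(d)
  out <- pmin(pmax(pe + d, 0.02), 0.98)
  setNames(out / sum(out), names(pe))
}

#' Generate a paired-condition synthetic corpus
#'
#' Produces two matched corpora from the same birds: condition "A" (baseline,
#' e.g. young adult or undirected song) and condition "B" with the configured
#' probability shifts and gap changes applied. Bird and sequence random
#' effects are shared between conditions; condition B adds a per-bird and
#' per-sequence random change component. The coupling `mode` controls the
#' expected per-transition log10 gap change:
#' `coupled`: `log10(gap_factor) + couple_slope * delta_p` (age-like),
#' `decoupled`: `log10(gap_factor)` uniformly (context-like),
#' `null`: 0.
#'
#' @param config A [song_config()] with a non-`NULL` `condition_effect`.
#' @param condition_labels Length-2 character vector naming the conditions.
#' @return A `"song_corpus"` whose `events` carry both conditions and whose
#'   `truth$change` table lists, per bird/context/target, the true
#'   probabilities in each condition, `delta_p`, and the configured expected
#'   log10 gap change.
#' @export
generate_condition_pair <- function(config, condition_labels = c("A", "B")) {
  stopifnot(inherits(config, "song_config"))
  ce <- config$condition_effect
  if (is.null(ce)) abort("config$condition_effect must be set for a condition pair")
  stopifnot(length(condition_labels) == 2)
  tm <- .transition_map(config)
  coded <- .code_grammar(config, tm)
  set.seed(config$seed)
  bird_seeds <- sample.int(2147483646L, config$n_birds)
  events <- vector("list", 2L * config$n_birds)
  truth_p <- vector("list", config$n_birds)
  change <- vector("list", config$n_birds)
  for (b in seq_len(config$n_birds)) {
    set.seed(bird_seeds[b])
    bird_id <- sprintf("bird%02d", b)
    par <- .bird_params(config, tm)
    p_gap_a <- .p_lookup(config, tm, par$probs)

    # condition-B probabilities: shift the termination-excluded part, keep
    # the termination share fixed
    probs_b <- par$probs
    for (ctx in names(probs_b)) {
      p <- probs_b[[ctx]]
      pe <- .p_excl(p, config$end_token)
      if (length(pe) < 2) next
      sh <- if (!is.null(ce$prob_shifts)) ce$prob_shifts[[ctx]] else NULL
      pe_b <- .shift_probs(pe, sh, ce$prob_shift_sd)
      p_end <- if (config$end_token %in% names(p)) unname(p[config$end_token]) else 0
      p_new <- pe_b * (1 - p_end)
      if (p_end > 0) p_new <- c(p_new, setNames(p_end, config$end_token))
      probs_b[[ctx]] <- p_new
    }
    p_gap_b <- .p_lookup(config, tm, probs_b)

    # expected change per transition key
    all_keys <- names(p_gap_a)
    delta_p <- p_gap_b[all_keys] - p_gap_a[all_keys]
    exp_d <- switch(ce$mode,
      coupled   = log10(ce$gap_factor) + ce$couple_slope * delta_p,
      decoupled = rep(log10(ce$gap_factor), length(all_keys)),
      null      = rep(0, length(all_keys)))
    exp_d <- setNames(as.numeric(exp_d), all_keys)

    u_chg <- rnorm(1, 0, ce$change_bird_sd)
    v_chg <- setNames(rnorm(length(par$v), 0, ce$change_sequence_sd), names(par$v))
    gap_shift <- exp_d + unname(v_chg[tm$seq_of[all_keys]]) + u_chg
    gap_shift <- setNames(as.numeric(gap_shift), all_keys)

    walk_a <- .walk_bird(coded, .rule_cum(coded, tm$map, par$probs),
                         config$renditions_per_bird, config$start_label,
                         config$max_syllables)
    ev_a <- .bird_events(config, tm, bird_id, condition_labels[1],
                         sprintf("b%02dA", b), p_gap_a, par$u, par$v, walk_a)
    walk_b <- .walk_bird(coded, .rule_cum(coded, tm$map, probs_b),
                         config$renditions_per_bird, config$start_label,
                         config$max_syllables)
    # gaps in B keep the baseline p (p_A) so the only sequencing/timing link
    # is the configured one; amplitudes likewise use baseline probabilities
    ev_b <- .bird_events(config, tm, bird_id, condition_labels[2],
                         sprintf("b%02dB", b), p_gap_a, par$u, par$v, walk_b,
                         gap_shift = gap_shift)
    # record the realised (condition-B) sequencing probability of each
    # outgoing transition; gaps above were drawn from the baseline p_A
    nxt_key <- ifelse(is.na(ev_b$context_to_next), NA_character_,
                      paste0(ev_b$context_to_next, ">",
                             c(ev_b$label[-1], NA_character_)))
    ev_b$p_to_next <- unname(p_gap_b[nxt_key])

    events[[2L * b - 1L]] <- ev_a
    events[[2L * b]] <- ev_b
    truth_p[[b]] <- bind_rows(
      .truth_probs(config, tm, bird_id, condition_labels[1], par$probs),
      .truth_probs(config, tm, bird_id, condition_labels[2], probs_b))
    change[[b]] <- tibble(
      bird_id = bird_id,
      context = sub(">.*$", "", all_keys),
      target = sub("^.*>", "", all_keys),
      sequence_id = unname(tm$seq_of[all_keys]),
      p_a = unname(p_gap_a[all_keys]),
      p_b = unname(p_gap_b[all_keys]),
      delta_p = unname(delta_p),
      expected_dlog10 = unname(exp_d)
    )
  }
  structure(list(
    events = .bind_events(events),
    truth = list(
      probabilities = bind_rows(truth_p),
      change = bind_rows(change),
      condition_labels = condition_labels
    ),
    config = config
  ), class = "song_corpus")
}

#' @export
print.song_corpus <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<song_corpus> %d syllable instances, %d birds, %d renditions, %d condition(s)\n",
              nrow(ev), dplyr::n_distinct(ev$bird_id),
              dplyr::n_distinct(paste(ev$condition, ev$rendition_id)),
              dplyr::n_distinct(ev$condition)))
  invisible(x)
}

#' Render one rendition as an audio waveform
#'
#' Each syllable is a raised-cosine-edged amplitude envelope on a sinusoidal
#' carrier; silent intervals carry only the configured white-noise floor. The
#' returned boundaries are the nominal support of the rendered envelope, so
#' with a zero noise floor all non-zero samples lie inside them.
#'
#' @param labels Character vector of syllable labels.
#' @param gap_ms Numeric vector of silent gaps between consecutive syllables
#'   (length `length(labels) - 1`), all at least 5 ms.
#' @param amplitude Peak amplitude per syllable (recycled if length 1).
#' @param waveform List as in [song_config()] (`sample_rate`, `syllable_ms`,
#'   `ramp_ms`, `carrier_hz`, `noise_floor`).
#' @param pad_s Leading/trailing silence in seconds.
#' @return List of class `"song_waveform"`: `samples`, `sample_rate`, and
#'   `boundaries` (tibble with `label`, `onset_s`, `offset_s`).
#' @export
synthesize_waveform <- function(labels, gap_ms, amplitude = 1,
                                waveform = list(), pad_s = 0.05) {
  wf <- modifyList(list(sample_rate = 32000, syllable_ms = 80, ramp_ms = 4,
                        carrier_hz = 3000, noise_floor = 0.005), waveform)
  n <- length(labels)
  if (n == 0) abort("no syllables to render")
  if (length(gap_ms) != max(n - 1, 0)) {
    abort("gap_ms must have length(labels) - 1 elements")
  }
  if (any(gap_ms < 5)) {
    abort("gap shorter than 5 ms violates the syllable definition (>= 5 ms of silence)")
  }
  amplitude <- rep_len(amplitude, n)
  fs <- wf$sample_rate
  syl_n <- round(wf$syllable_ms / 1000 * fs)
  ramp_n <- round(wf$ramp_ms / 1000 * fs)
  env1 <- rep(1, syl_n)
  if (ramp_n > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(ramp_n) - 0.5) / ramp_n))
    env1[seq_len(ramp_n)] <- r
    env1[syl_n + 1 - seq_len(ramp_n)] <- r
  }
  onsets_s <- pad_s + cumsum(c(0, gap_ms / 1000 + wf$syllable_ms / 1000))
  offsets_s <- onsets_s + wf$syllable_ms / 1000
  total_n <- round((offsets_s[n] + pad_s) * fs)
  samples <- if (wf$noise_floor > 0) rnorm(total_n, 0, wf$noise_floor) else numeric(total_n)
  tvec <- seq_len(syl_n) / fs
  for (i in seq_len(n)) {
    s0 <- round(onsets_s[i] * fs)
    idx <- s0 + seq_len(syl_n)
    carrier <- sin(2 * pi * wf$carrier_hz * (tvec + onsets_s[i]))
    samples[idx] <- samples[idx] + amplitude[i] * env1 * carrier
  }
  structure(list(
    samples = samples,
    sample_rate = fs,
    boundaries = tibble(label = labels, onset_s = onsets_s, offset_s = offsets_s)
  ), class = "song_waveform")
}

#' Render every rendition of a corpus as waveforms
#'
#' @param corpus A `"song_corpus"`.
#' @param renditions Optional character vector restricting which rendition ids
#'   to render.
#' @return A named list of `"song_waveform"` objects, one per rendition.
#' @export
render_corpus <- function(corpus, renditions = NULL) {
  stopifnot(inherits(corpus, "song_corpus"))
  ev <- corpus$events
  if (!is.null(renditions)) ev <- filter(ev, .data$rendition_id %in% renditions)
  set.seed(corpus$config$seed + 1L)  # noise-floor stream, distinct from structure
  out <- lapply(split(ev, ~ condition + rendition_id, drop = TRUE), function(d) {
    d <- d[order(d$position), ]
    synthesize_waveform(d$label, d$gap_to_next_ms[-nrow(d)], d$amplitude,
                        waveform = corpus$config$waveform)
  })
  out
}
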