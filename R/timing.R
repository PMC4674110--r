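# Per-transition timing rows: median gap durations attributed to resolved
# branch points, with the >= 5-instance filter.

# Fast extraction of transition instances from an event table that carries
# ground-truth or measured gaps in `gap_to_next_ms`.
.event_transitions <- function(events) {
  d <- events
  # generator output arrives grouped and position-ordered; only re-sort when
  # the grouping is actually broken
  pos_ok <- all(diff(d$position) == 1L | d$position[-1] == 1L)
  if (!pos_ok) {
    d <- d[order(d$bird_id, d$condition, d$rendition_id, d$position), ]
  }
  n <- nrow(d)
  gid <- paste(d$bird_id, d$condition, d$rendition_id, sep = "\r")
  same_next <- c(gid[-1] == gid[-n], FALSE)
  flag <- if ("repeat_flag" %in% names(d)) d$repeat_flag else rep(FALSE, n)
  src <- which(same_next & !is.na(d$gap_to_next_ms) &
                 !flag & !c(flag[-1], TRUE))
  prev_ok <- src > 1 & c(FALSE, gid[-1] == gid[-n])[src]
  prev_lab <- rep(NA_character_, length(src))
  prev_lab[prev_ok] <- d$label[src[prev_ok] - 1L]
  tibble(
    bird_id = d$bird_id[src],
    condition = d$condition[src],
    rendition_id = d$rendition_id[src],
    context = d$label[src],
    context2 = ifelse(is.na(prev_lab), NA_character_,
                      paste0(prev_lab, d$label[src])),
    target = d$label[src + 1L],
    gap_ms = d$gap_to_next_ms[src],
    target_amplitude = if ("amplitude" %in% names(d)) d$amplitude[src + 1L] else NA_real_
  )
}

#' Per-transition timing table
#'
#' Attributes every gap instance to its resolved branch point (split contexts
#' match on the order-2 context, pooled contexts on the order-1 context) and
#' summarises each (bird, condition, context, target) transition by its
#' median gap duration and median target-syllable amplitude. Only analysed
#' branch points (occurrence filter) and transitions with at least
#' `min_instances` gap instances are returned, since medians from small
#' samples are unreliable.
#'
#' @param events Event tibble with `gap_to_next_ms` (e.g. a corpus `events`
#'   table), or a transitions tibble from [measure_gaps()].
#' @param branch_points A `"branch_points"` table from [resolve_contexts()].
#' @param min_instances Minimum gap instances per transition.
#' @return A tibble of class `"coupling_rows"`: `bird_id`, `condition`,
#'   `sequence_id`, `target`, `p`, `transition_type`, `n_occurrences`,
#'   `n_instances`, `median_gap_ms`, `log10_gap`, `median_amp`, `log10_amp`.
#' @export
transition_timing <- function(events, branch_points, min_instances = 5) {
  stopifnot(inherits(branch_points, "branch_points"))
  tr <- if ("gap_to_next_ms" %in% names(events)) {
    .event_transitions(events)
  } else if ("gap_ms" %in% names(events)) {
    events
  } else {
    abort("events must carry gap_to_next_ms or be a measure_gaps() table")
  }
  bp <- branch_points
  bp_key <- paste(bp$bird_id, bp$condition, bp$context, bp$target, sep = "\r")
  k2 <- paste(tr$bird_id, tr$condition, tr$context2, tr$target, sep = "\r")
  ko <- paste(tr$bird_id, tr$condition, paste0(".", tr$context), tr$target, sep = "\r")
  k1 <- paste(tr$bird_id, tr$condition, tr$context, tr$target, sep = "\r")
  resolved <- ifelse(k2 %in% bp_key, k2, ifelse(ko %in% bp_key, ko, k1))
  keep <- resolved %in% bp_key
  tr <- tr[keep, ]
  resolved <- resolved[keep]
  idx <- split(seq_len(nrow(tr)), resolved)
  agg <- tibble(
    .key = names(idx),
    n_instances = lengths(idx),
    median_gap_ms = vapply(idx, function(i) median(tr$gap_ms[i]), numeric(1)),
    median_amp = vapply(idx, function(i) median(tr$target_amplitude[i]),
                        numeric(1))
  )
  bp$.key <- bp_key
  rows <- inner_join(bp, agg, by = ".key") %>%
    filter(.data$analyzed, .data$n_instances >= min_instances) %>%
    mutate(log10_gap = log10(.data$median_gap_ms),
           log10_amp = log10(.data$median_amp)) %>%
    select(dplyr::all_of(c(
      bird_id = "bird_id", condition = "condition", sequence_id = "context",
      target = "target", p = "p", transition_type = "classification",
      n_occurrences = "n_occurrences", n_instances = "n_instances",
      median_gap_ms = "median_gap_ms", log10_gap = "log10_gap",
      median_amp = "median_amp", log10_amp = "log10_amp")))
  class(rows) <- c("coupling_rows", class(rows))
  rows
}
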