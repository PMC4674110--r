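# Song syntax: transition counts, history-dependence tests, branch points.
#
# Transition probabilities exclude song terminations: the final syllable of a
# rendition increments a termination count for its context(s) but contributes
# no outgoing transition, and probabilities are renormalised over the
# remaining targets. A context is analysed only if it occurs at least 10
# times (termination-excluded) and is classified stereotyped when its
# maximal target probability strictly exceeds 0.95.

#' Flag variable syllable repeats
#'
#' Syllables repeated a variable number of times across renditions are not
#' analysed: for each bird/condition, a label is flagged when the lengths of
#' its maximal runs vary across the corpus. Transitions into, within, or out
#' of a flagged run are excluded from branch-point analysis downstream.
#' Fixed-length runs (including the usual run length of 1) are kept verbatim.
#'
#' @param events Tibble with `bird_id`, `condition`, `rendition_id`,
#'   `position`, `label`.
#' @return `events` with a logical `repeat_flag` column (identity transform
#'   plus an all-`FALSE` column when no variable repeats exist).
#' @export
exclude_repeats <- function(events) {
  stopifnot(all(c("bird_id", "condition", "rendition_id", "label") %in% names(events)))
  events$repeat_flag <- FALSE
  d <- events
  if ("position" %in% names(d) &&
      !all(diff(d$position) == 1L | d$position[-1] == 1L)) {
    d <- d[order(d$bird_id, d$condition, d$rendition_id, d$position), ]
  }
  # maximal runs of one label within one rendition, computed corpus-wide
  rl <- rle(paste(d$bird_id, d$condition, d$rendition_id, d$label, sep = "\r"))
  run_start <- cumsum(rl$lengths) - rl$lengths + 1L
  run_group <- paste(d$bird_id[run_start], d$condition[run_start],
                     d$label[run_start], sep = "\r")
  # a (bird, condition, label) is flagged when its run lengths vary
  varies <- tapply(rl$lengths, run_group,
                   function(x) length(unique(x)) > 1)
  flagged_groups <- names(varies)[varies]
  if (length(flagged_groups)) {
    events$repeat_flag <- paste(events$bird_id, events$condition, events$label,
                                sep = "\r") %in% flagged_groups
  }
  events
}

#' Count syllable transitions
#'
#' Counts every adjacent label pair per bird and condition, at order-1
#' contexts (the source label) and, up to `max_context_order`, longer
#' contexts (previous + source label). Rendition-final syllables increment
#' termination counts only (rows with `target = NA`). Transitions touching a
#' flagged variable repeat (see [exclude_repeats()]) are skipped.
#'
#' @param events Event tibble (`bird_id`, `condition`, `rendition_id`,
#'   `position`, `label`, optional `repeat_flag`).
#' @param max_context_order Longest context length counted (1 or 2).
#' @return A tibble of class `"transition_table"` with columns `bird_id`,
#'   `condition`, `order`, `context`, `target` (`NA` marks termination), `n`.
#' @export
count_transitions <- function(events, max_context_order = 2) {
  stopifnot(all(c("bird_id", "condition", "rendition_id", "label") %in% names(events)))
  if (nrow(events) == 0) {
    out <- tibble(bird_id = character(0), condition = character(0),
                  order = integer(0), context = character(0),
                  target = character(0), n = integer(0))
    class(out) <- c("transition_table", class(out))
    return(out)
  }
  d <- events
  if ("position" %in% names(d)) {
    d <- d[order(d$bird_id, d$condition, d$rendition_id, d$position), ]
  }
  n <- nrow(d)
  gid <- paste(d$bird_id, d$condition, d$rendition_id, sep = "\r")
  same_next <- c(gid[-1] == gid[-n], FALSE)
  nxt <- c(d$label[-1], NA_character_)
  nxt[!same_next] <- NA_character_          # termination
  prev <- c(NA_character_, d$label[-n])
  same_prev <- c(FALSE, gid[-1] == gid[-n])
  prev[!same_prev] <- NA_character_
  flag <- if ("repeat_flag" %in% names(d)) d$repeat_flag else rep(FALSE, n)
  nxt_flag <- c(flag[-1], FALSE)
  skip <- flag | (same_next & nxt_flag)

  fast_count <- function(bird, cond, ctx, tgt, ord) {
    key <- paste(bird, cond, ctx, tgt, sep = "\r")
    ux <- which(!duplicated(key))
    nn <- tabulate(match(key, key[ux]), length(ux))
    tibble(bird_id = bird[ux], condition = cond[ux], order = ord,
           context = ctx[ux], target = tgt[ux], n = nn)
  }
  keep <- !skip
  o1 <- fast_count(d$bird_id[keep], d$condition[keep], d$label[keep],
                   nxt[keep], 1L)
  out <- o1
  if (max_context_order >= 2) {
    has2 <- !is.na(prev) & !skip
    o2 <- fast_count(d$bird_id[has2], d$condition[has2],
                     paste0(prev[has2], d$label[has2]), nxt[has2], 2L)
    out <- bind_rows(o1, o2)
  }
  out <- out[order(out$bird_id, out$condition, out$order, out$context), ]
  class(out) <- c("transition_table", class(out))
  out
}

#' Transition probabilities from a transition table
#'
#' Termination-excluded probabilities per (bird, condition, order, context).
#'
#' @param table A `"transition_table"`.
#' @return Tibble with `n`, `p` (sums to 1 per context) and `n_occurrences`
#'   (termination-excluded context total).
#' @export
transition_probabilities <- function(table) {
  table %>%
    filter(!is.na(.data$target)) %>%
    group_by(.data$bird_id, .data$condition, .data$order, .data$context) %>%
    mutate(n_occurrences = sum(.data$n), p = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Likelihood-ratio test for history dependence
#'
#' G-test of homogeneity of target distributions across sequence contexts:
#' `G = 2 * sum(obs * ln(obs / exp))` with expectations from the pooled
#' target distribution scaled to each context's total, zero cells
#' contributing 0, and `df = (n_contexts - 1) * (n_targets - 1)` after
#' dropping empty rows/columns. The p-value is the upper chi-square tail.
#'
#' @param counts A contexts-by-targets count matrix, or a tibble with columns
#'   `context`, `target`, `n`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_contexts`,
#'   `n_targets`.
#' @export
lrt_context_dependence <- function(counts) {
  if (inherits(counts, "data.frame")) {
    stopifnot(all(c("context", "target", "n") %in% names(counts)))
    counts <- tidyr::pivot_wider(
      counts[, c("context", "target", "n")],
      names_from = "target", values_from = "n", values_fill = 0,
      values_fn = sum)
    rn <- counts$context
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- rn
  }
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2) abort("history-dependence test needs at least 2 contexts")
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)
  expd <- outer(rs, cs) / N
  pos <- counts > 0
  G <- 2 * sum(counts[pos] * log(counts[pos] / expd[pos]))
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  p <- if (df == 0) 1 else pchisq(G, df, lower.tail = FALSE)
  tibble(statistic = G, df = df, p_value = p,
         n_contexts = nrow(counts), n_targets = ncol(counts))
}

#' Resolve sequence contexts into branch points
#'
#' For each order-1 context, tests whether target distributions differ across
#' its order-2 predecessor contexts (likelihood-ratio test at `alpha`,
#' termination-excluded counts, predecessors with fewer than
#' `min_context_count` occurrences pooled into an "other" group). If the test
#' rejects, the context is split into separate branch points per predecessor;
#' otherwise counts are pooled across predecessors. The occurrence filter
#' (>= `min_occurrences`, termination-excluded) and the stereotyped
#' classification (max target probability strictly > `stereotyped_threshold`)
#' are then applied. Branch points are per-bird, per-condition objects.
#'
#' @param table A `"transition_table"` built with `max_context_order >= 2`.
#' @param alpha Per-test significance level (no multiplicity correction, as
#'   in the original analysis).
#' @param min_occurrences Minimum termination-excluded context occurrences.
#' @param stereotyped_threshold Stereotyped iff max p strictly exceeds this.
#' @param min_context_count Predecessor contexts with fewer total transitions
#'   are pooled before testing.
#' @return A tibble of class `"branch_points"`: one row per (branch point,
#'   target) with `context` (possibly predecessor-prefixed after a split),
#'   `target`, `n`, `p`, `n_occurrences`, `classification`
#'   (`"branch"`/`"stereotyped"`), `analyzed`, `split`, and the context test's
#'   `G`, `test_df`, `test_p`.
#' @export
resolve_contexts <- function(table, alpha = 0.05, min_occurrences = 10,
                             stereotyped_threshold = 0.95,
                             min_context_count = 5) {
  stopifnot(inherits(table, "transition_table"))
  if (!any(table$order >= 2)) {
    abort("transition table must be built with max_context_order >= 2")
  }
  tt <- as.data.frame(table)[!is.na(table$target), ]
  out <- list()
  for (grp in split(tt, paste(tt$bird_id, tt$condition, sep = "\r"))) {
    bird <- grp$bird_id[1]; cond <- grp$condition[1]
    is1 <- grp$order == 1L
    o1_ctx <- grp$context[is1]; o1_tgt <- grp$target[is1]; o1_n <- grp$n[is1]
    o2_ctx <- grp$context[!is1]; o2_tgt <- grp$target[!is1]; o2_n <- grp$n[!is1]
    o2_suffix <- substr(o2_ctx, 2, 2)
    o2_pred <- substr(o2_ctx, 1, 1)
    for (ctx in unique(o1_ctx)) {
      i2 <- which(o2_suffix == ctx)
      pred <- o2_pred[i2]; tgt2 <- o2_tgt[i2]; n2 <- o2_n[i2]
      G <- NA_real_; df <- NA_integer_; pv <- NA_real_; split_ctx <- FALSE
      grp2 <- NULL
      if (length(i2) && length(unique(pred)) >= 2) {
        pred_tot <- tapply(n2, pred, sum)
        sparse <- names(pred_tot)[pred_tot < min_context_count]
        grp2 <- ifelse(pred %in% sparse, ".", pred)
        if (length(unique(grp2)) >= 2 && length(unique(tgt2)) >= 2) {
          m <- tapply(n2, list(grp2, tgt2), sum)
          m[is.na(m)] <- 0
          res <- lrt_context_dependence(m)
          G <- res$statistic; df <- res$df; pv <- res$p_value
          split_ctx <- is.finite(pv) && pv < alpha
        }
        if (split_ctx) {
          for (g in unique(grp2)) {
            sel <- grp2 == g
            nn <- tapply(n2[sel], tgt2[sel], sum)
            out[[length(out) + 1L]] <- .branch_row(
              bird, cond, paste0(g, ctx),
              list(target = names(nn), n = as.integer(nn)),
              G, df, pv, TRUE, min_occurrences, stereotyped_threshold)
          }
          next
        }
      }
      sel <- o1_ctx == ctx
      nn <- tapply(o1_n[sel], o1_tgt[sel], sum)
      out[[length(out) + 1L]] <- .branch_row(
        bird, cond, ctx, list(target = names(nn), n = as.integer(nn)),
        G, df, pv, FALSE, min_occurrences, stereotyped_threshold)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  fields <- names(out[[1]])
  res <- as_tibble(setNames(lapply(fields, function(f) {
    unlist(lapply(out, `[[`, f), use.names = FALSE)
  }), fields))
  attr(res, "alpha") <- alpha
  attr(res, "min_occurrences") <- min_occurrences
  attr(res, "stereotyped_threshold") <- stereotyped_threshold
  class(res) <- c("branch_points", class(res))
  res
}

.branch_row <- function(bird, cond, ctx, cts, G, df, pv, split,
                        min_occurrences, stereotyped_threshold) {
  tot <- sum(cts$n)
  if (tot == 0) return(NULL)
  p <- cts$n / tot
  k <- length(p)
  list(
    bird_id = rep(bird, k), condition = rep(cond, k), context = rep(ctx, k),
    target = cts$target, n = cts$n, p = p,
    n_occurrences = rep(tot, k),
    classification = rep(if (max(p) > stereotyped_threshold) "stereotyped" else "branch", k),
    analyzed = rep(tot >= min_occurrences, k),
    split = rep(split, k), G = rep(G, k), test_df = rep(df, k),
    test_p = rep(pv, k)
  )
}
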