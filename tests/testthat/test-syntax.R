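# Transition counting, termination exclusion, the history-dependence G-test,
# context resolution and the variable-repeat exclusion rule.

bp_table <- function(rows) {
  # build a transition_table by hand: rows = list of c(bird, cond, order,
  # context, target-or-NA, n)
  out <- tibble::tibble(
    bird_id = vapply(rows, `[[`, character(1), 1),
    condition = vapply(rows, `[[`, character(1), 2),
    order = as.integer(vapply(rows, `[[`, character(1), 3)),
    context = vapply(rows, `[[`, character(1), 4),
    target = vapply(rows, function(r) {
      x <- r[[5]]; if (identical(x, "NA")) NA_character_ else x
    }, character(1)),
    n = as.integer(vapply(rows, `[[`, character(1), 6))
  )
  class(out) <- c("transition_table", class(out))
  out
}

test_that("transition counts and probabilities follow the worked examples", {
  ev <- events_from_strings(c(rep("eaf", 18), rep("eak", 2)))
  tt <- count_transitions(ev)
  o1 <- tt[tt$order == 1 & tt$context == "a" & !is.na(tt$target), ]
  expect_equal(setNames(o1$n, o1$target), c(f = 18L, k = 2L))
  pr <- transition_probabilities(tt)
  p1 <- pr[pr$order == 1 & pr$context == "a", ]
  expect_equal(sort(p1$p), c(0.10, 0.90), tolerance = 1e-12)
  # order-2 context 'ea' carries the same counts
  o2 <- tt[tt$order == 2 & tt$context == "ea" & !is.na(tt$target), ]
  expect_equal(sum(o2$n), 20L)

  # probabilities forced by the 82/13/5 ratio
  ev2 <- events_from_strings(c(rep("def", 82), rep("dec", 13), rep("deq", 5)))
  pr2 <- transition_probabilities(count_transitions(ev2))
  p2 <- pr2[pr2$order == 1 & pr2$context == "e", ]
  expect_equal(sort(p2$p, decreasing = TRUE), c(0.82, 0.13, 0.05),
               tolerance = 1e-12)
})

test_that("rendition-final syllables count as terminations only", {
  ev <- events_from_strings("ab")
  tt <- count_transitions(ev)
  expect_equal(tt$n[tt$order == 1 & tt$context == "a" & tt$target == "b"], 1L)
  # 'b' contributes a termination, never an outgoing transition
  expect_equal(tt$n[tt$order == 1 & tt$context == "b" & is.na(tt$target)], 1L)
  expect_false(any(tt$context == "b" & !is.na(tt$target)))
  # empty input contributes nothing
  expect_equal(nrow(count_transitions(ev[0, ])), 0)
})

test_that("the G statistic matches hand-evaluated cases", {
  same <- lrt_context_dependence(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  opp <- lrt_context_dependence(matrix(c(20, 0, 0, 20), 2, byrow = TRUE))
  expect_equal(opp$statistic, 80 * log(2), tolerance = 1e-9)  # 2*(20ln2+20ln2)*2
  expect_equal(opp$df, 1L)
  expect_lt(opp$p_value, 1e-12)

  expect_error(lrt_context_dependence(matrix(c(5, 5), 1)), "2 contexts")

  # tibble input is pivoted identically
  tb <- tibble::tibble(context = c("a", "a", "b", "b"),
                       target = c("x", "y", "x", "y"),
                       n = c(20, 0, 0, 20))
  expect_equal(lrt_context_dependence(tb)$statistic, 80 * log(2),
               tolerance = 1e-9)
})

test_that("the G-test rejects at roughly the nominal rate under the null", {
  set.seed(31)
  rej <- vapply(1:300, function(i) {
    m <- t(cbind(rmultinom(1, 100, c(0.7, 0.3)), rmultinom(1, 100, c(0.7, 0.3))))
    lrt_context_dependence(m)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("contexts pool when predecessors agree and split when they differ", {
  # identical predecessor distributions: one pooled branch point
  pool <- bp_table(list(
    c("b1", "A", "1", "d", "e", "60"), c("b1", "A", "1", "d", "g", "60"),
    c("b1", "A", "2", "ad", "e", "30"), c("b1", "A", "2", "ad", "g", "30"),
    c("b1", "A", "2", "bd", "e", "30"), c("b1", "A", "2", "bd", "g", "30")))
  bp <- resolve_contexts(pool)
  expect_equal(unique(bp$context), "d")
  expect_false(any(bp$split))
  expect_equal(sum(bp$p), 1, tolerance = 1e-12)

  # strongly different predecessors split into 'ad' and 'bd'
  split_tab <- bp_table(list(
    c("b1", "A", "1", "d", "e", "50"), c("b1", "A", "1", "d", "g", "50"),
    c("b1", "A", "2", "ad", "e", "45"), c("b1", "A", "2", "ad", "g", "5"),
    c("b1", "A", "2", "bd", "e", "5"), c("b1", "A", "2", "bd", "g", "45")))
  bp2 <- resolve_contexts(split_tab)
  expect_setequal(unique(bp2$context), c("ad", "bd"))
  expect_true(all(bp2$split))
  # the recorded test agrees with a direct G evaluation
  g_direct <- lrt_context_dependence(matrix(c(45, 5, 5, 45), 2, byrow = TRUE))
  expect_equal(unique(bp2$G), g_direct$statistic, tolerance = 1e-9)
})

test_that("occurrence filter and stereotyped threshold are strict", {
  tab <- bp_table(list(
    c("b1", "A", "1", "a", "f", "9"),            # 9 occurrences: excluded
    c("b1", "A", "2", "xa", "f", "9"),
    c("b1", "A", "1", "q", "r", "95"),           # p = 0.95 exactly: branch
    c("b1", "A", "1", "q", "s", "5"),
    c("b1", "A", "2", "xq", "r", "95"),
    c("b1", "A", "2", "xq", "s", "5"),
    c("b1", "A", "1", "m", "n", "96"),           # p = 0.96: stereotyped
    c("b1", "A", "1", "m", "o", "4"),
    c("b1", "A", "2", "xm", "n", "96"),
    c("b1", "A", "2", "xm", "o", "4")))
  bp <- resolve_contexts(tab)
  expect_false(bp$analyzed[bp$context == "a"])
  expect_equal(unique(bp$classification[bp$context == "q"]), "branch")
  expect_equal(unique(bp$classification[bp$context == "m"]), "stereotyped")
})

test_that("termination counts leave probabilities renormalised over real targets", {
  ev <- events_from_strings(c(rep("eaf", 8), rep("ea", 2)))  # 'a' ends 2 songs
  pr <- transition_probabilities(count_transitions(ev))
  p <- pr[pr$order == 1 & pr$context == "a", ]
  expect_equal(p$p, 1)               # f is the only non-termination target
  expect_equal(p$n_occurrences, 8L)  # termination-excluded denominator
})

test_that("variable repeats are flagged and their transitions excluded", {
  ev <- events_from_strings(c("abbc", "abbbc", "abc"))
  fl <- exclude_repeats(ev)
  expect_true(all(fl$repeat_flag[fl$label == "b"]))
  expect_false(any(fl$repeat_flag[fl$label != "b"]))
  tt <- count_transitions(fl)
  # transitions into, within, and out of b-runs are gone
  expect_false(any(tt$context == "b", na.rm = TRUE))
  expect_false(any(tt$target == "b", na.rm = TRUE))

  # fixed-length runs are kept verbatim
  ev2 <- events_from_strings(c("abbc", "abbc"))
  fl2 <- exclude_repeats(ev2)
  expect_false(any(fl2$repeat_flag))
  tt2 <- count_transitions(fl2)
  expect_equal(tt2$n[tt2$order == 1 & tt2$context == "b" & tt2$target == "b"], 2L)

  # no repeats: identity transform
  ev3 <- events_from_strings(c("abc", "abc"))
  expect_identical(exclude_repeats(ev3)$repeat_flag, rep(FALSE, 6))
})

test_that("estimated probabilities converge to generator truth", {
  co <- generate_corpus(small_config(seed = 17, n_birds = 4, renditions = 40))
  bp <- resolve_contexts(count_transitions(exclude_repeats(co$events)))
  truth <- co$truth$probabilities
  j <- dplyr::inner_join(
    bp[!bp$split, c("bird_id", "context", "target", "p", "n_occurrences")],
    truth[, c("bird_id", "context", "target", "p_true")],
    by = c("bird_id", "context", "target"))
  expect_gt(nrow(j), 40)
  band <- 3 * sqrt(j$p_true * (1 - j$p_true) / j$n_occurrences) + 1e-9
  expect_true(all(abs(j$p - j$p_true) <= band | j$n_occurrences < 30))
})
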