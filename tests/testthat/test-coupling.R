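# Mixed-model coupling analyses: degenerate oracles, change categorisation,
# amplitude residualisation, normality screening and the category contrast.

test_that("with zero random variance the mixed model matches least squares", {
  rows <- balanced_rows(n_birds = 6, noise_sd = 0.05, seed = 99)
  fit <- fit_coupling_model(rows)
  ols <- lm(log10_gap ~ p, data = rows)
  expect_lt(abs(fit$estimate - coef(ols)[["p"]]), 1e-6)
  expect_true(fit$boundary)        # variances on the zero boundary
  g <- glance(fit)
  expect_lt(g$var_bird, 1e-6)
})

test_that("an exact linear response is recovered without residual error", {
  rows <- balanced_rows(noise_sd = 0)
  rows$log10_gap <- 2 * rows$p
  fit <- fit_coupling_model(rows)
  expect_equal(fit$estimate, 2, tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("degenerate designs are rejected with informative errors", {
  rows <- balanced_rows()
  rows$p <- 0.5
  expect_error(fit_coupling_model(rows), "constant")
  one_bird <- balanced_rows()
  one_bird$bird_id <- "bird01"
  expect_error(fit_coupling_model(one_bird), "2 birds")
  expect_error(fit_coupling_model(balanced_rows(), response = "nope"), "nope")
})

test_that("tidy, glance, augment and autoplot expose the fit", {
  fit <- fit_coupling_model(balanced_rows())
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "num.df", "den.df", "p.value"))
  expect_equal(td$term, "p")
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$log10_gap, tolerance = 1e-9)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("stereotyped gaps come out shorter than branch gaps at study scale", {
  co <- generate_corpus(song_config(seed = 29))
  res <- run_pipeline(co)
  fit <- res$type_contrast
  expect_lt(fit$estimate, 0)       # stereotyped minus branch
  expect_lt(fit$p_value, 0.05)
  expect_error(compare_transition_types(res$rows$A[1:2, ]), "few|both")
})

test_that("change categorisation matches hand-evaluated contingency tests", {
  same <- categorize_changes(c(x = 50, y = 50), c(x = 50, y = 50))
  expect_true(all(same$category == "unchanged"))
  expect_true(all(same$statistic == 0))

  shift <- categorize_changes(c(x = 90, y = 10), c(x = 50, y = 50))
  # hand evaluation of the 2x2 without continuity correction: 800/21
  expect_equal(shift$statistic[shift$target == "x"], 800 / 21, tolerance = 1e-9)
  # agreement with the standard implementation
  ht <- chisq.test(matrix(c(90, 10, 50, 50), 2, byrow = TRUE), correct = FALSE)
  expect_equal(shift$statistic[shift$target == "x"], unname(ht$statistic),
               tolerance = 1e-9)
  expect_equal(shift$category[shift$target == "x"], "decreased")
  expect_equal(shift$category[shift$target == "y"], "increased")

  # the likelihood-ratio variant agrees with the G-test on the same table
  g <- lrt_context_dependence(matrix(c(90, 10, 50, 50), 2, byrow = TRUE))
  lrt <- categorize_changes(c(x = 90, y = 10), c(x = 50, y = 50), test = "lrt")
  expect_equal(lrt$statistic[lrt$target == "x"], g$statistic, tolerance = 1e-9)

  expect_error(categorize_changes(c(x = 0, y = 0), c(x = 5, y = 5)), "zero-total")
})

test_that("categorisation controls type-I error near the nominal level", {
  set.seed(41)
  rej <- vapply(1:400, function(i) {
    a <- rmultinom(1, 100, c(0.7, 0.3))[, 1]
    b <- rmultinom(1, 100, c(0.7, 0.3))[, 1]
    cats <- categorize_changes(setNames(a, c("x", "y")), setNames(b, c("x", "y")))
    cats$category[1] != "unchanged"
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("amplitude residualisation separates amplitude-driven coupling", {
  # gap fully determined by amplitude, probability independent of both:
  # after residualising out amplitude no coupling with p remains
  set.seed(7)
  n_birds <- 12
  d <- expand.grid(bird = seq_len(n_birds), seq = 1:4, target = 1:2)
  amp <- rnorm(nrow(d), 0, 0.2)
  rows <- tibble::tibble(
    bird_id = sprintf("b%02d", d$bird),
    sequence_id = sprintf("s%02d", d$seq),
    p = runif(nrow(d), 0.05, 0.95),
    log10_amp = amp,
    log10_gap = 2 - 0.8 * amp + rnorm(nrow(d), 0, 0.02)
  )
  res <- residualize_amplitude(rows)
  expect_equal(sum(res$rows$gap_residual), 0, tolerance = 1e-4)
  step2 <- res$residual_fit
  expect_lt(abs(step2$estimate), 2 * step2$std_error)

  # amplitude unrelated to gap: the residual slope equals the raw slope
  rows2 <- rows
  rows2$log10_gap <- 2 - 0.3 * rows2$p + rnorm(nrow(rows2), 0, 0.05)
  raw <- fit_coupling_model(rows2)
  res2 <- residualize_amplitude(rows2)
  expect_lt(abs(res2$residual_fit$estimate - raw$estimate), raw$std_error)

  rows3 <- rows
  rows3$log10_amp[3] <- NA
  expect_error(residualize_amplitude(rows3), "3")
})

test_that("change-coupling analysis validates its inputs", {
  rec <- tibble::tibble(bird_id = c("b1", "b2"), sequence_id = c("s1", "s2"),
                        target = c("x", "y"), delta_p = c(0.1, -0.1),
                        dlog10_gap = c(-0.05, 0.02), pct_gap_change = c(-10, 4),
                        category = c("increased", "decreased"))
  expect_error(change_coupling_analysis(rec), "3")
  rec3 <- dplyr::bind_rows(rec, rec, rec)
  rec3$delta_p <- 0.1
  expect_error(change_coupling_analysis(rec3), "equal|constant")
})

test_that("normality screen transforms and flags as documented", {
  out <- screen_normality(c(1, 10, 100, 2, 5))
  expect_equal(screen_normality(c(1, 10, 100))$log10_values, c(0, 1, 2))
  expect_error(screen_normality(c(0, 1, 2)), "positive")
  expect_error(screen_normality(c(1, 2)), "3")

  set.seed(13)
  x <- 10^rnorm(200, 2, 0.4)
  sc <- screen_normality(x)
  expect_lt(sc$p_value, 0.05)       # raw values clearly non-normal
  expect_gt(sc$log_p_value, 0.05)   # log10 restores normality
  expect_true(sc$transform_normalized)
})

test_that("the category contrast drops singletons and orders LS-means", {
  set.seed(55)
  n <- 40
  rec <- tibble::tibble(
    bird_id = rep(sprintf("b%02d", 1:10), 4),
    sequence_id = rep(sprintf("s%02d", 1:20), 2),
    target = "x",
    category = rep(c("increased", "decreased", "unchanged", "stereotyped"),
                   each = 10),
    pct_gap_change = rep(c(-18, 8, -5, -5), each = 10) + rnorm(n, 0, 3),
    delta_p = 0, dlog10_gap = 0)
  ct <- category_contrast(rec)
  ls <- ct$lsmeans
  expect_lt(ls$lsmean[ls$category == "increased"],
            ls$lsmean[ls$category == "unchanged"])
  expect_lt(ls$lsmean[ls$category == "unchanged"],
            ls$lsmean[ls$category == "decreased"])
  expect_named(tidy(ct), c("contrast", "estimate", "SE", "df", "t.ratio",
                           "adj.p.value"))
  rec$category[rec$category == "decreased"] <- "increased"
  rec$category[1] <- "decreased"
  expect_warning(ct2 <- category_contrast(rec), "single")
  expect_false("decreased" %in% ct2$lsmeans$category)
})
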