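# Mixed-effects analyses of sequencing/timing coupling.
#
# Every model here is a linear mixed model fitted by REML with random
# intercepts for bird and for sequence (branch point or chain) nested within
# bird, the structure dictated by repeated measures of multiple sequences
# per bird. Fixed-effect F tests use Satterthwaite denominator degrees of
# freedom (fractional df, as reported by the original JMP analyses). lme4
# constrains variance components to be non-negative; fits on that boundary
# are flagged rather than allowed to go negative.

.lmm_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
}

# Shared fitting core: response ~ predictor + (1|bird) + (1|bird:sequence).
.fit_lmm <- function(rows, response, predictor) {
  for (col in c(response, predictor, "bird_id", "sequence_id")) {
    if (!col %in% names(rows)) abort(sprintf("column '%s' not found", col))
  }
  if (dplyr::n_distinct(rows$bird_id) < 2) abort("need data from at least 2 birds")
  x <- rows[[predictor]]
  if (is.numeric(x) && (is.na(var(x)) || var(x) < 1e-14)) {
    abort(sprintf("degenerate design: predictor '%s' is constant", predictor))
  }
  if (!is.numeric(x) && dplyr::n_distinct(x) < 2) {
    abort(sprintf("degenerate design: predictor '%s' has a single level", predictor))
  }
  dat <- data.frame(
    .y = rows[[response]],
    .x = x,
    bird_id = factor(rows$bird_id),
    sequence_id = factor(paste(rows$bird_id, rows$sequence_id, sep = ":"))
  )
  if (any(!is.finite(dat$.y))) abort("non-finite response values")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(.y ~ .x + (1 | bird_id) + (1 | sequence_id),
                     data = dat, REML = TRUE, control = .lmm_control()))),
    error = function(e) NULL)
  aov <- if (!is.null(fit)) {
    tryCatch(suppressMessages(anova(fit, ddf = "Satterthwaite")),
             error = function(e) NULL)
  } else NULL
  if (is.null(fit) || is.null(aov)) {
    # degenerate fits (e.g. zero residual variance) break the Satterthwaite
    # machinery; fall back to the lme4 fit with residual denominator df and
    # model-based (non-hessian) standard errors
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(.y ~ .x + (1 | bird_id) + (1 | sequence_id),
                 data = dat, REML = TRUE, control = .lmm_control())))
    beta <- lme4::fixef(fit)
    V <- tryCatch(suppressWarnings(as.matrix(vcov(fit, use.hessian = FALSE))),
                  error = function(e) diag(NA_real_, length(beta)))
    se <- sqrt(pmax(diag(V), 0))
    den_df <- nrow(dat) - length(beta)
    tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
    num_df <- length(beta) - 1L
    Fval <- if (num_df == 1L) tval[2]^2 else {
      tryCatch({
        b1 <- beta[-1]
        drop(t(b1) %*% solve(V[-1, -1, drop = FALSE]) %*% b1) / num_df
      }, error = function(e) NA_real_)
    }
    aov <- data.frame(NumDF = num_df, DenDF = den_df, `F value` = Fval,
                      `Pr(>F)` = pf(Fval, num_df, den_df, lower.tail = FALSE),
                      check.names = FALSE)
    cf <- cbind(Estimate = beta, `Std. Error` = se, df = den_df,
                `t value` = tval,
                `Pr(>|t|)` = 2 * pt(-abs(tval), den_df))
  } else {
    cf <- summary(fit)$coefficients
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fit = fit, anova = aov, coefficients = cf, varcomp = vc, data = dat)
}

.coupling_result <- function(core, response, predictor, rows) {
  cf <- core$coefficients
  slope_rows <- setdiff(rownames(cf), "(Intercept)")
  term_names <- sub("^\\.x", predictor, slope_rows)
  structure(list(
    fit = core$fit,
    response = response,
    predictor = predictor,
    term = term_names,
    estimate = unname(cf[slope_rows, "Estimate"]),
    std_error = unname(cf[slope_rows, "Std. Error"]),
    F_statistic = core$anova[1, "F value"],
    num_df = core$anova[1, "NumDF"],
    den_df = core$anova[1, "DenDF"],
    p_value = core$anova[1, "Pr(>F)"],
    varcomp = tibble(
      component = c("bird", "sequence_in_bird", "residual"),
      variance = c(
        core$varcomp$vcov[core$varcomp$grp == "bird_id"],
        core$varcomp$vcov[core$varcomp$grp == "sequence_id"],
        core$varcomp$vcov[core$varcomp$grp == "Residual"])),
    boundary = lme4::isSingular(core$fit),
    residuals = unname(residuals(core$fit)),
    n = nrow(core$data),
    n_birds = dplyr::n_distinct(core$data$bird_id),
    rows = rows
  ), class = "coupling_fit")
}

#' Fit the sequencing/timing coupling model
#'
#' Linear mixed model `response ~ predictor` with random intercepts for bird
#' and sequence-within-bird, fitted by REML; the fixed-effect slope measures
#' how log10 gap duration changes per unit transition probability (the
#' canonical use, with an expected negative slope: more prevalent transitions
#' have shorter gaps).
#'
#' @param rows A `"coupling_rows"` table (or any tibble with `bird_id`,
#'   `sequence_id` and the named columns).
#' @param response,predictor Column names; defaults `log10_gap ~ p`.
#' @return An object of class `"coupling_fit"` with the slope estimate and
#'   standard error, Satterthwaite F/df/p, variance components, residuals and
#'   a boundary (singular-fit) flag. Supports [tidy()], [glance()],
#'   [augment()] and [autoplot()].
#' @export
fit_coupling_model <- function(rows, response = "log10_gap", predictor = "p") {
  core <- .fit_lmm(rows, response, predictor)
  .coupling_result(core, response, predictor, rows)
}

#' Compare gap durations between branch and stereotyped transitions
#'
#' Same mixed model with transition type as the fixed factor on log10 gap
#' duration. The reported effect is the stereotyped-minus-branch difference;
#' a negative estimate means stereotyped gaps are shorter.
#'
#' @param rows A `"coupling_rows"` table containing both transition types.
#' @return A `"coupling_fit"`.
#' @export
compare_transition_types <- function(rows) {
  if (!"transition_type" %in% names(rows)) abort("transition_type column required")
  types <- unique(rows$transition_type)
  if (!all(c("branch", "stereotyped") %in% types)) {
    abort("both transition types (branch, stereotyped) must be present")
  }
  if (nrow(rows) < 4) abort("too few rows to fit the mixed model")
  rows2 <- rows
  rows2$transition_type <- factor(rows2$transition_type,
                                  levels = c("branch", "stereotyped"))
  core <- .fit_lmm(rows2, "log10_gap", "transition_type")
  .coupling_result(core, "log10_gap", "transition_type", rows2)
}

#' Amplitude-residualised coupling analysis
#'
#' Because segmentation is amplitude-threshold based, syllable amplitude can
#' mediate the probability/gap relationship. Step 1 regresses log10 gap on
#' log10 amplitude (same random structure) and extracts conditional
#' residuals: gap variation not accounted for by amplitude. Step 2 regresses
#' those residuals on transition probability. A persistent negative step-2
#' slope indicates coupling beyond what amplitude explains.
#'
#' @param rows A `"coupling_rows"` table with `log10_amp` present for every
#'   row.
#' @return List of class `"amplitude_residualization"`: `amplitude_fit`
#'   (step 1), `residual_fit` (step 2), and `rows` with a `gap_residual`
#'   column.
#' @export
residualize_amplitude <- function(rows) {
  if (!"log10_amp" %in% names(rows)) abort("log10_amp column required")
  bad <- which(!is.finite(rows$log10_amp))
  if (length(bad)) {
    abort(sprintf("missing amplitudes in rows: %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  step1 <- fit_coupling_model(rows, response = "log10_gap", predictor = "log10_amp")
  rows2 <- rows
  rows2$gap_residual <- step1$residuals
  step2 <- fit_coupling_model(rows2, response = "gap_residual", predictor = "p")
  structure(list(amplitude_fit = step1, residual_fit = step2, rows = rows2),
            class = "amplitude_residualization")
}

#' Categorise transition-probability changes between two conditions
#'
#' Per target, a 2x2 contingency table (target vs all other targets, by
#' condition) is tested by the chi-square statistic without continuity
#' correction (or a likelihood-ratio G-test with `test = "lrt"`).
#' A transition is `increased` if the test rejects at `alpha` and its
#' probability rose, `decreased` if it fell, else `unchanged`.
#'
#' @param counts_a,counts_b Named termination-excluded target counts for one
#'   branch point under each condition (same target alphabet).
#' @param alpha Significance level.
#' @param test `"chisq"` (default) or `"lrt"`.
#' @return Tibble with per-target `p_a`, `p_b`, `delta_p`, `statistic`,
#'   `p_value`, `category`.
#' @export
categorize_changes <- function(counts_a, counts_b, alpha = 0.05,
                               test = c("chisq", "lrt")) {
  test <- match.arg(test)
  targets <- union(names(counts_a), names(counts_b))
  a <- setNames(rep(0, length(targets)), targets)
  b <- a
  a[names(counts_a)] <- counts_a
  b[names(counts_b)] <- counts_b
  ta <- sum(a); tb <- sum(b)
  if (ta == 0 || tb == 0) abort("zero-total margin: a condition has no transitions")
  # 2x2 tables, vectorised over targets: rows = condition, cols = target/rest
  x11 <- a; x12 <- ta - a; x21 <- b; x22 <- tb - b
  c1 <- x11 + x21; c2 <- x12 + x22; N <- ta + tb
  if (test == "chisq") {
    # Pearson X^2 for a 2x2 table without continuity correction
    stat <- N * (x11 * x22 - x12 * x21)^2 / (ta * tb * c1 * c2)
  } else {
    stat <- numeric(length(targets))
    for (i in seq_along(targets)) {
      m <- c(x11[i], x12[i], x21[i], x22[i])
      e <- c(ta * c1[i], ta * c2[i], tb * c1[i], tb * c2[i]) / N
      pos <- m > 0
      stat[i] <- 2 * sum(m[pos] * log(m[pos] / e[pos]))
    }
  }
  stat[c1 == 0] <- 0
  pv <- pchisq(stat, 1, lower.tail = FALSE)
  pv[c1 == 0] <- 1
  pa <- a / ta; pb <- b / tb
  category <- rep("unchanged", length(targets))
  sig <- is.finite(pv) & pv < alpha
  category[sig & pb > pa] <- "increased"
  category[sig & pb < pa] <- "decreased"
  tibble(target = targets, p_a = unname(pa), p_b = unname(pb),
         delta_p = unname(pb - pa), statistic = unname(stat),
         p_value = unname(pv), category = category)
}

#' Build paired-condition change records
#'
#' Matches transitions across two conditions (same bird, same resolved
#' context, same target), keeping only transitions with at least 5 instances
#' and at least the occurrence minimum in *both* conditions and belonging to
#' a sequence that is a branch point under at least one condition (those are
#' categorised by the contingency test). Transitions stereotyped under both
#' conditions are carried with category `"stereotyped"` for the category
#' contrast.
#'
#' @param rows_a,rows_b `"coupling_rows"` tables for the two conditions.
#' @param branch_a,branch_b Matching `"branch_points"` tables (for the
#'   per-branch-point contingency counts).
#' @param alpha,test Passed to [categorize_changes()].
#' @return Tibble of class `"change_records"`: per transition `delta_p`
#'   (p_B - p_A), `dlog10_gap` (log10 gap_B - log10 gap_A),
#'   `pct_gap_change` (100 * (median_B - median_A) / median_A) and
#'   `category`.
#' @export
change_records <- function(rows_a, rows_b, branch_a, branch_b,
                           alpha = 0.05, test = c("chisq", "lrt")) {
  test <- match.arg(test)
  by <- c("bird_id", "sequence_id", "target")
  j <- inner_join(
    rows_a %>% select(dplyr::all_of(c(by, p_a = "p", type_a = "transition_type",
                                      gap_a = "median_gap_ms",
                                      log_a = "log10_gap", amp_a = "log10_amp"))),
    rows_b %>% select(dplyr::all_of(c(by, p_b = "p", type_b = "transition_type",
                                      gap_b = "median_gap_ms",
                                      log_b = "log10_gap", amp_b = "log10_amp"))),
    by = by)
  if (nrow(j) == 0) {
    out <- tibble()
    class(out) <- c("change_records", class(out))
    return(out)
  }
  j <- mutate(j,
              delta_p = .data$p_b - .data$p_a,
              dlog10_gap = .data$log_b - .data$log_a,
              dlog10_amp = .data$amp_b - .data$amp_a,
              pct_gap_change = 100 * (.data$gap_b - .data$gap_a) / .data$gap_a)
  # category per target from the contingency test on the branch-point counts,
  # computed once per branch point
  ster <- j$type_a == "stereotyped" & j$type_b == "stereotyped"
  j$category <- ifelse(ster, "stereotyped", NA_character_)
  need <- unique(paste(j$bird_id, j$sequence_id, sep = "\r")[!ster])
  ia_list <- split(seq_len(nrow(branch_a)),
                   paste(branch_a$bird_id, branch_a$context, sep = "\r"))
  ib_list <- split(seq_len(nrow(branch_b)),
                   paste(branch_b$bird_id, branch_b$context, sep = "\r"))
  cat_lookup <- character(0)
  for (bpk in need) {
    ia <- ia_list[[bpk]]; ib <- ib_list[[bpk]]
    if (is.null(ia) || is.null(ib)) next
    cats <- categorize_changes(setNames(branch_a$n[ia], branch_a$target[ia]),
                               setNames(branch_b$n[ib], branch_b$target[ib]),
                               alpha = alpha, test = test)
    cat_lookup[paste(bpk, cats$target, sep = "\r")] <- cats$category
  }
  nb <- which(!ster)
  j$category[nb] <- unname(cat_lookup[paste(j$bird_id[nb], j$sequence_id[nb],
                                            j$target[nb], sep = "\r")])
  j <- filter(j, !is.na(.data$category))
  class(j) <- c("change_records", class(j))
  j
}

#' Regress gap-duration changes on transition-probability changes
#'
#' The central change analysis: mixed models (same nested random structure)
#' of the per-transition change in log10 gap duration, and of the percent
#' change in median gap duration, on the change in transition probability.
#' Stereotyped records are excluded; only branch-point transitions enter.
#' A significantly negative slope (the age-dependent pattern) means gaps
#' shortened most for transitions that became more prevalent; a null slope
#' (the social-context pattern) means timing changed independently of
#' sequencing.
#'
#' @param records A `"change_records"` table.
#' @return List of class `"change_coupling"`: `dlog10_fit` and `pct_fit`,
#'   both `"coupling_fit"` objects.
#' @export
change_coupling_analysis <- function(records) {
  rec <- filter(records, .data$category != "stereotyped")
  if (nrow(rec) < 3) abort("fewer than 3 change records")
  if (var(rec$delta_p) < 1e-14) {
    abort("degenerate design: all probability changes are equal")
  }
  list_out <- list(
    dlog10_fit = fit_coupling_model(rec, response = "dlog10_gap",
                                    predictor = "delta_p"),
    pct_fit = fit_coupling_model(rec, response = "pct_gap_change",
                                 predictor = "delta_p")
  )
  structure(list_out, class = "change_coupling")
}

#' Contrast percent gap change across transition-change categories
#'
#' Mixed model of percent gap change on category (increased / decreased /
#' unchanged / stereotyped; same random structure), followed by Tukey HSD
#' pairwise comparisons of the category least-squares means (Tukey-Kramer
#' under imbalance, Satterthwaite df).
#'
#' @param records A `"change_records"` table including stereotyped records.
#' @param alpha Family-wise level recorded on the result.
#' @return List of class `"category_contrast"`: the omnibus `"coupling_fit"`
#'   (`fit`), an `lsmeans` tibble and a `tukey` tibble of pairwise contrasts.
#'   Categories with a single observation are dropped with a warning.
#' @export
category_contrast <- function(records, alpha = 0.05) {
  tabs <- table(records$category)
  singletons <- names(tabs)[tabs < 2]
  if (length(singletons)) {
    warn(paste("dropping categories with a single observation:",
               paste(singletons, collapse = ", ")))
    records <- filter(records, !.data$category %in% singletons)
  }
  if (dplyr::n_distinct(records$category) < 2) {
    abort("need at least 2 categories for the contrast")
  }
  rec <- records
  rec$category <- factor(rec$category,
                         levels = intersect(c("increased", "decreased",
                                              "unchanged", "stereotyped"),
                                            unique(rec$category)))
  dat <- data.frame(
    pct_gap_change = rec$pct_gap_change,
    category = rec$category,
    bird_id = factor(rec$bird_id),
    sequence_id = factor(paste(rec$bird_id, rec$sequence_id, sep = ":"))
  )
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(pct_gap_change ~ category + (1 | bird_id) + (1 | sequence_id),
                   data = dat, REML = TRUE, control = .lmm_control())))
  aov <- suppressMessages(anova(fit, ddf = "Satterthwaite"))
  cf <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  core <- list(fit = fit, anova = aov, coefficients = cf, varcomp = vc,
               data = dat)
  res <- .coupling_result(core, "pct_gap_change", "category", rec)
  emm <- emmeans::emmeans(fit, "category", lmer.df = "satterthwaite")
  ls <- as_tibble(as.data.frame(emm))
  names(ls)[1] <- "category"
  names(ls)[names(ls) == "emmean"] <- "lsmean"
  tk <- as_tibble(as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                                  adjust = "tukey")))
  structure(list(fit = res, lsmeans = ls, tukey = tk, alpha = alpha),
            class = "category_contrast")
}

#' Normality screen with log10 transform
#'
#' Shapiro-Wilk test on the raw values; log10-transformed values are always
#' returned alongside (the analyses transform regardless, for consistency),
#' with a flag recording whether the transform normalised the sample.
#'
#' @param values Positive numeric vector, 3 to 5000 values.
#' @param alpha Level used for the normality flags.
#' @return List: `statistic`, `p_value` (raw), `log10_values`,
#'   `log_statistic`, `log_p_value`, `raw_normal`, `log_normal`,
#'   `transform_normalized`.
#' @export
screen_normality <- function(values, alpha = 0.05) {
  if (length(values) < 3) abort("need at least 3 values")
  if (length(values) > 5000) abort("Shapiro-Wilk supports at most 5000 values")
  if (any(values <= 0)) abort("non-positive values cannot be log10-transformed")
  sw <- shapiro.test(values)
  lv <- log10(values)
  swl <- shapiro.test(lv)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       log10_values = lv,
       log_statistic = unname(swl$statistic), log_p_value = swl$p.value,
       raw_normal = sw$p.value >= alpha,
       log_normal = swl$p.value >= alpha,
       transform_normalized = sw$p.value < alpha && swl$p.value >= alpha)
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("<coupling_fit> %s ~ %s  (n = %d, %d birds)\n",
              x$response, x$predictor, x$n, x$n_birds))
  for (i in seq_along(x$term)) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", x$term[i], x$estimate[i], x$std_error[i]))
  }
  cat(sprintf("  F(%d, %.1f) = %.2f, p = %.4g%s\n",
              x$num_df, x$den_df, x$F_statistic, x$p_value,
              if (x$boundary) "  [variance component on boundary]" else ""))
  invisible(x)
}

#' @export
print.change_coupling <- function(x, ...) {
  cat("<change_coupling>\n  delta log10 gap ~ delta p:\n")
  print(x$dlog10_fit)
  cat("  percent gap change ~ delta p:\n")
  print(x$pct_fit)
  invisible(x)
}

#' @export
print.category_contrast <- function(x, ...) {
  cat("<category_contrast> percent gap change by category\n")
  print(x$lsmeans)
  print(x$tukey)
  invisible(x)
}
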