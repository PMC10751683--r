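# Trial-level forced-choice accuracy modelling: known-word and
# working-memory exclusions, predictor standardization, binomial mixed
# models with sum-coded factors, above-chance tests, pairwise contrasts and
# simple slopes.

#' Discard trials whose foreign word was previously known
#'
#' Known-word trials are removed participant-by-participant: any trial
#' flagged as involving a previously known foreign translation is dropped.
#'
#' @param trials Trial tibble with a logical `known_word_flag` column.
#' @return List with `trials` (retained rows) and `removed_fraction`.
#' @export
filter_known_word_trials <- function(trials) {
  if (!"known_word_flag" %in% names(trials) ||
      anyNA(trials$known_word_flag)) {
    stop("data-integrity error: known_word_flag missing for some trials",
         call. = FALSE)
  }
  keep <- !trials$known_word_flag
  list(trials = trials[keep, , drop = FALSE],
       removed_fraction = mean(!keep))
}

#' Exclude participants with low verbal working memory
#'
#' Retains participants whose digit-span score is above
#' `mean - k * sd` (sample standard deviation); participants at or below
#' the threshold are excluded.
#'
#' @param participants Participant tibble with a numeric `wm_span` column.
#' @param k Number of standard deviations below the mean (default 1.5).
#' @return List with `participants` (retained), `excluded` (removed rows),
#'   `threshold`.
#' @export
exclude_low_wm <- function(participants, k = 1.5) {
  if (nrow(participants) < 2) {
    stop("invalid-input error: need at least two participants", call. = FALSE)
  }
  m <- mean(participants$wm_span)
  s <- stats::sd(participants$wm_span)
  if (s == 0) {
    warning("zero variance in wm_span; no participants excluded",
            call. = FALSE)
    return(list(participants = participants,
                excluded = participants[0, , drop = FALSE],
                threshold = -Inf))
  }
  thr <- m - k * s
  keep <- participants$wm_span > thr
  list(participants = participants[keep, , drop = FALSE],
       excluded = participants[!keep, , drop = FALSE],
       threshold = thr)
}

#' z-score covariates over the analysis rows
#'
#' Adds `<name>_z` columns with mean 0 and sample sd 1 computed over the
#' rows supplied (i.e. after any exclusions). The centering/scaling
#' parameters are recorded in the `"standardization"` attribute for reuse.
#'
#' @param trials Analysis tibble.
#' @param covariates Character vector of numeric column names.
#' @return `trials` with added `_z` columns.
#' @export
standardize_predictors <- function(trials, covariates) {
  params <- purrr::map_dfr(covariates, function(v) {
    x <- trials[[v]]
    if (!is.numeric(x)) {
      stop("degenerate-covariate error: '", v, "' is not numeric",
           call. = FALSE)
    }
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      stop("degenerate-covariate error: '", v, "' has zero variance",
           call. = FALSE)
    }
    trials[[paste0(v, "_z")]] <<- (x - mean(x)) / s
    tibble::tibble(covariate = v, center = mean(x), scale = s)
  })
  attr(trials, "standardization") <- params
  trials
}

#' Fit the binomial mixed-effects accuracy model
#'
#' Fits a logit-link binomial GLMM of `correct` on the supplied fixed
#' effects with random intercepts for participant and item. Factors are sum
#' coded (each level contrasted against the grand mean). On non-convergence
#' the model falls back down a documented ladder: full random structure ->
#' drop the item intercept -> plain logistic regression with cluster-robust
#' standard errors by participant; the fallback taken is recorded.
#'
#' @param trials Trial tibble with `correct` (0/1), `participant_id`, and
#'   an item identifier column.
#' @param fixed One-sided or two-sided formula of fixed effects, e.g.
#'   `correct ~ language * pos` or `~ dist_z + reg_z * wm_z`.
#' @param item Name of the item identifier column (default `"item_id"`;
#'   created as `pair_id` x `language` when absent).
#' @param nAGQ Integration points passed to [lme4::glmer()]; `0` uses the
#'   faster penalized-likelihood approximation (used in large simulation
#'   sweeps).
#' @return Object of class `accuracy_fit`: `model`, `data`, `fixed`,
#'   `fallback` (`"full"`, `"no_item"` or `"glm_robust"`), `coefficients`
#'   tibble (estimate, SE, z, p; robust SEs under the final fallback),
#'   `random_intercept_sd`.
#' @export
fit_accuracy_model <- function(trials, fixed = correct ~ 1,
                               item = "item_id", nAGQ = 1L) {
  d <- as.data.frame(trials)
  if (is.null(d$correct) || !all(d$correct %in% 0:1)) {
    stop("invalid-input error: 'correct' must be a 0/1 column",
         call. = FALSE)
  }
  if (length(unique(d$correct)) < 2) {
    stop("separation error: all responses identical (",
         unique(d$correct), ")", call. = FALSE)
  }
  if (is.null(d[[item]])) {
    if (!is.null(d$pair_id) && !is.null(d$language)) {
      d[[item]] <- interaction(d$pair_id, d$language, drop = TRUE)
    } else if (!is.null(d$pair_id)) {
      d[[item]] <- d$pair_id
    } else {
      stop("invalid-input error: no item identifier column", call. = FALSE)
    }
  }
  d$participant_id <- factor(d$participant_id)
  d[[item]] <- factor(d[[item]])
  if (nlevels(d$participant_id) < 2 || nlevels(d[[item]]) < 2) {
    stop("invalid-input error: need at least two participants and two items",
         call. = FALSE)
  }

  rhs <- if (length(fixed) == 3) deparse(fixed[[3]]) else deparse(fixed[[2]])
  fvars <- intersect(all.vars(fixed), names(d))
  contr <- list()
  for (v in fvars) {
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
    if (is.factor(d[[v]])) {
      d[[v]] <- droplevels(d[[v]])
      contr[[v]] <- named_contr_sum(d[[v]])
    }
  }
  if (!length(contr)) contr <- NULL

  cell_sep <- separation_check(d, fvars)
  if (!is.null(cell_sep)) {
    stop("separation error: all responses identical in cell ", cell_sep,
         call. = FALSE)
  }

  forms <- list(
    full = paste("correct ~", rhs,
                 "+ (1 | participant_id) + (1 |", item, ")"),
    no_item = paste("correct ~", rhs, "+ (1 | participant_id)"),
    glm_robust = paste("correct ~", rhs)
  )

  fit <- NULL
  fallback <- NA_character_
  for (lvl in c("full", "no_item")) {
    cand <- tryCatch(
      withCallingHandlers(
        lme4::glmer(stats::as.formula(forms[[lvl]]), data = d,
                    family = stats::binomial(), contrasts = contr,
                    nAGQ = nAGQ,
                    control = lme4::glmerControl(calc.derivs = FALSE)),
        warning = function(w) {
          if (grepl("failed to converge|unable to evaluate|degenerate",
                    conditionMessage(w))) {
            invokeRestart("muffleWarning")
          } else {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    if (!is.null(cand) && converged_ok(cand)) {
      fit <- cand
      fallback <- lvl
      break
    }
  }
  if (is.null(fit)) {
    fit <- stats::glm(stats::as.formula(forms$glm_robust), data = d,
                      family = stats::binomial(), contrasts = contr)
    fallback <- "glm_robust"
  }

  co <- if (fallback == "glm_robust") {
    vc <- sandwich::vcovCL(fit, cluster = d$participant_id)
    est <- stats::coef(fit)
    se <- sqrt(diag(vc))
    z <- est / se
    tibble::tibble(term = names(est), estimate = unname(est),
                   se = unname(se), z = unname(z),
                   p = 2 * stats::pnorm(-abs(unname(z))))
  } else {
    cc <- summary(fit)$coefficients
    tibble::tibble(term = rownames(cc), estimate = cc[, 1], se = cc[, 2],
                   z = cc[, 3], p = cc[, 4])
  }

  re_sd <- if (fallback == "glm_robust") {
    NULL
  } else {
    vc <- lme4::VarCorr(fit)
    stats::setNames(vapply(vc, function(m) sqrt(m[1, 1]), numeric(1)),
                    names(vc))
  }

  structure(list(model = fit, data = d, fixed = fixed, item = item,
                 fallback = fallback, coefficients = co,
                 random_intercept_sd = re_sd, nAGQ = nAGQ,
                 contrasts = contr),
            class = "accuracy_fit")
}

named_contr_sum <- function(f) {
  k <- nlevels(f)
  cm <- stats::contr.sum(k)
  colnames(cm) <- levels(f)[-k]
  cm
}

# Detect fully separated design cells (all 0 or all 1) over factor crossings.
separation_check <- function(d, fvars) {
  facs <- fvars[vapply(fvars, function(v) is.factor(d[[v]]), logical(1))]
  if (!length(facs)) return(NULL)
  cell <- interaction(d[facs], drop = TRUE)
  tab <- tapply(d$correct, cell, function(x) length(unique(x)))
  sizes <- tapply(d$correct, cell, length)
  bad <- names(tab)[tab == 1 & sizes >= 20]
  if (length(bad)) paste(bad, collapse = ", ") else NULL
}

converged_ok <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || !any(grepl("failed to converge", msgs))
}

#' @export
print.accuracy_fit <- function(x, ...) {
  cat(sprintf("<accuracy_fit (%s): %s>\n", x$fallback,
              deparse(x$fixed)))
  print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio test for a fixed-effect term
#'
#' Refits the accuracy model without the named term (and any higher-order
#' terms containing it) and compares by likelihood-ratio chi-square.
#'
#' @param fit An `accuracy_fit` (must not be the robust-GLM fallback).
#' @param term Fixed-effect term to test, e.g. `"language"` or
#'   `"reg_z:wm_z"`.
#' @return Tibble with `term`, `chi_sq`, `df`, `p`.
#' @export
lr_test <- function(fit, term) {
  full_terms <- attr(stats::terms(
    stats::as.formula(paste("~", rhs_of(fit$fixed)))), "term.labels")
  if (!term %in% full_terms) {
    stop("specification error: term '", term, "' is not in the model",
         call. = FALSE)
  }
  keep <- full_terms[!vapply(full_terms, function(t) {
    all(strsplit(term, ":")[[1]] %in% strsplit(t, ":")[[1]])
  }, logical(1))]
  r_rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"

  if (fit$fallback == "glm_robust") {
    f1 <- fit$model
    f0 <- stats::update(f1, stats::as.formula(paste("correct ~", r_rhs)))
    a <- stats::anova(f0, f1, test = "Chisq")
    return(tibble::tibble(term = term, chi_sq = a$Deviance[2],
                          df = a$Df[2], p = a[["Pr(>Chi)"]][2]))
  }
  re <- if (fit$fallback == "full") {
    paste("+ (1 | participant_id) + (1 |", fit$item, ")")
  } else {
    "+ (1 | participant_id)"
  }
  # the reduced model must carry the same data symbol ('d') as the full fit
  # for anova.merMod's common-data check
  d <- fit$data
  f0 <- lme4::glmer(
    stats::as.formula(paste("correct ~", r_rhs, re)),
    data = d, family = stats::binomial(),
    contrasts = drop_unused_contrasts(fit$contrasts, r_rhs),
    nAGQ = fit$nAGQ,
    control = lme4::glmerControl(calc.derivs = FALSE))
  a <- stats::anova(f0, fit$model)
  tibble::tibble(term = term, chi_sq = a$Chisq[2], df = a$Df[2],
                 p = a[["Pr(>Chisq)"]][2])
}

rhs_of <- function(f) {
  if (length(f) == 3) deparse(f[[3]]) else deparse(f[[2]])
}

drop_unused_contrasts <- function(contr, rhs) {
  if (is.null(contr)) return(NULL)
  used <- all.vars(stats::as.formula(paste("~", rhs)))
  out <- contr[intersect(names(contr), used)]
  if (length(out)) out else NULL
}

#' Per-group tests against chance accuracy
#'
#' Estimated marginal means per level of a grouping factor, tested against
#' chance (probability 0.5, i.e. 0 on the logit scale) with Sidak
#' adjustment `p_adj = 1 - (1 - p)^m` over the `m` levels.
#'
#' @param fit An `accuracy_fit`.
#' @param by Name of the grouping factor.
#' @return Tibble: `level`, `prob` (adjusted probability), `ci_low`,
#'   `ci_high`, `logit`, `se`, `z`, `p`, `p_adj`.
#' @export
test_above_chance <- function(fit, by) {
  check_in_model(fit, by)
  emm <- emmeans::emmeans(fit$model, specs = by, data = fit$data)
  tt <- as.data.frame(emmeans::test(emm, null = 0, adjust = "none"))
  m <- nrow(tt)
  pr <- as.data.frame(summary(emm, type = "response"))
  tibble::tibble(
    level = as.character(tt[[1]]),
    prob = pr$prob,
    ci_low = pr$asymp.LCL,
    ci_high = pr$asymp.UCL,
    logit = tt$emmean,
    se = tt$SE,
    z = tt$z.ratio,
    p = tt$p.value,
    p_adj = sidak_adjust(tt$p.value, m)
  )
}

#' Sidak family-wise adjustment
#'
#' @param p Vector of unadjusted p-values.
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values `1 - (1 - p)^m`.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

#' Pairwise comparisons of a factor's levels as odds ratios
#'
#' All level pairs of a fixed factor as odds ratios with confidence
#' intervals and family-wise adjusted p-values. Sidak adjustment is the
#' default; `"tukey"` uses the multivariate-t method of the estimation
#' backend.
#'
#' @param fit An `accuracy_fit`.
#' @param factor Factor name with at least two levels.
#' @param adjust `"sidak"` (default) or `"tukey"`.
#' @param by Optional conditioning factor (one table per level).
#' @return Tibble: (`by` level,) `contrast`, `odds_ratio`, `se`, `ci_low`,
#'   `ci_high`, `z`, `p_adj`.
#' @export
pairwise_factor_comparisons <- function(fit, factor,
                                        adjust = c("sidak", "tukey"),
                                        by = NULL) {
  adjust <- match.arg(adjust)
  check_in_model(fit, factor)
  if (nlevels(fit$data[[factor]]) < 2) {
    stop("specification error: factor '", factor,
         "' has fewer than two levels", call. = FALSE)
  }
  spec <- if (is.null(by)) factor else stats::as.formula(
    paste("~", factor, "|", by))
  emm <- emmeans::emmeans(fit$model, specs = spec, data = fit$data)
  pw <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  s <- as.data.frame(summary(pw, infer = c(TRUE, TRUE), type = "response"))
  out <- tibble::tibble(
    contrast = as.character(s$contrast),
    odds_ratio = s$odds.ratio,
    se = s$SE,
    ci_low = s$asymp.LCL,
    ci_high = s$asymp.UCL,
    z = s$z.ratio,
    p_adj = s$p.value
  )
  if (!is.null(by)) out <- dplyr::bind_cols(s[by], out)
  out
}

#' Simple slopes of a covariate at moderator values
#'
#' Conditional slope of a covariate with the moderator held at mean plus or
#' minus one standard deviation (computed over the fitted analysis rows),
#' with Sidak-adjusted tests. Requires the covariate-by-moderator
#' interaction in the model.
#'
#' @param fit An `accuracy_fit`.
#' @param covariate Covariate whose slope is conditioned.
#' @param moderator Numeric moderator in the interaction.
#' @param at Multiples of the moderator SD (default `c(-1, 1)`).
#' @return Tibble: `at_sd`, `moderator_value`, `slope`, `se`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `z`, `p`, `p_adj`.
#' @export
simple_slopes <- function(fit, covariate, moderator, at = c(-1, 1)) {
  full_terms <- attr(stats::terms(
    stats::as.formula(paste("~", rhs_of(fit$fixed)))), "term.labels")
  has_int <- any(vapply(full_terms, function(t) {
    parts <- strsplit(t, ":")[[1]]
    all(c(covariate, moderator) %in% parts)
  }, logical(1)))
  if (!has_int) {
    stop("specification error: no ", covariate, " x ", moderator,
         " interaction in the model", call. = FALSE)
  }
  mv <- fit$data[[moderator]]
  vals <- mean(mv) + at * stats::sd(mv)
  emt <- emmeans::emtrends(
    fit$model, specs = moderator, var = covariate,
    at = stats::setNames(list(vals), moderator), data = fit$data)
  s <- as.data.frame(summary(emt, infer = c(TRUE, TRUE)))
  slope_col <- paste0(covariate, ".trend")
  p_raw <- as.data.frame(emmeans::test(emt, adjust = "none"))$p.value
  tibble::tibble(
    at_sd = at,
    moderator_value = s[[moderator]],
    slope = s[[slope_col]],
    se = s$SE,
    odds_ratio = exp(s[[slope_col]]),
    ci_low = exp(s$asymp.LCL),
    ci_high = exp(s$asymp.UCL),
    z = s$z.ratio,
    p = p_raw,
    p_adj = sidak_adjust(p_raw, length(at))
  )
}

check_in_model <- function(fit, var) {
  if (!var %in% all.vars(fit$fixed)) {
    stop("specification error: '", var, "' is not in the fitted model",
         call. = FALSE)
  }
  invisible(TRUE)
}
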