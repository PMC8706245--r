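as_factor2 <- function(x) if (is.factor(x)) x else factor(x)

#' Two-way ANOVA with partial eta-squared
#'
#' Fits `outcome ~ stage * age` (or any two factors) by least squares with
#' sum-to-zero contrasts and computes Type III sums of squares -- the
#' conventional choice for unbalanced stage-by-age designs -- with partial
#' eta-squared `SS_effect / (SS_effect + SS_error)` for each effect. When a
#' design cell is empty the interaction is inestimable; the model then falls
#' back to main effects only and the result is flagged.
#'
#' @param data Cohort tibble.
#' @param outcome Name of the outcome column (string).
#' @param factors Character vector of the two factor columns.
#' @param ss_type 3 (default) or 2, passed to `car::Anova`.
#' @return Object of class `jump_anova`: list with `table` (tibble: effect,
#'   df, sumsq, f, p, partial_eta_sq), `fit`, `error_df`, `flags`.
#' @export
two_way_anova <- function(data, outcome, factors = c("stage", "age_group"),
                          ss_type = 3) {
  stopifnot(length(factors) == 2, all(factors %in% names(data)),
            outcome %in% names(data))
  df <- data
  df$.y <- df[[outcome]]
  df$.f1 <- droplevels(as_factor2(df[[factors[1]]]))
  df$.f2 <- droplevels(as_factor2(df[[factors[2]]]))
  if (nlevels(df$.f1) < 2 || nlevels(df$.f2) < 2) {
    abort("each factor needs at least 2 observed levels")
  }
  flags <- character(0)
  cells <- table(df$.f1, df$.f2)
  form <- .y ~ .f1 * .f2
  if (any(cells == 0)) {
    flags <- c(flags, "empty_cells_main_effects_only")
    form <- .y ~ .f1 + .f2
  }
  contr <- list(.f1 = "contr.sum", .f2 = "contr.sum")
  fit <- lm(form, data = df, contrasts = contr)
  at <- car::Anova(fit, type = ss_type)
  tab <- tibble::tibble(
    effect = rownames(at), sumsq = at[["Sum Sq"]], df = at[["Df"]],
    f = at[["F value"]], p = at[["Pr(>F)"]])
  err <- tab[tab$effect == "Residuals", ]
  tab <- tab[!tab$effect %in% c("Residuals", "(Intercept)"), ]
  tab$partial_eta_sq <- tab$sumsq / (tab$sumsq + err$sumsq)
  rename_map <- c(".f1" = factors[1], ".f2" = factors[2],
                  ".f1:.f2" = paste0(factors[1], ":", factors[2]))
  tab$effect <- unname(rename_map[tab$effect])
  structure(list(table = tab, fit = fit, error_df = err$df,
                 error_ss = err$sumsq, outcome = outcome,
                 factors = factors, flags = flags),
            class = "jump_anova")
}

#' @export
print.jump_anova <- function(x, ...) {
  cat(sprintf("<jump_anova> %s ~ %s * %s\n", x$outcome,
              x$factors[1], x$factors[2]))
  print(x$table)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.jump_anova <- function(x, ...) x$table

#' @export
glance.jump_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, df.residual = x$error_df,
                 sigma = s$sigma, nobs = length(resid(x$fit)))
}

#' LSD post-hoc pairwise comparisons
#'
#' Fisher's least-significant-difference tests between the levels of one
#' factor, using the pooled error mean square of the two-way ANOVA (so the
#' comparison respects the full design) and unadjusted p values.
#'
#' @param data Cohort tibble.
#' @param outcome Outcome column name.
#' @param factor Factor column whose levels are compared.
#' @param anova Optional [two_way_anova()] fit to take the error term from;
#'   by default one is fitted on `data` with the default factors, falling
#'   back to one-way error if the second factor is absent.
#' @return Tibble: `level_1`, `level_2`, `diff`, `se`, `t`, `df`, `p`,
#'   `flag`.
#' @export
lsd_posthoc <- function(data, outcome, factor, anova = NULL) {
  if (is.null(anova)) {
    others <- intersect(c("stage", "age_group"), names(data))
    second <- setdiff(others, factor)[1]
    anova <- if (!is.na(second)) {
      two_way_anova(data, outcome, c(factor, second))
    } else {
      NULL
    }
  }
  f <- droplevels(as_factor2(data[[factor]]))
  y <- data[[outcome]]
  if (is.null(anova)) {
    fit1 <- lm(y ~ f)
    mse <- sum(resid(fit1)^2) / fit1$df.residual
    dfe <- fit1$df.residual
  } else {
    mse <- anova$error_ss / anova$error_df
    dfe <- anova$error_df
  }
  lev <- levels(f)
  means <- tapply(y, f, mean)
  ns <- tapply(y, f, length)
  pairs <- utils::combn(lev, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    if (ns[l1] < 2 || ns[l2] < 2) {
      return(tibble::tibble(level_1 = l1, level_2 = l2, diff = NA_real_,
                            se = NA_real_, t = NA_real_, df = dfe,
                            p = NA_real_, flag = "level_with_n_lt_2"))
    }
    se <- sqrt(mse * (1 / ns[l1] + 1 / ns[l2]))
    tv <- (means[l1] - means[l2]) / se
    tibble::tibble(level_1 = l1, level_2 = l2,
                   diff = unname(means[l1] - means[l2]), se = se,
                   t = unname(tv), df = dfe,
                   p = unname(2 * pt(-abs(tv), dfe)), flag = "")
  })
}

#' Collinearity diagnostics
#'
#' Tolerance and variance inflation factor for each predictor:
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor j on the others. A
#' perfectly collinear predictor is reported with infinite VIF and flagged.
#'
#' @param data Tibble.
#' @param predictors Character vector of at least two predictor columns.
#' @return Tibble: `term`, `tolerance`, `vif`, `flag`.
#' @export
collinearity_diagnostics <- function(data, predictors) {
  stopifnot(length(predictors) >= 2)
  X <- as.data.frame(data[predictors])
  purrr::map_dfr(predictors, function(pj) {
    fit <- lm(stats::reformulate(setdiff(predictors, pj), response = pj),
              data = X)
    # a perfectly collinear predictor fits exactly; the flagged Inf VIF
    # below is the expected report, not a numerical accident
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) {
      tibble::tibble(term = pj, tolerance = 0, vif = Inf,
                     flag = "perfectly_collinear")
    } else {
      tibble::tibble(term = pj, tolerance = 1 - r2, vif = 1 / (1 - r2),
                     flag = "")
    }
  })
}

#' Durbin-Watson statistic
#'
#' `DW = sum((e_t - e_(t-1))^2) / sum(e_t^2)`; values near 2 indicate no
#' first-order autocorrelation of the residuals (1.5-2.5 is the customary
#' acceptance band).
#'
#' @param residuals Numeric residual vector (>= 2 values).
#' @return The statistic, in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) abort("need at least 2 residuals")
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Stepwise linear regression (forward entry, backward removal)
#'
#' The SPSS-style stepwise procedure: at each step the excluded candidate
#' with the smallest partial-F p value enters if it is below `p_enter`; then
#' any included predictor whose p value has risen above `p_remove` is
#' removed (worst first). Iterates to a fixed point. The returned model
#' reports unstandardized and standardized coefficients, per-predictor t and
#' p, tolerance and VIF, the Durbin-Watson statistic and R-squared.
#'
#' @param data Tibble.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must be >= `p_enter`.
#' @return Object of class `jump_stepwise`: list with `terms` (tibble),
#'   `selected`, `fit`, `r_squared`, `durbin_watson`, `flags`, `steps`.
#' @export
stepwise_regression <- function(data, outcome, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)))
  if (p_enter > p_remove) abort("p_enter must be <= p_remove")
  n <- nrow(data)
  if (n <= length(candidates) + 1) {
    abort("need n > number of candidates + 1")
  }
  included <- character(0)
  steps <- list()
  refit <- function(vars) {
    form <- if (length(vars)) {
      stats::reformulate(vars, response = outcome)
    } else {
      stats::reformulate("1", response = outcome)
    }
    lm(form, data = data)
  }
  coef_p <- function(fit) {
    ct <- summary(fit)$coefficients
    setNames(ct[, 4], rownames(ct))[-1]
  }
  repeat {
    changed <- FALSE
    # entry; with a numerically perfect fit the partial-F tests on the
    # residual noise floor are meaningless, so entry stops
    excluded <- setdiff(candidates, included)
    if (length(included) &&
        summary(refit(included))$r.squared > 1 - 1e-10) {
      excluded <- character(0)
    }
    if (length(excluded)) {
      entry_p <- vapply(excluded, function(v) {
        fit <- refit(c(included, v))
        summary(fit)$coefficients[v, 4]
      }, numeric(1))
      best <- names(which.min(entry_p))
      if (entry_p[best] < p_enter) {
        included <- c(included, best)
        steps[[length(steps) + 1]] <- paste0("+", best)
        changed <- TRUE
      }
    }
    # removal
    repeat {
      if (length(included) == 0) break
      pv <- coef_p(refit(included))[included]
      worst <- names(which.max(pv))
      if (pv[worst] > p_remove) {
        included <- setdiff(included, worst)
        steps[[length(steps) + 1]] <- paste0("-", worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  flags <- character(0)
  if (length(included) == 0) flags <- c(flags, "intercept_only")
  fit <- refit(included)
  ct <- summary(fit)$coefficients
  sy <- sd(data[[outcome]])
  terms <- tibble::tibble(
    term = rownames(ct), estimate = ct[, 1], std_error = ct[, 2],
    t = ct[, 3], p = ct[, 4])
  terms$beta <- unname(c(NA_real_, vapply(included, function(v) {
    ct[v, 1] * sd(data[[v]]) / sy
  }, numeric(1)))[seq_len(nrow(terms))])
  if (length(included) >= 2) {
    cd <- collinearity_diagnostics(data, included)
    terms <- dplyr::left_join(terms, cd[, c("term", "tolerance", "vif")],
                              by = "term")
  } else {
    terms$tolerance <- ifelse(terms$term == "(Intercept)", NA_real_, 1)
    terms$vif <- terms$tolerance
  }
  structure(list(terms = terms, selected = included, fit = fit,
                 r_squared = summary(fit)$r.squared,
                 durbin_watson = durbin_watson(resid(fit)),
                 flags = flags, steps = unlist(steps)),
            class = "jump_stepwise")
}

#' @export
print.jump_stepwise <- function(x, ...) {
  cat(sprintf("<jump_stepwise> %d predictor(s) selected, R^2 = %.3f, DW = %.3f\n",
              length(x$selected), x$r_squared, x$durbin_watson))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.jump_stepwise <- function(x, ...) x$terms

#' @export
glance.jump_stepwise <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 durbin_watson = x$durbin_watson,
                 n_selected = length(x$selected),
                 df.residual = x$fit$df.residual,
                 nobs = length(resid(x$fit)))
}
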