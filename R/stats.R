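#' Spearman correlation of beta power with kinematics
#'
#' Non-parametric (rank) correlation of the per-trial pre-movement beta
#' statistic with reaction time and reach duration, average-rank tie
#' handling, p-values from the t approximation.
#'
#' @param trials Tibble with `beta_logpower`, `rt_ms`, `duration_ms`.
#' @return Tibble with one row per metric: `metric`, `rho`, `p`, `n`,
#'   `flag` (`"constant input"` when a correlation is undefined).
#' @export
correlate_beta_kinematics <- function(trials) {
  need <- c("beta_logpower", "rt_ms", "duration_ms")
  stopifnot(all(need %in% names(trials)))
  d <- trials[complete.cases(trials[, need]), need]
  if (nrow(d) < 5) abort("need at least 5 complete trials.")
  one <- function(yname) {
    y <- d[[yname]]
    if (sd(d$beta_logpower) == 0 || sd(y) == 0) {
      return(tibble(metric = yname, rho = NA_real_, p = NA_real_,
                    n = nrow(d), flag = "constant input"))
    }
    ct <- suppressWarnings(
      cor.test(d$beta_logpower, y, method = "spearman", exact = FALSE)
    )
    tibble(metric = yname, rho = unname(ct$estimate), p = ct$p.value,
           n = nrow(d), flag = NA_character_)
  }
  bind_rows(one("rt_ms"), one("duration_ms"))
}

#' Regression of beta power on subsequent error magnitude
#'
#' Simple linear regression of absolute endpoint error on the trial's
#' pre-movement beta power, reported as the slope F-test with
#' `df = (1, n - 2)`.
#'
#' @param trials Tibble with `beta_logpower` and `endpoint_error_deg` (or
#'   a precomputed `abs_error` column).
#' @return One-row tibble `F`, `df1`, `df2`, `p`, `r_squared`, `slope`,
#'   `n`, `flag`.
#' @export
regress_beta_error <- function(trials) {
  stopifnot("beta_logpower" %in% names(trials))
  abs_err <- trials[["abs_error"]] %||% abs(trials$endpoint_error_deg)
  d <- tibble(beta = trials$beta_logpower, abs_error = abs_err)
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3) abort("need at least 3 complete trials.")
  if (sd(d$beta) == 0) {
    return(tibble(F = NA_real_, df1 = 1, df2 = nrow(d) - 2, p = NA_real_,
                  r_squared = NA_real_, slope = NA_real_, n = nrow(d),
                  flag = "zero-variance predictor"))
  }
  fit <- lm(abs_error ~ beta, data = d)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  tibble(F = fstat[1], df1 = fstat[2], df2 = fstat[3],
         p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
         r_squared = sm$r.squared, slope = unname(coef(fit)[2]),
         n = nrow(d), flag = NA_character_)
}

#' Covariate-adjusted epoch contrast
#'
#' Fixed-effects linear model `beta ~ epoch + covariates (+ subject)`:
#' the omnibus partial F test for the epoch factor, all pairwise contrasts
#' of covariate-adjusted epoch means with Bonferroni correction, and the
#' covariate coefficients. This is the analysis applied to the per-trial
#' beta table in both species (all ten epoch pairs for the five human
#' epochs; the three Baseline/EA/LA pairs in cat mode).
#'
#' @param trials Tibble with the response, an epoch factor and the
#'   covariate columns.
#' @param response Response column name (default `"beta_logpower"`).
#' @param epoch Condition column name (default `"epoch"`).
#' @param covariates Character vector of covariate columns (default
#'   reaction time and duration).
#' @param subject Optional subject column, entered as a fixed factor.
#' @return Object of class `bd_contrast`, with [tidy()] (pairwise table)
#'   and [glance()] (omnibus row) methods.
#' @export
epoch_contrast <- function(trials, response = "beta_logpower",
                           epoch = "epoch",
                           covariates = c("rt_ms", "duration_ms"),
                           subject = NULL) {
  cols <- c(response, epoch, covariates, subject)
  stopifnot(all(cols %in% names(trials)))
  d <- trials[, cols]
  names(d) <- c(".y", ".epoch", paste0(".c", seq_along(covariates)),
                if (!is.null(subject)) ".subject")
  d$.epoch <- factor(d$.epoch)
  d <- droplevels(d[complete.cases(d), ])
  lev <- levels(d$.epoch)
  if (length(lev) < 2) abort("need at least 2 epochs.")
  if (any(table(d$.epoch) < 3)) abort("every epoch needs at least 3 trials.")
  rhs <- c(".epoch", paste0(".c", seq_along(covariates)),
           if (!is.null(subject)) ".subject")
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  mm <- model.matrix(fml, d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(paste0("rank-deficient design; aliased columns: ",
                 paste(aliased, collapse = ", ")))
  }
  fit <- lm(fml, data = d)
  red <- lm(stats::as.formula(paste(".y ~", paste(setdiff(rhs, ".epoch"),
                                                  collapse = " + "))),
            data = d)
  av <- anova(red, fit)
  fstat <- av$F[2]
  if (!is.finite(fstat)) {
    # degenerate perfect fits: zero residual variance. No extra epoch sum
    # of squares means F = 0; any extra signal with zero residual is Inf.
    fstat <- if (abs(av$`Sum of Sq`[2]) < 1e-12) 0 else Inf
  }
  omnibus <- tibble(F = fstat, df1 = av$Df[2], df2 = av$Res.Df[2],
                    p = pf(fstat, av$Df[2], av$Res.Df[2], lower.tail = FALSE))
  # adjusted means: epoch effects at covariate grand means (and averaged
  # over subjects); with treatment coding the pairwise differences are
  # differences of epoch coefficients
  b <- coef(fit)
  V <- vcov(fit)
  coef_of <- function(l) if (l == lev[1]) NA else paste0(".epoch", l)
  eff <- setNames(numeric(length(lev)), lev)
  for (l in lev[-1]) eff[l] <- b[coef_of(l)]
  cov_means <- vapply(seq_along(covariates),
                      function(i) mean(d[[paste0(".c", i)]]), numeric(1))
  adj_base <- b["(Intercept)"] +
    sum(b[paste0(".c", seq_along(covariates))] * cov_means)
  if (!is.null(subject)) {
    sub_terms <- grep("^\\.subject", names(b), value = TRUE)
    if (length(sub_terms)) {
      tab <- table(d$.subject) / nrow(d)
      sub_lev <- levels(factor(d$.subject))
      w <- as.numeric(tab[sub_lev[-1]])
      adj_base <- adj_base + sum(b[sub_terms] * w)
    }
  }
  adjusted <- tibble(epoch = lev, adj_mean = unname(adj_base + eff),
                     n = as.integer(table(d$.epoch)[lev]))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  npairs <- length(pairs)
  df_res <- fit$df.residual
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    L <- setNames(rep(0, length(b)), names(b))
    if (pr[1] != lev[1]) L[coef_of(pr[1])] <- 1
    if (pr[2] != lev[1]) L[coef_of(pr[2])] <- -1
    est <- sum(L * b)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tt <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
    praw <- 2 * pt(-abs(tt), df_res)
    tibble(epoch_a = pr[1], epoch_b = pr[2], estimate = est, se = se,
           t = tt, p = praw, p_bonferroni = pmin(1, praw * npairs))
  })
  cov_tab <- tibble(
    name = covariates,
    coefficient = unname(b[paste0(".c", seq_along(covariates))]),
    p = vapply(seq_along(covariates), function(i) {
      ci <- paste0(".c", i)
      tt <- b[ci] / sqrt(V[ci, ci])
      2 * pt(-abs(tt), df_res)
    }, numeric(1))
  )
  structure(
    list(omnibus = omnibus, pairwise = pairwise, adjusted = adjusted,
         covariates = cov_tab, levels = lev, n = nrow(d),
         df_residual = df_res, fit = fit),
    class = "bd_contrast"
  )
}

#' @export
print.bd_contrast <- function(x, ...) {
  cat(sprintf("<bd_contrast> %d trials, %d epochs; omnibus F(%d, %d) = %.3f, p = %.3g\n",
              x$n, length(x$levels), x$omnibus$df1, x$omnibus$df2,
              x$omnibus$F, x$omnibus$p))
  print(x$pairwise, ...)
  invisible(x)
}

#' Balanced bootstrap comparison of conditions
#'
#' Equalises condition sizes by resampling: on each of `n_boot` replicates
#' `m = min(n_k)` observations are drawn with replacement from every
#' condition and the condition means recorded. Reports per-condition
#' bootstrap mean and SE, and for every condition pair the percentile
#' 95% CI of the mean difference and a Bonferroni-adjusted empirical
#' two-sided p value.
#'
#' @param trials Tibble holding the response and condition columns.
#' @param response,condition Column names (defaults `beta_logpower`,
#'   `epoch`).
#' @param n_boot Replicates (default 1000).
#' @param seed Integer seed; same seed gives bit-identical results.
#' @return Object of class `bd_bootstrap` with `conditions`, `pairwise`,
#'   `n_boot`, `m` and a `flag` noting degenerate (single-trial)
#'   conditions; [tidy()] and [glance()] methods.
#' @export
bootstrap_balanced <- function(trials, response = "beta_logpower",
                               condition = "epoch", n_boot = 1000,
                               seed = 1) {
  stopifnot(all(c(response, condition) %in% names(trials)))
  y <- trials[[response]]
  g <- factor(trials[[condition]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  lev <- levels(g)
  if (length(lev) < 2) abort("need at least 2 non-empty conditions.")
  sizes <- table(g)
  flag <- if (any(sizes == 1)) "degenerate resampling: single-trial condition" else NA_character_
  m <- min(sizes)
  groups <- split(y, g)
  withr::with_seed(stage_seed(seed, "bootstrap"), {
    means <- vapply(seq_len(n_boot), function(b) {
      vapply(groups, function(v) mean(v[sample.int(length(v), m, replace = TRUE)]),
             numeric(1))
    }, numeric(length(lev)))
  })
  means <- t(means)                      # n_boot x conditions
  conditions <- tibble(
    condition = lev,
    n = as.integer(sizes[lev]),
    observed_mean = vapply(groups, mean, numeric(1))[lev],
    boot_mean = colMeans(means),
    boot_se = apply(means, 2, sd)
  )
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  npairs <- length(pairs)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    d <- means[, pr[1]] - means[, pr[2]]
    ci <- unname(quantile(d, c(0.025, 0.975), type = 7))
    p_emp <- 2 * min(mean(d <= 0), mean(d >= 0))
    p_emp <- min(1, max(p_emp, 1 / n_boot))
    tibble(condition_a = pr[1], condition_b = pr[2],
           estimate = mean(d), ci_lo = ci[1], ci_hi = ci[2],
           p = p_emp, p_bonferroni = pmin(1, p_emp * npairs))
  })
  structure(list(conditions = conditions, pairwise = pairwise,
                 n_boot = n_boot, m = as.integer(m), flag = flag),
            class = "bd_bootstrap")
}

#' @export
print.bd_bootstrap <- function(x, ...) {
  cat(sprintf("<bd_bootstrap> %d replicates, balanced n = %d per condition\n",
              x$n_boot, x$m))
  if (!is.na(x$flag)) cat("note:", x$flag, "\n")
  print(x$pairwise, ...)
  invisible(x)
}
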