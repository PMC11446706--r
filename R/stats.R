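#' ICC(A,1): single-rater two-way mixed-effects absolute agreement
#'
#' Intraclass correlation for absolute agreement of single measurements
#' under a two-way model, computed from the ANOVA mean squares of the
#' subjects-by-sessions matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with MSR the between-subject, MSC the between-session and MSE the
#' residual mean square. The p-value is from the subject-effect F test
#' `F = MSR / MSE` with `(n-1, (n-1)(k-1))` degrees of freedom (the ICC
#' family's conventional test; the null is no subject-to-subject
#' consistency). Rows with missing values are dropped listwise.
#'
#' @param data numeric matrix or data frame, subjects in rows, sessions
#'   (raters) in columns; at least 3 complete rows and 2 columns.
#' @return A list: `icc`, `p`, `n` (complete subjects), `k`, `n_dropped`,
#'   `degenerate` (TRUE when total variance is zero, in which case ICC is
#'   defined as 1 and `p` is `NA`).
#' @export
icc_a1 <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("data must be numeric")
  complete <- complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("at least 2 sessions are required")
  if (n < 3L) stop("at least 3 complete subjects are required, got ", n)
  g <- mean(x)
  sst <- sum((x - g)^2)
  if (sst < 1e-24 * max(1, g^2))
    return(list(icc = 1, p = NA_real_, n = n, k = k,
                n_dropped = n_dropped, degenerate = TRUE))
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  f <- if (mse > 0) msr / mse else Inf
  p <- pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p = p, n = n, k = k, n_dropped = n_dropped,
       degenerate = FALSE)
}

#' Qualitative reliability band for an ICC
#'
#' Conventional interpretation: above 0.90 excellent, above 0.75 good,
#' 0.50 to 0.75 moderate, below 0.50 poor.
#'
#' @param icc numeric vector of ICC values.
#' @return Character vector of bands.
#' @export
icc_band <- function(icc) {
  out <- rep(NA_character_, length(icc))
  out[!is.na(icc) & icc < 0.50] <- "poor"
  out[!is.na(icc) & icc >= 0.50 & icc <= 0.75] <- "moderate"
  out[!is.na(icc) & icc > 0.75 & icc <= 0.90] <- "good"
  out[!is.na(icc) & icc > 0.90] <- "excellent"
  out
}

#' Normality-gated correlation
#'
#' Shapiro-Wilk is applied to each variable; when both pass at `alpha` the
#' Pearson coefficient is reported, otherwise Spearman's rank correlation.
#' The chosen type is always reported alongside the coefficient.
#'
#' @param x,y paired numeric vectors (missing pairs dropped; n >= 3).
#' @param alpha significance level of the normality gate.
#' @return A list: `type` ("pearson"/"spearman" or `NA` for degenerate
#'   input), `estimate`, `p`, `n`, and `flag` for degenerate cases.
#' @export
gated_correlation <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required, got ", n)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(type = NA_character_, estimate = NA_real_, p = NA_real_,
                n = n, flag = "constant_input"))
  normal <- shapiro.test(x)$p.value > alpha &&
    shapiro.test(y)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(type = method, estimate = unname(ct$estimate), p = ct$p.value,
       n = n, flag = NULL)
}

#' Holm step-down multiple-testing adjustment
#'
#' Familywise error control by Holm's method: p-values are sorted
#' ascending, the i-th smallest is multiplied by `(m - i + 1)`, a running
#' maximum enforces monotonicity, results are capped at 1 and mapped back
#' to the input order. `NA`s pass through.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(pvalues) {
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad))
    stop("p-values must lie in [0, 1]; offending value: ",
         pvalues[which(bad)[1]])
  p.adjust(pvalues, method = "holm")
}

#' Normality-gated group comparison
#'
#' Shapiro-Wilk gate at `alpha`: for paired data the gate is applied to the
#' differences, for independent groups to both samples. Normal data use the
#' t-test (paired, or Welch two-sample); otherwise the Wilcoxon signed-rank
#' (paired) or rank-sum test, exact when the larger sample has at most 25
#' observations and no ties, with the normal approximation as fallback.
#'
#' @param x,y numeric samples (equal length when `paired`); n >= 3 each.
#' @param paired logical.
#' @param alpha normality-gate significance level.
#' @return A list: `test` ("t", "wilcoxon" or "degenerate"), `statistic`,
#'   `p`, `normal` (gate outcome), and `flag` for degenerate cases.
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    if (length(x) < 3L) stop("at least 3 pairs are required")
    d <- x - y
    if (sd(d) == 0)
      return(list(test = "degenerate", statistic = NA_real_, p = 1,
                  normal = NA, flag = "zero_variance_differences"))
    normal <- shapiro.test(d)$p.value > alpha
    if (normal) {
      ht <- t.test(x, y, paired = TRUE)
    } else {
      exact <- length(d) <= 25 && !any(duplicated(abs(d[d != 0]))) &&
        all(d != 0)
      ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
    }
  } else {
    if (length(x) < 3L || length(y) < 3L)
      stop("at least 3 observations per group are required")
    if (sd(x) == 0 && sd(y) == 0)
      return(list(test = "degenerate", statistic = NA_real_, p = 1,
                  normal = NA, flag = "zero_variance_groups"))
    normal <- sd(x) > 0 && sd(y) > 0 &&
      shapiro.test(x)$p.value > alpha && shapiro.test(y)$p.value > alpha
    if (normal) {
      ht <- t.test(x, y)  # Welch
    } else {
      exact <- max(length(x), length(y)) <= 25 && !any(duplicated(c(x, y)))
      ht <- suppressWarnings(wilcox.test(x, y, exact = exact))
    }
  }
  list(test = if (normal) "t" else "wilcoxon",
       statistic = unname(ht$statistic), p = ht$p.value, normal = normal,
       flag = NULL)
}

#' Standardized response mean
#'
#' Effect size of a longitudinal change: mean of the paired changes divided
#' by their sample standard deviation.
#'
#' @param baseline,followup paired numeric vectors (n >= 2 complete pairs).
#' @return SRM, or `NA` with `attr(, "flag")` when the change sd is zero.
#' @export
srm <- function(baseline, followup) {
  if (length(baseline) != length(followup))
    stop("baseline and followup must be paired")
  ok <- !is.na(baseline) & !is.na(followup)
  d <- followup[ok] - baseline[ok]
  if (length(d) < 2L) stop("at least 2 complete pairs are required")
  s <- sd(d)
  if (s == 0) return(structure(NA_real_, flag = "zero_variance_change"))
  mean(d) / s
}

# subjects x sessions wide matrix for one (muscle, side, metric) cell
.session_matrix <- function(df, sessions) {
  subs <- sort(unique(df$subject_id))
  m <- matrix(NA_real_, length(subs), length(sessions),
              dimnames = list(subs, sessions))
  for (i in seq_len(nrow(df))) {
    s <- df$session[i]
    if (s %in% sessions) m[df$subject_id[i], s] <- df$value[i]
  }
  m
}

#' Test-retest reliability report
#'
#' For every (metric, side, muscle) cell with enough complete
#' subject-session pairs: ICC(A,1) with its subject-effect p-value and
#' qualitative band, plus the normality-gated baseline-vs-retest
#' correlation. Holm correction is applied to the correlation p-values
#' within each (metric, side) family of muscles, matching per-table
#' familywise control.
#'
#' @param table a [measurement_table] containing both sessions.
#' @param sessions length-2 character vector of session names.
#' @param alpha significance level.
#' @param holm apply Holm correction within each (metric, side) family.
#' @param min_n minimum complete subjects per cell (>= 3).
#' @return Data frame with columns `metric`, `side`, `muscle`, `n`, `icc`,
#'   `icc_p`, `icc_band`, `correlation_type`, `correlation`,
#'   `correlation_p`, `holm_adjusted_p`.
#' @export
reliability_report <- function(table, sessions = c("baseline", "week1"),
                               alpha = 0.05, holm = TRUE, min_n = 3) {
  table <- measurement_table(table)
  stopifnot(length(sessions) == 2L, min_n >= 3)
  df <- table[table$session %in% sessions, , drop = FALSE]
  if (!nrow(df)) stop("no rows for sessions ", paste(sessions, collapse = ", "))
  cells <- unique(df[c("metric", "side", "muscle")])
  cells <- cells[order(cells$metric, cells$side, cells$muscle), , drop = FALSE]
  out <- vector("list", nrow(cells))
  skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    sub <- df[df$metric == cells$metric[i] & df$side == cells$side[i] &
                df$muscle == cells$muscle[i], , drop = FALSE]
    m <- .session_matrix(sub, sessions)
    m <- m[complete.cases(m), , drop = FALSE]
    if (nrow(m) < min_n) {
      skipped <- skipped + 1L
      next
    }
    icc <- icc_a1(m)
    corr <- gated_correlation(m[, 1], m[, 2], alpha = alpha)
    out[[i]] <- data.frame(
      metric = cells$metric[i], side = cells$side[i],
      muscle = cells$muscle[i], n = icc$n,
      icc = icc$icc, icc_p = icc$p, icc_band = icc_band(icc$icc),
      correlation_type = corr$type %||% NA_character_,
      correlation = corr$estimate, correlation_p = corr$p,
      stringsAsFactors = FALSE)
  }
  if (skipped) message(skipped, " cell(s) skipped (fewer than ", min_n,
                       " complete subjects)")
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no cell had enough complete subjects")
  res$holm_adjusted_p <- res$correlation_p
  if (holm) {
    fam <- paste(res$metric, res$side)
    for (f in unique(fam)) {
      sel <- fam == f
      res$holm_adjusted_p[sel] <- holm_adjust(res$correlation_p[sel])
    }
  }
  rownames(res) <- NULL
  res
}

#' Longitudinal change report
#'
#' For every (metric, group, interval, side, muscle): baseline mean and sd,
#' change (followup minus baseline) mean and sd over subjects with both
#' visits, a normality-gated paired comparison of followup vs baseline, and
#' the standardized response mean. Holm correction is applied across
#' muscles within each (metric, group, interval, side) family. Subjects
#' missing a visit are dropped listwise per cell.
#'
#' @param table a [measurement_table].
#' @param baseline_session baseline session name.
#' @param followup_sessions session names to compare against baseline.
#' @param alpha significance level.
#' @param holm apply Holm correction.
#' @param min_n minimum paired subjects per cell.
#' @return Data frame with columns `metric`, `group`, `interval`, `side`,
#'   `muscle`, `n`, `baseline_mean`, `baseline_sd`, `change_mean`,
#'   `change_sd`, `test`, `p`, `holm_adjusted_p`, `srm`.
#' @export
longitudinal_report <- function(table, baseline_session = "baseline",
                                followup_sessions = c("month9", "month18"),
                                alpha = 0.05, holm = TRUE, min_n = 3) {
  table <- measurement_table(table)
  out <- list()
  for (metric in unique(table$metric)) {
    for (grp in unique(table$group)) {
      for (fu in followup_sessions) {
        df <- table[table$metric == metric & table$group == grp &
                      table$session %in% c(baseline_session, fu), ,
                    drop = FALSE]
        if (!nrow(df)) next
        cells <- unique(df[c("side", "muscle")])
        for (i in seq_len(nrow(cells))) {
          sub <- df[df$side == cells$side[i] & df$muscle == cells$muscle[i], ,
                    drop = FALSE]
          m <- .session_matrix(sub, c(baseline_session, fu))
          m <- m[complete.cases(m), , drop = FALSE]
          if (nrow(m) < min_n) next
          chg <- m[, 2] - m[, 1]
          cmp <- compare_groups(m[, 2], m[, 1], paired = TRUE, alpha = alpha)
          out[[length(out) + 1L]] <- data.frame(
            metric = metric, group = grp, interval = fu,
            side = cells$side[i], muscle = cells$muscle[i], n = nrow(m),
            baseline_mean = mean(m[, 1]), baseline_sd = sd(m[, 1]),
            change_mean = mean(chg), change_sd = sd(chg),
            test = cmp$test, p = cmp$p,
            srm = as.numeric(srm(m[, 1], m[, 2])),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no cell had enough paired subjects")
  res$holm_adjusted_p <- res$p
  if (holm) {
    fam <- paste(res$metric, res$group, res$interval, res$side)
    for (f in unique(fam)) {
      sel <- fam == f
      res$holm_adjusted_p[sel] <- holm_adjust(res$p[sel])
    }
  }
  res <- res[c("metric", "group", "interval", "side", "muscle", "n",
               "baseline_mean", "baseline_sd", "change_mean", "change_sd",
               "test", "p", "holm_adjusted_p", "srm")]
  rownames(res) <- NULL
  res
}
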