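# Three-timepoint within-sample inference: one-way repeated-measures ANOVA
# with Mauchly sphericity testing and Greenhouse-Geisser / Huynh-Feldt
# correction, Bonferroni-adjusted planned paired comparisons, a
# tie-corrected Friedman fallback, and Lilliefors-style normality screening.

# Orthonormal contrast matrix (k x (k-1)) spanning the within-subject space.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Standard within-subject decomposition for an `n x k` block of repeated
#' measurements (columns = conditions, here rest / 21k / control). Mauchly's
#' W is computed on the orthonormal-contrast covariance; when its p-value
#' falls below `alpha_sphericity`, degrees of freedom are corrected with the
#' Greenhouse-Geisser epsilon if it is below 0.75 and with Huynh-Feldt
#' (clipped at 1) otherwise. Planned pairwise paired t comparisons are
#' column 1 vs 2 and column 1 vs 3 with Bonferroni factor 2 (or all three
#' pairs with factor 3 when `all_pairs = TRUE`).
#'
#' @param x Numeric matrix or data.frame, `n >= 3` rows (samples), `k >= 2`
#'   columns (conditions), no missing cells.
#' @param alpha_sphericity Mauchly significance level that triggers the
#'   epsilon correction (default 0.05).
#' @param all_pairs Include the 2 vs 3 comparison (Bonferroni factor 3).
#' @return Object of class `rm_anova` with `F`, `df_num`, `df_den`,
#'   `p_uncorrected`, `mauchly_W`, `mauchly_p`, `epsilon_gg`, `epsilon_hf`,
#'   `correction_used` ("none", "gg" or "hf"), `p_corrected`, and `pairwise`
#'   (data.frame of contrasts with raw and Bonferroni p-values).
#' @export
rm_anova <- function(x, alpha_sphericity = 0.05, all_pairs = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (any(!is.finite(x))) stop("block contains missing cells", call. = FALSE)

  grand <- mean(x)
  cond_means <- colMeans(x)
  subj_means <- rowMeans(x)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fstat <- if (ms_err <= .Machine$double.eps * max(1, ms_cond)) {
    if (ss_cond <= .Machine$double.eps) 0 else Inf
  } else ms_cond / ms_err
  p_unc <- if (is.infinite(Fstat)) 0 else stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  if (Fstat == 0) p_unc <- 1

  # Mauchly's test on the orthonormalized contrast covariance
  C <- orthonormal_contrasts(k)
  S <- stats::cov(x)
  A <- t(C) %*% S %*% C
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  p <- k - 1
  trA <- sum(ev)
  if (trA <= 0 || any(ev < -1e-12 * max(abs(ev), 1))) {
    W <- NA_real_; mauchly_p <- NA_real_
    eps_gg <- 1; eps_hf <- 1
  } else {
    W <- prod(ev) / (trA / p)^p
    dfm <- p * (p + 1) / 2 - 1
    if (W <= 0 || dfm == 0) {
      mauchly_p <- if (dfm == 0) NA_real_ else 0
    } else {
      d <- 1 - (2 * p^2 + p + 2) / (6 * p * (n - 1))
      chi2 <- -(n - 1) * d * log(W)
      mauchly_p <- stats::pchisq(chi2, dfm, lower.tail = FALSE)
    }
    eps_gg <- trA^2 / (p * sum(ev^2))
    eps_hf <- min(1, (n * p * eps_gg - 2) / (p * (n - 1 - p * eps_gg)))
  }

  correction <- "none"
  p_corr <- p_unc
  if (is.finite(mauchly_p) && mauchly_p < alpha_sphericity) {
    correction <- if (eps_gg < 0.75) "gg" else "hf"
    eps <- if (correction == "gg") eps_gg else eps_hf
    p_corr <- if (Fstat == 0) 1
              else if (is.infinite(Fstat)) 0
              else stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)
  }

  pairs <- list(c(1L, 2L), c(1L, 3L))
  if (all_pairs) pairs <- c(pairs, list(c(2L, 3L)))
  pairs <- Filter(function(pr) max(pr) <= k, pairs)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    d <- x[, pr[1]] - x[, pr[2]]
    p_raw <- if (stats::sd(d) == 0) {
      if (all(d == 0)) 1 else 0
    } else stats::t.test(d)$p.value
    data.frame(contrast = paste(colnames(x)[pr] %||% pr, collapse = " vs "),
               p_raw = p_raw, p_bonferroni = min(1, p_raw * m),
               stringsAsFactors = FALSE)
  }))

  structure(list(F = Fstat, df_num = df1, df_den = df2,
                 p_uncorrected = p_unc, mauchly_W = W, mauchly_p = mauchly_p,
                 epsilon_gg = eps_gg, epsilon_hf = eps_hf,
                 correction_used = correction, p_corrected = p_corr,
                 pairwise = pw, n = n, k = k),
            class = "rm_anova")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%g, %g) = %.4g, p = %.4g (uncorrected)\n",
              x$df_num, x$df_den, x$F, x$p_uncorrected))
  cat(sprintf("  Mauchly W = %.4g (p = %.4g); eps GG = %.3f, HF = %.3f; correction: %s, p = %.4g\n",
              x$mauchly_W, x$mauchly_p, x$epsilon_gg, x$epsilon_hf,
              x$correction_used, x$p_corrected))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Friedman test with tie correction and Bonferroni pairwise follow-up
#'
#' Rank-based alternative for repeated measurements that violate normality.
#' Rows are midranked; the chi-square statistic uses the tie-corrected form
#' (it reduces to the classical Friedman statistic without ties). Planned
#' pairwise follow-ups are Wilcoxon signed-rank tests (normal approximation)
#' on the same contrasts as [rm_anova()], Bonferroni-adjusted.
#'
#' @inheritParams rm_anova
#' @return List with `chi2`, `df` (= k - 1), `p`, and `pairwise`.
#' @export
friedman_rm <- function(x, all_pairs = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  r <- t(apply(x, 1L, rank))
  R <- colSums(r)
  num <- (k - 1) * sum((R - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  chi2 <- if (den <= 0) 0 else num / den
  df <- k - 1
  p <- if (chi2 == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)

  pairs <- list(c(1L, 2L), c(1L, 3L))
  if (all_pairs) pairs <- c(pairs, list(c(2L, 3L)))
  pairs <- Filter(function(pr) max(pr) <= k, pairs)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    d <- x[, pr[1]] - x[, pr[2]]
    p_raw <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
    data.frame(contrast = paste(colnames(x)[pr] %||% pr, collapse = " vs "),
               p_raw = p_raw, p_bonferroni = min(1, p_raw * m),
               stringsAsFactors = FALSE)
  }))
  list(chi2 = chi2, df = df, p = p, pairwise = pw)
}

#' Normality screening per condition
#'
#' One-sample Kolmogorov-Smirnov test against a normal with estimated mean
#' and SD using the Lilliefors correction (plug-in KS would be
#' anti-conservative), plus SPSS-style (type 2) skewness and excess
#' kurtosis. A column passes when the KS p-value is at least `ks_alpha` and
#' the absolute skewness / excess kurtosis stay below the configured bounds
#' (conventional screening cutoffs 2 and 7).
#'
#' @inheritParams rm_anova
#' @param ks_alpha KS significance level (default 0.05).
#' @param skew_max,kurt_max Absolute bounds on skewness and excess kurtosis.
#' @return data.frame, one row per column: `column`, `ks_p`, `skewness`,
#'   `kurtosis`, `pass`, `reason`.
#' @export
normality_screen <- function(x, ks_alpha = 0.05, skew_max = 2, kurt_max = 7) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  res <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    nm <- colnames(x)[j] %||% as.character(j)
    if (stats::sd(v) == 0)
      return(data.frame(column = nm, ks_p = NA_real_, skewness = NA_real_,
                        kurtosis = NA_real_, pass = FALSE,
                        reason = "zero variance", stringsAsFactors = FALSE))
    ks_p <- if (length(v) >= 5L) nortest::lillie.test(v)$p.value
            else suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
    sk_type <- if (length(v) >= 4L) 2L else 1L
    sk <- e1071::skewness(v, type = sk_type)
    ku <- e1071::kurtosis(v, type = sk_type)
    pass <- ks_p >= ks_alpha && abs(sk) <= skew_max && abs(ku) <= kurt_max
    reason <- if (pass) "" else if (ks_p < ks_alpha) "ks" else "moments"
    data.frame(column = nm, ks_p = ks_p, skewness = sk, kurtosis = ku,
               pass = pass, reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Full three-timepoint decision procedure
#'
#' Screens each condition for normality; when every column passes, runs the
#' repeated-measures ANOVA (with sphericity handling), otherwise falls back
#' to the tie-corrected Friedman test. Returns the omnibus p-value, the
#' planned Bonferroni pairwise p-values and the screening table.
#'
#' @inheritParams rm_anova
#' @return List with `method` ("rm_anova" or "friedman"), `p_omnibus`,
#'   `pairwise`, `screen`, and the underlying `fit`.
#' @export
timepoint_test <- function(x, alpha_sphericity = 0.05, all_pairs = FALSE) {
  scr <- normality_screen(x)
  if (all(scr$pass)) {
    fit <- rm_anova(x, alpha_sphericity = alpha_sphericity, all_pairs = all_pairs)
    list(method = "rm_anova", p_omnibus = fit$p_corrected,
         pairwise = fit$pairwise, screen = scr, fit = fit)
  } else {
    fit <- friedman_rm(x, all_pairs = all_pairs)
    list(method = "friedman", p_omnibus = fit$p, pairwise = fit$pairwise,
         screen = scr, fit = fit)
  }
}
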