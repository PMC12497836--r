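# Repeated-measures dose-response statistics: paired t, simple linear
# regression with the F/R^2 identity, classical one-way RM-ANOVA with
# Greenhouse-Geisser correction, and Dunnett many-to-one comparisons with a
# Monte Carlo max-|t| family-wise adjustment.

#' Repeated-measures design matrix
#'
#' Wraps a subjects x conditions numeric matrix with a designated control
#' condition. Missing cells (`NA`) are allowed; each subject must contribute
#' at least two non-missing cells.
#'
#' @param values Numeric matrix, rows = subjects, columns = conditions
#'   (column names required).
#' @param control Control condition label (default first column).
#' @return An `rm_design` object.
#' @export
rm_design <- function(values, control = colnames(values)[1L]) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("condition columns must be named")
  if (ncol(values) < 2L) stop("need at least 2 conditions")
  if (!control %in% colnames(values)) {
    stop(sprintf("control '%s' is not a condition (have: %s)",
                 control, paste(colnames(values), collapse = ", ")))
  }
  ok <- rowSums(!is.na(values)) >= 2L
  if (any(!ok)) {
    stop(sprintf("%d subject(s) have fewer than 2 non-missing cells", sum(!ok)))
  }
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  structure(list(values = values, control = control), class = "rm_design")
}

#' Paired t-test
#'
#' Standard two-sided paired t on the within-subject differences
#' (`df = n - 1`). Pairs with a missing member are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return A list: `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x - y) == 0) {
    # identical pairs carry no evidence of a difference; a constant nonzero
    # difference has an infinite t and is rejected
    if (all(x == y)) {
      return(list(t = 0, df = length(x) - 1L, p_value = 1, mean_diff = 0,
                  n = length(x)))
    }
    stop("differences have zero variance; paired t is undefined")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(ht$estimate), n = length(x))
}

#' Simple linear regression with the F/R-squared identity
#'
#' Ordinary least squares of `y` on `x`, reporting the quantities printed in
#' dose-response correlation tables: `R^2 = 1 - SSE/SST`,
#' `F = (n - 2) R^2 / (1 - R^2)` with df `(1, n - 2)`, and the two-sided p
#' from the F distribution. A perfect fit reports `p = 0` and
#' `perfect_fit = TRUE`.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` not constant.
#' @return A `regression_result` list: `slope`, `intercept`, `r_squared`,
#'   `f_stat`, `df` (length 2), `p_value`, `n`, `perfect_fit`.
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x is constant; regression is undefined")
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  perfect <- r2 >= 1 - 1e-12
  f_stat <- if (perfect) Inf else (n - 2) * r2 / (1 - r2)
  p <- if (perfect) 0 else stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, f_stat = f_stat, df = c(1, n - 2),
                 p_value = p, n = n, perfect_fit = perfect),
            class = "regression_result")
}

#' F statistic implied by a printed R-squared
#'
#' The closed-form identity `F = df2 * R^2 / (1 - R^2)` linking the simple
#' linear regression columns of a published correlation table.
#'
#' @param r_squared Coefficient of determination.
#' @param df2 Denominator degrees of freedom (`n - 2`).
#' @return The F statistic.
#' @export
regression_f_from_r2 <- function(r_squared, df2) {
  stopifnot(r_squared >= 0, r_squared < 1, df2 > 0)
  df2 * r_squared / (1 - r_squared)
}

#' Construct data achieving an exact regression R-squared
#'
#' Builds `n` points whose OLS fit has exactly the requested `R^2`, by adding
#' residual noise orthogonal to the regressor with the norm the identity
#' requires. Used to exercise [linear_regression()] against published
#' regression tables where only `n`, `F` and `R^2` are printed.
#'
#' @param n Number of points (>= 4).
#' @param r_squared Target coefficient of determination in `(0, 1)`.
#' @param seed Seed for the orthogonal residual direction.
#' @return A list with vectors `x` and `y`.
#' @export
make_regression_data <- function(n, r_squared, seed = 1) {
  stopifnot(n >= 4, r_squared > 0, r_squared < 1)
  x <- seq_len(n)
  with_preserved_seed(seed, {
    e <- stats::rnorm(n)
    # project out intercept and slope directions
    e <- stats::residuals(stats::lm(e ~ x))
    ss_reg <- sum((x - mean(x))^2)            # slope 1
    e <- e * sqrt(ss_reg * (1 - r_squared) / r_squared / sum(e^2))
    list(x = as.numeric(x), y = as.numeric(x + e))
  })
}

# orthonormal contrast basis spanning the (k-1)-dim condition-difference space
contrast_basis <- function(k) {
  M <- diag(k) - 1 / k
  ev <- eigen(M, symmetric = TRUE)
  t(ev$vectors[, seq_len(k - 1L), drop = FALSE])
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject one-way ANOVA on complete cases:
#' `F = MS_condition / MS_(subject x condition)` with uncorrected df
#' `(k - 1, (n - 1)(k - 1))`. The Greenhouse-Geisser epsilon is computed from
#' the covariance of the orthonormally contrasted conditions,
#' `eps = tr(V)^2 / ((k - 1) tr(V^2))`, and scales both df for the reported
#' p-value. Optionally appends Dunnett many-to-one comparisons against the
#' design's control.
#'
#' @param design An [rm_design()] (or a subjects x conditions matrix).
#' @param dunnett If `TRUE`, include [dunnett_many_to_one()] results.
#' @param nsim,seed Monte Carlo settings forwarded to the Dunnett adjustment.
#' @return An `anova_result` list: `f_stat`, `df_num`, `df_den` (corrected,
#'   possibly fractional), `df_uncorrected`, `epsilon`, `p_value`,
#'   `n_subjects`, `k`, and `dunnett` (data frame or `NULL`).
#' @export
rm_anova_oneway <- function(design, dunnett = FALSE, nsim = 1e5, seed = 171) {
  if (!inherits(design, "rm_design")) design <- rm_design(design)
  Y <- design$values
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L) stop("need at least 2 complete-case subjects")

  grand <- mean(Y)
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- Y - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f_stat <- (ss_cond / df1) / (ss_err / df2)

  C <- contrast_basis(k)
  V <- C %*% stats::cov(Y) %*% t(C)
  eps <- sum(diag(V))^2 / ((k - 1) * sum(V * V))
  eps <- min(1, max(1 / (k - 1), eps))
  p <- stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)

  dn <- if (isTRUE(dunnett)) {
    dunnett_many_to_one(design, nsim = nsim, seed = seed)
  } else NULL
  structure(list(f_stat = f_stat, df_num = eps * df1, df_den = eps * df2,
                 df_uncorrected = c(df1, df2), epsilon = eps, p_value = p,
                 n_subjects = n, k = k, dunnett = dn),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way RM-ANOVA: F(%.3f, %.2f) = %.4g, p = %.4g (GG epsilon = %.3f, n = %d)\n",
              x$df_num, x$df_den, x$f_stat, x$p_value, x$epsilon, x$n_subjects))
  if (!is.null(x$dunnett)) {
    cat("Dunnett vs", attr(x$dunnett, "control"), "\n")
    print(x$dunnett, digits = 4)
  }
  invisible(x)
}

#' Dunnett many-to-one comparisons
#'
#' Paired-difference t statistics of every non-control condition against the
#' control, family-wise adjusted by the null distribution of the maximum
#' absolute statistic over the family, estimated by Monte Carlo under the
#' correlation of the observed difference scores (shared chi-square scale
#' with the smallest comparison df). Each comparison uses its
#' pairwise-complete subjects. Adjusted p-values are floored at the raw
#' paired-t p, so a family of one reproduces the paired t exactly.
#'
#' @param design An [rm_design()] (or matrix; first column then acts as
#'   control).
#' @param control Control label; defaults to the design's control.
#' @param nsim Monte Carlo replicates (default 1e5).
#' @param seed Monte Carlo seed, recorded in the output.
#' @return A `data.frame`: `condition`, `estimate` (mean difference vs
#'   control), `t`, `df`, `p_raw`, `p_adj`; attributes `control`, `seed`,
#'   `nsim`.
#' @export
dunnett_many_to_one <- function(design, control = NULL, nsim = 1e5, seed = 171) {
  if (!inherits(design, "rm_design")) design <- rm_design(design)
  if (is.null(control)) control <- design$control
  Y <- design$values
  if (!control %in% colnames(Y)) stop(sprintf("control '%s' not present", control))
  if (all(is.na(Y[, control]))) stop("control column is entirely missing")
  others <- setdiff(colnames(Y), control)
  if (length(others) < 1L) stop("need at least one non-control condition")

  D <- Y[, others, drop = FALSE] - Y[, control]
  stat <- lapply(others, function(cn) {
    d <- D[, cn]
    d <- d[is.finite(d)]
    if (length(d) < 2L) stop(sprintf("condition '%s' has < 2 complete pairs", cn))
    if (stats::sd(d) == 0) stop(sprintf("condition '%s': zero-variance differences", cn))
    tt <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    list(est = mean(d), t = tt, df = length(d) - 1L,
         p = 2 * stats::pt(-abs(tt), length(d) - 1L))
  })
  tval <- vapply(stat, `[[`, numeric(1), "t")
  m <- length(others)

  if (m == 1L) {
    p_adj <- vapply(stat, `[[`, numeric(1), "p")
  } else {
    R <- stats::cor(D, use = "pairwise.complete.obs")
    R[!is.finite(R)] <- 0.5
    diag(R) <- 1
    ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 1e-8))) %*% t(ev$vectors)
    df_mc <- min(vapply(stat, `[[`, numeric(1), "df"))
    maxabs <- with_preserved_seed(seed, {
      Z <- matrix(stats::rnorm(nsim * m), nsim, m) %*% L
      s <- sqrt(stats::rchisq(nsim, df_mc) / df_mc)
      do.call(pmax, as.data.frame(abs(Z / s)))
    })
    p_adj <- vapply(abs(tval), function(tt) mean(maxabs >= tt), numeric(1))
    p_adj <- pmax(p_adj, vapply(stat, `[[`, numeric(1), "p"))
  }

  out <- data.frame(condition = others,
                    estimate = vapply(stat, `[[`, numeric(1), "est"),
                    t = tval,
                    df = vapply(stat, `[[`, numeric(1), "df"),
                    p_raw = vapply(stat, `[[`, numeric(1), "p"),
                    p_adj = p_adj,
                    stringsAsFactors = FALSE)
  attr(out, "control") <- control
  attr(out, "seed") <- seed
  attr(out, "nsim") <- nsim
  out
}

# Run expr under set.seed(seed) without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
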