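# Incremental-R2 evaluation with covariates, liability-scale conversion for
# binary traits, percentile-bootstrap confidence intervals and observed
# relative accuracy.

as_cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cv <- as.matrix(covariates)
  if (nrow(cv) != n) stop2("covariates must have one row per individual")
  cv
}

#' Standard covariate design
#'
#' Builds the default covariate set used throughout the analyses: age,
#' age squared, sex, the age-by-sex interaction and the leading genetic
#' principal components.
#'
#' @param age numeric vector.
#' @param sex numeric/integer vector (any 0/1 or 1/2 coding).
#' @param pcs matrix of genetic principal components (default first 10 used).
#' @param n_pcs number of PCs to keep.
#' @return numeric covariate matrix.
#' @export
standard_covariates <- function(age, sex, pcs = NULL, n_pcs = 10) {
  out <- cbind(age = age, age2 = age^2, sex = as.numeric(sex),
               age_sex = age * as.numeric(sex))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    k <- min(n_pcs, ncol(pcs))
    out <- cbind(out, pcs[, seq_len(k), drop = FALSE])
  }
  out
}

model_r2 <- function(y, design, binary) {
  if (is.null(design)) {
    if (binary) {
      # null model: fitted probabilities constant, no variance explained
      return(0)
    }
    return(0)
  }
  if (binary) {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, design), y,
                                           family = stats::binomial()))
    mu <- fit$fitted.values
    if (stats::sd(mu) == 0) return(0)
    stats::cor(y, mu)^2
  } else {
    fit <- stats::lm.fit(cbind(1, design), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
}

#' Incremental R2 of a polygenic score
#'
#' R2 of the full model (covariates + PRS) minus R2 of the base model
#' (covariates only). Quantitative traits use ordinary least squares; binary
#' traits use logistic regression with the observed-scale R2 taken as the
#' squared Pearson correlation between outcome and fitted probabilities.
#' A constant PRS yields an incremental R2 of 0 with a warning; collinear
#' covariate columns are dropped with a warning. Negative values (sampling
#' noise) are reported as computed.
#'
#' @param phenotype numeric (or 0/1) outcome vector.
#' @param prs per-individual score vector.
#' @param covariates optional covariate matrix/data.frame.
#' @param binary treat the outcome as binary (logistic model)?
#' @return object of class `accuracy_result` with fields `r2_incremental`,
#'   `scale`, `n` (and `NA` CI bounds until bootstrapped).
#' @export
incremental_r2 <- function(phenotype, prs, covariates = NULL, binary = FALSE) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (length(prs) != n) stop2("prs length must match phenotype")
  cv <- as_cov_matrix(covariates, n)
  if (!is.null(cv)) {
    keep <- apply(cv, 2, function(x) stats::sd(x) > 0)
    if (any(!keep)) warning("dropping constant covariate column(s)", call. = FALSE)
    # drop exactly collinear columns
    if (any(keep)) {
      qr_ <- qr(cbind(1, cv[, keep, drop = FALSE]))
      full_rank_cols <- qr_$pivot[seq_len(qr_$rank)]
      keep_idx <- which(keep)[setdiff(full_rank_cols, 1) - 1L]
      if (length(keep_idx) < sum(keep)) {
        warning("dropping collinear covariate column(s)", call. = FALSE)
      }
      cv <- cv[, keep_idx, drop = FALSE]
    } else {
      cv <- NULL
    }
  }
  if (stats::sd(prs) == 0) {
    warning("constant PRS: incremental R2 is 0", call. = FALSE)
    r2 <- 0
  } else {
    base <- model_r2(y, cv, binary)
    full <- model_r2(y, cbind(cv, prs = prs), binary)
    r2 <- full - base
  }
  structure(list(r2_incremental = r2, scale = "observed",
                 ci_low = NA_real_, ci_high = NA_real_,
                 n = n, n_boot = 0L),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("incremental R2 (%s scale): %.6g", x$scale, x$r2_incremental))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  [%.6g, %.6g] (%d bootstrap reps)", x$ci_low, x$ci_high, x$n_boot))
  }
  cat("  n =", x$n, "\n")
  invisible(x)
}

#' Lee et al. liability-scale transformation
#'
#' Converts an observed-scale R2 from a binary-trait model to the liability
#' scale given the population prevalence `K` and the sample case proportion
#' `P`: `R2_l = C * R2_o / (1 + C * theta * R2_o)` with
#' `C = K(1-K)/z^2 * K(1-K)/(P(1-P))`, `z` the standard-normal density at
#' the liability threshold `t = qnorm(1 - K)`, and `theta` the ascertainment
#' correction (0 when `P = K`, reducing the factor to `K(1-K)/z^2`).
#'
#' @param r2_obs observed-scale R2.
#' @param K population prevalence in (0, 1).
#' @param P sample case proportion (defaults to `K`: population sample).
#' @return liability-scale R2.
#' @export
lee_transform <- function(r2_obs, K, P = K) {
  check_prob(K, "K")
  check_prob(P, "P")
  thr <- stats::qnorm(1 - K)
  z <- stats::dnorm(thr)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - thr)
  C * r2_obs / (1 + C * theta * r2_obs)
}

#' Liability-scale incremental R2 for a binary trait
#'
#' Computes the observed-scale incremental R2 from logistic regressions and
#' converts it with [lee_transform()].
#'
#' @inheritParams incremental_r2
#' @param prevalence population prevalence `K`; defaults to the sample case
#'   proportion.
#' @return `accuracy_result` on the liability scale.
#' @export
liability_r2 <- function(phenotype, prs, covariates = NULL, prevalence = NULL) {
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1))) stop2("phenotype must be binary 0/1")
  P <- mean(y)
  K <- prevalence %||% P
  check_prob(K, "prevalence")
  res <- incremental_r2(y, prs, covariates, binary = TRUE)
  res$r2_incremental <- lee_transform(res$r2_incremental, K, P)
  res$scale <- "liability"
  res
}

#' Percentile bootstrap confidence interval
#'
#' Resamples individuals (rows) with replacement `n_boot` times and returns
#' percentile bounds of the statistic. Replicates on which the statistic is
#' undefined (error or `NA`) are redrawn, with a logged count.
#'
#' @param statistic_fn function of the resampled data returning a scalar.
#' @param data vector, matrix or data.frame; rows are resampled.
#' @param n_boot number of replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95, i.e. 2.5/97.5 percentiles).
#' @param max_redraw cap on redraws before giving up.
#' @return list with `ci` (length-2 vector), `replicates` and `n_redrawn`.
#' @export
bootstrap_ci <- function(statistic_fn, data, n_boot = 1000, seed = 1,
                         conf = 0.95, max_redraw = 10 * n_boot) {
  if (n_boot < 2) stop2("n_boot must be >= 2")
  set.seed(seed)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- function(idx) {
    if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  }
  reps <- numeric(n_boot)
  redrawn <- 0L
  i <- 1L
  while (i <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic_fn(take(idx)), error = function(e) NA_real_)
    if (is.na(val)) {
      redrawn <- redrawn + 1L
      if (redrawn > max_redraw) stop2("statistic undefined on too many replicates")
      next
    }
    reps[i] <- val
    i <- i + 1L
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  list(ci = ci, replicates = reps, n_redrawn = redrawn)
}

#' Full accuracy evaluation with bootstrap CI
#'
#' Convenience wrapper: incremental R2 (observed or liability scale) plus a
#' percentile-bootstrap confidence interval over individuals.
#'
#' @inheritParams incremental_r2
#' @param prevalence population prevalence for the liability conversion
#'   (binary traits); defaults to the sample case proportion.
#' @param liability convert binary-trait R2 to the liability scale?
#' @param n_boot bootstrap replicates (0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @return `accuracy_result` with CI bounds filled in.
#' @export
accuracy_eval <- function(phenotype, prs, covariates = NULL, binary = FALSE,
                          liability = binary, prevalence = NULL,
                          n_boot = 1000, seed = 1) {
  eval_one <- function(y, s, cv) {
    if (binary && liability) {
      liability_r2(y, s, cv, prevalence = prevalence)$r2_incremental
    } else {
      incremental_r2(y, s, cv, binary = binary)$r2_incremental
    }
  }
  cv <- as_cov_matrix(covariates, length(phenotype))
  res <- incremental_r2(phenotype, prs, cv, binary = binary)
  if (binary && liability) {
    P <- mean(phenotype)
    res$r2_incremental <- lee_transform(res$r2_incremental,
                                        prevalence %||% P, P)
    res$scale <- "liability"
  }
  if (n_boot > 0) {
    dat <- cbind(y = as.numeric(phenotype), s = as.numeric(prs), cv)
    k <- ncol(dat) - 2L
    bs <- bootstrap_ci(function(d) {
      suppressWarnings(eval_one(d[, 1], d[, 2],
                                if (k > 0) d[, -(1:2), drop = FALSE] else NULL))
    }, dat, n_boot = n_boot, seed = seed)
    res$ci_low <- bs$ci[1]
    res$ci_high <- bs$ci[2]
    res$n_boot <- n_boot
  }
  res
}

#' Observed relative accuracy
#'
#' Ratio of the variance explained by a score in the target population to
#' the variance explained by the same score in the discovery population.
#'
#' @param result_target,result_discovery `accuracy_result` objects on the
#'   same scale for the same phenotype/score.
#' @return scalar `RA_OBS`.
#' @export
relative_accuracy_observed <- function(result_target, result_discovery) {
  if (result_target$scale != result_discovery$scale) {
    stop2("results must be on the same scale")
  }
  if (result_discovery$r2_incremental <= 0) {
    stop2("relative accuracy undefined: discovery R2 <= 0")
  }
  result_target$r2_incremental / result_discovery$r2_incremental
}
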