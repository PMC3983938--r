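#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson transform extends the Box-Cox family to the whole real
#' line. It is used here to symmetrize the right-skewed z-scores that arise
#' when a variant-carrying sample's validated read count is compared against
#' a large cohort of mostly-quiet controls, so that a normal-tail p-value is
#' defensible.
#'
#' The four branches are
#' \deqn{\psi(x,\lambda)=\frac{(x+1)^\lambda-1}{\lambda}}{psi = ((x+1)^l - 1)/l}
#' for \eqn{x \ge 0, \lambda \ne 0}; \eqn{\log(x+1)} for
#' \eqn{x \ge 0, \lambda = 0};
#' \eqn{-\left[(-x+1)^{2-\lambda}-1\right]/(2-\lambda)} for
#' \eqn{x < 0, \lambda \ne 2}; and \eqn{-\log(-x+1)} for
#' \eqn{x < 0, \lambda = 2}.
#'
#' @param x Numeric vector.
#' @param lambda Transformation exponent. The validation pipeline uses
#'   `lambda = 1/2` by default, which pulls in the long right tail of the
#'   count-derived z-scores; `lambda = 1` is the identity.
#' @return Numeric vector of transformed values. `psi` is continuous and
#'   strictly increasing in `x` for every `lambda`, with `psi(0, lambda) = 0`.
#' @examples
#' yeo_johnson(3, 0.5)   # ((3+1)^0.5 - 1) / 0.5 = 2
#' yeo_johnson(-3, 0.5)  # -((4)^1.5 - 1) / 1.5 = -14/3
#' @export
yeo_johnson <- function(x, lambda = 0.5) {
  stopifnot(is.numeric(x), is.numeric(lambda), length(lambda) == 1L)
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (lambda != 0) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log(x[pos] + 1)
  }
  if (lambda != 2) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log(-x[neg] + 1)
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Summarize a control read-count distribution
#'
#' Computes the mean and *population* standard deviation (divisor `N`, not
#' `N - 1`) of per-control-sample validated read counts for one evidence
#' category. Counts are deliberately not normalized across samples: the
#' method relies on a large control cohort to even out batch effects.
#'
#' @param counts Numeric vector of per-sample validated read counts
#'   \eqn{V_j}, one entry per control sample.
#' @param category Optional category label carried through to the output.
#' @return A one-row tibble with columns `category`, `n`, `mu`, `sigma`.
#' @examples
#' control_stats(c(0, 1, 0, 2, 1, 0, 3, 1, 0, 2))  # mu = 1, sigma = 1
#' @export
control_stats <- function(counts, category = NA_character_) {
  if (length(counts) == 0L) {
    stop("control_stats(): `counts` must contain at least one control sample")
  }
  stopifnot(is.numeric(counts), !anyNA(counts))
  mu <- sum(counts) / length(counts)
  sigma <- sqrt(sum((counts - mu)^2) / length(counts))
  tibble::tibble(
    category = category,
    n = length(counts),
    mu = mu,
    sigma = sigma
  )
}

#' One-sided p-value for an observed count against a control cohort
#'
#' Standardizes the experimental sample's validated read count against the
#' control distribution and converts the score to an upper-tail standard
#' normal probability after a Yeo-Johnson transform:
#' \deqn{z = (|\zeta_x| - \mu)/\sigma, \quad p = P[Z > \psi(z, \lambda)].}
#'
#' The p-value is `NA` when the observed count is zero (no evidence to test)
#' or when the control counts are constant (`sigma = 0`); the two reasons are
#' distinguished in the `na_reason` column.
#'
#' With `yj_mode = "counts"` the per-sample counts and the observed count are
#' themselves transformed before standardization and the untransformed normal
#' tail is used; the default `"zscore"` mode transforms the z statistic, which
#' is the fully explicit published form.
#'
#' @param observed Non-negative validated read count in the experimental
#'   sample.
#' @param counts Numeric vector of per-control-sample counts.
#' @param lambda Yeo-Johnson exponent (default 1/2).
#' @param category Optional category label carried through.
#' @param yj_mode `"zscore"` (default) or `"counts"`; see Details.
#' @return A one-row tibble: `category`, `observed`, `n_controls`, `mu`,
#'   `sigma`, `z`, `psi_z`, `p`, `na_reason`.
#' @examples
#' splice_p_value(6, c(0, 1, 0, 2, 1, 0, 3, 1, 0, 2))  # z = 5, p ~ 0.0019
#' @export
splice_p_value <- function(observed, counts, lambda = 0.5,
                           category = NA_character_,
                           yj_mode = c("zscore", "counts")) {
  yj_mode <- match.arg(yj_mode)
  stopifnot(length(observed) == 1L, is.numeric(observed), observed >= 0)
  if (yj_mode == "counts") {
    counts_t <- yeo_johnson(counts, lambda)
    observed_t <- yeo_johnson(observed, lambda)
    cs <- control_stats(counts_t)
  } else {
    cs <- control_stats(counts)
  }
  mu <- cs$mu
  sigma <- cs$sigma
  z <- psi_z <- p <- NA_real_
  na_reason <- NA_character_
  if (observed == 0) {
    na_reason <- "observed count is zero"
  } else if (sigma == 0) {
    na_reason <- "control counts are constant (sigma = 0)"
  } else if (yj_mode == "counts") {
    z <- (observed_t - mu) / sigma
    psi_z <- z
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    z <- (observed - mu) / sigma
    psi_z <- yeo_johnson(z, lambda)
    p <- stats::pnorm(psi_z, lower.tail = FALSE)
  }
  tibble::tibble(
    category = category,
    observed = as.numeric(observed),
    n_controls = length(counts),
    mu = if (yj_mode == "counts") mean(counts) else mu,
    sigma = if (yj_mode == "counts") sqrt(mean((counts - mean(counts))^2)) else sigma,
    z = z,
    psi_z = psi_z,
    p = p,
    na_reason = na_reason
  )
}

#' Combined one-tailed normal quantile for a power analysis
#'
#' @param alpha One-tailed significance level.
#' @param power Desired power (1 - beta).
#' @return `qnorm(1 - alpha) + qnorm(power)`. For `alpha = 0.05`,
#'   `power = 0.8` this is 2.4865 (4 d.p.).
#' @export
combined_power_quantile <- function(alpha = 0.05, power = 0.8) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  stats::qnorm(1 - alpha) + stats::qnorm(power)
}

#' Minimum control sample size for a target effect size
#'
#' \deqn{N = \lceil \sigma^2 z^2 / ES^2 \rceil} with
#' \eqn{z = z_{1-\alpha} + z_{power}} for a one-tailed test. `sigma` should
#' be estimated from (Yeo-Johnson transformed) pilot control counts and `ES`
#' is the smallest count excess worth detecting, in the same units.
#'
#' @param sigma Control-count standard deviation (> 0).
#' @param effect_size Minimal detectable effect in count units (> 0).
#' @param alpha One-tailed significance level (default 0.05).
#' @param power Desired power (default 0.8).
#' @return Integer minimum number of samples.
#' @examples
#' required_sample_size(1, 0.5)  # ceiling(2.4865^2 / 0.25) = 25
#' @export
required_sample_size <- function(sigma, effect_size, alpha = 0.05,
                                 power = 0.8) {
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      effect_size <= 0) {
    stop("required_sample_size(): `effect_size` must be a positive number")
  }
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  z <- combined_power_quantile(alpha, power)
  as.integer(ceiling(sigma^2 * z^2 / effect_size^2))
}
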