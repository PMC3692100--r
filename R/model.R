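#' Transition probabilities of the two-state gain/loss chain
#'
#' Closed-form transition matrix of the continuous-time Markov chain on
#' \{0 = absent, 1 = present\} with gain rate g (0 -> 1) and loss rate l
#' (1 -> 0): P01(t) = pi1 (1 - e^{-(g+l) t}), P10(t) = pi0 (1 - e^{-(g+l) t})
#' with pi1 = g / (g + l).
#'
#' @param g gain rate (>= 0).
#' @param l loss rate (>= 0); g + l must be positive.
#' @param t elapsed time (branch length, >= 0).
#' @return 2x2 row-stochastic matrix with dimnames \code{c("0","1")}.
#' @export
transition_probability <- function(g, l, t) {
  if (t < 0) stop("negative branch length")
  if (g < 0 || l < 0 || g + l <= 0) stop("rates must be >= 0 and not both 0")
  lam <- g + l
  pi1 <- g / lam
  pi0 <- l / lam
  e <- exp(-lam * t)
  matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
           pi1 * (1 - e), pi1 + pi0 * e),
         nrow = 2L, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Stationary frequencies of the gain/loss chain
#'
#' @inheritParams transition_probability
#' @return \code{c(pi0, pi1) = c(l, g) / (g + l)}.
#' @export
stationary_frequencies <- function(g, l) {
  if (g < 0 || l < 0 || g + l <= 0) stop("rates must be >= 0 and not both 0")
  c(pi0 = l / (g + l), pi1 = g / (g + l))
}

#' Gain/loss model parameters
#'
#' Container for the three model tiers: \code{single} (one gain and one loss
#' rate shared by all characters), \code{gamma_invariant} (overall rate
#' varies among characters following a discretized gamma distribution with
#' an extra zero-rate invariant category of proportion \code{p_inv}), and
#' \code{mixture} (gain and loss rates vary among characters independently,
#' each following its own discretized gamma).
#'
#' @param g gain rate (> 0).
#' @param l loss rate (> 0).
#' @param tier model tier.
#' @param alpha gamma shape of the overall-rate distribution
#'   (tier \code{gamma_invariant}).
#' @param p_inv invariant-category proportion in [0, 1).
#' @param K number of discrete gamma categories (tier \code{gamma_invariant}).
#' @param alpha_gain,alpha_loss gamma shapes of the independent gain and
#'   loss multipliers (tier \code{mixture}).
#' @param K_gain,K_loss category counts of the gain and loss grids.
#' @return object of class \code{gain_loss_params}.
#' @export
gain_loss_params <- function(g, l,
                             tier = c("single", "gamma_invariant", "mixture"),
                             alpha = 0.5, p_inv = 0, K = 4L,
                             alpha_gain = 0.5, alpha_loss = 0.5,
                             K_gain = 3L, K_loss = 3L) {
  tier <- match.arg(tier)
  if (g <= 0 || l <= 0) stop("rates must be strictly positive")
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  if (alpha <= 0 || alpha_gain <= 0 || alpha_loss <= 0) {
    stop("gamma shapes must be positive")
  }
  if (K < 1L || K_gain < 1L || K_loss < 1L) stop("category counts must be >= 1")
  structure(list(g = g, l = l, model_tier = tier, alpha = alpha,
                 p_inv = p_inv, K = as.integer(K),
                 alpha_gain = alpha_gain, alpha_loss = alpha_loss,
                 K_gain = as.integer(K_gain), K_loss = as.integer(K_loss)),
            class = "gain_loss_params")
}

#' @export
print.gain_loss_params <- function(x, ...) {
  cat("Gain/loss model (", x$model_tier, "): g = ", signif(x$g, 5),
      ", l = ", signif(x$l, 5), ", g/l = ", signif(x$g / x$l, 5), "\n",
      sep = "")
  if (x$model_tier == "gamma_invariant") {
    cat("  alpha =", signif(x$alpha, 4), " p_inv =", signif(x$p_inv, 4),
        " K =", x$K, "\n")
  }
  if (x$model_tier == "mixture") {
    cat("  alpha_gain =", signif(x$alpha_gain, 4),
        " alpha_loss =", signif(x$alpha_loss, 4),
        " grid =", x$K_gain, "x", x$K_loss, "\n")
  }
  invisible(x)
}

# Mean-of-quantile-bin discretization of Gamma(shape = a, rate = a)
# (mean 1), K equal-weight categories (Yang-style).
discretize_gamma <- function(alpha, K) {
  if (K == 1L) {
    return(1)
  }
  q <- stats::qgamma(seq(0, 1, length.out = K + 1L), shape = alpha, rate = alpha)
  # E[X ; a < X < b] for Gamma(a, a) = P(a+1 quantiles), since mean is 1
  upper <- stats::pgamma(q[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(q[-(K + 1L)], shape = alpha + 1, rate = alpha)
  K * (upper - lower)
}

#' Discretized rate mixture of a gain/loss model
#'
#' Expands model parameters into weighted (gain, loss) rate categories:
#' one category for tier \code{single}; K mean-of-quantile gamma categories
#' scaling gain and loss jointly plus a zero-rate invariant category for
#' tier \code{gamma_invariant}; a K_gain x K_loss product grid of
#' independent gain and loss multipliers for tier \code{mixture}. The
#' mixture is then globally rescaled so the expected number of events per
#' unit branch length at stationarity, averaged over categories, equals 1 -
#' branch lengths are thereby in expected events per character.
#'
#' @param params a \code{\link{gain_loss_params}}.
#' @param normalize rescale to unit mean event flux (default TRUE).
#' @return object of class \code{rate_mixture}: data frame with columns
#'   \code{gain}, \code{loss}, \code{weight}, \code{pi0}, \code{pi1}.
#'   The invariant category has rates 0 and carries the base model's
#'   stationary frequencies as its root prior.
#' @export
build_rate_mixture <- function(params, normalize = TRUE) {
  stopifnot(inherits(params, "gain_loss_params"))
  g <- params$g
  l <- params$l
  base_pi <- stationary_frequencies(g, l)
  cats <- switch(params$model_tier,
    single = data.frame(gain = g, loss = l, weight = 1),
    gamma_invariant = {
      r <- discretize_gamma(params$alpha, params$K)
      d <- data.frame(gain = g * r, loss = l * r,
                      weight = (1 - params$p_inv) / params$K)
      if (params$p_inv > 0) {
        d <- rbind(data.frame(gain = 0, loss = 0, weight = params$p_inv), d)
      }
      d
    },
    mixture = {
      rg <- discretize_gamma(params$alpha_gain, params$K_gain)
      rl <- discretize_gamma(params$alpha_loss, params$K_loss)
      grid <- expand.grid(i = seq_along(rg), j = seq_along(rl))
      data.frame(gain = g * rg[grid$i], loss = l * rl[grid$j],
                 weight = 1 / (params$K_gain * params$K_loss))
    })
  tot <- cats$gain + cats$loss
  cats$pi0 <- ifelse(tot > 0, cats$loss / tot, base_pi[[1L]])
  cats$pi1 <- ifelse(tot > 0, cats$gain / tot, base_pi[[2L]])
  if (normalize) {
    # event flux at stationarity: pi0 g + pi1 l = 2 g l / (g + l)
    flux <- sum(cats$weight * (cats$pi0 * cats$gain + cats$pi1 * cats$loss))
    if (flux <= 0) stop("mixture has zero event flux; cannot normalize")
    cats$gain <- cats$gain / flux
    cats$loss <- cats$loss / flux
  }
  structure(cats, class = c("rate_mixture", "data.frame"))
}

#' Mean event flux of a rate mixture
#'
#' Expected number of gain-plus-loss events per unit branch length at
#' stationarity, averaged over categories; 1 for a normalized mixture.
#'
#' @param mix a \code{rate_mixture}.
#' @return scalar flux.
#' @export
mixture_flux <- function(mix) {
  sum(mix$weight * (mix$pi0 * mix$gain + mix$pi1 * mix$loss))
}
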