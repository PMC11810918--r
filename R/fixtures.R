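# Known-truth simulation designs for validating feature selection and the
# interaction machinery.

#' Simulate a feature-selection benchmark design
#'
#' Generates `n_informative` standard-normal features that drive a logistic
#' class label plus `n_noise` independent standard-normal distractors.
#' Used to measure how often forward selection recovers planted signal.
#'
#' @param n Number of rows (default 300).
#' @param n_informative Number of informative features (default 3).
#' @param n_noise Number of noise features (default 50).
#' @param beta Logistic coefficient shared by the informative features
#'   (default 2.5, strong enough that each feature is individually detectable at n = 300); 0 yields a pure-null design.
#' @param seed Integer seed.
#' @return List with `features` (data frame; informative columns named
#'   `signal<k>`, noise columns `noise<k>`), `labels` (factor `"case"` /
#'   `"control"`), `informative` (names of planted features).
#' @export
simulate_selection_fixture <- function(n = 300L, n_informative = 3L,
                                       n_noise = 50L, beta = 2.5,
                                       seed = 1L) {
  set.seed(seed)
  sig <- matrix(stats::rnorm(n * n_informative), n, n_informative)
  noise <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  eta <- as.vector(sig %*% rep(beta, n_informative))
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  df <- as.data.frame(cbind(sig, noise))
  names(df) <- c(sprintf("signal%d", seq_len(n_informative)),
                 sprintf("noise%02d", seq_len(n_noise)))
  list(features = df,
       labels = factor(ifelse(y == 1, "case", "control"),
                       levels = c("control", "case")),
       informative = sprintf("signal%d", seq_len(n_informative)))
}

#' Simulate a planted two-way synergy design
#'
#' Class risk is driven (almost) exclusively by the product of two features:
#' cases concentrate where both features are high or both are low, a signal
#' invisible to either feature alone but exposed by a product interaction
#' column.
#'
#' @param n Number of rows (default 240).
#' @param strength Logistic coefficient on the product term (default 2.5).
#' @param n_noise Additional independent noise features (default 4).
#' @param seed Integer seed.
#' @return List with `features`, `labels`, and `synergy_pair` (the two
#'   parent feature names).
#' @export
simulate_synergy_fixture <- function(n = 240L, strength = 2.5, n_noise = 4L,
                                     seed = 1L) {
  set.seed(seed)
  a <- stats::rnorm(n)
  b <- stats::rnorm(n)
  eta <- strength * a * b
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  df <- data.frame(fa = a, fb = b)
  for (k in seq_len(n_noise)) df[[sprintf("noise%d", k)]] <- stats::rnorm(n)
  list(features = df,
       labels = factor(ifelse(y == 1, "case", "control"),
                       levels = c("control", "case")),
       synergy_pair = c("fa", "fb"))
}
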