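#' Nucleotide substitution models
#'
#' Constructs a JC or HKY substitution model, optionally with discrete-gamma
#' rate variation across sites (+Gamma). The rate matrix is normalised so one
#' unit of branch distance equals one expected substitution per site; JC is
#' HKY with `kappa = 1` and uniform base frequencies.
#'
#' @param kind `"JC"` or `"HKY"`.
#' @param pi Base frequencies (A, C, G, T); must sum to 1. Ignored for JC.
#' @param kappa Transition/transversion rate parameter (HKY only).
#' @param gamma_shape Shape of the discrete-gamma rate mixture, or `NULL`
#'   for rate homogeneity.
#' @param gamma_ncat Number of discrete-gamma categories (default 4).
#' @return An object of class `subst_model`.
#' @export
subst_model <- function(kind = c("JC", "HKY"), pi = rep(0.25, 4), kappa = 1,
                        gamma_shape = NULL, gamma_ncat = 4L) {
  kind <- match.arg(kind)
  if (kind == "JC") {
    pi <- rep(0.25, 4)
    kappa <- 1
  }
  if (abs(sum(pi) - 1) > 1e-8 || any(pi <= 0)) {
    stop_betsig("base frequencies must be positive and sum to 1", "betsig_argument_error")
  }
  if (kappa <= 0) stop_betsig("kappa must be positive", "betsig_argument_error")
  if (!is.null(gamma_shape) && gamma_shape <= 0) {
    stop_betsig("gamma shape must be positive", "betsig_argument_error")
  }
  structure(
    list(kind = kind, pi = setNames(as.numeric(pi), c("A", "C", "G", "T")),
         kappa = kappa, gamma_shape = gamma_shape, gamma_ncat = as.integer(gamma_ncat)),
    class = "subst_model"
  )
}

#' Discrete-gamma category rates
#'
#' Mean-one category rates for the +Gamma model: the gamma distribution with
#' shape `alpha` and mean 1 is cut at its `ncat`-quantiles and each category
#' takes the conditional mean of its interval (mean-of-interval
#' discretisation), giving equal-weight categories whose rates average 1.
#'
#' @param alpha Gamma shape (= rate, so the mean is 1).
#' @param ncat Number of categories.
#' @return Numeric vector of `ncat` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  if (ncat == 1L) return(1)
  q <- qgamma(seq_len(ncat - 1L) / ncat, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  # E[X | a < X < b] for Gamma(alpha, alpha) via the shape+1 identity
  p_up <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  ncat * diff(p_up)
}

model_gamma_rates <- function(model) {
  if (is.null(model$gamma_shape)) 1 else discrete_gamma_rates(model$gamma_shape, model$gamma_ncat)
}

#' Transition probability matrix
#'
#' The 4x4 matrix of state-change probabilities over a branch of `distance`
#' expected substitutions per site, using the closed-form JC/HKY spectral
#' solution. With a +Gamma model the matrix is averaged over the discrete
#' category rates.
#'
#' @param model A [subst_model()].
#' @param distance Expected substitutions per site (>= 0).
#' @return A 4x4 row-stochastic matrix, rows/columns in A, C, G, T order.
#' @export
transition_matrix <- function(model, distance) {
  if (distance < 0) stop_betsig("distance must be non-negative", "betsig_argument_error")
  rates <- model_gamma_rates(model)
  P <- matrix(0, 4, 4)
  for (r in rates) P <- P + hky_pmat(distance * r, model$pi, model$kappa)
  P <- P / length(rates)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

# closed-form HKY transition probabilities (states A,C,G,T; purines {A,G})
hky_pmat <- function(d, pi, kappa) {
  piR <- pi[1] + pi[3]
  piY <- pi[2] + pi[4]
  beta <- 1 / (2 * kappa * (pi[1] * pi[3] + pi[2] * pi[4]) + 2 * piR * piY)
  e2 <- exp(-beta * d)
  P <- matrix(0, 4, 4)
  for (i in 1:4) {
    purine_i <- i %in% c(1L, 3L)
    Pi <- if (purine_i) piR else piY
    e3 <- exp(-beta * d * (Pi * kappa + 1 - Pi))
    for (j in 1:4) {
      purine_j <- j %in% c(1L, 3L)
      if (i == j) {
        P[i, j] <- pi[j] + pi[j] * (1 / Pi - 1) * e2 + ((Pi - pi[j]) / Pi) * e3
      } else if (purine_i == purine_j) {
        P[i, j] <- pi[j] + pi[j] * (1 / Pi - 1) * e2 - (pi[j] / Pi) * e3
      } else {
        P[i, j] <- pi[j] * (1 - e2)
      }
    }
  }
  unname(P)
}
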