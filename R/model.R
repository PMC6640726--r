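#' Nucleotide substitution model
#'
#' Construct a reversible nucleotide substitution model (JC or GTR), with
#' optional discrete-gamma among-site rate variation. The instantaneous
#' rate matrix is normalized so that one unit of branch length corresponds
#' to one expected substitution per site at stationarity.
#'
#' @param family `"JC"` or `"GTR"`.
#' @param rates Six exchangeability parameters in the order
#'   AC, AG, AT, CG, CT, GT (ignored for `"JC"`).
#' @param base_freq Stationary base frequencies (A, C, G, T); must be
#'   positive and sum to 1 (ignored for `"JC"`, which fixes them at 1/4).
#' @param gamma_shape Shape of the mean-one gamma distribution of site
#'   rates, or `NULL` for rate homogeneity. `NA` requests estimation where
#'   supported (tree search).
#' @param n_categories Number of discrete gamma rate categories (>= 1).
#' @return An object of class `subst_model`.
#' @examples
#' m <- substitution_model("JC")
#' transition_prob(m, 0.1)
#' @export
substitution_model <- function(family = c("JC", "GTR"),
                               rates = rep(1, 6),
                               base_freq = rep(0.25, 4),
                               gamma_shape = NULL,
                               n_categories = 4L) {
  family <- match.arg(family)
  if (family == "JC") {
    rates <- rep(1, 6)
    base_freq <- rep(0.25, 4)
  }
  if (length(rates) != 6 || any(!is.finite(rates)) || any(rates <= 0))
    stop("`rates` must be six positive exchangeabilities")
  if (length(base_freq) != 4 || any(base_freq <= 0))
    stop("`base_freq` must be four positive frequencies")
  if (abs(sum(base_freq) - 1) > 1e-8)
    stop("`base_freq` must sum to 1")
  if (!is.null(gamma_shape) && !is.na(gamma_shape) && gamma_shape <= 0)
    stop("`gamma_shape` must be positive")
  stopifnot_scalar_count(n_categories, "n_categories", min = 1)

  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- rates[k] * base_freq[j]
    Q[j, i] <- rates[k] * base_freq[i]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(base_freq * diag(Q))
  Q <- Q / scale

  # Eigendecomposition of the symmetrized generator, for P(t) = exp(Qt).
  sp <- sqrt(base_freq)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    family = family, rates = rates, base_freq = base_freq,
    gamma_shape = gamma_shape,
    n_categories = if (is.null(gamma_shape)) 1L else as.integer(n_categories),
    Q = Q,
    eig_values = eig$values,
    V = diag(1 / sp) %*% eig$vectors,        # right eigenvectors of Q
    Vinv = t(eig$vectors) %*% diag(sp)
  ), class = "subst_model")
}

#' Transition probability matrix
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site); `t >= 0`.
#' @return The 4x4 matrix `P(t)` with rows = ancestral state.
#' @export
transition_prob <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  if (model$family == "JC") {
    e <- exp(-4 * t / 3)
    P <- matrix(0.25 * (1 - e), 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    diag(P) <- 0.25 + 0.75 * e
    return(P)
  }
  P <- model$V %*% (exp(model$eig_values * t) * model$Vinv)
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

# Mean rates of the K equal-probability discrete-gamma categories
# (mean-one gamma with shape = rate = alpha).
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / (sum(r) / k)   # guard tiny numerical drift; mean exactly 1
}

# Category rates for a model (1 if rate-homogeneous).
model_cat_rates <- function(model, gamma_shape = NULL) {
  a <- if (!is.null(gamma_shape)) gamma_shape else model$gamma_shape
  if (is.null(a) || is.na(a)) return(1)
  discrete_gamma_rates(a, model$n_categories)
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model", x$family))
  if (!is.null(x$gamma_shape))
    cat(sprintf(" + Gamma(alpha=%s, %d categories)",
                format(x$gamma_shape), x$n_categories))
  cat("\n  base frequencies:", paste(format(x$base_freq, digits = 3),
                                     collapse = " "), "\n")
  invisible(x)
}
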