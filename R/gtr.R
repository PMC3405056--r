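#' GTR+Gamma substitution model
#'
#' General time-reversible nucleotide substitution model with discrete-Gamma
#' among-site rate heterogeneity. The instantaneous rate matrix is normalized
#' so that one unit of branch length equals one expected substitution per
#' site at the stationary distribution.
#'
#' @param freqs base frequencies over (A, C, G, T); must be positive and sum
#'   to 1 (renormalized within a 1e-6 tolerance).
#' @param rates six positive exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param alpha Gamma shape parameter for among-site rate variation
#'   (`Inf` means rate-homogeneous).
#' @param k number of discrete Gamma rate categories (>= 1).
#' @return a `gtr_model` object.
#' @examples
#' jc <- gtr_model()                      # Jukes-Cantor special case
#' gtr_rate_matrix(jc)
#' @export
gtr_model <- function(freqs = rep(0.25, 4), rates = rep(1, 6),
                      alpha = Inf, k = 4L) {
  freqs <- as.numeric(freqs)
  rates <- as.numeric(rates)
  if (length(freqs) != 4 || any(freqs <= 0))
    stop("freqs must be 4 positive values")
  if (abs(sum(freqs) - 1) > 1e-6) stop("freqs must sum to 1")
  freqs <- freqs / sum(freqs)
  if (length(rates) != 6 || any(rates <= 0))
    stop("rates must be 6 positive exchangeabilities")
  if (!(is.infinite(alpha) || alpha > 0)) stop("alpha must be positive")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  names(freqs) <- .dna_letters
  structure(list(freqs = freqs, rates = rates, alpha = alpha, k = k),
            class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR model: pi = (", paste(signif(x$freqs, 4), collapse = ", "),
      "), alpha =", x$alpha, ", K =", x$k, "\n")
  invisible(x)
}

#' Instantaneous rate matrix of a GTR model
#'
#' Builds the 4x4 rate matrix Q with off-diagonals `s_ij * pi_j`, diagonal
#' set so rows sum to zero, normalized so the expected substitution rate
#' `-sum(pi_i Q_ii)` equals 1 (branch lengths are then in expected
#' substitutions per site).
#'
#' @param model a [gtr_model()].
#' @return 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
gtr_rate_matrix <- function(model) {
  s <- matrix(0, 4, 4)
  s[lower.tri(s)] <- model$rates[c(1, 2, 3, 4, 5, 6)]
  # fill in order (2,1)=AC (3,1)=AG (4,1)=AT (3,2)=CG (4,2)=CT (4,3)=GT
  s <- s + t(s)
  q <- s * rep(model$freqs, each = 4)
  diag(q) <- -rowSums(q)
  mu <- -sum(model$freqs * diag(q))
  q <- q / mu
  dimnames(q) <- list(.dna_letters, .dna_letters)
  q
}

#' Discrete-Gamma rate categories
#'
#' K equal-probability categories of a Gamma(shape = alpha, mean = 1)
#' distribution, each represented by its category mean, so the mean rate
#' across categories is exactly 1.
#'
#' @param alpha Gamma shape (> 0); `Inf` returns all rates 1.
#' @param k number of categories (>= 1).
#' @return non-decreasing numeric vector of `k` positive rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (is.infinite(alpha)) return(rep(1, k))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  if (k == 1) return(1)
  # category boundaries at quantiles i/k; category mean via the incomplete
  # Gamma identity E[X; a<X<b] = (shape/rate) * (F_{shape+1}(b) - F_{shape+1}(a))
  bounds <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  f <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  rates <- k * diff(f)
  rates / mean(rates)
}

# Eigen-decomposition of the reversible rate matrix via the symmetrized form
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)).  Cached structure for fast P(t).
gtr_eigen <- function(model) {
  q <- gtr_rate_matrix(model)
  sp <- sqrt(model$freqs)
  b <- (sp %o% (1 / sp)) * q
  b <- (b + t(b)) / 2   # symmetrize against rounding
  e <- eigen(b, symmetric = TRUE)
  list(vals = e$values,
       right = (1 / sp) * e$vectors,        # diag(1/sqrt(pi)) U
       left = t(sp * e$vectors))            # U' diag(sqrt(pi))
}

# Transition probability matrix P(t) = exp(Qt) from a cached decomposition.
transition_prob <- function(eig, t) {
  p <- eig$right %*% (exp(eig$vals * t) * eig$left)
  p[p < 0] <- 0
  p
}
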