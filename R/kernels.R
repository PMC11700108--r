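# Kernels for support vector regression. The Pearson-VII universal kernel
# (PUK) interpolates between Gaussian-like and Lorentzian-like shapes via
# the tailing factor omega and width sigma:
#   k(u, v) = 1 / [1 + (2 * ||u - v|| * sqrt(2^(1/omega) - 1) / sigma)^2]^omega

#' Pearson-VII universal kernel (PUK)
#'
#' @param u,v numeric feature vectors of equal length.
#' @param omega tailing factor, > 0 (default 1).
#' @param sigma half-width parameter, > 0 (default 1).
#' @return similarity in `(0, 1]`; 1 iff `u == v`.
#' @export
#' @examples
#' puk_kernel(c(0, 0), c(0, 0))             # 1
#' puk_kernel(0, 1, omega = 1, sigma = 2)   # 0.5
puk_kernel <- function(u, v, omega = 1, sigma = 1) {
  if (omega <= 0 || sigma <= 0)
    stop("puk_kernel: omega and sigma must be > 0")
  d <- sqrt(sum((u - v)^2))
  (1 + (2 * d * sqrt(2^(1 / omega) - 1) / sigma)^2)^(-omega)
}

#' Gaussian (RBF) kernel
#' @param u,v numeric feature vectors.
#' @param gamma inverse-width, > 0.
#' @return similarity in `(0, 1]`.
#' @export
rbf_kernel <- function(u, v, gamma = 0.25) {
  if (gamma <= 0) stop("rbf_kernel: gamma must be > 0")
  exp(-gamma * sum((u - v)^2))
}

#' Degree-2 polynomial kernel, (u.v + 1)^2
#' @param u,v numeric feature vectors.
#' @return kernel value.
#' @export
poly2_kernel <- function(u, v) (sum(u * v) + 1)^2

# Pairwise kernel matrix between row sets X (n x d) and Y (m x d).
kernel_matrix <- function(X, Y, kernel = c("RBF", "PUK", "POLY2"),
                          gamma = 0.25, omega = 1, sigma = 1) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (kernel == "POLY2") return((tcrossprod(X, Y) + 1)^2)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  if (kernel == "RBF") {
    exp(-gamma * d2)
  } else {
    (1 + 4 * d2 * (2^(1 / omega) - 1) / sigma^2)^(-omega)
  }
}
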