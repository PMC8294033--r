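`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# 1-D Gaussian blur operator as a dense band matrix; applied as R %*% X %*% t(C)
# this gives a separable 2-D blur with renormalised (edge-corrected) weights.
blur_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    idx <- seq_len(n) + offs[k]
    keep <- idx >= 1 & idx <= n
    M[cbind(which(keep), idx[keep])] <- M[cbind(which(keep), idx[keep])] + w[k]
  }
  M / rowSums(M)
}

gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  R <- blur_operator(nrow(mat), sigma)
  C <- blur_operator(ncol(mat), sigma)
  R %*% mat %*% t(C)
}

# Seeds derived from a master seed stay below 2^31 - 1.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
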