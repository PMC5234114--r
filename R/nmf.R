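#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius norm `||V - W H||_F` over non-negative factors by
#' Lee-Seung multiplicative updates, which keep the factors non-negative and
#' never increase the objective. Initialization is seeded uniform noise scaled
#' to the magnitude of `V`, so a fixed seed gives a reproducible
#' factorization. With `fixed_W` supplied only `H` is updated (used to project
#' new data onto an existing basis).
#'
#' @param V Non-negative numeric matrix.
#' @param rank Factorization rank; must not exceed `min(dim(V))`.
#' @param seed Integer seed for the initialization.
#' @param max_iter Maximum iterations (default 500).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param fixed_W Optional fixed basis (`nrow(V) x rank`); if given, W is not
#'   updated.
#'
#' @return List with `W`, `H`, `residual` (relative Frobenius residual
#'   `||V - WH|| / ||V||`), `objective` (per-iteration trace), `iters`.
#' @export
nmf_mu <- function(V, rank, seed = 1L, max_iter = 500L, tol = 1e-6,
                   fixed_W = NULL) {
  V <- as.matrix(V)
  if (any(V < 0)) rlang::abort("V must be non-negative.")
  if (rank < 1L || rank > min(dim(V))) {
    rlang::abort(sprintf("rank must be in 1..%d.", min(dim(V))))
  }
  eps <- .Machine$double.eps
  n <- nrow(V); m <- ncol(V)
  v_norm <- sqrt(sum(V^2))

  init <- withr::with_seed(as.integer(seed), {
    scale <- sqrt(max(mean(V), eps) / rank)
    list(
      W = matrix(stats::runif(n * rank, min = eps, max = 1) * scale, n, rank),
      H = matrix(stats::runif(rank * m, min = eps, max = 1) * scale, rank, m)
    )
  })
  W <- if (is.null(fixed_W)) init$W else {
    if (!all(dim(fixed_W) == c(n, rank))) {
      rlang::abort("`fixed_W` must be nrow(V) x rank.")
    }
    fixed_W
  }
  H <- init$H

  obj <- numeric(0)
  prev <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    # H update: H <- H * (W'V) / (W'WH)
    WtV <- crossprod(W, V)
    WtWH <- crossprod(W) %*% H
    H <- H * WtV / (WtWH + eps)
    if (is.null(fixed_W)) {
      # W update: W <- W * (VH') / (WHH')
      VHt <- tcrossprod(V, H)
      WHHt <- W %*% tcrossprod(H)
      W <- W * VHt / (WHHt + eps)
    }
    cur <- sqrt(sum((V - W %*% H)^2))
    obj <- c(obj, cur)
    iters <- it
    if (is.finite(prev) && prev > 0 && abs(prev - cur) / prev < tol) break
    prev <- cur
  }
  list(
    W = W, H = H,
    residual = if (v_norm > 0) obj[iters] / v_norm else 0,
    objective = obj, iters = iters
  )
}
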