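# Two-parameter logistic IRT model, marginal maximum likelihood EM with
# fixed quadrature and EAP ability scoring. The latent scale is
# identified by fixing the ability prior to the standard normal.

#' Fit a 2PL item response model
#'
#' `P(x = 1 | theta) = plogis(a_j (theta - b_j))` with discrimination
#' `a_j` and difficulty `b_j`. Estimation is marginal maximum likelihood
#' EM over a fixed grid of `n_quad` equally spaced quadrature nodes on
#' `[-6, 6]` with standard-normal weights; the M-step is a per-item
#' Newton fit of a weighted logistic regression on the nodes. Abilities
#' are expected a posteriori (EAP) under the N(0, 1) prior, which is
#' finite even for all-correct or all-wrong response patterns.
#'
#' Items with zero response variance cannot be scaled and are dropped
#' with a warning.
#'
#' @param data N x J 0/1 response matrix.
#' @param n_quad number of quadrature nodes (default 61).
#' @param tol convergence tolerance on the largest absolute parameter
#'   change (default 1e-4).
#' @param max_iter EM iteration cap.
#' @return an object of class `twopl_fit`: data frame `items` with `a`
#'   and `b` per retained item, `theta` (EAP per examinee), `loglik`,
#'   `trace`, `converged`, `dropped` (labels of constant items), and the
#'   quadrature spec.
#' @export
fit_2pl <- function(data, n_quad = 61L, tol = 1e-4, max_iter = 500L) {
  X <- as.matrix(data); storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least two examinees")
  if (is.null(colnames(X))) colnames(X) <- paste0("Item", seq_len(ncol(X)))
  v <- apply(X, 2L, stats::var)
  dropped <- colnames(X)[v == 0]
  if (length(v[v == 0]) > 0L) {
    warning("dropping ", sum(v == 0), " constant item(s)")
    X <- X[, v > 0, drop = FALSE]
  }
  N <- nrow(X); J <- ncol(X)
  nodes <- seq(-6, 6, length.out = n_quad)
  wq <- stats::dnorm(nodes); wq <- wq / sum(wq)

  a <- rep(1, J); b <- stats::qlogis(1 - pmin(pmax(colMeans(X), 0.02), 0.98)) # crude start
  onemX <- 1 - X
  trace <- numeric(0); converged <- FALSE

  for (iter in seq_len(max_iter)) {
    eta <- outer(nodes, b, `-`) * matrix(a, n_quad, J, byrow = TRUE)  # Q x J
    P <- clamp_prob(stats::plogis(eta))
    ll_iq <- X %*% t(log(P)) + onemX %*% t(log1p(-P))                 # N x Q
    ll_iq <- sweep(ll_iq, 2L, log(wq), `+`)
    mx <- matrixStats_rowMax(ll_iq)
    post <- exp(ll_iq - mx)
    rs <- rowSums(post)
    trace <- c(trace, sum(mx + log(rs)))
    post <- post / rs

    nq <- colSums(post)                     # expected examinees per node
    rqj <- crossprod(post, X)               # Q x J expected correct
    a_new <- a; b_new <- b
    D <- cbind(1, nodes)
    for (j in seq_len(J)) {
      beta0 <- c(-a[j] * b[j], a[j])        # slope-intercept form
      fit <- fit_link_glm(rqj[, j], nq, D, "logit", beta0 = beta0)
      a_new[j] <- fit$beta[2L]
      b_new[j] <- -fit$beta[1L] / fit$beta[2L]
    }
    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("2PL EM did not converge in ", max_iter, " iterations")

  eta <- outer(nodes, b, `-`) * matrix(a, n_quad, J, byrow = TRUE)
  P <- clamp_prob(stats::plogis(eta))
  ll_iq <- sweep(X %*% t(log(P)) + onemX %*% t(log1p(-P)), 2L, log(wq), `+`)
  mx <- matrixStats_rowMax(ll_iq)
  post <- exp(ll_iq - mx)
  loglik <- sum(mx + log(rowSums(post)))
  post <- post / rowSums(post)
  theta <- as.numeric(post %*% nodes)

  structure(list(items = data.frame(item = colnames(X), a = a, b = b,
                                    stringsAsFactors = FALSE),
                 theta = theta, loglik = loglik, trace = trace,
                 converged = converged, dropped = dropped,
                 quadrature = list(nodes = nodes, weights = wq)),
            class = "twopl_fit")
}

#' @export
print.twopl_fit <- function(x, ...) {
  cat("2PL fit:", nrow(x$items), "items,", length(x$theta), "examinees,",
      "loglik", format(x$loglik), "converged:", x$converged, "\n")
  invisible(x)
}
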