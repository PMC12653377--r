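# Marginal maximum likelihood EM for (mixed) cognitive diagnostic models.
#
# The complete-data model: examinee i belongs to latent class c (one of the
# 2^K attribute profiles) with probability pi_c; given the class, responses
# are independent Bernoulli with item success probabilities P_j(alpha_c)
# from the item response functions in items.R. The E-step computes class
# posteriors; the M-step has a closed form for the saturated G-DINA items
# (posterior-weighted proportion correct per reduced profile) and runs a
# short Newton/IRLS on the link-scale coefficients for the constrained
# additive families.

LINKS <- list(
  identity = list(linkfun = function(p) p,
                  linkinv = function(eta) pmin(pmax(eta, PROB_FLOOR), 1 - PROB_FLOOR),
                  mu_eta  = function(p) rep(1, length(p))),
  logit    = list(linkfun = stats::qlogis,
                  linkinv = stats::plogis,
                  mu_eta  = function(p) p * (1 - p)),
  log      = list(linkfun = function(p) log(p),
                  linkinv = function(eta) pmin(exp(eta), 1 - PROB_FLOOR),
                  mu_eta  = function(p) p)
)

family_link <- function(family) {
  switch(family, ACDM = "identity", LLM = "logit", RRUM = "log",
         stop("no link for family ", family))
}

# Weighted binomial Newton fit on aggregated cells.
# r, n: successes and trials per reduced profile; D: design; link name.
fit_link_glm <- function(r, n, D, link, beta0 = NULL, max_iter = 25L, tol = 1e-8) {
  lk <- LINKS[[link]]
  pobs <- clamp_prob(ifelse(n > 0, r / pmax(n, 1e-12), 0.5), 1e-4)
  if (is.null(beta0)) {
    w <- pmax(n, 1e-8)
    beta0 <- tryCatch(solve(crossprod(D, w * D), crossprod(D, w * lk$linkfun(pobs))),
                      error = function(e) c(lk$linkfun(mean(pobs)), rep(0, ncol(D) - 1L)))
  }
  beta <- as.numeric(beta0)
  ll <- function(b) {
    p <- clamp_prob(lk$linkinv(as.numeric(D %*% b)))
    sum(r * log(p) + (n - r) * log1p(-p))
  }
  ll_old <- ll(beta)
  for (it in seq_len(max_iter)) {
    p <- clamp_prob(lk$linkinv(as.numeric(D %*% beta)))
    me <- lk$mu_eta(p)
    grad <- crossprod(D, (r - n * p) / (p * (1 - p)) * me)
    W <- n * me^2 / (p * (1 - p))
    info <- crossprod(D, W * D)
    step <- tryCatch(solve(info + diag(1e-10, ncol(D)), grad),
                     error = function(e) MASS::ginv(info) %*% grad)
    lambda <- 1
    repeat {
      cand <- beta + lambda * as.numeric(step)
      if (ll(cand) >= ll_old - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    delta <- max(abs(lambda * step))
    beta <- beta + lambda * as.numeric(step)
    ll_new <- ll(beta)
    if (ll_new < ll_old - 1e-8 && lambda < 1e-4) break  # no ascent possible
    ll_old <- ll_new
    if (delta < tol) break
  }
  p <- clamp_prob(lk$linkinv(as.numeric(D %*% beta)))
  list(beta = as.numeric(beta), prob = p)
}

# M-step update for one item from aggregated (r_l, n_l) over reduced profiles.
mstep_item <- function(item, r, n, design) {
  L <- length(item$prob)
  n <- pmax(n, 1e-12)
  fam <- item$family
  if (fam == "GDINA" || L == 2L) {
    item$prob <- clamp_prob(r / n)
    if (L == 2L && fam %in% c("DINA", "DINO")) {
      item$g <- item$prob[1L]; item$s <- 1 - item$prob[2L]
    }
    return(item)
  }
  if (fam == "DINA") {
    g <- sum(r[-L]) / sum(n[-L]); sl <- 1 - r[L] / n[L]
    g <- clamp_prob(g); sl <- clamp_prob(sl)
    item$prob <- c(rep(g, L - 1L), 1 - sl)
    item$g <- g; item$s <- sl
    return(item)
  }
  if (fam == "DINO") {
    g <- r[1L] / n[1L]; sl <- 1 - sum(r[-1L]) / sum(n[-1L])
    g <- clamp_prob(g); sl <- clamp_prob(sl)
    item$prob <- c(g, rep(1 - sl, L - 1L))
    item$g <- g; item$s <- sl
    return(item)
  }
  # additive families: intercept + main effects on the family link
  link <- family_link(fam)
  fit <- fit_link_glm(r, n, design, link, beta0 = item$coefs)
  item$coefs <- fit$beta
  item$prob <- fit$prob
  item$intercept <- fit$beta[1L]
  item$main <- fit$beta[-1L]
  if (fam == "RRUM") {  # translate to (pistar, r) surface parameters
    item$pistar <- unname(exp(sum(fit$beta)))
    item$r <- unname(exp(-fit$beta[-1L]))
  }
  item
}

# initialize one item's reduced-profile probabilities: low success without
# mastery, high with full mastery, interpolated by mastery fraction, jittered
init_item <- function(family, req, Kstar_profiles, rng_jitter) {
  L <- nrow(Kstar_profiles)
  frac <- rowSums(Kstar_profiles) / ncol(Kstar_profiles)
  prob <- clamp_prob(0.2 + 0.6 * frac + rng_jitter(L), 0.01)
  it <- item_gdina_probs(prob, req)
  it$family <- family
  if (family %in% c("ACDM", "LLM", "RRUM")) it$coefs <- NULL
  it
}

#' Fit a (mixed) cognitive diagnostic model by EM
#'
#' Estimates latent-class proportions over all `2^K` knowledge states and
#' item parameters by marginal maximum likelihood. Each item may follow a
#' different family (`"GDINA"`, `"DINA"`, `"DINO"`, `"ACDM"`, `"LLM"`,
#' `"RRUM"`), which is how the mixed model selected by
#' [build_mixed_model()] is refitted.
#'
#' The E-step computes, for every examinee, the posterior over latent
#' classes; the M-step sets the class proportions to the mean posterior
#' and updates item parameters from posterior-weighted success counts
#' aggregated by reduced profile (closed form for saturated, DINA and
#' DINO items; a short Newton fit on the link scale for the additive
#' families). Iteration stops when the largest absolute change in any
#' class-success probability or mixing proportion falls below `tol`.
#'
#' @param data N x J 0/1 response matrix.
#' @param q a [qmatrix] with J rows.
#' @param families single family name recycled to all items, or a
#'   character vector of length J. Single-attribute items always get the
#'   saturated (two-parameter) fit regardless of the label.
#' @param tol convergence tolerance on parameter change (default `1e-4`).
#' @param max_iter iteration cap (default 1000).
#' @param seed seed for the jittered initialization.
#' @param init optional warm start: a list with `items` (list of
#'   [cdm_item] whose reduced-profile probabilities seed the iteration)
#'   and optionally `pi` (initial class proportions). Families still
#'   follow `families`.
#' @param n_starts number of independent jittered starts (seeded
#'   `seed`, `seed + 1`, ...); the fit with the highest marginal
#'   likelihood is returned. Ignored when `init` is given. Multiple
#'   starts guard against secondary modes of the mixture likelihood,
#'   which exist at realistic sample sizes once K is large.
#' @export
em_fit <- function(data, q, families = "GDINA", tol = 1e-4, max_iter = 1000L,
                   seed = 1L, init = NULL, n_starts = 1L) {
  if (is.null(init) && n_starts > 1L) {
    fits <- lapply(seq_len(n_starts) - 1L, function(k)
      em_fit(data, q, families = families, tol = tol, max_iter = max_iter,
             seed = seed + k, init = NULL, n_starts = 1L))
    return(fits[[which.max(vapply(fits, `[[`, numeric(1L), "loglik"))]])
  }
  X <- as.matrix(data); storage.mode(X) <- "double"
  stopifnot(inherits(q, "qmatrix"))
  N <- nrow(X); J <- ncol(X); K <- ncol(q)
  if (N < 2L) stop("need at least two examinees")
  if (J != nrow(q)) stop("response matrix has ", J, " items; Q-matrix has ", nrow(q))
  if (length(families) == 1L) families <- rep(families, J)
  stopifnot(length(families) == J,
            all(families %in% c("GDINA", "DINA", "DINO", "ACDM", "LLM", "RRUM")))

  profiles <- attribute_profiles(K)
  C <- nrow(profiles)
  req_list <- lapply(seq_len(J), function(j) which(unclass(q)[j, ] == 1L))
  ridx <- lapply(seq_len(J), function(j)
    profile_index(profiles[, req_list[[j]], drop = FALSE]))
  red_profiles <- lapply(req_list, function(r) attribute_profiles(length(r)))
  designs <- lapply(red_profiles, function(A) cbind(1, A))

  rng <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    function(L) stats::runif(L, -0.05, 0.05)
  })
  if (is.null(init)) {
    items <- lapply(seq_len(J), function(j)
      init_item(families[j], req_list[[j]], red_profiles[[j]], rng))
    pi_c <- rep(1 / C, C)
  } else {
    items <- lapply(seq_len(J), function(j) {
      it <- init$items[[j]]
      stopifnot(identical(as.integer(unname(it$req)),
                          as.integer(unname(req_list[[j]]))))
      out <- item_gdina_probs(clamp_prob(it$prob, 1e-4), req_list[[j]])
      out$family <- families[j]
      out
    })
    pi_c <- if (is.null(init$pi)) rep(1 / C, C) else pmax(init$pi, PROB_FLOOR)
    pi_c <- pi_c / sum(pi_c)
  }

  # collapse to unique response patterns (J <= 50 keeps the key exact)
  key <- as.numeric(X %*% 2^(seq_len(J) - 1L))
  first <- !duplicated(key)
  Xu <- X[first, , drop = FALSE]
  w <- as.numeric(tabulate(match(key, key[first])))

  pack <- function() c(unlist(lapply(items, `[[`, "prob")), pi_c)
  trace <- numeric(0)
  converged <- FALSE
  old <- pack()
  onemXu <- 1 - Xu

  for (iter in seq_len(max_iter)) {
    P <- item_prob_matrix(items, profiles)          # J x C
    P <- clamp_prob(P)
    ll_ic <- Xu %*% log(P) + onemXu %*% log1p(-P)   # U x C
    ll_ic <- sweep(ll_ic, 2L, log(pi_c), `+`)
    mx <- matrixStats_rowMax(ll_ic)
    post <- exp(ll_ic - mx)
    rs <- rowSums(post)
    trace <- c(trace, sum(w * (mx + log(rs))))
    post <- (w / rs) * post                          # weighted, normalized

    Nc <- colSums(post)                              # expected class sizes
    Rcj <- crossprod(post, Xu)                       # C x J expected correct
    pi_c <- pmax(Nc / N, PROB_FLOOR); pi_c <- pi_c / sum(pi_c)
    for (j in seq_len(J)) {
      agg_n <- rowsum(Nc, ridx[[j]])
      agg_r <- rowsum(Rcj[, j], ridx[[j]])
      items[[j]] <- mstep_item(items[[j]], as.numeric(agg_r), as.numeric(agg_n),
                               designs[[j]])
    }
    new <- pack()
    if (max(abs(new - old)) < tol) { converged <- TRUE; old <- new; break }
    old <- new
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")

  # log-likelihood at the returned (post-M-step) parameters
  P <- clamp_prob(item_prob_matrix(items, profiles))
  ll_ic <- sweep(Xu %*% log(P) + onemXu %*% log1p(-P), 2L, log(pi_c), `+`)
  mx <- matrixStats_rowMax(ll_ic)
  loglik <- sum(w * (mx + log(rowSums(exp(ll_ic - mx)))))
  trace <- c(trace, loglik)

  n_params <- sum(vapply(items, item_n_params, integer(1L))) + (C - 1L)
  structure(list(items = items, pi = as.numeric(pi_c), loglik = loglik,
                 n_params = n_params, n_obs = N, trace = trace,
                 converged = converged, n_iter = length(trace) - 1L,
                 K = K, profiles = profiles, q = q, families = families,
                 prob_matrix = P, seed = seed),
            class = "cdm_fit")
}

# fast row maxima
matrixStats_rowMax <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat("Cognitive diagnostic model fit\n")
  cat("  attributes:", x$K, " latent classes:", length(x$pi),
      " items:", length(x$items), " examinees:", x$n_obs, "\n")
  cat("  families:", paste(sort(unique(x$families)), collapse = ", "), "\n")
  cat("  loglik:", format(x$loglik), " parameters:", x$n_params,
      " iterations:", x$n_iter, " converged:", x$converged, "\n")
  invisible(x)
}

#' Posterior classification of examinees into knowledge states
#'
#' Computes each examinee's posterior distribution over the `2^K`
#' knowledge states under a fitted model, the maximum a posteriori (MAP)
#' state, and marginal per-attribute mastery probabilities (the
#' posterior-weighted average of each profile bit). MAP ties are broken
#' toward the lower class index; the number of tied rows is recorded in
#' `n_ties`.
#'
#' @param fit a `cdm_fit`.
#' @param data N x J 0/1 response matrix with the same J as the fit.
#' @return an object of class `cdm_classification` with elements
#'   `posterior` (N x 2^K), `map_state` (state strings), `map_index`,
#'   `map_prob`, `marginal_mastery` (N x K), `raw_score`, and `n_ties`.
#' @export
classify <- function(fit, data) {
  stopifnot(inherits(fit, "cdm_fit"))
  X <- as.matrix(data); storage.mode(X) <- "double"
  if (ncol(X) != length(fit$items))
    stop("data has ", ncol(X), " items; fit has ", length(fit$items))
  P <- fit$prob_matrix
  ll_ic <- sweep(X %*% log(P) + (1 - X) %*% log1p(-P), 2L, log(fit$pi), `+`)
  mx <- matrixStats_rowMax(ll_ic)
  post <- exp(ll_ic - mx)
  post <- post / rowSums(post)
  map_first <- max.col(post, ties.method = "first")
  map_last <- max.col(post, ties.method = "last")
  n_ties <- sum(map_first != map_last)
  states <- rownames(fit$profiles)
  structure(list(posterior = post,
                 map_index = map_first,
                 map_state = states[map_first],
                 map_prob = post[cbind(seq_len(nrow(post)), map_first)],
                 marginal_mastery = post %*% fit$profiles,
                 raw_score = as.integer(rowSums(X)),
                 n_ties = n_ties,
                 K = fit$K),
            class = "cdm_classification")
}

#' Model fit and reliability indices
#'
#' Deviance (`-2 loglik`), AIC (`deviance + 2 p`), BIC
#' (`deviance + p log N`), an item-level RMSEA, and Cronbach's alpha on
#' raw scores. The item RMSEA compares the model success probability with
#' the posterior-weighted observed proportion correct in each latent
#' class: `RMSEA_j = sqrt(sum_c pi_c (P_j(alpha_c) - Ptilde_jc)^2)`; the
#' overall value is the mean over items.
#'
#' @param fit a `cdm_fit`.
#' @param data the response matrix the model was fitted to.
#' @return a list with `deviance`, `aic`, `bic`, `rmsea`, `item_rmsea`,
#'   and `cronbach_alpha`.
#' @export
fit_indices <- function(fit, data) {
  stopifnot(inherits(fit, "cdm_fit"))
  X <- as.matrix(data); storage.mode(X) <- "double"
  dev <- -2 * fit$loglik
  aic <- dev + 2 * fit$n_params
  bic <- dev + fit$n_params * log(fit$n_obs)
  cls <- classify(fit, X)
  post <- cls$posterior
  Nc <- colSums(post)
  Rcj <- crossprod(post, X)                       # C x J
  Ptilde <- Rcj / pmax(Nc, 1e-12)                 # observed proportion by class
  P <- t(fit$prob_matrix)                         # C x J model probabilities
  item_rmsea <- sqrt(colSums(fit$pi * (P - Ptilde)^2))
  total <- rowSums(X)
  vt <- stats::var(total)
  if (vt <= 0) stop("total-score variance is zero; alpha undefined")
  J <- ncol(X)
  alpha <- J / (J - 1) * (1 - sum(apply(X, 2L, stats::var)) / vt)
  list(deviance = dev, aic = aic, bic = bic,
       rmsea = mean(item_rmsea), item_rmsea = as.numeric(item_rmsea),
       cronbach_alpha = alpha)
}

#' Simulation-based attribute classification reliability
#'
#' Draws simulees from the fitted class distribution, generates responses
#' from the fitted item response functions, re-classifies them by MAP
#' with the fitted parameters, and reports the per-attribute agreement
#' rate between generating and recovered mastery, averaged over
#' replications. The mean over attributes is reported alongside.
#'
#' @param fit a `cdm_fit`.
#' @param n_examinees simulees per replication (default: the fitted N,
#'   capped at 5000 for speed).
#' @param n_reps number of replications.
#' @param seed RNG seed.
#' @return a list with `attribute` (named per-attribute reliabilities)
#'   and `mean`.
#' @export
classification_reliability <- function(fit, n_examinees = NULL, n_reps = 5L,
                                       seed = 1L) {
  stopifnot(inherits(fit, "cdm_fit"))
  if (is.null(n_examinees)) n_examinees <- min(fit$n_obs, 5000L)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  K <- fit$K
  acc <- matrix(0, n_reps, K)
  for (r in seq_len(n_reps)) {
    cls_idx <- sample.int(length(fit$pi), n_examinees, replace = TRUE,
                          prob = fit$pi)
    alpha <- fit$profiles[cls_idx, , drop = FALSE]
    P <- t(fit$prob_matrix[, cls_idx, drop = FALSE])   # N x J
    X <- matrix(stats::rbinom(length(P), 1L, as.numeric(P)), nrow(P), ncol(P))
    rec <- classify(fit, X)
    alpha_hat <- fit$profiles[rec$map_index, , drop = FALSE]
    acc[r, ] <- colMeans(alpha_hat == alpha)
  }
  rel <- colMeans(acc)
  names(rel) <- colnames(fit$q)
  list(attribute = rel, mean = mean(rel))
}
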