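# Item-level Wald tests of reduced families against the saturated G-DINA
# item, and assembly of the mixed model.
#
# For a multi-attribute item the saturated fit estimates one success
# probability per reduced profile. Each reduced family is a set of linear
# restrictions on a link transform of those probabilities:
#   DINA  — all reduced profiles except full mastery share one probability
#   DINO  — all reduced profiles except no mastery share one probability
#   ACDM / LLM / RRUM — all interaction contrasts of the saturated
#           identity / logit / log-link coefficients are zero
# The statistic is (C f)' (C Sigma_f C')^{-1} (C f) with Sigma_f obtained
# from the probability covariance by the delta method, referred to a
# chi-square with df = number of restrictions.

CANDIDATE_FAMILIES <- c("DINA", "DINO", "ACDM", "LLM", "RRUM")
# tie-break precedence: more parsimonious first
FAMILY_PRECEDENCE <- c(DINA = 1L, DINO = 2L, ACDM = 3L, LLM = 4L, RRUM = 5L)

# covariance of the reduced-profile success probabilities of item j,
# from the posterior-weighted empirical (outer-product) information
item_prob_covariance <- function(fit, posterior, X, j) {
  profiles <- fit$profiles
  item <- fit$items[[j]]
  ridx <- reduced_index(item, profiles)
  L <- 2L^length(item$req)
  G <- matrix(0, ncol(posterior), L)
  G[cbind(seq_along(ridx), ridx)] <- 1
  post_l <- posterior %*% G                       # N x L membership mass
  p <- clamp_prob(item$prob, 1e-6)
  S <- post_l * ((matrix(X[, j], nrow(post_l), L) -
                  matrix(p, nrow(post_l), L, byrow = TRUE)) /
                 matrix(p * (1 - p), nrow(post_l), L, byrow = TRUE))
  info <- crossprod(S)
  sigma <- tryCatch(solve(info), error = function(e) {
    warning("singular item information for item ", j, "; using pseudo-inverse")
    MASS::ginv(info)
  })
  list(p = p, sigma = sigma)
}

# restriction set for a family on an item with L = 2^Kstar reduced profiles
wald_restrictions <- function(family, Kstar) {
  L <- 2L^Kstar
  if (family %in% c("DINA", "DINO")) {
    if (family == "DINA") idx <- seq_len(L - 1L) else idx <- 2:L
    Cmat <- matrix(0, length(idx) - 1L, L)
    for (i in seq_len(nrow(Cmat))) {
      Cmat[i, idx[1L]] <- 1
      Cmat[i, idx[i + 1L]] <- -1
    }
    list(C = Cmat, link = "identity", df = L - 2L)
  } else {
    Minv <- solve(gdina_design_matrix(Kstar))
    int_rows <- (Kstar + 2L):L                     # interaction coefficients
    list(C = Minv[int_rows, , drop = FALSE],
         link = family_link(family), df = L - Kstar - 1L)
  }
}

#' Wald test of a reduced family against the saturated item
#'
#' Tests whether constraining a multi-attribute item from the saturated
#' G-DINA form to a reduced family significantly deteriorates fit. The
#' covariance of the saturated reduced-profile success probabilities is
#' the inverse of the posterior-weighted outer-product (empirical)
#' information; link-scale covariances follow by the delta method.
#'
#' @param fit a saturated `cdm_fit`.
#' @param data the response matrix used for the fit.
#' @param item item index (1-based) or item label; must require at least
#'   two attributes.
#' @param family one of `"DINA"`, `"DINO"`, `"ACDM"`, `"LLM"`, `"RRUM"`.
#' @param posterior optional precomputed posterior matrix (from
#'   [classify()]); recomputed when missing.
#' @param cov optional precomputed result of the internal covariance step
#'   (used by [build_mixed_model()] to share work across families).
#' @return a list (`wald_result`): `item_label`, `family`, `statistic`,
#'   `df`, `p_value`.
#' @export
wald_test <- function(fit, data, item, family, posterior = NULL, cov = NULL) {
  stopifnot(inherits(fit, "cdm_fit"), family %in% CANDIDATE_FAMILIES)
  j <- if (is.character(item)) match(item, rownames(fit$q)) else as.integer(item)
  if (is.na(j) || j < 1L || j > length(fit$items)) stop("unknown item: ", item)
  Kstar <- length(fit$items[[j]]$req)
  if (Kstar < 2L) stop("Wald selection applies only to multi-attribute items")
  X <- as.matrix(data); storage.mode(X) <- "double"
  if (is.null(cov)) {
    if (is.null(posterior)) posterior <- classify(fit, X)$posterior
    cov <- item_prob_covariance(fit, posterior, X, j)
  }
  res <- wald_restrictions(family, Kstar)
  lk <- LINKS[[res$link]]
  f <- lk$linkfun(cov$p)
  jac <- switch(res$link,
                identity = rep(1, length(cov$p)),
                logit = 1 / (cov$p * (1 - cov$p)),
                log = 1 / cov$p)
  sigma_f <- (jac %o% jac) * cov$sigma
  v <- as.numeric(res$C %*% f)
  V <- res$C %*% sigma_f %*% t(res$C)
  stat <- tryCatch(as.numeric(crossprod(v, solve(V, v))),
                   error = function(e) {
                     warning("singular restricted covariance for item ", j,
                             " (", family, "); using pseudo-inverse")
                     as.numeric(t(v) %*% MASS::ginv(V) %*% v)
                   })
  stat <- max(stat, 0)
  structure(list(item_label = rownames(fit$q)[j], family = family,
                 statistic = stat, df = res$df,
                 p_value = stats::pchisq(stat, res$df, lower.tail = FALSE)),
            class = "wald_result")
}

#' Select an item's family from its Wald results
#'
#' Applies the four selection rules: (1) admit reduced families whose
#' Wald p-value exceeds `alpha`; (2) among admitted families prefer the
#' highest p-value; (3) optionally (`prefer_parsimony`) prefer DINA/DINO
#' among the admitted families; (4) fall back to the saturated G-DINA
#' model when no reduced family is admitted. Exact p-value ties are
#' broken toward the more parsimonious family in the fixed order
#' DINA, DINO, ACDM, LLM, RRUM.
#'
#' @param results list of `wald_result` for one item (possibly empty).
#' @param alpha significance level (default 0.05).
#' @param prefer_parsimony apply rule 3.
#' @return list with `family`, `rule` (which rule fired), and `p_value`
#'   (of the selected reduced family, `NA` for the saturated fallback).
#' @export
select_item_model <- function(results, alpha = 0.05, prefer_parsimony = FALSE) {
  if (length(results) == 0L)
    return(list(family = "GDINA", rule = "no candidates", p_value = NA_real_))
  fams <- vapply(results, `[[`, character(1L), "family")
  pvals <- vapply(results, `[[`, numeric(1L), "p_value")
  admitted <- which(pvals > alpha)
  if (length(admitted) == 0L)
    return(list(family = "GDINA", rule = "rule 4: all reduced rejected",
                p_value = NA_real_))
  if (prefer_parsimony) {
    gate <- admitted[fams[admitted] %in% c("DINA", "DINO")]
    if (length(gate) > 0L) {
      pick <- gate[order(-pvals[gate], FAMILY_PRECEDENCE[fams[gate]])][1L]
      return(list(family = fams[pick], rule = "rule 3: parsimony preference",
                  p_value = pvals[pick]))
    }
  }
  pick <- admitted[order(-pvals[admitted], FAMILY_PRECEDENCE[fams[admitted]])][1L]
  rule <- if (length(admitted) == 1L) "rule 1: single admissible family"
          else "rule 2: highest p-value among admitted"
  list(family = fams[pick], rule = rule, p_value = pvals[pick])
}

#' Build the mixed cognitive diagnostic model
#'
#' Fits the saturated G-DINA model, Wald-tests every reduced family for
#' each multi-attribute item, selects a family per item (single-attribute
#' items always keep the saturated form), refits the resulting mixed
#' model by [em_fit()], and reports fit indices for both fits.
#'
#' @param data N x J 0/1 response matrix.
#' @param q a [qmatrix].
#' @param alpha Wald selection level.
#' @param candidates reduced families to test (default all five).
#' @param prefer_parsimony apply selection rule 3.
#' @param ... passed to [em_fit()] (tolerances, seed).
#' @return a list with `plan` (data frame: item, n_attributes, family,
#'   rule, p_value), `wald` (per-item list of `wald_result`), `fit` (the
#'   refitted mixed model), `fit_saturated`, and `indices` /
#'   `indices_saturated`.
#' @export
build_mixed_model <- function(data, q, alpha = 0.05,
                              candidates = CANDIDATE_FAMILIES,
                              prefer_parsimony = FALSE, ...) {
  X <- as.matrix(data)
  multi <- which(rowSums(unclass(q)) >= 2L)
  if (any(rowSums(unclass(q)) >= 3L) && nrow(X) <= 1000L)
    warning("items with 3+ attributes and n <= 1000: Wald type-I error may be inflated")
  sat <- em_fit(X, q, families = "GDINA", ...)
  posterior <- classify(sat, X)$posterior
  families <- rep("GDINA", nrow(q))
  wald <- vector("list", nrow(q)); names(wald) <- rownames(q)
  sel <- vector("list", nrow(q))
  for (j in multi) {
    cov <- item_prob_covariance(sat, posterior, X, j)
    wald[[j]] <- lapply(candidates, function(fam)
      wald_test(sat, X, j, fam, posterior = posterior, cov = cov))
    sel[[j]] <- select_item_model(wald[[j]], alpha = alpha,
                                  prefer_parsimony = prefer_parsimony)
    families[j] <- sel[[j]]$family
  }
  plan <- data.frame(
    item = rownames(q),
    n_attributes = as.integer(rowSums(unclass(q))),
    family = families,
    rule = vapply(seq_len(nrow(q)), function(j)
      if (is.null(sel[[j]])) "single-attribute: saturated G-DINA"
      else sel[[j]]$rule, character(1L)),
    p_value = vapply(seq_len(nrow(q)), function(j)
      if (is.null(sel[[j]])) NA_real_ else sel[[j]]$p_value, numeric(1L)),
    stringsAsFactors = FALSE)
  mixed <- if (all(families == "GDINA")) sat
           else em_fit(X, q, families = families,
                       init = list(items = sat$items, pi = sat$pi), ...)
  list(plan = plan, wald = wald, fit = mixed, fit_saturated = sat,
       indices = fit_indices(mixed, X),
       indices_saturated = fit_indices(sat, X))
}
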