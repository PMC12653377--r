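#' @keywords internal
PROB_FLOOR <- 1e-10

clamp_prob <- function(p, eps = PROB_FLOOR) pmin(pmax(p, eps), 1 - eps)

#' Item parameter set constructors
#'
#' An item is described by a model family, the attributes it requires (its
#' Q-matrix row), and a family-specific parameter set. All families are
#' special cases of the saturated G-DINA model, which assigns a free
#' success probability to every *reduced* profile (the sub-vector of a
#' knowledge state restricted to the item's required attributes):
#'
#' * `item_dina(g, s, req)` — conjunctive: success probability `1 - s`
#'   when all required attributes are mastered, `g` otherwise.
#' * `item_dino(g, s, req)` — disjunctive: `1 - s` when at least one
#'   required attribute is mastered, `g` otherwise.
#' * `item_acdm(intercept, main, req)` — additive on the identity link:
#'   `P = intercept + sum(main[k] * alpha_k)`.
#' * `item_llm(intercept, main, req)` — additive on the logit link.
#' * `item_rrum(pistar, r, req)` — reduced reparameterized unified model:
#'   `P = pistar * prod(r[k]^(1 - alpha_k))`, i.e. additive on the log
#'   link; `pistar` is the success probability at full mastery and each
#'   `r[k] <= 1` is the penalty for lacking attribute k.
#' * `item_gdina(delta, req)` — saturated, identity link, one coefficient
#'   per subset of the required attributes (intercept, main effects in
#'   required-attribute order, then interactions by increasing order,
#'   `utils::combn` order within each order).
#' * `item_gdina_probs(prob, req)` — saturated, specified directly by the
#'   `2^K*` reduced-profile success probabilities in reduced class-space
#'   order (first required attribute = most significant bit).
#'
#' Every constructor validates that all implied success probabilities lie
#' in `[0, 1]` by enumerating the reduced profiles.
#'
#' @param g,s guessing and slip probabilities in `[0, 1)` with `g < 1 - s`.
#' @param intercept,main additive coefficients (main effects in the order
#'   of `req`).
#' @param pistar,r RRUM full-mastery probability and penalty factors.
#' @param delta saturated G-DINA coefficient vector of length `2^K*`.
#' @param prob reduced-profile success probabilities, length `2^K*`.
#' @param req integer vector of required attribute positions (1-based,
#'   strictly increasing, nonempty).
#' @return An object of class `cdm_item`: a list with elements `family`,
#'   `req`, and `prob` (success probability per reduced profile, in
#'   reduced class-space order), plus the family's natural parameters.
#' @name cdm_item
NULL

new_item <- function(family, req, prob, pars = list()) {
  req <- as.integer(req)
  if (length(req) < 1L) stop("an item must require at least one attribute")
  if (is.unsorted(req, strictly = TRUE)) stop("'req' must be strictly increasing")
  prob <- as.numeric(prob)
  if (length(prob) != 2L^length(req))
    stop("expected ", 2L^length(req), " reduced-profile probabilities")
  if (any(!is.finite(prob)) || any(prob < -1e-12) || any(prob > 1 + 1e-12))
    stop("item implies success probabilities outside [0, 1]")
  structure(c(list(family = family, req = req, prob = pmin(pmax(prob, 0), 1)),
              pars),
            class = "cdm_item")
}

#' @rdname cdm_item
#' @export
item_dina <- function(g, s, req) {
  stopifnot(g >= 0, s >= 0, g + s < 1 + 1e-12)
  L <- 2L^length(req)
  prob <- rep(g, L); prob[L] <- 1 - s  # last reduced profile = all mastered
  new_item("DINA", req, prob, list(g = g, s = s))
}

#' @rdname cdm_item
#' @export
item_dino <- function(g, s, req) {
  stopifnot(g >= 0, s >= 0, g + s < 1 + 1e-12)
  L <- 2L^length(req)
  prob <- rep(1 - s, L); prob[1L] <- g  # first reduced profile = none mastered
  new_item("DINO", req, prob, list(g = g, s = s))
}

additive_probs <- function(intercept, main, req, linkinv) {
  A <- attribute_profiles(length(req))
  linkinv(intercept + as.numeric(A %*% main))
}

#' @rdname cdm_item
#' @export
item_acdm <- function(intercept, main, req) {
  stopifnot(length(main) == length(req))
  prob <- additive_probs(intercept, main, req, identity)
  new_item("ACDM", req, prob, list(intercept = intercept, main = main))
}

#' @rdname cdm_item
#' @export
item_llm <- function(intercept, main, req) {
  stopifnot(length(main) == length(req))
  prob <- additive_probs(intercept, main, req, stats::plogis)
  new_item("LLM", req, prob, list(intercept = intercept, main = main))
}

#' @rdname cdm_item
#' @export
item_rrum <- function(pistar, r, req) {
  stopifnot(length(r) == length(req), pistar >= 0, pistar <= 1, all(r >= 0))
  A <- attribute_profiles(length(req))
  prob <- pistar * apply(matrix(r, nrow(A), ncol(A), byrow = TRUE)^(1 - A), 1L, prod)
  new_item("RRUM", req, prob, list(pistar = pistar, r = r))
}

#' Saturated G-DINA design matrix on the reduced class space
#'
#' Rows are the `2^Kstar` reduced profiles in reduced class-space order;
#' columns are the subset effects: intercept, main effects, then
#' interactions by increasing order (`utils::combn` order within each
#' order). Entry (l, S) is 1 when profile l masters every attribute in
#' subset S, so `prob = M %*% delta` under the identity link.
#'
#' @param Kstar number of required attributes.
#' @return a `2^Kstar` x `2^Kstar` 0/1 matrix.
#' @export
gdina_design_matrix <- function(Kstar) {
  A <- attribute_profiles(Kstar)
  subsets <- list(integer(0))
  for (ord in seq_len(Kstar))
    subsets <- c(subsets, utils::combn(Kstar, ord, simplify = FALSE))
  M <- vapply(subsets,
              function(S) if (length(S) == 0L) rep(1, nrow(A))
                          else apply(A[, S, drop = FALSE], 1L, prod),
              numeric(nrow(A)))
  storage.mode(M) <- "double"
  M
}

#' @rdname cdm_item
#' @export
item_gdina <- function(delta, req) {
  M <- gdina_design_matrix(length(req))
  if (length(delta) != ncol(M))
    stop("saturated item with ", length(req), " attributes needs ",
         ncol(M), " delta coefficients")
  new_item("GDINA", req, as.numeric(M %*% delta), list(delta = as.numeric(delta)))
}

#' @rdname cdm_item
#' @export
item_gdina_probs <- function(prob, req) {
  new_item("GDINA", req, prob)
}

#' Restrict a knowledge state to an item's required attributes
#'
#' @param profile 0/1 vector of length K (or a profile matrix, rows =
#'   profiles).
#' @param item a `cdm_item` (or an integer vector of required positions).
#' @return the reduced profile(s), order of required attributes preserved.
#' @export
reduce_profile <- function(profile, item) {
  req <- if (inherits(item, "cdm_item")) item$req else as.integer(item)
  if (is.matrix(profile)) profile[, req, drop = FALSE] else profile[req]
}

# map every full-space class index to its reduced-profile index for an item
reduced_index <- function(item, profiles) {
  red <- reduce_profile(profiles, item)
  profile_index(red)
}

#' Item response function
#'
#' Success probability of an item for a knowledge state. The probability
#' depends on the state only through its reduced profile.
#'
#' @param item a `cdm_item`.
#' @param profile 0/1 vector of length K, or a profile matrix (rows).
#' @return numeric success probabilities in `[0, 1]`.
#' @examples
#' it <- item_dina(g = 0.2, s = 0.1, req = c(1, 2))
#' irf(it, c(1, 1, 0))  # 0.9
#' irf(it, c(0, 1, 0))  # 0.2
#' @export
irf <- function(item, profile) {
  if (!is.matrix(profile)) profile <- matrix(profile, nrow = 1L)
  red <- reduce_profile(profile, item)
  item$prob[profile_index(red)]
}

# J x C matrix of success probabilities: item j by latent class c
item_prob_matrix <- function(items, profiles) {
  t(vapply(items, function(it) it$prob[reduced_index(it, profiles)],
           numeric(nrow(profiles))))
}

#' Log-likelihood of a response vector given a knowledge state
#'
#' Responses are conditionally independent given the state (the standard
#' CDM assumption), so the log-likelihood is the sum of Bernoulli terms
#' over items. Probabilities are floored at `1e-10` away from 0 and 1 so
#' boundary parameters cannot produce `-Inf`.
#'
#' @param responses 0/1 vector, one entry per item.
#' @param profile 0/1 knowledge state of length K.
#' @param items list of `cdm_item`.
#' @return the log-likelihood (scalar).
#' @export
response_vector_loglik <- function(responses, profile, items) {
  stopifnot(length(responses) == length(items))
  p <- clamp_prob(vapply(items, function(it) irf(it, profile), numeric(1L)))
  sum(responses * log(p) + (1 - responses) * log1p(-p))
}

#' Count the free parameters of an item, by family
#' @keywords internal
item_n_params <- function(item) {
  Kstar <- length(item$req)
  switch(item$family,
         DINA = 2L, DINO = 2L,
         ACDM = Kstar + 1L, LLM = Kstar + 1L, RRUM = Kstar + 1L,
         GDINA = as.integer(2L^Kstar),
         stop("unknown family: ", item$family))
}
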