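# EM estimation, classification, fit indices, reliability

make_dina_cohort <- function(N = 800, seed = 5) {
  qm <- qmatrix(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                      c(0, 1, 1), c(1, 0, 1), c(1, 1, 1), c(1, 0, 0),
                      c(0, 1, 0), c(0, 0, 1)))
  items <- simulate_item_plan(qm, "DINA", seed = seed)
  prof <- sample_profiles(population_independent(c(0.4, 0.6, 0.5)), N,
                          seed = seed + 1)
  X <- generate_responses(prof, items, seed = seed + 2)
  list(q = qm, items = items, prof = prof, X = X)
}

test_that("EM trace is nondecreasing and the final loglik matches brute force", {
  for (seed in c(5, 17)) {
    co <- make_dina_cohort(N = 300, seed = seed)
    fit <- em_fit(co$X, co$q, families = "GDINA", seed = 1)
    expect_true(all(diff(fit$trace) > -1e-8))
    expect_equal(fit$loglik,
                 bf_mixture_loglik(co$X, fit$prob_matrix, fit$pi),
                 tolerance = 1e-6)
    expect_equal(fit$n_params,
                 sum(2^rowSums(unclass(co$q))) + 2^3 - 1)
  }
})

test_that("a single-item saturated fit reaches the mixture likelihood ridge", {
  # one binary item, one attribute: the marginal model is a 2-point
  # Bernoulli mixture whose maximized loglik equals that of the observed
  # success rate; grid search over (pi, p0, p1) is the oracle
  set.seed(8)
  X <- matrix(rbinom(400, 1, 0.37), ncol = 1)
  qm <- qmatrix(matrix(1L, 1, 1))
  fit <- em_fit(X, qm, families = "GDINA", seed = 2)
  grid <- seq(0.01, 0.99, by = 0.01)
  best <- -Inf
  n1 <- sum(X); n0 <- nrow(X) - n1
  for (pi1 in grid) for (p0 in grid) for (p1 in grid) {
    m <- pi1 * p1 + (1 - pi1) * p0
    best <- max(best, n1 * log(m) + n0 * log(1 - m))
  }
  expect_equal(fit$loglik, best, tolerance = 1e-4)
})

test_that("DINA parameters are recovered from a seeded cohort", {
  co <- make_dina_cohort(N = 2000, seed = 6)
  fit <- em_fit(co$X, co$q, families = "DINA", seed = 1)
  g_err <- vapply(seq_along(co$items), function(j)
    fit$items[[j]]$g - co$items[[j]]$g, numeric(1L))
  s_err <- vapply(seq_along(co$items), function(j)
    fit$items[[j]]$s - co$items[[j]]$s, numeric(1L))
  expect_lt(max(abs(c(g_err, s_err))), 0.05)
  pi_true <- as.numeric(table(factor(profile_string(co$prof),
                                     levels = rownames(attribute_profiles(3)))) /
                        nrow(co$X))
  expect_lt(max(abs(fit$pi - pi_true)), 0.03)
})

test_that("constrained additive families are fitted on their link scales", {
  set.seed(31)
  qm <- qmatrix(rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0), c(0, 1),
                      c(1, 1), c(1, 1), c(1, 1)))
  fams <- c(rep("GDINA", 6), "ACDM", "LLM", "RRUM")
  items <- simulate_item_plan(qm, fams, seed = 9)
  prof <- sample_profiles(population_independent(c(0.5, 0.55)), 4000, seed = 10)
  X <- generate_responses(prof, items, seed = 11)
  fit <- em_fit(X, qm, families = fams, seed = 1)
  for (j in 7:9) {
    true_p <- irf(items[[j]], attribute_profiles(2))
    expect_lt(max(abs(fit$items[[j]]$prob - true_p)), 0.06)
    expect_equal(fit$items[[j]]$family, fams[j])
  }
  # RRUM surface parameters are translated back
  expect_true(is.numeric(fit$items[[9]]$pistar))
  expect_true(all(fit$items[[9]]$r >= 0))
})

test_that("posterior classification matches a brute-force Bayes table", {
  items <- list(item_dina(0.2, 0.1, 1L), item_llm(-0.5, c(1, 1.5), c(1L, 2L)),
                item_dino(0.15, 0.2, c(1L, 2L)), item_gdina_probs(c(0.3, 0.8), 2L))
  qm <- qmatrix(rbind(c(1, 0), c(1, 1), c(1, 1), c(0, 1)))
  pi_c <- c(0.4, 0.3, 0.2, 0.1)
  fit <- fake_fit(items, pi_c, qm)
  X <- rbind(c(1, 1, 0, 1), c(0, 0, 0, 0), c(1, 0, 1, 1))
  cls <- classify(fit, X)
  A <- attribute_profiles(2)
  for (i in 1:3) {
    joint <- vapply(1:4, function(c) {
      p <- vapply(items, function(it) irf(it, A[c, ]), numeric(1L))
      fit$pi[c] * prod(ifelse(X[i, ] == 1, p, 1 - p))
    }, numeric(1L))
    expect_equal(cls$posterior[i, ], joint / sum(joint), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(max(abs(rowSums(cls$posterior) - 1)), 0, tolerance = 1e-12)
  expect_equal(cls$marginal_mastery, cls$posterior %*% A, ignore_attr = TRUE)
})

test_that("an uninformative item yields a uniform posterior with lowest-index MAP", {
  it <- item_gdina_probs(c(0.5, 0.5), req = 1L)
  qm <- qmatrix(matrix(1L, 1, 1))
  fit <- fake_fit(list(it), c(0.5, 0.5), qm)
  cls <- classify(fit, matrix(c(1, 0), 2, 1))
  expect_equal(cls$posterior, matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(cls$map_state, c("0", "0"))
  expect_equal(cls$n_ties, 2L)
})

test_that("noise-free items classify deterministically with full confidence", {
  qm <- qmatrix(rbind(diag(2L), diag(2L), diag(2L)))
  items <- lapply(rep(1:2, 3), function(k) item_dina(0, 0, k))
  prof <- attribute_profiles(2)[c(1, 2, 3, 4, 2, 3), ]
  X <- generate_responses(prof, items, seed = 4)
  fit <- fake_fit(items, rep(0.25, 4), qm)
  cls <- classify(fit, X)
  expect_equal(cls$map_state, unname(profile_string(prof)))
  expect_true(all(cls$map_prob > 1 - 1e-6))
})

test_that("fit indices satisfy their defining identities", {
  co <- make_dina_cohort(N = 400, seed = 7)
  fit <- em_fit(co$X, co$q, families = "GDINA", seed = 1)
  fi <- fit_indices(fit, co$X)
  expect_equal(fi$deviance, -2 * fit$loglik)
  expect_equal(fi$aic, fi$deviance + 2 * fit$n_params)
  expect_equal(fi$bic, fi$deviance + fit$n_params * log(fit$n_obs))
  expect_true(all(fi$item_rmsea >= 0))
  expect_equal(fi$rmsea, mean(fi$item_rmsea))
})

test_that("Cronbach's alpha equals the direct variance computation", {
  X <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, 1), c(0, 0, 0),
             c(1, 0, 1))
  item_var <- apply(X, 2, var)
  total_var <- var(rowSums(X))
  alpha_direct <- 3 / 2 * (1 - sum(item_var) / total_var)
  qm <- qmatrix(matrix(1L, 3, 1))
  fit <- em_fit(X, qm, seed = 1)
  expect_equal(fit_indices(fit, X)$cronbach_alpha, alpha_direct)
  ones <- matrix(1L, 4, 3)
  fit1 <- suppressWarnings(em_fit(ones, qm, seed = 1, max_iter = 5))
  expect_error(fit_indices(fit1, ones), "alpha")
})

test_that("classification reliability is 1 for noise-free items and ~0.5 for coin-flip items", {
  qm <- qmatrix(rbind(diag(2L), diag(2L)))
  clean <- fake_fit(lapply(rep(1:2, 2), function(k)
    item_gdina_probs(c(1e-9, 1 - 1e-9), k)), rep(0.25, 4), qm)
  clean$n_obs <- 500L
  rel <- classification_reliability(clean, n_examinees = 400, n_reps = 2, seed = 3)
  expect_equal(unname(rel$attribute), c(1, 1))
  coin <- fake_fit(lapply(rep(1:2, 2), function(k)
    item_gdina_probs(c(0.5, 0.5), k)), rep(0.25, 4), qm)
  coin$n_obs <- 500L
  rel2 <- classification_reliability(coin, n_examinees = 2000, n_reps = 3, seed = 4)
  expect_true(all(abs(rel2$attribute - 0.5) < 0.05))
  expect_equal(rel2$mean, mean(rel2$attribute))
})
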