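# Wald-test selection of reduced families

test_that("satisfied restrictions give a zero statistic and p = 1", {
  qm <- qmatrix(rbind(c(1, 1), c(1, 0), c(0, 1)))
  items <- list(item_acdm(0.2, c(0.3, 0.4), c(1L, 2L)),
                item_gdina_probs(c(0.2, 0.8), 1L),
                item_gdina_probs(c(0.2, 0.8), 2L))
  fit <- fake_fit(items, rep(0.25, 4), qm)
  X <- matrix(rbinom(60, 1, 0.5), 20, 3)
  # inject an exactly-additive probability vector with a clean covariance
  cov <- list(p = irf(items[[1]], attribute_profiles(2)), sigma = diag(4) * 1e-4)
  w <- wald_test(fit, X, 1, "ACDM", cov = cov)
  expect_equal(w$statistic, 0, tolerance = 1e-16)
  expect_equal(w$p_value, 1)
  expect_equal(w$df, 2^2 - 2 - 1)
  # DINA restrictions on an exactly-DINA vector
  covd <- list(p = c(0.2, 0.2, 0.2, 0.9), sigma = diag(4) * 1e-4)
  wd <- wald_test(fit, X, 1, "DINA", cov = covd)
  expect_equal(wd$statistic, 0, tolerance = 1e-16)
  expect_equal(wd$df, 2^2 - 2)
})

test_that("single-attribute items cannot be Wald-tested", {
  qm <- qmatrix(rbind(c(1, 1), c(1, 0), c(0, 1)))
  fit <- fake_fit(list(item_acdm(0.2, c(0.3, 0.4), c(1L, 2L)),
                       item_gdina_probs(c(0.2, 0.8), 1L),
                       item_gdina_probs(c(0.2, 0.8), 2L)),
                  rep(0.25, 4), qm)
  expect_error(wald_test(fit, matrix(0L, 2, 3), 2, "DINA"), "multi-attribute")
})

test_that("selection rules pick the admitted family with the highest p", {
  mk <- function(fam, p) structure(list(item_label = "ItemX", family = fam,
                                        statistic = 1, df = 1, p_value = p),
                                   class = "wald_result")
  res <- list(mk("DINA", 0.001), mk("DINO", 0.002), mk("ACDM", 0.030),
              mk("LLM", 0.244), mk("RRUM", 0.070))
  sel <- select_item_model(res, alpha = 0.05)
  expect_equal(sel$family, "LLM")
  # all rejected -> saturated fallback
  low <- lapply(res, function(r) { r$p_value <- 0.01; r })
  expect_equal(select_item_model(low)$family, "GDINA")
  expect_match(select_item_model(low)$rule, "rule 4")
  # exact tie broken toward the more parsimonious family
  tie <- list(mk("ACDM", 0.40), mk("LLM", 0.40))
  expect_equal(select_item_model(tie)$family, "ACDM")
  # empty candidate set
  empty <- select_item_model(list())
  expect_equal(empty$family, "GDINA")
  expect_equal(empty$rule, "no candidates")
  # parsimony preference gates to DINA/DINO when admitted
  mix <- list(mk("DINA", 0.10), mk("LLM", 0.80))
  expect_equal(select_item_model(mix, prefer_parsimony = TRUE)$family, "DINA")
  expect_equal(select_item_model(mix)$family, "LLM")
})

test_that("an all-single-attribute Q-matrix yields an all-saturated plan", {
  qm <- qmatrix(rbind(diag(2L), diag(2L), diag(2L)))
  items <- simulate_item_plan(qm, "DINA", seed = 2)
  prof <- sample_profiles(population_independent(c(0.5, 0.5)), 400, seed = 3)
  X <- generate_responses(prof, items, seed = 4)
  mm <- build_mixed_model(X, qm, seed = 1)
  expect_true(all(mm$plan$family == "GDINA"))
  expect_true(all(vapply(mm$wald, is.null, logical(1L))))
  expect_match(mm$plan$rule[1], "single-attribute")
})

test_that("mixed-model selection recovers generating families at n = 3000", {
  qm <- qmatrix(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                      c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                      c(1, 1, 0), c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)))
  fams <- c(rep("GDINA", 6), "DINA", "LLM", "DINA", "ACDM")
  items <- simulate_item_plan(qm, fams, seed = 12)
  prof <- sample_profiles(population_independent(c(0.45, 0.55, 0.5)), 3000,
                          seed = 13)
  X <- generate_responses(prof, items, seed = 14)
  mm <- build_mixed_model(X, qm, seed = 1)
  multi <- which(mm$plan$n_attributes >= 2)
  # admissible equivalents: the generating family itself must be admitted
  # (p > alpha) for every multi-attribute item, and at least 70% of the
  # items must be assigned their generating family
  for (j in multi) {
    pj <- vapply(mm$wald[[j]], `[[`, numeric(1L), "p_value")
    names(pj) <- vapply(mm$wald[[j]], `[[`, character(1L), "family")
    expect_gt(pj[fams[j]], 0.05)
  }
  hits <- mean(mm$plan$family[multi] == fams[multi])
  expect_gte(hits, 0.7)
  # the mixed refit must not fit worse than saturated by AIC
  expect_lte(mm$indices$aic, mm$indices_saturated$aic)
})
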