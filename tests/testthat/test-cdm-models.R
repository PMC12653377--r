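test_that("the class space enumerates 2^K profiles with A1 as leading bit", {
  p7 <- attribute_profiles(7)
  expect_equal(nrow(p7), 128L)
  # "0000010" means only A6 mastered
  expect_equal(unname(p7["0000010", ]), c(0L, 0L, 0L, 0L, 0L, 1L, 0L))
  # index equals binary encoding + 1, and string order equals index order
  for (i in c(1L, 2L, 64L, 128L))
    expect_equal(profile_index(p7[i, ]), i)
  expect_identical(rownames(p7), sort(rownames(p7)))
  expect_equal(profile_from_string("0000010"), p7["0000010", , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(state_level(c("0000000", "1111111", "0100011")), c(0L, 7L, 3L))
})

test_that("reduce_profile restricts to required attributes in order", {
  prof <- as.integer(strsplit("0110011", "")[[1]])
  it <- item_gdina_probs(rep(0.5, 16), req = c(2L, 3L, 6L, 7L))
  expect_equal(unname(reduce_profile(prof, it)), c(1L, 1L, 1L, 1L))
  expect_equal(unname(reduce_profile(rep(0L, 7), it)), rep(0L, 4L))
})

test_that("DINA and DINO response functions follow their closed forms", {
  it <- item_dina(g = 0.2, s = 0.1, req = c(1L, 2L))
  expect_equal(irf(it, c(1, 1, 0)), 0.9)
  for (p in list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 1)))
    expect_equal(irf(it, p), 0.2)
  io <- item_dino(g = 0.2, s = 0.1, req = c(1L, 2L))
  expect_equal(irf(io, c(0, 0, 0)), 0.2)
  expect_equal(irf(io, c(1, 0, 0)), 0.9)
  expect_equal(irf(io, c(1, 1, 0)), 0.9)
})

test_that("saturated G-DINA with top-order delta only reproduces DINA", {
  dina <- item_dina(g = 0.2, s = 0.1, req = c(1L, 2L))
  gd <- item_gdina(delta = c(0.2, 0, 0, 0.7), req = c(1L, 2L))
  A <- attribute_profiles(2)
  for (l in seq_len(4)) {
    prof <- c(A[l, ], 0)
    expect_equal(irf(gd, prof), irf(dina, prof))
  }
})

test_that("G-DINA with zero interactions equals ACDM on every profile", {
  for (Kstar in 2:4) {
    req <- seq_len(Kstar)
    intercept <- 0.15
    main <- seq(0.05, 0.15, length.out = Kstar)
    delta <- c(intercept, main, rep(0, 2^Kstar - Kstar - 1L))
    gd <- item_gdina(delta, req)
    ac <- item_acdm(intercept, main, req)
    A <- attribute_profiles(Kstar)
    for (l in seq_len(2^Kstar))
      expect_equal(irf(gd, A[l, ]), irf(ac, A[l, ]))
  }
})

test_that("the RRUM surface multiplies penalty factors for missing skills", {
  it <- item_rrum(pistar = 0.8, r = c(0.5, 0.9), req = c(1L, 2L))
  expect_equal(irf(it, c(1, 0)), 0.8 * 0.5^0 * 0.9^1)  # = 0.72
  expect_equal(irf(it, c(0, 1)), 0.8 * 0.5^1 * 0.9^0)
  expect_equal(irf(it, c(1, 1)), 0.8)
})

test_that("LLM and RRUM are monotone in mastery for nonnegative effects", {
  ll <- item_llm(-1.5, c(0.8, 1.2, 0.5), req = 1:3)
  ru <- item_rrum(0.9, c(0.4, 0.7, 0.85), req = 1:3)  # r <= 1
  A <- attribute_profiles(3)
  for (it in list(ll, ru)) {
    p <- irf(it, A)
    for (l in seq_len(8)) for (k in 1:3) {
      if (A[l, k] == 0) {
        up <- A[l, ]; up[k] <- 1L
        expect_gte(irf(it, up), p[l])
      }
    }
  }
})

test_that("response functions ignore non-required attributes", {
  set.seed(11)
  it <- item_llm(-1, c(1, 0.5), req = c(2L, 4L))
  for (rep in 1:20) {
    prof <- rbinom(5, 1, 0.5)
    flipped <- prof
    flipped[c(1, 3, 5)] <- 1 - flipped[c(1, 3, 5)]
    expect_equal(irf(it, flipped), irf(it, prof))
  }
})

test_that("invalid item parameters are rejected", {
  expect_error(item_acdm(0.5, c(0.4, 0.4), req = c(1L, 2L)), "outside")
  expect_error(item_gdina(c(0.2, 0.7), req = c(1L, 2L)), "delta")
  expect_error(item_dina(0.6, 0.6, req = 1L))
})

test_that("response-vector log-likelihood matches the direct product", {
  it <- item_dina(0.2, 0.1, req = 1L)
  expect_equal(response_vector_loglik(1, 1, list(it)), log(0.9))
  set.seed(21)
  items <- list(item_dina(0.1, 0.1, 1L), item_dino(0.2, 0.05, c(1L, 2L)),
                item_acdm(0.2, c(0.3, 0.3), c(2L, 3L)),
                item_llm(-1, c(2, 1), c(1L, 3L)), item_rrum(0.9, c(0.4, 0.6), c(2L, 3L)))
  for (rep in 1:10) {
    prof <- rbinom(3, 1, 0.5)
    x <- rbinom(5, 1, 0.5)
    probs <- vapply(items, function(it) irf(it, prof), numeric(1L))
    expect_equal(response_vector_loglik(x, prof, items), bf_loglik(x, probs),
                 tolerance = 1e-12)
  }
  # flat probabilities: J log(1/2) regardless of the responses
  half <- lapply(1:4, function(j) item_gdina_probs(c(0.5, 0.5), req = 1L))
  expect_equal(response_vector_loglik(c(1, 0, 1, 0), c(1), half), 4 * log(0.5))
})
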