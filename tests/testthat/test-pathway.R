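# knowledge-state tabulation, stratification, retention, lattice, dominant path

test_that("state tabulation matches a brute-force group-by", {
  cls <- fake_classification(c("0000000", "0000000", "1111111"))
  tab <- tabulate_states(cls)
  expect_equal(tab$state, c("0000000", "1111111"))
  expect_equal(tab$count, c(2L, 1L))
  expect_equal(attr(tab, "total_n"), 3L)
  one <- tabulate_states(fake_classification("0100011"))
  expect_equal(one$count, 1L)
  set.seed(44)
  states <- profile_string(attribute_profiles(3)[sample(8, 200, TRUE), ])
  tab2 <- tabulate_states(fake_classification(states))
  ref <- table(states)
  expect_equal(tab2$count[match(names(ref), tab2$state)], unname(as.integer(ref)))
  expect_error(tabulate_states(character(0)), "no classified")
})

test_that("stratification by mastery count gives levels 0..K", {
  expect_equal(unname(stratify("0000000")), 0L)
  expect_equal(unname(stratify("1111111")), 7L)
  expect_equal(unname(stratify("0100011")), 3L)
  all7 <- stratify(rownames(attribute_profiles(7)))
  expect_equal(sort(unique(all7)), 0:7)   # eight levels for K = 7
})

test_that("top-state retention reproduces the published coverage arithmetic", {
  # 79 observed states with the cohort's head counts: the 17 dominant
  # states hold 351,332 of 361,967 examinees; 62 rare states hold 10,635
  cc <- reading_cohort_counts()
  p7 <- rownames(attribute_profiles(7))
  top_counts <- c(cc$retained_n - 16 * 12000, rep(12000, 16))
  rare_counts <- c(cc$excluded_n - 61 * 170, rep(170, 61))
  tab <- fake_state_table(p7[1:79], c(top_counts, rare_counts),
                          total_n = cc$total_n)
  top <- top_states(tab, 17)
  expect_equal(top$n_retained, cc$retained_n)
  expect_equal(top$n_excluded, cc$excluded_n)
  expect_equal(nrow(top$excluded), cc$states_rare)
  expect_equal(round(100 * top$coverage, 2), 97.06)
  # k covering everything
  all_top <- top_states(tab, 100)
  expect_equal(all_top$coverage, 1)
  # coverage is nondecreasing in k
  covs <- vapply(c(1, 5, 17, 40, 79), function(k) top_states(tab, k)$coverage,
                 numeric(1L))
  expect_true(all(diff(covs) >= 0))
})

test_that("rank-boundary ties retain the lower-index state", {
  tab <- fake_state_table(c("00", "01", "10", "11"), c(5L, 3L, 3L, 1L))
  top <- top_states(tab, 2)
  expect_true(top$ties)
  expect_equal(sort(top$retained$state), c("00", "01"))
})

test_that("the transition graph holds all and only first-order subset edges", {
  tab <- fake_state_table(c("0110011", "0110111"), c(10L, 5L))
  g <- build_graph(tab)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$from, "0110011")
  expect_equal(g$edges$to, "0110111")
  # disjoint level-1 states are parallel branches, no edge
  g2 <- build_graph(fake_state_table(c("1000000", "0000010"), c(3L, 4L)))
  expect_equal(nrow(g2$edges), 0L)
  # K = 4 complete lattice: 32 edges, identical to the brute-force oracle
  p4 <- rownames(attribute_profiles(4))
  g4 <- build_graph(fake_state_table(p4, rep(1L, 16)))
  expect_equal(nrow(g4$edges), 32L)
  oracle <- bf_subset_edges(p4)
  expect_equal(g4$edges[order(g4$edges$from, g4$edges$to), ],
               oracle[order(oracle$from, oracle$to), ], ignore_attr = TRUE)
  # random retained subsets match the oracle too; edges stay irreflexive,
  # antisymmetric, and between adjacent levels
  for (seed in 1:6) {
    set.seed(seed)
    sub <- sample(p4, 9)
    gs <- build_graph(fake_state_table(sub, rep(1L, 9)))
    os <- bf_subset_edges(sub)
    expect_equal(nrow(gs$edges), nrow(os))
    if (nrow(gs$edges) > 0) {
      expect_true(all(gs$edges$from != gs$edges$to))
      lv <- state_level(gs$edges$to) - state_level(gs$edges$from)
      expect_true(all(lv == 1L))
    }
  }
})

test_that("the dominant path reproduces the published nested trajectory", {
  chain <- reading_dominant_path()
  # nested-frequency cohort: counts decay along the acquisition order,
  # with off-path states kept strictly rarer
  off <- c("1000000", "0000011", "0101011", "0101111", "1101111")
  tab <- fake_state_table(c(chain, off),
                          c(900L, 800L, 700L, 600L, 500L, 400L, 300L, 200L,
                            90L, 80L, 70L, 60L, 50L))
  g <- build_graph(tab)
  dp <- dominant_path(g)
  expect_equal(as.character(dp), chain)
  expect_equal(attr(dp, "total_count"), sum(c(900, 800, 700, 600, 500, 400, 300, 200)))
})

test_that("a single chain is returned as-is and missing terminals error", {
  chain_tab <- fake_state_table(c("00", "01", "11"), c(4L, 2L, 1L))
  g <- build_graph(chain_tab)
  expect_equal(as.character(dominant_path(g)), c("00", "01", "11"))
  no_src <- build_graph(fake_state_table(c("01", "11"), c(2L, 1L)))
  expect_error(dominant_path(no_src), "terminal")
  gap <- build_graph(fake_state_table(c("0000", "0001", "1111"), c(3L, 2L, 1L)))
  expect_error(dominant_path(gap), "reachable levels")
})

test_that("the dynamic program equals exhaustive path enumeration at K = 4", {
  p4 <- rownames(attribute_profiles(4))
  for (seed in 1:8) {
    set.seed(seed)
    sub <- union(c("0000", "1111"), sample(p4, 10))
    counts <- sample(1:50, length(sub), replace = TRUE)
    tab <- fake_state_table(sub, counts)
    g <- build_graph(tab)
    oracle <- bf_best_path(g$nodes, g$edges, 4)
    if (is.finite(oracle$total)) {
      dp <- dominant_path(g)
      expect_equal(attr(dp, "total_count"), oracle$total)
      expect_equal(as.character(dp), oracle$path)
    } else {
      expect_error(dominant_path(g), "reachable levels")
    }
  }
})

test_that("alternative path criteria are available and sane", {
  tab <- fake_state_table(c("00", "01", "10", "11"), c(10L, 9L, 2L, 1L))
  g <- build_graph(tab)
  expect_equal(as.character(dominant_path(g, "sum")), c("00", "01", "11"))
  expect_equal(as.character(dominant_path(g, "bottleneck")), c("00", "01", "11"))
  expect_equal(as.character(dominant_path(g, "greedy")), c("00", "01", "11"))
})

test_that("graph exports write valid JSON and DOT", {
  tab <- fake_state_table(c("00", "01", "11"), c(4L, 2L, 1L))
  g <- build_graph(tab)
  j <- tempfile(fileext = ".json"); d <- tempfile(fileext = ".dot")
  pathway_to_json(g, j)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$nodes$state, c("00", "01", "11"))
  pathway_to_dot(g, d, dominant = dominant_path(g))
  txt <- readLines(d)
  expect_true(any(grepl("->", txt, fixed = TRUE)))
  expect_true(any(grepl("color=red", txt, fixed = TRUE)))
})
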