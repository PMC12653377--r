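# Brute-force oracles and small fixture builders, independent of the
# implementation paths they check.

# direct per-column tally
bf_column_counts <- function(m) {
  vapply(seq_len(ncol(m)), function(k) sum(m[, k]), numeric(1L))
}

# direct Bernoulli product log-likelihood over items
bf_loglik <- function(responses, probs, eps = 1e-10) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  log(prod(ifelse(responses == 1, p, 1 - p)))
}

# marginal mixture log-likelihood of a response matrix at given params
bf_mixture_loglik <- function(X, prob_matrix, pi_c, eps = 1e-10) {
  P <- pmin(pmax(prob_matrix, eps), 1 - eps)     # J x C
  total <- 0
  for (i in seq_len(nrow(X))) {
    lic <- vapply(seq_along(pi_c), function(c)
      pi_c[c] * prod(ifelse(X[i, ] == 1, P[, c], 1 - P[, c])), numeric(1L))
    total <- total + log(sum(lic))
  }
  total
}

# all first-order subset pairs among a set of state strings
bf_subset_edges <- function(states) {
  bits <- cdmpath::profile_from_string(states)
  from <- character(0); to <- character(0)
  for (i in seq_along(states)) for (j in seq_along(states)) {
    d <- bits[j, ] - bits[i, ]
    if (all(d >= 0) && sum(d) == 1) {
      from <- c(from, states[i]); to <- c(to, states[j])
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# enumerate every source-to-sink path and return the best total count
bf_best_path <- function(nodes, edges, K) {
  src <- strrep("0", K); snk <- strrep("1", K)
  count <- stats::setNames(nodes$count, nodes$state)
  succ <- split(edges$to, edges$from)
  best <- list(total = -Inf, path = NULL)
  walk <- function(path, total) {
    cur <- path[length(path)]
    if (cur == snk) {
      if (total > best$total ||
          (total == best$total &&
           paste(path, collapse = "|") < paste(best$path, collapse = "|")))
        best <<- list(total = total, path = path)
      return(invisible())
    }
    for (nxt in succ[[cur]]) walk(c(path, nxt), total + count[[nxt]])
  }
  if (!is.null(succ[[src]]) || src == snk) walk(src, count[[src]])
  best
}

# minimal hand-built classification object
fake_classification <- function(states, theta = NULL) {
  K <- nchar(states[1L])
  structure(list(map_state = states,
                 map_index = cdmpath::profile_index(
                   cdmpath::profile_from_string(states)),
                 K = K),
            class = "cdm_classification")
}

# a state_table from explicit states and counts
fake_state_table <- function(states, counts, total_n = sum(counts)) {
  df <- data.frame(state = states,
                   level = cdmpath::state_level(states),
                   count = as.integer(counts),
                   stringsAsFactors = FALSE)
  ord <- order(cdmpath::profile_index(cdmpath::profile_from_string(states)))
  df <- df[ord, ]; rownames(df) <- NULL
  structure(df, class = c("state_table", "data.frame"), total_n = total_n)
}

# a hand-built cdm_fit over K attributes from a list of items and class
# proportions (used to probe classify() against brute-force Bayes tables)
fake_fit <- function(items, pi_c, q) {
  K <- ncol(q)
  profiles <- cdmpath::attribute_profiles(K)
  P <- t(vapply(items, function(it) cdmpath::irf(it, profiles),
                numeric(nrow(profiles))))
  P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
  structure(list(items = items, pi = pi_c / sum(pi_c), prob_matrix = P,
                 profiles = profiles, K = K, q = q, n_obs = NA_integer_,
                 families = vapply(items, `[[`, character(1L), "family")),
            class = "cdm_fit")
}

# random binary Q-matrix with no all-zero rows
random_qmatrix <- function(J, K, seed) {
  set.seed(seed)
  ent <- matrix(0L, J, K)
  for (j in seq_len(J)) ent[j, sample.int(K, sample.int(min(3L, K), 1L))] <- 1L
  cdmpath::qmatrix(ent)
}
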