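# First-order learning-pathway network over observed knowledge states.
#
# States are stratified by the number of mastered attributes (Level 0 to
# Level K). A directed edge joins state s to state t when s is a subset
# of t and they differ by exactly one attribute — a first-order
# transition, the acquisition of a single new attribute. The dominant
# learning path is the source-to-sink chain through this layered DAG
# carrying the greatest student frequency.

#' Tabulate MAP knowledge states
#'
#' @param classification a `cdm_classification` (or a character vector of
#'   state strings).
#' @return an object of class `state_table`: data frame with `state`,
#'   `level`, `count`, sorted by class-space index, plus attribute
#'   `total_n`.
#' @export
tabulate_states <- function(classification) {
  states <- if (inherits(classification, "cdm_classification"))
    classification$map_state else as.character(classification)
  if (length(states) == 0L) stop("no classified examinees")
  tab <- table(states)
  df <- data.frame(state = names(tab),
                   level = state_level(names(tab)),
                   count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(profile_index(profile_from_string(df$state))), ]
  rownames(df) <- NULL
  structure(df, class = c("state_table", "data.frame"),
            total_n = length(states))
}

#' Stratify states by mastery level
#'
#' Level = number of mastered attributes; with K attributes the strata
#' are exactly levels `0..K` (eight levels for K = 7).
#'
#' @param states character vector of state strings.
#' @return named integer vector of levels.
#' @export
stratify <- function(states) {
  lv <- state_level(states)
  names(lv) <- states
  lv
}

#' Retain the most frequent knowledge states
#'
#' Keeps the `k` highest-count states; ties at the rank boundary are
#' broken toward the lower class-space index (equivalently, the
#' lexicographically smaller state string) and reported in `ties`.
#' Coverage is the fraction of all examinees whose MAP state is retained.
#'
#' @param table a `state_table`.
#' @param k number of states to retain (default 17). If `k` exceeds the
#'   number of observed states, all are retained.
#' @return list with `retained` (a `state_table`), `excluded` (ditto),
#'   `coverage` in `[0, 1]`, `n_retained`, `n_excluded`, and `ties`
#'   (TRUE when the rank boundary was tied).
#' @export
top_states <- function(table, k = 17L) {
  stopifnot(inherits(table, "state_table"), k >= 1L)
  total_n <- attr(table, "total_n")
  k <- min(k, nrow(table))
  ord <- order(-table$count, profile_index(profile_from_string(table$state)))
  keep_rows <- sort(ord[seq_len(k)])
  tied <- k < nrow(table) && table$count[ord[k]] == table$count[ord[k + 1L]]
  retained <- table[keep_rows, , drop = FALSE]
  excluded <- table[setdiff(seq_len(nrow(table)), keep_rows), , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  attr(retained, "total_n") <- attr(excluded, "total_n") <- total_n
  class(retained) <- class(excluded) <- c("state_table", "data.frame")
  list(retained = retained, excluded = excluded,
       coverage = sum(retained$count) / total_n,
       n_retained = sum(retained$count), n_excluded = sum(excluded$count),
       ties = tied)
}

#' Build the first-order transition graph over retained states
#'
#' @param retained a `state_table` (e.g. `top_states(...)$retained`).
#' @return an object of class `pathway_graph`: list with `nodes` (state,
#'   level, count), `edges` (data frame `from`, `to`), and `K`.
#' @export
build_graph <- function(retained) {
  stopifnot(inherits(retained, "state_table"))
  bits <- profile_from_string(retained$state)
  K <- ncol(bits)
  n <- nrow(bits)
  from <- character(0); to <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (retained$level[j] == retained$level[i] + 1L &&
          all(bits[i, ] <= bits[j, ])) {
        from <- c(from, retained$state[i])
        to <- c(to, retained$state[j])
      }
    }
  }
  structure(list(nodes = data.frame(state = retained$state,
                                    level = retained$level,
                                    count = retained$count,
                                    stringsAsFactors = FALSE),
                 edges = data.frame(from = from, to = to,
                                    stringsAsFactors = FALSE),
                 K = K),
            class = "pathway_graph")
}

#' Extract the dominant learning path
#'
#' Finds the path from the all-zero state to the all-one state through
#' the first-order transition graph that carries the greatest student
#' frequency. The default criterion maximizes the *sum* of node counts
#' along the path (dynamic program over the level-layered DAG); the
#' bottleneck criterion maximizes the minimum node count, and the greedy
#' criterion repeatedly steps to the highest-count successor. Ties are
#' broken lexicographically by state string.
#'
#' @param graph a `pathway_graph` containing the all-zero and all-one
#'   states.
#' @param method `"sum"` (default), `"bottleneck"`, or `"greedy"`.
#' @return character vector of state strings from source to sink, with
#'   attribute `total_count` (sum of node counts along the path).
#' @export
dominant_path <- function(graph, method = c("sum", "bottleneck", "greedy")) {
  method <- match.arg(method)
  nodes <- graph$nodes
  K <- graph$K
  src <- strrep("0", K); snk <- strrep("1", K)
  missing <- setdiff(c(src, snk), nodes$state)
  if (length(missing) > 0L)
    stop("graph lacks required terminal state(s): ", paste(missing, collapse = ", "))
  preds <- split(graph$edges$from, graph$edges$to)
  count <- stats::setNames(nodes$count, nodes$state)

  if (method == "greedy") {
    succs <- split(graph$edges$to, graph$edges$from)
    path <- src; cur <- src
    while (cur != snk) {
      nxt <- succs[[cur]]
      if (is.null(nxt)) stop("no path from ", cur, " to the full-mastery state")
      nxt <- nxt[order(-count[nxt], nxt)][1L]
      path <- c(path, nxt); cur <- nxt
    }
    attr(path, "total_count") <- sum(count[path])
    return(path)
  }

  # DP over levels; best[s] = best criterion value of a src->s path
  ord <- nodes$state[order(nodes$level, nodes$state)]
  best <- stats::setNames(rep(-Inf, length(ord)), ord)
  back <- stats::setNames(rep(NA_character_, length(ord)), ord)
  best[src] <- count[src]
  combine <- if (method == "sum") function(b, cnt) b + cnt
             else function(b, cnt) pmin(b, cnt)
  for (s in ord) {
    if (s == src) next
    ps <- preds[[s]]
    if (is.null(ps)) next
    vals <- combine(best[ps], count[s])
    if (all(!is.finite(vals))) next
    pick <- ps[order(-vals, ps)][1L]
    best[s] <- combine(best[pick], count[s])
    back[s] <- pick
  }
  if (!is.finite(best[snk])) {
    reach_levels <- sort(unique(nodes$level[is.finite(best[nodes$state])]))
    stop("no source-to-sink path; reachable levels: ",
         paste(reach_levels, collapse = ", "),
         " of 0..", K)
  }
  path <- snk
  while (path[1L] != src) path <- c(back[[path[1L]]], path)
  attr(path, "total_count") <- sum(count[path])
  path
}

#' Export a pathway graph
#'
#' `pathway_to_json()` writes nodes and edges as JSON;
#' `pathway_to_dot()` renders Graphviz DOT with states stratified by
#' level and the dominant path (if supplied) highlighted.
#'
#' @param graph a `pathway_graph`.
#' @param path output file path.
#' @param dominant optional state-string vector from [dominant_path()].
#' @return the path, invisibly.
#' @export
pathway_to_json <- function(graph, path) {
  jsonlite::write_json(list(nodes = graph$nodes, edges = graph$edges, K = graph$K),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pathway_to_json
#' @export
pathway_to_dot <- function(graph, path, dominant = NULL) {
  on_path <- function(a, b) {
    if (is.null(dominant)) return(FALSE)
    i <- match(a, dominant)
    !is.na(i) && i < length(dominant) && dominant[i + 1L] == b
  }
  lines <- c("digraph pathway {", "  rankdir=BT;")
  for (lv in sort(unique(graph$nodes$level)))
    lines <- c(lines, paste0("  { rank=same; ",
      paste(sprintf('"%s"', graph$nodes$state[graph$nodes$level == lv]),
            collapse = "; "), "; }"))
  lines <- c(lines, sprintf('  "%s" [label="%s\\n(n=%d)"%s];',
                            graph$nodes$state, graph$nodes$state, graph$nodes$count,
                            ifelse(graph$nodes$state %in% dominant,
                                   " color=red", "")))
  if (nrow(graph$edges) > 0L)
    lines <- c(lines, sprintf('  "%s" -> "%s"%s;', graph$edges$from, graph$edges$to,
                              ifelse(mapply(on_path, graph$edges$from, graph$edges$to),
                                     " [color=red penwidth=2]", "")))
  writeLines(c(lines, "}"), path)
  invisible(path)
}
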