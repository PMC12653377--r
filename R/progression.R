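# Tiered learning progression: rare knowledge states are absorbed into
# the dominant-state clusters, each cluster is located on the 2PL ability
# scale by its members' mean EAP theta, and clusters are stratified into
# tiers.

#' Absorb rare states into dominant-state clusters
#'
#' Single-pass nearest-centroid assignment: every rare state is mapped to
#' the closest dominant (retained) state by squared Euclidean distance on
#' the 0/1 mastery vectors, which on binary vectors equals Hamming
#' distance. The centers are fixed — the dominant states themselves never
#' move and each maps to itself. Distance ties are broken toward the
#' center with the larger examinee count, then lexicographically by
#' state string.
#'
#' @param rare a `state_table` (or data frame with `state`, `count`) of
#'   excluded states; may have zero rows.
#' @param centers a `state_table` of retained dominant states.
#' @return data frame `state`, `center`, `distance` covering both rare
#'   states (nearest center) and centers (themselves, distance 0).
#' @export
assign_rare_states <- function(rare, centers) {
  stopifnot(nrow(centers) >= 1L)
  cb <- profile_from_string(centers$state)
  map <- data.frame(state = centers$state, center = centers$state,
                    distance = 0L, stringsAsFactors = FALSE)
  if (nrow(rare) > 0L) {
    rb <- profile_from_string(rare$state)
    # Hamming distances: |r| + |c| - 2 r.c
    D <- outer(rowSums(rb), rowSums(cb), `+`) - 2 * (rb %*% t(cb))
    pick <- apply(D, 1L, function(d) {
      cand <- which(d == min(d))
      cand[order(-centers$count[cand], centers$state[cand])][1L]
    })
    map <- rbind(map,
                 data.frame(state = rare$state, center = centers$state[pick],
                            distance = as.integer(D[cbind(seq_len(nrow(rare)), pick)]),
                            stringsAsFactors = FALSE))
  }
  rownames(map) <- NULL
  map
}

#' Locate each cluster on the ability scale
#'
#' Averages per-examinee EAP abilities within each cluster (a dominant
#' state plus the rare states absorbed into it) to represent the ability
#' level associated with that knowledge state.
#'
#' @param classification a `cdm_classification`.
#' @param mapping state-to-center mapping from [assign_rare_states()].
#' @param theta numeric vector of abilities, one per examinee (e.g.
#'   `fit_2pl(data)$theta`).
#' @return data frame `state` (cluster center), `level`, `n`,
#'   `mean_theta`, sorted by `mean_theta`. Centers with no examinees are
#'   excluded with a warning.
#' @export
state_ability_table <- function(classification, mapping, theta) {
  stopifnot(inherits(classification, "cdm_classification"),
            length(theta) == length(classification$map_state))
  center <- mapping$center[match(classification$map_state, mapping$state)]
  if (anyNA(center))
    stop("mapping does not cover state(s): ",
         paste(unique(classification$map_state[is.na(center)]), collapse = ", "))
  n <- tapply(theta, center, length)
  mt <- tapply(theta, center, mean)
  empty <- setdiff(unique(mapping$center), names(mt))
  if (length(empty) > 0L)
    warning("cluster(s) with no examinees excluded: ",
            paste(empty, collapse = ", "))
  out <- data.frame(state = names(mt),
                    level = state_level(names(mt)),
                    n = as.integer(n),
                    mean_theta = as.numeric(mt),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_theta), ]
  rownames(out) <- NULL
  out
}

#' Stratify clusters into progression tiers
#'
#' Assigns each cluster a tier on the ability scale, either by explicit
#' theta boundaries (a strictly increasing vector of length `T - 1`,
#' e.g. the cut scores separating curriculum proficiency levels) or by
#' equal-count tiers, whose boundaries are chosen so each tier holds as
#' close as possible to an equal share of examinees.
#'
#' @param table output of [state_ability_table()].
#' @param boundaries optional strictly increasing numeric cut points.
#' @param tiers number of tiers when `boundaries` is `NULL` (default 3).
#' @return the table with a `tier` column (1 = lowest ability), plus
#'   attribute `boundaries`.
#' @export
set_levels <- function(table, boundaries = NULL, tiers = 3L) {
  stopifnot(nrow(table) >= 1L)
  if (!is.null(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE))
      stop("tier boundaries must be strictly increasing")
  } else {
    stopifnot(tiers >= 1L)
    if (tiers == 1L) {
      boundaries <- numeric(0)
    } else {
      # equal-count: cut at examinee-weighted theta quantiles
      ord <- order(table$mean_theta)
      cum <- cumsum(table$n[ord]) / sum(table$n)
      qs <- seq_len(tiers - 1L) / tiers
      cuts <- vapply(qs, function(q) {
        i <- which(cum >= q)[1L]
        if (i >= length(ord)) i <- length(ord) - 1L
        mean(table$mean_theta[ord[c(i, i + 1L)]])
      }, numeric(1L))
      boundaries <- unique(cuts)
    }
  }
  table$tier <- findInterval(table$mean_theta, boundaries) + 1L
  attr(table, "boundaries") <- boundaries
  table
}
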