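#' Enumerate the latent class space of attribute profiles
#'
#' With K binary attributes there are `2^K` possible knowledge states
#' (attribute profiles). The enumeration order is fixed throughout the
#' package: profile `i` (1-based) is the binary expansion of `i - 1` with
#' attribute 1 as the *most significant* bit. Hence the rendered string
#' reads left to right as A1, A2, ..., AK (so with K = 7, `"0000010"`
#' means only A6 is mastered), and lexicographic order of the strings
#' coincides with index order.
#'
#' @param K number of attributes (1 <= K <= 20).
#' @return An integer matrix with `2^K` rows and `K` columns; row `i` is
#'   the profile with index `i`. Row names are the rendered state strings.
#' @examples
#' attribute_profiles(2)  # 00, 01, 10, 11
#' @export
attribute_profiles <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 1, K <= 20)
  K <- as.integer(K)
  C <- 2L^K
  m <- matrix(0L, C, K)
  for (k in seq_len(K)) {
    # attribute k contributes bit 2^(K-k)
    m[, k] <- as.integer(bitwAnd(seq_len(C) - 1L, 2L^(K - k)) > 0L)
  }
  rownames(m) <- apply(m, 1L, paste0, collapse = "")
  m
}

#' Render a profile as a state string
#'
#' @param bits 0/1 vector (A1 first) or a matrix with one profile per row.
#' @return character vector of 0/1 strings, leftmost character = A1.
#' @export
profile_string <- function(bits) {
  if (is.matrix(bits)) return(apply(bits, 1L, paste0, collapse = ""))
  paste0(as.integer(bits), collapse = "")
}

#' Parse state strings back into profile rows
#'
#' @param s character vector of 0/1 strings of a common length.
#' @return integer matrix, one profile per row (A1 first).
#' @export
profile_from_string <- function(s) {
  stopifnot(is.character(s), length(s) >= 1L)
  K <- unique(nchar(s))
  if (length(K) != 1L) stop("state strings must have a common length")
  bits <- matrix(as.integer(unlist(strsplit(s, ""), use.names = FALSE)),
                 nrow = length(s), ncol = K, byrow = TRUE)
  if (any(bits != 0L & bits != 1L)) stop("state strings must be binary")
  rownames(bits) <- s
  bits
}

#' Index of a profile in the class-space enumeration
#'
#' Inverse of the `attribute_profiles()` ordering: the 1-based index is
#' the profile's binary encoding (A1 most significant) plus one.
#'
#' @param bits 0/1 vector or matrix of profiles (rows).
#' @return integer index / indices into `attribute_profiles(K)`.
#' @export
profile_index <- function(bits) {
  if (!is.matrix(bits)) bits <- matrix(bits, nrow = 1L)
  K <- ncol(bits)
  as.integer(bits %*% 2L^((K - 1L):0L)) + 1L
}

#' Mastery level of a state (number of mastered attributes)
#'
#' Stratifies knowledge states by the count of mastered attributes: the
#' empty state is Level 0, full mastery is Level K, giving K + 1 strata
#' (eight levels 0-7 for a 7-attribute assessment).
#'
#' @param state state string(s) or a 0/1 profile matrix.
#' @return integer vector of levels.
#' @export
state_level <- function(state) {
  if (is.character(state)) state <- profile_from_string(state)
  if (!is.matrix(state)) state <- matrix(state, nrow = 1L)
  as.integer(rowSums(state))
}
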