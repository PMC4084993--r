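#' Anagenetic DEC rate matrix for one epoch
#'
#' Builds the CTMC generator over ranges for epoch `k`.  Range expansion
#' `S -> S + {j}` (for `j` outside `S`, adjacent to at least one area of
#' `S`, and yielding a valid state) occurs at rate
#' `sum_{i in S} d * m_ij * A_ij`; range contraction `S -> S - {i}`
#' occurs at rate `e` per occupied area (when the reduced set is a valid
#' state); the empty range is absorbing.
#'
#' @param space A [build_state_space()] object.
#' @param params A [dec_params()] object.
#' @param epoch Epoch index (1 = oldest).
#' @return Square rate matrix `Q` (n_states x n_states), rows summing to
#'   zero, with state labels as dimnames.
#' @examples
#' sp <- build_state_space(c("A", "B"), 2)
#' Q <- build_rate_matrix(sp, dec_params(0.1, 0.05, n_areas = 2))
#' Q["A", "A+B"]  # = d
#' @export
build_rate_matrix <- function(space, params, epoch = 1L) {
  m <- params$epochs$multipliers[[epoch]]
  n_areas <- length(space$areas)
  if (!all(dim(m) == n_areas)) {
    stop("multiplier matrix does not match the number of areas",
         call. = FALSE)
  }
  A <- space$adjacency
  ns <- space$n_states
  Q <- matrix(0, ns, ns, dimnames = list(space$labels, space$labels))
  # index lookup by canonical label of the integer set
  lookup <- stats::setNames(seq_len(ns), vapply(space$states, set_key,
                                                character(1)))
  for (si in seq_len(ns)) {
    S <- space$states[[si]]
    if (!length(S)) next  # empty range is absorbing
    # expansions
    for (j in seq_len(n_areas)) {
      if (j %in% S) next
      rate <- sum(params$d * m[S, j] * A[S, j])
      if (rate <= 0) next
      tgt <- lookup[set_key(sort(c(S, j)))]
      if (is.na(tgt)) next  # exceeds max size or disconnected
      Q[si, tgt] <- Q[si, tgt] + rate
    }
    # contractions
    for (i in S) {
      tgt <- lookup[set_key(setdiff(S, i))]
      if (is.na(tgt)) next
      Q[si, tgt] <- Q[si, tgt] + params$e
    }
    Q[si, si] <- -sum(Q[si, -si])
  }
  Q
}

#' Transition probability matrix of the DEC chain
#'
#' Computes `P = exp(Q t)` by eigendecomposition when the generator is
#' numerically safely diagonalisable, falling back to scaling-and-squaring
#' Pade approximation ([Matrix::expm()]) otherwise.  Tiny negative entries
#' from roundoff are clamped to zero and rows renormalised.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param t Elapsed time in Ma (>= 0).
#' @return Row-stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("elapsed time must be >= 0", call. = FALSE)
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  dec <- q_eigen(Q)
  P <- p_matrix(dec, t)
  dimnames(P) <- dimnames(Q)
  P
}

# cacheable eigendecomposition of Q; validated by reconstruction, with a
# NULL marker forcing the Pade path when Q is defective/ill-conditioned
q_eigen <- function(Q, tol = 1e-9) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- eg$vectors %*% diag(eg$values, nrow(Q)) %*% Vinv
      ok <- max(abs(Re(recon) - Q)) < tol && max(abs(Im(recon))) < tol
    }
  }
  if (ok) {
    list(method = "eigen", values = eg$values, V = eg$vectors, Vinv = Vinv,
         Q = Q)
  } else {
    list(method = "pade", Q = Q)
  }
}

p_matrix <- function(dec, t) {
  P <- if (dec$method == "eigen") {
    Re(dec$V %*% (exp(dec$values * t) * dec$Vinv))
  } else {
    as.matrix(Matrix::expm(dec$Q * t))
  }
  P[P < 0] <- 0
  P / rowSums(P)
}
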