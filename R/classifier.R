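# Position-wise linear classifier and probabilistic aggregation.

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Position-wise class predictions
#'
#' Applies one shared full-connection layer followed by a row softmax to
#' every position of the mixed feature matrix, yielding the positional
#' prediction matrix `C` whose row `j` is the class distribution given
#' position `j`.
#'
#' @param F_mixed `l x f` mixed feature matrix (see [mix_features()]).
#' @param params list with weight matrix `Wc` (`f x M`) and bias `bc`.
#' @return `l x M` matrix; every row sums to 1.
#' @export
positional_predictions <- function(F_mixed, params) {
  if (ncol(params$Wc) < 2) stop("number of classes M must be >= 2", call. = FALSE)
  row_softmax(affine(F_mixed, params$Wc, params$bc))
}

#' Aggregate positional predictions
#'
#' The final class distribution is the expectation of the positional
#' predictions under the positional attention margin:
#' `p_d = sum_j C_jd * v_j` (law of total probability over positions).
#'
#' @param C `l x M` positional prediction matrix.
#' @param v positional margin weights of length `l`, summing to 1.
#' @param tol tolerance on `sum(v) == 1`.
#' @return Numeric class-probability vector of length `M`.
#' @export
aggregate_predictions <- function(C, v, tol = 1e-6) {
  if (abs(sum(v) - 1) > tol)
    stop("positional margin v is not normalized", call. = FALSE)
  as.vector(crossprod(C, v))
}

init_classifier <- function(f, M) {
  lin <- init_linear(f, M)
  list(Wc = lin$W, bc = lin$b)
}

# Batched head: stacked mixed features (B*l) x f, margin v (B*l).
# Returns P: B x M class probabilities and cache.
head_forward <- function(Fm, v, B, l, params) {
  Z <- affine(Fm, params$Wc, params$bc)
  C <- row_softmax(Z)
  M <- ncol(C)
  P <- matrix(0, B, M)
  for (b in seq_len(B)) {
    block <- ((b - 1L) * l + 1L):(b * l)
    P[b, ] <- crossprod(C[block, , drop = FALSE], v[block])
  }
  list(P = P, C = C)
}

# Backward from dP (B x M). Returns dFm, dv, grads.
head_backward <- function(dP, cache, Fm, v, B, l, params) {
  C <- cache$C
  M <- ncol(C)
  dC <- matrix(0, nrow(C), M)
  dv <- numeric(nrow(C))
  for (b in seq_len(B)) {
    block <- ((b - 1L) * l + 1L):(b * l)
    dC[block, ] <- tcrossprod(v[block], dP[b, ])
    dv[block] <- C[block, , drop = FALSE] %*% dP[b, ]
  }
  dZ <- C * (dC - rowSums(dC * C))
  g <- list(Wc = crossprod(Fm, dZ), bc = colSums(dZ))
  dFm <- tcrossprod(dZ, params$Wc)
  list(dFm = dFm, dv = dv, grads = g)
}
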