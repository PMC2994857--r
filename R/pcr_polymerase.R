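## pcr_polymerase: the mechanistic null model. Mutagenic PCR is modelled as
## k cycles of error-prone strand synthesis by a Taq misincorporation
## operator T (4x4, column-stochastic: tau_ij = Pr(adduct i | template j)).
## A cycle acts on the sense/nonsense strand pair (s, n) as
##     Phi: (s, n) -> ( (s + T n)/2 , (n + T s)/2 ),
## i.e. half the molecules retain the old strand and half acquire a newly
## synthesised complement-copy. Iterating Phi from a pure wild-type base and
## its complement yields the per-nucleotide PCR mutation matrix P(T, k).
##
## T carries 16 entries but only 12 degrees of freedom (4 column-sum
## constraints). Internally T is parameterised as the column-softmax of 16
## log-parameters; adding a constant to one column's log-parameters leaves
## T unchanged, so the parameter space is the 12-dimensional quotient of
## R^16 by the four column-constraint directions. The Jeffreys prior is the
## root pseudo-determinant of the Fisher information on that quotient.

## fixed index helpers ------------------------------------------------------

## vec ordering is column-major: entry (i,j) <-> (j-1)*4 + i
COMP_IDX <- c(4L, 3L, 2L, 1L)              # complement row for columns A,C,G,T
REF_IDX  <- (0:3) * 4L + COMP_IDX          # counter-diagonal positions in vec T

## orthonormal basis of the 12-dim quotient space: per column, three
## orthonormal contrasts orthogonal to the constant vector
quotient_basis <- function() {
  h <- cbind(c(1, -1, 0, 0) / sqrt(2),
             c(1, 1, -2, 0) / sqrt(6),
             c(1, 1, 1, -3) / sqrt(12))
  B <- matrix(0, 16L, 12L)
  for (j in 0:3) B[j * 4L + (1:4), j * 3L + (1:3)] <- h
  B
}
.QBASIS <- quotient_basis()

#' Polymerase misincorporation matrix
#'
#' Validates a 4x4 column-stochastic Taq misincorporation operator:
#' `T[i, j]` is the probability that adduct nucleotide i is paired against
#' template nucleotide j during strand synthesis. For a realistic
#' mutagenic-PCR fit the counter-diagonal entries (A opposite T, C opposite
#' G, ...) are close to 1.
#'
#' @param T 4x4 non-negative matrix with columns summing to 1.
#' @return classed matrix `polymerase_matrix`.
#' @examples
#' polymerase_matrix(complement_fidelity())  # the error-free polymerase
#' @export
polymerase_matrix <- function(T) {
  T <- as.matrix(T)
  stopifnot(identical(dim(T), c(4L, 4L)), all(T >= 0))
  cs <- colSums(T)
  if (any(abs(cs - 1) > 1e-9)) stop("columns of T must sum to 1")
  T <- sweep(T, 2L, cs, "/")
  dimnames(T) <- list(NUC, NUC)
  structure(T, class = c("polymerase_matrix", "matrix"))
}

#' @rdname polymerase_matrix
#' @export
complement_fidelity <- function() complement_operator()

## softmax parameterisation -------------------------------------------------

## 16 log-parameters (vec layout) -> column-stochastic T
theta_to_T <- function(theta16) {
  M <- matrix(theta16, 4L, 4L)
  M <- sweep(M, 2L, apply(M, 2L, max))   # guard overflow
  E <- exp(M)
  sweep(E, 2L, colSums(E), "/")
}

## T -> gauge-fixed log-parameters (counter-diagonal entries pinned to 0)
T_to_theta12 <- function(T) {
  lt <- matrix(log(pmax(as.vector(unclass(T)), 1e-300)), 4L, 4L)
  for (j in 1:4) lt[, j] <- lt[, j] - lt[COMP_IDX[j], j]
  as.vector(lt)[-REF_IDX]
}

theta12_to_theta16 <- function(theta12) {
  th <- numeric(16L)
  th[-REF_IDX] <- theta12
  th
}

## PCR cycle and push-forward ----------------------------------------------

#' One cycle of mutagenic PCR on a strand pair
#'
#' Applies the single-cycle operator to a sense/nonsense strand pair of
#' probability four-vectors: after denaturation, half of each strand
#' population persists and half is replaced by an error-prone
#' template-copy, giving `( (s + T n)/2, (n + T s)/2 )`.
#'
#' @param sp list with elements `s` and `n`, non-negative four-vectors each
#'   summing to 1.
#' @param T a [polymerase_matrix()].
#' @return list with updated `s` and `n`, still on the simplex.
#' @examples
#' K <- complement_fidelity()
#' sp <- list(s = c(1, 0, 0, 0), n = c(0, 0, 0, 1))
#' identical(pcr_cycle(sp, K)$s, sp$s)  # perfect fidelity: fixed point
#' @export
pcr_cycle <- function(sp, T) {
  stopifnot(is.list(sp), length(sp$s) == 4L, length(sp$n) == 4L)
  T <- unclass(T)
  list(s = as.vector(sp$s + T %*% sp$n) / 2,
       n = as.vector(sp$n + T %*% sp$s) / 2)
}

#' PCR mutation matrix from a polymerase matrix
#'
#' Pushes each pure wild-type base (sense strand) paired with its
#' complement (nonsense strand) through `k` cycles of [pcr_cycle()] and
#' column-concatenates the resulting sense-strand distributions into the
#' 4x4 per-site mutation matrix \eqn{P(T, k)}. The iterative form is used
#' rather than the expanded binomial polynomial to avoid underflow and
#' truncation error at realistic cycle counts.
#'
#' @param T a [polymerase_matrix()].
#' @param k number of PCR cycles (non-negative integer; `k = 0` gives the
#'   identity).
#' @return a [mutation_matrix()] with `source = "pcr_model_map"`.
#' @export
pcr_mutation_matrix <- function(T, k) {
  stopifnot(k >= 0, k == round(k))
  P <- pcr_pushforward(unclass(T), k, deriv = 0L)$P
  mutation_matrix(P, source = "pcr_model_map")
}

## Forward propagation of P(T, k) and its first/second derivatives with
## respect to the raw entries of T (where T enters linearly, so d2T = 0).
## Returns P (4x4), G (16 x 16: dP_e / dtau_a) and H (16 x 256:
## d2 P_e / dtau_a dtau_b with ab = (b-1)*16 + a), in vec index layout.
pcr_pushforward <- function(T, k, deriv = 0L) {
  I4 <- diag(4)
  P <- matrix(0, 4L, 4L)
  G <- if (deriv >= 1L) matrix(0, 16L, 16L) else NULL
  H <- if (deriv >= 2L) matrix(0, 16L, 256L) else NULL
  a_row <- rep(1:4, times = 4)   # k(a)
  a_col <- rep(1:4, each = 4)    # l(a)
  for (l in 1:4) {
    s <- I4[, l]; n <- I4[, COMP_IDX[l]]
    DS <- DN <- if (deriv >= 1L) matrix(0, 4L, 16L) else NULL
    HS <- HN <- if (deriv >= 2L) matrix(0, 4L, 256L) else NULL
    for (cyc in seq_len(k)) {
      if (deriv >= 2L) {
        ## terms E_a DN[,b] + E_b DN[,a] (+ same with DS for nonsense strand)
        M1s <- matrix(0, 4L, 256L); M2s <- M1s
        M1n <- matrix(0, 4L, 256L); M2n <- M1n
        for (a in 1:16) {
          cols_a <- a + 16L * (0:15)          # (a, b) for all b
          M1s[a_row[a], cols_a] <- DN[a_col[a], ]
          M1n[a_row[a], cols_a] <- DS[a_col[a], ]
          cols_b <- (1:16) + 16L * (a - 1L)   # (b, a) pairs: a acting as b
          M2s[a_row[a], cols_b] <- DN[a_col[a], ]
          M2n[a_row[a], cols_b] <- DS[a_col[a], ]
        }
        HS_new <- (HS + M1s + M2s + T %*% HN) / 2
        HN_new <- (HN + M1n + M2n + T %*% HS) / 2
        HS <- HS_new; HN <- HN_new
      }
      if (deriv >= 1L) {
        DS_new <- (DS + kronecker(t(n), I4) + T %*% DN) / 2
        DN_new <- (DN + kronecker(t(s), I4) + T %*% DS) / 2
        DS <- DS_new; DN <- DN_new
      }
      sp <- list(s = as.vector(s + T %*% n) / 2,
                 n = as.vector(n + T %*% s) / 2)
      s <- sp$s; n <- sp$n
    }
    P[, l] <- s
    e <- (l - 1L) * 4L + (1:4)
    if (deriv >= 1L) G[e, ] <- DS
    if (deriv >= 2L) H[e, ] <- HS
  }
  list(P = P, G = G, H = H)
}

## softmax Jacobian A[c, a] = d tau_c / d theta_a (16x16, block-diagonal)
softmax_jacobian <- function(T) {
  A <- matrix(0, 16L, 16L)
  for (j in 1:4) {
    sg <- T[, j]
    A[(j - 1L) * 4L + (1:4), (j - 1L) * 4L + (1:4)] <-
      diag(sg) - tcrossprod(sg)
  }
  A
}

## Chain-rule a raw-tau gradient matrix (entries x 16) into log-parameter
## (softmax) coordinates.
chain_first <- function(G_raw, T) G_raw %*% softmax_jacobian(T)

## derivatives of P in log-parameter coordinates, first order only
pcr_gradient_theta <- function(T, k) {
  pf <- pcr_pushforward(T, k, deriv = 1L)
  list(P = pf$P, G = chain_first(pf$G, T))
}

## full second-order chain rule for one output entry e:
## Htilde_e = A' H_e A + sum_c G_raw[e, c] * S_c,
## with S_c the softmax Hessian of tau_c. Returns 16 x 256 matrix.
chain_second <- function(G_raw, H_raw, T) {
  A <- softmax_jacobian(T)
  ## softmax Hessians, grouped per column j: S[i; k, m] for k,m in column j
  S <- vector("list", 16L)
  for (j in 1:4) {
    sg <- T[, j]
    for (i in 1:4) {
      Sj <- matrix(0, 4L, 4L)
      for (kk in 1:4) for (m in 1:4) {
        Sj[kk, m] <- sg[i] * ((i == kk) - sg[kk]) * ((i == m) - sg[m]) -
          sg[i] * sg[kk] * ((kk == m) - sg[m])
      }
      S[[(j - 1L) * 4L + i]] <- Sj
    }
  }
  out <- matrix(0, 16L, 256L)
  for (e in 1:16) {
    He <- matrix(H_raw[e, ], 16L, 16L)    # [a, b]
    Ht <- t(A) %*% He %*% A
    ## the S-term only involves raw entries c in the same column as their
    ## theta block; embed each 4x4 S_c at its column block
    for (c in 1:16) {
      g <- G_raw[e, c]
      if (g != 0) {
        j <- (c - 1L) %/% 4L
        idx <- j * 4L + (1:4)
        Ht[idx, idx] <- Ht[idx, idx] + g * S[[c]]
      }
    }
    out[e, ] <- as.vector(Ht)
  }
  out
}

## likelihood ---------------------------------------------------------------

#' Multinomial log-likelihood of counts under the polymerase model
#'
#' Log-probability of a misincorporation count matrix given the mutation
#' matrix implied by polymerase matrix `T` after `k` PCR cycles: the
#' product of four independent multinomial likelihoods (one per wild-type
#' base), including the multinomial coefficients.
#'
#' @param C a [misincorporation_counts()] matrix.
#' @param T a [polymerase_matrix()] (or plain 4x4 column-stochastic matrix).
#' @param k number of PCR cycles.
#' @param P optional precomputed `P(T, k)` to avoid recomputation.
#' @return scalar log-likelihood; `-Inf` (with a warning) if some count is
#'   positive where the model probability is zero.
#' @export
counts_log_likelihood <- function(C, T, k, P = NULL) {
  Cm <- unclass(C)[1:4, 1:4]
  if (is.null(P)) P <- pcr_pushforward(unclass(T), k, deriv = 0L)$P
  P <- unclass(P)[1:4, 1:4]
  if (any(P == 0 & Cm > 0)) {
    warning("zero model probability where counts are positive; log-likelihood is -Inf")
    return(-Inf)
  }
  coef <- sum(lgamma(colSums(Cm) + 1)) - sum(lgamma(Cm + 1))
  ll <- Cm * log(P)
  ll[Cm == 0] <- 0
  coef + sum(ll)
}

## Fisher information -------------------------------------------------------

## fast outer-product form of the FIM in log-parameter coordinates;
## analytically identical to the full expected-Hessian expression because
## the second-derivative term sums to zero over each stochastic column.
fim_outer <- function(T, column_totals, k, grad = NULL) {
  if (is.null(grad)) grad <- pcr_gradient_theta(unclass(T), k)
  w <- rep(column_totals, each = 4L) / pmax(as.vector(grad$P), 1e-300)
  crossprod(grad$G * sqrt(w))
}

#' Fisher information of the polymerase model
#'
#' The 16x16 expected information matrix of the counts log-likelihood with
#' respect to the polymerase log-parameters, using the approximation that
#' the expected count in cell (i, j) is `column_totals[j] * p_ij` (the
#' wild-type base composition is taken as observed). Each entry is the
#' negative expectation of the corresponding second derivative of the
#' log-likelihood, computed from first and second derivatives of
#' \eqn{P(T,k)} propagated through the cycle recursion. The matrix is
#' symmetric and positive semidefinite with exactly four null directions,
#' one per column-sum constraint.
#'
#' @param T a [polymerase_matrix()].
#' @param column_totals observed counts of each wild-type base
#'   (length-4 vector, A C G T order).
#' @param k number of PCR cycles.
#' @return object of class `fisher_info`: list with `F` (16x16),
#'   `pseudo_log_det` (log-determinant of the projection of `F` onto the
#'   12-dim quotient space) and `gc_weights` (= `column_totals`).
#' @export
fisher_information <- function(T, column_totals, k) {
  stopifnot(length(column_totals) == 4L, all(column_totals > 0))
  Tm <- unclass(T)[1:4, 1:4]
  pf <- pcr_pushforward(Tm, k, deriv = 2L)
  G <- chain_first(pf$G, Tm)
  H <- chain_second(pf$G, pf$H, Tm)
  p <- pmax(as.vector(pf$P), 1e-300)
  cw <- rep(column_totals, each = 4L)
  F <- matrix(0, 16L, 16L)
  for (e in 1:16) {
    He <- matrix(H[e, ], 16L, 16L)
    F <- F - cw[e] * He + (cw[e] / p[e]) * tcrossprod(G[e, ])
  }
  F <- (F + t(F)) / 2
  Fq <- crossprod(.QBASIS, F %*% .QBASIS)
  ld <- determinant(Fq, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop("singular projected Fisher information matrix")
  structure(list(F = F, pseudo_log_det = as.numeric(ld$modulus),
                 gc_weights = column_totals),
            class = "fisher_info")
}

#' Jeffreys log-prior for the polymerase matrix
#'
#' One half of the log pseudo-determinant of the Fisher information
#' restricted to the 12-dimensional quotient space (the four column-sum
#' constraint directions projected out). Invariant under per-column shifts
#' of the log-parameters and under reparameterisation.
#'
#' @inheritParams fisher_information
#' @param grad optional precomputed [pcr_gradient_theta] result (internal
#'   fast path used by the MAP optimiser).
#' @return scalar log-prior (unnormalised).
#' @export
jeffreys_log_prior <- function(T, column_totals, k, grad = NULL) {
  F <- fim_outer(T, column_totals, k, grad = grad)
  Fq <- crossprod(.QBASIS, F %*% .QBASIS)
  ld <- determinant(Fq, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus))
    stop("singular projected Fisher information matrix")
  0.5 * as.numeric(ld$modulus)
}

## MAP ----------------------------------------------------------------------

## heuristic starting polymerase matrix: spread the (complement-symmetrised)
## relative per-base mutation frequencies evenly over the k cycles
start_T <- function(C, k) {
  P <- unclass(relative_frequencies(C))[1:4, 1:4]
  Psym <- (P + P[COMP_IDX, COMP_IDX]) / 2
  T0 <- matrix(0, 4L, 4L)
  for (j in 1:4) {
    for (m in 1:4) if (m != j)
      T0[COMP_IDX[m], j] <- Psym[m, j] * (2 / max(k, 1L))
    T0[COMP_IDX[j], j] <- 1 - sum(T0[, j])
  }
  polymerase_matrix(T0)
}

## negative log-posterior over the 12 gauge-fixed coordinates; degenerate
## points (boundary of the feasible region, numerically singular FIM) get a
## large penalty so line searches back away from them
neg_log_post <- function(theta12, C, k, column_totals) {
  T <- theta_to_T(theta12_to_theta16(theta12))
  grad <- pcr_gradient_theta(T, k)
  ll <- suppressWarnings(counts_log_likelihood(C, T, k, P = grad$P))
  lp <- tryCatch(jeffreys_log_prior(T, column_totals, k, grad = grad),
                 error = function(e) -Inf)
  out <- -(ll + lp)
  if (!is.finite(out)) 1e10 else out
}

#' Maximum a posteriori polymerase fit
#'
#' Fits the 12-degree-of-freedom polymerase matrix `T` to a
#' misincorporation count matrix by maximising the multinomial likelihood
#' times the Jeffreys prior over the quotient parameter space
#' (quasi-Newton in gauge-fixed log-parameters, counter-diagonal entries
#' pinned). Deterministic given the data, `k` and optimiser settings.
#'
#' @param C a [misincorporation_counts()] matrix.
#' @param k number of PCR cycles (default 30, a typical mutagenic
#'   protocol).
#' @param control optional list overriding `optim` settings.
#' @return list with `T` (the MAP [polymerase_matrix()]), `P` (the implied
#'   [mutation_matrix()]), `k`, `log_posterior`, `log_likelihood`,
#'   `log_prior`, `convergence` (0 = converged), `theta12`.
#' @examples
#' \donttest{
#' fit <- map_estimate(ibmoi_counts()$us, k = 30)
#' round(100 * fit$P["G", "G"], 2)
#' }
#' @export
map_estimate <- function(C, k = 30L, control = list()) {
  column_totals <- colSums(unclass(C)[1:4, 1:4])
  th0 <- T_to_theta12(start_T(C, k))
  ctrl <- modifyList(list(maxit = 1000L, reltol = 1e-14), control)
  fit <- optim(th0, neg_log_post, method = "BFGS",
               control = ctrl, C = C, k = k, column_totals = column_totals)
  ## polish: restart BFGS from the optimum (resets the Hessian approximation)
  fit2 <- optim(fit$par, neg_log_post, method = "BFGS",
                control = ctrl, C = C, k = k, column_totals = column_totals)
  if (fit2$value <= fit$value) fit <- fit2
  if (fit$convergence != 0)
    stop("MAP optimisation did not converge (optim code ", fit$convergence, ")")
  T_hat <- polymerase_matrix(theta_to_T(theta12_to_theta16(fit$par)))
  grad <- pcr_gradient_theta(unclass(T_hat), k)
  ll <- counts_log_likelihood(C, T_hat, k, P = grad$P)
  lp <- jeffreys_log_prior(T_hat, column_totals, k, grad = grad)
  list(T = T_hat,
       P = mutation_matrix(grad$P, source = "pcr_model_map"),
       k = as.integer(k), log_posterior = ll + lp, log_likelihood = ll,
       log_prior = lp, convergence = fit$convergence, theta12 = fit$par)
}

## delta-method posterior standard deviations of the entries of P(T, k)
## around the MAP, from the inverse projected FIM
map_posterior_sd_P <- function(fit, column_totals) {
  T <- unclass(fit$T)
  grad <- pcr_gradient_theta(T, fit$k)
  F <- fim_outer(T, column_totals, fit$k, grad = grad)
  Fq <- crossprod(.QBASIS, F %*% .QBASIS)
  covq <- solve(Fq)
  Gq <- grad$G %*% .QBASIS               # 16 entries x 12 quotient coords
  v <- rowSums((Gq %*% covq) * Gq)
  matrix(sqrt(pmax(v, 0)), 4L, 4L, dimnames = list(NUC, NUC))
}

## Metropolis ---------------------------------------------------------------

#' Metropolis sampling of the polymerase posterior
#'
#' Random-walk Metropolis chain in the 12-dimensional quotient log-parameter
#' space, centred at the MAP, with a multivariate normal proposal whose
#' covariance is the inverse projected Fisher information (the asymptotic
#' posterior covariance) times an adapted scalar scale. Because
#' accept/reject uses the exact posterior density, the asymptotic proposal
#' only affects efficiency, not correctness. A short adaptation phase tunes
#' the scale into the 10-40% acceptance band before the recorded chain.
#'
#' @param C a [misincorporation_counts()] matrix.
#' @param k number of PCR cycles.
#' @param chain list of chain settings: `length` (post-burn-in steps),
#'   `burn_in`, `thin`, `seed` (mandatory), `adapt` (adaptation steps).
#' @param map optional precomputed [map_estimate()] fit.
#' @return list with `T_draws` and `P_draws` (4 x 4 x n arrays of thinned
#'   draws), `acceptance_rate`, `scale`, `map`, and `chain` settings.
#' @export
sample_posterior_T <- function(C, k = 30L,
                               chain = list(length = 50000L, burn_in = 5000L,
                                            thin = 10L, seed = 1L,
                                            adapt = 2000L),
                               map = NULL) {
  chain <- modifyList(list(length = 50000L, burn_in = 5000L, thin = 10L,
                           seed = 1L, adapt = 2000L), chain)
  if (is.null(chain$seed)) stop("a seed is mandatory for posterior sampling")
  set.seed(chain$seed)
  column_totals <- colSums(unclass(C)[1:4, 1:4])
  if (is.null(map)) map <- map_estimate(C, k)
  theta_map <- theta12_to_theta16(map$theta12)
  grad <- pcr_gradient_theta(unclass(map$T), k)
  F <- fim_outer(unclass(map$T), column_totals, k, grad = grad)
  Fq <- crossprod(.QBASIS, F %*% .QBASIS)
  Lprop <- t(chol(solve(Fq)))           # proposal factor in quotient coords

  log_post <- function(x) {             # x: quotient offset from MAP
    T <- theta_to_T(theta_map + as.vector(.QBASIS %*% x))
    g <- pcr_gradient_theta(T, k)
    ll <- suppressWarnings(counts_log_likelihood(C, T, k, P = g$P))
    if (!is.finite(ll)) return(-Inf)
    ## a numerically singular FIM marks the boundary of the feasible
    ## region; such proposals are rejected
    lp <- tryCatch(jeffreys_log_prior(T, column_totals, k, grad = g),
                   error = function(e) -Inf)
    ll + lp
  }

  x <- numeric(12L); lp <- log_post(x)
  scale <- 2.38 / sqrt(12)              # standard random-walk starting scale
  ## adaptation: tune scalar proposal scale toward 10-40% acceptance
  if (chain$adapt > 0L) {
    block <- 200L
    for (rep in seq_len(ceiling(chain$adapt / block))) {
      acc <- 0L
      for (i in seq_len(block)) {
        xp <- x + scale * as.vector(Lprop %*% rnorm(12L))
        lpp <- log_post(xp)
        if (log(runif(1)) < lpp - lp) { x <- xp; lp <- lpp; acc <- acc + 1L }
      }
      rate <- acc / block
      ## multiplicative update toward the 0.234 random-walk optimum,
      ## damped so sampling noise in the block rate does not destabilise it
      scale <- scale * exp(0.8 * (max(rate, 1 / block) - 0.234))
      if (rate < 0.10) scale <- scale / 1.4
      else if (rate > 0.40) scale <- scale * 1.4
    }
  }
  total <- chain$burn_in + chain$length
  keep_at <- seq(chain$burn_in + chain$thin, total, by = chain$thin)
  n_keep <- length(keep_at)
  T_draws <- array(0, c(4L, 4L, n_keep), dimnames = list(NUC, NUC, NULL))
  P_draws <- array(0, c(4L, 4L, n_keep), dimnames = list(NUC, NUC, NULL))
  acc <- 0L; ki <- 0L
  for (i in seq_len(total)) {
    xp <- x + scale * as.vector(Lprop %*% rnorm(12L))
    lpp <- log_post(xp)
    if (log(runif(1)) < lpp - lp) { x <- xp; lp <- lpp; acc <- acc + 1L }
    if (ki < n_keep && i == keep_at[ki + 1L]) {
      ki <- ki + 1L
      T <- theta_to_T(theta_map + as.vector(.QBASIS %*% x))
      T_draws[, , ki] <- T
      P_draws[, , ki] <- pcr_pushforward(T, k, deriv = 0L)$P
    }
  }
  rate <- acc / total
  if (rate < 0.005)
    warning("Metropolis acceptance rate below 0.5% after adaptation (",
            round(100 * rate, 2), "%)")
  list(T_draws = T_draws, P_draws = P_draws, acceptance_rate = rate,
       scale = scale, map = map, chain = chain)
}

#' Write a fitted polymerase model as JSON
#'
#' @param fit a [map_estimate()] result, optionally augmented with a
#'   `sampling` element from [sample_posterior_T()].
#' @param path output JSON file.
#' @param sampling optional [sample_posterior_T()] result for the chain
#'   summary.
#' @return the path, invisibly.
#' @export
write_polymerase_fit <- function(fit, path, sampling = NULL) {
  obj <- list(T_map = unclass(fit$T)[1:4, 1:4],
              P_map = unclass(fit$P)[1:4, 1:4],
              k = fit$k, log_posterior = fit$log_posterior)
  if (!is.null(sampling)) {
    obj$acceptance_rate <- sampling$acceptance_rate
    obj$chain_summary <- list(
      n_draws = dim(sampling$P_draws)[3],
      settings = sampling$chain[c("length", "burn_in", "thin", "seed")],
      P_posterior_mean = apply(sampling$P_draws, c(1, 2), mean))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
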