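## bayes_multinomial: Dirichlet-multinomial estimation of mutation
## frequencies from misincorporation counts.
##
## Each column of the mutation matrix P is treated as an independent
## multinomial; the objective (Jeffreys / Berger-Bernardo reference) prior
## Dirichlet(1/2, ..., 1/2) gives the conjugate posterior counts + 1/2.

#' Relative-frequency mutation matrix
#'
#' The simplest point estimate of the PCR mutation matrix: each column of
#' the count matrix is normalised to sum to one, equating misincorporation
#' counts with relative frequencies.
#'
#' @param C a [misincorporation_counts()] matrix with strictly positive
#'   column totals.
#' @return a `mutation_matrix`: 4x4 column-stochastic matrix with attribute
#'   `source = "relative"`.
#' @examples
#' C <- ibmoi_counts()$us
#' round(100 * relative_frequencies(C)["A", "A"], 2)  # 97.46
#' @export
relative_frequencies <- function(C) {
  tot <- colSums(C)
  if (any(tot == 0))
    stop("column total is zero for wild-type base ",
         paste(NUC[tot == 0], collapse = ", "),
         "; use the Dirichlet estimate (dirichlet_posterior) instead")
  mutation_matrix(sweep(unclass(C)[1:4, 1:4], 2L, tot, "/"), source = "relative")
}

#' Column-stochastic mutation matrix
#'
#' Validates a 4x4 matrix of per-PCR mutation probabilities
#' \eqn{p_{ij} = \Pr(\text{clone base } i \mid \text{wild-type base } j)}.
#'
#' @param P 4x4 matrix with entries in \[0, 1\] and columns summing to 1
#'   within 1e-12 (columns are renormalised to remove rounding residue).
#' @param source provenance tag: one of `"relative"`, `"natural"`,
#'   `"posterior_draw"`, `"pcr_model_map"`, `"pcr_model_draw"`.
#' @return classed matrix `mutation_matrix`.
#' @export
mutation_matrix <- function(P, source = "relative") {
  P <- as.matrix(P)
  stopifnot(identical(dim(P), c(4L, 4L)), all(P >= 0), all(P <= 1))
  cs <- colSums(P)
  if (any(abs(cs - 1) > 1e-12))
    stop("columns of a mutation matrix must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  P <- sweep(P, 2L, cs, "/")
  dimnames(P) <- list(NUC, NUC)
  structure(P, source = source, class = c("mutation_matrix", "matrix"))
}

#' @export
print.mutation_matrix <- function(x, digits = 4, ...) {
  cat("Mutation matrix (source: ", attr(x, "source"), "), percent:\n", sep = "")
  print(round(100 * unclass(x)[1:4, 1:4], digits))
  invisible(x)
}

#' Dirichlet posterior for multinomial counts
#'
#' Conjugate posterior `Dirichlet(counts + alpha)` for a multinomial
#' frequency vector under the objective reference prior with every
#' hyperparameter equal to `alpha` (default 1/2, the Jeffreys /
#' Berger-Bernardo choice).
#'
#' @param counts non-negative integer vector of category counts.
#' @param alpha scalar prior hyperparameter added to every component.
#' @return object of class `dirichlet_posterior` with fields
#'   `concentration` and `dim`.
#' @examples
#' dirichlet_posterior(c(27, 1, 11176, 19))$concentration
#' @export
dirichlet_posterior <- function(counts, alpha = 0.5) {
  stopifnot(is.numeric(counts), all(counts >= 0), all(counts == round(counts)),
            length(alpha) == 1L, alpha > 0)
  structure(list(concentration = as.numeric(counts) + alpha,
                 dim = length(counts), alpha = alpha),
            class = "dirichlet_posterior")
}

#' Natural-parameter posterior mean
#'
#' The posterior expectation of the multinomial log-frequencies,
#' \deqn{E[\log p_i] = \psi(n_i + \alpha_i) - \psi(\sum_i (n_i + \alpha_i)),}
#' with \eqn{\psi} the digamma function. For large counts
#' \eqn{\exp E[\log p_i]} is close to \eqn{n_i / \sum n_i}; for rare events
#' it differs materially from the relative count.
#'
#' @param post a [dirichlet_posterior()].
#' @return numeric vector of \eqn{E[\log p_i]}.
#' @examples
#' # two categories, no observations: exp(E[log p]) = 1/4 exactly
#' exp(natural_parameter_mean(dirichlet_posterior(c(0, 0))))
#' @export
natural_parameter_mean <- function(post) {
  stopifnot(inherits(post, "dirichlet_posterior"))
  digamma(post$concentration) - digamma(sum(post$concentration))
}

#' Natural-parameter mutation matrix
#'
#' Applies [natural_parameter_mean()] column-wise to a count matrix and
#' returns the exponentiated, column-renormalised frequencies as a
#' [mutation_matrix()].
#'
#' @inheritParams relative_frequencies
#' @param alpha prior hyperparameter per component.
#' @export
natural_frequencies <- function(C, alpha = 0.5) {
  P <- apply(unclass(C)[1:4, 1:4], 2L, function(col)
    exp(natural_parameter_mean(dirichlet_posterior(col, alpha))))
  P <- sweep(P, 2L, colSums(P), "/")
  mutation_matrix(P, source = "natural")
}

#' Sample frequency vectors from a Dirichlet posterior
#'
#' @param post a [dirichlet_posterior()].
#' @param n_draws number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return `n_draws` x `dim` matrix, each row on the simplex.
#' @export
sample_frequencies <- function(post, n_draws, seed = NULL) {
  stopifnot(inherits(post, "dirichlet_posterior"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- post$dim
  g <- matrix(rgamma(n_draws * k, shape = rep(post$concentration, each = n_draws)),
              nrow = n_draws)
  g / rowSums(g)
}

#' Sample whole mutation matrices from the Dirichlet null
#'
#' Draws each column independently from its Dirichlet posterior
#' (counts + alpha), giving draws of the PCR mutation matrix under the
#' black-box null model.
#'
#' @inheritParams relative_frequencies
#' @param n_draws number of matrices.
#' @param alpha prior hyperparameter.
#' @param seed optional integer seed.
#' @return list of `n_draws` column arrays: a 4 x 4 x n_draws array.
#' @export
sample_mutation_matrices <- function(C, n_draws, alpha = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- array(0, dim = c(4L, 4L, n_draws), dimnames = list(NUC, NUC, NULL))
  for (j in 1:4) {
    post <- dirichlet_posterior(unclass(C)[1:4, j], alpha)
    out[, j, ] <- t(sample_frequencies(post, n_draws))
  }
  out
}

#' Frequency-estimate table in the three-block layout
#'
#' Assembles the relative-count, natural-parameter and (optionally)
#' maximum-a-posteriori estimates of the mutation matrix as percentages
#' rounded to two decimals, one block per estimator.
#'
#' @inheritParams relative_frequencies
#' @param map_P optional `mutation_matrix` from [map_estimate()].
#' @param alpha prior hyperparameter for the natural-parameter block.
#' @return data.frame with columns `estimate`, `base`, `A`, `C`, `G`, `T`.
#' @export
frequency_table <- function(C, map_P = NULL, alpha = 0.5) {
  blocks <- list("Relative Count" = relative_frequencies(C),
                 "Natural Parameter" = natural_frequencies(C, alpha))
  if (!is.null(map_P)) blocks[["Maximum a posteriori"]] <- map_P
  do.call(rbind, lapply(names(blocks), function(nm) {
    M <- round(100 * unclass(blocks[[nm]])[1:4, 1:4], 2)
    data.frame(estimate = nm, base = NUC, M, row.names = NULL,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
}

#' @rdname frequency_table
#' @param path output TSV file.
#' @export
write_frequency_table <- function(C, path, map_P = NULL, alpha = 0.5) {
  write.table(frequency_table(C, map_P, alpha), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
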