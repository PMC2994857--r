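## simulate: synthetic clone populations with known mutation and selection
## structure. Clones are drawn per-site i.i.d. from the columns of the
## marginal per-site mutation matrix P (matching the inference model, which
## treats clones as independent draws from P); PCR lineage effects are
## deliberately not simulated. Purifying selection is hard rejection:
## at each selected codon site the three nucleotides are redrawn until the
## site satisfies the selection mode, which by site-independence equals
## rejection-resampling whole clones.

#' Simulation configuration
#'
#' Collects everything needed to generate matched unselected/selected clone
#' populations. Defaults emulate the reference experiment: 87 clones per
#' pool, 30 PCR cycles, and mutation frequencies derived from the
#' published unselected misincorporation counts.
#'
#' @param wild_type coding sequence; if `NULL` one is generated from
#'   `n_codons`, `gc` and the seed (sense codons only, ATG start).
#' @param n_codons number of codons for a generated wild type.
#' @param gc target GC content of the generated wild type.
#' @param P per-cycle-aggregate mutation matrix (a [mutation_matrix()]);
#'   default: relative frequencies of the published unselected counts.
#' @param T optional [polymerase_matrix()]; if given, `P` is computed as
#'   `pcr_mutation_matrix(T, k)`.
#' @param k PCR cycle count (used only with `T`; recorded either way).
#' @param n_clones clones per population.
#' @param selected_sites codon sites (1-based) under purifying selection in
#'   the selected pool.
#' @param selection_mode `"reject-nonsynonymous"` (any change keeping the
#'   translation survives) or `"reject-any-change"` (codon must stay
#'   identical, the start-codon ligation-artefact control).
#' @param code a [genetic_code()].
#' @param seed master seed; all randomness derives from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(wild_type = NULL, n_codons = 266L, gc = 0.5,
                              P = NULL, T = NULL, k = 30L, n_clones = 87L,
                              selected_sites = integer(0),
                              selection_mode = c("reject-nonsynonymous",
                                                 "reject-any-change"),
                              code = genetic_code("1"), seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  if (!is.null(T)) P <- pcr_mutation_matrix(T, k)
  if (is.null(P)) P <- relative_frequencies(ibmoi_counts()$us)
  if (is.null(wild_type))
    wild_type <- random_coding_sequence(n_codons, gc, code,
                                        seed = seed + 104729L)
  wild_type <- normalize_seq(wild_type)
  n_codons <- nchar(wild_type) / 3L
  stopifnot(n_codons == round(n_codons),
            all(selected_sites >= 1L), all(selected_sites <= n_codons))
  structure(list(wild_type = wild_type, n_codons = as.integer(n_codons),
                 P = P, k = as.integer(k), n_clones = as.integer(n_clones),
                 selected_sites = as.integer(selected_sites),
                 selection_mode = selection_mode, code = code,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Random stop-free coding sequence
#'
#' Generates a coding sequence of sense codons with approximately the
#' requested GC content, starting with ATG. Codons are drawn
#' position-independently from base frequencies matching `gc` and redrawn
#' while they translate to stop.
#'
#' @param n_codons sequence length in codons.
#' @param gc target GC fraction.
#' @param code a [genetic_code()].
#' @param seed integer seed.
#' @return nucleotide string of length `3 * n_codons`.
#' @export
random_coding_sequence <- function(n_codons, gc = 0.5,
                                   code = genetic_code("1"), seed = 1L) {
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw_codon <- function() {
    repeat {
      cd <- paste(sample(NUC, 3L, replace = TRUE, prob = probs), collapse = "")
      if (code$map[[cd]] != "*") return(cd)
    }
  }
  body <- vapply(seq_len(n_codons - 1L), function(i) draw_codon(), character(1))
  paste0("ATG", paste(body, collapse = ""))
}

#' Simulate matched unselected and selected clone populations
#'
#' Draws every clone nucleotide independently from the column of `cfg$P`
#' indexed by the wild-type base. The unselected pool is returned as-is;
#' in the selected pool each configured selected site is
#' rejection-resampled (per clone) until the selection mode is satisfied.
#'
#' @param cfg a [simulation_config()].
#' @return list with `us` and `mx` ([clone_population()]s) and `truth`
#'   (the generating `P`, `selected_sites`, `selection_mode`, `seed`).
#' @examples
#' cfg <- simulation_config(n_codons = 10, n_clones = 5, seed = 7)
#' sim <- simulate_clones(cfg)
#' sim$us$n_clones
#' @export
simulate_clones <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  wt_idx <- match(strsplit(cfg$wild_type, "")[[1]], NUC)
  L <- length(wt_idx)
  P <- unclass(cfg$P)[1:4, 1:4]
  draw_pop <- function() {
    m <- matrix(0L, cfg$n_clones, L)
    for (j in seq_len(L))
      m[, j] <- sample.int(4L, cfg$n_clones, replace = TRUE,
                           prob = P[, wt_idx[j]])
    m
  }
  us <- draw_pop()
  mx <- draw_pop()
  ## selection by per-site rejection resampling
  if (length(cfg$selected_sites)) {
    wt_codons <- substring(cfg$wild_type, seq(1L, L, 3L), seq(3L, L, 3L))
    wt_aa <- cfg$code$map[wt_codons]
    for (s in cfg$selected_sites) {
      cols <- (s - 1L) * 3L + (1:3)
      for (cl in seq_len(cfg$n_clones)) {
        it <- 0L
        repeat {
          cd <- paste(NUC[mx[cl, cols]], collapse = "")
          ok <- if (cfg$selection_mode == "reject-any-change")
            cd == wt_codons[s] else cfg$code$map[[cd]] == wt_aa[s]
          if (ok) break
          it <- it + 1L
          if (it > 100000L) stop("rejection loop exceeded iteration cap at site ", s)
          for (q in 1:3)
            mx[cl, cols[q]] <- sample.int(4L, 1L, prob = P[, wt_idx[cols[q]]])
        }
      }
    }
  }
  to_pop <- function(m, label) {
    clones <- apply(m, 1L, function(r) paste(NUC[r], collapse = ""))
    clone_population(cfg$wild_type, clones, label)
  }
  list(us = to_pop(us, "us"), mx = to_pop(mx, "mx"),
       truth = list(P = cfg$P, selected_sites = cfg$selected_sites,
                    selection_mode = cfg$selection_mode, seed = cfg$seed))
}

#' Write a simulated experiment to FASTA plus ground-truth JSON
#'
#' @param sim result of [simulate_clones()].
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- Biostrings::DNAStringSet(sim$us$wild_type)
  names(wt) <- "wild_type"
  paths <- c(wt = file.path(dir, "wild_type.fasta"),
             us = file.path(dir, "clones_us.fasta"),
             mx = file.path(dir, "clones_mx.fasta"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(wt, paths["wt"])
  for (lab in c("us", "mx")) {
    ss <- Biostrings::DNAStringSet(sim[[lab]]$clones)
    names(ss) <- sprintf("%s_clone_%03d", lab, seq_along(ss))
    Biostrings::writeXStringSet(ss, paths[[lab]])
  }
  jsonlite::write_json(list(P = unclass(sim$truth$P)[1:4, 1:4],
                            selected_sites = sim$truth$selected_sites,
                            selection_mode = sim$truth$selection_mode,
                            seed = sim$truth$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
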