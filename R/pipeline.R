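## app: run configuration, the end-to-end pipeline, subsampling analysis,
## and report assembly. All randomness flows from one master seed through
## named sub-streams so a rerun with the same configuration is numerically
## identical.

## fixed offsets for deriving stage seeds from the master seed
seed_stream <- function(seed, stage) {
  offsets <- c(null = 101L, eos_us = 211L, eos_mx = 307L, kappa = 401L,
               simulate = 503L, subsample = 601L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Pipeline run configuration
#'
#' Declarative configuration for [run_pipeline()]. Either sequence inputs
#' (wild-type FASTA plus one clone FASTA per population) or pre-tabulated
#' count tables can be supplied; with counts only, the frequency-estimate
#' report is produced and site-wise scoring is skipped unless codon counts
#' are also given.
#'
#' @param wild_type_fasta,us_fasta,mx_fasta input FASTA paths.
#' @param counts_tsv optional TSV of nucleotide misincorporation counts
#'   (layout of [write_nucleotide_counts()]) replacing sequence input.
#' @param null_model `"dirichlet"` (black-box PCR) or `"polymerase"`
#'   (mechanistic k-cycle model).
#' @param alpha Dirichlet hyperparameter used throughout.
#' @param k_cycles PCR cycles for the polymerase model.
#' @param n_mc Monte-Carlo size for EoS scoring.
#' @param reliability_n_mc Monte-Carlo size for reliability estimates.
#' @param mcmc list of Metropolis settings (see [sample_posterior_T()]).
#' @param genetic_code_id NCBI translation-table id.
#' @param threshold_odds posterior odds for flagging selected sites.
#' @param stop_policy premature-stop handling for codon counting.
#' @param seed master seed.
#' @param out_dir output directory.
#' @param make_plots write per-site bar charts (PNG) alongside the tables.
#' @return list of class `run_config`.
#' @export
run_config <- function(wild_type_fasta = NULL, us_fasta = NULL,
                       mx_fasta = NULL, counts_tsv = NULL,
                       null_model = c("dirichlet", "polymerase"),
                       alpha = 0.5, k_cycles = 30L, n_mc = 10000L,
                       reliability_n_mc = 2000L,
                       mcmc = list(length = 50000L, burn_in = 5000L,
                                   thin = 10L, adapt = 2000L),
                       genetic_code_id = "1", threshold_odds = 20,
                       stop_policy = "nonsynonymous", seed = 1L,
                       out_dir = "unigenic-out", make_plots = FALSE) {
  null_model <- match.arg(null_model)
  cfg <- list(wild_type_fasta = wild_type_fasta, us_fasta = us_fasta,
              mx_fasta = mx_fasta, counts_tsv = counts_tsv,
              null_model = null_model, alpha = alpha,
              k_cycles = as.integer(k_cycles), n_mc = as.integer(n_mc),
              reliability_n_mc = as.integer(reliability_n_mc), mcmc = mcmc,
              genetic_code_id = as.character(genetic_code_id),
              threshold_odds = threshold_odds, stop_policy = stop_policy,
              seed = as.integer(seed), out_dir = out_dir,
              make_plots = isTRUE(make_plots))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

## draws of the null mutation matrix, by model
null_P_draws <- function(C, cfg) {
  if (cfg$null_model == "dirichlet") {
    sample_mutation_matrices(C, cfg$n_mc, alpha = cfg$alpha,
                             seed = seed_stream(cfg$seed, "null"))
  } else {
    chain <- modifyList(cfg$mcmc, list(seed = seed_stream(cfg$seed, "null")))
    sample_posterior_T(C, cfg$k_cycles, chain = chain)$P_draws
  }
}

#' Run the full analysis pipeline
#'
#' Executes counting, null-model fitting, codon-probability lifting,
#' Evidence-of-Selection scoring with reliability for both populations,
#' and the whole-protein mutation-count diagnostic, writing all tables and
#' a reproducibility manifest to `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @return list with the in-memory results (`counts`, `null`, `eos`,
#'   `kappa`, `manifest`), invisibly writing TSV/JSON artifacts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  code <- genetic_code(cfg$genetic_code_id)
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  pops <- NULL; C_us <- NULL
  if (!is.null(cfg$counts_tsv)) {
    C_us <- stage("counts", read_nucleotide_counts(cfg$counts_tsv))
  } else {
    pops <- stage("counts", list(
      us = read_fasta_population(cfg$us_fasta, cfg$wild_type_fasta, "us"),
      mx = read_fasta_population(cfg$mx_fasta, cfg$wild_type_fasta, "mx")))
    C_us <- tabulate_nucleotide_counts(pops$us)
    for (lab in c("us", "mx")) {
      p <- file.path(cfg$out_dir, paste0("counts_nuc_", lab, ".tsv"))
      write_nucleotide_counts(tabulate_nucleotide_counts(pops[[lab]]), p)
      add(p)
    }
  }

  ## null model fit + frequency report
  map_fit <- NULL
  if (cfg$null_model == "polymerase") {
    map_fit <- stage("fit-null", map_estimate(C_us, cfg$k_cycles))
    p <- file.path(cfg$out_dir, "polymerase_fit.json")
    write_polymerase_fit(map_fit, p); add(p)
  }
  p <- file.path(cfg$out_dir, "frequency_estimates.tsv")
  write_frequency_table(C_us, p,
                        map_P = if (!is.null(map_fit)) map_fit$P,
                        alpha = cfg$alpha)
  add(p)

  eos <- NULL; kappa <- NULL
  if (!is.null(pops)) {
    counts_codon <- lapply(pops, tabulate_codon_counts, code = code,
                           stop_policy = cfg$stop_policy)
    for (lab in c("us", "mx")) {
      p <- file.path(cfg$out_dir, paste0("counts_codon_", lab, ".tsv"))
      write_codon_counts(counts_codon[[lab]], p); add(p)
    }
    P_draws <- stage("fit-null", null_P_draws(C_us, cfg))
    eos <- lapply(c(us = "us", mx = "mx"), function(lab)
      stage("eos", eos_scan(counts_codon[[lab]], P_draws, code,
                            n_mc = cfg$n_mc,
                            seed = seed_stream(cfg$seed, paste0("eos_", lab)),
                            alpha = cfg$alpha,
                            threshold_odds = cfg$threshold_odds,
                            reliability_n_mc = cfg$reliability_n_mc,
                            population = lab)))
    for (lab in c("us", "mx")) {
      p <- file.path(cfg$out_dir, paste0("eos_", lab, ".tsv"))
      write_eos_table(eos[[lab]], p); add(p)
    }
    ## whole-protein mutation-count diagnostic under the null point estimate
    parts <- stage("kappa", site_partitions_for_sequence(
      pops$us$wild_type, relative_frequencies(C_us), code))
    kappa <- mutation_count_distribution(parts, n_sim = 1e5,
                                         seed = seed_stream(cfg$seed, "kappa"))
    p <- file.path(cfg$out_dir, "kappa_pmf.tsv")
    write.table(data.frame(kappa = as.integer(names(kappa$pmf)),
                           mc = kappa$pmf, exact = kappa$exact),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    add(p)
    p <- file.path(cfg$out_dir, "expected_ns.tsv")
    write.table(expected_ns_table(parts, pops$us$n_clones), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    add(p)
    if (cfg$make_plots) {
      p <- file.path(cfg$out_dir, "eos_sites.png")
      grDevices::png(p, width = 1400, height = 600)
      plot_eos(eos$mx, eos$us, threshold_odds = cfg$threshold_odds)
      grDevices::dev.off()
      add(p)
    }
  }

  manifest <- list(package = "unigenicEoS",
                   version = as.character(utils::packageVersion("unigenicEoS")),
                   config = unclass(cfg), config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   artifacts = c(basename(artifacts), "manifest.json"))
  p <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  artifacts <- c(artifacts, p)
  invisible(list(counts = C_us, map = map_fit, eos = eos, kappa = kappa,
                 manifest = manifest, artifacts = artifacts))
}

#' Subsampling (sample-size) analysis
#'
#' Rescores subsets of the clone populations of increasing size, each
#' subset containing the previous one (subset-inclusive), to show how the
#' Evidence of Selection and its reliability grow with the number of
#' sequenced clones.
#'
#' @param us,mx [clone_population()]s.
#' @param subset_sizes increasing vector of clone counts to analyse.
#' @param cfg a [run_config()] providing model settings (inputs ignored).
#' @return named list (one element per size) of lists with `eos_us`,
#'   `eos_mx` score tables.
#' @export
subsample_analysis <- function(us, mx, subset_sizes, cfg = run_config()) {
  stopifnot(all(subset_sizes >= 1L),
            all(diff(subset_sizes) > 0),
            max(subset_sizes) <= min(us$n_clones, mx$n_clones))
  code <- genetic_code(cfg$genetic_code_id)
  set.seed(seed_stream(cfg$seed, "subsample"))
  ord_us <- sample.int(us$n_clones)   # one permutation; prefixes nest
  ord_mx <- sample.int(mx$n_clones)
  out <- list()
  for (m in subset_sizes) {
    sub_us <- clone_population(us$wild_type, us$clones[ord_us[seq_len(m)]], "us")
    sub_mx <- clone_population(mx$wild_type, mx$clones[ord_mx[seq_len(m)]], "mx")
    C <- tabulate_nucleotide_counts(sub_us)
    P_draws <- null_P_draws(C, cfg)
    out[[as.character(m)]] <- list(
      eos_us = eos_scan(tabulate_codon_counts(sub_us, code), P_draws, code,
                        n_mc = cfg$n_mc,
                        seed = seed_stream(cfg$seed, "eos_us"),
                        alpha = cfg$alpha, population = "us",
                        reliability_n_mc = 0L),
      eos_mx = eos_scan(tabulate_codon_counts(sub_mx, code), P_draws, code,
                        n_mc = cfg$n_mc,
                        seed = seed_stream(cfg$seed, "eos_mx"),
                        alpha = cfg$alpha, population = "mx",
                        reliability_n_mc = 0L))
  }
  out
}

#' Per-site Evidence-of-Selection bar chart
#'
#' Side-by-side bars of the selected (red) and unselected (blue)
#' population scores per codon site, with the selection threshold drawn as
#' a horizontal line.
#'
#' @param eos_mx,eos_us `eos_result` tables (unselected optional).
#' @param threshold_odds posterior odds drawn as the decision line.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_eos <- function(eos_mx, eos_us = NULL, threshold_odds = 20, ...) {
  if (is.null(eos_us)) {
    h <- rbind(mx = eos_mx$R)
    cols <- "firebrick"
  } else {
    h <- rbind(mx = eos_mx$R, us = eos_us$R)
    cols <- c("firebrick", "steelblue")
  }
  mids <- graphics::barplot(h, beside = TRUE, col = cols, border = NA,
                            names.arg = eos_mx$site,
                            xlab = "codon site",
                            ylab = expression(log[2] ~ "odds (EoS)"), ...)
  graphics::abline(h = log2(threshold_odds), lty = 2)
  if (!is.null(eos_us))
    graphics::legend("topright", legend = c("selected", "unselected"),
                     fill = cols, border = NA, bty = "n")
  invisible(mids)
}

#' Reliability (power) chart
#'
#' Plots the true-positive/false-negative (`D_HA`) and
#' true-negative/false-positive (`D_H0`) expected log-odds per site.
#'
#' @param eos an `eos_result` table with reliability columns.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_reliability <- function(eos, ...) {
  h <- rbind(D_HA = eos$D_HA, D_H0 = eos$D_H0)
  graphics::barplot(h, beside = TRUE, col = c("orchid4", "darkcyan"),
                    border = NA, names.arg = eos$site, xlab = "codon site",
                    ylab = expression(log[2] ~ "odds"), ...)
  graphics::legend("topright",
                   legend = c("true-pos : false-neg", "true-neg : false-pos"),
                   fill = c("orchid4", "darkcyan"), border = NA, bty = "n")
  invisible(NULL)
}
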