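# Synthetic study generator: emulates a continent-wide two-lineage mtDNA
# survey (wild W lineage structured into geographic clusters; domestic D
# lineage carried by all domestic cats, a configurable fraction of
# nuclear-wild samples — mito-nuclear discordance — and most admixed
# samples) with full ground truth for every downstream stage.

#' Default macro-region / sub-region sampling layout
#'
#' Twelve sub-regions in six European biogeographic macro-regions, each
#' with a centroid, the W-lineage cluster it belongs to, and per-class
#' sampling weights (normalized internally).
#'
#' @return data frame with columns `macro_region`, `sub_region`, `lat`,
#'   `lon`, `cluster`, `w_wild`, `w_domestic`, `w_admixed`.
#' @export
default_region_layout <- function() {
  data.frame(
    macro_region = c("Italy", "Italy", "CentralEurope", "CentralEurope",
                     "Iberia", "Iberia", "Balkans", "Balkans", "Balkans",
                     "EasternEurope", "EasternEurope", "Scotland"),
    sub_region = c("It-cnt", "It-sicily", "Eu-cnt", "Eu-sw", "Ib-sp",
                   "Ib-prt", "Balk-n", "Balk-s", "Balk-nw", "East-n",
                   "East-s", "Sco"),
    lat = c(42.5, 37.5, 51.0, 48.0, 40.2, 39.5, 45.0, 42.0, 46.3, 52.0,
            47.2, 57.0),
    lon = c(12.5, 14.0, 10.0, 7.0, -3.7, -8.0, 16.0, 21.5, 13.5, 19.0,
            19.5, -4.5),
    cluster = c("c1", "c1", "c2", "c2", "c4", "c4", "c2", "c2", "c2",
                "c2", "c1", "c3"),
    w_wild = c(14, 4, 18, 12, 8, 4, 10, 6, 8, 8, 5, 3),
    w_domestic = c(22, 6, 18, 12, 10, 4, 8, 6, 4, 6, 8, 6),
    w_admixed = c(8, 2, 8, 6, 4, 2, 6, 4, 4, 6, 14, 16),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic mtDNA survey
#'
#' Defaults emulate the composition of a continent-wide wildcat survey:
#' 430 wild, 213 domestic and 72 putative admixed samples typed at a
#' 669-bp fragment; two lineages separated by 7 fixed diagnostic sites;
#' 41.4% of nuclear-wild samples carrying discordant D-lineage mtDNA and
#' 61/72 of admixed samples carrying D-lineage mtDNA; W-lineage geography
#' simulated under a 4-cluster simultaneous-split scenario; inter-lineage
#' divergence 197,500 years at 2 years/generation.
#'
#' @param n_wild,n_domestic,n_admixed class sample sizes.
#' @param seq_length sites in the fragment.
#' @param n_diagnostic_sites fixed inter-lineage diagnostic sites.
#' @param discordance_fraction fraction of nuclear-wild samples assigned
#'   D-lineage mtDNA (exactly `round(fraction * n_wild)` samples).
#' @param admixed_d_fraction probability an admixed sample carries
#'   D-lineage mtDNA.
#' @param region_layout layout data frame (see
#'   [default_region_layout()]).
#' @param scenario [demographic_scenario()] for the W lineage; default the
#'   built-in simultaneous 4-cluster split.
#' @param scenario_params named "true" parameter vector for the scenario.
#' @param n_domestic_deme effective size of the panmictic D-lineage deme.
#' @param d_split_years inter-lineage divergence time in years.
#' @param rate_per_year substitution rate per site per year.
#' @param generation_time years per generation.
#' @param kappa,gamma_shape mutation-model settings.
#' @param coord_jitter_sd SD (degrees) of per-sample coordinate jitter
#'   around the sub-region centroid.
#' @param seed RNG seed; identical configs + seed give byte-identical
#'   outputs.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_wild = 430L, n_domestic = 213L, n_admixed = 72L,
                         seq_length = 669L, n_diagnostic_sites = 7L,
                         discordance_fraction = 0.414,
                         admixed_d_fraction = 61 / 72,
                         region_layout = default_region_layout(),
                         scenario = NULL, scenario_params = NULL,
                         n_domestic_deme = 6e4,
                         d_split_years = 197500,
                         rate_per_year = 2.28e-8, generation_time = 2,
                         kappa = 10, gamma_shape = 4,
                         coord_jitter_sd = 0.3, seed = 1L) {
  stopifnot(n_wild >= 0, n_domestic >= 0, n_admixed >= 0,
            discordance_fraction >= 0, discordance_fraction <= 1,
            admixed_d_fraction >= 0, admixed_d_fraction <= 1,
            seq_length >= n_diagnostic_sites)
  if (is.null(scenario)) {
    scenario <- builtin_scenarios("W")$w2_simultaneous
    if (is.null(scenario_params))
      scenario_params <- c(N1 = 25000, N2 = 25000, N3 = 5000, N4 = 15000,
                           Nanc = 50000, t = 32100)
  }
  if (is.null(scenario_params))
    stop("scenario_params must be supplied with a custom scenario")
  structure(list(n_wild = as.integer(n_wild),
                 n_domestic = as.integer(n_domestic),
                 n_admixed = as.integer(n_admixed),
                 seq_length = as.integer(seq_length),
                 n_diagnostic_sites = as.integer(n_diagnostic_sites),
                 discordance_fraction = discordance_fraction,
                 admixed_d_fraction = admixed_d_fraction,
                 region_layout = region_layout,
                 scenario = scenario, scenario_params = scenario_params,
                 n_domestic_deme = n_domestic_deme,
                 d_split_years = d_split_years,
                 rate_per_year = rate_per_year,
                 generation_time = generation_time,
                 kappa = kappa, gamma_shape = gamma_shape,
                 coord_jitter_sd = coord_jitter_sd,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a synthetic survey dataset with ground truth
#'
#' Draws sample metadata (class, sub-region, jittered coordinates),
#' assigns each sample a maternal lineage (D or W) according to the
#' configured discordance fractions, simulates W-lineage sequences under
#' the configured multi-deme coalescent scenario (deme = the W cluster of
#' the sample's sub-region) and D-lineage sequences under a single
#' panmictic deme, with root sequences separated by the diagnostic sites
#' plus clock-expected divergence. Diagnostic sites are held fixed within
#' lineages so the minimum inter-lineage Hamming distance is at least
#' `n_diagnostic_sites`.
#'
#' @param config a [study_config()].
#' @return list with `alignment` (character matrix), `metadata` (data
#'   frame), `truth` (ground-truth list: `panel`, `true_partition`,
#'   `true_split_times`, `true_lineage_of_sample`,
#'   `true_haplotype_of_sample`, `true_lineage_of_haplotype`,
#'   `w_sample_sizes`) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  lay <- config$region_layout
  L <- config$seq_length
  g <- config$generation_time
  mu_gen <- config$rate_per_year * g

  scen_demes <- config$scenario$demes
  bad <- setdiff(unique(lay$cluster), scen_demes)
  if (length(bad))
    stop("region layout references cluster(s) absent from the scenario: ",
         paste(bad, collapse = ", "))

  n_tot <- config$n_wild + config$n_domestic + config$n_admixed
  ids <- sprintf("cat%04d", seq_len(n_tot))
  cls <- c(rep("wild", config$n_wild), rep("domestic", config$n_domestic),
           rep("admixed", config$n_admixed))

  wts <- cbind(wild = lay$w_wild / sum(lay$w_wild),
               domestic = lay$w_domestic / sum(lay$w_domestic),
               admixed = lay$w_admixed / sum(lay$w_admixed))
  sub <- vapply(cls, function(cl)
    sample(lay$sub_region, 1L, prob = wts[, cl]), character(1))
  ridx <- match(sub, lay$sub_region)
  md <- data.frame(sample_id = ids, class = cls,
                   macro_region = lay$macro_region[ridx],
                   sub_region = sub,
                   lat = round(lay$lat[ridx] +
                                 stats::rnorm(n_tot, 0, config$coord_jitter_sd), 4),
                   lon = round(lay$lon[ridx] +
                                 stats::rnorm(n_tot, 0, config$coord_jitter_sd), 4),
                   stringsAsFactors = FALSE)

  # maternal lineage per sample
  lineage <- character(n_tot)
  lineage[cls == "domestic"] <- "D"
  wild_idx <- which(cls == "wild")
  n_disc <- round(config$discordance_fraction * config$n_wild)
  disc <- if (n_disc > 0) sample(wild_idx, n_disc) else integer(0)
  lineage[wild_idx] <- "W"
  lineage[disc] <- "D"
  adm_idx <- which(cls == "admixed")
  if (length(adm_idx))
    lineage[adm_idx] <- ifelse(stats::runif(length(adm_idx)) <
                                 config$admixed_d_fraction, "D", "W")

  # diagnostic panel and lineage root sequences
  diag_pos <- sort(sample.int(L, config$n_diagnostic_sites))
  w_root <- sample.int(4L, L, replace = TRUE)
  d_root <- w_root
  d_root[diag_pos] <- c(3L, 4L, 1L, 2L)[w_root[diag_pos]]  # transition partner
  # additional clock-expected inter-root divergence outside the panel
  exp_subs <- 2 * config$d_split_years * config$rate_per_year * L
  n_extra <- max(0L, stats::rpois(1L, exp_subs) - config$n_diagnostic_sites)
  if (n_extra > 0L) {
    extra <- sample(setdiff(seq_len(L), diag_pos), min(n_extra, L - length(diag_pos)))
    for (s in extra) d_root[s] <- sample(setdiff(1:4, d_root[s]), 1L)
  }
  panel <- data.frame(pos = diag_pos,
                      D = .BASES[d_root[diag_pos]],
                      W = .BASES[w_root[diag_pos]])

  # W-lineage sequences: multi-deme scenario, deme = cluster of sub-region
  w_idx <- which(lineage == "W")
  w_cluster <- lay$cluster[match(md$sub_region[w_idx], lay$sub_region)]
  w_sizes <- table(factor(w_cluster, levels = scen_demes))
  w_sizes <- stats::setNames(as.integer(w_sizes), scen_demes)
  w_sizes <- w_sizes[w_sizes > 0]
  seqs <- matrix(0L, n_tot, L)
  if (length(w_idx) >= 2L) {
    dem_w <- config$scenario$build(config$scenario_params)
    mut_w <- mutation_model(L = L, mu = mu_gen, kappa = config$kappa,
                            gamma_shape = config$gamma_shape,
                            root = paste(.BASES[w_root], collapse = ""),
                            site_mask = diag_pos)
    sim_w <- simulate_coalescent(dem_w, w_sizes, mut_w)
    for (d in names(w_sizes)) {
      tips <- which(sim_w$deme == d)
      samples <- w_idx[w_cluster == d]
      seqs[samples, ] <- sim_w$seqs[tips, , drop = FALSE]
    }
  } else if (length(w_idx) == 1L) {
    seqs[w_idx, ] <- w_root
  }

  # D-lineage sequences: independent panmictic deme
  d_idx <- which(lineage == "D")
  if (length(d_idx) >= 2L) {
    dem_d <- demography(sizes = c(dpool = config$n_domestic_deme))
    mut_d <- mutation_model(L = L, mu = mu_gen, kappa = config$kappa,
                            gamma_shape = config$gamma_shape,
                            root = paste(.BASES[d_root], collapse = ""),
                            site_mask = diag_pos)
    sim_d <- simulate_coalescent(dem_d, c(dpool = length(d_idx)), mut_d)
    seqs[d_idx, ] <- sim_d$seqs
  } else if (length(d_idx) == 1L) {
    seqs[d_idx, ] <- d_root
  }

  rownames(seqs) <- ids
  aln <- as_alignment(stats::setNames(.int_to_seq(seqs), ids))

  hap <- collapse_haplotypes(aln)
  lin_of_hap <- vapply(names(hap$haplotypes), function(h) {
    unique(lineage[match(hap$carriers[[h]], ids)])[1L]
  }, character(1))

  truth <- list(
    panel = panel,
    true_partition = stats::setNames(lay$cluster, lay$sub_region),
    true_split_times = config$scenario_params[grepl("^t",
                                                    names(config$scenario_params))],
    true_lineage_of_sample = stats::setNames(lineage, ids),
    true_haplotype_of_sample = hap$assignment,
    true_lineage_of_haplotype = lin_of_hap,
    w_sample_sizes = w_sizes
  )
  list(alignment = aln, metadata = md, truth = truth, config = config)
}

#' Write a synthetic dataset to disk
#'
#' FASTA (60-column wrap), metadata TSV, and ground truth as JSON.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "alignment.fasta")
  mdf <- file.path(dir, "metadata.tsv")
  tj <- file.path(dir, "truth.json")
  write_fasta(dataset$alignment, fa)
  write_metadata(dataset$metadata, mdf)
  tr <- dataset$truth
  tr$w_sample_sizes <- as.list(tr$w_sample_sizes)
  jsonlite::write_json(tr, tj, auto_unbox = TRUE, digits = NA)
  c(fasta = fa, metadata = mdf, truth = tj)
}
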