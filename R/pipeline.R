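# End-to-end pipeline driver: synthetic (or file) input -> haplotypes ->
# tree/dating -> network -> AMOVA/SAMOVA -> neutrality -> ABC, with one
# global seed deterministically deriving per-stage seeds so that toggling
# one stage never shifts another stage's randomness.

#' Pipeline configuration
#'
#' Exactly one of `input_fasta`+`input_metadata` or `synthetic` must be
#' set. Stage parameters mirror the defaults used throughout the package;
#' simulation-heavy stages are sized for desk-scale runs and are fully
#' configurable.
#'
#' @param synthetic a [study_config()] (its seed is re-derived from
#'   `seed`), or NULL when reading files.
#' @param input_fasta,input_metadata input file paths (alternative to
#'   `synthetic`).
#' @param panel optional diagnostic panel (data frame pos/D/W) for lineage
#'   assignment when reading files; synthetic runs use the ground-truth
#'   panel.
#' @param out_dir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("haplotypes", "tree", "network", "amova", "samova", "neutrality",
#'   "abc")`.
#' @param seed global integer seed.
#' @param epsilon,tv_weight median-joining network settings.
#' @param rate substitution rate per site per year.
#' @param calibration root calibration interval in years.
#' @param n_boot bootstrap replicates (tree support and dating CIs).
#' @param k_range SAMOVA K values to try.
#' @param nperm permutations for AMOVA/SAMOVA tests.
#' @param samova_restarts,samova_steps annealing effort per K.
#' @param neutrality_sims null-coalescent simulations per test.
#' @param abc_sims simulations per scenario.
#' @param abc_keep retained fraction.
#' @param abc_ppc_draws posterior predictive simulations (0 disables).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = study_config(),
                            input_fasta = NULL, input_metadata = NULL,
                            panel = NULL,
                            out_dir = tempfile("mitophylo_run_"),
                            stages = c("haplotypes", "tree", "network",
                                       "amova", "samova", "neutrality", "abc"),
                            seed = 1L,
                            epsilon = 10, tv_weight = 3,
                            rate = 2.28e-8, calibration = c(173000, 230000),
                            n_boot = 200L,
                            k_range = 2:6, nperm = 199L,
                            samova_restarts = 8L, samova_steps = 2000L,
                            neutrality_sims = 500L,
                            abc_sims = 2000L, abc_keep = 0.02,
                            abc_ppc_draws = 0L) {
  files_in <- !is.null(input_fasta) || !is.null(input_metadata)
  if (files_in && !is.null(synthetic))
    stop("set either input files or a synthetic config, not both")
  if (!files_in && is.null(synthetic))
    stop("set input files or a synthetic config")
  structure(list(synthetic = synthetic, input_fasta = input_fasta,
                 input_metadata = input_metadata, panel = panel,
                 out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 epsilon = epsilon, tv_weight = tv_weight, rate = rate,
                 calibration = calibration, n_boot = as.integer(n_boot),
                 k_range = k_range, nperm = as.integer(nperm),
                 samova_restarts = as.integer(samova_restarts),
                 samova_steps = as.integer(samova_steps),
                 neutrality_sims = as.integer(neutrality_sims),
                 abc_sims = as.integer(abc_sims), abc_keep = abc_keep,
                 abc_ppc_draws = as.integer(abc_ppc_draws)),
            class = "pipeline_config")
}

#' Run the full phylogeography pipeline
#'
#' Executes the configured stages in order (haplotype collapsing and
#' diversity; NJ tree with bootstrap and strict-clock dating calibrated at
#' the root; median-joining network; AMOVA; SAMOVA over a K range with
#' K selection; neutrality tests and mismatch distributions per lineage;
#' ABC scenario comparison for the W lineage) and writes every artifact
#' under `out_dir` together with a manifest of md5 hashes. Identical
#' config + seed give identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory results per stage, `artifacts` (named
#'   file paths) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  res <- list()

  # --- input ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- stage_seed(config$seed, "simulate")
    dataset <- generate_dataset(syn)
    aln <- dataset$alignment
    md <- dataset$metadata
    panel <- dataset$truth$panel
    cluster_map <- dataset$truth$true_partition
    paths <- write_dataset(dataset, file.path(config$out_dir, "input"))
    art <- c(art, paths)
    res$dataset <- dataset
  } else {
    aln <- read_fasta(config$input_fasta)
    md <- read_metadata(config$input_metadata)
    md <- md[match(rownames(aln), md$sample_id), ]
    panel <- config$panel
    cluster_map <- NULL
  }

  hap <- collapse_haplotypes(aln, md)
  res$haplotypes <- hap

  lineage <- NULL
  if (!is.null(panel)) {
    lin_of_hap <- vapply(names(hap$haplotypes), function(h)
      assign_lineage(hap$haplotypes[[h]], panel)$lineage, character(1))
    lineage <- unname(lin_of_hap[hap$assignment])
    res$lineage_of_haplotype <- lin_of_hap
  }

  run <- function(st) st %in% config$stages

  # --- haplotypes / diversity ---------------------------------------
  if (run("haplotypes")) {
    f1 <- file.path(config$out_dir, "haplotypes.tsv")
    write_haplotype_table(hap, f1)
    div <- diversity_table(aln, md$macro_region)
    f2 <- file.path(config$out_dir, "diversity.tsv")
    utils::write.table(div, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    art <- c(art, haplotypes = f1, diversity = f2)
    res$diversity <- div
  }

  # --- tree + dating -------------------------------------------------
  if (run("tree") && length(hap$haplotypes) >= 3L) {
    seed_t <- stage_seed(config$seed, "tree")
    hap_aln <- hap$seq_matrix
    D <- dist_model(hap_aln, "K80")
    tr <- nj_tree(D)
    supp <- bootstrap_support(hap_aln, tree = tr, B = config$n_boot,
                              seed = seed_t)
    rooted <- root_tree(tr)
    dated <- clock_date_tree(rooted, hap_aln, rate = config$rate,
                             n_boot = config$n_boot, seed = seed_t + 1L)
    dated <- calibrate_root(dated, config$calibration[1], config$calibration[2])
    f <- file.path(config$out_dir, "tree_dated.nwk")
    write_dated_tree(dated, f)
    art <- c(art, tree = f)
    res$tree <- list(nj = tr, support = supp, dated = dated)
  }

  # --- network -------------------------------------------------------
  if (run("network") && length(hap$haplotypes) >= 2L) {
    net <- mj_network(hap, epsilon = config$epsilon,
                      weights = c(ts = 1, tv = config$tv_weight))
    f1 <- file.path(config$out_dir, "network.gml")
    f2 <- file.path(config$out_dir, "network_edges.tsv")
    write_gml(net, f1); write_edge_list(net, f2)
    art <- c(art, network_gml = f1, network_edges = f2)
    res$network <- net
  }

  d2 <- hap_diff_squared(hap)
  hap_idx <- hap$assignment

  # --- amova ---------------------------------------------------------
  if (run("amova")) {
    seed_a <- stage_seed(config$seed, "amova")
    am_class <- amova(hap_idx, md$class, d2 = d2, nperm = config$nperm,
                      seed = seed_a)
    res$amova_classes <- am_class
    f <- file.path(config$out_dir, "amova_classes.tsv")
    write_amova_table(am_class, f)
    art <- c(art, amova_classes = f)
    if (!is.null(lineage)) {
      keep <- lineage %in% c("D", "W")
      am_lin <- amova(hap_idx[keep], lineage[keep], d2 = d2,
                      nperm = config$nperm, seed = seed_a + 1L)
      res$amova_lineages <- am_lin
      f2 <- file.path(config$out_dir, "amova_lineages.tsv")
      write_amova_table(am_lin, f2)
      art <- c(art, amova_lineages = f2)
    }
  }

  # --- samova (W lineage, sub-regions as populations) ---------------
  if (run("samova")) {
    seed_s <- stage_seed(config$seed, "samova")
    keep <- if (!is.null(lineage)) lineage == "W" else rep(TRUE, nrow(md))
    pops <- md$sub_region[keep]
    # populations need >= 1 sample and distinct coordinates
    coords <- do.call(rbind, lapply(split(md[keep, c("lon", "lat")], pops), colMeans))
    kmax <- min(max(config$k_range), nrow(coords) - 1L)
    ks <- config$k_range[config$k_range <= kmax]
    sam <- lapply(ks, function(K)
      samova(hap_idx[keep], pops, d2 = d2, coords = coords, K = K,
             restarts = config$samova_restarts, n_steps = config$samova_steps,
             nperm = config$nperm, seed = seed_s + K))
    sel <- select_k(sam)
    res$samova <- sam
    res$samova_k <- sel
    out <- list(selected_K = sel$K, fct = sel$fct, table = sel$table,
                partitions = lapply(sam, function(s)
                  list(K = s$K, fct = s$fct, p = s$p,
                       partition = as.list(s$partition))))
    f <- file.path(config$out_dir, "samova.json")
    jsonlite::write_json(out, f, auto_unbox = TRUE, digits = 10)
    art <- c(art, samova = f)
  }

  # --- neutrality ----------------------------------------------------
  if (run("neutrality")) {
    seed_n <- stage_seed(config$seed, "neutrality")
    grp <- if (!is.null(lineage)) lineage else md$class
    nt <- neutrality_table(aln, grp, n_sims = config$neutrality_sims,
                           seed = seed_n)
    f <- file.path(config$out_dir, "neutrality.tsv")
    utils::write.table(nt, f, sep = "\t", quote = FALSE, row.names = FALSE)
    art <- c(art, neutrality = f)
    res$neutrality <- nt
    for (gg in unique(grp)) {
      sub <- aln[grp == gg, , drop = FALSE]
      if (nrow(sub) >= 2L) {
        mm <- mismatch_distribution(sub)
        fm <- file.path(config$out_dir, paste0("mismatch_", gg, ".tsv"))
        utils::write.table(
          data.frame(differences = as.integer(names(mm$histogram)),
                     count = as.numeric(mm$histogram)),
          fm, sep = "\t", quote = FALSE, row.names = FALSE)
        art <- c(art, stats::setNames(fm, paste0("mismatch_", gg)))
        res$mismatch[[gg]] <- mm
      }
    }
  }

  # --- abc (W lineage clusters) -------------------------------------
  if (run("abc") && !is.null(lineage) && !is.null(cluster_map)) {
    seed_b <- stage_seed(config$seed, "abc")
    keep <- lineage == "W"
    deme <- unname(cluster_map[md$sub_region[keep]])
    ok_demes <- names(table(deme))[table(deme) >= 2L]
    keep2 <- deme %in% ok_demes
    if (length(ok_demes) >= 2L) {
      m <- .aln_int(aln)[keep, , drop = FALSE][keep2, , drop = FALSE]
      obs <- summary_stats(m, deme[keep2])
      scen <- builtin_scenarios("W")
      scen <- Filter(function(s) all(ok_demes %in% s$demes), scen)
      sizes <- stats::setNames(as.integer(table(deme[keep2])[ok_demes]), ok_demes)
      mut <- mutation_model(L = ncol(m),
                            mu = config$rate * 2,
                            gamma_shape = 4)
      set.seed(seed_b)
      ref <- abc_reference_table(scen, config$abc_sims, sizes, mut)
      mc <- abc_model_choice(obs, ref = ref, keep = config$abc_keep,
                             seed = seed_b + 1L)
      best <- scen[[mc$selected]]
      pp <- abc_parameter_posterior(obs, best, ref = list(
        params = ref$params, stats = ref$stats[ref$scenario == mc$selected, ,
                                               drop = FALSE],
        scenario = ref$scenario[ref$scenario == mc$selected]),
        keep = config$abc_keep, seed = seed_b + 2L)
      abc_out <- list(posterior = as.list(mc$posterior),
                      selected = mc$selected,
                      rejection = as.list(mc$rejection),
                      parameters = pp$summary)
      if (config$abc_ppc_draws > 0L) {
        ppc <- posterior_predictive_check(best, pp, obs,
                                          n_draws = config$abc_ppc_draws,
                                          sample_sizes = sizes, mut = mut,
                                          seed = seed_b + 3L)
        abc_out$predictive_check <- ppc
        res$abc_ppc <- ppc
      }
      f <- file.path(config$out_dir, "abc.json")
      jsonlite::write_json(abc_out, f, auto_unbox = TRUE, digits = 10)
      art <- c(art, abc = f)
      res$abc <- list(model_choice = mc, posterior = pp)
    }
  }

  # --- manifest ------------------------------------------------------
  hashes <- tools::md5sum(unlist(art))
  names(hashes) <- basename(names(hashes))
  manifest <- list(seed = config$seed, stages = config$stages,
                   files = as.list(hashes))
  fm <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE)
  res$artifacts <- art
  res$manifest <- manifest
  res
}
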