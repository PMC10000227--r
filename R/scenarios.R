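# Demographic scenarios = a set of demes with uniform priors on sizes and
# event times plus a builder turning one parameter draw into a concrete
# demography(). Ordering constraints between time parameters are honoured
# by rejection during prior sampling.

#' Construct a demographic scenario with priors
#'
#' @param name scenario label.
#' @param demes character vector of sampled deme names.
#' @param priors named list of `c(lo, hi)` uniform prior bounds, one per
#'   free parameter.
#' @param build function(params) -> [demography()].
#' @param constraints list of character vectors; the named parameters must
#'   be strictly increasing within each vector (e.g. ordered split times).
#' @param generation_time years per generation (default 2, wildcat).
#' @return object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(name, demes, priors, build,
                                 constraints = list(), generation_time = 2) {
  for (p in names(priors)) {
    b <- priors[[p]]
    if (length(b) != 2L || b[1] >= b[2])
      stop("prior for '", p, "' must be c(lo, hi) with lo < hi")
  }
  sc <- structure(list(name = name, demes = demes, priors = priors,
                       build = build, constraints = constraints,
                       generation_time = generation_time),
                  class = "demographic_scenario")
  validate_scenario(sc)
  sc
}

#' Validate a scenario by instantiating it at the prior midpoint
#'
#' @param scenario a `demographic_scenario`.
#' @return TRUE invisibly; errors on malformed scenarios.
#' @export
validate_scenario <- function(scenario) {
  mid <- vapply(scenario$priors, function(b) mean(b), numeric(1))
  # midpoints may violate ordering constraints; nudge into order
  for (cs in scenario$constraints) mid[cs] <- sort(mid[cs]) + seq_along(cs) * 1e-6
  dem <- scenario$build(mid)
  if (!inherits(dem, "demography")) stop("build() must return a demography")
  miss <- setdiff(scenario$demes, names(dem$sizes))
  if (length(miss)) stop("scenario demes missing from demography: ",
                         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Draw parameter vectors from a scenario's priors
#'
#' Uniform draws honouring ordering constraints by rejection.
#'
#' @param scenario a `demographic_scenario`.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return matrix (n x parameters).
#' @export
sample_priors <- function(scenario, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- scenario$priors
  draw <- function(m) {
    out <- vapply(pr, function(b) stats::runif(m, b[1], b[2]), numeric(m))
    matrix(out, nrow = m, dimnames = list(NULL, names(pr)))
  }
  X <- draw(n)
  ok <- rep(TRUE, n)
  for (cs in scenario$constraints)
    ok <- ok & apply(X[, cs, drop = FALSE], 1L, function(v) all(diff(v) > 0))
  while (any(!ok)) {
    m <- sum(!ok)
    X[!ok, ] <- draw(m)
    ok <- rep(TRUE, n)
    for (cs in scenario$constraints)
      ok <- ok & apply(X[, cs, drop = FALSE], 1L, function(v) all(diff(v) > 0))
  }
  X
}

#' Built-in demographic scenario libraries
#'
#' Two scenario sets for a two-lineage mtDNA survey structured into
#' SAMOVA-derived clusters:
#'
#' * `"W"` — four wild-lineage clusters (`c1` = Italy + South-Eastern
#'   Europe, `c2` = Central/North-Eastern Europe + Balkans, `c3` =
#'   Scotland, `c4` = Iberia). Scenario 1: sequential splits; scenario 2:
#'   simultaneous split; scenarios 3 and 4: as 1 and 2 but cluster 4
#'   originates from an admixture pulse between clusters 1 and 2.
#' * `"DW"` — three discordant-lineage clusters (`sco`, `ibe`, `eur`).
#'   Scenario 1: simultaneous recent split; scenario 2: sequential splits;
#'   scenario 3: as 2 with longer coalescence times.
#'
#' Priors are uniform; effective sizes up to 1e5 and split times up to
#' 6e4 generations.
#'
#' @param set `"W"` or `"DW"`.
#' @return named list of `demographic_scenario` objects.
#' @export
builtin_scenarios <- function(set = c("W", "DW")) {
  set <- match.arg(set)
  Npr <- c(100, 1e5)
  if (set == "W") {
    demes <- c("c1", "c2", "c3", "c4")
    tpr <- c(100, 6e4)
    base_priors <- list(N1 = Npr, N2 = Npr, N3 = Npr, N4 = Npr, Nanc = Npr)
    sizes_of <- function(p) c(c1 = p[["N1"]], c2 = p[["N2"]], c3 = p[["N3"]],
                              c4 = p[["N4"]], anc = p[["Nanc"]])
    list(
      w1_sequential = demographic_scenario(
        "w1_sequential", demes,
        c(base_priors, list(t1 = tpr, t2 = tpr, t3 = tpr)),
        function(p) demography(sizes_of(p), list(
          ev_merge(p[["t1"]], "c4", "c1"),
          ev_merge(p[["t2"]], "c3", "c2"),
          ev_merge(p[["t3"]], "c2", "anc"),
          ev_merge(p[["t3"]], "c1", "anc"))),
        constraints = list(c("t1", "t2", "t3"))),
      w2_simultaneous = demographic_scenario(
        "w2_simultaneous", demes,
        c(base_priors, list(t = tpr)),
        function(p) demography(sizes_of(p), list(
          ev_merge(p[["t"]], "c2", "anc"),
          ev_merge(p[["t"]], "c3", "anc"),
          ev_merge(p[["t"]], "c4", "anc"),
          ev_merge(p[["t"]], "c1", "anc")))),
      w3_sequential_admix = demographic_scenario(
        "w3_sequential_admix", demes,
        c(base_priors, list(t_adm = c(10, 2e4), t2 = tpr, t3 = tpr,
                            ra = c(0.05, 0.95))),
        function(p) demography(sizes_of(p), list(
          ev_admixture(p[["t_adm"]], "c4", "c1", "c2", p[["ra"]]),
          ev_merge(p[["t2"]], "c3", "c2"),
          ev_merge(p[["t3"]], "c2", "anc"),
          ev_merge(p[["t3"]], "c1", "anc"))),
        constraints = list(c("t_adm", "t2", "t3"))),
      w4_simultaneous_admix = demographic_scenario(
        "w4_simultaneous_admix", demes,
        c(base_priors, list(t_adm = c(10, 2e4), t = tpr, ra = c(0.05, 0.95))),
        function(p) demography(sizes_of(p), list(
          ev_admixture(p[["t_adm"]], "c4", "c1", "c2", p[["ra"]]),
          ev_merge(p[["t"]], "c2", "anc"),
          ev_merge(p[["t"]], "c3", "anc"),
          ev_merge(p[["t"]], "c1", "anc"))),
        constraints = list(c("t_adm", "t")))
    )
  } else {
    demes <- c("sco", "ibe", "eur")
    sizes_of <- function(p) c(sco = p[["Nsco"]], ibe = p[["Nibe"]],
                              eur = p[["Neur"]], anc = p[["Nanc"]])
    base_priors <- list(Nsco = Npr, Nibe = Npr, Neur = Npr, Nanc = Npr)
    seq_build <- function(p) demography(sizes_of(p), list(
      ev_merge(p[["t1"]], "sco", "eur"),
      ev_merge(p[["t2"]], "eur", "anc"),
      ev_merge(p[["t2"]], "ibe", "anc")))
    list(
      dw1_recent_simultaneous = demographic_scenario(
        "dw1_recent_simultaneous", demes,
        c(base_priors, list(t = c(10, 5000))),
        function(p) demography(sizes_of(p), list(
          ev_merge(p[["t"]], "sco", "anc"),
          ev_merge(p[["t"]], "ibe", "anc"),
          ev_merge(p[["t"]], "eur", "anc")))),
      dw2_sequential = demographic_scenario(
        "dw2_sequential", demes,
        c(base_priors, list(t1 = c(10, 2e4), t2 = c(10, 2e4))),
        seq_build, constraints = list(c("t1", "t2"))),
      dw3_sequential_long = demographic_scenario(
        "dw3_sequential_long", demes,
        c(base_priors, list(t1 = c(1000, 6e4), t2 = c(1000, 6e4))),
        seq_build, constraints = list(c("t1", "t2")))
    )
  }
}
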