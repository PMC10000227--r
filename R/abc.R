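# Approximate Bayesian computation: rejection + multinomial-logistic
# model choice and Beaumont-style local-linear parameter adjustment with
# Epanechnikov weights on logit-transformed parameters, plus posterior
# predictive model checking.

#' Summary-statistic vector of a multi-deme haplotype sample
#'
#' Per deme: haplotype count, segregating sites, haplotype diversity,
#' nucleotide diversity (per site), Tajima's D and singleton count; per
#' deme pair: Phi_ST and mean between-deme pairwise differences. The
#' ordering is fixed by the sorted deme names; statistics undefined for a
#' deme (e.g. Tajima's D with S = 0) are reported as 0 (their mask is part
#' of the definition, keeping vectors NaN-free and comparable).
#'
#' @param seqs integer-coded or character alignment matrix.
#' @param deme deme label per row.
#' @return named numeric vector.
#' @export
summary_stats <- function(seqs, deme) {
  if (inherits(seqs, "coalescent_sim")) { deme <- seqs$deme; seqs <- seqs$seqs }
  m <- if (is.integer(seqs)) seqs else .aln_int(as_alignment(seqs))
  if (any(m == 0L)) .summary_stats_general(m, deme)
  else .summary_stats_fast(m, deme)
}

# fast path for complete (no N/gap) matrices: restrict to polymorphic
# columns, collapse to distinct haplotypes, and express every statistic
# through per-deme haplotype count vectors.
.summary_stats_fast <- function(m, deme) {
  demes <- sort(unique(deme))
  n_all <- nrow(m)
  L <- ncol(m)
  vary <- which(colSums(m != matrix(m[1L, ], n_all, L, byrow = TRUE)) > 0L)
  mv <- m[, vary, drop = FALSE]
  keys <- if (length(vary)) apply(mv, 1L, paste, collapse = ".")
          else rep("x", n_all)
  uk <- unique(keys)
  H <- length(uk)
  mu <- mv[match(uk, keys), , drop = FALSE]
  Dd <- matrix(0, H, H)
  if (H > 1L) for (i in 1:(H - 1L)) for (j in (i + 1L):H)
    Dd[i, j] <- Dd[j, i] <- sum(mu[i, ] != mu[j, ])
  Fc <- unclass(table(factor(deme, levels = demes), factor(keys, levels = uk)))

  out <- numeric(0)
  for (d in demes) {
    f <- Fc[d, ]
    n <- sum(f)
    subm <- mv[deme == d, , drop = FALSE]
    S <- 0L; eta_s <- 0L
    if (n >= 2L) for (j in seq_len(ncol(subm))) {
      tab <- tabulate(subm[, j], 4L)
      kst <- sum(tab > 0L)
      if (kst >= 2L) {
        S <- S + 1L
        eta_s <- eta_s + min(sum(tab == 1L), kst - 1L)
      }
    }
    npair <- n * (n - 1) / 2
    k <- if (npair > 0) as.numeric(f %*% Dd %*% f) / 2 / npair else 0
    nh <- sum(f > 0L)
    hd <- if (n >= 2L && nh >= 2L) {
      p <- f / n; n * (1 - sum(p^2)) / (n - 1)
    } else 0
    td <- if (n >= 4L && S > 0L) tajimas_d(n = n, S = S, k = k)$D else 0
    out <- c(out, stats::setNames(
      c(nh, S, hd, k / L, td, eta_s),
      paste0(d, "_", c("nhap", "S", "Hd", "pi", "tajD", "singletons"))))
  }
  if (length(demes) > 1L) {
    D2 <- Dd^2
    for (i in 1:(length(demes) - 1L)) for (j in (i + 1L):length(demes)) {
      fa <- Fc[demes[i], ]; fb <- Fc[demes[j], ]
      na <- sum(fa); nb <- sum(fb)
      kb <- as.numeric(fa %*% Dd %*% fb) / (na * nb)
      F2 <- rbind(fa, fb)
      S2 <- F2 %*% D2 %*% t(F2)
      res <- .amova2(S2, c(na, nb))
      phist <- if (is.finite(res$phi_st)) res$phi_st else 0
      out <- c(out, stats::setNames(
        c(phist, kb), paste0(demes[i], ".", demes[j], "_", c("phist", "kbetween"))))
    }
  }
  out
}

# general path (pairwise deletion for ambiguous/gap sites)
.summary_stats_general <- function(m, deme) {
  demes <- sort(unique(deme))
  out <- numeric(0)
  for (d in demes) {
    sub <- m[deme == d, , drop = FALSE]
    n <- nrow(sub)
    keys <- .int_key(sub)
    nh <- length(unique(keys))
    sc <- .site_counts(sub)
    k <- if (n >= 2) .mean_pairwise_diff(sub) else 0
    hd <- if (n >= 2 && nh >= 2) haplotype_diversity(table(keys))$Hd else 0
    pi <- k / ncol(sub)
    td <- if (n >= 4 && sc$S > 0) tajimas_d(n = n, S = sc$S, k = k)$D else 0
    out <- c(out, stats::setNames(
      c(nh, sc$S, hd, pi, td, sc$eta_s),
      paste0(d, "_", c("nhap", "S", "Hd", "pi", "tajD", "singletons"))))
  }
  if (length(demes) > 1L) {
    for (i in 1:(length(demes) - 1L)) for (j in (i + 1L):length(demes)) {
      a <- m[deme == demes[i], , drop = FALSE]
      b <- m[deme == demes[j], , drop = FALSE]
      kb <- .mean_between_diff(a, b)
      phist <- .phi_st_two(a, b)
      out <- c(out, stats::setNames(
        c(phist, kb), paste0(demes[i], ".", demes[j], "_", c("phist", "kbetween"))))
    }
  }
  out
}

.mean_between_diff <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    tot <- tot + sum(a[i, ] != b[j, ] & a[i, ] > 0L & b[j, ] > 0L)
  tot / (nrow(a) * nrow(b))
}

# two-deme Phi_ST from sequence matrices (two-level AMOVA on diff^2)
.phi_st_two <- function(a, b) {
  m <- rbind(a, b)
  keys <- .int_key(m)
  uniq <- unique(keys)
  mi <- m[match(uniq, keys), , drop = FALSE]
  H <- length(uniq)
  d2 <- matrix(0, H, H, dimnames = list(uniq, uniq))
  if (H > 1L) for (i in 1:(H - 1L)) for (j in (i + 1L):H) {
    ok <- mi[i, ] > 0L & mi[j, ] > 0L
    d2[i, j] <- d2[j, i] <- sum(mi[i, ok] != mi[j, ok])^2
  }
  pop <- c(rep("a", nrow(a)), rep("b", nrow(b)))
  FF <- .pop_hap_counts(keys, pop, uniq)
  np <- rowSums(FF)
  S <- FF %*% d2 %*% t(FF)
  res <- .amova2(S, np)
  if (!is.finite(res$phi_st)) 0 else res$phi_st
}

#' Simulate an ABC reference table for one or more scenarios
#'
#' Draws parameters from each scenario's priors, simulates one dataset per
#' draw, and records parameters and summary statistics.
#'
#' @param scenarios named list of [demographic_scenario()] objects.
#' @param n_sims simulations per scenario.
#' @param sample_sizes named vector of per-deme sample sizes (shared by
#'   all scenarios).
#' @param mut a [mutation_model()].
#' @param seed optional RNG seed.
#' @return list with `params` (list of per-scenario matrices), `stats`
#'   (matrix), `scenario` (label per row).
#' @export
abc_reference_table <- function(scenarios, n_sims, sample_sizes, mut,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_stats <- NULL; labels <- character(0); params <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    X <- sample_priors(sc, n_sims)
    params[[nm]] <- X
    st <- matrix(NA_real_, n_sims, 0L)
    for (i in seq_len(n_sims)) {
      dem <- sc$build(X[i, ])
      sim <- simulate_coalescent(dem, sample_sizes, mut)
      sv <- summary_stats(sim$seqs, sim$deme)
      if (ncol(st) == 0L) st <- matrix(NA_real_, n_sims, length(sv),
                                       dimnames = list(NULL, names(sv)))
      st[i, ] <- sv
    }
    all_stats <- rbind(all_stats, st)
    labels <- c(labels, rep(nm, n_sims))
  }
  list(params = params, stats = all_stats, scenario = labels)
}

# Reduce centred statistic columns to their leading principal directions
# (computed without re-centring so the observed point stays at the
# origin). Keeps the regressions well-posed when the retained sample is
# small relative to the number of summary statistics.
.pc_scores <- function(Zc, n_obs, var_frac = 0.95, max_comp = 8L) {
  sv <- svd(Zc)
  ev <- sv$d^2
  kmax <- min(max_comp, max(1L, floor(n_obs / 10)), sum(ev > 1e-12))
  k <- min(which(cumsum(ev) / sum(ev) >= var_frac), kmax)
  k <- max(k, 1L)
  Zc %*% sv$v[, seq_len(k), drop = FALSE]
}

# robust standardization by pooled median absolute deviation; constant
# statistics get unit scale (they then contribute nothing to distances)
.standardize_stats <- function(stats_matrix, obs) {
  med <- apply(stats_matrix, 2L, stats::median)
  madv <- apply(stats_matrix, 2L, stats::mad)
  madv[madv < 1e-12] <- 1
  list(Z = sweep(sweep(stats_matrix, 2L, med), 2L, madv, "/"),
       z_obs = (obs - med) / madv)
}

#' ABC scenario choice: rejection and multinomial logistic regression
#'
#' Statistics are standardized by the pooled median absolute deviation;
#' the `keep` fraction of simulations closest to the observed vector in
#' Euclidean distance is retained; scenario posterior probabilities come
#' from a multinomial logistic regression of the scenario label on the
#' (centred) statistics among retained simulations, evaluated at the
#' observed point, with confidence intervals from the regression's
#' asymptotic coefficient covariance. The plain rejection estimate
#' (retained class fractions) is also reported.
#'
#' @param obs_stats observed summary-statistic vector (see
#'   [summary_stats()]).
#' @param ref a reference table from [abc_reference_table()], or NULL to
#'   simulate one here.
#' @param scenarios,n_sims_per_scenario,sample_sizes,mut used only when
#'   `ref` is NULL.
#' @param keep fraction of simulations retained (default 0.01).
#' @param n_ci_draws coefficient draws for the CI (0 disables).
#' @param seed optional RNG seed.
#' @return object of class `abc_model_choice`: `posterior` (named, sums to
#'   1), `ci` (matrix), `rejection` (named fractions), `selected`,
#'   `n_retained`.
#' @export
abc_model_choice <- function(obs_stats, ref = NULL, scenarios = NULL,
                             n_sims_per_scenario = 1e4L, sample_sizes = NULL,
                             mut = NULL, keep = 0.01, n_ci_draws = 200L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ref)) {
    if (is.null(scenarios) || length(scenarios) < 2L)
      stop("need a reference table or >= 2 scenarios")
    ref <- abc_reference_table(scenarios, n_sims_per_scenario, sample_sizes, mut)
  }
  labs <- unique(ref$scenario)
  if (length(labs) < 2L) stop("need >= 2 scenarios")
  std <- .standardize_stats(ref$stats, obs_stats[colnames(ref$stats)])
  d <- sqrt(rowSums(sweep(std$Z, 2L, std$z_obs)^2))
  n_keep <- max(length(labs) + 1L, ceiling(keep * length(d)))
  sel <- order(d)[seq_len(n_keep)]
  y <- factor(ref$scenario[sel], levels = labs)

  rejection <- as.numeric(table(y)) / length(sel)
  names(rejection) <- labs

  Z <- std$Z[sel, , drop = FALSE]
  Zc <- sweep(Z, 2L, std$z_obs)          # centred at observed -> intercept = obs
  keep_cols <- apply(Zc, 2L, function(v) stats::sd(v) > 1e-10)
  post <- rejection
  ci <- NULL
  if (nlevels(droplevels(y)) >= 2L && sum(keep_cols) >= 1L) {
    PC <- .pc_scores(Zc[, keep_cols, drop = FALSE], length(sel))
    colnames(PC) <- paste0("pc", seq_len(ncol(PC)))
    df <- data.frame(y = y, PC)
    fit <- tryCatch(
      nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200L,
                     Hess = n_ci_draws > 0L),
      error = function(e) NULL)
    if (!is.null(fit)) {
      nd <- df[1L, -1L, drop = FALSE]; nd[1L, ] <- 0
      pr <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(pr))) {         # two scenarios: prob of second level
        post <- stats::setNames(c(1 - pr, pr), levels(y))
      } else post <- stats::setNames(as.numeric(pr), colnames(pr))
      post <- post[labs]; post[is.na(post)] <- 0
      post <- post / sum(post)
      if (n_ci_draws > 0L) {
        ci <- tryCatch({
          V <- stats::vcov(fit)
          cf <- as.numeric(t(stats::coef(fit)))
          Ch <- chol(V + diag(1e-8, nrow(V)))
          draws <- matrix(stats::rnorm(n_ci_draws * length(cf)), n_ci_draws) %*%
            Ch + matrix(cf, n_ci_draws, length(cf), byrow = TRUE)
          nlev <- nlevels(y)
          probs <- t(apply(draws, 1L, function(b) {
            B <- matrix(b, nrow = nlev - 1L, byrow = TRUE)
            eta <- c(0, B[, 1L])        # evaluated at the observed point
            e <- exp(eta - max(eta)); e / sum(e)
          }))
          ciM <- t(apply(probs, 2L, stats::quantile, c(0.025, 0.975)))
          rownames(ciM) <- levels(y)
          ciM[labs, , drop = FALSE]
        }, error = function(e) NULL)
      }
    }
  }
  zero <- setdiff(labs, levels(droplevels(y)))
  if (length(zero))
    warning("scenario(s) with zero retained simulations: ",
            paste(zero, collapse = ", "))
  structure(list(posterior = post, ci = ci, rejection = rejection,
                 selected = names(post)[which.max(post)],
                 n_retained = length(sel)),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC model choice (", x$n_retained, " retained):\n", sep = "")
  for (nm in names(x$posterior)) {
    cat(sprintf("  %-24s %.3f", nm, x$posterior[[nm]]))
    if (!is.null(x$ci)) cat(sprintf("  (95%% CI %.3f-%.3f)",
                                    x$ci[nm, 1], x$ci[nm, 2]))
    cat(if (nm == x$selected) "  <- selected\n" else "\n")
  }
  invisible(x)
}

.logit <- function(x) log(x / (1 - x))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' ABC parameter posteriors by local-linear regression adjustment
#'
#' Among the retained simulations of one scenario, parameters are mapped
#' to the logit scale relative to their prior bounds, adjusted by a
#' weighted linear regression on the standardized statistics (Epanechnikov
#' weights in the retained distance range), back-transformed — so the
#' posterior always respects the prior bounds — and summarized by the
#' weighted median and 5-95% quantiles, in generations and in years via
#' the scenario's generation time. Degenerate regressions fall back to the
#' weighted rejection posterior with a warning.
#'
#' @param obs_stats observed summary-statistic vector.
#' @param scenario the `demographic_scenario` the posterior is for.
#' @param ref reference table for this scenario (from
#'   [abc_reference_table()] on `list(scenario)`), or NULL to simulate.
#' @param n_sims,sample_sizes,mut used when `ref` is NULL.
#' @param keep retained fraction.
#' @param seed optional RNG seed.
#' @return object of class `abc_posterior`: `summary` (data frame with
#'   median and q5/q95 per parameter, plus year-scale columns for time
#'   parameters), `draws` (adjusted parameter matrix), `weights`.
#' @export
abc_parameter_posterior <- function(obs_stats, scenario, ref = NULL,
                                    n_sims = 1e4L, sample_sizes = NULL,
                                    mut = NULL, keep = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ref))
    ref <- abc_reference_table(stats::setNames(list(scenario), scenario$name),
                               n_sims, sample_sizes, mut)
  sel_rows <- ref$scenario == scenario$name
  stats_m <- ref$stats[sel_rows, , drop = FALSE]
  X <- ref$params[[scenario$name]]
  std <- .standardize_stats(stats_m, obs_stats[colnames(stats_m)])
  d <- sqrt(rowSums(sweep(std$Z, 2L, std$z_obs)^2))
  n_keep <- max(20L, ceiling(keep * length(d)))
  sel <- order(d)[seq_len(n_keep)]
  dmax <- max(d[sel]) * (1 + 1e-9)
  w <- 1 - (d[sel] / dmax)^2            # Epanechnikov kernel
  w <- w / sum(w)

  pr <- scenario$priors
  lo <- vapply(pr, `[[`, numeric(1), 1L)
  hi <- vapply(pr, `[[`, numeric(1), 2L)
  Xs <- X[sel, , drop = FALSE]
  U <- sweep(sweep(Xs, 2L, lo), 2L, hi - lo, "/")
  U <- pmin(pmax(U, 1e-9), 1 - 1e-9)
  Lg <- .logit(U)

  Zc <- sweep(std$Z[sel, , drop = FALSE], 2L, std$z_obs)
  keep_cols <- apply(Zc, 2L, function(v) stats::sd(v) > 1e-10)
  adj <- Lg
  used_regression <- FALSE
  if (sum(keep_cols) >= 1L) {
    Zk <- .pc_scores(Zc[, keep_cols, drop = FALSE], length(sel))
    fit <- tryCatch(stats::lm.wfit(cbind(1, Zk), Lg, w), error = function(e) NULL)
    if (!is.null(fit)) {
      # rank-deficient fits are fine: residuals/fitted use the pivoted basis
      fit$coefficients[is.na(fit$coefficients)] <- 0
      # prediction at observed point = intercept; adjusted = intercept + residual
      adj <- matrix(fit$coefficients[1L, ], nrow(Lg), ncol(Lg), byrow = TRUE) +
        fit$residuals
      used_regression <- TRUE
    }
  }
  if (!used_regression)
    warning("degenerate regression; falling back to weighted rejection posterior")

  post <- sweep(.inv_logit(adj), 2L, hi - lo, "*")
  post <- sweep(post, 2L, lo, "+")
  colnames(post) <- names(pr)

  wq <- function(x, probs) {
    o <- order(x)
    cw <- cumsum(w[o]) / sum(w)
    x[o][vapply(probs, function(p) which(cw >= p)[1L], integer(1))]
  }
  sm <- do.call(rbind, lapply(names(pr), function(p) {
    q <- wq(post[, p], c(0.05, 0.5, 0.95))
    data.frame(parameter = p, q5 = q[1], median = q[2], q95 = q[3])
  }))
  g <- scenario$generation_time
  is_time <- grepl("^t", sm$parameter)
  sm$median_years <- ifelse(is_time, sm$median * g, NA_real_)
  sm$q5_years <- ifelse(is_time, sm$q5 * g, NA_real_)
  sm$q95_years <- ifelse(is_time, sm$q95 * g, NA_real_)

  structure(list(summary = sm, draws = post, weights = w,
                 scenario = scenario$name,
                 used_regression = used_regression,
                 generation_time = g),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("ABC parameter posterior for scenario '", x$scenario, "' (",
      if (x$used_regression) "regression-adjusted" else "rejection", "):\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Posterior predictive model checking
#'
#' Simulates datasets from parameter draws of the fitted posterior and
#' reports, per summary statistic, the two-sided tail probability of the
#' observed value (with `+1` smoothing) and a Bonferroni flag at
#' family-wise level `alpha`.
#'
#' @param scenario the fitted `demographic_scenario`.
#' @param posterior an `abc_posterior` for that scenario.
#' @param obs_stats observed summary-statistic vector.
#' @param n_draws number of predictive simulations.
#' @param sample_sizes,mut as in [abc_reference_table()].
#' @param alpha family-wise significance level.
#' @param seed optional RNG seed.
#' @return data frame with `stat`, `p`, `p_bonferroni`, `flagged`.
#' @export
posterior_predictive_check <- function(scenario, posterior, obs_stats,
                                       n_draws = 200L, sample_sizes, mut,
                                       alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(posterior$draws), n_draws, replace = TRUE,
                    prob = posterior$weights)
  sims <- matrix(NA_real_, n_draws, length(obs_stats),
                 dimnames = list(NULL, names(obs_stats)))
  for (b in seq_len(n_draws)) {
    dem <- scenario$build(posterior$draws[idx[b], ])
    sim <- simulate_coalescent(dem, sample_sizes, mut)
    sims[b, ] <- summary_stats(sim$seqs, sim$deme)[names(obs_stats)]
  }
  p <- vapply(names(obs_stats), function(s) {
    lo <- (sum(sims[, s] <= obs_stats[[s]]) + 1) / (n_draws + 1)
    hi <- (sum(sims[, s] >= obs_stats[[s]]) + 1) / (n_draws + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  m <- length(p)
  data.frame(stat = names(p), p = unname(p),
             p_bonferroni = pmin(1, unname(p) * m),
             flagged = unname(p) * m < alpha)
}
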