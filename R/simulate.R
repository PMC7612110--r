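#' Define a multi-endpoint two-arm trial scenario
#'
#' The observed per-endpoint mean vectors of the control and experimental
#' arms are drawn as \eqn{\bar X_G \sim N(\mu_G, \Sigma_G)} with
#' \eqn{\Sigma_G = \mathrm{diag}(\sigma_G/\sqrt{n_G})\, \Sigma(\rho)\,
#' \mathrm{diag}(\sigma_G/\sqrt{n_G})}, where \eqn{\Sigma(\rho)} has unit
#' diagonal and common off-diagonal correlation \eqn{\rho} (or a full
#' matrix).  The test statistic for endpoint \eqn{i} is the standardized
#' mean difference \eqn{T_i = (\bar X_i^E - \bar X_i^C) /
#' \widehat{SE}}, referred to a t distribution with Welch-Satterthwaite
#' degrees of freedom (`use_t = TRUE`, per-endpoint sample variances drawn
#' from their scaled chi-square distributions) or to a standard normal with
#' the true variances (`use_t = FALSE`).  Independent extra statistics
#' (e.g. a secondary endpoint with a normally distributed z statistic) can
#' be appended.
#'
#' @param means_control,means_experimental per-endpoint true means.
#' @param sds_control,sds_experimental per-observation standard deviations.
#' @param n_control,n_experimental per-arm sample sizes.
#' @param correlation common correlation \eqn{\rho} or a full matrix.
#' @param hypothesis_names labels for the endpoint hypotheses.
#' @param extra_statistics optional data frame with columns `name`, `mean`,
#'   `sd`, `null` for independent normal z statistics.
#' @param use_t logical; t reference with estimated variances, else normal.
#' @param one_sided currently only one-sided upper tests are generated.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(means_control, means_experimental,
                                sds_control, sds_experimental,
                                n_control, n_experimental,
                                correlation = 0,
                                hypothesis_names =
                                  paste0("H", seq_along(means_control)),
                                extra_statistics = NULL,
                                use_t = TRUE, one_sided = TRUE) {
  k <- length(means_control)
  stopifnot(length(means_experimental) == k, length(sds_control) == k,
            length(sds_experimental) == k, k >= 0)
  if (any(c(sds_control, sds_experimental) <= 0))
    stop("standard deviations must be positive")
  if (is.matrix(correlation)) {
    stopifnot(all(dim(correlation) == c(k, k)))
  } else {
    stopifnot(abs(correlation) < 1)
    correlation <- matrix(correlation, k, k)
    diag(correlation) <- 1
  }
  if (!is.null(extra_statistics)) {
    stopifnot(is.data.frame(extra_statistics),
              all(c("name", "mean", "sd", "null") %in%
                    names(extra_statistics)))
  }
  structure(list(
    means_control = means_control, means_experimental = means_experimental,
    sds_control = sds_control, sds_experimental = sds_experimental,
    n_control = n_control, n_experimental = n_experimental,
    correlation = correlation, hypothesis_names = hypothesis_names,
    extra_statistics = extra_statistics, use_t = use_t,
    one_sided = one_sided), class = "simulation_scenario")
}

scenario_truth <- function(scenario) {
  nulls <- scenario$means_experimental == scenario$means_control
  nm <- scenario$hypothesis_names
  if (!is.null(scenario$extra_statistics)) {
    nulls <- c(nulls, scenario$extra_statistics$null)
    nm <- c(nm, scenario$extra_statistics$name)
  }
  stats::setNames(nulls, nm)
}

#' Simulate one replicate of trial p-values
#'
#' Deterministic given `(seed, replicate_index)`.  Returns one-sided upper
#' p-values aligned with the scenario's hypothesis names, with the truth
#' labels (`TRUE` = null) as attribute `"null"`.
#'
#' @param scenario a [simulation_scenario].
#' @param replicate_index positive integer.
#' @param seed base RNG seed.
#' @return named numeric p-value vector with attribute `null`.
#' @export
generate_trial_pvalues <- function(scenario, replicate_index = 1L,
                                   seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed((as.integer(seed) + 7919L * as.integer(replicate_index)) %%
             .Machine$integer.max)
  k <- length(scenario$means_control)
  p <- numeric(0)
  if (k > 0) {
    Rchol <- chol(scenario$correlation)
    seC <- scenario$sds_control / sqrt(scenario$n_control)
    seE <- scenario$sds_experimental / sqrt(scenario$n_experimental)
    xC <- scenario$means_control + seC * drop(crossprod(Rchol,
                                                        stats::rnorm(k)))
    xE <- scenario$means_experimental + seE * drop(crossprod(Rchol,
                                                             stats::rnorm(k)))
    if (scenario$use_t) {
      nC <- scenario$n_control; nE <- scenario$n_experimental
      s2C <- scenario$sds_control^2 *
        stats::rchisq(k, nC - 1) / (nC - 1)
      s2E <- scenario$sds_experimental^2 *
        stats::rchisq(k, nE - 1) / (nE - 1)
      vhat <- s2C / nC + s2E / nE
      df <- vhat^2 / ((s2C / nC)^2 / (nC - 1) + (s2E / nE)^2 / (nE - 1))
      tstat <- (xE - xC) / sqrt(vhat)
      p <- stats::pt(tstat, df = df, lower.tail = FALSE)
    } else {
      z <- (xE - xC) / sqrt(seC^2 + seE^2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    names(p) <- scenario$hypothesis_names
  }
  if (!is.null(scenario$extra_statistics)) {
    ex <- scenario$extra_statistics
    zx <- stats::rnorm(nrow(ex), mean = ex$mean, sd = ex$sd)
    px <- stats::setNames(stats::pnorm(zx, lower.tail = FALSE), ex$name)
    p <- c(p, px)
  }
  attr(p, "null") <- scenario_truth(scenario)
  p
}

#' Estimate operating characteristics of a testing procedure
#'
#' Applies `procedure` (a function taking the named p-value vector and
#' returning the rejected hypothesis names, or a `graph_test` object) to
#' `replications` simulated trials and estimates the k-FWER for each `k`,
#' the FDP tail probability for each `gamma`, the FDR, and per-hypothesis
#' marginal rejection frequencies, each with its Monte-Carlo standard
#' error \eqn{\sqrt{f(1-f)/\mathrm{reps}}}.
#'
#' @param procedure function of the p-value vector.
#' @param scenario a [simulation_scenario].
#' @param ks integer vector of k values for the k-FWER estimates.
#' @param gammas numeric vector of FDP thresholds.
#' @param replications number of simulated trials.
#' @param seed RNG seed (forwarded to [generate_trial_pvalues()]).
#' @return object of class `operating_characteristics`.
#' @export
estimate_operating_characteristics <- function(procedure, scenario,
                                               ks = 1L, gammas = numeric(0),
                                               replications = 1e4,
                                               seed = 1L) {
  stopifnot(replications >= 1)
  truth <- scenario_truth(scenario)
  nm <- names(truth)
  rej_count <- stats::setNames(numeric(length(nm)), nm)
  V <- R <- fdp <- numeric(replications)
  for (b in seq_len(replications)) {
    p <- generate_trial_pvalues(scenario, b, seed)
    rej <- procedure(p)
    if (inherits(rej, "graph_test")) rej <- rej$rejected
    rej_count[rej] <- rej_count[rej] + 1
    R[b] <- length(rej)
    V[b] <- sum(truth[rej])
    fdp[b] <- V[b] / max(R[b], 1)
  }
  se <- function(f) sqrt(f * (1 - f) / replications)
  kfwer <- stats::setNames(vapply(ks, function(k) mean(V >= k),
                                  numeric(1)), paste0("k=", ks))
  fdptail <- if (length(gammas))
    stats::setNames(vapply(gammas, function(g) mean(fdp > g), numeric(1)),
                    paste0("gamma=", gammas)) else numeric(0)
  marg <- rej_count / replications
  structure(list(
    replications = replications, seed = seed,
    kfwer = kfwer, kfwer_se = se(kfwer),
    fdp_tail = fdptail, fdp_tail_se = se(fdptail),
    fdr = mean(fdp), fdr_se = stats::sd(fdp) / sqrt(replications),
    marginal_power = marg, marginal_power_se = se(marg),
    type1_per_hypothesis = marg[truth],
    truth_null = truth), class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("Operating characteristics from", x$replications, "replications\n")
  if (length(x$kfwer)) {
    cat("k-FWER:\n")
    print(signif(x$kfwer, 4))
  }
  if (length(x$fdp_tail)) {
    cat("P(FDP > gamma):\n")
    print(signif(x$fdp_tail, 4))
  }
  cat("FDR:", signif(x$fdr, 4), "\n")
  cat("Marginal rejection frequency:\n")
  print(signif(x$marginal_power, 4))
  invisible(x)
}
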