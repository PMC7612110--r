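#' Dependence model for weighted parametric tests
#'
#' Describes the joint distribution of the one-sided (upper-tailed) test
#' statistics as multivariate normal with the given correlation matrix, so
#' that \eqn{p_j = 1 - \Phi(Z_j)} with \eqn{(Z_1, \ldots, Z_m)} jointly
#' normal.
#'
#' @param correlation correlation matrix (unit diagonal, symmetric,
#'   positive semi-definite), or the string `"exchangeable:RHO"` together
#'   with `m` for an equicorrelated model.
#' @param m dimension, required for the shorthand form.
#' @return object of class `dependence_model` wrapping the matrix.
#' @export
dependence_model <- function(correlation, m = NULL) {
  if (is.character(correlation)) {
    if (!grepl("^exchangeable:", correlation))
      stop("string form must be 'exchangeable:RHO'")
    rho <- as.numeric(sub("^exchangeable:", "", correlation))
    if (is.null(m)) stop("'m' is required with the exchangeable shorthand")
    correlation <- matrix(rho, m, m)
    diag(correlation) <- 1
  }
  correlation <- as.matrix(correlation)
  if (!isSymmetric(unname(correlation), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(correlation) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9)
    stop("correlation matrix must be positive semi-definite")
  structure(list(correlation = correlation), class = "dependence_model")
}

# P(Z_j < upper_j for all j) for MVN with correlation R; deterministic.
mvn_rect_prob <- function(upper, R) {
  d <- length(upper)
  if (d == 1L) return(stats::pnorm(upper))
  if (all(abs(R[upper.tri(R)] - 1) < 1e-12))    # perfectly correlated
    return(stats::pnorm(min(upper)))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  alg <- if (d <= 19 && min(ev) > 1e-8) mvtnorm::Miwa(steps = 512)
         else mvtnorm::GenzBretz(abseps = 1e-8, maxpts = 50000)
  # pin the RNG so the quasi-Monte-Carlo fallback is reproducible
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20200617L)
  as.numeric(mvtnorm::pmvnorm(upper = upper, corr = R, algorithm = alg))
}

# P(any p_j <= c w_j alpha) under the model, one-sided upper tests
union_rejection_prob <- function(cc, weights, R, alpha) {
  t_j <- pmin(cc * weights * alpha, 1)
  pos <- weights > 0
  if (!any(pos)) return(0)
  if (all(t_j[pos] >= 1)) return(1)
  up <- stats::qnorm(1 - t_j[pos])
  1 - mvn_rect_prob(up, R[pos, pos, drop = FALSE])
}

#' Parametric critical constant c_J
#'
#' The largest constant such that the probability of rejecting any
#' \eqn{H_j}, \eqn{j \in J}, at thresholds \eqn{c_J w_j(J) \alpha} equals
#' \eqn{\alpha} under the joint normal model.  Found by bisection to
#' absolute tolerance 1e-6; always \eqn{\ge 1}, reaching \eqn{1/\max_j
#' w_j(J)} under perfect positive correlation.  Hypotheses with zero weight
#' contribute no rejection event.
#'
#' @param weights numeric vector \eqn{w_j(J)} (at least one positive,
#'   summing to at most 1).
#' @param model a [dependence_model] restricted to `J` (or a bare
#'   correlation matrix); `NULL` means unknown dependence, returning
#'   `c = 1` (the Bonferroni fallback).
#' @param alpha level in (0, 1).
#' @return scalar \eqn{c_J \ge 1}.
#' @export
compute_cJ <- function(weights, model, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  weights <- as.numeric(weights)
  if (sum(weights) > 1 + 1e-9) stop("weights must sum to at most 1")
  if (all(weights <= 0)) stop("at least one weight must be positive")
  if (is.null(model)) return(1)
  if (!inherits(model, "dependence_model")) model <- dependence_model(model)
  R <- model$correlation
  if (nrow(R) != length(weights))
    stop("model dimension does not match the number of weights")
  wmax <- max(weights)
  hi <- 1 / (wmax * alpha)            # thresholds capped at 1 beyond this
  f <- function(cc) union_rejection_prob(cc, weights, R, alpha) - alpha
  if (f(1) >= 0) return(1)            # Bonferroni already exhausts alpha
  if (f(hi) <= 0) return(hi)
  lo <- 1
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Check the parametric monotonicity condition
#'
#' For the weighted parametric test the shortcut is valid only when
#' \eqn{c_J w_j(J) \le c_{J'} w_j(J')} for all nested \eqn{J' \subseteq J}
#' and \eqn{j \in J'}.  Unlike the Bonferroni weights, this condition is
#' often violated; violations are reported, not raised.
#'
#' @param graph a [hypothesis_graph].
#' @param model a [dependence_model] over all `m` hypotheses.
#' @param alpha level in (0, 1).
#' @param max_m_exhaustive refuse enumeration above this size.
#' @param tol violation slack.
#' @return data frame of violations with the two subsets, the hypothesis
#'   and both scaled weights; zero rows if the condition holds.
#' @export
check_parametric_monotonicity <- function(graph, model, alpha,
                                          max_m_exhaustive = 10,
                                          tol = 1e-9) {
  m <- length(graph$names)
  if (m > max_m_exhaustive)
    stop("subset enumeration limited to m <= ", max_m_exhaustive)
  if (!inherits(model, "dependence_model")) model <- dependence_model(model)
  R <- model$correlation
  subsets <- .all_subsets(m)
  cw <- list()
  for (si in seq_along(subsets)) {
    J <- subsets[[si]]
    wJ <- unname(intersection_weights(graph, J))
    cJ <- if (all(wJ <= 0)) 1 else
      compute_cJ(wJ, dependence_model(R[J, J, drop = FALSE]), alpha)
    cw[[si]] <- stats::setNames(cJ * wJ, graph$names[J])
  }
  out <- data.frame(J_prime = character(0), J = character(0),
                    hypothesis = character(0), cw_J = numeric(0),
                    cw_J_prime = numeric(0), stringsAsFactors = FALSE)
  enc <- vapply(subsets, function(J) sum(2^(J - 1L)), numeric(1))
  for (si in seq_along(subsets)) {
    J <- subsets[[si]]
    for (ti in seq_along(subsets)) {
      Jp <- subsets[[ti]]
      if (length(Jp) >= length(J)) next
      if (bitwAnd(enc[ti], enc[si]) != enc[ti]) next  # Jp not a subset of J
      for (nmj in graph$names[Jp]) {
        if (cw[[si]][nmj] > cw[[ti]][nmj] + tol)
          out <- rbind(out, data.frame(
            J_prime = paste(graph$names[Jp], collapse = ","),
            J = paste(graph$names[J], collapse = ","),
            hypothesis = nmj, cw_J = unname(cw[[si]][nmj]),
            cw_J_prime = unname(cw[[ti]][nmj]), stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Weighted parametric graphical FWER test
#'
#' The graphical shortcut with thresholds \eqn{c_I w_i(I) \alpha}: the
#' Bonferroni thresholds inflated by the parametric constant of the current
#' active set.  Valid only when the parametric monotonicity condition
#' holds; the test verifies it first and refuses (listing the violating
#' subset pairs) otherwise.  With `model = NULL` every \eqn{c_I = 1} and the
#' test reduces to [graphical_fwer_test()].
#'
#' @inheritParams graphical_fwer_test
#' @param model a [dependence_model] for all hypotheses, or `NULL`.
#' @param check logical; verify monotonicity before testing.
#' @return a `graph_test`.
#' @export
parametric_fwer_test <- function(graph, p, model, alpha, check = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  p <- align_pvalues(graph, p)
  if (is.null(model))
    return(graphical_fwer_test(graph, p, alpha))
  if (!inherits(model, "dependence_model")) model <- dependence_model(model)
  if (check) {
    viol <- check_parametric_monotonicity(graph, model, alpha)
    if (nrow(viol))
      stop("parametric monotonicity is violated; the shortcut is invalid.\n",
           paste(utils::capture.output(print(viol)), collapse = "\n"))
  }
  R <- model$correlation
  cfun <- function(state) {
    idx <- match(state$names, graph$names)
    w <- unname(state$weights)
    if (all(w <= 0)) 1 else
      compute_cJ(w, dependence_model(R[idx, idx, drop = FALSE]), alpha)
  }
  res <- shortcut_continue(graph, p, alpha, stage = "base", cfun = cfun)
  new_graph_test("parametric-fwer", res$rejected, res$trace, alpha, graph,
                 extra = list(state = res$state))
}
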