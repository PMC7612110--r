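#' Number of augmentation rejections permitted by an FDP bound
#'
#' The largest integer \eqn{D} with \eqn{D / (D + |R|) \le \gamma}, capped
#' at the number of remaining hypotheses.  For \eqn{|R| \ge 1} this equals
#' \eqn{\lfloor \gamma |R| / (1 - \gamma) \rfloor}; for \eqn{|R| = 0} it is
#' 0 (there is nothing to augment without a rejection backbone).
#'
#' @param num_rejected number of stage-1 (FWER) rejections, \eqn{|R|}.
#' @param gamma FDP bound in \eqn{[0, 1)}.
#' @param num_remaining number of unrejected hypotheses (may be `Inf`).
#' @return integer \eqn{D \ge 0}.
#' @examples
#' augmentation_count(2, 0.45) # 1
#' augmentation_count(2, 0.5)  # 2
#' @export
augmentation_count <- function(num_rejected, gamma, num_remaining = Inf) {
  if (gamma < 0 || gamma >= 1) stop("'gamma' must lie in [0, 1)")
  stopifnot(num_rejected >= 0)
  if (num_rejected == 0) return(0L)
  D <- floor(gamma * num_rejected / (1 - gamma) + 1e-9)
  # guard against floating error on rational boundaries
  while ((D + 1) / (D + 1 + num_rejected) <= gamma + 1e-12) D <- D + 1
  while (D > 0 && D / (D + num_rejected) > gamma + 1e-12) D <- D - 1
  as.integer(min(D, num_remaining))
}

#' Augmented graphical procedure for FDP control
#'
#' Stage 1 runs the graphical FWER shortcut at level `alpha`, giving `|R|`
#' rejections.  The augmentation budget `D` is then fixed once via
#' [augmentation_count()] (it is not recomputed as augmented rejections
#' accrue) and the shortcut continues on the remaining graph at level
#' `delta` for up to `D` further rejections.  Controls
#' \eqn{P(\mathrm{FDP} > \gamma) \le \alpha}; `gamma = 0` reduces to FWER
#' control.
#'
#' @inheritParams augmented_kfwer
#' @param gamma FDP bound in \eqn{[0, 1)}.
#' @return a `graph_test` with stages `"base"` and `"augmented"`.
#' @export
augmented_fdp <- function(graph, p, alpha, gamma, delta = 1) {
  check_config(alpha, delta = delta, gamma = gamma)
  p <- align_pvalues(graph, p)
  s1 <- shortcut_continue(graph, p, alpha, stage = "base")
  D <- augmentation_count(length(s1$rejected), gamma,
                          length(s1$state$names))
  s2 <- shortcut_continue(s1$state, p, delta, max_rejections = D,
                          stage = "augmented")
  new_graph_test("aug-fdp", c(s1$rejected, s2$rejected),
                 rbind(s1$trace, s2$trace), alpha, graph,
                 extra = list(gamma = gamma, delta = delta, D = D,
                              state = s2$state))
}

#' Adjusted augmented graphical procedure for FDP control
#'
#' Thresholds the adjusted p-values at `alpha`, then additionally rejects
#' the `min(|I|, D)` remaining hypotheses with the smallest adjusted values
#' (ties broken by the shortcut's removal sequence, then smallest index),
#' with `D` from [augmentation_count()].  Equals [augmented_fdp()] with
#' `delta` large enough.
#'
#' @inheritParams augmented_fdp
#' @return a `graph_test` with adjusted p-values attached.
#' @export
adjusted_augmented_fdp <- function(graph, p, alpha, gamma) {
  check_config(alpha, gamma = gamma)
  p <- align_pvalues(graph, p)
  adj <- adjusted_pvalues(graph, p)
  base <- graph$names[adj <= alpha]
  rest <- setdiff(graph$names, base)
  D <- augmentation_count(length(base), gamma, length(rest))
  ord <- order_by_adjusted(adj, rest, graph)
  extra <- utils::head(ord, min(length(rest), D))
  trace <- data.frame(
    hypothesis = c(base, extra), p = unname(p[c(base, extra)]),
    threshold = c(rep(alpha, length(base)), rep(NA_real_, length(extra))),
    stage = c(rep("base", length(base)), rep("augmented", length(extra))),
    stringsAsFactors = FALSE)
  new_graph_test("adj-aug-fdp", c(base, extra), trace, alpha, graph,
                 adjusted = adj, extra = list(gamma = gamma, D = D))
}

#' Generalized graphical procedure for (asymptotic) FDP control
#'
#' Runs the generalized graphical k-FWER procedure for \eqn{k_j = 1, 2,
#' \ldots}; after round `j`, stops and returns that round's rejections as
#' soon as \eqn{|R_j| < k_j/\gamma - 1} (strict inequality, exactly as the
#' stopping rule is stated), with a hard cap at \eqn{k_j = m} to guarantee
#' termination.  `gamma = 0` is defined as the `k = 1` round alone, which
#' is FWER control.
#'
#' @inheritParams augmented_fdp
#' @param free_rejections passed to [generalized_kfwer()] for each round.
#' @return a `graph_test`; `rounds` records each round's `k` and
#'   rejection count.
#' @export
generalized_fdp <- function(graph, p, alpha, gamma, delta = 1,
                            free_rejections = TRUE) {
  check_config(alpha, delta = delta, gamma = gamma)
  p <- align_pvalues(graph, p)
  m <- length(graph$names)
  rounds <- data.frame(k = integer(0), rejections = integer(0))
  kj <- 1L
  repeat {
    res <- generalized_kfwer(graph, p, alpha, kj, delta = delta,
                             free_rejections = free_rejections)
    rounds <- rbind(rounds, data.frame(k = kj,
                                       rejections = length(res$rejected)))
    stop_now <- gamma == 0 || length(res$rejected) < kj / gamma - 1 ||
      kj >= m
    if (stop_now) {
      return(new_graph_test("gen-fdp", res$rejected, res$trace, alpha,
                            graph, extra = list(gamma = gamma,
                                                delta = delta,
                                                rounds = rounds)))
    }
    kj <- kj + 1L
  }
}

#' FDR bounds implied by FDP control at level alpha
#'
#' An FDP-controlling procedure at tail level `alpha` and proportion bound
#' `gamma` asymptotically controls the FDR at \eqn{2\alpha}; the
#' Lehmann-Romano argument gives the finite-sample bound
#' \eqn{\alpha^* = \alpha(1-\gamma) + \gamma}.  The latter is smaller
#' precisely when \eqn{\gamma < \alpha / (1 - \gamma)}.
#'
#' @param alpha FDP tail level in (0, 1).
#' @param gamma FDP bound in \eqn{[0, 1)}.
#' @return list with `asymptotic` (\eqn{2\alpha}), `lehmann_romano`
#'   (\eqn{\alpha(1-\gamma)+\gamma}, finite-sample valid), `smaller`
#'   (which bound is smaller) and `lr_beats_asymptotic`
#'   (the condition \eqn{\gamma < \alpha/(1-\gamma)}).
#' @export
fdr_bounds <- function(alpha, gamma) {
  check_config(alpha, gamma = gamma)
  asym <- 2 * alpha
  lr <- alpha * (1 - gamma) + gamma
  list(asymptotic = asym, lehmann_romano = lr,
       smaller = if (lr < asym) "lehmann_romano" else "asymptotic",
       lr_beats_asymptotic = gamma < alpha / (1 - gamma))
}
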