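#' Generalized (weighted) Bonferroni procedure for k-FWER control
#'
#' Rejects any \eqn{H_i} with \eqn{p_i \le k\alpha/m} (unweighted) or
#' \eqn{p_i \le w_i k \alpha} for known positive weights summing to one.
#' Single-step, no graph propagation.
#'
#' @param p numeric vector of p-values (optionally named).
#' @param k integer \eqn{\ge 1}: the number of tolerated false rejections.
#' @param alpha significance level in (0, 1).
#' @param weights optional per-hypothesis weights summing to 1.
#' @return character vector of rejected hypothesis names (or indices as
#'   character when `p` is unnamed).
#' @export
generalized_bonferroni <- function(p, k, alpha, weights = NULL) {
  stopifnot(k >= 1, alpha > 0, alpha < 1)
  m <- length(p)
  if (is.null(names(p))) names(p) <- as.character(seq_len(m))
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m) stop("'weights' must match the length of 'p'")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1 (got ", format(sum(weights)), ")")
  names(p)[p <= weights * k * alpha]
}

check_config <- function(alpha, k = 1, delta = 0, gamma = 0) {
  stopifnot(alpha > 0, alpha < 1)
  if (k < 1 || k != floor(k)) stop("'k' must be an integer >= 1")
  if (delta < 0) stop("'delta' must be >= 0 (Inf allowed)")
  if (gamma < 0 || gamma >= 1) stop("'gamma' must lie in [0, 1)")
  invisible(TRUE)
}

#' Augmented graphical procedure for k-FWER control
#'
#' Stage 1 runs the usual Bonferroni-based graphical FWER shortcut at level
#' `alpha`.  Stage 2 continues the shortcut on the remaining (updated) graph
#' with `alpha` replaced by the augmentation level `delta`, selecting
#' \eqn{j = \arg\min_i p_i / w_i(I)} at each step, until `k - 1` additional
#' rejections have been made or no active hypothesis satisfies
#' \eqn{p_j \le w_j(I)\,\delta}.  `delta = Inf` takes every available free
#' rejection regardless of the p-values (zero-weight hypotheses excepted).
#'
#' @inheritParams graphical_fwer_test
#' @param k integer \eqn{\ge 1}.
#' @param delta augmentation level \eqn{\ge 0}; may exceed `alpha` or be
#'   `Inf`.
#' @return a `graph_test`; trace rows are labelled `"base"` or
#'   `"augmented"`.
#' @examples
#' g <- example_graph("diabetes")
#' p <- c(H1 = 0.01, H2 = 0.03, H3 = 0.02, H4 = 0.024)
#' augmented_kfwer(g, p, alpha = 0.05, k = 2, delta = 0.5)
#' @export
augmented_kfwer <- function(graph, p, alpha, k, delta = 1) {
  check_config(alpha, k = k, delta = delta)
  p <- align_pvalues(graph, p)
  s1 <- shortcut_continue(graph, p, alpha, stage = "base")
  s2 <- shortcut_continue(s1$state, p, delta, max_rejections = k - 1,
                          stage = "augmented")
  new_graph_test("aug-kfwer", c(s1$rejected, s2$rejected),
                 rbind(s1$trace, s2$trace), alpha, graph,
                 extra = list(k = k, delta = delta, state = s2$state))
}

#' Adjusted augmented graphical procedure for k-FWER control
#'
#' Rejects every hypothesis whose adjusted p-value is at most `alpha`, then
#' additionally rejects the `min(|I|, k - 1)` remaining hypotheses with the
#' smallest adjusted p-values.  Ties among equal adjusted values are broken
#' by the position in the shortcut's removal sequence and then by the
#' smallest index, which makes this data-dependent-`delta` formulation of
#' [augmented_kfwer()] coincide with it for `delta` large enough.
#'
#' @inheritParams augmented_kfwer
#' @return a `graph_test` with the adjusted p-values attached.
#' @export
adjusted_augmented_kfwer <- function(graph, p, k, alpha) {
  check_config(alpha, k = k)
  p <- align_pvalues(graph, p)
  adj <- adjusted_pvalues(graph, p)
  base <- graph$names[adj <= alpha]
  rest <- setdiff(graph$names, base)
  ord <- order_by_adjusted(adj, rest, graph)
  extra <- utils::head(ord, min(length(rest), k - 1))
  trace <- data.frame(
    hypothesis = c(base, extra), p = unname(p[c(base, extra)]),
    threshold = c(rep(alpha, length(base)), rep(NA_real_, length(extra))),
    stage = c(rep("base", length(base)), rep("augmented", length(extra))),
    stringsAsFactors = FALSE)
  new_graph_test("adj-aug-kfwer", c(base, extra), trace, alpha, graph,
                 adjusted = adj, extra = list(k = k))
}

#' Generalized graphical procedure for k-FWER control
#'
#' The stepdown procedure that accounts for up to `k - 1` possibly-false
#' earlier rejections.  Step (ii) rejects \eqn{\{i : p_i \le w_i(M) k
#' \alpha\}} using the initial weights only.  If fewer than `k` hypotheses
#' are rejected (or everything is), the procedure stops -- invoking, when
#' `free_rejections` is `TRUE` and fewer than `k - 1` rejections were made,
#' the free-rejection subprocedure which continues the FWER shortcut on the
#' remaining graph at level `delta` until the total reaches `k - 1`.
#' Otherwise it iterates: reject any active \eqn{H_i} with
#' \deqn{p_i \le \min_{J \subseteq R, |J| = k-1} w_i(I \cup J)\, k \alpha,}
#' where the minimum runs over all subsets of the previously rejected set
#' `R` of size `k - 1`, computed by exact enumeration via
#' [intersection_weights()].
#'
#' @inheritParams augmented_kfwer
#' @param free_rejections logical; apply the free-rejection subprocedure at
#'   the early-stopping step.
#' @return a `graph_test`; trace stages are `"base"` (step ii),
#'   `"stepdown"` (step iv) and `"free"`.
#' @export
generalized_kfwer <- function(graph, p, alpha, k, delta = 1,
                              free_rejections = TRUE) {
  check_config(alpha, k = k, delta = delta)
  p <- align_pvalues(graph, p)
  nm <- graph$names
  entangled <- inherits(graph, "entangled_graph")
  # weights of the intersection hypothesis indexed by `keep`; the entangled
  # route uses the c-weighted component propagation (its weighting strategy
  # also satisfies the monotonicity condition, so the stepdown applies)
  wfun <- function(keep) {
    if (entangled) entangled_weights(graph, setdiff(nm, keep))
    else intersection_weights(graph, keep)
  }
  wM <- wfun(nm)
  thr0 <- unname(wM[nm]) * k * alpha
  R <- nm[p[nm] <= thr0]
  trace <- data.frame(hypothesis = R, p = unname(p[R]),
                      threshold = thr0[match(R, nm)],
                      stage = rep("base", length(R)),
                      stringsAsFactors = FALSE)
  I <- setdiff(nm, R)
  if (length(R) < k || length(I) == 0L) {
    if (free_rejections && length(R) < k - 1 && length(I) > 0L) {
      fr <- if (entangled) {
        entangled_continue(graph, R, p, delta,
                           max_rejections = k - 1 - length(R),
                           stage = "free")
      } else {
        st <- graph
        for (r in R) st <- remove_hypothesis(st, r)
        shortcut_continue(st, p, delta,
                          max_rejections = k - 1 - length(R),
                          stage = "free")
      }
      R <- c(R, fr$rejected)
      trace <- rbind(trace, fr$trace)
    }
    return(new_graph_test("gen-kfwer", R, trace, alpha, graph,
                          extra = list(k = k, delta = delta)))
  }
  repeat {
    if (choose(length(R), k - 1) > 1e6)
      stop("step (iv) would enumerate choose(", length(R), ", ", k - 1,
           ") subsets; this exceeds the supported problem size")
    subsetsJ <- if (k == 1) list(character(0)) else
      utils::combn(R, k - 1, simplify = FALSE)
    wmin <- rep(Inf, length(I))
    for (J in subsetsJ) {
      wK <- wfun(c(I, J))
      wmin <- pmin(wmin, unname(wK[I]))
    }
    thr <- wmin * k * alpha
    sel <- p[I] <= thr
    if (!any(sel)) break
    newR <- I[sel]
    trace <- rbind(trace, data.frame(
      hypothesis = newR, p = unname(p[newR]), threshold = thr[sel],
      stage = rep("stepdown", length(newR)), stringsAsFactors = FALSE))
    R <- c(R, newR)
    I <- setdiff(I, newR)
    if (!length(I)) break
  }
  new_graph_test("gen-kfwer", R, trace, alpha, graph,
                 extra = list(k = k, delta = delta))
}
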