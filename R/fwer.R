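# Sequentially rejective shortcut engine shared by the FWER test and all
# augmented stages.  At each step the candidate is j = argmin p_j / w_j(I)
# (ratio +Inf for zero weight, ties broken by the smallest index in the
# original graph); it is rejected when p_j <= c_I * w_j(I) * level, using
# plain <= so that a p-value exactly on the threshold rejects.  `cfun`, when
# given, returns the parametric inflation constant c_I for the current
# active set; otherwise c_I = 1 (weighted Bonferroni).
shortcut_continue <- function(state, p, level, max_rejections = Inf,
                              stage = "base", cfun = NULL) {
  rejected <- character(0)
  trace <- list()
  while (length(rejected) < max_rejections && length(state$names) > 0L) {
    w <- unname(state$weights)
    pa <- p[state$names]
    cI <- if (is.null(cfun)) 1 else cfun(state)
    thr <- cI * w * level
    thr[w <= 0] <- 0          # covers level = Inf: 0 * Inf would be NaN
    ratio <- ifelse(w > 0, pa / w, ifelse(pa == 0, 0, Inf))
    j <- which.min(ratio)     # ties: first index, i.e. smallest label order
    if (!(pa[j] <= thr[j])) break
    nmj <- state$names[j]
    rejected <- c(rejected, nmj)
    trace[[length(trace) + 1L]] <- data.frame(
      hypothesis = nmj, p = unname(pa[j]), threshold = unname(thr[j]),
      stage = stage, stringsAsFactors = FALSE)
    state <- remove_hypothesis(state, j)
  }
  list(rejected = rejected, state = state,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(hypothesis = character(0), p = numeric(0),
                    threshold = numeric(0), stage = character(0),
                    stringsAsFactors = FALSE))
}

new_graph_test <- function(procedure, rejected, trace, alpha, graph,
                           adjusted = NULL, extra = list()) {
  structure(
    c(list(procedure = procedure, rejected = rejected, trace = trace,
           adjusted = adjusted, alpha = alpha, graph = graph), extra),
    class = "graph_test")
}

#' @export
print.graph_test <- function(x, ...) {
  cat("Graphical multiple testing procedure:", x$procedure, "\n")
  cat("alpha =", format(x$alpha, digits = 6))
  for (f in c("k", "gamma", "delta"))
    if (!is.null(x[[f]])) cat(", ", f, " = ", format(x[[f]], digits = 6),
                              sep = "")
  cat("\n")
  if (length(x$rejected))
    cat("Rejected (", length(x$rejected), "): ",
        paste(x$rejected, collapse = ", "), "\n", sep = "")
  else cat("Rejected: none\n")
  invisible(x)
}

#' @export
summary.graph_test <- function(object, ...) {
  print(object)
  cat("\nRejection trace:\n")
  tr <- object$trace
  tr$threshold <- signif(tr$threshold, 6)
  print(tr, row.names = FALSE)
  if (!is.null(object$adjusted)) {
    cat("\nAdjusted p-values:\n")
    print(signif(object$adjusted, 6))
  }
  invisible(object)
}

#' Bonferroni-based graphical test for FWER control
#'
#' The sequentially rejective shortcut: reject any active \eqn{H_j} with
#' \eqn{p_j \le w_j(I)\,\alpha}, remove it from the graph (propagating its
#' level), and repeat until no hypothesis qualifies.  The final rejection set
#' does not depend on the order in which qualifying hypotheses are removed;
#' the implementation removes the hypothesis minimising \eqn{p_j / w_j(I)}
#' so that the recorded trace is deterministic and matches the selection
#' rule used by the augmented procedures.
#'
#' @param graph a [hypothesis_graph].
#' @param p numeric vector of p-values, named by hypothesis or aligned with
#'   `graph$names`.
#' @param alpha overall significance level in (0, 1).
#' @return a `graph_test` object: `rejected` (ordered), `trace`
#'   (one row per rejection with the threshold used), `alpha`.
#' @examples
#' g <- holm_graph(3)
#' graphical_fwer_test(g, c(H1 = 0.01, H2 = 0.2, H3 = 0.03), alpha = 0.05)
#' @export
graphical_fwer_test <- function(graph, p, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  p <- align_pvalues(graph, p)
  res <- shortcut_continue(graph, p, alpha, stage = "base")
  new_graph_test("fwer", res$rejected, res$trace, alpha, graph,
                 extra = list(state = res$state))
}

#' Adjusted p-values for the graphical FWER procedure
#'
#' The adjusted p-value of \eqn{H_j} is the smallest overall level at which
#' the shortcut rejects it.  It is computed sequentially: repeatedly select
#' the active hypothesis minimising \eqn{p_j / w_j(I)} (only hypotheses with
#' positive current weight are selectable), record the running maximum of
#' that ratio capped at 1, and remove the hypothesis.  Hypotheses that are
#' never selectable (weight permanently zero) receive adjusted value 1.
#'
#' @inheritParams graphical_fwer_test
#' @return named numeric vector of adjusted p-values in (0, 1].
#' @export
adjusted_pvalues <- function(graph, p) {
  p <- align_pvalues(graph, p)
  adj <- stats::setNames(rep(1, length(graph$names)), graph$names)
  state <- graph
  running <- 0
  selection <- character(0)
  repeat {
    w <- unname(state$weights)
    if (!length(w) || all(w <= 0)) break
    pa <- p[state$names]
    ratio <- ifelse(w > 0, pa / w, Inf)
    j <- which.min(ratio)
    running <- max(running, ratio[j])
    adj[state$names[j]] <- min(1, running)
    selection <- c(selection, state$names[j])
    state <- remove_hypothesis(state, j)
  }
  # the removal sequence; used by the adjusted augmented procedures to
  # break ties among equal adjusted values consistently with the shortcut
  attr(adj, "selection") <- selection
  adj
}

# order `rest` by adjusted value; ties resolved by the position in the
# adjusted-p-value removal sequence (never-selected hypotheses last), then
# by original index.  Running the selection this way makes the adjusted
# augmented procedures coincide with their delta = Inf counterparts.
order_by_adjusted <- function(adj, rest, graph) {
  sel <- attr(adj, "selection")
  rank_sel <- match(rest, sel)
  rank_sel[is.na(rank_sel)] <- length(sel) + 1L
  rest[order(adj[rest], rank_sel, match(rest, graph$names))]
}
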