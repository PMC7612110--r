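#' Weighted directed hypothesis graphs
#'
#' A hypothesis graph encodes a multiple testing strategy for hypotheses
#' \eqn{H_1, \ldots, H_m}: node weights \eqn{w_i(M)} are the fractions of the
#' overall significance level initially allocated to each hypothesis, and the
#' transition matrix \eqn{G = (g_{ij})} gives the fraction of a rejected
#' hypothesis' level that is propagated along the directed edge from
#' \eqn{H_i} to \eqn{H_j}.
#'
#' The regularity conditions are \eqn{0 \le g_{ij} \le 1}, \eqn{g_{ii} = 0},
#' \eqn{\sum_j g_{ij} \le 1} for every row, together with \eqn{w_i \ge 0} and
#' \eqn{\sum_i w_i \le 1}.  Sub-stochastic rows are permitted: level routed
#' along "missing" mass is simply lost, which is always conservative.
#'
#' @param names character vector of distinct hypothesis labels.
#' @param weights numeric vector of initial weights, same length as `names`.
#' @param transitions numeric matrix of edge fractions, `m` by `m`.
#' @return An object of class `hypothesis_graph` with elements
#'   `names`, `weights` (named), and `transitions` (dimnamed).
#' @examples
#' g <- holm_graph(3)
#' g
#' intersection_weights(g, c("H1", "H2"))
#' @export
hypothesis_graph <- function(names, weights, transitions) {
  names <- as.character(names)
  weights <- as.numeric(weights)
  transitions <- as.matrix(transitions)
  m <- length(names)
  if (m < 1L) stop("a hypothesis graph needs at least one hypothesis")
  if (anyDuplicated(names)) stop("hypothesis names must be unique")
  if (length(weights) != m)
    stop("'weights' must have one entry per hypothesis (", m, ")")
  if (!all(dim(transitions) == c(m, m)))
    stop("'transitions' must be a ", m, "x", m, " matrix")
  storage.mode(transitions) <- "double"
  dimnames(transitions) <- list(names, names)
  g <- structure(
    list(names = names, weights = stats::setNames(weights, names),
         transitions = transitions),
    class = "hypothesis_graph")
  viol <- validate_graph(g)
  if (length(viol)) stop("invalid hypothesis graph:\n  ",
                         paste(viol, collapse = "\n  "))
  g
}

#' @export
print.hypothesis_graph <- function(x, ...) {
  m <- length(x$names)
  cat("Hypothesis graph with", m, if (m == 1L) "hypothesis\n" else "hypotheses\n")
  df <- data.frame(weight = round(unname(x$weights), 6))
  rownames(df) <- x$names
  print(df)
  nz <- which(x$transitions > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    cat("Edges:\n")
    for (r in seq_len(nrow(nz)))
      cat(sprintf("  %s -> %s: %g\n", x$names[nz[r, 1]], x$names[nz[r, 2]],
                  x$transitions[nz[r, 1], nz[r, 2]]))
  } else cat("No edges.\n")
  invisible(x)
}

.graph_tol <- 1e-9

#' Check the regularity conditions of a hypothesis graph
#'
#' Reports every violated condition; an empty character vector means the
#' graph is valid.  Structural problems (non-square matrix, length mismatch)
#' raise an error instead, since no meaningful report is possible.
#'
#' @param graph a [hypothesis_graph], or a bare list with elements `names`,
#'   `weights`, `transitions` (used by [read_graph()] before construction).
#' @return character vector of human-readable violations, empty if valid.
#' @export
validate_graph <- function(graph) {
  nm <- as.character(graph$names)
  w <- as.numeric(graph$weights)
  G <- as.matrix(graph$transitions)
  m <- length(nm)
  if (length(w) != m || !all(dim(G) == c(m, m)))
    stop("structural error: weights must have length ", m,
         " and transitions must be ", m, "x", m)
  viol <- character(0)
  tol <- .graph_tol
  if (any(w < -tol))
    viol <- c(viol, paste0("negative weight for ",
                           paste(nm[w < -tol], collapse = ", ")))
  if (sum(w) > 1 + tol)
    viol <- c(viol, sprintf("weights sum to %.10g > 1", sum(w)))
  bad <- which(G < -tol | G > 1 + tol, arr.ind = TRUE)
  for (r in seq_len(nrow(bad)))
    viol <- c(viol, sprintf("transition %s -> %s = %.10g outside [0, 1]",
                            nm[bad[r, 1]], nm[bad[r, 2]],
                            G[bad[r, 1], bad[r, 2]]))
  dg <- which(abs(diag(G)) > tol)
  for (i in dg)
    viol <- c(viol, sprintf("diagonal entry for %s is %.10g (must be 0)",
                            nm[i], G[i, i]))
  rs <- rowSums(G)
  for (i in which(rs > 1 + tol))
    viol <- c(viol, sprintf("row %s sums to %.10g > 1", nm[i], rs[i]))
  viol
}

#' Remove a hypothesis and propagate its level
#'
#' Deletes node `j` from the (possibly already reduced) graph, adds
#' \eqn{w_j g_{jl}} to every remaining weight and updates the transitions by
#' \eqn{g_{lk}' = (g_{lk} + g_{lj} g_{jk}) / (1 - g_{lj} g_{jl})}, with the
#' convention that the entry is 0 when \eqn{g_{lj} g_{jl} = 1} (the level of
#' a two-node loop has nowhere left to go).
#'
#' @param state a [hypothesis_graph] (initial or already reduced).
#' @param j hypothesis to remove: a name or an index into `state$names`.
#' @return the reduced `hypothesis_graph`.
#' @export
remove_hypothesis <- function(state, j) {
  nm <- state$names
  if (is.character(j)) j <- match(j, nm)
  if (is.na(j) || j < 1L || j > length(nm))
    stop("hypothesis to remove is not in the active set")
  w <- unname(state$weights)
  G <- state$transitions
  keep <- setdiff(seq_along(nm), j)
  w2 <- w[keep] + w[j] * G[j, keep]
  G2 <- matrix(0, length(keep), length(keep))
  for (a in seq_along(keep)) {
    l <- keep[a]
    d <- 1 - G[l, j] * G[j, l]
    if (d > 1e-12) {
      G2[a, ] <- (G[l, keep] + G[l, j] * G[j, keep]) / d
    } # else row entries stay 0
    G2[a, a] <- 0
  }
  structure(
    list(names = nm[keep], weights = stats::setNames(w2, nm[keep]),
         transitions = matrix(G2, length(keep), length(keep),
                              dimnames = list(nm[keep], nm[keep]))),
    class = "hypothesis_graph")
}

#' Weights of an intersection hypothesis
#'
#' Computes \eqn{w_j(J)} for \eqn{j \in J} by removing all hypotheses outside
#' `subset` one at a time; the result does not depend on the removal order.
#'
#' @param graph a [hypothesis_graph].
#' @param subset non-empty set of hypothesis names (or indices) to keep.
#' @return named numeric vector of weights for the hypotheses in `subset`.
#' @export
intersection_weights <- function(graph, subset) {
  if (is.numeric(subset)) subset <- graph$names[subset]
  if (length(subset) == 0L) stop("'subset' must be non-empty")
  if (anyNA(subset) || !all(subset %in% graph$names))
    stop("'subset' contains hypotheses not in the graph")
  st <- graph
  for (nm in setdiff(graph$names, subset))
    st <- remove_hypothesis(st, nm)
  st$weights
}

#' Exhaustively check the weight monotonicity condition
#'
#' For nested subsets \eqn{J' \subseteq J} the propagated weights must
#' satisfy \eqn{w_j(J) \le w_j(J')} for every \eqn{j \in J'}.  Graphs obeying
#' the regularity conditions always satisfy this; the checker is a safeguard
#' for externally supplied weighting schemes and a building block for the
#' parametric variant where the analogous condition can genuinely fail.
#'
#' @param graph a [hypothesis_graph].
#' @param max_m_exhaustive largest `m` for which all subset pairs are
#'   enumerated; above it, `n_sample` random nested pairs are checked.
#' @param n_sample number of sampled pairs in the non-exhaustive regime.
#' @param tol slack added before declaring a violation.
#' @return data frame with columns `J_prime`, `J`, `hypothesis`,
#'   `w_J`, `w_J_prime` (zero rows when the condition holds).
#' @export
check_monotonicity <- function(graph, max_m_exhaustive = 12, n_sample = 200,
                               tol = 1e-12) {
  m <- length(graph$names)
  out <- data.frame(J_prime = character(0), J = character(0),
                    hypothesis = character(0), w_J = numeric(0),
                    w_J_prime = numeric(0), stringsAsFactors = FALSE)
  pairs <- list()
  if (m <= max_m_exhaustive) {
    subsets <- .all_subsets(m)
    for (J in subsets) {
      inner <- .all_subsets(length(J))
      for (ix in inner) {
        Jp <- J[ix]
        if (length(Jp) < length(J)) pairs[[length(pairs) + 1L]] <- list(J, Jp)
      }
    }
  } else {
    for (s in seq_len(n_sample)) {
      J <- sort(sample.int(m, sample.int(m, 1L)))
      if (length(J) < 2L) next
      Jp <- sort(sample(J, sample.int(length(J) - 1L, 1L)))
      pairs[[length(pairs) + 1L]] <- list(J, Jp)
    }
  }
  cache <- new.env(parent = emptyenv())
  wts <- function(J) {
    key <- paste(J, collapse = ",")
    if (is.null(cache[[key]]))
      cache[[key]] <- intersection_weights(graph, J)
    cache[[key]]
  }
  for (pr in pairs) {
    J <- pr[[1]]; Jp <- pr[[2]]
    wJ <- wts(J); wJp <- wts(Jp)
    for (j in Jp) {
      nmj <- graph$names[j]
      if (wJ[nmj] > wJp[nmj] + tol) {
        out <- rbind(out, data.frame(
          J_prime = paste(graph$names[Jp], collapse = ","),
          J = paste(graph$names[J], collapse = ","),
          hypothesis = nmj, w_J = unname(wJ[nmj]),
          w_J_prime = unname(wJp[nmj]), stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# all non-empty subsets of 1..m as integer vectors
.all_subsets <- function(m) {
  out <- list()
  for (mask in seq_len(2^m - 1L))
    out[[mask]] <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
  out
}

#' Holm procedure as a hypothesis graph
#'
#' Equal initial weights \eqn{1/m} and complete transitions
#' \eqn{g_{ij} = 1/(m-1)}; the propagated weights are \eqn{w_i(I) = 1/|I|}
#' for every subset, so the graphical shortcut reproduces Holm's stepdown.
#'
#' @param m number of hypotheses.
#' @param names optional hypothesis labels (defaults to `H1..Hm`).
#' @return a [hypothesis_graph].
#' @export
holm_graph <- function(m, names = paste0("H", seq_len(m))) {
  G <- matrix(if (m > 1) 1 / (m - 1) else 0, m, m)
  diag(G) <- 0
  hypothesis_graph(names, rep(1 / m, m), G)
}

# align a p-value vector with a graph; accepts named or positional vectors
align_pvalues <- function(graph, p) {
  nm <- graph$names
  if (!is.null(names(p))) {
    if (!all(nm %in% names(p)))
      stop("p-values are missing for: ",
           paste(setdiff(nm, names(p)), collapse = ", "))
    p <- p[nm]
  } else {
    if (length(p) != length(nm))
      stop("p-value vector has length ", length(p),
           " but the graph has ", length(nm), " hypotheses")
    names(p) <- nm
  }
  p <- as.numeric(stats::setNames(p, nm))
  names(p) <- nm
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p
}
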