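#' Entangled hypothesis graphs
#'
#' An entangled graph combines \eqn{L} component testing strategies over the
#' same hypotheses with mixing coefficients \eqn{c_l \ge 0},
#' \eqn{\sum_l c_l = 1}.  Rejections are propagated within each component
#' independently, and the effective weight of a hypothesis is the
#' c-weighted sum of its component weights.  This gives the procedure
#' memory: the level a hypothesis receives depends on where previously
#' rejected levels originated.
#'
#' Components are usually [hypothesis_graph]s.  For r-of-n gatekeeping the
#' component "Holm on a subset, then the full level to the secondary family"
#' cannot be written as a regular transition graph, so
#' [build_r_of_n_gatekeeper()] supplies rule-based gate components (class
#' `gate_component`) implementing those weights exactly; both kinds can be
#' mixed.
#'
#' @param components list of components sharing one hypothesis set in the
#'   same order.
#' @param coefficients numeric mixing weights, one per component.
#' @return an object of class `entangled_graph`.
#' @export
entangled_graph <- function(components, coefficients) {
  if (!length(components)) stop("need at least one component")
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(components))
    stop("one coefficient per component required")
  if (any(coefficients < 0) || abs(sum(coefficients) - 1) > 1e-9)
    stop("coefficients must be non-negative and sum to 1")
  nm <- component_names(components[[1]])
  for (i in seq_along(components)) {
    ci <- components[[i]]
    if (!identical(component_names(ci), nm))
      stop("component ", i, " has a different hypothesis set")
    if (inherits(ci, "hypothesis_graph")) {
      viol <- validate_graph(ci)
      if (length(viol)) stop("component ", i, " is invalid: ",
                             paste(viol, collapse = "; "))
    }
  }
  structure(list(names = nm, components = components,
                 coefficients = coefficients),
            class = "entangled_graph")
}

component_names <- function(comp) {
  if (inherits(comp, "hypothesis_graph")) comp$names
  else if (inherits(comp, "gate_component")) comp$names
  else stop("unsupported component type")
}

#' @export
print.entangled_graph <- function(x, ...) {
  cat("Entangled graph:", length(x$components), "components over",
      length(x$names), "hypotheses\n")
  cat("Coefficients:", paste(signif(x$coefficients, 6), collapse = ", "),
      "\n")
  invisible(x)
}

# weights of a single component after removing `rejected` (names)
component_weights <- function(comp, rejected) {
  UseMethod("component_weights")
}

#' @export
component_weights.hypothesis_graph <- function(comp, rejected) {
  st <- comp
  for (r in rejected) st <- remove_hypothesis(st, r)
  st$weights
}

# Gate component: Holm among `primaries`; once every primary is rejected the
# full level moves to a Holm split over the remaining `secondaries`.
#' @export
component_weights.gate_component <- function(comp, rejected) {
  prim_left <- setdiff(comp$primaries, rejected)
  sec_left <- setdiff(comp$secondaries, rejected)
  active <- setdiff(comp$names, rejected)
  w <- stats::setNames(rep(0, length(active)), active)
  if (length(prim_left)) {
    w[prim_left] <- 1 / length(prim_left)
  } else if (length(sec_left)) {
    w[sec_left] <- 1 / length(sec_left)
  } # else: all carriers rejected, remaining level is retired
  w
}

new_gate_component <- function(names, primaries, secondaries) {
  structure(list(names = names, primaries = primaries,
                 secondaries = secondaries), class = "gate_component")
}

#' Effective weights of an entangled graph after rejections
#'
#' Propagates the removal of `rejected` within every component
#' independently (order-invariant per component) and returns
#' \eqn{\sum_l c_l w_j^{(l)}(I)} for each remaining hypothesis.
#'
#' @param entangled an [entangled_graph].
#' @param rejected character vector of rejected hypothesis names (possibly
#'   empty).
#' @return named numeric vector over the remaining hypotheses.
#' @export
entangled_weights <- function(entangled, rejected = character(0)) {
  if (is.numeric(rejected)) rejected <- entangled$names[rejected]
  if (!all(rejected %in% entangled$names))
    stop("'rejected' contains hypotheses not in the graph")
  active <- setdiff(entangled$names, rejected)
  w <- stats::setNames(rep(0, length(active)), active)
  for (l in seq_along(entangled$components)) {
    wl <- component_weights(entangled$components[[l]], rejected)
    w[names(wl)] <- w[names(wl)] + entangled$coefficients[l] * wl
  }
  w
}

# Entangled analogue of shortcut_continue(): the candidate is the active
# hypothesis minimising p_j / (sum_l c_l w_j^(l)(I)) and is rejected while
# p_j <= effective_weight * level.
entangled_continue <- function(entangled, rejected, p, level,
                               max_rejections = Inf, stage = "base") {
  new_rej <- character(0)
  trace <- list()
  while (length(new_rej) < max_rejections) {
    active <- setdiff(entangled$names, c(rejected, new_rej))
    if (!length(active)) break
    w <- unname(entangled_weights(entangled, c(rejected, new_rej))[active])
    pa <- p[active]
    thr <- w * level
    thr[w <= 0] <- 0
    ratio <- ifelse(w > 0, pa / w, ifelse(pa == 0, 0, Inf))
    j <- which.min(ratio)
    if (!(pa[j] <= thr[j])) break
    new_rej <- c(new_rej, active[j])
    trace[[length(trace) + 1L]] <- data.frame(
      hypothesis = active[j], p = unname(pa[j]), threshold = unname(thr[j]),
      stage = stage, stringsAsFactors = FALSE)
  }
  list(rejected = new_rej,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(hypothesis = character(0), p = numeric(0),
                    threshold = numeric(0), stage = character(0),
                    stringsAsFactors = FALSE))
}

#' Entangled Bonferroni-based graphical FWER test
#'
#' Iteratively rejects any active \eqn{H_j} with \eqn{p_j \le
#' (\sum_l c_l w_j^{(l)}(I))\,\alpha}, updating every component.  With a
#' single component this is exactly [graphical_fwer_test()].
#'
#' @param entangled an [entangled_graph].
#' @inheritParams graphical_fwer_test
#' @return a `graph_test`.
#' @export
entangled_fwer_test <- function(entangled, p, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  p <- align_pvalues(entangled, p)
  res <- entangled_continue(entangled, character(0), p, alpha,
                            stage = "base")
  new_graph_test("fwer", res$rejected, res$trace, alpha, entangled)
}

#' Augmented k-FWER and FDP procedures on an entangled graph
#'
#' The augmented procedures substitute the entangled FWER engine for the
#' single-graph shortcut in both stages: stage 1 at `alpha`, stage 2 at
#' `delta` for up to `k - 1` (k-FWER) or `D` (FDP) extra rejections.
#'
#' @param entangled an [entangled_graph].
#' @inheritParams augmented_kfwer
#' @inheritParams augmented_fdp
#' @return a `graph_test`.
#' @export
entangled_augmented_kfwer <- function(entangled, p, alpha, k, delta = 1) {
  check_config(alpha, k = k, delta = delta)
  p <- align_pvalues(entangled, p)
  s1 <- entangled_continue(entangled, character(0), p, alpha,
                           stage = "base")
  s2 <- entangled_continue(entangled, s1$rejected, p, delta,
                           max_rejections = k - 1, stage = "augmented")
  new_graph_test("aug-kfwer", c(s1$rejected, s2$rejected),
                 rbind(s1$trace, s2$trace), alpha, entangled,
                 extra = list(k = k, delta = delta))
}

#' @rdname entangled_augmented_kfwer
#' @export
entangled_augmented_fdp <- function(entangled, p, alpha, gamma, delta = 1) {
  check_config(alpha, delta = delta, gamma = gamma)
  p <- align_pvalues(entangled, p)
  s1 <- entangled_continue(entangled, character(0), p, alpha,
                           stage = "base")
  D <- augmentation_count(length(s1$rejected), gamma,
                          length(entangled$names) - length(s1$rejected))
  s2 <- entangled_continue(entangled, s1$rejected, p, delta,
                           max_rejections = D, stage = "augmented")
  new_graph_test("aug-fdp", c(s1$rejected, s2$rejected),
                 rbind(s1$trace, s2$trace), alpha, entangled,
                 extra = list(gamma = gamma, delta = delta, D = D))
}

#' Build an r-of-n gatekeeper as an entangled graph
#'
#' One component per size-`r` subset \eqn{J_l} of the `n` primary
#' hypotheses: a Holm procedure on \eqn{J_l} whose full level passes to a
#' Holm split over the secondary family once all `r` members are rejected.
#' Coefficients are \eqn{1 / \binom{n}{r}}.  Secondary hypotheses therefore
#' become testable exactly when some `r` primaries have been rejected.
#'
#' @param n number of primary hypotheses.
#' @param r number of primary rejections required to open the gate.
#' @param secondary_names labels of the secondary family (one or more).
#' @param primary_names optional labels for the primaries (default
#'   `H1..Hn`).
#' @return an [entangled_graph] of `choose(n, r)` gate components.
#' @examples
#' eg <- build_r_of_n_gatekeeper(4, 2, "S1")
#' entangled_weights(eg)          # 1/4 each primary, 0 for S1
#' entangled_weights(eg, c("H1", "H2"))
#' @export
build_r_of_n_gatekeeper <- function(n, r, secondary_names,
                                    primary_names = paste0("H", seq_len(n))) {
  if (r < 1 || r > n) stop("'r' must satisfy 1 <= r <= n")
  if (length(primary_names) != n) stop("need ", n, " primary names")
  if (choose(n, r) > 1e5) stop("choose(n, r) too large to enumerate")
  nm <- c(primary_names, secondary_names)
  subs <- utils::combn(primary_names, r, simplify = FALSE)
  comps <- lapply(subs, function(J)
    new_gate_component(nm, J, secondary_names))
  entangled_graph(comps, rep(1 / length(subs), length(subs)))
}

#' Closed-form effective weights for the r-of-n gatekeeper
#'
#' Direct combinatorial evaluation of the entangled weights of
#' [build_r_of_n_gatekeeper()] after `n - n_unrejected` primaries have been
#' rejected (and no secondary).  Each unrejected primary receives
#' \deqn{\binom{n}{r}^{-1} \sum_j \binom{u-1}{j} \binom{n-u}{r-1-j}
#'       \frac{1}{1+j},}
#' with \eqn{u} the number of unrejected primaries, and the secondary
#' family jointly receives \eqn{\binom{n-u}{r} / \binom{n}{r}} (split
#' evenly across its members).  Used as an independent cross-check of the
#' component enumeration.
#'
#' @param n,r as in [build_r_of_n_gatekeeper()].
#' @param n_unrejected number of primaries not yet rejected.
#' @return list with `primary` (weight of each unrejected primary; `NA`
#'   when none remain) and `secondary_family` (total weight of the
#'   secondary family).
#' @export
gatekeeper_closed_form <- function(n, r, n_unrejected) {
  stopifnot(n_unrejected >= 0, n_unrejected <= n)
  u <- n_unrejected
  total <- choose(n, r)
  sec <- choose(n - u, r) / total
  if (u == 0) return(list(primary = NA_real_, secondary_family = sec))
  j <- 0:min(u - 1, r - 1)
  prim <- sum(choose(u - 1, j) * choose(n - u, r - 1 - j) / (1 + j)) / total
  list(primary = prim, secondary_family = sec)
}
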