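#' Read and write hypothesis graphs
#'
#' Graphs are stored as JSON or YAML (chosen by file extension) with fields
#' `format_version`, `hypotheses`, `weights` and `transitions`; entangled
#' graphs use `format_version`, `coefficients` and `components` (each
#' component a graph object).  Round-trips preserve full double precision.
#'
#' @param path file to read or write.
#' @return `read_graph()` returns a validated [hypothesis_graph] or
#'   [entangled_graph]; `write_graph()` returns `path` invisibly.
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- parse_by_ext(path)
  graph_from_list(obj, path)
}

graph_from_list <- function(obj, what = "graph") {
  if (!is.null(obj$components)) {
    comps <- lapply(obj$components, graph_from_list, what = what)
    return(entangled_graph(comps, as.numeric(obj$coefficients)))
  }
  for (f in c("hypotheses", "weights", "transitions"))
    if (is.null(obj[[f]]))
      stop("missing field '", f, "' in ", what)
  tr <- obj$transitions
  if (is.list(tr)) tr <- do.call(rbind, lapply(tr, as.numeric))
  g <- list(names = unlist(obj$hypotheses),
            weights = as.numeric(unlist(obj$weights)),
            transitions = as.matrix(tr))
  viol <- tryCatch(validate_graph(g), error = function(e) stop(
    "structural error in ", what, ": ", conditionMessage(e)))
  if (length(viol))
    stop("invalid graph in ", what, ":\n  ", paste(viol, collapse = "\n  "))
  hypothesis_graph(g$names, g$weights, g$transitions)
}

parse_by_ext <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE,
                          simplifyMatrix = TRUE)
}

#' @rdname read_graph
#' @param graph a [hypothesis_graph] or [entangled_graph] to serialise.
#' @export
write_graph <- function(graph, path) {
  obj <- graph_to_list(graph)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 17L)
  } else {
    writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                                pretty = TRUE), path)
  }
  invisible(path)
}

graph_to_list <- function(graph) {
  if (inherits(graph, "entangled_graph")) {
    for (comp in graph$components)
      if (!inherits(comp, "hypothesis_graph"))
        stop("only entangled graphs with plain graph components can be ",
             "serialised; gatekeeper components are rebuilt with ",
             "build_r_of_n_gatekeeper()")
    return(list(format_version = 1L,
                coefficients = graph$coefficients,
                components = lapply(graph$components, graph_to_list)))
  }
  # transitions as a list of rows: serialises identically in JSON and YAML
  list(format_version = 1L, hypotheses = graph$names,
       weights = unname(graph$weights),
       transitions = lapply(seq_along(graph$names), function(i)
         unname(graph$transitions[i, ])))
}

#' Read p-values from a CSV file
#'
#' Expects columns `hypothesis` and `p`.
#'
#' @param path CSV file.
#' @return named numeric vector.
#' @export
read_pvalues <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("hypothesis", "p") %in% names(df)))
    stop("p-value file needs columns 'hypothesis' and 'p'")
  p <- stats::setNames(as.numeric(df$p), df$hypothesis)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numbers in [0, 1]")
  p
}

#' @rdname read_pvalues
#' @param p named numeric vector to write.
#' @export
write_pvalues <- function(p, path) {
  utils::write.csv(data.frame(hypothesis = names(p), p = unname(p)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Random valid hypothesis graph
#'
#' Weights are drawn from the simplex (optionally with a random subset set
#' to zero) and each transition row is sub-stochastic with random sparsity;
#' the result always satisfies the regularity conditions.  Deterministic
#' per seed.
#'
#' @param m number of hypotheses.
#' @param seed RNG seed.
#' @param zero_weight_prob probability that a given initial weight is
#'   zeroed (renormalising the rest).
#' @param full_rows if `TRUE`, every transition row sums to exactly 1 and
#'   all weights are positive (complete propagation; useful when testing
#'   equivalences that require no level to be lost).
#' @return a [hypothesis_graph].
#' @export
random_graph <- function(m, seed = 1L, zero_weight_prob = 0.2,
                         full_rows = FALSE) {
  stopifnot(m >= 1)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w <- stats::rexp(m)
  if (!full_rows && m > 1) {
    z <- stats::runif(m) < zero_weight_prob
    if (all(z)) z[sample.int(m, 1L)] <- FALSE
    w[z] <- 0
  }
  w <- w / sum(w)
  G <- matrix(0, m, m)
  for (i in seq_len(m)) {
    if (m == 1L) break
    others <- setdiff(seq_len(m), i)
    e <- stats::rexp(length(others))
    scale <- if (full_rows) 1 else stats::runif(1)
    if (!full_rows) {
      keep <- stats::runif(length(others)) < 0.7
      e[!keep] <- 0
    }
    if (sum(e) > 0) G[i, others] <- scale * e / sum(e)
  }
  hypothesis_graph(paste0("H", seq_len(m)), w, G)
}
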