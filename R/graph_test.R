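#' Run a graphical multiple testing procedure
#'
#' Umbrella interface dispatching to the individual procedures; accepts a
#' [hypothesis_graph] or, for the FWER and augmented procedures, an
#' [entangled_graph].
#'
#' @param graph a [hypothesis_graph] or [entangled_graph].
#' @param p named p-value vector.
#' @param procedure one of `"fwer"`, `"aug-kfwer"`, `"adj-aug-kfwer"`,
#'   `"gen-kfwer"`, `"aug-fdp"`, `"adj-aug-fdp"`, `"gen-fdp"`.
#' @param alpha significance level.
#' @param k number of tolerated false rejections (k-FWER procedures).
#' @param gamma FDP bound (FDP procedures).
#' @param delta augmentation / free-rejection level.
#' @param model optional [dependence_model] for parametric thresholds
#'   (FWER only).
#' @param free_rejections passed to the generalized procedures.
#' @return a `graph_test` object.
#' @examples
#' g <- example_graph("diabetes")
#' graph_test(g, example_pvalues("diabetes-b"), "aug-fdp",
#'            alpha = 0.05, gamma = 0.5, delta = 0.5)
#' @export
graph_test <- function(graph, p,
                       procedure = c("fwer", "aug-kfwer", "adj-aug-kfwer",
                                     "gen-kfwer", "aug-fdp", "adj-aug-fdp",
                                     "gen-fdp"),
                       alpha = 0.05, k = 2L, gamma = 0.1, delta = 1,
                       model = NULL, free_rejections = TRUE) {
  procedure <- match.arg(procedure)
  if (inherits(graph, "entangled_graph")) {
    res <- switch(procedure,
      "fwer" = entangled_fwer_test(graph, p, alpha),
      "aug-kfwer" = entangled_augmented_kfwer(graph, p, alpha, k, delta),
      "aug-fdp" = entangled_augmented_fdp(graph, p, alpha, gamma, delta),
      "gen-kfwer" = generalized_kfwer(graph, p, alpha, k, delta,
                                      free_rejections),
      "gen-fdp" = generalized_fdp(graph, p, alpha, gamma, delta,
                                  free_rejections),
      stop("procedure '", procedure,
           "' is not available for entangled graphs"))
    return(res)
  }
  if (!is.null(model) && procedure != "fwer")
    stop("parametric thresholds are only implemented for the FWER shortcut")
  switch(procedure,
    "fwer" = if (is.null(model)) graphical_fwer_test(graph, p, alpha)
             else parametric_fwer_test(graph, p, model, alpha),
    "aug-kfwer" = augmented_kfwer(graph, p, alpha, k, delta),
    "adj-aug-kfwer" = adjusted_augmented_kfwer(graph, p, k, alpha),
    "gen-kfwer" = generalized_kfwer(graph, p, alpha, k, delta,
                                    free_rejections),
    "aug-fdp" = augmented_fdp(graph, p, alpha, gamma, delta),
    "adj-aug-fdp" = adjusted_augmented_fdp(graph, p, alpha, gamma),
    "gen-fdp" = generalized_fdp(graph, p, alpha, gamma, delta,
                                free_rejections))
}
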