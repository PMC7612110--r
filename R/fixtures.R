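#' Packaged example graphs
#'
#' Built in code (not from data files) so they are always available:
#'
#' \describe{
#'   \item{`"diabetes"`}{Four hypotheses: two dose-placebo comparisons on a
#'     primary endpoint (`H1`, `H2`, initial weight 1/2 each) gatekeeping
#'     the matching secondary-endpoint comparisons (`H3`, `H4`, weight 0),
#'     with edges `H1 -> H3` and `H2 -> H4` of weight 1/2.  The minimal
#'     graph consistent with the worked examples it is used in; the
#'     remaining half of each primary row is deliberately unassigned.}
#'   \item{`"pharmacodynamic-weighted3"`, `"pharmacodynamic-uniform"`}{The
#'     15-contrast qEEG dose/time study: contrasts `TiDj` (time slice `i`,
#'     dose `j`) with a serpentine propagation: the top dose cascades to
#'     earlier times and drops to the middle dose, the middle dose feeds
#'     forward to the latest time, crosses to the lowest dose and cascades
#'     back.  Initial weights are 1/3 on `T4D3`, `T5D2`, `T5D3`, or uniform
#'     1/15.  The topology is a reconstruction from the published rejection
#'     results, not a transcription of a printed matrix; see the package
#'     vignette.}
#'   \item{`"atmosphere"`}{The three-primary/two-secondary-family heart
#'     failure comparison (`H1`, `H2`, `H3`, `H41`, `H42`, `H51`, `H52`):
#'     weights 1/2 on `H1` and `H2`; `H2` passes half its level to `H3` and
#'     a quarter to each secondary in the `H5` family; secondaries share
#'     within the family and exit towards `H3`/`H2`.  Also a figure-derived
#'     reconstruction validated against the published outcomes.}
#'   \item{`"holm4"`}{The Holm procedure on four hypotheses.}
#' }
#'
#' @param name fixture name (see above).
#' @return a [hypothesis_graph].
#' @export
example_graph <- function(name = c("diabetes", "pharmacodynamic-weighted3",
                                   "pharmacodynamic-uniform", "atmosphere",
                                   "holm4")) {
  name <- match.arg(name)
  switch(name,
    "diabetes" = {
      G <- matrix(0, 4, 4)
      G[1, 3] <- 0.5
      G[2, 4] <- 0.5
      hypothesis_graph(paste0("H", 1:4), c(0.5, 0.5, 0, 0), G)
    },
    "pharmacodynamic-weighted3" = pharmacodynamic_graph(weighted3 = TRUE),
    "pharmacodynamic-uniform" = pharmacodynamic_graph(weighted3 = FALSE),
    "atmosphere" = {
      nm <- c("H1", "H2", "H3", "H41", "H42", "H51", "H52")
      G <- matrix(0, 7, 7, dimnames = list(nm, nm))
      G["H1", "H41"] <- 0.5; G["H1", "H42"] <- 0.5
      G["H2", "H3"] <- 0.5; G["H2", "H51"] <- 0.25; G["H2", "H52"] <- 0.25
      G["H3", "H51"] <- 0.5; G["H3", "H52"] <- 0.5
      G["H41", "H42"] <- 0.5; G["H41", "H2"] <- 0.5
      G["H42", "H41"] <- 0.5; G["H42", "H2"] <- 0.5
      G["H51", "H52"] <- 0.5; G["H51", "H3"] <- 0.5
      G["H52", "H51"] <- 0.5; G["H52", "H3"] <- 0.5
      hypothesis_graph(nm, c(0.5, 0.5, 0, 0, 0, 0, 0), unname(G))
    },
    "holm4" = holm_graph(4))
}

pharmacodynamic_names <- function()
  as.vector(outer(1:5, 1:3, function(i, j) paste0("T", i, "D", j)))

pharmacodynamic_graph <- function(weighted3 = TRUE) {
  nm <- pharmacodynamic_names()
  idx <- function(i, j) (j - 1L) * 5L + i
  G <- matrix(0, 15, 15)
  edge <- function(a, b, w) G[idx(a[1], a[2]), idx(b[1], b[2])] <<- w
  edge(c(5, 3), c(4, 3), .5); edge(c(5, 3), c(5, 2), .5)
  edge(c(4, 3), c(3, 3), .5); edge(c(4, 3), c(4, 2), .5)
  edge(c(3, 3), c(2, 3), .5); edge(c(3, 3), c(3, 2), .5)
  edge(c(2, 3), c(1, 3), 1)
  edge(c(1, 3), c(1, 2), 1)
  edge(c(4, 2), c(5, 2), .5); edge(c(4, 2), c(4, 1), .5)
  edge(c(3, 2), c(4, 2), .5); edge(c(3, 2), c(3, 1), .5)
  edge(c(2, 2), c(2, 1), 1)
  edge(c(1, 2), c(1, 1), 1)
  edge(c(5, 2), c(5, 1), 1)
  edge(c(5, 1), c(4, 1), 1)
  edge(c(4, 1), c(3, 1), 1)
  edge(c(3, 1), c(2, 2), 1)
  edge(c(2, 1), c(1, 1), 1)
  w <- rep(0, 15)
  if (weighted3) w[c(idx(4, 3), idx(5, 2), idx(5, 3))] <- 1 / 3
  else w <- rep(1 / 15, 15)
  hypothesis_graph(nm, w, G)
}

#' Packaged example p-value sets
#'
#' \describe{
#'   \item{`"diabetes-a"`}{`(.01, .03, .02, .024)` -- the k-FWER worked
#'     examples on the diabetes graph.}
#'   \item{`"diabetes-b"`}{`(.01, .015, .02, .024)` -- the FDP worked
#'     examples.}
#'   \item{`"pharmacodynamic"`}{the 15 mixed-model contrast p-values of the
#'     qEEG study.}
#'   \item{`"atmosphere"`}{the seven hypothetical p-values of the heart
#'     failure case study.}
#' }
#'
#' @param name p-value set name.
#' @return named numeric vector aligned with the matching
#'   [example_graph()].
#' @export
example_pvalues <- function(name = c("diabetes-a", "diabetes-b",
                                     "pharmacodynamic", "atmosphere")) {
  name <- match.arg(name)
  switch(name,
    "diabetes-a" = c(H1 = .01, H2 = .03, H3 = .02, H4 = .024),
    "diabetes-b" = c(H1 = .01, H2 = .015, H3 = .02, H4 = .024),
    "pharmacodynamic" = stats::setNames(
      c(0.7808, 0.0600, 0.0137, 0.0724, 0.0162,
        0.9433, 0.0053, 6.5e-6, 2.8e-6, 9.1e-8,
        0.9993, 1.0e-5, 1.7e-11, 4.2e-12, 8.1e-13),
      pharmacodynamic_names()),
    "atmosphere" = c(H1 = .1, H2 = .007, H3 = .05, H41 = .0015,
                     H42 = .04, H51 = .0031, H52 = .001))
}

#' Materialise packaged fixtures to files
#'
#' Writes every example graph (JSON) and p-value set (CSV) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_fixtures <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in c("diabetes", "pharmacodynamic-weighted3",
              "pharmacodynamic-uniform", "atmosphere", "holm4")) {
    f <- file.path(dir, paste0(g, ".json"))
    write_graph(example_graph(g), f)
    paths <- c(paths, f)
  }
  for (p in c("diabetes-a", "diabetes-b", "pharmacodynamic",
              "atmosphere")) {
    f <- file.path(dir, paste0(p, ".csv"))
    write_pvalues(example_pvalues(p), f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Synthetic proof-of-concept trial scenario for the 6-of-9 gatekeeper
#'
#' A nine-endpoint two-arm scenario in the mould of a proof-of-concept
#' acute heart failure trial: six endpoints with clear standardized
#' treatment effects, two with moderate ones, `H9` exactly null (mean 0.07
#' in both arms), and an independent secondary statistic `H10` distributed
#' N(3, 1).  The endpoint means and standard deviations are synthetic
#' placeholders chosen to produce realistic marginal powers at one-sided
#' level 0.1 -- they are not the empirical trial values, which are not
#' redistributable here -- so estimated operating characteristics are
#' qualitatively, not numerically, comparable to the published ones.
#'
#' @param n_per_arm sample size of each arm.
#' @param rho common correlation between the endpoint means.
#' @return a [simulation_scenario] with hypotheses `H1..H9` plus `H10`.
#' @export
prerelax_synthetic_scenario <- function(n_per_arm = 40, rho = 0.3) {
  effects <- c(0.55, 0.50, 0.40, 0.45, 0.50, 1.00, 1.00, 0.35, 0.00)
  mc <- c(rep(0, 8), 0.07)
  simulation_scenario(
    means_control = mc,
    means_experimental = mc + effects,
    sds_control = rep(1, 9), sds_experimental = rep(1, 9),
    n_control = n_per_arm, n_experimental = n_per_arm,
    correlation = rho,
    hypothesis_names = paste0("H", 1:9),
    extra_statistics = data.frame(name = "H10", mean = 3, sd = 1,
                                  null = FALSE),
    use_t = TRUE)
}
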