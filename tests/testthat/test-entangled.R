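test_that("single-component entanglement equals the plain graph machinery", {
  for (seed in 1:10) {
    g <- random_graph(5, seed = seed)
    eg <- entangled_graph(list(g), 1)
    p <- random_pvalues(g, seed + 800)
    expect_equal(entangled_weights(eg), g$weights)
    expect_equal(entangled_weights(eg, c("H1", "H3")),
                 intersection_weights(g, c("H2", "H4", "H5")))
    expect_setequal(entangled_fwer_test(eg, p, .05)$rejected,
                    graphical_fwer_test(g, p, .05)$rejected)
  }
})

test_that("entangled graph construction validates its inputs", {
  g <- holm_graph(3)
  expect_error(entangled_graph(list(g, holm_graph(4)), c(.5, .5)),
               "different hypothesis set")
  expect_error(entangled_graph(list(g, g), c(.7, .7)), "sum to 1")
})

test_that("6-of-9 gatekeeper weights reproduce the published closed forms", {
  eg <- build_r_of_n_gatekeeper(9, 6, "H10")
  expect_length(eg$components, 84)
  expect_equal(eg$coefficients, rep(1 / 84, 84))

  # no rejections: Holm weights 1/9 on the primaries, secondary locked
  w0 <- entangled_weights(eg)
  expect_equal(unname(w0[paste0("H", 1:9)]), rep(1 / 9, 9),
               tolerance = 1e-12)
  expect_equal(unname(w0["H10"]), 0)

  # |I| unrejected primaries -> published weights
  expected <- list("3" = c(83 / 252, 1 / 84), "2" = c(11 / 24, 1 / 12),
                   "1" = c(2 / 3, 1 / 3))
  for (nI in names(expected)) {
    rejected <- paste0("H", seq_len(9 - as.integer(nI)))
    w <- entangled_weights(eg, rejected)
    prim <- w[setdiff(paste0("H", 1:9), rejected)]
    expect_equal(unname(prim), rep(expected[[nI]][1], length(prim)),
                 tolerance = 1e-12)
    expect_equal(unname(w["H10"]), expected[[nI]][2], tolerance = 1e-12)
  }
  # all nine rejected: the secondary holds the full level
  expect_equal(unname(entangled_weights(eg, paste0("H", 1:9))["H10"]), 1)

  # |I| > 3: still Holm 1/|I| on the remaining primaries, secondary 0
  for (nrej in 1:3) {
    w <- entangled_weights(eg, paste0("H", seq_len(nrej)))
    expect_equal(unname(w[paste0("H", (nrej + 1):9)]),
                 rep(1 / (9 - nrej), 9 - nrej), tolerance = 1e-12)
    expect_equal(unname(w["H10"]), 0)
  }
})

test_that("closed-form gatekeeper weights match component enumeration", {
  for (n in c(4, 9)) {
    r <- if (n == 4) 2 else 6
    eg <- build_r_of_n_gatekeeper(n, r, "S")
    for (u in 0:n) {
      rejected <- utils::head(paste0("H", seq_len(n)), n - u)
      w <- entangled_weights(eg, rejected)
      cf <- gatekeeper_closed_form(n, r, u)
      if (u > 0)
        expect_equal(unname(w[paste0("H", (n - u + 1):n)]),
                     rep(cf$primary, u), tolerance = 1e-12)
      expect_equal(unname(w["S"]), cf$secondary_family, tolerance = 1e-12)
    }
  }
  expect_error(build_r_of_n_gatekeeper(4, 5, "S"), "1 <= r <= n")
})

test_that("n = r collapses to a single fixed-sequence component", {
  eg <- build_r_of_n_gatekeeper(3, 3, c("S1", "S2"))
  expect_length(eg$components, 1)
  # all primaries rejected: secondary family split evenly
  w <- entangled_weights(eg, paste0("H", 1:3))
  expect_equal(unname(w[c("S1", "S2")]), c(.5, .5))
})

test_that("entangled FWER test respects the gate", {
  eg <- build_r_of_n_gatekeeper(9, 6, "H10")
  # all primaries extreme, secondary hopeless: nine rejections, gate opens
  # but the secondary p-value exceeds its full level
  p <- c(stats::setNames(rep(1e-6, 9), paste0("H", 1:9)), H10 = 1)
  res <- entangled_fwer_test(eg, p, .05)
  expect_setequal(res$rejected, paste0("H", 1:9))
  # with a good secondary p-value it falls once six primaries are out
  p2 <- c(stats::setNames(rep(1e-6, 9), paste0("H", 1:9)), H10 = .002)
  expect_true("H10" %in% entangled_fwer_test(eg, p2, .05)$rejected)
})

test_that("entangled augmented procedures extend the entangled FWER test", {
  eg <- build_r_of_n_gatekeeper(4, 2, "S")
  p <- c(H1 = .002, H2 = .2, H3 = .3, H4 = .9, S = .5)
  base <- entangled_fwer_test(eg, p, .05)$rejected
  expect_equal(entangled_augmented_kfwer(eg, p, .05, k = 1,
                                         delta = Inf)$rejected, base)
  resk2 <- entangled_augmented_kfwer(eg, p, .05, k = 2, delta = Inf)
  expect_length(resk2$rejected, length(base) + 1)
  resfdp <- entangled_augmented_fdp(eg, p, .05, gamma = .5, delta = Inf)
  expect_length(resfdp$rejected,
                length(base) + augmentation_count(length(base), .5))
})

test_that("entangled FWER control holds under the global null", {
  eg <- build_r_of_n_gatekeeper(5, 3, "S")
  reps <- 1500
  set.seed(99)
  hits <- 0
  for (b in seq_len(reps)) {
    p <- stats::setNames(stats::runif(6), eg$names)
    hits <- hits + (length(entangled_fwer_test(eg, p, .05)$rejected) > 0)
  }
  expect_lte(hits / reps, .05 + 3 * sqrt(.05 * .95 / reps))
})
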