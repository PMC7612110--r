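test_that("generalized Bonferroni thresholds are k alpha / m (weighted)", {
  p <- c(a = .01, b = .02, c = .03, d = .04)
  expect_setequal(generalized_bonferroni(p, k = 2, alpha = .05),
                  c("a", "b"))
  # k = m with uniform weights is unadjusted testing at alpha
  expect_setequal(generalized_bonferroni(p, k = 4, alpha = .05),
                  c("a", "b", "c", "d"))
  expect_setequal(
    generalized_bonferroni(p, k = 1, alpha = .05,
                           weights = c(.5, .5, 0, 0)),
    c("a", "b"))
  expect_error(generalized_bonferroni(p, 1, .05, weights = rep(.3, 4)),
               "sum to 1")
})

test_that("augmented k-FWER reproduces the two-dose worked example", {
  g <- example_graph("diabetes")
  res <- augmented_kfwer(g, example_pvalues("diabetes-a"), alpha = .05,
                         k = 2, delta = 0.5)
  expect_equal(res$rejected, c("H1", "H2"))
  expect_equal(res$trace$stage, c("base", "augmented"))
})

test_that("augmented k-FWER with k = 1 is the plain FWER shortcut", {
  for (seed in 1:20) {
    g <- random_graph(5, seed = seed)
    p <- random_pvalues(g, seed + 10)
    expect_equal(augmented_kfwer(g, p, .05, k = 1, delta = 5)$rejected,
                 graphical_fwer_test(g, p, .05)$rejected)
  }
})

test_that("augmented and adjusted-augmented agree for delta = Inf", {
  for (seed in 1:30) {
    g <- random_graph(5, seed = seed, full_rows = TRUE)
    p <- random_pvalues(g, seed + 200)
    for (k in 1:3) {
      expect_setequal(
        augmented_kfwer(g, p, .05, k = k, delta = Inf)$rejected,
        adjusted_augmented_kfwer(g, p, k = k, alpha = .05)$rejected)
    }
  }
})

test_that("adjusted-augmented breaks ties by smallest index and caps at I", {
  g <- holm_graph(3)
  p <- c(H1 = .5, H2 = .5, H3 = .01)   # H1, H2 tie on adjusted values
  res <- adjusted_augmented_kfwer(g, p, k = 2, alpha = .05)
  expect_equal(res$rejected, c("H3", "H1"))
  res5 <- adjusted_augmented_kfwer(g, p, k = 10, alpha = .05)
  expect_setequal(res5$rejected, c("H1", "H2", "H3"))
})

test_that("generalized k-FWER matches the stepdown worked example", {
  g <- example_graph("diabetes")
  res <- generalized_kfwer(g, example_pvalues("diabetes-a"), .05, k = 2)
  expect_setequal(res$rejected, c("H1", "H2"))
  # the secondary hypotheses face zero thresholds at the stepdown stage
  expect_false(any(res$trace$stage == "stepdown"))
})

test_that("generalized k-FWER with k = 1 equals the FWER shortcut", {
  for (seed in 1:30) {
    g <- random_graph(5, seed = seed)
    p <- random_pvalues(g, seed + 300)
    expect_setequal(generalized_kfwer(g, p, .05, k = 1)$rejected,
                    graphical_fwer_test(g, p, .05)$rejected)
  }
})

test_that("generalized k-FWER on the Holm graph equals Lehmann-Romano", {
  for (m in c(4, 6)) {
    g <- holm_graph(m)
    for (seed in 1:25) {
      set.seed(seed * m)
      p <- stats::setNames(stats::runif(m)^1.5, g$names)
      for (k in 1:3) {
        expect_setequal(
          generalized_kfwer(g, p, .1, k = k,
                            free_rejections = FALSE)$rejected,
          lehmann_romano_oracle(p, k, .1))
      }
    }
  }
})

test_that("free-rejection subprocedure respects its budget and level", {
  g <- example_graph("diabetes")
  # k = 3 on the FDP example p-values: two base rejections = k - 1, so the
  # subprocedure must add nothing
  res <- generalized_kfwer(g, example_pvalues("diabetes-b"), .05, k = 3,
                           delta = 0.5)
  expect_setequal(res$rejected, c("H1", "H2"))
  expect_false(any(res$trace$stage == "free"))

  # nothing rejected in step (ii), delta = 0: free stage needs p = 0
  p0 <- c(H1 = .4, H2 = .5, H3 = .6, H4 = .7)
  expect_length(generalized_kfwer(g, p0, .05, k = 3, delta = 0)$rejected, 0)
  pz <- c(H1 = 0, H2 = .5, H3 = .6, H4 = .7)
  expect_equal(generalized_kfwer(g, pz, 1e-6, k = 3, delta = 0)$rejected,
               "H1")

  # delta = Inf with complete propagation: exactly k - 1 free rejections
  gh <- holm_graph(5)
  ph <- c(H1 = .9, H2 = .8, H3 = .7, H4 = .6, H5 = .5)
  res_inf <- generalized_kfwer(gh, ph, 1e-4, k = 4, delta = Inf)
  expect_length(res_inf$rejected, 3)
  expect_true(all(res_inf$trace$stage == "free"))
})

test_that("augmented rejection sets grow with k", {
  for (seed in 1:10) {
    g <- random_graph(6, seed = seed)
    p <- random_pvalues(g, seed + 400)
    prev <- character(0)
    for (k in 1:4) {
      cur <- augmented_kfwer(g, p, .05, k = k, delta = 0.6)$rejected
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("naive k-alpha substitution is anti-conservative on Holm", {
  # replacing alpha by k*alpha gives stepdown thresholds k*alpha/(m+1-i),
  # strictly larger than the valid k*alpha/(m+k-i) for k > 1, i < m + 1
  alpha <- .05
  for (m in c(3, 5, 8)) {
    for (k in 2:3) {
      i <- seq_len(m)
      expect_true(all(k * alpha / (m + 1 - i) > k * alpha / (m + k - i)))
    }
  }
})

test_that("hypotheses with fewer than k donors keep their initial level", {
  # the step-(iv) minimum over retained subsets J can keep every donor of
  # such a hypothesis alive, so its minimised weight never exceeds w_j(M):
  # its stepdown threshold is stuck at the initial w_j(M) * k * alpha
  for (seed in 1:15) {
    g <- random_graph(5, seed = seed)
    donors <- colSums(g$transitions > 0)
    for (k in 2:3) {
      set.seed(seed + 500 + k)
      R <- sort(sample(5, k + 1))        # hypothetical earlier rejections
      I <- setdiff(seq_len(5), R)
      Js <- utils::combn(R, k - 1, simplify = FALSE)
      for (j in I) {
        if (donors[j] >= k) next
        wmin <- min(vapply(Js, function(J)
          unname(intersection_weights(g, c(I, J))[g$names[j]]),
          numeric(1)))
        expect_lte(wmin, unname(g$weights[j]) + 1e-12)
      }
    }
  }
})

test_that("k-FWER is controlled under the global null (Monte Carlo)", {
  g <- example_graph("diabetes")
  reps <- 2000
  set.seed(7)
  P <- matrix(stats::runif(reps * 4), reps, 4,
              dimnames = list(NULL, g$names))
  for (k in 2:3) {
    v_aug <- v_gen <- 0
    for (b in seq_len(reps)) {
      p <- P[b, ]
      v_aug <- v_aug +
        (length(augmented_kfwer(g, p, .05, k, delta = Inf)$rejected) >= k)
      v_gen <- v_gen +
        (length(generalized_kfwer(g, p, .05, k)$rejected) >= k)
    }
    bound <- .05 + 3 * sqrt(.05 * .95 / reps)
    expect_lte(v_aug / reps, bound)
    expect_lte(v_gen / reps, bound)
  }
})
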