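test_that("augmentation count solves the integer maximisation", {
  expect_equal(augmentation_count(2, 0.45), 1L)
  expect_equal(augmentation_count(2, 0.5), 2L)
  expect_equal(augmentation_count(8, 0.2), 2L)
  expect_equal(augmentation_count(8, 0.3), 3L)
  expect_equal(augmentation_count(5, 0), 0L)
  expect_equal(augmentation_count(0, 0.9), 0L)
  expect_equal(augmentation_count(2, 0.5, num_remaining = 1), 1L)
  expect_error(augmentation_count(2, 1), "gamma")

  # exhaustive agreement over a dense grid (floating boundaries included)
  for (R in c(1:20, 50, 100)) {
    for (gamma in seq(0, 0.99, by = 0.01)) {
      expect_identical(augmentation_count(R, gamma),
                       augmentation_count_oracle(R, gamma),
                       info = sprintf("R=%d gamma=%.2f", R, gamma))
    }
  }
})

test_that("augmented FDP reproduces the gamma brackets of the example", {
  g <- example_graph("diabetes")
  p <- example_pvalues("diabetes-b")
  expect_setequal(augmented_fdp(g, p, .05, gamma = .25, delta = .5)$rejected,
                  c("H1", "H2"))
  expect_setequal(augmented_fdp(g, p, .05, gamma = .4, delta = .5)$rejected,
                  c("H1", "H2", "H3"))
  expect_setequal(augmented_fdp(g, p, .05, gamma = .5, delta = .5)$rejected,
                  c("H1", "H2", "H3", "H4"))
  # gamma = 0 reduces to the FWER shortcut
  expect_equal(augmented_fdp(g, p, .05, gamma = 0, delta = .5)$rejected,
               graphical_fwer_test(g, p, .05)$rejected)
})

test_that("augmented and adjusted-augmented FDP agree for delta = Inf", {
  for (seed in 1:30) {
    g <- random_graph(5, seed = seed, full_rows = TRUE)
    p <- random_pvalues(g, seed + 600)
    for (gamma in c(.2, .4, .6)) {
      expect_setequal(
        augmented_fdp(g, p, .05, gamma, delta = Inf)$rejected,
        adjusted_augmented_fdp(g, p, .05, gamma)$rejected)
    }
  }
})

test_that("everything remaining is rejected when D exceeds |I|", {
  g <- holm_graph(3)
  p <- c(H1 = .001, H2 = .002, H3 = .9)
  res <- adjusted_augmented_fdp(g, p, .05, gamma = .9)
  expect_setequal(res$rejected, c("H1", "H2", "H3"))
})

test_that("generalized FDP follows the round structure of the example", {
  g <- example_graph("diabetes")
  p <- example_pvalues("diabetes-b")
  r1 <- generalized_fdp(g, p, .05, gamma = .25, delta = .5)
  expect_setequal(r1$rejected, c("H1", "H2"))
  expect_equal(r1$rounds$k, 1L)

  r3 <- generalized_fdp(g, p, .05, gamma = .7, delta = .5)
  expect_setequal(r3$rejected, c("H1", "H2"))
  expect_equal(r3$rounds$k, 1:3)
  expect_equal(r3$rounds$rejections, rep(2L, 3))

  # gamma small enough that 1/gamma - 1 > m: identical to FWER
  r0 <- generalized_fdp(g, p, .05, gamma = .1, delta = .5)
  expect_equal(sort(r0$rejected),
               sort(graphical_fwer_test(g, p, .05)$rejected))
  expect_equal(generalized_fdp(g, p, .05, gamma = 0)$rejected,
               graphical_fwer_test(g, p, .05)$rejected)
})

test_that("augmented FDP rejection sets grow with gamma", {
  for (seed in 1:10) {
    g <- random_graph(6, seed = seed)
    p <- random_pvalues(g, seed + 700)
    prev <- character(0)
    for (gamma in c(0, .1, .2, .3, .5, .7)) {
      cur <- augmented_fdp(g, p, .05, gamma, delta = .8)$rejected
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("FDR bounds evaluate both printed forms", {
  b <- fdr_bounds(.05, .3)
  expect_equal(b$asymptotic, .10)
  expect_equal(b$lehmann_romano, .335)
  expect_equal(b$smaller, "asymptotic")
  expect_false(b$lr_beats_asymptotic)

  b2 <- fdr_bounds(.05, .02)
  expect_equal(b2$lehmann_romano, .05 * .98 + .02)
  expect_equal(b2$smaller, "lehmann_romano")
  expect_true(b2$lr_beats_asymptotic)

  b0 <- fdr_bounds(.05, 0)
  expect_equal(b0$lehmann_romano, .05)
})

test_that("FDP tail probability is controlled on the fixture (Monte Carlo)", {
  g <- example_graph("diabetes")
  reps <- 2000
  set.seed(11)
  bound <- .05 + 3 * sqrt(.05 * .95 / reps)
  for (config in c("null", "mixed")) {
    exceed <- stats::setNames(numeric(3), c(".1", ".2", ".3"))
    for (b in seq_len(reps)) {
      p <- stats::runif(4)
      nulls <- c(TRUE, TRUE, TRUE, TRUE)
      if (config == "mixed") {
        nulls <- c(FALSE, TRUE, FALSE, TRUE)
        p[!nulls] <- stats::pnorm(stats::rnorm(2, 3), lower.tail = FALSE)
      }
      names(p) <- g$names
      for (i in seq_along(exceed)) {
        gamma <- c(.1, .2, .3)[i]
        rej <- augmented_fdp(g, p, .05, gamma, delta = Inf)$rejected
        V <- sum(nulls[match(rej, g$names)])
        if (V / max(length(rej), 1) > gamma)
          exceed[i] <- exceed[i] + 1
      }
    }
    expect_true(all(exceed / reps <= bound),
                info = paste("config", config))
  }
})
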