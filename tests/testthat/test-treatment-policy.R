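chainMdp <- function() {
  readMdp(system.file("extdata", "chain_mdp.json", package = "OncoFusion"))
}

test_that("discounted return follows the geometric weighting", {
  expect_equal(discountedReturn(c(1, 1, 1, 1), 0.5), 1.875,
               tolerance = 1e-12)
  ## gamma -> 0 limit: only the first reward survives
  expect_equal(discountedReturn(c(3, 9, 9), 1e-12), 3, tolerance = 1e-9)
  r <- c(7, -2, 5)
  expect_equal(discountedReturn(r, 1), sum(r))
  expect_identical(discountedReturn(numeric(0), 0.9), 0)
  expect_identical(discountedReturn(c(0, 0, 0), 0.9), 0)
  expect_error(discountedReturn(c(1, 2), 0), "gamma")
})

test_that("the Bellman target handles terminal and discount limits", {
  q <- matrix(c(1, 2, 0.5, 2), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_identical(bellmanTarget(3, "a", TRUE, q, 0.9), 3)
  expect_identical(bellmanTarget(3, "a", FALSE, q, 1e-300), 3)
  ## r = 1, gamma = 0.5, max Q(s') = 2 -> 2.0
  expect_equal(bellmanTarget(1, "b", FALSE, q, 0.5), 2, tolerance = 1e-12)
})

test_that("the TD loss is zero at the fixed point and adds the entropy
          bonus", {
  mdp <- chainMdp()
  qstar <- valueIteration(mdp, tolerance = 1e-12)
  batch <- data.frame(s = c("s1", "s2", "s3"),
                      a = c("advance", "advance", "advance"),
                      r = c(0, 0, 10),
                      sPrime = c("s2", "s3", "s4"),
                      done = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  expect_lt(tdLoss(qstar, batch, qstar, gamma = mdp@gamma), 1e-16)
  ## single transition with Q(s, a) = 1 and target 3: (1 - 3)^2 = 4
  q1 <- matrix(c(1, 0, 3, 0), 2, 2,
               dimnames = list(c("s", "t"), c("a", "b")))
  b1 <- data.frame(s = "s", a = "a", r = 3, sPrime = "t", done = TRUE,
                   stringsAsFactors = FALSE)
  expect_equal(tdLoss(q1, b1, q1, gamma = 0.9), 4, tolerance = 1e-12)
  ## uniform Q row over 2 actions, lambda_H = 1, zero TD term: -ln 2
  q2 <- matrix(0, 1, 2, dimnames = list("s", c("a", "b")))
  b2 <- data.frame(s = "s", a = "a", r = 0, sPrime = "s", done = TRUE,
                   stringsAsFactors = FALSE)
  expect_equal(tdLoss(q2, b2, q2, gamma = 0.9, lambdaH = 1), -log(2),
               tolerance = 1e-12)
  expect_error(tdLoss(q2, b2[0, ], q2, 0.9), "nonempty")
})

test_that("action selection explores and breaks ties as documented", {
  expect_identical(greedyAction(c(0.5, 2, 1)), 2L)
  expect_identical(greedyAction(c(0, 0)), 1L)  # lowest index on ties
  set.seed(3)
  expect_identical(epsilonGreedy(c(0.5, 2, 1), 0), 2L)
  ## epsilon = 1: uniform over actions (3 standard errors)
  set.seed(11)
  draws <- replicate(10000L, epsilonGreedy(c(0, 1, 0, 0), 1))
  se <- sqrt(0.25 * 0.75 / 10000)
  for (a in 1:4) expect_lt(abs(mean(draws == a) - 0.25), 3 * se)
  expect_error(greedyAction(numeric(0)), "empty")
  expect_error(epsilonGreedy(c(1, 2), 1.5), "epsilon")
})

test_that("value iteration reproduces closed-form fixed points", {
  ## single absorbing state with reward 1 and gamma 0.5: Q* = 2
  one <- mdpSpec("s", "a", array(1, c(1, 1, 1)), array(1, c(1, 1, 1)),
                 gamma = 0.5)
  expect_equal(valueIteration(one, 1e-12)[1, 1], 2, tolerance = 1e-9)
  ## gamma -> 0 limit: Q*(s, a) = E[r(s, a)]
  mdp <- chainMdp()
  small <- mdpSpec(mdp@states, mdp@actions, mdp@trans, mdp@reward,
                   gamma = 1e-12, terminal = mdp@terminal,
                   initDist = mdp@initDist)
  q0 <- valueIteration(small, 1e-15)
  expected <- apply(mdp@trans * mdp@reward, c(1, 2), sum)
  expected[mdp@states %in% mdp@terminal, ] <- 0
  expect_equal(unname(q0), unname(expected), tolerance = 1e-9)
  ## the chain fixture matches the hand-derived optimum
  qstar <- valueIteration(mdp, tolerance = 1e-10)
  byHand <- matrix(c(8.1, 9, 10, 0, 7.79, 8.6, 9.5, 0), 4, 2)
  expect_equal(unname(qstar), byHand, tolerance = 1e-7)
  ## one extra sweep moves the result by less than the tolerance
  V <- apply(qstar, 1, max); V[mdp@states %in% mdp@terminal] <- 0
  qNext <- qstar
  for (s in 1:4) for (a in 1:2)
    qNext[s, a] <- sum(mdp@trans[s, a, ] *
                         (mdp@reward[s, a, ] + mdp@gamma * V))
  qNext[mdp@states %in% mdp@terminal, ] <- 0
  expect_lt(max(abs(qNext - qstar)), 1e-10)
})

test_that("Q-learning is deterministic under a fixed seed", {
  mdp <- chainMdp()
  cfgQ <- policyConfig(episodes = 60L, seed = 4L)
  a <- trainQLearning(mdp, cfgQ)
  b <- trainQLearning(mdp, cfgQ)
  expect_identical(a$Q, b$Q)
  expect_identical(a$log, b$log)
})

test_that("a large entropy weight drives the policy towards uniform", {
  mdp <- chainMdp()
  res <- trainQLearning(mdp, policyConfig(episodes = 300L, lambdaH = 25,
                                          lr = 0.05, seed = 2L))
  nonterm <- setdiff(mdp@states, mdp@terminal)
  for (s in nonterm) {
    pi <- exp(res$Q[s, ]); pi <- pi / sum(pi)
    expect_gt(shannonEntropy(pi) / log(2), 0.9)
  }
})

test_that("the toy oncology MDP is a valid absorbing process", {
  mdp <- toyOncologyMdp()
  expect_true(validObject(mdp))
  ## terminal state: absorbing self-loop with zero reward
  ti <- which(mdp@states == "terminal")
  for (a in seq_along(mdp@actions)) {
    expect_identical(mdp@trans[ti, a, ti], 1)
    expect_identical(sum(mdp@trans[ti, a, -ti]), 0)
    expect_identical(mdp@reward[ti, a, ti], 0)
  }
  ## seed argument does not change the tables
  expect_identical(toyOncologyMdp(1)@trans, toyOncologyMdp(99)@trans)
  ## value iteration converges to a finite optimum
  q <- valueIteration(mdp, tolerance = 1e-9)
  expect_true(all(is.finite(q)))
})

test_that("MDP JSON round-trips exactly", {
  mdp <- toyOncologyMdp()
  f <- withr::local_tempfile(fileext = ".json")
  writeMdp(mdp, f)
  back <- readMdp(f)
  expect_identical(back@states, mdp@states)
  expect_identical(back@trans, mdp@trans)
  expect_identical(back@reward, mdp@reward)
  expect_identical(back@gamma, mdp@gamma)
  expect_identical(back@terminal, mdp@terminal)
  expect_identical(back@initDist, mdp@initDist)
})
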