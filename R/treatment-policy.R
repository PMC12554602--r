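#' Construct a tabular MDP specification
#'
#' @param states character state labels.
#' @param actions character action labels.
#' @param trans transition array \code{P[s, a, s']}; each \code{P(.|s,a)}
#'   must sum to 1.
#' @param reward reward array \code{r(s, a, s')} of the same dimension, or
#'   a \code{|S| x |A|} matrix \code{r(s, a)} (expanded over s').
#' @param gamma discount factor in (0, 1].
#' @param terminal character subset of absorbing states.
#' @param initDist initial state distribution (default: uniform over
#'   non-terminal states).
#' @return a validated \linkS4class{MDPSpec}.
#' @export
mdpSpec <- function(states, actions, trans, reward, gamma = 0.9,
                    terminal = character(), initDist = NULL) {
  nS <- length(states); nA <- length(actions)
  if (is.matrix(reward) && identical(dim(reward), c(nS, nA))) {
    r3 <- array(0, dim = c(nS, nA, nS))
    for (sp in seq_len(nS)) r3[, , sp] <- reward
    reward <- r3
  }
  if (is.null(initDist)) {
    nonterm <- !(states %in% terminal)
    if (!any(nonterm)) nonterm <- rep(TRUE, nS)
    initDist <- as.numeric(nonterm) / sum(nonterm)
  }
  dimnames(trans) <- dimnames(reward) <- list(states, actions, states)
  new("MDPSpec", states = states, actions = actions, trans = trans,
      reward = reward, gamma = gamma, terminal = terminal,
      initDist = initDist)
}

#' Discounted return of a reward sequence
#'
#' \eqn{\sum_t \gamma^t r_t} over one episode of care (an empty sequence
#' returns 0 by convention).
#'
#' @param rewards numeric reward sequence.
#' @param gamma discount factor in (0, 1].
#' @return scalar return.
#' @export
#' @examples
#' discountedReturn(c(1, 1, 1, 1), 0.5)  # 1.875
discountedReturn <- function(rewards, gamma) {
  if (gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]")
  if (!length(rewards)) return(0)
  sum(gamma ^ (seq_along(rewards) - 1L) * rewards)
}

#' Bellman target for one transition
#'
#' \eqn{r} if the transition is terminal, else
#' \eqn{r + \gamma \max_{a'} Q_{target}(s', a')}.
#'
#' @param r observed reward.
#' @param sPrime next-state label or index.
#' @param done terminal flag.
#' @param qTarget target Q table (states x actions).
#' @param gamma discount factor.
#' @return scalar target value.
#' @export
bellmanTarget <- function(r, sPrime, done, qTarget, gamma) {
  if (done) return(r)
  r + gamma * max(qTarget[sPrime, ])
}

## Softmax policy over one Q row at a given temperature.
softPolicy <- function(qRow, temperature) softmaxVec(qRow / temperature)

#' Entropy-regularized temporal-difference loss
#'
#' Mean squared TD error over a batch of transitions minus
#' \eqn{\lambda_H} times the mean entropy of the softmax policy
#' \eqn{\pi(\cdot|s) = \mathrm{softmax}(Q(s,\cdot)/\mathrm{temperature})}.
#' Targets are computed from \code{qTarget} and treated as constants.
#'
#' @param q Q table (states x actions).
#' @param batch data.frame with columns \code{s}, \code{a} (labels or
#'   indices), \code{r}, \code{sPrime}, \code{done}.
#' @param qTarget target-network Q table.
#' @param gamma discount factor.
#' @param lambdaH entropy regularization weight (>= 0).
#' @param temperature softmax temperature (> 0).
#' @return scalar loss (can be negative through the entropy bonus).
#' @export
tdLoss <- function(q, batch, qTarget = q, gamma = 0.99, lambdaH = 0,
                   temperature = 1) {
  if (!nrow(batch)) stop("'batch' must be nonempty")
  if (temperature <= 0) stop("'temperature' must be > 0")
  td <- vapply(seq_len(nrow(batch)), function(i) {
    tgt <- bellmanTarget(batch$r[i], batch$sPrime[i], batch$done[i],
                         qTarget, gamma)
    (q[batch$s[i], batch$a[i]] - tgt)^2
  }, numeric(1))
  ent <- vapply(seq_len(nrow(batch)), function(i)
    shannonEntropy(softPolicy(q[batch$s[i], ], temperature)), numeric(1))
  mean(td) - lambdaH * mean(ent)
}

#' Action selection
#'
#' \code{greedyAction} returns the argmax action of a Q row with ties
#' broken towards the lowest action index; \code{epsilonGreedy} returns a
#' uniformly random action with probability \eqn{\epsilon} and the greedy
#' action otherwise (drawn from the ambient RNG stream, so seed with
#' \code{set.seed}).
#'
#' @param qRow finite numeric vector of action values for one state.
#' @param epsilon exploration probability in [0, 1].
#' @return 1-based action index.
#' @name actionSelection
NULL

#' @rdname actionSelection
#' @export
greedyAction <- function(qRow) {
  if (!length(qRow)) stop("empty action set")
  if (any(!is.finite(qRow))) stop("Q values must be finite")
  which.max(qRow)  # which.max breaks ties towards the lowest index
}

#' @rdname actionSelection
#' @export
epsilonGreedy <- function(qRow, epsilon) {
  checkProb(epsilon, "epsilon")
  if (!length(qRow)) stop("empty action set")
  if (epsilon > 0 && stats::runif(1L) < epsilon)
    sample.int(length(qRow), 1L)
  else greedyAction(qRow)
}

#' Value iteration (oracle for the Bellman fixed point)
#'
#' Synchronous value iteration on a tabular MDP until the sup-norm change
#' falls below \code{tolerance}; terminal states are pinned to value 0.
#'
#' @param mdp an \linkS4class{MDPSpec}.
#' @param tolerance convergence threshold on the sup-norm Q change.
#' @param maxIter iteration cap.
#' @return the optimal action-value table Q* (states x actions).
#' @export
valueIteration <- function(mdp, tolerance = 1e-8, maxIter = 10000L) {
  validObject(mdp)
  nS <- length(mdp@states); nA <- length(mdp@actions)
  termIdx <- mdp@states %in% mdp@terminal
  Q <- matrix(0, nS, nA, dimnames = list(mdp@states, mdp@actions))
  for (iter in seq_len(maxIter)) {
    V <- apply(Q, 1L, max)
    V[termIdx] <- 0
    Qnew <- Q
    for (s in seq_len(nS)) for (a in seq_len(nA)) {
      p <- mdp@trans[s, a, ]
      Qnew[s, a] <- sum(p * (mdp@reward[s, a, ] + mdp@gamma * V))
    }
    Qnew[termIdx, ] <- 0
    delta <- max(abs(Qnew - Q))
    Q <- Qnew
    if (delta < tolerance) return(Q)
  }
  warning("value iteration hit maxIter before reaching tolerance")
  Q
}

#' Q-learning policy configuration
#'
#' @param episodes number of training episodes.
#' @param maxSteps step cap per episode.
#' @param lr learning rate of the TD gradient step.
#' @param epsilonStart,epsilonEnd,epsilonDecaySteps linear epsilon-greedy
#'   schedule.
#' @param lambdaH entropy regularization weight (>= 0).
#' @param temperature softmax temperature of the policy used for the
#'   entropy term.
#' @param replayCapacity experience-replay buffer size.
#' @param batchSize replay sample size per update.
#' @param targetSyncInterval steps between hard target-network copies.
#' @param seed RNG seed.
#' @return named list.
#' @export
policyConfig <- function(episodes = 2000L, maxSteps = 50L, lr = 0.1,
                         epsilonStart = 1, epsilonEnd = 0.05,
                         epsilonDecaySteps = 2000L, lambdaH = 0,
                         temperature = 1, replayCapacity = 2000L,
                         batchSize = 32L, targetSyncInterval = 100L,
                         seed = 1L) {
  checkProb(epsilonStart, "epsilonStart")
  checkProb(epsilonEnd, "epsilonEnd")
  if (temperature <= 0) stop("'temperature' must be > 0")
  if (lambdaH < 0) stop("'lambdaH' must be >= 0")
  list(episodes = as.integer(episodes), maxSteps = as.integer(maxSteps),
       lr = lr, epsilonStart = epsilonStart, epsilonEnd = epsilonEnd,
       epsilonDecaySteps = as.integer(epsilonDecaySteps),
       lambdaH = lambdaH, temperature = temperature,
       replayCapacity = as.integer(replayCapacity),
       batchSize = as.integer(batchSize),
       targetSyncInterval = as.integer(targetSyncInterval),
       seed = as.numeric(seed))
}

#' Tabular Q-learning with replay and a target network
#'
#' Episode loop with epsilon-greedy acting, uniform experience-replay
#' sampling, gradient descent on the entropy-regularized TD loss and
#' periodic hard target synchronization.  Deterministic given the config
#' seed.
#'
#' @param mdp an \linkS4class{MDPSpec}.
#' @param config a \code{\link{policyConfig}}.
#' @return list with \code{Q} (learned table), \code{log} (data.frame of
#'   per-episode return and epsilon) and \code{config}.
#' @export
trainQLearning <- function(mdp, config = policyConfig()) {
  validObject(mdp)
  set.seed(config$seed)
  nS <- length(mdp@states); nA <- length(mdp@actions)
  termIdx <- which(mdp@states %in% mdp@terminal)
  Q <- matrix(0, nS, nA, dimnames = list(mdp@states, mdp@actions))
  Qtarget <- Q
  bufS <- integer(0); bufA <- integer(0); bufR <- numeric(0)
  bufSP <- integer(0); bufD <- logical(0)
  globalStep <- 0L
  epRet <- numeric(config$episodes)
  epEps <- numeric(config$episodes)
  for (ep in seq_len(config$episodes)) {
    s <- sample.int(nS, 1L, prob = mdp@initDist)
    rewards <- numeric(0)
    for (st in seq_len(config$maxSteps)) {
      globalStep <- globalStep + 1L
      frac <- min(1, globalStep / max(1L, config$epsilonDecaySteps))
      eps <- config$epsilonStart +
        frac * (config$epsilonEnd - config$epsilonStart)
      a <- epsilonGreedy(Q[s, ], eps)
      sp <- sample.int(nS, 1L, prob = mdp@trans[s, a, ])
      r <- mdp@reward[s, a, sp]
      done <- sp %in% termIdx
      rewards <- c(rewards, r)
      ## ring-buffer insert
      if (length(bufS) >= config$replayCapacity) {
        drop1 <- ((globalStep - 1L) %% config$replayCapacity) + 1L
        bufS[drop1] <- s; bufA[drop1] <- a; bufR[drop1] <- r
        bufSP[drop1] <- sp; bufD[drop1] <- done
      } else {
        bufS <- c(bufS, s); bufA <- c(bufA, a); bufR <- c(bufR, r)
        bufSP <- c(bufSP, sp); bufD <- c(bufD, done)
      }
      ## replay update
      nBuf <- length(bufS)
      if (nBuf >= config$batchSize) {
        pick <- sample.int(nBuf, config$batchSize)
        grad <- matrix(0, nS, nA)
        for (k in pick) {
          tgt <- if (bufD[k]) bufR[k]
                 else bufR[k] + mdp@gamma * max(Qtarget[bufSP[k], ])
          grad[bufS[k], bufA[k]] <- grad[bufS[k], bufA[k]] +
            2 * (Q[bufS[k], bufA[k]] - tgt) / config$batchSize
          if (config$lambdaH > 0) {
            pi <- softPolicy(Q[bufS[k], ], config$temperature)
            H <- shannonEntropy(pi)
            dHdq <- -pi * (log(pmax(pi, 1e-300)) + H) / config$temperature
            grad[bufS[k], ] <- grad[bufS[k], ] -
              config$lambdaH * dHdq / config$batchSize
          }
        }
        Q <- Q - config$lr * grad
        if (any(!is.finite(Q)))
          stop("Q-learning diverged (non-finite Q) at episode ", ep)
      }
      if (globalStep %% config$targetSyncInterval == 0L) Qtarget <- Q
      s <- sp
      if (done) break
    }
    epRet[ep] <- discountedReturn(rewards, mdp@gamma)
    epEps[ep] <- eps
  }
  Q[termIdx, ] <- 0
  list(Q = Q, log = data.frame(episode = seq_len(config$episodes),
                               return_ = epRet, epsilon = epEps),
       config = config)
}

#' A toy oncology treatment MDP
#'
#' A fixed, documented 6-state treatment process: remission, stable
#' disease, two progression stages, treatment toxicity and an absorbing
#' terminal state, with 3 actions (standard dose, intensified dose,
#' supportive care).  Rewards are positive for response (reaching or
#' staying in remission) and negative for toxicity-induced complications;
#' the terminal state is absorbing with zero reward.  The tables are fixed
#' constants; \code{seed} is accepted for interface symmetry and does not
#' alter them.
#'
#' @param seed ignored (the MDP is fixed).
#' @return an \linkS4class{MDPSpec} with gamma = 0.9.
#' @export
toyOncologyMdp <- function(seed = NULL) {
  states <- c("remission", "stable", "progression1", "progression2",
              "toxicity", "terminal")
  actions <- c("standard", "intensified", "supportive")
  nS <- length(states); nA <- length(actions)
  P <- array(0, dim = c(nS, nA, nS), dimnames = list(states, actions, states))
  R <- array(0, dim = c(nS, nA, nS), dimnames = list(states, actions, states))
  tr <- function(s, a, probs) P[s, a, ] <<- probs
  ## order: remission stable prog1 prog2 toxicity terminal
  tr("remission", "standard",    c(0.80, 0.15, 0.00, 0.00, 0.05, 0.00))
  tr("remission", "intensified", c(0.75, 0.05, 0.00, 0.00, 0.20, 0.00))
  tr("remission", "supportive",  c(0.60, 0.35, 0.05, 0.00, 0.00, 0.00))
  tr("stable", "standard",       c(0.35, 0.45, 0.15, 0.00, 0.05, 0.00))
  tr("stable", "intensified",    c(0.50, 0.20, 0.10, 0.00, 0.20, 0.00))
  tr("stable", "supportive",     c(0.05, 0.60, 0.35, 0.00, 0.00, 0.00))
  tr("progression1", "standard", c(0.10, 0.35, 0.35, 0.15, 0.05, 0.00))
  tr("progression1", "intensified", c(0.25, 0.30, 0.15, 0.05, 0.25, 0.00))
  tr("progression1", "supportive",  c(0.00, 0.10, 0.55, 0.35, 0.00, 0.00))
  tr("progression2", "standard", c(0.00, 0.15, 0.25, 0.40, 0.10, 0.10))
  tr("progression2", "intensified", c(0.05, 0.25, 0.20, 0.20, 0.25, 0.05))
  tr("progression2", "supportive",  c(0.00, 0.00, 0.15, 0.60, 0.00, 0.25))
  tr("toxicity", "standard",     c(0.00, 0.25, 0.25, 0.10, 0.30, 0.10))
  tr("toxicity", "intensified",  c(0.00, 0.10, 0.20, 0.10, 0.45, 0.15))
  tr("toxicity", "supportive",   c(0.10, 0.45, 0.25, 0.05, 0.15, 0.00))
  P["terminal", , "terminal"] <- 1

  ## reward shaping: response is rewarded, toxicity and death penalized
  for (a in actions) {
    R[, a, "remission"] <- 5
    R[, a, "stable"] <- 1
    R[, a, "progression1"] <- -1
    R[, a, "progression2"] <- -3
    R[, a, "toxicity"] <- -4      # toxicity-induced hospitalization
    R[, a, "terminal"] <- -10
  }
  R["terminal", , "terminal"] <- 0
  mdpSpec(states, actions, P, R, gamma = 0.9, terminal = "terminal")
}

#' Read / write a tabular MDP as JSON
#'
#' @param mdp an \linkS4class{MDPSpec}.
#' @param path JSON file path.
#' @return \code{writeMdp} the path invisibly; \code{readMdp} an
#'   \linkS4class{MDPSpec}.
#' @name mdpIO
NULL

#' @rdname mdpIO
#' @export
writeMdp <- function(mdp, path) {
  obj <- list(states = mdp@states, actions = mdp@actions,
              gamma = mdp@gamma, terminal = mdp@terminal,
              initDist = mdp@initDist,
              trans = as.numeric(mdp@trans),
              reward = as.numeric(mdp@reward))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname mdpIO
#' @param path JSON file path.
#' @export
readMdp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nS <- length(obj$states); nA <- length(obj$actions)
  mdpSpec(obj$states, obj$actions,
          array(as.numeric(obj$trans), dim = c(nS, nA, nS)),
          array(as.numeric(obj$reward), dim = c(nS, nA, nS)),
          gamma = as.numeric(obj$gamma),
          terminal = as.character(obj$terminal %||% character()),
          initDist = as.numeric(obj$initDist))
}
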