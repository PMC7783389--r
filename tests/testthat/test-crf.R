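test_that("sequence scoring is the sum of active state and transition weights", {
  alpha <- c("S", "O")
  m0 <- crf_manual(c("lower=atp", "bias=1"), alpha)
  feats <- list(c("lower=atp", "bias=1"), c("bias=1"))
  expect_equal(sequence_score(m0, feats, c("S", "O")), 0)
  expect_equal(sequence_score(m0, feats, c("O", "O")), 0)

  Ws <- matrix(0, 2, 2); Ws[1, 1] <- 2.5   # atom "lower=atp", label S
  m1 <- crf_manual(c("lower=atp", "bias=1"), alpha, Ws)
  expect_equal(sequence_score(m1, list(c("lower=atp")), "S"), 2.5)
  expect_equal(sequence_score(m1, list(c("lower=atp")), "O"), 0)
  expect_error(sequence_score(m1, list(c("lower=atp")), "Q"), "unknown")

  # score difference of two labelings = sum of differing weight contributions
  set.seed(3)
  inst <- random_crf_instance(3L, 3L)
  y1 <- c("A", "B", "C"); y2 <- c("A", "C", "C")
  d <- sequence_score(inst$model, inst$feats, y1) -
       sequence_score(inst$model, inst$feats, y2)
  ids <- match(inst$feats[[2]], inst$model$feature_index)
  manual <- sum(inst$model$state_weights[ids, "B"]) -
    sum(inst$model$state_weights[ids, "C"]) +
    inst$model$transition_weights["A", "B"] - inst$model$transition_weights["A", "C"] +
    inst$model$transition_weights["B", "C"] - inst$model$transition_weights["C", "C"]
  expect_equal(d, manual)
})

test_that("log-partition matches the uniform closed form and brute-force enumeration", {
  m0 <- crf_manual("bias=1", LETTERS[1:5])
  feats3 <- rep(list("bias=1"), 3)
  expect_equal(log_partition(m0, feats3), 3 * log(5))

  set.seed(11)
  inst <- random_crf_instance(4L, 3L)
  expect_equal(log_partition(inst$model, inst$feats),
               enumerate_crf(inst$model, inst$feats)$logZ, tolerance = 1e-10)

  # adding c to every state weight of one position shifts logZ by exactly c
  m <- inst$model
  shift <- 0.7
  feats_shift <- inst$feats
  # give position 2 an extra private atom with weight `shift` for all labels
  m2 <- crf_manual(c(m$feature_index, "shift=1"), m$label_alphabet,
                   rbind(m$state_weights, rep(shift, 3)),
                   m$transition_weights)
  feats_shift[[2]] <- c(feats_shift[[2]], "shift=1")
  expect_equal(log_partition(m2, feats_shift),
               log_partition(m, inst$feats) + shift, tolerance = 1e-10)
  expect_error(log_partition(m, list()), "empty")
})

test_that("probabilities normalize: enumerated exp(score - logZ) sums to one", {
  set.seed(5)
  for (rep in 1:5) {
    inst <- random_crf_instance(sample(2:4, 1L), sample(2:4, 1L))
    en <- enumerate_crf(inst$model, inst$feats)
    lz <- log_partition(inst$model, inst$feats)
    expect_equal(lz, en$logZ, tolerance = 1e-10)
    grid <- as.matrix(expand.grid(rep(list(inst$model$label_alphabet),
                                      length(inst$feats))))
    total <- sum(apply(grid, 1L, function(y) {
      exp(sequence_score(inst$model, inst$feats, unname(y)) - lz)
    }))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("viterbi equals the enumeration argmax with the stated tie-break", {
  m0 <- crf_manual("bias=1", c("S", "O", "B"))
  expect_equal(viterbi_decode(m0, rep(list("bias=1"), 4)), rep("S", 4))

  Ws <- matrix(0, 1, 3); Ws[1, 2] <- 5
  mO <- crf_manual("bias=1", c("S", "O", "B"), Ws)
  expect_equal(viterbi_decode(mO, rep(list("bias=1"), 6)), rep("O", 6))

  set.seed(13)
  inst <- random_crf_instance(5L, 4L)
  en <- enumerate_crf(inst$model, inst$feats)
  vit <- viterbi_decode(inst$model, inst$feats)
  expect_equal(vit, en$best_labels)
  expect_equal(sequence_score(inst$model, inst$feats, vit), en$best_score,
               tolerance = 1e-10)
})

test_that("the unregularized log-likelihood is non-positive and the gradient is exact", {
  set.seed(17)
  inst <- random_crf_instance(4L, 3L)
  cfg0 <- crf_config(c1 = 0, c2 = 0)
  m <- inst$model; m$config <- cfg0
  y <- list(c("A", "B", "A", "C"))
  r <- crf_loglik_grad(m, list(inst$feats), y)
  expect_lte(r$loglik, 0)

  # at w = 0 the gradient equals observed minus uniform expected counts
  z <- crf_manual(m$feature_index, m$label_alphabet, config = cfg0)
  r0 <- crf_loglik_grad(z, list(inst$feats), y)
  L <- length(m$label_alphabet)
  exp_state <- matrix(0, length(m$feature_index), L,
                      dimnames = dimnames(z$state_weights))
  for (t in seq_along(inst$feats)) {
    ids <- match(inst$feats[[t]], m$feature_index)
    exp_state[ids, y[[1]][t]] <- exp_state[ids, y[[1]][t]] + 1
    exp_state[ids, ] <- exp_state[ids, ] - 1 / L
  }
  expect_equal(r0$grad_state, exp_state, tolerance = 1e-12)
  exp_trans <- matrix(-(length(inst$feats) - 1) / L^2, L, L,
                      dimnames = dimnames(z$transition_weights))
  for (t in 2:length(inst$feats)) {
    exp_trans[y[[1]][t - 1], y[[1]][t]] <- exp_trans[y[[1]][t - 1], y[[1]][t]] + 1
  }
  expect_equal(r0$grad_trans, exp_trans, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(19)
  inst1 <- random_crf_instance(3L, 3L)
  inst2 <- random_crf_instance(4L, 3L)
  m <- inst1$model
  m$config <- crf_config(c1 = 0.05, c2 = 0.1)
  x <- list(inst1$feats, inst2$feats)
  y <- list(c("A", "C", "B"), c("B", "B", "A", "C"))
  objective <- function(model) crf_loglik_grad(model, x, y)$value
  r <- crf_loglik_grad(m, x, y)
  h <- 1e-6
  check <- function(getter, setter, grad) {
    for (i in seq_along(grad)) {
      mp <- setter(m, i, h); mm <- setter(m, i, -h)
      fd <- (objective(mp) - objective(mm)) / (2 * h)
      expect_equal(grad[i], fd, tolerance = 1e-5)
    }
  }
  set_state <- function(model, i, d) { model$state_weights[i] <- model$state_weights[i] + d; model }
  set_trans <- function(model, i, d) { model$transition_weights[i] <- model$transition_weights[i] + d; model }
  check(NULL, set_state, as.numeric(r$grad_state))
  check(NULL, set_trans, as.numeric(r$grad_trans))
})

test_that("fitting a separable corpus reproduces its labels and is deterministic", {
  toy <- separable_toyset()
  fit1 <- crf_fit(toy$x, toy$y, crf_config(max_iterations = 60))
  pred <- predict(fit1, toy$x)
  expect_identical(pred, toy$y)
  fit2 <- crf_fit(toy$x, toy$y, crf_config(max_iterations = 60))
  expect_identical(fit1$state_weights, fit2$state_weights)
  expect_identical(fit1$transition_weights, fit2$transition_weights)
  expect_lte(fit1$loglik, 0)
  # model object basics
  expect_s3_class(fit1, "crf")
  expect_true(all(is.finite(fit1$state_weights)))
  expect_output(print(fit1), "Linear-chain CRF")
  expect_output(print(summary(fit1)), "state weights")
  expect_named(coef(fit1), c("state", "transition"))
})

test_that("non-convergence within the iteration cap warns and flags the model", {
  toy <- separable_toyset(6L)
  expect_warning(fit <- crf_fit(toy$x, toy$y, crf_config(max_iterations = 2)),
                 "did not converge")
  expect_false(fit$converged)
})

test_that("hyperparameter tuning picks the config preserving the signal", {
  toy <- separable_toyset(12L)
  single <- crf_config(c1 = 0.3, c2 = 0.2, max_iterations = 40)
  expect_equal(tune_hyperparameters(toy$x, toy$y, list(single), k = 2),
               single, ignore_attr = TRUE)
  # duplicates do not change the result
  small <- crf_config(c1 = 0.1, c2 = 0.1, max_iterations = 40)
  heavy <- crf_config(c1 = 0.1, c2 = 1e4, max_iterations = 40)
  pick1 <- tune_hyperparameters(toy$x, toy$y, list(small, heavy), k = 2, seed = 9)
  pick2 <- tune_hyperparameters(toy$x, toy$y, list(small, heavy, small),
                                k = 2, seed = 9)
  expect_equal(pick1$c2, 0.1)
  expect_equal(pick2$c2, 0.1)
  expect_equal(attr(pick1, "cv_scores"), attr(pick2, "cv_scores")[1:2])
  expect_error(tune_hyperparameters(toy$x, toy$y, list(), k = 2), "empty")
})
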