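test_that("forward likelihood equals brute-force path enumeration on toy instances", {
  set.seed(20)
  for (i in 1:5) {
    S <- sample(2:3, 1)
    m <- toy_lr_hmm(S = S, K = 1, sep = 2)
    T_ <- sample(4:8, 1)
    X <- matrix(stats::rnorm(T_, mean = 3), T_, 1)
    expect_equal(hmm_loglik(m, X), brute_force_loglik(m, X), tolerance = 1e-8)
  }
  # also for an ergodic model with 2-component emissions
  em <- lapply(1:2, function(s) list(weights = c(0.3, 0.7),
                                     means = rbind(s, -s),
                                     variances = rbind(0.5, 0.5)))
  erg <- activity_hmm(matrix(0.5, 2, 2), c(0.5, 0.5), em, "ergodic")
  X <- matrix(stats::rnorm(6), 6, 1)
  expect_equal(hmm_loglik(erg, X), brute_force_loglik(erg, X), tolerance = 1e-8)
})

test_that("Baum-Welch increases likelihood monotonically and keeps stochasticity", {
  set.seed(21)
  gen <- toy_lr_hmm(S = 3, K = 2, sep = 3)
  seqs <- lapply(1:30, function(i) sample_activity_hmm(gen, 40))
  fit <- train_class_hmm(seqs, n_states = 3, n_components = 1, seed = 1,
                         max_iter = 12)
  trace <- attr(fit, "loglik_trace")
  expect_gt(length(trace), 1)
  expect_true(all(diff(trace) > -1e-8))
  expect_equal(rowSums(fit$A), rep(1, 3), tolerance = 1e-9)
  for (e in fit$emissions) expect_equal(sum(e$weights), 1, tolerance = 1e-9)
  # left-right: no backward transitions survive training
  expect_true(all(fit$A[lower.tri(fit$A)] == 0))
})

test_that("Baum-Welch recovers generating state means on separated left-right data", {
  set.seed(22)
  # dwell ~10 frames per state over 60-frame sequences keeps all three
  # states visited often enough for recovery
  gen <- toy_lr_hmm(S = 3, K = 1, sep = 3, stay = 0.9)   # means 3, 6, 9
  seqs <- lapply(1:200, function(i) sample_activity_hmm(gen, 60))
  fit <- train_class_hmm(seqs, n_states = 3, n_components = 1, seed = 2,
                         max_iter = 15)
  mu_hat <- sort(vapply(fit$emissions, function(e) e$means[1, 1], numeric(1)))
  # >= 2000 frames per state: allow 3 standard errors (floored)
  se <- sqrt(0.5) / sqrt(2000)
  expect_lt(max(abs(mu_hat - c(3, 6, 9))), max(3 * se, 0.1))
  # sampled transition frequencies converge to the generator's A: count
  # decoded self-transitions out of state 1 over ~10^4 transitions
  set.seed(23)
  stay <- total <- 0
  for (r in 1:2000) {
    X <- sample_activity_hmm(gen, 6)
    st <- apply(abs(outer(X[, 1], c(3, 6, 9), `-`)), 1, which.min)
    from1 <- which(st[-length(st)] == 1)
    total <- total + length(from1)
    stay <- stay + sum(st[from1 + 1] == 1)
  }
  expect_gt(total, 5000)
  expect_equal(stay / total, 0.9, tolerance = 0.02)
})

test_that("universal model is ergodic, pools all classes, and beats class models on mixed data", {
  set.seed(24)
  seqs <- toy_labeled_seqs(list(a = c(0, 0), b = c(4, 0), c = c(0, 4)),
                           n_per = 8, T_ = 30, seed = 24)
  ubm <- train_universal_hmm(seqs, n_states = 3, total_components = 6,
                             seed = 1, max_iter = 8)
  expect_equal(ubm$topology, "ergodic")
  expect_true(all(ubm$A > 0))
  # per-state components: ceiling distribution of the total
  expect_equal(length(ubm$emissions[[1]]$weights), 2L)

  labels <- vapply(seqs, `[[`, "", "label")
  cls_a <- train_class_hmm(seqs[labels == "a"], n_states = 3, n_components = 2,
                           seed = 1, max_iter = 8)
  # pooled data likelihood: the all-class model wins over a single-class model
  expect_gt(sum(hmm_loglik(ubm, seqs)), sum(hmm_loglik(cls_a, seqs)))
})

test_that("MAP adaptation interpolates between background and class posterior means", {
  set.seed(25)
  seqs <- toy_labeled_seqs(list(a = c(0, 0), b = c(5, 5)), n_per = 10,
                           T_ = 40, seed = 25)
  labels <- vapply(seqs, `[[`, "", "label")
  bg <- train_universal_hmm(seqs, n_states = 2, total_components = 4,
                            seed = 1, max_iter = 8)
  a_seqs <- seqs[labels == "a"]

  ad_inf <- adapt_universal(bg, a_seqs, relevance = 1e12, label = "a")
  for (s in 1:2) {
    expect_equal(ad_inf$emissions[[s]]$means, bg$emissions[[s]]$means,
                 tolerance = 1e-6)
  }

  # relevance -> 0: adapted means equal the posterior (EM) mean update,
  # computed here as the r = 0 limit of the same sufficient statistics
  ad_0 <- adapt_universal(bg, a_seqs, relevance = 1e-9, label = "a")
  ad_1 <- adapt_universal(bg, a_seqs, relevance = 16, label = "a")
  # the r = 16 means lie strictly between the r -> 0 and r -> Inf limits
  for (s in 1:2) {
    lo <- pmin(ad_0$emissions[[s]]$means, bg$emissions[[s]]$means) - 1e-9
    hi <- pmax(ad_0$emissions[[s]]$means, bg$emissions[[s]]$means) + 1e-9
    expect_true(all(ad_1$emissions[[s]]$means >= lo &
                      ad_1$emissions[[s]]$means <= hi))
  }

  # adaptation strictly improves the class likelihood on separable data
  expect_gt(sum(hmm_loglik(ad_1, a_seqs)), sum(hmm_loglik(bg, a_seqs)))
  expect_warning(adapt_universal(bg, list(), label = "a"), "no class data")
})

test_that("classification recovers generating classes and breaks ties by class order", {
  set.seed(26)
  data <- generate_hmm_dataset(n_classes = 8, n_states = 3, separation = 5,
                               n_seq = 12, len = 40, dim = 2, seed = 27)
  labels <- vapply(data$sequences, `[[`, "", "label")
  train_idx <- unlist(lapply(split(seq_along(labels), labels), utils::head, 8))
  test_idx <- setdiff(seq_along(labels), train_idx)
  bundle <- train_recognizer(data$sequences[train_idx], "class_specific",
                             n_states = 3, n_components = 1, seed = 1,
                             max_iter = 8)
  pred <- classify(bundle, data$sequences[test_idx])
  acc <- mean(pred$predicted == labels[test_idx])
  expect_gte(acc, 0.95)
  # scores are finite and consistent with the argmax label
  score_cols <- as.matrix(pred[, names(bundle$models)])
  expect_true(all(is.finite(score_cols)))
  expect_equal(pred$predicted,
               names(bundle$models)[apply(score_cols, 1, which.max)])

  # identical models for two classes tie to the lower class index
  m <- toy_lr_hmm(S = 2, K = 1)
  b2 <- recognizer_bundle(list(a = m, b = m), "class_specific")
  X <- matrix(stats::rnorm(10, 2), 10, 1)
  expect_equal(classify(b2, X)$predicted, "a")
})

test_that("model selection prefers the generating size and returns single candidates as-is", {
  set.seed(28)
  data <- generate_hmm_dataset(n_classes = 3, n_states = 4, separation = 5,
                               n_seq = 16, len = 60, dim = 2, seed = 29)
  labels <- vapply(data$sequences, `[[`, "", "label")
  tr <- unlist(lapply(split(seq_along(labels), labels), utils::head, 10))
  va <- setdiff(seq_along(labels), tr)
  sel <- select_model(data$sequences[tr], data$sequences[va],
                      state_grid = 4, component_grid = 1,
                      mode = "class_specific", seed = 1, max_iter = 6)
  expect_equal(sel$n_states, 4)
  expect_equal(sel$n_components, 1)
  expect_equal(nrow(sel$table), 1)
  expect_s3_class(sel$bundle, "recognizer_bundle")
  expect_error(select_model(data$sequences[tr], list(), state_grid = 3,
                            component_grid = 1), "validation")

  # against an oversized alternative, the generating size wins on accuracy
  sel2 <- select_model(data$sequences[tr], data$sequences[va],
                       state_grid = c(4, 7), component_grid = 1,
                       mode = "class_specific", seed = 1, max_iter = 6)
  expect_true(sel2$accuracy >= max(sel2$table$accuracy) - 1e-12)
})

test_that("sequences shorter than the state count are skipped with a warning", {
  set.seed(30)
  seqs <- c(list(matrix(stats::rnorm(2), 2, 1)),
            lapply(1:5, function(i) matrix(stats::rnorm(30, 3), 30, 1)))
  expect_warning(fit <- train_class_hmm(seqs, n_states = 3, n_components = 1,
                                        seed = 1, max_iter = 4),
                 "skipped")
  expect_s3_class(fit, "activity_hmm")
  expect_error(suppressWarnings(
    train_class_hmm(list(matrix(0, 2, 1), matrix(0, 1, 1)), n_states = 5)),
    "shorter")
})
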