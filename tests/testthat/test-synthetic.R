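test_that("corpus generation is deterministic, labeled, imbalanced as requested, and clip-safe", {
  rec <- default_test_recipes(duration_s = 0.5, counts = c(3, 2, 2, 2, 4, 2, 2, 0))
  c1 <- generate_corpus(rec, seed = 9)
  c2 <- generate_corpus(rec, seed = 9)
  expect_equal(nrow(c1$manifest), 17)   # zero-count class absent
  expect_false("teeth_brushing" %in% c1$manifest$label)
  expect_identical(lapply(c1$clips, `[[`, "samples"),
                   lapply(c2$clips, `[[`, "samples"))
  peaks <- vapply(c1$clips, function(cl) max(abs(cl$samples)), numeric(1))
  expect_true(all(peaks <= 1))
  expect_equal(as.numeric(table(c1$manifest$label)["brew_coffee"]), 3)

  # WAV output round-trips byte-identically for the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_corpus(rec[1:2], seed = 4, dir = d1)
  generate_corpus(rec[1:2], seed = 4, dir = d2)
  f <- list.files(d1, pattern = "wav$")[1]
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
  man <- utils::read.delim(file.path(d1, "manifest.tsv"))
  expect_true(all(c("clip_id", "path", "label") %in% names(man)))

  expect_error(class_recipe("x", 3, noise_band = c(5000, 9000)), "Nyquist")
  expect_error(class_recipe("x", -1), "n_clips")
})

test_that("identity-linked pair has near-zero fitted divergence; transformed pairs are found", {
  base <- class_recipe("don", 1, duration_s = 1, noise_band = c(400, 2000),
                       band_jitter = 0.05, gain_jitter_db = 2)
  idp <- generate_linked_pair(linked_class_pair(base, "lim", "identity"),
                              n_donor = 6, n_limited = 6, seed = 3)
  fs_d <- lapply(idp$donor, extract_features, feature_set = "mfcc")
  fs_l <- lapply(idp$limited, extract_features, feature_set = "mfcc")
  g_d <- fit_gmm(fs_d, n_components = 4, seed = 1)
  g_l <- fit_gmm(fs_l, n_components = 4, seed = 1)
  d_same <- as.numeric(symmetrized_divergence(g_d, g_l, 1000, seed = 2))

  # a +500 Hz shifted class is found as closest to its own donor among four
  shifted <- generate_linked_pair(
    linked_class_pair(base, "lim", "shift", 500), n_donor = 6, n_limited = 6,
    seed = 4)
  far1 <- class_recipe("far1", 1, duration_s = 1, noise_band = c(3000, 6000),
                       band_jitter = 0.05, gain_jitter_db = 2)
  far2 <- class_recipe("far2", 1, duration_s = 1, noise_band = c(100, 300),
                       band_jitter = 0.05, gain_jitter_db = 2)
  set.seed(5)
  mk <- function(r, n) lapply(1:n, function(i)
    audio_clip(aharTL:::render_clip(r), label = r$class_id,
               clip_id = paste0(r$class_id, i)))
  models <- list(
    lim = fit_gmm(lapply(shifted$limited, extract_features, feature_set = "mfcc"),
                  4, seed = 1),
    don = g_d,
    far1 = fit_gmm(lapply(mk(far1, 6), extract_features, feature_set = "mfcc"),
                   4, seed = 1),
    far2 = fit_gmm(lapply(mk(far2, 6), extract_features, feature_set = "mfcc"),
                   4, seed = 1))
  pairing <- closest_class("lim", models, draws = 1000, seed = 6)
  expect_equal(pairing$donor_class, "don")
  # identity-linked divergence is far below the divergence to distinct classes
  expect_lt(d_same, min(pairing$table[c("far1", "far2")]) / 5)
})

test_that("fitted divergence grows with the transformation magnitude", {
  base <- class_recipe("don", 1, duration_s = 1, noise_band = c(400, 2000),
                       band_jitter = 0.05, gain_jitter_db = 2)
  g_don <- NULL
  divs <- numeric(0)
  for (mag in c(0, 800, 2500)) {
    lp <- generate_linked_pair(linked_class_pair(base, "lim", "shift", mag),
                               n_donor = 6, n_limited = 6, seed = 11)
    fs_l <- lapply(lp$limited, extract_features, feature_set = "mfcc")
    if (is.null(g_don)) {
      g_don <- fit_gmm(lapply(lp$donor, extract_features, feature_set = "mfcc"),
                       4, seed = 1)
    }
    g_l <- fit_gmm(fs_l, 4, seed = 1)
    divs <- c(divs, as.numeric(symmetrized_divergence(g_don, g_l, 1000, seed = 2)))
  }
  expect_true(all(diff(divs) > 0))
})

test_that("HMM dataset generators separate with separation and store usable ground truth", {
  d <- generate_hmm_dataset(n_classes = 3, n_states = 3, separation = 8,
                            n_seq = 6, len = 30, dim = 2, seed = 12)
  expect_length(d$generators, 3)
  expect_length(d$sequences, 18)
  labels <- vapply(d$sequences, `[[`, "", "label")
  # classify test halves with models trained on train halves
  tr <- unlist(lapply(split(seq_along(labels), labels), utils::head, 4))
  te <- setdiff(seq_along(labels), tr)
  bundle <- train_recognizer(d$sequences[tr], "class_specific", n_states = 3,
                             n_components = 1, seed = 1, max_iter = 6)
  expect_equal(mean(classify(bundle, d$sequences[te])$predicted == labels[te]), 1)

  # zero-variance emissions give constant observations per state
  g <- d$generators[[1]]
  for (s in 1:3) g$emissions[[s]]$variances[] <- 1e-300
  X <- sample_activity_hmm(g, 20)
  expect_lte(nrow(unique(round(X, 6))), 3)
  expect_error(generate_hmm_dataset(separation = 0), "separation")
})
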