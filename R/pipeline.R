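#' Experiment configuration
#'
#' Bundles every knob of the end-to-end evaluation: feature selection,
#' normalization, proximity settings, transfer grids, recognizer sizes,
#' cross-validation layout and the systems to compare. Defaults follow
#' the full parameterization (16-component proximity GMMs, 2000 Monte
#' Carlo draws, 3-fold cross-validation, 50 repetitions); `scaled = TRUE`
#' swaps in the desk-scale sizes used by the package's own experiments.
#'
#' @param feature_set `"mfcc"`, `"mpeg7"`, `"pwp"` or `"all"`.
#' @param normalize Mean/variance scaling fitted on training folds.
#' @param systems Subset of `c("chmm", "chmm_tl", "uhmm", "uhmm_tl")`.
#' @param gmm_components Proximity GMM components.
#' @param kl_draws Monte Carlo draws per KL direction.
#' @param gmm_frame_cap Per-class frame subsample cap for proximity GMMs
#'   (keeps EM affordable; 0 disables).
#' @param esn_grid Transfer-learning grid, see [esn_grid()].
#' @param pairing_strategy Supervision alignment for [learn_transfer()].
#' @param washout Reservoir washout frames.
#' @param chmm_states,chmm_components Class-specific HMM size.
#' @param uhmm_states,uhmm_components Universal HMM size (components =
#'   total across states).
#' @param relevance MAP relevance factor for universal adaptation.
#' @param bw_max_iter Baum-Welch iteration cap.
#' @param folds Cross-validation folds.
#' @param repetitions Number of repetitions (fold assignment and all
#'   seeds re-randomized per repetition).
#' @param seed Master seed.
#' @param scaled Use desk-scale defaults for everything unset.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(feature_set = "mfcc", normalize = TRUE,
                              systems = c("chmm", "chmm_tl", "uhmm", "uhmm_tl"),
                              gmm_components = 16L, kl_draws = 2000L,
                              gmm_frame_cap = 4000L,
                              esn_grid = NULL,
                              pairing_strategy = "transport",
                              washout = 10L,
                              chmm_states = 3L, chmm_components = 2L,
                              uhmm_states = 5L, uhmm_components = 64L,
                              relevance = 16, bw_max_iter = 8L,
                              folds = 3L, repetitions = 1L, seed = 1L,
                              scaled = TRUE) {
  systems <- match.arg(systems, c("chmm", "chmm_tl", "uhmm", "uhmm_tl"),
                       several.ok = TRUE)
  if (is.null(esn_grid)) {
    esn_grid <- aharTL::esn_grid(if (scaled) "small" else "full")
  }
  if (!scaled) {
    chmm_states <- 5L; chmm_components <- 16L
    uhmm_states <- 7L; uhmm_components <- 128L
    bw_max_iter <- 25L
    repetitions <- 50L
  }
  cfg <- list(feature_set = feature_set, normalize = normalize,
              systems = systems, gmm_components = gmm_components,
              kl_draws = kl_draws, gmm_frame_cap = gmm_frame_cap,
              esn_grid = esn_grid, pairing_strategy = pairing_strategy,
              washout = washout, chmm_states = chmm_states,
              chmm_components = chmm_components, uhmm_states = uhmm_states,
              uhmm_components = uhmm_components, relevance = relevance,
              bw_max_iter = bw_max_iter, folds = folds,
              repetitions = repetitions, seed = seed)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "experiment_config")
}

# Stable short hash of a config (provenance stamp on every report).
config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  v <- utils::head(utf8ToInt(s), 10000)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Stratified cross-validation folds
#'
#' Shuffles each class independently and deals clips round-robin, so
#' class proportions per fold differ by at most one clip. Classes with
#' fewer than `k` clips are kept wholly in training (fold `NA`) with a
#' warning.
#'
#' @param labels Character vector of class labels, one per clip.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..k` (or `NA`).
#' @export
stratified_folds <- function(labels, k = 3L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  local_seed(seed)
  fold <- rep(NA_integer_, length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      warning("class ", cl, " has fewer than ", k,
              " clips; kept wholly in training")
      next
    }
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# Assert that no test clip leaks into any training-side computation.
check_no_leakage <- function(train_ids, test_ids, stage) {
  bad <- intersect(train_ids, test_ids)
  if (length(bad) > 0) {
    stop("leakage at stage '", stage, "': test clip(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " present on the training side")
  }
  invisible(TRUE)
}

# Extract features for a whole corpus (list of audio_clips or a manifest
# data frame with clip paths).
corpus_features <- function(corpus, feature_set, grid = frame_grid()) {
  if (is.data.frame(corpus)) {
    clips <- lapply(seq_len(nrow(corpus)), function(i) {
      read_clip(corpus$path[i], label = corpus$label[i],
                clip_id = corpus$clip_id[i])
    })
  } else if (!is.null(corpus$clips)) {
    clips <- corpus$clips
  } else {
    clips <- corpus
  }
  lapply(clips, extract_features, feature_set = feature_set, grid = grid)
}

# Train-fold transfer augmentation for one repetition/fold. Returns the
# augmented training list plus the pairing table.
augment_training <- function(train_feats, cfg, seed) {
  labels <- vapply(train_feats, `[[`, "", "label")
  counts <- table(labels)
  med <- stats::median(as.numeric(counts))
  limited <- names(counts)[counts < med]
  if (length(limited) == 0) {
    return(list(train = train_feats, pairings = list()))
  }
  classes <- sort(unique(labels))
  models <- lapply(classes, function(cl) {
    X <- do.call(rbind, lapply(train_feats[labels == cl], `[[`, "values"))
    if (cfg$gmm_frame_cap > 0 && nrow(X) > cfg$gmm_frame_cap) {
      local_seed(seed)
      X <- X[sample.int(nrow(X), cfg$gmm_frame_cap), , drop = FALSE]
    }
    ncomp <- min(cfg$gmm_components, max(1L, nrow(X) %/% 10L))
    fit_gmm(X, n_components = ncomp, seed = seed,
            feature_set = cfg$feature_set)
  })
  names(models) <- classes
  pairings <- list()
  out <- train_feats
  for (cl in limited) {
    # donors must hold more training data than the class they augment
    cand <- names(counts)[counts > counts[[cl]]]
    if (length(cand) == 0) next
    pairing <- closest_class(cl, models[c(cl, cand)], draws = cfg$kl_draws,
                             seed = seed)
    pairings[[cl]] <- pairing
    donor_seqs <- train_feats[labels == pairing$donor_class]
    limited_seqs <- train_feats[labels == cl]
    rt <- learn_transfer(donor_seqs, limited_seqs, grid = cfg$esn_grid,
                         washout = cfg$washout, seed = seed,
                         pairing_strategy = cfg$pairing_strategy)
    target <- max(0L, as.integer(round(med)) - as.integer(counts[[cl]]))
    plan <- augmentation_plan(pairing, target, washout = cfg$washout)
    out <- augment_class(out, plan, rt, seed = seed)
  }
  list(train = out, pairings = pairings)
}

#' Run the end-to-end recognition experiment
#'
#' For each repetition and fold: fit the normalizer on training folds,
#' identify donor classes and learn transfer maps on training folds only,
#' augment the data-poor classes, train the requested recognizers, and
#' score the held-out fold. Confusion matrices are row-normalized
#' percentages accumulated over folds and repetitions; the average
#' recognition rate is the unweighted mean of per-class recalls. A
#' programmatic no-leakage audit runs on every fold.
#'
#' @param corpus A manifest data frame (columns `clip_id`, `path`,
#'   `label`), a [generate_corpus()] result, a list of [audio_clip()]s,
#'   or a list of pre-extracted labeled [feature_seq()]s.
#' @param config An [experiment_config()].
#' @return An `evaluation_report`: list with `confusion` (per system,
#'   row-normalized %), `average_rate` (per system, %), `per_class_recall`
#'   (per system, %), `per_repetition` (data frame), `pairings`,
#'   `predictions`, `config`.
#' @export
run_experiment <- function(corpus, config = experiment_config()) {
  cfg <- config
  is_feats <- is.list(corpus) && length(corpus) > 0 &&
    inherits(corpus[[1]], "feature_seq")
  feats <- if (is_feats) corpus else
    corpus_features(corpus, cfg$feature_set)
  labels <- vapply(feats, `[[`, "", "label")
  ids <- vapply(feats, `[[`, "", "clip_id")
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  classes <- sort(unique(labels))
  nC <- length(classes)

  conf <- lapply(cfg$systems, function(s) matrix(0, nC, nC,
                                                 dimnames = list(classes, classes)))
  names(conf) <- cfg$systems
  per_rep <- list()
  pairings_all <- list()
  predictions <- list()

  for (rep_i in seq_len(cfg$repetitions)) {
    rep_seed <- (cfg$seed + 104729L * (rep_i - 1L)) %% 2147483647L
    fold <- stratified_folds(labels, cfg$folds, seed = rep_seed)
    rep_conf <- lapply(cfg$systems, function(s)
      matrix(0, nC, nC, dimnames = list(classes, classes)))
    names(rep_conf) <- cfg$systems

    for (f in seq_len(cfg$folds)) {
      test_idx <- which(!is.na(fold) & fold == f)
      train_idx <- setdiff(seq_along(feats), test_idx)
      check_no_leakage(ids[train_idx], ids[test_idx], "fold split")
      train_raw <- feats[train_idx]
      test_raw <- feats[test_idx]

      if (cfg$normalize) {
        nrm <- suppressWarnings(fit_normalizer(train_raw))
        train <- lapply(train_raw, apply_normalizer, norm = nrm)
        test <- lapply(test_raw, apply_normalizer, norm = nrm)
      } else {
        train <- train_raw; test <- test_raw
      }

      fold_seed <- (rep_seed + 31L * f) %% 2147483647L
      needs_tl <- any(cfg$systems %in% c("chmm_tl", "uhmm_tl"))
      if (needs_tl) {
        aug <- augment_training(train, cfg, seed = fold_seed)
        # audit: every augmentation source must be a training clip
        src <- vapply(aug$train[vapply(aug$train, `[[`, FALSE, "synthetic")],
                      function(s) s$provenance$source_clip, "")
        check_no_leakage(src, ids[test_idx], "augmentation")
        pairings_all[[length(pairings_all) + 1L]] <-
          list(repetition = rep_i, fold = f, pairings = aug$pairings)
      }

      truth <- vapply(test, `[[`, "", "label")
      for (sys in cfg$systems) {
        tl <- sys %in% c("chmm_tl", "uhmm_tl")
        mode <- if (sys %in% c("chmm", "chmm_tl")) "class_specific" else
          "universal_adapted"
        tr <- if (tl) aug$train else train
        bundle <- if (mode == "class_specific") {
          train_recognizer(tr, mode, n_states = cfg$chmm_states,
                           n_components = cfg$chmm_components,
                           seed = fold_seed, max_iter = cfg$bw_max_iter)
        } else {
          train_recognizer(tr, mode, n_states = cfg$uhmm_states,
                           n_components = cfg$uhmm_components,
                           seed = fold_seed, relevance = cfg$relevance,
                           max_iter = cfg$bw_max_iter)
        }
        pred <- classify(bundle, test)
        predictions[[length(predictions) + 1L]] <-
          cbind(data.frame(system = sys, repetition = rep_i, fold = f,
                           true = truth, stringsAsFactors = FALSE), pred)
        for (i in seq_along(truth)) {
          rep_conf[[sys]][truth[i], pred$predicted[i]] <-
            rep_conf[[sys]][truth[i], pred$predicted[i]] + 1
        }
      }
    }
    for (sys in cfg$systems) conf[[sys]] <- conf[[sys]] + rep_conf[[sys]]
    per_rep[[rep_i]] <- data.frame(
      repetition = rep_i,
      system = cfg$systems,
      rate = vapply(cfg$systems, function(sys) {
        m <- rep_conf[[sys]]
        100 * mean(diag(m / pmax(rowSums(m), 1)))
      }, numeric(1)),
      row.names = NULL
    )
  }

  confusion <- lapply(conf, function(m) 100 * m / pmax(rowSums(m), 1e-12))
  recalls <- lapply(confusion, diag)
  structure(
    list(confusion = confusion,
         average_rate = vapply(confusion, function(m) mean(diag(m)), numeric(1)),
         per_class_recall = recalls,
         per_repetition = do.call(rbind, per_rep),
         pairings = pairings_all,
         predictions = do.call(rbind, predictions),
         classes = classes,
         config = cfg),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (sys in names(x$average_rate)) {
    cat(sprintf("  %-8s average recognition rate %.1f%%\n", sys,
                x$average_rate[[sys]]))
  }
  invisible(x)
}

#' Write an evaluation report to files
#'
#' Emits per-system confusion matrices (CSV, row-normalized %), the
#' per-repetition rates, the pairing table, predictions and a config
#' echo.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
report_files <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sys in names(report$confusion)) {
    utils::write.csv(round(report$confusion[[sys]], 2),
                     file.path(dir, paste0("confusion_", sys, ".csv")))
  }
  utils::write.csv(report$per_repetition,
                   file.path(dir, "per_repetition.csv"), row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  summary_lines <- c(
    sprintf("config hash: %s", report$config$hash),
    sprintf("%s: average recognition rate %.2f%%", names(report$average_rate),
            unlist(report$average_rate))
  )
  if (length(report$pairings) > 0) {
    p1 <- report$pairings[[1]]$pairings
    summary_lines <- c(summary_lines, "", "pairings (repetition 1, fold 1):",
                       vapply(p1, function(p) sprintf("  %s <- %s (%.3f)",
                                                      p$limited_class,
                                                      p$donor_class,
                                                      p$divergence), ""))
  }
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  cfg <- report$config
  cfg$esn_grid <- lapply(cfg$esn_grid, as.numeric)
  jsonlite::write_json(cfg[setdiff(names(cfg), "hash")],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Minority-recall comparison of transfer-augmented and plain recognizers
#'
#' Runs the four-system experiment on freshly generated imbalanced corpora
#' over several seeds and aggregates the mean recall of the minority
#' (augmented) classes per system. This is the package's scaled analogue
#' of the full corpus study: same class layout and imbalance profile,
#' desk-scale clip counts and model sizes (see the methods vignette).
#'
#' @param n_seeds Number of independent corpus/experiment seeds.
#' @param duration_s Clip duration for the generated corpora.
#' @param base_seed Seed from which per-run seeds are derived.
#' @param systems Systems to compare.
#' @param verbose Print one line per seed.
#' @return List with `per_seed` (seeds x systems matrix of mean minority
#'   recalls, %), `means` (per system), `average_rates` (per system),
#'   `minority_classes`.
#' @export
minority_recall_study <- function(n_seeds = 10, duration_s = 2,
                                  base_seed = 1L,
                                  systems = c("chmm", "chmm_tl", "uhmm", "uhmm_tl"),
                                  verbose = FALSE) {
  counts <- c(40, 25, 10, 4, 60, 25, 15, 20)
  recipes <- default_test_recipes(duration_s = duration_s, counts = counts)
  ids <- vapply(recipes, `[[`, "", "class_id")
  minority <- ids[counts < stats::median(counts)]
  per_seed <- matrix(NA_real_, n_seeds, length(systems),
                     dimnames = list(NULL, systems))
  rates <- matrix(NA_real_, n_seeds, length(systems),
                  dimnames = list(NULL, systems))
  for (i in seq_len(n_seeds)) {
    seed_i <- (base_seed + 7907L * i) %% 2147483647L
    corp <- generate_corpus(recipes, seed = seed_i)
    feats <- corpus_features(corp, "mfcc")
    cfg <- experiment_config(systems = systems, repetitions = 1L,
                             uhmm_states = 5L, uhmm_components = 64L,
                             seed = seed_i)
    rep <- suppressMessages(run_experiment(feats, cfg))
    per_seed[i, ] <- vapply(systems, function(s)
      mean(rep$per_class_recall[[s]][minority]), numeric(1))
    rates[i, ] <- vapply(systems, function(s)
      rep$average_rate[[s]], numeric(1))
    if (verbose) {
      message(sprintf("seed %d/%d: %s", i, n_seeds,
                      paste(sprintf("%s=%.1f", systems, per_seed[i, ]),
                            collapse = " ")))
    }
  }
  list(per_seed = per_seed, means = colMeans(per_seed),
       average_rates = colMeans(rates), minority_classes = minority)
}
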