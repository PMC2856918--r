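# End-to-end orchestration: configuration, stage execution, reporting.

#' Pipeline configuration
#'
#' Collects the parameter blocks of every stage with defaults reproducing
#' the reference analysis constants: 7-cycle Morlet wavelets on the
#' 2-79 Hz grid, baseline -500..-100 ms, 250 Hz working rate, feature
#' selection at p < 0.05 in 13-79 Hz, a 20-hidden-unit network trained for
#' 20 conjugate-gradient iterations, the 0.95 output threshold, binomial
#' reactivation statistics at 0.05/(250 x 11), a 3 Hz zero-phase high-pass,
#' theta phase at 4/5/6 Hz, and cluster tests requiring 8 adjacent sensors.
#'
#' @param generator list of [generator_params()] arguments (or a
#'   `generator_params` object).
#' @param wavelet list: `f0_ratio`.
#' @param classifier list: `alpha`, `n_hidden`, `n_iter`, `threshold`,
#'   `train_times`, `loocv_times`, `n_test_points`, `test_window`.
#' @param replay list: `family_alpha`, `clf_range`.
#' @param highpass list: `cutoff`, `order`.
#' @param coupling list: `theta_freqs`, `headline_freq`, `min_events`,
#'   `cluster_n_perm`, `cluster_alpha`, `min_cluster`, `ws_n_perm`,
#'   `run_ws_perm`, `r_thresh`.
#' @param seed run seed; every random stage derives its stream from it.
#' @param out_dir optional directory for persisted artifacts.
#' @param verbose print stage progress.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), wavelet = list(),
                            classifier = list(), replay = list(),
                            highpass = list(), coupling = list(),
                            seed = 1, out_dir = NULL, verbose = TRUE) {
  merge_block <- function(defaults, user) {
    if (length(user) == 0) return(defaults)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults, user)
  }
  classifier <- merge_block(list(
    alpha = 0.05, n_hidden = 20, n_iter = 20, threshold = 0.95,
    train_times = c(-36, seq(44, 764, by = 80)),
    loocv_times = -36,
    n_test_points = 250, test_window = c(3250, 7750)), classifier)
  replay <- merge_block(list(family_alpha = 0.05, clf_range = c(44, 764)),
                        replay)
  highpass <- merge_block(list(cutoff = 3, order = 4), highpass)
  coupling <- merge_block(list(
    theta_freqs = c(4, 5, 6), headline_freq = 6, min_events = 2,
    cluster_n_perm = 500, cluster_alpha = 0.05, min_cluster = 8,
    ws_n_perm = 200, run_ws_perm = FALSE, r_thresh = 0.7), coupling)
  wavelet <- merge_block(list(f0_ratio = 7), wavelet)
  if (!inherits(generator, "generator_params")) {
    if (is.null(generator$rng_seed)) generator$rng_seed <- seed
    generator <- do.call(generator_params, generator)
  }
  if (!coupling$headline_freq %in% coupling$theta_freqs) {
    stop("headline_freq must be among theta_freqs")
  }
  structure(list(generator = generator, wavelet = wavelet,
                 classifier = classifier, replay = replay,
                 highpass = highpass, coupling = coupling,
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

# The union of time points the decoder needs: baseline window samples on
# the working 250 Hz grid, the training times, and the maintenance test
# grid.
decoder_times <- function(config, time_ms) {
  grid <- seq(time_ms[1], time_ms[length(time_ms)], by = 4)
  baseline <- grid[grid >= -500 & grid <= -100]
  test <- maintenance_test_points(grid, config$classifier$n_test_points,
                                  config$classifier$test_window)
  sort(unique(c(baseline, config$classifier$train_times, test)))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes generation, time-frequency analysis, classifier training,
#' leave-one-out validation, maintenance-period classification (within and
#' across conditions), reactivation detection and counting, phase
#' estimation, PLV tables, condition contrasts with cluster-based
#' permutation control, optional within-subject circular-shift nulls, and
#' the coupling-behavior correlation. Subjects are processed one at a time
#' so only stage summaries stay in memory.
#'
#' @param config a [pipeline_config()].
#' @return object of class `replay_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  gp <- config$generator
  spec <- wavelet_spec(f0_ratio = config$wavelet$f0_ratio)
  say <- function(...) if (config$verbose) message(sprintf(...))
  t_start <- Sys.time()

  kappa_scales <- if (gp$kappa_spread > 0 && gp$n_subjects > 1) {
    pmax(1 + gp$kappa_spread * seq(-1, 1, length.out = gp$n_subjects), 0)
  } else rep(1, gp$n_subjects)

  times_list <- list()
  events_list <- list()
  loocv <- list()
  plv_rows <- list()
  ws_perm <- list()
  accuracy <- numeric(gp$n_subjects)
  kappa_used <- list()
  n_events_truth <- list()

  for (s in seq_len(gp$n_subjects)) {
    say("subject %d/%d: generating", s, gp$n_subjects)
    gs <- generate_subject(gp, s, kappa_scale = kappa_scales[s])
    epochs <- gs$epochs
    accuracy[s] <- gs$truth$accuracy
    kappa_used[[s]] <- gs$truth$kappa
    n_events_truth[[s]] <- table(gs$truth$events$condition)
    times_needed <- decoder_times(config, epochs$time_ms)
    test_grid <- maintenance_test_points(
      seq(epochs$time_ms[1], epochs$time_ms[length(epochs$time_ms)], by = 4),
      config$classifier$n_test_points, config$classifier$test_window)

    say("subject %d: time-frequency analysis", s)
    tfs <- list()
    for (cond in CONDITIONS) {
      idx <- which(epochs$info$condition == cond)
      tf <- cwt_amplitude(subset_epochs(epochs, idx), spec,
                          times_ms = times_needed)
      tfs[[cond]] <- baseline_normalize(tf)
    }

    say("subject %d: classifiers", s)
    clfs <- list()
    for (cond in CONDITIONS) {
      clfs[[cond]] <- list()
      for (tp in config$classifier$train_times) {
        mask <- select_features(tfs[[cond]], tp,
                                alpha = config$classifier$alpha)
        clfs[[cond]][[as.character(tp)]] <- train_classifier(
          tfs[[cond]], mask,
          seed = derive_seed(config$seed, 301, s, match(cond, CONDITIONS),
                             round(tp)),
          n_hidden = config$classifier$n_hidden,
          n_iter = config$classifier$n_iter)
      }
      for (tp in config$classifier$loocv_times) {
        acc <- loocv_accuracy(tfs[[cond]], tp,
                              alpha = config$classifier$alpha,
                              seed = derive_seed(config$seed, 302, s,
                                                 match(cond, CONDITIONS),
                                                 round(tp)),
                              n_hidden = config$classifier$n_hidden,
                              n_iter = config$classifier$n_iter)
        loocv[[length(loocv) + 1]] <- data.frame(
          subject = s, condition = cond, time_ms = tp, accuracy = acc)
      }
    }

    say("subject %d: maintenance classification", s)
    srec_list <- list()
    for (cond_train in CONDITIONS) {
      for (cond_test in CONDITIONS) {
        for (clf in clfs[[cond_train]]) {
          rec <- classify_maintenance(clf, tfs[[cond_test]],
                                      test_points = test_grid,
                                      threshold = config$classifier$threshold)
          rec$subject <- s
          rec$cond_train <- cond_train
          rec$cond_test <- cond_test
          srec_list[[length(srec_list) + 1]] <-
            rec[, c("subject", "cond_train", "cond_test", "category",
                    "clf_time", "trial", "time_ms", "correct", "ambiguous")]
        }
      }
    }
    rm(tfs)

    say("subject %d: theta phase and PLV", s)
    hp <- zero_phase_highpass(epochs, config$highpass$cutoff,
                              config$highpass$order)
    rm(epochs)
    # subject-level detection; only the (small) reactivation sets are kept
    srec <- do.call(rbind, srec_list)
    rm(srec_list)
    bspec <- binomial_test_spec(
      n = gp$n_trials_per_category, r = 0.5,
      n_time_points = config$classifier$n_test_points,
      n_classifiers = length(config$classifier$train_times),
      family_alpha = config$replay$family_alpha)
    rs_s <- detect_reactivations(srec, bspec)
    rm(srec)
    times_list[[s]] <- rs_s$times
    events_list[[s]] <- rs_s$events
    ev_s <- merge_reactivation_events(rs_s, config$replay$clf_range)
    for (f in config$coupling$theta_freqs) {
      ph <- instantaneous_phase(hp, f, spec)
      for (cond in CONDITIONS) {
        ev <- ev_s[ev_s$cond_test == cond, , drop = FALSE]
        if (nrow(ev) == 0) next
        tab <- event_plv_table(ev, ph, config$coupling$min_events)
        tab$subject <- s
        tab$condition <- cond
        plv_rows[[length(plv_rows) + 1]] <- tab
        if (config$coupling$run_ws_perm &&
            f == config$coupling$headline_freq) {
          wp <- within_subject_permutation(
            ev, ph, n_perm = config$coupling$ws_n_perm,
            min_events = config$coupling$min_events,
            seed = derive_seed(config$seed, 401, s,
                               match(cond, CONDITIONS)))
          if (!is.null(wp)) {
            wp$subject <- s; wp$condition <- cond
            ws_perm[[length(ws_perm) + 1]] <- wp
          }
        }
      }
      rm(ph)
    }
    layout <- hp$layout
    rm(hp, gs)
    gc(verbose = FALSE)
  }

  say("group statistics")
  bspec <- binomial_test_spec(
    n = gp$n_trials_per_category, r = 0.5,
    n_time_points = config$classifier$n_test_points,
    n_classifiers = length(config$classifier$train_times),
    family_alpha = config$replay$family_alpha)
  rs <- structure(list(times = do.call(rbind, times_list),
                       events = do.call(rbind, events_list), spec = bspec),
                  class = "reactivation_set")
  counts <- count_reactivations(rs, clf_range = config$replay$clf_range)

  # per-subject totals: within-condition and cross-condition
  totals <- function(cond_train, cond_test) {
    sel <- counts[counts$cond_train == cond_train &
                    counts$cond_test == cond_test, , drop = FALSE]
    out <- stats::setNames(numeric(gp$n_subjects), seq_len(gp$n_subjects))
    if (nrow(sel) > 0) {
      agg <- tapply(sel$count, sel$subject, sum)
      out[names(agg)] <- agg
    }
    out
  }
  within_totals <- sapply(CONDITIONS,
                          function(cc) totals(cc, cc))  # subjects x cond

  safe_compare <- function(x, y) {
    tryCatch(compare_counts(x, y),
             error = function(e) list(t = NA_real_, df = NA_real_,
                                      p = NA_real_,
                                      mean_diff = mean(x - y),
                                      note = conditionMessage(e)))
  }
  count_tests <- list(
    configural_vs_control =
      safe_compare(within_totals[, "configural"], within_totals[, "control"]),
    nonconfigural_vs_control =
      safe_compare(within_totals[, "nonconfigural"],
                   within_totals[, "control"]),
    configural_vs_nonconfigural =
      safe_compare(within_totals[, "configural"],
                   within_totals[, "nonconfigural"]))

  specificity <- list()
  for (cond_test in CONDITIONS) {
    for (cond_train in setdiff(CONDITIONS, cond_test)) {
      nm <- sprintf("%s_tested:within_vs_%s_trained", cond_test, cond_train)
      specificity[[nm]] <- safe_compare(totals(cond_test, cond_test),
                                        totals(cond_train, cond_test))
    }
  }

  plv_tab <- if (length(plv_rows) > 0) do.call(rbind, plv_rows) else NULL
  adjacency <- sensor_adjacency(layout)
  zmats <- list()
  contrasts <- list()
  clusters <- list()
  if (!is.null(plv_tab)) {
    hf <- config$coupling$headline_freq
    for (cond in CONDITIONS) {
      t <- plv_tab[plv_tab$condition == cond & plv_tab$freq == hf, ,
                   drop = FALSE]
      if (nrow(t) == 0) next
      m <- matrix(NA_real_, gp$n_subjects, gp$n_sensors)
      zz <- subject_sensor_z(t)
      m[as.integer(rownames(zz)), seq_len(ncol(zz))] <- zz
      zmats[[cond]] <- m
    }
    pairs <- list(c("configural", "nonconfigural"),
                  c("configural", "control"),
                  c("nonconfigural", "control"))
    for (pr in pairs) {
      nm <- paste(pr, collapse = "_vs_")
      a <- zmats[[pr[1]]]; b <- zmats[[pr[2]]]
      if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) {
        contrasts[[nm]] <- "skipped: undefined PLV (no events) for a subject"
        next
      }
      contrasts[[nm]] <- coupling_contrast(a, b)
      clusters[[nm]] <- cluster_permutation(
        a, b, adjacency, n_perm = config$coupling$cluster_n_perm,
        alpha = config$coupling$cluster_alpha,
        min_size = config$coupling$min_cluster,
        seed = derive_seed(config$seed, 501, match(nm, names(contrasts))))
    }
  }

  behav <- NULL
  if (!is.null(zmats$configural) && !anyNA(zmats$configural) &&
      stats::sd(accuracy) > 0 && gp$n_subjects >= 3) {
    behav <- behavior_correlation(zmats$configural, accuracy, adjacency,
                                  r_thresh = config$coupling$r_thresh,
                                  min_cluster = config$coupling$min_cluster)
  }

  report <- structure(list(
    config = config,
    seed = config$seed,
    corrected_alpha = bspec$corrected_alpha,
    loocv = do.call(rbind, loocv),
    reactivation_times = rs$times,
    counts = counts,
    within_totals = within_totals,
    count_tests = count_tests,
    specificity = specificity,
    plv = plv_tab,
    zmaps = zmats,
    contrasts = contrasts,
    clusters = clusters,
    ws_perm = if (length(ws_perm) > 0) do.call(rbind, ws_perm) else NULL,
    behavior = behav,
    accuracy = accuracy,
    kappa_used = kappa_used,
    n_true_events = n_events_truth,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "replay_report")
  if (!is.null(config$out_dir)) save_report_tables(report, config$out_dir)
  report
}

# Persist the report's flat tables as delimited text plus a JSON summary.
save_report_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    if (!is.null(x)) utils::write.table(
      x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(report$loocv, "loocv.tsv")
  wt(report$counts, "reactivation_counts.tsv")
  wt(report$reactivation_times, "reactivation_times.tsv")
  wt(report$plv, "plv.tsv")
  summary <- list(seed = report$seed,
                  corrected_alpha = report$corrected_alpha,
                  count_tests = lapply(report$count_tests, function(x)
                    x[c("t", "p", "mean_diff")]),
                  accuracy = report$accuracy,
                  elapsed_s = report$elapsed_s)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.replay_report <- function(x, ...) {
  cat("<replay_report>\n")
  cat(sprintf("  seed %d; %d subjects; corrected alpha %.3g\n",
              x$seed, x$config$generator$n_subjects, x$corrected_alpha))
  if (!is.null(x$loocv)) {
    cat(sprintf("  baseline LOOCV accuracy (mean): %.3f\n",
                mean(x$loocv$accuracy)))
  }
  tot <- colMeans(x$within_totals)
  cat(sprintf("  mean within-condition reactivation counts: %s\n",
              paste(sprintf("%s %.1f", names(tot), tot), collapse = ", ")))
  for (nm in names(x$count_tests)) {
    ct <- x$count_tests[[nm]]
    cat(sprintf("  %s: t = %.2f, one-tailed p = %.4g\n", nm,
                ct$t %||% NA, ct$p %||% NA))
  }
  for (nm in names(x$clusters)) {
    cl <- x$clusters[[nm]]
    if (is.data.frame(cl) && nrow(cl) > 0) {
      cat(sprintf("  cluster test %s: %d cluster(s), min p = %.4g\n",
                  nm, nrow(cl), min(cl$p)))
    }
  }
  cat(sprintf("  elapsed %.1f s\n", x$elapsed_s))
  invisible(x)
}
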