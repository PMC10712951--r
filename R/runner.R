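# Experiment orchestration: fleets of seeded networks x lesion
# conditions, aggregated scores, and condition contrasts.

sim_builder <- function(sim) {
  switch(sim,
         satellites = build_satellite_dataset,
         weather = build_weather_dataset,
         typicality = build_typicality_dataset,
         stop("unknown simulation: ", sim))
}

default_test_trials <- list(satellites = seq(20, 140, by = 20),
                            weather = seq(10, 50, by = 10),
                            typicality = seq(10, 100, by = 10))

#' Build a network sized for a dataset
#'
#' Instantiates the default hippocampal architecture with the dataset's
#' input size, EC inhibition set point, and (for the typicality task)
#' reduced monosynaptic learning rate, then applies the lesion.
#'
#' @param dataset a `hippcat_dataset`.
#' @param seed network initialization seed.
#' @param condition lesion condition.
#' @param overrides architecture overrides (see [default_architecture()]).
#' @return an `hnet`.
#' @export
build_task_network <- function(dataset, seed, condition = "intact",
                               overrides = NULL) {
  msp_lr <- if (is.null(dataset$msp_lr)) 0.002 else dataset$msp_lr
  cfg <- default_architecture(dataset$input_size, dataset$ec_k,
                              msp_lr = msp_lr, overrides = overrides)
  apply_lesion(build_network(cfg, seed), condition)
}

# Probe inputs + labels for a simulation's RSA.
rsa_probes <- function(dataset) {
  if (dataset$name == "satellites") {
    ps <- dataset$probes$unique_feature
    list(inputs = ps$inputs, labels = ps$meta$category, excluded = NULL)
  } else if (dataset$name == "weather") {
    ps <- dataset$probes$recognition
    list(inputs = ps$inputs,
         labels = ifelse(ps$meta$p_sun > 0.5, "sun", "rain"),
         excluded = which(ps$meta$excluded))
  } else {
    ps <- dataset$probes$atypical_feature
    list(inputs = ps$inputs, labels = ps$meta$category, excluded = NULL)
  }
}

#' Run one network through the full pipeline
#'
#' build -> lesion -> train (with interim test batteries) -> final
#' scoring, optionally followed by representational similarity capture.
#'
#' @inheritParams build_task_network
#' @param test_trials interim test schedule (trial 0 and the final
#'   trial are always tested).
#' @param rsa if `TRUE`, compute initial- and settled-mode similarity
#'   matrices for DG/CA3/CA1 at the end of training.
#' @param engine settle engine.
#' @return list with `scores` (long data.frame over all test
#'   batteries), `trials` (learning curve), `stopped_at`, `network`,
#'   and optionally `rsa`.
#' @export
run_network <- function(dataset, seed, condition = "intact",
                        test_trials = integer(), rsa = FALSE,
                        overrides = NULL, engine = "cpp") {
  net <- build_task_network(dataset, seed, condition, overrides)
  fit <- train(net, dataset, seed = seed + 1L,
               test_trials = test_trials,
               test_fn = function(n, t) run_test_battery(n, dataset, t,
                                                         engine = engine),
               engine = engine)
  scores <- do.call(rbind, fit$interim)
  scores$network <- seed
  rownames(scores) <- NULL
  out <- list(scores = scores, trials = fit$trials,
              stopped_at = fit$stopped_at, network = fit$network)
  if (rsa) {
    pr <- rsa_probes(dataset)
    out$rsa <- lapply(c(initial = "initial", settled = "settled"),
                      function(m) {
      resp <- capture_responses(fit$network, pr$inputs, mode = m,
                                engine = engine)
      lapply(resp, similarity_matrix)
    })
    out$rsa_labels <- pr$labels
    out$rsa_excluded <- pr$excluded
  }
  out
}

#' Run a simulation experiment
#'
#' Runs `n_networks` independently initialized networks per lesion
#' condition through [run_network()], with seeds derived
#' deterministically from `seed`, and aggregates behaviour.  Network
#' runs are independent, so results do not depend on execution order.
#' A network run that fails is re-seeded (never silently dropped, up to
#' 3 attempts each).  For the weather task, `replenish_to_final = TRUE`
#' keeps launching networks until `n_networks` per condition survive
#' (i.e. have not met the stopping criterion) through the final trial;
#' stopped networks still contribute at trials up to their stop trial.
#'
#' @param sim `"satellites"`, `"weather"` or `"typicality"`.
#' @param n_networks networks per condition (100 in the standard
#'   design).
#' @param conditions lesion conditions to run.
#' @param seed base seed; all randomness derives from it.
#' @param test_trials interim test schedule; defaults per simulation.
#' @param rsa capture similarity matrices per network (averaged in the
#'   returned `rsa` element).
#' @param replenish_to_final see above (weather only).
#' @param out_dir if given, scores / learning curves / aggregate /
#'   similarity matrices and a JSON run manifest are written there as
#'   delimited tables.
#' @param overrides architecture overrides applied to every network.
#' @param engine settle engine.
#' @param progress print one line per network.
#' @return list with `scores`, `curves`, `aggregate`, `stopping`,
#'   optionally `rsa` (layer x mode matrices averaged across networks,
#'   plus `labels`/`excluded`), and `manifest`.
#' @export
run_experiment <- function(sim = c("satellites", "weather", "typicality"),
                           n_networks = 100,
                           conditions = c("intact", "MSP-only", "TSP-only"),
                           seed = 1,
                           test_trials = NULL,
                           rsa = FALSE,
                           replenish_to_final = FALSE,
                           out_dir = NULL,
                           overrides = NULL,
                           engine = "cpp",
                           progress = FALSE) {
  sim <- match.arg(sim)
  dataset <- sim_builder(sim)(seed)
  if (is.null(test_trials)) test_trials <- default_test_trials[[sim]]
  set.seed(as.integer(seed))
  seed_pool <- sample.int(.Machine$integer.max - 10L,
                          length(conditions) * n_networks * 10L)
  pool_i <- 0L
  next_seed <- function() {
    pool_i <<- pool_i + 1L
    seed_pool[pool_i]
  }

  all_scores <- list(); all_curves <- list(); stopping <- list()
  rsa_sums <- NULL; rsa_n <- 0; rsa_labels <- NULL; rsa_excluded <- NULL
  for (cond in conditions) {
    survivors <- 0L; launched <- 0L
    target_n <- n_networks
    max_launch <- if (replenish_to_final) n_networks * 10L else n_networks
    while ((if (replenish_to_final) survivors else launched) < target_n &&
           launched < max_launch) {
      launched <- launched + 1L
      res <- NULL
      for (attempt in 1:3) {
        s <- next_seed()
        res <- tryCatch(
          run_network(dataset, s, cond, test_trials = test_trials,
                      rsa = rsa && cond == "intact",
                      overrides = overrides, engine = engine),
          error = function(e) {
            warning("network run failed (", conditionMessage(e),
                    "); re-seeding", call. = FALSE)
            NULL
          })
        if (!is.null(res)) break
      }
      if (is.null(res)) stop("network run failed after 3 re-seeds")
      if (is.na(res$stopped_at)) survivors <- survivors + 1L
      res$scores$sim <- sim
      all_scores[[length(all_scores) + 1L]] <- res$scores
      cv <- res$trials
      cv$network <- unique(res$scores$network)
      cv$condition <- cond
      all_curves[[length(all_curves) + 1L]] <-
        cv[, c("network", "condition", "trial", "sse")]
      stopping[[length(stopping) + 1L]] <- data.frame(
        network = cv$network[1], condition = cond,
        stopped_at = res$stopped_at, n_trials = nrow(cv))
      if (!is.null(res$rsa)) {
        if (is.null(rsa_sums)) {
          rsa_sums <- res$rsa
          rsa_labels <- res$rsa_labels
          rsa_excluded <- res$rsa_excluded
        } else {
          for (m in names(rsa_sums))
            for (l in names(rsa_sums[[m]]))
              rsa_sums[[m]][[l]] <- rsa_sums[[m]][[l]] + res$rsa[[m]][[l]]
        }
        rsa_n <- rsa_n + 1
      }
      if (progress)
        message(sim, " ", cond, " network ", launched, "/", max_launch,
                " done")
    }
  }
  scores <- do.call(rbind, all_scores)
  curves <- do.call(rbind, all_curves)
  stopping <- do.call(rbind, stopping)
  agg <- aggregate_scores(scores)
  out <- list(scores = scores, curves = curves, aggregate = agg,
              stopping = stopping)
  if (rsa_n > 0) {
    out$rsa <- lapply(rsa_sums, function(ms)
      lapply(ms, function(m) m / rsa_n))
    out$rsa$labels <- rsa_labels
    out$rsa$excluded <- rsa_excluded
    out$rsa$n_networks <- rsa_n
  }
  out$manifest <- list(sim = sim, n_networks = n_networks,
                       conditions = conditions, seed = seed,
                       test_trials = test_trials,
                       replenish_to_final = replenish_to_final,
                       package_version =
                         as.character(utils::packageVersion("hippcat")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(curves, file.path(out_dir, "learning_curves.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(agg, file.path(out_dir, "aggregate.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (rsa_n > 0)
      for (m in c("initial", "settled"))
        write_similarity(out$rsa[[m]], out_dir, mode = m)
    jsonlite::write_json(out$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Aggregate long-format scores
#'
#' Mean, standard error and n per cell, with network initialization as
#' the sampling unit (scores are first averaged within network, then
#' summarized across networks).  Chance levels are carried through.
#'
#' @param scores long-format score table (e.g. from [run_experiment()]).
#' @param by grouping columns.
#' @param drop_excluded drop probes flagged excluded before averaging.
#' @return data.frame with `mean`, `sem` (`NA` for a single network),
#'   `n` and `chance` per group.
#' @export
aggregate_scores <- function(scores,
                             by = c("condition", "trial", "kind"),
                             drop_excluded = TRUE) {
  if (drop_excluded && !is.null(scores$excluded))
    scores <- scores[is.na(scores$excluded) | !scores$excluded, ]
  # per-network means first
  net_by <- unique(c(by, "network"))
  netm <- stats::aggregate(scores["score"], scores[net_by], mean)
  chance <- stats::aggregate(scores["chance"], scores[by], mean)
  agg <- stats::aggregate(netm["score"], netm[by], function(x)
    c(mean = mean(x), sem = if (length(x) > 1) sd(x) / sqrt(length(x))
      else NA_real_, n = length(x)))
  out <- cbind(agg[by], as.data.frame(agg$score))
  merge(out, chance, by = by, sort = TRUE)
}

#' Condition contrasts
#'
#' Two-factor analysis (condition x trial) of per-network mean scores
#' for one score kind: the omnibus test plus each pairwise condition
#' contrast, with network initialization as the sampling unit.
#'
#' @param scores long-format score table.
#' @param kind score kind to analyse.
#' @param drop_excluded drop probes flagged excluded.
#' @return data.frame with one row per contrast (`term`, `F`, `p`).
#' @export
condition_contrasts <- function(scores, kind, drop_excluded = TRUE) {
  d <- scores[scores$kind == kind, ]
  if (drop_excluded && !is.null(d$excluded))
    d <- d[is.na(d$excluded) | !d$excluded, ]
  netm <- stats::aggregate(d["score"],
                           d[c("condition", "trial", "network")], mean)
  netm$trial <- factor(netm$trial)
  netm$condition <- factor(netm$condition)
  res <- list()
  add <- function(label, data) {
    a <- anova(aov(score ~ condition * trial, data = data))
    res[[length(res) + 1L]] <<- data.frame(
      contrast = label,
      term = rownames(a)[1:3],
      F = a$`F value`[1:3],
      p = a$`Pr(>F)`[1:3])
  }
  add("omnibus", netm)
  conds <- levels(netm$condition)
  if (length(conds) > 2)
    for (pair in utils::combn(conds, 2, simplify = FALSE))
      add(paste(pair, collapse = " vs "),
          droplevels(netm[netm$condition %in% pair, ]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
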