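#' Contrastive Hebbian weight update
#'
#' Computes the weight change for one projection from the settled
#' activities of a trial's phases:
#' `lr * (post_plus %o% pre_plus - mean of minus-phase coproducts)`,
#' restricted to the projection's connectivity mask and softly bounded
#' into \[0, 1\]: increases are scaled by `(1 - w)` and decreases by `w`,
#' so weights approach but never cross the bounds.
#'
#' @param W current weight matrix (dst x src).
#' @param mask binary connectivity mask, same shape as `W`.
#' @param pre_plus,post_plus settled pre-/post-synaptic activations from
#'   the target-clamped plus phase.
#' @param minus list of minus phases, each a `list(pre = , post = )`;
#'   intact networks contrast two minus phases (theta trough and peak),
#'   lesioned networks one.
#' @param lr learning rate.
#' @return weight delta matrix (same shape as `W`).
#' @export
chl_delta <- function(W, mask, pre_plus, post_plus, minus, lr) {
  if (nrow(W) != length(post_plus) || ncol(W) != length(pre_plus))
    stop("dimension mismatch between phase activities and projection mask")
  co_plus <- tcrossprod(post_plus, pre_plus)
  co_minus <- Reduce(`+`, lapply(minus, function(m) {
    if (nrow(W) != length(m$post) || ncol(W) != length(m$pre))
      stop("dimension mismatch between phase activities and projection mask")
    tcrossprod(m$post, m$pre)
  })) / length(minus)
  d <- co_plus - co_minus
  lr * ifelse(d > 0, d * (1 - W), d * W) * mask
}

#' Hebbian (CPCA) weight update
#'
#' Self-organizing conditional-PCA Hebbian rule: each postsynaptically
#' active unit moves its incoming weights towards the presynaptic
#' activity pattern, `dw = lr * post * (pre - w)`, inside the mask.
#' Weights converge to the conditional probability of presynaptic
#' activity given postsynaptic activity, which tunes sparse conjunctive
#' units (DG/CA3) to the patterns they win for and builds the CA3
#' recurrent attractor — the basis of cued pattern completion.
#'
#' @param W current weight matrix (dst x src).
#' @param mask binary connectivity mask.
#' @param pre,post settled activations (plus phase).
#' @param lr learning rate.
#' @return weight delta matrix.
#' @export
hebb_delta <- function(W, mask, pre, post, lr) {
  if (nrow(W) != length(post) || ncol(W) != length(pre))
    stop("dimension mismatch between phase activities and projection mask")
  lr * (post %o% pre - post * W) * mask
}

#' Phase schedule for a lesion condition
#'
#' Intact networks use the theta-phase scheme: two minus phases (trough:
#' CA3->CA1 suppressed; peak: EC_in->CA1 suppressed) contrasted against
#' one plus phase.  Lesioned networks, having a single pathway, use a
#' single minus phase.
#'
#' @param condition `"intact"`, `"MSP-only"` or `"TSP-only"`.
#' @return character vector of phase labels, plus phase last.
#' @export
phase_schedule <- function(condition = c("intact", "MSP-only", "TSP-only")) {
  condition <- match.arg(condition)
  if (condition == "intact") c("trough", "peak", "plus") else c("minus", "plus")
}

#' Apply a pathway lesion
#'
#' `"TSP-only"` silences the monosynaptic pathway by setting the strength
#' of the EC_in->CA1 projection to 0; `"MSP-only"` silences the
#' trisynaptic output by zeroing the CA3->CA1 weights.  Either way the
#' lesioned projection contributes no drive and is excluded from
#' learning for the entire run, and the network switches to the
#' single-minus-phase schedule.  CA1 <-> EC_out is never lesioned since
#' it carries all output.  `"intact"` returns the network unchanged.
#'
#' @param network an `hnet`.
#' @param condition lesion condition.
#' @return the (possibly) lesioned network.
#' @export
apply_lesion <- function(network,
                         condition = c("intact", "MSP-only", "TSP-only")) {
  condition <- match.arg(condition)
  if (condition == "TSP-only") {
    key <- "EC_in->CA1"
  } else if (condition == "MSP-only") {
    key <- "CA3->CA1"
    network$projections[[key]]$W[] <- 0
    network$projections[[key]]$We[] <- 0
  } else return(network)
  network$projections[[key]]$strength <- 0
  network$projections[[key]]$learnable <- FALSE
  network$projections[[key]]$lr <- 0
  network$condition <- condition
  network
}

#' Run one learning trial
#'
#' Settles each phase of the schedule with the stimulus clamped on
#' `Input` throughout and the target clamped on `EC_out` during the plus
#' phase only, computes Contrastive Hebbian deltas for every learnable
#' projection (plus-phase coproduct contrasted against the mean of the
#' minus-phase coproducts), and applies them once at trial end.  Under
#' the autoencoder regime the target equals the input pattern.
#'
#' @param network an `hnet`.
#' @param input stimulus vector (length = Input size).
#' @param target target vector for EC_out; defaults to `input`.
#' @param keep_states if `TRUE`, the per-phase settled states are kept in
#'   the trial record.
#' @param pairing how the two theta minus phases are contrasted against
#'   the plus phase in intact networks.  `"per-pathway"` (default): each
#'   pathway learns from the minus phase in which it drives CA1 —
#'   monosynaptic projections contrast the trough phase, trisynaptic
#'   projections the peak phase — so the two pathways learn
#'   independently.  `"averaged"`: every projection contrasts the mean of
#'   the two minus-phase coproducts.  Lesioned networks have a single
#'   minus phase and are unaffected.
#' @inheritParams settle
#' @return list with the updated `network` and a `record` holding the
#'   trial sum squared error (`sse`, minus-phase EC_out vs. target,
#'   first minus phase), per-projection `mean_abs_dw`, and optionally
#'   `phases`.
#' @export
run_trial <- function(network, input, target = input, keep_states = FALSE,
                      pairing = c("per-pathway", "averaged"),
                      max_cycles = 100, tol = 1e-4, engine = "cpp") {
  pairing <- match.arg(pairing)
  if (length(input) != network$layers$Input$size)
    stop("pattern length does not match Input size")
  phases <- phase_schedule(network$condition)
  states <- list()
  for (ph in phases) {
    clamps <- list(Input = input)
    if (ph == "plus") clamps$EC_out <- target
    states[[ph]] <- settle(network, clamps, phase = ph,
                           max_cycles = max_cycles, tol = tol,
                           engine = engine)
  }
  minus_names <- setdiff(phases, "plus")
  plus_act <- states$plus$act
  sse <- sum((states[[minus_names[1]]]$act$EC_out - target)^2)

  mean_abs_dw <- numeric(0)
  for (key in names(network$projections)) {
    p <- network$projections[[key]]
    if (!p$learnable || p$lr == 0) next
    use <- minus_names
    if (pairing == "per-pathway" && length(minus_names) > 1)
      use <- if (p$pathway == "TSP") "peak" else "trough"
    minus <- lapply(use, function(ph)
      list(pre = states[[ph]]$act[[p$src]],
           post = states[[ph]]$act[[p$dst]]))
    hebb <- if (is.null(p$hebb)) 0 else p$hebb
    dw <- 0
    if (hebb < 1)
      dw <- (1 - hebb) * chl_delta(p$W, p$mask, plus_act[[p$src]],
                                   plus_act[[p$dst]], minus, p$lr)
    if (hebb > 0)
      dw <- dw + hebb * hebb_delta(p$W, p$mask, plus_act[[p$src]],
                                   plus_act[[p$dst]], p$lr)
    Wn <- p$W + dw
    network$projections[[key]]$W <- Wn
    network$projections[[key]]$We <-
      weight_contrast(Wn, p$wc_gain, p$wc_off) * p$mask
    mean_abs_dw[[key]] <- mean(abs(dw[p$mask == 1]))
  }
  record <- list(sse = sse, mean_abs_dw = mean_abs_dw)
  if (keep_states) record$phases <- states
  list(network = network, record = record)
}

#' Probabilistic-task stopping rule
#'
#' `TRUE` once at least `min_trials` trials have run and the most recent
#' `window` trials all have sum squared error below `threshold`.  The
#' window may begin before `min_trials` as long as the stop decision
#' itself falls at or after it.
#'
#' @param sse_history numeric vector of per-trial SSE so far.
#' @param rule list with `min_trials` (default 25), `window` (5) and
#'   `threshold` (1.2), or `NULL` for no stopping.
#' @return logical.
#' @export
check_stop <- function(sse_history,
                       rule = list(min_trials = 25, window = 5,
                                   threshold = 1.2)) {
  if (is.null(rule)) return(FALSE)
  n <- length(sse_history)
  n >= rule$min_trials &&
    n >= rule$window &&
    all(tail(sse_history, rule$window) < rule$threshold)
}

#' Train a network on a dataset
#'
#' Runs the trial schedule for a dataset: items are drawn by the
#' dataset's order policy (uniform with replacement for the satellite
#' task, shuffled epochs for the typicality task, frequency-weighted
#' contingency draws for the weather task), each trial updates weights
#' via [run_trial()], and an optional test callback is invoked (with
#' weights untouched) before training and after scheduled trial counts.
#'
#' @param network an `hnet`, already lesioned if applicable.
#' @param dataset a dataset from the `build_*_dataset()` constructors.
#' @param n_trials total training trials (ignored by epoch policies,
#'   which derive it from the dataset); the stopping rule may end
#'   training earlier.
#' @param seed integer seed for the trial order.
#' @param stopping_rule see [check_stop()]; default taken from the
#'   dataset (`NULL` for the deterministic tasks).
#' @param test_trials integer vector of trial counts after which
#'   `test_fn` runs; trial 0 (before training) is always included when a
#'   callback is given.
#' @param test_fn optional `function(network, trial)`; its results are
#'   collected in the returned `interim` list.
#' @param engine settle engine (see [settle()]).
#' @return list with the trained `network`, a `trials` data.frame
#'   (trial, item, sse, per-projection mean |dw|), `stopped_at` (`NA` if
#'   the rule never fired) and `interim`.
#' @export
train <- function(network, dataset, n_trials = NULL, seed = 1,
                  stopping_rule = dataset$stopping_rule,
                  test_trials = integer(), test_fn = NULL,
                  engine = "cpp") {
  if (is.null(dataset$items) || nrow(dataset$items) == 0)
    stop("empty dataset")
  set.seed(as.integer(seed))
  if (is.null(n_trials)) n_trials <- dataset$n_trials
  order_policy <- dataset$order_policy
  if (order_policy == "epochs") {
    n_items <- nrow(dataset$items)
    n_epochs <- ceiling(n_trials / n_items)
    item_order <- as.vector(replicate(n_epochs, sample.int(n_items)))
    item_order <- item_order[seq_len(n_trials)]
  } else if (order_policy == "sample") {
    item_order <- sample.int(nrow(dataset$items), n_trials, replace = TRUE)
  } else if (order_policy == "contingency") {
    item_order <- sample_weather_trials(dataset, n_trials)
  } else stop("unknown order policy: ", order_policy)

  interim <- list()
  run_tests <- function(trial) {
    if (!is.null(test_fn))
      interim[[as.character(trial)]] <<- test_fn(network, trial)
  }
  run_tests(0L)

  sse <- numeric(n_trials)
  dw_log <- vector("list", n_trials)
  stopped_at <- NA_integer_
  t_done <- 0L
  for (t in seq_len(n_trials)) {
    it <- item_order[t]
    pat <- dataset$items[it, ]
    res <- run_trial(network, pat, engine = engine)
    network <- res$network
    sse[t] <- res$record$sse
    dw_log[[t]] <- res$record$mean_abs_dw
    t_done <- t
    if (t %in% test_trials) run_tests(t)
    if (check_stop(sse[seq_len(t)], stopping_rule)) {
      stopped_at <- t
      break
    }
  }
  sse <- sse[seq_len(t_done)]
  dw <- do.call(rbind, dw_log[seq_len(t_done)])
  trials <- data.frame(trial = seq_len(t_done),
                       item = item_order[seq_len(t_done)],
                       sse = sse)
  if (!is.null(dw)) trials <- cbind(trials, as.data.frame(dw))
  if (!is.na(stopped_at) || !(t_done %in% test_trials)) run_tests(t_done)
  list(network = network, trials = trials, stopped_at = stopped_at,
       interim = interim)
}

#' Save / load a network
#'
#' Round-trips a network (weights, masks, seed, condition and full
#' configuration) through R's native serialization; the reloaded object
#' is bit-identical.
#'
#' @param network an `hnet`.
#' @param path file path.
#' @export
save_network <- function(network, path) {
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "hnet"))
  net
}
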