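# Test protocol: probing never changes weights; all behavioural scores
# are ratios of settled EC_out activation over defined unit sets.

#' Probe a network
#'
#' Clamps a probe input on `Input` and settles the network in test mode
#' (all gates open apart from any lesion, EC_out free).  Weights are
#' untouched.
#'
#' @param network an `hnet`.
#' @param probe_input stimulus vector (length = Input size).
#' @param gate_override optional gate overrides (see [net_input()]);
#'   used e.g. to sever big-loop recurrence.
#' @param full_state if `TRUE` return the whole settled state instead of
#'   just the EC_out activations.
#' @inheritParams settle
#' @return EC_out activation vector (or the full settled state).
#' @export
probe <- function(network, probe_input, gate_override = NULL,
                  full_state = FALSE, max_cycles = 100, tol = 1e-4,
                  engine = "cpp") {
  if (length(probe_input) != network$layers$Input$size)
    stop("probe length does not match Input size")
  st <- settle(network, list(Input = probe_input), phase = "test",
               max_cycles = max_cycles, tol = tol,
               gate_override = gate_override, engine = engine)
  if (full_state) st else st$act$EC_out
}

#' Sum-based ratio score
#'
#' Total activation over the correct units divided by total activation
#' over the denominator units (which must include the correct set).  A
#' silent denominator carries no evidence either way and falls back to
#' the chance level.
#'
#' @param outputs EC_out activation vector.
#' @param correct_units,denominator_units unit index vectors.
#' @param chance chance level returned for a zero denominator.
#' @return score in \[0, 1\].
#' @export
ratio_score <- function(outputs, correct_units, denominator_units,
                        chance = length(correct_units) /
                          length(denominator_units)) {
  stopifnot(length(correct_units) > 0, length(denominator_units) > 0,
            all(correct_units %in% denominator_units))
  den <- sum(outputs[denominator_units])
  if (den < 1e-3) return(chance)  # silent output carries no evidence
  sum(outputs[correct_units]) / den
}

#' Mean-based ratio score
#'
#' Mean activation over the correct units divided by the mean over the
#' full unit set — the literal recognition measure for the weather task
#' (which can exceed 1).  A fully silent unit set falls back to 1
#' (undifferentiated output).
#'
#' @inheritParams ratio_score
#' @param all_units the full scored unit set.
#' @export
mean_ratio_score <- function(outputs, correct_units, all_units) {
  stopifnot(length(correct_units) > 0, length(all_units) > 0)
  den <- mean(outputs[all_units])
  if (den < 1e-3) return(1)  # undifferentiated (silent) output
  mean(outputs[correct_units]) / den
}

#' Atypical-feature recognition score
#'
#' Activation over an item's k correct atypical-feature units divided by
#' the total activation over the 10 units of the item's atypical
#' (opposite-prototype) side; chance is k x 0.1.
#'
#' @inheritParams ratio_score
#' @param atypical_correct_units the item's k atypical-feature units.
#' @param all_atypical_side_units the 10 opposite-prototype units.
#' @return list with `score` and `chance`.
#' @export
atypical_feature_score <- function(outputs, atypical_correct_units,
                                   all_atypical_side_units) {
  k <- length(atypical_correct_units)
  if (k < 1 || k > 4) stop("training items have 1-4 atypical features")
  chance <- k * 0.1
  list(score = ratio_score(outputs, atypical_correct_units,
                           all_atypical_side_units, chance = chance),
       chance = chance)
}

#' Typicality-task generalization score
#'
#' Activation of the correct category's 5 label units relative to all 10
#' label units.  The default (`variant = "sum"`) is the normalized form
#' bounded in \[0, 1\] with chance 0.5; `variant = "mean"` is the literal
#' mean-over-correct / mean-over-both form (which equals 1 for
#' undifferentiated output and can exceed 1).
#'
#' @inheritParams ratio_score
#' @param correct_label_units the correct category's label units.
#' @param both_label_unit_sets all label units (both categories).
#' @param variant `"sum"` (default) or `"mean"`.
#' @export
generalization_typ_score <- function(outputs, correct_label_units,
                                     both_label_unit_sets,
                                     variant = c("sum", "mean")) {
  variant <- match.arg(variant)
  if (variant == "sum")
    ratio_score(outputs, correct_label_units, both_label_unit_sets,
                chance = 0.5)
  else {
    den <- mean(outputs[both_label_unit_sets])
    if (den < 1e-3) 0.5 else mean(outputs[correct_label_units]) / den
  }
}

# Score one probe set against a vector of EC_out outputs per probe.
score_probe_set <- function(ps, outs) {
  vapply(seq_len(nrow(ps$inputs)), function(i) {
    out <- outs[[i]]
    switch(ps$kind,
      recognition = mean_ratio_score(out, ps$correct[[i]], ps$denom[[i]]),
      ratio_score(out, ps$correct[[i]], ps$denom[[i]],
                  chance = ps$chance[i]))
  }, 0)
}

#' Run the full test battery for a dataset
#'
#' Probes every probe set of `dataset` (weights untouched; lesioned
#' networks are probed under their own condition) and returns one row
#' per probe.
#'
#' @param network an `hnet`.
#' @param dataset a `hippcat_dataset`.
#' @param trial trial index recorded alongside the scores.
#' @inheritParams settle
#' @return data.frame with columns `condition`, `trial`, `kind`,
#'   `probe`, `score`, `chance`, plus `category`/`n_atypical`/`excluded`
#'   metadata where the probe set provides them.
#' @export
run_test_battery <- function(network, dataset, trial = NA_integer_,
                             engine = "cpp") {
  res <- list()
  for (nm in names(dataset$probes)) {
    ps <- dataset$probes[[nm]]
    outs <- lapply(seq_len(nrow(ps$inputs)), function(i)
      probe(network, ps$inputs[i, ], engine = engine))
    sc <- score_probe_set(ps, outs)
    df <- data.frame(condition = network$condition, trial = trial,
                     kind = nm, probe = rownames(ps$inputs),
                     score = sc, chance = ps$chance,
                     stringsAsFactors = FALSE)
    for (col in c("category", "n_atypical", "excluded", "n_cards"))
      if (!is.null(ps$meta[[col]])) df[[col]] <- ps$meta[[col]]
    res[[nm]] <- df
  }
  out <- do.call(rbind, lapply(res, function(d) {
    for (col in c("category", "n_atypical", "excluded", "n_cards"))
      if (is.null(d[[col]])) d[[col]] <- NA
    d
  }))
  rownames(out) <- NULL
  out
}

#' Byte-exact fingerprint of a network's weights
#'
#' Serializes all weight matrices; two networks have `identical()`
#' fingerprints iff their weights are bit-identical.  Used to assert
#' test purity (probing never changes weights).
#'
#' @param network an `hnet`.
#' @return raw vector.
#' @export
weight_hash <- function(network) {
  serialize(lapply(network$projections, `[[`, "W"), NULL)
}
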