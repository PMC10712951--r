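# Dataset constructors for the three category-learning paradigms.  Each
# returns a `hippcat_dataset`: training patterns, probe sets, unit-role
# metadata, and the training-schedule defaults for that task.

new_dataset <- function(name, input_size, ec_k, items, item_meta,
                        probes, unit_roles, n_trials, order_policy,
                        stopping_rule = NULL, extra = list()) {
  ds <- c(list(name = name, input_size = input_size, ec_k = ec_k,
               items = items, item_meta = item_meta, probes = probes,
               unit_roles = unit_roles, n_trials = n_trials,
               order_policy = order_policy,
               stopping_rule = stopping_rule), extra)
  class(ds) <- "hippcat_dataset"
  ds
}

#' @export
print.hippcat_dataset <- function(x, ...) {
  cat("<hippcat_dataset> ", x$name, ": ", nrow(x$items),
      " training items over ", x$input_size, " input units\n", sep = "")
  cat("  probe sets:", paste(names(x$probes), collapse = ", "), "\n")
  invisible(x)
}

new_probe_set <- function(kind, inputs, correct, denom, chance, meta) {
  list(kind = kind, inputs = inputs, correct = correct, denom = denom,
       chance = chance, meta = meta)
}

#' Satellite categories (distinct categories with unique and shared features)
#'
#' Three categories of five "satellites" over 27 binary input units, 9
#' per category: 5 shared-feature units (the first being the
#' category-prototypical feature present in every exemplar of the
#' category) and 4 unique-feature units.  Each category contains its
#' prototype (all 5 shared features) plus four exemplars in which one
#' non-prototypical shared feature is swapped for a unique feature, so
#' non-prototype exemplars have 4 shared + 1 unique active features.
#' Which shared feature each exemplar swaps, and which unique unit it
#' receives, is a seeded assignment; the counts never vary.
#'
#' Probe sets:
#' * `unique_feature` — each of the 12 unique features presented alone,
#'   scored as correct-unit activation over the category's 4
#'   unique-feature units (chance 0.25);
#' * `categorization` — same inputs, scored as correct
#'   category-prototypical unit over the 3 prototypical units
#'   (chance 1/3);
#' * `generalization` — 18 novel satellites (6 per category), each
#'   combining 2 non-prototypical shared features with 2 unique features
#'   in combinations unseen in training, scored as categorization.
#'
#' @param seed integer seed for the arbitrary feature assignments.
#' @return a `hippcat_dataset`; training runs 140 trials of uniform
#'   draws with replacement.
#' @export
build_satellite_dataset <- function(seed = 1) {
  set.seed(as.integer(seed))
  n_cat <- 3; n_in <- 27
  block <- function(cat) (cat - 1) * 9
  proto_unit <- function(cat) block(cat) + 1          # category-prototypical
  shared_units <- function(cat) block(cat) + 1:5
  unique_units <- function(cat) block(cat) + 6:9

  items <- matrix(0, 0, n_in)
  meta <- data.frame(id = character(), category = integer(),
                     unique_unit = integer(), stringsAsFactors = FALSE)
  for (cat in seq_len(n_cat)) {
    proto <- numeric(n_in); proto[shared_units(cat)] <- 1
    items <- rbind(items, proto)
    meta <- rbind(meta, data.frame(id = paste0("cat", cat, "_proto"),
                                   category = cat, unique_unit = NA))
    swap <- sample(block(cat) + 2:5)       # which shared feature is swapped
    uniq <- sample(unique_units(cat))      # which unique unit replaces it
    for (j in 1:4) {
      v <- proto
      v[swap[j]] <- 0
      v[uniq[j]] <- 1
      items <- rbind(items, v)
      meta <- rbind(meta, data.frame(id = paste0("cat", cat, "_ex", j),
                                     category = cat, unique_unit = uniq[j]))
    }
  }
  rownames(items) <- meta$id

  # unique-feature and categorization probes: the 12 unique features
  ex <- meta[!is.na(meta$unique_unit), ]
  uin <- matrix(0, nrow(ex), n_in, dimnames = list(ex$id, NULL))
  for (i in seq_len(nrow(ex))) uin[i, ex$unique_unit[i]] <- 1
  p_unique <- new_probe_set(
    "unique_feature", uin,
    correct = as.list(ex$unique_unit),
    denom = lapply(ex$category, unique_units),
    chance = rep(0.25, nrow(ex)),
    meta = ex)
  p_cat <- new_probe_set(
    "categorization", uin,
    correct = as.list(proto_unit(ex$category)),
    denom = rep(list(proto_unit(seq_len(n_cat))), nrow(ex)),
    chance = rep(1 / 3, nrow(ex)),
    meta = ex)

  # generalization probes: 2 non-prototypical shared + 2 unique features
  gin <- matrix(0, 0, n_in)
  gmeta <- data.frame(id = character(), category = integer())
  for (cat in seq_len(n_cat)) {
    sh_pairs <- utils::combn(block(cat) + 2:5, 2)
    un_pairs <- utils::combn(unique_units(cat), 2)
    combos <- expand.grid(s = seq_len(ncol(sh_pairs)),
                          u = seq_len(ncol(un_pairs)))
    pick <- combos[sample.int(nrow(combos), 6), ]
    for (r in seq_len(6)) {
      v <- numeric(n_in)
      v[sh_pairs[, pick$s[r]]] <- 1
      v[un_pairs[, pick$u[r]]] <- 1
      gin <- rbind(gin, v)
      gmeta <- rbind(gmeta, data.frame(
        id = paste0("cat", cat, "_novel", r), category = cat))
    }
  }
  rownames(gin) <- gmeta$id
  p_gen <- new_probe_set(
    "generalization", gin,
    correct = as.list(proto_unit(gmeta$category)),
    denom = rep(list(proto_unit(seq_len(n_cat))), nrow(gmeta)),
    chance = rep(1 / 3, nrow(gmeta)),
    meta = gmeta)

  roles <- rep("unique", n_in)
  for (cat in seq_len(n_cat)) {
    roles[shared_units(cat)] <- "shared"
    roles[proto_unit(cat)] <- "category-prototypical"
  }
  new_dataset("satellites", n_in, ec_k = 5, items = items,
              item_meta = meta,
              probes = list(unique_feature = p_unique,
                            categorization = p_cat,
                            generalization = p_gen),
              unit_roles = roles, n_trials = 140,
              order_policy = "epochs")
}

#' Weather Prediction Task (probabilistic categories)
#'
#' Four cards, presented in the 14 possible combinations of one to
#' three cards, probabilistically predict one of two weather outcomes.
#' Input layout: 4 card units followed by 2 units per outcome (sun,
#' rain); doubling the outcome units raises the salience of category
#' information.  Training is observational autoencoding: a combination
#' is drawn by its presentation frequency, an outcome by the
#' combination's conditional probability, and cards plus outcome units
#' are presented as input and reconstructed as target.  The two
#' equiprobable combinations are flagged `excluded` for analysis but
#' still trained.
#'
#' Probe sets (cards only as input):
#' * `recognition` — mean activation of the presented cards' units over
#'   the mean across all 4 card units;
#' * `categorization` — activation of the 2 correct-outcome units over
#'   all 4 outcome units (chance 0.5).
#'
#' @param seed integer seed (the structure is deterministic; the seed
#'   only fixes the trial sampler's reproducibility downstream).
#' @param contingency_file YAML contingency table; defaults to the
#'   packaged reconstruction of the published task.
#' @return a `hippcat_dataset` with a `contingency` data.frame; training
#'   runs at most 50 trials under the stopping rule (min 25 trials, 5
#'   consecutive trials with SSE < 1.2).
#' @export
build_weather_dataset <- function(seed = 1, contingency_file = NULL) {
  if (is.null(contingency_file))
    contingency_file <- system.file("extdata", "weather_contingency.yaml",
                                    package = "hippcat")
  raw <- yaml::read_yaml(contingency_file)$combinations
  cont <- data.frame(
    combo = vapply(raw, function(x) paste(x$cards, collapse = "+"), ""),
    n_cards = vapply(raw, function(x) length(x$cards), 0L),
    freq = vapply(raw, `[[`, 0, "freq"),
    p_sun = vapply(raw, `[[`, 0, "p_sun"))
  cont$excluded <- cont$p_sun == 0.5
  cards <- lapply(raw, `[[`, "cards")
  if (any(cont$p_sun < 0 | cont$p_sun > 1))
    stop("outcome probabilities outside [0, 1]")
  if (abs(sum(cont$freq) - 1) > 1e-8)
    stop("combination frequencies do not sum to 1")

  n_in <- 8
  card_units <- 1:4; sun_units <- 5:6; rain_units <- 7:8
  # training pattern bank: each combination x each outcome
  items <- matrix(0, 0, n_in)
  meta <- data.frame(combo = character(), outcome = character(),
                     combo_idx = integer())
  for (i in seq_along(cards)) {
    for (out in c("sun", "rain")) {
      v <- numeric(n_in)
      v[cards[[i]]] <- 1
      v[if (out == "sun") sun_units else rain_units] <- 1
      items <- rbind(items, v)
      meta <- rbind(meta, data.frame(
        combo = cont$combo[i], outcome = out, combo_idx = i))
    }
  }
  rownames(items) <- paste0(meta$combo, "_", meta$outcome)

  pin <- matrix(0, length(cards), n_in,
                dimnames = list(cont$combo, NULL))
  for (i in seq_along(cards)) pin[i, cards[[i]]] <- 1
  p_rec <- new_probe_set(
    "recognition", pin,
    correct = cards,
    denom = rep(list(card_units), length(cards)),
    chance = rep(1, length(cards)),
    meta = cont)
  p_cat <- new_probe_set(
    "categorization", pin,
    correct = lapply(cont$p_sun, function(p)
      if (p > 0.5) sun_units else rain_units),
    denom = rep(list(c(sun_units, rain_units)), length(cards)),
    chance = rep(0.5, length(cards)),
    meta = cont)

  roles <- c(rep("card", 4), rep("label", 4))
  new_dataset("weather", n_in, ec_k = 4, items = items, item_meta = meta,
              probes = list(recognition = p_rec, categorization = p_cat),
              unit_roles = roles, n_trials = 50,
              order_policy = "contingency",
              stopping_rule = list(min_trials = 25, window = 5,
                                   threshold = 1.2),
              extra = list(contingency = cont, cards = cards))
}

# Draw a weather training sequence: combination by presentation
# frequency, then outcome by the combination's conditional probability.
# Returns indices into the dataset's pattern bank (combo x outcome).
sample_weather_trials <- function(dataset, n) {
  ci <- sample.int(nrow(dataset$contingency), n, replace = TRUE,
                   prob = dataset$contingency$freq)
  sun <- runif(n) < dataset$contingency$p_sun[ci]
  (ci - 1L) * 2L + ifelse(sun, 1L, 2L)
}

#' Typicality-continuum categories (intermixed features)
#'
#' Two categories of creatures over 10 binary features (one unit per
#' feature value, 20 feature units) plus 5 label units per category
#' (30 input units).  The two prototypes share no features.  Training
#' items (10 per category, labels active) share 9, 8, 7 or 6 features
#' with their prototype in the fixed distribution \{9:2, 8:3, 7:3, 6:2\};
#' the prototypes themselves are never trained.  The identity of each
#' item's atypical features is a seeded draw; the counts are fixed.
#'
#' Probe sets (feature units only, labels silent):
#' * `generalization` — 42 novel items: both prototypes plus 5 items at
#'   each remaining distance level (9, 8, 7, 6, 4, 3, 2, 1 features
#'   shared with the first prototype), scored as activation of the
#'   correct category's 5 label units over all 10 label units
#'   (chance 0.5);
#' * `atypical_feature` — the 20 training items, scored as activation of
#'   the item's k atypical-feature units over the 10 units of the
#'   atypical (opposite-prototype) side, chance k/10.
#'
#' @param seed integer seed for the item draws.
#' @return a `hippcat_dataset`; training runs 5 shuffled epochs of the
#'   20 items (100 trials).  `msp_lr` carries the task's reduced
#'   monosynaptic learning rate.
#' @export
build_typicality_dataset <- function(seed = 1) {
  set.seed(as.integer(seed))
  n_feat <- 10; n_in <- 30
  unit_a <- function(f) 2 * f - 1          # feature value of prototype A
  unit_b <- function(f) 2 * f              # feature value of prototype B
  label_units <- list(A = 21:25, B = 26:30)

  feat_vec <- function(b_side) {           # b_side: features taking B value
    v <- numeric(n_in)
    v[unit_a(setdiff(seq_len(n_feat), b_side))] <- 1
    v[unit_b(b_side)] <- 1
    v
  }
  sig <- function(b_side) paste(sort(b_side), collapse = ",")

  # per-category typicality distribution: shared features 9,9,8,8,8,7,7,7,6,6
  atypical_counts <- c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4)
  items <- matrix(0, 0, n_in)
  meta <- data.frame(id = character(), category = character(),
                     n_atypical = integer(), b_side = character())
  used <- list(A = character(), B = character())
  for (cat in c("A", "B")) {
    for (j in seq_along(atypical_counts)) {
      k <- atypical_counts[j]
      repeat {
        flip <- sort(sample.int(n_feat, k))
        if (!(sig(flip) %in% used[[cat]])) break
      }
      used[[cat]] <- c(used[[cat]], sig(flip))
      b_side <- if (cat == "A") flip else setdiff(seq_len(n_feat), flip)
      v <- feat_vec(b_side)
      v[label_units[[cat]]] <- 1
      items <- rbind(items, v)
      meta <- rbind(meta, data.frame(
        id = paste0(cat, j), category = cat, n_atypical = k,
        b_side = sig(b_side)))
    }
  }
  rownames(items) <- meta$id

  # 42-item novel test set: prototypes + 5 per remaining distance level
  levels_a <- c(0, 1, 2, 3, 4, 6, 7, 8, 9, 10)  # features taking the B value
  gin <- matrix(0, 0, n_in)
  gmeta <- data.frame(id = character(), category = character(),
                      shared_with_proto = integer())
  trained_sigs <- meta$b_side
  for (nb in levels_a) {
    cat <- if (nb < 5) "A" else "B"
    n_items <- if (nb %in% c(0, 10)) 1 else 5
    drawn <- character()
    for (r in seq_len(n_items)) {
      repeat {
        b_side <- sort(sample.int(n_feat, nb))
        s <- sig(b_side)
        if (!(s %in% trained_sigs) && !(s %in% drawn)) break
      }
      drawn <- c(drawn, s)
      gin <- rbind(gin, feat_vec(b_side))
      gmeta <- rbind(gmeta, data.frame(
        id = paste0("novel_b", nb, "_", r), category = cat,
        shared_with_proto = if (cat == "A") n_feat - nb else nb))
    }
  }
  rownames(gin) <- gmeta$id
  p_gen <- new_probe_set(
    "generalization", gin,
    correct = label_units[gmeta$category],
    denom = rep(list(21:30), nrow(gmeta)),
    chance = rep(0.5, nrow(gmeta)),
    meta = gmeta)

  # atypical-feature probes: trained items, features only
  ain <- items
  ain[, 21:30] <- 0
  rownames(ain) <- meta$id
  atyp_units <- lapply(seq_len(nrow(meta)), function(i) {
    b_side <- as.integer(strsplit(meta$b_side[i], ",")[[1]])
    if (meta$category[i] == "A") unit_b(b_side)
    else unit_a(setdiff(seq_len(n_feat), b_side))
  })
  side_units <- lapply(meta$category, function(cat)
    if (cat == "A") unit_b(seq_len(n_feat)) else unit_a(seq_len(n_feat)))
  p_atyp <- new_probe_set(
    "atypical_feature", ain,
    correct = atyp_units,
    denom = side_units,
    chance = meta$n_atypical * 0.1,
    meta = meta)

  roles <- c(rep(c("feature-value"), 20), rep("label", 10))
  new_dataset("typicality", n_in, ec_k = 15, items = items,
              item_meta = meta,
              probes = list(generalization = p_gen,
                            atypical_feature = p_atyp),
              unit_roles = roles, n_trials = 100,
              order_policy = "epochs",
              extra = list(msp_lr = 5e-4))
}

#' Export a dataset's patterns as a delimited table
#'
#' Writes one row per training item (id, category, then one column per
#' input unit, headed by the unit's role) so runs are auditable.
#'
#' @param dataset a `hippcat_dataset`.
#' @param path output file (tab-separated).
#' @export
export_dataset <- function(dataset, path) {
  tab <- data.frame(id = rownames(dataset$items),
                    category = dataset$item_meta$category,
                    dataset$items, check.names = FALSE)
  colnames(tab)[-(1:2)] <- paste0("u", seq_len(dataset$input_size), ".",
                                  abbreviate(dataset$unit_roles, 6))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
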