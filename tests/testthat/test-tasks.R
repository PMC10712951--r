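# The three category-learning paradigms.

test_that("satellite dataset has the published structure", {
  ds <- build_satellite_dataset(7)
  expect_equal(ds$input_size, 27)
  expect_equal(nrow(ds$items), 15)
  expect_true(all(rowSums(ds$items) == 5))   # 5 active features per item
  expect_equal(ds$n_trials, 140)

  # prototypes carry only shared features; exemplars 4 shared + 1 unique
  meta <- ds$item_meta
  protos <- ds$items[is.na(meta$unique_unit), ]
  expect_equal(nrow(protos), 3)
  # category-prototypical unit active in every exemplar of its category
  for (cat in 1:3) {
    block <- (cat - 1) * 9
    incat <- ds$items[meta$category == cat, ]
    expect_true(all(incat[, block + 1] == 1))
    # categories share no input units
    expect_true(all(ds$items[meta$category != cat, block + 1:9] == 0))
  }
  # each unique unit belongs to exactly one training exemplar
  uniq <- meta$unique_unit[!is.na(meta$unique_unit)]
  expect_equal(length(uniq), 12)
  expect_equal(anyDuplicated(uniq), 0)
  expect_true(all(colSums(ds$items[, uniq]) == 1))

  # probe sets
  expect_equal(nrow(ds$probes$unique_feature$inputs), 12)
  expect_true(all(rowSums(ds$probes$unique_feature$inputs) == 1))
  expect_equal(unique(ds$probes$unique_feature$chance), 0.25)
  expect_equal(nrow(ds$probes$generalization$inputs), 18)
  expect_equal(as.vector(table(ds$probes$generalization$meta$category)),
               c(6, 6, 6))
  gin <- ds$probes$generalization$inputs
  expect_true(all(rowSums(gin) == 4))  # 2 shared + 2 unique features
  # novel probes never equal a training item
  for (i in seq_len(nrow(gin)))
    expect_false(any(apply(ds$items, 1, function(r) all(r == gin[i, ]))))
  # the category-prototypical feature is never part of a novel probe
  expect_true(all(gin[, c(1, 10, 19)] == 0))
})

test_that("satellite structure is seed-stable in counts, seed-varying in identity", {
  a <- build_satellite_dataset(1)
  b <- build_satellite_dataset(1)
  c <- build_satellite_dataset(2)
  expect_identical(a$items, b$items)
  expect_identical(a$probes$generalization$inputs,
                   b$probes$generalization$inputs)
  expect_false(identical(a$items, c$items))
  expect_true(all(rowSums(c$items) == 5))     # counts never vary
})

test_that("weather contingency reproduces the published probability structure", {
  ds <- build_weather_dataset(1)
  cont <- ds$contingency
  expect_equal(nrow(cont), 14)                       # 4 + 6 + 4 subsets
  expect_equal(as.vector(table(cont$n_cards)), c(4, 6, 4))
  expect_equal(sum(cont$freq), 1, tolerance = 1e-9)
  expect_equal(sum(cont$excluded), 2)                # the two 50/50 combos
  p <- function(combo) cont$p_sun[cont$combo == combo]
  expect_equal(p("1+2"), 0.90)
  expect_equal(p("1+2+3"), 0.79)
  expect_equal(p("4"), 0.15)
  expect_equal(ds$input_size, 8)                     # 4 cards + 2x2 outcomes
  # training bank pairs every combination with both outcomes
  expect_equal(nrow(ds$items), 28)
  expect_true(all(rowSums(ds$items[, 5:8]) == 2))
})

test_that("weather trial sampler matches the contingency frequencies", {
  ds <- build_weather_dataset(1)
  set.seed(123)
  idx <- hippcat:::sample_weather_trials(ds, 100000)
  combo <- (idx - 1L) %/% 2L + 1L
  sun <- idx %% 2L == 1L
  # empirical P(sun | combo 4-alone) within 3 s.e. of 0.15
  four <- which(ds$contingency$combo == "4")
  n4 <- sum(combo == four)
  p4 <- mean(sun[combo == four])
  expect_lt(abs(p4 - 0.15), 3 * sqrt(0.15 * 0.85 / n4))
  # empirical presentation frequency of each combination
  freq <- tabulate(combo, 14) / length(combo)
  expect_true(all(abs(freq - ds$contingency$freq) <
                    3 * sqrt(ds$contingency$freq *
                               (1 - ds$contingency$freq) / length(combo)) +
                    1e-6))
})

test_that("typicality dataset spans the published continuum", {
  ds <- build_typicality_dataset(3)
  expect_equal(ds$input_size, 30)          # 10 feature pairs + 2x5 labels
  expect_equal(nrow(ds$items), 20)
  expect_equal(ds$n_trials, 100)
  meta <- ds$item_meta
  # shared-feature distribution per category: {9:2, 8:3, 7:3, 6:2}
  for (cat in c("A", "B"))
    expect_equal(as.vector(table(meta$n_atypical[meta$category == cat])),
                 c(2, 3, 3, 2))
  # one active unit per binary feature pair, labels active in training
  feats <- ds$items[, 1:20]
  for (f in 1:10)
    expect_true(all(rowSums(feats[, c(2 * f - 1, 2 * f)]) == 1))
  expect_true(all(rowSums(ds$items[, 21:30]) == 5))

  # 42-item novel test set: 2 prototypes + 5 at each remaining level
  gp <- ds$probes$generalization
  expect_equal(nrow(gp$inputs), 42)
  expect_true(all(rowSums(gp$inputs[, 21:30]) == 0))  # labels silent
  tab <- table(gp$meta$category, gp$meta$shared_with_proto)
  expect_equal(sum(tab[, "10"]), 2)                   # both prototypes
  # five novel items per category at each remaining distance level
  expect_true(all(tab[, c("9", "8", "7", "6")] == 5))
  # prototypes themselves are never trained
  protoA <- gp$inputs[1, 1:20]
  expect_false(any(apply(ds$items[, 1:20], 1, function(r) all(r == protoA))))
  # no novel probe equals a training item's feature vector
  for (i in seq_len(nrow(gp$inputs)))
    expect_false(any(apply(ds$items[, 1:20], 1,
                           function(r) all(r == gp$inputs[i, 1:20]))))

  # atypical-feature probes score k correct units over the 10-unit side
  ap <- ds$probes$atypical_feature
  expect_equal(ap$chance, meta$n_atypical * 0.1)
  for (i in seq_len(20)) {
    expect_equal(length(ap$correct[[i]]), meta$n_atypical[i])
    expect_length(ap$denom[[i]], 10)
    expect_true(all(ap$correct[[i]] %in% ap$denom[[i]]))
  }
})

test_that("typicality prototypes share no features", {
  ds <- build_typicality_dataset(5)
  gp <- ds$probes$generalization
  protoA <- gp$inputs[gp$meta$shared_with_proto == 10 &
                        gp$meta$category == "A", 1:20]
  protoB <- gp$inputs[gp$meta$shared_with_proto == 10 &
                        gp$meta$category == "B", 1:20]
  expect_equal(sum(protoA * protoB), 0)
  expect_equal(sum(protoA), 10)
  expect_equal(sum(protoB), 10)
})

test_that("datasets export to an auditable delimited table", {
  ds <- build_satellite_dataset(1)
  f <- tempfile(fileext = ".tsv")
  export_dataset(ds, f)
  tab <- read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(tab), 15)
  expect_equal(ncol(tab), 29)
  expect_equal(as.matrix(tab[, -(1:2)]) * 1, unname(ds$items),
               ignore_attr = TRUE)
})
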