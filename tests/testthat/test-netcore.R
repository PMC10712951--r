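# Circuit construction and settling dynamics.

test_that("default architecture builds the published circuit dimensions", {
  cfg <- default_architecture(27, 5)
  net <- build_network(cfg, seed = 7)
  expect_equal(net$layers$DG$size, 400)
  expect_equal(net$layers$CA3$size, 80)
  expect_equal(net$layers$CA1$size, 100)
  expect_equal(net$layers$EC_in$size, 27)
  # each DG/CA3 unit samples 25% of EC_in, CA3 samples 5% of DG
  expect_true(all(rowSums(net$projections[["EC_in->DG"]]$mask) ==
                    round(0.25 * 27)))
  expect_true(all(rowSums(net$projections[["EC_in->CA3"]]$mask) ==
                    round(0.25 * 27)))
  expect_true(all(rowSums(net$projections[["DG->CA3"]]$mask) ==
                    round(0.05 * 400)))
  # CA3 recurrence is full off-diagonal
  m <- net$projections[["CA3->CA3"]]$mask
  expect_true(all(diag(m) == 0))
  expect_true(all(m[upper.tri(m)] == 1) && all(m[lower.tri(m)] == 1))
  # one-to-one EC links are identity and non-learnable
  expect_false(net$projections[["Input->EC_in"]]$learnable)
  expect_equal(net$projections[["Input->EC_in"]]$W, diag(1, 27))
  # learning-rate ratio TSP : MSP is exactly 10
  expect_identical(net$projections[["EC_in->DG"]]$lr /
                     net$projections[["EC_in->CA1"]]$lr, 10)
})

test_that("network build is deterministic in the seed and varies across seeds", {
  cfg <- default_architecture(27, 5)
  a <- build_network(cfg, 11)
  b <- build_network(cfg, 11)
  c <- build_network(cfg, 12)
  expect_identical(weight_hash(a), weight_hash(b))
  expect_identical(a$projections[["EC_in->DG"]]$mask,
                   b$projections[["EC_in->DG"]]$mask)
  expect_false(identical(weight_hash(a), weight_hash(c)))
  expect_false(identical(a$projections[["EC_in->DG"]]$mask,
                         c$projections[["EC_in->DG"]]$mask))
})

test_that("invalid configurations are rejected", {
  cfg <- toy_config()
  cfg$projections[[4]]$frac <- 1.5
  expect_error(build_network(cfg, 1), "fraction")
  cfg <- toy_config()
  cfg$projections[[4]]$src <- "nonsense"
  expect_error(build_network(cfg, 1), "unknown source")
  cfg <- toy_config()
  cfg$layers$CA1$k <- 200
  expect_error(build_network(cfg, 1), "k_active")
})

test_that("net input matches an elementwise brute-force oracle", {
  net <- toy_network(3)
  set.seed(9)
  state <- lapply(net$layers, function(l) runif(l$size))
  for (dst in c("EC_in", "DG", "CA3", "CA1", "EC_out")) {
    expect_equal(net_input(dst, net, state, "test"),
                 brute_net_input(dst, net, state, "test"),
                 tolerance = 1e-12)
  }
  # trough phase silences CA3->CA1; peak silences EC_in->CA1
  expect_equal(net_input("CA1", net, state, "trough"),
               brute_net_input("CA1", net, state, "trough"),
               tolerance = 1e-12)
  zeroed <- state
  zeroed$CA3 <- rep(0, net$layers$CA3$size)
  expect_equal(net_input("CA1", net, state, "trough"),
               net_input("CA1", net, zeroed, "trough"), tolerance = 1e-12)
  zeroed2 <- state
  zeroed2$EC_in <- rep(0, net$layers$EC_in$size)
  expect_equal(net_input("CA1", net, state, "peak"),
               net_input("CA1", net, zeroed2, "peak"), tolerance = 1e-12)
})

test_that("all-zero presynaptic activity produces zero drive", {
  net <- toy_network(4)
  state <- lapply(net$layers, function(l) numeric(l$size))
  expect_equal(net_input("DG", net, state), numeric(net$layers$DG$size))
})

test_that("k-winner-take-all picks the top k and respects symmetry", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    k <- sample(seq_len(n - 1), 1)
    d <- rnorm(n)
    a <- apply_kwta(d, k, gain = 100)
    expect_true(all(a >= 0 & a <= 1))
    # exactly k strongly active for untied random drives
    expect_equal(sum(a > 0.5), k)
    expect_setequal(which(a > 0.5), order(d, decreasing = TRUE)[1:k])
    # monotone: activation is nondecreasing in drive
    expect_true(all(diff(a[order(d)]) >= -1e-12))
    # permutation equivariance
    perm <- sample(n)
    expect_equal(apply_kwta(d[perm], k, gain = 100), a[perm])
  }
  # ties: equal drives give equal activations
  expect_equal(apply_kwta(rep(0.3, 6), 2, gain = 50), rep(0.5, 6))
  expect_error(apply_kwta(c(1, NA, 0), 1, 10), "non-finite")
})

test_that("kwta floor silences weakly driven layers", {
  d <- c(0.05, 0.04, 0.01, 0.02)
  a <- apply_kwta(d, 2, gain = 100, floor = 0.5)
  expect_true(all(a < 0.01))
  a2 <- apply_kwta(d + 1, 2, gain = 100, floor = 0.5)
  expect_equal(sum(a2 > 0.5), 2)
})

test_that("settling respects clamps, stays bounded, and is deterministic", {
  net <- toy_network(5)
  pat <- c(1, 0, 1, 0, 0, 0)
  st <- settle(net, list(Input = pat), phase = "trough")
  expect_identical(st$act$Input, pat)   # clamp held bit-exactly
  for (l in names(st$act))
    expect_true(all(st$act[[l]] >= 0 & st$act[[l]] <= 1))
  st2 <- settle(net, list(Input = pat), phase = "trough")
  expect_identical(st$act, st2$act)
  expect_identical(st$cycles, st2$cycles)
  # plus phase holds the EC_out clamp too
  stp <- settle(net, list(Input = pat, EC_out = pat), phase = "plus")
  expect_identical(stp$act$EC_out, pat)
})

test_that("compiled and reference settling engines agree", {
  net <- toy_network(6)
  pat <- c(0, 1, 0, 0, 1, 0)
  for (ph in c("trough", "peak", "plus", "test")) {
    clamps <- list(Input = pat)
    if (ph == "plus") clamps$EC_out <- pat
    a <- settle(net, clamps, phase = ph, engine = "cpp")
    b <- settle(net, clamps, phase = ph, engine = "R")
    expect_equal(a$act, b$act, tolerance = 1e-12)
    expect_identical(a$cycles, b$cycles)
    expect_identical(a$converged, b$converged)
  }
})

test_that("non-convergence is flagged, not an error", {
  net <- toy_network(7)
  st <- settle(net, list(Input = c(1, 0, 0, 1, 0, 0)), max_cycles = 1)
  expect_false(st$converged)
  expect_identical(st$cycles, 1L)
})

test_that("gate override severs the big loop", {
  net <- toy_network(8)
  pat <- c(1, 1, 0, 0, 0, 0)
  full <- settle(net, list(Input = pat), phase = "test")
  cut <- settle(net, list(Input = pat), phase = "test",
                gate_override = list("EC_out->EC_in" = 0))
  # with the loop cut, EC_in is driven by Input alone
  expect_equal(which(cut$act$EC_in > 0.5), which(pat == 1))
  expect_true(all(cut$act$EC_in >= 0 & cut$act$EC_in <= 1))
  expect_length(full$act$EC_in, 6)
})

test_that("weight contrast is monotone, bounded and invertible", {
  w <- seq(0.05, 0.95, by = 0.01)
  for (g in c(1, 6, 10)) for (off in c(1, 1.25)) {
    e <- weight_contrast(w, g, off)
    expect_true(all(diff(e) >= 0))
    expect_true(all(e >= 0 & e <= 1))
    expect_equal(hippcat:::weight_contrast_inv(e, g, off), w,
                 tolerance = 1e-6)
  }
  expect_identical(weight_contrast(c(0, 1, 0.5), 1, 1), c(0, 1, 0.5))
})

test_that("architecture configs and networks round-trip through files", {
  cfg <- toy_config()
  f <- tempfile(fileext = ".yaml")
  write_architecture(cfg, f)
  cfg2 <- read_architecture(f)
  expect_equal(cfg2$layers$DG$size, 20)
  expect_identical(names(cfg2$projections), names(cfg$projections))
  net <- build_network(cfg2, 3)
  rds <- tempfile(fileext = ".rds")
  save_network(net, rds)
  net2 <- load_network(rds)
  expect_identical(net, net2)    # bit-exact round trip
})
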