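test_that("initialization builds an all-zero grid of the right shape", {
  net <- init_network(toy_schema(2, 1))
  expect_equal(net$N, 2L)
  expect_true(all(net$W == 0))
  expect_equal(init_network(generate_synthetic(ehos_like_spec(1))$schema)$N, 778L)
  expect_error(init_network(toy_schema(2, 1), v_on = 0), "positive")
  expect_error(init_network(toy_schema(2, 1), e_mag = -1), "positive")
})

test_that("association programs exactly the cross-set pairs at v_ON", {
  d <- disjoint_dataset(2, 8)
  net <- init_network(d$schema)
  net <- associate(net, get_memory(d, 1))
  # n(n-1) = 56 ordered cross-set pairs for one 8-feature memory
  expect_equal(sum(net$W == net$v_on), 56L)
  expect_true(all(net$W %in% c(0, net$v_on)))
  # idempotent
  net2 <- associate(net, get_memory(d, 1))
  expect_identical(net2$W, net$W)
  # a feature-disjoint second memory adds 56 more, no overlap
  net3 <- associate(net, get_memory(d, 2))
  expect_equal(sum(net3$W == net$v_on), 112L)
  expect_error(associate(net, rep(99L, 8)), "out of range")
})

test_that("no operation ever writes an intra-set or self weight", {
  set.seed(21)
  allowed <- function(net) {
    same_set <- outer(net$set_id, net$set_id, "==")
    all(net$W[same_set] == 0)   # includes the diagonal
  }
  for (rep in 1:10) {
    inst <- random_instance()
    net <- init_network(inst$dataset$schema)
    for (r in seq_len(inst$i))
      net <- associate(net, get_memory(inst$dataset, r))
    expect_true(allowed(net))
    m <- get_memory(inst$dataset, 1)
    net <- apply_predictive(net, m, 1 * net$v_on)$net   # low threshold: fires
    expect_true(allowed(net))
    net <- apply_forgetting(net, 0.1)
    net <- apply_erase(net, 2 * net$v_on)$net
    expect_true(allowed(net))
    expect_true(all(net$W >= 0 & net$W <= net$v_on))
  }
  # allowed directed weight count: N^2 - sum(M_i^2)
  sc <- toy_schema(3, c(2, 3, 4))
  expect_equal(sum(outer(rep(1:3, c(2, 3, 4)), rep(1:3, c(2, 3, 4)), "!=")),
               sc$N^2 - sum(sc$M^2))
})

test_that("single-pass outputs follow E + W^T E and the worked examples", {
  d <- disjoint_dataset(3, 8)
  net <- init_network(d$schema)
  # zero weights: f = E
  E <- numeric(net$N); E[c(1, 5)] <- 1
  expect_equal(compute_outputs(net, E)$f, E)
  # one stored memory, input on 4 of its features
  m <- get_memory(d, 1)
  net <- associate(net, m)
  glob <- net$schema$offset + m
  E <- numeric(net$N); E[glob[1:4]] <- 1
  f <- compute_outputs(net, E)$f
  # each concealed member feature collects 4 * v_ON
  expect_equal(unname(f[glob[5:8]]), rep(4e-3, 4))
  # each clamped feature: e_mag + 3 * v_ON from the other clamped members
  expect_equal(unname(f[glob[1:4]]), rep(1.003, 4))
  # all non-member neurons silent
  expect_equal(sum(f > 0), 8L)
  expect_error(compute_outputs(net, numeric(3)), "length")
  expect_error(compute_outputs(net, E * 2), "0 or e_mag")
})

test_that("clamped input always beats recurrent feedback (trust guarantee)", {
  set.seed(31)
  for (rep in 1:10) {
    inst <- random_instance()
    net <- init_network(inst$dataset$schema)
    for (r in seq_len(inst$i)) net <- associate(net, get_memory(inst$dataset, r))
    m <- get_memory(inst$dataset, 1)
    glob <- net$schema$offset + m
    E <- numeric(net$N); E[glob[1]] <- net$e_mag
    f <- compute_outputs(net, E)$f
    # active neurons << 1/v_ON here, so feedback stays below e_mag
    expect_true(all(f[-glob[1]] < net$e_mag))
    expect_true(f[glob[1]] > max(f[-glob[1]]))
  }
})

test_that("readout finds strict winners, sentinels, and ties", {
  net <- init_network(toy_schema(2, 2))
  expect_true(all(is.na(readout(numeric(4), net)$features)))
  ro <- readout(c(0.2, 0, 0, 0.1), net)
  expect_equal(ro$features, c(1L, 2L))
  expect_length(ro$tie_sets, 0)
  ro2 <- readout(c(0.2, 0.2, 0, 0.1), net)   # equal positive maxima in set 1
  expect_equal(ro2$tie_sets, 1L)
  expect_true(is.na(ro2$features[1]))
})

test_that("a lone stored memory is recalled perfectly from any partial input", {
  d <- disjoint_dataset(4, 4)
  net <- init_network(d$schema)
  m <- get_memory(d, 2)
  net <- associate(net, m)
  for (k in 1:4) {
    for (j in seq_len(ncol(sets <- utils::combn(4, k)))) {
      r <- recall(net, m, sets[, j])
      expect_true(r$hit)
      expect_equal(r$tiebreaks, 0L)   # deterministic, no ties
    }
  }
  # empty network: non-input sets all zero -> sentinels -> miss
  r0 <- recall(init_network(d$schema), m, c(1, 2))
  expect_false(r0$hit)
  expect_true(all(is.na(r0$readout$features[3:4])))
})

test_that("vectorized recall matches the neuron-by-neuron reference", {
  set.seed(1234)
  for (case in 1:200) {
    inst <- random_instance()
    net <- init_network(inst$dataset$schema)
    stored <- sample.int(inst$i, sample.int(inst$i, 1))
    for (r in stored) net <- associate(net, get_memory(inst$dataset, r))
    q <- get_memory(inst$dataset, sample.int(inst$i, 1))
    input_sets <- sort(sample.int(inst$n, sample.int(inst$n - 1, 1)))
    seed <- sample.int(1e6, 1)
    set.seed(seed); got <- recall(net, q, input_sets)
    set.seed(seed); want <- oracle_recall(net, q, input_sets)
    expect_identical(got$readout$features, want$features)
    expect_identical(got$hit, want$hit)
    set.seed(case)  # fresh stream for next case construction
  }
})

test_that("tie resolution terminates and a fair coin decides shared queries", {
  d <- shared_pair_dataset()
  net <- init_network(d$schema)
  net <- associate(net, get_memory(d, 1))
  net <- associate(net, get_memory(d, 2))
  set.seed(55)
  hits <- 0L
  for (i in 1:2000) {
    r <- recall(net, get_memory(d, 1), 1:4)
    expect_lte(r$tiebreaks, net$N)
    hits <- hits + r$hit
  }
  # first coin flip decides; subsequent sets resolve consistently
  expect_equal(hits / 2000, 0.5, tolerance = 0.06)
})

test_that("network checkpoints round-trip", {
  net <- associate(init_network(toy_schema(3, 2)), c(1L, 2L, 1L))
  path <- withr::local_tempfile(fileext = ".rds")
  write_network(net, path)
  expect_identical(read_network(path), net)
})
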