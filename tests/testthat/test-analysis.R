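test_that("robustness of the chain is zero: every edge deletion disconnects", {
  rob <- robustness(chain_grn(3))
  expect_equal(rob$r, 0)
  expect_equal(rob$per_edge$f_prime, c(0, 0))
  expect_equal(rob$n_essential, 2)
  expect_equal(essential_edge_count(chain_grn(3)), 2)
})

test_that("a network with no input-output path is fully neutral: r = f = 0", {
  p <- grn_params(n_nodes = 4, n_edges = 3)
  net <- grn_network(
    data.frame(source = c(1, 2, 1), target = c(2, 1, 1), sign = c(1, -1, 1)),
    p)
  rob <- robustness(net)
  expect_equal(rob$fitness, 0)
  expect_equal(rob$r, 0)        # every deletion leaves fitness at 0 = f
  expect_equal(rob$per_edge$f_prime, rep(0, 3))
  # under the f' < 0.8 definition a zero-fitness network has every edge
  # trivially below the cut; neutrality in the meaningful sense is f' = f
  expect_equal(rob$n_essential, 3)
  expect_equal(essential_edge_count(net, threshold = 0), 0)
})

test_that("essential-edge count is non-increasing in the threshold", {
  set.seed(61)
  net <- random_small_net(6, 10)
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95),
                   function(th) essential_edge_count(net, th), 0L)
  expect_true(all(diff(counts) >= 0))  # larger threshold, more essential
  expect_true(all(counts >= 0 & counts <= 10))
})

test_that("hysteresis finds the handcrafted toggle and not a plain relay", {
  strict <- hysteresis_sweep(bistable_grn(), strict_criterion())
  expect_equal(strict$verdict, "bistable")
  expect_gt(strict$max_gap, 0.5)
  expect_equal(classify_switch(strict), "toggle")
  loose <- hysteresis_sweep(bistable_grn(), loose_criterion())
  expect_equal(loose$verdict, "bistable")

  relay <- hysteresis_sweep(chain_grn(3), loose_criterion())
  expect_equal(relay$verdict, "monostable")
  expect_lt(relay$max_gap, 1e-9)
  expect_error(classify_switch(relay), "bistable")

  # an unregulated output sits at 0.5 on both branches
  p <- grn_params(n_nodes = 3, n_edges = 1)
  idle <- grn_network(data.frame(source = 2, target = 1, sign = 1), p)
  h <- hysteresis_sweep(idle, loose_criterion())
  expect_equal(h$verdict, "monostable")
  expect_true(all(abs(h$branches$up - 0.5) < 1e-12))
})

test_that("loose-criterion bistability implies strict-criterion bistability", {
  set.seed(62)
  nets <- c(list(bistable_grn(), chain_grn(3)),
            replicate(6, random_small_net(6, 10, beta = 6, mu = 0.5),
                      simplify = FALSE))
  for (net in nets) {
    if (is_bistable(net, loose_criterion())) {
      expect_true(is_bistable(net, strict_criterion()))
    }
  }
})

test_that("switch subtypes follow the jump pattern of the branches", {
  fake <- function(up, down) {
    structure(list(verdict = "bistable", max_gap = max(abs(up - down)),
                   branches = tibble::tibble(I = seq(0, 1, length.out = length(up)),
                                             up = up, down = down),
                   criterion = strict_criterion()),
              class = "grn_bistability")
  }
  g <- seq(0, 1, length.out = 101)
  # jumps in both sweeps inside (0, 1)
  up <- ifelse(g < 0.4, 0.1, 0.9); down <- ifelse(g < 0.2, 0.1, 0.9)
  expect_equal(classify_switch(fake(up, down)), "toggle")
  # only the up sweep jumps: the other fold lies outside the range
  up2 <- ifelse(g < 0.6, 0.1, 0.9); down2 <- rep(0.9, 101)
  expect_equal(classify_switch(fake(up2, down2)), "one_way")
  # branches differ everywhere with no jump
  expect_equal(classify_switch(fake(rep(0.2, 101), rep(0.8, 101))),
               "unswitchable")
})

test_that("effective node count matches the reachability oracle", {
  expect_equal(effective_node_count(chain_grn(4)), 4)
  # unregulated graph: only the output reaches itself
  p <- grn_params(n_nodes = 5, n_edges = 1)
  lone <- grn_network(data.frame(source = 0, target = 1, sign = 1), p)
  expect_equal(effective_node_count(lone), 1)
  set.seed(63)
  for (i in 1:20) {
    net <- random_small_net(sample(3:6, 1), sample(2:8, 1))
    expect_equal(effective_node_count(net), oracle_effective_nodes(net))
  }
})

test_that("simple path counting matches exhaustive enumeration", {
  expect_equal(count_paths(chain_grn(4))$n_path, 1)
  p <- grn_params(n_nodes = 4, n_edges = 6)
  # 0 -> {1, 2} -> 3 plus 0 -> 3 and 1 -> 2: exactly 4 simple paths
  dag <- grn_network(
    data.frame(source = c(0, 0, 1, 2, 0, 1), target = c(1, 2, 3, 3, 3, 2),
               sign = 1), p)
  expect_equal(count_paths(dag)$n_path, 4)
  pnp <- grn_params(n_nodes = 4, n_edges = 2)
  no_path <- grn_network(data.frame(source = c(1, 2), target = c(2, 3),
                                    sign = 1), pnp)
  expect_equal(count_paths(no_path)$n_path, 0)
  set.seed(64)
  for (i in 1:20) {
    net <- random_small_net(sample(4:6, 1), sample(3:10, 1))
    expect_equal(count_paths(net)$n_path, oracle_simple_paths(net))
  }
  # saturation flag: the cap stops the count
  dense <- random_small_net(6, 20)
  capped <- count_paths(dense, cap = 1)
  expect_true(capped$saturated || capped$n_path <= 1)
})

test_that("paths exist whenever fitness is positive", {
  set.seed(65)
  for (i in 1:15) {
    net <- random_small_net(5, 8)
    if (grn_fitness(net) > 1e-12) {
      expect_gte(count_paths(net)$n_path, 1)
    }
  }
})

test_that("motif census matches the brute-force subgraph scan", {
  # the 2-node pattern with mutual + auto activation everywhere
  p <- grn_params(n_nodes = 3, n_edges = 4)
  m <- count_motifs(grn_network(
    data.frame(source = c(0, 1, 0, 1), target = c(1, 0, 0, 1), sign = 1), p))
  expect_equal(m$mutual_activation, 1)
  expect_equal(m$auto_activation, 2)
  expect_equal(m$mutual_activation_with_auto, 1)
  expect_equal(m$auto_repression + m$mutual_repression + m$ffl_coherent +
                 m$fbl_positive + m$mutual_repression_with_auto, 0)
  set.seed(66)
  for (i in 1:15) {
    net <- random_small_net(6, 10)
    got <- unlist(count_motifs(net))
    want <- oracle_motifs(net)
    expect_equal(got[names(want)], want)
  }
})

test_that("sub-bin reweighting is the identity for matched fitness distributions", {
  set.seed(67)
  f <- runif(400, 0.50, 0.51)
  stat <- rpois(400, 5)
  es <- tibble::tibble(fitness = f, statistic = stat)
  ref <- tibble::tibble(fitness = f, statistic = rpois(400, 5))
  rw <- reweight_histogram(es, ref, target_bin = 50)
  raw <- as.numeric(table(stat)) / length(stat)
  expect_equal(rw$histogram$weight, raw, tolerance = 1e-12)
  expect_equal(sum(rw$histogram$weight), 1)
})

test_that("reweighting recovers the reference distribution of an f-determined statistic", {
  set.seed(68)
  # statistic is a deterministic function of f: reweighted evolved
  # histogram must equal the reference histogram exactly (up to sub-bin
  # resolution)
  stat_of <- function(f) floor((f - 0.5) * 1000)  # constant within sub-bin
  f_es <- runif(600, 0.500, 0.505)   # concentrated low in the bin
  f_ref <- runif(900, 0.50, 0.51)    # spread over the whole bin
  es <- tibble::tibble(fitness = f_es, statistic = stat_of(f_es))
  ref <- tibble::tibble(fitness = f_ref, statistic = stat_of(f_ref))
  rw <- suppressWarnings(reweight_histogram(es, ref, target_bin = 50))
  ref_hist <- table(factor(ref$statistic, levels = 0:9)) / nrow(ref)
  got <- rep(0, 10); names(got) <- 0:9
  got[as.character(rw$histogram$statistic)] <- rw$histogram$weight
  covered <- sort(unique(stat_of(f_es)))
  ref_cov <- as.numeric(ref_hist[as.character(covered)])
  expect_equal(as.numeric(got[as.character(covered)]),
               ref_cov / sum(ref_cov), tolerance = 1e-12)
})

test_that("reweighting flags orphan sub-bins and coverage gaps", {
  es <- tibble::tibble(fitness = c(0.5001, 0.509), statistic = c(1, 2))
  ref <- tibble::tibble(fitness = rep(0.5005, 5), statistic = 1:5)
  expect_warning(reweight_histogram(es, ref, target_bin = 50), "counterpart")
  # all evolved samples orphaned is an error, not a silent zero
  es2 <- tibble::tibble(fitness = c(0.509, 0.5095), statistic = c(1, 2))
  expect_error(suppressWarnings(reweight_histogram(es2, ref, target_bin = 50)),
               "orphan")
})

test_that("bistable fraction is zero for monostable sets and ordered across criteria", {
  set.seed(69)
  chains <- replicate(5, chain_grn(3), simplify = FALSE)
  tb <- bistable_fraction(chains, criterion = loose_criterion())
  expect_true(all(tb$p2 == 0))
  expect_equal(sum(tb$n), 5)
  # strict criterion can only call more networks bistable than loose
  nets <- c(chains, list(bistable_grn()))
  strict_tb <- bistable_fraction(nets, criterion = strict_criterion())
  loose_tb <- bistable_fraction(nets, criterion = loose_criterion())
  expect_gte(sum(strict_tb$n_bistable), sum(loose_tb$n_bistable))
})

test_that("the per-genotype analysis table assembles all statistics", {
  set.seed(70)
  nets <- replicate(3, random_small_net(5, 6), simplify = FALSE)
  tb <- analyze_networks(nets, criterion = loose_criterion(), motifs = TRUE)
  expect_equal(nrow(tb), 3)
  expect_true(all(c("fitness", "r", "n_essential", "n_effective", "n_path",
                    "verdict", "ffl_coherent") %in% names(tb)))
  expect_equal(tb$fitness, vapply(nets, grn_fitness, 0))
})
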