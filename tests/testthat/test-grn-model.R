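test_that("response function matches its closed form and is monotone", {
  expect_equal(response(0, beta = 2, mu = 0), 0.5)
  expect_equal(response(0.7, beta = 5, mu = 0.7), 0.5)  # R(mu) = 1/2
  expect_equal(response(1, beta = 2, mu = 0), 1 / (1 + exp(-2)))
  x <- seq(-3, 3, length.out = 50)
  expect_true(all(diff(response(x)) > 0))
  expect_lt(response(-50), 1e-10)
  expect_gt(response(50), 1 - 1e-10)
})

test_that("parameter validation enforces the model invariants", {
  expect_error(grn_params(n_nodes = 1), "n_nodes")
  expect_error(grn_params(n_nodes = 3, n_edges = 10))
  expect_error(grn_params(output_index = 0), "output_index")
  expect_error(grn_params(beta = 0))
  expect_error(grn_network(
    data.frame(source = c(0, 0), target = c(1, 1), sign = c(1, -1)),
    grn_params(n_nodes = 3, n_edges = 2)), "duplicate")
  expect_error(grn_network(
    data.frame(source = 0, target = 1, sign = 2),
    grn_params(n_nodes = 3, n_edges = 1)), "sign")
})

test_that("synchronous update matches hand evaluation", {
  p <- grn_params(n_nodes = 3, n_edges = 1)
  net <- grn_network(data.frame(source = 0, target = 2, sign = 1), p)
  s <- grn_step(net, rep(0.5, 3), input = 0.3)
  # unregulated node 1 relaxes to R(0) = 0.5; input node gets R(0.3)
  expect_equal(s[2], 0.5)
  expect_equal(s[1], response(0.3))
  expect_equal(s[3], response(0.5))  # 1/(1+e^-1)
  expect_equal(s[3], 1 / (1 + exp(-1)))
  # a fixed point maps to itself
  fix <- rep(0.5, 3)
  for (i in 1:200) fix <- grn_step(net, fix, 0.3)
  expect_equal(grn_step(net, fix, 0.3), fix, tolerance = 1e-12)
})

test_that("steady_output agrees with a pure-R fixed-point oracle", {
  set.seed(11)
  for (rep in 1:10) {
    net <- random_small_net(5, 7)
    for (input in c(0, 0.5, 1)) {
      got <- steady_output(net, input)
      if (got$converged) {
        expect_equal(got$output_level, oracle_steady(net, input),
                     tolerance = 1e-7)
      }
    }
  }
  # empty regulation of the output: constant map, converged at 0.5
  p <- grn_params(n_nodes = 3, n_edges = 1)
  net <- grn_network(data.frame(source = 1, target = 0, sign = 1), p)
  out <- steady_output(net, 1)
  expect_true(out$converged)
  expect_equal(out$output_level, 0.5)
})

test_that("fitness is zero without an input-output path and matches the oracle", {
  p <- grn_params(n_nodes = 4, n_edges = 2)
  no_path <- grn_network(
    data.frame(source = c(1, 2), target = c(2, 1), sign = c(1, -1)), p)
  expect_equal(grn_fitness(no_path), 0)
  set.seed(21)
  for (rep in 1:8) {
    net <- random_small_net(5, 6)
    f <- grn_fitness(net)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(f, oracle_fitness(net), tolerance = 1e-7)
  }
  # activation chain: fitness from composed scalar fixed points
  # chain 0 -> 1 -> 2: the steady state composes scalar fixed points,
  # x0* = R(I), x1* = R(x0*), x2* = R(x1*)
  ch <- chain_grn(3)
  f_hand <- abs(response(response(0.5)) -
                response(response(response(1))))
  expect_equal(grn_fitness(ch), f_hand, tolerance = 1e-9)
})

test_that("single-gene self-activation map has one fixed point at beta=2, mu=0 and two stable at beta=6, mu=0.5", {
  count_stable <- function(beta, mu) {
    g <- function(x) 1 / (1 + exp(-beta * (x - mu))) - x
    xs <- seq(0, 1, by = 1e-4)
    sgn <- sign(g(xs))
    roots <- which(diff(sgn) != 0)
    stable <- 0
    for (i in roots) {
      x <- uniroot(g, c(xs[i], xs[i + 1]))$root
      slope <- beta * response(x, beta, mu) * (1 - response(x, beta, mu))
      if (slope < 1) stable <- stable + 1
    }
    stable
  }
  expect_equal(count_stable(2, 0), 1)
  expect_equal(count_stable(6, 0.5), 2)
  # and iteration from 0.5 reaches the unique fixed point at beta=2
  p <- grn_params(n_nodes = 2, n_edges = 1)
  auto <- grn_network(data.frame(source = 1, target = 1, sign = 1), p)
  out <- steady_output(auto, 0)
  expect_true(out$converged)
})

test_that("random networks are uniform over topologies and reproducible", {
  p <- grn_params(n_nodes = 3, n_edges = 2)
  set.seed(5); a <- random_grn(p)
  set.seed(5); b <- random_grn(p)
  expect_identical(a$edges, b$edges)
  # saturated space: the unique topology
  ps <- grn_params(n_nodes = 2, n_edges = 4)
  sat <- random_grn(ps)
  expect_equal(sort(ps$n_nodes * sat$edges$source + sat$edges$target), 0:3)
  # frequencies of the 36 topologies within 4 sigma binomial error
  set.seed(99)
  n_draw <- 20000
  topo <- replicate(n_draw, paste(sort(grnmc:::net_codes(random_grn(p))),
                                  collapse = "-"))
  tab <- table(topo)
  expect_equal(length(tab), 36)
  p0 <- 1 / 36
  sigma <- sqrt(n_draw * p0 * (1 - p0))
  expect_true(all(abs(tab - n_draw * p0) < 4 * sigma))
})

test_that("rewire preserves the edge-count and multiplicity invariants", {
  set.seed(31)
  p <- grn_params(n_nodes = 4, n_edges = 5)
  net <- random_grn(p)
  for (i in 1:200) {
    mutant <- rewire(net)
    codes <- grnmc:::net_codes(mutant)
    expect_equal(length(codes), 5)
    expect_equal(anyDuplicated(codes), 0)
    # symmetric difference of edge sets is 0 (same pair redrawn) or 2
    d <- length(setdiff(codes, grnmc:::net_codes(net))) +
         length(setdiff(grnmc:::net_codes(net), codes))
    expect_true(d %in% c(0, 2))
    net <- mutant
  }
  sat <- random_grn(grn_params(n_nodes = 2, n_edges = 4))
  expect_error(rewire(sat), "saturated")
})

test_that("steady output is invariant to relabelling interior nodes", {
  set.seed(41)
  p <- grn_params(n_nodes = 5, n_edges = 7)
  net <- random_grn(p)
  # swap interior node labels 1 and 3 (0 input, 4 output stay put)
  perm <- c(0, 3, 2, 1, 4)
  permuted <- grn_network(
    tibble::tibble(source = perm[net$edges$source + 1],
                   target = perm[net$edges$target + 1],
                   sign = net$edges$sign), p)
  for (input in c(0, 1)) {
    expect_equal(steady_output(net, input)$output_level,
                 steady_output(permuted, input)$output_level,
                 tolerance = 1e-12)
  }
  expect_equal(grn_fitness(net), grn_fitness(permuted), tolerance = 1e-12)
})
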