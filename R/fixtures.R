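#' Generate test fixtures
#'
#' Deterministic (for a fixed RNG state) generators for the objects the
#' test oracles need: batches of random networks, exhaustively enumerable
#' toy genotype spaces, and the two handcrafted circuits.
#'
#' @param kind One of `"random_networks"`, `"enumerable_space"`,
#'   `"handcrafted_chain"`, `"handcrafted_bistable"`.
#' @param params A [grn_params()] object (ignored by the handcrafted
#'   kinds, which fix their own parameters).
#' @param n Number of networks for `"random_networks"`.
#' @return `random_networks`: a list of [grn_network()];
#'   `enumerable_space`: the tibble from [enumerate_genotypes()];
#'   handcrafted kinds: a single [grn_network()].
#' @examples
#' set.seed(1)
#' length(generate_fixture("random_networks", grn_params(4, 3), n = 5))
#' @export
generate_fixture <- function(kind = c("random_networks", "enumerable_space",
                                      "handcrafted_chain",
                                      "handcrafted_bistable"),
                             params = grn_params(), n = 10) {
  kind <- match.arg(kind)
  switch(kind,
    random_networks = replicate(n, random_grn(params), simplify = FALSE),
    enumerable_space = enumerate_genotypes(params),
    handcrafted_chain = chain_grn(3),
    handcrafted_bistable = bistable_grn()
  )
}
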