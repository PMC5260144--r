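# Shared fixtures: a hand-checkable toy network and a negative-feedback
# network with a limit cycle.

# 5 nodes: input IN drives A; A drives B; B inhibits A's sibling C; D isolated.
toy_network <- function() {
  mp_network(
    edges = data.frame(
      source = c("IN", "A", "IN", "B"),
      sign = c("+", "+", "+", "-"),
      target = c("A", "B", "C", "C")),
    nodes = data.frame(
      name = c("IN", "A", "B", "C", "D"),
      role = c("input", "internal", "internal", "internal", "internal"),
      phenotype = "internal"))
}

# negative feedback loop IN -> A -> B -| A gives a 2-cycle under clamped IN:
# A on -> B on -> A off -> B off -> A on ...
cyclic_network <- function() {
  mp_network(
    edges = data.frame(
      source = c("IN", "A", "B"),
      sign = c("+", "+", "-"),
      target = c("A", "B", "A")),
    nodes = data.frame(
      name = c("IN", "A", "B"),
      role = c("input", "internal", "internal"),
      phenotype = "internal"))
}

# brute-force fixed-point oracle using only the pure-R single-step update
brute_fixed_points <- function(net, I) {
  n <- length(net$nodes)
  fps <- list()
  for (code in 0:(2^n - 1)) {
    s <- structure(bitwAnd(code, 2L^(seq_len(n) - 1L)) > 0L, names = net$nodes)
    s <- apply_input(s, I, net)
    if (identical(unname(boolean_update(s, net)), unname(s)))
      fps[[length(fps) + 1L]] <- s
  }
  unique(fps)
}

# minimal scenario-scale config for fast lattice tests
small_config <- function(n_steps = 50L, ...) {
  simulation_config(L = 6L, n_steps = n_steps, seed = 1L,
                    cells = c(mac = 30L, b = 40L, h1 = 40L, h2 = 40L,
                              hr = 40L),
                    injections = data.frame(step = 0L, species = "Ag",
                                            amount = 300L, has_lps = TRUE),
                    ...)
}
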