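# Declarative configuration files, run manifests and test fixtures.

.config_keys <- c("L", "n_steps", "seed", "cells", "helper_active_frac", "helper_background_activation", "k",
                  "steps_per_day", "ag_replication", "ag_capacity",
                  "cell_cap_mult", "half_life", "injections", "rules",
                  "il10_suppression", "b_cell_presentation", "network")

#' Read / write a simulation configuration file
#'
#' YAML serialization of [simulation_config()]. Unknown keys are rejected,
#' never silently ignored. The rule table and network are referenced by file
#' path (`rules_file`, `network_file`) when not default.
#'
#' @param config an `mp_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mp_config"))
  x <- unclass(config)
  x$rules <- NULL
  x$network <- NULL
  x$cells <- as.list(x$cells)
  x$injections <- if (nrow(config$injections))
    lapply(seq_len(nrow(config$injections)), function(i)
      as.list(config$injections[i, ])) else list()
  x$half_life <- if (is.finite(x$half_life)) x$half_life else "Inf"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(x$cells)) x$cells <- unlist(x$cells)
  if (!is.null(x$injections)) {
    x$injections <- if (length(x$injections))
      do.call(rbind, lapply(x$injections, as.data.frame))
    else NULL
  }
  if (identical(x$half_life, "Inf")) x$half_life <- Inf
  do.call(simulation_config, x)
}

.hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run manifest
#'
#' Identifies a run completely: seed, hashes of the configuration, rule table
#' and network, package version and a timestamp. Two runs with equal
#' manifests (timestamp aside) produce byte-identical output.
#'
#' @param config an [simulation_config()].
#' @return Named list of class `mp_manifest`.
#' @export
run_manifest <- function(config) {
  stopifnot(inherits(config, "mp_config"))
  net <- .config_network(config)
  core <- unclass(config)
  core$rules <- NULL; core$network <- NULL
  structure(list(
    seed = config$seed,
    config_hash = .hash(core),
    rules_hash = .hash(as.data.frame(config$rules)),
    network_hash = .hash(list(net$nodes, net$role, net$edges)),
    package_version = as.character(utils::packageVersion("macpol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "mp_manifest")
}

#' Deterministic test fixtures
#'
#' Builds small synthetic objects for testing parsers and aggregators without
#' running an experiment. Families:
#' * `"random_network"` -- a random signed network with `n_nodes` nodes, the
#'   first `n_inputs` of which are inputs; edges drawn independently with
#'   probability `p_edge`, random sign.
#' * `"micro_lattice"` -- a minimal `mp_lattice` with prescribed agents and
#'   molecules placed at the origin site of an `L^3` lattice.
#' * `"timeseries"` -- a synthetic census table whose antigen trajectory is
#'   `"controlled"` (decays to zero) or `"dampened"` (grows monotonically).
#'
#' @param family fixture family name.
#' @param seed RNG seed; the fixture is a pure function of its arguments.
#' @param n_nodes,n_inputs,p_edge random-network parameters.
#' @param L,agents,molecules micro-lattice parameters (see
#'   [site_contents()]).
#' @param pattern,n_steps synthetic time-series parameters.
#' @return The fixture object.
#' @export
make_fixture <- function(family = c("random_network", "micro_lattice",
                                    "timeseries"),
                         seed = 1L, n_nodes = 8L, n_inputs = 2L,
                         p_edge = 0.25, L = 2L, agents = NULL,
                         molecules = integer(),
                         pattern = c("controlled", "dampened"),
                         n_steps = 50L) {
  family <- match.arg(family)
  set.seed(seed)
  switch(family,
    random_network = {
      stopifnot(n_nodes >= 2L, n_inputs >= 1L, n_inputs < n_nodes)
      nm <- c(paste0("IN", seq_len(n_inputs)),
              paste0("G", seq_len(n_nodes - n_inputs)))
      role <- c(rep("input", n_inputs), rep("internal", n_nodes - n_inputs))
      from <- rep(nm, each = n_nodes - n_inputs)
      to <- rep(nm[role == "internal"], n_nodes)
      pick <- stats::runif(length(from)) < p_edge & from != to
      edges <- data.frame(source = from[pick],
                          sign = sample(c("+", "-"), sum(pick), TRUE),
                          target = to[pick])
      key <- paste(edges$source, edges$target)
      edges <- edges[!duplicated(key), , drop = FALSE]
      if (!nrow(edges))
        edges <- data.frame(source = nm[1], sign = "+",
                            target = nm[role == "internal"][1])
      mp_network(edges, data.frame(name = nm, role = role, phenotype = role))
    },
    micro_lattice = {
      site <- site_contents(agents, molecules)
      config <- simulation_config(L = L, n_steps = 1L, seed = seed,
                                  cells = c(mac = 0L, b = 0L, h1 = 0L,
                                            h2 = 0L, hr = 0L),
                                  ag_replication = 0, half_life = Inf)
      lat <- init_population(config)
      ag <- site$agents
      if (nrow(ag)) {
        lat$agents <- data.frame(
          kind = match(ag$kind, .kind_levels),
          act = match(ag$activation, .act_levels),
          phen = match(ag$phenotype, .phen_levels) - 1L,
          grn = as.integer(ag$grn), site = 0L)
      }
      lat$mol[1, ] <- site$molecules
      lat$census <- .census_of(lat)
      lat
    },
    timeseries = {
      pattern <- match.arg(pattern)
      steps <- 0:n_steps
      ag <- if (pattern == "controlled")
        pmax(0, round(100 * exp(-steps / (n_steps / 5)))) else 100 + 10 * steps
      z <- matrix(0L, length(steps), 23,
                  dimnames = list(NULL, c(
                    "M0_r", "M0_a", "M0_p", "M1_r", "M1_a", "M1_p", "M2_r",
                    "M2_a", "M2_p", "B_a", "B_p", "H1_r", "H1_a", "H2_r",
                    "H2_a", "Hr_r", "Hr_a", "IFNg", "IL4", "IL10", "Ab",
                    "Ag_lps", "Ag_free")))
      z[, "Ag_lps"] <- as.integer(ag)
      ts <- cbind(data.frame(step = steps), as.data.frame(z))
      class(ts) <- c("mp_timeseries", "data.frame")
      ts
    })
}
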