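# Synchronous Boolean dynamics over an mp_network. States are named logical
# vectors aligned to net$nodes; internally a state packs into one integer
# (node i <-> bit 2^(i-1)), which bounds supported networks at 30 nodes and
# makes exhaustive enumeration of the default 18-node circuit cheap.

.macpol_cache <- new.env(parent = emptyenv())

.net_key <- function(net) {
  paste(c(net$nodes, net$role, net$edges$source, net$edges$sign,
          net$edges$target), collapse = "\r")
}

#' Create a network state
#'
#' @param net an `mp_network`.
#' @param active character vector of node names that are on; all other nodes
#'   are off. The all-zero state (the undifferentiated M0 ground state) is the
#'   default.
#' @return Named logical vector aligned to `net$nodes`.
#' @export
network_state <- function(net, active = character()) {
  stopifnot(inherits(net, "mp_network"))
  unknown <- setdiff(active, net$nodes)
  if (length(unknown)) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  structure(net$nodes %in% active, names = net$nodes)
}

#' @rdname network_state
#' @param state a state vector.
#' @return `active_nodes()` returns the names of the nodes that are on.
#' @export
active_nodes <- function(state) names(state)[as.logical(state)]

.check_state <- function(state, net) {
  if (length(state) != length(net$nodes) ||
      (!is.null(names(state)) && !identical(names(state), net$nodes)))
    stop("state is not aligned to the network (expected ",
         length(net$nodes), " bits in node order)")
  structure(as.logical(state), names = net$nodes)
}

state_to_int <- function(state) {
  sum(as.integer(state) * 2L^(seq_along(state) - 1L))
}

int_to_state <- function(code, net) {
  n <- length(net$nodes)
  structure(bitwAnd(code, 2L^(seq_len(n) - 1L)) > 0L, names = net$nodes)
}

#' One synchronous Boolean update
#'
#' Applies the update map to every node at once: a non-input node switches on
#' iff at least one of its activating parents is on and none of its inhibiting
#' parents is on; a node with no activating parents switches off. Input nodes
#' keep their current value (they are only changed by [apply_input()]).
#'
#' @param state named logical state vector aligned to `net`.
#' @param net an `mp_network`.
#' @return The successor state.
#' @export
boolean_update <- function(state, net) {
  state <- .check_state(state, net)
  out <- state
  for (n in net$nodes) {
    if (net$role[[n]] == "input") next
    act <- net$activators[[n]]
    inh <- net$inhibitors[[n]]
    out[[n]] <- (length(act) > 0L && any(state[act])) && !any(state[inh])
  }
  out
}

#' Clamp the input nodes of a state
#'
#' Overwrites the input-node bits of `state` with the stimulus vector `I`,
#' leaving every other bit untouched. For the bundled network the stimulus
#' order is (IFNg, IL10, IL4, LPS); [input_vector()] builds it by name.
#'
#' @param state named logical state vector.
#' @param I named logical vector over `net$input_nodes` (any order; matched by
#'   name), or an unnamed logical vector in `net$input_nodes` order.
#' @param net an `mp_network`.
#' @return The clamped state.
#' @export
apply_input <- function(state, I, net) {
  state <- .check_state(state, net)
  I <- .check_input(I, net)
  state[net$input_nodes] <- I[net$input_nodes]
  state
}

.check_input <- function(I, net) {
  I <- as.logical(unlist(I))
  if (is.null(names(I))) {
    if (length(I) != length(net$input_nodes))
      stop("unnamed input vector must have length ", length(net$input_nodes))
    names(I) <- net$input_nodes
  } else {
    missing <- setdiff(net$input_nodes, names(I))
    if (length(missing))
      stop("input vector is missing: ", paste(missing, collapse = ", "))
    I <- I[net$input_nodes]
  }
  I
}

#' @rdname apply_input
#' @param IFNg,IL10,IL4,LPS logical stimulus bits; `LPS` means LPS-bearing
#'   antigen is locally present.
#' @export
input_vector <- function(IFNg = FALSE, IL10 = FALSE, IL4 = FALSE, LPS = FALSE) {
  c(IFNg = as.logical(IFNg), IL10 = as.logical(IL10),
    IL4 = as.logical(IL4), LPS = as.logical(LPS))
}

#' Iterate the clamped dynamics
#'
#' Clamps the input nodes to `I`, then applies the synchronous update `k`
#' times. Inputs stay clamped throughout (input nodes have no parents, so the
#' update map holds them at their clamped value).
#'
#' @inheritParams apply_input
#' @param k number of synchronous updates, a positive integer.
#' @return The state after `k` updates of the clamped dynamics.
#' @export
iterate <- function(state, I, k, net) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("`k` must be a positive integer")
  x <- apply_input(state, I, net)
  for (i in seq_len(k)) x <- boolean_update(x, net)
  x
}

#' Full transition table of the clamped dynamics
#'
#' Precomputes the successor of every one of the `2^n` states as an integer
#' lookup table (`table[x + 1]` is the packed successor of packed state `x`).
#' Input nodes map to themselves, so iterating the table is the clamped
#' dynamics. Cached per network.
#'
#' @param net an `mp_network` with at most 22 nodes.
#' @return Integer vector of length `2^n`.
#' @export
transition_table <- function(net) {
  stopifnot(inherits(net, "mp_network"))
  n <- length(net$nodes)
  if (n > 22L)
    stop("network too large for a full transition table (", n, " nodes > 22)")
  key <- .net_key(net)
  hit <- .macpol_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- structure(seq_len(n), names = net$nodes)
  x <- 0:(2L^n - 1L)
  acc <- numeric(length(x))
  for (i in seq_len(n)) {
    node <- net$nodes[[i]]
    if (net$role[[node]] == "input") {
      bit <- bitwAnd(x, 2L^(i - 1L)) > 0L
    } else {
      act <- net$activators[[node]]
      inh <- net$inhibitors[[node]]
      amask <- sum(2L^(idx[act] - 1L))
      imask <- sum(2L^(idx[inh] - 1L))
      bit <- (amask > 0L & bitwAnd(x, amask) > 0L) & bitwAnd(x, imask) == 0L
    }
    acc <- acc + as.integer(bit) * 2L^(i - 1L)
  }
  tab <- as.integer(acc)
  .macpol_cache[[key]] <- tab
  tab
}

.input_mask <- function(net) {
  idx <- match(net$input_nodes, net$nodes)
  sum(2L^(idx - 1L))
}

.input_code <- function(I, net) {
  I <- .check_input(I, net)
  sum(as.integer(I) * 2L^(seq_along(net$input_nodes) - 1L))
}

#' Enumerate all fixed points under a clamped stimulus
#'
#' Brute force over every configuration of the non-input nodes with the input
#' nodes clamped at `I`: returns exactly the states `x` with `F(x) = x`. This
#' is the oracle against which the configured M1/M2 attractors and the forward
#' dynamics are validated.
#'
#' @inheritParams apply_input
#' @param net an `mp_network`; enumeration is refused beyond 22 nodes.
#' @return List of named logical state vectors (possibly empty), with the
#'   packed integer codes in attribute `"codes"`.
#' @export
enumerate_fixed_points <- function(net, I) {
  n <- length(net$nodes)
  if (n > 22L)
    stop("refusing to enumerate 2^", n - length(net$input_nodes),
         " internal configurations (", n, " nodes > 22)")
  tab <- transition_table(net)
  imask <- .input_mask(net)
  icode <- .input_code_packed(I, net)
  x <- 0:(2L^n - 1L)
  cand <- x[bitwAnd(x, imask) == icode]
  fp <- cand[tab[cand + 1L] == cand]
  out <- lapply(fp, int_to_state, net = net)
  attr(out, "codes") <- fp
  out
}

# stimulus bits placed at the actual input-node bit positions
.input_code_packed <- function(I, net) {
  I <- .check_input(I, net)
  idx <- match(net$input_nodes, net$nodes)
  sum(as.integer(I) * 2L^(idx - 1L))
}

#' Iterate until the trajectory closes
#'
#' Follows the clamped synchronous dynamics from `state` until it either
#' reaches a fixed point or revisits a state (a limit cycle). Cycles are
#' reported explicitly, never silently classified as commitment.
#'
#' @inheritParams apply_input
#' @param max_steps safety bound on trajectory length.
#' @return List with `state` (final state), `steps` (updates taken before the
#'   trajectory closed), `converged` (`TRUE` iff a fixed point was reached)
#'   and `cycle` (list of states on the limit cycle, empty if converged).
#' @export
iterate_until_convergence <- function(state, I, net, max_steps = 2L^length(net$nodes)) {
  tab <- transition_table(net)
  imask <- .input_mask(net)
  x <- state_to_int(.check_state(state, net))
  x <- bitwOr(bitwAnd(x, bitwNot(imask) %% 2L^length(net$nodes)),
              .input_code_packed(I, net))
  seen <- integer(0)
  for (s in 0:max_steps) {
    nx <- tab[x + 1L]
    if (nx == x)
      return(list(state = int_to_state(x, net), steps = s, converged = TRUE,
                  cycle = list()))
    if (x %in% seen) {
      cyc <- seen[which(seen == x):length(seen)]
      return(list(state = int_to_state(x, net), steps = s, converged = FALSE,
                  cycle = lapply(cyc, int_to_state, net = net)))
    }
    seen <- c(seen, x)
    x <- nx
  }
  stop("trajectory did not close within ", max_steps, " steps")
}

#' Attractor table: the M1/M2 fixed points under every stimulus
#'
#' For each of the `2^m` stimulus combinations (m = number of input nodes),
#' enumerates all fixed points of the clamped dynamics and identifies the M1
#' attractor (the fixed point with the M1 marker gene on) and the M2 attractor
#' (marker Arg1 on). Validation fails loudly if, under any stimulus, the
#' marker-active fixed point is not unique or a fixed point carries both
#' markers -- these conditions are what guarantee that a macrophage can commit
#' to at most one phenotype (f1 + f2 <= 1).
#'
#' @param net an `mp_network`.
#' @param m1_marker,m2_marker marker genes whose activity tags the two
#'   committed phenotypes.
#' @return An object of class `mp_attractors`: a data.frame (one row per
#'   stimulus/fixed-point pair) plus lookup tables used by [classify()] and
#'   the simulation engine.
#' @export
attractors <- function(net, m1_marker = "NOS2", m2_marker = "Arg1") {
  stopifnot(inherits(net, "mp_network"))
  if (!all(c(m1_marker, m2_marker) %in% net$nodes))
    stop("marker gene(s) not in network: ",
         paste(setdiff(c(m1_marker, m2_marker), net$nodes), collapse = ", "))
  m <- length(net$input_nodes)
  n_comb <- 2L^m
  rows <- list()
  m1_fp <- rep(NA_integer_, n_comb)
  m2_fp <- rep(NA_integer_, n_comb)
  i_m1 <- which(net$nodes == m1_marker)
  i_m2 <- which(net$nodes == m2_marker)
  for (code in 0:(n_comb - 1L)) {
    I <- structure(bitwAnd(code, 2L^(seq_len(m) - 1L)) > 0L,
                   names = net$input_nodes)
    fps <- enumerate_fixed_points(net, I)
    codes <- attr(fps, "codes")
    has1 <- bitwAnd(codes, 2L^(i_m1 - 1L)) > 0L
    has2 <- bitwAnd(codes, 2L^(i_m2 - 1L)) > 0L
    if (any(has1 & has2))
      stop("fixed point with both markers active under stimulus (",
           paste(net$input_nodes[I], collapse = ","), ")")
    if (sum(has1) > 1L || sum(has2) > 1L)
      stop("marker-active fixed point not unique under stimulus (",
           paste(net$input_nodes[I], collapse = ","), ")")
    if (any(has1)) m1_fp[code + 1L] <- codes[has1]
    if (any(has2)) m2_fp[code + 1L] <- codes[has2]
    lab <- ifelse(has1, "M1", ifelse(has2, "M2", "none"))
    if (length(codes))
      rows[[length(rows) + 1L]] <- data.frame(
        stimulus = paste(ifelse(I, "1", "0"), collapse = ""),
        fixed_point = codes,
        active = vapply(fps, function(s) paste(active_nodes(s), collapse = "+"),
                        ""),
        label = lab)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (all(is.na(m1_fp)) || all(is.na(m2_fp)))
    stop("network has no ", m1_marker, "-active or no ", m2_marker,
         "-active fixed point under any stimulus")
  if (any(stats::na.omit(m1_fp) %in% stats::na.omit(m2_fp)))
    stop("configuration error: an M1 attractor equals an M2 attractor")
  structure(list(table = tab, m1_fp = m1_fp, m2_fp = m2_fp,
                 m1_marker = m1_marker, m2_marker = m2_marker,
                 input_nodes = net$input_nodes, net_key = .net_key(net)),
            class = "mp_attractors")
}

.attractors_for <- function(net, att = NULL) {
  if (is.null(att)) {
    key <- paste0("att\r", .net_key(net))
    att <- .macpol_cache[[key]]
    if (is.null(att)) {
      att <- attractors(net)
      .macpol_cache[[key]] <- att
    }
  } else if (!identical(att$net_key, .net_key(net))) {
    stop("attractor table was built for a different network")
  }
  att
}

#' Classify a state as M1-committed, M2-committed or uncommitted
#'
#' A state is committed iff it *is* the M1 (or M2) attractor of the dynamics
#' clamped at the state's own input bits. Since under every stimulus the
#' marker-active fixed points are validated unique and marker-disjoint, at
#' most one label can ever fire.
#'
#' @param state named logical state vector.
#' @param net an `mp_network`.
#' @param att optional precomputed [attractors()] table.
#' @return One of `"M1_committed"`, `"M2_committed"`, `"uncommitted"`.
#' @export
classify <- function(state, net, att = NULL) {
  state <- .check_state(state, net)
  att <- .attractors_for(net, att)
  code <- state_to_int(state)
  icode <- sum(as.integer(state[net$input_nodes]) *
                 2L^(seq_along(net$input_nodes) - 1L))
  if (!is.na(att$m1_fp[icode + 1L]) && code == att$m1_fp[icode + 1L])
    return("M1_committed")
  if (!is.na(att$m2_fp[icode + 1L]) && code == att$m2_fp[icode + 1L])
    return("M2_committed")
  "uncommitted"
}

#' Attractor report
#'
#' One row per stimulus vector and fixed point of the clamped dynamics, with
#' the active genes and the M1/M2 classification. Suitable for writing as CSV.
#'
#' @param net an `mp_network`.
#' @param path optional CSV output path.
#' @return data.frame, invisibly if `path` is given.
#' @export
attractor_report <- function(net, path = NULL) {
  att <- .attractors_for(net)
  tab <- att$table
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @export
print.mp_attractors <- function(x, ...) {
  cat(sprintf("Attractor table over %d stimulus vectors (%s = M1 marker, %s = M2 marker)\n",
              2L^length(x$input_nodes), x$m1_marker, x$m2_marker))
  cat(sprintf("  %d stimuli admit an M1 attractor, %d an M2 attractor\n",
              sum(!is.na(x$m1_fp)), sum(!is.na(x$m2_fp))))
  print(x$table, ...)
  invisible(x)
}
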