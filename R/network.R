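#' Construct a signed Boolean regulatory network
#'
#' A regulatory network is a signed digraph over named nodes. Activating
#' parents (`+` edges) and inhibiting parents (`-` edges) feed the synchronous
#' Boolean update rule: a node switches on when at least one activating parent
#' is on and no inhibiting parent is on (see [boolean_update()]). Input nodes
#' are extracellular stimuli: they have no parents and are only ever changed
#' by clamping (see [apply_input()]).
#'
#' @param edges data.frame with columns `source`, `sign` (`"+"` or `"-"`) and
#'   `target`, one interaction per row.
#' @param nodes data.frame with columns `name`, `role` (one of `"input"`,
#'   `"receptor"`, `"internal"`) and `phenotype` (free tag, e.g. `"M1"`,
#'   `"M2"`, `"input"`, `"receptor"`). Row order fixes the state bit order.
#' @return An object of class `mp_network` with components `nodes` (character
#'   vector in bit order), `input_nodes`, `activators` and `inhibitors` (named
#'   lists of parent sets), `role` and `phenotype` (named character vectors).
#' @seealso [default_network()], [read_network()], [attractors()]
#' @export
mp_network <- function(edges, nodes) {
  stopifnot(is.data.frame(edges), is.data.frame(nodes))
  need_e <- c("source", "sign", "target")
  if (!all(need_e %in% names(edges)))
    stop("`edges` must have columns source, sign, target")
  if (!all(c("name", "role") %in% names(nodes)))
    stop("`nodes` must have columns name, role")
  if (is.null(nodes$phenotype)) nodes$phenotype <- nodes$role
  nm <- as.character(nodes$name)
  if (anyDuplicated(nm)) stop("duplicate node names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  bad_sign <- setdiff(unique(as.character(edges$sign)), c("+", "-"))
  if (length(bad_sign))
    stop("edge sign must be '+' or '-', got: ", paste(bad_sign, collapse = ", "))
  unknown <- setdiff(unique(c(edges$source, edges$target)), nm)
  if (length(unknown))
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conf <- vapply(unique(dup), function(k) {
      length(unique(edges$sign[key == k])) > 1L
    }, logical(1))
    if (any(conf))
      stop("duplicate edge with conflicting sign: ",
           paste(unique(dup)[conf], collapse = ", "))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  role <- structure(as.character(nodes$role), names = nm)
  if (!all(role %in% c("input", "receptor", "internal")))
    stop("node role must be input, receptor or internal")
  inputs <- nm[role == "input"]
  in_deg <- edges$target %in% inputs
  if (any(in_deg))
    stop("input node(s) may not have parents: ",
         paste(unique(edges$target[in_deg]), collapse = ", "))
  activators <- lapply(nm, function(n)
    as.character(edges$source[edges$target == n & edges$sign == "+"]))
  inhibitors <- lapply(nm, function(n)
    as.character(edges$source[edges$target == n & edges$sign == "-"]))
  names(activators) <- names(inhibitors) <- nm
  net <- structure(
    list(nodes = nm,
         input_nodes = inputs,
         activators = activators,
         inhibitors = inhibitors,
         role = role,
         phenotype = structure(as.character(nodes$phenotype), names = nm),
         edges = edges[, need_e]),
    class = "mp_network")
  net
}

#' The bundled macrophage polarization network
#'
#' Reconstruction of the minimal M1/M2 polarization circuit: four stimulus
#' inputs (IFNg, IL-10, IL-4, LPS), four receptors (IFNgR, IL-10R, IL-4Ra,
#' TLR4) and ten internal transducers/transcription factors/target genes.
#' The M1 branch runs LPS-TLR4-NF-kB-NOS2 and IFNg-IFNgR-STAT1-{SOCS3, NOS2};
#' the M2 branch runs IL-4-IL-4Ra-STAT6-{PPARg, SOCS1, KLF4, Arg1} and
#' IL-10-IL-10R-STAT3-IL-4Ra. Cross-inhibition: SOCS1 blocks STAT1, SOCS3
#' blocks STAT3, and KLF4, PPARg and STAT3 all repress NF-kB. NOS2 marks the
#' M1 attractor, Arg1 the M2 attractor.
#'
#' @param path optional path to an alternative edge-list file in the format
#'   of [read_network()].
#' @return An `mp_network`.
#' @export
default_network <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "macrophage_grn.tsv", package = "macpol",
                        mustWork = TRUE)
  read_network(path)
}

#' Read / write a signed edge-list network file
#'
#' Plain-text format: comment lines start with `#`; node metadata lines start
#' with `#node` and carry tab-separated fields name, role, phenotype; every
#' other non-empty line is one interaction `source<TAB>sign<TAB>target` with
#' sign `+` (activation) or `-` (inhibition). `write_network()` followed by
#' `read_network()` reproduces the network exactly.
#'
#' @param path file path.
#' @return `read_network()` returns an `mp_network`; `write_network()` returns
#'   `path` invisibly.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  node_ln <- grep("^#node\t", lines, value = TRUE)
  if (!length(node_ln)) stop("network file has no '#node' metadata lines: ", path)
  nf <- strsplit(sub("^#node\t", "", node_ln), "\t", fixed = TRUE)
  if (any(lengths(nf) != 3L)) stop("malformed '#node' line (need name, role, phenotype)")
  nodes <- data.frame(name      = vapply(nf, `[[`, "", 1L),
                      role      = vapply(nf, `[[`, "", 2L),
                      phenotype = vapply(nf, `[[`, "", 3L))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("network file has no edges: ", path)
  ef <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(ef) != 3L)) stop("malformed edge line (need source, sign, target)")
  edges <- data.frame(source = vapply(ef, `[[`, "", 1L),
                      sign   = vapply(ef, `[[`, "", 2L),
                      target = vapply(ef, `[[`, "", 3L))
  mp_network(edges, nodes)
}

#' @rdname read_network
#' @param net an `mp_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "mp_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#node\t%s\t%s\t%s", net$nodes,
                     unname(net$role[net$nodes]),
                     unname(net$phenotype[net$nodes])), con)
  writeLines(sprintf("%s\t%s\t%s", net$edges$source, net$edges$sign,
                     net$edges$target), con)
  invisible(path)
}

#' @export
print.mp_network <- function(x, ...) {
  cat(sprintf("Signed Boolean regulatory network: %d nodes (%d inputs), %d edges\n",
              length(x$nodes), length(x$input_nodes), nrow(x$edges)))
  cat("  inputs:  ", paste(x$input_nodes, collapse = ", "), "\n")
  cat("  internal:", paste(x$nodes[x$role == "internal"], collapse = ", "), "\n")
  n_act <- sum(x$edges$sign == "+")
  cat(sprintf("  %d activations, %d inhibitions\n", n_act, nrow(x$edges) - n_act))
  invisible(x)
}
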