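# The 15 mesoscopic contact rules, their R-level table representation, and
# the per-site application / macrophage differentiation operations. The
# compiled engine executes the same rules; the table is the user-facing,
# serializable description (probabilities and toggles are editable, the
# reactant/product structure is fixed).

.kind_levels <- c("Macrophage", "Bcell", "Th1", "Th2", "Treg")
.act_levels <- c("resting", "active", "presenting")
.phen_levels <- c("M0", "M1", "M2")
.mol_species <- c("IFNg", "IL4", "IL10", "Ab", "Ag_lps", "Ag_free")

.rule_def <- data.frame(
  id = 1:15,
  reactants = c("M^r + IFNg", "M^a + Ag", "M^p", "M^a",
                "M^p + H1^a", "M^p + H2^a", "M2^p + Hr^a",
                "B^a + Ag", "B^p", "B^p + H1^a", "B^p + H2^a",
                "H^r + APC^p", "H^a", "H1^a + B^p", "Ab + Ag"),
  products = c("M^a", "M^p", "M^a", "M^r",
               "M^p + H1^a + IFNg", "M^p + H2^a + IL4",
               "M2^p + Hr^a + IL10",
               "B^p", "B^a", "2B^p + 2H1^a + IFNg + Ab",
               "2B^p + 2H2^a + IL4 + Ab",
               "H^a + APC^p", "H^r", "H1^a + B^p + IFNg", "0"),
  description = c(
    "macrophage activation by IFNg (cytokine consumed)",
    "antigen phagocytosis and presentation by macrophages",
    "macrophage stops presenting",
    "macrophage returns to rest",
    "presentation to Th1 induces IFNg release",
    "presentation to Th2 induces IL-4 release",
    "Treg contact with an M2 presenter induces IL-10 release",
    "antigen phagocytosis and presentation by B cells",
    "B cell stops presenting",
    "Th1 help: B and Th1 duplicate, IFNg and antibody released",
    "Th2 help: B and Th2 duplicate, IL-4 and antibody released",
    "presenting cell (macrophage or B cell) activates resting helpers",
    "helper returns to rest",
    "Th1 recognises B-cell presentation, releases IFNg",
    "antibody neutralises antigen"))

#' The mesoscopic reaction-rule table
#'
#' Returns the 15 stochastic contact rules as a data.frame: reactant and
#' product patterns, the firing probability `p` (all 1 by default, so every
#' reaction happens whenever its reactants meet on a lattice site), and
#' whether the rule is subject to local IL-10 immunosuppression. IL-10 is a
#' potent down-regulator of antigen presentation and pro-inflammatory
#' cytokine release; with suppression enabled the antigen-presentation rules
#' (2, 8) and the IFNg-release rules (5, 14) do not fire at sites holding
#' IL-10 tokens.
#'
#' @param p firing probabilities, length 1 or 15.
#' @param il10_inhibited integer ids of the rules inhibited by local IL-10.
#' @return data.frame of class `mp_rules` with columns `id`, `reactants`,
#'   `products`, `description`, `p`, `il10_inhibited`.
#' @export
rule_table <- function(p = 1, il10_inhibited = c(2L, 5L, 8L, 14L)) {
  p <- rep_len(as.numeric(p), 15L)
  if (any(is.na(p) | p < 0 | p > 1)) stop("rule probabilities must be in [0, 1]")
  if (length(il10_inhibited) && !all(il10_inhibited %in% 1:15))
    stop("il10_inhibited must be rule ids in 1..15")
  out <- .rule_def
  out$p <- p
  out$il10_inhibited <- out$id %in% il10_inhibited
  class(out) <- c("mp_rules", "data.frame")
  out
}

#' Read / write a rule table
#'
#' Human-readable tab-separated serialization of [rule_table()]. The loader
#' accepts edited probabilities and IL-10-inhibition flags but rejects any
#' change to the reactant/product structure of the 15 rules.
#'
#' @param rules an `mp_rules` table.
#' @param path file path.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "mp_rules"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# macpol reaction rules: id, reactants, products, p, il10_inhibited", con)
  writeLines(sprintf("%d\t%s\t%s\t%g\t%d", rules$id, rules$reactants,
                     rules$products, rules$p, as.integer(rules$il10_inhibited)),
             con)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("rule file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (length(f) != 15L || any(lengths(f) != 5L))
    stop("rule file must contain exactly 15 tab-separated rule lines")
  id <- as.integer(vapply(f, `[[`, "", 1L))
  if (!identical(id, 1:15)) stop("rule ids must be 1..15 in order")
  rea <- vapply(f, `[[`, "", 2L)
  pro <- vapply(f, `[[`, "", 3L)
  if (!identical(rea, .rule_def$reactants) || !identical(pro, .rule_def$products))
    stop("structural change to rule reactants/products is not supported; ",
         "edit probabilities or inhibition flags only")
  p <- as.numeric(vapply(f, `[[`, "", 4L))
  inh <- as.integer(vapply(f, `[[`, "", 5L))
  if (any(is.na(p)) || any(is.na(inh) | !inh %in% 0:1))
    stop("malformed probability or inhibition flag")
  rule_table(p = p, il10_inhibited = id[inh == 1L])
}

#' Site contents: the multiset of entities on one lattice site
#'
#' @param agents data.frame with columns `kind` (Macrophage, Bcell, Th1, Th2,
#'   Treg), `activation` (resting, active, presenting), `phenotype` (M0, M1,
#'   M2; macrophages only) and optionally `grn` (packed integer network
#'   state). Zero-row default.
#' @param molecules named integer vector over the species IFNg, IL4, IL10,
#'   Ab, Ag_lps (LPS-bearing antigen), Ag_free; missing species count 0.
#' @return List of class `mp_site`.
#' @export
site_contents <- function(agents = NULL, molecules = integer()) {
  if (is.null(agents))
    agents <- data.frame(kind = character(), activation = character(),
                         phenotype = character(), grn = integer())
  stopifnot(is.data.frame(agents))
  if (is.null(agents$phenotype)) agents$phenotype <- rep("M0", nrow(agents))
  if (is.null(agents$grn)) agents$grn <- rep(0L, nrow(agents))
  if (!all(agents$kind %in% .kind_levels))
    stop("unknown agent kind; expected ", paste(.kind_levels, collapse = ", "))
  if (!all(agents$activation %in% .act_levels))
    stop("unknown activation state")
  if (any(agents$kind == "Bcell" & agents$activation == "resting"))
    stop("B cells have no resting state (only active/presenting)")
  if (!all(agents$phenotype %in% .phen_levels)) stop("unknown phenotype")
  mol <- structure(integer(length(.mol_species)), names = .mol_species)
  if (length(molecules)) {
    unknown <- setdiff(names(molecules), .mol_species)
    if (length(unknown)) stop("unknown molecule species: ",
                              paste(unknown, collapse = ", "))
    mol[names(molecules)] <- as.integer(molecules)
  }
  if (any(mol < 0)) stop("molecule counts must be non-negative")
  structure(list(agents = agents[, c("kind", "activation", "phenotype", "grn")],
                 molecules = mol),
            class = "mp_site")
}

#' Apply the reaction rules to one site
#'
#' Shuffles the 15 rules into a random order, then applies each rule greedily
#' to every disjoint matching reactant set still present, each firing
#' succeeding with probability `p_i`. An entity whose state is changed (or
#' that is consumed) by one firing cannot participate in another rule in the
#' same pass; catalytic participants remain available, but each rule fires at
#' most once per disjoint pair within its own pass. Products are added to the
#' same site.
#'
#' @param site an [site_contents()] object.
#' @param rules an [rule_table()].
#' @return Updated `mp_site`, with attributes `"fires"` (integer firing count
#'   per rule) and `"order"` (the shuffled rule order used).
#' @export
apply_rules_at_site <- function(site, rules = rule_table(),
                                b_cell_presentation = TRUE) {
  stopifnot(inherits(site, "mp_site"), inherits(rules, "mp_rules"))
  ag <- site$agents
  res <- .rules_site_cpp(
    match(ag$kind, .kind_levels),
    match(ag$activation, .act_levels),
    match(ag$phenotype, .phen_levels) - 1L,
    as.integer(ag$grn),
    unname(site$molecules),
    rules$p, rules$il10_inhibited,
    rep(0L, 5L), b_cell_presentation)
  out <- site_contents(
    data.frame(kind = .kind_levels[res$kind],
               activation = .act_levels[res$act],
               phenotype = .phen_levels[res$phen + 1L],
               grn = res$grn),
    structure(res$mol, names = .mol_species))
  if (any(out$molecules < 0)) stop("internal consistency error: negative count")
  attr(out, "fires") <- structure(res$fires, names = paste0("R", 1:15))
  attr(out, "order") <- res$order
  out
}

#' Create a single cell agent
#'
#' @param kind one of Macrophage, Bcell, Th1, Th2, Treg.
#' @param activation resting, active or presenting (B cells: never resting).
#' @param phenotype M0, M1 or M2 (macrophages only).
#' @param grn_state named logical network state (macrophages only); defaults
#'   to the all-zero state.
#' @param net the regulatory network the state is aligned to.
#' @return List of class `mp_agent`.
#' @export
cell_agent <- function(kind, activation = "resting", phenotype = "M0",
                       grn_state = NULL, net = default_network()) {
  kind <- match.arg(kind, .kind_levels)
  activation <- match.arg(activation, .act_levels)
  phenotype <- match.arg(phenotype, .phen_levels)
  if (kind == "Bcell" && activation == "resting")
    stop("B cells have no resting state")
  if (kind != "Macrophage" && phenotype != "M0")
    stop("phenotype applies to macrophages only")
  if (kind == "Macrophage" && is.null(grn_state))
    grn_state <- network_state(net)
  structure(list(kind = kind, activation = activation, phenotype = phenotype,
                 grn_state = grn_state),
            class = "mp_agent")
}

#' Macrophage differentiation update
#'
#' The bridge between the two scales: an undifferentiated (M0), active or
#' presenting macrophage reads its local stimulus vector off the site -- IFNg,
#' IL-10, IL-4 bits from the presence of the respective cytokine tokens, the
#' LPS bit from the presence of LPS-bearing antigen -- clamps its Boolean
#' network to it, applies `k` synchronous updates, and commits to M1 (M2) iff
#' the resulting state is the M1 (M2) attractor for that stimulus. Otherwise
#' it stays M0 and retains the updated network state. Resting or already
#' committed macrophages are untouched: commitment is terminal.
#'
#' @param agent an [cell_agent()] of kind Macrophage.
#' @param site an [site_contents()] providing the local molecule counts.
#' @param net the regulatory network.
#' @param k number of synchronous network updates per step.
#' @return The updated agent.
#' @export
differentiation_update <- function(agent, site, net = default_network(), k = 4) {
  stopifnot(inherits(agent, "mp_agent"))
  if (agent$kind != "Macrophage")
    stop("differentiation_update applies to macrophages only")
  if (agent$phenotype != "M0" || agent$activation == "resting")
    return(agent)
  mol <- site$molecules
  I <- input_vector(IFNg = mol[["IFNg"]] > 0, IL10 = mol[["IL10"]] > 0,
                    IL4 = mol[["IL4"]] > 0, LPS = mol[["Ag_lps"]] > 0)
  new_state <- iterate(agent$grn_state, I, k, net)
  agent$grn_state <- new_state
  lab <- classify(new_state, net)
  if (lab == "M1_committed") agent$phenotype <- "M1"
  else if (lab == "M2_committed") agent$phenotype <- "M2"
  agent
}
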