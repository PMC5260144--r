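# Lattice-level orchestration: configuration, population initialization,
# stepping through the compiled engine, diffusion, census time series and the
# conservation audit.

#' Simulation configuration
#'
#' Collects every tunable of a run. Defaults describe the reference desk-run
#' conditions: a 16^3 periodic lattice carrying 500 macrophages and 2500
#' lymphocytes (the roughly 5:1 lymphocyte:monocyte ratio of a standard human
#' differential white-cell count, helpers split evenly across Th1/Th2/Treg),
#' 800 steps at 8 steps per simulated day (100 days), six Boolean-network
#' updates per step, antigen replication at 0.05 per token per step under a
#' logistic carrying capacity, and a 20-step cytokine/antibody half-life.
#'
#' @param L lattice side length (sites are `L^3`, periodic in all axes).
#' @param n_steps number of simulation steps.
#' @param seed integer seed; fully determines the run.
#' @param cells named counts: `mac`, `b`, `h1`, `h2`, `hr`.
#' @param helper_active_frac fraction of helper T cells initialized in the
#'   active state; the default 0 starts every helper resting. B cells are
#'   always active at start, macrophages resting.
#' @param helper_background_activation per-step probability that a resting
#'   helper cell activates spontaneously (tonic/bystander activation). This
#'   maintains a small standing pool of active helpers; without it, the
#'   deterministic one-step helper deactivation (rule 13 at p = 1) empties
#'   the active pool before any B cell can present antigen and the adaptive
#'   cascade never ignites.
#' @param k Boolean-network updates per lattice step. The default 6 lets a
#'   macrophage reach any pure-stimulus attractor of the bundled network
#'   (all are at depth <= 6 from the naive state) within a single eligible
#'   step of sustained local stimulus.
#' @param steps_per_day time calibration used by injection schedules.
#' @param ag_replication per-token antigen replication probability per step.
#' @param ag_capacity antigen carrying capacity (logistic damping of
#'   replication); 0 disables the cap.
#' @param cell_cap_mult per-kind population cap as a multiple of the initial
#'   count (bounds the B/helper duplication cascade); 0 disables caps.
#' @param half_life cytokine/antibody half-life in steps; `Inf` disables
#'   decay.
#' @param injections data.frame with columns `step`, `species` (`"Ag"`,
#'   `"IFNg"`, `"IL4"`, `"IL10"`, `"Ab"`), `amount`, `has_lps` (used for
#'   `"Ag"` only). Step-0 injections are placed before the initial census.
#' @param rules an [rule_table()]; its probabilities and IL-10 inhibition
#'   flags are passed to the engine.
#' @param il10_suppression logical master switch for the IL-10
#'   immunosuppression mechanism (see [rule_table()]).
#' @param b_cell_presentation if `TRUE` (default), a presenting B cell also
#'   satisfies the presenter slot of the helper-activation rule (rule 12),
#'   alongside presenting macrophages. B cells are professional
#'   antigen-presenting cells; without this the helper pool can only be
#'   activated downstream of IFNg, which itself requires active helpers, and
#'   the adaptive response cannot bootstrap.
#' @param network an `mp_network`; default [default_network()].
#' @return List of class `mp_config`.
#' @export
simulation_config <- function(L = 16L, n_steps = 800L, seed = 1L,
                              cells = c(mac = 500L, b = 625L, h1 = 625L,
                                        h2 = 625L, hr = 625L),
                              helper_active_frac = 0,
                              helper_background_activation = 0.01,
                              k = 6L, steps_per_day = 8L,
                              ag_replication = 0.05, ag_capacity = 40000,
                              cell_cap_mult = 6, half_life = 20,
                              injections = NULL, rules = rule_table(),
                              il10_suppression = TRUE,
                              b_cell_presentation = TRUE, network = NULL) {
  if (is.null(injections))
    injections <- data.frame(step = integer(), species = character(),
                             amount = integer(), has_lps = logical())
  stopifnot(is.data.frame(injections))
  need <- c("step", "species", "amount")
  if (!all(need %in% names(injections)))
    stop("injections need columns step, species, amount")
  if (is.null(injections$has_lps)) injections$has_lps <- FALSE
  if (!all(injections$species %in% c("Ag", "IFNg", "IL4", "IL10", "Ab")))
    stop("unknown injection species")
  cells <- cells[c("mac", "b", "h1", "h2", "hr")]
  if (any(is.na(cells)) || any(cells < 0))
    stop("cells must be named non-negative counts: mac, b, h1, h2, hr")
  if (L < 1 || n_steps < 0 || k < 1) stop("invalid L, n_steps or k")
  if (helper_active_frac < 0 || helper_active_frac > 1)
    stop("helper_active_frac must be in [0, 1]")
  if (helper_background_activation < 0 || helper_background_activation > 1)
    stop("helper_background_activation must be in [0, 1]")
  if (ag_replication < 0 || ag_replication > 1)
    stop("ag_replication must be in [0, 1]")
  if (any(injections$amount < 0) || any(injections$step < 0))
    stop("injection steps and amounts must be non-negative")
  structure(list(
    L = as.integer(L), n_steps = as.integer(n_steps), seed = as.integer(seed),
    cells = vapply(cells, as.integer, 0L),
    helper_active_frac = helper_active_frac,
    helper_background_activation = helper_background_activation,
    k = as.integer(k),
    steps_per_day = as.integer(steps_per_day),
    ag_replication = ag_replication, ag_capacity = ag_capacity,
    cell_cap_mult = cell_cap_mult, half_life = half_life,
    injections = injections, rules = rules,
    il10_suppression = isTRUE(il10_suppression),
    b_cell_presentation = isTRUE(b_cell_presentation), network = network),
    class = "mp_config")
}

.config_network <- function(config) {
  if (is.null(config$network)) default_network() else config$network
}

.injection_matrix <- function(injections, steps = NULL) {
  inj <- injections
  if (!is.null(steps)) inj <- inj[inj$step %in% steps, , drop = FALSE]
  if (!nrow(inj))
    return(matrix(integer(), 0, 3))
  species <- ifelse(inj$species == "Ag",
                    ifelse(inj$has_lps, 5L, 6L),
                    match(inj$species, c("IFNg", "IL4", "IL10", "Ab")))
  cbind(as.integer(inj$step), as.integer(species), as.integer(inj$amount))
}

.engine_args <- function(config) {
  net <- .config_network(config)
  att <- .attractors_for(net)
  tt <- transition_table(net)
  ipos <- match(c("IFNg", "IL10", "IL4", "LPS"), net$nodes)
  if (any(is.na(ipos)))
    stop("engine requires input nodes named IFNg, IL10, IL4, LPS")
  blocked <- config$rules$il10_inhibited & config$il10_suppression
  surv <- if (is.finite(config$half_life)) 0.5^(1 / config$half_life) else 1
  cap <- if (config$cell_cap_mult > 0)
    pmax(1L, as.integer(ceiling(config$cells * config$cell_cap_mult)))
  else rep(0L, 5L)  # 0 = unlimited in the engine
  list(ttable = tt, m1_fp = att$m1_fp, m2_fp = att$m2_fp,
       input_bitpos = ipos - 1L, blocked = blocked, surv = surv, cap = cap)
}

#' Initialize the lattice population
#'
#' Places the configured cells uniformly at random on the `L^3` lattice. All
#' macrophages start undifferentiated (M0), resting, with the all-zero
#' network state; B cells start active; helper cells start resting (a
#' configurable fraction can start active). Step-0 injections are placed
#' before the initial census, so the antigen dose of a challenge scenario is
#' present in the first census row.
#'
#' @param config an [simulation_config()]. The caller controls the RNG;
#'   [simulate_run()] seeds it from `config$seed`.
#' @return Object of class `mp_lattice`: agent table, molecule matrix, step
#'   counter and accumulated census.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "mp_config"))
  n_sites <- config$L^3
  cl <- config$cells
  kind <- rep(1:5, times = cl)
  n <- length(kind)
  act <- integer(n)
  act[kind == 1L] <- 1L                       # macrophages rest
  act[kind == 2L] <- 2L                       # B cells active
  for (kk in 3:5) {
    idx <- which(kind == kk)
    n_act <- round(length(idx) * config$helper_active_frac)
    act[idx] <- 1L
    if (n_act > 0) act[sample(idx, n_act)] <- 2L
  }
  agents <- data.frame(kind = kind, act = act, phen = rep(0L, n),
                       grn = rep(0L, n),
                       site = sample.int(n_sites, n, replace = TRUE) - 1L)
  mol <- matrix(0L, n_sites, 6,
                dimnames = list(NULL, .mol_species))
  inj0 <- .injection_matrix(config$injections, steps = 0L)
  if (nrow(inj0))
    for (j in seq_len(nrow(inj0))) {
      sites <- sample.int(n_sites, inj0[j, 3], replace = TRUE)
      tab <- tabulate(sites, n_sites)
      mol[, inj0[j, 2]] <- mol[, inj0[j, 2]] + tab
    }
  lat <- structure(list(L = config$L, agents = agents, mol = mol, step = 0L,
                        config = config, census = NULL),
                   class = "mp_lattice")
  lat$census <- .census_of(lat)
  lat
}

.census_of <- function(lat) {
  res <- .engine_run_cpp(lat$L, 0L, lat$step, lat$agents$kind, lat$agents$act,
                         lat$agents$phen, lat$agents$grn, lat$agents$site,
                         lat$mol, integer(1), rep(NA_integer_, 16),
                         rep(NA_integer_, 16), 0:3, 1L, rep(1, 15),
                         rep(FALSE, 15), matrix(integer(), 0, 3),
                         0, 0, rep(0L, 5), 1, 0, TRUE, FALSE)
  res$census
}

#' Advance the simulation
#'
#' `sim_step()` runs one full step on a lattice (rules, differentiation,
#' diffusion, injections/decay/replication bookkeeping, census);
#' `simulate_run()` seeds the RNG from `config$seed`, initializes the
#' population and runs `config$n_steps` steps, returning the census time
#' series.
#'
#' @param lat an `mp_lattice`.
#' @param n number of steps to advance.
#' @param record_audit keep the per-step rule-firing/injection/decay log
#'   (attribute `"audit"` of the result) for conservation checks.
#' @return `sim_step()` the advanced `mp_lattice`; `simulate_run()` an
#'   `mp_timeseries` data.frame with one census row per step (including the
#'   initial one).
#' @export
sim_step <- function(lat, n = 1L, record_audit = FALSE) {
  stopifnot(inherits(lat, "mp_lattice"))
  config <- lat$config
  ea <- .engine_args(config)
  res <- .engine_run_cpp(lat$L, as.integer(n), lat$step,
                         lat$agents$kind, lat$agents$act, lat$agents$phen,
                         lat$agents$grn, lat$agents$site, lat$mol,
                         ea$ttable, ea$m1_fp, ea$m2_fp, ea$input_bitpos,
                         config$k, config$rules$p, ea$blocked,
                         .injection_matrix(config$injections),
                         config$ag_replication, config$ag_capacity,
                         ea$cap, ea$surv,
                         config$helper_background_activation,
                         config$b_cell_presentation, record_audit)
  lat$agents <- data.frame(kind = res$kind, act = res$act, phen = res$phen,
                           grn = res$grn, site = res$site)
  lat$mol <- res$mol
  lat$step <- lat$step + as.integer(n)
  lat$census <- rbind(lat$census, res$census[-1, , drop = FALSE])
  if (record_audit) attr(lat, "audit") <- res$audit
  lat
}

#' @rdname sim_step
#' @param config an [simulation_config()].
#' @export
simulate_run <- function(config, record_audit = FALSE) {
  stopifnot(inherits(config, "mp_config"))
  set.seed(config$seed)
  lat <- init_population(config)
  lat <- sim_step(lat, config$n_steps, record_audit = record_audit)
  ts <- as.data.frame(lat$census)
  ts <- cbind(step = 0:config$n_steps, ts)
  class(ts) <- c("mp_timeseries", "data.frame")
  attr(ts, "config") <- config
  if (record_audit) attr(ts, "audit") <- attr(lat, "audit")
  ts
}

#' Move every entity one diffusion step
#'
#' Each agent and each molecule token independently moves to one of its six
#' von Neumann neighbours or stays put, all seven outcomes equiprobable, with
#' periodic wrap-around. Every species uses the identical kernel (equal
#' diffusion speed); total counts are unchanged.
#'
#' @param lat an `mp_lattice`.
#' @return The lattice with updated positions.
#' @export
diffuse <- function(lat) {
  stopifnot(inherits(lat, "mp_lattice"))
  if (nrow(lat$agents))
    lat$agents$site <- .diffuse_sites_cpp(lat$agents$site, lat$L)
  n_sites <- lat$L^3
  for (q in seq_len(ncol(lat$mol))) {
    cnt <- lat$mol[, q]
    nz <- which(cnt > 0L)
    if (!length(nz)) next
    tok <- rep(nz - 1L, cnt[nz])
    moved <- .diffuse_sites_cpp(tok, lat$L)
    lat$mol[, q] <- tabulate(moved + 1L, n_sites)
  }
  lat
}

#' Write a census time series with its run manifest
#'
#' Writes the time series as a tidy CSV (one row per step, stable documented
#' header) and, alongside it, a JSON sidecar with the run manifest: seed,
#' configuration hash, rule-table hash and network hash. Two runs with equal
#' manifests produce equal outputs.
#'
#' @param ts an `mp_timeseries` from [simulate_run()].
#' @param path CSV output path; the manifest goes to `<path>.manifest.json`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "mp_timeseries"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  config <- attr(ts, "config")
  if (!is.null(config)) {
    man <- run_manifest(config)
    jsonlite::write_json(unclass(man), paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Reconcile the census against the audit log
#'
#' Checks, step by step, that every change in the census is attributable to a
#' logged rule firing, spawn, commitment, injection, decay or replication
#' event: macrophage totals constant, M1/M2 totals growing exactly by the
#' logged commitments, B/helper totals growing exactly by the logged
#' duplications, and each molecule species satisfying its bookkeeping
#' identity. Diffusion moves entities but never changes totals.
#'
#' @param ts an `mp_timeseries` produced with `record_audit = TRUE`.
#' @return data.frame of per-step discrepancies (all-zero when the run is
#'   consistent), with attribute `"ok"`.
#' @export
audit_reconcile <- function(ts) {
  au <- attr(ts, "audit")
  if (is.null(au)) stop("time series carries no audit log; rerun with record_audit = TRUE")
  au <- as.data.frame(au)
  x <- as.data.frame(ts)
  tot <- function(cols) rowSums(x[, cols, drop = FALSE])
  d <- function(v) diff(v)
  mac <- tot(c("M0_r", "M0_a", "M0_p", "M1_r", "M1_a", "M1_p",
               "M2_r", "M2_a", "M2_p"))
  disc <- data.frame(
    step = seq_len(nrow(au)),
    mac_total = d(mac),
    m1 = d(tot(c("M1_r", "M1_a", "M1_p"))) - au$commit_M1,
    m2 = d(tot(c("M2_r", "M2_a", "M2_p"))) - au$commit_M2,
    b = d(tot(c("B_a", "B_p"))) - au$spawn_B,
    h1 = d(tot(c("H1_r", "H1_a"))) - au$spawn_H1,
    h2 = d(tot(c("H2_r", "H2_a"))) - au$spawn_H2,
    hr = d(tot(c("Hr_r", "Hr_a"))),
    ifng = d(x$IFNg) - (au$inj_IFNg - au$decay_IFNg - au$fire_R1 +
                          au$fire_R5 + au$fire_R10 + au$fire_R14),
    il4 = d(x$IL4) - (au$inj_IL4 - au$decay_IL4 + au$fire_R6 + au$fire_R11),
    il10 = d(x$IL10) - (au$inj_IL10 - au$decay_IL10 + au$fire_R7),
    ab = d(x$Ab) - (au$inj_Ab - au$decay_Ab + au$fire_R10 + au$fire_R11 -
                      au$fire_R15),
    ag = d(x$Ag_lps + x$Ag_free) - (au$inj_Ag_lps + au$inj_Ag_free + au$ag_repl -
                                      au$fire_R2 - au$fire_R8 - au$fire_R15))
  attr(disc, "ok") <- all(disc[, -1] == 0)
  disc
}

#' @export
print.mp_timeseries <- function(x, ...) {
  n <- nrow(x) - 1L
  fin <- x[nrow(x), ]
  cat(sprintf("Census time series: %d steps on a lattice run\n", n))
  cat(sprintf("  final macrophages: M0=%d  M1=%d  M2=%d\n",
              sum(fin[c("M0_r", "M0_a", "M0_p")]),
              sum(fin[c("M1_r", "M1_a", "M1_p")]),
              sum(fin[c("M2_r", "M2_a", "M2_p")])))
  cat(sprintf("  final antigen: %d (LPS+) + %d (LPS-); antibodies: %d\n",
              fin$Ag_lps, fin$Ag_free, fin$Ab))
  invisible(x)
}

#' @export
plot.mp_timeseries <- function(x, ...) {
  m1 <- rowSums(x[, c("M1_r", "M1_a", "M1_p")])
  m2 <- rowSums(x[, c("M2_r", "M2_a", "M2_p")])
  ag <- x$Ag_lps + x$Ag_free
  graphics::matplot(x$step, cbind(m1, m2, ag), type = "l", lty = 1,
                    col = c("firebrick", "steelblue", "darkgreen"),
                    xlab = "step", ylab = "count", ...)
  graphics::legend("topleft", c("M1", "M2", "antigen"), lty = 1,
                   col = c("firebrick", "steelblue", "darkgreen"), bty = "n")
  invisible(x)
}
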