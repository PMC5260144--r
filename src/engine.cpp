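// Reactive lattice gas engine: agents and molecule tokens on an L x L x L
// periodic lattice. Each step runs (1) the 15 stochastic contact rules per
// site in shuffled order, (2) the Boolean-network differentiation update for
// eligible macrophages, (3) uniform 7-outcome diffusion of every entity,
// (4) antigen replication, molecule decay and scheduled injections, and
// (5) a census row. All randomness comes from R's RNG, so set.seed() fully
// determines a run.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <climits>
using namespace Rcpp;

// agent kinds
static const int MAC = 1, BCELL = 2, TH1 = 3, TH2 = 4, THR = 5;
// activation states
static const int REST = 1, ACT = 2, PRES = 3;
// molecule columns (0-based): IFNg, IL4, IL10, Ab, Ag(LPS+), Ag(LPS-)
static const int M_IFNG = 0, M_IL4 = 1, M_IL10 = 2, M_AB = 3, M_AGL = 4,
                 M_AG0 = 5;
static const int N_SPECIES = 6, N_RULES = 15;

static inline int rand_int(int n) {
  int r = (int)(unif_rand() * n);
  return r >= n ? n - 1 : r;
}

struct World {
  std::vector<int> kind, act, phen, grn, site;
  int cap[6];            // per-kind population cap (index by kind)
  int count[6];          // current per-kind counts
  int n() const { return (int)kind.size(); }
  void spawn(int k, int a, int s) {
    kind.push_back(k); act.push_back(a); phen.push_back(0);
    grn.push_back(0); site.push_back(s);
    count[k]++;
  }
};

struct Audit {
  int fires[N_RULES];
  int spawnB, spawnH1, spawnH2;
  int commitM1, commitM2;
  int inj[N_SPECIES];
  int decay[4];          // IFNg, IL4, IL10, Ab
  int repl;
  int bgact;             // spontaneous (bystander) helper activations
  void reset() { std::memset(this, 0, sizeof(Audit)); }
};

// Apply the 15 rules, in the shuffled order `perm`, to one site. `loc` holds
// the indices of the agents at the site. Only state-changed/consumed agents
// are marked used; catalytic participants stay available to later rules but
// each rule fires at most once per disjoint reactant pair within its pass.
static void process_site(World &w, IntegerMatrix &mol, int s,
                         const std::vector<int> &loc, const int *perm,
                         const double *p, const int *blocked, bool b_presents,
                         Audit &au) {
  const int m = (int)loc.size();
  std::vector<char> used(m, 0);

  // consume one antigen token, LPS-bearing first; returns false if none left
  auto eat_ag = [&]() -> bool {
    if (mol(s, M_AGL) > 0) { mol(s, M_AGL)--; return true; }
    if (mol(s, M_AG0) > 0) { mol(s, M_AG0)--; return true; }
    return false;
  };
  auto attempt = [&](int r) -> bool {
    return p[r] >= 1.0 || unif_rand() < p[r];
  };

  for (int ri = 0; ri < N_RULES; ri++) {
    const int r = perm[ri];               // 0-based rule index
    if (blocked[r] && mol(s, M_IL10) > 0) continue;  // IL-10 immunosuppression
    switch (r) {
    case 0:  // R1: M^r + IFNg -> M^a (cytokine consumed)
      for (int j = 0; j < m && mol(s, M_IFNG) > 0; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] != MAC || w.act[a] != REST) continue;
        if (attempt(r)) {
          mol(s, M_IFNG)--; w.act[a] = ACT; used[j] = 1; au.fires[r]++;
        }
      }
      break;
    case 1:  // R2: M^a + Ag -> M^p (phagocytosis; antigen consumed)
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] != MAC || w.act[a] != ACT) continue;
        if (mol(s, M_AGL) + mol(s, M_AG0) == 0) break;
        if (attempt(r)) {
          eat_ag(); w.act[a] = PRES; used[j] = 1; au.fires[r]++;
        }
      }
      break;
    case 2:  // R3: M^p -> M^a
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] != MAC || w.act[a] != PRES) continue;
        if (attempt(r)) { w.act[a] = ACT; used[j] = 1; au.fires[r]++; }
      }
      break;
    case 3:  // R4: M^a -> M^r
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] != MAC || w.act[a] != ACT) continue;
        if (attempt(r)) { w.act[a] = REST; used[j] = 1; au.fires[r]++; }
      }
      break;
    case 4: case 5: case 6: {  // R5/R6/R7: M^p + H^a -> ... + cytokine
      int hk = (r == 4) ? TH1 : (r == 5) ? TH2 : THR;
      int prod = (r == 4) ? M_IFNG : (r == 5) ? M_IL4 : M_IL10;
      int nmac = 0, nh = 0;
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j]) continue;
        if (w.kind[a] == MAC && w.act[a] == PRES &&
            (r != 6 || w.phen[a] == 2)) nmac++;   // R7 needs an M2 macrophage
        if (w.kind[a] == hk && w.act[a] == ACT) nh++;
      }
      int npair = nmac < nh ? nmac : nh;
      for (int q = 0; q < npair; q++)
        if (attempt(r)) { mol(s, prod)++; au.fires[r]++; }
      break;
    }
    case 7:  // R8: B^a + Ag -> B^p
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] != BCELL || w.act[a] != ACT) continue;
        if (mol(s, M_AGL) + mol(s, M_AG0) == 0) break;
        if (attempt(r)) {
          eat_ag(); w.act[a] = PRES; used[j] = 1; au.fires[r]++;
        }
      }
      break;
    case 8:  // R9: B^p -> B^a
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] != BCELL || w.act[a] != PRES) continue;
        if (attempt(r)) { w.act[a] = ACT; used[j] = 1; au.fires[r]++; }
      }
      break;
    case 9: case 10: {  // R10/R11: B^p + H^a -> 2B^p + 2H^a + cytokine + Ab
      int hk = (r == 9) ? TH1 : TH2;
      int prod = (r == 9) ? M_IFNG : M_IL4;
      std::vector<int> bs, hs;
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j]) continue;
        if (w.kind[a] == BCELL && w.act[a] == PRES) bs.push_back(j);
        else if (w.kind[a] == hk && w.act[a] == ACT) hs.push_back(j);
      }
      int npair = (int)(bs.size() < hs.size() ? bs.size() : hs.size());
      for (int q = 0; q < npair; q++) {
        if (!attempt(r)) continue;
        used[bs[q]] = 1; used[hs[q]] = 1;
        mol(s, prod)++; mol(s, M_AB)++;
        au.fires[r]++;
        if (w.count[BCELL] < w.cap[BCELL]) {
          w.spawn(BCELL, PRES, s); au.spawnB++;
        }
        if (w.count[hk] < w.cap[hk]) {
          w.spawn(hk, ACT, s);
          if (hk == TH1) au.spawnH1++; else au.spawnH2++;
        }
      }
      break;
    }
    case 11: {  // R12: H^r + APC^p -> H^a + APC^p (all helper classes; the
                // presenter is a presenting macrophage or, if enabled, a
                // presenting B cell)
      bool pres = false;
      for (int j = 0; j < m && !pres; j++) {
        int a = loc[j];
        if (!used[j] && w.act[a] == PRES &&
            (w.kind[a] == MAC || (b_presents && w.kind[a] == BCELL)))
          pres = true;
      }
      if (!pres) break;
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] < TH1 || w.act[a] != REST) continue;
        if (attempt(r)) { w.act[a] = ACT; used[j] = 1; au.fires[r]++; }
      }
      break;
    }
    case 12:  // R13: H^a -> H^r
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j] || w.kind[a] < TH1 || w.act[a] != ACT) continue;
        if (attempt(r)) { w.act[a] = REST; used[j] = 1; au.fires[r]++; }
      }
      break;
    case 13: {  // R14: H1^a + B^p -> H1^a + B^p + IFNg
      int nh = 0, nb = 0;
      for (int j = 0; j < m; j++) {
        int a = loc[j];
        if (used[j]) continue;
        if (w.kind[a] == TH1 && w.act[a] == ACT) nh++;
        else if (w.kind[a] == BCELL && w.act[a] == PRES) nb++;
      }
      int npair = nh < nb ? nh : nb;
      for (int q = 0; q < npair; q++)
        if (attempt(r)) { mol(s, M_IFNG)++; au.fires[r]++; }
      break;
    }
    case 14: {  // R15: Ab + Ag -> 0 (neutralisation)
      int n15 = std::min(mol(s, M_AB), mol(s, M_AGL) + mol(s, M_AG0));
      for (int q = 0; q < n15; q++) {
        if (!attempt(r)) continue;
        mol(s, M_AB)--; eat_ag(); au.fires[r]++;
      }
      break;
    }
    }
  }
}

static void shuffle(int *v, int n) {
  for (int i = n - 1; i > 0; i--) {
    int j = rand_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// census layout (23 columns)
static const char *CENSUS_COLS[23] = {
  "M0_r", "M0_a", "M0_p", "M1_r", "M1_a", "M1_p", "M2_r", "M2_a", "M2_p",
  "B_a", "B_p", "H1_r", "H1_a", "H2_r", "H2_a", "Hr_r", "Hr_a",
  "IFNg", "IL4", "IL10", "Ab", "Ag_lps", "Ag_free"};

static void census_row(const World &w, const IntegerMatrix &mol,
                       IntegerMatrix &out, int row) {
  int c[23] = {0};
  for (int i = 0; i < w.n(); i++) {
    int k = w.kind[i], a = w.act[i];
    if (k == MAC)       c[w.phen[i] * 3 + (a - 1)]++;
    else if (k == BCELL) c[9 + (a - 2)]++;
    else                 c[11 + (k - TH1) * 2 + (a == ACT ? 1 : 0)]++;
  }
  for (int s = 0; s < mol.nrow(); s++)
    for (int q = 0; q < N_SPECIES; q++) c[17 + q] += mol(s, q);
  for (int q = 0; q < 23; q++) out(row, q) = c[q];
}

// [[Rcpp::export(name = ".engine_run_cpp")]]
List engine_run_cpp(int L, int n_steps, int step_offset,
                    IntegerVector kind0, IntegerVector act0,
                    IntegerVector phen0, IntegerVector grn0,
                    IntegerVector site0, IntegerMatrix mol0,
                    IntegerVector ttable, IntegerVector m1_fp,
                    IntegerVector m2_fp, IntegerVector input_bitpos,
                    int k_grn, NumericVector p_rules,
                    LogicalVector il10_blocked, IntegerMatrix injections,
                    double ag_rep_p, double ag_capacity,
                    IntegerVector cell_cap, double decay_survival,
                    double bg_activation, bool b_presents,
                    bool record_audit) {
  const int n_sites = L * L * L;
  if (mol0.nrow() != n_sites || mol0.ncol() != N_SPECIES)
    stop("molecule matrix must be n_sites x 6");

  World w;
  w.kind = as<std::vector<int>>(kind0);
  w.act = as<std::vector<int>>(act0);
  w.phen = as<std::vector<int>>(phen0);
  w.grn = as<std::vector<int>>(grn0);
  w.site = as<std::vector<int>>(site0);   // 0-based site indices
  for (int k = 0; k < 6; k++) { w.cap[k] = 0; w.count[k] = 0; }
  for (int k = 1; k <= 5; k++)
    w.cap[k] = cell_cap[k - 1] <= 0 ? INT_MAX : cell_cap[k - 1];
  for (int i = 0; i < w.n(); i++) {
    if (w.site[i] < 0 || w.site[i] >= n_sites) stop("agent site out of range");
    w.count[w.kind[i]]++;
  }

  IntegerMatrix mol = clone(mol0);
  IntegerMatrix census(n_steps + 1, 23);
  census_row(w, mol, census, 0);

  const int n_audit_cols = N_RULES + 3 + 2 + N_SPECIES + 4 + 2;
  IntegerMatrix audit(record_audit ? n_steps : 0, n_audit_cols);

  // input clamping masks for the GRN state
  int imask = 0, ibit[4];
  for (int q = 0; q < 4; q++) {
    ibit[q] = 1 << input_bitpos[q];
    imask |= ibit[q];
  }
  double p[N_RULES];
  int blocked[N_RULES];
  for (int r = 0; r < N_RULES; r++) {
    p[r] = p_rules[r];
    blocked[r] = il10_blocked[r] ? 1 : 0;
  }

  RNGScope rng;
  std::vector<int> head(n_sites), order;
  std::vector<int> loc;
  int perm[N_RULES];
  Audit au;

  for (int step = 1; step <= n_steps; step++) {
    au.reset();
    const int global_step = step_offset + step;

    // ---- phase 0: tonic bystander activation of resting helper cells ----
    if (bg_activation > 0)
      for (int i = 0; i < w.n(); i++)
        if (w.kind[i] >= TH1 && w.act[i] == REST &&
            unif_rand() < bg_activation) {
          w.act[i] = ACT; au.bgact++;
        }

    // ---- phase 1: contact rules at every occupied site, shuffled order ----
    std::fill(head.begin(), head.end(), -1);
    std::vector<int> nxt(w.n());
    for (int i = 0; i < w.n(); i++) {
      nxt[i] = head[w.site[i]];
      head[w.site[i]] = i;
    }
    order.clear();
    for (int s = 0; s < n_sites; s++)
      if (head[s] >= 0 || (mol(s, M_AB) > 0 &&
                           mol(s, M_AGL) + mol(s, M_AG0) > 0))
        order.push_back(s);
    shuffle(order.data(), (int)order.size());
    for (size_t oi = 0; oi < order.size(); oi++) {
      int s = order[oi];
      loc.clear();
      for (int i = head[s]; i >= 0; i = nxt[i]) loc.push_back(i);
      for (int r = 0; r < N_RULES; r++) perm[r] = r;
      shuffle(perm, N_RULES);
      process_site(w, mol, s, loc, perm, p, blocked, b_presents, au);
    }

    // ---- phase 2: differentiation of eligible undifferentiated macrophages
    for (int i = 0; i < w.n(); i++) {
      if (w.kind[i] != MAC || w.phen[i] != 0) continue;
      if (w.act[i] != ACT && w.act[i] != PRES) continue;
      int s = w.site[i];
      int icode = (mol(s, M_IFNG) > 0 ? 1 : 0) | (mol(s, M_IL10) > 0 ? 2 : 0) |
                  (mol(s, M_IL4) > 0 ? 4 : 0) | (mol(s, M_AGL) > 0 ? 8 : 0);
      int x = w.grn[i] & ~imask;
      if (icode & 1) x |= ibit[0];
      if (icode & 2) x |= ibit[1];
      if (icode & 4) x |= ibit[2];
      if (icode & 8) x |= ibit[3];
      for (int q = 0; q < k_grn; q++) x = ttable[x];
      w.grn[i] = x;
      if (m1_fp[icode] != NA_INTEGER && x == m1_fp[icode]) {
        w.phen[i] = 1; au.commitM1++;
      } else if (m2_fp[icode] != NA_INTEGER && x == m2_fp[icode]) {
        w.phen[i] = 2; au.commitM2++;
      }
    }

    // ---- phase 3: diffusion (self + 6 von Neumann neighbours, uniform) ----
    const int L2 = L * L;
    auto move7 = [&](int s) -> int {
      int d = rand_int(7);
      if (d == 6) return s;
      int x = s % L, y = (s / L) % L, z = s / L2;
      switch (d) {
      case 0: x = (x + 1) % L; break;
      case 1: x = (x + L - 1) % L; break;
      case 2: y = (y + 1) % L; break;
      case 3: y = (y + L - 1) % L; break;
      case 4: z = (z + 1) % L; break;
      default: z = (z + L - 1) % L; break;
      }
      return x + L * y + L2 * z;
    };
    for (int i = 0; i < w.n(); i++) w.site[i] = move7(w.site[i]);
    {
      IntegerMatrix nm(n_sites, N_SPECIES);
      for (int s = 0; s < n_sites; s++)
        for (int q = 0; q < N_SPECIES; q++) {
          int c = mol(s, q);
          for (int t = 0; t < c; t++) nm(move7(s), q)++;
        }
      mol = nm;
    }

    // ---- phase 4: antigen replication, molecule decay, injections ----
    if (ag_rep_p > 0) {
      double tot = 0;
      for (int s = 0; s < n_sites; s++) tot += mol(s, M_AGL) + mol(s, M_AG0);
      double f = ag_capacity > 0 ? 1.0 - tot / ag_capacity : 1.0;
      if (f > 0) {
        double pe = ag_rep_p * f;
        for (int s = 0; s < n_sites; s++)
          for (int q = M_AGL; q <= M_AG0; q++)
            if (mol(s, q) > 0) {
              int b = (int)R::rbinom(mol(s, q), pe);
              mol(s, q) += b; au.repl += b;
            }
      }
    }
    if (decay_survival < 1.0) {
      for (int s = 0; s < n_sites; s++)
        for (int q = 0; q <= M_AB; q++)   // cytokines and antibodies decay
          if (mol(s, q) > 0) {
            int keep = (int)R::rbinom(mol(s, q), decay_survival);
            au.decay[q] += mol(s, q) - keep;
            mol(s, q) = keep;
          }
    }
    for (int j = 0; j < injections.nrow(); j++) {
      if (injections(j, 0) != global_step) continue;
      int species = injections(j, 1) - 1;  // 1..6 -> 0..5
      int amount = injections(j, 2);
      if (species < 0 || species >= N_SPECIES) stop("bad injection species");
      for (int t = 0; t < amount; t++) mol(rand_int(n_sites), species)++;
      au.inj[species] += amount;
    }

    // ---- phase 5: census ----
    census_row(w, mol, census, step);
    for (int q = 0; q < 23; q++)
      if (census(step, q) < 0) stop("negative census count");

    if (record_audit) {
      int col = 0;
      for (int r = 0; r < N_RULES; r++) audit(step - 1, col++) = au.fires[r];
      audit(step - 1, col++) = au.spawnB;
      audit(step - 1, col++) = au.spawnH1;
      audit(step - 1, col++) = au.spawnH2;
      audit(step - 1, col++) = au.commitM1;
      audit(step - 1, col++) = au.commitM2;
      for (int q = 0; q < N_SPECIES; q++) audit(step - 1, col++) = au.inj[q];
      for (int q = 0; q < 4; q++) audit(step - 1, col++) = au.decay[q];
      audit(step - 1, col++) = au.repl;
      audit(step - 1, col++) = au.bgact;
    }
  }

  colnames(census) = CharacterVector(CENSUS_COLS, CENSUS_COLS + 23);
  List out = List::create(
    _["census"] = census,
    _["kind"] = wrap(w.kind), _["act"] = wrap(w.act),
    _["phen"] = wrap(w.phen), _["grn"] = wrap(w.grn),
    _["site"] = wrap(w.site), _["mol"] = mol);
  if (record_audit) {
    CharacterVector ac(n_audit_cols);
    int col = 0;
    for (int r = 0; r < N_RULES; r++)
      ac[col++] = "fire_R" + std::to_string(r + 1);
    ac[col++] = "spawn_B"; ac[col++] = "spawn_H1"; ac[col++] = "spawn_H2";
    ac[col++] = "commit_M1"; ac[col++] = "commit_M2";
    const char *sp[6] = {"IFNg", "IL4", "IL10", "Ab", "Ag_lps", "Ag_free"};
    for (int q = 0; q < N_SPECIES; q++)
      ac[col++] = std::string("inj_") + sp[q];
    for (int q = 0; q < 4; q++)
      ac[col++] = std::string("decay_") + sp[q];
    ac[col++] = "ag_repl";
    ac[col++] = "bg_activation";
    colnames(audit) = ac;
    out["audit"] = audit;
  }
  return out;
}

// Single-site rule pass used by apply_rules_at_site(): applies the 15 rules
// in a freshly shuffled order to one site's contents.
// [[Rcpp::export(name = ".rules_site_cpp")]]
List rules_site_cpp(IntegerVector kind0, IntegerVector act0,
                    IntegerVector phen0, IntegerVector grn0,
                    IntegerVector molrow, NumericVector p_rules,
                    LogicalVector il10_blocked, IntegerVector cell_cap,
                    bool b_presents) {
  World w;
  int n0 = kind0.size();
  w.kind = as<std::vector<int>>(kind0);
  w.act = as<std::vector<int>>(act0);
  w.phen = as<std::vector<int>>(phen0);
  w.grn = as<std::vector<int>>(grn0);
  w.site.assign(n0, 0);
  for (int k = 0; k < 6; k++) { w.cap[k] = INT_MAX; w.count[k] = 0; }
  for (int k = 1; k <= 5; k++)
    if (cell_cap[k - 1] > 0) w.cap[k] = cell_cap[k - 1];
  for (int i = 0; i < n0; i++) w.count[w.kind[i]]++;
  IntegerMatrix mol(1, N_SPECIES);
  for (int q = 0; q < N_SPECIES; q++) mol(0, q) = molrow[q];

  double p[N_RULES];
  int blocked[N_RULES];
  for (int r = 0; r < N_RULES; r++) {
    p[r] = p_rules[r];
    blocked[r] = il10_blocked[r] ? 1 : 0;
  }
  RNGScope rng;
  int perm[N_RULES];
  for (int r = 0; r < N_RULES; r++) perm[r] = r;
  shuffle(perm, N_RULES);
  std::vector<int> loc(n0);
  for (int i = 0; i < n0; i++) loc[i] = i;
  Audit au;
  au.reset();
  process_site(w, mol, 0, loc, perm, p, blocked, b_presents, au);

  IntegerVector fires(N_RULES);
  for (int r = 0; r < N_RULES; r++) fires[r] = au.fires[r];
  IntegerVector mout(N_SPECIES);
  for (int q = 0; q < N_SPECIES; q++) mout[q] = mol(0, q);
  return List::create(
    _["kind"] = wrap(w.kind), _["act"] = wrap(w.act),
    _["phen"] = wrap(w.phen), _["grn"] = wrap(w.grn),
    _["mol"] = mout, _["fires"] = fires,
    _["order"] = IntegerVector(perm, perm + N_RULES) + 1);
}

// [[Rcpp::export(name = ".diffuse_sites_cpp")]]
IntegerVector diffuse_sites_cpp(IntegerVector sites, int L) {
  RNGScope rng;
  const int L2 = L * L;
  IntegerVector out(sites.size());
  for (int i = 0; i < sites.size(); i++) {
    int s = sites[i];
    if (s < 0 || s >= L * L2) stop("site index out of range");
    int d = rand_int(7);
    if (d == 6) { out[i] = s; continue; }
    int x = s % L, y = (s / L) % L, z = s / L2;
    switch (d) {
    case 0: x = (x + 1) % L; break;
    case 1: x = (x + L - 1) % L; break;
    case 2: y = (y + 1) % L; break;
    case 3: y = (y + L - 1) % L; break;
    case 4: z = (z + 1) % L; break;
    default: z = (z + L - 1) % L; break;
    }
    out[i] = x + L * y + L2 * z;
  }
  return out;
}
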