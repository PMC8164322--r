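// MCMC sampler for the multi-population isolation-with-migration coalescent
// with JC69 likelihood on unphased diploid genotypes (per-site analytic
// phasing summation), per-locus rate multipliers, and migration bands.
//
// Conventions:
//  * time (tau units) runs backward from the present (0) in expected
//    substitutions per site; populations are indexed 0..npop-1, leaves
//    first; population p exists on [tau[p], tau[parent[p]]).
//  * a migration band (src -> tgt, rate M) moves forward-in-time migrants
//    src -> tgt; backward in time, lineages resident in tgt jump to src at
//    rate M while both populations coexist.
//  * genealogy nodes: tips 0..ntips-1 (tips 2i, 2i+1 are the two alleles of
//    diploid i), internal nodes ntips..2*ntips-2; migs[v] holds the
//    migration events on the edge above v, sorted by time.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static const double TINF = std::numeric_limits<double>::infinity();

struct Model {
  int npop, nleaf, nband;
  std::vector<int> parent;      // -1 at root population
  std::vector<double> tau;      // 0 for leaves
  std::vector<double> theta;
  std::vector<int> bsrc, btgt;
  std::vector<double> brate;

  double pop_end(int p) const {
    return parent[p] < 0 ? TINF : tau[parent[p]];
  }
  void band_window(int j, double &lo, double &hi) const {
    lo = std::max(tau[bsrc[j]], tau[btgt[j]]);
    hi = std::min(pop_end(bsrc[j]), pop_end(btgt[j]));
  }
  int band_index(int above, int below) const {  // backward jump below->above
    for (int j = 0; j < nband; ++j)
      if (bsrc[j] == above && btgt[j] == below) return j;
    return -1;
  }
};

static Model model_from_list(const List &m) {
  Model M;
  M.npop = as<int>(m["npop"]);
  M.nleaf = as<int>(m["n_leaf"]);
  M.parent = as<std::vector<int>>(m["parent"]);
  M.tau = as<std::vector<double>>(m["tau"]);
  M.theta = as<std::vector<double>>(m["theta"]);
  M.bsrc = as<std::vector<int>>(m["band_src"]);
  M.btgt = as<std::vector<int>>(m["band_tgt"]);
  M.brate = as<std::vector<double>>(m["band_rate"]);
  M.nband = (int)M.brate.size();
  return M;
}

struct MigEvent { double t; int above; };

struct Gen {
  int ntips;
  std::vector<int> par, ch1, ch2;   // -1 where absent
  std::vector<double> age;
  std::vector<int> pop;             // population at the node's own time
  std::vector<std::vector<MigEvent>> migs;
  int root;
  int nnode() const { return 2 * ntips - 1; }
};

static Gen gen_from_list(const List &g) {
  Gen G;
  G.ntips = as<int>(g["ntips"]);
  G.par = as<std::vector<int>>(g["par"]);
  G.ch1 = as<std::vector<int>>(g["ch1"]);
  G.ch2 = as<std::vector<int>>(g["ch2"]);
  G.age = as<std::vector<double>>(g["age"]);
  G.pop = as<std::vector<int>>(g["pop"]);
  G.root = as<int>(g["root"]);
  G.migs.assign(G.nnode(), {});
  IntegerVector mn = g["mig_node"];
  NumericVector mt = g["mig_time"];
  IntegerVector ma = g["mig_above"];
  for (int k = 0; k < mn.size(); ++k)
    G.migs[mn[k]].push_back({mt[k], ma[k]});
  for (auto &v : G.migs)
    std::sort(v.begin(), v.end(),
              [](const MigEvent &a, const MigEvent &b) { return a.t < b.t; });
  return G;
}

// ---------- genealogy sufficient statistics / density ----------

struct Seg { double t0, t1; int pop, node; };

struct Stats {
  std::vector<double> A;  // per pop: integral of k(k-1) dt
  std::vector<int> C;     // per pop: coalescence count
  std::vector<double> L;  // per band: integral of k_tgt dt over window
  std::vector<int> E;     // per band: migration event count
  void init(const Model &M) {
    A.assign(M.npop, 0.0); C.assign(M.npop, 0);
    L.assign(M.nband, 0.0); E.assign(M.nband, 0);
  }
};

// Decompose the edge above v on [age[v], top] into population segments,
// validating funnels and migration events (each must match a live band).
// Returns final population, or -1 on inconsistency.
static int decompose_edge(const Gen &g, const Model &M, int v, double top,
                          std::vector<Seg> *out, Stats *S) {
  double t = g.age[v];
  int p = g.pop[v];
  if (t < M.tau[p] - 1e-12 || t > M.pop_end(p) + 1e-12) return -1;
  for (const MigEvent &e : g.migs[v]) {
    if (e.t < t - 1e-12 || e.t > top + 1e-12) return -1;
    while (M.pop_end(p) <= e.t && M.parent[p] >= 0) {
      double b = M.pop_end(p);
      if (out && b > t) out->push_back({t, b, p, v});
      t = b; p = M.parent[p];
    }
    int j = M.band_index(e.above, p);
    if (j < 0) return -1;
    double lo, hi; M.band_window(j, lo, hi);
    if (e.t < lo - 1e-12 || e.t > hi + 1e-12) return -1;
    if (out && e.t > t) out->push_back({t, e.t, p, v});
    if (S) S->E[j]++;
    t = e.t; p = e.above;
  }
  while (M.pop_end(p) < top && M.parent[p] >= 0) {
    double b = M.pop_end(p);
    if (out && b > t) out->push_back({t, b, p, v});
    t = b; p = M.parent[p];
  }
  if (top > M.pop_end(p) + 1e-12) return -1;
  if (out && top > t) out->push_back({t, top, p, v});
  return p;
}

// population of the lineage of edge-above-v at time t (no validation)
static int pop_at(const Gen &g, const Model &M, int v, double t) {
  double cur = g.age[v];
  int p = g.pop[v];
  for (const MigEvent &e : g.migs[v]) {
    if (e.t > t) break;
    while (M.pop_end(p) <= e.t && M.parent[p] >= 0) p = M.parent[p];
    p = e.above; cur = e.t;
  }
  while (M.pop_end(p) <= t && M.parent[p] >= 0) p = M.parent[p];
  (void)cur;
  return p;
}

// full-gen segment decomposition; false on inconsistency
static bool gen_segments(const Gen &g, const Model &M, std::vector<Seg> &segs,
                         Stats *S) {
  segs.clear();
  for (int u = g.ntips; u < g.nnode(); ++u) {
    if (g.ch1[u] < 0) continue;  // unused slot (never happens in full gen)
    double a = g.age[u];
    if (a < M.tau[g.pop[u]] - 1e-12 || a > M.pop_end(g.pop[u]) + 1e-12)
      return false;
    int f1 = decompose_edge(g, M, g.ch1[u], a, &segs, S);
    int f2 = decompose_edge(g, M, g.ch2[u], a, &segs, S);
    if (f1 != g.pop[u] || f2 != g.pop[u]) return false;
    if (S) S->C[g.pop[u]]++;
  }
  return true;
}

// sufficient statistics by time sweep over segment boundaries
static bool gen_stats(const Gen &g, const Model &M, Stats &S) {
  S.init(M);
  std::vector<Seg> segs;
  if (!gen_segments(g, M, segs, &S)) { return false; }
  // breakpoints: all segment boundaries plus band windows
  std::vector<double> bp;
  bp.reserve(2 * segs.size() + 2 * M.nband);
  for (const Seg &s : segs) { bp.push_back(s.t0); bp.push_back(s.t1); }
  double tmax = g.age[g.root];
  for (int j = 0; j < M.nband; ++j) {
    double lo, hi; M.band_window(j, lo, hi);
    if (lo < tmax) bp.push_back(lo);
    if (hi < tmax) bp.push_back(hi);
  }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::abs(a - b) < 1e-15; }),
           bp.end());
  std::vector<int> k(M.npop, 0);
  for (size_t i = 0; i + 1 < bp.size(); ++i) {
    double a = bp[i], b = bp[i + 1], mid = 0.5 * (a + b), dt = b - a;
    if (dt <= 0) continue;
    std::fill(k.begin(), k.end(), 0);
    for (const Seg &s : segs)
      if (s.t0 <= mid && mid < s.t1) k[s.pop]++;
    for (int p = 0; p < M.npop; ++p)
      if (k[p] > 1) S.A[p] += (double)k[p] * (k[p] - 1) * dt;
    for (int j = 0; j < M.nband; ++j) {
      double lo, hi; M.band_window(j, lo, hi);
      if (lo <= mid && mid < hi) S.L[j] += k[M.btgt[j]] * dt;
    }
  }
  return true;
}

static double stats_logdens(const Stats &S, const Model &M) {
  double ld = 0.0;
  for (int p = 0; p < M.npop; ++p)
    ld += S.C[p] * std::log(2.0 / M.theta[p]) - S.A[p] / M.theta[p];
  for (int j = 0; j < M.nband; ++j) {
    if (S.E[j] > 0) ld += S.E[j] * std::log(M.brate[j]);
    ld -= M.brate[j] * S.L[j];
  }
  return ld;
}

// ---------- JC69 likelihood with per-site phasing summation ----------

struct LocusData {
  int ndip;
  int nsites;
  std::vector<double> wt;             // pattern weights
  std::vector<std::vector<int>> pat;  // pattern -> genotype code per diploid
};

// genotype code: -1 missing; else 4*a+b with a<=b (bases 0..3)
static LocusData build_locus_data(const IntegerMatrix &geno) {
  LocusData D;
  D.ndip = geno.nrow();
  D.nsites = geno.ncol();
  std::map<std::vector<int>, int> seen;
  for (int s = 0; s < geno.ncol(); ++s) {
    std::vector<int> col(D.ndip);
    for (int i = 0; i < D.ndip; ++i) col[i] = geno(i, s);
    auto it = seen.find(col);
    if (it == seen.end()) {
      seen[col] = (int)D.pat.size();
      D.pat.push_back(col);
      D.wt.push_back(1.0);
    } else D.wt[it->second] += 1.0;
  }
  return D;
}

static double locus_loglik(const Gen &g, const LocusData &D, double rl) {
  int nn = g.nnode();
  // postorder: nodes by increasing age (children strictly younger)
  std::vector<int> ord(nn);
  for (int i = 0; i < nn; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (g.age[a] != g.age[b]) return g.age[a] < g.age[b];
    return a < b;
  });
  std::vector<double> ps(nn, 1.0), pd(nn, 0.0);
  for (int v = 0; v < nn; ++v) {
    if (g.par[v] < 0) continue;
    double d = rl * (g.age[g.par[v]] - g.age[v]);
    double e = std::exp(-4.0 * d / 3.0);
    ps[v] = 0.25 + 0.75 * e;
    pd[v] = 0.25 - 0.25 * e;
  }
  std::vector<std::array<double, 4>> part(nn);
  double ll = 0.0;
  for (size_t ip = 0; ip < D.pat.size(); ++ip) {
    const std::vector<int> &col = D.pat[ip];
    std::vector<int> hets;
    for (int i = 0; i < D.ndip; ++i) {
      int c = col[i];
      if (c >= 0 && (c / 4) != (c % 4)) hets.push_back(i);
    }
    int h = (int)hets.size();
    if (h > 20) stop("more than 20 heterozygous samples at one site");
    double site = 0.0;
    for (long mask = 0; mask < (1L << h); ++mask) {
      for (int i = 0; i < D.ndip; ++i) {
        int c = col[i];
        int t1 = 2 * i, t2 = 2 * i + 1;
        if (c < 0) {
          part[t1].fill(1.0); part[t2].fill(1.0);
        } else {
          int a = c / 4, b = c % 4;
          if (a != b) {
            int k = (int)(std::find(hets.begin(), hets.end(), i) - hets.begin());
            if ((mask >> k) & 1) std::swap(a, b);
          }
          part[t1].fill(0.0); part[t1][a] = 1.0;
          part[t2].fill(0.0); part[t2][b] = 1.0;
        }
      }
      for (int oi = 0; oi < nn; ++oi) {
        int u = ord[oi];
        if (g.ch1[u] < 0) continue;
        for (int x = 0; x < 4; ++x) part[u][x] = 1.0;
        for (int c : {g.ch1[u], g.ch2[u]}) {
          double sum = part[c][0] + part[c][1] + part[c][2] + part[c][3];
          for (int x = 0; x < 4; ++x)
            part[u][x] *= (ps[c] - pd[c]) * part[c][x] + pd[c] * sum;
        }
      }
      const std::array<double, 4> &r = part[g.root];
      site += 0.25 * (r[0] + r[1] + r[2] + r[3]);
    }
    if (!(site > 0.0)) return -TINF;
    ll += D.wt[ip] * std::log(site);
  }
  return ll;
}

// ---------- exported diagnostics ----------

// [[Rcpp::export]]
List gen_density_cpp(List gen, List model) {
  Gen g = gen_from_list(gen);
  Model M = model_from_list(model);
  Stats S;
  bool ok = gen_stats(g, M, S);
  double ld = ok ? stats_logdens(S, M) : NA_REAL;
  return List::create(_["valid"] = ok, _["log_density"] = ld,
                      _["C"] = S.C, _["A"] = S.A, _["E"] = S.E, _["L"] = S.L);
}

// [[Rcpp::export]]
double locus_loglik_cpp(List gen, IntegerMatrix geno, double r_l) {
  Gen g = gen_from_list(gen);
  if (2 * geno.nrow() != g.ntips)
    stop("genotype rows must be ntips/2 diploids");
  LocusData D = build_locus_data(geno);
  return locus_loglik(g, D, r_l);
}

// ---------- the sampler ----------

struct Priors {
  std::vector<double> th_a, th_b;   // per pop
  std::vector<double> tau_a, tau_b; // per pop (internal used)
  std::vector<double> m_a, m_b;     // per band
  double rate_alpha;                // Gamma(alpha, alpha) on r_l
};

static double dgamma_log(double x, double a, double b) {
  // shape a, rate b
  return a * std::log(b) - R::lgammafn(a) + (a - 1.0) * std::log(x) - b * x;
}

struct Sampler {
  Model M;
  Priors P;
  std::vector<Gen> gens;
  std::vector<LocusData> data;
  std::vector<double> rl;
  std::vector<Stats> stats;
  std::vector<double> ll;
  bool variable_rates;
  int nloci;

  // step sizes (finetuned)
  double st_slide = 0.005, st_theta = 0.5, st_tau = 0.002, st_m = 0.8,
         st_mix = 0.2, st_rl = 0.4;
  // regraft paths propose migration at >= this rate regardless of the
  // current M (Hastings-corrected), so events can be born at M ~ 0
  double mig_floor = 5.0;
  // acceptance bookkeeping: [tries, accepts] per family
  std::map<std::string, std::array<long, 2>> acc;

  double prior_logdens() const {
    double lp = 0.0;
    for (int p = 0; p < M.npop; ++p)
      lp += dgamma_log(M.theta[p], P.th_a[p], P.th_b[p]);
    for (int p = M.nleaf; p < M.npop; ++p)
      lp += dgamma_log(M.tau[p], P.tau_a[p], P.tau_b[p]);
    for (int j = 0; j < M.nband; ++j)
      lp += dgamma_log(M.brate[j], P.m_a[j], P.m_b[j]);
    if (variable_rates)
      for (double r : rl) lp += dgamma_log(r, P.rate_alpha, P.rate_alpha);
    return lp;
  }

  double total_ll() const {
    double s = 0.0;
    for (double x : ll) s += x;
    return s;
  }

  void tally(const std::string &k, bool a) {
    acc[k][0]++; if (a) acc[k][1]++;
  }

  // band exposure (lineage-time in the target population inside the band
  // window) and event counts of the edge above v, on [age[v], top]
  void edge_band_stats(const Gen &g, int v, double top,
                       std::vector<double> &L, std::vector<int> &E) const {
    L.assign(M.nband, 0.0); E.assign(M.nband, 0);
    std::vector<Seg> segs;
    decompose_edge(g, M, v, top, &segs, nullptr);
    for (const MigEvent &e : g.migs[v]) {
      int below = pop_at(g, M, v, e.t - 1e-15);
      int j = M.band_index(e.above, below);
      if (j >= 0) E[j]++;
    }
    for (const Seg &s : segs)
      for (int j = 0; j < M.nband; ++j) {
        if (s.pop != M.btgt[j]) continue;
        double lo, hi; M.band_window(j, lo, hi);
        double a = std::max(s.t0, lo), b = std::min(s.t1, hi);
        if (b > a) L[j] += b - a;
      }
  }

  // ---- regraft: detach the lineage above v, resimulate from the
  //      conditional structured-coalescent prior (migration proposed at
  //      rates floored below, with the matching Hastings correction);
  //      otherwise accepted on the likelihood ratio ----
  void regraft(int l) {
    Gen &g = gens[l];
    if (g.ntips < 2) return;
    int nn = g.nnode();
    int v;
    do { v = (int)(unif_rand() * nn); } while (v == g.root || v >= nn);
    Gen old = g;
    double ll_old = ll[l];
    std::vector<double> Lold; std::vector<int> Eold;
    if (M.nband) edge_band_stats(g, v, g.age[g.par[v]], Lold, Eold);

    int Pn = g.par[v];
    int w = (g.ch1[Pn] == v) ? g.ch2[Pn] : g.ch1[Pn];
    int Gp = g.par[Pn];
    // detach
    if (Gp >= 0) {
      if (g.ch1[Gp] == Pn) g.ch1[Gp] = w; else g.ch2[Gp] = w;
      g.par[w] = Gp;
      // migration events of P's edge belong to w's extended edge
      for (const MigEvent &e : g.migs[Pn]) g.migs[w].push_back(e);
      std::sort(g.migs[w].begin(), g.migs[w].end(),
                [](const MigEvent &a, const MigEvent &b) { return a.t < b.t; });
    } else {
      g.par[w] = -1;
      g.root = w;
    }
    g.par[v] = -1;
    g.migs[v].clear();
    g.migs[Pn].clear();
    g.ch1[Pn] = g.ch2[Pn] = -1;

    // occupancy of the remainder
    std::vector<Seg> segs;
    for (int u = 0; u < nn; ++u) {
      if (u == Pn || u == v || g.par[u] < 0) continue;
      if (is_descendant(g, u, v)) continue;
      decompose_edge(g, M, u, g.age[g.par[u]], &segs, nullptr);
    }
    // remainder root extends upward forever
    {
      double t = g.age[g.root];
      int p = g.pop[g.root];
      while (M.parent[p] >= 0) {
        segs.push_back({t, M.pop_end(p), p, g.root});
        t = M.pop_end(p); p = M.parent[p];
      }
      segs.push_back({t, TINF, p, g.root});
    }
    // breakpoints
    std::vector<double> bp;
    for (const Seg &s : segs) {
      if (std::isfinite(s.t0)) bp.push_back(s.t0);
      if (std::isfinite(s.t1)) bp.push_back(s.t1);
    }
    for (int p = 0; p < M.npop; ++p)
      if (std::isfinite(M.tau[p])) bp.push_back(M.tau[p]);
    for (int j = 0; j < M.nband; ++j) {
      double lo, hi; M.band_window(j, lo, hi);
      bp.push_back(lo);
      if (std::isfinite(hi)) bp.push_back(hi);
    }
    std::sort(bp.begin(), bp.end());

    // simulate the path
    double t = g.age[v];
    int p = g.pop[v];
    std::vector<MigEvent> path;
    int hit_node = -1; double hit_time = 0.0; int hit_pop = -1;
    for (int guard = 0; guard < 100000; ++guard) {
      double nb = TINF;
      for (double b : bp) if (b > t + 1e-15) { nb = b; break; }
      nb = std::min(nb, M.pop_end(p));
      double mid = std::isfinite(nb) ? 0.5 * (t + nb) : t + 1.0;
      // eligible coalescence partners
      int np = 0;
      for (const Seg &s : segs)
        if (s.pop == p && s.t0 <= mid && mid < s.t1) np++;
      double rc = 2.0 / M.theta[p] * np, rm = 0.0;
      std::vector<std::pair<int, double>> mb;
      for (int j = 0; j < M.nband; ++j) {
        if (M.btgt[j] != p) continue;
        double lo, hi; M.band_window(j, lo, hi);
        double mp = std::max(M.brate[j], mig_floor);
        if (lo <= mid && mid < hi) { mb.push_back({j, mp}); rm += mp; }
      }
      double tot = rc + rm;
      double dt = tot > 0 ? exp_rand() / tot : TINF;
      if (t + dt >= nb) {
        if (!std::isfinite(nb)) stop("regraft failed to coalesce");
        t = nb;
        while (M.pop_end(p) <= t && M.parent[p] >= 0) p = M.parent[p];
        continue;
      }
      t += dt;
      if (unif_rand() * tot < rc) {  // coalesce with a uniformly chosen partner
        int pick = (int)(unif_rand() * np), cnt = 0;
        for (const Seg &s : segs)
          if (s.pop == p && s.t0 <= t && t < s.t1) {
            if (cnt++ == pick) { hit_node = s.node; break; }
          }
        hit_time = t; hit_pop = p;
        break;
      } else {                        // migrate (backward) tgt -> src
        double u = unif_rand() * rm, c = 0.0;
        int j = mb.back().first;
        for (auto &q : mb) { c += q.second; if (u <= c) { j = q.first; break; } }
        path.push_back({t, M.bsrc[j]});
        p = M.bsrc[j];
      }
    }
    if (hit_node < 0) { g = old; return; }

    // re-attach: node Pn at hit_time on hit_node's edge
    int up = g.par[hit_node];
    g.age[Pn] = hit_time;
    g.pop[Pn] = hit_pop;
    g.ch1[Pn] = v; g.ch2[Pn] = hit_node;
    g.par[v] = Pn;
    g.par[Pn] = up;
    if (up >= 0) {
      if (g.ch1[up] == hit_node) g.ch1[up] = Pn; else g.ch2[up] = Pn;
    } else {
      g.root = Pn;
    }
    g.par[hit_node] = Pn;
    // split migration events of hit_node's edge at hit_time
    std::vector<MigEvent> below, above;
    for (const MigEvent &e : g.migs[hit_node])
      (e.t <= hit_time ? below : above).push_back(e);
    g.migs[hit_node] = below;
    g.migs[Pn] = above;
    g.migs[v] = path;

    double ll_new = locus_loglik(g, data[l], rl[l]);
    // Hastings correction for the floored migration proposal rates:
    // prior(path)/q(path) = prod_j (M_j/mp_j)^{E_j} exp(-(M_j - mp_j) L_j)
    double hastings = 0.0;
    if (M.nband) {
      std::vector<double> Lnew; std::vector<int> Enew;
      edge_band_stats(g, v, g.age[Pn], Lnew, Enew);
      for (int j = 0; j < M.nband; ++j) {
        double mp = std::max(M.brate[j], mig_floor);
        if (mp == M.brate[j]) continue;
        hastings += (Enew[j] - Eold[j]) * std::log(M.brate[j] / mp) -
                    (M.brate[j] - mp) * (Lnew[j] - Lold[j]);
      }
    }
    bool accept = std::log(unif_rand()) < ll_new - ll_old + hastings;
    if (accept) {
      Stats Snew;
      if (gen_stats(g, M, Snew)) { stats[l] = Snew; ll[l] = ll_new; }
      else { g = old; accept = false; }   // defensive: never corrupt state
    } else g = old;
    tally("regraft", accept);
  }

  static bool is_descendant(const Gen &g, int u, int anc) {
    while (u >= 0) { if (u == anc) return true; u = g.par[u]; }
    return false;
  }

  // ---- internal node age slide ----
  void age_slide(int l) {
    Gen &g = gens[l];
    if (g.ntips < 2) return;
    int u = g.ntips + (int)(unif_rand() * (g.ntips - 1));
    int pu = g.pop[u];
    double lo = std::max({g.age[g.ch1[u]], g.age[g.ch2[u]], M.tau[pu]});
    for (int c : {g.ch1[u], g.ch2[u]})
      if (!g.migs[c].empty()) lo = std::max(lo, g.migs[c].back().t);
    double hi = M.pop_end(pu);
    if (g.par[u] >= 0) hi = std::min(hi, g.age[g.par[u]]);
    if (!g.migs[u].empty()) hi = std::min(hi, g.migs[u].front().t);
    double a = g.age[u];
    double prop = a + st_slide * (2.0 * unif_rand() - 1.0);
    if (prop <= lo || prop >= hi) { tally("slide", false); return; }
    Gen old = g;
    Stats sold = stats[l];
    double dens_old = stats_logdens(stats[l], M), ll_old = ll[l];
    g.age[u] = prop;
    Stats snew;
    if (!gen_stats(g, M, snew)) { g = old; tally("slide", false); return; }
    double ll_new = locus_loglik(g, data[l], rl[l]);
    double lr = stats_logdens(snew, M) - dens_old + ll_new - ll_old;
    bool accept = std::log(unif_rand()) < lr;
    if (accept) { stats[l] = snew; ll[l] = ll_new; }
    else { g = old; stats[l] = sold; }
    tally("slide", accept);
  }

  // ---- theta multiplier (uses pooled sufficient statistics) ----
  void update_theta(int p) {
    double th = M.theta[p];
    double thn = th * std::exp(st_theta * (unif_rand() - 0.5));
    double Ctot = 0, Atot = 0;
    for (const Stats &S : stats) { Ctot += S.C[p]; Atot += S.A[p]; }
    double lr = Ctot * (std::log(2.0 / thn) - std::log(2.0 / th)) -
                Atot / thn + Atot / th +
                dgamma_log(thn, P.th_a[p], P.th_b[p]) -
                dgamma_log(th, P.th_a[p], P.th_b[p]) +
                std::log(thn / th);
    bool accept = std::log(unif_rand()) < lr;
    if (accept) M.theta[p] = thn;
    tally("theta", accept);
  }

  // ---- migration rate: multiplier walk + independence draw from the
  //      prior (the diffuse spike-at-zero prior spans many decades; the
  //      independence move crosses between the ~0 and >0 regimes) ----
  void update_m(int j) {
    double m = M.brate[j];
    double Et = 0, Lt = 0;
    for (const Stats &S : stats) { Et += S.E[j]; Lt += S.L[j]; }
    bool accept;
    if (unif_rand() < 0.5) {   // independence: prior cancels against proposal
      double mn = std::max(R::rgamma(P.m_a[j], 1.0 / P.m_b[j]), 1e-290);
      double lr = Et * (std::log(mn) - std::log(m)) - (mn - m) * Lt;
      accept = std::log(unif_rand()) < lr;
      if (accept) M.brate[j] = mn;
    } else {
      double mn = m * std::exp(st_m * (unif_rand() - 0.5));
      double lr = Et * (std::log(mn) - std::log(m)) - (mn - m) * Lt +
                  dgamma_log(mn, P.m_a[j], P.m_b[j]) -
                  dgamma_log(m, P.m_a[j], P.m_b[j]) +
                  std::log(mn / m);
      accept = std::log(unif_rand()) < lr;
      if (accept) M.brate[j] = mn;
    }
    tally("mig", accept);
  }

  // ---- tau rubber-band ----
  void update_tau(int p) {
    double told = M.tau[p];
    // children populations
    std::vector<int> kids;
    for (int q = 0; q < M.npop; ++q) if (M.parent[q] == p) kids.push_back(q);
    double lo = 0.0;
    for (int q : kids) lo = std::max(lo, M.tau[q]);
    double hi = M.pop_end(p);
    double tn = told + st_tau * (2.0 * unif_rand() - 1.0);
    // reflect into (lo, hi)
    if (tn < lo) tn = 2 * lo - tn;
    if (std::isfinite(hi) && tn > hi) tn = 2 * hi - tn;
    if (tn <= lo || (std::isfinite(hi) && tn >= hi)) { tally("tau", false); return; }

    Model Mn = M; Mn.tau[p] = tn;
    bool root_pop = M.parent[p] < 0;
    double end = M.pop_end(p);
    auto remap = [&](double t, int q) -> double {
      for (int kid : kids)
        if (q == kid)
          return M.tau[kid] + (t - M.tau[kid]) * (tn - M.tau[kid]) / (told - M.tau[kid]);
      if (q == p) {
        if (root_pop) return t + (tn - told);
        return end - (end - t) * (end - tn) / (end - told);
      }
      return t;
    };
    double jac = 0.0;
    for (int kid : kids)
      jac += std::log((tn - M.tau[kid]) / (told - M.tau[kid]));  // per event, added below
    // jac per-event factors collected while remapping
    double log_jac = 0.0;
    std::vector<Gen> newg(nloci);
    std::vector<Stats> news(nloci);
    std::vector<double> newll(nloci);
    double d_dens = 0.0, d_ll = 0.0;
    for (int l = 0; l < nloci; ++l) {
      Gen g = gens[l];
      for (int u = g.ntips; u < g.nnode(); ++u) {
        int q = g.pop[u];
        if (q == p || std::find(kids.begin(), kids.end(), q) != kids.end()) {
          double t2 = remap(g.age[u], q);
          if (t2 != g.age[u]) {
            if (q == p && !root_pop)
              log_jac += std::log((end - tn) / (end - told));
            else if (q != p)
              log_jac += std::log((tn - M.tau[q]) / (told - M.tau[q]));
            g.age[u] = t2;
          }
        }
      }
      for (int v2 = 0; v2 < g.nnode(); ++v2) {
        if (g.migs[v2].empty()) continue;
        // below pop of each event under the OLD model
        for (MigEvent &e : g.migs[v2]) {
          int below = pop_at(gens[l], M, v2, e.t - 1e-15);
          if (below == p || std::find(kids.begin(), kids.end(), below) != kids.end()) {
            double t2 = remap(e.t, below);
            if (below == p && !root_pop)
              log_jac += std::log((end - tn) / (end - told));
            else if (below != p)
              log_jac += std::log((tn - M.tau[below]) / (told - M.tau[below]));
            e.t = t2;
          }
        }
        std::sort(g.migs[v2].begin(), g.migs[v2].end(),
                  [](const MigEvent &a, const MigEvent &b) { return a.t < b.t; });
      }
      Stats S;
      if (!gen_stats(g, Mn, S)) { tally("tau", false); return; }
      double l2 = locus_loglik(g, data[l], rl[l]);
      d_dens += stats_logdens(S, Mn) - stats_logdens(stats[l], M);
      d_ll += l2 - ll[l];
      newg[l] = std::move(g); news[l] = std::move(S); newll[l] = l2;
    }
    (void)jac;
    double lr = d_dens + d_ll + log_jac +
                dgamma_log(tn, P.tau_a[p], P.tau_b[p]) -
                dgamma_log(told, P.tau_a[p], P.tau_b[p]);
    bool accept = std::log(unif_rand()) < lr;
    if (accept) {
      M.tau[p] = tn;
      gens = std::move(newg); stats = std::move(news); ll = std::move(newll);
    }
    tally("tau", accept);
  }

  // ---- locus-rate pair update (mean preserved exactly) ----
  void update_rl() {
    if (nloci < 2) return;
    int i = (int)(unif_rand() * nloci), j;
    do { j = (int)(unif_rand() * nloci); } while (j == i);
    double d = st_rl * (unif_rand() - 0.5);
    double ri = rl[i] + d, rj = rl[j] - d;
    if (ri <= 0 || rj <= 0) { tally("rl", false); return; }
    double li = locus_loglik(gens[i], data[i], ri);
    double lj = locus_loglik(gens[j], data[j], rj);
    double lr = li + lj - ll[i] - ll[j] +
                dgamma_log(ri, P.rate_alpha, P.rate_alpha) -
                dgamma_log(rl[i], P.rate_alpha, P.rate_alpha) +
                dgamma_log(rj, P.rate_alpha, P.rate_alpha) -
                dgamma_log(rl[j], P.rate_alpha, P.rate_alpha);
    bool accept = std::log(unif_rand()) < lr;
    if (accept) { rl[i] = ri; rl[j] = rj; ll[i] = li; ll[j] = lj; }
    tally("rl", accept);
  }

  // ---- joint scaling (mixing) move ----
  void mixing() {
    double c = std::exp(st_mix * (unif_rand() - 0.5));
    Model Mn = M;
    long k = 0;
    for (int p = 0; p < Mn.npop; ++p) { Mn.theta[p] *= c; k++; }
    for (int p = Mn.nleaf; p < Mn.npop; ++p) { Mn.tau[p] *= c; k++; }
    for (int j = 0; j < Mn.nband; ++j) { Mn.brate[j] /= c; k--; }
    double lp_old = prior_logdens();
    std::vector<Gen> newg(gens);
    double d_dens = 0.0, d_ll = 0.0;
    std::vector<Stats> news(nloci);
    std::vector<double> newll(nloci);
    bool ok = true;
    for (int l = 0; l < nloci && ok; ++l) {
      Gen &g = newg[l];
      for (int u = g.ntips; u < g.nnode(); ++u) { g.age[u] *= c; k++; }
      for (auto &mv : g.migs) for (MigEvent &e : mv) { e.t *= c; k++; }
      Stats S;
      if (!gen_stats(g, Mn, S)) { ok = false; break; }
      double l2 = locus_loglik(g, data[l], rl[l]);
      d_dens += stats_logdens(S, Mn) - stats_logdens(stats[l], M);
      d_ll += l2 - ll[l];
      news[l] = std::move(S); newll[l] = l2;
    }
    if (!ok) { tally("mix", false); return; }
    std::swap(M, Mn);
    double lp_new = prior_logdens();
    std::swap(M, Mn);
    double lr = lp_new - lp_old + d_dens + d_ll + k * std::log(c);
    bool accept = std::log(unif_rand()) < lr;
    if (accept) {
      M = Mn;
      gens = std::move(newg); stats = std::move(news); ll = std::move(newll);
    }
    tally("mix", accept);
  }

  void finetune() {
    auto adj = [&](const std::string &key, double &st) {
      auto &a = acc[key];
      if (a[0] < 20) return;
      double r = (double)a[1] / a[0];
      if (r > 0.45) st *= 1.3;
      else if (r < 0.25) st /= 1.3;
      a = {0, 0};
    };
    adj("slide", st_slide); adj("theta", st_theta); adj("tau", st_tau);
    adj("mig", st_m); adj("mix", st_mix); adj("rl", st_rl);
  }
};

// [[Rcpp::export]]
List run_mcmc_cpp(List model_list, List gens_list, List geno_list,
                  List priors_list, List settings) {
  Sampler S;
  S.M = model_from_list(model_list);
  S.nloci = gens_list.size();
  S.variable_rates = as<bool>(settings["variable_rates"]);
  S.P.th_a = as<std::vector<double>>(priors_list["theta_alpha"]);
  S.P.th_b = as<std::vector<double>>(priors_list["theta_beta"]);
  S.P.tau_a = as<std::vector<double>>(priors_list["tau_alpha"]);
  S.P.tau_b = as<std::vector<double>>(priors_list["tau_beta"]);
  S.P.m_a = as<std::vector<double>>(priors_list["m_alpha"]);
  S.P.m_b = as<std::vector<double>>(priors_list["m_beta"]);
  S.P.rate_alpha = as<double>(priors_list["rate_alpha"]);

  for (int l = 0; l < S.nloci; ++l) {
    S.gens.push_back(gen_from_list(gens_list[l]));
    S.data.push_back(build_locus_data(geno_list[l]));
    if (2 * S.data.back().ndip != S.gens.back().ntips)
      stop("locus %d: genotype rows do not match genealogy tips", l + 1);
  }
  S.rl.assign(S.nloci, 1.0);
  S.stats.resize(S.nloci);
  S.ll.resize(S.nloci);
  for (int l = 0; l < S.nloci; ++l) {
    if (!gen_stats(S.gens[l], S.M, S.stats[l]))
      stop("locus %d: initial genealogy inconsistent with the model", l + 1);
    S.ll[l] = locus_loglik(S.gens[l], S.data[l], S.rl[l]);
    if (!std::isfinite(S.ll[l]))
      stop("locus %d: non-finite likelihood at initialization", l + 1);
  }

  int burn = as<int>(settings["burn_in"]);
  int niter = as<int>(settings["n_iterations"]);
  int every = as<int>(settings["sample_every"]);
  int ftwin = as<int>(settings["finetune_window"]);

  int ninternal = S.M.npop - S.M.nleaf;
  int ncol = S.M.npop + ninternal + S.M.nband + 1;
  int nsamp = niter / every;
  NumericMatrix trace(nsamp, ncol);
  int row = 0;

  for (int it = 1; it <= burn + niter; ++it) {
    for (int l = 0; l < S.nloci; ++l) {
      S.regraft(l);
      S.age_slide(l);
    }
    for (int p = 0; p < S.M.npop; ++p) S.update_theta(p);
    for (int p = S.M.nleaf; p < S.M.npop; ++p) S.update_tau(p);
    for (int j = 0; j < S.M.nband; ++j) S.update_m(j);
    if (S.variable_rates)
      for (int r = 0; r < std::max(1, S.nloci / 2); ++r) S.update_rl();
    S.mixing();
    if (it <= ftwin && it % 50 == 0) S.finetune();
    if (it > burn && (it - burn) % every == 0 && row < nsamp) {
      int c = 0;
      for (int p = 0; p < S.M.npop; ++p) trace(row, c++) = S.M.theta[p];
      for (int p = S.M.nleaf; p < S.M.npop; ++p) trace(row, c++) = S.M.tau[p];
      for (int j = 0; j < S.M.nband; ++j) trace(row, c++) = S.M.brate[j];
      trace(row, c++) = S.total_ll();
      row++;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List acc_out;
  for (auto &kv : S.acc)
    acc_out[kv.first] = NumericVector::create(_["tries"] = (double)kv.second[0],
                                              _["accepts"] = (double)kv.second[1]);
  return List::create(_["trace"] = trace, _["acceptance"] = acc_out,
                      _["finetunes"] = NumericVector::create(
                          _["slide"] = S.st_slide, _["theta"] = S.st_theta,
                          _["tau"] = S.st_tau, _["mig"] = S.st_m,
                          _["mix"] = S.st_mix, _["rl"] = S.st_rl));
}
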