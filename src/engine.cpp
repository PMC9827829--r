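// Forward-time engine for the magic-trait / preference-locus linkage model.
//
// State lives in flat int8 arrays (one row of L alleles per chromosome) so a
// full generation at the default scale (2K = 10,000 adults, ~20,000 offspring,
// L = 100) stays in the low-millisecond range.  All randomness is drawn from
// R's RNG (unif_rand under RNGScope), so set.seed() at the R level makes every
// trajectory bit-reproducible, and the per-stage wrappers and the full-run
// loop share the same code path and hence the same draw sequence.
//
// Allele encoding (shared contract with R/core_types.R):
//   trait locus (position index 0):  1 = A, 2 = A'
//   other loci (indices 1..L-1):     0 = wild, 1 = preference-for-AA,
//                                    2 = preference-for-A'A', 3 = neutral
//   sex: 0 = female, 1 = male;  habitat: 1, 2

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <set>
using namespace Rcpp;

enum { TRAIT_A = 1, TRAIT_AP = 2 };
enum { AL_WILD = 0, AL_PREF_A = 1, AL_PREF_AP = 2, AL_NEUTRAL = 3 };
enum { PH_AA = 0, PH_HET = 1, PH_APAP = 2 };

struct Pars {
  double s, pf, mfrac, hetp, hetrel;
  int K, L, maxp, noff, ncross;
  bool mut_on_pool;
};

static Pars parse_pars(const List& p) {
  Pars q;
  q.s = as<double>(p["s"]);
  q.pf = as<double>(p["pf"]);
  q.mfrac = as<double>(p["mut_fraction"]);
  q.hetp = as<double>(p["het_mate_prob"]);
  q.hetrel = as<double>(p["het_selection_rel"]);
  q.K = as<int>(p["K"]);
  q.L = as<int>(p["L"]);
  q.maxp = as<int>(p["max_pairings"]);
  q.noff = as<int>(p["n_offspring"]);
  q.ncross = as<int>(p["n_crossovers"]);
  q.mut_on_pool = as<bool>(p["mut_on_pool"]);
  return q;
}

struct Pop {
  int N = 0, L = 0;
  std::vector<int8_t> c1, c2;   // row-major N x L
  std::vector<int8_t> sex, hab;
};

static Pop pop_from_r(const List& pl) {
  IntegerMatrix m1 = pl["chrom1"], m2 = pl["chrom2"];
  IntegerVector sx = pl["sex"], hb = pl["habitat"];
  Pop p;
  p.N = m1.nrow();
  p.L = m1.ncol();
  if (m2.nrow() != p.N || m2.ncol() != p.L)
    stop("chrom1 and chrom2 dimensions differ");
  p.c1.resize((size_t)p.N * p.L);
  p.c2.resize((size_t)p.N * p.L);
  p.sex.resize(p.N);
  p.hab.resize(p.N);
  for (int j = 0; j < p.L; ++j)
    for (int i = 0; i < p.N; ++i) {
      p.c1[(size_t)i * p.L + j] = (int8_t)m1(i, j);
      p.c2[(size_t)i * p.L + j] = (int8_t)m2(i, j);
    }
  for (int i = 0; i < p.N; ++i) {
    p.sex[i] = (int8_t)sx[i];
    p.hab[i] = (int8_t)hb[i];
  }
  return p;
}

static List pop_to_r(const Pop& p, int generation) {
  IntegerMatrix m1(p.N, p.L), m2(p.N, p.L);
  IntegerVector sx(p.N), hb(p.N);
  for (int j = 0; j < p.L; ++j)
    for (int i = 0; i < p.N; ++i) {
      m1(i, j) = p.c1[(size_t)i * p.L + j];
      m2(i, j) = p.c2[(size_t)i * p.L + j];
    }
  for (int i = 0; i < p.N; ++i) {
    sx[i] = p.sex[i];
    hb[i] = p.hab[i];
  }
  List out = List::create(_["chrom1"] = m1, _["chrom2"] = m2,
                          _["sex"] = sx, _["habitat"] = hb,
                          _["generation"] = generation);
  out.attr("class") = "sim_population";
  return out;
}

// uniform integer in [0, n)
static inline int ri(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline int phen(const Pop& p, int i) {
  int a = p.c1[(size_t)i * p.L], b = p.c2[(size_t)i * p.L];
  if (a == b) return a == TRAIT_A ? PH_AA : PH_APAP;
  return PH_HET;
}

// preference score d: #(pref-for-AA) - #(pref-for-A'A') over both chromosomes
static inline int pref_score_i(const Pop& p, int i) {
  const int8_t* g1 = &p.c1[(size_t)i * p.L];
  const int8_t* g2 = &p.c2[(size_t)i * p.L];
  int d = 0;
  for (int j = 1; j < p.L; ++j) {
    d += (g1[j] == AL_PREF_A) - (g1[j] == AL_PREF_AP);
    d += (g2[j] == AL_PREF_A) - (g2[j] == AL_PREF_AP);
  }
  return d;
}

// overflow-safe logistic
static inline double logistic(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double accept_prob(int d, int male_ph, const Pars& par) {
  if (male_ph == PH_HET) return par.hetp;
  double pA = logistic((double)d * par.pf);
  return male_ph == PH_AA ? pA : 1.0 - pA;
}

// ---- stage 1: formation of mating pairs (monogamous, female choice) --------
static void stage_pairs(const Pop& p, const Pars& par,
                        std::vector<int>& fem, std::vector<int>& mal) {
  fem.clear();
  mal.clear();
  std::vector<int> fpool, mpool;
  fpool.reserve(p.N / 2 + 1);
  mpool.reserve(p.N / 2 + 1);
  for (int i = 0; i < p.N; ++i) (p.sex[i] == 0 ? fpool : mpool).push_back(i);
  if (fpool.empty() || mpool.empty()) return;
  // females choose in a fresh uniformly random order each generation
  for (int i = (int)fpool.size() - 1; i > 0; --i)
    std::swap(fpool[i], fpool[ri(i + 1)]);
  std::vector<int8_t> mph(p.N, 0);
  for (int m : mpool) mph[m] = (int8_t)phen(p, m);
  int msz = (int)mpool.size();
  for (int f : fpool) {
    if (msz == 0) break;
    int d = pref_score_i(p, f);
    for (int t = 0; t < par.maxp && msz > 0; ++t) {
      int j = ri(msz);
      int m = mpool[j];
      if (unif_rand() < accept_prob(d, mph[m], par)) {
        fem.push_back(f);
        mal.push_back(m);
        mpool[j] = mpool[--msz];   // accepted male leaves the pool
        break;
      }
      // rejected males stay in the pool and may be redrawn, even by her
    }
  }
}

// ---- stage 2: reproduction -------------------------------------------------
static Pop stage_reproduce(const Pop& p, const Pars& par,
                           const std::vector<int>& fem,
                           const std::vector<int>& mal) {
  Pop o;
  o.L = p.L;
  int np = (int)fem.size();
  o.N = np * par.noff;
  o.c1.resize((size_t)o.N * o.L);
  o.c2.resize((size_t)o.N * o.L);
  o.sex.resize(o.N);
  o.hab.resize(o.N);
  int half = par.noff / 2;
  size_t k = 0;
  for (int i = 0; i < np; ++i) {
    const int8_t* f1 = &p.c1[(size_t)fem[i] * p.L];
    const int8_t* f2 = &p.c2[(size_t)fem[i] * p.L];
    const int8_t* m1 = &p.c1[(size_t)mal[i] * p.L];
    const int8_t* m2 = &p.c2[(size_t)mal[i] * p.L];
    for (int c = 0; c < par.noff; ++c, ++k) {
      const int8_t* mat = unif_rand() < 0.5 ? f1 : f2;
      const int8_t* pat = unif_rand() < 0.5 ? m1 : m2;
      std::memcpy(&o.c1[k * o.L], mat, o.L);
      std::memcpy(&o.c2[k * o.L], pat, o.L);
      o.sex[k] = c < half ? 0 : 1;          // fixed sexes, e.g. 2 F + 2 M
      o.hab[k] = p.hab[fem[i]];             // offspring stay with the mother
    }
  }
  return o;
}

// ---- stage 3a: recombination (tail swap after a uniform cut point) ---------
static void stage_recombine(Pop& p, const Pars& par) {
  if (par.ncross <= 0) return;
  for (int i = 0; i < p.N; ++i) {
    int8_t* a = &p.c1[(size_t)i * p.L];
    int8_t* b = &p.c2[(size_t)i * p.L];
    for (int r = 0; r < par.ncross; ++r) {
      int cut = 1 + ri(p.L - 1);            // trait locus never crosses
      for (int j = cut; j < p.L; ++j) std::swap(a[j], b[j]);
    }
  }
}

// ---- stage 3b: mutation ----------------------------------------------------
// n individuals get exactly one mutation each at a uniform non-trait position
// on a uniform homolog; the new state is uniform over the three mutant
// classes and overwrites whatever was there (back mutation allowed).
static int stage_mutate(Pop& p, const Pars& par, bool strict) {
  int nm = par.mut_on_pool ? (int)std::floor(par.mfrac * p.N)
                           : (int)std::floor(par.mfrac * 2.0 * par.K);
  if (nm > p.N) {
    if (strict)
      stop("mutation count (%d) exceeds offspring pool size (%d)", nm, p.N);
    nm = p.N;
  }
  if (nm <= 0) return 0;
  std::vector<int> idx(p.N);
  for (int i = 0; i < p.N; ++i) idx[i] = i;
  for (int t = 0; t < nm; ++t) {            // partial Fisher-Yates: w/o replacement
    int j = t + ri(p.N - t);
    std::swap(idx[t], idx[j]);
    int i = idx[t];
    int pos = 1 + ri(p.L - 1);
    int8_t* g = ri(2) == 0 ? &p.c1[(size_t)i * p.L] : &p.c2[(size_t)i * p.L];
    g[pos] = (int8_t)(1 + ri(3));
  }
  return nm;
}

static void compact(Pop& p, const std::vector<uint8_t>& keep) {
  size_t w = 0;
  for (int i = 0; i < p.N; ++i)
    if (keep[i]) {
      if ((int)w != i) {
        std::memmove(&p.c1[w * p.L], &p.c1[(size_t)i * p.L], p.L);
        std::memmove(&p.c2[w * p.L], &p.c2[(size_t)i * p.L], p.L);
        p.sex[w] = p.sex[i];
        p.hab[w] = p.hab[i];
      }
      ++w;
    }
  p.N = (int)w;
  p.c1.resize(w * p.L);
  p.c2.resize(w * p.L);
  p.sex.resize(w);
  p.hab.resize(w);
}

// ---- stage 4: ecological selection -----------------------------------------
static void stage_select(Pop& p, const Pars& par) {
  if (p.N == 0) return;
  std::vector<uint8_t> keep(p.N, 1);
  for (int i = 0; i < p.N; ++i) {
    int ph = phen(p, i);
    bool adapted = (ph == PH_AA && p.hab[i] == 1) ||
                   (ph == PH_APAP && p.hab[i] == 2);
    if (!adapted) {
      double pd = ph == PH_HET ? par.s * par.hetrel : par.s;
      if (pd > 1.0) pd = 1.0;
      if (unif_rand() < pd) keep[i] = 0;
    }
  }
  compact(p, keep);
}

// ---- stage 5: density-dependent regulation ---------------------------------
static void stage_regulate(Pop& p, const Pars& par) {
  if (p.N == 0) return;
  std::vector<int> h1, h2;
  for (int i = 0; i < p.N; ++i) (p.hab[i] == 1 ? h1 : h2).push_back(i);
  if ((int)h1.size() <= par.K && (int)h2.size() <= par.K) return;
  std::vector<uint8_t> keep(p.N, 0);
  auto pick = [&](std::vector<int>& v) {
    if ((int)v.size() <= par.K) {
      for (int i : v) keep[i] = 1;
      return;
    }
    for (int t = 0; t < par.K; ++t) {       // uniform K-subset
      int j = t + ri((int)v.size() - t);
      std::swap(v[t], v[j]);
      keep[v[t]] = 1;
    }
  };
  pick(h1);
  pick(h2);
  compact(p, keep);
}

// ---- per-generation metrics -------------------------------------------------
// columns of the metrics matrix (must match R side):
static const int MET_NCOL = 16;
static const char* MET_NAMES[MET_NCOL] = {
  "generation", "n_h1", "n_h2", "n_pairs", "match_prop",
  "freq_AA", "freq_AAprime", "freq_AprimeAprime",
  "dist_prefA_AA", "dist_prefAp_AA", "dist_neutral_AA",
  "dist_prefA_ApAp", "dist_prefAp_ApAp", "dist_neutral_ApAp",
  "mean_pref_per_chrom", "n_mutations"
};

static void metrics_row(const Pop& p, double* row, int generation,
                        int npairs, double match_prop, int nmut) {
  double sum[2][3] = {{0, 0, 0}, {0, 0, 0}};
  int cnt[2][3] = {{0, 0, 0}, {0, 0, 0}};
  long pref_total = 0;
  int nph[3] = {0, 0, 0}, nh1 = 0;
  for (int i = 0; i < p.N; ++i) {
    int ph = phen(p, i);
    nph[ph]++;
    if (p.hab[i] == 1) nh1++;
    long psum[3] = {0, 0, 0};
    int pcnt[3] = {0, 0, 0};
    const int8_t* g1 = &p.c1[(size_t)i * p.L];
    const int8_t* g2 = &p.c2[(size_t)i * p.L];
    for (int j = 1; j < p.L; ++j) {
      int a = g1[j];
      if (a != AL_WILD) { psum[a - 1] += j; pcnt[a - 1]++; }
      int b = g2[j];
      if (b != AL_WILD) { psum[b - 1] += j; pcnt[b - 1]++; }
    }
    pref_total += pcnt[0] + pcnt[1];
    int cls = ph == PH_AA ? 0 : (ph == PH_APAP ? 1 : -1);
    if (cls >= 0)
      for (int t = 0; t < 3; ++t)
        if (pcnt[t] > 0) {
          sum[cls][t] += (double)psum[t] / pcnt[t];
          cnt[cls][t]++;
        }
  }
  row[0] = generation;
  row[1] = nh1;
  row[2] = p.N - nh1;
  row[3] = npairs;
  row[4] = match_prop;
  for (int t = 0; t < 3; ++t)
    row[5 + t] = p.N > 0 ? (double)nph[t] / p.N : NA_REAL;
  for (int c = 0; c < 2; ++c)
    for (int t = 0; t < 3; ++t)
      row[8 + 3 * c + t] = cnt[c][t] > 0 ? sum[c][t] / cnt[c][t] : NA_REAL;
  row[14] = p.N > 0 ? (double)pref_total / (2.0 * p.N) : NA_REAL;
  row[15] = nmut;
}

// one full generation; returns via out-params
static void do_step(Pop& p, const Pars& par, std::vector<int>& fem,
                    std::vector<int>& mal, double& match_prop, int& nmut) {
  stage_pairs(p, par, fem, mal);
  match_prop = NA_REAL;
  int np = (int)fem.size();
  if (np > 0) {
    int match = 0;
    for (int k = 0; k < np; ++k)
      if (phen(p, fem[k]) == phen(p, mal[k])) match++;
    match_prop = (double)match / np;
  }
  Pop off = stage_reproduce(p, par, fem, mal);
  stage_recombine(off, par);
  nmut = off.N > 0 ? stage_mutate(off, par, false) : 0;
  stage_select(off, par);
  stage_regulate(off, par);
  p = std::move(off);
}

// ---------------------------------------------------------------------------
// exported wrappers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_form_pairs(List popList, List parsList) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  std::vector<int> fem, mal;
  stage_pairs(p, par, fem, mal);
  IntegerVector f(fem.size()), m(mal.size());
  for (size_t i = 0; i < fem.size(); ++i) {
    f[i] = fem[i] + 1;   // 1-based for R
    m[i] = mal[i] + 1;
  }
  return List::create(_["female"] = f, _["male"] = m);
}

// [[Rcpp::export]]
List cpp_reproduce(List popList, IntegerVector female, IntegerVector male,
                   List parsList) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  if (female.size() != male.size()) stop("female/male index length mismatch");
  std::vector<int> fem(female.size()), mal(male.size());
  for (int i = 0; i < female.size(); ++i) {
    fem[i] = female[i] - 1;
    mal[i] = male[i] - 1;
    if (fem[i] < 0 || fem[i] >= p.N || mal[i] < 0 || mal[i] >= p.N)
      stop("pair index out of range");
  }
  Pop o = stage_reproduce(p, par, fem, mal);
  return pop_to_r(o, as<int>(popList["generation"]));
}

// [[Rcpp::export]]
List cpp_recombine(List popList, List parsList) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  stage_recombine(p, par);
  return pop_to_r(p, as<int>(popList["generation"]));
}

// [[Rcpp::export]]
List cpp_mutate(List popList, List parsList, bool strict = true) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  int nm = stage_mutate(p, par, strict);
  return List::create(_["population"] = pop_to_r(p, as<int>(popList["generation"])),
                      _["n_mutations"] = nm);
}

// [[Rcpp::export]]
List cpp_apply_selection(List popList, List parsList) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  stage_select(p, par);
  return pop_to_r(p, as<int>(popList["generation"]));
}

// [[Rcpp::export]]
List cpp_regulate(List popList, List parsList) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  stage_regulate(p, par);
  return pop_to_r(p, as<int>(popList["generation"]));
}

// [[Rcpp::export]]
List cpp_step(List popList, List parsList) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  int gen = as<int>(popList["generation"]);
  std::vector<int> fem, mal;
  double mp;
  int nmut;
  // phenotypes of the parents must be captured before they are replaced
  std::vector<int8_t> parent_ph(p.N);
  for (int i = 0; i < p.N; ++i) parent_ph[i] = (int8_t)phen(p, i);
  do_step(p, par, fem, mal, mp, nmut);
  int np = (int)fem.size();
  IntegerVector f(np), m(np), fph(np), mph(np);
  for (int i = 0; i < np; ++i) {
    f[i] = fem[i] + 1;
    m[i] = mal[i] + 1;
    fph[i] = parent_ph[fem[i]];
    mph[i] = parent_ph[mal[i]];
  }
  return List::create(_["population"] = pop_to_r(p, gen + 1),
                      _["female"] = f, _["male"] = m,
                      _["female_phenotype"] = fph, _["male_phenotype"] = mph,
                      _["match_prop"] = mp, _["n_mutations"] = nmut);
}

// [[Rcpp::export]]
List cpp_run(List popList, List parsList, int generations,
             IntegerVector snapshot_gens, bool keep_final) {
  Pop p = pop_from_r(popList);
  Pars par = parse_pars(parsList);
  std::set<int> snapset(snapshot_gens.begin(), snapshot_gens.end());
  NumericMatrix M(generations + 1, MET_NCOL);
  CharacterVector cn(MET_NCOL);
  for (int j = 0; j < MET_NCOL; ++j) cn[j] = MET_NAMES[j];
  colnames(M) = cn;
  {
    std::vector<double> row0(MET_NCOL);
    metrics_row(p, row0.data(), 0, 0, NA_REAL, 0);
    for (int j = 0; j < MET_NCOL; ++j) M(0, j) = row0[j];
  }
  List snaps;
  CharacterVector snap_names;
  if (snapset.count(0)) {
    snaps.push_back(pop_to_r(p, 0));
    snap_names.push_back("0");
  }
  bool extinct = false;
  int ext_gen = NA_INTEGER, glast = 0;
  std::vector<int> fem, mal;
  std::vector<double> row(MET_NCOL);
  for (int g = 1; g <= generations; ++g) {
    double mp;
    int nmut;
    do_step(p, par, fem, mal, mp, nmut);
    metrics_row(p, row.data(), g, (int)fem.size(), mp, nmut);
    for (int j = 0; j < MET_NCOL; ++j) M(g, j) = row[j];
    glast = g;
    if (snapset.count(g)) {
      snaps.push_back(pop_to_r(p, g));
      snap_names.push_back(std::to_string(g));
    }
    if (p.N == 0 || row[1] == 0 || row[2] == 0) {
      extinct = true;
      ext_gen = g;
      break;
    }
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix Mout = M;
  if (glast < generations) {
    Mout = NumericMatrix(glast + 1, MET_NCOL);
    for (int i = 0; i <= glast; ++i)
      for (int j = 0; j < MET_NCOL; ++j) Mout(i, j) = M(i, j);
    colnames(Mout) = cn;
  }
  snaps.attr("names") = snap_names;
  return List::create(
      _["metrics"] = Mout, _["snapshots"] = snaps,
      _["final"] = keep_final ? (SEXP)pop_to_r(p, glast) : R_NilValue,
      _["extinct"] = extinct, _["extinct_generation"] = ext_gen);
}
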