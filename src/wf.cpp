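// Individual-based Wright-Fisher forward simulation for a two-founder
// experimental-evolution population.
//
// Genomes are ancestry mosaics: each chromosome copy is a list of breakpoint
// positions at which founder ancestry switches, plus the ancestry at the left
// end. With two fully homozygous founders this is a complete description of
// every genotype, and after ~20 generations the expected number of
// breakpoints per copy is small, so gamete formation and allele-frequency
// queries stay cheap regardless of marker density.
//
// Sex is explicit: males are achiasmatic (no crossing over, as in
// Drosophila) and hemizygous for X. All randomness comes from R's RNG so
// set.seed() controls the whole simulation.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Copy {
  int anc0;                 // ancestry at the left chromosome end: 1 focal, 0 other
  std::vector<double> bp;   // ascending positions where ancestry switches
};

// ancestry immediately to the right of position x
inline int ancestry_at(const Copy& c, double x) {
  size_t n = std::upper_bound(c.bp.begin(), c.bp.end(), x) - c.bp.begin();
  return c.anc0 ^ static_cast<int>(n & 1);
}

// Recombine two parental copies at crossover positions xo (sorted, strictly
// inside the chromosome). The gamete starts on copy a at the left end.
Copy recombine(const Copy& a, const Copy& b, const std::vector<double>& xo) {
  if (xo.empty()) return a;
  const Copy* src[2] = { &a, &b };
  Copy out;
  out.anc0 = a.anc0;
  int cur = a.anc0;
  double lo = -1.0;  // positions are >= 0
  size_t nseg = xo.size() + 1;
  for (size_t i = 0; i < nseg; ++i) {
    const Copy& s = *src[i % 2];
    double hi = (i < xo.size()) ? xo[i] : std::numeric_limits<double>::infinity();
    if (i > 0) {
      int anc_here = ancestry_at(s, lo);
      if (anc_here != cur) { out.bp.push_back(lo); cur ^= 1; }
    }
    // breakpoints of the source strictly inside (lo, hi)
    auto it0 = std::upper_bound(s.bp.begin(), s.bp.end(), lo);
    auto it1 = std::lower_bound(s.bp.begin(), s.bp.end(), hi);
    for (auto it = it0; it != it1; ++it) { out.bp.push_back(*it); cur ^= 1; }
    lo = hi;
  }
  return out;
}

// Piecewise-linear cumulative genetic map: node positions (bp) and
// cumulative Morgans; invert a genetic coordinate to a physical one.
struct GMap {
  std::vector<double> pos;  // ascending bp
  std::vector<double> cm;   // ascending cumulative Morgans, cm.front() == 0
  double length() const { return cm.back(); }
  double invert(double g) const {
    size_t i = std::upper_bound(cm.begin(), cm.end(), g) - cm.begin();
    if (i == 0) return pos.front();
    if (i >= cm.size()) return pos.back();
    double g0 = cm[i - 1], g1 = cm[i];
    double p0 = pos[i - 1], p1 = pos[i];
    if (g1 <= g0) return p0;  // zero-rate interval
    return p0 + (g - g0) / (g1 - g0) * (p1 - p0);
  }
};

// one maternal gamete: Poisson crossovers placed by inverse-CDF on the map
Copy female_gamete(const Copy& c0, const Copy& c1, const GMap& map) {
  double L = map.length();
  int k = (L > 0) ? static_cast<int>(R::rpois(L)) : 0;
  std::vector<double> xo(k);
  for (int i = 0; i < k; ++i) xo[i] = map.invert(unif_rand() * L);
  std::sort(xo.begin(), xo.end());
  bool start_first = unif_rand() < 0.5;
  return start_first ? recombine(c0, c1, xo) : recombine(c1, c0, xo);
}

struct Target { int chrom; double pos; double s; double h; };

struct Population {
  int N;
  std::vector<int> sex;                      // 0 male, 1 female
  // copies[c][2*i + j]: copy j of chromosome c in individual i
  std::vector<std::vector<Copy>> copies;
};

double fitness_of(const Population& pop, int i,
                  const std::vector<Target>& targets,
                  const std::vector<bool>& is_x) {
  double w = 1.0;
  for (const Target& t : targets) {
    int c = t.chrom;
    if (is_x[c] && pop.sex[i] == 0) {
      int a = ancestry_at(pop.copies[c][2 * i], t.pos);
      w *= (a == 1) ? (1.0 + t.s) : 1.0;   // hemizygous male
    } else {
      int d = ancestry_at(pop.copies[c][2 * i], t.pos) +
              ancestry_at(pop.copies[c][2 * i + 1], t.pos);
      if (d == 1) w *= 1.0 + t.h * t.s;
      else if (d == 2) w *= 1.0 + t.s;
    }
  }
  return w;
}

// sample an index proportional to cumulative weights
inline int sample_cum(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

}  // namespace

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
List wf_simulate_cpp(List marker_pos, List gmap_pos, List gmap_cm,
                     LogicalVector is_x_in, int N, double p_geno,
                     int generations,
                     IntegerVector sel_chrom, NumericVector sel_pos,
                     NumericVector sel_s, NumericVector sel_h) {
  int C = marker_pos.size();
  std::vector<GMap> maps(C);
  std::vector<bool> is_x(C);
  for (int c = 0; c < C; ++c) {
    maps[c].pos = as<std::vector<double>>(gmap_pos[c]);
    maps[c].cm = as<std::vector<double>>(gmap_cm[c]);
    is_x[c] = is_x_in[c];
  }
  std::vector<Target> targets;
  for (int k = 0; k < sel_chrom.size(); ++k)
    targets.push_back({ sel_chrom[k] - 1, sel_pos[k], sel_s[k], sel_h[k] });

  // --- founders: round(N * p_geno) focal homozygotes, sexes alternating
  //     within each founder class so both classes contain both sexes
  Population pop;
  pop.N = N;
  pop.sex.resize(N);
  pop.copies.assign(C, std::vector<Copy>(2 * N));
  int n_focal = static_cast<int>(std::round(N * p_geno));
  for (int i = 0; i < N; ++i) {
    int within = (i < n_focal) ? i : i - n_focal;
    pop.sex[i] = within % 2;  // male, female, male, ...
    int anc = (i < n_focal) ? 1 : 0;
    for (int c = 0; c < C; ++c) {
      pop.copies[c][2 * i].anc0 = anc;
      pop.copies[c][2 * i + 1].anc0 = anc;
    }
  }

  bool neutral = targets.empty();
  for (int g = 1; g <= generations; ++g) {
    std::vector<int> males, females;
    for (int i = 0; i < N; ++i) (pop.sex[i] ? females : males).push_back(i);
    if (males.empty() || females.empty())
      stop("sex went extinct at generation %d", g);

    std::vector<double> cum_m(males.size()), cum_f(females.size());
    double acc = 0.0;
    for (size_t i = 0; i < males.size(); ++i) {
      acc += neutral ? 1.0 : fitness_of(pop, males[i], targets, is_x);
      cum_m[i] = acc;
    }
    acc = 0.0;
    for (size_t i = 0; i < females.size(); ++i) {
      acc += neutral ? 1.0 : fitness_of(pop, females[i], targets, is_x);
      cum_f[i] = acc;
    }

    Population next;
    next.N = N;
    next.sex.resize(N);
    next.copies.assign(C, std::vector<Copy>(2 * N));
    for (int i = 0; i < N; ++i) {
      int mother = females[sample_cum(cum_f)];
      int father = males[sample_cum(cum_m)];
      int sex = (unif_rand() < 0.5) ? 1 : 0;
      next.sex[i] = sex;
      for (int c = 0; c < C; ++c) {
        // maternal gamete: recombinant
        next.copies[c][2 * i] = female_gamete(
            pop.copies[c][2 * mother], pop.copies[c][2 * mother + 1], maps[c]);
        // paternal gamete: whole copy, no crossing over
        if (is_x[c]) {
          if (sex == 1)  // daughters get the father's single X
            next.copies[c][2 * i + 1] = pop.copies[c][2 * father];
          // sons: paternal slot left empty (hemizygous)
        } else {
          int j = (unif_rand() < 0.5) ? 0 : 1;
          next.copies[c][2 * i + 1] = pop.copies[c][2 * father + j];
        }
      }
    }
    pop = std::move(next);
  }

  // --- focal-allele frequency at each marker
  List freqs(C);
  for (int c = 0; c < C; ++c) {
    NumericVector mp = marker_pos[c];
    int M = mp.size();
    std::vector<double> pos(mp.begin(), mp.end());
    std::vector<int> diff(M + 1, 0);
    long denom = 0;
    auto add_copy = [&](const Copy& cp) {
      double seg_start = 0.0;
      int anc = cp.anc0;
      for (size_t j = 0; j <= cp.bp.size(); ++j) {
        double seg_end = (j < cp.bp.size())
            ? cp.bp[j] : std::numeric_limits<double>::infinity();
        if (anc == 1) {
          int i0 = static_cast<int>(
              std::lower_bound(pos.begin(), pos.end(), seg_start) - pos.begin());
          int i1 = static_cast<int>(
              std::lower_bound(pos.begin(), pos.end(), seg_end) - pos.begin());
          if (i1 > i0) { diff[i0] += 1; diff[i1] -= 1; }
        }
        anc ^= 1;
        seg_start = seg_end;
      }
    };
    for (int i = 0; i < N; ++i) {
      if (is_x[c] && pop.sex[i] == 0) {
        add_copy(pop.copies[c][2 * i]);
        denom += 1;
      } else {
        add_copy(pop.copies[c][2 * i]);
        add_copy(pop.copies[c][2 * i + 1]);
        denom += 2;
      }
    }
    NumericVector f(M);
    int running = 0;
    for (int m = 0; m < M; ++m) {
      running += diff[m];
      f[m] = static_cast<double>(running) / static_cast<double>(denom);
    }
    freqs[c] = f;
  }
  return freqs;
}

// Draw a single gamete from a parent; exposed for unit tests of the meiosis
// model (crossover counts, male achiasmy, inheritance of mosaics).
// [[Rcpp::export(name = ".wf_gamete_cpp")]]
List wf_gamete_cpp(int anc0_a, NumericVector bp_a, int anc0_b,
                   NumericVector bp_b, NumericVector gpos, NumericVector gcm,
                   bool female) {
  Copy a{ anc0_a, std::vector<double>(bp_a.begin(), bp_a.end()) };
  Copy b{ anc0_b, std::vector<double>(bp_b.begin(), bp_b.end()) };
  Copy g;
  if (female) {
    GMap map;
    map.pos = as<std::vector<double>>(gpos);
    map.cm = as<std::vector<double>>(gcm);
    g = female_gamete(a, b, map);
  } else {
    g = (unif_rand() < 0.5) ? a : b;  // whole-copy transmission
  }
  return List::create(_["anc0"] = g.anc0, _["breakpoints"] = NumericVector(g.bp.begin(), g.bp.end()));
}

// Evaluate founder ancestry of a mosaic copy at given positions (test helper).
// [[Rcpp::export(name = ".wf_ancestry_cpp")]]
IntegerVector wf_ancestry_cpp(int anc0, NumericVector bp, NumericVector at) {
  Copy c{ anc0, std::vector<double>(bp.begin(), bp.end()) };
  IntegerVector out(at.size());
  for (int i = 0; i < at.size(); ++i) out[i] = ancestry_at(c, at[i]);
  return out;
}
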