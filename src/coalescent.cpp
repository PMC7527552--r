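// Structured-coalescent engine.
//
// Simulates genealogies of haploid lineages sampled from a set of demes with
// piecewise-exponential diploid sizes, backward-time migration, and
// join (forward-time split) events.  Two entry points:
//
//   coal_expected_sfs : accumulates expected branch length per joint
//                       derived-allele-count class (unfolded, per sampled
//                       deme) over nSims independent genealogies.
//   coal_sim_sites    : simulates one genealogy per locus and places one
//                       segregating site uniformly on total branch length
//                       (infinite sites conditioned on segregating).
//
// Time is measured in generations; a deme of diploid size N has pairwise
// coalescence rate 1/(2N) per generation between haploid lineages.
// A deme's size going backward from its reference time tref is
// N(t) = Nref * exp(-r * (t - tref)) with r the forward growth rate.
//
// The RNG is a mt19937_64 with an explicit seed and hand-rolled uniform /
// exponential transforms so that streams are reproducible across stdlib
// implementations.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  double unif() {  // in (0,1)
    uint64_t x = gen();
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo() { return -std::log(unif()); }
  int unif_int(int n) {  // 0..n-1
    return static_cast<int>(unif() * n) % n;
  }
};

struct Event {
  double time;
  int type;  // 0 = join(d1 -> d2), 1 = size change(d1), 2 = migration change
  int d1, d2;
  double size, growth;
  std::vector<double> mig;  // flattened nDemes x nDemes, row-major (type 2)
};

struct DemeState {
  double Nref, tref, r;
  bool active;
};

// Waiting time to next coalescence among k lineages in deme d, starting at
// absolute time t.  Returns +Inf if the (backward-shrinking-rate) process
// never fires.
double coal_wait(const DemeState& ds, double t, int k, Rng& rng) {
  double C = 0.5 * k * (k - 1);
  double B = C / (2.0 * ds.Nref) * std::exp(ds.r * (t - ds.tref));
  double E = rng.expo();
  if (std::fabs(ds.r) < 1e-300) return E / B;
  double arg = 1.0 + ds.r * E / B;
  if (arg <= 0.0) return INF;
  return std::log(arg) / ds.r;
}

struct Engine {
  int nDemes;
  std::vector<DemeState> deme;
  std::vector<double> mig;   // row-major nDemes x nDemes
  std::vector<double> mout;  // per-deme total out-rate
  std::vector<Event> events;
  std::vector<int> samples;  // haploid sample size per deme
  Rng rng;

  // per-sim state
  std::vector<std::vector<int>> demeLin;  // lineage ids per deme
  int nLive;

  Engine(int nDemes_, NumericVector N0, NumericVector growth0,
         NumericMatrix mig0, List evts, IntegerVector samples_, uint64_t seed)
      : nDemes(nDemes_), rng(seed) {
    deme.resize(nDemes);
    for (int d = 0; d < nDemes; ++d)
      deme[d] = {N0[d], 0.0, growth0[d], true};
    mig.assign(nDemes * nDemes, 0.0);
    for (int i = 0; i < nDemes; ++i)
      for (int j = 0; j < nDemes; ++j)
        if (i != j) mig[i * nDemes + j] = mig0(i, j);
    samples.assign(samples_.begin(), samples_.end());
    for (int i = 0; i < evts.size(); ++i) {
      List e = evts[i];
      Event ev;
      ev.time = as<double>(e["time"]);
      std::string ty = as<std::string>(e["type"]);
      ev.d1 = e.containsElementNamed("d1") ? as<int>(e["d1"]) - 1 : -1;
      ev.d2 = e.containsElementNamed("d2") ? as<int>(e["d2"]) - 1 : -1;
      ev.size = e.containsElementNamed("size") ? as<double>(e["size"]) : -1.0;
      ev.growth =
          e.containsElementNamed("growth") ? as<double>(e["growth"]) : 0.0;
      if (ty == "join") ev.type = 0;
      else if (ty == "size") ev.type = 1;
      else if (ty == "migration") {
        ev.type = 2;
        NumericMatrix m = as<NumericMatrix>(e["mig"]);
        ev.mig.assign(nDemes * nDemes, 0.0);
        for (int a = 0; a < nDemes; ++a)
          for (int b = 0; b < nDemes; ++b)
            if (a != b) ev.mig[a * nDemes + b] = m(a, b);
      } else stop("unknown event type");
      events.push_back(ev);
    }
    std::stable_sort(events.begin(), events.end(),
                     [](const Event& a, const Event& b) { return a.time < b.time; });
    refresh_mout();
  }

  void refresh_mout() {
    mout.assign(nDemes, 0.0);
    for (int d = 0; d < nDemes; ++d) {
      if (!deme[d].active) continue;
      for (int e = 0; e < nDemes; ++e)
        if (deme[e].active) mout[d] += mig[d * nDemes + e];
    }
  }

  void reset_state() {
    for (int d = 0; d < nDemes; ++d)
      deme[d] = {deme[d].Nref, deme[d].tref, deme[d].r, deme[d].active};
  }

  // Run one genealogy.  Callbacks:
  //   accum(dt)            : dt of branch length elapses on every live lineage
  //   merge(a, b, d, time) : lineage ids a,b coalesce in deme d; returns new id
  template <typename Accum, typename Merge>
  void run(std::vector<DemeState> deme0, std::vector<double> mig0v,
           Accum accum, Merge merge) {
    deme = deme0;
    mig = mig0v;
    refresh_mout();
    double t = 0.0;
    size_t evIdx = 0;
    int guard = 0;
    while (nLive > 1) {
      if (++guard > 100000000) stop("coalescent did not complete");
      double tEv = evIdx < events.size() ? events[evIdx].time : INF;
      // migration candidate
      double Rm = 0.0;
      for (int d = 0; d < nDemes; ++d) Rm += demeLin[d].size() * mout[d];
      double tMig = Rm > 0 ? t + rng.expo() / Rm : INF;
      // coalescence candidates
      double tCoal = INF;
      int cd = -1;
      for (int d = 0; d < nDemes; ++d) {
        int k = demeLin[d].size();
        if (k < 2) continue;
        double s = coal_wait(deme[d], t, k, rng);
        if (t + s < tCoal) { tCoal = t + s; cd = d; }
      }
      double tNext = std::min(std::min(tMig, tCoal), tEv);
      if (!std::isfinite(tNext))
        stop("demography never coalesces (disconnected demes?)");
      accum(tNext - t);
      t = tNext;
      if (tEv <= std::min(tMig, tCoal)) {
        apply_event(events[evIdx]);
        ++evIdx;
      } else if (tCoal <= tMig) {
        std::vector<int>& L = demeLin[cd];
        int i = rng.unif_int(L.size());
        int j = rng.unif_int(L.size() - 1);
        if (j >= i) ++j;
        int a = L[i], b = L[j];
        if (i < j) std::swap(i, j);  // remove larger index first
        L.erase(L.begin() + i);
        L.erase(L.begin() + j);
        int nid = merge(a, b, cd, t);
        L.push_back(nid);
        --nLive;
      } else {
        // migration: pick source deme weighted by k_d * mout[d]
        double u = rng.unif() * Rm;
        int sd = nDemes - 1;
        for (int d = 0; d < nDemes; ++d) {
          double w = demeLin[d].size() * mout[d];
          if (u < w) { sd = d; break; }
          u -= w;
        }
        int li = rng.unif_int(demeLin[sd].size());
        double v = rng.unif() * mout[sd];
        int dd = -1;
        for (int e = 0; e < nDemes; ++e) {
          double w = mig[sd * nDemes + e];
          if (!deme[e].active) continue;
          if (v < w) { dd = e; break; }
          v -= w;
        }
        if (dd < 0) continue;
        int lin = demeLin[sd][li];
        demeLin[sd].erase(demeLin[sd].begin() + li);
        demeLin[dd].push_back(lin);
      }
    }
  }

  void apply_event(const Event& ev) {
    if (ev.type == 0) {  // join: move lineages from d1 into d2
      std::vector<int>& src = demeLin[ev.d1];
      std::vector<int>& dst = demeLin[ev.d2];
      dst.insert(dst.end(), src.begin(), src.end());
      src.clear();
      deme[ev.d1].active = false;
      for (int e = 0; e < nDemes; ++e) {
        mig[ev.d1 * nDemes + e] = 0.0;
        mig[e * nDemes + ev.d1] = 0.0;
      }
      refresh_mout();
    } else if (ev.type == 1) {  // size/growth change
      deme[ev.d1].Nref = ev.size;
      deme[ev.d1].tref = ev.time;
      deme[ev.d1].r = ev.growth;
    } else {  // migration matrix replacement
      mig = ev.mig;
      for (int d = 0; d < nDemes; ++d)
        if (!deme[d].active)
          for (int e = 0; e < nDemes; ++e) {
            mig[d * nDemes + e] = 0.0;
            mig[e * nDemes + d] = 0.0;
          }
      refresh_mout();
    }
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector coal_expected_sfs(int nDemes, NumericVector N0,
                                NumericVector growth0, NumericMatrix mig0,
                                List events, IntegerVector samples, int nSims,
                                double seed) {
  Engine eng(nDemes, N0, growth0, mig0, events, samples,
             static_cast<uint64_t>(seed));
  // sampled demes and joint-cell geometry
  std::vector<int> sampDeme, stride;
  int nCells = 1;
  for (int d = 0; d < nDemes; ++d)
    if (samples[d] > 0) {
      sampDeme.push_back(d);
      stride.push_back(nCells);
      nCells *= samples[d] + 1;
    }
  int nSamp = sampDeme.size();
  int nTot = 0;
  for (int d = 0; d < nDemes; ++d) nTot += samples[d];
  std::vector<double> sfs(nCells, 0.0);

  // lineage cells: each lineage carries a precomputed linear cell index.
  std::vector<int> cell;           // per lineage id
  std::vector<std::vector<int>> cnt;  // per lineage id, counts per sampled deme

  std::vector<DemeState> deme0 = eng.deme;
  std::vector<double> mig0v = eng.mig;

  for (int s = 0; s < nSims; ++s) {
    cell.clear(); cnt.clear();
    eng.demeLin.assign(nDemes, {});
    int id = 0;
    for (int si = 0; si < nSamp; ++si) {
      int d = sampDeme[si];
      for (int i = 0; i < samples[d]; ++i) {
        std::vector<int> c(nSamp, 0);
        c[si] = 1;
        cnt.push_back(c);
        cell.push_back(stride[si]);
        eng.demeLin[d].push_back(id++);
      }
    }
    eng.nLive = nTot;
    eng.run(deme0, mig0v,
            [&](double dt) {
              for (int d = 0; d < nDemes; ++d)
                for (int lid : eng.demeLin[d]) sfs[cell[lid]] += dt;
            },
            [&](int a, int b, int, double) {
              std::vector<int> c(nSamp);
              int lin = 0;
              for (int si = 0; si < nSamp; ++si) {
                c[si] = cnt[a][si] + cnt[b][si];
                lin += stride[si] * c[si];
              }
              cnt.push_back(c);
              cell.push_back(lin);
              return (int)cnt.size() - 1;
            });
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }
  // the all-sampled cell is the MRCA class: no branch above the root
  for (double& v : sfs) v /= nSims;
  NumericVector out(sfs.begin(), sfs.end());
  IntegerVector dim(nSamp);
  for (int si = 0; si < nSamp; ++si) dim[si] = samples[sampDeme[si]] + 1;
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
List coal_sim_sites(int nDemes, NumericVector N0,
                    NumericVector growth0, NumericMatrix mig0,
                    List events, IntegerVector samples, int nLoci,
                    double seed) {
  Engine eng(nDemes, N0, growth0, mig0, events, samples,
             static_cast<uint64_t>(seed));
  int nTot = 0;
  for (int d = 0; d < nDemes; ++d) nTot += samples[d];
  IntegerMatrix geno(nTot, nLoci);  // haploid derived states
  NumericVector totlen(nLoci);      // total branch length per genealogy

  std::vector<DemeState> deme0 = eng.deme;
  std::vector<double> mig0v = eng.mig;
  // tree arrays (2*nTot - 1 nodes)
  std::vector<double> ntime;
  std::vector<int> lc, rc;

  for (int locus = 0; locus < nLoci; ++locus) {
    ntime.assign(nTot, 0.0);
    lc.assign(nTot, -1);
    rc.assign(nTot, -1);
    eng.demeLin.assign(nDemes, {});
    int id = 0;
    for (int d = 0; d < nDemes; ++d)
      for (int i = 0; i < samples[d]; ++i) eng.demeLin[d].push_back(id++);
    eng.nLive = nTot;
    eng.run(deme0, mig0v, [](double) {},
            [&](int a, int b, int, double t) {
              ntime.push_back(t);
              lc.push_back(a);
              rc.push_back(b);
              return (int)ntime.size() - 1;
            });
    int nNodes = ntime.size();  // root = nNodes - 1
    // parent time of node v: found via children links; compute branch lengths
    std::vector<double> blen(nNodes, 0.0);
    for (int v = nTot; v < nNodes; ++v) {
      blen[lc[v]] = ntime[v] - ntime[lc[v]];
      blen[rc[v]] = ntime[v] - ntime[rc[v]];
    }
    double total = 0.0;
    for (int v = 0; v < nNodes - 1; ++v) total += blen[v];
    totlen[locus] = total;
    double u = eng.rng.unif() * total;
    int mut = nNodes - 2;
    for (int v = 0; v < nNodes - 1; ++v) {
      if (u < blen[v]) { mut = v; break; }
      u -= blen[v];
    }
    // mark leaves under `mut`
    std::vector<int> stack = {mut};
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < nTot) geno(v, locus) = 1;
      else { stack.push_back(lc[v]); stack.push_back(rc[v]); }
    }
    if (locus % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Named("geno") = geno, Named("totlen") = totlen);
}
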