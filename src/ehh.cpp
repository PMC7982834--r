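#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Extended haplotype homozygosity by outward group splitting.
//
// Haplotypes carrying the core allele start in one group; moving marker by
// marker away from the core, each group splits by the allele carried, and
// EHH at that distance is the probability that two distinct carrier
// haplotypes are still in the same group:
//   EHH(x) = sum_g C(n_g, 2) / C(n_c, 2).
// EHH is non-increasing in |offset| by construction (groups only split).

struct GroupTracker {
  std::vector<int> group;   // group id per haplotype
  int n;
  explicit GroupTracker(int n_) : group(n_, 0), n(n_) {}
  // split groups by alleles at one site; returns homozygosity
  double step(const int* alleles, const std::vector<int>& rows) {
    std::unordered_map<long long, int> relab;
    relab.reserve(group.size() * 2);
    std::vector<int> sz;
    for (size_t i = 0; i < group.size(); ++i) {
      long long key = (static_cast<long long>(group[i]) << 1) |
        alleles[rows[i]];
      auto it = relab.find(key);
      int id;
      if (it == relab.end()) {
        id = static_cast<int>(sz.size());
        relab.emplace(key, id);
        sz.push_back(0);
      } else id = it->second;
      group[i] = id;
      sz[id] += 1;
    }
    double pairs = 0.0;
    for (int s : sz) pairs += 0.5 * s * (s - 1.0);
    double tot = 0.5 * n * (n - 1.0);
    return tot > 0 ? pairs / tot : NA_REAL;
  }
};

// EHH curve for one carrier set around a core site.
// H: haplotypes x sites (one chromosome, positions ascending);
// carriers: 0-based haplotype rows; core: 0-based site index.
// Extends in both directions until EHH < floor (that value is recorded)
// or the chromosome end. Returns ascending site indices with EHH values.
// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix H, int core, IntegerVector carriers,
                   double floor_) {
  const int m = H.ncol();
  std::vector<int> rows(carriers.begin(), carriers.end());
  const int nc = static_cast<int>(rows.size());
  if (nc < 2) return List::create(_["site"] = IntegerVector(0),
                                  _["ehh"] = NumericVector(0),
                                  _["defined"] = false);
  std::vector<int> site_l, site_r;
  std::vector<double> ehh_l, ehh_r;
  std::vector<int> colbuf(H.nrow());
  for (int dir = -1; dir <= 1; dir += 2) {
    GroupTracker tr(nc);
    for (int s = core + dir; s >= 0 && s < m; s += dir) {
      for (int i = 0; i < H.nrow(); ++i) colbuf[i] = H(i, s);
      double e = tr.step(colbuf.data(), rows);
      if (dir < 0) { site_l.push_back(s); ehh_l.push_back(e); }
      else { site_r.push_back(s); ehh_r.push_back(e); }
      if (e < floor_) break;
    }
  }
  const int total = static_cast<int>(site_l.size() + 1 + site_r.size());
  IntegerVector site(total);
  NumericVector ehh(total);
  int idx = 0;
  for (int i = static_cast<int>(site_l.size()) - 1; i >= 0; --i) {
    site[idx] = site_l[i]; ehh[idx] = ehh_l[i]; ++idx;
  }
  site[idx] = core; ehh[idx] = 1.0; ++idx;
  for (size_t i = 0; i < site_r.size(); ++i) {
    site[idx] = site_r[i]; ehh[idx] = ehh_r[i]; ++idx;
  }
  return List::create(_["site"] = site, _["ehh"] = ehh,
                      _["defined"] = true);
}

// Site-level integrated EHH (iES) for every site of one chromosome.
// The two allele-specific EHH curves are combined with pair-count
// weights, w_a = C(n_a,2) / (C(n_a,2) + C(n_d,2)), so the combined curve
// equals the probability that two random haplotypes sharing the core
// allele carry identical extended haplotypes. Integration is trapezoidal
// over physical distance, truncated where the combined EHH drops below
// `floor_`.
// [[Rcpp::export(name = ".ies_scan_cpp")]]
NumericVector ies_scan_cpp(IntegerMatrix H, NumericVector pos,
                           double floor_) {
  const int m = H.ncol();
  const int nh = H.nrow();
  NumericVector ies(m);
  std::vector<int> colbuf(nh);
  for (int core = 0; core < m; ++core) {
    std::vector<int> rows_a, rows_d;
    for (int i = 0; i < nh; ++i)
      (H(i, core) == 0 ? rows_a : rows_d).push_back(i);
    const double na = rows_a.size(), nd = rows_d.size();
    const double pa = 0.5 * na * (na - 1.0), pd = 0.5 * nd * (nd - 1.0);
    if (pa + pd <= 0) { ies[core] = NA_REAL; continue; }
    const double wa = pa / (pa + pd), wd = pd / (pa + pd);
    double total = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      GroupTracker tra(static_cast<int>(na)), trd(static_cast<int>(nd));
      double prev_e = 1.0, prev_pos = pos[core];
      for (int s = core + dir; s >= 0 && s < m; s += dir) {
        for (int i = 0; i < nh; ++i) colbuf[i] = H(i, s);
        double ea = na >= 2 ? tra.step(colbuf.data(), rows_a) : 0.0;
        double ed = nd >= 2 ? trd.step(colbuf.data(), rows_d) : 0.0;
        double e = wa * ea + wd * ed;
        if (e < floor_) break;
        total += 0.5 * (prev_e + e) * fabs(pos[s] - prev_pos);
        prev_e = e; prev_pos = pos[s];
      }
    }
    ies[core] = total;
  }
  return ies;
}
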