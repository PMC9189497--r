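// Compiled Wright-Fisher generation step.
//
// Mirrors the reference R implementation (.next_generation_r /
// .assemble_gamete) exactly in distribution; both engines draw from R's RNG
// so either is reproducible under set.seed. The gamete is assembled by
// walking the informative points (parental mutation positions, plus the
// inversion start for heterokaryotypes) in genomic order and drawing the
// crossover-count parity of each interval directly (an interval of
// effective length d flips the source chromatid with probability
// (1 - exp(-2 rho d))/2; the effective length excludes the inversion
// interval in heterokaryotypes). Gene-conversion initiations are thinned to
// the windows that can reach a mutable segment; each tract toggles the
// source inside [start, start+len) for content but never for the
// arrangement label. Chromosomes assort independently through an obligate
// 1/2 toggle at the chromosome boundary.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double INF = R_PosInf;

// [[Rcpp::export(name = ".cpp_next_generation")]]
List cpp_next_generation(List haps, IntegerVector arr, NumericVector fitness,
                         int N_next,
                         double rho, double inv1, double inv2, double chrb,
                         NumericVector gws, NumericVector gwcum, double gwtot,
                         double lambda, double gc_rate,
                         double u_del, double u_ben,
                         double h_del, double h_ben,
                         double s_scale, double alpha_g, double beta_g,
                         double kappa,
                         NumericVector cat_pos, NumericVector cat_s,
                         NumericVector cat_h, int n_cat,
                         NumericVector seg_start, NumericVector seg_cum,
                         double seg_total, bool selfing) {
  const int N = fitness.size();
  const int M = 2 * N_next;
  const int n_win = gws.size();

  // cumulative fitness for weighted parent sampling
  std::vector<double> cw(N);
  double acc = 0.0;
  int n_viable = 0;
  for (int i = 0; i < N; ++i) {
    if (fitness[i] > 0) ++n_viable;
    acc += fitness[i];
    cw[i] = acc;
  }
  if (acc <= 0) stop("all fitnesses are zero");
  auto draw_parent = [&]() -> int {
    double u = unif_rand() * acc;
    return (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
  };

  std::vector<double> new_pos, new_s, new_h;
  auto posof = [&](int id) -> double {
    return id <= n_cat ? cat_pos[id - 1] : new_pos[id - n_cat - 1];
  };
  auto sof = [&](int id) -> double {
    return id <= n_cat ? cat_s[id - 1] : new_s[id - n_cat - 1];
  };
  auto hof = [&](int id) -> double {
    return id <= n_cat ? cat_h[id - 1] : new_h[id - n_cat - 1];
  };

  // map a uniform draw on the segment union to a genomic position
  auto seg_pos = [&](double u) -> double {
    int j = (int)(std::upper_bound(seg_cum.begin(), seg_cum.end(), u) -
                  seg_cum.begin());
    if (j >= seg_cum.size()) j = seg_cum.size() - 1;
    double base = j > 0 ? seg_cum[j - 1] : 0.0;
    return seg_start[j] + (u - base);
  };

  std::vector<std::vector<int> > new_haps(M);
  IntegerVector new_arr(M);
  std::vector<double> tg; // gene-conversion toggles, reused per meiosis
  std::vector<int> dn;    // de novo ids, reused

  // one meiosis for parent p (0-based); returns arrangement label, fills out
  auto meiose = [&](int p, std::vector<int>& out) -> int {
    IntegerVector h1 = haps[2 * p];
    IntegerVector h2 = haps[2 * p + 1];
    const int a1 = arr[2 * p], a2 = arr[2 * p + 1];
    const int n1 = h1.size(), n2 = h2.size();
    const bool het = a1 != a2;

    // de novo mutations for this gamete (ids follow catalog order)
    dn.clear();
    int nd = (int)R::rpois(u_del);
    int nb = u_ben > 0 ? (int)R::rpois(u_ben) : 0;
    for (int k = 0; k < nd; ++k) {
      new_pos.push_back(seg_pos(unif_rand() * seg_total));
      new_s.push_back(-s_scale * R::rgamma(alpha_g, 1.0 / beta_g));
      new_h.push_back(h_del);
      dn.push_back(n_cat + (int)new_pos.size());
    }
    for (int k = 0; k < nb; ++k) {
      new_pos.push_back(seg_pos(unif_rand() * seg_total));
      new_s.push_back(s_scale * R::rexp(kappa));
      new_h.push_back(h_ben);
      dn.push_back(n_cat + (int)new_pos.size());
    }

    out.clear();
    if (n1 == 0 && n2 == 0) {
      out = dn; // positions were generated in increasing-id order, not pos
      std::sort(out.begin(), out.end(), [&](int a, int b) {
        return posof(a) < posof(b);
      });
      return (!het || unif_rand() < 0.5) ? a1 : a2;
    }

    // gene-conversion toggles (content only)
    int ngc = gc_rate > 0 ? (int)R::rpois(gc_rate) : 0;
    tg.clear();
    for (int k = 0; k < ngc; ++k) {
      double u = unif_rand() * gwtot;
      int j = (int)(std::upper_bound(gwcum.begin(), gwcum.end(), u) -
                    gwcum.begin());
      if (j >= n_win) j = n_win - 1;
      double st = gws[j] + (u - (j > 0 ? gwcum[j - 1] : 0.0));
      tg.push_back(st);
      tg.push_back(st + R::rpois(lambda));
    }
    std::sort(tg.begin(), tg.end());

    const int k0 = unif_rand() < 0.5 ? 0 : 1; // starting chromatid (0 = h1)
    const bool bnd = unif_rand() < 0.5;       // chromosome-boundary toggle
    const double inv_len = inv2 - inv1;
    int par = 0;      // crossover parity
    double eprev = 0; // effective (crossover-permitted) coordinate so far
    int lab_par = 0;  // crossover parity at the inversion start
    size_t gci = 0;   // toggles consumed so far
    int i1 = 0, i2 = 0;
    bool inv_done = !het;
    std::vector<int> tmp;
    tmp.reserve(n1 + n2);
    while (i1 < n1 || i2 < n2 || !inv_done) {
      double q1 = i1 < n1 ? posof(h1[i1]) : INF;
      double q2 = i2 < n2 ? posof(h2[i2]) : INF;
      double qi = inv_done ? INF : inv1;
      int which;
      double q;
      if (q1 <= q2 && q1 <= qi) { which = 1; q = q1; }
      else if (q2 <= qi)        { which = 2; q = q2; }
      else                      { which = 0; q = qi; }
      double e = het ? q - std::min(std::max(q - inv1, 0.0), inv_len) : q;
      double d = e - eprev;
      eprev = e;
      if (d > 0 && unif_rand() < 0.5 * (1.0 - std::exp(-2.0 * rho * d)))
        par ^= 1;
      int par_eff = par;
      if (bnd && q >= chrb) par_eff ^= 1;
      if (which == 0) { lab_par = par_eff; inv_done = true; continue; }
      while (gci < tg.size() && tg[gci] <= q) ++gci;
      int pc = par_eff ^ (int)(gci & 1);
      int src = pc ? 1 - k0 : k0;
      if (which == 1) {
        if (src == 0) tmp.push_back(h1[i1]);
        ++i1;
      } else {
        if (src == 1) tmp.push_back(h2[i2]);
        ++i2;
      }
    }
    // merge parental content (already position-sorted) with de novo
    if (dn.empty()) {
      out.swap(tmp);
    } else {
      std::sort(dn.begin(), dn.end(), [&](int a, int b) {
        return posof(a) < posof(b);
      });
      out.reserve(tmp.size() + dn.size());
      size_t ia = 0, ib = 0;
      while (ia < tmp.size() && ib < dn.size()) {
        if (posof(tmp[ia]) <= posof(dn[ib])) out.push_back(tmp[ia++]);
        else out.push_back(dn[ib++]);
      }
      while (ia < tmp.size()) out.push_back(tmp[ia++]);
      while (ib < dn.size()) out.push_back(dn[ib++]);
    }
    if (!het) return a1;
    int src_inv = lab_par ? 1 - k0 : k0;
    return src_inv == 0 ? a1 : a2;
  };

  for (int i = 0; i < N_next; ++i) {
    int pa = draw_parent();
    int pb = draw_parent();
    if (!selfing && n_viable > 1) {
      while (pb == pa) pb = draw_parent();
    }
    new_arr[2 * i] = meiose(pa, new_haps[2 * i]);
    new_arr[2 * i + 1] = meiose(pb, new_haps[2 * i + 1]);
  }

  // prune mutations fixed among the offspring
  std::vector<int> all;
  for (int j = 0; j < M; ++j)
    all.insert(all.end(), new_haps[j].begin(), new_haps[j].end());
  std::sort(all.begin(), all.end());
  std::vector<int> fixed;
  for (size_t i = 0; i < all.size();) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    if ((int)(j - i) == M) fixed.push_back(all[i]);
    i = j;
  }
  if (!fixed.empty()) {
    for (int j = 0; j < M; ++j) {
      std::vector<int>& h = new_haps[j];
      h.erase(std::remove_if(h.begin(), h.end(), [&](int id) {
                return std::binary_search(fixed.begin(), fixed.end(), id);
              }),
              h.end());
    }
  }

  // fitness of the offspring (multiplicative, factors floored at 0)
  NumericVector new_fit(N_next);
  for (int i = 0; i < N_next; ++i) {
    const std::vector<int>& A = new_haps[2 * i];
    const std::vector<int>& B = new_haps[2 * i + 1];
    double w = 1.0;
    size_t ia = 0, ib = 0;
    while (w > 0 && (ia < A.size() || ib < B.size())) {
      double pa = ia < A.size() ? posof(A[ia]) : INF;
      double pb = ib < B.size() ? posof(B[ib]) : INF;
      double f;
      if (pa == pb && A[ia] == B[ib]) {
        f = 1.0 + sof(A[ia]);
        ++ia; ++ib;
      } else if (pa <= pb) {
        f = 1.0 + hof(A[ia]) * sof(A[ia]);
        ++ia;
      } else {
        f = 1.0 + hof(B[ib]) * sof(B[ib]);
        ++ib;
      }
      w *= f > 0 ? f : 0.0;
    }
    new_fit[i] = w;
  }

  List out_haps(M);
  for (int j = 0; j < M; ++j) out_haps[j] = wrap(new_haps[j]);
  return List::create(_["haps"] = out_haps, _["arr"] = new_arr,
                      _["fitness"] = new_fit,
                      _["fixed"] = wrap(fixed),
                      _["new_pos"] = wrap(new_pos),
                      _["new_s"] = wrap(new_s), _["new_h"] = wrap(new_h));
}
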