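#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
// Pedigree must be in topological order (parents before offspring);
// sire/dam are 1-based indices into the same ordering, 0 = unknown.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector inbreeding_ml_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n);     // Mendelian sampling variance of each animal
  std::vector<double> coef(n, 0.0);
  std::vector<int> anc;         // ancestor work list (indices with coef != 0)
  anc.reserve(256);

  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, ds = dam[i] - 1;
    double fs = (s >= 0) ? F[s] : 0.0;
    double fd = (ds >= 0) ? F[ds] : 0.0;
    if (s >= 0 && ds >= 0)      d[i] = 0.5 - 0.25 * (fs + fd);
    else if (s >= 0 || ds >= 0) d[i] = 0.75 - 0.25 * (fs + fd);
    else                        d[i] = 1.0;

    if (s < 0 && ds < 0) { F[i] = 0.0; continue; }

    // A_ii = sum_j T_ij^2 d_j over ancestors j (including i); F_i = A_ii - 1
    anc.clear();
    coef[i] = 1.0;
    anc.push_back(i);
    std::make_heap(anc.begin(), anc.end());
    double aii = 0.0;
    while (!anc.empty()) {
      std::pop_heap(anc.begin(), anc.end());
      int j = anc.back();
      anc.pop_back();
      double c = coef[j];
      if (c == 0.0) continue;   // duplicate heap entry already processed
      coef[j] = 0.0;
      aii += c * c * d[j];
      int js = sire[j] - 1, jd = dam[j] - 1;
      if (js >= 0) {
        if (coef[js] == 0.0) { anc.push_back(js); std::push_heap(anc.begin(), anc.end()); }
        coef[js] += 0.5 * c;
      }
      if (jd >= 0) {
        if (coef[jd] == 0.0) { anc.push_back(jd); std::push_heap(anc.begin(), anc.end()); }
        coef[jd] += 0.5 * c;
      }
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// ---------------------------------------------------------------------------
// Single-site Gibbs sampler for the threshold repeatability animal model
//   liability = parity + hys + animal + pe + e,   e ~ N(0, 1)
// with a single threshold fixed at 0 and residual variance fixed at 1.
// Variance updates are scaled-inverse-chi-square; the additive effect uses
// the sparse symmetric A-inverse (full storage, CSR).
// Uses R's RNG, so results are exactly reproducible under set.seed().
// ---------------------------------------------------------------------------

// standard normal truncated to Z > a: naive rejection near the centre,
// Robert's (1995) exponential rejection in the tail
static inline double rtnorm_tail(double a) {
  if (a < 0.5) {
    for (;;) {
      double z = norm_rand();
      if (z > a) return z;
    }
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / alpha;
    double d = z - alpha;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return z;
  }
}

static inline double rtnorm01(double mean, bool positive) {
  // draw from N(mean, 1) truncated at 0 (above if positive, below otherwise)
  if (positive) return mean + rtnorm_tail(-mean);
  return mean - rtnorm_tail(mean);
}

struct LevelIndex {
  // CSR-style map level -> record indices
  std::vector<int> ptr, idx;
  void build(const IntegerVector& lev, int n_lev) {
    int n = lev.size();
    ptr.assign(n_lev + 1, 0);
    for (int r = 0; r < n; ++r) ptr[lev[r] + 1]++;
    for (int l = 0; l < n_lev; ++l) ptr[l + 1] += ptr[l];
    idx.assign(n, 0);
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int r = 0; r < n; ++r) idx[fill[lev[r]]++] = r;
  }
};

// [[Rcpp::export]]
List gibbs_threshold_cpp(IntegerVector y,
                         NumericVector liab_obs, bool gaussian,
                         IntegerVector parity, IntegerVector hys,
                         IntegerVector animal, IntegerVector pe,
                         IntegerVector pe_of_animal,
                         int n_parity, int n_hys, int n_animal, int n_pe,
                         IntegerVector Ai_p, IntegerVector Ai_j, NumericVector Ai_x,
                         int n_iter, int burn_in, int thin,
                         double nu0, double s2_a0, double s2_pe0, double s2_hys0,
                         double init_a, double init_pe, double init_hys) {
  RNGScope scope;
  const int n = y.size();

  LevelIndex Ipar, Ihys, Iani, Ipe;
  Ipar.build(parity, n_parity);
  Ihys.build(hys, n_hys);
  Iani.build(animal, n_animal);
  Ipe.build(pe, n_pe);

  std::vector<double> beta(n_parity, 0.0), h(n_hys, 0.0),
                      a(n_animal, 0.0), p(n_pe, 0.0);
  std::vector<bool> pe_owner_flag(n_pe, false);
  for (int i = 0; i < n_animal; ++i) {
    if (pe_of_animal[i] >= 0) pe_owner_flag[pe_of_animal[i]] = true;
  }
  std::vector<double> lambda(n, 0.0), e(n, 0.0);
  double s2a = init_a, s2pe = init_pe, s2hys = init_hys;

  if (gaussian) for (int r = 0; r < n; ++r) lambda[r] = liab_obs[r];
  for (int r = 0; r < n; ++r) e[r] = lambda[r];  // all effects start at 0

  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector keep_a(n_keep), keep_pe(n_keep), keep_hys(n_keep);
  std::vector<double> sum_a(n_animal, 0.0), sum_beta(n_parity, 0.0),
                      sum_h(n_hys, 0.0), sum_p(n_pe, 0.0);
  int kept = 0, accum = 0;

  for (int it = 0; it < n_iter; ++it) {
    // -- 1. liabilities (data augmentation) --------------------------------
    if (!gaussian) {
      for (int r = 0; r < n; ++r) {
        double mu = lambda[r] - e[r];  // current fitted value
        double lnew = rtnorm01(mu, y[r] == 1);
        e[r] += lnew - lambda[r];
        lambda[r] = lnew;
      }
    }

    // -- 2. fixed parity effects (flat prior) ------------------------------
    for (int l = 0; l < n_parity; ++l) {
      int nl = Ipar.ptr[l + 1] - Ipar.ptr[l];
      if (nl == 0) continue;
      double s = 0.0;
      for (int k = Ipar.ptr[l]; k < Ipar.ptr[l + 1]; ++k) s += e[Ipar.idx[k]];
      double mean = (s + nl * beta[l]) / nl;
      double neu = mean + norm_rand() / std::sqrt((double)nl);
      double delta = neu - beta[l];
      beta[l] = neu;
      for (int k = Ipar.ptr[l]; k < Ipar.ptr[l + 1]; ++k) e[Ipar.idx[k]] -= delta;
    }

    // -- 3. HYS effects ----------------------------------------------------
    double lam_h = 1.0 / s2hys;
    for (int l = 0; l < n_hys; ++l) {
      int nl = Ihys.ptr[l + 1] - Ihys.ptr[l];
      double s = 0.0;
      for (int k = Ihys.ptr[l]; k < Ihys.ptr[l + 1]; ++k) s += e[Ihys.idx[k]];
      double prec = nl + lam_h;
      double mean = (s + nl * h[l]) / prec;
      double neu = mean + norm_rand() / std::sqrt(prec);
      double delta = neu - h[l];
      h[l] = neu;
      for (int k = Ihys.ptr[l]; k < Ihys.ptr[l + 1]; ++k) e[Ihys.idx[k]] -= delta;
    }

    // -- 4. additive animal effects with A-inverse; for animals that also
    //       carry a permanent-environment level the (a, pe) pair is drawn
    //       jointly from its bivariate full conditional, which mixes far
    //       better than alternating single-site draws of two effects that
    //       enter every record identically
    double lam_a = 1.0 / s2a;
    double lam_p = 1.0 / s2pe;
    for (int i = 0; i < n_animal; ++i) {
      int nl = Iani.ptr[i + 1] - Iani.ptr[i];
      double s = 0.0;
      for (int k = Iani.ptr[i]; k < Iani.ptr[i + 1]; ++k) s += e[Iani.idx[k]];
      double off = 0.0, dii = 0.0;
      for (int k = Ai_p[i]; k < Ai_p[i + 1]; ++k) {
        int j = Ai_j[k];
        if (j == i) dii = Ai_x[k];
        else        off += Ai_x[k] * a[j];
      }
      int l = pe_of_animal[i];
      if (l < 0 || nl == 0) {
        double prec = nl + lam_a * dii;
        double mean = (s + nl * a[i] - lam_a * off) / prec;
        double neu = mean + norm_rand() / std::sqrt(prec);
        double delta = neu - a[i];
        a[i] = neu;
        if (l >= 0) {  // record-less cow: pe from its prior
          double pneu = norm_rand() / std::sqrt(lam_p);
          p[l] = pneu;
        }
        for (int k = Iani.ptr[i]; k < Iani.ptr[i + 1]; ++k) e[Iani.idx[k]] -= delta;
      } else {
        double rsum = s + nl * (a[i] + p[l]);
        double q11 = nl + lam_a * dii, q22 = nl + lam_p, q12 = (double)nl;
        double b1 = rsum - lam_a * off, b2 = rsum;
        double det = q11 * q22 - q12 * q12;
        double m1 = (q22 * b1 - q12 * b2) / det;
        double m2 = (q11 * b2 - q12 * b1) / det;
        // sample via the Cholesky of the precision: x = m + L^-T z
        double L11 = std::sqrt(q11), L21 = q12 / L11;
        double L22 = std::sqrt(q22 - L21 * L21);
        double z1 = norm_rand(), z2 = norm_rand();
        double w2 = z2 / L22;
        double w1 = (z1 - L21 * w2) / L11;
        double anew = m1 + w1, pnew = m2 + w2;
        double delta = (anew + pnew) - (a[i] + p[l]);
        a[i] = anew;
        p[l] = pnew;
        for (int k = Iani.ptr[i]; k < Iani.ptr[i + 1]; ++k) e[Iani.idx[k]] -= delta;
      }
    }

    // -- 5. permanent-environment levels not tied to an animal (none in the
    //       usual layout, kept for completeness)
    for (int l = 0; l < n_pe; ++l) {
      if (pe_owner_flag[l]) continue;
      int nl = Ipe.ptr[l + 1] - Ipe.ptr[l];
      double s = 0.0;
      for (int k = Ipe.ptr[l]; k < Ipe.ptr[l + 1]; ++k) s += e[Ipe.idx[k]];
      double prec = nl + lam_p;
      double mean = (s + nl * p[l]) / prec;
      double neu = mean + norm_rand() / std::sqrt(prec);
      double delta = neu - p[l];
      p[l] = neu;
      for (int k = Ipe.ptr[l]; k < Ipe.ptr[l + 1]; ++k) e[Ipe.idx[k]] -= delta;
    }

    // -- 6. variance components (scaled inverse chi-square) ----------------
    double qa = 0.0;
    for (int i = 0; i < n_animal; ++i) {
      double row = 0.0;
      for (int k = Ai_p[i]; k < Ai_p[i + 1]; ++k) row += Ai_x[k] * a[Ai_j[k]];
      qa += a[i] * row;
    }
    s2a = (qa + nu0 * s2_a0) / R::rchisq((double)n_animal + nu0);
    double qp = 0.0;
    for (int l = 0; l < n_pe; ++l) qp += p[l] * p[l];
    s2pe = (qp + nu0 * s2_pe0) / R::rchisq((double)n_pe + nu0);
    double qh = 0.0;
    for (int l = 0; l < n_hys; ++l) qh += h[l] * h[l];
    s2hys = (qh + nu0 * s2_hys0) / R::rchisq((double)n_hys + nu0);

    // -- 7. store ----------------------------------------------------------
    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      keep_a[kept] = s2a; keep_pe[kept] = s2pe; keep_hys[kept] = s2hys;
      ++kept;
    }
    if (it >= burn_in) {
      for (int i = 0; i < n_animal; ++i) sum_a[i] += a[i];
      for (int l = 0; l < n_parity; ++l) sum_beta[l] += beta[l];
      for (int l = 0; l < n_hys; ++l) sum_h[l] += h[l];
      for (int l = 0; l < n_pe; ++l) sum_p[l] += p[l];
      ++accum;
    }
  }

  NumericVector pm_a(n_animal), pm_beta(n_parity), pm_h(n_hys), pm_p(n_pe);
  for (int i = 0; i < n_animal; ++i) pm_a[i] = sum_a[i] / accum;
  for (int l = 0; l < n_parity; ++l) pm_beta[l] = sum_beta[l] / accum;
  for (int l = 0; l < n_hys; ++l) pm_h[l] = sum_h[l] / accum;
  for (int l = 0; l < n_pe; ++l) pm_p[l] = sum_p[l] / accum;

  return List::create(
    _["sigma2_a"] = keep_a, _["sigma2_pe"] = keep_pe, _["sigma2_hys"] = keep_hys,
    _["mean_animal"] = pm_a, _["mean_parity"] = pm_beta,
    _["mean_hys"] = pm_h, _["mean_pe"] = pm_p);
}
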