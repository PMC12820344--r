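// Weighted interval-censored log-likelihood for the five-state interpolated
// Markov chain model, with analytic gradient.
//
// The R side packs each person's observation sequence into a flat stream of
// operations over a scaled forward vector alpha (length 5, dead = index 4):
//   type 0: multiply by a (possibly fractional) step matrix
//   type 1: project on an observed living state (op_arg = state 0..3)
//   type 2: project on "alive, state unknown" (zero the dead entry)
//   type 3: terminal death step (sum_j alpha_j * frac * P[j][dead])
// Fractional steps use P_f = (1-f) I + f P. The person log-likelihood is the
// sum of the log projection constants; the gradient is computed by reverse
// accumulation through the same stream.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Packed {
  int npairs, npp, ncov, has_age;
  const int *pfrom, *pto;   // 0-based
  int nsteps;
  const double *step_t;     // age - centre at step start
  const double *step_frac;  // (0, 1]
  const int *step_x;        // 0-based column of X
  int nX;
  const double *X;          // ncov x nX, column-major
  int nops;
  const int *op_type, *op_arg;
  int nper;
  const int *p_start, *p_nops, *p_init;
  const double *w;
};

Packed unpack(const List &pack, const IntegerVector &pfrom,
              const IntegerVector &pto, const NumericVector &step_t,
              const NumericVector &step_frac, const IntegerVector &step_x,
              const NumericMatrix &X, const IntegerVector &op_type,
              const IntegerVector &op_arg, const IntegerVector &p_start,
              const IntegerVector &p_nops, const IntegerVector &p_init,
              const NumericVector &w) {
  Packed pk;
  pk.npairs = pfrom.size();
  pk.npp = as<int>(pack["npp"]);
  pk.ncov = as<int>(pack["ncov"]);
  pk.has_age = as<int>(pack["has_age"]);
  pk.pfrom = pfrom.begin();
  pk.pto = pto.begin();
  pk.nsteps = step_t.size();
  pk.step_t = step_t.begin();
  pk.step_frac = step_frac.begin();
  pk.step_x = step_x.begin();
  pk.nX = X.ncol();
  pk.X = X.begin();
  pk.nops = op_type.size();
  pk.op_type = op_type.begin();
  pk.op_arg = op_arg.begin();
  pk.nper = p_start.size();
  pk.p_start = p_start.begin();
  pk.p_nops = p_nops.begin();
  pk.p_init = p_init.begin();
  pk.w = w.begin();
  return pk;
}

// Phase A: all step matrices (living rows only; dead row implicit).
// P is nsteps x 25 row-major blocks: P[s*25 + i*5 + j].
void build_matrices(const Packed &pk, const double *par,
                    std::vector<double> &P, std::vector<int> &row_pairs,
                    std::vector<int> &row_npairs) {
  // covariate dot products D[p][x]
  std::vector<double> D((size_t)pk.npairs * pk.nX, 0.0);
  if (pk.ncov > 0) {
    for (int p = 0; p < pk.npairs; ++p) {
      const double *cp = par + (size_t)p * pk.npp + 1 + pk.has_age;
      for (int x = 0; x < pk.nX; ++x) {
        double d = 0.0;
        const double *xc = pk.X + (size_t)x * pk.ncov;
        for (int c = 0; c < pk.ncov; ++c) d += cp[c] * xc[c];
        D[(size_t)p * pk.nX + x] = d;
      }
    }
  }
  // pairs grouped by origin row
  row_npairs.assign(4, 0);
  row_pairs.assign(16, -1);
  for (int p = 0; p < pk.npairs; ++p) {
    int i = pk.pfrom[p];
    row_pairs[i * 4 + row_npairs[i]] = p;
    row_npairs[i]++;
  }
  P.assign((size_t)pk.nsteps * 25, 0.0);
  std::vector<double> eta(4);
  for (int s = 0; s < pk.nsteps; ++s) {
    double *Ps = &P[(size_t)s * 25];
    double t = pk.step_t[s];
    int x = pk.step_x[s];
    Ps[4 * 5 + 4] = 1.0;
    for (int i = 0; i < 4; ++i) {
      int k = row_npairs[i];
      if (k == 0) { Ps[i * 5 + i] = 1.0; continue; }
      double m = 0.0;
      for (int q = 0; q < k; ++q) {
        int p = row_pairs[i * 4 + q];
        double e = par[(size_t)p * pk.npp];
        if (pk.has_age) e += par[(size_t)p * pk.npp + 1] * t;
        if (pk.ncov) e += D[(size_t)p * pk.nX + x];
        eta[q] = e;
        if (e > m) m = e;
      }
      double z = std::exp(-m);
      double self = z;
      for (int q = 0; q < k; ++q) {
        eta[q] = std::exp(eta[q] - m);
        z += eta[q];
      }
      for (int q = 0; q < k; ++q) {
        int p = row_pairs[i * 4 + q];
        Ps[i * 5 + pk.pto[p]] = eta[q] / z;
      }
      Ps[i * 5 + i] = self / z;
    }
  }
}

inline void apply_step(const double *Ps, double frac, const double *a,
                       double *b) {
  for (int j = 0; j < 5; ++j) {
    double s = 0.0;
    for (int i = 0; i < 4; ++i) s += a[i] * Ps[i * 5 + j];
    b[j] = frac * s;
  }
  b[4] += a[4];                    // dead row of P is e_dead
  if (frac != 1.0) {
    for (int j = 0; j < 5; ++j) b[j] += (1.0 - frac) * a[j];
    b[4] -= (1.0 - frac) * a[4];   // already carried in full
  }
}

}  // namespace

// [[Rcpp::export]]
double negloglik_cpp(NumericVector par, List pack) {
  IntegerVector pfrom = pack["pair_from"], pto = pack["pair_to"];
  NumericVector step_t = pack["step_t"], step_frac = pack["step_frac"];
  IntegerVector step_x = pack["step_x"];
  NumericMatrix X = pack["X"];
  IntegerVector op_type = pack["op_type"], op_arg = pack["op_arg"];
  IntegerVector p_start = pack["p_start"], p_nops = pack["p_nops"],
                p_init = pack["p_init"];
  NumericVector w = pack["w"];
  Packed pk = unpack(pack, pfrom, pto, step_t, step_frac, step_x, X, op_type,
                     op_arg, p_start, p_nops, p_init, w);
  std::vector<double> P;
  std::vector<int> rp, rn;
  build_matrices(pk, par.begin(), P, rp, rn);

  double total = 0.0;
  double a[5], b[5];
  for (int ip = 0; ip < pk.nper; ++ip) {
    for (int j = 0; j < 5; ++j) a[j] = 0.0;
    a[pk.p_init[ip]] = 1.0;
    double logl = 0.0;
    int o0 = pk.p_start[ip], o1 = o0 + pk.p_nops[ip];
    for (int o = o0; o < o1; ++o) {
      int tp = pk.op_type[o], arg = pk.op_arg[o];
      if (tp == 0) {
        const double *Ps = &P[(size_t)arg * 25];
        apply_step(Ps, pk.step_frac[arg], a, b);
        for (int j = 0; j < 5; ++j) a[j] = b[j];
      } else if (tp == 1) {
        double c = a[arg];
        if (!(c > 0.0)) { logl = R_NegInf; break; }
        logl += std::log(c);
        for (int j = 0; j < 5; ++j) a[j] = 0.0;
        a[arg] = 1.0;
      } else if (tp == 2) {
        a[4] = 0.0;
        double c = a[0] + a[1] + a[2] + a[3];
        if (!(c > 0.0)) { logl = R_NegInf; break; }
        logl += std::log(c);
        for (int j = 0; j < 4; ++j) a[j] /= c;
      } else {  // death
        const double *Ps = &P[(size_t)arg * 25];
        double f = pk.step_frac[arg];
        double c = 0.0;
        for (int i = 0; i < 4; ++i) c += a[i] * f * Ps[i * 5 + 4];
        if (!(c > 0.0)) { logl = R_NegInf; break; }
        logl += std::log(c);
      }
    }
    if (logl == R_NegInf) return R_PosInf;
    total += pk.w[ip] * logl;
  }
  return -total;
}

// [[Rcpp::export]]
List negloglik_grad_cpp(NumericVector par, List pack) {
  IntegerVector pfrom = pack["pair_from"], pto = pack["pair_to"];
  NumericVector step_t = pack["step_t"], step_frac = pack["step_frac"];
  IntegerVector step_x = pack["step_x"];
  NumericMatrix X = pack["X"];
  IntegerVector op_type = pack["op_type"], op_arg = pack["op_arg"];
  IntegerVector p_start = pack["p_start"], p_nops = pack["p_nops"],
                p_init = pack["p_init"];
  NumericVector w = pack["w"];
  Packed pk = unpack(pack, pfrom, pto, step_t, step_frac, step_x, X, op_type,
                     op_arg, p_start, p_nops, p_init, w);
  std::vector<double> P;
  std::vector<int> rp, rn;
  build_matrices(pk, par.begin(), P, rp, rn);

  int npar = par.size();
  NumericVector grad(npar);
  double total = 0.0;
  bool bad = false;

  std::vector<double> Astore;  // alpha before each op (5 per op)
  std::vector<double> cstore;  // projection constants per op
  double a[5], b[5], adj[5], adj0[5];

  for (int ip = 0; ip < pk.nper && !bad; ++ip) {
    int o0 = pk.p_start[ip], nops = pk.p_nops[ip];
    double wp = pk.w[ip];
    Astore.assign((size_t)nops * 5, 0.0);
    cstore.assign(nops, 1.0);
    for (int j = 0; j < 5; ++j) a[j] = 0.0;
    a[pk.p_init[ip]] = 1.0;
    double logl = 0.0;
    // forward
    for (int oo = 0; oo < nops; ++oo) {
      int o = o0 + oo;
      for (int j = 0; j < 5; ++j) Astore[(size_t)oo * 5 + j] = a[j];
      int tp = pk.op_type[o], arg = pk.op_arg[o];
      if (tp == 0) {
        const double *Ps = &P[(size_t)arg * 25];
        apply_step(Ps, pk.step_frac[arg], a, b);
        for (int j = 0; j < 5; ++j) a[j] = b[j];
      } else if (tp == 1) {
        double c = a[arg];
        if (!(c > 0.0)) { bad = true; break; }
        cstore[oo] = c;
        logl += std::log(c);
        for (int j = 0; j < 5; ++j) a[j] = 0.0;
        a[arg] = 1.0;
      } else if (tp == 2) {
        a[4] = 0.0;
        double c = a[0] + a[1] + a[2] + a[3];
        if (!(c > 0.0)) { bad = true; break; }
        cstore[oo] = c;
        logl += std::log(c);
        for (int j = 0; j < 4; ++j) a[j] /= c;
      } else {
        const double *Ps = &P[(size_t)arg * 25];
        double f = pk.step_frac[arg];
        double c = 0.0;
        for (int i = 0; i < 4; ++i) c += a[i] * f * Ps[i * 5 + 4];
        if (!(c > 0.0)) { bad = true; break; }
        cstore[oo] = c;
        logl += std::log(c);
      }
    }
    if (bad) break;
    total += wp * logl;
    // backward (reverse accumulation)
    for (int j = 0; j < 5; ++j) adj[j] = 0.0;
    for (int oo = nops - 1; oo >= 0; --oo) {
      int o = o0 + oo;
      int tp = pk.op_type[o], arg = pk.op_arg[o];
      const double *ab = &Astore[(size_t)oo * 5];
      if (tp == 1) {
        for (int j = 0; j < 5; ++j) adj[j] = 0.0;
        adj[arg] = 1.0 / cstore[oo];
      } else if (tp == 2) {
        double c = cstore[oo];
        double dot = 0.0;
        for (int j = 0; j < 4; ++j) dot += adj[j] * (ab[j] / c);
        for (int j = 0; j < 4; ++j) adj0[j] = (1.0 + adj[j] - dot) / c;
        adj0[4] = 0.0;
        for (int j = 0; j < 5; ++j) adj[j] = adj0[j];
      } else if (tp == 3) {
        const double *Ps = &P[(size_t)arg * 25];
        double f = pk.step_frac[arg];
        double c = cstore[oo];
        double t = pk.step_t[arg];
        int x = pk.step_x[arg];
        // eta gradient for each living row i: W on column dead only
        for (int i = 0; i < 4; ++i) {
          double Wi = ab[i] * f / c;  // dlogL/dM[i][dead]
          if (Wi == 0.0) continue;
          double pd = Ps[i * 5 + 4];
          double si = pd * Wi;
          for (int q = 0; q < rn[i]; ++q) {
            int p = rp[i * 4 + q];
            int to = pk.pto[p];
            double pk_ = Ps[i * 5 + to];
            double g = pk_ * ((to == 4 ? Wi : 0.0) - si) * wp;
            if (g == 0.0) continue;
            double *gp = &grad[(size_t)p * pk.npp];
            gp[0] += g;
            if (pk.has_age) gp[1] += g * t;
            for (int cc = 0; cc < pk.ncov; ++cc) {
              gp[1 + pk.has_age + cc] += g * pk.X[(size_t)x * pk.ncov + cc];
            }
          }
        }
        // adjoint before (death is terminal; incoming adj is zero)
        for (int i = 0; i < 4; ++i) adj[i] = f * Ps[i * 5 + 4] / c;
        adj[4] = 0.0;
      } else {  // step
        const double *Ps = &P[(size_t)arg * 25];
        double f = pk.step_frac[arg];
        double t = pk.step_t[arg];
        int x = pk.step_x[arg];
        for (int i = 0; i < 4; ++i) {
          if (ab[i] == 0.0) continue;
          // s_i = sum_j p_ij adj_j over all 5 columns
          double si = 0.0;
          for (int j = 0; j < 5; ++j) si += Ps[i * 5 + j] * adj[j];
          double fa = f * ab[i] * wp;
          for (int q = 0; q < rn[i]; ++q) {
            int p = rp[i * 4 + q];
            int to = pk.pto[p];
            double pk_ = Ps[i * 5 + to];
            double g = fa * pk_ * (adj[to] - si);
            if (g == 0.0) continue;
            double *gp = &grad[(size_t)p * pk.npp];
            gp[0] += g;
            if (pk.has_age) gp[1] += g * t;
            for (int cc = 0; cc < pk.ncov; ++cc) {
              gp[1 + pk.has_age + cc] += g * pk.X[(size_t)x * pk.ncov + cc];
            }
          }
        }
        // adjoint before: adj0 = Mf adj
        for (int i = 0; i < 5; ++i) {
          double s = 0.0;
          if (i < 4) {
            for (int j = 0; j < 5; ++j) s += Ps[i * 5 + j] * adj[j];
            s *= f;
            s += (1.0 - f) * adj[i];
          } else {
            s = adj[4];
          }
          adj0[i] = s;
        }
        for (int j = 0; j < 5; ++j) adj[j] = adj0[j];
      }
    }
  }
  if (bad) {
    return List::create(_["value"] = R_PosInf,
                        _["gradient"] = NumericVector(npar));
  }
  for (int k = 0; k < npar; ++k) grad[k] = -grad[k];
  return List::create(_["value"] = -total, _["gradient"] = grad);
}
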