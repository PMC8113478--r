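// Unrolled-Euler integration of the NN-CME and exact reverse-mode gradient.
//
// Forward: P_{k+1} = P_k + dt * (D P_k + sum_m (e_dst - e_src) g_out(m) P_src)
// with g = relu(W2 tanh(W1 P_k + b1) + r); the network input is the current
// probability vector, so the generator is state-dependent.
//
// Loss: at snapshot steps, either the squared Euclidean distance between the
// observed marginal of P and the histogram, or the negative multinomial
// log-likelihood of observed counts. The backward sweep
// (discretise-then-differentiate) propagates the adjoint through every Euler
// step and through the network, and optionally accumulates gradients with
// respect to kinetic parameters entering D linearly via derivative matrices.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List nncme_grad_cpp(NumericMatrix W1, NumericVector b1, NumericMatrix W2,
                    NumericVector r, NumericVector P0,
                    IntegerVector Dp, IntegerVector Di, NumericVector Dx,
                    IntegerVector src, IntegerVector dst, IntegerVector outidx,
                    double dt, IntegerVector snap_steps, NumericMatrix H,
                    IntegerVector obs_map, int loss_type, List Dk_list,
                    bool want_grad) {
  const int S = P0.size();
  const int hdim = b1.size();
  const int K = r.size();
  const int M = src.size();
  const int nshot = snap_steps.size();
  const int nsteps = (nshot > 0) ? snap_steps[nshot - 1] : 0;
  const int B = H.nrow();
  const int nkin = Dk_list.size();

  std::vector<double> Ppath((size_t)(nsteps + 1) * S);
  std::vector<double> hpath(want_grad ? (size_t)nsteps * hdim : 0);
  std::vector<double> gpath((size_t)std::max(nsteps, 1) * K);
  std::vector<double> linpath(want_grad ? (size_t)nsteps * K : 0);

  for (int s = 0; s < S; ++s) Ppath[s] = P0[s];

  std::vector<double> a(hdim), hv(hdim), lin(K), q(B);
  NumericMatrix Psnap(S, nshot);

  double J = 0.0;
  int snap_ptr = 0;

  auto snapshot_loss = [&](const double* P, int j) {
    std::fill(q.begin(), q.end(), 0.0);
    for (int s = 0; s < S; ++s) q[obs_map[s]] += P[s];
    double val = 0.0;
    if (loss_type == 0) {
      for (int b = 0; b < B; ++b) {
        double d = q[b] - H(b, j);
        val += d * d;
      }
    } else {
      for (int b = 0; b < B; ++b) {
        if (H(b, j) > 0) {
          double qb = q[b] > 1e-12 ? q[b] : 1e-12;
          val -= H(b, j) * std::log(qb);
        }
      }
    }
    return val;
  };

  // ---- forward sweep ----
  for (int k = 0; k < nsteps; ++k) {
    double* P = &Ppath[(size_t)k * S];
    double* Pn = &Ppath[(size_t)(k + 1) * S];
    // network forward
    std::fill(a.begin(), a.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      double ps = P[s];
      if (ps == 0.0) continue;
      const double* w = &W1[(size_t)s * hdim];
      for (int i = 0; i < hdim; ++i) a[i] += w[i] * ps;
    }
    for (int i = 0; i < hdim; ++i) hv[i] = std::tanh(a[i] + b1[i]);
    for (int o = 0; o < K; ++o) lin[o] = r[o];
    for (int j = 0; j < hdim; ++j) {
      double hj = hv[j];
      const double* w = &W2[(size_t)j * K];
      for (int o = 0; o < K; ++o) lin[o] += w[o] * hj;
    }
    double* g = &gpath[(size_t)k * K];
    for (int o = 0; o < K; ++o) g[o] = lin[o] > 0 ? lin[o] : 0.0;
    if (want_grad) {
      std::copy(hv.begin(), hv.end(), &hpath[(size_t)k * hdim]);
      std::copy(lin.begin(), lin.end(), &linpath[(size_t)k * K]);
    }
    // Euler step
    for (int s = 0; s < S; ++s) Pn[s] = P[s];
    for (int col = 0; col < S; ++col) {
      double pc = P[col];
      if (pc == 0.0) continue;
      for (int e = Dp[col]; e < Dp[col + 1]; ++e)
        Pn[Di[e]] += dt * Dx[e] * pc;
    }
    for (int m = 0; m < M; ++m) {
      double flux = dt * g[outidx[m]] * P[src[m]];
      Pn[dst[m]] += flux;
      Pn[src[m]] -= flux;
    }
  }

  // ---- losses at snapshots ----
  for (int j = 0; j < nshot; ++j) {
    const double* P = &Ppath[(size_t)snap_steps[j] * S];
    J += snapshot_loss(P, j);
    for (int s = 0; s < S; ++s) Psnap(s, j) = P[s];
  }

  NumericMatrix gW1(hdim, S), gW2(K, hdim);
  NumericVector gb1(hdim), gkin(nkin);

  if (want_grad) {
    std::vector<double> lam(S, 0.0), lam_new(S), dgout(K), v(K), dh(hdim),
        da(hdim);
    // pre-extract kinetic derivative matrices
    std::vector<IntegerVector> Kp(nkin), Ki(nkin);
    std::vector<NumericVector> Kx(nkin);
    for (int qn = 0; qn < nkin; ++qn) {
      List dk = Dk_list[qn];
      Kp[qn] = as<IntegerVector>(dk["p"]);
      Ki[qn] = as<IntegerVector>(dk["i"]);
      Kx[qn] = as<NumericVector>(dk["x"]);
    }
    snap_ptr = nshot - 1;
    for (int k = nsteps; k >= 0; --k) {
      if (snap_ptr >= 0 && snap_steps[snap_ptr] == k) {
        const double* P = &Ppath[(size_t)k * S];
        std::fill(q.begin(), q.end(), 0.0);
        for (int s = 0; s < S; ++s) q[obs_map[s]] += P[s];
        for (int s = 0; s < S; ++s) {
          int b = obs_map[s];
          if (loss_type == 0) {
            lam[s] += 2.0 * (q[b] - H(b, snap_ptr));
          } else if (H(b, snap_ptr) > 0) {
            double qb = q[b] > 1e-12 ? q[b] : 1e-12;
            lam[s] -= H(b, snap_ptr) / qb;
          }
        }
        --snap_ptr;
      }
      if (k == 0) break;
      // propagate adjoint through step (k-1) -> k; inputs from step k-1
      const double* P = &Ppath[(size_t)(k - 1) * S];
      const double* hk = &hpath[(size_t)(k - 1) * hdim];
      const double* link = &linpath[(size_t)(k - 1) * K];
      const double* g = &gpath[(size_t)(k - 1) * K];

      std::copy(lam.begin(), lam.end(), lam_new.begin());
      // D^T lam
      for (int col = 0; col < S; ++col) {
        double acc = 0.0;
        for (int e = Dp[col]; e < Dp[col + 1]; ++e)
          acc += Dx[e] * lam[Di[e]];
        lam_new[col] += dt * acc;
      }
      // kinetic-parameter accumulation: dt * lam^T (Dk P)
      for (int qn = 0; qn < nkin; ++qn) {
        const IntegerVector& kp = Kp[qn];
        const IntegerVector& ki = Ki[qn];
        const NumericVector& kx = Kx[qn];
        double acc = 0.0;
        for (int col = 0; col < S; ++col) {
          double pc = P[col];
          if (pc == 0.0) continue;
          for (int e = kp[col]; e < kp[col + 1]; ++e)
            acc += kx[e] * pc * lam[ki[e]];
        }
        gkin[qn] += dt * acc;
      }
      // template adjoint
      std::fill(dgout.begin(), dgout.end(), 0.0);
      for (int m = 0; m < M; ++m) {
        double dl = lam[dst[m]] - lam[src[m]];
        dgout[outidx[m]] += dl * P[src[m]];
        lam_new[src[m]] += dt * g[outidx[m]] * dl;
      }
      // network backward: dJ/dlin = dt * dgout * relu'
      for (int o = 0; o < K; ++o)
        v[o] = link[o] > 0 ? dt * dgout[o] : 0.0;
      std::fill(dh.begin(), dh.end(), 0.0);
      for (int j = 0; j < hdim; ++j) {
        double hj = hk[j];
        double* gw = &gW2[(size_t)j * K];
        const double* w = &W2[(size_t)j * K];
        double acc = 0.0;
        for (int o = 0; o < K; ++o) {
          gw[o] += v[o] * hj;
          acc += w[o] * v[o];
        }
        dh[j] = acc;
      }
      for (int i = 0; i < hdim; ++i) {
        da[i] = dh[i] * (1.0 - hk[i] * hk[i]);
        gb1[i] += da[i];
      }
      for (int s = 0; s < S; ++s) {
        double ps = P[s];
        double* gw = &gW1[(size_t)s * hdim];
        const double* w = &W1[(size_t)s * hdim];
        double acc = 0.0;
        for (int i = 0; i < hdim; ++i) {
          gw[i] += da[i] * ps;
          acc += w[i] * da[i];
        }
        lam_new[s] += acc;
      }
      lam.swap(lam_new);
    }
  }

  return List::create(_["J"] = J, _["gW1"] = gW1, _["gb1"] = gb1,
                      _["gW2"] = gW2, _["gkin"] = gkin,
                      _["P_snap"] = Psnap);
}
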