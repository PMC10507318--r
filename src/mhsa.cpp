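#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multi-head self-attention with per-head dimension 1.
//
// Q, K, V are (B*T) x H matrices in time-major row order: row r = b + t*B
// (0-based) holds position t of example b, and column h is head h. With
// one-dimensional heads the attention scores reduce to products of scalars:
//   S[b,i,j,h] = Q(b+iB, h) * K(b+jB, h)
// softmaxed over j (scale 1/sqrt(d_head) = 1), and
//   out(b+iB, h) = sum_j A[b,i,j,h] * V(b+jB, h).
//
// The kernel copies each head/example slice into small local buffers so the
// inner i/j loops run on L1-resident data. The softmax weights needed by the
// backward pass are stored j-fastest in a flat vector indexed
//   j + T*(i + T*(b + B*h))
// and are skipped entirely in evaluation mode (keep_attn = false).

// [[Rcpp::export(name = ".mhsa_forward")]]
List mhsa_forward(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                  int B, int T, bool keep_attn) {
  const int H = Q.ncol();
  const int BT = B * T;
  NumericMatrix out(BT, H);
  NumericVector A(keep_attn ? (R_xlen_t)BT * T * H : (R_xlen_t)1);
  double *a_ptr = A.begin();
  std::vector<double> q(T), k(T), v(T), s(T);
  for (int h = 0; h < H; ++h) {
    const double *q_col = &Q(0, h);
    const double *k_col = &K(0, h);
    const double *v_col = &V(0, h);
    double *o_col = &out(0, h);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < T; ++t) {
        q[t] = q_col[b + t * B];
        k[t] = k_col[b + t * B];
        v[t] = v_col[b + t * B];
      }
      double *a_be = keep_attn ? a_ptr + (R_xlen_t)T * T * (b + (R_xlen_t)B * h) : (double *)0;
      for (int i = 0; i < T; ++i) {
        const double qi = q[i];
        double smax = -1e300;
        for (int j = 0; j < T; ++j) {
          s[j] = qi * k[j];
          if (s[j] > smax) smax = s[j];
        }
        double z = 0.0;
        for (int j = 0; j < T; ++j) { s[j] = std::exp(s[j] - smax); z += s[j]; }
        const double inv = 1.0 / z;
        double acc = 0.0;
        for (int j = 0; j < T; ++j) {
          const double a = s[j] * inv;
          acc += a * v[j];
          if (keep_attn) a_be[i * T + j] = a;
        }
        o_col[b + i * B] = acc;
      }
    }
  }
  return List::create(_["out"] = out, _["attn"] = A);
}

// [[Rcpp::export(name = ".mhsa_backward")]]
List mhsa_backward(NumericMatrix G, NumericVector A,
                   NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                   int B, int T) {
  const int H = Q.ncol();
  const int BT = B * T;
  NumericMatrix dQ(BT, H), dK(BT, H), dV(BT, H);
  const double *a_ptr = A.begin();
  std::vector<double> q(T), k(T), v(T), g(T), dk(T), dv(T), dA(T);
  for (int h = 0; h < H; ++h) {
    const double *q_col = &Q(0, h);
    const double *k_col = &K(0, h);
    const double *v_col = &V(0, h);
    const double *g_col = &G(0, h);
    double *dq_col = &dQ(0, h);
    double *dk_col = &dK(0, h);
    double *dv_col = &dV(0, h);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < T; ++t) {
        q[t] = q_col[b + t * B];
        k[t] = k_col[b + t * B];
        v[t] = v_col[b + t * B];
        g[t] = g_col[b + t * B];
        dk[t] = 0.0;
        dv[t] = 0.0;
      }
      const double *a_be = a_ptr + (R_xlen_t)T * T * (b + (R_xlen_t)B * h);
      for (int i = 0; i < T; ++i) {
        const double gi = g[i];
        const double *a_row = a_be + i * T;
        double dot = 0.0;
        for (int j = 0; j < T; ++j) {
          dA[j] = gi * v[j];
          dv[j] += a_row[j] * gi;
          dot += dA[j] * a_row[j];
        }
        double dq = 0.0;
        const double qi = q[i];
        for (int j = 0; j < T; ++j) {
          const double ds = a_row[j] * (dA[j] - dot);
          dq += ds * k[j];
          dk[j] += ds * qi;
        }
        dq_col[b + i * B] = dq;
      }
      for (int t = 0; t < T; ++t) {
        dk_col[b + t * B] = dk[t];
        dv_col[b + t * B] = dv[t];
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
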