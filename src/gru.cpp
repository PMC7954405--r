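// Batched GRU forward pass and backpropagation through time.
//
// Sequences are padded into a cube X of dimension (inputDim, batch, maxT)
// with per-sequence lengths `lens`; for t > lens[i] the hidden state of
// sequence i is frozen at its own final step, so no padded step ever leaks
// into a prediction or a gradient. When `lens` is non-increasing (callers
// sort batches by length) each timestep only touches the active column
// prefix, which avoids computing on padded steps altogether.
//
// Training-time activations are cached on the C++ side and exchanged with R
// through an external pointer, so the large (hidden x batch x time) cubes are
// never copied across the interface.
//
// Gate equations (update z, reset r, candidate c):
//   z_t = sigmoid(Wz x_t + Uz h_{t-1} + bz)
//   r_t = sigmoid(Wr x_t + Ur h_{t-1} + br)
//   c_t = tanh(Wc x_t + Uc (r_t % h_{t-1}) + bc)
//   h_t = (1 - z_t) % c_t + z_t % h_{t-1}

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct GruCache {
  cube H, Z, R, C;
};

static inline mat sigmoid(const mat& a) { return 1.0 / (1.0 + exp(-a)); }

static bool nonIncreasing(const ivec& lens) {
  for (uword i = 1; i < lens.n_elem; ++i)
    if (lens(i) > lens(i - 1)) return false;
  return true;
}

// Forward pass. Returns the final hidden state per sequence; optionally the
// full hidden-state cube (returnH) and/or an activation cache for backward.
// [[Rcpp::export]]
Rcpp::List cppGruForward(const arma::mat& Wz, const arma::mat& Wr,
                         const arma::mat& Wc, const arma::mat& Uz,
                         const arma::mat& Ur, const arma::mat& Uc,
                         const arma::vec& bz, const arma::vec& br,
                         const arma::vec& bc, const arma::cube& X,
                         const arma::ivec& lens, bool cache,
                         bool returnH) {
  const uword B = X.n_cols, T = X.n_slices, H = Wz.n_rows, D = X.n_rows;
  const bool sorted = nonIncreasing(lens);

  // all input projections in one gemm per gate
  mat Xf(const_cast<double*>(X.memptr()), D, B * T, false, true);
  mat WXz = Wz * Xf, WXr = Wr * Xf, WXc = Wc * Xf;

  GruCache* st = new GruCache();
  st->H.set_size(H, B, T);
  if (cache) { st->Z.zeros(H, B, T); st->R.zeros(H, B, T); st->C.zeros(H, B, T); }

  mat h(H, B, fill::zeros);
  uword k = B;
  for (uword t = 0; t < T; ++t) {
    if (sorted) while (k > 0 && (uword)lens(k - 1) < t + 1) --k;
    else k = B;
    if (k > 0) {
      mat hA = h.cols(0, k - 1);
      mat az = WXz.cols(t * B, t * B + k - 1) + Uz * hA;
      mat ar = WXr.cols(t * B, t * B + k - 1) + Ur * hA;
      az.each_col() += bz; ar.each_col() += br;
      mat z = sigmoid(az), r = sigmoid(ar);
      mat ac = WXc.cols(t * B, t * B + k - 1) + Uc * (r % hA);
      ac.each_col() += bc;
      mat c = tanh(ac);
      mat hn = (1.0 - z) % c + z % hA;
      for (uword i = 0; i < k; ++i) {   // only reachable when lens is unsorted
        if ((uword)(t + 1) > (uword)lens(i)) {
          hn.col(i) = hA.col(i);
          z.col(i).zeros(); r.col(i).zeros(); c.col(i).zeros();
        }
      }
      h.cols(0, k - 1) = hn;
      if (cache) {
        st->Z.slice(t).cols(0, k - 1) = z;
        st->R.slice(t).cols(0, k - 1) = r;
        st->C.slice(t).cols(0, k - 1) = c;
      }
    }
    st->H.slice(t) = h;
  }

  mat Hfinal(H, B);
  for (uword i = 0; i < B; ++i)
    Hfinal.col(i) = st->H.slice((uword)lens(i) - 1).col(i);

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("Hfinal") = Hfinal);
  if (returnH) out["H"] = st->H;
  if (cache) {
    Rcpp::XPtr<GruCache> ptr(st, true);
    out["cache"] = ptr;
  } else {
    delete st;
  }
  return out;
}

// Hidden states at per-sequence steps (1-based), gathered from a cache.
// [[Rcpp::export]]
arma::mat cppGruGather(SEXP cachePtr, const arma::ivec& steps) {
  Rcpp::XPtr<GruCache> st(cachePtr);
  const uword B = st->H.n_cols, H = st->H.n_rows;
  mat out(H, B);
  for (uword i = 0; i < B; ++i)
    out.col(i) = st->H.slice((uword)steps(i) - 1).col(i);
  return out;
}

// Backward pass. Upstream gradients arrive as W supervision points per
// sequence: dHsteps (W x B, 1-based time indices) and dHvals (H x B x W).
// [[Rcpp::export]]
Rcpp::List cppGruBackward(const arma::mat& Wz, const arma::mat& Wr,
                          const arma::mat& Wc, const arma::mat& Uz,
                          const arma::mat& Ur, const arma::mat& Uc,
                          const arma::cube& X, const arma::ivec& lens,
                          SEXP cachePtr, const arma::imat& dHsteps,
                          const arma::cube& dHvals) {
  Rcpp::XPtr<GruCache> st(cachePtr);
  const cube& Hc = st->H;
  const uword B = X.n_cols, T = X.n_slices, H = Wz.n_rows, D = X.n_rows;
  const uword W = dHsteps.n_rows;
  const bool sorted = nonIncreasing(lens);

  cube dH(H, B, T, fill::zeros);
  for (uword w = 0; w < W; ++w)
    for (uword i = 0; i < B; ++i)
      dH.slice((uword)dHsteps(w, i) - 1).col(i) += dHvals.slice(w).col(i);

  // active-column widths and compact offsets per timestep
  uvec ks(T), off(T);
  {
    uword k = B, acc = 0;
    for (uword t = 0; t < T; ++t) {
      if (sorted) { while (k > 0 && (uword)lens(k - 1) < t + 1) --k; ks(t) = k; }
      else ks(t) = B;
    }
    for (uword t = 0; t < T; ++t) { off(t) = acc; acc += ks(t); }
  }
  const uword SA = off(T - 1) + ks(T - 1);

  // gate pre-activation gradients and their gemm partners, padded steps removed
  mat DAZc(H, SA), DARc(H, SA), DACc(H, SA);
  mat Xc(D, SA), Hpc(H, SA), RHc(H, SA);

  mat dh(H, B, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    dh += dH.slice(tt);
    const uword k = ks(tt);
    if (k == 0) continue;

    mat hprev = (tt == 0) ? mat(H, k, fill::zeros)
                          : mat(Hc.slice(tt - 1).cols(0, k - 1));
    mat z = st->Z.slice(tt).cols(0, k - 1);
    mat r = st->R.slice(tt).cols(0, k - 1);
    mat c = st->C.slice(tt).cols(0, k - 1);
    mat dhA = dh.cols(0, k - 1);

    mat dz = dhA % (hprev - c);
    mat dc = dhA % (1.0 - z);
    mat dhp = dhA % z;
    mat dac = dc % (1.0 - c % c);
    mat g = Uc.t() * dac;
    mat dr = g % hprev;
    dhp += g % r;
    mat daz = dz % z % (1.0 - z);
    mat dar = dr % r % (1.0 - r);
    dhp += Uz.t() * daz + Ur.t() * dar;

    for (uword i = 0; i < k; ++i) {     // only reachable when lens is unsorted
      if ((uword)(tt + 1) > (uword)lens(i)) {
        daz.col(i).zeros(); dar.col(i).zeros(); dac.col(i).zeros();
        dhp.col(i) = dhA.col(i);
      }
    }
    const uword o = off(tt);
    DAZc.cols(o, o + k - 1) = daz;
    DARc.cols(o, o + k - 1) = dar;
    DACc.cols(o, o + k - 1) = dac;
    Xc.cols(o, o + k - 1) = X.slice(tt).cols(0, k - 1);
    Hpc.cols(o, o + k - 1) = hprev;
    RHc.cols(o, o + k - 1) = r % hprev;
    dh.cols(0, k - 1) = dhp;
  }

  return Rcpp::List::create(
    Rcpp::Named("Wz") = mat(DAZc * Xc.t()), Rcpp::Named("Wr") = mat(DARc * Xc.t()),
    Rcpp::Named("Wc") = mat(DACc * Xc.t()),
    Rcpp::Named("Uz") = mat(DAZc * Hpc.t()), Rcpp::Named("Ur") = mat(DARc * Hpc.t()),
    Rcpp::Named("Uc") = mat(DACc * RHc.t()),
    Rcpp::Named("bz") = vec(sum(DAZc, 1)), Rcpp::Named("br") = vec(sum(DARc, 1)),
    Rcpp::Named("bc") = vec(sum(DACc, 1)));
}
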