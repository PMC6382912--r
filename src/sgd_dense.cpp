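#include <Rcpp.h>
#include <vector>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

// Treat denormal floats as zero inside the training kernel: converged
// classifiers produce vanishing gradients whose denormal arithmetic is
// orders of magnitude slower on common hardware, without affecting the
// result at any meaningful precision.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int ftz, daz;
  FlushDenormals() {
    ftz = _MM_GET_FLUSH_ZERO_MODE();
    daz = _MM_GET_DENORMALS_ZERO_MODE();
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
#endif
};

// Fused mini-batch SGD on a dense ReLU network (affine layers + terminal
// softmax, cross-entropy loss).  Runs a block of iterations between two
// validation evaluations.  Weight/bias matrices are updated in place; the
// caller owns them exclusively (deep copies of the model parameters).
// Batch indices are drawn from R's RNG so runs are reproducible under
// set.seed().  Returns the last mini-batch loss (NaN signals divergence).
// [[Rcpp::export]]
double sgd_dense_block(List W, List b, NumericMatrix X, IntegerVector y,
                       int n_classes, int iterations, double lr,
                       int batch_size) {
  FlushDenormals scoped_ftz;
  const int L = W.size();
  const int n = X.nrow();
  std::vector<double*> w(L), bias(L);
  std::vector<int> nin(L), nout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix Wl = W[l];
    NumericVector bl = b[l];
    w[l] = REAL(Wl); bias[l] = REAL(bl);
    nin[l] = Wl.nrow(); nout[l] = Wl.ncol();
  }
  const double* x = REAL(X);
  const int p = nin[0];

  // activations: acts[0] = batch input, acts[l+1] = output of layer l
  std::vector<std::vector<double>> acts(L + 1);
  acts[0].resize((size_t)batch_size * p);
  for (int l = 0; l < L; ++l) acts[l + 1].resize((size_t)batch_size * nout[l]);
  std::vector<double> G, Gprev;
  std::vector<int> bi(batch_size);

  double loss = 0.0;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < batch_size; ++i) {
      int idx = (int)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
      bi[i] = idx;
    }
    // gather batch rows (row-major per sample)
    for (int i = 0; i < batch_size; ++i)
      for (int k = 0; k < p; ++k)
        acts[0][(size_t)i * p + k] = x[bi[i] + (size_t)k * n];
    // forward
    for (int l = 0; l < L; ++l) {
      const double* A = acts[l].data();
      double* Z = acts[l + 1].data();
      const int ni = nin[l], no = nout[l];
      for (int j = 0; j < no; ++j) {
        const double* wcol = w[l] + (size_t)j * ni;
        for (int i = 0; i < batch_size; ++i) {
          const double* arow = A + (size_t)i * ni;
          double s = bias[l][j];
          for (int k = 0; k < ni; ++k) s += arow[k] * wcol[k];
          Z[(size_t)i * no + j] = s;
        }
      }
      if (l < L - 1)  // hidden ReLU
        for (size_t q = 0; q < acts[l + 1].size(); ++q)
          if (Z[q] < 0) Z[q] = 0;
    }
    // softmax + cross-entropy gradient
    const int C = n_classes;
    double* S = acts[L].data();
    G.assign((size_t)batch_size * C, 0.0);
    loss = 0.0;
    for (int i = 0; i < batch_size; ++i) {
      double* srow = S + (size_t)i * C;
      double m = srow[0];
      for (int j = 1; j < C; ++j) if (srow[j] > m) m = srow[j];
      double Zs = 0.0;
      for (int j = 0; j < C; ++j) Zs += std::exp(srow[j] - m);
      for (int j = 0; j < C; ++j) {
        double pr = std::exp(srow[j] - m) / Zs;
        // flush vanishing probabilities: keeps gradients free of denormal
        // values (which are pathologically slow) and lets the zero-skip
        // below drop the work entirely
        G[(size_t)i * C + j] = pr < 1e-16 ? 0.0 : pr / batch_size;
      }
      int yt = y[bi[i]] - 1;
      double pt = std::exp(srow[yt] - m) / Zs;
      loss -= std::log(pt > 1e-300 ? pt : 1e-300) / batch_size;
      G[(size_t)i * C + yt] -= 1.0 / batch_size;
    }
    if (!std::isfinite(loss)) return NA_REAL;
    // backward + in-place updates
    for (int l = L - 1; l >= 0; --l) {
      const int ni = nin[l], no = nout[l];
      const double* A = acts[l].data();
      if (l > 0) {
        // input gradient (needs pre-update weights), then ReLU mask
        Gprev.assign((size_t)batch_size * ni, 0.0);
        for (int j = 0; j < no; ++j) {
          const double* wcol = w[l] + (size_t)j * ni;
          for (int i = 0; i < batch_size; ++i) {
            const double g = G[(size_t)i * no + j];
            if (std::fabs(g) < 1e-14) continue;  // update below weight noise
            double* grow = Gprev.data() + (size_t)i * ni;
            for (int k = 0; k < ni; ++k) grow[k] += g * wcol[k];
          }
        }
        for (size_t q = 0; q < Gprev.size(); ++q)
          if (A[q] <= 0) Gprev[q] = 0;
      }
      for (int j = 0; j < no; ++j) {
        double* wcol = w[l] + (size_t)j * ni;
        double gb = 0.0;
        for (int i = 0; i < batch_size; ++i) {
          const double g = G[(size_t)i * no + j];
          gb += g;
          if (std::fabs(g) < 1e-14) continue;  // update below weight noise
          const double glr = lr * g;
          const double* arow = A + (size_t)i * ni;
          for (int k = 0; k < ni; ++k) wcol[k] -= glr * arow[k];
        }
        bias[l][j] -= lr * gb;
      }
      if (l > 0) G.swap(Gprev);
    }
  }
  return loss;
}
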