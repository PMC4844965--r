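// Core numeric kernels for the HMAX-style front end: Gabor filtering (S1),
// local max pooling (C1) and prototype-tuned radial-basis responses with
// global max pooling (S2/C2).
//
// S1 uses an im2col + GEMM formulation of "same" convolution with zero
// padding (exact, just BLAS-friendly); S2 uses integral images for patch
// means/norms and raw-pointer loops for the template dot products.
#include <map>
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// "same" convolution of one image with a set of equally sized kernels.
// kernels: k*k x nk matrix (each column one kernel, column-major, already
// flipped the way conv2 requires). Returns |response| maps, H x W x nk.
static arma::cube conv_same_abs(const arma::mat& image,
                                const arma::mat& kernels, const int k) {
  const int H = image.n_rows, W = image.n_cols;
  const int half = (k - 1) / 2;
  arma::mat P(H + k - 1, W + k - 1, arma::fill::zeros);
  P.submat(half, half, half + H - 1, half + W - 1) = image;
  arma::mat X(H * W, k * k);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < k; ++i) {
      double* dst = X.colptr(j * k + i);
      for (int c = 0; c < W; ++c)
        std::memcpy(dst + c * H, P.colptr(c + j) + i, H * sizeof(double));
    }
  }
  arma::mat R = arma::abs(X * kernels);
  arma::cube out(H, W, kernels.n_cols);
  for (unsigned s = 0; s < kernels.n_cols; ++s)
    out.slice(s) = arma::reshape(R.col(s), H, W);
  return out;
}

// conv2(image, kernel) flips the kernel; our Gabor bank is applied as a
// correlation (template matching), so flip here once to match the
// conventional conv2-based formulation used by reference implementations.
static arma::mat flip_kernels(const List& kerns) {
  const arma::mat k0 = as<arma::mat>(kerns[0]);
  const int k = k0.n_rows;
  arma::mat K(k * k, kerns.size());
  for (int s = 0; s < kerns.size(); ++s) {
    arma::mat km = arma::flipud(arma::fliplr(as<arma::mat>(kerns[s])));
    K.col(s) = arma::vectorise(km);
  }
  return K;
}

// Full S1 + C1 pass. filters: list (one per size) of lists (one per
// orientation) of kernel matrices. Bands pair consecutive sizes.
// Returns a list of H_b x W_b x norient cubes, one per band.
// [[Rcpp::export]]
List cpp_s1_c1(const arma::mat& image, const List& filters,
               const IntegerVector& pool, const IntegerVector& step) {
  const int nsz = filters.size();
  const int nb = pool.size();
  if (nsz != 2 * nb) stop("filter sizes must pair into bands");
  std::vector<arma::cube> s1(nsz);
  for (int i = 0; i < nsz; ++i) {
    const List kerns = filters[i];
    const arma::mat k0 = as<arma::mat>(kerns[0]);
    s1[i] = conv_same_abs(image, flip_kernels(kerns), k0.n_rows);
  }
  List out(nb);
  for (int b = 0; b < nb; ++b) {
    const arma::cube& A = s1[2 * b];
    const arma::cube& Bc = s1[2 * b + 1];
    const int H = A.n_rows, W = A.n_cols, ns = A.n_slices;
    const int pp = pool[b], st = step[b];
    const int nr = (H - pp) / st + 1, nc = (W - pp) / st + 1;
    arma::cube c1(nr, nc, ns);
    for (int s = 0; s < ns; ++s) {
      arma::mat m = arma::max(A.slice(s), Bc.slice(s));
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
          c1(i, j, s) = m.submat(i * st, j * st,
                                 i * st + pp - 1, j * st + pp - 1).max();
    }
    out[b] = c1;
  }
  return out;
}

// C1 pooling of two S1 maps (one band, one orientation); kept as a
// separately callable primitive.
// [[Rcpp::export]]
arma::mat cpp_c1_pool(const arma::mat& s1a, const arma::mat& s1b,
                      const int pool, const int step) {
  const arma::mat m = arma::max(s1a, s1b);
  const int H = m.n_rows, W = m.n_cols;
  const int nr = (H - pool) / step + 1;
  const int nc = (W - pool) / step + 1;
  arma::mat out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = m.submat(i * step, j * step,
                           i * step + pool - 1, j * step + pool - 1).max();
  return out;
}

// S2/C2 for one image: for every prototype (zero-mean, unit-norm cube of
// size k x k x norient) compute exp(-gamma * ||patch_hat - P||^2) at every
// valid position in every band whose C1 maps are large enough, where
// patch_hat is the input patch normalised the same way (zero mean across
// the whole patch, unit norm). A patch with (near-)zero norm gives
// response 0: no stimulus energy, baseline. C2 is the max over positions
// and bands. Ties resolve to the first maximum in scan order.
// [[Rcpp::export]]
NumericVector cpp_s2_c2(const List& bands, const List& protos,
                        const double gamma) {
  const int nb = bands.size();
  const int np = protos.size();
  std::vector<arma::cube> B(nb);
  for (int b = 0; b < nb; ++b) B[b] = as<arma::cube>(bands[b]);

  // per band: integral images of the across-orientation sum of squares
  // and of values, for O(1) patch means and norms
  std::vector<arma::mat> I1(nb), I2(nb);
  for (int b = 0; b < nb; ++b) {
    arma::mat s = arma::sum(B[b], 2);
    arma::mat s2(B[b].n_rows, B[b].n_cols, arma::fill::zeros);
    for (unsigned k = 0; k < B[b].n_slices; ++k)
      s2 += arma::square(B[b].slice(k));
    I1[b] = arma::cumsum(arma::cumsum(s, 0), 1);
    I2[b] = arma::cumsum(arma::cumsum(s2, 0), 1);
  }
  auto boxsum = [](const arma::mat& I, int r0, int c0, int k) {
    double s = I(r0 + k - 1, c0 + k - 1);
    if (r0 > 0) s -= I(r0 - 1, c0 + k - 1);
    if (c0 > 0) s -= I(r0 + k - 1, c0 - 1);
    if (r0 > 0 && c0 > 0) s += I(r0 - 1, c0 - 1);
    return s;
  };

  // group prototypes by patch size and stack each group into one matrix
  std::map<int, std::vector<int>> groups;
  const int ns = as<arma::cube>(protos[0]).n_slices;
  for (int p = 0; p < np; ++p) {
    const arma::cube P = as<arma::cube>(protos[p]);
    if ((int)P.n_slices != ns) stop("orientation count mismatch");
    groups[P.n_rows].push_back(p);
  }
  for (int b = 0; b < nb; ++b)
    if ((int)B[b].n_slices != ns) stop("orientation count mismatch");

  std::vector<double> best_sim(np, -1e300);
  std::vector<bool> any_pos(np, false), any_valid(np, false);

  for (auto& g : groups) {
    const int k = g.first;
    const std::vector<int>& idx = g.second;
    arma::mat Pk(k * k * ns, idx.size());
    for (size_t q = 0; q < idx.size(); ++q)
      Pk.col(q) = arma::vectorise(as<arma::cube>(protos[idx[q]]));
    const double n_el = double(k) * double(k) * double(ns);
    for (int b = 0; b < nb; ++b) {
      const int H = B[b].n_rows, W = B[b].n_cols;
      if (k > H || k > W) continue;
      const int nr = H - k + 1, nc = W - k + 1;
      const long npos = (long)nr * nc;
      // im2col over the band
      arma::mat X(npos, k * k * ns);
      for (int s = 0; s < ns; ++s) {
        const arma::mat& sl = B[b].slice(s);
        for (int j = 0; j < k; ++j) {
          for (int i = 0; i < k; ++i) {
            double* dst = X.colptr(s * k * k + j * k + i);
            for (int c = 0; c < nc; ++c)
              std::memcpy(dst + (long)c * nr, sl.colptr(c + j) + i,
                          nr * sizeof(double));
          }
        }
      }
      // patch norms from the integral images
      arma::vec inv_nrm(npos);
      arma::uvec valid(npos);
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          const double s1 = boxsum(I1[b], r, c, k);
          const double s2 = boxsum(I2[b], r, c, k);
          const double mu = s1 / n_el;
          const double nrm2 = s2 - n_el * mu * mu;
          const long pos = r + (long)c * nr;
          valid[pos] = nrm2 >= 1e-24;  // flat patch: baseline response
          inv_nrm[pos] = valid[pos] ? 1.0 / std::sqrt(nrm2) : 0.0;
        }
      }
      arma::mat G = X * Pk;  // dot products, npos x n_protos_of_size_k
      for (size_t q = 0; q < idx.size(); ++q) {
        double bs = best_sim[idx[q]];
        bool av = any_valid[idx[q]];
        const double* col = G.colptr(q);
        for (long pos = 0; pos < npos; ++pos) {
          if (!valid[pos]) continue;
          const double sim = col[pos] * inv_nrm[pos];
          if (sim > bs) { bs = sim; av = true; }
        }
        best_sim[idx[q]] = bs;
        any_valid[idx[q]] = av;
        any_pos[idx[q]] = true;
      }
    }
  }

  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    if (!any_pos[p]) stop("prototype larger than every C1 map");
    if (!any_valid[p]) { out[p] = 0.0; continue; }
    // P unit-norm, patch normalised: ||patch_hat - P||^2 = 2 - 2 sim
    double d2 = 2.0 - 2.0 * best_sim[p];
    if (d2 < 0.0) d2 = 0.0;  // guard float round-off at the source patch
    out[p] = std::exp(-gamma * d2);
  }
  return out;
}
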