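// Morlet continuous wavelet transform, computed in the frequency domain.
//
// The analytic Morlet atom at analysis frequency f has the frequency-domain
// profile exp(-(f' - f)^2 / (2 sigma_f^2)) on positive frequencies only,
// with sigma_f = f / omega0 (omega0 cycles). Amplitude normalization is
// unit peak per frequency, so a unit sinusoid at f yields |W| = 1/2 at f.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fill the frequency-domain Morlet profile for analysis frequency f into
// prod = spectrum * psi over its effective support (+/- 6 sigma_f), zero
// elsewhere. n is the transform length, fs the sampling rate.
static void morlet_product(const cx_vec& spectrum, double fs, double f,
                           double omega0, cx_vec& prod) {
  const uword n = spectrum.n_elem;
  prod.zeros();
  const double df = fs / static_cast<double>(n);
  const double sigma_f = f / omega0;
  const double lo = f - 6.0 * sigma_f;
  const double hi = f + 6.0 * sigma_f;
  // positive-frequency bins run from 1 to floor(n/2)
  uword kmax = n / 2;
  uword k0 = lo <= df ? 1 : static_cast<uword>(std::floor(lo / df));
  uword k1 = static_cast<uword>(std::ceil(hi / df));
  if (k1 > kmax) k1 = kmax;
  for (uword k = k0; k <= k1; ++k) {
    double fk = k * df;
    double z = (fk - f) / sigma_f;
    prod(k) = spectrum(k) * std::exp(-0.5 * z * z);
  }
}

// [[Rcpp::export]]
arma::mat cpp_cwt_power(const arma::vec& x, double fs,
                        const arma::vec& freqs, double omega0) {
  const uword n = x.n_elem;
  cx_vec spectrum = fft(conv_to<cx_vec>::from(x));
  mat out(n, freqs.n_elem);
  cx_vec prod(n), w(n);
  for (uword j = 0; j < freqs.n_elem; ++j) {
    morlet_product(spectrum, fs, freqs(j), omega0, prod);
    w = ifft(prod);
    for (uword t = 0; t < n; ++t) out(t, j) = std::norm(w(t));
  }
  return out;
}

// Effective positive-frequency support of the Morlet profile at analysis
// frequency f, as a closed bin range [k0, k1] on an n-point grid.
static void morlet_support(uword n, double fs, double f, double omega0,
                           uword& k0, uword& k1) {
  const double df = fs / static_cast<double>(n);
  const double sigma_f = f / omega0;
  const double lo = f - 6.0 * sigma_f, hi = f + 6.0 * sigma_f;
  uword kmax = n / 2;
  k0 = lo <= df ? 1 : static_cast<uword>(std::floor(lo / df));
  k1 = static_cast<uword>(std::ceil(hi / df));
  if (k1 > kmax) k1 = kmax;
}

// Band-averaged wavelet power per channel, accumulated directly into
// per-frame interval means. V is sample x channel; band_of maps each
// analysis frequency to a 0-based band index; frame_of maps each sample
// to a 0-based imaging-frame index (or -1 for samples outside all frames).
// Returns a channel x band x frame cube of mean power.
//
// Two performance devices, both exact up to single precision:
// single-precision FFTs (band power is an average of O(10^3) samples, so
// float round-off is negligible), and, for bands whose wavelet support
// fits in half the spectrum, coefficient evaluation at every second
// sample via spectral folding -- W(t) at stride 2 equals the half-length
// inverse FFT of the aliased product spectrum, exactly.
// [[Rcpp::export]]
arma::cube cpp_band_power(const arma::mat& V, double fs,
                          const arma::vec& freqs,
                          const arma::ivec& band_of, int n_bands,
                          const arma::ivec& frame_of, int n_frames,
                          double omega0) {
  const uword n = V.n_rows, nch = V.n_cols;
  cube acc(nch, static_cast<uword>(n_bands), static_cast<uword>(n_frames),
           fill::zeros);
  vec freq_per_band(n_bands, fill::zeros);
  for (uword j = 0; j < freqs.n_elem; ++j)
    if (band_of(j) >= 0) freq_per_band(band_of(j)) += 1.0;

  // decimation per band: 2 when every member frequency's support fits in
  // n/2 bins (and n is even), else 1
  const uword half = n / 2;
  std::vector<int> dec(n_bands, (n % 2 == 0) ? 2 : 1);
  for (uword j = 0; j < freqs.n_elem; ++j) {
    int b = band_of(j);
    if (b < 0) continue;
    uword k0, k1;
    morlet_support(n, fs, freqs(j), omega0, k0, k1);
    if (k1 - k0 + 1 >= half) dec[b] = 1;
  }
  // samples per frame for each decimation stride
  mat samp_per_frame(n_frames, 2, fill::zeros);
  for (uword t = 0; t < n; ++t) {
    int fr = frame_of(t);
    if (fr < 0) continue;
    samp_per_frame(fr, 0) += 1.0;
    if (t % 2 == 0) samp_per_frame(fr, 1) += 1.0;
  }

  const float dfl = static_cast<float>(fs) / static_cast<float>(n);
  cx_fvec prod(n), prod2(half > 0 ? half : 1), w;
  for (uword c = 0; c < nch; ++c) {
    cx_fvec spectrum = fft(conv_to<cx_fvec>::from(
      conv_to<fvec>::from(V.col(c))));
    for (uword j = 0; j < freqs.n_elem; ++j) {
      int b = band_of(j);
      if (b < 0) continue;
      uword k0, k1;
      morlet_support(n, fs, freqs(j), omega0, k0, k1);
      const float f = static_cast<float>(freqs(j));
      const float sigma_f = f / static_cast<float>(omega0);
      if (dec[b] == 2) {
        prod2.zeros();
        for (uword k = k0; k <= k1; ++k) {
          float z = (k * dfl - f) / sigma_f;
          prod2(k % half) += spectrum(k) * std::exp(-0.5f * z * z);
        }
        w = ifft(prod2);
        const float scale = 0.5f;          // (m / n) amplitude factor
        for (uword t2 = 0; t2 < half; ++t2) {
          int fr = frame_of(2 * t2);
          if (fr >= 0) acc(c, b, fr) += std::norm(w(t2) * scale);
        }
      } else {
        prod.zeros();
        for (uword k = k0; k <= k1; ++k) {
          float z = (k * dfl - f) / sigma_f;
          prod(k) = spectrum(k) * std::exp(-0.5f * z * z);
        }
        w = ifft(prod);
        for (uword t = 0; t < n; ++t) {
          int fr = frame_of(t);
          if (fr >= 0) acc(c, b, fr) += std::norm(w(t));
        }
      }
    }
  }
  for (int fr = 0; fr < n_frames; ++fr)
    for (int b = 0; b < n_bands; ++b)
      for (uword c = 0; c < nch; ++c) {
        double denom = samp_per_frame(fr, dec[b] == 2 ? 1 : 0) *
          freq_per_band(b);
        acc(c, b, fr) = denom > 0 ? acc(c, b, fr) / denom : NA_REAL;
      }
  return acc;
}
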