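// Variational mode decomposition, ADMM in the Fourier domain.
// Follows the reference formulation: modes updated as Wiener filters about
// their current centre frequencies on the positive half-spectrum, centre
// frequencies as spectral centroids, dual ascent on the reconstruction
// constraint. The input is mirror-extended by half its length on each side
// before the call (done in R) so T here is always even. The one-sided
// spectrum is zero on the negative half throughout the iteration, so all
// updates run on the positive half only.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List vmd_core(const arma::vec& x, int K, double alpha, double tau,
                    double tol, int max_iter, int init) {
  const uword T = x.n_elem;
  const uword half = T / 2;

  // positive-half frequency grid in cycles/sample: 0, 1/T, ..., 1/2 - 1/T
  vec freqs = regspace<vec>(0, half - 1) / static_cast<double>(T);

  // one-sided spectrum of the input (fftshifted full spectrum, upper half)
  cx_vec f_full = shift(fft(x), static_cast<int>(half));
  cx_vec f_plus = f_full.tail(half);

  // centre-frequency init (cycles/sample)
  vec omega(K, fill::zeros);
  if (init == 1) {
    for (int k = 0; k < K; ++k)
      omega(k) = (0.5 / K) * k;
  }

  cx_mat u_hat(half, K, fill::zeros);
  cx_mat u_prev(half, K, fill::zeros);
  cx_vec lambda_hat(half, fill::zeros);
  cx_vec sum_uk(half, fill::zeros);

  double udiff = tol + 1.0;
  int n = 0;
  for (n = 0; n < max_iter && udiff > tol; ++n) {
    u_prev = u_hat;
    for (int k = 0; k < K; ++k) {
      // accumulator holds sum over all modes except k (previous iterate for
      // modes >= k, current for modes < k)
      if (k == 0)
        sum_uk += u_prev.col(K - 1) - u_prev.col(0);
      else
        sum_uk += u_hat.col(k - 1) - u_prev.col(k);

      u_hat.col(k) = (f_plus - sum_uk - lambda_hat / 2.0) /
                     (1.0 + alpha * square(freqs - omega(k)));

      vec pw = square(abs(u_hat.col(k)));
      double tot = accu(pw);
      if (tot > 0.0)
        omega(k) = dot(freqs, pw) / tot;
    }
    if (tau != 0.0)
      lambda_hat += tau * (sum(u_hat, 1) - f_plus);

    udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      cx_vec d = u_hat.col(k) - u_prev.col(k);
      udiff += std::abs(cdot(d, d)) / T;
    }
  }

  // back to time domain: rebuild two-sided spectra by Hermitian symmetry
  mat modes(T, K);
  cx_vec uh(T);
  for (int k = 0; k < K; ++k) {
    uh.zeros();
    uh.tail(half) = u_hat.col(k);
    for (uword i = 1; i <= half; ++i)
      uh(i) = std::conj(uh(T - i));
    uh(0) = std::conj(uh(T - 1));
    modes.col(k) = real(ifft(shift(uh, -static_cast<int>(half))));
  }

  return Rcpp::List::create(
      Rcpp::Named("modes") = modes,
      Rcpp::Named("omega") = omega,
      Rcpp::Named("iterations") = n,
      Rcpp::Named("converged") = (udiff <= tol));
}
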