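#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// Overdamped Langevin engine on a periodic 1D free-energy landscape with
// position-dependent diffusivity (Ito convention, explicit spurious drift).
//
// Landscape: F(x) = f0 + sum_k fc[k-1] cos(k x) + fs[k-1] sin(k x)  [kcal/mol]
// Diffusivity: log D(x) = ld0 + sum_k ldc[k-1] cos(k x) + lds[k-1] sin(k x)
//              D in rad^2/ps, x in rad, dt in ps, beta in mol/kcal.

namespace {

struct Landscape {
  std::vector<double> fc, fs, ldc, lds;
  double f0, ld0;

  double F(double x) const {
    double v = f0;
    for (size_t k = 0; k < fc.size(); ++k)
      v += fc[k] * std::cos((k + 1) * x) + fs[k] * std::sin((k + 1) * x);
    return v;
  }
  double dF(double x) const {
    double v = 0.0;
    for (size_t k = 0; k < fc.size(); ++k) {
      double kk = k + 1;
      v += kk * (-fc[k] * std::sin(kk * x) + fs[k] * std::cos(kk * x));
    }
    return v;
  }
  double logD(double x) const {
    double v = ld0;
    for (size_t k = 0; k < ldc.size(); ++k)
      v += ldc[k] * std::cos((k + 1) * x) + lds[k] * std::sin((k + 1) * x);
    return v;
  }
  double dlogD(double x) const {
    double v = 0.0;
    for (size_t k = 0; k < ldc.size(); ++k) {
      double kk = k + 1;
      v += kk * (-ldc[k] * std::sin(kk * x) + lds[k] * std::cos(kk * x));
    }
    return v;
  }
};

Landscape make_landscape(NumericVector fc, NumericVector fs, double f0,
                         NumericVector ldc, NumericVector lds, double ld0) {
  Landscape L;
  L.fc = as<std::vector<double>>(fc);
  L.fs = as<std::vector<double>>(fs);
  L.ldc = as<std::vector<double>>(ldc);
  L.lds = as<std::vector<double>>(lds);
  L.f0 = f0;
  L.ld0 = ld0;
  return L;
}

// splitmix64: decorrelates per-stream seeds derived from (seed, stream id)
inline std::uint64_t splitmix64(std::uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

std::mt19937_64 stream_rng(std::uint64_t seed, std::uint64_t stream) {
  return std::mt19937_64(splitmix64(splitmix64(seed) ^ (stream * 0x5851f42d4c957f2dULL + 1)));
}

// One Euler-Maruyama step; throws if the deterministic drift exceeds the
// stability bound of 0.2 rad.
inline double em_step(const Landscape &L, double x, double beta, double dt,
                      double bias_k, double bias_center, double eta) {
  double D = std::exp(L.logD(x));
  double grad = L.dF(x);
  if (bias_k > 0.0) grad += bias_k * (x - bias_center);
  double drift = -beta * D * grad * dt + D * L.dlogD(x) * dt;
  if (std::fabs(drift) > 0.2)
    stop("timestep too large: |drift| = %.3f rad > 0.2 rad per step; reduce dt",
         std::fabs(drift));
  return x + drift + std::sqrt(2.0 * D * dt) * eta;
}

}  // namespace

// [[Rcpp::export(name = ".langevin_cpp")]]
NumericVector langevin_cpp(NumericVector fc, NumericVector fs, double f0,
                           NumericVector ldc, NumericVector lds, double ld0,
                           double beta, double dt, double nsteps_d, int stride,
                           double x0, double bias_center, double bias_k,
                           double seed_d, double stream_d) {
  const Landscape L = make_landscape(fc, fs, f0, ldc, lds, ld0);
  const long long nsteps = (long long)nsteps_d;
  std::mt19937_64 rng = stream_rng((std::uint64_t)seed_d, (std::uint64_t)stream_d);
  std::normal_distribution<double> norm(0.0, 1.0);

  const long long nout = nsteps / stride;
  NumericVector out(nout);
  double x = x0;
  long long j = 0;
  for (long long i = 1; i <= nsteps; ++i) {
    x = em_step(L, x, beta, dt, bias_k, bias_center, norm(rng));
    if (i % stride == 0) out[j++] = x;
  }
  return out;
}

// Replica-exchange umbrella campaign: one walker per window, lockstep
// propagation, neighbour swap attempts every exchange_every steps with
// Metropolis acceptance on the bias energies (the landscape term cancels).
// [[Rcpp::export(name = ".campaign_cpp")]]
List campaign_cpp(NumericVector fc, NumericVector fs, double f0,
                  NumericVector ldc, NumericVector lds, double ld0,
                  double beta, double dt, double nsteps_d, int stride,
                  NumericVector centers, double bias_k, double exchange_every_d,
                  double seed_d, bool do_exchange) {
  const Landscape L = make_landscape(fc, fs, f0, ldc, lds, ld0);
  const long long nsteps = (long long)nsteps_d;
  const long long exchange_every = (long long)exchange_every_d;
  const int nw = centers.size();
  const long long nout = nsteps / stride;

  std::vector<std::mt19937_64> rng(nw);
  for (int w = 0; w < nw; ++w) rng[w] = stream_rng((std::uint64_t)seed_d, (std::uint64_t)w + 1);
  std::mt19937_64 xrng = stream_rng((std::uint64_t)seed_d, 0);  // exchange stream
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> x(nw);
  for (int w = 0; w < nw; ++w) x[w] = centers[w];

  NumericMatrix out(nout, nw);
  long long attempts = 0, accepted = 0;
  long long j = 0;
  for (long long i = 1; i <= nsteps; ++i) {
    for (int w = 0; w < nw; ++w)
      x[w] = em_step(L, x[w], beta, dt, bias_k, centers[w], norm(rng[w]));
    if (do_exchange && exchange_every > 0 && i % exchange_every == 0) {
      int parity = (unif(xrng) < 0.5) ? 0 : 1;
      for (int w = parity; w + 1 < nw; w += 2) {
        double du = 0.5 * bias_k *
                    ((x[w + 1] - centers[w]) * (x[w + 1] - centers[w]) +
                     (x[w] - centers[w + 1]) * (x[w] - centers[w + 1]) -
                     (x[w] - centers[w]) * (x[w] - centers[w]) -
                     (x[w + 1] - centers[w + 1]) * (x[w + 1] - centers[w + 1]));
        ++attempts;
        if (du <= 0.0 || unif(xrng) < std::exp(-beta * du)) {
          std::swap(x[w], x[w + 1]);
          ++accepted;
        }
      }
    }
    if (i % stride == 0) {
      for (int w = 0; w < nw; ++w) out(j, w) = x[w];
      ++j;
    }
  }
  double acc = attempts > 0 ? (double)accepted / (double)attempts : NA_REAL;
  return List::create(_["samples"] = out, _["acceptance"] = acc,
                      _["attempts"] = (double)attempts);
}

// Brute-force first-passage sampler: walkers start at x0, are mirrored at the
// reflecting boundary and stopped at first crossing of the absorbing boundary.
// Returns first-passage times in ps; censored walkers (step cap hit) are NA.
// [[Rcpp::export(name = ".fpt_cpp")]]
NumericVector fpt_cpp(NumericVector fc, NumericVector fs, double f0,
                      NumericVector ldc, NumericVector lds, double ld0,
                      double beta, double dt, double x0, double reflect_at,
                      double absorb_at, int n_walkers, double max_steps_d,
                      double seed_d) {
  const Landscape L = make_landscape(fc, fs, f0, ldc, lds, ld0);
  const long long max_steps = (long long)max_steps_d;
  // orient so that motion from reflect toward absorb is generic
  const double sgn = (absorb_at > reflect_at) ? 1.0 : -1.0;
  NumericVector out(n_walkers);
  std::normal_distribution<double> norm(0.0, 1.0);

  for (int w = 0; w < n_walkers; ++w) {
    std::mt19937_64 rng = stream_rng((std::uint64_t)seed_d, (std::uint64_t)w + 1);
    double x = x0;
    if (sgn * (x - absorb_at) >= 0.0) {  // already past the absorbing boundary
      out[w] = 0.0;
      continue;
    }
    double t = NA_REAL;
    for (long long i = 1; i <= max_steps; ++i) {
      x = em_step(L, x, beta, dt, 0.0, 0.0, norm(rng));
      if (sgn * (x - reflect_at) < 0.0) x = 2.0 * reflect_at - x;  // mirror
      if (sgn * (x - absorb_at) >= 0.0) {
        t = (double)i * dt;
        break;
      }
    }
    out[w] = t;
    if (w % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Auxiliary-coordinate sampler for restraint FEP inputs: overdamped Langevin
// on U(d) = 0.5*k_ref*(d-d0)^2 + flat-bottom(lower, upper, k_rest), constant D.
// [[Rcpp::export(name = ".aux_langevin_cpp")]]
NumericVector aux_langevin_cpp(double k_ref, double d0, double lower,
                               double upper, double k_rest, double D,
                               double beta, double dt, double nsteps_d,
                               int stride, double x0, double seed_d) {
  const long long nsteps = (long long)nsteps_d;
  std::mt19937_64 rng = stream_rng((std::uint64_t)seed_d, 42);
  std::normal_distribution<double> norm(0.0, 1.0);
  const long long nout = nsteps / stride;
  NumericVector out(nout);
  double x = x0;
  long long j = 0;
  const double sd = std::sqrt(2.0 * D * dt);
  for (long long i = 1; i <= nsteps; ++i) {
    double grad = k_ref * (x - d0);
    if (x < lower) grad += k_rest * (x - lower);
    if (x > upper) grad += k_rest * (x - upper);
    double drift = -beta * D * grad * dt;
    if (std::fabs(drift) > 0.2)
      stop("timestep too large for auxiliary coordinate; reduce dt");
    x += drift + sd * norm(rng);
    if (i % stride == 0) out[j++] = x;
  }
  return out;
}
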