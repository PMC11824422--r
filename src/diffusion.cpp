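// One-dimensional Wright-Fisher diffusion engine for expected folded SFSs.
//
// The density phi(x, t) of segregating sites at population frequency x obeys
//   d phi / dt = d/dx [ D dpsi/dx - c psi ],   psi = V(x) phi,
// with V(x) = x(1-x)/nu, M(x) = gamma x(1-x), c = M/V = gamma * nu, D = 1/2.
// Time is measured in 2*N_anc generations, gamma = 2*N_anc*s, and nu is the
// relative population size of the current epoch.  New mutations are injected
// near x = 0 at a rate that reproduces the classical theta/x equilibrium
// profile (per unit theta).  The flux form with psi = V*phi has a constant
// advection coefficient, so a Scharfetter-Gummel (exponentially fitted) flux
// is exact for the advective part and remains stable for |gamma| up to the
// lethal-equivalent cutoff.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Bernoulli function B(z) = z / (exp(z) - 1), numerically safe.
static double bern(double z) {
  if (std::fabs(z) < 1e-10) return 1.0 - z / 2.0;
  if (z > 700.0) return 0.0;
  if (z < -700.0) return -z;
  return z / std::expm1(z);
}

// Equilibrium density per unit theta at relative size nu and scaled
// coefficient gamma (<= 0): phi(x) = nu * r(x) / (x (1 - x)) with
// r(x) = expm1(a (1-x)) / expm1(a), a = -2 gamma nu.  Neutral limit r = 1 - x.
static double phi_equilibrium(double x, double gamma, double nu) {
  double a = -2.0 * gamma * nu;
  double r;
  if (std::fabs(a) < 1e-8) {
    r = 1.0 - x;
  } else {
    // r = exp(-a x) (1 - exp(-a (1-x))) / (1 - exp(-a)), stable for a > 0
    r = std::exp(-a * x) * (-std::expm1(-a * (1.0 - x))) / (-std::expm1(-a));
  }
  return nu * r / (x * (1.0 - x));
}

// Non-uniform grid on [0,1], quadratically crowded at both boundaries.
static std::vector<double> make_grid(int pts) {
  std::vector<double> x(pts);
  for (int j = 0; j < pts; ++j) {
    double u = (double)j / (double)(pts - 1);
    double s = std::sin(M_PI * u / 2.0);
    x[j] = s * s;
  }
  x[0] = 0.0;
  x[pts - 1] = 1.0;
  return x;
}

// Thomas algorithm for a tridiagonal system (in place on copies).
static void solve_tridiag(std::vector<double>& a, std::vector<double>& b,
                          std::vector<double>& c, std::vector<double>& d,
                          std::vector<double>& out) {
  int m = (int)b.size();
  for (int i = 1; i < m; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  out[m - 1] = d[m - 1] / b[m - 1];
  for (int i = m - 2; i >= 0; --i) {
    out[i] = (d[i] - c[i] * out[i + 1]) / b[i];
  }
}

struct Tridiag {
  // A phi (interior nodes 1..G-2): lower, diag, upper
  std::vector<double> lo, di, up;
};

// Build the spatial operator A such that dphi/dt = A phi (interior nodes).
static Tridiag build_operator(const std::vector<double>& x, double gamma,
                              double nu) {
  int G = (int)x.size();
  int m = G - 2;
  double c = gamma * nu;  // advection coefficient for psi
  double D = 0.5;
  Tridiag A;
  A.lo.assign(m, 0.0);
  A.di.assign(m, 0.0);
  A.up.assign(m, 0.0);
  std::vector<double> V(G);
  for (int j = 0; j < G; ++j) V[j] = x[j] * (1.0 - x[j]) / nu;
  for (int j = 1; j <= G - 2; ++j) {
    double hl = x[j] - x[j - 1];
    double hr = x[j + 1] - x[j];
    double w = (x[j + 1] - x[j - 1]) / 2.0;
    double PeL = c * hl / D;
    double PeR = c * hr / D;
    // fluxes: J_{j-1/2} = (D/hl)[B(-PeL) psi_{j-1} - B(PeL) psi_j]
    //         J_{j+1/2} = (D/hr)[B(-PeR) psi_j   - B(PeR) psi_{j+1}]
    // dphi_j/dt = (J_{j-1/2} - J_{j+1/2}) / w
    double kl = D / hl, kr = D / hr;
    int i = j - 1;
    if (j > 1) A.lo[i] = kl * bern(-PeL) * V[j - 1] / w;
    A.di[i] = -(kl * bern(PeL) + kr * bern(-PeR)) * V[j] / w;
    if (j < G - 2) A.up[i] = kr * bern(PeR) * V[j + 1] / w;
    // psi at the boundary nodes is identically zero (V = 0), so the
    // boundary terms drop out: mass simply flows off the grid there.
  }
  return A;
}

// Integrate phi over one epoch of duration T at size nu with injection.
// theta-scaled injection: phi[1] += dt / x[1] * (1/2) * 2/(x[2]-x[0]).
static void integrate_epoch(std::vector<double>& phi,
                            const std::vector<double>& x, double gamma,
                            double nu, double T, double dt_target) {
  if (T <= 0) return;
  int G = (int)x.size();
  int m = G - 2;
  Tridiag A = build_operator(x, gamma, nu);
  int nsteps = (int)std::ceil(T / dt_target);
  if (nsteps < 20) nsteps = 20;
  double dt = T / nsteps;
  double inj = (1.0 / x[1]) * 0.5 * 2.0 / (x[2] - x[0]);  // per unit time
  // Crank-Nicolson: (I - dt/2 A) phi_new = (I + dt/2 A) phi_old + dt*src
  std::vector<double> lo(m), di(m), up(m), rhs(m), out(m);
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < m; ++i) {
      lo[i] = -dt / 2.0 * A.lo[i];
      di[i] = 1.0 - dt / 2.0 * A.di[i];
      up[i] = -dt / 2.0 * A.up[i];
      double acc = phi[i + 1] * (1.0 + dt / 2.0 * A.di[i]);
      if (i > 0) acc += dt / 2.0 * A.lo[i] * phi[i];
      if (i < m - 1) acc += dt / 2.0 * A.up[i] * phi[i + 2];
      rhs[i] = acc;
    }
    rhs[0] += dt * inj;
    solve_tridiag(lo, di, up, rhs, out);
    for (int i = 0; i < m; ++i) phi[i + 1] = out[i];
  }
}

// [[Rcpp::export(name = ".diffusion_sfs_cpp")]]
NumericVector diffusion_sfs_cpp(int n, double gamma, NumericVector sizes,
                                NumericVector durations, int pts,
                                double dt_target) {
  // sizes: relative sizes of the non-ancestral epochs (oldest first);
  // durations: matching epoch durations in units of 2*N_anc generations.
  // The ancestral epoch has size 1 and the density starts at its
  // equilibrium.  Returns the unfolded spectrum E[X_1..X_{n-1}] per unit
  // theta; folding is done on the R side.
  std::vector<double> x = make_grid(pts);
  int G = pts;
  std::vector<double> phi(G, 0.0);
  for (int j = 1; j < G - 1; ++j) phi[j] = phi_equilibrium(x[j], gamma, 1.0);
  phi[0] = 0.0;
  phi[G - 1] = 0.0;
  for (int e = 0; e < sizes.size(); ++e) {
    integrate_epoch(phi, x, gamma, sizes[e], durations[e], dt_target);
  }
  // Sample: E[X_i] = int phi(x) C(n,i) x^i (1-x)^(n-i) dx, trapezoid rule.
  NumericVector out(n - 1);
  for (int i = 1; i <= n - 1; ++i) {
    double lchoose = R::lchoose((double)n, (double)i);
    double acc = 0.0;
    double prev = 0.0;
    for (int j = 0; j < G; ++j) {
      double f;
      if (x[j] <= 0.0 || x[j] >= 1.0) {
        f = 0.0;  // kernel vanishes at the boundaries for 1 <= i <= n-1
      } else {
        f = phi[j] * std::exp(lchoose + i * std::log(x[j]) +
                              (n - i) * std::log1p(-x[j]));
      }
      if (j > 0) acc += 0.5 * (f + prev) * (x[j] - x[j - 1]);
      prev = f;
    }
    out[i - 1] = acc;
  }
  return out;
}

// [[Rcpp::export(name = ".equilibrium_sfs_cpp")]]
NumericVector equilibrium_sfs_cpp(int n, double gamma, int pts) {
  // Stationary spectrum on the grid without time stepping (size 1).
  std::vector<double> x = make_grid(pts);
  int G = pts;
  NumericVector out(n - 1);
  for (int i = 1; i <= n - 1; ++i) {
    double lchoose = R::lchoose((double)n, (double)i);
    double acc = 0.0, prev = 0.0;
    for (int j = 0; j < G; ++j) {
      double f = 0.0;
      if (x[j] > 0.0 && x[j] < 1.0) {
        f = phi_equilibrium(x[j], gamma, 1.0) *
            std::exp(lchoose + i * std::log(x[j]) +
                     (n - i) * std::log1p(-x[j]));
      }
      if (j > 0) acc += 0.5 * (f + prev) * (x[j] - x[j - 1]);
      prev = f;
    }
    out[i - 1] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward Wright-Fisher oracles (haploid, fitnesses 1 and 1+s, s <= 0).
// Population of N haploids; time unit for the scaled parameters is N
// generations and gamma = N*s, matching the diffusion engine's units
// (haploid N corresponds to 2*N_anc diploid-equivalent lineages).

// Equilibrium oracle by independent mutation trajectories (renewal reward):
// each new mutation starts at count 1; E[X_i] per unit theta is half the
// mean, over trajectories, of the summed per-generation probability that a
// without-replacement sample of n contains exactly i copies.
// [[Rcpp::export(name = ".wf_trajectory_sfs_cpp")]]
List wf_trajectory_sfs_cpp(int N, double gamma, int n, int reps) {
  double s = gamma / (double)N;
  int nb = n / 2;
  NumericMatrix contrib(reps, nb);  // folded bins per trajectory
  for (int r = 0; r < reps; ++r) {
    int k = 1;
    std::vector<double> acc(nb, 0.0);
    while (k > 0 && k < N) {
      double xfreq = (double)k / (double)N;
      // accumulate exact hypergeometric sampling probabilities
      for (int i = 1; i <= n - 1; ++i) {
        double p = std::exp(R::lchoose(k, i) + R::lchoose(N - k, n - i) -
                            R::lchoose(N, n));
        int f = (i <= n - i) ? i : (n - i);
        if (!(ISNAN(p)) && p > 0) acc[f - 1] += p;
      }
      double xp = xfreq * (1.0 + s) / (1.0 + s * xfreq);
      if (xp < 0) xp = 0;
      if (xp > 1) xp = 1;
      k = (int)R::rbinom((double)N, xp);
    }
    for (int b = 0; b < nb; ++b) contrib(r, b) = 0.5 * acc[b];
  }
  return List::create(Named("contrib") = contrib);
}

// Two-epoch (or equilibrium) whole-population oracle with infinite-sites
// injection; returns one folded sample per replicate run.
// [[Rcpp::export(name = ".wf_population_sfs_cpp")]]
NumericMatrix wf_population_sfs_cpp(int N0, double gamma, double nu,
                                    double tau, int n, int nreps,
                                    double theta, double burn_mult) {
  double s = gamma / (double)N0;
  int nb = n / 2;
  NumericMatrix out(nreps, nb);
  for (int r = 0; r < nreps; ++r) {
    std::vector<int> seg;
    int N = N0;
    long burn = (long)std::ceil(burn_mult * N0);
    long post = (long)std::ceil(tau * N0);
    for (long g = 0; g < burn + post; ++g) {
      if (g == burn && nu != 1.0) {
        // instantaneous size change: binomially resample counts
        int N1 = (int)std::lround(nu * N0);
        if (N1 < 2) N1 = 2;
        for (size_t m = 0; m < seg.size(); ++m) {
          seg[m] = (int)R::rbinom((double)N1, (double)seg[m] / (double)N);
        }
        N = N1;
      }
      // drift + selection
      size_t keep = 0;
      for (size_t m = 0; m < seg.size(); ++m) {
        double xfreq = (double)seg[m] / (double)N;
        double xp = xfreq * (1.0 + s) / (1.0 + s * xfreq);
        if (xp < 0) xp = 0;
        if (xp > 1) xp = 1;
        int k = (int)R::rbinom((double)N, xp);
        if (k > 0 && k < N) seg[keep++] = k;
      }
      seg.resize(keep);
      // inject: theta/2 new mutations per generation at the current size
      // relative to N0 (per-individual mutation rate is constant)
      int nnew = (int)R::rpois(theta / 2.0 * (double)N / (double)N0);
      for (int m = 0; m < nnew; ++m) seg.push_back(1);
    }
    // sample n haplotypes without replacement at each segregating site
    for (size_t m = 0; m < seg.size(); ++m) {
      int j = (int)R::rhyper((double)seg[m], (double)(N - seg[m]), (double)n);
      if (j > 0 && j < n) {
        int f = (j <= n - j) ? j : (n - j);
        out(r, f - 1) += 1.0;
      }
    }
  }
  return out;
}
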