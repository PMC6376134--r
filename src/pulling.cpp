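#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Overdamped (Brownian) constant-velocity pulling integrator.
//
// Beads follow x <- x + (dt/gamma) F + sqrt(2 kB T dt / gamma) eta per
// coordinate; the spring anchor starts at the pulled bead and moves at
// constant velocity along the pulling direction.  Harmonic bonds marked
// breakable are removed permanently once their extension exceeds
// break_ext.  Separation is declared when every breakable bond is broken
// AND the pulled bead has moved sep_dist past its bound position along the
// pulling direction.  The recorded force is the spring force projected on
// the pulling direction, in pN.
//
// Uses R's RNG (norm_rand) so set.seed() in R gives full determinism.

static const double KB_KCAL = 0.0019872041;   // kcal mol-1 K-1
static const double KCAL_A_TO_PN = 69.479;    // 1 kcal mol-1 A-1 in pN

// [[Rcpp::export(name = ".cgPull")]]
List cgPull(NumericMatrix pos0, LogicalVector fixed, int pulled,
            IntegerVector bond_i, IntegerVector bond_j, NumericVector r0,
            NumericVector bond_k, NumericVector break_ext,
            LogicalVector breakable, double spring_k, double velocity,
            NumericVector dir, double gamma, double temperature, double dt,
            double duration, double record_every, double sep_dist,
            bool early_stop, double stop_after, double confine_k) {
  const int n = pos0.nrow();
  const int nb = bond_i.size();
  const int ip = pulled - 1;  // 0-based
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos0(i, c);
  std::vector<double> f(3 * n, 0.0);
  std::vector<bool> broken(nb, false);
  std::vector<double> break_time(nb, -1.0);
  int n_breakable = 0, n_broken = 0;
  for (int b = 0; b < nb; ++b) if (breakable[b]) ++n_breakable;

  const double d0x = dir[0], d0y = dir[1], d0z = dir[2];
  const double ax0 = x[3 * ip], ay0 = x[3 * ip + 1], az0 = x[3 * ip + 2];
  const long nsteps = (long)std::llround(duration / dt);
  const int rec_stride = std::max(1, (int)std::lround(record_every / dt));
  const double namp =
      temperature > 0 ? std::sqrt(2.0 * KB_KCAL * temperature * dt / gamma)
                      : 0.0;

  std::vector<double> rec_t, rec_f, rec_ext;
  rec_t.reserve(nsteps / rec_stride + 2);
  rec_f.reserve(nsteps / rec_stride + 2);
  rec_ext.reserve(nsteps / rec_stride + 2);

  double sep_time = -1.0, max_force = R_NegInf, max_force_time = 0.0;
  double all_broken_time = -1.0, first_break_time = -1.0;

  for (long step = 0; step <= nsteps; ++step) {
    const double t = step * dt;
    std::fill(f.begin(), f.end(), 0.0);

    // harmonic bonds (breakable ones removed past their break extension)
    for (int b = 0; b < nb; ++b) {
      if (broken[b]) continue;
      const int i = bond_i[b] - 1, j = bond_j[b] - 1;
      const double dx = x[3 * j] - x[3 * i];
      const double dy = x[3 * j + 1] - x[3 * i + 1];
      const double dz = x[3 * j + 2] - x[3 * i + 2];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      const double ext = r - r0[b];
      if (breakable[b] && ext > break_ext[b]) {
        broken[b] = true;
        break_time[b] = t;
        ++n_broken;
        if (first_break_time < 0) first_break_time = t;
        if (n_broken == n_breakable) all_broken_time = t;
        continue;
      }
      const double fm = bond_k[b] * ext / r;  // pulls i toward j when ext>0
      f[3 * i] += fm * dx;     f[3 * j] -= fm * dx;
      f[3 * i + 1] += fm * dy; f[3 * j + 1] -= fm * dy;
      f[3 * i + 2] += fm * dz; f[3 * j + 2] -= fm * dz;
    }

    // weak transverse confinement of mobile beads about their initial
    // positions (a crowding surrogate for the surrounding protein matrix);
    // acts only perpendicular to the pulling direction, so axial motion --
    // pulling, unbinding, drag -- is unaffected
    if (confine_k > 0) {
      for (int i = 0; i < n; ++i) {
        if (fixed[i]) continue;
        const double ddx = x[3 * i] - pos0(i, 0);
        const double ddy = x[3 * i + 1] - pos0(i, 1);
        const double ddz = x[3 * i + 2] - pos0(i, 2);
        const double along = ddx * d0x + ddy * d0y + ddz * d0z;
        f[3 * i] -= confine_k * (ddx - along * d0x);
        f[3 * i + 1] -= confine_k * (ddy - along * d0y);
        f[3 * i + 2] -= confine_k * (ddz - along * d0z);
      }
    }

    // moving harmonic spring on the pulled bead
    const double axp = ax0 + velocity * t * d0x;
    const double ayp = ay0 + velocity * t * d0y;
    const double azp = az0 + velocity * t * d0z;
    const double sx = axp - x[3 * ip];
    const double sy = ayp - x[3 * ip + 1];
    const double sz = azp - x[3 * ip + 2];
    f[3 * ip] += spring_k * sx;
    f[3 * ip + 1] += spring_k * sy;
    f[3 * ip + 2] += spring_k * sz;
    const double force_pn =
        spring_k * (sx * d0x + sy * d0y + sz * d0z) * KCAL_A_TO_PN;

    // separation bookkeeping (before this step's move)
    const double proj = (x[3 * ip] - ax0) * d0x + (x[3 * ip + 1] - ay0) * d0y +
                        (x[3 * ip + 2] - az0) * d0z;
    const bool separated_now =
        (n_broken == n_breakable) && (proj >= sep_dist);
    if (sep_time < 0 && separated_now) sep_time = t;
    if (sep_time < 0 && force_pn > max_force) {
      max_force = force_pn;
      max_force_time = t;
    }

    if (step % rec_stride == 0) {
      rec_t.push_back(t);
      rec_f.push_back(force_pn);
      rec_ext.push_back(velocity * t - proj);
    }

    if (early_stop && sep_time >= 0 && t >= sep_time + stop_after) break;

    // Euler-Maruyama update of mobile beads
    for (int i = 0; i < n; ++i) {
      if (fixed[i]) continue;
      for (int c = 0; c < 3; ++c) {
        double dxc = (dt / gamma) * f[3 * i + c];
        if (namp > 0) dxc += namp * norm_rand();
        x[3 * i + c] += dxc;
      }
    }
  }

  NumericMatrix pos_final(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) pos_final(i, c) = x[3 * i + c];

  return List::create(
      _["time"] = wrap(rec_t), _["force_pN"] = wrap(rec_f),
      _["extension_A"] = wrap(rec_ext),
      _["break_time"] = wrap(break_time),
      _["first_break_time"] = first_break_time,
      _["all_broken_time"] = all_broken_time,
      _["separation_time"] = sep_time,
      _["max_force_pN"] = (max_force == R_NegInf ? NA_REAL : max_force),
      _["max_force_time"] = max_force_time,
      _["positions"] = pos_final);
}
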