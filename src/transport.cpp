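// Condensed-history electron transport at desk scale.
//
// One history = one primary electron stepped through the machine stack
// (slabs + absorbing apertures along -z), an optional air gap, and a
// voxelized phantom (entrance plane at z = phantom origin). Per step:
// CSDA collision loss (log-log interpolated mass stopping power x density),
// a radiative fraction removed but not transported, and a Highland-form
// Gaussian deflection. Steps never cross voxel faces or slab boundaries.
// Energy bookkeeping is exact: injected = phantom deposit + upstream
// deposit + radiative + escaped + wall-absorbed.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr double ME = 0.511;        // electron rest mass, MeV
constexpr double EPS_STEP = 1e-6;   // mm, boundary push-through

struct FineTable {
  double e0, de;
  std::vector<double> sp;       // linear stopping power, MeV/cm
  std::vector<double> radfrac;  // radiative / collision loss ratio
  double density;               // g/cm^3
  double x0;                    // radiation length, g/cm^2
  double lookup_sp(double e) const {
    double f = (e - e0) / de;
    if (f <= 0) return sp.front();
    size_t i = (size_t)f;
    if (i >= sp.size() - 1) return sp.back();
    double w = f - i;
    return sp[i] * (1 - w) + sp[i + 1] * w;
  }
  double lookup_rf(double e) const {
    double f = (e - e0) / de;
    if (f <= 0) return radfrac.front();
    size_t i = (size_t)f;
    if (i >= radfrac.size() - 1) return radfrac.back();
    double w = f - i;
    return radfrac[i] * (1 - w) + radfrac[i + 1] * w;
  }
};

// log-log interpolation on the coarse bundled table
double loglog_interp(const std::vector<double>& le, const std::vector<double>& lv,
                     double loge) {
  if (loge <= le.front()) return std::exp(lv.front());
  if (loge >= le.back()) return std::exp(lv.back());
  size_t lo = 0, hi = le.size() - 1;
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (le[mid] <= loge) lo = mid; else hi = mid;
  }
  double w = (loge - le[lo]) / (le[hi] - le[lo]);
  return std::exp(lv[lo] * (1 - w) + lv[hi] * w);
}

struct Element {
  int type;       // 0 = slab, 1 = aperture (air inside radius, absorber outside)
  double z0, z1;  // mm
  int mat;        // slab material index
  double ap_r;    // aperture radius, mm
  double tanb;    // exit-plane tilt (bevel), aperture only
};

struct Pstate {
  double e, x, y, z, u, v, w;
  double weight;
};

double highland_sigma(double e, double t_gcm2, double x0) {
  if (t_gcm2 <= 0 || x0 <= 0) return 0.0;
  double pc = std::sqrt(e * (e + 2.0 * ME));
  double betapc = pc * pc / (e + ME);
  double tr = t_gcm2 / x0;
  double s = (13.6 / betapc) * std::sqrt(tr) * (1.0 + 0.038 * std::log(tr));
  return s > 0 ? s : 0.0;
}

void deflect(Pstate& p, double gx, double gy) {
  // orthonormal transverse basis about the current direction
  double e1x, e1y, e1z;
  double uu = p.u, vv = p.v, ww = p.w;
  if (std::fabs(ww) < 0.99999) {
    double n = std::sqrt(uu * uu + vv * vv);
    e1x = -vv / n; e1y = uu / n; e1z = 0.0;
  } else {
    e1x = 1.0; e1y = 0.0; e1z = 0.0;
  }
  double e2x = vv * e1z - ww * e1y;
  double e2y = ww * e1x - uu * e1z;
  double e2z = uu * e1y - vv * e1x;
  double dx = uu + gx * e1x + gy * e2x;
  double dy = vv + gx * e1y + gy * e2y;
  double dz = ww + gx * e1z + gy * e2z;
  double n = std::sqrt(dx * dx + dy * dy + dz * dz);
  p.u = dx / n; p.v = dy / n; p.w = dz / n;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_transport(List source, List elements_list, List phantom,
                       List materials, List config,
                       double phsp_plane_z, bool record_phsp) {
  // --- materials: build fine lookup tables ---
  const double cutoff = as<double>(config["cutoff"]);
  const double max_step = as<double>(config["max_step"]);
  const double max_step_air = as<double>(config["max_step_air"]);
  const R_xlen_t n_hist = (R_xlen_t)as<double>(config["n_histories"]);
  const uint64_t seed = (uint64_t)as<double>(config["seed"]);

  const size_t nmat = materials.size();
  std::vector<FineTable> mats(nmat);
  const double e_top = 16.0;
  for (size_t m = 0; m < nmat; ++m) {
    List mm = materials[m];
    std::vector<double> le = as<std::vector<double>>(mm["log_e"]);
    std::vector<double> ls = as<std::vector<double>>(mm["log_sp"]);
    std::vector<double> rf_e = as<std::vector<double>>(mm["radfrac"]);
    FineTable& ft = mats[m];
    ft.density = as<double>(mm["density"]);
    ft.x0 = as<double>(mm["x0"]);
    ft.e0 = cutoff * 0.5;
    ft.de = 0.02;
    size_t n = (size_t)((e_top - ft.e0) / ft.de) + 2;
    ft.sp.resize(n); ft.radfrac.resize(n);
    for (size_t i = 0; i < n; ++i) {
      double e = ft.e0 + i * ft.de;
      double loge = std::log(e);
      ft.sp[i] = loglog_interp(le, ls, loge) * ft.density; // MeV/cm
      // radfrac supplied on same log-energy nodes, linear interp in log E
      double rf;
      if (loge <= le.front()) rf = rf_e.front();
      else if (loge >= le.back()) rf = rf_e.back();
      else {
        size_t lo = 0, hi = le.size() - 1;
        while (hi - lo > 1) { size_t mid = (lo + hi) / 2; if (le[mid] <= loge) lo = mid; else hi = mid; }
        double w = (loge - le[lo]) / (le[hi] - le[lo]);
        rf = rf_e[lo] * (1 - w) + rf_e[hi] * w;
      }
      ft.radfrac[i] = rf;
    }
  }
  const int air_mat = as<int>(config["air_material"]);

  // --- machine elements ---
  std::vector<Element> els;
  {
    NumericVector z0 = elements_list["z0"], z1 = elements_list["z1"],
                  apr = elements_list["ap_r"], tanb = elements_list["tanb"];
    IntegerVector type = elements_list["type"], mat = elements_list["mat"];
    for (R_xlen_t i = 0; i < z0.size(); ++i) {
      Element e;
      e.type = type[i]; e.z0 = z0[i]; e.z1 = z1[i];
      e.mat = mat[i]; e.ap_r = apr[i]; e.tanb = tanb[i];
      els.push_back(e);
    }
  }

  // --- phantom grid ---
  NumericVector origin = phantom["origin"], spacing = phantom["spacing"];
  IntegerVector dims = phantom["dims"];
  IntegerVector vox_mat = phantom["material"]; // length 1 (uniform) or nvox
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const bool uniform = (vox_mat.size() == 1);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double px1 = ox + nx * sx, py1 = oy + ny * sy, pz1 = oz + nz * sz;

  NumericVector edep(nvox);
  IntegerVector entries(nvox);

  // --- source ---
  std::string skind = as<std::string>(source["kind"]);
  double src_z = as<double>(source["z"]);
  double mean_e = 0, sig_e = 0, sig_spot = 0, sig_div = 0;
  NumericMatrix phsp_in;
  R_xlen_t n_rec = 0;
  if (skind == "beam") {
    mean_e = as<double>(source["mean_energy"]);
    sig_e = as<double>(source["sigma_e"]);
    sig_spot = as<double>(source["sigma_spot"]);
    sig_div = as<double>(source["sigma_div"]);
  } else {
    phsp_in = as<NumericMatrix>(source["records"]); // cols E,x,y,u,v,w,weight
    n_rec = phsp_in.nrow();
    if (n_rec == 0) stop("phase-space source has no records");
  }

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  // world bounds
  double lat_max = std::max({std::fabs(ox), std::fabs(px1), std::fabs(oy),
                             std::fabs(py1), 400.0});
  double z_min_world = src_z - 50.0;

  // tallies
  double t_injected = 0, t_phantom = 0, t_upstream = 0, t_radiative = 0,
         t_escaped = 0, t_wall = 0;
  double n_escaped = 0, n_wall = 0;

  std::vector<double> ps_out;
  double n_ps = 0;

  for (R_xlen_t h = 0; h < n_hist; ++h) {
    Pstate p;
    if (skind == "beam") {
      double e;
      do { e = mean_e + sig_e * gauss(rng); } while (e <= 0);
      p.e = e;
      p.x = sig_spot * gauss(rng);
      p.y = sig_spot * gauss(rng);
      p.z = src_z;
      double tx = sig_div * gauss(rng), ty = sig_div * gauss(rng);
      double n = std::sqrt(tx * tx + ty * ty + 1.0);
      p.u = tx / n; p.v = ty / n; p.w = 1.0 / n;
      p.weight = 1.0;
    } else {
      R_xlen_t i = h % n_rec;
      p.e = phsp_in(i, 0); p.x = phsp_in(i, 1); p.y = phsp_in(i, 2);
      p.u = phsp_in(i, 3); p.v = phsp_in(i, 4); p.w = phsp_in(i, 5);
      p.weight = phsp_in(i, 6);
      p.z = src_z;
    }
    t_injected += p.e * p.weight;
    R_xlen_t last_vox = -1;
    bool alive = true;

    while (alive) {
      bool in_phantom = (p.z >= oz && p.z < pz1 &&
                         p.x >= ox && p.x < px1 && p.y >= oy && p.y < py1);
      int mat_idx;
      double step_cap;
      R_xlen_t vox = -1;

      if (in_phantom) {
        int ix = (int)((p.x - ox) / sx);
        int iy = (int)((p.y - oy) / sy);
        int iz = (int)((p.z - oz) / sz);
        if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
        if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
        if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
        vox = (R_xlen_t)ix + (R_xlen_t)nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz);
        mat_idx = uniform ? vox_mat[0] : vox_mat[vox];
        if (vox != last_vox) { entries[vox] += 1; last_vox = vox; }
        // distance to nearest voxel face along direction
        double tmin = max_step;
        if (p.u > 0) tmin = std::min(tmin, (ox + (ix + 1) * sx - p.x) / p.u);
        else if (p.u < 0) tmin = std::min(tmin, (ox + ix * sx - p.x) / p.u);
        if (p.v > 0) tmin = std::min(tmin, (oy + (iy + 1) * sy - p.y) / p.v);
        else if (p.v < 0) tmin = std::min(tmin, (oy + iy * sy - p.y) / p.v);
        if (p.w > 0) tmin = std::min(tmin, (oz + (iz + 1) * sz - p.z) / p.w);
        else if (p.w < 0) tmin = std::min(tmin, (oz + iz * sz - p.z) / p.w);
        step_cap = tmin + EPS_STEP;
      } else {
        // upstream / surrounding region: find containing element
        mat_idx = air_mat;
        bool killed = false;
        for (const Element& el : els) {
          if (p.z >= el.z0 && p.z < el.z1) {
            if (el.type == 0) { mat_idx = el.mat; }
            else {
              double r2 = p.x * p.x + p.y * p.y;
              double zedge = el.z1 + p.x * el.tanb;
              if (r2 >= el.ap_r * el.ap_r && p.z < zedge) { killed = true; }
            }
            break;
          }
        }
        if (killed) {
          t_wall += p.e * p.weight; n_wall += 1; alive = false; break;
        }
        // distance to next element z-boundary or phantom entrance
        double tz = max_step_air;
        if (p.w != 0) {
          for (const Element& el : els) {
            for (double zb : {el.z0, el.z1}) {
              double t = (zb - p.z) / p.w;
              if (t > EPS_STEP && t < tz) tz = t;
            }
          }
          double t = (oz - p.z) / p.w;
          if (t > EPS_STEP && t < tz) tz = t;
          t = (pz1 - p.z) / p.w;
          if (t > EPS_STEP && t < tz) tz = t;
        }
        step_cap = std::min(max_step_air, tz + EPS_STEP);
      }

      const FineTable& ft = mats[mat_idx];
      double sp = ft.lookup_sp(p.e);          // MeV/cm
      // cap fractional energy loss per step at 20%
      double s = step_cap;
      double s_eloss = 0.2 * p.e / sp * 10.0; // mm
      if (s_eloss < s) s = s_eloss;
      if (s < EPS_STEP) s = EPS_STEP;

      double de_col = sp * (s / 10.0);
      double rf = ft.lookup_rf(p.e);
      double de_rad = rf * de_col;

      if (p.e - de_col - de_rad <= cutoff) {
        // terminal step: residual energy deposits locally
        if (in_phantom) { edep[vox] += p.e * p.weight; t_phantom += p.e * p.weight; }
        else t_upstream += p.e * p.weight;
        alive = false;
        break;
      }

      if (in_phantom) { edep[vox] += de_col * p.weight; t_phantom += de_col * p.weight; }
      else t_upstream += de_col * p.weight;
      t_radiative += de_rad * p.weight;

      // phase-space plane crossing (before move uses old z)
      double z_new = p.z + p.w * s;
      if (record_phsp && p.w > 0 && p.z < phsp_plane_z && z_new >= phsp_plane_z) {
        double tcross = (phsp_plane_z - p.z) / p.w;
        ps_out.push_back(p.e);
        ps_out.push_back(p.x + p.u * tcross);
        ps_out.push_back(p.y + p.v * tcross);
        ps_out.push_back(p.u); ps_out.push_back(p.v); ps_out.push_back(p.w);
        ps_out.push_back(p.weight);
        n_ps += 1;
      }

      p.x += p.u * s; p.y += p.v * s; p.z = z_new;
      p.e -= de_col + de_rad;

      // multiple scattering
      double sig = highland_sigma(p.e, (s / 10.0) * ft.density, ft.x0);
      if (sig > 0) deflect(p, sig * gauss(rng), sig * gauss(rng));

      // world escape
      if (p.z >= pz1 || p.z < z_min_world ||
          std::fabs(p.x) > lat_max || std::fabs(p.y) > lat_max ||
          (p.z >= oz && p.z < pz1 &&
           (p.x < ox || p.x >= px1 || p.y < oy || p.y >= py1))) {
        t_escaped += p.e * p.weight; n_escaped += 1; alive = false;
      }
      // leaving the phantom resets the entry tracker so re-entry counts anew
      if (alive && last_vox >= 0 &&
          !(p.z >= oz && p.z < pz1 && p.x >= ox && p.x < px1 &&
            p.y >= oy && p.y < py1))
        last_vox = -1;
    }
  }

  NumericMatrix ps_mat(record_phsp ? (R_xlen_t)n_ps : 0, 7);
  if (record_phsp && n_ps > 0) {
    for (R_xlen_t i = 0; i < (R_xlen_t)n_ps; ++i)
      for (int j = 0; j < 7; ++j) ps_mat(i, j) = ps_out[i * 7 + j];
  }

  return List::create(
    _["energy"] = edep,
    _["entries"] = entries,
    _["injected"] = t_injected,
    _["deposited_phantom"] = t_phantom,
    _["deposited_upstream"] = t_upstream,
    _["radiative"] = t_radiative,
    _["escaped"] = t_escaped,
    _["wall_absorbed"] = t_wall,
    _["n_escaped"] = n_escaped,
    _["n_wall"] = n_wall,
    _["phsp"] = ps_mat);
}
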