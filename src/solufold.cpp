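// Compute-heavy kernels: Shrake-Rupley SASA, ideal-geometry chain building,
// the toy-folder composite loss and its finite-difference gradient.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// ideal backbone constants; must match R/backbone.R
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329,
                    B_C_O = 1.231;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7,
                    A_CA_C_O = 120.5;
static const double T_OMEGA = 180.0;

// ---------------------------------------------------------------- SASA ----

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii, double probe,
                       int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  // deterministic Fibonacci sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    px[k] = std::cos(ga * k) * rk;
    py[k] = std::sin(ga * k) * rk;
    pz[k] = zk;
  }
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;
  for (int i = 0; i < n; ++i) {
    // neighbor list
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = R[i] + R[j];
      if (d2 < rr * rr) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xyz(i, 0) + R[i] * px[k];
      double qy = xyz(i, 1) + R[i] * py[k];
      double qz = xyz(i, 2) + R[i] * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1), dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return area;
}

// ------------------------------------------------------- chain building ----

static inline arma::vec3 nerf(const arma::vec3& a, const arma::vec3& b,
                              const arma::vec3& c, double bond, double angle,
                              double torsion) {
  // standard IUPAC dihedral sign convention
  double th = angle * DEG, chi = torsion * DEG;
  arma::vec3 d2 = {-std::cos(th), std::sin(th) * std::cos(chi),
                   -std::sin(th) * std::sin(chi)};
  d2 *= bond;
  arma::vec3 bc = arma::normalise(c - b);
  arma::vec3 ab = b - a;
  arma::vec3 nrm = arma::normalise(arma::cross(ab, bc));
  arma::vec3 m2 = arma::cross(nrm, bc);
  arma::mat33 M;
  M.col(0) = bc; M.col(1) = m2; M.col(2) = nrm;
  return c + M * d2;
}

struct Chain {
  arma::mat N, CA, C, O;
};

static Chain build_chain(const arma::vec& phi, const arma::vec& psi) {
  const int n = phi.n_elem;
  Chain ch;
  ch.N.set_size(n, 3); ch.CA.set_size(n, 3); ch.C.set_size(n, 3);
  ch.O.set_size(n, 3);
  arma::vec3 N0 = {0, 0, 0};
  arma::vec3 CA0 = {B_N_CA, 0, 0};
  double th = A_N_CA_C * DEG;
  arma::vec3 C0 = CA0 + B_CA_C * arma::vec3({-std::cos(th), std::sin(th), 0.0});
  ch.N.row(0) = N0.t(); ch.CA.row(0) = CA0.t(); ch.C.row(0) = C0.t();
  for (int i = 1; i < n; ++i) {
    arma::vec3 pN = ch.N.row(i - 1).t(), pCA = ch.CA.row(i - 1).t(),
               pC = ch.C.row(i - 1).t();
    arma::vec3 Ni = nerf(pN, pCA, pC, B_C_N, A_CA_C_N, psi[i - 1]);
    arma::vec3 CAi = nerf(pCA, pC, Ni, B_N_CA, A_C_N_CA, T_OMEGA);
    arma::vec3 Ci = nerf(pC, Ni, CAi, B_CA_C, A_N_CA_C, phi[i]);
    ch.N.row(i) = Ni.t(); ch.CA.row(i) = CAi.t(); ch.C.row(i) = Ci.t();
  }
  for (int i = 0; i < n; ++i) {
    arma::vec3 Oi = nerf(ch.N.row(i).t(), ch.CA.row(i).t(), ch.C.row(i).t(),
                         B_C_O, A_CA_C_O, psi[i] + 180.0);
    ch.O.row(i) = Oi.t();
  }
  return ch;
}

// [[Rcpp::export]]
List cpp_build_chain(NumericVector phi, NumericVector psi) {
  Chain ch = build_chain(as<arma::vec>(phi), as<arma::vec>(psi));
  return List::create(_["n"] = wrap(ch.N), _["ca"] = wrap(ch.CA),
                      _["c"] = wrap(ch.C), _["o"] = wrap(ch.O));
}

// CB from ideal geometry; must match R place_cb (bond 1.522, angle 110.4,
// torsion -122.6 with reference atoms C, N, CA)
static arma::mat place_cb_mat(const Chain& ch) {
  const int n = ch.CA.n_rows;
  arma::mat CB(n, 3);
  for (int i = 0; i < n; ++i)
    CB.row(i) = nerf(ch.C.row(i).t(), ch.N.row(i).t(), ch.CA.row(i).t(),
                     1.522, 110.4, -122.6).t();
  return CB;
}

// mean Ca distance after optimal (Kabsch) superposition of x onto y
static double mean_dev_superposed(const arma::mat& x, const arma::mat& y,
                                  double clamp) {
  arma::rowvec cx = arma::mean(x, 0), cy = arma::mean(y, 0);
  arma::mat xc = x.each_row() - cx, yc = y.each_row() - cy;
  arma::mat U, V; arma::vec sv;
  arma::svd(U, sv, V, xc.t() * yc);
  double d = arma::det(U * V.t());
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  arma::mat Rm = V * D * U.t();
  arma::mat xt = xc * Rm.t();
  arma::vec dist = arma::sqrt(arma::sum(arma::square(xt - yc), 1));
  if (clamp > 0) dist = arma::clamp(dist, 0.0, clamp);
  return arma::mean(dist);
}

// distogram bin edges: 63 edges uniform 2.3125..21.6875, 64 bins, open tails
static inline double bin_edge(int k) {  // k = 0..62
  return 2.3125 + k * (21.6875 - 2.3125) / 62.0;
}

static inline double norm_cdf(double z) {
  return 0.5 * std::erfc(-z / std::sqrt(2.0));
}

// -log p(true bin) for a smoothed (discretized Gaussian) toy distogram
static inline double nll_bin(double d_pred, int bin, double sigma) {
  double lo = (bin <= 1) ? -1e30 : bin_edge(bin - 2);
  double hi = (bin >= 64) ? 1e30 : bin_edge(bin - 1);
  double p = norm_cdf((hi - d_pred) / sigma) - norm_cdf((lo - d_pred) / sigma);
  if (p < 1e-12) p = 1e-12;
  return -std::log(p);
}

// composite toy loss for one ensemble member, from class propensities S (Nx3)
static arma::vec4 toy_loss_core(const arma::mat& S, const arma::mat& PHI,
                                const arma::mat& PSI, const arma::mat& target_ca,
                                const arma::imat& true_bin,
                                const arma::uvec& use_ca, double beta,
                                double beta_blend, double sigma, double clamp) {
  const int n = S.n_rows;
  // blend weights: row-wise softmax(beta * s) — a dominant class reproduces
  // its ideal torsions, and confidence (below) equals blend purity
  arma::mat B(n, 3);
  for (int i = 0; i < n; ++i) {
    double m = S.row(i).max(), z = 0.0;
    for (int c = 0; c < 3; ++c) { B(i, c) = std::exp(beta_blend * (S(i, c) - m)); z += B(i, c); }
    B.row(i) /= z;
  }
  arma::vec phi = arma::sum(B % PHI, 1), psi = arma::sum(B % PSI, 1);
  Chain ch = build_chain(phi, psi);
  double l_fape = mean_dev_superposed(ch.CA, target_ca, clamp);
  arma::mat CB = place_cb_mat(ch);
  arma::mat P(n, 3);
  for (int i = 0; i < n; ++i)
    P.row(i) = use_ca[i] ? ch.CA.row(i) : CB.row(i);
  double l_dist = 0.0; int npair = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int b = true_bin(i, j);
      if (b <= 0) continue;
      double d = arma::norm(P.row(i) - P.row(j));
      l_dist += nll_bin(d, b, sigma);
      ++npair;
    }
  if (npair > 0) l_dist /= npair;
  // plddt_i = max softmax(beta * s_i)
  double mean_plddt = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = S.row(i).max(), z = 0.0;
    for (int c = 0; c < 3; ++c) z += std::exp(beta * (S(i, c) - m));
    mean_plddt += 1.0 / z;
  }
  mean_plddt /= n;
  arma::vec4 out;
  out[0] = l_fape; out[1] = l_dist;
  out[2] = 1.0 - mean_plddt; out[3] = 1.0 - mean_plddt;  // toy pTM = mean pLDDT
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_toy_loss(NumericMatrix S, NumericMatrix PHI, NumericMatrix PSI,
                           NumericMatrix target_ca, IntegerMatrix true_bin,
                           LogicalVector use_ca, NumericVector weights,
                           double beta, double beta_blend, double sigma,
                           double clamp) {
  arma::uvec uca(use_ca.size());
  for (int i = 0; i < use_ca.size(); ++i) uca[i] = use_ca[i] ? 1 : 0;
  arma::vec4 comp = toy_loss_core(as<arma::mat>(S), as<arma::mat>(PHI),
                                  as<arma::mat>(PSI), as<arma::mat>(target_ca),
                                  as<arma::imat>(true_bin), uca, beta,
                                  beta_blend, sigma, clamp);
  double total = 0.0;
  for (int k = 0; k < 4; ++k) total += weights[k] * comp[k];
  return NumericVector::create(comp[0], comp[1], comp[2], comp[3], total);
}

// gradient of the weighted composite loss w.r.t. the PSSM logits for one
// ensemble member: central finite differences on the per-position class
// propensities (the only channel through which the loss sees the logits),
// chained exactly through the propensity table and the softmax
// [[Rcpp::export]]
NumericMatrix cpp_member_grad(NumericMatrix Q, NumericMatrix Pm,
                              NumericMatrix PHI, NumericMatrix PSI,
                              NumericMatrix target_ca, IntegerMatrix true_bin,
                              LogicalVector use_ca, NumericVector weights,
                              double beta, double beta_blend, double sigma,
                              double clamp, double h) {
  arma::mat q = as<arma::mat>(Q);          // N x 20 softmax probabilities
  arma::mat pm = as<arma::mat>(Pm);        // 20 x 3
  arma::mat S = q * pm;                    // N x 3 propensities
  arma::mat phiM = as<arma::mat>(PHI), psiM = as<arma::mat>(PSI);
  arma::mat tca = as<arma::mat>(target_ca);
  arma::imat tb = as<arma::imat>(true_bin);
  arma::uvec uca(use_ca.size());
  for (int i = 0; i < use_ca.size(); ++i) uca[i] = use_ca[i] ? 1 : 0;
  arma::vec w = as<arma::vec>(weights);
  const int n = S.n_rows;
  arma::mat gS(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      double keep = S(i, c);
      S(i, c) = keep + h;
      arma::vec4 lp = toy_loss_core(S, phiM, psiM, tca, tb, uca, beta,
                                    beta_blend, sigma, clamp);
      S(i, c) = keep - h;
      arma::vec4 lm = toy_loss_core(S, phiM, psiM, tca, tb, uca, beta,
                                    beta_blend, sigma, clamp);
      S(i, c) = keep;
      gS(i, c) = (arma::dot(w, lp) - arma::dot(w, lm)) / (2.0 * h);
    }
  }
  // chain rule: dL/dq = gS * Pm', then through row-wise softmax
  arma::mat gq = gS * pm.t();              // N x 20
  arma::mat glog(n, 20);
  for (int i = 0; i < n; ++i) {
    double dot = arma::dot(q.row(i), gq.row(i));
    glog.row(i) = q.row(i) % (gq.row(i) - dot);
  }
  return wrap(glog);
}
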