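#include <Rcpp.h>
using namespace Rcpp;

// Per-tree data of the time-lagged heteroscedastic Laplace likelihood,
// parsed once into plain C++ storage (see sapflow_build_data_cpp).
struct TreeData {
  std::vector<double> D, I, ca, Jfull;
  std::vector<int> at;          // 1-based positions of valid rows in the full grid
  int nfull;
  double dt;
  bool young;
  int grp;                      // driver-sharing group (trees with identical
                                // drivers and age group reuse one E vector)
  int i_lambda, i_iota, i_gamma, i_rho, i_chi, i_a, i_b, i_c;  // theta indices
};

struct ModelData {
  std::vector<TreeData> trees;
  int n_groups;
  bool printed;                 // reversed interpolation-weight convention
};

// [[Rcpp::export]]
SEXP sapflow_build_data_cpp(List trees, int n_groups, bool printed) {
  XPtr<ModelData> md(new ModelData, true);
  md->n_groups = n_groups;
  md->printed = printed;
  for (int k = 0; k < trees.size(); ++k) {
    List tr = trees[k];
    TreeData td;
    td.D = as< std::vector<double> >(tr["D"]);
    td.I = as< std::vector<double> >(tr["I"]);
    td.ca = as< std::vector<double> >(tr["ca"]);
    td.Jfull = as< std::vector<double> >(tr["Jfull"]);
    td.at = as< std::vector<int> >(tr["at"]);
    td.nfull = as<int>(tr["nfull"]);
    td.dt = as<double>(tr["dt"]);
    td.young = as<bool>(tr["young"]);
    td.grp = as<int>(tr["grp"]);
    td.i_lambda = as<int>(tr["i_lambda"]);
    td.i_iota = as<int>(tr["i_iota"]);
    td.i_gamma = as<int>(tr["i_gamma"]);
    td.i_rho = as<int>(tr["i_rho"]);
    td.i_chi = as<int>(tr["i_chi"]);
    td.i_a = as<int>(tr["i_a"]);
    td.i_b = as<int>(tr["i_b"]);
    td.i_c = as<int>(tr["i_c"]);
    md->trees.push_back(td);
  }
  return md;
}

// Log-likelihood at `theta` for the model data behind `ptr`. The
// observation matched to model row t is the observed series linearly
// interpolated at t + chi; rows whose lag lookup leaves the grid are
// skipped. Young trees use the saturating heteroscedastic Laplace scale
// c + a b J / (a J + b), old trees the constant scale c.
// [[Rcpp::export]]
double sapflow_loglik_ptr_cpp(NumericVector theta, SEXP ptr) {
  XPtr<ModelData> md(ptr);
  std::vector< std::vector<double> > ecache(md->n_groups);
  double ll = 0.0;
  for (size_t k = 0; k < md->trees.size(); ++k) {
    const TreeData& tr = md->trees[k];
    int n = tr.D.size();
    std::vector<double>& E = ecache[tr.grp];
    if (E.empty()) {
      double la = theta[tr.i_lambda];
      double io = theta[tr.i_iota];
      double ga = theta[tr.i_gamma];
      E.resize(n);
      for (int i = 0; i < n; ++i) {
        double u = std::sqrt(tr.ca[i] / (1.6 * la * tr.D[i])) - 1.0;
        if (u < 0.0) u = 0.0;
        double light = io * ga * tr.I[i] / (io * tr.I[i] + ga);
        E[i] = 1.6 * u * light * tr.D[i];
      }
    }
    double rho = theta[tr.i_rho];
    double chi = theta[tr.i_chi];
    double aa = tr.young ? theta[tr.i_a] : 0.0;
    double bb = tr.young ? theta[tr.i_b] : 0.0;
    double cs = theta[tr.i_c];
    int k0 = (int)std::floor(chi / tr.dt + 1e-12);
    double f = chi / tr.dt - k0;
    bool exact = f < 1e-12;
    double w0 = exact ? 1.0 : (md->printed ? f : 1.0 - f);
    for (int i = 0; i < n; ++i) {
      int j0 = tr.at[i] + k0;  // 1-based
      double lag;
      if (exact) {
        if (j0 > tr.nfull) continue;
        lag = tr.Jfull[j0 - 1];
      } else {
        if (j0 + 1 > tr.nfull) continue;
        lag = w0 * tr.Jfull[j0 - 1] + (1.0 - w0) * tr.Jfull[j0];
      }
      double Jm = rho * E[i];
      double eps = lag - Jm;
      if (!std::isfinite(eps)) return R_NegInf;
      double s = tr.young ? cs + aa * bb * Jm / (aa * Jm + bb) : cs;
      ll += -std::log(2.0 * s) - std::fabs(eps) / s;
    }
  }
  return ll;
}
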