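#include <Rcpp.h>
using namespace Rcpp;

// Structure factor on a set of q vectors.
//
// Q      : n_vox x 3 Cartesian scattering vectors (A^-1, q = 2*pi*s)
// xyz    : n_atom x 3 Cartesian coordinates (A)
// felem  : n_vox x n_elem form factors evaluated per voxel per element
// elem   : 0-based element index per atom into the columns of felem
// occ    : occupancy per atom
//
// F(q) = sum_a occ_a f_a(|q|) exp(i q . r_a)
// [[Rcpp::export]]
ComplexVector cpp_sf_grid(NumericMatrix Q, NumericMatrix xyz,
                          NumericMatrix felem, IntegerVector elem,
                          NumericVector occ) {
  const int nv = Q.nrow(), na = xyz.nrow();
  ComplexVector out(nv);
  for (int v = 0; v < nv; ++v) {
    const double qx = Q(v, 0), qy = Q(v, 1), qz = Q(v, 2);
    double re = 0.0, im = 0.0;
    for (int a = 0; a < na; ++a) {
      const double ph = qx * xyz(a, 0) + qy * xyz(a, 1) + qz * xyz(a, 2);
      const double f = occ[a] * felem(v, elem[a]);
      re += f * std::cos(ph);
      im += f * std::sin(ph);
    }
    out[v].r = re;
    out[v].i = im;
  }
  return out;
}

// Accumulate first and second moments of structure factors over an
// explicit ensemble of perturbed coordinate sets.
//
// coords : n_atom x 3 x n_samp array of Cartesian coordinates
//
// Returns sum_k F_k(q) (complex) and sum_k |F_k(q)|^2 so the caller can
// form the ensemble variance <|F|^2> - |<F>|^2.
// [[Rcpp::export]]
List cpp_sf_ensemble(NumericMatrix Q, NumericVector coords,
                     NumericMatrix felem, IntegerVector elem,
                     NumericVector occ) {
  IntegerVector dims = coords.attr("dim");
  if (dims.size() != 3 || dims[1] != 3)
    stop("coords must be an n_atom x 3 x n_samp array");
  const int na = dims[0], ns = dims[2];
  const int nv = Q.nrow();
  const double *cd = coords.begin();

  NumericVector sre(nv), sim(nv), sI(nv);
  std::vector<double> ax(na), ay(na), az(na), fa(na);

  for (int s = 0; s < ns; ++s) {
    const double *base = cd + (size_t)s * 3 * na;
    for (int a = 0; a < na; ++a) {
      ax[a] = base[a];
      ay[a] = base[a + na];
      az[a] = base[a + 2 * na];
    }
    for (int v = 0; v < nv; ++v) {
      const double qx = Q(v, 0), qy = Q(v, 1), qz = Q(v, 2);
      double re = 0.0, im = 0.0;
      for (int a = 0; a < na; ++a) {
        const double ph = qx * ax[a] + qy * ay[a] + qz * az[a];
        const double f = occ[a] * felem(v, elem[a]);
        re += f * std::cos(ph);
        im += f * std::sin(ph);
      }
      sre[v] += re;
      sim[v] += im;
      sI[v] += re * re + im * im;
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sum_re"] = sre, _["sum_im"] = sim,
                      _["sum_I"] = sI, _["n"] = ns);
}

// Pairwise sum for the general Gaussian-covariance diffuse model with
// isotropic per-pair covariance blocks v_ij * I3.
//
// I_D(q) = sum_ij f_i f_j exp(-q^2 (v_ii + v_jj)/2) (exp(q^2 v_ij) - 1)
//          cos(q . (r_i - r_j))
//
// vmat   : n_atom x n_atom per-axis covariances (A^2)
// linear : replace exp(x) - 1 by x (one-phonon linearization)
// [[Rcpp::export]]
NumericVector cpp_gaussian_diffuse(NumericMatrix Q, NumericVector q2,
                                   NumericMatrix xyz, NumericMatrix felem,
                                   IntegerVector elem, NumericVector occ,
                                   NumericMatrix vmat, bool linear) {
  const int nv = Q.nrow(), na = xyz.nrow();
  NumericVector out(nv);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < na; ++j) {
      const double vij = vmat(i, j);
      if (vij == 0.0 && i != j) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double vii = vmat(i, i), vjj = vmat(j, j);
      for (int v = 0; v < nv; ++v) {
        const double x = q2[v] * vij;
        const double corr = linear ? x : std::expm1(x);
        if (corr == 0.0) continue;
        const double damp = std::exp(-0.5 * q2[v] * (vii + vjj));
        const double ph = Q(v, 0) * dx + Q(v, 1) * dy + Q(v, 2) * dz;
        out[v] += occ[i] * felem(v, elem[i]) * occ[j] * felem(v, elem[j]) *
                  damp * corr * std::cos(ph);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Ensemble moments on a full cubic index lattice.  Every grid q vector is
// the linear image q = M (i,j,k) of integer indices i,j,k in [-m, m]
// (index i fastest), so per-sample phases factor into per-axis complex
// exponentials: exp(i q.r) = e1^i * e2^j * e3^k with u = M^T r.
// [[Rcpp::export]]
List cpp_sf_ensemble_lattice(int m, NumericMatrix M, NumericVector coords,
                             NumericMatrix felem, IntegerVector elem,
                             NumericVector occ) {
  IntegerVector dims = coords.attr("dim");
  if (dims.size() != 3 || dims[1] != 3)
    stop("coords must be an n_atom x 3 x n_samp array");
  const int na = dims[0], ns = dims[2];
  const int n = 2 * m + 1;
  const size_t nv = (size_t)n * n * n;
  if ((size_t)felem.nrow() != nv) stop("felem rows must match the lattice");
  const double *cd = coords.begin();

  NumericVector sre(nv), sim(nv), sI(nv);
  std::vector<std::complex<double>> e1(n), e2(n), e3(n), row(nv);

  for (int s = 0; s < ns; ++s) {
    const double *base = cd + (size_t)s * 3 * na;
    std::fill(row.begin(), row.end(), std::complex<double>(0.0, 0.0));
    for (int a = 0; a < na; ++a) {
      const double rx = base[a], ry = base[a + na], rz = base[a + 2 * na];
      const double u1 = M(0, 0) * rx + M(1, 0) * ry + M(2, 0) * rz;
      const double u2 = M(0, 1) * rx + M(1, 1) * ry + M(2, 1) * rz;
      const double u3 = M(0, 2) * rx + M(1, 2) * ry + M(2, 2) * rz;
      for (int t = 0; t < n; ++t) {
        const double tt = t - m;
        e1[t] = std::complex<double>(std::cos(tt * u1), std::sin(tt * u1));
        e2[t] = std::complex<double>(std::cos(tt * u2), std::sin(tt * u2));
        e3[t] = std::complex<double>(std::cos(tt * u3), std::sin(tt * u3));
      }
      const double oa = occ[a];
      const int ea = elem[a];
      size_t v = 0;
      for (int k = 0; k < n; ++k) {
        for (int j = 0; j < n; ++j) {
          const std::complex<double> pjk = e2[j] * e3[k];
          for (int i = 0; i < n; ++i, ++v) {
            row[v] += oa * felem(v, ea) * (e1[i] * pjk);
          }
        }
      }
    }
    for (size_t v = 0; v < nv; ++v) {
      sre[v] += row[v].real();
      sim[v] += row[v].imag();
      sI[v] += std::norm(row[v]);
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sum_re"] = sre, _["sum_im"] = sim,
                      _["sum_I"] = sI, _["n"] = ns);
}
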