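#include <Rcpp.h>
using namespace Rcpp;

// Structured-grid kernels for the Darcy-Starling flow solve and the implicit
// diffusion step of the drug transport equations.  The linear systems are
// symmetric positive definite 7-point stencils:
//
//   (A x)[c] = d[c] x[c] - sum_faces g_f x[neighbour]
//
// where d already contains the face conductances, mass/reaction terms and
// Dirichlet boundary contributions (assembled in R), and gx/gy/gz hold the
// conductance of interior faces.  gx has dims (nx+1, ny, nz) with zero padding
// at i = 0 and i = nx; gx[i, j, k] couples cells (i-1, j, k) and (i, j, k)
// (1-based R cell indices i and i+1).

static inline int idx3(int i, int j, int k, int nx, int ny) {
    return i + nx * (j + ny * k);
}

static void stencil_apply(const IntegerVector& dims,
                          const NumericVector& gx, const NumericVector& gy,
                          const NumericVector& gz, const NumericVector& d,
                          const double* x, double* y) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const int c = idx3(i, j, k, nx, ny);
                double acc = d[c] * x[c];
                // x faces: gx index (i, j, k) couples (i-1) and i
                const double gxm = gx[i + (nx + 1) * (j + ny * k)];
                const double gxp = gx[(i + 1) + (nx + 1) * (j + ny * k)];
                if (gxm != 0.0) acc -= gxm * x[c - 1];
                if (gxp != 0.0) acc -= gxp * x[c + 1];
                const double gym = gy[i + nx * (j + (ny + 1) * k)];
                const double gyp = gy[i + nx * ((j + 1) + (ny + 1) * k)];
                if (gym != 0.0) acc -= gym * x[c - nx];
                if (gyp != 0.0) acc -= gyp * x[c + nx];
                const double gzm = gz[i + nx * (j + ny * k)];
                const double gzp = gz[i + nx * (j + ny * (k + 1))];
                if (gzm != 0.0) acc -= gzm * x[c - nx * ny];
                if (gzp != 0.0) acc -= gzp * x[c + nx * ny];
                y[c] = acc;
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector stencil_matvec_cpp(IntegerVector dims, NumericVector gx,
                                 NumericVector gy, NumericVector gz,
                                 NumericVector d, NumericVector x) {
    NumericVector y(x.size());
    stencil_apply(dims, gx, gy, gz, d, REAL(x), REAL(y));
    return y;
}

// Jacobi-preconditioned conjugate gradients for the stencil system above.
// tol is relative to ||b||; returns x, iteration count and achieved residual.
// [[Rcpp::export]]
List cg_stencil_cpp(IntegerVector dims, NumericVector gx, NumericVector gy,
                    NumericVector gz, NumericVector d, NumericVector b,
                    NumericVector x0, double tol, int maxit) {
    const int n = b.size();
    NumericVector x = clone(x0);
    std::vector<double> r(n), z(n), p(n), Ap(n);

    stencil_apply(dims, gx, gy, gz, d, REAL(x), Ap.data());
    double bnorm = 0.0;
    for (int c = 0; c < n; ++c) {
        r[c] = b[c] - Ap[c];
        bnorm += b[c] * b[c];
    }
    bnorm = std::sqrt(bnorm);
    if (bnorm == 0.0) {
        std::fill(REAL(x), REAL(x) + n, 0.0);
        return List::create(_["x"] = x, _["iter"] = 0, _["relres"] = 0.0);
    }

    double rz = 0.0;
    for (int c = 0; c < n; ++c) {
        z[c] = r[c] / d[c];
        p[c] = z[c];
        rz += r[c] * z[c];
    }

    double relres = 0.0;
    int it = 0;
    for (; it < maxit; ++it) {
        double rnorm = 0.0;
        for (int c = 0; c < n; ++c) rnorm += r[c] * r[c];
        relres = std::sqrt(rnorm) / bnorm;
        if (relres <= tol) break;

        stencil_apply(dims, gx, gy, gz, d, p.data(), Ap.data());
        double pAp = 0.0;
        for (int c = 0; c < n; ++c) pAp += p[c] * Ap[c];
        if (pAp <= 0.0) stop("cg_stencil: matrix not positive definite");
        const double alpha = rz / pAp;
        for (int c = 0; c < n; ++c) {
            x[c] += alpha * p[c];
            r[c] -= alpha * Ap[c];
        }
        double rz_new = 0.0;
        for (int c = 0; c < n; ++c) {
            z[c] = r[c] / d[c];
            rz_new += r[c] * z[c];
        }
        const double beta = rz_new / rz;
        rz = rz_new;
        for (int c = 0; c < n; ++c) p[c] = z[c] + beta * p[c];
    }
    return List::create(_["x"] = x, _["iter"] = it, _["relres"] = relres);
}

// Conservative first-order upwind divergence of (u v) on face volumetric
// fluxes.  qx/qy/qz are oriented (+axis) volume flow rates per face (m^3/s),
// including outer-boundary faces; dims of qx are (nx+1, ny, nz).  Inflow
// through the outer boundary carries zero concentration.  Returns the net
// outflux rate per cell (amount/s, positive = net loss) and the total amount
// leaving through the outer boundary per second.
// [[Rcpp::export]]
List upwind_div_cpp(IntegerVector dims, NumericVector u, NumericVector qx,
                    NumericVector qy, NumericVector qz) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericVector out(u.size());
    double bnd = 0.0;

    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i <= nx; ++i) {
                const double q = qx[i + (nx + 1) * (j + ny * k)];
                if (q == 0.0) continue;
                const int cl = (i > 0)  ? idx3(i - 1, j, k, nx, ny) : -1;
                const int cr = (i < nx) ? idx3(i, j, k, nx, ny) : -1;
                const double uu = (q > 0.0) ? (cl >= 0 ? u[cl] : 0.0)
                                            : (cr >= 0 ? u[cr] : 0.0);
                const double f = q * uu;
                if (cl >= 0) out[cl] += f; else bnd -= f;
                if (cr >= 0) out[cr] -= f; else bnd += f;
            }
        }
    }
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j <= ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const double q = qy[i + nx * (j + (ny + 1) * k)];
                if (q == 0.0) continue;
                const int cl = (j > 0)  ? idx3(i, j - 1, k, nx, ny) : -1;
                const int cr = (j < ny) ? idx3(i, j, k, nx, ny) : -1;
                const double uu = (q > 0.0) ? (cl >= 0 ? u[cl] : 0.0)
                                            : (cr >= 0 ? u[cr] : 0.0);
                const double f = q * uu;
                if (cl >= 0) out[cl] += f; else bnd -= f;
                if (cr >= 0) out[cr] -= f; else bnd += f;
            }
        }
    }
    for (int k = 0; k <= nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                const double q = qz[i + nx * (j + ny * k)];
                if (q == 0.0) continue;
                const int cl = (k > 0)  ? idx3(i, j, k - 1, nx, ny) : -1;
                const int cr = (k < nz) ? idx3(i, j, k, nx, ny) : -1;
                const double uu = (q > 0.0) ? (cl >= 0 ? u[cl] : 0.0)
                                            : (cr >= 0 ? u[cr] : 0.0);
                const double f = q * uu;
                if (cl >= 0) out[cl] += f; else bnd -= f;
                if (cr >= 0) out[cr] -= f; else bnd += f;
            }
        }
    }
    return List::create(_["out"] = out, _["boundary_out"] = bnd);
}
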