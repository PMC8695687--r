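#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Catmull-Rom (Keys, a = -0.5) cubic convolution weight
static inline double cubic_w(double x) {
    x = std::fabs(x);
    if (x < 1.0) return ((1.5 * x - 2.5) * x) * x + 1.0;
    if (x < 2.0) return (((-0.5 * x + 2.5) * x) - 4.0) * x + 2.0;
    return 0.0;
}

static inline double get_vox(const NumericVector &d, int nx, int ny, int nz,
                             int i, int j, int k, double fill) {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
    return d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
}

// Sample a 3-D volume at continuous 0-based voxel coordinates.
// method: 0 = nearest, 1 = trilinear, 3 = tricubic (Catmull-Rom).
// [[Rcpp::export(name = ".sample_volume_cpp")]]
NumericVector sample_volume_cpp(NumericVector data, IntegerVector dims,
                                NumericMatrix pts, int method, double fill) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = pts.nrow();
    NumericVector out(n);
    for (R_xlen_t p = 0; p < n; ++p) {
        double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
        if (!R_finite(x) || !R_finite(y) || !R_finite(z)) { out[p] = NA_REAL; continue; }
        if (method == 0) {
            int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
            out[p] = get_vox(data, nx, ny, nz, i, j, k, fill);
        } else if (method == 1) {
            int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
            double fx = x - i0, fy = y - j0, fz = z - k0;
            double acc = 0.0;
            for (int dk = 0; dk <= 1; ++dk)
                for (int dj = 0; dj <= 1; ++dj)
                    for (int di = 0; di <= 1; ++di) {
                        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
                        if (w != 0.0)
                            acc += w * get_vox(data, nx, ny, nz, i0 + di, j0 + dj, k0 + dk, fill);
                    }
            out[p] = acc;
        } else {
            int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
            double acc = 0.0;
            double wx[4], wy[4], wz[4];
            for (int t = 0; t < 4; ++t) {
                wx[t] = cubic_w(x - (i0 - 1 + t));
                wy[t] = cubic_w(y - (j0 - 1 + t));
                wz[t] = cubic_w(z - (k0 - 1 + t));
            }
            for (int dk = 0; dk < 4; ++dk) {
                if (wz[dk] == 0.0) continue;
                for (int dj = 0; dj < 4; ++dj) {
                    if (wy[dj] == 0.0) continue;
                    double wzy = wz[dk] * wy[dj];
                    for (int di = 0; di < 4; ++di) {
                        if (wx[di] == 0.0) continue;
                        acc += wzy * wx[di] *
                            get_vox(data, nx, ny, nz, i0 - 1 + di, j0 - 1 + dj, k0 - 1 + dk, fill);
                    }
                }
            }
            out[p] = acc;
        }
    }
    return out;
}
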