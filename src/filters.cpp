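#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable uniform (cuboid) mean filter with zero padding outside the grid.
// Widths are forced odd by the R caller.
// [[Rcpp::export(name = ".box_mean_cpp")]]
NumericVector box_mean_cpp(NumericVector data, IntegerVector dims,
                           IntegerVector width) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector cur = clone(data);
    NumericVector nxt(n);

    const int nd[3] = {nx, ny, nz};
    const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};

    for (int ax = 0; ax < 3; ++ax) {
        int w = width[ax];
        if (w <= 1) continue;
        int half = w / 2;
        double inv = 1.0 / w;
        int len = nd[ax];
        R_xlen_t st = stride[ax];
        // iterate over all 1-D lines along axis ax
        int d1 = (ax == 0) ? 1 : 0;
        int d2 = (ax == 2) ? 1 : 2;
        for (int b = 0; b < nd[d2]; ++b) {
            for (int a = 0; a < nd[d1]; ++a) {
                R_xlen_t base = (R_xlen_t)a * stride[d1] + (R_xlen_t)b * stride[d2];
                // sliding window sum with zero padding
                double s = 0.0;
                for (int t = 0; t < half && t < len; ++t) s += cur[base + (R_xlen_t)t * st];
                for (int t = 0; t < len; ++t) {
                    int add = t + half;
                    if (add < len) s += cur[base + (R_xlen_t)add * st];
                    nxt[base + (R_xlen_t)t * st] = s * inv;
                    int rem = t - half;
                    if (rem >= 0) s -= cur[base + (R_xlen_t)rem * st];
                }
            }
        }
        std::swap(cur, nxt);
    }
    return cur;
}
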