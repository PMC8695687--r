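#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a binary 3-D volume.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels start at 1;
// background is 0. Iterative BFS so deep stacks cannot overflow.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n, 0);

    std::vector<int> off;
    for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (connectivity == 6 && manh > 1) continue;
                off.push_back(di); off.push_back(dj); off.push_back(dk);
            }
    const int noff = (int)(off.size() / 3);

    int next_label = 0;
    std::vector<R_xlen_t> queue;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || labels[s] != 0) continue;
        ++next_label;
        labels[s] = next_label;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            R_xlen_t cur = queue.back();
            queue.pop_back();
            int i = (int)(cur % nx);
            int j = (int)((cur / nx) % ny);
            int k = (int)(cur / ((R_xlen_t)nx * ny));
            for (int m = 0; m < noff; ++m) {
                int ii = i + off[3 * m], jj = j + off[3 * m + 1], kk = k + off[3 * m + 2];
                if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
                R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                if (mask[nb] && labels[nb] == 0) {
                    labels[nb] = next_label;
                    queue.push_back(nb);
                }
            }
        }
    }
    labels.attr("n_components") = next_label;
    return labels;
}
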