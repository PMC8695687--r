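#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Density-based clustering (DBSCAN) of 3-D points with a uniform-grid
// neighbour index (cell size = eps). Returns cluster id per point, 0 = noise.
// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(NumericMatrix pts, double eps, int min_pts) {
    const int n = pts.nrow();
    IntegerVector cl(n, 0);
    if (n == 0) return cl;
    const double eps2 = eps * eps;

    auto cell_key = [&](double x, double y, double z) -> uint64_t {
        int64_t i = (int64_t)std::floor(x / eps) + 1000000;
        int64_t j = (int64_t)std::floor(y / eps) + 1000000;
        int64_t k = (int64_t)std::floor(z / eps) + 1000000;
        return (uint64_t)i * 4000037ULL * 4000037ULL + (uint64_t)j * 4000037ULL + (uint64_t)k;
    };
    std::unordered_map<uint64_t, std::vector<int> > grid;
    for (int p = 0; p < n; ++p)
        grid[cell_key(pts(p, 0), pts(p, 1), pts(p, 2))].push_back(p);

    std::vector<int> nbuf;
    auto neighbours = [&](int p, std::vector<int> &out) {
        out.clear();
        double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
        for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
                for (int di = -1; di <= 1; ++di) {
                    auto it = grid.find(cell_key(x + di * eps, y + dj * eps, z + dk * eps));
                    if (it == grid.end()) continue;
                    for (int q : it->second) {
                        double dx = pts(q, 0) - x, dy = pts(q, 1) - y, dz = pts(q, 2) - z;
                        if (dx * dx + dy * dy + dz * dz <= eps2) out.push_back(q);
                    }
                }
    };

    std::vector<char> visited(n, 0);
    int next_cl = 0;
    std::vector<int> seeds;
    for (int p = 0; p < n; ++p) {
        if (visited[p]) continue;
        visited[p] = 1;
        neighbours(p, nbuf);
        if ((int)nbuf.size() < min_pts) continue;  // noise unless claimed later
        ++next_cl;
        cl[p] = next_cl;
        seeds = nbuf;
        for (size_t s = 0; s < seeds.size(); ++s) {
            int q = seeds[s];
            if (cl[q] == 0) cl[q] = next_cl;  // border point
            if (visited[q]) continue;
            visited[q] = 1;
            std::vector<int> nb2;
            neighbours(q, nb2);
            if ((int)nb2.size() >= min_pts)
                seeds.insert(seeds.end(), nb2.begin(), nb2.end());
        }
    }
    cl.attr("n_clusters") = next_cl;
    return cl;
}
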