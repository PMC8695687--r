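#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Isosurface extraction: marching tetrahedra on the Kuhn (6-tet) subdivision
// of each grid cell. The volume is implicitly padded with one layer at
// pad_value so isosurfaces always close at the grid boundary. Vertices are
// returned in 0-based voxel coordinates of the input grid; triangle winding
// is fixed numerically so normals point from the supra-iso side outward.
// ---------------------------------------------------------------------------

struct V3 { double x, y, z; };

static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 sub(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 add(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 scl(V3 a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline V3 crossp(V3 a, V3 b) {
    return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double dotp(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm3(V3 a) { return std::sqrt(dotp(a, a)); }

// Kuhn subdivision: 6 tetrahedra per cube, all sharing the main diagonal
// 0-7 (corner 0 = (0,0,0), corner 7 = (1,1,1), bit order x,y,z).
static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

class MTState {
public:
    const double *data;
    int nx, ny, nz;
    double iso, pad;
    std::unordered_map<uint64_t, int> edge_vertex;
    std::vector<double> verts;   // flat xyz
    std::vector<int> faces;      // flat 0-based triples

    double val(int i, int j, int k) const {
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return pad;
        return data[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
    }
    // node id for grid node possibly in the padded range [-1, n]
    uint64_t node_id(int i, int j, int k) const {
        uint64_t I = (uint64_t)(i + 1), J = (uint64_t)(j + 1), K = (uint64_t)(k + 1);
        return I + (uint64_t)(nx + 2) * (J + (uint64_t)(ny + 2) * K);
    }
    int edge_point(int ai, int aj, int ak, int bi, int bj, int bk) {
        uint64_t a = node_id(ai, aj, ak), b = node_id(bi, bj, bk);
        if (a > b) { std::swap(a, b); std::swap(ai, bi); std::swap(aj, bj); std::swap(ak, bk); }
        uint64_t key = a * 2000000011ULL + b;
        auto it = edge_vertex.find(key);
        if (it != edge_vertex.end()) return it->second;
        double va = val(ai, aj, ak), vb = val(bi, bj, bk);
        double t = (iso - va) / (vb - va);
        if (t < 0) t = 0; if (t > 1) t = 1;
        int id = (int)(verts.size() / 3);
        verts.push_back(ai + t * (bi - ai));
        verts.push_back(aj + t * (bj - aj));
        verts.push_back(ak + t * (bk - ak));
        edge_vertex[key] = id;
        return id;
    }
    V3 vpos(int id) const { return v3(verts[3 * id], verts[3 * id + 1], verts[3 * id + 2]); }

    void emit(int a, int b, int c, V3 inside_pt, V3 outside_pt) {
        V3 n = crossp(sub(vpos(b), vpos(a)), sub(vpos(c), vpos(a)));
        V3 outdir = sub(outside_pt, inside_pt);
        if (dotp(n, outdir) < 0) std::swap(b, c);
        faces.push_back(a); faces.push_back(b); faces.push_back(c);
    }

    void do_tet(const int ci[4][3]) {
        double v[4];
        bool in[4];
        int nin = 0;
        for (int t = 0; t < 4; ++t) {
            v[t] = val(ci[t][0], ci[t][1], ci[t][2]);
            in[t] = v[t] > iso;
            if (in[t]) ++nin;
        }
        if (nin == 0 || nin == 4) return;
        V3 cin = v3(0, 0, 0), cout = v3(0, 0, 0);
        for (int t = 0; t < 4; ++t) {
            V3 p = v3(ci[t][0], ci[t][1], ci[t][2]);
            if (in[t]) cin = add(cin, scl(p, 1.0 / nin));
            else cout = add(cout, scl(p, 1.0 / (4 - nin)));
        }
        int idx[4], m = 0;
        if (nin == 1 || nin == 3) {
            bool flag = (nin == 1);
            int lone = -1;
            for (int t = 0; t < 4; ++t) if (in[t] == flag) lone = t;
            int others[3];
            for (int t = 0, q = 0; t < 4; ++t) if (t != lone) others[q++] = t;
            for (int q = 0; q < 3; ++q)
                idx[q] = edge_point(ci[lone][0], ci[lone][1], ci[lone][2],
                                    ci[others[q]][0], ci[others[q]][1], ci[others[q]][2]);
            emit(idx[0], idx[1], idx[2], cin, cout);
        } else { // 2 in, 2 out -> quad
            int ins[2], outs[2];
            int qi = 0, qo = 0;
            for (int t = 0; t < 4; ++t) { if (in[t]) ins[qi++] = t; else outs[qo++] = t; }
            // quad cycle: (i0,o0), (i0,o1), (i1,o1), (i1,o0)
            int e00 = edge_point(ci[ins[0]][0], ci[ins[0]][1], ci[ins[0]][2],
                                 ci[outs[0]][0], ci[outs[0]][1], ci[outs[0]][2]);
            int e01 = edge_point(ci[ins[0]][0], ci[ins[0]][1], ci[ins[0]][2],
                                 ci[outs[1]][0], ci[outs[1]][1], ci[outs[1]][2]);
            int e11 = edge_point(ci[ins[1]][0], ci[ins[1]][1], ci[ins[1]][2],
                                 ci[outs[1]][0], ci[outs[1]][1], ci[outs[1]][2]);
            int e10 = edge_point(ci[ins[1]][0], ci[ins[1]][1], ci[ins[1]][2],
                                 ci[outs[0]][0], ci[outs[0]][1], ci[outs[0]][2]);
            emit(e00, e01, e11, cin, cout);
            emit(e00, e11, e10, cin, cout);
            (void)m;
        }
    }
};

// [[Rcpp::export(name = ".marching_tets_cpp")]]
List marching_tets_cpp(NumericVector data, IntegerVector dims, double iso,
                       double pad_value) {
    MTState st;
    st.data = REAL(data);
    st.nx = dims[0]; st.ny = dims[1]; st.nz = dims[2];
    st.iso = iso; st.pad = pad_value;

    // cells span padded node range [-1, n-1] on each axis
    for (int k = -1; k < st.nz; ++k)
        for (int j = -1; j < st.ny; ++j)
            for (int i = -1; i < st.nx; ++i) {
                // quick reject: all 8 corners same side
                bool any_in = false, any_out = false;
                for (int c = 0; c < 8; ++c) {
                    double v = st.val(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
                    if (v > iso) any_in = true; else any_out = true;
                }
                if (!any_in || !any_out) continue;
                for (int t = 0; t < 6; ++t) {
                    int ci[4][3];
                    for (int q = 0; q < 4; ++q) {
                        int c = TETS[t][q];
                        ci[q][0] = i + (c & 1);
                        ci[q][1] = j + ((c >> 1) & 1);
                        ci[q][2] = k + ((c >> 2) & 1);
                    }
                    st.do_tet(ci);
                }
            }

    int nv = (int)(st.verts.size() / 3), nf = (int)(st.faces.size() / 3);
    NumericMatrix V(nv, 3);
    IntegerMatrix F(nf, 3);
    for (int v = 0; v < nv; ++v)
        for (int c = 0; c < 3; ++c) V(v, c) = st.verts[3 * v + c];
    for (int f = 0; f < nf; ++f)
        for (int c = 0; c < 3; ++c) F(f, c) = st.faces[3 * f + c];
    return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Closest point on a triangle (Ericson, Real-Time Collision Detection)
// ---------------------------------------------------------------------------
static V3 closest_on_tri(V3 p, V3 a, V3 b, V3 c) {
    V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
    double d1 = dotp(ab, ap), d2 = dotp(ac, ap);
    if (d1 <= 0 && d2 <= 0) return a;
    V3 bp = sub(p, b);
    double d3 = dotp(ab, bp), d4 = dotp(ac, bp);
    if (d3 >= 0 && d4 <= d3) return b;
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) return add(a, scl(ab, d1 / (d1 - d3)));
    V3 cp = sub(p, c);
    double d5 = dotp(ab, cp), d6 = dotp(ac, cp);
    if (d6 >= 0 && d5 <= d6) return c;
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) return add(a, scl(ac, d2 / (d2 - d6)));
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        return add(b, scl(sub(c, b), w));
    }
    double denom = 1.0 / (va + vb + vc);
    return add(a, add(scl(ab, vb * denom), scl(ac, vc * denom)));
}

// Flatten triangle coordinates once so inner loops touch plain arrays.
static void flatten_tris(const NumericMatrix &V, const IntegerMatrix &F,
                         std::vector<double> &T) {
    const int nf = F.nrow();
    T.resize((size_t)nf * 9);
    for (int f = 0; f < nf; ++f)
        for (int c = 0; c < 3; ++c) {
            int vi = F(f, c);
            T[(size_t)f * 9 + c * 3 + 0] = V(vi, 0);
            T[(size_t)f * 9 + c * 3 + 1] = V(vi, 1);
            T[(size_t)f * 9 + c * 3 + 2] = V(vi, 2);
        }
}

// [[Rcpp::export(name = ".mesh_closest_cpp")]]
List mesh_closest_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix pts) {
    const int nf = F.nrow();
    const int np = pts.nrow();
    std::vector<double> T;
    flatten_tris(V, F, T);
    NumericMatrix out(np, 3);
    IntegerVector face(np);
    NumericVector dist(np);
    for (int p = 0; p < np; ++p) {
        V3 q = v3(pts(p, 0), pts(p, 1), pts(p, 2));
        double best = R_PosInf;
        V3 bestpt = v3(NA_REAL, NA_REAL, NA_REAL);
        int bestf = -1;
        for (int f = 0; f < nf; ++f) {
            const double *t = &T[(size_t)f * 9];
            V3 a = v3(t[0], t[1], t[2]);
            V3 b = v3(t[3], t[4], t[5]);
            V3 c = v3(t[6], t[7], t[8]);
            V3 cp = closest_on_tri(q, a, b, c);
            double d = norm3(sub(q, cp));
            if (d < best) { best = d; bestpt = cp; bestf = f; }
        }
        out(p, 0) = bestpt.x; out(p, 1) = bestpt.y; out(p, 2) = bestpt.z;
        face[p] = bestf;  // 0-based; R side adds 1
        dist[p] = best;
    }
    return List::create(_["point"] = out, _["face"] = face, _["distance"] = dist);
}

// ---------------------------------------------------------------------------
// Moller-Trumbore ray-triangle; all positive hits of a ray against the mesh
// ---------------------------------------------------------------------------
static bool ray_tri(V3 o, V3 d, V3 a, V3 b, V3 c, double &t, double &u, double &v) {
    const double EPS = 1e-12;
    V3 e1 = sub(b, a), e2 = sub(c, a);
    V3 pv = crossp(d, e2);
    double det = dotp(e1, pv);
    if (std::fabs(det) < EPS) return false;
    double inv = 1.0 / det;
    V3 tv = sub(o, a);
    u = dotp(tv, pv) * inv;
    if (u < 0 || u > 1) return false;
    V3 qv = crossp(tv, e1);
    v = dotp(d, qv) * inv;
    if (v < 0 || u + v > 1) return false;
    t = dotp(e2, qv) * inv;
    return true;
}

// [[Rcpp::export(name = ".ray_mesh_cpp")]]
List ray_mesh_cpp(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                  NumericVector dir) {
    const int nf = F.nrow();
    V3 o = v3(origin[0], origin[1], origin[2]);
    V3 d = v3(dir[0], dir[1], dir[2]);
    std::vector<double> T;
    flatten_tris(V, F, T);
    std::vector<double> ts;
    std::vector<int> fs;
    double t, u, v;
    for (int f = 0; f < nf; ++f) {
        const double *tf = &T[(size_t)f * 9];
        V3 a = v3(tf[0], tf[1], tf[2]);
        V3 b = v3(tf[3], tf[4], tf[5]);
        V3 c = v3(tf[6], tf[7], tf[8]);
        if (ray_tri(o, d, a, b, c, t, u, v) && t > 1e-9) {
            ts.push_back(t);
            fs.push_back(f);
        }
    }
    // sort by t
    std::vector<size_t> ord(ts.size());
    for (size_t q = 0; q < ord.size(); ++q) ord[q] = q;
    std::sort(ord.begin(), ord.end(), [&](size_t a2, size_t b2) { return ts[a2] < ts[b2]; });
    NumericVector Tout((int)ts.size());
    IntegerVector Fi((int)ts.size());
    for (size_t q = 0; q < ord.size(); ++q) {
        Tout[q] = ts[ord[q]];
        Fi[q] = fs[ord[q]];
    }
    return List::create(_["t"] = Tout, _["face"] = Fi);
}

// Parity-based point-in-mesh for closed meshes; direction jittered on
// ambiguous (near-edge) hits.
// [[Rcpp::export(name = ".points_in_mesh_cpp")]]
LogicalVector points_in_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix pts) {
    const int nf = F.nrow();
    const int np = pts.nrow();
    LogicalVector out(np);
    std::vector<double> T;
    flatten_tris(V, F, T);
    // probe directions with irrational, non-lattice component ratios (mesh
    // vertices lie on grid edges, so lattice-diagonal rays hit edges exactly)
    const double base_dir[5][3] = {
        {0.2408268053590720, 0.5439677128788901, 0.8037550010406725},
        {0.7216842905105668, 0.1123872301025267, 0.6830344462844368},
        {0.1536875505829405, 0.9106836025229592, 0.3835847042375782},
        {0.6263893584718653, 0.7135762836522218, 0.3140089105745218},
        {0.4337102861300150, 0.2981060000932221, 0.8503071752821338}};
    const double EPSB = 1e-7;   // barycentric band treated as ambiguous
    for (int p = 0; p < np; ++p) {
        bool done = false;
        for (int attempt = 0; attempt < 5 && !done; ++attempt) {
            V3 o = v3(pts(p, 0), pts(p, 1), pts(p, 2));
            V3 d = v3(base_dir[attempt][0], base_dir[attempt][1], base_dir[attempt][2]);
            int crossings = 0;
            bool ambiguous = false;
            for (int f = 0; f < nf; ++f) {
                const double *tf = &T[(size_t)f * 9];
                V3 a = v3(tf[0], tf[1], tf[2]);
                V3 b = v3(tf[3], tf[4], tf[5]);
                V3 c = v3(tf[6], tf[7], tf[8]);
                // unclipped barycentric hit test so that near-misses through
                // shared edges are caught as ambiguous, not silently dropped
                V3 e1 = sub(b, a), e2 = sub(c, a);
                V3 pv = crossp(d, e2);
                double det = dotp(e1, pv);
                if (std::fabs(det) < 1e-12) continue;
                double inv = 1.0 / det;
                V3 tv = sub(o, a);
                double u = dotp(tv, pv) * inv;
                if (u < -EPSB || u > 1 + EPSB) continue;
                V3 qv = crossp(tv, e1);
                double v = dotp(d, qv) * inv;
                if (v < -EPSB || u + v > 1 + EPSB) continue;
                double t = dotp(e2, qv) * inv;
                if (t <= 1e-10) continue;
                if (u < EPSB || v < EPSB || u + v > 1 - EPSB) {
                    ambiguous = true;
                    break;
                }
                ++crossings;
            }
            if (!ambiguous) {
                out[p] = (crossings % 2) == 1;
                done = true;
            }
        }
        if (!done) out[p] = NA_LOGICAL;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Voxelization of a closed mesh given in 0-based voxel coordinates of the
// target grid: parity fill along +z columns through voxel centers (with a
// tiny irrational in-plane offset so column rays never hit triangle edges).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".voxelize_mesh_cpp")]]
LogicalVector voxelize_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                                IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int nf = F.nrow();
    const double ox = 2.3e-4, oy = 3.7e-4;  // break edge/vertex ties
    std::vector<std::vector<double> > cols((size_t)nx * ny);
    for (int f = 0; f < nf; ++f) {
        double ax = V(F(f, 0), 0) - ox, ay = V(F(f, 0), 1) - oy, az = V(F(f, 0), 2);
        double bx = V(F(f, 1), 0) - ox, by = V(F(f, 1), 1) - oy, bz = V(F(f, 1), 2);
        double cx = V(F(f, 2), 0) - ox, cy = V(F(f, 2), 1) - oy, cz = V(F(f, 2), 2);
        int i0 = std::max(0, (int)std::ceil(std::min(ax, std::min(bx, cx))));
        int i1 = std::min(nx - 1, (int)std::floor(std::max(ax, std::max(bx, cx))));
        int j0 = std::max(0, (int)std::ceil(std::min(ay, std::min(by, cy))));
        int j1 = std::min(ny - 1, (int)std::floor(std::max(ay, std::max(by, cy))));
        double d = (by - cy) * (ax - cx) + (cx - bx) * (ay - cy);
        if (std::fabs(d) < 1e-14) continue;  // degenerate in-plane projection
        for (int j = j0; j <= j1; ++j)
            for (int i = i0; i <= i1; ++i) {
                double l1 = ((by - cy) * (i - cx) + (cx - bx) * (j - cy)) / d;
                double l2 = ((cy - ay) * (i - cx) + (ax - cx) * (j - cy)) / d;
                double l3 = 1.0 - l1 - l2;
                if (l1 < 0 || l2 < 0 || l3 < 0) continue;
                double z = l1 * az + l2 * bz + l3 * cz;
                cols[(size_t)i + (size_t)nx * j].push_back(z);
            }
    }
    LogicalVector out((R_xlen_t)nx * ny * nz, false);
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            std::vector<double> &zs = cols[(size_t)i + (size_t)nx * j];
            if (zs.empty()) continue;
            std::sort(zs.begin(), zs.end());
            // voxel center k is inside if an odd number of crossings lie below
            size_t q = 0;
            bool inside = false;
            for (int k = 0; k < nz; ++k) {
                while (q < zs.size() && zs[q] < k) { inside = !inside; ++q; }
                if (inside) out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
            }
        }
    return out;
}
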