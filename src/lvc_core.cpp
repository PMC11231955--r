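#include <Rcpp.h>
#include <climits>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel linear indexing is 0-based, x fastest (matches R column-major arrays).
static inline int lin(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

// Max-min fuzzy-connectedness propagation from a single seed over the
// 26-neighbourhood. Path strength is the minimum edge affinity along the
// path; edge affinity is the smaller endpoint objectness
// g(v) = (HU - low)/(high - low) clipped to [0,1]. Best-first expansion
// (Dijkstra with min-composition) reaches the same fixed point as
// iterative relaxation but visits each voxel once.
//
// Returned codes store the neighbour-offset index (0..26, 13 = self) of
// the direction from each voxel toward its predecessor on an optimal
// path. Ties are resolved deterministically: among equal-strength paths
// the predecessor with the highest own connectivity strength wins (the
// strongest-connectivity neighbour), then the fewer-hop path (the
// growing wavefront), then the lowest code; equal-priority queue
// entries pop in linear-index order.
// [[Rcpp::export(name = ".fc_propagate")]]
List fc_propagate(NumericVector hu, IntegerVector dims, int seed0,
                  double low, double high) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (hu.size() != n) stop("volume size does not match dims");
    if (seed0 < 0 || seed0 >= n) stop("seed outside grid");

    const double span = high - low;
    std::vector<double> g(n);
    std::vector<char> active(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const double v = hu[i];
        active[i] = (v > low && v < high);
        double gi = (v - low) / span;
        if (gi < 0) gi = 0; else if (gi > 1) gi = 1;
        g[i] = gi;
    }
    if (!active[seed0]) stop("seed voxel is deactivated (HU outside window)");

    IntegerVector codes(n, 13);
    NumericVector strength(n, 0.0);
    std::vector<int> hops(n, INT_MAX);
    std::vector<double> preds(n, -1.0);   // strength of chosen predecessor
    std::vector<char> done(n, 0);

    struct QE { double s; int h; int idx; };
    struct Cmp {
        bool operator()(const QE& a, const QE& b) const {
            if (a.s != b.s) return a.s < b.s;   // higher strength first
            if (a.h != b.h) return a.h > b.h;   // then fewer hops
            return a.idx > b.idx;               // then lower index
        }
    };
    std::priority_queue<QE, std::vector<QE>, Cmp> pq;

    strength[seed0] = 1.0;
    hops[seed0] = 0;
    pq.push({1.0, 0, seed0});

    while (!pq.empty()) {
        QE top = pq.top(); pq.pop();
        const int u = top.idx;
        if (done[u] || top.s < strength[u] || top.h > hops[u]) continue;
        done[u] = 1;
        const int ux = u % nx, uy = (u / nx) % ny, uz = u / (nx * ny);
        const double su = strength[u];
        for (int dx = -1; dx <= 1; ++dx) {
            const int vx = ux + dx;
            if (vx < 0 || vx >= nx) continue;
            for (int dy = -1; dy <= 1; ++dy) {
                const int vy = uy + dy;
                if (vy < 0 || vy >= ny) continue;
                for (int dz = -1; dz <= 1; ++dz) {
                    if (dx == 0 && dy == 0 && dz == 0) continue;
                    const int vz = uz + dz;
                    if (vz < 0 || vz >= nz) continue;
                    const int v = lin(vx, vy, vz, nx, ny);
                    if (!active[v] || done[v]) continue;
                    const double aff = g[u] < g[v] ? g[u] : g[v];
                    const double cand = su < aff ? su : aff;
                    if (cand <= 0) continue;
                    // code of direction v -> u (predecessor direction)
                    const int code = 9 * (-dx + 1) + 3 * (-dy + 1) + (-dz + 1);
                    const int h = hops[u] + 1;
                    if (cand > strength[v]) {
                        strength[v] = cand;
                        preds[v] = su;
                        hops[v] = h;
                        codes[v] = code;
                        pq.push({cand, h, v});
                    } else if (cand == strength[v]) {
                        if (su > preds[v] ||
                            (su == preds[v] && (h < hops[v] ||
                             (h == hops[v] && code < codes[v])))) {
                            preds[v] = su;
                            codes[v] = code;
                            if (h < hops[v]) {
                                hops[v] = h;
                                pq.push({cand, h, v});
                            }
                        }
                    }
                }
            }
        }
    }
    return List::create(_["codes"] = codes, _["strength"] = strength);
}

// Squared distances for voxels with no feature yet; large finite sentinel
// keeps the parabola-envelope arithmetic free of Inf - Inf.
static const double DT_BIG = 1e30;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// sample spacing s; f holds squared distances on input and is overwritten.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double sp;
        while (true) {
            const double qq = q * s, vv = v[k] * s;
            sp = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
            if (sp <= z[k] && k > 0) { --k; } else break;
        }
        if (sp <= z[k]) {          // k == 0 and new parabola dominates
            v[0] = q;
        } else {
            ++k;
            v[k] = q;
            z[k] = sp;
        }
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        const double qq = q * s;
        while (z[k + 1] < qq) ++k;
        const double dd = qq - v[k] * s;
        d[q] = dd * dd + f[v[k]];
    }
    for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance transform (mm) to the nearest TRUE voxel, with
// anisotropic spacing. Returns +Inf everywhere when no voxel is set.
// [[Rcpp::export(name = ".edt")]]
NumericVector edt(LogicalVector feature, IntegerVector dims,
                  NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    std::vector<double> sq(n);
    for (R_xlen_t i = 0; i < n; ++i) sq[i] = feature[i] ? 0.0 : DT_BIG;

    const int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy) {
            const R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            for (int xx = 0; xx < nx; ++xx) f[xx] = sq[base + xx];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int xx = 0; xx < nx; ++xx) sq[base + xx] = f[xx];
        }
    for (int zz = 0; zz < nz; ++zz)
        for (int xx = 0; xx < nx; ++xx) {
            for (int yy = 0; yy < ny; ++yy) f[yy] = sq[lin(xx, yy, zz, nx, ny)];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int yy = 0; yy < ny; ++yy) sq[lin(xx, yy, zz, nx, ny)] = f[yy];
        }
    for (int yy = 0; yy < ny; ++yy)
        for (int xx = 0; xx < nx; ++xx) {
            for (int zz = 0; zz < nz; ++zz) f[zz] = sq[lin(xx, yy, zz, nx, ny)];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int zz = 0; zz < nz; ++zz) sq[lin(xx, yy, zz, nx, ny)] = f[zz];
        }

    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = sq[i] >= DT_BIG / 2 ? R_PosInf : std::sqrt(sq[i]);
    return out;
}
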