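#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Gray-level texture matrix kernels. All functions take a 3D integer array
// `levels` (dims attribute set) holding discretized gray levels 1..ng inside
// the VOI and 0 outside, so the mask is implicit. Connectivity conventions:
// GLCM uses the 13 unique Chebyshev-distance-1 directions with symmetric
// pairing; zones (GLSZM/GLDZM) are 26-connected; NGLDM counts equal-level
// 26-neighbours (coarseness threshold alpha = 0).

static inline int idx3(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

// The 13 unique direction offsets (half of the 26-neighbourhood).
static const int DIRS[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
    {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export(name = ".cpp_glcm")]]
NumericMatrix cpp_glcm(IntegerVector levels, int ng) {
    IntegerVector dm = levels.attr("dim");
    int nx = dm[0], ny = dm[1], nz = dm[2];
    NumericMatrix acc(ng, ng);
    int n_valid_dirs = 0;
    std::vector<double> p(ng * ng);
    for (int d = 0; d < 13; ++d) {
        int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        std::fill(p.begin(), p.end(), 0.0);
        double tot = 0.0;
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int a = levels[idx3(x, y, z, nx, ny)];
                    if (a == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                        z2 < 0 || z2 >= nz) continue;
                    int b = levels[idx3(x2, y2, z2, nx, ny)];
                    if (b == 0) continue;
                    // symmetric: count the pair in both orientations
                    p[(a - 1) + ng * (b - 1)] += 1.0;
                    p[(b - 1) + ng * (a - 1)] += 1.0;
                    tot += 2.0;
                }
        if (tot > 0) {
            ++n_valid_dirs;
            for (int k = 0; k < ng * ng; ++k) acc[k] += p[k] / tot;
        }
    }
    if (n_valid_dirs == 0)
        stop("no valid in-mask voxel pair for GLCM computation");
    for (int k = 0; k < ng * ng; ++k) acc[k] /= n_valid_dirs;
    return acc;
}

// 26-connected labelling of equal-level regions. Returns an integer array of
// zone labels (0 outside the mask, 1..nzones inside).
// [[Rcpp::export(name = ".cpp_label_zones")]]
IntegerVector cpp_label_zones(IntegerVector levels) {
    IntegerVector dm = levels.attr("dim");
    int nx = dm[0], ny = dm[1], nz = dm[2];
    int n = nx * ny * nz;
    IntegerVector lab(n, 0);
    lab.attr("dim") = dm;
    int next = 0;
    std::vector<int> stack;
    for (int s = 0; s < n; ++s) {
        if (levels[s] == 0 || lab[s] != 0) continue;
        int g = levels[s];
        ++next;
        lab[s] = next;
        stack.push_back(s);
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (dx == 0 && dy == 0 && dz == 0) continue;
                        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                            z2 < 0 || z2 >= nz) continue;
                        int w = idx3(x2, y2, z2, nx, ny);
                        if (levels[w] == g && lab[w] == 0) {
                            lab[w] = next;
                            stack.push_back(w);
                        }
                    }
        }
    }
    return lab;
}

// Chebyshev distance of every in-mask voxel to the mask border (border
// voxels, i.e. voxels with an out-of-mask or out-of-grid 26-neighbour, have
// distance 1). Multi-source BFS over the 26-neighbourhood.
// [[Rcpp::export(name = ".cpp_border_distance")]]
IntegerVector cpp_border_distance(IntegerVector levels) {
    IntegerVector dm = levels.attr("dim");
    int nx = dm[0], ny = dm[1], nz = dm[2];
    int n = nx * ny * nz;
    IntegerVector dist(n, 0);
    dist.attr("dim") = dm;
    std::queue<int> q;
    for (int s = 0; s < n; ++s) {
        if (levels[s] == 0) continue;
        int x = s % nx, y = (s / nx) % ny, z = s / (nx * ny);
        bool border = false;
        for (int dz = -1; dz <= 1 && !border; ++dz)
            for (int dy = -1; dy <= 1 && !border; ++dy)
                for (int dx = -1; dx <= 1 && !border; ++dx) {
                    if (dx == 0 && dy == 0 && dz == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                        z2 < 0 || z2 >= nz) { border = true; break; }
                    if (levels[idx3(x2, y2, z2, nx, ny)] == 0) {
                        border = true; break;
                    }
                }
        if (border) { dist[s] = 1; q.push(s); }
    }
    while (!q.empty()) {
        int v = q.front(); q.pop();
        int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                    if (dx == 0 && dy == 0 && dz == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                        z2 < 0 || z2 >= nz) continue;
                    int w = idx3(x2, y2, z2, nx, ny);
                    if (levels[w] != 0 && dist[w] == 0) {
                        dist[w] = dist[v] + 1;
                        q.push(w);
                    }
                }
    }
    return dist;
}

// Dependence count per in-mask voxel: number of in-mask 26-neighbours with
// the same gray level (alpha = 0). Out-of-mask voxels get -1.
// [[Rcpp::export(name = ".cpp_dependence_counts")]]
IntegerVector cpp_dependence_counts(IntegerVector levels) {
    IntegerVector dm = levels.attr("dim");
    int nx = dm[0], ny = dm[1], nz = dm[2];
    int n = nx * ny * nz;
    IntegerVector dep(n, -1);
    dep.attr("dim") = dm;
    for (int s = 0; s < n; ++s) {
        if (levels[s] == 0) continue;
        int g = levels[s];
        int x = s % nx, y = (s / nx) % ny, z = s / (nx * ny);
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                    if (dx == 0 && dy == 0 && dz == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                        z2 < 0 || z2 >= nz) continue;
                    if (levels[idx3(x2, y2, z2, nx, ny)] == g) ++k;
                }
        dep[s] = k;
    }
    return dep;
}
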