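#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// The 13 unique 3D direction vectors at Chebyshev distance 1 (half of the 26
// neighbours; the other half are their negations and are covered by symmetry).
static const int DIRS[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int idx3(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

static void get_dims(const IntegerVector &a, int &nx, int &ny, int &nz) {
    IntegerVector d = a.attr("dim");
    if (d.size() != 3) stop("expected a 3D array");
    nx = d[0]; ny = d[1]; nz = d[2];
}

// Per-direction symmetric gray-level co-occurrence counts.
// levels: 3D integer array, 0 outside mask, 1..nbins inside.
// Returns nbins x nbins x 13 count array (each pair counted in both orders).
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector levels, int nbins) {
    int nx, ny, nz;
    get_dims(levels, nx, ny, nz);
    NumericVector out(nbins * nbins * 13);
    out.attr("dim") = IntegerVector::create(nbins, nbins, 13);
    for (int d = 0; d < 13; ++d) {
        const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        double *M = &out[(size_t)d * nbins * nbins];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int i = levels[idx3(x, y, z, nx, ny)];
                    if (i == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                        continue;
                    int j = levels[idx3(x2, y2, z2, nx, ny)];
                    if (j == 0) continue;
                    M[(i - 1) + nbins * (j - 1)] += 1.0;
                    M[(j - 1) + nbins * (i - 1)] += 1.0;
                }
    }
    return out;
}

// Per-direction gray-level run-length counts of maximal runs.
// Returns nbins x Lmax x 13 with Lmax = max(nx, ny, nz).
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector levels, int nbins) {
    int nx, ny, nz;
    get_dims(levels, nx, ny, nz);
    int lmax = std::max(nx, std::max(ny, nz));
    NumericVector out(nbins * lmax * 13);
    out.attr("dim") = IntegerVector::create(nbins, lmax, 13);
    for (int d = 0; d < 13; ++d) {
        const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        double *M = &out[(size_t)d * nbins * lmax];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int lev = levels[idx3(x, y, z, nx, ny)];
                    if (lev == 0) continue;
                    // run starts here iff the previous voxel along d is not
                    // an in-mask voxel of the same level
                    int xp = x - dx, yp = y - dy, zp = z - dz;
                    if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
                        levels[idx3(xp, yp, zp, nx, ny)] == lev)
                        continue;
                    int len = 1;
                    int xn = x + dx, yn = y + dy, zn = z + dz;
                    while (xn >= 0 && xn < nx && yn >= 0 && yn < ny && zn >= 0 && zn < nz &&
                           levels[idx3(xn, yn, zn, nx, ny)] == lev) {
                        ++len;
                        xn += dx; yn += dy; zn += dz;
                    }
                    M[(lev - 1) + nbins * (len - 1)] += 1.0;
                }
    }
    return out;
}

// City-block distance from each in-mask voxel to the nearest out-of-mask
// voxel; the array boundary counts as outside, so border voxels get 1.
// Multi-source BFS over the 6-neighbourhood. Out-of-mask voxels get 0.
// [[Rcpp::export]]
IntegerVector cpp_distance_map(IntegerVector levels) {
    int nx, ny, nz;
    get_dims(levels, nx, ny, nz);
    size_t n = (size_t)nx * ny * nz;
    IntegerVector dist(n);
    std::queue<int> q;
    const int offs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int id = idx3(x, y, z, nx, ny);
                if (levels[id] == 0) { dist[id] = 0; continue; }
                bool border = false;
                for (int k = 0; k < 6 && !border; ++k) {
                    int x2 = x + offs[k][0], y2 = y + offs[k][1], z2 = z + offs[k][2];
                    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz ||
                        levels[idx3(x2, y2, z2, nx, ny)] == 0)
                        border = true;
                }
                if (border) { dist[id] = 1; q.push(id); }
                else dist[id] = NA_INTEGER;
            }
    while (!q.empty()) {
        int id = q.front(); q.pop();
        int z = id / (nx * ny), rem = id % (nx * ny);
        int y = rem / nx, x = rem % nx;
        for (int k = 0; k < 6; ++k) {
            int x2 = x + offs[k][0], y2 = y + offs[k][1], z2 = z + offs[k][2];
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int id2 = idx3(x2, y2, z2, nx, ny);
            if (dist[id2] == NA_INTEGER) {
                dist[id2] = dist[id] + 1;
                q.push(id2);
            }
        }
    }
    dist.attr("dim") = IntegerVector::create(nx, ny, nz);
    return dist;
}

// Connected zones of equal gray level (26-connectivity flood fill).
// Returns a data frame with one row per zone: level, size, and the minimum
// over the zone of the supplied border-distance map.
// [[Rcpp::export]]
DataFrame cpp_zones(IntegerVector levels, IntegerVector distmap) {
    int nx, ny, nz;
    get_dims(levels, nx, ny, nz);
    size_t n = (size_t)nx * ny * nz;
    std::vector<char> seen(n, 0);
    std::vector<int> zl, zs, zd;
    std::vector<int> stack;
    for (size_t start = 0; start < n; ++start) {
        if (levels[start] == 0 || seen[start]) continue;
        int lev = levels[start];
        int size = 0, dmin = INT_MAX;
        stack.clear();
        stack.push_back((int)start);
        seen[start] = 1;
        while (!stack.empty()) {
            int id = stack.back(); stack.pop_back();
            ++size;
            if (distmap[id] < dmin) dmin = distmap[id];
            int z = id / (nx * ny), rem = id % (nx * ny);
            int y = rem / nx, x = rem % nx;
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!dx && !dy && !dz) continue;
                        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                            continue;
                        int id2 = idx3(x2, y2, z2, nx, ny);
                        if (!seen[id2] && levels[id2] == lev) {
                            seen[id2] = 1;
                            stack.push_back(id2);
                        }
                    }
        }
        zl.push_back(lev); zs.push_back(size); zd.push_back(dmin);
    }
    return DataFrame::create(_["level"] = zl, _["size"] = zs, _["distance"] = zd);
}

// Label connected components of a binary mask under an arbitrary offset set
// (rows of `offsets` are neighbour displacement vectors). Labels 1..K in
// first-encounter order; 0 outside.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerMatrix offsets) {
    IntegerVector dm = mask.attr("dim");
    if (dm.size() != 3) stop("expected a 3D array");
    int nx = dm[0], ny = dm[1], nz = dm[2];
    size_t n = (size_t)nx * ny * nz;
    IntegerVector lab(n);
    int no = offsets.nrow();
    int next = 0;
    std::vector<int> stack;
    for (size_t start = 0; start < n; ++start) {
        if (!mask[start] || lab[start]) continue;
        ++next;
        stack.clear();
        stack.push_back((int)start);
        lab[start] = next;
        while (!stack.empty()) {
            int id = stack.back(); stack.pop_back();
            int z = id / (nx * ny), rem = id % (nx * ny);
            int y = rem / nx, x = rem % nx;
            for (int k = 0; k < no; ++k) {
                int x2 = x + offsets(k, 0), y2 = y + offsets(k, 1), z2 = z + offsets(k, 2);
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                    continue;
                int id2 = idx3(x2, y2, z2, nx, ny);
                if (mask[id2] && !lab[id2]) {
                    lab[id2] = next;
                    stack.push_back(id2);
                }
            }
        }
    }
    lab.attr("dim") = IntegerVector::create(nx, ny, nz);
    return lab;
}

// Neighbouring gray-level dependence counts. For each in-mask voxel of level
// i, k = number of in-mask neighbours within Chebyshev distance delta with
// |level - i| <= alpha; the dependence count is j = k + 1 (always >= 1).
// Returns nbins x (2*delta+1)^3 count matrix.
// [[Rcpp::export]]
NumericMatrix cpp_ngldm(IntegerVector levels, int nbins, int alpha, int delta) {
    int nx, ny, nz;
    get_dims(levels, nx, ny, nz);
    int side = 2 * delta + 1;
    int jmax = side * side * side;
    NumericMatrix out(nbins, jmax);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int i = levels[idx3(x, y, z, nx, ny)];
                if (i == 0) continue;
                int k = 0;
                for (int dz = -delta; dz <= delta; ++dz)
                    for (int dy = -delta; dy <= delta; ++dy)
                        for (int dx = -delta; dx <= delta; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                                continue;
                            int j = levels[idx3(x2, y2, z2, nx, ny)];
                            if (j != 0 && std::abs(j - i) <= alpha) ++k;
                        }
                out(i - 1, k) += 1.0;  // column k holds dependence count j = k + 1
            }
    return out;
}

// Neighbourhood gray-tone difference sums. s[i] = sum over in-mask voxels of
// level i+1 of |level - mean neighbour level| (neighbours: in-mask voxels
// within Chebyshev distance delta); n[i] = occurrence count of voxels with at
// least one valid neighbour.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, int nbins, int delta) {
    int nx, ny, nz;
    get_dims(levels, nx, ny, nz);
    NumericVector s(nbins), cnt(nbins);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int i = levels[idx3(x, y, z, nx, ny)];
                if (i == 0) continue;
                double sum = 0.0;
                int m = 0;
                for (int dz = -delta; dz <= delta; ++dz)
                    for (int dy = -delta; dy <= delta; ++dy)
                        for (int dx = -delta; dx <= delta; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                                continue;
                            int j = levels[idx3(x2, y2, z2, nx, ny)];
                            if (j != 0) { sum += j; ++m; }
                        }
                if (m == 0) continue;  // isolated voxel: no valid neighbourhood
                s[i - 1] += std::abs((double)i - sum / m);
                cnt[i - 1] += 1.0;
            }
    return List::create(_["s"] = s, _["n"] = cnt);
}

// Separable 3D convolution with reflect boundary handling. kx/ky/kz are odd-
// length kernels applied along the first/second/third array dimension.
static void conv_axis(std::vector<double> &buf, const NumericVector &k,
                      int nline, std::vector<double> &line, std::vector<double> &res) {
    // helper operates on `line` of length nline, writes to res
    int half = ((int)k.size() - 1) / 2;
    for (int i = 0; i < nline; ++i) {
        double acc = 0.0;
        for (int t = -half; t <= half; ++t) {
            int p = i + t;
            // reflect (mirror without repeating the edge sample when possible)
            while (p < 0 || p >= nline) {
                if (p < 0) p = -p - 1;
                if (p >= nline) p = 2 * nline - p - 1;
            }
            acc += line[p] * k[t + half];
        }
        res[i] = acc;
    }
    (void)buf;
}

// [[Rcpp::export]]
NumericVector cpp_sep_conv3d(NumericVector x, NumericVector kx,
                             NumericVector ky, NumericVector kz) {
    IntegerVector d = x.attr("dim");
    if (d.size() != 3) stop("expected a 3D array");
    int nx = d[0], ny = d[1], nz = d[2];
    NumericVector out = clone(x);
    std::vector<double> line(std::max(nx, std::max(ny, nz)));
    std::vector<double> res(line.size());
    std::vector<double> dummy;
    if (kx.size() > 1)
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y) {
                for (int i = 0; i < nx; ++i) line[i] = out[idx3(i, y, z, nx, ny)];
                conv_axis(dummy, kx, nx, line, res);
                for (int i = 0; i < nx; ++i) out[idx3(i, y, z, nx, ny)] = res[i];
            }
    if (ky.size() > 1)
        for (int z = 0; z < nz; ++z)
            for (int x1 = 0; x1 < nx; ++x1) {
                for (int i = 0; i < ny; ++i) line[i] = out[idx3(x1, i, z, nx, ny)];
                conv_axis(dummy, ky, ny, line, res);
                for (int i = 0; i < ny; ++i) out[idx3(x1, i, z, nx, ny)] = res[i];
            }
    if (kz.size() > 1)
        for (int y = 0; y < ny; ++y)
            for (int x1 = 0; x1 < nx; ++x1) {
                for (int i = 0; i < nz; ++i) line[i] = out[idx3(x1, y, i, nx, ny)];
                conv_axis(dummy, kz, nz, line, res);
                for (int i = 0; i < nz; ++i) out[idx3(x1, y, i, nx, ny)] = res[i];
            }
    out.attr("dim") = d;
    return out;
}
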