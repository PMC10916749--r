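#include <Rcpp.h>
using namespace Rcpp;

// Kernels supporting the native 3D CNN: im2col/col2im turn "same"-padded
// 3x3x3 convolution into one BLAS matrix product per sample; max-pooling
// stores argmax indices so the backward pass is a scatter.
// Volume layout: 4D array (nx, ny, nz, channels), column-major.

static void dims4(const NumericVector &x, int &nx, int &ny, int &nz, int &nc) {
    IntegerVector d = x.attr("dim");
    if (d.size() != 4) stop("expected a 4D array (x, y, z, channel)");
    nx = d[0]; ny = d[1]; nz = d[2]; nc = d[3];
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, int k, int pad) {
    int nx, ny, nz, nc;
    dims4(x, nx, ny, nz, nc);
    size_t V = (size_t)nx * ny * nz;
    int kk = k * k * k;
    NumericMatrix cols(V, (size_t)kk * nc);
    int half = k / 2;  // used with pad == half for "same" output
    if (pad != half) stop("only same-size convolution supported (pad = k/2)");
    size_t col = 0;
    for (int c = 0; c < nc; ++c) {
        const double *xc = &x[(size_t)c * V];
        for (int kz = -half; kz <= half; ++kz)
            for (int ky = -half; ky <= half; ++ky)
                for (int kx = -half; kx <= half; ++kx) {
                    double *dst = &cols[col * V];
                    size_t r = 0;
                    for (int z = 0; z < nz; ++z) {
                        int z2 = z + kz;
                        bool zok = z2 >= 0 && z2 < nz;
                        for (int y = 0; y < ny; ++y) {
                            int y2 = y + ky;
                            bool yok = y2 >= 0 && y2 < ny;
                            for (int x1 = 0; x1 < nx; ++x1, ++r) {
                                int x2 = x1 + kx;
                                if (zok && yok && x2 >= 0 && x2 < nx)
                                    dst[r] = xc[x2 + (size_t)nx * (y2 + (size_t)ny * z2)];
                                else
                                    dst[r] = 0.0;
                            }
                        }
                    }
                    ++col;
                }
    }
    return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix cols, IntegerVector dim, int k, int pad) {
    int nx = dim[0], ny = dim[1], nz = dim[2], nc = dim[3];
    size_t V = (size_t)nx * ny * nz;
    int half = k / 2;
    if (pad != half) stop("only same-size convolution supported (pad = k/2)");
    NumericVector out((size_t)V * nc);
    size_t col = 0;
    for (int c = 0; c < nc; ++c) {
        double *oc = &out[(size_t)c * V];
        for (int kz = -half; kz <= half; ++kz)
            for (int ky = -half; ky <= half; ++ky)
                for (int kx = -half; kx <= half; ++kx) {
                    const double *src = &cols[col * V];
                    size_t r = 0;
                    for (int z = 0; z < nz; ++z) {
                        int z2 = z + kz;
                        bool zok = z2 >= 0 && z2 < nz;
                        for (int y = 0; y < ny; ++y) {
                            int y2 = y + ky;
                            bool yok = y2 >= 0 && y2 < ny;
                            for (int x1 = 0; x1 < nx; ++x1, ++r) {
                                int x2 = x1 + kx;
                                if (zok && yok && x2 >= 0 && x2 < nx)
                                    oc[x2 + (size_t)nx * (y2 + (size_t)ny * z2)] += src[r];
                            }
                        }
                    }
                    ++col;
                }
    }
    out.attr("dim") = dim;
    return out;
}

// 2x2x2 max pooling, stride 2 (trailing odd slices dropped). Returns pooled
// values and 1-based argmax indices into the input array.
// [[Rcpp::export]]
List cpp_maxpool3(NumericVector x) {
    int nx, ny, nz, nc;
    dims4(x, nx, ny, nz, nc);
    int ox = nx / 2, oy = ny / 2, oz = nz / 2;
    size_t Vi = (size_t)nx * ny * nz, Vo = (size_t)ox * oy * oz;
    NumericVector out(Vo * nc);
    IntegerVector arg(Vo * nc);
    for (int c = 0; c < nc; ++c) {
        const double *xc = &x[(size_t)c * Vi];
        double *oc = &out[(size_t)c * Vo];
        int *ac = &arg[(size_t)c * Vo];
        size_t r = 0;
        for (int z = 0; z < oz; ++z)
            for (int y = 0; y < oy; ++y)
                for (int x1 = 0; x1 < ox; ++x1, ++r) {
                    double best = -1e300;
                    size_t besti = 0;
                    for (int dz = 0; dz < 2; ++dz)
                        for (int dy = 0; dy < 2; ++dy)
                            for (int dx = 0; dx < 2; ++dx) {
                                size_t id = (size_t)(2 * x1 + dx) +
                                            (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                                if (xc[id] > best) { best = xc[id]; besti = id; }
                            }
                    oc[r] = best;
                    ac[r] = (int)((size_t)c * Vi + besti) + 1;
                }
    }
    out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
    arg.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
    return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3_backward(NumericVector grad_out, IntegerVector argmax,
                                    IntegerVector in_dim) {
    size_t n = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
    NumericVector gin(n);
    for (R_xlen_t i = 0; i < grad_out.size(); ++i)
        gin[argmax[i] - 1] += grad_out[i];
    gin.attr("dim") = in_dim;
    return gin;
}
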