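#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

// world -> continuous voxel coordinates.
// world = origin + A %*% (vox * spacing), A orthonormal (columns = world
// directions of the voxel axes), so vox_j = <A[,j], world - origin> / spacing_j.
static inline void worldToVoxel(const double* axes, const double* origin,
                                const double* spacing,
                                double wx, double wy, double wz,
                                double& vx, double& vy, double& vz) {
    const double dx = wx - origin[0], dy = wy - origin[1], dz = wz - origin[2];
    vx = (axes[0] * dx + axes[1] * dy + axes[2] * dz) / spacing[0];
    vy = (axes[3] * dx + axes[4] * dy + axes[5] * dz) / spacing[1];
    vz = (axes[6] * dx + axes[7] * dy + axes[8] * dz) / spacing[2];
}

static inline double sampleNearest(const double* v, const int* dim,
                                   double vx, double vy, double vz,
                                   double outside) {
    const long ix = (long)std::floor(vx + 0.5), iy = (long)std::floor(vy + 0.5), iz = (long)std::floor(vz + 0.5);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= dim[0] || iy >= dim[1] || iz >= dim[2])
        return outside;
    return v[ix + (long)dim[0] * (iy + (long)dim[1] * iz)];
}

static inline double sampleTrilin(const double* v, const int* dim,
                                  double vx, double vy, double vz,
                                  double outside) {
    const double fx = std::floor(vx), fy = std::floor(vy), fz = std::floor(vz);
    const long ix = (long)fx, iy = (long)fy, iz = (long)fz;
    const double tx = vx - fx, ty = vy - fy, tz = vz - fz;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
        const double wz = dz ? tz : 1.0 - tz;
        if (wz == 0.0) continue;
        for (int dy = 0; dy <= 1; ++dy) {
            const double wy = dy ? ty : 1.0 - ty;
            if (wy == 0.0) continue;
            for (int dx = 0; dx <= 1; ++dx) {
                const double wx = dx ? tx : 1.0 - tx;
                if (wx == 0.0) continue;
                const long jx = ix + dx, jy = iy + dy, jz = iz + dz;
                double val;
                if (jx < 0 || jy < 0 || jz < 0 ||
                    jx >= dim[0] || jy >= dim[1] || jz >= dim[2])
                    val = outside;
                else
                    val = v[jx + (long)dim[0] * (jy + (long)dim[1] * jz)];
                acc += wx * wy * wz * val;
            }
        }
    }
    return acc;
}

// [[Rcpp::export]]
NumericVector sampleVolumeCpp(NumericVector values, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix axes, NumericMatrix pts,
                              double outside, int mode) {
    const int n = pts.nrow();
    NumericVector out(n);
    // column-major axes: axes(i, j) = world component i of voxel axis j;
    // flatten transposed so worldToVoxel reads rows of A^T contiguously.
    double A[9];
    for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
            A[3 * j + i] = axes(i, j);
    const double* v = REAL(values);
    for (int k = 0; k < n; ++k) {
        double vx, vy, vz;
        worldToVoxel(A, REAL(origin), REAL(spacing),
                     pts(k, 0), pts(k, 1), pts(k, 2), vx, vy, vz);
        out[k] = (mode == 0)
            ? sampleNearest(v, INTEGER(dim), vx, vy, vz, outside)
            : sampleTrilin(v, INTEGER(dim), vx, vy, vz, outside);
    }
    return out;
}

// Mean log-compressed transmission for a batch of probe poses.
// Scan-line geometry (origins rayO, unit directions rayD) is given in the
// probe frame; pose p places it in the world via R_p x + s_p. Attenuation is
// sampled nearest-voxel so that piecewise-constant media yield step-size
// invariant reflection sums (one sharp interface contributes exactly r^2).
// [[Rcpp::export]]
NumericVector tbarPosesCpp(NumericVector mu, IntegerVector dim,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix axes,
                           NumericMatrix rayO, NumericMatrix rayD,
                           double depth, double step, double nu,
                           NumericMatrix rotations, NumericMatrix bases,
                           double outside) {
    const int nRays = rayO.nrow();
    const int nPoses = bases.nrow();
    const int nSamp = (int)std::floor(depth / step + 1e-9) + 1; // depths 0..K*step
    const double logDen = std::log1p(nu);
    double A[9];
    for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i)
            A[3 * j + i] = axes(i, j);
    const double* v = REAL(mu);
    const double* org = REAL(origin);
    const double* sp = REAL(spacing);
    const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    NumericVector out(nPoses);
    for (int p = 0; p < nPoses; ++p) {
        // rotation stored row-major: rotations(p, 3*i + j) = R[i][j]
        double R[9];
        for (int k = 0; k < 9; ++k) R[k] = rotations(p, k);
        const double sx = bases(p, 0), sy = bases(p, 1), sz = bases(p, 2);
        double sum = 0.0;
        for (int i = 0; i < nRays; ++i) {
            const double bx = rayO(i, 0), by = rayO(i, 1), bz = rayO(i, 2);
            const double dx = rayD(i, 0), dy = rayD(i, 1), dz = rayD(i, 2);
            const double ox = R[0] * bx + R[1] * by + R[2] * bz + sx;
            const double oy = R[3] * bx + R[4] * by + R[5] * bz + sy;
            const double oz = R[6] * bx + R[7] * by + R[8] * bz + sz;
            const double wx = R[0] * dx + R[1] * dy + R[2] * dz;
            const double wy = R[3] * dx + R[4] * dy + R[5] * dz;
            const double wz = R[6] * dx + R[7] * dy + R[8] * dz;
            // ray in continuous voxel coordinates: one transform per ray,
            // then a multiply-add per sample
            double ovx, ovy, ovz, wvx, wvy, wvz;
            worldToVoxel(A, org, sp, ox, oy, oz, ovx, ovy, ovz);
            wvx = (A[0] * wx + A[1] * wy + A[2] * wz) / sp[0];
            wvy = (A[3] * wx + A[4] * wy + A[5] * wz) / sp[1];
            wvz = (A[6] * wx + A[7] * wy + A[8] * wz) / sp[2];
            double acc = 0.0;  // accumulated sum of squared reflection ratios
            double muPrev = 0.0;
            double that = 1.0;
            for (int k = 0; k < nSamp; ++k) {
                const double l = k * step;
                const long ix = (long)std::floor(ovx + l * wvx + 0.5);
                const long iy = (long)std::floor(ovy + l * wvy + 0.5);
                const long iz = (long)std::floor(ovz + l * wvz + 0.5);
                double muK;
                if (ix < 0 || iy < 0 || iz < 0 ||
                    ix >= d0 || iy >= d1 || iz >= d2)
                    muK = outside;
                else
                    muK = v[ix + (long)d0 * (iy + (long)d1 * iz)];
                if (k > 0 && muK != muPrev) {
                    const double r = (muK - muPrev) / (muK + muPrev);
                    acc += r * r;
                    that = std::log1p(nu * std::exp(-acc)) / logDen;
                }
                muPrev = muK;
                sum += that;
            }
        }
        out[p] = sum / ((double)nRays * nSamp);
    }
    return out;
}

// 6-connected components of a binary mask; labels 1..n by discovery order
// (array scan order), 0 outside the mask.
// [[Rcpp::export]]
IntegerVector labelComponentsCpp(LogicalVector mask, IntegerVector dim) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const long n = (long)nx * ny * nz;
    IntegerVector lab(n, 0);
    const int* m = LOGICAL(mask);
    int next = 0;
    std::vector<long> stack;
    for (long s = 0; s < n; ++s) {
        if (!m[s] || lab[s]) continue;
        ++next;
        stack.push_back(s);
        lab[s] = next;
        while (!stack.empty()) {
            const long c = stack.back();
            stack.pop_back();
            const long x = c % nx, y = (c / nx) % ny, z = c / ((long)nx * ny);
            const long nb[6] = {
                x > 0 ? c - 1 : -1, x < nx - 1 ? c + 1 : -1,
                y > 0 ? c - nx : -1, y < ny - 1 ? c + nx : -1,
                z > 0 ? c - (long)nx * ny : -1, z < nz - 1 ? c + (long)nx * ny : -1
            };
            for (int k = 0; k < 6; ++k) {
                const long q = nb[k];
                if (q >= 0 && m[q] && !lab[q]) {
                    lab[q] = next;
                    stack.push_back(q);
                }
            }
        }
    }
    lab.attr("dim") = dim;
    return lab;
}
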