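#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Large finite stand-in for +Inf so the parabola intersections stay well defined.
static const double DT_INF = 1e15;

// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher squared EDT),
// with physical sample positions x (mm) so anisotropic spacing is exact.
static void dt1d(const std::vector<double>& f, const std::vector<double>& x,
                 std::vector<double>& d) {
    const int n = (int)f.size();
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -std::numeric_limits<double>::infinity();
    z[1] = std::numeric_limits<double>::infinity();
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            int p = v[k];
            s = ((f[q] + x[q] * x[q]) - (f[p] + x[p] * x[p])) / (2.0 * (x[q] - x[p]));
            if (k > 0 && s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < x[q]) ++k;
        double dx = x[q] - x[v[k]];
        d[q] = dx * dx + f[v[k]];
    }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest TRUE
// voxel center of `mask`. TRUE voxels get 0. All-FALSE masks return DT_INF-scale
// values; the R wrapper turns those into Inf.
// [[Rcpp::export(name = ".edt_mm_cpp")]]
NumericVector edt_mm_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
    NumericVector out(ntot);
    for (R_xlen_t i = 0; i < ntot; ++i) out[i] = mask[i] ? 0.0 : DT_INF;

    // pass along x
    {
        std::vector<double> f(nx), d(nx), x(nx);
        for (int i = 0; i < nx; ++i) x[i] = i * spacing[0];
        for (int k = 0; k < nz; ++k) {
            for (int j = 0; j < ny; ++j) {
                R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
                for (int i = 0; i < nx; ++i) f[i] = out[base + i];
                dt1d(f, x, d);
                for (int i = 0; i < nx; ++i) out[base + i] = d[i];
            }
        }
    }
    // pass along y
    {
        std::vector<double> f(ny), d(ny), x(ny);
        for (int j = 0; j < ny; ++j) x[j] = j * spacing[1];
        for (int k = 0; k < nz; ++k) {
            for (int i = 0; i < nx; ++i) {
                R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * nx * ny;
                for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
                dt1d(f, x, d);
                for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
            }
        }
    }
    // pass along z
    {
        std::vector<double> f(nz), d(nz), x(nz);
        for (int k = 0; k < nz; ++k) x[k] = k * spacing[2];
        const R_xlen_t nxy = (R_xlen_t)nx * ny;
        for (int j = 0; j < ny; ++j) {
            for (int i = 0; i < nx; ++i) {
                R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * nx;
                for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
                dt1d(f, x, d);
                for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
            }
        }
    }
    for (R_xlen_t i = 0; i < ntot; ++i) out[i] = std::sqrt(out[i]);
    return out;
}

// Dilation of a binary mask by a direction-dependent ellipsoidal structuring
// element. margins are mm reach per anatomical direction in the fixed patient
// frame (+x left, +y posterior, +z superior), ordered
// (left, right, anterior, posterior, superior, inferior).
// A voxel center v is set iff some source voxel center u satisfies
//   sum_axis ((v-u)_axis / m_axis(sign))^2 <= 1,
// where the axis margin is chosen by the sign of the offset component.
// [[Rcpp::export(name = ".dilate_margins_cpp")]]
LogicalVector dilate_margins_cpp(LogicalVector mask, IntegerVector dims,
                                 NumericVector spacing, NumericVector margins) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
    const double mL = margins[0], mR = margins[1], mA = margins[2],
                 mP = margins[3], mS = margins[4], mI = margins[5];

    const int ixp = (int)std::floor(mL / sx + 1e-9), ixm = (int)std::floor(mR / sx + 1e-9);
    const int iyp = (int)std::floor(mP / sy + 1e-9), iym = (int)std::floor(mA / sy + 1e-9);
    const int izp = (int)std::floor(mS / sz + 1e-9), izm = (int)std::floor(mI / sz + 1e-9);

    std::vector<int> di, dj, dk;
    for (int i = -ixm; i <= ixp; ++i) {
        double dx = i * sx;
        double mx = (i > 0) ? mL : mR;
        double tx;
        if (i == 0) tx = 0.0;
        else if (mx <= 0.0) continue;
        else tx = (dx * dx) / (mx * mx);
        if (tx > 1.0 + 1e-9) continue;
        for (int j = -iym; j <= iyp; ++j) {
            double dy = j * sy;
            double my = (j > 0) ? mP : mA;
            double ty;
            if (j == 0) ty = 0.0;
            else if (my <= 0.0) continue;
            else ty = (dy * dy) / (my * my);
            if (tx + ty > 1.0 + 1e-9) continue;
            for (int k = -izm; k <= izp; ++k) {
                double dz = k * sz;
                double mz = (k > 0) ? mS : mI;
                double tz;
                if (k == 0) tz = 0.0;
                else if (mz <= 0.0) continue;
                else tz = (dz * dz) / (mz * mz);
                if (tx + ty + tz > 1.0 + 1e-9) continue;
                di.push_back(i); dj.push_back(j); dk.push_back(k);
            }
        }
    }

    const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
    LogicalVector out(ntot);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int k = 0; k < nz; ++k) {
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nxy;
            for (int i = 0; i < nx; ++i) {
                if (!mask[base + i]) continue;
                for (size_t o = 0; o < di.size(); ++o) {
                    int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
                    if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
                    out[(R_xlen_t)ii + (R_xlen_t)jj * nx + (R_xlen_t)kk * nxy] = TRUE;
                }
            }
        }
    }
    return out;
}
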