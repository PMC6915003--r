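#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam projector on a centered 2D grid.
//
// Pixel (i, j), 0-based, covers the half-open cell
//   x in [xmin + i*dx, xmin + (i+1)*dx), y likewise,
// with xmin = -nx*dx/2 so the rotation center is the grid center.
// The ray at angle theta with radial offset s is
//   p(t) = s*(cos t, sin t) + t*(-sin t, cos t),
// and the projection entry is the exact line integral (value * mm):
// the sum over traversed pixels of value * intersection length,
// accumulated by a Siddon-style parametric traversal.  The
// backprojector scatters with the identical weights, so the pair is an
// exact adjoint up to floating-point rounding.

static const double EPS = 1e-12;

// Tie-break for rays running exactly along a pixel boundary (axis-aligned
// angles on even grids): bias the on-boundary coordinate by 1e-9 mm toward
// the upper cell.  The R brute-force oracle uses the same convention.
static const double TIE = 1e-9;

struct Ray {
    double px, py;   // point on ray
    double ux, uy;   // unit direction
};

// Clip the ray to the image box; returns false if it misses.
static bool clip_box(const Ray &r, double xmin, double xmax,
                     double ymin, double ymax, double &t0, double &t1) {
    t0 = -1e30;
    t1 = 1e30;
    if (std::fabs(r.ux) < EPS) {
        if (r.px + TIE < xmin || r.px + TIE >= xmax) return false;
    } else {
        double ta = (xmin - r.px) / r.ux;
        double tb = (xmax - r.px) / r.ux;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
    }
    if (std::fabs(r.uy) < EPS) {
        if (r.py + TIE < ymin || r.py + TIE >= ymax) return false;
    } else {
        double ta = (ymin - r.py) / r.uy;
        double tb = (ymax - r.py) / r.uy;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
    }
    return t1 > t0 + EPS;
}

// Traverse one ray.  mode 0: accumulate sum of img*seglen (forward).
// mode 1: img[cell] += w*seglen (backprojection scatter).
static double traverse(double *img, int nx, int ny, double dx, double dy,
                       double theta, double s, int mode, double w) {
    Ray r;
    double c = std::cos(theta), sn = std::sin(theta);
    r.px = s * c;
    r.py = s * sn;
    r.ux = -sn;
    r.uy = c;

    double xmin = -0.5 * nx * dx, xmax = 0.5 * nx * dx;
    double ymin = -0.5 * ny * dy, ymax = 0.5 * ny * dy;

    double t0, t1;
    if (!clip_box(r, xmin, xmax, ymin, ymax, t0, t1)) return 0.0;

    // Entry cell, from a point nudged inside the box; for an axis-parallel
    // ray the perpendicular index is fixed and uses the tie-break bias.
    double tm = t0 + EPS * (t1 - t0);
    int ix = (std::fabs(r.ux) < EPS)
        ? (int)std::floor((r.px + TIE - xmin) / dx)
        : (int)std::floor((r.px + r.ux * tm - xmin) / dx);
    int iy = (std::fabs(r.uy) < EPS)
        ? (int)std::floor((r.py + TIE - ymin) / dy)
        : (int)std::floor((r.py + r.uy * tm - ymin) / dy);
    if (ix < 0) ix = 0;
    if (ix > nx - 1) ix = nx - 1;
    if (iy < 0) iy = 0;
    if (iy > ny - 1) iy = ny - 1;

    int sx = (r.ux > 0) - (r.ux < 0);
    int sy = (r.uy > 0) - (r.uy < 0);
    double dtx = (std::fabs(r.ux) < EPS) ? 1e30 : dx / std::fabs(r.ux);
    double dty = (std::fabs(r.uy) < EPS) ? 1e30 : dy / std::fabs(r.uy);

    // Parameter of the next x / y plane crossing.
    double txn, tyn;
    if (std::fabs(r.ux) < EPS) txn = 1e30;
    else {
        double xb = xmin + (ix + (sx > 0 ? 1 : 0)) * dx;
        txn = (xb - r.px) / r.ux;
    }
    if (std::fabs(r.uy) < EPS) tyn = 1e30;
    else {
        double yb = ymin + (iy + (sy > 0 ? 1 : 0)) * dy;
        tyn = (yb - r.py) / r.uy;
    }

    double acc = 0.0, t = t0;
    while (t < t1 - EPS) {
        double tn = std::min(std::min(txn, tyn), t1);
        double seg = tn - t;
        if (seg > 0 && ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
            if (mode == 0) acc += img[ix + (size_t)nx * iy] * seg;
            else           img[ix + (size_t)nx * iy] += w * seg;
        }
        bool adv = false;
        if (txn <= tn + EPS && txn < 1e29) { ix += sx; txn += dtx; adv = true; }
        if (tyn <= tn + EPS && tyn < 1e29) { iy += sy; tyn += dty; adv = true; }
        if (!adv && tn >= t1 - EPS) break;
        t = tn;
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
    }
    return acc;
}

// [[Rcpp::export(name = ".cpp_radon_forward")]]
NumericMatrix cpp_radon_forward(NumericMatrix img, double dx, double dy,
                                NumericVector angles, NumericVector svals) {
    int nx = img.nrow(), ny = img.ncol();
    int na = angles.size(), ns = svals.size();
    NumericMatrix out(na, ns);
    double *p = &img(0, 0);
    for (int a = 0; a < na; ++a)
        for (int b = 0; b < ns; ++b)
            out(a, b) = traverse(p, nx, ny, dx, dy, angles[a], svals[b], 0, 0.0);
    return out;
}

// [[Rcpp::export(name = ".cpp_radon_back")]]
NumericMatrix cpp_radon_back(NumericMatrix sino, double dx, double dy,
                             NumericVector angles, NumericVector svals,
                             int nx, int ny) {
    int na = angles.size(), ns = svals.size();
    if (sino.nrow() != na || sino.ncol() != ns)
        stop("sinogram dimensions do not match geometry");
    NumericMatrix img(nx, ny);
    double *p = &img(0, 0);
    for (int a = 0; a < na; ++a)
        for (int b = 0; b < ns; ++b) {
            double w = sino(a, b);
            if (w != 0.0)
                traverse(p, nx, ny, dx, dy, angles[a], svals[b], 1, w);
        }
    return img;
}
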