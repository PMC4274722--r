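#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic quasi-uniform unit-sphere points (Fibonacci spiral).
static std::vector<double> spherePoints(int n) {
    std::vector<double> pts(3 * n);
    const double golden = M_PI * (3.0 - std::sqrt(5.0));
    for (int i = 0; i < n; ++i) {
        double z = 1.0 - (2.0 * i + 1.0) / n;
        double r = std::sqrt(std::max(0.0, 1.0 - z * z));
        double phi = golden * i;
        pts[3 * i] = r * std::cos(phi);
        pts[3 * i + 1] = r * std::sin(phi);
        pts[3 * i + 2] = z;
    }
    return pts;
}

// Shrake-Rupley accessible surface area, one value per atom.
// xyz: n x 3, radii: n (van der Waals), probe: solvent radius,
// npoints: sphere sample size.
// [[Rcpp::export(name = ".cppAsa")]]
NumericVector cppAsa(NumericMatrix xyz, NumericVector radii,
                     double probe, int npoints) {
    int n = xyz.nrow();
    if (n == 0) stop("empty atom list");
    std::vector<double> pts = spherePoints(npoints);
    NumericVector area(n);
    std::vector<int> nbr;
    nbr.reserve(64);
    for (int i = 0; i < n; ++i) {
        double ri = radii[i] + probe;
        double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
        nbr.clear();
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            double rj = radii[j] + probe;
            double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
            double d2 = dx * dx + dy * dy + dz * dz;
            double lim = ri + rj;
            if (d2 < lim * lim) nbr.push_back(j);
        }
        int acc = 0;
        for (int p = 0; p < npoints; ++p) {
            double px = xi + ri * pts[3 * p];
            double py = yi + ri * pts[3 * p + 1];
            double pz = zi + ri * pts[3 * p + 2];
            bool free_pt = true;
            for (size_t k = 0; k < nbr.size(); ++k) {
                int j = nbr[k];
                double rj = radii[j] + probe;
                double dx = xyz(j, 0) - px, dy = xyz(j, 1) - py,
                       dz = xyz(j, 2) - pz;
                if (dx * dx + dy * dy + dz * dz < rj * rj) {
                    free_pt = false;
                    break;
                }
            }
            if (free_pt) ++acc;
        }
        area[i] = 4.0 * M_PI * ri * ri * acc / npoints;
    }
    return area;
}

// Minimum interatomic distance between two coordinate sets.
// [[Rcpp::export(name = ".cppMinDist")]]
double cppMinDist(NumericMatrix a, NumericMatrix b) {
    double best = R_PosInf;
    for (int i = 0; i < a.nrow(); ++i) {
        double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
        for (int j = 0; j < b.nrow(); ++j) {
            double dx = b(j, 0) - xi, dy = b(j, 1) - yi, dz = b(j, 2) - zi;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best) best = d2;
        }
    }
    return std::sqrt(best);
}

// Atom index pairs within cutoff (1-based indices).
// [[Rcpp::export(name = ".cppContactPairs")]]
IntegerMatrix cppContactPairs(NumericMatrix a, NumericMatrix b,
                              double cutoff) {
    double c2 = cutoff * cutoff;
    std::vector<int> ia, ib;
    for (int i = 0; i < a.nrow(); ++i) {
        double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
        for (int j = 0; j < b.nrow(); ++j) {
            double dx = b(j, 0) - xi, dy = b(j, 1) - yi, dz = b(j, 2) - zi;
            if (dx * dx + dy * dy + dz * dz <= c2) {
                ia.push_back(i + 1);
                ib.push_back(j + 1);
            }
        }
    }
    IntegerMatrix out(ia.size(), 2);
    for (size_t k = 0; k < ia.size(); ++k) {
        out(k, 0) = ia[k];
        out(k, 1) = ib[k];
    }
    return out;
}
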