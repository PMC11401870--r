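#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Nearest atom (2D projection) for each query point, via a uniform grid
// index over the atom coordinates. Ties in distance resolve to the lowest
// atom index. Returns 1-based indices.
// [[Rcpp::export(name = ".nearestIndex")]]
IntegerVector nearest_index(NumericVector ax, NumericVector ay,
                            NumericVector px, NumericVector py) {
    const int na = ax.size(), np = px.size();
    if (na == 0) stop("no atoms");
    double xmin = ax[0], xmax = ax[0], ymin = ay[0], ymax = ay[0];
    for (int i = 1; i < na; ++i) {
        if (ax[i] < xmin) xmin = ax[i];
        if (ax[i] > xmax) xmax = ax[i];
        if (ay[i] < ymin) ymin = ay[i];
        if (ay[i] > ymax) ymax = ay[i];
    }
    double span = std::max(xmax - xmin, ymax - ymin);
    if (span <= 0.0) span = 1.0;
    int ncell = (int)std::ceil(std::sqrt((double)na));
    if (ncell < 1) ncell = 1;
    if (ncell > 4096) ncell = 4096;
    const double h = span / ncell * (1.0 + 1e-12);
    const int gx = std::max(1, (int)std::ceil((xmax - xmin) / h));
    const int gy = std::max(1, (int)std::ceil((ymax - ymin) / h));

    // bucket atoms by cell, preserving index order within buckets
    std::vector<int> count((size_t)gx * gy, 0);
    std::vector<int> cellOf(na);
    for (int i = 0; i < na; ++i) {
        int cx = (int)((ax[i] - xmin) / h); if (cx >= gx) cx = gx - 1;
        int cy = (int)((ay[i] - ymin) / h); if (cy >= gy) cy = gy - 1;
        cellOf[i] = cy * gx + cx;
        ++count[cellOf[i]];
    }
    std::vector<int> start((size_t)gx * gy + 1, 0);
    for (size_t c = 0; c < count.size(); ++c) start[c + 1] = start[c] + count[c];
    std::vector<int> items(na);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < na; ++i) items[(size_t)fill[cellOf[i]]++] = i;

    IntegerVector out(np);
    for (int p = 0; p < np; ++p) {
        const double x = px[p], y = py[p];
        int cx = (int)std::floor((x - xmin) / h);
        int cy = (int)std::floor((y - ymin) / h);
        if (cx < 0) cx = 0; if (cx >= gx) cx = gx - 1;
        if (cy < 0) cy = 0; if (cy >= gy) cy = gy - 1;
        double best = R_PosInf;
        int besti = -1;
        const int rmax = std::max(gx, gy);
        for (int r = 0; r <= rmax; ++r) {
            // cells at Chebyshev ring r are at least (r-1)*h away
            if (besti >= 0 && (double)(r - 1) * h > std::sqrt(best)) break;
            const int x0 = std::max(0, cx - r), x1 = std::min(gx - 1, cx + r);
            const int y0 = std::max(0, cy - r), y1 = std::min(gy - 1, cy + r);
            for (int iy = y0; iy <= y1; ++iy) {
                for (int ix = x0; ix <= x1; ++ix) {
                    if (r > 0 && ix != x0 && ix != x1 && iy != y0 && iy != y1)
                        continue;  // interior already visited
                    const int c = iy * gx + ix;
                    for (int k = start[c]; k < start[c + 1]; ++k) {
                        const int i = items[k];
                        const double dx = ax[i] - x, dy = ay[i] - y;
                        const double d2 = dx * dx + dy * dy;
                        if (d2 < best || (d2 == best && i < besti)) {
                            best = d2;
                            besti = i;
                        }
                    }
                }
            }
        }
        out[p] = besti + 1;
    }
    return out;
}

// Hit counting for one energy: points are hits if within radius[nearest]
// of the nearest atom; tallies per category code (1 = nucleotide,
// 2 = water, 0 = other). Returns c(hits_nuc, hits_water).
// [[Rcpp::export(name = ".countHits")]]
IntegerVector count_hits(IntegerVector nearest, NumericVector ax,
                         NumericVector ay, IntegerVector cat,
                         NumericVector radius2, NumericVector px,
                         NumericVector py) {
    int hn = 0, hw = 0;
    const int np = px.size();
    for (int p = 0; p < np; ++p) {
        const int i = nearest[p] - 1;
        const double dx = ax[i] - px[p], dy = ay[i] - py[p];
        if (dx * dx + dy * dy <= radius2[i]) {
            if (cat[i] == 1) ++hn; else if (cat[i] == 2) ++hw;
        }
    }
    IntegerVector out(2);
    out[0] = hn; out[1] = hw;
    return out;
}
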