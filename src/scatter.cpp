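#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Orientationally averaged intensity by the Debye sum:
//   I(Q) = sum_j sum_k f_j f_k sin(Q r_jk)/(Q r_jk),  sinc(0) = 1.
// Exact for isotropic averaging; O(n^2) in atoms, used both as a production
// calculator for small systems and as the reference for the golden-vector
// method.
// [[Rcpp::export(name = ".cppDebye")]]
NumericVector cppDebye(NumericMatrix coords, NumericVector f, NumericVector q) {
    const int n = coords.nrow(), nq = q.size();
    if (f.size() != n) stop("amplitude/coordinate length mismatch");
    NumericVector out(nq);
    double fsum2 = 0.0, f2sum = 0.0;
    for (int j = 0; j < n; ++j) { fsum2 += f[j]; f2sum += f[j] * f[j]; }
    fsum2 *= fsum2;
    // self terms contribute sum f_j^2 at every Q
    for (int iq = 0; iq < nq; ++iq) out[iq] = f2sum;
    for (int j = 0; j < n - 1; ++j) {
        const double xj = coords(j, 0), yj = coords(j, 1), zj = coords(j, 2);
        for (int k = j + 1; k < n; ++k) {
            const double dx = xj - coords(k, 0);
            const double dy = yj - coords(k, 1);
            const double dz = zj - coords(k, 2);
            const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            const double w = 2.0 * f[j] * f[k];
            for (int iq = 0; iq < nq; ++iq) {
                const double x = q[iq] * d;
                out[iq] += (x < 1e-12) ? w : w * std::sin(x) / x;
            }
        }
    }
    // guard against tiny negative round-off at high Q
    for (int iq = 0; iq < nq; ++iq) if (out[iq] < 0 && out[iq] > -1e-9 * fsum2) out[iq] = 0;
    return out;
}

// Golden-vector intensity: average of |sum_j f_j exp(i Q d_m . r_j)|^2 over
// a fixed set of unit directions d_m.
// [[Rcpp::export(name = ".cppGolden")]]
NumericVector cppGolden(NumericMatrix coords, NumericVector f, NumericVector q,
                        NumericMatrix dirs) {
    const int n = coords.nrow(), nq = q.size(), m = dirs.nrow();
    if (f.size() != n) stop("amplitude/coordinate length mismatch");
    NumericVector out(nq);
    std::vector<double> proj(n);
    for (int im = 0; im < m; ++im) {
        const double ux = dirs(im, 0), uy = dirs(im, 1), uz = dirs(im, 2);
        for (int j = 0; j < n; ++j)
            proj[j] = ux * coords(j, 0) + uy * coords(j, 1) + uz * coords(j, 2);
        for (int iq = 0; iq < nq; ++iq) {
            const double qq = q[iq];
            double re = 0.0, im2 = 0.0;
            for (int j = 0; j < n; ++j) {
                const double ph = qq * proj[j];
                re += f[j] * std::cos(ph);
                im2 += f[j] * std::sin(ph);
            }
            out[iq] += re * re + im2 * im2;
        }
    }
    for (int iq = 0; iq < nq; ++iq) out[iq] /= m;
    return out;
}

static inline long long cellKey(int ix, int iy, int iz) {
    // pack three signed 20-bit cell indices into one key
    return ((long long)(ix + 524288) << 40) |
           ((long long)(iy + 524288) << 20) |
           (long long)(iz + 524288);
}

// Steric-clash detection with a cell list (cells of edge `cutoff`, 27-cell
// neighbourhood), near-linear in the number of selected atoms. Pairs within
// the same residue or in sequence-adjacent residues of the same chain are
// excluded. `sel` is 0-based indices of atoms subject to the check;
// `chainId`/`resid` are per-atom (full length). If countAll is false the
// scan stops at the first clashing pair.
// [[Rcpp::export(name = ".cppClash")]]
List cppClash(NumericMatrix coords, IntegerVector sel, double cutoff,
              IntegerVector chainId, IntegerVector resid, bool countAll) {
    const int ns = sel.size();
    if (ns == 0) stop("empty atom selection");
    const double cut2 = cutoff * cutoff;
    std::unordered_map<long long, std::vector<int>> cells;
    cells.reserve(ns * 2);
    std::vector<int> cx(ns), cy(ns), cz(ns);
    for (int a = 0; a < ns; ++a) {
        const int i = sel[a];
        cx[a] = (int)std::floor(coords(i, 0) / cutoff);
        cy[a] = (int)std::floor(coords(i, 1) / cutoff);
        cz[a] = (int)std::floor(coords(i, 2) / cutoff);
        cells[cellKey(cx[a], cy[a], cz[a])].push_back(a);
    }
    long long npairs = 0;
    for (int a = 0; a < ns; ++a) {
        const int i = sel[a];
        const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
        for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dz = -1; dz <= 1; ++dz) {
                    auto it = cells.find(cellKey(cx[a] + dx, cy[a] + dy, cz[a] + dz));
                    if (it == cells.end()) continue;
                    for (int b : it->second) {
                        if (b <= a) continue;  // each pair once
                        const int j = sel[b];
                        if (chainId[i] == chainId[j] &&
                            std::abs(resid[i] - resid[j]) <= 1) continue;
                        const double ddx = xi - coords(j, 0);
                        const double ddy = yi - coords(j, 1);
                        const double ddz = zi - coords(j, 2);
                        if (ddx * ddx + ddy * ddy + ddz * ddz < cut2) {
                            ++npairs;
                            if (!countAll)
                                return List::create(_["clash"] = true,
                                                    _["n_pairs"] = 1);
                        }
                    }
                }
    }
    return List::create(_["clash"] = npairs > 0, _["n_pairs"] = (double)npairs);
}
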