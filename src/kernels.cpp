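// Affine-gap dynamic-programming kernels shared by all aligners.
//
// All kernels operate on a precomputed similarity matrix S (n1 x n2) holding
// the score of pairing position i of the first sequence with position j of
// the second.  This makes the same machinery usable for plain sequences
// (S = substitution matrix indexed by symbol codes) and for profile-profile
// merging in progressive MSA (S = mean pairwise column scores).
//
// Gap model: a gap run of length L costs open + (L - 1) * extend, with
// open <= 0 and extend <= 0 (Gotoh three-state recursion).

#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double NEG = -1e30;

static inline bool feq(double a, double b) {
    return std::fabs(a - b) <= 1e-6;
}

// Three-state Gotoh DP with optional diagonal band and co-optimal traceback.
// States: M = both positions consumed (diagonal), X = gap in the second
// sequence (first consumed), Y = gap in the first sequence.
struct Gotoh {
    int n1, n2;
    const NumericMatrix& S;
    double open, ext;
    bool local, termpen;
    bool banded;
    int dlo, dhi;   // band on diagonals j - i (only used when banded)
    std::vector<double> M, X, Y;
    int maxPaths;
    std::vector< std::vector< std::pair<int,int> > > out;
    std::vector< std::pair<int,int> > cols;   // reversed (end -> start)

    Gotoh(const NumericMatrix& S_, double open_, double ext_,
          bool local_, bool termpen_, bool banded_, int dlo_, int dhi_)
        : n1(S_.nrow()), n2(S_.ncol()), S(S_), open(open_), ext(ext_),
          local(local_), termpen(termpen_), banded(banded_),
          dlo(dlo_), dhi(dhi_),
          M((size_t)(n1 + 1) * (n2 + 1), NEG),
          X((size_t)(n1 + 1) * (n2 + 1), NEG),
          Y((size_t)(n1 + 1) * (n2 + 1), NEG),
          maxPaths(1) {}

    inline size_t id(int i, int j) const {
        return (size_t)i * (n2 + 1) + j;
    }
    inline bool inBand(int i, int j) const {
        if (!banded) return true;
        int d = j - i;
        return d >= dlo && d <= dhi;
    }

    void fill() {
        if (!local) {
            M[id(0, 0)] = 0.0;
            for (int i = 1; i <= n1; ++i) {
                if (!inBand(i, 0)) break;
                X[id(i, 0)] = termpen ? open + (i - 1) * ext : 0.0;
            }
            for (int j = 1; j <= n2; ++j) {
                if (!inBand(0, j)) break;
                Y[id(0, j)] = termpen ? open + (j - 1) * ext : 0.0;
            }
        }
        for (int i = 1; i <= n1; ++i) {
            int jlo = 1, jhi = n2;
            if (banded) {
                jlo = std::max(jlo, i + dlo);
                jhi = std::min(jhi, i + dhi);
            }
            for (int j = jlo; j <= jhi; ++j) {
                double dm = M[id(i - 1, j - 1)];
                double dx = X[id(i - 1, j - 1)];
                double dy = Y[id(i - 1, j - 1)];
                double best = std::max(dm, std::max(dx, dy));
                if (local) best = std::max(best, 0.0);
                if (best > NEG / 2) M[id(i, j)] = S(i - 1, j - 1) + best;

                double xm = M[id(i - 1, j)], xx = X[id(i - 1, j)],
                       xy = Y[id(i - 1, j)];
                double bx = NEG;
                if (xm > NEG / 2) bx = std::max(bx, xm + open);
                if (xx > NEG / 2) bx = std::max(bx, xx + ext);
                if (xy > NEG / 2) bx = std::max(bx, xy + open);
                X[id(i, j)] = bx;

                double ym = M[id(i, j - 1)], yy = Y[id(i, j - 1)],
                       yx = X[id(i, j - 1)];
                double by = NEG;
                if (ym > NEG / 2) by = std::max(by, ym + open);
                if (yy > NEG / 2) by = std::max(by, yy + ext);
                if (yx > NEG / 2) by = std::max(by, yx + open);
                Y[id(i, j)] = by;
            }
        }
    }

    bool full() const { return (int)out.size() >= maxPaths; }

    void emit() {
        if (full()) return;
        out.push_back(std::vector< std::pair<int,int> >(cols.rbegin(),
                                                        cols.rend()));
    }

    // Traceback.  Predecessor preference is diagonal > gap-in-second
    // (consume first sequence) > gap-in-first, which makes the first
    // reported alignment deterministic.
    void tbM(int i, int j) {
        if (full()) return;
        cols.push_back(std::make_pair(i - 1, j - 1));
        double need = M[id(i, j)] - S(i - 1, j - 1);
        int pi = i - 1, pj = j - 1;
        if (pi == 0 && pj == 0) {
            if (feq(need, 0.0)) emit();
        } else {
            if (pi >= 1 && pj >= 1 && feq(M[id(pi, pj)], need)) tbM(pi, pj);
            if (!full() && pi >= 1 && feq(X[id(pi, pj)], need)) tbX(pi, pj);
            if (!full() && pj >= 1 && feq(Y[id(pi, pj)], need)) tbY(pi, pj);
            if (!full() && local && feq(need, 0.0)) emit();
        }
        cols.pop_back();
    }

    void tbX(int i, int j) {   // i >= 1; consumes s1[i-1] against a gap
        if (full()) return;
        cols.push_back(std::make_pair(i - 1, -1));
        if (j == 0) {
            // Remaining prefix of s1 is one terminal gap run; valid under
            // both terminal-penalty conventions (it reproduces the column-0
            // initialization exactly).
            for (int t = i - 2; t >= 0; --t)
                cols.push_back(std::make_pair(t, -1));
            emit();
            for (int t = 0; t <= i - 2; ++t) cols.pop_back();
        } else {
            double v = X[id(i, j)];
            int pi = i - 1;
            if (pi >= 1 && j >= 1 && feq(M[id(pi, j)] + open, v)) tbM(pi, j);
            if (!full() && pi >= 1 && feq(X[id(pi, j)] + ext, v)) tbX(pi, j);
            if (!full() && j >= 1 && feq(Y[id(pi, j)] + open, v)) tbY(pi, j);
        }
        cols.pop_back();
    }

    void tbY(int i, int j) {   // j >= 1; consumes s2[j-1] against a gap
        if (full()) return;
        cols.push_back(std::make_pair(-1, j - 1));
        if (i == 0) {
            for (int t = j - 2; t >= 0; --t)
                cols.push_back(std::make_pair(-1, t));
            emit();
            for (int t = 0; t <= j - 2; ++t) cols.pop_back();
        } else {
            double v = Y[id(i, j)];
            int pj = j - 1;
            if (i >= 1 && pj >= 1 && feq(M[id(i, pj)] + open, v)) tbM(i, pj);
            if (!full() && pj >= 1 && feq(Y[id(i, pj)] + ext, v)) tbY(i, pj);
            if (!full() && i >= 1 && feq(X[id(i, pj)] + open, v)) tbX(i, pj);
        }
        cols.pop_back();
    }

    void traceFrom(int i, int j, int state) {
        if (state == 0) tbM(i, j);
        else if (state == 1) tbX(i, j);
        else tbY(i, j);
    }
};

static IntegerMatrix colsToMatrix(const std::vector< std::pair<int,int> >& v) {
    IntegerMatrix m(v.size(), 2);
    for (size_t r = 0; r < v.size(); ++r) {
        m(r, 0) = v[r].first;
        m(r, 1) = v[r].second;
    }
    return m;
}

// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double open, double ext,
                     bool local, bool termpen,
                     bool banded, int dlo, int dhi, int maxPaths) {
    Gotoh g(S, open, ext, local, termpen, banded, dlo, dhi);
    g.maxPaths = maxPaths;
    g.fill();
    int n1 = g.n1, n2 = g.n2;

    List traces;
    double best = NEG;

    if (local) {
        best = 0.0;
        for (int i = 1; i <= n1; ++i)
            for (int j = 1; j <= n2; ++j) {
                best = std::max(best, g.M[g.id(i, j)]);
                best = std::max(best, g.X[g.id(i, j)]);
                best = std::max(best, g.Y[g.id(i, j)]);
            }
        if (best <= 1e-12) {
            traces.push_back(IntegerMatrix(0, 2));
            return List::create(_["score"] = 0.0, _["traces"] = traces);
        }
        for (int i = 1; i <= n1 && !g.full(); ++i)
            for (int j = 1; j <= n2 && !g.full(); ++j) {
                if (feq(g.M[g.id(i, j)], best)) g.traceFrom(i, j, 0);
                if (!g.full() && feq(g.X[g.id(i, j)], best))
                    g.traceFrom(i, j, 1);
                if (!g.full() && feq(g.Y[g.id(i, j)], best))
                    g.traceFrom(i, j, 2);
            }
    } else if (termpen) {
        if (n1 == 0 && n2 == 0) {
            traces.push_back(IntegerMatrix(0, 2));
            return List::create(_["score"] = 0.0, _["traces"] = traces);
        }
        best = std::max(g.M[g.id(n1, n2)],
                        std::max(g.X[g.id(n1, n2)], g.Y[g.id(n1, n2)]));
        if (feq(g.M[g.id(n1, n2)], best)) g.traceFrom(n1, n2, 0);
        if (!g.full() && feq(g.X[g.id(n1, n2)], best)) g.traceFrom(n1, n2, 1);
        if (!g.full() && feq(g.Y[g.id(n1, n2)], best)) g.traceFrom(n1, n2, 2);
    } else {
        if (n1 == 0 && n2 == 0) {
            traces.push_back(IntegerMatrix(0, 2));
            return List::create(_["score"] = 0.0, _["traces"] = traces);
        }
        // Free terminal gaps: alignment may end anywhere on the last row or
        // column; the remaining residues become unpenalized gap columns.
        std::vector< std::pair<int,int> > cand;
        cand.push_back(std::make_pair(n1, n2));
        for (int i = n1 - 1; i >= 0; --i) cand.push_back(std::make_pair(i, n2));
        for (int j = n2 - 1; j >= 0; --j) cand.push_back(std::make_pair(n1, j));
        for (size_t c = 0; c < cand.size(); ++c) {
            int i = cand[c].first, j = cand[c].second;
            best = std::max(best, g.M[g.id(i, j)]);
            best = std::max(best, g.X[g.id(i, j)]);
            best = std::max(best, g.Y[g.id(i, j)]);
        }
        for (size_t c = 0; c < cand.size() && !g.full(); ++c) {
            int i = cand[c].first, j = cand[c].second;
            // suffix terminal gaps (pushed reversed: end of trace first)
            int nsuf = 0;
            if (j == n2) {
                for (int t = n1 - 1; t >= i; --t, ++nsuf)
                    g.cols.push_back(std::make_pair(t, -1));
            } else {
                for (int t = n2 - 1; t >= j; --t, ++nsuf)
                    g.cols.push_back(std::make_pair(-1, t));
            }
            if (i == 0 && j == 0) {
                // whole alignment is terminal gaps (one sequence empty)
                if (feq(best, 0.0) && nsuf > 0) g.emit();
            } else {
                if (feq(g.M[g.id(i, j)], best)) g.traceFrom(i, j, 0);
                if (!g.full() && feq(g.X[g.id(i, j)], best))
                    g.traceFrom(i, j, 1);
                if (!g.full() && feq(g.Y[g.id(i, j)], best))
                    g.traceFrom(i, j, 2);
            }
            for (int t = 0; t < nsuf; ++t) g.cols.pop_back();
        }
    }

    for (size_t t = 0; t < g.out.size(); ++t)
        traces.push_back(colsToMatrix(g.out[t]));
    return List::create(_["score"] = best, _["traces"] = traces);
}

// Score-only Gotoh with rolling rows (used for E-value score sampling).
// [[Rcpp::export]]
double gotoh_score_cpp(NumericMatrix S, double open, double ext,
                       bool local, bool termpen) {
    int n1 = S.nrow(), n2 = S.ncol();
    std::vector<double> Mp(n2 + 1, NEG), Xp(n2 + 1, NEG), Yp(n2 + 1, NEG);
    std::vector<double> Mc(n2 + 1), Xc(n2 + 1), Yc(n2 + 1);
    double best = local ? 0.0 : NEG;

    if (!local) {
        Mp[0] = 0.0;
        for (int j = 1; j <= n2; ++j)
            Yp[j] = termpen ? open + (j - 1) * ext : 0.0;
        if (!termpen) {
            best = std::max(best, Mp[n2]);
            best = std::max(best, Yp[n2]);
        }
    }
    for (int i = 1; i <= n1; ++i) {
        std::fill(Mc.begin(), Mc.end(), NEG);
        std::fill(Xc.begin(), Xc.end(), NEG);
        std::fill(Yc.begin(), Yc.end(), NEG);
        if (!local)
            Xc[0] = termpen ? open + (i - 1) * ext : 0.0;
        for (int j = 1; j <= n2; ++j) {
            double b = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
            if (local) b = std::max(b, 0.0);
            if (b > NEG / 2) Mc[j] = S(i - 1, j - 1) + b;
            double bx = NEG;
            if (Mp[j] > NEG / 2) bx = std::max(bx, Mp[j] + open);
            if (Xp[j] > NEG / 2) bx = std::max(bx, Xp[j] + ext);
            if (Yp[j] > NEG / 2) bx = std::max(bx, Yp[j] + open);
            Xc[j] = bx;
            double by = NEG;
            if (Mc[j - 1] > NEG / 2) by = std::max(by, Mc[j - 1] + open);
            if (Yc[j - 1] > NEG / 2) by = std::max(by, Yc[j - 1] + ext);
            if (Xc[j - 1] > NEG / 2) by = std::max(by, Xc[j - 1] + open);
            Yc[j] = by;
            if (local)
                best = std::max(best,
                                std::max(Mc[j], std::max(Xc[j], Yc[j])));
        }
        if (!local && !termpen) {
            best = std::max(best, Mc[n2]);
            best = std::max(best, Xc[n2]);
            best = std::max(best, Yc[n2]);
        }
        Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
    }
    if (!local) {
        if (termpen) {
            best = std::max(Mp[n2], std::max(Xp[n2], Yp[n2]));
        } else {
            for (int j = 0; j <= n2; ++j) {
                best = std::max(best, Mp[j]);
                best = std::max(best, Xp[j]);
                best = std::max(best, Yp[j]);
            }
        }
    }
    return best;
}

// Gapped X-drop extension in one direction.  The seed pair is cell (1,1),
// i.e. S(0,0) scores the seed column itself.  Cells whose best state value
// falls more than X below the best score seen so far are pruned (set to
// NEG) and never extended.  Returns the best score, and the trace of the
// best path from the seed to the best end point in relative 0-based
// coordinates (-1 = gap).
// [[Rcpp::export]]
List xdrop_extend_cpp(NumericMatrix S, double open, double ext, double X) {
    int n1 = S.nrow(), n2 = S.ncol();
    if (n1 < 1 || n2 < 1) stop("seed outside the similarity matrix");
    std::vector<double> M((size_t)(n1 + 1) * (n2 + 1), NEG);
    std::vector<double> Gx(M.size(), NEG), Gy(M.size(), NEG);
    size_t nc = n2 + 1;
    #define ID(i, j) ((size_t)(i) * nc + (j))

    M[ID(1, 1)] = S(0, 0);
    double bestSeen = S(0, 0);
    double best = S(0, 0);
    int bi = 1, bj = 1, bstate = 0;

    for (int i = 1; i <= n1; ++i) {
        for (int j = 1; j <= n2; ++j) {
            if (i == 1 && j == 1) continue;
            double dm = M[ID(i - 1, j - 1)], dx = Gx[ID(i - 1, j - 1)],
                   dy = Gy[ID(i - 1, j - 1)];
            double b = std::max(dm, std::max(dx, dy));
            double m = (b > NEG / 2) ? S(i - 1, j - 1) + b : NEG;
            double bx = NEG;
            if (M[ID(i - 1, j)] > NEG / 2)
                bx = std::max(bx, M[ID(i - 1, j)] + open);
            if (Gx[ID(i - 1, j)] > NEG / 2)
                bx = std::max(bx, Gx[ID(i - 1, j)] + ext);
            if (Gy[ID(i - 1, j)] > NEG / 2)
                bx = std::max(bx, Gy[ID(i - 1, j)] + open);
            double by = NEG;
            if (M[ID(i, j - 1)] > NEG / 2)
                by = std::max(by, M[ID(i, j - 1)] + open);
            if (Gy[ID(i, j - 1)] > NEG / 2)
                by = std::max(by, Gy[ID(i, j - 1)] + ext);
            if (Gx[ID(i, j - 1)] > NEG / 2)
                by = std::max(by, Gx[ID(i, j - 1)] + open);
            double cb = std::max(m, std::max(bx, by));
            if (cb < NEG / 2) continue;
            if (R_finite(X) && cb < bestSeen - X) continue;   // pruned
            M[ID(i, j)] = m; Gx[ID(i, j)] = bx; Gy[ID(i, j)] = by;
            if (cb > bestSeen) bestSeen = cb;
            if (m > best)  { best = m;  bi = i; bj = j; bstate = 0; }
            if (bx > best) { best = bx; bi = i; bj = j; bstate = 1; }
            if (by > best) { best = by; bi = i; bj = j; bstate = 2; }
        }
    }

    // Single deterministic traceback (M > X > Y preference).
    std::vector< std::pair<int,int> > cols;
    int i = bi, j = bj, state = bstate;
    while (!(i == 1 && j == 1 && state == 0)) {
        if (state == 0) {
            cols.push_back(std::make_pair(i - 1, j - 1));
            double need = M[ID(i, j)] - S(i - 1, j - 1);
            int pi = i - 1, pj = j - 1;
            if (feq(M[ID(pi, pj)], need)) state = 0;
            else if (feq(Gx[ID(pi, pj)], need)) state = 1;
            else if (feq(Gy[ID(pi, pj)], need)) state = 2;
            else stop("X-drop traceback failed");
            i = pi; j = pj;
        } else if (state == 1) {
            cols.push_back(std::make_pair(i - 1, -1));
            double v = Gx[ID(i, j)];
            int pi = i - 1;
            if (feq(M[ID(pi, j)] + open, v)) state = 0;
            else if (feq(Gx[ID(pi, j)] + ext, v)) state = 1;
            else if (feq(Gy[ID(pi, j)] + open, v)) state = 2;
            else stop("X-drop traceback failed");
            i = pi;
        } else {
            cols.push_back(std::make_pair(-1, j - 1));
            double v = Gy[ID(i, j)];
            int pj = j - 1;
            if (feq(M[ID(i, pj)] + open, v)) state = 0;
            else if (feq(Gy[ID(i, pj)] + ext, v)) state = 2;
            else if (feq(Gx[ID(i, pj)] + open, v)) state = 1;
            else stop("X-drop traceback failed");
            j = pj;
        }
    }
    cols.push_back(std::make_pair(0, 0));   // the seed column
    std::reverse(cols.begin(), cols.end());
    #undef ID
    return List::create(_["score"] = best, _["trace"] = colsToMatrix(cols));
}
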