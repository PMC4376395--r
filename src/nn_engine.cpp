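#include <Rcpp.h>
using namespace Rcpp;

// Simplified nearest-neighbor secondary-structure engine.
//
// Model: pseudoknot-free structures over one strand (or two strands joined at
// a nick); Watson-Crick and G.U wobble pairs; the only energy terms are the
// published stacking free energies between directly adjacent pairs (i,j) and
// (i+1,j-1). Isolated pairs and all loops contribute 0. Minimum hairpin loop
// of `minLoop` unpaired bases applies within a strand; pairs across the nick
// are exempt. Stacks spanning the nick are not scored (the backbone is
// interrupted). An optional maximum pairing span emulates windowed (local)
// folding.
//
// Bases are encoded 0=A, 1=C, 2=G, 3=U. The 6x6 stack matrix is indexed by
// pair type (CG, GC, GU, UG, AU, UA) of (seq[i], seq[j]) x (seq[j-1], seq[i+1]).

static const double INF = 1e9;

static inline int pairType(int a, int b) {
    // 1=CG 2=GC 3=GU 4=UG 5=AU 6=UA, 0 = not a pair
    if (a == 1 && b == 2) return 1;
    if (a == 2 && b == 1) return 2;
    if (a == 2 && b == 3) return 3;
    if (a == 3 && b == 2) return 4;
    if (a == 0 && b == 3) return 5;
    if (a == 3 && b == 0) return 6;
    return 0;
}

struct Engine {
    const IntegerVector &s;
    int n, nick, minLoop, maxspan, banned;
    const NumericMatrix &st;

    Engine(const IntegerVector &seq, int nick_, int minLoop_,
           const NumericMatrix &stack, int maxspan_, int banned_)
        : s(seq), n(seq.size()), nick(nick_), minLoop(minLoop_),
          maxspan(maxspan_), banned(banned_), st(stack) {}

    bool crossesNick(int i, int j) const {
        return nick > 0 && i < nick && j >= nick;
    }
    bool canPair(int i, int j) const {
        if (i == banned || j == banned) return false;
        if (pairType(s[i], s[j]) == 0) return false;
        if (!crossesNick(i, j) && (j - i - 1) < minLoop) return false;
        if (maxspan > 0 && (j - i) > maxspan) return false;
        return true;
    }
    // stack between (i,j) and (i+1,j-1); 0 when a backbone nick interrupts it
    double stackE(int i, int j) const {
        if (nick > 0 && (i + 1 == nick || j == nick)) return 0.0;
        int p1 = pairType(s[i], s[j]);
        int p2 = pairType(s[j - 1], s[i + 1]);
        if (p1 == 0 || p2 == 0) return 0.0;
        return st(p1 - 1, p2 - 1);
    }

    double mfe() const {
        if (n < 2) return 0.0;
        std::vector<double> V(n * n, INF), W(n * n, 0.0), Wno(n * n, 0.0);
        // iterate by increasing span
        for (int span = 1; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                // V(i,j): minimum energy given (i,j) paired
                double v = INF;
                if (canPair(i, j)) {
                    if (j - 1 < i + 1) {
                        v = 0.0; // empty interior (possible across the nick)
                    } else {
                        double opt1 = INF;
                        if (canPair(i + 1, j - 1))
                            opt1 = stackE(i, j) + V[(i + 1) * n + (j - 1)];
                        double opt2 = Wno[(i + 1) * n + (j - 1)];
                        v = std::min(opt1, opt2);
                    }
                }
                V[i * n + j] = v;
                // W(i,j) and Wno(i,j)
                double w = (i + 1 <= j) ? W[(i + 1) * n + j] : 0.0;
                double wno = w;
                for (int k = i + 1; k <= j; ++k) {
                    if (!canPair(i, k)) continue;
                    double rest = (k + 1 <= j) ? W[(k + 1) * n + j] : 0.0;
                    double cand = V[i * n + k] + rest;
                    if (cand < w) w = cand;
                    if (k < j && cand < wno) wno = cand;
                }
                W[i * n + j] = w;
                Wno[i * n + j] = wno;
            }
        }
        return W[0 * n + (n - 1)];
    }

    double partition(double kT) const {
        if (n < 2) return 1.0;
        std::vector<double> Zb(n * n, 0.0), Z(n * n, 1.0);
        for (int span = 1; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                double zb = 0.0;
                if (canPair(i, j)) {
                    if (j - 1 <= i + 1) {
                        zb = 1.0; // interior empty or a single base
                    } else {
                        double zin = Z[(i + 1) * n + (j - 1)];
                        double zbin = Zb[(i + 1) * n + (j - 1)];
                        zb = std::exp(-stackE(i, j) / kT) * zbin + (zin - zbin);
                    }
                }
                Zb[i * n + j] = zb;
                double z = (i + 1 <= j) ? Z[(i + 1) * n + j] : 1.0;
                for (int k = i + 1; k <= j; ++k) {
                    if (Zb[i * n + k] == 0.0) continue;
                    double rest = (k + 1 <= j) ? Z[(k + 1) * n + j] : 1.0;
                    z += Zb[i * n + k] * rest;
                }
                Z[i * n + j] = z;
            }
        }
        return Z[0 * n + (n - 1)];
    }
};

// [[Rcpp::export(name = "c_nn_mfe")]]
double c_nn_mfe(IntegerVector seq, int nick, int minLoop,
                NumericMatrix stack, int maxspan) {
    Engine e(seq, nick, minLoop, stack, maxspan, -1);
    return e.mfe();
}

// [[Rcpp::export(name = "c_nn_partition")]]
double c_nn_partition(IntegerVector seq, int nick, int minLoop,
                      NumericMatrix stack, double kT, int maxspan) {
    Engine e(seq, nick, minLoop, stack, maxspan, -1);
    return e.partition(kT);
}

// Per-base unpaired probabilities: P(m unpaired) = Z[m banned] / Z.
// [[Rcpp::export(name = "c_nn_unpaired")]]
NumericVector c_nn_unpaired(IntegerVector seq, int minLoop,
                            NumericMatrix stack, double kT, int maxspan) {
    int n = seq.size();
    NumericVector out(n);
    Engine base(seq, 0, minLoop, stack, maxspan, -1);
    double Z = base.partition(kT);
    for (int m = 0; m < n; ++m) {
        Engine e(seq, 0, minLoop, stack, maxspan, m);
        out[m] = e.partition(kT) / Z;
    }
    return out;
}
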