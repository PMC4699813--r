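#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Normalized Hill transfer: f(x) = x^n (1 + k^n) / (x^n + k^n), f(0)=0, f(1)=1.
static inline double hillT(double x, double k, double n) {
    if (x <= 0.0) return 0.0;
    double xn = std::pow(x, n), kn = std::pow(k, n);
    return xn * (1.0 + kn) / (xn + kn);
}

// Steady-state evaluation of one model over all conditions.
// Species are visited in topological order; clamped species take the clamp
// value; a gate's output is min over input contributions (AND), a species'
// state is max over its active gates (OR), or the constitutive baseline when
// no gate is active.
static void evalStates(const std::vector<int> &topo,
                       const IntegerVector &gateTarget,
                       const IntegerVector &gateOff,
                       const IntegerVector &inputSrc,
                       const IntegerVector &inputSign,
                       const std::vector<char> &active,
                       const std::vector<double> &kGate,
                       const std::vector<double> &nGate,
                       const NumericVector &baseline,
                       const NumericMatrix &clamp,
                       const std::vector<std::vector<int> > &gatesOf,
                       NumericMatrix &states) {
    const int nCond = clamp.ncol();
    for (int c = 0; c < nCond; ++c) {
        for (size_t t = 0; t < topo.size(); ++t) {
            const int s = topo[t];
            const double cl = clamp(s, c);
            if (!ISNAN(cl)) { states(s, c) = cl; continue; }
            double best = -1.0;
            const std::vector<int> &gs = gatesOf[s];
            for (size_t j = 0; j < gs.size(); ++j) {
                const int gi = gs[j];
                if (!active[gi]) continue;
                double gmin = 1.0;
                for (int ii = gateOff[gi]; ii < gateOff[gi + 1]; ++ii) {
                    const double x = states(inputSrc[ii], c);
                    const double f = hillT(x, kGate[gi], nGate[gi]);
                    const double contrib = inputSign[ii] > 0 ? f : 1.0 - f;
                    if (contrib < gmin) gmin = contrib;
                }
                if (gmin > best) best = gmin;
            }
            states(s, c) = best >= 0.0 ? best : baseline[s];
        }
    }
}

static std::vector<std::vector<int> > gateIndex(const IntegerVector &gateTarget,
                                                int nSpecies) {
    std::vector<std::vector<int> > gatesOf(nSpecies);
    for (int g = 0; g < gateTarget.size(); ++g)
        gatesOf[gateTarget[g]].push_back(g);
    return gatesOf;
}

static std::vector<int> asStd(const IntegerVector &v) {
    return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(IntegerVector gateTarget, IntegerVector gateOff,
                           IntegerVector inputSrc, IntegerVector inputSign,
                           NumericVector kGate, NumericVector nGate,
                           NumericVector baseline, NumericMatrix clamp,
                           IntegerVector topo) {
    const int nSpecies = clamp.nrow();
    NumericMatrix states(nSpecies, clamp.ncol());
    std::vector<char> active(gateTarget.size(), 1);
    std::vector<double> kv(kGate.begin(), kGate.end());
    std::vector<double> nv(nGate.begin(), nGate.end());
    evalStates(asStd(topo), gateTarget, gateOff, inputSrc, inputSign, active,
               kv, nv, baseline, clamp, gateIndex(gateTarget, nSpecies),
               states);
    return states;
}

// Pooled MSE over donors from sufficient statistics per (gene, condition):
// cnt = number of non-missing donor values, sm = their sum, ssq = their sum
// of squares. MSE = sum(cnt*p^2 - 2*p*sm + ssq) / sum(cnt).
static double mseFromStates(const NumericMatrix &states,
                            const IntegerVector &geneSpecies,
                            const NumericMatrix &cnt, const NumericMatrix &sm,
                            const NumericMatrix &ssq) {
    double num = 0.0, den = 0.0;
    for (int g = 0; g < geneSpecies.size(); ++g) {
        const int s = geneSpecies[g];
        for (int c = 0; c < cnt.ncol(); ++c) {
            const double n = cnt(g, c);
            if (n <= 0.0) continue;
            const double p = states(s, c);
            num += n * p * p - 2.0 * p * sm(g, c) + ssq(g, c);
            den += n;
        }
    }
    return den > 0.0 ? num / den : NA_REAL;
}

// One MSE per genome row. A genome assigns each candidate gate either 0
// (inactive) or a 1-based index into the (kGrid, nGrid) parameter grid.
// [[Rcpp::export]]
NumericVector cpp_mse_genomes(IntegerMatrix genomes, NumericVector kGrid,
                              NumericVector nGrid, IntegerVector gateTarget,
                              IntegerVector gateOff, IntegerVector inputSrc,
                              IntegerVector inputSign, NumericVector baseline,
                              NumericMatrix clamp, IntegerVector topo,
                              IntegerVector geneSpecies, NumericMatrix cnt,
                              NumericMatrix sm, NumericMatrix ssq) {
    const int nSpecies = clamp.nrow(), G = gateTarget.size();
    const std::vector<std::vector<int> > gatesOf =
        gateIndex(gateTarget, nSpecies);
    const std::vector<int> topoV = asStd(topo);
    NumericMatrix states(nSpecies, clamp.ncol());
    NumericVector out(genomes.nrow());
    std::vector<char> active(G);
    std::vector<double> kv(G), nv(G);
    for (int r = 0; r < genomes.nrow(); ++r) {
        for (int g = 0; g < G; ++g) {
            const int code = genomes(r, g);
            active[g] = code > 0;
            if (code > 0) {
                kv[g] = kGrid[code - 1];
                nv[g] = nGrid[code - 1];
            }
        }
        evalStates(topoV, gateTarget, gateOff, inputSrc, inputSign, active,
                   kv, nv, baseline, clamp, gatesOf, states);
        out[r] = mseFromStates(states, geneSpecies, cnt, sm, ssq);
    }
    return out;
}

// One MSE per row of an activity matrix, with fixed per-gate parameters
// (used by model reduction, where parameters are frozen and only gate
// membership varies).
// [[Rcpp::export]]
NumericVector cpp_mse_active(IntegerMatrix activeMat, NumericVector kGate,
                             NumericVector nGate, IntegerVector gateTarget,
                             IntegerVector gateOff, IntegerVector inputSrc,
                             IntegerVector inputSign, NumericVector baseline,
                             NumericMatrix clamp, IntegerVector topo,
                             IntegerVector geneSpecies, NumericMatrix cnt,
                             NumericMatrix sm, NumericMatrix ssq) {
    const int nSpecies = clamp.nrow(), G = gateTarget.size();
    const std::vector<std::vector<int> > gatesOf =
        gateIndex(gateTarget, nSpecies);
    const std::vector<int> topoV = asStd(topo);
    NumericMatrix states(nSpecies, clamp.ncol());
    NumericVector out(activeMat.nrow());
    std::vector<char> active(G);
    std::vector<double> kv(kGate.begin(), kGate.end());
    std::vector<double> nv(nGate.begin(), nGate.end());
    for (int r = 0; r < activeMat.nrow(); ++r) {
        for (int g = 0; g < G; ++g) active[g] = activeMat(r, g) > 0;
        evalStates(topoV, gateTarget, gateOff, inputSrc, inputSign, active,
                   kv, nv, baseline, clamp, gatesOf, states);
        out[r] = mseFromStates(states, geneSpecies, cnt, sm, ssq);
    }
    return out;
}
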